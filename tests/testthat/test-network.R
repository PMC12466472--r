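test_that("network genus filters apply strict / inclusive thresholds", {
  n <- 100
  rel <- cbind(common = runif(n, 0.1, 0.2),          # passes both
               rare = c(runif(49, 0.1, 0.2), rep(0, 51)),  # prevalence 0.49
               thin = rep(0.001, n),                 # mean exactly 0.001
               ok50 = c(runif(50, 0.1, 0.2), rep(0, 50)))  # prevalence 0.50
  counts <- round(rel / rowSums(rel) * 1e5)
  tab <- abundance_table(counts)
  sel <- select_network_genera(tab)
  expect_true("common" %in% sel)
  expect_false("rare" %in% sel)   # 49% < 50%
  expect_true("ok50" %in% sel)    # 50% inclusive
  # mean exactly at the floor is excluded (strict >) - check on raw matrix
  sel2 <- select_network_genera(abundance_table(
    cbind(a = rep(1000, 10), b = rep(1, 10))), mean_rel_min = 1 / 1001)
  expect_false("b" %in% sel2)
})

test_that("partial correlation removes indirect association", {
  set.seed(40)
  n <- 1000
  z <- rnorm(n)
  X <- cbind(x = z + rnorm(n), y = z + rnorm(n), z = z)
  sp <- spearman_partial_matrix(X)
  # x and y are conditionally independent given z
  expect_lt(abs(sp$r["x", "y"]), 0.1)
  # but x and z remain strongly partially correlated
  expect_gt(sp$r["x", "z"], 0.4)
  expect_equal(sp$r, t(sp$r), tolerance = 1e-12)
  expect_equal(unname(diag(sp$r)), rep(1, 3))
  expect_equal(sp$df, n - 3)

  # duplicated column triggers the pseudo-inverse path with a warning
  expect_warning(spearman_partial_matrix(cbind(X, x2 = X[, "x"])),
                 "pseudo-inverse")
})

test_that("build_network keeps exactly the BH-surviving edges", {
  ids <- paste0("g", 1:5)
  p <- matrix(1, 5, 5, dimnames = list(ids, ids))
  r <- matrix(0.1, 5, 5, dimnames = list(ids, ids)); diag(r) <- 1
  net0 <- build_network(r, p)
  expect_equal(nrow(net0$edges), 0)

  p["g2", "g4"] <- p["g4", "g2"] <- 1e-10
  net1 <- build_network(r, p)
  expect_equal(nrow(net1$edges), 1)
  expect_equal(net1$edges$a, "g2")
  expect_equal(net1$edges$b, "g4")
  expect_equal(net1$nodes, c("g2", "g4"))

  # column order invariance
  perm <- c(3, 1, 5, 2, 4)
  net2 <- build_network(r[perm, perm], p[perm, perm])
  expect_equal(net2$edges, net1$edges)
})

test_that("topology metrics match igraph ground truths", {
  mk_net <- function(edges) {
    structure(list(label = NULL,
                   nodes = sort(unique(c(edges[, 1], edges[, 2]))),
                   edges = data.frame(a = edges[, 1], b = edges[, 2],
                                      r = 0.5, p = 0.01, q = 0.01,
                                      stringsAsFactors = FALSE),
                   n_tested = nrow(edges)), class = "co_network")
  }
  k4 <- t(combn(paste0("v", 1:4), 2))
  tk4 <- network_topology(mk_net(k4))
  expect_equal(tk4$clustering_coefficient, 1)
  expect_equal(tk4$average_distance, 1)
  p3 <- cbind(c("a", "b"), c("b", "c"))
  tp3 <- network_topology(mk_net(p3))
  expect_equal(tp3$clustering_coefficient, 0)
  star <- cbind(rep("hub", 5), paste0("leaf", 1:5))
  ts <- network_topology(mk_net(star))
  expect_equal(unname(which.max(ts$degree)),
               unname(which(names(ts$degree) == "hub")))
  expect_equal(unname(which.max(ts$betweenness)),
               unname(which(names(ts$betweenness) == "hub")))
})

test_that("edge taxonomy partitions generalists with direction precedence", {
  e1 <- data.frame(a = c("A", "A", "B", "C"), b = c("B", "C", "D", "E"),
                   r = c(-0.21, 0.50, 0.60, 0.30),
                   p = 0.001, q = 0.001, stringsAsFactors = FALSE)
  e2 <- data.frame(a = c("A", "A", "B", "D"), b = c("B", "C", "D", "E"),
                   r = c(0.13, 0.45, 0.30, -0.2),
                   p = 0.001, q = 0.001, stringsAsFactors = FALSE)
  n1 <- structure(list(label = "E1", nodes = unique(c(e1$a, e1$b)),
                       edges = e1, n_tested = 10), class = "co_network")
  n2 <- structure(list(label = "E2", nodes = unique(c(e2$a, e2$b)),
                       edges = e2, n_tested = 10), class = "co_network")
  cls <- classify_generalist_edges(n1, n2)
  row <- function(a, b) cls[cls$a == a & cls$b == b, ]
  expect_equal(row("A", "B")$generalist_class, "direction_change")
  expect_equal(row("A", "C")$generalist_class, "stable")       # |0.50-0.45| < 0.2
  expect_equal(row("B", "D")$generalist_class, "strength_change") # |0.6-0.3| > 0.2
  expect_equal(row("C", "E")$status, "specialist_E1")
  expect_equal(row("D", "E")$status, "specialist_E2")
  # partition: specialist + generalist classes exhaust all pairs
  gen <- cls[cls$status == "generalist", ]
  expect_false(any(is.na(gen$generalist_class)))
  expect_true(all(is.na(cls$generalist_class[cls$status != "generalist"])))
  expect_equal(nrow(gen) + sum(cls$status != "generalist"), nrow(cls))

  # absolute-magnitude reading via flag
  cls2 <- classify_generalist_edges(n1, n2, on_signed = FALSE)
  expect_equal(cls2[cls2$a == "B" & cls2$b == "D", ]$generalist_class,
               "strength_change")
})

test_that("node sign profile splits degree into positive and negative", {
  e <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                  r = c(0.5, -0.4, 0.3), p = 0.001, q = 0.001,
                  stringsAsFactors = FALSE)
  net <- structure(list(label = NULL, nodes = c("A", "B", "C"), edges = e,
                        n_tested = 3), class = "co_network")
  prof <- node_sign_profile_and_key_taxa(net, top_n = 2)$profile
  expect_equal(prof$n_pos + prof$n_neg, prof$degree)
  a <- prof[prof$node == "A", ]
  expect_equal(c(a$n_pos, a$n_neg), c(1L, 1L))
  expect_equal(a$log10_neg_pos, 0)
  b <- prof[prof$node == "B", ]
  expect_true(is.na(b$log10_neg_pos)) # all-positive node: ratio undefined
  key <- node_sign_profile_and_key_taxa(net, top_n = 1)$key_taxa
  expect_equal(key, "A") # degree tie broken alphabetically
})
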