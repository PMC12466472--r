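# shared fixtures and small oracles, built in code at test time

# Rand index between two partitions (pair-counting, brute force)
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    same_a <- a[i] == a[(i + 1):n]
    same_b <- b[i] == b[(i + 1):n]
    agree <- agree + sum(same_a == same_b)
  }
  agree / choose(n, 2)
}

# small deterministic count table used across community tests
small_counts <- function() {
  m <- matrix(c(10, 10, 10, 10,
                40,  0,  0,  0,
                 5, 15, 20, 10,
                 0,  0, 25, 25), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("S", 1:4), paste0("g", 1:4)))
  abundance_table(m)
}

two_cluster_cfg <- function(seed = 11, n = 120) {
  sim_config(n_samples = n, n_genera = 40, seed = seed)
}
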