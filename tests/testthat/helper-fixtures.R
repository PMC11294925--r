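# Shared fixtures and independent oracles, all built in code.

# brute-force dynamic-programming oracle for the query-global /
# reference-ends-free unit-cost edit distance (independent of the compiled
# kernel)
feg_oracle <- function(q, r) {
  m <- nchar(q); n <- nchar(r)
  qq <- strsplit(q, "")[[1]]; rr <- strsplit(r, "")[[1]]
  D <- matrix(0, m + 1, n + 1)
  D[, 1] <- 0:m
  D[1, ] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- as.integer(qq[i] != rr[j] & qq[i] != "N" & rr[j] != "N")
      D[i + 1, j + 1] <- min(D[i, j] + sub, D[i, j + 1] + 1, D[i + 1, j] + 1)
    }
  }
  min(D[m + 1, ])
}

# small cohort configuration: same structure as the default design but a
# fraction of its size, for fast end-to-end tests
small_sim_config <- function(seed = 1L, ...) {
  n <- matrix(4L, 2, 5,
              dimnames = list(c("site1", "site2"), reef_habitats()))
  sim_config(site_names = c("site1", "site2"), n_per_cell = n, seed = seed,
             ...)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# all permutations of seq_len(n) as a list (test-local, independent of the
# package's enumerator)
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(perms_oracle(n - 1L), function(p) {
    lapply(seq_len(n), function(pos) append(p, n, after = pos - 1L))
  }))
}
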