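test_that("Levins breadth hits its boundary and hand-computed values", {
  conc <- levins_breadth(c(1, 0, 0, 0, 0), R = 5)
  expect_equal(conc$B, 1)
  expect_equal(conc$B_A, 0)
  unif <- levins_breadth(rep(0.2, 5), R = 5)
  expect_equal(unif$B, 5)
  expect_equal(unif$B_A, 1)
  mid <- levins_breadth(c(0.5, 0.3, 0.2), R = 5)
  expect_equal(mid$B, 1 / 0.38)          # 2.6316
  expect_equal(mid$B_A, (1 / 0.38 - 1) / 4)  # 0.4079
  expect_error(levins_breadth(c(0, 0)), "zero")
  expect_error(levins_breadth(1, R = 1), "R = 1")
  expect_error(levins_breadth(c(0.7, 0.2), R = 5), "sum to 1")
})

test_that("breadth is standardised and permutation-invariant on random vectors", {
  set.seed(19)
  for (i in 1:50) {
    R <- sample(2:30, 1)
    p <- rgamma(R, 1); p <- p / sum(p)
    b <- levins_breadth(p, R)
    expect_gte(b$B_A, 0)
    expect_lte(b$B_A, 1)
    expect_equal(levins_breadth(sample(p), R)$B_A, b$B_A, tolerance = 1e-12)
  }
})

test_that("habitat breadth handles single-habitat and uniform species", {
  calls <- data.frame(
    species = c(rep("A", 10), rep("B", 25)),
    habitat = c(rep("fringing", 10), rep(reef_habitats(), times = 5)),
    site = "site1")
  hb <- habitat_breadth(calls)
  expect_equal(hb$B_A[hb$species == "A"], 0)
  expect_equal(hb$B_A[hb$species == "B"], 1)
  expect_true(all(hb$R == 5))
  hb_site <- habitat_breadth(calls, per_site = TRUE)
  expect_identical(unique(hb_site$context), "site1")
})

test_that("habitat breadth recovers the generating distribution", {
  w <- species_habitat_counts()
  cfg <- sim_config(n_per_cell = matrix(3000L, 1, 5,
                                        dimnames = list("site1",
                                                        reef_habitats())),
                    site_names = "site1", seed = 51)
  sim <- simulate_colonies(cfg, generate_reference_panel(seed = 51))
  calls <- data.frame(species = sim$metadata$true_species,
                      habitat = sim$metadata$habitat)
  hb <- habitat_breadth(calls)
  # truth: expected habitat profile of each species given equal per-habitat
  # draws is proportional to its share of each habitat column
  shares <- sweep(w, 2, colSums(w), "/")
  for (sp in rownames(w)) {
    p_true <- shares[sp, ] / sum(shares[sp, ])
    truth <- levins_breadth(as.numeric(p_true), R = 5)$B_A
    est <- hb$B_A[hb$species == sp]
    expect_lt(abs(est - truth), 0.06)
  }
})

test_that("symbiont breadth evaluates the formula per colony", {
  m <- rbind(one = c(1000, 0, 0), even = c(50, 50, 50))
  colnames(m) <- c("C1", "C2", "C3")
  sb <- symbiont_breadth(m)
  expect_equal(sb$B_A[sb$context == "one"], 0)
  expect_equal(sb$B_A[sb$context == "even"], 1)
  # shares (0.9, 0.1) in a 475-column dataset
  wide <- matrix(0L, 1, 475, dimnames = list("w", paste0("C", 1:475)))
  wide[1, 1] <- 900L; wide[1, 2] <- 100L
  sbw <- symbiont_breadth(wide)
  expect_equal(sbw$B, 1 / 0.82, tolerance = 1e-12)           # 1.2195
  expect_equal(sbw$B_A, (1 / 0.82 - 1) / 474, tolerance = 1e-12) # 4.63e-4
  # zero-total colonies are skipped
  m0 <- rbind(m, zero = c(0, 0, 0))
  expect_identical(nrow(symbiont_breadth(m0)), 2L)
})

test_that("Horn-Morisita matches its formula on boundary and hand cases", {
  expect_equal(horn_morisita(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1)
  expect_equal(horn_morisita(c(1, 0), c(0, 1)), 0)
  expect_equal(horn_morisita(c(1, 0), c(0.5, 0.5)), 2 / 3)
  expect_error(horn_morisita(c(1, 0), c(1, 0, 0)), "equal length")
  expect_error(horn_morisita(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("overlap is symmetric and invariant to simultaneous state reordering", {
  set.seed(29)
  for (i in 1:25) {
    R <- sample(3:10, 1)
    p <- rgamma(R, 1); p <- p / sum(p)
    q <- rgamma(R, 1); q <- q / sum(q)
    expect_equal(horn_morisita(p, q), horn_morisita(q, p), tolerance = 1e-14)
    o <- sample(R)
    expect_equal(horn_morisita(p[o], q[o]), horn_morisita(p, q),
                 tolerance = 1e-14)
  }
})

test_that("the overlap matrix matches direct recomputation on a toy table", {
  counts <- list(A = c(10, 5, 0, 0, 0), B = c(2, 8, 10, 0, 0),
                 C = c(0, 0, 5, 5, 10))
  calls <- do.call(rbind, lapply(names(counts), function(sp) {
    data.frame(species = sp,
               habitat = rep(reef_habitats(), times = counts[[sp]]))
  }))
  ov <- overlap_matrix(calls)
  expect_identical(nrow(ov), 6L)   # all ordered pairs
  for (r in seq_len(nrow(ov))) {
    pj <- counts[[ov$species_j[r]]] / sum(counts[[ov$species_j[r]]])
    pk <- counts[[ov$species_k[r]]] / sum(counts[[ov$species_k[r]]])
    direct <- 2 * sum(pj * pk) / (sum(pj^2) + sum(pk^2))
    expect_equal(ov$C_H[r], direct, tolerance = 1e-12)
  }
  # identical habitat distributions overlap completely, both orientations
  calls2 <- rbind(calls, transform(calls[calls$species == "A", ],
                                   species = "D"))
  ov2 <- overlap_matrix(calls2)
  expect_equal(ov2$C_H[ov2$species_j == "A" & ov2$species_k == "D"], 1)
  expect_equal(ov2$C_H[ov2$species_j == "D" & ov2$species_k == "A"], 1)
})

test_that("per-site overlap emits one value per pair per site", {
  calls <- expand.grid(species = c("A", "B"), habitat = reef_habitats(),
                       site = reef_sites(), stringsAsFactors = FALSE)
  ov <- overlap_matrix(calls, per_site = TRUE)
  expect_identical(nrow(ov), 2L * 4L)
  expect_setequal(unique(ov$context), reef_sites())
})

test_that("breadth correlation is exact by rank enumeration for few species", {
  hb <- data.frame(species = letters[1:6], B_A = (1:6) / 10)
  sb_conc <- data.frame(species = letters[1:6], B_A = (1:6) / 100)
  conc <- breadth_correlation(hb, sb_conc)
  expect_equal(conc$rho, 1)
  expect_true(conc$exact)
  sb_anti <- data.frame(species = letters[1:6], B_A = (6:1) / 100)
  expect_equal(breadth_correlation(hb, sb_anti)$rho, -1)
  # oracle: enumerate all 720 rank permutations with cor()
  set.seed(61)
  y <- runif(6)
  sb_rand <- data.frame(species = letters[1:6], B_A = y)
  bc <- breadth_correlation(hb, sb_rand)
  rho_all <- vapply(perms_oracle(6), function(p) {
    stats::cor(1:6, rank(y[p]), method = "spearman")
  }, 0)
  expect_equal(bc$p, mean(abs(rho_all) >= abs(bc$rho) - 1e-12),
               tolerance = 1e-12)
  expect_error(breadth_correlation(hb[1:2, ], sb_rand[1:2, ]), ">= 3")
})
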