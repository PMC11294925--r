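test_that("relative abundance matches a binomial GLM fit per habitat", {
  calls <- data.frame(
    species = c(rep("A", 4), rep("B", 6), rep("A", 2), rep("B", 8)),
    habitat = rep(c("back", "fore5"), each = 10))
  ra <- relative_abundance(calls)
  cell <- ra[ra$species == "A" & ra$habitat == "back", ]
  expect_equal(cell$proportion, 0.4)
  # oracle: intercept-only logistic fit on that habitat's indicator
  ind <- as.integer(calls$species[calls$habitat == "back"] == "A")
  fit <- stats::glm(ind ~ 1, family = binomial,
                    control = stats::glm.control(epsilon = 1e-14))
  ci <- stats::plogis(stats::confint.default(fit))
  expect_equal(cell$ci_low, unname(ci[1]), tolerance = 1e-7)
  expect_equal(cell$ci_high, unname(ci[2]), tolerance = 1e-7)
})

test_that("boundary proportions are flagged degenerate with one-sided intervals", {
  calls <- data.frame(species = rep("A", 10), habitat = rep("back", 10))
  ra <- relative_abundance(calls)
  expect_true(ra$degenerate)
  expect_equal(ra$proportion, 1)
  expect_equal(ra$ci_high, 1)
  expect_lt(ra$ci_low, 1)
})

test_that("identical proportions across habitats give a null LRT", {
  ind <- rep(c(1, 0), times = 10)
  hab <- rep(c("h1", "h2"), each = 10)
  res <- habitat_lrt(ind, hab)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_identical(res$df, 1L)
})

test_that("the LRT equals an independent Bernoulli log-likelihood computation", {
  # counts (5/10, 0/10): hand-coded per-colony Bernoulli sums
  ind <- c(rep(1, 5), rep(0, 5), rep(0, 10))
  hab <- rep(c("h1", "h2"), each = 10)
  res <- habitat_lrt(ind, hab)
  ll <- function(x, p) sum(ifelse(x == 1, log(p), log(1 - p)))
  ll_sat <- ll(ind[hab == "h1"], 0.5) + 0   # p = 0 cell contributes 0
  ll_null <- ll(ind, mean(ind))
  expect_equal(res$chi2, 2 * (ll_sat - ll_null), tolerance = 1e-12)
  expect_error(habitat_lrt(ind[hab == "h1"], hab[hab == "h1"]), "2 habitats")
})

test_that("the LRT matches the logistic-regression deviance oracle on random data", {
  set.seed(101)
  for (i in 1:25) {
    nh <- sample(2:5, 1)
    n <- sample(5:20, nh, replace = TRUE)
    p <- runif(nh, 0.1, 0.9)
    ind <- unlist(mapply(function(nn, pp) rbinom(nn, 1, pp), n, p,
                         SIMPLIFY = FALSE))
    hab <- rep(paste0("h", seq_len(nh)), times = n)
    res <- habitat_lrt(ind, hab)
    ctl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
    fit1 <- suppressWarnings(stats::glm(ind ~ factor(hab), family = binomial,
                                        control = ctl))
    fit0 <- suppressWarnings(stats::glm(ind ~ 1, family = binomial,
                                        control = ctl))
    expect_equal(res$chi2, fit0$deviance - fit1$deviance, tolerance = 1e-8)
    expect_identical(res$df, nh - 1L)
  }
})

test_that("larger habitat effects give monotonically stronger evidence", {
  make <- function(delta) {
    k <- round(c(0.5 - delta, 0.5 + delta) * 50)
    ind <- c(rep(1, k[1]), rep(0, 50 - k[1]), rep(1, k[2]), rep(0, 50 - k[2]))
    habitat_lrt(ind, rep(c("h1", "h2"), each = 50))$chi2
  }
  chi <- vapply(c(0.1, 0.25, 0.4), make, 0)
  expect_true(all(diff(chi) > 0))
  expect_lt(habitat_lrt(c(rep(1, 45), rep(0, 5), rep(0, 45), rep(1, 5)),
                        rep(c("h1", "h2"), each = 50))$p, 0.001)
})

test_that("Bray-Curtis follows its formula and bounds", {
  m <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1),
             d = c(0.25, 0.25, 0.5))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["a", "d"], 0.5)   # (0.25 + 0.25 + 0.5) / 2
  expect_error(bray_curtis(rbind(a = c(1, 0), z = c(0, 0))), "all-zero")
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(runif(40), 8, 5)
  expect_equal(as.matrix(bray_curtis(m)),
               as.matrix(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA reproduces Euclidean geometry", {
  # collinear points in 1-D: one positive eigenvalue, exact distances
  x <- matrix(c(0, 1, 3, 6), ncol = 1)
  p <- pcoa(dist(x))
  expect_identical(ncol(p$points), 1L)
  expect_equal(as.matrix(dist(p$points)), as.matrix(dist(x)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # regular simplex: n-1 equal positive eigenvalues
  dm <- matrix(1, 4, 4); diag(dm) <- 0
  ps <- pcoa(stats::as.dist(dm))
  expect_equal(ps$eigenvalues[1:3], rep(ps$eigenvalues[1], 3),
               tolerance = 1e-10)
  expect_identical(ncol(ps$points), 3L)
  expect_error(pcoa(dist(matrix(c(0, 1), ncol = 1))), "at least 3")
})

test_that("PCoA matches cmdscale and accounts for negative eigenvalues", {
  set.seed(9)
  x <- matrix(rnorm(30), 10, 3)
  d <- dist(x)
  p <- pcoa(d)
  cs <- stats::cmdscale(d, k = ncol(p$points), eig = TRUE)
  expect_equal(p$eigenvalues[seq_len(ncol(p$points))],
               cs$eig[seq_len(ncol(p$points))], tolerance = 1e-9)
  expect_equal(max(abs(as.matrix(dist(p$points)) - as.matrix(d))), 0,
               tolerance = 1e-10)
  # non-Euclidean Bray-Curtis: reconstruction error bounded by the
  # magnitude of the negative part of the spectrum
  comp <- matrix(runif(50), 10, 5)
  db <- bray_curtis(comp)
  pb <- pcoa(db)
  err <- max(abs(as.matrix(dist(pb$points))^2 - as.matrix(db)^2))
  expect_lte(err, abs(pb$negative_sum) + 1e-10)
  expect_lte(pb$negative_sum, 0)
})

test_that("PERMANOVA pseudo-F matches adonis2 and is relabeling-invariant", {
  skip_if_not_installed("vegan")
  set.seed(13)
  m <- matrix(runif(60), 12, 5)
  d <- bray_curtis(m)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  pm <- permanova(d, g, n_perm = 99, seed = 1)
  ad <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(pm$statistic, ad$F[1], tolerance = 1e-10)
  # simultaneous relabeling of D and groups leaves F unchanged
  perm <- sample(12)
  dm <- as.matrix(d)[perm, perm]
  pm2 <- permanova(stats::as.dist(dm), g[perm], n_perm = 9, seed = 1)
  expect_equal(pm2$statistic, pm$statistic, tolerance = 1e-10)
})

test_that("well-separated clusters reach the minimum attainable p-value", {
  # groups of 10: the chance that a random relabeling reproduces the
  # partition (the only way to match the observed F) is ~1e-5
  set.seed(3)
  x <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
             matrix(rnorm(20, 50, 0.01), 10, 2))
  d <- dist(x)
  g <- rep(c("a", "b"), each = 10)
  pm <- permanova(d, g, n_perm = 199, seed = 3)
  expect_equal(pm$p, 1 / 200)
  expect_error(permanova(d, g, n_perm = 0), "n_perm")
})

test_that("permutation tests are reproducible under a fixed seed", {
  set.seed(23)
  m <- matrix(runif(40), 8, 5)
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 4)
  expect_identical(permanova(d, g, n_perm = 199, seed = 7),
                   permanova(d, g, n_perm = 199, seed = 7))
  expect_identical(dbrda(d, g, n_perm = 99, seed = 7)$test,
                   dbrda(d, g, n_perm = 99, seed = 7)$test)
})

test_that("exact PERMANOVA p-values match an exhaustive adonis2 enumeration", {
  skip_if_not_installed("vegan")
  set.seed(31)
  x <- matrix(rnorm(12), 6, 2)
  d <- dist(x)
  g <- factor(c("a", "a", "b", "b", "c", "c"))
  pm <- permanova(d, g, exact = TRUE)
  f_all <- vapply(perms_oracle(6), function(p) {
    vegan::adonis2(d ~ gp, data = data.frame(gp = g[p]),
                   permutations = 0)$F[1]
  }, 0)
  expect_identical(pm$n_perm, 720L)
  expect_equal(pm$p, mean(f_all >= pm$statistic - 1e-12), tolerance = 1e-12)
  # sampled p within binomial error of the exact p
  pm_s <- permanova(d, g, n_perm = 999, seed = 2)
  expect_lt(abs(pm_s$p - pm$p), 3 * sqrt(pm$p * (1 - pm$p) / 999) + 2e-3)
})

test_that("dbRDA matches capscale and handles the separable two-cluster case", {
  skip_if_not_installed("vegan")
  set.seed(41)
  x <- matrix(rnorm(24), 8, 3)
  d <- dist(x)
  g <- factor(rep(c("a", "b"), each = 4))
  db <- dbrda(d, g, n_perm = 99, seed = 1)
  cp <- vegan::capscale(d ~ g)
  expect_equal(db$test$statistic,
               unname(vegan::anova.cca(cp, permutations = 9)$F[1]),
               tolerance = 1e-8)
  expect_equal(db$prop_constrained, unname(cp$CCA$tot.chi / cp$tot.chi),
               tolerance = 1e-8)
  # two tight clusters perfectly separated by the constraint
  xc <- rbind(matrix(rnorm(8, 0, 1e-3), 4, 2),
              matrix(rnorm(8, 10, 1e-3), 4, 2))
  dc <- dist(xc)
  dbc <- dbrda(dc, g, n_perm = 99, seed = 1)
  expect_gt(dbc$prop_constrained, 0.999)
})

test_that("the degenerate two-groups-of-two case enumerates by hand", {
  # within-group distances 0, between-group 1: 8 of the 24 label
  # permutations preserve the partition, so the exact p is 1/3
  dm <- matrix(1, 4, 4)
  dm[1:2, 1:2] <- 0; dm[3:4, 3:4] <- 0
  d <- stats::as.dist(dm)
  g <- factor(c("a", "a", "b", "b"))
  pm <- permanova(d, g, exact = TRUE)
  expect_true(is.infinite(pm$statistic) || pm$statistic > 1e12)
  expect_equal(pm$p, 1 / 3)
  db <- suppressWarnings(dbrda(d, g, exact = TRUE))
  expect_equal(db$test$p, 1 / 3)
})

test_that("exact dbRDA p-values match a capscale enumeration oracle", {
  skip_if_not_installed("vegan")
  set.seed(43)
  x <- matrix(rnorm(12), 6, 2)
  d <- dist(x)
  g <- factor(c("a", "a", "b", "b", "c", "c"))
  db <- dbrda(d, g, exact = TRUE)
  f_all <- vapply(perms_oracle(6), function(p) {
    gp <- g[p]
    cp <- vegan::capscale(d ~ gp)
    unname((cp$CCA$tot.chi / 2) / (cp$CA$tot.chi / 3))
  }, 0)
  expect_equal(db$test$p, mean(f_all >= db$test$statistic - 1e-12),
               tolerance = 1e-12)
})
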