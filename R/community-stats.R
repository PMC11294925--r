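# Community statistics for species-by-habitat data: relative abundance with
# binomial-GLM-equivalent confidence intervals and likelihood-ratio tests,
# Bray-Curtis dissimilarity, principal coordinates analysis, distance-based
# redundancy analysis and PERMANOVA. All statistics are computed in closed
# form or by explicit permutation here; vegan/stats fits are used only as
# independent oracles in the test suite.

# binomial log-likelihood with 0*log(0) = 0
.binll <- function(k, n, p) {
  t1 <- ifelse(k > 0, k * log(p), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log(1 - p), 0)
  sum(t1 + t2)
}

#' Relative abundance of each species per habitat
#'
#' For every focal species and habitat (optionally habitat x site), the
#' proportion of colonies that are the focal species, with a confidence
#' interval computed as a Wald interval on the logit scale and
#' back-transformed. This matches a saturated binomial GLM with habitat as a
#' factor, whose fitted values equal the observed proportions. Boundary
#' cells (proportion 0 or 1) get an interval from a half-count adjusted
#' logit and are flagged `degenerate`.
#'
#' @param calls Data.frame with columns `species` and `habitat` (and `site`
#'   when `by_site = TRUE`), one row per colony.
#' @param by_site Also stratify by site.
#' @param conf_level Confidence level (default 0.95).
#' @param habitats Habitat levels (defaults to the levels present, in
#'   [reef_habitats()] order where applicable).
#' @return A data.frame with columns `species`, `habitat` (, `site`), `n`,
#'   `k`, `proportion`, `ci_low`, `ci_high`, `degenerate`. Cells with no
#'   colonies at all are omitted (missing, not zero).
#' @export
relative_abundance <- function(calls, by_site = FALSE, conf_level = 0.95,
                               habitats = NULL) {
  stopifnot(all(c("species", "habitat") %in% names(calls)))
  if (by_site) stopifnot("site" %in% names(calls))
  if (is.null(habitats)) {
    habitats <- intersect(reef_habitats(), unique(calls$habitat))
    habitats <- union(habitats, unique(calls$habitat))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  strata <- if (by_site) interaction(calls$habitat, calls$site, drop = TRUE)
            else factor(calls$habitat, levels = habitats)
  species <- sort(unique(calls$species[!is.na(calls$species)]))
  out <- list()
  for (s in levels(strata)) {
    in_s <- strata == s & !is.na(strata)
    n <- sum(in_s)
    if (n == 0L) next
    for (sp in species) {
      k <- sum(calls$species[in_s] == sp, na.rm = TRUE)
      p <- k / n
      degenerate <- k == 0L || k == n
      if (degenerate) {
        # half-count adjusted logit interval at boundary cells
        ka <- k + 0.5; na <- n + 1
        pa <- ka / na
        se <- sqrt(1 / ka + 1 / (na - ka))
        lo <- if (k == 0L) 0 else stats::plogis(stats::qlogis(pa) - z * se)
        hi <- if (k == n) 1 else stats::plogis(stats::qlogis(pa) + z * se)
      } else {
        se <- sqrt(1 / k + 1 / (n - k))
        lo <- stats::plogis(stats::qlogis(p) - z * se)
        hi <- stats::plogis(stats::qlogis(p) + z * se)
      }
      row <- data.frame(species = sp, stratum = s, n = n, k = k,
                        proportion = p, ci_low = lo, ci_high = hi,
                        degenerate = degenerate, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  if (by_site) {
    parts <- strsplit(res$stratum, ".", fixed = TRUE)
    res$habitat <- vapply(parts, `[`, "", 1L)
    res$site <- vapply(parts, `[`, "", 2L)
  } else {
    res$habitat <- res$stratum
  }
  res$stratum <- NULL
  res
}

#' Likelihood-ratio test for a habitat effect on a species indicator
#'
#' Tests whether the proportion of colonies belonging to the focal species
#' differs among habitats, as twice the log-likelihood difference between
#' the habitat-saturated binomial model (fitted cell proportions) and the
#' intercept-only model (pooled proportion), referred to a chi-squared
#' distribution with (habitats - 1) degrees of freedom. Equals the deviance
#' difference of the corresponding logistic regression.
#'
#' @param indicator 0/1 vector, one per colony (1 = focal species).
#' @param habitat Habitat label per colony.
#' @return List of class `lrt_result`: `chi2`, `df`, `p`.
#' @export
habitat_lrt <- function(indicator, habitat) {
  stopifnot(length(indicator) == length(habitat),
            all(indicator %in% c(0, 1)))
  habitat <- factor(habitat)
  habitat <- droplevels(habitat)
  if (nlevels(habitat) < 2L) {
    stop("habitat effect is not testable with fewer than 2 habitats")
  }
  k <- tapply(indicator, habitat, sum)
  n <- tapply(indicator, habitat, length)
  p_hat <- k / n
  p0 <- sum(k) / sum(n)
  chi2 <- 2 * (.binll(k, n, p_hat) - .binll(k, n, p0))
  chi2 <- max(chi2, 0)
  df <- nlevels(habitat) - 1L
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' Bray-Curtis dissimilarity
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), bounded in [0, 1] for
#' nonnegative rows.
#'
#' @param composition Numeric matrix, samples x species (counts or
#'   proportions); every row must have a positive total.
#' @return A `dist` object with the row names as labels.
#' @export
bray_curtis <- function(composition) {
  composition <- as.matrix(composition)
  if (any(composition < 0)) stop("composition must be nonnegative")
  if (any(rowSums(composition) <= 0)) {
    stop("Bray-Curtis undefined for all-zero rows: ",
         paste(rownames(composition)[rowSums(composition) <= 0], collapse = ", "))
  }
  n <- nrow(composition)
  d <- matrix(0, n, n, dimnames = list(rownames(composition),
                                       rownames(composition)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- sum(abs(composition[i, ] - composition[j, ]))
      den <- sum(composition[i, ] + composition[j, ])
      d[i, j] <- d[j, i] <- num / den
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Classic metric scaling: Gower double-centering of -D^2/2 followed by
#' eigendecomposition. Coordinates are returned for the positive eigenvalues
#' only (eigenvectors scaled by the square root of their eigenvalue);
#' negative eigenvalues are reported and their axes dropped, with no
#' Lingoes/Cailliez correction applied.
#'
#' @param d A `dist` object or symmetric distance matrix (n >= 3).
#' @return List of class `pcoa_result`: `eigenvalues` (all, descending),
#'   `points` (n x m coordinates for the m positive eigenvalues),
#'   `negative_sum` (sum of negative eigenvalues, <= 0).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3L) stop("PCoA requires at least 3 samples")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  a <- -0.5 * dm^2
  g <- sweep(sweep(a, 1L, rowMeans(a)), 2L, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * sqrt(.Machine$double.eps)
  pos <- e$values > tol
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = sum(pos))
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(eigenvalues = e$values, points = pts,
                 negative_sum = sum(e$values[e$values < -tol])),
            class = "pcoa_result")
}

# all permutations of 1..n (n <= 9), identity first
.all_perms <- function(n) {
  if (n > 9L) stop("exhaustive enumeration limited to n <= 9")
  if (n == 1L) return(list(1L))
  smaller <- .all_perms(n - 1L)
  out <- vector("list", n * length(smaller))
  k <- 0L
  for (p in smaller) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# squared-distance sums of squares for PERMANOVA
.permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(groups)
  lower <- lower.tri(d2)
  ss_total <- sum(d2[lower]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Pseudo-F from squared-distance sums of squares: SS_total is the sum of
#' all squared pairwise distances over n, SS_within sums within-group
#' squared distances over group sizes, and
#' F = (SS_between / (a-1)) / (SS_within / (n-a)). The p-value comes from
#' free permutation of sample labels with the (1 + count)/(1 + n_perm)
#' estimator, or from exhaustive enumeration of all label permutations when
#' `exact = TRUE` (n <= 9).
#'
#' @param d `dist` or symmetric distance matrix.
#' @param groups Factor (or coercible) of group labels, >= 2 groups.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param seed Integer seed controlling the permutations.
#' @param exact Enumerate all permutations instead of sampling.
#' @return List of class `permtest_result`: `statistic`, `df_between`,
#'   `df_within`, `p`, `n_perm`, `seed`, `exact`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L, exact = FALSE) {
  dm <- as.matrix(d)
  groups <- droplevels(as.factor(groups))
  n <- nrow(dm)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (!exact && n_perm < 1L) stop("n_perm must be >= 1")
  d2 <- dm^2
  f_obs <- .permanova_f(d2, groups)
  if (exact) {
    perms <- .all_perms(n)
    f_perm <- vapply(perms, function(p) .permanova_f(d2, groups[p]), 0)
    p_val <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      if (.permanova_f(d2, groups[sample.int(n)]) >= f_obs - 1e-12) {
        cnt <- cnt + 1L
      }
    }
    p_val <- (1 + cnt) / (1 + n_perm)
  }
  structure(list(statistic = f_obs, df_between = nlevels(groups) - 1L,
                 df_within = n - nlevels(groups), p = p_val,
                 n_perm = n_perm, seed = seed, exact = exact),
            class = "permtest_result")
}

# constrained pseudo-F of PCoA axes Y regressed on a factor
.dbrda_f <- function(y, groups) {
  x <- stats::model.matrix(~groups)
  qx <- qr(x)
  fitted <- qr.fitted(qx, y)
  constrained <- sum(fitted^2)
  total <- sum(y^2)
  q <- nlevels(groups) - 1L
  n <- nrow(y)
  residual <- total - constrained
  # a constraint explaining everything leaves only rounding noise behind
  if (residual <= total * 1e-12) return(Inf)
  (constrained / q) / (residual / (n - q - 1L))
}

#' Distance-based redundancy analysis with a categorical constraint
#'
#' PCoA axes from the positive eigenvalues are regressed on the constraining
#' factor's dummy matrix; the constrained ordination is the eigenanalysis of
#' the fitted values, and the statistic is
#' F = (constrained inertia / q) / (residual inertia / (n - q - 1)) with
#' q = levels - 1. The p-value comes from permuting sample labels (seeded),
#' or exhaustive enumeration when `exact = TRUE`. Built on positive PCoA
#' axes only, in the style of a constrained analysis of principal
#' coordinates.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param groups Constraining factor, >= 2 levels.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param seed Integer seed.
#' @param exact Enumerate all label permutations (n <= 9).
#' @return List of class `dbrda_result`: `eigenvalues` (constrained,
#'   descending), `scores` (sample scores on constrained axes),
#'   `centroids` (factor-level centroids in the constrained space),
#'   `prop_constrained` (fraction of positive-axis inertia explained), and
#'   `test` (a `permtest_result`).
#' @export
dbrda <- function(d, groups, n_perm = 999L, seed = 1L, exact = FALSE) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("constraining factor needs >= 2 levels")
  if (any(table(groups) < 2L)) {
    warning("some factor levels have a single sample; test is still defined")
  }
  ord <- pcoa(d)
  y <- ord$points
  stopifnot(nrow(y) == length(groups))
  f_obs <- .dbrda_f(y, groups)
  x <- stats::model.matrix(~groups)
  fitted <- qr.fitted(qr(x), y)
  e <- eigen(crossprod(fitted), symmetric = TRUE)
  q <- nlevels(groups) - 1L
  keep <- seq_len(min(q, sum(e$values > max(e$values) * 1e-10)))
  axes <- e$vectors[, keep, drop = FALSE]
  scores <- y %*% axes
  colnames(scores) <- paste0("dbRDA", seq_along(keep))
  centroids <- apply(scores, 2L, function(col) tapply(col, groups, mean))
  if (exact) {
    perms <- .all_perms(nrow(y))
    f_perm <- vapply(perms, function(p) .dbrda_f(y, groups[p]), 0)
    p_val <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      if (.dbrda_f(y, groups[sample.int(nrow(y))]) >= f_obs - 1e-12) {
        cnt <- cnt + 1L
      }
    }
    p_val <- (1 + cnt) / (1 + n_perm)
  }
  test <- structure(list(statistic = f_obs, df_between = q,
                         df_within = nrow(y) - q - 1L, p = p_val,
                         n_perm = n_perm, seed = seed, exact = exact),
                    class = "permtest_result")
  structure(list(eigenvalues = e$values[keep], scores = scores,
                 centroids = centroids,
                 prop_constrained = sum(fitted^2) / sum(y^2),
                 test = test),
            class = "dbrda_result")
}
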