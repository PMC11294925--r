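# Niche breadth and overlap. Levins' breadth B = 1 / sum(p_j^2) measures the
# uniformity of a proportion vector over resource states; B_A = (B-1)/(R-1)
# standardises it to [0, 1] against the number of resource states R. The
# Horn-Morisita index C_H = 2*sum(p_ij*p_ik) / (sum(p_ij^2) + sum(p_ik^2))
# measures overlap between two such vectors, 0 (disjoint) to 1 (identical).

#' Levins' niche breadth
#'
#' @param p Nonnegative proportion vector summing to 1 (within 1e-9).
#' @param R Number of resource states to standardise against; must be at
#'   least the number of states in `p` and >= 2 for `B_A`. Defaults to
#'   `length(p)`.
#' @return List with `B` (1 <= B <= R) and `B_A` ((B-1)/(R-1) in [0, 1]).
#' @export
levins_breadth <- function(p, R = length(p)) {
  if (sum(p) <= 0) stop("proportion vector sums to zero")
  if (any(p < 0)) stop("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  if (R < length(p[p > 0])) stop("R smaller than the support of p")
  if (R < 2) stop("B_A undefined for R = 1")
  B <- 1 / sum(p^2)
  list(B = B, B_A = (B - 1) / (R - 1))
}

#' Habitat niche breadth per host species
#'
#' For each species (optionally per site), p_j is the fraction of that
#' species' colonies found in habitat j, and breadth is standardised against
#' the full set of sampled habitat states R (unoccupied habitats included),
#' so a species confined to one habitat scores B_A = 0.
#'
#' @param calls Data.frame with columns `species`, `habitat` (and `site`
#'   when `per_site`).
#' @param per_site Compute one breadth per species per site.
#' @param habitats Resource states; defaults to [reef_habitats()].
#' @return A data.frame: `species`, `context` (`"pooled"` or the site), `R`,
#'   `B`, `B_A`. Species absent from a site are skipped.
#' @export
habitat_breadth <- function(calls, per_site = FALSE,
                            habitats = reef_habitats()) {
  stopifnot(all(c("species", "habitat") %in% names(calls)))
  contexts <- if (per_site) unique(calls$site) else "pooled"
  out <- list()
  for (ctx in contexts) {
    sub <- if (per_site) calls[calls$site == ctx, , drop = FALSE] else calls
    for (sp in unique(sub$species)) {
      counts <- table(factor(sub$habitat[sub$species == sp],
                             levels = habitats))
      if (sum(counts) == 0L) next
      p <- as.numeric(counts) / sum(counts)
      b <- levins_breadth(p, R = length(habitats))
      out[[length(out) + 1L]] <- data.frame(
        species = sp, context = ctx, R = length(habitats),
        B = b$B, B_A = b$B_A, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Symbiont niche breadth per colony
#'
#' Per colony, p is the vector of ITS2 DIV read shares and R is the total
#' number of DIV columns in the analysed matrix (a dataset property, recorded
#' in the output), so a colony dominated by a single DIV scores near 0.
#'
#' @param div_counts Integer matrix, colonies x DIVs (rownames are colony
#'   ids). Zero-total colonies are skipped.
#' @param hosts Optional data.frame with `colony_id` and a species column
#'   (`species` or `host`) used to group colonies.
#' @return A data.frame: `species` (NA if no host table), `context` (colony
#'   id), `R`, `B`, `B_A`.
#' @export
symbiont_breadth <- function(div_counts, hosts = NULL) {
  R <- ncol(div_counts)
  totals <- rowSums(div_counts)
  keep <- totals > 0
  host_of <- function(id) {
    if (is.null(hosts)) return(NA_character_)
    col <- if ("species" %in% names(hosts)) "species" else "host"
    i <- match(id, hosts$colony_id)
    if (is.na(i)) NA_character_ else hosts[[col]][i]
  }
  ids <- rownames(div_counts)[keep]
  rows <- lapply(ids, function(id) {
    p <- div_counts[id, ] / sum(div_counts[id, ])
    b <- levins_breadth(as.numeric(p), R = R)
    data.frame(species = host_of(id), context = id, R = R,
               B = b$B, B_A = b$B_A, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Horn-Morisita niche overlap between two proportion vectors
#'
#' @param p_j,p_k Proportion vectors over the same ordered resource states,
#'   each summing to 1 (within 1e-9).
#' @return The overlap C_H in [0, 1].
#' @export
horn_morisita <- function(p_j, p_k) {
  if (length(p_j) != length(p_k)) stop("vectors must have equal length")
  if (sum(p_j) <= 0 && sum(p_k) <= 0) stop("both vectors are zero")
  if (abs(sum(p_j) - 1) > 1e-9 || abs(sum(p_k) - 1) > 1e-9) {
    stop("proportion vectors must sum to 1")
  }
  2 * sum(p_j * p_k) / (sum(p_j^2) + sum(p_k^2))
}

# habitat-use proportion vector of one species within a calls table
.habitat_profile <- function(calls, sp, habitats) {
  counts <- table(factor(calls$habitat[calls$species == sp],
                         levels = habitats))
  if (sum(counts) == 0L) return(NULL)
  as.numeric(counts) / sum(counts)
}

# pooled DIV-share vector of one host species
.symbiont_profile <- function(div_counts, hosts, sp) {
  col <- if ("species" %in% names(hosts)) "species" else "host"
  ids <- intersect(rownames(div_counts),
                   hosts$colony_id[hosts[[col]] == sp])
  if (!length(ids)) return(NULL)
  tot <- colSums(div_counts[ids, , drop = FALSE])
  if (sum(tot) <= 0) return(NULL)
  as.numeric(tot) / sum(tot)
}

#' Pairwise niche overlap among host species
#'
#' Computes the Horn-Morisita overlap for every ordered species pair, on
#' habitat-use vectors (`resource = "habitat"`) or pooled DIV-share vectors
#' (`resource = "symbiont"`), optionally per site. Both orientations are
#' emitted; the index as implemented from its formula is symmetric in j and
#' k, so paired rows carry equal values.
#'
#' @param calls Data.frame with `species`, `habitat` (and `site`).
#' @param div_counts DIV matrix, required when `resource = "symbiont"`.
#' @param resource `"habitat"` or `"symbiont"`.
#' @param per_site One overlap per pair per site (habitat resource only).
#' @param habitats Habitat resource states.
#' @return A data.frame: `species_j`, `species_k`, `context`, `C_H`. Pairs
#'   with a missing profile are skipped.
#' @export
overlap_matrix <- function(calls, div_counts = NULL,
                           resource = c("habitat", "symbiont"),
                           per_site = FALSE, habitats = reef_habitats()) {
  resource <- match.arg(resource)
  if (resource == "symbiont" && is.null(div_counts)) {
    stop("symbiont overlap requires a DIV count matrix")
  }
  species <- unique(calls$species)
  if (length(species) < 2L) stop("need at least 2 species")
  contexts <- if (per_site) unique(calls$site) else "pooled"
  out <- list()
  for (ctx in contexts) {
    sub <- if (per_site) calls[calls$site == ctx, , drop = FALSE] else calls
    profs <- lapply(species, function(sp) {
      if (resource == "habitat") .habitat_profile(sub, sp, habitats)
      else .symbiont_profile(div_counts, sub, sp)
    })
    names(profs) <- species
    for (j in species) {
      for (k in setdiff(species, j)) {
        if (is.null(profs[[j]]) || is.null(profs[[k]])) next
        out[[length(out) + 1L]] <- data.frame(
          species_j = j, species_k = k, context = ctx,
          C_H = horn_morisita(profs[[j]], profs[[k]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Spearman's rho on two numeric vectors via ranks
.spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

#' Correlation between habitat and symbiont niche breadth across species
#'
#' Species-level mean B_A values from the two breadth tables are correlated
#' with Spearman's rank correlation. The p-value is two-sided by permutation
#' of one vector's ranks: exact enumeration of all permutations when the
#' number of species is <= 8, sampled permutations otherwise.
#'
#' @param habitat_breadths Output of [habitat_breadth()].
#' @param symbiont_breadths Output of [symbiont_breadth()] with host species.
#' @param n_perm Permutations used when species count > 8.
#' @param seed Seed for sampled permutations.
#' @return List of class `breadth_correlation`: `means` (data.frame
#'   `species`, `habitat_B_A`, `symbiont_B_A`), `rho`, `p`, `exact`.
#' @export
breadth_correlation <- function(habitat_breadths, symbiont_breadths,
                                n_perm = 9999L, seed = 1L) {
  hb <- tapply(habitat_breadths$B_A, habitat_breadths$species, mean)
  sb <- tapply(symbiont_breadths$B_A, symbiont_breadths$species, mean)
  common <- intersect(names(hb), names(sb))
  if (length(common) < 3L) stop("need >= 3 species with both breadth means")
  x <- as.numeric(hb[common]); y <- as.numeric(sb[common])
  rho <- .spearman(x, y)
  n <- length(common)
  if (n <= 8L) {
    perms <- .all_perms(n)
    rho_perm <- vapply(perms, function(p) .spearman(x, y[p]), 0)
    p_val <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(.spearman(x, y[sample.int(n)])) >= abs(rho) - 1e-12) {
        cnt <- cnt + 1L
      }
    }
    p_val <- (1 + cnt) / (1 + n_perm)
    exact <- FALSE
  }
  structure(list(
    means = data.frame(species = common, habitat_B_A = x, symbiont_B_A = y,
                       stringsAsFactors = FALSE),
    rho = rho, p = p_val, exact = exact
  ), class = "breadth_correlation")
}
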