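# Synthetic cohort generator: marker sequences, DIV count matrices and
# metadata with the statistical structure the downstream analysis assumes.
# Haplotype-diagnostic positions are fixed per panel and excluded from
# simulated noise, so the true species of every simulated colony remains
# recoverable by construction.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort generator.
#' Defaults reproduce the built-in study design: 4 sites x 5 habitats with
#' the per-cell mtORF sample sizes of [sampling_design()] (724 colonies),
#' species mixtures per habitat proportional to [species_habitat_counts()],
#' host-symbiont association probabilities from [symbiont_assoc_probs()],
#' and Dirichlet-multinomial DIV counts around [div_profiles()].
#'
#' @param species_names Host species labels.
#' @param habitat_names Ordered habitat labels.
#' @param site_names Site labels.
#' @param n_per_cell Integer matrix (sites x habitats) of colonies per cell.
#' @param abundance_weights Nonnegative matrix (species x habitats); each
#'   habitat column is normalised to a species mixture.
#' @param symbiont_assoc Matrix (host species x symbiont species) of primary
#'   symbiont probabilities; rows sum to 1.
#' @param dual_prob Probability that a colony hosts a second symbiont
#'   species. Default 13/423, the dual-infection rate of the built-in
#'   association design.
#' @param div_profile_means Matrix (symbiont species x DIVs) of mean DIV
#'   relative abundances; rows sum to 1.
#' @param concentration Dirichlet concentration (overdispersion) of per-colony
#'   DIV proportions around the species mean; larger is less overdispersed.
#' @param read_depth Mean ITS2 reads per colony (Poisson).
#' @param mtorf_noise_rate Per-base substitution probability at
#'   non-diagnostic mtORF positions.
#' @param its2_dropout Probability that a colony yields no usable ITS2 data.
#' @param psba_dropout Probability that a Cladocopium-dominant colony yields
#'   no psbA sequence.
#' @param meandrina_hap8_frac Fraction of P. meandrina colonies carrying
#'   mtORF haplotype 8 rather than haplotype 1.
#' @param dual_mix_weight Read-share of the primary symbiont in dual
#'   infections.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(species_names = pocillopora_species(),
                       habitat_names = reef_habitats(),
                       site_names = reef_sites(),
                       n_per_cell = NULL,
                       abundance_weights = NULL,
                       symbiont_assoc = NULL,
                       dual_prob = 13 / 423,
                       div_profile_means = div_profiles(),
                       concentration = 20,
                       read_depth = 1000,
                       mtorf_noise_rate = 0,
                       its2_dropout = 0.14,
                       psba_dropout = 0.26,
                       meandrina_hap8_frac = 0.2,
                       dual_mix_weight = 0.75,
                       seed = 1L) {
  if (is.null(n_per_cell)) {
    d <- sampling_design()
    n_per_cell <- matrix(0L, length(site_names), length(habitat_names),
                         dimnames = list(site_names, habitat_names))
    for (i in seq_len(nrow(d))) {
      n_per_cell[d$site[i], d$habitat[i]] <- d$n_mtorf[i]
    }
  }
  if (is.null(abundance_weights)) {
    abundance_weights <- species_habitat_counts()[species_names, habitat_names,
                                                  drop = FALSE]
  }
  if (is.null(symbiont_assoc)) {
    symbiont_assoc <- symbiont_assoc_probs()[species_names, , drop = FALSE]
  }
  cfg <- structure(list(
    species_names = species_names, habitat_names = habitat_names,
    site_names = site_names, n_per_cell = n_per_cell,
    abundance_weights = abundance_weights, symbiont_assoc = symbiont_assoc,
    dual_prob = dual_prob, div_profile_means = div_profile_means,
    concentration = concentration, read_depth = read_depth,
    mtorf_noise_rate = mtorf_noise_rate, its2_dropout = its2_dropout,
    psba_dropout = psba_dropout, meandrina_hap8_frac = meandrina_hap8_frac,
    dual_mix_weight = dual_mix_weight, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.matrix(cfg$n_per_cell), all(cfg$n_per_cell >= 0))
  w <- cfg$abundance_weights
  if (any(w < 0) || any(colSums(w) <= 0)) {
    stop("abundance_weights must be nonnegative with a positive sum per habitat")
  }
  if (!setequal(rownames(w), cfg$species_names)) {
    stop("abundance_weights rows must cover species_names")
  }
  a <- cfg$symbiont_assoc
  if (any(abs(rowSums(a) - 1) > 1e-9)) {
    stop("symbiont_assoc rows must sum to 1")
  }
  dv <- cfg$div_profile_means
  if (any(abs(rowSums(dv) - 1) > 1e-9)) {
    stop("div_profile_means rows must sum to 1")
  }
  stopifnot(cfg$dual_prob >= 0, cfg$dual_prob <= 1,
            cfg$mtorf_noise_rate >= 0, cfg$mtorf_noise_rate < 1,
            cfg$read_depth > 0, cfg$concentration > 0)
  invisible(cfg)
}

# deterministic substitution used for diagnostic positions: always yields a
# different base than the input
.rotate_base <- function(base) {
  c(A = "C", C = "G", G = "T", T = "A")[base]
}

#' Generate a synthetic mtORF reference haplotype panel
#'
#' Builds one reference sequence per mtORF haplotype (1, 8, 10, 3a, 3b, 3e,
#' 2, 11, 5a) on a common random backbone. Each haplotype other than 1 and 8
#' carries private substitutions at 5 diagnostic positions; haplotype 8
#' carries 7, so haplotypes 1 and 8 differ at exactly 7 positions (the
#' seven-base-pair mitochondrial lineage split within P. meandrina) and every
#' other pair differs at >= 5 positions. Diagnostic positions are recorded on
#' the panel and excluded from simulation noise.
#'
#' @param seed Integer seed; the panel is deterministic given it.
#' @param length Amplicon length in bases (>= 100).
#' @return A data.frame of class `reference_panel` with columns `haplotype`,
#'   `species`, `sequence`, and attributes `marker` ("mtORF") and
#'   `diagnostic_positions`.
#' @export
generate_reference_panel <- function(seed = 1L, length = 800L) {
  length <- as.integer(length)
  haps <- c("1", "8", "10", "3a", "3b", "3e", "2", "11", "5a")
  n_diag <- 7L + 5L * (length(haps) - 2L)
  if (length < 100L || length < n_diag) {
    stop("amplicon length too short to place all diagnostic positions")
  }
  set.seed(seed)
  backbone <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  diag_pos <- sort(sample.int(length, n_diag))
  blocks <- split(diag_pos, rep(seq_along(haps)[-1L],
                                times = c(7L, rep(5L, length(haps) - 2L))))
  seqs <- character(length(haps))
  names(seqs) <- haps
  seqs["1"] <- paste(backbone, collapse = "")
  for (i in seq_along(haps)[-1L]) {
    s <- backbone
    pos <- blocks[[as.character(i)]]
    s[pos] <- .rotate_base(s[pos])
    seqs[haps[i]] <- paste(s, collapse = "")
  }
  map <- haplotype_species_map()
  panel <- data.frame(
    haplotype = haps,
    species = map$species[match(haps, map$haplotype)],
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
  attr(panel, "marker") <- "mtORF"
  attr(panel, "diagnostic_positions") <- diag_pos
  class(panel) <- c("reference_panel", "data.frame")
  panel
}

#' Histone-3 amplicon templates for the RFLP assay
#'
#' A 700 bp amplicon pair: the P. meandrina template carries no XhoI
#' recognition site (CTCGAG), while the P. grandis template carries exactly
#' one, placed so that a complete digest yields ~400 and ~300 bp fragments.
#'
#' @param seed Integer seed.
#' @param length Amplicon length (default 700).
#' @param site_start 1-based start of the recognition site in the P. grandis
#'   template (default 400, giving fragments of 400 and 300 after the cut
#'   one base into the site).
#' @return Named character vector with elements `"P. meandrina"` and
#'   `"P. grandis"`.
#' @export
histone_templates <- function(seed = 1L, length = 700L, site_start = 400L) {
  set.seed(seed + 7L)
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  seq0 <- paste(base, collapse = "")
  # scrub accidental recognition sites from the uncut template
  while (grepl("CTCGAG", seq0, fixed = TRUE)) {
    at <- regexpr("CTCGAG", seq0, fixed = TRUE)[1L]
    base[at] <- .rotate_base(base[at])
    seq0 <- paste(base, collapse = "")
  }
  grd <- base
  grd[site_start:(site_start + 5L)] <- c("C", "T", "C", "G", "A", "G")
  c("P. meandrina" = seq0, "P. grandis" = paste(grd, collapse = ""))
}

#' Simulate a colony cohort with marker sequences
#'
#' For every site x habitat cell, draws colony species labels from the
#' habitat's normalised abundance weights, then emits per colony: metadata
#' (with the true species held out for evaluation), an mtORF amplicon equal
#' to its haplotype reference plus i.i.d. substitutions at non-diagnostic
#' positions, and -- for haplotype-1 colonies -- a histone-3 amplicon that
#' contains the XhoI motif for P. grandis and lacks it for P. meandrina.
#'
#' @param config A [sim_config()].
#' @param panel A [generate_reference_panel()] covering all configured
#'   species.
#' @return List of class `colony_sim`: `metadata` (data.frame `colony_id`,
#'   `site`, `habitat`, `true_species`, `haplotype`), `mtorf` and `histone`
#'   (named character vectors of sequences).
#' @export
simulate_colonies <- function(config, panel) {
  validate_sim_config(config)
  hap_of <- list(
    "P. tuahiniensis" = "10", "P. meandrina" = c("1", "8"),
    "P. grandis" = "1", "P. verrucosa" = "3a",
    "P. cf. effusa" = "2", "P. acuta" = "5a"
  )
  missing_sp <- setdiff(config$species_names, names(hap_of))
  if (length(missing_sp)) {
    stop("species absent from the reference panel mapping: ",
         paste(missing_sp, collapse = ", "))
  }
  if (!all(unlist(hap_of[config$species_names]) %in% panel$haplotype)) {
    stop("panel does not cover all haplotypes required by the configuration")
  }
  set.seed(config$seed)
  diag_pos <- attr(panel, "diagnostic_positions")
  ref_chars <- lapply(panel$sequence, function(s) strsplit(s, "")[[1]])
  names(ref_chars) <- panel$haplotype
  hist_tpl <- histone_templates(config$seed)

  meta <- list(); mtorf <- character(0); histone <- character(0)
  k <- 0L
  for (site in config$site_names) {
    for (hab in config$habitat_names) {
      n <- config$n_per_cell[site, hab]
      if (n == 0L) next
      w <- config$abundance_weights[config$species_names, hab]
      if (sum(w) <= 0) stop("habitat ", hab, " has zero total abundance weight")
      sp <- sample(config$species_names, n, replace = TRUE, prob = w / sum(w))
      for (s in sp) {
        k <- k + 1L
        id <- sprintf("col%04d", k)
        hap <- if (identical(s, "P. meandrina")) {
          sample(c("8", "1"), 1L,
                 prob = c(config$meandrina_hap8_frac,
                          1 - config$meandrina_hap8_frac))
        } else hap_of[[s]][1L]
        seq_chars <- ref_chars[[hap]]
        if (config$mtorf_noise_rate > 0) {
          editable <- setdiff(seq_along(seq_chars), diag_pos)
          hit <- editable[stats::runif(length(editable)) < config$mtorf_noise_rate]
          if (length(hit)) seq_chars[hit] <- .rotate_base(seq_chars[hit])
        }
        mtorf[id] <- paste(seq_chars, collapse = "")
        if (hap == "1") histone[id] <- hist_tpl[[s]]
        meta[[k]] <- data.frame(colony_id = id, site = site, habitat = hab,
                                true_species = s, haplotype = hap,
                                stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(metadata = do.call(rbind, meta),
                 mtorf = mtorf, histone = histone),
            class = "colony_sim")
}

# Dirichlet draw; zero shape parameters yield exact zeros
.rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, stats::rgamma(length(alpha), shape = alpha), 0)
  if (sum(g) <= 0) stop("degenerate Dirichlet draw: all shapes zero")
  g / sum(g)
}

#' Simulate symbiont data for a colony cohort
#'
#' Each colony draws one symbiont species from its host's association
#' probabilities (or two, with the configured dual-infection probability);
#' DIV counts are Dirichlet-multinomial around the mixture of the drawn
#' species' mean profiles with Poisson total around `read_depth`. A psbA
#' clade label is emitted only for Cladocopium-dominant colonies, thinned by
#' the psbA dropout rate; ITS2 profiles are independently thinned by the
#' ITS2 dropout rate.
#'
#' @param metadata Colony metadata with `colony_id` and `true_species`.
#' @param config A [sim_config()].
#' @return List of class `symbiont_sim`: `div_counts` (integer matrix,
#'   colonies with ITS2 data x DIVs), `psba` (data.frame `colony_id`,
#'   `clade`), `truth` (data.frame `colony_id`, `symbionts` (`;`-separated),
#'   `dominant`).
#' @export
simulate_symbionts <- function(metadata, config) {
  validate_sim_config(config)
  unknown <- setdiff(unique(metadata$true_species),
                     rownames(config$symbiont_assoc))
  if (length(unknown)) {
    stop("host species without symbiont association probabilities: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(config$seed + 1L)
  profiles <- config$div_profile_means
  symb <- colnames(config$symbiont_assoc)
  clmap <- psba_clade_map()
  n <- nrow(metadata)
  counts <- matrix(0L, n, ncol(profiles),
                   dimnames = list(metadata$colony_id, colnames(profiles)))
  truth_sets <- character(n); dominant <- character(n)
  psba_id <- character(0); psba_clade <- character(0)
  has_its2 <- logical(n)
  for (i in seq_len(n)) {
    p_assoc <- config$symbiont_assoc[metadata$true_species[i], ]
    primary <- sample(symb, 1L, prob = p_assoc)
    set_i <- primary
    mean_prof <- profiles[primary, ]
    if (stats::runif(1) < config$dual_prob && sum(p_assoc[symb != primary]) > 0) {
      rest <- p_assoc[symb != primary]
      secondary <- sample(names(rest), 1L, prob = rest / sum(rest))
      set_i <- c(primary, secondary)
      mean_prof <- config$dual_mix_weight * profiles[primary, ] +
        (1 - config$dual_mix_weight) * profiles[secondary, ]
    }
    truth_sets[i] <- paste(set_i, collapse = ";")
    dominant[i] <- primary
    has_its2[i] <- stats::runif(1) >= config$its2_dropout
    if (has_its2[i]) {
      p <- .rdirichlet1(config$concentration * mean_prof)
      total <- stats::rpois(1L, config$read_depth)
      if (total > 0L) {
        counts[i, ] <- as.integer(stats::rmultinom(1L, total, p))
      }
    }
    if (primary %in% c("C. latusorum", "C. pacificum") &&
        stats::runif(1) >= config$psba_dropout) {
      clades <- clmap$clade[clmap$species == primary]
      psba_id <- c(psba_id, metadata$colony_id[i])
      psba_clade <- c(psba_clade, sample(clades, 1L))
    }
  }
  structure(list(
    div_counts = counts[has_its2, , drop = FALSE],
    psba = data.frame(colony_id = psba_id, clade = psba_clade,
                      stringsAsFactors = FALSE),
    truth = data.frame(colony_id = metadata$colony_id,
                       symbionts = truth_sets, dominant = dominant,
                       stringsAsFactors = FALSE)
  ), class = "symbiont_sim")
}

#' Deterministically expand a species-by-habitat count table into a cohort
#'
#' Emits exactly `counts[s, h]` colonies of species `s` in habitat `h`, with
#' no randomness; used to reconstruct cohorts whose cell counts are known.
#'
#' @param counts Integer matrix, species x habitats.
#' @return A data.frame with columns `colony_id`, `habitat`, `species`.
#' @export
cohort_from_counts <- function(counts = species_habitat_counts()) {
  sp <- rep(rep(rownames(counts), times = ncol(counts)), times = as.vector(counts))
  hab <- rep(rep(colnames(counts), each = nrow(counts)), times = as.vector(counts))
  data.frame(colony_id = sprintf("fix%04d", seq_along(sp)),
             habitat = hab, species = sp, stringsAsFactors = FALSE)
}
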