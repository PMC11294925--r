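# Built-in study design: a 4-site x 5-habitat reef sampling layout for
# cryptic Pocillopora species and their Symbiodiniaceae symbionts at Moorea,
# French Polynesia. These tables are the package defaults for the simulator
# and the worked examples; all downstream functions accept arbitrary designs.

#' Reef habitat zones, ordered from shore to the deep fore reef
#'
#' The five structural habitat zones used as host niche resource states:
#' fringing reef (~1 m), back reef lagoon (~2 m), and the fore reef slope at
#' 5, 10 and 20 m depth.
#'
#' @return Character vector of length 5, in shore-to-deep order.
#' @export
reef_habitats <- function() {
  c("fringing", "back", "fore5", "fore10", "fore20")
}

#' Sampling sites
#'
#' @return Character vector of the four long-term monitoring sites.
#' @export
reef_sites <- function() {
  c("site1", "site2", "site4", "site5")
}

#' Host species labels
#'
#' The six sympatric Pocillopora species distinguishable with the mtORF and
#' histone-3 markers, ordered by overall abundance in the default design.
#'
#' @return Character vector of length 6.
#' @export
pocillopora_species <- function() {
  c("P. meandrina", "P. tuahiniensis", "P. verrucosa",
    "P. acuta", "P. grandis", "P. cf. effusa")
}

#' Symbiont species labels
#'
#' @return Character vector of the five Symbiodiniaceae species recognised by
#'   the diagnostic DIV and psbA clade maps.
#' @export
symbiont_species <- function() {
  c("C. latusorum", "C. pacificum", "Cladocopium C116",
    "S. microadriaticum", "D. glynnii")
}

#' Per-cell sample sizes of the default sampling design
#'
#' Number of colonies genotyped with each marker in every site x habitat cell:
#' `n_mtorf` (host species identification), `n_its2` (symbiont DIV profiling)
#' and `n_psba` (Cladocopium species identification). Column sums give 724
#' mtORF, 377 ITS2 and 326 psbA samples.
#'
#' @return A data.frame with columns `site`, `habitat`, `n_mtorf`, `n_its2`,
#'   `n_psba`; one row per site x habitat cell.
#' @export
sampling_design <- function() {
  hab <- rep(reef_habitats(), each = 4L)
  site <- rep(reef_sites(), times = 5L)
  n_mtorf <- c(20L, 35L, 50L, 49L,   # fringing
               61L, 60L, 50L, 50L,   # back
               35L, 36L, 50L, 33L,   # fore5
               20L, 17L, 14L, 11L,   # fore10
               35L, 35L, 37L, 26L)   # fore20
  n_its2 <- c(20L, 35L, 0L, 0L,
              51L, 51L, 0L, 0L,
              31L, 31L, 34L, 31L,
              0L, 0L, 0L, 0L,
              18L, 27L, 24L, 24L)
  n_psba <- c(5L, 12L, 0L, 0L,
              46L, 41L, 0L, 0L,
              21L, 25L, 29L, 30L,
              0L, 0L, 0L, 0L,
              35L, 30L, 30L, 22L)
  data.frame(site = site, habitat = hab,
             n_mtorf = n_mtorf, n_its2 = n_its2, n_psba = n_psba,
             stringsAsFactors = FALSE)
}

#' Marker coverage summary of the default design
#'
#' Totals of colonies with ITS2 data, with psbA data, with both markers, and
#' with at least one symbiont marker. The two-marker overlap is a design
#' constant (280 colonies); the union follows by inclusion-exclusion.
#'
#' @return Named numeric vector with elements `n_mtorf`, `n_its2`, `n_psba`,
#'   `n_both`, `n_symbiont_typed`.
#' @export
marker_summary <- function() {
  d <- sampling_design()
  n_its2 <- sum(d$n_its2)
  n_psba <- sum(d$n_psba)
  n_both <- 280
  c(n_mtorf = sum(d$n_mtorf),
    n_its2 = n_its2,
    n_psba = n_psba,
    n_both = n_both,
    n_symbiont_typed = n_its2 + n_psba - n_both)
}

#' Default species-by-habitat colony counts
#'
#' A species x habitat table of colony counts consistent with the default
#' sampling design: habitat column sums equal the per-habitat mtORF sample
#' sizes, and species row sums give the overall species tallies
#' (303/182/88/75/56/20 of 724). The habitat profiles encode the qualitative
#' distribution patterns the design emulates: P. acuta confined to the
#' fringing reef (one back-reef colony), P. tuahiniensis absent from the
#' fringing reef and peaking at 20 m, P. meandrina hump-shaped with a 5 m
#' peak, P. verrucosa skewed shallow, P. grandis flat but rare at 20 m, and
#' P. cf. effusa absent from the fringing reef and commoner on the fore reef.
#'
#' @return Integer matrix (6 species x 5 habitats) with dimnames.
#' @export
species_habitat_counts <- function() {
  m <- rbind(
    "P. meandrina"    = c(40L, 110L, 92L, 28L, 33L),
    "P. tuahiniensis" = c(0L,  35L,  40L, 22L, 85L),
    "P. verrucosa"    = c(28L, 42L,  8L,  4L,  6L),
    "P. acuta"        = c(74L, 1L,   0L,  0L,  0L),
    "P. grandis"      = c(12L, 31L,  6L,  4L,  3L),
    "P. cf. effusa"   = c(0L,  2L,   8L,  4L,  6L)
  )
  colnames(m) <- reef_habitats()
  m
}

#' mtORF haplotype to species lookup
#'
#' Haplotype 10 identifies P. tuahiniensis; haplotype 1 is shared by
#' P. meandrina and P. grandis and therefore maps to `"AMBIGUOUS"` until the
#' histone-3 RFLP assay resolves it; haplotype 8, a distinct mitochondrial
#' lineage differing from haplotype 1 by seven base pairs, is treated as
#' P. meandrina; haplotypes 3a/3b/3e/3f/3h are P. verrucosa; 2 and 11 are
#' P. cf. effusa; 5a is P. acuta.
#'
#' @return A data.frame with columns `haplotype` and `species`.
#' @export
haplotype_species_map <- function() {
  data.frame(
    haplotype = c("10", "1", "8", "3a", "3b", "3e", "3f", "3h", "2", "11", "5a"),
    species = c("P. tuahiniensis", "AMBIGUOUS", "P. meandrina",
                rep("P. verrucosa", 5L), "P. cf. effusa", "P. cf. effusa",
                "P. acuta"),
    stringsAsFactors = FALSE
  )
}

#' Diagnostic ITS2 DIVs per symbiont species
#'
#' DIV names whose presence is treated as diagnostic of a symbiont species:
#' C42a/C42g for C. latusorum, C1d/C1ag for C. pacificum, C116 for the
#' unalignable Cladocopium C116 group, A1/A1fi for S. microadriaticum and
#' D1/D2d/D6/D4 for D. glynnii. No DIV appears under two species.
#'
#' @return Named list mapping symbiont species to character vectors of DIVs.
#' @export
div_diagnostic_map <- function() {
  list(
    "C. latusorum"       = c("C42a", "C42g"),
    "C. pacificum"       = c("C1d", "C1ag"),
    "Cladocopium C116"   = "C116",
    "S. microadriaticum" = c("A1", "A1fi"),
    "D. glynnii"         = c("D1", "D2d", "D6", "D4")
  )
}

#' psbA clade to Cladocopium species lookup
#'
#' Nine plastid minicircle clades: I-IV fall within C. latusorum and V-IX
#' within C. pacificum (clades VII-IX less well supported, hence the map is
#' data rather than code and can be overridden).
#'
#' @return A data.frame with columns `clade` and `species`.
#' @export
psba_clade_map <- function() {
  data.frame(
    clade = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX"),
    species = c(rep("C. latusorum", 4L), rep("C. pacificum", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Default host-symbiont association design
#'
#' Per-colony symbiont species sets for the 423 symbiont-typed colonies of
#' the default design, one row per distinct set with its colony tally.
#' Row denominators per host: P. meandrina 156, P. grandis 27, P. cf. effusa
#' 13, P. tuahiniensis 140, P. verrucosa 47, P. acuta 40. Thirteen colonies
#' carry two symbiont species, so marginal percentages per host can exceed
#' 100.
#'
#' @return A data.frame with columns `host`, `symbionts` (species separated
#'   by `;`) and `n`.
#' @export
association_design <- function() {
  lat <- "C. latusorum"; pac <- "C. pacificum"; c116 <- "Cladocopium C116"
  smic <- "S. microadriaticum"; gly <- "D. glynnii"
  rows <- list(
    c("P. meandrina", lat, 151L),
    c("P. meandrina", c116, 5L),
    c("P. grandis", lat, 22L),
    c("P. grandis", paste(lat, smic, sep = ";"), 3L),
    c("P. grandis", c116, 1L),
    c("P. grandis", smic, 1L),
    c("P. cf. effusa", lat, 10L),
    c("P. cf. effusa", paste(lat, gly, sep = ";"), 1L),
    c("P. cf. effusa", paste(lat, pac, sep = ";"), 1L),
    c("P. cf. effusa", pac, 1L),
    c("P. tuahiniensis", pac, 129L),
    c("P. tuahiniensis", paste(pac, gly, sep = ";"), 1L),
    c("P. tuahiniensis", lat, 8L),
    c("P. tuahiniensis", c116, 2L),
    c("P. verrucosa", pac, 42L),
    c("P. verrucosa", paste(pac, gly, sep = ";"), 1L),
    c("P. verrucosa", lat, 2L),
    c("P. verrucosa", gly, 2L),
    c("P. acuta", gly, 32L),
    c("P. acuta", paste(gly, pac, sep = ";"), 5L),
    c("P. acuta", paste(gly, lat, sep = ";"), 1L),
    c("P. acuta", pac, 1L),
    c("P. acuta", c116, 1L)
  )
  out <- data.frame(
    host = vapply(rows, `[`, "", 1L),
    symbionts = vapply(rows, `[`, "", 2L),
    n = as.integer(vapply(rows, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  out
}

#' Expand an association design into per-colony symbiont calls
#'
#' @param design A data.frame as returned by [association_design()].
#' @return A data.frame with one row per colony: `colony_id`, `host`,
#'   `symbionts` (`;`-separated species set).
#' @export
expand_association_design <- function(design = association_design()) {
  idx <- rep(seq_len(nrow(design)), design$n)
  out <- data.frame(
    colony_id = sprintf("assoc_%03d", seq_along(idx)),
    host = design$host[idx],
    symbionts = design$symbionts[idx],
    stringsAsFactors = FALSE
  )
  out
}

#' Mean DIV relative-abundance profiles per symbiont species
#'
#' Each symbiont species is given a mean profile over the shared DIV column
#' space: diagnostic DIVs carry most of the mass, with background intragenomic
#' variants (e.g. the C1 radiation shared by both Cladocopium species) making
#' up the rest. Profiles sum to 1.
#'
#' @return Numeric matrix, one row per symbiont species, one column per DIV.
#' @export
div_profiles <- function() {
  divs <- c("C42a", "C42g", "C1", "C42.2", "C3cg",
            "C1d", "C1ag", "C1ah", "C3cw",
            "C116", "C116a", "A1", "A1fi", "A1z",
            "D1", "D2d", "D6", "D4")
  m <- matrix(0, nrow = 5L, ncol = length(divs),
              dimnames = list(symbiont_species(), divs))
  m["C. latusorum", c("C42a", "C42g", "C1", "C42.2", "C3cg")] <-
    c(0.45, 0.25, 0.15, 0.10, 0.05)
  m["C. pacificum", c("C1d", "C1ag", "C1", "C1ah", "C3cw")] <-
    c(0.45, 0.25, 0.15, 0.10, 0.05)
  m["Cladocopium C116", c("C116", "C116a")] <- c(0.80, 0.20)
  m["S. microadriaticum", c("A1", "A1fi", "A1z")] <- c(0.70, 0.25, 0.05)
  m["D. glynnii", c("D1", "D2d", "D6", "D4")] <- c(0.55, 0.20, 0.15, 0.10)
  m
}

#' Default host to symbiont association probabilities
#'
#' Primary-symbiont probability vectors per host species, consistent with the
#' default association design's dominant-symbiont frequencies.
#'
#' @return Numeric matrix, hosts x symbiont species; rows sum to 1.
#' @export
symbiont_assoc_probs <- function() {
  sp <- symbiont_species()
  m <- matrix(0, nrow = 6L, ncol = 5L,
              dimnames = list(pocillopora_species(), sp))
  m["P. meandrina", ] <- c(151, 0, 5, 0, 0) / 156
  m["P. tuahiniensis", ] <- c(8, 130, 2, 0, 0) / 140
  m["P. verrucosa", ] <- c(2, 43, 0, 0, 2) / 47
  m["P. acuta", ] <- c(0, 1, 1, 0, 38) / 40
  m["P. grandis", ] <- c(25, 0, 1, 1, 0) / 27
  m["P. cf. effusa", ] <- c(12, 1, 0, 0, 0) / 13
  sweep(m, 1L, rowSums(m), "/")
}
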