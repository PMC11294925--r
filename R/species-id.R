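# Host species assignment: nearest-reference mtORF haplotype calling with
# free-end-gap edit distance, the Table-2-style haplotype -> species lookup,
# and in-silico XhoI digestion of histone-3 amplicons to split the two
# species sharing mtORF haplotype 1.

.check_dna <- function(x, what = "sequence") {
  x <- toupper(chartr("u", "t", x))
  if (grepl("[^ACGTN]", x)) {
    stop(what, " contains characters outside {A,C,G,T,N}")
  }
  x
}

# Unit-cost edit distance of each query aligned globally into one reference
# whose ends are free: every query base is consumed (matched, mismatched or
# gapped at cost 1) while reference overhangs cost nothing, so amplicon
# trimming relative to the reference is unpenalised. Minimising a distance
# with free ends on BOTH sequences would be degenerate (aligning nothing
# costs zero), hence the query is the globally aligned side. Computed by a
# compiled dynamic program; the aligned length used for the identity
# threshold is the query length (the query is aligned in full).
.editdist_free_ends <- function(queries, reference) {
  d <- .feg_editdist_matrix(queries, reference)
  list(distance = as.numeric(d[, 1L]), aligned = nchar(queries))
}

# Distance matrix (queries x panel references) taking the better of the two
# query orientations; the reverse complement is only aligned for queries
# whose forward minimum is nonzero. Distances are computed exactly up to a
# cap comfortably above the identity threshold; anything beyond it is
# already LOW_IDENTITY, so the capped value only affects the reported
# distance of rejected queries.
.panel_distances <- function(queries, panel, max_distance_frac = 0.03) {
  queries <- vapply(queries, .check_dna, "", USE.NAMES = FALSE)
  cap <- as.integer(ceiling(max_distance_frac * max(nchar(queries))) + 8L)
  dist <- .feg_editdist_matrix(queries, panel$sequence, cap)
  imperfect <- which(apply(dist, 1L, min) > 0L)
  if (length(imperfect)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(queries[imperfect])))
    dist_rev <- .feg_editdist_matrix(rc, panel$sequence, cap)
    better <- apply(dist_rev, 1L, min) < apply(dist[imperfect, , drop = FALSE],
                                               1L, min)
    dist[imperfect[better], ] <- dist_rev[better, , drop = FALSE]
  }
  dist <- matrix(as.numeric(dist), nrow = length(queries))
  alen <- matrix(nchar(queries), nrow = length(queries), ncol = nrow(panel))
  colnames(dist) <- colnames(alen) <- panel$haplotype
  list(distance = dist, aligned = alen)
}

# haplotype decision from one row of the panel-distance matrices
.haplotype_decision <- function(dist, alen, panel, max_distance_frac) {
  i <- which(dist == min(dist))
  if (min(dist) / max(alen[i[1L]], 1) > max_distance_frac) {
    return(list(haplotype = NA_character_, distance = as.integer(min(dist)),
                flags = "LOW_IDENTITY"))
  }
  if (length(i) > 1L) {
    return(list(haplotype = NA_character_, distance = as.integer(min(dist)),
                flags = "TIE"))
  }
  list(haplotype = panel$haplotype[i], distance = as.integer(dist[i]),
       flags = character(0))
}

#' Assign an mtORF query sequence to its nearest reference haplotype
#'
#' Computes the unit-cost edit distance between the query and every panel
#' reference under global alignment with free end gaps (length differences
#' at the amplicon ends are not penalised). Both orientations of the query
#' are scanned and the better one used. The minimum-distance reference gives
#' the haplotype; ties yield no call with flag `TIE`, and queries whose
#' best identity falls below the threshold yield no call with flag
#' `LOW_IDENTITY`.
#'
#' @param query DNA sequence (character scalar; A/C/G/T/N, case-insensitive,
#'   U tolerated).
#' @param panel A reference panel data.frame with columns `haplotype` and
#'   `sequence`.
#' @param max_distance_frac Maximum tolerated distance / aligned length
#'   (default 0.03).
#' @return List with `haplotype` (character or `NA`), `distance` (integer),
#'   `flags` (character vector, possibly empty).
#' @export
assign_haplotype <- function(query, panel, max_distance_frac = 0.03) {
  if (nrow(panel) == 0L) stop("empty reference panel")
  query <- .check_dna(query, "query")
  if (nchar(query) < 200L) stop("query shorter than 200 bases")
  d <- .panel_distances(query, panel)
  .haplotype_decision(d$distance[1L, ], d$aligned[1L, ], panel,
                      max_distance_frac)
}

#' Map an mtORF haplotype to a Pocillopora species
#'
#' Haplotype 1 returns `"AMBIGUOUS"`: it is shared by P. meandrina and
#' P. grandis and requires the histone-3 RFLP assay to resolve.
#'
#' @param haplotype Haplotype name (e.g. `"10"`, `"3a"`).
#' @param map Lookup table; defaults to [haplotype_species_map()].
#' @return Species label, or `"AMBIGUOUS"`.
#' @export
haplotype_to_species <- function(haplotype, map = haplotype_species_map()) {
  i <- match(haplotype, map$haplotype)
  if (is.na(i)) {
    stop("unknown haplotype '", haplotype, "'; known haplotypes: ",
         paste(map$haplotype, collapse = ", "))
  }
  map$species[i]
}

#' In-silico restriction digest
#'
#' Cuts an amplicon at every forward-strand occurrence of the recognition
#' site, `cut_offset` bases into the site (XhoI cuts C^TCGAG, so the default
#' offset is 1). The XhoI site is palindromic, so forward-strand scanning
#' covers both strands. Fragment lengths always sum to the amplicon length.
#'
#' @param amplicon DNA sequence.
#' @param recognition_site Recognition motif (default `"CTCGAG"`).
#' @param cut_offset Bases into the site at which the cut falls (default 1).
#' @return List of class `digest_result`: `fragment_lengths` (descending),
#'   `n_sites`, `pattern_call` (`"single_band"`, `"two_band"` or
#'   `"three_band_like"`).
#' @export
insilico_digest <- function(amplicon, recognition_site = "CTCGAG",
                            cut_offset = 1L) {
  amplicon <- .check_dna(amplicon, "amplicon")
  if (nchar(amplicon) == 0L) stop("empty amplicon")
  if (nchar(recognition_site) > nchar(amplicon)) {
    stop("recognition site longer than amplicon")
  }
  hits <- gregexpr(recognition_site, amplicon, fixed = TRUE)[[1L]]
  starts <- hits[hits > 0L]
  cuts <- starts + cut_offset - 1L       # position of last base before cut
  bounds <- c(0L, sort(cuts), nchar(amplicon))
  frags <- diff(bounds)
  frags <- frags[frags > 0L]
  n_sites <- length(starts)
  pattern <- if (n_sites == 0L) "single_band"
             else if (n_sites == 1L) "two_band"
             else "three_band_like"
  structure(list(fragment_lengths = sort(as.integer(frags), decreasing = TRUE),
                 n_sites = n_sites, pattern_call = pattern),
            class = "digest_result")
}

#' Resolve a haplotype-1 colony to species from its digest pattern
#'
#' An uncut histone-3 amplicon (single ~700 bp band) indicates P. meandrina;
#' any cutting (two bands at ~400/300, or a three-band partial-digest
#' phenotype) indicates P. grandis. The partial-digest pattern gets a
#' `PARTIAL_DIGEST` flag.
#'
#' @param digest A `digest_result` from [insilico_digest()].
#' @return List with `species` and `flags`.
#' @export
rflp_to_species <- function(digest) {
  if (digest$n_sites == 0L && digest$pattern_call == "single_band") {
    return(list(species = "P. meandrina", flags = character(0)))
  }
  flags <- if (digest$pattern_call == "three_band_like") "PARTIAL_DIGEST"
           else character(0)
  list(species = "P. grandis", flags = flags)
}

#' Call the species of one colony from its marker sequences
#'
#' Orchestrates haplotype assignment, the haplotype -> species lookup, and
#' RFLP resolution when the haplotype is 1 and a histone sequence is
#' supplied. Haplotype-1 colonies without histone data are returned as
#' `"AMBIGUOUS"` with flag `NO_RFLP`.
#'
#' @param mtorf mtORF query sequence.
#' @param histone Optional histone-3 amplicon sequence.
#' @param panel Reference panel.
#' @param map Haplotype -> species lookup.
#' @param max_distance_frac Passed to [assign_haplotype()].
#' @return List of class `species_call`: `haplotype`, `species`, `distance`,
#'   `method` (`"mtORF"` or `"mtORF+RFLP"`), `flags`.
#' @export
call_species <- function(mtorf, histone = NULL, panel,
                         map = haplotype_species_map(),
                         max_distance_frac = 0.03) {
  hap <- assign_haplotype(mtorf, panel, max_distance_frac)
  if (is.na(hap$haplotype)) {
    return(structure(list(haplotype = NA_character_, species = NA_character_,
                          distance = hap$distance, method = "mtORF",
                          flags = hap$flags), class = "species_call"))
  }
  species <- haplotype_to_species(hap$haplotype, map)
  method <- "mtORF"
  flags <- hap$flags
  if (identical(species, "AMBIGUOUS")) {
    if (is.null(histone)) {
      flags <- c(flags, "NO_RFLP")
    } else {
      res <- rflp_to_species(insilico_digest(histone))
      species <- res$species
      flags <- c(flags, res$flags)
      method <- "mtORF+RFLP"
    }
  }
  structure(list(haplotype = hap$haplotype, species = species,
                 distance = hap$distance, method = method, flags = flags),
            class = "species_call")
}

#' Call species for a whole cohort
#'
#' @param mtorf Named character vector of mtORF sequences (names are colony
#'   ids).
#' @param histone Named character vector of histone sequences for the
#'   colonies that have them.
#' @param panel Reference panel.
#' @param map Haplotype -> species lookup.
#' @param max_distance_frac Passed to [assign_haplotype()].
#' @return A data.frame with one row per colony: `colony_id`, `haplotype`,
#'   `species`, `distance`, `method`, `flags` (`;`-separated).
#' @export
call_species_cohort <- function(mtorf, histone = character(0), panel,
                                map = haplotype_species_map(),
                                max_distance_frac = 0.03) {
  ids <- names(mtorf)
  if (is.null(ids)) stop("mtorf must be a named vector of sequences")
  d <- .panel_distances(unname(mtorf), panel)   # batched alignments
  rows <- lapply(seq_along(ids), function(ii) {
    id <- ids[ii]
    hap <- .haplotype_decision(d$distance[ii, ], d$aligned[ii, ], panel,
                               max_distance_frac)
    if (is.na(hap$haplotype)) {
      return(data.frame(colony_id = id, haplotype = NA_character_,
                        species = NA_character_, distance = hap$distance,
                        method = "mtORF",
                        flags = paste(hap$flags, collapse = ";"),
                        stringsAsFactors = FALSE))
    }
    species <- haplotype_to_species(hap$haplotype, map)
    method <- "mtORF"; flags <- hap$flags
    if (identical(species, "AMBIGUOUS")) {
      if (id %in% names(histone)) {
        res <- rflp_to_species(insilico_digest(histone[[id]]))
        species <- res$species; flags <- c(flags, res$flags)
        method <- "mtORF+RFLP"
      } else {
        flags <- c(flags, "NO_RFLP")
      }
    }
    data.frame(colony_id = id, haplotype = hap$haplotype, species = species,
               distance = hap$distance, method = method,
               flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
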