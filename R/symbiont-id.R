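# Symbiont species calling from ITS2 DIV profiles and psbA clade labels,
# and construction of the host x symbiont association table. ITS2 is not a
# species-level marker within Cladocopium, so the psbA clade, when present,
# is authoritative for Cladocopium species identity.

#' Classify symbiont species from an ITS2 DIV profile
#'
#' A symbiont species is called present when the summed read share of its
#' diagnostic DIVs (computed on the full profile) reaches `min_frac`.
#' Multiple species may be called on one colony (dual infections). Profiles
#' with no diagnostic signal return an empty set with flag `UNCLASSIFIED`.
#'
#' @param counts Named nonnegative integer vector: DIV name -> read count.
#' @param map Diagnostic DIV map; defaults to [div_diagnostic_map()].
#' @param min_frac Minimum diagnostic read share to call a species present
#'   (default 0.05).
#' @return A data.frame with columns `species` and `share`, ordered by
#'   decreasing share; attribute `flags` carries `UNCLASSIFIED` when empty.
#' @export
classify_from_its2 <- function(counts, map = div_diagnostic_map(),
                               min_frac = 0.05) {
  total <- sum(counts)
  if (length(counts) == 0L || total <= 0) stop("empty DIV profile")
  dup <- intersect(unlist(map), unlist(map)[duplicated(unlist(map))])
  if (length(dup)) stop("DIVs diagnostic for two species: ",
                        paste(dup, collapse = ", "))
  shares <- vapply(map, function(divs) {
    sum(counts[intersect(names(counts), divs)]) / total
  }, numeric(1))
  keep <- shares >= min_frac
  out <- data.frame(species = names(shares)[keep],
                    share = unname(shares[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$share), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flags") <- if (nrow(out) == 0L) "UNCLASSIFIED" else character(0)
  out
}

#' Reconcile ITS2 species calls with a psbA clade label
#'
#' For Cladocopium, psbA is authoritative: its clade's species replaces or
#' confirms the ITS2 Cladocopium call, with a conflict flag when both
#' markers exist and disagree. Non-Cladocopium ITS2 calls pass through, and
#' colonies with only one marker are called from that marker alone. The
#' unalignable Cladocopium C116 group is kept as its own genus-level call
#' and never overridden by psbA.
#'
#' @param its2_calls Data.frame from [classify_from_its2()] (possibly empty).
#' @param psba_clade psbA clade label (`"I"`..`"IX"`) or `NA`/`NULL` when
#'   absent.
#' @param clade_map Clade -> species lookup; defaults to [psba_clade_map()].
#' @return List of class `symbiont_call`: `species_set` (character),
#'   `dominant` (largest diagnostic share, or the psbA species when ITS2 is
#'   absent), `evidence` (named character: `"ITS2"`, `"psbA"` or `"both"`),
#'   `conflict` (logical).
#' @export
reconcile_with_psba <- function(its2_calls, psba_clade = NULL,
                                clade_map = psba_clade_map()) {
  cladocopium <- c("C. latusorum", "C. pacificum")
  set <- its2_calls$species
  share_of <- stats::setNames(its2_calls$share, its2_calls$species)
  evidence <- stats::setNames(rep("ITS2", length(set)), set)
  conflict <- FALSE
  if (!is.null(psba_clade) && !is.na(psba_clade)) {
    i <- match(psba_clade, clade_map$clade)
    if (is.na(i)) {
      stop("unknown psbA clade '", psba_clade, "'; known clades: ",
           paste(clade_map$clade, collapse = ", "))
    }
    psba_species <- clade_map$species[i]
    its2_clado <- intersect(set, cladocopium)
    if (length(its2_clado)) {
      conflict <- !psba_species %in% its2_clado
      set <- union(setdiff(set, its2_clado), psba_species)
      # the psbA species inherits the diagnostic share of the ITS2
      # Cladocopium signal it confirms or overrides
      share_of[psba_species] <- max(share_of[its2_clado])
      evidence <- evidence[!names(evidence) %in% its2_clado]
      evidence[psba_species] <- if (conflict) "psbA" else "both"
    } else {
      set <- union(set, psba_species)
      # psbA-only Cladocopium outranks ITS2 species when no ITS2 exists
      share_of[psba_species] <- if (length(its2_calls$species)) 0 else Inf
      evidence[psba_species] <- "psbA"
    }
  }
  dominant <- NA_character_
  if (length(set)) {
    dominant <- set[which.max(share_of[set])]
  }
  structure(list(species_set = set, dominant = dominant,
                 evidence = evidence[set], conflict = conflict),
            class = "symbiont_call")
}

#' Call symbionts for a whole cohort
#'
#' @param div_counts Integer matrix, colonies x DIVs (rownames are colony
#'   ids). Colonies with zero totals are skipped.
#' @param psba Data.frame with `colony_id` and `clade`; may cover colonies
#'   absent from `div_counts` (psbA-only colonies are called from psbA
#'   alone).
#' @param map Diagnostic DIV map.
#' @param clade_map psbA clade -> species lookup.
#' @param min_frac Diagnostic share threshold.
#' @return A data.frame: `colony_id`, `symbionts` (`;`-separated species
#'   set), `dominant`, `conflict`, `flags`.
#' @export
symbiont_calls <- function(div_counts, psba = NULL,
                           map = div_diagnostic_map(),
                           clade_map = psba_clade_map(), min_frac = 0.05) {
  empty_its2 <- data.frame(species = character(0), share = numeric(0),
                           stringsAsFactors = FALSE)
  clade_of <- function(id) {
    if (is.null(psba)) return(NA_character_)
    i <- match(id, psba$colony_id)
    if (is.na(i)) NA_character_ else psba$clade[i]
  }
  ids_its2 <- if (is.null(div_counts)) character(0) else rownames(div_counts)
  ids_psba <- if (is.null(psba)) character(0) else psba$colony_id
  ids <- union(ids_its2, ids_psba)
  rows <- lapply(ids, function(id) {
    flags <- character(0)
    if (id %in% ids_its2) {
      counts <- div_counts[id, ]
      if (sum(counts) <= 0) {
        its2 <- empty_its2
        flags <- "ZERO_TOTAL"
      } else {
        its2 <- classify_from_its2(counts, map, min_frac)
        flags <- attr(its2, "flags")
      }
    } else {
      its2 <- empty_its2
    }
    call <- reconcile_with_psba(its2, clade_of(id), clade_map)
    data.frame(colony_id = id,
               symbionts = paste(call$species_set, collapse = ";"),
               dominant = call$dominant, conflict = call$conflict,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Host x symbiont association table
#'
#' Joins host species calls to symbiont calls on colony id and tabulates,
#' for every host species, the percentage (and count) of its symbiont-typed
#' colonies hosting each symbiont species. Because some colonies host two
#' symbiont species, row percentages can exceed 100.
#'
#' @param symbionts Data.frame with `colony_id` and `symbionts`
#'   (`;`-separated species set); rows with an empty set are dropped.
#' @param hosts Data.frame with `colony_id` and a host species column named
#'   `species` (or `host`).
#' @return List of class `association_table`: `percent` and `count`
#'   (host x symbiont matrices) and `n_colonies` (per-host denominators).
#' @export
association_table <- function(symbionts, hosts) {
  host_col <- if ("species" %in% names(hosts)) "species" else "host"
  merged <- merge(symbionts, hosts[, c("colony_id", host_col)],
                  by = "colony_id")
  names(merged)[names(merged) == host_col] <- "host"
  merged <- merged[!is.na(merged$host) & nzchar(merged$symbionts), ,
                   drop = FALSE]
  if (nrow(merged) == 0L) stop("no colonies with both a host and a symbiont call")
  sets <- strsplit(merged$symbionts, ";", fixed = TRUE)
  host_levels <- unique(merged$host)
  symb_levels <- unique(unlist(sets))
  count <- matrix(0L, length(host_levels), length(symb_levels),
                  dimnames = list(host_levels, symb_levels))
  denom <- table(factor(merged$host, levels = host_levels))
  for (i in seq_along(sets)) {
    count[merged$host[i], sets[[i]]] <- count[merged$host[i], sets[[i]]] + 1L
  }
  percent <- 100 * sweep(count, 1L, as.numeric(denom), "/")
  structure(list(percent = percent, count = count,
                 n_colonies = stats::setNames(as.integer(denom), host_levels)),
            class = "association_table")
}
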