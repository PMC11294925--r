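# File formats and pipeline orchestration. FASTA goes through Biostrings;
# tabular artifacts are tab-separated UTF-8 with a commented provenance
# header line ('# ...') recording package version and seed.

#' Read a FASTA file
#'
#' Accepts wrapped and unwrapped line styles; sequences are case-folded to
#' upper case and U is mapped to T. Duplicate ids and empty files are
#' errors.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs))) stop("sequences must be named")
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

.provenance_line <- function(seed = NA) {
  ver <- tryCatch(as.character(utils::packageVersion("crypticniche")),
                  error = function(e) "dev")
  sprintf("# crypticniche %s | seed=%s | written=%s", ver, seed,
          format(Sys.time(), "%Y-%m-%d"))
}

#' Write a data.frame as tab-separated values with a provenance header
#'
#' @param x Data.frame.
#' @param path Output path.
#' @param seed Seed recorded in the header comment.
#' @export
write_tsv <- function(x, path, seed = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance_line(seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' Comment lines starting with `#` are skipped.
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a SymPortal-style DIV count matrix
#'
#' Tab-separated, header row of DIV names, first column sample ids, integer
#' cells. Column order is preserved (it defines the resource-state count R
#' for symbiont niche breadth).
#'
#' @param path Input path.
#' @return Integer matrix with sample rownames and DIV colnames.
#' @export
read_div_matrix <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("DIV matrix needs a sample column plus DIV columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!is.finite(suppressWarnings(as.numeric(m))) |
                 as.numeric(m) != round(as.numeric(m)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("non-integer DIV count at row %d ('%s'), column '%s'",
                 rc[1L], ids[rc[1L]], colnames(m)[rc[2L]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a DIV count matrix
#'
#' @param m Integer matrix, samples x DIVs.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @export
write_div_matrix <- function(m, path, seed = NA) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, seed)
}

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Integer seed recorded in every output and driving the
#'   simulator and permutation tests.
#' @param n_perm Permutations for PERMANOVA/dbRDA.
#' @param min_frac ITS2 diagnostic share threshold.
#' @param max_distance_frac Haplotype-assignment identity threshold.
#' @param per_site Emit per-site niche breadth/overlap tables as well.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "identify", "symbionts", "stats", "niche")` in that
#'   order. Later stages depend on earlier ones.
#' @param sim Simulation configuration ([sim_config()]); its seed is
#'   overridden by `seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_perm = 999L,
                            min_frac = 0.05, max_distance_frac = 0.03,
                            per_site = TRUE,
                            stages = c("simulate", "identify", "symbionts",
                                       "stats", "niche"),
                            sim = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_perm = as.integer(n_perm), min_frac = min_frac,
                 max_distance_frac = max_distance_frac, per_site = per_site,
                 stages = stages, sim = sim),
            class = "pipeline_config")
}

.stage_deps <- c(identify = "simulate", symbionts = "simulate",
                 stats = "identify", niche = "stats")

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order -- simulate, identify (host
#' species), symbionts, stats (relative abundance, LRTs, ordinations,
#' PERMANOVA), niche (breadths, overlaps, breadth correlation) -- writing
#' every artifact under `config$out_dir` with a provenance header, and
#' logging record counts per stage. Missing stage dependencies are an
#' error naming the missing stage.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a named list of output paths plus a `log` data.frame
#'   of per-stage record counts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stages <- config$stages
  for (st in names(.stage_deps)) {
    if (st %in% stages && !(.stage_deps[[st]] %in% stages)) {
      stop("stage '", st, "' requires stage '", .stage_deps[[st]],
           "' which is not enabled")
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (!quiet) message(...)
  outputs <- list()
  log <- list()
  note <- function(stage, what, n) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, what = what, n = n,
                                           stringsAsFactors = FALSE)
  }

  sim <- NULL; calls <- NULL; symb <- NULL; meta <- NULL
  if ("simulate" %in% stages) {
    panel <- generate_reference_panel(config$seed)
    sim <- simulate_colonies(config$sim, panel)
    symb_sim <- simulate_symbionts(sim$metadata, config$sim)
    meta <- sim$metadata
    write_tsv(meta, path("metadata.tsv"), config$seed)
    write_fasta(sim$mtorf, path("mtorf.fasta"))
    if (length(sim$histone)) write_fasta(sim$histone, path("histone.fasta"))
    write_fasta(stats::setNames(panel$sequence, panel$haplotype),
                path("panel.fasta"))
    write_div_matrix(symb_sim$div_counts, path("div_counts.tsv"), config$seed)
    write_tsv(symb_sim$psba, path("psba.tsv"), config$seed)
    outputs$metadata <- path("metadata.tsv")
    outputs$div_counts <- path("div_counts.tsv")
    note("simulate", "colonies", nrow(meta))
    note("simulate", "colonies_with_its2", nrow(symb_sim$div_counts))
    note("simulate", "colonies_with_psba", nrow(symb_sim$psba))
    say("simulate: ", nrow(meta), " colonies")
    sim$symbionts <- symb_sim
  }
  if ("identify" %in% stages) {
    panel <- generate_reference_panel(config$seed)
    calls <- call_species_cohort(sim$mtorf, sim$histone, panel,
                                 max_distance_frac = config$max_distance_frac)
    calls <- merge(calls, meta[, c("colony_id", "site", "habitat")],
                   by = "colony_id")
    write_tsv(calls, path("species_calls.tsv"), config$seed)
    outputs$species_calls <- path("species_calls.tsv")
    note("identify", "calls", nrow(calls))
    note("identify", "ambiguous", sum(calls$species == "AMBIGUOUS", na.rm = TRUE))
    say("identify: ", nrow(calls), " species calls")
  }
  if ("symbionts" %in% stages) {
    symb <- symbiont_calls(sim$symbionts$div_counts, sim$symbionts$psba,
                           min_frac = config$min_frac)
    write_tsv(symb, path("symbiont_calls.tsv"), config$seed)
    outputs$symbiont_calls <- path("symbiont_calls.tsv")
    note("symbionts", "calls", nrow(symb))
    if (!is.null(calls)) {
      assoc <- association_table(symb, calls)
      assoc_df <- data.frame(host = rownames(assoc$percent),
                             n = assoc$n_colonies,
                             round(assoc$percent, 2), check.names = FALSE)
      write_tsv(assoc_df, path("association_table.tsv"), config$seed)
      outputs$association_table <- path("association_table.tsv")
    }
    say("symbionts: ", nrow(symb), " symbiont calls")
  }
  if ("stats" %in% stages) {
    ra <- relative_abundance(calls)
    write_tsv(ra, path("relative_abundance.tsv"), config$seed)
    outputs$relative_abundance <- path("relative_abundance.tsv")
    lrt <- lapply(sort(unique(calls$species)), function(sp) {
      habs <- unique(calls$habitat[calls$species == sp])
      if (length(habs) < 2L) return(NULL)
      sub <- calls[calls$habitat %in% habs, ]
      r <- habitat_lrt(as.integer(sub$species == sp), sub$habitat)
      data.frame(species = sp, chi2 = r$chi2, df = r$df, p = r$p,
                 stringsAsFactors = FALSE)
    })
    lrt <- do.call(rbind, lrt)
    write_tsv(lrt, path("habitat_lrt.tsv"), config$seed)
    # composition of the site x habitat cells in species proportions
    cells <- interaction(calls$site, calls$habitat, drop = TRUE)
    comp <- prop.table(table(cells, calls$species), margin = 1L)
    comp <- unclass(comp)
    d <- bray_curtis(comp)
    hab_of_cell <- sub("^[^.]*\\.", "", rownames(comp))
    db <- dbrda(d, hab_of_cell, n_perm = config$n_perm, seed = config$seed)
    pm <- permanova(d, hab_of_cell, n_perm = config$n_perm,
                    seed = config$seed)
    jsonlite::write_json(
      list(dbrda = list(F = db$test$statistic, df = c(db$test$df_between,
                                                      db$test$df_within),
                        p = db$test$p, n_perm = db$test$n_perm,
                        prop_constrained = db$prop_constrained),
           permanova = list(F = pm$statistic, df = c(pm$df_between,
                                                     pm$df_within),
                            p = pm$p, n_perm = pm$n_perm),
           seed = config$seed),
      path("composition_tests.json"), auto_unbox = TRUE, digits = NA)
    outputs$composition_tests <- path("composition_tests.json")
    note("stats", "abundance_cells", nrow(ra))
    note("stats", "composition_cells", nrow(comp))
    say("stats: dbRDA F=", round(db$test$statistic, 2),
        ", PERMANOVA F=", round(pm$statistic, 2))
  }
  if ("niche" %in% stages) {
    hb <- habitat_breadth(calls, per_site = config$per_site)
    sb <- symbiont_breadth(sim$symbionts$div_counts, calls)
    ov <- overlap_matrix(calls, per_site = config$per_site)
    write_tsv(hb, path("habitat_breadth.tsv"), config$seed)
    write_tsv(sb, path("symbiont_breadth.tsv"), config$seed)
    write_tsv(ov, path("habitat_overlap.tsv"), config$seed)
    bc <- breadth_correlation(hb, sb)
    jsonlite::write_json(
      list(rho = bc$rho, p = bc$p, exact = bc$exact,
           means = bc$means, seed = config$seed),
      path("breadth_correlation.json"), auto_unbox = TRUE, digits = NA)
    outputs$habitat_breadth <- path("habitat_breadth.tsv")
    outputs$symbiont_breadth <- path("symbiont_breadth.tsv")
    outputs$breadth_correlation <- path("breadth_correlation.json")
    note("niche", "habitat_breadths", nrow(hb))
    note("niche", "symbiont_breadths", nrow(sb))
    say("niche: rho=", round(bc$rho, 3))
  }
  outputs$log <- do.call(rbind, log)
  write_tsv(outputs$log, path("run_log.tsv"), config$seed)
  invisible(outputs)
}
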