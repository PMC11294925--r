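panel_fix <- generate_reference_panel(seed = 1, length = 800)

test_that("every panel reference assigns to itself at distance zero", {
  for (i in seq_len(nrow(panel_fix))) {
    res <- assign_haplotype(panel_fix$sequence[i], panel_fix)
    expect_identical(res$haplotype, panel_fix$haplotype[i])
    expect_identical(res$distance, 0L)
    expect_length(res$flags, 0)
  }
})

test_that("single substitutions move the distance by one without changing the call", {
  seq10 <- strsplit(panel_fix$sequence[panel_fix$haplotype == "10"], "")[[1]]
  set.seed(4)
  pos <- sample(seq_along(seq10), 1)
  seq10[pos] <- setdiff(c("A", "C", "G", "T"), seq10[pos])[1]
  res <- assign_haplotype(paste(seq10, collapse = ""), panel_fix)
  expect_identical(res$haplotype, "10")
  expect_identical(res$distance, 1L)
})

test_that("queries equidistant from two references are flagged TIE", {
  # move 3 of the 7 hap1/hap8 split positions to hap8's base (distances 3
  # and 4), then set a 4th split position to a third base so both distances
  # become 4
  s1 <- strsplit(panel_fix$sequence[panel_fix$haplotype == "1"], "")[[1]]
  s8 <- strsplit(panel_fix$sequence[panel_fix$haplotype == "8"], "")[[1]]
  diff_pos <- which(s1 != s8)
  q <- s1
  q[diff_pos[1:3]] <- s8[diff_pos[1:3]]
  third <- setdiff(c("A", "C", "G", "T"), c(s1[diff_pos[4]], s8[diff_pos[4]]))
  q[diff_pos[4]] <- third[1]
  res <- assign_haplotype(paste(q, collapse = ""), panel_fix)
  expect_identical(res$flags, "TIE")
  expect_true(is.na(res$haplotype))
})

test_that("alignment distances match a dynamic-programming oracle", {
  set.seed(8)
  refs <- random_dna(3, 40)
  small_panel <- data.frame(haplotype = c("a", "b", "c"), species = NA,
                            sequence = refs, stringsAsFactors = FALSE)
  for (i in 1:20) {
    q <- random_dna(1, sample(30:50, 1))
    got <- crypticniche:::.panel_distances(q, small_panel,
                                           max_distance_frac = 2)$distance[1, ]
    want_fwd <- vapply(refs, function(r) feg_oracle(q, r), 0, USE.NAMES = FALSE)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    want_rev <- vapply(refs, function(r) feg_oracle(rc, r), 0, USE.NAMES = FALSE)
    want <- if (min(want_rev) < min(want_fwd)) want_rev else want_fwd
    expect_equal(unname(got), want)
  }
})

test_that("reverse-complemented queries are recognised", {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(panel_fix$sequence[panel_fix$haplotype == "5a"])))
  res <- assign_haplotype(rc, panel_fix)
  expect_identical(res$haplotype, "5a")
  expect_identical(res$distance, 0L)
})

test_that("divergent and malformed queries are rejected appropriately", {
  set.seed(3)
  res <- assign_haplotype(random_dna(1, 800), panel_fix)
  expect_identical(res$flags, "LOW_IDENTITY")
  expect_error(assign_haplotype("ACGTX", panel_fix), "A,C,G,T,N")
  expect_error(assign_haplotype(random_dna(1, 100), panel_fix), "200")
  expect_error(assign_haplotype(random_dna(1, 800), panel_fix[0, ]), "empty")
})

test_that("haplotypes map to species as in the validated lookup", {
  expect_identical(haplotype_to_species("8"), "P. meandrina")
  expect_identical(haplotype_to_species("1"), "AMBIGUOUS")
  expect_identical(haplotype_to_species("10"), "P. tuahiniensis")
  expect_identical(haplotype_to_species("3f"), "P. verrucosa")
  expect_identical(haplotype_to_species("11"), "P. cf. effusa")
  expect_error(haplotype_to_species("99"), "known haplotypes")
})

test_that("digest fragment arithmetic follows the cut offset", {
  tpl <- histone_templates(seed = 1)
  no_cut <- insilico_digest(tpl[["P. meandrina"]])
  expect_identical(no_cut$fragment_lengths, 700L)
  expect_identical(no_cut$pattern_call, "single_band")
  cut <- insilico_digest(tpl[["P. grandis"]])
  expect_identical(sort(cut$fragment_lengths), c(300L, 400L))
  expect_identical(cut$pattern_call, "two_band")
  # hand-checked cut arithmetic: site starting at 0-based 399 cuts 400/300
  set.seed(6)
  base <- strsplit(random_dna(1, 700), "")[[1]]
  amp <- paste(c(base[1:399], "CTCGAG", base[406:700]), collapse = "")
  d <- insilico_digest(amp)
  if (d$n_sites == 1L) expect_identical(d$fragment_lengths, c(400L, 300L))
  minimal <- insilico_digest("CTCGAG")
  expect_setequal(minimal$fragment_lengths, c(1L, 5L))
  expect_error(insilico_digest("ACG", recognition_site = "CTCGAG"), "longer")
})

test_that("fragment lengths always sum to the amplicon length", {
  set.seed(12)
  for (i in 1:50) {
    amp <- random_dna(1, sample(20:200, 1))
    motif <- paste(sample(c("A", "C", "G", "T"), 3), collapse = "")
    d <- insilico_digest(amp, recognition_site = motif,
                         cut_offset = sample(1:3, 1))
    expect_identical(sum(d$fragment_lengths), nchar(amp))
    # one more fragment than cuts, except when a cut falls on a boundary
    expect_lte(length(d$fragment_lengths), d$n_sites + 1L)
    expect_gte(length(d$fragment_lengths), 1L)
  }
})

test_that("digest patterns resolve haplotype-1 colonies", {
  expect_identical(
    rflp_to_species(list(n_sites = 0L, pattern_call = "single_band"))$species,
    "P. meandrina")
  expect_identical(
    rflp_to_species(list(n_sites = 1L, pattern_call = "two_band"))$species,
    "P. grandis")
  partial <- rflp_to_species(list(n_sites = 2L,
                                  pattern_call = "three_band_like"))
  expect_identical(partial$species, "P. grandis")
  expect_identical(partial$flags, "PARTIAL_DIGEST")
})

test_that("the full call pipeline recovers simulated species exactly at zero noise", {
  cfg <- small_sim_config(seed = 17)
  sim <- simulate_colonies(cfg, panel_fix)
  calls <- call_species_cohort(sim$mtorf, sim$histone, panel_fix)
  m <- merge(calls, sim$metadata, by = "colony_id")
  cm <- table(m$true_species, m$species)
  off_diag <- rownames(cm)[row(cm)] != colnames(cm)[col(cm)]
  expect_true(all(cm[off_diag] == 0))
  expect_identical(mean(m$species == m$true_species), 1)
  # grandis went through the RFLP branch
  expect_true(all(m$method[m$true_species == "P. grandis"] == "mtORF+RFLP"))
})

test_that("haplotype-1 colonies without histone data stay ambiguous", {
  hap1 <- panel_fix$sequence[panel_fix$haplotype == "1"]
  cl <- call_species(hap1, histone = NULL, panel = panel_fix)
  expect_identical(cl$species, "AMBIGUOUS")
  expect_true("NO_RFLP" %in% cl$flags)
  tpl <- histone_templates(seed = 1)
  cl2 <- call_species(hap1, histone = tpl[["P. grandis"]], panel = panel_fix)
  expect_identical(cl2$species, "P. grandis")
  expect_identical(cl2$method, "mtORF+RFLP")
})
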