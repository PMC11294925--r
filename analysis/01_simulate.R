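#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort at the scale of the built-in
# sampling design (4 sites x 5 habitats, 724 colonies) and write all raw
# artifacts: colony metadata, mtORF and histone-3 amplicons, the reference
# haplotype panel, the ITS2 DIV count matrix and the psbA clade table.

suppressPackageStartupMessages(library(crypticniche))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- generate_reference_panel(seed = seed)
cfg <- sim_config(seed = seed)
sim <- simulate_colonies(cfg, panel)
symb <- simulate_symbionts(sim$metadata, cfg)

write_tsv(sim$metadata, file.path(out, "metadata.tsv"), seed)
write_fasta(sim$mtorf, file.path(out, "mtorf.fasta"))
write_fasta(sim$histone, file.path(out, "histone.fasta"))
write_fasta(stats::setNames(panel$sequence, panel$haplotype),
            file.path(out, "panel.fasta"))
write_div_matrix(symb$div_counts, file.path(out, "div_counts.tsv"), seed)
write_tsv(symb$psba, file.path(out, "psba.tsv"), seed)
write_tsv(symb$truth, file.path(out, "symbiont_truth.tsv"), seed)

message(sprintf("simulated %d colonies across %d sites x %d habitats",
                nrow(sim$metadata), length(cfg$site_names),
                length(cfg$habitat_names)))
message(sprintf("%d colonies with ITS2 profiles, %d with psbA clades",
                nrow(symb$div_counts), nrow(symb$psba)))
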