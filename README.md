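# crypticniche

Niche breadth and overlap analysis for morphologically cryptic coral
species (*Pocillopora* spp.) and their algal symbionts (Symbiodiniaceae),
from marker data to community statistics.

Several *Pocillopora* species co-occur on Indo-Pacific reefs and cannot be
told apart in the field; they can, however, partition the reef's structural
habitat zones (fringing reef, back reef, fore reef at 5/10/20 m) and host
different symbiont species. This package implements the full analysis chain
for that question:

* **Host identification** — mtORF haplotype assignment by nearest reference
  under a free-reference-end edit distance (compiled, banded DP), the
  haplotype-to-species lookup, and an in-silico XhoI RFLP of the histone-3
  amplicon to split *P. meandrina* from *P. grandis*, which share mtORF
  haplotype 1 (single ~700 bp band = *P. meandrina*; ~400 + ~300 bp =
  *P. grandis*).
* **Symbiont identification** — species calls from diagnostic ITS2 DIV read
  shares (C42a/C42g → *C. latusorum*, C1d/C1ag → *C. pacificum*, C116,
  A1/A1fi → *S. microadriaticum*, D1/D2d/D6/D4 → *D. glynnii*), reconciled
  with psbA^ncr^ clades (I–IV → *C. latusorum*, V–IX → *C. pacificum*),
  which are authoritative within *Cladocopium*; host × symbiont association
  tables with dual-infection accounting.
* **Community statistics** — habitat-wise relative abundance with
  binomial-GLM-equivalent confidence intervals and likelihood-ratio tests
  (χ² = 2[ℓ_saturated − ℓ_pooled], df = H − 1); Bray–Curtis dissimilarity
  d(x,y) = Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ); PCoA; dbRDA constrained on habitat; and
  PERMANOVA — all implemented here, with permutation p-values
  (1 + #{F^π ≥ F})/(1 + n_perm) and exact enumeration for small n.
* **Niche metrics** — Levins' breadth B = 1/Σp_j², standardised
  B_A = (B−1)/(R−1) ∈ [0,1]; Horn–Morisita overlap
  C_H = 2Σp_ij p_ik / (Σp_ij² + Σp_ik²); and the cross-species Spearman
  correlation between habitat and symbiont niche breadth with an exact
  permutation p-value.
* **Synthetic data** — a generator emulating a 4-site × 5-habitat sampling
  design (724 colonies; 377 ITS2 / 326 psbA assays), species-specific
  habitat profiles, haplotype-defining sequence variation (including the
  seven-base split between haplotypes 1 and 8), the RFLP site, and
  host-specific symbiont associations with occasional dual infections —
  so the whole pipeline is testable without any sequencing run.

## Worked example

```r
library(crypticniche)

panel <- generate_reference_panel(seed = 1)     # synthetic haplotype panel
cfg   <- sim_config(seed = 1)                   # 724-colony default design
sim   <- simulate_colonies(cfg, panel)
calls <- call_species_cohort(sim$mtorf, sim$histone, panel)
table(calls$species)
#>        P. acuta   P. cf. effusa      P. grandis    P. meandrina
#>              73              15              49             303
#> P. tuahiniensis    P. verrucosa
#>             190              94

symb <- simulate_symbionts(sim$metadata, cfg)
sc   <- symbiont_calls(symb$div_counts, symb$psba)
calls <- merge(calls, sim$metadata[, c("colony_id", "site", "habitat")],
               by = "colony_id")
tab <- association_table(sc, calls)
round(tab$percent["P. acuta", ], 2)
#>       D. glynnii     C. latusorum     C. pacificum Cladocopium C116
#>            98.44             0.00             3.12             1.56
#> S. microadriaticum
#>              0.00

hb <- habitat_breadth(calls, per_site = TRUE)
aggregate(B_A ~ species, hb, mean)
#>           species         B_A
#> 1        P. acuta 0.004800591
#> 2   P. cf. effusa 0.429590018
#> 3      P. grandis 0.288114339
#> 4    P. meandrina 0.668496196
#> 5 P. tuahiniensis 0.487093988
#> 6    P. verrucosa 0.368705838
```

The species tallies recover the simulation truth exactly (the generator
keeps diagnostic positions noise-free), most *P. acuta* colonies host the
generalist *D. glynnii*, and *P. acuta* — confined to the fringing reef —
has a standardised habitat niche breadth near 0 while the habitat
generalist *P. meandrina* is highest.

## Analysis workflow

Numbered drivers under `analysis/` run the stages in order and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # cohort, sequences, DIV matrix, psbA table
Rscript analysis/02_identify.R    # host species calls + recovery report
Rscript analysis/03_symbionts.R   # symbiont calls + association table
Rscript analysis/04_community.R   # abundance, LRTs, dbRDA, PERMANOVA
Rscript analysis/05_niche.R       # breadths, overlaps, breadth correlation
```

Each stage reads the previous stage's outputs; every table carries a
provenance header line with the package version and seed.

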