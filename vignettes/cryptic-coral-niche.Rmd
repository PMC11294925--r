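---
title: "Methods: marker-based identification and niche analysis of cryptic corals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based identification and niche analysis of cryptic corals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticniche)
```

## The problem

Corals of the genus *Pocillopora* comprise several sympatric species that
cannot be told apart reliably by colony morphology. Within a single reef,
structural habitat zones — fringing reef, back reef lagoon, and the fore
reef slope at 5, 10 and 20 m — differ strongly in light, flow, temperature
and nutrients, and cryptic species can partition these zones while looking
identical in the field. Each colony also hosts photosynthetic algal
symbionts (Symbiodiniaceae) whose species identity contributes to holobiont
performance. `crypticniche` implements the analysis chain for this setting:
genetic species assignment of hosts and symbionts from marker data,
community composition statistics across habitats, and niche breadth/overlap
metrics — plus a synthetic-data generator so that every stage is testable
end to end without any field data.

## Host species assignment

Hosts are identified from the mitochondrial open reading frame (mtORF)
amplicon (~800 bp). Each query is compared against a reference panel of
named haplotypes; the call is the reference with minimum unit-cost edit
distance under an alignment that is global in the query but free at the
reference ends, so trimming differences at the amplicon boundaries are not
penalised. Both query orientations are scanned. Two safeguards apply:

* **TIE** — two references at equal minimum distance produce no call rather
  than an arbitrary winner, mirroring manual review of chromatograms.
* **LOW_IDENTITY** — a best distance above 3% of the aligned query length
  produces no call. The threshold is a flag, not a hard failure, and is a
  package choice (`max_distance_frac`), since nearest-reference assignment
  has no canonical cutoff.

A distance minimised with free ends on *both* sequences would be degenerate
(aligning nothing costs zero), which is why the query side is global. The
dynamic program is compiled (Rcpp) and banded: with the query consumed in
full, a leading reference offset of $s$ forces at least $s + m - n$ query
gaps, so all alignments within the reported distance cap lie in a diagonal
band. Distances beyond the cap — already past the identity threshold — are
reported as the cap value plus one. The test suite checks the kernel
against a plain dynamic-programming oracle, including indel cases.

Haplotypes map to species through a validated lookup
(`haplotype_species_map()`): haplotype 10 is *P. tuahiniensis*; 3a/3b/3e/3f/3h
are *P. verrucosa*; 2 and 11 are *P.* cf. *effusa*; 5a is *P. acuta*;
haplotype 8 is pooled with *P. meandrina* (a distinct mitochondrial lineage,
seven base pairs from haplotype 1, that genome-wide data do not separate
from *P. meandrina*). Haplotype 1 is shared by *P. meandrina* and
*P. grandis* and therefore maps to `AMBIGUOUS` until resolved by a
restriction assay: the histone-3 amplicon of *P. grandis* carries an XhoI
recognition site (CTCGAG, cut one base in) while that of *P. meandrina* does
not. `insilico_digest()` reproduces the gel logic — one ~700 bp band means
*P. meandrina*; ~400 + ~300 bp bands mean *P. grandis*; a three-band pattern
(incomplete digestion) still means *P. grandis* and is flagged
`PARTIAL_DIGEST`. The site is palindromic, so forward-strand scanning
suffices. Haplotype-1 colonies without histone data stay `AMBIGUOUS`
(`NO_RFLP`).

## Symbiont species assignment

ITS2 amplicon profiles arrive as SymPortal-style tables of named defining
intragenomic variants (DIVs). A symbiont species is called present when the
summed read share of its diagnostic DIVs reaches `min_frac` (default 0.05,
a package choice — no canonical "hosted" threshold exists): C42a/C42g for
*Cladocopium latusorum*, C1d/C1ag for *C. pacificum*, C116 for the
unalignable *Cladocopium* C116 group, A1/A1fi for *Symbiodinium
microadriaticum*, D1/D2d/D6/D4 for *Durusdinium glynnii*. Multiple calls on
one colony are dual infections. Because ITS2 does not separate
*Cladocopium* species reliably, the plastid minicircle (psbA^ncr^) clade is
authoritative when present: clades I–IV map to *C. latusorum* and V–IX to
*C. pacificum* (`psba_clade_map()`, kept as data because the deepest clades
are less well supported), replacing or confirming the ITS2 *Cladocopium*
call, with disagreements flagged as conflicts. Colonies with a single
marker are called from that marker alone. `association_table()` then
tabulates, per host species, the percentage of symbiont-typed colonies
hosting each symbiont; dual infections legitimately push row sums past
100%.

## Community statistics

All statistics are computed in closed form or by explicit permutation in
this package; `vegan` and `stats::glm` serve only as independent oracles in
the test suite.

* **Relative abundance.** Per species and habitat, the proportion of
  colonies that are the focal species, with a Wald interval on the logit
  scale — exactly the fitted values and intervals of a saturated binomial
  GLM with habitat as a factor. Boundary cells (0 or 1) use a half-count
  adjusted logit and are flagged `degenerate`. Empty cells are missing, not
  zero.
* **Habitat effect.** `habitat_lrt()` computes
  $\chi^2 = 2[\ell_{\text{saturated}} - \ell_{\text{pooled}}]$ from cell
  counts, with $df = H - 1$; this equals the deviance difference of the
  corresponding logistic regression (parity-tested to $10^{-8}$). Species
  present in a single habitat are untestable and excluded, and sites are
  pooled for this test.
* **Bray–Curtis.** $d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$ on
  the species-proportion rows of the site × habitat cells (proportions, not
  raw counts, form the composition rows).
* **PCoA.** Gower double-centering of $-D^2/2$ and eigendecomposition;
  coordinates for positive eigenvalues only. Negative eigenvalues are
  reported and dropped — no Lingoes/Cailliez correction by default, a
  documented and deliberate policy; the squared-distance reconstruction
  error is bounded by the magnitude of the negative part of the spectrum.
* **dbRDA.** Positive PCoA axes regressed on the constraint's dummy matrix;
  the statistic is $(I_{\text{constr}}/q) / (I_{\text{resid}}/(n-q-1))$
  with $q$ = levels − 1, i.e. a constrained analysis of principal
  coordinates. A constraint explaining everything leaves only rounding
  noise in the residual, which is clamped to an infinite statistic rather
  than noise-signed nonsense.
* **PERMANOVA.** $SS_{\text{total}} = \sum_{i<j} d_{ij}^2 / n$,
  $SS_{\text{within}} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g$, pseudo-F
  from the ratio of between/within mean squares.

Permutation p-values use free permutation of sample labels (no strata) and
the $(1 + \#\{F^\pi \ge F\}) / (1 + n_{\text{perm}})$ estimator, which
cannot return zero. Exhaustive enumeration (`exact = TRUE`) replaces
sampling for $n \le 9$, where the estimator becomes the exact proportion
over all $n!$ relabelings. All permutation tests are bit-reproducible under
a fixed seed.

## Niche metrics

Levins' breadth $B = 1/\sum_j p_j^2$ measures the uniformity of a
proportion vector over resource states; $B_A = (B-1)/(R-1) \in [0,1]$
standardises it by the number of states $R$. For habitat breadth, $p_j$ is
the fraction of a species' colonies in habitat $j$ and $R$ is fixed at the
five sampled habitat states even when a species occupies fewer — a species
confined to one habitat scores exactly 0, and the standardisation reflects
the design's resource states rather than each species' occupancy. For
symbiont breadth, $p$ is a colony's DIV read-share vector and $R$ is the
number of DIV columns in the analysed matrix — a dataset property recorded
in the output, since DIV inventories differ between datasets.

The Horn–Morisita overlap
$C_H = 2\sum_i p_{ij} p_{ik} / (\sum_i p_{ij}^2 + \sum_i p_{ik}^2)$
ranges from 0 (disjoint resource use) to 1 (identical). As implemented from
this formula it is symmetric in $j$ and $k$; both orientations are emitted
so each row is self-describing. Species-level summaries are arithmetic
means over sites (habitat breadth) or colonies (symbiont breadth), and the
breadth–breadth association across species uses Spearman's rank correlation
with a two-sided permutation p-value — exact enumeration of all rank
permutations when there are at most 8 species (720 permutations for 6),
since the large-sample t approximation is meaningless at $n = 6$.

No sampling-effort correction is applied across habitats (quadrat effort
differed between habitats in the emulated design); this is a documented
limitation of the raw-proportion approach.

## The synthetic-data generator

The generator (`sim_config()`, `simulate_colonies()`,
`simulate_symbionts()`) emulates the study design the analysis assumes:

* **Sampling layout.** 4 sites × 5 habitats with the per-cell mtORF sample
  sizes of `sampling_design()` (724 colonies in total; 377 ITS2 and 326
  psbA assays, 280 colonies with both markers).
* **Species mixtures.** Habitat columns of `species_habitat_counts()`
  normalised to mixing weights. The published sources for this design give
  species totals and qualitative habitat patterns but not the full species
  × habitat table, so the default counts were reconstructed once to match
  the row totals (303/182/88/75/56/20), the habitat column totals, and the
  stated patterns (*P. acuta* fringing-only save one back-reef colony;
  *P. tuahiniensis* absent from the fringing reef and peaking at 20 m;
  *P. meandrina* hump-shaped with a 5 m peak; *P. verrucosa* skewed
  shallow; *P. grandis* flat but scarce at 20 m; *P.* cf. *effusa* absent
  from the fringing reef, fore reef over back reef). They are defaults, not
  dials.
* **Marker sequences.** A random backbone with private diagnostic
  substitutions per haplotype: 5 per haplotype, 7 between haplotypes 1 and
  8, so every pair differs at ≥ 5 positions except the 1/8 pair at exactly
  7. Sequencing noise is i.i.d. substitution at non-diagnostic positions
  only, so haplotype identity is never destroyed and recovery stays
  well-defined — noise adds the same distance to every reference.
  *P. meandrina* colonies carry haplotype 8 with probability 0.2 (the
  lineage is a within-species minority; no published frequency, chosen
  once). Histone amplicons are 700 bp with the XhoI site placed to yield
  400 + 300 fragments for *P. grandis*.
* **Symbionts.** Each colony draws a primary symbiont from its host's
  association probabilities (`symbiont_assoc_probs()`, consistent with the
  built-in association design) and, with probability 13/423 (the design's
  dual-infection rate), a secondary one. DIV counts are
  Dirichlet-multinomial: proportions drawn around the (mixed) species mean
  profile with concentration 20, totals Poisson with mean 1000 reads.
  Amplicon counts are overdispersed in real data, and the
  Dirichlet-multinomial is the standard model for that; per-colony read
  depths are not published, so depth and concentration are exposed
  configuration with defaults chosen once at realistic orders of magnitude.
  ITS2 and psbA dropout are independent Bernoulli per colony at the
  observed missingness rates (14% and 26%); psbA labels are only emitted
  for *Cladocopium*-dominant colonies. In dual infections the primary
  symbiont contributes 75% of the profile mass.

What the generator does **not** emulate: read-level errors, chimeras,
intragenomic ITS2 phylogenetics, spatial autocorrelation within habitats,
and between-site differences in species mixtures (all sites share one
mixture per habitat). Passing recovery and calibration tests on this
generator therefore demonstrates the correctness of the analysis chain
under its stated assumptions, not robustness to every artefact of real
amplicon data.

## Numerical choices and degenerate inputs

* Edit-distance ties produce flags, never arbitrary winners; diagnostic
  DIV maps refuse DIVs claimed by two species.
* Zero-total DIV profiles are skipped with a `ZERO_TOTAL` flag; profiles
  with no diagnostic signal are `UNCLASSIFIED`, not errors.
* `levins_breadth()` validates that proportions sum to 1 (±1e-9) and that
  $R \ge 2$; all-zero rows are rejected by `bray_curtis()` since the
  dissimilarity is undefined there.
* Permutation statistics treat comparisons with a $10^{-12}$ slack so that
  ties at the observed statistic count as exceedances.

## Problem sizes used by the tests

The test suite and the acceptance script run the full 724-colony design for
end-to-end recovery (with and without 0.5% sequence noise), 100 random
small datasets for GLM parity, exhaustive enumeration at $n \le 8$ for the
permutation oracles, and around a dozen replicate cohorts of 2,000 colonies
for breadth/overlap calibration — sizes chosen so the whole suite completes
in a few minutes while keeping Monte Carlo error well below the tested
tolerances.
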