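---
title: "Methods: lineage structure, cytonuclear discordance and pool-seq differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage structure, cytonuclear discordance and pool-seq differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popflow)
```

popflow implements the two-tier analysis design common to range-wide
population-genomic surveys of non-model trees: a modest SNP array
(~100 nuclear loci plus a few chloroplast loci) genotyped on a large,
geographically dense sample, followed by pooled sequence capture on a
small number of lineage-representative pools.  This vignette records
the models behind each stage, the parameters that matter, and the
design choices made where several defensible options existed.

## The synthetic survey generator

Real surveys of this kind publish filtered genotype tables rather than
raw data, so the package ships a generator whose output has the
statistical structure every downstream stage assumes, together with a
*truth ledger* naming each planted feature.  The generative model is:

* **Lineage frequencies.** Each locus draws an ancestral frequency
  `p ~ Uniform(0.05, 0.95)`; lineage `k` then draws its frequency from
  the Balding–Nichols beta,
  `Beta(p(1−F_k)/F_k, (1−p)(1−F_k)/F_k)`, the standard generative
  stand-in for a structured population with divergence parameter
  `F_k`.  The default `lineage_fst = (0.145, 0.231, 0.337)` was solved
  from pairwise lineage differentiation values near 0.19–0.28 under
  the approximation `Fst(i,j) ≈ (F_i + F_j)/2`, so the three simulated
  lineages (northeast, south, west) reproduce the asymmetric
  divergence pattern of a cottonwood-like survey in which the western
  subspecies is the most differentiated.  Localities are nested inside
  lineages by a second Balding–Nichols layer (`pop_fst = 0.04`,
  matching within-lineage `Fsc ≈ 0.04`).
* **Individuals.** Genotypes are `Binomial(2, p_ind)` with `p_ind` the
  admixture-weighted frequency.  A fraction `admix_fraction = 0.17` of
  trees mix their home lineage (weight `Uniform(0.5, 0.95)`) with a
  random other lineage; with the 0.667 threshold this reproduces the
  observed ratio of classified-pure to admixed trees.
* **Chloroplasts.** Each lineage carries a diagnostic haplotype over
  the (default three) cpSNPs.  A tree inherits the haplotype of its
  major-ancestry lineage — the maternal side of an admixed tree is
  taken to be its major parent — except for planted *capture events*:
  non-admixed, non-hybrid trees swap in another lineage's haplotype
  with probability `capture_rates[nuclear, donor]`.  The default
  matrix sends western chloroplasts into the two eastern lineages at
  0.066 and the reverse at 0.015, about a five-to-one realized
  asymmetry.  Restricting planting to unambiguous trees is deliberate:
  it makes the ledger exactly recoverable by `detect_capture()`, which
  is the property the acceptance tests check.
* **Nuisance processes.** Clonal ramets (exact copies, probability
  `clone_rate = 0.05`), F1 interspecific hybrids (heterozygous across
  a 36-locus diagnostic panel, `hybrid_rate = 0.03`), and missing
  calls (`missing_rate = 0.01` per call, with 2% of trees as "failed
  extractions" at ten times that rate so the missingness filter has
  realistic work).

What the generator does **not** emulate: linkage between loci,
genotyping error at non-panel loci, isolation-by-distance within
lineages, and any mechanistic (river-network) model of seed dispersal.
Passing tests therefore demonstrate correct *bookkeeping and
estimation* on data satisfying the model's assumptions, not robustness
to violations of them.

## QC chain

Filters run in a fixed order — hybrids, clones, missingness — and
their report is additive to the input count.  Decisions worth
recording:

* Hybrid exclusion is a *foreign-allele fraction* over a diagnostic
  panel at which the focal species is fixed; an F1 scores 0.5, and the
  default cutoff 0.1 removes anything beyond occasional genotyping
  noise.  Proprietary assay decision rules are not published, so the
  cutoff is a parameter, not a guess at one.
* Clone collapse keeps the *first* individual in input order of any
  set with pairwise mismatches ≤ `max_mismatch` (default 0), computed
  ignoring loci missing in either member.  A small positive
  `max_mismatch` absorbs genotyping error.
* Missingness is *strictly greater than* 10%: with 93 loci, 10 missing
  calls (10.75%) removes a tree, 9 (9.68%) does not.

## Diversity and differentiation

Per locus, `Ho` is the heterozygote fraction, `Hs` the mean
within-population `2p(1−p)` with Nei's `2n/(2n−1)` correction (the
matching Nei–Chesser term `Hs/(2·n_harm·r)` is added to `Ht`), and
`Ht` uses the unweighted mean of population frequencies.  Multilocus
Fst is reported two ways on purpose: Nei's `Gst` as the ratio of
multilocus sums (the definition the pool stage uses), and
Weir–Cockerham θ from summed variance components (what Fstat-style
software reports).  Field studies routinely mix the two without
comment; reporting both makes the comparison explicit.  Negative
per-locus estimates stay in the multilocus sums and are truncated only
in the headline value, with the raw value always alongside.

The AMOVA decomposes allele-copy variance at three levels.  Because
genotype values are allele counts, every sum of squares reduces to
per-population allele sums, which makes the permutation tests (whole
populations among groups for `Fct`; individuals among populations
within groups for `Fsc`) cheap.  Variance components are estimated per
locus with the standard unequal-sample-size coefficients and summed
across loci; the identity `(1−Fct)(1−Fsc) = (1−Fst)` then holds to
machine precision by construction, and the test suite verifies the
components against an independent deviations-from-means oracle.  The
permutation default is 10,000; the examples here use fewer because the
p-values of interest are far from the rejection boundary.

Populations enter only with at least `min_pop_size = 3` genotyped
trees.  The survey literature oscillates between "more than three" and
"three or more"; the inclusive reading is the default and the knob is
exposed.

## Lineage classes and the EM estimator

Classification is strict: a tree is pure for its max-Q cluster at
threshold `t` iff `Q > t`, so a tree at exactly 0.667 is admixed — the
conservative reading of thresholds quoted as "> 0.667" and "> 0.9".
The two default thresholds nest, and ties in the maximum break toward
the lowest cluster index.

The supervised EM estimator exists so the pipeline can run without an
external Structure/ADMIXTURE run: given per-lineage reference
frequencies (clamped to `[1e−4, 1−1e−4]`), each gene copy is modelled
as drawn from lineage `k` with probability `q_k`.  The EM update is
the classic allele-count ratio; the log-likelihood is non-decreasing
(asserted in tests) and identical references trigger an explicit
non-identifiability warning with a uniform return.  It deliberately
does not re-implement unsupervised clustering.

## Cytonuclear discordance

Haplotypes are allele strings over the retained cpSNPs; any missing cp
call excludes the tree (no imputation), and a heterozygous organellar
call is treated as an assay error worth stopping for.  Haplotypes map
to lineages by the *modal nuclear lineage among their pure carriers*
(default pure@0.9), with the modal fraction reported as confidence so
weakly supported maps are visible; surveys assign haplotypes to
subspecies by geography and typicality without a formula, and the
modal rule is the closest formalization that needs no coordinates.  A
capture event `i → j` is a tree pure for nuclear lineage `j` (default
pure@0.667, the cluster-membership convention) carrying a haplotype
mapped to lineage `i ≠ j`; the report keeps ordered-pair counts, the
per-tree rows, and the asymmetry ratio.

## Pool-seq stage

Frequencies, not read counts, carry the differentiation analysis — as
in the source pipeline — so no pool-size/coverage variance correction
is applied; this is a documented limitation, and unbiased pool-seq
estimators are out of scope.  The retention rules are exactly the
published ones (biallelic; every individual pool's coverage within
[150, 500]; merged pool present at ≥ 200; quality ≥ 20; named
chromosomes only), and frequencies strictly below the 2% detection
limit are zeroed, idempotently.  The limit reflects the low-frequency
variant caller's threshold: below it, a call is indistinguishable from
sequencing error.

Pool Fst per SNP uses `Hs` = mean of the two sides' `2p(1−p)` and `Ht`
of the mean frequency; the multilocus value is the ratio of sums, with
monomorphic SNPs contributing zeros to both (so padding with
monomorphic sites changes nothing — a test asserts this).  For
one-vs-rest the "rest" frequency is the unweighted mean of the other
pools, which equals the pooled frequency when pools have equal sizes,
as they do here (20 diploids each).  Under this two-side formula a
negative per-SNP value cannot arise, so no truncation is needed.

Genome scans tile chromosomes with half-open 500-kb windows, score
windows with ≥ 5 SNPs, flag those strictly above the 99th percentile
of window means (ties therefore never flag a flat track), and merge
adjacent flagged windows into regions.  The published analysis found
peaks visually; the quantile rule is a reproducible stand-in, and all
three knobs are parameters.  BED export is the single 0-based
half-open surface of the package; everything internal is 1-based
inclusive.

## Joint spectra and divergence models

The AFS grid is `(2N+1) × (2M+1)` so allele counts 0…2N are all
representable; frequencies map to counts by rounding halves away from
zero (the gridding convention is not published; round-half-up is the
least surprising choice and is pinned by a test).  Masking removes
cells at or below the cutoff on *both* axes — a 3 × 3 corner at the
default 5% with pools of 20 — mirroring how the spectra are displayed.
The alternate allele relative to the reference genome stands in for
the derived allele; without an outgroup no other polarization is
available, and the metadata records this.

Expected spectra are simulated, not solved: independent loci evolve
through a two-deme forward Wright–Fisher process (ancestral frequency
`Beta(0.5, 0.5)`, which puts mass at intermediate and extreme
frequencies like a site-frequency spectrum; deterministic migration
then binomial drift over `2Ne` copies per generation), are sampled
down to the pool sizes, accumulated, averaged over replicates and
normalized over unmasked cells.  The four histories differ only in
when migration is active; `T_switch` is expressed in generations
before present and must precede the split.  Model choice minimizes the
Jensen–Shannon divergence between normalized observed and expected
grids over unmasked cells — any proper divergence would serve; JS is
symmetric and bounded.  Candidates within 5% (relative) of the best
score are reported as *ties* rather than silently broken, because
isolation-with-migration, ancient-migration and secondary-contact
spectra are genuinely hard to distinguish; the acceptance experiment
asserts both sides of this (the generating model wins ≥ 90% of trials
against a well-separated alternative, and matched recent-migration
candidates tie in most trials).

No published effective sizes or split times exist for these lineages,
so the divergence-model defaults (`Ne = 1000`, `T_split = 2Ne`) are
illustrative; the calibration experiments in the tests and acceptance
script use `Ne = 100–200` with `T_split = 2–3 Ne` and 10,000 loci,
sizes chosen so the full suite runs in about a minute on one CPU while
keeping Monte-Carlo error well inside the asserted margins.

## Numerical notes

* All simulators take explicit integer seeds, run on a private RNG
  stream, and restore the caller's RNG state; identical spec + seed is
  byte-identical output.
* `which.max` tie-breaks (lowest index) are relied on for both max-Q
  classification and haplotype mapping, and are documented behaviour.
* Division-by-zero guards: empty populations at a locus drop out of
  the AMOVA sums; an all-monomorphic contrast flags Fst as undefined
  rather than returning 0/0.
* Q-matrix rows must sum to 1 within `1e−3` (then renormalized);
  ragged Structure files and off-sum rows error with the row number.

## Known limitations

Locus-level QC (per-SNP call rate, HWE exclusion) is intentionally
absent — the mirrored survey did not perform it.  The pool stage
inherits the bias of raw frequency ratios at finite coverage; the
windowed scan has no significance machinery beyond the quantile rule;
and the divergence-model comparison is a goodness-of-fit ranking, not
demographic inference — composite-likelihood machinery would be the
next step and is out of scope.
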