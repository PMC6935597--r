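#' Specification of a structured-lineage simulation
#'
#' Describes the generative model behind [simulate_lineages()]: a set of
#' divergent lineages with Balding-Nichols allele frequencies around a
#' shared ancestral frequency, nested population substructure, a fraction
#' of two-lineage admixed individuals, asymmetric chloroplast-capture
#' planting, plus the nuisance processes a real SNP-array survey carries
#' (clones, interspecific hybrids, missing calls).
#'
#' Defaults emulate a range-wide cottonwood survey: three lineages
#' (northeast, south, west) whose pairwise divergence matches AMOVA
#' Fct values near 0.19-0.28, ~84 localities per lineage with 4 trees
#' each (~1008 trees), 93 nuclear SNPs, 3 chloroplast SNPs, a 36-locus
#' species-diagnostic panel, and capture rates roughly five times higher
#' into the two eastern lineages than the reverse direction.
#'
#' @param n_lineages Number of lineages (>= 2).
#' @param n_pops_per_lineage Localities sampled per lineage.
#' @param n_ind_per_pop Trees per locality.
#' @param n_loci Nuclear SNP count.
#' @param n_cp_loci Chloroplast SNP count (haploid, lineage-diagnostic).
#' @param n_diagnostic_loci Interspecific diagnostic panel size; the focal
#'   species is fixed for the reference allele at these loci.
#' @param lineage_fst Balding-Nichols divergence parameter per lineage,
#'   each in (0, 1); recycled to `n_lineages`.
#' @param pop_fst Within-lineage population divergence (same scale).
#' @param admix_fraction Proportion of individuals drawn as two-lineage
#'   mixtures.
#' @param capture_rates `n_lineages x n_lineages` matrix; entry `[k, j]`
#'   is the probability that a non-admixed, non-hybrid individual of
#'   nuclear lineage `k` carries the chloroplast haplotype of lineage `j`.
#'   Diagonal must be zero.
#' @param missing_rate Per-call missing probability at nuclear loci.  A
#'   small fraction (`failed_rate`) of individuals are "failed extractions"
#'   with a tenfold rate, so the missingness filter has work to do.
#' @param failed_rate Proportion of individuals with elevated missingness.
#' @param clone_rate Probability that an individual contributes a clonal
#'   duplicate (ramet) to the sample.
#' @param hybrid_rate Proportion of interspecific F1 hybrids, heterozygous
#'   across the diagnostic panel.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#'
#' @return A validated list of class `lineage_sim_spec`.
#' @seealso [simulate_lineages()]
#' @export
lineage_sim_spec <- function(n_lineages = 3,
                             n_pops_per_lineage = 84,
                             n_ind_per_pop = 4,
                             n_loci = 93,
                             n_cp_loci = 3,
                             n_diagnostic_loci = 36,
                             lineage_fst = c(0.145, 0.231, 0.337),
                             pop_fst = 0.04,
                             admix_fraction = 0.17,
                             capture_rates = NULL,
                             missing_rate = 0.01,
                             failed_rate = 0.02,
                             clone_rate = 0.05,
                             hybrid_rate = 0.03,
                             seed = 1L) {
  if (n_lineages < 2) abort("`n_lineages` must be at least 2")
  lineage_fst <- rep_len(lineage_fst, n_lineages)
  if (any(lineage_fst <= 0) || any(lineage_fst >= 1)) {
    abort("`lineage_fst` values must lie in (0, 1)")
  }
  if (is.null(capture_rates)) {
    capture_rates <- matrix(0, n_lineages, n_lineages)
    if (n_lineages == 3) {
      # rows = nuclear lineage, cols = chloroplast donor lineage
      capture_rates[1, 3] <- 0.066  # west cp into northeastern nuclei
      capture_rates[2, 3] <- 0.066  # west cp into southern nuclei
      capture_rates[3, 1] <- 0.015  # the rarer reverse direction
      capture_rates[3, 2] <- 0.015
    }
  }
  capture_rates <- as.matrix(capture_rates)
  if (!all(dim(capture_rates) == n_lineages)) {
    abort("`capture_rates` must be an n_lineages x n_lineages matrix")
  }
  if (any(diag(capture_rates) != 0)) {
    abort("`capture_rates` diagonal must be zero")
  }
  probs <- c(capture_rates, admix_fraction, missing_rate, failed_rate,
             clone_rate, hybrid_rate, pop_fst)
  if (any(probs < 0) || any(probs > 1) ||
      missing_rate >= 1 || clone_rate >= 1) {
    abort("all probabilities must lie in [0, 1] (rates strictly below 1)")
  }
  if (any(rowSums(capture_rates) > 1)) {
    abort("capture_rates rows must sum to at most 1")
  }
  structure(
    list(n_lineages = as.integer(n_lineages),
         n_pops_per_lineage = as.integer(n_pops_per_lineage),
         n_ind_per_pop = as.integer(n_ind_per_pop),
         n_loci = as.integer(n_loci),
         n_cp_loci = as.integer(n_cp_loci),
         n_diagnostic_loci = as.integer(n_diagnostic_loci),
         lineage_fst = lineage_fst, pop_fst = pop_fst,
         admix_fraction = admix_fraction, capture_rates = capture_rates,
         missing_rate = missing_rate, failed_rate = failed_rate,
         clone_rate = clone_rate, hybrid_rate = hybrid_rate,
         seed = as.integer(seed)),
    class = "lineage_sim_spec"
  )
}

#' Specification of a two-deme divergence model
#'
#' Parameterizes the forward Wright-Fisher simulation behind
#' [simulate_divergence_afs()]: two demes of constant diploid size `Ne`
#' split `T_split` generations ago from a common ancestral pool, with one
#' of four migration histories.
#'
#' @param model One of `"isolation"` (no gene flow after the split),
#'   `"isolation_with_migration"` (constant gene flow throughout),
#'   `"ancient_migration"` (gene flow that stopped `T_switch` generations
#'   before present; "isolation after migration"), or
#'   `"secondary_contact"` (isolation first, gene flow resumed `T_switch`
#'   generations before present).
#' @param Ne Effective diploid size of each deme.
#' @param T_split Generations since the split.
#' @param m12,m21 Per-generation migration proportions: `m12` is the
#'   fraction of deme 1's gene pool replaced by deme 2 each generation
#'   (and vice versa), each in \[0, 0.5\].
#' @param T_switch Generations before present at which migration stops
#'   (ancient_migration) or starts (secondary_contact); must be below
#'   `T_split`.
#' @param n_loci Number of independent loci.
#' @param seed Integer seed.
#'
#' @return A validated list of class `divergence_model_spec`.
#' @export
divergence_model_spec <- function(model = c("isolation",
                                            "isolation_with_migration",
                                            "ancient_migration",
                                            "secondary_contact"),
                                  Ne = 1000, T_split = 2000,
                                  m12 = 0, m21 = 0, T_switch = NULL,
                                  n_loci = 10000, seed = 1L) {
  model <- match.arg(model)
  if (any(c(m12, m21) < 0) || any(c(m12, m21) > 0.5)) {
    abort("migration rates must lie in [0, 0.5]")
  }
  if (model == "isolation" && (m12 != 0 || m21 != 0)) {
    abort("the isolation model implies m12 = m21 = 0")
  }
  if (model %in% c("ancient_migration", "secondary_contact")) {
    if (is.null(T_switch)) abort("`T_switch` is required for epoch models")
    if (T_switch >= T_split) abort("`T_switch` must be below `T_split`")
  }
  structure(
    list(model = model, Ne = as.integer(Ne), T_split = as.integer(T_split),
         m12 = m12, m21 = m21,
         T_switch = if (is.null(T_switch)) NULL else as.integer(T_switch),
         n_loci = as.integer(n_loci), seed = as.integer(seed)),
    class = "divergence_model_spec"
  )
}
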