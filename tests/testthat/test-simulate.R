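small_spec <- function(...) {
  lineage_sim_spec(n_pops_per_lineage = 5, n_ind_per_pop = 6,
                   n_loci = 40, seed = 11, ...)
}

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_lineages(small_spec())
  b <- simulate_lineages(small_spec())
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$cp, b$cp)
  expect_identical(a$ledger, b$ledger)

  f <- tibble::tibble(chrom = "c", pos = 1:50, A = runif(50), B = runif(50))
  p1 <- simulate_pools(f, seed = 4)
  p2 <- simulate_pools(f, seed = 4)
  expect_identical(p1, p2)

  d1 <- simulate_divergence_afs(divergence_model_spec(
    "isolation", Ne = 50, T_split = 100, n_loci = 200, seed = 3))
  d2 <- simulate_divergence_afs(divergence_model_spec(
    "isolation", Ne = 50, T_split = 100, n_loci = 200, seed = 3))
  expect_identical(d1, d2)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(lineage_sim_spec(n_lineages = 1), "at least 2")
  expect_error(lineage_sim_spec(lineage_fst = c(0, 0.1, 0.1)), "0, 1")
  expect_error(lineage_sim_spec(missing_rate = 1.2), "probabilities")
  bad <- diag(0.5, 3)
  expect_error(lineage_sim_spec(capture_rates = bad), "diagonal")
  expect_error(divergence_model_spec("isolation", m12 = 0.1), "implies")
  expect_error(divergence_model_spec("secondary_contact", T_split = 100,
                                     T_switch = 100), "below")
  expect_error(divergence_model_spec("isolation", m12 = 0.7), NULL)
})

test_that("no-divergence limit gives near-zero between-lineage Fst", {
  sim <- simulate_lineages(lineage_sim_spec(
    n_pops_per_lineage = 4, n_ind_per_pop = 25, n_loci = 100,
    lineage_fst = rep(1e-9, 3), pop_fst = 1e-9,
    admix_fraction = 0, missing_rate = 0, failed_rate = 0,
    clone_rate = 0, hybrid_rate = 0, seed = 21))
  div <- diversity_indices(sim$genotypes, sim$ledger$lineage,
                           min_pop_size = 2)
  expect_lt(abs(div$summary$Fst_gst_raw), 0.02)
  expect_lt(abs(div$summary$Fst_theta_raw), 0.02)
})

test_that("mean Fst rises monotonically with the lineage divergence dial", {
  fst_at <- function(f) {
    sim <- simulate_lineages(lineage_sim_spec(
      n_pops_per_lineage = 3, n_ind_per_pop = 30, n_loci = 80,
      lineage_fst = rep(f, 3), pop_fst = 1e-9, admix_fraction = 0,
      missing_rate = 0, failed_rate = 0, clone_rate = 0,
      hybrid_rate = 0, seed = 31))
    diversity_indices(sim$genotypes, sim$ledger$lineage,
                      min_pop_size = 2)$summary$Fst_gst_raw
  }
  vals <- vapply(c(0.01, 0.05, 0.15, 0.35), fst_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("planted capture events appear in the ledger and are recovered", {
  rates <- matrix(0, 3, 3)
  rates[1, 3] <- 0.25  # west chloroplast into northeastern nuclei
  sim <- simulate_lineages(lineage_sim_spec(
    n_pops_per_lineage = 4, n_ind_per_pop = 10, capture_rates = rates,
    admix_fraction = 0, clone_rate = 0, hybrid_rate = 0,
    missing_rate = 0, failed_rate = 0, seed = 41))
  planted <- sum(sim$ledger$capture_from == "west" &
                   sim$ledger$lineage == "northeast", na.rm = TRUE)
  expect_gt(planted, 0)
  cls <- classify_individuals(sim$q)
  hap <- build_cp_haplotypes(sim$cp)
  map <- map_haplotypes_to_lineages(hap, cls)
  cap <- detect_capture(hap, cls, map)
  got <- cap$pairs$n[cap$pairs$cp_lineage == "west" &
                       cap$pairs$nuclear_lineage == "northeast"]
  expect_identical(as.integer(got), as.integer(planted))
  expect_identical(cap$n_discordant, as.integer(planted))
})

test_that("pool read simulation respects fixed pools and converges to truth", {
  fixed <- tibble::tibble(chrom = "c", pos = 1:100, A = 0)
  pc <- simulate_pools(fixed, error_rate = 0, seed = 5)
  expect_true(all(pc$alt_depth == 0))

  f <- tibble::tibble(chrom = "c", pos = 1:200, A = runif(200, 0.05, 0.95))
  big <- simulate_pools(f, mean_coverage = 1e5, coverage_dispersion = 1e4,
                        error_rate = 0, seed = 6)
  est <- big$alt_depth / big$coverage
  expect_lt(mean(abs(est - f$A)), 0.01)
})

test_that("pool frequency estimates are unbiased at survey coverage", {
  f <- tibble::tibble(chrom = "c", pos = 1:1000, A = runif(1000, 0.02, 0.98))
  pc <- simulate_pools(f, mean_coverage = 300, error_rate = 0, seed = 7)
  est <- pc$alt_depth / pc$coverage
  expect_lt(abs(mean(est - f$A)), 0.005)
})

test_that("pool simulation rejects empty pools and bad coverage", {
  g <- toy_genotypes(matrix(0, 2, 3))
  expect_error(simulate_pools(g, pools = list(p1 = character(0))), "empty")
  f <- tibble::tibble(chrom = "c", pos = 1, A = 0.5)
  expect_error(simulate_pools(f, mean_coverage = 0), "positive")
})

test_that("divergence with T_split = 0 leaves demes identical", {
  d <- simulate_divergence_afs(divergence_model_spec(
    "isolation", Ne = 100, T_split = 0, n_loci = 300, seed = 8))
  expect_identical(d$p1, d$p2)
  expect_identical(d$p1, d$p_anc)
})

test_that("long isolation fixes more differences than migration at same T", {
  T <- 600
  iso <- simulate_divergence_afs(divergence_model_spec(
    "isolation", Ne = 100, T_split = T, n_loci = 2000, seed = 9))
  im <- simulate_divergence_afs(divergence_model_spec(
    "isolation_with_migration", Ne = 100, T_split = T,
    m12 = 0.01, m21 = 0.01, n_loci = 2000, seed = 9))
  fixed_diff <- function(d) mean((d$p1 == 0 & d$p2 == 1) |
                                   (d$p1 == 1 & d$p2 == 0))
  expect_gt(fixed_diff(iso), fixed_diff(im))
})

test_that("epoch models gate migration by T_switch", {
  # secondary contact with a long contact phase ends up closer between
  # demes than ancient migration that stopped long ago, other things equal
  anc <- simulate_divergence_afs(divergence_model_spec(
    "ancient_migration", Ne = 100, T_split = 600, T_switch = 500,
    m12 = 0.05, m21 = 0.05, n_loci = 1500, seed = 10))
  sec <- simulate_divergence_afs(divergence_model_spec(
    "secondary_contact", Ne = 100, T_split = 600, T_switch = 500,
    m12 = 0.05, m21 = 0.05, n_loci = 1500, seed = 10))
  expect_lt(mean(abs(sec$p1 - sec$p2)), mean(abs(anc$p1 - anc$p2)))
})
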