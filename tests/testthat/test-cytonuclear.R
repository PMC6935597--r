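test_that("haplotype construction concatenates alleles and catalogues", {
  cp <- tibble::tibble(id = c("a", "b", "c", "d"),
                       C1 = c("A", "A", "T", "A"),
                       C2 = c("C", "C", "C", "G"),
                       C3 = c("G", "G", "G", "G"))
  h <- build_cp_haplotypes(cp)
  expect_identical(nrow(h$catalogue), 3L)
  expect_identical(h$catalogue$haplotype[1], "ACG")
  expect_identical(h$catalogue$n[1], 2L)

  same <- tibble::tibble(id = c("a", "b"), C1 = "A", C2 = "C")
  expect_identical(nrow(build_cp_haplotypes(same)$catalogue), 1L)
})

test_that("missing cp calls exclude the individual; heterozygotes error", {
  cp <- tibble::tibble(id = c("a", "b"), C1 = c("A", NA), C2 = c("C", "C"))
  h <- build_cp_haplotypes(cp)
  expect_identical(h$excluded, "b")
  expect_identical(h$haplotypes$id, "a")

  het <- tibble::tibble(id = c("a", "b"), C1 = c("A", "A/T"))
  expect_error(build_cp_haplotypes(het), "heterozygous.*b.*C1")
})

test_that("haplotypes map to the modal pure lineage with tie handling", {
  cp <- tibble::tibble(id = sprintf("i%d", 1:6),
                       C1 = c("A", "A", "A", "T", "T", "G"))
  h <- build_cp_haplotypes(cp)
  q <- tibble::tibble(id = sprintf("i%d", 1:6),
                      lin1 = c(0.95, 0.95, 0.05, 0.95, 0.05, 0.5),
                      lin2 = c(0.05, 0.05, 0.95, 0.05, 0.95, 0.5))
  cls <- classify_individuals(q, thresholds = c(0.667, 0.9))
  w <- testthat::capture_warnings(
    map <- map_haplotypes_to_lineages(h, cls))
  expect_match(w, "tie", all = FALSE)
  expect_match(w, "unmapped", all = FALSE)
  a <- map[map$haplotype == "A", ]
  expect_identical(a$lineage, "lin1")
  expect_equal(a$confidence, 2 / 3)
  # T is split 1-1: tie broken toward the lower cluster index
  t_row <- map[map$haplotype == "T", ]
  expect_identical(t_row$lineage, "lin1")
  expect_equal(t_row$confidence, 0.5)
  # G's only carrier is admixed: unmapped
  expect_false(map$mapped[map$haplotype == "G"])
})

test_that("fully concordant data yield a zero capture report", {
  sim <- simulate_lineages(lineage_sim_spec(
    n_pops_per_lineage = 4, n_ind_per_pop = 6,
    capture_rates = matrix(0, 3, 3), admix_fraction = 0,
    clone_rate = 0, hybrid_rate = 0, missing_rate = 0, failed_rate = 0,
    seed = 29))
  cls <- classify_individuals(sim$q)
  h <- build_cp_haplotypes(sim$cp)
  map <- map_haplotypes_to_lineages(h, cls)
  cap <- detect_capture(h, cls, map)
  expect_identical(cap$n_discordant, 0L)
  expect_identical(nrow(cap$pairs), 0L)
})

test_that("planted asymmetric captures are recovered per ordered pair", {
  rates <- matrix(0, 3, 3)
  rates[2, 1] <- 0.20  # northeast cp into southern nuclei
  rates[1, 2] <- 0.04  # reverse, rarer
  sim <- simulate_lineages(lineage_sim_spec(
    n_pops_per_lineage = 5, n_ind_per_pop = 10, capture_rates = rates,
    admix_fraction = 0, clone_rate = 0, hybrid_rate = 0,
    missing_rate = 0, failed_rate = 0, seed = 37))
  cls <- classify_individuals(sim$q)
  h <- build_cp_haplotypes(sim$cp)
  map <- map_haplotypes_to_lineages(h, cls)
  cap <- detect_capture(h, cls, map)
  planted <- table(sim$ledger$capture_from, sim$ledger$lineage)
  for (r in seq_len(nrow(cap$pairs))) {
    expect_identical(
      as.integer(cap$pairs$n[r]),
      as.integer(planted[cap$pairs$cp_lineage[r],
                         cap$pairs$nuclear_lineage[r]]))
  }
  expect_identical(cap$n_discordant,
                   sum(!is.na(sim$ledger$capture_from)))
})

test_that("capture accounting partitions the haplotyped individuals", {
  sim <- simulate_lineages(lineage_sim_spec(
    n_pops_per_lineage = 5, n_ind_per_pop = 8, seed = 43))
  cls <- classify_individuals(sim$q)
  h <- build_cp_haplotypes(sim$cp)
  map <- suppressWarnings(map_haplotypes_to_lineages(h, cls))
  cap <- detect_capture(h, cls, map)
  expect_identical(cap$n_discordant + cap$n_concordant + cap$n_excluded,
                   nrow(h$haplotypes))
})
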