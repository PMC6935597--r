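sizes2020 <- c(A = 20, B = 20)

test_that("AFS grid shape, placement and conservation", {
  f <- tibble::tibble(chrom = "c", pos = 1, A = 0.5, B = 0.5)
  g <- build_afs(f, "A", "B", pool_sizes = sizes2020)
  expect_identical(dim(g$counts), c(41L, 41L))
  expect_identical(g$counts["20", "20"], 1)
  expect_identical(sum(g$counts), 1)

  set.seed(3)
  f2 <- tibble::tibble(chrom = "c", pos = 1:500,
                       A = runif(500), B = runif(500))
  g2 <- build_afs(f2, "A", "B", pool_sizes = sizes2020)
  expect_identical(sum(g2$counts), 500)
  masked <- mask_low_freq(g2)
  expect_identical(sum(masked$counts[masked$mask]) +
                     sum(masked$counts[!masked$mask]), 500)
  expect_error(build_afs(f2, "A", "Z", pool_sizes = sizes2020), "pool")
})

test_that("frequency binning rounds halves away from zero", {
  # 0.0125 * 40 = 0.5 -> class 1, not 0 (banker's rounding would give 0)
  f <- tibble::tibble(chrom = "c", pos = 1:2, A = c(0.0125, 0.0375),
                      B = c(0, 0))
  g <- build_afs(f, "A", "B", pool_sizes = sizes2020)
  expect_identical(g$counts["1", "1"], 0)
  expect_identical(unname(g$counts["1", "0"]), 1)
  expect_identical(unname(g$counts["2", "0"]), 1)
})

test_that("swapping the pools transposes the grid", {
  set.seed(5)
  f <- tibble::tibble(chrom = "c", pos = 1:200,
                      A = runif(200), B = runif(200))
  ab <- build_afs(f, "A", "B", pool_sizes = sizes2020)
  ba <- build_afs(f, "B", "A", pool_sizes = sizes2020)
  expect_identical(unname(ba$counts), unname(t(ab$counts)))
})

test_that("the low-frequency mask covers only the both-rare corner", {
  f <- tibble::tibble(chrom = "c", pos = 1, A = 0, B = 0.75)
  g <- build_afs(f, "A", "B", pool_sizes = sizes2020)
  m5 <- mask_low_freq(g, 0.05)
  expect_identical(sum(m5$mask), 9L)  # 3x3 corner: counts {0,1,2}^2
  expect_true(all(which(m5$mask, arr.ind = TRUE) <= 3))
  expect_false(m5$mask[1, 31])  # rare in A, common in B: kept
  m0 <- mask_low_freq(g, 0)
  expect_identical(sum(m0$mask), 1L)
  expect_true(m0$mask[1, 1])
  expect_error(mask_low_freq(g, 0.5), "0.5")
})

test_that("expected spectra normalize and mirror the generating history", {
  recent <- expected_afs(divergence_model_spec(
    "isolation", Ne = 1000, T_split = 0, n_loci = 4000, seed = 51),
    n_reps = 2, mask_cutoff = NULL, sampling = "round")
  expect_equal(sum(recent$counts[!recent$mask]), 1, tolerance = 1e-9)
  # T_split = 0 and sampling-free gridding: mass hugs the diagonal
  idx <- which(recent$counts > 0, arr.ind = TRUE)
  w <- recent$counts[idx]
  near <- abs((idx[, 1] - 1) / 40 - (idx[, 2] - 1) / 40) <= 0.1
  expect_gte(sum(w[near]) / sum(w), 0.95)

  deep_iso <- expected_afs(divergence_model_spec(
    "isolation", Ne = 100, T_split = 400, n_loci = 3000, seed = 52),
    n_reps = 2, mask_cutoff = NULL)
  deep_im <- expected_afs(divergence_model_spec(
    "isolation_with_migration", Ne = 100, T_split = 400,
    m12 = 0.05, m21 = 0.05, n_loci = 3000, seed = 52),
    n_reps = 2, mask_cutoff = NULL)
  corner_mass <- function(g) {
    idx <- which(g$counts > 0, arr.ind = TRUE)
    sep <- abs((idx[, 1] - 1) / 40 - (idx[, 2] - 1) / 40) > 0.8
    sum(g$counts[idx][sep])
  }
  expect_gt(corner_mass(deep_iso), corner_mass(deep_im))
})

test_that("model scoring is zero for self and recovers the generator", {
  iso <- expected_afs(divergence_model_spec(
    "isolation", Ne = 100, T_split = 300, n_loci = 3000, seed = 53),
    n_reps = 2, mask_cutoff = NULL)
  im <- expected_afs(divergence_model_spec(
    "isolation_with_migration", Ne = 100, T_split = 300,
    m12 = 0.02, m21 = 0.02, n_loci = 3000, seed = 53),
    n_reps = 2, mask_cutoff = NULL)
  obs <- iso
  ms <- classify_divergence_model(obs, list(isolation = iso,
                                            isolation_with_migration = im))
  expect_identical(ms$best, "isolation")
  expect_equal(ms$scores$score[ms$scores$model == "isolation"], 0)

  expect_error(classify_divergence_model(obs, list(a = iso)), "two")
  allmask <- obs
  allmask$mask[] <- TRUE
  expect_error(
    classify_divergence_model(allmask, list(a = iso, b = im)), "masked")
})

test_that("tidy/glance on model scores flag ties", {
  g1 <- expected_afs(divergence_model_spec(
    "isolation", Ne = 100, T_split = 200, n_loci = 1000, seed = 54),
    n_reps = 1, mask_cutoff = NULL)
  ms <- classify_divergence_model(g1, list(a = g1, b = g1))
  expect_identical(ms$best, "a")
  expect_identical(ms$ties, "b")
  td <- tidy(ms)
  expect_true(td$tied[td$model == "b"])
  expect_identical(glance(ms)$n_ties, 1L)
})
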