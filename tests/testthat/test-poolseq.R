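test_that("pool-variant rules retain exactly the expected survivor set", {
  pf <- filter_pool_variants(toy_variants())
  w <- tidyr::pivot_wider(tibble::as_tibble(pf)[, c("pool", "chrom", "pos",
                                                    "freq")],
                          names_from = "pool", values_from = "freq")
  expect_identical(nrow(w), 1L)
  expect_identical(w$chrom, "Chr01")
  expect_identical(w$pos, 100)
  rej <- attr(pf, "rejections")
  expect_identical(rej$n[rej$reason == "not_biallelic"], 1L)
  expect_identical(rej$n[rej$reason == "pool_coverage"], 2L)
  expect_identical(rej$n[rej$reason == "off_chromosome"], 1L)
  expect_identical(rej$n[rej$reason == "low_quality"], 1L)
})

test_that("a SNP absent from the merged pool is dropped", {
  v <- toy_variants()
  v <- v[!(v$pos == 100 & v$pool == "merged"), ]
  pf <- filter_pool_variants(v)
  expect_identical(nrow(tibble::as_tibble(pf)), 0L)
  expect_error(filter_pool_variants(v[, c("chrom", "pos", "pool")]),
               "depth")
})

test_that("detection limit zeroes strictly-below frequencies, idempotently", {
  p <- toy_pool_freqs(tibble::tibble(A = c(0.015, 0.020, 0.5, 0),
                                     B = c(0.019999, 0.02, 0.98, 0.01)))
  out <- apply_detection_limit(p, 0.02)
  w <- tidyr::pivot_wider(tibble::as_tibble(out)[, c("pool", "pos", "freq")],
                          names_from = "pool", values_from = "freq")
  expect_equal(w$A, c(0, 0.020, 0.5, 0))
  expect_equal(w$B, c(0, 0.02, 0.98, 0))
  expect_identical(apply_detection_limit(out, 0.02)$freq, out$freq)
  expect_error(apply_detection_limit(p, 0.6), "0.5")
})

test_that("endemic classification follows the polymorphic-only-here rule", {
  p <- toy_pool_freqs(tibble::tibble(
    ne = c(0.3, 0.3, 0, 1),
    s = c(0, 0.2, 0, 1),
    adm = c(0, 0.4, 0, 1),
    w = c(0, 0.1, 0, 1)
  ))
  res <- classify_endemic(p, admixed_pool = "adm")
  expect_identical(res$per_snp$category,
                   c("endemic:ne", "polymorphic_in_all", "invariant",
                     "invariant"))
  s <- res$summary
  expect_identical(s$endemic[s$pool == "ne" & s$set == "all_pools"], 1)
  # excluding the admixed pool cannot lose ne's endemic SNP
  expect_identical(s$endemic[s$pool == "ne" & s$set == "excluding_admixed"],
                   1)
})

test_that("pool Fst matches hand-evaluated Nei Gst on toy frequencies", {
  pair <- toy_pool_freqs(tibble::tibble(A = 0.2, B = 0.4))
  expect_equal(pool_fst(pair, c("A", "B"))$fst, 1 / 21)

  fixed <- toy_pool_freqs(tibble::tibble(A = 0, B = 1))
  expect_equal(pool_fst(fixed, c("A", "B"))$fst, 1)

  # monomorphic SNPs add zeros to both sums and change nothing
  padded <- toy_pool_freqs(tibble::tibble(A = c(0.2, rep(0, 1000)),
                                          B = c(0.4, rep(0, 1000))))
  expect_equal(pool_fst(padded, c("A", "B"))$fst, 1 / 21)

  mono <- toy_pool_freqs(tibble::tibble(A = c(0, 1), B = c(0, 1)))
  expect_warning(res <- pool_fst(mono, c("A", "B")), "monomorphic")
  expect_true(is.na(res$fst))
})

test_that("one-vs-rest uses the unweighted mean of the other pools", {
  p <- toy_pool_freqs(tibble::tibble(a = 0.6, b = 0.1, c = 0.2, d = 0.3))
  res <- pool_fst(p, "a")
  rest <- mean(c(0.1, 0.2, 0.3))
  hs <- (expected_heterozygosity(0.6) + expected_heterozygosity(rest)) / 2
  ht <- expected_heterozygosity((0.6 + rest) / 2)
  expect_equal(res$fst, (ht - hs) / ht)
})

test_that("the pairwise Fst matrix is symmetric with zero diagonal", {
  set.seed(12)
  p <- toy_pool_freqs(tibble::tibble(a = runif(50), b = runif(50),
                                     c = runif(50)))
  fm <- pool_fst_matrix(p)
  expect_equal(fm, t(fm))
  expect_equal(unname(diag(fm)), rep(0, 3))
  expect_true(all(fm >= 0 & fm <= 1))
})

test_that("windowed scan finds a planted elevated region and merges it", {
  set.seed(13)
  pos <- sort(sample(1:3e7, 3000))
  fst <- runif(3000, 0, 0.1)
  plant <- pos >= 1.2e7 & pos < 1.8e7  # 6 Mb elevated block
  fst[plant] <- runif(sum(plant), 0.7, 0.8)
  track <- tibble::tibble(chrom = "Chr14", pos = pos, fst = fst)
  sc <- fst_scan(track, window_size_bp = 5e5, min_snps = 2,
                 peak_quantile = 0.8)
  expect_identical(nrow(sc$regions), 1L)
  expect_lte(abs(sc$regions$start - 1.2e7), 5e5)
  expect_lte(abs(sc$regions$end - 1.8e7), 5e5)
})

test_that("scan tie rule and whole-chromosome window behave", {
  flat <- tibble::tibble(chrom = "Chr01", pos = seq(1, 1e6, by = 1e4),
                         fst = 0.2)
  sc <- fst_scan(flat, window_size_bp = 1e5, min_snps = 2)
  expect_identical(sum(sc$windows$peak), 0L)

  one <- fst_scan(flat, window_size_bp = 2e6, min_snps = 2)
  expect_equal(one$windows$mean_fst, mean(flat$fst))
})

test_that("pool Fst grows with divergence time under isolation", {
  fst_at_T <- function(T) {
    d <- simulate_divergence_afs(divergence_model_spec(
      "isolation", Ne = 150, T_split = T, n_loci = 800, seed = 47))
    p <- toy_pool_freqs(tibble::tibble(A = d$p1, B = d$p2))
    pool_fst(p, c("A", "B"))$fst
  }
  vals <- vapply(c(25, 100, 300, 700), fst_at_T, numeric(1))
  expect_true(all(diff(vals) > 0))
})
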