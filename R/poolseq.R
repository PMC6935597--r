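#' Default pool-variant filtering rules
#'
#' The shipped defaults are the sequence-capture pipeline's published
#' settings: biallelic SNPs only, per-pool coverage within
#' \[150, 500\] in every individual pool, present in the merged pool at
#' coverage >= 200, call quality >= 20, and located on one of the 19
#' named chromosomes (scaffolds dropped).
#'
#' @param cov_range Inclusive per-pool coverage bounds.
#' @param merged_min_cov Minimum merged-pool coverage.
#' @param min_qual Minimum variant quality.
#' @param chromosomes Retained chromosome names.
#' @return A named list of rules for [filter_pool_variants()].
#' @export
pool_filter_rules <- function(cov_range = c(150, 500),
                              merged_min_cov = 200,
                              min_qual = 20,
                              chromosomes = sprintf("Chr%02d", 1:19)) {
  list(cov_range = cov_range, merged_min_cov = merged_min_cov,
       min_qual = min_qual, chromosomes = chromosomes)
}

#' Filter pool-seq variants and estimate pool allele frequencies
#'
#' Applies the pool-variant retention rules to a raw variant table and
#' returns per-pool alternate-allele frequencies for the survivors,
#' together with a per-reason rejection tally.
#'
#' @param variants A tibble with one row per SNP x pool: columns `chrom`,
#'   `pos`, `pool`, `ref_depth`, `alt_depth` (or `coverage` + `alt_depth`),
#'   `qual`, and optionally `n_alleles` (default 2).  The merged pool is
#'   the row whose `pool` equals `merged_pool`.
#' @param rules A [pool_filter_rules()] list.
#' @param merged_pool Name of the merged-pool rows.
#' @param pool_sizes Named vector of diploid individuals per pool
#'   (default 20 each).
#' @return A tibble of class `pool_freqs` (long: `pool`, `chrom`, `pos`,
#'   `freq`, `coverage`) for the individual pools plus a `merged` row
#'   set, with `attr(, "pool_sizes")` and `attr(, "rejections")`.
#' @export
filter_pool_variants <- function(variants, rules = pool_filter_rules(),
                                 merged_pool = "merged",
                                 pool_sizes = NULL) {
  v <- tibble::as_tibble(variants)
  need <- c("chrom", "pos", "pool")
  if (!all(need %in% names(v))) {
    abort("variant table needs `chrom`, `pos` and `pool` columns")
  }
  if (!"coverage" %in% names(v)) {
    if (!all(c("ref_depth", "alt_depth") %in% names(v))) {
      abort("variant table needs per-pool depth fields (ref_depth/alt_depth or coverage)")
    }
    v$coverage <- v$ref_depth + v$alt_depth
  }
  if (!"alt_depth" %in% names(v)) {
    abort("variant table needs per-pool depth fields (alt_depth)")
  }
  if (!"qual" %in% names(v)) v$qual <- Inf
  if (!"n_alleles" %in% names(v)) v$n_alleles <- 2L

  ind_pools <- setdiff(unique(v$pool), merged_pool)
  per_snp <- v |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      biallelic = all(.data$n_alleles == 2),
      qual_ok = all(.data$qual >= rules$min_qual),
      n_ind_pools = sum(.data$pool != merged_pool),
      cov_ok = all(.data$coverage[.data$pool != merged_pool] >=
                     rules$cov_range[1] &
                   .data$coverage[.data$pool != merged_pool] <=
                     rules$cov_range[2]),
      merged_ok = any(.data$pool == merged_pool &
                        .data$coverage >= rules$merged_min_cov),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      chrom_ok = .data$chrom %in% rules$chromosomes,
      all_pools = .data$n_ind_pools == length(ind_pools),
      keep = .data$biallelic & .data$qual_ok & .data$cov_ok &
        .data$merged_ok & .data$chrom_ok & .data$all_pools
    )
  rejections <- tibble::tibble(
    reason = c("not_biallelic", "low_quality", "pool_coverage",
               "absent_from_merged", "off_chromosome",
               "missing_in_a_pool"),
    n = c(sum(!per_snp$biallelic), sum(!per_snp$qual_ok),
          sum(!per_snp$cov_ok), sum(!per_snp$merged_ok),
          sum(!per_snp$chrom_ok), sum(!per_snp$all_pools))
  )
  kept <- per_snp[per_snp$keep, c("chrom", "pos")]
  out <- v |>
    dplyr::semi_join(kept, by = c("chrom", "pos")) |>
    dplyr::mutate(freq = .data$alt_depth / .data$coverage) |>
    dplyr::select("pool", "chrom", "pos", "freq", "coverage") |>
    dplyr::arrange(.data$pool, .data$chrom, .data$pos)
  if (is.null(pool_sizes)) {
    pool_sizes <- setNames(rep(20L, length(ind_pools)), ind_pools)
  }
  structure(out, pool_sizes = pool_sizes, rejections = rejections,
            merged_pool = merged_pool,
            class = c("pool_freqs", class(tibble::tibble())))
}

#' Apply the pool-frequency detection limit
#'
#' Pool allele frequencies strictly below the detection limit (default
#' 2%) are set to 0; the mirrored top end (above `1 - limit`) is left
#' untouched, matching the published rule.  The operation is idempotent.
#'
#' @param p A `pool_freqs` tibble (any tibble with a `freq` column).
#' @param limit Detection limit in `[0, 0.5)`.
#' @return The same tibble with thresholded `freq`.
#' @export
apply_detection_limit <- function(p, limit = 0.02) {
  if (limit < 0 || limit >= 0.5) abort("`limit` must lie in [0, 0.5)")
  p$freq <- ifelse(!is.na(p$freq) & p$freq < limit, 0, p$freq)
  p
}

pool_freq_wide <- function(p) {
  tidyr::pivot_wider(tibble::as_tibble(p)[, c("pool", "chrom", "pos", "freq")],
                     names_from = "pool", values_from = "freq")
}

#' Classify SNPs as endemic, shared or invariant across pools
#'
#' A SNP is polymorphic in a pool iff its frequency lies strictly
#' between 0 and 1.  Categories over the considered pool set:
#' `polymorphic_in_all`, `endemic:<pool>` (polymorphic in exactly one
#' pool), `shared_subset` (some but not all, more than one), and
#' `invariant`.  The summary is computed both including and excluding
#' the admixed pool when one is named.
#'
#' @param p A `pool_freqs` tibble (detection limit usually applied
#'   first).
#' @param pools Pools to consider; default all individual pools.
#' @param admixed_pool Name of the admixed pool, for the
#'   excluding-admixed summary (`NULL` to skip).
#' @return A list: `per_snp` (tibble with `category`), `summary`
#'   (per-pool polymorphic and endemic counts, with and without the
#'   admixed pool), `n_snps`.
#' @export
classify_endemic <- function(p, pools = NULL, admixed_pool = NULL) {
  w <- pool_freq_wide(p)
  merged <- attr(p, "merged_pool") %||% "merged"
  all_pools <- setdiff(names(w), c("chrom", "pos", merged))
  pools <- pools %||% all_pools
  if (length(pools) < 2) abort("need at least two pools")
  cat_for <- function(use_pools) {
    fm <- as.matrix(w[, use_pools, drop = FALSE])
    poly <- fm > 0 & fm < 1
    npoly <- rowSums(poly)
    cat <- dplyr::case_when(
      npoly == 0 ~ "invariant",
      npoly == length(use_pools) ~ "polymorphic_in_all",
      npoly == 1 ~ paste0("endemic:",
                          use_pools[apply(poly, 1, which.max)]),
      TRUE ~ "shared_subset"
    )
    list(cat = cat, poly = poly)
  }
  full <- cat_for(pools)
  per_snp <- dplyr::bind_cols(w[, c("chrom", "pos")],
                              tibble::tibble(category = full$cat))
  summarise_set <- function(res, use_pools, label) {
    tibble::tibble(
      pool = use_pools,
      set = label,
      polymorphic = unname(colSums(res$poly)),
      endemic = vapply(use_pools, function(pl) {
        sum(res$cat == paste0("endemic:", pl))
      }, numeric(1), USE.NAMES = FALSE)
    )
  }
  summary <- summarise_set(full, pools, "all_pools")
  if (!is.null(admixed_pool) && admixed_pool %in% pools) {
    rest <- setdiff(pools, admixed_pool)
    noad <- cat_for(rest)
    summary <- dplyr::bind_rows(
      summary, summarise_set(noad, rest, "excluding_admixed"))
  }
  list(per_snp = per_snp, summary = summary, n_snps = nrow(w))
}

#' Pool differentiation index (Nei Gst on pool frequencies)
#'
#' Per SNP, `Hs` is the mean expected heterozygosity `2p(1-p)` over the
#' contrast's two sides and `Ht` the expected heterozygosity of the mean
#' frequency; the multilocus Fst is the ratio of multilocus sums,
#' `(sum Ht - sum Hs) / sum Ht`.  For a one-vs-rest contrast the "rest"
#' frequency is the unweighted mean of the other pools' frequencies.
#' Monomorphic SNPs contribute zeros to both sums and are included by
#' default, as in pairwise comparisons that keep sites monomorphic for
#' the pair.
#'
#' @param p A `pool_freqs` tibble.
#' @param contrast Either `c(pool_a, pool_b)` for a pair, or a single
#'   pool name for one-vs-rest.
#' @param include_monomorphic Keep SNPs monomorphic in the contrast.
#' @return A list of class `fst_result`: `fst` (multilocus), `track`
#'   (per-SNP tibble of class `fst_track`: `chrom`, `pos`, `fst`, `hs`,
#'   `ht`), `contrast`.
#' @export
pool_fst <- function(p, contrast, include_monomorphic = TRUE) {
  w <- pool_freq_wide(p)
  merged <- attr(p, "merged_pool") %||% "merged"
  all_pools <- setdiff(names(w), c("chrom", "pos", merged))
  if (!all(contrast %in% all_pools)) {
    abort("contrast pools not present in the frequency table")
  }
  if (length(contrast) == 2) {
    f1 <- w[[contrast[1]]]
    f2 <- w[[contrast[2]]]
    label <- paste(contrast, collapse = "_vs_")
  } else if (length(contrast) == 1) {
    rest <- setdiff(all_pools, contrast)
    f1 <- w[[contrast]]
    f2 <- rowMeans(as.matrix(w[, rest, drop = FALSE]))
    label <- paste0(contrast, "_vs_rest")
  } else {
    abort("`contrast` must name one or two pools")
  }
  hs <- (expected_heterozygosity(f1) + expected_heterozygosity(f2)) / 2
  ht <- expected_heterozygosity((f1 + f2) / 2)
  keep <- if (include_monomorphic) rep(TRUE, length(hs)) else ht > 0
  hs <- hs[keep]; ht <- ht[keep]
  if (sum(ht, na.rm = TRUE) == 0) {
    warn("all SNPs monomorphic in this contrast; Fst undefined")
    fst_ml <- NA_real_
  } else {
    fst_ml <- (sum(ht, na.rm = TRUE) - sum(hs, na.rm = TRUE)) /
      sum(ht, na.rm = TRUE)
  }
  track <- tibble::tibble(
    chrom = w$chrom[keep], pos = w$pos[keep],
    hs = hs, ht = ht,
    fst = ifelse(ht > 0, (ht - hs) / ht, 0)
  )
  structure(list(fst = fst_ml,
                 track = structure(track,
                                   contrast = label,
                                   class = c("fst_track",
                                             class(tibble::tibble()))),
                 contrast = label,
                 n_snps = nrow(track)),
            class = "fst_result")
}

#' Pairwise pool Fst matrix
#'
#' @param p A `pool_freqs` tibble.
#' @param pools Pools to compare; default all individual pools.
#' @inheritParams pool_fst
#' @return A symmetric matrix of multilocus Fst values, zero diagonal.
#' @export
pool_fst_matrix <- function(p, pools = NULL, include_monomorphic = TRUE) {
  w <- pool_freq_wide(p)
  merged <- attr(p, "merged_pool") %||% "merged"
  pools <- pools %||% setdiff(names(w), c("chrom", "pos", merged))
  out <- matrix(0, length(pools), length(pools),
                dimnames = list(pools, pools))
  for (i in seq_along(pools)) {
    for (j in seq_along(pools)) {
      if (j <= i) next
      f <- pool_fst(p, c(pools[i], pools[j]), include_monomorphic)$fst
      out[i, j] <- out[j, i] <- f
    }
  }
  out
}

#' Windowed Fst genome scan
#'
#' Tiles each chromosome with half-open windows `[start, start + size)`,
#' averages per-SNP Fst within windows holding at least `min_snps`
#' SNPs, flags windows whose mean lies strictly above the
#' `peak_quantile` of all window means, and merges adjacent flagged
#' windows into peak regions.
#'
#' @param track A per-SNP `fst_track` tibble (`chrom`, `pos`, `fst`).
#' @param window_size_bp Window width in base pairs.
#' @param min_snps Minimum SNPs for a window to be scored.
#' @param peak_quantile Quantile of window means defining a peak.
#' @return A list of class `fst_scan`: `windows` (tibble `chrom`,
#'   `start`, `end`, `mean_fst`, `n_snps`, `peak`) and `regions`
#'   (merged peak intervals, 1-based inclusive).
#' @export
fst_scan <- function(track, window_size_bp = 5e5, min_snps = 5,
                     peak_quantile = 0.99) {
  t <- dplyr::arrange(tibble::as_tibble(track), .data$chrom, .data$pos)
  t$win <- floor((t$pos - 1) / window_size_bp)
  windows <- t |>
    dplyr::group_by(.data$chrom, .data$win) |>
    dplyr::summarise(mean_fst = mean(.data$fst, na.rm = TRUE),
                     n_snps = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(start = .data$win * window_size_bp + 1,
                  end = (.data$win + 1) * window_size_bp) |>
    dplyr::filter(.data$n_snps >= min_snps)
  if (nrow(windows) == 0) {
    return(structure(list(windows = windows,
                          regions = tibble::tibble(chrom = character(),
                                                   start = numeric(),
                                                   end = numeric())),
                     class = "fst_scan"))
  }
  thr <- quantile(windows$mean_fst, peak_quantile, names = FALSE)
  windows$peak <- windows$mean_fst > thr  # strict: all-tied means no peaks
  flagged <- dplyr::filter(windows, .data$peak)
  regions <- if (nrow(flagged) == 0) {
    tibble::tibble(chrom = character(), start = numeric(),
                   end = numeric(), mean_fst = numeric())
  } else flagged |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(gap = .data$win - dplyr::lag(.data$win, default = -10) > 1,
                  region = cumsum(.data$gap)) |>
    dplyr::group_by(.data$chrom, .data$region) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     mean_fst = mean(.data$mean_fst), .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "mean_fst")
  structure(list(windows = dplyr::select(windows, -"win"),
                 regions = regions, threshold = thr,
                 window_size_bp = window_size_bp),
            class = "fst_scan")
}
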