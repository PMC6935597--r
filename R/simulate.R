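# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Balding-Nichols draw: beta around ancestral p (vector) with divergence F
rbn <- function(p, f) {
  if (f < 1e-8) return(p)
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

default_lineage_names <- function(k) {
  if (k == 3) c("northeast", "south", "west") else sprintf("lin%d", seq_len(k))
}

# distinct chloroplast haplotype alleles per lineage, n_cp_loci long
cp_lineage_alleles <- function(k, n_cp) {
  base <- c("A", "C", "G", "T")
  out <- matrix(base[1], k, n_cp)
  # flip a distinct locus per lineage so haplotype strings are diagnostic
  for (i in seq_len(k)) {
    j <- ((i - 1) %% n_cp) + 1
    out[i, j] <- base[(i %% 4) + 1]
    if (i > n_cp) out[i, ((i) %% n_cp) + 1] <- base[((i + 1) %% 4) + 1]
  }
  rownames(out) <- default_lineage_names(k)
  out
}

#' Simulate a structured multi-lineage SNP-array survey
#'
#' Draws a full synthetic survey from a [lineage_sim_spec()]: nuclear
#' genotypes under the Balding-Nichols model with nested population
#' substructure, admixed individuals as binomial mixtures of two lineage
#' gene pools, lineage-diagnostic chloroplast haplotypes with planted
#' capture events, an interspecific diagnostic panel with planted F1
#' hybrids, clonal duplicates, and missing calls.  Every planted feature
#' is recorded in a truth ledger so downstream detectors can be scored
#' exactly.
#'
#' @param spec A [lineage_sim_spec()].
#' @return A list of class `lineage_sim` with elements
#'   \describe{
#'     \item{genotypes}{[genotype_table()] of nuclear + diagnostic loci.}
#'     \item{cp}{tibble of haploid chloroplast calls, one column per cp
#'       locus.}
#'     \item{q}{true admixture proportions (tibble, `id` + one column per
#'       lineage).}
#'     \item{ledger}{per-individual truth: lineage, admixture, hybrid and
#'       clone flags, chloroplast lineage, capture direction.}
#'     \item{diagnostic_panel}{tibble naming the panel loci and their
#'       focal allele.}
#'   }
#' @examples
#' sim <- simulate_lineages(lineage_sim_spec(
#'   n_pops_per_lineage = 4, n_ind_per_pop = 5, seed = 7
#' ))
#' sim$ledger
#' @export
simulate_lineages <- function(spec) {
  stopifnot(inherits(spec, "lineage_sim_spec"))
  with_seed(spec$seed, {
    K <- spec$n_lineages
    L <- spec$n_loci
    lname <- default_lineage_names(K)

    p_anc <- runif(L, 0.05, 0.95)
    p_lin <- vapply(seq_len(K),
                    function(k) rbn(p_anc, spec$lineage_fst[k]),
                    numeric(L))
    # population frequencies nested within lineages
    n_pop <- spec$n_pops_per_lineage
    pop_tbl <- tidyr::expand_grid(lineage = seq_len(K), pop = seq_len(n_pop))
    p_pop <- lapply(seq_len(nrow(pop_tbl)), function(i) {
      rbn(p_lin[, pop_tbl$lineage[i]], spec$pop_fst)
    })

    n_base <- K * n_pop * spec$n_ind_per_pop
    ind <- tibble::tibble(
      lineage = rep(pop_tbl$lineage, each = spec$n_ind_per_pop),
      pop_idx = rep(seq_len(nrow(pop_tbl)), each = spec$n_ind_per_pop)
    )
    ind$population <- sprintf("pop_%s_%02d", lname[ind$lineage],
                              pop_tbl$pop[ind$pop_idx])
    # crude geography: one lat/lon jitter per locality
    pop_lat <- 42 + 10 * runif(nrow(pop_tbl))
    pop_lon <- -114 + 45 * runif(nrow(pop_tbl))
    ind$latitude <- round(pop_lat[ind$pop_idx], 4)
    ind$longitude <- round(pop_lon[ind$pop_idx], 4)

    # admixture: a fraction of individuals mix their lineage (major) with
    # a random other lineage; the rest are pure
    admixed <- runif(n_base) < spec$admix_fraction
    other <- vapply(ind$lineage, function(k) {
      sample(setdiff(seq_len(K), k), 1)
    }, integer(1))
    q_major <- ifelse(admixed, runif(n_base, 0.5, 0.95), 1)
    qmat <- matrix(0, n_base, K, dimnames = list(NULL, lname))
    qmat[cbind(seq_len(n_base), ind$lineage)] <- q_major
    qmat[cbind(seq_len(n_base), other)] <-
      qmat[cbind(seq_len(n_base), other)] + (1 - q_major)

    # per-individual allele frequency: own locality's pool for the major
    # side, the other lineage's range-wide pool for the minor side
    geno <- matrix(NA_real_, n_base, L)
    for (i in seq_len(n_base)) {
      p_i <- q_major[i] * p_pop[[ind$pop_idx[i]]] +
        (1 - q_major[i]) * p_lin[, other[i]]
      geno[i, ] <- rbinom(L, 2, pmin(pmax(p_i, 0), 1))
    }
    colnames(geno) <- sprintf("N%03d", seq_len(L))

    # interspecific diagnostic panel: focal species fixed for the
    # reference allele; F1 hybrids heterozygous throughout the panel
    hybrid <- runif(n_base) < spec$hybrid_rate
    D <- spec$n_diagnostic_loci
    diag_geno <- matrix(0, n_base, D)
    diag_geno[hybrid, ] <- 1
    colnames(diag_geno) <- sprintf("D%03d", seq_len(D))

    # chloroplast: maternal lineage = major parent, except planted
    # captures among non-admixed, non-hybrid trees
    cp_lineage <- ind$lineage
    capture_from <- rep(NA_integer_, n_base)
    eligible <- which(!admixed & !hybrid)
    for (i in eligible) {
      pr <- spec$capture_rates[ind$lineage[i], ]
      donor <- sample.int(K + 1, 1, prob = c(pr, 1 - sum(pr)))
      if (donor <= K) {
        cp_lineage[i] <- donor
        capture_from[i] <- donor
      }
    }
    cp_alleles <- cp_lineage_alleles(K, spec$n_cp_loci)
    cp_calls <- cp_alleles[cp_lineage, , drop = FALSE]
    colnames(cp_calls) <- sprintf("C%03d", seq_len(spec$n_cp_loci))

    base <- tibble::tibble(
      id = sprintf("ind%04d", seq_len(n_base)),
      population = ind$population,
      latitude = ind$latitude, longitude = ind$longitude,
      lineage = lname[ind$lineage], admixed = admixed,
      q_major = q_major, hybrid = hybrid,
      cp_lineage = lname[cp_lineage],
      capture_from = ifelse(is.na(capture_from), NA_character_,
                            lname[capture_from]),
      clone_of = NA_character_
    )

    # clonal ramets copy everything (nuclear, panel, chloroplast)
    clone_idx <- which(runif(n_base) < spec$clone_rate)
    rows <- sort(c(seq_len(n_base), clone_idx))
    ledger <- base[rows, ]
    dup <- duplicated(ledger$id)
    ledger$clone_of[dup] <- ledger$id[dup]
    ledger$id[dup] <- paste0(ledger$id[dup], "_r2")
    geno_all <- cbind(geno, diag_geno)[rows, , drop = FALSE]
    cp_all <- cp_calls[rows, , drop = FALSE]
    n_tot <- nrow(ledger)

    # missingness at nuclear + panel loci; a few failed extractions
    failed <- runif(n_tot) < spec$failed_rate
    rate <- ifelse(failed, pmin(10 * spec$missing_rate, 0.6),
                   spec$missing_rate)
    if (spec$missing_rate > 0) {
      miss <- matrix(runif(n_tot * ncol(geno_all)), n_tot) < rate
      geno_all[miss] <- NA_real_
    }

    loci <- tibble::tibble(
      locus = colnames(geno_all),
      chrom = sprintf("Chr%02d", (seq_len(ncol(geno_all)) %% 19) + 1),
      pos = 1e5 * seq_len(ncol(geno_all)),
      gene = ifelse(startsWith(colnames(geno_all), "D"),
                    "diagnostic", "candidate")
    )
    g <- genotype_table(
      geno_all,
      ledger[, c("id", "population", "latitude", "longitude")],
      loci
    )
    qtbl <- tibble::tibble(id = ledger$id)
    qtbl <- dplyr::bind_cols(qtbl, tibble::as_tibble(qmat[rows, , drop = FALSE]))
    cp_tbl <- dplyr::bind_cols(tibble::tibble(id = ledger$id),
                               tibble::as_tibble(cp_all))
    structure(
      list(genotypes = g, cp = cp_tbl, q = qtbl,
           ledger = ledger,
           diagnostic_panel = tibble::tibble(
             locus = colnames(diag_geno), focal = "ref"
           ),
           lineages = lname, spec = spec),
      class = "lineage_sim"
    )
  })
}

#' Simulate pooled sequencing read counts
#'
#' Emulates pool-seq of equimolar DNA pools: per SNP and pool, coverage is
#' drawn from a negative-binomial (mean `mean_coverage`, dispersion
#' `coverage_dispersion`), and alternate-read counts are binomial at the
#' true pool frequency perturbed by a symmetric per-read error rate.
#'
#' @param freqs True pool allele frequencies: either a wide tibble with
#'   columns `chrom`, `pos` and one numeric column per pool, or a
#'   [genotype_table()] together with `pools` (a named list of individual
#'   ids), in which case true frequencies are the mean alternate-allele
#'   dosage / 2 among pool members.
#' @param pools Named list of individual id vectors (genotype input only).
#' @param pool_sizes Named integer vector of diploid individuals per pool;
#'   inferred from `pools` when genotypes are given. Default 20 per pool.
#' @param mean_coverage Mean sequencing depth per SNP per pool.
#' @param coverage_dispersion Negative-binomial size parameter; larger is
#'   closer to Poisson.
#' @param error_rate Per-read probability of reading the other allele.
#' @param seed Integer seed.
#'
#' @return A tibble of class `pool_counts`: `pool`, `chrom`, `pos`,
#'   `ref_depth`, `alt_depth`, `coverage`, with pool sizes in
#'   `attr(, "pool_sizes")`.
#' @export
simulate_pools <- function(freqs, pools = NULL, pool_sizes = NULL,
                           mean_coverage = 300, coverage_dispersion = 30,
                           error_rate = 0.002, seed = 1L) {
  if (mean_coverage <= 0) abort("`mean_coverage` must be positive")
  if (inherits(freqs, "geno_tbl")) {
    if (is.null(pools) || is.null(names(pools))) {
      abort("genotype input requires a named list of `pools`")
    }
    if (any(lengths(pools) == 0)) abort("empty pool")
    m <- geno_matrix(freqs)
    loci <- geno_loci(freqs)
    f <- vapply(pools, function(ids) {
      colMeans(m[rownames(m) %in% ids, , drop = FALSE], na.rm = TRUE) / 2
    }, numeric(ncol(m)))
    freqs <- dplyr::bind_cols(
      tibble::tibble(chrom = loci$chrom %||% "Chr01",
                     pos = loci$pos %||% seq_len(ncol(m))),
      tibble::as_tibble(f)
    )
    if (is.null(pool_sizes)) pool_sizes <- lengths(pools)
  }
  freqs <- tibble::as_tibble(freqs)
  pool_names <- setdiff(names(freqs), c("chrom", "pos", "locus"))
  if (length(pool_names) == 0) abort("no pool frequency columns found")
  if (is.null(pool_sizes)) {
    pool_sizes <- setNames(rep(20L, length(pool_names)), pool_names)
  }
  long <- tidyr::pivot_longer(freqs, dplyr::all_of(pool_names),
                              names_to = "pool", values_to = "freq")
  with_seed(seed, {
    n <- nrow(long)
    cov <- rnbinom(n, mu = mean_coverage, size = coverage_dispersion)
    f_err <- long$freq * (1 - error_rate) + (1 - long$freq) * error_rate
    alt <- rbinom(n, cov, f_err)
    out <- tibble::tibble(
      pool = long$pool,
      chrom = long$chrom %||% "Chr01",
      pos = long$pos,
      ref_depth = cov - alt, alt_depth = alt, coverage = cov
    )
    structure(dplyr::arrange(out, .data$pool, .data$chrom, .data$pos),
              pool_sizes = pool_sizes,
              class = c("pool_counts", class(tibble::tibble())))
  })
}

#' Forward-simulate joint allele frequencies under a divergence model
#'
#' Evolves independent biallelic loci through a two-deme Wright-Fisher
#' process: an ancestral frequency is drawn per locus from a symmetric
#' Beta(0.5, 0.5) standing-variation distribution, both demes start from
#' it at the split, and each subsequent generation applies deterministic
#' migration followed by binomial drift over `2 Ne` gene copies.  The
#' four supported histories differ only in when migration is active.
#'
#' @param spec A [divergence_model_spec()].
#' @return A tibble with one row per locus: `p_anc`, `p1`, `p2` (final
#'   allele frequencies in each deme).
#' @examples
#' afs <- simulate_divergence_afs(divergence_model_spec(
#'   "isolation", Ne = 100, T_split = 200, n_loci = 500, seed = 2
#' ))
#' @export
simulate_divergence_afs <- function(spec) {
  stopifnot(inherits(spec, "divergence_model_spec"))
  with_seed(spec$seed, {
    L <- spec$n_loci
    n2 <- 2L * spec$Ne
    p_anc <- rbeta(L, 0.5, 0.5)
    p1 <- p_anc
    p2 <- p_anc
    if (spec$T_split > 0) {
      for (g in seq_len(spec$T_split)) {
        t_ago <- spec$T_split - g
        mig_on <- switch(spec$model,
          isolation = FALSE,
          isolation_with_migration = TRUE,
          ancient_migration = t_ago >= spec$T_switch,
          secondary_contact = t_ago < spec$T_switch
        )
        if (mig_on) {
          p1n <- (1 - spec$m12) * p1 + spec$m12 * p2
          p2n <- (1 - spec$m21) * p2 + spec$m21 * p1
        } else {
          p1n <- p1
          p2n <- p2
        }
        p1 <- rbinom(L, n2, p1n) / n2
        p2 <- rbinom(L, n2, p2n) / n2
      }
    }
    tibble::tibble(locus = seq_len(L), p_anc = p_anc, p1 = p1, p2 = p2)
  })
}
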