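# per-locus, per-population allele-copy bookkeeping for AMOVA:
# s = alt-allele copies, n = total non-missing copies (pops x loci)
amova_pop_sums <- function(m, pop) {
  s <- rowsum(ifelse(is.na(m), 0, m), pop)
  n <- rowsum((!is.na(m)) * 2, pop)
  list(s = s, n = n, pops = rownames(s))
}

# three-level variance components from population sums; group_of_pop maps
# each population (row of s/n) to its group.  For binary allele values
# sum(x^2) = sum(x), so every sum of squares reduces to terms in (s, n);
# Excoffier-style n coefficients convert mean squares to components.
# Vectorized across loci so permutation tests stay cheap.
amova_components <- function(s, n, group_of_pop) {
  div0 <- function(num, den) ifelse(den > 0, num / den, 0)
  N <- colSums(n); S <- colSums(s)
  Sg <- rowsum(s, group_of_pop)
  Ng <- rowsum(n, group_of_pop)
  sum_sp2 <- colSums(div0(s^2, n))
  sum_Sg2 <- colSums(div0(Sg^2, Ng))
  ss_wp <- S - sum_sp2
  ss_ap <- sum_sp2 - sum_Sg2
  ss_ag <- sum_Sg2 - div0(S^2, N)
  Pl <- colSums(n > 0)
  Gl <- colSums(Ng > 0)
  df_wp <- N - Pl; df_ap <- Pl - Gl; df_ag <- Gl - 1
  sum_npg2 <- colSums(div0(n^2, Ng[group_of_pop, , drop = FALSE]))
  n1 <- div0(N - sum_npg2, df_ap)
  n2 <- div0(sum_npg2 - div0(colSums(n^2), N), df_ag)
  n3 <- div0(N - div0(colSums(Ng^2), N), df_ag)
  c_l <- div0(ss_wp, df_wp)
  b_l <- ifelse(df_ap > 0, div0(div0(ss_ap, df_ap) - c_l, n1), 0)
  a_l <- div0(div0(ss_ag, df_ag) - c_l - n2 * b_l, n3)
  valid <- df_wp > 0 & df_ag > 0
  sig_a <- sum(a_l[valid]); sig_b <- sum(b_l[valid])
  sig_c <- sum(c_l[valid])
  tot <- sig_a + sig_b + sig_c
  list(sigma2_among_groups = sig_a,
       sigma2_among_pops_within = sig_b,
       sigma2_within_pops = sig_c,
       Fct = sig_a / tot,
       Fsc = sig_b / (sig_b + sig_c),
       Fst = (sig_a + sig_b) / tot)
}

#' Hierarchical AMOVA (groups / populations / individuals)
#'
#' Allele-based analysis of molecular variance over biallelic SNPs:
#' gene copies are decomposed into variance among groups, among
#' populations within groups, and within populations, yielding the
#' hierarchical fixation indices `Fct`, `Fsc` and `Fst`, which satisfy
#' `(1 - Fct)(1 - Fsc) = (1 - Fst)` by construction.  Significance is
#' assessed by permutation: whole populations are permuted among groups
#' for `Fct`, and individuals among populations within their group for
#' `Fsc`.
#'
#' @param g A [genotype_table()].
#' @param groups Group (lineage) label per individual.
#' @param populations Population label per individual; defaults to the
#'   table's `population` column.
#' @param min_pop_size Populations below this size are dropped.
#' @param n_perm Number of permutations (0 skips the tests).
#' @param seed Seed for the permutation stream.
#' @return An object of class `amova_fit` with variance components, the
#'   three F-statistics and permutation p-values.  `tidy()` returns the
#'   component table, `glance()` a one-row summary.
#' @export
amova_hierarchical <- function(g, groups, populations = NULL,
                               min_pop_size = 3, n_perm = 10000,
                               seed = 1L) {
  populations <- populations %||% g$population
  m <- geno_matrix(g)
  sizes <- table(populations)
  keep_pops <- names(sizes)[sizes >= min_pop_size]
  sel <- populations %in% keep_pops
  m <- m[sel, , drop = FALSE]
  pop <- as.character(populations[sel])
  grp <- as.character(groups[sel])
  pop_group <- tapply(grp, pop, function(x) x[1])
  if (length(unique(pop_group)) < 2) {
    abort("need at least two groups with populations passing `min_pop_size`")
  }
  ps <- amova_pop_sums(m, pop)
  group_of_pop <- as.character(pop_group[ps$pops])
  obs <- amova_components(ps$s, ps$n, group_of_pop)

  p_fct <- p_fsc <- NA_real_
  if (n_perm > 0) {
    perms <- with_seed(seed, {
      fct_perm <- vapply(seq_len(n_perm), function(i) {
        amova_components(ps$s, ps$n, sample(group_of_pop))$Fct
      }, numeric(1))
      fsc_perm <- vapply(seq_len(n_perm), function(i) {
        new_pop <- pop
        for (gr in unique(group_of_pop)) {
          idx <- which(grp == gr)
          new_pop[idx] <- pop[idx][sample.int(length(idx))]
        }
        ps_i <- amova_pop_sums(m, new_pop)
        amova_components(ps_i$s, ps_i$n,
                         as.character(pop_group[ps_i$pops]))$Fsc
      }, numeric(1))
      list(fct = fct_perm, fsc = fsc_perm)
    })
    p_fct <- (1 + sum(perms$fct >= obs$Fct)) / (n_perm + 1)
    p_fsc <- (1 + sum(perms$fsc >= obs$Fsc)) / (n_perm + 1)
  }
  components <- tibble::tibble(
    level = c("among_groups", "among_pops_within_groups", "within_pops"),
    sigma2 = c(obs$sigma2_among_groups, obs$sigma2_among_pops_within,
               obs$sigma2_within_pops)
  )
  components$pct <- 100 * components$sigma2 / sum(components$sigma2)
  structure(list(components = components,
                 Fct = obs$Fct, Fsc = obs$Fsc, Fst = obs$Fst,
                 p_Fct = p_fct, p_Fsc = p_fsc,
                 n_perm = n_perm, seed = seed,
                 n_pops = length(ps$pops),
                 n_groups = length(unique(group_of_pop))),
            class = "amova_fit")
}

#' @export
print.amova_fit <- function(x, ...) {
  cat(sprintf("Hierarchical AMOVA: %d groups, %d populations\n",
              x$n_groups, x$n_pops))
  print(x$components)
  cat(sprintf("Fct = %.4f (p = %s), Fsc = %.4f (p = %s), Fst = %.4f\n",
              x$Fct, format(x$p_Fct), x$Fsc, format(x$p_Fsc), x$Fst))
  invisible(x)
}
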