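# independent oracle: nested ANOVA sums of squares on expanded gene
# copies (deviations from means), converted to variance components with
# coefficients derived from first principles here, independently of the
# package's population-sum bookkeeping
brute_force_amova <- function(m, pop, grp) {
  copies <- data.frame(x = numeric(0), pop = character(0),
                       grp = character(0), locus = integer(0))
  for (l in seq_len(ncol(m))) {
    for (i in seq_len(nrow(m))) {
      gval <- m[i, l]
      if (is.na(gval)) next
      x <- switch(as.character(gval), "0" = c(0, 0), "1" = c(0, 1),
                  "2" = c(1, 1))
      copies <- rbind(copies, data.frame(x = x, pop = pop[i],
                                         grp = grp[i], locus = l))
    }
  }
  sig <- c(a = 0, b = 0, c = 0)
  for (l in unique(copies$locus)) {
    d <- copies[copies$locus == l, ]
    N <- nrow(d)
    xbar <- mean(d$x)
    pop_means <- tapply(d$x, d$pop, mean)
    grp_means <- tapply(d$x, d$grp, mean)
    n_p <- table(d$pop)
    N_g <- table(d$grp)
    pop_grp <- tapply(d$grp, d$pop, function(v) v[1])
    ss_wp <- sum((d$x - pop_means[d$pop])^2)
    ss_ap <- sum(n_p * (pop_means - grp_means[pop_grp[names(pop_means)]])^2)
    ss_ag <- sum(N_g * (grp_means - xbar)^2)
    P <- length(n_p); G <- length(N_g)
    npg2_by_g <- tapply(as.numeric(n_p)^2, pop_grp[names(n_p)], sum)
    n1 <- (N - sum(npg2_by_g / N_g[names(npg2_by_g)])) / (P - G)
    n2 <- (sum(npg2_by_g / N_g[names(npg2_by_g)]) - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(N_g^2) / N) / (G - 1)
    sc <- ss_wp / (N - P)
    sb <- (ss_ap / (P - G) - sc) / n1
    sa <- (ss_ag / (G - 1) - sc - n2 * sb) / n3
    sig <- sig + c(a = sa, b = sb, c = sc)
  }
  sig
}

# a constructed pool-variant table exercising every retention rule:
# 4 individual pools + merged, one row per SNP x pool; exactly one SNP
# (Chr01:100) satisfies every rule
toy_variants <- function() {
  snps <- tibble::tibble(
    chrom = c("Chr01", "Chr01", "Chr02", "scaffold_12", "Chr03", "Chr04"),
    pos = c(100, 200, 300, 400, 500, 600),
    n_alleles = c(2L, 2L, 3L, 2L, 2L, 2L),
    qual = c(30, 30, 30, 30, 10, 30)
  )
  pools <- c("ne", "s", "adm", "w")
  cov <- rbind(
    c(300, 200, 450, 160),  # retained
    c(149, 300, 300, 300),  # one pool below 150
    c(300, 300, 300, 300),  # triallelic
    c(300, 300, 300, 300),  # scaffold
    c(300, 300, 300, 300),  # low quality
    c(300, 300, 300, 501)   # one pool above 500
  )
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_along(pools)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = snps$chrom[i], pos = snps$pos[i], pool = pools[j],
        coverage = cov[i, j], alt_depth = round(cov[i, j] * 0.3),
        qual = snps$qual[i], n_alleles = snps$n_alleles[i])
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      chrom = snps$chrom[i], pos = snps$pos[i], pool = "merged",
      coverage = sum(cov[i, ]), alt_depth = round(sum(cov[i, ]) * 0.3),
      qual = snps$qual[i], n_alleles = snps$n_alleles[i])
  }
  dplyr::bind_rows(rows)
}
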