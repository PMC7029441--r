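# Independent brute-force oracles used to cross-check the statistical
# machinery. These deliberately avoid the code paths they validate.

# exhaustive two-sided Wilcoxon rank-sum p-value: enumerate every
# assignment of the pooled ranks to group 1 and tail-sum the U statistic
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  n_tot <- ncol(combos)
  p_le <- sum(u_all <= u_obs + 1e-9) / n_tot
  p_ge <- sum(u_all >= u_obs - 1e-9) / n_tot
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher exact p by hypergeometric enumeration over the table
# support, summing outcomes no more probable than the observed one
# (with the customary relative-error guard against float equality)
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

# literal step-by-step recomputation of the rank-weighted ECDF-difference
# ssGSEA sum, written as an explicit walk over ranked positions
oracle_ssgsea <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(expr)))
  r <- rank(expr, ties.method = "average")
  ord <- names(expr)[order(-expr, names(expr))]
  n <- length(expr)
  members <- ord %in% gene_set
  m <- sum(members)
  denom_in <- sum((r[ord[members]])^alpha)
  cum_in <- 0
  cum_out <- 0
  es <- 0
  for (i in seq_len(n)) {
    if (members[i]) {
      cum_in <- cum_in + r[[ord[i]]]^alpha / denom_in
    } else {
      cum_out <- cum_out + 1 / (n - m)
    }
    es <- es + (cum_in - cum_out)
  }
  es
}

# direct trapezoid of a 4PL on a fine grid, for AUC cross-checks
oracle_auc_fourpl <- function(top, bottom, log10_ic50, hill, lmin, lmax,
                              n = 20001L) {
  l <- seq(lmin, lmax, length.out = n)
  v <- bottom + (top - bottom) / (1 + 10^(hill * (l - log10_ic50)))
  sum((v[-1] + v[-n]) / 2) * (l[2] - l[1]) / (lmax - lmin)
}

# small ready-made cohort shared by several I/O and pipeline tests
tiny_cohort <- function(seed = 7, n_samples = 10, n_drugs = 3, noise_sd = 0.05) {
  cfg <- sim_config(
    n_samples = n_samples, n_expression = min(n_samples, 10),
    drugs = sprintf("drug%02d", seq_len(n_drugs)),
    n_expr_genes = 25, n_cna_genes = 8, n_gene_sets = 2,
    noise_sd = noise_sd, seed = seed
  )
  simulate_cohort(cfg)
}

# null screen inputs drawn directly from the generator's no-effect model:
# Bernoulli alteration features and Gaussian AUCs with nothing planted
null_screen_tables <- function(n_samples, n_features, n_drugs,
                               prevalence = 0.3) {
  ids <- sprintf("S%03d", seq_len(n_samples))
  feats <- sprintf("F%03d", seq_len(n_features))
  drugs <- sprintf("D%02d", seq_len(n_drugs))
  alter <- tidyr::expand_grid(sample_id = ids, feature = feats) |>
    dplyr::mutate(status = ifelse(
      stats::runif(dplyr::n()) < prevalence, "altered", "wild-type"
    ))
  aucs <- tidyr::expand_grid(sample_id = ids, drug_id = drugs) |>
    dplyr::mutate(
      auc = 0.6 + 0.12 * stats::rnorm(dplyr::n()),
      status = "ok"
    )
  list(alterations = alter, aucs = aucs)
}
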