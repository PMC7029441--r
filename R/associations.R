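#' Two-sided Wilcoxon rank-sum test
#'
#' Thin, validated wrapper around the standard rank-sum machinery: the
#' exact null distribution is enumerated when the pooled size is <= 20 and
#' there are no ties; otherwise mid-ranks are used with the tie-corrected
#' normal approximation and continuity correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A one-row tibble: `statistic` (Mann-Whitney U of `x`), `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("both groups must be non-empty.")
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic), p = ht$p.value)
}

# shared engine: one Wilcoxon comparison of AUCs between two sample groups
compare_auc_groups <- function(auc_a, auc_b) {
  ht <- wilcoxon_rank_sum(auc_a, auc_b)
  mean_a <- mean(auc_a)
  mean_b <- mean(auc_b)
  tibble(
    delta_auc = mean_a - mean_b,
    fold_change = mean_a / mean_b,
    p = ht$p
  )
}

#' Alteration-versus-wild-type drug sensitivity screen
#'
#' For every (alteration feature, drug) pair, compares the AUCs of altered
#' tumors against wild-type tumors with a two-sided Wilcoxon rank-sum
#' test. Unknown-status samples are excluded per feature; AUC cells that
#' failed curve QC are excluded; pairs with fewer than `min_group` samples
#' in either arm are skipped. P-values are Benjamini-Hochberg adjusted
#' across all tested pairs of the screen.
#'
#' @param alterations Long alteration tibble from [build_alteration_matrix()].
#' @param aucs Long AUC tibble (`sample_id`, `drug_id`, `auc`, `status`).
#' @param min_group Minimum per-arm group size (default 3).
#' @param fdr_method Multiple-testing method passed to [stats::p.adjust()].
#'
#' @return Tibble of association records: `feature`, `drug`, `n_altered`,
#'   `n_wildtype`, `delta_auc` (mean altered - mean wild-type),
#'   `fold_change` (ratio of means), `p`, `q`. Negative `delta_auc` means
#'   the altered tumors are more sensitive.
#' @export
gene_drug_screen <- function(alterations, aucs, min_group = 3,
                             fdr_method = "BH") {
  aucs_ok <- aucs |> filter(.data$status == "ok", is.finite(.data$auc))
  auc_by_drug <- split(
    aucs_ok[c("sample_id", "auc")],
    aucs_ok$drug_id
  )
  alt_known <- alterations |> filter(.data$status != "unknown")
  status_by_feature <- split(
    alt_known[c("sample_id", "status")],
    alt_known$feature
  )

  res <- purrr::imap(status_by_feature, function(st, feat) {
    alt_ids <- st$sample_id[st$status == "altered"]
    wt_ids <- st$sample_id[st$status == "wild-type"]
    purrr::imap(auc_by_drug, function(av, drug) {
      a <- av$auc[av$sample_id %in% alt_ids]
      w <- av$auc[av$sample_id %in% wt_ids]
      if (length(a) < min_group || length(w) < min_group) {
        return(NULL)
      }
      compare_auc_groups(a, w) |>
        mutate(
          feature = feat, drug = drug,
          n_altered = length(a), n_wildtype = length(w)
        )
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()

  if (is.null(res) || nrow(res) == 0) {
    return(tibble(
      feature = character(), drug = character(),
      n_altered = integer(), n_wildtype = integer(),
      delta_auc = numeric(), fold_change = numeric(),
      p = numeric(), q = numeric()
    ))
  }
  res |>
    mutate(q = p.adjust(.data$p, method = fdr_method)) |>
    select(
      "feature", "drug", "n_altered", "n_wildtype",
      "delta_auc", "fold_change", "p", "q"
    ) |>
    arrange(.data$feature, .data$drug)
}

#' One-versus-rest subtype drug sensitivity screen
#'
#' Compares each sample class (molecular subtype, histology, HER2 status,
#' or HCNA-versus-rest chromosomal instability) against all remaining
#' samples, per drug, with a two-sided Wilcoxon rank-sum test. Direction is
#' `"sensitive"` when the class mean AUC is below the rest (lower AUC =
#' fewer surviving cells) and `"resistant"` otherwise; `significant` marks
#' records with `q` below `fdr_level`.
#'
#' @param labels Tibble `sample_id`, `group` giving one class label per
#'   sample (build it from metadata, [assign_subtype()], etc.). Rows with
#'   NA group are dropped.
#' @param aucs Long AUC tibble.
#' @param min_group Minimum per-arm size.
#' @param fdr_method,fdr_level BH-style adjustment and significance level.
#'
#' @return Tibble: `group`, `drug`, `n_group`, `n_rest`, `delta_auc`,
#'   `direction`, `p`, `q`, `significant`.
#' @export
subtype_drug_screen <- function(labels, aucs, min_group = 3,
                                fdr_method = "BH", fdr_level = 0.1) {
  labels <- labels |> filter(!is.na(.data$group))
  groups <- unique(labels$group)
  if (length(groups) < 2) {
    abort("grouping is degenerate: need >= 2 distinct classes.")
  }
  aucs_ok <- aucs |>
    filter(.data$status == "ok", is.finite(.data$auc)) |>
    inner_join(labels, by = "sample_id")
  res <- purrr::map(sort(groups), function(g) {
    purrr::map(sort(unique(aucs_ok$drug_id)), function(drug) {
      dd <- aucs_ok |> filter(.data$drug_id == drug)
      a <- dd$auc[dd$group == g]
      r <- dd$auc[dd$group != g]
      if (length(a) < min_group || length(r) < min_group) {
        return(NULL)
      }
      compare_auc_groups(a, r) |>
        mutate(group = g, drug = drug, n_group = length(a), n_rest = length(r))
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(
      group = character(), drug = character(), n_group = integer(),
      n_rest = integer(), delta_auc = numeric(), direction = character(),
      p = numeric(), q = numeric(), significant = logical()
    ))
  }
  res |>
    mutate(
      q = p.adjust(.data$p, method = fdr_method),
      direction = ifelse(.data$delta_auc < 0, "sensitive", "resistant"),
      significant = .data$q < fdr_level
    ) |>
    select(
      "group", "drug", "n_group", "n_rest", "delta_auc",
      "direction", "p", "q", "significant"
    ) |>
    arrange(.data$group, .data$drug)
}

#' Co-occurrence of two alterations (Fisher exact test)
#'
#' Cross-tabulates two alteration features over the samples with known
#' status for both, and tests independence with a two-sided Fisher exact
#' (hypergeometric) test. A degenerate table with an empty margin returns
#' p = 1 with a warning.
#'
#' @param feature_a,feature_b Feature names present in `alterations`.
#' @param alterations Long alteration tibble.
#'
#' @return One-row tibble: `feature_a`, `feature_b`, `n`, `n_both`,
#'   `odds_ratio`, `p`.
#' @export
cooccurrence_test <- function(feature_a, feature_b, alterations) {
  wide <- alterations |>
    filter(.data$feature %in% c(feature_a, feature_b), .data$status != "unknown") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "status") |>
    tidyr::drop_na()
  if (nrow(wide) < 1 || !all(c(feature_a, feature_b) %in% names(wide))) {
    abort("the two features share no known-status samples.")
  }
  a <- wide[[feature_a]] == "altered"
  b <- wide[[feature_b]] == "altered"
  tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate 2x2 table (empty margin); p set to 1.")
    return(tibble(
      feature_a = feature_a, feature_b = feature_b, n = nrow(wide),
      n_both = sum(a & b), odds_ratio = NA_real_, p = 1
    ))
  }
  ht <- fisher.test(tab, alternative = "two.sided")
  tibble(
    feature_a = feature_a, feature_b = feature_b, n = nrow(wide),
    n_both = sum(a & b), odds_ratio = unname(ht$estimate), p = ht$p.value
  )
}

#' Arrange association records for volcano plotting
#'
#' Adds `log2_fold_change` and `neg_log10_p` and applies the deterministic
#' plotting sort: q ascending, then absolute effect descending, then
#' feature and drug lexically.
#'
#' @param records Output of [gene_drug_screen()].
#' @return The records with plotting columns, sorted.
#' @export
volcano_table <- function(records) {
  records |>
    mutate(
      log2_fold_change = log2(.data$fold_change),
      neg_log10_p = -log10(.data$p)
    ) |>
    arrange(
      .data$q, desc(abs(.data$delta_auc)), .data$feature, .data$drug
    )
}

#' Volcano plot of a gene-drug association screen
#'
#' Fold-change of mean AUC on the x axis (log2), significance on the y
#' axis; point size tracks the number of altered tumors, colour marks
#' records below `fdr_level`.
#'
#' @param records Output of [gene_drug_screen()] or [volcano_table()].
#' @param fdr_level Highlight threshold on `q`.
#' @param label_top Label the `label_top` most significant records.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, fdr_level = 0.1, label_top = 10) {
  df <- if ("neg_log10_p" %in% names(records)) records else volcano_table(records)
  df <- df |> mutate(hit = .data$q < fdr_level)
  lab <- df |> head(label_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fold_change, .data$neg_log10_p)) +
    ggplot2::geom_point(
      ggplot2::aes(size = .data$n_altered, colour = .data$hit),
      alpha = 0.7
    ) +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = paste0(.data$feature, " / ", .data$drug)),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#B2182B")) +
    ggplot2::labs(
      x = "log2 fold-change of mean AUC (altered / wild-type)",
      y = "-log10 p", size = "altered tumors",
      colour = paste0("q < ", fdr_level)
    ) +
    ggplot2::theme_minimal()
}
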