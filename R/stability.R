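#' Assemble the feature matrix for biomarker regression
#'
#' Combines transcriptome and genomic features into one samples x features
#' design: expression is log2(x + 1)-transformed then z-scored per gene
#' over the selected samples (columns named `expr_<gene>`); alteration
#' features become 0/1 indicators. An alteration feature with more than
#' `max_unknown` unknown status among the selected samples is dropped;
#' below that, unknowns are imputed as wild-type (0) and the imputed count
#' reported via a message. Constant columns are removed.
#'
#' @param expression Expression tibble (first column `gene`, one column
#'   per sample), or NULL.
#' @param alterations Long alteration tibble, or NULL.
#' @param samples Sample IDs to include; defaults to the samples present
#'   in both inputs (or in whichever is given).
#' @param max_unknown Maximum tolerated unknown fraction per alteration
#'   feature.
#'
#' @return Tibble with `sample_id` plus one numeric column per feature;
#'   the `provenance` attribute maps each feature to
#'   `"expression"`/`"mutation"`/`"cna"`.
#' @export
assemble_features <- function(expression = NULL, alterations = NULL,
                              samples = NULL, max_unknown = 0.2) {
  if (is.null(expression) && is.null(alterations)) {
    abort("need at least one of `expression`, `alterations`.")
  }
  expr_samples <- if (!is.null(expression)) names(expression)[-1] else NULL
  alt_samples <- if (!is.null(alterations)) unique(alterations$sample_id) else NULL
  if (is.null(samples)) {
    samples <- if (!is.null(expr_samples) && !is.null(alt_samples)) {
      intersect(expr_samples, alt_samples)
    } else {
      expr_samples %||% alt_samples
    }
  }
  samples <- sort(samples)
  if (length(samples) < 10) {
    abort("fewer than 10 samples with complete data; cohort too small.")
  }

  blocks <- list()
  provenance <- tibble(feature = character(), provenance = character())

  if (!is.null(expression)) {
    miss <- setdiff(samples, expr_samples)
    if (length(miss) > 0) {
      abort(paste0("samples absent from expression: ", paste(miss, collapse = ", ")))
    }
    genes <- expression[[1]]
    mat <- t(as.matrix(expression[, samples, drop = FALSE])) # samples x genes
    colnames(mat) <- paste0("expr_", genes)
    mat <- log2(mat + 1)
    keep <- apply(mat, 2, sd) > 0
    mat <- scale(mat[, keep, drop = FALSE])
    blocks$expr <- mat
    provenance <- bind_rows(provenance, tibble(
      feature = colnames(mat), provenance = "expression"
    ))
  }

  if (!is.null(alterations)) {
    alt <- alterations |> filter(.data$sample_id %in% samples)
    wide <- alt |>
      tidyr::pivot_wider(names_from = "feature", values_from = "status") |>
      arrange(.data$sample_id)
    if (!identical(wide$sample_id, samples)) {
      miss <- setdiff(samples, wide$sample_id)
      if (length(miss) > 0) {
        abort(paste0("samples absent from alterations: ", paste(miss, collapse = ", ")))
      }
    }
    feats <- setdiff(names(wide), "sample_id")
    n_imputed <- 0L
    cols <- list()
    for (f in feats) {
      st <- wide[[f]]
      unk <- mean(st == "unknown")
      if (unk > max_unknown) next
      n_imputed <- n_imputed + sum(st == "unknown")
      cols[[f]] <- as.numeric(st == "altered")
    }
    if (n_imputed > 0) {
      inform(paste0(n_imputed, " unknown alteration cell(s) imputed as wild-type."))
    }
    if (length(cols) > 0) {
      amat <- do.call(cbind, cols)
      rownames(amat) <- wide$sample_id
      amat <- amat[samples, , drop = FALSE]
      keep <- apply(amat, 2, sd) > 0
      amat <- amat[, keep, drop = FALSE]
      if (ncol(amat) > 0) {
        blocks$alt <- amat
        kind <- ifelse(
          grepl("-(amp|del)$", colnames(amat)), "cna", "mutation"
        )
        provenance <- bind_rows(provenance, tibble(
          feature = colnames(amat), provenance = kind
        ))
      }
    }
  }

  full <- do.call(cbind, blocks)
  out <- as_tibble(full) |> mutate(sample_id = samples, .before = 1)
  attr(out, "provenance") <- provenance
  out
}

#' Bootstrapped elastic-net stability selection for one drug
#'
#' Repeats an elastic-net regression of drug response (AUC) on the feature
#' matrix over `B` random subsamples of `fraction` of the tumors (drawn
#' without replacement, seeded and indexed per bootstrap so runs are
#' reproducible). In each subsample the penalty strength is chosen by
#' internal cross-validation; a feature "appears" when its coefficient is
#' nonzero at the selected penalty. The final assessment per feature is
#' its appearance count out of `B` and its average weight.
#'
#' @param features Feature tibble from [assemble_features()] (first column
#'   `sample_id`).
#' @param response Named numeric vector of per-sample response (AUC) for
#'   one drug, or an unnamed vector aligned to `features$sample_id`.
#' @param B Number of bootstraps (default 100).
#' @param fraction Subsample share of the tumors (default 0.8).
#' @param alpha Elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param seed Integer seed for the subsample and cross-validation streams.
#' @param lambda_rule `"lambda.min"` or `"lambda.1se"`.
#' @param weight_includes_zeros If TRUE, average coefficients over all `B`
#'   bootstraps (zeros included) instead of only those where the feature
#'   was selected.
#' @param drug Optional drug identifier carried into the result.
#'
#' @return A `stability_result` tibble: `drug`, `feature`, `provenance`,
#'   `appearance_count`, `mean_weight` (NA when never selected), sorted by
#'   [rank_features()] order; attributes record `B`, `fraction`, `alpha`
#'   and `lambda_rule`.
#' @export
bootstrap_elastic_net <- function(features, response, B = 100, fraction = 0.8,
                                  alpha = 0.5, seed = NULL,
                                  lambda_rule = c("lambda.min", "lambda.1se"),
                                  weight_includes_zeros = FALSE,
                                  drug = NA_character_) {
  lambda_rule <- match.arg(lambda_rule)
  if (B < 1) abort("`B` must be >= 1.")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  x <- as.matrix(features[-1])
  sample_ids <- features$sample_id
  if (!is.null(names(response))) {
    miss <- setdiff(sample_ids, names(response))
    if (length(miss) > 0) {
      abort(paste0("response missing for sample(s): ", paste(miss, collapse = ", ")))
    }
    y <- unname(response[sample_ids])
  } else {
    if (length(response) != nrow(x)) {
      abort("unnamed `response` must align with `features` rows.")
    }
    y <- response
  }
  keep <- is.finite(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  m <- floor(fraction * n)
  if (m < 3) abort("subsample size too small to fit.")
  seed <- seed %||% 1L

  p <- ncol(x)
  counts <- integer(p)
  weight_sum <- numeric(p)
  for (b in seq_len(B)) {
    set.seed(seed + b) # b-indexed stream: bootstrap b is reproducible alone
    idx <- sample.int(n, m)
    xb <- x[idx, , drop = FALSE]
    yb <- y[idx]
    if (sd(yb) == 0) next # constant response: nothing selectable
    cf <- tryCatch(
      {
        if (m >= 15) {
          cv <- glmnet::cv.glmnet(xb, yb, alpha = alpha, nfolds = 5)
          as.numeric(coef(cv, s = cv[[lambda_rule]]))[-1]
        } else {
          # too few samples for stable cross-validation: take a fixed point
          # one quarter of the way down the default lambda path
          fit <- glmnet::glmnet(xb, yb, alpha = alpha)
          s <- fit$lambda[max(1L, ceiling(length(fit$lambda) / 4))]
          inform("subsample too small for CV; using fixed lambda path point.")
          as.numeric(coef(fit, s = s))[-1]
        }
      },
      error = function(e) rep(0, p)
    )
    sel <- cf != 0
    counts <- counts + sel
    weight_sum <- weight_sum + if (weight_includes_zeros) cf else cf * sel
  }

  prov <- attr(features, "provenance")
  mean_weight <- ifelse(
    counts > 0,
    weight_sum / if (weight_includes_zeros) B else counts,
    NA_real_
  )
  out <- tibble(
    drug = drug, feature = colnames(x),
    appearance_count = as.integer(counts), mean_weight = mean_weight
  )
  if (!is.null(prov)) {
    out <- out |>
      left_join(prov, by = "feature") |>
      select("drug", "feature", "provenance", everything())
  }
  out <- rank_features(out)
  attr(out, "B") <- B
  attr(out, "fraction") <- fraction
  attr(out, "alpha") <- alpha
  attr(out, "lambda_rule") <- lambda_rule
  class(out) <- c("stability_result", class(out))
  out
}

#' Order stability-selection results into the biomarker ranking
#'
#' Deterministic sort: appearance count descending, then absolute mean
#' weight descending (NA last), then feature name.
#'
#' @param results Tibble from [bootstrap_elastic_net()].
#' @return The sorted tibble.
#' @export
rank_features <- function(results) {
  results |>
    arrange(
      desc(.data$appearance_count),
      desc(abs(coalesce(.data$mean_weight, 0))),
      .data$feature
    )
}

#' @export
tidy.stability_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.stability_result <- function(x, ...) {
  tibble(
    drug = x$drug[1],
    n_features = nrow(x),
    B = attr(x, "B"),
    fraction = attr(x, "fraction"),
    alpha = attr(x, "alpha"),
    lambda_rule = attr(x, "lambda_rule"),
    n_stable = sum(x$appearance_count >= 0.8 * attr(x, "B"))
  )
}

#' Pearson correlation between one gene's expression and drug response
#'
#' @param expression_gene Numeric expression values (one gene).
#' @param response Matched numeric response (AUC) values.
#' @return One-row tibble: `r`, `p` (t-distribution, n - 2 df), `n`.
#' @export
expression_drug_correlation <- function(expression_gene, response) {
  ok <- is.finite(expression_gene) & is.finite(response)
  x <- expression_gene[ok]
  y <- response[ok]
  if (length(x) < 3) abort("need >= 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in expression or response; correlation undefined.")
  }
  ht <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Bar chart of the top stability-selected biomarkers
#'
#' @param results A `stability_result` tibble.
#' @param top Number of features to show.
#' @return A ggplot object.
#' @export
plot_stability <- function(results, top = 15) {
  df <- head(rank_features(results), top) |>
    mutate(
      label = paste0(.data$feature, " (", .data$appearance_count, ")"),
      label = factor(.data$label, levels = rev(.data$label))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = coalesce(.data$mean_weight, 0), y = .data$label
  )) +
    ggplot2::geom_col(fill = "#2166AC") +
    ggplot2::labs(
      x = "average elastic-net weight", y = NULL,
      title = df$drug[1],
      subtitle = paste0("appearance count out of ", attr(results, "B"), " in parentheses")
    ) +
    ggplot2::theme_minimal()
}
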