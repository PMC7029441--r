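#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Rank-weighted ECDF-difference enrichment score of one gene set in one
#' sample. Genes are ranked by expression (mid-ranks for ties) and walked
#' in decreasing order; at each position the score accumulates the step-up
#' of the weighted in-set ECDF minus the step-up of the uniform out-of-set
#' ECDF. In-set weights are rank^alpha (highest expression = largest
#' rank), normalized to sum 1 over the set, so the sum form is
#' `ES = sum_i [P_in(i) - P_out(i)]`. The score depends on the expression
#' values only through their ranks.
#'
#' @param expr Named numeric vector of expression over the gene universe.
#' @param gene_set Character vector of member genes. Its intersection with
#'   the universe must be non-empty and a strict subset of it.
#' @param alpha Rank-weight exponent (canonical 0.25).
#' @param normalize If TRUE, divide the sum by (universe size - set size);
#'   FALSE (default) reports the raw sum form.
#'
#' @return A single numeric enrichment score.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, normalize = FALSE) {
  if (is.null(names(expr)) || anyDuplicated(names(expr))) {
    abort("`expr` must be a named vector with unique gene names.")
  }
  in_set <- names(expr) %in% gene_set
  m <- sum(in_set)
  n <- length(expr)
  if (m == 0) abort("gene set does not intersect the expression universe.")
  if (m == n) abort("gene set equals the expression universe; score undefined.")

  r <- rank(expr, ties.method = "average") # ascending mid-ranks, max = n
  ord <- order(-expr, names(expr)) # decreasing expression, names break ties
  in_ord <- in_set[ord]
  w <- r[ord]^alpha
  w[!in_ord] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (n - m)
  es <- sum(p_in - p_out)
  if (normalize) es <- es / (n - m)
  es
}

#' Score a gene-set collection across all samples
#'
#' Applies [ssgsea_score()] to every (sample, gene set) combination.
#' Degenerate sets (empty intersection with the universe, or covering it
#' entirely) are skipped with a warning. Scores are independent of gene
#' row order; optional per-set z-scoring standardizes each set's scores
#' across samples.
#'
#' @param expression Expression tibble: first column `gene`, one numeric
#'   column per sample (or a genes x samples matrix with rownames).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param alpha Rank-weight exponent.
#' @param normalize Passed to [ssgsea_score()].
#' @param z_score If TRUE, z-score each set's scores across samples.
#'
#' @return Long tibble: `sample_id`, `set`, `es`; the `z_scored` and
#'   `normalized` flags are recorded as attributes.
#' @export
score_matrix <- function(expression, gene_sets, alpha = 0.25,
                         normalize = FALSE, z_score = FALSE) {
  if (is.data.frame(expression)) {
    genes <- expression[[1]]
    mat <- as.matrix(expression[-1])
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(expression)
  }
  if (anyDuplicated(rownames(mat))) {
    abort("duplicate gene identifiers in the expression matrix.")
  }
  universe <- rownames(mat)
  usable <- purrr::keep(gene_sets, function(gs) {
    k <- length(intersect(gs, universe))
    k > 0 && k < length(universe)
  })
  skipped <- setdiff(names(gene_sets), names(usable))
  if (length(skipped) > 0) {
    warn(paste0(
      "skipping degenerate gene set(s): ", paste(skipped, collapse = ", ")
    ))
  }
  out <- purrr::imap(usable, function(gs, nm) {
    es <- vapply(
      colnames(mat),
      function(s) ssgsea_score(setNames(mat[, s], universe), gs,
        alpha = alpha, normalize = normalize
      ),
      numeric(1)
    )
    tibble(sample_id = colnames(mat), set = nm, es = unname(es))
  }) |>
    purrr::list_rbind()
  if (isTRUE(z_score) && nrow(out) > 0) {
    out <- out |>
      group_by(.data$set) |>
      mutate(es = as.numeric(scale(.data$es))) |>
      ungroup()
  }
  out <- arrange(out, .data$set, .data$sample_id)
  attr(out, "z_scored") <- isTRUE(z_score)
  attr(out, "normalized") <- isTRUE(normalize)
  attr(out, "alpha") <- alpha
  out
}
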