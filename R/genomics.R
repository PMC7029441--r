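#' Filter mutation calls on variant allele frequency and read depth
#'
#' Keeps calls with VAF strictly above `min_vaf` AND depth strictly above
#' `min_depth` (defaults: VAF > 5% and > 20 reads). Boundary records are
#' dropped. The filter is idempotent and preserves row order.
#'
#' @param mutations Tibble with at least `vaf` (fraction in \[0, 1\]) and
#'   `depth` (reads) columns.
#' @param min_vaf Minimum variant allele frequency, as a fraction.
#' @param min_depth Minimum read depth.
#'
#' @return The surviving rows, as a tibble.
#' @export
filter_mutations <- function(mutations, min_vaf = 0.05, min_depth = 20) {
  mutations <- as_tibble(mutations)
  if (nrow(mutations) > 0 &&
      (any(!is.finite(mutations$vaf)) || any(mutations$vaf < 0 | mutations$vaf > 1))) {
    abort("`vaf` must be a fraction in [0, 1].")
  }
  mutations |> filter(.data$vaf > min_vaf, .data$depth > min_depth)
}

#' Declare the alteration features to materialize
#'
#' Builds a feature specification from filtered mutations and CNA calls:
#' one gene-level mutation feature per mutated gene, one protein-change
#' feature per recurrent protein change (seen in >= `min_recurrent`
#' samples), and one CNA feature per (gene, call) seen.
#'
#' @param mutations Filtered mutation tibble.
#' @param cnas CNA tibble (`sample_id`, `gene`, `call`, `log2_ratio`).
#' @param min_recurrent Minimum carrier count for a protein-change feature.
#'
#' @return Tibble with `feature`, `kind` (`mut`/`protein`/`cna`), `gene`,
#'   `value` (protein change or CNA call; NA for gene-level).
#' @export
feature_spec <- function(mutations, cnas = NULL, min_recurrent = 2) {
  mutations <- as_tibble(mutations)
  genes <- mutations |>
    distinct(.data$gene) |>
    transmute(
      feature = .data$gene, kind = "mut", gene = .data$gene,
      value = NA_character_
    )
  prot <- mutations |>
    distinct(.data$sample_id, .data$gene, .data$protein_change) |>
    count(.data$gene, .data$protein_change) |>
    filter(.data$n >= min_recurrent, !is.na(.data$protein_change)) |>
    transmute(
      feature = paste0(.data$gene, "-", .data$protein_change),
      kind = "protein", gene = .data$gene, value = .data$protein_change
    )
  out <- bind_rows(genes, prot)
  if (!is.null(cnas) && nrow(cnas) > 0) {
    cna_feats <- as_tibble(cnas) |>
      filter(.data$call != "neutral") |>
      distinct(.data$gene, .data$call) |>
      transmute(
        feature = paste0(.data$gene, "-", .data$call),
        kind = "cna", gene = .data$gene, value = .data$call
      )
    out <- bind_rows(out, cna_feats)
  }
  arrange(out, .data$feature)
}

#' Build the samples x features alteration matrix
#'
#' Each cell is `"altered"`, `"wild-type"` or `"unknown"`. A sample is
#' altered for a feature when a surviving mutation (or matching CNA call)
#' hits it; wild-type when the sample was sequenced and carries no match;
#' unknown when the sample has no sequencing data — unknown-status samples
#' are excluded, never counted as wild-type.
#'
#' @param mutations Filtered mutation tibble (`sample_id`, `gene`,
#'   `protein_change`, ...).
#' @param cnas CNA tibble, or NULL.
#' @param samples Character vector of all cohort sample IDs (matrix rows).
#' @param sequenced Character vector of sample IDs with genomic data.
#' @param spec Feature specification from [feature_spec()], or NULL to
#'   derive it from the inputs.
#'
#' @return Long tibble: `sample_id`, `feature`, `status`.
#' @export
build_alteration_matrix <- function(mutations, cnas, samples, sequenced,
                                    spec = NULL) {
  mutations <- as_tibble(mutations)
  if (is.null(spec)) spec <- feature_spec(mutations, cnas)
  known_genes <- unique(c(mutations$gene, if (!is.null(cnas)) cnas$gene))
  orphan <- setdiff(spec$gene, known_genes)
  if (length(orphan) > 0) {
    warn(paste0(
      "feature_spec names gene(s) absent from the data: ",
      paste(orphan, collapse = ", "), " (columns will be all wild-type/unknown)."
    ))
  }

  hits <- purrr::pmap(spec, function(feature, kind, gene, value) {
    carriers <- switch(kind,
      mut = mutations$sample_id[mutations$gene == gene],
      protein = mutations$sample_id[
        mutations$gene == gene &
          !is.na(mutations$protein_change) & mutations$protein_change == value
      ],
      cna = if (is.null(cnas)) character(0) else {
        cnas$sample_id[cnas$gene == gene & cnas$call == value]
      },
      abort(paste0("unknown feature kind: ", kind))
    )
    tibble(feature = feature, sample_id = unique(carriers))
  }) |>
    purrr::list_rbind() |>
    mutate(altered = TRUE)

  tidyr::expand_grid(sample_id = samples, feature = spec$feature) |>
    left_join(hits, by = c("sample_id", "feature")) |>
    mutate(status = case_when(
      !is.na(.data$altered) & .data$sample_id %in% sequenced ~ "altered",
      .data$sample_id %in% sequenced ~ "wild-type",
      .default = "unknown"
    )) |>
    select("sample_id", "feature", "status") |>
    arrange(.data$sample_id, .data$feature)
}

#' Assign molecular subtypes (EBV / MSI / HCNA / LCNA)
#'
#' Rule-based decision tree mirroring TCGA-style gastric classification:
#' the EBV flag wins, then the MSI flag; remaining samples are split on
#' copy-number burden — the fraction of assayed genes with a non-neutral
#' CNA call — at `burden_threshold` into high-CNA (HCNA, chromosomal
#' instability) versus low-CNA (LCNA, genomically stable). Samples with no
#' CNA assay rows have zero burden and fall to LCNA; samples missing from
#' `metadata` are labelled `"unknown"` and excluded downstream.
#'
#' @param metadata Sample metadata tibble (`sample_id`, `subtype_flag` in
#'   `{"EBV","MSI","none"}`, ...).
#' @param cna_table CNA tibble (`sample_id`, `gene`, `call`), possibly
#'   missing some samples.
#' @param burden_threshold Non-neutral fraction at or above which a sample
#'   is HCNA.
#'
#' @return Tibble: `sample_id`, `subtype`, `cna_burden`.
#' @export
assign_subtype <- function(metadata, cna_table, burden_threshold = 0.2) {
  metadata <- as_tibble(metadata)
  burden <- as_tibble(cna_table) |>
    group_by(.data$sample_id) |>
    summarise(cna_burden = mean(.data$call != "neutral"), .groups = "drop")
  metadata |>
    left_join(burden, by = "sample_id") |>
    mutate(
      cna_burden = tidyr::replace_na(.data$cna_burden, 0),
      subtype = case_when(
        .data$subtype_flag == "EBV" ~ "EBV",
        .data$subtype_flag == "MSI" ~ "MSI",
        .data$cna_burden >= burden_threshold ~ "HCNA",
        .default = "LCNA"
      )
    ) |>
    select("sample_id", "subtype", "cna_burden")
}

#' Per-subtype mutation frequencies and ternary coordinates
#'
#' For each feature, the alteration frequency among known-status samples of
#' the EBV, LCNA and HCNA subtypes (unknown-status samples never enter a
#' denominator), plus the frequency triple normalized to sum 1 — the
#' coordinates of a ternary mutation-landscape diagram. Features altered in
#' none of the three subtypes are omitted from the ternary output.
#'
#' @param alterations Long alteration tibble from [build_alteration_matrix()].
#' @param subtypes Tibble `sample_id`, `subtype` from [assign_subtype()].
#'
#' @return Tibble: `feature`, `freq_EBV`, `freq_LCNA`, `freq_HCNA`,
#'   `n_altered`, `tern_EBV`, `tern_LCNA`, `tern_HCNA`.
#' @export
subtype_mutation_frequencies <- function(alterations, subtypes) {
  sub3 <- subtypes |> filter(.data$subtype %in% c("EBV", "LCNA", "HCNA"))
  if (n_distinct(sub3$subtype) < 1) {
    abort("need samples in at least one of the EBV/LCNA/HCNA subtypes.")
  }
  freqs <- alterations |>
    inner_join(sub3, by = "sample_id") |>
    filter(.data$status != "unknown") |>
    group_by(.data$feature, .data$subtype) |>
    summarise(
      freq = mean(.data$status == "altered"),
      n_alt = sum(.data$status == "altered"),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "subtype", values_from = c("freq", "n_alt"),
      values_fill = 0
    )
  for (s in c("EBV", "LCNA", "HCNA")) {
    fcol <- paste0("freq_", s)
    ncol_ <- paste0("n_alt_", s)
    if (!fcol %in% names(freqs)) freqs[[fcol]] <- 0
    if (!ncol_ %in% names(freqs)) freqs[[ncol_]] <- 0
  }
  freqs |>
    mutate(
      n_altered = .data$n_alt_EBV + .data$n_alt_LCNA + .data$n_alt_HCNA,
      total = .data$freq_EBV + .data$freq_LCNA + .data$freq_HCNA,
      tern_EBV = ifelse(.data$total > 0, .data$freq_EBV / .data$total, NA_real_),
      tern_LCNA = ifelse(.data$total > 0, .data$freq_LCNA / .data$total, NA_real_),
      tern_HCNA = ifelse(.data$total > 0, .data$freq_HCNA / .data$total, NA_real_)
    ) |>
    filter(.data$total > 0) |>
    select(
      "feature", "freq_EBV", "freq_LCNA", "freq_HCNA", "n_altered",
      "tern_EBV", "tern_LCNA", "tern_HCNA"
    ) |>
    arrange(.data$feature)
}

#' Shared and private mutations between tissue and matched PDC
#'
#' For each matched tissue/PDC pair, counts mutations (keyed by gene +
#' protein change, after filtering) found in both members, only in the
#' tissue, or only in the PDC — the concordance structure of a
#' tumor-versus-model comparison. Samples whose `pair_id` does not resolve
#' to exactly one tissue and one PDC member are skipped with a warning.
#'
#' @param mutations Filtered mutation tibble.
#' @param metadata Metadata tibble with `sample_id`, `origin`
#'   (`"tissue"`/`"pdc"`) and `pair_id`.
#'
#' @return Tibble: `pair_id`, `n_shared`, `n_tissue_private`,
#'   `n_pdc_private`.
#' @export
tissue_pdc_concordance <- function(mutations, metadata) {
  metadata <- as_tibble(metadata)
  paired <- metadata |> filter(!is.na(.data$pair_id), .data$pair_id != "")
  pair_ok <- paired |>
    group_by(.data$pair_id) |>
    summarise(
      ok = n() == 2 && setequal(.data$origin, c("tissue", "pdc")),
      .groups = "drop"
    )
  bad <- pair_ok$pair_id[!pair_ok$ok]
  if (length(bad) > 0) {
    warn(paste0(
      "skipping pair(s) without exactly one tissue and one PDC member: ",
      paste(bad, collapse = ", ")
    ))
  }
  good_pairs <- pair_ok$pair_id[pair_ok$ok]
  muts <- as_tibble(mutations) |>
    mutate(key = paste0(.data$gene, "|", .data$protein_change)) |>
    distinct(.data$sample_id, .data$key)

  purrr::map(good_pairs, function(pid) {
    members <- paired |> filter(.data$pair_id == pid)
    t_id <- members$sample_id[members$origin == "tissue"]
    p_id <- members$sample_id[members$origin == "pdc"]
    t_set <- muts$key[muts$sample_id == t_id]
    p_set <- muts$key[muts$sample_id == p_id]
    tibble(
      pair_id = pid,
      n_shared = length(intersect(t_set, p_set)),
      n_tissue_private = length(setdiff(t_set, p_set)),
      n_pdc_private = length(setdiff(p_set, t_set))
    )
  }) |>
    purrr::list_rbind() |>
    arrange(.data$pair_id)
}

#' Ternary scatter of per-subtype mutation frequencies
#'
#' Projects the (EBV, LCNA, HCNA) frequency triples of
#' [subtype_mutation_frequencies()] onto a two-dimensional ternary plane;
#' point size tracks the number of altered tumors.
#'
#' @param freqs Output of [subtype_mutation_frequencies()].
#' @param label_top Label the `label_top` most frequently altered features.
#' @return A ggplot object.
#' @export
plot_ternary_frequencies <- function(freqs, label_top = 8) {
  df <- freqs |>
    mutate(
      x = .data$tern_HCNA + .data$tern_EBV / 2,
      y = .data$tern_EBV * sqrt(3) / 2
    )
  lab <- df |> arrange(desc(.data$n_altered)) |> head(label_top)
  tri <- tibble(
    x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(data = tri, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_altered), alpha = 0.7) +
    ggplot2::geom_text(
      data = lab, ggplot2::aes(label = .data$feature),
      vjust = -1, size = 3
    ) +
    ggplot2::annotate("text",
      x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.05),
      label = c("LCNA", "HCNA", "EBV"), fontface = "bold"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(size = "altered tumors")
}
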