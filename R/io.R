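#' Run configuration for the analysis pipeline
#'
#' Houses every tunable threshold of the pipeline with the study defaults:
#' mutation filter VAF > 5% and depth > 20 reads, plate Z' >= 0.3,
#' association screens with per-arm minimum 3 and Benjamini-Hochberg FDR
#' 0.1, ssGSEA exponent 0.25, and 100 elastic-net bootstraps at an 80%
#' subsample with mixing parameter 0.5.
#'
#' @param min_vaf,min_depth Mutation filter thresholds (strict `>`).
#' @param min_z Plate Z'-factor QC threshold.
#' @param burden_threshold HCNA/LCNA copy-number burden boundary.
#' @param min_group Minimum per-arm group size in association screens.
#' @param fdr_method,fdr_level Multiple-testing adjustment and level.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param ssgsea_normalize Report normalized ssGSEA scores.
#' @param B,fraction Bootstrap count and subsample share.
#' @param enet_alpha Elastic-net mixing parameter.
#' @param lambda_rule `"lambda.min"` or `"lambda.1se"`.
#' @param dilution_top,dilution_fold,dilution_points Dilution series (uM).
#' @param seed Integer seed for the stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(min_vaf = 0.05, min_depth = 20, min_z = 0.3,
                       burden_threshold = 0.2, min_group = 3,
                       fdr_method = "BH", fdr_level = 0.1,
                       ssgsea_alpha = 0.25, ssgsea_normalize = FALSE,
                       B = 100, fraction = 0.8, enet_alpha = 0.5,
                       lambda_rule = "lambda.min",
                       dilution_top = 20, dilution_fold = 4, dilution_points = 7,
                       seed = 1L) {
  if (min_vaf <= 0 || min_depth <= 0 || min_z <= 0 || min_group <= 0 ||
      fdr_level <= 0 || ssgsea_alpha <= 0) {
    abort("all thresholds must be strictly positive.")
  }
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  if (B < 1) abort("`B` must be >= 1.")
  structure(
    list(
      min_vaf = min_vaf, min_depth = min_depth, min_z = min_z,
      burden_threshold = burden_threshold, min_group = min_group,
      fdr_method = fdr_method, fdr_level = fdr_level,
      ssgsea_alpha = ssgsea_alpha, ssgsea_normalize = ssgsea_normalize,
      B = B, fraction = fraction, enet_alpha = enet_alpha,
      lambda_rule = lambda_rule,
      dilution_top = dilution_top, dilution_fold = dilution_fold,
      dilution_points = dilution_points, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise an error; absent keys keep their defaults.
#'
#' @param path Path to a YAML file of [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s) in ", path, ": ", paste(bad, collapse = ", ")))
  }
  do.call(run_config, vals)
}

cohort_specs <- list(
  plates = list(
    file = "plates.tsv",
    cols = readr::cols(
      plate_id = readr::col_character(), well_row = readr::col_integer(),
      well_col = readr::col_integer(), sample_id = readr::col_character(),
      drug_id = readr::col_character(), conc_uM = readr::col_double(),
      role = readr::col_character(), signal = readr::col_double()
    )
  ),
  mutations = list(
    file = "mutations.tsv",
    cols = readr::cols(
      sample_id = readr::col_character(), gene = readr::col_character(),
      protein_change = readr::col_character(), vaf = readr::col_double(),
      depth = readr::col_integer()
    )
  ),
  cna = list(
    file = "cna.tsv",
    cols = readr::cols(
      sample_id = readr::col_character(), gene = readr::col_character(),
      call = readr::col_character(), log2_ratio = readr::col_double()
    )
  ),
  metadata = list(
    file = "metadata.tsv",
    cols = readr::cols(
      sample_id = readr::col_character(), subtype_flag = readr::col_character(),
      histology = readr::col_character(), her2 = readr::col_character(),
      origin = readr::col_character(), pair_id = readr::col_character()
    )
  )
)

read_cohort_table <- function(dir, spec_name) {
  spec <- cohort_specs[[spec_name]]
  path <- file.path(dir, spec$file)
  if (!file.exists(path)) abort(paste0("missing cohort file: ", path))
  expected <- names(spec$cols$cols)
  header <- names(readr::read_tsv(path,
    n_max = 0, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  missing_cols <- setdiff(expected, header)
  if (length(missing_cols) > 0) {
    abort(paste0(
      "malformed header in ", spec$file, ": missing column(s) ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  readr::read_tsv(path, col_types = spec$cols, progress = FALSE, show_col_types = FALSE)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(paste0("malformed GMT line (needs name, description, >=1 gene): ", substr(ln, 1, 40)))
    }
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' Write a GMT gene-set file
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- purrr::imap_chr(gene_sets, function(genes, nm) {
    paste(c(nm, nm, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a complete cohort directory
#'
#' Loads `plates.tsv`, `mutations.tsv`, `cna.tsv`, `expression.tsv`,
#' `metadata.tsv` and (if present) `genesets.gmt`, validates headers,
#' checks the expression matrix for duplicate genes, and cross-checks
#' sample identifiers: samples that appear in a data table but not in the
#' metadata raise a reconciliation error naming them.
#'
#' @param dir Cohort directory.
#' @return A cohort bundle list: `plates`, `mutations`, `cna`,
#'   `expression`, `metadata`, `gene_sets`.
#' @export
read_cohort <- function(dir) {
  bundle <- list(
    plates = read_cohort_table(dir, "plates"),
    mutations = read_cohort_table(dir, "mutations"),
    cna = read_cohort_table(dir, "cna"),
    metadata = read_cohort_table(dir, "metadata")
  )
  expr_path <- file.path(dir, "expression.tsv")
  if (!file.exists(expr_path)) abort(paste0("missing cohort file: ", expr_path))
  expression <- readr::read_tsv(expr_path,
    col_types = readr::cols(
      gene = readr::col_character(), .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (names(expression)[1] != "gene") {
    abort("malformed header in expression.tsv: first column must be `gene`.")
  }
  dup <- unique(expression$gene[duplicated(expression$gene)])
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate gene row(s) in expression.tsv: ", paste(dup, collapse = ", ")
    ))
  }
  bundle$expression <- expression

  gmt_path <- file.path(dir, "genesets.gmt")
  bundle$gene_sets <- if (file.exists(gmt_path)) read_gmt(gmt_path) else list()

  known <- bundle$metadata$sample_id
  for (tab in c("plates", "mutations", "cna")) {
    ids <- unique(bundle[[tab]]$sample_id)
    ids <- ids[!is.na(ids)]
    stray <- setdiff(ids, known)
    if (length(stray) > 0) {
      abort(paste0(
        "sample ID(s) in ", tab, " absent from metadata: ",
        paste(stray, collapse = ", ")
      ))
    }
  }
  stray_expr <- setdiff(names(bundle$expression)[-1], known)
  if (length(stray_expr) > 0) {
    abort(paste0(
      "sample ID(s) in expression absent from metadata: ",
      paste(stray_expr, collapse = ", ")
    ))
  }
  bundle
}

#' Write a cohort bundle to a directory
#'
#' Inverse of [read_cohort()]; output is deterministic (fixed column
#' order, stable row sort) so repeated writes are byte-identical.
#'
#' @param bundle Cohort bundle (e.g. `simulate_cohort(cfg)$bundle`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$plates, file.path(dir, "plates.tsv"), progress = FALSE)
  readr::write_tsv(bundle$mutations, file.path(dir, "mutations.tsv"), progress = FALSE)
  readr::write_tsv(bundle$cna, file.path(dir, "cna.tsv"), progress = FALSE)
  readr::write_tsv(bundle$expression, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  if (length(bundle$gene_sets) > 0) {
    write_gmt(bundle$gene_sets, file.path(dir, "genesets.gmt"))
  }
  invisible(dir)
}

#' Write result tables with a manifest
#'
#' Writes each named tibble as a TSV with deterministic column order and
#' row sort (rows are sorted by all character/factor key columns, left to
#' right), and returns a manifest of files and row counts.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory.
#' @return Tibble manifest: `file`, `rows`.
#' @export
write_results <- function(tables, dir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a fully named list.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::imap(tables, function(tab, nm) {
    tab <- as_tibble(tab)
    keys <- names(tab)[vapply(tab, function(c) is.character(c) || is.factor(c), logical(1))]
    if (length(keys) > 0) tab <- arrange(tab, across(all_of(keys)))
    path <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tab, path, progress = FALSE)
    tibble(file = paste0(nm, ".tsv"), rows = nrow(tab))
  }) |>
    purrr::list_rbind() |>
    arrange(.data$file)
  manifest
}

#' Run the full pharmacogenomic pipeline on a cohort
#'
#' Chains every stage: plate QC and AUC matrix, mutation filtering,
#' alteration matrix, subtype assignment, per-subtype mutation
#' frequencies, tissue/PDC concordance, the gene-drug and subtype-drug
#' association screens, ssGSEA pathway scores, and (optionally)
#' bootstrapped elastic-net stability selection for selected drugs.
#'
#' @param bundle Cohort bundle from [read_cohort()] or
#'   `simulate_cohort(cfg)$bundle`.
#' @param config A [run_config()].
#' @param stability_drugs Drug IDs to run stability selection on (NULL =
#'   skip this stage, the most expensive one).
#' @param outdir If non-NULL, all result tables are written there via
#'   [write_results()].
#'
#' @return Named list of result tibbles: `qc`, `auc`, `mutations_filtered`,
#'   `alterations`, `subtypes`, `ternary`, `concordance`, `associations`,
#'   `subtype_screen`, `ssgsea_scores`, `stability` (and `manifest` when
#'   written).
#' @export
run_pipeline <- function(bundle, config = run_config(),
                         stability_drugs = NULL, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  pdc_ids <- bundle$metadata$sample_id[bundle$metadata$origin == "pdc"]

  auc_res <- build_auc_matrix(bundle$plates, min_z = config$min_z)

  muts <- filter_mutations(bundle$mutations, config$min_vaf, config$min_depth)
  sequenced <- union(unique(bundle$mutations$sample_id), unique(bundle$cna$sample_id))
  alterations <- build_alteration_matrix(
    muts, bundle$cna,
    samples = pdc_ids, sequenced = sequenced
  )
  subtypes <- assign_subtype(
    bundle$metadata |> filter(.data$origin == "pdc"),
    bundle$cna,
    burden_threshold = config$burden_threshold
  )
  ternary <- subtype_mutation_frequencies(alterations, subtypes)
  concordance <- tissue_pdc_concordance(muts, bundle$metadata)

  associations <- gene_drug_screen(
    alterations, auc_res$auc,
    min_group = config$min_group, fdr_method = config$fdr_method
  )
  mol_labels <- subtypes |> transmute(.data$sample_id, group = .data$subtype)
  subtype_screen <- subtype_drug_screen(
    mol_labels, auc_res$auc,
    min_group = config$min_group,
    fdr_method = config$fdr_method, fdr_level = config$fdr_level
  )

  ssgsea_scores <- if (length(bundle$gene_sets) > 0 && ncol(bundle$expression) > 1) {
    score_matrix(bundle$expression, bundle$gene_sets,
      alpha = config$ssgsea_alpha, normalize = config$ssgsea_normalize
    )
  } else {
    tibble(sample_id = character(), set = character(), es = numeric())
  }

  stability <- NULL
  if (!is.null(stability_drugs)) {
    auc_ok <- auc_res$auc |> filter(.data$status == "ok")
    expr_ids <- names(bundle$expression)[-1]
    stability <- purrr::map(stability_drugs, function(d) {
      resp <- auc_ok |> filter(.data$drug_id == d)
      y <- setNames(resp$auc, resp$sample_id)
      common <- sort(Reduce(intersect, list(
        expr_ids, unique(alterations$sample_id), names(y)
      )))
      features <- assemble_features(bundle$expression, alterations, samples = common)
      bootstrap_elastic_net(
        features, y[common],
        B = config$B, fraction = config$fraction,
        alpha = config$enet_alpha, seed = config$seed,
        lambda_rule = config$lambda_rule, drug = d
      )
    }) |>
      purrr::list_rbind()
  }

  results <- list(
    qc = auc_res$qc,
    auc = auc_res$auc,
    mutations_filtered = muts,
    alterations = alterations,
    subtypes = subtypes,
    ternary = ternary,
    concordance = concordance,
    associations = associations,
    subtype_screen = subtype_screen,
    ssgsea_scores = ssgsea_scores
  )
  if (!is.null(stability)) results$stability <- stability
  if (!is.null(outdir)) {
    results$manifest <- write_results(
      results[!vapply(results, is.null, logical(1))], outdir
    )
  }
  results
}
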