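#' Declare a planted ground-truth effect for the simulator
#'
#' @param kind One of `"alteration_shift"` (carriers of an alteration get
#'   an additive AUC shift for one drug), `"subtype_shift"` (a sample
#'   class gets an AUC shift), `"expression_linear"` (one transcript is
#'   linearly predictive of one drug's AUC on the standardized scale) or
#'   `"pathway_shift"` (a gene set is up-regulated in a sample class).
#' @param feature Target of the effect: an alteration feature name
#'   (`"PIK3CA-E542K"`, `"TP53"`, `"KRAS-amp"`), a class spec
#'   (`"subtype:EBV"`, `"histology:diffuse"`, `"her2:pos"`,
#'   `"mutation:ALK"`) or, for `expression_linear`, a gene name.
#' @param drug Drug identifier (ignored for `pathway_shift`).
#' @param magnitude Effect size: additive AUC shift for the `_shift`
#'   kinds, standardized slope for `expression_linear`, per-gene shift in
#'   SD units of log2 expression for `pathway_shift`.
#' @param noise_sd Residual SD on the standardized response scale for
#'   `expression_linear`.
#' @param set Gene-set name for `pathway_shift`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(kind = c(
                             "alteration_shift", "subtype_shift",
                             "expression_linear", "pathway_shift"
                           ),
                           feature, drug = NA_character_, magnitude,
                           noise_sd = 0.7, set = NULL) {
  kind <- match.arg(kind)
  structure(
    list(
      kind = kind, feature = feature, drug = drug,
      magnitude = magnitude, noise_sd = noise_sd, set = set
    ),
    class = "planted_effect"
  )
}

# default per-subtype gene mutation probabilities, mirroring the familiar
# gastric landscape: TP53 enriched in high-CNA tumors, CDH1/NF1 in
# genomically stable (LCNA) tumors, PIK3CA/ARID1A in EBV-positive tumors
default_mutation_probs <- function() {
  tribble(
    ~gene,     ~EBV,  ~MSI,  ~HCNA, ~LCNA,
    "TP53",     0.20,  0.40,  0.70,  0.30,
    "CDH1",     0.10,  0.10,  0.08,  0.35,
    "PIK3CA",   0.50,  0.35,  0.10,  0.10,
    "ARID1A",   0.45,  0.35,  0.10,  0.12,
    "APC",      0.08,  0.20,  0.10,  0.10,
    "NF1",      0.05,  0.10,  0.05,  0.20,
    "KRAS",     0.08,  0.15,  0.10,  0.08,
    "ERBB2",    0.05,  0.10,  0.12,  0.05,
    "ERBB3",    0.08,  0.12,  0.08,  0.05,
    "FGFR2",    0.04,  0.06,  0.08,  0.06,
    "ALK",      0.08,  0.08,  0.08,  0.08,
    "BRCA2",    0.05,  0.10,  0.15,  0.05,
    "MLH1",     0.04,  0.25,  0.03,  0.03,
    "SMAD4",    0.06,  0.10,  0.12,  0.08,
    "RHOA",     0.04,  0.05,  0.04,  0.12,
    "CTNNB1",   0.06,  0.08,  0.05,  0.06,
    "PTEN",     0.10,  0.15,  0.08,  0.06,
    "EGFR",     0.05,  0.06,  0.08,  0.04,
    "MET",      0.04,  0.05,  0.06,  0.04,
    "FBXW7",    0.05,  0.12,  0.08,  0.05
  )
}

default_hotspots <- function() {
  list(
    PIK3CA = c(E542K = 0.5, H1047R = 0.3, E545K = 0.2),
    KRAS = c(G12D = 0.6, G12V = 0.4),
    TP53 = c(R175H = 0.3, R273C = 0.2),
    RHOA = c(Y42C = 0.6)
  )
}

#' Build a simulation configuration
#'
#' All arguments have cohort-realistic defaults; [full_scale_preset()]
#' returns the full-scale configuration (131 samples, 60 drugs, 41
#' expression-profiled samples, 7-point fourfold dilutions from 20 uM).
#'
#' @param n_samples Number of PDC samples.
#' @param n_expression Number of samples with expression profiles.
#' @param subtype_mix Named mixture over EBV/MSI/HCNA/LCNA (sums to 1).
#' @param mutation_probs Tibble `gene` x subtype columns of per-subtype
#'   mutation probabilities.
#' @param hotspots Named list of per-gene hotspot protein-change
#'   probability vectors.
#' @param n_cna_genes Number of genes on the CNA panel.
#' @param cna_rates Named vector `c(HCNA=, other=)`: per-gene non-neutral
#'   call probability by CNA class.
#' @param n_expr_genes Number of background expression genes.
#' @param drugs Character vector of drug identifiers.
#' @param auc_mean_range Range of per-drug mean noiseless AUC.
#' @param auc_sd Between-sample SD of noiseless AUC within a drug.
#' @param top_sd,bottom_max,hill_range 4PL parameter draws: SD of the top
#'   plateau around 1, maximal bottom plateau, Hill slope range.
#' @param dilution List `top` (uM), `fold`, `n_points`.
#' @param noise_sd Plate noise SD on the viability scale.
#' @param unsequenced_fraction Share of samples without genomic data
#'   (status unknown for every alteration).
#' @param pair_fraction Share of PDCs given a matched tissue specimen.
#' @param pair_retention Probability a tissue mutation is retained in the
#'   matched PDC-vs-tissue comparison.
#' @param pair_private_rate Per-gene probability of a tissue-private
#'   mutation.
#' @param n_gene_sets Number of random background gene sets.
#' @param planted List of [planted_effect()]s.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 131,
                       n_expression = 41,
                       subtype_mix = c(EBV = 0.09, MSI = 0.20, HCNA = 0.45, LCNA = 0.26),
                       mutation_probs = default_mutation_probs(),
                       hotspots = default_hotspots(),
                       n_cna_genes = 30,
                       cna_rates = c(HCNA = 0.35, other = 0.05),
                       n_expr_genes = 200,
                       drugs = sprintf("drug%02d", 1:60),
                       auc_mean_range = c(0.4, 0.9),
                       auc_sd = 0.12,
                       top_sd = 0.02,
                       bottom_max = 0.4,
                       hill_range = c(0.7, 2),
                       dilution = list(top = 20, fold = 4, n_points = 7),
                       noise_sd = 0.05,
                       unsequenced_fraction = 0.2,
                       pair_fraction = 0.15,
                       pair_retention = 0.8,
                       pair_private_rate = 0.05,
                       n_gene_sets = 4,
                       planted = list(),
                       seed = 1L) {
  stopifnot(abs(sum(subtype_mix) - 1) < 1e-8)
  probs <- as.matrix(mutation_probs[-1])
  if (any(probs < 0 | probs > 1)) abort("mutation probabilities must lie in [0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (unsequenced_fraction < 0 || unsequenced_fraction >= 1) {
    abort("`unsequenced_fraction` must be in [0, 1).")
  }
  cfg <- list(
    n_samples = n_samples, n_expression = n_expression,
    subtype_mix = subtype_mix, mutation_probs = mutation_probs,
    hotspots = hotspots, n_cna_genes = n_cna_genes, cna_rates = cna_rates,
    n_expr_genes = n_expr_genes, drugs = drugs,
    auc_mean_range = auc_mean_range, auc_sd = auc_sd,
    top_sd = top_sd, bottom_max = bottom_max, hill_range = hill_range,
    dilution = dilution, noise_sd = noise_sd,
    unsequenced_fraction = unsequenced_fraction,
    pair_fraction = pair_fraction, pair_retention = pair_retention,
    pair_private_rate = pair_private_rate, n_gene_sets = n_gene_sets,
    planted = planted, seed = as.integer(seed)
  )
  for (pe in planted) {
    if (!inherits(pe, "planted_effect")) abort("`planted` must hold planted_effect objects.")
    if (pe$kind != "pathway_shift" && !is.na(pe$drug) && !pe$drug %in% drugs) {
      abort(paste0("planted effect references unknown drug: ", pe$drug))
    }
  }
  structure(cfg, class = "sim_config")
}

#' The full-scale cohort preset
#'
#' A configuration mirroring the study conditions: 131 tumor samples, 41
#' of them expression-profiled, a 60-drug panel screened in a seven-point
#' fourfold dilution series from 20 uM down to 4.88 nM, subtype-skewed
#' TP53/CDH1/PIK3CA mutation frequencies, one planted linearly-predictive
#' transcript (RNF11) and one planted alteration sensitivity
#' (PIK3CA-E542K).
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
full_scale_preset <- function(seed = 1L) {
  sim_config(
    n_samples = 131, n_expression = 41,
    drugs = sprintf("drug%02d", 1:60),
    dilution = list(top = 20, fold = 4, n_points = 7),
    planted = list(
      planted_effect("expression_linear",
        feature = "RNF11", drug = "drug07",
        magnitude = 0.7, noise_sd = 0.7
      ),
      planted_effect("alteration_shift",
        feature = "PIK3CA-E542K", drug = "drug03", magnitude = -0.2
      )
    ),
    seed = seed
  )
}

# resolve the carrier sample set of a class/alteration spec against truth
resolve_group <- function(feature, truth_samples, truth_mutations, truth_cna) {
  if (grepl(":", feature, fixed = TRUE)) {
    parts <- strsplit(feature, ":", fixed = TRUE)[[1]]
    key <- parts[1]
    val <- parts[2]
    return(switch(key,
      subtype = truth_samples$sample_id[truth_samples$subtype == val],
      histology = truth_samples$sample_id[truth_samples$histology == val],
      her2 = truth_samples$sample_id[truth_samples$her2 == val],
      mutation = unique(truth_mutations$sample_id[truth_mutations$gene == val]),
      abort(paste0("unknown class spec: ", feature))
    ))
  }
  if (grepl("-(amp|del)$", feature)) {
    gene <- sub("-(amp|del)$", "", feature)
    call <- sub("^.*-", "", feature)
    return(unique(truth_cna$sample_id[truth_cna$gene == gene & truth_cna$call == call]))
  }
  if (grepl("-", feature, fixed = TRUE)) {
    gene <- sub("-.*$", "", feature)
    pc <- sub("^[^-]*-", "", feature)
    return(unique(truth_mutations$sample_id[
      truth_mutations$gene == gene & truth_mutations$protein_change == pc
    ]))
  }
  unique(truth_mutations$sample_id[truth_mutations$gene == feature])
}

# invert the window-normalized AUC for log10_ic50 given the other 4PL
# parameters; the AUC is strictly increasing in log10_ic50
solve_log10_ic50 <- function(target, top, bottom, hill, lmin, lmax) {
  target <- min(max(target, bottom + 0.01), top - 0.01)
  f <- function(l) {
    auc_fourpl(list(top = top, bottom = bottom, log10_ic50 = l, hill = hill), lmin, lmax) - target
  }
  stats::uniroot(f, c(lmin - 8, lmax + 8), tol = 1e-8)$root
}

random_protein_change <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "L", "K", "S", "T", "V", "Y")
  paste0(
    sample(aa, n, replace = TRUE),
    sample(30:900, n, replace = TRUE),
    sample(aa, n, replace = TRUE)
  )
}

# draw one mutation record set for a sample given its subtype
draw_mutations <- function(sample_id, subtype, cfg) {
  probs <- cfg$mutation_probs[[subtype]]
  genes <- cfg$mutation_probs$gene
  hit <- runif(length(genes)) < probs
  if (!any(hit)) {
    return(NULL)
  }
  g <- genes[hit]
  pc <- vapply(g, function(gene) {
    hs <- cfg$hotspots[[gene]]
    if (!is.null(hs) && runif(1) < sum(hs)) {
      sample(names(hs), 1, prob = hs)
    } else {
      paste0("p.", random_protein_change(1))
    }
  }, character(1))
  n <- length(g)
  # most calls clear the VAF > 5% / depth > 20 filter; a minority fall below
  vaf <- ifelse(runif(n) < 0.12, runif(n, 0.005, 0.05), 0.05 + rbeta(n, 2, 4) * 0.85)
  depth <- ifelse(runif(n) < 0.08, sample(5:20, n, replace = TRUE),
    21 + rpois(n, 90)
  )
  tibble(
    sample_id = sample_id, gene = g, protein_change = unname(pc),
    vaf = round(vaf, 4), depth = as.integer(depth)
  )
}

#' Simulate a complete synthetic PDC cohort with known ground truth
#'
#' Draws molecular subtypes from the configured mixture, per-(gene,
#' subtype) Bernoulli mutations with VAF/depth marks, a gene-level CNA
#' panel whose burden separates HCNA from LCNA samples, a log-normal
#' expression matrix for the profiled subset, per-(sample, drug) noiseless
#' AUC values with all planted effects applied, 4PL parameters solved to
#' reproduce those AUCs exactly, matched tissue/PDC pairs, and finally raw
#' screening plates via [simulate_plates()]. A held-out fraction of
#' samples is left unsequenced so unknown-status handling is exercised.
#'
#' @param cfg A [sim_config()].
#' @return A list with `bundle` (plates, mutations, cna, expression,
#'   metadata, gene_sets — the on-disk cohort) and `truth` (realized
#'   subtypes, mutation/CNA carriers, per-cell 4PL parameters and
#'   noiseless AUC, planted-effect manifest).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  ids <- sprintf("S%03d", seq_len(n))

  subtype <- sample(names(cfg$subtype_mix), n, replace = TRUE, prob = cfg$subtype_mix)
  histology <- sample(c("diffuse", "intestinal", "mixed"), n,
    replace = TRUE, prob = c(0.35, 0.45, 0.20)
  )
  her2 <- ifelse(
    runif(n) < ifelse(subtype == "HCNA", 0.25, 0.05), "pos",
    ifelse(runif(n) < 0.05, "unknown", "neg")
  )
  sequenced <- runif(n) >= cfg$unsequenced_fraction
  expr_ids <- sort(sample(ids, min(cfg$n_expression, n)))

  truth_samples <- tibble(
    sample_id = ids, subtype = subtype, histology = histology, her2 = her2,
    sequenced = sequenced, expression_profiled = ids %in% expr_ids
  )

  # --- mutations (drawn for every sample; unsequenced are masked on output)
  truth_mutations <- purrr::map2(ids, subtype, draw_mutations, cfg = cfg) |>
    purrr::list_rbind()

  # --- CNA panel
  cna_genes <- sprintf("CNAG%02d", seq_len(cfg$n_cna_genes))
  rate <- ifelse(subtype == "HCNA", cfg$cna_rates[["HCNA"]], cfg$cna_rates[["other"]])
  truth_cna <- purrr::map(seq_len(n), function(i) {
    nonneutral <- runif(cfg$n_cna_genes) < rate[i]
    call <- ifelse(nonneutral, sample(c("amp", "del"), cfg$n_cna_genes, replace = TRUE), "neutral")
    tibble(
      sample_id = ids[i], gene = cna_genes, call = call,
      log2_ratio = round(ifelse(call == "amp", rnorm(cfg$n_cna_genes, 1, 0.3),
        ifelse(call == "del", rnorm(cfg$n_cna_genes, -1, 0.3),
          rnorm(cfg$n_cna_genes, 0, 0.1)
        )
      ), 3)
    )
  }) |>
    purrr::list_rbind()

  # --- expression (log-normal per gene), planted genes appended to universe
  planted_genes <- unique(unlist(lapply(cfg$planted, function(pe) {
    if (pe$kind == "expression_linear") pe$feature else NULL
  })))
  genes <- unique(c(sprintf("EXPR%04d", seq_len(cfg$n_expr_genes)), planted_genes))
  mu <- runif(length(genes), 2, 8)
  sdv <- runif(length(genes), 0.4, 1.2)
  log2_expr <- matrix(rnorm(length(genes) * length(expr_ids), mu, sdv),
    nrow = length(genes),
    dimnames = list(genes, expr_ids)
  )

  # --- gene sets: one per configured pathway_shift effect, plus random sets
  gene_sets <- list()
  for (pe in cfg$planted) {
    if (pe$kind == "pathway_shift") {
      nm <- pe$set %||% "PLANTED_SET"
      gene_sets[[nm]] <- sort(sample(genes, min(20, length(genes) - 1)))
      members <- gene_sets[[nm]]
      grp <- resolve_group(pe$feature, truth_samples, truth_mutations, truth_cna)
      grp <- intersect(grp, expr_ids)
      log2_expr[members, grp] <- log2_expr[members, grp] +
        pe$magnitude * sdv[match(members, genes)]
    }
  }
  for (k in seq_len(cfg$n_gene_sets)) {
    size <- min(sample(15:25, 1), length(genes) - 1)
    gene_sets[[sprintf("SET%02d", k)]] <- sort(sample(genes, size))
  }
  expression <- as_tibble(round(2^log2_expr, 4)) |>
    mutate(gene = genes, .before = 1)

  # --- noiseless drug response with planted effects
  n_drugs <- length(cfg$drugs)
  drug_mean <- runif(n_drugs, cfg$auc_mean_range[1], cfg$auc_mean_range[2])
  names(drug_mean) <- cfg$drugs
  for (pe in cfg$planted) {
    if (pe$kind %in% c("alteration_shift", "subtype_shift")) {
      if (drug_mean[[pe$drug]] + pe$magnitude < 0 ||
          drug_mean[[pe$drug]] + pe$magnitude > 1) {
        abort(paste0(
          "planted magnitude ", pe$magnitude, " on ", pe$drug,
          " pushes mean AUC outside [0, 1]; infeasible configuration."
        ))
      }
    }
  }

  eps <- matrix(rnorm(n * n_drugs), n, n_drugs, dimnames = list(ids, cfg$drugs))
  auc0 <- sweep(eps * cfg$auc_sd, 2, drug_mean, `+`)
  for (pe in cfg$planted) {
    if (pe$kind == "alteration_shift" || pe$kind == "subtype_shift") {
      grp <- resolve_group(pe$feature, truth_samples, truth_mutations, truth_cna)
      auc0[intersect(grp, ids), pe$drug] <- auc0[intersect(grp, ids), pe$drug] + pe$magnitude
    }
    if (pe$kind == "expression_linear") {
      z <- as.numeric(scale(log2_expr[pe$feature, ]))
      auc0[expr_ids, pe$drug] <- drug_mean[[pe$drug]] +
        cfg$auc_sd * (pe$magnitude * z + pe$noise_sd * rnorm(length(expr_ids)))
    }
  }
  auc0 <- pmin(pmax(auc0, 0.02), 0.98) # viability saturation

  # --- 4PL parameters reproducing each noiseless AUC
  series <- make_dilution_series(cfg$dilution$top, cfg$dilution$fold, cfg$dilution$n_points)
  lmin <- log10(min(series))
  lmax <- log10(max(series))
  cells <- tidyr::expand_grid(sample_id = ids, drug_id = cfg$drugs)
  top <- pmin(pmax(rnorm(nrow(cells), 1, cfg$top_sd), 0.92), 1.1)
  hill <- runif(nrow(cells), cfg$hill_range[1], cfg$hill_range[2])
  target <- auc0[cbind(cells$sample_id, cells$drug_id)]
  bottom <- runif(nrow(cells), 0, pmin(cfg$bottom_max, pmax(0.01, target - 0.05)))
  lic50 <- vapply(seq_len(nrow(cells)), function(i) {
    solve_log10_ic50(target[i], top[i], bottom[i], hill[i], lmin, lmax)
  }, numeric(1))
  truth_fourpl <- cells |>
    mutate(
      top = top, bottom = bottom, hill = hill, log10_ic50 = lic50,
      auc_noiseless = vapply(seq_len(nrow(cells)), function(i) {
        auc_fourpl(
          list(top = top[i], bottom = bottom[i], log10_ic50 = lic50[i], hill = hill[i]),
          lmin, lmax
        )
      }, numeric(1))
    )

  # --- matched tissue specimens for a subset of PDCs
  n_pairs <- floor(cfg$pair_fraction * n)
  pair_pdc <- sort(sample(ids[sequenced], min(n_pairs, sum(sequenced))))
  tissue_rows <- NULL
  tissue_muts <- NULL
  if (length(pair_pdc) > 0) {
    pair_id <- sprintf("pair%03d", seq_along(pair_pdc))
    tissue_id <- paste0(pair_pdc, "T")
    tissue_rows <- tibble(
      sample_id = tissue_id,
      subtype_flag = ifelse(subtype[match(pair_pdc, ids)] %in% c("EBV", "MSI"),
        subtype[match(pair_pdc, ids)], "none"
      ),
      histology = histology[match(pair_pdc, ids)],
      her2 = her2[match(pair_pdc, ids)],
      origin = "tissue", pair_id = pair_id
    )
    tissue_muts <- purrr::map(seq_along(pair_pdc), function(i) {
      pdc_m <- truth_mutations |> filter(.data$sample_id == pair_pdc[i])
      kept <- pdc_m[runif(nrow(pdc_m)) < cfg$pair_retention, ]
      extra_genes <- setdiff(cfg$mutation_probs$gene, pdc_m$gene)
      extra_hit <- extra_genes[runif(length(extra_genes)) < cfg$pair_private_rate]
      extra <- if (length(extra_hit) > 0) {
        tibble(
          sample_id = pair_pdc[i], gene = extra_hit,
          protein_change = paste0("p.", random_protein_change(length(extra_hit))),
          vaf = round(0.05 + rbeta(length(extra_hit), 2, 4) * 0.85, 4),
          depth = as.integer(21 + rpois(length(extra_hit), 90))
        )
      } else {
        NULL
      }
      bind_rows(kept, extra) |> mutate(sample_id = tissue_id[i])
    }) |>
      purrr::list_rbind()
  }

  pdc_meta <- tibble(
    sample_id = ids,
    subtype_flag = ifelse(subtype %in% c("EBV", "MSI"), subtype, "none"),
    histology = histology, her2 = her2, origin = "pdc",
    pair_id = NA_character_
  )
  if (!is.null(tissue_rows)) {
    pdc_meta$pair_id[match(pair_pdc, pdc_meta$sample_id)] <- tissue_rows$pair_id
  }
  metadata <- bind_rows(pdc_meta, tissue_rows)

  mutations_out <- bind_rows(
    truth_mutations |> filter(.data$sample_id %in% ids[sequenced]),
    tissue_muts
  ) |>
    arrange(.data$sample_id, .data$gene, .data$protein_change)
  cna_out <- truth_cna |>
    filter(.data$sample_id %in% ids[sequenced]) |>
    arrange(.data$sample_id, .data$gene)

  truth <- list(
    samples = truth_samples,
    mutations = truth_mutations,
    cna = truth_cna,
    fourpl = truth_fourpl,
    drug_mean = tibble(drug_id = cfg$drugs, mean_auc = unname(drug_mean)),
    planted = purrr::map(cfg$planted, function(pe) {
      tibble(
        kind = pe$kind, feature = pe$feature, drug = pe$drug,
        magnitude = pe$magnitude
      )
    }) |> purrr::list_rbind(),
    dilution = cfg$dilution,
    seed = cfg$seed
  )

  plates <- simulate_plates(truth, cfg$noise_sd, series, seed = cfg$seed + 500000L)

  list(
    bundle = list(
      plates = plates,
      mutations = mutations_out,
      cna = cna_out,
      expression = expression,
      metadata = metadata,
      gene_sets = gene_sets
    ),
    truth = truth
  )
}

#' Synthesize raw screening plates from ground-truth dose-response curves
#'
#' One plate per sample: duplicate treated wells at every (drug,
#' concentration) with viability = 4PL(conc) + Gaussian noise, 16 DMSO
#' vehicle wells and 16 positive-control (killed) wells, all converted to
#' raw luminescence through a per-plate DMSO scale factor so the Z'-factor
#' is computable per plate.
#'
#' @param truth Ground-truth list from [simulate_cohort()] (needs
#'   `$fourpl`).
#' @param noise_sd Viability-scale noise SD of treated wells.
#' @param series Concentration series (uM).
#' @param seed Integer seed.
#' @param n_replicates Treated replicate wells per concentration.
#' @return Stacked plate-well tibble in the `plates.tsv` schema.
#' @export
simulate_plates <- function(truth, noise_sd, series, seed = 1L, n_replicates = 2L) {
  set.seed(seed)
  concs <- as.numeric(series)
  fp <- truth$fourpl
  purrr::map(split(fp, fp$sample_id), function(df) {
    sid <- df$sample_id[1]
    scale_f <- 10000 * runif(1, 0.9, 1.1)
    grid <- tidyr::expand_grid(
      drug_id = df$drug_id, conc_uM = concs, replicate = seq_len(n_replicates)
    ) |>
      left_join(df, by = "drug_id")
    v <- fourpl_value(log10(grid$conc_uM), grid$top, grid$bottom, grid$log10_ic50, grid$hill) +
      rnorm(nrow(grid), 0, noise_sd)
    treated <- tibble(
      plate_id = paste0("P_", sid),
      sample_id = sid, drug_id = grid$drug_id, conc_uM = grid$conc_uM,
      role = "treat", signal = round(v * scale_f, 2)
    )
    controls <- tibble(
      plate_id = paste0("P_", sid), sample_id = sid,
      drug_id = NA_character_, conc_uM = NA_real_,
      role = rep(c("dmso", "positive"), each = 16),
      signal = round(c(
        (1 + rnorm(16, 0, noise_sd)) * scale_f,
        pmax(0.002 + rnorm(16, 0, noise_sd / 25), 0) * scale_f
      ), 2)
    )
    out <- bind_rows(treated, controls)
    out |>
      mutate(
        well_row = (row_number() - 1L) %/% 24L + 1L,
        well_col = (row_number() - 1L) %% 24L + 1L
      ) |>
      select(
        "plate_id", "well_row", "well_col", "sample_id", "drug_id",
        "conc_uM", "role", "signal"
      )
  }) |>
    purrr::list_rbind() |>
    arrange(.data$plate_id, .data$well_row, .data$well_col)
}
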