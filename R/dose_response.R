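#' Build a serial dilution series
#'
#' Generates the descending geometric concentration series used on a
#' screening plate, e.g. the classic seven-point fourfold series from
#' 20 uM down to 4.88 nM.
#'
#' @param top Highest concentration, in uM. Must be finite and positive.
#' @param fold Dilution factor between consecutive points (> 1).
#' @param n_points Number of concentrations (>= 1).
#'
#' @return A numeric vector of descending concentrations in uM, of class
#'   `dilution_series`, with `top`, `fold` and `n_points` attributes.
#'
#' @examples
#' s <- make_dilution_series(20, 4, 7)
#' min(s) * 1000  # 4.88 nM
#' @export
make_dilution_series <- function(top, fold, n_points) {
  if (!is.numeric(top) || length(top) != 1L || !is.finite(top) || top <= 0) {
    abort("`top` must be a single positive finite concentration (uM).")
  }
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold <= 1) {
    abort("`fold` must be a single finite dilution factor > 1.")
  }
  if (!is.numeric(n_points) || length(n_points) != 1L || !is.finite(n_points) ||
      n_points < 1 || n_points != round(n_points)) {
    abort("`n_points` must be a single integer >= 1.")
  }
  values <- top / fold^(seq_len(n_points) - 1)
  structure(values,
    top = top, fold = fold, n_points = as.integer(n_points),
    class = c("dilution_series", "numeric")
  )
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf(
    "<dilution_series> %d points, %.4g-fold, %.4g uM down to %.4g uM\n",
    attr(x, "n_points"), attr(x, "fold"), max(x), min(x)
  ))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Normalize a plate to its DMSO vehicle controls
#'
#' Relative viability is computed per plate as raw signal divided by the
#' mean signal of that plate's DMSO wells, so the DMSO wells themselves
#' average exactly 1.
#'
#' @param plate A plate-well data frame with at least `plate_id`, `role`
#'   (`"treat"`, `"dmso"` or `"positive"`) and `signal` columns. Several
#'   plates may be stacked; normalization is always per `plate_id`.
#'
#' @return The input as a tibble with an added `viability` column.
#' @export
normalize_plate <- function(plate) {
  plate <- as_tibble(plate)
  required <- c("plate_id", "role", "signal")
  missing_cols <- setdiff(required, names(plate))
  if (length(missing_cols) > 0) {
    abort(paste0("plate table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dmso_stats <- plate |>
    filter(.data$role == "dmso") |>
    group_by(.data$plate_id) |>
    summarise(n_dmso = n(), dmso_mean = mean(.data$signal), .groups = "drop")
  bad <- setdiff(unique(plate$plate_id), dmso_stats$plate_id)
  if (length(bad) > 0) {
    abort(paste0("no DMSO control wells on plate(s): ", paste(bad, collapse = ", ")))
  }
  if (any(dmso_stats$n_dmso < 2)) {
    abort(paste0(
      "fewer than 2 DMSO wells on plate(s): ",
      paste(dmso_stats$plate_id[dmso_stats$n_dmso < 2], collapse = ", ")
    ))
  }
  if (any(dmso_stats$dmso_mean <= 0)) {
    abort(paste0(
      "degenerate DMSO controls (mean signal <= 0) on plate(s): ",
      paste(dmso_stats$plate_id[dmso_stats$dmso_mean <= 0], collapse = ", ")
    ))
  }
  plate |>
    left_join(dmso_stats, by = "plate_id") |>
    mutate(viability = .data$signal / .data$dmso_mean) |>
    select(-"n_dmso", -"dmso_mean")
}

#' Z'-factor plate quality statistic
#'
#' Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|, comparing the
#' positive (killed) and negative (DMSO vehicle) control wells of a plate.
#' Z' is at most 1; a well-separated assay scores above ~0.5.
#'
#' @param pos_signals Raw signals of the positive-control wells (>= 2).
#' @param neg_signals Raw signals of the negative-control wells (>= 2).
#' @param threshold Minimum Z' for the plate to pass QC.
#' @param plate_id Optional plate identifier carried into the report.
#'
#' @return A one-row tibble: `plate_id`, `z_factor`, `pass`.
#' @export
z_factor <- function(pos_signals, neg_signals, threshold = 0.3, plate_id = NA_character_) {
  if (length(pos_signals) < 2 || length(neg_signals) < 2) {
    abort("need >= 2 wells in each control group to compute Z'.")
  }
  mu_p <- mean(pos_signals)
  mu_n <- mean(neg_signals)
  if (isTRUE(all.equal(mu_p, mu_n)) || mu_p == mu_n) {
    abort("positive and negative control means coincide; Z' separation undefined.")
  }
  z <- 1 - 3 * (sd(pos_signals) + sd(neg_signals)) / abs(mu_p - mu_n)
  tibble(plate_id = plate_id, z_factor = z, pass = z >= threshold)
}

# 4PL viability at log10 concentration l, decreasing orientation for hill > 0
fourpl_value <- function(l, top, bottom, log10_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (l - log10_ic50)))
}

#' Construct a four-parameter logistic dose-response object
#'
#' The model is `v(c) = bottom + (top - bottom) / (1 + 10^(hill * (log10(c)
#' - log10_ic50)))`: viability decreases with dose when `hill > 0`.
#'
#' @param top,bottom Upper and lower viability plateaus.
#' @param log10_ic50 Inflection point, log10(uM).
#' @param hill Hill slope.
#' @param converged,ambiguous Fit status flags.
#' @param se_log10_ic50 Standard error of `log10_ic50` (NA if unknown).
#' @param data Optional tibble of the fitted points (`log10_conc`, `viability`).
#'
#' @return An object of class `fourpl_fit`.
#' @export
fourpl <- function(top, bottom, log10_ic50, hill, converged = TRUE,
                   ambiguous = FALSE, se_log10_ic50 = NA_real_, data = NULL) {
  structure(
    list(
      top = top, bottom = bottom, log10_ic50 = log10_ic50, hill = hill,
      converged = converged, ambiguous = ambiguous,
      se_log10_ic50 = se_log10_ic50, data = data
    ),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> top=%.3g bottom=%.3g log10_ic50=%.3g hill=%.3g [%s%s]\n",
    x$top, x$bottom, x$log10_ic50, x$hill,
    if (x$converged) "converged" else "non-convergent",
    if (x$ambiguous) ", ambiguous" else ""
  ))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, log10_conc, ...) {
  fourpl_value(log10_conc, object$top, object$bottom, object$log10_ic50, object$hill)
}

#' @rdname fourpl
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(
    term = c("top", "bottom", "log10_ic50", "hill"),
    estimate = c(x$top, x$bottom, x$log10_ic50, x$hill)
  )
}

#' @rdname fourpl
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(
    converged = x$converged, ambiguous = x$ambiguous,
    se_log10_ic50 = x$se_log10_ic50,
    n_points = if (is.null(x$data)) NA_integer_ else nrow(x$data)
  )
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on the log10-concentration scale
#' (Levenberg-Marquardt, bounded). Mirrors standard dose-response curve
#' fitting practice: initial values are taken from the data (top = max
#' viability, bottom = min viability, IC50 = median log dose, hill = 1).
#'
#' A fit is flagged `ambiguous` when the curve carries no usable
#' dose-response information: fitted span `top - bottom < span_tol`, a
#' non-positive Hill slope (viability not decreasing with dose), or a
#' log10 IC50 standard error above one log unit. Ambiguous and
#' non-convergent fits are excluded from every downstream analysis.
#'
#' @param concs Concentrations in uM (>= 4 distinct values).
#' @param viabilities Relative viabilities matched to `concs`.
#' @param span_tol Minimal top-bottom span below which the curve is
#'   considered flat/no-response.
#'
#' @return A [fourpl()] object with `converged`/`ambiguous` flags.
#' @export
fit_dose_response <- function(concs, viabilities, span_tol = 0.05) {
  ok <- is.finite(concs) & is.finite(viabilities) & concs > 0
  concs <- concs[ok]
  viabilities <- viabilities[ok]
  if (length(unique(concs)) < 4) {
    abort("need >= 4 distinct positive concentrations with finite viabilities.")
  }
  l <- log10(concs)
  dat <- tibble(log10_conc = l, viability = viabilities)

  # degenerate flat input: no span to fit, report a flat no-response curve
  if (diff(range(viabilities)) < 1e-8) {
    v <- mean(viabilities)
    return(fourpl(v, v, median(l), 1,
      converged = TRUE, ambiguous = TRUE, data = dat
    ))
  }

  vmax <- max(viabilities)
  # data-driven start, plus perturbed fallbacks: an exactly collinear
  # Jacobian at the first start occasionally aborts the optimizer
  starts <- list(
    list(top = vmax, bottom = min(viabilities), log10_ic50 = median(l), hill = 1),
    list(top = vmax, bottom = min(viabilities), log10_ic50 = mean(l), hill = 1.2),
    list(top = 1, bottom = 0, log10_ic50 = median(l), hill = 1)
  )
  lower <- c(top = -0.2, bottom = -0.2, log10_ic50 = min(l) - 3, hill = -10)
  upper <- c(top = 1.5 * vmax, bottom = 1.5 * vmax, log10_ic50 = max(l) + 3, hill = 10)

  fit <- NULL
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viability ~ bottom + (top - bottom) / (1 + 10^(hill * (log10_conc - log10_ic50))),
        data = dat, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(fourpl(NA_real_, NA_real_, NA_real_, NA_real_,
      converged = FALSE, ambiguous = FALSE, data = dat
    ))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["log10_ic50", "Std. Error"],
    error = function(e) NA_real_
  )
  # orient: a negative hill with swapped plateaus is the same curve
  if (cf[["hill"]] < 0 && cf[["top"]] < cf[["bottom"]]) {
    cf[c("top", "bottom")] <- cf[c("bottom", "top")]
    cf[["hill"]] <- -cf[["hill"]]
  }
  ambiguous <- (cf[["top"]] - cf[["bottom"]]) < span_tol ||
    cf[["hill"]] <= 0 ||
    (is.finite(se) && se > 1)
  fourpl(cf[["top"]], cf[["bottom"]], cf[["log10_ic50"]], cf[["hill"]],
    converged = TRUE, ambiguous = ambiguous, se_log10_ic50 = se, data = dat
  )
}

# window-normalized trapezoidal AUC of a 4PL over [lmin, lmax], 101-point grid
auc_fourpl <- function(fit, lmin, lmax, n_grid = 101L) {
  grid <- seq(lmin, lmax, length.out = n_grid)
  v <- fourpl_value(grid, fit$top, fit$bottom, fit$log10_ic50, fit$hill)
  h <- (lmax - lmin) / (n_grid - 1)
  sum((v[-1] + v[-n_grid]) / 2) * h / (lmax - lmin)
}

#' Dose-response AUC of a fitted curve or of raw viability points
#'
#' The sensitivity score is the trapezoidal integral of viability over the
#' tested log10-concentration window, divided by the window width: a
#' dimensionless mean viability, ~1 for an inactive drug and ~0 for a
#' fully lethal one (lower AUC = more sensitive). For a `fourpl_fit` the
#' fitted curve is integrated on a 101-point grid; non-convergent and
#' ambiguous fits yield an excluded record with no numeric AUC. A plain
#' numeric viability vector is integrated directly on the observed points.
#'
#' @param fit_or_points A [fourpl()] object, or a numeric viability vector
#'   matched to `series`.
#' @param series Concentrations tested, uM (a [make_dilution_series()]
#'   vector or any numeric vector spanning >= 2 concentrations).
#' @param sample_id,drug_id Optional identifiers carried into the record.
#'
#' @return A one-row tibble: `sample_id`, `drug_id`, `auc`, `status`
#'   (`"ok"`, `"excluded_nonconvergent"` or `"excluded_ambiguous"`).
#' @export
compute_auc <- function(fit_or_points, series, sample_id = NA_character_,
                        drug_id = NA_character_) {
  series <- as.numeric(series)
  if (length(unique(series)) < 2 || any(series <= 0)) {
    abort("`series` must span >= 2 positive concentrations.")
  }
  lmin <- log10(min(series))
  lmax <- log10(max(series))
  rec <- function(auc, status) {
    tibble(sample_id = sample_id, drug_id = drug_id, auc = auc, status = status)
  }
  if (inherits(fit_or_points, "fourpl_fit")) {
    f <- fit_or_points
    if (!f$converged) {
      return(rec(NA_real_, "excluded_nonconvergent"))
    }
    if (f$ambiguous) {
      return(rec(NA_real_, "excluded_ambiguous"))
    }
    return(rec(auc_fourpl(f, lmin, lmax), "ok"))
  }
  v <- as.numeric(fit_or_points)
  if (length(v) != length(series)) {
    abort("viability vector and `series` lengths differ.")
  }
  ord <- order(series)
  l <- log10(series[ord])
  v <- v[ord]
  auc <- sum(diff(l) * (v[-1] + v[-length(v)]) / 2) / (lmax - lmin)
  rec(auc, "ok")
}

#' Build the samples x drugs AUC matrix from raw plates
#'
#' Runs the full plate-to-AUC stage: per-plate Z'-factor QC (plates below
#' `min_z` are dropped with a warning), DMSO normalization, averaging of
#' replicate wells on the viability scale, 4PL fitting per (sample, drug),
#' and window-normalized AUC with exclusion flags.
#'
#' @param plates Stacked plate-well tibble (schema of `plates.tsv`:
#'   `plate_id`, `well_row`, `well_col`, `sample_id`, `drug_id`, `conc_uM`,
#'   `role`, `signal`).
#' @param min_z Z' threshold below which a plate is dropped.
#' @param replicate_tol Viability range among replicate wells of one
#'   (sample, drug, concentration) above which a data-consistency warning
#'   is raised.
#'
#' @return A list with `auc` (long tibble: `sample_id`, `drug_id`, `auc`,
#'   `status`) and `qc` (per-plate Z' report).
#' @export
build_auc_matrix <- function(plates, min_z = 0.3, replicate_tol = 0.5) {
  plates <- as_tibble(plates)

  qc <- plates |>
    group_by(.data$plate_id) |>
    group_map(function(df, key) {
      pos <- df$signal[df$role == "positive"]
      neg <- df$signal[df$role == "dmso"]
      if (length(pos) < 2 || length(neg) < 2) {
        return(tibble(plate_id = key$plate_id, z_factor = NA_real_, pass = TRUE))
      }
      z_factor(pos, neg, threshold = min_z, plate_id = key$plate_id)
    }) |>
    purrr::list_rbind()

  failed <- qc$plate_id[!qc$pass]
  if (length(failed) > 0) {
    warn(paste0(
      "dropping ", length(failed), " plate(s) failing Z' QC: ",
      paste(failed, collapse = ", ")
    ))
    plates <- plates |> filter(!.data$plate_id %in% failed)
  }

  treated <- normalize_plate(plates) |>
    filter(.data$role == "treat")

  averaged <- treated |>
    group_by(.data$sample_id, .data$drug_id, .data$conc_uM) |>
    summarise(viability = mean(.data$viability), .groups = "drop")
  spread <- treated |>
    group_by(.data$sample_id, .data$drug_id, .data$conc_uM) |>
    summarise(v_range = diff(range(.data$viability)), .groups = "drop")
  n_conflict <- sum(spread$v_range > replicate_tol)
  if (n_conflict > 0) {
    warn(paste0(
      n_conflict, " (sample, drug, concentration) replicate group(s) disagree ",
      "by more than ", replicate_tol, " viability units."
    ))
  }

  auc <- averaged |>
    group_by(.data$sample_id, .data$drug_id) |>
    group_map(function(df, key) {
      fit <- fit_dose_response(df$conc_uM, df$viability)
      compute_auc(fit, df$conc_uM,
        sample_id = key$sample_id, drug_id = key$drug_id
      )
    }) |>
    purrr::list_rbind() |>
    arrange(.data$sample_id, .data$drug_id)

  list(auc = auc, qc = qc)
}

#' Plot a fitted dose-response curve with its points
#'
#' @param fit A [fourpl()] object holding fitted data.
#' @param n_grid Curve resolution.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(fit, n_grid = 200L) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (is.null(fit$data)) abort("fit carries no data points to plot.")
  grid <- tibble(
    log10_conc = seq(min(fit$data$log10_conc), max(fit$data$log10_conc),
      length.out = n_grid
    )
  )
  grid$viability <- predict(fit, grid$log10_conc)
  ggplot2::ggplot(fit$data, ggplot2::aes(.data$log10_conc, .data$viability)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#B2182B") +
    ggplot2::labs(
      x = "log10 concentration (uM)", y = "relative viability",
      title = sprintf(
        "4PL fit: IC50 = %.3g uM, hill = %.2f",
        10^fit$log10_ic50, fit$hill
      )
    ) +
    ggplot2::theme_minimal()
}
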