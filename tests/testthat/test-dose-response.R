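test_that("dilution series is exactly geometric with the documented endpoints", {
  s <- make_dilution_series(20, 4, 7)
  expect_length(s, 7)
  expect_identical(s[1], 20)
  # consecutive ratio is the fold factor to machine precision
  expect_equal(s[-length(s)] / s[-1], rep(4, 6), tolerance = 1e-15)
  expect_equal(min(s), 20 / 4^6)
  expect_equal(signif(min(s) * 1000, 3), 4.88) # 4.88 nM floor

  expect_equal(as.numeric(make_dilution_series(10, 2, 4)), c(10, 5, 2.5, 1.25))
  expect_equal(as.numeric(make_dilution_series(3, 5, 1)), 3)
  expect_error(make_dilution_series(-1, 4, 7), "positive")
  expect_error(make_dilution_series(20, 1, 7), "fold")
  expect_error(make_dilution_series(20, 4, 0), "integer")
})

test_that("plate normalization divides by the per-plate DMSO mean", {
  plate <- tibble::tibble(
    plate_id = "P1",
    role = c("dmso", "dmso", "treat", "treat"),
    signal = c(9000, 11000, 5000, 0)
  )
  out <- normalize_plate(plate)
  expect_equal(out$viability[out$role == "treat"], c(0.5, 0))
  expect_equal(mean(out$viability[out$role == "dmso"]), 1.0)

  expect_error(
    normalize_plate(dplyr::mutate(plate, role = "treat")),
    "no DMSO"
  )
  expect_error(
    normalize_plate(dplyr::mutate(plate, signal = -signal)),
    "degenerate"
  )
  one_dmso <- plate[c(1, 3, 4), ]
  expect_error(normalize_plate(one_dmso), "fewer than 2")
})

test_that("Z'-factor follows its formula, caps at 1 and is affine-invariant", {
  # zero-variance limit
  expect_equal(z_factor(c(5, 5, 5), c(100, 100, 100))$z_factor, 1.0)
  # direct arithmetic: 1 - 3*(5+5)/100 = 0.7
  pos <- c(-5, 0, 5)
  neg <- c(95, 100, 105) # both SDs are 5, means 0 and 100
  expect_equal(z_factor(pos, neg)$z_factor, 0.7)
  expect_error(z_factor(c(1, 2, 3), c(2, 2, 2)), "coincide")

  # Z' <= 1 and invariant under joint affine rescaling
  set.seed(11)
  for (i in 1:20) {
    p <- rnorm(8, 0, runif(1, 0.1, 5))
    n <- rnorm(8, 50, runif(1, 0.1, 5))
    z <- z_factor(p, n)$z_factor
    expect_lte(z, 1)
    a <- runif(1, 0.5, 3)
    b <- runif(1, -10, 10)
    expect_equal(z_factor(a * p + b, a * n + b)$z_factor, z, tolerance = 1e-10)
  }
})

test_that("4PL fit recovers noiseless parameters and flags pathologies", {
  s <- make_dilution_series(20, 4, 7)
  v <- fourpl_value(log10(s), 1, 0, -0.5, 1)
  fit <- fit_dose_response(s, v)
  expect_true(fit$converged)
  expect_false(fit$ambiguous)
  expect_equal(fit$top, 1, tolerance = 1e-3)
  expect_equal(fit$bottom, 0, tolerance = 1e-3)
  expect_equal(fit$log10_ic50, -0.5, tolerance = 1e-3)
  expect_equal(fit$hill, 1, tolerance = 1e-3)
  expect_equal(tidy(fit)$term, c("top", "bottom", "log10_ic50", "hill"))
  expect_true(glance(fit)$converged)

  # flat curve: flagged no-response, not an error
  flat <- fit_dose_response(s, rep(1, 7))
  expect_true(flat$converged)
  expect_true(flat$ambiguous)
  expect_equal(flat$top, flat$bottom)

  # viability increasing with dose: non-positive hill -> ambiguous
  incr <- fit_dose_response(s, fourpl_value(log10(s), 1, 0, -0.5, -1))
  expect_true(incr$ambiguous)

  expect_error(fit_dose_response(c(1, 2, 3), c(1, 1, 0.5)), ">= 4 distinct")
})

test_that("AUC handles plateaus, midpoint step, and exclusion statuses", {
  s <- make_dilution_series(20, 4, 7)
  expect_equal(compute_auc(rep(1, 7), s)$auc, 1.0)
  expect_equal(compute_auc(rep(0, 7), s)$auc, 0.0)

  # hill -> infinity with IC50 at the window center: half the window at 1
  center <- mean(log10(range(s)))
  step <- fourpl(1, 0, center, 1e6)
  expect_equal(compute_auc(step, s)$auc, 0.5, tolerance = 1e-6)

  bad <- fourpl(NA, NA, NA, NA, converged = FALSE)
  rec <- compute_auc(bad, s)
  expect_identical(rec$status, "excluded_nonconvergent")
  expect_true(is.na(rec$auc))
  amb <- fourpl(1, 0, 0, 1, ambiguous = TRUE)
  expect_identical(compute_auc(amb, s)$status, "excluded_ambiguous")
})

test_that("AUC is monotone in IC50 and bottom, bounded by the plateaus", {
  s <- make_dilution_series(20, 4, 7)
  set.seed(21)
  for (i in 1:25) {
    top <- runif(1, 0.8, 1.1)
    bottom <- runif(1, 0, 0.5)
    hill <- runif(1, 0.5, 3)
    ic <- sort(runif(3, -2.5, 1.5))
    aucs <- vapply(
      ic, function(l) compute_auc(fourpl(top, bottom, l, hill), s)$auc,
      numeric(1)
    )
    expect_true(all(diff(aucs) > 0)) # lower IC50 -> lower AUC
    expect_true(all(aucs >= bottom & aucs <= top))
    # lower bottom -> lower AUC at fixed ic50
    a_lo <- compute_auc(fourpl(top, bottom - 0.2, ic[2], hill), s)$auc
    expect_lt(a_lo, aucs[2])
    # agreement with an independent fine-grid trapezoid
    expect_equal(
      aucs[2],
      oracle_auc_fourpl(top, bottom, ic[2], hill, log10(min(s)), log10(max(s))),
      tolerance = 1e-3
    )
  }
})

test_that("build_auc_matrix averages replicates, drops bad plates, propagates exclusions", {
  sim <- tiny_cohort(seed = 31, n_samples = 4, n_drugs = 3)
  res <- build_auc_matrix(sim$bundle$plates)
  expect_setequal(names(res), c("auc", "qc"))
  expect_equal(nrow(res$auc), 4 * 3)
  expect_true(all(res$qc$pass))
  expect_true(all(is.na(res$auc$auc) == (res$auc$status != "ok")))

  # wreck one plate's controls: it must be dropped with a warning
  plates <- sim$bundle$plates
  bad_id <- plates$plate_id[1]
  plates$signal[plates$plate_id == bad_id & plates$role != "treat"] <-
    rnorm(sum(plates$plate_id == bad_id & plates$role != "treat"), 5000, 4000)
  expect_warning(res2 <- build_auc_matrix(plates), "Z' QC")
  expect_lt(nrow(res2$auc), nrow(res$auc))
  expect_false(res2$qc$pass[res2$qc$plate_id == bad_id])
})
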