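test_that("Wilcoxon p-values match the exhaustive enumeration oracle", {
  expect_equal(wilcoxon_rank_sum(c(0.2, 0.3), c(0.8, 0.9))$p, 1 / 3,
    tolerance = 1e-12
  )
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  set.seed(101)
  for (n1 in c(2, 3, 5, 8)) {
    for (n2 in c(2, 4, 8)) {
      for (rep in 1:3) {
        x <- rnorm(n1)
        y <- rnorm(n2, mean = runif(1, -1, 1))
        expect_equal(
          wilcoxon_rank_sum(x, y)$p, oracle_wilcoxon_p(x, y),
          tolerance = 1e-12,
          label = sprintf("wilcoxon n1=%d n2=%d rep=%d", n1, n2, rep)
        )
      }
    }
  }
})

test_that("Fisher co-occurrence matches hypergeometric enumeration", {
  alter_from_pairs <- function(a, b) {
    n <- length(a)
    dplyr::bind_rows(
      tibble::tibble(
        sample_id = sprintf("s%02d", 1:n), feature = "FA",
        status = ifelse(a, "altered", "wild-type")
      ),
      tibble::tibble(
        sample_id = sprintf("s%02d", 1:n), feature = "FB",
        status = ifelse(b, "altered", "wild-type")
      )
    )
  }
  # diagonal table [[3,0],[0,3]] -> two-sided p = 2 / C(6,3) = 0.1
  res <- cooccurrence_test("FA", "FB", alter_from_pairs(
    rep(c(TRUE, FALSE), each = 3), rep(c(TRUE, FALSE), each = 3)
  ))
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  # perfect independence [[2,2],[2,2]] -> p = 1
  res2 <- cooccurrence_test("FA", "FB", alter_from_pairs(
    rep(c(TRUE, FALSE), each = 4), rep(c(TRUE, FALSE), 4)
  ))
  expect_equal(res2$p, 1.0)
  # all tables with n <= 12 against the enumeration oracle
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    a <- runif(n) < 0.5
    b <- runif(n) < 0.5
    tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_warning(
        resn <- cooccurrence_test("FA", "FB", alter_from_pairs(a, b)),
        "degenerate"
      )
      expect_equal(resn$p, 1)
    } else {
      resn <- cooccurrence_test("FA", "FB", alter_from_pairs(a, b))
      expect_equal(resn$p, oracle_fisher_p(tab), tolerance = 1e-12)
    }
  }
})

test_that("gene-drug screen plants are recovered and small groups skipped", {
  set.seed(303)
  tabs <- null_screen_tables(n_samples = 100, n_features = 30, n_drugs = 5)
  # plant a -1.5 pooled-SD shift on (F001, D01) for altered samples
  carriers <- tabs$alterations$sample_id[
    tabs$alterations$feature == "F001" & tabs$alterations$status == "altered"
  ]
  idx <- tabs$aucs$drug_id == "D01" & tabs$aucs$sample_id %in% carriers
  tabs$aucs$auc[idx] <- tabs$aucs$auc[idx] - 1.5 * 0.12
  scr <- gene_drug_screen(tabs$alterations, tabs$aucs)
  top <- scr[which.min(scr$q), ]
  expect_identical(c(top$feature, top$drug), c("F001", "D01"))
  expect_lt(top$delta_auc, 0)
  expect_lt(top$q, 0.1)
  expect_true(all(scr$q >= scr$p))
  expect_true(all(scr$p > 0 & scr$p <= 1))

  # a feature with 2 altered samples is skipped at min_group = 3
  small <- tabs$alterations |>
    dplyr::mutate(status = ifelse(
      feature == "F002",
      ifelse(sample_id %in% c("S001", "S002"), "altered", "wild-type"),
      status
    ))
  scr2 <- gene_drug_screen(small, tabs$aucs, min_group = 3)
  expect_false("F002" %in% scr2$feature)

  # unknown-status samples are excluded from both arms
  unk <- tabs$alterations |>
    dplyr::mutate(status = ifelse(feature == "F003" & sample_id <= "S050",
      "unknown", status
    ))
  scr3 <- gene_drug_screen(unk, tabs$aucs)
  f3 <- scr3[scr3$feature == "F003", ]
  expect_true(all(f3$n_altered + f3$n_wildtype <= 50))
})

test_that("screen output is invariant to row order of its inputs", {
  set.seed(404)
  tabs <- null_screen_tables(n_samples = 40, n_features = 8, n_drugs = 3)
  scr <- gene_drug_screen(tabs$alterations, tabs$aucs)
  perm <- gene_drug_screen(
    tabs$alterations[sample(nrow(tabs$alterations)), ],
    tabs$aucs[sample(nrow(tabs$aucs)), ]
  )
  expect_equal(scr, perm)
})

test_that("subtype screen flags planted sensitivity with the right direction", {
  set.seed(505)
  n <- 90
  ids <- sprintf("S%03d", 1:n)
  labels <- tibble::tibble(
    sample_id = ids,
    group = sample(c("diffuse", "intestinal", "mixed"), n,
      replace = TRUE, prob = c(0.4, 0.4, 0.2)
    )
  )
  aucs <- tidyr::expand_grid(sample_id = ids, drug_id = c("V", "W")) |>
    dplyr::mutate(auc = 0.6 + 0.1 * rnorm(dplyr::n()), status = "ok")
  sel <- aucs$drug_id == "V" &
    aucs$sample_id %in% labels$sample_id[labels$group == "diffuse"]
  aucs$auc[sel] <- aucs$auc[sel] - 0.15
  scr <- subtype_drug_screen(labels, aucs, fdr_level = 0.1)
  hit <- scr[scr$group == "diffuse" & scr$drug == "V", ]
  expect_identical(hit$direction, "sensitive")
  expect_true(hit$significant)

  # an empty class is skipped, the others still tested
  labels2 <- labels |> dplyr::mutate(group = ifelse(group == "mixed", "diffuse", group))
  scr2 <- subtype_drug_screen(labels2, aucs)
  expect_setequal(unique(scr2$group), c("diffuse", "intestinal"))
  expect_error(
    subtype_drug_screen(dplyr::mutate(labels, group = "one"), aucs),
    "degenerate"
  )
})

test_that("volcano table adds plotting coordinates with a stable sort", {
  recs <- tibble::tibble(
    feature = c("A", "B", "C"), drug = "d",
    n_altered = c(5L, 6L, 7L), n_wildtype = 20L,
    delta_auc = c(-0.3, 0.1, -0.2), fold_change = c(0.5, 1, 0.7),
    p = c(0.001, 1, 0.04), q = c(0.003, 1, 0.06)
  )
  v <- volcano_table(recs)
  expect_equal(v$neg_log10_p[v$feature == "B"], 0) # p = 1 boundary
  expect_equal(v$log2_fold_change[v$feature == "B"], 0) # ratio 1
  expect_identical(v$feature, c("A", "C", "B")) # q ascending
  # ties in q broken by |delta|, then keys: deterministic across shuffles
  recs2 <- recs |> dplyr::mutate(q = 0.5)
  expect_identical(volcano_table(recs2[c(2, 3, 1), ]), volcano_table(recs2))
  p <- plot_volcano(recs)
  expect_s3_class(p, "ggplot")
})
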