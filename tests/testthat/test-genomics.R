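mut_row <- function(sample_id, gene, protein_change = "p.A100V",
                    vaf = 0.3, depth = 100) {
  tibble::tibble(
    sample_id = sample_id, gene = gene, protein_change = protein_change,
    vaf = vaf, depth = depth
  )
}

test_that("mutation filter applies strict VAF/depth thresholds and is idempotent", {
  recs <- dplyr::bind_rows(
    mut_row("s1", "TP53", vaf = 0.06, depth = 25), # kept
    mut_row("s2", "TP53", vaf = 0.04, depth = 100), # below VAF
    mut_row("s3", "TP53", vaf = 0.50, depth = 20), # depth not > 20
    mut_row("s4", "TP53", vaf = 0.05, depth = 50) # VAF not > 0.05
  )
  kept <- filter_mutations(recs)
  expect_identical(kept$sample_id, "s1")
  expect_identical(filter_mutations(kept), kept) # idempotent
  # order-preserving on a shuffled input
  set.seed(5)
  shuffled <- recs[sample(nrow(recs)), ]
  out <- filter_mutations(shuffled, min_vaf = 0.01, min_depth = 1)
  expect_identical(out$sample_id, shuffled$sample_id)
  expect_error(filter_mutations(mut_row("s1", "TP53", vaf = 1.2)), "\\[0, 1\\]")
})

test_that("alteration matrix distinguishes altered / wild-type / unknown", {
  muts <- mut_row("s1", "KRAS", protein_change = "G12D")
  cnas <- tibble::tibble(
    sample_id = c("s1", "s2"), gene = "KRAS",
    call = c("amp", "neutral"), log2_ratio = c(1.2, 0)
  )
  spec <- tibble::tibble(
    feature = c("KRAS", "KRAS-G12D", "KRAS-amp"),
    kind = c("mut", "protein", "cna"),
    gene = "KRAS", value = c(NA, "G12D", "amp")
  )
  am <- build_alteration_matrix(muts, cnas,
    samples = c("s1", "s2", "s3"),
    sequenced = c("s1", "s2"), spec = spec
  )
  get <- function(s, f) am$status[am$sample_id == s & am$feature == f]
  expect_identical(get("s1", "KRAS"), "altered")
  expect_identical(get("s2", "KRAS"), "wild-type")
  expect_identical(get("s3", "KRAS"), "unknown") # unsequenced, never wild-type
  expect_identical(get("s1", "KRAS-G12D"), "altered")
  expect_identical(get("s1", "KRAS-amp"), "altered")
  expect_identical(get("s2", "KRAS-amp"), "wild-type")

  # protein-change features demand the exact change
  muts2 <- mut_row("s2", "KRAS", protein_change = "G12V")
  am2 <- build_alteration_matrix(
    dplyr::bind_rows(muts, muts2), cnas,
    samples = c("s1", "s2"), sequenced = c("s1", "s2"), spec = spec
  )
  expect_identical(
    am2$status[am2$sample_id == "s2" & am2$feature == "KRAS-G12D"], "wild-type"
  )
  # unknown gene in the feature_spec warns and yields no altered cells
  spec3 <- tibble::tibble(feature = "MYC", kind = "mut", gene = "MYC", value = NA)
  expect_warning(
    am3 <- build_alteration_matrix(muts, cnas,
      samples = "s1", sequenced = "s1", spec = spec3
    ),
    "absent"
  )
  expect_identical(am3$status, "wild-type")
})

test_that("subtype assignment follows the EBV > MSI > CNA-burden decision tree", {
  meta <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    subtype_flag = c("EBV", "MSI", "none", "none")
  )
  cna <- tidyr::expand_grid(
    sample_id = c("a", "b", "c", "d"), gene = sprintf("g%02d", 1:10)
  ) |>
    dplyr::mutate(call = "neutral")
  # sample a: EBV flag wins even with maximal burden
  cna$call[cna$sample_id == "a"] <- "amp"
  # sample c: 30% non-neutral -> HCNA at threshold 0.2
  cna$call[cna$sample_id == "c"][1:3] <- "del"
  st <- assign_subtype(meta, cna, burden_threshold = 0.2)
  expect_identical(st$subtype, c("EBV", "MSI", "HCNA", "LCNA"))
  # every sample gets exactly one label; counts sum to cohort size
  expect_identical(sort(st$sample_id), sort(meta$sample_id))
  expect_equal(sum(table(st$subtype)), nrow(meta))
})

test_that("per-subtype frequencies and ternary coordinates match hand arithmetic", {
  samples <- c(sprintf("e%d", 1:4), sprintf("l%d", 1:10), sprintf("h%d", 1:10))
  subtypes <- tibble::tibble(
    sample_id = samples,
    subtype = rep(c("EBV", "LCNA", "HCNA"), c(4, 10, 10))
  )
  alter <- tidyr::expand_grid(sample_id = samples, feature = c("G1", "G2", "G3")) |>
    dplyr::mutate(status = "wild-type")
  # G1: 2/4 EBV, 1/10 LCNA, 0/10 HCNA
  alter$status[alter$feature == "G1" & alter$sample_id %in% c("e1", "e2", "l1")] <- "altered"
  # G2: altered nowhere; G3: only HCNA
  alter$status[alter$feature == "G3" & alter$sample_id == "h1"] <- "altered"
  fr <- subtype_mutation_frequencies(alter, subtypes)
  g1 <- fr[fr$feature == "G1", ]
  expect_equal(
    c(g1$freq_EBV, g1$freq_LCNA, g1$freq_HCNA), c(0.5, 0.1, 0.0)
  )
  expect_equal(
    c(g1$tern_EBV, g1$tern_LCNA, g1$tern_HCNA), c(0.833, 0.167, 0),
    tolerance = 1e-3
  )
  expect_false("G2" %in% fr$feature) # all-zero triple omitted
  g3 <- fr[fr$feature == "G3", ]
  expect_equal(c(g3$tern_EBV, g3$tern_LCNA, g3$tern_HCNA), c(0, 0, 1))
  expect_true(all(dplyr::select(fr, dplyr::starts_with("freq_")) >= 0 &
    dplyr::select(fr, dplyr::starts_with("freq_")) <= 1))

  # unknown-status samples never inflate a denominator
  alter_unk <- alter |>
    dplyr::mutate(status = ifelse(sample_id %in% c("e3", "e4"), "unknown", status))
  fr_unk <- subtype_mutation_frequencies(alter_unk, subtypes)
  expect_equal(fr_unk$freq_EBV[fr_unk$feature == "G1"], 1.0) # 2 altered / 2 known
})

test_that("tissue/PDC concordance is plain set algebra with consistent margins", {
  meta <- tibble::tibble(
    sample_id = c("t1", "p1", "t2", "p2", "t3", "p3", "solo"),
    origin = c("tissue", "pdc", "tissue", "pdc", "tissue", "pdc", "pdc"),
    pair_id = c("q1", "q1", "q2", "q2", "q3", "q3", NA)
  )
  muts <- dplyr::bind_rows(
    mut_row("t1", "A"), mut_row("t1", "B"),
    mut_row("p1", "B"), mut_row("p1", "C"),
    mut_row("t2", "A"), mut_row("p2", "A"), # identical sets
    mut_row("t3", "A"), mut_row("p3", "B") # disjoint sets
  )
  cc <- tissue_pdc_concordance(muts, meta)
  q1 <- cc[cc$pair_id == "q1", ]
  expect_equal(
    c(q1$n_shared, q1$n_tissue_private, q1$n_pdc_private), c(1, 1, 1)
  )
  expect_equal(unlist(cc[cc$pair_id == "q2", -1]), c(1, 0, 0),
    ignore_attr = TRUE
  )
  expect_equal(cc$n_shared[cc$pair_id == "q3"], 0)
  # margins: shared + private reproduce the per-member totals
  for (pid in cc$pair_id) {
    row <- cc[cc$pair_id == pid, ]
    tid <- meta$sample_id[meta$pair_id %in% pid & meta$origin == "tissue"]
    pidc <- meta$sample_id[meta$pair_id %in% pid & meta$origin == "pdc"]
    expect_equal(row$n_shared + row$n_tissue_private, sum(muts$sample_id == tid))
    expect_equal(row$n_shared + row$n_pdc_private, sum(muts$sample_id == pidc))
  }
  # a dangling pair id is skipped with a warning
  meta_bad <- dplyr::bind_rows(meta, tibble::tibble(
    sample_id = "t4", origin = "tissue", pair_id = "q4"
  ))
  expect_warning(cc2 <- tissue_pdc_concordance(muts, meta_bad), "skipping")
  expect_setequal(cc2$pair_id, c("q1", "q2", "q3"))
})
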