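test_that("fold threshold defaults to the cotangent of 22.5 degrees", {
  p <- bias_parameters()
  expect_equal(p$fold_threshold, 1 + sqrt(2), tolerance = 1e-12)
  expect_error(bias_parameters(fold_threshold = 0.9))
})

test_that("detection floor is inclusive and high-abundance cut is exclusive", {
  ab <- toy_abundance(data.frame(
    barcode = c("A", "B", "C", "D", "E"),
    cell_type = "Gr", timepoint = 2.5,
    abundance = c(0.011, 0.009, 0.01, 0.06, 0.05)))
  pres <- detect_produced_types(ab)
  at <- function(b) pres$present[pres$barcode == b & pres$cell_type == "Gr" &
                                   pres$timepoint == 2.5]
  expect_true(at("A"))
  expect_false(at("B"))
  expect_true(at("C"))   # floor itself counts as measurable

  hi <- flag_high_abundance(ab)
  h <- function(b) hi$high[hi$barcode == b & hi$cell_type == "Gr" &
                             hi$timepoint == 2.5]
  expect_true(h("D"))
  expect_false(h("E"))   # strictly "above 0.05"
  expect_false(h("B"))
})

test_that("combination labels merge CD4/CD8 into T and drop empty clones", {
  ab <- toy_abundance(data.frame(
    barcode = c("GT", "GT", "T4", "NONE"),
    cell_type = c("Gr", "CD8T", "CD4T", "B"),
    timepoint = 2.5,
    abundance = c(0.05, 0.02, 0.02, 0.001)))
  comb <- combination_labels(ab, timepoint = 2.5)
  lab <- setNames(comb$combination, comb$barcode)
  expect_equal(unname(lab["GT"]), "Gr+T")
  expect_equal(unname(lab["T4"]), "T")
  expect_true(is.na(lab["NONE"]))
})

test_that("relative copy number normalises within mouse and timepoint", {
  ab <- toy_abundance(data.frame(
    barcode = c("X", "Y", "Z"),
    cell_type = c("B", "B", "Gr"),
    timepoint = 2.5,
    abundance = c(3, 1, 2)))
  r <- relative_copy_number(ab, c("B", "CD4T", "CD8T"), 2.5)
  v <- setNames(r$rcn, r$barcode)
  expect_equal(unname(v[c("X", "Y", "Z")]), c(0.75, 0.25, 0))
  # single clone owning a lineage -> 1
  rg <- relative_copy_number(ab, "Gr", 2.5)
  expect_equal(rg$rcn[rg$barcode == "Z"], 1)
})

test_that("lineage bias applies specialization precedence then the fold rule", {
  ab <- toy_abundance(data.frame(
    barcode = c("MS", "LB", "LB", "BAL", "BAL", "UND"),
    cell_type = c("Gr", "Gr", "B", "Gr", "B", "CD4T"),
    timepoint = 2.5,
    abundance = c(0.5, 0.10, 0.50, 0.20, 0.20, 0.005)))
  lb <- classify_lineage_bias(ab, timepoint = 2.5)
  lab <- setNames(lb$lineage_bias, lb$barcode)
  expect_equal(unname(lab["MS"]), "myeloid_specialized")
  # relative copy numbers: myeloid 0.10/0.80, lymphoid 0.50/0.70;
  # 0.714 > 2.4142 x 0.125 -> lymphoid biased
  expect_equal(unname(lab["LB"]), "lymphoid_biased")
  expect_equal(unname(lab["BAL"]), "balanced")
  expect_false("UND" %in% names(lab)[lab != "undetected"])

  # no clone is simultaneously specialized and biased; labels are exhaustive
  expect_true(all(table(lb$barcode) == 1))
})

test_that("B/T bias mirrors the lineage rule on the lymphoid compartment", {
  ab <- toy_abundance(data.frame(
    barcode = c("BS", "EQ", "EQ", "TB", "TB"),
    cell_type = c("B", "B", "CD8T", "B", "CD4T"),
    timepoint = 6.5,
    abundance = c(0.2, 0.2, 0.2, 0.01, 0.10)))
  bt <- classify_bt_bias(ab, timepoint = 6.5)
  lab <- setNames(bt$bt_bias, bt$barcode)
  expect_equal(unname(lab["BS"]), "B_specialized")
  expect_equal(unname(lab["EQ"]), "BT_balanced")
  expect_equal(unname(lab["TB"]), "T_biased")
})

test_that("temporal classes partition clones by early/late presence", {
  ab <- toy_abundance(data.frame(
    barcode = c("E", "P", "P", "L"),
    cell_type = "Gr",
    timepoint = c(2.5, 2.5, 6.5, 6.5),
    abundance = c(0.05, 0.05, 0.05, 0.05)))
  tm <- classify_temporal(ab)
  g <- tm[tm$cell_type == "Gr", ]
  lab <- setNames(g$temporal, g$barcode)
  expect_equal(unname(lab[c("E", "P", "L")]),
               c("early", "persisted", "late"))
  # other cell types: neither
  expect_true(all(tm$temporal[tm$cell_type == "B"] == "neither"))
  # exactly one temporal label per clone per cell type
  expect_true(all(table(tm$barcode, tm$cell_type) == 1))
})

test_that("dynamics uses the late/early production ratio of persisted clones", {
  ab <- toy_abundance(data.frame(
    barcode = c("UP", "UP", "DN", "DN", "TIE", "TIE", "NP"),
    cell_type = "CD4T",
    timepoint = c(2.5, 6.5, 2.5, 6.5, 2.5, 6.5, 2.5),
    abundance = c(0.10, 0.30, 0.30, 0.10, 0.10, 0.10, 0.10)))
  dyn <- classify_dynamics(ab)
  d4 <- dyn[dyn$cell_type == "CD4T", ]
  lab <- setNames(d4$dynamics, d4$barcode)
  expect_equal(unname(lab[c("UP", "DN", "TIE", "NP")]),
               c("expanded", "shrunken", "neither", "not_applicable"))
  expect_equal(d4$ratio[d4$barcode == "UP"], 3)
})

test_that("early/late overlap tallies conserve the early clone count", {
  ab <- toy_abundance(data.frame(
    barcode = c("A", "A", "B", "B", "C", "D", "D", "D"),
    cell_type = c("Gr", "Gr", "Gr", "B", "CD4T", "B", "Gr", "B"),
    timepoint = c(2.5, 6.5, 2.5, 6.5, 2.5, 2.5, 6.5, 6.5),
    abundance = 0.05))
  ov <- early_late_overlap(ab)
  # A -> myeloid_specialized, B -> lymphoid_specialized, C -> undetected,
  # D -> multilineage; all four clones detected early
  v <- setNames(ov$n, ov$category)
  expect_equal(unname(v[c("multilineage", "myeloid_specialized",
                          "lymphoid_specialized", "undetected")]),
               c(1L, 1L, 1L, 1L))
  expect_equal(sum(ov$fraction), 1)
})

test_that("bias labels are invariant to rescaling a mouse's abundances", {
  set.seed(21)
  ab <- random_abundance(25)
  m <- SummarizedExperiment::assay(ab)
  scaled <- clonal_abundance_matrix(m * 7, parse_sample_keys(colnames(m)))
  for (tp in c(2.5, 6.5)) {
    a <- classify_lineage_bias(ab, timepoint = tp)
    b <- classify_lineage_bias(scaled, timepoint = tp)
    # specialization calls can differ (floor is absolute); fold calls cannot
    both <- a$lineage_bias %in% c("balanced", "myeloid_biased",
                                  "lymphoid_biased") &
      b$lineage_bias %in% c("balanced", "myeloid_biased", "lymphoid_biased")
    expect_equal(a$lineage_bias[both], b$lineage_bias[both])
  }
})

test_that("raising thresholds only moves labels toward the conservative side", {
  set.seed(33)
  ab <- random_abundance(30)
  p1 <- bias_parameters()
  p2 <- bias_parameters(fold_threshold = 5)
  a <- classify_lineage_bias(ab, p1, 2.5)$lineage_bias
  b <- classify_lineage_bias(ab, p2, 2.5)$lineage_bias
  # a balanced clone never becomes biased under a stricter fold threshold
  expect_false(any(a == "balanced" &
                     b %in% c("myeloid_biased", "lymphoid_biased")))

  p3 <- bias_parameters(detect_floor = 0.05)
  n1 <- sum(detect_produced_types(ab, p1)$present)
  n3 <- sum(detect_produced_types(ab, p3)$present)
  expect_lte(n3, n1)
})

test_that("all label axes match the literal brute-force oracle", {
  set.seed(9)
  params <- bias_parameters()
  for (rep in 1:10) {
    ab <- random_abundance(20)
    want <- oracle_labels(ab, params)
    for (tp in c(2.5, 6.5)) {
      tpn <- format(tp, trim = TRUE)
      comb <- combination_labels(ab, params, tp)
      expect_equal(comb$combination[match(want$barcode, comb$barcode)],
                   want[[paste0("combination_", tpn)]])
      lb <- classify_lineage_bias(ab, params, tp)
      expect_equal(lb$lineage_bias[match(want$barcode, lb$barcode)],
                   want[[paste0("lineage_bias_", tpn)]])
      bt <- classify_bt_bias(ab, params, tp)
      expect_equal(bt$bt_bias[match(want$barcode, bt$barcode)],
                   want[[paste0("bt_bias_", tpn)]])
    }
    tm <- classify_temporal(ab, params)
    dy <- classify_dynamics(ab, params)
    for (ct in cell_types()) {
      sub <- tm[tm$cell_type == ct, ]
      expect_equal(sub$temporal[match(want$barcode, sub$barcode)],
                   want[[paste0("temporal_", ct)]])
    }
    for (ct in c("CD4T", "CD8T")) {
      sub <- dy[dy$cell_type == ct, ]
      expect_equal(sub$dynamics[match(want$barcode, sub$barcode)],
                   want[[paste0("dynamics_", ct)]])
    }
  }
})
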