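test_that("thresholding is boundary-inclusive and names missing markers", {
  cells <- make_cells(list("CD45", "CD45"))
  cells$CD45 <- c(5, 4.99)
  cells <- apply_thresholds(cells, c(CD45 = 5))
  expect_equal(cells$positive_CD45, c(TRUE, FALSE))
  expect_error(apply_thresholds(make_cells(list("CD45")), c(NotAMarker = 1)),
               "NotAMarker")
  # all-zero thresholds make every measured marker positive
  all0 <- apply_thresholds(make_cells(list("CD45")),
                           setNames(rep(0, 3), c("CD45", "CD68", "Ly6G")))
  expect_true(all(all0$positive_CD45, all0$positive_CD68, all0$positive_Ly6G))
})

test_that("marker aliases resolve to canonical panel names", {
  expect_equal(normalize_marker_names(c("F4/80", "aSMA", "E-Cadherin",
                                        "EpCam (CD326)", "collagen 1")),
               c("F480", "aSMA", "ECadherin", "EpCAM", "Collagen1"))
})

test_that("the six published gates classify canonical marker patterns", {
  pats <- list(
    c("CD45", "CD11b", "F480"),                    # macrophage
    c("CD45", "CD11b", "Ly6G"),                    # neutrophil (F4/80- CD68-)
    c("CD45", "CD11b", "CD68", "CD163", "CD206"),  # M2 macrophage
    c("CD45", "CD11b", "CD68", "MHCII"),           # M1 macrophage
    c("CD45", "CD11b", "F480", "Ly6G"),            # immature monocyte
    c("CD45", "CD11b", "CD68", "CD11c"),           # dendritic cell
    character(0))                                  # nothing positive
  cells <- make_cells(pats)
  cells <- apply_thresholds(cells, default_thresholds())
  cells <- assign_phenotypes(cells)
  expect_equal(cells$phenotype,
               c("macrophage", "neutrophil", "M2_macrophage", "M1_macrophage",
                 "immature_monocyte", "dendritic_cell", "none"))
  # multi-label: the M2 cell also satisfies the base macrophage gate
  expect_true(cells$is_macrophage[3])
  # every M1 satisfies the F4/80-or-CD68 core
  expect_true(all(!cells$is_M1_macrophage |
                    (cells$positive_F480 | cells$positive_CD68)))
})

test_that("rule construction rejects contradictions and unknown markers", {
  expect_error(phenotype_rule("bad", all_pos = "CD45", all_neg = "CD45"),
               "both")
  expect_error(phenotype_rule("bad", all_pos = "CD999"), "unknown")
})

test_that("exclusion inheritance flag tightens the M1/M2 sub-gates", {
  # a CD11c+ MHCII+ macrophage-core cell: literal reading gates it M1
  # (and dendritic, which wins precedence); with inherited exclusions the
  # M1 gate itself rejects it
  cells <- make_cells(list(c("CD45", "CD11b", "CD68", "MHCII", "CD11c")))
  cells <- apply_thresholds(cells, default_thresholds())
  lit <- assign_phenotypes(cells, default_phenotype_rules(FALSE))
  inh <- assign_phenotypes(cells, default_phenotype_rules(TRUE))
  expect_true(lit$is_M1_macrophage)
  expect_false(inh$is_M1_macrophage)
  expect_equal(lit$phenotype, "dendritic_cell")
})

test_that("phenotype assignment is a pure function of positivity", {
  b <- generate_dataset(small_synth_config(seed = 9))
  cells <- apply_thresholds(b$cells, default_thresholds())
  a1 <- assign_phenotypes(cells)
  a2 <- assign_phenotypes(cells)
  expect_identical(a1$phenotype, a2$phenotype)
})

test_that("raising a threshold never increases percent positive", {
  set.seed(11)
  b <- generate_dataset(small_synth_config(seed = 3))
  for (m in c("CD68", "CD206", "CD31")) {
    pp <- sapply(c(1, 3, 5, 10, 30), function(thr) {
      percent_positive(apply_thresholds(b$cells, setNames(thr, m)), m)
    })
    expect_true(all(diff(pp) <= 0))
  }
})

test_that("percent positive follows its definition, per region too", {
  cells <- make_cells(c(rep(list("CD45"), 4), rep(list(character(0)), 6)))
  cells <- apply_thresholds(cells, c(CD45 = 5))
  expect_equal(percent_positive(cells, "CD45"), 40)
  expect_equal(percent_positive(cells, "CD45", region = cells$positive_CD45), 100)
  expect_true(is.na(percent_positive(cells, "CD45", region = rep(FALSE, 10))))
})
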