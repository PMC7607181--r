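test_that("core_score is the intensity x density product with bounds", {
  expect_equal(core_score(3, 100), 300)
  expect_equal(core_score(0, 80), 0)
  expect_equal(core_score(2, 40), 80)
  expect_equal(core_score(c(1, 2, NA), c(10, 20, 30)), c(10, 40, NA))
  expect_error(core_score(4, 50), class = "ihcmet_param_error")
  expect_error(core_score(1.5, 50), class = "ihcmet_param_error")
  expect_error(core_score(2, 101), class = "ihcmet_param_error")
  expect_error(core_score(2, -1), class = "ihcmet_param_error")
})

test_that("core_score is monotone in each argument and stays in [0, 300]", {
  for (i in 0:2) for (d in seq(0, 90, by = 10)) {
    expect_lte(core_score(i, d), core_score(i + 1, d))
    expect_lte(core_score(i, d), core_score(i, d + 10))
  }
  grid <- expand.grid(i = 0:3, d = seq(0, 100, by = 5))
  s <- core_score(grid$i, grid$d)
  expect_true(all(s >= 0 & s <= 300))
})

test_that("tumor_score averages evaluable cores, drops missing", {
  expect_equal(tumor_score(c(100, 200, 300)), 200)
  expect_equal(tumor_score(50), 50)
  expect_equal(tumor_score(c(300, NA, 0)), 150)
  expect_true(is.na(tumor_score(c(NA_real_, NA_real_))))
  expect_error(tumor_score(numeric(0)), class = "ihcmet_param_error")
})

test_that("positivity cutoff is >= 1 on the mean score", {
  expect_true(is_positive(1))
  expect_false(is_positive(0))
  expect_false(is_positive(0.5))  # mean of cores scoring 1 and 0
  expect_true(is_positive(0.5, cutoff = 0.5))
  expect_error(is_positive(301), class = "ihcmet_param_error")
})

test_that("phenotype truth table: 8 combinations, 4 classes, total partition", {
  flags <- expand.grid(glut1 = c(TRUE, FALSE), pck1 = c(TRUE, FALSE),
                       pck2 = c(TRUE, FALSE))
  ph <- classify_phenotype(flags$glut1, flags$pck1, flags$pck2)
  expect_false(anyNA(ph))
  expect_setequal(as.character(unique(ph)),
                  c("glycolytic", "gluconeogenic", "mixed", "unspecified"))
  # spot definitions
  expect_equal(as.character(classify_phenotype(TRUE, FALSE, FALSE)),
               "glycolytic")
  expect_equal(as.character(classify_phenotype(FALSE, FALSE, FALSE)),
               "unspecified")
  expect_equal(as.character(classify_phenotype(FALSE, TRUE, FALSE)),
               "gluconeogenic")
  expect_equal(as.character(classify_phenotype(TRUE, FALSE, TRUE)),
               "mixed")
  # any NA flag -> unclassified, even when two flags would suffice
  expect_true(is.na(classify_phenotype(FALSE, NA, TRUE)))
  expect_true(is.na(classify_phenotype(NA, TRUE, TRUE)))
})

test_that("combined PCK score is the sum, NA-propagating, bounded by 600", {
  expect_equal(combined_pck_score(0, 0), 0)
  expect_equal(combined_pck_score(120, 80), 200)
  expect_equal(combined_pck_score(300, 300), 600)
  expect_true(is.na(combined_pck_score(NA, 100)))
  expect_error(combined_pck_score(301, 0), class = "ihcmet_param_error")
})

test_that("score_cohort aggregates cores and is invariant to core order", {
  rows <- rbind(
    core_rows(1, rep("PCK2", 3), c(3, NA, 0), c(100, NA, 0)),
    core_rows(1, rep("GLUT1", 2), c(1, 1), c(30, 50)),
    core_rows(1, rep("PCK1", 1), 0, 0),
    core_rows(1, rep("LDHB", 1), 2, 90))
  sc <- score_cohort(rows)
  expect_equal(sc$score_PCK2, 150)   # (300 + 0)/2, NA dropped
  expect_equal(sc$score_GLUT1, 40)
  expect_true(sc$pos_PCK2 && sc$pos_GLUT1 && !sc$pos_PCK1)
  expect_equal(as.character(sc$phenotype), "mixed")
  # shuffling and duplicating the core set leaves positivity unchanged
  shuf <- rows[sample(nrow(rows)), ]
  expect_equal(score_cohort(shuf)$pos_PCK2, sc$pos_PCK2)
  dup <- rbind(rows, rows)
  expect_equal(score_cohort(dup)$score_PCK2, sc$score_PCK2)
})

test_that("cohort_summary computes Table-1-style percentages", {
  # 38 positive of 94 evaluable -> 40%; 109 of 258 -> 42%; 0 of 10 -> 0%
  mk <- function(n_pos, n_neg, n_missing = 0) {
    rbind(
      if (n_pos) do.call(rbind, lapply(seq_len(n_pos), function(i)
        core_rows(i, "PCK2", 2, 50))),
      if (n_neg) do.call(rbind, lapply(seq_len(n_neg), function(i)
        core_rows(n_pos + i, "PCK2", 0, 0))),
      if (n_missing) do.call(rbind, lapply(seq_len(n_missing), function(i)
        core_rows(n_pos + n_neg + i, "PCK2", NA, NA))))
  }
  s <- cohort_summary(score_cohort(mk(38, 56, 3)))
  r <- s$positivity[s$positivity$marker == "PCK2", ]
  expect_equal(r$n_evaluable, 94)
  expect_equal(r$percent, 40)
  s2 <- cohort_summary(score_cohort(mk(109, 149)))
  expect_equal(s2$positivity[s2$positivity$marker == "PCK2", "percent"], 42)
  s3 <- cohort_summary(score_cohort(mk(0, 10)))
  expect_equal(s3$positivity[s3$positivity$marker == "PCK2", "percent"], 0)
  # marker never seen -> n 0 and NA percent, never 0
  r4 <- s3$positivity[s3$positivity$marker == "GLUT1", ]
  expect_equal(r4$n_evaluable, 0)
  expect_true(is.na(r4$percent))
})

test_that("phenotype fractions sum to 1 over classifiable samples", {
  co <- generate_cohort(cohort_params(n_patients = 300, seed = 3))
  s <- cohort_summary(score_cohort(co$cohort))
  for (st in unique(s$phenotype$stratum)) {
    f <- s$phenotype$fraction[s$phenotype$stratum == st]
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})
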