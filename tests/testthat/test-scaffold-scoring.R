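# helpers to build assignment tables directly
assign_tbl <- function(ids, scaffold) tibble::tibble(id = ids, scaffold = scaffold)

test_that("P-scores follow the prior-normalized fraction formula", {
  ctx <- enrichment_context(1244, 12440)
  # absent from actives -> 0
  sc <- score_scaffolds(assign_tbl(character(0), character(0)),
                        assign_tbl(paste0("d", 1:5), rep("X", 5)), ctx)
  expect_equal(sc$p_score, 0)
  # exclusive to actives -> 1/prior = 11
  sc <- score_scaffolds(assign_tbl(paste0("f", 1:7), rep("X", 7)),
                        assign_tbl(character(0), character(0)), ctx)
  expect_equal(sc$p_score, 11, tolerance = 1e-12)
  # the null-skeleton worked example: 48 vs 57 at prior 0.090909
  sc <- score_scaffolds(assign_tbl(paste0("f", 1:48), rep("", 48)),
                        assign_tbl(paste0("d", 1:57), rep("", 57)), ctx)
  expect_equal(sc$p_score, (48 / 105) / (1 / 11), tolerance = 1e-12)
  expect_equal(round(sc$p_score, 2), 5.03)
  # scale invariance: multiplying both counts by k leaves the score fixed
  sck <- score_scaffolds(assign_tbl(paste0("f", 1:(48 * 3)), rep("", 144)),
                         assign_tbl(paste0("d", 1:(57 * 3)), rep("", 171)),
                         enrichment_context(3 * 1244, 3 * 12440))
  expect_equal(sck$p_score, sc$p_score, tolerance = 1e-12)
})

test_that("chi-square p-values match a from-scratch Pearson computation", {
  ctx <- enrichment_context(100, 1000)
  cases <- list(c(40, 60), c(5, 5), c(1, 30), c(90, 200))
  for (cs in cases) {
    sc <- score_scaffolds(assign_tbl(paste0("f", seq_len(cs[1])), rep("X", cs[1])),
                          assign_tbl(paste0("d", seq_len(cs[2])), rep("X", cs[2])),
                          ctx)
    expect_equal(sc$chi2_p,
                 pearson_chi2_p(cs[1], 100 - cs[1], cs[2], 1000 - cs[2]),
                 tolerance = 1e-10)
  }
})

test_that("I-scores average member pIC50 and stay within member range", {
  ctx <- enrichment_context(4, 40)
  fi <- assign_tbl(c("a", "b", "c"), c("X", "X", "Y"))
  pic <- tibble::tibble(id = c("a", "b", "c", "d"), pic50 = c(6, 8, 9, 5))
  sc <- score_scaffolds(fi, assign_tbl("d1", "Y"), ctx, pic)
  expect_equal(sc$i_score[sc$scaffold == "X"], 7)
  expect_equal(sc$i_score[sc$scaffold == "Y"], 9)
  expect_true(all(sc$i_score >= 6 & sc$i_score <= 9, na.rm = TRUE))
})

test_that("filter evaluation reproduces definition arithmetic", {
  ctx <- enrichment_context(100, 100)
  fi <- assign_tbl(paste0("f", 1:60), rep("X", 60))
  dcy <- assign_tbl(paste0("d", 1:10), rep("X", 10))
  ev <- evaluate_filter("X", fi, dcy, ctx)
  expect_equal(ev$sensitivity, 0.6)
  expect_equal(ev$specificity, 0.9)
  # filter matching everything
  ctx2 <- enrichment_context(60, 10)
  ev2 <- evaluate_filter("X", fi, dcy, ctx2)
  expect_equal(ev2$sensitivity, 1)
  expect_equal(ev2$specificity, 0)
  expect_warning(ev3 <- evaluate_filter(character(0), fi, dcy, ctx), "empty")
  expect_equal(ev3$sensitivity, 0)
  expect_equal(ev3$specificity, 1)
})

test_that("filter growth is monotone in sensitivity and specificity", {
  set.seed(11)
  scaffolds <- LETTERS[1:8]
  fi <- assign_tbl(rep(paste0("f", 1:50), each = 2),
                   sample(scaffolds, 100, replace = TRUE))
  dcy <- assign_tbl(rep(paste0("d", 1:200), each = 2),
                    sample(scaffolds, 400, replace = TRUE))
  ctx <- enrichment_context(50, 200)
  prev <- list(sensitivity = 0, specificity = 1)
  for (k in seq_along(scaffolds)) {
    ev <- evaluate_filter(scaffolds[1:k], fi, dcy, ctx)
    expect_gte(ev$sensitivity, prev$sensitivity)
    expect_lte(ev$specificity, prev$specificity)
    expect_true(ev$sensitivity >= 0 && ev$sensitivity <= 1)
    expect_true(ev$specificity >= 0 && ev$specificity <= 1)
    prev <- ev
  }
})

test_that("filter selection honors both modes", {
  scores <- tibble::tibble(
    scaffold = c("a", "b", "c", "d"),
    p_score = c(3.2, 2.9, 5.0, 5.0),
    chi2_p = c(0.001, 0.001, 0.001, 0.2),
    i_score = NA_real_
  )
  expect_setequal(select_filter_scaffolds(scores, "p_threshold", 3),
                  c("a", "c", "d"))
  expect_setequal(select_filter_scaffolds(scores, "significance"),
                  c("a", "b", "c"))
})

test_that("repurposing scores add the mean filter I-PR and the skeleton I-BM", {
  pr_scores <- tibble::tibble(scaffold = c("R1", "R2"), i_score = c(6, 8))
  bm_scores <- tibble::tibble(scaffold = "S1", i_score = 7)
  pr <- assign_tbl(c("m1", "m1", "m2"), c("R1", "R2", "R1"))
  bm <- assign_tbl(c("m1", "m2", "m3"), c("S1", "S9", "S9"))
  rp <- repurposing_score(pr, bm, pr_scores, bm_scores,
                          ids = c("m1", "m2", "m3"))
  expect_equal(rp$rps[rp$id == "m1"], mean(c(6, 8)) + 7)  # both terms
  expect_equal(rp$rps[rp$id == "m2"], 6)                  # PR term only
  expect_equal(rp$rps[rp$id == "m3"], 0)                  # no scored scaffold
})

test_that("RpS thresholding meets the sensitivity target", {
  pos <- c(2, 4, 6, 8, 10); neg <- c(1, 3, 5, 7, 9)
  scores <- c(pos, neg); labels <- rep(1:0, each = 5)
  th <- rps_threshold(scores, labels, target_sensitivity = 0.8)
  # largest cutoff keeping 4 of 5 positives strictly above: just below 4
  expect_gte(th$threshold, 3); expect_lt(th$threshold, 4)
  expect_equal(th$sensitivity, 0.8)
  expect_equal(th$auc, concordance_auc(scores, labels))
  # target 1.0: threshold just below the smallest positive
  th2 <- rps_threshold(scores, labels, target_sensitivity = 1)
  expect_lt(th2$threshold, 2)
  expect_equal(th2$sensitivity, 1)
  # perfectly separated sets: AUC 1
  th3 <- rps_threshold(c(5, 6, 7, 1, 2, 3), rep(1:0, each = 3), 0.9)
  expect_equal(th3$auc, 1)
  expect_equal(th3$specificity, 1)
})
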