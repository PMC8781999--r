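test_that("univariate screen matches the pooled-variance t formula", {
  x1 <- c(1.2, 2.1, 1.7); x0 <- c(3.0, 2.6, 3.4)
  desc <- data.frame(d = c(x1, x0))
  labels <- rep(1:0, each = 3)
  out <- univariate_screen(desc, labels)
  # from-scratch pooled t
  sp2 <- ((3 - 1) * var(x1) + (3 - 1) * var(x0)) / 4
  t_hand <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p, p_hand, tolerance = 1e-12)

  # identical class distributions: p near 1, not retained
  desc2 <- data.frame(a = rep(c(1, 2, 3), 2))
  out2 <- univariate_screen(desc2, rep(1:0, each = 3))
  expect_false(out2$retained)
  # well-separated classes retained
  set.seed(1)
  desc3 <- data.frame(a = c(rnorm(20, 10, 0.01), rnorm(20, 0, 0.01)))
  expect_true(univariate_screen(desc3, rep(1:0, each = 20))$retained)
  # constant in both classes: dropped with a warning
  expect_warning(
    out4 <- univariate_screen(data.frame(k = rep(1, 10)), rep(1:0, 5)),
    "zero variance")
  expect_false(out4$retained)
})

test_that("ROC cutoffs satisfy AUC and operating-point constraints", {
  # perfectly separated
  r <- roc_cutoff(c(1, 2, 3, 11, 12, 13), rep(0:1, each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sens, 1); expect_equal(r$spec, 1)
  expect_gt(r$cutoff, 3); expect_lte(r$cutoff, 11)
  # labels independent of values: no rule
  set.seed(42)
  v <- rnorm(200)
  expect_null(roc_cutoff(v, rep(0:1, 100)))
  # rank AUC equals brute-force concordance on a hand-sized set
  vals <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 6)
  labs <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  expect_equal(faahscreen:::rank_auc(vals, labs), concordance_auc(vals, labs))
  # orientation flip: smaller values mark actives
  r2 <- roc_cutoff(c(1, 2, 3, 11, 12, 13), rep(1:0, each = 3))
  expect_equal(r2$orientation, "less_is_active")
  expect_equal(r2$sens, 1); expect_equal(r2$spec, 1)
  expect_equal(flagize(c(2, 12), r2$cutoff, r2$orientation), c(1L, 0L))
})

test_that("the flag transform is a >= indicator after orientation", {
  expect_equal(flagize(5.0, 4.582), 1L)
  expect_equal(flagize(4.582, 4.582), 1L)  # boundary: >= gives 1
  expect_equal(flagize(4.0, 4.582), 0L)
  expect_equal(flagize(c(1, NA, 9), 5), c(0L, NA_integer_, 1L))
  # idempotence on already-binary data with cutoff 0.5
  f <- c(0L, 1L, 1L, 0L)
  expect_equal(flagize(f, 0.5), f)
})

test_that("logistic refits recover the published coefficients", {
  fix <- generate_flag_fixture(5000, seed = 101)
  fit <- fit_flag_logistic(fix$flags, fix$labels)
  truth <- published_model()
  est <- fit$coefficients
  se <- fit$se
  nm_map <- c("(Intercept)" = "intercept", flgWPSA1 = "flgWPSA1",
              flgSpMAD_D = "flgSpMAD_D", flgRDF85m = "flgRDF85m",
              flgCrippenLogP = "flgCrippenLogP")
  for (nm in names(est)) {
    expect_lt(abs(est[[nm]] - truth[[nm_map[[nm]]]]), 3 * se[[nm]])
  }
})

test_that("backward elimination empties an uninformative model", {
  set.seed(5)
  flags <- data.frame(a = rbinom(400, 1, 0.5), b = rbinom(400, 1, 0.5))
  labels <- rbinom(400, 1, 0.3)
  fit <- fit_flag_logistic(flags, labels, selection = "backward_p05")
  expect_setequal(fit$dropped, c("a", "b"))
  # intercept-only fit approximates the base-rate logit
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               log(mean(labels) / (1 - mean(labels))), tolerance = 1e-6)
  exact <- fit_flag_logistic(data.frame(z = rep(0:1, 50)),
                             labels = c(rbinom(50, 1, 0.3), rbinom(50, 1, 0.3)))
  expect_s3_class(exact, "flag_logistic")
})

test_that("degenerate flags are rejected informatively", {
  labels <- rep(0:1, each = 20)
  expect_warning(
    expect_error(
      fit_flag_logistic(data.frame(k = rep(1, 40)), labels),
      "no informative flags"),
    "constant")
  # complete separation names the flag
  expect_error(
    fit_flag_logistic(data.frame(s = labels), labels),
    "separation.*'s'")
})

test_that("the published model evaluates and classifies correctly", {
  f0 <- c(flgWPSA1 = 0, flgSpMAD_D = 0, flgRDF85m = 0, flgCrippenLogP = 0)
  p0 <- predict_published(f0)
  expect_equal(p0$prob, 1 / (1 + exp(2.103)), tolerance = 1e-12)
  expect_equal(round(p0$prob, 3), 0.109)
  expect_false(p0$highly_active)

  f1 <- c(flgWPSA1 = 1, flgSpMAD_D = 1, flgRDF85m = 1, flgCrippenLogP = 1)
  p1 <- predict_published(f1)
  expect_equal(p1$prob, 1 / (1 + exp(-(1.323 + 0.736 + 1.709 + 1.076 - 2.103))),
               tolerance = 1e-12)
  expect_equal(round(p1$prob, 3), 0.939)
  expect_true(p1$highly_active)

  fs <- c(flgWPSA1 = 0, flgSpMAD_D = 1, flgRDF85m = 0, flgCrippenLogP = 0)
  ps <- predict_published(fs)
  expect_equal(round(ps$prob, 3), 0.203)
  expect_false(ps$highly_active)

  expect_error(predict_published(c(flgWPSA1 = 1)), "missing flag")
})

test_that("the published model is monotone in every flag", {
  grid <- expand.grid(flgWPSA1 = 0:1, flgSpMAD_D = 0:1, flgRDF85m = 0:1,
                      flgCrippenLogP = 0:1)
  p <- predict_published(grid)$prob
  for (col in names(grid)) {
    up <- grid; up[[col]] <- 1
    lo <- grid; lo[[col]] <- 0
    expect_true(all(predict_published(up)$prob >= predict_published(lo)$prob))
  }
  expect_true(all(p > 0 & p < 1))
})
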