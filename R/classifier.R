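# Descriptor selection, ROC cutoff discretization, the flag transform and
# the binary logistic activity model.

#' Univariate descriptor screen (t-test)
#'
#' Two-sided independent-samples t-test (pooled variance) per descriptor
#' column between the strong (1) and weak (0) classes. Descriptors are
#' retained at p < `alpha`; near-constant descriptors (zero variance in
#' both classes) are dropped with a warning.
#'
#' @param descriptors data frame of numeric descriptor columns.
#' @param labels binary class labels (1 = strong/active, 0 = weak).
#' @param alpha retention level (default 0.05).
#' @return tibble `descriptor`, `t`, `p`, `retained`.
#' @export
univariate_screen <- function(descriptors, labels, alpha = 0.05) {
  stopifnot(nrow(descriptors) == length(labels))
  res <- lapply(names(descriptors), function(nm) {
    x <- descriptors[[nm]]
    ok <- !is.na(x) & !is.na(labels)
    x1 <- x[ok & labels == 1]; x0 <- x[ok & labels == 0]
    if (length(x1) < 2 || length(x0) < 2) {
      return(tibble(descriptor = nm, t = NA_real_, p = NA_real_,
                    retained = FALSE))
    }
    if (stats::var(x1) == 0 && stats::var(x0) == 0) {
      warning("descriptor '", nm, "' has zero variance in both classes; dropped",
              call. = FALSE)
      return(tibble(descriptor = nm, t = NA_real_, p = NA_real_,
                    retained = FALSE))
    }
    tt <- stats::t.test(x1, x0, var.equal = TRUE)
    tibble(descriptor = nm, t = unname(tt$statistic), p = tt$p.value,
           retained = tt$p.value < alpha)
  })
  dplyr::bind_rows(res)
}

#' ROC-derived discretization cutoff for one descriptor
#'
#' Computes the rank-statistic AUC (orientation flipped so AUC >= 0.5),
#' then scans candidate cutoffs (midpoints between adjacent observed
#' values) for those achieving at least `min_sens` sensitivity and
#' `min_spec` specificity under the flag convention (value >= cutoff
#' predicts active, after orientation alignment). Among feasible cutoffs
#' the one maximizing sensitivity + specificity (Youden) is returned,
#' ties broken toward higher sensitivity. Returns `NULL` when the AUC is
#' below `min_auc` or no cutoff is feasible.
#'
#' @param values numeric descriptor values.
#' @param labels binary labels (1 = active).
#' @param min_sens,min_spec minimum sensitivity and specificity (0.75).
#' @param min_auc minimum AUC to consider the descriptor (0.8).
#' @return A one-row tibble (`cutoff`, `orientation`, `auc`, `sens`,
#'   `spec`) or `NULL`.
#' @export
roc_cutoff <- function(values, labels, min_sens = 0.75, min_spec = 0.75,
                       min_auc = 0.8) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  auc <- rank_auc(values, labels)
  orientation <- "greater_is_active"
  v <- values
  if (!is.na(auc) && auc < 0.5) {
    orientation <- "less_is_active"
    v <- -values
    auc <- 1 - auc
  }
  if (is.na(auc) || auc < min_auc) return(NULL)
  sv <- sort(unique(v))
  cand <- if (length(sv) > 1) (utils::head(sv, -1) + sv[-1]) / 2 else sv
  pos <- v[labels == 1]; neg <- v[labels == 0]
  sens <- vapply(cand, function(c) mean(pos >= c), 0)
  spec <- vapply(cand, function(c) mean(neg < c), 0)
  feas <- sens >= min_sens & spec >= min_spec
  if (!any(feas)) return(NULL)
  j <- order(sens + spec, sens, decreasing = TRUE)
  j <- j[feas[j]][1]
  cut <- cand[j]
  tibble(cutoff = if (orientation == "less_is_active") -cut else cut,
         orientation = orientation, auc = auc, sens = sens[j], spec = spec[j])
}

#' Flag transform
#'
#' Binarizes a descriptor against its cutoff: flag = 1 when the value is
#' greater than or equal to the cutoff, 0 below it. For
#' `less_is_active` rules value and cutoff are negated first, so the flag
#' is 1 when the value is less than or equal to the published cutoff.
#' Missing values give missing flags.
#'
#' @param values numeric vector.
#' @param cutoff numeric cutoff.
#' @param orientation `"greater_is_active"` or `"less_is_active"`.
#' @return integer vector of 0/1 flags (NA where the value is missing).
#' @export
flagize <- function(values, cutoff, orientation = "greater_is_active") {
  if (orientation == "less_is_active") {
    values <- -values; cutoff <- -cutoff
  }
  as.integer(values >= cutoff)
}

#' Published flag-logistic activity model
#'
#' The four-flag binary logistic model discriminating strong from weak
#' FAAH inhibitors:
#' `logit(P) = 1.323*flgWPSA1 + 0.736*flgSpMAD_D + 1.709*flgRDF85m +
#' 1.076*flgCrippenLogP - 2.103`.
#'
#' @return named numeric vector of coefficients (with `intercept`).
#' @export
published_model <- function() {
  c(flgWPSA1 = 1.323, flgSpMAD_D = 0.736, flgRDF85m = 1.709,
    flgCrippenLogP = 1.076, intercept = -2.103)
}

#' Published descriptor cutoffs
#'
#' The ROC-derived discretization cutoffs of the eleven descriptors that
#' separate strong from weak inhibitors at sensitivity and specificity of
#' at least 0.75 each; all are oriented "greater is active".
#'
#' @return tibble `descriptor`, `cutoff`, `orientation`.
#' @export
published_cutoffs <- function() {
  tibble(
    descriptor = c("CrippenLogP", "SpMAD_D", "SpMax5_Bhi", "Au", "Ae",
                   "Ai", "As", "Av", "RDF85m", "WPSA1", "WPSA2"),
    cutoff = c(4.582, 12.569, 3.333, 98.038, 96.826, 100.252, 97.668,
               81.277, 5.699, 382.111, 767.505),
    orientation = "greater_is_active"
  )
}

#' Fit a flag logistic model
#'
#' Maximum-likelihood binary logistic regression of activity on 0/1 flag
#' descriptors, without regularization. Optional backward elimination
#' repeatedly drops the slope with the largest p-value until all
#' remaining slopes have p < 0.05. Constant flags are dropped with a
#' warning; complete separation is a fatal error naming the separating
#' flag.
#'
#' @param flags data frame of 0/1 flag columns.
#' @param labels binary outcome (1 = active).
#' @param selection `"none"` or `"backward_p05"`.
#' @return object of class `flag_logistic`: list with `coefficients`,
#'   `se`, `p`, `sensitivity`, `specificity` (at P = 0.5), `fit` (the
#'   glm), `dropped`.
#' @export
fit_flag_logistic <- function(flags, labels, selection = c("none", "backward_p05")) {
  selection <- match.arg(selection)
  flags <- as.data.frame(flags)
  keep <- vapply(flags, function(x) length(unique(x[!is.na(x)])) > 1, logical(1))
  if (any(!keep)) {
    warning("dropping constant flag(s): ",
            paste(names(flags)[!keep], collapse = ", "), call. = FALSE)
    flags <- flags[, keep, drop = FALSE]
  }
  if (!ncol(flags)) stop("no informative flags left", call. = FALSE)
  dropped <- character(0)
  repeat {
    dat <- cbind(flags, .y = labels)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial()))
    cf <- summary(fit)$coefficients
    if (any(abs(cf[-1, "Estimate"]) > 15)) {
      sep <- rownames(cf)[-1][which.max(abs(cf[-1, "Estimate"]))]
      stop("complete separation detected for flag '", sep, "'", call. = FALSE)
    }
    if (selection == "none") break
    slopes <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
    if (!nrow(slopes) || all(slopes[, "Pr(>|z|)"] < 0.05)) break
    worst <- rownames(slopes)[which.max(slopes[, "Pr(>|z|)"])]
    dropped <- c(dropped, worst)
    flags <- flags[, setdiff(colnames(flags), worst), drop = FALSE]
    if (!ncol(flags)) {  # intercept-only model
      fit <- stats::glm(labels ~ 1, family = stats::binomial())
      cf <- summary(fit)$coefficients
      break
    }
  }
  pr <- stats::predict(fit, type = "response")
  pred <- as.integer(pr > 0.5)
  structure(list(
    coefficients = stats::coef(fit),
    se = cf[, "Std. Error"],
    p = cf[, "Pr(>|z|)"],
    sensitivity = if (any(labels == 1)) mean(pred[labels == 1] == 1) else NA_real_,
    specificity = if (any(labels == 0)) mean(pred[labels == 0] == 0) else NA_real_,
    fit = fit, dropped = dropped
  ), class = "flag_logistic")
}

#' Predict activity probability with the published model
#'
#' Evaluates the published four-flag logistic model on flag vectors and
#' classifies compounds as highly active when the predicted probability
#' exceeds `prob_cut` (default 0.7).
#'
#' @param flags data frame (or named vector) with columns/entries
#'   `flgWPSA1`, `flgSpMAD_D`, `flgRDF85m`, `flgCrippenLogP`.
#' @param prob_cut classification boundary on the probability.
#' @return tibble `prob`, `highly_active`; rows with missing flags give
#'   `NA`.
#' @export
predict_published <- function(flags, prob_cut = 0.7) {
  cf <- published_model()
  if (is.null(dim(flags))) flags <- as.data.frame(as.list(flags))
  need <- setdiff(names(cf), "intercept")
  miss <- setdiff(need, names(flags))
  if (length(miss)) stop("missing flag(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  logit <- cf[["intercept"]] +
    as.matrix(flags[, need, drop = FALSE]) %*% cf[need]
  p <- as.numeric(1 / (1 + exp(-logit)))
  tibble(prob = p, highly_active = p > prob_cut)
}
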