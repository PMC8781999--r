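# Scaffold enrichment (P) and potency (I) scoring against a decoy
# background, scaffold filters, and the composite repurposing score RpS.

#' Enrichment context
#'
#' Set sizes and the prior probability that a compound drawn from the
#' pooled inhibitor + decoy library is an inhibitor,
#' `prior = n_fi / (n_fi + n_dcy)`. With the standard 10:1 decoy ratio the
#' prior is 1/11 = 0.090909..., the random expectation every P-score is
#' measured against (P = 1 means "no better than chance").
#'
#' @param n_fi number of inhibitors.
#' @param n_dcy number of decoys.
#' @return list with `n_fi`, `n_dcy`, `prior`.
#' @export
enrichment_context <- function(n_fi, n_dcy) {
  stopifnot(n_fi > 0, n_dcy > 0)
  list(n_fi = as.integer(n_fi), n_dcy = as.integer(n_dcy),
       prior = n_fi / (n_fi + n_dcy))
}

#' Score scaffolds by enrichment and potency
#'
#' For every scaffold observed in either set, counts the compounds that
#' contain it (at most once per compound), computes the enrichment score
#' `p_score = (count_fi / (count_fi + count_dcy)) / prior`, a chi-square
#' p-value on the 2x2 contains-scaffold x set table (Pearson, no
#' continuity correction), and the potency score `i_score`, the mean
#' pIC50 of the inhibitors containing the scaffold.
#'
#' The P-score ranges from 0 (absent from inhibitors) to `1/prior`
#' (exclusive to them); 1 is the random expectation.
#'
#' @param fi_scaf scaffold assignments for the inhibitor set
#'   (tibble `id`, `scaffold`; see [scaffold_assignments()]).
#' @param dcy_scaf scaffold assignments for the decoy set.
#' @param ctx an [enrichment_context()] giving the full set sizes
#'   (needed because compounds without scaffolds still count).
#' @param fi_pic50 optional tibble `id`, `pic50` for the inhibitors.
#' @return tibble sorted by decreasing `p_score` with columns `scaffold`,
#'   `count_fi`, `count_dcy`, `p_score`, `chi2_p`, `i_score`.
#' @export
score_scaffolds <- function(fi_scaf, dcy_scaf, ctx, fi_pic50 = NULL) {
  fi_scaf <- dplyr::distinct(fi_scaf[, c("id", "scaffold")])
  dcy_scaf <- dplyr::distinct(dcy_scaf[, c("id", "scaffold")])
  a <- table(fi_scaf$scaffold)
  b <- table(dcy_scaf$scaffold)
  scaffolds <- union(names(a), names(b))
  # match() rather than name indexing: the null scaffold is the empty string
  count_fi <- as.integer(a)[match(scaffolds, names(a))]
  count_fi[is.na(count_fi)] <- 0L
  count_dcy <- as.integer(b)[match(scaffolds, names(b))]
  count_dcy[is.na(count_dcy)] <- 0L

  p_score <- (count_fi / (count_fi + count_dcy)) / ctx$prior
  chi2_p <- vapply(seq_along(scaffolds), function(i) {
    tab <- matrix(c(count_fi[i], ctx$n_fi - count_fi[i],
                    count_dcy[i], ctx$n_dcy - count_dcy[i]), nrow = 2)
    if (any(tab < 0)) return(NA_real_)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, 0)

  i_score <- rep(NA_real_, length(scaffolds))
  if (!is.null(fi_pic50)) {
    joined <- merge(fi_scaf, fi_pic50[, c("id", "pic50")], by = "id")
    means <- tapply(joined$pic50, joined$scaffold, mean, na.rm = TRUE)
    i_score <- as.numeric(means[scaffolds])
  }

  out <- tibble(scaffold = scaffolds, count_fi = count_fi,
                count_dcy = count_dcy, p_score = p_score,
                chi2_p = chi2_p, i_score = i_score)
  out[order(-out$p_score, out$scaffold), , drop = FALSE]
}

#' Select filter scaffolds
#'
#' Two selection modes mirror the two scaffold families: `"significance"`
#' (skeleton-style) keeps scaffolds with `p_score > 1` whose 2x2
#' chi-square is significant at `alpha`; `"p_threshold"` (ring-style)
#' keeps scaffolds with `p_score >= threshold` (default 3).
#'
#' @param scores output of [score_scaffolds()].
#' @param mode `"significance"` or `"p_threshold"`.
#' @param threshold P-score threshold for `"p_threshold"` mode.
#' @param alpha significance level for `"significance"` mode.
#' @return character vector of selected scaffold SMILES.
#' @export
select_filter_scaffolds <- function(scores,
                                    mode = c("significance", "p_threshold"),
                                    threshold = 3, alpha = 0.05) {
  mode <- match.arg(mode)
  keep <- if (mode == "significance") {
    scores$p_score > 1 & !is.na(scores$chi2_p) & scores$chi2_p < alpha
  } else {
    scores$p_score >= threshold
  }
  scores$scaffold[keep]
}

#' Sensitivity and specificity of a scaffold filter
#'
#' A compound "hits" the filter when it contains at least one filter
#' scaffold. Sensitivity is the hit fraction among inhibitors,
#' specificity one minus the hit fraction among decoys.
#'
#' @param filter_scaffolds character vector of scaffold SMILES.
#' @param fi_scaf,dcy_scaf scaffold assignments of the two sets.
#' @param ctx an [enrichment_context()] with the full set sizes.
#' @return list with `sensitivity`, `specificity`, `hits_fi`, `hits_dcy`.
#' @export
evaluate_filter <- function(filter_scaffolds, fi_scaf, dcy_scaf, ctx) {
  if (!length(filter_scaffolds)) {
    warning("empty filter set: sensitivity 0, specificity 1", call. = FALSE)
    return(list(sensitivity = 0, specificity = 1, hits_fi = 0L, hits_dcy = 0L))
  }
  hits_fi <- length(unique(fi_scaf$id[fi_scaf$scaffold %in% filter_scaffolds]))
  hits_dcy <- length(unique(dcy_scaf$id[dcy_scaf$scaffold %in% filter_scaffolds]))
  list(sensitivity = hits_fi / ctx$n_fi,
       specificity = 1 - hits_dcy / ctx$n_dcy,
       hits_fi = hits_fi, hits_dcy = hits_dcy)
}

#' Repurposing score (RpS)
#'
#' For each compound, the mean potency score (I-score) of the filter
#' plain-ring fragments it contains, plus the I-score of its Bemis-Murcko
#' skeleton. A term without a scored scaffold contributes 0, so compounds
#' containing no scored scaffold at all get RpS = 0.
#'
#' @param pr_assign plain-ring assignments of the compounds
#'   (tibble `id`, `scaffold`).
#' @param bm_assign skeleton assignments of the compounds.
#' @param pr_scores tibble `scaffold`, `i_score` for the filter rings
#'   (typically [score_scaffolds()] rows restricted to the selected
#'   filter set).
#' @param bm_scores tibble `scaffold`, `i_score` for the scored skeletons.
#' @param ids compound identifiers to report (defaults to all ids present
#'   in either assignment table).
#' @return tibble `id`, `rps`, `i_pr_mean`, `i_bm`.
#' @export
repurposing_score <- function(pr_assign, bm_assign, pr_scores, bm_scores,
                              ids = NULL) {
  if (is.null(ids)) ids <- unique(c(pr_assign$id, bm_assign$id))
  pr_tab <- merge(dplyr::distinct(pr_assign[, c("id", "scaffold")]),
                  pr_scores[!is.na(pr_scores$i_score), c("scaffold", "i_score")],
                  by = "scaffold")
  ipr <- tapply(pr_tab$i_score, pr_tab$id, mean)
  bm_tab <- merge(dplyr::distinct(bm_assign[, c("id", "scaffold")]),
                  bm_scores[!is.na(bm_scores$i_score), c("scaffold", "i_score")],
                  by = "scaffold")
  # a compound has one skeleton; if duplicated rows slipped in, average
  ibm <- tapply(bm_tab$i_score, bm_tab$id, mean)
  i_pr <- as.numeric(ipr[ids]); i_pr[is.na(i_pr)] <- 0
  i_bm <- as.numeric(ibm[ids]); i_bm[is.na(i_bm)] <- 0
  tibble(id = ids, rps = i_pr + i_bm, i_pr_mean = i_pr, i_bm = i_bm)
}

# Rank-statistic AUC: probability that a random positive scores above a
# random negative (ties count 1/2). Equals the Mann-Whitney U statistic
# normalized by n_pos * n_neg.
rank_auc <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC threshold for the repurposing score
#'
#' Chooses the largest cutoff `t` (midpoint between adjacent observed
#' scores) such that the fraction of positives scoring strictly above `t`
#' still meets the target sensitivity. Also reports the rank-statistic
#' AUC and the specificity achieved at the chosen threshold.
#'
#' @param scores numeric RpS values.
#' @param labels binary labels (1 = inhibitor, 0 = decoy).
#' @param target_sensitivity minimum sensitivity to preserve (default 0.9).
#' @return list with `threshold`, `auc`, `sensitivity`, `specificity`.
#' @export
rps_threshold <- function(scores, labels, target_sensitivity = 0.9) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both labels must be present", call. = FALSE)
  }
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v <- sort(unique(scores))
  cand <- c(min(v) - 1, (utils::head(v, -1) + v[-1]) / 2)
  sens <- vapply(cand, function(t) mean(pos > t), 0)
  feas <- which(sens >= target_sensitivity)
  if (!length(feas)) {
    warning("target sensitivity unreachable; returning just below the ",
            "minimum positive score", call. = FALSE)
    thr <- min(pos) - 1e-9
  } else {
    thr <- max(cand[feas])
  }
  list(threshold = thr,
       auc = rank_auc(scores, labels),
       sensitivity = mean(pos > thr),
       specificity = mean(neg <= thr))
}
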