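# The candidate screening cascade and the docking-result post-filter.

#' Substitution-count limits of the inhibitor set
#'
#' Upper bounds on halogen substitution observed across the inhibitor
#' set: at most 8 fluorine, 3 chlorine, 2 bromine and 1 iodine atoms
#' (all lower bounds are 0). Candidates outside these ranges are
#' structurally unlike any known inhibitor.
#'
#' @return named integer vector of maxima.
#' @export
substitution_limits <- function() {
  c(nF = 8L, nCl = 3L, nBr = 2L, nI = 1L)
}

#' Halogen substitution filter
#'
#' Passes compounds whose halogen substitution counts all fall within the
#' inhibitor-set ranges (boundary inclusive).
#'
#' @param subst tibble from [side_chain_stats()] (needs `nF`, `nCl`,
#'   `nBr`, `nI`).
#' @param limits named maxima, see [substitution_limits()].
#' @return logical vector.
#' @export
substitution_filter <- function(subst, limits = substitution_limits()) {
  subst$nF <= limits[["nF"]] & subst$nCl <= limits[["nCl"]] &
    subst$nBr <= limits[["nBr"]] & subst$nI <= limits[["nI"]]
}

#' Ligand efficiency
#'
#' Binding energy per heavy atom, `LE = |dG| / n_heavy`. Docking energies
#' are negative for binders while ligand efficiency is conventionally
#' reported positive, hence the absolute value.
#'
#' @param dg binding energy in kcal/mol.
#' @param n_heavy heavy-atom count (>= 1).
#' @return numeric vector.
#' @export
ligand_efficiency <- function(dg, n_heavy) {
  if (any(n_heavy < 1, na.rm = TRUE)) {
    stop("ligand efficiency undefined for n_heavy < 1", call. = FALSE)
  }
  abs(dg) / n_heavy
}

#' Docking-result post-filter
#'
#' Passes ligands with ligand efficiency inside `[le_low, le_high]` and
#' binding energy at most `dg_max` (more negative = stronger binding).
#' The upper efficiency bound discards small ligands whose high per-atom
#' efficiency does not translate into potency; the lower bound and the
#' energy cutoff remove weak binders. Rows flagged `covalent` can be
#' exempted from the energy cutoff (covalent poses score poorly on
#' non-covalent terms); the exemption is off by default.
#'
#' @param dock tibble with `id`, `dg` (kcal/mol) and either `le` or
#'   `n_heavy` (to compute it); optional logical `covalent`.
#' @param le_low,le_high ligand-efficiency window (0.25-0.4).
#' @param dg_max maximum acceptable binding energy (-6 kcal/mol).
#' @param exempt_covalent exempt covalent poses from the energy cutoff?
#' @return the table with columns `le` and `pass_docking` added.
#' @export
docking_filter <- function(dock, le_low = 0.25, le_high = 0.4, dg_max = -6,
                           exempt_covalent = FALSE) {
  if (!"le" %in% names(dock)) {
    dock$le <- ligand_efficiency(dock$dg, dock$n_heavy)
  }
  ok_le <- dock$le >= le_low & dock$le <= le_high
  ok_dg <- dock$dg <= dg_max
  if (exempt_covalent && "covalent" %in% names(dock)) {
    ok_dg <- ok_dg | (dock$covalent %in% TRUE)
  }
  dock$pass_docking <- ok_le & ok_dg
  dock
}

#' Screen a candidate library
#'
#' Applies the full repurposing cascade to candidate records:
#' \enumerate{
#'   \item property window + organometallic removal,
#'   \item halogen substitution filter,
#'   \item repurposing score `RpS` strictly above `rps_cut`,
#'   \item published-model probability strictly above `prob_cut`,
#'   \item docking post-filter (only when a docking table is supplied).
#' }
#' Stages short-circuit: a compound failing a stage is not evaluated at
#' later stages (`NA` in those columns). Descriptors (stage 4) are only
#' computed for stage-3 survivors. Results are ordered by decreasing RpS,
#' ties broken by id; per-stage survivor counts are reported via
#' `message()` and attached as the `"stage_counts"` attribute.
#'
#' @param candidates compound-record tibble.
#' @param bm_scores,pr_scores scored scaffold tables (`scaffold`,
#'   `i_score`) for skeletons and filter rings, see [score_scaffolds()]
#'   and [select_filter_scaffolds()].
#' @param rps_cut RpS threshold (default 5.17).
#' @param prob_cut probability threshold (default 0.7).
#' @param window property window for stage 1.
#' @param docking optional docking table (`id`, `dg`, optional
#'   `covalent`).
#' @param seed embedding seed for the descriptor stage.
#' @param ... passed to [docking_filter()].
#' @return tibble of per-candidate screening results.
#' @export
screen_library <- function(candidates, bm_scores, pr_scores, rps_cut = 5.17,
                           prob_cut = 0.7, window = property_window(),
                           docking = NULL, seed = 1, ...) {
  res <- tibble(
    id = candidates$id,
    pass_property = NA, pass_substitution = NA,
    rps = NA_real_, pass_rps = NA,
    prob = NA_real_, pass_prob = NA,
    pass_docking = NA, final = FALSE
  )
  # stage 1: property window + organometallics
  suppressMessages(f1 <- property_filter(candidates, window,
                                         drop_organometallic = TRUE))
  res$pass_property <- res$id %in% f1$id
  s1 <- candidates[candidates$id %in% f1$id, , drop = FALSE]

  # stage 2: substitution ranges
  if (nrow(s1)) {
    subst <- side_chain_stats(s1)
    ok2 <- substitution_filter(subst)
    res$pass_substitution[match(s1$id, res$id)] <- ok2
    s2 <- s1[ok2, , drop = FALSE]
  } else s2 <- s1

  # stage 3: repurposing score
  if (nrow(s2)) {
    pr_assign <- scaffold_assignments(s2, "pr")
    bm_assign <- scaffold_assignments(s2, "bm")
    rps <- repurposing_score(pr_assign, bm_assign, pr_scores, bm_scores,
                             ids = s2$id)
    res$rps[match(rps$id, res$id)] <- rps$rps
    ok3 <- rps$rps > rps_cut
    res$pass_rps[match(rps$id, res$id)] <- ok3
    s3 <- s2[ok3, , drop = FALSE]
  } else s3 <- s2

  # stage 4: published-model probability
  if (nrow(s3)) {
    desc <- descriptor_panel(s3, seed = seed)
    cuts <- published_cutoffs()
    fl <- tibble(
      flgWPSA1 = flagize(desc$WPSA1, cuts$cutoff[cuts$descriptor == "WPSA1"]),
      flgSpMAD_D = flagize(desc$SpMAD_D, cuts$cutoff[cuts$descriptor == "SpMAD_D"]),
      flgRDF85m = flagize(desc$RDF85m, cuts$cutoff[cuts$descriptor == "RDF85m"]),
      flgCrippenLogP = flagize(desc$CrippenLogP, cuts$cutoff[cuts$descriptor == "CrippenLogP"])
    )
    pp <- predict_published(fl, prob_cut = prob_cut)
    res$prob[match(s3$id, res$id)] <- pp$prob
    ok4 <- pp$highly_active %in% TRUE
    res$pass_prob[match(s3$id, res$id)] <- ok4
    s4 <- s3[ok4, , drop = FALSE]
  } else s4 <- s3

  # stage 5: docking post-filter (optional)
  if (!is.null(docking) && nrow(s4)) {
    d <- merge(tibble(id = s4$id,
                      n_heavy = s4$n_heavy), docking, by = "id")
    d <- docking_filter(d, ...)
    res$pass_docking[match(d$id, res$id)] <- d$pass_docking
    final_ids <- d$id[d$pass_docking]
  } else if (is.null(docking)) {
    final_ids <- s4$id
  } else final_ids <- character(0)

  res$final <- res$id %in% final_ids
  counts <- c(input = nrow(candidates), property = nrow(s1),
              substitution = nrow(s2), rps = nrow(s3), probability = nrow(s4),
              docking = if (is.null(docking)) NA_integer_ else length(final_ids))
  message("screen_library survivors: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  res <- res[order(-ifelse(is.na(res$rps), -Inf, res$rps), res$id), , drop = FALSE]
  attr(res, "stage_counts") <- counts
  res
}
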