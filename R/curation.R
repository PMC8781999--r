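#' Physicochemical property window
#'
#' The closed property intervals used to match decoys (and screening
#' candidates) to the inhibitor set: molecular weight 150-620 g/mol, logP
#' -0.8 to 9.2, 1-12 hydrogen-bond acceptors and 0-4 donors.
#'
#' @param mw_min,mw_max molecular weight bounds (g/mol).
#' @param logp_min,logp_max logP bounds.
#' @param hba_min,hba_max hydrogen-bond acceptor count bounds.
#' @param hbd_min,hbd_max hydrogen-bond donor count bounds.
#' @return A named list of class `property_window`.
#' @export
property_window <- function(mw_min = 150, mw_max = 620,
                            logp_min = -0.8, logp_max = 9.2,
                            hba_min = 1, hba_max = 12,
                            hbd_min = 0, hbd_max = 4) {
  w <- list(mw_min = mw_min, mw_max = mw_max, logp_min = logp_min,
            logp_max = logp_max, hba_min = hba_min, hba_max = hba_max,
            hbd_min = hbd_min, hbd_max = hbd_max)
  for (p in c("mw", "logp", "hba", "hbd")) {
    if (w[[paste0(p, "_min")]] > w[[paste0(p, "_max")]]) {
      stop("property window has min > max for ", p, call. = FALSE)
    }
  }
  structure(w, class = "property_window")
}

#' Merge duplicate activity records
#'
#' Duplicates (identical canonical SMILES) are merged into a single entry
#' whose IC50 is the arithmetic mean of the member IC50 values; pIC50 is
#' recomputed as -log10 of the merged IC50. Records with missing or
#' non-positive IC50 (including qualified values such as ">1e-6" dropped
#' at parse time) are removed with a warning.
#'
#' @param records compound-record tibble with a `pic50` column.
#' @return tibble with one row per distinct canonical structure.
#' @export
merge_duplicates <- function(records) {
  bad <- is.na(records$pic50)
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) without a usable IC50", sum(bad)),
            call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) stop("no records with usable IC50 values", call. = FALSE)
  records %>%
    group_by(.data$smiles_canonical) %>%
    summarise(
      id = .data$id[1],
      smiles_input = .data$smiles_input[1],
      mw = .data$mw[1], logp = .data$logp[1], hba = .data$hba[1],
      hbd = .data$hbd[1], n_heavy = .data$n_heavy[1],
      pic50 = -log10(mean(10^(-.data$pic50))),
      label = "unlabeled",
      set_tag = .data$set_tag[1],
      .groups = "drop"
    ) %>%
    select("id", "smiles_input", "smiles_canonical", "mw", "logp", "hba",
           "hbd", "n_heavy", "pic50", "label", "set_tag")
}

#' Label strong and weak inhibitors
#'
#' Potency classes follow strict inequalities: strong inhibitors have
#' pIC50 above `strong_above` (default 8), weak inhibitors below
#' `weak_below` (default 5); everything else, including boundary values,
#' stays unlabeled. Strong compounds are the actives (1) and weak the
#' inactives (0) for classifier training.
#'
#' @param records compound-record tibble with `pic50`.
#' @param strong_above,weak_below pIC50 thresholds.
#' @return The records with updated `label` and a binary `active` column
#'   (`NA` for unlabeled rows).
#' @export
label_activity <- function(records, strong_above = 8, weak_below = 5) {
  lab <- rep("unlabeled", nrow(records))
  lab[!is.na(records$pic50) & records$pic50 > strong_above] <- "strong"
  lab[!is.na(records$pic50) & records$pic50 < weak_below] <- "weak"
  records$label <- lab
  records$active <- ifelse(lab == "strong", 1L,
                           ifelse(lab == "weak", 0L, NA_integer_))
  records
}

#' Filter compounds by property window
#'
#' Retains compounds whose MW, logP, HBA and HBD all fall inside the
#' closed window intervals, optionally also removing organometallics.
#' Per-rule rejection counts are attached as the `"rejections"` attribute
#' and reported via `message()`.
#'
#' @param records compound-record tibble.
#' @param window a [property_window()].
#' @param drop_organometallic remove compounds with disallowed elements?
#' @return filtered tibble with a `rejections` attribute.
#' @export
property_filter <- function(records, window = property_window(),
                            drop_organometallic = TRUE) {
  ok_mw <- records$mw >= window$mw_min & records$mw <= window$mw_max
  ok_lp <- records$logp >= window$logp_min & records$logp <= window$logp_max
  ok_ha <- records$hba >= window$hba_min & records$hba <= window$hba_max
  ok_hd <- records$hbd >= window$hbd_min & records$hbd <= window$hbd_max
  ok_om <- if (drop_organometallic) !is_organometallic(records) else TRUE
  rej <- c(mw = sum(!ok_mw, na.rm = TRUE), logp = sum(!ok_lp, na.rm = TRUE),
           hba = sum(!ok_ha, na.rm = TRUE), hbd = sum(!ok_hd, na.rm = TRUE),
           organometallic = if (drop_organometallic) sum(ok_mw & ok_lp & ok_ha & ok_hd & is_organometallic(records), na.rm = TRUE) else 0L)
  keep <- ok_mw & ok_lp & ok_ha & ok_hd & ok_om
  keep[is.na(keep)] <- FALSE
  message(sprintf("property_filter: retained %d/%d (rejections: %s)",
                  sum(keep), length(keep),
                  paste(names(rej), rej, sep = "=", collapse = ", ")))
  out <- records[keep, , drop = FALSE]
  attr(out, "rejections") <- rej
  out
}

#' Sample a property-matched decoy set
#'
#' Draws a uniform random sample without replacement from a
#' property-filtered decoy pool, ten times (by default) the size of the
#' inhibitor set and structurally disjoint from it (by canonical SMILES).
#'
#' @param pool compound-record tibble, already filtered to the inhibitor
#'   property window.
#' @param fi inhibitor records the decoys must not overlap.
#' @param ratio decoys per inhibitor (default 10).
#' @param seed integer seed; the same seed reproduces the same sample.
#' @return tibble of `ratio * nrow(fi)` decoy records tagged `"DCY"`.
#' @export
sample_decoys <- function(pool, fi, ratio = 10, seed = 1) {
  pool <- pool[!(pool$smiles_canonical %in% fi$smiles_canonical), , drop = FALSE]
  pool <- pool[!duplicated(pool$smiles_canonical), , drop = FALSE]
  need <- ratio * nrow(fi)
  if (nrow(pool) < need) {
    stop(sprintf("decoy pool too small: need %d, have %d after exclusions",
                 need, nrow(pool)), call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(nrow(pool), need)
  out <- pool[idx, , drop = FALSE]
  out$set_tag <- "DCY"
  out
}
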