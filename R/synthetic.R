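# Synthetic-library generator: combinatorial structure libraries with
# planted scaffold enrichment, scaffold-dependent potency, and
# activity-correlated docking scores. Every stage of the pipeline can be
# exercised against known ground truth without any database download.

# default decoration pools; prefixes attach via their last written atom,
# suffixes via their first, so paste0(prefix, core, suffix) is a valid
# SMILES with both substituents single-bonded to the core ring system.
.PREFIXES <- c("CCCC", "CCCCC", "CC(C)CC", "CCOCC", "CCCOC", "OCCCC",
               "FC(F)(F)CC", "ClCCCC", "OC(=O)CCC", "NC(=O)CCC",
               "CCCCN(C)C", "O=[N+]([O-])CCC")
# every suffix carries an N or O so each assembled molecule satisfies the
# hydrogen-bond-acceptor window bound (HBA >= 1)
.SUFFIXES <- c("CCOCC", "CC(=O)OC", "CCCO", "CC(=O)N", "CCN(C)C", "CC#N",
               "CCOC(C)=O", "CCCC(=O)O", "CCNC(C)=O", "CCCOC", "CCC#N",
               "CCCN")
.CORES <- c(benzene = "c1ccccc1", pyridine = "c1ccncc1",
            piperazine = "N1CCN(CC1)", piperidine = "C1CCN(CC1)",
            morpholine = "C1COCCN1", thiophene = "c1ccsc1",
            furan = "c1ccoc1", pyrimidine = "c1cncnc1",
            cyclohexane = "C1CCCCC1", pyrrolidine = "C1CCN(C1)",
            naphthalene = "c1ccc2ccccc2c1", imidazole = "c1cncn1")

#' Configuration for the synthetic library generator
#'
#' The generator assembles structures as prefix + ring core + suffix and
#' plants scaffold enrichment: enriched cores are over-sampled in the
#' inhibitor-like set (proportionally to their odds) and under-sampled
#' (1/odds) in the decoy set. Inhibitors on an enriched core draw pIC50
#' from the potent class distribution, the rest from the weak class, so
#' potency is scaffold-dependent. The prefix/suffix pools are split
#' between the two sets, which guarantees structural disjointness.
#'
#' @param n_fi number of inhibitor-like compounds (default 200).
#' @param decoy_ratio decoys per inhibitor (default 10).
#' @param enriched_scaffolds named numeric vector: core SMILES ->
#'   enrichment odds (> 1 enriches; default piperazine at odds 20).
#' @param cores named character vector of ring-core SMILES.
#' @param prefixes,suffixes substituent pools.
#' @param pic50_active_mean,pic50_active_sd potent-class pIC50
#'   distribution (default N(8.5, 0.6)).
#' @param pic50_inactive_mean,pic50_inactive_sd weak-class distribution
#'   (default N(4.5, 0.4)).
#' @param dock_intercept mean docking energy of the weak class
#'   (kcal/mol, default -8.12).
#' @param dock_slope shift added for the strong class (default -1.59,
#'   giving a strong-class mean of -9.71 kcal/mol).
#' @param dock_noise_sd Gaussian noise SD; length 2 = (weak, strong),
#'   default c(1.44, 1.14).
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_fi = 200, decoy_ratio = 10,
                             enriched_scaffolds = c("N1CCN(CC1)" = 20),
                             cores = .CORES,
                             prefixes = .PREFIXES, suffixes = .SUFFIXES,
                             pic50_active_mean = 8.5, pic50_active_sd = 0.6,
                             pic50_inactive_mean = 4.5, pic50_inactive_sd = 0.4,
                             dock_intercept = -8.12, dock_slope = -1.59,
                             dock_noise_sd = c(1.44, 1.14), seed = 1) {
  stopifnot(n_fi >= 50, decoy_ratio >= 1, all(enriched_scaffolds > 0),
            pic50_active_sd > 0, pic50_inactive_sd > 0,
            all(dock_noise_sd >= 0))
  structure(list(
    n_fi = as.integer(n_fi), decoy_ratio = as.integer(decoy_ratio),
    enriched_scaffolds = enriched_scaffolds, cores = cores,
    prefixes = prefixes, suffixes = suffixes,
    pic50_active_mean = pic50_active_mean, pic50_active_sd = pic50_active_sd,
    pic50_inactive_mean = pic50_inactive_mean,
    pic50_inactive_sd = pic50_inactive_sd,
    dock_intercept = dock_intercept, dock_slope = dock_slope,
    dock_noise_sd = rep(dock_noise_sd, length.out = 2), seed = seed
  ), class = "synthetic_config")
}

#' Generate a synthetic inhibitor/decoy library
#'
#' Draws `n_fi` inhibitor-like compounds (core sampled proportionally to
#' enrichment odds, decorated with substituents from the FI half of the
#' pools, pIC50 from the core's potency class) and `decoy_ratio * n_fi`
#' decoys (core odds inverted, substituents from the decoy half of the
#' pools, no pIC50). All structures pass the standard property window;
#' the two sets are disjoint by canonical SMILES. Fully reproducible for
#' a fixed config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `fi` (records with `pic50`, `label`, `core`), `dcy`
#'   (records with `core`) and `truth` (tibble `core`, `smiles`, `odds`,
#'   `class`).
#' @export
generate_library <- function(config = synthetic_config()) {
  set.seed(config$seed)
  cores <- config$cores
  odds <- rep(1, length(cores))
  names(odds) <- cores
  planted <- intersect(names(config$enriched_scaffolds), cores)
  if (length(planted) < length(config$enriched_scaffolds)) {
    stop("enriched scaffolds must be members of the core pool", call. = FALSE)
  }
  odds[planted] <- config$enriched_scaffolds[planted]

  half <- function(x, first) {
    idx <- seq_along(x) %% 2 == 1
    if (first) x[idx] else x[!idx]
  }
  build <- function(n, w, pre, suf) {
    ci <- sample.int(length(cores), n, replace = TRUE, prob = w)
    tibble(core = unname(cores[ci]),
           smiles = paste0(sample(pre, n, replace = TRUE), cores[ci],
                           sample(suf, n, replace = TRUE)))
  }
  fi_raw <- build(config$n_fi, odds,
                  half(config$prefixes, TRUE), half(config$suffixes, TRUE))
  n_dcy <- config$n_fi * config$decoy_ratio
  dcy_raw <- build(n_dcy, 1 / odds,
                   half(config$prefixes, FALSE), half(config$suffixes, FALSE))

  enriched <- fi_raw$core %in% planted
  pic50 <- ifelse(enriched,
                  stats::rnorm(config$n_fi, config$pic50_active_mean,
                               config$pic50_active_sd),
                  stats::rnorm(config$n_fi, config$pic50_inactive_mean,
                               config$pic50_inactive_sd))

  fi <- suppressWarnings(compound_records(
    fi_raw$smiles, id = sprintf("FI%04d", seq_len(config$n_fi)),
    pic50 = pic50, set_tag = "FI"))
  fi$core <- fi_raw$core[match(fi$id, sprintf("FI%04d", seq_len(config$n_fi)))]
  fi <- label_activity(fi)
  dcy <- suppressWarnings(compound_records(
    dcy_raw$smiles, id = sprintf("DCY%05d", seq_len(n_dcy)),
    set_tag = "DCY"))
  dcy$core <- dcy_raw$core[match(dcy$id, sprintf("DCY%05d", seq_len(n_dcy)))]

  # structural disjointness: the split substituent pools make collisions
  # rare (symmetric cores can still produce equivalent molecules); any
  # colliding decoy is resampled deterministically
  for (it in 1:25) {
    clash <- which(dcy$smiles_canonical %in% fi$smiles_canonical)
    if (!length(clash)) break
    repl <- build(length(clash), 1 / odds,
                  half(config$prefixes, FALSE), half(config$suffixes, FALSE))
    rec <- suppressWarnings(compound_records(
      repl$smiles, id = dcy$id[clash], set_tag = "DCY"))
    rec$core <- repl$core
    dcy[clash, names(rec)] <- rec
  }
  if (any(dcy$smiles_canonical %in% fi$smiles_canonical)) {
    stop("generator invariant violated: FI and DCY overlap", call. = FALSE)
  }

  w <- property_window()
  in_window <- function(r) {
    r$mw >= w$mw_min & r$mw <= w$mw_max &
      r$logp >= w$logp_min & r$logp <= w$logp_max &
      r$hba >= w$hba_min & r$hba <= w$hba_max &
      r$hbd >= w$hbd_min & r$hbd <= w$hbd_max
  }
  if (!all(in_window(fi), na.rm = TRUE) || !all(in_window(dcy), na.rm = TRUE) ||
      nrow(fi) < config$n_fi || nrow(dcy) < n_dcy) {
    stop("generator produced structures outside the property window; ",
         "check the substituent pools", call. = FALSE)
  }

  # canonical plain-ring form of each core, for ground-truth comparisons
  probe <- paste0("C", unname(cores), "C")
  pr_can <- vapply(plain_rings(probe), function(x)
    if (length(x)) x[1] else "", "")
  truth <- tibble(core = names(cores), smiles = unname(cores),
                  pr_canonical = pr_can,
                  odds = unname(odds[cores]),
                  class = ifelse(cores %in% planted, "active", "inactive"))
  list(fi = fi, dcy = dcy, truth = truth)
}

#' Simulate docking scores correlated with activity
#'
#' Draws a binding energy per compound from
#' `dG = intercept + slope * shift + noise`, where the shift is 1 for
#' strong inhibitors, 0 for weak ones, and interpolates linearly in
#' pIC50 between the two class centers otherwise (0 when no pIC50 is
#' available). With the default parameters the strong and weak class
#' means reproduce -9.71 and -8.12 kcal/mol.
#'
#' @param records compound-record tibble (needs `n_heavy`; uses `label`
#'   and `pic50` when present).
#' @param config a [synthetic_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @return tibble `id`, `dg`, `n_heavy`, `le`.
#' @export
simulate_docking <- function(records, config = synthetic_config(),
                             seed = config$seed) {
  set.seed(seed)
  lab <- if ("label" %in% names(records)) records$label else rep("unlabeled", nrow(records))
  pic <- if ("pic50" %in% names(records)) records$pic50 else rep(NA_real_, nrow(records))
  shift <- ifelse(lab == "strong", 1, ifelse(lab == "weak", 0, NA))
  interp <- (pic - config$pic50_inactive_mean) /
    (config$pic50_active_mean - config$pic50_inactive_mean)
  shift[is.na(shift)] <- pmin(pmax(interp[is.na(shift)], 0), 1)
  shift[is.na(shift)] <- 0
  sd_i <- config$dock_noise_sd[1] +
    shift * (config$dock_noise_sd[2] - config$dock_noise_sd[1])
  dg <- config$dock_intercept + config$dock_slope * shift +
    stats::rnorm(nrow(records), 0, sd_i)
  tibble(id = records$id, dg = dg, n_heavy = records$n_heavy,
         le = ligand_efficiency(dg, records$n_heavy))
}

#' Generate a flag/label fixture from the published model
#'
#' Draws `n` independent Bernoulli(0.5) flag vectors and labels from the
#' published logistic model's probabilities — the standard fixture for
#' coefficient-recovery tests.
#'
#' @param n number of observations (>= 100).
#' @param coefficients named coefficient vector (with `intercept`);
#'   defaults to [published_model()].
#' @param seed RNG seed.
#' @return list with `flags` (tibble) and `labels` (0/1 vector).
#' @export
generate_flag_fixture <- function(n, coefficients = published_model(),
                                  seed = 1) {
  stopifnot(n >= 100)
  set.seed(seed)
  nm <- setdiff(names(coefficients), "intercept")
  flags <- as.data.frame(matrix(stats::rbinom(n * length(nm), 1, 0.5), n,
                                dimnames = list(NULL, nm)))
  logit <- coefficients[["intercept"]] +
    as.matrix(flags) %*% coefficients[nm]
  p <- 1 / (1 + exp(-logit))
  labels <- stats::rbinom(n, 1, p)
  list(flags = tibble::as_tibble(flags), labels = labels)
}
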