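# shared fixtures: small structure sets and tabular record builders

quiet_records <- function(smiles, ...) {
  suppressWarnings(compound_records(smiles, ...))
}

# fabricated record rows for purely tabular operations (no chemistry)
fake_records <- function(n, prefix = "cmpd", mw = 300, logp = 2, hba = 3,
                         hbd = 1, n_heavy = 20, pic50 = NA_real_) {
  tibble::tibble(
    id = paste0(prefix, seq_len(n)),
    smiles_input = paste0("FAKE", prefix, seq_len(n)),
    smiles_canonical = paste0("FAKE", prefix, seq_len(n)),
    mw = rep_len(mw, n), logp = rep_len(logp, n),
    hba = rep_len(hba, n), hbd = rep_len(hbd, n),
    n_heavy = rep_len(n_heavy, n), pic50 = rep_len(pic50, n),
    label = "unlabeled", set_tag = "candidate"
  )
}

# brute-force pairwise-concordance AUC (independent oracle)
concordance_auc <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# from-scratch Pearson chi-square p-value for a 2x2 table
pearson_chi2_p <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  expd <- outer(rs, cs) / n
  stat <- sum((tab - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
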