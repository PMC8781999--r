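test_that("substitution filter applies inclusive inhibitor-set ranges", {
  subst <- tibble::tibble(nF = c(0, 9, 0, 0), nCl = c(0, 0, 4, 0),
                          nBr = c(0, 0, 0, 0), nI = c(0, 0, 0, 1))
  expect_equal(substitution_filter(subst), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("ligand efficiency reproduces reported values", {
  expect_equal(round(ligand_efficiency(-10.298, 41), 4), 0.2512)
  expect_equal(round(ligand_efficiency(-10.464, 34), 4), 0.3078)
  expect_equal(ligand_efficiency(0, 10), 0)
  expect_error(ligand_efficiency(-5, 0), "n_heavy")
})

test_that("docking filter combines efficiency window and energy cutoff", {
  dock <- tibble::tibble(
    id = c("montelukast", "weak", "overefficient", "borderline"),
    dg = c(-10.298, -5.0, -9.0, -6.0),
    n_heavy = c(41, 30, 20, 24)
  )
  out <- docking_filter(dock)
  expect_true(out$pass_docking[out$id == "montelukast"])
  expect_false(out$pass_docking[out$id == "weak"])          # dG > -6
  expect_false(out$pass_docking[out$id == "overefficient"]) # LE 0.45 > 0.4
  expect_true(out$pass_docking[out$id == "borderline"])     # both boundaries
  # idempotence
  expect_equal(docking_filter(out)$pass_docking, out$pass_docking)
  # covalent exemption: revefenacin-like covalent pose
  cov <- tibble::tibble(id = "cov", dg = -5.710, n_heavy = 15,
                        covalent = TRUE)
  expect_false(docking_filter(cov)$pass_docking)
  expect_true(docking_filter(cov, exempt_covalent = TRUE)$pass_docking)
})

test_that("the screening cascade short-circuits and orders by RpS", {
  lib <- generate_library(synthetic_config(seed = 5, n_fi = 60))
  ctx <- enrichment_context(nrow(lib$fi), nrow(lib$dcy))
  fi_pr <- scaffold_assignments(lib$fi, "pr")
  dcy_pr <- scaffold_assignments(lib$dcy, "pr")
  fi_bm <- scaffold_assignments(lib$fi, "bm")
  dcy_bm <- scaffold_assignments(lib$dcy, "bm")
  prs <- score_scaffolds(fi_pr, dcy_pr, ctx, lib$fi[, c("id", "pic50")])
  bms <- score_scaffolds(fi_bm, dcy_bm, ctx, lib$fi[, c("id", "pic50")])
  pr_filter <- prs[prs$scaffold %in%
                     select_filter_scaffolds(prs, "p_threshold", 3), ]
  bm_sel <- bms[bms$scaffold %in% select_filter_scaffolds(bms, "significance"), ]

  # candidates: a planted-core FI compound (high RpS), a decoy, and an
  # organometallic that must fail stage 1
  planted_id <- lib$fi$id[lib$fi$core == "N1CCN(CC1)"][1]
  cand <- rbind(lib$fi[lib$fi$id == planted_id,
                       setdiff(names(lib$fi), c("active", "core"))],
                lib$dcy[1, setdiff(names(lib$dcy), "core")])
  metal <- cand[1, ]
  metal$id <- "metal"; metal$smiles_canonical <- "[Fe]"
  cand <- rbind(cand, metal)

  suppressMessages(
    res <- screen_library(cand, bm_sel, pr_filter, rps_cut = 5,
                          prob_cut = 0.05))
  expect_false(res$pass_property[res$id == "metal"])
  # short-circuit: stages after a failed one are unevaluated
  expect_true(is.na(res$rps[res$id == "metal"]))
  expect_true(is.na(res$prob[res$id == "metal"]))
  # the planted compound passes rps and the (low) probability stage
  expect_true(res$pass_rps[res$id == planted_id])
  expect_true(res$final[res$id == planted_id])
  # ordering: non-increasing RpS with NA last
  r <- res$rps
  expect_true(all(diff(ifelse(is.na(r), -Inf, r)) <= 1e-12))
  # survivor counts never increase through the cascade
  counts <- attr(res, "stage_counts")
  counts <- counts[!is.na(counts)]
  expect_true(all(diff(unname(counts)) <= 0))
})

test_that("RpS exactly at the threshold is rejected (strict inequality)", {
  lib <- generate_library(synthetic_config(seed = 5, n_fi = 60))
  ctx <- enrichment_context(nrow(lib$fi), nrow(lib$dcy))
  fi_pr <- scaffold_assignments(lib$fi, "pr")
  dcy_pr <- scaffold_assignments(lib$dcy, "pr")
  fi_bm <- scaffold_assignments(lib$fi, "bm")
  dcy_bm <- scaffold_assignments(lib$dcy, "bm")
  prs <- score_scaffolds(fi_pr, dcy_pr, ctx, lib$fi[, c("id", "pic50")])
  bms <- score_scaffolds(fi_bm, dcy_bm, ctx, lib$fi[, c("id", "pic50")])
  pr_filter <- prs[prs$scaffold %in%
                     select_filter_scaffolds(prs, "p_threshold", 3), ]
  bm_sel <- bms[bms$scaffold %in% select_filter_scaffolds(bms, "significance"), ]
  cand <- lib$fi[1:3, setdiff(names(lib$fi), c("active", "core"))]
  rps0 <- repurposing_score(scaffold_assignments(cand, "pr"),
                            scaffold_assignments(cand, "bm"),
                            pr_filter, bm_sel, ids = cand$id)
  suppressMessages(
    res <- screen_library(cand, bm_sel, pr_filter,
                          rps_cut = max(rps0$rps), prob_cut = 0.05))
  top <- res$id[which.max(res$rps)]
  expect_false(res$pass_rps[res$id == top])
})
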