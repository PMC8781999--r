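# Scaffold decomposition: Murcko frameworks (MF), Bemis-Murcko skeletons
# (BM) and plain-ring fragments (PR), computed on the kekulized heavy-atom
# molecular graph.
#
# MF: rings, the linker atoms/bonds connecting ring systems, and any
#     exocyclic multiple-bonded atom attached to a retained atom; element
#     identity and bond orders are preserved. Acyclic molecules map to the
#     null framework.
# BM: the MF with every atom relabeled to carbon and every bond set to
#     single order - a pure connectivity scaffold.
# PR: one fragment per fused ring system (rings sharing an atom or a bond,
#     so spiro junctions fuse); all single-bonded substituents removed,
#     exocyclic double-bonded heteroatoms attached to ring atoms retained.

# Atom set of the Murcko framework: the 2-core of the bond graph (rings
# plus ring-ring linkers) extended by exocyclic multiple-bonded atoms.
.mf_atoms <- function(g) {
  if (nrow(g$bonds) == 0) return(integer(0))
  ig <- mol_igraph(g)
  core <- which(igraph::coreness(ig) >= 2)
  if (!length(core)) return(integer(0))
  multi <- g$bonds[g$bonds[, 3] >= 2, , drop = FALSE]
  extra <- integer(0)
  if (nrow(multi)) {
    a_in <- multi[, 1] %in% core; b_in <- multi[, 2] %in% core
    extra <- c(multi[a_in & !b_in, 2], multi[b_in & !a_in, 1])
  }
  sort(unique(c(core, extra)))
}

#' Murcko framework of a molecule
#'
#' Removes all side-chain atoms, keeping the ring systems, the atoms
#' linking them and exocyclic multiple-bonded atoms (e.g. a carbonyl
#' oxygen on a ring); atom types and bond orders are preserved. Acyclic
#' molecules yield the null framework (empty string).
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical framework SMILES ("" for the
#'   null framework).
#' @export
murcko_framework <- function(smiles) {
  g <- mol_graphs(smiles)
  frags <- lapply(g, function(x) {
    if (is.null(x)) return(NULL)
    a <- .mf_atoms(x)
    if (!length(a)) return(list(elem = character(0),
                                bonds = x$bonds[0, , drop = FALSE]))
    graph_subset(x, a)
  })
  canon_fragments(frags)
}

# Murcko framework as molgraph list (internal; avoids re-canonicalizing
# when both the fragment and its MW are needed).
.mf_graphs <- function(smiles) {
  g <- mol_graphs(smiles)
  lapply(g, function(x) {
    if (is.null(x)) return(NULL)
    a <- .mf_atoms(x)
    if (!length(a)) return(list(elem = character(0),
                                bonds = x$bonds[0, , drop = FALSE],
                                explicit_h = integer(0)))
    graph_subset(x, a)
  })
}

#' Bemis-Murcko skeleton of a molecule
#'
#' The ring systems and their linker atoms with all atom labels converted
#' to carbon and all bonds to single order: a pure ring-and-linker
#' connectivity scaffold. Exocyclic multiple-bonded atoms, which the
#' Murcko framework retains, are not part of the skeleton — after bond
#' flattening they would be indistinguishable from side chains, and
#' excluding them keeps the transform idempotent. Acyclic molecules yield
#' the null skeleton (empty string), which is itself counted in skeleton
#' statistics.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical skeleton SMILES ("" = null).
#' @export
bm_skeleton <- function(smiles) {
  g <- mol_graphs(smiles)
  frags <- lapply(g, function(x) {
    if (is.null(x)) return(NULL)
    ig <- mol_igraph(x)
    core <- which(igraph::coreness(ig) >= 2)
    if (!length(core)) {
      return(list(elem = character(0), bonds = x$bonds[0, , drop = FALSE]))
    }
    x <- graph_subset(x, core)
    x$elem <- rep("C", length(x$elem))
    if (nrow(x$bonds)) x$bonds[, 3] <- 1L
    x$explicit_h <- integer(length(x$elem))
    x$charge <- integer(length(x$elem))
    x
  })
  canon_fragments(frags)
}

#' Plain-ring fragments of a molecule
#'
#' Splits a molecule into one fragment per fused ring system (rings
#' sharing an atom or bond, including spiro junctions, form one system),
#' erases every single-bonded substituent and keeps only double-bonded
#' heteroatoms attached directly to ring atoms. Duplicate fragments
#' within one molecule collapse to a single entry.
#'
#' @param smiles character vector of SMILES.
#' @return list (one element per input) of character vectors of canonical
#'   fragment SMILES; acyclic molecules give an empty vector.
#' @export
plain_rings <- function(smiles) {
  g <- mol_graphs(smiles)
  frags <- list(); owner <- integer(0)
  for (i in seq_along(g)) {
    x <- g[[i]]
    if (is.null(x)) next
    rs <- ring_systems(x)
    for (sys_atoms in rs$systems) {
      keep <- sys_atoms
      dbl <- x$bonds[x$bonds[, 3] >= 2, , drop = FALSE]
      if (nrow(dbl)) {
        a_in <- dbl[, 1] %in% sys_atoms; b_in <- dbl[, 2] %in% sys_atoms
        het_b <- dbl[a_in & !b_in, 2]; het_a <- dbl[b_in & !a_in, 1]
        het <- c(het_b[x$elem[het_b] != "C"], het_a[x$elem[het_a] != "C"])
        keep <- c(keep, het)
      }
      frags[[length(frags) + 1L]] <- graph_subset(x, keep)
      owner <- c(owner, i)
    }
  }
  can <- canon_fragments(frags)
  out <- rep(list(character(0)), length(smiles))
  for (i in seq_along(smiles)) {
    v <- unique(can[owner == i])
    out[[i]] <- v[nzchar(v)]
  }
  out
}

# SMARTS patterns behind the substitution-group counts. All groups are
# terminal by construction, so whole-molecule matches equal side-chain
# matches.
.SUBST_SMARTS <- c(
  nF = "[F]", nCl = "[Cl]", nBr = "[Br]", nI = "[I]",
  nOH = "[OX2H1;!$([OX2H1]C=O)]",
  nCOOH = "[CX3](=O)[OX2H1]",
  nCONH2 = "[CX3](=O)[NX3H2]",
  nNH2 = "[NX3H2;!$([NX3H2]C=O)]",
  nNO2 = "[$([NX3](=O)=O),$([NX3+](=[OX1])[O-])]"
)

#' Side-chain size and substitution-group profile
#'
#' For each compound: `sc`, the side-chain mass, is the difference between
#' the molecular weight and the molecular weight of its hydrogen-completed
#' Murcko framework; `sc_heavy` the number of heavy atoms outside the
#' framework; and counts of the major substitution groups (halogens by
#' element, their total `nX`, hydroxyl excluding carboxylic OH, carboxylic
#' acid, primary amide, primary amine excluding amides, nitro). For
#' acyclic molecules (null framework) `sc` equals the molecular weight and
#' the `acyclic` flag is set.
#'
#' @param records compound-record tibble (see [compound_records()]).
#' @return tibble with columns `id`, `sc`, `sc_heavy`, `acyclic` and the
#'   substitution counts `nF`, `nCl`, `nBr`, `nI`, `nX`, `nOH`, `nCOOH`,
#'   `nCONH2`, `nNH2`, `nNO2`.
#' @export
side_chain_stats <- function(records) {
  smiles <- records$smiles_canonical
  mf <- .mf_graphs(smiles)
  mw_mf <- fragment_mw(mf)
  acyclic <- vapply(mf, function(x) is.null(x) || length(x$elem) == 0, logical(1))
  mw_mf[acyclic] <- 0
  g <- mol_graphs(smiles)
  n_mf <- vapply(mf, function(x) if (is.null(x)) 0L else length(x$elem), 0L)

  counts <- .subst_counts(smiles)
  tibble(
    id = records$id,
    sc = pmax(records$mw - mw_mf, 0),
    sc_heavy = records$n_heavy - n_mf,
    acyclic = acyclic
  ) %>% dplyr::bind_cols(counts)
}

.subst_counts <- function(smiles) {
  sdfset <- .smiles_sdfset(smiles)
  res <- lapply(names(.SUBST_SMARTS), function(nm) {
    v <- integer(length(smiles))
    hits <- ChemmineR::smartsSearchOB(sdfset$sdf, .SUBST_SMARTS[[nm]],
                                      uniqueMatches = TRUE)
    v[sdfset$index] <- as.integer(hits)
    v
  })
  names(res) <- names(.SUBST_SMARTS)
  out <- as_tibble(res)
  out$nX <- out$nF + out$nCl + out$nBr + out$nI
  out[, c("nF", "nCl", "nBr", "nI", "nX", "nOH", "nCOOH", "nCONH2",
          "nNH2", "nNO2")]
}

# SDFset for SMARTS matching, with the surviving input indices.
.smiles_sdfset <- function(smiles) {
  txt <- ob_smiles_to_sdf(smiles)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = TRUE))
  ids <- ChemmineR::sdfid(sdfset)
  list(sdf = sdfset, index = as.integer(sub("^t", "", ids)))
}

#' Scaffold assignments for a compound set
#'
#' Long-format scaffold membership used by the enrichment scoring: one row
#' per compound x distinct scaffold. For kind `"bm"` acyclic compounds
#' contribute the null skeleton (empty string), which the downstream
#' scoring treats like any other skeleton; for `"mf"` and `"pr"` acyclic
#' compounds contribute nothing.
#'
#' @param records compound-record tibble.
#' @param kind `"mf"`, `"bm"` or `"pr"`.
#' @return tibble with columns `id`, `scaffold`, `kind`.
#' @export
scaffold_assignments <- function(records, kind = c("bm", "pr", "mf")) {
  kind <- match.arg(kind)
  smiles <- records$smiles_canonical
  if (kind == "pr") {
    pr <- plain_rings(smiles)
    tb <- tibble(
      id = rep(records$id, lengths(pr)),
      scaffold = unlist(pr, use.names = FALSE) %||% character(0)
    )
  } else {
    sc <- if (kind == "mf") murcko_framework(smiles) else bm_skeleton(smiles)
    tb <- tibble(id = records$id, scaffold = sc)
    if (kind == "mf") tb <- tb[nzchar(tb$scaffold), , drop = FALSE]
  }
  tb <- dplyr::distinct(tb)
  tb$kind <- kind
  tb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
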