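# Descriptor panel: the 2D descriptors (Crippen logP, spectral mean
# absolute deviation of the topological distance matrix, Burden-matrix
# eigenvalue) and conformer-based 3D descriptors (WHIM total size indices,
# radial distribution function, charge-weighted surface areas) consumed by
# the flag classifier.

#' Deterministic 3D embedding of a molecule
#'
#' Generates a single conformer by distance-geometry embedding: distance
#' bounds are assembled from covalent-radius bond lengths, law-of-cosines
#' 1-3 distances (angles by hybridization) and through-bond path upper
#' bounds, a distance matrix is drawn inside the bounds (reproducibly for
#' a fixed `seed`) and embedded into 3D by classical multidimensional
#' scaling. The raw geometry is hydrogen-completed and relaxed with Open
#' Babel's MMFF94s steepest-descent minimizer, and EEM partial charges
#' (iterative electronegativity equalization) are attached. Hydrogen
#' coordinates are discarded after minimization; hydrogen charges are
#' condensed onto the bonded heavy atom.
#'
#' When minimization fails (e.g. force-field typing failure) the embedded
#' geometry is kept and flagged (`minimized = FALSE`).
#'
#' @param smiles a single SMILES string.
#' @param seed integer seed; identical input and seed give identical
#'   coordinates.
#' @param minimize_steps steepest-descent steps (default 1500).
#' @return An object of class `conformer`: list with `smiles`, `elem`,
#'   `coords` (heavy atoms, Angstrom, centered), `charges` (condensed,
#'   elementary charge units), `masses`, `n_h` (attached hydrogens),
#'   `degree`, `minimized`.
#' @export
embed_3d <- function(smiles, seed = 1, minimize_steps = 1500) {
  stopifnot(length(smiles) == 1)
  g <- mol_graph(smiles)
  if (is.null(g)) stop("unparsable structure: ", smiles, call. = FALSE)
  n <- length(g$elem)
  coords <- if (n == 1) matrix(0, 1, 3) else .dg_embed(g, seed)
  .finish_conformer(g, coords, smiles, minimize_steps)
}

# Distance-geometry embedding of the heavy-atom graph.
.dg_embed <- function(g, seed) {
  n <- length(g$elem)
  blen <- .elem_lookup(.R_COV, g$elem[g$bonds[, 1]], 0.77) +
    .elem_lookup(.R_COV, g$elem[g$bonds[, 2]], 0.77)
  blen <- blen * c(1, 0.87, 0.78)[pmin(g$bonds[, 3], 3)]
  ig <- mol_igraph(g)
  igraph::E(ig)$weight <- blen
  U <- igraph::distances(ig, weights = blen)
  U[!is.finite(U)] <- 8  # disconnected fragments: loose default
  L <- matrix(2.5, n, n)
  # exact 1-2 distances
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    L[i, j] <- L[j, i] <- U[i, j] <- U[j, i] <- blen[k]
  }
  # 1-3 distances from idealized angles at the central atom
  adj <- lapply(seq_len(n), function(i)
    c(g$bonds[g$bonds[, 1] == i, 2], g$bonds[g$bonds[, 2] == i, 1]))
  ord_max <- vapply(seq_len(n), function(i) {
    k <- g$bonds[, 1] == i | g$bonds[, 2] == i
    if (!any(k)) 1L else max(g$bonds[k, 3])
  }, 0L)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    theta <- if (ord_max[j] >= 3 || length(nb) == 1) pi else
      if (ord_max[j] == 2) 2 * pi / 3 else acos(-1 / 3)
    for (a in seq_along(nb)) for (b in seq_len(a - 1)) {
      i <- nb[a]; k <- nb[b]
      d <- sqrt(U[i, j]^2 + U[j, k]^2 - 2 * U[i, j] * U[j, k] * cos(theta))
      L[i, k] <- L[k, i] <- U[i, k] <- U[k, i] <- min(d, U[i, k])
    }
  }
  L <- pmin(L, U)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  u <- matrix(stats::runif(n * n), n, n)
  u <- (u + t(u)) / 2
  D <- L + u * (U - L)
  diag(D) <- 0
  X <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = min(3, n - 1)))
  if (ncol(X) < 3) X <- cbind(X, matrix(0, nrow(X), 3 - ncol(X)))
  X
}

# Hydrogen completion + MMFF94s minimization + EEM charges via Open Babel;
# returns the conformer object.
.finish_conformer <- function(g, coords, smiles, minimize_steps) {
  .ob_check()
  block <- frag_molblock(g, "t1", coords)
  f1 <- tempfile(fileext = ".sdf"); f2 <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(f1, f2)), add = TRUE)
  writeLines(block, f1)
  hadd <- suppressWarnings(system2("obabel", c(shQuote(f1), "-osdf", "-h"),
                                   stdout = TRUE, stderr = FALSE))
  minimized <- FALSE
  mol_sdf <- hadd
  if (length(hadd) > 3 && minimize_steps > 0 && nzchar(Sys.which("obminimize"))) {
    writeLines(hadd, f2)
    mini <- suppressWarnings(system2(
      "obminimize", c("-ff", "MMFF94s", "-n", as.character(minimize_steps),
                      "-sd", "-osdf", shQuote(f2)),
      stdout = TRUE, stderr = FALSE))
    if (length(mini) > 3 && any(grepl("V2000", mini))) {
      mol_sdf <- mini
      minimized <- TRUE
    }
  }
  writeLines(mol_sdf, f2)
  mol2 <- suppressWarnings(system2(
    "obabel", c(shQuote(f2), "-omol2", "--partialcharge", "eem"),
    stdout = TRUE, stderr = FALSE))
  at <- .parse_mol2(mol2)
  heavy <- which(at$elem != "H")
  charges <- at$charge[heavy]
  n_h <- integer(length(heavy))
  if (length(at$bonds)) {
    hmap <- match(seq_along(at$elem), heavy)
    for (k in seq_len(nrow(at$bonds))) {
      i <- at$bonds[k, 1]; j <- at$bonds[k, 2]
      if (at$elem[i] == "H" && at$elem[j] != "H") {
        charges[hmap[j]] <- charges[hmap[j]] + at$charge[i]
        n_h[hmap[j]] <- n_h[hmap[j]] + 1L
      } else if (at$elem[j] == "H" && at$elem[i] != "H") {
        charges[hmap[i]] <- charges[hmap[i]] + at$charge[j]
        n_h[hmap[i]] <- n_h[hmap[i]] + 1L
      }
    }
  }
  xyz <- at$coords[heavy, , drop = FALSE]
  xyz <- sweep(xyz, 2, colMeans(xyz))
  deg <- tabulate(c(g$bonds[, 1], g$bonds[, 2]), nbins = length(g$elem))
  structure(list(smiles = smiles, elem = at$elem[heavy], coords = xyz,
                 charges = charges, masses = .elem_lookup(.MASS, at$elem[heavy], 12.011),
                 n_h = n_h, degree = deg[seq_along(heavy)],
                 minimized = minimized),
            class = "conformer")
}

# Minimal TRIPOS mol2 reader for the files produced above (coordinates,
# atom types, partial charges, bonds). Only what the descriptors need.
.parse_mol2 <- function(lines) {
  ai <- grep("^@<TRIPOS>ATOM", lines)
  bi <- grep("^@<TRIPOS>BOND", lines)
  sect_end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  if (!length(ai)) stop("Open Babel produced no mol2 output", call. = FALSE)
  a_end <- min(sect_end[sect_end > ai[1]]) - 1L
  rows <- strsplit(trimws(lines[(ai[1] + 1L):a_end]), "[[:space:]]+")
  rows <- rows[lengths(rows) >= 9]
  elem <- vapply(rows, function(r) sub("\\..*$", "", r[6]), "")
  coords <- t(vapply(rows, function(r) as.numeric(r[3:5]), numeric(3)))
  charge <- vapply(rows, function(r) as.numeric(r[9]), 0)
  charge[is.na(charge)] <- 0
  bonds <- NULL
  if (length(bi)) {
    b_end <- min(sect_end[sect_end > bi[1]]) - 1L
    if (b_end > bi[1]) {
      brows <- strsplit(trimws(lines[(bi[1] + 1L):b_end]), "[[:space:]]+")
      brows <- brows[lengths(brows) >= 3]
      bonds <- t(vapply(brows, function(r) as.integer(r[2:3]), integer(2)))
    }
  }
  list(elem = elem, coords = coords, charge = charge, bonds = bonds)
}

#' Crippen-type logP
#'
#' Atomic-contribution (Wildman-Crippen classification) octanol/water
#' partition coefficient estimate, as implemented by Open Babel. The same
#' estimate is used for property-window filtering, so descriptor and
#' curation logP are consistent. Additive over disconnected fragments.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector.
#' @export
crippen_logp <- function(smiles) {
  ob_properties(smiles, length(smiles), props = "logP")$logP
}

#' Spectral mean absolute deviation of the topological distance matrix
#'
#' Eigenvalues of the heavy-atom graph distance matrix; the descriptor is
#' the mean absolute deviation of the spectrum from its mean,
#' `SpMAD = sum(|lambda_i - mean(lambda)|) / n`. Invariant under atom
#' renumbering; single-atom molecules return 0.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector.
#' @export
spmad_distance <- function(smiles) {
  g <- mol_graphs(smiles)
  vapply(g, function(x) {
    if (is.null(x)) return(NA_real_)
    n <- length(x$elem)
    if (n < 2) return(0)
    D <- igraph::distances(mol_igraph(x))
    D[!is.finite(D)] <- n  # disconnected: conventional large distance
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    mean(abs(ev - mean(ev)))
  }, 0)
}

#' Burden-matrix eigenvalue descriptor (SpMax5, ionization-weighted)
#'
#' Builds the modified Burden matrix: diagonal entries are relative first
#' ionization potentials (element IP / carbon IP), off-diagonal entries
#' are 0.1 x bond order for bonded pairs (plus 0.01 when either atom is
#' terminal) and 0.001 otherwise. Returns the 5th largest absolute
#' eigenvalue; molecules with fewer than 5 heavy atoms return the
#' smallest available eigenvalue, flagged via the `"degenerate"`
#' attribute.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector with logical attribute `degenerate`.
#' @export
burden_spmax5 <- function(smiles) {
  g <- mol_graphs(smiles)
  vals <- numeric(length(g)); degen <- logical(length(g))
  for (i in seq_along(g)) {
    x <- g[[i]]
    if (is.null(x)) { vals[i] <- NA_real_; next }
    n <- length(x$elem)
    B <- matrix(0.001, n, n)
    diag(B) <- .atom_weights(x$elem, "ionization")
    deg <- tabulate(c(x$bonds[, 1], x$bonds[, 2]), nbins = n)
    for (k in seq_len(nrow(x$bonds))) {
      a <- x$bonds[k, 1]; b <- x$bonds[k, 2]
      v <- 0.1 * x$bonds[k, 3] + if (deg[a] == 1 || deg[b] == 1) 0.01 else 0
      B[a, b] <- B[b, a] <- v
    }
    ev <- sort(abs(eigen(B, symmetric = TRUE, only.values = TRUE)$values),
               decreasing = TRUE)
    if (n >= 5) vals[i] <- ev[5] else { vals[i] <- ev[n]; degen[i] <- TRUE }
  }
  attr(vals, "degenerate") <- degen
  vals
}

#' WHIM total size index
#'
#' Eigenvalues `lambda_1 >= lambda_2 >= lambda_3` of the weighted
#' covariance matrix of the centered conformer coordinates; the total
#' size index is `A = l1*l2 + l1*l3 + l2*l3`. Weighting schemes (all
#' relative to carbon): unweighted, Sanderson electronegativity, first
#' ionization potential, Kier-Hall intrinsic state, van der Waals volume.
#' Invariant under rigid motion; planar conformers have `lambda_3 = 0`.
#'
#' @param conformer a [embed_3d()] conformer.
#' @param weighting one of `"unweighted"`, `"sanderson_en"`,
#'   `"ionization"`, `"istate"`, `"vdw_volume"`.
#' @return the A index (numeric scalar).
#' @export
whim_size <- function(conformer,
                      weighting = c("unweighted", "sanderson_en",
                                    "ionization", "istate", "vdw_volume")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "istate") {
    .intrinsic_state(conformer$elem, conformer$n_h, conformer$degree) / 2
  } else {
    .atom_weights(conformer$elem, weighting)
  }
  X <- conformer$coords
  if (nrow(X) == 1) return(0)
  mu <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc * w, Xc) / sum(w)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]
}

#' Radial distribution function descriptor
#'
#' `g(r) = sum_{i<j} w_i w_j exp(-beta (r - r_ij)^2)` over heavy-atom
#' pairs, with weights relative to carbon (default: atomic mass). The
#' standard code 085 corresponds to r = 8.5 Angstrom with smoothing
#' beta = 100 per square Angstrom.
#'
#' @param conformer a [embed_3d()] conformer.
#' @param r evaluation radius in Angstrom.
#' @param beta Gaussian smoothing parameter (1/Angstrom^2).
#' @param weighting atom weighting scheme (default `"mass"`).
#' @return numeric scalar (0 for single-atom molecules).
#' @export
rdf_descriptor <- function(conformer, r = 8.5, beta = 100,
                           weighting = "mass") {
  X <- conformer$coords
  n <- nrow(X)
  if (n < 2) return(0)
  w <- .atom_weights(conformer$elem, weighting)
  d <- as.matrix(stats::dist(X))
  iu <- upper.tri(d)
  sum((w %o% w)[iu] * exp(-beta * (r - d[iu])^2))
}

# Deterministic Fibonacci sphere directions.
.sphere_points <- function(n = 256) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface areas (Shrake-Rupley)
#'
#' Numerical solvent-accessible surface area per heavy atom, using Bondi
#' van der Waals radii, a 1.4 Angstrom probe and 256 deterministic test
#' points per atom.
#'
#' @param conformer a [embed_3d()] conformer.
#' @param probe probe radius in Angstrom.
#' @param n_points test points per atom.
#' @return numeric vector of per-atom SASA (square Angstrom).
#' @export
atom_sasa <- function(conformer, probe = 1.4, n_points = 256) {
  X <- conformer$coords
  n <- nrow(X)
  rad <- .elem_lookup(.R_VDW, conformer$elem, 1.7) + probe
  sp <- .sphere_points(n_points)
  out <- numeric(n)
  if (n == 1) return(4 * pi * rad^2)
  d2 <- as.matrix(stats::dist(X))
  for (i in seq_len(n)) {
    pts <- sweep(sp * rad[i], 2, X[i, ], `+`)
    nb <- which(d2[i, ] < rad[i] + rad & seq_len(n) != i)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- (pts[, 1] - X[j, 1])^2 + (pts[, 2] - X[j, 2])^2 +
        (pts[, 3] - X[j, 3])^2
      free <- free & dd >= rad[j]^2
    }
    out[i] <- 4 * pi * rad[i]^2 * mean(free)
  }
  out
}

#' Charge-weighted partial surface area descriptors (WPSA1, WPSA2)
#'
#' From per-atom solvent-accessible surface areas and partial charges:
#' `PPSA1` is the summed surface of positively charged atoms, `PPSA2` is
#' PPSA1 times the total positive charge, and
#' `WPSAk = PPSAk * TMSA / 1000` with TMSA the total molecular surface
#' area.
#'
#' @param conformer a [embed_3d()] conformer (with charges).
#' @param sasa optional precomputed per-atom surface areas.
#' @return named list with `WPSA1`, `WPSA2`, `PPSA1`, `PPSA2`, `TMSA`.
#' @export
cpsa_wpsa <- function(conformer, sasa = NULL) {
  if (is.null(conformer$charges) || all(is.na(conformer$charges))) {
    stop("conformer has no partial charges", call. = FALSE)
  }
  if (is.null(sasa)) sasa <- atom_sasa(conformer)
  q <- conformer$charges
  pos <- q > 0
  tmsa <- sum(sasa)
  ppsa1 <- sum(sasa[pos])
  ppsa2 <- sum(q[pos]) * ppsa1
  list(WPSA1 = ppsa1 * tmsa / 1000, WPSA2 = ppsa2 * tmsa / 1000,
       PPSA1 = ppsa1, PPSA2 = ppsa2, TMSA = tmsa)
}

#' Compute the full descriptor panel
#'
#' The eleven descriptors used by the activity classifier: CrippenLogP,
#' SpMAD_D and SpMax5_Bhi from the molecular graph, and the WHIM size
#' indices (Au, Ae, Ai, As, Av), RDF85m, WPSA1 and WPSA2 from a
#' deterministic conformer.
#'
#' @param x compound-record tibble or character vector of SMILES.
#' @param seed embedding seed.
#' @return tibble with `id` and one column per descriptor; rows where 3D
#'   embedding failed carry `NA` in the 3D columns.
#' @export
descriptor_panel <- function(x, seed = 1) {
  if (is.data.frame(x)) {
    smiles <- x$smiles_canonical
    ids <- x$id
  } else {
    smiles <- standardize_smiles(x)
    ids <- paste0("cmpd", seq_along(x))
  }
  out <- tibble(
    id = ids,
    CrippenLogP = crippen_logp(smiles),
    SpMAD_D = spmad_distance(smiles),
    SpMax5_Bhi = as.numeric(burden_spmax5(smiles)),
    Au = NA_real_, Ae = NA_real_, Ai = NA_real_, As = NA_real_,
    Av = NA_real_, RDF85m = NA_real_, WPSA1 = NA_real_, WPSA2 = NA_real_
  )
  for (i in seq_along(smiles)) {
    conf <- tryCatch(embed_3d(smiles[i], seed = seed), error = function(e) NULL)
    if (is.null(conf)) next
    out$Au[i] <- whim_size(conf, "unweighted")
    out$Ae[i] <- whim_size(conf, "sanderson_en")
    out$Ai[i] <- whim_size(conf, "ionization")
    out$As[i] <- whim_size(conf, "istate")
    out$Av[i] <- whim_size(conf, "vdw_volume")
    out$RDF85m[i] <- rdf_descriptor(conf)
    sasa <- atom_sasa(conf)
    wp <- cpsa_wpsa(conf, sasa)
    out$WPSA1[i] <- wp$WPSA1
    out$WPSA2[i] <- wp$WPSA2
  }
  out
}
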