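# Internal molecular-graph representation.
#
# A "molgraph" is a plain list:
#   elem  - character vector of element symbols (heavy atoms only; Open
#           Babel's kekulized V2000 output carries no explicit hydrogens
#           unless the input SMILES does; explicit H are dropped here)
#   bonds - integer matrix with columns from, to, order (Kekule orders)
# Graphs are parsed once per distinct input string and cached for the
# session, which makes repeated scaffold work on combinatorial libraries
# cheap.

.fs_cache <- new.env(parent = emptyenv())

.molgraph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  # V2000 old-style charge codes live in the 5th numeric field
  chg_code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, length(elem))
  charge <- integer(length(elem))
  charge[chg_code %in% 1:3] <- 4L - as.integer(chg_code[chg_code %in% 1:3])
  charge[chg_code %in% 5:7] <- 4L - as.integer(chg_code[chg_code %in% 5:7])
  if (is.null(dim(bb))) {
    bb <- if (length(bb) >= 3) matrix(bb, ncol = length(bb)) else
      matrix(numeric(0), ncol = 3)
  }
  bonds <- if (nrow(bb) == 0 || ncol(bb) < 3 || all(is.na(bb[, 1]))) {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
  } else {
    m <- cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
    m
  }
  # drop explicit hydrogens, remembering how many were attached where
  h <- which(elem == "H")
  nh <- integer(length(elem))
  if (length(h)) {
    keep <- setdiff(seq_along(elem), h)
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]
      if (a %in% h && !(b %in% h)) nh[b] <- nh[b] + 1L
      if (b %in% h && !(a %in% h)) nh[a] <- nh[a] + 1L
    }
    remap <- integer(length(elem)); remap[keep] <- seq_along(keep)
    hb <- bonds[, 1] %in% h | bonds[, 2] %in% h
    bonds <- bonds[!hb, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]; bonds[, 2] <- remap[bonds[, 2]]
    elem <- elem[keep]
    nh <- nh[keep]
    charge <- charge[keep]
  }
  list(elem = elem, bonds = bonds, explicit_h = nh, charge = charge)
}

# Parse a character vector of SMILES into molgraphs (cached, batched).
# Returns a named-by-position list; NULL where parsing failed.
mol_graphs <- function(smiles) {
  res <- vector("list", length(smiles))
  key <- paste0("g:", smiles)
  have <- vapply(key, function(k) !is.null(.fs_cache[[k]]), logical(1))
  res[have] <- lapply(key[have], function(k) .fs_cache[[k]])
  todo <- which(!have & !is.na(smiles) & nzchar(smiles))
  if (length(todo)) {
    usm <- unique(smiles[todo])
    sdf_txt <- ob_smiles_to_sdf(usm)
    parsed <- vector("list", length(usm))
    if (length(sdf_txt)) {
      tf <- tempfile(fileext = ".sdf")
      writeLines(sdf_txt, tf)
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf, skipErrors = TRUE))
      unlink(tf)
      if (length(sdfset)) {
        ids <- vapply(ChemmineR::SDFset2SDF(sdfset), function(s)
          ChemmineR::header(s)[["Molecule_Name"]], "")
        idx <- as.integer(sub("^t", "", ids))
        for (j in seq_along(idx)) {
          if (!is.na(idx[j]) && idx[j] >= 1 && idx[j] <= length(usm)) {
            parsed[[idx[j]]] <- .molgraph_from_sdf(sdfset[[j]])
          }
        }
      }
    }
    names(parsed) <- usm
    for (u in usm) .fs_cache[[paste0("g:", u)]] <- parsed[[u]]
    res[todo] <- parsed[match(smiles[todo], usm)]
  }
  res
}

mol_graph <- function(smiles) mol_graphs(smiles)[[1]]

# ---- fragments ------------------------------------------------------------

# Induced subgraph on `atoms` (integer indices), re-indexed from 1.
graph_subset <- function(g, atoms) {
  atoms <- sort(unique(atoms))
  remap <- integer(length(g$elem)); remap[atoms] <- seq_along(atoms)
  keep <- g$bonds[, 1] %in% atoms & g$bonds[, 2] %in% atoms
  b <- g$bonds[keep, , drop = FALSE]
  if (nrow(b)) { b[, 1] <- remap[b[, 1]]; b[, 2] <- remap[b[, 2]] }
  list(elem = g$elem[atoms], bonds = b,
       explicit_h = if (is.null(g$explicit_h)) integer(length(atoms)) else g$explicit_h[atoms],
       charge = if (is.null(g$charge)) integer(length(atoms)) else g$charge[atoms])
}

# Serialize a molgraph as a V2000 molblock (implicit H completion is left
# to the reader). `title` carries the alignment index; `coords` is an
# optional n x 3 matrix (zero coordinates otherwise).
frag_molblock <- function(g, title, coords = NULL) {
  n <- length(g$elem); m <- nrow(g$bonds)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  c(title, "  faahscreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], g$elem),
    if (m) sprintf("%3d%3d%3d  0", g$bonds[, 1], g$bonds[, 2], g$bonds[, 3]),
    "M  END", "$$$$")
}

# Canonical SMILES for a list of fragment molgraphs (batched; NULL or
# empty graphs yield "").
canon_fragments <- function(graphs) {
  n <- length(graphs)
  out <- rep("", n)
  todo <- which(vapply(graphs, function(g) !is.null(g) && length(g$elem) > 0, logical(1)))
  if (!length(todo)) return(out)
  blocks <- unlist(lapply(todo, function(i) frag_molblock(graphs[[i]], paste0("t", i))))
  can <- ob_sdf_to_canonical(blocks, n)
  out[todo] <- ifelse(is.na(can[todo]), "", can[todo])
  out
}

# Molecular weight (average masses, implicit-H completed) for fragment
# molgraphs, via Open Babel for consistency with whole-molecule MW.
fragment_mw <- function(graphs) {
  n <- length(graphs)
  out <- rep(NA_real_, n)
  todo <- which(vapply(graphs, function(g) !is.null(g) && length(g$elem) > 0, logical(1)))
  if (!length(todo)) return(out)
  blocks <- unlist(lapply(todo, function(i) frag_molblock(graphs[[i]], paste0("t", i))))
  pr <- ob_properties(blocks, n, from = "sdf", props = "MW")
  out[todo] <- pr$MW[todo]
  out
}

# ---- ring perception ------------------------------------------------------

mol_igraph <- function(g) {
  n <- length(g$elem)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(g$bonds)) {
    ig <- igraph::add_edges(ig, t(g$bonds[, 1:2, drop = FALSE]))
  }
  ig
}

# Ring atoms, ring bonds (non-bridge edges) and fused ring systems
# (components of the ring-bond subgraph; spiro junctions merge systems).
ring_systems <- function(g) {
  n <- length(g$elem)
  if (nrow(g$bonds) == 0) {
    return(list(ring_atoms = integer(0), ring_bonds = integer(0),
                systems = list()))
  }
  ig <- mol_igraph(g)
  br <- igraph::bridges(ig)
  ring_bonds <- setdiff(seq_len(nrow(g$bonds)), as.integer(br))
  if (!length(ring_bonds)) {
    return(list(ring_atoms = integer(0), ring_bonds = integer(0),
                systems = list()))
  }
  ring_atoms <- sort(unique(as.integer(g$bonds[ring_bonds, 1:2])))
  sub <- igraph::subgraph_from_edges(ig, ring_bonds, delete.vertices = FALSE)
  comp <- igraph::components(sub)$membership
  systems <- split(ring_atoms, comp[ring_atoms])
  names(systems) <- NULL
  list(ring_atoms = ring_atoms, ring_bonds = ring_bonds, systems = systems)
}

# ---- implicit hydrogens and Lipinski H-bond counts ------------------------

.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

# Implicit hydrogen count per heavy atom under the standard neutral
# valence model with charge adjustment (N+ carries 4 bonds/H, O- one
# fewer, carbon loses one per unit of either charge sign). Hypervalent
# atoms (e.g. the sulfone S, azo N-oxides written hypervalently) get 0.
implicit_h <- function(g) {
  n <- length(g$elem)
  so <- numeric(n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      so[g$bonds[k, 1]] <- so[g$bonds[k, 1]] + g$bonds[k, 3]
      so[g$bonds[k, 2]] <- so[g$bonds[k, 2]] + g$bonds[k, 3]
    }
  }
  q <- if (is.null(g$charge)) integer(n) else g$charge
  target <- .elem_lookup(.DEFAULT_VALENCE, g$elem, 0)
  target <- ifelse(g$elem == "C", target - abs(q), target + q)
  eh <- if (is.null(g$explicit_h)) integer(n) else g$explicit_h
  pmax(0, target - so - eh)
}

# Lipinski-style hydrogen-bond acceptor (N + O atoms) and donor (N-H +
# O-H hydrogens) counts.
lipinski_hbond <- function(g) {
  if (is.null(g)) return(c(hba = NA_integer_, hbd = NA_integer_))
  no <- g$elem %in% c("N", "O")
  h <- implicit_h(g) + (if (is.null(g$explicit_h)) 0L else g$explicit_h)
  c(hba = as.integer(sum(no)), hbd = as.integer(sum(h[no])))
}
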