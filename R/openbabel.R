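# Thin, batched wrappers around the Open Babel command line tools.
#
# All heavy per-molecule work (canonicalization, property computation,
# SMILES -> molblock conversion) is funnelled through single obabel
# invocations on temporary files: the CLI processes thousands of molecules
# per second, whereas per-molecule in-process calls dominate runtime.
# Records are aligned through injected "t<i>" titles, so unparsable
# entries are detected rather than silently shifting rows.

ob_available <- function() {
  nzchar(Sys.which("obabel"))
}

.ob_check <- function() {
  if (!ob_available()) {
    stop("Open Babel ('obabel') not found on PATH", call. = FALSE)
  }
}

# Run obabel on a character vector written to a temp file.
.ob_run <- function(lines, ext, args) {
  .ob_check()
  inf <- tempfile(fileext = ext)
  on.exit(unlink(inf), add = TRUE)
  writeLines(lines, inf)
  # -e: skip unparsable records instead of aborting the batch
  suppressWarnings(system2("obabel", c(shQuote(inf), "-e", args),
                           stdout = TRUE, stderr = FALSE))
}

# Map "SMILES\ttitle" / "title v1 v2 ..." output lines back onto the input
# index encoded in the title. Returns a list of character matrices rows.
.ob_title_index <- function(titles) {
  as.integer(sub("^t", "", titles))
}

#' Canonical SMILES via Open Babel
#'
#' Converts SMILES strings to Open Babel canonical SMILES in one batched
#' call. Unparsable inputs yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @keywords internal
ob_canonical <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  lines <- paste(smiles, paste0("t", seq_along(smiles)))
  out <- .ob_run(lines, ".smi", c("-ocan"))
  res <- rep(NA_character_, length(smiles))
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    idx <- .ob_title_index(vapply(parts[ok], function(p) trimws(p[2]), ""))
    res[idx] <- vapply(parts[ok], `[`, "", 1L)
  }
  res
}

# Batched molecular properties from obabel --append. `input` may be SMILES
# (from = "smi") or concatenated molblock text lines (from = "sdf", titles
# already embedded as t<i>). Returns a data.frame with one row per input
# molecule (NA rows where obabel failed).
ob_properties <- function(input, n, from = c("smi", "sdf"),
                          props = c("logP", "MW", "HBA2", "HBD")) {
  from <- match.arg(from)
  if (from == "smi") {
    if (length(input) == 0) n <- 0
    lines <- paste(input, paste0("t", seq_along(input)))
    ext <- ".smi"
  } else {
    lines <- input
    ext <- ".sdf"
  }
  res <- matrix(NA_real_, nrow = n, ncol = length(props),
                dimnames = list(NULL, props))
  if (n == 0) return(as.data.frame(res))
  out <- .ob_run(lines, ext, c("-otxt", "--append", shQuote(paste(props, collapse = " "))))
  if (length(out)) {
    parts <- strsplit(trimws(out), "[[:space:]]+")
    ok <- lengths(parts) == (length(props) + 1L)
    for (p in parts[ok]) {
      i <- .ob_title_index(p[1])
      if (!is.na(i) && i >= 1 && i <= n) {
        res[i, ] <- suppressWarnings(as.numeric(p[-1]))
      }
    }
  }
  as.data.frame(res)
}

# SMILES -> SDF (V2000, kekulized) text, titles "t<i>". Used to build
# molecular graphs; no coordinates are generated.
ob_smiles_to_sdf <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  lines <- paste(smiles, paste0("t", seq_along(smiles)))
  .ob_run(lines, ".smi", c("-osdf"))
}

# SDF text -> canonical SMILES, aligned on embedded t<i> titles.
ob_sdf_to_canonical <- function(sdf_lines, n) {
  res <- rep(NA_character_, n)
  if (n == 0) return(res)
  out <- .ob_run(sdf_lines, ".sdf", c("-ocan"))
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    idx <- .ob_title_index(vapply(parts[ok], function(p) trimws(p[2]), ""))
    keep <- !is.na(idx) & idx >= 1 & idx <= n
    res[idx[keep]] <- vapply(parts[ok], `[`, "", 1L)[keep]
  }
  res
}
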