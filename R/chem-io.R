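#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
NULL

.ALLOWED_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

#' Build compound records from SMILES strings
#'
#' The workhorse behind [parse_structures()]: standardizes each structure
#' (largest organic fragment kept, Open Babel canonical SMILES), computes
#' the physicochemical panel used throughout the pipeline (MW, Crippen-type
#' logP, Lipinski hydrogen-bond acceptor/donor counts, heavy-atom count)
#' and attaches optional activity data.
#'
#' Unparsable structures are dropped with a warning naming their position.
#'
#' @param smiles character vector of SMILES strings.
#' @param id compound identifiers (defaults to `cmpd<i>`).
#' @param ic50 optional IC50 values in molar units; converted to pIC50.
#' @param pic50 optional pIC50 values (ignored when `ic50` is given).
#' @param set_tag set membership tag (`"FI"`, `"DCY"` or `"candidate"`).
#' @return A tibble with one row per parsable structure and columns
#'   `id`, `smiles_input`, `smiles_canonical`, `mw`, `logp`, `hba`, `hbd`,
#'   `n_heavy`, `pic50`, `label`, `set_tag`.
#' @export
compound_records <- function(smiles, id = NULL, ic50 = NULL, pic50 = NULL,
                             set_tag = "candidate") {
  if (length(smiles) == 0) stop("no structures supplied", call. = FALSE)
  if (is.null(id)) id <- paste0("cmpd", seq_along(smiles))
  stopifnot(length(id) == length(smiles))
  if (!is.null(ic50)) {
    pic50 <- ifelse(!is.na(ic50) & ic50 > 0, -log10(ic50), NA_real_)
  }
  if (is.null(pic50)) pic50 <- rep(NA_real_, length(smiles))

  std <- standardize_smiles(smiles)
  bad <- which(is.na(std))
  if (length(bad)) {
    warning(sprintf("skipping %d unparsable structure(s) at position(s): %s",
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")),
            call. = FALSE)
  }
  keep <- which(!is.na(std))
  if (!length(keep)) stop("zero parsable structures", call. = FALSE)

  can <- std[keep]
  g <- mol_graphs(can)
  props <- .cached_properties(can)
  hb <- vapply(g, lipinski_hbond, c(hba = 0L, hbd = 0L))
  tibble(
    id = as.character(id[keep]),
    smiles_input = smiles[keep],
    smiles_canonical = can,
    mw = props$MW,
    logp = props$logP,
    hba = as.integer(hb["hba", ]),
    hbd = as.integer(hb["hbd", ]),
    n_heavy = vapply(g, function(x) if (is.null(x)) NA_integer_ else length(x$elem), 0L),
    pic50 = pic50[keep],
    label = rep("unlabeled", length(keep)),
    set_tag = rep(set_tag, length.out = length(smiles))[keep]
  )
}

# Largest-organic-fragment standardization + canonicalization. Returns
# canonical SMILES (NA = unparsable). Multi-fragment inputs (salts,
# mixtures) keep the fragment with the most heavy atoms, ties broken
# toward the fragment containing carbon.
standardize_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  key <- paste0("s:", smiles)
  have <- vapply(key, function(k) !is.null(.fs_cache[[k]]), logical(1))
  out[have] <- vapply(key[have], function(k) .fs_cache[[k]], "")
  todo <- which(!have)
  if (length(todo)) {
    usm <- unique(smiles[todo])
    # cheap path: single-fragment inputs canonicalize directly
    multi <- grepl(".", usm, fixed = TRUE)
    res <- rep(NA_character_, length(usm))
    res[!multi] <- ob_canonical(usm[!multi])
    if (any(multi)) {
      res[multi] <- vapply(usm[multi], function(s) {
        frags <- strsplit(s, ".", fixed = TRUE)[[1]]
        cans <- ob_canonical(frags)
        g <- mol_graphs(cans)
        sizes <- vapply(g, function(x) if (is.null(x)) -1L else length(x$elem), 0L)
        has_c <- vapply(g, function(x) !is.null(x) && "C" %in% x$elem, logical(1))
        if (all(sizes < 0)) return(NA_character_)
        best <- order(has_c, sizes, decreasing = TRUE)[1]
        cans[best]
      }, "")
    }
    res[!is.na(res) & !nzchar(res)] <- NA_character_
    for (j in seq_along(usm)) .fs_cache[[paste0("s:", usm[j])]] <- res[j]
    out[todo] <- res[match(smiles[todo], usm)]
  }
  out
}

.cached_properties <- function(can_smiles) {
  key <- paste0("p:", can_smiles)
  have <- vapply(key, function(k) !is.null(.fs_cache[[k]]), logical(1))
  res <- matrix(NA_real_, nrow = length(can_smiles), ncol = 2,
                dimnames = list(NULL, c("logP", "MW")))
  if (any(have)) {
    res[have, ] <- t(vapply(key[have], function(k) .fs_cache[[k]], numeric(2)))
  }
  todo <- which(!have)
  if (length(todo)) {
    usm <- unique(can_smiles[todo])
    pr <- ob_properties(usm, length(usm), props = c("logP", "MW"))
    m <- as.matrix(pr)
    for (j in seq_along(usm)) .fs_cache[[paste0("p:", usm[j])]] <- m[j, ]
    res[todo, ] <- m[match(can_smiles[todo], usm), ]
  }
  as.data.frame(res)
}

#' Read molecules from SMILES, SDF or CSV files
#'
#' Reads a structure file and returns standardized compound records.
#' Formats: `.smi` (one SMILES plus optional identifier per line), SDF
#' V2000, or CSV with columns `id`, `smiles` and optionally `ic50`
#' (molar) or `pic50`.
#'
#' @param path path to the input file.
#' @param format `"auto"` (by extension), `"smiles"`, `"sdf"` or `"csv"`.
#' @param set_tag set tag recorded on the returned records.
#' @return A tibble of compound records; see [compound_records()].
#' @export
parse_structures <- function(path, format = c("auto", "smiles", "sdf", "csv"),
                             set_tag = "candidate") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     smi = "smiles", smiles = "smiles",
                     sdf = "sdf", mol = "sdf",
                     csv = "csv", tsv = "csv",
                     stop("cannot guess format of ", path, call. = FALSE))
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("zero parsable structures in ", path, call. = FALSE)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smi <- vapply(parts, `[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
    ids[is.na(ids)] <- paste0("cmpd", which(is.na(ids)))
    compound_records(smi, id = ids, set_tag = set_tag)
  } else if (format == "sdf") {
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
    if (!length(sdfset)) stop("zero parsable structures in ", path, call. = FALSE)
    smi <- as.character(ChemmineR::sdf2smiles(sdfset))
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids)] <- paste0("cmpd", which(!nzchar(ids)))
    compound_records(smi, id = ids, set_tag = set_tag)
  } else {
    sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
    tb <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, comment.char = "")
    names(tb) <- tolower(names(tb))
    if (!all(c("id", "smiles") %in% names(tb))) {
      stop("csv input needs columns 'id' and 'smiles'", call. = FALSE)
    }
    compound_records(tb$smiles, id = tb$id,
                     ic50 = if ("ic50" %in% names(tb)) .parse_ic50(tb$ic50)$value,
                     pic50 = if ("pic50" %in% names(tb)) as.numeric(tb$pic50),
                     set_tag = set_tag)
  }
}

# IC50 columns may carry qualifiers (">", "<", "~"); qualified entries are
# flagged so curation can drop them.
.parse_ic50 <- function(x) {
  x <- as.character(x)
  qualified <- grepl("^[[:space:]]*[<>~]", x)
  value <- suppressWarnings(as.numeric(gsub("[^0-9eE.+-]", "", x)))
  value[qualified] <- NA_real_
  list(value = value, qualified = qualified)
}

#' Write a results table to CSV
#'
#' CSV writer with stable column order and shortest-round-trip float
#' formatting, so that reading the file back reproduces every numeric
#' value bit-identically.
#'
#' @param records a non-empty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0) {
    stop("refusing to write an empty table", call. = FALSE)
  }
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' Detect organometallic compounds
#'
#' A compound is organometallic when any atom falls outside the allowed
#' organic element set \{H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I\}.
#' These are removed during curation: no metal-bearing compound occurs in
#' the inhibitor set, and such atoms break descriptor computation.
#'
#' @param smiles character vector of SMILES (or a compound-record tibble,
#'   in which case `smiles_canonical` is used).
#' @return logical vector.
#' @export
is_organometallic <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles_canonical
  g <- mol_graphs(smiles)
  vapply(g, function(x) {
    if (is.null(x)) return(NA)
    !all(x$elem %in% .ALLOWED_ELEMENTS)
  }, logical(1))
}
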