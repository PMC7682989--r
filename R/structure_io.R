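#' @importFrom stats optim setNames uniroot rnorm sd
#' @importFrom utils read.table write.table head tail
NULL

#' Atomic structure model
#'
#' A light container for an atomic model: one row per coordinate record, with
#' chain identity, author residue numbering, residue/atom names, element,
#' Cartesian position in Angstrom and occupancy. All geometry in the package
#' (axes, superpositions, surface areas) operates on these tables.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer, author
#'   numbering), `resid` (3-letter residue code), `elety` (atom name, e.g.
#'   `"CA"`), `elesy` (element symbol), `x`, `y`, `z` (Angstrom), `o`
#'   (occupancy) and logical `het` (HETATM flag).
#' @param entry_id character label for the model (e.g. a PDB accession).
#' @param protomer_chains character vector of chain ids that constitute the
#'   protomers of the assembly; defaults to all chains present.
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, entry_id = "model",
                            protomer_chains = NULL) {
  required <- c("chain", "resno", "resid", "elety", "elesy",
                "x", "y", "z", "o")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite coordinates in atom records")
  if (any(!nzchar(atoms$elesy)) || any(is.na(atoms$elesy)))
    stop("empty element symbol in atom records")
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(protomer_chains)) protomer_chains <- unique(atoms$chain)
  if (!all(protomer_chains %in% atoms$chain))
    stop("protomer_chains refer to chain(s) absent from the model")
  structure(list(entry_id = entry_id,
                 atoms = atoms,
                 protomer_chains = protomer_chains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, chains %s\n",
              x$entry_id, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

guess_element <- function(elety) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "HG", "CU", "CD")
  e <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)))
  out <- substr(e, 1, 1)
  hit <- substr(e, 1, 2) %in% two & nchar(e) >= 2
  out[hit] <- substr(e[hit], 1, 2)
  out
}

#' Read an atomic coordinate file
#'
#' Parses PDB or mmCIF coordinate records into a [structure_model]. All
#' ATOM/HETATM records are kept; author residue numbering is preserved
#' exactly. When alternate-location conformers are present only the
#' highest-occupancy conformer of each atom is retained, so every atom has a
#' single position.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (default: decide from the file
#'   extension, falling back to PDB).
#' @param entry_id optional label; defaults to the file's base name.
#' @return A [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE,
                                           verbose = FALSE)
      else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad))
    stop("malformed coordinate record at row ", bad[1], " of ", path)
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[miss] <- guess_element(at$elety[miss])
  o <- at$o
  o[is.na(o)] <- 1
  atoms <- data.frame(chain = chain,
                      resno = as.integer(at$resno),
                      resid = at$resid,
                      elety = trimws(at$elety),
                      elesy = trimws(elesy),
                      x = at$x, y = at$y, z = at$z,
                      o = o,
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  # alternate locations: keep the highest-occupancy conformer per atom
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & nzchar(alt))) {
    key <- paste(atoms$chain, atoms$resno, at$insert, atoms$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      i[which.max(atoms$o[i])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
    rownames(atoms) <- NULL
  }
  if (is.null(entry_id))
    entry_id <- tools::file_path_sans_ext(basename(path))
  structure_model(atoms, entry_id = entry_id)
}

#' Write a structure model to a PDB file
#'
#' Coordinates are written at PDB precision (3 decimals), preserving atom
#' order and author residue numbering.
#'
#' @param model a [structure_model].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno,
                   resid = at$resid,
                   eleno = seq_len(nrow(at)),
                   elety = at$elety,
                   chain = at$chain,
                   o = at$o,
                   b = rep(0, nrow(at)),
                   elesy = at$elesy)
  invisible(path)
}

#' Select atoms of a structure model
#'
#' @param model a [structure_model].
#' @param ranges optional data.frame with columns `chain` (may be `NA` for
#'   any chain), `start`, `end` (inclusive author residue numbers), as stored
#'   in a [domain_partition]; `NULL` selects all residues.
#' @param chain optional chain id restriction.
#' @param elety optional atom-name restriction (e.g. `"CA"`).
#' @param include_het include HETATM records (default `FALSE`).
#' @return Integer indices into `model$atoms`.
#' @export
atom_select <- function(model, ranges = NULL, chain = NULL, elety = NULL,
                        include_het = FALSE) {
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!include_het) keep <- keep & !at$het
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  if (!is.null(ranges)) {
    inr <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(ranges))) {
      hit <- at$resno >= ranges$start[i] & at$resno <= ranges$end[i]
      if (!is.na(ranges$chain[i])) hit <- hit & at$chain == ranges$chain[i]
      inr <- inr | hit
    }
    keep <- keep & inr
  }
  which(keep)
}

#' Calpha coordinates of a residue-range selection
#'
#' @inheritParams atom_select
#' @param warn_missing warn when declared residues are unresolved.
#' @return Matrix of Calpha positions (rows named by residue number).
#' @export
ca_coords <- function(model, ranges = NULL, chain = NULL,
                      warn_missing = TRUE) {
  idx <- atom_select(model, ranges, chain, elety = "CA")
  at <- model$atoms[idx, , drop = FALSE]
  if (nrow(at) == 0) stop("empty Calpha selection")
  if (warn_missing && !is.null(ranges)) {
    declared <- sum(pmax(0L, ranges$end - ranges$start + 1L))
    if (nrow(at) < declared)
      message(sprintf("selection: %d of %d declared residues resolved",
                      nrow(at), declared))
  }
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- paste(at$chain, at$resno, sep = ":")
  m
}
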