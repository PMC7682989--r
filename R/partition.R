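#' Domain partition of an elevator transporter
#'
#' Named residue-range sets defining the scaffold (trimerization) domain, the
#' mobile transport domain, helical hairpins HP1/HP2, TM8a and the combined
#' HP2/TM8a motif, together with labelled reference residues (gate tips,
#' crosslink sites, membrane anchors). Ranges use author residue numbering,
#' inclusive on both ends, and are chain-relative: a range with chain `NA`
#' applies to whichever chain a selection is made on.
#'
#' @param sets named list of data.frames (`chain`, `start`, `end`); must
#'   contain `scaffold`, `transport`, `hp1`, `hp2`, `tm8a`,
#'   `hp2_tm8a_motif`.
#' @param reference_residues named list of single residue numbers plus an
#'   `n_terminus_range` entry of the form `c(start, end)`.
#' @return An object of class `domain_partition`.
#' @export
domain_partition <- function(sets, reference_residues) {
  needed <- c("scaffold", "transport", "hp1", "hp2", "tm8a",
              "hp2_tm8a_motif")
  missing_sets <- setdiff(needed, names(sets))
  if (length(missing_sets))
    stop("partition lacks set(s): ", paste(missing_sets, collapse = ", "))
  ref_needed <- c("r276", "p356", "h37", "k55", "a364", "n_terminus_range")
  missing_ref <- setdiff(ref_needed, names(reference_residues))
  if (length(missing_ref))
    stop("partition lacks reference residue(s): ",
         paste(missing_ref, collapse = ", "))
  for (nm in needed) {
    rg <- sets[[nm]]
    if (!all(c("chain", "start", "end") %in% names(rg)))
      stop("set '", nm, "' must have chain/start/end columns")
    if (any(rg$end < rg$start))
      stop("set '", nm, "' has a range with end < start")
    # ranges within a set must not overlap (per chain)
    for (ch in unique(rg$chain)) {
      sub <- rg[is.na(rg$chain) == is.na(ch) &
                  (is.na(ch) | rg$chain %in% ch), , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
        stop("overlapping ranges within set '", nm, "'")
    }
  }
  if (!ranges_contained(sets$hp2, sets$transport))
    stop("hp2 is not contained in the transport domain")
  if (!ranges_contained(sets$hp2_tm8a_motif, sets$transport))
    stop("hp2_tm8a_motif is not contained in the transport domain")
  scalar_refs <- reference_residues[setdiff(ref_needed, "n_terminus_range")]
  for (nm in names(scalar_refs)) {
    res <- as.integer(scalar_refs[[nm]])
    hit <- any(vapply(sets, function(rg)
      any(res >= rg$start & res <= rg$end), logical(1)))
    if (!hit)
      stop("reference residue '", nm, "' (", res,
           ") falls outside every named set")
    scalar_refs[[nm]] <- res
  }
  ntr <- as.integer(reference_residues$n_terminus_range)
  if (length(ntr) != 2 || ntr[2] < ntr[1])
    stop("n_terminus_range must be c(start, end)")
  structure(list(sets = sets,
                 reference_residues = c(scalar_refs,
                                        list(n_terminus_range = ntr))),
            class = "domain_partition")
}

ranges_contained <- function(inner, outer) {
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(inner$start[i] >= outer$start & inner$end[i] <= outer$end)
  }, logical(1)))
}

parse_range_strings <- function(x) {
  # entries like "12-84" or "A:12-84"
  out <- lapply(x, function(s) {
    s <- trimws(as.character(s))
    chain <- NA_character_
    if (grepl(":", s, fixed = TRUE)) {
      parts <- strsplit(s, ":", fixed = TRUE)[[1]]
      chain <- parts[1]
      s <- parts[2]
    }
    m <- regmatches(s, regexec("^(-?[0-9]+)\\s*-\\s*(-?[0-9]+)$", s))[[1]]
    if (length(m) != 3) stop("cannot parse residue range '", s, "'")
    data.frame(chain = chain, start = as.integer(m[2]),
               end = as.integer(m[3]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Load a domain partition from a YAML config
#'
#' The config has a `sets` mapping (set name to a list of `"start-end"` or
#' `"chain:start-end"` strings) and a `reference_residues` mapping. The
#' packaged default (`system.file("extdata", "gltph_partition.yaml",
#' package = "elevatorEM")`) is a curator-derived partition of the GltPh
#' transporter, built from the secondary-structure annotation of the
#' deposited models; it is data, not code, and can be overridden per run.
#'
#' @param path YAML file; `NULL` loads the packaged GltPh default.
#' @return A validated [domain_partition].
#' @export
load_partition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gltph_partition.yaml",
                        package = "elevatorEM")
  if (!file.exists(path)) stop("partition config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sets) || is.null(cfg$reference_residues))
    stop("partition config needs 'sets' and 'reference_residues' blocks")
  sets <- lapply(cfg$sets, parse_range_strings)
  refs <- cfg$reference_residues
  if (!is.null(refs$n_terminus_range) && is.character(refs$n_terminus_range)) {
    rg <- parse_range_strings(refs$n_terminus_range)
    refs$n_terminus_range <- c(rg$start[1], rg$end[1])
  }
  domain_partition(sets, refs)
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("domain_partition with sets:\n")
  for (nm in names(x$sets)) {
    rg <- x$sets[[nm]]
    cat(sprintf("  %-15s %s\n", nm,
                paste(ifelse(is.na(rg$chain), "", paste0(rg$chain, ":")),
                      rg$start, "-", rg$end, sep = "", collapse = ", ")))
  }
  invisible(x)
}

#' Residue ranges of a named partition set
#'
#' @param partition a [domain_partition].
#' @param set one of the named sets.
#' @return The ranges data.frame.
#' @export
partition_set <- function(partition, set) {
  rg <- partition$sets[[set]]
  if (is.null(rg)) stop("unknown partition set '", set, "'")
  rg
}
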