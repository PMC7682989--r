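## Shrake-Rupley solvent-accessible surface area on a deterministic
## (seed-free) spherical spiral lattice, and the PISA-style half-buried
## inter-domain interface area derived from it.

#' Packaged van der Waals radii
#'
#' Chothia-type heavy-atom radii (Angstrom) read from the packaged table;
#' elements without an entry fall back to 1.70 A with a warning.
#'
#' @return Named numeric vector of radii.
#' @export
vdw_radii <- function() {
  path <- system.file("extdata", "vdw_radii.tsv", package = "elevatorEM")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(tab$radius, toupper(tab$element))
}

# deterministic Fibonacci spiral lattice on the unit sphere (n x 3)
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elesy, radii) {
  el <- toupper(elesy)
  r <- radii[el]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(el[unknown]), collapse = ", "),
            "; using 1.70 A fallback")
    r[unknown] <- 1.70
  }
  as.numeric(r)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each selected atom, `n_points` test points are placed on a
#' deterministic spherical spiral lattice of radius `r_vdw + probe`; a point
#' is accessible iff it lies outside every other selected atom's expanded
#' sphere. The atom's area is the accessible fraction times
#' `4 * pi * (r_vdw + probe)^2`. Hydrogens are ignored.
#'
#' @param model a [structure_model].
#' @param idx integer atom indices defining the selection (default: all
#'   non-hydrogen, non-HETATM atoms).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points lattice points per atom (default 960).
#' @param radii named radius table (default [vdw_radii()]).
#' @return List of class `sasa_result`: `per_atom` (Angstrom^2, one entry
#'   per selected atom), `total`, `probe`, `n_points`, `idx`.
#' @export
sasa <- function(model, idx = NULL, probe = 1.4, n_points = 960,
                 radii = vdw_radii()) {
  if (probe <= 0) stop("probe radius must be > 0")
  if (n_points < 100) stop("need at least 100 lattice points")
  at <- model$atoms
  if (is.null(idx)) idx <- which(!at$het & toupper(at$elesy) != "H")
  idx <- idx[toupper(at$elesy[idx]) != "H"]
  if (length(idx) == 0) stop("empty atom selection")
  xyz <- as.matrix(at[idx, c("x", "y", "z")])
  r_exp <- atom_radii(at$elesy[idx], radii) + probe
  L <- sphere_lattice(n_points)
  n <- length(idx)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2 <- rowSums(sweep(xyz, 2, ci)^2)
    nb <- which(d2 < (r_exp[i] + r_exp)^2 & seq_len(n) != i)
    pts <- sweep(L * r_exp[i], 2, ci, "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 >= r_exp[j]^2
    }
    per_atom[i] <- mean(exposed) * 4 * pi * r_exp[i]^2
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe = probe, n_points = n_points, idx = idx),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: %d atoms, total %.1f A^2 (probe %.2f A, %d points)\n",
              length(x$per_atom), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Buried interface area between two residue sets
#'
#' PISA-style half-buried convention:
#' `(SASA(A alone) + SASA(B alone) - SASA(A union B)) / 2`. Each component
#' is evaluated in isolation — atoms outside the two sets never shadow the
#' interface. Heteroatoms are excluded by default (protein-protein
#' interface); the full-buried value is exactly twice the reported area.
#'
#' @param model a [structure_model].
#' @param ranges_a,ranges_b residue-range data.frames of the two sets (see
#'   [atom_select]); must select disjoint atom sets.
#' @param chain chain restriction applied to both sets.
#' @param probe probe radius, Angstrom.
#' @param n_points lattice points per atom.
#' @param include_het include HETATM records.
#' @param convention `"half"` (PISA, default) or `"full"`.
#' @return List of class `interface_report`: `area` (Angstrom^2),
#'   `sasa_a`, `sasa_b`, `sasa_ab`, `convention`.
#' @export
buried_interface_area <- function(model, ranges_a, ranges_b, chain = NULL,
                                  probe = 1.4, n_points = 960,
                                  include_het = FALSE,
                                  convention = c("half", "full")) {
  convention <- match.arg(convention)
  ia <- atom_select(model, ranges_a, chain, include_het = include_het)
  ib <- atom_select(model, ranges_b, chain, include_het = include_het)
  if (length(ia) == 0 || length(ib) == 0)
    stop("interface sets must both be non-empty")
  if (length(intersect(ia, ib)))
    stop("interface residue sets overlap")
  sa <- sasa(model, ia, probe, n_points)$total
  sb <- sasa(model, ib, probe, n_points)$total
  sab <- sasa(model, c(ia, ib), probe, n_points)$total
  area <- (sa + sb - sab) / 2
  if (convention == "full") area <- 2 * area
  structure(list(area = max(0, area), sasa_a = sa, sasa_b = sb,
                 sasa_ab = sab, convention = convention),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: %.1f A^2 (%s-buried convention)\n",
              x$area, x$convention))
  invisible(x)
}

#' Interface-area change between two states
#'
#' Buried interface area between the HP2/TM8a motif and the scaffold in
#' `state`, minus the same quantity in `reference`.
#'
#' @param state,reference [structure_model]s.
#' @param partition a [domain_partition].
#' @param chain_state,chain_ref protomer chains (defaults: first of each).
#' @param ... forwarded to [buried_interface_area()].
#' @return Signed area difference in Angstrom^2, with the two interface
#'   reports as attributes `state` and `reference`.
#' @export
interface_delta <- function(state, reference, partition,
                            chain_state = NULL, chain_ref = NULL, ...) {
  if (is.null(chain_state)) chain_state <- state$protomer_chains[1]
  if (is.null(chain_ref)) chain_ref <- reference$protomer_chains[1]
  motif <- partition_set(partition, "hp2_tm8a_motif")
  scaf <- partition_set(partition, "scaffold")
  a <- buried_interface_area(state, motif, scaf, chain = chain_state, ...)
  b <- buried_interface_area(reference, motif, scaf, chain = chain_ref, ...)
  out <- a$area - b$area
  attr(out, "state") <- a
  attr(out, "reference") <- b
  out
}
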