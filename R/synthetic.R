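## Seeded synthetic fixtures: two-domain toy structures with planted
## tilt/rotation/shift, exact three-fold toy trimers, planar and dimpled
## membrane-slab density maps, and titration isotherms. Every generator is
## a pure function of its arguments and seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rotation_matrix <- function(axis, angle_deg) {
  u <- normalize3(as.numeric(axis))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * c + s * K + (1 - c) * (u %o% u)
}

# helix-like Calpha cylinder: n points, given radius and total length,
# axis along z, centered at the origin
helix_points <- function(n = 100, radius = 4, length = 40,
                         turn_deg = 100) {
  i <- seq_len(n)
  th <- (i - 1) * turn_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th),
        seq(-length / 2, length / 2, length.out = n))
}

toy_atoms <- function(xyz, chain, resno_start, resid = "ALA") {
  data.frame(chain = chain,
             resno = seq(resno_start, length.out = nrow(xyz)),
             resid = resid, elety = "CA", elesy = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, het = FALSE, stringsAsFactors = FALSE)
}

toy_partition <- function() {
  sets <- list(
    scaffold = data.frame(chain = NA_character_, start = 1L, end = 100L),
    transport = data.frame(chain = NA_character_, start = 101L, end = 200L),
    hp1 = data.frame(chain = NA_character_, start = 105L, end = 125L),
    hp2 = data.frame(chain = NA_character_, start = 150L, end = 170L),
    tm8a = data.frame(chain = NA_character_, start = 171L, end = 185L),
    hp2_tm8a_motif = data.frame(chain = NA_character_, start = 150L,
                                end = 185L))
  domain_partition(sets, list(r276 = 110L, p356 = 160L, h37 = 37L,
                              k55 = 55L, a364 = 175L,
                              n_terminus_range = c(1L, 5L)))
}

#' Two-domain toy structures with planted tilt, rotation and shift
#'
#' Builds a reference state with a "scaffold" Calpha cylinder along the
#' membrane normal (z) and a "transport" cylinder tilted by `tilt` degrees,
#' then a second state in which the transport domain is additionally
#' rotated by `rotation` degrees about a fixed pivot axis through its
#' centroid and translated by `shift` Angstrom along the normal, while the
#' scaffold is unchanged. The planted values are exactly the quantities
#' [transport_tilt()], [rotation_between()] and
#' [com_shift_along_normal()] measure (with `membrane_frame_from(c(0, 0,
#' 1))`).
#'
#' @param tilt transport-domain tilt of the reference state, degrees
#'   (clamped to \[0, 90\] with a warning).
#' @param rotation planted inter-state rotation, degrees (clamped to
#'   \[0, 180\]).
#' @param shift planted translocation along the normal, Angstrom (negative
#'   = toward the cytoplasm).
#' @param seed integer seed (reserved for optional jitter; the default
#'   geometry is deterministic).
#' @param jitter_sd per-coordinate Gaussian jitter applied identically to
#'   both states, Angstrom (default 0).
#' @return List with `state_a`, `state_b` ([structure_model]s),
#'   `partition`, `frame` and `truth` (`planted_tilt`, `planted_rotation`,
#'   `rotation_axis`, `planted_shift`, `seed`).
#' @export
make_two_domain_toy <- function(tilt = 35, rotation = 0, shift = 0,
                                seed = 1, jitter_sd = 0) {
  clamp <- function(x, lo, hi, what) {
    if (x < lo || x > hi) {
      warning(what, " clamped into [", lo, ", ", hi, "]")
      x <- min(hi, max(lo, x))
    }
    x
  }
  tilt <- clamp(tilt, 0, 90, "tilt")
  rotation <- clamp(rotation, 0, 180, "rotation")
  scaffold <- helix_points(100, radius = 5, length = 45)
  transport <- helix_points(100, radius = 4, length = 40)
  transport <- transport %*% t(rotation_matrix(c(1, 0, 0), tilt))
  transport <- sweep(transport, 2, c(18, 0, 0), "+")
  if (jitter_sd > 0) {
    jit <- with_seed(seed, matrix(rnorm(600, sd = jitter_sd), 200, 3))
    scaffold <- scaffold + jit[1:100, ]
    transport <- transport + jit[101:200, ]
  }
  pivot_axis <- normalize3(c(0.3, 1, 0.2))  # fixed, oblique to the normal
  centroid <- colMeans(transport)
  rot <- rotation_matrix(pivot_axis, rotation)
  transport_b <- sweep(sweep(transport, 2, centroid) %*% t(rot), 2,
                       centroid, "+")
  transport_b <- sweep(transport_b, 2, c(0, 0, shift), "+")
  state_a <- structure_model(rbind(toy_atoms(scaffold, "A", 1),
                                   toy_atoms(transport, "A", 101)),
                             entry_id = "toy_ref")
  state_b <- structure_model(rbind(toy_atoms(scaffold, "A", 1),
                                   toy_atoms(transport_b, "A", 101)),
                             entry_id = "toy_moved")
  list(state_a = state_a, state_b = state_b,
       partition = toy_partition(),
       frame = membrane_frame_from(c(0, 0, 1), colMeans(scaffold)),
       truth = list(planted_tilt = tilt, planted_rotation = rotation,
                    rotation_axis = pivot_axis, planted_shift = shift,
                    seed = seed))
}

#' Exact three-fold toy trimer
#'
#' One two-domain protomer placed off the z-axis, copied by exact 120 and
#' 240 degree rotations about z into chains A/B/C. [membrane_frame()] on
#' the result recovers the normal `(0, 0, 1)` to machine precision.
#'
#' @param seed integer seed (reserved; geometry is deterministic).
#' @return List with `model` ([structure_model]) and `partition`.
#' @export
make_toy_trimer <- function(seed = 1) {
  scaffold <- sweep(helix_points(100, radius = 5, length = 45), 2,
                    c(22, 0, 0), "+")
  transport <- helix_points(100, radius = 4, length = 40)
  transport <- transport %*% t(rotation_matrix(c(1, 0, 0), 35))
  transport <- sweep(transport, 2, c(40, 0, 0), "+")
  protomer <- rbind(scaffold, transport)
  chains <- c("A", "B", "C")
  atoms <- do.call(rbind, lapply(0:2, function(k) {
    xyz <- protomer %*% t(rotation_matrix(c(0, 0, 1), 120 * k))
    rbind(toy_atoms(xyz[1:100, ], chains[k + 1], 1),
          toy_atoms(xyz[101:200, ], chains[k + 1], 101))
  }))
  list(model = structure_model(atoms, entry_id = "toy_trimer",
                               protomer_chains = chains),
       partition = toy_partition())
}

#' Membrane-slab density map with a planted deformation
#'
#' A uniform-density slab between `-half_thickness` and `+half_thickness`
#' (value 1 inside, 0 outside), locally deflected toward the stated side by
#' a Gaussian profile of the stated depth: both faces follow
#' `z = +/- half_thickness + s * depth * exp(-r^2 / (2 * sigma^2))` with
#' `s = -1` for the cytoplasmic side and `+1` for the extracellular side,
#' emulating a bilayer bending around a protruding transport domain. Voxel
#' values are antialiased at the faces (fractional occupancy), and optional
#' Gaussian voxel noise is seeded.
#'
#' @param voxel voxel size, Angstrom.
#' @param half_thickness slab half-thickness, Angstrom (default 15).
#' @param dimple_depth planted deformation depth, Angstrom (must not exceed
#'   `half_thickness`).
#' @param dimple_sigma Gaussian width of the deformation, Angstrom (must
#'   exceed the voxel size).
#' @param side `"cytoplasmic"` (deflection toward -z) or
#'   `"extracellular"`.
#' @param dimple_center in-plane center `c(x, y)` of the deformation.
#' @param extent in-plane half-extent of the map, Angstrom (default 40).
#' @param noise_sd Gaussian voxel noise standard deviation (default 0).
#' @param seed integer seed for the noise.
#' @return List with `grid` (a [density_grid]) and `truth`
#'   (`dimple_depth`, `dimple_sigma`, `side`, `dimple_center`, `seed`).
#' @export
make_slab_density <- function(voxel = 1, half_thickness = 15,
                              dimple_depth = 0, dimple_sigma = 8,
                              side = c("cytoplasmic", "extracellular"),
                              dimple_center = c(0, 0), extent = 40,
                              noise_sd = 0, seed = 1) {
  side <- match.arg(side)
  if (voxel <= 0) stop("voxel must be > 0")
  if (dimple_depth > half_thickness)
    stop("dimple_depth exceeds the slab half-thickness")
  if (dimple_depth > 0 && dimple_sigma <= voxel)
    stop("dimple_sigma must exceed the voxel size")
  zmax <- half_thickness + dimple_depth + 6
  x <- seq(-extent, extent, by = voxel)
  y <- seq(-extent, extent, by = voxel)
  z <- seq(-zmax, zmax, by = voxel)
  s <- if (side == "cytoplasmic") -1 else 1
  g <- exp(-(outer((x - dimple_center[1])^2,
                   (y - dimple_center[2])^2, "+")) / (2 * dimple_sigma^2))
  offset <- s * dimple_depth * g            # nx x ny midplane deflection
  vals <- array(0, dim = c(length(x), length(y), length(z)))
  hv <- voxel / 2
  for (k in seq_along(z)) {
    lo <- pmax(z[k] - hv, offset - half_thickness)
    hi <- pmin(z[k] + hv, offset + half_thickness)
    vals[, , k] <- pmax(0, hi - lo) / voxel   # fractional slab occupancy
  }
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, array(rnorm(length(vals), sd = noise_sd),
                                         dim = dim(vals)))
  list(grid = density_grid(vals, voxel = voxel,
                           origin = c(-extent, -extent, -zmax)),
       truth = list(dimple_depth = dimple_depth,
                    dimple_sigma = dimple_sigma, side = side,
                    dimple_center = dimple_center, seed = seed))
}

#' Synthetic titration isotherm
#'
#' Simulated independent-sites heats with optional seeded Gaussian noise.
#' The default design is a typical blocker-binding titration: 40 uM
#' macromolecule in a 185 uL cell titrated with 25 x 2 uL injections of a
#' 400 uM syringe solution at 15 degrees C.
#'
#' @param n sites per macromolecule.
#' @param kd dissociation constant, mol/L.
#' @param dh binding enthalpy, cal/mol of injectant.
#' @param design an [itc_experiment] giving the titration design (default
#'   as above).
#' @param q_offset baseline heat per injection, ucal.
#' @param noise_sd Gaussian heat noise, ucal (default 0).
#' @param seed integer seed.
#' @return An [itc_experiment] with `heats` filled in.
#' @export
make_itc_isotherm <- function(n = 1, kd = 3.8e-6, dh = -8000,
                              design = NULL, q_offset = 0,
                              noise_sd = 0, seed = 1) {
  if (is.null(design))
    design <- itc_experiment(cell_conc = 40e-6, syringe_conc = 400e-6,
                             injection_volumes = rep(2e-6, 25),
                             cell_volume = 185e-6, temperature = 15)
  heats <- simulate_isotherm(design, n, kd, dh, q_offset)
  if (noise_sd > 0)
    heats <- heats + with_seed(seed, rnorm(length(heats), sd = noise_sd))
  design$heats <- heats
  design
}
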