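# shared builders and independent oracles for the test suite

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, elem = "C") {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           %s",
          serial, name, resn, chain, resno, x, y, z, occ, elem)
}

write_toy_pdb <- function(path, xyz, chain = "A", resno = NULL,
                          elem = "C") {
  if (is.null(resno)) resno <- seq_len(nrow(xyz))
  lines <- vapply(seq_len(nrow(xyz)), function(i)
    pdb_atom_line(i, "CA", "GLY", chain, resno[i],
                  xyz[i, 1], xyz[i, 2], xyz[i, 3], elem = elem),
    character(1))
  writeLines(c(lines, "END"), path)
  path
}

# a structure_model straight from coordinates (all-carbon CA pseudo-atoms)
model_from_xyz <- function(xyz, chain = "A", resno = NULL, elesy = "C",
                           elety = "CA", entry_id = "toy") {
  if (is.null(resno)) resno <- seq_len(nrow(xyz))
  structure_model(data.frame(chain = chain, resno = resno, resid = "GLY",
                             elety = elety, elesy = elesy,
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             o = 1, het = FALSE, stringsAsFactors = FALSE),
                  entry_id = entry_id)
}

rigid_transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, t, "+")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

rot_mat <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
}

# analytic SASA of two intersecting spheres with expanded radii R1, R2 at
# center distance d: exposed area of each = full sphere minus the buried
# spherical cap
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  cap <- function(R, r, d) {
    # cap of sphere R buried inside sphere r at distance d
    if (d + R <= r) return(4 * pi * R^2)   # fully inside
    ca <- (d^2 + R^2 - r^2) / (2 * d * R)
    2 * pi * R^2 * (1 - ca)
  }
  c(4 * pi * R1^2 - cap(R1, R2, d), 4 * pi * R2^2 - cap(R2, R1, d))
}

# brute-force dense-lattice SASA for a small atom set (independent of the
# package implementation: random directions, seeded)
brute_sasa <- function(xyz, radii_exp, n_pts = 1e5, seed = 42) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n_pts), n_pts, 3)
  u <- u / sqrt(rowSums(u^2))
  vapply(seq_len(nrow(xyz)), function(i) {
    pts <- sweep(u * radii_exp[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_pts)
    for (j in seq_len(nrow(xyz))[-i]) {
      exposed <- exposed &
        rowSums(sweep(pts, 2, xyz[j, ])^2) >= radii_exp[j]^2
    }
    mean(exposed) * 4 * pi * radii_exp[i]^2
  }, numeric(1))
}

# high-precision bisection solution of the independent-sites mass-action
# equation (xt - xb)(n*mt - xb) = kd * xb
bisect_bound <- function(mt, xt, n, kd, iters = 200) {
  if (xt == 0) return(0)
  g <- function(xb) (xt - xb) * (n * mt - xb) - kd * xb
  lo <- 0
  hi <- min(n * mt, xt)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# independent re-simulation of a titration using the bisection solver
oracle_isotherm <- function(design, n, kd, dh, q_offset = 0) {
  v0 <- design$cell_volume
  mt <- design$cell_conc
  xt <- 0
  xb_prev <- 0
  out <- numeric(length(design$injection_volumes))
  for (i in seq_along(out)) {
    v <- design$injection_volumes[i]
    f <- 1 - v / v0
    mt <- mt * f
    xt <- xt * f + (v / v0) * design$syringe_conc
    xb <- bisect_bound(mt, xt, n, kd)
    out[i] <- dh * v0 * (xb - xb_prev * f) * 1e6 + q_offset
    xb_prev <- xb
  }
  out
}

flat_frame <- function() membrane_frame_from(c(0, 0, 1), c(0, 0, 0))

# three rim pseudo-atoms far from the slab center, used as a flat
# zero-level reference for synthetic deformation maps
rim_model <- function(r = 35) {
  model_from_xyz(rbind(c(r, r, 0), c(-r, -r, 0), c(r, -r, 0)))
}
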