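## Nanodisc membrane-deformation analysis: segment the lipid slab out of a
## cryo-EM density map, extract per-leaflet height fields along the membrane
## normal, reference them to a residue-anchored zero level, and report
## signed deformation extrema.

# deterministic in-plane basis (u, v) orthogonal to the frame normal
plane_basis <- function(frame) {
  n <- frame$normal
  e <- if (abs(n[1]) <= abs(n[2]) && abs(n[1]) <= abs(n[3])) c(1, 0, 0)
       else if (abs(n[2]) <= abs(n[3])) c(0, 1, 0) else c(0, 0, 1)
  u <- normalize3(c(n[2] * e[3] - n[3] * e[2],
                    n[3] * e[1] - n[1] * e[3],
                    n[1] * e[2] - n[2] * e[1]))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

# project Cartesian points into frame coordinates (a, b = in-plane; h = height)
frame_coords <- function(pts, frame, basis = plane_basis(frame)) {
  rel <- sweep(pts, 2, frame$center)
  cbind(a = as.numeric(rel %*% basis$u),
        b = as.numeric(rel %*% basis$v),
        h = as.numeric(rel %*% frame$normal))
}

#' Segment nanodisc density out of a cryo-EM map
#'
#' A voxel belongs to the nanodisc iff its value is at least
#' `threshold_sigma` map standard deviations (computed after masking out
#' protein-proximal voxels), it lies farther than
#' `protein_mask_radius` from every model atom, and its height above the
#' frame center along the membrane normal is at most `slab_half_width` in
#' magnitude.
#'
#' @param density a [density_grid].
#' @param model optional [structure_model] whose atoms mask the protein;
#'   `NULL` masks nothing.
#' @param frame a [membrane_frame] (map and model must share its coordinate
#'   system).
#' @param threshold_sigma density threshold in map-sigma units (default 1).
#' @param protein_mask_radius exclusion radius around atoms, Angstrom
#'   (default 4).
#' @param slab_half_width half-width of the accepted slab about the frame
#'   center, Angstrom (default 25).
#' @return A binary [density_grid] (1 = nanodisc).
#' @export
segment_nanodisc <- function(density, model = NULL, frame,
                             threshold_sigma = 1,
                             protein_mask_radius = 4,
                             slab_half_width = 25) {
  if (threshold_sigma <= 0) stop("threshold_sigma must be > 0")
  d <- dim(density$values)
  ax <- voxel_axes(density)
  protein_free <- array(TRUE, dim = d)
  if (!is.null(model) && nrow(model$atoms) > 0) {
    xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
    r <- protein_mask_radius
    for (k in seq_len(nrow(xyz))) {
      p <- xyz[k, ]
      i <- which(abs(ax[[1]] - p[1]) <= r)
      j <- which(abs(ax[[2]] - p[2]) <= r)
      l <- which(abs(ax[[3]] - p[3]) <= r)
      if (!length(i) || !length(j) || !length(l)) next
      dx2 <- (ax[[1]][i] - p[1])^2
      dy2 <- (ax[[2]][j] - p[2])^2
      dz2 <- (ax[[3]][l] - p[3])^2
      box <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
      protein_free[i, j, l] <- protein_free[i, j, l] & !box
    }
  }
  thr <- threshold_sigma * sd(density$values[protein_free])
  if (!is.finite(thr) || thr <= 0)
    stop("empty nanodisc segmentation: map has no density contrast")
  # height of each voxel along the normal
  hx <- (ax[[1]] - frame$center[1]) * frame$normal[1]
  hy <- (ax[[2]] - frame$center[2]) * frame$normal[2]
  hz <- (ax[[3]] - frame$center[3]) * frame$normal[3]
  h <- outer(outer(hx, hy, "+"), hz, "+")
  sel <- density$values >= thr & protein_free & abs(h) <= slab_half_width
  if (!any(sel))
    stop("empty nanodisc segmentation; lower threshold_sigma or check the ",
         "frame/slab settings")
  density_grid(array(as.numeric(sel), dim = d),
               voxel = density$voxel, origin = density$origin)
}

#' Leaflet height field of a segmented nanodisc
#'
#' The segmented map is resampled into the membrane frame (normal = height
#' axis). For every in-plane grid column, the height of the outermost
#' segmented sample on the requested side is returned, refined to sub-voxel
#' precision by linear interpolation of the 0.5-crossing of the trilinearly
#' interpolated occupancy. Columns with no segmented voxel are unmasked.
#'
#' @param segmented binary [density_grid] from [segment_nanodisc()].
#' @param frame a [membrane_frame].
#' @param side `"extracellular"` (heights toward +normal) or
#'   `"cytoplasmic"`.
#' @param spacing in-plane node spacing, Angstrom (default: smallest voxel).
#' @param height_range heights scanned along the normal (default +/- 30 A).
#' @return Object of class `deformation_map`: matrices `heights` and `mask`
#'   on in-plane coordinates `a`, `b`, plus the frame, basis and `side`;
#'   `zero_level` is `NA` until [reference_zero()] is applied.
#' @export
leaflet_surface <- function(segmented, frame,
                            side = c("extracellular", "cytoplasmic"),
                            spacing = NULL, height_range = c(-30, 30)) {
  side <- match.arg(side)
  if (!any(segmented$values > 0)) stop("segmentation is empty")
  basis <- plane_basis(frame)
  d <- dim(segmented$values)
  corners <- as.matrix(expand.grid(
    segmented$origin[1] + c(0, (d[1] - 1) * segmented$voxel[1]),
    segmented$origin[2] + c(0, (d[2] - 1) * segmented$voxel[2]),
    segmented$origin[3] + c(0, (d[3] - 1) * segmented$voxel[3])))
  fc <- frame_coords(corners, frame, basis)
  if (is.null(spacing)) spacing <- min(segmented$voxel)
  a_nodes <- seq(min(fc[, "a"]), max(fc[, "a"]), by = spacing)
  b_nodes <- seq(min(fc[, "b"]), max(fc[, "b"]), by = spacing)
  dz <- min(segmented$voxel) / 2
  t_nodes <- seq(height_range[1], height_range[2], by = dz)
  nt <- length(t_nodes)
  grid2d <- as.matrix(expand.grid(a = a_nodes, b = b_nodes))
  heights <- matrix(NA_real_, length(a_nodes), length(b_nodes))
  mask <- matrix(FALSE, length(a_nodes), length(b_nodes))
  # sample all columns at one height slice at a time (memory-friendly)
  occ <- matrix(0, nrow(grid2d), nt)
  base_pts <- outer(grid2d[, "a"], basis$u) + outer(grid2d[, "b"], basis$v)
  base_pts <- sweep(base_pts, 2, frame$center, "+")
  for (k in seq_len(nt)) {
    pts <- sweep(base_pts, 2, t_nodes[k] * frame$normal, "+")
    occ[, k] <- interp_density(segmented, pts, outside = 0)
  }
  inside <- occ >= 0.5
  for (q in seq_len(nrow(grid2d))) {
    ins <- which(inside[q, ])
    if (!length(ins)) next
    k <- if (side == "extracellular") max(ins) else min(ins)
    h <- t_nodes[k]
    # refine the 0.5 crossing toward the outside of the slab
    kn <- if (side == "extracellular") k + 1 else k - 1
    if (kn >= 1 && kn <= nt && occ[q, k] > occ[q, kn]) {
      fr <- (occ[q, k] - 0.5) / (occ[q, k] - occ[q, kn])
      h <- h + fr * (t_nodes[kn] - t_nodes[k])
    }
    i <- (q - 1) %% length(a_nodes) + 1
    j <- (q - 1) %/% length(a_nodes) + 1
    heights[i, j] <- h
    mask[i, j] <- TRUE
  }
  structure(list(heights = heights, mask = mask,
                 a = a_nodes, b = b_nodes,
                 side = side, frame = frame, basis = basis,
                 zero_level = NA_real_, displacement = NULL),
            class = "deformation_map")
}

#' @export
print.deformation_map <- function(x, ...) {
  cat(sprintf(
    "deformation_map (%s): %d x %d nodes, %d valid, zero_level %s\n",
    x$side, length(x$a), length(x$b), sum(x$mask),
    if (is.na(x$zero_level)) "unset" else sprintf("%.2f A", x$zero_level)))
  invisible(x)
}

# in-plane (a, b) coordinates of the Calphas of a residue reference
project_reference <- function(map, model, reference, chain = NULL) {
  if (is.numeric(reference)) {
    reference <- data.frame(chain = NA_character_,
                            start = min(reference), end = max(reference))
  }
  X <- ca_coords(model, reference, chain, warn_missing = FALSE)
  frame_coords(X, map$frame, map$basis)[, c("a", "b"), drop = FALSE]
}

#' Reference a height field to a residue-anchored zero level
#'
#' The zero level is the mean height over valid nodes whose in-plane
#' distance to the projected reference Calpha(s) lies within the annulus;
#' the displacement field is `heights - zero_level`. With the membrane
#' normal pointing extracellular, negative displacement on the
#' extracellular side means inward bending (toward the cytoplasm) and
#' negative displacement on the cytoplasmic side means outward bending —
#' the two sides' reporting conventions.
#'
#' @param map a `deformation_map`.
#' @param model the [structure_model] in the map's coordinate system.
#' @param reference single residue number, `c(start, end)` range, or a
#'   ranges data.frame.
#' @param chain chain restriction for the reference residues.
#' @param annulus `c(r_min, r_max)` in Angstrom (default `c(0, 8)`).
#' @return The map with `zero_level` and `displacement` filled in.
#' @export
reference_zero <- function(map, model, reference, chain = NULL,
                           annulus = c(0, 8)) {
  ab <- project_reference(map, model, reference, chain)
  nodes <- as.matrix(expand.grid(a = map$a, b = map$b))
  dmin <- rep(Inf, nrow(nodes))
  for (k in seq_len(nrow(ab)))
    dmin <- pmin(dmin, sqrt((nodes[, 1] - ab[k, 1])^2 +
                              (nodes[, 2] - ab[k, 2])^2))
  in_ann <- matrix(dmin >= annulus[1] & dmin <= annulus[2],
                   length(map$a), length(map$b))
  use <- in_ann & map$mask
  if (!any(use))
    stop("reference annulus contains no valid height samples; widen the ",
         "annulus or check the reference residues")
  map$zero_level <- mean(map$heights[use])
  map$displacement <- map$heights - map$zero_level
  map$displacement[!map$mask] <- NA_real_
  map
}

#' Signed deformation extremum of a displacement field
#'
#' Returns the signed displacement of largest magnitude within a region of
#' the membrane plane.
#'
#' @param map a `deformation_map` with a zero level set.
#' @param region `"all"`, a logical matrix matching the node grid, or a
#'   list `list(center = c(a, b), radius = r)` in in-plane coordinates (see
#'   [project_reference] via `model`/`reference` for residue-anchored
#'   regions).
#' @param model,reference,chain when `region = "near_transport_domain"`,
#'   the region is all nodes within `radius` of the projected Calpha
#'   centroid of `reference` (typically the transport-domain ranges of a
#'   partition) of `model`.
#' @param radius in-plane radius for `"near_transport_domain"`, Angstrom
#'   (default 15).
#' @return Signed displacement in Angstrom.
#' @export
max_deformation <- function(map, region = "all", model = NULL,
                            reference = NULL, chain = NULL, radius = 15) {
  if (is.null(map$displacement))
    stop("set the zero level with reference_zero() first")
  sel <- map$mask
  if (is.matrix(region)) {
    sel <- sel & region
  } else if (is.list(region)) {
    sel <- sel & node_disc(map, region$center, region$radius)
  } else if (identical(region, "near_transport_domain")) {
    if (is.null(model) || is.null(reference))
      stop("near_transport_domain needs `model` and `reference`")
    ab <- project_reference(map, model, reference, chain)
    sel <- sel & node_disc(map, colMeans(ab), radius)
  } else if (!identical(region, "all")) {
    stop("unknown region specification")
  }
  if (!any(sel)) stop("region contains no valid displacement samples")
  vals <- map$displacement[sel]
  vals[which.max(abs(vals))]
}

node_disc <- function(map, center, radius) {
  outer((map$a - center[1])^2, (map$b - center[2])^2, "+") <= radius^2
}

#' Export a displacement field as a TSV grid
#'
#' Long-format table with in-plane coordinates, height, displacement and
#' mask, suitable for plotting.
#'
#' @param map a `deformation_map`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_deformation_tsv <- function(map, path) {
  df <- expand.grid(a = map$a, b = map$b)
  df$height <- as.numeric(map$heights)
  df$displacement <- if (is.null(map$displacement)) NA_real_
                     else as.numeric(map$displacement)
  df$valid <- as.logical(map$mask)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
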