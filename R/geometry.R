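## Rigid-body geometry of elevator-transporter domains: membrane frame,
## tilt angle alpha1, inter-state rotation alpha2, gating distance d,
## Calpha RMSD and transport-domain translocation along the membrane normal.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

# Kabsch optimal rigid superposition of point set P onto Q (both N x 3).
# Returns rotation R and translation t with Q ~ P %*% t(R) + t, plus rmsd.
kabsch <- function(P, Q) {
  if (nrow(P) != nrow(Q)) stop("point sets differ in size")
  if (nrow(P) < 3) stop("need at least 3 points for superposition")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  dsign <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, dsign)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t, "+")
  list(R = R, t = t,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

apply_rigid <- function(X, R, t) sweep(X %*% t(R), 2, t, "+")

# rotation angle (deg) and unit axis of a 3x3 rotation matrix
rotation_angle_axis <- function(R) {
  tr <- sum(diag(R))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  if (ang > 179.999) {
    return(list(angle = 180, axis = c(NA, NA, NA), axis_defined = FALSE))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(ax^2)) < 1e-9) {
    # numerically the identity: acos() inflates rounding noise near tr = 3,
    # while the skew part stays at machine epsilon
    return(list(angle = ang, axis = c(NA, NA, NA), axis_defined = FALSE))
  }
  list(angle = ang, axis = normalize3(ax), axis_defined = TRUE)
}

#' Membrane reference frame
#'
#' A unit membrane normal (pointing toward the extracellular side) and a
#' center point, the reference frame for tilt angles, translocation
#' displacements and deformation maps.
#'
#' @param normal 3-vector; normalized internally.
#' @param center 3-vector, Angstrom.
#' @return An object of class `membrane_frame`.
#' @export
membrane_frame_from <- function(normal, center = c(0, 0, 0)) {
  structure(list(normal = normalize3(as.numeric(normal)),
                 center = as.numeric(center)),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("membrane_frame: normal (%.4f, %.4f, %.4f), center (%.2f, %.2f, %.2f)\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Principal (long) axis of a Calpha point cloud
#'
#' Returns the inertia eigenvector with the smallest moment — the long axis
#' of a roughly cylindrical domain. The sign is chosen so the dot product
#' with the membrane normal is non-negative when a frame is supplied;
#' otherwise the first non-zero component is made positive (deterministic).
#'
#' @param model a [structure_model].
#' @param ranges residue ranges of the selection (see [atom_select]).
#' @param chain chain restriction.
#' @param frame optional [membrane_frame] fixing the axis orientation.
#' @return Unit 3-vector.
#' @export
principal_axis <- function(model, ranges = NULL, chain = NULL,
                           frame = NULL) {
  X <- ca_coords(model, ranges, chain, warn_missing = FALSE)
  if (nrow(X) < 3) stop("principal_axis needs at least 3 Calpha atoms")
  Xc <- sweep(X, 2, colMeans(X))
  if (max(abs(Xc)) < 1e-9) stop("degenerate point cloud (all coincident)")
  # smallest inertia moment <-> largest covariance eigenvalue
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  if (!is.null(frame)) {
    if (sum(ax * frame$normal) < 0) ax <- -ax
  } else {
    nz <- which(abs(ax) > 1e-9)[1]
    if (ax[nz] < 0) ax <- -ax
  }
  normalize3(ax)
}

#' Membrane frame of a trimeric transporter
#'
#' The membrane normal is the axis of the three-fold symmetry: the rotation
#' extracted from the optimal rigid superposition of one protomer's scaffold
#' Calphas onto the next protomer's (the rotation angle must be near 120
#' degrees). The center is the centroid of the query protomer's scaffold
#' Calphas, and the normal is oriented toward the extracellular side using
#' the HP2/TM8a motif centroid as the extracellular marker.
#'
#' @param model a trimeric [structure_model] (3 protomer chains), unless
#'   `normal` is supplied.
#' @param partition a [domain_partition].
#' @param chain query protomer chain (default: first protomer chain).
#' @param normal optional explicit normal override (skips symmetry
#'   extraction); used for single-protomer models.
#' @param symmetry_tol accepted deviation of the protomer-to-protomer
#'   rotation from 120 degrees (default 15).
#' @return A `membrane_frame`.
#' @export
membrane_frame <- function(model, partition, chain = NULL, normal = NULL,
                           symmetry_tol = 15) {
  chains <- model$protomer_chains
  if (is.null(chain)) chain <- chains[1]
  scaffold <- partition_set(partition, "scaffold")
  center <- colMeans(ca_coords(model, scaffold, chain, warn_missing = FALSE))
  if (is.null(normal)) {
    if (length(chains) < 3)
      stop("membrane_frame needs 3 protomer chains or an explicit normal")
    a <- ca_coords(model, scaffold, chains[1], warn_missing = FALSE)
    b <- ca_coords(model, scaffold, chains[2], warn_missing = FALSE)
    shared <- intersect(sub("^[^:]*:", "", rownames(a)),
                        sub("^[^:]*:", "", rownames(b)))
    if (length(shared) < 3) stop("too few shared scaffold residues")
    a <- a[match(shared, sub("^[^:]*:", "", rownames(a))), , drop = FALSE]
    b <- b[match(shared, sub("^[^:]*:", "", rownames(b))), , drop = FALSE]
    fit <- kabsch(a, b)
    ra <- rotation_angle_axis(fit$R)
    if (abs(ra$angle - 120) > symmetry_tol)
      stop(sprintf(
        "protomer superposition rotation is %.1f deg, not ~120 deg; %s",
        ra$angle, "not a 3-fold symmetric trimer"))
    normal <- ra$axis
  }
  frame <- membrane_frame_from(normal, center)
  # orient toward the extracellular side (HP2/TM8a motif marker)
  marker <- colMeans(ca_coords(model, partition_set(partition,
                                                    "hp2_tm8a_motif"),
                               chain, warn_missing = FALSE))
  if (sum((marker - frame$center) * frame$normal) < 0)
    frame$normal <- -frame$normal
  frame
}

#' Tilt angle of a domain axis against the membrane normal
#'
#' `alpha1 = acos(|axis . normal|)` in degrees, folded into \[0, 90\] (the
#' acute-angle convention).
#'
#' @param axis unit 3-vector (normalized internally).
#' @param frame a [membrane_frame].
#' @return Angle in degrees.
#' @export
tilt_angle <- function(axis, frame) {
  a <- normalize3(as.numeric(axis))
  acos(pmin(1, abs(sum(a * frame$normal)))) * 180 / pi
}

#' Transport-domain tilt of one protomer
#'
#' Convenience wrapper: principal axis of the transport-domain Calphas
#' (including HP2 by default) against the trimer membrane frame.
#'
#' @inheritParams membrane_frame
#' @param frame optional precomputed [membrane_frame].
#' @param exclude_hp2 drop the HP2 ranges from the transport selection
#'   (sensitivity option).
#' @return alpha1 in degrees.
#' @export
transport_tilt <- function(model, partition, chain = NULL, frame = NULL,
                           exclude_hp2 = FALSE) {
  if (is.null(chain)) chain <- model$protomer_chains[1]
  if (is.null(frame)) frame <- membrane_frame(model, partition, chain)
  rg <- partition_set(partition, "transport")
  if (exclude_hp2) rg <- subtract_ranges(rg, partition_set(partition, "hp2"))
  ax <- principal_axis(model, rg, chain, frame = frame)
  tilt_angle(ax, frame)
}

subtract_ranges <- function(rg, minus) {
  out <- list()
  for (i in seq_len(nrow(rg))) {
    pieces <- data.frame(chain = rg$chain[i], start = rg$start[i],
                         end = rg$end[i], stringsAsFactors = FALSE)
    for (j in seq_len(nrow(minus))) {
      nxt <- list()
      for (k in seq_len(nrow(pieces))) {
        s <- pieces$start[k]; e <- pieces$end[k]
        ms <- minus$start[j]; me <- minus$end[j]
        if (me < s || ms > e) { nxt[[length(nxt) + 1]] <- pieces[k, ]; next }
        if (ms > s) nxt[[length(nxt) + 1]] <-
            data.frame(chain = pieces$chain[k], start = s, end = ms - 1)
        if (me < e) nxt[[length(nxt) + 1]] <-
            data.frame(chain = pieces$chain[k], start = me + 1, end = e)
      }
      pieces <- if (length(nxt)) do.call(rbind, nxt) else pieces[0, ]
    }
    out[[i]] <- pieces
  }
  do.call(rbind, out)
}

# shared Calpha coordinate pair for a residue-range set, matched by author
# residue number; returns list(a=..., b=..., n=...)
shared_ca <- function(state_a, state_b, ranges, chain_a, chain_b,
                      min_shared = 3) {
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(character(0), NULL))
  A <- tryCatch(ca_coords(state_a, ranges, chain_a, warn_missing = FALSE),
                error = function(e) empty)
  B <- tryCatch(ca_coords(state_b, ranges, chain_b, warn_missing = FALSE),
                error = function(e) empty)
  ra <- as.integer(sub("^[^:]*:", "", rownames(A)))
  rb <- as.integer(sub("^[^:]*:", "", rownames(B)))
  shared <- intersect(ra, rb)
  if (length(shared) < min_shared)
    stop("only ", length(shared), " shared Calpha atoms (need >= ",
         min_shared, ")")
  dropped <- length(union(ra, rb)) - length(shared)
  if (dropped > 0)
    message(dropped, " unresolved residue(s) dropped from the comparison")
  list(a = A[match(shared, ra), , drop = FALSE],
       b = B[match(shared, rb), , drop = FALSE],
       n = length(shared))
}

#' Rigid-body rotation of the transport domain between two states
#'
#' After superposing state B's scaffold Calphas onto state A's, the optimal
#' rigid transform mapping state A's transport Calphas onto the superposed
#' state B's is extracted; `alpha2` is the rotation angle of that transform,
#' `acos((trace(R) - 1) / 2)` in degrees. Only residues resolved in both
#' states (by author number) enter either superposition.
#'
#' @param state_a,state_b [structure_model]s of the two states.
#' @param partition a [domain_partition].
#' @param chain_a,chain_b protomer chains to compare (defaults: first
#'   protomer chain of each model).
#' @param min_shared minimum shared Calpha count per set (default 20).
#' @return List with `angle` (degrees), `axis` (unit 3-vector or NA at 180
#'   degrees), `n_scaffold`, `n_transport`.
#' @export
rotation_between <- function(state_a, state_b, partition,
                             chain_a = NULL, chain_b = NULL,
                             min_shared = 20) {
  if (is.null(chain_a)) chain_a <- state_a$protomer_chains[1]
  if (is.null(chain_b)) chain_b <- state_b$protomer_chains[1]
  sc <- shared_ca(state_a, state_b, partition_set(partition, "scaffold"),
                  chain_a, chain_b, min_shared)
  tr <- shared_ca(state_a, state_b, partition_set(partition, "transport"),
                  chain_a, chain_b, min_shared)
  scaffold_fit <- kabsch(sc$b, sc$a)            # B -> A scaffold frame
  b_transport <- apply_rigid(tr$b, scaffold_fit$R, scaffold_fit$t)
  dom_fit <- kabsch(tr$a, b_transport)
  ra <- rotation_angle_axis(dom_fit$R)
  list(angle = ra$angle, axis = ra$axis, axis_defined = ra$axis_defined,
       n_scaffold = sc$n, n_transport = tr$n)
}

#' Calpha-Calpha distance between two residues
#'
#' @param model a [structure_model].
#' @param res_a,res_b author residue numbers.
#' @param chain chain id (default: first protomer chain).
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(model, res_a, res_b, chain = NULL) {
  if (is.null(chain)) chain <- model$protomer_chains[1]
  one <- function(res) {
    idx <- atom_select(model,
                       data.frame(chain = chain, start = res, end = res),
                       elety = "CA")
    if (length(idx) == 0)
      stop("residue ", res, " (chain ", chain, ") has no Calpha atom")
    as.numeric(model$atoms[idx[1], c("x", "y", "z")])
  }
  sqrt(sum((one(res_a) - one(res_b))^2))
}

#' Calpha RMSD between two states after optimal superposition
#'
#' @inheritParams rotation_between
#' @param ranges residue ranges to compare (`NULL` = all shared residues).
#' @return RMSD in Angstrom.
#' @export
rmsd_ca <- function(state_a, state_b, ranges = NULL,
                    chain_a = NULL, chain_b = NULL) {
  if (is.null(chain_a)) chain_a <- state_a$protomer_chains[1]
  if (is.null(chain_b)) chain_b <- state_b$protomer_chains[1]
  sh <- shared_ca(state_a, state_b, ranges, chain_a, chain_b, min_shared = 3)
  kabsch(sh$b, sh$a)$rmsd
}

#' Transport-domain center-of-mass shift along the membrane normal
#'
#' After superposing state B's scaffold onto state A's, returns
#' `(COM_b - COM_a) . normal` for the transport-domain Calphas; negative
#' values point toward the cytoplasm.
#'
#' @inheritParams rotation_between
#' @param frame [membrane_frame] of state A (computed from it when `NULL`).
#' @return Signed displacement in Angstrom.
#' @export
com_shift_along_normal <- function(state_a, state_b, partition,
                                   frame = NULL,
                                   chain_a = NULL, chain_b = NULL,
                                   min_shared = 20) {
  if (is.null(chain_a)) chain_a <- state_a$protomer_chains[1]
  if (is.null(chain_b)) chain_b <- state_b$protomer_chains[1]
  if (is.null(frame)) frame <- membrane_frame(state_a, partition, chain_a)
  sc <- shared_ca(state_a, state_b, partition_set(partition, "scaffold"),
                  chain_a, chain_b, min_shared)
  tr <- shared_ca(state_a, state_b, partition_set(partition, "transport"),
                  chain_a, chain_b, min_shared)
  scaffold_fit <- kabsch(sc$b, sc$a)
  b_transport <- apply_rigid(tr$b, scaffold_fit$R, scaffold_fit$t)
  sum((colMeans(b_transport) - colMeans(tr$a)) * frame$normal)
}
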