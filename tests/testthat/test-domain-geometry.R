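test_that("principal_axis recovers collinear and rotated cylinder axes", {
  z_line <- cbind(0, 0, seq(0, 19))
  m <- model_from_xyz(z_line)
  ax <- principal_axis(m)
  expect_equal(abs(sum(ax * c(0, 0, 1))), 1, tolerance = 1e-9)

  # helical cylinder rotated 35 deg about x: axis recovered within 0.5 deg
  toy <- make_two_domain_toy(tilt = 35)
  ax <- principal_axis(toy$state_a,
                       partition_set(toy$partition, "transport"),
                       frame = toy$frame)
  target <- as.numeric(rot_mat(c(1, 0, 0), 35) %*% c(0, 0, 1))
  ang <- acos(min(1, abs(sum(ax * target)))) * 180 / pi
  expect_lt(ang, 0.5)

  expect_error(principal_axis(model_from_xyz(rbind(c(0, 0, 0), c(1, 1, 1)))),
               "at least 3")
  expect_error(principal_axis(model_from_xyz(matrix(1, 5, 3))),
               "degenerate")
})

test_that("membrane_frame recovers the three-fold axis of a trimer", {
  tri <- make_toy_trimer()
  fr <- membrane_frame(tri$model, tri$partition)
  expect_equal(fr$normal, c(0, 0, 1), tolerance = 1e-6)
  expect_equal(fr$center,
               colMeans(ca_coords(tri$model,
                                  partition_set(tri$partition, "scaffold"),
                                  "A")),
               tolerance = 1e-9, ignore_attr = TRUE)

  # rigidly rotated trimer: normal follows the rotation
  R0 <- rot_mat(c(1, 2, 0.5), 37)
  rot <- rigid_transform_model(tri$model, R0, c(5, -3, 11))
  fr2 <- membrane_frame(rot, tri$partition)
  expect_equal(fr2$normal, as.numeric(R0 %*% c(0, 0, 1)),
               tolerance = 1e-6)

  # monomer without an override is an error; with an override it works
  mono_atoms <- tri$model$atoms[tri$model$atoms$chain == "A", ]
  mono <- structure_model(mono_atoms, protomer_chains = "A")
  expect_error(membrane_frame(mono, tri$partition), "3 protomer chains")
  fr3 <- membrane_frame(mono, tri$partition, normal = c(0, 0, 1))
  expect_equal(fr3$normal, c(0, 0, 1))
})

test_that("tilt_angle follows the acute-angle convention", {
  fr <- flat_frame()
  expect_equal(tilt_angle(c(0, 0, 1), fr), 0)
  expect_equal(tilt_angle(c(0, 0, -1), fr), 0)  # folded into [0, 90]
  expect_equal(tilt_angle(c(1, 0, 0), fr), 90)
  expect_equal(tilt_angle(c(0, 1, 1), fr), 45, tolerance = 1e-9)
  expect_error(tilt_angle(c(0, 0, 0), fr), "zero-length")
})

test_that("rotation_between recovers planted rotations exactly", {
  toy <- make_two_domain_toy(tilt = 35, rotation = 0)
  # acos() near trace = 3 resolves angles only to ~sqrt(machine eps) rad
  expect_equal(rotation_between(toy$state_a, toy$state_a,
                                toy$partition)$angle, 0, tolerance = 1e-5)
  toy23 <- make_two_domain_toy(tilt = 35, rotation = 23)
  rb <- rotation_between(toy23$state_a, toy23$state_b, toy23$partition)
  expect_equal(rb$angle, 23, tolerance = 0.01)
  expect_equal(abs(sum(rb$axis * toy23$truth$rotation_axis)), 1,
               tolerance = 1e-6)
})

test_that("ca_distance measures Calpha separations and flags absences", {
  m <- model_from_xyz(rbind(c(0, 0, 0), c(3, 4, 0)), resno = c(10, 20))
  expect_equal(ca_distance(m, 10, 20), 5)
  expect_equal(ca_distance(m, 10, 10), 0)
  expect_error(ca_distance(m, 10, 99), "99")
})

test_that("rmsd_ca vanishes under rigid motion and is symmetric", {
  toy <- make_two_domain_toy(tilt = 20)
  m <- toy$state_a
  moved <- rigid_transform_model(m, rot_mat(c(0, 1, 1), 73), c(10, -4, 2))
  expect_equal(rmsd_ca(m, m), 0, tolerance = 1e-12)
  expect_equal(rmsd_ca(m, moved), 0, tolerance = 1e-9)
  b <- toy$state_b
  expect_equal(rmsd_ca(m, b), rmsd_ca(b, m), tolerance = 1e-9)
})

test_that("com_shift_along_normal reports signed translocation", {
  toy0 <- make_two_domain_toy(tilt = 35, rotation = 0, shift = 0)
  expect_equal(com_shift_along_normal(toy0$state_a, toy0$state_a,
                                      toy0$partition, frame = toy0$frame),
               0, tolerance = 1e-9)
  toy15 <- make_two_domain_toy(tilt = 35, rotation = 0, shift = -15)
  expect_equal(com_shift_along_normal(toy15$state_a, toy15$state_b,
                                      toy15$partition, frame = toy15$frame),
               -15, tolerance = 1e-6)
})

test_that("planted tilt/rotation/shift are recovered across the value grid", {
  angles <- c(0, 7, 23, 29, 47)
  shifts <- c(0, -5, -15)
  for (i in seq_along(angles)) {
    for (s in shifts) {
      toy <- make_two_domain_toy(tilt = angles[i], rotation = angles[i],
                                 shift = s)
      a1 <- transport_tilt(toy$state_a, toy$partition, frame = toy$frame)
      expect_lt(abs(a1 - angles[i]), 0.5)
      a2 <- rotation_between(toy$state_a, toy$state_b, toy$partition)$angle
      expect_lt(abs(a2 - angles[i]), 0.5)
      sh <- com_shift_along_normal(toy$state_a, toy$state_b,
                                   toy$partition, frame = toy$frame)
      expect_lt(abs(sh - s), 0.05)
    }
  }
})

test_that("metrics are invariant under a common rigid transform", {
  toy <- make_two_domain_toy(tilt = 29, rotation = 23, shift = -7)
  R0 <- rot_mat(c(2, -1, 3), 51)
  t0 <- c(7, 13, -2)
  a_t <- rigid_transform_model(toy$state_a, R0, t0)
  b_t <- rigid_transform_model(toy$state_b, R0, t0)
  frame_t <- membrane_frame_from(as.numeric(R0 %*% toy$frame$normal),
                                 as.numeric(R0 %*% toy$frame$center) + t0)
  expect_equal(transport_tilt(a_t, toy$partition, frame = frame_t),
               transport_tilt(toy$state_a, toy$partition,
                              frame = toy$frame),
               tolerance = 1e-6)
  expect_equal(rotation_between(a_t, b_t, toy$partition)$angle,
               rotation_between(toy$state_a, toy$state_b,
                                toy$partition)$angle,
               tolerance = 1e-6)
  expect_equal(rmsd_ca(a_t, b_t), rmsd_ca(toy$state_a, toy$state_b),
               tolerance = 1e-6)
  expect_equal(com_shift_along_normal(a_t, b_t, toy$partition,
                                      frame = frame_t),
               com_shift_along_normal(toy$state_a, toy$state_b,
                                      toy$partition, frame = toy$frame),
               tolerance = 1e-6)
  # rotation angle is symmetric in the two states
  expect_equal(rotation_between(toy$state_a, toy$state_b,
                                toy$partition)$angle,
               rotation_between(toy$state_b, toy$state_a,
                                toy$partition)$angle,
               tolerance = 1e-6)
})

test_that("superposition matches a brute-force angle grid search", {
  set.seed(7)
  P <- matrix(rnorm(24, sd = 6), 8, 3)
  Q <- sweep(P %*% t(rot_mat(c(0, 0, 1), 6.4)), 2, c(1, 2, 3), "+")
  # independent oracle: exhaustive search over rotations about z
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  grid <- seq(0, 10, by = 0.01)
  rmsd_at <- vapply(grid, function(th)
    sqrt(mean(rowSums((Pc %*% t(rot_mat(c(0, 0, 1), th)) - Qc)^2))),
    numeric(1))
  oracle_angle <- grid[which.min(rmsd_at)]
  fit <- elevatorEM:::kabsch(P, Q)
  ang <- elevatorEM:::rotation_angle_axis(fit$R)$angle
  expect_lt(abs(ang - oracle_angle), 0.1)
  expect_lt(fit$rmsd, 1e-9)
})

test_that("comparisons shrink, not abort, when residues are unresolved", {
  toy <- make_two_domain_toy(tilt = 35, rotation = 23)
  b <- toy$state_b
  b$atoms <- b$atoms[b$atoms$resno != 150, ]  # drop one transport residue
  expect_message(
    rb <- rotation_between(toy$state_a, b, toy$partition),
    "unresolved")
  expect_equal(rb$angle, 23, tolerance = 0.05)
  expect_equal(rb$n_transport, 99)
  # but a vanishing intersection is an error
  empty <- b
  empty$atoms <- empty$atoms[empty$atoms$resno <= 100, ]
  expect_error(suppressMessages(
    rotation_between(toy$state_a, empty, toy$partition)), "shared")
})
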