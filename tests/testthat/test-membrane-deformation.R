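test_that("segmentation selects the slab and honors the protein mask", {
  slab <- make_slab_density(voxel = 1.5, extent = 24)
  fr <- flat_frame()
  seg <- segment_nanodisc(slab$grid, NULL, fr, slab_half_width = 25)
  ax <- elevatorEM:::voxel_axes(seg)
  core <- abs(ax[[3]]) <= 13   # interior slab sections
  expect_true(all(seg$values[, , core] == 1))
  expect_true(all(seg$values[, , abs(ax[[3]]) > 16.5] == 0))

  # protein atoms carve out an exclusion cylinder
  prot <- model_from_xyz(cbind(0, 0, seq(-15, 15, by = 1.5)))
  seg2 <- segment_nanodisc(slab$grid, prot, fr, protein_mask_radius = 4,
                           slab_half_width = 25)
  i0 <- which.min(abs(ax[[1]]))
  j0 <- which.min(abs(ax[[2]]))
  k0 <- which.min(abs(ax[[3]]))
  expect_equal(seg2$values[i0, j0, k0], 0)
  expect_equal(seg$values[i0, j0, k0], 1)

  # a contrast-free map cannot be segmented
  flat0 <- density_grid(array(0, dim = c(8, 8, 8)), voxel = 2)
  expect_error(segment_nanodisc(flat0, NULL, fr), "empty|contrast")
})

test_that("flat slab leaflet surfaces sit at +/- half thickness", {
  slab <- make_slab_density(voxel = 1, extent = 20)
  fr <- flat_frame()
  seg <- segment_nanodisc(slab$grid, NULL, fr, slab_half_width = 25)
  for (side in c("extracellular", "cytoplasmic")) {
    surf <- leaflet_surface(seg, fr, side = side)
    target <- if (side == "extracellular") 15 else -15
    expect_true(all(abs(surf$heights[surf$mask] - target) <= 0.5))
    surf <- reference_zero(surf, rim_model(r = 18), c(1L, 3L),
                           annulus = c(0, 8))
    expect_lt(max(abs(surf$displacement[surf$mask])), 0.5)
    expect_lt(abs(max_deformation(surf, "all")), 0.5)
  }
})

test_that("planted dimple depths are recovered across voxel sizes", {
  for (voxel in c(1.0, 1.5)) {
    for (depth in c(0, 2, 4, 8)) {
      slab <- make_slab_density(voxel = voxel, dimple_depth = depth,
                                dimple_sigma = 8, extent = 30)
      fr <- flat_frame()
      seg <- segment_nanodisc(slab$grid, NULL, fr, slab_half_width = 30)
      surf <- leaflet_surface(seg, fr, side = "cytoplasmic")
      surf <- reference_zero(surf, rim_model(r = 27), c(1L, 3L))
      got <- max_deformation(surf, list(center = c(0, 0), radius = 12))
      tol <- 0.5 + voxel / 2
      if (depth == 0) {
        expect_lt(abs(got), tol)
      } else {
        expect_lt(abs(got - (-depth)), tol)  # cytoplasmic: negative=outward
      }
    }
  }
})

test_that("a reference annulus with no valid samples is an error", {
  slab <- make_slab_density(voxel = 1.5, extent = 20)
  fr <- flat_frame()
  prot <- model_from_xyz(as.matrix(expand.grid(x = seq(-6, 6, 2),
                                               y = seq(-6, 6, 2),
                                               z = seq(-18, 18, 3))))
  seg <- segment_nanodisc(slab$grid, prot, fr, protein_mask_radius = 4,
                          slab_half_width = 25)
  surf <- leaflet_surface(seg, fr, side = "cytoplasmic")
  center_ref <- model_from_xyz(rbind(c(0, 0, 0)))
  expect_error(reference_zero(surf, center_ref, 1L, annulus = c(0, 2)),
               "annulus")
})

test_that("a tilted flat slab is recovered as a plane with the right gradient", {
  slab <- make_slab_density(voxel = 1, extent = 25)
  tilt <- 5
  fr <- membrane_frame_from(as.numeric(rot_mat(c(1, 0, 0), tilt) %*%
                                         c(0, 0, 1)), c(0, 0, 0))
  seg <- segment_nanodisc(slab$grid, NULL, fr, slab_half_width = 25)
  surf <- leaflet_surface(seg, fr, side = "cytoplasmic")
  df <- expand.grid(a = surf$a, b = surf$b)
  df$h <- as.numeric(surf$heights)
  df <- df[as.logical(surf$mask) &
             sqrt(df$a^2 + df$b^2) < 15, ]  # away from map edges
  fit <- stats::lm(h ~ a + b, data = df)
  grad <- sqrt(sum(coef(fit)[2:3]^2))
  expect_equal(grad, tan(tilt * pi / 180), tolerance = 0.2)
  expect_lt(sd(residuals(fit)), 0.3)
})

test_that("the deformation stage is equivariant under a common translation", {
  slab <- make_slab_density(voxel = 1.5, dimple_depth = 6, extent = 24)
  fr <- flat_frame()
  shift <- c(7.5, -4.5, 12)
  grid2 <- slab$grid
  grid2$origin <- grid2$origin + shift
  fr2 <- membrane_frame_from(fr$normal, fr$center + shift)
  rim <- rim_model(r = 21)
  rim2 <- rigid_transform_model(rim, diag(3), shift)
  run <- function(g, f, r) {
    seg <- segment_nanodisc(g, NULL, f, slab_half_width = 30)
    surf <- leaflet_surface(seg, f, side = "cytoplasmic")
    reference_zero(surf, r, c(1L, 3L))$displacement
  }
  d1 <- run(slab$grid, fr, rim)
  d2 <- run(grid2, fr2, rim2)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("doubling map resolution at least halves the surface error", {
  err <- function(vx) {
    s <- make_slab_density(voxel = vx, dimple_depth = 6, dimple_sigma = 10,
                           extent = 30)
    fr <- flat_frame()
    seg <- segment_nanodisc(s$grid, NULL, fr, slab_half_width = 40)
    surf <- leaflet_surface(seg, fr, side = "cytoplasmic")
    ij <- expand.grid(a = surf$a, b = surf$b)
    truth <- -15 - 6 * exp(-(ij$a^2 + ij$b^2) / (2 * 100))
    sqrt(mean((as.numeric(surf$heights) - truth)^2, na.rm = TRUE))
  }
  expect_gt(err(2) / err(1), 2)
})

test_that("displacement fields export as TSV grids", {
  slab <- make_slab_density(voxel = 1.5, dimple_depth = 4, extent = 20)
  fr <- flat_frame()
  seg <- segment_nanodisc(slab$grid, NULL, fr, slab_half_width = 30)
  surf <- reference_zero(leaflet_surface(seg, fr, side = "cytoplasmic"),
                         rim_model(r = 18), c(1L, 3L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_deformation_tsv(surf, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), length(surf$a) * length(surf$b))
  expect_true(all(c("a", "b", "height", "displacement", "valid") %in%
                    names(tab)))
})
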