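test_that("make_phantom builds the declared geometry deterministically", {
  ph <- make_phantom(c(20, 20, 20), 3, layout_sphere_oar())
  expect_s3_class(ph$grid, "voxel_grid")
  ptv <- ph$structures$masks$PTV
  expect_true(any(ptv))
  # fully inside the grid: no mask voxel on a boundary face
  idx <- which(ptv, arr.ind = TRUE)
  expect_true(all(idx > 1) && all(idx < 20))
  # identical seed -> bit-identical masks; jittered layouts reproduce too
  lay <- layout_sphere_oar()
  lay[[1]]$jitter_mm <- 2
  a <- make_phantom(c(20, 20, 20), 3, lay, seed = 7)
  b <- make_phantom(c(20, 20, 20), 3, lay, seed = 7)
  expect_identical(a$structures$masks, b$structures$masks)
})

test_that("make_phantom rejects degenerate and ambiguous layouts", {
  # target bigger than the grid
  lay <- layout_sphere_oar(target_radius = 200)
  expect_error(make_phantom(c(20, 20, 20), 3, lay), "beyond the grid")
  # overlapping target/OAR without priorities names both structures
  lay2 <- list(
    list(name = "PTV", role = "target", shape = "sphere",
         center = c(30, 30, 30), radius = 15),
    list(name = "Stem", role = "oar", shape = "sphere",
         center = c(30, 40, 30), radius = 10))
  expect_error(make_phantom(c(20, 20, 20), 3, lay2), "'PTV' and 'Stem'")
  # with priorities the overlap is resolved and masks are disjoint
  lay2[[1]]$priority <- 2; lay2[[2]]$priority <- 1
  ph <- make_phantom(c(20, 20, 20), 3, lay2)
  expect_false(any(ph$structures$masks$PTV & ph$structures$masks$Stem))
})

test_that("voxel linear indexing is bijective and x-fastest", {
  g <- voxel_grid(c(4, 3, 2))
  lin <- grid_index(g, as.matrix(expand.grid(i = 1:4, j = 1:3, k = 1:2)))
  expect_identical(sort(as.integer(lin)), 0:23)
  # round trip
  expect_equal(grid_index(g, grid_subscript(g, lin)), lin)
  # x-fastest: advancing i by 1 advances the linear index by 1
  expect_equal(grid_index(g, c(2, 1, 1)) - grid_index(g, c(1, 1, 1)), 1)
  expect_equal(grid_index(g, c(1, 2, 1)) - grid_index(g, c(1, 1, 1)), 4)
})

test_that("depth-dose curve is single-peaked with exact parametric anchors", {
  bm <- beam_model()
  E <- 100
  r0 <- beam_range(E, bm)
  # entrance value equals ratio x peak exactly
  expect_equal(depth_dose(0, E, bm), bm$entrance_ratio * 1)
  # dense scan: argmax within one peak width of R0
  d <- seq(0, r0 + 20, by = 0.1)
  dd <- depth_dose(d, E, bm)
  expect_lt(abs(d[which.max(dd)] - r0), bm$peak_width_mm)
  # single-peaked: non-decreasing before the argmax, non-increasing after
  im <- which.max(dd)
  expect_true(all(diff(dd[1:im]) >= -1e-12))
  expect_true(all(diff(dd[im:length(dd)]) <= 1e-12))
  # zero beyond the distal cutoff
  expect_identical(depth_dose(r0 + 10 * bm$peak_width_mm, E, bm), 0)
  expect_error(depth_dose(300, 5, bm), "outside model table")
  expect_error(depth_dose(-1, E, bm), ">= 0")
})

test_that("LET_d depth curve is monotone from entrance to distal value", {
  bm <- beam_model()
  E <- 120
  edge <- beam_range(E, bm) + bm$peak_width_mm
  expect_equal(depth_letd(0, E, bm), bm$let_entrance)
  expect_equal(depth_letd(edge, E, bm), bm$let_distal)
  d <- seq(0, edge, length.out = 1000)
  lt <- depth_letd(d, E, bm)
  expect_true(all(diff(lt) >= -1e-12))
  # beyond the edge the curve stays at the distal value (still monotone)
  expect_equal(depth_letd(edge + 50, E, bm), bm$let_distal)
})

test_that("simulated influence has the numerator = LET x dose structure", {
  ph <- make_phantom(c(12, 12, 12), 3, layout_sphere_oar(c(18, 18, 18), 9, 4))
  bm <- beam_model()
  sp <- spot_list(
    data.frame(field = 1, x_mm = 0, y_mm = 0, energy = 55, fluence = 1),
    data.frame(field = 1, gantry_deg = 90, couch_deg = 0,
               isocenter_x = 18, isocenter_y = 18, isocenter_z = 18))
  infl <- simulate_influence(ph$grid, sp, bm)
  expect_s3_class(infl, "influence_matrix")
  # elementwise N >= entrance LET x D for all stored entries (monotone curve)
  expect_true(all(infl$letd_numerator@x >= bm$let_entrance * infl$dose@x - 1e-12))
  # per-entry ratio bounded by the distal LET
  expect_true(all(infl$letd_numerator@x <= bm$let_distal * infl$dose@x + 1e-12))
  # determinism: identical inputs give bit-identical matrices
  infl2 <- simulate_influence(ph$grid, sp, bm)
  expect_identical(infl$dose, infl2$dose)
  expect_identical(infl$letd_numerator, infl2$letd_numerator)
})

test_that("single entrance voxel has LET_d ratio equal to the entrance value", {
  # one-voxel grid right at the surface: the stored N/D ratio must be the
  # entrance LET_d (up to the within-voxel depth of the voxel centre)
  g <- voxel_grid(c(1, 1, 1), spacing = c(1, 1, 1), origin = c(0.5, 0.5, 0.5))
  bm <- beam_model(sigma0_mm = 4)
  sp <- spot_list(
    data.frame(field = 1, x_mm = 0, y_mm = 0, energy = 150, fluence = 1),
    data.frame(field = 1, gantry_deg = 90, couch_deg = 0,
               isocenter_x = 0.5, isocenter_y = 0.5, isocenter_z = 0.5))
  infl <- simulate_influence(g, sp, bm)
  ratio <- infl$letd_numerator@x / infl$dose@x
  expect_equal(ratio, depth_letd(0.5, 150, bm), tolerance = 1e-12)
})

test_that("density scale below 1 pulls the Bragg argmax proximally", {
  g <- voxel_grid(c(40, 9, 9), spacing = c(3, 3, 3))
  iso <- c(60, 13.5, 13.5)
  sp <- spot_list(
    data.frame(field = 1, x_mm = 0, y_mm = 0, energy = 90, fluence = 1),
    data.frame(field = 1, gantry_deg = 90, couch_deg = 0,
               isocenter_x = iso[1], isocenter_y = iso[2], isocenter_z = iso[3]))
  col_argmax <- function(density) {
    bm <- beam_model(density_scale = density)
    infl <- simulate_influence(g, sp, bm)
    d <- as.numeric(infl$dose[, 1])
    arr <- array(d, g$dims)
    which.max(apply(arr, 1, max))
  }
  expect_lt(col_argmax(0.965), col_argmax(1.0))
})

test_that("simulate_influence validates spots and output", {
  g <- voxel_grid(c(10, 10, 10), spacing = c(3, 3, 3))
  bm <- beam_model()
  sp_out <- spot_list(
    data.frame(field = 1, x_mm = 500, y_mm = 0, energy = 100, fluence = 1),
    data.frame(field = 1, gantry_deg = 90, couch_deg = 0,
               isocenter_x = 15, isocenter_y = 15, isocenter_z = 15))
  expect_error(simulate_influence(g, sp_out, bm), "outside the lateral")
})

test_that("sparsity floor discards only a negligible dose fraction", {
  case <- tiny_case()
  bm_full <- case$params
  bm_full$sparsity_floor <- 0
  full <- simulate_influence(case$grid, case$spots, bm_full)
  kept <- sum(case$infl$dose@x) / sum(full$dose@x)
  expect_gt(kept, 0.995)
  # no stored entry below the declared floor (per-column relative)
  for (j in seq_len(ncol(case$infl$dose))) {
    xs <- case$infl$dose[, j]
    xs <- xs[xs > 0]
    expect_true(all(xs > case$params$sparsity_floor * max(xs) - 1e-15))
  }
})
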