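test_that("hemisphere sections reproduce analytic sphere geometry", {
  cr <- hemisphere_crown(4)
  g <- radial_sample(cr, 24, 24)
  ms <- compute_parameter_maps(g, cr)

  ## rotational symmetry: each radial row constant across sections
  expect_lt(max(apply(ms$maps$h, 1, function(r) diff(range(r)))), 2e-2)

  ## analytic heights: the section curve is the arc of the unit circle from
  ## the apex (z = 0.8 after the 80% cut) to the cut plane; equal-arc
  ## sampling gives h(d) = cos(d * acos(0.2)) - 0.2
  a1 <- acos(0.2)
  d <- (seq_len(24) - 1) / 23
  h_exp <- cos(d * a1) - 0.2
  expect_lt(max(abs(ms$maps$h - h_exp)), 1e-2)

  ## normals point radially from the original sphere centre (0, 0, -0.2)
  ctr_dir <- g$points
  ctr_dir[, , 3] <- ctr_dir[, , 3] + 0.2
  dots <- g$normals[, , 1] * ctr_dir[, , 1] + g$normals[, , 2] * ctr_dir[, , 2] +
    g$normals[, , 3] * ctr_dir[, , 3]
  expect_gt(min(dots / sqrt(ctr_dir[, , 1]^2 + ctr_dir[, , 2]^2 + ctr_dir[, , 3]^2)),
            0.999)

  ## map invariants
  expect_true(all(ms$maps$h >= 0))
  expect_true(all(ms$maps$r >= 0))
  expect_equal(ms$maps$h[24, ], rep(0, 24))
  nsq <- ms$maps$Nx^2 + ms$maps$Ny^2 + ms$maps$Nz^2
  expect_lt(max(abs(nsq - 1)), 1e-6)
})

test_that("sphere curvature and cone flank geometry match analytic values", {
  cr <- hemisphere_crown(4)
  ms <- compute_parameter_maps(radial_sample(cr, 20, 20), cr)
  expect_gt(mean(abs(ms$maps$c - 1) <= 0.05), 0.9)

  cone <- cone_mesh()
  crc <- orient_and_crop(cone$mesh, cone$outline, cone$anchor,
                         keep_fraction = 1)
  mc <- compute_parameter_maps(radial_sample(crc, 20, 16), crc)
  ## on a 45-degree flank the section is a straight line with r + h equal
  ## to the apex height everywhere
  flank <- 3:19
  expect_lt(max(abs(mc$maps$r[flank, ] + mc$maps$h[flank, ] - 1)), 1e-3)
})

test_that("sections that miss the z axis raise a named error", {
  cr <- hemisphere_crown(3)
  shifted <- cr
  shifted$mesh$vertices[, 1] <- shifted$mesh$vertices[, 1] + 5
  expect_error(radial_sample(shifted, 8, 8), "section")
})

test_that("centroid-size normalization follows the stated formula", {
  maps <- list(c = matrix(2, 2, 2), h = matrix(3, 2, 2), r = matrix(4, 2, 2),
               Nx = matrix(0, 2, 2), Ny = matrix(0, 2, 2), Nz = matrix(1, 2, 2))
  ms <- manual_mapset(maps)
  msn <- centroid_size_normalize(ms)
  expect_equal(msn$centroid_size, 10) # sqrt(4 * (9 + 16))
  expect_equal(msn$maps$h, matrix(0.3, 2, 2))
  expect_equal(msn$maps$r, matrix(0.4, 2, 2))
  expect_equal(msn$maps$c, matrix(20, 2, 2))
  expect_identical(msn$maps$Nz, ms$maps$Nz)
  expect_error(centroid_size_normalize(msn), "already")
  expect_error(centroid_size_normalize(manual_mapset(lapply(maps, `*`, 0))),
               "centroid size is zero")
})

test_that("maps are scale invariant after centroid-size normalization", {
  tm <- make_tooth_mesh(tooth_spec(mesh_resolution = 1500))
  sp1 <- list(mesh = tm$mesh, outline = tm$outline,
              buccal_anchor = tm$buccal_anchor)
  m5 <- tri_mesh(tm$mesh$vertices * 5, tm$mesh$faces)
  sp5 <- list(mesh = m5, outline = tm$outline * 5,
              buccal_anchor = tm$buccal_anchor * 5)
  ms1 <- specimens_to_mapsets(list(sp1), 20, 20)[[1]]
  ms5 <- specimens_to_mapsets(list(sp5), 20, 20)[[1]]
  for (p in names(ms1$maps))
    expect_lt(max(abs(ms1$maps[[p]] - ms5$maps[[p]])), 1e-6)
  expect_equal(ms5$centroid_size / ms1$centroid_size, 5, tolerance = 1e-9)
})

test_that("area weights tile the unit disk", {
  expect_equal(area_weight_matrix(1, 1)[1, 1], pi)
  w24 <- area_weight_matrix(2, 4)
  expect_equal(w24[1, ], rep(pi / 16, 4))
  expect_equal(w24[2, ], rep(3 * pi / 16, 4))
  set.seed(8)
  for (i in 1:5) {
    K <- sample(2:400, 1); L <- sample(2:400, 1)
    expect_lt(abs(sum(area_weight_matrix(K, L)) - pi), 1e-12)
  }
})

test_that("weighting realizes the area-weighted map metric", {
  maps0 <- list(c = matrix(0, 6, 8), h = matrix(0, 6, 8), r = matrix(0, 6, 8),
                Nx = matrix(0, 6, 8), Ny = matrix(0, 6, 8), Nz = matrix(1, 6, 8))
  msA <- apply_weights(manual_mapset(maps0, normalized = TRUE))
  expect_equal(sum((msA$maps$h - msA$maps$h)^2), 0)
  ## constant offset delta: weighted squared distance = delta^2
  delta <- 0.7
  maps1 <- maps0; maps1$h <- maps1$h + delta
  msB <- apply_weights(manual_mapset(maps1, normalized = TRUE))
  expect_equal(sum((msB$maps$h - msA$maps$h)^2), delta^2, tolerance = 1e-12)
  expect_error(apply_weights(msA), "already applied")
})

test_that("normal maps render to RGB and decode back", {
  maps <- list(c = matrix(1, 5, 5), h = matrix(2, 5, 5),
               r = matrix(seq(0.2, 1, length.out = 5), 5, 5, byrow = FALSE),
               Nx = matrix(0, 5, 5), Ny = matrix(0, 5, 5), Nz = matrix(1, 5, 5))
  maps$r[] <- rep(seq(0.2, 1, length.out = 5), 5) # radial increase
  ms <- manual_mapset(maps)
  img <- render_map(ms, "Nxyz", pad = FALSE)
  expect_equal(dim(img), c(5, 5, 3))
  expect_equal(img[1, 1, ] * 255, c(128, 128, 255))
  expect_equal(length(unique(as.vector(render_map(ms, "h", pad = FALSE)))), 3)

  ## round trip of arbitrary unit normals within 1/255 per channel
  set.seed(4)
  n <- crownmap:::unitize_rows(matrix(rnorm(75), 25, 3))
  mapsN <- maps
  mapsN$Nx <- matrix(n[, 1], 5, 5); mapsN$Ny <- matrix(n[, 2], 5, 5)
  mapsN$Nz <- matrix(n[, 3], 5, 5)
  imgN <- render_map(manual_mapset(mapsN), "Nxyz", pad = FALSE)
  for (ch in 1:3) {
    back <- imgN[, , ch] * 2 - 1
    expect_lt(max(abs(back - mapsN[[c("Nx", "Ny", "Nz")[ch]]])), 1 / 255 + 1e-12)
  }
})
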