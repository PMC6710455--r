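square_surface <- function(half = 6, z1 = 5, z2 = 6, n = 4) {
  # diamond (star-shaped square) contours at two planes
  mk <- function(z) new_contour2d(z, c(20, 20), rep(half, n))
  structure(list(id = 1L, contours = list(mk(z1), mk(z2))),
            class = "nucleus_surface")
}

test_that("a two-plane prism meshes to its analytic area, watertight", {
  vs <- c(1, 1, 1)
  s <- square_surface(half = 6)
  mesh <- surface_mesh(s, vs, smooth = FALSE)
  # diamond with half-diagonal d: perimeter 4*d*sqrt(2), dz = 1
  d <- 6
  lateral <- 4 * d * sqrt(2) * 1
  # each cap: 4 triangles from a side (d*sqrt(2)) to the apex at height 0.5
  slant <- sqrt((d / sqrt(2))^2 + 0.5^2)
  cap <- 4 * 0.5 * d * sqrt(2) * slant
  expect_equal(mesh$area_um2, lateral + 2 * cap, tolerance = 1e-9)
  ed <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
              mesh$triangles[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2))
})

test_that("a traced sphere meshes to 4 pi R^2 within 5%", {
  res <- allele_segmentation()
  mesh <- surface_mesh(res$surfaces[[1]], c(0.25, 0.25, 0.5))
  expect_lt(abs(mesh$area_um2 - 4 * pi * 16) / (4 * pi * 16), 0.05)
})

test_that("sphere morphometry: volume, sphericity near 1, centroid", {
  res <- allele_segmentation()
  m <- measure_nucleus(res$surfaces[[1]], c(0.25, 0.25, 0.5))
  V <- 4 / 3 * pi * 4^3
  expect_lt(abs(m$volume_um3 - V) / V, 0.02)
  expect_lt(abs(m$form_factor - 1), 0.05)
  expect_lt(sqrt(sum((m$centroid_um - c(8, 8, 8))^2)), 0.3)
})

test_that("a prolate ellipsoid has smaller form factor than a sphere", {
  e <- ellipsoid_spec(c(10, 8, 8), c(6, 3, 3), intensity = 150)
  ph <- generate_phantom(phantom_spec(list(e), shape = c(80, 64, 32),
                                      voxel_size = c(0.25, 0.25, 0.5),
                                      noise_sigma = 0, blur_sigma_xy = 0,
                                      blur_sigma_z = 0))
  res <- segment_stack(ph$channels$dna,
                       phantom_cfg(d_min_xy = 20, d_max_xy = 52))
  expect_length(res$surfaces, 1)
  m <- measure_nucleus(res$surfaces[[1]], c(0.25, 0.25, 0.5))
  msph <- measure_nucleus(allele_segmentation()$surfaces[[1]],
                          c(0.25, 0.25, 0.5))
  expect_lt(m$form_factor, msph$form_factor)
  # analytic sphericity of a 2:1 prolate via the Thomsen area
  am <- analytic_morphometry(e)
  sph_analytic <- pi^(1 / 3) * (6 * am$volume_um3)^(2 / 3) / am$area_um2
  expect_equal(m$form_factor, sph_analytic, tolerance = 0.05)
})

test_that("scaling voxel size scales V by 8 and A by 4 exactly", {
  s <- square_surface()
  m1 <- measure_nucleus(s, c(1, 1, 1))
  m2 <- measure_nucleus(s, c(2, 2, 2))
  expect_equal(m2$volume_um3, 8 * m1$volume_um3, tolerance = 1e-12)
  expect_equal(m2$area_um2, 4 * m1$area_um2, tolerance = 1e-12)
})

test_that("allele extraction returns the two bright spheres, not speckles", {
  ph <- allele_phantom()
  res <- allele_segmentation()
  # add dim speckles inside the nucleus to the channel
  ch <- ph$channels$ch2
  a <- stack_array(ch)
  set.seed(8)
  for (i in 1:10) {
    p <- c(sample(24:40, 2), sample(12:20, 1))
    a[p[1], p[2], p[3]] <- pmax(a[p[1], p[2], p[3]], 60)
  }
  ch2 <- as_image_stack(a, voxel_size = c(0.25, 0.25, 0.5), bits = 8)
  objs <- extract_alleles(ch2, res$mask, 1, k = 2)
  expect_length(objs, 2)
  expect_false(attr(objs, "undercount"))
  got <- t(vapply(objs, `[[`, numeric(3), "centroid_um"))
  want <- rbind(c(9.5, 8, 8), c(6.5, 8, 8))
  for (i in 1:2)
    expect_lt(min(sqrt(rowSums(sweep(got, 2, want[i, ])^2))), 0.25)
})

test_that("a signal-free channel flags an undercount", {
  res <- allele_segmentation()
  flat <- as_image_stack(array(7, dim = c(64, 64, 32)),
                         voxel_size = c(0.25, 0.25, 0.5), bits = 8L)
  objs <- extract_alleles(flat, res$mask, 1, k = 2)
  expect_true(attr(objs, "undercount"))
  expect_lte(length(objs), 1)
})

test_that("allele extraction is invariant under intensity doubling", {
  ph <- allele_phantom()
  res <- allele_segmentation()
  o1 <- extract_alleles(ph$channels$ch2, res$mask, 1, k = 2)
  a2 <- pmin(stack_array(ph$channels$ch2) * 2, 65535)
  ch2 <- as_image_stack(a2, voxel_size = c(0.25, 0.25, 0.5), bits = 16L)
  o2 <- extract_alleles(ch2, res$mask, 1, k = 2)
  expect_equal(lapply(o1, `[[`, "voxels"), lapply(o2, `[[`, "voxels"))
})

test_that("envelope and pairwise distances match the analytic phantom", {
  ph <- allele_phantom()
  res <- allele_segmentation()
  mesh <- surface_mesh(res$surfaces[[1]], c(0.25, 0.25, 0.5))
  objs <- extract_alleles(ph$channels$ch2, res$mask, 1, k = 2)
  e <- ellipsoid_spec(c(8, 8, 8), c(4, 4, 4),
                      spheres = list(
                        list(channel = 2, offset = c(1.5, 0, 0),
                             radius = 0.5, intensity = 200),
                        list(channel = 2, offset = c(-1.5, 0, 0),
                             radius = 0.5, intensity = 200)))
  am <- analytic_morphometry(e)
  tol <- 2 * 0.25  # two lateral voxels
  for (o in objs) {
    ed <- envelope_distance(o, mesh, c(0.25, 0.25, 0.5))
    expect_lt(abs(ed$surface_um - am$envelope_distances$distance_um[1]),
              tol)
    expect_lt(abs(ed$centroid_um -
                    am$envelope_distances$centroid_distance_um[1]), tol)
  }
  pd <- pairwise_object_distance(objs[[1]], objs[[2]], c(0.25, 0.25, 0.5))
  expect_lt(abs(pd - am$pairwise$distance_um), tol)
  # identity: an object against itself is at distance 0
  expect_equal(pairwise_object_distance(objs[[1]], objs[[1]],
                                        c(0.25, 0.25, 0.5)), 0)
})

test_that("Otsu on a two-level histogram threshold lies between levels", {
  vals <- c(rep(10, 100), rep(200, 100))
  st <- as_image_stack(array(vals, dim = c(20, 10, 1)), bits = 8L)
  lab <- as_label_mask(array(1L, dim = c(20, 10, 1)))
  objs <- extract_alleles(st, lab, 1, k = 1)
  vox <- objs[[1]]$voxels
  expect_equal(nrow(vox), 100)  # only the bright half is foreground
})
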