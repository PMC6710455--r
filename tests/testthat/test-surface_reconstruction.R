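test_that("laminar Q is 1 on a bright rim, 0 inside uniformity", {
  p <- disk_plane(64, 64, list(c(32, 32, 20)), fg = 150, bg = 0)
  on_rim <- new_contour2d(1, c(32, 32), rep(20, 36))
  expect_equal(laminar_quality(p, on_rim, 4)$Q, 1)
  # contour strictly inside a uniform region: ties everywhere, Q = 0
  inside <- new_contour2d(1, c(32, 32), rep(10, 36))
  expect_equal(laminar_quality(p, inside, 4)$Q, 0)
})

test_that("laminar Q equals the brute-force oracle on an offset circle", {
  set.seed(13)
  p <- disk_plane(64, 64, list(c(32, 32, 20))) + matrix(rnorm(64 * 64, 0, 8),
                                                        64, 64)
  ct <- new_contour2d(1, c(33, 31), rep(18, 48))
  q <- laminar_quality(p, ct, 4)
  oq <- oracle_laminar_q(p, contour_vertices(ct), contour_centroid(ct), 4)
  expect_equal(q$Q, oq, tolerance = 1e-12)
})

test_that("propagation terminates near the poles of an ellipsoid", {
  ph <- sphere_phantom()
  cfg <- phantom_cfg()
  st <- ph$channels$dna
  pl <- get_plane(st, 16)
  ct <- trace_plane(pl, list(x = 32, y = 32), 16, cfg)
  bg <- background_threshold(pl)
  up <- propagate(st, ct, +1L, cfg, bg)
  dn <- propagate(st, ct, -1L, cfg, bg)
  # sphere poles at z = 8 +- 4 um: planes 8.5 and 24.5
  expect_lte(abs((16 + length(up$contours)) - 24.5), 2.5)
  expect_lte(abs((16 - length(dn$contours)) - 8.5), 2.5)
  expect_true(up$reason %in% c("point-like", "low-signal", "quality"))
  expect_true(dn$reason %in% c("point-like", "low-signal", "quality"))
})

test_that("a cylinder stack hits the z-limit cap", {
  pl <- disk_plane(64, 64, list(c(32, 32, 16)))
  a <- array(rep(pl, 30), dim = c(64, 64, 30))
  st <- as_image_stack(a, voxel_size = c(0.25, 0.25, 0.5))
  cfg <- phantom_cfg(z_max = 10)
  ct <- trace_plane(pl, list(x = 32, y = 32), 5, cfg)
  res <- propagate(st, ct, +1L, cfg, background_threshold(pl))
  expect_equal(res$reason, "z-limit")
  expect_lte(length(res$contours) + 1, 10)
})

test_that("area regrowth stops the trace between stacked nuclei", {
  e1 <- ellipsoid_spec(c(15, 16, 9), c(5, 5, 4), intensity = 150)
  e2 <- ellipsoid_spec(c(17, 16, 16.6), c(5, 5, 4), intensity = 150)
  ph <- generate_phantom(phantom_spec(list(e1, e2), shape = c(128, 128, 52),
                                      voxel_size = c(0.25, 0.25, 0.5),
                                      noise_sigma = 15, seed = 5))
  cfg <- nt_config(voxel_size = c(0.25, 0.25, 0.5), d_min_xy = 28,
                   d_max_xy = 52, z_min = 10, z_max = 30)
  st <- ph$channels$dna
  pl <- get_plane(st, 18)  # equator of the lower nucleus
  ct <- trace_plane(pl, list(x = 60, y = 64), 18, cfg)
  up <- propagate(st, ct, +1L, cfg, background_threshold(pl))
  expect_true(up$reason %in% c("area-regrowth", "quality", "point-like",
                               "low-signal"))
  # no propagated centroid enters the upper nucleus core
  for (c2 in up$contours) {
    ctr <- contour_centroid(c2)
    p_um <- c((ctr[1] - 0.5) * 0.25, (ctr[2] - 0.5) * 0.25,
              (c2$z - 0.5) * 0.5)
    nd <- sum(((p_um - c(17, 16, 16.6)) / c(5, 5, 4) / 0.7)^2)
    expect_gt(nd, 1)
  }
})

test_that("segment_one accepts a sphere with 5% volume accuracy", {
  ph <- sphere_phantom()
  cfg <- phantom_cfg()
  q <- build_seed_queue(ph$channels$dna, cfg)
  s <- segment_one(ph$channels$dna, q[1, ], cfg)
  expect_s3_class(s, "nucleus_surface")
  m <- measure_nucleus(s, cfg$voxel_size)
  V <- 4 / 3 * pi * 64
  expect_lt(abs(m$volume_um3 - V) / V, 0.05)
  # accepted plane count within the axial prior
  expect_gte(length(s$contours), cfg$z_min)
  expect_lte(length(s$contours), cfg$z_max)
})

test_that("background seeds and too-thin nuclei are rejected", {
  set.seed(21)
  a <- array(pmax(0, rnorm(64 * 64 * 12, 25, 12)), dim = c(64, 64, 12))
  st <- as_image_stack(a, voxel_size = c(0.25, 0.25, 0.5))
  cfg <- phantom_cfg()
  r <- segment_one(st, list(x = 32, y = 32, z = 6, weight = 1), cfg)
  expect_true(is.list(r) && isTRUE(r$rejected))
  # pancake nucleus thinner than z_min planes
  e <- ellipsoid_spec(c(8, 8, 4), c(4, 4, 0.6), intensity = 150)
  ph <- generate_phantom(phantom_spec(list(e), shape = c(64, 64, 16),
                                      voxel_size = c(0.25, 0.25, 0.5),
                                      noise_sigma = 0, blur_sigma_xy = 0,
                                      blur_sigma_z = 0))
  cfg2 <- phantom_cfg(z_min = 6)
  q <- build_seed_queue(ph$channels$dna, cfg2)
  r2 <- segment_one(ph$channels$dna, q[1, ], cfg2)
  expect_true(is.list(r2) && isTRUE(r2$rejected))
  expect_equal(r2$reason, "too-few-planes")
})

test_that("five separated nuclei are all recovered with IoU >= 0.9", {
  ph <- five_phantom()
  res <- five_segmentation()
  expect_equal(length(res$surfaces), 5)
  for (k in 1:5) {
    best <- max(vapply(seq_along(res$surfaces), function(j)
      mask_iou(res$mask$labels, ph$truth$mask$labels, j, k), numeric(1)))
    expect_gte(best, 0.9)
  }
  # all seeds inside accepted nuclei were consumed (none re-traced):
  # exactly 5 surfaces even though the queue held many more seeds
  expect_gt(nrow(res$queue), 5)
})

test_that("empty queues and label disjointness behave", {
  ph <- sphere_phantom()
  cfg <- phantom_cfg()
  empty <- consume_seeds(ph$channels$dna, empty_queue <- data.frame(
    x = integer(0), y = integer(0), z = integer(0), weight = numeric(0)),
    cfg)
  expect_length(empty$surfaces, 0)
  res <- five_segmentation()
  lab <- res$mask$labels
  expect_equal(sum(tabulate(lab[lab > 0])), sum(lab > 0))
  expect_equal(sort(unique(as.vector(lab[lab > 0]))),
               seq_along(res$surfaces))
})

test_that("accepted area profiles are unimodal up to 5% tolerance", {
  res <- five_segmentation()
  for (s in res$surfaces) {
    a <- vapply(s$contours, `[[`, numeric(1), "area")
    pk <- which.max(a)
    if (pk > 1)
      expect_true(all(diff(a[1:pk]) > -0.05 * max(a)))
    if (pk < length(a))
      expect_true(all(diff(a[pk:length(a)]) < 0.05 * max(a)))
  }
})

test_that("adjacent contours stay within the tubular continuity bound", {
  res <- five_segmentation()
  cfg <- five_cfg()
  for (s in res$surfaces) {
    for (i in seq_len(length(s$contours) - 1)) {
      v1 <- contour_vertices(s$contours[[i]])
      v2 <- contour_vertices(s$contours[[i + 1]])
      h12 <- max(apply(v1, 1, function(q)
        min(sqrt((v2[, 1] - q[1])^2 + (v2[, 2] - q[2])^2))))
      h21 <- max(apply(v2, 1, function(q)
        min(sqrt((v1[, 1] - q[1])^2 + (v1[, 2] - q[2])^2))))
      expect_lte(max(h12, h21), cfg$delta_tube + 1)
    }
  }
})

test_that("wall-cropped nuclei are moved to the side list", {
  # centred nucleus: kept
  res <- five_segmentation()
  expect_length(res$cropped, 0)
  # nucleus protruding past z = 1
  e <- ellipsoid_spec(c(8, 8, 1), c(3.5, 3.5, 3), intensity = 150)
  ph <- generate_phantom(phantom_spec(list(e), shape = c(64, 64, 20),
                                      voxel_size = c(0.25, 0.25, 0.5),
                                      noise_sigma = 0))
  out <- segment_stack(ph$channels$dna, phantom_cfg(z_min = 3))
  expect_length(out$surfaces, 0)
  expect_gte(length(out$cropped), 1)
  # nucleus tangent to the x border
  e2 <- ellipsoid_spec(c(3.5, 8, 5), c(3.5, 3.5, 3), intensity = 150)
  ph2 <- generate_phantom(phantom_spec(list(e2), shape = c(64, 64, 20),
                                       voxel_size = c(0.25, 0.25, 0.5),
                                       noise_sigma = 0))
  out2 <- segment_stack(ph2$channels$dna, phantom_cfg(z_min = 3))
  expect_length(out2$surfaces, 0)
  expect_gte(length(out2$cropped), 1)
})
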