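test_that("disk-mean convolution is exact on constants and vs brute force", {
  expect_equal(circular_convolution(matrix(7, 12, 12), 3),
               matrix(7, 12, 12), tolerance = 1e-10)
  expect_error(circular_convolution(matrix(1, 5, 5), 0.5), "radius")
  # single bright pixel: response = intensity/|disk| wherever covered
  p <- matrix(0, 9, 9); p[5, 5] <- 90
  resp <- circular_convolution(p, 2)
  for (x in 3:7) for (y in 3:7)
    expect_equal(resp[x, y], oracle_disk_mean(p, x, y, 2),
                 tolerance = 1e-9)
  # matched filter peaks at the disk centre
  p2 <- disk_plane(41, 41, list(c(21, 21, 10)))
  resp2 <- circular_convolution(p2, 10)
  expect_equal(which(resp2 == max(resp2), arr.ind = TRUE)[1, ],
               c(row = 21, col = 21))
})

test_that("tentative seeds appear at disk centres and not on flat planes", {
  # filter radius (d_min/2 = 7) close to the disk radius (8) keeps the
  # response plateau at the disk centre small
  cfg <- nt_config(d_min_xy = 14, d_max_xy = 30, w_min = 50)
  expect_equal(nrow(detect_tentative_seeds(matrix(5, 40, 40), 1, cfg)), 0)
  p <- disk_plane(64, 40, list(c(16, 20, 8), c(48, 20, 8)))
  seeds <- detect_tentative_seeds(p, 4, cfg)
  expect_equal(nrow(seeds), 2)
  expect_equal(seeds$z, c(4, 4))
  d <- pmin(sqrt((seeds$x - 16)^2 + (seeds$y - 20)^2),
            sqrt((seeds$x - 48)^2 + (seeds$y - 20)^2))
  expect_true(all(d <= 1.5))
  expect_true(all(diff(seeds$weight) <= 0))
})

test_that("ring filter keeps central seeds and rejects junction seeds", {
  cfg <- nt_config(d_min_xy = 16, d_max_xy = 36)
  p <- disk_plane(48, 48, list(c(24, 24, 14)))
  expect_true(ring_contrast_filter(p, list(x = 24, y = 24), cfg)$keep)
  # seed at the waist between two touching disks
  p2 <- disk_plane(72, 48, list(c(22, 24, 14), c(50, 24, 14)))
  rc <- ring_contrast_filter(p2, list(x = 36, y = 24), cfg)
  expect_false(rc$keep)
})

test_that("ring filter rejects nearly all seeds in pure noise", {
  set.seed(42)
  cfg <- nt_config(d_min_xy = 16, d_max_xy = 36)
  rejected <- 0
  for (i in 1:20) {
    # detector-noise background: relative fluctuation well above tau_fluct
    p <- matrix(pmax(0, rnorm(64 * 64, 20, 16)), 64, 64)
    if (!ring_contrast_filter(p, list(x = 32, y = 32), cfg)$keep)
      rejected <- rejected + 1
  }
  expect_gte(rejected, 19)
})

test_that("multipole moments equal the brute-force oracle to 1e-12", {
  set.seed(7)
  for (i in 1:25) {
    p <- matrix(runif(49, 0, 200), 7, 7)
    cx <- runif(1, 3, 5); cy <- runif(1, 3, 5)
    m <- multipole_moments(p, c(cx, cy), 3, 0.5)
    o <- oracle_moments(p, cx, cy, 3, 0.5)
    for (f in c("m", "p_x", "p_y", "q_xx", "q_yy", "q_xy", "M_q", "M_d"))
      expect_equal(m[[f]], o[[f]],
                   tolerance = 1e-12 * max(1, abs(o[[f]])))
  }
})

test_that("point-symmetric intensity gives zero dipole magnitude", {
  p <- matrix(0, 11, 11)
  set.seed(3)
  for (i in 1:5) {
    dx <- sample(-4:4, 1); dy <- sample(-4:4, 1); v <- runif(1, 10, 100)
    p[6 + dx, 6 + dy] <- p[6 + dx, 6 + dy] + v
    p[6 - dx, 6 - dy] <- p[6 - dx, 6 - dy] + v
  }
  m <- multipole_moments(p, c(6, 6), 5, 0.5)
  expect_lt(abs(m$p_x), 1e-9 * m$m)
  expect_lt(abs(m$p_y), 1e-9 * m$m)
  expect_lt(m$M_q, 1e-9 * m$m)
})

test_that("moments are translation covariant and 90-degree det-invariant", {
  set.seed(9)
  base <- matrix(runif(81, 0, 100), 9, 9)
  big <- matrix(0, 21, 21)
  big[3:11, 3:11] <- base
  m1 <- multipole_moments(big, c(7, 7), 4, 0.5)
  big2 <- matrix(0, 21, 21)
  big2[9:17, 8:16] <- base  # translate pattern and centre together
  m2 <- multipole_moments(big2, c(13, 12), 4, 0.5)
  for (f in c("m", "p_x", "p_y", "q_yy", "q_xy", "M_q", "M_d"))
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-12 * max(1, abs(m1[[f]])))
  # rotate the patch by 90 degrees: determinant magnitude is preserved
  rot <- t(base)[ncol(base):1, ]
  bigr <- matrix(0, 21, 21)
  bigr[3:11, 3:11] <- rot
  mr <- multipole_moments(bigr, c(7, 7), 4, 0.5)
  expect_equal(m1$M_d, mr$M_d, tolerance = 1e-9 * max(1, abs(m1$M_d)))
})

test_that("shape gate separates centred from displaced and oblique shapes", {
  p <- disk_plane(41, 41, list(c(21, 21, 14)), fg = 150, bg = 0)
  ctr <- multipole_moments(p, c(21, 21), 10, 0.5)
  off <- multipole_moments(p, c(26, 21), 10, 0.5)
  expect_gt(off$M_q, ctr$M_q)
  expect_true(shape_gate(ctr, mq_max = 1e-6 * ctr$m, md_max = 1e-6 * ctr$m))
  # obliquely oriented 10:1 bar has larger |M_d| than an equal-mass disk
  bar <- matrix(0, 41, 41)
  for (x in 1:41) for (y in 1:41) {
    u <- (x - 21 + y - 21) / sqrt(2); v <- (x - 21 - (y - 21)) / sqrt(2)
    if (abs(u) <= 15 && abs(v) <= 1.5) bar[x, y] <- 150
  }
  mb <- multipole_moments(bar, c(21, 21), 10, 0.5)
  expect_gt(abs(mb$M_d), abs(ctr$M_d))
})

test_that("seed queue is weight-sorted and finds the nucleus equator", {
  # all-background stack: empty queue
  bgst <- as_image_stack(array(10, dim = c(32, 32, 4)),
                         voxel_size = c(0.25, 0.25, 0.5))
  expect_equal(nrow(build_seed_queue(bgst, phantom_cfg())), 0)

  ph <- sphere_phantom()
  q <- build_seed_queue(ph$channels$dna, phantom_cfg())
  expect_gt(nrow(q), 0)
  expect_true(all(diff(q$weight) <= 0))
  # top seed near the equatorial plane (z = 16/17) and in-plane centre
  expect_lte(abs(q$z[1] - 16.5), 2.5)
  expect_lt(sqrt((q$x[1] - 32.5)^2 + (q$y[1] - 32.5)^2),
            phantom_cfg()$d_min_xy / 4)
  # no nucleus is seedless: at least one seed inside the sphere
  expect_gt(sum(ph$truth$mask$labels[cbind(q$x, q$y, q$z)] == 1), 0)
})
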