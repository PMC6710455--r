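# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain double loops from the defining formulas, sharing
# no code with the implementation.

oracle_disk_mean <- function(plane, x, y, radius) {
  r <- floor(radius)
  vals <- c()
  nx <- nrow(plane); ny <- ncol(plane)
  for (dx in -r:r) for (dy in -r:r) {
    if (dx^2 + dy^2 > radius^2) next
    px <- x + dx; py <- y + dy
    # mirror reflection at the border (half-sample convention)
    if (px < 1) px <- 1 - px
    if (px > nx) px <- 2 * nx + 1 - px
    if (py < 1) py <- 1 - py
    if (py > ny) py <- 2 * ny + 1 - py
    vals <- c(vals, plane[px, py])
  }
  mean(vals)
}

oracle_moments <- function(plane, cx, cy, r_m, eps) {
  m <- p_x <- p_y <- q_xx <- q_yy <- q_xy <- 0
  for (i in seq_len(nrow(plane))) for (j in seq_len(ncol(plane))) {
    x <- i - cx; y <- j - cy
    r <- sqrt(x^2 + y^2)
    if (!(r_m - r > 0)) next
    I <- plane[i, j]
    m <- m + I
    p_x <- p_x + x / (r + eps)^0.5 * I
    p_y <- p_y + y / (r + eps)^0.5 * I
    q_xx <- q_xx + 2 * (x^2 - x^2) / (r + eps)^2 * I
    q_yy <- q_yy + 2 * (y^2 - x^2) / (r + eps)^2 * I
    q_xy <- q_xy + 2 * x * y / (r + eps)^2 * I
  }
  list(m = m, p_x = p_x, p_y = p_y, q_xx = q_xx, q_yy = q_yy,
       q_xy = q_xy, M_q = (p_x^2 + p_y^2) / m,
       M_d = (q_xx * q_yy - q_xy^2) / m)
}

# full convolution of a radial profile with the +-1 box-derivative mask
oracle_edge_response <- function(samples, h, r_lo, r_hi) {
  best_r <- NA; best_f <- -Inf
  for (r0 in ceiling(r_lo):floor(r_hi)) {
    if (r0 - h < 0 || r0 + h > length(samples) - 1) next
    f <- 0
    for (u in -h:h) {
      if (u == 0) next
      f <- f + samples[r0 + u + 1] * (if (u < 0) 1 else -1)
    }
    if (!is.na(f) && f > best_f) { best_f <- f; best_r <- r0 }
  }
  list(r0 = best_r, F = best_f)
}

# independent cyclic chain-scan clustering
oracle_cluster <- function(x, y, max_dev) {
  n <- length(x)
  cl <- integer(n)
  cl[1] <- 1
  if (n > 1) for (i in 2:n)
    cl[i] <- if (sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
                 <= max_dev) cl[i - 1] else cl[i - 1] + 1
  if (n > 1 && cl[n] != cl[1] &&
      sqrt((x[1] - x[n])^2 + (y[1] - y[n])^2) <= max_dev)
    cl[cl == cl[n]] <- cl[1]
  cl
}

oracle_bilinear <- function(plane, px, py) {
  x0 <- min(max(floor(px), 1), nrow(plane) - 1)
  y0 <- min(max(floor(py), 1), ncol(plane) - 1)
  fx <- px - x0; fy <- py - y0
  plane[x0, y0] * (1 - fx) * (1 - fy) +
    plane[x0 + 1, y0] * fx * (1 - fy) +
    plane[x0, y0 + 1] * (1 - fx) * fy +
    plane[x0 + 1, y0 + 1] * fx * fy
}

# per-point laminar integrals and Q from first principles
oracle_laminar_q <- function(plane, verts, center, delta_r) {
  wins <- 0; total <- 0
  for (i in seq_len(nrow(verts))) {
    d <- verts[i, ] - center
    r0 <- sqrt(sum(d^2))
    if (r0 < 1e-9) next
    dir <- d / r0
    lm <- lp <- 0
    ok <- TRUE
    for (u in seq_len(delta_r)) {
      for (s in c(-1, 1)) {
        px <- center[1] + (r0 + s * u) * dir[1]
        py <- center[2] + (r0 + s * u) * dir[2]
        if (px < 1 || px > nrow(plane) || py < 1 || py > ncol(plane)) {
          ok <- FALSE
        } else {
          v <- oracle_bilinear(plane, px, py)
          if (s < 0) lm <- lm + v else lp <- lp + v
        }
      }
    }
    if (!ok) next
    total <- total + 1
    if (lm > lp) wins <- wins + 1
  }
  if (total == 0) NA_real_ else wins / total
}

# radius of a polygon about an origin along given ray angles, by direct
# ray-segment intersection
polygon_radii_about_oracle <- function(ct, origin, n_rays) {
  v <- contour_vertices(ct)
  m <- nrow(v)
  out <- numeric(n_rays)
  for (k in seq_len(n_rays)) {
    a <- 2 * pi * (k - 1) / n_rays
    d <- c(cos(a), sin(a))
    best <- NA
    for (e in seq_len(m)) {
      p1 <- v[e, ]; p2 <- v[e %% m + 1, ]
      s <- p2 - p1
      den <- d[1] * (-s[2]) - d[2] * (-s[1])
      if (abs(den) < 1e-12) next
      rhs <- p1 - origin
      t1 <- (rhs[1] * (-s[2]) - rhs[2] * (-s[1])) / den
      t2 <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
      if (t1 >= 0 && t2 >= -1e-9 && t2 <= 1 + 1e-9)
        if (is.na(best) || t1 < best) best <- t1
    }
    out[k] <- best
  }
  out
}
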