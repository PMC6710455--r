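#' Seed point detection
#'
#' Tentative nucleus centres are detected independently on every
#' z-plane: each plane is convolved with a circular (disk-mean) filter
#' whose radius is half the minimal nucleus diameter, the local maxima
#' of the response become candidate seeds, and each candidate's
#' response value becomes its priority weight. Several seeds per 3D
#' nucleus are expected; the priority order decides which one initiates
#' tracing. Candidates are screened by two filters: ring-contrast
#' stability (mean intensity over concentric rings must stay stable and
#' its fluctuation low inside the minimal nucleus radius, which rejects
#' seeds sitting at the junction of two touching nuclei) and
#' intensity-weighted dipole/quadrupole shape moments that reject
#' highly irregular, non-oval candidate regions.
#'
#' @name seed_detection
NULL

reflect_pad <- function(m, p) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- c(rev(seq_len(min(p, nx))), seq_len(nx),
          nx + 1 - rev(seq_len(min(p, nx))))
  if (p > nx) ix <- rep(ix, length.out = nx + 2 * p)  # degenerate tiny plane
  iy <- c(rev(seq_len(min(p, ny))), seq_len(ny),
          ny + 1 - rev(seq_len(min(p, ny))))
  m[ix, iy]
}

disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

#' Circular (disk-mean) filter convolution
#'
#' The response at (x, y) is the mean intensity over the disk of the
#' given radius centred there -- a matched filter for round bright
#' objects. Borders are handled by reflect padding, so the operator is
#' linear in intensity and exact at the edge.
#'
#' @param plane numeric matrix `(nx, ny)`.
#' @param radius disk radius in px (>= 1).
#' @return Response matrix of the same shape.
#' @export
circular_convolution <- function(plane, radius) {
  if (radius < 1) stop("filter radius must be >= 1 px")
  off <- disk_offsets(radius)
  r <- floor(radius)
  k <- matrix(0, 2 * r + 1, 2 * r + 1)
  k[cbind(off$dx + r + 1, off$dy + r + 1)] <- 1 / nrow(off)
  padded <- reflect_pad(plane, r)
  resp <- EBImage::filter2(padded, k, boundary = "replicate")
  resp[(r + 1):(r + nrow(plane)), (r + 1):(r + ncol(plane)), drop = FALSE]
}

#' Detect tentative seeds on one plane
#'
#' Local maxima (8-neighbourhood) of the circular-convolution response
#' at radius `d_min_xy / 2`, with non-maximum suppression at exclusion
#' distance `d_min_xy / 2`; the response value at the maximum is the
#' seed's priority weight, and candidates below `w_min` are dropped.
#' When `w_min` is `NULL` it is estimated from the plane as background
#' mean + 2 background sd, the background taken as the 1st-20th
#' percentile intensity band.
#'
#' With `multi_radius = TRUE` the response is the maximum over three
#' filter radii spanning the size prior (`d_min_xy/2` to `d_max_xy/2`),
#' which favours seeds at the widest cross-section of large nuclei at
#' some extra cost; the default single radius follows the size prior's
#' lower bound.
#'
#' @param plane numeric matrix.
#' @param z plane index carried into the seeds.
#' @param cfg an [nt_config()] (uses `d_min_xy`, `w_min`,
#'   `multi_radius`).
#' @return data frame with columns `x`, `y`, `z`, `weight`, ordered by
#'   weight descending.
#' @export
detect_tentative_seeds <- function(plane, z, cfg) {
  radius <- cfg$d_min_xy / 2
  resp <- circular_convolution(plane, radius)
  if (isTRUE(cfg$multi_radius)) {
    for (r2 in c((cfg$d_min_xy + cfg$d_max_xy) / 4, cfg$d_max_xy / 2))
      resp <- pmax(resp, circular_convolution(plane, r2))
  }
  nx <- nrow(resp); ny <- ncol(resp)
  if (nx < 3 || ny < 3) return(empty_seeds())
  core <- resp[2:(nx - 1), 2:(ny - 1)]
  nb <- list(resp[1:(nx - 2), 2:(ny - 1)], resp[3:nx, 2:(ny - 1)],
             resp[2:(nx - 1), 1:(ny - 2)], resp[2:(nx - 1), 3:ny],
             resp[1:(nx - 2), 1:(ny - 2)], resp[1:(nx - 2), 3:ny],
             resp[3:nx, 1:(ny - 2)], resp[3:nx, 3:ny])
  ge_all <- Reduce("&", lapply(nb, function(n) core >= n))
  gt_any <- Reduce("|", lapply(nb, function(n) core > n))
  is_max <- ge_all & gt_any
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(empty_seeds())
  sx <- idx[, 1] + 1L; sy <- idx[, 2] + 1L
  w <- resp[cbind(sx, sy)]
  w_min <- cfg$w_min
  if (is.null(w_min)) {
    band <- stats::quantile(plane, c(0.01, 0.20))
    bg <- plane[plane >= band[1] & plane <= band[2]]
    w_min <- mean(bg) + 2 * stats::sd(bg)
    if (!is.finite(w_min)) w_min <- mean(bg)
  }
  keep <- w >= w_min & w > 0
  sx <- sx[keep]; sy <- sy[keep]; w <- w[keep]
  if (!length(sx)) return(empty_seeds())
  o <- order(-w, sy, sx)
  sx <- sx[o]; sy <- sy[o]; w <- w[o]
  excl2 <- radius^2
  taken <- logical(length(sx))
  for (i in seq_along(sx)) {
    if (taken[i]) next
    d2 <- (sx - sx[i])^2 + (sy - sy[i])^2
    taken[d2 <= excl2 & seq_along(sx) > i] <- TRUE
  }
  data.frame(x = sx[!taken], y = sy[!taken], z = z, weight = w[!taken])
}

empty_seeds <- function()
  data.frame(x = integer(0), y = integer(0), z = integer(0),
             weight = numeric(0))

#' Ring-contrast stability filter
#'
#' Evaluates concentric rings of width `ring_width` around a seed,
#' stepping from `r = ring_width` out to `d_max_xy / 2`, recording each
#' ring's mean intensity and intensity sd. The seed is rejected when,
#' for rings still inside the minimal nucleus radius `d_min_xy / 2`,
#' the relative ring-to-ring mean change exceeds `tau_contrast` (the
#' contrast ratio is not stable) or the ring fluctuation sd/mean rises
#' above `tau_fluct` (a rapid increase in intensity fluctuation at
#' sub-nuclear diameters marks a seed sitting between nuclei or in
#' background). Rings extending outside the plane are truncated and
#' flagged.
#'
#' @param plane numeric matrix.
#' @param seed list or one-row data frame with `x`, `y`.
#' @param cfg an [nt_config()].
#' @return list: `keep` (logical), `reason` (`NA` or
#'   `"contrast"`/`"fluctuation"`), `rings` (data frame: r_outer, mean,
#'   sd, truncated).
#' @export
ring_contrast_filter <- function(plane, seed, cfg) {
  w <- cfg$ring_width
  r_out <- seq(w, cfg$d_max_xy / 2, by = w)
  nx <- nrow(plane); ny <- ncol(plane)
  rmax <- max(r_out)
  wx <- max(1, floor(seed$x - rmax)):min(nx, ceiling(seed$x + rmax))
  wy <- max(1, floor(seed$y - rmax)):min(ny, ceiling(seed$y + rmax))
  d <- sqrt(outer((wx - seed$x)^2, (wy - seed$y)^2, "+"))
  vals <- plane[wx, wy, drop = FALSE]
  stats_df <- do.call(rbind, lapply(seq_along(r_out), function(k) {
    lo <- r_out[k] - w; hi <- r_out[k]
    sel <- d > lo & d <= hi
    full_area <- pi * (hi^2 - lo^2)
    n <- sum(sel)
    data.frame(r_outer = hi,
               mean = if (n) mean(vals[sel]) else NA_real_,
               sd = if (n > 1) stats::sd(vals[sel]) else 0,
               truncated = n < 0.9 * full_area)
  }))
  inner <- stats_df$r_outer <= cfg$d_min_xy / 2
  keep <- TRUE; reason <- NA_character_
  mu <- stats_df$mean
  for (k in which(inner)) {
    if (k == 1 || is.na(mu[k]) || is.na(mu[k - 1])) next
    if (mu[k - 1] > 0 &&
        abs(mu[k] - mu[k - 1]) / mu[k - 1] > cfg$tau_contrast) {
      keep <- FALSE; reason <- "contrast"; break
    }
    if (mu[k] > 0 && stats_df$sd[k] / mu[k] > cfg$tau_fluct) {
      keep <- FALSE; reason <- "fluctuation"; break
    }
  }
  list(keep = keep, reason = reason, rings = stats_df)
}

#' Modified dipole and quadrupole moments of a candidate region
#'
#' Implements the intensity-weighted shape moments literally, with
#' coordinates a in \{x, y\} relative to the centre, r the pixel
#' distance from the centre, and Theta the unit step (1 for positive
#' argument):
#'
#' * mass `m = sum Theta(r_m - r) I`
#' * dipole `p_a = sum s_a I` with `s_a = Theta(r_m - r) a / (r + eps)^(1/2)`
#' * quadrupole `q_aa = sum s_aa I` with
#'   `s_aa = 2 Theta(r_m - r) (a^2 - x^2) / (r + eps)^2`
#' * `q_xy = q_yx = sum s_xy I` with
#'   `s_xy = 2 Theta(r_m - r) x y / (r + eps)^2`
#' * magnitudes `M_q = (p_x^2 + p_y^2) / m` and
#'   `M_d = det(q) / m = (q_xx q_yy - q_xy^2) / m`.
#'
#' Two literal quirks are kept as written and must be kept in mind when
#' setting gates: (1) the `(a^2 - x^2)` numerator makes `q_xx`
#' identically zero, so `det(q) = -q_xy^2 <= 0` and the quadrupole
#' magnitude responds only to obliquely oriented anisotropy; (2) the
#' magnitude built from the dipole components is the one conventionally
#' associated with displacement asymmetry, although its label pairs it
#' with "quadrupole" in the defining equations -- the naming mismatch is
#' preserved, the formulas are authoritative.
#'
#' @param plane numeric matrix.
#' @param center numeric `c(x, y)` (px, 1-based, may be fractional).
#' @param r_m analysis radius (px).
#' @param eps regularising constant (px).
#' @return list with `m`, `p_x`, `p_y`, `q_xx`, `q_yy`, `q_xy`, `M_q`,
#'   `M_d`, `r_m`, `eps`. Zero mass within `r_m` is an error (degenerate
#'   candidate).
#' @export
multipole_moments <- function(plane, center, r_m, eps) {
  nx <- nrow(plane); ny <- ncol(plane)
  wx <- max(1, floor(center[1] - r_m)):min(nx, ceiling(center[1] + r_m))
  wy <- max(1, floor(center[2] - r_m)):min(ny, ceiling(center[2] + r_m))
  xx <- outer(wx - center[1], rep(1, length(wy)))
  yy <- outer(rep(1, length(wx)), wy - center[2])
  r <- sqrt(xx^2 + yy^2)
  theta <- as.numeric(r_m - r > 0)
  I <- plane[wx, wy, drop = FALSE]
  m <- sum(theta * I)
  if (m <= 0) stop("degenerate mass: no intensity within r_m of the centre")
  p_x <- sum(theta * xx / (r + eps)^0.5 * I)
  p_y <- sum(theta * yy / (r + eps)^0.5 * I)
  q_xx <- sum(2 * theta * (xx^2 - xx^2) / (r + eps)^2 * I)
  q_yy <- sum(2 * theta * (yy^2 - xx^2) / (r + eps)^2 * I)
  q_xy <- sum(2 * theta * xx * yy / (r + eps)^2 * I)
  list(m = m, p_x = p_x, p_y = p_y, q_xx = q_xx, q_yy = q_yy, q_xy = q_xy,
       M_q = (p_x^2 + p_y^2) / m,
       M_d = (q_xx * q_yy - q_xy * q_xy) / m,
       r_m = r_m, eps = eps)
}

#' Moment-magnitude gate
#'
#' Keeps a candidate iff the dipole-built magnitude `M_q` is at most
#' `mq_max` and `|M_d|` is at most `md_max`. The shipped default gates
#' are calibrated on phantoms (see [seed_moment_gates()]); on real data
#' they are meant to be tuned per imaging modality.
#'
#' @param meas output of [multipole_moments()].
#' @param mq_max,md_max magnitude limits (intensity-scaled units).
#' @return `TRUE` to keep, `FALSE` to reject.
#' @export
shape_gate <- function(meas, mq_max, md_max)
  meas$M_q <= mq_max && abs(meas$M_d) <= md_max

#' Intensity-scaled moment gates
#'
#' The literal moment magnitudes scale linearly with image intensity
#' (M_q ~ I * N * r for a fixed shape), so absolute gates must be set
#' relative to the image's intensity scale. This helper converts the
#' dimensionless configuration gates `mq_max`, `md_max` into absolute
#' limits by multiplying with `I_ref * r_m^2` (dipole) and `I_ref * r_m^2`
#' (quadrupole), `I_ref` being a robust foreground intensity estimate
#' (90th percentile of the plane). The dimensionless defaults were
#' calibrated once on ellipsoid phantoms so that centred nuclear
#' sections pass with an ample margin while half-radius displaced or
#' obliquely elongated regions fail.
#'
#' @param plane numeric matrix.
#' @param cfg an [nt_config()].
#' @return list with absolute `mq_max`, `md_max`.
#' @export
seed_moment_gates <- function(plane, cfg) {
  i_ref <- as.numeric(stats::quantile(plane, 0.9))
  if (i_ref <= 0) i_ref <- max(mean(plane), 1)
  list(mq_max = cfg$mq_max * i_ref * cfg$r_m^2,
       md_max = cfg$md_max * i_ref * cfg$r_m^2)
}

#' Build the priority-ordered seed queue for a whole stack
#'
#' Scans every z-plane independently (one plane resident at a time),
#' detects tentative seeds, screens them with the ring-contrast filter
#' and the moment gate, and concatenates the survivors sorted by weight
#' descending (ties broken by (z, y, x) ascending).
#'
#' @param stack an `image_stack`.
#' @param cfg an [nt_config()].
#' @return data frame `x`, `y`, `z`, `weight`, weight-descending.
#' @export
build_seed_queue <- function(stack, cfg) {
  sh <- stack_shape(stack)
  out <- vector("list", sh[3])
  for (z in seq_len(sh[3])) {
    plane <- get_plane(stack, z)
    cand <- detect_tentative_seeds(plane, z, cfg)
    if (!nrow(cand)) next
    gates <- seed_moment_gates(plane, cfg)
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      s <- cand[i, ]
      rc <- ring_contrast_filter(plane, s, cfg)
      if (!rc$keep) return(FALSE)
      meas <- tryCatch(multipole_moments(plane, c(s$x, s$y), cfg$r_m,
                                         cfg$eps),
                       error = function(e) NULL)
      if (is.null(meas)) return(FALSE)
      shape_gate(meas, gates$mq_max, gates$md_max)
    }, logical(1))
    out[[z]] <- cand[keep, , drop = FALSE]
  }
  q <- do.call(rbind, c(out, list(empty_seeds())))
  q[order(-q$weight, q$z, q$y, q$x), , drop = FALSE]
}
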