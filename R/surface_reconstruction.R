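#' Assembling contours into 3D nucleus surfaces
#'
#' Per-plane contours are gated by the laminar quality estimator Q and
#' propagated plane by plane in both z-directions until a termination
#' rule fires: the quality drops below threshold, the contour shrinks
#' to a point, the enclosed fluorescence falls to background level, the
#' area starts regrowing after a monotone decrease (a sign that the
#' trace has slid into the nucleus stacked above/below), or the stack
#' boundary or the axial size prior is reached. The seed queue is
#' consumed in priority order and every remaining seed inside an
#' accepted nucleus is eliminated, so each nucleus is traced exactly
#' once.
#'
#' @name surface_reconstruction
NULL

#' Laminar quality estimator Q
#'
#' For every boundary point, parametrised by the ray from the contour's
#' mass centre, the image brightness is integrated (discrete unit-step
#' sums) over a laminar layer of width `delta_r` just inside
#' (`L_minus`) and just outside (`L_plus`) the boundary. Q is the
#' fraction of boundary points with `L_minus > L_plus` (strict; ties
#' count 0), so `Q = 1` for a contour lying exactly on the rim of a
#' bright object and `Q = 0` for a contour strictly inside a uniform
#' region. (The defining expression printed as a step function of the
#' layer ratio is degenerate -- identically 1 for positive intensities
#' -- so the stated intent, comparing the inner and outer integrals, is
#' what is implemented.)
#'
#' Boundary points whose laminar layer leaves the plane are excluded
#' from the mean and flagged; a contour with all points clipped has
#' undefined quality (`Q = NA`).
#'
#' @param plane numeric matrix.
#' @param ct a `contour2d`.
#' @param delta_r laminar width (px, >= 1).
#' @return list `Q`, `L_minus`, `L_plus` (per boundary point), `clipped`
#'   (logical per point).
#' @export
laminar_quality <- function(plane, ct, delta_r) {
  stopifnot(delta_r >= 1)
  ctr <- contour_centroid(ct)
  v <- contour_vertices(ct)
  nx <- nrow(plane); ny <- ncol(plane)
  n <- nrow(v)
  us <- seq_len(delta_r)
  Lm <- Lp <- rep(NA_real_, n)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    d <- v[i, ] - ctr
    r0 <- sqrt(sum(d^2))
    if (r0 < 1e-9) { clipped[i] <- TRUE; next }
    dir <- d / r0
    rin <- r0 - us; rout <- r0 + us
    px <- ctr[1] + c(rin, rout) * dir[1]
    py <- ctr[2] + c(rin, rout) * dir[2]
    if (any(px < 1 | px > nx | py < 1 | py > ny)) {
      clipped[i] <- TRUE; next
    }
    s <- bilinear_sample(plane, px, py)
    Lm[i] <- sum(s[seq_len(delta_r)])
    Lp[i] <- sum(s[delta_r + seq_len(delta_r)])
  }
  ok <- !clipped
  Q <- if (any(ok)) mean(Lm[ok] > Lp[ok]) else NA_real_
  list(Q = Q, L_minus = Lm, L_plus = Lp, clipped = clipped)
}

# scanline fill of a contour polygon; returns integer matrix of (x, y)
# pixel coordinates inside the polygon
contour_fill_pixels <- function(ct, nx, ny) {
  v <- contour_vertices(ct)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ylo <- max(1L, floor(min(y))); yhi <- min(ny, ceiling(max(y)))
  out <- vector("list", max(0, yhi - ylo + 1))
  j <- 0
  for (yy in ylo:yhi) {
    cross <- ((y <= yy) & (yn > yy)) | ((yn <= yy) & (y > yy))
    if (!any(cross)) next
    xi <- x[cross] + (yy - y[cross]) * (xn[cross] - x[cross]) /
      (yn[cross] - y[cross])
    xi <- sort(xi)
    j <- j + 1
    spans <- matrix(xi[seq_len(2 * (length(xi) %/% 2))], ncol = 2,
                    byrow = TRUE)
    px <- unlist(lapply(seq_len(nrow(spans)), function(s) {
      a <- ceiling(spans[s, 1]); b <- floor(spans[s, 2])
      if (b < a) integer(0) else max(1L, a):min(nx, b)
    }))
    if (length(px)) out[[j]] <- cbind(px, yy)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) matrix(integer(0), 0, 2) else m
}

point_in_contour <- function(ct, px, py) {
  v <- contour_vertices(ct)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  for (e in seq_along(x)) {
    cr <- ((y[e] <= py) & (yn[e] > py)) | ((yn[e] <= py) & (y[e] > py))
    if (any(cr)) {
      xi <- x[e] + (py[cr] - y[e]) * (xn[e] - x[e]) / (yn[e] - y[e])
      inside[cr] <- xor(inside[cr], px[cr] < xi)
    }
  }
  inside
}

mean_inside_contour <- function(plane, ct) {
  pix <- contour_fill_pixels(ct, nrow(plane), ncol(plane))
  if (!nrow(pix)) return(NA_real_)
  mean(plane[pix])
}

#' Background intensity estimate of a plane
#'
#' Median + 1 sd of the 1st-to-20th percentile intensity band,
#' computed once per stack from the plane of the highest-priority
#' seed; used by the low-signal termination rule.
#'
#' @param plane numeric matrix.
#' @return scalar background threshold.
#' @export
background_threshold <- function(plane) {
  band <- stats::quantile(plane, c(0.01, 0.20))
  bg <- plane[plane >= band[1] & plane <= band[2]]
  s <- stats::sd(bg)
  stats::median(bg) + if (is.finite(s)) s else 0
}

a_point_area <- function(cfg) pi * (cfg$a_point_factor * cfg$d_min_xy / 2)^2

# detect area regrowth: two consecutive increases after a strictly
# decreasing run of length >= 2 ending at the local minimum
area_regrowth <- function(areas) {
  m <- length(areas)
  if (m < 5) return(FALSE)
  a <- areas
  a[m] > a[m - 1] && a[m - 1] > a[m - 2] &&
    a[m - 2] < a[m - 3] && a[m - 3] < a[m - 4]
}

#' Propagate a contour across planes in one z-direction
#'
#' Repeatedly traces the next plane in contour-initialised mode and
#' applies the termination rules in order: tracing failure or
#' `Q < q_min` ("quality"), contour area below the point threshold
#' ("point-like"), mean intensity inside the contour below the
#' background estimate ("low-signal"), two consecutive area increases
#' after a monotone decrease ("area-regrowth", the regrowth planes are
#' discarded), stack border or more than `z_max` planes from the start
#' ("z-limit").
#'
#' @param stack an `image_stack`.
#' @param start a `contour2d` at the start plane.
#' @param direction +1 or -1.
#' @param cfg an [nt_config()].
#' @param bg_thresh background threshold ([background_threshold()]).
#' @return list `contours` (beyond the start plane, in propagation
#'   order) and `reason`.
#' @export
propagate <- function(stack, start, direction, cfg, bg_thresh) {
  sh <- stack_shape(stack)
  out <- list()
  areas <- start$area
  prior <- start
  apoint <- a_point_area(cfg)
  repeat {
    z <- prior$z + direction
    if (z < 1 || z > sh[3]) return(list(contours = out, reason = "z-limit"))
    if (length(out) + 1 >= cfg$z_max)
      return(list(contours = out, reason = "z-limit"))
    plane <- get_plane(stack, z)
    ct <- trace_plane(plane, prior, z, cfg)
    if (is.null(ct)) return(list(contours = out, reason = "quality"))
    q <- laminar_quality(plane, ct, cfg$delta_r)
    ct$quality <- q$Q
    if (is.na(q$Q) || q$Q < cfg$q_min)
      return(list(contours = out, reason = "quality"))
    if (ct$area < apoint)
      return(list(contours = out, reason = "point-like"))
    mi <- mean_inside_contour(plane, ct)
    if (is.na(mi) || mi < bg_thresh)
      return(list(contours = out, reason = "low-signal"))
    areas <- c(areas, ct$area)
    if (area_regrowth(areas)) {
      # drop the two regrowth planes (the last kept contour and this one)
      out <- out[seq_len(max(0, length(out) - 1))]
      return(list(contours = out, reason = "area-regrowth"))
    }
    out[[length(out) + 1]] <- ct
    prior <- ct
  }
}

new_nucleus_surface <- function(id, contours, seed, term_down, term_up,
                                touches_wall = FALSE) {
  zs <- vapply(contours, `[[`, numeric(1), "z")
  o <- order(zs)
  structure(list(id = id, contours = contours[o], seed = seed,
                 z_range = range(zs), term_down = term_down,
                 term_up = term_up, touches_wall = touches_wall),
            class = "nucleus_surface")
}

# A boundary cannot be localised closer to the lateral wall than the
# edge-mask half-width (rays clip there and radii fall back to
# interpolation), so any vertex within that margin marks the nucleus as
# touching the wall.
surface_touches_wall <- function(contours, nx, ny, margin) {
  for (ct in contours) {
    v <- contour_vertices(ct)
    if (any(v[, 1] <= margin + 1 | v[, 1] >= nx - margin |
              v[, 2] <= margin + 1 | v[, 2] >= ny - margin))
      return(TRUE)
  }
  FALSE
}

#' Segment one nucleus from a seed
#'
#' Runs the seeded two-iteration trace at the seed's plane; if the
#' resulting contour's Q is below `q_min` the seed is abandoned.
#' Otherwise the contour is propagated in both z-directions (the
#' downward direction starts from the same seed-plane contour, so both
#' directions share one starting cross-section) and the planes are
#' concatenated. Surfaces with fewer than `z_min` or more than `z_max`
#' planes are rejected.
#'
#' @param stack an `image_stack`.
#' @param seed one-row data frame / list with `x`, `y`, `z`, `weight`.
#' @param cfg an [nt_config()].
#' @param bg_thresh background threshold; computed from the seed plane
#'   when `NULL`.
#' @param id nucleus id for the surface.
#' @return A `nucleus_surface`, or a list
#'   `list(rejected = TRUE, reason = ...)`.
#' @export
segment_one <- function(stack, seed, cfg, bg_thresh = NULL, id = 1L) {
  plane <- get_plane(stack, seed$z)
  if (is.null(bg_thresh)) bg_thresh <- background_threshold(plane)
  ct0 <- trace_plane(plane, seed, seed$z, cfg)
  if (is.null(ct0))
    return(list(rejected = TRUE, reason = "trace-failure"))
  q <- laminar_quality(plane, ct0, cfg$delta_r)
  ct0$quality <- q$Q
  if (is.na(q$Q) || q$Q < cfg$q_min)
    return(list(rejected = TRUE, reason = "quality"))
  up <- propagate(stack, ct0, +1L, cfg, bg_thresh)
  dn <- propagate(stack, ct0, -1L, cfg, bg_thresh)
  contours <- c(rev(dn$contours), list(ct0), up$contours)
  if (length(contours) < cfg$z_min)
    return(list(rejected = TRUE, reason = "too-few-planes"))
  if (length(contours) > cfg$z_max)
    return(list(rejected = TRUE, reason = "z-extent"))
  sh <- stack_shape(stack)
  new_nucleus_surface(id, contours, seed,
                      term_down = dn$reason, term_up = up$reason,
                      touches_wall = surface_touches_wall(
                        contours, sh[1], sh[2], cfg$mask_halfwidth))
}

#' Rasterise accepted surfaces to a label mask
#'
#' Scanline polygon fill per plane; overlap voxels go to the
#' earlier-segmented (higher-priority) nucleus and are counted as
#' conflicts.
#'
#' @param surfaces list of `nucleus_surface` (in priority order).
#' @param shape stack shape `c(nx, ny, nz)`.
#' @param voxel_size physical voxel size.
#' @return list `mask` (a `label_mask` with contiguous labels following
#'   the order of `surfaces`), `conflict_voxels` (count).
#' @export
rasterize_surfaces <- function(surfaces, shape, voxel_size) {
  a <- array(0L, dim = shape)
  conflicts <- 0L
  for (i in seq_along(surfaces)) {
    s <- surfaces[[i]]
    for (ct in s$contours) {
      pix <- contour_fill_pixels(ct, shape[1], shape[2])
      if (!nrow(pix)) next
      lin <- pix[, 1] + (pix[, 2] - 1L) * shape[1] +
        (ct$z - 1L) * shape[1] * shape[2]
      free <- a[lin] == 0L
      conflicts <- conflicts + sum(!free)
      a[lin[free]] <- i
    }
  }
  list(mask = as_label_mask(a, voxel_size), conflict_voxels = conflicts)
}

#' Consume the seed queue
#'
#' Pops the highest-weight seed, segments a nucleus from it, and on
#' acceptance eliminates every remaining seed whose (x, y) lies inside
#' the accepted contour at that seed's z-plane; repeats until the queue
#' is empty. Accepted surfaces are rasterised into a label mask.
#'
#' @param stack an `image_stack`.
#' @param queue seed data frame from [build_seed_queue()] (weight
#'   descending).
#' @param cfg an [nt_config()].
#' @return list `surfaces`, `rejections` (data frame: x, y, z, weight,
#'   reason), `mask`, `conflict_voxels`.
#' @export
consume_seeds <- function(stack, queue, cfg) {
  surfaces <- list()
  rej <- list()
  bg_thresh <- NULL
  sh <- stack_shape(stack)
  while (nrow(queue) > 0) {
    seed <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    if (is.null(bg_thresh))
      bg_thresh <- background_threshold(get_plane(stack, seed$z))
    res <- segment_one(stack, seed, cfg, bg_thresh,
                       id = length(surfaces) + 1L)
    if (inherits(res, "nucleus_surface")) {
      surfaces[[length(surfaces) + 1]] <- res
      if (nrow(queue) > 0) {
        zs <- vapply(res$contours, `[[`, numeric(1), "z")
        drop <- logical(nrow(queue))
        for (j in seq_len(nrow(queue))) {
          zi <- match(queue$z[j], zs)
          if (!is.na(zi))
            drop[j] <- point_in_contour(res$contours[[zi]], queue$x[j],
                                        queue$y[j])
        }
        queue <- queue[!drop, , drop = FALSE]
      }
    } else {
      rej[[length(rej) + 1]] <- data.frame(x = seed$x, y = seed$y,
                                           z = seed$z,
                                           weight = seed$weight,
                                           reason = res$reason)
    }
  }
  ras <- rasterize_surfaces(surfaces, sh, stack$voxel_size)
  list(surfaces = surfaces,
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    weight = numeric(0), reason = character(0)),
       mask = ras$mask, conflict_voxels = ras$conflict_voxels)
}

#' Discard nuclei cropped by the stack walls
#'
#' Removes surfaces any of whose contour vertices touch an x/y border
#' pixel, or whose propagation hit the first or last plane of the
#' stack ("z-limit" at the stack boundary). Cropped nuclei are kept in
#' a side list; only fully contained nuclei are suitable for
#' morphometry.
#'
#' @param result output of [consume_seeds()].
#' @param shape stack shape.
#' @param voxel_size physical voxel size.
#' @return list `surfaces` (kept), `cropped`, `mask` (rebuilt from the
#'   kept surfaces), `rejections`, `conflict_voxels`.
#' @export
discard_cropped <- function(result, shape, voxel_size) {
  keep <- list(); cropped <- list()
  for (s in result$surfaces) {
    z_at_wall <- (s$term_down == "z-limit" && s$z_range[1] <= 1) ||
      (s$term_up == "z-limit" && s$z_range[2] >= shape[3])
    if (s$touches_wall || z_at_wall) cropped[[length(cropped) + 1]] <- s
    else keep[[length(keep) + 1]] <- s
  }
  for (i in seq_along(keep)) keep[[i]]$id <- i
  ras <- rasterize_surfaces(keep, shape, voxel_size)
  list(surfaces = keep, cropped = cropped, mask = ras$mask,
       rejections = result$rejections,
       conflict_voxels = ras$conflict_voxels)
}

#' Segment a whole stack
#'
#' Full pipeline: per-plane seed detection and screening, priority-
#' ordered boundary tracing with bidirectional z-propagation, seed
#' elimination, rasterisation, and removal of wall-cropped nuclei.
#' Deterministic: no randomness anywhere in segmentation.
#'
#' @param stack an `image_stack`.
#' @param cfg an [nt_config()].
#' @return As [discard_cropped()], plus `queue` (the initial seed
#'   queue).
#' @export
segment_stack <- function(stack, cfg) {
  queue <- build_seed_queue(stack, cfg)
  res <- consume_seeds(stack, queue, cfg)
  out <- discard_cropped(res, stack_shape(stack), stack$voxel_size)
  out$queue <- queue
  out
}

#' Per-nucleus summary table
#' @param result output of [segment_stack()] or [discard_cropped()].
#' @return data frame: id, planes, z range, voxel count, termination
#'   reasons, wall flag.
#' @export
surface_summary <- function(result) {
  vox <- tabulate(result$mask$labels[result$mask$labels > 0],
                  nbins = max(1, length(result$surfaces)))
  do.call(rbind, lapply(result$surfaces, function(s)
    data.frame(id = s$id, planes = length(s$contours),
               z_lo = s$z_range[1], z_hi = s$z_range[2],
               voxels = vox[s$id],
               term_down = s$term_down, term_up = s$term_up,
               touches_wall = s$touches_wall)))
}
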