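#' Boundary tracing on a single plane
#'
#' A nucleus boundary on one z-plane is traced by casting equally
#' spaced radial rays from an origin inside the nucleus, locating on
#' every ray the strongest bright-to-dark edge by convolving the
#' intensity profile with an antisymmetric edge mask, removing outlier
#' boundary points by chain clustering (maximal intracluster
#' deviation), and re-tracing the remaining rays under a neighbour
#' continuity constraint until the contour closes. No absolute
#' intensity threshold is used anywhere: the tracer responds only to
#' intensity differences, making it invariant to global intensity
#' scaling.
#'
#' @name contour_tracing
NULL

#' Cast radial rays with bilinear sampling
#'
#' Angles are `2*pi*k/n_rays`, k = 0..n_rays-1; each profile is sampled
#' at unit-pixel steps from the origin by bilinear interpolation and
#' clipped at the plane border (clipping flagged).
#'
#' @param plane numeric matrix.
#' @param origin numeric `c(x, y)` inside the plane.
#' @param n_rays number of rays (>= 8).
#' @param r_max maximal ray length (px).
#' @return list of rays; each has `angle`, `samples` (length
#'   `floor(r_max) + 1`, `NA` beyond the border), `clipped`.
#' @export
cast_rays <- function(plane, origin, n_rays, r_max) {
  nx <- nrow(plane); ny <- ncol(plane)
  if (origin[1] < 1 || origin[1] > nx || origin[2] < 1 || origin[2] > ny)
    stop("ray origin lies outside the plane")
  if (n_rays < 8) stop("n_rays must be >= 8")
  rr <- 0:floor(r_max)
  lapply(seq_len(n_rays) - 1L, function(k) {
    ang <- 2 * pi * k / n_rays
    px <- origin[1] + rr * cos(ang)
    py <- origin[2] + rr * sin(ang)
    ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
    s <- rep(NA_real_, length(rr))
    s[ok] <- bilinear_sample(plane, px[ok], py[ok])
    list(angle = ang, samples = s, clipped = !all(ok))
  })
}

bilinear_sample <- function(plane, px, py) {
  nx <- nrow(plane); ny <- ncol(plane)
  x0 <- pmin(pmax(floor(px), 1L), nx - 1L)
  y0 <- pmin(pmax(floor(py), 1L), ny - 1L)
  fx <- px - x0; fy <- py - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  plane[i00] * (1 - fx) * (1 - fy) + plane[i10] * fx * (1 - fy) +
    plane[i01] * (1 - fx) * fy + plane[i11] * fx * fy
}

#' Antisymmetric box-derivative edge mask
#'
#' `M(u) = +1` for `u < 0`, `-1` for `u > 0`, `M(0) = 0`, for
#' `u in [-h, h]`. The sign is chosen so that a bright-inside to
#' dark-outside step yields a positive convolution response; the zero
#' sum guarantees zero response on constant profiles.
#'
#' @param h half-width (px, >= 1).
#' @return list `h`, `values` (length `2h + 1`).
#' @export
edge_mask <- function(h) {
  u <- -h:h
  list(h = as.integer(h), values = -sign(u))
}

#' Edge response along one ray
#'
#' Discrete convolution `F(r0) = sum_u I(r0 + u) M(u)` over
#' `u in [-h, h]`, maximised over an integer search window
#' `[r_lo, r_hi]` (ties broken toward the smallest radius). An edge is
#' only accepted when its response exceeds a confidence floor of
#' `kappa` times the median absolute response over the full valid
#' radius range of the profile -- this rejects the degenerate constant
#' profile (response identically zero) and spurious maxima in pure
#' noise, while leaving clean steps untouched.
#'
#' @param samples numeric profile (unit steps, index 1 = r 0); `NA`
#'   beyond the border.
#' @param mask an [edge_mask()].
#' @param window numeric `c(r_lo, r_hi)` in px.
#' @param kappa confidence floor multiplier.
#' @return list `r0` (px, `NA` if no edge), `F` (response at `r0`),
#'   `found`.
#' @export
edge_response <- function(samples, mask, window, kappa = 3) {
  h <- mask$h
  n <- length(samples)
  valid_hi <- n - 1L - h  # radii r with r +- h sampled
  if (valid_hi < h) return(list(r0 = NA_real_, F = NA_real_, found = FALSE))
  rs <- h:valid_hi
  Fall <- vapply(rs, function(r0) {
    seg <- samples[(r0 - h):(r0 + h) + 1L]
    if (anyNA(seg)) return(NA_real_)
    sum(seg * mask$values)
  }, numeric(1))
  floor_med <- stats::median(abs(Fall), na.rm = TRUE)
  if (!is.finite(floor_med)) floor_med <- 0
  r_lo <- max(ceiling(window[1]), h)
  r_hi <- min(floor(window[2]), valid_hi)
  if (r_hi < r_lo) return(list(r0 = NA_real_, F = NA_real_, found = FALSE))
  sel <- rs >= r_lo & rs <= r_hi
  Fw <- Fall[sel]; rw <- rs[sel]
  if (all(is.na(Fw))) return(list(r0 = NA_real_, F = NA_real_,
                                  found = FALSE))
  imax <- which(Fw == max(Fw, na.rm = TRUE))[1]
  Fstar <- Fw[imax]
  found <- is.finite(Fstar) && Fstar > 0 && Fstar > kappa * floor_med
  list(r0 = if (found) rw[imax] else NA_real_,
       F = Fstar, found = found)
}

#' Chain-cluster candidate boundary points
#'
#' Walks the per-ray boundary points in cyclic angular order: a point
#' whose Euclidean distance to its predecessor is at most `max_dev`
#' joins the predecessor's cluster, otherwise a new cluster starts.
#' The first and last clusters are merged when the cyclic junction
#' distance is within `max_dev`. Singleton clusters are loose points
#' and are marked removed.
#'
#' @param pts data frame with `ray` (0-based ray index), `x`, `y`,
#'   ordered by ray angle.
#' @param max_dev maximal intracluster deviation (px).
#' @return `pts` with added `cluster` (`NA` for removed points) and
#'   `removed`.
#' @export
cluster_boundary_points <- function(pts, max_dev) {
  n <- nrow(pts)
  if (n == 0) return(cbind(pts, cluster = integer(0), removed = logical(0)))
  cl <- integer(n); cl[1] <- 1L
  if (n > 1) for (i in 2:n) {
    d <- sqrt((pts$x[i] - pts$x[i - 1])^2 + (pts$y[i] - pts$y[i - 1])^2)
    cl[i] <- if (d <= max_dev) cl[i - 1] else cl[i - 1] + 1L
  }
  if (n > 1 && cl[n] != cl[1]) {
    d <- sqrt((pts$x[1] - pts$x[n])^2 + (pts$y[1] - pts$y[n])^2)
    if (d <= max_dev) cl[cl == cl[n]] <- cl[1]
  }
  sizes <- table(cl)
  removed <- sizes[as.character(cl)] < 2
  cl[removed] <- NA_integer_
  ids <- unique(stats::na.omit(cl))
  cl <- match(cl, ids)
  pts$cluster <- cl
  pts$removed <- unname(as.logical(removed))
  pts
}

#' A traced closed contour
#'
#' Star-shaped about its origin by construction: one radial distance
#' per equally spaced angle.
#'
#' @param z plane index.
#' @param origin numeric `c(x, y)`.
#' @param rho radial distances, one per angle `2*pi*k/n`.
#' @param interpolated logical per ray: radius filled by interpolation.
#' @return A `contour2d` with derived polygon area (shoelace).
#' @export
new_contour2d <- function(z, origin, rho, interpolated = rep(FALSE,
                                                             length(rho))) {
  n <- length(rho)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  vx <- origin[1] + rho * cos(ang)
  vy <- origin[2] + rho * sin(ang)
  area <- abs(sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)) / 2
  structure(list(z = z, origin = origin, rho = rho, angles = ang,
                 interpolated = interpolated, area = area,
                 quality = NA_real_),
            class = "contour2d")
}

#' Vertices of a contour polygon
#' @param ct a `contour2d`.
#' @return Two-column matrix of (x, y) vertices in pixel coordinates.
#' @export
contour_vertices <- function(ct)
  cbind(ct$origin[1] + ct$rho * cos(ct$angles),
        ct$origin[2] + ct$rho * sin(ct$angles))

#' Centroid (mass centre) of a contour polygon
#' @param ct a `contour2d`.
#' @return numeric `c(x, y)` (shoelace centroid).
#' @export
contour_centroid <- function(ct) {
  v <- contour_vertices(ct)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# per-angle radius of an existing polygon about a new origin
# (polygon assumed star-shaped about that origin)
polygon_radii_about <- function(ct, origin, n_rays) {
  v <- contour_vertices(ct)
  dx <- v[, 1] - origin[1]; dy <- v[, 2] - origin[2]
  a <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  o <- order(a)
  a <- a[o]; r <- r[o]
  a_ext <- c(a[length(a)] - 2 * pi, a, a[1] + 2 * pi)
  r_ext <- c(r[length(r)], r, r[1])
  target <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  stats::approx(a_ext, r_ext, xout = target, rule = 2)$y
}

interpolate_gaps <- function(rho, found) {
  n <- length(rho)
  if (all(found)) return(rho)
  if (!any(found)) return(rho)
  idx_ok <- which(found)
  for (i in which(!found)) {
    # cyclic linear interpolation between nearest accepted neighbours
    dl <- (i - idx_ok) %% n
    dr <- (idx_ok - i) %% n
    l <- idx_ok[which.min(dl)]; r <- idx_ok[which.min(dr)]
    gl <- min(dl); gr <- min(dr)
    rho[i] <- (rho[l] * gr + rho[r] * gl) / (gl + gr)
  }
  rho
}

#' Re-trace a closed contour from the largest cluster
#'
#' Accepts the radii of the largest cluster (ties broken toward the
#' cluster containing the highest-confidence point), then walks
#' cyclically ray by ray away from it; each subsequent ray's radius is
#' re-searched within `+- max_dev` of its neighbour's accepted radius.
#' Rays with no edge in their restricted window are filled afterwards
#' by cyclic linear interpolation of the radius and flagged; more than
#' 25 percent interpolated rays is a tracing failure.
#'
#' @param rays output of [cast_rays()].
#' @param pts clustered boundary points ([cluster_boundary_points()]),
#'   with `F` the per-point confidence.
#' @param origin,z contour origin and plane index.
#' @param mask an [edge_mask()].
#' @param cfg an [nt_config()].
#' @return A `contour2d`, or `NULL` on tracing failure.
#' @export
retrace_closed_contour <- function(rays, pts, origin, z, mask, cfg) {
  n <- length(rays)
  kept <- pts[!pts$removed, , drop = FALSE]
  if (nrow(kept) < 3) return(NULL)
  sizes <- tapply(seq_len(nrow(kept)), kept$cluster, length)
  mx <- max(sizes)
  best_cl <- as.integer(names(sizes)[sizes == mx])
  if (length(best_cl) > 1) {
    conf <- vapply(best_cl, function(ci)
      max(kept$F[kept$cluster == ci]), numeric(1))
    best_cl <- best_cl[which.max(conf)]
  }
  in_cl <- kept[kept$cluster == best_cl, , drop = FALSE]
  rho <- rep(NA_real_, n)
  found <- rep(FALSE, n)
  rho[in_cl$ray + 1L] <- in_cl$r0
  found[in_cl$ray + 1L] <- TRUE
  # walk from the ray after the cluster, cyclically
  cl_rays <- sort(in_cl$ray)
  start <- (cl_rays[length(cl_rays)] + 1L) %% n
  prev <- rho[cl_rays[length(cl_rays)] + 1L]
  ord <- (start + 0:(n - 1)) %% n
  ord <- ord[!found[ord + 1L]]
  for (k in ord) {
    er <- edge_response(rays[[k + 1L]]$samples, mask,
                        c(prev - cfg$max_dev, prev + cfg$max_dev),
                        cfg$kappa_edge)
    if (er$found) {
      rho[k + 1L] <- er$r0
      found[k + 1L] <- TRUE
      prev <- er$r0
    }
    # on a miss the neighbour radius is carried forward as the window
    # centre for the next ray; the missing radius itself is filled later
  }
  if (sum(!found) > 0.25 * n) return(NULL)
  rho <- interpolate_gaps(rho, found)
  if (anyNA(rho)) return(NULL)
  new_contour2d(z, origin, rho, interpolated = !found)
}

trace_pass <- function(plane, origin, z, windows, mask, cfg, cluster = TRUE) {
  rays <- cast_rays(plane, origin, cfg$n_rays, cfg$r_max)
  n <- length(rays)
  res <- lapply(seq_len(n), function(i)
    edge_response(rays[[i]]$samples, mask, windows[[i]], cfg$kappa_edge))
  found <- vapply(res, `[[`, logical(1), "found")
  if (!cluster) {
    rho <- vapply(res, function(r) if (r$found) r$r0 else NA_real_,
                  numeric(1))
    if (sum(!found) > 0.25 * n || sum(found) < 3) return(NULL)
    rho <- interpolate_gaps(rho, found)
    return(new_contour2d(z, origin, rho, interpolated = !found))
  }
  if (sum(found) < 3) return(NULL)
  idx <- which(found)
  pts <- data.frame(ray = idx - 1L,
                    r0 = vapply(res[idx], `[[`, numeric(1), "r0"),
                    F = vapply(res[idx], `[[`, numeric(1), "F"))
  ang <- 2 * pi * pts$ray / n
  pts$x <- origin[1] + pts$r0 * cos(ang)
  pts$y <- origin[2] + pts$r0 * sin(ang)
  pts <- cluster_boundary_points(pts, cfg$max_dev)
  retrace_closed_contour(rays, pts, origin, z, mask, cfg)
}

#' Trace one plane, seeded or contour-initialised
#'
#' Seed mode (`init` has `x`, `y`): two tracing iterations from the
#' seed -- the first with the full radial window roughly localises the
#' boundary, the second is restricted to `+- delta_pass` around the
#' first pass's radii; both iterations cluster their boundary points
#' and re-trace from the largest cluster.
#'
#' Contour mode (`init` is a `contour2d` from the neighbouring plane):
#' a single pass from the prior contour's own centroid, each ray
#' restricted to the tubular neighbourhood `prior radius +- delta_tube`
#' -- the continuity constraint that keeps the trace from leaking into
#' an adjacent nucleus or collapsing onto an internal inhomogeneity.
#'
#' @param plane numeric matrix.
#' @param init a seed (list with `x`, `y`) or a `contour2d`.
#' @param z plane index of `plane`.
#' @param cfg an [nt_config()].
#' @return A `contour2d`, or `NULL` on tracing failure.
#' @export
trace_plane <- function(plane, init, z, cfg) {
  mask <- edge_mask(cfg$mask_halfwidth)
  h <- cfg$mask_halfwidth
  full <- list(c(h, cfg$r_max - h))
  if (inherits(init, "contour2d")) {
    origin <- contour_centroid(init)
    nx <- nrow(plane); ny <- ncol(plane)
    if (origin[1] < 1 || origin[1] > nx || origin[2] < 1 ||
        origin[2] > ny) return(NULL)
    prior <- polygon_radii_about(init, origin, cfg$n_rays)
    windows <- lapply(prior, function(p)
      c(max(h, p - cfg$delta_tube), p + cfg$delta_tube))
    return(trace_pass(plane, origin, z, windows, mask, cfg,
                      cluster = FALSE))
  }
  origin <- c(init$x, init$y)
  w1 <- rep(full, cfg$n_rays)
  c1 <- trace_pass(plane, origin, z, w1, mask, cfg, cluster = TRUE)
  if (is.null(c1)) return(NULL)
  w2 <- lapply(c1$rho, function(p)
    c(max(h, p - cfg$delta_pass), p + cfg$delta_pass))
  c2 <- trace_pass(plane, origin, z, w2, mask, cfg, cluster = TRUE)
  if (is.null(c2)) return(c1)
  c2
}
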