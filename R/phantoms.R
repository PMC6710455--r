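#' Synthetic ellipsoid phantoms
#'
#' Phantom stacks emulate confocal volumes of fluorescently stained
#' nuclei: ellipsoidal interiors of known centre, semi-axes and
#' orientation, optional bright chromocenter blobs, per-channel internal
#' spheres standing in for FISH-labelled alleles, separable Gaussian
#' blur (the axial optical resolution of a confocal stack is ~3x worse
#' than lateral), additive Gaussian noise, and optional small bright
#' background particles mimicking unspecific stain binding. Every
#' quantity of interest (volume, surface area, internal-sphere geometry)
#' is known analytically, which is what makes phantoms usable as ground
#' truth for segmentation and morphometry.
#'
#' @name phantoms
NULL

euler_rotation <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), sin(g), 0, -sin(g), cos(g)), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Specify one ellipsoidal nucleus
#'
#' @param center centre `c(x, y, z)` in micrometres (stack coordinates).
#' @param semiaxes semi-axes `c(a, b, c)` in micrometres, all positive.
#' @param angles intrinsic Euler angles (z-y-x, radians) rotating the
#'   ellipsoid frame into stack coordinates.
#' @param intensity interior base intensity (arbitrary units).
#' @param chromocenters `NULL`, or `list(count=, radius=, gain=)`:
#'   that many bright blobs of the given radius (um) and additive
#'   intensity gain placed at random inside the ellipsoid.
#' @param spheres list of internal spheres, each
#'   `list(channel=, offset=c(x,y,z) um relative to center, radius= um,
#'   intensity=)`. Each sphere must lie strictly inside the ellipsoid
#'   (checked analytically).
#' @return An `ellipsoid_spec`.
#' @export
ellipsoid_spec <- function(center, semiaxes, angles = c(0, 0, 0),
                           intensity = 150, chromocenters = NULL,
                           spheres = list()) {
  stopifnot(length(center) == 3, length(semiaxes) == 3,
            length(angles) == 3)
  if (any(semiaxes <= 0)) stop("semi-axes must be positive")
  spec <- structure(list(center = as.numeric(center),
                         semiaxes = as.numeric(semiaxes),
                         angles = as.numeric(angles),
                         intensity = intensity,
                         chromocenters = chromocenters,
                         spheres = spheres),
                    class = "ellipsoid_spec")
  for (sp in spheres) {
    d <- ellipsoid_interior_clearance(spec, spec$center + sp$offset)
    if (d <= sp$radius)
      stop("internal sphere (channel ", sp$channel,
           ") does not lie strictly inside the ellipsoid: clearance ",
           format(d), " um <= radius ", format(sp$radius), " um")
  }
  spec
}

# distance from an interior point to the ellipsoid surface (um);
# numeric minimisation over the surface parametrisation, multi-start
ellipsoid_point_surface_distance <- function(spec, p_world) {
  R <- euler_rotation(spec$angles)
  p <- drop(t(R) %*% (p_world - spec$center))
  ax <- spec$semiaxes
  f <- function(par) {
    th <- par[1]; ph <- par[2]
    q <- c(ax[1] * sin(th) * cos(ph), ax[2] * sin(th) * sin(ph),
           ax[3] * cos(th))
    sqrt(sum((q - p)^2))
  }
  starts <- as.matrix(expand.grid(th = seq(0.2, pi - 0.2, length.out = 5),
                                  ph = seq(0, 2 * pi, length.out = 7)[-7]))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], f, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
    if (r$value < best) best <- r$value
  }
  best
}

ellipsoid_interior_clearance <- function(spec, p_world) {
  # clearance only meaningful for interior points; return -distance outside
  R <- euler_rotation(spec$angles)
  q <- drop(t(R) %*% (p_world - spec$center)) / spec$semiaxes
  d <- ellipsoid_point_surface_distance(spec, p_world)
  if (sum(q^2) > 1) -d else d
}

#' Specify a whole phantom stack
#'
#' @param ellipsoids list of [ellipsoid_spec()] objects; they may touch
#'   or overlap.
#' @param shape stack shape `c(nx, ny, nz)` in voxels.
#' @param voxel_size `c(dx, dy, dz)` in micrometres.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#'   Required: validation phantoms must state their noise level
#'   explicitly.
#' @param background background intensity level.
#' @param blur_sigma_xy,blur_sigma_z separable Gaussian blur sds, in px
#'   (lateral) and planes (axial); defaults 1.5 px / 1.0 plane
#'   approximate the ~3x worse axial optical resolution at 80/200 nm
#'   sampling. Set to 0 to disable.
#' @param particle_density background particle density (count per um^3;
#'   default 0 for clean stacks): small bright disks of 1-3 px radius.
#' @param particle_intensity intensity range `c(lo, hi)` of particles.
#' @param bits output bit depth (8 or 16).
#' @param seed RNG seed; identical spec + seed give bit-identical voxels.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(ellipsoids, shape, voxel_size, noise_sigma,
                         background = 10, blur_sigma_xy = 1.5,
                         blur_sigma_z = 1.0, particle_density = 0,
                         particle_intensity = c(100, 200), bits = 8L,
                         seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1), length(voxel_size) == 3,
            all(voxel_size > 0), noise_sigma >= 0, bits %in% c(8L, 16L))
  structure(list(ellipsoids = ellipsoids, shape = as.integer(shape),
                 voxel_size = as.numeric(voxel_size),
                 noise_sigma = noise_sigma, background = background,
                 blur_sigma_xy = blur_sigma_xy, blur_sigma_z = blur_sigma_z,
                 particle_density = particle_density,
                 particle_intensity = particle_intensity,
                 bits = as.integer(bits), seed = as.integer(seed)),
            class = "phantom_spec")
}

# reflect-boundary 1D Gaussian convolution matrix (n x n)
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1) return(diag(n))
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-h, h)
    # reflect about the edges (half-sample convention: 0 -> 1, n+1 -> n)
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + k[j]
  }
  K
}

blur_volume <- function(a, sigma_xy, sigma_z) {
  d <- dim(a)
  if (sigma_xy > 0) {
    Kx <- gauss_conv_matrix(d[1], sigma_xy)
    Ky <- gauss_conv_matrix(d[2], sigma_xy)
    for (z in seq_len(d[3])) a[, , z] <- Kx %*% a[, , z] %*% t(Ky)
  }
  if (sigma_z > 0 && d[3] > 1) {
    Kz <- gauss_conv_matrix(d[3], sigma_z)
    m <- matrix(a, nrow = d[1] * d[2], ncol = d[3])
    a <- array(m %*% t(Kz), dim = d)
  }
  a
}

#' Generate a phantom stack with ground truth
#'
#' Voxel intensity is background + the maximum over all components
#' (ellipsoid interiors, chromocenters, spheres) covering the voxel --
#' a max combination reproduces the "no clear border" phenotype of
#' touching nuclei instead of a bright seam -- then blurred, then
#' Gaussian noise is added, then values are clipped and rounded to the
#' output bit depth. Ground-truth labels assign each voxel to the
#' covering ellipsoid with the smallest normalised distance
#' ((x-x0)' A (x-x0)); voxels inside two or more ellipsoids are recorded
#' in the ambiguity mask.
#'
#' @param spec a [phantom_spec()].
#' @return A list:
#'   \describe{
#'     \item{channels}{named list of `image_stack`s; `"dna"` is the
#'       nuclear stain, additional `"ch<k>"` entries hold the internal
#'       sphere channels.}
#'     \item{truth}{list with `mask` (a `label_mask`), `ambiguity`
#'       (logical array), `nuclei` (data frame: id, analytic volume um^3
#'       and surface area um^2, centre, semi-axes), `spheres` (data
#'       frame: nucleus, channel, centre um, radius um).}
#'   }
#' @export
generate_phantom <- function(spec) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  sh <- spec$shape; vs <- spec$voxel_size
  xs <- (seq_len(sh[1]) - 0.5) * vs[1]
  ys <- (seq_len(sh[2]) - 0.5) * vs[2]
  zs <- (seq_len(sh[3]) - 0.5) * vs[3]

  dna <- array(0, dim = sh)
  labels <- array(0L, dim = sh)
  best_nd <- array(Inf, dim = sh)
  ncover <- array(0L, dim = sh)
  ch_ids <- sort(unique(unlist(lapply(spec$ellipsoids, function(e)
    vapply(e$spheres, function(s) s$channel, 0)))))
  ch_arrays <- lapply(ch_ids, function(i) array(0, dim = sh))
  names(ch_arrays) <- as.character(ch_ids)

  sph_rows <- list()
  for (k in seq_along(spec$ellipsoids)) {
    e <- spec$ellipsoids[[k]]
    R <- euler_rotation(e$angles)
    rmax <- max(e$semiaxes)
    ix <- which(xs >= e$center[1] - rmax & xs <= e$center[1] + rmax)
    iy <- which(ys >= e$center[2] - rmax & ys <= e$center[2] + rmax)
    iz <- which(zs >= e$center[3] - rmax & zs <= e$center[3] + rmax)
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(x = xs[ix], y = ys[iy], z = zs[iz])
    rel <- t(t(as.matrix(g)) - e$center) %*% R  # = R^T (p - c) rowwise
    q <- sweep(rel, 2, e$semiaxes, "/")
    nd <- rowSums(q^2)
    inside <- nd <= 1
    if (!any(inside)) next
    gi <- as.matrix(expand.grid(x = ix, y = iy, z = iz))[inside, , drop = FALSE]
    lin <- gi[, 1] + (gi[, 2] - 1L) * sh[1] + (gi[, 3] - 1L) * sh[1] * sh[2]
    dna[lin] <- pmax(dna[lin], e$intensity)
    ncover[lin] <- ncover[lin] + 1L
    better <- nd[inside] < best_nd[lin]
    labels[lin[better]] <- k
    best_nd[lin[better]] <- nd[inside][better]

    if (!is.null(e$chromocenters)) {
      cc <- e$chromocenters
      placed <- 0
      while (placed < cc$count) {
        u <- stats::runif(3, -1, 1)
        if (sum(u^2) > 1) next
        ctr <- e$center + drop(R %*% (u * e$semiaxes * 0.8))
        placed <- placed + 1
        dd <- outer(outer((xs[ix] - ctr[1])^2, (ys[iy] - ctr[2])^2, "+"),
                    (zs[iz] - ctr[3])^2, "+")
        inblob <- which(dd <= cc$radius^2)
        if (length(inblob)) {
          gib <- as.matrix(expand.grid(x = ix, y = iy, z = iz))[inblob, ,
                                                                drop = FALSE]
          linb <- gib[, 1] + (gib[, 2] - 1L) * sh[1] +
            (gib[, 3] - 1L) * sh[1] * sh[2]
          keep <- labels[linb] == k
          dna[linb[keep]] <- pmax(dna[linb[keep]],
                                  e$intensity + cc$gain)
        }
      }
    }
    for (sp in e$spheres) {
      ctr <- e$center + sp$offset
      arr <- ch_arrays[[as.character(sp$channel)]]
      jx <- which(xs >= ctr[1] - sp$radius & xs <= ctr[1] + sp$radius)
      jy <- which(ys >= ctr[2] - sp$radius & ys <= ctr[2] + sp$radius)
      jz <- which(zs >= ctr[3] - sp$radius & zs <= ctr[3] + sp$radius)
      if (length(jx) && length(jy) && length(jz)) {
        dd <- outer(outer((xs[jx] - ctr[1])^2, (ys[jy] - ctr[2])^2, "+"),
                    (zs[jz] - ctr[3])^2, "+")
        insph <- which(dd <= sp$radius^2)
        gis <- as.matrix(expand.grid(x = jx, y = jy, z = jz))[insph, ,
                                                              drop = FALSE]
        lins <- gis[, 1] + (gis[, 2] - 1L) * sh[1] +
          (gis[, 3] - 1L) * sh[1] * sh[2]
        arr[lins] <- pmax(arr[lins], sp$intensity)
        ch_arrays[[as.character(sp$channel)]] <- arr
      }
      sph_rows[[length(sph_rows) + 1]] <-
        data.frame(nucleus = k, channel = sp$channel, cx = ctr[1],
                   cy = ctr[2], cz = ctr[3], radius = sp$radius)
    }
  }

  finish <- function(a) {
    a <- a + spec$background
    if (spec$particle_density > 0) {
      vol <- prod(sh) * prod(vs)
      np <- stats::rpois(1, spec$particle_density * vol)
      for (i in seq_len(np)) {
        px <- sample.int(sh[1], 1); py <- sample.int(sh[2], 1)
        pz <- sample.int(sh[3], 1)
        pr <- stats::runif(1, 1, 3)
        pint <- stats::runif(1, spec$particle_intensity[1],
                             spec$particle_intensity[2])
        wx <- max(1, px - 3):min(sh[1], px + 3)
        wy <- max(1, py - 3):min(sh[2], py + 3)
        dd <- outer((wx - px)^2, (wy - py)^2, "+")
        sel <- dd <= pr^2
        a[wx, wy, pz][sel] <- pmax(a[wx, wy, pz][sel], pint)
      }
    }
    a <- blur_volume(a, spec$blur_sigma_xy, spec$blur_sigma_z)
    if (spec$noise_sigma > 0)
      a <- a + stats::rnorm(length(a), 0, spec$noise_sigma)
    a <- round(pmin(pmax(a, 0), 2^spec$bits - 1))
    as_image_stack(a, voxel_size = vs, bits = spec$bits)
  }

  extra <- lapply(ch_arrays, finish)
  names(extra) <- if (length(extra)) paste0("ch", ch_ids) else character(0)
  channels <- c(list(dna = finish(dna)), extra)

  nuc <- do.call(rbind, lapply(seq_along(spec$ellipsoids), function(k) {
    e <- spec$ellipsoids[[k]]
    am <- analytic_morphometry(e)
    data.frame(id = k, volume_um3 = am$volume_um3, area_um2 = am$area_um2,
               cx = e$center[1], cy = e$center[2], cz = e$center[3],
               a = e$semiaxes[1], b = e$semiaxes[2], c = e$semiaxes[3])
  }))
  truth <- list(mask = as_label_mask(labels, vs),
                ambiguity = ncover >= 2L,
                nuclei = nuc,
                spheres = if (length(sph_rows)) do.call(rbind, sph_rows)
                          else NULL)
  list(channels = channels, truth = truth)
}

#' A reproducible field of ellipsoidal nuclei
#'
#' Convenience builder for validation phantoms: `n` ellipsoids with
#' semi-axes drawn uniformly from `semiaxis_range`, randomly oriented,
#' placed on a jittered grid that keeps every nucleus fully inside the
#' stack (so none is cropped by the walls), at a packing where
#' neighbours may approach to within a micrometre of each other.
#' The default geometry -- a 256 x 256 x 60 stack at 0.25 x 0.25 x 0.5
#' um voxels (64 x 64 x 30 um), nuclei of 4-6 um semi-axes, additive
#' Gaussian noise of 10 percent of the interior intensity -- emulates a
#' moderately downsampled confocal stack of a densely populated
#' granule-cell field.
#'
#' @param n number of nuclei (default 8; placed on a 4 x 2 grid, more
#'   nuclei extend the grid).
#' @param shape,voxel_size stack geometry.
#' @param intensity interior intensity.
#' @param semiaxis_range range (um) for the uniform semi-axis draw.
#' @param noise_frac noise sd as a fraction of `intensity`.
#' @param with_spheres give every nucleus two channel-2 internal
#'   spheres (radius 0.5 um at +-1.5 um along a random direction).
#' @param seed RNG seed (drives placement, orientation and noise).
#' @return A [phantom_spec()].
#' @export
phantom_field_spec <- function(n = 8, shape = c(256, 256, 60),
                               voxel_size = c(0.25, 0.25, 0.5),
                               intensity = 150,
                               semiaxis_range = c(4, 6),
                               noise_frac = 0.1, with_spheres = FALSE,
                               seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  ext <- shape * voxel_size
  ncol_ <- 4; nrow_ <- ceiling(n / ncol_)
  xs <- seq(ext[1] * 0.17, ext[1] * 0.83, length.out = ncol_)
  ys <- seq(ext[2] * 0.3, ext[2] * 0.7, length.out = max(nrow_, 2))
  zl <- c(0.45, 0.55) * ext[3]
  ells <- vector("list", n)
  for (i in seq_len(n)) {
    cx <- xs[(i - 1) %% ncol_ + 1] + stats::runif(1, -1.2, 1.2)
    cy <- ys[(i - 1) %/% ncol_ + 1] + stats::runif(1, -1.2, 1.2)
    cz <- zl[(i - 1) %% 2 + 1] + stats::runif(1, -1, 1)
    ax <- sort(stats::runif(3, semiaxis_range[1], semiaxis_range[2]))
    sph <- if (with_spheres) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      list(list(channel = 2, offset = 1.5 * u, radius = 0.5,
                intensity = 200),
           list(channel = 2, offset = -1.5 * u, radius = 0.5,
                intensity = 200))
    } else list()
    ells[[i]] <- ellipsoid_spec(center = c(cx, cy, cz), semiaxes = ax,
                                angles = stats::runif(3, 0, pi),
                                intensity = intensity, spheres = sph)
  }
  phantom_spec(ells, shape = shape, voxel_size = voxel_size,
               noise_sigma = noise_frac * intensity, seed = seed)
}

#' Analytic morphometry of one ellipsoid spec
#'
#' Volume is exact, (4/3) pi a b c. Surface area uses the Thomsen
#' approximation with p = 1.6075 (relative error below 1.1 percent for
#' any aspect ratio). The envelope distance of each internal sphere is
#' the minimal distance from the sphere surface to the ellipsoid
#' surface, found by numeric minimisation over the surface
#' parametrisation (tolerance well below 1e-6 um); pairwise sphere
#' surface distances are closed-form.
#'
#' @param spec an [ellipsoid_spec()].
#' @return list with `volume_um3`, `area_um2`, `envelope_distances`
#'   (data frame: channel, distance um, centroid distance um) and
#'   `pairwise` (data frame of sphere-surface to sphere-surface
#'   distances, um), the last two `NULL` when there are no spheres.
#' @export
analytic_morphometry <- function(spec) {
  ax <- spec$semiaxes
  volume <- 4 / 3 * pi * prod(ax)
  p <- 1.6075
  area <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                       ax[2]^p * ax[3]^p) / 3)^(1 / p)
  env <- NULL; pw <- NULL
  ns <- length(spec$spheres)
  if (ns > 0) {
    env <- do.call(rbind, lapply(spec$spheres, function(sp) {
      dc <- ellipsoid_point_surface_distance(spec, spec$center + sp$offset)
      data.frame(channel = sp$channel, distance_um = dc - sp$radius,
                 centroid_distance_um = dc)
    }))
    if (ns >= 2) {
      comb <- utils::combn(ns, 2)
      pw <- do.call(rbind, lapply(seq_len(ncol(comb)), function(j) {
        s1 <- spec$spheres[[comb[1, j]]]; s2 <- spec$spheres[[comb[2, j]]]
        cd <- sqrt(sum((s1$offset - s2$offset)^2))
        data.frame(i = comb[1, j], j = comb[2, j],
                   distance_um = max(0, cd - s1$radius - s2$radius))
      }))
    }
  }
  list(volume_um3 = volume, area_um2 = area,
       envelope_distances = env, pairwise = pw)
}
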