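#' Morphometry of reconstructed nuclei
#'
#' Quantifies accepted nuclei and their internal objects in physical
#' units: nucleus volume (contour areas integrated over z), membrane
#' area (triangulated shell), sphericity form factor, Otsu-based
#' extraction of bright internal objects (FISH-labelled alleles) from
#' additional channels, and minimal distances from those objects to the
#' nuclear envelope and to each other. Pixel coordinate `x` maps to the
#' physical voxel-centre coordinate `(x - 0.5) * dx` micrometres.
#'
#' @name morphometry
NULL

px_to_um <- function(xy_px, z_px, voxel_size)
  cbind((xy_px[, 1] - 0.5) * voxel_size[1],
        (xy_px[, 2] - 0.5) * voxel_size[2],
        (z_px - 0.5) * voxel_size[3])

#' Triangulated closed shell of a nucleus surface
#'
#' Adjacent contours share the same angular sampling grid, so they are
#' stitched ring to ring with triangle strips; the two end contours are
#' capped by triangle fans to an apex half a plane spacing beyond the
#' end plane. The mesh is closed (every edge shared by exactly two
#' triangles); vertices are in micrometres.
#'
#' Traced radii are quantised to whole pixels, and the resulting
#' sub-pixel surface roughness systematically inflates the area of a
#' triangulated shell (every facet is slightly tilted against the true
#' surface). By default the radii are therefore de-quantised before
#' stitching with a narrow (1,2,1)/4 moving average, applied twice
#' along the angular direction and once across adjacent planes; the
#' kernel support (~3 samples, well under a pixel of radial effect on
#' nucleus-sized contours) only removes the quantisation jitter and
#' leaves real shape unchanged. Set `smooth = FALSE` to mesh the raw
#' radii.
#'
#' @param surface a `nucleus_surface` with at least 2 planes.
#' @param voxel_size `c(dx, dy, dz)` in micrometres.
#' @param smooth de-quantise radii before stitching (default `TRUE`).
#' @return list `vertices` (n x 3 matrix, um), `triangles` (m x 3
#'   integer matrix of vertex indices), `area_um2`.
#' @export
surface_mesh <- function(surface, voxel_size, smooth = TRUE) {
  K <- length(surface$contours)
  if (K < 2) stop("surface mesh needs at least 2 planes")
  n <- length(surface$contours[[1]]$rho)
  contours <- surface$contours
  if (smooth) {
    ring_avg <- function(r) {
      m <- length(r)
      (2 * r + r[c(m, seq_len(m - 1))] + r[c(seq_len(m - 1) + 1, 1)]) / 4
    }
    R <- vapply(contours, `[[`, numeric(n), "rho")
    R <- apply(apply(R, 2, ring_avg), 2, ring_avg)
    if (K >= 3) {
      Rz <- R
      for (i in 2:(K - 1))
        Rz[, i] <- 0.25 * R[, i - 1] + 0.5 * R[, i] + 0.25 * R[, i + 1]
      R <- Rz
    }
    for (i in seq_len(K))
      contours[[i]] <- new_contour2d(contours[[i]]$z,
                                     contours[[i]]$origin, R[, i])
  }
  rings <- lapply(contours, function(ct) {
    if (ct$area <= 0) stop("degenerate zero-area contour in surface")
    px_to_um(contour_vertices(ct), ct$z, voxel_size)
  })
  verts <- do.call(rbind, rings)
  tri <- list()
  for (k in seq_len(K - 1)) {
    a <- (k - 1) * n + seq_len(n)
    b <- k * n + seq_len(n)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    tri[[length(tri) + 1]] <- cbind(a, b, a2)
    tri[[length(tri) + 1]] <- cbind(a2, b, b2)
  }
  # caps: apex dz/2 beyond the end planes
  c1 <- contour_centroid(contours[[1]])
  cK <- contour_centroid(contours[[K]])
  apex1 <- px_to_um(rbind(c1), contours[[1]]$z - 0.5, voxel_size)
  apexK <- px_to_um(rbind(cK), contours[[K]]$z + 0.5, voxel_size)
  verts <- rbind(verts, apex1, apexK)
  i1 <- nrow(verts) - 1L; iK <- nrow(verts)
  a <- seq_len(n); a2 <- c(a[-1], a[1])
  tri[[length(tri) + 1]] <- cbind(a2, a, rep(i1, n))
  b <- (K - 1) * n + seq_len(n); b2 <- c(b[-1], b[1])
  tri[[length(tri) + 1]] <- cbind(b, b2, rep(iK, n))
  tris <- do.call(rbind, tri)
  v1 <- verts[tris[, 1], , drop = FALSE]
  v2 <- verts[tris[, 2], , drop = FALSE]
  v3 <- verts[tris[, 3], , drop = FALSE]
  cr <- cross3(v2 - v1, v3 - v1)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  list(vertices = verts, triangles = tris, area_um2 = area)
}

cross3 <- function(a, b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])

#' Nucleus morphometry
#'
#' Volume integrates the per-plane contour (shoelace) areas over the
#' plane spacing; membrane area comes from the triangulated shell; the
#' form factor is the sphericity `pi^(1/3) (6 V)^(2/3) / A`,
#' dimensionless, equal to 1 for a sphere and strictly smaller for any
#' other shape.
#'
#' @param surface a `nucleus_surface`.
#' @param voxel_size `c(dx, dy, dz)` in micrometres.
#' @return list `id`, `volume_um3`, `area_um2`, `form_factor`,
#'   `centroid_um`.
#' @export
measure_nucleus <- function(surface, voxel_size) {
  areas_px <- vapply(surface$contours, `[[`, numeric(1), "area")
  vol <- sum(areas_px) * prod(voxel_size)
  mesh <- surface_mesh(surface, voxel_size)
  ff <- pi^(1 / 3) * (6 * vol)^(2 / 3) / mesh$area_um2
  ctrs <- t(vapply(surface$contours, function(ct) {
    c(contour_centroid(ct), ct$z)
  }, numeric(3)))
  w <- areas_px / sum(areas_px)
  cen_px <- colSums(ctrs * w)
  cen <- px_to_um(rbind(cen_px[1:2]), cen_px[3], voxel_size)
  list(id = surface$id, volume_um3 = vol, area_um2 = mesh$area_um2,
       form_factor = ff, centroid_um = drop(cen))
}

otsu_threshold <- function(vals, bits) {
  mx <- 2^bits - 1
  img <- EBImage::Image(matrix(vals / mx, nrow = 1))
  EBImage::otsu(img, range = c(0, 1), levels = 256) * mx
}

label_components_26 <- function(fg_lin, shape) {
  # 26-connected components of foreground voxels via the adjacency graph
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  pos <- arrayInd(fg_lin, shape)
  idx_of <- new.env(hash = TRUE, parent = emptyenv())
  key <- as.character(fg_lin)
  for (i in seq_along(fg_lin)) assign(key[i], i, envir = idx_of)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ,
               drop = FALSE]
  edges <- list()
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny &
      nb[, 3] >= 1 & nb[, 3] <= nz
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * nx + (nb[ok, 3] - 1) * nx * ny
    j <- vapply(as.character(nb_lin), function(k)
      if (exists(k, envir = idx_of, inherits = FALSE))
        get(k, envir = idx_of) else NA_integer_, integer(1),
      USE.NAMES = FALSE)
    src <- which(ok)[!is.na(j)]
    if (length(src))
      edges[[length(edges) + 1]] <- cbind(src, j[!is.na(j)])
  }
  g <- igraph::make_empty_graph(n = length(fg_lin), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  igraph::components(g)$membership
}

#' Extract bright internal objects (alleles) from a channel
#'
#' Otsu's threshold is computed on the channel intensities restricted
#' to one nucleus mask (per nucleus, not globally -- the histogram of
#' the local context is what separates specific from unspecific
#' signal); voxels above threshold are grouped into 26-connected
#' components, ranked by integrated brightness, and the top `k` are
#' returned, discarding dimmer unspecific puncta. Fewer than `k`
#' components found sets the `undercount` flag. Otsu depends only on
#' the histogram shape, so the extraction is invariant under intensity
#' scaling.
#'
#' @param channel an `image_stack` (same geometry as the mask).
#' @param mask a `label_mask`.
#' @param nucleus label id of the nucleus within `mask`.
#' @param k expected object count (default 2, the two alleles).
#' @return list of objects, each with `voxels` (n x 3, px),
#'   `integrated`, `centroid_um`, `surface_voxels` (n x 3, px),
#'   `channel`; attribute `undercount` when fewer than `k` were found.
#' @export
extract_alleles <- function(channel, mask, nucleus, k = 2) {
  sh <- stack_shape(channel)
  if (!all(dim(mask$labels) == sh))
    stop("channel geometry does not match the mask")
  inmask <- which(mask$labels == nucleus)
  if (!length(inmask)) stop("empty nucleus mask for label ", nucleus)
  a <- stack_array(channel)
  vals <- a[inmask]
  thr <- otsu_threshold(vals, channel$bits)
  fg <- inmask[vals > thr]
  if (!length(fg)) {
    out <- list()
    attr(out, "undercount") <- TRUE
    return(out)
  }
  memb <- label_components_26(fg, sh)
  comp_ids <- unique(memb)
  objs <- lapply(comp_ids, function(ci) {
    lin <- fg[memb == ci]
    vox <- arrayInd(lin, sh)
    um <- px_to_um(vox[, 1:2, drop = FALSE], vox[, 3], channel$voxel_size)
    fgset <- array(FALSE, dim = sh)
    fgset[lin] <- TRUE
    surf <- vapply(seq_len(nrow(vox)), function(i) {
      p <- vox[i, ]
      for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        q <- p + d
        if (any(q < 1) || any(q > sh)) return(TRUE)
        if (!fgset[q[1], q[2], q[3]]) return(TRUE)
      }
      FALSE
    }, logical(1))
    list(voxels = vox, integrated = sum(a[lin]),
         centroid_um = colMeans(um),
         surface_voxels = vox[surf, , drop = FALSE],
         channel = channel$channel)
  })
  o <- order(-vapply(objs, `[[`, numeric(1), "integrated"))
  objs <- objs[o[seq_len(min(k, length(objs)))]]
  attr(objs, "undercount") <- length(objs) < k
  objs
}

# minimal distances from points to a triangle soup (Ericson's algorithm,
# vectorised over triangles)
point_mesh_distance <- function(p, mesh) {
  A <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  P <- matrix(p, nrow(A), 3, byrow = TRUE)
  ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  v <- vb / ifelse(denom == 0, 1, denom)
  w <- vc / ifelse(denom == 0, 1, denom)
  cl <- A + ab * v + ac * w  # interior candidate
  # vertex regions
  reg_a <- d1 <= 0 & d2 <= 0
  reg_b <- d3 >= 0 & d4 <= d3
  reg_c <- d6 >= 0 & d5 <= d6
  # edge regions
  vv <- d1 / ifelse(d1 - d3 == 0, 1, d1 - d3)
  reg_ab <- vc <= 0 & d1 >= 0 & d3 <= 0
  ww <- d2 / ifelse(d2 - d6 == 0, 1, d2 - d6)
  reg_ac <- vb <= 0 & d2 >= 0 & d6 <= 0
  uu <- (d4 - d3) / ifelse((d4 - d3) + (d5 - d6) == 0, 1,
                           (d4 - d3) + (d5 - d6))
  reg_bc <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  cl[reg_bc, ] <- B[reg_bc, , drop = FALSE] +
    uu[reg_bc] * (C[reg_bc, , drop = FALSE] - B[reg_bc, , drop = FALSE])
  cl[reg_ac, ] <- A[reg_ac, , drop = FALSE] +
    ww[reg_ac] * ac[reg_ac, , drop = FALSE]
  cl[reg_ab, ] <- A[reg_ab, , drop = FALSE] +
    vv[reg_ab] * ab[reg_ab, , drop = FALSE]
  cl[reg_c, ] <- C[reg_c, , drop = FALSE]
  cl[reg_b, ] <- B[reg_b, , drop = FALSE]
  cl[reg_a, ] <- A[reg_a, , drop = FALSE]
  min(sqrt(rowSums((cl - P)^2)))
}

#' Distance from an internal object to the nuclear envelope
#'
#' Minimum Euclidean distance (um) from the object's surface-voxel
#' centres to the triangulated nucleus shell; the distance from the
#' object's centroid to the shell is reported alongside, since either
#' convention is in use for allele-to-periphery measurements.
#'
#' @param object one element of [extract_alleles()].
#' @param mesh a [surface_mesh()].
#' @param voxel_size `c(dx, dy, dz)` um.
#' @return list `surface_um`, `centroid_um`.
#' @export
envelope_distance <- function(object, mesh, voxel_size) {
  sv <- object$surface_voxels
  pts <- px_to_um(sv[, 1:2, drop = FALSE], sv[, 3], voxel_size)
  ds <- vapply(seq_len(nrow(pts)), function(i)
    point_mesh_distance(pts[i, ], mesh), numeric(1))
  list(surface_um = min(ds),
       centroid_um = point_mesh_distance(object$centroid_um, mesh))
}

#' Minimal surface-to-surface distance between two internal objects
#'
#' @param a,b objects from [extract_alleles()].
#' @param voxel_size `c(dx, dy, dz)` um.
#' @return distance in micrometres; 0 when the voxel sets touch or
#'   overlap.
#' @export
pairwise_object_distance <- function(a, b, voxel_size) {
  pa <- px_to_um(a$surface_voxels[, 1:2, drop = FALSE],
                 a$surface_voxels[, 3], voxel_size)
  pb <- px_to_um(b$surface_voxels[, 1:2, drop = FALSE],
                 b$surface_voxels[, 3], voxel_size)
  ka <- nrow(pa); kb <- nrow(pb)
  d2 <- outer(rowSums(pa^2), rep(1, kb)) +
    outer(rep(1, ka), rowSums(pb^2)) - 2 * pa %*% t(pb)
  dmin <- sqrt(max(0, min(d2)))
  # voxel sets overlapping -> 0
  keys_a <- paste(a$voxels[, 1], a$voxels[, 2], a$voxels[, 3])
  keys_b <- paste(b$voxels[, 1], b$voxels[, 2], b$voxels[, 3])
  if (any(keys_a %in% keys_b)) return(0)
  dmin
}

#' Morphometry table for a segmentation result
#'
#' @param result output of [segment_stack()].
#' @param voxel_size `c(dx, dy, dz)` um.
#' @param channels optional named list of `image_stack`s with internal
#'   objects; for each channel the two brightest objects per nucleus
#'   are extracted and their envelope and pairwise distances reported.
#' @return data frame, one row per nucleus.
#' @export
morphometry_table <- function(result, voxel_size, channels = NULL) {
  rows <- lapply(result$surfaces, function(s) {
    m <- measure_nucleus(s, voxel_size)
    row <- data.frame(id = m$id, volume_um3 = m$volume_um3,
                      area_um2 = m$area_um2, form_factor = m$form_factor,
                      cx_um = m$centroid_um[1], cy_um = m$centroid_um[2],
                      cz_um = m$centroid_um[3])
    if (!is.null(channels)) {
      mesh <- surface_mesh(s, voxel_size)
      for (nm in names(channels)) {
        objs <- tryCatch(extract_alleles(channels[[nm]], result$mask,
                                         s$id), error = function(e) list())
        for (i in seq_along(objs)) {
          ed <- envelope_distance(objs[[i]], mesh, voxel_size)
          row[[paste0(nm, "_obj", i, "_envelope_um")]] <- ed$surface_um
          row[[paste0(nm, "_obj", i, "_envelope_centroid_um")]] <-
            ed$centroid_um
        }
        if (length(objs) >= 2)
          row[[paste0(nm, "_pair_um")]] <-
            pairwise_object_distance(objs[[1]], objs[[2]], voxel_size)
      }
    }
    row
  })
  if (!length(rows)) return(data.frame())
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(nms, names(r))) r[[nm]] <- NA
    r[nms]
  })
  do.call(rbind, rows)
}
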