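#' Image stacks with plane streaming
#'
#' An `image_stack` is a 3D grayscale intensity volume addressed one
#' z-plane at a time. It can be backed either by an in-memory array or
#' by a multi-page TIFF on disk; in the latter case [get_plane()] reads
#' single pages on demand and keeps only a small fixed number of planes
#' resident (two by default), so whole-stack workflows never need the
#' full volume in memory. Both backends return identical pixel values
#' regardless of access order.
#'
#' Planes are numeric matrices of dimension `(nx, ny)` indexed
#' `[x, y]`, 1-based, with x the fastest-varying axis; intensities are
#' raw integer counts (0 .. 2^bits - 1) stored as numeric. All geometry
#' is in pixel units; physical micrometres enter only at the morphometry
#' boundary through `voxel_size`.
#'
#' @name image_stack
NULL

new_image_stack <- function(backend, shape, bits, voxel_size,
                            channel = 1L, data = NULL, path = NULL,
                            cache_planes = 2L) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  s <- list(backend = backend, shape = as.integer(shape),
            bits = as.integer(bits),
            voxel_size = as.numeric(voxel_size),
            channel = as.integer(channel),
            data = data, path = path,
            cache = new.env(parent = emptyenv()),
            cache_planes = as.integer(cache_planes))
  s$cache$keys <- integer(0)
  s$cache$vals <- list()
  class(s) <- "image_stack"
  s
}

#' Create an in-memory image stack
#'
#' @param a numeric or integer array `(nx, ny, nz)`; a matrix is treated
#'   as a single plane.
#' @param voxel_size physical voxel size `c(dx, dy, dz)` in micrometres.
#' @param bits bit depth (8 or 16); default picks the smallest depth
#'   holding `max(a)`.
#' @param channel integer channel id.
#' @return An `image_stack`.
#' @export
as_image_stack <- function(a, voxel_size = c(0.08, 0.08, 0.2),
                           bits = NULL, channel = 1L) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  stopifnot(length(dim(a)) == 3)
  if (is.null(bits)) bits <- if (max(a) > 255) 16L else 8L
  storage.mode(a) <- "double"
  new_image_stack("array", dim(a), bits, voxel_size,
                  channel = channel, data = a)
}

#' Open a multi-page grayscale TIFF as a streamed stack
#'
#' Page metadata is read up front; pixel data is read per page on
#' demand. RGB/multi-sample pages and pages whose shape differs from
#' page 1 are rejected with an error naming the offending page. Voxel
#' size is supplied by the caller (TIFF resolution tags are ignored for
#' geometry; a conflicting tag only triggers a warning).
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @param voxel_size physical voxel size `c(dx, dy, dz)` in micrometres.
#' @param channel integer channel id.
#' @param cache_planes number of planes kept resident (>= 1, default 2).
#' @return An `image_stack` with lazily readable planes.
#' @export
open_stack <- function(path, voxel_size = c(0.08, 0.08, 0.2),
                       channel = 1L, cache_planes = 2L) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  info <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e) stop("unreadable TIFF ", path, ": ",
                                            conditionMessage(e)))
  info <- as.data.frame(info)  # one row of metadata per page
  nz <- nrow(info)
  for (i in seq_len(nz)) {
    if (info$samples.per.pixel[i] != 1)
      stop("format error: page ", i, " of ", path,
           " has ", info$samples.per.pixel[i],
           " samples per pixel (grayscale required)")
    if (info$width[i] != info$width[1] ||
        info$length[i] != info$length[1])
      stop("format error: page ", i, " of ", path,
           " has shape ", info$width[i], "x", info$length[i],
           " inconsistent with page 1 (", info$width[1], "x",
           info$length[1], ")")
  }
  bits <- info$bits.per.sample[1]
  if (!bits %in% c(8L, 16L))
    stop("format error: ", path, " has ", bits,
         "-bit samples; 8- or 16-bit required")
  xres <- if ("x.resolution" %in% names(info)) info$x.resolution[1]
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    tag_dx <- 1e4 / xres  # TIFF res is px/cm under the common convention
    if (abs(tag_dx - voxel_size[1]) > 0.5 * voxel_size[1])
      warning("TIFF resolution tag of ", path,
              " disagrees with the supplied voxel size; using the ",
              "supplied value")
  }
  # readTIFF returns pages as (rows = y, cols = x); planes are stored (x, y)
  new_image_stack("tiff", c(info$width[1], info$length[1], nz), bits,
                  voxel_size,
                  channel = channel, path = path,
                  cache_planes = max(1L, cache_planes))
}

#' Number of planes, plane shape, dtype of a stack
#' @param stack an `image_stack`.
#' @return `stack_shape`: integer `c(nx, ny, nz)`.
#' @export
stack_shape <- function(stack) stack$shape

#' Extract one z-plane
#'
#' @param stack an `image_stack`.
#' @param z 1-based plane index.
#' @return Numeric matrix `(nx, ny)` of raw intensities.
#' @export
get_plane <- function(stack, z) {
  z <- as.integer(z)
  if (z < 1 || z > stack$shape[3])
    stop("plane index ", z, " out of range [1, ", stack$shape[3], "]")
  if (stack$backend == "array") return(stack$data[, , z])
  ca <- stack$cache
  hit <- match(z, ca$keys)
  if (!is.na(hit)) return(ca$vals[[hit]])
  pg <- tiff::readTIFF(stack$path, all = z, as.is = TRUE)
  if (is.list(pg)) pg <- pg[[1]]
  pl <- t(pg) * 1.0
  if (length(ca$keys) >= stack$cache_planes) {  # drop least-recently added
    ca$keys <- ca$keys[-1]
    ca$vals <- ca$vals[-1]
  }
  ca$keys <- c(ca$keys, z)
  ca$vals <- c(ca$vals, list(pl))
  pl
}

#' Materialise a stack as an array
#' @param stack an `image_stack`.
#' @return Numeric array `(nx, ny, nz)`.
#' @export
stack_array <- function(stack) {
  if (stack$backend == "array") return(stack$data)
  sh <- stack$shape
  a <- array(0, dim = sh)
  for (z in seq_len(sh[3])) a[, , z] <- get_plane(stack, z)
  a
}

#' Write an intensity stack as a multi-page TIFF
#'
#' Lossless for integer intensities within the stack's bit depth; one
#' page per z-plane.
#'
#' @param stack an `image_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  sh <- stack$shape
  mx <- 2^stack$bits - 1
  pages <- vector("list", sh[3])
  for (z in seq_len(sh[3])) {
    pl <- get_plane(stack, z)
    if (min(pl) < 0 || max(pl) > mx)
      stop("intensities out of range for ", stack$bits, "-bit output")
    pages[[z]] <- t(pl) / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bits,
                  reduce = FALSE)
  invisible(path)
}

#' Label masks
#'
#' A `label_mask` is an integer array of the same geometry as its source
#' stack: 0 marks background, k >= 1 the k-th nucleus. A single integer
#' per voxel enforces that labels partition the foreground; labels are
#' kept contiguous 1..K.
#'
#' @param a integer array `(nx, ny, nz)` of labels.
#' @param voxel_size physical voxel size in micrometres.
#' @return A `label_mask`.
#' @export
as_label_mask <- function(a, voxel_size = c(0.08, 0.08, 0.2)) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  stopifnot(length(dim(a)) == 3, min(a) >= 0)
  storage.mode(a) <- "integer"
  structure(list(labels = a, voxel_size = as.numeric(voxel_size)),
            class = "label_mask")
}

#' Write a label mask as a multi-page TIFF
#'
#' The sample depth is promoted 8 -> 16 -> 32 bit as needed for the
#' largest label. The 32-bit pages use floating-point samples, which
#' represent integer labels exactly up to 2^24 - 1; more labels than
#' that are rejected.
#'
#' @param mask a `label_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  K <- max(mask$labels)
  if (K > 2^24 - 1) stop("too many labels (", K, ") for lossless output")
  bits <- if (K <= 255) 8L else if (K <= 65535) 16L else 32L
  mx <- 2^bits - 1
  nz <- dim(mask$labels)[3]
  pages <- lapply(seq_len(nz),
                  function(z) t(mask$labels[, , z]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  invisible(path)
}

#' Read a label mask from a multi-page TIFF
#' @param path path written by [write_label_mask()].
#' @param voxel_size physical voxel size in micrometres.
#' @return A `label_mask`.
#' @export
read_label_mask <- function(path, voxel_size = c(0.08, 0.08, 0.2)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # as.is gives integers for 8/16-bit pages; 32-bit float pages come back
  # in [0,1] and are rescaled
  a <- vapply(pages, function(pg) {
    m <- t(pg)
    if (!is.integer(pg) && max(m) <= 1) m <- round(m * (2^32 - 1))
    m
  }, matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  as_label_mask(round(a), voxel_size)
}

#' Export per-plane nucleus contours as JSON lines
#'
#' One record per nucleus and plane: nucleus id, 1-based z index and the
#' ordered vertex lists `x`, `y` in pixel coordinates of the closed
#' polygon. [read_contours()] inverts the format exactly.
#'
#' @param surfaces list of `nucleus_surface` objects (see
#'   [segment_stack()]), or an empty list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_contours <- function(surfaces, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in surfaces) {
    for (ct in s$contours) {
      v <- contour_vertices(ct)
      rec <- list(nucleus = s$id, z = ct$z,
                  x = round(v[, 1], 4), y = round(v[, 2], 4))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read contours written by [export_contours()]
#' @param path input path.
#' @return A list of records, each with fields `nucleus`, `z`, `x`, `y`.
#' @export
read_contours <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) jsonlite::fromJSON(l))
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack %s  %dx%dx%d  %d-bit  voxel %s um  channel %d>\n",
              x$backend, x$shape[1], x$shape[2], x$shape[3], x$bits,
              paste(format(x$voxel_size), collapse = "x"), x$channel))
  invisible(x)
}
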