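#' Default run configuration
#'
#' Returns the full set of tunable parameters of the segmentation
#' pipeline with their documented defaults. Every downstream function
#' takes (a subset of) this list, so a run is fully described by one
#' configuration object plus the input stack.
#'
#' Parameter groups and units:
#'
#' * Geometry: `voxel_size` = c(dx, dy, dz) in micrometres (dx = dy,
#'   lateral; dz axial). Default 0.08 x 0.08 x 0.2 um, the acquisition
#'   geometry of high-resolution confocal FISH stacks (80 nm/px lateral,
#'   200 nm z-spacing).
#' * Nucleus size prior: `d_min_xy`, `d_max_xy` (px) -- minimal/maximal
#'   nucleus diameter on an xy-section; `z_min`, `z_max` (planes) --
#'   minimal/maximal axial extent.
#' * Seed screening: `ring_width` (px), `tau_contrast` (relative
#'   ring-to-ring mean change tolerated inside the minimal radius),
#'   `tau_fluct` (ring std/mean ceiling), `eps` (regulariser of the
#'   moment kernels, px), `r_m` (moment analysis radius, px; `NULL` means
#'   `d_min_xy / 2`), `mq_max`, `md_max` (moment-magnitude gates,
#'   phantom-calibrated intensity-scaled units, see
#'   [seed_moment_gates()]), `w_min` (minimal priority weight; `NULL`
#'   means estimated per plane as background mean + 2 background sd).
#' * Tracing: `n_rays` (boundary sampling, default 90 = 4 deg),
#'   `mask_halfwidth` (edge mask half-width h, px), `max_dev` (maximal
#'   intracluster deviation, px), `delta_tube` (tubular search half-width
#'   for plane-to-plane propagation, px), `delta_pass` (second-pass
#'   half-width for seeded tracing, px; default `3 * max_dev`), `r_max`
#'   (ray length, px; `NULL` means `d_max_xy / 2 + 2 * mask_halfwidth`),
#'   `kappa_edge` (edge-confidence floor multiplier).
#' * Surface assembly: `q_min` (laminar quality threshold in \[0, 1\]),
#'   `delta_r` (laminar layer width, px), `a_point_factor` (a contour is
#'   "point-like" when its area drops below the area of a circle of
#'   diameter `a_point_factor * d_min_xy`; default 1/4).
#' * Evaluation: `theta_detect` (overlap fraction of a ground-truth
#'   nucleus required to count as detected), `theta_defect` (voxel-defect
#'   fraction separating precise from non-precise matches), `iou_floor`
#'   (minimal IoU for a 1:1 pair to count as a match at all).
#'
#' @param ... named overrides of individual defaults.
#' @return A named list of parameters, class `"nt_config"`.
#' @export
#' @examples
#' cfg <- nt_config(d_min_xy = 20, d_max_xy = 60)
#' cfg$d_min_xy
nt_config <- function(...) {
  cfg <- list(
    voxel_size   = c(0.08, 0.08, 0.2),
    d_min_xy     = 24,
    d_max_xy     = 80,
    z_min        = 4,
    z_max        = 40,
    w_min        = NULL,
    multi_radius = FALSE,
    ring_width   = 2,
    tau_contrast = 0.25,
    tau_fluct    = 0.6,
    eps          = 0.5,
    r_m          = NULL,
    mq_max       = 0.008,
    md_max       = 0.05,
    n_rays       = 90,
    mask_halfwidth = 4,
    max_dev      = 3,
    delta_tube   = 4,
    delta_pass   = NULL,
    r_max        = NULL,
    kappa_edge   = 3,
    q_min        = 0.85,
    delta_r      = 4,
    a_point_factor = 0.25,
    theta_detect = 0.3,
    theta_defect = 0.05,
    iou_floor    = 0.5,
    seed         = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg <- fill_derived_config(cfg)
  validate_config(cfg)
  class(cfg) <- "nt_config"
  cfg
}

fill_derived_config <- function(cfg) {
  if (is.null(cfg$r_m)) cfg$r_m <- cfg$d_min_xy / 2
  if (is.null(cfg$r_max))
    cfg$r_max <- cfg$d_max_xy / 2 + 2 * cfg$mask_halfwidth
  if (is.null(cfg$delta_pass)) cfg$delta_pass <- 3 * cfg$max_dev
  cfg
}

#' Validate a configuration
#'
#' Checks ranges and cross-key consistency; invalid combinations are
#' rejected with a message naming the offending keys.
#'
#' @param cfg a list as produced by [nt_config()].
#' @return `cfg`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg,
                                                 call. = FALSE)
  chk(length(cfg$voxel_size) == 3 && all(cfg$voxel_size > 0),
      "voxel_size must be three positive numbers")
  chk(abs(cfg$voxel_size[1] - cfg$voxel_size[2]) < 1e-12,
      "voxel_size: dx must equal dy")
  chk(cfg$d_min_xy > 0 && cfg$d_max_xy > cfg$d_min_xy,
      "d_min_xy must be positive and smaller than d_max_xy")
  chk(cfg$z_min > 0 && cfg$z_max >= cfg$z_min,
      "z_min must be positive and no larger than z_max")
  chk(cfg$ring_width >= 1, "ring_width must be >= 1 px")
  chk(cfg$tau_contrast > 0, "tau_contrast must be positive")
  chk(cfg$tau_fluct > 0, "tau_fluct must be positive")
  chk(cfg$eps > 0, "eps must be positive")
  chk(cfg$n_rays >= 8, "n_rays must be >= 8")
  chk(cfg$mask_halfwidth >= 1, "mask_halfwidth must be >= 1 px")
  chk(cfg$max_dev > 0, "max_dev must be positive")
  chk(cfg$delta_tube > 0, "delta_tube must be positive")
  chk(cfg$q_min >= 0 && cfg$q_min <= 1, "q_min must lie in [0, 1]")
  chk(cfg$delta_r >= 1, "delta_r must be >= 1 px")
  chk(cfg$theta_detect > 0 && cfg$theta_detect <= 1,
      "theta_detect must lie in (0, 1]")
  chk(cfg$theta_defect > 0 && cfg$theta_defect < 1,
      "theta_defect must lie in (0, 1)")
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Keys absent from the file keep their [nt_config()] defaults; unknown
#' keys are an error.
#'
#' @param path path to a YAML file of configuration keys.
#' @return An `nt_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$voxel_size)) vals$voxel_size <- as.numeric(vals$voxel_size)
  do.call(nt_config, vals)
}

#' @export
print.nt_config <- function(x, ...) {
  cat("<nucleotrace configuration>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-15s %s\n", k,
                if (is.null(v)) "NULL" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}
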