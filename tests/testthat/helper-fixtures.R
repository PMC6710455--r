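# Shared fixtures, built in code. Heavier phantoms are memoised so that
# several test files can reuse one segmentation run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# plane with one or more bright disks on a dark background
disk_plane <- function(nx, ny, disks, fg = 150, bg = 10) {
  m <- matrix(bg, nx, ny)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (d in disks)
    m[(xs - d[1])^2 + (ys - d[2])^2 <= d[3]^2] <- fg
  m
}

# configuration for the coarse (0.25 x 0.25 x 0.5 um) phantom geometry
phantom_cfg <- function(...)
  nt_config(voxel_size = c(0.25, 0.25, 0.5), d_min_xy = 20, d_max_xy = 48,
            z_min = 4, z_max = 24, ...)

# clean single sphere (R = 4 um) phantom, no blur/noise
sphere_phantom <- function() fixture("sphere", function() {
  e <- ellipsoid_spec(center = c(8, 8, 8), semiaxes = c(4, 4, 4),
                      intensity = 150)
  generate_phantom(phantom_spec(list(e), shape = c(64, 64, 32),
                                voxel_size = c(0.25, 0.25, 0.5),
                                noise_sigma = 0, blur_sigma_xy = 0,
                                blur_sigma_z = 0))
})

# sphere phantom with two channel-2 internal spheres, no blur/noise
allele_phantom <- function() fixture("allele", function() {
  sph <- list(list(channel = 2, offset = c(1.5, 0, 0), radius = 0.5,
                   intensity = 200),
              list(channel = 2, offset = c(-1.5, 0, 0), radius = 0.5,
                   intensity = 200))
  e <- ellipsoid_spec(center = c(8, 8, 8), semiaxes = c(4, 4, 4),
                      intensity = 150, spheres = sph)
  generate_phantom(phantom_spec(list(e), shape = c(64, 64, 32),
                                voxel_size = c(0.25, 0.25, 0.5),
                                noise_sigma = 0, blur_sigma_xy = 0,
                                blur_sigma_z = 0))
})

allele_segmentation <- function() fixture("allele_seg", function()
  segment_stack(allele_phantom()$channels$dna, phantom_cfg()))

# five well-separated ellipsoids with mild noise/blur
five_phantom <- function() fixture("five", function() {
  centers <- list(c(10, 10, 10), c(30, 10, 10), c(10, 30, 10),
                  c(30, 30, 10), c(20, 20, 10))
  ells <- lapply(seq_along(centers), function(i)
    ellipsoid_spec(center = centers[[i]],
                   semiaxes = c(4.2, 4.0, 3.8) + 0.1 * i,
                   angles = c(0.3 * i, 0.2 * i, 0.1 * i),
                   intensity = 150))
  generate_phantom(phantom_spec(ells, shape = c(160, 160, 40),
                                voxel_size = c(0.25, 0.25, 0.5),
                                noise_sigma = 10, seed = 3))
})

five_cfg <- function()
  phantom_cfg(d_min_xy = 24, d_max_xy = 48, z_min = 8, z_max = 24)

five_segmentation <- function() fixture("five_seg", function()
  segment_stack(five_phantom()$channels$dna, five_cfg()))

# per-label IoU between a prediction label and a truth label
mask_iou <- function(pred_labels, truth_labels, i, j) {
  p <- pred_labels == i
  t_ <- truth_labels == j
  sum(p & t_) / sum(p | t_)
}
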