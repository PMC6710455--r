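#' Pipeline entry points
#'
#' High-level runs tying the modules together: each takes a
#' configuration (an [nt_config()] or the path of a YAML file) plus
#' input/output paths, writes all products as plain TIFF/CSV/JSON
#' files, and returns its main result invisibly. These functions back
#' the `nucleotrace` command-line script (subcommands `segment`,
#' `phantom`, `evaluate`, `morph`, `metrics`) shipped under
#' `inst/cli/`.
#'
#' @name pipeline
NULL

resolve_config <- function(config) {
  if (inherits(config, "nt_config")) return(config)
  if (is.character(config)) return(read_config(config))
  if (is.list(config)) return(do.call(nt_config, config))
  stop("config must be an nt_config, a list, or a YAML path")
}

#' Run full segmentation on a stack
#'
#' @param input path to a multi-page TIFF, or an `image_stack`.
#' @param config an [nt_config()], list of overrides, or YAML path.
#' @param outdir output directory (created if missing): writes
#'   `labels.tif`, `contours.jsonl`, `nuclei.csv`, `log.csv`.
#' @return The [segment_stack()] result, invisibly.
#' @export
run_segment <- function(input, config = nt_config(), outdir = ".") {
  cfg <- resolve_config(config)
  stack <- if (inherits(input, "image_stack")) input else
    open_stack(input, voxel_size = cfg$voxel_size)
  res <- segment_stack(stack, cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_label_mask(res$mask, file.path(outdir, "labels.tif"))
  export_contours(res$surfaces, file.path(outdir, "contours.jsonl"))
  smry <- surface_summary(res)
  if (is.null(smry)) smry <- data.frame()
  utils::write.csv(smry, file.path(outdir, "nuclei.csv"),
                   row.names = FALSE)
  log_df <- rbind(
    if (length(res$surfaces)) do.call(rbind, lapply(res$surfaces,
      function(s) data.frame(x = s$seed$x, y = s$seed$y, z = s$seed$z,
                             weight = s$seed$weight, outcome = "accepted",
                             reason = ""))) else NULL,
    if (nrow(res$rejections)) cbind(res$rejections[, c("x", "y", "z",
                                                       "weight")],
                                    outcome = "rejected",
                                    reason = res$rejections$reason)
    else NULL)
  if (is.null(log_df)) log_df <- data.frame()
  utils::write.csv(log_df, file.path(outdir, "log.csv"),
                   row.names = FALSE)
  if (!length(res$surfaces))
    warning("no nuclei accepted in this stack")
  invisible(res)
}

#' Generate and write a phantom
#'
#' @param spec a [phantom_spec()].
#' @param outdir output directory: writes `phantom_<channel>.tif`,
#'   `truth.tif`, `analytic.csv`.
#' @return The [generate_phantom()] result, invisibly.
#' @export
run_phantom <- function(spec, outdir = ".") {
  ph <- generate_phantom(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ph$channels))
    write_stack(ph$channels[[nm]],
                file.path(outdir, paste0("phantom_", nm, ".tif")))
  write_label_mask(ph$truth$mask, file.path(outdir, "truth.tif"))
  utils::write.csv(ph$truth$nuclei, file.path(outdir, "analytic.csv"),
                   row.names = FALSE)
  invisible(ph)
}

#' Evaluate a predicted mask against ground truth
#'
#' @param prediction,truth label-mask TIFF paths or `label_mask`s.
#' @param config configuration (thresholds).
#' @param outdir output directory: writes `evaluation.csv` (counts and
#'   metrics), `evaluation.json`, `assignments.csv`.
#' @return The [evaluate_masks()] report, invisibly.
#' @export
run_evaluate <- function(prediction, truth, config = nt_config(),
                         outdir = ".") {
  cfg <- resolve_config(config)
  pm <- if (is.character(prediction)) read_label_mask(prediction) else
    prediction
  tm <- if (is.character(truth)) read_label_mask(truth) else truth
  rep_ <- evaluate_masks(pm, tm, cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(c("I", "II"), function(l) {
    q <- rep_[[paste0("quality_", l)]]
    data.frame(quality = l, TP = q$TP, FP = q$FP, FN = q$FN,
               recall = q$metrics[["recall"]],
               precision = q$metrics[["precision"]],
               f_measure = q$metrics[["f_measure"]],
               accuracy = q$metrics[["accuracy"]])
  }))
  counts_df <- as.data.frame(rep_$counts)
  utils::write.csv(cbind(counts_df[rep(1, nrow(rows)), ], rows),
                   file.path(outdir, "evaluation.csv"), row.names = FALSE)
  as_json_level <- function(q)
    list(TP = q$TP, FP = q$FP, FN = q$FN, metrics = as.list(q$metrics))
  jsonlite::write_json(list(counts = rep_$counts,
                            quality_I = as_json_level(rep_$quality_I),
                            quality_II = as_json_level(rep_$quality_II)),
                       file.path(outdir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(rep_$assignments, file.path(outdir, "assignments.csv"),
                   row.names = FALSE)
  invisible(rep_)
}

#' Metrics from category counts alone
#'
#' Counts-only mode: folds PS/NP/OS/US/FP/ND counts into TP/FP/FN at
#' both quality levels and computes recall, precision, F-measure and
#' accuracy.
#'
#' @param counts data frame with columns PS, NP, OS, US, FP, ND (one
#'   row per stack), e.g. [reference_category_counts()].
#' @return data frame with one row per stack and quality level.
#' @export
run_metrics <- function(counts) {
  do.call(rbind, lapply(seq_len(nrow(counts)), function(r) {
    do.call(rbind, lapply(c("II", "I"), function(l) {
      tc <- quality_counts(counts[r, c("PS", "NP", "OS", "US", "FP",
                                       "ND")], l)
      m <- segmentation_metrics(tc[["TP"]], tc[["FP"]], tc[["FN"]])
      cbind(data.frame(stack = if ("stack" %in% names(counts))
        counts$stack[r] else r, quality = l,
        TP = tc[["TP"]], FP = tc[["FP"]], FN = tc[["FN"]]),
        as.data.frame(as.list(m)))
    }))
  }))
}

#' Morphometry run over a segmentation result
#'
#' @param result a [segment_stack()] result (or output directory of a
#'   previous [run_segment()] together with the original stack is not
#'   supported -- morphometry needs the surfaces, run in-session).
#' @param config configuration (voxel size).
#' @param channels optional named list of channel `image_stack`s or
#'   TIFF paths.
#' @param outdir output directory: writes `morphometry.csv`.
#' @return The morphometry data frame, invisibly.
#' @export
run_morph <- function(result, config = nt_config(), channels = NULL,
                      outdir = ".") {
  cfg <- resolve_config(config)
  if (!is.null(channels))
    channels <- lapply(channels, function(ch)
      if (is.character(ch)) open_stack(ch, voxel_size = cfg$voxel_size)
      else ch)
  tab <- morphometry_table(result, cfg$voxel_size, channels)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tab, file.path(outdir, "morphometry.csv"),
                   row.names = FALSE)
  invisible(tab)
}
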