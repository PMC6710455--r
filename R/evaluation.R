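#' Instance-level segmentation evaluation
#'
#' Compares a predicted label mask against ground truth and assigns
#' every nucleus to one of six categories: PS (precise segmentation),
#' NP (non-precise: defects up to a few percent of voxels), OS
#' (over-segmented: one nucleus split into several), US
#' (under-segmented: several nuclei merged into one), FP (false
#' positive: a detection matching no nucleus), ND (not detected). The
#' categories are then folded into TP/FP/FN under two counting
#' conventions -- quality I credits only precise segmentations as true
#' positives, quality II also credits non-precise ones -- and the four
#' standard metrics (recall, precision, F-measure, accuracy) are
#' computed from the counts.
#'
#' @name evaluation
NULL

#' Categorise predictions against ground truth
#'
#' Builds the voxel-overlap matrix between predicted and true labels
#' and applies, in order:
#'
#' 1. a prediction covering >= 2 truths, each at overlap fraction >=
#'    `theta_detect` of the truth, is under-segmentation (one US per
#'    such prediction; its truths are consumed);
#' 2. a truth covered by >= 2 remaining predictions at >= `theta_detect`
#'    is over-segmentation (one OS per such truth; its predictions are
#'    consumed);
#' 3. remaining 1:1 pairs at >= `theta_detect`: IoU >= `1 - theta_defect`
#'    is PS, IoU >= `iou_floor` is NP, below the floor the pair does not
#'    count as a match (the truth becomes ND, the prediction FP);
#' 4. unmatched truths are ND, unmatched predictions FP.
#'
#' @param prediction,truth `label_mask` objects sharing geometry, or
#'   plain integer arrays.
#' @param theta_detect minimal overlap fraction of a truth nucleus for
#'   a prediction to count as detecting it.
#' @param theta_defect voxel-defect fraction separating PS from NP
#'   (PS requires IoU >= 1 - theta_defect).
#' @param iou_floor minimal IoU for an NP match.
#' @return list `counts` (PS, NP, OS, US, FP, ND) and `assignments`
#'   (data frame: kind = truth/prediction, id, category, matched id).
#' @export
categorize <- function(prediction, truth, theta_detect = 0.3,
                       theta_defect = 0.05, iou_floor = 0.5) {
  p <- if (inherits(prediction, "label_mask")) prediction$labels else
    prediction
  t_ <- if (inherits(truth, "label_mask")) truth$labels else truth
  if (!all(dim(p) == dim(t_)))
    stop("prediction and truth masks have different geometry")
  np <- max(p); nt <- max(t_)
  counts <- c(PS = 0L, NP = 0L, OS = 0L, US = 0L, FP = 0L, ND = 0L)
  assign_rows <- list()
  note <- function(kind, id, cat, match = NA_integer_)
    assign_rows[[length(assign_rows) + 1]] <<-
    data.frame(kind = kind, id = id, category = cat, match = match)

  sel <- p > 0 | t_ > 0
  ov <- table(factor(p[sel], levels = 0:np),
              factor(t_[sel], levels = 0:nt))
  ov <- matrix(as.integer(ov), np + 1, nt + 1)  # rows: pred 0..np
  pred_sz <- tabulate(p[p > 0], nbins = max(np, 1))
  tru_sz <- tabulate(t_[t_ > 0], nbins = max(nt, 1))

  claims <- matrix(FALSE, np, nt)
  if (np > 0 && nt > 0)
    claims <- (ov[-1, -1, drop = FALSE] /
                 matrix(tru_sz, np, nt, byrow = TRUE)) >= theta_detect
  pred_used <- logical(np); tru_used <- logical(nt)

  # 1. under-segmentation
  if (np > 0 && nt > 0) for (i in seq_len(np)) {
    js <- which(claims[i, ])
    if (length(js) >= 2) {
      counts["US"] <- counts["US"] + 1L
      pred_used[i] <- TRUE
      tru_used[js] <- TRUE
      note("prediction", i, "US")
      for (j in js) note("truth", j, "US", i)
      claims[i, ] <- FALSE
      claims[, js] <- FALSE
    }
  }
  # 2. over-segmentation
  if (np > 0 && nt > 0) for (j in seq_len(nt)) {
    if (tru_used[j]) next
    is <- which(claims[, j])
    if (length(is) >= 2) {
      counts["OS"] <- counts["OS"] + 1L
      tru_used[j] <- TRUE
      pred_used[is] <- TRUE
      note("truth", j, "OS")
      for (i in is) note("prediction", i, "OS", j)
      claims[is, ] <- FALSE
      claims[, j] <- FALSE
    }
  }
  # 3. one-to-one pairs
  if (np > 0 && nt > 0) for (j in seq_len(nt)) {
    if (tru_used[j]) next
    is <- which(claims[, j])
    if (length(is) != 1) next
    i <- is
    if (pred_used[i] || sum(claims[i, ]) != 1) next
    inter <- ov[i + 1, j + 1]
    iou <- inter / (pred_sz[i] + tru_sz[j] - inter)
    if (iou >= 1 - theta_defect) {
      counts["PS"] <- counts["PS"] + 1L
      cat_ <- "PS"
    } else if (iou >= iou_floor) {
      counts["NP"] <- counts["NP"] + 1L
      cat_ <- "NP"
    } else {
      next  # below floor: not a match at all
    }
    pred_used[i] <- TRUE; tru_used[j] <- TRUE
    note("truth", j, cat_, i)
    note("prediction", i, cat_, j)
  }
  # 4. leftovers
  for (j in seq_len(nt)) if (!tru_used[j]) {
    counts["ND"] <- counts["ND"] + 1L
    note("truth", j, "ND")
  }
  for (i in seq_len(np)) if (!pred_used[i]) {
    counts["FP"] <- counts["FP"] + 1L
    note("prediction", i, "FP")
  }
  list(counts = as.list(counts),
       assignments = if (length(assign_rows)) do.call(rbind, assign_rows)
       else data.frame(kind = character(0), id = integer(0),
                       category = character(0), match = integer(0)))
}

#' Fold category counts into TP/FP/FN
#'
#' Quality I counts only precise segmentations as true positives and
#' pools every defective outcome (NP, OS, US) with the false
#' positives; quality II credits non-precise segmentations as true
#' positives. In both conventions the false negatives are the
#' undetected nuclei.
#'
#' @param counts list or named vector with PS, NP, OS, US, FP, ND.
#' @param level `"I"` or `"II"`.
#' @return named vector `c(TP, FP, FN)`.
#' @export
quality_counts <- function(counts, level = c("I", "II")) {
  level <- match.arg(level)
  counts <- as.list(counts)
  with(counts, if (level == "I")
    c(TP = PS, FP = NP + OS + US + FP, FN = ND)
    else
      c(TP = PS + NP, FP = OS + US + FP, FN = ND))
}

#' Recall, precision, F-measure and accuracy from TP/FP/FN
#'
#' recall = TP/(TP+FN); precision = TP/(TP+FP);
#' F = 2 r p / (r + p); accuracy = TP/(TP+FP+FN). Undefined quantities
#' (zero denominators) are returned as `NA` rather than 0.
#'
#' @param TP,FP,FN nonnegative counts.
#' @return named numeric `c(recall, precision, f_measure, accuracy)`.
#' @export
segmentation_metrics <- function(TP, FP, FN) {
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f <- if (is.na(recall) || is.na(precision) || recall + precision == 0)
    NA_real_ else 2 * recall * precision / (recall + precision)
  acc <- if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_
  c(recall = recall, precision = precision, f_measure = f,
    accuracy = acc)
}

#' Full evaluation report
#'
#' @param prediction,truth `label_mask`s sharing geometry.
#' @param cfg an [nt_config()] supplying the thresholds.
#' @return list `counts`, `assignments`, and per quality level the
#'   TP/FP/FN counts and metrics.
#' @export
evaluate_masks <- function(prediction, truth, cfg = nt_config()) {
  cat_ <- categorize(prediction, truth, cfg$theta_detect,
                     cfg$theta_defect, cfg$iou_floor)
  lv <- lapply(c(I = "I", II = "II"), function(l) {
    tc <- quality_counts(cat_$counts, l)
    list(TP = tc[["TP"]], FP = tc[["FP"]], FN = tc[["FN"]],
         metrics = segmentation_metrics(tc[["TP"]], tc[["FP"]],
                                        tc[["FN"]]))
  })
  list(counts = cat_$counts, assignments = cat_$assignments,
       quality_I = lv$I, quality_II = lv$II)
}

#' Bundled reference validation tables
#'
#' `reference_category_counts()` returns the published manual-validation
#' category counts (PS, NP, OS, US, FP, ND) for seven confocal stacks of
#' rodent brain tissue of varying contrast and labelling; they serve as
#' the canonical input for checking the category-folding and metric
#' computations. `reference_metric_cells()` returns the corresponding
#' published TP/FP/FN counts and metric values as printed (strings,
#' preserving the printed rounding), quality II and quality I per stack.
#'
#' @return A data frame.
#' @export
reference_category_counts <- function() {
  utils::read.csv(system.file("extdata", "validation_category_counts.csv",
                              package = "nucleotrace"))
}

#' @rdname reference_category_counts
#' @export
reference_metric_cells <- function() {
  utils::read.csv(system.file("extdata", "validation_metric_cells.csv",
                              package = "nucleotrace"),
                  colClasses = "character")
}

#' Round half-up to a fixed number of decimals
#'
#' Matches the rounding convention of printed tables (0.845 -> 0.85),
#' unlike R's round-half-even.
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits)
  floor(x * 10^digits + 0.5) / 10^digits
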