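#' BOLD run container
#'
#' A `bold_run` wraps a frames x units signal matrix together with the
#' repetition time, the rigid-body motion table and session metadata. Units
#' are either atlas voxels (voxel space, matching the atlas unit order) or
#' parcels (matching `parcel_table()` order).
#'
#' @param data numeric matrix, frames x units; must be finite.
#' @param tr_seconds repetition time in seconds.
#' @param motion data.frame with columns trans_x, trans_y, trans_z, rot_x,
#'   rot_y, rot_z (translations mm, rotations radians), one row per frame,
#'   or NULL.
#' @param meta named list: subject, visit ("baseline"/"experimental"),
#'   condition ("none"/"SAL-TMS"/"DN-TMS"), phase ("pre"/"post"), run index.
#' @param space "voxel" or "parcel".
#' @param slice integer vector assigning each unit to an acquisition slice
#'   (used by [compute_tsnr()]); defaults, for voxel space, to the voxel z
#'   plane, and for parcel space to one slice per unit.
#' @return object of class `bold_run`.
#' @export
bold_run <- function(data, tr_seconds, motion = NULL, meta = list(),
                     space = c("voxel", "parcel"), slice = NULL) {
  space <- match.arg(space)
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("a BOLD run needs at least 2 frames")
  if (!all(is.finite(data))) stop("non-finite values in BOLD data")
  if (!is.null(motion)) {
    mc <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    if (!all(mc %in% names(motion)))
      stop("motion table must have columns ", paste(mc, collapse = ", "))
    if (nrow(motion) != nrow(data))
      stop("motion table frame count does not match BOLD data")
    motion <- as.data.frame(motion)[, mc]
  }
  if (is.null(slice)) slice <- seq_len(ncol(data))
  if (length(slice) != ncol(data))
    stop("slice assignment must have one entry per unit")
  structure(list(data = data, tr_seconds = tr_seconds, motion = motion,
                 meta = meta, space = space, slice = as.integer(slice)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  m <- x$meta
  cat(sprintf("bold_run: %d frames x %d %s units, TR %.3g s\n",
              nrow(x$data), ncol(x$data), x$space, x$tr_seconds))
  if (length(m))
    cat("  ", paste(sprintf("%s=%s", names(m), unlist(m)), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

#' Run-level temporal signal-to-noise ratio
#'
#' Slice-based tSNR: for each slice the mean signal across the slice's units
#' is reduced to a single series; the slice tSNR is its temporal mean over
#' its temporal standard deviation; the run tSNR is the mean across slices.
#' Slices with zero temporal variance contribute +Inf and are reported in
#' the `degenerate_slices` attribute.
#'
#' @param run a `bold_run`.
#' @return the run tSNR (numeric scalar), possibly Inf, with attribute
#'   `degenerate_slices` listing zero-variance slices.
#' @export
compute_tsnr <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  sl <- factor(run$slice)
  # frames x n_slices matrix of slice-mean series
  g <- vapply(levels(sl), function(l)
    rowMeans(run$data[, sl == l, drop = FALSE]), numeric(nrow(run$data)))
  mu <- colMeans(g)
  sdv <- apply(g, 2, stats::sd)
  if (all(sdv == 0)) stop("degenerate tSNR: all slices temporally constant")
  ts <- ifelse(sdv == 0, Inf, mu / sdv)
  out <- mean(ts)
  attr(out, "degenerate_slices") <- levels(sl)[sdv == 0]
  out
}

#' Frame-to-frame relative displacement
#'
#' Composite relative motion per frame transition: the Euclidean norm of the
#' 6-vector of frame-to-frame differences, with rotation differences
#' converted to arc length in mm on a sphere of radius `rot_radius_mm`.
#'
#' @param motion motion table (see [bold_run()]).
#' @param rot_radius_mm conversion radius for rotations; default 50 mm.
#' @return numeric vector of length frames - 1.
#' @export
relative_motion <- function(motion, rot_radius_mm = 50) {
  m <- as.matrix(motion[, c("trans_x", "trans_y", "trans_z",
                            "rot_x", "rot_y", "rot_z")])
  d <- diff(m)
  d[, 4:6] <- d[, 4:6] * rot_radius_mm
  sqrt(rowSums(d^2))
}

#' Quality-control decision for a BOLD run
#'
#' A run is excluded if its tSNR falls below the group mean minus two group
#' standard deviations, or if it has more than five frame-to-frame relative
#' displacements greater than 0.5 mm ("more than five" is strict: exactly
#' five is retained). Counts of moves exceeding 0.1 mm and 0.5 mm are both
#' reported.
#'
#' @param run a `bold_run` with a motion table.
#' @param group_tsnr_mean,group_tsnr_sd tSNR statistics of the full run pool.
#' @param rot_radius_mm see [relative_motion()].
#' @return object of class `qc_report`: list with run id, tsnr, move counts,
#'   `excluded` flag and `reasons`.
#' @export
qc_run <- function(run, group_tsnr_mean, group_tsnr_sd, rot_radius_mm = 50) {
  stopifnot(inherits(run, "bold_run"))
  if (is.null(run$motion)) stop("qc_run requires a motion table")
  tsnr <- as.numeric(compute_tsnr(run))
  rel <- relative_motion(run$motion, rot_radius_mm)
  n05 <- sum(rel > 0.5)
  n01 <- sum(rel > 0.1)
  reasons <- character(0)
  thr <- group_tsnr_mean - 2 * group_tsnr_sd
  if (tsnr < thr)
    reasons <- c(reasons, sprintf("tSNR %.3g below group mean - 2 sd (%.3g)",
                                  tsnr, thr))
  if (n05 > 5)
    reasons <- c(reasons, sprintf("%d movements > 0.5 mm (limit 5)", n05))
  structure(list(run_id = run$meta, tsnr = tsnr,
                 n_moves_gt_0p5mm = n05, n_moves_gt_0p1mm = n01,
                 excluded = length(reasons) > 0, reasons = reasons),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: tSNR %.3g, moves>0.5mm %d, moves>0.1mm %d -> %s\n",
              x$tsnr, x$n_moves_gt_0p5mm, x$n_moves_gt_0p1mm,
              if (x$excluded) "EXCLUDED" else "retained"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}
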