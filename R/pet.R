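#' SUV map container
#'
#' Per-unit FDG standardised uptake values for one session, raw or
#' whole-brain normalised (WBn-suv).
#'
#' @param values numeric vector of nonnegative uptake values, one per unit.
#' @param meta named list: subject, visit, condition.
#' @param normalized logical: are values whole-brain normalised?
#' @param space "voxel" or "parcel".
#' @param unit_weights optional per-unit weights used for weighted means in
#'   parcel space (voxel counts); NULL means equal weights.
#' @return object of class `suv_map`.
#' @export
suv_map <- function(values, meta = list(), normalized = FALSE,
                    space = c("voxel", "parcel"), unit_weights = NULL) {
  space <- match.arg(space)
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("SUV values must be finite and nonnegative")
  structure(list(values = values, meta = meta, normalized = normalized,
                 space = space, unit_weights = unit_weights),
            class = "suv_map")
}

#' @export
print.suv_map <- function(x, ...) {
  cat(sprintf("suv_map: %d %s units, %s (mean %.4f)\n", length(x$values),
              x$space, if (x$normalized) "WBn-normalized" else "raw",
              mean(x$values)))
  invisible(x)
}

suv_weights <- function(suv, mask) {
  if (is.null(suv$unit_weights)) rep(1, length(mask)) else suv$unit_weights[mask]
}

#' Whole-brain intensity normalisation of an SUV map
#'
#' Divides every unit by the (weighted) mean over the brain-mask units, so
#' the post-normalisation mask mean is exactly 1: the WBn-suv convention
#' with the arithmetic mean as the whole-brain reference statistic.
#' Idempotent and invariant to positive rescaling of the input.
#'
#' @param suv a `suv_map`.
#' @param brain_mask integer unit indices of the reference mask; defaults
#'   to all units.
#' @return the normalised `suv_map`.
#' @export
normalize_wbn <- function(suv, brain_mask = seq_along(suv$values)) {
  stopifnot(inherits(suv, "suv_map"))
  if (!length(brain_mask)) stop("empty brain mask")
  w <- suv_weights(suv, brain_mask)
  ref <- sum(suv$values[brain_mask] * w) / sum(w)
  if (!is.finite(ref) || ref <= 0)
    stop("whole-brain reference mean must be positive")
  suv$values <- suv$values / ref
  suv$normalized <- TRUE
  suv
}

#' ROI mean with an exclusion set
#'
#' Mean uptake over the ROI units minus the exclusion units (used for
#' network-level metabolism with the stimulated target excluded). Weighted
#' by unit weights in parcel space.
#'
#' @param suv a `suv_map` (normally WBn-normalised).
#' @param roi integer unit indices of the ROI.
#' @param exclude integer unit indices to remove (may be empty or overlap
#'   the ROI arbitrarily).
#' @return the mean over the remaining units; error if the exclusion
#'   empties the ROI.
#' @export
roi_mean_excluding <- function(suv, roi, exclude = integer(0)) {
  stopifnot(inherits(suv, "suv_map"))
  if (!length(roi)) stop("empty ROI")
  keep <- setdiff(roi, exclude)
  if (!length(keep)) stop("exclusion set empties the ROI")
  w <- suv_weights(suv, keep)
  sum(suv$values[keep] * w) / sum(w)
}

#' Per-subject, per-ROI changes in WBn-suv
#'
#' For each subject, ROI and condition contrast, the change
#' `delta = WBn-suv(condition) - WBn-suv(reference)`. Target ROIs use the
#' target sphere itself; network ROIs exclude a sphere of
#' `exclusion_radius_mm` around the stimulated target of the condition
#' being contrasted (the target-exclusion convention for network-level
#' analysis).
#'
#' @param suv_sessions nested list: `suv_sessions[[subject]][[session]]`
#'   where session names are "baseline", "SAL-TMS", "DN-TMS"; each entry a
#'   WBn-normalised `suv_map`.
#' @param rois named list of unit-index vectors shared across subjects
#'   (network ROIs, sgACC, ...).
#' @param target_units named list per subject: list(dn = units, sal =
#'   units) giving each subject's target spheres.
#' @param exclusion_units like `target_units` but the (larger) exclusion
#'   spheres used for network ROIs; defaults to the target spheres.
#' @param contrasts character vector among "SAL-TMS>baseline",
#'   "DN-TMS>baseline", "SAL-TMS>DN-TMS".
#' @return data.frame (class `delta_suv_table`) with columns subject, roi,
#'   contrast, delta.
#' @export
delta_suv_table <- function(suv_sessions, rois, target_units,
                            exclusion_units = NULL,
                            contrasts = c("SAL-TMS>baseline",
                                          "DN-TMS>baseline",
                                          "SAL-TMS>DN-TMS")) {
  if (is.null(exclusion_units)) exclusion_units <- target_units
  cond_of <- function(contrast) strsplit(contrast, ">", fixed = TRUE)[[1]]
  out <- list()
  for (subj in names(suv_sessions)) {
    maps <- suv_sessions[[subj]]
    tg <- target_units[[subj]]
    ex <- exclusion_units[[subj]]
    for (ct in contrasts) {
      cc <- cond_of(ct)
      for (s in cc) if (is.null(maps[[s]]))
        stop(sprintf("missing session '%s' for subject %s", s, subj))
      a <- maps[[cc[1]]]; b <- maps[[cc[2]]]
      if (!a$normalized || !b$normalized)
        stop("delta_suv_table expects WBn-normalised maps")
      # exclusion sphere of the stimulated condition (first term of contrast)
      excl <- if (cc[1] == "SAL-TMS") ex$sal else if (cc[1] == "DN-TMS") ex$dn
      rows <- list()
      for (rn in names(rois)) {
        d <- roi_mean_excluding(a, rois[[rn]], excl) -
          roi_mean_excluding(b, rois[[rn]], excl)
        rows[[rn]] <- data.frame(subject = subj, roi = rn, contrast = ct,
                                 delta = d)
      }
      for (tn in c("dn_target", "sal_target")) {
        u <- if (tn == "dn_target") tg$dn else tg$sal
        d <- roi_mean_excluding(a, u) - roi_mean_excluding(b, u)
        rows[[tn]] <- data.frame(subject = subj, roi = tn, contrast = ct,
                                 delta = d)
      }
      out[[paste(subj, ct)]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(!is.finite(res$delta))) stop("non-finite delta values")
  class(res) <- c("delta_suv_table", "data.frame")
  res
}
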