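#' Fisher z transform of a correlation
#'
#' `z = atanh(r)` after clipping `r` to +/-(1 - 1e-7) so the transform stays
#' finite at perfect correlation.
#'
#' @param r correlation(s) in \[-1, 1\].
#' @return Fisher z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation outside [-1, 1]")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Inverse Fisher z transform
#' @param z Fisher z value(s).
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Seed specification for seed-based FC
#'
#' A seed is a set of units (`kind = "sphere"` or `"region_set"`) whose
#' unweighted mean series is extracted, or a whole-map weight vector
#' (`kind = "map_weighted"`), as when an sgACC seed FC map is itself used
#' as the seed; weights are normalised to unit sum internally (by sum of
#' absolute values, preserving sign).
#'
#' @param kind "sphere", "region_set" or "map_weighted".
#' @param units integer unit indices (sphere / region_set).
#' @param weights numeric weight per unit of the run space (map_weighted).
#' @param name descriptive label.
#' @return object of class `seed_spec`.
#' @export
seed_spec <- function(kind = c("sphere", "region_set", "map_weighted"),
                      units = NULL, weights = NULL, name = "seed") {
  kind <- match.arg(kind)
  if (kind == "map_weighted") {
    if (is.null(weights) || all(weights == 0))
      stop("map_weighted seed needs nonzero weights")
  } else {
    if (is.null(units) || !length(units)) stop("seed unit set is empty")
    units <- as.integer(units)
  }
  structure(list(kind = kind, units = units, weights = weights, name = name),
            class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  n <- if (x$kind == "map_weighted") sum(x$weights != 0) else length(x$units)
  cat(sprintf("seed_spec '%s': %s over %d units\n", x$name, x$kind, n))
  invisible(x)
}

#' Extract the seed time course from a run
#'
#' Unweighted mean across seed units, or the weighted mean for map-weighted
#' seeds (weights normalised to sum of absolute values 1).
#'
#' @param run a `bold_run`.
#' @param seed a `seed_spec`.
#' @return numeric vector of length frames.
#' @export
extract_timecourse <- function(run, seed) {
  stopifnot(inherits(run, "bold_run"), inherits(seed, "seed_spec"))
  if (seed$kind == "map_weighted") {
    w <- seed$weights
    if (length(w) != ncol(run$data))
      stop("seed weight vector does not match run unit count")
    w <- w / sum(abs(w))
    as.numeric(run$data %*% w)
  } else {
    if (any(seed$units < 1L | seed$units > ncol(run$data)))
      stop("seed units outside run space")
    rowMeans(run$data[, seed$units, drop = FALSE])
  }
}

#' Nuisance regression with temporal derivatives
#'
#' Simultaneous least-squares regression, from every unit series, of an
#' intercept plus nine base regressors -- mean whole-brain signal, the six
#' rigid-body motion parameters, mean white-matter signal and mean
#' ventricular signal -- and their temporal derivatives (first differences,
#' first frame padded with 0): 19 design columns. Residuals are exactly
#' orthogonal to every design column.
#'
#' @param run a `bold_run` with a motion table.
#' @param atlas an `atlas` (used for default masks), or NULL if `masks` is
#'   given explicitly.
#' @param masks list with unit-index vectors `whole_brain`, `white_matter`,
#'   `ventricles`; defaults to [nuisance_masks()] for the run's space (in
#'   parcel space mask series are unit-count weighted, so the global signal
#'   matches the voxel-space definition). Tissue masks may be empty, in
#'   which case their regressors are omitted.
#' @return the residualised `bold_run`, with attribute `design_columns`
#'   recording the design column names.
#' @export
regress_nuisance <- function(run, atlas = NULL, masks = NULL) {
  stopifnot(inherits(run, "bold_run"))
  if (is.null(masks)) {
    if (is.null(atlas)) stop("need an atlas or explicit masks")
    masks <- nuisance_masks(atlas, run$space)
  }
  if (!length(masks$whole_brain)) stop("whole-brain mask is empty")
  if (is.null(run$motion)) stop("motion table required for nuisance regression")
  n <- nrow(run$data)
  wts <- attr(masks, "weights")
  msk_series <- function(units) {
    if (is.null(wts)) rowMeans(run$data[, units, drop = FALSE])
    else {
      w <- wts[units]
      as.numeric(run$data[, units, drop = FALSE] %*% (w / sum(w)))
    }
  }
  base <- list(whole_brain = msk_series(masks$whole_brain))
  mot <- as.matrix(run$motion)
  for (j in seq_len(ncol(mot))) base[[colnames(mot)[j]]] <- mot[, j]
  if (length(masks$white_matter))
    base$white_matter <- msk_series(masks$white_matter)
  if (length(masks$ventricles))
    base$ventricles <- msk_series(masks$ventricles)
  X <- do.call(cbind, base)
  dX <- rbind(0, diff(X))
  colnames(dX) <- paste0("d_", colnames(X))
  design <- cbind(intercept = rep(1, n), X, dX)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  run$data <- qr.resid(qrd, run$data)
  attr(run, "design_columns") <- colnames(design)
  run
}

#' Nuisance masks in the unit space of a run
#'
#' Voxel space: [atlas_masks()]. Parcel space: parcel indices, with a
#' `weights` attribute carrying the per-parcel voxel counts so that mask
#' mean series reproduce the voxel-space (unit-weighted) definitions.
#' @param atlas an `atlas`.
#' @param space "voxel" or "parcel".
#' @return list of index vectors `whole_brain`, `white_matter`,
#'   `ventricles`.
#' @export
nuisance_masks <- function(atlas, space = c("voxel", "parcel")) {
  space <- match.arg(space)
  if (space == "voxel") return(atlas_masks(atlas))
  pt <- parcel_table(atlas)
  out <- list(whole_brain = seq_len(nrow(pt)),
              white_matter = which(pt$region == "white_matter"),
              ventricles = which(pt$region == "ventricles"))
  attr(out, "weights") <- pt$n_units
  out
}

#' Denoise a run: nuisance regression then low-pass filtering
#'
#' Enforces the pipeline order regression -> temporal filtering.
#' @param run a `bold_run`.
#' @param atlas,masks see [regress_nuisance()].
#' @param cutoff_hz see [lowpass_filter()]; use NULL to skip filtering.
#' @return the denoised `bold_run`.
#' @export
denoise_run <- function(run, atlas = NULL, masks = NULL, cutoff_hz = 0.08) {
  run <- regress_nuisance(run, atlas, masks)
  if (!is.null(cutoff_hz)) run <- lowpass_filter(run, cutoff_hz)
  attr(run, "denoised") <- TRUE
  run
}

#' Seed-based FC map
#'
#' Fisher z of the Pearson correlation between the seed series and every
#' unit series. Zero-variance units are masked (NA) with a warning; units
#' inside the seed are reported via the `in_seed` attribute.
#'
#' @param run a denoised `bold_run`.
#' @param seed a `seed_spec`.
#' @return object of class `fc_map`: numeric vector of z values (one per
#'   unit) with attributes `seed` and `in_seed`.
#' @export
seed_fc_map <- function(run, seed) {
  s <- extract_timecourse(run, seed)
  if (stats::sd(s) == 0) stop("seed series has zero variance")
  v <- apply(run$data, 2, stats::sd)
  z <- rep(NA_real_, ncol(run$data))
  ok <- v > 0
  if (any(!ok)) warning(sprintf("%d zero-variance units masked", sum(!ok)))
  z[ok] <- fisher_z(as.numeric(stats::cor(s, run$data[, ok, drop = FALSE])))
  in_seed <- if (seed$kind == "map_weighted") which(seed$weights != 0) else seed$units
  structure(z, class = "fc_map", seed = seed, in_seed = in_seed)
}

#' Average FC maps (or z matrices) in z space
#'
#' Group averaging is performed on Fisher z values; averaging is linear, so
#' averaging averages of equal-sized halves equals the global mean.
#' @param maps list of numeric vectors/matrices of equal dimension.
#' @return elementwise mean, preserving attributes of the first element.
#' @export
average_fc <- function(maps) {
  stopifnot(length(maps) >= 1L)
  out <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  attributes(out) <- attributes(maps[[1]])
  out
}

#' Region-pair FC matrix
#'
#' Pair-wise Fisher z correlations of the mean signal within every cortical
#' region of the atlas (51 regions in the 7-network configuration), rows and
#' columns grouped by network. Runs are concatenated after per-run
#' standardisation of each region series. The diagonal is masked (NA).
#'
#' @param runs a `bold_run` or list of `bold_run`s from one session.
#' @param atlas an `atlas`.
#' @return object of class `fc_matrix`: symmetric numeric matrix of z
#'   values with region names as dimnames and attribute `parcels` (the
#'   region table used).
#' @export
fc_matrix <- function(runs, atlas) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1L)
  pt <- parcel_table(atlas, cortical_only = TRUE)
  if (any(pt$n_units == 0)) stop("region with no units: ",
                                 paste(pt$region[pt$n_units == 0], collapse = ", "))
  blocks <- lapply(runs, function(run) {
    m <- parcel_means(run, atlas, pt)
    scale(m)                               # per-run standardisation
  })
  x <- do.call(rbind, blocks)
  r <- stats::cor(x)
  z <- fisher_z(r)
  z <- (z + t(z)) / 2                      # enforce exact symmetry
  diag(z) <- NA_real_
  dimnames(z) <- list(pt$region, pt$region)
  structure(z, class = "fc_matrix", parcels = pt)
}

# frames x regions matrix of region-mean series for a run
parcel_means <- function(run, atlas, pt = parcel_table(atlas, cortical_only = TRUE)) {
  if (run$space == "parcel") {
    full <- parcel_table(atlas)
    idx <- match(pt$region, full$region)
    run$data[, idx, drop = FALSE]
  } else {
    vapply(pt$label, function(lab)
      rowMeans(run$data[, region_units(atlas, lab), drop = FALSE]),
      numeric(nrow(run$data)))
  }
}

#' @export
print.fc_matrix <- function(x, ...) {
  pt <- attr(x, "parcels")
  cat(sprintf("fc_matrix: %d x %d regions (%d networks), mean |z| %.3f\n",
              nrow(x), ncol(x), length(unique(pt$network)),
              mean(abs(x), na.rm = TRUE)))
  invisible(x)
}

#' Network-block summary of an FC (or delta-FC) matrix
#'
#' Mean z over all region pairs of one network against another (off-diagonal
#' entries only when the two networks coincide).
#' @param m an `fc_matrix` (or matrix with a `parcels` attribute).
#' @param net_a,net_b network names.
#' @param exclude_regions optional regions to drop from both blocks.
#' @return mean z over the block.
#' @export
fc_block_mean <- function(m, net_a, net_b, exclude_regions = NULL) {
  pt <- attr(m, "parcels")
  ia <- which(pt$network == net_a & !(pt$region %in% exclude_regions))
  ib <- which(pt$network == net_b & !(pt$region %in% exclude_regions))
  if (!length(ia) || !length(ib)) stop("unknown network in block summary")
  mean(unclass(m)[ia, ib], na.rm = TRUE)
}

#' Whole-network ROI pair Fisher z
#'
#' Fisher z correlation between the mean series of two whole-network ROIs
#' (unit-count weighted in parcel space), averaged across runs. This is
#' the quantity used for the DN-SAL network-pair FC change.
#'
#' @param runs a denoised `bold_run` or list of them.
#' @param atlas an `atlas`.
#' @param net_a,net_b network names.
#' @return mean Fisher z across runs.
#' @export
network_pair_z <- function(runs, atlas, net_a, net_b) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  ptc <- parcel_table(atlas, cortical_only = TRUE)
  wa <- ptc$n_units * (ptc$network == net_a)
  wb <- ptc$n_units * (ptc$network == net_b)
  if (!sum(wa) || !sum(wb)) stop("unknown network in pair z")
  mean(vapply(runs, function(run) {
    pm <- parcel_means(run, atlas, ptc)
    fisher_z(stats::cor(as.numeric(pm %*% (wa / sum(wa))),
                        as.numeric(pm %*% (wb / sum(wb)))))
  }, numeric(1)))
}

#' Gaussian smoothing of a voxel-space map or run
#'
#' Separable Gaussian blur on the atlas voxel grid with the given
#' full-width-at-half-maximum, mask-normalised so values are not diluted at
#' the brain edge. Only meaningful in voxel space; parcel-space inputs are
#' returned unchanged (parcel averaging already pools over space).
#'
#' @param values numeric vector (one value per atlas unit) or frames x units
#'   matrix.
#' @param atlas an `atlas`.
#' @param fwhm_mm kernel FWHM in mm; 0 returns the input unchanged.
#' @return smoothed values, same shape as the input.
#' @export
smooth_units <- function(values, atlas, fwhm_mm = 6) {
  if (fwhm_mm <= 0) return(values)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  dm <- atlas$dim
  idx <- atlas$units$index
  kern <- function(ax) {
    s <- sigma / atlas$voxel_size_mm[ax]
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k / sum(k)
  }
  ks <- lapply(1:3, kern)
  blur1 <- function(vol, ax) {
    k <- ks[[ax]]; half <- (length(k) - 1L) / 2L
    out <- array(0, dim(vol))
    for (o in seq_along(k)) {
      sh <- o - half - 1L
      src <- pmin(pmax(seq_len(dm[ax]) + sh, 1L), dm[ax]) # replicate edges
      out <- out + k[o] * switch(ax,
        vol[src, , , drop = FALSE], vol[, src, , drop = FALSE],
        vol[, , src, drop = FALSE])
    }
    out
  }
  blur <- function(v) {
    vol <- array(0, dm); msk <- array(0, dm)
    vol[idx] <- v; msk[idx] <- 1
    for (ax in 1:3) { vol <- blur1(vol, ax); msk <- blur1(msk, ax) }
    (vol / pmax(msk, 1e-12))[idx]
  }
  if (is.matrix(values)) t(apply(values, 1, blur)) else blur(as.numeric(values))
}
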