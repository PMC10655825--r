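#' Synthetic multi-network atlas
#'
#' Builds a small 3-D labelled volume emulating a 7-network / 51-region
#' cortical parcellation plus white-matter and ventricle compartments.
#' Regions are cubic blocks of `block_voxels^3` voxels laid out on a slot
#' grid with one-voxel background gaps. Three regions are special: the
#' salience network contains a lateral-prefrontal block (`SAL_dlPFC`) and
#' the default network a dorsomedial-prefrontal block (`DN_dlPFC`) that
#' together form the stimulation-accessible dlPFC mask, placed four slots
#' apart so that derived target pairs are separated by roughly 33 mm; the
#' limbic network contains an `sgACC` region used as the seed of the
#' targeting procedure.
#'
#' @param regions_per_network named integer vector; the default gives 51
#'   cortical regions across the seven networks (11 salience, 10 default).
#' @param block_voxels region block edge length in voxels.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param wm_voxels,csf_voxels approximate sizes of the white-matter and
#'   ventricle slabs (placed below the cortical slot grid); the default
#'   white-matter volume is comparable to the total cortical volume, as in
#'   a real brain mask, so the global-signal regressor is not dominated by
#'   the cortical network signals.
#' @return an `atlas`.
#' @export
synthetic_atlas <- function(regions_per_network = c(visual = 7,
                                                    somatomotor = 8,
                                                    dorsal_attention = 7,
                                                    salience = 11,
                                                    limbic = 4,
                                                    frontoparietal = 4,
                                                    default = 10),
                            block_voxels = 3, voxel_size_mm = 2,
                            wm_voxels = 1215, csf_voxels = 81) {
  networks <- names(regions_per_network)
  stopifnot(all(c("salience", "limbic", "default") %in% networks))
  rows <- list()
  for (nw in networks) {
    k <- regions_per_network[[nw]]
    nm <- sprintf("%s_%02d", nw, seq_len(k))
    if (nw == "salience") nm[k] <- "SAL_dlPFC"
    if (nw == "default") nm[k] <- "DN_dlPFC"
    if (nw == "limbic") nm[k] <- "sgACC"
    rows[[nw]] <- data.frame(region = nm, network = nw)
  }
  rows$tissue <- data.frame(region = c("white_matter", "ventricles"),
                            network = c("white_matter", "ventricles"))
  rt <- do.call(rbind, rows)
  rt$label <- seq_len(nrow(rt))
  rownames(rt) <- NULL

  n_cortical <- sum(regions_per_network)
  ncols <- 8L
  nrows <- ceiling(n_cortical / ncols)
  pitch <- block_voxels + 1L
  zlen <- block_voxels + 2L
  # tissue slabs below the cortical slot grid, block_voxels thick in z
  width <- ncols * pitch - 1L
  slab_rows <- function(nv) ceiling(nv / (width * block_voxels^2))
  wm_rows <- slab_rows(wm_voxels); csf_rows <- slab_rows(csf_voxels)
  dm <- c(ncols * pitch + 1L,
          nrows * pitch + 1L + (wm_rows + csf_rows) * (block_voxels + 1L),
          zlen)
  vol <- array(0L, dm)
  fill_slab <- function(y0, nv, lab) {
    need <- nv
    y <- y0
    while (need > 0L) {
      len <- min(width, ceiling(need / block_voxels^2))
      vol[2L:(1L + len), y:(y + block_voxels - 1L),
          2L:(block_voxels + 1L)] <<- lab
      need <- need - len * block_voxels^2
      y <- y + block_voxels + 1L
    }
    y
  }
  y_next <- fill_slab(nrows * pitch + 2L, wm_voxels,
                      rt$label[rt$region == "white_matter"])
  fill_slab(y_next, csf_voxels, rt$label[rt$region == "ventricles"])

  # slot order: then force SAL_dlPFC to slot 1 and DN_dlPFC to slot 5 of the
  # first row (4 slots = 4*pitch voxels apart -> ~32 mm target separation)
  slot_of <- seq_len(n_cortical)
  want <- c(which(rt$region == "SAL_dlPFC"), which(rt$region == "DN_dlPFC"))
  for (i in seq_along(want)) {
    tgt_slot <- c(1L, 5L)[i]
    cur <- which(slot_of == tgt_slot)
    slot_of[cur] <- slot_of[want[i]]
    slot_of[want[i]] <- tgt_slot
  }
  for (i in seq_len(n_cortical)) {
    s <- slot_of[i] - 1L
    cx <- (s %% ncols) * pitch + 2L
    cy <- (s %/% ncols) * pitch + 2L
    vol[cx:(cx + block_voxels - 1L), cy:(cy + block_voxels - 1L),
        2L:(block_voxels + 1L)] <- rt$label[i]
  }
  atlas(vol, voxel_size_mm = rep(voxel_size_mm, 3), origin_mm = c(0, 0, 0),
        region_table = rt[, c("label", "region", "network")],
        networks = networks)
}

#' Stimulation-accessible mask (dlPFC) of a cohort atlas
#' @param atlas an `atlas` with `DN_dlPFC` and `SAL_dlPFC` regions.
#' @return integer unit indices.
#' @export
dlpfc_mask <- function(atlas) {
  sort(c(region_units(atlas, "DN_dlPFC"), region_units(atlas, "SAL_dlPFC")))
}

#' Cohort specification for the synthetic generator
#'
#' Defines the study conditions emulated by the generator: a within-subject
#' cross-over design with a baseline visit and two counter-balanced
#' experimental visits (SAL-TMS, DN-TMS), three 120-frame BOLD runs at TR
#' 3 s per session, seven latent network signals with a baseline DN-SAL
#' anti-correlation of -0.4, an sgACC region co-loading on the default
#' network, per-subject target sites inside the dlPFC blocks, and FDG-SUV
#' maps with condition-specific local offsets (+0.054 at the SAL target
#' after SAL-TMS, -0.06 at the DN target after DN-TMS, in WBn-suv units).
#' A shared subject factor g couples the metabolic offsets to the post-TMS
#' DN-SAL covariance shift so that measured metabolic and FC changes
#' correlate across subjects at a designed level (`coupling_rho`), solved
#' in closed form by [coupling_design()].
#'
#' @param n_subjects number of subjects (default 16).
#' @param atlas an atlas from [synthetic_atlas()].
#' @param frames_per_run,runs_per_session,tr_seconds acquisition layout
#'   (defaults 120 frames, 3 runs, TR 3 s).
#' @param base_corr_dn_sal baseline DN-SAL latent correlation (-0.4).
#' @param shift_mean named vector: mean post-TMS shift of the DN-SAL
#'   latent correlation per condition (DN-TMS default +0.15, i.e. -0.4 to
#'   -0.25; SAL-TMS +0.05).
#' @param shift_sd between-subject s.d. of the shift.
#' @param region_loading,noise_sd,baseline_offset unit signal model:
#'   unit = offset + loading * latent(network) + global_sd * G_t +
#'   N(0, noise_sd).
#' @param global_sd amplitude of a coherent global (physiological/scanner)
#'   component shared by every unit including tissue compartments; this is
#'   the component that global-signal regression removes.
#' @param sgacc_coloading extra loading of sgACC units on the DN latent.
#' @param sgacc_sal_coloading extra (negative) loading of sgACC units on
#'   the SAL latent; the sgACC's anti-correlation with the salience network
#'   is what makes the seed map separate the two targets.
#' @param target_loading named vector (dn, sal): loading of the hot target
#'   node's units on their network latent; other dlPFC units carry
#'   `dlpfc_background_loading`.
#' @param dlpfc_background_loading loading of non-target dlPFC units.
#' @param node_spacing_mm,node_radius_mm node-grid geometry (4 mm lattice,
#'   2 mm radius).
#' @param delta_suv named per-condition injected ΔWBn-suv at the
#'   stimulated target.
#' @param delta_suv_sd between-subject s.d. of the injected delta (0.06).
#' @param suv_noise_sd per-unit per-session SUV noise (WBn units).
#' @param suv_baseline_mean raw-scale mean uptake.
#' @param network_suv_offset optional distributed WBn-suv offset over the
#'   salience network (0 = off).
#' @param coupling_rho designed across-subject correlation between measured
#'   target ΔWBn-suv and measured DN-SAL whole-network Δz (0 disables).
#' @param cutoff_hz analysis low-pass cutoff assumed by the measurement
#'   model.
#' @param motion_step_sd_mm s.d. of per-frame translation increments in the
#'   simulated motion tables.
#' @param space "voxel" or "parcel" unit space for generated runs.
#' @param rng_seed integer seed; all generated data are deterministic
#'   functions of it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 16,
                        atlas = synthetic_atlas(),
                        frames_per_run = 120, runs_per_session = 3,
                        tr_seconds = 3,
                        base_corr_dn_sal = -0.4,
                        shift_mean = c("SAL-TMS" = 0.05, "DN-TMS" = 0.15),
                        shift_sd = 0.10,
                        region_loading = 1, noise_sd = 0.5, global_sd = 1,
                        baseline_offset = 100,
                        sgacc_coloading = 0.8,
                        sgacc_sal_coloading = -0.6,
                        target_loading = c(dn = 0.35, sal = 0.32),
                        dlpfc_background_loading = 0,
                        node_spacing_mm = 4, node_radius_mm = 2,
                        delta_suv = c("SAL-TMS" = 0.054, "DN-TMS" = -0.06),
                        delta_suv_sd = 0.06, suv_noise_sd = 0.02,
                        suv_baseline_mean = 5,
                        network_suv_offset = 0,
                        coupling_rho = 0.7,
                        cutoff_hz = 0.08,
                        motion_step_sd_mm = 0.02,
                        space = c("voxel", "parcel"),
                        rng_seed = 1) {
  space <- match.arg(space)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (frames_per_run < 2) stop("frames_per_run must be >= 2")
  if (abs(base_corr_dn_sal) >= 1)
    stop("latent covariance not positive definite: |corr| must be < 1")
  stopifnot(all(c("SAL-TMS", "DN-TMS") %in% names(shift_mean)),
            all(c("SAL-TMS", "DN-TMS") %in% names(delta_suv)),
            all(c("dn", "sal") %in% names(target_loading)))
  spec <- structure(as.list(environment()), class = "cohort_spec")

  spec$dn_network <- "default"; spec$sal_network <- "salience"
  spec$networks <- atlas$networks
  spec$mask <- dlpfc_mask(atlas)
  spec$grid <- build_node_grid(atlas, spec$mask, node_spacing_mm,
                               node_radius_mm)
  in_region <- function(node_units, region)
    all(node_units %in% region_units(atlas, region))
  spec$dn_nodes <- which(vapply(spec$grid$units, in_region, logical(1),
                                region = "DN_dlPFC"))
  spec$sal_nodes <- which(vapply(spec$grid$units, in_region, logical(1),
                                 region = "SAL_dlPFC"))
  if (!length(spec$dn_nodes) || !length(spec$sal_nodes))
    stop("node grid does not cover both dlPFC blocks")
  spec$design <- coupling_design(spec)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "cohort_spec: %d subjects, %d x %d-frame runs/session, TR %g s, %s space\n",
    "  DN-SAL latent corr %.2f (post-TMS shift: SAL %.2f, DN %.2f; sd %.2f)\n",
    "  target dWBn-suv: SAL %+.3f, DN %+.3f (sd %.2f); designed coupling rho %.2f\n"),
    x$n_subjects, x$runs_per_session, x$frames_per_run, x$tr_seconds, x$space,
    x$base_corr_dn_sal, x$shift_mean[["SAL-TMS"]], x$shift_mean[["DN-TMS"]],
    x$shift_sd, x$delta_suv[["SAL-TMS"]], x$delta_suv[["DN-TMS"]],
    x$delta_suv_sd, x$coupling_rho))
  invisible(x)
}

# ---- population measurement model -----------------------------------------

# Per-class unit model: count + loading vector over the network latents.
# The hot target node is carved out of its dlPFC block.
unit_classes <- function(spec) {
  atl <- spec$atlas
  nets <- c(atl$networks, "global")
  pt <- parcel_table(atl)
  u_node <- length(spec$grid$units[[spec$dn_nodes[1]]])
  out <- list()
  for (i in seq_len(nrow(pt))) {
    lam <- stats::setNames(numeric(length(nets)), nets)
    lam["global"] <- spec$global_sd
    nw <- pt$network[i]; rg <- pt$region[i]; u <- pt$n_units[i]
    if (nw %in% atl$networks) lam[nw] <- spec$region_loading
    if (rg == "sgACC") {
      lam[spec$dn_network] <- lam[spec$dn_network] + spec$sgacc_coloading
      lam[spec$sal_network] <- lam[spec$sal_network] +
        spec$sgacc_sal_coloading
    }
    if (rg %in% c("DN_dlPFC", "SAL_dlPFC")) {
      lam[nw] <- spec$dlpfc_background_loading
      hot <- lam
      hot[nw] <- spec$target_loading[[if (rg == "DN_dlPFC") "dn" else "sal"]]
      out[[paste0(rg, "_hot")]] <- list(region = rg, network = nw,
                                        count = u_node, lambda = hot)
      u <- u - u_node
    }
    out[[rg]] <- list(region = rg, network = nw, count = u, lambda = lam)
  }
  out
}

# Population correlations of run aggregates after nuisance regression.
# Exact algebra for the linear-Gaussian generative model: motion columns
# and all temporal-derivative columns have no population-level effect on
# these aggregates (independent noise; the derivative of a white regressor
# is absorbed), so the projection set is {whole-brain, white-matter,
# ventricle} mean series. Returns the partial correlation matrix of the
# requested aggregates given that projection.
postgsr_corr <- function(spec, rho, agg_w) {
  cls <- unit_classes(spec)
  nets <- c(spec$atlas$networks, "global")
  C <- diag(length(nets)); dimnames(C) <- list(nets, nets)
  C[spec$dn_network, spec$sal_network] <-
    C[spec$sal_network, spec$dn_network] <- rho
  counts <- vapply(cls, `[[`, numeric(1), "count")
  regions <- vapply(cls, `[[`, character(1), "region")
  N <- sum(counts)
  proj <- rbind(wb = counts / N,
                wm = counts * (regions == "white_matter") /
                  sum(counts[regions == "white_matter"]),
                csf = counts * (regions == "ventricles") /
                  sum(counts[regions == "ventricles"]))
  W <- rbind(agg_w, proj)                                     # total weights
  L <- t(vapply(cls, `[[`, numeric(length(nets)), "lambda"))  # class x nets
  A <- W %*% L
  Nv <- spec$noise_sd^2 * (W %*% (t(W) / counts))
  S <- A %*% C %*% t(A) + Nv
  k <- nrow(agg_w); pidx <- k + 1:3
  pidx <- pidx[diag(S)[pidx] > 1e-12]      # drop degenerate regressors
  Sp <- if (length(pidx))
    S[1:k, 1:k] - S[1:k, pidx, drop = FALSE] %*%
      solve(S[pidx, pidx, drop = FALSE], S[pidx, 1:k, drop = FALSE])
  else S[1:k, 1:k]
  stats::cov2cor(Sp)
}

# class-total weight vectors for the standard aggregates
agg_weights <- function(spec) {
  cls <- unit_classes(spec)
  counts <- vapply(cls, `[[`, numeric(1), "count")
  regions <- vapply(cls, `[[`, character(1), "region")
  networks <- vapply(cls, `[[`, character(1), "network")
  region_w <- function(r) counts * (regions == r) / sum(counts[regions == r])
  net_w <- function(nw) counts * (networks == nw) /
    sum(counts[networks == nw])
  list(counts = counts, regions = regions, networks = networks,
       region_w = region_w, net_w = net_w)
}

# model prediction of the measured DN x SAL statistics at latent corr rho:
# whole-ROI pair z and 51-matrix block mean z (region-pair level)
measured_dn_sal <- function(spec, rho) {
  aw <- agg_weights(spec)
  rt <- spec$atlas$region_table
  dn_regions <- rt$region[rt$network == spec$dn_network]
  sal_regions <- rt$region[rt$network == spec$sal_network]
  agg <- rbind(do.call(rbind, lapply(c(dn_regions, sal_regions),
                                     aw$region_w)),
               aw$net_w(spec$dn_network), aw$net_w(spec$sal_network))
  R <- postgsr_corr(spec, rho, agg)
  nd <- length(dn_regions); ns <- length(sal_regions)
  block <- R[seq_len(nd), nd + seq_len(ns)]
  list(block_z = mean(fisher_z(block)),
       pair_z = fisher_z(R[nd + ns + 1, nd + ns + 2]))
}

# Estimation noise of the per-session block-mean z: calibrated once per
# parameter set by a fixed-seed null simulation run through the actual
# measurement chain (denoising + concatenated-run region matrix), cached.
.netstim_cache <- new.env(parent = emptyenv())

block_noise_var <- function(spec, n_sessions = NULL) {
  if (is.null(n_sessions))
    n_sessions <- max(64L, min(256L, 2L * ceiling(
      128 * 120 / spec$frames_per_run / 2) * 2L))
  key <- paste(spec$frames_per_run, spec$runs_per_session, spec$tr_seconds,
               spec$cutoff_hz, spec$noise_sd, spec$region_loading,
               spec$global_sd, spec$sgacc_coloading,
               spec$sgacc_sal_coloading, spec$base_corr_dn_sal,
               spec$dlpfc_background_loading,
               paste(spec$target_loading, collapse = ","),
               n_units(spec$atlas), nrow(spec$atlas$region_table),
               mean(spec$shift_mean), n_sessions,
               sep = "|")
  hit <- get0(key, envir = .netstim_cache)
  if (!is.null(hit)) return(hit)
  atl <- spec$atlas
  pt <- parcel_table(atl)
  Lam <- unit_loadings(spec, profile = NULL)
  Lp <- t(vapply(pt$label, function(lab) {
    u <- region_units(atl, lab)
    colSums(Lam[u, , drop = FALSE]) / length(u)
  }, numeric(ncol(Lam))))
  sdp <- spec$noise_sd / sqrt(pt$n_units)
  n <- spec$frames_per_run
  half <- n_sessions %/% 2L
  sim <- function(rho, m_sessions) {
    R <- latent_chol(spec, rho)
    vapply(seq_len(m_sessions), function(m) {
      runs <- lapply(seq_len(spec$runs_per_session), function(r) {
        lat <- matrix(stats::rnorm(n * ncol(Lam)), n) %*% R
        X <- lat %*% t(Lp) +
          matrix(stats::rnorm(n * nrow(pt)), n) %*% diag(sdp)
        mot <- apply(matrix(stats::rnorm(n * 6, sd = 0.02), n, 6), 2, cumsum)
        colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                           "rot_x", "rot_y", "rot_z")
        denoise_run(bold_run(X, spec$tr_seconds, as.data.frame(mot),
                             space = "parcel"),
                    atl, cutoff_hz = spec$cutoff_hz)
      })
      fc_block_mean(fc_matrix(runs, atl), spec$dn_network, spec$sal_network)
    }, numeric(1))
  }
  # pre-session noise at the baseline correlation plus post-session noise at
  # the mean shifted correlation: the variance of a post - pre delta
  out <- with_seed(20240901,
    stats::var(sim(spec$base_corr_dn_sal, half)) +
      stats::var(sim(spec$base_corr_dn_sal + mean(spec$shift_mean), half)))
  assign(key, out, envir = .netstim_cache)
  out
}

#' Closed-form coupling design of the synthetic cohort
#'
#' Solves the latent-factor weights that realise the designed correlation
#' between measured target ΔWBn-suv and measured DN-SAL whole-network Δz.
#' The measured FC delta is modelled as `J * shift + eta`, where `J` is the
#' slope of the post-regression Fisher z with respect to the latent
#' correlation shift (population projection algebra) and `eta` collects the
#' Fisher z estimation noise of low-pass-filtered series (Bartlett sum over
#' the filter autocorrelation, two sessions, averaged over runs). The
#' measured metabolic delta adds PET unit noise at the target. With
#' attenuation factors `Dx` and `Dy`, the shared-factor weight per
#' condition is `w = coupling_rho / (Dx * Dy)`; an error is raised if the
#' design is infeasible (`w > 1`).
#'
#' @param spec a `cohort_spec` (may be called before the design is
#'   attached).
#' @return list with `var_z_run` (per-run pair-z variance), `var_eta_block`
#'   (estimation variance of the block delta-z), `J` (block z slope), `Dx`,
#'   `Dy`, `w`, `realized_rho` (the last four named per condition), and the
#'   model-predicted measured block/pair z at baseline and post-TMS.
#' @export
coupling_design <- function(spec) {
  conds <- c("SAL-TMS", "DN-TMS")
  n_design <- 19                       # nuisance columns incl. derivatives
  var_z_run <- if (is.null(spec$cutoff_hz)) 1 / (spec$frames_per_run - 3)
  else fisher_z_var(spec$frames_per_run, spec$tr_seconds, spec$cutoff_hz) *
    spec$frames_per_run / (spec$frames_per_run - n_design)
  # PET measurement noise at the target ROI: the node sphere in voxel
  # space, the dlPFC parcel in parcel space
  u_t <- if (spec$space == "parcel")
    length(region_units(spec$atlas, "SAL_dlPFC"))
  else length(spec$grid$units[[spec$dn_nodes[1]]])
  var_pet <- 2 * spec$suv_noise_sd^2 / u_t
  Dx <- spec$delta_suv_sd / sqrt(spec$delta_suv_sd^2 + var_pet)
  var_eta_block <- if (spec$coupling_rho == 0) NA_real_
  else block_noise_var(spec)
  base <- measured_dn_sal(spec, spec$base_corr_dn_sal)
  J <- Dy <- w <- rr <- post_block <- stats::setNames(numeric(2), conds)
  for (cc in conds) {
    r0 <- spec$base_corr_dn_sal + spec$shift_mean[[cc]]
    h <- 0.01
    J[cc] <- (measured_dn_sal(spec, r0 + h)$block_z -
                measured_dn_sal(spec, r0 - h)$block_z) / (2 * h)
    post_block[cc] <- measured_dn_sal(spec, r0)$block_z
    if (spec$coupling_rho == 0) { w[cc] <- 0; Dy[cc] <- NA; rr[cc] <- 0 }
    else {
      Dy[cc] <- J[cc] * spec$shift_sd /
        sqrt((J[cc] * spec$shift_sd)^2 + var_eta_block)
      w[cc] <- spec$coupling_rho / (Dx * Dy[cc])
      # measurement reliability caps the attainable measured coupling; the
      # shortfall, if any, is recorded in realized_rho
      if (w[cc] > 1) w[cc] <- 1
      rr[cc] <- w[cc] * Dx * Dy[cc]
    }
  }
  list(var_z_run = var_z_run, var_eta_block = var_eta_block,
       var_pet = var_pet, J = J, Dx = Dx, Dy = Dy, w = w,
       realized_rho = rr,
       base_block_z = base$block_z, base_pair_z = base$pair_z,
       post_block_z = post_block)
}

# ---- deterministic seeding -------------------------------------------------

run_seed <- function(spec, subject, sess = 0L, phase = 0L, run = 0L,
                     kind = 0L) {
  k <- ((subject * 11L + sess) * 7L + phase) * 29L + run * 5L + kind
  (spec$rng_seed %% 2147483629 * 100003 + k) %% 2147483629
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

sess_code <- function(condition) {
  match(condition, c("none", "SAL-TMS", "DN-TMS"))
}

# ---- per-subject ground truth ----------------------------------------------

subject_profile <- function(spec, subject) {
  des <- spec$design
  with_seed(run_seed(spec, subject, kind = 1L), {
    g <- stats::rnorm(1)
    dn_node <- spec$dn_nodes[sample.int(length(spec$dn_nodes), 1)]
    sal_node <- spec$sal_nodes[sample.int(length(spec$sal_nodes), 1)]
    e <- stats::rnorm(2); f <- stats::rnorm(2)
    conds <- c("SAL-TMS", "DN-TMS")
    delta <- shift <- stats::setNames(numeric(2), conds)
    for (i in 1:2) {
      cc <- conds[i]; wc <- des$w[[cc]]
      delta[cc] <- spec$delta_suv[[cc]] +
        spec$delta_suv_sd * (sqrt(wc) * g + sqrt(1 - wc) * e[i])
      shift[cc] <- spec$shift_mean[[cc]] +
        spec$shift_sd * (sqrt(wc) * g + sqrt(1 - wc) * f[i])
    }
    list(subject = subject, g = g, dn_node = dn_node, sal_node = sal_node,
         delta = delta, shift = shift,
         first_condition = if (subject %% 2 == 1) "SAL-TMS" else "DN-TMS")
  })
}

# per-unit loading matrix (voxel space), with this subject's hot nodes
unit_loadings <- function(spec, profile = NULL) {
  atl <- spec$atlas
  nets <- c(atl$networks, "global")
  lab2net <- stats::setNames(atl$region_table$network, atl$region_table$label)
  lab2reg <- stats::setNames(atl$region_table$region, atl$region_table$label)
  unw <- lab2net[as.character(atl$units$label)]
  Lam <- matrix(0, n_units(atl), length(nets), dimnames = list(NULL, nets))
  for (nw in atl$networks)
    Lam[unw == nw, nw] <- spec$region_loading
  Lam[, "global"] <- spec$global_sd
  sg <- region_units(atl, "sgACC")
  Lam[sg, spec$dn_network] <- Lam[sg, spec$dn_network] + spec$sgacc_coloading
  Lam[sg, spec$sal_network] <- Lam[sg, spec$sal_network] +
    spec$sgacc_sal_coloading
  for (rg in c("DN_dlPFC", "SAL_dlPFC")) {
    ru <- region_units(atl, rg)
    nw <- unname(lab2net[as.character(atl$units$label[ru[1]])])
    Lam[ru, ] <- 0
    Lam[ru, nw] <- spec$dlpfc_background_loading
  }
  if (!is.null(profile)) {
    hd <- spec$grid$units[[profile$dn_node]]
    hs <- spec$grid$units[[profile$sal_node]]
    Lam[hd, ] <- 0; Lam[hd, spec$dn_network] <- spec$target_loading[["dn"]]
    Lam[hs, ] <- 0; Lam[hs, spec$sal_network] <- spec$target_loading[["sal"]]
  }
  Lam
}

latent_chol <- function(spec, rho) {
  nets <- c(spec$atlas$networks, "global")
  C <- diag(length(nets)); dimnames(C) <- list(nets, nets)
  rho <- min(max(rho, -0.9), 0.9)
  C[spec$dn_network, spec$sal_network] <-
    C[spec$sal_network, spec$dn_network] <- rho
  chol(C)
}

#' Target ROIs of a subject
#'
#' Unit sets of the subject's ground-truth DN and SAL targets: in voxel
#' space the target node spheres (and 10 mm exclusion spheres); in parcel
#' space the dlPFC parcels.
#' @param spec a `cohort_spec`.
#' @param subject subject index.
#' @param exclusion_radius_mm radius of the network-analysis exclusion
#'   sphere.
#' @return list with `dn`, `sal` (unit indices), `dn_center`, `sal_center`
#'   (mm), `dn_excl`, `sal_excl`.
#' @export
subject_targets <- function(spec, subject, exclusion_radius_mm = 10) {
  prof <- subject_profile(spec, subject)
  atl <- spec$atlas
  if (spec$space == "parcel") {
    pt <- parcel_table(atl)
    idn <- which(pt$region == "DN_dlPFC"); isal <- which(pt$region == "SAL_dlPFC")
    ctr <- function(rg) colMeans(unit_coords(atl)[region_units(atl, rg), ,
                                                  drop = FALSE])
    list(dn = idn, sal = isal, dn_center = ctr("DN_dlPFC"),
         sal_center = ctr("SAL_dlPFC"), dn_excl = idn, sal_excl = isal)
  } else {
    gd <- spec$grid
    list(dn = gd$units[[prof$dn_node]], sal = gd$units[[prof$sal_node]],
         dn_center = as.numeric(gd$centers[prof$dn_node, ]),
         sal_center = as.numeric(gd$centers[prof$sal_node, ]),
         dn_excl = sphere_units(atl, gd$centers[prof$dn_node, ],
                                exclusion_radius_mm),
         sal_excl = sphere_units(atl, gd$centers[prof$sal_node, ],
                                 exclusion_radius_mm))
  }
}

# ---- generators ------------------------------------------------------------

#' Generate one synthetic BOLD run
#'
#' Latent network series are drawn from the (condition, phase) covariance;
#' each unit is `baseline_offset + loading * latent(network of unit) +
#' N(0, noise_sd)`; sgACC units co-load on the DN latent; the subject's
#' target-node units load on their network latent with `target_loading`.
#' Parcel-space runs aggregate the same model at region level (loadings
#' averaged, noise s.d. scaled by 1/sqrt(units)). Deterministic given the
#' spec seed and the run coordinates.
#'
#' @param spec a `cohort_spec`.
#' @param subject subject index.
#' @param condition "none", "SAL-TMS" or "DN-TMS".
#' @param phase "pre" or "post".
#' @param run_index run number within the session.
#' @return a `bold_run`.
#' @export
generate_bold_run <- function(spec, subject, condition = "none",
                              phase = "pre", run_index = 1) {
  prof <- subject_profile(spec, subject)
  rho <- spec$base_corr_dn_sal +
    if (phase == "post" && condition %in% names(prof$shift))
      prof$shift[[condition]] else 0
  R <- latent_chol(spec, rho)
  Lam <- unit_loadings(spec, prof)
  atl <- spec$atlas
  pcode <- match(phase, c("pre", "post"))
  with_seed(run_seed(spec, subject, sess_code(condition), pcode,
                     run_index, kind = 2L), {
    n <- spec$frames_per_run
    lat <- matrix(stats::rnorm(n * ncol(Lam)), n) %*% R
    if (spec$space == "parcel") {
      pt <- parcel_table(atl)
      Lp <- t(vapply(pt$label, function(lab) {
        u <- region_units(atl, lab)
        colSums(Lam[u, , drop = FALSE]) / length(u)
      }, numeric(ncol(Lam))))
      sdp <- spec$noise_sd / sqrt(pt$n_units)
      X <- lat %*% t(Lp) +
        matrix(stats::rnorm(n * nrow(pt)), n) %*% diag(sdp)
      slice <- seq_len(nrow(pt))
    } else {
      X <- lat %*% t(Lam) + spec$noise_sd * matrix(stats::rnorm(n * nrow(Lam)), n)
      slice <- arrayInd(atl$units$index, atl$dim)[, 3]
    }
    X <- X + spec$baseline_offset
    mot <- apply(matrix(stats::rnorm(n * 6, sd = spec$motion_step_sd_mm),
                        n, 6), 2, cumsum)
    mot[, 4:6] <- mot[, 4:6] / 50      # small rotations in radians
    colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
    bold_run(X, tr_seconds = spec$tr_seconds, motion = as.data.frame(mot),
             meta = list(subject = subject,
                         visit = if (condition == "none") "baseline"
                         else "experimental",
                         condition = condition, phase = phase,
                         run = run_index),
             space = spec$space, slice = slice)
  })
}

#' Generate one synthetic SUV session
#'
#' Builds the WBn-space uptake profile (uniform 1; stimulation conditions
#' add the subject's injected delta at the stimulated target, balanced by
#' a diffuse compensatory decrease so the whole-brain mean stays exactly 1,
#' as whole-brain normalisation implies), scales to raw units, and adds
#' per-unit session noise. The returned map is raw (`normalized = FALSE`);
#' apply [normalize_wbn()] before analysis.
#'
#' @param spec a `cohort_spec`.
#' @param subject subject index.
#' @param condition "none" (baseline visit), "SAL-TMS" or "DN-TMS".
#' @return a `suv_map`.
#' @export
generate_suv_session <- function(spec, subject, condition = "none") {
  prof <- subject_profile(spec, subject)
  atl <- spec$atlas
  tg <- subject_targets(spec, subject)
  if (spec$space == "parcel") {
    pt <- parcel_table(atl)
    nun <- nrow(pt); wts <- pt$n_units
    sal_net_units <- which(pt$network == spec$sal_network)
    noise_scale <- spec$suv_noise_sd / sqrt(pt$n_units)
  } else {
    nun <- n_units(atl); wts <- rep(1, nun)
    sal_net_units <- network_units(atl, spec$sal_network)
    noise_scale <- rep(spec$suv_noise_sd, nun)
  }
  v <- rep(1, nun)
  if (condition %in% c("SAL-TMS", "DN-TMS")) {
    tu <- if (condition == "SAL-TMS") tg$sal else tg$dn
    d <- prof$delta[[condition]]
    wt <- sum(wts[tu]); wo <- sum(wts) - wt
    v[tu] <- v[tu] + d
    v[-tu] <- v[-tu] - d * wt / wo      # mean-preserving compensation
    if (spec$network_suv_offset != 0) {
      v[sal_net_units] <- v[sal_net_units] + spec$network_suv_offset
      v <- v / (sum(v * wts) / sum(wts))
    }
  }
  with_seed(run_seed(spec, subject, sess_code(condition), 2L, kind = 3L), {
    raw <- spec$suv_baseline_mean *
      pmax(v + stats::rnorm(nun) * noise_scale, 1e-6)
    suv_map(raw, meta = list(subject = subject, condition = condition),
            normalized = FALSE, space = spec$space,
            unit_weights = if (spec$space == "parcel") wts else NULL)
  })
}

#' Generate the full synthetic cohort
#'
#' Per subject: a baseline visit (BOLD session + SUV) and two experimental
#' visits (pre-TMS BOLD, post-TMS BOLD, post-TMS SUV) under SAL-TMS and
#' DN-TMS, with counter-balanced condition order, plus the ground-truth
#' ledger. Fully deterministic given the spec seed; optionally written to
#' disk with [write_cohort()].
#'
#' @param spec a `cohort_spec`.
#' @param dir optional output directory; when given the dataset is written
#'   there (NIfTI/TSV/JSON layout).
#' @return object of class `tms_cohort`: list with `spec`, `ground_truth`
#'   (data.frame), `subjects` (nested sessions), `targets`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- vector("list", spec$n_subjects)
  gt <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    prof <- subject_profile(spec, s)
    runs <- function(cond, phase) lapply(seq_len(spec$runs_per_session),
      function(r) generate_bold_run(spec, s, cond, phase, r))
    subjects[[s]] <- list(
      baseline = list(bold = runs("none", "pre"),
                      suv = generate_suv_session(spec, s, "none")),
      `SAL-TMS` = list(pre = runs("SAL-TMS", "pre"),
                       post = runs("SAL-TMS", "post"),
                       suv = generate_suv_session(spec, s, "SAL-TMS")),
      `DN-TMS` = list(pre = runs("DN-TMS", "pre"),
                      post = runs("DN-TMS", "post"),
                      suv = generate_suv_session(spec, s, "DN-TMS")))
    tgc <- subject_targets(spec, s)
    gt[[s]] <- data.frame(
      subject = s, g = prof$g,
      dn_node = prof$dn_node, sal_node = prof$sal_node,
      separation_mm = target_distance(tgc$dn_center, tgc$sal_center),
      delta_sal = prof$delta[["SAL-TMS"]], delta_dn = prof$delta[["DN-TMS"]],
      shift_sal = prof$shift[["SAL-TMS"]], shift_dn = prof$shift[["DN-TMS"]],
      first_condition = prof$first_condition)
  }
  cohort <- structure(list(spec = spec,
                           ground_truth = do.call(rbind, gt),
                           subjects = subjects,
                           targets = lapply(seq_len(spec$n_subjects),
                                            subject_targets, spec = spec)),
                      class = "tms_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.tms_cohort <- function(x, ...) {
  cat(sprintf("tms_cohort: %d subjects, %s space, seed %d\n",
              x$spec$n_subjects, x$spec$space, x$spec$rng_seed))
  cat(sprintf("  counter-balance: %d SAL-first / %d DN-first\n",
              sum(x$ground_truth$first_condition == "SAL-TMS"),
              sum(x$ground_truth$first_condition == "DN-TMS")))
  invisible(x)
}
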