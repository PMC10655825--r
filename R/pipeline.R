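#' Pipeline configuration
#'
#' Validated configuration for the end-to-end analysis. Unknown fields are
#' rejected (constructing from a JSON/YAML list with an unrecognised key is
#' an error). The defaults mirror the study analysis: sgACC seed radius
#' 10 mm, 0.08 Hz low-pass, 4 mm node lattice with 2 mm node radius, 10 mm
#' target-exclusion spheres, two-sided paired tests, sign-flipping
#' permutation max-T for family-wise-corrected maps.
#'
#' @param cohort_spec a [cohort_spec()] describing the (synthetic) input
#'   cohort.
#' @param sgacc_radius_mm radius of the sgACC seed sphere; the seed region
#'   itself is the atlas `sgACC` block.
#' @param cutoff_hz low-pass cutoff.
#' @param smoothing_fwhm_mm Gaussian FWHM applied to voxel-space FC maps
#'   (0 disables; parcel space never smooths).
#' @param grid_spacing_mm,node_radius_mm node-grid geometry for targeting.
#' @param exclusion_radius_mm radius of the sphere excluded around the
#'   stimulated target in network-level PET analysis.
#' @param qc_tsnr_sd,qc_max_moves QC thresholds: exclude a run when tSNR <
#'   group mean - `qc_tsnr_sd` * sd, or when more than `qc_max_moves`
#'   relative movements exceed 0.5 mm.
#' @param contrasts PET contrasts to compute.
#' @param n_permutations,alpha permutation max-T configuration.
#' @param subgroup_k divergent-subgroup size (skipped when n < 2k).
#' @param out_dir optional output directory for staged TSV/JSON products.
#' @param rng_seed seed for the permutation stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_spec,
                            sgacc_radius_mm = 10,
                            cutoff_hz = 0.08,
                            smoothing_fwhm_mm = 6,
                            grid_spacing_mm = 4,
                            node_radius_mm = 2,
                            exclusion_radius_mm = 10,
                            qc_tsnr_sd = 2,
                            qc_max_moves = 5,
                            contrasts = c("SAL-TMS>baseline",
                                          "DN-TMS>baseline",
                                          "SAL-TMS>DN-TMS"),
                            n_permutations = 1000,
                            alpha = 0.05,
                            subgroup_k = 5,
                            out_dir = NULL,
                            rng_seed = 1) {
  if (missing(cohort_spec) || !inherits(cohort_spec, "cohort_spec"))
    stop("pipeline_config needs a cohort_spec")
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  stopifnot(cutoff_hz > 0, exclusion_radius_mm >= 0, n_permutations >= 1,
            alpha > 0, alpha < 1)
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort generation, QC (tSNR + motion exclusion),
#' denoising (nuisance regression then low-pass), target derivation from
#' the baseline visit (voxel space: two-stage sgACC-map seeding over the
#' node grid; parcel space: the dlPFC parcels stand in for targets),
#' session FC matrices and DN-SAL whole-network pair z, WBn-suv deltas
#' with target exclusion, group statistics (paired t / Cohen's d, matrix
#' comparisons, permutation max-T over the parcel delta map), metabolic-FC
#' coupling and the divergent-subgroup subanalysis, and a report. Staged
#' outputs and a manifest are written when `out_dir` is set. Re-running
#' with an identical configuration and seed reproduces identical tables.
#'
#' @param config a `pipeline_config`.
#' @return object of class `netstim_run` with elements `qc`, `targets`,
#'   `fc`, `pet`, `stats`, `coupling`, `report`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$cohort_spec
  atl <- spec$atlas
  res <- list(config = config)

  stage <- function(nm) message(sprintf("[netstim] stage: %s", nm))

  stage("simulate")
  cohort <- generate_cohort(spec)

  stage("qc")
  sessions_of <- function(sub)
    list(baseline = sub$baseline$bold,
         sal_pre = sub$`SAL-TMS`$pre, sal_post = sub$`SAL-TMS`$post,
         dn_pre = sub$`DN-TMS`$pre, dn_post = sub$`DN-TMS`$post)
  nested <- lapply(cohort$subjects, sessions_of)
  all_runs <- unlist(nested, recursive = FALSE)
  all_runs <- do.call(c, unname(all_runs))
  tsnrs <- vapply(all_runs, function(r) as.numeric(compute_tsnr(r)),
                  numeric(1))
  gm <- mean(tsnrs); gs <- stats::sd(tsnrs)
  qc <- lapply(all_runs, qc_run, group_tsnr_mean = gm, group_tsnr_sd = gs)
  # drop excluded runs; a subject is excluded only when a whole session
  # becomes unusable
  kept_sessions <- lapply(nested, function(ss)
    lapply(ss, function(runs)
      Filter(function(run) !qc_run(run, gm, gs)$excluded, runs)))
  excl_subj <- which(vapply(kept_sessions, function(ss)
    any(lengths(ss) == 0L), logical(1)))
  keep_subj <- setdiff(seq_along(cohort$subjects), excl_subj)
  if (!length(keep_subj)) {
    res$qc <- list(reports = qc, group_mean = gm, group_sd = gs,
                   n_runs_excluded = sum(vapply(qc, `[[`, logical(1),
                                                "excluded")),
                   excluded_subjects = excl_subj,
                   analyzed_subjects = integer(0))
    res$report <- c("netstim report", "zero analyzable subjects after QC")
    class(res) <- "netstim_run"
    return(res)
  }
  res$qc <- list(reports = qc, group_mean = gm, group_sd = gs,
                 n_runs_excluded = sum(vapply(qc, `[[`, logical(1),
                                              "excluded")),
                 excluded_subjects = excl_subj,
                 analyzed_subjects = keep_subj)

  stage("denoise")
  den <- lapply(keep_subj, function(s)
    lapply(kept_sessions[[s]], function(runs)
      lapply(runs, denoise_run, atlas = atl, cutoff_hz = config$cutoff_hz)))
  names(den) <- keep_subj

  stage("targets")
  targets <- lapply(seq_along(keep_subj), function(i) {
    s <- keep_subj[i]
    if (spec$space == "voxel") {
      grid <- build_node_grid(atl, dlpfc_mask(atl), config$grid_spacing_mm,
                              config$node_radius_mm)
      sg_seed <- seed_spec("region_set", units = region_units(atl, "sgACC"),
                           name = "sgACC")
      wmap <- average_fc(lapply(den[[i]]$baseline, seed_fc_map,
                                seed = sg_seed))
      w <- unclass(wmap); w[grid$mask] <- 0       # dlPFC exclusion
      tp <- derive_targets(den[[i]]$baseline,
                           seed_spec("map_weighted", weights = w,
                                     name = "sgACC FC map"),
                           grid)
      tp$identity <- list(
        dn = confirm_network_identity(den[[i]]$baseline,
                                      tp$dn_target$center_mm, atl,
                                      config$node_radius_mm),
        sal = confirm_network_identity(den[[i]]$baseline,
                                       tp$sal_target$center_mm, atl,
                                       config$node_radius_mm))
      tg <- list(dn = tp$grid$units[[tp$dn_target$node_id]],
                 sal = tp$grid$units[[tp$sal_target$node_id]],
                 dn_center = tp$dn_target$center_mm,
                 sal_center = tp$sal_target$center_mm,
                 dn_excl = sphere_units(atl, tp$dn_target$center_mm,
                                        config$exclusion_radius_mm),
                 sal_excl = sphere_units(atl, tp$sal_target$center_mm,
                                         config$exclusion_radius_mm))
      list(pair = tp, units = tg)
    } else {
      list(pair = NULL,
           units = subject_targets(spec, s, config$exclusion_radius_mm))
    }
  })

  stage("fc")
  pair_z <- function(runs)
    network_pair_z(runs, atl, spec$dn_network, spec$sal_network)
  fc <- lapply(seq_along(keep_subj), function(i) {
    list(mat_baseline = fc_matrix(den[[i]]$baseline, atl),
         mat_sal_pre = fc_matrix(den[[i]]$sal_pre, atl),
         mat_sal_post = fc_matrix(den[[i]]$sal_post, atl),
         mat_dn_pre = fc_matrix(den[[i]]$dn_pre, atl),
         mat_dn_post = fc_matrix(den[[i]]$dn_post, atl),
         pairz = c(baseline = pair_z(den[[i]]$baseline),
                   sal_pre = pair_z(den[[i]]$sal_pre),
                   sal_post = pair_z(den[[i]]$sal_post),
                   dn_pre = pair_z(den[[i]]$dn_pre),
                   dn_post = pair_z(den[[i]]$dn_post)))
  })
  res$fc <- fc

  stage("pet")
  rois <- stats::setNames(
    lapply(spec$networks, function(nw)
      if (spec$space == "voxel") network_units(atl, nw)
      else which(parcel_table(atl)$network == nw)),
    spec$networks)
  rois$sgACC <- if (spec$space == "voxel") region_units(atl, "sgACC")
  else which(parcel_table(atl)$region == "sgACC")
  suv_sessions <- lapply(keep_subj, function(s) {
    sub <- cohort$subjects[[s]]
    list(baseline = normalize_wbn(sub$baseline$suv),
         `SAL-TMS` = normalize_wbn(sub$`SAL-TMS`$suv),
         `DN-TMS` = normalize_wbn(sub$`DN-TMS`$suv))
  })
  names(suv_sessions) <- as.character(keep_subj)
  tunits <- lapply(targets, `[[`, "units")
  names(tunits) <- as.character(keep_subj)
  pet <- delta_suv_table(suv_sessions, rois, tunits,
                         exclusion_units = lapply(tunits, function(t)
                           list(dn = t$dn_excl, sal = t$sal_excl)),
                         contrasts = config$contrasts)
  res$pet <- pet
  res$targets <- targets

  stage("stats")
  tests <- list()
  for (ct in unique(pet$contrast))
    for (rn in unique(pet$roi)) {
      d <- pet$delta[pet$contrast == ct & pet$roi == rn]
      lbl <- paste(rn, ct)
      tests[[lbl]] <- tryCatch(paired_t_d(d, lbl), error = function(e) NULL)
    }
  tests <- Filter(Negate(is.null), tests)
  mats <- list(
    sal_post_vs_pre = matrix_comparison(lapply(fc, `[[`, "mat_sal_pre"),
                                        lapply(fc, `[[`, "mat_sal_post")),
    dn_post_vs_pre = matrix_comparison(lapply(fc, `[[`, "mat_dn_pre"),
                                       lapply(fc, `[[`, "mat_dn_post")),
    sal_post_vs_baseline = matrix_comparison(lapply(fc, `[[`, "mat_baseline"),
                                             lapply(fc, `[[`, "mat_sal_post")),
    dn_post_vs_baseline = matrix_comparison(lapply(fc, `[[`, "mat_baseline"),
                                            lapply(fc, `[[`, "mat_dn_post")))
  block <- vapply(mats, function(m)
    fc_block_mean(m$delta_z, spec$dn_network, spec$sal_network), numeric(1))
  # parcel-level permutation-corrected delta-SUV map (stimulated conditions)
  ptc <- parcel_table(atl, cortical_only = TRUE)
  parcel_roi <- function(lab)
    if (spec$space == "voxel") region_units(atl, lab)
    else which(parcel_table(atl)$label == lab)
  perm <- lapply(c("SAL-TMS>baseline", "DN-TMS>baseline"), function(ct) {
    if (!ct %in% config$contrasts) return(NULL)
    dmat <- t(vapply(names(suv_sessions), function(s) {
      cc <- strsplit(ct, ">", fixed = TRUE)[[1]]
      vapply(ptc$label, function(lab)
        roi_mean_excluding(suv_sessions[[s]][[cc[1]]], parcel_roi(lab)) -
          roi_mean_excluding(suv_sessions[[s]][[cc[2]]], parcel_roi(lab)),
        numeric(1))
    }, numeric(nrow(ptc))))
    out <- permutation_maxT(dmat, config$n_permutations,
                            rng_seed = config$rng_seed, alpha = config$alpha)
    out$regions <- ptc$region
    out
  })
  names(perm) <- c("SAL-TMS>baseline", "DN-TMS>baseline")
  res$stats <- list(tests = tests, matrices = mats, block_delta_z = block,
                    permutation = perm)

  stage("couple")
  pz <- t(vapply(fc, `[[`, numeric(5), "pairz"))
  coupling <- list()
  tgt_delta <- function(ct, roi) pet$delta[pet$contrast == ct & pet$roi == roi]
  n_an <- length(keep_subj)
  safe_couple <- function(x, y, xl, yl)
    tryCatch(coupling_correlation(x, y, xl, yl), error = function(e) NULL)
  coupling$sal <- safe_couple(tgt_delta("SAL-TMS>baseline", "sal_target"),
                              pz[, "sal_post"] - pz[, "sal_pre"],
                              "SAL target dWBn-suv (SAL-TMS)",
                              "DN-SAL pair dz (post-pre)")
  coupling$dn <- safe_couple(tgt_delta("DN-TMS>baseline", "dn_target"),
                             pz[, "dn_post"] - pz[, "dn_pre"],
                             "DN target dWBn-suv (DN-TMS)",
                             "DN-SAL pair dz (post-pre)")
  if (n_an >= 2 * config$subgroup_k) {
    coupling$subgroups <- list(
      sal = subgroup_divergence(tgt_delta("SAL-TMS>baseline", "sal_target"),
                                pz[, "sal_post"] - pz[, "sal_pre"],
                                k = config$subgroup_k, ids = keep_subj),
      dn = subgroup_divergence(tgt_delta("DN-TMS>baseline", "dn_target"),
                               pz[, "dn_post"] - pz[, "dn_pre"],
                               k = config$subgroup_k, ids = keep_subj))
  }
  res$coupling <- coupling
  res$ground_truth <- cohort$ground_truth

  stage("report")
  class(res) <- "netstim_run"
  res$report <- write_report(res, path = NULL)

  if (!is.null(config$out_dir)) res$manifest <- write_run(res, config$out_dir)
  res
}

#' Human-readable summary of a pipeline run
#'
#' Tables mirroring the study's result structure: QC exclusions, target
#' geometry and identity, per-contrast target and network deltas, DN x SAL
#' block delta z for both FC baselines, coupling correlations and subgroup
#' means.
#'
#' @param run a `netstim_run`.
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly if written.
#' @export
write_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "netstim_run"))
  L <- c("netstim pipeline report", strrep("=", 40))
  if (!length(run$qc$analyzed_subjects)) {
    L <- c(L, "zero analyzable subjects after QC")
    if (!is.null(path)) { writeLines(L, path); return(invisible(L)) }
    return(L)
  }
  need <- c("qc", "targets", "pet", "stats", "coupling")
  miss <- need[!need %in% names(run)]
  if (length(miss))
    stop("incomplete run; missing stages: ", paste(miss, collapse = ", "))
  L <- c(L, sprintf("QC: %d runs excluded", run$qc$n_runs_excluded))
  L <- c(L, sprintf("QC: %d/%d subjects analyzable (excluded: %s)",
                    length(run$qc$analyzed_subjects),
                    length(run$qc$analyzed_subjects) +
                      length(run$qc$excluded_subjects),
                    if (length(run$qc$excluded_subjects))
                      paste(run$qc$excluded_subjects, collapse = ", ")
                    else "none"))
  if (!is.null(run$targets[[1]]$pair)) {
    sep <- vapply(run$targets, function(t) t$pair$separation_mm, numeric(1))
    idn <- vapply(run$targets, function(t) t$pair$identity$dn$network,
                  character(1))
    isal <- vapply(run$targets, function(t) t$pair$identity$sal$network,
                   character(1))
    L <- c(L, sprintf("Targets: mean separation %.1f mm; identity DN->%s, SAL->%s",
                      mean(sep),
                      paste0(sum(idn == "default"), "/", length(idn), " default"),
                      paste0(sum(isal == "salience"), "/", length(isal),
                             " salience")))
  }
  L <- c(L, "", "Paired tests (delta WBn-suv):")
  for (tt in run$stats$tests)
    L <- c(L, sprintf("  %-40s n=%2d mean=%+.4f t=%+.3f p=%.4g d=%+.3f",
                      tt$label, tt$n, tt$mean, tt$t, tt$p, tt$d))
  L <- c(L, "", "DN x SAL block mean delta z:")
  for (nm in names(run$stats$block_delta_z))
    L <- c(L, sprintf("  %-22s %+.4f", nm, run$stats$block_delta_z[[nm]]))
  L <- c(L, "", "Metabolic-FC coupling:")
  for (nm in c("sal", "dn")) {
    cp <- run$coupling[[nm]]
    if (!is.null(cp))
      L <- c(L, sprintf("  %s ~ %s: r=%.3f R^2=%.3f p=%.4g (n=%d)",
                        cp$x_label, cp$y_label, cp$r, cp$r_squared, cp$p, cp$n))
  }
  if (!is.null(run$coupling$subgroups))
    for (nm in names(run$coupling$subgroups)) {
      sg <- run$coupling$subgroups[[nm]]
      L <- c(L, sprintf(
        "  subgroups (%s): bottom-%d FC dz %+.4f | top-%d FC dz %+.4f",
        nm, sg$k, sg$bottom$fc_mean, sg$k, sg$top$fc_mean))
    }
  if (!is.null(path)) { writeLines(L, path); return(invisible(L)) }
  L
}

#' @export
print.netstim_run <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}

# write staged outputs + manifest; every file in the tree is listed with
# its md5 checksum, alongside the config hash and seed
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  pet_path <- file.path(dir, "delta_suv.tsv")
  utils::write.table(run$pet, pet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tests <- do.call(rbind, lapply(run$stats$tests, function(t)
    data.frame(label = t$label, n = t$n, mean = t$mean, t = t$t, p = t$p,
               d = t$d)))
  utils::write.table(tests, file.path(dir, "group_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(run$stats$matrices))
    write_fc_matrix(run$stats$matrices[[nm]]$delta_z,
                    file.path(dir, paste0("delta_z_", nm, ".tsv")))
  jsonlite::write_json(
    list(block_delta_z = as.list(run$stats$block_delta_z),
         coupling = lapply(Filter(Negate(is.null),
                                  run$coupling[c("sal", "dn")]),
                           function(cp) cp[c("n", "r", "r_squared", "p")])),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(run$report, file.path(dir, "report.txt"))
  cfg_min <- cfg[setdiff(names(cfg), "cohort_spec")]
  cfg_min$cohort_seed <- cfg$cohort_spec$rng_seed
  cfg_min$n_subjects <- cfg$cohort_spec$n_subjects
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg_min, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    rng_seed = cfg$rng_seed,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest
}
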