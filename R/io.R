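#' Write a BOLD run to disk
#'
#' Voxel-space runs are written as a 4-D NIfTI volume in the atlas frame
#' (off-mask voxels zero); parcel-space runs as a frames x parcels TSV.
#' The motion table is written alongside as TSV with the standard six
#' columns, and the metadata as JSON.
#'
#' @param run a `bold_run`.
#' @param atlas the `atlas` defining the unit space.
#' @param stem output path without extension.
#' @return invisibly, the written file paths.
#' @export
write_bold_run <- function(run, atlas, stem) {
  paths <- character(0)
  if (run$space == "voxel") {
    dm <- atlas$dim
    vol <- array(0, c(dm, nrow(run$data)))
    off <- prod(dm) * (seq_len(nrow(run$data)) - 1L)
    for (t in seq_len(nrow(run$data)))
      vol[atlas$units$index + off[t]] <- run$data[t, ]
    img <- RNifti::asNifti(vol)
    aff <- diag(4); diag(aff)[1:3] <- atlas$voxel_size_mm
    aff[1:3, 4] <- atlas$origin_mm
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    p <- paste0(stem, "_bold.nii"); RNifti::writeNifti(img, p)
  } else {
    p <- paste0(stem, "_bold.tsv")
    utils::write.table(round(run$data, 8), p, sep = "\t", quote = FALSE,
                       row.names = FALSE,
                       col.names = parcel_table(atlas)$region)
  }
  paths <- c(paths, p)
  if (!is.null(run$motion)) {
    pm <- paste0(stem, "_motion.tsv")
    utils::write.table(run$motion, pm, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, pm)
  }
  pj <- paste0(stem, "_meta.json")
  jsonlite::write_json(c(run$meta, list(tr_seconds = run$tr_seconds,
                                        space = run$space)),
                       pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

#' Read a BOLD run written by [write_bold_run()]
#' @param stem path stem used at write time.
#' @param atlas the `atlas`.
#' @return a `bold_run`.
#' @export
load_bold_run <- function(stem, atlas) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  mp <- paste0(stem, "_motion.tsv")
  motion <- if (file.exists(mp)) utils::read.delim(mp) else NULL
  if (meta$space == "voxel") {
    vol <- as.array(RNifti::readNifti(paste0(stem, "_bold.nii")))
    nf <- dim(vol)[4]
    data <- t(matrix(vol[rep(atlas$units$index, nf) +
                           rep(prod(atlas$dim) * (seq_len(nf) - 1L),
                               each = n_units(atlas))],
                     n_units(atlas), nf))
    slice <- arrayInd(atlas$units$index, atlas$dim)[, 3]
  } else {
    data <- as.matrix(utils::read.delim(paste0(stem, "_bold.tsv")))
    slice <- NULL
  }
  bold_run(data, tr_seconds = meta$tr_seconds, motion = motion,
           meta = meta[setdiff(names(meta), c("tr_seconds", "space"))],
           space = meta$space, slice = slice)
}

#' Write an SUV map (NIfTI in voxel space, TSV in parcel space)
#' @param suv a `suv_map`.
#' @param atlas the `atlas`.
#' @param stem output path without extension.
#' @export
write_suv_map <- function(suv, atlas, stem) {
  if (suv$space == "voxel") {
    vol <- array(0, atlas$dim)
    vol[atlas$units$index] <- suv$values
    img <- RNifti::asNifti(vol)
    aff <- diag(4); diag(aff)[1:3] <- atlas$voxel_size_mm
    aff[1:3, 4] <- atlas$origin_mm
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    p <- paste0(stem, "_suv.nii"); RNifti::writeNifti(img, p)
  } else {
    p <- paste0(stem, "_suv.tsv")
    utils::write.table(data.frame(region = parcel_table(atlas)$region,
                                  value = round(suv$values, 10)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(p)
}

#' Write a synthetic cohort to disk
#'
#' BIDS-like layout under `dir`: atlas volume + lookup, ground-truth JSON,
#' and per subject `sub-<ID>/ses-<visit>/` BOLD runs, motion tables and SUV
#' maps. Deterministic content for a fixed spec seed.
#'
#' @param cohort a `tms_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atl <- cohort$spec$atlas
  write_atlas(atl, file.path(dir, "atlas_labels.nii"),
              file.path(dir, "atlas_lookup.tsv"))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"), digits = NA)
  ses_name <- c(baseline = "baseline", `SAL-TMS` = "saltms",
                `DN-TMS` = "dntms")
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    for (ses in names(sub)) {
      sd <- file.path(dir, sprintf("sub-%02d", s),
                      paste0("ses-", ses_name[[ses]]))
      dir.create(sd, recursive = TRUE, showWarnings = FALSE)
      stem <- function(ph, r) file.path(sd, sprintf(
        "sub-%02d_ses-%s_phase-%s_run-%d", s, ses_name[[ses]], ph, r))
      if (ses == "baseline") {
        for (r in seq_along(sub[[ses]]$bold))
          write_bold_run(sub[[ses]]$bold[[r]], atl, stem("pre", r))
      } else {
        for (ph in c("pre", "post"))
          for (r in seq_along(sub[[ses]][[ph]]))
            write_bold_run(sub[[ses]][[ph]][[r]], atl, stem(ph, r))
      }
      write_suv_map(sub[[ses]]$suv, atl,
                    file.path(sd, sprintf("sub-%02d_ses-%s", s,
                                          ses_name[[ses]])))
    }
  }
  invisible(dir)
}

#' Write an FC matrix as TSV (regions as header row/column)
#' @param m an `fc_matrix` (or delta matrix with dimnames).
#' @param path output path.
#' @export
write_fc_matrix <- function(m, path) {
  df <- data.frame(region = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
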