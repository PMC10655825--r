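#' Parcellation atlas objects
#'
#' An `atlas` holds an integer-labelled 3-D volume together with a lookup
#' table mapping each label to a named region and a network. Regions are
#' grouped into a fixed, ordered set of cortical networks (seven in the
#' configuration mirroring the Yeo et al. 7-network / 51-region scheme);
#' additional non-cortical labels (e.g. white matter, ventricles) may be
#' present for nuisance extraction and are kept out of the cortical network
#' list. The atlas defines the unit space for all downstream computation:
#' units are the voxels with a nonzero label, ordered by ascending linear
#' voxel index, so unit indexing is deterministic.
#'
#' @param labels 3-D integer array, 0 = background.
#' @param voxel_size_mm numeric length 3, voxel edge lengths in mm (RAS).
#' @param origin_mm numeric length 3, world coordinate of voxel (0,0,0).
#' @param region_table data.frame with columns `label`, `region`, `network`.
#' @param networks character vector of cortical network names, in display
#'   order. Networks appearing in `region_table` but not listed here (such
#'   as tissue compartments) are treated as non-cortical.
#' @return An object of class `atlas`.
#' @export
atlas <- function(labels, voxel_size_mm, origin_mm, region_table,
                  networks) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("label volume must be a 3-D array")
  if (any(labels != round(labels)))
    stop("atlas format error: non-integer labels in volume")
  storage.mode(labels) <- "integer"
  req <- c("label", "region", "network")
  if (!all(req %in% names(region_table)))
    stop("region_table must have columns label, region, network")
  region_table <- region_table[, req]
  region_table$label <- as.integer(region_table$label)
  present <- sort(unique(labels[labels != 0L]))
  missing <- setdiff(present, region_table$label)
  if (length(missing))
    stop(sprintf("labelled region undefined: no lookup row for label %s",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(region_table$label))
    stop("duplicate labels in region_table")
  if (anyDuplicated(region_table$region))
    stop("region names must be unique (each region maps to one network)")
  region_table <- region_table[region_table$label %in% present, , drop = FALSE]
  region_table <- region_table[order(region_table$label), , drop = FALSE]
  rownames(region_table) <- NULL

  idx <- which(labels != 0L)          # ascending linear voxel index
  dm <- dim(labels)
  vox0 <- arrayInd(idx, dm) - 1L      # 0-based voxel coordinates
  world <- sweep(vox0 %*% diag(as.numeric(voxel_size_mm)), 2,
                 as.numeric(origin_mm), "+")
  units <- data.frame(index = idx, label = labels[idx],
                      x = world[, 1], y = world[, 2], z = world[, 3])
  obj <- structure(list(labels = labels,
                        dim = dm,
                        voxel_size_mm = as.numeric(voxel_size_mm),
                        origin_mm = as.numeric(origin_mm),
                        region_table = region_table,
                        networks = as.character(networks),
                        units = units),
                   class = "atlas")
  stopifnot(all(table(obj$units$label) > 0))
  obj
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("atlas: %s volume, %.3g x %.3g x %.3g mm voxels\n",
              paste(x$dim, collapse = " x "),
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  ctx <- x$region_table$network %in% x$networks
  cat(sprintf("  %d units, %d cortical regions in %d networks (%s)\n",
              nrow(x$units), sum(ctx), length(x$networks),
              paste(x$networks, collapse = ", ")))
  if (any(!ctx))
    cat(sprintf("  non-cortical labels: %s\n",
                paste(x$region_table$region[!ctx], collapse = ", ")))
  invisible(x)
}

#' Number of units (labelled voxels) in an atlas
#' @param atlas an `atlas`.
#' @export
n_units <- function(atlas) nrow(atlas$units)

#' World coordinates of atlas units
#' @param atlas an `atlas`.
#' @return numeric matrix, one row per unit, columns x/y/z in mm.
#' @export
unit_coords <- function(atlas) {
  as.matrix(atlas$units[, c("x", "y", "z")])
}

#' Unit indices of a named region (or label)
#' @param atlas an `atlas`.
#' @param region region name (character) or integer label.
#' @return integer vector of unit indices (positions in the atlas unit order).
#' @export
region_units <- function(atlas, region) {
  if (is.character(region)) {
    row <- match(region, atlas$region_table$region)
    if (is.na(row)) stop(sprintf("unknown region '%s'", region))
    lab <- atlas$region_table$label[row]
  } else lab <- as.integer(region)
  which(atlas$units$label %in% lab)
}

#' Unit indices of all regions of a network
#' @param atlas an `atlas`.
#' @param network network name.
#' @param exclude_regions optional character vector of region names to drop.
#' @export
network_units <- function(atlas, network, exclude_regions = NULL) {
  rt <- atlas$region_table
  keep <- rt$network == network
  if (!any(keep)) stop(sprintf("unknown network '%s'", network))
  if (!is.null(exclude_regions)) keep <- keep & !(rt$region %in% exclude_regions)
  which(atlas$units$label %in% rt$label[keep])
}

#' Standard nuisance masks derived from an atlas
#'
#' `whole_brain` covers every labelled unit; `white_matter` and `ventricles`
#' are taken from identically named non-cortical regions when present
#' (empty otherwise).
#' @param atlas an `atlas`.
#' @return list of integer unit-index vectors.
#' @export
atlas_masks <- function(atlas) {
  rt <- atlas$region_table
  get <- function(nm) {
    if (nm %in% rt$region) region_units(atlas, nm) else integer(0)
  }
  list(whole_brain = seq_len(n_units(atlas)),
       white_matter = get("white_matter"),
       ventricles = get("ventricles"))
}

#' Canonical parcel table
#'
#' Regions ordered by network (cortical networks first, in the atlas network
#' order; non-cortical labels last), regions within a network by label. This
#' ordering defines the unit order for parcel-space runs and the row/column
#' order of region-pair FC matrices.
#' @param atlas an `atlas`.
#' @param cortical_only drop non-cortical labels.
#' @return data.frame with columns label, region, network, n_units.
#' @export
parcel_table <- function(atlas, cortical_only = FALSE) {
  rt <- atlas$region_table
  cnt <- table(factor(atlas$units$label, levels = rt$label))
  rt$n_units <- as.integer(cnt)
  ord <- match(rt$network, atlas$networks)
  ord[is.na(ord)] <- length(atlas$networks) + 1L
  rt <- rt[order(ord, rt$label), , drop = FALSE]
  if (cortical_only) rt <- rt[rt$network %in% atlas$networks, , drop = FALSE]
  rownames(rt) <- NULL
  rt
}

#' Units within a sphere
#'
#' All units whose voxel centre lies at Euclidean distance less than or equal
#' to `radius_mm` from `center_mm` (boundary inclusive).
#'
#' @param atlas an `atlas`.
#' @param center_mm numeric length 3, world coordinates in mm.
#' @param radius_mm sphere radius in mm, >= 0.
#' @return integer vector of unit indices; empty with a warning if no unit
#'   falls inside the sphere.
#' @export
sphere_units <- function(atlas, center_mm, radius_mm) {
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  xyz <- unit_coords(atlas)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  out <- which(d2 <= radius_mm^2 + 1e-9)
  if (!length(out)) warning("empty sphere: no atlas unit within radius")
  out
}

#' Euclidean distance between two points in mm
#' @param a,b numeric length-3 world coordinates.
#' @export
target_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L)
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Read an atlas from a NIfTI label volume and a TSV lookup table
#'
#' The lookup table must have columns `label`, `region`, `network`; every
#' nonzero label in the volume must have a row.
#'
#' @param label_volume_path path to a NIfTI volume of integer labels.
#' @param lookup_table_path path to a tab-separated lookup table.
#' @param networks cortical network names in order; defaults to the order of
#'   first appearance in the lookup table, excluding the `white_matter` and
#'   `ventricles` tissue labels.
#' @return an `atlas`.
#' @export
load_atlas <- function(label_volume_path, lookup_table_path, networks = NULL) {
  if (!file.exists(label_volume_path)) stop("label volume not found")
  if (!file.exists(lookup_table_path)) stop("lookup table not found")
  img <- RNifti::readNifti(label_volume_path)
  vol <- as.array(img)
  if (max(abs(vol - round(vol))) > 1e-6)
    stop("atlas format error: non-integer labels in volume")
  vol <- round(vol)
  lut <- utils::read.delim(lookup_table_path, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(networks)) {
    nets <- unique(lut$network)
    networks <- setdiff(nets, c("white_matter", "ventricles"))
  }
  aff <- RNifti::xform(img)
  pix <- sqrt(colSums(aff[1:3, 1:3]^2))   # voxel sizes from the affine
  origin <- aff[1:3, 4]
  atlas(vol, voxel_size_mm = pix, origin_mm = origin,
        region_table = lut, networks = networks)
}

#' Write an atlas to a NIfTI label volume and a TSV lookup table
#' @param atlas an `atlas`.
#' @param label_volume_path,lookup_table_path output paths.
#' @return invisibly, the two paths.
#' @export
write_atlas <- function(atlas, label_volume_path, lookup_table_path) {
  img <- RNifti::asNifti(atlas$labels)
  aff <- diag(4)
  diag(aff)[1:3] <- atlas$voxel_size_mm
  aff[1:3, 4] <- atlas$origin_mm
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, label_volume_path)
  utils::write.table(atlas$region_table, lookup_table_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(label_volume_path, lookup_table_path))
}
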