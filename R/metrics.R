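.metric_masks <- function(A, B) {
  a <- .vol_data(A); b <- .vol_data(B)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  list(a = a > 0, b = b > 0)
}

#' Dice per case (DPC)
#'
#' Volumetric overlap `2|A n B| / (|A| + |B|)`. Two empty masks count as
#' perfect agreement (DPC = 1).
#'
#' @param A,B aligned binary 3-d masks (or `ct_volume`s carrying masks).
#' @return Fraction in [0, 1].
#' @export
dpc <- function(A, B) {
  m <- .metric_masks(A, B)
  na <- sum(m$a); nb <- sum(m$b)
  if (na + nb == 0) return(1)
  2 * sum(m$a & m$b) / (na + nb)
}

#' Volumetric overlap error (VOE)
#'
#' `1 - |A n B| / |A u B|`, the complement of the Jaccard index. Two empty
#' masks give 0.
#'
#' @inheritParams dpc
#' @return Fraction in [0, 1].
#' @export
voe <- function(A, B) {
  m <- .metric_masks(A, B)
  u <- sum(m$a | m$b)
  if (u == 0) return(0)
  1 - sum(m$a & m$b) / u
}

#' Relative absolute volume difference (RAVD)
#'
#' `||B| - |A|| / |A|` with `A` the reference mask. Undefined (error) when
#' the reference is empty.
#'
#' @param A reference (ground-truth) binary mask.
#' @param B predicted binary mask.
#' @return Non-negative fraction.
#' @export
ravd <- function(A, B) {
  m <- .metric_masks(A, B)
  na <- sum(m$a)
  if (na == 0) stop("undefined metric: reference mask is empty")
  abs(sum(m$b) - na) / na
}

#' Extract the surface voxels of a binary mask
#'
#' Surface voxels are foreground voxels with at least one background
#' 6-neighbor; the volume boundary counts as background (so interior cavity
#' walls are surface too).
#'
#' @param mask binary 3-d array.
#' @param spacing voxel spacing in mm (used for the mm coordinates).
#' @return A list of class `surface_set` with `voxels` (n x 3 matrix of
#'   1-based indices) and `mm` (n x 3 matrix of physical coordinates).
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1)) {
  m <- .vol_data(mask) > 0
  storage.mode(m) <- "logical"
  vox <- cpp_surface_voxels(m)
  colnames(vox) <- c("i", "j", "t")
  mm <- sweep(vox, 2, as.numeric(spacing), `*`)
  structure(list(voxels = vox, mm = mm, spacing = as.numeric(spacing)),
            class = "surface_set")
}

# distances (mm) from each surface voxel of `from` to the nearest surface
# voxel of `to`, via an exact anisotropic Euclidean distance transform
.surface_distances <- function(from_vox, to_mask_sites, spacing) {
  dt <- cpp_edt3d(to_mask_sites, as.numeric(spacing))
  dt[from_vox]
}

.surface_pair <- function(A, B, spacing) {
  m <- .metric_masks(A, B)
  if (sum(m$a) == 0 || sum(m$b) == 0)
    stop("undefined metric: surface distances need two non-empty masks")
  sa <- extract_surface(m$a, spacing)
  sb <- extract_surface(m$b, spacing)
  sites_a <- array(FALSE, dim(m$a)); sites_a[sa$voxels] <- TRUE
  sites_b <- array(FALSE, dim(m$b)); sites_b[sb$voxels] <- TRUE
  d_ab <- .surface_distances(sa$voxels, sites_b, spacing)
  d_ba <- .surface_distances(sb$voxels, sites_a, spacing)
  list(d_ab = d_ab, d_ba = d_ba)
}

#' Average symmetric surface distance (ASSD)
#'
#' Mean of the nearest-surface distances taken symmetrically between the two
#' mask surfaces, in mm:
#' `(sum_a d(a, S(B)) + sum_b d(b, S(A))) / (|S(A)| + |S(B)|)`.
#'
#' @inheritParams dpc
#' @param spacing voxel spacing in mm.
#' @return Distance in mm (0 for identical masks). Errors when either mask
#'   is empty.
#' @export
assd <- function(A, B, spacing = c(1, 1, 1)) {
  d <- .surface_pair(A, B, spacing)
  (sum(d$d_ab) + sum(d$d_ba)) / (length(d$d_ab) + length(d$d_ba))
}

#' Root-mean-square symmetric surface distance (RMSD)
#'
#' Square root of the mean squared symmetric nearest-surface distance, in
#' mm. Always at least as large as [assd()].
#'
#' @inheritParams assd
#' @return Distance in mm.
#' @export
rmsd <- function(A, B, spacing = c(1, 1, 1)) {
  d <- .surface_pair(A, B, spacing)
  sqrt((sum(d$d_ab^2) + sum(d$d_ba^2)) / (length(d$d_ab) + length(d$d_ba)))
}

#' Evaluate one segmentation case with all five metrics
#'
#' DPC, VOE, RAVD, ASSD and RMSD for a predicted mask against its ground
#' truth. The surface metrics are reported as `NA` (with a warning) when
#' either mask is empty, and are excluded from aggregates downstream.
#'
#' @param gt ground-truth binary mask.
#' @param pred predicted binary mask.
#' @param spacing voxel spacing in mm.
#' @param case_id identifier carried into the report.
#' @return A one-row data frame with columns `case_id`, `dpc`, `voe`,
#'   `ravd`, `assd`, `rmsd`.
#' @export
evaluate_case <- function(gt, pred, spacing = c(1, 1, 1), case_id = "case") {
  m <- .metric_masks(gt, pred)
  r_ravd <- if (sum(m$a) > 0) ravd(gt, pred) else NA_real_
  if (sum(m$a) > 0 && sum(m$b) > 0) {
    a_ <- assd(gt, pred, spacing)
    r_ <- rmsd(gt, pred, spacing)
  } else {
    warning(sprintf("case %s: empty mask, surface metrics undefined", case_id))
    a_ <- NA_real_
    r_ <- NA_real_
  }
  data.frame(case_id = case_id, dpc = dpc(gt, pred), voe = voe(gt, pred),
             ravd = r_ravd, assd = a_, rmsd = r_, stringsAsFactors = FALSE)
}

#' Aggregate per-case metric reports
#'
#' Binds per-case rows and appends mean and standard-deviation summary rows
#' (computed per volume, then averaged; `NA` metrics are excluded).
#'
#' @param reports list of data frames from [evaluate_case()].
#' @param path optional CSV output path.
#' @return Data frame of per-case rows plus `mean` and `sd` rows.
#' @export
aggregate_metrics <- function(reports, path = NULL) {
  df <- do.call(rbind, reports)
  nums <- df[, c("dpc", "voe", "ravd", "assd", "rmsd"), drop = FALSE]
  summ <- data.frame(
    case_id = c("mean", "sd"),
    rbind(colMeans(nums, na.rm = TRUE),
          apply(nums, 2, stats::sd, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  out <- rbind(df, summ)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
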