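#' CT volume container
#'
#' A light container for a 3-d CT intensity array in Hounsfield units with
#' per-axis voxel spacing. The array is indexed (row, column, slice); the
#' slice axis is the third axis and slice indices are 1-based throughout the
#' package.
#'
#' @param data numeric 3-d array (H x W x D) of intensities in HU.
#' @param spacing numeric length-3 vector, mm per voxel along each axis.
#' @return An object of class `ct_volume` with elements `data` and `spacing`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (H x W x D)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (mm/voxel)")
  structure(list(data = data, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(x$data), max(x$data)))
  invisible(x)
}

.vol_data <- function(vol) {
  if (inherits(vol, "ct_volume")) vol$data else vol
}

.check_mask <- function(mask) {
  m <- .vol_data(mask)
  if (!all(m %in% c(0, 1))) stop("mask must be binary (0/1)")
  m
}

#' Preprocessing configuration
#'
#' Bundles the parameters of the deterministic CT preprocessing pipeline:
#' clamp intensities to `[hu_lo, hu_hi]` HU, center-crop each slice to
#' `crop_size` pixels, optionally histogram-equalize, rescale to [0, 1],
#' optionally keep only slices containing tumor, and assemble stacks of
#' `n_slices` consecutive slices around each retained center slice.
#'
#' @param hu_lo,hu_hi Hounsfield window bounds (defaults -200, 200).
#' @param crop_size side length of the centered square crop (default 448).
#' @param n_slices odd number of consecutive slices per stack (default 3).
#' @param equalize apply global histogram equalization (default TRUE).
#' @param keep_only_tumor_slices drop slices whose mask is empty (default
#'   TRUE; a training-stage operation, disabled at inference).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_lo = -200, hu_hi = 200, crop_size = 448L,
                              n_slices = 3L, equalize = TRUE,
                              keep_only_tumor_slices = TRUE) {
  if (hu_lo >= hu_hi) stop("invalid config: hu_lo must be < hu_hi")
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L || n_slices %% 2L == 0L)
    stop("invalid config: n_slices must be odd and >= 1")
  crop_size <- as.integer(crop_size)
  if (crop_size < 1L) stop("invalid config: crop_size must be >= 1")
  structure(list(hu_lo = hu_lo, hu_hi = hu_hi, crop_size = crop_size,
                 n_slices = n_slices, equalize = isTRUE(equalize),
                 keep_only_tumor_slices = isTRUE(keep_only_tumor_slices)),
            class = "preprocess_config")
}

#' Clamp CT intensities to a Hounsfield window
#'
#' Every voxel is clamped to `[lo, hi]`; shape and spacing are unchanged.
#'
#' @param vol a `ct_volume` or numeric array.
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return Same type as `vol`.
#' @export
window_hu <- function(vol, lo = -200, hi = 200) {
  if (lo >= hi) stop("invalid config: lo must be < hi")
  if (inherits(vol, "ct_volume")) {
    vol$data <- pmin(pmax(vol$data, lo), hi)
    vol
  } else {
    pmin(pmax(vol, lo), hi)
  }
}

#' Center-crop a 2-d slice
#'
#' Extracts a `crop_size` x `crop_size` window centered on the input. When
#' the margin is odd the extra pixel is discarded from the high-index side,
#' i.e. the low-side margin is `floor((dim - crop)/2)`.
#'
#' @param slice_2d numeric matrix.
#' @param crop_size side length, at most `min(dim(slice_2d))`.
#' @return A `crop_size` x `crop_size` matrix.
#' @export
center_crop <- function(slice_2d, crop_size) {
  d <- dim(slice_2d)
  if (is.null(d) || length(d) != 2L) stop("`slice_2d` must be a matrix")
  crop_size <- as.integer(crop_size)
  if (crop_size > min(d))
    stop(sprintf("crop_size %d exceeds input dims %d x %d", crop_size, d[1], d[2]))
  off <- (d - crop_size) %/% 2L
  slice_2d[off[1] + seq_len(crop_size), off[2] + seq_len(crop_size), drop = FALSE]
}

#' Global histogram equalization
#'
#' Maps each pixel to the empirical CDF of its intensity bin, using `bins`
#' equal-width bins over `[lo, hi]`. The output is a monotone non-decreasing
#' function of the input with values in (0, 1]; a constant image maps to a
#' constant image.
#'
#' @param slice_2d numeric matrix with finite values.
#' @param lo,hi intensity range defining the binning (defaults: data range).
#' @param bins number of histogram bins (default 256).
#' @return Matrix of equalized intensities in (0, 1].
#' @export
hist_equalize <- function(slice_2d, lo = min(slice_2d), hi = max(slice_2d),
                          bins = 256L) {
  if (!all(is.finite(slice_2d))) stop("non-finite values in slice")
  bins <- as.integer(bins)
  if (hi <= lo) {                      # constant image: single occupied bin
    out <- array(1, dim(slice_2d))
    return(out)
  }
  idx <- floor((slice_2d - lo) / (hi - lo) * bins) + 1L
  idx <- pmin(pmax(idx, 1L), bins)
  counts <- tabulate(idx, nbins = bins)
  cdf <- cumsum(counts) / length(slice_2d)
  out <- cdf[idx]
  dim(out) <- dim(slice_2d)
  out
}

#' Rescale a slice to [0, 1]
#'
#' Applies `(x - min) / (max - min)`. A constant input maps to all zeros.
#'
#' @param slice_2d numeric matrix with finite values.
#' @return Matrix with values in [0, 1].
#' @export
normalize01 <- function(slice_2d) {
  if (!all(is.finite(slice_2d))) stop("non-finite values in slice")
  rng <- range(slice_2d)
  if (rng[1] == rng[2]) return(array(0, dim(slice_2d)))
  (slice_2d - rng[1]) / (rng[2] - rng[1])
}

#' Indices of slices containing tumor
#'
#' @param mask binary 3-d array or `ct_volume`-like mask.
#' @return Ascending integer vector of 1-based slice indices with at least
#'   one foreground voxel; empty when the mask is empty.
#' @export
filter_tumor_slices <- function(mask) {
  m <- .check_mask(mask)
  which(apply(m, 3, function(s) any(s > 0)))
}

#' Assemble a 2.5D multi-slice stack
#'
#' Builds the rank-3 stack of `n` consecutive slices centered on slice `t`:
#' channel `k` holds slice `t + k - ceiling(n/2)`; slices falling outside
#' `[1, D]` are zero-filled planes. The center channel equals slice `t`
#' exactly.
#'
#' @param vol a `ct_volume` or 3-d array (already preprocessed).
#' @param t 1-based center slice index.
#' @param n odd number of slices.
#' @return Array of dim `(n, H, W)` with attributes `center_index` and
#'   `n_slices`.
#' @export
build_stack <- function(vol, t, n = 3L) {
  v <- .vol_data(vol)
  d <- dim(v)
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) stop("invalid config: n must be odd and >= 1")
  t <- as.integer(t)
  if (t < 1L || t > d[3]) stop(sprintf("slice index %d out of range [1, %d]", t, d[3]))
  half <- n %/% 2L
  out <- array(0, c(n, d[1], d[2]))
  for (k in seq_len(n)) {
    s <- t + k - 1L - half
    if (s >= 1L && s <= d[3]) out[k, , ] <- v[, , s]
  }
  attr(out, "center_index") <- t
  attr(out, "n_slices") <- n
  out
}

# Apply the per-slice pipeline (window -> crop -> equalize -> normalize) to a
# whole volume; returns a (crop, crop, D) array.
.preprocess_slices <- function(vol_data, cfg) {
  d <- dim(vol_data)
  out <- array(0, c(cfg$crop_size, cfg$crop_size, d[3]))
  for (t in seq_len(d[3])) {
    s <- window_hu(vol_data[, , t], cfg$hu_lo, cfg$hu_hi)
    s <- center_crop(s, cfg$crop_size)
    if (cfg$equalize) s <- hist_equalize(s, cfg$hu_lo, cfg$hu_hi)
    out[, , t] <- normalize01(s)
  }
  out
}

#' Preprocess one CT case into 2.5D training stacks
#'
#' Runs window -> crop -> equalize -> normalize on every slice, selects
#' center slices (all slices, or only tumor-bearing ones when
#' `cfg$keep_only_tumor_slices`), and emits one multi-slice stack per
#' retained center slice together with the center slice's cropped mask.
#'
#' @param vol a `ct_volume` or 3-d HU array.
#' @param mask aligned binary 3-d array (tumor annotation).
#' @param cfg a [preprocess_config()].
#' @return List of samples; each sample is a list with `stack`
#'   (`(n, crop, crop)` array), `mask` (`crop x crop` binary matrix) and
#'   `center_index`.
#' @export
preprocess_case <- function(vol, mask, cfg = preprocess_config()) {
  v <- .vol_data(vol)
  m <- .check_mask(mask)
  if (!identical(dim(v), dim(m))) stop("volume and mask shapes differ")
  proc <- .preprocess_slices(v, cfg)
  centers <- if (cfg$keep_only_tumor_slices) filter_tumor_slices(m) else seq_len(dim(v)[3])
  lapply(centers, function(t) {
    list(stack = build_stack(proc, t, cfg$n_slices),
         mask = center_crop(m[, , t], cfg$crop_size),
         center_index = t)
  })
}
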