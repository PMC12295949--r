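#' Phantom generator configuration
#'
#' Parameters of the seeded low-contrast abdominal-CT-like phantom: an
#' ellipsoidal "liver" on a darker background with embedded spherical
#' "tumors" whose mean intensity sits only slightly below the liver mean,
#' Gaussian-smoothed and noised. Default intensities are plausible CT-like
#' Hounsfield values chosen for testability, not clinical fidelity.
#'
#' @param shape volume dimensions `(H, W, D)`, each >= 32 in-plane.
#' @param spacing voxel spacing in mm.
#' @param liver_axes ranges (min, max) of the ellipsoid semi-axes, voxels,
#'   as a 3 x 2 matrix (rows = axes).
#' @param n_tumors range (min, max) of the number of tumors.
#' @param tumor_radius range (min, max) of tumor radii, voxels.
#' @param bg_hu,liver_hu,tumor_hu mean/sd pairs of the per-voxel intensity
#'   draws in HU for background, liver and tumor tissue. The default
#'   liver-tumor contrast is 15 HU (60 vs 45), emulating the low-contrast
#'   regime of clinical liver CT.
#' @param noise_sd sd of the additive Gaussian noise applied after
#'   smoothing (HU).
#' @param smooth_sigma sd (voxels) of the in-plane Gaussian smoothing of the
#'   intensity texture.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 64L, 24L),
                           spacing = c(0.8, 0.8, 1.5),
                           liver_axes = rbind(c(20, 26), c(16, 22), c(8, 11)),
                           n_tumors = c(1L, 3L),
                           tumor_radius = c(3, 6),
                           bg_hu = c(-100, 20),
                           liver_hu = c(60, 10),
                           tumor_hu = c(45, 10),
                           noise_sd = 5,
                           smooth_sigma = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape[1:2] < 32L) || shape[3] < 4L)
    stop("invalid config: in-plane dims must be >= 32, depth >= 4")
  if (max(tumor_radius) >= min(liver_axes))
    stop("invalid config: tumor radii must be smaller than liver semi-axes")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 liver_axes = liver_axes, n_tumors = as.integer(n_tumors),
                 tumor_radius = tumor_radius, bg_hu = bg_hu,
                 liver_hu = liver_hu, tumor_hu = tumor_hu,
                 noise_sd = noise_sd, smooth_sigma = smooth_sigma),
            class = "phantom_config")
}

# separable Gaussian smoothing of each slice (reflecting borders)
.gauss_smooth_slices <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(m, margin) {
    n <- dim(m)[margin]
    idx <- outer(seq_len(n), seq(-r, r), `+`)
    idx[idx < 1L] <- 1L - idx[idx < 1L] + 1L   # reflect
    idx[idx > n] <- 2L * n - idx[idx > n]
    if (margin == 1L) {
      out <- matrix(0, nrow(m), ncol(m))
      for (o in seq_len(2L * r + 1L)) out <- out + k[o] * m[idx[, o], , drop = FALSE]
      out
    } else {
      out <- matrix(0, nrow(m), ncol(m))
      for (o in seq_len(2L * r + 1L)) out <- out + k[o] * m[, idx[, o], drop = FALSE]
      out
    }
  }
  for (t in seq_len(dim(vol)[3])) {
    s <- vol[, , t]
    vol[, , t] <- smooth1(smooth1(s, 1L), 2L)
  }
  vol
}

#' Generate one CT phantom with liver and tumor masks
#'
#' Deterministic in `seed`: draws an ellipsoidal liver, places spherical
#' tumors fully inside it, fills each region with Gaussian intensities,
#' smooths in-plane and adds noise. Every tumor voxel is also a liver voxel.
#'
#' @param cfg a [phantom_config()].
#' @param seed integer seed for this case.
#' @return List with `volume` (a [ct_volume()]), `liver` and `tumor`
#'   (binary 3-d arrays), and `seed`.
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L) {
  set.seed(seed)
  d <- cfg$shape
  ax <- vapply(1:3, function(i) runif(1, cfg$liver_axes[i, 1], cfg$liver_axes[i, 2]),
               numeric(1))
  ctr <- d / 2 + runif(3, -2, 2)
  ii <- slice.index(array(0, d), 1)
  jj <- slice.index(array(0, d), 2)
  tt <- slice.index(array(0, d), 3)
  liver <- ((ii - ctr[1]) / ax[1])^2 + ((jj - ctr[2]) / ax[2])^2 +
    ((tt - ctr[3]) / ax[3])^2 <= 1
  n_t <- sample(seq(cfg$n_tumors[1], cfg$n_tumors[2]), 1)
  tumor <- array(FALSE, d)
  for (k in seq_len(n_t)) {
    placed <- FALSE
    for (try in 1:100) {
      r <- runif(1, cfg$tumor_radius[1], cfg$tumor_radius[2])
      # candidate center inside the shrunken liver ellipsoid
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      cen <- ctr + u * pmax(ax - r - 1, 0.5)
      sph <- ((ii - cen[1]))^2 + ((jj - cen[2]))^2 + ((tt - cen[3]))^2 <= r^2
      if (any(sph) && all(liver[sph])) {
        tumor <- tumor | sph
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible phantom geometry: tumor cannot fit in liver")
  }
  vol <- array(rnorm(prod(d), cfg$bg_hu[1], cfg$bg_hu[2]), d)
  nl <- sum(liver & !tumor)
  vol[liver & !tumor] <- rnorm(nl, cfg$liver_hu[1], cfg$liver_hu[2])
  vol[tumor] <- rnorm(sum(tumor), cfg$tumor_hu[1], cfg$tumor_hu[2])
  vol <- .gauss_smooth_slices(vol, cfg$smooth_sigma)
  vol <- vol + rnorm(prod(d), 0, cfg$noise_sd)
  list(volume = ct_volume(vol, cfg$spacing),
       liver = array(as.numeric(liver), d),
       tumor = array(as.numeric(tumor), d),
       seed = seed)
}

# Phantom geometry scaled to an arbitrary volume shape (used by the CLI):
# liver semi-axes as fixed fractions of each dimension, tumor radii tied to
# the smallest semi-axis. At the default 64 x 64 x 24 shape this reproduces
# the standard configuration's geometry.
.scaled_phantom_config <- function(shape, ...) {
  shape <- as.integer(shape)
  axes <- rbind(shape[1] * c(0.31, 0.41),
                shape[2] * c(0.25, 0.34),
                shape[3] * c(0.33, 0.46))
  r_hi <- max(1.2, 0.5 * min(axes[, 1]) - 1)
  phantom_config(shape = shape, liver_axes = axes,
                 tumor_radius = c(max(1.2, 0.6 * r_hi), r_hi), ...)
}

#' Generate a phantom dataset with train/validation/test splits
#'
#' Cases are generated with independent per-case seeds derived from the
#' master seed, shuffled deterministically and split by the (normalized)
#' fractions. Splits are disjoint and cover all cases.
#'
#' @param n_cases number of phantoms.
#' @param cfg a [phantom_config()].
#' @param fractions train/validation/test proportions (normalized to sum
#'   to 1; default 8:2:2).
#' @param seed master seed.
#' @return List with `cases` (list of phantoms), `manifest` (data frame of
#'   case id, seed, split), and `splits` (named list of case indices).
#' @export
generate_dataset <- function(n_cases = 12L, cfg = phantom_config(),
                             fractions = c(8, 2, 2), seed = 39L) {
  n_cases <- as.integer(n_cases)
  if (n_cases < length(fractions))
    stop(sprintf("need at least %d cases for %d splits",
                 length(fractions), length(fractions)))
  fr <- fractions / sum(fractions)
  counts <- floor(fr * n_cases)
  rem <- n_cases - sum(counts)
  if (rem > 0) {
    extra <- order(fr * n_cases - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  case_seeds <- seed + 1000L * seq_len(n_cases)
  cases <- lapply(seq_len(n_cases), function(i)
    generate_phantom(cfg, seed = case_seeds[i]))
  set.seed(seed)
  ord <- sample.int(n_cases)
  split_names <- c("train", "validation", "test")[seq_along(fractions)]
  split <- rep(split_names, times = counts)[order(ord)]
  manifest <- data.frame(case_id = sprintf("phantom%03d", seq_len(n_cases)),
                         seed = case_seeds, split = split,
                         stringsAsFactors = FALSE)
  list(cases = cases, manifest = manifest,
       splits = lapply(stats::setNames(nm = split_names),
                       function(s) which(split == s)))
}
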