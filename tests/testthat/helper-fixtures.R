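# Shared fixtures: everything is generated in code at test time.

tiny_model <- function(n_slices = 3L, seed = 1L, plan = c(8L, 16L, 32L),
                       reduction = 4L) {
  ris_unet(model_config(n_slices = n_slices, depth = length(plan),
                        channel_plan = plan, se_reduction = reduction),
           seed = seed)
}

random_mask <- function(dims, p = 0.2) {
  array(as.numeric(runif(prod(dims)) < p), dims)
}

# A small blob mask: sphere of radius r centered at ctr.
sphere_mask <- function(dims, ctr, r) {
  ii <- slice.index(array(0, dims), 1)
  jj <- slice.index(array(0, dims), 2)
  tt <- slice.index(array(0, dims), 3)
  array(as.numeric((ii - ctr[1])^2 + (jj - ctr[2])^2 + (tt - ctr[3])^2 <= r^2),
        dims)
}

# Brute-force all-pairs symmetric surface distances (the independent oracle
# for assd/rmsd): O(|S(A)| * |S(B)|) on the mm coordinates.
brute_surface_distances <- function(A, B, spacing) {
  sa <- extract_surface(A, spacing)$mm
  sb <- extract_surface(B, spacing)$mm
  # explicit per-axis differences (no cancellation-prone expansion)
  d2 <- outer(sa[, 1], sb[, 1], `-`)^2 + outer(sa[, 2], sb[, 2], `-`)^2 +
    outer(sa[, 3], sb[, 3], `-`)^2
  d <- sqrt(d2)
  list(d_ab = apply(d, 1, min), d_ba = apply(d, 2, min))
}

brute_assd <- function(A, B, spacing) {
  d <- brute_surface_distances(A, B, spacing)
  (sum(d$d_ab) + sum(d$d_ba)) / (length(d$d_ab) + length(d$d_ba))
}

brute_rmsd <- function(A, B, spacing) {
  d <- brute_surface_distances(A, B, spacing)
  sqrt((sum(d$d_ab^2) + sum(d$d_ba^2)) / (length(d$d_ab) + length(d$d_ba)))
}

# small phantom dataset reused by engine tests
small_dataset <- function(n_cases = 4L, seed = 11L) {
  generate_dataset(n_cases, phantom_config(shape = c(32L, 32L, 8L),
                                           liver_axes = rbind(c(10, 12),
                                                              c(9, 11),
                                                              c(3, 3.5)),
                                           tumor_radius = c(2, 2.8),
                                           n_tumors = c(1L, 1L)),
                   fractions = c(2, 1, 1), seed = seed)
}
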