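#' Reference channel plan of the default five-level network
#'
#' Per-level feature widths of the default 2.5D configuration. The plan
#' follows U-Net-style (approximate) doubling and is frozen so that the
#' default model's trainable parameter budget is 15.02 M.
#'
#' @return Integer vector of length 5.
#' @export
reference_channel_plan <- function() c(80L, 156L, 312L, 616L, 1220L)

#' Model configuration
#'
#' Architecture hyperparameters of the Res-Inception-SE U-Net. The parameter
#' count is a pure function of this configuration.
#'
#' @param n_slices odd number of input channels (2.5D slices; 1 gives the
#'   plain 2D model).
#' @param depth number of encoder levels including the bottleneck
#'   (default 5, i.e. four 2x2 max-poolings).
#' @param channel_plan integer vector of per-level widths (length `depth`,
#'   non-decreasing). Defaults to [reference_channel_plan()] at depth 5, and
#'   to doubling from `base_channels` otherwise.
#' @param base_channels width of the first level when `channel_plan` is not
#'   given (ignored otherwise).
#' @param se_reduction squeeze-and-excitation bottleneck reduction ratio
#'   (default 16); bottleneck width is `max(width %/% r, 1)`.
#' @param out_channels number of output channels (default 1, binary tumor
#'   probability).
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_slices = 3L, depth = 5L, channel_plan = NULL,
                         base_channels = NULL, se_reduction = 16L,
                         out_channels = 1L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L || n_slices %% 2L == 0L)
    stop("invalid config: n_slices must be odd and >= 1")
  depth <- as.integer(depth)
  if (depth < 2L) stop("invalid config: depth must be >= 2")
  if (is.null(channel_plan)) {
    channel_plan <- if (!is.null(base_channels))
      as.integer(base_channels) * 2L^(seq_len(depth) - 1L)
    else if (depth == 5L) reference_channel_plan()
    else 16L * 2L^(seq_len(depth) - 1L)
  }
  channel_plan <- as.integer(channel_plan)
  if (length(channel_plan) != depth)
    stop("invalid config: channel_plan length must equal depth")
  if (any(channel_plan < 4L) || any(diff(channel_plan) < 0L))
    stop("invalid config: channel widths must be >= 4 and non-decreasing")
  structure(list(n_slices = n_slices, depth = depth,
                 channel_plan = channel_plan,
                 se_reduction = as.integer(se_reduction),
                 out_channels = as.integer(out_channels)),
            class = "model_config")
}

# parameter count of one bias-free conv + BN block
.count_cbr <- function(k, cin, cout) k * k * cin * cout + 2 * cout

.count_ris <- function(cin, cout, r) {
  w <- .ris_widths(cout)
  cb <- max(cout %/% r, 1L)
  .count_cbr(1, cin, w[["f1"]]) +
    .count_cbr(3, w[["f1"]], w[["f2"]]) +
    .count_cbr(3, w[["f2"]], w[["f3"]]) +
    .count_cbr(3, w[["f3"]], w[["f3"]]) +
    .count_cbr(3, w[["f3"]], w[["f4"]]) +
    .count_cbr(1, cout, cout) +
    (cout * cb + cb + cb * cout + cout) +
    (cin * cout + 2 * cout)
}

#' Count trainable parameters
#'
#' Total number of trainable parameters (convolution weights and biases,
#' batch-norm scales and shifts, SE bottleneck weights), computed directly
#' from the configuration. For a built model the counted arrays are summed
#' instead; the two agree by construction.
#'
#' @param x a `model_config` or `ris_unet` object.
#' @param units `"millions"` (rounded to 2 decimals, the conventional way a
#'   parameter budget is reported) or `"count"` (exact integer).
#' @return Numeric scalar.
#' @examples
#' count_parameters(model_config())       # default 2.5D model: 15.02
#' @export
count_parameters <- function(x, units = c("millions", "count")) {
  units <- match.arg(units)
  if (inherits(x, "ris_unet")) {
    total <- sum(vapply(as.list(x$P), length, numeric(1)))
  } else if (inherits(x, "model_config")) {
    p <- x$channel_plan
    d <- x$depth
    r <- x$se_reduction
    total <- .count_ris(x$n_slices, p[1], r)
    for (i in 2:d) total <- total + .count_ris(p[i - 1], p[i], r)
    for (i in (d - 1):1) {
      total <- total + (4 * p[i + 1] * p[i] + p[i])     # transposed 2x2 conv
      total <- total + .count_ris(2 * p[i], p[i], r)    # decoder block
    }
    total <- total + (p[1] * x$out_channels + x$out_channels)
  } else stop("`x` must be a model_config or ris_unet")
  if (units == "millions") round(total / 1e6, 2) else total
}

#' Build a Res-Inception-SE U-Net
#'
#' Allocates and initializes all network parameters (Kaiming-uniform
#' convolution weights, zero biases, unit batch-norm scales). Initialization
#' draws from R's RNG; set a seed (or pass `seed`) for reproducible weights.
#'
#' @param config a [model_config()].
#' @param seed optional integer seed applied before initialization.
#' @return An object of class `ris_unet`.
#' @export
ris_unet <- function(config = model_config(), seed = NULL) {
  if (!inherits(config, "model_config")) stop("`config` must be a model_config")
  if (!is.null(seed)) set.seed(seed)
  P <- new.env(parent = emptyenv())
  S <- new.env(parent = emptyenv())
  p <- config$channel_plan
  d <- config$depth
  r <- config$se_reduction
  .init_ris(P, S, "enc1", config$n_slices, p[1], r)
  for (i in 2:d) .init_ris(P, S, paste0("enc", i), p[i - 1], p[i], r)
  for (i in (d - 1):1) {
    .init_convt2(P, paste0("up", i), p[i + 1], p[i])
    .init_ris(P, S, paste0("dec", i), 2L * p[i], p[i], r)
  }
  .init_conv(P, "final", 1L, p[1], config$out_channels)
  structure(list(config = config, P = P, S = S), class = "ris_unet")
}

# Coerce a model input to (H, W, C, N): accepts a single stack (n, H, W),
# a list of stacks, or an already-batched 4-d array.
.as_input_batch <- function(x, n_slices) {
  if (is.list(x)) {
    arrs <- lapply(x, function(s) aperm(s, c(2, 3, 1)))
    d <- dim(arrs[[1]])
    out <- array(0, c(d[1], d[2], d[3], length(arrs)))
    for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
    return(out)
  }
  d <- dim(x)
  if (length(d) == 3L) {
    if (d[1] != n_slices)
      stop(sprintf("stack has %d channels, model expects %d", d[1], n_slices))
    out <- aperm(x, c(2, 3, 1))
    dim(out) <- c(dim(out), 1L)
    return(out)
  }
  if (length(d) == 4L) return(x)
  stop("input must be a (n, H, W) stack, a list of stacks, or a 4-d array")
}

# Full forward pass; returns sigmoid probabilities and (optionally) the
# caches needed for backprop.
.model_fw <- function(model, x, training = FALSE, keep_cache = training) {
  cfg <- model$config
  d <- dim(x)
  div <- 2L^(cfg$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf(
      "spatial dims (%d, %d) must be divisible by 2^(depth-1) = %d",
      d[1], d[2], div))
  if (d[3] != cfg$n_slices)
    stop(sprintf("input has %d channels, model expects n_slices = %d",
                 d[3], cfg$n_slices))
  P <- model$P; S <- model$S
  depth <- cfg$depth
  enc <- vector("list", depth)
  pools <- vector("list", depth - 1L)
  h <- x
  for (i in seq_len(depth)) {
    e <- .ris_fw(P, S, paste0("enc", i), h, training)
    enc[[i]] <- e
    if (i < depth) {
      pl <- cpp_maxpool2_fw(e$out)
      pools[[i]] <- list(idx = pl$idx, dim = dim(e$out))
      h <- pl$y
    } else h <- e$out
  }
  dec <- vector("list", depth - 1L)
  ups <- vector("list", depth - 1L)
  for (i in (depth - 1L):1L) {
    up <- cpp_convt2_fw(h, P[[paste0("up", i, ".w")]], P[[paste0("up", i, ".b")]])
    ups[[i]] <- list(x = h, updim = dim(up))
    cat_ <- .concat_c(list(up, enc[[i]]$out))
    dcb <- .ris_fw(P, S, paste0("dec", i), cat_, training)
    dec[[i]] <- dcb
    h <- dcb$out
  }
  logits <- cpp_conv2d_fw(h, P[["final.w"]], P[["final.b"]])
  prob <- 1 / (1 + exp(-logits))
  cache <- if (keep_cache)
    list(x = x, enc = lapply(enc, `[[`, "cache"), pools = pools, ups = ups,
         dec = lapply(dec, `[[`, "cache"), dec_in = h, prob = prob,
         skipw = vapply(seq_len(depth - 1L),
                        function(i) dim(enc[[i]]$out)[3], integer(1)),
         upw = vapply(seq_len(depth - 1L),
                      function(i) ups[[i]]$updim[3], integer(1)))
  else NULL
  list(prob = prob, cache = cache)
}

# Backward pass from dL/dprob; returns the gradient environment.
.model_bw <- function(model, cache, gprob) {
  P <- model$P; S <- model$S
  cfg <- model$config
  depth <- cfg$depth
  G <- new.env(parent = emptyenv())
  prob <- cache$prob
  glogits <- gprob * prob * (1 - prob)
  cr <- cpp_conv2d_bw(cache$dec_in, P[["final.w"]], glogits)
  .acc(G, "final.w", cr$gw)
  .acc(G, "final.b", cr$gb)
  gh <- cr$gx
  gskip <- vector("list", depth - 1L)
  for (i in seq_len(depth - 1L)) {
    gcat <- .ris_bw(P, G, S, paste0("dec", i), cache$dec[[i]], gh)
    parts <- .split_c(gcat, c(cache$upw[i], cache$skipw[i]))
    gskip[[i]] <- parts[[2]]
    ur <- cpp_convt2_bw(cache$ups[[i]]$x, P[[paste0("up", i, ".w")]], parts[[1]])
    .acc(G, paste0("up", i, ".w"), ur$gw)
    .acc(G, paste0("up", i, ".b"), ur$gb)
    gh <- ur$gx
  }
  for (i in depth:1L) {
    ge <- if (i == depth) gh else
      cpp_maxpool_bw(cache$pools[[i]]$idx, gh, cache$pools[[i]]$dim) +
        gskip[[i]]
    gh <- .ris_bw(P, G, S, paste0("enc", i), cache$enc[[i]], ge)
  }
  G
}

#' Forward pass of the network
#'
#' Runs the model in inference mode on a 2.5D stack (or a batch of stacks)
#' and returns per-pixel tumor probabilities in (0, 1) at full input
#' resolution. Spatial dimensions must be divisible by `2^(depth-1)`.
#'
#' @param model a [ris_unet()] model.
#' @param x a `(n, H, W)` stack from [build_stack()], a list of such stacks,
#'   or an `(H, W, n, N)` array.
#' @return Probability array: `(H, W)` matrix for a single stack, otherwise
#'   an `(H, W, 1, N)` array.
#' @export
model_forward <- function(model, x) {
  single <- !is.list(x) && length(dim(x)) == 3L
  xb <- .as_input_batch(x, model$config$n_slices)
  prob <- .model_fw(model, xb, training = FALSE)$prob
  if (single) prob[, , 1, 1] else prob
}

#' @export
predict.ris_unet <- function(object, newdata, ...) {
  if (inherits(newdata, "ct_volume")) return(predict_volume(object, newdata, ...))
  model_forward(object, newdata)
}

#' @export
print.ris_unet <- function(x, ...) {
  cfg <- x$config
  cat("<ris_unet> Res-Inception-SE U-Net\n")
  cat(sprintf("  input channels (2.5D slices): %d\n", cfg$n_slices))
  cat(sprintf("  depth: %d levels, channel plan: %s\n", cfg$depth,
              paste(cfg$channel_plan, collapse = "-")))
  cat(sprintf("  SE reduction: %d\n", cfg$se_reduction))
  cat(sprintf("  trainable parameters: %.2f M\n",
              count_parameters(cfg, "count") / 1e6))
  invisible(x)
}

#' @export
summary.ris_unet <- function(object, ...) {
  print(object)
  nms <- sort(ls(object$P))
  sizes <- vapply(nms, function(n) length(object$P[[n]]), numeric(1))
  df <- data.frame(parameter = nms, size = sizes, row.names = NULL)
  cat(sprintf("  %d parameter tensors; largest: %s (%d values)\n",
              nrow(df), df$parameter[which.max(df$size)], max(df$size)))
  invisible(df)
}

#' Save a model checkpoint
#'
#' Serializes the weights, batch-norm running statistics and the
#' configuration (also embedded as JSON metadata) to an RDS file.
#'
#' @param model a `ris_unet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_risunet <- function(model, path) {
  obj <- list(config = model$config,
              config_json = jsonlite::toJSON(unclass(model$config),
                                             auto_unbox = TRUE),
              params = as.list(model$P),
              state = as.list(model$S))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_risunet()].
#' @return A `ris_unet` model.
#' @export
load_risunet <- function(path) {
  obj <- readRDS(path)
  P <- list2env(obj$params, parent = emptyenv())
  S <- list2env(obj$state, parent = emptyenv())
  structure(list(config = obj$config, P = P, S = S), class = "ris_unet")
}
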