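# Internal neural-network plumbing: parameter initialization and hand-written
# forward/backward passes for the layers the network is built from. Parameters
# live in an environment `P` (named numeric arrays), batch-norm running
# statistics in `S`. Gradients are accumulated into an environment `G` that
# mirrors `P`'s names. Activations are (H, W, C, N) arrays.

.acc <- function(G, nm, val) {
  if (is.null(G[[nm]])) G[[nm]] <- val else G[[nm]] <- G[[nm]] + val
  invisible(NULL)
}

# Kaiming-uniform initialization (fan-in, ReLU gain), biases zero.
# Convolutions feeding a batch-norm layer carry no bias: BN's shift makes it
# redundant and its gradient would be identically zero.
.init_conv <- function(P, nm, k, cin, cout, bias = TRUE) {
  fan_in <- k * k * cin
  bound <- sqrt(6 / fan_in)
  P[[paste0(nm, ".w")]] <- array(runif(k * k * cin * cout, -bound, bound),
                                 c(k, k, cin, cout))
  if (bias) P[[paste0(nm, ".b")]] <- numeric(cout)
}

.init_convt2 <- function(P, nm, cin, cout) {
  fan_in <- 4 * cin
  bound <- sqrt(6 / fan_in)
  P[[paste0(nm, ".w")]] <- array(runif(4 * cin * cout, -bound, bound),
                                 c(2, 2, cin, cout))
  P[[paste0(nm, ".b")]] <- numeric(cout)
}

.init_bn <- function(P, S, nm, c) {
  P[[paste0(nm, ".g")]] <- rep(1, c)
  P[[paste0(nm, ".be")]] <- numeric(c)
  S[[paste0(nm, ".rm")]] <- numeric(c)
  S[[paste0(nm, ".rv")]] <- rep(1, c)
}

.init_cbr <- function(P, S, nm, k, cin, cout) {
  .init_conv(P, paste0(nm, ".conv"), k, cin, cout, bias = FALSE)
  .init_bn(P, S, paste0(nm, ".bn"), cout)
}

# The squeeze weights are drawn non-negative: the pooled descriptor of a
# post-ReLU feature map is non-negative, so this keeps every bottleneck unit
# strictly active at initialization (no dead ReLU units in the gate).
.init_se <- function(P, nm, c, reduction) {
  cb <- max(c %/% reduction, 1L)
  b1 <- sqrt(6 / c)
  b2 <- sqrt(6 / cb)
  P[[paste0(nm, ".w1")]] <- matrix(runif(c * cb, 0, b1), c, cb)
  P[[paste0(nm, ".b1")]] <- numeric(cb)
  P[[paste0(nm, ".w2")]] <- matrix(runif(cb * c, -b2, b2), cb, c)
  P[[paste0(nm, ".b2")]] <- numeric(c)
}

# Branch widths of a Res-Inception-SE block: the three 3x3 branches get
# floor(cout/4) channels each, the 1x1 branch takes the remainder.
.ris_widths <- function(cout) {
  w <- cout %/% 4L
  c(f1 = cout - 3L * w, f2 = w, f3 = w, f4 = w)
}

.init_ris <- function(P, S, nm, cin, cout, reduction) {
  w <- .ris_widths(cout)
  .init_cbr(P, S, paste0(nm, ".f1"), 1L, cin, w["f1"])
  .init_cbr(P, S, paste0(nm, ".f2"), 3L, w["f1"], w["f2"])
  .init_cbr(P, S, paste0(nm, ".f3a"), 3L, w["f2"], w["f3"])
  .init_cbr(P, S, paste0(nm, ".f3b"), 3L, w["f3"], w["f3"])
  .init_cbr(P, S, paste0(nm, ".f4"), 3L, w["f3"], w["f4"])
  .init_cbr(P, S, paste0(nm, ".fuse"), 1L, cout, cout)
  .init_se(P, paste0(nm, ".se"), cout, reduction)
  .init_conv(P, paste0(nm, ".res"), 1L, cin, cout, bias = FALSE)
  .init_bn(P, S, paste0(nm, ".resbn"), cout)
}

# ---- conv + batch norm + ReLU ----------------------------------------------

.cbr_fw <- function(P, S, nm, x, training, eps = 1e-5, momentum = 0.1) {
  w <- P[[paste0(nm, ".conv.w")]]
  z <- cpp_conv2d_fw(x, w, numeric(dim(w)[4]))
  g <- P[[paste0(nm, ".bn.g")]]
  be <- P[[paste0(nm, ".bn.be")]]
  if (training) {
    r <- cpp_bn_train_fw(z, g, be, eps)
    S[[paste0(nm, ".bn.rm")]] <- (1 - momentum) * S[[paste0(nm, ".bn.rm")]] + momentum * r$mean
    S[[paste0(nm, ".bn.rv")]] <- (1 - momentum) * S[[paste0(nm, ".bn.rv")]] + momentum * r$var
    y <- r$y
    cache <- list(x = x, z = z, mean = r$mean, invstd = r$invstd,
                  training = TRUE)
  } else {
    y <- cpp_bn_eval_fw(z, g, be, S[[paste0(nm, ".bn.rm")]],
                        S[[paste0(nm, ".bn.rv")]], eps)
    cache <- list(x = x, z = z, training = FALSE)
  }
  mask <- y > 0
  a <- y * mask
  cache$mask <- mask
  list(out = a, cache = cache)
}

.cbr_bw <- function(P, G, S, nm, cache, ga, eps = 1e-5) {
  gy <- ga * cache$mask
  g <- P[[paste0(nm, ".bn.g")]]
  if (cache$training) {
    r <- cpp_bn_train_bw(cache$z, cache$mean, cache$invstd, g, gy)
    .acc(G, paste0(nm, ".bn.g"), r$ggamma)
    .acc(G, paste0(nm, ".bn.be"), r$gbeta)
    gz <- r$gx
  } else {
    gz <- cpp_bn_eval_bw(g, S[[paste0(nm, ".bn.rv")]], eps, gy)
  }
  cr <- cpp_conv2d_bw(cache$x, P[[paste0(nm, ".conv.w")]], gz)
  .acc(G, paste0(nm, ".conv.w"), cr$gw)
  cr$gx
}

# plain conv + BN (no ReLU): the residual projection path
.convbn_fw <- function(P, S, nm, bnnm, x, training, eps = 1e-5, momentum = 0.1) {
  w <- P[[paste0(nm, ".w")]]
  z <- cpp_conv2d_fw(x, w, numeric(dim(w)[4]))
  g <- P[[paste0(bnnm, ".g")]]
  be <- P[[paste0(bnnm, ".be")]]
  if (training) {
    r <- cpp_bn_train_fw(z, g, be, eps)
    S[[paste0(bnnm, ".rm")]] <- (1 - momentum) * S[[paste0(bnnm, ".rm")]] + momentum * r$mean
    S[[paste0(bnnm, ".rv")]] <- (1 - momentum) * S[[paste0(bnnm, ".rv")]] + momentum * r$var
    list(out = r$y, cache = list(x = x, z = z, mean = r$mean,
                                 invstd = r$invstd, training = TRUE))
  } else {
    y <- cpp_bn_eval_fw(z, g, be, S[[paste0(bnnm, ".rm")]],
                        S[[paste0(bnnm, ".rv")]], eps)
    list(out = y, cache = list(x = x, z = z, training = FALSE))
  }
}

.convbn_bw <- function(P, G, S, nm, bnnm, cache, gy, eps = 1e-5) {
  g <- P[[paste0(bnnm, ".g")]]
  if (cache$training) {
    r <- cpp_bn_train_bw(cache$z, cache$mean, cache$invstd, g, gy)
    .acc(G, paste0(bnnm, ".g"), r$ggamma)
    .acc(G, paste0(bnnm, ".be"), r$gbeta)
    gz <- r$gx
  } else {
    gz <- cpp_bn_eval_bw(g, S[[paste0(bnnm, ".rv")]], eps, gy)
  }
  cr <- cpp_conv2d_bw(cache$x, P[[paste0(nm, ".w")]], gz)
  .acc(G, paste0(nm, ".w"), cr$gw)
  cr$gx
}

# ---- squeeze-and-excitation -------------------------------------------------

.channel_means <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  matrix(colMeans(m), d[3], d[4])        # C x N
}

.se_fw <- function(P, nm, x) {
  d <- dim(x)
  s <- .channel_means(x)                                  # C x N
  h <- crossprod(P[[paste0(nm, ".w1")]], s) + P[[paste0(nm, ".b1")]]   # Cb x N
  h <- h * (h > 0)
  z2 <- crossprod(P[[paste0(nm, ".w2")]], h) + P[[paste0(nm, ".b2")]]  # C x N
  wgt <- 1 / (1 + exp(-z2))
  scale <- array(rep(wgt, each = d[1] * d[2]), d)
  list(out = x * scale, cache = list(x = x, s = s, h = h, wgt = wgt))
}

.se_bw <- function(P, G, nm, cache, gy) {
  x <- cache$x
  d <- dim(x)
  hw <- d[1] * d[2]
  wgt <- cache$wgt
  scale <- array(rep(wgt, each = hw), d)
  gx <- gy * scale
  gwgt <- matrix(colSums(matrix(gy * x, hw, d[3] * d[4])), d[3], d[4])
  gz2 <- gwgt * wgt * (1 - wgt)
  .acc(G, paste0(nm, ".b2"), rowSums(gz2))
  .acc(G, paste0(nm, ".w2"), cache$h %*% t(gz2))
  gh <- P[[paste0(nm, ".w2")]] %*% gz2
  gh <- gh * (cache$h > 0)
  .acc(G, paste0(nm, ".b1"), rowSums(gh))
  .acc(G, paste0(nm, ".w1"), cache$s %*% t(gh))
  gs <- P[[paste0(nm, ".w1")]] %*% gh                     # C x N
  gx + array(rep(gs / hw, each = hw), d)
}

# ---- channel concat / split -------------------------------------------------

.concat_c <- function(parts) {
  d1 <- dim(parts[[1]])
  cs <- vapply(parts, function(p) dim(p)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (p in parts) {
    cp <- dim(p)[3]
    out[, , off + seq_len(cp), ] <- p
    off <- off + cp
  }
  out
}

.split_c <- function(g, widths) {
  off <- 0L
  out <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    out[[i]] <- g[, , off + seq_len(widths[i]), , drop = FALSE]
    off <- off + widths[i]
  }
  out
}

# ---- Res-Inception-SE block -------------------------------------------------

.ris_fw <- function(P, S, nm, x, training) {
  c1 <- .cbr_fw(P, S, paste0(nm, ".f1"), x, training)
  c2 <- .cbr_fw(P, S, paste0(nm, ".f2"), c1$out, training)
  c3a <- .cbr_fw(P, S, paste0(nm, ".f3a"), c2$out, training)
  c3b <- .cbr_fw(P, S, paste0(nm, ".f3b"), c3a$out, training)
  pl <- cpp_maxpool3s1_fw(c3b$out)
  c4 <- .cbr_fw(P, S, paste0(nm, ".f4"), pl$y, training)
  cat_ <- .concat_c(list(c1$out, c2$out, c3b$out, c4$out))
  cf <- .cbr_fw(P, S, paste0(nm, ".fuse"), cat_, training)
  se <- .se_fw(P, paste0(nm, ".se"), cf$out)
  res <- .convbn_fw(P, S, paste0(nm, ".res"), paste0(nm, ".resbn"), x, training)
  out <- se$out + res$out
  list(out = out,
       cache = list(c1 = c1$cache, c2 = c2$cache, c3a = c3a$cache,
                    c3b = c3b$cache, plidx = pl$idx, pldim = dim(c3b$out),
                    c4 = c4$cache, cf = cf$cache, se = se$cache,
                    res = res$cache,
                    widths = c(dim(c1$out)[3], dim(c2$out)[3],
                               dim(c3b$out)[3], dim(c4$out)[3])))
}

.ris_bw <- function(P, G, S, nm, cache, gout) {
  gx_res <- .convbn_bw(P, G, S, paste0(nm, ".res"), paste0(nm, ".resbn"),
                       cache$res, gout)
  gcf <- .se_bw(P, G, paste0(nm, ".se"), cache$se, gout)
  gcat <- .cbr_bw(P, G, S, paste0(nm, ".fuse"), cache$cf, gcf)
  gs <- .split_c(gcat, cache$widths)
  gpl <- .cbr_bw(P, G, S, paste0(nm, ".f4"), cache$c4, gs[[4]])
  g3_extra <- cpp_maxpool_bw(cache$plidx, gpl, cache$pldim)
  g3 <- gs[[3]] + g3_extra
  g3a <- .cbr_bw(P, G, S, paste0(nm, ".f3b"), cache$c3b, g3)
  g2 <- gs[[2]] + .cbr_bw(P, G, S, paste0(nm, ".f3a"), cache$c3a, g3a)
  g1 <- gs[[1]] + .cbr_bw(P, G, S, paste0(nm, ".f2"), cache$c2, g2)
  gx_main <- .cbr_bw(P, G, S, paste0(nm, ".f1"), cache$c1, g1)
  gx_main + gx_res
}
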