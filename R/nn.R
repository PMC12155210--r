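# Minimal 3D convolutional network engine used by the multi-task valve-ROI
# model: feature maps are (channels x voxels) matrices, convolutions are
# 3x3x3 with pad 1 realised through im2col + GEMM, and every layer has an
# explicit backward pass. No autodiff framework is involved; gradients are
# verified against finite differences in the test suite.

lrelu <- function(x, slope) {
  neg <- x < 0
  x * (1 - (1 - slope) * neg)
}
lrelu_grad <- function(x, slope) 1 - (1 - slope) * (x < 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

conv_fwd <- function(W, b, x, dims, stride) {
  cols <- cpp_im2col3(x, dims, stride)
  list(y = sweep(W %*% cols, 1, b, "+"), cols = cols)
}

# gradients of a conv layer, reusing the im2col columns from the forward pass
conv_bwd <- function(W, cols, in_channels, dims, stride, dy) {
  dW <- tcrossprod(dy, cols)
  db <- rowSums(dy)
  dcols <- crossprod(W, dy)
  dx <- cpp_col2im3(dcols, in_channels, dims, stride)
  list(dW = dW, db = db, dx = dx)
}

half_dims <- function(d) as.integer((d - 1) %/% 2 + 1)

init_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build the three-branch multi-task network
#'
#' A 3D U-Net-style encoder-decoder whose decoder head emits per-voxel
#' cylinder segmentation logits (branch 1) and whose latent bottleneck is
#' globally average-pooled into a descriptor feeding a regularized MLP
#' (fully connected, LeakyReLU, LayerNorm, dropout, fully connected, tanh)
#' that regresses the 7 cylinder parameters (branch 2). The pooled
#' descriptor length equals the encoder output channel count
#' (`4 * base_channels`, 256 at the default width). Branch 3 — the
#' differentiable cylinder reconstruction — lives in the loss, see
#' [combined_loss()].
#'
#' @param input_shape model input shape; each axis must be divisible by 8.
#'   Default `c(176, 176, 128)`.
#' @param base_channels encoder width at the first level (default 64,
#'   giving a 256-channel latent space; the desk preset uses 8).
#' @param mlp_hidden hidden width of the regression MLP (default
#'   `4 * base_channels`).
#' @param dropout dropout probability in the MLP (default 0.1).
#' @param lrelu_slope LeakyReLU negative slope (default 0.01).
#' @param seed RNG seed for weight initialization.
#' @return An `avc_network` with weights, configuration and layer shapes.
#' @export
build_network <- function(input_shape = c(176, 176, 128), base_channels = 64,
                          mlp_hidden = NULL, dropout = 0.1, lrelu_slope = 0.01,
                          seed = 1L) {
  input_shape <- as.integer(input_shape)
  if (any(input_shape %% 8L != 0L))
    stop("input shape must be divisible by 8 along every axis")
  C <- as.integer(base_channels)
  H <- if (is.null(mlp_hidden)) 4L * C else as.integer(mlp_hidden)
  s0 <- input_shape; s1 <- half_dims(s0); s2 <- half_dims(s1); s3 <- half_dims(s2)
  par <- with_seed(seed, function() list(
    W1 = init_mat(C, 27, 27), b1 = numeric(C),
    W2 = init_mat(2L * C, C * 27, C * 27), b2 = numeric(2L * C),
    W3 = init_mat(4L * C, 2L * C * 27, 2L * C * 27), b3 = numeric(4L * C),
    W4 = init_mat(C, 6L * C * 27, 6L * C * 27), b4 = numeric(C),
    W5 = init_mat(C, 2L * C * 27, 2L * C * 27), b5 = numeric(C),
    W6 = init_mat(1L, C, C), b6 = -1.5,  # start near the foreground prior

    Wm1 = init_mat(H, 4L * C, 4L * C), bm1 = numeric(H),
    ln_g = rep(1, H), ln_b = numeric(H),
    Wm2 = init_mat(7L, H, H) * 0.1, bm2 = numeric(7)))
  structure(list(par = par,
                 cfg = list(input_shape = s0, base_channels = C,
                            mlp_hidden = H, dropout = dropout,
                            lrelu_slope = lrelu_slope,
                            dims = list(s0 = s0, s1 = s1, s2 = s2, s3 = s3))),
            class = "avc_network")
}

#' @export
print.avc_network <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<avc_network> input %s, base channels %d, latent %d, %d regressed parameters\n",
              paste(cfg$input_shape, collapse = "x"), cfg$base_channels,
              4 * cfg$base_channels, nrow(x$par$Wm2)))
  invisible(x)
}

#' Regression head dimensionality
#'
#' @param net an `avc_network`.
#' @return Number of regressed cylinder parameters (7: normal, origin,
#'   rescaled radius; height is fixed at 40 mm).
#' @export
n_regressed_params <- function(net) nrow(net$par$Wm2)

# forward pass for one sample; x is a numeric vector of length prod(s0)
net_forward <- function(net, x, train = FALSE) {
  p <- net$par; cfg <- net$cfg; d <- cfg$dims; sl <- cfg$lrelu_slope
  if (length(x) != prod(d$s0)) stop("input shape incompatible with the network")
  x <- matrix(x, nrow = 1)
  cf1 <- conv_fwd(p$W1, p$b1, x, d$s0, 2L); a1 <- cf1$y; h1 <- lrelu(a1, sl)
  cf2 <- conv_fwd(p$W2, p$b2, h1, d$s1, 2L); a2 <- cf2$y; h2 <- lrelu(a2, sl)
  cf3 <- conv_fwd(p$W3, p$b3, h2, d$s2, 2L); a3 <- cf3$y; h3 <- lrelu(a3, sl)
  u3 <- cpp_upsample_nn(h3, d$s3)
  c3 <- rbind(u3, h2)
  cf4 <- conv_fwd(p$W4, p$b4, c3, d$s2, 1L); a4 <- cf4$y; d3 <- lrelu(a4, sl)
  u2 <- cpp_upsample_nn(d3, d$s2)
  c2 <- rbind(u2, h1)
  cf5 <- conv_fwd(p$W5, p$b5, c2, d$s1, 1L); a5 <- cf5$y; d2 <- lrelu(a5, sl)
  u1 <- cpp_upsample_nn(d2, d$s1)
  logits <- sweep(p$W6 %*% u1, 1, p$b6, "+")
  g <- rowMeans(h3)
  m1 <- as.vector(p$Wm1 %*% g + p$bm1)
  am <- lrelu(m1, sl)
  mu <- mean(am); va <- mean((am - mu)^2); sdv <- sqrt(va + 1e-5)
  xhat <- (am - mu) / sdv
  ln <- p$ln_g * xhat + p$ln_b
  if (train && cfg$dropout > 0) {
    keep <- stats::rbinom(length(ln), 1, 1 - cfg$dropout) / (1 - cfg$dropout)
  } else keep <- rep(1, length(ln))
  dp <- ln * keep
  pre <- as.vector(p$Wm2 %*% dp + p$bm2)
  pv <- tanh(pre)
  list(logits = as.vector(logits), pv = pv,
       cache = list(a1 = a1, a2 = a2, a3 = a3, h3 = h3, a4 = a4, a5 = a5,
                    u1 = u1, g = g, m1 = m1, am = am, xhat = xhat,
                    sdv = sdv, keep = keep, dp = dp, pv = pv,
                    cols1 = cf1$cols, cols2 = cf2$cols, cols3 = cf3$cols,
                    cols4 = cf4$cols, cols5 = cf5$cols))
}

# backward pass: dlogits (vector), dpv (vector length 7) -> gradient list
net_backward <- function(net, cache, dlogits, dpv) {
  p <- net$par; cfg <- net$cfg; d <- cfg$dims; sl <- cfg$lrelu_slope
  C <- cfg$base_channels
  gr <- list()
  # regression head
  dpre <- dpv * (1 - cache$pv^2)
  gr$Wm2 <- outer(dpre, cache$dp); gr$bm2 <- dpre
  ddp <- as.vector(t(p$Wm2) %*% dpre)
  dln <- ddp * cache$keep
  gr$ln_g <- dln * cache$xhat; gr$ln_b <- dln
  dxhat <- dln * p$ln_g
  H <- length(dxhat)
  dam <- (dxhat - mean(dxhat) - cache$xhat * mean(dxhat * cache$xhat)) / cache$sdv
  dm1 <- dam * lrelu_grad(cache$m1, sl)
  gr$Wm1 <- outer(dm1, cache$g); gr$bm1 <- dm1
  dg <- as.vector(t(p$Wm1) %*% dm1)
  # pooled descriptor -> latent
  n3 <- prod(d$s3)
  dh3_reg <- matrix(dg / n3, nrow = 4 * C, ncol = n3)
  # segmentation head
  dlog <- matrix(dlogits, nrow = 1)
  gr$W6 <- tcrossprod(dlog, cache$u1); gr$b6 <- sum(dlog)
  du1 <- crossprod(p$W6, dlog)
  dd2 <- cpp_upsample_nn_bwd(du1, d$s1)
  da5 <- dd2 * lrelu_grad(cache$a5, sl)
  bw5 <- conv_bwd(p$W5, cache$cols5, 2L * C, d$s1, 1L, da5)
  gr$W5 <- bw5$dW; gr$b5 <- bw5$db
  du2 <- bw5$dx[1:C, , drop = FALSE]
  dh1_dec <- bw5$dx[(C + 1):(2 * C), , drop = FALSE]
  dd3 <- cpp_upsample_nn_bwd(du2, d$s2)
  da4 <- dd3 * lrelu_grad(cache$a4, sl)
  bw4 <- conv_bwd(p$W4, cache$cols4, 6L * C, d$s2, 1L, da4)
  gr$W4 <- bw4$dW; gr$b4 <- bw4$db
  du3 <- bw4$dx[1:(4 * C), , drop = FALSE]
  dh2_dec <- bw4$dx[(4 * C + 1):(6 * C), , drop = FALSE]
  dh3 <- cpp_upsample_nn_bwd(du3, d$s3) + dh3_reg
  # encoder
  da3 <- dh3 * lrelu_grad(cache$a3, sl)
  bw3 <- conv_bwd(p$W3, cache$cols3, 2L * C, d$s2, 2L, da3)
  gr$W3 <- bw3$dW; gr$b3 <- bw3$db
  dh2 <- bw3$dx + dh2_dec
  da2 <- dh2 * lrelu_grad(cache$a2, sl)
  bw2 <- conv_bwd(p$W2, cache$cols2, C, d$s1, 2L, da2)
  gr$W2 <- bw2$dW; gr$b2 <- bw2$db
  dh1 <- bw2$dx + dh1_dec
  da1 <- dh1 * lrelu_grad(cache$a1, sl)
  bw1 <- conv_bwd(p$W1, cache$cols1, 1L, d$s0, 2L, da1)
  gr$W1 <- bw1$dW; gr$b1 <- bw1$db
  gr
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

accum_grads <- function(acc, gr) {
  if (is.null(acc)) return(gr)
  for (nm in names(gr)) acc[[nm]] <- acc[[nm]] + gr[[nm]]
  acc
}

scale_grads <- function(gr, s) lapply(gr, function(g) g * s)
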