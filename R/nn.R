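#' @useDynLib tauseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd
#' @importFrom utils head
NULL

# ---------------------------------------------------------------------------
# Compact CPU CNN toolkit. Parameters live in flat named lists of arrays;
# every layer exposes a forward returning (y, cache) and a backward mapping
# the upstream gradient to (dx, parameter gradients). Channel is always the
# last array dimension.
# ---------------------------------------------------------------------------

he_init <- function(dim, fan_in) {
  array(stats::rnorm(prod(dim), sd = sqrt(2 / fan_in)), dim = dim)
}

conv2d_init <- function(k, cin, cout) {
  list(w = he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
}

conv3d_init <- function(k, cin, cout) {
  list(w = he_init(c(k, k, k, cin, cout), k^3 * cin), b = numeric(cout))
}

upconv2d_init <- function(cin, cout) {
  list(w = he_init(c(2, 2, cin, cout), 4 * cin), b = numeric(cout))
}

norm_init <- function(c) list(g = rep(1, c), b = numeric(c))

dense_init <- function(cin, cout) {
  list(w = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

# Per-sample, per-channel normalization with learned scale/shift. Identical
# behaviour at train and inference time, which keeps every forward pass
# deterministic.
inorm_fwd <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  C <- d[length(d)]
  m <- matrix(x, ncol = C)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(xhat, 2, g, `*`)
  y <- sweep(y, 2, b, `+`)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, g = g, d = d))
}

inorm_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[length(d)]
  dym <- matrix(dy, ncol = C)
  dg <- colSums(dym * cache$xhat)
  db <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$g, `*`)
  n <- nrow(dym)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$istd, `*`)
  dim(dx) <- d
  list(dx = dx, dg = dg, db = db)
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

lrelu_fwd <- function(x, slope = 0.01) {
  pos <- x > 0
  list(y = x * (slope + (1 - slope) * pos),
       cache = list(pos = pos, slope = slope))
}
lrelu_bwd <- function(dy, cache) {
  dy * (cache$slope + (1 - cache$slope) * cache$pos)
}

# inference-only instance norm (no cache, fused scale/shift)
inorm_eval <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  C <- d[length(d)]
  m <- matrix(x, ncol = C)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  A <- g / sqrt(pmax(v, 0) + eps)
  y <- sweep(m, 2, A, `*`)
  y <- sweep(y, 2, b - mu * A, `+`)
  dim(y) <- d
  y
}

# Softmax over the channel (last) dimension.
softmax_channels <- function(z) {
  d <- dim(z)
  C <- d[length(d)]
  m <- matrix(z, ncol = C)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

softmax_bwd <- function(dp, p) {
  d <- dim(p)
  C <- d[length(d)]
  dpm <- matrix(dp, ncol = C)
  pm <- matrix(p, ncol = C)
  dz <- pm * (dpm - rowSums(dpm * pm))
  dim(dz) <- d
  dz
}

# ---------------------------------------------------------------------------
# Adam with optional polynomial learning-rate decay.
# ---------------------------------------------------------------------------

adam_state <- function(params) {
  zeros <- lapply(params, function(p) {
    z <- p * 0
    z
  })
  list(t = 0L, m = zeros, v = zeros)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Polynomially decayed learning rate
#'
#' `lr0 * (1 - (step - 1) / total)^gamma`, the schedule used by both the
#' localizer and the segmentation networks.
#'
#' @param lr0 base learning rate.
#' @param step current optimizer step (1-based).
#' @param total total number of steps.
#' @param gamma decay exponent.
#' @return scalar learning rate.
#' @export
poly_decay <- function(lr0, step, total, gamma = 0.1) {
  frac <- max(0, 1 - (step - 1) / total)
  lr0 * frac^gamma
}

# Accumulate grads (sum) across samples of a batch.
acc_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
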