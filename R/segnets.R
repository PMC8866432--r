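# Segmentation networks: additive attention gate, texture attention block,
# Attention U-Net, TAU-Net (texture-attention U-Net) and the 3D hybrid
# fuser. Forward and backward passes are hand-wired over the kernel layer;
# parameters live in flat named lists so the same Adam driver serves every
# network.

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:2] == db[1:2]))
  array(cbind(matrix(a, ncol = da[3]), matrix(b, ncol = db[3])),
        dim = c(da[1:2], da[3] + db[3]))
}

upsample2_nearest <- function(a) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Attention gate: phi = sigmoid(psi(ReLU(W_l x_l + W_h x_h))), x_hat = phi*x_l
# ---------------------------------------------------------------------------

#' Attention gate weights
#'
#' Separate 1x1 projections of the low-level (skip) and high-level (gating)
#' features into a shared intermediate width (default: half the skip
#' channels), a ReLU, a 1-channel scoring projection and a sigmoid.
#'
#' @param cl skip (low-level) channels.
#' @param ch gating (high-level) channels.
#' @param fint intermediate width; default `max(1, cl %/% 2)`.
#' @return named list of weight matrices/vectors.
#' @export
ag_weights <- function(cl, ch, fint = NULL) {
  if (is.null(fint)) fint <- max(1L, cl %/% 2L)
  list(Wl = matrix(stats::rnorm(cl * fint, sd = sqrt(2 / cl)), cl, fint),
       Wh = matrix(stats::rnorm(ch * fint, sd = sqrt(2 / ch)), ch, fint),
       ba = numeric(fint),
       wpsi = matrix(stats::rnorm(fint, sd = sqrt(2 / fint)), fint, 1),
       bpsi = 0)
}

ag_fwd_core <- function(W, xl, xh) {
  dl <- dim(xl)
  XL <- matrix(xl, ncol = dl[3])
  XH <- matrix(xh, ncol = dim(xh)[3])
  A <- sweep(XL %*% W$Wl + XH %*% W$Wh, 2, W$ba, `+`)
  Rl <- pmax(A, 0)
  s <- Rl %*% W$wpsi + W$bpsi
  phi <- 1 / (1 + exp(-s))
  Y <- XL * as.vector(phi)
  list(y = array(Y, dim = dl), phi = matrix(phi, dl[1], dl[2]),
       cache = list(XL = XL, XH = XH, pos = A > 0, Rl = Rl, phi = phi,
                    dl = dl, dh = dim(xh)))
}

ag_bwd_core <- function(W, cache, dy) {
  DY <- matrix(dy, ncol = cache$dl[3])
  phi <- as.vector(cache$phi)
  dphi <- rowSums(DY * cache$XL)
  dXL <- DY * phi
  ds <- dphi * phi * (1 - phi)
  dRl <- ds %*% t(W$wpsi)
  dA <- dRl * cache$pos
  list(dxl = array(dXL + dA %*% t(W$Wl), dim = cache$dl),
       dxh = array(dA %*% t(W$Wh), dim = cache$dh),
       grads = list(Wl = crossprod(cache$XL, dA),
                    Wh = crossprod(cache$XH, dA),
                    ba = colSums(dA),
                    wpsi = crossprod(cache$Rl, matrix(ds, ncol = 1)),
                    bpsi = sum(ds)))
}

#' Apply an attention gate
#'
#' The gating feature must already live on the skip feature's grid. Returns
#' the attention coefficient map (always in (0, 1)) and the attended skip
#' features `phi * x_l`, elementwise bounded by `|x_l|`.
#'
#' @param x_l skip features, array `(H, W, Cl)`.
#' @param x_h gating features, array `(H, W, Ch)`.
#' @param weights an [ag_weights()] list.
#' @return list with `phi` (H x W matrix) and `x_l_hat`.
#' @export
attention_gate <- function(x_l, x_h, weights) {
  if (!all(dim(x_l)[1:2] == dim(x_h)[1:2]))
    stop("shape error: x_l and x_h grids differ")
  r <- ag_fwd_core(weights, x_l, x_h)
  list(phi = r$phi, x_l_hat = r$y)
}

#' Texture attention block
#'
#' Concatenates precomputed texture descriptor maps onto the high-level
#' features (`x_h_new = concat(x_h, txfea)`), gates the skip features with
#' the enriched gating signal, and emits the block output
#' `upsample(concat(x_l_hat, x_h_new))`. With zero texture input and zero
#' weights on the texture channels this reduces exactly to the plain
#' attention gate.
#'
#' @inheritParams attention_gate
#' @param txfea texture features on `x_h`'s grid, array `(H, W, Ct)`.
#' @param weights an [ag_weights()] list built for `ch + ct` gating
#'   channels.
#' @param upsample whether to apply the 2x nearest-neighbor upsampling to
#'   the concatenated output.
#' @return list with `phi`, `x_l_hat`, `x_h_new` and `output`.
#' @export
texture_attention_block <- function(x_l, x_h, txfea, weights,
                                    upsample = TRUE) {
  if (!all(dim(x_h)[1:2] == dim(txfea)[1:2]))
    stop("shape error: txfea grid must equal x_h grid")
  xh_new <- concat_ch(x_h, txfea)
  g <- attention_gate(x_l, xh_new, weights)
  out <- concat_ch(g$x_l_hat, xh_new)
  if (upsample) out <- upsample2_nearest(out)
  list(phi = g$phi, x_l_hat = g$x_l_hat, x_h_new = xh_new, output = out)
}

# ---------------------------------------------------------------------------
# Conv block: two 3x3 conv + per-sample norm + ReLU
# ---------------------------------------------------------------------------

cb_init <- function(cin, cout) {
  c1 <- conv2d_init(3, cin, cout)
  c2 <- conv2d_init(3, cout, cout)
  n1 <- norm_init(cout); n2 <- norm_init(cout)
  list(c1.w = c1$w, c1.b = c1$b, n1.g = n1$g, n1.b = n1$b,
       c2.w = c2$w, c2.b = c2$b, n2.g = n2$g, n2.b = n2$b)
}

pget <- function(P, pfx, nm) P[[paste0(pfx, ".", nm)]]

cb_fwd <- function(P, pfx, x) {
  z1 <- conv2d_fwd_cpp(x, pget(P, pfx, "c1.w"), pget(P, pfx, "c1.b"), 1L)
  n1 <- inorm_fwd(z1, pget(P, pfx, "n1.g"), pget(P, pfx, "n1.b"))
  r1 <- relu_fwd(n1$y)
  z2 <- conv2d_fwd_cpp(r1$y, pget(P, pfx, "c2.w"), pget(P, pfx, "c2.b"), 1L)
  n2 <- inorm_fwd(z2, pget(P, pfx, "n2.g"), pget(P, pfx, "n2.b"))
  r2 <- relu_fwd(n2$y)
  list(y = r2$y, cache = list(x = x, r1 = r1$y, n1 = n1$cache,
                              n2 = n2$cache, m1 = r1$cache, m2 = r2$cache))
}

cb_bwd <- function(P, pfx, cache, dy) {
  g <- list()
  d <- relu_bwd(dy, cache$m2)
  nb <- inorm_bwd(d, cache$n2)
  g[[paste0(pfx, ".n2.g")]] <- nb$dg
  g[[paste0(pfx, ".n2.b")]] <- nb$db
  cb2 <- conv2d_bwd_cpp(cache$r1, pget(P, pfx, "c2.w"), nb$dx, 1L)
  g[[paste0(pfx, ".c2.w")]] <- cb2$dw
  g[[paste0(pfx, ".c2.b")]] <- cb2$db
  d <- relu_bwd(cb2$dx, cache$m1)
  nb <- inorm_bwd(d, cache$n1)
  g[[paste0(pfx, ".n1.g")]] <- nb$dg
  g[[paste0(pfx, ".n1.b")]] <- nb$db
  cb1 <- conv2d_bwd_cpp(cache$x, pget(P, pfx, "c1.w"), nb$dx, 1L)
  g[[paste0(pfx, ".c1.w")]] <- cb1$dw
  g[[paste0(pfx, ".c1.b")]] <- cb1$db
  list(dx = cb1$dx, grads = g)
}

prefix_names <- function(lst, pfx) {
  stats::setNames(lst, paste0(pfx, ".", names(lst)))
}

# ---------------------------------------------------------------------------
# Attention U-Net / TAU-Net construction
# ---------------------------------------------------------------------------

build_unet_family <- function(widths, in_ch, n_classes, tex_channels, seed) {
  if (!is.null(seed)) set.seed(seed)
  w <- widths
  P <- list()
  P <- c(P, prefix_names(cb_init(in_ch, w[1]), "e1"))
  for (l in 2:5) P <- c(P, prefix_names(cb_init(w[l - 1], w[l]),
                                        paste0("e", l)))
  for (l in 4:1) {
    up <- upconv2d_init(w[l + 1], w[l])
    P <- c(P, prefix_names(up, paste0("up", l)))
    ag <- ag_weights(w[l], w[l] + tex_channels[l])
    P <- c(P, prefix_names(ag, paste0("ag", l)))
    P <- c(P, prefix_names(cb_init(2 * w[l] + tex_channels[l], w[l]),
                           paste0("d", l)))
  }
  hd <- dense_init(w[1], n_classes)
  P <- c(P, list(head.w = hd$w, head.b = hd$b))
  structure(list(params = P, widths = w, in_ch = in_ch,
                 n_classes = n_classes, tex_channels = tex_channels),
            class = "tauseg_net")
}

#' Build an Attention U-Net
#'
#' Five-step encoder (two 3x3 convolutions + normalization + ReLU per step,
#' 2x2 max pooling between steps), transposed-convolution decoder, and an
#' attention gate on every skip connection. The forward pass maps a
#' `1 x H x W` slice to `C` per-pixel class probabilities summing to 1.
#' `H` and `W` must be divisible by 32.
#'
#' @param widths encoder channel widths (5 values).
#' @param in_ch input channels (slices are fed single-channel).
#' @param n_classes output classes (background, pancreas, tumor).
#' @param seed RNG seed for weight initialization.
#' @return a `tauseg_net` object.
#' @export
build_attention_unet <- function(widths = c(32, 64, 128, 256, 512),
                                 in_ch = 1L, n_classes = 3L, seed = NULL) {
  net <- build_unet_family(widths, in_ch, n_classes, c(0L, 0L, 0L, 0L), seed)
  net$arch <- "attention_unet"
  net
}

#' Build a TAU-Net (texture attention U-Net)
#'
#' Identical to [build_attention_unet()] except that two skip connections
#' carry texture attention blocks: the scale-4 skip (second up-sampling
#' stage, feature maps a quarter of the input size) receives the dense
#' SIFT tensor computed with stride 4, and the scale-1 skip (last layer)
#' receives the LBP scalar slice.
#'
#' @inheritParams build_attention_unet
#' @param sift_channels SIFT descriptor channels fused at scale 4.
#' @param lbp_channels LBP channels fused at scale 1.
#' @return a `tauseg_net` object; its forward pass requires `tx = list(sift,
#'   lbp)` texture tensors.
#' @export
build_tau_net <- function(widths = c(32, 64, 128, 256, 512), in_ch = 1L,
                          n_classes = 3L, sift_channels = 128L,
                          lbp_channels = 1L, seed = NULL) {
  net <- build_unet_family(widths, in_ch, n_classes,
                           c(lbp_channels, 0L, sift_channels, 0L), seed)
  net$arch <- "tau_net"
  net
}

check_input_shape <- function(net, d) {
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0)
    stop("shape error: H and W must be divisible by 2^5")
}

net_texture_at <- function(net, l, d, tx) {
  ct <- net$tex_channels[l]
  if (ct == 0) return(NULL)
  scale <- 2^(l - 1)
  nm <- if (l == 3) "sift" else "lbp"
  t <- tx[[nm]]
  if (is.null(t))
    stop("configuration error: network expects texture input '", nm, "'")
  if (!all(dim(t) == c(d[1] / scale, d[2] / scale, ct)))
    stop("shape error: texture input '", nm, "' has wrong shape")
  t
}

unet_fwd <- function(net, x, tx = NULL) {
  P <- net$params
  d <- dim(x)
  check_input_shape(net, d)
  enc <- vector("list", 5)
  pool_idx <- vector("list", 4)
  h <- x
  for (l in 1:5) {
    cb <- cb_fwd(P, paste0("e", l), h)
    enc[[l]] <- cb
    if (l < 5) {
      mp <- maxpool2d_fwd_cpp(cb$y)
      pool_idx[[l]] <- list(idx = mp$idx, dims = dim(cb$y))
      h <- mp$y
    } else h <- cb$y
  }
  dec <- vector("list", 4)
  for (l in 4:1) {
    u <- upconv2d_fwd_cpp(h, pget(P, paste0("up", l), "w"),
                          pget(P, paste0("up", l), "b"))
    txf <- net_texture_at(net, l, d, tx)
    hn <- if (is.null(txf)) u else concat_ch(u, txf)
    ag <- ag_fwd_core(P[paste0("ag", l, ".", c("Wl", "Wh", "ba", "wpsi",
                                               "bpsi"))] |>
                        stats::setNames(c("Wl", "Wh", "ba", "wpsi", "bpsi")),
                      enc[[l]]$y, hn)
    cat_in <- concat_ch(ag$y, hn)
    cb <- cb_fwd(P, paste0("d", l), cat_in)
    dec[[l]] <- list(h_in = h, u = u, hn = hn, ag = ag, cat_in = cat_in,
                     cb = cb, has_tx = !is.null(txf))
    h <- cb$y
  }
  H1 <- matrix(h, ncol = net$widths[1])
  logits <- sweep(H1 %*% P$head.w, 2, P$head.b, `+`)
  logits <- array(logits, dim = c(d[1], d[2], net$n_classes))
  probs <- softmax_channels(logits)
  list(probs = probs,
       cache = list(enc = enc, pool_idx = pool_idx, dec = dec, h_last = H1,
                    probs = probs, d = d))
}

unet_bwd <- function(net, cache, dprobs) {
  P <- net$params
  g <- list()
  dz <- softmax_bwd(dprobs, cache$probs)
  DZ <- matrix(dz, ncol = net$n_classes)
  g$head.w <- crossprod(cache$h_last, DZ)
  g$head.b <- colSums(DZ)
  dh <- array(DZ %*% t(P$head.w),
              dim = c(cache$d[1], cache$d[2], net$widths[1]))
  dskip <- vector("list", 5)
  for (l in 1:4) {
    dc <- cache$dec[[l]]
    cbb <- cb_bwd(P, paste0("d", l), dc$cb$cache, dh)
    g <- c(g, cbb$grads)
    cl <- net$widths[l]
    cn <- dim(dc$hn)[3]
    dcat <- cbb$dx
    dxl_hat <- dcat[, , seq_len(cl), drop = FALSE]
    dhn <- dcat[, , cl + seq_len(cn), drop = FALSE]
    agw <- P[paste0("ag", l, ".", c("Wl", "Wh", "ba", "wpsi", "bpsi"))] |>
      stats::setNames(c("Wl", "Wh", "ba", "wpsi", "bpsi"))
    agb <- ag_bwd_core(agw, dc$ag$cache, dxl_hat)
    g <- c(g, prefix_names(agb$grads, paste0("ag", l)))
    dskip[[l]] <- agb$dxl
    dhn <- dhn + agb$dxh
    cu <- net$widths[l]
    du <- dhn[, , seq_len(cu), drop = FALSE]  # texture channels are fixed
    ub <- upconv2d_bwd_cpp(dc$h_in, pget(P, paste0("up", l), "w"), du)
    g[[paste0("up", l, ".w")]] <- ub$dw
    g[[paste0("up", l, ".b")]] <- ub$db
    dh <- ub$dx
  }
  # dh now holds the gradient at e5's output
  for (l in 5:1) {
    dy <- if (l == 5) dh
          else maxpool_bwd_cpp(dh, cache$pool_idx[[l]]$idx,
                               cache$pool_idx[[l]]$dims) + dskip[[l]]
    cbb <- cb_bwd(P, paste0("e", l), cache$enc[[l]]$cache, dy)
    g <- c(g, cbb$grads)
    dh <- cbb$dx
  }
  g
}

#' Forward pass of a segmentation network
#'
#' @param net a `tauseg_net` from [build_attention_unet()] or
#'   [build_tau_net()].
#' @param x input slice, array `(H, W, in_ch)` or matrix.
#' @param tx for TAU-Net: `list(sift = , lbp = )` texture tensors on the
#'   scale-4 and scale-1 grids (see [sift_feature_tensor()],
#'   [lbp_feature_tensor()]).
#' @return per-pixel class probability array `(H, W, C)` summing to 1.
#' @export
segnet_forward <- function(net, x, tx = NULL) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  unet_fwd(net, x, tx)$probs
}

#' Number of trainable parameters
#' @param net a `tauseg_net` or `tauseg_fuser`.
#' @return integer count.
#' @export
param_count <- function(net) sum(vapply(net$params, length, integer(1)))

#' Copy Attention U-Net weights into a TAU-Net
#'
#' Fills every shared parameter of a TAU-Net (same widths) from an
#' Attention U-Net and zeroes the weights acting on the texture channels.
#' With all-zero texture inputs the two networks are then functionally
#' identical -- the equivalence used to verify the TA block wiring.
#'
#' @param aunet source [build_attention_unet()] network.
#' @param tau destination [build_tau_net()] network of the same widths.
#' @return the TAU-Net with transferred parameters.
#' @export
transfer_aunet_to_tau <- function(aunet, tau) {
  stopifnot(all(aunet$widths == tau$widths))
  for (nm in names(tau$params)) {
    src <- aunet$params[[nm]]
    dst <- tau$params[[nm]]
    if (is.null(src)) next
    if (identical(dim(src), dim(dst)) || (is.null(dim(src)) &&
                                          length(src) == length(dst))) {
      tau$params[[nm]] <- src
    } else if (is.matrix(dst)) {
      # gate Wh widened by texture channels: shared channels lead
      dst[] <- 0
      dst[seq_len(nrow(src)), ] <- src
      tau$params[[nm]] <- dst
    } else {
      # conv weight widened on input channels (texture channels trail)
      dst[] <- 0
      ds <- dim(src)
      dst[, , seq_len(ds[3]), ] <- src
      tau$params[[nm]] <- dst
    }
  }
  tau
}

# ---------------------------------------------------------------------------
# Hybrid 3D fuser
# ---------------------------------------------------------------------------

#' Build the 3D hybrid fuser
#'
#' A single 3x3x3 convolution mapping the six stacked probability maps of
#' two segmentation networks to three channels, followed by per-voxel
#' normalization to probabilities (ReLU then renormalize), so each voxel is
#' relabeled using its neighborhood along all three axes.
#'
#' @param init `"random"`, or `"average"` for the identity initialization
#'   that averages the two input map sets and passes them through.
#' @param n_classes number of classes (3).
#' @param seed RNG seed for random init.
#' @return a `tauseg_fuser` object.
#' @export
build_hybrid_fuser <- function(init = c("random", "average"), n_classes = 3L,
                               seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  cin <- 2L * n_classes
  if (init == "average") {
    w <- array(0, dim = c(3, 3, 3, cin, n_classes))
    for (cc in seq_len(n_classes)) {
      w[2, 2, 2, cc, cc] <- 0.5
      w[2, 2, 2, n_classes + cc, cc] <- 0.5
    }
    b <- numeric(n_classes)
  } else {
    k <- conv3d_init(3, cin, n_classes)
    w <- k$w; b <- k$b
  }
  structure(list(params = list(w = w, b = b), n_classes = n_classes),
            class = "tauseg_fuser")
}

fuser_fwd <- function(fuser, stacked) {
  z <- conv3d_fwd_cpp(stacked, fuser$params$w, fuser$params$b, 1L)
  r <- pmax(z, 0) + 1e-8
  d <- dim(r)
  m <- matrix(r, ncol = d[4])
  p <- m / rowSums(m)
  list(probs = array(p, dim = d), z = z, r = r)
}

#' Fuse two probability map sets
#'
#' @param maps_a,maps_b per-class probability arrays `(X, Y, Z, C)` from
#'   the two segmentation networks, on the same grid.
#' @param fuser a [build_hybrid_fuser()] object.
#' @return fused probability array `(X, Y, Z, C)`, per-voxel sum 1.
#' @export
fuse <- function(maps_a, maps_b, fuser) {
  if (!all(dim(maps_a) == dim(maps_b))) stop("shape error: map shapes differ")
  stacked <- array(c(maps_a, maps_b), dim = c(dim(maps_a)[1:3],
                                              2 * dim(maps_a)[4]))
  fuser_fwd(fuser, stacked)$probs
}

#' Train the hybrid fuser
#'
#' Cross entropy on the fused probabilities against integer labels.
#'
#' @param fuser a `tauseg_fuser`.
#' @param pairs list of training items `list(a = , b = , labels = )` where
#'   `a`, `b` are `(X, Y, Z, C)` probability arrays and `labels` an integer
#'   array.
#' @param steps optimizer steps.
#' @param lr Adam learning rate.
#' @param gamma polynomial decay exponent.
#' @param seed RNG seed (item sampling).
#' @return the trained fuser; `$loss_history` records per-step loss.
#' @export
train_fuser <- function(fuser, pairs, steps = 100L, lr = 1e-2, gamma = 0.1,
                        seed = 1L) {
  set.seed(seed)
  st <- adam_state(fuser$params)
  hist <- numeric(steps)
  for (s in seq_len(steps)) {
    it <- pairs[[sample.int(length(pairs), 1)]]
    stacked <- array(c(it$a, it$b), dim = c(dim(it$a)[1:3],
                                            2 * dim(it$a)[4]))
    fw <- fuser_fwd(fuser, stacked)
    d <- dim(fw$probs)
    U <- one_hot(it$labels, d[4])
    N <- prod(d[1:3])
    p <- pmax(fw$probs, 1e-8)
    hist[s] <- -sum(U * log(p)) / N
    dp <- -(U / p) / N
    # renormalization backward: y = r / sum(r)
    m_r <- matrix(fw$r, ncol = d[4])
    m_dp <- matrix(dp, ncol = d[4])
    m_y <- matrix(fw$probs, ncol = d[4])
    dr <- (m_dp - rowSums(m_dp * m_y)) / rowSums(m_r)
    dz <- array(dr, dim = d) * (fw$z > 0)
    bw <- conv3d_bwd_cpp(stacked, fuser$params$w, dz, 1L)
    upd <- adam_step(fuser$params, list(w = bw$dw, b = bw$db), st,
                     poly_decay(lr, s, steps, gamma))
    fuser$params <- upd$params
    st <- upd$state
  }
  fuser$loss_history <- hist
  fuser
}

# ---------------------------------------------------------------------------
# Segmentation network training
# ---------------------------------------------------------------------------

#' Train a segmentation network on 2D slice samples
#'
#' Adam with polynomial learning-rate decay on the composite loss
#' (WPCE + GDL + boundary-F1, weights 0.33 each by default).
#'
#' @param net a `tauseg_net`.
#' @param samples list of items `list(x = (H,W,1) array, U = one-hot
#'   (H,W,C), tx = texture list or NULL)`.
#' @param steps optimizer steps.
#' @param batch_size slices averaged per step.
#' @param lr base learning rate.
#' @param gamma polynomial decay exponent.
#' @param loss_weights WPCE/GDL/BF1 coefficients.
#' @param theta0,theta boundary-loss kernels.
#' @param seed RNG seed (batch sampling).
#' @return the trained network; `$loss_history` records per-step mean loss.
#' @export
train_segnet <- function(net, samples, steps = 100L, batch_size = 4L,
                         lr = 1e-3, gamma = 0.1,
                         loss_weights = c(0.33, 0.33, 0.33), theta0 = 3L,
                         theta = 3L, seed = 1L) {
  set.seed(seed)
  st <- adam_state(net$params)
  hist <- numeric(steps)
  nb <- min(batch_size, length(samples))
  for (s in seq_len(steps)) {
    ids <- sample.int(length(samples), nb)
    tot <- NULL
    lsum <- 0
    for (i in ids) {
      sm <- samples[[i]]
      fw <- unet_fwd(net, sm$x, sm$tx)
      lo <- suppressWarnings(
        total_loss(sm$U, fw$probs, weights = loss_weights, theta0 = theta0,
                   theta = theta, with_grad = TRUE))
      g <- unet_bwd(net, fw$cache, lo$grad)
      tot <- acc_grads(tot, g)
      lsum <- lsum + lo$value
    }
    tot <- scale_grads(tot, 1 / nb)
    hist[s] <- lsum / nb
    upd <- adam_step(net$params, tot, st, poly_decay(lr, s, steps, gamma))
    net$params <- upd$params
    st <- upd$state
  }
  net$loss_history <- hist
  net
}
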