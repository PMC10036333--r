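# Residual U-Net used by the self-supervised denoiser.
#
# Depth is fixed at four 2x down-samplings, which is what makes inference
# require input sides divisible by 16. Each res-block is one 3x3
# convolution + batch normalization + ReLU with an identity shortcut
# (1x1 projection when the channel count changes). The two central
# res-blocks are followed by 0.5 dropout; skip connections concatenate
# encoder features into the decoder (materialized inside the convolution
# kernels as stacked-channel inputs); the final activation is softplus so
# predictions are strictly positive.

net_block_table <- function(base_filters, in_ch = 1L) {
  f <- base_filters
  data.frame(
    name = c("b1", "b2", "b3", "b4", "c1", "c2", "d4", "d3", "d2", "d1"),
    cin = c(in_ch, f, 2 * f, 4 * f, 8 * f, 16 * f,
            16 * f + 8 * f, 8 * f + 4 * f, 4 * f + 2 * f, 2 * f + f),
    cout = c(f, 2 * f, 4 * f, 8 * f, 16 * f, 16 * f,
             8 * f, 4 * f, 2 * f, f),
    stringsAsFactors = FALSE)
}

# Initialize all trainable parameters (flat named list) plus batch-norm
# running statistics (kept separate: updated by momentum, not by Adam).
net_init <- function(base_filters = 32L, in_ch = 1L, dropout_rate = 0.5) {
  tab <- net_block_table(base_filters, in_ch)
  params <- list()
  bn_state <- list()
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]; cin <- tab$cin[i]; cout <- tab$cout[i]
    cv <- conv_init(cin, cout, 3L)
    params[[paste0(nm, ".w")]] <- cv$w
    params[[paste0(nm, ".b")]] <- cv$b
    params[[paste0(nm, ".gamma")]] <- rep(1, cout)
    params[[paste0(nm, ".beta")]] <- numeric(cout)
    bn_state[[paste0(nm, ".rmean")]] <- numeric(cout)
    bn_state[[paste0(nm, ".rvar")]] <- rep(1, cout)
    if (cin != cout)
      params[[paste0(nm, ".pw")]] <-
        matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  }
  hd <- conv_init(base_filters, 1L, 1L)
  params[["head.w"]] <- hd$w
  params[["head.b"]] <- hd$b
  list(arch = list(base_filters = base_filters, in_ch = in_ch,
                   dropout_rate = dropout_rate, table = tab),
       params = params, bn_state = bn_state,
       # per-block im2col buffers, recycled across batches (environment so
       # updates survive R's copy-on-modify of the net list)
       ws = new.env(parent = emptyenv()))
}

# One res-block. xb (optional) carries the encoder skip features, stacked
# after xa's channels inside the convolution.
rb_forward <- function(net, nm, xa, xb, train) {
  p <- net$params
  bn <- list(gamma = p[[paste0(nm, ".gamma")]],
             beta = p[[paste0(nm, ".beta")]],
             rmean = net$bn_state[[paste0(nm, ".rmean")]],
             rvar = net$bn_state[[paste0(nm, ".rvar")]])
  C2 <- if (is.null(xb)) 0L else dim(xb)[4]
  ws <- net$ws
  k3 <- paste0(nm, ".col3"); k1 <- paste0(nm, ".col1")
  cf <- conv_fwd(xa, dim(xa), xb, C2, p[[paste0(nm, ".w")]],
                 p[[paste0(nm, ".b")]], 3L, keep_col = train,
                 reuse = if (train) ws[[k3]] else NULL)
  if (train) ws[[k3]] <- cf$col
  bnout <- bn_forward(cf$y, bn, train)
  pw <- p[[paste0(nm, ".pw")]]
  if (is.null(pw)) {
    s <- xa
    col1 <- NULL
  } else {
    pf <- conv_fwd(xa, dim(xa), xb, C2, pw, numeric(ncol(pw)), 1L,
                   keep_col = train,
                   reuse = if (train) ws[[k1]] else NULL)
    if (train) ws[[k1]] <- pf$col
    s <- pf$y
    col1 <- pf$col
  }
  y <- relu_add(bnout$y, s)
  list(y = y,
       cache = list(col3 = cf$col, col1 = col1, dims = dim(xa), C2 = C2,
                    bn = bnout$cache, y = y, stats = bnout$stats, nm = nm))
}

rb_backward <- function(net, cache, dy, need_dx = TRUE) {
  nm <- cache$nm
  p <- net$params
  dpre <- relu_mask_mul(dy, cache$y)
  bnp <- list(gamma = p[[paste0(nm, ".gamma")]])
  bnb <- bn_backward(dpre, bnp, cache$bn)
  cb <- conv_bwd(cache$col3, cache$dims, cache$C2, p[[paste0(nm, ".w")]],
                 bnb$dx, 3L, need_dx)
  grads <- list()
  grads[[paste0(nm, ".w")]] <- cb$dw
  grads[[paste0(nm, ".b")]] <- cb$db
  grads[[paste0(nm, ".gamma")]] <- bnb$dgamma
  grads[[paste0(nm, ".beta")]] <- bnb$dbeta
  pw <- p[[paste0(nm, ".pw")]]
  if (is.null(pw)) {
    dxa <- if (need_dx) cb$dx + dpre else NULL
    dxb <- NULL
  } else {
    pb <- conv_bwd(cache$col1, cache$dims, cache$C2, pw, dpre, 1L, need_dx)
    grads[[paste0(nm, ".pw")]] <- pb$dw
    if (need_dx) {
      dxa <- cb$dx + pb$dx
      dxb <- if (cache$C2 > 0) cb$dx2 + pb$dx2 else NULL
    } else {
      dxa <- NULL
      dxb <- NULL
    }
  }
  list(dxa = dxa, dxb = dxb, grads = grads)
}

# Full forward pass. Input x: array (H, W, N, in_ch) with H, W divisible
# by 16. Returns the softplus prediction, the pre-activation and (when
# training) every cache needed for the backward pass.
net_forward <- function(net, x, train = FALSE, keep_cache = train) {
  rate <- net$arch$dropout_rate
  C <- list()
  e1 <- rb_forward(net, "b1", x, NULL, train); C$b1 <- e1$cache
  pl1 <- maxpool2(e1$y); C$p1 <- pl1[c("which", "dims")]
  e2 <- rb_forward(net, "b2", pl1$y, NULL, train); C$b2 <- e2$cache
  pl2 <- maxpool2(e2$y); C$p2 <- pl2[c("which", "dims")]
  e3 <- rb_forward(net, "b3", pl2$y, NULL, train); C$b3 <- e3$cache
  pl3 <- maxpool2(e3$y); C$p3 <- pl3[c("which", "dims")]
  e4 <- rb_forward(net, "b4", pl3$y, NULL, train); C$b4 <- e4$cache
  pl4 <- maxpool2(e4$y); C$p4 <- pl4[c("which", "dims")]
  c1 <- rb_forward(net, "c1", pl4$y, NULL, train); C$c1 <- c1$cache
  dr1 <- dropout_forward(c1$y, rate, train); C$dr1 <- dr1$mask
  c2 <- rb_forward(net, "c2", dr1$y, NULL, train); C$c2 <- c2$cache
  dr2 <- dropout_forward(c2$y, rate, train); C$dr2 <- dr2$mask
  u4 <- upsample2(dr2$y)
  d4 <- rb_forward(net, "d4", u4, e4$y, train); C$d4 <- d4$cache
  u3 <- upsample2(d4$y)
  d3 <- rb_forward(net, "d3", u3, e3$y, train); C$d3 <- d3$cache
  u2 <- upsample2(d3$y)
  d2 <- rb_forward(net, "d2", u2, e2$y, train); C$d2 <- d2$cache
  u1 <- upsample2(d2$y)
  d1 <- rb_forward(net, "d1", u1, e1$y, train); C$d1 <- d1$cache
  hf <- conv_fwd(d1$y, dim(d1$y), NULL, 0L, net$params[["head.w"]],
                 net$params[["head.b"]], 1L, keep_col = train,
                 reuse = if (train) net$ws[["head.col"]] else NULL)
  if (train) net$ws[["head.col"]] <- hf$col
  C$head_col <- hf$col
  C$head_dims <- dim(d1$y)
  lin <- hf$y
  pred <- softplus(lin)
  list(pred = pred, lin = lin, cache = if (keep_cache) C else NULL)
}

# Backward pass from d(loss)/d(pred). Returns flat named gradient list
# aligned with net$params, plus the fresh batch-norm statistics so the
# caller can update running averages.
net_backward <- function(net, fw, dpred) {
  C <- fw$cache
  dlin <- dpred * softplus_grad(fw$lin)
  hb <- conv_bwd(C$head_col, C$head_dims, 0L, net$params[["head.w"]],
                 dlin, 1L)
  grads <- list("head.w" = hb$dw, "head.b" = hb$db)
  acc <- function(g) for (n in names(g)) grads[[n]] <<- g[[n]]

  b <- rb_backward(net, C$d1, hb$dx); acc(b$grads)
  de1_skip <- b$dxb
  dd2 <- upsample2_backward(b$dxa)

  b <- rb_backward(net, C$d2, dd2); acc(b$grads)
  de2_skip <- b$dxb
  dd3 <- upsample2_backward(b$dxa)

  b <- rb_backward(net, C$d3, dd3); acc(b$grads)
  de3_skip <- b$dxb
  dd4 <- upsample2_backward(b$dxa)

  b <- rb_backward(net, C$d4, dd4); acc(b$grads)
  de4_skip <- b$dxb
  dc2d <- upsample2_backward(b$dxa)

  if (!is.null(C$dr2)) dc2d <- dc2d * C$dr2
  b <- rb_backward(net, C$c2, dc2d); acc(b$grads)
  dc1d <- b$dxa
  if (!is.null(C$dr1)) dc1d <- dc1d * C$dr1
  b <- rb_backward(net, C$c1, dc1d); acc(b$grads)

  dp4 <- maxpool2_backward(b$dxa, C$p4)
  b <- rb_backward(net, C$b4, dp4 + de4_skip); acc(b$grads)
  dp3 <- maxpool2_backward(b$dxa, C$p3)
  b <- rb_backward(net, C$b3, dp3 + de3_skip); acc(b$grads)
  dp2 <- maxpool2_backward(b$dxa, C$p2)
  b <- rb_backward(net, C$b2, dp2 + de2_skip); acc(b$grads)
  dp1 <- maxpool2_backward(b$dxa, C$p1)
  # the input has no upstream consumer: skip its gradient
  b <- rb_backward(net, C$b1, dp1 + de1_skip, need_dx = FALSE)
  acc(b$grads)

  stats <- lapply(C[c("b1", "b2", "b3", "b4", "c1", "c2",
                      "d4", "d3", "d2", "d1")],
                  function(cc) cc$stats)
  list(grads = grads, bn_stats = stats)
}

# Apply fresh batch statistics to the running averages.
net_update_bn <- function(net, bn_stats) {
  for (nm in names(bn_stats)) {
    st <- bn_stats[[nm]]
    if (is.null(st)) next
    km <- paste0(nm, ".rmean"); kv <- paste0(nm, ".rvar")
    net$bn_state[[km]] <- BN_MOMENTUM * net$bn_state[[km]] +
      (1 - BN_MOMENTUM) * st$mu
    net$bn_state[[kv]] <- BN_MOMENTUM * net$bn_state[[kv]] +
      (1 - BN_MOMENTUM) * st$v
  }
  net
}
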