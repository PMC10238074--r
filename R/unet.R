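# Compact 2D U-Net, implemented directly in R: im2col convolutions as matrix
# products, ReLU, 2x2 max-pool / nearest-neighbour upsample, skip
# concatenation, Adam. Feature maps are (H*W, C) matrices in column-major
# (row index fastest) pixel order. Sized for B-scan segmentation at desk
# scale; exactness of the backward pass is verified against numerical
# gradients in the test suite.

.unet_cache <- new.env(parent = emptyenv())

# gather-index matrix for 3x3 "same" convolution over a (H, W, Cin) map,
# into the zero-padded (H+2, W+2, Cin) vector
im2col_idx <- function(H, W, Cin) {
  key <- paste("i", H, W, Cin, sep = "_")
  if (!is.null(.unet_cache[[key]])) return(.unet_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  cols <- matrix(0L, H * W, 9L * Cin)
  k <- 1L
  for (ch in seq_len(Cin)) {
    base_ch <- (ch - 1L) * Hp * Wp
    for (dc in 0:2) {
      for (dr in 0:2) {
        cols[, k] <- base_ch + (c + dc - 1L) * Hp + (r + dr)
        k <- k + 1L
      }
    }
  }
  .unet_cache[[key]] <- cols
  cols
}

pad_map <- function(X, H, W) {
  Cin <- ncol(X)
  Hp <- H + 2L; Wp <- W + 2L
  pad <- array(0, c(Hp, Wp, Cin))
  pad[2:(H + 1L), 2:(W + 1L), ] <- array(X, c(H, W, Cin))
  as.vector(pad)
}

conv_init <- function(Cin, Cout, k = 3L) {
  list(W = matrix(stats::rnorm(k * k * Cin * Cout, sd = sqrt(2 / (k * k * Cin))),
                  k * k * Cin, Cout),
       b = rep(0, Cout), k = k, Cin = Cin, Cout = Cout)
}

conv_forward <- function(layer, X, H, W) {
  if (layer$k == 1L) {
    out <- X %*% layer$W
    out <- sweep(out, 2, layer$b, `+`)
    return(list(out = out, P = X, H = H, W = W))
  }
  P <- matrix(pad_map(X, H, W)[im2col_idx(H, W, ncol(X))], H * W)
  out <- P %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  list(out = out, P = P, H = H, W = W)
}

# permutation turning the forward weight matrix (9*Cin, Cout) into the
# flipped-kernel matrix (9*Cout, Cin) used for the input gradient
flip_perm <- function(Cin, Cout) {
  key <- paste("f", Cin, Cout, sep = "_")
  if (!is.null(.unet_cache[[key]])) return(.unet_cache[[key]])
  co <- rep(seq_len(Cout), each = 9L)
  dc <- rep(rep(0:2, each = 3L), times = Cout)
  dr <- rep(0:2, times = 3L * Cout)
  rows <- matrix(0L, 9L * Cout, Cin)
  cols <- matrix(0L, 9L * Cout, Cin)
  for (ci in seq_len(Cin)) {
    rows[, ci] <- (ci - 1L) * 9L + (2L - dc) * 3L + (2L - dr) + 1L
    cols[, ci] <- co
  }
  m <- cbind(as.vector(rows), as.vector(cols))
  .unet_cache[[key]] <- m
  m
}

conv_backward <- function(layer, cache, dOut) {
  dW <- crossprod(cache$P, dOut)
  db <- colSums(dOut)
  if (layer$k == 1L) {
    return(list(dX = dOut %*% t(layer$W), dW = dW, db = db))
  }
  H <- cache$H; W <- cache$W
  Cin <- layer$Cin; Cout <- layer$Cout
  # dX = "full" correlation of dOut with flipped kernels, via im2col again
  Wb <- matrix(layer$W[flip_perm(Cin, Cout)], 9L * Cout, Cin)
  Pd <- matrix(pad_map(dOut, H, W)[im2col_idx(H, W, Cout)], H * W)
  list(dX = Pd %*% Wb, dW = dW, db = db)
}

relu_forward <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_backward <- function(cache, dOut) dOut * cache$mask

pool_idx <- function(H, W) {
  key <- paste("p", H, W, sep = "_")
  if (!is.null(.unet_cache[[key]])) return(.unet_cache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  r <- rep(seq_len(Ho), times = Wo)
  c <- rep(seq_len(Wo), each = Ho)
  i1 <- (2L * c - 2L) * H + (2L * r - 1L)
  m <- cbind(i1, i1 + 1L, i1 + H, i1 + H + 1L)
  .unet_cache[[key]] <- m
  m
}

pool_forward <- function(X, H, W) {
  idx <- pool_idx(H, W)
  C <- ncol(X)
  n <- nrow(idx)
  out <- matrix(-Inf, n, C)
  choice <- matrix(0L, n, C)
  for (k in 1:4) {
    cand <- X[idx[, k], , drop = FALSE]
    better <- cand > out
    out[better] <- cand[better]
    choice[better] <- rep(idx[, k], times = C)[as.vector(better)]
  }
  list(out = out, choice = choice, H = H, W = W, C = C)
}

pool_backward <- function(cache, dOut) {
  dX <- matrix(0, cache$H * cache$W, cache$C)
  for (ch in seq_len(cache$C)) {
    dX[cache$choice[, ch], ch] <- dX[cache$choice[, ch], ch] + dOut[, ch]
  }
  dX
}

up_idx <- function(Ho, Wo) {
  # map child (2Ho x 2Wo) pixel -> parent (Ho x Wo) pixel, column-major
  key <- paste("u", Ho, Wo, sep = "_")
  if (!is.null(.unet_cache[[key]])) return(.unet_cache[[key]])
  H <- 2L * Ho; W <- 2L * Wo
  r <- rep(seq_len(H), times = W)
  c <- rep(seq_len(W), each = H)
  m <- (ceiling(c / 2) - 1L) * Ho + ceiling(r / 2)
  .unet_cache[[key]] <- m
  m
}

upsample_forward <- function(X, Ho, Wo) {
  map <- up_idx(Ho, Wo)
  list(out = X[map, , drop = FALSE], map = map, n_parent = Ho * Wo)
}

upsample_backward <- function(cache, dOut) {
  out <- rowsum(dOut, cache$map)
  # rowsum orders by sorted unique group == 1..n_parent (all present)
  out
}

# ---- network assembly ------------------------------------------------------

unet_init <- function(depth = 2L, base = 8L, seed = 1L) {
  with_seed(seed, function() {
    ch <- base * 2L^(0:depth)
    enc <- list(); up <- list(); dec <- list()
    cin <- 1L
    for (l in seq_len(depth + 1L)) {
      enc[[l]] <- list(conv1 = conv_init(cin, ch[l]),
                       conv2 = conv_init(ch[l], ch[l]))
      cin <- ch[l]
    }
    for (l in seq_len(depth)) {
      up[[l]] <- conv_init(ch[l + 1L], ch[l])
      dec[[l]] <- list(conv1 = conv_init(2L * ch[l], ch[l]),
                       conv2 = conv_init(ch[l], ch[l]))
    }
    out <- conv_init(ch[1], 1L, k = 1L)
    list(depth = depth, base = base, enc = enc, up = up, dec = dec, out = out)
  })
}

unet_forward <- function(net, x, H, W) {
  D <- net$depth
  ec <- vector("list", D + 1L)
  pc <- vector("list", D)
  enc_out <- vector("list", D + 1L)
  cur <- x; h <- H; w <- W
  for (l in seq_len(D + 1L)) {
    c1 <- conv_forward(net$enc[[l]]$conv1, cur, h, w)
    r1 <- relu_forward(c1$out)
    c2 <- conv_forward(net$enc[[l]]$conv2, r1$out, h, w)
    r2 <- relu_forward(c2$out)
    ec[[l]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, h = h, w = w)
    enc_out[[l]] <- r2$out
    if (l <= D) {
      p <- pool_forward(r2$out, h, w)
      pc[[l]] <- p
      cur <- p$out
      h <- h %/% 2L; w <- w %/% 2L
    }
  }
  uc <- vector("list", D)
  dc <- vector("list", D)
  cur <- enc_out[[D + 1L]]
  for (l in rev(seq_len(D))) {
    hh <- ec[[l]]$h; ww <- ec[[l]]$w
    us <- upsample_forward(cur, hh %/% 2L, ww %/% 2L)
    cv <- conv_forward(net$up[[l]], us$out, hh, ww)
    rl <- relu_forward(cv$out)
    cat_in <- cbind(rl$out, enc_out[[l]])
    d1 <- conv_forward(net$dec[[l]]$conv1, cat_in, hh, ww)
    dr1 <- relu_forward(d1$out)
    d2 <- conv_forward(net$dec[[l]]$conv2, dr1$out, hh, ww)
    dr2 <- relu_forward(d2$out)
    uc[[l]] <- list(us = us, cv = cv, rl = rl, n_up = ncol(rl$out))
    dc[[l]] <- list(d1 = d1, dr1 = dr1, d2 = d2, dr2 = dr2)
    cur <- dr2$out
  }
  oc <- conv_forward(net$out, cur, H, W)
  list(logits = oc$out, ec = ec, pc = pc, uc = uc, dc = dc, oc = oc)
}

unet_backward <- function(net, fw, dlogits) {
  D <- net$depth
  g <- list(enc = vector("list", D + 1L), up = vector("list", D),
            dec = vector("list", D))
  ob <- conv_backward(net$out, fw$oc, dlogits)
  g$out <- list(dW = ob$dW, db = ob$db)
  denc_extra <- vector("list", D + 1L)  # gradient arriving via skip concat
  # decoder stages were executed l = D..1, so gradients flow back l = 1..D
  g_cur <- ob$dX
  for (l in seq_len(D)) {
    g_in <- relu_backward(fw$dc[[l]]$dr2, g_cur)
    b2 <- conv_backward(net$dec[[l]]$conv2, fw$dc[[l]]$d2, g_in)
    dd1 <- relu_backward(fw$dc[[l]]$dr1, b2$dX)
    b1 <- conv_backward(net$dec[[l]]$conv1, fw$dc[[l]]$d1, dd1)
    n_up <- fw$uc[[l]]$n_up
    d_up_branch <- b1$dX[, seq_len(n_up), drop = FALSE]
    denc_extra[[l]] <- b1$dX[, -seq_len(n_up), drop = FALSE]
    dru <- relu_backward(fw$uc[[l]]$rl, d_up_branch)
    bu <- conv_backward(net$up[[l]], fw$uc[[l]]$cv, dru)
    g_cur <- upsample_backward(fw$uc[[l]]$us, bu$dX)
    g$dec[[l]] <- list(conv1 = list(dW = b1$dW, db = b1$db),
                       conv2 = list(dW = b2$dW, db = b2$db))
    g$up[[l]] <- list(dW = bu$dW, db = bu$db)
  }
  # g_cur now feeds the bottleneck encoder output (l = D+1)
  for (l in rev(seq_len(D + 1L))) {
    total <- if (l == D + 1L) {
      g_cur
    } else {
      pool_backward(fw$pc[[l]], g_below) + denc_extra[[l]]
    }
    dr2 <- relu_backward(fw$ec[[l]]$r2, total)
    b2 <- conv_backward(net$enc[[l]]$conv2, fw$ec[[l]]$c2, dr2)
    dr1 <- relu_backward(fw$ec[[l]]$r1, b2$dX)
    b1 <- conv_backward(net$enc[[l]]$conv1, fw$ec[[l]]$c1, dr1)
    g$enc[[l]] <- list(conv1 = list(dW = b1$dW, db = b1$db),
                       conv2 = list(dW = b2$dW, db = b2$db))
    g_below <- b1$dX
  }
  g
}

# ---- loss ------------------------------------------------------------------

# Weighted binary cross-entropy + soft-Dice on sigmoid probabilities.
# Returns loss value and gradient w.r.t. logits.
seg_loss <- function(logits, y, pos_weight = 3, bce_weight = 1,
                     dice_weight = 0.5) {
  p <- 1 / (1 + exp(-logits))
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(y)
  bce <- -mean(pos_weight * y * log(pc) + (1 - y) * log(1 - pc))
  dbce_dz <- (pos_weight * y * (pc - 1) + (1 - y) * pc) / n
  inter <- sum(p * y)
  denom <- sum(p) + sum(y)
  sdice <- 1 - (2 * inter + 1) / (denom + 1)
  # d(sdice)/dp = -(2*y*(denom+1) - (2*inter+1)) / (denom+1)^2
  dsd_dp <- -(2 * y * (denom + 1) - (2 * inter + 1)) / (denom + 1)^2
  dsd_dz <- dsd_dp * p * (1 - p)
  list(loss = bce_weight * bce + dice_weight * sdice,
       dlogits = matrix(bce_weight * dbce_dz + dice_weight * dsd_dz,
                        nrow(logits), 1))
}

# ---- Adam over the nested parameter structure ------------------------------

flatten_params <- function(net) {
  out <- list()
  push <- function(path, layer) {
    out[[paste0(path, ".W")]] <<- layer$W
    out[[paste0(path, ".b")]] <<- layer$b
  }
  for (l in seq_along(net$enc)) {
    push(sprintf("enc%d.c1", l), net$enc[[l]]$conv1)
    push(sprintf("enc%d.c2", l), net$enc[[l]]$conv2)
  }
  for (l in seq_along(net$up)) {
    push(sprintf("up%d", l), net$up[[l]])
    push(sprintf("dec%d.c1", l), net$dec[[l]]$conv1)
    push(sprintf("dec%d.c2", l), net$dec[[l]]$conv2)
  }
  push("out", net$out)
  out
}

flatten_grads <- function(net, g) {
  out <- list()
  push <- function(path, gl) {
    out[[paste0(path, ".W")]] <<- gl$dW
    out[[paste0(path, ".b")]] <<- gl$db
  }
  for (l in seq_along(net$enc)) {
    push(sprintf("enc%d.c1", l), g$enc[[l]]$conv1)
    push(sprintf("enc%d.c2", l), g$enc[[l]]$conv2)
  }
  for (l in seq_along(net$up)) {
    push(sprintf("up%d", l), g$up[[l]])
    push(sprintf("dec%d.c1", l), g$dec[[l]]$conv1)
    push(sprintf("dec%d.c2", l), g$dec[[l]]$conv2)
  }
  push("out", g$out)
  out
}

assign_params <- function(net, flat) {
  pull <- function(path) list(W = flat[[paste0(path, ".W")]],
                              b = flat[[paste0(path, ".b")]])
  for (l in seq_along(net$enc)) {
    p <- pull(sprintf("enc%d.c1", l))
    net$enc[[l]]$conv1$W <- p$W; net$enc[[l]]$conv1$b <- p$b
    p <- pull(sprintf("enc%d.c2", l))
    net$enc[[l]]$conv2$W <- p$W; net$enc[[l]]$conv2$b <- p$b
  }
  for (l in seq_along(net$up)) {
    p <- pull(sprintf("up%d", l))
    net$up[[l]]$W <- p$W; net$up[[l]]$b <- p$b
    p <- pull(sprintf("dec%d.c1", l))
    net$dec[[l]]$conv1$W <- p$W; net$dec[[l]]$conv1$b <- p$b
    p <- pull(sprintf("dec%d.c2", l))
    net$dec[[l]]$conv2$W <- p$W; net$dec[[l]]$conv2$b <- p$b
  }
  p <- pull("out")
  net$out$W <- p$W; net$out$b <- p$b
  net
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(flat)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    flat[[k]] <- flat[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}
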