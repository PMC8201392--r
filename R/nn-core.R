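# Internal mini conv-net engine.
#
# Layout conventions (column-major throughout):
#   * a single image is the vector of its H x W x 3 array (pixel index runs
#     over rows, then columns, then channels); a batch arrives as a
#     (H*W*3) x B matrix with one image per column;
#   * inside the network, the activation of a layer is stored as a
#     (npos*B) x C matrix: rows run over spatial position (fastest) then
#     batch item, columns over channels.  Batch norm is then simply a
#     per-column standardisation, and convolution is one gather plus one
#     matrix multiply per layer.
#
# Every conv block is kernel 3, stride 2, pad 1 (halves each spatial side),
# followed by batch norm and leaky ReLU -- stride-2 convolutions stand in
# for pooling, darknet-style.  Gather index tables depend only on
# (input size, channel plan, batch size) and are memoised.

.nn_leaky_slope <- 0.1
.nn_bn_eps <- 1e-5
.nn_bn_momentum <- 0.1
.nn_cache <- new.env(parent = emptyenv())

# Spatial patch table for one conv layer: Pspat[pos, kk] is the index of
# patch element kk = (dr, dc) (row offset fastest) inside the zero-padded
# single-channel image, for output position pos.
nn_conv_geom <- function(H, W, k = 3L, s = 2L, p = 1L) {
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  Ho <- (H + 2L * p - k) %/% s + 1L
  Wo <- (W + 2L * p - k) %/% s + 1L
  npos <- Ho * Wo
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  r0 <- (io - 1L) * s
  c0 <- (jo - 1L) * s
  Pspat <- matrix(0L, npos, k * k)
  kk <- 0L
  for (dc in 0:(k - 1L)) {
    for (dr in 0:(k - 1L)) {
      kk <- kk + 1L
      Pspat[, kk] <- (r0 + dr + 1L) + (c0 + dc) * Hp
    }
  }
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  interior <- (ii + p) + (jj + p - 1L) * Hp
  list(Pspat = Pspat, interior = interior, npos = npos, npix = H * W,
       npad = Hp * Wp, Ho = Ho, Wo = Wo, k = k)
}

# Batch-expanded index tables for one layer at batch size B.
#   gather: (npos*B) x (k*k*C) matrix of indices into the padded activation
#           vector (layout: padpos, then batch, then channel);
#   pad_rows: rows of the (npad*B) x C padded matrix holding real pixels.
nn_layer_index <- function(geom, C, B) {
  key <- paste(geom$npix, geom$npos, C, B, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  npos <- geom$npos
  npad <- geom$npad
  boff <- rep((seq_len(B) - 1L) * npad, each = npos)
  ksp <- ncol(geom$Pspat)
  gather <- matrix(0L, npos * B, ksp * C)
  col <- 0L
  for (ch in seq_len(C)) {
    choff <- (ch - 1L) * npad * B
    for (kk in seq_len(ksp)) {
      col <- col + 1L
      gather[, col] <- rep(geom$Pspat[, kk], times = B) + boff + choff
    }
  }
  pad_rows <- rep(geom$interior, times = B) +
    rep((seq_len(B) - 1L) * npad, each = geom$npix)
  # scatter rows: within one kernel offset kk no two output positions write
  # the same padded pixel (stride 2 < kernel 3 still maps distinct centres
  # to distinct offset positions), so col2im is ksp collision-free adds
  scat <- matrix(0L, npos * B, ksp)
  for (kk in seq_len(ksp)) {
    scat[, kk] <- rep(geom$Pspat[, kk], times = B) + boff
  }
  out <- list(gather = gather, pad_rows = pad_rows, scat = scat,
              ksp = ksp, npos = npos, npad = npad, B = B)
  .nn_cache[[key]] <- out
  out
}

# Forward through one conv+BN+leaky block.
# X: (npix*B) x C_in activation. Returns list(out (npos*B) x C_out, cache).
nn_block_forward <- function(X, layer, geom, train) {
  B <- nrow(X) %/% geom$npix
  C_in <- ncol(X)
  li <- nn_layer_index(geom, C_in, B)
  Xp <- matrix(0, geom$npad * B, C_in)
  Xp[li$pad_rows, ] <- X
  A <- Xp
  dim(A) <- NULL
  A <- A[li$gather]
  dim(A) <- dim(li$gather)                     # (npos*B) x (k*k*C_in)
  Z <- A %*% layer$W
  N <- nrow(Z)
  Z <- Z + rep(layer$b, each = N)
  if (train) {
    mu <- colMeans(Z)
    Zc <- Z - rep(mu, each = N)
    v <- colMeans(Zc * Zc)
    inv_sd <- 1 / sqrt(v + .nn_bn_eps)
    xhat <- Zc * rep(inv_sd, each = N)
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    inv_sd <- 1 / sqrt(v + .nn_bn_eps)
    xhat <- (Z - rep(mu, each = N)) * rep(inv_sd, each = N)
  }
  Y <- xhat * rep(layer$gamma, each = N) + rep(layer$beta, each = N)
  fmask <- .nn_leaky_slope + (1 - .nn_leaky_slope) * (Y > 0)
  Y <- Y * fmask
  list(out = Y,
       cache = list(A = A, xhat = xhat, fmask = fmask, mu = mu, v = v,
                    inv_sd = inv_sd, B = B, C_in = C_in))
}

# Backward through one block. d_out: (npos*B) x C_out gradient.
nn_block_backward <- function(d_out, layer, geom, cache, train,
                              need_input_grad = TRUE) {
  dY <- d_out * cache$fmask
  xhat <- cache$xhat
  N <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(layer$gamma, each = N)
  if (train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dZ <- (dxhat - rep(s1 / N, each = N) - xhat * rep(s2 / N, each = N)) *
      rep(cache$inv_sd, each = N)
  } else {
    dZ <- dxhat * rep(cache$inv_sd, each = N)
  }
  dW <- crossprod(cache$A, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (need_input_grad) {
    li <- nn_layer_index(geom, cache$C_in, cache$B)
    dA <- dZ %*% t(layer$W)                    # (npos*B) x (k*k*C_in)
    dXp <- matrix(0, geom$npad * cache$B, cache$C_in)
    for (kk in seq_len(li$ksp)) {
      rows <- li$scat[, kk]
      cols <- seq.int(kk, by = li$ksp, length.out = cache$C_in)
      dXp[rows, ] <- dXp[rows, ] + dA[, cols, drop = FALSE]
    }
    dX <- dXp[li$pad_rows, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db, dgamma = dgamma, dbeta = dbeta)
}

# Convert an image batch (H*W*3) x B into the internal (npix*B) x 3 layout.
nn_pack_input <- function(Ximg, npix) {
  B <- ncol(Ximg)
  dim(Ximg) <- c(npix, 3L, B)
  X <- aperm(Ximg, c(1L, 3L, 2L))
  dim(X) <- c(npix * B, 3L)
  X
}

nn_unpack_input_grad <- function(dX, npix) {
  B <- nrow(dX) %/% npix
  dim(dX) <- c(npix, B, 3L)
  g <- aperm(dX, c(1L, 3L, 2L))
  dim(g) <- c(npix * 3L, B)
  g
}

# Full forward pass. Ximg: (H*W*3) x B image batch. Returns logits B x K,
# feats B x C_last, caches.
nn_forward <- function(net, Ximg, train = FALSE) {
  B <- ncol(Ximg)
  X <- nn_pack_input(Ximg, net$geom[[1]]$npix)
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- nn_block_forward(X, net$layers[[i]], net$geom[[i]], train)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  npos <- net$geom[[length(net$geom)]]$npos
  feats <- rowsum(X, rep(seq_len(B), each = npos)) / npos   # B x C_last
  logits <- feats %*% net$head$W
  logits <- sweep(logits, 2L, net$head$b, `+`)              # B x K
  list(logits = logits, feats = feats, caches = caches)
}

# Backward from dlogits (B x K). Returns parameter grads and, when
# requested, the input gradient as a (H*W*3) x B matrix.
nn_backward <- function(net, fw, dlogits, train = FALSE,
                        need_input_grad = FALSE) {
  B <- nrow(dlogits)
  dW_head <- crossprod(fw$feats, dlogits)
  db_head <- colSums(dlogits)
  dfeats <- dlogits %*% t(net$head$W)          # B x C_last
  nl <- length(net$layers)
  npos <- net$geom[[nl]]$npos
  dX <- dfeats[rep(seq_len(B), each = npos), , drop = FALSE] / npos
  grads <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    bk <- nn_block_backward(dX, net$layers[[i]], net$geom[[i]],
                            fw$caches[[i]], train,
                            need_input_grad = (i > 1L) || need_input_grad)
    grads[[i]] <- bk[c("dW", "db", "dgamma", "dbeta")]
    dX <- bk$dX
  }
  dinput <- if (need_input_grad) {
    nn_unpack_input_grad(dX, net$geom[[1]]$npix)
  }
  list(layers = grads, dW_head = dW_head, db_head = db_head,
       dinput = dinput)
}

# Softmax over the class dimension of a B x K logit matrix.
nn_softmax <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# He-style initialisation of one conv block (uses the current RNG stream).
nn_init_layer <- function(ksz, C_out) {
  list(W = matrix(stats::rnorm(ksz * C_out, sd = sqrt(2 / ksz)), ksz, C_out),
       b = numeric(C_out),
       gamma = rep(1, C_out), beta = numeric(C_out),
       run_mean = numeric(C_out), run_var = rep(1, C_out))
}

nn_new <- function(input_size, n_classes, channels = c(8L, 16L, 32L)) {
  H <- as.integer(input_size)
  C_in <- 3L
  geom <- vector("list", length(channels))
  layers <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    geom[[i]] <- nn_conv_geom(H, H)
    layers[[i]] <- nn_init_layer(geom[[i]]$k^2 * C_in, channels[i])
    H <- geom[[i]]$Ho
    C_in <- channels[i]
  }
  feature_dim <- channels[length(channels)]
  head <- list(W = matrix(stats::rnorm(feature_dim * n_classes, sd = 0.1),
                          feature_dim, n_classes),
               b = numeric(n_classes))
  list(layers = layers, head = head, geom = geom,
       input_size = as.integer(input_size), n_classes = as.integer(n_classes),
       feature_dim = feature_dim, channels = channels)
}

# One SGD(+classical momentum) step; frozen: logical per conv block (the
# head is always trainable). vel is the velocity state (NULL on first call).
nn_sgd_step <- function(net, grads, lr, frozen, vel = NULL, momentum = 0.9) {
  if (is.null(vel)) {
    vel <- list(layers = lapply(net$layers, function(l) {
      list(dW = 0 * l$W, db = 0 * l$b, dgamma = 0 * l$gamma,
           dbeta = 0 * l$beta)
    }), dW_head = 0 * net$head$W, db_head = 0 * net$head$b)
  }
  for (i in seq_along(net$layers)) {
    if (frozen[i]) next
    g <- grads$layers[[i]]
    v <- vel$layers[[i]]
    for (nm in c("dW", "db", "dgamma", "dbeta")) {
      v[[nm]] <- momentum * v[[nm]] + g[[nm]]
    }
    vel$layers[[i]] <- v
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * v$dW
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * v$db
    net$layers[[i]]$gamma <- net$layers[[i]]$gamma - lr * v$dgamma
    net$layers[[i]]$beta <- net$layers[[i]]$beta - lr * v$dbeta
  }
  vel$dW_head <- momentum * vel$dW_head + grads$dW_head
  vel$db_head <- momentum * vel$db_head + grads$db_head
  net$head$W <- net$head$W - lr * vel$dW_head
  net$head$b <- net$head$b - lr * vel$db_head
  list(net = net, vel = vel)
}

# Fold the batch statistics of a training-mode forward into the running
# BN statistics of the unfrozen blocks.
nn_update_running <- function(net, caches, frozen) {
  m <- .nn_bn_momentum
  for (i in seq_along(net$layers)) {
    if (frozen[i]) next
    net$layers[[i]]$run_mean <- (1 - m) * net$layers[[i]]$run_mean +
      m * caches[[i]]$mu
    net$layers[[i]]$run_var <- (1 - m) * net$layers[[i]]$run_var +
      m * caches[[i]]$v
  }
  net
}
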