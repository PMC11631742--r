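# Minimal reverse-mode neural-network core.
#
# No deep-learning framework is assumed: layers are environments exposing
# forward(x, train)/backward(dy) with parameters and gradients as plain
# arrays, and the heavy lifting (im2col convolution, channel mixing) is
# delegated to BLAS matrix products. Shapes use channel-first layouts:
# images (C, H, W, N), skeleton feature maps (C, T, V, N). Every gradient
# implemented here is finite-difference-checked in the unit suite.

new_layer <- function(type, children = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$opt_state <- list()
  e$children <- children
  e
}

collect_layers <- function(layer) {
  out <- list()
  if (length(layer$params)) out <- list(layer)
  for (ch in layer$children) out <- c(out, collect_layers(ch))
  out
}

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

# ---- convolution ------------------------------------------------------------

# Cached im2col index matrix: rows (C*kh*kw) x cols (OH*OW*N), linear indices
# into the zero-padded (C, Hp, Wp, N) array. Column order: oh, ow, n.
im2col_index <- function(C, H, W, N, kh, kw, sh, sw, ph, pw) {
  Hp <- H + 2 * ph; Wp <- W + 2 * pw
  OH <- (Hp - kh) %/% sh + 1L
  OW <- (Wp - kw) %/% sw + 1L
  c_vec <- rep(seq_len(C), times = kh * kw)
  dh <- rep(rep(seq_len(kh), each = C), times = kw)
  dw <- rep(seq_len(kw), each = C * kh)
  rowpart <- c_vec + C * (dh - 1) + C * Hp * (dw - 1)
  h0 <- rep((seq_len(OH) - 1L) * sh, times = OW)
  w0 <- rep((seq_len(OW) - 1L) * sw, each = OH)
  colpart <- C * h0 + C * Hp * w0
  samp <- rep((seq_len(N) - 1L) * (C * Hp * Wp), each = OH * OW)
  cols <- rep(colpart, times = N) + samp
  idx <- outer(rowpart, cols, "+")
  storage.mode(idx) <- "integer"
  list(idx = idx, OH = OH, OW = OW, Hp = Hp, Wp = Wp)
}

pad_input <- function(x, ph, pw) {
  d <- dim(x)
  if (ph == 0 && pw == 0) return(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * ph, d[3] + 2 * pw, d[4]))
  xp[, (ph + 1):(ph + d[2]), (pw + 1):(pw + d[3]), ] <- x
  xp
}

#' 2D convolution layer
#'
#' Kernel (kh x kw), stride (sh, sw), symmetric zero padding (ph, pw).
#' Also serves as the temporal convolution of the graph network with
#' H = time and kw = 1.
#' @keywords internal
conv2d_layer <- function(c_in, c_out, kh, kw = kh, sh = 1, sw = sh,
                         ph = (kh - 1) %/% 2, pw = (kw - 1) %/% 2, bias = TRUE) {
  l <- new_layer("conv2d")
  l$meta <- list(c_in = c_in, c_out = c_out, kh = kh, kw = kw,
                 sh = sh, sw = sw, ph = ph, pw = pw, bias = bias)
  l$params$W <- he_init(c_in * kh * kw, c(c_out, c_in * kh * kw))
  if (bias) l$params$b <- numeric(c_out)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    m <- l$meta
    sg_assert(d[1] == m$c_in, sprintf("conv2d: expected %d channels, got %d", m$c_in, d[1]))
    key <- paste(d, collapse = "x")
    if (is.null(l$cache_key) || l$cache_key != key) {
      l$geom <- im2col_index(d[1], d[2], d[3], d[4], m$kh, m$kw, m$sh, m$sw, m$ph, m$pw)
      l$cache_key <- key
      l$in_dim <- d
    }
    xp <- pad_input(x, m$ph, m$pw)
    cols <- matrix(xp[l$geom$idx], nrow = nrow(l$geom$idx))
    y <- l$params$W %*% cols
    if (m$bias) y <- y + l$params$b
    if (train) l$cols <- cols
    array(y, dim = c(m$c_out, l$geom$OH, l$geom$OW, d[4]))
  }
  l$backward <- function(dy) {
    m <- l$meta; g <- l$geom; d <- l$in_dim
    dym <- matrix(dy, nrow = m$c_out)
    l$grads$W <- tcrossprod(dym, l$cols)
    if (m$bias) l$grads$b <- rowSums(dym)
    dcols <- crossprod(l$params$W, dym)
    dxp <- numeric(d[1] * g$Hp * g$Wp * d[4])
    C <- d[1]
    for (tap in seq_len(m$kh * m$kw)) {     # taps are collision-free scatters
      rows <- ((tap - 1) * C + 1):(tap * C)
      ii <- as.vector(g$idx[rows, ])
      dxp[ii] <- dxp[ii] + as.vector(dcols[rows, ])
    }
    dxp <- array(dxp, dim = c(C, g$Hp, g$Wp, d[4]))
    dxp[, (m$ph + 1):(m$ph + d[2]), (m$pw + 1):(m$pw + d[3]), , drop = FALSE]
  }
  l
}

# Temporal convolution over dim 2 of (C, T, V, N) blocks, kernel k x 1,
# "same" zero padding, optional stride. Internally time is moved to the
# last axis so each kernel tap is one full-tensor GEMM plus a contiguous
# flat-range accumulation (no strided gathers); striding subsamples the
# full stride-1 output.
tconv_layer <- function(c_in, c_out, k, stride = 1) {
  l <- new_layer("tconv")
  pad <- (k - 1) %/% 2
  l$meta <- list(c_in = c_in, c_out = c_out, k = k, s = stride, p = pad)
  for (j in seq_len(k)) l$params[[paste0("W", j)]] <- he_init(c_in * k, c(c_out, c_in))
  l$forward <- function(x, train = TRUE) {
    d <- dim(x); m <- l$meta
    sg_assert(d[1] == m$c_in, "tconv: channel mismatch")
    Tn <- d[2]; nv <- d[3] * d[4]
    OT <- (Tn + 2 * m$p - m$k) %/% m$s + 1L
    xt <- aperm(x, c(1, 3, 4, 2))               # (C, N, V, T)
    dim(xt) <- c(m$c_in, nv * Tn)
    if (train) { l$xt <- xt; l$in_dim <- d; l$OT <- OT }
    cy <- m$c_out * nv                          # flat chunk per time step
    yv <- numeric(cy * Tn)                      # full stride-1 output
    for (j in seq_len(m$k)) {
      off <- j - m$p - 1L                       # t_in = t_out + off
      zv <- l$params[[paste0("W", j)]] %*% xt
      o1 <- max(1L, 1L - off); o2 <- min(Tn, Tn - off)
      if (o1 > o2) next
      yi <- ((o1 - 1L) * cy + 1L):(o2 * cy)
      zi <- ((o1 + off - 1L) * cy + 1L):((o2 + off) * cy)
      yv[yi] <- yv[yi] + zv[zi]
    }
    dim(yv) <- c(m$c_out, nv, Tn)
    if (m$s > 1L) yv <- yv[, , seq.int(1L, Tn, m$s), drop = FALSE]
    dim(yv) <- c(m$c_out, d[3], d[4], OT)
    aperm(yv, c(1, 4, 2, 3))                    # (C_out, OT, N, V)
  }
  l$backward <- function(dy) {
    d <- l$in_dim; m <- l$meta
    Tn <- d[2]; nv <- d[3] * d[4]
    dyt <- aperm(dy, c(1, 3, 4, 2))
    if (m$s > 1L) {                             # re-expand to stride-1 grid
      full <- array(0, dim = c(m$c_out, nv, Tn))
      dim(dyt) <- c(m$c_out, nv, l$OT)
      full[, , seq.int(1L, Tn, m$s)] <- dyt
      dyt <- full
    }
    dim(dyt) <- c(m$c_out, nv * Tn)
    cx <- m$c_in * nv; cyc <- m$c_out * nv
    dxv <- numeric(cx * Tn)
    for (j in seq_len(m$k)) {
      off <- j - m$p - 1L
      o1 <- max(1L, 1L - off); o2 <- min(Tn, Tn - off)
      if (o1 > o2) next
      dyi <- ((o1 - 1L) * cyc + 1L):(o2 * cyc)
      xi <- ((o1 + off - 1L) * cx + 1L):((o2 + off) * cx)
      dys <- dyt[dyi]; dim(dys) <- c(m$c_out, length(dys) / m$c_out)
      xs <- l$xt[xi]; dim(xs) <- c(m$c_in, length(xs) / m$c_in)
      l$grads[[paste0("W", j)]] <- tcrossprod(dys, xs)
      dz <- crossprod(l$params[[paste0("W", j)]], dys)
      dxv[xi] <- dxv[xi] + as.vector(dz)
    }
    dim(dxv) <- c(m$c_in, d[3], d[4], Tn)
    aperm(dxv, c(1, 4, 2, 3))
  }
  l
}

# ---- batch normalization ----------------------------------------------------

bn_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn")
  l$meta <- list(C = C, momentum = momentum, eps = eps)
  l$params$gamma <- rep(1, C)
  l$params$beta <- rep(0, C)
  l$run_mean <- rep(0, C)
  l$run_var <- rep(1, C)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    xm <- matrix(x, nrow = d[1])
    if (train) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc^2)
      l$run_mean <- (1 - l$meta$momentum) * l$run_mean + l$meta$momentum * mu
      l$run_var <- (1 - l$meta$momentum) * l$run_var + l$meta$momentum * v
      inv <- 1 / sqrt(v + l$meta$eps)
      xhat <- xc * inv
      l$xhat <- xhat; l$inv <- inv; l$in_dim <- d
      array(l$params$gamma * xhat + l$params$beta, dim = d)
    } else {
      inv <- 1 / sqrt(l$run_var + l$meta$eps)
      array(l$params$gamma * (xm - l$run_mean) * inv + l$params$beta, dim = d)
    }
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    dym <- matrix(dy, nrow = d[1])
    m <- ncol(dym)
    l$grads$gamma <- rowSums(dym * l$xhat)
    l$grads$beta <- rowSums(dym)
    coef <- l$params$gamma * l$inv / m
    dx <- coef * (m * dym - rowSums(dym) - l$xhat * rowSums(dym * l$xhat))
    array(dx, dim = d)
  }
  l
}

# ---- element-wise and pooling ----------------------------------------------

relu_layer <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, train = TRUE) {
    if (train) l$mask <- x > 0
    x * (x > 0)
  }
  l$backward <- function(dy) dy * l$mask
  l
}

maxpool_layer <- function(kh = 3, kw = kh, sh = 2, sw = sh,
                          ph = (kh - 1) %/% 2, pw = (kw - 1) %/% 2) {
  l <- new_layer("maxpool")
  l$meta <- list(kh = kh, kw = kw, sh = sh, sw = sw, ph = ph, pw = pw)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)                      # (C, H, W, N) pooled per channel
    m <- l$meta
    xs <- aperm(x, c(2, 3, 1, 4))    # (H, W, C, N)
    dim(xs) <- c(1, d[2], d[3], d[1] * d[4])
    key <- paste(d, collapse = "x")
    if (is.null(l$cache_key) || l$cache_key != key) {
      l$geom <- im2col_index(1L, d[2], d[3], d[1] * d[4], m$kh, m$kw, m$sh, m$sw, m$ph, m$pw)
      l$cache_key <- key
      l$in_dim <- d
    }
    # pad with -Inf so border windows never elect a padding cell
    dxs <- dim(xs)
    xp <- array(-Inf, dim = c(1, dxs[2] + 2 * m$ph, dxs[3] + 2 * m$pw, dxs[4]))
    xp[, (m$ph + 1):(m$ph + dxs[2]), (m$pw + 1):(m$pw + dxs[3]), ] <- xs
    cols <- matrix(xp[l$geom$idx], nrow = nrow(l$geom$idx))
    best <- cols[1, ]; besti <- rep(1L, ncol(cols))
    for (r in seq_len(nrow(cols))[-1]) {
      upd <- cols[r, ] > best
      best[upd] <- cols[r, upd]; besti[upd] <- r
    }
    if (train) l$besti <- besti
    g <- l$geom
    y <- array(best, dim = c(g$OH, g$OW, d[1], d[4]))
    aperm(y, c(3, 1, 2, 4))
  }
  l$backward <- function(dy) {
    d <- l$in_dim; m <- l$meta; g <- l$geom
    dys <- aperm(dy, c(2, 3, 1, 4))
    dyv <- as.vector(dys)
    dxp <- numeric(g$Hp * g$Wp * d[1] * d[4])
    for (r in seq_len(nrow(g$idx))) {
      sel <- l$besti == r
      if (!any(sel)) next
      ii <- g$idx[r, sel]
      dxp[ii] <- dxp[ii] + dyv[sel]
    }
    dxp <- array(dxp, dim = c(1, g$Hp, g$Wp, d[1] * d[4]))
    dx <- dxp[, (m$ph + 1):(m$ph + d[2]), (m$pw + 1):(m$pw + d[3]), , drop = FALSE]
    dim(dx) <- c(d[2], d[3], d[1], d[4])
    aperm(dx, c(3, 1, 2, 4))
  }
  l
}

gap_layer <- function() {
  l <- new_layer("gap")
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)                      # (C, d2, d3, N) -> (C, N)
    if (train) l$in_dim <- d
    xs <- aperm(x, c(2, 3, 1, 4))
    matrix(colMeans(matrix(xs, nrow = d[2] * d[3])), nrow = d[1])
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    p <- d[2] * d[3]
    dys <- array(rep(as.vector(dy) / p, each = p), dim = c(d[2], d[3], d[1], d[4]))
    aperm(dys, c(3, 1, 2, 4))
  }
  l
}

# Global average pool over time (dim 2) and joints (dim 4) of (C, T, N, V).
gap_tv_layer <- function() {
  l <- new_layer("gap_tv")
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (train) l$in_dim <- d
    sv <- rowMeans(matrix(x, ncol = d[4]))      # mean over V -> (C, T, N)
    dim(sv) <- c(d[1], d[2], d[3])
    st <- colMeans(matrix(aperm(sv, c(2, 1, 3)), nrow = d[2]))  # mean over T
    matrix(st, nrow = d[1])                      # (C, N)
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    p <- d[2] * d[4]
    # gradient spreads equally over the T x V positions of each (c, n)
    per_ctn <- array(rep(as.vector(dy) / p, each = d[2]), dim = c(d[2], d[1], d[3]))
    base <- aperm(per_ctn, c(2, 1, 3))           # (C, T, N)
    array(rep(as.vector(base), times = d[4]), dim = d)
  }
  l
}

dense_layer <- function(f_in, f_out) {
  l <- new_layer("dense")
  l$params$W <- he_init(f_in, c(f_out, f_in))
  l$params$b <- numeric(f_out)
  l$forward <- function(x, train = TRUE) {
    if (train) l$x <- x
    l$params$W %*% x + l$params$b
  }
  l$backward <- function(dy) {
    l$grads$W <- tcrossprod(dy, l$x)
    l$grads$b <- rowSums(dy)
    crossprod(l$params$W, dy)
  }
  l
}

# ---- graph convolution and joint attention ----------------------------------

# Spatial graph convolution: y = sum_s A_s x W_s, one 1x1 channel mix per
# partition subset followed by mixing along the joint axis with that
# subset's normalized adjacency. x is (C, T, V, N).
gconv_layer <- function(c_in, c_out, A_list) {
  l <- new_layer("gconv")
  l$A <- A_list
  l$meta <- list(c_in = c_in, c_out = c_out, S = length(A_list))
  for (s in seq_along(A_list)) {
    l$params[[paste0("W", s)]] <- he_init(c_in, c(c_out, c_in))
  }
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)                                 # (C, T, N, V): V last
    co <- l$meta$c_out
    xm <- matrix(x, nrow = d[1])
    if (train) { l$xm <- xm; l$in_dim <- d }
    out <- 0
    for (s in seq_len(l$meta$S)) {
      z <- l$params[[paste0("W", s)]] %*% xm
      dim(z) <- c(co * d[2] * d[3], d[4])
      out <- out + z %*% t(l$A[[s]])            # joint mix in one GEMM
    }
    dim(out) <- c(co, d[2], d[3], d[4])
    out
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    co <- l$meta$c_out
    dym <- matrix(dy, ncol = d[4])
    dx <- 0
    for (s in seq_len(l$meta$S)) {
      dz <- dym %*% l$A[[s]]
      dim(dz) <- c(co, d[2] * d[3] * d[4])
      l$grads[[paste0("W", s)]] <- tcrossprod(dz, l$xm)
      dx <- dx + crossprod(l$params[[paste0("W", s)]], dz)
    }
    dim(dx) <- d
    dx
  }
  l
}

# Learned per-joint multiplicative attention: weights softmax-normalized
# over the V joints (non-negative, sum to 1), broadcast over channels, time
# and samples. The applied multiplier is V * w_v so that the uniform
# initialization is the identity map (multiplying by w_v alone shrinks all
# features 25-fold and stalls optimization). Joint axis last: (C, T, N, V).
attention_layer <- function(V) {
  l <- new_layer("attention")
  l$params$a <- numeric(V)
  l$forward <- function(x, train = TRUE) {
    d <- dim(x)
    w <- exp(l$params$a - max(l$params$a))
    w <- w / sum(w)
    if (train) { l$x <- x; l$w <- w; l$in_dim <- d }
    x * rep(d[4] * w, each = d[1] * d[2] * d[3])
  }
  l$backward <- function(dy) {
    d <- l$in_dim
    dx <- dy * rep(d[4] * l$w, each = d[1] * d[2] * d[3])
    g <- d[4] * colSums(matrix(dy * l$x, ncol = d[4]))
    l$grads$a <- l$w * (g - sum(l$w * g))
    dx
  }
  l
}

attention_weights_of <- function(l) {
  w <- exp(l$params$a - max(l$params$a))
  w / sum(w)
}

# ---- composition ------------------------------------------------------------

sequential_layer <- function(layers) {
  l <- new_layer("sequential", children = layers)
  l$forward <- function(x, train = TRUE) {
    for (ch in l$children) x <- ch$forward(x, train)
    x
  }
  l$backward <- function(dy) {
    for (ch in rev(l$children)) dy <- ch$backward(dy)
    dy
  }
  l
}

# Residual block: main path vs identity/projection shortcut, summed before
# the closing ReLU. Used by both the image CNN (spatial stride) and the
# graph network (temporal stride).
residual_layer <- function(main, shortcut = NULL) {
  kids <- if (is.null(shortcut)) list(main) else list(main, shortcut)
  l <- new_layer("residual", children = kids)
  l$main <- main; l$shortcut <- shortcut
  l$relu <- relu_layer()
  l$children <- c(l$children, list(l$relu))
  l$forward <- function(x, train = TRUE) {
    y <- l$main$forward(x, train)
    s <- if (is.null(l$shortcut)) x else l$shortcut$forward(x, train)
    l$relu$forward(y + s, train)
  }
  l$backward <- function(dy) {
    dy <- l$relu$backward(dy)
    dx_main <- l$main$backward(dy)
    dx_short <- if (is.null(l$shortcut)) dy else l$shortcut$backward(dy)
    dx_main + dx_short
  }
  l
}

# ---- loss and optimizers ----------------------------------------------------

softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

#' Softmax cross-entropy on logit columns
#' @param logits K x N matrix; @param y integer class labels in 1..K.
#' @return list(loss, dlogits, probs)
#' @keywords internal
cross_entropy <- function(logits, y) {
  n <- ncol(logits)
  p <- softmax_cols(logits)
  picked <- p[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(y, seq_len(n))] <- dl[cbind(y, seq_len(n))] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}

make_optimizer <- function(kind = c("sgd", "adam"), lr = 0.01, momentum = 0.9,
                           weight_decay = 0) {
  kind <- match.arg(kind)
  opt <- new.env(parent = emptyenv())
  opt$kind <- kind; opt$lr <- lr; opt$momentum <- momentum
  opt$wd <- weight_decay; opt$t <- 0L
  opt$step <- function(layers, lr = opt$lr) {
    opt$t <- opt$t + 1L
    for (l in layers) {
      for (nm in names(l$params)) {
        g <- l$grads[[nm]]
        if (is.null(g)) next
        if (opt$wd > 0 && substr(nm, 1, 1) == "W") g <- g + opt$wd * l$params[[nm]]
        if (opt$kind == "sgd") {
          buf <- l$opt_state[[paste0("m_", nm)]]
          buf <- if (is.null(buf)) g else opt$momentum * buf + g
          l$opt_state[[paste0("m_", nm)]] <- buf
          l$params[[nm]] <- l$params[[nm]] - lr * buf
        } else {
          b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
          m <- l$opt_state[[paste0("m_", nm)]] %||% (g * 0)
          v <- l$opt_state[[paste0("v_", nm)]] %||% (g * 0)
          m <- b1 * m + (1 - b1) * g
          v <- b2 * v + (1 - b2) * g^2
          l$opt_state[[paste0("m_", nm)]] <- m
          l$opt_state[[paste0("v_", nm)]] <- v
          mh <- m / (1 - b1^opt$t); vh <- v / (1 - b2^opt$t)
          l$params[[nm]] <- l$params[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
      }
    }
    invisible(NULL)
  }
  opt
}

cosine_lr <- function(lr0, epoch, total_epochs) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(total_epochs - 1, 1)))
}

# Deep copy / restore of all parameters and batch-norm running statistics
# (for best-epoch checkpointing and on-disk serialization).
snapshot_params <- function(root) {
  lapply(collect_layers(root), function(l) {
    list(params = l$params, run_mean = l$run_mean, run_var = l$run_var)
  })
}

restore_params <- function(root, snap) {
  layers <- collect_layers(root)
  sg_assert(length(layers) == length(snap), "parameter snapshot shape mismatch")
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run_mean)) {
      layers[[i]]$run_mean <- snap[[i]]$run_mean
      layers[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(NULL)
}
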