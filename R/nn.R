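# Minimal tape-based autodiff core for small convolutional networks.
#
# Feature maps are H x W x C arrays, processed one sample at a time. A tape
# records each op; backward() replays it in reverse, accumulating gradients
# into named parameter slots. Convolution is im2col + BLAS matmul; the im2col
# index maps are cached per (shape, kernel, stride, dilation).

.nn_cache <- new.env(parent = emptyenv())

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = integer(), backward = NULL,
                    param_name = NULL) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  node <- list(id = tp$n, value = value, parents = parents,
               backward = backward, param_name = param_name)
  tp$nodes[[tp$n]] <- node
  node
}

tp_leaf <- function(tp, value, param_name = NULL) {
  tp_push(tp, value, param_name = param_name)
}

# Backpropagate grad_out through the tape from node `out`; returns a named
# list of gradients for every leaf that carries a param_name. `out` may be a
# list of nodes with `grad_out` a matching list of seed gradients.
tape_backward <- function(tp, out, grad_out) {
  grads <- vector("list", tp$n)
  if (!is.null(out$id)) { out <- list(out); grad_out <- list(grad_out) }
  for (k in seq_along(out)) {
    id <- out[[k]]$id
    grads[[id]] <- if (is.null(grads[[id]])) grad_out[[k]]
                   else grads[[id]] + grad_out[[k]]
  }
  pgrads <- list()
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    if (!is.null(node$param_name)) {
      pn <- node$param_name
      pgrads[[pn]] <- if (is.null(pgrads[[pn]])) g else pgrads[[pn]] + g
    }
    if (!is.null(node$backward) && length(node$parents)) {
      pg <- node$backward(g, node)
      for (k in seq_along(node$parents)) {
        pid <- node$parents[k]
        if (is.null(pg[[k]])) next
        grads[[pid]] <- if (is.null(grads[[pid]])) pg[[k]] else grads[[pid]] + pg[[k]]
      }
    }
    grads[id] <- list(NULL)
  }
  pgrads
}

# ---- im2col indexing -------------------------------------------------------

conv_index <- function(H, W, C, k, stride, dilation) {
  key <- paste(H, W, C, k, stride, dilation, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- dilation * (k - 1) %/% 2
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (H + 2L * pad - dilation * (k - 1) - 1L) %/% stride + 1L
  Wo <- (W + 2L * pad - dilation * (k - 1) - 1L) %/% stride + 1L
  oy <- (seq_len(Ho) - 1L) * stride          # top-left y of each window (0-based, padded)
  ox <- (seq_len(Wo) - 1L) * stride
  # base linear index (1-based) in padded [Hp, Wp] for output grid, column-major
  base <- outer(oy + 1L, ox * Hp, `+`)       # Ho x Wo
  koff <- as.vector(outer((0:(k - 1)) * dilation,
                          (0:(k - 1)) * dilation * Hp, `+`))  # k*k offsets
  idx1 <- outer(as.vector(base), koff, `+`)  # (Ho*Wo) x (k*k)
  choff <- (seq_len(C) - 1L) * (Hp * Wp)
  idx <- matrix(0L, Ho * Wo, k * k * C)
  for (c in seq_len(C))
    idx[, ((c - 1L) * k * k + 1L):(c * k * k)] <- idx1 + choff[c]
  out <- list(idx = idx, pad = pad, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  .nn_cache[[key]] <- out
  out
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  xp
}

# ---- ops -------------------------------------------------------------------

# x: node [H,W,Cin]; Wm: k*k*Cin x Cout weight matrix; b: length-Cout bias.
nn_conv2d <- function(tp, x, Wm, b, k, stride = 1L, dilation = 1L,
                      name = NULL) {
  d <- dim(x$value)
  Cin <- d[3]
  ci <- conv_index(d[1], d[2], Cin, k, stride, dilation)
  xp <- pad_array(x$value, ci$pad)
  # index as a vector: a matrix index into a 3-D array would be read as
  # per-row coordinates
  cols <- matrix(xp[as.vector(ci$idx)], nrow(ci$idx), ncol(ci$idx))
  out <- cols %*% Wm
  out <- sweep(out, 2, b, `+`)
  Wn <- tp_leaf(tp, Wm, param_name = if (is.null(name)) NULL else paste0(name, ".W"))
  bn <- tp_leaf(tp, b, param_name = if (is.null(name)) NULL else paste0(name, ".b"))
  val <- array(out, c(ci$Ho, ci$Wo, ncol(Wm)))
  bw <- function(g, node) {
    gm <- matrix(g, ci$Ho * ci$Wo, dim(node$value)[3])
    dW <- crossprod(cols, gm)
    db <- colSums(gm)
    dcols <- gm %*% t(Wm)
    # col2im: scatter-add into the padded frame
    npad <- ci$Hp * ci$Wp * Cin
    acc <- rowsum(as.vector(dcols), group = as.vector(ci$idx))
    dxp <- numeric(npad)
    dxp[as.integer(rownames(acc))] <- acc[, 1]
    dxp <- array(dxp, c(ci$Hp, ci$Wp, Cin))
    dx <- if (ci$pad > 0)
      dxp[(ci$pad + 1L):(ci$pad + d[1]), (ci$pad + 1L):(ci$pad + d[2]), , drop = FALSE]
    else dxp
    list(dx, dW, db)
  }
  tp_push(tp, val, parents = c(x$id, Wn$id, bn$id), backward = bw)
}

# Per-channel normalization over the spatial grid (batch statistics computed
# per sample), affine gamma/beta; running stats updated for inference.
nn_batchnorm <- function(tp, x, gamma, beta, name = NULL, eps = 1e-5,
                         training = TRUE, run = NULL, momentum = 0.1) {
  d <- dim(x$value)
  C <- d[3]
  xm <- matrix(x$value, d[1] * d[2], C)
  if (training || is.null(run)) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    if (!is.null(run)) {
      run$mean <- (1 - momentum) * run$mean + momentum * mu
      run$var <- (1 - momentum) * run$var + momentum * va
    }
  } else {
    mu <- run$mean; va <- run$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  gn <- tp_leaf(tp, gamma, param_name = if (is.null(name)) NULL else paste0(name, ".g"))
  bn <- tp_leaf(tp, beta, param_name = if (is.null(name)) NULL else paste0(name, ".be"))
  n <- d[1] * d[2]
  bw <- function(g, node) {
    gm <- matrix(g, n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    if (training) {
      # standard normalization backward per channel
      t1 <- sweep(gm, 2, gamma, `*`)
      s1 <- colSums(t1)
      s2 <- colSums(t1 * xhat)
      dx <- sweep(t1, 2, s1 / n) - sweep(xhat, 2, s2 / n, `*`)
      dx <- sweep(dx, 2, istd, `*`)
    } else {
      dx <- sweep(sweep(gm, 2, gamma, `*`), 2, istd, `*`)
    }
    list(array(dx, d), dgamma, dbeta)
  }
  tp_push(tp, array(y, d), parents = c(x$id, gn$id, bn$id), backward = bw)
}

nn_relu <- function(tp, x) {
  m <- x$value > 0
  tp_push(tp, x$value * m, parents = x$id,
          backward = function(g, node) list(g * m))
}

nn_leaky_relu <- function(tp, x, slope = 0.1) {
  m <- ifelse(x$value > 0, 1, slope)
  tp_push(tp, x$value * m, parents = x$id,
          backward = function(g, node) list(g * m))
}

nn_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-x$value))
  tp_push(tp, s, parents = x$id,
          backward = function(g, node) list(g * s * (1 - s)))
}

nn_maxpool2 <- function(tp, x) {
  d <- dim(x$value)
  Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  C <- d[3]
  xm <- x$value[seq_len(2L * Ho), seq_len(2L * Wo), , drop = FALSE]
  # four candidates per output cell
  a <- xm[seq(1, 2 * Ho, 2), seq(1, 2 * Wo, 2), , drop = FALSE]
  b <- xm[seq(2, 2 * Ho, 2), seq(1, 2 * Wo, 2), , drop = FALSE]
  cc <- xm[seq(1, 2 * Ho, 2), seq(2, 2 * Wo, 2), , drop = FALSE]
  dd <- xm[seq(2, 2 * Ho, 2), seq(2, 2 * Wo, 2), , drop = FALSE]
  val <- pmax(a, b, cc, dd)
  bw <- function(g, node) {
    dx <- array(0, d)
    # distribute to the (first) argmax among the four candidates
    sel_a <- (a == val)
    sel_b <- (b == val) & !sel_a
    sel_c <- (cc == val) & !sel_a & !sel_b
    sel_d <- (dd == val) & !sel_a & !sel_b & !sel_c
    dx[seq(1, 2 * Ho, 2), seq(1, 2 * Wo, 2), ] <- g * sel_a
    dx[seq(2, 2 * Ho, 2), seq(1, 2 * Wo, 2), ] <-
      dx[seq(2, 2 * Ho, 2), seq(1, 2 * Wo, 2), ] + g * sel_b
    dx[seq(1, 2 * Ho, 2), seq(2, 2 * Wo, 2), ] <-
      dx[seq(1, 2 * Ho, 2), seq(2, 2 * Wo, 2), ] + g * sel_c
    dx[seq(2, 2 * Ho, 2), seq(2, 2 * Wo, 2), ] <-
      dx[seq(2, 2 * Ho, 2), seq(2, 2 * Wo, 2), ] + g * sel_d
    list(dx)
  }
  tp_push(tp, val, parents = x$id, backward = bw)
}

resize_ops_cached <- function(h_in, w_in, h_out, w_out, method) {
  key <- paste("rz", h_in, w_in, h_out, w_out, method, sep = "_")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- list(Ry = resize_operator(h_in, h_out, method),
              Rx = resize_operator(w_in, w_out, method))
  .nn_cache[[key]] <- out
  out
}

nn_resize <- function(tp, x, h_out, w_out, method = "bilinear") {
  d <- dim(x$value)
  if (d[1] == h_out && d[2] == w_out) return(x)
  rz <- resize_ops_cached(d[1], d[2], h_out, w_out, method)
  C <- d[3]
  val <- array(0, c(h_out, w_out, C))
  for (k in seq_len(C)) val[, , k] <- rz$Ry %*% x$value[, , k] %*% t(rz$Rx)
  bw <- function(g, node) {
    dx <- array(0, d)
    for (k in seq_len(C)) dx[, , k] <- crossprod(rz$Ry, g[, , k]) %*% rz$Rx
    list(dx)
  }
  tp_push(tp, val, parents = x$id, backward = bw)
}

nn_concat <- function(tp, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2])
  val <- array(0, c(da[1], da[2], da[3] + db[3]))
  val[, , seq_len(da[3])] <- a$value
  val[, , da[3] + seq_len(db[3])] <- b$value
  bw <- function(g, node) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  }
  tp_push(tp, val, parents = c(a$id, b$id), backward = bw)
}

nn_add <- function(tp, a, b) {
  tp_push(tp, a$value + b$value, parents = c(a$id, b$id),
          backward = function(g, node) list(g, g))
}

# scale by a fixed scalar (no gradient to the scalar)
nn_scale <- function(tp, x, s) {
  tp_push(tp, x$value * s, parents = x$id,
          backward = function(g, node) list(g * s))
}

# ---- parameter containers and init ----------------------------------------

he_init <- function(k, c_in, c_out) {
  sd <- sqrt(2 / (k * k * c_in))
  matrix(stats::rnorm(k * k * c_in * c_out, 0, sd), k * k * c_in, c_out)
}

# Register a conv(+BN) block's parameters into env `P` under `name`.
init_conv <- function(P, name, k, c_in, c_out, bn = TRUE) {
  P$params[[paste0(name, ".W")]] <- he_init(k, c_in, c_out)
  P$params[[paste0(name, ".b")]] <- numeric(c_out)
  if (bn) {
    P$params[[paste0(name, ".g")]] <- rep(1, c_out)
    P$params[[paste0(name, ".be")]] <- rep(0, c_out)
    P$stats[[name]] <- local({
      e <- new.env(parent = emptyenv())
      e$mean <- numeric(c_out); e$var <- rep(1, c_out)
      e
    })
  }
  invisible(P)
}

n_trainable <- function(params) sum(vapply(params, length, 0L))

# ---- optimizers ------------------------------------------------------------

optimizer_new <- function(type = c("adamw", "sgd"), lr = 1e-3,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                          weight_decay = 0, momentum = 0.937) {
  type <- match.arg(type)
  list(type = type, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weight_decay = weight_decay, momentum = momentum,
       state = new.env(parent = emptyenv()), t = 0L)
}

optimizer_step <- function(opt, params, grads, lr = NULL, clip = 5) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  st <- opt$state
  for (nm in names(grads)) {
    g <- grads[[nm]]
    p <- params[[nm]]
    if (is.null(p)) next
    if (anyNA(g) || any(!is.finite(g))) next   # skip exploded gradients
    if (is.finite(clip)) g <- pmin(pmax(g, -clip), clip)
    if (opt$type == "adamw") {
      if (opt$weight_decay > 0) p <- p - lr * opt$weight_decay * p
      mkey <- paste0(nm, ".m"); vkey <- paste0(nm, ".v")
      m <- if (is.null(st[[mkey]])) g * 0 else st[[mkey]]
      v <- if (is.null(st[[vkey]])) g * 0 else st[[vkey]]
      m <- opt$beta1 * m + (1 - opt$beta1) * g
      v <- opt$beta2 * v + (1 - opt$beta2) * g^2
      st[[mkey]] <- m; st[[vkey]] <- v
      mh <- m / (1 - opt$beta1^opt$t)
      vh <- v / (1 - opt$beta2^opt$t)
      p <- p - lr * mh / (sqrt(vh) + opt$eps)
    } else {
      if (opt$weight_decay > 0) g <- g + opt$weight_decay * p
      vkey <- paste0(nm, ".mom")
      v <- if (is.null(st[[vkey]])) g * 0 else st[[vkey]]
      v <- opt$momentum * v + g
      st[[vkey]] <- v
      p <- p - lr * v
    }
    params[[nm]] <- p
  }
  list(opt = opt, params = params)
}

#' Cosine-annealed learning rate
#'
#' `eta_min + (lr0 - eta_min) * (1 + cos(pi * epoch / T_max)) / 2`: the rate
#' starts at `lr0` at epoch 0 and reaches `eta_min` at epoch `T_max`.
#'
#' @param epoch 0-based epoch index.
#' @param lr0 initial learning rate.
#' @param t_max annealing period in epochs.
#' @param eta_min floor of the schedule (default 0).
#' @return The learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, lr0, t_max = 50, eta_min = 0) {
  e <- epoch %% (2 * t_max)
  e <- ifelse(e > t_max, 2 * t_max - e, e)   # periodic restart-free reflection
  eta_min + (lr0 - eta_min) * (1 + cos(pi * e / t_max)) / 2
}
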