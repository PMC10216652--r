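# Minimal reverse-mode automatic differentiation over dense arrays, sized
# for desk-scale convolutional models.  Activations are arrays (H, W, C, N);
# dense activations are (N, F) matrices.  Convolution is im2col + BLAS
# matrix products; the col2im scatter in the backward pass reuses a cached
# sparse 0/1 gather matrix (Matrix package).  Nothing here is exported: the
# U-Net and DenseNet modules are the public surface.

nnCounter <- new.env(parent = emptyenv())
nnCounter$id <- 0L

nnNode <- function(value, parents = list(), backfn = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  nnCounter$id <- nnCounter$id + 1L
  e$id <- nnCounter$id
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$param <- param
  class(e) <- "nnNode"
  e
}

nnParam <- function(value) {
  e <- nnNode(value, param = TRUE)
  e$m <- 0
  e$v <- 0
  e$cache <- list()
  e
}

nnVal <- function(x) if (inherits(x, "nnNode")) x$value else x

addGrad <- function(node, g) {
  if (!inherits(node, "nnNode")) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# reverse pass from a scalar loss node
nnBackward <- function(loss) {
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (inherits(p, "nnNode"))
      stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)),
               decreasing = TRUE)
  loss$grad <- 1
  for (nd in nodes[ord]) {
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd$grad)
    if (!nd$param) {
      # processed: release value/grad and break closure references so the
      # allocator can reclaim intermediate activations during the pass
      nd$backfn <- NULL
      nd$grad <- NULL
      nd$value <- NULL
      nd$parents <- list()
    }
  }
  invisible(NULL)
}

nnZeroGrads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

adamStep <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# ---- shape helpers -------------------------------------------------------

convOutSize <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# gather indices for im2col on a padded (Hp, Wp, C) volume
im2colIndex <- function(Hp, Wp, C, KH, KW, stride) {
  OH <- (Hp - KH) %/% stride + 1L
  OW <- (Wp - KW) %/% stride + 1L
  patch <- rep(seq_len(KH), times = KW) +
    (rep(seq_len(KW), each = KH) - 1L) * Hp
  base <- as.vector(outer(patch, (seq_len(C) - 1L) * Hp * Wp, "+"))
  pos <- as.vector(outer((seq_len(OH) - 1L) * stride,
                         (seq_len(OW) - 1L) * stride * Hp, "+")) + 1L
  idx <- outer(base, pos - 1L, "+")          # (KH*KW*C) x (OH*OW)
  list(idx = idx, OH = OH, OW = OW)
}

padArray <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# broadcast a per-channel vector over an (H, W, C, N) array
bcChan <- function(v, H, W, C, N) {
  array(rep(rep(v, each = H * W), times = N), c(H, W, C, N))
}

chanStat <- function(x, f) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  f(m)
}

# ---- ops -----------------------------------------------------------------

# W: nnParam holding a (KH*KW*Cin) x Cout matrix with attr "kdim" = c(KH,KW)
opConv2d <- function(x, W, b, stride = 1L, pad = 0L) {
  xv <- nnVal(x)
  d <- dim(xv)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  kd <- attr(W$value, "kdim")
  KH <- kd[1]; KW <- kd[2]
  Cout <- ncol(W$value)
  key <- paste(H, Wd, C, KH, KW, stride, pad, sep = "_")
  if (is.null(W$cache[[key]])) {
    Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
    ii <- im2colIndex(Hp, Wp, C, KH, KW, stride)
    A <- Matrix::sparseMatrix(i = seq_along(ii$idx),
                              j = as.vector(ii$idx), x = 1,
                              dims = c(length(ii$idx), Hp * Wp * C))
    W$cache[[key]] <- list(idx = ii$idx, OH = ii$OH, OW = ii$OW, A = A,
                           Hp = Hp, Wp = Wp)
  }
  cc <- W$cache[[key]]
  xp <- padArray(xv, pad)
  S <- cc$Hp * cc$Wp * C
  K <- nrow(cc$idx); P <- ncol(cc$idx)
  idxN <- as.vector(outer(as.vector(cc$idx), (seq_len(N) - 1L) * S, "+"))
  cols <- matrix(xp[idxN], K, P * N)
  outMat <- crossprod(W$value, cols) + b$value
  out <- aperm(array(outMat, c(Cout, cc$OH, cc$OW, N)), c(2, 3, 1, 4))
  node <- nnNode(out, parents = list(x, W, b))
  # the im2col matrix is large: rebuild it in the backward pass instead of
  # keeping it alive in the closure
  rm(cols, outMat, out, idxN, xp)
  node$backfn <- function(g) {
    gMat <- matrix(aperm(g, c(3, 1, 2, 4)), Cout, P * N)
    xp <- padArray(xv, pad)
    idxN <- as.vector(outer(as.vector(cc$idx), (seq_len(N) - 1L) * S, "+"))
    cols <- matrix(xp[idxN], K, P * N)
    rm(xp, idxN)
    dW <- tcrossprod(cols, gMat)
    rm(cols)
    attr(dW, "kdim") <- kd
    addGrad(W, dW)
    addGrad(b, rowSums(gMat))
    if (inherits(x, "nnNode")) {
      dcols <- W$value %*% gMat
      rm(gMat)
      dxp <- as.matrix(Matrix::crossprod(cc$A, matrix(dcols, K * P, N)))
      rm(dcols)
      dxp <- array(dxp, c(cc$Hp, cc$Wp, C, N))
      dx <- if (pad > 0L)
        dxp[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE]
      else dxp
      addGrad(x, dx)
    }
  }
  node
}

opRelu <- function(x) {
  xv <- nnVal(x)
  out <- pmax(xv, 0)
  pos <- xv > 0
  node <- nnNode(out, parents = list(x))
  rm(xv, out)
  node$backfn <- function(g) addGrad(x, g * pos)
  node
}

# gamma param env also carries running mean/var for inference
opBatchNorm <- function(x, gamma, beta, training = TRUE, momentum = 0.1,
                        eps = 1e-5) {
  xv <- nnVal(x)
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- H * W * N
  if (training) {
    mu <- chanStat(xv, colMeans)
    xc <- xv - bcChan(mu, H, W, C, N)
    var <- chanStat(xc^2, colMeans)
    if (is.null(gamma$rmean)) { gamma$rmean <- mu; gamma$rvar <- var }
    else {
      gamma$rmean <- (1 - momentum) * gamma$rmean + momentum * mu
      gamma$rvar <- (1 - momentum) * gamma$rvar + momentum * var
    }
  } else {
    mu <- gamma$rmean
    var <- gamma$rvar
    if (is.null(mu)) { mu <- numeric(C); var <- rep(1, C) }
    xc <- xv - bcChan(mu, H, W, C, N)
  }
  istd <- 1 / sqrt(var + eps)
  xhat <- xc * bcChan(istd, H, W, C, N)
  out <- xhat * bcChan(gamma$value, H, W, C, N) +
    bcChan(beta$value, H, W, C, N)
  node <- nnNode(out, parents = list(x, gamma, beta))
  rm(out, xc, xv, mu, var)
  node$backfn <- function(g) {
    addGrad(gamma, chanStat(g * xhat, colSums))
    addGrad(beta, chanStat(g, colSums))
    if (inherits(x, "nnNode")) {
      if (training) {
        gm <- chanStat(g, colMeans)
        gxm <- chanStat(g * xhat, colMeans)
        dx <- bcChan(gamma$value * istd, H, W, C, N) *
          (g - bcChan(gm, H, W, C, N) - xhat * bcChan(gxm, H, W, C, N))
      } else {
        dx <- g * bcChan(gamma$value * istd, H, W, C, N)
      }
      addGrad(x, dx)
    }
  }
  node
}

opMaxPool <- function(x, k = 2L, stride = k, pad = 0L) {
  xv <- nnVal(x)
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- padArray(xv, pad, fill = -Inf)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  ii <- im2colIndex(Hp, Wp, 1L, k, k, stride)
  Pt <- ncol(ii$idx)
  S2 <- Hp * Wp
  idxAll <- as.vector(outer(as.vector(ii$idx),
                            (seq_len(C * N) - 1L) * S2, "+"))
  patches <- matrix(xp[idxAll], k * k)
  mx <- patches[1, ]
  am <- rep(1L, ncol(patches))
  for (r in seq_len(k * k)[-1]) {
    upd <- patches[r, ] > mx
    mx[upd] <- patches[r, upd]
    am[upd] <- r
  }
  out <- array(mx, c(ii$OH, ii$OW, C, N))
  idxMat <- matrix(idxAll, k * k)
  node <- nnNode(out, parents = list(x))
  rm(out, xp, patches, idxAll, mx, xv, ii)
  node$backfn <- function(g) {
    chosen <- idxMat[cbind(am, seq_along(am))]
    acc <- rowsum(as.vector(g), group = chosen)
    dxp <- array(0, c(Hp, Wp, C, N))
    dxp[as.integer(rownames(acc))] <- acc
    dx <- if (pad > 0L)
      dxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
    else dxp
    addGrad(x, dx)
  }
  node
}

opAvgPool2 <- function(x) {
  xv <- nnVal(x)
  d <- dim(xv)
  OH <- d[1] %/% 2L; OW <- d[2] %/% 2L
  r1 <- 2L * seq_len(OH) - 1L; c1 <- 2L * seq_len(OW) - 1L
  out <- (xv[r1, c1, , , drop = FALSE] + xv[r1 + 1L, c1, , , drop = FALSE] +
          xv[r1, c1 + 1L, , , drop = FALSE] +
          xv[r1 + 1L, c1 + 1L, , , drop = FALSE]) / 4
  node <- nnNode(out, parents = list(x))
  rm(out, xv)
  node$backfn <- function(g) {
    dx <- array(0, d)
    q <- g / 4
    dx[r1, c1, , ] <- q
    dx[r1 + 1L, c1, , ] <- q
    dx[r1, c1 + 1L, , ] <- q
    dx[r1 + 1L, c1 + 1L, , ] <- q
    addGrad(x, dx)
  }
  node
}

opUpsample2 <- function(x) {
  xv <- nnVal(x)
  d <- dim(xv)
  ridx <- rep(seq_len(d[1]), each = 2L)
  cidx <- rep(seq_len(d[2]), each = 2L)
  out <- xv[ridx, cidx, , , drop = FALSE]
  node <- nnNode(out, parents = list(x))
  rm(out, xv)
  node$backfn <- function(g) {
    r1 <- 2L * seq_len(d[1]) - 1L; c1 <- 2L * seq_len(d[2]) - 1L
    dx <- g[r1, c1, , , drop = FALSE] + g[r1 + 1L, c1, , , drop = FALSE] +
      g[r1, c1 + 1L, , , drop = FALSE] + g[r1 + 1L, c1 + 1L, , , drop = FALSE]
    addGrad(x, dx)
  }
  node
}

# crop the spatial dims to (H, W), keeping the top-left region; used for
# "same"-size padding with even kernels
opCropTo <- function(x, H, W) {
  xv <- nnVal(x)
  d <- dim(xv)
  if (d[1] == H && d[2] == W) return(x)
  out <- xv[seq_len(H), seq_len(W), , , drop = FALSE]
  node <- nnNode(out, parents = list(x))
  rm(out, xv)
  node$backfn <- function(g) {
    dx <- array(0, d)
    dx[seq_len(H), seq_len(W), , ] <- g
    addGrad(x, dx)
  }
  node
}

opGlobalAvgPool <- function(x) {
  xv <- nnVal(x)
  d <- dim(xv)
  HW <- d[1] * d[2]
  out <- t(matrix(colMeans(matrix(xv, HW, d[3] * d[4])), d[3], d[4]))
  node <- nnNode(out, parents = list(x))   # (N, C)
  rm(out, xv)
  node$backfn <- function(g) {
    gv <- as.vector(t(g)) / HW              # per (C, N)
    addGrad(x, array(rep(gv, each = HW), d))
  }
  node
}

opConcat <- function(xs) {
  vals <- lapply(xs, nnVal)
  d1 <- dim(vals[[1]])
  Cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(Cs), d1[4]))
  off <- 0L
  for (i in seq_along(vals)) {
    out[, , off + seq_len(Cs[i]), ] <- vals[[i]]
    off <- off + Cs[i]
  }
  node <- nnNode(out, parents = xs)
  rm(out, vals)
  node$backfn <- function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      addGrad(xs[[i]], g[, , off + seq_len(Cs[i]), , drop = FALSE])
      off <- off + Cs[i]
    }
  }
  node
}

opFlatten <- function(x) {
  xv <- nnVal(x)
  d <- dim(xv)
  out <- t(matrix(xv, prod(d[1:3]), d[4]))   # (N, H*W*C)
  node <- nnNode(out, parents = list(x))
  rm(out, xv)
  node$backfn <- function(g) addGrad(x, array(t(g), d))
  node
}

opDense <- function(x, W, b) {
  xv <- nnVal(x)
  out <- xv %*% W$value + matrix(b$value, nrow(xv), length(b$value),
                                 byrow = TRUE)
  node <- nnNode(out, parents = list(x, W, b))
  node$backfn <- function(g) {
    addGrad(W, crossprod(xv, g))
    addGrad(b, colSums(g))
    if (inherits(x, "nnNode")) addGrad(x, tcrossprod(g, W$value))
  }
  node
}

opMSELoss <- function(pred, target) {
  pv <- nnVal(pred)
  diff <- pv - target
  node <- nnNode(mean(diff^2), parents = list(pred))
  node$backfn <- function(g) addGrad(pred, g * 2 * diff / length(diff))
  node
}

# logits (N, K); labels integer 1..K
opSoftmaxCELoss <- function(logits, labels) {
  lv <- nnVal(logits)
  p <- softmaxRows(lv)
  N <- nrow(lv)
  picked <- p[cbind(seq_len(N), labels)]
  node <- nnNode(-mean(log(pmax(picked, 1e-12))), parents = list(logits))
  node$backfn <- function(g) {
    d <- p
    d[cbind(seq_len(N), labels)] <- d[cbind(seq_len(N), labels)] - 1
    addGrad(logits, g * d / N)
  }
  node
}

softmaxRows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# parameter constructors -----------------------------------------------------

initConvParam <- function(KH, KW, Cin, Cout) {
  fanIn <- KH * KW * Cin
  W <- matrix(rnorm(fanIn * Cout, sd = sqrt(2 / fanIn)), fanIn, Cout)
  attr(W, "kdim") <- c(KH, KW)
  list(W = nnParam(W), b = nnParam(numeric(Cout)))
}

initDenseParam <- function(Fin, Fout) {
  list(W = nnParam(matrix(rnorm(Fin * Fout, sd = sqrt(2 / Fin)), Fin, Fout)),
       b = nnParam(numeric(Fout)))
}

initBNParam <- function(C) {
  list(gamma = nnParam(rep(1, C)), beta = nnParam(numeric(C)))
}

# collect every nnParam reachable in a (nested) list
collectParams <- function(x) {
  if (inherits(x, "nnNode")) return(if (x$param) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, collectParams)))
  list()
}

# stack a list of matrices into an (H, W, 1, N) batch array
stackImages <- function(images) {
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), c(d[1], d[2], 1L, length(images)))
}
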