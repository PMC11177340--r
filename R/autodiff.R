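# Tape-based reverse-mode automatic differentiation.
#
# The engine uses coarse-grained ops (matrix multiply, convolution via
# im2col, windowed attention application, normalisation layers) so that a
# forward pass through the full network records only a few hundred tape
# nodes.  Feature maps are stored as (H*W) x C matrices with the R
# column-major spatial convention: pixel (row i, col j) of an H x W plane
# lives at matrix row (j-1)*H + i.  Token grids use the same convention.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

#' @keywords internal
ad_node <- function(tape, val, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  class(nd) <- "ad_node"
  nd
}

is_node <- function(x) inherits(x, "ad_node")

# value of node-or-plain-array
nv <- function(x) if (is_node(x)) x$val else x

tape_of <- function(...) {
  for (a in list(...)) if (is_node(a) && !is.null(a$tape_ref)) return(a$tape_ref)
  NULL
}

# Leaves: wrap a parameter environment (with $val) so its gradient can be
# collected after backward().  Constants never receive gradients.
ad_leaf <- function(tape, param) {
  nd <- ad_node(tape, param$val)
  nd$param <- param
  nd$tape_ref <- tape
  nd
}

ad_const <- function(tape, val) {
  nd <- ad_node(tape, val)
  nd$is_const <- TRUE
  nd$tape_ref <- tape
  nd
}

acc_grad <- function(p, g) {
  if (is.null(p) || !is_node(p) || isTRUE(p$is_const)) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Run reverse pass from scalar node `root`; afterwards every parameter leaf
# env touched by the graph has its gradient summed into param$grad.
ad_backward <- function(tape, root) {
  stopifnot(length(nv(root)) == 1L)
  root$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    nd$backward(nd$grad, nd)
  }
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param) && !is.null(nd$grad)) {
      nd$param$grad <- if (is.null(nd$param$grad)) nd$grad else nd$param$grad + nd$grad
    }
  }
  invisible(NULL)
}

mk <- function(tape, val, parents, bw) {
  nd <- ad_node(tape, val, parents, bw)
  nd$tape_ref <- tape
  nd
}


# fast column-broadcast helpers (x is n x C, v length C)
addc <- function(x, v) x + rep(v, each = nrow(x))
mulc <- function(x, v) x * rep(v, each = nrow(x))

## ---- elementary ops --------------------------------------------------------

ad_add <- function(tp, a, b) {
  mk(tp, nv(a) + nv(b), list(a, b), function(g, nd) {
    acc_grad(nd$parents[[1]], g)
    acc_grad(nd$parents[[2]], g)
  })
}

# sum of n same-shape nodes
ad_addn <- function(tp, xs) {
  v <- nv(xs[[1]])
  for (k in seq_along(xs)[-1]) v <- v + nv(xs[[k]])
  mk(tp, v, xs, function(g, nd) for (p in nd$parents) acc_grad(p, g))
}

ad_sub <- function(tp, a, b) {
  mk(tp, nv(a) - nv(b), list(a, b), function(g, nd) {
    acc_grad(nd$parents[[1]], g)
    acc_grad(nd$parents[[2]], -g)
  })
}

ad_mul <- function(tp, a, b) {
  va <- nv(a); vb <- nv(b)
  mk(tp, va * vb, list(a, b), function(g, nd) {
    acc_grad(nd$parents[[1]], g * vb)
    acc_grad(nd$parents[[2]], g * va)
  })
}

ad_scale <- function(tp, a, s) {
  mk(tp, nv(a) * s, list(a), function(g, nd) acc_grad(nd$parents[[1]], g * s))
}

ad_mm <- function(tp, a, b) {
  va <- nv(a); vb <- nv(b)
  mk(tp, va %*% vb, list(a, b), function(g, nd) {
    acc_grad(nd$parents[[1]], tcrossprod(g, vb))
    acc_grad(nd$parents[[2]], crossprod(va, g))
  })
}

# add a length-C bias vector to every row of an N x C matrix
ad_add_bias <- function(tp, a, b) {
  va <- nv(a); vb <- nv(b)
  mk(tp, addc(va, vb), list(a, b), function(g, nd) {
    acc_grad(nd$parents[[1]], g)
    acc_grad(nd$parents[[2]], colSums(g))
  })
}

ad_tanh <- function(tp, a) {
  v <- tanh(nv(a))
  mk(tp, v, list(a), function(g, nd) acc_grad(nd$parents[[1]], g * (1 - v * v)))
}

ad_sigmoid <- function(tp, a) {
  v <- stats::plogis(nv(a))
  mk(tp, v, list(a), function(g, nd) acc_grad(nd$parents[[1]], g * v * (1 - v)))
}

ad_relu <- function(tp, a) {
  va <- nv(a)
  v <- pmax(va, 0)
  mk(tp, v, list(a), function(g, nd) acc_grad(nd$parents[[1]], g * (va > 0)))
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

ad_softplus <- function(tp, a) {
  va <- nv(a)
  mk(tp, softplus(va), list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], g * stats::plogis(va))
  })
}

# Mish(x) = x * tanh(softplus(x))
ad_mish <- function(tp, a) {
  x <- nv(a)
  sp <- softplus(x)
  t <- tanh(sp)
  mk(tp, x * t, list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], g * (t + x * (1 - t * t) * stats::plogis(x)))
  })
}

ad_square <- function(tp, a) {
  va <- nv(a)
  mk(tp, va * va, list(a), function(g, nd) acc_grad(nd$parents[[1]], 2 * g * va))
}

ad_sum <- function(tp, a) {
  va <- nv(a)
  mk(tp, sum(va), list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], array(g, dim = dim(va) %||% length(va)))
  })
}

ad_mean <- function(tp, a) ad_scale(tp, ad_sum(tp, a), 1 / length(nv(a)))

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- structural ops --------------------------------------------------------

ad_gather_rows <- function(tp, a, idx) {
  va <- nv(a)
  nr <- nrow(va)
  mk(tp, va[idx, , drop = FALSE], list(a), function(g, nd) {
    rs <- rowsum(g, group = idx)
    Z <- matrix(0, nr, ncol(va))
    Z[as.integer(rownames(rs)), ] <- rs
    acc_grad(nd$parents[[1]], Z)
  })
}

ad_cols <- function(tp, a, jidx) {
  va <- nv(a)
  mk(tp, va[, jidx, drop = FALSE], list(a), function(g, nd) {
    Z <- matrix(0, nrow(va), ncol(va))
    Z[, jidx] <- Z[, jidx] + g
    acc_grad(nd$parents[[1]], Z)
  })
}

ad_cbind <- function(tp, xs) {
  vals <- lapply(xs, nv)
  ncols <- vapply(vals, ncol, 1L)
  mk(tp, do.call(cbind, vals), xs, function(g, nd) {
    off <- 0L
    for (k in seq_along(nd$parents)) {
      acc_grad(nd$parents[[k]], g[, off + seq_len(ncols[k]), drop = FALSE])
      off <- off + ncols[k]
    }
  })
}

# y = U %*% x for a constant sparse matrix U (used for bilinear up-sampling
# and area down-sampling applied per channel-column)
ad_spmm <- function(tp, U, a) {
  va <- nv(a)
  mk(tp, as.matrix(U %*% va), list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], as.matrix(Matrix::crossprod(U, g)))
  })
}

ad_softmax_rows <- function(tp, a) {
  va <- nv(a)
  m <- va - va[cbind(seq_len(nrow(va)), max.col(va, ties.method = "first"))]
  e <- exp(m)
  s <- e / rowSums(e)
  mk(tp, s, list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], s * (g - rowSums(g * s)))
  })
}

## ---- normalisation ---------------------------------------------------------

# Layer norm across columns of each row, with per-column affine params.
ad_layernorm <- function(tp, a, gamma, beta, eps = 1e-5) {
  x <- nv(a)
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- xc * istd
  gv <- nv(gamma)
  out <- addc(mulc(xh, gv), nv(beta))
  mk(tp, out, list(a, gamma, beta), function(g, nd) {
    dxh <- mulc(g, gv)
    dx <- istd * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
    acc_grad(nd$parents[[1]], dx)
    acc_grad(nd$parents[[2]], colSums(g * xh))
    acc_grad(nd$parents[[3]], colSums(g))
  })
}

# Batch norm across rows of each column.  `state` is an environment holding
# running_mean / running_var.  `training` is TRUE (batch statistics, running
# stats updated with momentum 0.1), "batch" (batch statistics, no update;
# deterministic per-sample inference), or FALSE (running statistics).
ad_batchnorm <- function(tp, a, gamma, beta, state, training = TRUE, eps = 1e-5) {
  x <- nv(a)
  N <- nrow(x)
  gv <- nv(gamma)
  if (isTRUE(training) || identical(training, "batch")) {
    mu <- colMeans(x)
    xc <- addc(x, -mu)
    va <- colMeans(xc * xc)
    if (isTRUE(training)) {
      state$running_mean <- 0.9 * state$running_mean + 0.1 * mu
      state$running_var <- 0.9 * state$running_var + 0.1 * va * N / max(N - 1L, 1L)
    }
    istd <- 1 / sqrt(va + eps)
    xh <- mulc(xc, istd)
    out <- addc(mulc(xh, gv), nv(beta))
    mk(tp, out, list(a, gamma, beta), function(g, nd) {
      dxh <- mulc(g, gv)
      m1 <- colMeans(dxh)
      m2 <- colMeans(dxh * xh)
      dx <- mulc(addc(dxh - mulc(xh, m2), -m1), istd)
      acc_grad(nd$parents[[1]], dx)
      acc_grad(nd$parents[[2]], colSums(g * xh))
      acc_grad(nd$parents[[3]], colSums(g))
    })
  } else {
    istd <- 1 / sqrt(state$running_var + eps)
    xh <- mulc(addc(x, -state$running_mean), istd)
    out <- addc(mulc(xh, gv), nv(beta))
    mk(tp, out, list(a, gamma, beta), function(g, nd) {
      acc_grad(nd$parents[[1]], mulc(g, gv * istd))
      acc_grad(nd$parents[[2]], colSums(g * xh))
      acc_grad(nd$parents[[3]], colSums(g))
    })
  }
}

## ---- pooling ---------------------------------------------------------------

# global pooling over rows (spatial positions), returning a 1 x C matrix
ad_pool_avg <- function(tp, a) {
  va <- nv(a)
  N <- nrow(va)
  mk(tp, matrix(colMeans(va), 1L), list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], matrix(rep(g / N, each = N), N))
  })
}

ad_pool_max <- function(tp, a) {
  va <- nv(a)
  widx <- max.col(t(va), ties.method = "first")
  v <- va[cbind(widx, seq_len(ncol(va)))]
  mk(tp, matrix(v, 1L), list(a), function(g, nd) {
    Z <- matrix(0, nrow(va), ncol(va))
    Z[cbind(widx, seq_len(ncol(va)))] <- g
    acc_grad(nd$parents[[1]], Z)
  })
}

# per-row (per-pixel) mean / max across channels, returning N x 1
ad_rowmean <- function(tp, a) {
  va <- nv(a)
  C <- ncol(va)
  mk(tp, matrix(rowMeans(va), ncol = 1L), list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], matrix(g / C, nrow(va), C))
  })
}

ad_rowmax <- function(tp, a) {
  va <- nv(a)
  jidx <- max.col(va, ties.method = "first")
  mk(tp, matrix(va[cbind(seq_len(nrow(va)), jidx)], ncol = 1L), list(a),
     function(g, nd) {
       Z <- matrix(0, nrow(va), ncol(va))
       Z[cbind(seq_len(nrow(va)), jidx)] <- g
       acc_grad(nd$parents[[1]], Z)
     })
}

## ---- convolution -----------------------------------------------------------

# Precompute the im2col index map for an H x W plane and k x k kernel with
# symmetric zero padding: an (H*W) x k^2 matrix of indices into the input
# vector augmented with a trailing zero entry at position H*W + 1.
conv_index_map <- function(H, W, k) {
  pad <- (k - 1L) %/% 2L
  ij <- expand.grid(i = seq_len(H), j = seq_len(W))      # row-fastest: matches p=(j-1)*H+i
  offs <- expand.grid(di = seq_len(k) - 1L - pad, dj = seq_len(k) - 1L - pad)
  M <- matrix(H * W + 1L, H * W, k * k)
  for (q in seq_len(k * k)) {
    ii <- ij$i + offs$di[q]
    jj <- ij$j + offs$dj[q]
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    M[ok, q] <- (jj[ok] - 1L) * H + ii[ok]
  }
  M
}

# x: (H*W) x Cin, weight: (Cin*k^2) x Cout with layout [(c-1)*k^2 + q, cout],
# bias: length Cout.  idx_map from conv_index_map (cached by the layer).
ad_conv2d <- function(tp, a, weight, bias, idx_map) {
  x <- nv(a)
  Cin <- ncol(x)
  Xcol <- im2col_gather(x, idx_map)                  # HW x (K*Cin), col (c-1)*K + q
  Wv <- nv(weight)
  out <- addc(Xcol %*% Wv, nv(bias))
  mk(tp, out, list(a, weight, bias), function(g, nd) {
    acc_grad(nd$parents[[2]], crossprod(Xcol, g))
    acc_grad(nd$parents[[3]], colSums(g))
    acc_grad(nd$parents[[1]], col2im_scatter(tcrossprod(g, Wv), idx_map, Cin))
  })
}

## ---- windowed attention application ---------------------------------------

# Given row-softmaxed attention scores A ((nW*Nw) x Nw, rows grouped by
# window) and values V in the same window-grouped row order ((nW*Nw) x dv),
# compute out[(w,i), ] = sum_j A[(w,i), j] * V[(w,j), ].
ad_window_apply <- function(tp, A, V, Nw) {
  Av <- nv(A); Vv <- nv(V)
  mk(tp, win_apply_fw(Av, Vv, Nw), list(A, V), function(g, nd) {
    bw <- win_apply_bw(g, Av, Vv, Nw)
    acc_grad(nd$parents[[1]], bw$dA)
    acc_grad(nd$parents[[2]], bw$dV)
  })
}

## ---- resampling matrices ---------------------------------------------------

# Sparse matrix performing x2 bilinear up-sampling (half-pixel centers,
# edge-clamped) on an H x W plane vectorised column-major.
upsample2_matrix <- function(H, W) {
  Ho <- 2L * H; Wo <- 2L * W
  src <- function(n_out, n_in) {
    pos <- ((seq_len(n_out) - 0.5) / 2) - 0.5   # input coordinate, 0-based
    lo <- floor(pos)
    w_hi <- pos - lo
    lo0 <- pmin(pmax(lo, 0), n_in - 1L)
    hi0 <- pmin(pmax(lo + 1L, 0), n_in - 1L)
    list(lo = lo0 + 1L, hi = hi0 + 1L, w = w_hi)
  }
  sy <- src(Ho, H); sx <- src(Wo, W)
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  rows <- (jo - 1L) * Ho + io
  triplets <- list()
  for (cy in 1:2) for (cx in 1:2) {
    ii <- if (cy == 1) sy$lo[io] else sy$hi[io]
    jj <- if (cx == 1) sx$lo[jo] else sx$hi[jo]
    wy <- if (cy == 1) 1 - sy$w[io] else sy$w[io]
    wx <- if (cx == 1) 1 - sx$w[jo] else sx$w[jo]
    triplets[[length(triplets) + 1L]] <-
      data.frame(i = rows, j = (jj - 1L) * H + ii, x = wy * wx)
  }
  tr <- do.call(rbind, triplets)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(Ho * Wo, H * W))
}

# Sparse matrix averaging f x f blocks (area pooling) of an H x W plane.
downsample_area_matrix <- function(H, W, f) {
  stopifnot(H %% f == 0L, W %% f == 0L)
  Ho <- H %/% f; Wo <- W %/% f
  i_in <- rep(seq_len(H), times = W)
  j_in <- rep(seq_len(W), each = H)
  rows_out <- ((ceiling(j_in / f) - 1L) * Ho) + ceiling(i_in / f)
  Matrix::sparseMatrix(i = rows_out, j = (j_in - 1L) * H + i_in,
                       x = rep(1 / (f * f), H * W), dims = c(Ho * Wo, H * W))
}

## ---- extra structural ops --------------------------------------------------

# (N*g) x C -> N x (g*C): out[t, (c-1)*g + q] = in[(t-1)*g + q, c]
ad_fold_rows <- function(tp, a, g) {
  va <- nv(a)
  N <- nrow(va) %/% g
  C <- ncol(va)
  v <- va
  dim(v) <- c(g, N, C)
  v <- aperm(v, c(2, 1, 3))
  dim(v) <- c(N, g * C)
  mk(tp, v, list(a), function(gr, nd) {
    dim(gr) <- c(N, g, C)
    gr <- aperm(gr, c(2, 1, 3))
    dim(gr) <- c(N * g, C)
    acc_grad(nd$parents[[1]], gr)
  })
}

# multiply every row of x (N x C) by the matching entry of a column node w (N x 1)
ad_rowscale <- function(tp, x, w) {
  xv <- nv(x); wv <- as.vector(nv(w))
  mk(tp, xv * wv, list(x, w), function(g, nd) {
    acc_grad(nd$parents[[1]], g * wv)
    acc_grad(nd$parents[[2]], matrix(rowSums(g * xv), ncol = 1L))
  })
}

# multiply every column of x (N x C) by the matching entry of a row node w (1 x C)
ad_colscale <- function(tp, x, w) {
  xv <- nv(x); wv <- as.vector(nv(w))
  mk(tp, mulc(xv, wv), list(x, w), function(g, nd) {
    acc_grad(nd$parents[[1]], mulc(g, wv))
    acc_grad(nd$parents[[2]], matrix(colSums(g * xv), 1L))
  })
}

## ---- segment (per-sample) pooling for batched maps -------------------------

# x is (B*L) x C with B contiguous equal segments; per-segment column means
ad_seg_pool_avg <- function(tp, a, B) {
  va <- nv(a)
  L <- nrow(va) %/% B
  seg <- rep(seq_len(B), each = L)
  v <- rowsum(va, seg) / L
  dimnames(v) <- NULL
  mk(tp, v, list(a), function(g, nd) {
    acc_grad(nd$parents[[1]], g[seg, , drop = FALSE] / L)
  })
}

# per-segment column maxima (first index on ties)
ad_seg_pool_max <- function(tp, a, B) {
  va <- nv(a)
  n <- nrow(va); C <- ncol(va)
  L <- n %/% B
  out <- matrix(0, B, C)
  widx <- matrix(0L, B, C)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * L + seq_len(L)
    block <- va[rows, , drop = FALSE]
    jj <- max.col(t(block), ties.method = "first")
    widx[b, ] <- (b - 1L) * L + jj
    out[b, ] <- block[cbind(jj, seq_len(C))]
  }
  mk(tp, out, list(a), function(g, nd) {
    Z <- matrix(0, n, C)
    for (b in seq_len(B)) {
      Z[cbind(widx[b, ], seq_len(C))] <- Z[cbind(widx[b, ], seq_len(C))] + g[b, ]
    }
    acc_grad(nd$parents[[1]], Z)
  })
}

# multiply each segment's rows by that segment's row of w (B x C node)
ad_seg_colscale <- function(tp, x, w, B) {
  xv <- nv(x); wv <- nv(w)
  L <- nrow(xv) %/% B
  seg <- rep(seq_len(B), each = L)
  val <- xv * wv[seg, , drop = FALSE]
  dimnames(val) <- NULL
  mk(tp, val, list(x, w), function(g, nd) {
    acc_grad(nd$parents[[1]], g * wv[seg, , drop = FALSE])
    gw <- rowsum(g * xv, seg)
    dimnames(gw) <- NULL
    acc_grad(nd$parents[[2]], gw)
  })
}
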