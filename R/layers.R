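# Parameter containers and reusable layers built on the autodiff ops.

new_param <- function(val, name = NULL) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$name <- name
  class(p) <- "prt_param"
  p
}

n_elements <- function(p) length(p$val)

# Xavier-uniform initialisation for a fan_in x fan_out matrix
init_xavier <- function(fan_in, fan_out, rng_sd = NULL) {
  b <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out)
}

init_normal <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

pn <- function(tp, p) ad_leaf(tp, p)

## Linear ---------------------------------------------------------------------

layer_linear <- function(fan_in, fan_out, name = "lin", w_sd = NULL) {
  W <- if (is.null(w_sd)) init_xavier(fan_in, fan_out) else init_normal(fan_in, fan_out, w_sd)
  ly <- list(
    W = new_param(W, paste0(name, ".W")),
    b = new_param(rep(0, fan_out), paste0(name, ".b"))
  )
  ly$params <- list(W = ly$W, b = ly$b)
  ly$forward <- function(tp, x) ad_add_bias(tp, ad_mm(tp, x, pn(tp, ly$W)), pn(tp, ly$b))
  ly
}

## Layer norm -----------------------------------------------------------------

layer_ln <- function(C, name = "ln") {
  ly <- list(
    g = new_param(rep(1, C), paste0(name, ".g")),
    b = new_param(rep(0, C), paste0(name, ".b"))
  )
  ly$params <- list(g = ly$g, b = ly$b)
  ly$forward <- function(tp, x) ad_layernorm(tp, x, pn(tp, ly$g), pn(tp, ly$b))
  ly
}

## Batch norm -----------------------------------------------------------------

layer_bn <- function(C, name = "bn") {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  ly <- list(
    g = new_param(rep(1, C), paste0(name, ".g")),
    b = new_param(rep(0, C), paste0(name, ".b")),
    state = st
  )
  ly$params <- list(g = ly$g, b = ly$b)
  ly$forward <- function(tp, x, training = TRUE) {
    ad_batchnorm(tp, x, pn(tp, ly$g), pn(tp, ly$b), st, training = training)
  }
  ly
}

## Conv 2d --------------------------------------------------------------------

layer_conv2d <- function(Cin, Cout, k, H, W, name = "conv", w_sd = NULL) {
  fan_in <- Cin * k * k
  Wm <- if (is.null(w_sd)) init_xavier(fan_in, Cout) else init_normal(fan_in, Cout, w_sd)
  cache <- new.env(parent = emptyenv())
  ly <- list(
    W = new_param(Wm, paste0(name, ".W")),
    b = new_param(rep(0, Cout), paste0(name, ".b")),
    idx = conv_index_map(H, W, k),
    cache = cache
  )
  ly$params <- list(W = ly$W, b = ly$b)
  ly$forward <- function(tp, x, B = 1L) {
    ly_idx <- if (B == 1L) ly$idx else {
      key <- as.character(B)
      if (is.null(cache[[key]])) cache[[key]] <- batch_conv_idx(ly$idx, B)
      cache[[key]]
    }
    ad_conv2d(tp, x, pn(tp, ly$W), pn(tp, ly$b), ly_idx)
  }
  ly
}

# replicate an im2col index map for B stacked images: per-image indices are
# offset by (b-1)*HW; the zero-pad marker HW+1 maps to B*HW+1
batch_conv_idx <- function(idx, B) {
  HW <- nrow(idx)
  out <- matrix(0L, HW * B, ncol(idx))
  pad <- idx == HW + 1L
  for (b in seq_len(B)) {
    block <- idx + (b - 1L) * HW
    block[pad] <- B * HW + 1L
    out[(b - 1L) * HW + seq_len(HW), ] <- block
  }
  out
}

## Two-layer perceptron (used in transformer blocks and channel attention) ----

layer_mlp <- function(C, hidden, Cout = C, name = "mlp", act = ad_mish) {
  l1 <- layer_linear(C, hidden, paste0(name, ".fc1"))
  l2 <- layer_linear(hidden, Cout, paste0(name, ".fc2"))
  ly <- list(l1 = l1, l2 = l2)
  ly$params <- c(prefix_params(l1$params, "fc1"), prefix_params(l2$params, "fc2"))
  ly$forward <- function(tp, x) l2$forward(tp, act(tp, l1$forward(tp, x)))
  ly
}

prefix_params <- function(ps, pre) {
  names(ps) <- paste(pre, names(ps), sep = ".")
  ps
}

## Cached resampling matrices -------------------------------------------------

.resample_cache <- new.env(parent = emptyenv())

get_upsample2 <- function(H, W, B = 1L) {
  key <- paste0("u", H, "x", W, "b", B)
  if (is.null(.resample_cache[[key]])) {
    U <- if (B == 1L) upsample2_matrix(H, W) else {
      Matrix::bdiag(rep(list(get_upsample2(H, W)), B))
    }
    .resample_cache[[key]] <- methods::as(U, "CsparseMatrix")
  }
  .resample_cache[[key]]
}

get_downsample <- function(H, W, f) {
  key <- paste0("d", H, "x", W, "f", f)
  if (is.null(.resample_cache[[key]])) .resample_cache[[key]] <- downsample_area_matrix(H, W, f)
  .resample_cache[[key]]
}

# Plain-numeric resampling helpers (no gradient), operating on H x W matrices.
upsample2_plane <- function(m) {
  H <- nrow(m); W <- ncol(m)
  matrix(as.matrix(get_upsample2(H, W) %*% as.vector(m)), 2L * H, 2L * W)
}

downsample_plane <- function(m, f) {
  if (f == 1L) return(m)
  H <- nrow(m); W <- ncol(m)
  matrix(as.matrix(get_downsample(H, W, f) %*% as.vector(m)), H %/% f, W %/% f)
}
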