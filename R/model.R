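# The progressive-refinement windowed-attention dose-prediction network.
#
# Architecture: a full-resolution convolutional stem, four encoder stages
# (patch embedding / patch merging -> constant-window attention block ->
# shifted-window attention block -> convolutional block attention), a
# four-stage convolutional decoder with skip connections, and four
# prediction branches emitting dose maps at n/8, n/4, n/2 and n that are
# refined coarse-to-fine by upsample-and-add.
#
# The attention is the "enhanced" variant: per head, scores are
# S = tanh(Q + K) %*% W_alpha / sqrt(dk), an Nw x Nw matrix per window, with
# a learnable W_alpha in R^{dk x Nw}; rows are softmax-normalised and applied
# to V, and head outputs are concatenated.

#' Model configuration
#'
#' @param grid_size Input side length n (divisible by 8 * patch_size *
#'   window_side / 8; default 64 for desk-scale work, 512 at clinical scale).
#' @param in_channels Input channels (33 = 3 slices x 11 maps).
#' @param patch_size Pixel side P of a patch token (default 2).
#' @param embed_dim Embedding dimension Ce of stage 1; doubles per stage.
#' @param heads Attention heads h; `embed_dim` must be divisible by `heads`.
#' @param window_side Token side of an attention window (Nw = window_side^2).
#' @param mlp_ratio Hidden-width multiplier of the transformer MLPs.
#' @param decoder_channels Four decoder widths, coarse to fine; the clinical
#'   scale uses (512, 256, 128, 64), the default test scale (64, 32, 16, 8).
#' @param cbam_reduction Channel reduction of the channel-attention MLP.
#' @return A `prt_model_config` list.
#' @export
prt_model_config <- function(grid_size = 64L, in_channels = 33L, patch_size = 2L,
                             embed_dim = 32L, heads = 4L, window_side = 4L,
                             mlp_ratio = 2, decoder_channels = c(64L, 32L, 16L, 8L),
                             cbam_reduction = 4L) {
  stopifnot(embed_dim %% heads == 0L, length(decoder_channels) == 4L,
            grid_size %% (8L * patch_size) == 0L,
            (grid_size / patch_size / 8L) %% 1 == 0)
  side1 <- grid_size %/% patch_size
  stopifnot(side1 %% window_side == 0L, (side1 %/% 8L) >= 1L)
  structure(list(grid_size = as.integer(grid_size), in_channels = as.integer(in_channels),
                 patch_size = as.integer(patch_size), embed_dim = as.integer(embed_dim),
                 heads = as.integer(heads), window_side = as.integer(window_side),
                 mlp_ratio = mlp_ratio, decoder_channels = as.integer(decoder_channels),
                 cbam_reduction = as.integer(cbam_reduction)),
            class = "prt_model_config")
}

## ---- window geometry -------------------------------------------------------

# Gather/scatter indices (and the cross-region attention mask for shifted
# partitions) that reorder a side x side token grid, vectorised column-major,
# into window-grouped row order.
window_geom <- function(side, w, shift) {
  N <- side * side
  t_r <- rep(seq_len(side), times = side)
  t_c <- rep(seq_len(side), each = side)
  if (shift > 0L) {
    sr <- ((t_r - 1L + shift) %% side) + 1L
    sc <- ((t_c - 1L + shift) %% side) + 1L
    src <- (sc - 1L) * side + sr
  } else {
    src <- seq_len(N)
  }
  wid <- (ceiling(t_c / w) - 1L) * (side %/% w) + ceiling(t_r / w)
  win <- ((t_c - 1L) %% w) * w + ((t_r - 1L) %% w) + 1L
  perm_frame <- order(wid, win)
  idx <- src[perm_frame]          # gather: grouped_row -> original token row
  inv <- order(idx)               # scatter back
  Nw <- w * w
  mask <- NULL
  if (shift > 0L && w < side) {
    grp <- function(p) ifelse(p <= side - w, 0L, ifelse(p <= side - shift, 1L, 2L))
    region <- 3L * grp(t_r) + grp(t_c)
    reg_g <- region[perm_frame]
    base <- (ceiling(seq_len(N) / Nw) - 1L) * Nw
    mask <- matrix(0, N, Nw)
    for (j in seq_len(Nw)) {
      mask[, j] <- ifelse(reg_g == reg_g[base + j], 0, -1e9)
    }
  }
  list(idx = idx, inv = inv, Nw = Nw, win = win, mask = mask)
}

# offset a per-sample permutation/index vector to B stacked samples
batch_offsets <- function(idx, N, B) {
  if (B == 1L) return(idx)
  unlist(lapply(seq_len(B), function(b) idx + (b - 1L) * as.integer(N)),
         use.names = FALSE)
}

# pixel gather index turning an H x H plane into patch-grouped rows
# (P^2 consecutive rows per token, column-major within the patch)
patch_index <- function(side, P) {
  hs <- side %/% P
  N <- hs * hs
  idx <- integer(N * P * P)
  q_pr <- rep(seq_len(P), times = P)
  q_pc <- rep(seq_len(P), each = P)
  for (t in seq_len(N)) {
    tr <- ((t - 1L) %% hs) + 1L
    tc <- ((t - 1L) %/% hs) + 1L
    i <- (tr - 1L) * P + q_pr
    j <- (tc - 1L) * P + q_pc
    idx[(t - 1L) * P * P + seq_len(P * P)] <- (j - 1L) * side + i
  }
  idx
}

## ---- layers specific to the network ---------------------------------------

layer_emsa <- function(Ce, heads, Nw, name) {
  dk <- Ce %/% heads
  hp <- lapply(seq_len(heads), function(h) list(
    Wq = new_param(init_xavier(Ce, dk), paste0(name, ".h", h, ".Wq")),
    Wk = new_param(init_xavier(Ce, dk), paste0(name, ".h", h, ".Wk")),
    Wv = new_param(init_xavier(Ce, dk), paste0(name, ".h", h, ".Wv")),
    Wa = new_param(init_xavier(dk, Nw), paste0(name, ".h", h, ".Wa"))
  ))
  params <- list()
  for (h in seq_len(heads)) {
    params <- c(params, prefix_params(hp[[h]], paste0("h", h)))
  }
  ly <- list(heads = hp, params = params, dk = dk, Nw = Nw)
  # xg: window-grouped token rows; mask: optional (N x Nw) additive constant
  ly$forward <- function(tp, xg, mask = NULL) {
    outs <- lapply(hp, function(hh) {
      Q <- ad_mm(tp, xg, pn(tp, hh$Wq))
      K <- ad_mm(tp, xg, pn(tp, hh$Wk))
      V <- ad_mm(tp, xg, pn(tp, hh$Wv))
      S <- ad_scale(tp, ad_mm(tp, ad_tanh(tp, ad_add(tp, Q, K)), pn(tp, hh$Wa)),
                    1 / sqrt(dk))
      if (!is.null(mask)) S <- ad_add(tp, S, mask)
      A <- ad_softmax_rows(tp, S)
      ad_window_apply(tp, A, V, Nw)
    })
    ad_cbind(tp, outs)
  }
  ly
}

layer_swin_block <- function(Ce, heads, geom, mlp_ratio, name) {
  ln1 <- layer_ln(Ce, paste0(name, ".ln1"))
  ln2 <- layer_ln(Ce, paste0(name, ".ln2"))
  attn <- layer_emsa(Ce, heads, geom$Nw, paste0(name, ".attn"))
  mlp <- layer_mlp(Ce, max(4L, round(Ce * mlp_ratio)), Ce, paste0(name, ".mlp"))
  params <- c(prefix_params(ln1$params, "ln1"), prefix_params(attn$params, "attn"),
              prefix_params(ln2$params, "ln2"), prefix_params(mlp$params, "mlp"))
  cache <- new.env(parent = emptyenv())
  ly <- list(params = params, ln1 = ln1, ln2 = ln2, attn = attn, mlp = mlp,
             geom = geom, cache = cache)
  ly$forward <- function(tp, x, training = TRUE, B = 1L) {
    key <- as.character(B)
    if (is.null(cache[[key]])) {
      N <- length(geom$idx)
      cache[[key]] <- list(
        idx = batch_offsets(geom$idx, N, B),
        inv = batch_offsets(geom$inv, N, B),
        mask = if (is.null(geom$mask)) NULL else {
          do.call(rbind, rep(list(geom$mask), B))
        })
    }
    bg <- cache[[key]]
    xg <- ad_gather_rows(tp, ln1$forward(tp, x), bg$idx)
    a <- attn$forward(tp, xg, bg$mask)
    x1 <- ad_add(tp, x, ad_gather_rows(tp, a, bg$inv))
    ad_add(tp, x1, mlp$forward(tp, ln2$forward(tp, x1)))
  }
  ly
}

layer_cbam <- function(C, side, reduction, name) {
  hidden <- max(2L, C %/% reduction)
  fc1 <- layer_linear(C, hidden, paste0(name, ".fc1"))
  fc2 <- layer_linear(hidden, C, paste0(name, ".fc2"))
  conv7 <- layer_conv2d(2L, 1L, 7L, side, side, paste0(name, ".conv7"))
  params <- c(prefix_params(fc1$params, "fc1"), prefix_params(fc2$params, "fc2"),
              prefix_params(conv7$params, "conv7"))
  shared_mlp <- function(tp, z) fc2$forward(tp, ad_relu(tp, fc1$forward(tp, z)))
  ly <- list(params = params, fc1 = fc1, fc2 = fc2, conv7 = conv7)
  ly$forward <- function(tp, x, training = TRUE, B = 1L) {
    mc <- ad_sigmoid(tp, ad_add(tp, shared_mlp(tp, ad_seg_pool_avg(tp, x, B)),
                                shared_mlp(tp, ad_seg_pool_max(tp, x, B))))
    xc <- ad_seg_colscale(tp, x, mc, B)
    sm <- ad_cbind(tp, list(ad_rowmean(tp, xc), ad_rowmax(tp, xc)))
    ms <- ad_sigmoid(tp, conv7$forward(tp, sm, B))
    xs <- ad_rowscale(tp, xc, ms)
    ad_add(tp, x, xs)
  }
  ly
}

layer_decoder_stage <- function(Cin, Cskip, Cout, side_in, name) {
  so <- 2L * side_in
  conv1 <- layer_conv2d(Cin + Cskip, Cout, 3L, so, so, paste0(name, ".conv1"))
  bn1 <- layer_bn(Cout, paste0(name, ".bn1"))
  conv2 <- layer_conv2d(Cout, Cout, 3L, so, so, paste0(name, ".conv2"))
  bn2 <- layer_bn(Cout, paste0(name, ".bn2"))
  params <- c(prefix_params(conv1$params, "conv1"), prefix_params(bn1$params, "bn1"),
              prefix_params(conv2$params, "conv2"), prefix_params(bn2$params, "bn2"))
  ly <- list(params = params, bn_states = list(bn1 = bn1$state, bn2 = bn2$state))
  ly$forward <- function(tp, x, skip, training = TRUE, B = 1L) {
    up <- ad_spmm(tp, get_upsample2(side_in, side_in, B), x)
    h <- ad_cbind(tp, list(up, skip))
    h <- ad_mish(tp, bn1$forward(tp, conv1$forward(tp, h, B), training))
    ad_mish(tp, bn2$forward(tp, conv2$forward(tp, h, B), training))
  }
  ly
}

# generation module G: two conv-BN-Mish blocks then a 1-channel 3x3 conv
layer_head <- function(C, side, name) {
  conv1 <- layer_conv2d(C, C, 3L, side, side, paste0(name, ".conv1"))
  bn1 <- layer_bn(C, paste0(name, ".bn1"))
  conv2 <- layer_conv2d(C, C, 3L, side, side, paste0(name, ".conv2"))
  bn2 <- layer_bn(C, paste0(name, ".bn2"))
  conv3 <- layer_conv2d(C, 1L, 3L, side, side, paste0(name, ".conv3"), w_sd = 0.01)
  params <- c(prefix_params(conv1$params, "conv1"), prefix_params(bn1$params, "bn1"),
              prefix_params(conv2$params, "conv2"), prefix_params(bn2$params, "bn2"),
              prefix_params(conv3$params, "conv3"))
  ly <- list(params = params, bn_states = list(bn1 = bn1$state, bn2 = bn2$state))
  ly$forward <- function(tp, x, training = TRUE, B = 1L) {
    h <- ad_mish(tp, bn1$forward(tp, conv1$forward(tp, x, B), training))
    h <- ad_mish(tp, bn2$forward(tp, conv2$forward(tp, h, B), training))
    conv3$forward(tp, h, B)
  }
  ly
}

## ---- model construction ----------------------------------------------------

#' Construct the dose-prediction network
#'
#' Builds all layers and initialises weights reproducibly from `seed`.
#'
#' @param config A [prt_model_config()].
#' @param seed Integer initialisation seed.
#' @return A `prt_net` object; pass it to [prt_forward()],
#'   [train_model()] or [predict_volume()].
#' @export
prt_net <- function(config = prt_model_config(), seed = 1L) {
  set.seed(seed)
  n <- config$grid_size; P <- config$patch_size
  w <- config$window_side
  sides <- (n %/% P) %/% c(1L, 2L, 4L, 8L)
  dims <- config$embed_dim * c(1L, 2L, 4L, 8L)
  dc <- config$decoder_channels
  params <- list()
  add_params <- function(ps, pre) {
    params[[length(params) + 1L]] <<- prefix_params(ps, pre)
  }

  stem <- layer_conv2d(config$in_channels, dc[4], 3L, n, n, "stem")
  add_params(stem$params, "stem")

  embed_idx <- patch_index(n, P)
  embed <- layer_linear(P * P * config$in_channels, config$embed_dim, "embed")
  add_params(embed$params, "embed")
  geom0 <- window_geom(sides[1], w, 0L)
  pos <- new_param(init_normal(geom0$Nw, config$embed_dim, 0.02), "pos")
  add_params(list(table = pos), "pos")

  merges <- list(NULL)
  stages <- vector("list", 4L)
  for (s in 1:4) {
    side <- sides[s]
    shift <- if (side > w) w %/% 2L else 0L
    gW <- window_geom(side, min(w, side), 0L)
    gS <- window_geom(side, min(w, side), shift)
    if (s > 1) {
      mg <- list(idx = patch_index(sides[s - 1], 2L),
                 lin = layer_linear(4L * dims[s - 1], dims[s], paste0("merge", s)))
      add_params(mg$lin$params, paste0("merge", s))
      merges[[s]] <- mg
    }
    wmsa <- layer_swin_block(dims[s], config$heads, gW, config$mlp_ratio,
                             paste0("enc", s, ".wmsa"))
    swmsa <- layer_swin_block(dims[s], config$heads, gS, config$mlp_ratio,
                              paste0("enc", s, ".swmsa"))
    cbam <- layer_cbam(dims[s], side, config$cbam_reduction, paste0("enc", s, ".cbam"))
    add_params(wmsa$params, paste0("enc", s, ".wmsa"))
    add_params(swmsa$params, paste0("enc", s, ".swmsa"))
    add_params(cbam$params, paste0("enc", s, ".cbam"))
    stages[[s]] <- list(wmsa = wmsa, swmsa = swmsa, cbam = cbam, side = side)
  }

  dec_in <- c(dims[4], dc[1], dc[2], dc[3])
  dec_skip <- c(dims[3], dims[2], dims[1], dc[4])
  dec_sides <- c(sides[4], sides[3], sides[2], sides[1])
  decoders <- vector("list", 4L)
  bn_states <- list()
  for (i in 1:4) {
    dcd <- layer_decoder_stage(dec_in[i], dec_skip[i], dc[i], dec_sides[i],
                               paste0("dec", i))
    add_params(dcd$params, paste0("dec", i))
    bn_states <- c(bn_states, prefix_params(dcd$bn_states, paste0("dec", i)))
    decoders[[i]] <- dcd
  }

  head_sides <- 2L * dec_sides
  heads_G <- vector("list", 4L)
  for (i in 1:4) {
    hd <- layer_head(dc[i], head_sides[i], paste0("head", i))
    add_params(hd$params, paste0("head", i))
    bn_states <- c(bn_states, prefix_params(hd$bn_states, paste0("head", i)))
    heads_G[[i]] <- hd
  }

  flat <- do.call(c, params)
  model <- list(config = config, stem = stem, embed = embed, embed_idx = embed_idx,
                pos = pos, pos_win = geom0$win, merges = merges, stages = stages,
                decoders = decoders, heads_G = heads_G, sides = sides, dims = dims,
                head_sides = head_sides, params = flat, bn_states = bn_states)
  class(model) <- "prt_net"
  model
}

#' Named parameter registry
#'
#' @param model A [prt_net()].
#' @return Named list of parameter environments (`$val`, `$grad`).
#' @export
prt_params <- function(model) model$params

#' Total number of learnable scalars
#' @param model A [prt_net()].
#' @return Integer parameter count.
#' @export
prt_n_params <- function(model) sum(vapply(model$params, n_elements, 1L))

## ---- forward pass ----------------------------------------------------------

# internal: xmat is (n^2 x in_channels); returns list of 4 ad nodes, each a
# (side_i^2 x 1) column of the prediction pyramid, plus encoder skips
model_forward <- function(tp, model, xmat, training = TRUE, B = 1L) {
  cfg <- model$config
  P <- cfg$patch_size
  n2 <- cfg$grid_size^2

  stem_out <- ad_mish(tp, model$stem$forward(tp, xmat, B))

  eidx <- batch_offsets(model$embed_idx, n2, B)
  xp <- ad_fold_rows(tp, ad_gather_rows(tp, xmat, eidx), P * P)
  tok <- model$embed$forward(tp, xp)
  pos_full <- ad_gather_rows(tp, pn(tp, model$pos), rep(model$pos_win, B))
  tok <- ad_add(tp, tok, pos_full)

  skips <- vector("list", 4L)
  for (s in 1:4) {
    if (s > 1) {
      mg <- model$merges[[s]]
      midx <- batch_offsets(mg$idx, model$sides[s - 1L]^2, B)
      tok <- mg$lin$forward(tp, ad_fold_rows(tp, ad_gather_rows(tp, tok, midx), 4L))
    }
    tok <- model$stages[[s]]$wmsa$forward(tp, tok, training, B)
    tok <- model$stages[[s]]$swmsa$forward(tp, tok, training, B)
    tok <- model$stages[[s]]$cbam$forward(tp, tok, training, B)
    skips[[s]] <- tok
  }

  h <- skips[[4]]
  dec_skips <- list(skips[[3]], skips[[2]], skips[[1]], stem_out)
  phis <- vector("list", 4L)
  pyr <- vector("list", 4L)
  for (i in 1:4) {
    h <- model$decoders[[i]]$forward(tp, h, dec_skips[[i]], training, B)
    phis[[i]] <- model$heads_G[[i]]$forward(tp, h, training, B)
    if (i == 1L) {
      pyr[[i]] <- phis[[i]]
    } else {
      side_prev <- model$head_sides[i - 1L]
      U <- get_upsample2(side_prev, side_prev, B)
      pyr[[i]] <- ad_add(tp, phis[[i]], ad_spmm(tp, U, pyr[[i - 1L]]))
    }
  }
  list(pyramid = pyr, phis = phis, skips = skips)
}

#' Run the network on one sample
#'
#' @param model A [prt_net()].
#' @param input Either a `triplet_sample` or a (33, n, n) input array.
#' @param training Normalisation-statistics mode: TRUE trains (batch
#'   statistics, running averages updated), `"batch"` uses per-sample batch
#'   statistics without updating (deterministic inference consistent with
#'   how the per-slice graphs are optimised), FALSE uses running statistics.
#' @return A `prediction_pyramid`: list of four matrices at sides n/8, n/4,
#'   n/2, n (coarse to fine).
#' @export
prt_forward <- function(model, input, training = FALSE) {
  x <- if (inherits(input, "triplet_sample")) input$input else input
  n <- model$config$grid_size
  stopifnot(dim(x)[1] == model$config$in_channels, dim(x)[2] == n, dim(x)[3] == n)
  xmat <- t(matrix(x, nrow = dim(x)[1]))
  tp <- new_tape()
  out <- model_forward(tp, model, xmat, training = training)
  pyr <- lapply(seq_len(4L), function(i) {
    side <- model$head_sides[i]
    matrix(nv(out$pyramid[[i]]), side, side)
  })
  class(pyr) <- "prediction_pyramid"
  pyr
}

#' Enhanced self-attention (reference implementation)
#'
#' Direct numeric evaluation of the per-window attention: per head,
#' `Q = x W_Q`, `K = x W_K`, `V = x W_V`,
#' `S = tanh(Q + K) W_alpha / sqrt(dk)`, `A = row-softmax(S)`, output
#' `A V`; head outputs are concatenated. Used as the oracle against the
#' network's internal path.
#'
#' @param x Nw x Ce token matrix of one window.
#' @param heads List of per-head weight lists with elements `Wq`, `Wk`,
#'   `Wv` (Ce x dk) and `Wa` (dk x Nw).
#' @return List with `output` (Nw x Ce) and `attention` (list of row-softmax
#'   matrices, one per head).
#' @export
enhanced_self_attention <- function(x, heads) {
  outs <- list(); atts <- list()
  for (h in seq_along(heads)) {
    hh <- heads[[h]]
    dk <- ncol(hh$Wq)
    stopifnot(nrow(x) == ncol(hh$Wa))
    Q <- x %*% hh$Wq; K <- x %*% hh$Wk; V <- x %*% hh$Wv
    S <- (tanh(Q + K) %*% hh$Wa) / sqrt(dk)
    E <- exp(S - apply(S, 1, max))
    A <- E / rowSums(E)
    atts[[h]] <- A
    outs[[h]] <- A %*% V
  }
  list(output = do.call(cbind, outs), attention = atts)
}

## ---- checkpointing ---------------------------------------------------------

#' Extract a checkpoint (weights + batch-norm statistics + config)
#' @param model A [prt_net()].
#' @return Serialisable list; restore with [prt_restore()].
#' @export
prt_checkpoint <- function(model) {
  list(config = model$config,
       values = lapply(model$params, function(p) p$val),
       bn = lapply(model$bn_states, function(st) {
         list(mean = st$running_mean, var = st$running_var)
       }))
}

#' Rebuild a network from a checkpoint
#' @param ckpt A list from [prt_checkpoint()].
#' @return A `prt_net` with restored weights.
#' @export
prt_restore <- function(ckpt) {
  model <- prt_net(ckpt$config, seed = 1L)
  stopifnot(identical(names(model$params), names(ckpt$values)))
  for (nm in names(ckpt$values)) model$params[[nm]]$val <- ckpt$values[[nm]]
  for (nm in names(ckpt$bn)) {
    model$bn_states[[nm]]$running_mean <- ckpt$bn[[nm]]$mean
    model$bn_states[[nm]]$running_var <- ckpt$bn[[nm]]$var
  }
  model
}

# zero every parameter in a (sub)registry -- used to audit residual identities
zero_params <- function(params) {
  for (p in params) p$val <- p$val * 0
  invisible(NULL)
}

#' Run the network on several samples in one stacked pass
#'
#' Forwards `samples` as a single batch, so batch-norm uses the joint batch
#' statistics — exactly the statistics under which a batch is optimised
#' during training. Deterministic for `training = "batch"` (the default;
#' `TRUE` additionally updates the running averages).
#'
#' @param model A [prt_net()].
#' @param samples List of `triplet_sample`s (or (33, n, n) arrays).
#' @param training Normalisation mode; see [prt_forward()].
#' @return List of `prediction_pyramid`s, one per sample.
#' @export
prt_forward_batch <- function(model, samples, training = "batch") {
  B <- length(samples)
  X <- do.call(rbind, lapply(samples, function(s) {
    x <- if (inherits(s, "triplet_sample")) s$input else s
    t(matrix(x, nrow = dim(x)[1]))
  }))
  tp <- new_tape()
  out <- model_forward(tp, model, X, training = training, B = B)
  vals <- lapply(out$pyramid, nv)
  lapply(seq_len(B), function(b) {
    pyr <- lapply(1:4, function(i) {
      side <- model$head_sides[i]
      L <- side * side
      matrix(vals[[i]][(b - 1L) * L + seq_len(L), ], side, side)
    })
    class(pyr) <- "prediction_pyramid"
    pyr
  })
}
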