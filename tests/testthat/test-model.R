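# Network contracts: attention algebra, residual identities, window
# partitions, the refinement pyramid, parameter audit, determinism.

cfg64 <- prt_model_config()
net <- prt_net(cfg64, seed = 101)

rand_input <- function(seed = 1) {
  set.seed(seed)
  array(runif(33 * 64 * 64), c(33, 64, 64))
}

test_that("attention rows are probability vectors and zero W_alpha gives uniform attention", {
  set.seed(31)
  Ce <- 8L; Nw <- 4L; h <- 2L; dk <- Ce / h
  x <- matrix(rnorm(Nw * Ce), Nw, Ce)
  heads <- lapply(1:h, function(i) list(Wq = matrix(rnorm(Ce * dk), Ce),
                                        Wk = matrix(rnorm(Ce * dk), Ce),
                                        Wv = matrix(rnorm(Ce * dk), Ce),
                                        Wa = matrix(rnorm(dk * Nw), dk)))
  res <- enhanced_self_attention(x, heads)
  for (A in res$attention) {
    expect_equal(rowSums(A), rep(1, Nw), tolerance = 1e-12)
    expect_true(all(A >= 0))
  }
  # W_alpha = 0: scores all zero, attention uniform, output = mean of V rows
  heads0 <- lapply(heads, function(hh) { hh$Wa <- hh$Wa * 0; hh })
  res0 <- enhanced_self_attention(x, heads0)
  V1 <- x %*% heads0[[1]]$Wq * 0 + x %*% heads0[[1]]$Wv
  expect_equal(res0$output[, 1:dk],
               matrix(rep(colMeans(x %*% heads[[1]]$Wv), each = Nw), Nw),
               tolerance = 1e-12)
})

test_that("a scalar hand-worked attention case evaluates exactly", {
  # Nw = 2 tokens, Ce = 1, one head, dk = 1
  x <- matrix(c(1, -2), 2, 1)
  Wq <- matrix(0.5); Wk <- matrix(-1); Wv <- matrix(2)
  Wa <- matrix(c(3, -3), 1, 2)
  # Q = (0.5, -1), K = (-1, 2), V = (2, -4); tanh(Q+K) = tanh(-0.5), tanh(1)
  # S row i = tanh(Q_i + K_i) * (3, -3) / 1
  t1 <- tanh(-0.5); t2 <- tanh(1)
  S <- rbind(c(3 * t1, -3 * t1), c(3 * t2, -3 * t2))
  A <- exp(S) / rowSums(exp(S))
  expected <- A %*% c(2, -4)
  res <- enhanced_self_attention(x, list(list(Wq = Wq, Wk = Wk, Wv = Wv, Wa = Wa)))
  expect_equal(as.vector(res$output), as.vector(expected), tolerance = 1e-12)
})

test_that("the network's attention path matches the reference implementation", {
  set.seed(41)
  Ce <- 8L; h <- 2L
  ly <- prtdose:::layer_emsa(Ce, h, 4L, "t")
  x <- matrix(rnorm(8 * Ce), 8, Ce)   # two windows of Nw = 4
  tp <- prtdose:::new_tape()
  out <- prtdose:::nv(ly$forward(tp, prtdose:::ad_const(tp, x)))
  weights <- lapply(ly$heads, function(hh) list(Wq = hh$Wq$val, Wk = hh$Wk$val,
                                                Wv = hh$Wv$val, Wa = hh$Wa$val))
  for (w in 1:2) {
    rows <- (w - 1) * 4 + 1:4
    ref <- enhanced_self_attention(x[rows, ], weights)
    expect_equal(out[rows, ], ref$output, tolerance = 1e-12)
  }
})

test_that("zero-weight attention blocks are identity maps", {
  set.seed(51)
  for (blk_name in c("wmsa", "swmsa")) {
    geom <- prtdose:::window_geom(8L, 4L, if (blk_name == "swmsa") 2L else 0L)
    blk <- prtdose:::layer_swin_block(8L, 2L, geom, 2, "t")
    prtdose:::zero_params(blk$params)
    x <- matrix(rnorm(64 * 8), 64, 8)
    tp <- prtdose:::new_tape()
    out <- prtdose:::nv(blk$forward(tp, prtdose:::ad_const(tp, x)))
    expect_equal(out, x, tolerance = 1e-12)
  }
})

test_that("window partitions are bijections and shifting changes attention supports", {
  for (side in c(8L, 16L)) {
    gW <- prtdose:::window_geom(side, 4L, 0L)
    gS <- prtdose:::window_geom(side, 4L, 2L)
    expect_identical(sort(gW$idx), seq_len(side^2))
    expect_identical(sort(gS$idx), seq_len(side^2))
    expect_identical(gW$idx[gW$inv], seq_len(side^2))
    expect_identical(gS$idx[gS$inv], seq_len(side^2))
    # corner token (1,1): co-window sets differ between the two partitions
    members <- function(g) {
      grouped_pos <- which(g$idx == 1L)
      w0 <- ceiling(grouped_pos / g$Nw)
      sort(g$idx[(w0 - 1) * g$Nw + seq_len(g$Nw)])
    }
    expect_false(identical(members(gW), members(gS)))
  }
})

test_that("shifted-window attention masks exactly the cross-wrap pairs", {
  g <- prtdose:::window_geom(8L, 4L, 2L)
  expect_false(is.null(g$mask))
  expect_true(all(g$mask %in% c(0, -1e9)))
  # every row attends to at least itself
  base <- (ceiling(seq_len(64) / 16) - 1) * 16
  self_col <- seq_len(64) - base
  expect_true(all(g$mask[cbind(seq_len(64), self_col)] == 0))
})

test_that("CBAM with zero weights scales by 1.25 and preserves shape", {
  set.seed(61)
  cb <- prtdose:::layer_cbam(8L, 8L, 4L, "t")
  prtdose:::zero_params(cb$params)
  x <- matrix(rnorm(64 * 8), 64, 8)
  tp <- prtdose:::new_tape()
  out <- prtdose:::nv(cb$forward(tp, prtdose:::ad_const(tp, x)))
  expect_equal(out, 1.25 * x, tolerance = 1e-12)
  # channel weights are strictly inside (0, 1) for random weights
  cb2 <- prtdose:::layer_cbam(8L, 8L, 4L, "t2")
  tp2 <- prtdose:::new_tape()
  out2 <- prtdose:::nv(cb2$forward(tp2, prtdose:::ad_const(tp2, x)))
  expect_equal(dim(out2), dim(x))
  expect_true(all(is.finite(out2)))
})

test_that("Mish activation matches its closed form", {
  tp <- prtdose:::new_tape()
  v <- prtdose:::nv(prtdose:::ad_mish(tp, prtdose:::ad_const(tp, c(0, 10, -3, 1.5))))
  expect_equal(v[1], 0)
  expect_lt(abs(v[2] - 10), 1e-3)
  expect_equal(v, c(0, 10, -3, 1.5) * tanh(log1p(exp(c(0, 10, -3, 1.5)))),
               tolerance = 1e-9)
})

test_that("forward pass emits the four-level pyramid with doubling sizes, deterministically", {
  x <- rand_input(7)
  pyr <- prt_forward(net, x)
  expect_equal(vapply(pyr, nrow, 1L), c(8L, 16L, 32L, 64L))
  expect_equal(vapply(pyr, ncol, 1L), c(8L, 16L, 32L, 64L))
  pyr2 <- prt_forward(net, x)
  expect_identical(pyr, pyr2)
})

test_that("zeroing the generation heads gives an all-zero pyramid; zeroing heads 2-4 telescopes p1", {
  net0 <- prt_net(cfg64, seed = 33)
  for (i in 1:4) prtdose:::zero_params(net0$heads_G[[i]]$params)
  x <- rand_input(8)
  pyr0 <- prt_forward(net0, x)
  for (p in pyr0) expect_true(all(p == 0))

  net1 <- prt_net(cfg64, seed = 34)
  for (i in 2:4) prtdose:::zero_params(net1$heads_G[[i]]$params)
  pyr1 <- prt_forward(net1, x)
  up <- pyr1[[1]]
  for (k in 1:3) up <- prtdose:::upsample2_plane(up)
  expect_equal(pyr1[[4]], up, tolerance = 1e-10)
})

test_that("every parameter group receives gradient from the deep-supervised loss", {
  case <- tiny_case(seed = 44)
  s <- build_triplets(case)[[2]]
  tp <- prtdose:::new_tape()
  ln <- prtdose:::sample_loss_node(tp, net, s, loss_config(), training = TRUE)
  for (p in net$params) p$grad <- NULL
  prtdose:::ad_backward(tp, ln)
  gnorm <- vapply(net$params, function(p) {
    if (is.null(p$grad)) 0 else max(abs(p$grad))
  }, 1.0)
  # every branch head's final conv gets gradient (deep supervision reaches all)
  for (i in 1:4) {
    expect_gt(gnorm[[paste0("head", i, ".conv3.W")]], 0)
  }
  # and no top-level component is silent
  groups <- unique(sub("\\..*$", "", names(gnorm)))
  for (g in groups) {
    expect_gt(max(gnorm[startsWith(names(gnorm), g)]), 0)
  }
  for (p in net$params) p$grad <- NULL
})

test_that("parameter count matches the closed-form audit from the configuration", {
  cfg <- cfg64
  Ce <- cfg$embed_dim; h <- cfg$heads; Nw <- cfg$window_side^2
  dims <- Ce * c(1, 2, 4, 8)
  dc <- cfg$decoder_channels
  lin <- function(fi, fo) (fi + 1) * fo
  conv <- function(ci, co, k = 3) (k * k * ci + 1) * co
  n_block <- function(C) {
    dk <- C / h
    attn <- h * (3 * C * dk + dk * Nw)
    mlp <- lin(C, max(4, round(C * cfg$mlp_ratio))) + lin(max(4, round(C * cfg$mlp_ratio)), C)
    2 * C + attn + 2 * C + mlp
  }
  n_cbam <- function(C) {
    h2 <- max(2, C %/% cfg$cbam_reduction)
    lin(C, h2) + lin(h2, C) + conv(2, 1, 7)
  }
  expected <- conv(33, dc[4]) +                       # stem
    lin(cfg$patch_size^2 * 33, Ce) + Nw * Ce          # embedding + positions
  for (s in 1:4) {
    if (s > 1) expected <- expected + lin(4 * dims[s - 1], dims[s])
    expected <- expected + 2 * n_block(dims[s]) + n_cbam(dims[s])
  }
  dec_in <- c(dims[4], dc[1], dc[2], dc[3])
  dec_skip <- c(dims[3], dims[2], dims[1], dc[4])
  for (i in 1:4) {
    expected <- expected + conv(dec_in[i] + dec_skip[i], dc[i]) + 2 * dc[i] +
      conv(dc[i], dc[i]) + 2 * dc[i]
    expected <- expected + conv(dc[i], dc[i]) + 2 * dc[i] +
      conv(dc[i], dc[i]) + 2 * dc[i] + conv(dc[i], 1)
  }
  expect_equal(prt_n_params(net), expected)
})

test_that("checkpoints restore weights and reproduce outputs exactly", {
  x <- rand_input(9)
  ck <- prt_checkpoint(net)
  net2 <- prt_restore(ck)
  expect_identical(prt_forward(net2, x), prt_forward(net, x))
})

test_that("a batched forward over identical samples reproduces the single-sample pass", {
  s <- build_triplets(tiny_case(seed = 71))[[2]]
  xmat <- t(matrix(s$input, nrow = 33))
  tp1 <- prtdose:::new_tape()
  one <- prtdose:::model_forward(tp1, net, xmat, training = "batch", B = 1L)
  tp2 <- prtdose:::new_tape()
  two <- prtdose:::model_forward(tp2, net, rbind(xmat, xmat),
                                 training = "batch", B = 2L)
  for (i in 1:4) {
    L <- net$head_sides[i]^2
    v2 <- prtdose:::nv(two$pyramid[[i]])
    expect_equal(v2[seq_len(L), , drop = FALSE], prtdose:::nv(one$pyramid[[i]]),
                 tolerance = 1e-10)
    expect_equal(v2[L + seq_len(L), , drop = FALSE], v2[seq_len(L), , drop = FALSE],
                 tolerance = 1e-12)
  }
  # batched loss over the pair equals the single-sample loss
  tp3 <- prtdose:::new_tape()
  lb <- prtdose:::nv(prtdose:::batch_loss_node(tp3, net, list(s, s), loss_config(),
                                               training = "batch"))
  tp4 <- prtdose:::new_tape()
  l1 <- prtdose:::nv(prtdose:::sample_loss_node(tp4, net, s, loss_config(),
                                                training = "batch"))
  expect_equal(lb, l1, tolerance = 1e-12)
})
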