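# Shared fixtures and independent oracles used across the test files.

# central finite-difference gradient of f (scalar-valued) w.r.t. param env p
fd_grad <- function(f, p, eps = 1e-5) {
  g <- p$val * 0
  for (i in seq_along(p$val)) {
    v0 <- p$val[i]
    p$val[i] <- v0 + eps; fp <- f()
    p$val[i] <- v0 - eps; fm <- f()
    p$val[i] <- v0
    g[i] <- (fp - fm) / (2 * eps)
  }
  g
}

# run backward from a scalar built by `build(tp)`; returns param$grad
ad_grad_of <- function(build, params) {
  for (p in params) p$grad <- NULL
  tp <- prtdose:::new_tape()
  root <- build(tp)
  prtdose:::ad_backward(tp, root)
  lapply(params, function(p) p$grad)
}

# small smooth dose-like random slice (nonnegative, smooth bumps)
smooth_field <- function(n, seed, scale = 40) {
  set.seed(seed)
  f <- function() {
    cx <- runif(1, 0.25, 0.75) * n; cy <- runif(1, 0.25, 0.75) * n
    s <- runif(1, n / 6, n / 3)
    outer(seq_len(n), seq_len(n), function(i, j) exp(-((i - cy)^2 + (j - cx)^2) / (2 * s^2)))
  }
  m <- f() + 0.6 * f() + 0.3 * f()
  scale * m / max(m)
}

# brute-force gamma pass rate: per-voxel loop, dense offsets, explicit
# bilinear interpolation (independent of the shift-based implementation)
gamma_oracle_2d <- function(pred, truth, spacing, dd_pct = 3, dta = 2,
                            radius = 6, step = 0.1, thresh_pct = 10) {
  dmax <- max(truth)
  dd <- dd_pct / 100 * dmax
  H <- nrow(truth); W <- ncol(truth)
  offs <- expand.grid(dy = seq(-radius, radius, by = step),
                      dx = seq(-radius, radius, by = step))
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  dist2 <- (offs$dy^2 + offs$dx^2) / dta^2
  bilin <- function(fy, fx) {
    ok <- fy >= 0 & fy <= H - 1 & fx >= 0 & fx <= W - 1
    out <- rep(NA_real_, length(fy))
    y0 <- floor(fy[ok]); x0 <- floor(fx[ok])
    y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
    wy <- fy[ok] - y0; wx <- fx[ok] - x0
    gv <- function(iy, ix) pred[cbind(iy + 1, ix + 1)]
    out[ok] <- (1 - wy) * ((1 - wx) * gv(y0, x0) + wx * gv(y0, x1)) +
      wy * ((1 - wx) * gv(y1, x0) + wx * gv(y1, x1))
    out
  }
  pass <- 0L; nev <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (truth[i, j] < thresh_pct / 100 * dmax) next
    nev <- nev + 1L
    pv <- bilin((i - 1) + offs$dy / spacing[1], (j - 1) + offs$dx / spacing[2])
    g2 <- dist2 + (pv - truth[i, j])^2 / dd^2
    if (min(g2, na.rm = TRUE) <= 1 + 1e-12) pass <- pass + 1L
  }
  100 * pass / nev
}

tiny_case <- function(seed = 1, slices = 3, noise = 0) {
  generate_case(phantom_config(grid_shape = c(slices, 64, 64),
                               noise_sd_Gy = noise, seed = seed))
}

# literal step-by-step oracle for the rank loss (both variants)
rank_loss_oracle <- function(p, y, variant = "log1m") {
  m <- length(p)
  idx <- order(y, method = "radix")
  ys <- y[idx]; ps <- p[idx]
  total <- 0
  for (s in seq_len(m - 1)) {
    rho <- exp(ps[s + 1] - ps[s]) / (1 + exp(ps[s + 1] - ps[s]))
    omega <- if (ys[s + 1] > ys[s]) 1 else if (ys[s + 1] == ys[s]) 0.5 else 0
    comp <- if (variant == "log1m") log(1 - rho) else 1 - log(rho)
    total <- total + omega * log(rho) + (1 - omega) * comp
  }
  -total / (2 * m)
}

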