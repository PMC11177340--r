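# The fused training loss: mean-squared-error loss, one-sided PTV voxel
# loss, and pairwise rank loss, applied with deep supervision over the
# four-level prediction pyramid.
#
# Public functions operate on plain numeric arrays (used for evaluation,
# testing and reporting); ad_*_loss counterparts build the identical
# quantities on the autodiff tape for training, and the two routes are
# checked against each other in the test suite.

#' Loss configuration
#'
#' @param lambda_k PTV-region weight of the voxel loss (default 0.7).
#' @param mu_i Non-PTV-region weight of the voxel loss (default 0.3).
#' @param rank_variant `"log1m"` (standard pairwise logistic likelihood,
#'   default) or `"as_printed"` (the literal `(1 - omega) * (1 - log rho)`
#'   form, kept for auditability).
#' @param branch_weights Four nonnegative weights for the deep-supervision
#'   branches, coarse to fine (default all 1).
#' @param components Character subset of `c("Lm", "Lp", "Lr")` selecting the
#'   fused-loss terms; `"Lm"`, `"Lm&Lp"` and `"Lm&Lp&Lr"` strings are also
#'   accepted.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda_k = 0.7, mu_i = 0.3,
                        rank_variant = c("log1m", "as_printed"),
                        branch_weights = rep(1, 4),
                        components = c("Lm", "Lp", "Lr")) {
  stopifnot(lambda_k >= 0, mu_i >= 0, all(branch_weights >= 0),
            length(branch_weights) == 4L)
  if (length(components) == 1L && grepl("&", components, fixed = TRUE)) {
    components <- strsplit(components, "&", fixed = TRUE)[[1]]
  }
  stopifnot(all(components %in% c("Lm", "Lp", "Lr")), "Lm" %in% components)
  structure(list(lambda_k = lambda_k, mu_i = mu_i,
                 rank_variant = match.arg(rank_variant),
                 branch_weights = branch_weights,
                 components = components),
            class = "loss_config")
}

#' Mean-squared-error loss
#'
#' `Lm = ||p - y||^2 / (2m)` over the m pixels of the map.
#'
#' @param p,y Numeric arrays of equal shape (prediction, target).
#' @return Scalar loss.
#' @export
mse_loss <- function(p, y) {
  stopifnot(length(p) == length(y))
  sum((p - y)^2) / (2 * length(p))
}

#' One-sided PTV voxel loss
#'
#' Inside the PTV every deviation is penalised; outside only predictions
#' ABOVE the target are penalised (the dose should fall off fast, so
#' under-dosing normal tissue is free):
#' `Lp = lambda_k * mean_PTV((p-y)^2)/2 + mu_i * mean_nonPTV(max(p-y,0)^2)/2`.
#' An empty region contributes zero.
#'
#' @param p,y Numeric arrays of equal shape.
#' @param ptv_mask Binary array of the same shape.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
voxel_loss <- function(p, y, ptv_mask, config = loss_config()) {
  stopifnot(length(p) == length(y), length(ptv_mask) == length(p))
  inP <- ptv_mask > 0
  nP <- sum(inP); nN <- sum(!inP)
  tP <- if (nP > 0) sum((p[inP] - y[inP])^2) / (2 * nP) else 0
  tN <- if (nN > 0) sum(pmax(p[!inP] - y[!inP], 0)^2) / (2 * nN) else 0
  config$lambda_k * tP + config$mu_i * tN
}

#' Rank ordering of a prediction/target pair
#'
#' Vectorises both maps, sorts the target ascending (stable), reorders the
#' prediction by the same permutation, and scores each adjacent pair:
#' `rho(sigma) = logistic(p*(sigma+1) - p*(sigma))` and `omega(sigma)` is 1
#' where the target strictly increases and 1/2 where it ties (a decrease is
#' unreachable after ascending sort).
#'
#' @param p,y Numeric arrays of equal shape, at least 2 pixels.
#' @return A `rank_ordering` list with `lambda_index`, `y_star`, `p_star`,
#'   `rho`, `omega`.
#' @export
rank_ordering <- function(p, y) {
  stopifnot(length(p) == length(y), length(p) >= 2L)
  idx <- order(as.vector(y), method = "radix")   # stable
  ys <- as.vector(y)[idx]
  ps <- as.vector(p)[idx]
  dp <- diff(ps)
  structure(list(lambda_index = idx, y_star = ys, p_star = ps,
                 rho = stats::plogis(dp),
                 omega = ifelse(diff(ys) > 0, 1, 0.5)),
            class = "rank_ordering")
}

#' Pairwise rank loss
#'
#' Negative mean pairwise log-likelihood over the adjacent pairs of the
#' target-sorted sequences:
#' `Lr = -(1/2m) * sum(omega * log(rho) + (1 - omega) * c(rho))` where
#' `c(rho)` is `log(1 - rho)` for the default `log1m` variant and
#' `1 - log(rho)` for the literal `as_printed` variant.
#'
#' @inheritParams voxel_loss
#' @return Scalar loss.
#' @export
rank_loss <- function(p, y, config = loss_config()) {
  ro <- rank_ordering(p, y)
  m <- length(p)
  dp <- diff(ro$p_star)
  log_rho <- stats::plogis(dp, log.p = TRUE)         # log sigma(dp)
  comp <- if (config$rank_variant == "log1m") {
    stats::plogis(-dp, log.p = TRUE)                 # log(1 - rho)
  } else {
    1 - log_rho
  }
  -sum(ro$omega * log_rho + (1 - ro$omega) * comp) / (2 * m)
}

#' Fused loss
#'
#' Sum of the configured components: `L = Lm + Lp + Lr`.
#'
#' @inheritParams voxel_loss
#' @return Scalar loss.
#' @export
fused_loss <- function(p, y, ptv_mask, config = loss_config()) {
  total <- 0
  if ("Lm" %in% config$components) total <- total + mse_loss(p, y)
  if ("Lp" %in% config$components) total <- total + voxel_loss(p, y, ptv_mask, config)
  if ("Lr" %in% config$components) total <- total + rank_loss(p, y, config)
  total
}

# area-average downsample of a target/mask plane to pyramid level i (1..4,
# level 4 = full resolution); masks are re-binarised at 0.5
pyramid_targets <- function(y, mask, levels = 4L) {
  out <- vector("list", levels)
  for (i in seq_len(levels)) {
    f <- 2^(levels - i)
    out[[i]] <- list(y = downsample_plane(y, f),
                     mask = (downsample_plane(mask, f) >= 0.5) * 1)
  }
  out
}

#' Deep-supervised pyramid loss
#'
#' Applies the fused loss to every pyramid level against area-average
#' downsampled targets (PTV masks re-binarised at 0.5), weighted by
#' `config$branch_weights` (coarse to fine).
#'
#' @param pyramid List of 4 predicted maps at sizes n/8, n/4, n/2, n.
#' @param y Full-resolution target plane.
#' @param ptv_mask Full-resolution binary PTV plane.
#' @param config A [loss_config()].
#' @return Scalar loss.
#' @export
deep_supervised_loss <- function(pyramid, y, ptv_mask, config = loss_config()) {
  stopifnot(length(pyramid) == 4L)
  tg <- pyramid_targets(y, ptv_mask)
  total <- 0
  for (i in 1:4) {
    if (config$branch_weights[i] == 0) next
    total <- total + config$branch_weights[i] *
      fused_loss(pyramid[[i]], tg[[i]]$y, tg[[i]]$mask, config)
  }
  total
}

## ---- differentiable versions (training path) -------------------------------

# p: ad_node holding an m x 1 column (or any matrix); y, ptv_mask constants
ad_mse_loss <- function(tp, p, y) {
  d <- ad_sub(tp, p, y)
  ad_scale(tp, ad_sum(tp, ad_square(tp, d)), 1 / (2 * length(y)))
}

ad_voxel_loss <- function(tp, p, y, ptv_mask, config) {
  inP <- as.numeric(ptv_mask > 0)
  nP <- sum(inP); nN <- sum(1 - inP)
  d <- ad_sub(tp, p, y)
  terms <- list()
  if (nP > 0 && config$lambda_k > 0) {
    dP <- ad_mul(tp, d, array(inP, dim = dim(nv(d))))
    terms <- c(terms, list(ad_scale(tp, ad_sum(tp, ad_square(tp, dP)),
                                    config$lambda_k / (2 * nP))))
  }
  if (nN > 0 && config$mu_i > 0) {
    dN <- ad_mul(tp, ad_relu(tp, d), array(1 - inP, dim = dim(nv(d))))
    terms <- c(terms, list(ad_scale(tp, ad_sum(tp, ad_square(tp, dN)),
                                    config$mu_i / (2 * nN))))
  }
  if (!length(terms)) return(ad_const(tp, 0))
  if (length(terms) == 1L) terms[[1]] else ad_addn(tp, terms)
}

# uses log sigma(d) = d - softplus(d) and log(1 - sigma(d)) = -softplus(d)
ad_rank_loss <- function(tp, p, y, config) {
  m <- length(y)
  idx <- order(as.vector(y), method = "radix")
  ys <- as.vector(y)[idx]
  omega <- ifelse(diff(ys) > 0, 1, 0.5)
  pv <- if (is.matrix(nv(p))) p else p   # p is m x 1 column
  psort <- ad_gather_rows(tp, pv, idx)
  dp <- ad_sub(tp, ad_gather_rows(tp, psort, 2:m),
               ad_gather_rows(tp, psort, 1:(m - 1)))
  sp <- ad_softplus(tp, dp)
  if (config$rank_variant == "log1m") {
    # term = omega * (d - sp) + (1 - omega) * (-sp) = omega * d - sp
    s <- ad_add(tp, ad_mul(tp, dp, matrix(omega, ncol = 1)), ad_scale(tp, sp, -1))
  } else {
    # term = omega * (d - sp) + (1 - omega) * (1 - d + sp)
    logr <- ad_sub(tp, dp, sp)
    s <- ad_add(tp, ad_mul(tp, logr, matrix(2 * omega - 1, ncol = 1)),
                matrix(1 - omega, ncol = 1))
  }
  ad_scale(tp, ad_sum(tp, s), -1 / (2 * m))
}

ad_fused_loss <- function(tp, p, y, ptv_mask, config) {
  terms <- list()
  if ("Lm" %in% config$components) terms <- c(terms, list(ad_mse_loss(tp, p, y)))
  if ("Lp" %in% config$components) {
    terms <- c(terms, list(ad_voxel_loss(tp, p, y, ptv_mask, config)))
  }
  if ("Lr" %in% config$components) terms <- c(terms, list(ad_rank_loss(tp, p, y, config)))
  if (length(terms) == 1L) terms[[1]] else ad_addn(tp, terms)
}

# pyramid: list of 4 ad_nodes holding (HW_i x 1) columns; y, mask full-res planes
ad_deep_supervised_loss <- function(tp, pyramid, y, ptv_mask, config) {
  tg <- pyramid_targets(y, ptv_mask)
  terms <- list()
  for (i in 1:4) {
    if (config$branch_weights[i] == 0) next
    li <- ad_fused_loss(tp, pyramid[[i]],
                        matrix(as.vector(tg[[i]]$y), ncol = 1),
                        as.vector(tg[[i]]$mask), config)
    terms <- c(terms, list(ad_scale(tp, li, config$branch_weights[i])))
  }
  if (length(terms) == 1L) terms[[1]] else ad_addn(tp, terms)
}
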