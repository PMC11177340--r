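# Dosimetric metrics: masked errors, DVH order statistics, isodose overlap,
# plan criteria, low-dose bands, gamma index vs brute-force search.

test_that("masked errors ignore everything outside the body", {
  set.seed(71)
  truth <- array(runif(6 * 6 * 2, 0, 45), c(6, 6, 2))
  body <- array(rbinom(72, 1, 0.7), c(6, 6, 2))
  expect_equal(masked_errors(truth, truth, body), list(mae = 0, mse = 0, rmse = 0))
  pred <- truth + 1
  e <- masked_errors(pred, truth, body)
  expect_equal(unlist(e), c(mae = 1, mse = 1, rmse = 1))
  pred2 <- pred
  pred2[body == 0] <- 999
  expect_equal(masked_errors(pred2, truth, body), e)
  expect_error(masked_errors(pred, truth, body * 0), "empty")
})

test_that("DVH is a non-increasing curve matching exhaustive counting", {
  dose <- array(45, c(3, 3, 2))
  mask <- array(1, c(3, 3, 2))
  cv <- dvh(dose, mask)
  expect_equal(cv$cum_volume_pct[cv$dose_bins_Gy <= 45], rep(100, sum(cv$dose_bins_Gy <= 45)))
  expect_equal(cv$cum_volume_pct[cv$dose_bins_Gy > 45], rep(0, sum(cv$dose_bins_Gy > 45)))
  set.seed(73)
  d2 <- array(runif(1000, 0, 50), c(10, 10, 10))
  m2 <- array(0, c(10, 10, 10)); m2[sample(1000, 10)] <- 1
  cv2 <- dvh(d2, m2, bin_width_Gy = 0.5)
  expect_true(all(diff(cv2$cum_volume_pct) <= 0))
  sel <- d2[m2 == 1]
  for (b in seq_along(cv2$dose_bins_Gy)) {
    expect_equal(cv2$cum_volume_pct[b], 100 * mean(sel >= cv2$dose_bins_Gy[b]))
  }
})

test_that("Dq and Vd follow the stated order-statistic conventions", {
  dose <- array(1:100, c(10, 10, 1))
  mask <- array(1, c(10, 10, 1))
  expect_equal(dose_at_volume(dose, 95, mask), 5)
  expect_equal(dose_at_volume(dose, 2, mask), 98)
  expect_equal(volume_at_dose(dose, mask, 30), 71)
  uni <- array(45, c(4, 4, 1)); um <- array(1, c(4, 4, 1))
  expect_equal(dose_at_volume(uni, 95, um), 45)
  expect_equal(volume_at_dose(uni, um, 30), 100)
  # Vd non-increasing in d; V_{Dq} >= q consistency on random structures
  set.seed(79)
  for (rep in 1:5) {
    dd <- array(runif(100, 0, 60), c(10, 10, 1))
    thr <- sort(runif(10, 0, 60))
    vds <- vapply(thr, function(t) volume_at_dose(dd, mask, t), 1.0)
    expect_true(all(diff(vds) <= 0))
    for (q in c(2, 50, 95, 98)) {
      expect_gte(volume_at_dose(dd, mask, dose_at_volume(dd, q, mask)), q)
    }
  }
  # curve-based lookup follows the curve convention: the largest bin dose
  # still covering q% of the volume (here 6 Gy, since 95 voxels are >= 6)
  cv <- dvh(dose, mask, bin_width_Gy = 0.1)
  expect_equal(dose_at_volume(cv, 95), 6, tolerance = 1e-9)
})

test_that("isodose overlap reproduces hand-counted DSC and the Jaccard identity", {
  # two 4x4 squares overlapping in a 4x2 half: DSC = 2*8 / (16+16) = 0.5
  a <- matrix(0, 8, 10); a[3:6, 3:6] <- 10
  b <- matrix(0, 8, 10); b[3:6, 5:8] <- 10
  rep1 <- isodose_overlap(b, a, 5, spacing_mm = c(1, 1))
  expect_equal(rep1$dsc, 0.5)
  expect_equal(rep1$jaccard, rep1$dsc / (2 - rep1$dsc), tolerance = 1e-12)
  identical_rep <- isodose_overlap(a, a, 5, spacing_mm = c(1, 1))
  expect_equal(identical_rep$dsc, 1)
  expect_equal(identical_rep$hausdorff_mm, 0)
  disjoint <- isodose_overlap(matrix(c(10, 0, 0, 0), 2), matrix(c(0, 0, 0, 10), 2),
                              5, spacing_mm = c(1, 1))
  expect_equal(disjoint$dsc, 0)
  # empty side flags undefined distances
  none <- isodose_overlap(matrix(0, 4, 4), matrix(10, 4, 4), 5, spacing_mm = c(1, 1))
  expect_false(none$distances_defined)
  expect_true(is.na(none$hausdorff_mm))
})

test_that("Jaccard identity, HD95 <= HD and symmetry hold on random masks", {
  set.seed(83)
  for (rep in 1:8) {
    a <- matrix(runif(400), 20) > 0.6
    b <- matrix(runif(400), 20) > 0.6
    if (!any(a) || !any(b)) next
    r1 <- isodose_overlap(b * 10, a * 10, 5, spacing_mm = c(2, 2))
    r2 <- isodose_overlap(a * 10, b * 10, 5, spacing_mm = c(2, 2))
    expect_equal(r1$jaccard, r1$dsc / (2 - r1$dsc), tolerance = 1e-12)
    expect_lte(r1$hd95_mm, r1$hausdorff_mm)
    expect_equal(r1$hausdorff_mm, r2$hausdorff_mm, tolerance = 1e-12)
    expect_equal(r1$hd95_mm, r2$hd95_mm, tolerance = 1e-12)
    expect_equal(r1$dsc, r2$dsc, tolerance = 1e-12)
  }
})

test_that("plan criteria evaluate boundary and failure cases correctly", {
  case <- tiny_case(seed = 14)
  # uniform 45 Gy: PTV D95 passes at the boundary, D2 passes, D98 passes
  uni <- array(45, dim(case$dose$values))
  tab <- check_plan_criteria(uni * (case$structures$masks$body), case$structures)
  d95 <- tab[tab$criterion == "D95 >= prescription", ]
  expect_true(d95$pass)
  # zero dose: all OAR criteria pass, PTV criteria fail
  tab0 <- check_plan_criteria(array(0, dim(uni)), case$structures)
  # lower-bound PTV criteria fail; the D2 upper bound holds vacuously
  expect_false(tab0$pass[tab0$criterion == "D95 >= prescription"])
  expect_false(tab0$pass[tab0$criterion == "D98 > 95% prescription"])
  expect_true(tab0$pass[tab0$criterion == "D2 < 110% prescription"])
  expect_true(all(tab0$pass[tab0$structure != "PTV"]))
  # bladder half at 35 Gy: V30 = 50 fails the strict "< 50%" criterion
  bl <- case$structures$masks$bladder
  idx <- which(bl == 1)
  half <- array(0, dim(bl))
  half[idx[seq_len(floor(length(idx) / 2) * 2) %% 2 == 0]] <- 35
  # construct exactly half the voxels at 35
  half <- array(0, dim(bl))
  take <- idx[seq_len(length(idx) %/% 2 * 2)]
  half[take[seq_along(take) %% 2 == 1]] <- 35
  v30 <- volume_at_dose(half, bl, 30)
  tabh <- check_plan_criteria(half, case$structures)
  row <- tabh[tabh$structure == "bladder" & tabh$criterion == "V30 < 50%", ]
  if (length(idx) %% 2 == 0) expect_equal(row$value, 50)
  expect_equal(row$pass, row$value < 50)
  # missing structure is marked not evaluable
  st2 <- case$structures$masks
  st2$spinal_cord <- NULL
  tabm <- check_plan_criteria(half, st2)
  expect_false(tabm$evaluable[tabm$structure == "spinal_cord"])
})

test_that("low-dose band counts partition [4,20) and match a naive loop", {
  case <- tiny_case(seed = 15, noise = 1)
  d <- case$dose$values
  body <- case$structures$masks$body
  cts <- low_dose_voxel_counts(d, body_mask = body)
  expect_equal(sum(cts), sum(d[body == 1] >= 4 & d[body == 1] < 20))
  naive <- c(0L, 0L, 0L)
  bands <- list(c(4, 10), c(10, 15), c(15, 20))
  for (i in seq_along(d)) {
    if (body[i] == 0) next
    for (b in 1:3) if (d[i] >= bands[[b]][1] && d[i] < bands[[b]][2]) {
      naive[b] <- naive[b] + 1L
    }
  }
  expect_equal(unname(cts), naive)
  expect_error(low_dose_voxel_counts(d, bands = list(c(4, 12), c(10, 15))), "overlap")
  # uniform 5 Gy body: everything in the first band
  u <- array(5, dim(d)) * body
  cu <- low_dose_voxel_counts(u, body_mask = body)
  expect_equal(unname(cu), c(sum(body), 0L, 0L))
})

test_that("gamma is exact for identical inputs and for a uniform 3% rescale", {
  case <- tiny_case(seed = 16)
  sl <- case$dose$values[, , 2]
  body <- case$structures$masks$body[, , 2]
  g1 <- gamma_index(sl, sl, gamma_params(), body_mask = body, spacing_mm = c(2.5, 2.5))
  expect_equal(g1$pass_rate_pct, 100)
  expect_true(all(g1$gamma[!is.na(g1$gamma)] <= 1e-9))
  # uniform 1.03x scaling: dose difference <= Delta everywhere under global 3%
  g2 <- gamma_index(1.03 * sl, sl, gamma_params(), body_mask = body,
                    spacing_mm = c(2.5, 2.5))
  expect_equal(g2$pass_rate_pct, 100)
  # outside-body voxels are never evaluated
  expect_true(all(is.na(g1$gamma[body == 0])))
})

test_that("gamma pass rate matches the brute-force oracle and is monotone in tolerances", {
  set.seed(91)
  pass_impl <- pass_oracle <- numeric(0)
  for (rep in 1:4) {
    truth <- smooth_field(24, seed = 300 + rep)
    pred <- truth * (1 + 0.025 * smooth_field(24, seed = 400 + rep, scale = 1)) +
      0.4 * smooth_field(24, seed = 500 + rep, scale = 1)
    gi <- gamma_index(pred, truth, gamma_params(), spacing_mm = c(2.5, 2.5))
    go <- gamma_oracle_2d(pred, truth, c(2.5, 2.5))
    pass_impl <- c(pass_impl, gi$pass_rate_pct)
    pass_oracle <- c(pass_oracle, go)
    # monotonicity: looser criteria can only raise the pass rate
    g53 <- gamma_index(pred, truth, gamma_params(dose_tolerance_pct = 5, dta_mm = 2),
                       spacing_mm = c(2.5, 2.5))
    g23 <- gamma_index(pred, truth, gamma_params(dose_tolerance_pct = 3, dta_mm = 3),
                       spacing_mm = c(2.5, 2.5))
    expect_gte(g53$pass_rate_pct, gi$pass_rate_pct)
    expect_gte(g23$pass_rate_pct, gi$pass_rate_pct)
  }
  expect_lt(max(abs(pass_impl - pass_oracle)), 0.5)
})

test_that("3D gamma reduces to the slice result for single-slice volumes", {
  case <- tiny_case(seed = 17)
  vol <- case$dose$values
  body <- case$structures$masks$body
  pred <- vol * 1.02
  g3 <- gamma_index(pred, vol, gamma_params(), body_mask = body,
                    spacing_mm = c(5, 2.5, 2.5))
  expect_equal(g3$pass_rate_pct, 100)
  expect_equal(g3$n_evaluated, sum(vol >= 0.1 * max(vol) & body == 1))
})
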