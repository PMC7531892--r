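test_that("trajectory reconstruction integrates flow fields correctly", {
  d <- c(16, 16)
  zero <- replicate(4, list(u = matrix(0, d[1], d[2]),
                            v = matrix(0, d[1], d[2])), simplify = FALSE)
  tr <- reconstruct_trajectories(zero)
  expect_true(all(tr$x[, , 5] == tr$x[, , 1]))
  expect_false(any(tr$truncated))
  # uniform flow (1, 0) px/frame: x(t) = x0 + t
  unif <- replicate(3, list(u = matrix(1, d[1], d[2]),
                            v = matrix(0, d[1], d[2])), simplify = FALSE)
  tru <- reconstruct_trajectories(unif)
  expect_equal(tru$x[4, 7, ], 4 + 0:3)
  expect_equal(tru$y[4, 7, ], rep(7, 4))
  expect_true(any(tru$truncated))  # pixels near the border leave the field
})

test_that("trajectories in a rotational flow stay on their circles", {
  # rigid rotation about the field centre by a small angle per frame
  n <- 33; omega <- 0.02
  cx <- (n + 1) / 2
  gx <- matrix(seq_len(n), n, n); gy <- t(gx)
  flow <- replicate(20, list(u = (cos(omega) - 1) * (gx - cx) - sin(omega) * (gy - cx),
                             v = sin(omega) * (gx - cx) + (cos(omega) - 1) * (gy - cx)),
                    simplify = FALSE)
  tr <- reconstruct_trajectories(flow)
  r0 <- sqrt((tr$x[, , 1] - cx)^2 + (tr$y[, , 1] - cx)^2)
  r1 <- sqrt((tr$x[, , 21] - cx)^2 + (tr$y[, , 21] - cx)^2)
  sel <- r0 > 3 & r0 < 12  # interior circles, away from centre and border
  expect_lt(max(abs(r1[sel] / r0[sel] - 1)), 0.02)
})

test_that("time-averaged MSD matches analytic and brute-force values", {
  # linear trajectory at 2 px/frame: MSD(tau) = 4 tau^2 (e.g. MSD(3) = 36)
  pos <- cbind(2 * (0:9), rep(0, 10))
  msd <- compute_msd(pos)
  expect_equal(msd$msd[3], 36)
  expect_equal(msd$msd, 4 * (1:9)^2)
  # static: identically zero
  expect_true(all(compute_msd(cbind(rep(1, 8), rep(2, 8)))$msd == 0))
  # direct double-loop equality on a random 10-point trajectory
  set.seed(51)
  p <- matrix(rnorm(20), 10, 2)
  expect_lt(max(abs(compute_msd(p)$msd - msd_brute(p))), 1e-12)
})

test_that("MSD model fits are exact on noise-free curves of their own model", {
  tau <- (1:10) * 2
  fD <- fit_msd_models(data.frame(tau_s = tau, msd = 4 * 0.25 * tau))
  expect_equal(unname(fD$fits$D$par["D"]), 0.25, tolerance = 1e-6)
  expect_lt(fD$fits$D$rss, 1e-12)
  fV <- fit_msd_models(data.frame(tau_s = tau, msd = 4 * tau^2))  # v = 2
  expect_equal(unname(fV$fits$V$par["v"]), 2, tolerance = 1e-6)
  expect_lt(fV$fits$V$rss, 1e-10)
  expect_error(fit_msd_models(data.frame(tau_s = 1:3, msd = 1:3)), "4 lag")
})

test_that("the full anomalous-drift model recovers its parameters from noisy forward data", {
  set.seed(52)
  tau <- (1:15) * 2
  truth <- 4 * 0.1 * tau^0.7 + 0.05^2 * tau^2 + 0.001
  msd <- truth * (1 + rnorm(15, 0, 0.02))
  fit <- fit_msd_models(data.frame(tau_s = tau, msd = msd))$fits$DAV
  expect_true(fit$ok)
  expect_lt(abs(fit$par[["D"]] - 0.1) / 0.1, 0.2)
  expect_lt(abs(fit$par[["alpha"]] - 0.7) / 0.7, 0.2)
})

test_that("nested models never fit worse than their restrictions", {
  set.seed(53)
  for (i in 1:5) {
    tau <- (1:12) * 2
    msd <- abs(4 * runif(1, 0.01, 0.1) * tau^runif(1, 0.5, 1.5) +
                 runif(1, 0, 1e-3) + rnorm(12, 0, 0.01 * i))
    f <- fit_msd_models(data.frame(tau_s = tau, msd = msd))$fits
    # up to the optimizer's relative tolerance
    tol <- function(r) r * 1e-3 + 1e-10
    expect_lte(f$DA$rss, f$D$rss + tol(f$D$rss))
    expect_lte(f$DV$rss, f$D$rss + tol(f$D$rss))
    expect_lte(f$DV$rss, f$V$rss + tol(f$V$rss))
    expect_lte(f$DAV$rss, f$DA$rss + tol(f$DA$rss))
    expect_lte(f$DAV$rss, f$DV$rss + tol(f$DV$rss))
  }
})

test_that("model selection penalizes complexity and handles degenerate inputs", {
  tau <- (1:10) * 2
  # noise-free diffusion: D beats DA/DV/DAV despite their equal fit quality
  fD <- fit_msd_models(structure(data.frame(tau_s = tau, msd = tau), n_frames = 21L))
  expect_equal(select_model(fD)$model, "D")
  # noise-free drift: V wins
  fV <- fit_msd_models(structure(data.frame(tau_s = tau, msd = 4 * tau^2),
                                 n_frames = 21L))
  expect_equal(select_model(fV)$model, "V")
  # single successful fit: that model wins
  f1 <- fD
  for (m in c("D", "DA", "DV", "DAV")) f1$fits[[m]]$ok <- FALSE
  expect_equal(select_model(f1)$model, "V")
  f0 <- fD
  for (m in names(f0$fits)) f0$fits[[m]]$ok <- FALSE
  expect_true(is.na(select_model(f0)$model))
})

test_that("Bayesian selection recovers the generating motion class on simulated trajectories", {
  n_tr <- 60
  tr_d <- simulate_trajectories("D", n = n_tr, n_frames = 100, dt = 2,
                                D = 0.005, sigma_loc = 0.01, seed = 54)
  sel_d <- vapply(tr_d, function(p)
    select_model(fit_msd_models(compute_msd(p, dt = 2, max_lag = 15)))$model,
    character(1))
  expect_gte(mean(sel_d == "D"), 0.9)
  tr_v <- simulate_trajectories("V", n = n_tr, n_frames = 100, dt = 2,
                                v = 0.02, sigma_loc = 0.01, seed = 55)
  sel_v <- vapply(tr_v, function(p)
    select_model(fit_msd_models(compute_msd(p, dt = 2, max_lag = 15)))$model,
    character(1))
  expect_gte(mean(sel_v == "V"), 0.9)
  # recovered D is unbiased within 15%
  dhat <- vapply(tr_d, function(p) {
    s <- select_model(fit_msd_models(compute_msd(p, dt = 2, max_lag = 15)))
    if ("D" %in% names(s$par)) s$par[["D"]] else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(dhat, na.rm = TRUE) / 0.005 - 1), 0.15)
})

test_that("the per-pixel pipeline recovers a spatial split of motion classes", {
  # dynamics scaled so trajectories stay well inside the field over the
  # whole series (net displacement ~ a few px out of a 36 px field)
  d <- c(36, 36)
  model_map <- matrix(1L, d[1], d[2]); model_map[19:36, ] <- 2L  # left D, right V
  sp <- motion_spec(field_shape = d, rho_c = 4, nu = 1, model = model_map,
                    D = 5e-5, v = 0.002, n_frames = 100, seed = 56)
  g <- generate_flow_series(sp)
  # true flow fields isolate trajectory/MSD/selection from flow estimation
  maps <- hid_pipeline(g$flow, pixel_size = 41, frame_interval = 2)
  truth <- ifelse(model_map == 1L, "D", "V")
  # away from the split line and the border, where flow interpolation mixes
  sel_d <- cbind(rep(6:14, each = 9), rep(14:22, times = 9))
  sel_v <- cbind(rep(24:32, each = 9), rep(14:22, times = 9))
  acc <- mean(c(maps$model[sel_d] == truth[sel_d],
                maps$model[sel_v] == truth[sel_v]), na.rm = TRUE)
  expect_gte(acc, 0.85)
  # drift speed on the V side is recovered in um/s
  expect_lt(abs(mean(maps$v[sel_v], na.rm = TRUE) - 0.002) / 0.002, 0.25)
})

test_that("a 3-frame series yields maps with every pixel flagged unclassifiable", {
  sp <- motion_spec(field_shape = c(12, 12), rho_c = 3, nu = 1, model = "D",
                    n_frames = 3, seed = 57)
  g <- generate_flow_series(sp)
  maps <- hid_pipeline(g$frames, pixel_size = 41, frame_interval = 2)
  expect_equal(dim(maps$model_code), c(12L, 12L))
  expect_true(all(is.na(maps$model_code)))
  expect_equal(maps$n_unclassified, 144L)
})

test_that("recovered parameters scale correctly with the pixel size", {
  sp <- motion_spec(field_shape = c(16, 16), rho_c = 3, nu = 1, model = "V",
                    v = 0.002, n_frames = 30, seed = 58)
  g <- generate_flow_series(sp)
  m1 <- hid_pipeline(g$flow, pixel_size = 41, frame_interval = 2)
  m2 <- hid_pipeline(g$flow, pixel_size = 82, frame_interval = 2)
  sel <- !is.na(m1$v) & !is.na(m2$v)
  expect_gt(sum(sel), 10)
  expect_equal(m2$v[sel] / m1$v[sel], rep(2, sum(sel)), tolerance = 1e-6)
})

test_that("uniform dynamics produce spatially homogeneous parameter maps", {
  sp <- motion_spec(field_shape = c(24, 24), rho_c = 4, nu = 1, model = "D",
                    D = 1e-4, n_frames = 100, seed = 59)
  g <- generate_flow_series(sp)
  maps <- hid_pipeline(g$flow, pixel_size = 41, frame_interval = 2)
  dv <- maps$D[!is.na(maps$D)]
  expect_gt(length(dv), 100)
  expect_lt(stats::sd(dv) / mean(dv), 0.25)
})
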