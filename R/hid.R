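#' Reconstruct per-pixel trajectories from a flow-field sequence
#'
#' Forward integration: each pixel starts at its own centre and is advected
#' by the displacement field of every frame transition, with bilinear
#' interpolation of the flow at non-integer positions. Trajectories that
#' leave the field are clamped to the border and flagged.
#'
#' @param flow list of flow fields (each with matrices `u`, `v` in
#'   px/frame), e.g. from [estimate_flow()] or a generated series.
#' @return List: `x`, `y` (arrays nx x ny x n_frames, px), `truncated`
#'   (logical matrix).
#' @export
reconstruct_trajectories <- function(flow) {
  if (length(flow) < 1L) stop("reconstruct_trajectories: need >= 1 flow field")
  d <- dim(flow[[1]]$u)
  nt <- length(flow) + 1L
  X <- array(NA_real_, c(d, nt)); Y <- array(NA_real_, c(d, nt))
  gx <- matrix(seq_len(d[1]), d[1], d[2])
  gy <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  X[, , 1] <- gx; Y[, , 1] <- gy
  trunc <- matrix(FALSE, d[1], d[2])
  cx <- gx; cy <- gy
  for (t in seq_along(flow)) {
    du <- matrix(bilinear_sample(flow[[t]]$u, cx, cy), d[1], d[2])
    dv <- matrix(bilinear_sample(flow[[t]]$v, cx, cy), d[1], d[2])
    cx <- cx + du; cy <- cy + dv
    out <- cx < 1 | cx > d[1] | cy < 1 | cy > d[2]
    trunc <- trunc | out
    cx <- pmin(pmax(cx, 1), d[1]); cy <- pmin(pmax(cy, 1), d[2])
    X[, , t + 1L] <- cx; Y[, , t + 1L] <- cy
  }
  list(x = X, y = Y, truncated = trunc)
}

#' Time-averaged mean square displacement of a trajectory
#'
#' MSD(tau) = mean over t of |r(t + tau) - r(t)|^2 for tau = 1..n-1 frames.
#'
#' @param pos matrix (n_frames x 2) of positions (any length unit).
#' @param dt frame interval, s.
#' @param max_lag largest lag in frames (default n - 1).
#' @return data.frame: `tau_s`, `msd` (squared input units); the trajectory
#'   length is kept in attribute `"n_frames"`.
#' @export
compute_msd <- function(pos, dt = 1, max_lag = NULL) {
  n <- nrow(pos)
  if (n < 3L) stop("compute_msd: trajectory too short (need >= 3 points)")
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- min(max_lag, n - 1L)
  msd <- vapply(seq_len(max_lag), function(k) {
    d <- pos[(k + 1L):n, , drop = FALSE] - pos[seq_len(n - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  out <- data.frame(tau_s = seq_len(max_lag) * dt, msd = msd)
  attr(out, "n_frames") <- n
  out
}

## Relative covariance of the time-averaged MSD of 2D Brownian motion:
## Cov[MSD(tau_i), MSD(tau_j)] / (MSD(tau_i) MSD(tau_j)) for a trajectory of
## n_frames positions, estimated once by Monte Carlo (scale-free) and cached.
## The MSD bins of one trajectory are strongly correlated; this matrix is
## what makes model comparison on MSD curves statistically meaningful.
.msd_cov_cache <- new.env(parent = emptyenv())
msd_rel_cov <- function(n_frames, n_lags, n_sim = 1500L) {
  key <- paste(n_frames, n_lags, sep = "_")
  if (!is.null(.msd_cov_cache[[key]])) return(.msd_cov_cache[[key]])
  C <- with_seed(181731L, {
    ms <- replicate(n_sim, {
      p <- cbind(cumsum(stats::rnorm(n_frames)),
                 cumsum(stats::rnorm(n_frames)))
      vapply(seq_len(n_lags), function(k) {
        d <- p[(k + 1L):n_frames, , drop = FALSE] -
          p[seq_len(n_frames - k), , drop = FALSE]
        mean(rowSums(d^2))
      }, numeric(1))
    })
    if (n_lags == 1L) ms <- matrix(ms, 1L)
    S <- stats::cov(t(ms))
    m <- rowMeans(ms)
    S / outer(m, m)
  })
  .msd_cov_cache[[key]] <- C
  C
}

## the five MSD model formulas; tau in s, parameters in um/s units
msd_model_value <- function(model, tau, p) {
  switch(model,
         D   = 4 * p["D"] * tau + p["o"],
         DA  = 4 * p["D"] * tau^p["alpha"] + p["o"],
         V   = p["v"]^2 * tau^2 + p["o"],
         DV  = 4 * p["D"] * tau + p["v"]^2 * tau^2 + p["o"],
         DAV = 4 * p["D"] * tau^p["alpha"] + p["v"]^2 * tau^2 + p["o"],
         stop("unknown model ", model))
}

msd_model_pars <- list(D = c("D", "o"), DA = c("D", "alpha", "o"),
                       V = c("v", "o"), DV = c("D", "v", "o"),
                       DAV = c("D", "alpha", "v", "o"))

## bounded least squares for one model with optional multi-start.
## Starting values are floored at a small fraction of the data scale: the
## Levenberg-Marquardt finite-difference step is relative to the parameter,
## so a start at ~0 freezes that parameter (zero Jacobian column).
fit_one_msd_model <- function(model, tau, msd, starts) {
  pars <- msd_model_pars[[model]]
  lower <- c(D = 0, alpha = 1e-3, v = 0, o = 0)[pars]
  upper <- c(D = Inf, alpha = 2, v = Inf, o = Inf)[pars]
  s_msd <- max(msd, 1e-300)
  st_floor <- c(D = 1e-4 * s_msd / (4 * max(tau)),
                alpha = 1e-3,
                v = 1e-4 * sqrt(s_msd) / max(tau),
                o = 1e-4 * s_msd)[pars]
  best <- NULL
  for (st in starts) {
    st <- pmax(pmin(st[pars], upper), lower, st_floor)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st,
                         lower = lower, upper = upper,
                         fn = function(p) {
                           names(p) <- pars
                           msd_model_value(model, tau, p) - msd
                         },
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = stats::setNames(as.numeric(fit$par), pars),
                   rss = rss, ok = fit$info %in% 1:4)
  }
  if (is.null(best))
    return(list(model = model, par = NULL, rss = Inf, ok = FALSE,
                n_par = length(pars)))
  c(best, list(model = model, n_par = length(pars)))
}

#' Fit the five MSD models to an MSD curve
#'
#' Least-squares fits of the five model forms
#' MSD_D = 4 D tau + o; MSD_DA = 4 D tau^alpha + o; MSD_V = v^2 tau^2 + o;
#' MSD_DV = 4 D tau + v^2 tau^2 + o; MSD_DAV = 4 D tau^alpha + v^2 tau^2 + o,
#' with bounds D, v, o >= 0 and alpha in (0, 2]. The anomalous exponent is
#' initialised from the log-log slope of the first lags, and each richer
#' model is additionally started from the solution of its nested restriction
#' so that nested models never fit worse than their restrictions.
#'
#' @param msd_curve data.frame with `tau_s` and `msd` (um^2), from
#'   [compute_msd()].
#' @return A `msd_fits` list of five fits (par, rss, ok, n_par), plus
#'   `tau_s`, `msd`, `n`.
#' @export
fit_msd_models <- function(msd_curve) {
  tau <- msd_curve$tau_s; msd <- msd_curve$msd
  if (length(tau) < 4L)
    stop("fit_msd_models: need >= 4 lag points for the 4-parameter model")
  # initial guesses from the data; o0 extrapolates the curve to tau = 0
  # (captures a localisation-noise offset)
  msd1 <- max(msd[1], 1e-12)
  nL <- length(tau)
  o0 <- max(2 * msd[1] - msd[2], 0)
  k <- min(3L, nL)
  slope <- if (all(msd[1:k] > 0))
    stats::coef(stats::lm(log(msd[1:k]) ~ log(tau[1:k])))[2] else 1
  a0 <- min(max(as.numeric(slope), 0.1), 2)
  D0 <- msd1 / (4 * tau[1])
  Da0 <- msd1 / (4 * tau[1]^a0)
  v0 <- sqrt(msd1) / tau[1]
  v_tail <- sqrt(max(msd[nL] - o0, 1e-12)) / tau[nL]
  base <- c(D = D0, alpha = a0, v = v0 / 2, o = 0)
  fits <- list()
  fits$D <- fit_one_msd_model("D", tau, msd, list(
    base, c(D = max(D0 - o0 / (4 * tau[1]), 0), alpha = a0, v = 0, o = o0)))
  fits$V <- fit_one_msd_model("V", tau, msd, list(
    c(v = v0, o = 0), c(v = v_tail, o = o0)))
  # seed richer models from their restrictions (nested consistency)
  seed_da <- list(c(D = Da0, alpha = a0, o = 0),
                  c(D = max(Da0 - o0 / (4 * tau[1]^a0), 0), alpha = a0, o = o0))
  if (fits$D$ok) seed_da <- c(seed_da,
    list(c(D = fits$D$par[["D"]], alpha = 1, o = fits$D$par[["o"]])))
  fits$DA <- fit_one_msd_model("DA", tau, msd, seed_da)
  seed_dv <- list(c(D = D0 / 2, v = v0 / 2, o = 0))
  if (fits$D$ok) seed_dv <- c(seed_dv,
    list(c(D = fits$D$par[["D"]], v = 1e-9, o = fits$D$par[["o"]])))
  if (fits$V$ok) seed_dv <- c(seed_dv,
    list(c(D = 1e-12, v = fits$V$par[["v"]], o = fits$V$par[["o"]])))
  fits$DV <- fit_one_msd_model("DV", tau, msd, seed_dv)
  seed_dav <- list(c(D = Da0, alpha = a0, v = v0 / 2, o = 0))
  if (fits$DA$ok) seed_dav <- c(seed_dav,
    list(c(D = fits$DA$par[["D"]], alpha = fits$DA$par[["alpha"]], v = 1e-9,
           o = fits$DA$par[["o"]])))
  if (fits$DV$ok) seed_dav <- c(seed_dav,
    list(c(D = fits$DV$par[["D"]], alpha = 1, v = fits$DV$par[["v"]],
           o = fits$DV$par[["o"]])))
  fits$DAV <- fit_one_msd_model("DAV", tau, msd, seed_dav)
  nf <- attr(msd_curve, "n_frames")
  structure(list(fits = fits, tau_s = tau, msd = msd, n = length(tau),
                 n_frames = if (is.null(nf)) length(tau) + 1L else nf),
            class = "msd_fits")
}

#' Select the best MSD model by Bayesian model comparison
#'
#' The default `"evidence"` criterion accounts for the strong correlation
#' between the lag bins of a time-averaged MSD curve: each candidate is
#' refitted by generalized least squares under the Monte-Carlo covariance of
#' the time-averaged MSD (the relative covariance of Brownian motion, scaled
#' by a smooth model-free reference curve common to all candidates) and
#' scored by chi^2 + 2 k log(n) -- a Gaussian log-likelihood with a
#' conservative Occam penalty of 2 log(n) per parameter standing in for the
#' parameter-volume factor of the model evidence. Ignoring the bin
#' correlations (plain `"BIC"`/`"AIC"` on raw residuals, also available)
#' systematically over-selects the anomalous-exponent models, which absorb
#' the smooth realization-to-realization wiggle of a single trajectory's
#' MSD. Ties resolve to the simpler model.
#'
#' @param fits a `msd_fits` from [fit_msd_models()].
#' @param criterion `"evidence"` (default), `"BIC"` or `"AIC"`.
#' @return List: `model` (winner id, or NA if all fits failed), `par`,
#'   `scores` (named per model), `rss` (unweighted RSS of the winner).
#' @export
select_model <- function(fits, criterion = c("evidence", "BIC", "AIC")) {
  criterion <- match.arg(criterion)
  n <- fits$n
  order_simple <- c("D", "V", "DA", "DV", "DAV")  # by parameter count
  if (criterion == "evidence") {
    scores <- gls_evidence_scores(fits, order_simple)
  } else {
    # floor the RSS at numerical noise so that exact fits score as ties and
    # the complexity penalty decides (simpler model wins)
    rss_floor <- n * (1e-6 * mean(abs(fits$msd)) + 1e-300)^2
    scores <- vapply(order_simple, function(m) {
      f <- fits$fits[[m]]
      if (!f$ok || !is.finite(f$rss)) return(Inf)
      rss <- max(f$rss, rss_floor)
      pen <- if (criterion == "BIC") f$n_par * log(n) else 2 * f$n_par
      n * log(rss / n) + pen
    }, numeric(1))
  }
  if (all(!is.finite(scores)))
    return(list(model = NA_character_, par = NULL, scores = scores,
                rss = NA_real_))
  win <- order_simple[which.min(scores)]  # which.min takes first on ties
  f <- fits$fits[[win]]
  par <- if (!is.null(attr(scores, "par")[[win]])) attr(scores, "par")[[win]]
         else f$par
  list(model = win, par = par, scores = scores, rss = f$rss)
}

## GLS scores: chi^2 under a common TA-MSD covariance + 2k log n.
## The covariance is the Brownian relative covariance scaled by a smooth
## model-free reference curve (the most flexible candidate's fit), shared by
## all candidates so that the Gaussian normalisation cancels in comparison.
gls_evidence_scores <- function(fits, models) {
  tau <- fits$tau_s; msd <- fits$msd; n <- fits$n
  C <- msd_rel_cov(fits$n_frames, n)
  ref <- if (fits$fits$DAV$ok && !is.null(fits$fits$DAV$par))
    msd_model_value("DAV", tau, fits$fits$DAV$par) else msd
  y <- pmax(ref, 1e-12 * max(msd, 1e-300))
  Sig <- C * outer(y, y) + diag((1e-8 * mean(y))^2 + 1e-300, n)
  L <- tryCatch(t(chol(Sig)), error = function(e) NULL)
  pars_out <- stats::setNames(vector("list", length(models)), models)
  if (is.null(L)) {
    scores <- rep(Inf, length(models))
    attr(scores, "par") <- pars_out
    return(scores)
  }
  scores <- vapply(models, function(m) {
    f <- fits$fits[[m]]
    if (!f$ok || is.null(f$par)) return(Inf)
    pr <- msd_model_pars[[m]]
    lower <- c(D = 0, alpha = 1e-3, v = 0, o = 0)[pr]
    upper <- c(D = Inf, alpha = 2, v = Inf, o = Inf)[pr]
    s_msd <- max(msd, 1e-300)
    st_floor <- c(D = 1e-4 * s_msd / (4 * max(tau)), alpha = 1e-3,
                  v = 1e-4 * sqrt(s_msd) / max(tau), o = 1e-4 * s_msd)[pr]
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(pmax(pmin(f$par, upper), lower, st_floor),
                         lower = lower, upper = upper,
                         fn = function(p) {
                           names(p) <- pr
                           forwardsolve(L, msd_model_value(m, tau, p) - msd)
                         },
                         control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pars_out[[m]] <<- stats::setNames(as.numeric(fit$par), pr)
    sum(fit$fvec^2) + 2 * length(pr) * log(n)
  }, numeric(1))
  attr(scores, "par") <- pars_out
  scores
}

#' Per-pixel MSD model maps from a time series
#'
#' Runs the full per-pixel dynamics analysis: optical flow between
#' consecutive frames, trajectory reconstruction by forward integration,
#' time-averaged MSD per pixel (lags up to `msd_max_frac` of the series),
#' five-model fitting and information-criterion selection. Returns
#' categorical and parameter maps over the field.
#'
#' @param series array nx x ny x n_frames, or a precomputed flow list.
#' @param pixel_size nm (default 41).
#' @param frame_interval s (default 2).
#' @param msd_max_frac fraction of the series length used as maximum MSD lag
#'   (default 0.5; long-lag estimates are noisy).
#' @param msd_max_lag absolute cap on the number of MSD lags (default 15;
#'   the discriminating information is concentrated at short lags).
#' @param criterion model-selection criterion (see [select_model()]).
#' @param mask optional logical matrix restricting analysed pixels.
#' @param stride analyse every stride-th pixel (maps keep full shape, other
#'   pixels NA).
#' @param ... passed to [estimate_flow()] when `series` is a frame array.
#' @return A `parameter_maps` list: `model` (character matrix), `model_code`
#'   (integer matrix, 1=D 2=DA 3=V 4=DV 5=DAV), `D`, `alpha`, `v`, `offset`
#'   (matrices, um^2/s, -, um/s, um^2), `n_unclassified`.
#' @export
hid_pipeline <- function(series, pixel_size = 41, frame_interval = 2,
                         msd_max_frac = 0.5, msd_max_lag = 15L,
                         criterion = "evidence",
                         mask = NULL, stride = 1L, ...) {
  if (is.list(series) && !is.null(series[[1]]$u)) {
    flow <- series
  } else {
    stopifnot(length(dim(series)) == 3L)
    nt <- dim(series)[3]
    if (nt < 3L) stop("hid_pipeline: need >= 3 frames")
    flow <- lapply(seq_len(nt - 1L), function(t)
      estimate_flow(series[, , t], series[, , t + 1L], ...))
  }
  traj <- reconstruct_trajectories(flow)
  d <- dim(traj$x)[1:2]; nt <- dim(traj$x)[3]
  px_um <- pixel_size / 1000
  max_lag <- min(max(3L, floor((nt - 1L) * msd_max_frac)), msd_max_lag)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  model_ids <- c(D = 1L, DA = 2L, V = 3L, DV = 4L, DAV = 5L)
  mm <- matrix(NA_character_, d[1], d[2])
  code <- matrix(NA_integer_, d[1], d[2])
  Dm <- am <- vm <- om <- matrix(NA_real_, d[1], d[2])
  n_unc <- 0L
  sel_i <- seq(1L, d[1], by = stride); sel_j <- seq(1L, d[2], by = stride)
  for (i in sel_i) for (j in sel_j) {
    if (!mask[i, j]) next
    pos <- cbind(traj$x[i, j, ], traj$y[i, j, ]) * px_um
    curve <- compute_msd(pos, dt = frame_interval, max_lag = max_lag)
    if (nrow(curve) < 4L || all(curve$msd < 1e-20)) { n_unc <- n_unc + 1L; next }
    fits <- fit_msd_models(curve)
    sel <- select_model(fits, criterion = criterion)
    if (is.na(sel$model)) { n_unc <- n_unc + 1L; next }
    mm[i, j] <- sel$model
    code[i, j] <- model_ids[[sel$model]]
    p <- sel$par
    if ("D" %in% names(p)) Dm[i, j] <- p[["D"]]
    if ("alpha" %in% names(p)) am[i, j] <- p[["alpha"]]
    if ("v" %in% names(p)) vm[i, j] <- p[["v"]]
    om[i, j] <- p[["o"]]
  }
  structure(list(model = mm, model_code = code, D = Dm, alpha = am,
                 v = vm, offset = om, truncated = traj$truncated,
                 n_unclassified = n_unc,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "parameter_maps")
}
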