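#' Synthesise a Gaussian random field with Whittle-Matern correlation
#'
#' Spectral (FFT) synthesis on a periodic grid using the 2D Matern power
#' spectrum S(k) ~ (rho_c^-2 + |k|^2)^-(nu+1), which corresponds to the
#' Whittle-Matern correlation function with correlation length `rho_c` and
#' smoothness `nu`. The field is normalised to zero mean and unit variance.
#'
#' @param shape field size in pixels, length 2.
#' @param rho_c correlation length in pixels.
#' @param nu smoothness parameter (> 0).
#' @param seed optional RNG seed.
#' @return Matrix of the requested shape.
#' @export
matern_field <- function(shape, rho_c, nu, seed = NULL) {
  shape <- as.integer(rep_len(shape, 2L))
  if (rho_c <= 0 || nu <= 0) stop("matern_field: rho_c and nu must be positive")
  with_seed(seed, {
    kx <- 2 * pi * c(0:(shape[1] %/% 2), -((ceiling(shape[1] / 2) - 1):1)) / shape[1]
    ky <- 2 * pi * c(0:(shape[2] %/% 2), -((ceiling(shape[2] / 2) - 1):1)) / shape[2]
    k2 <- outer(kx^2, ky^2, "+")
    spec <- (1 / rho_c^2 + k2)^(-(nu + 1))
    w <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    f <- Re(stats::fft(stats::fft(w) * sqrt(spec), inverse = TRUE)) / prod(shape)
    f <- f - mean(f)
    f / stats::sd(f)
  })
}

#' Specification of synthetic chromatin motion
#'
#' Defines a 2D live-imaging experiment: a textured reference frame advected
#' frame-to-frame by a vector field whose direction has Whittle-Matern
#' spatial correlation (known `rho_c`, `nu`) and whose per-pixel displacement
#' magnitude follows an assigned dynamics model. Models: `"D"` free
#' diffusion, `"V"` directed drift; a per-pixel model map mixes them.
#'
#' Defaults follow the live-cell imaging conditions the analyses assume:
#' 41 nm pixels, 2 s frame interval, 20-frame series.
#'
#' @param field_shape pixels per axis, length 2.
#' @param pixel_size nm.
#' @param n_frames number of frames.
#' @param frame_interval s.
#' @param rho_c direction correlation length, pixels.
#' @param nu direction smoothness (dimensionless).
#' @param model `"D"` or `"V"`, or an integer matrix of `field_shape` with
#'   1 = D, 2 = V per pixel.
#' @param D diffusion coefficient, um^2/s.
#' @param v drift speed, um/s.
#' @param theta_sd sd of the direction angle field, radians.
#' @param texture_sigma texture correlation length of the reference frame, px.
#' @param noise_sd additive per-frame Gaussian noise (fraction of texture sd).
#' @param seed RNG seed.
#' @return A `motion_spec` list.
#' @export
motion_spec <- function(field_shape = c(64L, 64L), pixel_size = 41,
                        n_frames = 20L, frame_interval = 2,
                        rho_c = 10, nu = 1, model = "D",
                        D = 0.005, v = 0.02,
                        theta_sd = 0.5, texture_sigma = 2, noise_sd = 0.02,
                        seed = 1L) {
  if (nu <= 0 || rho_c <= 0) stop("motion_spec: rho_c and nu must be positive")
  if (D < 0 || v < 0) stop("motion_spec: D and v must be >= 0")
  if (n_frames < 1L) stop("motion_spec: n_frames must be >= 1")
  structure(list(field_shape = as.integer(rep_len(field_shape, 2L)),
                 pixel_size = pixel_size, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, rho_c = rho_c, nu = nu,
                 model = model, D = D, v = v, theta_sd = theta_sd,
                 texture_sigma = texture_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "motion_spec")
}

## bilinear sample of matrix m at fractional coordinates (x, y), 1-based,
## replicate-padded at the border
bilinear_sample <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(as.vector(x), 1), nx); y <- pmin(pmax(as.vector(y), 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Generate a flow-advected synthetic time series with known dynamics
#'
#' Per-pixel displacement at each frame transition is `magnitude * (cos
#' theta, sin theta)` where `theta` is a Matern-correlated direction field
#' (temporally persistent for drift pixels, redrawn each transition for
#' diffusive pixels) and the magnitude follows the assigned model: drift
#' pixels move `v * dt`, diffusive pixels take Rayleigh steps with scale
#' `sqrt(2 D dt)`. Frames are produced by backward-warping the previous
#' frame by the true flow; true per-pixel trajectories are returned.
#'
#' @param spec a [motion_spec()].
#' @return List with `frames` (array nx x ny x n_frames), `flow` (list of
#'   n_frames - 1 elements, each with matrices `u`, `v` in px/frame),
#'   `traj_x`, `traj_y` (arrays nx x ny x n_frames, positions in px),
#'   `theta0` (frame-0 direction field), and `meta` (list; includes
#'   `rho_c_identifiable`).
#' @export
generate_flow_series <- function(spec) {
  stopifnot(inherits(spec, "motion_spec"))
  sh <- spec$field_shape
  nt <- spec$n_frames
  dt <- spec$frame_interval
  px_um <- spec$pixel_size / 1000           # um per pixel
  identifiable <- spec$rho_c <= min(sh) / 2
  if (!identifiable)
    warning("rho_c = ", spec$rho_c, " px exceeds half the field extent; ",
            "correlation length not identifiable")
  model_map <- spec$model
  if (is.character(model_map) && length(model_map) == 1L)
    model_map <- matrix(match(model_map, c("D", "V")), sh[1], sh[2])
  stopifnot(all(model_map %in% 1:2))
  with_seed(spec$seed, {
    texture <- gaussian_blur(matrix(stats::rnorm(prod(sh)), sh[1], sh[2]),
                             spec$texture_sigma)
    texture <- (texture - min(texture)) / diff(range(texture)) + 0.2
    frames <- array(NA_real_, c(sh, nt))
    frames[, , 1] <- texture
    # persistent drift direction field; global offset is arbitrary
    theta_drift <- stats::runif(1, 0, 2 * pi) +
      spec$theta_sd * matern_field(sh, spec$rho_c, spec$nu)
    gx <- matrix(seq_len(sh[1]), sh[1], sh[2])
    gy <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
    traj_x <- array(NA_real_, c(sh, nt)); traj_y <- array(NA_real_, c(sh, nt))
    traj_x[, , 1] <- gx; traj_y[, , 1] <- gy
    flow <- vector("list", max(nt - 1L, 0L))
    v_step_px <- spec$v * dt / px_um        # drift step, px/frame
    d_scale_px <- sqrt(2 * spec$D * dt) / px_um  # per-axis step sd, px
    for (t in seq_len(nt - 1L)) {
      # fresh correlated direction field per transition; the uniform global
      # offset makes per-pixel step directions isotropic over time (so
      # diffusive pixels perform an unbiased random walk) without affecting
      # the rotation-invariant spatial correlation
      theta_t <- stats::runif(1, 0, 2 * pi) +
        spec$theta_sd * matern_field(sh, spec$rho_c, spec$nu)
      theta <- ifelse(model_map == 2L, theta_drift, theta_t)
      # |step| ~ Rayleigh(d_scale_px) + uniform direction = 2D Gaussian walk
      mag <- ifelse(model_map == 2L, v_step_px,
                    d_scale_px * sqrt(-2 * log(stats::runif(prod(sh)))))
      mag <- matrix(mag, sh[1], sh[2])
      u <- mag * cos(theta); v <- mag * sin(theta)
      flow[[t]] <- list(u = u, v = v)
      prev <- frames[, , t]
      warped <- bilinear_sample(prev, gx - u, gy - v)
      if (spec$noise_sd > 0)
        warped <- warped + stats::rnorm(length(warped),
                                        0, spec$noise_sd * stats::sd(texture))
      frames[, , t + 1L] <- matrix(warped, sh[1], sh[2])
      traj_x[, , t + 1L] <- traj_x[, , t] + u
      traj_y[, , t + 1L] <- traj_y[, , t] + v
    }
    list(frames = frames, flow = flow, traj_x = traj_x, traj_y = traj_y,
         theta0 = theta_drift,
         meta = list(rho_c_identifiable = identifiable,
                     pixel_size = spec$pixel_size,
                     frame_interval = dt, model_map = model_map))
  })
}

#' Simulate per-pixel trajectories under the five MSD dynamics models
#'
#' Generates 2D trajectories whose time-averaged mean square displacement
#' follows MSD(tau) = 4 D tau^alpha + v^2 tau^2 + 4 sigma_loc^2, i.e. the
#' D/DA/V/DV/DAV family: fractional Brownian motion per axis for the
#' diffusive part (exact covariance, Cholesky factorisation), a constant
#' random-direction drift, and i.i.d. Gaussian localisation noise that
#' produces the constant offset.
#'
#' @param model one of "D", "DA", "V", "DV", "DAV".
#' @param n number of trajectories.
#' @param n_frames frames per trajectory.
#' @param dt frame interval, s.
#' @param D diffusion coefficient, um^2/s (um^2/s^alpha for anomalous).
#' @param alpha anomalous exponent in (0, 2]; ignored unless model has "A".
#' @param v drift speed, um/s; ignored unless model has "V".
#' @param sigma_loc localisation noise sd per coordinate, um.
#' @param seed RNG seed.
#' @return List of `n` matrices (n_frames x 2), positions in um.
#' @export
simulate_trajectories <- function(model = c("D", "DA", "V", "DV", "DAV"),
                                  n = 100L, n_frames = 20L, dt = 2,
                                  D = 0.005, alpha = 0.5, v = 0.02,
                                  sigma_loc = 0, seed = 1L) {
  model <- match.arg(model)
  has_a <- model %in% c("DA", "DAV")
  has_v <- model %in% c("V", "DV", "DAV")
  has_d <- model != "V"
  a <- if (has_a) alpha else 1
  if (a <= 0 || a > 2) stop("alpha must be in (0, 2]")
  tt <- (seq_len(n_frames) - 1L) * dt
  L <- NULL
  if (has_d && D > 0) {
    # per-axis fBm covariance: E[X_s X_t] = D (s^a + t^a - |s-t|^a)
    C <- D * (outer(tt^a, tt^a, "+") - abs(outer(tt, tt, "-"))^a)
    C <- C + diag(1e-12 * max(diag(C) + 1), n_frames)
    L <- t(chol(C))
  }
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      pos <- matrix(0, n_frames, 2)
      if (!is.null(L))
        pos <- pos + cbind(L %*% stats::rnorm(n_frames),
                           L %*% stats::rnorm(n_frames))
      if (has_v && v > 0) {
        phi <- stats::runif(1, 0, 2 * pi)
        pos <- pos + outer(tt, c(v * cos(phi), v * sin(phi)))
      }
      if (sigma_loc > 0)
        pos <- pos + matrix(stats::rnorm(2 * n_frames, 0, sigma_loc),
                            n_frames, 2)
      pos
    })
  })
}
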