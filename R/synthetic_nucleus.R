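#' Specification of a synthetic nucleus
#'
#' Parameters of the ground-truth-known nuclear volume generator. The nucleus
#' is an ellipsoid containing curvilinear chains of spherical chromatin
#' domains (CDs) joined by thin linkers, bright chromocenters, and
#' signal-free nucleoli, imaged through an anisotropic Gaussian PSF with
#' additive Gaussian read noise.
#'
#' Defaults emulate 3D-SIM sampling of a mammalian nucleus: 40 nm lateral /
#' 80 nm axial voxels, CD diameters 250 +/- 30 nm (the bulk of chromatin
#' domains measures 200-300 nm across), PSF FWHM 120 nm lateral and 320 nm
#' axial converted to sigma via FWHM / (2 sqrt(2 log 2)) ~ FWHM / 2.355.
#'
#' @param volume_shape voxels per axis (x, y, z).
#' @param voxel_size nm per axis; may be anisotropic.
#' @param cd_diameter_mean,cd_diameter_sd CD diameter distribution, nm.
#' @param chain_count,cds_per_chain number of CD chains and CDs per chain.
#' @param linker_width linker tube diameter, nm.
#' @param chromocenter_count,chromocenter_diameter chromocenters (bright
#'   heterochromatin clusters), count and diameter in nm.
#' @param nucleolus_count,nucleolus_diameter nucleoli (signal-free), nm.
#' @param background_level,chromatin_peak_level intensity levels (a.u.).
#' @param noise_sd additive Gaussian noise sd (a.u.).
#' @param psf_fwhm_lateral,psf_fwhm_axial PSF full width at half maximum, nm.
#' @param seed integer RNG seed.
#' @return A `nucleus_spec` list.
#' @export
nucleus_spec <- function(volume_shape = c(96L, 96L, 48L),
                         voxel_size = c(40, 40, 80),
                         cd_diameter_mean = 250, cd_diameter_sd = 30,
                         chain_count = 60L, cds_per_chain = 16L,
                         linker_width = 80,
                         chromocenter_count = 2L, chromocenter_diameter = 500,
                         nucleolus_count = 1L, nucleolus_diameter = 800,
                         background_level = 100, chromatin_peak_level = 600,
                         noise_sd = 10,
                         psf_fwhm_lateral = 120, psf_fwhm_axial = 320,
                         seed = 1L) {
  spec <- list(volume_shape = as.integer(rep_len(volume_shape, 3L)),
               voxel_size = rep_len(as.numeric(voxel_size), 3L),
               cd_diameter_mean = cd_diameter_mean,
               cd_diameter_sd = cd_diameter_sd,
               chain_count = as.integer(chain_count),
               cds_per_chain = as.integer(cds_per_chain),
               linker_width = linker_width,
               chromocenter_count = as.integer(chromocenter_count),
               chromocenter_diameter = chromocenter_diameter,
               nucleolus_count = as.integer(nucleolus_count),
               nucleolus_diameter = nucleolus_diameter,
               background_level = background_level,
               chromatin_peak_level = chromatin_peak_level,
               noise_sd = noise_sd,
               psf_sigma_lateral = psf_fwhm_lateral / (2 * sqrt(2 * log(2))),
               psf_sigma_axial = psf_fwhm_axial / (2 * sqrt(2 * log(2))),
               seed = as.integer(seed))
  validate_nucleus_spec(spec)
  structure(spec, class = "nucleus_spec")
}

validate_nucleus_spec <- function(s) {
  pos <- c("voxel_size", "cd_diameter_mean", "linker_width",
           "background_level", "chromatin_peak_level")
  for (f in pos) if (any(s[[f]] <= 0))
    stop("nucleus_spec: `", f, "` must be positive")
  if (any(s$volume_shape < 4L)) stop("nucleus_spec: `volume_shape` too small")
  if (s$cd_diameter_mean - 2 * s$cd_diameter_sd <= 0)
    stop("nucleus_spec: cd_diameter_mean - 2*cd_diameter_sd must be positive")
  if (s$noise_sd < 0) stop("nucleus_spec: `noise_sd` must be >= 0")
  ext <- s$volume_shape * s$voxel_size
  if (s$chain_count > 0L && s$cd_diameter_mean > min(ext) / 3)
    stop("nucleus_spec: `cd_diameter_mean` too large for `volume_shape`")
  if (s$nucleolus_count > 0L && s$nucleolus_diameter > min(ext) / 2)
    stop("nucleus_spec: `nucleolus_diameter` too large for `volume_shape`")
  if (s$chromocenter_count > 0L && s$chromocenter_diameter > min(ext) / 2)
    stop("nucleus_spec: `chromocenter_diameter` too large for `volume_shape`")
  invisible(s)
}

## physical voxel-centre coordinate grids (nm), as three arrays
coord_grids <- function(shape, voxel) {
  gx <- (seq_len(shape[1]) - 1) * voxel[1]
  gy <- (seq_len(shape[2]) - 1) * voxel[2]
  gz <- (seq_len(shape[3]) - 1) * voxel[3]
  list(x = array(rep(gx, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(gy, each = shape[1]), times = shape[3]), shape),
       z = array(rep(gz, each = shape[1] * shape[2]), shape))
}

## mark voxels inside a sphere (centre nm, diameter nm); returns linear indices
sphere_indices <- function(shape, voxel, centre, diameter) {
  r <- diameter / 2
  lo <- pmax(1L, floor((centre - r) / voxel) + 1L)
  hi <- pmin(shape, ceiling((centre + r) / voxel) + 1L)
  if (any(lo > hi)) return(integer(0))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  cx <- (ix - 1) * voxel[1] - centre[1]
  cy <- (iy - 1) * voxel[2] - centre[2]
  cz <- (iz - 1) * voxel[3] - centre[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  sel <- which(d2 <= r^2, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(integer(0))
  (ix[sel[, 1]] - 1L) + (iy[sel[, 2]] - 1L) * shape[1] +
    (iz[sel[, 3]] - 1L) * shape[1] * shape[2] + 1L
}

## ellipsoid mask given centre and semi-axes in nm
ellipsoid_mask <- function(shape, voxel, centre, semi) {
  g <- coord_grids(shape, voxel)
  ((g$x - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
    ((g$z - centre[3]) / semi[3])^2 <= 1
}

## smoothed random walk of CD centres inside a shrunken ellipsoid
chain_walk <- function(n, centre, semi, step_nm) {
  inside <- function(p) sum(((p - centre) / semi)^2) <= 1
  repeat {
    p <- centre + (stats::runif(3) * 2 - 1) * semi * 0.8
    if (inside(p)) break
  }
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- p
  for (i in seq_len(n - 1L)) {
    for (try in 1:50) {
      ndir <- dir + stats::rnorm(3, sd = 0.45)   # smooth direction change
      ndir <- ndir / sqrt(sum(ndir^2))
      cand <- pts[i, ] + ndir * step_nm
      if (inside(cand)) { dir <- ndir; pts[i + 1L, ] <- cand; break }
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    }
    if (is.na(pts[i + 1L, 1])) pts[i + 1L, ] <- pts[i, ]  # stuck: stay
  }
  pts
}

#' Generate a synthetic nucleus with known chromatin topography
#'
#' Builds an ellipsoidal nuclear mask containing curvilinear chains of
#' spherical CDs connected by thin linkers, chromocenters at peak intensity
#' and nucleoli at background intensity; convolves with the anisotropic
#' Gaussian PSF and adds Gaussian noise. The returned ground truth assigns
#' class 1 to the interchromatin compartment and nucleoli, class 2 to
#' linkers and outer CD shells, class 3 to inner CD shells (perichromatin),
#' classes 4-5 to CD cores (varying per domain), and classes 6-7 to
#' chromocenter rims and cores.
#'
#' @param spec a [nucleus_spec()].
#' @return List with elements `dna` (a [volume_image()]), `classmap`
#'   (ground-truth class labels, 0 outside the nucleus), `nucleolus_mask`,
#'   `nuclear_mask`, and `cd_table` (data.frame of true CD centres and
#'   diameters in nm).
#' @export
generate_nucleus <- function(spec) {
  stopifnot(inherits(spec, "nucleus_spec"))
  validate_nucleus_spec(spec)
  shape <- spec$volume_shape; voxel <- spec$voxel_size
  ext <- shape * voxel
  centre <- (shape - 1) * voxel / 2
  semi <- 0.42 * ext
  with_seed(spec$seed, {
    nuc <- ellipsoid_mask(shape, voxel, centre, semi)
    classes <- array(0L, shape)
    classes[nuc] <- 1L                     # IC by default
    cd_centres <- NULL; cd_diams <- NULL
    # chains of CDs with linkers
    if (spec$chain_count > 0L) {
      for (ch in seq_len(spec$chain_count)) {
        pts <- chain_walk(spec$cds_per_chain, centre, semi * 0.92,
                          step_nm = spec$cd_diameter_mean)
        diams <- pmax(spec$cd_diameter_mean - 2 * spec$cd_diameter_sd,
                      stats::rnorm(nrow(pts), spec$cd_diameter_mean,
                                   spec$cd_diameter_sd))
        cd_centres <- rbind(cd_centres, pts)
        cd_diams <- c(cd_diams, diams)
        # linkers: sample points along segments, stamp small spheres
        if (nrow(pts) > 1L && spec$linker_width > 0) {
          for (i in seq_len(nrow(pts) - 1L)) {
            seg <- pts[i + 1L, ] - pts[i, ]
            len <- sqrt(sum(seg^2))
            if (len < 1e-9) next
            nstep <- max(2L, ceiling(len / (spec$linker_width / 2)))
            for (tt in seq(0, 1, length.out = nstep)) {
              idx <- sphere_indices(shape, voxel, pts[i, ] + tt * seg,
                                    spec$linker_width)
              idx <- idx[classes[idx] == 1L]
              classes[idx] <- 2L
            }
          }
        }
      }
      # CD spheres: two perichromatin shells, then a core of intermediate
      # (class 4) or dense (class 5) chromatin, varying per domain
      core_class <- 4L + (stats::runif(length(cd_diams)) < 0.5)
      for (i in seq_along(cd_diams)) {
        idx <- sphere_indices(shape, voxel, cd_centres[i, ], cd_diams[i])
        idx <- idx[classes[idx] %in% c(1L, 2L)]
        classes[idx] <- 2L
        mid <- sphere_indices(shape, voxel, cd_centres[i, ], 0.85 * cd_diams[i])
        mid <- mid[classes[mid] %in% c(1L, 2L)]
        classes[mid] <- 3L
        core <- sphere_indices(shape, voxel, cd_centres[i, ], 0.6 * cd_diams[i])
        core <- core[classes[core] %in% c(1L, 2L, 3L)]
        classes[core] <- core_class[i]
      }
    }
    # chromocenters: bright heterochromatin blobs (class-6 rim, class-7 core)
    if (spec$chromocenter_count > 0L) {
      for (i in seq_len(spec$chromocenter_count)) {
        for (try in 1:100) {
          p <- centre + (stats::runif(3) * 2 - 1) * semi * 0.6
          if (sum(((p - centre) / semi)^2) <= 0.8) break
        }
        idx <- sphere_indices(shape, voxel, p, spec$chromocenter_diameter)
        idx <- idx[classes[idx] > 0L]
        classes[idx] <- 6L
        core <- sphere_indices(shape, voxel, p, 0.8 * spec$chromocenter_diameter)
        core <- core[classes[core] == 6L]
        classes[core] <- 7L
      }
    }
    # nucleoli: signal-free rounds; class 1 (no detectable chromatin)
    nucleolus <- array(FALSE, shape)
    if (spec$nucleolus_count > 0L) {
      for (i in seq_len(spec$nucleolus_count)) {
        for (try in 1:100) {
          p <- centre + (stats::runif(3) * 2 - 1) * semi * 0.4
          if (sum(((p - centre) / semi)^2) <= 0.5) break
        }
        idx <- sphere_indices(shape, voxel, p, spec$nucleolus_diameter)
        idx <- idx[classes[idx] > 0L]
        nucleolus[idx] <- TRUE
        classes[idx] <- 1L
      }
    }
    # intensity: background outside and in IC/nucleoli, ramp to peak by class
    lev <- class_intensity_levels(spec$background_level,
                                  spec$chromatin_peak_level)
    vol <- array(spec$background_level, shape)
    for (k in 2:7) vol[classes == k] <- lev[k]
    blurred <- gaussian_blur(vol, c(spec$psf_sigma_lateral / voxel[1],
                                    spec$psf_sigma_lateral / voxel[2],
                                    spec$psf_sigma_axial / voxel[3]))
    if (spec$noise_sd > 0)
      blurred <- blurred + stats::rnorm(length(blurred), 0, spec$noise_sd)
    cd_table <- if (is.null(cd_centres)) {
      data.frame(x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
                 diameter_nm = numeric(0))
    } else {
      data.frame(x_nm = cd_centres[, 1], y_nm = cd_centres[, 2],
                 z_nm = cd_centres[, 3], diameter_nm = cd_diams)
    }
    list(dna = volume_image(blurred, voxel, "dna"),
         classmap = classes,
         nucleolus_mask = nucleolus,
         nuclear_mask = nuc,
         cd_table = cd_table)
  })
}

## intensity level ladder from background (class 1) to peak (class 7)
class_intensity_levels <- function(background, peak) {
  background + (0:6) / 6 * (peak - background)
}

#' Synthetic nucleus of concentric equal-volume intensity plateaus
#'
#' An ellipsoidal nucleus whose interior is divided into `n_classes`
#' concentric shells of approximately equal volume, each at a distinct
#' intensity plateau. Used as a construction-based oracle for the intensity
#' classifier: the true class of every voxel is known.
#'
#' @param shape voxels per axis.
#' @param voxel_size nm per axis.
#' @param n_classes number of plateaus.
#' @param background_level,peak_level intensity ladder endpoints.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return List with `dna` ([volume_image()]), `true_classes` (array, 0
#'   outside), `nuclear_mask`.
#' @export
plateau_nucleus <- function(shape = c(64L, 64L, 32L),
                            voxel_size = c(40, 40, 80),
                            n_classes = 7L,
                            background_level = 100, peak_level = 800,
                            noise_sd = 0, seed = 1L) {
  shape <- as.integer(rep_len(shape, 3L))
  voxel <- rep_len(as.numeric(voxel_size), 3L)
  centre <- (shape - 1) * voxel / 2
  semi <- 0.44 * shape * voxel
  g <- coord_grids(shape, voxel)
  rho <- sqrt(((g$x - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
              ((g$z - centre[3]) / semi[3])^2)
  nuc <- rho <= 1
  # equal-volume concentric shells: class k occupies rho^3 in ((k-1)/n, k/n]
  frac <- pmin(rho^3, 1)
  cls <- array(0L, shape)
  cls[nuc] <- pmin(n_classes, floor(frac[nuc] * n_classes) + 1L)
  lev <- background_level + (seq_len(n_classes) - 1) / (n_classes - 1) *
    (peak_level - background_level)
  vol <- array(background_level, shape)
  for (k in seq_len(n_classes)) vol[cls == k] <- lev[k]
  with_seed(seed, {
    if (noise_sd > 0) vol <- vol + stats::rnorm(length(vol), 0, noise_sd)
    list(dna = volume_image(vol, voxel, "dna"), true_classes = cls,
         nuclear_mask = nuc)
  })
}

#' Specification for synthetic marker foci placement
#'
#' @param n_foci number of foci.
#' @param class_weights 7 nonnegative relative placement affinities, one per
#'   chromatin class.
#' @param spot_amplitude peak intensity of a rendered spot (a.u.).
#' @param spot_sigma isotropic Gaussian spot sigma, nm.
#' @param mcnr_mean,mcnr_sd simulated per-spot modulation contrast-to-noise
#'   ratio distribution.
#' @param seed RNG seed.
#' @return A `foci_spec` list.
#' @export
foci_spec <- function(n_foci = 500L, class_weights = rep(1, 7),
                      spot_amplitude = 1000, spot_sigma = 60,
                      mcnr_mean = 12, mcnr_sd = 3, seed = 1L) {
  if (n_foci < 0) stop("foci_spec: n_foci must be >= 0")
  if (length(class_weights) != 7L || any(class_weights < 0) ||
      sum(class_weights) <= 0)
    stop("foci_spec: class_weights must be 7 nonnegative numbers with positive sum")
  structure(list(n_foci = as.integer(n_foci), class_weights = class_weights,
                 spot_amplitude = spot_amplitude, spot_sigma = spot_sigma,
                 mcnr_mean = mcnr_mean, mcnr_sd = mcnr_sd,
                 seed = as.integer(seed)),
            class = "foci_spec")
}

#' Place synthetic marker foci with class-biased affinity
#'
#' Focus locations are drawn from the nuclear voxels with probability
#' proportional to `class_weights[class]`, jittered uniformly within the
#' voxel, and rendered as 3D Gaussian spots. A per-spot MCNR value is drawn
#' and painted into an MCNR map around the spot.
#'
#' @param classmap integer array of chromatin classes (0 outside nucleus).
#' @param spec a [foci_spec()].
#' @param voxel_size nm per axis.
#' @return List with `marker` ([volume_image()]), `truth` (data.frame:
#'   x_nm, y_nm, z_nm, class, mcnr), `mcnr_map` ([volume_image()]).
#' @export
place_foci <- function(classmap, spec, voxel_size) {
  stopifnot(inherits(spec, "foci_spec"))
  shape <- dim(classmap)
  voxel <- rep_len(as.numeric(voxel_size), 3L)
  present <- sort(unique(classmap[classmap > 0L]))
  wanted <- which(spec$class_weights > 0)
  missing <- setdiff(wanted, present)
  if (length(missing))
    stop("place_foci: nonzero weight on class(es) absent from the map: ",
         paste(missing, collapse = ", "))
  with_seed(spec$seed, {
    marker <- array(0, shape)
    mcnr <- array(0, shape)
    if (spec$n_foci == 0L) {
      truth <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                          z_nm = numeric(0), class = integer(0),
                          mcnr = numeric(0))
      return(list(marker = volume_image(marker, voxel, "marker"),
                  truth = truth,
                  mcnr_map = volume_image(mcnr, voxel, "mcnr")))
    }
    inside <- which(classmap > 0L)
    w <- spec$class_weights[classmap[inside]]
    pick <- sample(inside, spec$n_foci, replace = TRUE, prob = w)
    ai <- arrayInd(pick, shape)
    jit <- matrix(stats::runif(3 * spec$n_foci, -0.5, 0.5), ncol = 3)
    cen <- sweep((ai - 1) + jit, 2, voxel, "*")
    mcnr_vals <- pmax(0, stats::rnorm(spec$n_foci, spec$mcnr_mean, spec$mcnr_sd))
    r_nm <- 3 * spec$spot_sigma
    for (i in seq_len(spec$n_foci)) {
      idx <- sphere_indices(shape, voxel, cen[i, ], 2 * r_nm)
      if (!length(idx)) next
      aidx <- arrayInd(idx, shape)
      d2 <- ((aidx[, 1] - 1) * voxel[1] - cen[i, 1])^2 +
            ((aidx[, 2] - 1) * voxel[2] - cen[i, 2])^2 +
            ((aidx[, 3] - 1) * voxel[3] - cen[i, 3])^2
      marker[idx] <- marker[idx] +
        spec$spot_amplitude * exp(-d2 / (2 * spec$spot_sigma^2))
      mcnr[idx] <- pmax(mcnr[idx], mcnr_vals[i])
    }
    truth <- data.frame(x_nm = cen[, 1], y_nm = cen[, 2], z_nm = cen[, 3],
                        class = classmap[pick], mcnr = mcnr_vals)
    list(marker = volume_image(marker, voxel, "marker"),
         truth = truth,
         mcnr_map = volume_image(mcnr, voxel, "mcnr"))
  })
}

#' Project and blur a high-resolution segmentation to SIM-like resolution
#'
#' Average-intensity projection over `n_sections` consecutive planes followed
#' by Gaussian filtering, emulating how an electron-microscopy binary
#' segmentation is degraded to match optical super-resolution data.
#'
#' @param vol 3D array or [volume_image()] (e.g. a binary segmentation).
#' @param n_sections number of consecutive z planes to average (>= 1).
#' @param sigma Gaussian sigma in voxels for the lateral axes (length 1 or 2;
#'   0 disables filtering).
#' @param start first plane of the projection window (default 1).
#' @return 2D matrix: the blurred average-intensity projection.
#' @export
sim_mimic <- function(vol, n_sections, sigma = 0, start = 1L) {
  v <- vol_values(vol)
  stopifnot(length(dim(v)) == 3L)
  nz <- dim(v)[3]
  if (n_sections < 1L || start < 1L || start + n_sections - 1L > nz)
    stop("sim_mimic: projection window [", start, ", ",
         start + n_sections - 1L, "] outside axial extent ", nz)
  proj <- apply(v[, , start:(start + n_sections - 1L), drop = FALSE],
                c(1, 2), mean)
  sigma <- rep_len(sigma, 2L)
  if (any(sigma > 0)) proj <- gaussian_blur(proj, sigma)
  proj
}
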