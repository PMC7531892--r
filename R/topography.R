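#' Segment the nucleus from a DNA counterstain volume
#'
#' Gaussian-smoothed Otsu threshold, morphological closing (the chromatin
#' signal is a reticular chain whose interchromatin gaps belong to the
#' nucleus), 3D hole filling, and retention of the largest connected
#' component.
#'
#' @param dna a [volume_image()] (or bare array) of the counterstain channel.
#' @param smooth_sigma smoothing sigma in voxels before thresholding.
#' @param close_radius closing radius in voxels (0 disables).
#' @return Logical array: the nuclear mask.
#' @export
segment_nucleus <- function(dna, smooth_sigma = 1, close_radius = 2) {
  v <- vol_values(dna)
  if (diff(range(v)) <= 0)
    stop("segment_nucleus: constant image, no nucleus found")
  sm <- if (smooth_sigma > 0) gaussian_blur(v, smooth_sigma) else v
  thr <- otsu_threshold(sm)
  mask <- sm >= thr
  if (!any(mask)) stop("segment_nucleus: no nucleus found")
  if (close_radius > 0 && !all(mask)) {
    # dilation by <= r, erosion by > r: at radius 2 the digital-ball
    # asymmetry cancels and closing is volume-neutral on smooth boundaries
    dil <- distance_to_set(mask, 1) <= close_radius
    if (any(!dil)) mask <- distance_to_set(!dil, 1) > close_radius
    else mask <- dil
  }
  mask <- fill_holes(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Calibrate intensities against the extranuclear background mode
#'
#' The modal intensity of the voxels outside the nuclear mask (the large
#' background volume) is subtracted from the whole volume and negative
#' values are clipped at zero, anchoring the lower end of the dynamic range
#' of each micrograph.
#'
#' @param dna a [volume_image()] or array.
#' @param mask logical nuclear mask.
#' @param bins histogram bins for the mode estimate.
#' @return A [volume_image()] with attribute-free calibrated values; the
#'   subtracted mode is attached as attribute `"calibration"` of the values.
#' @export
calibrate_intensity <- function(dna, mask, bins = 256L) {
  v <- vol_values(dna)
  if (!any(mask) || all(mask))
    stop("calibrate_intensity: mask must be nonempty and not full-frame")
  outside <- v[!mask]
  if (length(outside) == 0L) stop("calibrate_intensity: mode undefined")
  m <- hist_mode(outside, bins = bins)
  out <- pmax(v - m, 0)
  res <- if (inherits(dna, "volume_image"))
    volume_image(out, dna$voxel_size, dna$channel) else
    volume_image(out, 1)
  res$calibration <- m
  res
}

#' Classify nuclear voxels into ordered chromatin intensity classes
#'
#' Fits a Gaussian mixture to the calibrated in-mask intensities, orders the
#' components by mean, and assigns each voxel to a class; classes are then
#' spatially regularised by iterated conditional modes (ICM) with a
#' 6-neighbourhood Potts penalty. Class 1 collects the non-detectable
#' chromatin signal (interchromatin compartment, including nucleoli);
#' increasing classes have strictly increasing mean intensity up to the
#' densest heterochromatin.
#'
#' @param dna calibrated [volume_image()] (see [calibrate_intensity()]).
#' @param mask logical nuclear mask.
#' @param n_classes number of classes (default 7).
#' @param icm_beta Potts smoothing weight (0 disables smoothing).
#' @param icm_iter ICM sweeps.
#' @param max_fit_voxels subsample cap for the mixture fit.
#' @param seed RNG seed for the subsample.
#' @return A `chromatin_classmap`: list with `labels` (integer array, 0
#'   outside the mask), `voxel_size`, `class_volumes` (um^3, length
#'   `n_classes`), `mixture` (means, sds, proportions), `n_classes`.
#' @importFrom mclust Mclust mclustBIC
#' @export
classify_chromatin <- function(dna, mask, n_classes = 7L, icm_beta = 0.7,
                               icm_iter = 3L, max_fit_voxels = 30000L,
                               seed = 1L) {
  v <- vol_values(dna)
  voxel <- vol_voxel(dna, default = 1)
  if (!any(mask)) stop("classify_chromatin: empty mask")
  x <- v[mask]
  if (length(unique(round(x, 10))) < n_classes)
    stop("classify_chromatin: fewer distinct intensity levels than classes; ",
         "reduce n_classes")
  xs <- with_seed(seed,
                  if (length(x) > max_fit_voxels) sample(x, max_fit_voxels) else x)
  # Mclust draws its initialisation subset from the ambient RNG for large n
  fit <- with_seed(seed, tryCatch(
    Mclust(xs, G = n_classes, modelNames = "V", verbose = FALSE),
    error = function(e) NULL))
  if (!is.null(fit) && !is.null(fit$parameters)) {
    mu <- fit$parameters$mean
    sd_ <- sqrt(fit$parameters$variance$sigmasq)
    pro <- fit$parameters$pro
  } else {
    # EM degenerates on (near-)discrete intensities (e.g. noise-free
    # plateaus, zero within-class variance); k-means centres with pooled
    # within-cluster spread are the exact classifier there
    km <- with_seed(seed,
                    stats::kmeans(xs, centers = stats::quantile(
                      xs, probs = seq(0.5, n_classes - 0.5) / n_classes),
                      iter.max = 50))
    mu <- as.numeric(km$centers)
    sd_ <- vapply(seq_len(n_classes), function(k) {
      s <- stats::sd(xs[km$cluster == k])
      if (!is.finite(s)) 0 else s
    }, numeric(1))
    pro <- as.numeric(km$size) / length(xs)
  }
  sd_ <- rep_len(pmax(sd_, 1e-6 * max(abs(mu) + 1)), n_classes)
  ord <- order(mu)
  mu <- mu[ord]; sd_ <- sd_[ord]; pro <- pro[ord]
  # per-voxel log posterior per class (vectorised over classes)
  loglik <- vapply(seq_len(n_classes), function(k)
    stats::dnorm(x, mu[k], sd_[k], log = TRUE) + log(pro[k]),
    numeric(length(x)))
  lab_in <- max.col(loglik, ties.method = "first")
  labels <- array(0L, dim(v))
  labels[mask] <- lab_in
  if (icm_beta > 0 && icm_iter > 0) {
    labels <- icm_smooth(labels, v, mask, mu, sd_, pro,
                         beta = icm_beta, iters = icm_iter)
  }
  class_volumes <- tabulate(labels[mask], nbins = n_classes) * voxel_um3(voxel)
  structure(list(labels = labels, voxel_size = voxel,
                 class_volumes = class_volumes,
                 mixture = list(mean = mu, sd = sd_, pro = pro),
                 n_classes = as.integer(n_classes)),
            class = "chromatin_classmap")
}

#' @export
print.chromatin_classmap <- function(x, ...) {
  cat("chromatin_classmap:", paste(dim(x$labels), collapse = " x "),
      "voxels,", x$n_classes, "classes\n")
  cat("  class volumes (um^3):", paste(signif(x$class_volumes, 3),
                                       collapse = ", "), "\n")
  invisible(x)
}

## ICM with 6-neighbourhood Potts penalty; vectorised sweeps
icm_smooth <- function(labels, v, mask, mu, sd_, pro, beta, iters) {
  d <- dim(labels)
  K <- length(mu)
  x <- v[mask]
  widx <- which(mask)
  # data term once: -log N(x; mu_k, sd_k) - log pi_k
  data_cost <- vapply(seq_len(K), function(k)
    -(stats::dnorm(x, mu[k], sd_[k], log = TRUE) + log(pro[k])),
    numeric(length(x)))
  for (it in seq_len(iters)) {
    # neighbour disagreement count per class, via 6 shifted copies
    cost <- data_cost
    for (ax in seq_along(d)) for (s in c(-1L, 1L)) {
      nb <- shift_array(labels, ax, s, fill = 0L)[widx]
      inside <- nb > 0L
      for (k in seq_len(K)) {
        cost[, k] <- cost[, k] + beta * (inside & nb != k)
      }
    }
    new_lab <- max.col(-cost, ties.method = "first")
    if (all(new_lab == labels[widx])) break
    labels[widx] <- new_lab
  }
  labels
}

#' Extract the surface between the interchromatin compartment and chromatin
#'
#' The surface mask holds the chromatin-side boundary: voxels of class >= 2
#' that share a face with a class-1 voxel. Face (6-)adjacency keeps the
#' shell one voxel thick and consistent with the face-counting area estimate
#' of [surface_to_volume()]; the voxel count of a digital sphere's shell
#' then tracks its analytic surface area.
#'
#' @param classmap a `chromatin_classmap`.
#' @return Logical array: the surface voxel set.
#' @export
extract_ic_surface <- function(classmap) {
  lab <- classmap$labels
  if (!any(lab == 1L)) stop("extract_ic_surface: no class-1 voxels")
  if (!any(lab >= 2L)) return(array(FALSE, dim(lab)))  # all-IC nucleus
  has_ic_neigh <- face_neighbour_any(lab == 1L)
  (lab >= 2L) & has_ic_neigh
}

## TRUE where a face (6-)neighbour of the voxel is TRUE in m
face_neighbour_any <- function(m) {
  d <- dim(m)
  acc <- array(FALSE, d)
  for (ax in seq_along(d)) for (s in c(-1L, 1L))
    acc <- acc | shift_array(m, ax, s, fill = FALSE)
  acc
}

#' Chromatin surface-area-to-volume ratio
#'
#' Surface area is estimated from the voxel faces separating class-1 from
#' class >= 2 voxels, each weighted by its physical face area; volume is the
#' total volume of classes 2..7. `method = "corrected"` multiplies the face
#' count area by 2/3, which removes the systematic overestimate of digital
#' face counting for smooth (isotropically oriented) surfaces; the default
#' `"faces"` reports the raw face area, exact for axis-aligned shapes.
#'
#' @param classmap a `chromatin_classmap`.
#' @param method `"faces"` or `"corrected"`.
#' @return List: `area_um2`, `volume_um3`, `ratio_um` (um^-1).
#' @export
surface_to_volume <- function(classmap, method = c("faces", "corrected")) {
  method <- match.arg(method)
  lab <- classmap$labels
  voxel <- classmap$voxel_size
  chrom <- lab >= 2L
  ic <- lab == 1L
  if (!any(chrom)) stop("surface_to_volume: zero chromatin volume")
  area_nm2 <- 0
  d <- dim(lab)
  face_area <- c(voxel[2] * voxel[3], voxel[1] * voxel[3], voxel[1] * voxel[2])
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb_ic <- shift_array(ic, ax, s, fill = FALSE)
    area_nm2 <- area_nm2 + sum(chrom & nb_ic) * face_area[ax]
  }
  if (method == "corrected") area_nm2 <- area_nm2 * 2 / 3
  area_um2 <- area_nm2 / 1e6
  volume_um3 <- sum(chrom) * voxel_um3(voxel)
  list(area_um2 = area_um2, volume_um3 = volume_um3,
       ratio_um = area_um2 / volume_um3)
}

#' Measure chromatin-domain widths
#'
#' Splits the chromatin mask into domains (connected components, further
#' divided by a watershed on the interior distance transform so that touching
#' domains separate) and reports each domain's width as twice the maximum of
#' the interior Euclidean distance transform, in nm, plus one mean voxel
#' size: the distance transform measures to the nearest background voxel
#' centre, which sits about half a voxel beyond the true boundary on each
#' side.
#'
#' @param x a `chromatin_classmap` (classes >= `min_class` form the mask) or
#'   a logical array.
#' @param voxel_size nm per axis (taken from the classmap when given one).
#' @param min_class first class counted as chromatin domain material.
#' @param split watershed-split touching domains (default TRUE).
#' @param tolerance_nm watershed merge tolerance on the distance map, nm;
#'   the default (half a lateral voxel at typical 3D-SIM sampling) absorbs
#'   discretisation maxima of the distance transform without merging
#'   genuinely distinct domains.
#' @param min_voxels discard domains smaller than this (noise).
#' @return List: `widths_nm` (per domain), `mean_nm`, `ci95_nm` (length 2),
#'   `n_domains`.
#' @export
measure_cd_widths <- function(x, voxel_size = NULL, min_class = 2L,
                              split = TRUE, tolerance_nm = 20,
                              min_voxels = 4L) {
  if (inherits(x, "chromatin_classmap")) {
    mask <- x$labels >= min_class
    voxel <- x$voxel_size
  } else {
    mask <- as.logical(x); dim(mask) <- dim(x)
    if (is.null(voxel_size)) stop("voxel_size required for a bare mask")
    voxel <- rep_len(as.numeric(voxel_size), 3L)
  }
  if (!any(mask))
    return(list(widths_nm = numeric(0), mean_nm = NA_real_,
                ci95_nm = c(NA_real_, NA_real_), n_domains = 0L))
  # interior distance: distance to nearest background voxel
  dist_in <- distance_to_set(!mask, voxel)
  dist_in[!mask] <- 0
  if (split) {
    seg <- watershed3d(dist_in, tolerance = tolerance_nm)
  } else {
    seg <- label_components(mask)
  }
  ids <- setdiff(unique(as.vector(seg)), 0L)
  half_voxel <- mean(voxel) / 2
  widths <- vapply(ids, function(i) {
    sel <- seg == i
    if (sum(sel) < min_voxels) return(NA_real_)
    2 * (max(dist_in[sel]) + half_voxel)
  }, numeric(1))
  widths <- widths[!is.na(widths)]
  n <- length(widths)
  if (n == 0L)
    return(list(widths_nm = numeric(0), mean_nm = NA_real_,
                ci95_nm = c(NA_real_, NA_real_), n_domains = 0L))
  m <- mean(widths)
  ci <- if (n > 1L) m + c(-1, 1) * stats::qt(0.975, n - 1L) *
    stats::sd(widths) / sqrt(n) else c(NA_real_, NA_real_)
  list(widths_nm = widths, mean_nm = m, ci95_nm = ci, n_domains = n)
}

#' Partition the nucleus into A/B compartment proxies
#'
#' The B proxy unites the perinuclear rim (nuclear voxels within
#' `rim_thickness` nm of the nuclear boundary) with chromocenter regions
#' (connected components of the top heterochromatin classes above a volume
#' threshold); the A proxy is the residual nuclear volume.
#'
#' @param classmap a `chromatin_classmap`.
#' @param rim_thickness nm.
#' @param chromocenter_classes classes forming chromocenters (default 6:7).
#' @param chromocenter_min_um3 minimum chromocenter component volume.
#' @return List: logical arrays `A_proxy`, `B_proxy`, plus `rim`, and
#'   `chromocenters`.
#' @export
compartment_masks <- function(classmap, rim_thickness,
                              chromocenter_classes = 6:7,
                              chromocenter_min_um3 = 0.05) {
  lab <- classmap$labels
  voxel <- classmap$voxel_size
  nuc <- lab > 0L
  if (!any(nuc)) stop("compartment_masks: empty nucleus")
  dist_out <- distance_to_set(!nuc, voxel)   # distance to outside
  if (rim_thickness >= max(dist_out[nuc]))
    stop("compartment_masks: rim_thickness exceeds the nuclear radius")
  rim <- nuc & dist_out <= rim_thickness
  cc_mask <- array(lab %in% chromocenter_classes, dim(lab))
  chromo <- array(FALSE, dim(lab))
  if (any(cc_mask)) {
    labcc <- label_components(cc_mask)
    sizes <- tabulate(labcc[labcc > 0L])
    keep <- which(sizes * voxel_um3(voxel) > chromocenter_min_um3)
    if (length(keep)) chromo <- array(labcc %in% keep, dim(lab))
  }
  B <- rim | chromo
  A <- nuc & !B
  list(A_proxy = A, B_proxy = B, rim = rim, chromocenters = chromo)
}
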