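#' Detect immunofluorescence foci by Otsu thresholding and 3D watershed
#'
#' The marker channel is thresholded (Otsu over in-mask intensities,
#' sub-threshold voxels zeroed), touching spots are split by a 3D watershed
#' on the smoothed intensity, and each region's 3D centroid is computed as
#' its intensity-weighted centre of mass in physical nm.
#'
#' @param marker a [volume_image()] of the marker channel.
#' @param mask logical nuclear mask.
#' @param smooth_sigma smoothing sigma (voxels) before watershed seeding;
#'   suppresses spurious local maxima closer than about two voxels.
#' @param tolerance watershed merge tolerance as a fraction of the in-mask
#'   dynamic range: shallower local maxima are absorbed into their
#'   neighbour.
#' @param min_voxels discard regions smaller than this many voxels.
#' @return A `foci_set` data.frame: x_nm, y_nm, z_nm, peak, integrated,
#'   mcnr (NA), class (NA), distance_nm (NA); the Otsu threshold is stored
#'   in attribute `"threshold"`.
#' @export
detect_foci <- function(marker, mask = NULL, smooth_sigma = 0.7,
                        tolerance = 0.1, min_voxels = 2L) {
  v <- vol_values(marker)
  voxel <- vol_voxel(marker, default = 1)
  if (is.null(mask)) mask <- array(TRUE, dim(v))
  empty <- foci_frame(0L)
  inm <- v[mask]
  if (diff(range(inm)) <= 0) {
    attr(empty, "threshold") <- NA_real_
    return(empty)
  }
  thr <- otsu_threshold(inm)
  fg <- v
  fg[!mask | v < thr] <- 0
  if (!any(fg > 0)) { attr(empty, "threshold") <- thr; return(empty) }
  sm <- if (smooth_sigma > 0) gaussian_blur(fg, smooth_sigma) else fg
  sm[fg == 0] <- 0
  seg <- watershed3d(sm, tolerance = tolerance * diff(range(inm)))
  ids <- setdiff(unique(as.vector(seg)), 0L)
  if (!length(ids)) { attr(empty, "threshold") <- thr; return(empty) }
  rows <- lapply(ids, function(i) {
    sel <- which(seg == i)
    if (length(sel) < min_voxels) return(NULL)
    w <- v[sel]
    ai <- arrayInd(sel, dim(v))
    cen <- colSums(sweep(ai - 1, 1, w, "*")) / sum(w) * voxel
    data.frame(x_nm = cen[1], y_nm = cen[2], z_nm = cen[3],
               peak = max(w), integrated = sum(w),
               mcnr = NA_real_, class = NA_integer_, distance_nm = NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- foci_frame(0L)
  rownames(out) <- NULL
  class(out) <- c("foci_set", "data.frame")
  attr(out, "threshold") <- thr
  attr(out, "voxel_size") <- voxel
  out
}

foci_frame <- function(n) {
  out <- data.frame(x_nm = numeric(n), y_nm = numeric(n), z_nm = numeric(n),
                    peak = numeric(n), integrated = numeric(n),
                    mcnr = numeric(n), class = integer(n),
                    distance_nm = numeric(n))
  class(out) <- c("foci_set", "data.frame")
  out
}

## centroid voxel indices (1-based) for a foci_set within a given grid
centroid_voxels <- function(foci, dim3, voxel) {
  ix <- pmin(pmax(round(foci$x_nm / voxel[1]) + 1L, 1L), dim3[1])
  iy <- pmin(pmax(round(foci$y_nm / voxel[2]) + 1L, 1L), dim3[2])
  iz <- pmin(pmax(round(foci$z_nm / voxel[3]) + 1L, 1L), dim3[3])
  cbind(ix, iy, iz)
}

#' Filter foci by reconstruction quality (MCNR)
#'
#' Removes foci whose centroid voxel in the modulation contrast-to-noise
#' ratio map falls below the cutoff; foci at MCNR >= cutoff are retained.
#' The quality cutoff defaults to 5.
#'
#' @param foci a `foci_set`.
#' @param mcnr_map a [volume_image()] co-registered with the marker volume.
#' @param cutoff minimum MCNR retained.
#' @return Filtered `foci_set` with `mcnr` filled; the number removed is in
#'   attribute `"n_removed"`.
#' @export
filter_mcnr <- function(foci, mcnr_map, cutoff = 5) {
  if (is.null(mcnr_map)) stop("filter_mcnr: MCNR map required")
  m <- vol_values(mcnr_map)
  voxel <- vol_voxel(mcnr_map, default = attr(foci, "voxel_size"))
  if (nrow(foci) == 0L) { attr(foci, "n_removed") <- 0L; return(foci) }
  idx <- centroid_voxels(foci, dim(m), voxel)
  vals <- m[idx]
  foci$mcnr <- vals
  keep <- vals >= cutoff
  out <- foci[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("foci_set", "data.frame")
  attr(out, "threshold") <- attr(foci, "threshold")
  attr(out, "voxel_size") <- attr(foci, "voxel_size")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Assign chromatin classes to foci
#'
#' Each focus gets the class of the voxel containing its centroid.
#'
#' @param foci a `foci_set`.
#' @param classmap a `chromatin_classmap`.
#' @return The `foci_set` with `class` filled.
#' @export
assign_classes <- function(foci, classmap) {
  if (nrow(foci) == 0L) return(foci)
  idx <- centroid_voxels(foci, dim(classmap$labels), classmap$voxel_size)
  foci$class <- classmap$labels[idx]
  foci
}

#' Class enrichment of marker foci relative to chromatin class volumes
#'
#' Counts foci per chromatin class and compares the observed fractions with
#' the expected fractions under uniform placement (each class's share of the
#' nuclear volume): log2[(n_c / N) / (V_c / V_nuc)]. Classes with zero
#' observed counts give NA unless `pseudocount` adds 0.5 to every class
#' count.
#'
#' @param foci a `foci_set` (classes filled or a `classmap` supplied).
#' @param classmap a `chromatin_classmap`.
#' @param pseudocount add 0.5 per class to avoid -Inf (default FALSE).
#' @param marker optional marker name.
#' @return An `enrichment_profile` data.frame: class, observed, expected_fraction,
#'   log2_fc.
#' @export
class_enrichment <- function(foci, classmap, pseudocount = FALSE,
                             marker = "") {
  if (nrow(foci) == 0L) stop("class_enrichment: no foci")
  if (anyNA(foci$class)) foci <- assign_classes(foci, classmap)
  K <- classmap$n_classes
  if (any(foci$class < 1L | foci$class > K))
    stop("class_enrichment: focus centroid outside the nucleus")
  n_c <- tabulate(foci$class, nbins = K)
  N <- sum(n_c)
  V <- classmap$class_volumes
  expected <- V / sum(V)
  obs_frac <- if (pseudocount) (n_c + 0.5) / (N + 0.5 * K) else n_c / N
  log2fc <- ifelse(n_c == 0L & !pseudocount, NA_real_,
                   log2(obs_frac / expected))
  out <- data.frame(class = seq_len(K), observed = n_c,
                    expected_fraction = expected, log2_fc = log2fc)
  attr(out, "marker") <- marker
  attr(out, "n_foci") <- N
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Signed distances from foci to the interchromatin-compartment surface
#'
#' Euclidean distance (anisotropy-aware distance transform, nm) from each
#' focus centroid to the nearest surface voxel. Sign convention: negative
#' when the centroid voxel lies in class 1 (the IC side), positive inside
#' chromatin.
#'
#' @param foci a `foci_set`.
#' @param surface logical surface voxel array (see [extract_ic_surface()]).
#' @param classmap a `chromatin_classmap`.
#' @return The `foci_set` with `distance_nm` filled; summary (mean and 95%
#'   CI) in attributes `"mean_nm"` and `"ci95_nm"`.
#' @export
surface_distances <- function(foci, surface, classmap) {
  if (!any(surface)) stop("surface_distances: empty surface")
  voxel <- classmap$voxel_size
  dmap <- distance_to_set(surface, voxel)
  if (nrow(foci) > 0L) {
    idx <- centroid_voxels(foci, dim(surface), voxel)
    d <- dmap[idx]
    cls <- classmap$labels[idx]
    foci$distance_nm <- ifelse(cls == 1L, -d, d)
    if (anyNA(foci$class)) foci$class <- cls
  }
  n <- nrow(foci)
  m <- if (n) mean(foci$distance_nm) else NA_real_
  ci <- if (n > 1L) m + c(-1, 1) * stats::qt(0.975, n - 1L) *
    stats::sd(foci$distance_nm) / sqrt(n) else c(NA_real_, NA_real_)
  attr(foci, "mean_nm") <- m
  attr(foci, "ci95_nm") <- ci
  foci
}

#' Class proportions and focus densities within a submask
#'
#' Restricts the topography and foci statistics to a region of interest
#' (e.g. a replication-labelled submask): chromatin class volume fractions
#' within the submask and, per marker, the focus density in um^-3 of
#' submask volume.
#'
#' @param classmap a `chromatin_classmap`.
#' @param submask logical array, subset of the nuclear mask.
#' @param foci_list named list of `foci_set` objects (may be empty).
#' @return List: `class_fractions` (length n_classes), `volume_um3`,
#'   `density_per_um3` (named per marker), `counts` (named per marker).
#' @export
submask_analysis <- function(classmap, submask, foci_list = list()) {
  lab <- classmap$labels
  if (!any(submask)) stop("submask_analysis: empty submask")
  if (any(submask & lab == 0L))
    stop("submask_analysis: submask extends outside the nucleus")
  K <- classmap$n_classes
  n_c <- tabulate(lab[submask], nbins = K)
  vol <- sum(submask) * voxel_um3(classmap$voxel_size)
  dens <- counts <- stats::setNames(numeric(length(foci_list)),
                                    names(foci_list))
  for (nm in names(foci_list)) {
    f <- foci_list[[nm]]
    inside <- if (nrow(f)) {
      idx <- centroid_voxels(f, dim(lab), classmap$voxel_size)
      sum(submask[idx])
    } else 0L
    counts[nm] <- inside
    dens[nm] <- inside / vol
  }
  list(class_fractions = n_c / sum(n_c), volume_um3 = vol,
       density_per_um3 = dens, counts = counts)
}

#' Pixel-wise colocalization of two channels
#'
#' Pearson correlation over in-mask voxels, plus Manders' coefficients:
#' M1 is the fraction of channel-1 intensity in voxels where channel 2 is
#' above its Otsu threshold; M2 the converse.
#'
#' @param ch1,ch2 co-registered [volume_image()]s or arrays.
#' @param mask logical mask (default: everywhere).
#' @return List: `pcc` (NA if either channel has zero variance), `m1`, `m2`,
#'   and the two thresholds.
#' @export
colocalize <- function(ch1, ch2, mask = NULL) {
  a <- vol_values(ch1); b <- vol_values(ch2)
  if (!identical(dim(a), dim(b)))
    stop("colocalize: channel shapes differ: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  if (!any(mask)) stop("colocalize: empty mask")
  x <- a[mask]; y <- b[mask]
  pcc <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)
  t1 <- tryCatch(otsu_threshold(x), error = function(e) NA_real_)
  t2 <- tryCatch(otsu_threshold(y), error = function(e) NA_real_)
  m1 <- if (is.na(t2) || sum(x) == 0) NA_real_ else sum(x[y >= t2]) / sum(x)
  m2 <- if (is.na(t1) || sum(y) == 0) NA_real_ else sum(y[x >= t1]) / sum(y)
  list(pcc = pcc, m1 = m1, m2 = m2, threshold1 = t1, threshold2 = t2)
}
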