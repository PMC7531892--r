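#' Volume image container
#'
#' A `volume_image` is a numeric 3D array (or 2D matrix) of voxel intensities
#' together with the physical voxel size in nanometres per array axis. All
#' physical measurements in the package (volumes, surface areas, distances)
#' are computed from `voxel_size`, so anisotropic sampling (typical for
#' 3D-SIM, e.g. 40 nm lateral / 125 nm axial) is handled throughout.
#'
#' Array axis 1 is called x, axis 2 y, axis 3 z. Physical coordinates are in
#' nm from the volume origin, with the centre of voxel (1,1,1) at (0,0,0):
#' `x_nm = (i - 1) * voxel_size[1]`.
#'
#' @param values numeric array (2D or 3D) of intensities.
#' @param voxel_size numeric scalar or vector (nm per axis, recycled to the
#'   number of array dimensions).
#' @param channel optional channel name.
#' @return A `volume_image` object.
#' @export
volume_image <- function(values, voxel_size, channel = "") {
  if (!is.array(values) && !is.matrix(values))
    stop("`values` must be a matrix or array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("`values` must be 2D or 3D")
  voxel_size <- rep_len(as.numeric(voxel_size), nd)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("all voxel sizes must be positive")
  if (length(values) == 0L) stop("grid must be nonempty")
  structure(list(values = values, voxel_size = voxel_size,
                 channel = as.character(channel)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("volume_image", if (nzchar(x$channel)) paste0("[", x$channel, "]"),
      paste(dim(x$values), collapse = " x "), "voxels;",
      paste(signif(x$voxel_size, 4), collapse = " x "), "nm/voxel\n")
  cat("  intensity range:", paste(signif(range(x$values), 5), collapse = " .. "), "\n")
  invisible(x)
}

## accept either a volume_image or a bare array
vol_values <- function(x) if (inherits(x, "volume_image")) x$values else x
vol_voxel <- function(x, default = NULL) {
  if (inherits(x, "volume_image")) return(x$voxel_size)
  if (is.null(default)) stop("voxel size required but input is a bare array")
  rep_len(default, length(dim(x)))
}

## voxel volume in cubic micrometres
voxel_um3 <- function(voxel_size) prod(voxel_size) / 1e9

#' Otsu threshold from a binned histogram
#'
#' Maximises the between-class variance over a fixed-width histogram of the
#' input values, as used for immunofluorescence foci thresholding. Returns
#' the threshold on the intensity scale (upper edge of the chosen bin), so
#' voxels `>= threshold` form the foreground.
#'
#' @param x numeric values.
#' @param bins number of histogram bins.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x, bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant input: Otsu threshold undefined")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = bins)
  p <- h / sum(h)
  w0 <- cumsum(p)                       # class-0 weight up to bin t
  mids <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  # between-class variance for cut after bin t (vectorised over t)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, bins)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  t_star <- which.max(bcv)
  breaks[t_star + 1L]
}

#' Histogram mode of a set of intensities
#'
#' The modal value over a fixed-width binned histogram; used to calibrate
#' each micrograph against the extranuclear background.
#'
#' @param x numeric values.
#' @param bins number of bins (default 256).
#' @return Centre of the most populated bin.
#' @export
hist_mode <- function(x, bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("mode undefined: empty input")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = bins)
  i <- which.max(h)
  (breaks[i] + breaks[i + 1L]) / 2
}

## --- separable Gaussian smoothing ------------------------------------------

## 1D convolution along the first dimension of a matrix (columns = lines),
## zero padded, kernel centred.
conv_lines <- function(m, kern) {
  r <- (length(kern) - 1L) / 2L
  n <- nrow(m)
  pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- stats::filter(pad, kern, method = "convolution", sides = 2L)
  matrix(out[(r + 1L):(r + n), ], n, ncol(m))
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur with per-axis sigma (in voxels)
#'
#' Normalised so that constants are preserved exactly (the blurred field is
#' divided by the blur of an all-ones field, which also corrects edge
#' attenuation from zero padding).
#'
#' @param a numeric 2D or 3D array.
#' @param sigma numeric, sigma in voxel units per axis (recycled).
#' @return Array of the same shape.
#' @export
gaussian_blur <- function(a, sigma) {
  d <- dim(a)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  if (all(sigma <= 0)) return(a)
  ones <- array(1, d)
  blur_axis <- function(x, axis, s) {
    if (s <= 0) return(x)
    k <- gauss_kernel(s)
    perm <- c(axis, setdiff(seq_len(nd), axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- conv_lines(matrix(xp, dp[1], prod(dp[-1])), k)
    aperm(array(m, dp), order(perm))
  }
  num <- a; den <- ones
  for (ax in seq_len(nd)) {
    num <- blur_axis(num, ax, sigma[ax])
    den <- blur_axis(den, ax, sigma[ax])
  }
  num / den
}

## --- anisotropic Euclidean distance transform --------------------------------

## 1D squared distance transform (lower envelope of parabolas), physical
## spacing h. f is squared distance so far; returns updated squared distance.
dt1d <- function(f, h) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  xs <- (seq_len(n) - 1) * h
  for (q in 2L:n) {
    if (!is.finite(f[q])) next
    repeat {
      p <- v[k]
      if (!is.finite(f[p])) { s <- -Inf } else {
        s <- ((f[q] + xs[q]^2) - (f[p] + xs[p]^2)) / (2 * (xs[q] - xs[p]))
      }
      if (s <= z[k] && k > 1L) { k <- k - 1L } else break
    }
    if (!is.finite(f[v[k]])) { v[k] <- q; z[k + 1L] <- Inf } else {
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  out <- numeric(n); j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < xs[q]) j <- j + 1L
    p <- v[j]
    out[q] <- if (is.finite(f[p])) (xs[q] - xs[p])^2 + f[p] else Inf
  }
  out
}

#' Euclidean distance transform to a target voxel set
#'
#' Exact Euclidean distance (in nm) from every voxel to the nearest voxel of
#' `target`, honouring anisotropic voxel sizes, via the separable
#' lower-envelope algorithm.
#'
#' @param target logical array marking the target set.
#' @param voxel_size nm per axis (recycled).
#' @return Numeric array of distances in nm (`Inf` if target is empty).
#' @export
distance_to_set <- function(target, voxel_size) {
  d <- dim(target)
  nd <- length(d)
  voxel_size <- rep_len(voxel_size, nd)
  f <- array(ifelse(target, 0, Inf), d)
  for (ax in seq_len(nd)) {
    perm <- c(ax, setdiff(seq_len(nd), ax))
    fp <- aperm(f, perm)
    dp <- dim(fp)
    m <- matrix(fp, dp[1], prod(dp[-1]))
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (all(!is.finite(col)) || all(col == 0)) next
      m[, j] <- dt1d(col, voxel_size[ax])
    }
    f <- aperm(array(m, dp), order(perm))
  }
  sqrt(f)
}

## --- 3D connected components and hole filling --------------------------------

## 6-connected (face) neighbour linear-index offsets with boundary masks
neighbour_shifts <- function(d) {
  nd <- length(d)
  out <- list()
  for (ax in seq_len(nd)) for (s in c(-1L, 1L)) out[[length(out) + 1L]] <- c(ax, s)
  out
}

## shift a logical/numeric array by one voxel along axis, padding with `fill`
shift_array <- function(a, axis, by, fill = 0) {
  d <- dim(a)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  if (by == 1L) { idx_src[[axis]] <- seq_len(d[axis] - 1L); idx_dst[[axis]] <- 2:d[axis] }
  else { idx_src[[axis]] <- 2:d[axis]; idx_dst[[axis]] <- seq_len(d[axis] - 1L) }
  out <- array(fill, d)
  out_call <- as.call(c(list(as.name("["), as.name("a")), idx_src))
  block <- eval(out_call)
  assign_call <- as.call(c(list(as.name("[<-"), as.name("out")), idx_dst, list(as.name("block"))))
  eval(assign_call)
}

#' Label 3D connected components (face connectivity)
#'
#' @param mask logical array.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  n <- length(mask)
  lab <- integer(n)
  mk <- as.logical(mask)
  # precompute neighbour offsets in linear index space with validity masks
  strides <- c(1L, cumprod(d)[-length(d)])
  ai <- arrayInd(seq_len(n), d)
  ok <- list(); off <- integer()
  kdirs <- neighbour_shifts(d)
  for (i in seq_along(kdirs)) {
    ax <- kdirs[[i]][1]; s <- kdirs[[i]][2]
    ok[[i]] <- if (s == 1L) ai[, ax] < d[ax] else ai[, ax] > 1L
    off[i] <- s * strides[ax]
  }
  cur <- 0L
  unvisited <- mk
  repeat {
    seed <- which.max(unvisited)
    if (!unvisited[seed]) break
    cur <- cur + 1L
    frontier <- seed
    unvisited[seed] <- FALSE
    lab[seed] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (i in seq_along(off)) {
        cand <- frontier[ok[[i]][frontier]] + off[i]
        cand <- cand[unvisited[cand]]
        if (length(cand)) {
          unvisited[cand] <- FALSE
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  array(lab, d)
}

#' Fill interior holes of a 3D mask
#'
#' Background voxels not 6-connected to the array border are set to TRUE.
#' @param mask logical array.
#' @return Logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- label_components(bg)
  # collect labels touching any border face
  border <- logical(max(lab, 0L))
  if (length(border) == 0L) return(mask)
  for (ax in seq_along(d)) {
    idx <- lapply(d, seq_len)
    for (side in c(1L, d[ax])) {
      idx2 <- idx; idx2[[ax]] <- side
      face <- eval(as.call(c(list(as.name("["), as.name("lab")), idx2)))
      face <- face[face > 0L]
      if (length(face)) border[unique(face)] <- TRUE
    }
  }
  hole <- bg & !array(ifelse(lab > 0L, border[pmax(lab, 1L)], FALSE), d)
  mask | hole
}

#' 3D watershed of an intensity (or distance) landscape
#'
#' Splits the positive voxels of `height` into objects around local maxima
#' by ordered flooding with 26-connectivity: voxels are visited from highest
#' to lowest; a voxel with no labelled neighbour seeds a new object, one
#' with labelled neighbours joins the neighbouring object with the highest
#' peak, and any other adjacent object whose dynamic (peak minus current
#' level) is below `tolerance` is merged into it. Unlike a per-slice
#' watershed this treats the volume as fully three-dimensional.
#'
#' @param height numeric array; zero/negative voxels are background.
#' @param tolerance minimum peak-to-saddle height for an object to stay
#'   separate, in intensity units of `height`.
#' @return Integer array of object labels (0 = background).
#' @export
watershed3d <- function(height, tolerance = 0) {
  d <- dim(height)
  n <- length(height)
  fgi <- which(height > 0)
  lab <- integer(n)
  if (!length(fgi)) return(array(lab, d))
  ord <- fgi[order(height[fgi], decreasing = TRUE)]
  # 26-neighbourhood offsets with coordinate deltas for border checks
  sh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = if (length(d) == 3L) -1:1 else 0))
  sh <- sh[rowSums(abs(sh)) > 0, , drop = FALSE]
  strides <- c(1L, d[1], if (length(d) == 3L) d[1] * d[2] else 0L)
  offs <- as.integer(sh %*% strides)
  ai <- arrayInd(seq_len(n), d)
  parent <- integer(0)
  peak <- numeric(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nd3 <- length(d) == 3L
  for (v in ord) {
    cx <- ai[v, 1L]; cy <- ai[v, 2L]; cz <- if (nd3) ai[v, 3L] else 1L
    okn <- (cx + sh[, 1L]) >= 1L & (cx + sh[, 1L]) <= d[1] &
           (cy + sh[, 2L]) >= 1L & (cy + sh[, 2L]) <= d[2]
    if (nd3) okn <- okn & (cz + sh[, 3L]) >= 1L & (cz + sh[, 3L]) <= d[3]
    nb <- v + offs[okn]
    nl <- lab[nb]
    nl <- nl[nl > 0L]
    if (!length(nl)) {
      parent <- c(parent, length(parent) + 1L)
      peak <- c(peak, height[v])
      lab[v] <- length(parent)
    } else {
      roots <- unique(vapply(nl, find_root, integer(1)))
      win <- roots[which.max(peak[roots])]
      lab[v] <- win
      if (length(roots) > 1L) {
        h <- height[v]
        for (r in setdiff(roots, win))
          if (peak[r] - h < tolerance) parent[r] <- win
      }
    }
  }
  # resolve labels to roots, compact ids
  if (length(parent)) {
    root_of <- vapply(seq_along(parent), find_root, integer(1))
    ids <- integer(length(parent))
    ids[unique(root_of)] <- seq_along(unique(root_of))
    lab[lab > 0L] <- ids[root_of[lab[lab > 0L]]]
  }
  array(lab, d)
}

## run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}
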