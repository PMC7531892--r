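# Independent oracles and small constructors shared across the test files.
# Every oracle is a direct, brute-force restatement of the definition and
# never calls the implementation path it checks.

## Otsu: exhaustive between-class-variance maximisation over a binned
## histogram; returns the upper edge of the best bin.
otsu_brute <- function(x, bins = 64L) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), bins)
  mids <- (br[-1] + br[-(bins + 1L)]) / 2
  best <- -Inf; bt <- NA_real_
  for (t in 1:(bins - 1L)) {
    w0 <- sum(h[1:t]); w1 <- sum(h[(t + 1L):bins])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1L):bins] * mids[(t + 1L):bins]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; bt <- br[t + 1L] }
  }
  bt
}

## distance transform: minimum over all target voxels, physical units
edt_brute <- function(target, voxel) {
  tg <- arrayInd(which(target), dim(target))
  all_i <- arrayInd(seq_along(target), dim(target))
  out <- apply(all_i, 1, function(p)
    min(sqrt(colSums(((t(tg) - p) * voxel)^2))))
  array(out, dim(target))
}

## direct O(N^2) spatial autocorrelation (mean-subtracted, unbiased,
## normalised to r(0) = 1) of a real or complex matrix
autocorr_brute <- function(f) {
  d <- dim(f)
  f <- f - mean(f)
  lagx <- -(d[1] - 1L):(d[1] - 1L)
  lagy <- -(d[2] - 1L):(d[2] - 1L)
  out <- matrix(NA_real_, length(lagx), length(lagy))
  for (a in seq_along(lagx)) for (b in seq_along(lagy)) {
    dx <- lagx[a]; dy <- lagy[b]
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    s <- 0; n <- 0
    for (i in xs) for (j in ys) {
      s <- s + Re(f[i, j] * Conj(f[i + dx, j + dy]))
      n <- n + 1
    }
    out[a, b] <- s / n
  }
  out / out[d[1], d[2]]
}

## direct double-loop time-averaged MSD
msd_brute <- function(pos, dt = 1) {
  n <- nrow(pos)
  vapply(seq_len(n - 1L), function(k) {
    acc <- 0
    for (t in seq_len(n - k)) acc <- acc + sum((pos[t + k, ] - pos[t, ])^2)
    acc / (n - k)
  }, numeric(1))
}

## voxelised sphere/ellipsoid masks on a physical grid (centre/sizes in nm)
sphere_mask <- function(shape, voxel, centre, diameter) {
  g <- expand.grid(x = (0:(shape[1] - 1)) * voxel[1],
                   y = (0:(shape[2] - 1)) * voxel[2],
                   z = (0:(shape[3] - 1)) * voxel[3])
  array((g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2 <=
          (diameter / 2)^2, shape)
}

ellipsoid_mask_oracle <- function(shape, voxel, centre, semi) {
  g <- expand.grid(x = (0:(shape[1] - 1)) * voxel[1],
                   y = (0:(shape[2] - 1)) * voxel[2],
                   z = (0:(shape[3] - 1)) * voxel[3])
  array(((g$x - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
          ((g$z - centre[3]) / semi[3])^2 <= 1, shape)
}

## a chromatin_classmap built directly from a label array
classmap_from_labels <- function(labels, voxel, n_classes = 7L) {
  structure(list(labels = labels, voxel_size = voxel,
                 class_volumes = tabulate(labels[labels > 0L], n_classes) *
                   prod(voxel) / 1e9,
                 mixture = NULL, n_classes = n_classes),
            class = "chromatin_classmap")
}

## a foci_set data.frame at given nm coordinates
make_foci <- function(x_nm, y_nm, z_nm) {
  f <- data.frame(x_nm = x_nm, y_nm = y_nm, z_nm = z_nm,
                  peak = 1, integrated = 1, mcnr = NA_real_,
                  class = NA_integer_, distance_nm = NA_real_)
  class(f) <- c("foci_set", "data.frame")
  f
}

## render 3D Gaussian spots at given nm positions into a volume
render_spots <- function(shape, voxel, centres, amplitude = 1000, sigma = 60) {
  v <- array(0, shape)
  g <- expand.grid(x = (0:(shape[1] - 1)) * voxel[1],
                   y = (0:(shape[2] - 1)) * voxel[2],
                   z = (0:(shape[3] - 1)) * voxel[3])
  for (i in seq_len(nrow(centres))) {
    d2 <- (g$x - centres[i, 1])^2 + (g$y - centres[i, 2])^2 +
      (g$z - centres[i, 3])^2
    v <- v + array(amplitude * exp(-d2 / (2 * sigma^2)), shape)
  }
  v
}
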