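test_that("spot detection recovers sub-voxel centroids and splits close pairs", {
  voxel <- c(40, 40, 80)
  # single Gaussian spot: centroid within 0.25 voxel per axis
  cen <- matrix(c(15.3, 16.7, 8.2) * voxel, 1)
  v <- render_spots(c(32, 32, 16), voxel, cen)
  det <- detect_foci(volume_image(v, voxel))
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_nm - cen[1]) / voxel[1], 0.25)
  expect_lt(abs(det$y_nm - cen[2]) / voxel[2], 0.25)
  expect_lt(abs(det$z_nm - cen[3]) / voxel[3], 0.25)
  # two spots 5 sigma apart split into two foci
  cen2 <- rbind(c(400, 640, 640), c(400 + 5 * 60, 640, 640))
  v2 <- render_spots(c(32, 32, 16), voxel, cen2)
  det2 <- detect_foci(volume_image(v2, voxel))
  expect_equal(nrow(det2), 2L)
  # empty channel: empty set, no error
  det0 <- detect_foci(volume_image(array(0, c(16, 16, 8)), voxel))
  expect_equal(nrow(det0), 0L)
})

test_that("detection round-trip on well-separated spots reaches 95% recall and precision", {
  voxel <- c(40, 40, 80)
  shape <- c(48, 48, 24)
  # grid of spots, pairwise spacing >= 8 voxels >> 4 sigma
  gx <- seq(6, 42, by = 9) * voxel[1]
  gy <- seq(6, 42, by = 9) * voxel[2]
  cen <- as.matrix(expand.grid(x = gx, y = gy))
  set.seed(41)
  cen <- cbind(cen + matrix(runif(2 * nrow(cen), -40, 40), ncol = 2),
               z = runif(nrow(cen), 6, 18) * voxel[3])
  v <- render_spots(shape, voxel, cen, amplitude = 1000, sigma = 60)
  v <- v + array(rnorm(prod(shape), 0, 40), shape)  # SNR >= 10 on the peak
  det <- detect_foci(volume_image(v, voxel))
  dmat <- sqrt(outer(det$x_nm, cen[, 1], "-")^2 +
               outer(det$y_nm, cen[, 2], "-")^2 +
               outer(det$z_nm, cen[, 3], "-")^2)
  recall <- mean(apply(dmat, 2, min) <= 80)   # match radius ~ one voxel
  precision <- mean(apply(dmat, 1, min) <= 80)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("MCNR filtering retains foci at the cutoff and logs removals", {
  voxel <- c(40, 40, 80)
  cen <- rbind(c(400, 400, 400), c(1200, 1200, 800))
  v <- render_spots(c(40, 40, 20), voxel, cen)
  det <- detect_foci(volume_image(v, voxel))
  expect_equal(nrow(det), 2L)
  ord <- order(det$x_nm)
  mc <- array(4.9, c(40, 40, 20))
  mc[det$x_nm[ord[2]] / 40 + 1, det$y_nm[ord[2]] / 40 + 1, ] <- 5.1
  mcv <- volume_image(mc, voxel)
  kept <- filter_mcnr(det, mcv, cutoff = 5)
  expect_equal(nrow(kept), 1L)               # 4.9 discarded, 5.1 retained
  expect_equal(attr(kept, "n_removed"), 1L)
  expect_equal(nrow(filter_mcnr(det, mcv, cutoff = 0)), 2L)  # identity
  alllow <- volume_image(array(1, c(40, 40, 20)), voxel)
  expect_equal(nrow(filter_mcnr(det, alllow, cutoff = 5)), 0L)
  expect_error(filter_mcnr(det, NULL), "required")
  # counts conserved through the filter
  expect_equal(nrow(kept) + attr(kept, "n_removed"), nrow(det))
})

test_that("class enrichment follows its defining arithmetic and converges for uniform placement", {
  voxel <- c(40, 40, 80)
  pl <- plateau_nucleus(shape = c(48, 48, 24), seed = 2)
  cmap <- classmap_from_labels(pl$true_classes, voxel)
  # all foci in one class occupying fraction p: log2 FC = -log2(p)
  idx3 <- which(pl$true_classes == 3L)
  set.seed(5)
  pick <- sample(idx3, 200, replace = TRUE)
  ai <- arrayInd(pick, dim(pl$true_classes))
  f <- make_foci((ai[, 1] - 1) * 40, (ai[, 2] - 1) * 40, (ai[, 3] - 1) * 80)
  enr <- class_enrichment(f, cmap)
  p3 <- cmap$class_volumes[3] / sum(cmap$class_volumes)
  expect_equal(enr$log2_fc[3], -log2(p3), tolerance = 1e-10)
  expect_true(all(is.na(enr$log2_fc[-3])))  # empty classes: NA, not -Inf
  expect_equal(sum(enr$observed), 200L)
  # uniform placement at n = 10^4: |log2 FC| < 0.1 per class
  un <- place_foci(pl$true_classes, foci_spec(n_foci = 10000, seed = 6), voxel)
  fu <- make_foci(un$truth$x_nm, un$truth$y_nm, un$truth$z_nm)
  enru <- class_enrichment(fu, cmap)
  expect_true(all(abs(enru$log2_fc) < 0.1))
  # 4x affinity on class 2 peaks at class 2
  b <- place_foci(pl$true_classes,
                  foci_spec(n_foci = 2000, class_weights = c(1, 4, 1, 1, 1, 1, 1),
                            seed = 7), voxel)
  fb <- make_foci(b$truth$x_nm, b$truth$y_nm, b$truth$z_nm)
  enrb <- class_enrichment(fb, cmap)
  expect_equal(which.max(enrb$log2_fc), 2L)
  expect_error(class_enrichment(f[0, ], cmap), "no foci")
})

test_that("surface distances are signed, exact on flat interfaces, and match brute force", {
  voxel <- c(40, 40, 40)
  shape <- c(24, 24, 12)
  lab <- array(1L, shape)
  lab[13:24, , ] <- 4L          # flat interface between x=12 and x=13
  cm <- classmap_from_labels(lab, voxel)
  surf <- extract_ic_surface(cm)   # the x = 13 plane
  f0 <- make_foci(c(15, 12, 9) * 40, rep(200, 3), rep(200, 3))
  fd <- surface_distances(f0, surf, cm)
  expect_equal(fd$distance_nm[1], 3 * 40)   # 3 voxels inside chromatin
  expect_equal(fd$distance_nm[2], 0)        # on a surface voxel
  expect_equal(fd$distance_nm[3], -3 * 40)  # IC side: negative
  # brute force equality on a random 16^3 volume
  set.seed(8)
  shape2 <- c(16, 16, 16); voxel2 <- c(40, 40, 80)
  lab2 <- array(sample(1:4, prod(shape2), replace = TRUE), shape2)
  cm2 <- classmap_from_labels(lab2, voxel2)
  s2 <- extract_ic_surface(cm2)
  pts <- cbind(sample(0:15, 20, TRUE), sample(0:15, 20, TRUE),
               sample(0:15, 20, TRUE))
  f2 <- make_foci(pts[, 1] * 40, pts[, 2] * 40, pts[, 3] * 80)
  fd2 <- surface_distances(f2, s2, cm2)
  sv <- arrayInd(which(s2), shape2)
  for (i in 1:20) {
    d_brute <- min(sqrt(colSums(((t(sv) - (pts[i, ] + 1)) * voxel2)^2)))
    expect_equal(abs(fd2$distance_nm[i]), d_brute, tolerance = 1e-9)
  }
  expect_error(surface_distances(f2, array(FALSE, shape2), cm2), "empty")
})

test_that("submask statistics restrict correctly and compute densities", {
  voxel <- c(40, 40, 80)
  pl <- plateau_nucleus(shape = c(40, 40, 20), seed = 3)
  cmap <- classmap_from_labels(pl$true_classes, voxel)
  nuc <- pl$true_classes > 0L
  # whole nucleus: proportions equal global class proportions
  sa <- submask_analysis(cmap, nuc)
  expect_equal(sa$class_fractions,
               cmap$class_volumes / sum(cmap$class_volumes), tolerance = 1e-12)
  # submask entirely one class: one-hot proportions
  sub2 <- pl$true_classes == 2L
  sa2 <- submask_analysis(cmap, sub2)
  expect_equal(sa2$class_fractions[2], 1)
  expect_equal(sum(sa2$class_fractions[-2]), 0)
  # density arithmetic: n foci in V um^3 -> n/V per um^3
  f <- make_foci(rep(400, 50), rep(400, 50), rep(400, 50))
  sa3 <- submask_analysis(cmap, nuc, list(marker = f))
  expect_equal(unname(sa3$density_per_um3["marker"]), 50 / sa3$volume_um3)
  expect_error(submask_analysis(cmap, array(FALSE, dim(nuc))), "empty")
})

test_that("colocalization returns exact limits and matches the direct formula", {
  set.seed(9)
  a <- array(runif(16^3, 0, 100), c(16, 16, 16))
  va <- volume_image(a, 40)
  expect_equal(colocalize(va, va)$pcc, 1)
  anti <- volume_image(max(a) - a, 40)
  expect_equal(colocalize(va, anti)$pcc, -1)
  b <- array(runif(16^3, 0, 50), c(16, 16, 16))
  cc <- colocalize(va, volume_image(b, 40))
  pcc_direct <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(cc$pcc, pcc_direct, tolerance = 1e-12)
  expect_true(cc$m1 >= 0 && cc$m1 <= 1 && cc$m2 >= 0 && cc$m2 <= 1)
  # zero variance: NA sentinel, not an error
  flat <- volume_image(array(5, c(16, 16, 16)), 40)
  expect_true(is.na(colocalize(va, flat)$pcc))
  expect_error(colocalize(va, volume_image(matrix(1, 4, 4), 40)), "shapes")
})
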