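make_ellipsoid_image <- function(shape = c(48, 48, 24), voxel = c(40, 40, 80),
                                 level = 500, background = 100) {
  centre <- (shape - 1) * voxel / 2
  semi <- 0.4 * shape * voxel
  m <- ellipsoid_mask_oracle(shape, voxel, centre, semi)
  v <- array(background, shape); v[m] <- level
  list(img = volume_image(v, voxel, "dna"), mask = m, semi = semi)
}

test_that("nuclear segmentation recovers an ellipsoid volume within 5%", {
  e <- make_ellipsoid_image()
  mask <- segment_nucleus(e$img)
  v_analytic <- 4 / 3 * pi * prod(e$semi) / prod(c(40, 40, 80))
  expect_lt(abs(sum(mask) - v_analytic) / v_analytic, 0.05)
  expect_error(segment_nucleus(volume_image(array(5, c(8, 8, 4)), 40)),
               "constant")
})

test_that("with two nuclei in frame only the larger connected one is retained", {
  shape <- c(64, 32, 16); voxel <- c(40, 40, 80)
  big <- sphere_mask(shape, voxel, c(700, 620, 600), 1000)
  small <- sphere_mask(shape, voxel, c(1900, 620, 600), 500)
  v <- array(100, shape); v[big | small] <- 600
  mask <- segment_nucleus(volume_image(v, voxel))
  expect_gt(sum(mask & big) / sum(big), 0.9)
  expect_equal(sum(mask & small), 0L)
  expect_equal(max(label_components(mask)), 1L)
})

test_that("background-mode calibration anchors the outside mode at zero", {
  e <- make_ellipsoid_image(level = 600, background = 100)
  cal <- calibrate_intensity(e$img, e$mask)
  expect_equal(cal$calibration, 100, tolerance = 1)
  expect_equal(max(cal$values), 500, tolerance = 1)
  expect_equal(hist_mode(cal$values[!e$mask]), 0, tolerance = 1)
  expect_error(calibrate_intensity(e$img, array(TRUE, dim(e$img$values))),
               "full-frame")
})

test_that("7-plateau nuclei are classified at >99% voxel accuracy (noise-free) and >=95% at SNR 5", {
  pl <- plateau_nucleus(shape = c(48, 48, 24), noise_sd = 0, seed = 2)
  cm <- classify_chromatin(pl$dna, pl$nuclear_mask, seed = 2)
  acc <- mean(cm$labels[pl$nuclear_mask] == pl$true_classes[pl$nuclear_mask])
  expect_gt(acc, 0.99)
  # plateau separation 116.7 intensity units; SNR 5 => noise sd ~ 23
  pln <- plateau_nucleus(shape = c(48, 48, 24), noise_sd = 23, seed = 3)
  cmn <- classify_chromatin(pln$dna, pln$nuclear_mask, seed = 3)
  accn <- mean(cmn$labels[pln$nuclear_mask] == pln$true_classes[pln$nuclear_mask])
  expect_gt(accn, 0.95)
  # degenerate: constant nucleus
  flat <- volume_image(array(5, c(16, 16, 8)), c(40, 40, 80))
  expect_error(classify_chromatin(flat, array(TRUE, c(16, 16, 8))), "distinct")
})

test_that("class maps partition the nucleus with monotone class mean intensity", {
  pl <- plateau_nucleus(shape = c(40, 40, 20), noise_sd = 15, seed = 5)
  cm <- classify_chromatin(pl$dna, pl$nuclear_mask, seed = 5)
  expect_true(all(cm$labels[!pl$nuclear_mask] == 0L))
  expect_true(all(cm$labels[pl$nuclear_mask] %in% 1:7))
  expect_equal(sum(cm$class_volumes),
               sum(pl$nuclear_mask) * prod(c(40, 40, 80)) / 1e9)
  mu <- vapply(1:7, function(k) mean(pl$dna$values[cm$labels == k]), 0)
  expect_true(all(diff(mu) > 0))
})

test_that("classification is invariant to affine intensity rescaling before calibration", {
  pl <- plateau_nucleus(shape = c(40, 40, 20), noise_sd = 0, seed = 6)
  mask <- pl$nuclear_mask
  run <- function(img) {
    cal <- calibrate_intensity(img, mask)
    classify_chromatin(cal, mask, seed = 6)$labels
  }
  base <- run(pl$dna)
  resc <- volume_image(2.5 * pl$dna$values + 37, pl$dna$voxel_size)
  expect_equal(run(resc), base)
})

test_that("nucleolus voxels carry no chromatin signal and classify as class 1", {
  sp <- nucleus_spec(nucleolus_count = 2L, seed = 11)
  sim <- generate_nucleus(sp)
  mask <- sim$nuclear_mask  # classifier behaviour, not segmentation, on test
  cal <- calibrate_intensity(sim$dna, mask)
  cm <- classify_chromatin(cal, mask, seed = 11)
  # probe the nucleolar interior: the rim receives PSF bleed-through from
  # surrounding chromatin
  interior <- sim$nucleolus_mask &
    distance_to_set(!sim$nucleolus_mask, sp$voxel_size) > 250
  sel <- interior & mask
  expect_gt(sum(sel), 50)
  expect_gt(mean(cm$labels[sel] == 1L), 0.9)
})

test_that("IC surface of a solid sphere is a one-sided shell of the expected size", {
  # oracle: a face-connected inner boundary shell at radius ~ r - 1/2 holds
  # one voxel per surface grid column, i.e. E[max|n|] * 4 pi (r - 1/2)^2
  # voxels, with the orientation factor E[max|n|] of a uniform unit normal
  set.seed(31)
  nv <- matrix(rnorm(3e5), ncol = 3)
  nv <- abs(nv / sqrt(rowSums(nv^2)))
  e_max <- mean(apply(nv, 1, max))   # ~0.831
  for (r_vox in c(8, 12)) {
    n <- 2 * r_vox + 10
    shape <- c(n, n, n); voxel <- c(40, 40, 40)
    lab <- array(1L, shape)
    sph <- sphere_mask(shape, voxel, (shape - 1) * voxel / 2, 2 * r_vox * 40)
    lab[sph] <- 4L
    cm <- classmap_from_labels(lab, voxel)
    surf <- extract_ic_surface(cm)
    expect_true(all(lab[surf] >= 2L))
    expected <- e_max * 4 * pi * (r_vox - 0.5)^2
    expect_lt(abs(sum(surf) - expected) / expected, 0.10)
    # the shell hugs the sphere boundary: surface voxels lie near radius r
    ai <- arrayInd(which(surf), shape)
    rad <- sqrt(rowSums((sweep(ai - 1, 2, (n - 1) / 2) * 40)^2))
    expect_true(all(abs(rad - r_vox * 40) < 1.8 * 40))
  }
  # all-IC nucleus: empty surface
  lab2 <- array(0L, c(12, 12, 8))
  lab2[sphere_mask(c(12, 12, 8), c(40, 40, 40), c(220, 220, 140), 300)] <- 1L
  expect_equal(sum(extract_ic_surface(classmap_from_labels(lab2, c(40, 40, 40)))), 0)
  # checkerboard of class 1/2: every class-2 voxel is surface
  cb <- array(1L + (outer(outer(1:8, 1:8, "+"), 1:8, "+") %% 2L), c(8, 8, 8))
  cmcb <- classmap_from_labels(cb, voxel)
  scb <- extract_ic_surface(cmcb)
  expect_true(all(scb[cb == 2L]))
})

test_that("surface voxel set matches a brute-force neighbourhood scan", {
  set.seed(21)
  shape <- c(12, 12, 10)
  lab <- array(sample(0:4, prod(shape), replace = TRUE,
                      prob = c(0.2, 0.4, 0.2, 0.1, 0.1)), shape)
  cm <- classmap_from_labels(lab, c(40, 40, 80))
  surf <- extract_ic_surface(cm)
  brute <- array(FALSE, shape)
  for (i in 1:12) for (j in 1:12) for (k in 1:10) {
    if (lab[i, j, k] < 2L) next
    for (nb in list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                    c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))) {
      if (any(nb < 1) || nb[1] > 12 || nb[2] > 12 || nb[3] > 10) next
      if (lab[nb[1], nb[2], nb[3]] == 1L) brute[i, j, k] <- TRUE
    }
  }
  expect_equal(surf, brute)
})

test_that("surface-to-volume ratio matches analytic geometry", {
  shape <- c(40, 40, 40); voxel <- c(50, 50, 50)
  nuc_lab <- function(obj) {
    lab <- array(0L, shape)
    nuc <- ellipsoid_mask_oracle(shape, voxel, (shape - 1) * voxel / 2,
                                 c(950, 950, 950))
    lab[nuc] <- 1L; lab[obj] <- 4L
    classmap_from_labels(lab, voxel)
  }
  # axis-aligned cube: face counting is exact
  cube <- array(FALSE, shape); cube[15:24, 15:24, 15:24] <- TRUE  # L = 10
  s2v <- surface_to_volume(nuc_lab(cube), method = "faces")
  expect_equal(s2v$area_um2, 6 * 10^2 * 50^2 / 1e6)
  expect_equal(s2v$volume_um3, 10^3 * 50^3 / 1e9)
  # sphere: corrected estimate approaches 3/r
  for (r_vox in c(10, 12)) {
    sph <- sphere_mask(shape, voxel, (shape - 1) * voxel / 2, 2 * r_vox * 50)
    sv <- surface_to_volume(nuc_lab(sph), method = "corrected")
    r_um <- r_vox * 50 / 1000
    expect_lt(abs(sv$ratio_um - 3 / r_um) / (3 / r_um), 0.15)
  }
  # halving the radius doubles the ratio
  s1 <- surface_to_volume(nuc_lab(sphere_mask(shape, voxel,
        (shape - 1) * voxel / 2, 2 * 14 * 50)), method = "corrected")
  s2 <- surface_to_volume(nuc_lab(sphere_mask(shape, voxel,
        (shape - 1) * voxel / 2, 2 * 7 * 50)), method = "corrected")
  expect_equal(s2$ratio_um / s1$ratio_um, 2, tolerance = 0.15)
})

test_that("domain width measurement matches spheres and splits touching domains", {
  m <- sphere_mask(c(24, 24, 24), c(40, 40, 40), c(460, 460, 460), 400)
  w <- measure_cd_widths(m, voxel_size = c(40, 40, 40))
  expect_equal(w$n_domains, 1L)
  expect_lt(abs(w$mean_nm - 400), 41)  # within one voxel
  m2 <- sphere_mask(c(36, 24, 24), c(40, 40, 40), c(380, 460, 460), 400) |
        sphere_mask(c(36, 24, 24), c(40, 40, 40), c(780, 460, 460), 400)
  w2 <- measure_cd_widths(m2, voxel_size = c(40, 40, 40))
  expect_equal(w2$n_domains, 2L)
  expect_true(all(abs(w2$widths_nm - 400) < 41))
  # empty mask: empty distribution
  w0 <- measure_cd_widths(array(FALSE, c(8, 8, 8)), voxel_size = 40)
  expect_equal(w0$n_domains, 0L)
})

test_that("domain widths recover the generator's mean CD diameter within 15%", {
  sp <- nucleus_spec(chain_count = 10L, cds_per_chain = 8L, noise_sd = 5,
                     seed = 14)
  sim <- generate_nucleus(sp)
  w <- measure_cd_widths(sim$classmap >= 2L, voxel_size = sp$voxel_size)
  expect_lt(abs(w$mean_nm - 250) / 250, 0.15)
})

test_that("compartment proxies partition the nucleus around rim and chromocenters", {
  shape <- c(32, 32, 32); voxel <- c(50, 50, 50)
  lab <- array(0L, shape)
  R <- 700
  nuc <- sphere_mask(shape, voxel, (shape - 1) * voxel / 2, 2 * R)
  lab[nuc] <- 1L
  cm <- classmap_from_labels(lab, voxel)
  # rim 0, no chromocenters: A is the whole nucleus
  cm0 <- compartment_masks(cm, rim_thickness = 0)
  expect_equal(cm0$A_proxy, nuc)
  # spherical shell volume within 10% of analytic
  t_nm <- 150
  cmr <- compartment_masks(cm, rim_thickness = t_nm)
  v_shell <- 4 / 3 * pi * (R^3 - (R - t_nm)^3) / prod(voxel)
  expect_lt(abs(sum(cmr$rim) - v_shell) / v_shell, 0.25)
  # masks partition the nucleus
  expect_true(all(xor(cmr$A_proxy[nuc], cmr$B_proxy[nuc])))
  expect_true(!any(cmr$A_proxy[!nuc] | cmr$B_proxy[!nuc]))
  # chromocenters join B
  lab2 <- lab
  lab2[sphere_mask(shape, voxel, c(800, 800, 800), 500) & nuc] <- 7L
  cm2 <- compartment_masks(classmap_from_labels(lab2, voxel), rim_thickness = 0)
  expect_true(all(cm2$B_proxy[lab2 == 7L]))
  expect_error(compartment_masks(cm, rim_thickness = 5000), "rim_thickness")
})
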