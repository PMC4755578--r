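test_that("synthetic textures have a power-law spectrum, byte range, determinism", {
  imgs <- synth_textures(2, side = 256, spectrum_exponent = 2, seed = 50)
  for (img in imgs) {
    expect_true(all(img >= 0 & img <= 255))
    expect_lt(abs(spectral_slope(img) - (-2)), 0.3)
  }
  imgs2 <- synth_textures(2, side = 256, spectrum_exponent = 2, seed = 50)
  expect_identical(imgs, imgs2)
  # exponent is honored
  flat <- synth_textures(1, side = 256, spectrum_exponent = 1, seed = 51)
  expect_lt(abs(spectral_slope(flat[[1]]) - (-1)), 0.3)
})

test_that("patch extraction is shaped, bounded and seeded", {
  imgs <- synth_textures(3, side = 64, seed = 60)
  ps <- extract_patches(imgs, patch_side = 25, n = 10, seed = 61)
  expect_equal(dim(ps$patches), c(10L, 625L))
  expect_true(all(ps$patches >= 0 & ps$patches <= 255))
  ps2 <- extract_patches(imgs, patch_side = 25, n = 10, seed = 61)
  expect_identical(ps, ps2)
  expect_error(extract_patches(list(matrix(0, 10, 10)), patch_side = 25,
                               n = 1, seed = 1),
               "smaller than patch_side")
  # PNG round trip through files
  dir <- withr::local_tempdir()
  paths <- file.path(dir, sprintf("t%d.png", 1:2))
  for (i in 1:2) png::writePNG(imgs[[i]] / 255, paths[i])
  psf <- extract_patches(paths, patch_side = 25, n = 5, seed = 62)
  expect_equal(dim(psf$patches), c(5L, 625L))
})

test_that("whitening gives unit uncorrelated components and a tight round trip", {
  imgs <- synth_textures(6, side = 96, seed = 70)
  ps <- extract_patches(imgs, patch_side = 12, n = 10000, seed = 71)
  wm <- fit_whitening(ps, d = 40)
  codes <- whiten_patches(wm, ps)
  expect_equal(dim(codes), c(40L, 10000L))
  C <- tcrossprod(codes) / (ncol(codes) - 1)
  expect_lt(max(abs(C - diag(40))), 0.05)
  # round-trip residual variance equals the discarded eigenvalue mass
  rec <- unwhiten_codes(wm, codes)
  resid_var <- sum((ps$patches - rec)^2) / (nrow(ps$patches) - 1)
  expect_lt(abs(resid_var - wm$discarded_variance) /
              wm$discarded_variance, 1e-2)
  expect_true(all(diff(wm$eigenvalues) <= 0))
  expect_true(all(wm$eigenvalues > 0))
  expect_error(fit_whitening(ps$patches[1:30, ], d = 40), "more patches")
})

test_that("gabor bank spans orientations and is orientation selective", {
  bank <- gabor_bank(12, patch_side = 25)
  expect_equal(dim(bank$filters), c(12L, 625L))
  expect_equal(diff(bank$orientations), rep(180 / 12, 11))
  expect_equal(sqrt(rowSums(bank$filters^2)), rep(1, 12))
  expect_lt(max(abs(rowMeans(bank$filters))), 1e-12)
  # each filter prefers a matched grating over the orthogonal one
  half <- 12; xy <- expand.grid(x = -half:half, y = -half:half)
  for (i in seq_len(12)) {
    th <- bank$orientations[i] * pi / 180
    grat_par <- cos(2 * pi * (xy$x * cos(th) + xy$y * sin(th)) / 8)
    tho <- th + pi / 2
    grat_orth <- cos(2 * pi * (xy$x * cos(tho) + xy$y * sin(tho)) / 8)
    expect_gt(abs(sum(bank$filters[i, ] * grat_par)),
              abs(sum(bank$filters[i, ] * grat_orth)))
  }
})

test_that("rotating and resampling the first filter reproduces the others", {
  p <- 25
  bank <- gabor_bank(8, patch_side = p)
  f0 <- matrix(bank$filters[1, ], p, p)
  half <- (p - 1) / 2
  rotate_bilinear <- function(img, psi) {
    out <- matrix(0, p, p)
    for (ix in 1:p) for (iy in 1:p) {
      # source coordinates: rotate the target grid backwards
      x <- (ix - 1 - half) * cos(psi) + (iy - 1 - half) * sin(psi) + half
      y <- -(ix - 1 - half) * sin(psi) + (iy - 1 - half) * cos(psi) + half
      x0 <- floor(x); y0 <- floor(y)
      if (x0 < 0 || y0 < 0 || x0 >= p - 1 || y0 >= p - 1) next
      fx <- x - x0; fy <- y - y0
      out[ix, iy] <- (1 - fx) * (1 - fy) * img[x0 + 1, y0 + 1] +
        fx * (1 - fy) * img[x0 + 2, y0 + 1] +
        (1 - fx) * fy * img[x0 + 1, y0 + 2] +
        fx * fy * img[x0 + 2, y0 + 2]
    }
    out
  }
  for (i in c(3, 5)) { # mid-range orientations
    psi <- bank$orientations[i] * pi / 180
    rot <- as.numeric(rotate_bilinear(f0, psi))
    ip <- sum(rot * bank$filters[i, ]) /
      sqrt(sum(rot^2) * sum(bank$filters[i, ]^2))
    expect_gt(abs(ip), 0.95)
  }
})

test_that("composed feedforward matrix is the filter-response map", {
  imgs <- synth_textures(4, side = 96, seed = 80)
  ps <- extract_patches(imgs, patch_side = 25, n = 2000, seed = 81)
  wm <- fit_whitening(ps, d = 30)
  bank <- gabor_bank(20, patch_side = 25)
  W <- compose_feedforward(bank, wm)
  expect_equal(dim(W), c(20L, 30L))
  codes <- whiten_patches(wm, ps)[, 1:5]
  rec <- t(unwhiten_codes(wm, codes, add_mean = FALSE))
  expect_equal(W %*% codes, bank$filters %*% rec, tolerance = 1e-10)
  expect_equal(drop(W %*% rep(0, 30)), rep(0, 20))
  bank_small <- gabor_bank(20, patch_side = 12)
  expect_error(compose_feedforward(bank_small, wm), "match")
})

test_that("image_network assembles the pipeline at the requested drive", {
  imgs <- synth_textures(4, side = 96, seed = 90)
  net <- image_network(imgs, M = 20, d = 8, n_patches = 1500,
                       target_drive = 0.1, seed = 91)
  expect_s3_class(net$params, "network_params")
  expect_equal(c(net$params$M, net$params$N), c(20, 8))
  drive <- net$params$W %*% net$codes
  expect_equal(mean(sqrt(colMeans(drive^2))), 0.1, tolerance = 1e-10)
  smp <- code_sampler(net$codes)
  expect_equal(dim(smp(7)), c(8L, 7L))
  probe <- gabor_probe_code(net, 90)
  expect_length(probe, 8)
  # the objective requires the bank to drive every input component
  expect_error(image_network(imgs, M = 20, d = 30, n_patches = 1500,
                             seed = 91),
               "rank-deficient")
  expect_equal(sqrt(sum(probe^2)), net$mean_code_norm, tolerance = 1e-10)
})
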