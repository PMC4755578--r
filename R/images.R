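#' Synthetic power-law textures
#'
#' Random-phase Gaussian textures whose radially averaged spatial power
#' spectrum falls off as \eqn{f^{-\beta}} (default \eqn{\beta = 2}, the
#' roughly 1/f^2 spectrum of natural scenes), rescaled to the 0-255 byte
#' range around mid-grey. `contrast_scale` sets the pixel RMS contrast as a
#' fraction of the half-range, so the default emulates the predominance of
#' low contrasts in natural images.
#'
#' @param n Number of images.
#' @param side Image side in pixels (>= 64).
#' @param spectrum_exponent Power-spectrum exponent beta (default 2).
#' @param contrast_scale RMS pixel contrast as a fraction of 127.5
#'   (default 0.35).
#' @param seed Optional seed; same seed, same images.
#' @return List of `side` x `side` numeric matrices with values in [0, 255].
#' @export
synth_textures <- function(n, side = 256, spectrum_exponent = 2,
                           contrast_scale = 0.35, seed = NULL) {
  stopifnot(n >= 1, side >= 64, spectrum_exponent >= 0, contrast_scale > 0)
  with_seed(seed, {
    fr <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
    f <- sqrt(outer(fr^2, fr^2, "+"))
    amp <- ifelse(f > 0, f^(-spectrum_exponent / 2), 0)  # amplitude ~ f^(-b/2)
    lapply(seq_len(n), function(i) {
      z <- matrix(stats::rnorm(side^2), side, side)
      img <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / side^2
      img <- img - mean(img)
      img <- img / stats::sd(img) * contrast_scale * 127.5 + 127.5
      pmin(pmax(img, 0), 255)
    })
  })
}

#' Radially averaged log-log spectral slope of an image
#'
#' Fits a line to log mean power versus log frequency over mid-range radial
#' frequencies; used to verify that generated textures have the intended
#' power-law spectrum.
#'
#' @param img Square numeric matrix.
#' @return Fitted slope (a 1/f^2 image gives about -2).
#' @export
spectral_slope <- function(img) {
  side <- nrow(img)
  stopifnot(ncol(img) == side)
  P <- Mod(stats::fft(img - mean(img)))^2
  fr <- c(0:(side %/% 2), -((side - side %/% 2 - 1):1)) / side
  f <- sqrt(outer(fr^2, fr^2, "+"))
  bins <- seq(2 / side, 0.35, length.out = 24)
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  pw <- vapply(seq_len(length(bins) - 1L), function(i) {
    sel <- f >= bins[i] & f < bins[i + 1]
    if (any(sel)) mean(P[sel]) else NA_real_
  }, numeric(1))
  ok <- is.finite(pw) & pw > 0
  unname(stats::coef(stats::lm(log(pw[ok]) ~ log(mids[ok])))[2])
}

#' Extract random square patches from grayscale images
#'
#' Draws `n` patches of `patch_side` x `patch_side` pixels at seeded uniform
#' locations from the supplied images (each chosen uniformly per patch).
#' Images may be numeric matrices (grayscale, any range), 3-d arrays (RGB;
#' converted by the standard Rec.601 luminance weights and scaled to 0-255),
#' or file paths to PNG images.
#'
#' @param images List of matrices/arrays, or character vector of PNG paths.
#' @param patch_side Patch side in pixels (default 25).
#' @param n Number of patches.
#' @param seed Optional seed for the patch locations.
#' @return A `"patch_set"`: `patches` (n x patch_side^2 matrix, one flattened
#'   patch per row), `patch_side`.
#' @export
extract_patches <- function(images, patch_side = 25, n, seed = NULL) {
  if (is.character(images)) images <- lapply(images, read_gray_image)
  if (is.matrix(images) || is.array(images)) images <- list(images)
  images <- lapply(seq_along(images), function(i) {
    img <- to_gray(images[[i]])
    if (nrow(img) < patch_side || ncol(img) < patch_side)
      stop("image ", i, " is smaller than patch_side (",
           nrow(img), "x", ncol(img), " < ", patch_side, ")")
    img
  })
  with_seed(seed, {
    pick <- sample.int(length(images), n, replace = TRUE)
    P <- t(vapply(seq_len(n), function(j) {
      img <- images[[pick[j]]]
      r0 <- sample.int(nrow(img) - patch_side + 1L, 1L)
      c0 <- sample.int(ncol(img) - patch_side + 1L, 1L)
      as.numeric(img[r0:(r0 + patch_side - 1L), c0:(c0 + patch_side - 1L)])
    }, numeric(patch_side^2)))
    structure(list(patches = P, patch_side = patch_side),
              class = "patch_set")
  })
}

read_gray_image <- function(path) {
  img <- png::readPNG(path)
  to_gray(img) # readPNG returns [0,1]; to_gray rescales
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    w <- c(0.299, 0.587, 0.114)
    img <- w[1] * img[, , 1] + w[2] * img[, , 2] + w[3] * img[, , 3]
  }
  img <- as.matrix(img)
  if (max(img) <= 1) img <- img * 255   # [0,1]-coded images to byte scale
  img
}

#' Fit a PCA reduction + whitening model to image patches
#'
#' Mean-centers the patches, keeps the top `d` principal components and
#' whitens by dividing each eigenvector by the square root of its eigenvalue
#' (plus a small floor for stability), so whitened training data has unit,
#' uncorrelated variance. The `reconstruction` matrix maps whitened codes
#' back to (mean-free) pixel space by undoing the scaling and projection.
#'
#' @param patches A [extract_patches()] result or an n x p^2 matrix.
#' @param d Reduced dimension (default 100).
#' @param eig_floor_frac Eigenvalue floor as a fraction of the largest
#'   eigenvalue (default 1e-8).
#' @return A `"whitening_model"`: `mean_vector`, `eigenvectors` (p^2 x d),
#'   `eigenvalues` (length d), `whitener` (d x p^2), `reconstruction`
#'   (p^2 x d), `d`, `discarded_variance`.
#' @export
fit_whitening <- function(patches, d = 100, eig_floor_frac = 1e-8) {
  P <- if (inherits(patches, "patch_set")) patches$patches else as.matrix(patches)
  if (nrow(P) <= d)
    stop("need more patches (", nrow(P), ") than components d = ", d)
  mu <- colMeans(P)
  pc <- stats::prcomp(P, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  d <- min(d, sum(ev > 0))
  floor_ <- eig_floor_frac * ev[1]
  lam <- ev[seq_len(d)] + floor_
  V <- pc$rotation[, seq_len(d), drop = FALSE]
  structure(list(mean_vector = mu, eigenvectors = V, eigenvalues = lam,
                 whitener = t(V) / sqrt(lam),       # rows scaled: D^-1/2 V^T
                 reconstruction = t(t(V) * sqrt(lam)),
                 d = d,
                 discarded_variance = sum(ev[-seq_len(d)])),
            class = "whitening_model")
}

#' Project patches to whitened codes
#'
#' @param model A [fit_whitening()] model.
#' @param patches A `patch_set` or n x p^2 matrix.
#' @return d x n matrix of whitened codes, one sample per column (the input
#'   convention of [network_params()]).
#' @export
whiten_patches <- function(model, patches) {
  P <- if (inherits(patches, "patch_set")) patches$patches else as.matrix(patches)
  model$whitener %*% (t(P) - model$mean_vector)
}

#' Reconstruct patches from whitened codes
#'
#' @param model A [fit_whitening()] model.
#' @param codes d x n matrix of whitened codes.
#' @param add_mean Add back the training mean patch (default TRUE).
#' @return n x p^2 matrix of reconstructed patches.
#' @export
unwhiten_codes <- function(model, codes, add_mean = TRUE) {
  R <- model$reconstruction %*% codes
  if (add_mean) R <- R + model$mean_vector
  t(R)
}

#' A single Gabor patch
#'
#' Cosine-phase Gabor: an oriented sinusoid of the given wavelength under an
#' isotropic Gaussian envelope, centered in the patch, mean-subtracted and
#' unit-normed.
#'
#' @param orientation_deg Orientation in degrees (0 = horizontal carrier
#'   variation along x).
#' @param patch_side Patch side in pixels.
#' @param wavelength Carrier wavelength in pixels.
#' @param sigma Envelope standard deviation in pixels.
#' @param phase Carrier phase in radians (0 = even/cosine).
#' @return Numeric vector of length `patch_side^2` (flattened patch).
#' @export
gabor_patch <- function(orientation_deg, patch_side = 25, wavelength = 8,
                        sigma = 4, phase = 0) {
  half <- (patch_side - 1) / 2
  gx <- matrix(rep(-half:half, patch_side), patch_side, patch_side)
  gy <- t(gx)
  th <- orientation_deg * pi / 180
  xp <- gx * cos(th) + gy * sin(th)
  g <- exp(-(gx^2 + gy^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / wavelength + phase)
  g <- g - mean(g)
  as.numeric(g / sqrt(sum(g^2)))
}

#' Bank of orientation-spanning Gabor filters
#'
#' M Gabor filters sharing center, spatial frequency, envelope and phase,
#' with orientations equally spaced over [0, 180) degrees (spacing 180/M);
#' each filter is mean-subtracted and unit-normed.
#'
#' @param M Number of filters (>= 2).
#' @inheritParams gabor_patch
#' @return A `"gabor_bank"`: `filters` (M x patch_side^2), `orientations`
#'   (degrees), `spatial_frequency` (cycles/pixel), `envelope_sigma`,
#'   `phase`, `patch_side`.
#' @export
gabor_bank <- function(M, patch_side = 25, wavelength = 8, sigma = 4,
                       phase = 0) {
  stopifnot(M >= 2)
  oris <- (seq_len(M) - 1) * 180 / M
  filt <- t(vapply(oris, gabor_patch, numeric(patch_side^2),
                   patch_side = patch_side, wavelength = wavelength,
                   sigma = sigma, phase = phase))
  structure(list(filters = filt, orientations = oris,
                 spatial_frequency = 1 / wavelength, envelope_sigma = sigma,
                 phase = phase, patch_side = patch_side),
            class = "gabor_bank")
}

#' Compose the ecological feedforward matrix
#'
#' The feedforward matrix of the ecological model is the product of the
#' Gabor filter bank (M x p^2) and the whitening model's reconstruction map
#' (p^2 x d): applying it to a whitened code gives exactly the filter
#' responses to the reconstructed (mean-free) patch.
#'
#' @param bank A [gabor_bank()].
#' @param model A [fit_whitening()] model for the same patch size.
#' @return M x d feedforward matrix.
#' @export
compose_feedforward <- function(bank, model) {
  stopifnot(inherits(bank, "gabor_bank"), inherits(model, "whitening_model"))
  if (ncol(bank$filters) != length(model$mean_vector))
    stop("Gabor patch size does not match whitening patch size")
  bank$filters %*% model$reconstruction
}

#' Assemble the ecological hypercolumn network
#'
#' Full input pipeline: random patches from the supplied images, PCA
#' reduction + whitening to d dimensions, an M-filter Gabor bank, and the
#' composed M x d feedforward matrix. Whitened codes are rescaled by a
#' single global factor so the mean RMS feedforward drive per neuron equals
#' `target_drive`, placing the network in the low-contrast sensitive regime
#' of the logistic (natural scenes are dominated by low contrasts).
#'
#' A practical constraint: a bank sharing center, frequency, envelope and
#' phase has low effective rank (the azimuthal harmonics under the spectral
#' annulus of the filters), and the log-determinant objective is finite only
#' when the input dimension does not exceed what the bank transmits. The
#' composed feedforward matrix is therefore checked for conditioning, and
#' desk-scale runs use `d` near the bank's effective rank (about 9 for the
#' default wavelength-8, sigma-4 cosine Gabors).
#'
#' @param images Images accepted by [extract_patches()].
#' @param M Output neurons / Gabor orientations (default 60).
#' @param d Whitened input dimension (default 8).
#' @param n_patches Training patches to extract (default 10000).
#' @param patch_side Patch side in pixels (default 25).
#' @param wavelength,sigma,phase Gabor parameters, see [gabor_patch()].
#' @param target_drive Desired mean RMS of W x over the training codes
#'   (default 0.1).
#' @param seed Seed for patch extraction.
#' @return An `"image_network"` list: `params` ([network_params()], K = 0),
#'   `codes` (d x n scaled training codes), `whitening`, `bank`,
#'   `input_scale`, `mean_code_norm`.
#' @export
image_network <- function(images, M = 60, d = 8, n_patches = 5000,
                          patch_side = 25, wavelength = 8, sigma = 4,
                          phase = 0, target_drive = 0.1, seed = NULL) {
  ps <- extract_patches(images, patch_side = patch_side, n = n_patches,
                        seed = seed)
  wm <- fit_whitening(ps, d = d)
  bank <- gabor_bank(M, patch_side = patch_side, wavelength = wavelength,
                     sigma = sigma, phase = phase)
  W <- compose_feedforward(bank, wm)
  sv <- svd(W)$d
  if (sv[length(sv)] / sv[1] < 1e-6)
    stop("feedforward matrix is rank-deficient: the Gabor bank cannot ",
         "drive all ", d, " whitened components; reduce d toward the ",
         "bank's effective rank")
  codes <- whiten_patches(wm, ps)
  drive_rms <- sqrt(colMeans((W %*% codes)^2))
  input_scale <- target_drive / mean(drive_rms)
  codes <- codes * input_scale
  structure(list(params = network_params(W), codes = codes, whitening = wm,
                 bank = bank, input_scale = input_scale,
                 mean_code_norm = mean(sqrt(colSums(codes^2)))),
            class = "image_network")
}

#' Sampler over stored training codes
#'
#' Draws columns with replacement from a code matrix, for use as the
#' `sampler` argument of [train_network()].
#'
#' @param codes d x n matrix.
#' @return Function of one argument n returning a d x n matrix.
#' @export
code_sampler <- function(codes) {
  codes <- as.matrix(codes)
  function(n) codes[, sample.int(ncol(codes), n, replace = TRUE), drop = FALSE]
}

#' Whitened code of an oriented Gabor probe
#'
#' Builds a Gabor stimulus with the bank's spatial frequency and envelope at
#' the requested orientation, projects it through the whitening model, and
#' scales it to `contrast` times the mean norm of the training codes (the
#' mean contrast of the training stimuli).
#'
#' @param net An [image_network()].
#' @param orientation_deg Probe orientation in degrees.
#' @param contrast Multiplicative contrast (1 = mean training contrast).
#' @return Input vector of length d.
#' @export
gabor_probe_code <- function(net, orientation_deg, contrast = 1) {
  stopifnot(inherits(net, "image_network"))
  probe <- gabor_patch(orientation_deg, patch_side = net$bank$patch_side,
                       wavelength = 1 / net$bank$spatial_frequency,
                       sigma = net$bank$envelope_sigma,
                       phase = net$bank$phase)
  code <- drop(net$whitening$whitener %*% probe)
  code <- code / sqrt(sum(code^2)) * net$mean_code_norm
  contrast * code
}
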