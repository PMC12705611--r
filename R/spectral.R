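#' Reflectance band windows for the minimum-corrected NDVI
#'
#' The index uses mean reflectance over a near-infrared window (symbol m750,
#' 740--750 nm) and a green window (m550, 540--560 nm), plus the per-pixel
#' minimum reflectance over the retained 430--800 nm range (mmin).
#'
#' @param nir_window,green_window,retained_range Two-element numeric ranges
#'   in nm.
#' @return A list of class `band_windows`.
#' @export
band_windows <- function(nir_window = c(740, 750),
                         green_window = c(540, 560),
                         retained_range = c(430, 800)) {
  chk <- function(w, nm) {
    if (length(w) != 2 || w[1] >= w[2]) {
      stop("band_windows: `", nm, "` must be an increasing range", call. = FALSE)
    }
  }
  chk(nir_window, "nir_window"); chk(green_window, "green_window")
  chk(retained_range, "retained_range")
  if (nir_window[1] < retained_range[1] || nir_window[2] > retained_range[2] ||
      green_window[1] < retained_range[1] || green_window[2] > retained_range[2]) {
    stop("band_windows: windows must lie inside the retained range", call. = FALSE)
  }
  structure(list(nir_window = nir_window, green_window = green_window,
                 retained_range = retained_range),
            class = "band_windows")
}

# window means + per-pixel minimum for a matrix of spectra (pixels x bands)
band_summaries <- function(spectra, wavelengths, bands) {
  keep <- wavelengths >= bands$retained_range[1] &
    wavelengths <= bands$retained_range[2]
  nir <- wavelengths >= bands$nir_window[1] & wavelengths <= bands$nir_window[2]
  grn <- wavelengths >= bands$green_window[1] &
    wavelengths <= bands$green_window[2]
  if (!any(nir) || !any(grn)) {
    stop("wavelength grid does not cover the NDVI band windows", call. = FALSE)
  }
  list(
    m750 = rowMeans(spectra[, nir, drop = FALSE]),
    m550 = rowMeans(spectra[, grn, drop = FALSE]),
    mmin = apply(spectra[, keep, drop = FALSE], 1, min)
  )
}

#' Minimum-corrected NDVI of one reflectance spectrum
#'
#' Computes (m750 - m550) / (m750 + m550 + 2 * mmin), where m750 and m550 are
#' the mean reflectances over the near-infrared and green windows and mmin is
#' the minimum reflectance over the retained range. The minimum term in the
#' denominator damps the index for dark pixels. For nonnegative reflectance
#' the value always lies in \[-1, 1\].
#'
#' @param spectrum Nonnegative reflectance values.
#' @param wavelengths Wavelength grid in nm, same length as `spectrum`.
#' @param bands A [band_windows()] object.
#' @return A scalar NDVI value.
#' @export
#' @examples
#' wl <- seq(430, 800, 5)
#' ndvi_pixel(rep(0.4, length(wl)), wl) # flat spectrum -> 0
ndvi_pixel <- function(spectrum, wavelengths, bands = band_windows()) {
  if (any(spectrum < 0)) {
    stop("ndvi_pixel: reflectance must be nonnegative", call. = FALSE)
  }
  s <- band_summaries(matrix(spectrum, nrow = 1), wavelengths, bands)
  den <- s$m750 + s$m550 + 2 * s$mmin
  if (den == 0) {
    stop("ndvi_pixel: all-zero spectrum gives an undefined NDVI", call. = FALSE)
  }
  (s$m750 - s$m550) / den
}

#' Per-pixel NDVI of a cube with equal-count binning
#'
#' Computes the minimum-corrected NDVI for every in-mask pixel, sorts the
#' values and splits them into `n_bins` equal-count bins; the image summary
#' is the mean of the bin means (which equals the plain pixel mean whenever
#' `n_bins` divides the pixel count evenly).
#'
#' @param cube An `hs_cube` from [make_cube()] (or any list with `cube`,
#'   `wavelengths`, `mask`).
#' @param mask Optional logical matrix overriding `cube$mask`.
#' @param n_bins Number of equal-count bins (default 50).
#' @param bands A [band_windows()] object.
#' @return A list of class `ndvi_result`: `per_pixel`, `bin_means`,
#'   `image_mean`.
#' @export
ndvi_image <- function(cube, mask = NULL, n_bins = 50, bands = band_windows()) {
  if (is.null(mask)) mask <- cube$mask
  if (!any(mask)) stop("ndvi_image: mask is empty", call. = FALSE)
  spectra <- cube_to_matrix(cube, mask)
  s <- band_summaries(spectra, cube$wavelengths, bands)
  den <- s$m750 + s$m550 + 2 * s$mmin
  if (any(den == 0)) {
    stop("ndvi_image: all-zero spectra give undefined NDVI values", call. = FALSE)
  }
  nd <- (s$m750 - s$m550) / den
  n <- length(nd)
  if (n < n_bins) {
    warning("fewer in-mask pixels than bins; bins collapse to singletons")
    n_bins <- n
  }
  srt <- sort(nd)
  bin <- ceiling(seq_len(n) * n_bins / n)
  bin_means <- as.numeric(tapply(srt, bin, mean))
  structure(
    list(per_pixel = nd, bin_means = bin_means, image_mean = mean(bin_means)),
    class = "ndvi_result"
  )
}

# flatten an hs_cube to an (in-mask pixels) x bands matrix
cube_to_matrix <- function(cube, mask = cube$mask) {
  arr <- cube$cube
  nb <- dim(arr)[3]
  flat <- matrix(arr, ncol = nb)     # pixels (column-major) x bands
  flat[as.vector(mask), , drop = FALSE]
}

#' Two-atom nonnegative spectral dictionary for shoot health
#'
#' Factorises a set of plant mean spectra into two nonnegative atoms by
#' alternating nonnegative least squares, labelling the atom with the higher
#' minimum-corrected NDVI as "green" (healthy tissue) and the other as
#' "non-green". Initialisation is deterministic: the input spectra with the
#' highest and lowest NDVI seed the two atoms.
#'
#' @param spectra Matrix of mean spectra (rows = spectra, cols = bands), or a
#'   data frame.
#' @param wavelengths Wavelength grid in nm.
#' @param bands A [band_windows()] object.
#' @param max_iter,tol Alternating-update controls.
#' @return A list of class `spectral_dictionary`: `atoms` (2 x bands, rows
#'   named green/non_green), `wavelengths`, `coefficients` (n x 2 nonnegative),
#'   `recon_error` (mean squared reconstruction error), `degenerate` flag.
#' @export
fit_health_dictionary <- function(spectra, wavelengths,
                                  bands = band_windows(),
                                  max_iter = 100, tol = 1e-10) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) {
    stop("fit_health_dictionary: need at least 2 spectra", call. = FALSE)
  }
  if (any(spectra < 0)) {
    stop("fit_health_dictionary: spectra must be nonnegative", call. = FALSE)
  }
  nd <- apply(spectra, 1, ndvi_pixel, wavelengths = wavelengths, bands = bands)
  if (max(nd) - min(nd) < 1e-10 &&
      max(apply(spectra, 2, function(x) diff(range(x)))) < 1e-10) {
    warning("all spectra identical: dictionary is degenerate (single atom)")
    atoms <- rbind(green = spectra[1, ], non_green = spectra[1, ])
    return(structure(
      list(atoms = atoms, wavelengths = wavelengths,
           coefficients = cbind(green = rep(1, nrow(spectra)),
                                non_green = rep(0, nrow(spectra))),
           recon_error = 0, degenerate = TRUE),
      class = "spectral_dictionary"
    ))
  }
  atoms <- rbind(spectra[which.max(nd), ], spectra[which.min(nd), ])
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    co <- nnls_two(t(atoms), t(spectra))           # n x 2
    # atom update: per band, nonnegative LS in the two coefficient columns;
    # scale is pinned by the data, so no renormalisation is needed and
    # coefficient shares remain comparable to mixture weights
    atoms <- t(nnls_two(co, spectra))              # 2 x bands
    recon <- nnls_two(t(atoms), t(spectra)) %*% atoms
    err <- mean((spectra - recon)^2)
    if (abs(err_prev - err) < tol) break
    err_prev <- err
  }
  co <- nnls_two(t(atoms), t(spectra))
  nd_atom <- apply(atoms, 1, ndvi_pixel, wavelengths = wavelengths,
                   bands = bands)
  ord <- order(nd_atom, decreasing = TRUE)         # green first
  atoms <- atoms[ord, , drop = FALSE]
  co <- co[, ord, drop = FALSE]
  rownames(atoms) <- c("green", "non_green")
  colnames(co) <- c("green", "non_green")
  structure(
    list(atoms = atoms, wavelengths = wavelengths, coefficients = co,
         recon_error = mean((spectra - co %*% atoms)^2), degenerate = FALSE),
    class = "spectral_dictionary"
  )
}

# closed-form 2-variable nonnegative least squares, vectorised over columns
# of B: minimise ||B[,j] - A c||^2 subject to c >= 0, A is p x 2.
# returns an ncol(B) x 2 matrix of coefficients.
nnls_two <- function(A, B) {
  G <- crossprod(A)                   # 2 x 2
  bt <- crossprod(A, B)               # 2 x m
  m <- ncol(B)
  det_g <- G[1, 1] * G[2, 2] - G[1, 2]^2
  if (det_g <= 1e-300) {
    # collinear atoms: project on first only
    c1 <- pmax(bt[1, ] / max(G[1, 1], 1e-300), 0)
    return(cbind(c1, rep(0, m)))
  }
  c1 <- (G[2, 2] * bt[1, ] - G[1, 2] * bt[2, ]) / det_g
  c2 <- (G[1, 1] * bt[2, ] - G[1, 2] * bt[1, ]) / det_g
  bad <- c1 < 0 | c2 < 0
  if (any(bad)) {
    a1 <- pmax(bt[1, bad] / G[1, 1], 0)
    a2 <- pmax(bt[2, bad] / G[2, 2], 0)
    # residual^2 up to ||b||^2: -2 c.b + c' G c, evaluated on each axis
    r1 <- -2 * a1 * bt[1, bad] + a1^2 * G[1, 1]
    r2 <- -2 * a2 * bt[2, bad] + a2^2 * G[2, 2]
    use1 <- r1 <= r2
    c1[bad] <- ifelse(use1, a1, 0)
    c2[bad] <- ifelse(use1, 0, a2)
  }
  cbind(c1, c2)
}

#' Nonnegative projection coefficients onto a fitted dictionary
#'
#' Projects spectra onto the two dictionary atoms by nonnegative least
#' squares, returning the per-spectrum (green, non_green) coefficients. For
#' spectra that are mixtures of the endmember scale the dictionary was
#' fitted at, the green coefficient share approximates the green mixture
#' weight.
#'
#' @param dictionary A [fit_health_dictionary()] result.
#' @param spectra Matrix of spectra (rows) on the dictionary's grid.
#' @return An n x 2 nonnegative matrix with columns `green`, `non_green`.
#' @export
dictionary_coefficients <- function(dictionary, spectra) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(dictionary$wavelengths)) {
    stop("dictionary_coefficients: spectra are on an incompatible grid",
         call. = FALSE)
  }
  co <- nnls_two(t(dictionary$atoms), t(spectra))
  colnames(co) <- c("green", "non_green")
  co
}

#' Healthy-pixel fraction of a cube under a fitted dictionary
#'
#' Each in-mask pixel is projected onto the two dictionary atoms by
#' nonnegative least squares and called healthy when its green-atom weight
#' exceeds its non-green weight.
#'
#' @param cube An `hs_cube`.
#' @param dictionary A [fit_health_dictionary()] result on the same grid.
#' @param mask Optional logical matrix overriding `cube$mask`.
#' @return Scalar fraction in \[0, 1\].
#' @export
health_fraction <- function(cube, dictionary, mask = NULL) {
  if (is.null(mask)) mask <- cube$mask
  if (!any(mask)) stop("health_fraction: mask is empty", call. = FALSE)
  if (length(dictionary$wavelengths) != length(cube$wavelengths)) {
    stop("health_fraction: dictionary fitted on an incompatible grid",
         call. = FALSE)
  }
  spectra <- cube_to_matrix(cube, mask)
  co <- nnls_two(t(dictionary$atoms), t(spectra))
  mean(co[, 1] > co[, 2])
}

#' Euclidean multi-view shoot size
#'
#' Combines the shoot pixel counts of the three camera views into one size
#' proxy: the Euclidean norm sqrt(top^2 + side^2 + front^2).
#'
#' @param counts Three nonnegative pixel counts.
#' @return Scalar size.
#' @export
#' @examples
#' euclidean_size(c(3, 4, 0)) # 5
euclidean_size <- function(counts) {
  if (length(counts) != 3) {
    stop("euclidean_size: expected 3 view counts", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("euclidean_size: counts must be nonnegative", call. = FALSE)
  }
  sqrt(sum(counts^2))
}

#' Pixel-count-weighted mean health fraction
#'
#' Averages per-view health fractions weighted by the corresponding per-view
#' pixel counts; views with zero pixels contribute nothing.
#'
#' @param health Per-view health fractions.
#' @param counts Per-view pixel counts (nonnegative, not all zero).
#' @return Scalar weighted health fraction.
#' @export
#' @examples
#' weighted_health(c(1, 0), c(3, 1)) # 0.75
weighted_health <- function(health, counts) {
  if (length(health) != length(counts)) {
    stop("weighted_health: health and counts must have equal length",
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("weighted_health: counts must be nonnegative", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("weighted_health: all counts are zero", call. = FALSE)
  }
  sum(health * counts) / sum(counts)
}
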