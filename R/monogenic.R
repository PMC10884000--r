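#' 3-D image volumes
#'
#' Minimal voxel container: a 3-D numeric array plus voxel spacing
#' (mm/voxel per axis) and world origin.
#'
#' @param data 3-D numeric array.
#' @param spacing positive length-3 voxel spacing (mm).
#' @param origin world position of voxel (1,1,1).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  a <- as.array(data)
  if (length(dim(a)) != 3L) stop("data must be a 3-D array")
  if (!all(is.finite(a))) stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(data = a, spacing = spacing, origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume3d: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read/write NIfTI volumes
#'
#' Thin wrappers around the RNifti package (suggested dependency).
#'
#' @param path NIfTI file path.
#' @return `read_volume` returns a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package")
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim(img)), spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @param vol a [volume3d()].
#' @export
write_volume <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI volumes requires the RNifti package")
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

## centered FFT frequency axis in cycles/mm
fft_freqs <- function(n, spacing) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * spacing)
}

#' Monogenic decomposition of a 3-D volume
#'
#' Band-passes the volume with an isotropic log-Gabor radial filter
#' `G(w) = exp(-ln^2(|w|/w0) / (2 ln^2 sigma_r))` (zero DC) to obtain the
#' even part `f_e`, applies the three Riesz multipliers `-i w_j / |w|` to
#' the filtered spectrum for the odd part `f_o`, and forms the local
#' amplitude `A = sqrt(f_e^2 + |f_o|^2)`. Single scale; the centre
#' wavelength is configurable.
#'
#' @param vol a [volume3d()] (at least 8 voxels per axis).
#' @param center_wavelength_mm centre wavelength of the band-pass (mm);
#'   must be resolvable, i.e. at least two voxels.
#' @param bandwidth_sigma log-Gabor relative bandwidth `sigma_r` in (0, 1).
#' @return An object of class `monogenic_decomposition` with `fe` (array),
#'   `fo` (list of 3 arrays), `A` (array) and the input geometry.
#' @export
monogenic_decompose <- function(vol, center_wavelength_mm,
                                bandwidth_sigma = 0.55) {
  stopifnot(inherits(vol, "volume3d"), bandwidth_sigma > 0, bandwidth_sigma < 1)
  d <- dim(vol$data)
  if (any(d < 8L)) stop("volume must be at least 8 voxels per axis")
  if (center_wavelength_mm < 2 * max(vol$spacing))
    stop("wavelength ", center_wavelength_mm,
         " mm not resolvable at spacing ", max(vol$spacing), " mm")
  w0 <- 1 / center_wavelength_mm
  wx <- fft_freqs(d[1], vol$spacing[1])
  wy <- fft_freqs(d[2], vol$spacing[2])
  wz <- fft_freqs(d[3], vol$spacing[3])
  WX <- array(wx, d)
  WY <- array(rep(wy, each = d[1]), d)
  WZ <- array(rep(wz, each = d[1] * d[2]), d)
  wn <- sqrt(WX^2 + WY^2 + WZ^2)
  G <- array(0, d)
  nz <- wn > 0
  G[nz] <- exp(-log(wn[nz] / w0)^2 / (2 * log(bandwidth_sigma)^2))
  Fv <- stats::fft(vol$data)
  FG <- Fv * G
  fe <- Re(stats::fft(FG, inverse = TRUE)) / prod(d)
  wn[!nz] <- 1                              # avoid 0/0; G is 0 there anyway
  riesz <- function(W) Re(stats::fft(FG * (complex(imaginary = -1) * W / wn),
                                     inverse = TRUE)) / prod(d)
  fo <- list(riesz(WX), riesz(WY), riesz(WZ))
  A <- sqrt(fe^2 + fo[[1]]^2 + fo[[2]]^2 + fo[[3]]^2)
  structure(list(fe = fe, fo = fo, A = A, spacing = vol$spacing,
                 center_wavelength_mm = center_wavelength_mm,
                 bandwidth_sigma = bandwidth_sigma),
            class = "monogenic_decomposition")
}

#' Phase-asymmetry map
#'
#' Edge-selective feature map
#' `R(x) = max(0, |f_o(x)| - |f_e(x)| - T Abar) / (A(x) + eps)`,
#' where `|f_o|` is the Euclidean norm of the three Riesz components and
#' `Abar` is the volume-median amplitude. Scaling the threshold `T` (a
#' 0-1 value, 0.5 by default) by `Abar` keeps the map invariant to global
#' intensity scaling. R vanishes on even-symmetric (ridge-like) structures
#' and peaks on step edges.
#'
#' @param dec a [monogenic_decompose()] result.
#' @param T noise threshold in [0, 1].
#' @param eps amplitude floor; default `1e-3 * Abar`.
#' @return An object of class `asymmetry_map` with the array `R` and the
#'   parameters used.
#' @export
phase_asymmetry <- function(dec, T = 0.5, eps = NULL) {
  stopifnot(inherits(dec, "monogenic_decomposition"), T >= 0, T <= 1)
  fo_norm <- sqrt(dec$fo[[1]]^2 + dec$fo[[2]]^2 + dec$fo[[3]]^2)
  Abar <- stats::median(dec$A)
  eps <- eps %||% (1e-3 * max(Abar, .Machine$double.xmin))
  if (eps <= 0) stop("eps must be positive")
  R <- pmax(0, fo_norm - abs(dec$fe) - T * Abar) / (dec$A + eps)
  structure(list(R = R, T = T, eps = eps, Abar = Abar),
            class = "asymmetry_map")
}

#' Normalised cross-correlation
#'
#' Pearson correlation over voxels of two equally shaped maps; the
#' similarity used to guide registration-based segmentation.
#'
#' @param map_a,map_b numeric arrays, `asymmetry_map`s or [volume3d()]s of
#'   identical shape.
#' @return Scalar in [-1, 1].
#' @export
ncc <- function(map_a, map_b) {
  arr <- function(x) {
    if (inherits(x, "asymmetry_map")) x$R
    else if (inherits(x, "volume3d")) x$data
    else as.array(x)
  }
  a <- arr(map_a); b <- arr(map_b)
  if (!identical(dim(a), dim(b))) stop("maps differ in shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input to ncc")
  stats::cor(as.vector(a), as.vector(b))
}
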