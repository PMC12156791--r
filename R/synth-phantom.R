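#' Implant geometry for synthetic radiographs
#'
#' Describes the rendered implant silhouette: a vertical, near-saturated
#' threaded profile. All coordinates are 0-based pixel indices (column for
#' `axis_col`, row for `top_row`), matching the convention used by
#' [roi_spec()].
#'
#' @param axis_col Column of the implant long axis; `NULL` centres it.
#' @param radius Core half-width of the implant body, pixels.
#' @param thread_pitch Vertical distance between thread crests, pixels.
#' @param top_row Row of the implant collar (top of the silhouette).
#' @param thread_amp Radial amplitude of the sinusoidal thread profile, pixels.
#'
#' @return An object of class `implant_geometry`. `$first_thread_row` is the
#'   row of the first thread crest below the collar, the anchor used for
#'   region-of-interest placement.
#' @export
implant_geometry <- function(axis_col = NULL, radius = 12, thread_pitch = 8,
                             top_row = 30, thread_amp = 2) {
  stopifnot(radius > 0, thread_pitch > 0, top_row >= 0, thread_amp >= 0)
  structure(
    list(
      axis_col = axis_col, radius = radius, thread_pitch = thread_pitch,
      top_row = top_row, thread_amp = thread_amp,
      first_thread_row = top_row + thread_pitch
    ),
    class = "implant_geometry"
  )
}

#' Binary silhouette mask of an implant
#'
#' @param geom An [implant_geometry()].
#' @param width,height Image dimensions in pixels.
#' @return Logical matrix (`height` x `width`), `TRUE` on the implant.
#' @export
implant_mask <- function(geom, width, height) {
  stopifnot(inherits(geom, "implant_geometry"))
  axis_col <- if (is.null(geom$axis_col)) floor(width / 2) else geom$axis_col
  rows <- seq_len(height) - 1L # 0-based
  halfw <- ifelse(
    rows < geom$top_row, -1,
    geom$radius + geom$thread_amp *
      sin(2 * pi * (rows - geom$top_row) / geom$thread_pitch)
  )
  cols <- seq_len(width) - 1L
  outer(halfw, abs(cols - axis_col), ">=")
}

# -- trabecular texture synthesis --------------------------------------------
# Spectral synthesis of band-limited Gaussian random fields. The texture model
# renders bone marrow as thin dark channels along the near-zero level set of a
# Gaussian field (log(|field| + eps): a log-attenuation style intensity
# mapping), superimposed on a bright trabecular matrix. The complexity knob
# weights in a second, finer channel family; its calibration against the
# downstream box-counting FD is described in the methods vignette.
TEX_WAVELENGTH_PRIMARY <- 16 # px, dominant trabecular spacing
TEX_WAVELENGTH_SECONDARY <- 10 # px, fine interstitial channels
TEX_BANDWIDTH <- 0.35 # SD of the log-normal radial band
TEX_CHANNEL_EPS <- 0.02 # channel depth regularizer
TEX_SECONDARY_GAIN <- 0.7 # knob-to-secondary-family weight

fbm_noise <- function(width, height) {
  matrix(
    complex(real = stats::rnorm(width * height), imaginary = stats::rnorm(width * height)),
    nrow = height, ncol = width
  )
}

# FFT frequencies for length n, in cycles per pixel.
fft_freq <- function(n) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / n
}

# Gaussian field with a log-normal radial amplitude band centred at the given
# wavelength; standardized to zero mean, unit SD.
band_field <- function(noise, width, height, wavelength, bandwidth = TEX_BANDWIDTH) {
  f <- sqrt(outer(fft_freq(height)^2, fft_freq(width)^2, "+"))
  amp <- exp(-(log(pmax(f, 1e-9) * wavelength))^2 / (2 * bandwidth^2))
  amp[1, 1] <- 0
  field <- Re(stats::fft(noise * amp, inverse = TRUE))
  (field - mean(field)) / stats::sd(field)
}

# Standardized trabecular texture field for a given complexity knob value;
# consumes two pre-drawn complex noise fields so that longitudinal series can
# vary the knob while keeping the anatomy (the noise realization) fixed.
trabecular_field <- function(noise1, noise2, width, height, hurst) {
  b1 <- band_field(noise1, width, height, TEX_WAVELENGTH_PRIMARY)
  b2 <- band_field(noise2, width, height, TEX_WAVELENGTH_SECONDARY)
  fld <- log(abs(b1) + TEX_CHANNEL_EPS) +
    TEX_SECONDARY_GAIN * hurst * log(abs(b2) + TEX_CHANNEL_EPS)
  (fld - mean(fld)) / stats::sd(fld)
}

#' Synthesize a trabecular-bone phantom radiograph
#'
#' Generates an 8-bit grayscale image whose texture mimics trabecular bone on
#' a periapical radiograph: a bright bony matrix crossed by thin dark marrow
#' channels, produced by spectral synthesis of band-limited Gaussian random
#' fields whose near-zero level sets are rendered as channels. `hurst` is the
#' single dimensionless complexity knob in (0, 1): it controls how strongly a
#' second, finer channel family is mixed in, and is calibrated so that the
#' fractal dimension measured by the full downstream pipeline decreases
#' monotonically as `hurst` increases (lower values = more complex texture).
#' An implant silhouette is optionally rendered as a near-saturated vertical
#' threaded profile, and i.i.d. Gaussian pixel noise is added before
#' quantization.
#'
#' The generator is a pure function of its arguments: identical parameters
#' and seed reproduce the image bit-for-bit, and the caller's RNG state is
#' left untouched.
#'
#' @param width,height Image size in pixels; at least 96 so that the standard
#'   10x30 mesial and distal ROIs fit beside an implant.
#' @param hurst Complexity knob in (0, 1); lower = more complex.
#' @param mean_gray Mean background gray level (8-bit).
#' @param contrast Gray-level SD of the trabecular texture.
#' @param implant An [implant_geometry()], or `NULL` for bone only.
#' @param noise_sd SD of additive Gaussian pixel noise, gray levels.
#' @param seed Integer seed.
#'
#' @return A [radiograph()] with the implant geometry (if any) attached as
#'   attribute `"implant"`.
#' @export
#' @examples
#' ph <- trabecular_phantom(hurst = 0.4, seed = 7)
#' range(ph)
trabecular_phantom <- function(width = 160, height = 160, hurst = 0.5,
                               mean_gray = 110, contrast = 25,
                               implant = implant_geometry(),
                               noise_sd = 2, seed = 1) {
  if (width < 96 || height < 96) {
    stop("phantom must be at least 96x96 px so 10x30 ROIs fit beside the implant",
      call. = FALSE
    )
  }
  if (hurst <= 0 || hurst >= 1) stop("`hurst` must lie in (0, 1)", call. = FALSE)
  px <- with_seed(seed, {
    base <- if (contrast > 0) {
      n1 <- fbm_noise(width, height)
      n2 <- fbm_noise(width, height)
      mean_gray + contrast * trabecular_field(n1, n2, width, height, hurst)
    } else {
      matrix(mean_gray, height, width)
    }
    if (noise_sd > 0) base <- base + stats::rnorm(width * height, sd = noise_sd)
    base
  })
  px <- clip255(round(px))
  if (!is.null(implant)) {
    mask <- implant_mask(implant, width, height)
    px[mask] <- 250
  }
  out <- radiograph(px)
  attr(out, "implant") <- implant
  out
}
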