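#' Noise model for synthetic angiograms
#'
#' OCTA en-face angiograms show a bright decorrelation signal over
#' flow-positive pixels on a darker static-tissue background, both degraded
#' by multiplicative speckle, with slowly varying background granularity
#' from residual tissue signal. The synthetic model is:
#' intensity = level * speckle + granularity, where `level` is
#' `vessel_level` or `background_level` (fractions of the 16-bit range),
#' speckle is gamma-distributed with unit mean and coefficient of variation
#' `speckle_cv`, and granularity is a Gaussian random field (white noise
#' smoothed at `granularity_scale_px`) scaled to SD `granularity_amp`.
#' All-zero noise parameters give an exactly two-valued image.
#'
#' @param speckle_cv coefficient of variation of the multiplicative
#'   speckle, in \[0, 1\].
#' @param background_level,vessel_level mean levels as fractions of full
#'   scale, background < vessel.
#' @param granularity_amp SD of the additive background field (fraction of
#'   full scale), in \[0, 1\].
#' @param granularity_scale_px correlation length of the background field.
#' @return list of class `mnv_noise_params`.
#' @export
noise_params <- function(speckle_cv = 0.20, background_level = 0.25,
                         vessel_level = 0.65, granularity_amp = 0.05,
                         granularity_scale_px = 6) {
  stopifnot(
    speckle_cv >= 0, speckle_cv <= 1,
    background_level > 0, background_level < 1,
    vessel_level > background_level, vessel_level <= 1,
    granularity_amp >= 0, granularity_amp <= 1, granularity_scale_px > 0
  )
  structure(
    list(
      speckle_cv = speckle_cv, background_level = background_level,
      vessel_level = vessel_level, granularity_amp = granularity_amp,
      granularity_scale_px = granularity_scale_px
    ),
    class = "mnv_noise_params"
  )
}

#' Synthesize an en-face angiogram from a vessel mask
#'
#' Applies the noise model of [noise_params()] to a binary vessel mask and
#' quantizes to 16-bit integers. Vessel pixels have strictly higher
#' expected intensity than background; the image is deterministic per
#' `(mask, noise, seed)`.
#'
#' @param mask logical vessel mask.
#' @param noise `mnv_noise_params`.
#' @param seed integer RNG seed.
#' @param pixel_scale mm per pixel carried on the resulting angiogram.
#' @return `mnv_angiogram` (see [as_angiogram()]).
#' @export
synthesize_angiogram <- function(mask, noise = noise_params(), seed = 1L,
                                 pixel_scale = 0.012) {
  stopifnot(inherits(noise, "mnv_noise_params"))
  m <- mask_matrix(mask)
  set.seed(seed)
  base <- ifelse(m, noise$vessel_level, noise$background_level)
  img <- base
  if (noise$granularity_amp > 0) {
    field <- matrix(stats::rnorm(length(m)), nrow(m), ncol(m))
    field <- EBImage::gblur(field, sigma = noise$granularity_scale_px)
    field <- field / stats::sd(field) * noise$granularity_amp
    img <- img + field
  }
  if (noise$speckle_cv > 0) {
    shape <- 1 / noise$speckle_cv^2
    speckle <- matrix(stats::rgamma(length(m), shape = shape,
                                    rate = shape), nrow(m), ncol(m))
    img <- base * speckle + (img - base)
  }
  img <- pmin(pmax(img, 0), 1)
  as_angiogram(round(img * 65535), pixel_scale = pixel_scale)
}
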