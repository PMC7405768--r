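#' Specify a drifting sinusoidal grating
#'
#' The stimulus is a time-dependent light-intensity map
#' `I(x, t) = L0 * (1 + c * sin(2*pi*(sf * <p, x> - tf * t) + phase))`,
#' where `p = (cos(theta), sin(theta))` is the direction of spatial
#' variation for grating orientation `theta` (0 degrees = vertical stripes,
#' angles counterclockwise) and `L0` the mean luminance.
#'
#' @param contrast modulation depth `c` in [0, 1].
#' @param orientation_deg grating orientation, degrees.
#' @param sf_cpd spatial frequency, cycles/degree.
#' @param tf_hz temporal (drift) frequency, Hz (default 4).
#' @param phase spatial phase, radians.
#' @param mean_luminance mean intensity `L0` (arbitrary units).
#' @return object of class `grating_spec`.
#' @export
grating_spec <- function(contrast = 1, orientation_deg = 0, sf_cpd = 2.5,
                         tf_hz = 4, phase = 0, mean_luminance = 1) {
  if (contrast < 0 || contrast > 1)
    stop_config("grating_spec: contrast must be in [0, 1] (got %g)", contrast)
  if (sf_cpd < 0 || tf_hz < 0 || mean_luminance < 0)
    stop_config("grating_spec: sf, tf and mean luminance must be nonnegative")
  structure(list(contrast = contrast, orientation_deg = orientation_deg,
                 sf_cpd = sf_cpd, tf_hz = tf_hz, phase = phase,
                 mean_luminance = mean_luminance), class = "grating_spec")
}

#' @export
print.grating_spec <- function(x, ...) {
  cat(sprintf("<grating> c=%.2f  ori=%g deg  sf=%g c/d  tf=%g Hz\n",
              x$contrast, x$orientation_deg, x$sf_cpd, x$tf_hz))
  invisible(x)
}

#' Evaluate the grating light-intensity map
#'
#' @param spec a [grating_spec()].
#' @param x matrix (or length-2 vector) of visual positions in degrees.
#' @param t time(s) in seconds.
#' @return intensity values (nonnegative for contrast <= 1).
#' @examples
#' grating_intensity(grating_spec(contrast = 0), c(0.3, 0.1), 0.2)  # 1
#' @export
grating_intensity <- function(spec, x, t) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2)
  th <- spec$orientation_deg * pi / 180
  proj <- x[, 1] * cos(th) + x[, 2] * sin(th)
  spec$mean_luminance *
    (1 + spec$contrast * sin(2 * pi * (spec$sf_cpd * proj - spec$tf_hz * t) +
                               spec$phase))
}

#' Magnocellular LGN filter parameters
#'
#' Spatial difference-of-Gaussians (centre/surround), biphasic temporal
#' kernel (difference of two gamma-shaped lobes), output rectification, and
#' a hyperbolic-ratio contrast saturation applied to the cycle-peak rate.
#' ON and OFF cells differ only by the sign of the spatial kernel.
#'
#' @param center_radius_deg,surround_radius_deg Gaussian SDs of the centre
#'   and surround (degrees); the surround defaults to 3x the centre.
#' @param surround_strength surround amplitude relative to centre (its
#'   integral ratio; < 1 keeps a net-ON centre response).
#' @param tpeak1_ms,tpeak2_ms times-to-peak of the two temporal lobes.
#' @param lobe2_strength relative amplitude of the rebound lobe.
#' @param base_rate_sps maintained discharge at zero contrast, spikes/s.
#' @param max_rate_sps saturating increment of the cycle-peak rate.
#' @param c50 contrast of half saturation of the LGN response.
#' @return object of class `lgn_filter`.
#' @export
lgn_filter <- function(center_radius_deg = 0.05, surround_radius_deg = 0.15,
                       surround_strength = 0.8, tpeak1_ms = 20,
                       tpeak2_ms = 40, lobe2_strength = 0.7,
                       base_rate_sps = 20, max_rate_sps = 80, c50 = 0.15) {
  stopifnot(center_radius_deg > 0, surround_radius_deg > 0,
            base_rate_sps >= 0, max_rate_sps > 0, c50 > 0)
  structure(as.list(environment()), class = "lgn_filter")
}

# Normalized spatial gain of the DoG at spatial frequency f (c/deg):
# Fourier transform of unit-integral centre minus `surround_strength` times
# unit-integral surround, relative to its value at the 2.5 c/d anchor.
lgn_spatial_gain <- function(filter, sf_cpd, anchor_cpd = 2.5) {
  ft <- function(f)
    exp(-2 * pi^2 * filter$center_radius_deg^2 * f^2) -
      filter$surround_strength *
        exp(-2 * pi^2 * filter$surround_radius_deg^2 * f^2)
  pmax(ft(sf_cpd), 0) / ft(anchor_cpd)
}

# Normalized temporal gain at drift frequency tf (Hz) of the biphasic
# kernel, relative to the 4 Hz anchor.
lgn_temporal_gain <- function(filter, tf_hz, anchor_hz = 4) {
  amp <- function(f) {
    w <- 2 * pi * f
    t1 <- filter$tpeak1_ms / 1000
    t2 <- filter$tpeak2_ms / 1000
    # gamma lobes k(t) = t/tp^2 exp(-t/tp); |FT| = 1 / (1 + (w tp)^2)
    lob <- function(tp) 1 / (1 + (w * tp)^2)
    abs(lob(t1) - filter$lobe2_strength * lob(t2))
  }
  amp(tf_hz) / amp(anchor_hz)
}

#' Saturating LGN contrast-response function
#'
#' Cycle-peak firing rate of an LGN cell driven at its preferred spatial
#' frequency, as a hyperbolic ratio of contrast:
#' `R(c) = base + max * c / (c + c50)`.  Monotone increasing and concave.
#'
#' @param c contrast in [0, 1] (vectorised).
#' @param filter an [lgn_filter()].
#' @return peak rate, spikes/s.
#' @examples
#' f <- lgn_filter(c50 = 0.1)
#' lgn_contrast_response(0.1, f)  # base + max/2
#' @export
lgn_contrast_response <- function(c, filter = lgn_filter()) {
  if (any(c < 0 | c > 1)) stop_config("lgn_contrast_response: c must be in [0, 1]")
  filter$base_rate_sps + filter$max_rate_sps * c / (c + filter$c50)
}

#' LGN firing-rate trace for a drifting grating
#'
#' For sinusoidal gratings the spatiotemporal filtering is evaluated
#' analytically: the response of the linear stage is a sinusoid at the drift
#' frequency whose amplitude carries the spatial and temporal gains of the
#' filter, and whose spatial phase is set by the cell's receptive-field
#' centre (OFF cells are shifted by half a cycle).  The amplitude is scaled
#' so that at the anchor sf/tf the cycle-peak rate follows the saturating
#' contrast-response function; the trace is rectified at zero after adding
#' the maintained rate.
#'
#' @param cell one-row slice of an [build_lgn_mosaic()] table (or a list
#'   with `x_deg`, `y_deg`, `polarity`).
#' @param filter an [lgn_filter()].
#' @param spec a [grating_spec()].
#' @param times time grid in seconds.
#' @return numeric vector of nonnegative rates (spikes/s) on `times`.
#' @export
lgn_rate <- function(cell, filter, spec, times) {
  amp <- (lgn_contrast_response(spec$contrast, filter) - filter$base_rate_sps) *
    lgn_spatial_gain(filter, spec$sf_cpd) *
    lgn_temporal_gain(filter, spec$tf_hz)
  th <- spec$orientation_deg * pi / 180
  proj <- cell$x_deg * cos(th) + cell$y_deg * sin(th)
  ph <- 2 * pi * spec$sf_cpd * proj + spec$phase +
    if (identical(cell$polarity, "OFF")) pi else 0
  pmax(0, filter$base_rate_sps +
            amp * sin(ph - 2 * pi * spec$tf_hz * times))
}

#' Generate LGN spikes from a rate trace
#'
#' Inhomogeneous Poisson process with instantaneous rate `r(t)` thinned by
#' an absolute refractory period.  Reproducible given the seed.
#'
#' @param trace nonnegative rate trace, spikes/s.
#' @param times time grid in seconds (uniform step).
#' @param refractory_ms absolute refractory period (default 2).
#' @param seed integer seed.
#' @return spike times in seconds.
#' @export
generate_lgn_spikes <- function(trace, times, refractory_ms = 2, seed = 1L) {
  if (any(trace < 0)) stop_config("generate_lgn_spikes: trace must be nonnegative")
  dt <- if (length(times) > 1) times[2] - times[1] else 0
  with_seed(seed, {
    fire <- runif(length(trace)) < trace * dt
    sp <- times[fire]
    if (length(sp) > 1) {
      keep <- logical(length(sp))
      last <- -Inf
      for (k in seq_along(sp)) {
        if (sp[k] - last >= refractory_ms / 1000) {
          keep[k] <- TRUE
          last <- sp[k]
        }
      }
      sp <- sp[keep]
    }
    sp
  })
}
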