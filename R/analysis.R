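#' Per-neuron mean firing rates over an analysis window
#'
#' Spike count in the window divided by the window length, for every neuron
#' in the network (neurons with no spikes get 0).
#'
#' @param record spike data.frame (`neuron`, `t_ms`) or a `v1_simulation`.
#' @param window_s numeric length-2 `c(from, to)` in seconds (default: the
#'   last-half convention, e.g. seconds 5-10 of a 10 s run).
#' @param n_neurons total neuron count (inferred from a `v1_simulation`).
#' @return data.frame `neuron`, `rate_sps`.
#' @export
mean_rates <- function(record, window_s = c(5, 10), n_neurons = NULL) {
  if (inherits(record, "v1_simulation")) {
    if (missing(window_s)) window_s <- record$window_s
    n_neurons <- nrow(record$network$neurons)
    if (window_s[2] > record$duration_s + 1e-9)
      stop_config("mean_rates: window [%g, %g] s extends past the record (%g s)",
                  window_s[1], window_s[2], record$duration_s)
    record <- record$record
  }
  if (is.null(n_neurons)) n_neurons <- max(record$neuron, 0)
  if (diff(window_s) <= 0) stop_config("mean_rates: empty window")
  sel <- record$t_ms >= window_s[1] * 1000 & record$t_ms < window_s[2] * 1000
  counts <- tabulate(record$neuron[sel], nbins = n_neurons)
  data.frame(neuron = seq_len(n_neurons), rate_sps = counts / diff(window_s))
}

#' Drop silent neurons from a battery of rate summaries
#'
#' A neuron is silent when its peak mean rate across the whole stimulus
#' battery is strictly below the threshold (5 spikes/s); in the tuned model
#' this removes ~5-10\% of neurons, matching the convention used for
#' experimental population averages.  A peak of exactly 5 is retained.
#'
#' @param rate_table matrix or data.frame of per-neuron rates, one column
#'   per stimulus in the battery (rows = neurons).
#' @param threshold silence threshold in spikes/s (default 5; strict `<`).
#' @return list with `keep` (logical per neuron), `peak` (per-neuron peak
#'   rate), `silent_fraction`.
#' @export
drop_silent <- function(rate_table, threshold = 5) {
  m <- as.matrix(rate_table)
  peak <- apply(m, 1, max)
  keep <- !(peak < threshold)
  list(keep = keep, peak = peak, silent_fraction = mean(!keep))
}

#' Circular variance of an orientation tuning curve
#'
#' `CV = 1 - |sum_k r_k exp(2 i theta_k)| / sum_k r_k` with theta in
#' radians; 0 for a response at a single orientation, 1 for a flat curve.
#'
#' @param rates nonnegative responses.
#' @param orientations_deg matching orientations in degrees.
#' @return CV in [0, 1], or NA (with a warning) if all rates are zero.
#' @export
circular_variance <- function(rates, orientations_deg) {
  stopifnot(length(rates) == length(orientations_deg))
  if (length(rates) < 2)
    stop_config("circular_variance: need >= 2 orientations")
  if (sum(rates) == 0) {
    warning("circular_variance undefined for an all-zero curve")
    return(NA_real_)
  }
  th <- orientations_deg * pi / 180
  1 - Mod(sum(rates * exp(2i * th))) / sum(rates)
}

#' Modulation ratio (F1/F0) of a cycle-averaged response
#'
#' First-harmonic amplitude at the drift frequency over the mean of the
#' cycle-averaged firing rate.  Values > 1 mark simple cells, < 1 complex
#' cells.  Cycle averaging uses the final integer number of stimulus cycles
#' inside the analysis window to avoid partial-cycle bias.
#'
#' @param record spike data.frame (`neuron`, `t_ms`).
#' @param neuron neuron id.
#' @param tf_hz drift frequency, Hz.
#' @param window_s analysis window in seconds.
#' @param n_bins bins per cycle for the cycle average.
#' @return F1/F0, or NA (flagged by warning) if the neuron never spikes.
#' @export
modulation_ratio <- function(record, neuron, tf_hz, window_s = c(5, 10),
                             n_bins = 32) {
  period_s <- 1 / tf_hz
  n_cycles <- floor(diff(window_s) / period_s)
  if (n_cycles < 1) stop_config("modulation_ratio: window shorter than one cycle")
  t0 <- window_s[2] - n_cycles * period_s
  sp <- record$t_ms[record$neuron == neuron] / 1000
  sp <- sp[sp >= t0 & sp < window_s[2]]
  if (!length(sp)) {
    warning("modulation_ratio undefined: neuron ", neuron, " has no spikes")
    return(NA_real_)
  }
  phase <- ((sp - t0) %% period_s) / period_s
  hist_r <- tabulate(pmin(floor(phase * n_bins) + 1L, n_bins), n_bins) /
    (n_cycles * period_s / n_bins)
  f0 <- mean(hist_r)
  f1 <- 2 * Mod(mean(hist_r * exp(-2i * pi * (seq_len(n_bins) - 0.5) / n_bins)))
  f1 / f0
}

#' Orthogonal-to-preferred response ratio
#'
#' Preferred orientation is the argmax of the measured curve; the O/P ratio
#' is the rate at preferred + 90 degrees over the rate at preferred.  Lower
#' values mean sharper orientation selectivity.
#'
#' @param rates responses at `orientations_deg` (which must contain, for
#'   the argmax, an orientation 90 degrees away modulo 180).
#' @param orientations_deg orientations, degrees.
#' @return O/P in [0, Inf), NA with warning if the preferred rate is 0.
#' @export
op_ratio <- function(rates, orientations_deg) {
  stopifnot(length(rates) == length(orientations_deg))
  ipref <- which.max(rates)
  if (rates[ipref] == 0) {
    warning("op_ratio undefined for an all-zero curve")
    return(NA_real_)
  }
  target <- (orientations_deg[ipref] + 90) %% 180
  d <- abs(((orientations_deg - target + 90) %% 180) - 90)
  iorth <- which.min(d)
  rates[iorth] / rates[ipref]
}

#' Estimate the semisaturation contrast C50
#'
#' Fits the hyperbolic-ratio (Naka-Rushton) curve
#' `r(c) = r0 + rmax * c^n / (c^n + c50^n)` (exponent fixed to 1 by
#' default) and returns the contrast at which the fitted response rises to
#' half of its fitted maximum increment.  Falls back to linear
#' interpolation of the half-rise point when the fit fails.
#'
#' @param contrasts contrast levels in [0, 1] (>= 4 values).
#' @param rates measured responses.
#' @param exponent Naka-Rushton exponent (fixed, default 1).
#' @return list with `c50`, `method` ("fit" or "interpolation"), and
#'   `flagged` (TRUE for degenerate curves, with `c50 = NA`).
#' @export
estimate_c50 <- function(contrasts, rates, exponent = 1) {
  if (length(contrasts) < 4) stop_config("estimate_c50: need >= 4 contrasts")
  o <- order(contrasts)
  contrasts <- contrasts[o]; rates <- rates[o]
  if (diff(range(rates)) < 1e-9)
    return(list(c50 = NA_real_, method = "none", flagged = TRUE))
  fit <- tryCatch({
    st <- list(r0 = min(rates), rmax = diff(range(rates)), c50 = 0.2)
    f <- if (requireNamespace("minpack.lm", quietly = TRUE))
      minpack.lm::nlsLM(rates ~ r0 + rmax * contrasts^exponent /
                          (contrasts^exponent + c50^exponent),
                        start = st,
                        lower = c(0, 0, 1e-4), upper = c(Inf, Inf, 10))
    else
      nls(rates ~ r0 + rmax * contrasts^exponent /
            (contrasts^exponent + c50^exponent), start = st)
    co <- coef(f)
    if (co[["c50"]] <= 0 || co[["c50"]] > 2) stop("implausible fit")
    list(c50 = unname(co[["c50"]]), method = "fit", flagged = FALSE)
  }, error = function(e) NULL)
  if (!is.null(fit)) return(fit)
  # interpolate the contrast of half-maximal rise
  half <- min(rates) + diff(range(rates)) / 2
  above <- which(rates >= half)[1]
  if (is.na(above) || above == 1)
    return(list(c50 = NA_real_, method = "none", flagged = TRUE))
  c50 <- contrasts[above - 1] + (half - rates[above - 1]) *
    diff(contrasts[(above - 1):above]) / diff(rates[(above - 1):above])
  list(c50 = c50, method = "interpolation", flagged = FALSE)
}

#' Pixelised cortical activity map
#'
#' Divides the sheet into square pixels (50 um default, so a 3 x 3 HC sheet
#' gives 30 x 30 = 900 pixels) and returns, per pixel, the firing rate of
#' one cell class averaged over the member neurons and over the averaging
#' window.  Pixels containing no neurons of the class are NA, not zero.
#'
#' @param sim a `v1_simulation`, or a spike record data.frame (then
#'   `neurons` and `grid` must be given).
#' @param cls "E" or "I".
#' @param pixel_um pixel side, um.
#' @param window_s averaging window `c(from, to)` in seconds (default: the
#'   last `map_window` seconds of the record; 1 s in the standard maps).
#' @param neurons,grid needed when `sim` is a bare record.
#' @return object of class `activity_map`: `rate` matrix (rows = y pixels),
#'   `pixel_um`, `window_s`, `cls`, `n_per_pixel`.
#' @export
activity_map <- function(sim, cls = "E", pixel_um = 50, window_s = NULL,
                         neurons = NULL, grid = NULL) {
  if (inherits(sim, "v1_simulation")) {
    neurons <- sim$network$neurons
    grid <- sim$network$grid
    if (is.null(window_s)) window_s <- c(sim$duration_s - 1, sim$duration_s)
    record <- sim$record
  } else {
    record <- sim
    if (is.null(neurons) || is.null(grid))
      stop_config("activity_map: need neurons and grid with a bare record")
    if (is.null(window_s)) stop_config("activity_map: window_s required")
  }
  nx <- round(grid$n_cols * grid$hc_side / pixel_um)
  ny <- round(grid$n_rows * grid$hc_side / pixel_um)
  sel <- neurons$cls == cls
  px <- pmin(pmax(floor(neurons$x_um / pixel_um), 0), nx - 1)
  py <- pmin(pmax(floor(neurons$y_um / pixel_um), 0), ny - 1)
  pix <- px * ny + py + 1   # column-major over (y, x)
  rates <- mean_rates(record, window_s, n_neurons = nrow(neurons))$rate_sps
  tot <- tapply(rates[sel], factor(pix[sel], levels = seq_len(nx * ny)), sum)
  cnt <- tapply(rep(1, sum(sel)), factor(pix[sel], levels = seq_len(nx * ny)), sum)
  m <- matrix(as.numeric(tot) / as.numeric(cnt), nrow = ny, ncol = nx)
  structure(list(rate = m, pixel_um = pixel_um, window_s = window_s,
                 cls = cls,
                 n_per_pixel = matrix(ifelse(is.na(cnt), 0, cnt), ny, nx)),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> %d x %d pixels (%g um), %s cells, window %.1f-%.1f s, mean %.2f sp/s\n",
              nrow(x$rate), ncol(x$rate), x$pixel_um, x$cls,
              x$window_s[1], x$window_s[2], mean(x$rate, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.activity_map <- function(x, ...) {
  image(t(x$rate), main = sprintf("%s-cell activity (sp/s)", x$cls),
        xaxt = "n", yaxt = "n", ...)
  invisible(x)
}

#' Stability of activity maps across contrast
#'
#' Pearson correlation of peak-normalised maps against the highest-contrast
#' map, a scale-free footprint-similarity score (the maps of a
#' contrast-invariant cortex correlate near 1 across contrast).
#'
#' @param maps list of `activity_map`s (same grid), ordered by contrast.
#' @return numeric vector of correlations with the last (reference) map;
#'   NA with warning for degenerate (constant) maps.
#' @export
map_stability <- function(maps) {
  if (length(maps) < 2) stop_config("map_stability: need >= 2 maps")
  norm <- lapply(maps, function(m) {
    v <- as.numeric(m$rate)
    pk <- max(v, na.rm = TRUE)
    if (!is.finite(pk) || pk == 0) v else v / pk
  })
  ref <- norm[[length(norm)]]
  vapply(norm, function(v) {
    ok <- is.finite(v) & is.finite(ref)
    if (sd(v[ok]) == 0 || sd(ref[ok]) == 0) {
      warning("map_stability: degenerate (constant) map")
      return(NA_real_)
    }
    stats::cor(v[ok], ref[ok])
  }, numeric(1))
}

#' Fraction of a population spiking per time bin
#'
#' The summed-spike series: the number of *distinct* neurons of the
#' population that fire in each bin, divided by the population size.  In
#' the optimally driven model this fraction rarely exceeds 0.2 in 5-ms
#' bins: the gamma rhythm is far from a full population spike.
#'
#' @param record spike data.frame (`neuron`, `t_ms`).
#' @param population neuron ids forming the population.
#' @param bin_ms bin width (default 5).
#' @param t_range `c(from, to)` in ms (default: range of the record).
#' @return data.frame `t_ms` (bin centres), `fraction`.
#' @export
summed_spike_fraction <- function(record, population, bin_ms = 5,
                                  t_range = NULL) {
  if (is.null(t_range))
    t_range <- c(0, if (nrow(record)) max(record$t_ms) else bin_ms)
  breaks <- seq(t_range[1], t_range[2] + bin_ms, by = bin_ms)
  sel <- record$neuron %in% population & record$t_ms >= t_range[1] &
    record$t_ms < breaks[length(breaks)]
  bin <- findInterval(record$t_ms[sel], breaks)
  nrn <- record$neuron[sel]
  distinct <- tapply(nrn, factor(bin, levels = seq_len(length(breaks) - 1)),
                     function(z) length(unique(z)))
  frac <- ifelse(is.na(distinct), 0, distinct) / length(population)
  data.frame(t_ms = breaks[-length(breaks)] + bin_ms / 2,
             fraction = as.numeric(frac))
}

#' Power spectral density and spectrogram of a population signal
#'
#' Welch periodogram averaging of the mean-subtracted series: Hann-windowed
#' segments (500 ms default) with 50\% overlap.  Power is normalised so that
#' the summed PSD equals the windowed signal variance (Parseval).  A
#' short-time spectrogram over the same windows is returned as well.
#'
#' @param series numeric signal sampled at `fs` Hz (e.g. a
#'   [summed_spike_fraction()] series).
#' @param fs sampling frequency, Hz.
#' @param segment_s Welch segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return object of class `spectral_result`: `freq` (Hz), `psd`,
#'   `spectrogram` (segments x freq), `seg_times`.
#' @export
spectral <- function(series, fs, segment_s = 0.5, overlap = 0.5) {
  nseg <- round(segment_s * fs)
  if (length(series) < nseg)
    stop_config("spectral: series (%d samples) shorter than one %g s segment",
                length(series), segment_s)
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(series) - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  wnorm <- sum(win^2)
  nf <- floor(nseg / 2) + 1
  spec <- matrix(0, length(starts), nf)
  for (k in seq_along(starts)) {
    x <- series[starts[k]:(starts[k] + nseg - 1)]
    x <- (x - mean(x)) * win
    X <- fft(x)[seq_len(nf)]
    p <- Mod(X)^2 / (wnorm * fs)
    # one-sided: double everything except DC (and Nyquist for even nseg)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    spec[k, ] <- p * dbl
  }
  structure(list(freq = (seq_len(nf) - 1) * fs / nseg,
                 psd = colMeans(spec), spectrogram = spec,
                 seg_times = (starts - 1 + nseg / 2) / fs, fs = fs,
                 df = fs / nseg),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  pk <- x$freq[which.max(x$psd[x$freq > 0]) + 1]
  cat(sprintf("<spectral_result> %d frequencies up to %.0f Hz; peak (excl. DC) at %.1f Hz\n",
              length(x$freq), max(x$freq), pk))
  invisible(x)
}

#' Population tuning curve from a battery of simulations
#'
#' Convenience helper: given per-neuron rate columns for a battery
#' (as from repeated [mean_rates()] calls) and the population ids, returns
#' mean and SEM per stimulus value.
#'
#' @param rate_table neurons x stimuli matrix of rates.
#' @param values stimulus values (one per column).
#' @param population row indices to average over.
#' @return data.frame `value`, `mean_rate`, `sem`, `n`.
#' @export
tuning_curve <- function(rate_table, values, population) {
  m <- as.matrix(rate_table)[population, , drop = FALSE]
  data.frame(value = values, mean_rate = colMeans(m),
             sem = apply(m, 2, sd) / sqrt(nrow(m)), n = nrow(m))
}
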