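#' Short-term depression of I -> E synapses
#'
#' After an inhibitory neuron spikes, its synapses onto E-cells are
#' transiently weakened: if the cell spikes at `t1` having previously spiked
#' at `t0`, the I->E weight used at `t1` is the baseline times
#' `1 - 0.12 * exp(-(t1 - t0) / 20 ms)`.  The weakening is maximal (12\%)
#' for immediately successive spikes and has essentially recovered ~40 ms
#' after a spike.  Depression applies to I->E synapses only, not I->I.
#'
#' @param dt_ms time since the presynaptic I-cell's previous spike, ms
#'   (>= 0; `Inf` for a first spike).
#' @param depression maximal fractional weakening (default 0.12).
#' @param tau_ms recovery time constant (default 20).
#' @return multiplier in `[1 - depression, 1]`.
#' @examples
#' depression_multiplier(0)    # 0.88
#' depression_multiplier(20)   # 1 - 0.12 * exp(-1)
#' @export
depression_multiplier <- function(dt_ms, depression = 0.12, tau_ms = 20) {
  if (any(dt_ms < 0)) stop_config("depression_multiplier: dt_ms must be >= 0")
  1 - depression * exp(-dt_ms / tau_ms)
}

#' Adaptive spiking threshold of E-cells
#'
#' Each spike raises an E-cell's threshold by 20\% of baseline (an additive
#' jump of +0.2 on the normalized voltage scale where baseline threshold is
#' 1); the excess then relaxes back 90\% of the way within 10 ms.  The decay
#' is exponential with time constant `10 / ln(10)` ms -- the unique
#' exponential satisfying that contract -- so with spikes at times `s_k <= t`
#' the threshold is `1 + 0.2 * sum_k exp(-(t - s_k) / tau)`.
#'
#' @param spike_times numeric vector of past spike times, ms (may be empty).
#' @param t evaluation time(s), ms; must be >= all spike times.
#' @param jump threshold increment per spike (default 0.2).
#' @param decay_fraction,decay_ms the relaxation contract: a fraction
#'   `decay_fraction` of any excess decays within `decay_ms` ms.
#' @return threshold value(s) at `t` (>= 1; exactly 1 with no spikes).
#' @examples
#' threshold_trace(0, 0)    # 1.2 immediately after a spike
#' threshold_trace(0, 10)   # 1.02: 90\% of the excess gone after 10 ms
#' @export
threshold_trace <- function(spike_times, t, jump = 0.2,
                            decay_fraction = 0.9, decay_ms = 10) {
  if (length(spike_times) && any(t < max(spike_times)))
    stop_config("threshold_trace: t must be >= the last spike time")
  tau <- decay_ms / (-log(1 - decay_fraction))   # 10 / ln(10) by default
  vapply(t, function(tt) {
    1 + jump * sum(exp(-(tt - spike_times) / tau))
  }, numeric(1))
}
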