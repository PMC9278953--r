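## Synthetic stand-ins for the raw electrophysiology inputs, with known
## ground truth, so every analysis stage is testable without recordings.

#' Synthetic outside-out-patch K+ current family
#'
#' Generates a voltage-clamp current family from a Boltzmann-activated,
#' mono-exponentially activating, slowly inactivating K+ conductance with
#' additive Gaussian noise: per step, \eqn{I(t) = g_{max} m(t) h(t) (V -
#' E_{rev}) + \epsilon}.  The activation time constant follows the same
#' bell-shaped voltage dependence as the Kv3 mechanism
#' (floor + peak Gaussian).  Ground truth is attached to the result.
#'
#' @param v_half Half-activation voltage (mV); e.g. -6.6 for a WT-like
#'   patch, -15.5 for an AD-like patch.
#' @param slope Boltzmann slope (mV), default 12.
#' @param gmax Maximal conductance (nS), default 20.
#' @param tau_peak,tau_center,tau_floor Activation-kinetics bell: peak
#'   amplitude (ms), center voltage (mV), floor (ms).
#' @param tau_inact Slow inactivation time constant (ms), default 1000.
#' @param e_rev Reversal potential (mV), default -90.
#' @param noise_sd Additive current noise SD (nA), default 0.
#' @param holding,steps,step_duration,dt Step protocol (defaults: hold
#'   -110 mV, steps -90 to +50 by 20, 300 ms, 0.025 ms sampling).
#' @param seed RNG seed.
#' @return List with `traces` (long data frame `step_mV`, `time_ms`,
#'   `i_nA`), `peaks`, and `truth` (all generating parameters).
#' @export
generate_patch_family <- function(v_half = -6.6, slope = 12, gmax = 20,
                                  tau_peak = 4, tau_center = -25,
                                  tau_floor = 0.5, tau_inact = 1000,
                                  e_rev = -90, noise_sd = 0,
                                  holding = -110,
                                  steps = seq(-90, 50, by = 20),
                                  step_duration = 300, dt = 0.025,
                                  seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gmax <= 0) stop("gmax must be > 0")
  set.seed(seed)
  tt <- seq(dt, step_duration, by = dt)
  minf_fn <- function(v) 1 / (1 + exp(-(v - v_half) / slope))
  hinf_fn <- function(v) 1 / (1 + exp((v - (v_half - 25)) / 10))
  tau_fn <- function(v)
    tau_floor + tau_peak * exp(-0.5 * ((v - tau_center) / 25)^2)
  m0 <- minf_fn(holding); h0 <- hinf_fn(holding)
  traces <- lapply(steps, function(vs) {
    m <- minf_fn(vs) + (m0 - minf_fn(vs)) * exp(-tt / tau_fn(vs))
    h <- hinf_fn(vs) + (h0 - hinf_fn(vs)) * exp(-tt / tau_inact)
    i <- gmax * m * h * (vs - e_rev) * 1e-3
    if (noise_sd > 0) i <- i + rnorm(length(i), 0, noise_sd)
    data.frame(step_mV = vs, time_ms = tt, i_nA = i)
  })
  traces <- do.call(rbind, traces)
  peaks <- do.call(rbind, lapply(split(traces, traces$step_mV),
    function(d) data.frame(step_mV = d$step_mV[1],
                           i_peak_nA = d$i_nA[which.max(abs(d$i_nA))])))
  rownames(peaks) <- NULL
  peaks <- peaks[order(peaks$step_mV), ]
  truth <- list(v_half = v_half, slope = slope, gmax = gmax,
                tau_peak = tau_peak, tau_center = tau_center,
                tau_floor = tau_floor, tau_inact = tau_inact,
                e_rev = e_rev, noise_sd = noise_sd, seed = seed)
  list(traces = traces, peaks = peaks, truth = truth)
}

#' Homogeneous Poisson spike trains
#'
#' @param rate Firing rate (Hz), >= 0.
#' @param duration Train length (ms).
#' @param n Number of trains.
#' @param seed RNG seed.
#' @return List of numeric vectors of spike times (ms).
#' @export
generate_poisson_trains <- function(rate, duration, n, seed = 1) {
  if (rate < 0) stop("rate must be >= 0")
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    cnt <- stats::rpois(1, rate * duration / 1000)
    sort(runif(cnt, 0, duration))
  })
}
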