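## Declarative single-cell experiment runners and spike/AP analysis.

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a detection threshold with refractory enforcement.
#'
#' @param trace A `sim_trace` data frame (or numeric voltage vector with
#'   `dt` supplied).
#' @param threshold Detection threshold (mV), default -20.
#' @param refractory Minimum inter-event interval (ms), default 1.
#' @param dt Sampling interval (ms); taken from the trace attribute when
#'   omitted.
#' @return Numeric vector of spike times (ms), class `spike_train`.
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 1,
                          dt = NULL) {
  if (is.data.frame(trace)) {
    v <- trace$v_mV
    if (is.null(dt)) dt <- attr(trace, "dt")
    if (is.null(dt)) {
      dts <- diff(trace$time_ms)
      if (max(dts) - min(dts) > 1e-9)
        stop("non-uniform sampling")
      dt <- dts[1]
    }
  } else {
    v <- trace
    if (is.null(dt)) stop("dt required for a bare voltage vector")
  }
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  if (length(up) == 0)
    return(structure(numeric(0), class = "spike_train"))
  times <- up * dt
  # enforce refractory sequentially (a vectorized diff can drop too many)
  out <- times[1]
  for (t in times[-1]) if (t - out[length(out)] >= refractory)
    out <- c(out, t)
  structure(out, class = "spike_train")
}

#' Action potential waveform metrics
#'
#' Measures one spike: threshold as the voltage at the spike foot, found
#' by searching backwards from the peak for the last sample at which
#' dV/dt is below the criterion (default 20 V/s) --- robust to slow
#' depolarizing ramps preceding the spike; amplitude as peak minus
#' threshold, half-width at threshold + amplitude/2, maximal dV/dt, and
#' AHP as threshold minus the post-spike minimum.
#'
#' @param trace A `sim_trace` (or voltage vector plus `dt`).
#' @param spike_time Time (ms) of the spike to analyze (e.g. from
#'   [detect_spikes()]).
#' @param dvdt_criterion Threshold criterion on dV/dt (V/s).
#' @param window Search window (ms) around the spike.
#' @param dt Sampling interval (ms) if `trace` is a bare vector.
#' @return List with `threshold`, `amplitude`, `half_width`, `max_dvdt`,
#'   `ahp` (mV, mV, ms, V/s, mV).
#' @export
ap_metrics <- function(trace, spike_time, dvdt_criterion = 20,
                       window = 3, dt = NULL) {
  if (is.data.frame(trace)) {
    v <- trace$v_mV
    if (is.null(dt)) dt <- attr(trace, "dt")
  } else v <- trace
  n <- length(v)
  i_sp <- round(spike_time / dt) + 1
  i0 <- max(1, i_sp - round(window / dt))
  i1 <- min(n, i_sp + round(window / dt))
  seg <- v[i0:i1]
  dvdt <- c(diff(seg) / dt, 0)  # mV/ms == V/s
  i_pk_rel <- which.max(seg)
  if (i_pk_rel <= 1 || i_pk_rel >= length(seg))
    stop("no spike peak found within window")
  pre <- dvdt[seq_len(i_pk_rel - 1)]
  # last upward crossing of the criterion before the peak: the spike foot
  cross <- which(pre[-length(pre)] < dvdt_criterion &
                 pre[-1] >= dvdt_criterion)
  if (length(cross) == 0) {
    if (all(pre >= dvdt_criterion)) cross <- 0
    else stop("dV/dt criterion never reached before peak")
  }
  thr_rel <- cross[length(cross)] + 1
  threshold <- seg[thr_rel]
  peak <- seg[i_pk_rel]
  amplitude <- peak - threshold
  half <- threshold + amplitude / 2
  # half-width: linear-interpolated crossings around the peak
  up_i <- thr_rel + which(seg[thr_rel:i_pk_rel] >= half)[1] - 1
  t_up <- interp_cross(seg, up_i - 1, half, dt)
  after <- seg[i_pk_rel:length(seg)]
  dn_rel <- which(after <= half)[1]
  if (is.na(dn_rel)) stop("spike does not repolarize within window")
  dn_i <- i_pk_rel + dn_rel - 1
  t_dn <- interp_cross(seg, dn_i - 1, half, dt)
  # AHP: minimum after the peak
  ahp <- threshold - min(after)
  list(threshold = threshold, amplitude = amplitude,
       half_width = t_dn - t_up, max_dvdt = max(dvdt[seq_len(i_pk_rel)]),
       ahp = ahp)
}

## time of the linear crossing of `level` between samples i and i+1
interp_cross <- function(seg, i, level, dt) {
  if (i < 1) return(0)
  v1 <- seg[i]; v2 <- seg[i + 1]
  if (v2 == v1) return(i * dt)
  (i - 1 + (level - v1) / (v2 - v1)) * dt
}

#' Square-pulse F-I protocol
#'
#' 300 ms square current injections normalized to the cell's capacitance,
#' reported as spike frequency versus current density (pA/pF).
#'
#' @param cell A `cell_model`.
#' @param amplitudes Current densities (pA/pF); default 1 to 21 by 2.
#' @param duration Pulse length (ms), default 300.
#' @param pre,post Baseline before/after the pulse (ms).
#' @param dt Time step (ms).
#' @return Data frame with columns `amp_pA_pF`, `n_spikes`, `freq_Hz`.
#' @export
run_fi_curve <- function(cell, amplitudes = seq(1, 21, by = 2),
                         duration = 300, pre = 50, post = 50, dt = 0.025) {
  cap <- cell_capacitance_pF(cell)
  n_pre <- round(pre / dt); n_dur <- round(duration / dt)
  n_post <- round(post / dt)
  res <- lapply(amplitudes, function(a) {
    i_nA <- a * cap * 1e-3  # pA/pF * pF = pA -> nA
    i_vec <- c(rep(0, n_pre), rep(i_nA, n_dur), rep(0, n_post))
    tr <- simulate_cell(cell, duration = (n_pre + n_dur + n_post) * dt,
                        dt = dt, i_inj = i_vec)
    sp <- detect_spikes(tr)
    sp <- sp[sp > pre & sp <= pre + duration]
    data.frame(amp_pA_pF = a, n_spikes = length(sp),
               freq_Hz = length(sp) / (duration / 1000))
  })
  do.call(rbind, res)
}

## lowest two amplitudes eliciting >= 1 spike in a reference (control)
## F-I table; used to operationalize "near-threshold"
near_threshold_amps <- function(fi_control) {
  amps <- fi_control$amp_pA_pF[fi_control$n_spikes >= 1]
  utils::head(sort(amps), 2)
}

#' Voltage-clamp activation family
#'
#' Imposes voltage steps on a Kv3-type conductance and returns the current
#' family and peak I-V table.  Under clamp the gating ODEs have exact
#' exponential solutions, which are evaluated in closed form.
#'
#' @param gmax Maximal conductance (nS).
#' @param e_rev Reversal potential (mV), default -90.
#' @param delta_shift,kin_scale,tau_inact Kv3 gating knobs.
#' @param holding Holding potential (mV), default -110.
#' @param steps Step potentials (mV), default -90 to +50 by 20.
#' @param step_duration Step length (ms), default 300.
#' @param dt Sample interval (ms).
#' @param mtau_parse See [kv3_mtau()].
#' @return List with `traces` (long data frame: `step_mV`, `time_ms`,
#'   `i_nA`) and `peaks` (`step_mV`, `i_peak_nA`, `t_peak_ms`).
#' @export
run_vclamp_activation <- function(gmax = 20, e_rev = -90, delta_shift = 0,
                                  kin_scale = 1, tau_inact = 1000,
                                  holding = -110,
                                  steps = seq(-90, 50, by = 20),
                                  step_duration = 300, dt = 0.025,
                                  mtau_parse = "gaussian") {
  if (is.unsorted(steps)) stop("steps must be sorted ascending")
  tt <- seq(dt, step_duration, by = dt)
  m0 <- kv3_minf(holding, delta_shift)
  h0 <- kv3_hinf(holding, delta_shift)
  traces <- lapply(steps, function(vs) {
    minf <- kv3_minf(vs, delta_shift)
    mtau <- kv3_mtau(vs, delta_shift, kin_scale, mtau_parse)
    hinf <- kv3_hinf(vs, delta_shift)
    m <- minf + (m0 - minf) * exp(-tt / mtau)
    h <- hinf + (h0 - hinf) * exp(-tt / tau_inact)
    i <- gmax * m * h * (vs - e_rev) * 1e-3  # nA
    data.frame(step_mV = vs, time_ms = tt, i_nA = i)
  })
  traces <- do.call(rbind, traces)
  peaks <- do.call(rbind, lapply(split(traces, traces$step_mV),
    function(d) {
      k <- which.max(abs(d$i_nA))
      data.frame(step_mV = d$step_mV[1], i_peak_nA = d$i_nA[k],
                 t_peak_ms = d$time_ms[k])
    }))
  rownames(peaks) <- NULL
  peaks <- peaks[order(peaks$step_mV), ]
  list(traces = traces, peaks = peaks)
}

#' Synaptic bombardment protocol
#'
#' Imposes a fixed number of excitatory and inhibitory alpha synapses at
#' uniformly random onset times over the simulation window and reports the
#' evoked firing rate, optionally across a sweep of Kv3 activation-voltage
#' shifts and over several seeds.
#'
#' @param cell A PV `cell_model`.
#' @param delta_shifts Kv3 activation-voltage shifts (mV) to test.
#' @param n_seeds Seeds per shift (events are redrawn per seed, shared
#'   across shifts within a seed).
#' @param duration Window (ms), default 1000.
#' @param n_exc,n_inh Numbers of excitatory / inhibitory events (1000 /
#'   500).
#' @param gmax Synaptic peak conductance (nS), default 10.
#' @param tau_exc,tau_inh Alpha time constants (ms).
#' @param i_bias Constant bias current (nA), default 0.
#' @param seed Base seed.
#' @param dt Time step (ms).
#' @return Data frame with `delta_shift`, `seed`, `rate_Hz`; summary with
#'   `mean_rate_Hz` and `sem` per shift in attribute `"summary"`.
#' @export
run_bombardment <- function(cell, delta_shifts = 0, n_seeds = 10,
                            duration = 1000, n_exc = 1000, n_inh = 500,
                            gmax = 10, tau_exc = 0.5, tau_inh = 5.8,
                            i_bias = 0, seed = 1, dt = 0.025) {
  rows <- list()
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s - 1)
    exc <- if (n_exc > 0)
      data.frame(onset = runif(n_exc, 0, duration), gmax = gmax) else NULL
    inh <- if (n_inh > 0)
      data.frame(onset = runif(n_inh, 0, duration), gmax = gmax) else NULL
    for (ds in delta_shifts) {
      cc <- cell
      cc$params$kv3_delta_shift <- ds
      tr <- simulate_cell(cc, duration, dt = dt, i_inj = i_bias,
                          exc_events = exc, inh_events = inh,
                          tau_exc = tau_exc, tau_inh = tau_inh)
      rate <- length(detect_spikes(tr)) / (duration / 1000)
      rows[[length(rows) + 1]] <-
        data.frame(delta_shift = ds, seed = seed + s - 1, rate_Hz = rate)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$delta_shift), function(d)
    data.frame(delta_shift = d$delta_shift[1],
               mean_rate_Hz = mean(d$rate_Hz),
               sem = sd(d$rate_Hz) / sqrt(nrow(d)))))
  rownames(summ) <- NULL
  summ <- summ[order(-summ$delta_shift), ]
  attr(out, "summary") <- summ
  out
}

#' gEPSP train protocol (dynamic-clamp style)
#'
#' Delivers a regular train of excitatory conductance events (gEPSPs) with
#' per-event amplitude variability and reports the per-event spike
#' probability under each dynamic-clamp condition.  Event times and
#' amplitudes are identical across conditions, and each condition is held
#' at a common baseline potential with a constant bias current, so
#' probability differences isolate the injected conductance.
#'
#' @param cell A PV `cell_model` (conditions are applied on top of it).
#' @param conditions Named list of dynamic-clamp settings; each entry is a
#'   list with `g_total` (nS) and `delta_shift` (mV).  Default: control
#'   (0 nS), `+gKv3` (20 nS, 0 mV), `+gKv3&Vshift` (20 nS, -10 mV).
#' @param rate Event rate (Hz), default 10.
#' @param n_events Number of events, default 20.
#' @param g_epsp Mean peak conductance per event (nS); the default is
#'   calibrated so the control condition fires on most events.
#' @param jitter_cv Coefficient of variation of the per-event amplitude
#'   (Gaussian, truncated at 0), default 0.06.
#' @param tau Alpha time constant of the gEPSP (ms).
#' @param v_hold Holding potential (mV) imposed per condition.
#' @param seed RNG seed for the amplitude draws.
#' @param dt Time step (ms).
#' @return Data frame with `condition`, `n_events`, `n_spiking`,
#'   `probability`.
#' @export
run_gepsp_train <- function(cell,
                            conditions = list(
                              control = list(g_total = 0, delta_shift = 0),
                              gkv3 = list(g_total = 20, delta_shift = 0),
                              gkv3_vshift = list(g_total = 20,
                                                 delta_shift = -10)),
                            rate = 10, n_events = 20, g_epsp = 1.16,
                            jitter_cv = 0.08, tau = 5, v_hold = -70,
                            seed = 1, dt = 0.025) {
  if (rate <= 0) stop("rate must be > 0")
  period <- 1000 / rate
  onsets <- 50 + period * (seq_len(n_events) - 1)
  duration <- onsets[n_events] + period
  set.seed(seed)
  amps <- pmax(0, g_epsp * (1 + jitter_cv * rnorm(n_events)))
  ev <- data.frame(onset = onsets, gmax = amps)
  out <- lapply(names(conditions), function(nm) {
    cond <- conditions[[nm]]
    cc <- attach_dynamic_clamp(cell, cond$g_total, cond$delta_shift)
    bias <- holding_bias(cc, v_hold)
    tr <- simulate_cell(cc, duration, dt = dt, i_inj = bias,
                        exc_events = if (g_epsp > 0) ev else NULL,
                        tau_exc = tau)
    sp <- detect_spikes(tr)
    hit <- vapply(onsets, function(t0)
      any(sp >= t0 & sp < t0 + period), logical(1))
    data.frame(condition = nm, n_events = n_events,
               n_spiking = sum(hit), probability = mean(hit))
  })
  do.call(rbind, out)
}

#' Subthreshold EPSP amplitude versus Kv3 shift
#'
#' Measures the peak depolarization evoked by a single subthreshold gEPSP
#' at each Kv3 activation-voltage shift.  Each condition is first held at
#' a common baseline potential with a constant bias current (as
#' current-clamp recordings hold cells near -70 mV), so that amplitude
#' differences reflect the conductance change rather than resting-potential
#' offsets.  Errors if any condition spikes.
#'
#' @param cell A PV `cell_model`.
#' @param g_epsp Peak conductance (nS), subthreshold in all conditions.
#' @param delta_shifts Kv3 shifts (mV) to test.
#' @param tau Alpha time constant (ms).
#' @param v_hold Baseline potential (mV) imposed via bias current.
#' @param dt Time step (ms).
#' @return Data frame with `delta_shift`, `epsp_mV`.
#' @export
run_subthreshold_epsp <- function(cell, g_epsp = 1,
                                  delta_shifts = c(0, -5, -10),
                                  tau = 1, v_hold = -70, dt = 0.025) {
  out <- lapply(delta_shifts, function(ds) {
    cc <- cell
    cc$params$kv3_delta_shift <- ds
    bias <- holding_bias(cc, v_hold)
    ev <- if (g_epsp > 0) data.frame(onset = 100, gmax = g_epsp) else NULL
    tr <- simulate_cell(cc, 200, dt = dt, i_inj = bias, exc_events = ev,
                        tau_exc = tau)
    if (length(detect_spikes(tr)) > 0)
      stop("gEPSP is suprathreshold at delta_shift = ", ds)
    base <- tr$v_mV[round(100 / dt)]
    data.frame(delta_shift = ds, epsp_mV = max(tr$v_mV) - base)
  })
  do.call(rbind, out)
}

## constant bias current that settles the cell at v_target (secant search
## on the 300 ms endpoint voltage)
holding_bias <- function(cell, v_target, dt = 0.025) {
  endpoint <- function(b)
    tail(simulate_cell(cell, 300, dt = dt, i_inj = b)$v_mV, 1)
  b0 <- 0; v0 <- endpoint(0)
  b1 <- 0.02; v1 <- endpoint(b1)
  for (k in 1:6) {
    if (abs(v1 - v0) < 1e-9) break
    b2 <- b1 + (v_target - v1) * (b1 - b0) / (v1 - v0)
    b0 <- b1; v0 <- v1
    b1 <- b2; v1 <- endpoint(b2)
    if (abs(v1 - v_target) < 0.01) break
  }
  b1
}

#' Nav conductance-density / shift / kinetics scan
#'
#' F-I curves and first-spike AP metrics across multiplicative Nav density
#' factors (and optional voltage-shift / kinetic-scale grids).
#'
#' @param cell A PV `cell_model`.
#' @param density_factors Multipliers on the control Nav density.
#' @param v_shifts Rigid Nav voltage shifts (mV).
#' @param kin_scales Nav kinetic scale factors.
#' @param amplitudes Current densities (pA/pF) for the F-I curves; the
#'   default grid extends beyond the standard 1-21 pA/pF range because
#'   depolarization-block failures at reduced Nav density emerge at high
#'   drive.
#' @param metric_amp Amplitude (pA/pF) at which the first AP is measured,
#'   default 21 (a level at which all density variants still spike).
#' @return List with `fi` (long data frame) and `metrics`.
#' @export
scan_nav <- function(cell, density_factors = c(0.5, 0.75, 1, 1.25, 1.5),
                     v_shifts = 0, kin_scales = 1,
                     amplitudes = c(seq(1, 21, by = 2), seq(41, 141, by = 20)),
                     metric_amp = 21) {
  grid <- expand.grid(density = density_factors, v_shift = v_shifts,
                      kin_scale = kin_scales)
  fi <- list(); met <- list()
  for (k in seq_len(nrow(grid))) {
    cc <- cell
    cc$params$gna_S_cm2 <- cell$params$gna_S_cm2 * grid$density[k]
    cc$params$na_vshift <- cell$params$na_vshift + grid$v_shift[k]
    cc$params$na_kin_scale <- cell$params$na_kin_scale * grid$kin_scale[k]
    f <- run_fi_curve(cc, amplitudes)
    f$density <- grid$density[k]; f$v_shift <- grid$v_shift[k]
    f$kin_scale <- grid$kin_scale[k]
    fi[[k]] <- f
    met[[k]] <- cbind(grid[k, , drop = FALSE],
                      first_ap_metrics(cc, metric_amp))
  }
  list(fi = do.call(rbind, fi), metrics = do.call(rbind, met))
}

## metrics of the first AP in a 300 ms train at `amp` pA/pF
first_ap_metrics <- function(cell, amp = 9, dt = 0.025) {
  cap <- cell_capacitance_pF(cell)
  n_pre <- round(50 / dt); n_dur <- round(300 / dt)
  i_vec <- c(rep(0, n_pre), rep(amp * cap * 1e-3, n_dur))
  tr <- simulate_cell(cell, 350, dt = dt, i_inj = i_vec)
  sp <- detect_spikes(tr)
  sp <- sp[sp > 50]
  if (length(sp) == 0)
    return(data.frame(threshold = NA_real_, amplitude = NA_real_,
                      half_width = NA_real_, max_dvdt = NA_real_,
                      ahp = NA_real_))
  as.data.frame(ap_metrics(tr, sp[1]))
}

#' Kv7 density / shift scan
#'
#' Adds an M-type Kv7 conductance at each density and activation-voltage
#' shift and reports F-I curves plus first-spike AP metrics.
#'
#' @param cell A PV `cell_model`.
#' @param densities_mS_cm2 Kv7 densities (mS/cm2), default 0 and 2.
#' @param delta_shifts Kv7 activation-voltage shifts (mV).
#' @param amplitudes Current densities (pA/pF).
#' @return List with `fi` and `metrics` data frames.
#' @export
scan_kv7 <- function(cell, densities_mS_cm2 = c(0, 2),
                     delta_shifts = c(0, -10),
                     amplitudes = seq(1, 21, by = 2)) {
  grid <- expand.grid(density = densities_mS_cm2,
                      delta_shift = delta_shifts)
  fi <- list(); met <- list()
  for (k in seq_len(nrow(grid))) {
    cc <- cell
    cc$params$gkv7_S_cm2 <- grid$density[k] * 1e-3
    cc$params$kv7_delta_shift <- grid$delta_shift[k]
    f <- run_fi_curve(cc, amplitudes)
    f$density_mS_cm2 <- grid$density[k]
    f$delta_shift <- grid$delta_shift[k]
    fi[[k]] <- f
    met[[k]] <- cbind(grid[k, , drop = FALSE], first_ap_metrics(cc))
  }
  list(fi = do.call(rbind, fi), metrics = do.call(rbind, met))
}

#' Kv3 inactivation scan
#'
#' Varies the Kv3 slow-inactivation time constant over a 50-1000 ms grid
#' and reports F-I curves plus first-spike AP metrics.  Because PV action
#' potentials last only a few hundred microseconds, even the fastest
#' inactivation in this range accumulates negligibly, so firing should be
#' insensitive across the grid.
#'
#' @param cell A PV `cell_model`.
#' @param tau_inacts Inactivation time constants (ms), default
#'   c(50, 200, 1000).
#' @param amplitudes Current densities (pA/pF).
#' @return List with `fi` and `metrics` data frames.
#' @export
scan_kv3_inactivation <- function(cell, tau_inacts = c(50, 200, 1000),
                                  amplitudes = seq(1, 21, by = 2)) {
  fi <- list(); met <- list()
  for (k in seq_along(tau_inacts)) {
    cc <- cell
    cc$params$kv3_tau_inact <- tau_inacts[k]
    f <- run_fi_curve(cc, amplitudes)
    f$tau_inact <- tau_inacts[k]
    fi[[k]] <- f
    m <- first_ap_metrics(cc)
    m$tau_inact <- tau_inacts[k]
    met[[k]] <- m
  }
  list(fi = do.call(rbind, fi), metrics = do.call(rbind, met))
}
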