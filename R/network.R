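## Reduced layer-5 circuit: 200 bursting pyramidal cells (PC) + 20
## fast-spiking PV interneurons, probabilistic connectivity, gap junctions
## among PV cells, an LFP proxy, and the Kv3 shift sweep.

#' Network specification
#'
#' Population sizes, connection probabilities, synaptic weights (single
#' draw per edge, jittered +/-10% around the nominal value, calibrated so
#' unitary somatic PSPs on a quiescent cell held at -70 mV stay below
#' 1 mV), gap-junction conductance, and
#' per-cell bias-current ranges.  Defaults reproduce the package's
#' calibrated control regime: sparse PC firing near 7 Hz under a dense
#' PV inhibitory tone near 63 Hz.
#'
#' @param n_pc,n_pv Population sizes (200, 20).
#' @param p_pc_pc,p_pv_pc,p_pv_pv_chem,p_pv_pv_gap,p_pc_pv Connection
#'   probabilities (0.10, 0.36, 0.78, 0.61, 0.80).
#' @param w_pc_pc,w_pc_pv,w_pv_pc,w_pv_pv Nominal synaptic conductances
#'   (nS).
#' @param g_gap Gap-junction conductance (nS).
#' @param tau_e,tau_i Exponential synaptic decay constants (ms).
#' @param e_exc,e_inh Synaptic reversal potentials (mV).
#' @param delay Synaptic delay (ms).
#' @param pc_bias_nA,pv_bias_nA Ranges (length-2) of the per-cell constant
#'   bias currents (nA), drawn uniformly per run.
#' @param duration Simulation length (ms).
#' @param pc_config,pv_config Cell-model overrides (see [make_pc_cell()],
#'   [make_pv_cell()]).
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(n_pc = 200, n_pv = 20,
                         p_pc_pc = 0.10, p_pv_pc = 0.36,
                         p_pv_pv_chem = 0.78, p_pv_pv_gap = 0.61,
                         p_pc_pv = 0.80,
                         w_pc_pc = 0.4, w_pc_pv = 0.3,
                         w_pv_pc = 0.76, w_pv_pv = 2.2,
                         g_gap = 0.5,
                         tau_e = 2, tau_i = 5,
                         e_exc = 0, e_inh = -80, delay = 0.5,
                         pc_bias_nA = c(0.045, 0.078),
                         pv_bias_nA = c(0.095, 0.135),
                         duration = 1000,
                         pc_config = list(), pv_config = list()) {
  probs <- c(p_pc_pc, p_pv_pc, p_pv_pv_chem, p_pv_pv_gap, p_pc_pv)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_pc <= 0 || n_pv <= 0) stop("population sizes must be > 0")
  structure(as.list(environment()), class = "network_spec")
}

#' Build a connectivity realization
#'
#' Independent Bernoulli draws per ordered cell pair (unordered for gap
#' junctions), no self-connections, single weight draw per edge
#' (uniform +/-10% jitter around the nominal conductance).  Deterministic
#' per seed.
#'
#' @param spec A [network_spec()].
#' @param seed RNG seed.
#' @return Object of class `network_realization`: edge table (`pre`,
#'   `post`, `w_nS`, `is_inh`), gap-junction pair list, and the spec.
#' @export
build_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  n_pc <- spec$n_pc; n_pv <- spec$n_pv
  pc_ids <- seq_len(n_pc)
  pv_ids <- n_pc + seq_len(n_pv)

  draw_proj <- function(pre_ids, post_ids, p, w, is_inh) {
    if (p == 0 || length(pre_ids) == 0) {
      return(data.frame(pre = integer(0), post = integer(0),
                        w_nS = numeric(0), is_inh = logical(0)))
    }
    pairs <- expand.grid(pre = pre_ids, post = post_ids)
    pairs <- pairs[pairs$pre != pairs$post, ]
    on <- runif(nrow(pairs)) < p
    pairs <- pairs[on, , drop = FALSE]
    pairs$w_nS <- w * runif(nrow(pairs), 0.9, 1.1)
    pairs$is_inh <- is_inh
    pairs
  }

  edges <- rbind(
    draw_proj(pc_ids, pc_ids, spec$p_pc_pc, spec$w_pc_pc, FALSE),
    draw_proj(pc_ids, pv_ids, spec$p_pc_pv, spec$w_pc_pv, FALSE),
    draw_proj(pv_ids, pc_ids, spec$p_pv_pc, spec$w_pv_pc, TRUE),
    draw_proj(pv_ids, pv_ids, spec$p_pv_pv_chem, spec$w_pv_pv, TRUE))
  rownames(edges) <- NULL

  gp <- expand.grid(a = pv_ids, b = pv_ids)
  gp <- gp[gp$a < gp$b, ]
  gp <- gp[runif(nrow(gp)) < spec$p_pv_pv_gap, , drop = FALSE]
  rownames(gp) <- NULL

  structure(list(edges = edges, gaps = gp, spec = spec, seed = seed),
            class = "network_realization")
}

#' Run a network simulation
#'
#' Simulates the realized circuit for the spec's duration with per-cell
#' bias currents and initial voltages drawn per seed (the randomized
#' "activity level" of each cell), optionally applying a Kv3
#' activation-voltage shift to the PV cells only.
#'
#' @param net A `network_realization` from [build_network()].
#' @param delta_shift Kv3 activation-voltage shift (mV) applied to PV
#'   cells, default 0.
#' @param seed RNG seed for bias currents and initial conditions.
#' @param dt Time step (ms), default 0.025.
#' @param lfp_fs LFP proxy sampling rate (Hz) after block-average
#'   decimation, default 1000.
#' @return Object of class `network_run`: `spikes` (data frame `cell_id`,
#'   `time_ms`), `rates` (per-cell Hz), `pc_rate`/`pv_rate` summaries,
#'   `lfp_mV` (LFP proxy, see Details), `lfp_fs`, `duration`, `meta`.
#' @details The LFP proxy is the negated sum of ionic transmembrane
#'   currents of all cells, converted to mV through a nominal 1 MOhm
#'   tissue impedance.  Its absolute scale therefore carries an arbitrary
#'   factor; band-limited comparisons across conditions are meaningful,
#'   absolute spectral densities only up to that factor.
#' @export
run_network <- function(net, delta_shift = 0, seed = 1, dt = 0.025,
                        lfp_fs = 1000) {
  stopifnot(inherits(net, "network_realization"))
  spec <- net$spec
  n_pc <- spec$n_pc; n_pv <- spec$n_pv
  n_cells <- n_pc + n_pv
  set.seed(seed)
  bias <- c(runif(n_pc, spec$pc_bias_nA[1], spec$pc_bias_nA[2]),
            runif(n_pv, spec$pv_bias_nA[1], spec$pv_bias_nA[2]))
  v0 <- runif(n_cells, -75, -60)

  pc <- make_pc_cell(spec$pc_config)
  pv <- make_pv_cell(spec$pv_config)
  pvp <- pv$params
  pvp$kv3_delta_shift <- pvp$kv3_delta_shift + delta_shift
  pvp$kv3_mtau_parse <-
    if (identical(pvp$kv3_mtau_parse, "whole")) 1L else 0L

  n_steps <- round(spec$duration / dt)
  decim <- max(1L, round(1000 / (lfp_fs * dt)))
  res <- .simulate_network_cpp(
    pc$params, pvp, n_pc, n_pv,
    as.integer(net$edges$pre - 1), as.integer(net$edges$post - 1),
    net$edges$w_nS, net$edges$is_inh,
    as.integer(net$gaps$a - 1), as.integer(net$gaps$b - 1), spec$g_gap,
    bias, v0, dt, n_steps, spec$tau_e, spec$tau_i, spec$e_exc,
    spec$e_inh,
    as.integer(round(spec$delay / dt)), -10, 1.5, decim, integer(0))
  if (isTRUE(res$blowup))
    stop("numerical blow-up at t = ", format(res$t_fail), " ms")

  spikes <- data.frame(cell_id = res$spike_id, time_ms = res$spike_t)
  counts <- tabulate(res$spike_id, nbins = n_cells)
  rates <- counts / (spec$duration / 1000)
  pc_rates <- rates[seq_len(n_pc)]
  pv_rates <- rates[n_pc + seq_len(n_pv)]
  structure(list(
    spikes = spikes, rates = rates,
    pc_rate = list(mean = mean(pc_rates),
                   sem = sd(pc_rates) / sqrt(n_pc)),
    pv_rate = list(mean = mean(pv_rates),
                   sem = sd(pv_rates) / sqrt(n_pv)),
    lfp_mV = -res$lfp,  # nA x 1 MOhm = mV, negated summed current
    lfp_fs = 1000 / (decim * dt) / 1,
    duration = spec$duration,
    meta = list(delta_shift = delta_shift, seed = seed, dt = dt,
                n_pc = n_pc, n_pv = n_pv, lfp_impedance_MOhm = 1)),
    class = "network_run")
}

#' LFP band-pass and gamma-band power
#'
#' Band-passes the LFP proxy to 5-50 Hz with a zero-phase 2nd-order
#' Butterworth filter, estimates the power spectrum with Welch's averaged
#' periodogram (500 ms Hann windows, 50% overlap), and reports gamma
#' power as the mean spectral density over 30-50 Hz.
#'
#' @param run A `network_run`, or a numeric LFP vector (mV) with
#'   `fs` supplied.
#' @param fs Sampling rate (Hz) when `run` is a bare vector.
#' @param band Band-pass edges (Hz), default c(5, 50).
#' @param gamma_band Averaging band for gamma power (Hz), default
#'   c(30, 50).
#' @return List of class `lfp_result`: `lfp` (filtered trace),
#'   `spectrum` (data frame `freq_Hz`, `psd_mV2_Hz`), `gamma_power`.
#' @export
compute_lfp <- function(run, fs = NULL, band = c(5, 50),
                        gamma_band = c(30, 50)) {
  if (inherits(run, "network_run")) {
    x <- run$lfp_mV
    fs <- run$lfp_fs
  } else x <- as.numeric(run)
  if (is.null(fs)) stop("fs required")
  if (length(x) / fs < 2 / band[1])
    stop("run shorter than 2 periods of the lowest band frequency")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  sp <- welch_psd(xf, fs)
  in_band <- sp$freq >= gamma_band[1] & sp$freq <= gamma_band[2]
  structure(list(lfp = xf,
                 spectrum = data.frame(freq_Hz = sp$freq,
                                       psd_mV2_Hz = sp$psd),
                 gamma_power = mean(sp$psd[in_band])),
            class = "lfp_result")
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments (default 500 ms)
#' with 50% overlap, one-sided density normalization (units^2 / Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length (s), default 0.5.
#' @param overlap Fractional overlap, default 0.5.
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 0.5, overlap = 0.5) {
  nw <- round(window_s * fs)
  if (nw > length(x)) nw <- length(x)
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1))
  u <- sum(w^2)
  nf <- floor(nw / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 / (fs * u)
    p <- p[seq_len(nf)]
    if (nf > 2) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    acc <- acc + p
  }
  list(freq = seq(0, by = fs / nw, length.out = nf),
       psd = acc / length(starts))
}

#' Gamma power versus Kv3 shift sweep
#'
#' Runs the network across a grid of PV Kv3 activation-voltage shifts
#' with several seeds per shift, computes gamma power per run, and fits
#' \eqn{\gamma = a e^{b |shift|} + c} by least squares.
#'
#' @param spec A [network_spec()].
#' @param shifts Shift grid (mV), default 0 to -10 in 2.5 mV steps (>= 4
#'   points required).
#' @param n_seeds Seeds per shift, default 5.
#' @param seed Base seed (connectivity uses `seed`, runs use consecutive
#'   seeds).
#' @return List with `table` (per-run `shift`, `seed`, `gamma_power`,
#'   `pc_rate`, `pv_rate`), `summary` (mean gamma per shift), and `fit`
#'   (an `exp_fit` on the per-shift means, including `r_squared`).
#' @export
shift_sweep <- function(spec, shifts = seq(0, -10, by = -2.5),
                        n_seeds = 5, seed = 1) {
  if (length(shifts) < 4) stop("need >= 4 grid points")
  net <- build_network(spec, seed = seed)
  rows <- list()
  for (sh in shifts) {
    for (s in seq_len(n_seeds)) {
      run <- run_network(net, delta_shift = sh, seed = seed + s)
      lf <- compute_lfp(run)
      rows[[length(rows) + 1]] <- data.frame(
        shift = sh, seed = seed + s, gamma_power = lf$gamma_power,
        pc_rate = run$pc_rate$mean, pv_rate = run$pv_rate$mean)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$shift), function(d)
    data.frame(shift = d$shift[1], mean_gamma = mean(d$gamma_power),
               sem = sd(d$gamma_power) / sqrt(nrow(d)))))
  summ <- summ[order(-summ$shift), ]
  rownames(summ) <- NULL
  fit <- fit_exponential_trend(abs(summ$shift), summ$mean_gamma)
  list(table = tab, summary = summ, fit = fit)
}

#' Pairwise spike-train synchrony
#'
#' Pearson correlations of binned spike counts (default 5 ms bins) over
#' all pairs of the requested cells; cells without spikes are excluded.
#'
#' @param spikes Data frame with `cell_id`, `time_ms` (e.g.
#'   `run$spikes`).
#' @param duration Observation window (ms).
#' @param cell_ids Cells to include (default: all present).
#' @param bin_ms Bin width (ms), default 5.
#' @return List with `mean_correlation`, `n_pairs`, `n_active`.
#' @export
synchrony_metrics <- function(spikes, duration, cell_ids = NULL,
                              bin_ms = 5) {
  if (is.null(cell_ids)) cell_ids <- sort(unique(spikes$cell_id))
  breaks <- seq(0, duration, by = bin_ms)
  mats <- vapply(cell_ids, function(cid) {
    st <- spikes$time_ms[spikes$cell_id == cid]
    graphics::hist(st[st > 0 & st <= duration], breaks = breaks,
                   plot = FALSE)$counts
  }, numeric(length(breaks) - 1))
  active <- which(apply(mats, 2, var) > 0)
  if (length(active) < 2)
    return(list(mean_correlation = NA_real_, n_pairs = 0L,
                n_active = length(active)))
  cm <- stats::cor(mats[, active, drop = FALSE])
  list(mean_correlation = mean(cm[lower.tri(cm)]),
       n_pairs = sum(lower.tri(cm)), n_active = length(active))
}
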