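## Shared fixtures: calibrated cells and small protocol helpers.

pv <- make_pv_cell()
pc <- make_pc_cell()

## F-I frequencies at specific amplitudes for a cell variant
fi_at <- function(cell, amps) run_fi_curve(cell, amplitudes = amps)$freq_Hz

## PV variant with modified parameters
pv_with <- function(...) {
  cfg <- list(...)
  cell <- pv
  for (nm in names(cfg)) cell$params[[nm]] <- cfg[[nm]]
  cell
}

## voltage trace of a 300 ms square pulse at `amp` pA/pF
pulse_trace <- function(cell, amp, pre = 50, dur = 300, dt = 0.025) {
  cap <- cell_capacitance_pF(cell)
  i <- c(rep(0, round(pre / dt)), rep(amp * cap * 1e-3, round(dur / dt)))
  simulate_cell(cell, (round(pre / dt) + round(dur / dt)) * dt,
                dt = dt, i_inj = i)
}
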