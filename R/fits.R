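## Curve fitting for voltage-clamp analysis and trend fitting.

#' Chord conductance
#'
#' \eqn{g = I_{peak} / (V - E_{rev})}.  With current in nA and voltages in
#' mV the result is in uS; it is returned in nS.  Negative conductances
#' (wrong-sign currents) are clipped to zero with a warning.
#'
#' @param i_peak Peak current (nA); vectorized.
#' @param v Step potential (mV).
#' @param e_rev Reversal potential (mV).
#' @return Conductance (nS).
#' @export
#' @examples
#' chord_conductance(1, 10, -90)  # 10 nS
chord_conductance <- function(i_peak, v, e_rev) {
  if (any(v == e_rev)) stop("v must differ from e_rev")
  g <- i_peak / (v - e_rev) * 1e3  # nA/mV = uS -> nS
  if (any(g < 0)) {
    warning("negative chord conductance clipped to 0")
    g[g < 0] <- 0
  }
  g
}

#' Boltzmann fit of an activation curve
#'
#' Least-squares fit of \eqn{g(v) = g_{max} / (1 + \exp(-(v -
#' V_{1/2})/k))}.  Initial values: \eqn{V_{1/2}} from the half-maximum
#' crossing of the monotonized data, slope from the 25-75% span, gmax
#' from the plateau.
#'
#' @param v Step potentials (mV).
#' @param g Chord conductances (nS), same length as `v`, at least 4
#'   distinct voltages.
#' @return List of class `boltzmann_fit`: `v_half`, `slope`, `gmax`,
#'   `rss`, `converged`, `fitted`.
#' @export
fit_boltzmann <- function(v, g) {
  if (length(unique(v)) < 4) stop("need >= 4 distinct voltages")
  ord <- order(v)
  v <- v[ord]; g <- g[ord]
  gmono <- cummax(g)
  gmax0 <- max(g)
  vh0 <- v[which(gmono >= gmax0 / 2)[1]]
  v25 <- v[which(gmono >= 0.25 * gmax0)[1]]
  v75 <- v[which(gmono >= 0.75 * gmax0)[1]]
  k0 <- max((v75 - v25) / 2.2, 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ gmax / (1 + exp(-(v - vh) / k)),
                      start = list(gmax = gmax0, vh = vh0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(v_half = NA_real_, slope = NA_real_,
                          gmax = NA_real_, rss = NA_real_,
                          converged = FALSE, fitted = rep(NA_real_,
                                                          length(v))),
                     class = "boltzmann_fit"))
  }
  cf <- coef(fit)
  rss <- sum(residuals(fit)^2)
  tss <- sum((g - mean(g))^2)
  ok <- unname(cf["k"] > 0 && cf["gmax"] > 0) &&
    (tss == 0 || 1 - rss / tss > 0.5)
  structure(list(v_half = unname(cf["vh"]), slope = unname(cf["k"]),
                 gmax = unname(cf["gmax"]), rss = rss,
                 converged = ok, fitted = fitted(fit)),
            class = "boltzmann_fit")
}

#' Mono-exponential fit of a current rising phase
#'
#' Fits \eqn{I(t) = A (1 - e^{-t/\tau}) + I_0} to a segment that starts at
#' the step onset, returning the activation time constant.
#'
#' @param t Time since step onset (ms).
#' @param i Current (any units), same length as `t`.
#' @return List with `tau` (ms), `amplitude`, `offset`, `converged`.
#' @export
fit_monoexp_rise <- function(t, i) {
  if (length(t) < 4) stop("need >= 4 samples")
  rng <- diff(range(i))
  if (rng == 0) stop("flat segment")
  # crude tau start: time to reach 63% of span
  span63 <- i[1] + 0.632 * (i[length(i)] - i[1])
  idx <- which((i - span63) * sign(i[length(i)] - i[1]) >= 0)[1]
  tau0 <- max(t[max(idx, 2)], diff(t)[1])
  fit <- tryCatch(
    minpack.lm::nlsLM(i ~ A * (1 - exp(-t / tau)) + c0,
                      start = list(A = i[length(i)] - i[1], tau = tau0,
                                   c0 = i[1]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
                converged = FALSE))
  cf <- coef(fit)
  list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
       offset = unname(cf["c0"]), converged = unname(cf["tau"]) > 0)
}

#' Exponential trend fit with R-squared
#'
#' Least-squares fit of \eqn{y = a e^{b x} + c} with \eqn{R^2 = 1 -
#' RSS/TSS} about the mean of `y` (the convention used throughout the
#' package for nonlinear fits).
#'
#' @param x,y Numeric vectors, at least 4 points.
#' @return List of class `exp_fit`: `a`, `b`, `c`, `r_squared`,
#'   `converged`, `fitted`.
#' @export
fit_exponential_trend <- function(x, y) {
  if (length(x) < 4) stop("need >= 4 points")
  c0 <- min(y) - 0.05 * diff(range(y)) - 1e-12
  # log-linear start on y - c0
  pos <- y - c0 > 0
  b0 <- tryCatch(unname(coef(stats::lm(log(y[pos] - c0) ~ x[pos]))[2]),
                 error = function(e) 0.1)
  if (!is.finite(b0) || b0 == 0) b0 <- 0.1
  a0 <- (y[which.max(x)] - c0) / exp(b0 * max(x))
  if (!is.finite(a0) || a0 == 0) a0 <- diff(range(y)) + 1e-9
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(b * x) + c0f,
                      start = list(a = a0, b = b0, c0f = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          r_squared = NA_real_, converged = FALSE,
                          fitted = rep(NA_real_, length(x))),
                     class = "exp_fit"))
  cf <- coef(fit)
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c0f"]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 converged = TRUE, fitted = fitted(fit)),
            class = "exp_fit")
}

#' @importFrom stats residuals fitted lm
NULL
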