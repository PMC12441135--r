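# Membrane-property extraction and current-type classification from
# voltage-step recordings.
#
# Conventions (matching standard whole-cell practice):
#  - steady-state IV: mean current over the final 5 ms of each step;
#  - single-latency readings: median of the 3 samples around the latency;
#  - membrane resistance: inverse slope of the steady-state IV within
#    +/- 20 mV of the -20 mV holding potential;
#  - capacitance: charge integral of the capacitive transient of the
#    -10 mV step from -20 mV holding, truncation-corrected;
#  - reversal potential: zero crossing of the -70 mV holding IV (linear
#    interpolation, crossing nearest holding);
#  - specific outward conductance: steps 0 / -20 mV at 40 ms (holding -70);
#  - specific inward conductance: steps -120 / -100 mV at 10 ms
#    (holding -20); both normalized by capacitance and floored at 0.

#' Build an IV curve from a step recording
#'
#' @param rec An `iv_recording`.
#' @param latency Read currents at this time after step onset, ms (median of
#'   the 3 surrounding samples). Mutually exclusive with `window`.
#' @param window Average currents over `c(from, to)` ms; the default (last
#'   5 ms of the step) gives the steady-state IV.
#' @return `data.frame` with columns `V` (mV) and `I` (pA), one row per
#'   step level.
#' @export
build_iv_curve <- function(rec, latency = NULL, window = NULL) {
  stopifnot(inherits(rec, "iv_recording"))
  if (!is.null(latency)) {
    I <- trace_at_latency(rec, latency)
  } else {
    if (is.null(window)) {
      window <- c(rec$protocol$step_duration - 5, rec$protocol$step_duration)
    }
    sel <- rec$t >= window[1] & rec$t <= window[2]
    if (!any(sel)) stop("averaging window outside the trace")
    I <- colMeans(rec$traces[sel, , drop = FALSE])
  }
  data.frame(V = rec$protocol$step_levels, I = unname(I))
}

# 3-sample median around a stated latency (robust single-point reading).
trace_at_latency <- function(rec, latency) {
  if (latency <= 0 || latency >= rec$protocol$step_duration) {
    stop("latency outside the trace")
  }
  i <- which.min(abs(rec$t - latency))
  idx <- intersect(seq_len(length(rec$t)), (i - 1):(i + 1))
  apply(rec$traces[idx, , drop = FALSE], 2, stats::median)
}

#' Membrane resistance from the steady-state IV at -20 mV holding
#'
#' Inverse slope of the least-squares line through the steady-state IV
#' restricted to `[holding - 20, holding + 20]` mV.
#'
#' @param iv IV curve (`data.frame` with `V`, `I`) from a holding -20 mV
#'   recording, or the `iv_recording` itself.
#' @param holding Holding potential, mV (taken from the recording when one
#'   is supplied).
#' @return Membrane resistance in MOhm.
#' @export
membrane_resistance <- function(iv, holding = -20) {
  if (inherits(iv, "iv_recording")) {
    holding <- iv$protocol$holding
    iv <- build_iv_curve(iv)
  }
  sel <- iv$V >= holding - 20 & iv$V <= holding + 20
  if (sum(sel) < 3) stop("need at least 3 IV points within +/-20 mV of holding")
  fit <- stats::lm(I ~ V, data = iv[sel, ])
  slope <- stats::coef(fit)[["V"]]      # pA/mV = nS
  if (!is.finite(slope) || slope <= 0) stop("singular or non-positive IV slope")
  1000 / slope                          # MOhm
}

#' Membrane capacitance from the capacitive transient at -20 mV holding
#'
#' Uses the `holding - 10` mV step (command Delta V = -10 mV): the transient
#' decay time constant is estimated from the early samples, the transient
#' charge Q is integrated (trapezoid, including the extrapolated onset
#' sample) over a window of 5 time constants, corrected for the truncated
#' exponential tail, and C_m = Q / Delta V.
#'
#' @param rec An `iv_recording` at holding -20 mV containing the
#'   `holding - 10` mV step.
#' @param delta_v Command step amplitude used, mV (default -10; must be
#'   nonzero).
#' @return Capacitance in pF.
#' @export
membrane_capacitance <- function(rec, delta_v = -10) {
  stopifnot(inherits(rec, "iv_recording"))
  if (delta_v == 0) stop("capacitance requires a nonzero voltage step")
  V <- rec$protocol$holding + delta_v
  j <- match(V, rec$protocol$step_levels)
  if (is.na(j)) stop(sprintf("recording has no %g mV step", V))
  t <- rec$t
  I <- rec$traces[, j]
  dur <- rec$protocol$step_duration
  # slow (gating + leak) component fitted beyond the transient and
  # extrapolated under it, so only the capacitive charge is integrated
  post <- t >= 2
  slow <- fit_exponential(t[post], I[post])
  baseline <- if (slow$flagged || slow$tau < 5) {
    # no credible slow relaxation; a constant baseline suffices
    rep(mean(I[post]), length(t))
  } else {
    slow$a + slow$b * exp(-t / slow$tau)
  }
  y <- I - baseline
  # transient decay constant from the contiguous early log-linear segment
  good <- abs(y) > 0.1 * abs(y[1]) & sign(y) == sign(y[1])
  n_seg <- match(FALSE, good, nomatch = length(y) + 1L) - 1L
  seg <- seq_len(min(n_seg, length(y)))
  seg <- seg[t[seg] <= 3]   # the transient is over well before 3 ms
  if (length(seg) < 3) stop("no capacitive transient detected")
  fit <- stats::lm(log(abs(y[seg])) ~ t[seg])
  tau <- -1 / stats::coef(fit)[[2]]
  if (!is.finite(tau) || tau <= 0) stop("no capacitive transient detected")
  t_end <- min(5 * tau, dur - 5)
  use <- t <= t_end
  # prepend the extrapolated t = 0 sample so the leading area is counted
  y0 <- y[1] * exp(t[1] / tau)
  tt <- c(0, t[use])
  yy <- c(y0, y[use])
  q <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  q <- q / (1 - exp(-t_end / tau))      # truncated-tail correction
  q / delta_v                           # pF (pA*ms / mV)
}

#' Reversal potential from the steady-state IV at -70 mV holding
#'
#' Linear interpolation between the IV points bracketing zero current; with
#' several crossings the one nearest the holding potential is returned.
#'
#' @param iv IV curve (`data.frame` with `V`, `I`) from a holding -70 mV
#'   recording, or the `iv_recording` itself.
#' @param holding Holding potential, mV.
#' @return Reversal potential in mV, or `NA` when the IV does not cross
#'   zero.
#' @export
reversal_potential <- function(iv, holding = -70) {
  if (inherits(iv, "iv_recording")) {
    holding <- iv$protocol$holding
    iv <- build_iv_curve(iv)
  }
  V <- iv$V; I <- iv$I
  crossings <- numeric(0)
  for (i in seq_len(length(V) - 1)) {
    if (I[i] == 0) crossings <- c(crossings, V[i])
    if (I[i] * I[i + 1] < 0) {
      crossings <- c(crossings,
                     V[i] - I[i] * (V[i + 1] - V[i]) / (I[i + 1] - I[i]))
    }
  }
  if (I[length(I)] == 0) crossings <- c(crossings, V[length(V)])
  if (!length(crossings)) return(NA_real_)
  crossings[which.min(abs(crossings - holding))]
}

#' Specific outward conductance (nS/pF)
#'
#' `[I(0 mV, 40 ms) - I(-20 mV, 40 ms)] / 20 mV / C_m`, floored at 0, from
#' the holding -70 mV recording.
#'
#' @param rec An `iv_recording` at holding -70 mV.
#' @param C_m Membrane capacitance, pF.
#' @param latency Measurement latency, ms (default 40).
#' @return Specific conductance in nS/pF.
#' @export
specific_outward_conductance <- function(rec, C_m, latency = 40) {
  stopifnot(inherits(rec, "iv_recording"), C_m > 0)
  I <- trace_at_latency(rec, latency)
  lv <- rec$protocol$step_levels
  if (!all(c(0, -20) %in% lv)) stop("recording lacks the 0 / -20 mV steps")
  g <- (I[[match(0, lv)]] - I[[match(-20, lv)]]) / 20 / C_m
  max(g, 0)
}

#' Specific inward conductance (nS/pF)
#'
#' `[I(-120 mV, 10 ms) - I(-100 mV, 10 ms)] / (-20 mV) / C_m`, floored at 0
#' (positive for inward rectification), from the holding -20 mV recording.
#'
#' @param rec An `iv_recording` at holding -20 mV.
#' @param C_m Membrane capacitance, pF.
#' @param latency Measurement latency, ms (default 10).
#' @return Specific conductance in nS/pF.
#' @export
specific_inward_conductance <- function(rec, C_m, latency = 10) {
  stopifnot(inherits(rec, "iv_recording"), C_m > 0)
  I <- trace_at_latency(rec, latency)
  lv <- rec$protocol$step_levels
  if (!all(c(-120, -100) %in% lv)) {
    stop("recording lacks the -120 / -100 mV steps")
  }
  g <- (I[[match(-120, lv)]] - I[[match(-100, lv)]]) / (-20) / C_m
  max(g, 0)
}

#' Classify a cell by its current types
#'
#' Outward current is present when `G_out_spec >= theta_out`, inward when
#' `G_in_spec >= theta_in`. Cells with neither are `small`; cells with an
#' outward current are `inward_and_outward` (the outward-present group);
#' inward-only cells split at the strong/moderate threshold of 0.5 nS/pF
#' (inclusive: exactly 0.5 is strong).
#'
#' @param G_out_spec,G_in_spec Specific conductances, nS/pF.
#' @param theta_out,theta_in Presence thresholds, nS/pF (default 0.1).
#' @param strong_threshold Strong/moderate inward cut, nS/pF (default 0.5).
#' @return One of `"small"`, `"moderate_inward_only"`,
#'   `"strong_inward_only"`, `"inward_and_outward"`.
#' @export
classify_cell <- function(G_out_spec, G_in_spec, theta_out = 0.1,
                          theta_in = 0.1, strong_threshold = 0.5) {
  outward <- G_out_spec >= theta_out
  inward <- G_in_spec >= theta_in
  if (!outward && !inward) return("small")
  if (outward) return("inward_and_outward")
  if (G_in_spec >= strong_threshold) "strong_inward_only" else
    "moderate_inward_only"
}

#' Full membrane-property panel for one cell
#'
#' @param rec20,rec70 `iv_recording`s at holdings -20 and -70 mV.
#' @param theta_out,theta_in,strong_threshold Classification thresholds,
#'   nS/pF.
#' @return An object of class `membrane_properties`: list with `R_m` (MOhm),
#'   `C_m` (pF), `V_rev` (mV), `G_out_spec`, `G_in_spec` (nS/pF), and
#'   `current_class`.
#' @export
membrane_properties <- function(rec20, rec70, theta_out = 0.1,
                                theta_in = 0.1, strong_threshold = 0.5) {
  stopifnot(rec20$protocol$holding == -20, rec70$protocol$holding == -70)
  C_m <- membrane_capacitance(rec20)
  props <- list(
    cell_id = rec20$cell_id,
    R_m = membrane_resistance(rec20),
    C_m = C_m,
    V_rev = reversal_potential(rec70),
    G_out_spec = specific_outward_conductance(rec70, C_m),
    G_in_spec = specific_inward_conductance(rec20, C_m)
  )
  props$current_class <- classify_cell(props$G_out_spec, props$G_in_spec,
                                       theta_out, theta_in, strong_threshold)
  structure(props, class = "membrane_properties")
}

#' @export
print.membrane_properties <- function(x, ...) {
  cat(sprintf(
    "<membrane_properties %s> R_m %.0f MOhm, C_m %.1f pF, V_rev %s mV, G_out %.3f, G_in %.3f nS/pF -> %s\n",
    x$cell_id, x$R_m, x$C_m,
    if (is.na(x$V_rev)) "NA" else sprintf("%.1f", x$V_rev),
    x$G_out_spec, x$G_in_spec, x$current_class))
  invisible(x)
}

# Generic 3-parameter exponential fit y = a + b*exp(-t/tau); returns a
# flagged non-fit instead of raising on flat or non-convergent traces.
fit_exponential <- function(t, y) {
  flagged <- function(reason) {
    list(a = NA_real_, b = NA_real_, tau = NA_real_,
         resid_norm = NA_real_, flagged = TRUE, reason = reason)
  }
  if (stats::sd(y) < 1e-9 || diff(range(y)) < 1e-6) return(flagged("flat trace"))
  a0 <- mean(utils::tail(y, max(5, length(y) %/% 10)))
  b0 <- y[1] - a0
  if (abs(b0) < 1e-6) return(flagged("no relaxation"))
  z <- (y - a0) / b0
  ok <- z > 1e-3
  if (sum(ok) < 5) return(flagged("no relaxation"))
  tau0 <- tryCatch({
    f <- stats::lm(log(z[ok]) ~ t[ok])
    -1 / stats::coef(f)[[2]]
  }, error = function(e) NA_real_)
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 5
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-t / tau),
                      start = list(a = a0, b = b0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flagged("non-convergent fit"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) {
    return(flagged("non-positive tau"))
  }
  list(a = cf[["a"]], b = cf[["b"]], tau = cf[["tau"]],
       resid_norm = sqrt(sum(stats::resid(fit)^2)), flagged = FALSE,
       reason = NA_character_)
}

#' Fit the voltage-dependent activation time constant
#'
#' Fits `I(t) = A*(1 - exp(-t/tau)) + B` (equivalently a decaying
#' exponential offset) to the rising outward current of a depolarizing step,
#' after discarding the capacitive-transient window. Non-convergent or flat
#' traces are flagged, not raised.
#'
#' @param rec An `iv_recording` (typically holding -70 mV).
#' @param V Step level to fit, mV.
#' @param skip_ms Initial window excluded from the fit (capacitive
#'   transient), ms.
#' @return List with `V`, `tau` (ms), amplitude `A`, offset `B`,
#'   `resid_norm`, and `flagged`.
#' @export
fit_activation_tau <- function(rec, V, skip_ms = 2) {
  j <- match(V, rec$protocol$step_levels)
  if (is.na(j)) stop(sprintf("recording has no %g mV step", V))
  sel <- rec$t >= skip_ms
  f <- fit_exponential(rec$t[sel], rec$traces[sel, j])
  list(V = V, tau = f$tau, A = if (is.na(f$b)) NA_real_ else -f$b,
       B = f$a, resid_norm = f$resid_norm, flagged = f$flagged,
       reason = f$reason)
}

#' Fit the inward-current inactivation time constant
#'
#' Fits `I(t) = A*exp(-t/tau) + B` to the decaying inward current of a
#' strong hyperpolarizing step (V at or below -110 mV), after discarding the
#' capacitive-transient window.
#'
#' @inheritParams fit_activation_tau
#' @return List with `V`, `tau` (ms), `A`, `B`, `resid_norm`, `flagged`.
#' @export
fit_inactivation_tau <- function(rec, V, skip_ms = 2) {
  j <- match(V, rec$protocol$step_levels)
  if (is.na(j)) stop(sprintf("recording has no %g mV step", V))
  sel <- rec$t >= skip_ms
  f <- fit_exponential(rec$t[sel], rec$traces[sel, j])
  list(V = V, tau = f$tau, A = f$b, B = f$a, resid_norm = f$resid_norm,
       flagged = f$flagged, reason = f$reason)
}

#' Membrane-property table for a cohort
#'
#' @param cells Cohort as returned by [simulate_ephys_cohort()], or any list
#'   of elements with `rec20`/`rec70`.
#' @param ... Thresholds passed to [membrane_properties()].
#' @return `data.frame` with one row per cell (id, R_m, C_m, V_rev,
#'   conductances, class, and the true class when available).
#' @export
cohort_properties <- function(cells, ...) {
  rows <- lapply(cells, function(cell) {
    p <- membrane_properties(cell$rec20, cell$rec70, ...)
    data.frame(cell_id = p$cell_id, R_m = p$R_m, C_m = p$C_m,
               V_rev = p$V_rev, G_out_spec = p$G_out_spec,
               G_in_spec = p$G_in_spec, current_class = p$current_class,
               true_class = if (is.null(cell$true_class)) NA_character_
                            else cell$true_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
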