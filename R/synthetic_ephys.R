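# Conductance-model generator for voltage-step recordings.
#
# Per step to command voltage V from holding Vh, the simulated current is
#   I(t) = 1000*(V - Vh)/R_s * exp(-t/(R_s*C_m))        capacitive transient
#        + 1000*(V - V_rev)/R_m                         ohmic leak
#        + g_out * n(t; V) * (V - E_K)                  delayed rectifier Kv
#        + g_in * a(V) * h(t; V) * (V - E_K)            inward rectifier Kir
#        (+ optional instantaneous linear depolarization-activated component)
# with currents in pA, voltages in mV, conductances in nS, resistances in
# MOhm, capacitance in pF, time in ms. Kv activation n follows first-order
# kinetics toward a Boltzmann steady state (faster at more positive
# potentials) from its holding-potential steady state; Kir activates
# instantaneously below E_K and inactivates (first-order, faster at more
# negative potentials) only at potentials negative to -100 mV.

#' Voltage-step protocol
#'
#' @param holding Holding potential, mV (-70 or -20).
#' @param step_levels Command voltages, mV, strictly increasing (default
#'   -170 to +60 in 10 mV increments).
#' @param step_duration Step length, ms (default 50).
#' @param sample_interval Sampling interval, ms (default 0.05).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(holding, step_levels = seq(-170, 60, by = 10),
                          step_duration = 50, sample_interval = 0.05) {
  stopifnot(holding %in% c(-70, -20), step_duration > 0, sample_interval > 0)
  if (any(diff(step_levels) <= 0)) {
    stop("step levels must be strictly increasing")
  }
  structure(list(holding = holding, step_levels = as.numeric(step_levels),
                 step_duration = step_duration,
                 sample_interval = sample_interval),
            class = "step_protocol")
}

#' Ground-truth membrane model parameters
#'
#' @param R_m Membrane resistance, MOhm.
#' @param C_m Membrane capacitance, pF.
#' @param R_s Series (access) resistance, MOhm.
#' @param V_rev Leak reversal potential, mV.
#' @param E_K Potassium reversal potential, mV (default -100; the Kir branch
#'   activates below this value).
#' @param g_out Maximal delayed-rectifier (Kv) conductance, nS.
#' @param V_half_out,k_out Boltzmann midpoint/slope of Kv activation, mV.
#' @param tau_out_min,tau_out_max,tau_out_vhalf,tau_out_k Kv activation time
#'   constant schedule: logistic in V, decreasing with depolarization,
#'   ranging from `tau_out_max` (hyperpolarized) to `tau_out_min`, ms.
#' @param g_in Maximal inward-rectifier (Kir) conductance, nS.
#' @param V_half_in,k_in Boltzmann midpoint/slope of the instantaneous Kir
#'   activation (increasing with hyperpolarization), mV.
#' @param h_inf Kir steady-state inactivation level below -100 mV.
#' @param tau_h_ref,tau_h_vref,tau_h_k Kir inactivation time constant
#'   schedule `tau_h_ref * exp((V - tau_h_vref)/tau_h_k)` ms (decreasing
#'   with hyperpolarization).
#' @param kir_inact_threshold Potential below which Kir inactivation is
#'   engaged, mV.
#' @param g_linear Optional instantaneous linear conductance activated at
#'   depolarized potentials (>= `lin_threshold`), nS; models the
#'   non-delayed linear outward current seen late after injury.
#' @param lin_threshold Activation threshold of the linear component, mV.
#' @return An object of class `ephys_params`.
#' @export
ephys_params <- function(R_m = 2000, C_m = 20, R_s = 10, V_rev = -66.56,
                         E_K = -100,
                         g_out = 0, V_half_out = 10, k_out = 10,
                         tau_out_min = 2, tau_out_max = 25,
                         tau_out_vhalf = 0, tau_out_k = 20,
                         g_in = 0, V_half_in = -110, k_in = 8,
                         h_inf = 0.4, tau_h_ref = 15, tau_h_vref = -170,
                         tau_h_k = 40, kir_inact_threshold = -100,
                         g_linear = 0, lin_threshold = -40) {
  if (!(R_m > 0 && C_m > 0 && R_s > 0)) {
    stop("R_m, C_m and R_s must be positive")
  }
  stopifnot(g_out >= 0, g_in >= 0, g_linear >= 0, k_out > 0, k_in > 0,
            tau_out_min > 0, tau_out_max >= tau_out_min, tau_h_ref > 0,
            h_inf >= 0, h_inf <= 1)
  structure(as.list(environment()), class = "ephys_params")
}

#' Kv activation steady state, time constant, and state trajectory
#'
#' Closed-form pieces of the generator model, exported so tests and analyses
#' can evaluate expected currents analytically.
#'
#' @param V Command voltage, mV.
#' @param params An [ephys_params()].
#' @return `kv_n_inf()`/`kv_tau()`: numeric; `kv_state()`: n(t).
#' @export
kv_n_inf <- function(V, params) {
  1 / (1 + exp((params$V_half_out - V) / params$k_out))
}

#' @rdname kv_n_inf
#' @export
kv_tau <- function(V, params) {
  params$tau_out_min + (params$tau_out_max - params$tau_out_min) /
    (1 + exp((V - params$tau_out_vhalf) / params$tau_out_k))
}

#' @rdname kv_n_inf
#' @param t Time since step onset, ms (vectorized).
#' @param holding Holding potential before the step, mV.
#' @export
kv_state <- function(t, V, holding, params) {
  ninf <- kv_n_inf(V, params)
  n0 <- kv_n_inf(holding, params)
  ninf + (n0 - ninf) * exp(-t / kv_tau(V, params))
}

#' Kir activation, inactivation time constant, and inactivation trajectory
#'
#' @inheritParams kv_n_inf
#' @return `kir_a()`: instantaneous activation; `kir_tau_h()`: ms;
#'   `kir_h()`: h(t) (identically 1 at or above the inactivation threshold).
#' @export
kir_a <- function(V, params) {
  1 / (1 + exp((V - params$V_half_in) / params$k_in))
}

#' @rdname kir_a
#' @export
kir_tau_h <- function(V, params) {
  params$tau_h_ref * exp((V - params$tau_h_vref) / params$tau_h_k)
}

#' @rdname kir_a
#' @param t Time since step onset, ms (vectorized).
#' @export
kir_h <- function(t, V, params) {
  if (V >= params$kir_inact_threshold) return(rep(1, length(t)))
  params$h_inf + (1 - params$h_inf) * exp(-t / kir_tau_h(V, params))
}

#' Noise-free model current for one voltage step
#'
#' @param t Time since step onset, ms (vectorized).
#' @param V Command voltage, mV.
#' @param holding Holding potential, mV.
#' @param params An [ephys_params()].
#' @return Current in pA.
#' @export
model_current <- function(t, V, holding, params) {
  tau_rs <- params$R_s * params$C_m / 1000   # ms
  i_cap <- 1000 * (V - holding) / params$R_s * exp(-t / tau_rs)
  i_leak <- 1000 * (V - params$V_rev) / params$R_m
  i_kv <- params$g_out * kv_state(t, V, holding, params) * (V - params$E_K)
  i_kir <- params$g_in * kir_a(V, params) * kir_h(t, V, params) *
    (V - params$E_K)
  i_lin <- if (V >= params$lin_threshold) {
    params$g_linear * (V - params$V_rev)
  } else 0
  i_cap + i_leak + i_kv + i_kir + i_lin
}

#' Simulate a voltage-step recording
#'
#' @param params An [ephys_params()] (the ground truth).
#' @param protocol A [step_protocol()].
#' @param noise_sd Additive Gaussian current noise, pA.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @param cell_id,clone_id Metadata.
#' @return An object of class `iv_recording`: list with `protocol`, `t`
#'   (ms since step onset), `traces` (time samples x step levels, pA),
#'   `cell_id`, `clone_id`.
#' @export
simulate_iv_recording <- function(params, protocol, noise_sd = 0, seed = 1,
                                  cell_id = "cell1", clone_id = NA) {
  stopifnot(inherits(params, "ephys_params"),
            inherits(protocol, "step_protocol"), noise_sd >= 0)
  t <- seq(protocol$sample_interval, protocol$step_duration,
           by = protocol$sample_interval)
  traces <- vapply(protocol$step_levels, function(V) {
    model_current(t, V, protocol$holding, params)
  }, numeric(length(t)))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    traces <- traces + stats::rnorm(length(traces), 0, noise_sd)
  }
  colnames(traces) <- protocol$step_levels
  structure(list(protocol = protocol, t = t, traces = traces,
                 cell_id = cell_id, clone_id = clone_id),
            class = "iv_recording")
}

#' @export
print.iv_recording <- function(x, ...) {
  cat(sprintf(
    "<iv_recording %s> holding %g mV, %d steps (%g..%g mV), %g ms @ %g ms\n",
    x$cell_id, x$protocol$holding, length(x$protocol$step_levels),
    min(x$protocol$step_levels), max(x$protocol$step_levels),
    x$protocol$step_duration, x$protocol$sample_interval))
  invisible(x)
}

#' Closed-form specific conductances implied by model parameters
#'
#' Evaluates the exact model current (no transient truncation, no sampling)
#' at the measurement latencies and voltage pairs that define the specific
#' conductances, normalized by the true capacitance. Serves as the analytic
#' oracle for recovery tests and for inverting a target conductance to a
#' channel conductance.
#'
#' @param params An [ephys_params()].
#' @return Named numeric: `G_out_spec` (steps 0/-20 mV at 40 ms, holding
#'   -70) and `G_in_spec` (steps -120/-100 mV at 10 ms, holding -20), nS/pF.
#' @export
specific_conductances_closed_form <- function(params) {
  no_cap <- params
  no_cap$R_s <- 1e12   # suppress the transient term analytically
  g_out <- (model_current(40, 0, -70, no_cap) -
              model_current(40, -20, -70, no_cap)) / 20 / params$C_m
  g_in <- (model_current(10, -120, -20, no_cap) -
             model_current(10, -100, -20, no_cap)) / (-20) / params$C_m
  c(G_out_spec = max(g_out, 0), G_in_spec = max(g_in, 0))
}

# Solve for the channel conductance that yields a target specific
# conductance (the measurement is affine in g).
solve_channel_conductance <- function(params, target,
                                      which = c("in", "out")) {
  which <- match.arg(which)
  field <- if (which == "in") "g_in" else "g_out"
  key <- if (which == "in") "G_in_spec" else "G_out_spec"
  p0 <- params; p0[[field]] <- 0
  p1 <- params; p1[[field]] <- 1
  g0 <- specific_conductances_closed_form(p0)[[key]]
  g1 <- specific_conductances_closed_form(p1)[[key]]
  g <- (target - g0) / (g1 - g0)
  if (g < 0) stop("target specific conductance below the leak contribution")
  g
}

#' Simulate a cohort of cells across the four current-type classes
#'
#' Draws per-cell passive parameters and channel conductances so that the
#' closed-form specific conductances fall inside class-typical bands:
#' `small` (no channels), `moderate_inward_only` (G_in 0.2-0.45 nS/pF),
#' `strong_inward_only` (G_in 0.55-1.2 nS/pF), `inward_and_outward`
#' (both G_in and G_out 0.3-1.0 nS/pF). Each cell is recorded from both
#' holding potentials.
#'
#' @param n_per_class Cells per class.
#' @param noise_sd Additive current noise, pA.
#' @param seed Integer seed.
#' @return List of cells; each has `cell_id`, `true_class`, `params`,
#'   `rec20` and `rec70` ([simulate_iv_recording()] outputs at holdings
#'   -20 and -70 mV).
#' @export
simulate_ephys_cohort <- function(n_per_class = 10, noise_sd = 0, seed = 1) {
  classes <- c("small", "moderate_inward_only", "strong_inward_only",
               "inward_and_outward")
  set.seed(as.integer(seed))
  cells <- list()
  k <- 0L
  for (cls in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      p <- ephys_params(R_m = stats::runif(1, 1500, 2500),
                        C_m = stats::runif(1, 15, 30),
                        R_s = stats::runif(1, 8, 14))
      if (cls %in% c("moderate_inward_only")) {
        p$g_in <- solve_channel_conductance(p, stats::runif(1, 0.2, 0.45),
                                            "in")
      } else if (cls == "strong_inward_only") {
        p$g_in <- solve_channel_conductance(p, stats::runif(1, 0.55, 1.2),
                                            "in")
      } else if (cls == "inward_and_outward") {
        p$g_in <- solve_channel_conductance(p, stats::runif(1, 0.3, 1.0),
                                            "in")
        p$g_out <- solve_channel_conductance(p, stats::runif(1, 0.3, 1.0),
                                             "out")
      }
      id <- sprintf("%s_%02d", cls, i)
      cells[[id]] <- list(
        cell_id = id, true_class = cls, params = p,
        rec20 = simulate_iv_recording(p, step_protocol(-20),
                                      noise_sd, derive_seed(seed, 2L * k),
                                      cell_id = id),
        rec70 = simulate_iv_recording(p, step_protocol(-70),
                                      noise_sd, derive_seed(seed, 2L * k + 1L),
                                      cell_id = id))
    }
  }
  cells
}

#' Write voltage-step recordings to a long-format CSV
#'
#' Columns: `cell_id, holding_mV, step_mV, t_ms, I_pA`.
#'
#' @param recs A list of `iv_recording` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_iv_recordings <- function(recs, path) {
  if (inherits(recs, "iv_recording")) recs <- list(recs)
  rows <- lapply(recs, function(r) {
    data.frame(cell_id = r$cell_id,
               holding_mV = r$protocol$holding,
               step_mV = rep(r$protocol$step_levels, each = length(r$t)),
               t_ms = rep(r$t, times = length(r$protocol$step_levels)),
               I_pA = as.vector(r$traces),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read voltage-step recordings from a long-format CSV
#'
#' @param path CSV written by [write_iv_recordings()] (or matching its
#'   column contract).
#' @return Named list of `iv_recording` objects, one per
#'   (cell_id, holding) pair, named `"<cell_id>@<holding>"`.
#' @export
read_iv_recordings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "holding_mV", "step_mV", "t_ms", "I_pA")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("trace table is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  out <- list()
  for (key in unique(paste(df$cell_id, df$holding_mV, sep = "@"))) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    g <- df[df$cell_id == parts[1] & df$holding_mV == as.numeric(parts[2]), ]
    t <- sort(unique(g$t_ms))
    levels <- sort(unique(g$step_mV))
    traces <- matrix(NA_real_, nrow = length(t), ncol = length(levels),
                     dimnames = list(NULL, levels))
    for (j in seq_along(levels)) {
      gj <- g[g$step_mV == levels[j], ]
      traces[match(gj$t_ms, t), j] <- gj$I_pA
    }
    proto <- step_protocol(as.numeric(parts[2]), levels,
                           step_duration = max(t),
                           sample_interval = t[2] - t[1])
    out[[key]] <- structure(list(protocol = proto, t = t, traces = traces,
                                 cell_id = parts[1], clone_id = NA),
                            class = "iv_recording")
  }
  out
}
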