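# Forward model of the two-step SOCE stimulation paradigm: a histamine
# bolus in Ca2+-free (EGTA) buffer releases ER stores, Ca2+ re-addition
# drives plasma-membrane entry. Traces are generated per imaging cycle with
# known ground truth so downstream FRET analysis can be verified exactly.

#' Stimulation protocol for the two-step SOCE paradigm
#'
#' @param n_cycles total imaging cycles (default 100).
#' @param cycle_interval_s seconds between cycles (default 3).
#' @param histamine_event_cycle cycle after which histamine is added
#'   (default 10).
#' @param calcium_event_cycle cycle after which Ca2+ is re-added
#'   (default 50).
#' @param added_volume_fraction volume of each stimulant bolus as a fraction
#'   of the original bath volume (default 0.5, i.e. 50 percent of the
#'   original volume, so 3x stocks land at 1x).
#' @param stock_histamine_uM histamine stock concentration (default 300).
#' @param stock_calcium_mM CaCl2 stock concentration (default 3).
#' @return an object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(n_cycles = 100L,
                                 cycle_interval_s = 3,
                                 histamine_event_cycle = 10L,
                                 calcium_event_cycle = 50L,
                                 added_volume_fraction = 0.5,
                                 stock_histamine_uM = 300,
                                 stock_calcium_mM = 3) {
  n_cycles <- check_count(n_cycles, "n_cycles", lower = 1L)
  check_number(cycle_interval_s, "cycle_interval_s", lower = 0,
               strict_lower = TRUE)
  histamine_event_cycle <- check_count(histamine_event_cycle,
                                       "histamine_event_cycle", lower = 1L)
  calcium_event_cycle <- check_count(calcium_event_cycle,
                                     "calcium_event_cycle", lower = 1L)
  if (!(histamine_event_cycle < calcium_event_cycle &&
        calcium_event_cycle <= n_cycles))
    stop_invalid(paste("need 1 <= histamine_event_cycle <",
                       "calcium_event_cycle <= n_cycles (got %d, %d, %d)"),
                 histamine_event_cycle, calcium_event_cycle, n_cycles)
  check_number(added_volume_fraction, "added_volume_fraction", lower = 0,
               strict_lower = TRUE)
  check_number(stock_histamine_uM, "stock_histamine_uM", lower = 0)
  check_number(stock_calcium_mM, "stock_calcium_mM", lower = 0)
  structure(list(n_cycles = n_cycles,
                 cycle_interval_s = cycle_interval_s,
                 histamine_event_cycle = histamine_event_cycle,
                 calcium_event_cycle = calcium_event_cycle,
                 added_volume_fraction = added_volume_fraction,
                 stock_histamine_uM = stock_histamine_uM,
                 stock_calcium_mM = stock_calcium_mM),
            class = "stimulation_protocol")
}

#' Calcium dynamics parameters for the synthetic SOCE response
#'
#' Baselines follow the resting concentrations of the system under study:
#' roughly 100 nM cytosolic and 600 nM intraperoxisomal Ca2+. The two
#' transients are double-exponential pulses (rise/decay time constants);
#' the peroxisomal trace is the cytosolic trace passed through a
#' first-order lag and rescaled, emulating the delayed equilibration of
#' the peroxisomal lumen.
#'
#' @param baseline_cytosolic_nM resting cytosolic Ca2+ (default 100).
#' @param baseline_peroxisomal_nM resting peroxisomal Ca2+ (default 600).
#' @param er_peak_amplitude_nM cytosolic amplitude of the histamine (ER
#'   release) transient (default 400).
#' @param pm_peak_amplitude_nM cytosolic amplitude of the Ca2+-readdition
#'   (plasma-membrane entry) transient (default 300).
#' @param rise_tau_s rise time constant of both transients (default 4).
#' @param decay_tau_s decay time constant (default 12).
#' @param peroxisomal_lag_tau_s first-order lag of the peroxisomal trace
#'   behind the cytosolic trace (default 15; 0 means no lag).
#' @param cell_cv lognormal coefficient of variation of per-cell transient
#'   amplitudes (default 0.1).
#' @param condition_multipliers named list mapping a condition label to a
#'   list with `baseline_scale`, `er_scale`, `pm_scale`. Defaults model a
#'   control ("NC") and a tether knock-down ("siACBD5") whose SOCE-driven
#'   peroxisomal uptake is blunted.
#' @return an object of class `ca_dynamics_params`.
#' @export
ca_dynamics_params <- function(baseline_cytosolic_nM = 100,
                               baseline_peroxisomal_nM = 600,
                               er_peak_amplitude_nM = 400,
                               pm_peak_amplitude_nM = 300,
                               rise_tau_s = 4,
                               decay_tau_s = 12,
                               peroxisomal_lag_tau_s = 15,
                               cell_cv = 0.1,
                               condition_multipliers = list(
                                 NC = list(baseline_scale = 1,
                                           er_scale = 1, pm_scale = 1),
                                 siACBD5 = list(baseline_scale = 1,
                                                er_scale = 0.6,
                                                pm_scale = 0.4))) {
  for (nm in c("baseline_cytosolic_nM", "baseline_peroxisomal_nM",
               "rise_tau_s", "decay_tau_s"))
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  check_number(er_peak_amplitude_nM, "er_peak_amplitude_nM", lower = 0)
  check_number(pm_peak_amplitude_nM, "pm_peak_amplitude_nM", lower = 0)
  check_number(peroxisomal_lag_tau_s, "peroxisomal_lag_tau_s", lower = 0)
  check_number(cell_cv, "cell_cv", lower = 0)
  if (!is.list(condition_multipliers) || is.null(names(condition_multipliers)))
    stop_invalid("'condition_multipliers' must be a named list")
  for (nm in names(condition_multipliers)) {
    m <- condition_multipliers[[nm]]
    for (k in c("baseline_scale", "er_scale", "pm_scale")) {
      if (is.null(m[[k]]))
        stop_invalid("condition '%s' is missing multiplier '%s'", nm, k)
      check_number(m[[k]], paste0(nm, "$", k), lower = 0)
    }
  }
  structure(list(baseline_cytosolic_nM = baseline_cytosolic_nM,
                 baseline_peroxisomal_nM = baseline_peroxisomal_nM,
                 er_peak_amplitude_nM = er_peak_amplitude_nM,
                 pm_peak_amplitude_nM = pm_peak_amplitude_nM,
                 rise_tau_s = rise_tau_s,
                 decay_tau_s = decay_tau_s,
                 peroxisomal_lag_tau_s = peroxisomal_lag_tau_s,
                 cell_cv = cell_cv,
                 condition_multipliers = condition_multipliers),
            class = "ca_dynamics_params")
}

# Normalised double-exponential pulse: 0 for u <= 0, peak value 1.
pulse_shape <- function(u, rise_tau, decay_tau) {
  if (rise_tau >= decay_tau) rise_tau <- decay_tau * 0.999
  u_star <- rise_tau * decay_tau / (decay_tau - rise_tau) *
    log(decay_tau / rise_tau)
  peak <- exp(-u_star / decay_tau) - exp(-u_star / rise_tau)
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- (exp(-u[pos] / decay_tau) - exp(-u[pos] / rise_tau)) / peak
  out
}

# Discrete first-order lag with time constant tau, initialised at steady
# state on the first sample; tau = 0 returns the input unchanged.
first_order_lag <- function(x, tau, dt) {
  if (tau <= 0) return(x)
  a <- 1 - exp(-dt / tau)
  y <- numeric(length(x))
  y[1] <- x[1]
  for (k in seq_along(x)[-1]) y[k] <- y[k - 1] + a * (x[k] - y[k - 1])
  y
}

#' Simulate ground-truth cytosolic and peroxisomal Ca2+ traces
#'
#' Each cell's cytosolic trace is flat at baseline, shows a transient after
#' the histamine event cycle (ER store release) and a second rise after the
#' Ca2+-readdition cycle (plasma-membrane entry). The peroxisomal trace is
#' the first-order-lagged cytosolic trace rescaled by the baseline ratio
#' and the condition multipliers. Per-cell amplitude variability uses one
#' derived random stream per cell, so increasing `n_cells` never changes
#' earlier cells.
#'
#' @param protocol a [stimulation_protocol()].
#' @param params a [ca_dynamics_params()].
#' @param condition condition label; must be a name of
#'   `params$condition_multipliers`.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return a data.frame with columns cell_id, condition, cycle, time_s,
#'   ca_cyt_nM, ca_perox_nM.
#' @export
simulate_ca_traces <- function(protocol, params, condition = "NC",
                               n_cells = 1L, seed = 1L) {
  stopifnot(inherits(protocol, "stimulation_protocol"),
            inherits(params, "ca_dynamics_params"))
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  known <- names(params$condition_multipliers)
  if (!condition %in% known)
    stop_invalid("unknown condition '%s'; known conditions: %s",
                 condition, paste(known, collapse = ", "))
  m <- params$condition_multipliers[[condition]]
  dt <- protocol$cycle_interval_s
  cycles <- seq_len(protocol$n_cycles)
  t_s <- (cycles - 1) * dt
  t_hist <- (protocol$histamine_event_cycle) * dt  # bolus lands after the cycle
  t_ca <- (protocol$calcium_event_cycle) * dt
  scale_perox <- params$baseline_peroxisomal_nM / params$baseline_cytosolic_nM

  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    amp <- with_seed(derive_seed(seed, i), {
      if (params$cell_cv > 0) {
        sdl <- sqrt(log(1 + params$cell_cv^2))
        exp(stats::rnorm(2, -sdl^2 / 2, sdl))
      } else c(1, 1)
    })
    cyt <- params$baseline_cytosolic_nM +
      amp[1] * params$er_peak_amplitude_nM *
        pulse_shape(t_s - t_hist, params$rise_tau_s, params$decay_tau_s) +
      amp[2] * params$pm_peak_amplitude_nM *
        pulse_shape(t_s - t_ca, params$rise_tau_s, params$decay_tau_s)
    perox <- scale_perox * (
      m$baseline_scale * params$baseline_cytosolic_nM +
        amp[1] * m$er_scale * params$er_peak_amplitude_nM *
          pulse_shape(t_s - t_hist, params$rise_tau_s, params$decay_tau_s) +
        amp[2] * m$pm_scale * params$pm_peak_amplitude_nM *
          pulse_shape(t_s - t_ca, params$rise_tau_s, params$decay_tau_s))
    perox <- first_order_lag(perox, params$peroxisomal_lag_tau_s, dt)
    out[[i]] <- data.frame(cell_id = sprintf("cell%03d", i),
                           condition = condition, cycle = cycles,
                           time_s = t_s, ca_cyt_nM = cyt,
                           ca_perox_nM = perox)
  }
  do.call(rbind, out)
}

#' Hill-type FRET sensor forward model
#'
#' Converts a Ca2+ concentration into the sensor's corrected FRET/donor
#' ratio: R(Ca) = r_min + (r_max - r_min) * Ca^n / (Ca^n + kd^n). Constants
#' are configurable plumbing with defaults in the working range of
#' calmodulin-based cameleon sensors; no published calibration is assumed.
#'
#' @param kd_nM half-saturation constant (default 600).
#' @param hill_n Hill coefficient (default 1).
#' @param r_min,r_max ratio at zero / saturating Ca2+ (defaults 1 and 3).
#' @return an object of class `sensor_params`.
#' @export
sensor_params <- function(kd_nM = 600, hill_n = 1, r_min = 1, r_max = 3) {
  check_number(kd_nM, "kd_nM", lower = 0, strict_lower = TRUE)
  check_number(hill_n, "hill_n", lower = 0, strict_lower = TRUE)
  check_number(r_min, "r_min", lower = 0, strict_lower = TRUE)
  check_number(r_max, "r_max", lower = r_min, strict_lower = TRUE)
  structure(list(kd_nM = kd_nM, hill_n = hill_n, r_min = r_min,
                 r_max = r_max), class = "sensor_params")
}

#' Apply the Hill sensor to a Ca2+ concentration
#'
#' @param ca_nM Ca2+ concentration(s) in nM (>= 0).
#' @param sensor a [sensor_params()].
#' @return the true FRET/donor ratio(s).
#' @export
sensor_ratio <- function(ca_nM, sensor = sensor_params()) {
  stopifnot(inherits(sensor, "sensor_params"))
  if (any(ca_nM < 0)) stop_invalid("Ca2+ concentrations must be >= 0")
  can <- ca_nM^sensor$hill_n
  sensor$r_min + (sensor$r_max - sensor$r_min) *
    can / (can + sensor$kd_nM^sensor$hill_n)
}
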