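# Bleed-through/background corrected FRET ratio analysis of the two-step
# SOCE protocol. Per cycle the corrected sensitized-emission-to-donor ratio
# is
#   ratio = [(FRET - bg_f) - (donor - bg_d) * bt_df - (acceptor - bg_a) * bt_af]
#           / [(donor - bg_d) - (acceptor - bg_a) * bt_ad]
# with the three crosstalk coefficients measured on single-fluorophore
# control cells.

#' Bleed-through coefficient set
#'
#' @param bt_donor_to_fret donor signal detected in the FRET channel.
#' @param bt_acceptor_to_fret acceptor signal detected in the FRET channel.
#' @param bt_acceptor_to_donor acceptor signal detected in the donor
#'   channel.
#' @return an object of class `bleedthrough`.
#' @export
bleedthrough <- function(bt_donor_to_fret, bt_acceptor_to_fret,
                         bt_acceptor_to_donor = 0) {
  for (nm in c("bt_donor_to_fret", "bt_acceptor_to_fret",
               "bt_acceptor_to_donor"))
    check_number(get(nm), nm, lower = 0, upper = 1, strict_upper = TRUE)
  structure(list(bt_donor_to_fret = bt_donor_to_fret,
                 bt_acceptor_to_fret = bt_acceptor_to_fret,
                 bt_acceptor_to_donor = bt_acceptor_to_donor),
            class = "bleedthrough")
}

check_trace <- function(trace, need_mrfp = FALSE) {
  need <- c("cell_id", "cycle", "donor", "fret", "acceptor",
            "bg_donor", "bg_fret", "bg_acceptor")
  if (need_mrfp) need <- c(need, "mrfp", "bg_mrfp")
  miss <- setdiff(need, names(trace))
  if (length(miss))
    stop_invalid("intensity trace is missing column(s): %s",
                 paste(miss, collapse = ", "))
  invisible(trace)
}

# slope through the origin, least squares over all observations
origin_slope <- function(x, y) sum(x * y) / sum(x * x)

#' Estimate bleed-through coefficients from single-fluorophore controls
#'
#' Crosstalk is calibrated as the least-squares slope through the origin of
#' the background-corrected contaminated channel against the
#' background-corrected source channel, pooled over all observations of
#' all control cells (bright cells therefore carry more weight).
#'
#' @param donor_only_traces intensity table of donor-only (CFP) control
#'   cells.
#' @param acceptor_only_traces intensity table of acceptor-only (YFP)
#'   control cells.
#' @return a [bleedthrough()] object.
#' @export
estimate_bleedthrough <- function(donor_only_traces, acceptor_only_traces) {
  check_trace(donor_only_traces); check_trace(acceptor_only_traces)
  if (nrow(donor_only_traces) == 0L || nrow(acceptor_only_traces) == 0L)
    stop_invalid("control trace sets must be non-empty")
  d <- donor_only_traces$donor - donor_only_traces$bg_donor
  if (all(d <= 0))
    stop_invalid("degenerate donor-only controls: all donor intensities <= background")
  a <- acceptor_only_traces$acceptor - acceptor_only_traces$bg_acceptor
  if (all(a <= 0))
    stop_invalid("degenerate acceptor-only controls: all acceptor intensities <= background")
  bleedthrough(
    bt_donor_to_fret = origin_slope(
      d, donor_only_traces$fret - donor_only_traces$bg_fret),
    bt_acceptor_to_fret = origin_slope(
      a, acceptor_only_traces$fret - acceptor_only_traces$bg_fret),
    bt_acceptor_to_donor = max(0, origin_slope(
      a, acceptor_only_traces$donor - acceptor_only_traces$bg_donor)))
}

#' Background- and bleed-through-corrected FRET/donor ratio
#'
#' Cycles whose corrected-donor denominator is at or below
#' `denominator_floor` are flagged invalid rather than dropped, so window
#' statistics can exclude them explicitly.
#'
#' @param trace intensity table for one or more cells.
#' @param bt a [bleedthrough()] object.
#' @param denominator_floor positivity floor for the denominator
#'   (default 0: only non-positive denominators are invalid).
#' @return a data.frame with columns cell_id, cycle, time_s, ratio, valid.
#' @export
correct_ratio <- function(trace, bt, denominator_floor = 0) {
  check_trace(trace)
  stopifnot(inherits(bt, "bleedthrough"))
  check_number(denominator_floor, "denominator_floor")
  num <- (trace$fret - trace$bg_fret) -
    (trace$donor - trace$bg_donor) * bt$bt_donor_to_fret -
    (trace$acceptor - trace$bg_acceptor) * bt$bt_acceptor_to_fret
  den <- (trace$donor - trace$bg_donor) -
    (trace$acceptor - trace$bg_acceptor) * bt$bt_acceptor_to_donor
  valid <- is.finite(num) & is.finite(den) & den > denominator_floor
  if (!any(valid))
    stop_invalid("no valid cycle in trace: every denominator <= floor (%g)",
                 denominator_floor)
  ratio <- ifelse(valid, num / den, NA_real_)
  data.frame(cell_id = trace$cell_id, cycle = trace$cycle,
             time_s = if ("time_s" %in% names(trace)) trace$time_s else
               NA_real_,
             ratio = ratio, valid = valid)
}

#' Analysis windows for the SOCE response metrics
#'
#' Inclusive 1-based cycle ranges: baseline = mean ratio over cycles 1-9;
#' the ER-based response is the maximum over cycles 9-25 minus baseline;
#' the PM-based response is the maximum over cycles 49-70 minus the mean
#' over cycles 47-49. Cycle 9 belongs to both the baseline and the ER
#' search window, and cycle 49 to both PM windows, as printed.
#'
#' @param baseline_cycles,er_search_cycles,pm_reference_cycles,pm_search_cycles
#'   inclusive integer ranges `c(first, last)`.
#' @return an object of class `soce_windows`.
#' @export
soce_windows <- function(baseline_cycles = c(1L, 9L),
                         er_search_cycles = c(9L, 25L),
                         pm_reference_cycles = c(47L, 49L),
                         pm_search_cycles = c(49L, 70L)) {
  rngs <- list(baseline_cycles = baseline_cycles,
               er_search_cycles = er_search_cycles,
               pm_reference_cycles = pm_reference_cycles,
               pm_search_cycles = pm_search_cycles)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || any(r != round(r)) || r[1] < 1L || r[2] < r[1])
      stop_invalid("'%s' must be an inclusive 1-based range c(first, last)",
                   nm)
    rngs[[nm]] <- as.integer(r)
  }
  if (rngs$baseline_cycles[1] > rngs$er_search_cycles[2])
    stop_invalid("baseline window must start before the ER search window ends")
  if (rngs$pm_reference_cycles[1] > rngs$pm_search_cycles[2])
    stop_invalid("PM reference window must start before the PM search window ends")
  structure(rngs, class = "soce_windows")
}

window_values <- function(ratio_df, rng, window_name) {
  sel <- ratio_df$cycle >= rng[1] & ratio_df$cycle <= rng[2] & ratio_df$valid
  if (max(ratio_df$cycle) < rng[2] || min(ratio_df$cycle) > rng[1])
    stop_invalid("trace does not cover the %s window (cycles %d-%d)",
                 window_name, rng[1], rng[2])
  v <- ratio_df$ratio[sel]
  if (!length(v))
    stop_invalid("metric undefined: no valid cycle in the %s window (cycles %d-%d)",
                 window_name, rng[1], rng[2])
  v
}

#' Extract the three SOCE response metrics from a corrected ratio trace
#'
#' @param ratio a single cell's ratio trace from [correct_ratio()].
#' @param windows a [soce_windows()].
#' @return a data.frame row: cell_id, baseline, er_response, pm_response.
#' @export
extract_soce_metrics <- function(ratio, windows = soce_windows()) {
  stopifnot(inherits(windows, "soce_windows"))
  if (length(unique(ratio$cell_id)) != 1L)
    stop_invalid("extract_soce_metrics() expects a single cell's trace")
  baseline <- mean(window_values(ratio, windows$baseline_cycles, "baseline"))
  er <- max(window_values(ratio, windows$er_search_cycles, "ER search")) -
    baseline
  pm_ref <- mean(window_values(ratio, windows$pm_reference_cycles,
                               "PM reference"))
  pm <- max(window_values(ratio, windows$pm_search_cycles, "PM search")) -
    pm_ref
  data.frame(cell_id = ratio$cell_id[1], baseline = baseline,
             er_response = er, pm_response = pm)
}

#' Classify a cell by background-corrected mRFP expression
#'
#' The mean over cycles of (mrfp - bg_mrfp) is compared against the gate
#' threshold: strictly below is "neg", strictly above "pos". A value
#' exactly at the threshold is classified "pos" with a warning, since the
#' gate is defined only by strict inequalities.
#'
#' @param trace a single cell's intensity table (must carry mrfp columns).
#' @param threshold gate threshold, a.u. (default 0.5).
#' @return "pos" or "neg".
#' @export
classify_mrfp <- function(trace, threshold = 0.5) {
  check_trace(trace, need_mrfp = TRUE)
  check_number(threshold, "threshold", lower = 0)
  m <- mean(trace$mrfp - trace$bg_mrfp)
  if (m == threshold) {
    warning(sprintf("mRFP mean exactly at the %g gate; classified 'pos'",
                    threshold), call. = FALSE)
    return("pos")
  }
  if (m < threshold) "neg" else "pos"
}

#' Per-group population summaries of ratio traces or metrics
#'
#' For per-cycle traces, returns the across-cell mean and SEM of the ratio
#' at each cycle and group; for scalar metrics, the per-group mean, SEM and
#' n per metric. SEM = sample sd / sqrt(n); with a single cell the SEM is
#' reported as NA.
#'
#' @param ratios combined ratio traces of many cells (from
#'   [correct_ratio()]), or NULL.
#' @param metrics combined metric rows (from [extract_soce_metrics()]), or
#'   NULL.
#' @param groups named character vector mapping cell_id to group label.
#' @return a list with elements `per_cycle` and/or `per_metric`.
#' @export
summarize_population <- function(ratios = NULL, metrics = NULL, groups) {
  sem <- function(x) if (length(x) < 2L) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  out <- list()
  if (!is.null(ratios)) {
    ratios$group <- unname(groups[as.character(ratios$cell_id)])
    if (anyNA(ratios$group)) stop_invalid("every cell_id needs a group label")
    ok <- ratios[ratios$valid, ]
    agg <- do.call(rbind, lapply(
      split(ok, list(ok$group, ok$cycle), drop = TRUE),
      function(d) data.frame(group = d$group[1], cycle = d$cycle[1],
                             mean = mean(d$ratio), sem = sem(d$ratio),
                             n = nrow(d))))
    out$per_cycle <- agg[order(agg$group, agg$cycle), ]
    rownames(out$per_cycle) <- NULL
  }
  if (!is.null(metrics)) {
    metrics$group <- unname(groups[as.character(metrics$cell_id)])
    if (anyNA(metrics$group)) stop_invalid("every cell_id needs a group label")
    vars <- c("baseline", "er_response", "pm_response")
    agg <- do.call(rbind, lapply(split(metrics, metrics$group), function(d) {
      do.call(rbind, lapply(vars, function(v)
        data.frame(group = d$group[1], metric = v, mean = mean(d[[v]]),
                   sem = sem(d[[v]]), n = nrow(d))))
    }))
    rownames(agg) <- NULL
    out$per_metric <- agg
  }
  out
}
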