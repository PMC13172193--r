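# Rendering of observed microscope channels from a true FRET/donor ratio.
# The forward model is the exact algebraic inverse of the ratio correction
# in correct_ratio(): with pure donor signal D, pure acceptor signal A and
# sensitized emission S = ratio * D,
#   donor_obs    = D + A * bt_acceptor_to_donor + bg_d
#   acceptor_obs = A + bg_a
#   fret_obs     = S + (donor_obs - bg_d) * bt_donor_to_fret
#                    + (acceptor_obs - bg_a) * bt_acceptor_to_fret + bg_f
# Donor crosstalk into the FRET channel is applied to the background-
# corrected observed donor channel (which itself carries the small
# acceptor-into-donor term), exactly as the correction subtracts it, so
# with noise_model "none" the correction recovers the ratio to machine
# precision.

#' Optical parameters: crosstalk, background, expression and noise
#'
#' @param bt_donor_to_fret fraction of pure donor signal bleeding into the
#'   FRET channel (default 0.57).
#' @param bt_acceptor_to_fret fraction of pure acceptor signal bleeding
#'   into the FRET channel (default 0.26).
#' @param bt_acceptor_to_donor fraction of pure acceptor signal bleeding
#'   into the donor channel (default 0.02).
#' @param background_donor,background_fret,background_acceptor,background_mrfp
#'   per-channel background levels, a.u. (defaults 10).
#' @param donor_expression_mean,donor_expression_sd per-cell pure donor
#'   signal distribution, a.u. (defaults 100 and 20).
#' @param acceptor_level pure acceptor signal as a fraction of the pure
#'   donor signal of the same cell (default 0.5); the sensor carries donor
#'   and acceptor 1:1 but detection efficiencies differ.
#' @param noise_model `list(type = "none")`,
#'   `list(type = "gaussian", sd_frac = ...)` (sd proportional to the
#'   noise-free channel value) or `list(type = "poisson", gain = ...)`.
#' @param mrfp_mean_pos,mrfp_mean_neg background-corrected mRFP levels for
#'   tether-positive / negative cells, a.u. (defaults 2 and 0.05). mRFP
#'   does not cross into the FRET channels (its introduction leaves the
#'   bleed-through coefficients unchanged).
#' @return an object of class `optical_params`.
#' @export
optical_params <- function(bt_donor_to_fret = 0.57,
                           bt_acceptor_to_fret = 0.26,
                           bt_acceptor_to_donor = 0.02,
                           background_donor = 10,
                           background_fret = 10,
                           background_acceptor = 10,
                           background_mrfp = 10,
                           donor_expression_mean = 100,
                           donor_expression_sd = 20,
                           acceptor_level = 0.5,
                           noise_model = list(type = "none"),
                           mrfp_mean_pos = 2,
                           mrfp_mean_neg = 0.05) {
  for (nm in c("bt_donor_to_fret", "bt_acceptor_to_fret",
               "bt_acceptor_to_donor"))
    check_number(get(nm), nm, lower = 0, upper = 1, strict_upper = TRUE)
  for (nm in c("background_donor", "background_fret", "background_acceptor",
               "background_mrfp", "donor_expression_sd",
               "mrfp_mean_pos", "mrfp_mean_neg"))
    check_number(get(nm), nm, lower = 0)
  check_number(donor_expression_mean, "donor_expression_mean", lower = 0,
               strict_lower = TRUE)
  check_number(acceptor_level, "acceptor_level", lower = 0,
               strict_lower = TRUE)
  if (!is.list(noise_model) ||
      !noise_model$type %in% c("none", "gaussian", "poisson"))
    stop_invalid("'noise_model' must have type none, gaussian or poisson")
  if (noise_model$type == "gaussian")
    check_number(noise_model$sd_frac, "noise_model$sd_frac", lower = 0)
  if (noise_model$type == "poisson")
    check_number(noise_model$gain, "noise_model$gain", lower = 0,
                 strict_lower = TRUE)
  structure(list(bt_donor_to_fret = bt_donor_to_fret,
                 bt_acceptor_to_fret = bt_acceptor_to_fret,
                 bt_acceptor_to_donor = bt_acceptor_to_donor,
                 background_donor = background_donor,
                 background_fret = background_fret,
                 background_acceptor = background_acceptor,
                 background_mrfp = background_mrfp,
                 donor_expression_mean = donor_expression_mean,
                 donor_expression_sd = donor_expression_sd,
                 acceptor_level = acceptor_level,
                 noise_model = noise_model,
                 mrfp_mean_pos = mrfp_mean_pos,
                 mrfp_mean_neg = mrfp_mean_neg),
            class = "optical_params")
}

apply_noise <- function(x, noise_model) {
  switch(noise_model$type,
         none = x,
         gaussian = x + stats::rnorm(length(x), 0,
                                     abs(x) * noise_model$sd_frac),
         poisson = stats::rpois(length(x),
                                pmax(x, 0) / noise_model$gain) *
           noise_model$gain)
}

#' Render observed FRET channel intensities from a true ratio trace
#'
#' @param true_ratio per-cycle true FRET/donor ratio (numeric vector, > 0).
#' @param optics an [optical_params()].
#' @param seed integer seed (used for expression level and noise).
#' @param cell_id identifier written into the output table.
#' @param time_s optional per-cycle acquisition times (defaults to
#'   3 s cycles).
#' @param mrfp_status "pos" or "neg": which mRFP population the cell
#'   belongs to.
#' @return a data.frame intensity trace with columns cell_id, cycle,
#'   time_s, donor, fret, acceptor, mrfp, bg_donor, bg_fret, bg_acceptor,
#'   bg_mrfp, plus attribute `true_ratio`.
#' @export
render_fret_channels <- function(true_ratio, optics = optical_params(),
                                 seed = 1L, cell_id = "cell001",
                                 time_s = NULL,
                                 mrfp_status = c("neg", "pos")) {
  stopifnot(inherits(optics, "optical_params"))
  mrfp_status <- match.arg(mrfp_status)
  if (any(!is.finite(true_ratio)) || any(true_ratio <= 0))
    stop_invalid("'true_ratio' must be finite and > 0")
  n <- length(true_ratio)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) * 3
  with_seed(seed, {
    d_pure <- max(stats::rnorm(1, optics$donor_expression_mean,
                               optics$donor_expression_sd),
                  optics$donor_expression_mean * 0.1)
    a_pure <- optics$acceptor_level * d_pure
    s_pure <- true_ratio * d_pure
    donor <- d_pure + a_pure * optics$bt_acceptor_to_donor +
      optics$background_donor
    acceptor <- a_pure + optics$background_acceptor
    fret <- s_pure +
      (donor - optics$background_donor) * optics$bt_donor_to_fret +
      (acceptor - optics$background_acceptor) * optics$bt_acceptor_to_fret +
      optics$background_fret
    mrfp_level <- if (mrfp_status == "pos") optics$mrfp_mean_pos else
      optics$mrfp_mean_neg
    mrfp <- mrfp_level + optics$background_mrfp
    donor <- apply_noise(rep_len(donor, n), optics$noise_model)
    fret <- apply_noise(fret, optics$noise_model)
    acceptor <- apply_noise(rep_len(acceptor, n), optics$noise_model)
    mrfp <- apply_noise(rep_len(mrfp, n), optics$noise_model)
    out <- data.frame(cell_id = cell_id, cycle = seq_len(n),
                      time_s = time_s, donor = donor, fret = fret,
                      acceptor = acceptor, mrfp = mrfp,
                      bg_donor = optics$background_donor,
                      bg_fret = optics$background_fret,
                      bg_acceptor = optics$background_acceptor,
                      bg_mrfp = optics$background_mrfp)
    attr(out, "true_ratio") <- true_ratio
    out
  })
}

#' Render single-fluorophore control traces for bleed-through calibration
#'
#' Emulates cells expressing only the donor (CFP) or only the acceptor
#' (YFP) fluorophore, used to measure the crosstalk coefficients.
#'
#' @param kind "donor" or "acceptor".
#' @param optics an [optical_params()].
#' @param n_cells number of control cells.
#' @param n_cycles imaging cycles per cell.
#' @param seed integer seed.
#' @return a data.frame in the intensity-trace schema.
#' @export
render_control_channels <- function(kind = c("donor", "acceptor"),
                                    optics = optical_params(),
                                    n_cells = 10L, n_cycles = 20L,
                                    seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(optics, "optical_params"))
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  n_cycles <- check_count(n_cycles, "n_cycles", lower = 1L)
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    out[[i]] <- with_seed(derive_seed(seed, i), {
      lvl <- max(stats::rnorm(1, optics$donor_expression_mean,
                              optics$donor_expression_sd),
                 optics$donor_expression_mean * 0.1)
      if (kind == "donor") {
        donor <- lvl + optics$background_donor
        fret <- lvl * optics$bt_donor_to_fret + optics$background_fret
        acceptor <- rep(optics$background_acceptor, 1)
      } else {
        donor <- lvl * optics$bt_acceptor_to_donor + optics$background_donor
        fret <- lvl * optics$bt_acceptor_to_fret + optics$background_fret
        acceptor <- lvl + optics$background_acceptor
      }
      data.frame(cell_id = sprintf("%s_ctrl%03d", kind, i),
                 cycle = seq_len(n_cycles),
                 time_s = (seq_len(n_cycles) - 1) * 3,
                 donor = apply_noise(rep_len(donor, n_cycles),
                                     optics$noise_model),
                 fret = apply_noise(rep_len(fret, n_cycles),
                                    optics$noise_model),
                 acceptor = apply_noise(rep_len(acceptor, n_cycles),
                                        optics$noise_model),
                 mrfp = optics$background_mrfp,
                 bg_donor = optics$background_donor,
                 bg_fret = optics$background_fret,
                 bg_acceptor = optics$background_acceptor,
                 bg_mrfp = optics$background_mrfp)
    })
  }
  do.call(rbind, out)
}
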