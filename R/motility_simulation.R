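# Generator of cell-level mean-speed datasets with subject random
# intercepts and the factorial design of the motility experiments:
# siRNA (NC / siACBD5) and nocodazole (DMSO / noco) vary between subjects,
# the stimulation step (EGTA / histamine / Ca) is repeated within each
# subject (cell).

#' Ground truth for the mixed-model generator
#'
#' Defaults emulate the motility study conditions: a control mean speed
#' near 390 nm/s, a large positive knock-down effect, a positive
#' microtubule-disruption effect, equal negative effects of both
#' stimulation steps, no interactions, and 3 independent experiments times
#' 9-10 cells per between-subject condition with all three stimulation
#' levels observed per cell.
#'
#' @param beta named numeric vector of fixed effects on the treatment-coded
#'   scale (reference levels NC, DMSO, EGTA). Recognised names:
#'   `(Intercept)`, `sirnasiACBD5`, `noconoco`, `stimulationhistamine`,
#'   `stimulationCa`, and the interaction terms formed from them with `:`.
#'   Unlisted terms are 0.
#' @param sigma_subject between-subject (cell) sd, nm/s (default 60).
#' @param sigma_resid residual sd, nm/s (default 50).
#' @param n_subjects_per_condition subjects per siRNA x nocodazole cell
#'   (default 10).
#' @param n_experiments independent experiments the subjects are spread
#'   over (default 3; recorded as a column, not used in generation).
#' @return an object of class `lmm_truth`.
#' @export
lmm_truth <- function(beta = c(`(Intercept)` = 390,
                               sirnasiACBD5 = 139.1,
                               noconoco = 95.7,
                               stimulationhistamine = -69.7,
                               stimulationCa = -69.7),
                      sigma_subject = 60, sigma_resid = 50,
                      n_subjects_per_condition = 10L,
                      n_experiments = 3L) {
  if (is.null(names(beta)) || !"(Intercept)" %in% names(beta))
    stop_invalid("'beta' must be named and include '(Intercept)'")
  check_number(sigma_subject, "sigma_subject", lower = 0)
  check_number(sigma_resid, "sigma_resid", lower = 0, strict_lower = TRUE)
  n_subjects_per_condition <- check_count(n_subjects_per_condition,
                                          "n_subjects_per_condition",
                                          lower = 1L)
  n_experiments <- check_count(n_experiments, "n_experiments", lower = 1L)
  structure(list(beta = beta, sigma_subject = sigma_subject,
                 sigma_resid = sigma_resid,
                 n_subjects_per_condition = n_subjects_per_condition,
                 n_experiments = n_experiments), class = "lmm_truth")
}

#' Factor columns of a motility record table, with reference levels set
#' @keywords internal
motility_factor_levels <- list(sirna = c("NC", "siACBD5"),
                               noco = c("DMSO", "noco"),
                               stimulation = c("EGTA", "histamine", "Ca"))

#' Simulate a cell-level mean-speed dataset from known mixed-model truth
#'
#' y = X beta + b_subject + eps with b ~ N(0, sigma_subject^2) and
#' eps ~ N(0, sigma_resid^2). Each subject contributes one observation per
#' stimulation level; siRNA and nocodazole are between-subject.
#'
#' @param truth an [lmm_truth()].
#' @param seed integer seed.
#' @return a data.frame with columns subject, experiment, sirna, noco,
#'   stimulation, mean_speed_nm_s; the design matrix term names match
#'   `names(truth$beta)`.
#' @export
simulate_motility_dataset <- function(truth = lmm_truth(), seed = 1L) {
  stopifnot(inherits(truth, "lmm_truth"))
  if (truth$n_subjects_per_condition < 1L)
    stop_invalid("every between-subject condition needs at least one subject")
  lv <- motility_factor_levels
  between <- expand.grid(sirna = lv$sirna, noco = lv$noco,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- list()
  subj_i <- 0L
  for (b in seq_len(nrow(between))) {
    for (s in seq_len(truth$n_subjects_per_condition)) {
      subj_i <- subj_i + 1L
      rows[[subj_i]] <- data.frame(
        subject = sprintf("S%03d", subj_i),
        experiment = sprintf("E%d", ((subj_i - 1L) %% truth$n_experiments) + 1L),
        sirna = between$sirna[b], noco = between$noco[b],
        stimulation = lv$stimulation)
    }
  }
  df <- do.call(rbind, rows)
  for (nm in names(lv)) df[[nm]] <- factor(df[[nm]], levels = lv[[nm]])
  X <- stats::model.matrix(~ sirna * noco * stimulation, df)
  unknown <- setdiff(names(truth$beta), colnames(X))
  if (length(unknown))
    stop_invalid("unknown beta term(s): %s", paste(unknown, collapse = ", "))
  beta_full <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta_full[names(truth$beta)] <- truth$beta
  mu <- drop(X %*% beta_full)
  n_subj <- subj_i
  b_subj <- with_seed(derive_seed(seed, 1L),
                      stats::rnorm(n_subj, 0, truth$sigma_subject))
  eps <- with_seed(derive_seed(seed, 2L),
                   stats::rnorm(nrow(df), 0, truth$sigma_resid))
  subj_index <- as.integer(factor(df$subject, levels = unique(df$subject)))
  df$mean_speed_nm_s <- mu + b_subj[subj_index] + eps
  df
}
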