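# Random-intercept linear mixed model, estimated by REML, written directly
# against the model's closed-form structure. With a single grouping factor
# the marginal covariance is block diagonal, V = sigma_e^2 (I + lambda Z Z')
# with lambda = sigma_b^2 / sigma_e^2, and each block inverse is
# I - lambda/(1 + lambda n_j) J. The REML criterion is profiled over
# sigma_e^2 and minimised over lambda >= 0 by bounded one-dimensional
# search; beta follows by generalized least squares. Satterthwaite degrees
# of freedom use the variance of the variance-component estimates from the
# numerically differentiated REML information matrix.

# Precomputed sufficient statistics for one design
lmm_suffstat <- function(y, X, group) {
  g <- as.integer(factor(group, levels = unique(group)))
  nj <- as.numeric(tabulate(g))
  Sx <- rowsum(X, g, reorder = FALSE)
  Sy <- as.numeric(rowsum(y, g, reorder = FALSE))
  list(n = length(y), p = ncol(X), XtX = crossprod(X),
       Xty = crossprod(X, y)[, 1], yty = sum(y * y),
       Sx = Sx, Sy = Sy, nj = nj, J = length(nj))
}

# GLS pieces at a given lambda
lmm_parts <- function(ss, lambda) {
  cj <- lambda / (1 + lambda * ss$nj)
  A <- ss$XtX - crossprod(ss$Sx * sqrt(cj))
  bvec <- ss$Xty - crossprod(ss$Sx, ss$Sy * cj)[, 1]
  R <- chol(A)
  beta <- backsolve(R, backsolve(R, bvec, transpose = TRUE))
  quad <- ss$yty - sum(cj * ss$Sy^2) - sum(beta * bvec)
  list(A = A, R = R, beta = beta, quad = max(quad, 1e-300),
       logdetA = 2 * sum(log(diag(R))),
       logdetV0 = sum(log1p(lambda * ss$nj)))
}

# REML criterion profiled over sigma_e^2 (to be minimised over lambda)
lmm_profile_obj <- function(ss, lambda) {
  pr <- lmm_parts(ss, lambda)
  pr$logdetV0 + pr$logdetA + (ss$n - ss$p) * log(pr$quad)
}

# -2 * restricted log-likelihood at (sigma2_b, sigma2_e)
lmm_neg2reml <- function(ss, sigma2_b, sigma2_e) {
  pr <- lmm_parts(ss, sigma2_b / sigma2_e)
  (ss$n - ss$p) * log(2 * pi) + (ss$n - ss$p) * log(sigma2_e) +
    pr$logdetV0 + pr$logdetA + pr$quad / sigma2_e
}

# coefficient covariance at (sigma2_b, sigma2_e)
lmm_vcov_beta <- function(ss, sigma2_b, sigma2_e) {
  pr <- lmm_parts(ss, sigma2_b / sigma2_e)
  sigma2_e * chol2inv(pr$R)
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Fits `response ~ fixed effects + (1 | subject)` with treatment
#' (reference-level) coding. For the motility design the references are
#' NC, DMSO and EGTA, so the intercept is the mean speed of the control
#' conditions. Per-coefficient degrees of freedom use Satterthwaite's
#' approximation; 95\% confidence intervals are Wald intervals
#' beta +/- t(df) * se.
#'
#' @param records data.frame of observations.
#' @param fixed one-sided or two-sided formula of fixed effects; default
#'   `mean_speed_nm_s ~ sirna * noco * stimulation`.
#' @param subject name of the grouping column (default "subject").
#' @return an object of class `lmm_fit` with elements `coefficients`
#'   (term, beta, se, df, t, p, ci_lo, ci_hi), `sigma2_subject`,
#'   `sigma2_resid`, `lambda`, `reml_criterion`, `vcov_beta`, `n`,
#'   `n_subjects`, `formula`, and internals used by [contrast_f_test()].
#' @export
fit_random_intercept_lmm <- function(records,
                                     fixed = mean_speed_nm_s ~
                                       sirna * noco * stimulation,
                                     subject = "subject") {
  if (!subject %in% names(records))
    stop_invalid("no grouping column '%s' in records", subject)
  for (nm in intersect(names(motility_factor_levels), names(records)))
    if (!is.factor(records[[nm]]))
      records[[nm]] <- factor(records[[nm]],
                              levels = motility_factor_levels[[nm]])
  mf <- stats::model.frame(fixed, records)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(fixed), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_invalid("design matrix is rank deficient; aliased term(s): %s",
                 paste(aliased, collapse = ", "))
  }
  group <- records[[subject]][as.integer(rownames(mf))]
  if (length(unique(group)) < 2L)
    stop_invalid("need at least 2 subjects")
  ss <- lmm_suffstat(y, X, group)
  all_singleton <- all(ss$nj == 1)
  if (all_singleton)
    warning("all subjects have a single observation; sigma2_subject is not identifiable and is set to 0",
            call. = FALSE)

  if (all_singleton) {
    lambda <- 0
  } else {
    # coarse deterministic grid, then bounded refinement around the best
    grid <- c(0, 10^seq(-4, 4, by = 0.25))
    fg <- vapply(grid, function(l) lmm_profile_obj(ss, l), numeric(1))
    k <- which.min(fg)
    lo <- grid[max(k - 1L, 1L)]
    hi <- grid[min(k + 1L, length(grid))]
    if (lo == hi) hi <- lo + 1
    opt <- stats::optimize(function(l) lmm_profile_obj(ss, l),
                           interval = c(lo, hi), tol = 1e-10)
    lambda <- if (lmm_profile_obj(ss, 0) <= opt$objective) 0 else
      opt$minimum
  }
  pr <- lmm_parts(ss, lambda)
  sigma2_e <- pr$quad / (ss$n - ss$p)
  sigma2_b <- lambda * sigma2_e
  beta <- stats::setNames(pr$beta, colnames(X))
  Cb <- sigma2_e * chol2inv(pr$R)
  dimnames(Cb) <- list(colnames(X), colnames(X))
  reml_crit <- lmm_neg2reml(ss, sigma2_b, sigma2_e)
  boundary <- sigma2_b < 1e-10 * sigma2_e

  # Satterthwaite machinery: gradient of vcov(beta) wrt the variance
  # components, and the asymptotic covariance of the component estimates
  theta <- c(sigma2_b, sigma2_e)
  if (boundary) {
    Gk <- NULL; A_vc <- NULL
  } else {
    h <- pmax(abs(theta) * 1e-4, 1e-8)
    Gk <- lapply(1:2, function(k) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h[k]; tm[k] <- max(tm[k] - h[k], 1e-12)
      (lmm_vcov_beta(ss, tp[1], tp[2]) -
         lmm_vcov_beta(ss, tm[1], tm[2])) / (tp[k] - tm[k])
    })
    f2 <- function(th) lmm_neg2reml(ss, max(th[1], 1e-12), th[2])
    H <- matrix(0, 2, 2)
    for (k in 1:2) for (l in 1:2) {
      if (l < k) { H[k, l] <- H[l, k]; next }
      tpp <- theta + h * ((1:2) == k) + h * ((1:2) == l)
      tpm <- theta + h * ((1:2) == k) - h * ((1:2) == l)
      tmp <- theta - h * ((1:2) == k) + h * ((1:2) == l)
      tmm <- theta - h * ((1:2) == k) - h * ((1:2) == l)
      H[k, l] <- (f2(tpp) - f2(tpm) - f2(tmp) + f2(tmm)) /
        (4 * h[k] * h[l])
    }
    A_vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(A_vc) && any(!is.finite(A_vc))) A_vc <- NULL
  }
  resid_df <- ss$n - ss$p

  satt_df_vec <- function(lmat) {
    # one df per row of lmat (each row a coefficient-space vector)
    apply(lmat, 1, function(l) {
      f <- drop(l %*% Cb %*% l)
      if (boundary || is.null(A_vc)) return(resid_df)
      g <- vapply(Gk, function(G) drop(l %*% G %*% l), numeric(1))
      den <- drop(t(g) %*% A_vc %*% g)
      if (den <= 0) return(resid_df)
      df <- 2 * f^2 / den
      if (!is.finite(df) || df <= 0) resid_df else df
    })
  }
  se <- sqrt(diag(Cb))
  df <- satt_df_vec(diag(ss$p))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tcrit <- stats::qt(0.975, df)
  coefs <- data.frame(term = colnames(X), beta = unname(beta),
                      se = se, df = df, t = unname(tval), p = unname(pval),
                      ci_lo = unname(beta - tcrit * se),
                      ci_hi = unname(beta + tcrit * se),
                      row.names = NULL)
  structure(list(coefficients = coefs, sigma2_subject = sigma2_b,
                 sigma2_resid = sigma2_e, lambda = lambda,
                 reml_criterion = reml_crit, vcov_beta = Cb,
                 n = ss$n, n_subjects = ss$J, resid_df = resid_df,
                 formula = fixed, subject = subject,
                 boundary = boundary,
                 internals = list(ss = ss, Gk = Gk, A_vc = A_vc)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept linear mixed model (REML)\n")
  cat(sprintf("  %d observations, %d subjects\n", x$n, x$n_subjects))
  cat(sprintf("  sigma2_subject = %.4g, sigma2_resid = %.4g\n",
              x$sigma2_subject, x$sigma2_resid))
  cat("Fixed effects (Satterthwaite df, Wald 95% CI):\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' F-test of a linear contrast of the fixed effects
#'
#' Tests L beta = 0 with F = (L beta)' (L C L')^{-1} (L beta) / q,
#' q = rank(L). The denominator degrees of freedom follow Satterthwaite's
#' method applied to the eigen-decomposition of L C L'.
#'
#' @param fit an [fit_random_intercept_lmm()] result.
#' @param contrast_rows numeric matrix (or vector) in coefficient space;
#'   columns must match the fit's coefficients.
#' @param description optional label carried into the result.
#' @return a data.frame row: description, F, df_num, df_den, p.
#' @export
contrast_f_test <- function(fit, contrast_rows, description = "") {
  stopifnot(inherits(fit, "lmm_fit"))
  L <- rbind(contrast_rows)
  if (ncol(L) != nrow(fit$coefficients))
    stop_invalid("contrast has %d columns; fit has %d coefficients",
                 ncol(L), nrow(fit$coefficients))
  q <- qr(L)$rank
  if (q == 0L) stop_invalid("contrast matrix has rank zero")
  if (q < nrow(L)) {
    # reduce to a full-row-rank basis of the same row space
    L <- t(qr.Q(qr(t(L)))[, seq_len(q), drop = FALSE])
  }
  beta <- fit$coefficients$beta
  Cb <- fit$vcov_beta
  M <- L %*% Cb %*% t(L)
  Fval <- drop(t(L %*% beta) %*% solve(M, L %*% beta)) / q
  if (fit$boundary || is.null(fit$internals$A_vc)) {
    df_den <- fit$resid_df
  } else {
    eg <- eigen(M, symmetric = TRUE)
    nus <- numeric(0)
    for (m in seq_len(q)) {
      if (eg$values[m] <= 0) next
      lm_ <- drop(t(eg$vectors[, m]) %*% L)
      g <- vapply(fit$internals$Gk,
                  function(G) drop(lm_ %*% G %*% lm_), numeric(1))
      den <- drop(t(g) %*% fit$internals$A_vc %*% g)
      nus <- c(nus, if (den <= 0) fit$resid_df else
        2 * eg$values[m]^2 / den)
    }
    nus <- nus[is.finite(nus) & nus > 0]
    E <- sum(nus[nus > 2] / (nus[nus > 2] - 2))
    df_den <- if (E > q) 2 * E / (E - q) else fit$resid_df
  }
  p <- stats::pf(Fval, q, df_den, lower.tail = FALSE)
  data.frame(description = description, F = Fval, df_num = q,
             df_den = df_den, p = p)
}

# contrast matrix selecting a set of coefficients by name
coef_selector <- function(fit, terms) {
  nm <- fit$coefficients$term
  idx <- match(terms, nm)
  if (anyNA(idx))
    stop_invalid("term(s) not in model: %s",
                 paste(terms[is.na(idx)], collapse = ", "))
  L <- matrix(0, length(idx), length(nm))
  L[cbind(seq_along(idx), idx)] <- 1
  colnames(L) <- nm
  L
}

model_terms <- function(formula) attr(stats::terms(formula), "term.labels")

#' Stepwise backward reduction of the three-factor motility model
#'
#' Starting from the full interaction model
#' `mean_speed_nm_s ~ sirna * noco * stimulation` with a subject random
#' intercept, the procedure (1) jointly F-tests the three-way interaction
#' terms and drops them if p >= alpha; (2) jointly tests and drops the
#' two-way interactions involving nocodazole; (3) jointly tests and drops
#' the siRNA x stimulation interaction; (4) tests equality of the
#' histamine and Ca coefficients and, if p >= alpha, pools the two
#' stimulation steps into one "stimulated" level; (5) fits the final model
#' and reports a joint F-test of every dropped direction against the full
#' model. Every step records its F-test whether or not the drop occurs.
#'
#' @param records motility record table (see
#'   [simulate_motility_dataset()]).
#' @param alpha drop threshold (default 0.05).
#' @param subject grouping column (default "subject").
#' @return an object of class `reduction_trace`: list with `steps`
#'   (data.frame), `final_label`, `final_fit`, `full_fit`, `joint_test`.
#' @export
backward_reduce <- function(records, alpha = 0.05, subject = "subject") {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  full_formula <- mean_speed_nm_s ~ sirna * noco * stimulation
  fit_full <- fit_random_intercept_lmm(records, full_formula, subject)
  steps <- list(); dropped_terms <- character(0)
  note_step <- function(step, description, test, decision, terms_after) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, description = description,
      F = if (is.null(test)) NA_real_ else test$F,
      df_num = if (is.null(test)) NA_real_ else test$df_num,
      df_den = if (is.null(test)) NA_real_ else test$df_den,
      p = if (is.null(test)) NA_real_ else test$p,
      decision = decision,
      terms_after = paste(terms_after, collapse = " + "))
  }
  current_formula <- full_formula
  current_fit <- fit_full

  refit <- function(formula) fit_random_intercept_lmm(records, formula,
                                                      subject)
  drop_set <- function(formula, terms) {
    stats::update(formula, paste("~ . -", paste(terms, collapse = " - ")))
  }
  coef_names_of <- function(fit, pattern)
    grep(pattern, fit$coefficients$term, value = TRUE)

  # steps 1-3: term groups tested and dropped in order
  groups <- list(
    list(step = 1L, pattern = "^sirna.*:noco.*:stimulation",
         terms = "sirna:noco:stimulation",
         description = "three-way interaction siRNA:noco:stimulation"),
    list(step = 2L, pattern = "(^sirna[^:]*:noco[^:]*$)|(^noco[^:]*:stimulation[^:]*$)",
         terms = c("sirna:noco", "noco:stimulation"),
         description = "two-way interactions involving nocodazole"),
    list(step = 3L, pattern = "^sirna[^:]*:stimulation[^:]*$",
         terms = "sirna:stimulation",
         description = "siRNA:stimulation interaction"))
  for (gset in groups) {
    present <- intersect(gset$terms, model_terms(current_formula))
    if (!length(present)) {
      note_step(gset$step, gset$description, NULL, "skipped: terms absent",
                model_terms(current_formula))
      next
    }
    cn <- coef_names_of(current_fit, gset$pattern)
    test <- contrast_f_test(current_fit, coef_selector(current_fit, cn),
                            gset$description)
    # marginality: a term cannot be dropped under a retained higher-order
    # interaction that contains it
    higher <- setdiff(grep(":", model_terms(current_formula), value = TRUE),
                      present)
    blocked <- any(vapply(present, function(lo) {
      lof <- strsplit(lo, ":", fixed = TRUE)[[1]]
      any(vapply(higher, function(hi)
        all(lof %in% strsplit(hi, ":", fixed = TRUE)[[1]]), logical(1)))
    }, logical(1)))
    if (test$p >= alpha && blocked) {
      note_step(gset$step, gset$description, test,
                "retain: contained in a retained higher-order interaction",
                model_terms(current_formula))
      next
    }
    if (test$p >= alpha) {
      current_formula <- drop_set(current_formula, present)
      current_fit <- refit(current_formula)
      dropped_terms <- c(dropped_terms, present)
      note_step(gset$step, gset$description, test, "drop",
                model_terms(current_formula))
    } else {
      note_step(gset$step, gset$description, test, "retain",
                model_terms(current_formula))
    }
  }

  # step 4: equality of the two stimulation steps (only meaningful once no
  # interaction involves stimulation)
  pooled <- FALSE
  stim_in_interaction <- any(grepl("stimulation",
                                   grep(":", model_terms(current_formula),
                                        value = TRUE)))
  hist_i <- match("stimulationhistamine", current_fit$coefficients$term)
  ca_i <- match("stimulationCa", current_fit$coefficients$term)
  if (!stim_in_interaction && !is.na(hist_i) && !is.na(ca_i)) {
    l <- rep(0, nrow(current_fit$coefficients))
    l[hist_i] <- 1; l[ca_i] <- -1
    test <- contrast_f_test(current_fit, l,
                            "equality of histamine and Ca effects")
    if (test$p >= alpha) {
      records$stimulated <- factor(
        ifelse(records$stimulation == "EGTA", "EGTA", "stimulated"),
        levels = c("EGTA", "stimulated"))
      current_formula <- mean_speed_nm_s ~ sirna + noco + stimulated
      current_fit <- refit(current_formula)
      pooled <- TRUE
      note_step(4L, "equality of histamine and Ca effects", test,
                "pool stimulation levels", model_terms(current_formula))
    } else {
      note_step(4L, "equality of histamine and Ca effects", test,
                "keep separate levels", model_terms(current_formula))
    }
  } else {
    note_step(4L, "equality of histamine and Ca effects", NULL,
              "skipped: stimulation still in an interaction",
              model_terms(current_formula))
  }

  # step 5: joint test of every dropped direction against the full model
  drop_rows <- NULL
  if (length(dropped_terms)) {
    # coefficient columns of the full model belonging to dropped terms
    asgn <- attr(stats::model.matrix(
      stats::terms(full_formula),
      stats::model.frame(full_formula, transform_records(records))),
      "assign")
    term_labels <- model_terms(full_formula)
    coef_term <- c("(Intercept)", term_labels)[asgn + 1L]
    sel <- which(coef_term %in% dropped_terms)
    drop_rows <- coef_selector(fit_full, fit_full$coefficients$term[sel])
  }
  if (pooled) {
    l <- rep(0, nrow(fit_full$coefficients))
    l[match("stimulationhistamine", fit_full$coefficients$term)] <- 1
    l[match("stimulationCa", fit_full$coefficients$term)] <- -1
    drop_rows <- rbind(drop_rows, l)
  }
  joint <- if (is.null(drop_rows)) NULL else
    contrast_f_test(fit_full, drop_rows,
                    "final vs full: all dropped directions")
  if (!is.null(joint))
    note_step(5L, "joint test of final vs full model", joint,
              "reported", model_terms(current_formula))

  final_label <- if (pooled) "histamine + Ca combined" else
    if (!any(grepl(":", model_terms(current_formula)))) "no interactions"
    else "full interaction"
  structure(list(steps = do.call(rbind, steps), final_label = final_label,
                 final_fit = current_fit, full_fit = fit_full,
                 joint_test = joint, alpha = alpha),
            class = "reduction_trace")
}

# factor coercion shared with fit_random_intercept_lmm
transform_records <- function(records) {
  for (nm in intersect(names(motility_factor_levels), names(records)))
    if (!is.factor(records[[nm]]))
      records[[nm]] <- factor(records[[nm]],
                              levels = motility_factor_levels[[nm]])
  records
}

#' @export
print.reduction_trace <- function(x, ...) {
  cat(sprintf("Stepwise backward model reduction (alpha = %g)\n", x$alpha))
  print(x$steps[, c("step", "description", "F", "df_num", "df_den", "p",
                    "decision")], digits = 3, row.names = FALSE)
  cat(sprintf("Final model: %s\n", x$final_label))
  invisible(x)
}
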