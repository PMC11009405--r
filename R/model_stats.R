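# Trial-level inferential layer: linear mixed-effects models (lme4
# backend) with the factor structures used throughout the analysis,
# Bonferroni post hoc contrasts built from the fixed-effect covariance,
# Spearman correlations, effect-size utilities, and exclusion filters.

#' Specify a mixed model
#'
#' @param dependent name of the dependent column.
#' @param fixed character vector of fixed-effect terms (factors and/or
#'   covariates); interactions via `"a:b"` or use `interactions = TRUE`
#'   to cross all listed factors.
#' @param random_slope optional continuous covariate entered as a
#'   per-subject random slope in addition to the random intercept.
#' @param interactions cross all fixed terms (`a * b * ...`).
#' @return a `model_spec` list.
#' @export
model_spec <- function(dependent, fixed, random_slope = NULL,
                       interactions = TRUE) {
  structure(list(dependent = dependent, fixed = fixed,
                 random_slope = random_slope,
                 interactions = interactions),
            class = "model_spec")
}

#' Fit a linear mixed-effects model
#'
#' REML fit (lme4) of the declared structure with a per-subject random
#' intercept (plus optional random slope). Fixed-effect p-values use the
#' Wald normal approximation (no Satterthwaite backend is available in the
#' target library); pairwise post hoc contrasts over requested factors are
#' Bonferroni-adjusted. Singular fits with a random slope are refitted
#' without the slope and flagged.
#'
#' @param data tidy trial table (one row per trial x interval); must
#'   contain a `subject` column.
#' @param spec a [model_spec()].
#' @param posthoc optional character vector of factor names: all pairwise
#'   contrasts of their level combinations (averaged over the remaining
#'   factors) are tested.
#' @return a `model_result`: `coefficients` (estimate, SE, z, p),
#'   `contrasts`, `fit`, `converged`, `singular`, `n_used`, `n_dropped`.
#' @export
fit_mixed_model <- function(data, spec, posthoc = NULL) {
  stopifnot(inherits(spec, "model_spec"), "subject" %in% names(data))
  if (length(unique(data$subject)) < 5)
    warning("fewer than 5 subjects")
  use <- stats::complete.cases(
    data[, c(spec$dependent, spec$fixed, "subject"), drop = FALSE])
  n_dropped <- sum(!use)
  d <- data[use, , drop = FALSE]
  for (f in spec$fixed)
    if (is.character(d[[f]]) || is.logical(d[[f]]))
      d[[f]] <- factor(d[[f]])
  fixed_part <- paste(spec$fixed,
                      collapse = if (spec$interactions) " * " else " + ")
  ran_part <- if (is.null(spec$random_slope)) "(1 | subject)" else
    sprintf("(1 + %s | subject)", spec$random_slope)
  form <- stats::as.formula(
    paste(spec$dependent, "~", fixed_part, "+", ran_part))
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  refitted <- FALSE
  if (singular && !is.null(spec$random_slope)) {
    form <- stats::as.formula(
      paste(spec$dependent, "~", fixed_part, "+ (1 | subject)"))
    fit <- lme4::lmer(form, data = d, REML = TRUE)
    singular <- lme4::isSingular(fit)
    refitted <- TRUE
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z),
                      p = 2 * stats::pnorm(-abs(unname(z))),
                      ci_lo = unname(beta - 1.96 * se),
                      ci_hi = unname(beta + 1.96 * se))
  contrasts <- if (!is.null(posthoc))
    pairwise_contrasts(fit, d, posthoc, spec) else NULL
  structure(list(coefficients = coefs, contrasts = contrasts, fit = fit,
                 converged = length(fit@optinfo$conv$lme4) == 0,
                 singular = singular, slope_dropped = refitted,
                 n_used = nrow(d), n_dropped = n_dropped,
                 formula = form),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> ", deparse(x$formula), "\n", sep = "")
  print(x$coefficients, digits = 4)
  if (!is.null(x$contrasts)) {
    cat("post hoc (Bonferroni over", nrow(x$contrasts), "contrasts):\n")
    print(x$contrasts, digits = 4)
  }
  invisible(x)
}

# All pairwise contrasts between the level combinations of `factors`,
# averaged over the remaining model factors (cell means on the model
# matrix), Wald z tests, Bonferroni-adjusted.
pairwise_contrasts <- function(fit, data, factors, spec) {
  all_terms <- spec$fixed
  grids <- lapply(all_terms, function(f) {
    if (is.factor(data[[f]])) levels(data[[f]]) else mean(data[[f]])
  })
  names(grids) <- all_terms
  grid <- expand.grid(grids, stringsAsFactors = FALSE)
  for (f in all_terms)
    if (is.factor(data[[f]]))
      grid[[f]] <- factor(grid[[f]], levels = levels(data[[f]]))
  X <- stats::model.matrix(stats::delete.response(stats::terms(
    lme4::nobars(stats::formula(fit)))), grid)
  key <- do.call(paste, c(grid[factors], sep = "."))
  cells <- unique(key)
  M <- t(vapply(cells, function(cl) colMeans(X[key == cl, , drop = FALSE]),
                numeric(ncol(X))))
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  pairs <- utils::combn(length(cells), 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    cvec <- M[pairs[1, j], ] - M[pairs[2, j], ]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    z <- est / se
    data.frame(contrast = paste(cells[pairs[1, j]], "-", cells[pairs[2, j]]),
               estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  out$p_adj <- pmin(1, out$p * m)
  rownames(out) <- NULL
  out
}

#' Spearman correlations with Bonferroni correction
#'
#' One rank correlation per family (e.g. interval x drawing condition),
#' adjusted over the number of families tested.
#'
#' @param pairs named list of data.frames with columns `x` and `y`
#'   (complete pairs; e.g. per-subject off-on burst-amplitude change vs
#'   clinical limb-score change).
#' @param min_n minimal complete pairs per family.
#' @return data.frame with `family`, `n`, `rho`, `p`, `p_adj`.
#' @export
spearman_correlations <- function(pairs, min_n = 5) {
  m <- length(pairs)
  out <- lapply(names(pairs), function(nm) {
    d <- pairs[[nm]]
    d <- d[stats::complete.cases(d[, c("x", "y")]), , drop = FALSE]
    if (nrow(d) < min_n)
      stop("family '", nm, "' has fewer than ", min_n, " complete pairs")
    if (length(unique(d$x)) < 2 || length(unique(d$y)) < 2)
      return(data.frame(family = nm, n = nrow(d), rho = NA_real_,
                        p = NA_real_, flagged = TRUE))
    ct <- suppressWarnings(
      stats::cor.test(d$x, d$y, method = "spearman", exact = FALSE))
    data.frame(family = nm, n = nrow(d), rho = unname(ct$estimate),
               p = ct$p.value, flagged = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' Pooled-SD Cohen's d
#'
#' `d = (m1 - m2) / sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param m1,s1,m2,s2 group means and SDs.
#' @return Cohen's d.
#' @export
pooled_effect_size <- function(m1, s1, m2, s2) {
  stopifnot(s1 > 0, s2 > 0)
  (m1 - m2) / sqrt((s1^2 + s2^2) / 2)
}

#' Confidence interval of a paired mean difference from its t statistic
#'
#' `mean_diff +/- t_{1-alpha/2, n-1} * (mean_diff / t_stat)` -- the
#' standard error is recovered from the printed t value.
#'
#' @param mean_diff paired mean difference.
#' @param t_stat paired t statistic (nonzero).
#' @param n number of pairs.
#' @param level confidence level.
#' @return `c(lo, hi)`.
#' @export
paired_ci <- function(mean_diff, t_stat, n, level = 0.95) {
  stopifnot(n >= 2)
  if (t_stat == 0) stop("t_stat = 0: CI undefined")
  se <- mean_diff / t_stat
  tc <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  c(mean_diff - tc * se, mean_diff + tc * se)
}

#' Exclusion filters for robustness analyses
#'
#' Returns the filtered table plus a per-condition report of removals,
#' mirroring the full / accurate-only / non-tremor analysis versions.
#'
#' @param trials trial table with `inaccurate` and `tremor_subject` flags
#'   plus `drawing` and `stim` columns.
#' @param drop_inaccurate,drop_tremor_subjects filters to apply.
#' @return list with `data` and `report` (counts removed per condition).
#' @export
exclusion_filters <- function(trials, drop_inaccurate = FALSE,
                              drop_tremor_subjects = FALSE) {
  keep <- rep(TRUE, nrow(trials))
  if (drop_inaccurate) keep <- keep & !trials$inaccurate
  if (drop_tremor_subjects) keep <- keep & !trials$tremor_subject
  removed <- trials[!keep, , drop = FALSE]
  report <- if (nrow(removed)) {
    stats::aggregate(list(n_removed = seq_len(nrow(removed))),
                     by = list(drawing = removed$drawing,
                               stim = removed$stim), FUN = length)
  } else data.frame(drawing = character(0), stim = character(0),
                    n_removed = integer(0))
  out <- trials[keep, , drop = FALSE]
  cells <- table(out$drawing, out$stim)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("filter empties design cell ",
         rownames(cells)[empty[1, 1]], "/", colnames(cells)[empty[1, 2]])
  }
  list(data = out, report = report)
}

#' Generate a trial table with known fixed and random effects
#'
#' Model-level generator for calibration and recovery simulations of the
#' mixed-effects layer: log10 velocity with drawing and stimulation main
#' effects, a per-subject random intercept, and Gaussian trial noise.
#'
#' @param n_subjects,trials_per_condition design size.
#' @param intercept grand mean of log10 velocity.
#' @param drawing_effect template-minus-free effect (log10 units).
#' @param stim_effect on-minus-off effect (log10 units).
#' @param subject_sd random-intercept SD; @param resid_sd residual SD.
#' @return tidy data.frame (`subject`, `drawing`, `stim`, `log_velocity`).
#' @export
simulate_trial_table <- function(n_subjects = 19, trials_per_condition = 12,
                                 intercept = 0.9, drawing_effect = -0.18,
                                 stim_effect = 0.05, subject_sd = 0.1,
                                 resid_sd = 0.2) {
  subs <- sprintf("S%02d", seq_len(n_subjects))
  u <- stats::rnorm(n_subjects, 0, subject_sd)
  grid <- expand.grid(subject = subs, drawing = c("free", "template"),
                      stim = c("off", "on"),
                      trial = seq_len(trials_per_condition),
                      stringsAsFactors = FALSE)
  mu <- intercept + u[match(grid$subject, subs)] +
    (grid$drawing == "template") * drawing_effect +
    (grid$stim == "on") * stim_effect
  grid$log_velocity <- mu + stats::rnorm(nrow(grid), 0, resid_sd)
  grid
}
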