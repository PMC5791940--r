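#' Progression-free survival from follow-up dates
#'
#' PFS runs from treatment start to the earliest of cancer progression or
#' all-cause death (event = 1), censored at the last follow-up otherwise.
#' Durations are converted to months at 30.44 days/month.
#'
#' @param start_date treatment start (`Date`).
#' @param progression_date date of progression, or `NA`/`NULL`.
#' @param death_date date of death, or `NA`/`NULL`.
#' @param last_followup date of last follow-up (`Date`); required when no
#'   event occurred.
#' @return List with `pfs_time` (months) and `event` (0/1).
#' @examples
#' compute_pfs(as.Date("2014-01-01"), progression_date = as.Date("2014-05-23"),
#'             last_followup = as.Date("2015-01-01"))
#' @export
compute_pfs <- function(start_date, progression_date = NULL,
                        death_date = NULL, last_followup = NULL) {
  start_date <- as.Date(start_date)
  norm <- function(d) if (is.null(d) || all(is.na(d))) NA else as.Date(d)
  progression_date <- norm(progression_date)
  death_date <- norm(death_date)
  last_followup <- norm(last_followup)
  event_dates <- c(progression_date, death_date)
  event_dates <- event_dates[!is.na(event_dates)]
  all_dates <- c(event_dates, last_followup)
  all_dates <- all_dates[!is.na(all_dates)]
  if (length(all_dates) == 0L)
    stop("need a progression, death, or last follow-up date", call. = FALSE)
  if (any(all_dates < start_date))
    stop("dates precede treatment start", call. = FALSE)
  if (length(event_dates) > 0L) {
    end <- min(event_dates)
    event <- 1L
  } else {
    end <- last_followup
    event <- 0L
  }
  list(pfs_time = as.numeric(end - start_date) / 30.44, event = event)
}

check_records <- function(records, covariates = character(0)) {
  stopifnot(is.data.frame(records))
  need <- c("pfs_time", "event", covariates)
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(records$pfs_time <= 0))
    stop("pfs_time must be positive", call. = FALSE)
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0/1", call. = FALSE)
  if (sum(records$event) < 1)
    stop("no events in the cohort", call. = FALSE)
  invisible(records)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Breslow tie handling, via
#' `survival::coxph`. Covariates must be non-constant columns of `records`.
#'
#' @param records data frame with `pfs_time` (months), `event` (0/1) and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @return An object of class `cox_fit`: list with `model` (the `coxph`
#'   fit), `coefficients` (data frame: term, coef, hr, ci_low, ci_high, p),
#'   `loglik` (log partial likelihood at the optimum), and
#'   `linear_predictor` (per subject).
#' @export
fit_cox <- function(records, covariates) {
  check_records(records, covariates)
  for (cv in covariates) {
    x <- records[[cv]]
    if (is.numeric(x) && length(unique(x)) < 2L)
      stop("covariate '", cv, "' is constant", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(pfs_time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w)))
        stop("Cox fit did not converge (separation?)", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(stats::coef(fit))))
    stop("Cox fit did not converge (separation?)", call. = FALSE)
  sm <- summary(fit)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    coef = sm$coefficients[, "coef"],
    se = sm$coefficients[, "se(coef)"],
    hr = sm$coefficients[, "exp(coef)"],
    ci_low = exp(sm$coefficients[, "coef"] -
                   1.96 * sm$coefficients[, "se(coef)"]),
    ci_high = exp(sm$coefficients[, "coef"] +
                    1.96 * sm$coefficients[, "se(coef)"]),
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL
  )
  structure(list(model = fit, coefficients = coefs,
                 loglik = fit$loglik[length(fit$loglik)],
                 linear_predictor = unname(fit$linear.predictors),
                 covariates = covariates),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

cutoff_result <- function(feature, cutoff, records, fit_row, risk,
                          significant = TRUE, extra = list()) {
  above <- sum(records[[feature]] > cutoff)
  structure(c(list(feature = feature, cutoff = cutoff,
                   n_above = above, n_below = nrow(records) - above,
                   hr = fit_row$hr, ci_low = fit_row$ci_low,
                   ci_high = fit_row$ci_high, p = fit_row$p,
                   risk = risk, significant = significant), extra),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (!x$significant) {
    cat("No significant cutoff for", x$feature, "\n")
  } else {
    cat(sprintf("%s: cutoff %.6g (%d above / %d below), HR %.3g (%.3g-%.3g), P = %.3g [risk: %s]\n",
                x$feature, x$cutoff, x$n_above, x$n_below,
                x$hr, x$ci_low, x$ci_high, x$p, x$risk))
  }
  invisible(x)
}

fit_binary_cox <- function(records, grp) {
  rec <- records
  rec$.grp <- grp
  fit <- tryCatch(
    survival::coxph(survival::Surv(pfs_time, event) ~ .grp, data = rec,
                    ties = "breslow"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  b <- stats::coef(fit)[1]
  se <- sqrt(stats::vcov(fit)[1, 1])
  if (!is.finite(b) || !is.finite(se)) return(NULL)
  data.frame(hr = exp(b), ci_low = exp(b - 1.96 * se),
             ci_high = exp(b + 1.96 * se),
             p = 2 * stats::pnorm(-abs(b / se)))
}

#' Hazard-ratio-maximizing optimal cutoff
#'
#' Exhaustively scans midpoints between sorted unique feature values
#' (keeping both groups at or above `min_group_fraction` of the cohort). At
#' each candidate, a univariate Cox model on the risk-group indicator is
#' fitted; among candidates with Wald P <= `p_threshold`, the one with the
#' largest hazard ratio is returned. For a single binary split on one
#' covariate this scan is equivalent to recursive partitioning and is
#' deterministic.
#'
#' @param records data frame with `pfs_time`, `event` and the feature.
#' @param feature feature column name.
#' @param min_group_fraction minimum fraction of subjects in each group
#'   (default 0.05).
#' @param p_threshold Wald significance threshold (default 0.05).
#' @param risk which side of the cutoff defines the risk group whose hazard
#'   ratio is maximized: `"above"` (default) or `"below"`.
#' @return A `cutoff_result` with `cutoff`, `n_above`, `n_below`, `hr`,
#'   `ci_low`, `ci_high`, `p`. When no candidate reaches `p_threshold`, the
#'   result has `significant = FALSE` and additionally inherits class
#'   `no_significant_cutoff`; numeric fields then describe the best
#'   (non-significant) candidate by hazard ratio.
#' @export
optimal_cutoff <- function(records, feature, min_group_fraction = 0.05,
                           p_threshold = 0.05, risk = c("above", "below")) {
  risk <- match.arg(risk)
  check_records(records, feature)
  x <- records[[feature]]
  ux <- sort(unique(x))
  if (length(ux) < 2L) stop("feature '", feature, "' is constant",
                            call. = FALSE)
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  n <- length(x)
  min_n <- max(1L, ceiling(min_group_fraction * n))
  rows <- vector("list", length(mids))
  for (k in seq_along(mids)) {
    above <- x > mids[k]
    if (sum(above) < min_n || sum(!above) < min_n) next
    grp <- if (risk == "above") as.integer(above) else as.integer(!above)
    fr <- fit_binary_cox(records, grp)
    if (is.null(fr)) next
    rows[[k]] <- cbind(cutoff = mids[k], fr)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    stop("no admissible cutoff candidate", call. = FALSE)
  sig <- rows[rows$p <= p_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    best <- rows[which.max(rows$hr), , drop = FALSE]
    res <- cutoff_result(feature, best$cutoff, records, best, risk,
                         significant = FALSE)
    class(res) <- c("no_significant_cutoff", class(res))
    return(res)
  }
  best <- sig[which.max(sig$hr), , drop = FALSE]
  cutoff_result(feature, best$cutoff, records, best, risk)
}

#' Hazard ratios at fixed quantile cutoffs
#'
#' Dichotomizes the cohort at the upper and lower `fractions` quantiles of a
#' feature (e.g. the upper third splits off the `round(n * 1/3)` highest
#' values) and reports the Cox hazard ratio of the extreme group versus the
#' rest. Used for small validation cohorts where an optimal-cutoff search is
#' unstable. A dichotomization whose groups contain no event yields `NA`
#' hazard ratios.
#'
#' @param records data frame with `pfs_time`, `event` and the feature.
#' @param feature feature column name.
#' @param fractions quantile fractions (default 0.10, 0.25, 1/3).
#' @param sides `"upper"`, `"lower"`, or both (default).
#' @return List of `cutoff_result` objects, one per side x fraction, each
#'   with extra fields `side` and `fraction`.
#' @export
quantile_cutoff_sweep <- function(records, feature,
                                  fractions = c(0.10, 0.25, 1/3),
                                  sides = c("upper", "lower")) {
  check_records(records, feature)
  sides <- match.arg(sides, several.ok = TRUE)
  x <- records[[feature]]
  n <- length(x)
  ord <- order(x)
  out <- list()
  for (side in sides) {
    for (f in fractions) {
      k <- round(n * f)
      if (k < 1L || k >= n) next
      if (side == "upper") {
        cutoff <- (x[ord][n - k] + x[ord][n - k + 1]) / 2
        extreme <- x > cutoff
      } else {
        cutoff <- (x[ord][k] + x[ord][k + 1]) / 2
        extreme <- x <= cutoff
      }
      grp <- as.integer(extreme)
      fr <- NULL
      if (sum(records$event[extreme]) > 0 && sum(records$event[!extreme]) > 0)
        fr <- fit_binary_cox(records, grp)
      if (is.null(fr))
        fr <- data.frame(hr = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p = NA_real_)
      res <- cutoff_result(feature, cutoff, records, fr,
                           risk = if (side == "upper") "above" else "below",
                           significant = !is.na(fr$p) && fr$p <= 0.05,
                           extra = list(side = side, fraction = f))
      out[[paste(side, format(f, digits = 3), sep = "_")]] <- res
    }
  }
  out
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator of the survival function within each group, via
#' `survival::survfit`. S(0) = 1 and each curve is nonincreasing.
#'
#' @param records data frame with `pfs_time` and `event`.
#' @param group vector of group labels (one per subject).
#' @return A `survfit` object (supports `summary` and `plot`).
#' @export
km_curve <- function(records, group) {
  stopifnot(is.data.frame(records), nrow(records) == length(group))
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  rec <- records
  rec$.grp <- group
  survival::survfit(survival::Surv(pfs_time, event) ~ .grp, data = rec)
}

#' Harrell's concordance index
#'
#' Event-anchored pair counting: a pair is usable when the subject with the
#' shorter observed time had an event (or, at a tied time, exactly one of
#' the pair was censored, anchoring on the event). A usable pair is
#' concordant when the shorter-lived subject has the higher risk score; risk
#' ties count 1/2. Pairs of events at identical times are not usable.
#'
#' @param risk numeric risk scores (higher = worse prognosis), a `cox_fit`
#'   (its linear predictor is used), or a fitted `coxph` model.
#' @param records data frame with `pfs_time` and `event`; required when
#'   `risk` is a model, optional when `risk` is numeric and `time`/`event`
#'   are given directly.
#' @param time,event alternative direct inputs when `risk` is numeric.
#' @return Concordance in \[0, 1\].
#' @export
harrell_c <- function(risk, records = NULL, time = NULL, event = NULL) {
  if (inherits(risk, "cox_fit")) risk <- risk$linear_predictor
  if (inherits(risk, "coxph")) risk <- unname(risk$linear.predictors)
  if (!is.null(records)) {
    time <- records$pfs_time
    event <- records$event
  }
  stopifnot(is.numeric(risk), length(risk) == length(time),
            length(time) == length(event))
  n <- length(risk)
  ti <- matrix(time, n, n)
  ei <- matrix(event, n, n)
  tj <- t(ti)
  ej <- t(ei)
  # row i anchors: i had the event and demonstrably shorter survival than j
  usable <- (ti < tj & ei == 1) | (ti == tj & ei == 1 & ej == 0)
  diag(usable) <- FALSE
  if (!any(usable)) stop("no usable pairs", call. = FALSE)
  ri <- matrix(risk, n, n)
  rj <- t(ri)
  conc <- sum(usable & ri > rj)
  ties <- sum(usable & ri == rj)
  (conc + 0.5 * ties) / sum(usable)
}

#' Incremental predictive value via Harrell's C comparison
#'
#' Fits a base and an extended Cox model (the extended covariate set must
#' contain the base set), computes Harrell's C for both, and assesses the
#' difference by a paired bootstrap over subjects: both models are refitted
#' on each resample and the difference in C recomputed. Percentile intervals
#' and a two-sided bootstrap P-value for delta C = 0 are reported.
#' Degenerate resamples (non-convergent fits, no events, constant
#' covariates) are skipped and counted.
#'
#' @param records data frame with `pfs_time`, `event` and covariates.
#' @param base_covariates,extended_covariates character vectors of column
#'   names; `extended_covariates` must be a superset.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed for the bootstrap resampling.
#' @return An object of class `cindex_comparison`: list with `c_base`,
#'   `c_extended`, their percentile 95% CIs, `delta`, `p`, `n_boot_used`.
#' @export
compare_c <- function(records, base_covariates, extended_covariates,
                      n_boot = 500L, seed = 1L) {
  if (!all(base_covariates %in% extended_covariates))
    stop("extended covariate set must contain the base set", call. = FALSE)
  fit_b <- fit_cox(records, base_covariates)
  fit_e <- fit_cox(records, extended_covariates)
  c_b <- harrell_c(fit_b, records)
  c_e <- harrell_c(fit_e, records)
  identical_models <- setequal(base_covariates, extended_covariates)

  n <- nrow(records)
  set.seed(seed)
  deltas <- cb <- ce <- numeric(0)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    rec <- records[idx, , drop = FALSE]
    res <- tryCatch({
      if (identical_models) {
        fb <- fit_cox(rec, base_covariates)
        cbv <- harrell_c(fb, rec)
        c(cbv, cbv)
      } else {
        fb <- fit_cox(rec, base_covariates)
        fe <- fit_cox(rec, extended_covariates)
        c(harrell_c(fb, rec), harrell_c(fe, rec))
      }
    }, error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1L; next }
    cb <- c(cb, res[1]); ce <- c(ce, res[2])
    deltas <- c(deltas, res[2] - res[1])
  }
  if (length(deltas) < 2L)
    stop("bootstrap failed on nearly all resamples", call. = FALSE)
  p <- if (all(deltas == 0)) 1 else
    min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  structure(list(
    c_base = c_b, c_base_ci = stats::quantile(cb, c(0.025, 0.975),
                                              names = FALSE),
    c_extended = c_e, c_extended_ci = stats::quantile(ce, c(0.025, 0.975),
                                                      names = FALSE),
    delta = c_e - c_b,
    delta_ci = stats::quantile(deltas, c(0.025, 0.975), names = FALSE),
    p = p, n_boot_used = length(deltas), n_boot_skipped = skipped
  ), class = "cindex_comparison")
}

#' @export
print.cindex_comparison <- function(x, ...) {
  cat(sprintf("Harrell's C: base %.3f (%.3f-%.3f) vs extended %.3f (%.3f-%.3f)\n",
              x$c_base, x$c_base_ci[1], x$c_base_ci[2],
              x$c_extended, x$c_extended_ci[1], x$c_extended_ci[2]))
  cat(sprintf("  delta C = %.3f (%.3f-%.3f), bootstrap P = %.3g (%d resamples)\n",
              x$delta, x$delta_ci[1], x$delta_ci[2], x$p, x$n_boot_used))
  invisible(x)
}
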