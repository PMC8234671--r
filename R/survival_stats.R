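#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over `survival::survfit` returning the curve as a table:
#' survival is recomputed only at event times (censored times reduce the risk
#' set without a step), starts at 1 and is non-increasing.
#'
#' @param records data.frame with columns `time` (days, > 0) and `event`
#'   (0 = censored, 1 = event).
#' @return data.frame with one row per distinct event time: `time`, `n_risk`,
#'   `n_event`, `survival`.
#' @export
km_estimate <- function(records) {
  check_survival_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  s <- summary(fit, censored = FALSE)
  data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
             survival = s$surv)
}

check_survival_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% colnames(records)))
  if (!nrow(records)) stop("no survival records")
  if (any(records$time <= 0)) stop("survival times must be positive")
  if (length(setdiff(records$event, c(0, 1)))) stop("event must be 0 or 1")
  invisible(records)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' referred to chi-square with 1 df (via `survival::survdiff`).
#'
#' @param groupA,groupB data.frames with `time` and `event` columns.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(groupA, groupB) {
  check_survival_records(groupA)
  check_survival_records(groupB)
  if (sum(groupA$event) + sum(groupB$event) == 0) {
    stop("log-rank test needs at least one event")
  }
  df <- rbind(data.frame(time = groupA$time, event = groupA$event, g = "A"),
              data.frame(time = groupB$time, event = groupB$event, g = "B"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Fits `survival::coxph` on the named covariates with Efron tie handling by
#' default. Categorical covariates are dummy-coded against a declared
#' reference level; records with missing covariate values are dropped with a
#' message reporting the count. Infinite-coefficient (monotone-likelihood)
#' and non-convergence warnings from the fitter are promoted to errors.
#'
#' @param records data.frame with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param reference named list mapping categorical covariate names to their
#'   reference level (e.g. `list(stratum = "mid", cytogenetic_risk =
#'   "favorable")`); unlisted factors keep their first level.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `rg_cox`: list with `table` (term, level, coef,
#'   hr, ci_low, ci_high, se, p), `loglik`, `converged`, `n`, `n_events`,
#'   `n_dropped`, `xlevels`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(records, covariates, reference = list(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_survival_records(records)
  missing_cov <- setdiff(covariates, colnames(records))
  if (length(missing_cov)) {
    stop("covariate(s) not in records: ", paste(missing_cov, collapse = ", "))
  }
  dat <- records[, c("time", "event", covariates), drop = FALSE]
  complete <- stats::complete.cases(dat)
  n_dropped <- sum(!complete)
  if (n_dropped) {
    message("cox_fit: dropping ", n_dropped,
            " record(s) with missing covariate values")
  }
  dat <- dat[complete, , drop = FALSE]
  for (cov in covariates) {
    v <- dat[[cov]]
    if (length(unique(v)) < 2L) stop("constant covariate: ", cov)
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      f <- factor(v)
      ref <- reference[[cov]]
      if (!is.null(ref)) {
        if (!ref %in% levels(f)) {
          stop("reference level '", ref, "' not found in covariate ", cov)
        }
        f <- stats::relevel(f, ref = ref)
      }
      dat[[cov]] <- f
    }
  }
  if (sum(dat$event) < length(covariates)) {
    stop("fewer events than model parameters")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-8, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        stop("cox_fit: ", conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  sf <- summary(fit)
  coefs <- sf$coefficients
  tab <- data.frame(term = rownames(coefs),
                    coef = coefs[, "coef"],
                    hr = exp(coefs[, "coef"]),
                    ci_low = exp(coefs[, "coef"] - 1.96 * coefs[, "se(coef)"]),
                    ci_high = exp(coefs[, "coef"] + 1.96 * coefs[, "se(coef)"]),
                    se = coefs[, "se(coef)"],
                    p = coefs[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = fit$loglik[2L],
                 score_chi2 = unname(sf$sctest["test"]),
                 converged = fit$iter < 50, n = nrow(dat),
                 n_events = sum(dat$event), n_dropped = n_dropped,
                 xlevels = fit$xlevels, covariates = covariates, fit = fit),
            class = "rg_cox")
}

#' @export
print.rg_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit:", x$n, "records,", x$n_events,
      "events\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Forest-plot table for a Cox fit
#'
#' One row per covariate level: reference levels of categorical covariates
#' are listed with hazard ratio exactly 1 and empty CI/p; fitted terms carry
#' `exp(coef)` with the 95% Wald interval `exp(coef +/- 1.96 se)`.
#'
#' @param fit an `rg_cox` object from [cox_fit()].
#' @return data.frame with columns `covariate`, `level`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `reference`.
#' @export
forest_table <- function(fit) {
  stopifnot(inherits(fit, "rg_cox"))
  if (!fit$converged) stop("forest_table requires a converged fit")
  rows <- list()
  for (cov in fit$covariates) {
    lv <- fit$xlevels[[cov]]
    if (is.null(lv)) {
      i <- match(cov, fit$table$term)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, level = "", hr = fit$table$hr[i],
        ci_low = fit$table$ci_low[i], ci_high = fit$table$ci_high[i],
        p = fit$table$p[i], reference = FALSE, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, level = lv[1L], hr = 1, ci_low = NA_real_,
        ci_high = NA_real_, p = NA_real_, reference = TRUE,
        stringsAsFactors = FALSE)
      for (l in lv[-1L]) {
        i <- match(paste0(cov, l), fit$table$term)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cov, level = l, hr = fit$table$hr[i],
          ci_low = fit$table$ci_low[i], ci_high = fit$table$ci_high[i],
          p = fit$table$p[i], reference = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
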