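# Survival analyses: Kaplan-Meier estimation with Greenwood intervals,
# log-rank comparison, Cox proportional-hazards regression (Efron tie
# handling, Wald tests), the expression-by-subtype interaction test, and
# univariate-to-multivariate covariate selection. Backed by the survival
# package.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood (log-scale) confidence intervals
#' and a right-continuous rate extractor: `rate_at(60)` returns the 5-year
#' survival probability, carrying the last value forward when no step
#' straddles the requested time.
#'
#' @param time follow-up times (months).
#' @param event event indicators, 0/1.
#' @return object of class `km_fit`: list with the `survival::survfit`
#'   object `fit` and the function `rate_at(t)` returning `surv`, `lower`,
#'   `upper` at time `t`.
#' @export
km_estimate <- function(time, event) {
  keep <- is.finite(time) & is.finite(event)
  time <- time[keep]; event <- event[keep]
  if (length(time) < 1L) stop("km_estimate: no usable subjects")
  if (all(time <= 0)) stop("km_estimate: all follow-up at time zero")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log")
  rate_at <- function(t) {
    s <- summary(fit, times = t, extend = TRUE)
    list(surv = s$surv, lower = s$lower, upper = s$upper)
  }
  structure(list(fit = fit, rate_at = rate_at, n = length(time),
                 events = sum(event)), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  r <- x$rate_at(60)
  cat(sprintf("Kaplan-Meier fit: n=%d, events=%d, 5-year rate %.1f%% [%.1f-%.1f]\n",
              x$n, x$events, 100 * r$surv, 100 * r$lower, 100 * r$upper))
  invisible(x)
}

#' Log-rank test
#'
#' Standard (observed - expected)^2 / variance log-rank statistic comparing
#' survival across groups; one degree of freedom for two groups.
#'
#' @param time follow-up times.
#' @param event event indicators, 0/1.
#' @param group group labels.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("logrank_test: need at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie correction. Reports, per
#' covariate term, the coefficient, hazard ratio, 95% Wald confidence
#' interval and Wald p-value. Non-convergence or infinite coefficients are
#' flagged rather than silently returned.
#'
#' @param time follow-up times.
#' @param event event indicators, 0/1.
#' @param covariates data frame of covariates (factors or numerics).
#' @return object of class `cox_result`: data frame with columns `term`,
#'   `coef`, `hr`, `lower`, `upper`, `se`, `p`; attributes `n`, `events`,
#'   `converged`, `ties`, and the underlying `coxph` fit in `"fit"`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- is.finite(time) & is.finite(event) &
    stats::complete.cases(covariates)
  time <- time[keep]; event <- event[keep]
  covariates <- covariates[keep, , drop = FALSE]
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("cox_fit: covariate '", nm, "' is constant")
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|coefficient may be infinite",
                conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  res <- data.frame(term = rownames(co),
                    coef = co[, "coef"],
                    hr = exp(co[, "coef"]),
                    lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    se = co[, "se(coef)"],
                    p = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, class = c("cox_result", "data.frame"),
            n = s$n, events = s$nevent, converged = converged,
            ties = "efron", fit = fit)
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox regression (Efron ties): n=%d, events=%d%s\n",
              attr(x, "n"), attr(x, "events"),
              if (isTRUE(attr(x, "converged"))) "" else "  [NOT CONVERGED]"))
  df <- data.frame(term = x$term,
                   `HR [95CI]` = sprintf("%.2f [%.2f-%.2f]", x$hr, x$lower,
                                         x$upper),
                   p = signif(x$p, 3), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Expression-by-subtype interaction test
#'
#' Fits a Cox model with main effects for the binary expression group and
#' the binary subtype indicator plus their product, and returns the Wald
#' p-value of the product term — the test of whether the expression effect
#' differs between strata (e.g. basal vs non-basal).
#'
#' @param time follow-up times.
#' @param event event indicators, 0/1.
#' @param expression_group binary factor (e.g. up / no_up).
#' @param subtype_indicator binary factor (e.g. basal / non-basal).
#' @return list with `p` (Wald p of the product term), `coef` (product
#'   coefficient) and the full `cox_result` in `fit`.
#' @export
interaction_test <- function(time, event, expression_group,
                             subtype_indicator) {
  g <- as.factor(expression_group)
  s <- as.factor(subtype_indicator)
  if (nlevels(droplevels(g)) != 2L || nlevels(droplevels(s)) != 2L)
    stop("interaction_test: both factors must be binary")
  if (any(table(g, s) == 0L))
    stop("interaction_test: empty cell in the factor cross")
  keep <- is.finite(time) & is.finite(event) & !is.na(g) & !is.na(s)
  dat <- data.frame(.time = time[keep], .event = event[keep],
                    g = droplevels(g[keep]), s = droplevels(s[keep]))
  fit <- survival::coxph(survival::Surv(.time, .event) ~ g * s, data = dat,
                         ties = "efron")
  co <- summary(fit)$coefficients
  prod_row <- grep(":", rownames(co))
  list(p = co[prod_row, "Pr(>|z|)"], coef = co[prod_row, "coef"],
       fit = fit)
}

#' Select covariates for multivariate analysis
#'
#' Returns the covariates whose univariate Wald p-value is below `alpha`
#' (the univariate-screen convention for building the multivariate model).
#'
#' @param univariate named numeric vector (or one-row-per-term data frame
#'   with columns `term` and `p`) of univariate Wald p-values.
#' @param alpha screening threshold (default 0.05).
#' @return character vector of selected covariate names (possibly empty).
#' @export
build_multivariate <- function(univariate, alpha = 0.05) {
  if (is.data.frame(univariate)) {
    p <- univariate$p
    names(p) <- univariate$term
    univariate <- p
  }
  names(univariate)[!is.na(univariate) & univariate < alpha]
}
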