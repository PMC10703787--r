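#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via \pkg{survival}, returned as a tidy step
#' table.  Censoring tied with events at the same time is handled
#' events-first (the standard product-limit convention).
#'
#' @param time follow-up times (>= 0), e.g. years.
#' @param event logical/0-1 event indicator.
#' @param group optional grouping factor for stratified curves.
#' @return An object of class `km_curve`: data.frame with columns `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (length(time) == 0L) stop("empty survival input")
  stopifnot(all(time >= 0), length(event) == length(time))
  event <- as.integer(as.logical(event))
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  out <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, n_censor = sm$n.censor,
                    surv = sm$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at a query time
#'
#' Right-continuous step lookup on a [km_estimate()] curve; times before
#' the first event return 1.
#'
#' @param km a `km_curve`.
#' @param t query time(s).
#' @param group group to query (defaults to the only group present).
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(km, t, group = NULL) {
  g <- if (is.null(group)) unique(km$group)[1] else as.character(group)
  cur <- km[km$group == g & km$n_event > 0, , drop = FALSE]
  if (nrow(cur) == 0L) return(rep(1, length(t)))
  sf <- stats::stepfun(cur$time, c(1, cur$surv), right = FALSE)
  sf(t)
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank over pooled event times, with
#' df = number of groups - 1.  If no events occurred at all the comparison
#' is vacuous and p = 1 is returned with a warning.
#'
#' @param time,event as in [km_estimate()].
#' @param labels grouping factor (>= 2 groups).
#' @return List with `statistic`, `df`, `p_value`, `n`, `observed`,
#'   `expected` (per group).
#' @export
logrank_test <- function(time, event, labels) {
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 groups")
  event <- as.integer(as.logical(event))
  if (sum(event) == 0L) {
    warning("no events in any group: log-rank test is vacuous")
    return(list(statistic = 0, df = nlevels(labels) - 1L, p_value = 1,
                n = table(labels), observed = tapply(event, labels, sum),
                expected = tapply(event, labels, sum)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ labels)
  df <- nlevels(labels) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = sd$n, observed = sd$obs, expected = sd$exp)
}

#' Univariate Cox proportional hazards model
#'
#' Partial-likelihood fit with the Efron tie correction and a Wald
#' confidence interval on the log-hazard scale.  A binary covariate with
#' all events in one level gives a monotone likelihood; the fit is then
#' flagged and the confidence interval unbounded.
#'
#' @param time,event as in [km_estimate()].
#' @param covariate covariate vector; a two-level factor or 0/1 for a
#'   group comparison (HR is level 2 vs level 1).
#' @param conf_level confidence level, default 0.95.
#' @return List with `hr`, `ci_low`, `ci_high`, `p_value`, `coef`, `se`,
#'   `n`, `n_event`, `monotone` (logical flag).
#' @export
cox_univariate <- function(time, event, covariate, conf_level = 0.95) {
  event <- as.integer(as.logical(event))
  if (is.character(covariate) || is.logical(covariate))
    covariate <- factor(covariate)
  monotone <- FALSE
  if (is.factor(covariate) || length(unique(covariate)) == 2L) {
    ev_by <- tapply(event, covariate, sum)
    if (any(ev_by == 0) && any(ev_by > 0)) monotone <- TRUE
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ covariate,
                         ties = "efron")
  co <- summary(fit)$coefficients[1, ]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (monotone) {
    warning("monotone partial likelihood: hazard ratio diverges, ",
            "confidence interval unbounded")
    ci <- if (co[["coef"]] > 0) c(0, Inf) else c(0, Inf)
  } else {
    ci <- exp(co[["coef"]] + c(-1, 1) * z * co[["se(coef)"]])
  }
  list(hr = unname(exp(co[["coef"]])), ci_low = ci[1], ci_high = ci[2],
       p_value = unname(co[["Pr(>|z|)"]]), coef = unname(co[["coef"]]),
       se = unname(co[["se(coef)"]]), n = fit$n, n_event = fit$nevent,
       monotone = monotone)
}

#' Two-sided Student's t-test (pooled variance)
#'
#' Classical equal-variance two-sample t with df = n1 + n2 - 2 (set
#' `welch = TRUE` for the unequal-variance form).
#'
#' @param x,y numeric samples, each with >= 2 values.
#' @param welch use the Welch correction instead of pooling.
#' @return List with `t`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
students_t_test <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs >= 2 finite values")
  tt <- tryCatch(stats::t.test(x, y, var.equal = !welch),
                 error = function(e)
                   stop("t-test failed (zero pooled variance?): ",
                        conditionMessage(e)))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Treatment-by-stratum interaction test for a binary response
#'
#' Logistic model `response ~ arm * stratum` fit by maximum likelihood
#' (IRLS via [stats::glm()]); the reported p-value is the Wald test of the
#' interaction coefficient.  Complete or quasi-complete separation is
#' flagged and p set to NA.
#'
#' @param response logical/0-1 outcome.
#' @param arm,stratum binary factors.
#' @return List with `estimate` (interaction log-odds coefficient), `se`,
#'   `p_value`, `separation` (logical), `fit` (the glm object).
#' @export
interaction_test <- function(response, arm, stratum) {
  response <- as.integer(as.logical(response))
  arm <- factor(arm); stratum <- factor(stratum)
  if (nlevels(arm) != 2L || nlevels(stratum) != 2L)
    stop("arm and stratum must each have exactly 2 levels")
  if (any(table(arm, stratum) == 0))
    stop("all four arm x stratum cells must be observed")
  fit <- suppressWarnings(stats::glm(response ~ arm * stratum,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  irow <- grep(":", rownames(co))
  est <- co[irow, "Estimate"]; se <- co[irow, "Std. Error"]
  sep <- !fit$converged || abs(est) > 15 || se > 100
  if (sep) warning("separation detected: interaction p-value set to NA")
  list(estimate = unname(est), se = unname(se),
       p_value = if (sep) NA_real_ else unname(co[irow, "Pr(>|z|)"]),
       separation = sep, fit = fit)
}
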