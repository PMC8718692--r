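# Survival engine: Kaplan-Meier curves, log-rank tests and univariate Cox
# regression wrap the survival package (Efron ties); the maximally
# selected rank-statistic cutpoint search is implemented here.

#' Kaplan-Meier curves per group
#'
#' Product-limit estimator for each group. Estimation always uses all
#' data; truncating the display at e.g. 5 years is a plotting choice.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group optional group labels (default: one group).
#' @return named list of data.frames (time, n_risk, n_event, n_censor,
#'   surv), class \code{km_list}.
#' @export
km_fit <- function(time, event, group = NULL) {
  check_surv(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  group <- factor(group)
  if (any(table(group) == 0L)) stopf("empty group")
  out <- lapply(levels(group), function(g) {
    sel <- group == g
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               n_censor = sf$n.censor, surv = sf$surv)
  })
  names(out) <- levels(group)
  class(out) <- c("km_list", class(out))
  out
}

#' Five-year survival rate from a KM curve
#' @param km one element of a \code{\link{km_fit}} result.
#' @param horizon time horizon in the data's time unit (default 60,
#'   i.e. five years in months).
#' @return estimated S(horizon).
#' @export
km_rate_at <- function(km, horizon = 60) {
  s <- km$surv[km$time <= horizon]
  if (!length(s)) 1 else min(s)
}

#' Log-rank test across groups
#'
#' Observed-minus-expected statistic with hypergeometric variance,
#' df = n_groups - 1.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 non-empty groups).
#' @return list(chisq, df, p_value).
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stopf("log-rank needs at least 2 non-empty groups")
  if (sum(event) == 0L) stopf("no events: log-rank statistic undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards regression
#'
#' Efron handling of tied event times; Wald inference from the observed
#' information. Monotone-likelihood fits (perfect separation) are
#' returned with \code{converged = FALSE}.
#'
#' @param time,event survival data.
#' @param covariate numeric covariate (finite).
#' @return list of class \code{cox_fit}: beta, se, hr, z, p_value,
#'   ci_lower, ci_upper, converged, ties.
#' @export
cox_univariate <- function(time, event, covariate) {
  check_surv(time, event)
  if (any(!is.finite(covariate))) stopf("covariate must be finite")
  if (sum(event) == 0L) stopf("no events: Cox likelihood is flat")
  if (stats::sd(covariate) == 0) {
    fit <- list(beta = 0, se = NA_real_, hr = 1, z = NA_real_, p_value = 1,
                ci_lower = NA_real_, ci_upper = NA_real_, converged = TRUE,
                ties = "efron")
    class(fit) <- "cox_fit"
    return(fit)
  }
  warned <- FALSE
  cf <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ covariate, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(cf))
  se <- sqrt(unname(diag(stats::vcov(cf))))
  z <- beta / se
  fit <- list(beta = beta, se = se, hr = exp(beta), z = z,
              p_value = 2 * stats::pnorm(-abs(z)),
              ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
              converged = !warned, ties = "efron")
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox (Efron ties): HR = %.3f [%.3f, %.3f], beta = %.4f (se %.4f), p = %.3g%s\n",
              x$hr, x$ci_lower, x$ci_upper, x$beta, x$se, x$p_value,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Two-group log-rank numerator and variance
#'
#' O - E for the indicator group and its hypergeometric variance, used
#' by the standardized statistic of the cutpoint search.
#' @noRd
logrank_uv <- function(time, event, in_high) {
  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; hi <- as.numeric(in_high[ord])
  n <- length(tt)
  r <- rle(tt)
  starts <- cumsum(r$lengths) - r$lengths + 1L   # first index of each unique time
  n_t <- n - starts + 1L                         # at risk at each unique time
  n1_rev <- rev(cumsum(rev(hi)))                 # group-1 at risk from position i on
  n1_t <- n1_rev[starts]
  d_t <- rowsum(ev, tt)[, 1]                     # events per unique time (sorted)
  d1_t <- rowsum(ev * hi, tt)[, 1]
  keep <- d_t > 0
  n_t <- n_t[keep]; n1_t <- n1_t[keep]; d_t <- d_t[keep]; d1_t <- d1_t[keep]
  U <- sum(d1_t - d_t * n1_t / n_t)
  vt <- d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / pmax(n_t - 1, 1)
  V <- sum(vt[n_t > 1])
  c(U = U, V = V)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans the midpoints of consecutive distinct score values for which
#' both resulting groups hold at least \code{ceiling(minprop * n)}
#' samples, computes the standardized two-group log-rank statistic
#' |O - E| / sqrt(V) at each candidate, and returns the maximizer (ties
#' go to the lower cut). The selection-bias-adjusted p-value is not
#' computed; downstream tests are run on the resulting groups.
#'
#' @param time,event survival data.
#' @param score numeric vector with at least two distinct values.
#' @param minprop minimum proportion of samples per side (default 0.1).
#' @return list of class \code{cutpoint_result}: cutpoint, statistic,
#'   n_low, n_high, minprop, candidates (data.frame cut/statistic).
#' @export
max_sel_cutpoint <- function(time, event, score, minprop = 0.1) {
  check_surv(time, event)
  if (minprop <= 0 || minprop >= 0.5) stopf("minprop must be in (0, 0.5)")
  n <- length(score)
  if (length(unique(score)) < 2L) stopf("score is constant; no cutpoint exists")
  s_sorted <- sort(unique(score))
  mids <- (s_sorted[-1] + s_sorted[-length(s_sorted)]) / 2
  min_n <- ceiling(minprop * n)
  ok <- vapply(mids, function(cut) {
    n_hi <- sum(score > cut)
    n_hi >= min_n && (n - n_hi) >= min_n
  }, logical(1))
  if (!any(ok)) stopf("no candidate cutpoint satisfies minprop = %.2f", minprop)
  mids <- mids[ok]
  stat <- vapply(mids, function(cut) {
    uv <- logrank_uv(time, event, score > cut)
    if (uv["V"] <= 0) 0 else abs(uv["U"]) / sqrt(uv["V"])
  }, numeric(1))
  best <- which.max(stat)  # first max = lower cut on ties
  res <- list(cutpoint = mids[best], statistic = stat[best],
              n_low = sum(score <= mids[best]), n_high = sum(score > mids[best]),
              minprop = minprop,
              candidates = data.frame(cut = mids, statistic = stat))
  class(res) <- "cutpoint_result"
  res
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("maximally selected cutpoint: %.4g (standardized log-rank %.3f), n = %d low / %d high\n",
              x$cutpoint, x$statistic, x$n_low, x$n_high))
  invisible(x)
}

#' @noRd
check_surv <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0)) stopf("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stopf("event indicators must be 0/1")
  if (length(time) != length(event)) stopf("time and event lengths differ")
  invisible(TRUE)
}
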