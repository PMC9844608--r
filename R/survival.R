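## Survival stratification by fusion positivity: Kaplan-Meier product-limit
## curves and the log-rank test, computed with the survival package behind
## this module's interface.

#' Kaplan-Meier product-limit estimate for one group
#'
#' @param records data.frame with columns `time` (months, >= 0) and `event`
#'   (1 = death observed, 0 = right-censored); optionally pre-filtered to a
#'   stratum via `select`.
#' @param select optional logical vector choosing the records to estimate
#'   on (e.g. `records$fusion_positive`)
#' @return data.frame step table with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`; survival starts at 1 and is non-increasing.
#' @export
kmEstimate <- function(records, select = NULL) {
  if (!is.null(select)) records <- records[select, , drop = FALSE]
  if (!nrow(records)) .stopf("kmEstimate: empty group")
  if (any(records$time < 0)) .stopf("kmEstimate: negative survival time")
  if (!all(records$event %in% c(0, 1))) .stopf("kmEstimate: event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank test between fusion-positive and fusion-negative strata
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' (1 degree of freedom); p from the upper chi-square tail. When the two
#' strata combined contain no events the statistic is 0 and p = 1.
#'
#' @param records data.frame with columns `time`, `event` and a logical
#'   stratum column named by `strata` (default `"fusion_positive"`)
#' @param strata name of the logical stratum column
#' @return list with `chisq`, `p`, and `table` (per-stratum n, observed and
#'   expected event counts).
#' @export
logrankTest <- function(records, strata = "fusion_positive") {
  if (!strata %in% names(records))
    .stopf("logrankTest: no stratum column '%s'", strata)
  g <- as.logical(records[[strata]])
  if (!any(g) || !any(!g))
    .stopf("logrankTest: both strata must be non-empty")
  tab0 <- data.frame(stratum = c("negative", "positive"),
                     n = c(sum(!g), sum(g)), observed = c(0, 0),
                     expected = c(0, 0))
  if (sum(records$event) == 0)
    return(list(chisq = 0, p = 1, table = tab0))
  records$..stratum <- g
  sd <- survival::survdiff(survival::Surv(time, event) ~ ..stratum,
                           data = records)
  tab <- data.frame(stratum = c("negative", "positive"),
                    n = as.vector(sd$n),
                    observed = as.vector(sd$obs),
                    expected = as.vector(sd$exp))
  list(chisq = unname(sd$chisq), p = 1 - pchisq(unname(sd$chisq), df = 1),
       table = tab)
}
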