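# median-expression grouping, Kaplan-Meier curves and the log-rank test.
# The product-limit estimate and the log-rank statistic are computed by the
# survival package (survfit/survdiff) behind this module's interface.

#' Split samples at the median expression
#'
#' Values strictly above the median are labeled "high", strictly below "low";
#' values equal to the median go to "high" (fixed convention — the log-rank
#' test is label-symmetric, so the direction of any survival claim must be
#' read from the KM curves).
#'
#' @param expression numeric vector, length >= 2.
#' @return factor with levels "low", "high".
#' @examples
#' medianSplit(c(1, 2, 3, 4))  # low low high high
#' @export
medianSplit <- function(expression) {
  .assert(length(expression) >= 2, "need at least 2 samples")
  if (max(expression) == min(expression))
    stop("constant expression: no median split possible", call. = FALSE)
  m <- median(expression)
  g <- factor(ifelse(expression >= m, "high", "low"), levels = c("low", "high"))
  if (any(table(g) == 0))
    stop("degenerate median split: one group is empty", call. = FALSE)
  g
}

#' Kaplan-Meier curve for one group
#'
#' Product-limit survival estimate, reported at each distinct observed time.
#' S(0) = 1 and the curve is right-continuous and non-increasing; ties between
#' deaths and censorings at the same time are handled with deaths first (the
#' standard convention).
#'
#' @param table data.frame(time, event) or data.frame(time, event, group).
#' @param group when `table` has a group column, the group to extract.
#' @return data.frame(time, n_risk, n_event, n_censor, surv).
#' @export
kmCurve <- function(table, group = NULL) {
  if (!is.null(group)) {
    .assert("group" %in% names(table), "table has no 'group' column")
    table <- table[table$group == group, , drop = FALSE]
    .assert(nrow(table) > 0, "group '", group, "' is empty")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: observed minus expected events summed over
#' distinct event times, normalized by the hypergeometric variance; chi-square
#' with 1 df, two-sided p-value.  Symmetric under swapping the group labels.
#'
#' @param table data.frame(time, event, group) with exactly two non-empty
#'   groups and at least one event.
#' @return list(chi2, p, observed, expected) with per-group observed and
#'   expected event counts.
#' @export
logrankTest <- function(table) {
  .assert(all(c("time", "event", "group") %in% names(table)),
          "table needs columns time, event, group")
  g <- factor(table$group)
  tabg <- table(g)
  if (nlevels(g) != 2 || any(tabg == 0))
    stop("log-rank test needs exactly two non-empty groups (got ",
         paste(names(tabg), tabg, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  .assert(sum(table$event == 1) >= 1, "no events observed")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g,
                            data = data.frame(time = table$time,
                                              event = table$event, g = g))
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = setNames(sd_$obs, levels(g)),
       expected = setNames(sd_$exp, levels(g)))
}
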