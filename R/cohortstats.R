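#' Pearson chi-square test for a 2x2 table
#'
#' Chi-square test of independence without continuity correction (df = 1),
#' with a one-tailed option for directional hypotheses on the first group's
#' event proportion: the one-tailed p is half the two-tailed p when the
#' observed effect lies in the tested direction, and one minus half
#' otherwise.
#'
#' @param a,b Events and non-events in group 1.
#' @param c,d Events and non-events in group 2.
#' @param tail `"two"` or `"one"`.
#' @param direction For the one-tailed test: `"greater"` tests that group 1's
#'   event proportion exceeds group 2's (default), `"less"` the reverse.
#' @return List with `statistic` (chi-square), `df`, and `p`.
#' @examples
#' chisq2x2(13, 11, 9, 15, tail = "one")$p # 0.123
#' chisq2x2(18, 6, 16, 8)$p                # 0.53
#' @export
chisq2x2 <- function(a, b, c, d, tail = c("two", "one"),
                     direction = c("greater", "less")) {
  tail <- match.arg(tail)
  direction <- match.arg(direction)
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stop("all table margins must be positive")
  n <- sum(counts)
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  pTwo <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (tail == "two") return(list(statistic = stat, df = 1L, p = pTwo))
  obsDiff <- a / (a + b) - c / (c + d)
  inDirection <- if (direction == "greater") obsDiff >= 0 else obsDiff <= 0
  p <- if (inDirection) pTwo / 2 else 1 - pTwo / 2
  list(statistic = stat, df = 1L, p = p)
}

#' Survival records from a subject table
#'
#' Reformats the cohort subject table into time-to-event records where the
#' event is conversion to dementia and survival means not converting;
#' subjects who did not convert are censored at their last follow-up month.
#'
#' @param subjects Subject table with `subject_id`, `carrier`, `converted`,
#'   `event_or_censor_month`.
#' @return Data frame with `subject_id`, `group` (`"carrier"` /
#'   `"non-carrier"`), `time_months`, `event`.
#' @export
survivalRecords <- function(subjects) {
  need <- c("subject_id", "carrier", "converted", "event_or_censor_month")
  if (!all(need %in% names(subjects)))
    stop("subjects table lacks required columns")
  if (any(subjects$event_or_censor_month <= 0))
    stop("time_months must be > 0")
  data.frame(subject_id = subjects$subject_id,
             group = ifelse(subjects$carrier, "carrier", "non-carrier"),
             time_months = subjects$event_or_censor_month,
             event = as.logical(subjects$converted),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier conversion-free survival curves
#'
#' Product-limit survival curves per group with pointwise confidence
#' intervals from the Greenwood variance on the log scale (the `survfit`
#' default). Curves start at 1; censored subjects are marked in the fit.
#'
#' @param records Data frame from [survivalRecords()].
#' @param confLevel Confidence level (default 0.95).
#' @return A `survival::survfit` object.
#' @export
kmCurves <- function(records, confLevel = 0.95) {
  if (nrow(records) < 1L) stop("need at least one record")
  survival::survfit(
    survival::Surv(time_months, event) ~ group,
    data = records, conf.type = "log", conf.int = confLevel)
}

#' Fleming-Harrington weighted log-rank test
#'
#' Two-group weighted log-rank test with weights
#' `S(t-)^p * (1 - S(t-))^q`, where S is the pooled Kaplan-Meier estimate
#' just before each event time. `p = q = 0` reduces to the standard log-rank
#' test; `p = 1, q = 0` (the default) emphasises early differences. The
#' statistic is the squared weighted score over its hypergeometric variance,
#' referred to chi-square with 1 df.
#'
#' @param records Data frame from [survivalRecords()].
#' @param p,q Weight exponents (>= 0).
#' @return List with `statistic`, `df`, `p.value`, and the score `U` and
#'   variance `V`.
#' @export
flemingHarringtonTest <- function(records, p = 1, q = 0) {
  if (p < 0 || q < 0) stop("weight exponents must be >= 0")
  groups <- unique(records$group)
  if (length(groups) != 2L) stop("exactly two groups are required")
  if (!any(records$event)) stop("no events: test undefined")
  time <- records$time_months
  event <- records$event
  g1 <- records$group == groups[1]
  eventTimes <- sort(unique(time[event]))
  U <- 0; V <- 0; S <- 1
  for (t in eventTimes) {
    atRisk <- time >= t
    nj <- sum(atRisk)
    n1j <- sum(atRisk & g1)
    dj <- sum(event & time == t)
    d1j <- sum(event & time == t & g1)
    w <- S^p * (1 - S)^q
    U <- U + w * (d1j - dj * n1j / nj)
    if (nj > 1)
      V <- V + w^2 * dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    S <- S * (1 - dj / nj)
  }
  if (V <= 0) stop("degenerate variance: test undefined")
  stat <- U^2 / V
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       U = U, V = V, groups = groups)
}
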