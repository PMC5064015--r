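#' Median absolute deviation with the normal-consistency constant
#'
#' `constant * median(|x - median(x)|)`, with `constant = 1.4826` by default
#' so the statistic is consistent for the standard deviation under
#' normality. Thin wrapper over [stats::mad()] kept for a stable surface.
#'
#' @param values Numeric vector with at least one finite value.
#' @param constant Scale constant.
#' @return The scaled median absolute deviation.
#' @export
mad_scaled <- function(values, constant = 1.4826) {
  values <- values[is.finite(values)]
  if (length(values) == 0) {
    abort("mad_scaled needs at least one finite value",
          class = "consigamp_validation_error")
  }
  stats::mad(values, constant = constant)
}

#' Stratify samples into expression-high versus the rest
#'
#' Samples whose value strictly exceeds `median + k * MAD` (MAD scaled by
#' 1.4826) form the `"high"` group; everyone else is `"rest"`. With a
#' constant input no sample is high and a warning is raised.
#'
#' @param expr_values Named numeric vector (names = sample ids).
#' @param k Multiplier on the MAD (default 1).
#' @return A tibble `sample`, `value`, `group` (factor high/rest), with the
#'   cutoff in attribute `"cutoff"`.
#' @export
stratify_high <- function(expr_values, k = 1) {
  stopifnot(!is.null(names(expr_values)))
  v <- expr_values[!is.na(expr_values)]
  ctr <- median(v)
  cutoff <- ctr + k * mad_scaled(v)
  if (mad_scaled(v) == 0 && all(v == ctr)) {
    warn("constant expression vector: no sample exceeds the cutoff")
  }
  out <- tibble(
    sample = names(v),
    value = unname(v),
    group = factor(ifelse(v > cutoff, "high", "rest"), levels = c("high", "rest"))
  )
  attr(out, "cutoff") <- cutoff
  out
}

#' Administrative censoring at a maximum follow-up
#'
#' Records with follow-up beyond `max_months` are censored at `max_months`
#' (time set to the cap, event set to 0); records at or below the cap are
#' unchanged.
#'
#' @param records Tibble with columns `time` and `event`.
#' @param max_months Follow-up cap in months (default 120, i.e. ten years).
#' @return The truncated records.
#' @export
truncate_followup <- function(records, max_months = 120) {
  over <- !is.na(records$time) & records$time > max_months
  records$event[over] <- 0L
  records$time[over] <- max_months
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function under right censoring.
#' At tied times, events are counted before censorings: a censored
#' observation at an event time is still at risk for that event.
#'
#' @param records Tibble with columns `time` (positive) and `event` (0/1).
#' @return An object of class `"km_curve"`: a tibble with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`), plus attributes `n` (sample size) and `n_events`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  t <- records$time
  d <- as.integer(records$event)
  stopifnot(all(is.finite(t)), all(d %in% c(0L, 1L)))
  times <- sort(unique(t[d == 1L]))
  n <- length(t)
  surv <- numeric(length(times))
  n_risk <- integer(length(times))
  n_event <- integer(length(times))
  n_cens <- integer(length(times))
  s <- 1
  for (j in seq_along(times)) {
    tj <- times[j]
    n_risk[j] <- sum(t >= tj)
    n_event[j] <- sum(t == tj & d == 1L)
    n_cens[j] <- sum(t == tj & d == 0L)
    s <- s * (1 - n_event[j] / n_risk[j])
    surv[j] <- s
  }
  out <- tibble(time = times, n_risk = n_risk, n_event = n_event,
                n_censor = n_cens, survival = surv)
  structure(out, n = n, n_events = sum(d),
            class = c("km_curve", class(out)))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param curve A `"km_curve"` object.
#' @param times Numeric times.
#' @return Survival probabilities (right-continuous step function, S(0)=1).
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(x) {
    i <- findInterval(x, curve$time)
    if (i == 0) 1 else curve$survival[i]
  }, numeric(1))
}

# Shared machinery for weighted two-group log-rank statistics.
# weight_fn receives the pooled number at risk at each event time.
weighted_logrank <- function(groupA, groupB, weight_fn, test_name) {
  if (nrow(groupA) == 0 || nrow(groupB) == 0) {
    abort("both groups must be non-empty", class = "consigamp_validation_error")
  }
  t <- c(groupA$time, groupB$time)
  d <- as.integer(c(groupA$event, groupB$event))
  g <- rep(c(1L, 2L), c(nrow(groupA), nrow(groupB)))
  if (sum(d) == 0) {
    abort("no events in either group", class = "consigamp_validation_error")
  }
  times <- sort(unique(t[d == 1L]))
  o_minus_e <- 0
  v <- 0
  for (tj in times) {
    at_risk <- t >= tj
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g == 1L)
    d_j <- sum(t == tj & d == 1L)
    d1_j <- sum(t == tj & d == 1L & g == 1L)
    if (n_j < 1) next
    w <- weight_fn(n_j)
    o_minus_e <- o_minus_e + w * (d1_j - d_j * n1_j / n_j)
    if (n_j > 1) {
      v <- v + w^2 * d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  if (v <= 0) {
    abort("zero variance: no comparable events between the groups",
          class = "consigamp_degenerate_error")
  }
  stat <- o_minus_e^2 / v
  structure(
    list(statistic = stat, df = 1L, p = pchisq(stat, df = 1, lower.tail = FALSE),
         observed_minus_expected = o_minus_e, variance = v, test_name = test_name),
    class = "survdiff_test")
}

#' Two-group log-rank test
#'
#' Classic (unweighted) log-rank comparison of two survival distributions:
#' at each distinct event time the observed events in group A are compared
#' with their hypergeometric expectation given the pooled risk set; the
#' statistic is `(sum(O-E))^2 / sum(V)` referred to a chi-square with one
#' degree of freedom.
#'
#' @param groupA,groupB Tibbles with columns `time`, `event`.
#' @return An object of class `"survdiff_test"` with elements `statistic`,
#'   `df`, `p`, `observed_minus_expected`, `variance`, `test_name`.
#' @export
logrank_test <- function(groupA, groupB) {
  weighted_logrank(groupA, groupB, function(n_j) 1, "log-rank")
}

#' Gehan-Breslow generalized Wilcoxon test
#'
#' Weighted log-rank test with weight equal to the pooled number at risk at
#' each event time, emphasising early differences; reduces to the log-rank
#' statistic when all events share one time.
#'
#' @inheritParams logrank_test
#' @return An object of class `"survdiff_test"`.
#' @export
gehan_wilcoxon_test <- function(groupA, groupB) {
  weighted_logrank(groupA, groupB, function(n_j) n_j, "Gehan-Breslow-Wilcoxon")
}

#' @export
print.survdiff_test <- function(x, ...) {
  cat(sprintf("%s test: chi-square = %.4g on %d df, p = %.4g\n",
              x$test_name, x$statistic, x$df, x$p))
  invisible(x)
}

#' @export
tidy.survdiff_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = as.integer(x$df), p.value = x$p,
         method = x$test_name)
}

#' @export
glance.survdiff_test <- function(x, ...) tidy(x)

#' @export
tidy.km_curve <- function(x, ...) {
  tibble(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
         n_censor = x$n_censor, estimate = x$survival)
}

#' @export
glance.km_curve <- function(x, ...) {
  med <- if (any(x$survival <= 0.5)) x$time[which(x$survival <= 0.5)[1]] else NA_real_
  tibble(n = attr(x, "n"), events = attr(x, "n_events"), median_survival = med)
}

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability")
}

#' Kaplan-Meier curves and tests for two expression groups
#'
#' Convenience wrapper combining [stratify_high()], [truncate_followup()],
#' [km_estimate()], [logrank_test()] and [gehan_wilcoxon_test()] for one
#' gene against a clinical table.
#'
#' @param expr Genes x samples expression matrix.
#' @param gene Gene symbol (row of `expr`).
#' @param clinical Clinical tibble with `sample_id`, `time_months`, `event`.
#' @param max_months Follow-up cap (see [truncate_followup()]).
#' @param k MAD multiplier for the cutoff.
#' @return A list with `groups` (stratification tibble), `curves` (named
#'   list of `"km_curve"`), `logrank` and `gehan` test results.
#' @export
survival_by_expression <- function(expr, gene, clinical, max_months = 120, k = 1) {
  if (!gene %in% rownames(expr)) {
    abort(paste0("gene absent from expression matrix: ", gene),
          class = "consigamp_validation_error")
  }
  shared <- intersect(colnames(expr), clinical$sample_id)
  cl <- clinical %>%
    filter(.data$sample_id %in% shared, !is.na(.data$time_months), !is.na(.data$event))
  strat <- stratify_high(expr[gene, cl$sample_id], k = k)
  rec <- cl %>%
    left_join(strat, by = c(sample_id = "sample")) %>%
    rename(time = "time_months") %>%
    truncate_followup(max_months)
  hi <- rec %>% filter(.data$group == "high")
  lo <- rec %>% filter(.data$group == "rest")
  if (nrow(hi) == 0) {
    abort(sprintf(
      "empty 'high' group at cutoff %.4g (expression range %.4g-%.4g)",
      attr(strat, "cutoff"), min(strat$value), max(strat$value)),
      class = "consigamp_degenerate_error")
  }
  list(
    groups = strat,
    cutoff = attr(strat, "cutoff"),
    curves = list(high = km_estimate(hi), rest = km_estimate(lo)),
    logrank = logrank_test(hi, lo),
    gehan = gehan_wilcoxon_test(hi, lo)
  )
}
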