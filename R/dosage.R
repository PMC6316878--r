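#' Restricted mean survival time of a Kaplan-Meier curve
#'
#' Area under the survival step function from 0 to `horizon`; the curve is 1
#' before the first observed time and stays flat after the last one.
#'
#' @param curve a [km_estimate()] result (or `times`/`events` vectors via
#'   `...` when `curve` is NULL).
#' @param horizon integration horizon in months (default 120).
#' @return RMST in months.
#' @export
km_rmst <- function(curve, horizon = 120) {
  stopifnot(inherits(curve, "survival_curve"))
  keep <- curve$time <= horizon
  tt <- c(0, curve$time[keep], horizon)
  ss <- c(1, curve$surv[keep])   # survival over (t_i, t_{i+1}] is S(t_i)
  sum(diff(tt) * ss)
}

.rmst <- function(times, events, horizon = 120) {
  km_rmst(km_estimate(pmin(times, horizon), events & times <= horizon),
          horizon)
}

#' Gene-dosage consistency check on the survival endpoint
#'
#' Variants where the heterozygote shows the most extreme outcome relative
#' to both homozygotes violate a gene-dosage relationship and are excluded.
#' The per-group outcome scalar is the restricted mean survival time over
#' `[0, horizon]`; the verdict is `consistent` when the heterozygote RMST
#' lies weakly between the two homozygote RMSTs, `inconsistent` otherwise,
#' and `not-evaluable` (treated as a pass) when fewer than three genotype
#' groups are available.
#'
#' @param groups named list with elements `0`, `1`, `2` (those available),
#'   each a `list(times, events)`; alternatively `time`/`event`/`genotype`
#'   vectors in a single list.
#' @param horizon RMST horizon in months (default 120).
#' @return list of class `dosage_verdict`: `verdict`, `metric` (per-group
#'   RMST), `endpoint = "dfs"`.
#' @export
dosage_check_survival <- function(groups, horizon = 120) {
  if (!is.null(groups$genotype)) {
    g <- groups$genotype
    groups <- lapply(c(0, 1, 2), function(code) {
      sel <- !is.na(g) & g == code
      if (!any(sel)) return(NULL)
      list(times = groups$time[sel], events = groups$event[sel])
    })
    names(groups) <- c("0", "1", "2")
    groups <- Filter(Negate(is.null), groups)
  }
  if (any(vapply(groups, function(x) length(x[[1]]) == 0, logical(1)))) {
    stop("empty genotype group", call. = FALSE)
  }
  metric <- vapply(groups, function(x) .rmst(x[[1]], as.logical(x[[2]]),
                                             horizon), numeric(1))
  .dosage_verdict(metric, names(groups), "dfs")
}

#' Gene-dosage consistency check on the response endpoint
#'
#' Same betweenness rule as [dosage_check_survival()] with the responder
#' proportion as the per-genotype scalar.
#'
#' @param table contingency matrix with genotype rows (`0`, `1`, `2`) and
#'   responder/non-responder columns.
#' @return list of class `dosage_verdict`.
#' @export
dosage_check_response <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 3) {
    return(.dosage_verdict(stats::setNames(rowSums(table) * NA_real_,
                                           rownames(table)),
                           rownames(table), "response"))
  }
  if (any(rowSums(table) == 0)) stop("zero-total genotype row", call. = FALSE)
  prop <- table[, 1] / rowSums(table)
  .dosage_verdict(prop, rownames(table), "response")
}

.dosage_verdict <- function(metric, group_names, endpoint) {
  names(metric) <- group_names
  if (length(metric) < 3 || anyNA(metric)) {
    verdict <- "not-evaluable"
  } else {
    het <- metric[2]
    homs <- metric[c(1, 3)]
    verdict <- if (min(homs) <= het && het <= max(homs)) "consistent"
               else "inconsistent"
  }
  structure(list(verdict = verdict, metric = metric, endpoint = endpoint),
            class = "dosage_verdict")
}
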