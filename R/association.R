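#' Pearson chi-square test for a response contingency table
#'
#' Genotype groups (2 or 3 rows after collapsing) against
#' responder/non-responder columns. No continuity correction; the p-value is
#' the upper chi-square tail with `(rows - 1) * (cols - 1)` degrees of
#' freedom.
#'
#' @param table integer matrix, rows = genotype groups, columns =
#'   responder/non-responder.
#' @return list with `statistic`, `df`, `raw_p`.
#' @export
response_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || nrow(table) < 2 || ncol(table) < 2) {
    stop("need a non-negative table with >= 2 rows and columns", call. = FALSE)
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: zero row or column total", call. = FALSE)
  }
  n <- sum(table)
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       raw_p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Administrative truncation of disease-free survival
#'
#' Follow-up is capped at `horizon` months: any DFS value strictly greater
#' than the horizon is set to the horizon and censored; values at or below
#' the horizon are unchanged.
#'
#' @param dfs_months non-negative times in months.
#' @param event logical event indicators.
#' @param horizon truncation horizon (default 120 months).
#' @return data.frame with truncated `dfs_months` and `dfs_event`.
#' @export
truncate_dfs <- function(dfs_months, event, horizon = 120) {
  if (any(dfs_months < 0, na.rm = TRUE)) stop("negative DFS time", call. = FALSE)
  over <- !is.na(dfs_months) & dfs_months > horizon
  data.frame(dfs_months = ifelse(over, horizon, dfs_months),
             dfs_event = ifelse(over, FALSE, event))
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention: subjects censored at an event time are counted at
#' risk at that time (events precede censorings within a tied time).
#'
#' @param times non-negative follow-up times.
#' @param events logical event indicators.
#' @return data.frame of class `survival_curve` with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (one row per distinct time).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events))
  ut <- sort(unique(times))
  n_event <- vapply(ut, function(t) sum(times == t & events), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & !events), numeric(1))
  n_risk <- length(times) - c(0, cumsum(n_event + n_censor))[seq_along(ut)]
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("survival_curve", "data.frame"))
}

# k-group log-rank statistic with hypergeometric variance.
# Returns the chi-square statistic, df and a degeneracy flag (no events or
# a single populated group).
.logrank_stat <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  ut <- sort(unique(time[event]))
  if (k < 2 || length(ut) == 0) {
    return(list(stat = 0, df = max(k - 1, 1), degenerate = TRUE))
  }
  J <- length(ut)
  n_jg <- matrix(0, J, k)
  d_jg <- matrix(0, J, k)
  levs <- levels(group)
  for (g in seq_len(k)) {
    tg <- sort(time[group == levs[g]])
    n_jg[, g] <- length(tg) - findInterval(ut, tg, left.open = TRUE)
    te <- time[group == levs[g] & event]
    d_jg[, g] <- tabulate(match(te, ut), nbins = J)
  }
  n_j <- rowSums(n_jg)
  d_j <- rowSums(d_jg)
  O <- colSums(d_jg)
  W <- n_jg / n_j
  E <- colSums(d_j * W)
  cj <- d_j * (n_j - d_j) / pmax(n_j - 1, 1)
  V <- diag(colSums(cj * W), k) - crossprod(W, cj * W)
  z <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(crossprod(z, solve(Vk, z))), error = function(e) {
    s <- svd(Vk)
    pos <- s$d > max(s$d) * 1e-10
    drop(crossprod(z, s$v[, pos, drop = FALSE] %*%
                        ((t(s$u[, pos, drop = FALSE]) %*% z) / s$d[pos])))
  })
  list(stat = max(stat, 0), df = k - 1, degenerate = FALSE)
}

#' K-group log-rank test
#'
#' @param groups either a list of per-group `list(times, events)` elements,
#'   or a single list with `time`, `event` and a `group` factor.
#' @return list with `statistic`, `df`, `raw_p`, and `degenerate` (TRUE when
#'   no events are available, in which case `raw_p` is 1 by convention).
#' @export
logrank <- function(groups) {
  if (!is.null(groups$group)) {
    time <- groups$time; event <- groups$event; grp <- groups$group
  } else {
    if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
    if (any(vapply(groups, function(g) length(g[[1]]) == 0, logical(1)))) {
      stop("empty group", call. = FALSE)
    }
    time <- unlist(lapply(groups, `[[`, 1))
    event <- unlist(lapply(groups, `[[`, 2))
    grp <- factor(rep(seq_along(groups),
                      vapply(groups, function(g) length(g[[1]]), integer(1))))
  }
  r <- .logrank_stat(time, as.logical(event), grp)
  p <- if (r$degenerate) 1 else stats::pchisq(r$stat, r$df, lower.tail = FALSE)
  list(statistic = r$stat, df = r$df, raw_p = p, degenerate = r$degenerate)
}

# B within-stratum permutations of 1..n as a B x n index matrix
.gen_perms <- function(n, B, strata = NULL, seed = 1L) {
  set.seed(seed)
  idx <- matrix(rep(seq_len(n), each = B), nrow = B)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    cols <- which(strata == s)
    if (length(cols) > 1) {
      for (b in seq_len(B)) idx[b, cols] <- cols[sample.int(length(cols))]
    }
  }
  idx
}

#' Permutation-adjusted p-value for one variant
#'
#' Monte-Carlo multiplicity adjustment: the outcome vector is permuted `B`
#' times (within strata when given), the raw test p-value is recomputed for
#' every permutation, and the adjusted p-value is
#' `(1 + #\{permuted p <= observed p\}) / (B + 1)` (add-one rule, so the
#' result is never 0). Defaults follow the pipeline convention of 1000
#' permutations for the response endpoint and 100 for survival.
#'
#' @param test `"response_chisq"` or `"dfs_logrank"`.
#' @param outcome for response: a factor/character vector with values
#'   `responder`/`non-responder` (NA allowed); for survival: a data.frame
#'   with columns `time` (or `dfs_months`) and `event` (or `dfs_event`).
#' @param genotype_groups factor of (possibly collapsed) genotype groups,
#'   aligned with the outcome; NA entries are excluded from the test but the
#'   permutation is applied to the full outcome vector first, mirroring
#'   permutation of the original data.
#' @param B number of permutations (default 1000 for response, 100 for
#'   survival).
#' @param strata optional stratification factor; labels are permuted within
#'   strata only.
#' @param seed integer seed; identical seed gives identical permutations.
#' @return list of class `assoc_result`: `test`, `raw_p`, `adjusted_p`,
#'   `n_permutations`, `statistic`, `group_counts`, `flag` (`"ok"`,
#'   `"degenerate_outcome"` or `"degenerate_groups"`).
#' @export
perm_adjust <- function(test = c("response_chisq", "dfs_logrank"),
                        outcome, genotype_groups, B = NULL, strata = NULL,
                        seed = 1L) {
  test <- match.arg(test)
  if (is.null(B)) B <- if (test == "response_chisq") 1000L else 100L
  stopifnot(B >= 1)
  grp <- droplevels(as.factor(genotype_groups))
  if (test == "response_chisq") {
    y <- as.character(outcome)
    y[!y %in% c("responder", "non-responder")] <- NA
    defined <- !is.na(y)
    n <- length(y)
    eval_one <- function(yy) {
      keep <- !is.na(yy) & !is.na(grp)
      g <- droplevels(grp[keep])
      if (nlevels(g) < 2 || length(unique(yy[keep])) < 2) return(NULL)
      tab <- table(g, factor(yy[keep], c("responder", "non-responder")))
      if (any(colSums(tab) == 0)) return(NULL)
      response_chisq(tab)
    }
    obs <- eval_one(y)
    counts <- table(grp[defined])
  } else {
    if (!is.null(outcome$dfs_months)) {
      tt <- outcome$dfs_months; ee <- outcome$dfs_event
    } else {
      tt <- outcome$time; ee <- outcome$event
    }
    defined <- !is.na(tt) & !is.na(ee)
    n <- length(tt)
    eval_one <- function(ti, ev) {
      keep <- !is.na(ti) & !is.na(ev) & !is.na(grp)
      g <- droplevels(grp[keep])
      if (nlevels(g) < 2) return(NULL)
      r <- .logrank_stat(ti[keep], as.logical(ev[keep]), g)
      if (r$degenerate) return(NULL)
      list(statistic = r$stat, df = r$df,
           raw_p = stats::pchisq(r$stat, r$df, lower.tail = FALSE))
    }
    obs <- eval_one(tt, ee)
    counts <- table(grp[defined])
  }
  if (is.null(obs)) {
    return(structure(list(test = test, raw_p = 1, adjusted_p = 1,
                          n_permutations = B, statistic = NA_real_,
                          group_counts = counts,
                          flag = if (nlevels(grp) < 2) "degenerate_groups"
                                 else "degenerate_outcome"),
                     class = "assoc_result"))
  }
  perms <- .gen_perms(n, B, strata = strata, seed = seed)
  hits <- 0L
  thr <- obs$raw_p * (1 + 1e-9)
  for (b in seq_len(B)) {
    pb <- if (test == "response_chisq") eval_one(y[perms[b, ]])
          else eval_one(tt[perms[b, ]], ee[perms[b, ]])
    p_b <- if (is.null(pb)) 1 else pb$raw_p
    if (p_b <= thr) hits <- hits + 1L
  }
  structure(list(test = test, raw_p = obs$raw_p,
                 adjusted_p = (1 + hits) / (B + 1),
                 n_permutations = B, statistic = obs$statistic,
                 group_counts = counts, flag = "ok"),
            class = "assoc_result")
}

# Vectorized permutation scan for the response endpoint: one shared set of
# outcome permutations is evaluated against every variant's group factor.
# glist: named list of group factors (NA = missing call), y: character
# outcome vector. Returns a data.frame.
.perm_scan_response <- function(glist, y, B = 1000L, seed = 1L) {
  y <- as.character(y)
  y[!y %in% c("responder", "non-responder")] <- NA
  n <- length(y)
  perms <- .gen_perms(n, B, seed = seed)
  Y <- matrix(y[t(perms)], nrow = B, byrow = TRUE) == "responder"
  rows <- lapply(names(glist), function(v) {
    grp <- droplevels(as.factor(glist[[v]]))
    keep <- !is.na(grp) & !is.na(y)
    g <- droplevels(grp[keep])
    k <- nlevels(g)
    if (k < 2 || length(unique(y[keep])) < 2) {
      return(data.frame(variant_id = v, raw_p = 1, adjusted_p = 1,
                        statistic = NA_real_, df = NA_integer_,
                        flag = "degenerate", stringsAsFactors = FALSE))
    }
    G <- stats::model.matrix(~ 0 + g)
    tot <- colSums(G)
    obs <- response_chisq(table(g, factor(y[keep],
                                          c("responder", "non-responder"))))
    Yk <- Y[, keep, drop = FALSE]
    Yk[is.na(Yk)] <- FALSE  # permuted NA outcomes count as non-responder? no:
    # NA outcomes never reach `keep` columns when y is NA there, but a
    # permutation can move an NA outcome onto a kept sample; treat that
    # sample as missing by dropping it from both margins.
    M <- !is.na(Y[, keep, drop = FALSE])
    R <- (Yk * M) %*% G                   # responders per group, B x k
    Ntot <- M %*% G                       # non-missing per group, B x k
    Nn <- Ntot - R
    Rs <- rowSums(R); Ns <- rowSums(Ntot)
    Er <- Rs * Ntot / Ns
    En <- (Ns - Rs) * Ntot / Ns
    X2 <- rowSums((R - Er)^2 / Er + (Nn - En)^2 / En)
    p_b <- stats::pchisq(X2, df = k - 1, lower.tail = FALSE)
    p_b[!is.finite(p_b)] <- 1
    adj <- (1 + sum(p_b <= obs$raw_p * (1 + 1e-9))) / (B + 1)
    data.frame(variant_id = v, raw_p = obs$raw_p, adjusted_p = adj,
               statistic = obs$statistic, df = obs$df, flag = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Permutation scan for the survival endpoint (shared permutations, optional
# strata). time/event may contain NA (lost to follow-up).
.perm_scan_dfs <- function(glist, time, event, B = 100L, strata = NULL,
                           seed = 1L) {
  n <- length(time)
  perms <- .gen_perms(n, B, strata = strata, seed = seed)
  rows <- lapply(names(glist), function(v) {
    grp <- droplevels(as.factor(glist[[v]]))
    eval_one <- function(ti, ev) {
      keep <- !is.na(ti) & !is.na(ev) & !is.na(grp)
      g <- droplevels(grp[keep])
      if (nlevels(g) < 2) return(NULL)
      r <- .logrank_stat(ti[keep], as.logical(ev[keep]), g)
      if (r$degenerate) return(NULL)
      list(stat = r$stat, df = r$df,
           p = stats::pchisq(r$stat, r$df, lower.tail = FALSE))
    }
    obs <- eval_one(time, event)
    if (is.null(obs)) {
      return(data.frame(variant_id = v, raw_p = 1, adjusted_p = 1,
                        statistic = NA_real_, df = NA_integer_,
                        flag = "degenerate", stringsAsFactors = FALSE))
    }
    thr <- obs$p * (1 + 1e-9)
    hits <- 0L
    for (b in seq_len(B)) {
      pb <- eval_one(time[perms[b, ]], event[perms[b, ]])
      if ((if (is.null(pb)) 1 else pb$p) <= thr) hits <- hits + 1L
    }
    data.frame(variant_id = v, raw_p = obs$p,
               adjusted_p = (1 + hits) / (B + 1),
               statistic = obs$stat, df = obs$df, flag = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.fit_flag <- function(coefs, ses, converged) {
  if (!converged) return("non-convergence")
  if (any(!is.finite(coefs)) || any(!is.finite(ses))) return("non-convergence")
  if (any(abs(coefs) > 10) || any(ses > 100)) return("separation")
  "ok"
}

#' Cox proportional-hazards fit for one variant
#'
#' Partial likelihood with Efron tie handling. The variant's p-value is the
#' likelihood-ratio test of the model with the variant term against the
#' nested covariate-only model; the hazard ratio carries a Wald 95% CI.
#' Non-convergence and monotone-likelihood/separation patterns are flagged
#' rather than silently reported.
#'
#' @param times,events survival outcome (events logical).
#' @param variant_dose numeric dose (0/1/2 or collapsed 0/1) or a group
#'   factor.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list of class `cox_fit`: `coef`, `hr`, `ci` (length 2), `p_lrt`,
#'   `flag`, `n`, `n_events`, `covariates`.
#' @export
cox_fit <- function(times, events, variant_dose, covariates = NULL) {
  keep <- !is.na(times) & !is.na(events) & !is.na(variant_dose)
  dat <- data.frame(.time = times, .event = as.logical(events),
                    .dose = variant_dose)
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  dat <- dat[keep, , drop = FALSE]
  if (sum(dat$.event) < 1) stop("no events in data", call. = FALSE)
  covs <- if (is.null(covariates)) character(0) else colnames(covariates)
  rhs0 <- if (length(covs)) paste(sprintf("`%s`", covs), collapse = " + ")
          else "1"
  f1 <- stats::as.formula(paste("survival::Surv(.time, .event) ~ .dose +",
                                rhs0))
  f0 <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs0))
  warned <- FALSE
  fit1 <- withCallingHandlers(
    survival::coxph(f1, data = dat, ties = "efron"),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
  fit0 <- suppressWarnings(survival::coxph(f0, data = dat, ties = "efron"))
  ll1 <- fit1$loglik[length(fit1$loglik)]
  ll0 <- fit0$loglik[length(fit0$loglik)]
  dose_idx <- grep("^\\.dose", names(stats::coef(fit1)))
  lrt <- max(0, 2 * (ll1 - ll0))
  df <- length(dose_idx)
  beta <- stats::coef(fit1)[dose_idx]
  se <- sqrt(diag(fit1$var))[dose_idx]
  flag <- .fit_flag(beta, se, !warned || all(is.finite(beta)))
  if (warned && any(abs(beta) > 10)) flag <- "monotone-likelihood"
  structure(list(coef = beta, hr = exp(beta),
                 ci = exp(cbind(beta - 1.96 * se, beta + 1.96 * se)),
                 se = se,
                 p_lrt = stats::pchisq(lrt, df, lower.tail = FALSE),
                 flag = flag, n = nrow(dat), n_events = sum(dat$.event),
                 covariates = covs),
            class = "cox_fit")
}

#' Binary logistic regression fit for one variant
#'
#' Binomial likelihood; LRT of the variant term against the covariate-only
#' model; odds ratio with Wald 95% CI. Perfect separation is flagged.
#'
#' @param response factor/character `responder`/`non-responder` (responder
#'   modelled as the success), or logical.
#' @param variant_dose numeric dose or group factor.
#' @param covariates optional data.frame of adjustment covariates.
#' @return list of class `logistic_fit`: `coef`, `or`, `ci`, `p_lrt`,
#'   `flag`, `n`, `covariates`.
#' @export
logistic_fit <- function(response, variant_dose, covariates = NULL) {
  if (!is.logical(response)) {
    response <- as.character(response) == "responder"
  }
  keep <- !is.na(response) & !is.na(variant_dose)
  dat <- data.frame(.y = response, .dose = variant_dose)
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    keep <- keep & stats::complete.cases(covariates)
  }
  dat <- dat[keep, , drop = FALSE]
  if (length(unique(dat$.y)) < 2) {
    stop("degenerate outcome: all responses identical", call. = FALSE)
  }
  covs <- if (is.null(covariates)) character(0) else colnames(covariates)
  rhs0 <- if (length(covs)) paste(sprintf("`%s`", covs), collapse = " + ")
          else "1"
  warned <- FALSE
  fit1 <- withCallingHandlers(
    stats::glm(stats::as.formula(paste(".y ~ .dose +", rhs0)),
               family = stats::binomial(), data = dat),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
  fit0 <- suppressWarnings(
    stats::glm(stats::as.formula(paste(".y ~", rhs0)),
               family = stats::binomial(), data = dat))
  dose_idx <- grep("^\\.dose", names(stats::coef(fit1)))
  lrt <- max(0, fit0$deviance - fit1$deviance)
  df <- length(dose_idx)
  beta <- stats::coef(fit1)[dose_idx]
  se <- sqrt(diag(stats::vcov(fit1)))[dose_idx]
  flag <- .fit_flag(beta, se, fit1$converged)
  if (warned && flag == "ok") flag <- "separation"
  structure(list(coef = beta, or = exp(beta),
                 ci = exp(cbind(beta - 1.96 * se, beta + 1.96 * se)),
                 se = se,
                 p_lrt = stats::pchisq(lrt, df, lower.tail = FALSE),
                 flag = flag, n = nrow(dat), covariates = covs),
            class = "logistic_fit")
}

#' Multiple-testing adjustment
#'
#' Wrapper over the standard step procedures with the pipeline's method
#' vocabulary; `fdr_bh` is Benjamini-Hochberg.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param method one of `bonferroni`, `holm`, `hochberg`, `hommel`,
#'   `fdr_bh`.
#' @return adjusted p-values, clipped to 1, in the input order.
#' @export
adjust_pvalues <- function(p_values,
                           method = c("bonferroni", "holm", "hochberg",
                                      "hommel", "fdr_bh")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = switch(method, fdr_bh = "BH", method))
}
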