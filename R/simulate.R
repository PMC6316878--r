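#' Simulation configuration for synthetic cohorts
#'
#' Describes a synthetic breast-cancer pharmacogenomic cohort: biallelic
#' variant panel with given minor allele frequencies, optional departure from
#' Hardy-Weinberg equilibrium, planted logistic genotype-to-response effects,
#' planted proportional-hazards genotype-to-DFS effects with independent
#' exponential censoring and an administrative follow-up horizon, completely
#' at random missing calls, and clinical covariates drawn from the marginal
#' composition typical of a validation-scale cohort.
#'
#' Defaults emulate the validation-scale cohort the pipeline targets:
#' 805 samples, 55 variants with MAFs spread over 0.05-0.48, a 75% baseline
#' responder rate among neoadjuvant patients, a baseline recurrence hazard of
#' 0.003 events/month (roughly 30% cumulative events over the 120-month
#' horizon), exponential loss-to-follow-up at 0.005/month, and a 0.6% missing
#' call rate.
#'
#' @param n_samples number of patients.
#' @param n_variants number of panel variants.
#' @param maf_vector per-variant minor allele frequencies in `[0, 0.5]`;
#'   recycled to `n_variants`.
#' @param inbreeding_f per-variant inbreeding coefficient; 0 means exact HWE.
#'   Must satisfy `f >= -min(p,q)/max(p,q)` and `f <= 1` for every variant.
#' @param effect_map `NULL` or a data.frame with columns `variant` (index or
#'   id), `model` (`"additive"`, `"dominant"`, `"recessive"`),
#'   `response_or` (odds ratio per dose unit) and `dfs_hr` (hazard ratio per
#'   dose unit). Variants not listed are null (OR = HR = 1).
#' @param baseline_response_rate responder probability at dose 0.
#' @param baseline_hazard recurrence hazard (events/month) at dose 0.
#' @param censoring_rate exponential loss-to-follow-up rate (events/month).
#' @param followup_horizon administrative censoring horizon in months.
#' @param missing_rate per-call missing probability.
#' @param covariate_spec named list of category probabilities for `arm`,
#'   `stage`, `grade`, `er`, `pr`, `her2`, `subtype`.
#' @param confound_variant optional variant index whose dose shifts the
#'   stage distribution (hook for testing multivariate adjustment); `NULL`
#'   for independent covariates.
#' @param seed integer; the single global seed. Stage substreams (genotypes,
#'   response, survival, missingness, covariates) are derived from it
#'   deterministically.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 805L,
                              n_variants = 55L,
                              maf_vector = seq(0.05, 0.48,
                                               length.out = n_variants),
                              inbreeding_f = 0,
                              effect_map = NULL,
                              baseline_response_rate = 0.75,
                              baseline_hazard = 0.003,
                              censoring_rate = 0.005,
                              followup_horizon = 120,
                              missing_rate = 0.006,
                              covariate_spec = default_covariate_spec(),
                              confound_variant = NULL,
                              seed = 1L) {
  maf_vector <- rep_len(maf_vector, n_variants)
  inbreeding_f <- rep_len(inbreeding_f, n_variants)
  if (n_samples < 1 || n_variants < 1) {
    stop("n_samples and n_variants must be positive", call. = FALSE)
  }
  if (any(maf_vector < 0 | maf_vector > 0.5)) {
    stop("maf_vector entries must lie in [0, 0.5]", call. = FALSE)
  }
  p <- 1 - maf_vector
  q <- maf_vector
  fmin <- ifelse(q > 0 & q < 1, -pmin(p, q) / pmax(p, q), 0)
  if (any(inbreeding_f < fmin - 1e-12 | inbreeding_f > 1)) {
    stop("inbreeding_f outside admissible range [-min(p,q)/max(p,q), 1]",
         call. = FALSE)
  }
  if (!is.null(effect_map)) {
    effect_map <- as.data.frame(effect_map)
    need <- c("variant", "model", "response_or", "dfs_hr")
    if (!all(need %in% names(effect_map))) {
      stop("effect_map needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (!all(effect_map$model %in% c("additive", "dominant", "recessive"))) {
      stop("unknown effect model in effect_map", call. = FALSE)
    }
    if (any(effect_map$response_or <= 0) || any(effect_map$dfs_hr <= 0)) {
      stop("odds and hazard ratios must be positive", call. = FALSE)
    }
    if (is.numeric(effect_map$variant) &&
        any(effect_map$variant < 1 | effect_map$variant > n_variants)) {
      stop("effect_map refers to variants outside the panel", call. = FALSE)
    }
  }
  stopifnot(baseline_response_rate >= 0, baseline_response_rate <= 1,
            baseline_hazard > 0, censoring_rate >= 0, followup_horizon > 0,
            missing_rate >= 0, missing_rate < 1)
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              maf_vector = maf_vector,
              inbreeding_f = inbreeding_f,
              effect_map = effect_map,
              baseline_response_rate = baseline_response_rate,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              followup_horizon = followup_horizon,
              missing_rate = missing_rate,
              covariate_spec = covariate_spec,
              confound_variant = confound_variant,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Default clinical covariate composition
#'
#' Marginal category probabilities mirroring a validation-scale cohort:
#' mostly hormonally treated luminal disease, about a fifth of patients
#' treated neoadjuvantly, stage I/II predominant.
#'
#' @return named list of probability vectors.
#' @export
default_covariate_spec <- function() {
  list(
    arm = c(neoadjuvant = 0.21, adjuvant = 0.26, hormonal_only = 0.43,
            none = 0.10),
    stage = c(S0 = 0.08, SI = 0.47, SII = 0.37, SIII = 0.08),
    grade = c(G1 = 0.23, G2 = 0.50, G3 = 0.27),
    er = c(positive = 0.77, negative = 0.23),
    pr = c(positive = 0.73, negative = 0.27),
    her2 = c(positive = 0.24, negative = 0.76),
    subtype = c(`luminal A` = 0.41, `luminal B` = 0.39, HER2 = 0.08,
                `triple negative` = 0.12)
  )
}

# per-variant dose under a genetic model; g in {0,1,2}
.dose <- function(g, model) {
  switch(model,
         additive = g,
         dominant = as.integer(g >= 1),
         recessive = as.integer(g == 2),
         stop("unknown model: ", model))
}

# resolve effect_map rows to variant indices
.effect_rows <- function(cfg, variant_ids) {
  em <- cfg$effect_map
  if (is.null(em) || nrow(em) == 0) return(NULL)
  idx <- if (is.numeric(em$variant)) as.integer(em$variant)
         else match(as.character(em$variant), variant_ids)
  if (anyNA(idx)) stop("effect_map refers to unknown variants", call. = FALSE)
  em$.idx <- idx
  em
}

#' Draw genotypes under (possibly perturbed) Hardy-Weinberg proportions
#'
#' Each variant's genotypes are i.i.d. draws with
#' `P(het) = 2pq(1-f)`, `P(common hom) = p^2 + pqf`,
#' `P(rare hom) = q^2 + pqf`, where `q` is the MAF and `f` the inbreeding
#' coefficient (`f = 0` gives exact HWE).
#'
#' @param cfg a [simulation_config()].
#' @return a [genotype_matrix()] with variants `v1..vK`, samples `s1..sN`.
#' @export
gen_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(sub_seed(cfg$seed, "genotypes"))
  q <- cfg$maf_vector
  p <- 1 - q
  f <- cfg$inbreeding_f
  probs <- cbind(p^2 + p * q * f, 2 * p * q * (1 - f), q^2 + p * q * f)
  calls <- matrix(NA_integer_, cfg$n_variants, cfg$n_samples)
  for (v in seq_len(cfg$n_variants)) {
    calls[v, ] <- sample(0:2, cfg$n_samples, replace = TRUE, prob = probs[v, ])
  }
  genotype_matrix(calls,
                  variant_ids = sprintf("v%d", seq_len(cfg$n_variants)),
                  sample_ids = sprintf("s%d", seq_len(cfg$n_samples)))
}

#' Simulate therapy response under a logistic genotype model
#'
#' `logit P(response) = logit(baseline) + sum over planted effects of
#' log(OR) * dose(g, model)`. Labels are drawn for every sample; the cohort
#' assembler restricts them to neoadjuvantly treated patients.
#'
#' @param genotypes a [genotype_matrix()].
#' @param cfg the [simulation_config()] that produced it.
#' @return factor with levels `responder`, `non-responder`, one per sample.
#' @export
gen_response <- function(genotypes, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(sub_seed(cfg$seed, "response"))
  eta <- rep(stats::qlogis(cfg$baseline_response_rate), ncol(genotypes))
  em <- .effect_rows(cfg, rownames(genotypes))
  if (!is.null(em)) {
    for (r in seq_len(nrow(em))) {
      g <- genotypes[em$.idx[r], ]
      d <- .dose(ifelse(is.na(g), 0L, g), em$model[r])
      eta <- eta + log(em$response_or[r]) * d
    }
  }
  pr <- stats::plogis(eta)
  lab <- ifelse(stats::runif(length(pr)) < pr, "responder", "non-responder")
  factor(lab, levels = c("responder", "non-responder"))
}

#' Simulate disease-free survival under proportional hazards
#'
#' Event times are exponential with hazard
#' `baseline_hazard * prod(HR^dose)`; censoring is the minimum of an
#' independent exponential at `censoring_rate` and the administrative
#' follow-up horizon. The event flag is true when the event time precedes
#' both.
#'
#' @param genotypes a [genotype_matrix()].
#' @param cfg the [simulation_config()].
#' @return data.frame with `dfs_months` and logical `dfs_event`.
#' @export
gen_survival <- function(genotypes, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(sub_seed(cfg$seed, "survival"))
  n <- ncol(genotypes)
  loghr <- rep(0, n)
  em <- .effect_rows(cfg, rownames(genotypes))
  if (!is.null(em)) {
    for (r in seq_len(nrow(em))) {
      g <- genotypes[em$.idx[r], ]
      d <- .dose(ifelse(is.na(g), 0L, g), em$model[r])
      loghr <- loghr + log(em$dfs_hr[r]) * d
    }
  }
  t_event <- stats::rexp(n, rate = cfg$baseline_hazard * exp(loghr))
  t_cens <- if (cfg$censoring_rate > 0) stats::rexp(n, cfg$censoring_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_cens, cfg$followup_horizon)
  data.frame(dfs_months = pmin(t_event, t_cens),
             dfs_event = t_event <= t_cens)
}

#' Mask genotype calls completely at random
#'
#' @param matrix_ a [genotype_matrix()].
#' @param cfg the [simulation_config()]; `cfg$missing_rate` is the per-call
#'   independent masking probability.
#' @return the matrix with masked entries set to `NA`.
#' @export
gen_missing <- function(matrix_, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$missing_rate <= 0) return(matrix_)
  set.seed(sub_seed(cfg$seed, "missing"))
  mask <- stats::runif(length(matrix_)) < cfg$missing_rate
  matrix_[mask] <- NA_integer_
  matrix_
}

# draw one categorical covariate column
.draw_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Assemble a full synthetic cohort
#'
#' Runs [gen_genotypes()], [gen_response()], [gen_survival()] and
#' [gen_missing()] and builds the clinical table: therapy arm and covariates
#' from `covariate_spec`, response restricted to neoadjuvant patients
#' (`not-applicable` elsewhere), DFS months/event for patients not lost to
#' follow-up. A small fraction (1%) of patients is marked lost to follow-up
#' with DFS fields missing.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `genotypes` ([genotype_matrix()]) and
#'   `clinical` (data.frame, one row per sample).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  gm <- gen_genotypes(cfg)
  response <- gen_response(gm, cfg)
  surv <- gen_survival(gm, cfg)
  set.seed(sub_seed(cfg$seed, "covariates"))
  n <- cfg$n_samples
  spec <- cfg$covariate_spec
  clin <- data.frame(
    sample_id = colnames(gm),
    arm = .draw_cat(n, spec$arm),
    stage = .draw_cat(n, spec$stage),
    grade = .draw_cat(n, spec$grade),
    er = .draw_cat(n, spec$er),
    pr = .draw_cat(n, spec$pr),
    her2 = .draw_cat(n, spec$her2),
    subtype = .draw_cat(n, spec$subtype),
    stringsAsFactors = FALSE
  )
  if (!is.null(cfg$confound_variant)) {
    # confounding hook: rare-allele dose pushes patients toward higher stage
    d <- gm[cfg$confound_variant, ]
    d[is.na(d)] <- 0L
    shift <- stats::runif(n) < 0.3 * d
    lv <- levels(clin$stage)
    clin$stage <- factor(lv[pmin(as.integer(clin$stage) + shift, length(lv))],
                         levels = lv)
  }
  clin$lost_to_followup <- stats::runif(n) < 0.01
  clin$response <- ifelse(clin$arm == "neoadjuvant",
                          as.character(response), "not-applicable")
  clin$response <- factor(clin$response,
                          levels = c("responder", "non-responder",
                                     "not-applicable"))
  clin$dfs_months <- ifelse(clin$lost_to_followup, NA_real_, surv$dfs_months)
  clin$dfs_event <- ifelse(clin$lost_to_followup, NA, surv$dfs_event)
  gm <- gen_missing(gm, cfg)
  list(genotypes = gm, clinical = clin)
}
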