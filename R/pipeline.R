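#' Run configuration
#'
#' Validates the knobs of a pipeline run. Defaults mirror the analysis
#' conventions: 1000 permutations for the response endpoint, 100 for
#' survival, a 120-month administrative DFS horizon, and significance
#' declared at adjusted p < 0.05.
#'
#' @param phase `"testing"` or `"validation"`.
#' @param thresholds a [qc_thresholds()].
#' @param b_response,b_dfs permutation counts per endpoint.
#' @param dfs_horizon months.
#' @param alpha significance level on the adjusted p-value.
#' @param response_covariates,dfs_covariates covariate column names for the
#'   multivariate fits (defaults: stage for response; grade, stage, ER, PR
#'   for DFS).
#' @param max_panel_size validation panel size cap.
#' @param seed integer global seed.
#' @param paths optional named list of input file paths (`genotypes`,
#'   `clinical`, `evidence`); checked for existence when given.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(phase = c("testing", "validation"),
                       thresholds = qc_thresholds(),
                       b_response = 1000L, b_dfs = 100L,
                       dfs_horizon = 120, alpha = 0.05,
                       response_covariates = "stage",
                       dfs_covariates = c("grade", "stage", "er", "pr"),
                       max_panel_size = 58L, seed = 1L, paths = NULL) {
  phase <- match.arg(phase)
  stopifnot(alpha > 0, alpha < 1, b_response >= 1, b_dfs >= 1,
            dfs_horizon > 0, max_panel_size >= 1)
  if (!is.null(paths)) {
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files)) {
      stop("missing input file(s): ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(phase = phase, thresholds = thresholds,
                 b_response = as.integer(b_response),
                 b_dfs = as.integer(b_dfs), dfs_horizon = dfs_horizon,
                 alpha = alpha, response_covariates = response_covariates,
                 dfs_covariates = dfs_covariates,
                 max_panel_size = as.integer(max_panel_size),
                 seed = as.integer(seed), paths = paths),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file; keys as in [run_config()] (`thresholds` may be a
#'   mapping with `hwe_alpha`, `maf_min`, `max_missing_fraction`,
#'   `min_genotype_count`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  th <- if (!is.null(y$thresholds)) do.call(qc_thresholds, y$thresholds)
        else qc_thresholds()
  y$thresholds <- th
  do.call(run_config, y)
}

# collapsed group factors + uncollapsed genotype rows for a matrix
.group_factors <- function(gm, min_count) {
  out <- lapply(rownames(gm), function(v) genotype_groups(gm[v, ], min_count))
  names(out) <- rownames(gm)
  out
}

# additive dose on the collapsed scale (0-based group index)
.group_dose <- function(grp) as.integer(grp) - 1L

#' Testing-phase pipeline
#'
#' QC filter cascade, permutation-adjusted association per endpoint
#' (response: Pearson chi-square over neoadjuvant patients; DFS: log-rank
#' with permutations stratified by therapy arm and the administrative
#' 120-month truncation), gene-dosage gate on significant variants,
#' priority-matrix evidence integration and panel construction. Every
#' stage's variant counts are logged in the returned `funnel`.
#'
#' @param genotypes a [genotype_matrix()] (testing cohort).
#' @param clinical validated clinical table aligned to the genotype samples.
#' @param evidence evidence table ([read_evidence()] schema); may be empty.
#' @param cfg a [run_config()].
#' @return list: `panel`, `associations` (long data.frame over endpoints),
#'   `filter_report`, `priority_calls`, `dosage`, `funnel`.
#' @export
run_testing_phase <- function(genotypes, clinical, evidence,
                              cfg = run_config("testing")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  clinical <- validate_clinical(clinical)
  if (!identical(colnames(genotypes), clinical$sample_id)) {
    clinical <- clinical[match(colnames(genotypes), clinical$sample_id), ]
    if (anyNA(clinical$sample_id)) {
      stop("[qc] clinical table does not cover all genotyped samples",
           call. = FALSE)
    }
  }
  gm <- orient_genotypes(genotypes)
  th <- cfg$thresholds
  funnel <- list(input = nrow(gm))
  qc <- apply_filters(gm, th)
  gm <- qc$matrix
  funnel$qc_pass <- nrow(gm)

  glist <- .group_factors(gm, th$min_genotype_count)

  ## response endpoint: neoadjuvant patients only
  neo <- clinical$arm == "neoadjuvant"
  y <- ifelse(neo, as.character(clinical$response), NA)
  glist_neo <- lapply(glist, function(g) droplevels(g[neo]))
  resp <- .perm_scan_response(glist_neo, y[neo], B = cfg$b_response,
                              seed = sub_seed(cfg$seed, "perm_response"))
  resp$endpoint <- "response"

  ## DFS endpoint: patients with follow-up, truncated, strata = therapy arm
  fu <- !clinical$lost_to_followup
  tr <- truncate_dfs(clinical$dfs_months, clinical$dfs_event,
                     cfg$dfs_horizon)
  glist_fu <- lapply(glist, function(g) droplevels(g[fu]))
  dfs <- .perm_scan_dfs(glist_fu, tr$dfs_months[fu], tr$dfs_event[fu],
                        B = cfg$b_dfs,
                        strata = as.character(clinical$arm[fu]),
                        seed = sub_seed(cfg$seed, "perm_dfs"))
  dfs$endpoint <- "dfs"
  associations <- rbind(resp, dfs)

  sig_resp <- resp$variant_id[resp$adjusted_p < cfg$alpha & resp$flag == "ok"]
  sig_dfs <- dfs$variant_id[dfs$adjusted_p < cfg$alpha & dfs$flag == "ok"]
  funnel$significant <- length(union(sig_resp, sig_dfs))

  ## gene-dosage gate on significant variants; evaluated on the collapsed
  ## grouping, so variants whose sparse homozygote was merged away are
  ## not-evaluable (pass), mirroring the analysis order collapse -> gate
  dosage <- lapply(union(sig_resp, sig_dfs), function(v) {
    g <- gm[v, ]
    three <- nlevels(glist[[v]]) == 3
    verdicts <- character(0)
    if (v %in% sig_dfs) {
      verdicts["dfs"] <- if (!three) "not-evaluable"
        else dosage_check_survival(list(time = tr$dfs_months[fu],
                                        event = tr$dfs_event[fu],
                                        genotype = g[fu]),
                                   horizon = cfg$dfs_horizon)$verdict
    }
    if (v %in% sig_resp) {
      gg <- g[neo]
      yy <- y[neo]
      keep <- !is.na(gg) & !is.na(yy)
      tab <- table(factor(gg[keep], 0:2),
                   factor(yy[keep], c("responder", "non-responder")))
      verdicts["response"] <- if (!three || any(rowSums(tab) == 0))
        "not-evaluable" else dosage_check_response(tab)$verdict
    }
    data.frame(variant_id = v,
               endpoint = names(verdicts), verdict = unname(verdicts),
               stringsAsFactors = FALSE)
  })
  dosage <- if (length(dosage)) do.call(rbind, dosage)
            else data.frame(variant_id = character(), endpoint = character(),
                            verdict = character(), stringsAsFactors = FALSE)
  ## only the survival verdict excludes: the dosage relationship is
  ## evaluated on KM curves of DFS-associated variants; the response-side
  ## verdict is reported as a diagnostic column but does not gate
  drop_dosage <- unique(dosage$variant_id[dosage$verdict == "inconsistent" &
                                            dosage$endpoint == "dfs"])
  sig_resp <- setdiff(sig_resp, drop_dosage)
  sig_dfs <- setdiff(sig_dfs, drop_dosage)
  funnel$dosage_pass <- length(union(sig_resp, sig_dfs))

  ## evidence integration
  ev_ids <- if (nrow(evidence)) as.character(evidence$variant_id)
            else character(0)
  calls <- lapply(union(sig_resp, sig_dfs), function(v) {
    i <- match(v, ev_ids)
    if (is.na(i)) {
      return(data.frame(variant_id = v, significant_endpoint = "none",
                        insilico_call = "unknown", level = "unranked",
                        rationale = "no evidence record",
                        stringsAsFactors = FALSE))
    }
    .priority_call(evidence[i, , drop = FALSE],
                   v %in% sig_resp, v %in% sig_dfs)
  })
  priority_calls <- if (length(calls)) do.call(rbind, calls)
    else data.frame(variant_id = character(), significant_endpoint = character(),
                    insilico_call = character(), level = character(),
                    rationale = character(), stringsAsFactors = FALSE)
  panel <- build_panel(priority_calls, associations, cfg$max_panel_size)
  funnel$panel <- nrow(panel)
  list(panel = panel, associations = associations, filter_report = qc$report,
       priority_calls = priority_calls, dosage = dosage,
       funnel = unlist(funnel))
}

#' Validation-phase pipeline
#'
#' Re-tests the panel variants in an independent cohort: rare-genotype
#' collapsing, Pearson chi-square + permutation adjustment and
#' stage-adjusted logistic regression for response; log-rank + permutation
#' adjustment (stratified by therapy arm) on the cytotoxic-therapy subset
#' plus grade/stage/ER/PR-adjusted Cox regression for DFS; the gene-dosage
#' gate; and per-molecular-subtype log-rank tests. A panel variant is
#' `validated` when significant in this phase (adjusted p < alpha on either
#' endpoint) and dosage-consistent. Panel variants absent from the
#' validation genotypes are reported, not fatal. Patients lost to follow-up
#' are excluded from survival analyses but retained for response.
#'
#' @param genotypes validation-cohort [genotype_matrix()].
#' @param clinical validation clinical table.
#' @param panel data.frame with a `variant_id` column (testing-phase panel).
#' @param cfg a [run_config()].
#' @return list: `results` (per-variant data.frame), `subtype` (per-subtype
#'   log-rank p's), `missing_variants`, `maf` (per-variant genotype counts
#'   and MAF).
#' @export
run_validation_phase <- function(genotypes, clinical, panel,
                                 cfg = run_config("validation")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!nrow(panel)) stop("empty panel", call. = FALSE)
  clinical <- validate_clinical(clinical)
  clinical <- clinical[match(colnames(genotypes), clinical$sample_id), ]
  gm <- orient_genotypes(genotypes)
  present <- intersect(panel$variant_id, rownames(gm))
  missing_variants <- setdiff(panel$variant_id, present)
  if (!length(present)) stop("no panel variant present in validation genotypes",
                             call. = FALSE)
  th <- cfg$thresholds
  tr <- truncate_dfs(clinical$dfs_months, clinical$dfs_event, cfg$dfs_horizon)
  neo <- clinical$arm == "neoadjuvant"
  fu <- !clinical$lost_to_followup
  cyto <- clinical$arm %in% c("neoadjuvant", "adjuvant")
  y <- ifelse(neo, as.character(clinical$response), NA)

  glist <- .group_factors(genotype_matrix(gm[present, , drop = FALSE]),
                          th$min_genotype_count)
  ## response: chi-square + permutation, logistic adjusted to stage
  glist_neo <- lapply(glist, function(g) droplevels(g[neo]))
  resp <- .perm_scan_response(glist_neo, y[neo], B = cfg$b_response,
                              seed = sub_seed(cfg$seed, "val_response"))
  ## DFS on cytotoxic subset with follow-up, strata = therapy arm
  sel <- cyto & fu
  glist_cyto <- lapply(glist, function(g) droplevels(g[sel]))
  dfs <- .perm_scan_dfs(glist_cyto, tr$dfs_months[sel], tr$dfs_event[sel],
                        B = cfg$b_dfs,
                        strata = as.character(clinical$arm[sel]),
                        seed = sub_seed(cfg$seed, "val_dfs"))

  rows <- lapply(present, function(v) {
    grp <- glist[[v]]
    dose <- .group_dose(grp)
    ## multivariate fits
    lf <- tryCatch({
      covs <- clinical[neo, cfg$response_covariates, drop = FALSE]
      logistic_fit(y[neo], dose[neo], covs)
    }, error = function(e) NULL)
    cf <- tryCatch({
      covs <- clinical[sel, cfg$dfs_covariates, drop = FALSE]
      cox_fit(tr$dfs_months[sel], tr$dfs_event[sel], dose[sel], covs)
    }, error = function(e) NULL)
    ## dosage gate (survival, collapsed grouping: two groups pass as
    ## not-evaluable)
    g <- gm[v, ]
    vd <- if (nlevels(grp) < 3) {
      structure(list(verdict = "not-evaluable",
                     metric = c(`0` = NA_real_), endpoint = "dfs"),
                class = "dosage_verdict")
    } else {
      dosage_check_survival(list(time = tr$dfs_months[sel],
                                 event = tr$dfs_event[sel],
                                 genotype = g[sel]),
                            horizon = cfg$dfs_horizon)
    }
    r <- resp[resp$variant_id == v, ]
    d <- dfs[dfs$variant_id == v, ]
    sig <- (r$flag == "ok" && r$adjusted_p < cfg$alpha) ||
      (d$flag == "ok" && d$adjusted_p < cfg$alpha)
    data.frame(variant_id = v,
               response_raw_p = r$raw_p, response_adj_p = r$adjusted_p,
               logistic_or = if (is.null(lf)) NA_real_ else unname(lf$or[1]),
               logistic_p = if (is.null(lf)) NA_real_ else lf$p_lrt,
               logistic_flag = if (is.null(lf)) "failed" else lf$flag,
               dfs_raw_p = d$raw_p, dfs_adj_p = d$adjusted_p,
               cox_hr = if (is.null(cf)) NA_real_ else unname(cf$hr[1]),
               cox_ci_low = if (is.null(cf)) NA_real_ else cf$ci[1, 1],
               cox_ci_high = if (is.null(cf)) NA_real_ else cf$ci[1, 2],
               cox_p = if (is.null(cf)) NA_real_ else cf$p_lrt,
               cox_flag = if (is.null(cf)) "failed" else cf$flag,
               dosage_verdict = vd$verdict,
               validated = sig && vd$verdict != "inconsistent",
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)

  ## per-subtype log-rank on the cytotoxic subset
  subtypes <- if ("subtype" %in% names(clinical)) levels(clinical$subtype)
              else character(0)
  sub_rows <- lapply(present, function(v) {
    grp <- glist[[v]]
    ps <- vapply(subtypes, function(st) {
      ss <- sel & !is.na(clinical$subtype) & clinical$subtype == st
      g <- droplevels(grp[ss])
      if (nlevels(g) < 2 || sum(tr$dfs_event[ss], na.rm = TRUE) == 0) {
        return(NA_real_)
      }
      logrank(list(time = tr$dfs_months[ss], event = tr$dfs_event[ss],
                   group = g))$raw_p
    }, numeric(1))
    data.frame(variant_id = v, subtype = subtypes, logrank_p = unname(ps),
               stringsAsFactors = FALSE)
  })
  subtype <- if (length(sub_rows)) do.call(rbind, sub_rows)
             else data.frame(variant_id = character(), subtype = character(),
                             logrank_p = numeric())
  ## MAF table for drift comparison
  maf <- do.call(rbind, lapply(present, function(v) {
    cnt <- genotype_counts(gm, v)
    data.frame(variant_id = v, n0 = cnt[[1]], n1 = cnt[[2]], n2 = cnt[[3]],
               maf = compute_maf(cnt[[1]], cnt[[2]], cnt[[3]]),
               stringsAsFactors = FALSE)
  }))
  list(results = results, subtype = subtype,
       missing_variants = missing_variants, maf = maf)
}

#' Compare minor allele frequencies between two cohorts
#'
#' @param set_a_counts,set_b_counts data.frames with columns `variant_id`,
#'   `n0`, `n1`, `n2`.
#' @return data.frame over the shared variants with `maf_a`, `maf_b` and
#'   `abs_diff`.
#' @export
compare_maf_sets <- function(set_a_counts, set_b_counts) {
  shared <- intersect(set_a_counts$variant_id, set_b_counts$variant_id)
  ia <- match(shared, set_a_counts$variant_id)
  ib <- match(shared, set_b_counts$variant_id)
  maf_of <- function(df, i) {
    vapply(i, function(j) compute_maf(df$n0[j], df$n1[j], df$n2[j]),
           numeric(1))
  }
  maf_a <- maf_of(set_a_counts, ia)
  maf_b <- maf_of(set_b_counts, ib)
  data.frame(variant_id = shared, maf_a = maf_a, maf_b = maf_b,
             abs_diff = abs(maf_a - maf_b), stringsAsFactors = FALSE)
}
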