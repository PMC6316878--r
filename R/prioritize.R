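#' In-silico consensus deleteriousness call
#'
#' Combines per-tool predictions into a single call (`deleterious`,
#' `neutral` or `unknown`) according to the variant's functional class:
#'
#' * **missense** — strict four-tool consensus: if any of Mutation Assessor,
#'   SIFT, LRT or PROVEAN is missing the call is `unknown`; `deleterious`
#'   requires Mutation Assessor H or M, SIFT score <= 0.05, LRT = D and
#'   PROVEAN = D simultaneously; anything else is `neutral`.
#' * **splice-site** — a MaxEntScan alternative-allele score below the
#'   reference score, or a dbscSNV ada score >= 0.6, marks putative splice
#'   disruption (`deleterious`); with no splice scores the call is
#'   `unknown`.
#' * **synonymous / utr / intronic-intergenic / indel** — RegulomeDB
#'   category 1, PINES p <= 0.05, IW score < 0.01 or a conserved miRNA
#'   target site each suffice for `deleterious`; otherwise `neutral`.
#'
#' Across all classes, a CADD PHRED score >= 19 upgrades a `neutral` or
#' `unknown` call to `deleterious` (supplementary ensemble evidence).
#'
#' @param e one evidence record: a list/one-row data.frame with fields
#'   `variant_class` and the per-tool columns of [read_evidence()]; missing
#'   tools are `NA`.
#' @return `"deleterious"`, `"neutral"` or `"unknown"`.
#' @export
insilico_consensus <- function(e) {
  get_ <- function(f) if (!is.null(e[[f]])) e[[f]] else NA
  cls <- as.character(e$variant_class)
  call <- if (cls == "missense") {
    ma <- get_("mutation_assessor"); sift <- get_("sift_score")
    lrt <- get_("lrt"); prov <- get_("provean")
    if (anyNA(c(ma, sift, lrt, prov))) "unknown"
    else if (ma %in% c("H", "M") && sift <= 0.05 && lrt == "D" && prov == "D")
      "deleterious"
    else "neutral"
  } else if (cls == "splice-site") {
    mref <- get_("maxentscan_ref"); malt <- get_("maxentscan_alt")
    ada <- get_("dbscsnv_ada")
    if (!is.na(mref) && !is.na(malt)) {
      if (malt < mref) "deleterious" else "neutral"
    } else if (!is.na(ada)) {
      if (ada >= 0.6) "deleterious" else "neutral"
    } else "unknown"
  } else {
    reg <- get_("regulome_category"); pines <- get_("pines_p")
    iw <- get_("iw_score"); mir <- get_("mirna_site")
    hit <- isTRUE(!is.na(reg) && reg == 1) ||
      isTRUE(!is.na(pines) && pines <= 0.05) ||
      isTRUE(!is.na(iw) && iw < 0.01) ||
      isTRUE(!is.na(mir) && mir)
    if (hit) "deleterious" else "neutral"
  }
  cadd <- get_("cadd_phred")
  if (call != "deleterious" && !is.na(cadd) && cadd >= 19) call <- "deleterious"
  call
}

#' Priority-matrix level assignment
#'
#' Statistical significance is mandatory for every level; a non-significant
#' variant is `unranked`. Significant variants are matched against the
#' priority columns left to right, first match wins:
#'
#' | level   | PharmGKB   | ClinVar                        | in-silico            | cancer-related |
#' |---------|------------|--------------------------------|----------------------|----------------|
#' | highest | associated | drug-response or cancer-neoplasm | deleterious        | no             |
#' | high    | associated | no-data                        | deleterious or neutral | no           |
#' | medium  | no-data    | drug-response or cancer-neoplasm | deleterious        | no             |
#' | low     | no-data    | no-data                        | neutral              | yes            |
#'
#' A ClinVar `other` status counts as `no-data` here. An `unknown` in-silico
#' call satisfies the high column's deleterious/neutral slot (treated as
#' neutral) but never the deleterious requirement.
#'
#' @param significant logical: significant on at least one endpoint after
#'   permutation adjustment.
#' @param pharmgkb `"associated"` or `"no-data"`.
#' @param clinvar `"drug-response"`, `"cancer-neoplasm"`, `"other"` or
#'   `"no-data"`.
#' @param insilico_call `"deleterious"`, `"neutral"` or `"unknown"`.
#' @param cancer_related logical.
#' @return one of `"highest"`, `"high"`, `"medium"`, `"low"`, `"unranked"`.
#' @export
assign_priority <- function(significant, pharmgkb, clinvar, insilico_call,
                            cancer_related) {
  pharmgkb <- match.arg(pharmgkb, c("associated", "no-data"))
  clinvar <- match.arg(clinvar, c("drug-response", "cancer-neoplasm",
                                  "other", "no-data"))
  insilico_call <- match.arg(insilico_call,
                             c("deleterious", "neutral", "unknown"))
  if (!isTRUE(significant)) return("unranked")
  cv_path <- clinvar %in% c("drug-response", "cancer-neoplasm")
  cv_none <- !cv_path                    # "other" maps to no-data
  del <- insilico_call == "deleterious"
  neu_or_del <- insilico_call %in% c("deleterious", "neutral", "unknown")
  if (pharmgkb == "associated" && cv_path && del && !cancer_related)
    return("highest")
  if (pharmgkb == "associated" && cv_none && neu_or_del && !cancer_related)
    return("high")
  if (pharmgkb == "no-data" && cv_path && del && !cancer_related)
    return("medium")
  if (pharmgkb == "no-data" && cv_none && insilico_call == "neutral" &&
      cancer_related)
    return("low")
  "unranked"
}

#' Build the ranked validation panel
#'
#' Orders ranked variants by priority level (highest first), then by the
#' smaller adjusted p-value across endpoints, then lexicographically by
#' variant id for determinism, and truncates at `max_size`. Unranked
#' variants never enter the panel; every panel row carries the matched-rule
#' rationale.
#'
#' @param priority_calls data.frame with columns `variant_id`, `level`,
#'   `rationale`.
#' @param association_results data.frame with columns `variant_id`,
#'   `endpoint`, `adjusted_p` (long format over endpoints).
#' @param max_size maximum panel size (default 58).
#' @return data.frame panel: `variant_id`, `level`, `best_adjusted_p`,
#'   `response_adj_p`, `dfs_adj_p`, `rationale`.
#' @export
build_panel <- function(priority_calls, association_results, max_size = 58L) {
  ranked <- priority_calls[priority_calls$level != "unranked", , drop = FALSE]
  if (!nrow(ranked)) {
    warning("no ranked variants: empty panel")
    return(data.frame(variant_id = character(), level = character(),
                      best_adjusted_p = numeric(),
                      response_adj_p = numeric(), dfs_adj_p = numeric(),
                      rationale = character(), stringsAsFactors = FALSE))
  }
  getp <- function(v, ep) {
    sel <- association_results$variant_id == v &
      association_results$endpoint == ep
    if (any(sel)) min(association_results$adjusted_p[sel]) else NA_real_
  }
  ranked$response_adj_p <- vapply(ranked$variant_id, getp, numeric(1),
                                  ep = "response")
  ranked$dfs_adj_p <- vapply(ranked$variant_id, getp, numeric(1), ep = "dfs")
  ranked$best_adjusted_p <- pmin(ranked$response_adj_p, ranked$dfs_adj_p,
                                 na.rm = TRUE)
  lvl <- match(ranked$level, c("highest", "high", "medium", "low"))
  o <- order(lvl, ranked$best_adjusted_p, ranked$variant_id)
  ranked <- ranked[o, , drop = FALSE]
  ranked <- utils::head(ranked, max_size)
  rownames(ranked) <- NULL
  ranked[, c("variant_id", "level", "best_adjusted_p", "response_adj_p",
             "dfs_adj_p", "rationale")]
}

# evidence row -> priority call with rationale
.priority_call <- function(ev_row, sig_response, sig_dfs) {
  call <- insilico_consensus(ev_row)
  significant <- isTRUE(sig_response) || isTRUE(sig_dfs)
  level <- assign_priority(significant,
                           as.character(ev_row$pharmgkb_status),
                           as.character(ev_row$clinvar_status),
                           call,
                           isTRUE(ev_row$cancer_related))
  endpoint <- if (sig_response && sig_dfs) "both"
              else if (sig_response) "response"
              else if (sig_dfs) "dfs" else "none"
  rationale <- paste(c(
    sprintf("significant=%s", endpoint),
    sprintf("pharmgkb=%s", ev_row$pharmgkb_status),
    sprintf("clinvar=%s", ev_row$clinvar_status),
    sprintf("insilico=%s", call),
    sprintf("cancer_related=%s", isTRUE(ev_row$cancer_related))
  ), collapse = "; ")
  data.frame(variant_id = as.character(ev_row$variant_id),
             significant_endpoint = endpoint,
             insilico_call = call, level = level, rationale = rationale,
             stringsAsFactors = FALSE)
}
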