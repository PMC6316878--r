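#' QC thresholds
#'
#' Defaults follow the pipeline's filter cascade: variants are kept when in
#' Hardy-Weinberg equilibrium (exact test p > 0.01), common enough
#' (MAF > 0.05) and sufficiently genotyped (< 50% missing calls across the
#' cohort). Homozygote groups observed in fewer than `min_genotype_count`
#' patients are collapsed with the heterozygotes before association testing.
#'
#' @param hwe_alpha HWE exact-test significance level (exclude if p <= alpha).
#' @param maf_min minimum minor allele frequency (exclusive bound).
#' @param max_missing_fraction maximum tolerated missing-call fraction
#'   (exclusive bound), denominator = all cohort samples.
#' @param min_genotype_count minimum homozygote group size before collapsing.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_alpha = 0.01, maf_min = 0.05,
                          max_missing_fraction = 0.5,
                          min_genotype_count = 5L) {
  stopifnot(hwe_alpha >= 0, hwe_alpha < 1,
            maf_min >= 0, maf_min < 1,
            max_missing_fraction > 0, max_missing_fraction <= 1,
            min_genotype_count >= 1)
  structure(list(hwe_alpha = hwe_alpha, maf_min = maf_min,
                 max_missing_fraction = max_missing_fraction,
                 min_genotype_count = as.integer(min_genotype_count)),
            class = "qc_thresholds")
}

#' Genotype group counts for one variant
#'
#' @param gm a [genotype_matrix()].
#' @param variant variant id (or row index).
#' @return named integer vector `c(n0, n1, n2, n_missing)`; the first three
#'   count common homozygotes, heterozygotes and rare homozygotes among
#'   non-missing calls, and the four entries sum to the cohort size.
#' @export
genotype_counts <- function(gm, variant) {
  if (is.character(variant) && !variant %in% rownames(gm)) {
    stop("unknown variant id: ", variant, call. = FALSE)
  }
  g <- gm[variant, ]
  c(n0 = sum(g == 0L, na.rm = TRUE),
    n1 = sum(g == 1L, na.rm = TRUE),
    n2 = sum(g == 2L, na.rm = TRUE),
    n_missing = sum(is.na(g)))
}

#' Minor allele frequency from genotype counts
#'
#' `MAF = min(q, 1 - q)` with `q = (n1 + 2 n2) / (2 (n0 + n1 + n2))`, so the
#' result never exceeds 0.5 regardless of genotype orientation.
#'
#' @param n0,n1,n2 counts of common homozygotes, heterozygotes, rare
#'   homozygotes.
#' @return frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (any(c(n0, n1, n2) < 0)) stop("negative genotype count", call. = FALSE)
  if (n == 0) stop("MAF undefined: no informative samples", call. = FALSE)
  q <- (n1 + 2 * n2) / (2 * n)
  min(q, 1 - q)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: conditional on the observed allele counts, the
#' probability of every admissible heterozygote count is computed and the
#' p-value is the summed probability of all outcomes no more probable than
#' the observed one (the standard two-sided exact HWE convention).
#' Monomorphic variants return p = 1. Probabilities are computed by the
#' stable ratio recurrence over neighbouring heterozygote counts.
#'
#' @param n0,n1,n2 genotype counts.
#' @return exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) < 0)) stop("negative genotype count", call. = FALSE)
  n <- n0 + n1 + n2
  if (n == 0) stop("HWE test undefined: no informative samples", call. = FALSE)
  na <- n1 + 2 * min(n0, n2)            # rarer allele count
  nb <- 2 * n - na
  if (na == 0 || nb == 0) return(1)
  # admissible heterozygote counts share parity with the rare allele count
  h <- seq(na %% 2, na, by = 2)
  # unnormalized recurrence: P(h+2)/P(h) = 4*nAA(h)*nBB(h) / ((h+2)*(h+1))
  # with nAA(h) = (na - h)/2, nBB(h) = (nb - h)/2
  lp <- numeric(length(h))
  for (i in seq_along(h)[-1]) {
    hh <- h[i - 1]
    lp[i] <- lp[i - 1] +
      log(4 * ((na - hh) / 2) * ((nb - hh) / 2)) -
      log((hh + 2) * (hh + 1))
  }
  lp <- lp - max(lp)
  probs <- exp(lp)
  probs <- probs / sum(probs)
  p_obs <- probs[match(n1, h)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with allele totals",
                         call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' Apply the per-variant QC filter cascade
#'
#' A variant passes when `maf > maf_min` AND `hwe_p > hwe_alpha` AND
#' `missing_fraction < max_missing_fraction`. The recorded verdict is the
#' first failing rule in the order MAF, HWE, missingness (the pass/fail set
#' itself does not depend on this order). The missing fraction denominator
#' is the full cohort size. The HWE test uses non-missing calls.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `matrix` (the passing subset), `report` (per-variant
#'   data.frame: `variant_id`, `maf`, `hwe_p`, `missing_fraction`,
#'   `verdict`) and `totals` (verdict counts).
#' @export
apply_filters <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  th <- thresholds
  n_samples <- ncol(gm)
  rows <- lapply(rownames(gm), function(v) {
    cnt <- genotype_counts(gm, v)
    n_inf <- sum(cnt[1:3])
    maf <- if (n_inf > 0) compute_maf(cnt[1], cnt[2], cnt[3]) else NA_real_
    hwe_p <- if (n_inf > 0) hwe_exact_test(cnt[1], cnt[2], cnt[3]) else NA_real_
    miss <- cnt[["n_missing"]] / n_samples
    verdict <- if (is.na(maf) || maf <= th$maf_min) "fail_maf"
      else if (hwe_p <= th$hwe_alpha) "fail_hwe"
      else if (miss >= th$max_missing_fraction) "fail_missing"
      else "pass"
    data.frame(variant_id = v, maf = maf, hwe_p = hwe_p,
               missing_fraction = miss, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  verdicts <- factor(report$verdict,
                     levels = c("pass", "fail_maf", "fail_hwe", "fail_missing"))
  keep <- report$verdict == "pass"
  list(matrix = genotype_matrix(gm[keep, , drop = FALSE]),
       report = report,
       totals = table(verdicts))
}

#' Collapse sparse homozygote groups
#'
#' When a homozygote genotype is observed in fewer than `min_count` patients
#' it is merged with the heterozygotes, turning the three-genotype comparison
#' into a two-group common-homozygote vs rare-allele (or rare-homozygote vs
#' common-allele) comparison. A count of exactly `min_count` keeps three
#' groups.
#'
#' @param n0,n1,n2 genotype counts (orientation: `n0` = common homozygote).
#' @param min_count collapsing threshold (default 5).
#' @return list with `scheme` (`"three-group"` or `"common-vs-rare-allele"`
#'   or `"rare-vs-common-allele"`), `labels` (group label per genotype code
#'   0/1/2) and `counts` (collapsed group sizes).
#' @export
collapse_rare <- function(n0, n1, n2, min_count = 5L) {
  stopifnot(n0 >= 0, n1 >= 0, n2 >= 0)
  if (n2 < min_count) {
    list(scheme = "common-vs-rare-allele",
         labels = c(`0` = "common homozygous", `1` = "rare allele",
                    `2` = "rare allele"),
         counts = c(`common homozygous` = n0, `rare allele` = n1 + n2))
  } else if (n0 < min_count) {
    list(scheme = "rare-vs-common-allele",
         labels = c(`0` = "common allele", `1` = "common allele",
                    `2` = "rare homozygous"),
         counts = c(`common allele` = n0 + n1, `rare homozygous` = n2))
  } else {
    list(scheme = "three-group",
         labels = c(`0` = "common homozygous", `1` = "heterozygous",
                    `2` = "rare homozygous"),
         counts = c(`common homozygous` = n0, heterozygous = n1,
                    `rare homozygous` = n2))
  }
}

# map a genotype vector to a (possibly collapsed) group factor
genotype_groups <- function(g, min_count = 5L) {
  cnt <- c(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
           sum(g == 2L, na.rm = TRUE))
  cl <- collapse_rare(cnt[1], cnt[2], cnt[3], min_count)
  lab <- unname(cl$labels[as.character(g)])
  factor(lab, levels = unique(unname(cl$labels)))
}

#' Non-reference discordance rate between two call sets
#'
#' Concordance metric for cross-platform genotype validation: among aligned
#' call pairs where at least one platform reports a non-reference genotype
#' (code > 0), the percentage that disagree. Pairs with a missing call on
#' either side are dropped first.
#'
#' @param calls_a,calls_b aligned genotype code vectors.
#' @return list with `rate` (percent, `NA` when undefined), `n_nonref`
#'   (denominator), `n_discordant` and `defined` flag.
#' @export
nonref_discordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors must be aligned", call. = FALSE)
  }
  keep <- !is.na(calls_a) & !is.na(calls_b)
  a <- calls_a[keep]
  b <- calls_b[keep]
  nonref <- a > 0 | b > 0
  n_nonref <- sum(nonref)
  if (n_nonref == 0) {
    return(list(rate = NA_real_, n_nonref = 0L, n_discordant = 0L,
                defined = FALSE))
  }
  n_disc <- sum(a[nonref] != b[nonref])
  list(rate = 100 * n_disc / n_nonref, n_nonref = n_nonref,
       n_discordant = n_disc, defined = TRUE)
}
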