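#' Genotype matrix container
#'
#' A `genotype_matrix` is an integer matrix with variants as rows and samples
#' as columns. Calls are coded by the number of copies of the *rare* allele
#' carried by the sample: `0` = common homozygote, `1` = heterozygote,
#' `2` = rare homozygote, `NA` = missing call. Row names are variant
#' identifiers (rs IDs or `chrom:pos:ref:alt` strings), column names are
#' sample identifiers.
#'
#' @param calls integer matrix (or coercible) of codes in `{0, 1, 2, NA}`.
#' @param variant_ids optional character vector of row identifiers; defaults
#'   to `rownames(calls)`.
#' @param sample_ids optional character vector of column identifiers; defaults
#'   to `colnames(calls)`.
#' @return an object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'   dimnames = list(c("rs1", "rs2"), c("s1", "s2"))))
#' dim(gm)
#' @export
genotype_matrix <- function(calls, variant_ids = rownames(calls),
                            sample_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(variant_ids) && nrow(calls) == 0) variant_ids <- character(0)
  if (is.null(sample_ids) && ncol(calls) == 0) sample_ids <- character(0)
  if (is.null(variant_ids) || is.null(sample_ids)) {
    stop("genotype_matrix requires variant and sample identifiers", call. = FALSE)
  }
  variant_ids <- as.character(variant_ids)
  sample_ids <- as.character(sample_ids)
  if (length(variant_ids) != nrow(calls) || length(sample_ids) != ncol(calls)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(variant_ids)) {
    stop("duplicate variant ids: ",
         paste(unique(variant_ids[duplicated(variant_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    stop("genotype codes must be 0, 1, 2 or NA; offending values: ",
         paste(utils::head(unique(calls[bad])), collapse = ", "), call. = FALSE)
  }
  dimnames(calls) <- list(variant_ids, sample_ids)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Orient genotype codes to the common allele
#'
#' Genotype codes in this package count copies of the *rare* allele in the
#' analyzed cohort, not the non-reference allele. When the non-reference
#' allele frequency of a variant exceeds 0.5 (common for panel variants where
#' the reference genome carries the minor allele), its row is flipped
#' (`g -> 2 - g`) so that code 0 always denotes the common homozygote.
#' Orientation should be fixed on the full cohort before any subsetting so
#' that testing and validation subsets share group labels.
#'
#' @param gm a [genotype_matrix()].
#' @return the reoriented `genotype_matrix`, with a logical attribute
#'   `"flipped"` marking which rows were flipped.
#' @export
orient_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_eff <- rowSums(!is.na(gm))
  alt_af <- rowSums(gm, na.rm = TRUE) / (2 * pmax(n_eff, 1L))
  flip <- !is.na(alt_af) & n_eff > 0 & alt_af > 0.5
  if (any(flip)) {
    gm[flip, ] <- 2L - gm[flip, , drop = FALSE]
  }
  attr(gm, "flipped") <- stats::setNames(flip, rownames(gm))
  gm
}

# Deterministic per-stage substream seed derived from the single global seed.
# Stage names hash to small offsets so stages draw independent streams while
# the whole run remains a pure function of one integer.
sub_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
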