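#' @importFrom data.table fread
NULL

.pkg_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("pgxprio"))
  s <- if (is.null(seed)) "" else sprintf(" seed=%s", seed)
  sprintf("# pgxprio %s%s", v, s)
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect has variants as rows and samples as columns: first column
#' `variant_id`, remaining columns one per sample, codes `0`/`1`/`2`/`NA`
#' (empty also accepted as missing). Lines starting with `#` are comments.
#' The VCF path uses only the per-sample `GT` subfield: the code is the count
#' of non-reference alleles; `./.` (or any GT containing `.`) is missing;
#' both `/` and `|` separators are accepted. Multi-allelic sites are
#' rejected. Note VCF-derived codes count *non-reference* alleles; call
#' [orient_genotypes()] afterwards to re-orient to the cohort's common
#' allele.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`; default guessed from the extension.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path,
                           format = if (grepl("\\.vcf$", path)) "vcf" else "tsv") {
  format <- match.arg(format, c("tsv", "vcf"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "vcf") return(.read_genotypes_vcf(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
  if (!nrow(dt) || names(dt)[1] != "variant_id") {
    stop("genotype TSV must start with a 'variant_id' column", call. = FALSE)
  }
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate variant id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(dt[, -1])
  bad <- which(!is.na(m) & !(m %in% 0:2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("parse error in %s at data row %d: invalid genotype code '%s'",
                 path, bad[1, 1], m[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  genotype_matrix(m, variant_ids = ids, sample_ids = colnames(m))
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) > 1
  if (any(multi)) {
    stop("multi-allelic sites unsupported: ",
         paste(rownames(vcf)[multi], collapse = ", "), call. = FALSE)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF carries no GT field", call. = FALSE)
  code <- function(x) {
    ifelse(grepl("\\.", x) | x == "", NA_integer_,
           vapply(strsplit(x, "[/|]"),
                  function(a) sum(a == "1"), integer(1)))
  }
  m <- matrix(code(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  bad <- vapply(strsplit(gt[!is.na(m)], "[/|]"),
                function(a) any(!a %in% c("0", "1")), logical(1))
  if (any(bad)) stop("non-biallelic GT allele in ", path, call. = FALSE)
  genotype_matrix(m)
}

#' Write a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param format `"tsv"` (default) or `"vcf"` (minimal sites-only VCF with a
#'   GT field; variant ids parsed as `chrom:pos:ref:alt` when possible,
#'   otherwise written as `1:<row>:A:G` placeholders with the id in the ID
#'   column).
#' @param seed optional seed recorded in the header comment.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf"), seed = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.pkg_header(seed), con)
    writeLines(paste(c("variant_id", colnames(gm)), collapse = "\t"), con)
    body <- apply(gm, 1, function(r) paste(ifelse(is.na(r), "NA", r),
                                           collapse = "\t"))
    writeLines(paste(rownames(gm), body, sep = "\t"), con)
  } else {
    parts <- strsplit(rownames(gm), ":", fixed = TRUE)
    ok <- lengths(parts) == 4
    chrom <- ifelse(ok, vapply(parts, `[`, "", 1), "1")
    pos <- ifelse(ok, vapply(parts, `[`, "", 2), as.character(seq_len(nrow(gm))))
    ref <- ifelse(ok, vapply(parts, `[`, "", 3), "A")
    alt <- ifelse(ok, vapply(parts, `[`, "", 4), "G")
    gt <- matrix(c("0/0", "0/1", "1/1")[gm + 1L], nrow = nrow(gm))
    gt[is.na(gm)] <- "./."
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##source=pgxprio%s",
                         if (is.null(seed)) "" else sprintf(";seed=%s", seed)),
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", colnames(gm)), collapse = "\t")), con)
    writeLines(paste(chrom, pos, rownames(gm), ref, alt, ".", ".", ".", "GT",
                     apply(gt, 1, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

.clinical_required <- c("sample_id", "arm", "response", "dfs_months",
                        "dfs_event", "lost_to_followup")
.clinical_optional <- c("stage", "grade", "er", "pr", "her2", "subtype")

#' Read and validate a clinical table
#'
#' Schema (TSV, `#` comments allowed): mandatory columns `sample_id`,
#' `arm` (`neoadjuvant`/`adjuvant`/`hormonal_only`/`none`), `response`
#' (`responder`/`non-responder`/`not-applicable`), `dfs_months`, `dfs_event`,
#' `lost_to_followup`; optional covariates `stage`, `grade`, `er`, `pr`,
#' `her2`, `subtype` (empty cells become missing). Unknown columns are
#' preserved. Enforced invariants: response is defined only for neoadjuvant
#' patients; DFS fields are absent exactly for patients lost to follow-up.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  clin <- as.data.frame(dt)
  missing_cols <- setdiff(.clinical_required, names(clin))
  if (length(missing_cols)) {
    stop("clinical table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_clinical(clin)
}

#' Validate clinical table invariants
#' @param clin data.frame with the [read_clinical()] schema.
#' @return the table, with categorical columns as factors.
#' @export
validate_clinical <- function(clin) {
  if (anyDuplicated(clin$sample_id)) {
    stop("duplicate sample ids in clinical table", call. = FALSE)
  }
  clin$arm <- factor(clin$arm, levels = c("neoadjuvant", "adjuvant",
                                          "hormonal_only", "none"))
  if (anyNA(clin$arm)) stop("unknown therapy arm value", call. = FALSE)
  clin$response <- factor(clin$response,
                          levels = c("responder", "non-responder",
                                     "not-applicable"))
  has_resp <- !is.na(clin$response) & clin$response != "not-applicable"
  bad <- has_resp & clin$arm != "neoadjuvant"
  if (any(bad)) {
    stop("response recorded for non-neoadjuvant sample(s): ",
         paste(utils::head(clin$sample_id[bad]), collapse = ", "),
         call. = FALSE)
  }
  clin$lost_to_followup <- as.logical(clin$lost_to_followup)
  clin$dfs_event <- as.logical(clin$dfs_event)
  ltf <- clin$lost_to_followup %in% TRUE
  bad_dfs <- (ltf & (!is.na(clin$dfs_months) | !is.na(clin$dfs_event))) |
    (!ltf & (is.na(clin$dfs_months) | is.na(clin$dfs_event)))
  if (any(bad_dfs)) {
    stop("DFS fields must be absent exactly for lost-to-followup samples: ",
         paste(utils::head(clin$sample_id[bad_dfs]), collapse = ", "),
         call. = FALSE)
  }
  if (any(clin$dfs_months < 0, na.rm = TRUE)) {
    stop("negative DFS time", call. = FALSE)
  }
  if ("subtype" %in% names(clin)) {
    clin$subtype <- factor(clin$subtype,
                           levels = c("luminal A", "luminal B", "HER2",
                                      "triple negative"))
  }
  clin
}

#' Write a clinical table
#' @param clin validated clinical data.frame.
#' @param path output TSV.
#' @param seed optional seed recorded in the header comment.
#' @export
write_clinical <- function(clin, path, seed = NULL) {
  con <- file(path, "w")
  writeLines(.pkg_header(seed), con)
  close(con)
  suppressWarnings(utils::write.table(clin, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

.evidence_required <- c("variant_id", "variant_class", "pharmgkb_status",
                        "clinvar_status", "cancer_related")

#' Read a per-variant evidence table
#'
#' TSV with one row per variant. Mandatory: `variant_id`, `variant_class`
#' (`missense`/`synonymous`/`splice-site`/`utr`/`intronic-intergenic`/
#' `indel`), `pharmgkb_status` (`associated`/`no-data`), `clinvar_status`
#' (`drug-response`/`cancer-neoplasm`/`other`/`no-data`), `cancer_related`
#' (logical). Optional in-silico columns (missing values allowed
#' everywhere): `mutation_assessor` (`H`/`M`/`L`/`N`), `sift_score`, `lrt`
#' (`D`/`N`/`U`), `provean` (`D`/`N`), `metasvm`, `metalr` (`D`/`T`),
#' `cadd_phred`, `dbscsnv_ada`, `maxentscan_ref`, `maxentscan_alt`,
#' `regulome_category`, `pines_p`, `iw_score`, `mirna_site` (logical).
#'
#' @param path TSV file.
#' @return data.frame, one row per variant.
#' @export
read_evidence <- function(path) {
  ev <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        na.strings = c("NA", "", ".")))
  missing_cols <- setdiff(.evidence_required, names(ev))
  if (length(missing_cols)) {
    stop("evidence table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ev$variant_id)) {
    stop("duplicate variant ids in evidence table", call. = FALSE)
  }
  ev$cancer_related <- as.logical(ev$cancer_related)
  if ("mirna_site" %in% names(ev)) ev$mirna_site <- as.logical(ev$mirna_site)
  ev
}

#' Write a results report
#'
#' TSV writer for association/QC/panel tables. Numeric columns are rendered
#' with 17 significant digits so a round-trip preserves them exactly.
#'
#' @param results data.frame.
#' @param path output TSV.
#' @param seed optional seed recorded in the header comment.
#' @export
write_report <- function(results, path, seed = NULL) {
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  out[out == "nan" | out == "NA"] <- NA
  con <- file(path, "w")
  writeLines(.pkg_header(seed), con)
  close(con)
  suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a results report written by [write_report()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_report <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = c("NA", "")))
}

.genomic_classes <- c("exonic", "intronic", "splicing", "UTR3", "UTR5",
                      "upstream", "downstream", "intergenic", "ncRNA")
.exonic_classes <- c("synonymous SNV", "non-synonymous SNV", "stopgain",
                     "stoploss", "frameshift insertion", "frameshift deletion",
                     "non-frameshift insertion", "non-frameshift deletion",
                     "unknown")

#' Summarize variant functional classes
#'
#' Tabulates variant records by genomic class (with percentages of the full
#' set) and, for exonic variants, by coding consequence (percentages of the
#' exonic subset). Classes outside the known enumerations are pooled as
#' `"other"` without interpretation. Percentages are rounded to one decimal.
#'
#' @param records data.frame with columns `genomic_class` and (for exonic
#'   rows) `exonic_class`.
#' @return list of class `class_summary` with data.frames `genomic` and
#'   `exonic` (columns `class`, `count`, `percentage`) and the totals.
#' @export
summarize_classes <- function(records) {
  if (!nrow(records)) {
    empty <- data.frame(class = character(), count = integer(),
                        percentage = numeric())
    return(structure(list(genomic = empty, exonic = empty,
                          n_total = 0L, n_exonic = 0L),
                     class = "class_summary"))
  }
  gc <- as.character(records$genomic_class)
  gc[!gc %in% .genomic_classes] <- "other"
  gtab <- table(gc)
  genomic <- data.frame(class = names(gtab), count = as.integer(gtab),
                        percentage = round(100 * as.integer(gtab) /
                                             nrow(records), 1),
                        stringsAsFactors = FALSE)
  exonic_rows <- records[gc == "exonic", , drop = FALSE]
  if (nrow(exonic_rows) && "exonic_class" %in% names(records)) {
    ec <- as.character(exonic_rows$exonic_class)
    ec[is.na(ec) | !ec %in% .exonic_classes] <- "unknown"
    etab <- table(ec)
    exonic <- data.frame(class = names(etab), count = as.integer(etab),
                         percentage = round(100 * as.integer(etab) /
                                              nrow(exonic_rows), 1),
                         stringsAsFactors = FALSE)
  } else {
    exonic <- data.frame(class = character(), count = integer(),
                         percentage = numeric())
  }
  structure(list(genomic = genomic, exonic = exonic,
                 n_total = nrow(records), n_exonic = nrow(exonic_rows)),
            class = "class_summary")
}

#' Count novel variants (no rs identifier)
#'
#' A record is novel when its `rs_id` is absent (NA or empty). Optionally
#' reports per-group counts, normalized by the number of genes per group.
#'
#' @param records data.frame with column `rs_id` and optionally `gene_group`.
#' @param genes_per_group optional named vector: number of genes in each
#'   group, used to normalize per-group novel counts.
#' @return list with `n_novel`, `n_total`, `fraction`, and (when grouping
#'   information is present) a `per_group` data.frame.
#' @export
count_novel <- function(records, genes_per_group = NULL) {
  novel <- is.na(records$rs_id) | records$rs_id == ""
  out <- list(n_novel = sum(novel), n_total = nrow(records),
              fraction = if (nrow(records)) sum(novel) / nrow(records) else NA_real_)
  if ("gene_group" %in% names(records)) {
    tab <- tapply(novel, records$gene_group, sum)
    pg <- data.frame(gene_group = names(tab), n_novel = as.integer(tab),
                     stringsAsFactors = FALSE)
    if (!is.null(genes_per_group)) {
      pg$per_gene <- pg$n_novel / as.numeric(genes_per_group[pg$gene_group])
    }
    out$per_group <- pg
  }
  out
}
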