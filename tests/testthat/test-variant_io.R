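test_that("genotype TSV write -> read round-trips exactly", {
  co <- make_cohort(n_samples = 30, n_variants = 8, seed = 1)
  gm <- co$genotypes
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path, seed = 1)
  back <- read_genotypes(path)
  expect_identical(unclass(back)[, ], unclass(gm)[, ])
  expect_identical(rownames(back), rownames(gm))
})

test_that("VCF GT codes map to 0/1/2/missing and multi-allelics are rejected", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", ".", ".", "GT",
          "0/0", "0/1", "1/1", "./.", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", ".", ".", "GT",
          "0|0", "1|0", "0/0", "1/1", sep = "\t")), vcf)
  gm <- read_genotypes(vcf, format = "vcf")
  expect_equal(unname(gm["rs1", ]), c(0L, 1L, 2L, NA))
  expect_equal(unname(gm["rs2", ]), c(0L, 1L, 0L, 2L))

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("1", "100", "rs9", "A", "G,T", ".", ".", ".", "GT", "1/2",
          sep = "\t")), bad)
  expect_error(read_genotypes(bad, format = "vcf"), "rs9")
})

test_that("VCF round-trip through the minimal writer is lossless", {
  skip_if_not_installed("VariantAnnotation")
  co <- make_cohort(n_samples = 10, n_variants = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(co$genotypes, path, format = "vcf")
  back <- read_genotypes(path, format = "vcf")
  expect_identical(unclass(back)[, ], unclass(co$genotypes)[, ])
})

test_that("malformed genotype inputs produce informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_id\ts1\ts2", "v1\t0\t1", "v1\t2\t0"), path)
  expect_error(read_genotypes(path), "duplicate variant id")
  writeLines(c("variant_id\ts1\ts2", "v1\t0\t1", "v2\t3\t0"), path)
  expect_error(read_genotypes(path), "invalid genotype code")
  expect_error(genotype_matrix(matrix(0L, 1, 2,
    dimnames = list("v1", c("s", "s")))), "duplicate sample")
})

test_that("clinical table schema and invariants are enforced", {
  co <- make_cohort(n_samples = 40, n_variants = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(co$clinical, path)
  back <- read_clinical(path)
  expect_equal(back$sample_id, co$clinical$sample_id)
  expect_equal(back$dfs_months, co$clinical$dfs_months)

  # response on an adjuvant sample violates the schema
  bad <- co$clinical
  i <- which(bad$arm == "adjuvant")[1]
  bad$response[i] <- "responder"
  expect_error(validate_clinical(bad), "non-neoadjuvant")

  # DFS fields must be absent exactly for lost-to-followup patients
  bad2 <- co$clinical
  j <- which(!bad2$lost_to_followup)[1]
  bad2$dfs_months[j] <- NA
  expect_error(validate_clinical(bad2), "lost-to-followup")

  # empty optional covariate is missing, not an error
  ok <- co$clinical
  ok$stage[1] <- NA
  expect_silent(validate_clinical(ok))

  # missing mandatory column is a schema error
  writeLines("sample_id\tarm\nx\tneoadjuvant", path)
  expect_error(read_clinical(path), "mandatory column")
})

test_that("report round-trip preserves numeric fields to full precision", {
  df <- data.frame(variant_id = c("a", "b"),
                   raw_p = c(0.12345678901234567, 3.4e-12),
                   adjusted_p = c(1 / 3, 2 / 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(df, path, seed = 99)
  back <- read_report(path)
  expect_identical(back$raw_p, df$raw_p)
  expect_identical(back$adjusted_p, df$adjusted_p)
  expect_match(readLines(path, n = 1), "^# pgxprio .* seed=99$")
})

test_that("summarize_classes reproduces per-class percentages", {
  # single record: its class at 100.0
  one <- summarize_classes(data.frame(genomic_class = "intronic"))
  expect_equal(one$genomic$percentage, 100.0)

  # unknown classes pool into "other"; percentages sum to ~100
  set.seed(1)
  rec <- data.frame(
    genomic_class = sample(c("exonic", "intronic", "UTR3", "weird"), 500,
                           replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1)),
    exonic_class = NA_character_)
  rec$exonic_class[rec$genomic_class == "exonic"] <-
    sample(c("synonymous SNV", "non-synonymous SNV", "stopgain"),
           sum(rec$genomic_class == "exonic"), replace = TRUE)
  s <- summarize_classes(rec)
  expect_true("other" %in% s$genomic$class)
  expect_equal(sum(s$genomic$count), 500)
  expect_lt(abs(sum(s$genomic$percentage) - 100), 0.1 * nrow(s$genomic))
  expect_equal(sum(s$exonic$count), s$n_exonic)
  expect_lt(abs(sum(s$exonic$percentage) - 100), 0.1 * nrow(s$exonic))

  empty <- summarize_classes(data.frame(genomic_class = character()))
  expect_equal(empty$n_total, 0L)
})

test_that("count_novel counts absent rs ids and normalizes per gene", {
  rec <- data.frame(rs_id = c("rs1", "rs2", NA, "", "rs3"),
                    gene_group = c("A", "A", "A", "B", "B"))
  out <- count_novel(rec, genes_per_group = c(A = 1, B = 5))
  expect_equal(out$n_novel, 2L)
  expect_equal(out$fraction, 0.4)
  expect_equal(out$per_group$per_gene[out$per_group$gene_group == "A"], 1)
  expect_equal(out$per_group$per_gene[out$per_group$gene_group == "B"], 0.2)
  # all known: zero
  expect_equal(count_novel(data.frame(rs_id = c("rs1", "rs2")))$n_novel, 0L)
})

test_that("evidence table reader validates its schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ev <- make_evidence(c("v1", "v2"))
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_evidence(path)
  expect_equal(back$variant_id, c("v1", "v2"))
  utils::write.table(ev[, -2], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_evidence(path), "mandatory column")
})
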