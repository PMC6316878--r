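ev_base <- function(...) {
  out <- list(variant_id = "v", variant_class = "missense",
              pharmgkb_status = "no-data", clinvar_status = "no-data",
              cancer_related = FALSE, mutation_assessor = NA,
              sift_score = NA, lrt = NA, provean = NA, cadd_phred = NA,
              dbscsnv_ada = NA, maxentscan_ref = NA, maxentscan_alt = NA,
              regulome_category = NA, pines_p = NA, iw_score = NA,
              mirna_site = NA)
  mod <- list(...)
  out[names(mod)] <- mod
  out
}

test_that("missense consensus requires all four tools and strict agreement", {
  expect_equal(insilico_consensus(ev_base(mutation_assessor = "M",
                                          sift_score = 0.01, lrt = "D",
                                          provean = "D")), "deleterious")
  # any missing tool: unknown, even if the others call deleterious
  expect_equal(insilico_consensus(ev_base(sift_score = 0.01, lrt = "D",
                                          provean = "D", cadd_phred = 10)),
               "unknown")
  # one dissenting tool: neutral
  expect_equal(insilico_consensus(ev_base(mutation_assessor = "L",
                                          sift_score = 0.01, lrt = "D",
                                          provean = "D")), "neutral")
  # CADD >= 19 upgrades a non-deleterious call
  expect_equal(insilico_consensus(ev_base(mutation_assessor = "N",
                                          sift_score = 0.8, lrt = "N",
                                          provean = "N", cadd_phred = 25)),
               "deleterious")
  expect_equal(insilico_consensus(ev_base(cadd_phred = 19)), "deleterious")
})

test_that("splice and noncoding evidence routes give the documented calls", {
  expect_equal(insilico_consensus(ev_base(variant_class = "splice-site",
                                          maxentscan_ref = 9.1,
                                          maxentscan_alt = 4.2)),
               "deleterious")
  expect_equal(insilico_consensus(ev_base(variant_class = "splice-site",
                                          maxentscan_ref = 5.0,
                                          maxentscan_alt = 7.0)), "neutral")
  expect_equal(insilico_consensus(ev_base(variant_class = "splice-site")),
               "unknown")
  for (hit in list(list(regulome_category = 1), list(pines_p = 0.01),
                   list(iw_score = 0.005), list(mirna_site = TRUE))) {
    e <- do.call(ev_base, c(list(variant_class = "utr"), hit))
    expect_equal(insilico_consensus(e), "deleterious")
  }
  expect_equal(insilico_consensus(ev_base(variant_class = "synonymous",
                                          pines_p = 0.2, iw_score = 0.5)),
               "neutral")
})

test_that("assign_priority matches the priority matrix left to right", {
  expect_equal(assign_priority(TRUE, "associated", "drug-response",
                               "deleterious", FALSE), "highest")
  expect_equal(assign_priority(TRUE, "associated", "no-data", "neutral",
                               FALSE), "high")
  expect_equal(assign_priority(TRUE, "no-data", "cancer-neoplasm",
                               "deleterious", FALSE), "medium")
  expect_equal(assign_priority(TRUE, "no-data", "no-data", "neutral", TRUE),
               "low")
  # significance is mandatory in every column
  expect_equal(assign_priority(FALSE, "associated", "drug-response",
                               "deleterious", FALSE), "unranked")
  # ClinVar "other" maps to no-data
  expect_equal(assign_priority(TRUE, "associated", "other", "neutral", FALSE),
               "high")
  # unknown in-silico call fails the deleterious requirement
  expect_equal(assign_priority(TRUE, "no-data", "drug-response", "unknown",
                               FALSE), "unranked")
})

test_that("assign_priority truth table is frozen over the full input space", {
  # independent restatement of the priority matrix: columns scanned in
  # order, each a conjunction over the four evidence axes
  columns <- list(
    highest = function(pg, cv, ins, cr) {
      pg == "associated" && cv %in% c("drug-response", "cancer-neoplasm") &&
        ins == "deleterious" && !cr
    },
    high = function(pg, cv, ins, cr) {
      pg == "associated" && cv %in% c("other", "no-data") && !cr
    },
    medium = function(pg, cv, ins, cr) {
      pg == "no-data" && cv %in% c("drug-response", "cancer-neoplasm") &&
        ins == "deleterious" && !cr
    },
    low = function(pg, cv, ins, cr) {
      pg == "no-data" && cv %in% c("other", "no-data") && ins == "neutral" &&
        cr
    }
  )
  grid <- expand.grid(sig = c(TRUE, FALSE),
                      pg = c("associated", "no-data"),
                      cv = c("drug-response", "cancer-neoplasm", "other",
                             "no-data"),
                      ins = c("deleterious", "neutral", "unknown"),
                      cr = c(TRUE, FALSE), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    r <- grid[i, ]
    want <- "unranked"
    if (r$sig) {
      for (lv in names(columns)) {
        if (columns[[lv]](r$pg, r$cv, r$ins, r$cr)) { want <- lv; break }
      }
    }
    expect_equal(assign_priority(r$sig, r$pg, r$cv, r$ins, r$cr), want,
                 info = paste(unlist(r), collapse = "/"))
  }
})

test_that("build_panel orders by level, p-value, then id, and truncates", {
  calls <- data.frame(
    variant_id = c("v3", "v1", "v2", "v4", "v5"),
    level = c("medium", "highest", "highest", "unranked", "low"),
    rationale = "r", stringsAsFactors = FALSE)
  assoc <- data.frame(
    variant_id = rep(c("v1", "v2", "v3", "v4", "v5"), each = 2),
    endpoint = rep(c("response", "dfs"), 5),
    adjusted_p = c(0.02, 0.9, 0.02, 0.5, 0.001, 0.7, 0.01, 0.01, 0.04, 0.6))
  panel <- build_panel(calls, assoc, max_size = 10)
  # ties on level+p broken lexicographically; unranked never enters
  expect_equal(panel$variant_id, c("v1", "v2", "v3", "v5"))
  expect_false("v4" %in% panel$variant_id)
  expect_true(all(nzchar(panel$rationale)))
  # truncation
  expect_equal(nrow(build_panel(calls, assoc, max_size = 2)), 2)
  # deterministic across calls
  expect_identical(panel, build_panel(calls, assoc, max_size = 10))
  expect_warning(build_panel(calls[calls$level == "unranked", , drop = FALSE],
                             assoc), "empty panel")
})
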