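test_that("target-domain filtering keeps only the target domain", {
  m <- matrix(c(5, 1, 2,
                3, 4, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("bact", "euk", "noDom")))
  x <- asvFromSamples(m, marker = "16S")
  tx <- makeTaxonomy(c("bact", "euk", "noDom"),
                     domain = c("Bacteria", "Eukaryota", ""))
  res <- filterTargetDomain(x, tx, "Bacteria")
  expect_identical(asvIds(res$table), "bact")
  expect_identical(sampleIds(res$table), c("s1", "s2"))
  expect_equal(res$report$n_asvs_removed_by_rule[["non_target"]], 1)
  expect_equal(res$report$n_asvs_removed_by_rule[["unassigned_domain"]], 1)

  # all-target table passes through unchanged
  allb <- filterTargetDomain(x[1, ], tx, "Bacteria")
  expect_identical(asvAbundance(allb$table), asvAbundance(x[1, ]))
})

test_that("host-read removal follows the identity/coverage threshold rules", {
  asvs <- c("hostGood", "hostPoor", "rotifer", "microbe")
  m <- matrix(10, nrow = 4, ncol = 4,
              dimnames = list(c("pm_w", "ea_w", "mat1", "ctl1"), asvs))
  md <- makeMetadata(rownames(m),
                     sample_class = c("individual", "individual", "mat",
                                      "control"),
                     host = c("P_murrayi", "E_antarcticus", "none", "none"),
                     wash_status = c("washed", "washed", "not_applicable",
                                     "not_applicable"))
  tx <- makeTaxonomy(asvs,
                     domain = "Eukaryota",
                     genus = c("Plectus", "Plectus", "Rotifera", "Tychonema"),
                     percent_identity = c(96, 94, 99, 99),
                     query_coverage = c(92, 95, 99, 99))
  x <- asvFromSamples(m, marker = "18S")
  res <- removeHostReads(x, tx, md)
  a <- asvAbundance(res$table, transpose = TRUE)
  # confident host hit zeroed only in that host's samples
  expect_equal(a["pm_w", "hostGood"], 0)
  expect_equal(a["ea_w", "hostGood"], 10)
  # poor assignment (<95% ID) zeroed in all individual samples
  expect_equal(a["pm_w", "hostPoor"], 0)
  expect_equal(a["ea_w", "hostPoor"], 0)
  # non-host taxa untouched everywhere; mats and controls never touched
  expect_equal(a[, "rotifer"], c(pm_w = 10, ea_w = 10, mat1 = 10, ctl1 = 10))
  expect_equal(a["mat1", ], c(hostGood = 10, hostPoor = 10, rotifer = 10,
                              microbe = 10))

  # 16S table with no host-matching ASVs: output equals input
  x16 <- asvFromSamples(m[, "microbe", drop = FALSE], marker = "16S")
  tx16 <- makeTaxonomy("microbe", genus = "Tychonema")
  r16 <- removeHostReads(x16, tx16, md)
  expect_identical(asvAbundance(r16$table), asvAbundance(x16))
  # 18S table without a host pattern map is a configuration error
  expect_error(removeHostReads(x, tx, md, host_patterns = NULL),
               "host_patterns")
})

test_that("negative-control subtraction clips at zero and drops controls", {
  m <- matrix(c(12, 3, 8,
                 3, 0, 2,
                 5, 1, 0,
                 2, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(c("s1", "s2", "c1", "c2"),
                              c("X", "Y", "Z")))
  x <- asvFromSamples(m)
  res <- subtractNegativeControls(x, c("c1", "c2"))
  a <- asvAbundance(res$table, transpose = TRUE)
  expect_equal(a["s1", "X"], 7)   # 12 - max(5, 2)
  expect_equal(a["s2", "X"], 0)   # 3 < 5 clipped
  expect_equal(a["s1", "Y"], 3 - 1)
  expect_equal(a[, "Z"], c(s1 = 8, s2 = 2))  # absent from controls
  expect_identical(sampleIds(res$table), c("s1", "s2"))
  expect_warning(ident <- subtractNegativeControls(x, character()),
                 "unchanged")
  expect_identical(asvAbundance(ident$table), asvAbundance(x))
})

test_that("low-depth discard uses a strict less-than threshold", {
  m <- matrix(c(99, 0, 60, 40, 150, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("below", "exact", "above"), c("a", "b")))
  x <- asvFromSamples(m)
  res <- discardLowDepthSamples(x, min_reads = 100)
  expect_identical(sampleIds(res$table), c("exact", "above"))
  expect_identical(res$report$details$discarded_samples, "below")
  ident <- discardLowDepthSamples(x, min_reads = 0)
  expect_identical(asvAbundance(ident$table), asvAbundance(x))
})

test_that("taxon renaming applies the shipped Phormidesmis rule", {
  tx <- makeTaxonomy(c("a1", "a2"), genus = c("Phormidesmis", "Nostoc"))
  res <- renameTaxa(tx)
  expect_identical(res$taxonomy$genus, c("Phormidium", "Nostoc"))
  expect_identical(renameTaxa(tx, character())$taxonomy$genus,
                   c("Phormidesmis", "Nostoc"))
  none <- renameTaxa(tx, c(Absent = "AlsoAbsent"))
  expect_identical(none$taxonomy, tx)
  expect_equal(none$report$details$n_fields_renamed, 0)
})

test_that("filters are idempotent, never increase counts, and audit totals", {
  set.seed(101)
  st <- generateStudy(smallParams(seed = 5))
  x <- st$table

  apply_twice <- function(f, x, ...) {
    once <- f(x, ...)$table
    twice <- f(once, ...)$table
    expect_identical(asvAbundance(twice), asvAbundance(once))
    once
  }
  t1 <- apply_twice(filterTargetDomain, x, st$taxonomy, "Eukaryota")
  t2 <- apply_twice(removeHostReads, t1, st$taxonomy, st$metadata)
  ctl <- st$metadata$sample_id[st$metadata$sample_class == "control"]
  t3 <- subtractNegativeControls(t2, ctl)$table
  t4 <- apply_twice(discardLowDepthSamples, t3, 100)

  # monotone: no filter increases any count on the samples/ASVs it keeps
  expect_true(all(asvAbundance(t2) <= asvAbundance(t1)))
  expect_true(all(asvAbundance(t3) <=
                  asvAbundance(t2)[, sampleIds(t3)]))

  # report chain reconciles totals exactly at every step
  prep <- suppressWarnings(preprocessStudy(x, st$taxonomy, st$metadata))
  reps <- prep$reports
  expect_equal(sum(reps$remove_host_reads$reads_before),
               sum(reps$filter_target_domain$reads_after))
  expect_equal(sum(reps$subtract_negative_controls$reads_before),
               sum(reps$remove_host_reads$reads_after))
  expect_equal(sum(reps$discard_low_depth_samples$reads_before),
               sum(reps$subtract_negative_controls$reads_after))
  expect_equal(sum(reps$discard_low_depth_samples$reads_after),
               sum(asvAbundance(prep$table)))
  # removed + retained reconciles ASV totals for the domain filter
  rep1 <- reps$filter_target_domain
  expect_equal(sum(rep1$n_asvs_removed_by_rule) +
                 nrow(filterTargetDomain(x, prep$taxonomy,
                                         "Eukaryota")$table),
               nrow(x))
})
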