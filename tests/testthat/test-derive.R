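test_that("individuals are averaged arithmetically per mat replicate", {
  m <- rbind(i1 = c(A = 2, B = 0), i2 = c(A = 4, B = 2), i3 = c(A = 9, B = 9))
  md <- makeMetadata(rownames(m), wash_status = c("washed", "washed",
                                                  "unwashed"))
  x <- asvFromSamples(m)
  prof <- averageIndividuals(x, md, "P_murrayi", "washed")
  expect_equal(ncol(prof), 1L)
  expect_equal(asvAbundance(prof)[, 1], c(A = 3, B = 1))
  expect_equal(colData(prof)$n_individuals, 2L)
  expect_identical(colData(prof)$microbiome_type, "internal")

  single <- averageIndividuals(x, md, "P_murrayi", "unwashed")
  expect_equal(asvAbundance(single)[, 1], c(A = 9, B = 9))
  expect_equal(colData(single)$n_individuals, 1L)
  expect_identical(colData(single)$microbiome_type, "unwashed")

  expect_warning(none <- averageIndividuals(x, md, "Tardigrada", "washed"),
                 "no washed individuals")
  expect_equal(ncol(none), 0L)
  expect_error(averageIndividuals(x, md, "none", "washed"), "host")
})

test_that("external derivation is clipped subtraction with an audit", {
  unw <- makeProfile(c(A = 10, B = 4, C = 0), "unwashed")
  int <- makeProfile(c(A = 3, B = 6, C = 1), "internal")
  ext <- deriveExternal(unw, int)
  expect_equal(asvAbundance(ext)[, 1], c(A = 7, B = 0, C = 0))
  expect_identical(colData(ext)$microbiome_type, "external")
  expect_equal(metadata(ext)$derivation$n_clipped, 2)

  # annihilation and identity cases
  same <- deriveExternal(unw, makeProfile(c(A = 10, B = 4, C = 0),
                                          "internal"))
  expect_true(all(asvAbundance(same) == 0))
  free <- deriveExternal(unw, makeProfile(c(A = 0, B = 0, C = 0), "internal"))
  expect_equal(asvAbundance(free)[, 1], asvAbundance(unw)[, 1])

  # mismatched design keys refuse to combine
  other <- makeProfile(c(A = 1, B = 1, C = 1), "internal", stream = "Delta")
  expect_error(deriveExternal(unw, other), "design key mismatch")
})

test_that("derivation satisfies its algebraic identities on random tables", {
  set.seed(77)
  for (rep in 1:25) {
    k <- sample(3:12, 1)
    ids <- paste0("a", seq_len(k))
    u <- setNames(rpois(k, 6), ids)
    i <- setNames(rpois(k, 6), ids)
    ext <- asvAbundance(deriveExternal(
      makeProfile(u, "unwashed"), makeProfile(i, "internal")))[, 1]
    expect_true(all(ext >= 0))
    expect_true(all(ext <= u))
    # exact identity of clipped subtraction
    expect_equal(ext + pmin(i, u), u)
    # permutation equivariance: relabeling ASVs commutes with derivation
    p <- sample(k)
    ext_p <- asvAbundance(deriveExternal(
      makeProfile(u[p], "unwashed"), makeProfile(i[p], "internal")))[, 1]
    expect_equal(ext_p, ext[p])
  }
})

test_that("buildAllMicrobiomes yields the expected profile families", {
  m <- rbind(w1 = c(A = 5, B = 1), w2 = c(A = 3, B = 3),
             u1 = c(A = 9, B = 4), u2 = c(A = 7, B = 2),
             mat1 = c(A = 50, B = 50))
  md <- makeMetadata(rownames(m),
                     sample_class = c(rep("individual", 4), "mat"),
                     host = c(rep("P_murrayi", 4), "none"),
                     wash_status = c("washed", "washed", "unwashed",
                                     "unwashed", "not_applicable"))
  x <- asvFromSamples(m)
  prof <- buildAllMicrobiomes(x, md)
  types <- table(colData(prof)$microbiome_type)
  expect_equal(as.vector(types[c("internal", "unwashed", "external", "mat")]),
               c(1L, 1L, 1L, 1L))
  ext <- asvAbundance(profileSubset(prof, "external"))[, 1]
  expect_equal(ext, c(A = 8 - 4, B = 3 - 2))

  # washed-only replicate: internal exists, external absent with warning
  md2 <- md[md$wash_status != "unwashed", ]
  expect_warning(p2 <- buildAllMicrobiomes(x[, md2$sample_id], md2),
                 "lack a washed or unwashed")
  expect_equal(sum(colData(p2)$microbiome_type == "external"), 0L)
  expect_equal(sum(colData(p2)$microbiome_type == "internal"), 1L)
})

test_that("derived external profiles track the generator's true external", {
  # recovery property at small scale: over seeded synthetic studies the
  # derived external composition sits closer (Bray-Curtis) to the true
  # external than to the true internal composition
  hits <- 0L; runs <- 8L
  for (s in seq_len(runs)) {
    st <- generateStudy(smallParams(seed = 100 + s))
    prep <- suppressWarnings(preprocessStudy(st$table, st$taxonomy,
                                             st$metadata))
    prof <- suppressWarnings(buildAllMicrobiomes(prep$table, prep$metadata))
    ext <- profileSubset(prof, "external")
    cd <- colData(ext)
    d_ext <- d_int <- numeric(0)
    for (j in seq_len(ncol(ext))) {
      key <- sprintf("%s|%s|%s|%d", cd$host[j], cd$stream[j], cd$mat_type[j],
                     cd$replicate[j])
      der <- asvAbundance(ext)[, j]
      der <- der[names(der) %in% st$truth$asv_ids]
      if (sum(der) == 0) next
      der <- der / sum(der)
      truth_e <- st$truth$external[[key]][match(names(der), st$truth$asv_ids)]
      truth_i <- st$truth$internal[[key]][match(names(der), st$truth$asv_ids)]
      bc <- function(a, b) sum(abs(a / sum(a) - b / sum(b))) / 2
      d_ext <- c(d_ext, bc(der, truth_e))
      d_int <- c(d_int, bc(der, truth_i))
    }
    if (mean(d_ext) < mean(d_int)) hits <- hits + 1L
  }
  expect_gte(hits / runs, 0.9)
})
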