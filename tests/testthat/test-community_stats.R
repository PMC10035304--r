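test_that("relative-abundance conversion normalizes rows and is idempotent", {
  m <- rbind(s1 = c(A = 3, B = 1), s2 = c(A = 0, B = 0))
  x <- asvFromSamples(m)
  expect_warning(r <- toRelativeAbundance(x), "all-zero")
  a <- asvAbundance(r, transpose = TRUE)
  expect_equal(a["s1", ], c(A = 0.75, B = 0.25))
  expect_equal(a["s2", ], c(A = 0, B = 0))
  expect_identical(toRelativeAbundance(r), r)
})

test_that("Bray-Curtis is a [0,1] semimetric matching the field standard", {
  x <- rbind(a = c(0.5, 0.5, 0), b = c(0, 0.5, 0.5), c = c(0.5, 0.5, 0),
             d = c(0, 0, 1))
  d <- brayCurtis(t(x))
  expect_equal(d["a", "c"], 0)        # identical profiles
  expect_equal(d["a", "d"], 1)        # disjoint supports
  expect_equal(d["a", "b"], 0.5)      # hand evaluation of the formula

  skip_if_not_installed("vegan")
  set.seed(31)
  for (i in 1:10) {
    m <- t(vapply(1:6, function(j) randomSimplex(12), numeric(12)))
    dd <- brayCurtis(t(m))
    expect_equal(max(abs(dd - t(dd))), 0)
    expect_true(all(diag(dd) == 0))
    expect_true(all(dd >= 0 & dd <= 1))
    expect_equal(dd, as.matrix(vegan::vegdist(m, "bray")),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(brayCurtis(matrix(1, 3, 1)), "at least 2 samples")
})

test_that("PERMANOVA partitions variance like adonis2 and sums R2 to one", {
  skip_if_not_installed("vegan")
  set.seed(41)
  m <- t(vapply(1:12, function(j) randomSimplex(20), numeric(20)))
  rownames(m) <- paste0("s", 1:12)
  d <- brayCurtis(t(m))
  md <- data.frame(g = factor(rep(c("A", "B", "C"), each = 4)),
                   h = factor(rep(c("x", "y"), 6)),
                   row.names = rownames(m))
  r <- permanova(d, md, c("g", "h", "g:h"), n_perm = 499, seed = 9)
  a <- vegan::adonis2(as.dist(d) ~ g + h + g:h, data = md,
                      permutations = 499, by = "terms")
  expect_equal(r@terms$SS, a$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(r@terms$F, a$F[1:3], tolerance = 1e-9)
  expect_equal(r@terms$R2, a$R2[1:3], tolerance = 1e-9)
  expect_equal(r@residual_SS, a$SumOfSqs[4], tolerance = 1e-9)
  expect_equal(sum(r@terms$R2) + r@residual_SS / r@total_SS, 1,
               tolerance = 1e-9)
  # bit-reproducible under the seed; p never 0
  r2 <- permanova(d, md, c("g", "h", "g:h"), n_perm = 499, seed = 9)
  expect_identical(r@terms$p, r2@terms$p)
  expect_true(all(r@terms$p > 0))
  md$g2 <- factor(as.integer(md$g))  # perfectly confounded with g
  expect_error(permanova(d, md, c("g", "g2"), n_perm = 9), "aliased")
})

test_that("a perfectly separated design explains all variance", {
  # within-group profiles identical, between-group distinct
  m <- cbind(g1a = c(1, 0, 0), g1b = c(1, 0, 0),
             g2a = c(0, 1, 0), g2b = c(0, 1, 0))
  d <- brayCurtis(m)
  md <- data.frame(g = factor(c("A", "A", "B", "B")),
                   row.names = colnames(m))
  r <- permanova(d, md, "g", n_perm = 99, seed = 1)
  expect_equal(r@terms$R2, 1, tolerance = 1e-12)
  expect_equal(r@residual_SS, 0, tolerance = 1e-12)
})

test_that("exhaustive permutation p equals brute-force enumeration", {
  set.seed(51)
  for (i in 1:5) {
    y <- matrix(rnorm(6 * 3), 6, 3)
    rownames(y) <- paste0("s", 1:6)
    d <- as.matrix(dist(y))
    g <- factor(rep(c("A", "B"), each = 3))
    r <- permanova(d, data.frame(g = g, row.names = rownames(y)), "g",
                   exhaustive = TRUE)
    expect_equal(r@terms$p, oracleExactP(d, g), tolerance = 1e-12)
    # and the F statistic agrees with the distance-sums route
    expect_equal(r@terms$F, oracleDistF(d, g), tolerance = 1e-9)
  }
})

test_that("Euclidean univariate PERMANOVA reproduces classical ANOVA F", {
  set.seed(61)
  for (i in 1:5) {
    y <- rnorm(15)
    g <- factor(rep(c("A", "B", "C"), each = 5))
    d <- as.matrix(dist(y))
    rownames(d) <- colnames(d) <- paste0("s", 1:15)
    r <- permanova(d, data.frame(g = g, row.names = rownames(d)), "g",
                   n_perm = 49, seed = 1)
    expect_equal(r@terms$F, anova(lm(y ~ g))$`F value`[1], tolerance = 1e-9)
  }
})

test_that("pairwise contrasts agree with the two-level full model", {
  set.seed(71)
  m <- t(vapply(1:9, function(j) randomSimplex(15), numeric(15)))
  rownames(m) <- paste0("s", 1:9)
  d <- brayCurtis(t(m))
  md <- data.frame(g = factor(rep(c("A", "B", "C"), each = 3)),
                   row.names = rownames(m))
  pw <- pairwisePermanova(d, md, "g", n_perm = 199, seed = 4)
  expect_equal(nrow(pw), 3L)  # 3 levels -> 3 pairs
  # a two-level factor's single pair reproduces the full model
  sel <- md$g %in% c("A", "B")
  full <- permanova(d[sel, sel], md[sel, , drop = FALSE], "g",
                    n_perm = 199, seed = 4)
  row_ab <- pw[pw$level1 == "A" & pw$level2 == "B", ]
  expect_equal(row_ab$R2, full@terms$R2, tolerance = 1e-12)
  expect_identical(row_ab$p, full@terms$p)
  expect_true(all(pw$p_holm >= pw$p))
  # singleton levels are skipped with a warning
  md2 <- md; md2$g <- factor(c("A", "A", "A", "B", "B", "B", "C", "C", "D"))
  expect_warning(pw2 <- pairwisePermanova(d, md2, "g", n_perm = 99, seed = 1),
                 "skipped")
  expect_equal(nrow(pw2), 3L)
})

test_that("PCoA recovers closed-form and cmdscale eigenstructure", {
  # 3 equidistant points (d = 1): two equal positive eigenvalues, zero third
  d3 <- matrix(1, 3, 3) - diag(3)
  rownames(d3) <- colnames(d3) <- c("a", "b", "c")
  p3 <- pcoaOrdination(d3)
  expect_equal(p3$eigenvalues[1:2], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(p3$eigenvalues), 1, tolerance = 1e-12)

  set.seed(81)
  y <- matrix(rnorm(8 * 3), 8, 3)
  rownames(y) <- paste0("s", 1:8)
  dE <- as.matrix(dist(y))
  pE <- pcoaOrdination(dE)
  expect_true(all(pE$eigenvalues >= -1e-9))  # Euclidean embeddability
  cs <- suppressWarnings(cmdscale(as.dist(dE), k = 7, eig = TRUE))
  expect_equal(pE$eigenvalues, cs$eig[1:7], tolerance = 1e-9)
  # pairwise distances in the full embedding reproduce the input
  emb <- as.matrix(dist(pE$points))
  expect_equal(emb, dE, tolerance = 1e-9, ignore_attr = TRUE)

  # duplicated sample shows up as a zero-distance coordinate pair
  dD <- as.matrix(dist(y[c(1, 1, 2, 3, 4), ]))
  rownames(dD) <- colnames(dD) <- paste0("q", 1:5)
  pD <- pcoaOrdination(dD)
  expect_lt(sqrt(sum((pD$points[1, ] - pD$points[2, ])^2)), 1e-6)
})

test_that("dispersion analysis matches betadisper and handles degeneracy", {
  skip_if_not_installed("vegan")
  set.seed(91)
  m <- t(vapply(1:12, function(j) randomSimplex(18), numeric(18)))
  rownames(m) <- paste0("s", 1:12)
  d <- brayCurtis(t(m))
  g <- factor(rep(c("A", "B"), each = 6))
  mine <- dispersionTest(d, g, n_perm = 199, seed = 5)
  bd <- vegan::betadisper(as.dist(d), g, type = "centroid")
  expect_equal(unname(mine@distances), unname(bd$distances), tolerance = 1e-9)
  expect_equal(mine@statistic, anova(bd)$`F value`[1], tolerance = 1e-9)
  expect_identical(dispersionTest(d, g, n_perm = 199, seed = 5)@p, mine@p)

  # degenerate: two groups of identical duplicated points
  ddup <- matrix(0, 4, 4)
  ddup[1:2, 3:4] <- 1; ddup[3:4, 1:2] <- 1
  rownames(ddup) <- colnames(ddup) <- paste0("s", 1:4)
  deg <- dispersionTest(ddup, factor(c("A", "A", "B", "B")), n_perm = 99,
                        seed = 1)
  expect_true(deg@degenerate)
  expect_equal(deg@p, 1)
  expect_true(all(deg@distances < 1e-9))
  expect_error(dispersionTest(d, factor(c(rep("A", 11), "B"))), "single member")
})

test_that("dispersion test detects a genuinely wider group", {
  set.seed(95)
  hits <- 0L; runs <- 10L
  for (i in seq_len(runs)) {
    tight <- matrix(rnorm(10 * 3, sd = 0.1), 10, 3)
    spread <- matrix(rnorm(10 * 3, sd = 1), 10, 3)
    y <- rbind(tight, spread)
    rownames(y) <- paste0("s", 1:20)
    d <- as.matrix(dist(y))
    g <- factor(rep(c("tight", "spread"), each = 10))
    res <- dispersionTest(d, g, n_perm = 199, seed = i)
    if (res@p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / runs, 0.95)
})

test_that("permutation ANOVA on scalars matches lm and flags degeneracy", {
  set.seed(99)
  g <- factor(rep(c("A", "B", "C"), each = 6))
  y <- rnorm(18) + as.numeric(g)
  df <- data.frame(y = y, g = g)
  r <- alphaPermutationAnova(df, "y", "g", n_perm = 199, seed = 2)
  expect_equal(r$F, anova(lm(y ~ g))$`F value`[1], tolerance = 1e-9)
  expect_identical(alphaPermutationAnova(df, "y", "g", n_perm = 199,
                                         seed = 2)$p, r$p)
  # constant response
  dfc <- data.frame(y = rep(3, 18), g = g)
  rc <- alphaPermutationAnova(dfc, "y", "g", n_perm = 99, seed = 1)
  expect_equal(rc$F, 0)
  expect_equal(rc$p, 1)
  expect_true(attr(rc, "degenerate"))
  # a strong injected shift is detected
  y2 <- rnorm(16)
  y2[9:16] <- y2[9:16] + 3 * sd(y2)
  df2 <- data.frame(y = y2, g = factor(rep(c("A", "B"), each = 8)))
  r2 <- alphaPermutationAnova(df2, "y", "g", n_perm = 999, seed = 3)
  expect_lte(r2$p, 0.01)
})

test_that("taxon summaries aggregate ranks and group statistics", {
  m <- rbind(s1 = c(a1 = 0.1, a2 = 0.2, a3 = 0.7),
             s2 = c(a1 = 0.1, a2 = 0.2, a3 = 0.7),
             s3 = c(a1 = 0.5, a2 = 0.5, a3 = 0))
  x <- asvFromSamples(m, mode = "relative")
  tx <- makeTaxonomy(c("a1", "a2", "a3"),
                     genus = c("Tychonema", "Tychonema", ""))
  groups <- c("g1", "g1", "g2")
  out <- taxonSummary(x, tx, "genus", groups)
  g1_tych <- out[out$group == "g1" & out$taxon == "Tychonema", ]
  expect_equal(g1_tych$mean, 0.3)        # 0.1 + 0.2 summed within sample
  expect_equal(g1_tych$sd, 0)            # identical samples
  expect_true("unassigned" %in% out$taxon)
  expect_equal(out[out$group == "g2" & out$taxon == "Tychonema", "mean"], 1)
  expect_error(taxonSummary(x, tx, "species", groups), "unknown rank")
})
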