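# shared fixtures and independent oracles, built in code at test time

suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# small AsvExperiment from a samples x ASVs matrix written as rows = samples
asvFromSamples <- function(m, mode = "counts", marker = "unspecified",
                           colData = NULL) {
  AsvExperiment(t(m), mode = mode, marker = marker, colData = colData)
}

# minimal taxonomy data.frame
makeTaxonomy <- function(asv_id, domain = "Bacteria", genus = "",
                         phylum = "", family = "",
                         percent_identity = 100, query_coverage = 100) {
  data.frame(asv_id = asv_id, domain = domain, phylum = phylum,
             class = "", order = "", family = family, genus = genus,
             percent_identity = percent_identity,
             query_coverage = query_coverage, stringsAsFactors = FALSE)
}

# minimal metadata row(s)
makeMetadata <- function(sample_id, sample_class = "individual",
                         host = "P_murrayi", wash_status = "washed",
                         stream = "Canada", mat_type = "black",
                         replicate = 1L, marker = "18S") {
  validateSampleMetadata(data.frame(
    sample_id = sample_id, sample_class = sample_class, host = host,
    wash_status = wash_status, stream = stream, mat_type = mat_type,
    replicate = replicate, marker = marker, stringsAsFactors = FALSE))
}

# single-profile AsvExperiment for derivation tests
makeProfile <- function(abund, type, host = "P_murrayi", stream = "Canada",
                        mat_type = "black", replicate = 1L, n = 1L) {
  id <- sprintf("%s.%s.%s.%s.r%d", type, host, stream, mat_type, replicate)
  AsvExperiment(matrix(abund, ncol = 1,
                       dimnames = list(names(abund), id)),
                mode = "counts",
                colData = S4Vectors::DataFrame(
                  microbiome_type = type, host = host, stream = stream,
                  mat_type = mat_type, replicate = as.integer(replicate),
                  n_individuals = as.integer(n), row.names = id))
}

# ---- independent oracles ----

# one-way PERMANOVA F from within/between group distance sums
# (Anderson's formula on squared dissimilarities; no Gower/hat matrices)
oracleDistF <- function(d, g) {
  g <- as.factor(g)
  n <- nrow(d); a <- nlevels(g)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (lev in levels(g)) {
    rows <- which(g == lev)
    sub <- d[rows, rows, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(rows)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# exact permutation p for a balanced two-group design by enumerating the
# choose(n, n1) distinct label splits (each split occurs equally often among
# the n! row permutations)
oracleExactP <- function(d, g) {
  g <- as.factor(g)
  f_obs <- oracleDistF(d, g)
  lev <- levels(g)
  n1 <- sum(g == lev[1])
  splits <- utils::combn(nrow(d), n1, simplify = FALSE)
  fs <- vapply(splits, function(idx) {
    gg <- factor(ifelse(seq_len(nrow(d)) %in% idx, lev[1], lev[2]))
    oracleDistF(d, gg)
  }, numeric(1))
  mean(fs >= f_obs - 1e-12 * max(1, abs(f_obs)))
}

# Faith's PD by brute-force path-union enumeration (root-to-tip node paths
# via ape::nodepath; edges deduplicated across tips)
oracleFaithPD <- function(present, tree) {
  root <- length(tree$tip.label) + 1L
  edges <- character()
  for (tip in match(present, tree$tip.label)) {
    path <- ape::nodepath(tree, root, tip)
    edges <- union(edges, paste(path[-length(path)], path[-1]))
  }
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[key %in% edges])
}

# random simplex vector
randomSimplex <- function(k) {
  x <- rexp(k)
  x / sum(x)
}

# scaled-down generator parameters for fast unit tests (not the study
# conditions; those are simulationParams() defaults)
smallParams <- function(...) {
  simulationParams(n_streams = 2, replicates_per_mat = 2, S = 60,
                   depth_mat = 3000, depth_individual = 500, ...)
}
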