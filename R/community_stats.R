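# Compositional statistics implemented from first principles:
# relative-abundance conversion, Bray-Curtis, sequential-SS PERMANOVA with
# permutation p-values, pairwise contrasts, PCoA, betadisper-style
# dispersion testing, permutation ANOVA for scalar responses, and taxon
# relative-abundance summaries.

#' Convert read counts to relative abundance
#'
#' Divides every sample's counts by its total; all-zero samples are left at
#' zero with a warning. Idempotent: a relative-mode table is returned
#' unchanged.
#'
#' @param x an [AsvExperiment-class].
#' @return An [AsvExperiment-class] in relative mode.
#' @export
toRelativeAbundance <- function(x) {
  .assertAsv(x)
  if (identical(x@mode, "relative")) return(x)
  m <- asvAbundance(x)
  tot <- colSums(m)
  if (any(tot == 0))
    .warnf("%d all-zero sample(s) left at zero: %s", sum(tot == 0),
           paste(colnames(m)[tot == 0], collapse = ", "))
  ok <- tot > 0
  m[, ok] <- sweep(m[, ok, drop = FALSE], 2L, tot[ok], "/")
  AsvExperiment(m, mode = "relative", marker = x@marker,
                rowData = rowData(x), colData = colData(x),
                metadata = metadata(x))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \deqn{d_{jk} = 1 - \frac{2\sum_i \min(x_{ij}, x_{ik})}{\sum_i x_{ij} + \sum_i x_{ik}}}
#' computed on relative abundances (enforced; convert with
#' [toRelativeAbundance()] first).
#'
#' @param x an [AsvExperiment-class] in relative mode, or a numeric
#'   samples-in-columns matrix.
#' @return symmetric numeric matrix of dissimilarities in `[0, 1]` with
#'   sample ids as dimnames.
#' @export
brayCurtis <- function(x) {
  if (methods::is(x, "AsvExperiment")) {
    .assertAsv(x, mode = "relative")
    m <- asvAbundance(x)
  } else m <- as.matrix(x)
  n <- ncol(m)
  if (n < 2L) .stopf("Bray-Curtis needs at least 2 samples")
  tot <- colSums(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(n - 1L)) {
    rest <- (j + 1L):n
    shared <- colSums(pmin(m[, rest, drop = FALSE], m[, j]))
    denom <- tot[j] + tot[rest]
    dv <- ifelse(denom > 0, 1 - 2 * shared / denom, 0)
    d[j, rest] <- dv
    d[rest, j] <- dv
  }
  d
}

# Gower-centered inner-product matrix G = -1/2 J D^2 J
.gowerCenter <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1L, rm), 2L, rm) + gm
}

.asDistMatrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12 ||
      any(abs(diag(d)) > 1e-12))
    .stopf("a symmetric zero-diagonal dissimilarity matrix is required")
  d
}

# align a metadata data.frame to distance-matrix ids
.alignMeta <- function(d, data) {
  ids <- rownames(d)
  if (!is.null(ids)) {
    if (all(ids %in% rownames(data))) return(data[ids, , drop = FALSE])
    for (col in c("profile_id", "sample_id"))
      if (col %in% names(data) && all(ids %in% data[[col]]))
        return(data[match(ids, data[[col]]), , drop = FALSE])
  }
  if (nrow(data) != nrow(d))
    .stopf("metadata rows (%d) do not match distance matrix (%d)",
           nrow(data), nrow(d))
  data
}

# full-rank sequential projection machinery for a term list
.sequentialHats <- function(terms, data) {
  data <- as.data.frame(data)
  for (nm in names(data))
    if (is.character(data[[nm]]) || is.logical(data[[nm]]))
      data[[nm]] <- factor(data[[nm]])
  fml <- stats::reformulate(terms)
  tt <- stats::terms(fml, keep.order = TRUE)
  X <- stats::model.matrix(tt, data)
  assign <- attr(X, "assign")
  labels <- attr(tt, "term.labels")
  for (term in labels) {
    k <- match(term, labels)
    v <- data[[term]]
    if (!grepl(":", term, fixed = TRUE) && is.factor(v) &&
        nlevels(droplevels(v)) < 2L)
      .stopf("factor '%s' has fewer than 2 levels among these profiles", term)
  }
  n <- nrow(X)
  hats <- vector("list", length(labels) + 1L)
  ranks <- integer(length(labels) + 1L)
  for (k in 0:length(labels)) {
    Xk <- X[, assign <= k, drop = FALSE]
    qr_k <- qr(Xk)
    Q <- qr.Q(qr_k)[, seq_len(qr_k$rank), drop = FALSE]
    hats[[k + 1L]] <- tcrossprod(Q)
    ranks[k + 1L] <- qr_k$rank
  }
  df <- diff(ranks)
  aliased <- labels[df == 0L]
  if (length(aliased))
    .stopf("term(s) aliased with earlier terms (singular design): %s",
           paste(aliased, collapse = ", "))
  increments <- lapply(seq_along(labels),
                       function(k) hats[[k + 1L]] - hats[[k]])
  list(labels = labels, df = df, increments = increments,
       h_full = hats[[length(labels) + 1L]], rank_full = ranks[length(ranks)],
       n = n)
}

# all permutations of 1..n (n small), identity first
.allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .allPerms(n - 1L))
    for (pos in n:1)
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the variance of a dissimilarity matrix among design terms with
#' sequential (Type-I) sums of squares, in the user-given term order, in the
#' style of `vegan::adonis2(by = "terms")`. The Gower-centered inner-product
#' matrix is `G = -1/2 J D^(2) J`; `SS_total = trace(G)`; each term's SS is
#' the trace of the increment of the cumulative hat (projection) matrices
#' applied to `G`; pseudo-F is the term mean square over the residual mean
#' square; p-values come from simultaneous free permutation of rows, with
#' the (1 + #{F* >= F}) / (1 + n_perm) convention so p is never 0. With
#' `exhaustive = TRUE` all `n!` row permutations are enumerated (n <= 8) and
#' p = #{F* >= F} / n!.
#'
#' @param d dissimilarity matrix (symmetric matrix or `dist`).
#' @param data data.frame of design variables, one row per sample (aligned
#'   by rownames, `profile_id`/`sample_id` column, or row order).
#' @param terms character vector of term labels in testing order, e.g.
#'   `c("host", "stream", "host:stream")`.
#' @param n_perm number of free permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all row permutations instead (n <= 8).
#' @return a [PermanovaResult-class].
#' @export
permanova <- function(d, data, terms, n_perm = 9999, seed = 1,
                      exhaustive = FALSE) {
  d <- .asDistMatrix(d)
  data <- .alignMeta(d, data)
  n <- nrow(d)
  if (n < 3L) .stopf("PERMANOVA needs at least 3 samples")
  G <- .gowerCenter(d)
  sq <- .sequentialHats(terms, data)
  if (sq$n != n) .stopf("design rows do not match distance matrix")
  ss_total <- sum(diag(G))
  ss_terms <- vapply(sq$increments, function(H) sum(H * G), numeric(1))
  ss_res <- ss_total - sum(sq$h_full * G)
  df_res <- n - sq$rank_full
  if (df_res < 1L) .stopf("no residual degrees of freedom")
  ms_res <- ss_res / df_res
  f_obs <- (ss_terms / sq$df) / ms_res

  f_ge <- function(fp, fo) {
    tol <- 1e-12 * pmax(1, abs(fo))
    tol[!is.finite(fo)] <- 0
    cmp <- fp >= fo - tol
    !is.na(cmp) & cmp
  }
  perm_f <- function(p) {
    Gp <- G[p, p]
    ssr <- ss_total - sum(sq$h_full * Gp)
    ssk <- vapply(sq$increments, function(H) sum(H * Gp), numeric(1))
    (ssk / sq$df) / (ssr / df_res)
  }
  if (exhaustive) {
    if (n > 8L) .stopf("exhaustive mode limited to n <= 8 (n! permutations)")
    perms <- .allPerms(n)
    counts <- numeric(length(ss_terms))
    for (p in perms) {
      fp <- perm_f(p)
      counts <- counts + f_ge(fp, f_obs)
    }
    pvals <- counts / length(perms)
    n_used <- length(perms)
  } else {
    counts <- withSeed(seed, function() {
      cnt <- numeric(length(ss_terms))
      for (b in seq_len(n_perm)) {
        fp <- perm_f(sample.int(n))
        cnt <- cnt + f_ge(fp, f_obs)
      }
      cnt
    })
    pvals <- (1 + counts) / (1 + n_perm)
    n_used <- n_perm
  }
  if (ms_res <= 1e-12 * max(1, ss_total)) {
    # all variance explained: F degenerates; report Inf F where SS > 0
    f_obs <- ifelse(ss_terms > 0, Inf, 0)
  }
  new("PermanovaResult",
      terms = data.frame(term = sq$labels, df = sq$df, SS = ss_terms,
                         F = f_obs, R2 = ss_terms / ss_total, p = pvals,
                         stringsAsFactors = FALSE),
      residual_df = df_res, residual_SS = ss_res, total_SS = ss_total,
      n_perm = n_used, exhaustive = exhaustive,
      seed = if (exhaustive) NA_real_ else as.numeric(seed))
}

#' Pairwise post hoc PERMANOVA contrasts
#'
#' One single-factor PERMANOVA per unordered pair of factor levels, run on
#' the sub-matrix of samples in those two levels, with Holm-adjusted
#' p-values across pairs. Levels with fewer than 2 members are skipped with
#' a warning.
#'
#' @param d dissimilarity matrix.
#' @param data design data.frame.
#' @param factor_name name of the factor column to contrast.
#' @param n_perm,seed permutation settings (the same seed is used for every
#'   pair, so a two-level factor reproduces the full-model result).
#' @return data.frame with one row per tested pair: `level1`, `level2`,
#'   `df`, `SS`, `F`, `R2`, `p`, `p_holm`.
#' @export
pairwisePermanova <- function(d, data, factor_name, n_perm = 999, seed = 1) {
  d <- .asDistMatrix(d)
  data <- .alignMeta(d, data)
  f <- factor(data[[factor_name]])
  if (nlevels(f) < 2L) .stopf("factor '%s' has fewer than 2 levels", factor_name)
  sizes <- table(f)
  ok_levels <- names(sizes)[sizes >= 2L]
  skipped <- setdiff(levels(f), ok_levels)
  if (length(skipped))
    .warnf("level(s) with < 2 members skipped: %s",
           paste(skipped, collapse = ", "))
  pairs <- utils::combn(ok_levels, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- f %in% pr
    res <- permanova(d[sel, sel, drop = FALSE],
                     data.frame(.g = droplevels(f[sel]),
                                row.names = rownames(d)[sel]),
                     terms = ".g", n_perm = n_perm, seed = seed)
    tt <- res@terms
    data.frame(level1 = pr[1], level2 = pr[2], df = tt$df, SS = tt$SS,
               F = tt$F, R2 = tt$R2, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Principal coordinates analysis (classical MDS on a dissimilarity matrix)
#'
#' Eigendecomposition of the Gower-centered matrix. All axes are returned,
#' including those with negative eigenvalues (the "imaginary" axes of a
#' non-Euclidean dissimilarity), flagged in `negative`; coordinates are
#' eigenvectors scaled by the square root of the absolute eigenvalue.
#'
#' @param d dissimilarity matrix (symmetric matrix or `dist`).
#' @return list with `points` (samples x axes), `eigenvalues`, and
#'   `negative` (logical flag per axis).
#' @export
pcoaOrdination <- function(d) {
  d <- .asDistMatrix(d)
  if (nrow(d) < 3L) .stopf("PCoA needs at least 3 samples")
  G <- .gowerCenter(d)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  # centering removes exactly one dimension: drop the eigenvalue nearest
  # zero (it sorts between the positive and negative axes, so dropping the
  # last sorted value would discard a genuine negative axis instead)
  keep <- setdiff(seq_len(nrow(d)), which.min(abs(e$values)))
  lam <- e$values[keep]
  pts <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(abs(lam)), length(lam))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_along(lam))
  list(points = pts, eigenvalues = lam, negative = lam < 0)
}

# distances to group centroids in PCoA space with Anderson's
# real-minus-imaginary squared-distance correction; clamped at 0
.centroidDistances <- function(pts, lam, groups, tol) {
  use <- abs(lam) > tol
  pts <- pts[, use, drop = FALSE]
  pos <- lam[use] > 0
  n <- nrow(pts)
  d2 <- numeric(n)
  for (g in levels(groups)) {
    rows <- which(groups == g)
    cen <- colMeans(pts[rows, , drop = FALSE])
    dev2 <- sweep(pts[rows, , drop = FALSE], 2L, cen)^2
    d2[rows] <- rowSums(dev2[, pos, drop = FALSE]) -
      rowSums(dev2[, !pos, drop = FALSE])
  }
  clamped <- d2 < 0
  d2[clamped] <- 0
  list(dist = sqrt(d2), clamped = clamped)
}

.dispersionF <- function(dd, groups) {
  k <- nlevels(groups); n <- length(dd)
  gm <- tapply(dd, groups, mean)
  ss_b <- sum(tabulate(groups) * (gm - mean(dd))^2)
  ss_w <- sum((dd - gm[as.integer(groups)])^2)
  if (ss_w <= 0) return(NA_real_)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

#' Test homogeneity of multivariate group dispersions
#'
#' A betadisper-style analysis: samples are embedded by PCoA, each sample's
#' distance to its group centroid is computed with the real-minus-imaginary
#' correction for negative eigenvalues (clamped at zero, flagged), and the
#' group effect on those distances is tested with a one-way F statistic
#' whose p-value comes from permuting group labels and recomputing the
#' whole procedure (centroids included) each time.
#'
#' @param d dissimilarity matrix.
#' @param groups factor (or coercible) of group membership, every group with
#'   at least 2 members.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @return a [DispersionResult-class].
#' @export
dispersionTest <- function(d, groups, n_perm = 999, seed = 1) {
  d <- .asDistMatrix(d)
  groups <- factor(groups)
  if (length(groups) != nrow(d))
    .stopf("groups length (%d) does not match distance matrix (%d)",
           length(groups), nrow(d))
  small <- names(which(table(groups) < 2L))
  if (length(small))
    .stopf("group(s) with a single member: %s", paste(small, collapse = ", "))
  ord <- pcoaOrdination(d)
  tol <- max(abs(ord$eigenvalues), 1e-12) * 1e-8
  obs <- .centroidDistances(ord$points, ord$eigenvalues, groups, tol)
  scale0 <- max(ord$points^2, 1e-12)
  if (all(obs$dist^2 <= scale0 * 1e-12)) {
    return(new("DispersionResult",
               distances = stats::setNames(obs$dist, rownames(d)),
               clamped = obs$clamped, groups = groups,
               group_means = c(tapply(obs$dist, groups, mean)),
               statistic = NA_real_, p = 1, degenerate = TRUE,
               n_perm = n_perm, seed = as.numeric(seed)))
  }
  f_obs <- .dispersionF(obs$dist, groups)
  if (is.na(f_obs)) {
    p <- 1
  } else {
    count <- withSeed(seed, function() {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        gp <- groups[sample.int(length(groups))]
        fp <- .dispersionF(
          .centroidDistances(ord$points, ord$eigenvalues, gp, tol)$dist, gp)
        if (!is.na(fp) && fp >= f_obs - 1e-12 * max(1, abs(f_obs)))
          cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + count) / (1 + n_perm)
  }
  new("DispersionResult",
      distances = stats::setNames(obs$dist, rownames(d)),
      clamped = obs$clamped, groups = groups,
      group_means = c(tapply(obs$dist, groups, mean)),
      statistic = if (is.na(f_obs)) NA_real_ else f_obs, p = p,
      degenerate = FALSE, n_perm = n_perm, seed = as.numeric(seed))
}

#' Permutation ANOVA for a scalar response
#'
#' Sequential (Type-I) sums of squares for a scalar response (for example an
#' alpha-diversity metric) over an ordered list of design terms, with
#' p-values from free permutation of the response values. The single-factor
#' case reproduces the classical one-way ANOVA F exactly; only the p-value
#' is permutation-based.
#'
#' @param data data.frame holding the response and design columns.
#' @param response name of the numeric response column.
#' @param terms character vector of term labels in testing order.
#' @param n_perm,seed permutation settings.
#' @return data.frame with one row per term (`term`, `df`, `SS`, `F`, `p`)
#'   plus attributes `residual_df`, `residual_SS`, `degenerate`.
#' @export
alphaPermutationAnova <- function(data, response, terms, n_perm = 999,
                                  seed = 1) {
  y <- data[[response]]
  if (!is.numeric(y) || anyNA(y))
    .stopf("response '%s' must be numeric without NA", response)
  sq <- .sequentialHats(terms, data)
  n <- length(y)
  ss_total <- sum((y - mean(y))^2)
  quad <- function(H, yy) drop(crossprod(yy, H %*% yy))
  df_res <- n - sq$rank_full
  if (df_res < 1L) .stopf("no residual degrees of freedom")
  if (ss_total <= 1e-14 * max(1, mean(y)^2)) {
    out <- data.frame(term = sq$labels, df = sq$df, SS = 0,
                      F = 0, p = 1, stringsAsFactors = FALSE)
    attr(out, "residual_df") <- df_res
    attr(out, "residual_SS") <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ss_terms <- vapply(sq$increments, quad, numeric(1), yy = y)
  ss_res <- sum(y^2) - quad(sq$h_full, y)
  f_stats <- function(yy) {
    ssk <- vapply(sq$increments, quad, numeric(1), yy = yy)
    ssr <- sum(yy^2) - quad(sq$h_full, yy)
    (ssk / sq$df) / (ssr / df_res)
  }
  f_obs <- (ss_terms / sq$df) / (ss_res / df_res)
  counts <- withSeed(seed, function() {
    cnt <- numeric(length(ss_terms))
    for (b in seq_len(n_perm)) {
      fp <- f_stats(y[sample.int(n)])
      cnt <- cnt + (fp >= f_obs - 1e-12 * pmax(1, abs(f_obs)))
    }
    cnt
  })
  out <- data.frame(term = sq$labels, df = sq$df, SS = ss_terms, F = f_obs,
                    p = (1 + counts) / (1 + n_perm), stringsAsFactors = FALSE)
  attr(out, "residual_df") <- df_res
  attr(out, "residual_SS") <- ss_res
  attr(out, "degenerate") <- FALSE
  out
}

#' Group-wise relative abundance of taxa at a rank
#'
#' Aggregates ASV relative abundances to a taxonomic rank (ASVs with an
#' empty name at that rank are pooled under `"unassigned"`) and summarizes
#' mean and SD relative abundance per group of samples.
#'
#' @param x an [AsvExperiment-class] in relative mode.
#' @param taxonomy taxonomy data.frame.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @param groups vector of group labels, one per sample (or the name of a
#'   `colData` column of `x`).
#' @return data.frame with columns `group`, `taxon`, `mean`, `sd`, `n`,
#'   sorted by group then descending mean abundance.
#' @export
taxonSummary <- function(x, taxonomy, rank, groups) {
  .assertAsv(x, mode = "relative")
  if (!rank %in% .TAX_RANKS)
    .stopf("unknown rank '%s'; must be one of %s", rank,
           paste(.TAX_RANKS, collapse = ", "))
  if (length(groups) == 1L && is.character(groups) &&
      groups %in% names(colData(x)))
    groups <- colData(x)[[groups]]
  groups <- factor(groups)
  if (length(groups) != ncol(x))
    .stopf("groups length does not match sample count")
  tax <- taxonomy[[rank]][match(asvIds(x), taxonomy$asv_id)]
  tax[is.na(tax) | tax == ""] <- "unassigned"
  agg <- rowsum(asvAbundance(x), group = tax)  # taxa x samples
  rows <- lapply(levels(groups), function(g) {
    sub <- agg[, groups == g, drop = FALSE]
    data.frame(group = g, taxon = rownames(agg),
               mean = rowMeans(sub),
               sd = apply(sub, 1L, stats::sd),
               n = ncol(sub), row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$group, -out$mean), , drop = FALSE]
}
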