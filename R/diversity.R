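# Alpha diversity: Hill numbers of order q and Faith's phylogenetic
# diversity, plus a tidy per-profile metric table.

#' Hill diversity of order q
#'
#' The effective number of equally abundant taxa:
#' \deqn{{}^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}{qD = (sum p_i^q)^(1/(1-q))}
#' for \eqn{q \ne 1}, and \eqn{\exp(-\sum_i p_i \log p_i)} at \eqn{q = 1}.
#' The abundance vector is renormalized internally to proportions, so counts
#' and relative abundances give identical results; zero entries are excluded
#' from the sums. q = 0 is ASV richness, q = 1 exponential Shannon, q = 2
#' inverse Simpson.
#'
#' @param abundances nonnegative numeric vector with at least one positive
#'   entry.
#' @param q diversity order, real >= 0 (may be a vector).
#' @return numeric, one effective number per order in `q`.
#' @examples
#' hillDiversity(c(1, 1, 1, 1), q = 2)       # 4
#' hillDiversity(c(0.8, 0.2), q = 2)         # 1.470588...
#' @export
hillDiversity <- function(abundances, q) {
  if (any(abundances < 0) || any(!is.finite(abundances)))
    .stopf("abundances must be finite and nonnegative")
  if (any(q < 0)) .stopf("q must be >= 0")
  tot <- sum(abundances)
  if (tot == 0) .stopf("diversity is undefined for an all-zero profile")
  p <- abundances[abundances > 0] / tot
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-12) exp(-sum(p * log(p)))
    else sum(p^qq)^(1 / (1 - qq))
  }, numeric(1))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal rooted subtree connecting the root
#' and every tip with positive abundance (the rooted/inclusive convention:
#' branches on the path from the root to the observed tips are counted, so a
#' single-tip community has PD equal to its root-to-tip path length).
#'
#' @param abundances nonnegative named numeric vector; names are tree tip
#'   labels. Only presence (abundance > 0) matters.
#' @param tree a rooted `ape::phylo` with branch lengths (see
#'   [readAsvTree()]).
#' @return numeric(1), total branch length of the spanned subtree.
#' @export
faithPD <- function(abundances, tree) {
  tree <- validateAsvTree(tree)
  if (is.null(names(abundances)))
    .stopf("abundances must be named by tree tip labels")
  present <- names(abundances)[abundances > 0]
  if (!length(present)) .stopf("Faith's PD is undefined for an all-zero profile")
  miss <- setdiff(present, tree$tip.label)
  if (length(miss))
    .stopf("tip(s) with positive abundance missing from tree: %s",
           paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  used <- logical(ntip + tree$Nnode)
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    while (node != 0L && !used[node]) {  # climb to root, stop at visited node
      used[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(elen[used])
}

#' Tidy alpha-diversity table over a profile set
#'
#' Computes ASV richness (q = 0), exponential Shannon (q = 1), inverse
#' Simpson (q = 2) and, when a tree is supplied, Faith's PD for every
#' profile, returning one row per profile x metric together with the
#' profile's design metadata. All-zero profiles get `NA` values flagged
#' `undefined = TRUE` so they can be excluded downstream.
#'
#' @param profiles an [AsvExperiment-class] of profiles (columns).
#' @param tree optional rooted `ape::phylo`; when absent, `faith_pd` rows are
#'   omitted with a warning.
#' @return data.frame with columns `profile_id`, the profile colData columns,
#'   `metric`, `q`, `value`, `undefined`.
#' @export
alphaTable <- function(profiles, tree = NULL) {
  .assertAsv(profiles)
  if (ncol(profiles) == 0L) .stopf("no profiles given")
  metrics <- data.frame(metric = c("richness", "shannon", "simpson"),
                        q = c(0, 1, 2))
  if (is.null(tree)) .warnf("no tree supplied; faith_pd rows omitted")
  else metrics <- rbind(metrics, data.frame(metric = "faith_pd", q = NA))
  m <- asvAbundance(profiles)
  cd <- as.data.frame(colData(profiles))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    ok <- sum(v) > 0
    vals <- vapply(seq_len(nrow(metrics)), function(k) {
      if (!ok) return(NA_real_)
      if (metrics$metric[k] == "faith_pd")
        faithPD(stats::setNames(v, rownames(m)), tree)
      else hillDiversity(v, metrics$q[k])
    }, numeric(1))
    data.frame(profile_id = colnames(m)[j],
               cd[rep(j, nrow(metrics)), , drop = FALSE],
               metric = metrics$metric, q = metrics$q, value = vals,
               undefined = !ok, row.names = NULL)
  })
  do.call(rbind, rows)
}
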