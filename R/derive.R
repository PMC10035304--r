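# Construction of representative internal, unwashed and external microbiome
# profiles per host x mat replicate: per-replicate averaging of individuals
# followed by clipped subtraction of internal from unwashed abundances.

.PROFILE_COLS <- c("microbiome_type", "host", "stream", "mat_type",
                   "replicate", "n_individuals")

# colData skeleton for a profile set
.profileColData <- function(microbiome_type, host, stream, mat_type,
                            replicate, n_individuals, ids) {
  DataFrame(microbiome_type = microbiome_type, host = host, stream = stream,
            mat_type = mat_type, replicate = as.integer(replicate),
            n_individuals = as.integer(n_individuals), row.names = ids)
}

#' Average individual specimens into one profile per mat replicate
#'
#' For one host and one wash status, individuals are grouped by
#' (stream, mat type, replicate) and their ASV counts averaged arithmetically
#' into a single representative profile. Averaging is on raw counts by
#' default, so deeper-sequenced individuals carry more weight;
#' `normalize_individuals = TRUE` first scales each individual to its mean
#' depth within the group (depth-normalized averaging, for sensitivity
#' analysis). Replicates with no matching individual yield no profile and are
#' logged with a warning.
#'
#' @param x preprocessed [AsvExperiment-class] in counts mode (host reads
#'   already removed).
#' @param metadata sample metadata data.frame.
#' @param host host name (must not be `"none"`).
#' @param wash_status `"washed"` or `"unwashed"`.
#' @param normalize_individuals average depth-normalized individuals instead
#'   of raw counts.
#' @return An [AsvExperiment-class] of profiles (columns), with
#'   `microbiome_type` `"internal"` for washed and `"unwashed"` otherwise,
#'   design keys and `n_individuals` in `colData()`.
#' @export
averageIndividuals <- function(x, metadata, host,
                               wash_status = c("washed", "unwashed"),
                               normalize_individuals = FALSE) {
  .assertAsv(x, mode = "counts")
  wash_status <- match.arg(wash_status)
  if (identical(host, "none")) .stopf("host must name a host taxon, not 'none'")
  metadata <- metadata[match(sampleIds(x), metadata$sample_id), , drop = FALSE]
  sel <- !is.na(metadata$sample_id) &
    metadata$sample_class == "individual" &
    metadata$host == host & metadata$wash_status == wash_status
  mtype <- if (wash_status == "washed") "internal" else "unwashed"
  if (!any(sel)) {
    .warnf("no %s individuals of host %s", wash_status, host)
    empty <- matrix(0, nrow(x), 0, dimnames = list(asvIds(x), character()))
    return(AsvExperiment(empty, mode = "counts", marker = x@marker,
                         colData = .profileColData(character(), character(),
                                                   character(), character(),
                                                   integer(), integer(),
                                                   character())))
  }
  md <- metadata[sel, , drop = FALSE]
  m <- asvAbundance(x)[, sel, drop = FALSE]
  key <- interaction(md$stream, md$mat_type, md$replicate, drop = TRUE,
                     sep = "|")
  groups <- levels(key)
  prof <- matrix(0, nrow(x), length(groups),
                 dimnames = list(asvIds(x), NULL))
  n_ind <- integer(length(groups))
  for (g in seq_along(groups)) {
    cols <- which(key == groups[g])
    sub <- m[, cols, drop = FALSE]
    if (normalize_individuals) {
      depths <- colSums(sub)
      target <- mean(depths[depths > 0])
      ok <- depths > 0
      sub[, ok] <- sweep(sub[, ok, drop = FALSE], 2L, depths[ok] / target, "/")
    }
    prof[, g] <- rowMeans(sub)
    n_ind[g] <- length(cols)
  }
  parts <- do.call(rbind, strsplit(groups, "|", fixed = TRUE))
  ids <- sprintf("%s.%s.%s.%s.r%s", mtype, host, parts[, 1], parts[, 2],
                 parts[, 3])
  colnames(prof) <- ids
  AsvExperiment(prof, mode = "counts", marker = x@marker,
                colData = .profileColData(mtype, host, parts[, 1], parts[, 2],
                                          as.integer(parts[, 3]), n_ind, ids))
}

# clipped subtraction on aligned abundance vectors; ASVs missing from either
# side are treated as 0
.clipSubtract <- function(unwashed, internal) {
  ids <- union(names(unwashed), names(internal))
  u <- stats::setNames(numeric(length(ids)), ids)
  i <- u
  u[names(unwashed)] <- unwashed
  i[names(internal)] <- internal
  ext <- pmax(u - i, 0)
  clipped <- i > u
  list(external = ext, n_clipped = sum(clipped),
       clipped_mass = sum((i - u)[clipped]),
       clipped_mass_fraction = if (sum(i) > 0)
         sum(pmin(i, pmax(i - u, 0))[clipped]) / sum(i) else 0)
}

#' Derive an external microbiome by clipped subtraction
#'
#' Subtracts the internal (washed, gut) profile's absolute ASV abundances
#' from the unwashed profile of the same host and mat replicate; any
#' subtraction that would go negative (reads present in washed but not
#' unwashed specimens) is equalized to zero. The result is the derived
#' external (cuticle) microbiome for that replicate.
#'
#' @param unwashed,internal single-profile [AsvExperiment-class] objects
#'   sharing host and design keys (as produced by [averageIndividuals()]).
#' @return A single-profile [AsvExperiment-class] with
#'   `microbiome_type = "external"`; `metadata()$derivation` records the
#'   number of clipped ASVs and the clipped mass fraction.
#' @examples
#' \dontrun{
#' ext <- deriveExternal(unw[, 1], int[, 1])
#' metadata(ext)$derivation
#' }
#' @export
deriveExternal <- function(unwashed, internal) {
  .assertAsv(unwashed); .assertAsv(internal)
  if (ncol(unwashed) != 1L || ncol(internal) != 1L)
    .stopf("deriveExternal expects single-profile inputs")
  cu <- colData(unwashed); ci <- colData(internal)
  for (k in c("host", "stream", "mat_type", "replicate"))
    if (!identical(as.character(cu[[k]]), as.character(ci[[k]])))
      .stopf("design key mismatch between profiles: %s (%s vs %s)",
             k, cu[[k]], ci[[k]])
  res <- .clipSubtract(
    stats::setNames(asvAbundance(unwashed)[, 1], asvIds(unwashed)),
    stats::setNames(asvAbundance(internal)[, 1], asvIds(internal)))
  id <- sprintf("external.%s.%s.%s.r%s", cu$host, cu$stream, cu$mat_type,
                cu$replicate)
  AsvExperiment(matrix(res$external, ncol = 1,
                       dimnames = list(names(res$external), id)),
                mode = "counts", marker = unwashed@marker,
                colData = .profileColData("external", cu$host, cu$stream,
                                          cu$mat_type, cu$replicate,
                                          min(cu$n_individuals,
                                              ci$n_individuals), id),
                metadata = list(derivation = list(
                  n_clipped = res$n_clipped,
                  clipped_mass_fraction = res$clipped_mass_fraction)))
}

#' Build all microbiome profiles for a study
#'
#' For every host in the metadata and every mat replicate: averages washed
#' individuals into an internal profile and unwashed individuals into an
#' unwashed profile, then derives the external profile by clipped
#' subtraction wherever both exist. Mat samples are passed through unchanged
#' as `microbiome_type = "mat"` profiles. Replicates with only one of the
#' washed/unwashed profiles yield no external profile (warned).
#'
#' @param x preprocessed [AsvExperiment-class] in counts mode.
#' @param metadata sample metadata data.frame restricted to retained samples.
#' @param normalize_individuals see [averageIndividuals()].
#' @return An [AsvExperiment-class] of profiles with colData columns
#'   `microbiome_type` (mat/internal/unwashed/external), `host`, `stream`,
#'   `mat_type`, `replicate`, `n_individuals`; `metadata()$derivation` holds
#'   per-profile clipping summaries.
#' @export
buildAllMicrobiomes <- function(x, metadata, normalize_individuals = FALSE) {
  .assertAsv(x, mode = "counts")
  metadata <- metadata[metadata$sample_id %in% sampleIds(x), , drop = FALSE]
  hosts <- setdiff(unique(metadata$host[metadata$sample_class == "individual"]),
                   "none")
  pieces <- list()
  derivations <- list()

  mat_ids <- metadata$sample_id[metadata$sample_class == "mat"]
  if (length(mat_ids)) {
    md <- metadata[match(mat_ids, metadata$sample_id), , drop = FALSE]
    mm <- asvAbundance(x)[, mat_ids, drop = FALSE]
    pieces$mat <- AsvExperiment(
      mm, mode = "counts", marker = x@marker,
      colData = .profileColData("mat", "none", md$stream, md$mat_type,
                                md$replicate, 1L, mat_ids))
  }

  for (h in hosts) {
    int <- suppressWarnings(averageIndividuals(x, metadata, h, "washed",
                                               normalize_individuals))
    unw <- suppressWarnings(averageIndividuals(x, metadata, h, "unwashed",
                                               normalize_individuals))
    pieces[[paste0("internal.", h)]] <- int
    pieces[[paste0("unwashed.", h)]] <- unw
    keyOf <- function(p) sprintf("%s|%s|%s", colData(p)$stream,
                                 colData(p)$mat_type, colData(p)$replicate)
    ik <- keyOf(int); uk <- keyOf(unw)
    shared <- intersect(ik, uk)
    orphan <- union(setdiff(ik, uk), setdiff(uk, ik))
    if (length(orphan))
      .warnf("host %s: %d replicate(s) lack a washed or unwashed profile; no external profile derived", # nolint
             h, length(orphan))
    for (k in shared) {
      ext <- deriveExternal(unw[, which(uk == k)], int[, which(ik == k)])
      derivations[[sampleIds(ext)]] <- metadata(ext)$derivation
      metadata(ext) <- list()
      pieces[[sampleIds(ext)]] <- ext
    }
  }
  pieces <- Filter(function(p) ncol(p) > 0, pieces)
  if (!length(pieces)) .stopf("no profiles could be constructed")
  abund <- do.call(cbind, lapply(pieces, asvAbundance))
  cd <- do.call(rbind, lapply(pieces, function(p)
    colData(p)[, .PROFILE_COLS, drop = FALSE]))
  AsvExperiment(abund, mode = "counts", marker = x@marker, colData = cd,
                metadata = list(derivation = derivations))
}

#' Subset a profile set by microbiome type
#'
#' @param profiles profile [AsvExperiment-class] from [buildAllMicrobiomes()].
#' @param types character vector of microbiome types to keep.
#' @return the subset profile set.
#' @export
profileSubset <- function(profiles, types) {
  .assertAsv(profiles)
  profiles[, colData(profiles)$microbiome_type %in% types]
}
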