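# Multi-seed parameter-recovery assessment on synthetic studies: does the
# full pipeline recover the diversity gradient, the host-vs-environment
# variance partitioning, and the true external composition?

# run pipeline up to profiles for one generated study
.pipelineProfiles <- function(st) {
  prep <- suppressWarnings(preprocessStudy(st$table, st$taxonomy,
                                           st$metadata))
  suppressWarnings(buildAllMicrobiomes(prep$table, prep$metadata))
}

# mean Hill-q1 diversity per microbiome type
.meanHillByType <- function(profiles, q = 1) {
  m <- asvAbundance(profiles)
  types <- colData(profiles)$microbiome_type
  vals <- vapply(seq_len(ncol(m)), function(j) {
    if (sum(m[, j]) == 0) NA_real_ else hillDiversity(m[, j], q)
  }, numeric(1))
  tapply(vals, types, mean, na.rm = TRUE)
}

# per-term R2 of a single-marker PERMANOVA on one microbiome type
.typeR2 <- function(profiles, type, n_perm, seed) {
  sub <- profileSubset(profiles, type)
  rel <- toRelativeAbundance(sub)
  d <- brayCurtis(rel)
  res <- permanova(d, as.data.frame(colData(sub)),
                   c("host", "mat_type", "stream"), n_perm = n_perm,
                   seed = seed)
  stats::setNames(res@terms$R2, res@terms$term)
}

# mean Bray-Curtis from derived external profiles to true external vs true
# internal compositions
.externalRecovery <- function(profiles, truth) {
  ext <- profileSubset(profiles, "external")
  cd <- colData(ext)
  d_ext <- d_int <- numeric(0)
  for (j in seq_len(ncol(ext))) {
    key <- sprintf("%s|%s|%s|%d", cd$host[j], cd$stream[j], cd$mat_type[j],
                   cd$replicate[j])
    if (is.null(truth$external[[key]])) next
    der <- asvAbundance(ext)[, j]
    v <- stats::setNames(numeric(length(truth$asv_ids)), truth$asv_ids)
    hit <- intersect(names(der), truth$asv_ids)
    v[hit] <- der[hit]
    if (sum(v) == 0) next
    m <- cbind(derived = v / sum(v), true_ext = truth$external[[key]],
               true_int = truth$internal[[key]])
    d <- brayCurtis(m)
    d_ext <- c(d_ext, d["derived", "true_ext"])
    d_int <- c(d_int, d["derived", "true_int"])
  }
  c(to_true_external = mean(d_ext), to_true_internal = mean(d_int))
}

#' Assess parameter recovery over seeded synthetic studies
#'
#' Runs the full pipeline (preprocess, derive, diversity, PERMANOVA) on
#' `n_seeds` independently generated synthetic studies and records, per
#' seed: (a) whether the mean Hill-q1 diversity follows the built-in
#' gradient mat > external > internal; (b) whether the internal-only
#' PERMANOVA attributes more variance to host than to stream
#' (`R2(host) > R2(stream)`), under generator defaults; (c) whether under
#' the environment-dominant regime (`sigma_stream = 1.2`,
#' `gamma_external = 0.4`) the external-only PERMANOVA attributes at least
#' as much variance to stream as to host; (d) whether derived external
#' profiles are closer (Bray-Curtis) to the generator's true external than
#' to its true internal compositions.
#'
#' @param n_seeds number of independent synthetic studies (default 20).
#' @param master_seed master seed; per-study seeds derive from it.
#' @param n_perm permutations per PERMANOVA.
#' @return list with `per_seed` (logical data.frame, one row per seed) and
#'   `fractions` (named numeric: fraction of seeds where each property
#'   held).
#' @export
evaluateRecovery <- function(n_seeds = 20, master_seed = 1, n_perm = 499) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    st <- generateStudy(simulationParams(
      seed = deriveSeed(master_seed, paste0("recovery_", s))))
    prof <- .pipelineProfiles(st)
    hills <- .meanHillByType(prof)
    diversity_ordering <- hills[["mat"]] > hills[["external"]] &&
      hills[["external"]] > hills[["internal"]]
    r2_int <- .typeR2(prof, "internal", n_perm,
                      deriveSeed(master_seed, paste0("perm_int_", s)))
    rec <- .externalRecovery(prof, st$truth)

    ste <- generateStudy(simulationParams(
      sigma_stream = 1.2, gamma_external = 0.4,
      seed = deriveSeed(master_seed, paste0("recovery_env_", s))))
    prof_e <- .pipelineProfiles(ste)
    r2_ext <- .typeR2(prof_e, "external", n_perm,
                      deriveSeed(master_seed, paste0("perm_ext_", s)))
    data.frame(
      seed_index = s,
      diversity_ordering = diversity_ordering,
      internal_host_gt_stream = r2_int[["host"]] > r2_int[["stream"]],
      external_stream_ge_host = r2_ext[["stream"]] >= r2_ext[["host"]],
      external_recovered = rec[["to_true_external"]] <
        rec[["to_true_internal"]],
      hill_q1_mat = hills[["mat"]], hill_q1_external = hills[["external"]],
      hill_q1_internal = hills[["internal"]],
      r2_host_internal = r2_int[["host"]],
      r2_stream_internal = r2_int[["stream"]],
      r2_host_external = r2_ext[["host"]],
      r2_stream_external = r2_ext[["stream"]],
      bc_to_true_external = rec[["to_true_external"]],
      bc_to_true_internal = rec[["to_true_internal"]])
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       fractions = c(
         diversity_ordering = mean(per_seed$diversity_ordering),
         internal_host_gt_stream = mean(per_seed$internal_host_gt_stream),
         external_stream_ge_host = mean(per_seed$external_stream_ge_host),
         external_recovered = mean(per_seed$external_recovered)))
}
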