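# Filtering and cleanup rules that turn a raw ASV table into an
# analysis-ready community table. Every function returns
# list(table = <AsvExperiment>, report = <FilterReport>) and is idempotent.

#' Keep only ASVs assigned to the target domain
#'
#' Removes non-bacterial ASVs from a 16S table (or non-eukaryotic ASVs from
#' an 18S table). ASVs with an empty or missing domain assignment are treated
#' conservatively as non-target and removed, counted separately under the
#' rule `unassigned_domain`. The sample set is unchanged.
#'
#' @param x an [AsvExperiment-class].
#' @param taxonomy taxonomy data.frame (see [readTaxonomy()]); ASVs absent
#'   from it count as unassigned.
#' @param target `"Bacteria"` or `"Eukaryota"`.
#' @return `list(table, report)`.
#' @export
filterTargetDomain <- function(x, taxonomy, target = c("Bacteria", "Eukaryota")) {
  .assertAsv(x)
  target <- match.arg(target)
  dom <- taxonomy$domain[match(asvIds(x), taxonomy$asv_id)]
  dom[is.na(dom)] <- ""
  keep <- dom == target
  unassigned <- dom == ""
  before <- colSums(asvAbundance(x))
  out <- x[keep, ]
  if (!any(keep)) .warnf("no ASVs assigned to domain %s remain", target)
  rep <- newFilterReport(
    "filter_target_domain",
    n_asvs_removed = c(non_target = sum(!keep & !unassigned),
                       unassigned_domain = sum(unassigned)),
    reads_before = before, reads_after = colSums(asvAbundance(out)),
    details = list(target = target, removed_asvs = asvIds(x)[!keep]))
  list(table = out, report = rep)
}

# default lineage patterns identifying each host's own reads; matched
# case-insensitively against every rank of an ASV's lineage
defaultHostPatterns <- function() {
  list(E_antarcticus = c("Eudorylaimus", "E_antarcticus"),
       P_murrayi = c("Plectus", "P_murrayi"),
       Tardigrada = c("Tardigrada", "Hypsibius", "Macrobiotus"))
}

#' Remove host-derived reads from individual samples
#'
#' Applies the 18S host-read rule: an ASV whose taxonomy matches a host's
#' lineage patterns with a confident assignment (percent identity >=
#' `min_identity` and query coverage >= `min_coverage`) is zeroed only in
#' individual samples of that host; a host-matching ASV whose assignment
#' falls below either threshold is zeroed in all individual samples. Mat and
#' control samples are never touched, and a 16S table with no host-matching
#' ASVs passes through unchanged.
#'
#' @param x an [AsvExperiment-class] in counts mode.
#' @param taxonomy taxonomy data.frame.
#' @param metadata sample metadata (see [readSampleMetadata()]).
#' @param host_patterns named list, host name -> character vector of taxon
#'   name patterns identifying that host's own lineage. Required for 18S
#'   tables; [defaultHostPatterns()] covers the Dry Valley hosts.
#' @param min_identity,min_coverage assignment-quality thresholds (percent).
#' @return `list(table, report)`.
#' @export
removeHostReads <- function(x, taxonomy, metadata,
                            host_patterns = defaultHostPatterns(),
                            min_identity = 95, min_coverage = 90) {
  .assertAsv(x)
  if (is.null(host_patterns) || !length(host_patterns)) {
    if (identical(asvMarker(x), "18S"))
      .stopf("host_patterns is required for an 18S table")
    host_patterns <- list()
  }
  metadata <- metadata[match(sampleIds(x), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id))
    .stopf("metadata lacks records for sample(s): %s",
           paste(setdiff(sampleIds(x), metadata$sample_id), collapse = ", "))
  m <- asvAbundance(x)
  before <- colSums(m)
  idx <- match(asvIds(x), taxonomy$asv_id)
  lin <- as.matrix(taxonomy[idx, .TAX_RANKS, drop = FALSE])
  lin[is.na(lin)] <- ""
  pid <- taxonomy$percent_identity[idx]
  qcov <- taxonomy$query_coverage[idx]
  pid[is.na(pid)] <- 100; qcov[is.na(qcov)] <- 100

  is_ind <- metadata$sample_class == "individual"
  n_conf <- 0L; n_poor <- 0L
  zeroed <- character()
  for (h in names(host_patterns)) {
    pat <- paste(host_patterns[[h]], collapse = "|")
    hits <- apply(lin, 1L, function(r) any(grepl(pat, r, ignore.case = TRUE)))
    if (!any(hits)) next
    confident <- hits & pid >= min_identity & qcov >= min_coverage
    poor <- hits & !confident
    if (any(confident)) {
      cols <- is_ind & metadata$host == h
      m[confident, cols] <- 0
      n_conf <- n_conf + sum(confident)
    }
    if (any(poor)) {
      m[poor, is_ind] <- 0
      n_poor <- n_poor + sum(poor)
    }
    zeroed <- union(zeroed, asvIds(x)[hits])
  }
  out <- AsvExperiment(m, mode = x@mode, marker = x@marker,
                       rowData = rowData(x), colData = colData(x),
                       metadata = metadata(x))
  rep <- newFilterReport(
    "remove_host_reads",
    n_asvs_removed = c(host_confident = n_conf, host_poor_assignment = n_poor),
    reads_before = before, reads_after = colSums(m),
    details = list(min_identity = min_identity, min_coverage = min_coverage,
                   host_asvs = zeroed))
  list(table = out, report = rep)
}

#' Subtract negative-control reads from experimental samples
#'
#' For each ASV, the maximum read count observed across the negative
#' controls is subtracted from every experimental sample's count for that
#' ASV, clipping at zero; the control samples are then dropped from the
#' table.
#'
#' @param x an [AsvExperiment-class] in counts mode.
#' @param control_ids sample ids of the negative controls. Empty -> identity
#'   with a warning.
#' @return `list(table, report)`.
#' @export
subtractNegativeControls <- function(x, control_ids) {
  .assertAsv(x, mode = "counts")
  if (!length(control_ids)) {
    .warnf("no negative controls given; table returned unchanged")
    return(list(table = x,
                report = newFilterReport("subtract_negative_controls",
                                         reads_before = colSums(asvAbundance(x)),
                                         reads_after = colSums(asvAbundance(x)))))
  }
  miss <- setdiff(control_ids, sampleIds(x))
  if (length(miss))
    .stopf("control id(s) not in table: %s", paste(miss, collapse = ", "))
  m <- asvAbundance(x)
  before <- colSums(m)
  ctl <- m[, control_ids, drop = FALSE]
  cmax <- apply(ctl, 1L, max)
  keep <- setdiff(sampleIds(x), control_ids)
  cleaned <- pmax(m[, keep, drop = FALSE] - cmax, 0)
  out <- AsvExperiment(cleaned, mode = x@mode, marker = x@marker,
                       rowData = rowData(x)[, , drop = FALSE],
                       colData = colData(x)[keep, , drop = FALSE],
                       metadata = metadata(x))
  rep <- newFilterReport(
    "subtract_negative_controls",
    n_samples_discarded = length(control_ids),
    reads_before = before, reads_after = colSums(cleaned),
    details = list(control_ids = control_ids,
                   contaminant_asvs = asvIds(x)[cmax > 0],
                   subtracted_per_asv = cmax[cmax > 0]))
  list(table = out, report = rep)
}

#' Discard samples with insufficient sequencing depth
#'
#' Samples whose total read count is strictly below `min_reads` are removed
#' (a sample with exactly `min_reads` reads survives).
#'
#' @param x an [AsvExperiment-class] in counts mode.
#' @param min_reads minimum total reads per sample (default 100).
#' @return `list(table, report)`; the report lists the discarded samples.
#' @export
discardLowDepthSamples <- function(x, min_reads = 100) {
  .assertAsv(x, mode = "counts")
  tot <- colSums(asvAbundance(x))
  drop <- tot < min_reads
  if (all(drop)) .warnf("all %d samples fall below %d reads", ncol(x), min_reads)
  out <- x[, !drop]
  rep <- newFilterReport(
    "discard_low_depth_samples",
    n_samples_discarded = sum(drop),
    reads_before = tot, reads_after = tot[!drop],
    details = list(min_reads = min_reads,
                   discarded_samples = sampleIds(x)[drop]))
  list(table = out, report = rep)
}

#' Rename taxa across a taxonomy table
#'
#' Replaces any lineage field exactly equal to a key of `rename_map` with its
#' value. The shipped default collapses *Phormidesmis* into *Phormidium*,
#' reflecting the uncertain delineation of that cyanobacterial clade.
#'
#' @param taxonomy taxonomy data.frame.
#' @param rename_map named character vector, old name -> new name.
#' @return `list(taxonomy, report)`.
#' @export
renameTaxa <- function(taxonomy, rename_map = c(Phormidesmis = "Phormidium")) {
  n_renamed <- 0L
  renamed <- character()
  if (length(rename_map)) {
    for (rank in .TAX_RANKS) {
      hit <- taxonomy[[rank]] %in% names(rename_map)
      if (any(hit)) {
        old <- taxonomy[[rank]][hit]
        taxonomy[[rank]][hit] <- unname(rename_map[old])
        n_renamed <- n_renamed + sum(hit)
        renamed <- union(renamed, old)
      }
    }
  }
  rep <- newFilterReport("rename_taxa",
                         renamed_taxa = rename_map[renamed],
                         details = list(n_fields_renamed = n_renamed))
  list(taxonomy = taxonomy, report = rep)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: target-domain filtering, host-read removal,
#' negative-control subtraction, and low-depth sample discard; taxonomy
#' renaming is applied to the taxonomy table first. Controls are taken from
#' the metadata (`sample_class == "control"`).
#'
#' @param x raw [AsvExperiment-class] in counts mode.
#' @param taxonomy taxonomy data.frame.
#' @param metadata sample metadata data.frame.
#' @param target target domain (default chosen from the marker: Bacteria for
#'   16S, Eukaryota for 18S or unspecified).
#' @param host_patterns see [removeHostReads()].
#' @param min_identity,min_coverage,min_reads filter thresholds.
#' @param rename_map see [renameTaxa()].
#' @return list with `table` (cleaned AsvExperiment), `taxonomy` (renamed),
#'   `metadata` (restricted to retained samples) and `reports` (list of
#'   FilterReports in application order).
#' @export
preprocessStudy <- function(x, taxonomy, metadata, target = NULL,
                            host_patterns = defaultHostPatterns(),
                            min_identity = 95, min_coverage = 90,
                            min_reads = 100,
                            rename_map = c(Phormidesmis = "Phormidium")) {
  .assertAsv(x, mode = "counts")
  if (is.null(target))
    target <- if (identical(asvMarker(x), "16S")) "Bacteria" else "Eukaryota"
  ren <- renameTaxa(taxonomy, rename_map)
  s1 <- filterTargetDomain(x, ren$taxonomy, target)
  s2 <- removeHostReads(s1$table, ren$taxonomy, metadata, host_patterns,
                        min_identity, min_coverage)
  ctl <- intersect(metadata$sample_id[metadata$sample_class == "control"],
                   sampleIds(s2$table))
  s3 <- if (length(ctl)) subtractNegativeControls(s2$table, ctl)
        else list(table = s2$table,
                  report = newFilterReport("subtract_negative_controls"))
  s4 <- discardLowDepthSamples(s3$table, min_reads)
  meta_kept <- metadata[metadata$sample_id %in% sampleIds(s4$table), ,
                        drop = FALSE]
  list(table = s4$table, taxonomy = ren$taxonomy, metadata = meta_kept,
       reports = list(rename_taxa = ren$report,
                      filter_target_domain = s1$report,
                      remove_host_reads = s2$report,
                      subtract_negative_controls = s3$report,
                      discard_low_depth_samples = s4$report))
}
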