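# Orchestration: preprocess -> derive -> diversity -> community statistics
# under one config and one master seed, with a reproducible run report.

.MODEL_A_TERMS <- c("host", "microbiome_type", "mat_type", "stream",
                    "host:microbiome_type", "host:mat_type",
                    "microbiome_type:mat_type",
                    "host:microbiome_type:mat_type")
.MODEL_BC_TERMS <- c("host", "mat_type", "stream")

#' Build a run configuration
#'
#' Inputs may be given as file paths (`asv_table`, `taxonomy_file`,
#' `metadata_file`, `tree_file`) or as in-memory objects (`table`,
#' `taxonomy`, `metadata`, `tree`). The three PERMANOVA models follow the
#' combined / external-only / internal-only structure: model A tests host,
#' microbiome type, mat type, stream and their host/microbiome/mat
#' interactions on internal and external profiles together; models B and C
#' drop microbiome type and test external-only and internal-only profiles.
#'
#' @param ... configuration fields overriding the defaults below.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  cfg <- list(
    asv_table = NULL, taxonomy_file = NULL, metadata_file = NULL,
    tree_file = NULL, table = NULL, taxonomy = NULL, metadata = NULL,
    tree = NULL, mode_hint = "counts",
    target = NULL, host_patterns = defaultHostPatterns(),
    min_identity = 95, min_coverage = 90, min_reads = 100,
    rename_map = c(Phormidesmis = "Phormidium"),
    normalize_individuals = FALSE,
    formula_all = .MODEL_A_TERMS,
    formula_external = .MODEL_BC_TERMS,
    formula_internal = .MODEL_BC_TERMS,
    n_perm = 9999, seed = 1, out_dir = NULL)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    .stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  for (f in c("asv_table", "taxonomy_file", "metadata_file", "tree_file"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      .stopf("config path does not exist: %s = %s", f, cfg[[f]])
  structure(cfg, class = "RunConfig")
}

.permanovaToDf <- function(res) {
  tt <- res@terms
  rbind(tt, data.frame(term = "Residual", df = res@residual_df,
                       SS = res@residual_SS, F = NA, R2 = res@residual_SS /
                         res@total_SS, p = NA))
}

#' Run the full study analysis
#'
#' Executes the whole chain on one configuration: read inputs, preprocess
#' (domain filter, host-read removal, control subtraction, depth filter),
#' build mat/internal/unwashed/external profiles, compute the alpha
#' diversity table, run the three PERMANOVA models, the mats-vs-microbiome
#' pairwise contrasts (one two-group contrast per host x microbiome type),
#' the dispersion test across community types, and phylum/family/genus
#' taxon summaries. Every stochastic stage consumes a seed derived from the
#' master seed and the stage name ([deriveSeed()]), so a rerun with the same
#' seed produces a byte-identical report body. If `out_dir` is set, tables,
#' results (JSON) and a markdown report are written there; on a stage
#' failure the outputs produced so far are still written.
#'
#' @param config a [runConfig()].
#' @return list with elements `table`, `taxonomy`, `metadata`, `profiles`,
#'   `reports`, `alpha`, `permanova` (models A/B/C), `contrasts`,
#'   `dispersion`, `taxa`, `report` (markdown lines), `config`.
#' @export
runStudy <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  out <- list(config = config)
  current_stage <- "setup"
  stage <- function(name) current_stage <<- name
  finish <- function() {
    if (!is.null(config$out_dir)) .writeRunOutputs(out, config$out_dir)
    out
  }
  res <- tryCatch({
    stage("read_inputs")
    tab <- if (!is.null(config$table)) config$table
           else readAsvTable(config$asv_table, mode_hint = config$mode_hint)
    taxonomy <- if (!is.null(config$taxonomy)) config$taxonomy
                else readTaxonomy(config$taxonomy_file)
    metadata <- if (!is.null(config$metadata)) config$metadata
                else readSampleMetadata(config$metadata_file)
    tree <- if (!is.null(config$tree)) config$tree
            else if (!is.null(config$tree_file)) readAsvTree(config$tree_file)
            else NULL

    stage("preprocess")
    prep <- preprocessStudy(tab, taxonomy, metadata, target = config$target,
                            host_patterns = config$host_patterns,
                            min_identity = config$min_identity,
                            min_coverage = config$min_coverage,
                            min_reads = config$min_reads,
                            rename_map = config$rename_map)
    out$table <- prep$table; out$taxonomy <- prep$taxonomy
    out$metadata <- prep$metadata; out$reports <- prep$reports

    stage("derive_profiles")
    profiles <- suppressWarnings(
      buildAllMicrobiomes(prep$table, prep$metadata,
                          normalize_individuals = config$normalize_individuals))
    out$profiles <- profiles

    stage("alpha_diversity")
    out$alpha <- if (is.null(tree)) suppressWarnings(alphaTable(profiles))
                 else alphaTable(profiles, tree)

    stage("permanova_models")
    rel <- toRelativeAbundance(profiles)
    cd <- as.data.frame(colData(profiles))
    runModel <- function(types, terms, stage_name) {
      sel <- cd$microbiome_type %in% types
      sub <- rel[, sel]
      d <- brayCurtis(sub)
      permanova(d, cd[sel, , drop = FALSE], terms, n_perm = config$n_perm,
                seed = deriveSeed(config$seed, stage_name))
    }
    out$permanova <- list(
      all = runModel(c("internal", "external"), config$formula_all,
                     "permanova_all"),
      external = runModel("external", config$formula_external,
                          "permanova_external"),
      internal = runModel("internal", config$formula_internal,
                          "permanova_internal"))

    stage("pairwise_contrasts")
    hosts <- setdiff(unique(cd$host), "none")
    contrasts <- list()
    for (h in hosts) for (ty in c("external", "internal")) {
      sel <- cd$microbiome_type == "mat" |
        (cd$microbiome_type == ty & cd$host == h)
      if (sum(cd$microbiome_type[sel] == ty) < 2L) next
      sub <- rel[, sel]
      d <- brayCurtis(sub)
      pr <- pairwisePermanova(d, data.frame(
        grp = cd$microbiome_type[sel], row.names = colnames(sub)),
        "grp", n_perm = config$n_perm,
        seed = deriveSeed(config$seed, paste0("contrast_", h, "_", ty)))
      pr$host <- h; pr$microbiome_type <- ty
      contrasts[[paste(h, ty, sep = ".")]] <- pr
    }
    out$contrasts <- if (length(contrasts))
      do.call(rbind, c(contrasts, list(make.row.names = FALSE))) else NULL

    stage("dispersion")
    sel <- cd$microbiome_type %in% c("mat", "internal", "external")
    out$dispersion <- dispersionTest(
      brayCurtis(rel[, sel]), cd$microbiome_type[sel],
      n_perm = min(config$n_perm, 999),
      seed = deriveSeed(config$seed, "dispersion"))

    stage("taxon_summaries")
    out$taxa <- lapply(stats::setNames(nm = c("phylum", "family", "genus")),
                       function(rk) taxonSummary(rel, prep$taxonomy, rk,
                                                 cd$microbiome_type))

    stage("report")
    out$report <- .renderRunReport(out, config)
    out
  }, error = function(e) {
    if (!is.null(config$out_dir))
      try(.writeRunOutputs(out, config$out_dir), silent = TRUE)
    .stopf("stage '%s' failed: %s", current_stage, conditionMessage(e))
  })
  out <- res
  finish()
}

# markdown run report; body is deterministic for a fixed seed (no clocks)
.renderRunReport <- function(out, config) {
  L <- character()
  add <- function(...) L <<- c(L, sprintf(...))
  add("# External microbiome study report")
  add("")
  add("Master seed: %d; permutations per test: %d", config$seed,
      config$n_perm)
  add("Thresholds: min_reads=%d, min_identity=%g, min_coverage=%g",
      config$min_reads, config$min_identity, config$min_coverage)
  add("Note: group effects on alpha diversity and dispersions are tested by")
  add("sequential-SS permutation F tests (not mixed-effects models).")
  add("")
  add("## Filtering")
  for (nm in names(out$reports)) {
    r <- out$reports[[nm]]
    add("- %s: %s ASVs removed, %d samples discarded", nm,
        if (length(r$n_asvs_removed_by_rule))
          paste(sum(r$n_asvs_removed_by_rule)) else "0",
        r$n_samples_discarded)
  }
  add("")
  add("## Profiles")
  tb <- table(colData(out$profiles)$microbiome_type)
  for (nm in names(tb)) add("- %s: %d", nm, tb[[nm]])
  add("")
  fmtPerm <- function(res) {
    df <- .permanovaToDf(res)
    c(sprintf("| term | df | SS | F | R2 | p |"),
      sprintf("|---|---|---|---|---|---|"),
      sprintf("| %s | %d | %.5g | %s | %.4f | %s |", df$term, df$df, df$SS,
              ifelse(is.na(df$F), "", sprintf("%.4g", df$F)), df$R2,
              ifelse(is.na(df$p), "", sprintf("%.4g", df$p))))
  }
  add("## PERMANOVA A: all host microbiomes (internal + external)")
  L <- c(L, fmtPerm(out$permanova$all), "")
  add("## PERMANOVA B: external microbiomes")
  L <- c(L, fmtPerm(out$permanova$external), "")
  add("## PERMANOVA C: internal microbiomes")
  L <- c(L, fmtPerm(out$permanova$internal), "")
  add("## Pairwise contrasts vs mats")
  if (!is.null(out$contrasts)) {
    add("| host | microbiome | R2 | p | p_holm |")
    add("|---|---|---|---|---|")
    for (i in seq_len(nrow(out$contrasts)))
      add("| %s | %s | %.4f | %.4g | %.4g |", out$contrasts$host[i],
          out$contrasts$microbiome_type[i], out$contrasts$R2[i],
          out$contrasts$p[i], out$contrasts$p_holm[i])
  }
  add("")
  add("## Dispersion across community types")
  gm <- out$dispersion@group_means
  for (nm in names(gm)) add("- mean distance to centroid, %s: %.5g", nm, gm[[nm]])
  if (out$dispersion@degenerate) add("- degenerate (all dispersions zero), p = 1")
  else add("- F = %.5g, permutation p = %.5g", out$dispersion@statistic,
           out$dispersion@p)
  L
}

.writeRunOutputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  if (!is.null(out$table)) writeAsvTable(out$table, fp("cleaned_table.tsv"))
  if (!is.null(out$taxonomy)) writeTaxonomy(out$taxonomy, fp("taxonomy.tsv"))
  if (!is.null(out$metadata))
    writeSampleMetadata(out$metadata, fp("metadata.tsv"))
  if (!is.null(out$profiles)) {
    writeAsvTable(out$profiles, fp("profiles.tsv"))
    utils::write.table(as.data.frame(colData(out$profiles)),
                       fp("profile_metadata.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out$alpha))
    utils::write.table(out$alpha, fp("alpha_diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  json <- list(seed = out$config$seed, n_perm = out$config$n_perm)
  if (!is.null(out$permanova))
    json$permanova <- lapply(out$permanova, .permanovaToDf)
  if (!is.null(out$contrasts)) json$contrasts <- out$contrasts
  if (!is.null(out$dispersion))
    json$dispersion <- list(group_means = as.list(out$dispersion@group_means),
                            F = out$dispersion@statistic,
                            p = out$dispersion@p,
                            degenerate = out$dispersion@degenerate)
  if (!is.null(out$reports))
    json$filter_reports <- lapply(out$reports, function(r)
      r[c("rule", "n_asvs_removed_by_rule", "n_samples_discarded")])
  jsonlite::write_json(json, fp("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (!is.null(out$report)) writeLines(out$report, fp("report.md"))
  invisible(out_dir)
}
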