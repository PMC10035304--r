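#' Read an ASV abundance table from TSV
#'
#' Accepts either orientation of a tab-separated abundance matrix and
#' normalizes to the package's ASVs-by-samples layout. Orientation is
#' auto-detected from the header sentinel: a first header cell of
#' `sample_id` means rows are samples; `asv_id` or the QIIME/BIOM dense
#' dialect's `#OTU ID` means rows are ASVs. A leading
#' `#exomibe mode=... marker=...` comment written by [writeAsvTable()] is
#' honoured; otherwise `mode_hint` decides the abundance mode. Other leading
#' `#`-comment lines (e.g. `# Constructed from biom file`) are skipped.
#'
#' @param path path to a TSV file.
#' @param mode_hint `"counts"` or `"relative"`; used when the file carries no
#'   mode annotation.
#' @param marker amplicon marker to record when the file carries none.
#' @return An [AsvExperiment-class].
#' @seealso [writeAsvTable()]
#' @export
readAsvTable <- function(path, mode_hint = c("counts", "relative"),
                         marker = "unspecified") {
  mode_hint <- match.arg(mode_hint)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .stopf("empty ASV table file: %s", path)

  # annotation comment (ours), then any other comment lines, then header
  if (grepl("^#exomibe\\b", lines[1])) {
    ann <- lines[1]
    m <- regmatches(ann, regexec("mode=(\\S+)", ann))[[1]]
    if (length(m) == 2 && m[2] %in% c("counts", "relative")) mode_hint <- m[2]
    k <- regmatches(ann, regexec("marker=(\\S+)", ann))[[1]]
    if (length(k) == 2) marker <- k[2]
    lines <- lines[-1]
  }
  while (length(lines) && grepl("^#", lines[1]) &&
         !grepl("^#OTU ID\t", lines[1]))
    lines <- lines[-1]
  if (length(lines) < 2L) .stopf("no data rows in ASV table: %s", path)

  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sentinel <- header[1]
  rows_are <- if (identical(sentinel, "sample_id")) "samples"
    else if (sentinel %in% c("asv_id", "#OTU ID")) "asvs"
    else .stopf(paste0("cannot detect orientation: header must start with ",
                       "'sample_id', 'asv_id' or '#OTU ID', got '%s'"), sentinel)

  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_col <- length(header)
  bad <- which(vapply(body, length, 0L) != n_col)
  if (length(bad))
    .stopf("row %d has %d fields, expected %d", bad[1] + 1L,
           length(body[[bad[1]]]), n_col)
  row_ids <- vapply(body, `[[`, "", 1L)
  col_ids <- header[-1]
  vals <- matrix(NA_real_, length(body), n_col - 1L,
                 dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      .stopf("malformed numeric cell at row '%s', column '%s': '%s'",
             row_ids[i], col_ids[j], body[[i]][j + 1L])
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(row_ids))
    .stopf("duplicate row ids in %s: %s", path,
           paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  if (anyDuplicated(col_ids))
    .stopf("duplicate column ids in %s: %s", path,
           paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  if (rows_are == "samples") vals <- t(vals)
  AsvExperiment(vals, mode = mode_hint, marker = marker)
}

#' Write an ASV abundance table as TSV
#'
#' Writes a samples-by-ASVs TSV with a `sample_id` header sentinel and an
#' `#exomibe` annotation line carrying mode and marker, so that
#' [readAsvTable()] round-trips the object exactly (bit-exact for counts,
#' to full double precision for relative abundances).
#'
#' @param x an [AsvExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAsvTable <- function(x, path) {
  .assertAsv(x)
  m <- asvAbundance(x, transpose = TRUE)  # samples x ASVs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#exomibe mode=%s marker=%s", x@mode, x@marker), con)
  writeLines(paste(c("sample_id", colnames(m)), collapse = "\t"), con)
  fmt <- function(v) {
    out <- vapply(v, function(z) {
      if (z == round(z) && abs(z) < 2^53) sprintf("%.0f", z)
      else sprintf("%.17g", z)
    }, "")
    out
  }
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a per-ASV taxonomy table
#'
#' Expects a TSV with columns `asv_id`, `lineage` (semicolon-delimited ranks
#' from domain down to genus), `percent_identity` and `query_coverage` (the
#' assignment quality of the taxonomic hit). Lineages shorter than six ranks
#' are padded with empty strings. Missing quality columns default to 100
#' (pass-through) with a warning so that the host-read filter remains usable
#' without quality metadata.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `asv_id`, `domain` ... `genus`,
#'   `percent_identity`, `query_coverage`.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("asv_id", "lineage") %in% names(df)))
    .stopf("taxonomy table must have columns 'asv_id' and 'lineage'")
  if (anyDuplicated(df$asv_id))
    .stopf("duplicate asv_id in taxonomy table: %s",
           paste(unique(df$asv_id[duplicated(df$asv_id)]), collapse = ", "))
  for (qc in c("percent_identity", "query_coverage")) {
    if (!qc %in% names(df)) {
      .warnf("taxonomy table lacks column '%s'; defaulting to 100", qc)
      df[[qc]] <- "100"
    }
  }
  out <- parseLineages(df$lineage)
  out <- data.frame(asv_id = df$asv_id, out,
                    percent_identity = as.numeric(df$percent_identity),
                    query_coverage = as.numeric(df$query_coverage),
                    stringsAsFactors = FALSE)
  for (qc in c("percent_identity", "query_coverage")) {
    v <- out[[qc]]
    if (anyNA(v) || any(v < 0 | v > 100))
      .stopf("'%s' must be numeric in [0, 100]", qc)
  }
  out
}

# split semicolon lineages into the six canonical ranks, padding with ""
parseLineages <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  m <- matrix("", length(parts), length(.TAX_RANKS),
              dimnames = list(NULL, .TAX_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    n <- min(length(p), length(.TAX_RANKS))
    if (n > 0) m[i, seq_len(n)] <- p[seq_len(n)]
  }
  as.data.frame(m, stringsAsFactors = FALSE)
}

#' Write a taxonomy table as TSV
#'
#' @param taxonomy data.frame as returned by [readTaxonomy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  lin <- apply(as.matrix(taxonomy[, .TAX_RANKS, drop = FALSE]), 1L, function(r) {
    last <- max(c(0L, which(r != "")))
    paste(r[seq_len(last)], collapse = ";")
  })
  out <- data.frame(asv_id = taxonomy$asv_id, lineage = lin,
                    percent_identity = taxonomy$percent_identity,
                    query_coverage = taxonomy$query_coverage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `sample_class`
#' (mat/individual/control), `host` (a host taxon name, or `none` for mat and
#' control samples), `wash_status` (washed/unwashed/not_applicable), `stream`,
#' `mat_type` (black/orange), `replicate` (integer) and `marker` (16S/18S).
#' Cross-field design rules are enforced: individual samples must name a host
#' and a wash status; mat and control samples must have `host = none`.
#'
#' @param path path to a TSV file.
#' @return validated data.frame of sample records.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  validateSampleMetadata(df)
}

#' Validate a sample metadata data.frame
#'
#' @param df data.frame with the columns described in [readSampleMetadata()].
#' @return the validated data.frame, with `replicate` coerced to integer.
#' @export
validateSampleMetadata <- function(df) {
  need <- c("sample_id", "sample_class", "host", "wash_status", "stream",
            "mat_type", "replicate", "marker")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    .stopf("duplicate sample_id: %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  chk <- function(col, allowed) {
    bad <- !df[[col]] %in% allowed
    if (any(bad))
      .stopf("invalid %s '%s' for sample '%s'", col, df[[col]][bad][1],
             df$sample_id[bad][1])
  }
  chk("sample_class", .SAMPLE_CLASSES)
  chk("wash_status", .WASH_STATUSES)
  chk("mat_type", .MAT_TYPES)
  chk("marker", c("16S", "18S"))
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(df$replicate)) .stopf("replicate must be an integer")

  ind <- df$sample_class == "individual"
  bad <- ind & (df$host == "none" | df$host == "")
  if (any(bad))
    .stopf("individual sample '%s' must name a host", df$sample_id[bad][1])
  bad <- ind & df$wash_status == "not_applicable"
  if (any(bad))
    .stopf("individual sample '%s' must have wash_status washed or unwashed",
           df$sample_id[bad][1])
  bad <- !ind & df$host != "none"
  if (any(bad))
    .stopf("%s sample '%s' must have host = none",
           df$sample_class[bad][1], df$sample_id[bad][1])
  df
}

#' Write a sample metadata table as TSV
#'
#' @param df metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSampleMetadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree over ASVs
#'
#' Parses a newick file into an `ape::phylo` object and validates it for use
#' with [faithPD()]: the tree must be rooted, tip labels unique, and branch
#' lengths nonnegative. Missing branch lengths are set to 0 with a warning.
#'
#' @param path path to a newick file.
#' @return an object of class `phylo`.
#' @export
readAsvTree <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) .stopf("empty newick file: %s", path)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    .stopf("unparseable newick in %s", path)
  validateAsvTree(tree)
}

#' Validate a phylo tree for phylogenetic diversity use
#'
#' @param tree an `ape::phylo`.
#' @return the tree, with any missing branch lengths replaced by 0 (warned).
#' @export
validateAsvTree <- function(tree) {
  if (!inherits(tree, "phylo")) .stopf("expected an ape 'phylo' tree")
  if (anyDuplicated(tree$tip.label))
    .stopf("duplicate tip labels: %s",
           paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                 collapse = ", "))
  if (!ape::is.rooted(tree)) .stopf("tree must be rooted")
  if (is.null(tree$edge.length)) {
    .warnf("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    .warnf("%d missing branch length(s) set to 0", sum(is.na(tree$edge.length)))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) .stopf("negative branch lengths not allowed")
  tree
}

#' Write a tree as newick
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAsvTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
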