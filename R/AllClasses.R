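#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData assay<- rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' AsvExperiment: an ASV abundance table with sample and taxon annotation
#'
#' The universal currency of the pipeline: an amplicon sequence variant (ASV)
#' abundance matrix stored as a [SummarizedExperiment::SummarizedExperiment]
#' with ASVs as rows and samples (or derived microbiome profiles) as columns.
#' Per-ASV taxonomy lives in `rowData()`, per-sample design metadata in
#' `colData()`. Two extra slots track the abundance `mode` (`"counts"` for
#' read counts or averages of read counts, `"relative"` for proportions) and
#' the amplicon `marker` (`"16S"`, `"18S"`, or `"unspecified"`).
#'
#' Validity requires: all abundances finite and nonnegative; unique ASV and
#' sample identifiers; and in relative mode every sample with any nonzero
#' entry summing to 1 within 1e-9.
#'
#' @slot mode character(1), `"counts"` or `"relative"`.
#' @slot marker character(1), `"16S"`, `"18S"` or `"unspecified"`.
#' @export
setClass("AsvExperiment",
  contains = "SummarizedExperiment",
  slots = c(mode = "character", marker = "character")
)

.validAsvExperiment <- function(object) {
  msgs <- character()
  if (length(object@mode) != 1L || !object@mode %in% c("counts", "relative"))
    msgs <- c(msgs, "mode must be one of 'counts', 'relative'")
  if (length(object@marker) != 1L ||
      !object@marker %in% c("16S", "18S", "unspecified"))
    msgs <- c(msgs, "marker must be one of '16S', '18S', 'unspecified'")
  if (!"abundance" %in% names(assays(object)))
    msgs <- c(msgs, "assay 'abundance' is required")
  else {
    m <- assay(object, "abundance")
    if (!is.numeric(m))
      msgs <- c(msgs, "abundance values must be numeric")
    else {
      if (any(!is.finite(m)))
        msgs <- c(msgs, "abundance values must be finite")
      else if (any(m < 0))
        msgs <- c(msgs, "abundance values must be nonnegative")
      else if (identical(object@mode, "relative") && ncol(m) > 0L) {
        cs <- colSums(m)
        bad <- cs > 0 & abs(cs - 1) > 1e-9
        if (any(bad))
          msgs <- c(msgs, paste0("relative-mode sample(s) do not sum to 1: ",
                                 paste(colnames(m)[bad], collapse = ", ")))
      }
    }
    if (nrow(m) > 0L && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
      msgs <- c(msgs, "ASV ids must be present and unique")
    if (ncol(m) > 0L && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
      msgs <- c(msgs, "sample ids must be present and unique")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("AsvExperiment", .validAsvExperiment)

#' Construct an AsvExperiment
#'
#' @param abundance numeric matrix, ASVs as rows and samples as columns, with
#'   dimnames. A samples-by-ASVs matrix can be passed transposed by the
#'   caller; this constructor takes the Bioconductor features-by-samples
#'   orientation.
#' @param mode `"counts"` or `"relative"`.
#' @param marker `"16S"`, `"18S"` or `"unspecified"`.
#' @param rowData,colData optional `DataFrame`s of per-ASV taxonomy and
#'   per-sample metadata.
#' @param metadata optional list stored in `metadata()`.
#' @return An [AsvExperiment-class] object.
#' @examples
#' m <- matrix(c(3, 0, 1, 5), nrow = 2,
#'             dimnames = list(c("asv1", "asv2"), c("s1", "s2")))
#' AsvExperiment(m, mode = "counts")
#' @export
AsvExperiment <- function(abundance, mode = c("counts", "relative"),
                          marker = "unspecified", rowData = NULL,
                          colData = NULL, metadata = list()) {
  mode <- match.arg(mode)
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  args <- list(assays = list(abundance = abundance), metadata = metadata)
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment, args)
  new("AsvExperiment", se, mode = mode, marker = marker)
}

#' PERMANOVA result
#'
#' Sequential (Type-I) partitioning of a dissimilarity matrix among design
#' terms, with pseudo-F, R-squared and permutation p-values. `terms` is a
#' data.frame with columns `term`, `df`, `SS`, `F`, `R2`, `p`.
#'
#' @slot terms data.frame of per-term statistics.
#' @slot residual_df,residual_SS residual degrees of freedom and sum of squares.
#' @slot total_SS total sum of squares (trace of the Gower matrix).
#' @slot n_perm number of permutations used (0 in exhaustive mode's
#'   random-draw sense; see `exhaustive`).
#' @slot exhaustive logical; TRUE when all row permutations were enumerated.
#' @slot seed integer seed used for the permutation stream (NA if exhaustive).
#' @export
setClass("PermanovaResult",
  slots = c(terms = "data.frame", residual_df = "numeric",
            residual_SS = "numeric", total_SS = "numeric",
            n_perm = "numeric", exhaustive = "logical", seed = "numeric")
)

setValidity("PermanovaResult", function(object) {
  msgs <- character()
  need <- c("term", "df", "SS", "F", "R2", "p")
  if (!all(need %in% names(object@terms)))
    msgs <- c(msgs, "terms must have columns term, df, SS, F, R2, p")
  else {
    if (abs(sum(object@terms$SS) + object@residual_SS - object@total_SS) >
        1e-9 * max(1, abs(object@total_SS)))
      msgs <- c(msgs, "term SS plus residual SS must equal total SS")
    if (any(object@terms$R2 < -1e-12 | object@terms$R2 > 1 + 1e-12))
      msgs <- c(msgs, "R2 must lie in [0, 1]")
    if (any(!is.na(object@terms$p) &
            (object@terms$p <= 0 | object@terms$p > 1)))
      msgs <- c(msgs, "p-values must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Multivariate dispersion result
#'
#' Distances of samples to their group centroid in principal-coordinate
#' space (with Anderson-style real-minus-imaginary correction for negative
#' eigenvalues), a group F test on those distances, and a permutation p-value.
#'
#' @slot distances numeric, per-sample distance to its group centroid.
#' @slot clamped logical, TRUE where the negative-eigenvalue correction made a
#'   squared distance negative and it was clamped at 0.
#' @slot groups factor of group membership.
#' @slot group_means numeric, mean dispersion per group.
#' @slot statistic F statistic (NA when degenerate).
#' @slot p permutation p-value (1 when degenerate).
#' @slot degenerate logical, TRUE when all dispersions are (numerically) zero.
#' @slot n_perm,seed permutation settings.
#' @export
setClass("DispersionResult",
  slots = c(distances = "numeric", clamped = "logical", groups = "factor",
            group_means = "numeric", statistic = "numeric", p = "numeric",
            degenerate = "logical", n_perm = "numeric", seed = "numeric")
)
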