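#' @rdname AsvExperiment-accessors
#' @export
setGeneric("asvAbundance", function(x, ...) standardGeneric("asvAbundance"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("asvIds", function(x) standardGeneric("asvIds"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("abundanceMode", function(x) standardGeneric("abundanceMode"))

#' @rdname AsvExperiment-accessors
#' @export
setGeneric("asvMarker", function(x) standardGeneric("asvMarker"))

#' Accessors for AsvExperiment
#'
#' `asvAbundance()` returns the abundance matrix (ASVs x samples, or
#' samples x ASVs with `transpose = TRUE`); `asvIds()` and `sampleIds()` the
#' identifier vectors; `abundanceMode()` the `"counts"`/`"relative"` flag;
#' `asvMarker()` the amplicon marker.
#'
#' @param x an [AsvExperiment-class].
#' @param transpose return samples x ASVs instead of ASVs x samples.
#' @param ... unused.
#' @name AsvExperiment-accessors
NULL

#' @rdname AsvExperiment-accessors
#' @export
setMethod("asvAbundance", "AsvExperiment", function(x, transpose = FALSE, ...) {
  m <- assay(x, "abundance")
  if (transpose) t(m) else m
})

#' @rdname AsvExperiment-accessors
#' @export
setMethod("asvIds", "AsvExperiment", function(x) rownames(x))

#' @rdname AsvExperiment-accessors
#' @export
setMethod("sampleIds", "AsvExperiment", function(x) colnames(x))

#' @rdname AsvExperiment-accessors
#' @export
setMethod("abundanceMode", "AsvExperiment", function(x) x@mode)

#' @rdname AsvExperiment-accessors
#' @export
setMethod("asvMarker", "AsvExperiment", function(x) x@marker)

#' @export
setMethod("show", "AsvExperiment", function(object) {
  cat(sprintf("AsvExperiment: %d ASVs x %d samples [mode=%s, marker=%s]\n",
              nrow(object), ncol(object), object@mode, object@marker))
  callNextMethod()
})

#' @export
setMethod("show", "PermanovaResult", function(object) {
  cat("PERMANOVA (sequential sums of squares, ",
      if (object@exhaustive) "exhaustive permutations"
      else sprintf("%d free permutations", object@n_perm),
      ")\n", sep = "")
  tab <- object@terms
  tab$SS <- signif(tab$SS, 5); tab$F <- signif(tab$F, 5)
  tab$R2 <- signif(tab$R2, 5)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: df = %d, SS = %.5g, R2 = %.5g\n",
              as.integer(object@residual_df), object@residual_SS,
              object@residual_SS / object@total_SS))
  cat(sprintf("Total SS = %.5g\n", object@total_SS))
})

#' @export
setMethod("show", "DispersionResult", function(object) {
  cat("Multivariate homogeneity of group dispersions\n")
  cat("Group mean distances to centroid:\n")
  print(signif(object@group_means, 5))
  if (object@degenerate) {
    cat("Degenerate: all dispersions zero; F undefined, p = 1\n")
  } else {
    cat(sprintf("F = %.5g, permutation p = %.5g (%d permutations)\n",
                object@statistic, object@p, as.integer(object@n_perm)))
  }
})
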