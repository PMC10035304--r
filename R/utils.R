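# internal helpers: controlled RNG scope, seed derivation, small assertions

.MAT_TYPES <- c("black", "orange")
.SAMPLE_CLASSES <- c("mat", "individual", "control")
.WASH_STATUSES <- c("washed", "unwashed", "not_applicable")
.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

# run fun() under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched
withSeed <- function(seed, fun) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  fun()
}

#' Derive a stage-specific seed from a master seed
#'
#' Stochastic pipeline stages each consume a seed derived deterministically
#' from the master seed and the stage name, so a stage can be rerun in
#' isolation and still match the full run. The derivation folds the stage
#' name into a 31-bit hash mixed with the master seed.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(17, "permanova_internal")
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 1) + 1)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assertAsv <- function(x, mode = NULL) {
  if (!methods::is(x, "AsvExperiment"))
    .stopf("expected an AsvExperiment, got %s", class(x)[1])
  if (!is.null(mode) && !identical(x@mode, mode))
    .stopf("expected an AsvExperiment in '%s' mode, got '%s'", mode, x@mode)
  invisible(x)
}

# FilterReport: audit record of one filtering step (plain list, printable)
newFilterReport <- function(rule, n_asvs_removed = c(), n_samples_discarded = 0L,
                            renamed_taxa = character(), reads_before = NULL,
                            reads_after = NULL, details = list()) {
  structure(list(rule = rule,
                 n_asvs_removed_by_rule = n_asvs_removed,
                 n_samples_discarded = as.integer(n_samples_discarded),
                 renamed_taxa = renamed_taxa,
                 reads_before = reads_before,
                 reads_after = reads_after,
                 details = details),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport [%s]\n", x$rule))
  if (length(x$n_asvs_removed_by_rule))
    for (nm in names(x$n_asvs_removed_by_rule))
      cat(sprintf("  ASVs removed (%s): %d\n", nm,
                  x$n_asvs_removed_by_rule[[nm]]))
  if (x$n_samples_discarded > 0)
    cat(sprintf("  samples discarded: %d\n", x$n_samples_discarded))
  if (length(x$renamed_taxa))
    cat(sprintf("  taxa renamed: %d\n", length(x$renamed_taxa)))
  if (!is.null(x$reads_before))
    cat(sprintf("  total reads: %.0f -> %.0f\n",
                sum(x$reads_before), sum(x$reads_after)))
  invisible(x)
}
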