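# Internal helpers: logging, validation, sample alignment.

.mk_env <- new.env(parent = emptyenv())
.mk_env$verbose <- 1L

#' Set meqtlkit logging verbosity
#'
#' @param level 0 = silent, 1 = messages (default), 2 = debug.
#' @return The previous level, invisibly.
#' @export
mk_verbosity <- function(level) {
  old <- .mk_env$verbose
  .mk_env$verbose <- as.integer(level)
  invisible(old)
}

mk_log <- function(..., level = 1L) {
  if (.mk_env$verbose >= level) {
    message("[meqtlkit] ", sprintf(...))
  }
  invisible(NULL)
}

mk_stop <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    mk_stop("'%s' must be a single number in (0, 1), got %s", name,
            paste(format(x), collapse = ","))
  invisible(x)
}

#' Align samples across genotype, methylation and covariate inputs
#'
#' Samples are matched by ID intersection and all objects are reordered to a
#' common sample order (the genotype order restricted to the intersection).
#' Counts of samples dropped from each input are logged.
#'
#' @param genotypes A `genotype_matrix`.
#' @param methylation A `methylation_matrix`.
#' @param covariates A data.frame with a `sample_id` column (or rownames).
#' @return A list with the three inputs sample-aligned.
#' @export
align_samples <- function(genotypes, methylation, covariates = NULL) {
  gs <- rownames(genotypes$dosage)
  ms <- rownames(methylation$beta)
  common <- intersect(gs, ms)
  if (!is.null(covariates)) {
    cs <- if ("sample_id" %in% names(covariates)) as.character(covariates$sample_id) else rownames(covariates)
    common <- intersect(common, cs)
  }
  if (length(common) == 0L) mk_stop("no samples shared across inputs")
  common <- gs[gs %in% common]  # genotype order, restricted
  dropped <- c(genotype = length(gs) - length(common),
               methylation = length(ms) - length(common))
  if (any(dropped > 0L))
    mk_log("sample alignment dropped: %s",
           paste(names(dropped), dropped, sep = "=", collapse = ", "))
  genotypes$dosage <- genotypes$dosage[common, , drop = FALSE]
  methylation$beta <- methylation$beta[common, , drop = FALSE]
  if (!is.null(covariates)) {
    if ("sample_id" %in% names(covariates)) {
      covariates <- covariates[match(common, covariates$sample_id), , drop = FALSE]
    } else {
      covariates <- covariates[common, , drop = FALSE]
    }
    rownames(covariates) <- common
  }
  list(genotypes = genotypes, methylation = methylation, covariates = covariates)
}

# Normalize chromosome labels to a canonical form without the "chr" prefix.
norm_chrom <- function(x) {
  x <- as.character(x)
  had <- grepl("^chr", x, ignore.case = TRUE)
  if (any(had)) {
    mk_log("normalized %d 'chr'-prefixed chromosome labels", sum(had), level = 2L)
    x[had] <- sub("^chr", "", x[had], ignore.case = TRUE)
  }
  x
}
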