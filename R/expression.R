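EXPR_UNITS <- c("counts", "fpkm", "tpm", "log2", "zscore")

#' Construct an expression matrix
#'
#' A genes x samples numeric matrix with a declared unit. Abundance units
#' (`counts`, `fpkm`, `tpm`) must be non-negative; `log2` and `zscore`
#' mark transformed data.
#'
#' @param values numeric matrix with gene row names and sample column
#'   names.
#' @param unit one of `counts`, `fpkm`, `tpm`, `log2`, `zscore`.
#' @return An `expr_matrix` (matrix subclass with a `unit` attribute).
#' @export
expr_matrix <- function(values, unit = "counts") {
  unit <- match.arg(unit, EXPR_UNITS)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_data("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_data("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values))) stop_data("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop_data("duplicate sample ids")
  if (unit %in% c("counts", "fpkm", "tpm") && any(values < 0, na.rm = TRUE))
    stop_data("negative values are not valid for unit '", unit, "'")
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' Unit of an expression matrix
#' @param m an `expr_matrix`.
#' @return The unit string.
#' @export
expr_unit <- function(m) attr(m, "unit")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              expr_unit(x), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The DESeq-style normalization scale: for every gene with strictly
#' positive values in all samples, the reference is its geometric mean
#' across samples; a sample's size factor is the median over those genes
#' of the ratio of its value to the reference.
#'
#' @param m an `expr_matrix` with unit `counts`, `fpkm` or `tpm`.
#' @return Named numeric vector of positive per-sample size factors.
#' @examples
#' m <- expr_matrix(matrix(c(10, 30, 20, 60), 2,
#'                  dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' estimate_size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
estimate_size_factors <- function(m) {
  if (!expr_unit(m) %in% c("counts", "fpkm", "tpm"))
    stop_usage("size factors need abundance units, not ", expr_unit(m))
  v <- unclass(m)
  pos <- rowSums(v > 0) == ncol(v)
  if (!any(pos))
    stop_data("no gene with all-positive values; cannot form the reference")
  lv <- log(v[pos, , drop = FALSE])
  ref <- rowMeans(lv)
  apply(exp(lv - ref), 2, median)
}

#' Normalize an abundance matrix by size factors
#'
#' @param m an `expr_matrix` with an abundance unit.
#' @param size_factors named per-sample factors; estimated with
#'   [estimate_size_factors()] when omitted.
#' @return An `expr_matrix` of the same unit with each sample divided by
#'   its size factor.
#' @export
normalize_counts <- function(m, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  if (any(size_factors <= 0)) stop_data("size factors must be positive")
  if (!is.null(names(size_factors))) {
    miss <- setdiff(colnames(m), names(size_factors))
    if (length(miss)) stop_data("no size factor for sample(s): ",
                                paste(miss, collapse = ", "))
    size_factors <- size_factors[colnames(m)]
  }
  expr_matrix(sweep(unclass(m), 2, size_factors, "/"), unit = expr_unit(m))
}

#' Log2 transformation with pseudocount
#'
#' @param m an `expr_matrix` not already log2- or z-transformed.
#' @param pseudocount added before taking log2 (default 1).
#' @return An `expr_matrix` with unit `log2`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (expr_unit(m) %in% c("log2", "zscore"))
    stop_usage("matrix is already transformed (unit ", expr_unit(m), ")")
  v <- unclass(m)
  if (any(v < 0)) stop_data("negative values cannot be log-transformed")
  if (any(v + pseudocount <= 0))
    stop_data("value + pseudocount must be positive everywhere")
  out <- log2(v + pseudocount)
  structure(out, unit = "log2", class = c("expr_matrix", class(out)))
}

#' Per-gene z-transformation
#'
#' Centers and scales each gene across samples using the population
#' standard deviation (denominator n). Genes with zero variance become
#' all-zero rows, with a warning naming how many were degenerate.
#'
#' @param m an `expr_matrix` with at least two samples.
#' @return An `expr_matrix` with unit `zscore`.
#' @export
zscore_genes <- function(m) {
  v <- unclass(m)
  if (ncol(v) < 2L) stop_usage("z-transformation needs >= 2 samples")
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans((v - mu)^2))
  zero <- sd_pop == 0
  if (any(zero))
    warning(sum(zero), " zero-variance gene(s) set to all-zero z rows")
  sd_pop[zero] <- 1
  z <- (v - mu) / sd_pop
  z[zero, ] <- 0
  structure(z, unit = "zscore", class = c("expr_matrix", class(z)))
}

#' Per-gene log2 fold change between sample groups
#'
#' `log2((mean_B + pseudocount) / (mean_A + pseudocount))` per gene: the
#' fold change of group B over group A.
#'
#' @param m an `expr_matrix` with an abundance unit (normalized counts,
#'   FPKM or TPM).
#' @param group_a,group_b disjoint, non-empty character vectors of sample
#'   ids.
#' @param pseudocount added to both group means (default 1).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(m, group_a, group_b, pseudocount = 1) {
  if (!length(group_a) || !length(group_b))
    stop_usage("both sample groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop_usage("sample groups overlap: ",
               paste(intersect(group_a, group_b), collapse = ", "))
  miss <- setdiff(c(group_a, group_b), colnames(m))
  if (length(miss)) stop_data("unknown sample(s): ",
                              paste(miss, collapse = ", "))
  if (!expr_unit(m) %in% c("counts", "fpkm", "tpm"))
    stop_usage("fold changes need abundance units, not ", expr_unit(m))
  v <- unclass(m)
  ma <- rowMeans(v[, group_a, drop = FALSE])
  mb <- rowMeans(v[, group_b, drop = FALSE])
  setNames(log2((mb + pseudocount) / (ma + pseudocount)), rownames(v))
}
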