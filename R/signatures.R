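#' Define a gene signature
#'
#' A named, unique gene list with free-text provenance (where the genes
#' came from: source cistromes, fold-change threshold, ...).
#'
#' @param name signature name.
#' @param gene_ids non-empty character vector; duplicates are removed.
#' @param provenance free-text derivation note.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, gene_ids, provenance = "") {
  gene_ids <- unique(as.character(gene_ids))
  if (!length(gene_ids)) stop_data("signature '", name, "' has no genes")
  structure(list(name = name, gene_ids = gene_ids, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes\n", x$name, length(x$gene_ids)))
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Score samples against a gene signature
#'
#' Two scoring modes, both raw sums over the signature genes found in the
#' matrix: `zscore_sum` sums the per-gene z-transformed expression
#' (dimensionless; used for patient cohorts), `log2_sum` sums
#' log2-transformed abundances with pseudocount 1 (log2 units; used for
#' cell lines). Signature genes absent from the matrix are skipped and
#' counted in the result so that scores are only compared at equal
#' coverage.
#'
#' @param m an `expr_matrix`; `zscore_sum` needs >= 2 samples (the
#'   z-transform is applied internally unless the unit is already
#'   `zscore`); `log2_sum` needs an abundance unit (`fpkm`, `tpm`,
#'   `counts`) or `log2`.
#' @param sig a [gene_signature()].
#' @param mode `"zscore_sum"` or `"log2_sum"`.
#' @param normalize divide the sum by the number of genes found (off by
#'   default; the raw sum is the published form).
#' @return Data frame `sample_id`, `score`, with attributes
#'   `n_genes_found`, `n_genes_missing`, `mode`.
#' @export
signature_score <- function(m, sig, mode = c("zscore_sum", "log2_sum"),
                            normalize = FALSE) {
  mode <- match.arg(mode)
  found <- intersect(sig$gene_ids, rownames(m))
  if (!length(found))
    stop_data("none of the ", length(sig$gene_ids), " genes of signature '",
              sig$name, "' are present in the matrix")
  if (mode == "zscore_sum") {
    z <- if (identical(expr_unit(m), "zscore")) m else zscore_genes(m)
    v <- unclass(z)[found, , drop = FALSE]
  } else {
    if (identical(expr_unit(m), "zscore"))
      stop_usage("log2_sum cannot be applied to z-scored data")
    lg <- if (identical(expr_unit(m), "log2")) m else log_transform(m, 1)
    v <- unclass(lg)[found, , drop = FALSE]
  }
  score <- colSums(v)
  if (normalize) score <- score / length(found)
  out <- data.frame(sample_id = colnames(m), score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "n_genes_found") <- length(found)
  attr(out, "n_genes_missing") <- length(sig$gene_ids) - length(found)
  attr(out, "mode") <- mode
  out
}

#' Derive a signature from cistrome consensus and differential expression
#'
#' The consensus of two or more cistrome-annotated gene sets (their
#' intersection) filtered to the genes whose expression log2 fold change
#' strictly exceeds `fc_thresh`. This is the derivation used to distill a
#' transcription factor's bound-gene consensus into an expression-backed
#' signature.
#'
#' @param bound_gene_sets list of >= 2 character vectors of bound genes
#'   (one per cistrome sample).
#' @param de_log2fc named numeric vector of log2 fold changes; consensus
#'   genes missing from it are treated as not passing the filter.
#' @param fc_thresh strict lower fold-change bound (default 2).
#' @param name signature name (default `"consensus"`).
#' @return A [gene_signature()] with derivation provenance.
#' @export
derive_signature <- function(bound_gene_sets, de_log2fc, fc_thresh = 2,
                             name = "consensus") {
  if (!is.list(bound_gene_sets) || length(bound_gene_sets) < 2L)
    stop_usage("need at least 2 bound-gene sets")
  if (!length(de_log2fc)) stop_usage("empty fold-change table")
  consensus <- Reduce(intersect, lapply(bound_gene_sets, unique))
  if (!length(consensus)) {
    sizes <- paste(sprintf("set %d: %d genes", seq_along(bound_gene_sets),
                           lengths(bound_gene_sets)), collapse = "; ")
    stop_data("empty consensus across ", length(bound_gene_sets),
              " sets (", sizes, ")")
  }
  consensus <- sort(consensus)
  fc <- de_log2fc[consensus]
  keep <- !is.na(fc) & fc > fc_thresh
  if (!any(keep))
    stop_data("no consensus gene passes log2FC > ", fc_thresh)
  gene_signature(name, consensus[keep],
                 provenance = sprintf(
                   "consensus of %d cistrome gene sets (%d genes), filtered at log2FC > %g (%d genes)",
                   length(bound_gene_sets), length(consensus), fc_thresh,
                   sum(keep)))
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the query gene set overlaps it more
#' than expected by chance among the universe, using the upper-tail
#' hypergeometric probability ([hyper_upper_tail()]), then adjusts across
#' pathways with Benjamini-Hochberg. Pathways are intersected with the
#' universe before testing.
#'
#' @param query character vector of genes; must be a subset of
#'   `universe`.
#' @param universe character vector of background genes.
#' @param pathways named list of character vectors.
#' @return Data frame `pathway`, `k`, `n`, `K`, `N`, `p_value`, `log_p`,
#'   `padj`, sorted by ascending p (ties by pathway name).
#' @export
ora <- function(query, universe, pathways) {
  query <- unique(query); universe <- unique(universe)
  off <- setdiff(query, universe)
  if (length(off))
    stop_usage("query genes outside the universe: ",
               paste(head(off, 10), collapse = ", "),
               if (length(off) > 10) ", ..." else "")
  if (!length(pathways) || is.null(names(pathways)))
    stop_usage("pathways must be a named list")
  N <- length(universe); n <- length(query)
  rows <- lapply(pathways, function(p) {
    p <- intersect(unique(p), universe)
    hyper_table(k = length(intersect(query, p)), K = length(p), n = n, N = N)
  })
  out <- cbind(data.frame(pathway = names(pathways),
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out$padj <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @name signature-io
#' @title Read and write signature files
#' @description Two-column TSV (`set_name`, `gene_id`), one row per gene;
#'   several signatures may share a file.
#' @param path file path.
#' @param sig a `gene_signature` (writer) .
#' @return `read_signatures()` returns a named list of
#'   [gene_signature()]s; the writer returns `path` invisibly.
NULL

#' @rdname signature-io
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_data(path, ": expected columns set_name, gene_id")
  split_ <- split(as.character(df[[2]]), as.character(df[[1]]))
  lapply(setNames(names(split_), names(split_)), function(nm)
    gene_signature(nm, split_[[nm]], provenance = paste("read from", path)))
}

#' @rdname signature-io
#' @export
write_signature <- function(sig, path) {
  writeLines(c("set_name\tgene_id",
               paste(sig$name, sig$gene_ids, sep = "\t")), path)
  invisible(path)
}
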