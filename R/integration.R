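#' Link peaks to genes by distance to the TSS
#'
#' One link per (peak, gene) pair whose distance from the peak center to
#' the gene's TSS is at most `max_dist` bp (inclusive). A peak may link
#' several genes and a gene several peaks.
#'
#' @param peaks a `peak_set`.
#' @param genes a `gene_models` object.
#' @param max_dist maximum center-to-TSS distance in bp (default 50000).
#' @param anchor `"tss"` (default) measures to the TSS; `"body"` measures
#'   to the nearest point of the gene span.
#' @return Data frame `peak`, `gene_id`, `distance`, ordered by
#'   (chrom, start, gene_id).
#' @export
link_peaks_to_genes <- function(peaks, genes, max_dist = 50000,
                                anchor = c("tss", "body")) {
  anchor <- match.arg(anchor)
  if (max_dist < 0) stop_usage("max_dist must be >= 0")
  g <- genes$genes
  tss <- gene_tss(genes)
  peaks <- sort_peaks(peaks)
  ctr <- peak_center(peaks)
  out <- list()
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(g$chrom == ch)
    if (!length(gi)) next
    if (anchor == "tss") {
      d <- abs(outer(ctr[pi], tss[g$gene_id[gi]], "-"))
    } else {
      below <- outer(ctr[pi], g$start[gi], function(c_, s) pmax(s - c_, 0))
      above <- outer(ctr[pi], g$end[gi] - 1L, function(c_, e) pmax(c_ - e, 0))
      d <- below + above
    }
    hit <- which(d <= max_dist, arr.ind = TRUE)
    if (!nrow(hit)) next
    out[[ch]] <- data.frame(peak = peaks$name[pi][hit[, 1]],
                            gene_id = g$gene_id[gi][hit[, 2]],
                            distance = as.integer(d[hit]),
                            chrom = ch, start = peaks$start[pi][hit[, 1]],
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peak = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("peak", "gene_id", "distance")]
}

#' Classify genes as activated, repressed or unchanged
#'
#' The accessibility/expression integration rule: a gene is *activated*
#' when it lies within `max_dist` of the center of at least one gained
#' (newly accessible) peak and its expression log2 fold change exceeds
#' `up_thresh` (strictly); *repressed* when it is linked to at least one
#' lost peak and its fold change is strictly below `down_thresh`. A gene
#' qualifying for both classes at once is reported `unchanged` with
#' `conflict = TRUE` rather than silently picking a side; every other
#' gene is `unchanged`.
#'
#' @param gained,lost `peak_set`s of newly accessible and closed regions
#'   (typically `unique_b` / `unique_a` of [partition_peaks()]).
#' @param genes a `gene_models` object.
#' @param log2fc named numeric vector of per-gene log2 fold changes
#'   (treated over control). Genes absent from the models are skipped
#'   with a warning.
#' @param up_thresh,down_thresh strict fold-change cutoffs (defaults +1,
#'   -1).
#' @param max_dist maximum center-to-TSS link distance (default 50000).
#' @param anchor passed to [link_peaks_to_genes()].
#' @return Data frame `gene_id`, `class`, `log2fc`, `n_gained_links`,
#'   `n_lost_links`, `min_distance`, `conflict`, one row per scored gene
#'   in `log2fc` order.
#' @export
classify_genes <- function(gained, lost, genes, log2fc, up_thresh = 1,
                           down_thresh = -1, max_dist = 50000,
                           anchor = c("tss", "body")) {
  anchor <- match.arg(anchor)
  ids <- names(log2fc)
  if (is.null(ids)) stop_usage("log2fc must be a named per-gene vector")
  known <- ids %in% genes$genes$gene_id
  if (any(!known))
    warning(sum(!known), " gene(s) in the fold-change table are absent ",
            "from the gene models and were skipped")
  ids <- ids[known]
  gl <- link_peaks_to_genes(gained, genes, max_dist, anchor)
  ll <- link_peaks_to_genes(lost, genes, max_dist, anchor)
  ng <- table(gl$gene_id)[ids]; ng[is.na(ng)] <- 0L
  nl <- table(ll$gene_id)[ids]; nl[is.na(nl)] <- 0L
  mind <- rep(NA_integer_, length(ids))
  alld <- rbind(gl, ll)
  if (nrow(alld)) {
    agg <- tapply(alld$distance, alld$gene_id, min)
    mind <- as.integer(agg[ids])
  }
  fc <- unname(log2fc[ids])
  act <- ng > 0 & fc > up_thresh
  rep_ <- nl > 0 & fc < down_thresh
  conflict <- act & rep_
  class_ <- ifelse(conflict, "unchanged",
            ifelse(act, "activated",
            ifelse(rep_, "repressed", "unchanged")))
  data.frame(gene_id = ids, class = as.character(class_), log2fc = fc,
             n_gained_links = as.integer(ng), n_lost_links = as.integer(nl),
             min_distance = mind, conflict = as.logical(conflict),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression response of enhancer-bound genes
#'
#' Restricts a cistrome (annotated peak set) to enhancer peaks (intronic
#' or intergenic), links them to genes, and splits the linked genes by
#' expression response: `enhancer_up` with log2FC strictly above
#' `up_thresh`, `enhancer_down` strictly below `down_thresh`. Percentages
#' are reported among linked genes with a fold-change value.
#'
#' @param annotated annotated cistrome peaks ([annotate_peaks()] output).
#' @param genes a `gene_models` object.
#' @param log2fc named per-gene log2 fold changes (e.g. knockdown over
#'   control).
#' @param up_thresh,down_thresh strict cutoffs (defaults +1, -1).
#' @param max_dist link distance (default 50000).
#' @return List with `enhancer_up`, `enhancer_down` (character vectors),
#'   `pct_up`, `pct_down`, and `n_linked` (linked genes with a fold
#'   change).
#' @export
enhancer_expression_classes <- function(annotated, genes, log2fc,
                                        up_thresh = 1, down_thresh = -1,
                                        max_dist = 50000) {
  enh <- annotated[annotated$is_enhancer, , drop = FALSE]
  if (!nrow(enh))
    return(list(enhancer_up = character(0), enhancer_down = character(0),
                pct_up = NA_real_, pct_down = NA_real_, n_linked = 0L))
  ps <- peak_set(enh$chrom, enh$start, enh$end, name = enh$name,
                 label = "enhancers")
  links <- link_peaks_to_genes(ps, genes, max_dist)
  linked <- intersect(unique(links$gene_id), names(log2fc))
  fc <- log2fc[linked]
  up <- sort(linked[fc > up_thresh])
  down <- sort(linked[fc < down_thresh])
  n <- length(linked)
  list(enhancer_up = up, enhancer_down = down,
       pct_up = if (n) 100 * length(up) / n else NA_real_,
       pct_down = if (n) 100 * length(down) / n else NA_real_,
       n_linked = n)
}

#' Write a gene classification table as TSV
#' @param classification output of [classify_genes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  header <- paste(colnames(classification), collapse = "\t")
  body <- vapply(seq_len(nrow(classification)), function(i)
    paste(vapply(classification[i, ], function(v)
      if (is.numeric(v) && !is.integer(v)) fmt_num(v) else as.character(v),
      character(1)), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
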