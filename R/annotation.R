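#' Annotation window configuration
#'
#' Window sizes for HOMER-style categorical annotation. The promoter
#' window extends `promoter_upstream` bp upstream to
#' `promoter_downstream` bp downstream of the TSS (strand-aware); the TTS
#' window extends `tts_window` bp on each side of the transcript end.
#'
#' @param promoter_upstream bp upstream of the TSS (default 1000).
#' @param promoter_downstream bp downstream of the TSS (default 100).
#' @param tts_window bp each side of the TES (default 100).
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(promoter_upstream = 1000,
                              promoter_downstream = 100,
                              tts_window = 100) {
  if (promoter_upstream < 0 || promoter_downstream < 0 || tts_window < 0)
    stop_usage("annotation windows must be >= 0")
  structure(list(promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 tts_window = tts_window),
            class = "annotation_config")
}

ANNOT_CATEGORIES <- c("promoter", "exon", "intron", "TTS", "intergenic")

# positions (0-based) covered by a strand-aware window around an anchor:
# [anchor - up, anchor + down] in the gene's orientation, inclusive
window_bounds <- function(anchor, strand, up, down) {
  lo <- ifelse(strand == "+", anchor - up, anchor - down)
  hi <- ifelse(strand == "+", anchor + down, anchor + up)
  cbind(lo, hi)
}

#' Annotate peaks against gene models
#'
#' Classifies each peak by the genomic context of its center, with
#' priority promoter > TTS > exon > intron > intergenic, so that the
#' categories partition the peak set. The promoter and TTS windows are
#' strand-aware; `nearest_gene` is the gene whose TSS is closest to the
#' peak center (ties resolved to the lexicographically smallest gene id,
#' restricted to genes on the same chromosome), and `tss_distance` is
#' signed, positive downstream in the gene's orientation. Peaks in introns
#' or intergenic space are flagged `is_enhancer`, the enhancer definition
#' used for cistrome/expression integration.
#'
#' @param peaks a `peak_set`.
#' @param genes a `gene_models` object.
#' @param cfg an [annotation_config()].
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `category`, `nearest_gene`, `tss_distance`, `is_enhancer` (one row
#'   per peak, input order preserved).
#' @export
annotate_peaks <- function(peaks, genes, cfg = annotation_config()) {
  n <- nrow(peaks)
  ctr <- peak_center(peaks)
  category <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)
  tssd <- rep(NA_integer_, n)
  g <- genes$genes
  tss <- gene_tss(genes); tes <- gene_tes(genes)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    gi <- which(g$chrom == ch)
    if (!length(gi)) next
    c_ <- ctr[pi]
    gtss <- tss[g$gene_id[gi]]; gtes <- tes[g$gene_id[gi]]
    gstr <- g$strand[gi]
    # nearest gene by |center - TSS|, ties to smallest gene_id
    dmat <- abs(outer(c_, gtss, "-"))
    ord <- order(g$gene_id[gi])
    pick <- apply(dmat[, ord, drop = FALSE], 1, which.min)
    ng <- gi[ord][pick]
    nearest[pi] <- g$gene_id[ng]
    tssd[pi] <- as.integer(ifelse(g$strand[ng] == "+",
                                  c_ - tss[g$gene_id[ng]],
                                  tss[g$gene_id[ng]] - c_))
    # category membership, vectorised per gene set on this chromosome
    pb <- window_bounds(gtss, gstr, cfg$promoter_upstream,
                        cfg$promoter_downstream)
    in_prom <- rowSums(outer(c_, pb[, 1], ">=") &
                       outer(c_, pb[, 2], "<=")) > 0
    tb <- window_bounds(gtes, gstr, cfg$tts_window, cfg$tts_window)
    in_tts <- rowSums(outer(c_, tb[, 1], ">=") &
                      outer(c_, tb[, 2], "<=")) > 0
    in_gene <- rowSums(outer(c_, g$start[gi], ">=") &
                       outer(c_, g$end[gi], "<")) > 0
    ex <- genes$exons[genes$exons$gene_id %in% g$gene_id[gi], , drop = FALSE]
    in_exon <- if (nrow(ex))
      rowSums(outer(c_, ex$start, ">=") & outer(c_, ex$end, "<")) > 0
    else rep(FALSE, length(c_))
    cat_ <- ifelse(in_prom, "promoter",
            ifelse(in_tts, "TTS",
            ifelse(in_gene & in_exon, "exon",
            ifelse(in_gene, "intron", "intergenic"))))
    category[pi] <- cat_
  }
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             name = peaks$name, category = category,
             nearest_gene = nearest, tss_distance = tssd,
             is_enhancer = category %in% c("intron", "intergenic"),
             stringsAsFactors = FALSE)
}

#' Genomic distribution of annotated peaks
#'
#' Fraction of peaks per annotation category (the "percentage of all
#' peaks" summary).
#'
#' @param annotated output of [annotate_peaks()].
#' @return Named numeric vector over promoter, exon, intron, TTS,
#'   intergenic, summing to 1.
#' @export
genomic_distribution <- function(annotated) {
  if (!nrow(annotated)) stop_usage("no annotated peaks")
  counts <- table(factor(annotated$category, levels = ANNOT_CATEGORIES))
  out <- as.numeric(counts) / nrow(annotated)
  setNames(out, ANNOT_CATEGORIES)
}

#' Write annotated peaks as TSV
#' @param annotated output of [annotate_peaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated <- function(annotated, path) {
  header <- paste(colnames(annotated), collapse = "\t")
  body <- vapply(seq_len(nrow(annotated)), function(i)
    paste(vapply(annotated[i, ], as.character, character(1)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
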