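#' @name peak-io
#' @title Read and write BED6 and ENCODE narrowPeak files
#'
#' @description
#' Tab-separated peak readers/writers. Coordinates are kept 0-based
#' half-open, matching the file formats. narrowPeak column 10 (summit
#' offset) maps to the `summit` field; `-1` means absent. The extra
#' narrowPeak statistics columns (signalValue, pValue, qValue) are carried
#' through verbatim so that writing a file that was just read reproduces it
#' byte for byte.
#'
#' @param path file path.
#' @param x a `peak_set`.
#' @param label condition label to attach; defaults to the file name.
#' @return `read_bed()`/`read_narrowpeak()` return a `peak_set`; the
#'   writers return `path` invisibly.
NULL

read_peak_lines <- function(path, ncol_expect, what) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(NULL)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != ncol_expect)
  if (length(bad))
    stop_data(path, " line ", bad[1], ": expected ", ncol_expect,
              " tab-separated fields for ", what, ", found ", nf[bad[1]])
  do.call(rbind, parts)
}

#' @rdname peak-io
#' @export
read_bed <- function(path, label = basename(path)) {
  m <- read_peak_lines(path, 6L, "BED6")
  if (is.null(m)) return(peak_set(character(0), integer(0), integer(0),
                                  label = label))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop_data(path, ": non-integer coordinates")
  peak_set(m[, 1], start, end, name = m[, 4],
           score = suppressWarnings(as.numeric(m[, 5])), strand = m[, 6],
           label = label)
}

#' @rdname peak-io
#' @export
write_bed <- function(x, path) {
  lines <- paste(x$chrom, x$start, x$end, x$name, fmt_num(x$score),
                 x$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname peak-io
#' @export
read_narrowpeak <- function(path, label = basename(path)) {
  m <- read_peak_lines(path, 10L, "narrowPeak")
  if (is.null(m)) return(peak_set(character(0), integer(0), integer(0),
                                  label = label))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop_data(path, ": non-integer coordinates")
  summit <- suppressWarnings(as.integer(m[, 10]))
  if (anyNA(summit)) stop_data(path, ": non-integer summit column")
  summit[summit < 0L] <- NA_integer_
  out <- peak_set(m[, 1], start, end, name = m[, 4],
                  score = suppressWarnings(as.numeric(m[, 5])),
                  strand = m[, 6], summit = summit, label = label)
  out$signal <- m[, 7]; out$pval <- m[, 8]; out$qval <- m[, 9]
  out
}

#' @rdname peak-io
#' @export
write_narrowpeak <- function(x, path) {
  signal <- if (is.null(x$signal)) rep("0", nrow(x)) else x$signal
  pval <- if (is.null(x$pval)) rep("-1", nrow(x)) else x$pval
  qval <- if (is.null(x$qval)) rep("-1", nrow(x)) else x$qval
  summit <- ifelse(is.na(x$summit), -1L, x$summit)
  lines <- paste(x$chrom, x$start, x$end, x$name, fmt_num(x$score),
                 x$strand, signal, pval, qval, summit, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses `gene` and `exon` features of a GTF (1-based inclusive
#' coordinates) into 0-based half-open gene models. Exons are attached to
#' their gene via the `gene_id` attribute; a gene without exon lines gets a
#' single exon spanning its transcript. When several lines share a
#' `gene_id` only one `gene` feature is allowed per id; overlapping
#' transcript evidence should be collapsed upstream.
#'
#' @param path GTF file path.
#' @return A `gene_models` object: list with data frames `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`; 0-based half-open) and
#'   `exons` (`gene_id`, `start`, `end`).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty GTF: ", path)
    return(gene_models(
      data.frame(gene_id = character(0), chrom = character(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = character(0), start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 9L)
  if (length(bad))
    stop_data(path, " line ", lineno[bad[1]],
              ": malformed GTF (", nf[bad[1]], " fields, expected 9)")
  m <- do.call(rbind, parts)
  feat <- m[, 3]
  sel <- feat %in% c("gene", "exon")
  m <- m[sel, , drop = FALSE]; lineno <- lineno[sel]; feat <- feat[sel]
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1)
  if (length(bad))
    stop_data(path, " line ", lineno[bad[1]], ": invalid GTF coordinates")
  strand <- m[, 7]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop_data(path, " line ", lineno[bad[1]], ": unknown strand '",
              strand[bad[1]], "'")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", m[, 9])
  bad <- which(gid == m[, 9])
  if (length(bad))
    stop_data(path, " line ", lineno[bad[1]], ": missing gene_id attribute")
  gsel <- feat == "gene"
  genes <- data.frame(gene_id = gid[gsel], chrom = m[gsel, 1],
                      strand = strand[gsel], start = start1[gsel] - 1L,
                      end = end1[gsel], stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop_data(path, ": duplicate gene_id ",
              genes$gene_id[duplicated(genes$gene_id)][1])
  exons <- data.frame(gene_id = gid[!gsel], start = start1[!gsel] - 1L,
                      end = end1[!gsel], stringsAsFactors = FALSE)
  orphans <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphans))
    stop_data(path, ": exon with unknown gene_id ", orphans[1])
  gene_models(genes, exons)
}

#' Assemble gene models
#'
#' @param genes data frame with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open transcript span).
#' @param exons data frame with `gene_id`, `start`, `end`; genes absent
#'   here receive a single exon spanning the transcript.
#' @return A `gene_models` object.
#' @export
gene_models <- function(genes, exons = NULL) {
  if (anyDuplicated(genes$gene_id)) stop_data("duplicate gene_id")
  if (nrow(genes) && any(genes$start >= genes$end))
    stop_data("gene with start >= end")
  if (is.null(exons))
    exons <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  missing_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_ex)) {
    i <- match(missing_ex, genes$gene_id)
    exons <- rbind(exons, data.frame(gene_id = missing_ex,
                                     start = genes$start[i],
                                     end = genes$end[i],
                                     stringsAsFactors = FALSE))
  }
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  gi <- match(exons$gene_id, genes$gene_id)
  if (nrow(exons) &&
      any(exons$start < genes$start[gi] | exons$end > genes$end[gi]))
    stop_data("exon outside its transcript span")
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  out <- list(genes = genes, exons = exons)
  class(out) <- "gene_models"
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Transcription start sites
#'
#' Strand-aware TSS positions: `start` for `+` genes, `end - 1` for `-`
#' genes (0-based).
#' @param gm a `gene_models` object.
#' @return Named integer vector, one TSS per gene.
#' @export
gene_tss <- function(gm) {
  g <- gm$genes
  setNames(as.integer(ifelse(g$strand == "+", g$start, g$end - 1L)),
           g$gene_id)
}

gene_tes <- function(gm) {
  g <- gm$genes
  setNames(as.integer(ifelse(g$strand == "+", g$end - 1L, g$start)),
           g$gene_id)
}

#' Write gene models as GTF
#'
#' Emits one `gene` line and one `exon` line per exon, 1-based inclusive,
#' in a canonical layout that [read_gtf()] parses back losslessly.
#'
#' @param gm a `gene_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gm, path) {
  g <- gm$genes
  gl <- paste(g$chrom, "chromlink", "gene", g$start + 1L, g$end, ".",
              g$strand, ".", sprintf('gene_id "%s";', g$gene_id), sep = "\t")
  e <- gm$exons
  gi <- match(e$gene_id, g$gene_id)
  el <- paste(g$chrom[gi], "chromlink", "exon", e$start + 1L, e$end, ".",
              g$strand[gi], ".", sprintf('gene_id "%s";', e$gene_id),
              sep = "\t")
  # interleave: each gene followed by its exons
  ord <- order(c(seq_len(nrow(g)), gi + 0.5))
  writeLines(c(gl, el)[ord], path)
  invisible(path)
}

#' @name genome-io
#' @title Read and write genome FASTA
#' @description Genomes are handled as named character vectors of
#'   uppercase sequence (one element per chromosome; FASTA names truncated
#'   at the first whitespace). Files written by [write_genome()] are
#'   re-read byte-identically.
#' @param path FASTA file path.
#' @param genome named character vector of sequences.
#' @param width line width for writing (bp).
#' @return `read_genome()` returns the named character vector;
#'   `write_genome()` returns `path` invisibly.
NULL

#' @rdname genome-io
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname genome-io
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: per line, set name, description, then member genes,
#'   tab-separated.
#' @return Named list of character vectors of gene ids; descriptions kept
#'   in attribute `description`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop_data(path, " line ", short[1],
              ": GMT lines need name, description and >=1 gene")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, genes, d)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), sets, description)
  writeLines(unlist(lines, use.names = FALSE), path)
  invisible(path)
}

#' @name matrix-io
#' @title Read and write expression matrices and fold-change tables
#' @description TSV layout: header row of sample ids, first column gene
#'   ids. Fold-change tables are two columns, `gene` and `log2fc`. Parsing
#'   is locale-independent (`.` decimal separator).
#' @param path file path.
#' @param unit expression unit of the values being read (see
#'   [expr_matrix()]).
#' @param m an `expr_matrix`.
#' @param x named numeric vector of per-gene log2 fold changes.
#' @return Readers return an `expr_matrix` / named numeric vector; writers
#'   return `path` invisibly.
NULL

#' @rdname matrix-io
#' @export
read_expr_matrix <- function(path, unit = "counts") {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = NA, dec = ".")
  if (ncol(df) < 2L) stop_data(path, ": expected gene column plus samples")
  genes <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(v)) stop_data(path, ": non-numeric expression values")
  rownames(v) <- genes
  expr_matrix(v, unit = unit)
}

#' @rdname matrix-io
#' @export
write_expr_matrix <- function(m, path) {
  v <- unclass(m)
  header <- paste(c("gene", colnames(v)), collapse = "\t")
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], fmt_num(v[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname matrix-io
#' @export
read_log2fc <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, dec = ".")
  if (ncol(df) < 2L) stop_data(path, ": expected columns gene, log2fc")
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' @rdname matrix-io
#' @export
write_log2fc <- function(x, path) {
  writeLines(c("gene\tlog2fc",
               paste(names(x), fmt_num(unname(x)), sep = "\t")), path)
  invisible(path)
}
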