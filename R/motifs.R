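IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

#' Define a DNA motif
#'
#' A motif is either an IUPAC consensus string (exact ambiguity-code
#' matching) or a 4 x width probability matrix (rows A, C, G, T) scored as
#' a log2 likelihood ratio against a uniform background, with a bit-score
#' threshold. Scanning always covers both strands.
#'
#' @param name motif name (used for ranking and labels).
#' @param consensus IUPAC consensus string, e.g. the E-box `"CAGCTG"` or
#'   its degenerate core `"CANNTG"`.
#' @param matrix 4 x width numeric matrix of base probabilities, rows in
#'   A, C, G, T order; columns are renormalised after adding `pseudocount`.
#' @param threshold minimum log2-odds score in bits for a matrix-mode hit.
#' @param pseudocount probability mass added per matrix cell before
#'   renormalisation (matrix mode; default 0.001).
#' @return A `motif` object.
#' @examples
#' motif("Ebox", consensus = "CAGCTG")
#' @export
motif <- function(name, consensus = NULL, matrix = NULL, threshold = NULL,
                  pseudocount = 0.001) {
  if (is.null(consensus) == is.null(matrix))
    stop_usage("motif needs exactly one of consensus or matrix")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    codes <- strsplit(consensus, "")[[1]]
    if (!length(codes) || !all(codes %in% names(IUPAC_CODES)))
      stop_data("invalid IUPAC consensus: ", consensus)
    out <- list(name = name, consensus = consensus, matrix = NULL,
                threshold = NULL, pseudocount = NULL)
  } else {
    matrix <- as.matrix(matrix)
    if (nrow(matrix) != 4L || ncol(matrix) < 1L || any(matrix < 0))
      stop_data("motif matrix must be 4 x width, non-negative (rows A,C,G,T)")
    if (is.null(threshold)) stop_usage("matrix motifs need a bit threshold")
    rownames(matrix) <- c("A", "C", "G", "T")
    matrix <- sweep(matrix + pseudocount, 2,
                    colSums(matrix + pseudocount), "/")
    out <- list(name = name, consensus = NULL, matrix = matrix,
                threshold = threshold, pseudocount = pseudocount)
  }
  class(out) <- "motif"
  out
}

#' @export
print.motif <- function(x, ...) {
  if (!is.null(x$consensus))
    cat(sprintf("motif %s: consensus %s\n", x$name, x$consensus))
  else
    cat(sprintf("motif %s: %d-position probability matrix, threshold %g bits\n",
                x$name, ncol(x$matrix), x$threshold))
  invisible(x)
}

#' Width of a motif in bp
#' @param m a `motif`.
#' @return Integer width.
#' @export
motif_width <- function(m) {
  if (!is.null(m$consensus)) nchar(m$consensus) else ncol(m$matrix)
}

#' Reverse complement of an IUPAC string
#' @param x character vector of IUPAC sequences.
#' @return Reverse-complemented strings (ambiguity codes mapped to their
#'   complements).
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    codes <- rev(strsplit(toupper(s), "")[[1]])
    paste(IUPAC_COMPLEMENT[codes], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# regex for one IUPAC consensus; sequence N only matches consensus N
iupac_regex <- function(consensus) {
  codes <- strsplit(consensus, "")[[1]]
  paste0(vapply(codes, function(cc) {
    opts <- IUPAC_CODES[[cc]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

# all overlapping match offsets (0-based) of a consensus in each sequence
consensus_offsets <- function(seqs, consensus) {
  pat <- paste0("(?=", iupac_regex(consensus), ")")
  res <- gregexpr(pat, seqs, perl = TRUE)
  lapply(res, function(r) {
    p <- as.integer(r)
    if (length(p) == 1L && p[1] == -1L) integer(0) else p - 1L
  })
}

# matrix-mode scan of one sequence (integer-encoded), one strand
pwm_scores <- function(codes, lods, width) {
  n <- length(codes) - width + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(width)) {
    v <- lods[, j][codes[j:(j + n - 1L)]]
    v[is.na(v)] <- -Inf          # N or unknown base never contributes
    sc <- sc + v
  }
  sc
}

#' Scan a sequence for motif hits on both strands
#'
#' Consensus mode matches the IUPAC pattern exactly (an `N` in the
#' sequence matches only the consensus code `N`); matrix mode scores each
#' offset as the log2 likelihood ratio of the position probabilities
#' against a uniform 0.25 background and reports offsets scoring at least
#' the motif's bit threshold. Minus-strand hits are found by scanning with
#' the reverse-complemented motif and reported at their offset on the
#' given (forward) sequence.
#'
#' @param sequence a single DNA string over A, C, G, T, N (uppercased
#'   internally).
#' @param m a [motif()].
#' @return Data frame with columns `offset` (0-based), `strand`, `score`
#'   (width for consensus hits, bits for matrix hits), ordered by offset
#'   with `+` before `-` at equal offset. Sequences shorter than the motif
#'   yield zero rows.
#' @examples
#' scan_motif("AACAGCTGTT", motif("Ebox", "CAGCTG"))  # palindromic: + and -
#' @export
scan_motif <- function(sequence, m) {
  stopifnot(length(sequence) == 1L)
  s <- toupper(sequence)
  w <- motif_width(m)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nchar(s) < w) return(empty)
  if (!is.null(m$consensus)) {
    fwd <- consensus_offsets(s, m$consensus)[[1]]
    rev_ <- consensus_offsets(s, revcomp(m$consensus))[[1]]
    out <- data.frame(
      offset = c(fwd, rev_),
      strand = c(rep("+", length(fwd)), rep("-", length(rev_))),
      score = rep(w, length(fwd) + length(rev_)), stringsAsFactors = FALSE)
  } else {
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    lods <- log2(m$matrix / 0.25)
    rc <- lods[4:1, rev(seq_len(ncol(lods))), drop = FALSE]  # revcomp matrix
    fs <- pwm_scores(codes, lods, w)
    rs <- pwm_scores(codes, rc, w)
    fhit <- which(fs >= m$threshold); rhit <- which(rs >= m$threshold)
    out <- data.frame(
      offset = c(fhit, rhit) - 1L,
      strand = c(rep("+", length(fhit)), rep("-", length(rhit))),
      score = c(fs[fhit], rs[rhit]), stringsAsFactors = FALSE)
  }
  out <- out[order(out$offset, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

window_sequences <- function(peaks, genome, flank) {
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss))
    stop_data("chromosome(s) absent from genome: ",
              paste(miss, collapse = ", "))
  lens <- setNames(nchar(genome), names(genome))
  win <- center_window(peaks, flank, lens)
  toupper(substr(genome[win$chrom], win$start + 1L, win$end))
}

has_hit <- function(seqs, m) {
  if (!is.null(m$consensus)) {
    fwd <- grepl(iupac_regex(m$consensus), seqs, perl = TRUE)
    rev_ <- grepl(iupac_regex(revcomp(m$consensus)), seqs, perl = TRUE)
    fwd | rev_
  } else {
    vapply(seqs, function(s) nrow(scan_motif(s, m)) > 0L, logical(1),
           USE.NAMES = FALSE)
  }
}

#' Test peaks for motif presence in their center windows
#'
#' A peak carries a motif when the +/- `flank` bp window around its center
#' contains at least one hit on either strand (presence/absence; hit
#' counts are not used).
#'
#' @param peaks a `peak_set`.
#' @param genome named character vector of chromosome sequences
#'   ([read_genome()]).
#' @param m a [motif()].
#' @param flank window half-width in bp (default 50).
#' @return Logical vector, one element per peak.
#' @export
peak_has_motif <- function(peaks, genome, m, flank = 50) {
  has_hit(window_sequences(peaks, genome, flank), m)
}

#' Motif enrichment in a target peak set versus a background set
#'
#' For each motif, counts carrier peaks (motif present in the peak-center
#' window) in the target set and in the pooled population target +
#' background, and computes the cumulative hypergeometric upper-tail
#' probability of observing at least that many carriers among the target
#' peaks. Rows are ranked by ascending log p-value ([rank_by_logp()]).
#'
#' @param target,background disjoint `peak_set`s; the population is their
#'   union.
#' @param motifs list of [motif()] objects (or a single motif).
#' @param genome named character vector of sequences.
#' @param flank window half-width in bp (default 50).
#' @return Data frame with one row per motif: `motif`, `k` (target
#'   carriers), `n` (target size), `K` (population carriers), `N`
#'   (population size), `p_value`, `log_p` (natural log), `rank`.
#' @export
enrich_motifs <- function(target, background, motifs, genome, flank = 50) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  if (!nrow(target)) stop_usage("empty target peak set")
  if (!nrow(background)) stop_usage("empty background peak set")
  tw <- window_sequences(target, genome, flank)
  bw <- window_sequences(background, genome, flank)
  nms <- vapply(motifs, `[[`, character(1), "name")
  rows <- lapply(motifs, function(m) {
    kt <- sum(has_hit(tw, m))
    kb <- sum(has_hit(bw, m))
    hyper_table(k = kt, K = kt + kb, n = length(tw),
                N = length(tw) + length(bw))
  })
  out <- cbind(data.frame(motif = nms, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rank_by_logp(out)
}

#' Rank enrichment rows by log p-value
#'
#' Rank 1 is the most enriched (smallest log p); ties are broken by motif
#' name, lexicographically, so ranking is independent of input row order.
#'
#' @param rows data frame with columns `motif` and `log_p`.
#' @return The rows sorted by rank with a 1-based `rank` column (1..M, no
#'   gaps).
#' @export
rank_by_logp <- function(rows) {
  if (!nrow(rows)) stop_usage("cannot rank an empty enrichment table")
  ord <- order(rows$log_p, rows$motif)
  out <- rows[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank differential between two enrichment tables
#'
#' The waterfall comparison: for every motif, the change in enrichment
#' rank between condition A and condition B, `shift = rank_a - rank_b`.
#' A positive shift means the motif is more enriched (better ranked) in B.
#'
#' @param rows_a,rows_b ranked enrichment tables ([rank_by_logp()]) over
#'   the same motif universe.
#' @return Data frame `motif`, `rank_a`, `rank_b`, `shift`, sorted by
#'   shift descending (ties by motif name).
#' @export
rank_differential <- function(rows_a, rows_b) {
  miss_b <- setdiff(rows_a$motif, rows_b$motif)
  miss_a <- setdiff(rows_b$motif, rows_a$motif)
  if (length(miss_a) || length(miss_b))
    stop_usage("motif universes differ; missing from A: ",
               paste(miss_a, collapse = ", "), "; missing from B: ",
               paste(miss_b, collapse = ", "))
  i <- match(rows_a$motif, rows_b$motif)
  out <- data.frame(motif = rows_a$motif, rank_a = rows_a$rank,
                    rank_b = rows_b$rank[i],
                    shift = rows_a$rank - rows_b$rank[i],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$shift, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset a peak set to motif carriers
#'
#' Retains only the peaks whose center windows contain the motif,
#' preserving order; the set label is suffixed with the motif name. This
#' is the "retain only accessible features containing the motif" filter.
#'
#' @inheritParams peak_has_motif
#' @return A `peak_set` of carrier peaks.
#' @export
filter_peaks_with_motif <- function(peaks, genome, m, flank = 50) {
  keep <- peak_has_motif(peaks, genome, m, flank)
  as_peak_subset(peaks, keep, paste0(peak_label(peaks), ".", m$name))
}

#' @name motif-io
#' @title Read and write motif definition files
#' @description Plain-text motif files: each motif starts with a header
#'   line `>name<TAB>consensus<TAB>.` (consensus mode) or
#'   `>name<TAB>MATRIX<TAB>threshold` followed by one line per position
#'   with four whitespace-separated probabilities (A C G T).
#' @param path file path.
#' @param motifs list of [motif()] objects.
#' @return `read_motifs()` returns a list of motifs; `write_motifs()`
#'   returns `path` invisibly.
NULL

#' @rdname motif-io
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop_data(path, ": no motif header lines")
  ends <- c(heads[-1] - 1L, length(lines))
  out <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^>", "", lines[heads[i]]), "\t", fixed = TRUE)[[1]]
    if (length(hd) < 2L)
      stop_data(path, ": malformed motif header '", lines[heads[i]], "'")
    if (identical(hd[2], "MATRIX")) {
      if (length(hd) < 3L)
        stop_data(path, ": matrix motif '", hd[1], "' lacks a threshold")
      body <- lines[(heads[i] + 1L):ends[i]]
      rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
      if (!length(rows) || any(lengths(rows) != 4L) || anyNA(unlist(rows)))
        stop_data(path, ": matrix motif '", hd[1],
                  "' needs 4 probabilities per position line")
      pm <- t(do.call(rbind, rows))       # 4 x width, rows A,C,G,T
      # stored probabilities already include any pseudocount
      out[[i]] <- motif(hd[1], matrix = pm, threshold = as.numeric(hd[3]),
                        pseudocount = 0)
    } else {
      out[[i]] <- motif(hd[1], consensus = hd[2])
    }
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' @rdname motif-io
#' @export
write_motifs <- function(motifs, path) {
  if (inherits(motifs, "motif")) motifs <- list(motifs)
  lines <- unlist(lapply(motifs, function(m) {
    if (!is.null(m$consensus))
      paste0(">", m$name, "\t", m$consensus, "\t.")
    else c(paste0(">", m$name, "\tMATRIX\t", fmt_num(m$threshold)),
           vapply(seq_len(ncol(m$matrix)), function(j)
             paste(fmt_num(m$matrix[, j]), collapse = " "), character(1)))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
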