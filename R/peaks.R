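#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals in 0-based half-open
#' coordinates with a condition label, the container used throughout for
#' ATAC-seq and ChIP-seq peaks. An optional per-peak summit offset (distance
#' of the point of maximal signal from `start`, as in ENCODE narrowPeak
#' column 10) refines the peak center used for windowing.
#'
#' @param chrom character vector of chromosome names, or a data frame with
#'   columns `chrom`, `start`, `end` (and optionally `name`, `score`,
#'   `strand`, `summit`).
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param name optional peak identifiers; autogenerated when missing.
#' @param score optional numeric scores (default 0).
#' @param strand one of `"+"`, `"-"`, `"."` per peak (default `"."`).
#' @param summit optional summit offsets from `start`; `NA` means absent.
#' @param label condition label for the whole set.
#' @return A `peak_set`: a data frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `summit` and a `label` attribute.
#' @examples
#' peak_set("chr1", c(0L, 500L), c(100L, 900L), label = "ctrl")
#' @export
peak_set <- function(chrom, start = NULL, end = NULL, name = NULL,
                     score = NULL, strand = NULL, summit = NULL,
                     label = "peaks") {
  if (is.data.frame(chrom)) {
    df <- chrom
    chrom <- df$chrom; start <- df$start; end <- df$end
    if (is.null(name)   && !is.null(df$name))   name   <- df$name
    if (is.null(score)  && !is.null(df$score))  score  <- df$score
    if (is.null(strand) && !is.null(df$strand)) strand <- df$strand
    if (is.null(summit) && !is.null(df$summit)) summit <- df$summit
  }
  start <- as.integer(start); end <- as.integer(end)
  n <- length(start)
  if (length(end) != n)
    stop_data("start and end must have equal length")
  chrom <- rep_len(as.character(chrom), n)
  if (n && any(is.na(start) | is.na(end)))
    stop_data("peak coordinates contain NA")
  if (any(start < 0L)) stop_data("negative start coordinate")
  if (any(start >= end)) stop_data("peak with start >= end")
  if (is.null(name)) name <- if (n) sprintf("peak_%d", seq_len(n)) else character(0)
  if (is.null(score)) score <- rep(0, n)
  if (is.null(strand)) strand <- rep(".", n)
  if (!all(strand %in% c("+", "-", "."))) stop_data("strand must be +, - or .")
  if (is.null(summit)) summit <- rep(NA_integer_, n)
  summit <- as.integer(summit)
  bad <- !is.na(summit) & (summit < 0L | summit >= end - start)
  if (any(bad)) stop_data("summit offset outside peak for: ",
                          paste(name[bad], collapse = ", "))
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = as.character(name), score = as.numeric(score),
                    strand = as.character(strand), summit = summit,
                    stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("peak_set", "data.frame")
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d intervals on %d chromosome(s)\n",
              peak_label(x), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... %d more\n", nrow(x) - 6))
  invisible(x)
}

#' Label of a peak set
#' @param x a `peak_set`.
#' @return The condition label (string).
#' @export
peak_label <- function(x) {
  lab <- attr(x, "label")
  if (is.null(lab)) "peaks" else lab
}

as_peak_subset <- function(x, idx, label = peak_label(x)) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("peak_set", "data.frame")
  out
}

sort_peaks <- function(x) {
  as_peak_subset(x, order(x$chrom, x$start, x$end, x$name))
}

#' Peak centers
#'
#' The center of a peak is its summit position when a summit offset is
#' recorded, otherwise the floor midpoint of the interval.
#'
#' @param x a `peak_set`.
#' @return Integer vector of 0-based center positions.
#' @export
peak_center <- function(x) {
  mid <- as.integer((x$start + x$end) %/% 2L)
  ifelse(!is.na(x$summit), x$start + x$summit, mid)
}

#' Overlap length between intervals
#'
#' Vectorised length in bp of the intersection of two intervals; zero when
#' they touch (half-open), are disjoint, or lie on different chromosomes.
#'
#' @param a,b `peak_set`s (or single-row slices); rows are recycled.
#' @return Integer vector of overlap lengths (>= 0).
#' @examples
#' a <- peak_set("chr1", 0L, 100L); b <- peak_set("chr1", 40L, 100L)
#' overlap_length(a, b)  # 60
#' @export
overlap_length <- function(a, b) {
  len <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  as.integer(ifelse(a$chrom == b$chrom, len, 0L))
}

check_min_frac <- function(min_frac) {
  if (!is.numeric(min_frac) || length(min_frac) != 1L || is.na(min_frac) ||
      min_frac <= 0 || min_frac > 1)
    stop_usage("min_frac must be a single number in (0, 1], got ", min_frac)
}

#' Fractional-overlap predicate for peak pairs
#'
#' Two peaks are considered overlapping when the length of their overlapping
#' region is greater than `min_frac` of the length of either peak. With
#' `mode = "either"` (the default reading) the condition must hold for at
#' least one of the two peaks; `mode = "both"` requires it for both
#' (reciprocal overlap). The inequality is strict.
#'
#' @param a,b `peak_set`s; rows recycled.
#' @param min_frac fraction in (0, 1]; default 0.5.
#' @param mode `"either"` or `"both"`.
#' @return Logical vector.
#' @examples
#' a <- peak_set("chr1", 0L, 200L); b <- peak_set("chr1", 140L, 160L)
#' peaks_overlap(a, b)  # TRUE: the 20 bp overlap exceeds half of b (10 bp)
#' @export
peaks_overlap <- function(a, b, min_frac = 0.5, mode = c("either", "both")) {
  check_min_frac(min_frac)
  mode <- match.arg(mode)
  ov <- overlap_length(a, b)
  fa <- ov > min_frac * (a$end - a$start)
  fb <- ov > min_frac * (b$end - b$start)
  if (mode == "either") fa | fb else fa & fb
}

# indices of rows in `a` having >=1 qualifying overlap in `b`
# (IRanges candidate pairs, then the fractional rule)
overlap_hits <- function(a, b, min_frac, mode) {
  if (!nrow(a) || !nrow(b)) return(logical(nrow(a)))
  hit <- logical(nrow(a))
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
    ra <- IRanges::IRanges(a$start[ia] + 1L, a$end[ia])
    rb <- IRanges::IRanges(b$start[ib] + 1L, b$end[ib])
    fo <- IRanges::findOverlaps(ra, rb)
    if (!length(fo)) next
    qa <- S4Vectors::queryHits(fo); qb <- S4Vectors::subjectHits(fo)
    ov <- pmin(a$end[ia][qa], b$end[ib][qb]) -
          pmax(a$start[ia][qa], b$start[ib][qb])
    fa <- ov > min_frac * (a$end[ia][qa] - a$start[ia][qa])
    fb <- ov > min_frac * (b$end[ib][qb] - b$start[ib][qb])
    ok <- if (mode == "either") fa | fb else fa & fb
    hit[ia[unique(qa[ok])]] <- TRUE
  }
  hit
}

#' Partition two peak sets into unique and shared regions
#'
#' Applies the fractional-overlap rule ([peaks_overlap()]) pairwise: a peak
#' of A is "shared" when it overlaps at least one peak of B, otherwise
#' "unique"; symmetrically for B. This is the shared/unique region
#' decomposition used to define newly accessible and closed chromatin
#' between conditions.
#'
#' @param a,b `peak_set`s.
#' @param min_frac fraction in (0, 1]; default 0.5.
#' @param mode `"either"` or `"both"`; see [peaks_overlap()].
#' @return A `peak_partition`: list with `peak_set`s `unique_a`, `shared_a`,
#'   `unique_b`, `shared_b`, each sorted by (chrom, start, end).
#' @examples
#' a <- peak_set("chr1", c(0L, 1000L), c(100L, 1400L), label = "A")
#' b <- peak_set("chr1", 40L, 100L, label = "B")
#' partition_peaks(a, b)
#' @export
partition_peaks <- function(a, b, min_frac = 0.5, mode = c("either", "both")) {
  check_min_frac(min_frac)
  mode <- match.arg(mode)
  ha <- overlap_hits(a, b, min_frac, mode)
  hb <- overlap_hits(b, a, min_frac, mode)
  la <- peak_label(a); lb <- peak_label(b)
  out <- list(
    unique_a = sort_peaks(as_peak_subset(a, !ha, paste0(la, ".unique"))),
    shared_a = sort_peaks(as_peak_subset(a, ha,  paste0(la, ".shared"))),
    unique_b = sort_peaks(as_peak_subset(b, !hb, paste0(lb, ".unique"))),
    shared_b = sort_peaks(as_peak_subset(b, hb,  paste0(lb, ".shared"))))
  class(out) <- "peak_partition"
  out
}

#' @export
print.peak_partition <- function(x, ...) {
  cat("peak_partition:\n")
  for (nm in names(x))
    cat(sprintf("  %-9s %6d  (%s)\n", nm, nrow(x[[nm]]), peak_label(x[[nm]])))
  invisible(x)
}

#' Multi-way peak membership profiles
#'
#' For every peak of every input set, records which of the sets it overlaps
#' under the fractional rule (membership in its own set is reflexively
#' `TRUE`). The profiles support region groupings across three or more
#' conditions (e.g. regions open in one, two, or all conditions).
#'
#' @param sets named list of two or more `peak_set`s.
#' @param min_frac fraction in (0, 1]; default 0.5.
#' @param mode `"either"` or `"both"`.
#' @return Data frame with columns `set`, `chrom`, `start`, `end`, `name`
#'   and one logical column per input set, ordered set by set then by
#'   (chrom, start, end).
#' @export
peak_membership <- function(sets, min_frac = 0.5, mode = c("either", "both")) {
  check_min_frac(min_frac)
  mode <- match.arg(mode)
  if (!is.list(sets) || length(sets) < 2L)
    stop_usage("peak_membership needs at least 2 peak sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    names(sets) <- vapply(sets, peak_label, character(1))
  if (anyDuplicated(names(sets)))
    names(sets) <- make.unique(names(sets))
  rows <- lapply(names(sets), function(nm) {
    s <- sort_peaks(sets[[nm]])
    prof <- sapply(names(sets), function(other) {
      if (other == nm) rep(TRUE, nrow(s))
      else overlap_hits(s, sets[[other]], min_frac, mode)
    })
    if (nrow(s) == 1L) prof <- matrix(prof, nrow = 1,
                                      dimnames = list(NULL, names(sets)))
    if (!nrow(s)) prof <- matrix(logical(0), nrow = 0, ncol = length(sets),
                                 dimnames = list(NULL, names(sets)))
    cbind(data.frame(set = rep(nm, nrow(s)), chrom = s$chrom,
                     start = s$start, end = s$end, name = s$name,
                     stringsAsFactors = FALSE),
          as.data.frame(prof))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixed-flank windows around peak centers
#'
#' Builds the +/- `flank` bp window around each peak center (summit when
#' present, floor midpoint otherwise), clipped at chromosome ends. These
#' are the windows whose sequence is scanned for motifs.
#'
#' @param x a `peak_set`.
#' @param flank half-width in bp (> 0); default 50.
#' @param chrom_length named integer vector of chromosome lengths, or a
#'   single length applying to every chromosome.
#' @return A `peak_set` of windows (same names, label suffixed `.window`).
#' @examples
#' p <- peak_set("chr1", 100L, 200L)
#' center_window(p, 50, c(chr1 = 1e6))  # the 100 bp window 100-200
#' @export
center_window <- function(x, flank = 50, chrom_length) {
  if (!is.numeric(flank) || length(flank) != 1L || flank <= 0)
    stop_usage("flank must be a single positive number")
  if (any(chrom_length <= 0)) stop_usage("chrom_length must be positive")
  if (length(chrom_length) == 1L && is.null(names(chrom_length)))
    len <- rep(as.numeric(chrom_length), nrow(x))
  else {
    miss <- setdiff(unique(x$chrom), names(chrom_length))
    if (length(miss))
      stop_data("no chromosome length for: ", paste(miss, collapse = ", "))
    len <- as.numeric(chrom_length[x$chrom])
  }
  ctr <- peak_center(x)
  ws <- pmax(0, ctr - flank)
  we <- pmin(len, ctr + flank)
  peak_set(x$chrom, as.integer(ws), as.integer(we), name = x$name,
           score = x$score, strand = x$strand,
           label = paste0(peak_label(x), ".window"))
}
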