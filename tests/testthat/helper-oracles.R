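# Independent brute-force oracles and small fixture builders.
# These re-derive expected results from first principles (plain loops and
# arithmetic) and deliberately avoid the package's own code paths.

# all-pairs fractional-overlap test: does interval i of `a` overlap any
# interval of `b` under the rule, per the printed definition
brute_hit_any <- function(a, b, min_frac = 0.5, mode = "either") {
  n <- nrow(a)
  hit <- logical(n)
  if (!n || !nrow(b)) return(hit)
  for (i in seq_len(n)) {
    same <- b$chrom == a$chrom[i]
    if (!any(same)) next
    ov <- pmax(0, pmin(a$end[i], b$end[same]) - pmax(a$start[i], b$start[same]))
    fa <- ov > min_frac * (a$end[i] - a$start[i])
    fb <- ov > min_frac * (b$end[same] - b$start[same])
    hit[i] <- if (mode == "either") any(fa | fb) else any(fa & fb)
  }
  hit
}

brute_partition_counts <- function(a, b, min_frac = 0.5, mode = "either") {
  ha <- brute_hit_any(a, b, min_frac, mode)
  hb <- brute_hit_any(b, a, min_frac, mode)
  list(shared_a = a$name[ha], unique_a = a$name[!ha],
       shared_b = b$name[hb], unique_b = b$name[!hb])
}

# exact hypergeometric upper tail by combinatorial summation
brute_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random interval sets in plain base R (independent of the generator)
random_interval_set <- function(n, label, n_chroms = 2, L = 100000,
                                wmin = 50, wmax = 800) {
  chrom <- sprintf("chr%d", sample(n_chroms, n, replace = TRUE))
  w <- sample(wmin:wmax, n, replace = TRUE)
  start <- vapply(w, function(wi) sample.int(L - wi, 1), integer(1))
  peak_set(chrom, start, start + w,
           name = sprintf("%s_%d", label, seq_len(n)), label = label)
}

# position-by-position IUPAC consensus scan of one strand (loops only)
brute_consensus_offsets <- function(s, consensus) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T", "N"))
  sv <- strsplit(s, "")[[1]]
  cv <- strsplit(consensus, "")[[1]]
  w <- length(cv)
  hits <- integer(0)
  if (length(sv) < w) return(hits)
  for (off in 0:(length(sv) - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(sv[off + j] %in% iupac[[cv[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# tiny deterministic gene models for annotation/integration tests
toy_genes <- function() {
  gene_models(
    data.frame(gene_id = c("gPlus", "gMinus"),
               chrom = c("chr1", "chr1"),
               strand = c("+", "-"),
               start = c(10000L, 40000L), end = c(16000L, 46000L),
               stringsAsFactors = FALSE),
    data.frame(gene_id = c("gPlus", "gPlus", "gMinus"),
               start = c(10000L, 14000L, 40000L),
               end = c(11000L, 16000L, 46000L), stringsAsFactors = FALSE))
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a),
                                                      as.character(b))
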