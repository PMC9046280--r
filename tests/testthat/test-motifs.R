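test_that("consensus scanning: palindrome, IUPAC codes, no-hit", {
  hits <- scan_motif("AACAGCTGTT", motif("Ebox", "CAGCTG"))
  expect_identical(hits$offset, c(2L, 2L))
  expect_identical(hits$strand, c("+", "-"))   # CAGCTG is its own revcomp
  core <- scan_motif("CATTTG", motif("core", "CANNTG"))
  expect_identical(core$offset, c(0L, 0L))
  expect_setequal(core$strand, c("+", "-"))
  expect_identical(nrow(scan_motif("TTTTTT", motif("Ebox", "CAGCTG"))), 0L)
  # shorter than motif: empty, not an error
  expect_identical(nrow(scan_motif("CAG", motif("Ebox", "CAGCTG"))), 0L)
})

test_that("sequence N matches only the consensus code N", {
  expect_identical(nrow(scan_motif("CANCTG", motif("m", "CAGCTG"))), 0L)
  withN <- scan_motif("CANCTG", motif("m", "CANCTG"))
  expect_true(any(withN$strand == "+" & withN$offset == 0))
  # consensus N matches sequence N too
  expect_identical(scan_motif("CANCTG", motif("m", "CANNTG"))$offset[1], 0L)
})

test_that("scanning agrees with an independent position-by-position oracle", {
  set.seed(17)
  alphabet <- c("A", "C", "G", "T", "N")
  for (i in 1:30) {
    s <- paste(sample(alphabet, 60, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    cons <- paste(sample(c("A", "C", "G", "T", "R", "W", "N"), 5,
                         replace = TRUE), collapse = "")
    m <- motif("m", cons)
    got <- scan_motif(s, m)
    expect_identical(got$offset[got$strand == "+"],
                     brute_consensus_offsets(s, cons))
    expect_identical(got$offset[got$strand == "-"],
                     brute_consensus_offsets(s, revcomp(cons)))
  }
})

test_that("scan of a reverse-complemented sequence mirrors hits", {
  set.seed(23)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    m <- motif("m", "CASSTG")
    f <- scan_motif(s, m)
    r <- scan_motif(revcomp(s), m)
    w <- motif_width(m)
    mirrored <- sort(nchar(s) - w - f$offset[f$strand == "+"])
    expect_identical(sort(r$offset[r$strand == "-"]), as.integer(mirrored))
    expect_identical(nrow(f), nrow(r))
  }
})

test_that("consensus scanning agrees with Biostrings on N-free sequence", {
  set.seed(29)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  m <- motif("ebox", "CANNTG")
  got <- scan_motif(s, m)
  ref <- Biostrings::matchPattern(Biostrings::DNAString("CANNTG"),
                                  Biostrings::DNAString(s), fixed = FALSE)
  expect_identical(got$offset[got$strand == "+"],
                   as.integer(Biostrings::start(ref) - 1L))
})

test_that("matrix mode scores log2 odds against uniform background", {
  # near-deterministic CAG matrix
  pm <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pm["C", 1] <- 1; pm["A", 2] <- 1; pm["G", 3] <- 1
  m <- motif("cag", matrix = pm, threshold = 5, pseudocount = 0.001)
  hits <- scan_motif("TTCAGCTGTT", m)
  expect_true(any(hits$strand == "+" & hits$offset == 2))
  # score close to 3 * log2(1/0.25) = 6 bits
  expect_equal(hits$score[hits$strand == "+"], 6, tolerance = 0.02)
  # minus strand finds the revcomp CTG at offset 5
  expect_true(any(hits$strand == "-" & hits$offset == 5))
  expect_identical(nrow(scan_motif("TTTTTT", m)), 0L)
  # N contributes -Inf: no hit across an N
  expect_identical(nrow(scan_motif("CNG", m)), 0L)
  expect_error(motif("bad", matrix = pm[1:3, ], threshold = 1), "4 x width")
})

test_that("peak carrier calls recover the generator truth table exactly", {
  mx <- simulate_motif_experiment(targets = list(t = list(n = 300,
                                                          rate = 0.4)),
                                  n_background = 700,
                                  rate_background = 0.05, seed = 5)
  all_peaks <- peak_set(rbind(as.data.frame(mx$targets$t),
                              as.data.frame(mx$background)))
  carrier <- peak_has_motif(all_peaks, mx$genome, mx$motifs[[1]])
  truth <- mx$truth$carrier[match(all_peaks$name, mx$truth$name)]
  expect_identical(unname(carrier), truth)
  # every planted peak is a carrier; chance hits are possible on top
  expect_true(all(carrier[mx$truth$planted[match(all_peaks$name,
                                                 mx$truth$name)]]))
  kept <- filter_peaks_with_motif(all_peaks, mx$genome, mx$motifs[[1]])
  expect_identical(kept$name, all_peaks$name[carrier])
  expect_match(peak_label(kept), "planted_CAGCTG")
  expect_error(peak_has_motif(peak_set("chrX", 0, 100), mx$genome,
                              mx$motifs[[1]]), "chrX")
})

test_that("hypergeometric tail reproduces exact combinatorial sums", {
  expect_equal(hyper_upper_tail(5, K = 6, n = 10, N = 20), 13013 / 184756,
               tolerance = 1e-12)
  expect_equal(hyper_upper_tail(2, K = 2, n = 2, N = 4), 1 / 6,
               tolerance = 1e-12)
  expect_identical(hyper_upper_tail(0, K = 6, n = 10, N = 20), 1)
  expect_error(hyper_upper_tail(7, K = 6, n = 10, N = 20), "exceed")
})

test_that("hypergeometric tail matches full enumeration on a small grid", {
  set.seed(31)
  worst <- 0
  for (rep in 1:300) {
    N <- sample(2:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    p <- hyper_upper_tail(k, K, n, N)
    q <- brute_hyper_upper(k, K, n, N)
    worst <- max(worst, abs(p - q) / q)
  }
  expect_lt(worst, 1e-10)
})

test_that("the tail is monotonically non-increasing in k", {
  for (k in 1:10) {
    expect_lte(hyper_upper_tail(k, K = 12, n = 10, N = 40),
               hyper_upper_tail(k - 1, K = 12, n = 10, N = 40))
  }
})

test_that("enrichment rows carry consistent counts and ranks", {
  mx <- simulate_motif_experiment(targets = list(t = list(n = 100,
                                                          rate = 1)),
                                  n_background = 300,
                                  rate_background = 0, seed = 2)
  tab <- enrich_motifs(mx$targets$t, mx$background, mx$motifs, mx$genome)
  planted <- tab[tab$motif == "planted_CAGCTG", ]
  expect_identical(planted$k, 100L)          # carrier rate 1: k = n
  expect_identical(planted$n, 100L)
  expect_identical(planted$rank, 1L)
  expect_true(all(diff(tab$rank) == 1L))
  expect_true(all(tab$log_p <= 0))
  expect_true(all(tab$k <= pmin(tab$n, tab$K)))
  expect_error(enrich_motifs(mx$targets$t[0, ], mx$background, mx$motifs,
                             mx$genome), "empty")
})

test_that("rank assignment breaks ties by name and ignores input order", {
  rows <- data.frame(motif = c("zeta", "alpha", "mid"),
                     log_p = c(log(0.5), log(0.5), log(1e-3)),
                     stringsAsFactors = FALSE)
  r1 <- rank_by_logp(rows)
  expect_identical(r1$motif, c("mid", "alpha", "zeta"))
  r2 <- rank_by_logp(rows[c(3, 1, 2), ])
  expect_identical(r1$motif, r2$motif)
  expect_identical(r1$rank, 1:3)
})

test_that("rank differential computes shifts and validates universes", {
  ra <- data.frame(motif = c("a", "b", "c"), rank = c(126L, 1L, 2L))
  rb <- data.frame(motif = c("a", "b", "c"), rank = c(8L, 2L, 1L))
  rd <- rank_differential(ra, rb)
  expect_identical(rd$shift[rd$motif == "a"], 118L)
  expect_identical(rd$motif[1], "a")          # sorted by shift descending
  same <- rank_differential(ra, ra)
  expect_true(all(same$shift == 0L))
  expect_error(rank_differential(ra, rb[-1, ]), "missing from B: a")
})

test_that("motif files round-trip consensus and matrix definitions", {
  pm <- matrix(c(.7, .1, .1, .1,
                 .1, .7, .1, .1), 4, 2)
  ms <- list(motif("ebox", "CAGCTG"),
             motif("pwm1", matrix = pm, threshold = 1.5))
  f <- withr::local_tempfile(fileext = ".txt")
  write_motifs(ms, f)
  back <- read_motifs(f)
  expect_identical(back$ebox$consensus, "CAGCTG")
  expect_equal(back$pwm1$matrix, ms[[2]]$matrix, tolerance = 1e-12)
  expect_identical(back$pwm1$threshold, 1.5)
  f2 <- withr::local_tempfile()
  write_motifs(back, f2)
  expect_identical(readLines(f), readLines(f2))
})
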