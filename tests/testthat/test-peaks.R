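test_that("overlap_length handles abutment, containment and chromosomes", {
  iv <- function(c, s, e) peak_set(c, s, e)
  expect_identical(overlap_length(iv("chr1", 0, 100), iv("chr1", 40, 100)), 60L)
  expect_identical(overlap_length(iv("chr1", 0, 100), iv("chr1", 100, 200)), 0L)
  expect_identical(overlap_length(iv("chr1", 0, 100), iv("chr2", 0, 100)), 0L)
  expect_identical(overlap_length(iv("chr1", 0, 200), iv("chr1", 140, 160)), 20L)
})

test_that("fractional-overlap rule: strict inequality, either-peak reading", {
  iv <- function(c, s, e) peak_set(c, s, e)
  expect_true(peaks_overlap(iv("chr1", 0, 100), iv("chr1", 40, 100)))   # 60 > 50
  expect_false(peaks_overlap(iv("chr1", 0, 100), iv("chr1", 90, 200)))  # 10 <= 50, 55
  # small peak engulfed: qualifies through its own length under "either"
  expect_true(peaks_overlap(iv("chr1", 0, 200), iv("chr1", 140, 160)))
  expect_false(peaks_overlap(iv("chr1", 0, 200), iv("chr1", 140, 160),
                             mode = "both"))
  # exactly half is not enough (strict >)
  expect_false(peaks_overlap(iv("chr1", 0, 100), iv("chr1", 50, 150)))
  expect_error(peaks_overlap(iv("chr1", 0, 100), iv("chr1", 0, 100),
                             min_frac = 1.5), "min_frac")
  expect_error(peaks_overlap(iv("chr1", 0, 100), iv("chr1", 0, 100),
                             min_frac = 0), "min_frac")
})

test_that("peaks_overlap is symmetric in its arguments", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_interval_set(1, "a"); b <- random_interval_set(1, "b")
    expect_identical(peaks_overlap(a, b), peaks_overlap(b, a))
    expect_identical(peaks_overlap(a, b, mode = "both"),
                     peaks_overlap(b, a, mode = "both"))
  }
})

test_that("partition_peaks covers the degenerate and forced cases", {
  a <- peak_set("chr1", 0, 100, label = "A")
  b <- peak_set("chr1", 40, 100, label = "B")
  p <- partition_peaks(a, b)
  expect_identical(nrow(p$shared_a), 1L)
  expect_identical(nrow(p$shared_b), 1L)
  expect_identical(nrow(p$unique_a), 0L)
  expect_identical(nrow(p$unique_b), 0L)
  empty <- peak_set(character(0), integer(0), integer(0), label = "B")
  p2 <- partition_peaks(a, empty)
  expect_identical(p2$unique_a$name, a$name)
  expect_identical(nrow(p2$shared_a) + nrow(p2$shared_b) + nrow(p2$unique_b),
                   0L)
})

test_that("partition matches the all-pairs brute-force oracle", {
  set.seed(7)
  for (rep in 1:20) {
    a <- random_interval_set(120, "a")
    b <- random_interval_set(150, "b")
    p <- partition_peaks(a, b)
    o <- brute_partition_counts(a, b)
    expect_setequal_chr(p$shared_a$name, o$shared_a)
    expect_setequal_chr(p$unique_a$name, o$unique_a)
    expect_setequal_chr(p$shared_b$name, o$shared_b)
    expect_setequal_chr(p$unique_b$name, o$unique_b)
    # unique + shared reconstitute each input set
    expect_identical(nrow(p$unique_a) + nrow(p$shared_a), nrow(a))
    expect_identical(nrow(p$unique_b) + nrow(p$shared_b), nrow(b))
  }
})

test_that("partition output order is deterministic (chrom, start, end)", {
  set.seed(11)
  a <- random_interval_set(60, "a"); b <- random_interval_set(60, "b")
  p1 <- partition_peaks(a, b)
  shuf <- a[sample(nrow(a)), ]
  attr(shuf, "label") <- "A"; class(shuf) <- class(a)
  p2 <- partition_peaks(shuf, b)
  expect_identical(p1$shared_a$name, p2$shared_a$name)
  expect_identical(p1$unique_a$start, p2$unique_a$start)
})

test_that("multiway membership is reflexive and matches the oracle", {
  s1 <- peak_set("chr1", c(0, 1000), c(200, 1200), name = c("p1", "p2"),
                 label = "s1")
  s2 <- peak_set("chr1", 20, 220, name = "q1", label = "s2")
  s3 <- peak_set("chr1", 5000, 5200, name = "r1", label = "s3")
  m <- peak_membership(list(s1 = s1, s2 = s2, s3 = s3))
  p1 <- m[m$name == "p1", ]
  expect_true(p1$s1 && p1$s2 && !p1$s3)
  p2 <- m[m$name == "p2", ]
  expect_true(p2$s1 && !p2$s2 && !p2$s3)
  expect_true(all(m[m$set == "s3", "s3"]))
  expect_error(peak_membership(list(s1)), "at least 2")

  set.seed(11)
  sets <- list(x = random_interval_set(80, "x"),
               y = random_interval_set(90, "y"),
               z = random_interval_set(70, "z"))
  mm <- peak_membership(sets)
  for (nm in names(sets)) {
    sub <- mm[mm$set == nm, ]
    rows <- sets[[nm]][match(sub$name, sets[[nm]]$name), ]
    for (other in setdiff(names(sets), nm)) {
      expect_identical(unname(sub[[other]]),
                       unname(brute_hit_any(rows, sets[[other]])),
                       info = paste(nm, "vs", other))
    }
    expect_true(all(sub[[nm]]))
  }
})

test_that("center_window uses summit or midpoint and clips at ends", {
  p <- peak_set("chr1", 100, 200)
  w <- center_window(p, 50, c(chr1 = 1e6))
  expect_identical(c(w$start, w$end), c(100L, 200L))
  edge <- center_window(peak_set("chr1", 0, 10), 50, c(chr1 = 1e6))
  expect_identical(c(edge$start, edge$end), c(0L, 55L))
  ps <- peak_set("chr1", 100, 200, summit = 10)
  ws <- center_window(ps, 50, c(chr1 = 1e6))
  expect_identical(c(ws$start, ws$end), c(60L, 160L))
  expect_error(center_window(p, 50, c(chr1 = 0)), "chrom_length")
  expect_error(center_window(p, 0, c(chr1 = 1e6)), "flank")
  # never wider than 2*flank
  set.seed(3)
  r <- random_interval_set(200, "r", L = 2000)
  wr <- center_window(r, 50, 2000)
  expect_true(all(wr$end - wr$start <= 100))
})

test_that("peak_set validation rejects malformed intervals", {
  expect_error(peak_set("chr1", 10, 10), "start >= end")
  expect_error(peak_set("chr1", -5, 10), "negative")
  expect_error(peak_set("chr1", 0, 100, summit = 100), "summit")
  expect_error(peak_set("chr1", 0, 100, strand = "x"), "strand")
})

test_that("BED6 and narrowPeak files round-trip byte-identically", {
  p <- peak_set("chr2", c(100, 5000), c(420, 5600), name = c("pk1", "pk2"),
                score = c(17, 940), strand = c(".", "+"),
                summit = c(42L, NA), label = "demo")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(p, bed)
  p2 <- read_bed(bed)
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(p2, bed2)
  expect_identical(readLines(bed), readLines(bed2))
  expect_identical(p2$start, p$start)
  expect_identical(p2$name, p$name)

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(p, np)
  q <- read_narrowpeak(np)
  np2 <- withr::local_tempfile(fileext = ".narrowPeak")
  write_narrowpeak(q, np2)
  expect_identical(readLines(np), readLines(np2))
  expect_identical(q$summit, p$summit)   # -1 decoded back to NA
  expect_error(read_bed(np), "expected 6")
  expect_error(read_narrowpeak(bed), "expected 10")
  expect_error(read_bed(file.path(tempdir(), "nope.bed")), "not found")
})
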