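#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulated study: a miniature random genome,
#' non-overlapping gene models, two condition-structured peak sets with
#' planted shared/unique design and planted motif occurrences, and a
#' negative-binomial count matrix with planted size factors, planted
#' activated/repressed genes (each coupled to a condition-unique peak
#' within linking distance of its TSS), and planted signature-positive
#' samples. Defaults describe the study conditions the generator emulates;
#' see the methods vignette for the rationale behind each value.
#'
#' @param seed integer master seed; each artifact kind (genome, genes,
#'   peaks, motif planting, expression, signature) draws from its own
#'   stream derived from it.
#' @param n_chroms,chrom_length genome shape (default 2 x 500 kb).
#' @param n_genes number of genes (default 200).
#' @param gene_length min/max transcript length in bp.
#' @param exons_per_gene min/max exon count per gene.
#' @param conditions two condition labels.
#' @param n_shared_peaks loci accessible in both conditions (default 100).
#' @param n_unique_peaks per-condition unique peak counts (length 2).
#' @param peak_width min/max peak width in bp (default 200-600).
#' @param planted_motif IUPAC consensus written into carrier peak windows
#'   (default the E-box `CAGCTG`).
#' @param n_decoy_motifs unplanted random consensus motifs forming the
#'   rest of the motif universe.
#' @param decoy_width min/max decoy motif width.
#' @param carrier_rate per-condition motif carrier probability for
#'   condition-unique peaks (length 2, aligned with `conditions`).
#' @param carrier_rate_shared carrier probability for shared loci.
#' @param n_activated,n_repressed planted regulated gene counts; each
#'   activated gene receives a peak unique to the second condition within
#'   `max_link_dist` of its TSS, each repressed gene a peak unique to the
#'   first.
#' @param planted_log2fc planted fold-change magnitude (default 2).
#' @param log2fc_mode how the emitted fold-change table is produced:
#'   `"noisy"` (planted value + Gaussian observation noise, the default),
#'   `"planted"` (exact planted values), or `"estimated"` (recomputed
#'   from the simulated counts with [log2_fold_change()]).
#' @param log2fc_noise_sd observation noise sd for `"noisy"` (default
#'   0.25).
#' @param n_samples per-condition sample counts (length 2, default 3+3).
#' @param nb_mean min/max per-gene base mean (log-uniform draw).
#' @param nb_dispersion NB dispersion alpha; variance = mean +
#'   alpha * mean^2 (default 0.05).
#' @param size_factors per-sample true size factors (recycled; default all
#'   1).
#' @param signature_size planted signature gene count (default 50; drawn
#'   from unregulated genes).
#' @param signature_frac_positive fraction of samples that are
#'   signature-positive (default 0.5).
#' @param signature_shift_sd planted shift on signature genes in
#'   positive samples, in units of the gene's cross-sample log2 sd
#'   (default 1.5).
#' @param max_link_dist peak-to-gene linking distance the design respects
#'   (default 50000).
#' @param flank motif window half-width used when planting (default 50).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 500000,
                       n_genes = 200, gene_length = c(1000, 3000),
                       exons_per_gene = c(2, 4),
                       conditions = c("condA", "condB"),
                       n_shared_peaks = 100, n_unique_peaks = c(50, 50),
                       peak_width = c(200, 600),
                       planted_motif = "CAGCTG", n_decoy_motifs = 14,
                       decoy_width = c(6, 8),
                       carrier_rate = c(0.05, 0.6),
                       carrier_rate_shared = 0.05,
                       n_activated = 10, n_repressed = 10,
                       planted_log2fc = 2,
                       log2fc_mode = "noisy", log2fc_noise_sd = 0.25,
                       n_samples = c(3, 3),
                       nb_mean = c(20, 2000), nb_dispersion = 0.05,
                       size_factors = 1,
                       signature_size = 50, signature_frac_positive = 0.5,
                       signature_shift_sd = 1.5,
                       max_link_dist = 50000, flank = 50) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              exons_per_gene = as.integer(exons_per_gene),
              conditions = as.character(conditions),
              n_shared_peaks = as.integer(n_shared_peaks),
              n_unique_peaks = as.integer(n_unique_peaks),
              peak_width = as.integer(peak_width),
              planted_motif = toupper(planted_motif),
              n_decoy_motifs = as.integer(n_decoy_motifs),
              decoy_width = as.integer(decoy_width),
              carrier_rate = as.numeric(carrier_rate),
              carrier_rate_shared = as.numeric(carrier_rate_shared),
              n_activated = as.integer(n_activated),
              n_repressed = as.integer(n_repressed),
              planted_log2fc = as.numeric(planted_log2fc),
              log2fc_mode = match.arg(log2fc_mode,
                                      c("noisy", "planted", "estimated")),
              log2fc_noise_sd = as.numeric(log2fc_noise_sd),
              n_samples = as.integer(n_samples),
              nb_mean = as.numeric(nb_mean),
              nb_dispersion = as.numeric(nb_dispersion),
              size_factors = as.numeric(size_factors),
              signature_size = as.integer(signature_size),
              signature_frac_positive = as.numeric(signature_frac_positive),
              signature_shift_sd = as.numeric(signature_shift_sd),
              max_link_dist = as.integer(max_link_dist),
              flank = as.integer(flank))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (length(conditions) != 2L || anyDuplicated(conditions))
      stop_usage("exactly two distinct condition labels are required")
    if (length(n_unique_peaks) != 2L || length(carrier_rate) != 2L ||
        length(n_samples) != 2L)
      stop_usage("n_unique_peaks, carrier_rate and n_samples need one value per condition")
    rates <- c(carrier_rate, carrier_rate_shared, signature_frac_positive)
    if (any(rates < 0 | rates > 1))
      stop_usage("probabilities must lie in [0, 1]")
    counts <- c(n_chroms, chrom_length, n_genes, n_shared_peaks,
                n_unique_peaks, n_decoy_motifs, n_activated, n_repressed,
                n_samples, signature_size, max_link_dist, flank)
    if (any(counts < 0)) stop_usage("counts must be >= 0")
    if (n_chroms < 1 || chrom_length < 1000)
      stop_usage("need at least one chromosome of >= 1 kb")
    if (n_activated + n_repressed > n_genes)
      stop_usage("more regulated genes than genes")
    if (any(n_unique_peaks < c(n_repressed, n_activated)))
      stop_usage("n_unique_peaks must cover the regulated-gene design ",
                 "(lost peaks for repressed genes come from condition 1, ",
                 "gained peaks from condition 2)")
    if (nb_dispersion < 0) stop_usage("nb_dispersion must be >= 0")
    if (any(size_factors <= 0)) stop_usage("size factors must be positive")
  })
  invisible(cfg)
}

# one deterministic RNG stream per artifact kind (seed arithmetic kept
# inside 32-bit integer range)
sim_stream <- function(cfg, kind) {
  offset <- match(kind, c("genome", "genes", "classes", "peaks",
                          "planting", "decoys", "expression", "signature"))
  set.seed(as.integer((as.numeric(cfg$seed) * 8 + offset - 1) %%
                      2147483647))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config (seed %d): %d x %d bp genome, %d genes, ",
                     "%d shared + %d/%d unique peaks, %d+%d samples\n"),
              x$seed, x$n_chroms, x$chrom_length, x$n_genes,
              x$n_shared_peaks, x$n_unique_peaks[1], x$n_unique_peaks[2],
              x$n_samples[1], x$n_samples[2]))
  invisible(x)
}

#' @name sim-config-io
#' @title Read and write generator configurations
#' @description Flat `key = value` text files; vector values are
#'   comma-joined. Round-trips are lossless.
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `read_sim_config()` returns a `sim_config`; the writer returns
#'   `path` invisibly.
NULL

#' @rdname sim-config-io
#' @export
write_sim_config <- function(cfg, path) {
  lines <- vapply(names(unclass(cfg)), function(k) {
    v <- cfg[[k]]
    val <- if (is.character(v)) paste(v, collapse = ",")
           else paste(fmt_num(as.numeric(v)), collapse = ",")
    paste0(k, " = ", val)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname sim-config-io
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop_data(path, " line ", bad[1], ": expected key = value")
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- strsplit(vapply(kv, `[`, character(1), 3L), ",", fixed = TRUE)
  args <- setNames(vals, keys)
  known <- names(formals(sim_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop_data(path, ": unknown config key(s): ",
              paste(unknown, collapse = ", "))
  chr_keys <- c("conditions", "planted_motif", "log2fc_mode")
  args <- lapply(setNames(keys, keys), function(k) {
    v <- trimws(args[[k]])
    if (k %in% chr_keys) v else as.numeric(v)
  })
  do.call(sim_config, args)
}

# ---- genome and gene models -------------------------------------------

random_chrom <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# place k non-overlapping spans of the given lengths uniformly in [0, L)
place_spans <- function(lengths, L) {
  k <- length(lengths)
  if (!k) return(integer(0))
  free <- L - sum(lengths)
  if (free < 0)
    stop_data("infeasible packing: ", sum(lengths), " bp of features do ",
              "not fit a ", L, " bp chromosome; increase chrom_length")
  gaps <- sort(runif(k, 0, free))
  as.integer(floor(gaps + cumsum(c(0, lengths[-k]))))
}

#' Simulate a random genome with non-overlapping gene models
#'
#' Chromosome sequences are i.i.d. uniform A/C/G/T. Genes get random
#' strand, 2-4 exons (first starting at the transcript start, last ending
#' at its end), and are packed without overlap; packing that cannot fit
#' raises an error suggesting a larger genome. Identical seeds give
#' byte-identical FASTA/GTF output.
#'
#' @param cfg a [sim_config()].
#' @param with_sequence generate chromosome sequence (set `FALSE` for
#'   coordinate-only studies; the genome element is then `NULL`).
#' @return List with `genome` (named character vector or `NULL`), `genes`
#'   (a `gene_models`), and `chrom_lengths`.
#' @export
simulate_genome <- function(cfg, with_sequence = TRUE) {
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  lens <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  genome <- NULL
  if (with_sequence) {
    sim_stream(cfg, "genome")
    genome <- setNames(vapply(lens, random_chrom, character(1)), chroms)
  }
  sim_stream(cfg, "genes")
  genes_per_chrom <- diff(floor(seq(0, cfg$n_genes, length.out =
                                      cfg$n_chroms + 1)))
  gene_rows <- list(); exon_rows <- list()
  idx <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    k <- genes_per_chrom[ci]
    if (!k) next
    glen <- sample(cfg$gene_length[1]:cfg$gene_length[2], k, replace = TRUE)
    starts <- place_spans(glen, cfg$chrom_length)
    ids <- sprintf("G%05d", idx + seq_len(k))
    idx <- idx + k
    strand <- sample(c("+", "-"), k, replace = TRUE)
    gene_rows[[ci]] <- data.frame(gene_id = ids, chrom = chroms[ci],
                                  strand = strand, start = starts,
                                  end = starts + glen,
                                  stringsAsFactors = FALSE)
    exon_rows[[ci]] <- do.call(rbind, lapply(seq_len(k), function(i) {
      nex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
      # split the span into 2*nex-1 alternating exon/intron blocks
      nblk <- 2L * nex - 1L
      w <- runif(nblk, 0.5, 1.5)
      blk <- diff(c(0, floor(cumsum(w) / sum(w) * glen[i])))
      blk <- pmax(blk, 1L)
      bounds <- cumsum(c(0, blk))
      bounds[length(bounds)] <- glen[i]
      es <- starts[i] + bounds[seq(1, nblk, by = 2)]
      ee <- starts[i] + bounds[seq(1, nblk, by = 2) + 1L]
      data.frame(gene_id = ids[i], start = as.integer(es),
                 end = as.integer(ee), stringsAsFactors = FALSE)
    }))
  }
  genes <- if (idx) gene_models(do.call(rbind, gene_rows),
                                do.call(rbind, exon_rows))
           else gene_models(data.frame(gene_id = character(0),
                                       chrom = character(0),
                                       strand = character(0),
                                       start = integer(0), end = integer(0),
                                       stringsAsFactors = FALSE))
  list(genome = genome, genes = genes, chrom_lengths = lens)
}

# ---- peaks with planted membership and motifs -------------------------

instantiate_iupac <- function(consensus) {
  codes <- strsplit(consensus, "")[[1]]
  paste(vapply(codes, function(cc) {
    opts <- setdiff(strsplit(IUPAC_CODES[[cc]], "")[[1]], "N")
    if (!length(opts)) "A" else if (length(opts) == 1L) opts
    else sample(opts, 1)
  }, character(1)), collapse = "")
}

# IUPAC compatibility: could one consensus match inside an instance of the
# other? True when some full-containment alignment has intersecting base
# sets at every position, on either strand. Such decoys would inherit the
# planted motif's enrichment and are rejected.
iupac_compatible <- function(a, b) {
  one <- function(x, y) {            # x fits inside y
    xs <- strsplit(IUPAC_CODES[strsplit(x, "")[[1]]], "")
    ys <- strsplit(IUPAC_CODES[strsplit(y, "")[[1]]], "")
    wx <- length(xs); wy <- length(ys)
    if (wx > wy) return(FALSE)
    for (off in 0:(wy - wx)) {
      ok <- all(vapply(seq_len(wx), function(i)
        length(intersect(xs[[i]], ys[[off + i]])) > 0, logical(1)))
      if (ok) return(TRUE)
    }
    FALSE
  }
  any(vapply(unique(c(b, revcomp(b))), function(bb)
    one(a, bb) || one(bb, a), logical(1)))
}

# decoys are degenerate consensuses (0-3 two-fold ambiguity codes) so the
# motif universe spans a realistic range of background occurrence rates
draw_decoys <- function(n, width_range, planted) {
  twofold <- c("R", "Y", "S", "W", "K", "M")
  out <- list()
  while (length(out) < n) {
    w <- sample(width_range[1]:width_range[2], 1)
    s <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    namb <- sample(0:min(3, w - 2L), 1)
    if (namb) s[sample(w, namb)] <- sample(twofold, namb, replace = TRUE)
    s <- paste(s, collapse = "")
    if (iupac_compatible(s, planted)) next
    out[[length(out) + 1L]] <- motif(sprintf("decoy_%02d",
                                             length(out) + 1L),
                                     consensus = s)
  }
  out
}

random_decoy_motifs <- function(cfg) {
  sim_stream(cfg, "decoys")
  draw_decoys(cfg$n_decoy_motifs, cfg$decoy_width, cfg$planted_motif)
}

#' Simulate condition-structured peak sets with planted motifs
#'
#' Places `n_shared_peaks` loci present in both condition peak sets (the
#' second condition's copy jittered by less than a quarter width, so the
#' pair passes the fractional-overlap rule) and per-condition unique
#' loci. Unique loci are coupled to the planted regulated genes: each
#' repressed gene gets a condition-1-unique ("lost") peak and each
#' activated gene a condition-2-unique ("gained") peak centered within
#' `max_link_dist` of its TSS. All distinct loci are separated by more
#' than a peak width, so the partition truth is exact by construction.
#' The planted motif is written into the genome inside carrier peaks'
#' center windows at the configured per-condition rates; carrier truth is
#' then finalised by re-scanning every window, so chance occurrences of
#' short motifs are counted into the truth table.
#'
#' @param cfg a [sim_config()].
#' @param gsim output of [simulate_genome()].
#' @param gene_truth data frame with `gene_id`, `class` (from
#'   [simulate_study()]; pass `NULL` to sample classes internally).
#' @return List with `peaks` (named list of two `peak_set`s), `genome`
#'   (with motifs planted), `motifs` (motif universe, planted first),
#'   `truth` (data frames `membership` and `carriers`).
#' @export
simulate_peaks <- function(cfg, gsim, gene_truth = NULL) {
  if (is.null(gene_truth))
    gene_truth <- assign_gene_classes(cfg, gsim$genes)
  genome <- gsim$genome
  lens <- gsim$chrom_lengths
  chroms <- names(lens)
  tss <- gene_tss(gsim$genes)
  gtab <- gsim$genes$genes
  sim_stream(cfg, "peaks")
  half_max <- cfg$peak_width[2] %/% 2L
  min_gap <- cfg$peak_width[2] + 2L * cfg$flank + 10L
  taken <- lapply(setNames(chroms, chroms), function(x) integer(0))
  draw_width <- function(n) sample(cfg$peak_width[1]:cfg$peak_width[2], n,
                                   replace = TRUE)
  accept_center <- function(ch, ctr) {
    if (ctr < half_max + cfg$flank + 1L ||
        ctr > lens[[ch]] - half_max - cfg$flank - 1L) return(FALSE)
    if (any(abs(taken[[ch]] - ctr) < min_gap)) return(FALSE)
    taken[[ch]][length(taken[[ch]]) + 1L] <<- ctr
    TRUE
  }
  place_near <- function(gene_id) {
    ch <- gtab$chrom[match(gene_id, gtab$gene_id)]
    for (i in 1:2000) {
      ctr <- tss[[gene_id]] + as.integer(round(runif(1, -0.8, 0.8) *
                                               cfg$max_link_dist))
      ctr <- min(max(ctr, half_max + cfg$flank + 1L),
                 lens[[ch]] - half_max - cfg$flank - 1L)
      if (accept_center(ch, ctr)) return(list(chrom = ch, center = ctr))
    }
    stop_data("could not place a peak near gene ", gene_id,
              "; genome too crowded, increase chrom_length")
  }
  place_anywhere <- function() {
    for (i in 1:5000) {
      ch <- sample(chroms, 1)
      ctr <- as.integer(floor(runif(1, half_max + cfg$flank + 1L,
                                    lens[[ch]] - half_max - cfg$flank)))
      if (accept_center(ch, ctr)) return(list(chrom = ch, center = ctr))
    }
    stop_data("peak design exceeds genome capacity; increase chrom_length")
  }
  loci <- list()
  add_locus <- function(where, membership, linked_gene = NA_character_) {
    w <- draw_width(1)
    loci[[length(loci) + 1L]] <<- data.frame(
      chrom = where$chrom, center = where$center, width = w,
      membership = membership, linked_gene = linked_gene,
      stringsAsFactors = FALSE)
  }
  rep_genes <- gene_truth$gene_id[gene_truth$class == "repressed"]
  act_genes <- gene_truth$gene_id[gene_truth$class == "activated"]
  for (g in rep_genes) add_locus(place_near(g), "unique1", g)
  for (g in act_genes) add_locus(place_near(g), "unique2", g)
  for (i in seq_len(cfg$n_unique_peaks[1] - length(rep_genes)))
    add_locus(place_anywhere(), "unique1")
  for (i in seq_len(cfg$n_unique_peaks[2] - length(act_genes)))
    add_locus(place_anywhere(), "unique2")
  for (i in seq_len(cfg$n_shared_peaks)) add_locus(place_anywhere(), "shared")
  loci <- do.call(rbind, loci)
  loci$locus <- sprintf("L%05d", seq_len(nrow(loci)))
  # realise per-condition intervals; shared loci jittered in condition 2.
  # jitter is capped so (a) the pair still passes the 50% overlap rule and
  # (b) a planted motif site can sit inside both copies' center windows
  jit_cap <- pmin(as.integer(0.2 * loci$width),
                  2L * cfg$flank - nchar(cfg$planted_motif) - 4L)
  jit <- ifelse(loci$membership == "shared",
                as.integer(round(runif(nrow(loci), -1, 1) * jit_cap)), 0L)
  mk_set <- function(which_cond) {
    memb <- if (which_cond == 1L) c("unique1", "shared")
            else c("unique2", "shared")
    sel <- loci$membership %in% memb
    off <- if (which_cond == 2L) jit[sel] else rep(0L, sum(sel))
    ctr <- loci$center[sel] + off
    half <- loci$width[sel] %/% 2L
    ps <- peak_set(loci$chrom[sel], ctr - half, ctr - half + loci$width[sel],
                   name = loci$locus[sel],
                   summit = half,  # summit at the design center
                   label = cfg$conditions[which_cond])
    sort_peaks(ps)
  }
  sets <- list(mk_set(1L), mk_set(2L))
  names(sets) <- cfg$conditions
  # ---- motif planting -------------------------------------------------
  motifs <- c(list(motif(paste0("planted_", cfg$planted_motif),
                         consensus = cfg$planted_motif)),
              random_decoy_motifs(cfg))
  sim_stream(cfg, "planting")
  mw <- nchar(cfg$planted_motif)
  rate <- ifelse(loci$membership == "shared", cfg$carrier_rate_shared,
                 ifelse(loci$membership == "unique1", cfg$carrier_rate[1],
                        cfg$carrier_rate[2]))
  plant <- runif(nrow(loci)) < rate
  if (!is.null(genome) && any(plant)) {
    for (i in which(plant)) {
      # keep the site inside the center window of both condition copies
      lo <- max(-cfg$flank, -cfg$flank + jit[i])
      hi <- min(cfg$flank, cfg$flank + jit[i]) - mw
      off <- as.integer(floor(runif(1, lo, hi + 1)))
      pos <- loci$center[i] + off          # 0-based genome position
      inst <- instantiate_iupac(cfg$planted_motif)
      ch <- loci$chrom[i]
      substr(genome[[ch]], pos + 1L, pos + mw) <- inst
    }
  }
  # truth by post-scan: chance hits count as carriers too
  carriers <- NULL
  if (!is.null(genome)) {
    pm <- motifs[[1]]
    carriers <- do.call(rbind, lapply(cfg$conditions, function(cd) {
      s <- sets[[cd]]
      data.frame(condition = cd, locus = s$name,
                 carrier = peak_has_motif(s, genome, pm, cfg$flank),
                 planted = plant[match(s$name, loci$locus)],
                 stringsAsFactors = FALSE)
    }))
  }
  membership <- data.frame(locus = loci$locus, chrom = loci$chrom,
                           center = loci$center, width = loci$width,
                           membership = loci$membership,
                           linked_gene = loci$linked_gene,
                           stringsAsFactors = FALSE)
  list(peaks = sets, genome = genome, motifs = motifs,
       truth = list(membership = membership, carriers = carriers))
}

assign_gene_classes <- function(cfg, genes) {
  sim_stream(cfg, "classes")
  ids <- genes$genes$gene_id
  n <- length(ids)
  cls <- rep("unchanged", n)
  pick <- sample(n, cfg$n_activated + cfg$n_repressed)
  cls[pick[seq_len(cfg$n_activated)]] <- "activated"
  if (cfg$n_repressed)
    cls[pick[cfg$n_activated + seq_len(cfg$n_repressed)]] <- "repressed"
  lfc <- ifelse(cls == "activated", cfg$planted_log2fc,
                ifelse(cls == "repressed", -cfg$planted_log2fc, 0))
  data.frame(gene_id = ids, class = cls, planted_log2fc = lfc,
             stringsAsFactors = FALSE)
}

#' Simulate a count matrix with planted structure
#'
#' Negative-binomial counts (variance = mean + alpha * mean^2) with
#' per-gene base means drawn log-uniformly, multiplied by per-sample size
#' factors; activated/repressed genes have their mean scaled by
#' `2^(+/- planted_log2fc)` in the second condition; signature genes are
#' shifted upward in signature-positive samples by
#' `signature_shift_sd` cross-sample log2 standard deviations (the log2
#' sd implied by the NB noise model, `sqrt(1/mean + alpha)/ln 2`).
#'
#' @param cfg a [sim_config()].
#' @param genes a `gene_models`.
#' @param gene_truth data frame from the class assignment (columns
#'   `gene_id`, `class`, `planted_log2fc`).
#' @return List with `counts` (an `expr_matrix`), `log2fc` (named vector
#'   per `log2fc_mode`), `truth` (list: `gene_truth` with emitted
#'   log2fc, `size_factors`, `signature_genes`, `positive_samples`,
#'   `condition` per sample).
#' @export
simulate_expression <- function(cfg, genes, gene_truth = NULL) {
  if (is.null(gene_truth)) gene_truth <- assign_gene_classes(cfg, genes)
  ids <- gene_truth$gene_id
  n <- length(ids)
  ns <- sum(cfg$n_samples)
  if (!n) stop_usage("no genes to simulate expression for")
  sample_ids <- c(sprintf("%s_s%d", cfg$conditions[1],
                          seq_len(cfg$n_samples[1])),
                  sprintf("%s_s%d", cfg$conditions[2],
                          seq_len(cfg$n_samples[2])))
  condition <- rep(cfg$conditions, cfg$n_samples)
  sf <- rep_len(cfg$size_factors, ns)
  names(sf) <- sample_ids
  # signature design first, from its own stream
  sim_stream(cfg, "signature")
  unreg <- which(gene_truth$class == "unchanged")
  sig_idx <- integer(0); pos <- integer(0)
  sig_genes <- character(0); pos_samples <- character(0)
  if (cfg$signature_size > 0) {
    if (length(unreg) < cfg$signature_size)
      stop_usage("not enough unregulated genes for the signature design")
    sig_idx <- sort(sample(unreg, cfg$signature_size))
    sig_genes <- ids[sig_idx]
    npos <- round(cfg$signature_frac_positive * ns)
    pos <- sort(sample(ns, npos))
    pos_samples <- sample_ids[pos]
  }
  sim_stream(cfg, "expression")
  base_mu <- exp(runif(n, log(cfg$nb_mean[1]), log(cfg$nb_mean[2])))
  lfc <- gene_truth$planted_log2fc
  mu <- outer(base_mu, rep(1, ns))
  in_b <- condition == cfg$conditions[2]
  mu[, in_b] <- mu[, in_b] * 2^lfc
  if (length(sig_idx) && length(pos)) {
    sd_log2 <- sqrt(1 / base_mu[sig_idx] + cfg$nb_dispersion) / log(2)
    mu[sig_idx, pos] <- mu[sig_idx, pos] *
      2^(cfg$signature_shift_sd * sd_log2)
  }
  mu <- sweep(mu, 2, sf, "*")
  counts <- if (cfg$nb_dispersion > 0)
    matrix(rnbinom(n * ns, mu = mu, size = 1 / cfg$nb_dispersion), n, ns)
  else matrix(stats::rpois(n * ns, lambda = mu), n, ns)
  dimnames(counts) <- list(ids, sample_ids)
  m <- expr_matrix(counts, unit = "counts")
  lfc_out <- switch(cfg$log2fc_mode,
    planted = setNames(lfc, ids),
    noisy = setNames(lfc + rnorm(n, 0, cfg$log2fc_noise_sd), ids),
    estimated = {
      norm <- normalize_counts(m)
      log2_fold_change(norm, sample_ids[!in_b], sample_ids[in_b])
    })
  gene_truth$log2fc <- unname(lfc_out[ids])
  list(counts = m, log2fc = lfc_out,
       truth = list(gene_truth = gene_truth, size_factors = sf,
                    signature_genes = sig_genes,
                    positive_samples = pos_samples,
                    condition = setNames(condition, sample_ids)))
}

#' Simulate a complete miniature study
#'
#' Orchestrates [simulate_genome()], gene-class assignment,
#' [simulate_peaks()] and [simulate_expression()] into one seeded study
#' whose every planted quantity is recorded in machine-readable truth
#' tables, so that each downstream operation can be checked against
#' ground truth without external files.
#'
#' @param cfg a [sim_config()].
#' @param with_sequence generate and mutate genome sequence (needed for
#'   motif operations; set `FALSE` for coordinate/expression-only
#'   studies).
#' @return A `chromlink_sim` list: `genome`, `chrom_lengths`, `genes`,
#'   `peaks` (two `peak_set`s), `motifs`, `counts`, `log2fc`, `truth`
#'   (membership, carriers, gene_truth, size_factors, signature), `cfg`.
#' @export
simulate_study <- function(cfg = sim_config(), with_sequence = TRUE) {
  gsim <- simulate_genome(cfg, with_sequence)
  gene_truth <- assign_gene_classes(cfg, gsim$genes)
  psim <- simulate_peaks(cfg, gsim, gene_truth)
  esim <- simulate_expression(cfg, gsim$genes, gene_truth)
  out <- list(genome = psim$genome, chrom_lengths = gsim$chrom_lengths,
              genes = gsim$genes, peaks = psim$peaks, motifs = psim$motifs,
              counts = esim$counts, log2fc = esim$log2fc,
              truth = c(psim$truth, esim$truth), cfg = cfg)
  class(out) <- "chromlink_sim"
  out
}

#' @export
print.chromlink_sim <- function(x, ...) {
  cat(sprintf(paste0("chromlink_sim (seed %d): %d genes, peak sets [%s], ",
                     "%d x %d counts\n"), x$cfg$seed, nrow(x$genes$genes),
              paste(sprintf("%s: %d", names(x$peaks),
                            vapply(x$peaks, nrow, integer(1))),
                    collapse = ", "),
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits FASTA (when sequence was generated), GTF, one narrowPeak per
#' condition, counts and log2fc TSVs, the motif universe, all truth
#' tables, and the configuration. All files are plain text and
#' reproducible byte for byte from the same configuration.
#'
#' @param sim a `chromlink_sim` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  if (!is.null(sim$genome)) write_genome(sim$genome, p("genome.fa"))
  write_gtf(sim$genes, p("genes.gtf"))
  for (cd in names(sim$peaks))
    write_narrowpeak(sim$peaks[[cd]], p(sprintf("peaks_%s.narrowPeak", cd)))
  write_motifs(sim$motifs, p("motifs.txt"))
  write_expr_matrix(sim$counts, p("counts.tsv"))
  write_log2fc(sim$log2fc, p("log2fc.tsv"))
  tr <- sim$truth
  wtsv <- function(df, path) write.table(df, path, sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  wtsv(tr$membership, p("truth_membership.tsv"))
  if (!is.null(tr$carriers)) wtsv(tr$carriers, p("truth_carriers.tsv"))
  wtsv(tr$gene_truth, p("truth_genes.tsv"))
  wtsv(data.frame(sample_id = names(tr$size_factors),
                  size_factor = unname(tr$size_factors),
                  condition = unname(tr$condition),
                  signature_positive = names(tr$size_factors) %in%
                    tr$positive_samples), p("truth_samples.tsv"))
  writeLines(tr$signature_genes, p("truth_signature_genes.txt"))
  write_sim_config(sim$cfg, p("config.txt"))
  invisible(dir)
}

#' Simulate a focused motif-enrichment experiment
#'
#' A single-chromosome genome tiled with fixed-width peaks split into one
#' background set and one or more target sets, with the planted motif
#' written into each peak's center window with the per-set carrier
#' probability. Decoy motifs complete the universe. Carrier truth is
#' finalised by post-scanning, so background chance hits are part of the
#' truth.
#'
#' @param targets named list; each element `list(n = , rate = )` gives a
#'   target set's peak count and planted carrier rate.
#' @param n_background,rate_background background set size and rate.
#' @param planted_motif IUPAC consensus (default `CAGCTG`).
#' @param n_decoys decoy motif count (default 14).
#' @param peak_width,flank peak geometry (defaults 200 bp, +/- 50 bp).
#' @param seed integer seed.
#' @return List with `genome`, `targets` (named list of `peak_set`s),
#'   `background` (`peak_set`), `motifs` (planted first), `truth`
#'   (per-peak carrier flags).
#' @export
simulate_motif_experiment <- function(targets = list(target = list(n = 200,
                                                                   rate = 0.6)),
                                      n_background = 2000,
                                      rate_background = 0.05,
                                      planted_motif = "CAGCTG",
                                      n_decoys = 14, peak_width = 200,
                                      flank = 50, seed = 1) {
  stopifnot(length(targets) >= 1, n_background >= 1)
  set.seed(seed)
  ns <- vapply(targets, function(t) t$n, numeric(1))
  rates <- vapply(targets, function(t) t$rate, numeric(1))
  ntot <- sum(ns) + n_background
  pitch <- peak_width + 2L * flank + 50L
  L <- ntot * pitch + pitch
  genome <- c(chr1 = random_chrom(L))
  centers <- pitch %/% 2L + pitch * (seq_len(ntot) - 1L) + flank
  grp <- rep(c(names(targets), ".bg"), c(ns, n_background))
  grp <- sample(grp)                       # interleave sets along the chrom
  rate <- c(setNames(rates, names(targets)), ".bg" = rate_background)[grp]
  mw <- nchar(planted_motif)
  plant <- runif(ntot) < rate
  for (i in which(plant)) {
    off <- as.integer(floor(runif(1, -flank, flank - mw + 1)))
    pos <- centers[i] + off
    substr(genome[["chr1"]], pos + 1L, pos + mw) <-
      instantiate_iupac(planted_motif)
  }
  half <- peak_width %/% 2L
  all_peaks <- peak_set("chr1", centers - half, centers - half + peak_width,
                        name = sprintf("w%05d", seq_len(ntot)),
                        summit = half, label = "windows")
  motifs <- c(list(motif(paste0("planted_", planted_motif),
                         consensus = planted_motif)),
              draw_decoys(n_decoys, c(6, 8), planted_motif))
  carrier <- peak_has_motif(all_peaks, genome, motifs[[1]], flank)
  tgt <- lapply(setNames(names(targets), names(targets)), function(nm)
    as_peak_subset(all_peaks, grp == nm, nm))
  list(genome = genome,
       targets = tgt,
       background = as_peak_subset(all_peaks, grp == ".bg", "background"),
       motifs = motifs,
       truth = data.frame(name = all_peaks$name, set = grp,
                          planted = plant, carrier = carrier,
                          stringsAsFactors = FALSE))
}
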