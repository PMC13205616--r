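# Synthetic planted-motif benchmark data.
#
# Labels follow an AND grammar over a motif pair: positives carry one motif
# in each anchor, negatives are background or single-motif sequences.  The
# co-occurrence requirement forces a classifier to combine information
# across the two anchors, which is exactly what a chromatin pair classifier
# must do; single-motif negatives make an OR detector insufficient.

#' Configuration for the synthetic pair generator
#'
#' Defaults describe the benchmark condition used throughout the package:
#' 2000 pairs of 500 bp anchors, one planted motif pair, full insertion,
#' 2\% label noise.
#'
#' @param n_pairs number of labelled pairs.
#' @param anchor_len length of each anchor sequence (bp).
#' @param motif_pairs list of `c(motif_a, motif_b)` character pairs over
#'   A/C/G/T; positives carry both members of one sampled pair.
#' @param insertion_rate probability that a positive pair actually receives
#'   its motifs (1 = always).
#' @param positional_mean,positional_sd Gaussian placement of `motif_b`
#'   relative to the anchor-B start (a TSS proxy), emulating the enrichment
#'   of regulatory motifs a few hundred bp downstream of the TSS;
#'   `motif_a` is placed uniformly in anchor A.
#' @param background_gc GC fraction of background sequence.
#' @param neg_mix length-3 numeric (background, motif-A-only,
#'   motif-B-only) mixing proportions for negatives.
#' @param label_noise probability that a recorded label is flipped.
#' @param seed master seed; per-record seeds are derived from it and
#'   recorded in the manifest.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_pairs = 2000L, anchor_len = 500L,
                         motif_pairs = list(c("TGACGTCA", "CACGTGGC")),
                         insertion_rate = 1,
                         positional_mean = 250, positional_sd = 40,
                         background_gc = 0.5,
                         neg_mix = c(1, 1, 1) / 3,
                         label_noise = 0.02, seed = 1L) {
  stopifnot(insertion_rate >= 0, insertion_rate <= 1,
            label_noise >= 0, label_noise <= 1,
            background_gc > 0, background_gc < 1,
            length(neg_mix) == 3, all(neg_mix >= 0))
  if (!is.list(motif_pairs)) motif_pairs <- list(motif_pairs)
  for (mp in motif_pairs) {
    if (length(mp) != 2 || !all(strsplit(paste(mp, collapse = ""),
                                         "")[[1]] %in% c("A", "C", "G", "T")))
      stop("motif_pairs must be pairs of A/C/G/T strings", call. = FALSE)
    if (any(nchar(mp) > anchor_len))
      stop("motif longer than anchor_len", call. = FALSE)
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 anchor_len = as.integer(anchor_len),
                 motif_pairs = motif_pairs,
                 insertion_rate = insertion_rate,
                 positional_mean = positional_mean,
                 positional_sd = positional_sd,
                 background_gc = background_gc,
                 neg_mix = neg_mix / sum(neg_mix),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synth_config")
}

random_background <- function(n, gc) {
  at <- (1 - gc) / 2
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c(at, gc / 2, gc / 2, at))
}

plant_motif <- function(chars, motif, pos0) {
  m <- strsplit(motif, "")[[1]]
  chars[(pos0 + 1):(pos0 + length(m))] <- m
  chars
}

#' Generate labelled synthetic interaction pairs
#'
#' Positives contain both motifs of a sampled motif pair, one per anchor
#' (motif A uniformly placed, motif B with the configured positional bias);
#' negatives are background or single-motif sequences per `neg_mix`.  The
#' returned manifest records the exact planted motifs and their 0-based
#' positions, sufficient to score motif-recovery of the attribution module.
#'
#' @param config a [synth_config()].
#' @return list with `x` (an `(n, 2*anchor_len, 4)` one-hot array, anchor A
#'   columns first), `labels` (possibly noise-flipped), `seq_a`, `seq_b`
#'   (character vectors), and `manifest` (data frame with `pair_id`,
#'   `label_true`, `label`, `motif_a`, `pos_a`, `motif_b`, `pos_b`,
#'   `record_seed`).
#' @export
generate_pairs <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  L <- config$anchor_len
  rec_seed <- sample.int(.Machine$integer.max - 1L, n)
  label_true <- stats::rbinom(n, 1, 0.5)
  flip <- stats::runif(n) < config$label_noise
  neg_kind <- sample(c("bg", "a_only", "b_only"), n, replace = TRUE,
                     prob = config$neg_mix)
  mp_idx <- sample.int(length(config$motif_pairs), n, replace = TRUE)

  enc <- c(A = 1L, T = 2L, G = 3L, C = 4L)  # channel order A,T,G,C
  x <- array(0, c(n, 2L * L, 4L))
  seq_a <- character(n); seq_b <- character(n)
  motif_a <- character(n); motif_b <- character(n)
  pos_a <- rep(NA_integer_, n); pos_b <- rep(NA_integer_, n)

  draw_pos_a <- function(mlen) sample.int(L - mlen + 1L, 1L) - 1L
  draw_pos_b <- function(mlen) {
    p <- round(stats::rnorm(1, config$positional_mean, config$positional_sd))
    max(0L, min(L - mlen, as.integer(p)))
  }

  for (i in seq_len(n)) {
    set.seed(rec_seed[i])
    a <- random_background(L, config$background_gc)
    b <- random_background(L, config$background_gc)
    mp <- config$motif_pairs[[mp_idx[i]]]
    want_a <- FALSE; want_b <- FALSE
    if (label_true[i] == 1) {
      if (stats::runif(1) < config$insertion_rate) {
        want_a <- TRUE; want_b <- TRUE
      }
    } else {
      want_a <- neg_kind[i] == "a_only"
      want_b <- neg_kind[i] == "b_only"
    }
    if (want_a) {
      pos_a[i] <- draw_pos_a(nchar(mp[1]))
      a <- plant_motif(a, mp[1], pos_a[i])
      motif_a[i] <- mp[1]
    }
    if (want_b) {
      pos_b[i] <- draw_pos_b(nchar(mp[2]))
      b <- plant_motif(b, mp[2], pos_b[i])
      motif_b[i] <- mp[2]
    }
    seq_a[i] <- paste(a, collapse = "")
    seq_b[i] <- paste(b, collapse = "")
    s <- c(a, b)
    x[cbind(i, seq_along(s), enc[s])] <- 1
  }
  labels <- ifelse(flip, 1L - label_true, label_true)
  manifest <- data.frame(pair_id = seq_len(n), label_true = label_true,
                         label = labels, motif_a = motif_a, pos_a = pos_a,
                         motif_b = motif_b, pos_b = pos_b,
                         record_seed = rec_seed)
  list(x = x, labels = labels, seq_a = seq_a, seq_b = seq_b,
       manifest = manifest, config = config)
}

#' Generate a toy genome with genes and open-chromatin regions
#'
#' Writes a small multi-chromosome genome (FASTA), gene models (GFF3),
#' distal open-chromatin intervals (BED) and a JSON ground-truth manifest,
#' sized to exercise the tiling, flank-expansion and candidate-gene logic
#' of the scan module.  OCRs are placed at least `ocr_gene_gap` bp from any
#' gene so that the distal filter retains them all by construction.
#'
#' @param dir output directory (created if needed).
#' @param n_chrom,chrom_len number and length of chromosomes.
#' @param n_genes total genes (split across chromosomes); gene bodies are
#'   2-4 kb with random strand.
#' @param n_ocrs total OCRs of length `ocr_len`.
#' @param ocr_len OCR width (bp).
#' @param ocr_gene_gap minimum distance between an OCR and the nearest
#'   gene (bp).
#' @param background_gc GC fraction.
#' @param seed RNG seed.
#' @return list with file paths (`fasta`, `gff3`, `bed`, `manifest`) and
#'   in-memory objects (`genome`, `genes`, `ocrs`).
#' @export
generate_toy_genome <- function(dir = tempfile("toygenome"),
                                n_chrom = 2L, chrom_len = 100000L,
                                n_genes = 20L, n_ocrs = 10L,
                                ocr_len = 400L, ocr_gene_gap = 2500L,
                                background_gc = 0.45, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  seqs <- vapply(chroms, function(ch)
    paste(random_background(chrom_len, background_gc), collapse = ""), "")
  genome <- genome_ref(seqs)

  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  genes <- NULL
  slot_of <- function(k, n, margin) {
    # k-th of n evenly spaced slots, away from chromosome edges
    usable <- chrom_len - 2 * margin
    margin + round((k - 0.5) * usable / n)
  }
  gi <- 0L
  occupied <- vector("list", n_chrom)
  names(occupied) <- chroms
  for (ci in seq_len(n_chrom)) {
    ng <- per_chrom[ci]
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      center <- slot_of(k, ng, 6000L)
      glen <- sample(2000:4000, 1)
      start <- center - glen %/% 2
      end <- start + glen
      strand <- sample(c("+", "-"), 1)
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("gene_%03d", gi), chrom = chroms[ci],
        strand = strand, start = start, end = end,
        tss = if (strand == "+") start else end - 1L,
        tts = if (strand == "+") end - 1L else start))
      occupied[[ci]] <- rbind(occupied[[ci]], c(start, end))
    }
  }

  # OCRs in gaps, at least ocr_gene_gap from every gene
  ocrs <- NULL
  oi <- 0L
  tries <- 0L
  while (oi < n_ocrs && tries < 20000L) {
    tries <- tries + 1L
    ci <- sample.int(n_chrom, 1)
    start <- sample.int(chrom_len - ocr_len - 2L, 1)
    end <- start + ocr_len
    occ <- occupied[[ci]]
    dist_ok <- all(start >= occ[, 2] + ocr_gene_gap |
                     end <= occ[, 1] - ocr_gene_gap)
    overlap_prev <- !is.null(ocrs) &&
      any(ocrs$chrom == chroms[ci] & ocrs$start < end + 200 &
            ocrs$end > start - 200)
    if (dist_ok && !overlap_prev) {
      oi <- oi + 1L
      ocrs <- rbind(ocrs, data.frame(chrom = chroms[ci], start = start,
                                     end = end,
                                     name = sprintf("ocr_%03d", oi)))
    }
  }
  if (oi < n_ocrs)
    warning("placed only ", oi, " of ", n_ocrs, " OCRs")

  fasta <- file.path(dir, "genome.fa")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- chroms
  Biostrings::writeXStringSet(ss, fasta)

  gff3 <- file.path(dir, "genes.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  rtracklayer::export(gr, gff3, format = "gff3")

  bed <- file.path(dir, "ocrs.bed")
  ogr <- GenomicRanges::GRanges(
    seqnames = ocrs$chrom,
    ranges = IRanges::IRanges(start = ocrs$start + 1L, end = ocrs$end),
    name = ocrs$name)
  rtracklayer::export(ogr, bed, format = "bed")

  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, n_chrom = n_chrom,
                            chrom_len = chrom_len, genes = genes,
                            ocrs = ocrs),
                       manifest, auto_unbox = TRUE, digits = NA)
  list(fasta = fasta, gff3 = gff3, bed = bed, manifest = manifest,
       genome = genome, genes = genes, ocrs = ocrs, dir = dir)
}
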