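# Sequence I/O and encoding conventions.
#
# All coordinates are 0-based half-open internally.  GFF3 input (1-based
# closed) is converted on read.  One-hot row order is fixed to A,T,G,C
# throughout so attribution matrices are directly comparable across the
# package.

CTCI_BASES <- c("A", "T", "G", "C")

#' Reference genome handle
#'
#' Wraps a set of chromosome sequences with a clipping accessor.  Accepts a
#' named character vector or a [Biostrings::DNAStringSet].  Soft-masked
#' (lowercase) bases are uppercased.
#'
#' @param x named character vector of sequences, or a `DNAStringSet`.
#' @return object of class `genome_ref`.
#' @export
genome_ref <- function(x) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("genome sequences must be named by chromosome", call. = FALSE)
  x <- toupper(x)
  structure(list(seqs = x, lengths = nchar(x)), class = "genome_ref")
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return a [genome_ref()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  g <- genome_ref(ss)
  message(length(g$seqs), " sequences read from ", basename(path))
  g
}

#' @export
print.genome_ref <- function(x, ...) {
  cat("Reference genome:", length(x$seqs), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Chromosome names of a genome
#' @param genome a [genome_ref()].
#' @export
chrom_names <- function(genome) names(genome$seqs)

#' Fetch an interval from the genome
#'
#' Returns exactly `end - start` characters; parts of the request outside
#' the chromosome are filled with `N`.
#'
#' @param genome a [genome_ref()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @export
genome_sequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seqs))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  if (end <= start) stop("empty interval [", start, ",", end, ")",
                         call. = FALSE)
  L <- genome$lengths[[chrom]]
  s <- max(0, start); e <- min(L, end)
  core <- if (s < e) substr(genome$seqs[[chrom]], s + 1, e) else ""
  left <- max(0, min(end, 0) - start)        # part before the chromosome
  paste0(strrep("N", left), core,
         strrep("N", (end - start) - left - nchar(core)))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

check_strand <- function(strand) {
  if (!strand %in% c("+", "-"))
    stop("unknown strand symbol: '", strand, "'", call. = FALSE)
}

#' Extract the paired TSS/TTS gene sequence (3000 bp)
#'
#' Concatenates the 1 kb upstream + 0.5 kb downstream window around the
#' transcription start site with the 0.5 kb upstream + 1 kb downstream
#' window around the transcription termination site, in the gene's 5'->3'
#' orientation (minus-strand genes are reverse-complemented).  Out-of-bounds
#' portions are `N`-filled, so the result is always exactly 3000 bp.
#'
#' @param genome a [genome_ref()].
#' @param gene list or one-row data frame with `chrom`, `strand`, `tss`,
#'   `tts` (0-based coordinates of the first and last transcribed base).
#' @return character string of length 3000.
#' @export
extract_gene_sequence <- function(genome, gene) {
  check_strand(gene$strand)
  if (gene$strand == "+") {
    paste0(genome_sequence(genome, gene$chrom, gene$tss - 1000, gene$tss + 500),
           genome_sequence(genome, gene$chrom, gene$tts - 500, gene$tts + 1000))
  } else {
    paste0(revcomp(genome_sequence(genome, gene$chrom,
                                   gene$tss - 499, gene$tss + 1001)),
           revcomp(genome_sequence(genome, gene$chrom,
                                   gene$tts - 999, gene$tts + 501)))
  }
}

#' Extract the promoter-proximal sequence (1500 bp)
#'
#' 1 kb upstream + 0.5 kb downstream of the TSS in gene orientation; the
#' gene-side anchor of promoter-distal pairs.
#'
#' @inheritParams extract_gene_sequence
#' @return character string of length 1500.
#' @export
extract_promoter_sequence <- function(genome, gene) {
  check_strand(gene$strand)
  if (gene$strand == "+") {
    genome_sequence(genome, gene$chrom, gene$tss - 1000, gene$tss + 500)
  } else {
    revcomp(genome_sequence(genome, gene$chrom,
                            gene$tss - 499, gene$tss + 1001))
  }
}

#' Normalise a distal-element sequence to a fixed length
#'
#' Sequences shorter than `target_len` are `N`-padded equally at both ends
#' (odd deficit: the extra `N` goes on the right); longer sequences keep the
#' central `target_len` window (odd excess: the window sits one base to the
#' left of centre).
#'
#' @param seq A/C/G/T/N string.
#' @param target_len output length (default 1500).
#' @export
normalize_distal_sequence <- function(seq, target_len = 1500L) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0)
    stop("seq must be a single non-empty string", call. = FALSE)
  n <- nchar(seq)
  if (n == target_len) return(seq)
  if (n < target_len) {
    d <- target_len - n
    left <- d %/% 2
    paste0(strrep("N", left), seq, strrep("N", d - left))
  } else {
    start <- (n - target_len) %/% 2
    substr(seq, start + 1, start + target_len)
  }
}

#' One-hot encode a DNA sequence
#'
#' Row order A, T, G, C; `N` (and padding) becomes an all-zero column.
#' Case-insensitive; any other character is an error naming its position.
#'
#' @param seq A/C/G/T/N string.
#' @return 4 x nchar(seq) numeric matrix with rownames A,T,G,C.
#' @export
one_hot_encode <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, c(CTCI_BASES, "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("invalid character '", ch[bad], "' at position ", bad, call. = FALSE)
  }
  m <- matrix(0, 4, length(ch), dimnames = list(CTCI_BASES, NULL))
  hit <- idx <= 4
  m[cbind(idx[hit], which(hit))] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' All-zero columns decode to `N`.
#'
#' @param m 4 x L matrix with rows in A,T,G,C order.
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 4)
  out <- rep("N", ncol(m))
  nz <- colSums(m) > 0
  out[nz] <- CTCI_BASES[apply(m[, nz, drop = FALSE], 2, which.max)]
  paste(out, collapse = "")
}

#' Encode paired anchor sequences into a model input array
#'
#' One-hot encodes each `(seq_a[i], seq_b[i])` pair with anchor A's columns
#' first, returning the `(n, L, 4)` array accepted by [ctci_fit()] and
#' [predict.ctci_fit()].
#'
#' @param seq_a,seq_b equal-length character vectors of anchor sequences;
#'   within a vector all sequences must have the same width.
#' @return numeric array `(n, nchar(seq_a) + nchar(seq_b), 4)`, channels
#'   in A,T,G,C order.
#' @export
encode_sequence_pairs <- function(seq_a, seq_b) {
  stopifnot(length(seq_a) == length(seq_b), length(seq_a) >= 1)
  la <- unique(nchar(seq_a)); lb <- unique(nchar(seq_b))
  if (length(la) != 1 || length(lb) != 1)
    stop("all anchor sequences must have equal width", call. = FALSE)
  n <- length(seq_a)
  x <- array(0, c(n, la + lb, 4L))
  for (i in seq_len(n)) {
    x[i, , ] <- t(cbind(one_hot_encode(seq_a[i]), one_hot_encode(seq_b[i])))
  }
  x
}

# ---- interaction pairs -------------------------------------------------

#' Construct an interaction pair
#'
#' The training/prediction unit: two genomic anchors plus a mode and an
#' optional 0/1 label.  Promoter-promoter (PPI) pairs have two gene
#' anchors; promoter-distal (PDI) pairs have an interval (distal element)
#' as `anchor_a` and a gene as `anchor_b`.
#'
#' @param anchor_a for PDI: list with `chrom`, `start`, `end` (0-based
#'   half-open); for PPI: a gene (as in [extract_gene_sequence()]).
#' @param anchor_b a gene.
#' @param mode `"PPI"` or `"PDI"`.
#' @param label 0, 1 or `NA` (unknown).
#' @param name optional identifier.
#' @export
interaction_pair <- function(anchor_a, anchor_b, mode = c("PPI", "PDI"),
                             label = NA, name = NULL) {
  mode <- match.arg(mode)
  if (mode == "PDI" && is.null(anchor_a$start))
    stop("PDI anchor_a must be an interval (chrom/start/end)", call. = FALSE)
  if (mode == "PPI" && is.null(anchor_a$tss))
    stop("PPI anchors must both be genes", call. = FALSE)
  if (is.null(anchor_b$tss))
    stop("anchor_b must be a gene", call. = FALSE)
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b, mode = mode,
                 label = label, name = name),
            class = "ctci_pair")
}

#' @export
print.ctci_pair <- function(x, ...) {
  a <- if (x$mode == "PDI")
    sprintf("%s:%d-%d", x$anchor_a$chrom, x$anchor_a$start, x$anchor_a$end)
  else x$anchor_a$gene_id
  cat(sprintf("%s pair  [%s] ~ [%s]  label: %s\n", x$mode, a,
              x$anchor_b$gene_id, ifelse(is.na(x$label), "unknown",
                                         x$label)))
  invisible(x)
}

#' Encode an interaction pair into a model-ready one-hot matrix
#'
#' PDI pairs become 4 x 3000 (distal 1500 columns first, then promoter
#' 1500); PPI pairs become 4 x 6000 (gene A's 3000 columns first, then gene
#' B's).
#'
#' @param pair an [interaction_pair()].
#' @param genome a [genome_ref()].
#' @return object of class `ctci_encoded`: list with `matrix` (4 x L) and
#'   `pair` (provenance).
#' @export
encode_pair <- function(pair, genome) {
  stopifnot(inherits(pair, "ctci_pair"))
  if (pair$mode == "PDI") {
    distal <- genome_sequence(genome, pair$anchor_a$chrom,
                              pair$anchor_a$start, pair$anchor_a$end)
    seq <- paste0(normalize_distal_sequence(distal, 1500L),
                  extract_promoter_sequence(genome, pair$anchor_b))
  } else {
    seq <- paste0(extract_gene_sequence(genome, pair$anchor_a),
                  extract_gene_sequence(genome, pair$anchor_b))
  }
  structure(list(matrix = one_hot_encode(seq), pair = pair),
            class = "ctci_encoded")
}

# ---- pair files --------------------------------------------------------

#' Read interaction pairs from a tab-delimited file
#'
#' Two layouts are recognised by column count: a BEDPE-like anchor-pair
#' table (`chromA startA endA chromB startB endB name [label]`, coordinates
#' 0-based half-open, read as PDI with anchor B's interval midpoint used as
#' TSS proxy when `genes` is not supplied) and a gene-pair table
#' (`geneA geneB [label]`), read as PPI.  A missing label column yields
#' `NA` (unknown) labels.
#'
#' @param path input file.
#' @param genes optional gene annotation (data frame from [read_genes()])
#'   used to resolve gene identifiers to coordinates.
#' @param mode force `"PPI"` or `"PDI"`; default inferred from the layout.
#' @return list of [interaction_pair()] objects.
#' @export
read_pairs <- function(path, genes = NULL, mode = NULL) {
  if (!file.exists(path)) stop("pair file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  pairs <- vector("list", length(lines))
  lookup_gene <- function(id, lineno) {
    if (is.null(genes)) {
      return(list(gene_id = id))
    }
    hit <- genes[genes$gene_id == id, , drop = FALSE]
    if (nrow(hit) == 0)
      stop("line ", lineno, ": unknown gene id '", id, "'", call. = FALSE)
    as.list(hit[1, ])
  }
  as_int <- function(x) suppressWarnings(as.integer(x))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 6) {
      lab <- if (length(f) >= 8) as_int(f[8]) else NA
      nm <- if (length(f) >= 7) f[7] else NULL
      a <- list(chrom = f[1], start = as_int(f[2]),
                end = as_int(f[3]))
      bchrom <- f[4]; bs <- as_int(f[5]); be <- as_int(f[6])
      if (anyNA(c(a$start, a$end, bs, be)))
        stop("malformed line ", i, " in ", path, call. = FALSE)
      b <- list(gene_id = if (!is.null(nm)) paste0(nm, "_B") else
                  sprintf("%s:%d-%d", bchrom, bs, be),
                chrom = bchrom, strand = "+",
                tss = bs + (be - bs) %/% 2, tts = be - 1,
                start = bs, end = be)
      pairs[[i]] <- interaction_pair(a, b, mode = mode %||% "PDI",
                                     label = lab, name = nm)
    } else if (length(f) >= 2) {
      lab <- if (length(f) >= 3) suppressWarnings(as.integer(f[3])) else NA
      pairs[[i]] <- interaction_pair(lookup_gene(f[1], i),
                                     lookup_gene(f[2], i),
                                     mode = mode %||% "PPI", label = lab)
    } else {
      stop("malformed line ", i, " in ", path, call. = FALSE)
    }
  }
  message(length(pairs), " pairs read from ", basename(path))
  pairs
}

#' Write interaction pairs
#'
#' Inverse of [read_pairs()]: PDI pairs as BEDPE-like rows, PPI pairs as
#' gene-pair rows.  `write_pairs` then `read_pairs` is the identity on
#' records.
#'
#' @param pairs list of [interaction_pair()] objects.
#' @param path output file.
#' @export
write_pairs <- function(pairs, path) {
  rows <- vapply(pairs, function(p) {
    lab <- if (is.na(p$label)) NULL else p$label
    if (p$mode == "PDI") {
      b <- p$anchor_b
      bs <- b$start %||% (b$tss - 750)
      be <- b$end %||% (b$tss + 750)
      paste(c(p$anchor_a$chrom, p$anchor_a$start, p$anchor_a$end,
              b$chrom, bs, be, p$name %||% ".", lab), collapse = "\t")
    } else {
      paste(c(p$anchor_a$gene_id, p$anchor_b$gene_id, lab), collapse = "\t")
    }
  }, "")
  writeLines(rows, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- annotation readers ------------------------------------------------

#' Read gene annotation from GFF3
#'
#' Keeps `gene` features (falling back to all features when none are typed
#' `gene`) and derives strand-aware TSS/TTS coordinates, converting the
#' 1-based closed GFF3 convention to the package's 0-based half-open one.
#'
#' @param path GFF3 file.
#' @return data frame with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open) and `tss`, `tts` (0-based positions of the first
#'   and last transcribed base).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
        else sprintf("gene_%d", seq_along(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  plus <- strand == "+"
  out <- data.frame(gene_id = id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = strand, start = start0, end = end0,
                    tss = ifelse(plus, start0, end0 - 1L),
                    tts = ifelse(plus, end0 - 1L, start0))
  message(nrow(out), " gene records read from ", basename(path))
  out
}

#' Read intervals from a BED file
#'
#' @param path BED3+ file (0-based half-open, as BED).
#' @return data frame with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  if ("name" %in% names(S4Vectors::mcols(gr)))
    out$name <- as.character(gr$name)
  message(nrow(out), " intervals read from ", basename(path))
  out
}
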