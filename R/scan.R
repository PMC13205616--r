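# Genome tiling, pairing, interaction maps, hubs, target ranking.

#' Tile a region into fixed-width windows
#'
#' Windows start at `start + k * step` for `k = 0, 1, ...` and must lie
#' fully inside the region, so the count is
#' `floor((L - window) / step) + 1`.
#'
#' @param region list or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window window width (bp).
#' @param step step between window starts (bp); defaults to `window`
#'   (non-overlapping tiling).
#' @param on_short `"error"` (default) or `"empty"`: behaviour when the
#'   region is shorter than one window.
#' @return data frame with `chrom`, `start`, `end`, one row per window.
#' @export
tile_region <- function(region, window, step = window,
                        on_short = c("error", "empty")) {
  on_short <- match.arg(on_short)
  L <- region$end - region$start
  stopifnot(step >= 1)
  if (window > L) {
    if (on_short == "error")
      stop("window (", window, ") exceeds region length (", L, ")",
           call. = FALSE)
    warning("window exceeds region length; returning no windows")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  k <- 0:((L - window) %/% step)
  data.frame(chrom = region$chrom, start = region$start + k * step,
             end = region$start + k * step + window)
}

#' All ordered window pairs
#'
#' Full Cartesian product including self-pairs, enumerated row-major
#' (`idx_a` varies slowest); `n` windows give `n^2` pairs.
#'
#' @param windows data frame of windows (from [tile_region()]).
#' @return data frame with `idx_a`, `idx_b` window indices.
#' @export
pair_windows <- function(windows) {
  n <- nrow(windows)
  stopifnot(n >= 1)
  data.frame(idx_a = rep(seq_len(n), each = n),
             idx_b = rep(seq_len(n), times = n))
}

# Resolve a model argument: a ctci_fit, or a function(list of 4xL one-hot
# matrices) -> probabilities (used for stub models in tests and examples).
score_function <- function(model) {
  if (is.function(model)) return(model)
  function(x) predict(model, x)
}

model_threshold <- function(model, threshold = NULL) {
  if (!is.null(threshold)) return(threshold)
  if (!is.function(model) && !is.null(model$config$threshold))
    return(model$config$threshold)
  0.5
}

#' Predict the interaction map of a genomic region
#'
#' Tiles the region, encodes every ordered window pair (window A's columns
#' first) and fills the square matrix `M[i, j] = P(interaction of window i
#' with window j)`.  With `symmetrize = TRUE` the matrix is replaced by
#' `(M + t(M)) / 2`.
#'
#' @param model a fitted classifier ([ctci_fit()]) whose `input_len` is
#'   twice the window width, or a scoring function (see Details).
#' @param genome a [genome_ref()].
#' @param region list with `chrom`, `start`, `end`.
#' @param window,step tiling scheme (defaults: non-overlapping windows of
#'   half the model input width).
#' @param symmetrize average the two orientations of each pair.
#' @return object of class `interaction_map`: list with `windows` (data
#'   frame), `matrix` (n x n probabilities), `region`, `n_evaluations`.
#' @details `model` may be any function mapping a list of 4 x L one-hot
#'   matrices to a numeric vector of probabilities, which permits stub
#'   models and cheap baselines.
#' @export
predict_region_map <- function(model, genome, region, window = NULL,
                               step = NULL, symmetrize = FALSE) {
  if (is.null(window)) {
    if (is.function(model))
      stop("window must be given when model is a function", call. = FALSE)
    window <- model$config$input_len %/% 2L
  }
  if (is.null(step)) step <- window
  if (!is.function(model) && 2L * window != model$config$input_len)
    stop("model input_len (", model$config$input_len,
         ") is not twice the window width (", window, ")", call. = FALSE)
  windows <- tile_region(region, window, step)
  n <- nrow(windows)
  enc <- lapply(seq_len(n), function(i)
    one_hot_encode(genome_sequence(genome, windows$chrom[i],
                                   windows$start[i], windows$end[i])))
  pairs <- pair_windows(windows)
  score <- score_function(model)
  mats <- lapply(seq_len(nrow(pairs)), function(r)
    cbind(enc[[pairs$idx_a[r]]], enc[[pairs$idx_b[r]]]))
  p <- score(mats)
  M <- matrix(p, n, n, byrow = TRUE)  # row-major pair order
  if (symmetrize) M <- (M + t(M)) / 2
  structure(list(windows = windows, matrix = M, region = region,
                 n_evaluations = nrow(pairs), symmetrized = symmetrize),
            class = "interaction_map")
}

#' @export
print.interaction_map <- function(x, ...) {
  cat("Interaction map:", nrow(x$windows), "windows over",
      sprintf("%s:%d-%d", x$region$chrom, x$region$start, x$region$end),
      "\n  ", x$n_evaluations, "pair evaluations; probability range",
      sprintf("[%.3f, %.3f]\n", min(x$matrix), max(x$matrix)))
  invisible(x)
}

#' Write an interaction map as matrix text and BEDPE
#'
#' The matrix file has one header line with the window coordinates; the
#' BEDPE file lists above-threshold pairs with the probability in the score
#' column, in a layout [read_pairs()] accepts.
#'
#' @param map an `interaction_map`.
#' @param matrix_path,bedpe_path output paths (`NULL` = skip).
#' @param threshold probability cutoff for the BEDPE records.
#' @export
write_interaction_map <- function(map, matrix_path = NULL,
                                  bedpe_path = NULL, threshold = 0.5) {
  w <- map$windows
  if (!is.null(matrix_path)) {
    hdr <- paste(sprintf("%s:%d-%d", w$chrom, w$start, w$end),
                 collapse = "\t")
    con <- file(matrix_path, "w")
    writeLines(paste0("#", hdr), con)
    utils::write.table(map$matrix, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    close(con)
  }
  if (!is.null(bedpe_path)) {
    idx <- which(map$matrix > threshold, arr.ind = TRUE)
    rows <- apply(idx, 1, function(ij) {
      paste(c(w$chrom[ij[1]], w$start[ij[1]], w$end[ij[1]],
              w$chrom[ij[2]], w$start[ij[2]], w$end[ij[2]],
              sprintf("pair_%d_%d", ij[1], ij[2]),
              signif(map$matrix[ij[1], ij[2]], 6)), collapse = "\t")
    })
    writeLines(if (length(rows)) rows else character(), bedpe_path)
  }
  invisible(map)
}

#' Candidate promoter-distal pairs genome-wide
#'
#' Implements the distal-element pairing rule: keep OCRs whose distance to
#' the nearest gene exceeds `min_gene_distance`, expand each retained OCR
#' by `flank` on both sides (clipped at chromosome bounds when `genome` is
#' given), and pair the OCR with every gene overlapping the expanded
#' window.
#'
#' @param ocrs data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param genes gene annotation data frame (see [read_genes()]).
#' @param flank expansion in bp on each side (default 1 Mb).
#' @param min_gene_distance minimum OCR-to-gene distance for an OCR to
#'   count as distal (default 2 kb).
#' @param genome optional [genome_ref()] for bound clipping.
#' @return list of PDI [interaction_pair()] objects (label unknown).
#' @export
pdi_candidate_pairs <- function(ocrs, genes, flank = 1000000L,
                                min_gene_distance = 2000L, genome = NULL) {
  ogr <- GenomicRanges::GRanges(ocrs$chrom,
                                IRanges::IRanges(ocrs$start + 1L, ocrs$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L, genes$end))
  dn <- GenomicRanges::distanceToNearest(ogr, ggr)
  dist <- rep(Inf, length(ogr))
  dist[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance
  keep <- which(dist > min_gene_distance)

  out <- list()
  for (i in keep) {
    s1 <- ocrs$start[i] - flank
    e1 <- ocrs$end[i] + flank
    s1 <- max(0L, s1)
    if (!is.null(genome) && ocrs$chrom[i] %in% names(genome$seqs))
      e1 <- min(e1, genome$lengths[[ocrs$chrom[i]]])
    hit <- genes$chrom == ocrs$chrom[i] & genes$start < e1 & genes$end > s1
    for (j in which(hit)) {
      out[[length(out) + 1L]] <- interaction_pair(
        anchor_a = list(chrom = ocrs$chrom[i], start = ocrs$start[i],
                        end = ocrs$end[i]),
        anchor_b = as.list(genes[j, ]),
        mode = "PDI",
        name = paste0(ocrs$name[i] %||% sprintf("ocr_%d", i), ":",
                      genes$gene_id[j]))
    }
  }
  out
}

#' Interaction degree per node
#'
#' The degree of a gene or OCR is its number of distinct partners with
#' probability above the threshold.
#'
#' @param predictions data frame with `node_a`, `node_b`, `probability`.
#' @param threshold probability cutoff.
#' @return data frame `node`, `degree`, sorted by decreasing degree with
#'   ties broken by node identifier.
#' @export
degree_table <- function(predictions, threshold = 0.5) {
  sel <- predictions[predictions$probability > threshold, , drop = FALSE]
  # distinct undirected partner sets
  edges <- unique(data.frame(
    a = pmin(sel$node_a, sel$node_b),
    b = pmax(sel$node_a, sel$node_b)))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  nodes <- sort(unique(c(predictions$node_a, predictions$node_b)))
  deg <- table(factor(c(edges$a, edges$b), levels = nodes))
  out <- data.frame(node = nodes, degree = as.integer(deg))
  out[order(-out$degree, out$node), , drop = FALSE]
}

#' Top interaction hubs
#'
#' @param table a [degree_table()] result.
#' @param k number of nodes to keep (default 1500, the hub-selection size
#'   used for genome-scale motif analysis).
#' @return character vector of node identifiers.
#' @export
top_hubs <- function(table, k = 1500L) {
  if (k > nrow(table)) {
    warning("k (", k, ") exceeds node count (", nrow(table),
            "); returning all nodes")
    k <- nrow(table)
  }
  table$node[seq_len(k)]
}

#' Rank candidate target genes of a regulatory region
#'
#' Tiles the regulatory region (window/step as in the published UPA2
#' analysis: 1.5 kb windows, 200 bp steps, giving 43 sub-regions for a
#' 10 kb region), scores every (sub-window, candidate promoter) pair and
#' aggregates per gene.
#'
#' @param model fitted classifier or scoring function; `input_len` must be
#'   `2 * window`.
#' @param genome a [genome_ref()].
#' @param region regulatory region (list with `chrom`, `start`, `end`).
#' @param candidate_genes data frame of genes (see [read_genes()]).
#' @param window,step tiling of the regulatory region; `window` defaults
#'   to half the model input width and is also the promoter length used
#'   for the gene side.
#' @param aggregate `"max"` (default; the strongest sub-window contact) or
#'   `"mean"`.
#' @return data frame `gene_id`, `score`, sorted by decreasing score, ties
#'   broken by gene identifier.
#' @export
rank_targets <- function(model, genome, region, candidate_genes,
                         window = NULL, step = 200L,
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (nrow(candidate_genes) == 0)
    stop("empty candidate gene set", call. = FALSE)
  if (is.null(window)) {
    if (is.function(model))
      stop("window must be given when model is a function", call. = FALSE)
    window <- model$config$input_len %/% 2L
  }
  windows <- tile_region(region, window, step)
  wenc <- lapply(seq_len(nrow(windows)), function(i)
    one_hot_encode(genome_sequence(genome, windows$chrom[i],
                                   windows$start[i], windows$end[i])))
  score <- score_function(model)
  scores <- vapply(seq_len(nrow(candidate_genes)), function(j) {
    gene <- as.list(candidate_genes[j, ])
    prom <- promoter_window(genome, gene, window)
    mats <- lapply(wenc, function(w) cbind(w, one_hot_encode(prom)))
    p <- score(mats)
    if (aggregate == "max") max(p) else mean(p)
  }, 0)
  out <- data.frame(gene_id = candidate_genes$gene_id, score = scores)
  out[order(-out$score, out$gene_id), , drop = FALSE]
}

# Promoter-anchored window of arbitrary length w: 2/3 upstream, 1/3
# downstream of the TSS, the same 1000:500 split as the 1.5 kb convention.
promoter_window <- function(genome, gene, w) {
  if (w == 1500L) return(extract_promoter_sequence(genome, gene))
  up <- round(w * 2 / 3)
  down <- w - up
  check_strand(gene$strand)
  if (gene$strand == "+") {
    genome_sequence(genome, gene$chrom, gene$tss - up, gene$tss + down)
  } else {
    revcomp(genome_sequence(genome, gene$chrom,
                            gene$tss - down + 1, gene$tss + up + 1))
  }
}

#' Correlation between two interaction maps
#'
#' Plain utility: Pearson correlation of the matrix entries (upper
#' triangles for symmetric comparisons).
#'
#' @param m1,m2 matrices or `interaction_map` objects of equal size.
#' @param upper use the upper triangle only.
#' @export
map_correlation <- function(m1, m2, upper = TRUE) {
  if (inherits(m1, "interaction_map")) m1 <- m1$matrix
  if (inherits(m2, "interaction_map")) m2 <- m2$matrix
  stopifnot(all(dim(m1) == dim(m2)))
  if (upper) {
    iu <- upper.tri(m1, diag = TRUE)
    stats::cor(m1[iu], m2[iu])
  } else stats::cor(as.vector(m1), as.vector(m2))
}
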