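# Per-base importance, continuous-run motif calling, motif cooperation,
# saturation mutagenesis, interval enrichment, motif clustering.

as_single_input <- function(x) {
  m <- if (inherits(x, "ctci_encoded")) x$matrix else x
  stopifnot(is.matrix(m), nrow(m) == 4)
  m
}

attribution_matrix <- function(values, method) {
  stopifnot(is.matrix(values), nrow(values) == 4)
  rownames(values) <- CTCI_BASES
  structure(list(values = values, method = method),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat("Attribution matrix (", x$method, "): 4 x ", ncol(x$values),
      ", total ", signif(sum(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' Integrated-gradients attribution
#'
#' Path integral of the gradient of the interaction probability from a
#' baseline (default: the all-zero matrix, i.e. an all-`N` sequence) to the
#' input, times `(input - baseline)`.  Satisfies the completeness identity
#' `sum(M) = f(x) - f(baseline)` up to the Riemann discretisation error,
#' which shrinks as `steps` grows (the default trapezoid rule converges at
#' O(1/steps^2)).
#'
#' @param model a fitted [ctci_fit()].
#' @param x encoded pair (a 4 x L matrix or [encode_pair()] result) whose
#'   width matches the model.
#' @param baseline same shape as `x` (default all zeros).
#' @param steps number of path steps (>= 1).
#' @param rule `"trapezoid"` (default) or `"right"` (right-endpoint
#'   Riemann sum; with `steps = 1` this reduces exactly to
#'   [gradient_x_input()]).
#' @return an `attribution_matrix` (4 x L, rows A,T,G,C) with method tag
#'   `"integrated_gradients"`.
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 50L,
                                 rule = c("trapezoid", "right")) {
  rule <- match.arg(rule)
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  m <- as_single_input(x)
  L <- ncol(m)
  x1 <- t(m)                         # L x 4
  x0 <- if (is.null(baseline)) x1 * 0 else t(as_single_input(baseline))
  stopifnot(all(dim(x0) == dim(x1)))
  if (rule == "trapezoid") {
    alphas <- seq(0, 1, length.out = steps + 1)
    w <- c(0.5, rep(1, steps - 1), 0.5) / steps
  } else {
    alphas <- seq_len(steps) / steps
    w <- rep(1 / steps, steps)
  }
  np <- length(alphas)
  X <- array(0, c(np, L, 4))
  for (j in seq_len(np)) X[j, , ] <- x0 + alphas[j] * (x1 - x0)
  dX <- nn_input_grad(model$params, X, model$config, wrt = "prob")$dX
  avg <- matrix(0, L, 4)
  for (j in seq_len(np)) avg <- avg + w[j] * dX[j, , ]
  attribution_matrix(t((x1 - x0) * avg), "integrated_gradients")
}

#' Gradient-times-input attribution
#'
#' Elementwise gradient of the output probability with respect to the
#' one-hot input, multiplied by the input.  Fast single-pass
#' approximation; all-zero (`N`) columns receive zero attribution by
#' construction.
#'
#' @inheritParams integrated_gradients
#' @return an `attribution_matrix` with method tag `"gradient_x_input"`.
#' @export
gradient_x_input <- function(model, x) {
  m <- as_single_input(x)
  L <- ncol(m)
  X <- array(0, c(1L, L, 4L))
  X[1, , ] <- t(m)
  dX <- nn_input_grad(model$params, X, model$config, wrt = "prob")$dX
  attribution_matrix(t(dX[1, , ] * t(m)), "gradient_x_input")
}

#' Call motifs as continuous high-attribution runs
#'
#' Per-position score is the column maximum of the attribution matrix and
#' the per-position base is the row argmax (ties resolved in A,T,G,C row
#' order).  A motif is a maximal run of consecutive positions with score
#' strictly greater than `r`, of length at least `N`; shorter sub-runs are
#' absorbed into their maximal run rather than reported separately.
#'
#' @param M an `attribution_matrix` or plain 4 x L matrix (rows A,T,G,C).
#' @param r attribution threshold (0.2 reproduces the published worked
#'   example; 0.5 is the published genome-scale setting).
#' @param N minimum run length (>= 2).
#' @param pair_id optional identifier carried into the output.
#' @return data frame of class `motif_calls`: `start`, `end` (1-based
#'   inclusive column indices), `length`, `motif`, `score` (mean
#'   per-position score of the run).
#' @export
call_motifs <- function(M, r = 0.5, N = 5L, pair_id = NULL) {
  if (inherits(M, "attribution_matrix")) M <- M$values
  stopifnot(is.matrix(M), nrow(M) == 4, r >= 0, N >= 2)
  score <- apply(M, 2, max)
  base <- CTCI_BASES[apply(M, 2, which.max)]
  runs <- rle(score > r)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= N)
  out <- data.frame(
    start = starts[keep], end = ends[keep],
    length = runs$lengths[keep],
    motif = vapply(keep, function(k)
      paste(base[starts[k]:ends[k]], collapse = ""), ""),
    score = vapply(keep, function(k)
      mean(score[starts[k]:ends[k]]), 0))
  if (!is.null(pair_id) && nrow(out) > 0) out$pair_id <- pair_id
  class(out) <- c("motif_calls", "data.frame")
  out
}

#' Mine motifs across a set of encoded pairs
#'
#' Computes an attribution matrix per pair, optionally normalises it by its
#' maximum absolute entry (so the run threshold `r` acts on a common
#' [-1, 1] scale across pairs), calls motifs and returns them ranked by
#' run score.
#'
#' @param model a fitted [ctci_fit()].
#' @param x list of encoded pairs (4 x L matrices) or an `(n, L, 4)` array.
#' @param r,N see [call_motifs()].
#' @param method `"gradient_x_input"` (fast default) or
#'   `"integrated_gradients"`.
#' @param steps path steps when using integrated gradients.
#' @param normalize divide each attribution matrix by its max |entry|.
#' @param top_n keep this many top-scoring calls (`Inf` = all).
#' @return `motif_calls` data frame with a `pair_id` column, sorted by
#'   decreasing score.
#' @export
mine_motifs <- function(model, x, r = 0.2, N = 5L,
                        method = c("gradient_x_input",
                                   "integrated_gradients"),
                        steps = 20L, normalize = TRUE, top_n = Inf) {
  method <- match.arg(method)
  if (is.array(x) && length(dim(x)) == 3)
    x <- lapply(seq_len(dim(x)[1]), function(i) t(x[i, , ]))
  calls <- list()
  for (i in seq_along(x)) {
    A <- if (method == "gradient_x_input") gradient_x_input(model, x[[i]])
         else integrated_gradients(model, x[[i]], steps = steps)
    V <- A$values
    if (normalize && max(abs(V)) > 0) V <- V / max(abs(V))
    calls[[i]] <- call_motifs(V, r = r, N = N, pair_id = i)
  }
  out <- do.call(rbind, calls)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(start = integer(), end = integer(),
                      length = integer(), motif = character(),
                      score = numeric(), pair_id = integer())
  } else {
    out <- out[order(-out$score), , drop = FALSE]
    if (is.finite(top_n)) out <- utils::head(out, top_n)
  }
  class(out) <- c("motif_calls", "data.frame")
  out
}

#' Substring-tolerant edit distance between a motif and a set of calls
#'
#' Continuous-run motif calls have data-driven lengths, so a call that is
#' an exact substring of a planted/known motif (or contains it) counts as
#' distance 0.  For each call the distance is the smaller of the two
#' partial (best local alignment) Levenshtein distances between motif and
#' call; the minimum over calls is returned.
#'
#' @param motif reference motif string.
#' @param calls character vector of called motifs (or a `motif_calls`
#'   data frame).
#' @return integer: the best (smallest) distance over calls.
#' @export
motif_edit_distance <- function(motif, calls) {
  if (is.data.frame(calls)) calls <- calls$motif
  if (length(calls) == 0) return(NA_integer_)
  d1 <- as.numeric(utils::adist(motif, calls, partial = TRUE))
  d2 <- vapply(calls, function(cl)
    as.numeric(utils::adist(cl, motif, partial = TRUE)), numeric(1))
  as.integer(min(pmin(d1, d2)))
}

#' Motif cooperation scan
#'
#' Fixes `motif_a` at `pos_a` in anchor A and slides `motif_b` across
#' anchor B in non-overlapping steps of its own length (window = step =
#' `nchar(motif_b)`), recording at each placement the model's gradient
#' response.  The response is the summed attribution over motif A's
#' columns (default) or the output probability.  The cooperation score at
#' the peak position is `AB / (A + B - b)` where `AB` is the response with
#' both motifs present, `A` and `B` the solo responses, and `b` the
#' motif-free background response.
#'
#' @param model a fitted [ctci_fit()].
#' @param anchor_a,anchor_b background sequences (motifs are written into
#'   copies of them); lengths must sum to the model input width.
#' @param motif_a,motif_b A/C/G/T strings.
#' @param pos_a 0-based position of motif A within anchor A.
#' @param response `"attribution"` or `"probability"`.
#' @param method attribution method, as in [mine_motifs()].
#' @return object of class `cooperation_result`: list with `positions`
#'   (data frame: `pos` 0-based placement in anchor B, `AB`, `B_solo`,
#'   `score`), `P_m` (0-based argmax placement), `A_solo`, `background`,
#'   `score` (at `P_m`), `score_defined`.
#' @export
cooperation_scan <- function(model, anchor_a, anchor_b, motif_a, motif_b,
                             pos_a = 0L,
                             response = c("attribution", "probability"),
                             method = c("gradient_x_input",
                                        "integrated_gradients")) {
  response <- match.arg(response)
  method <- match.arg(method)
  la <- nchar(anchor_a); lb <- nchar(anchor_b)
  ma <- nchar(motif_a); mb <- nchar(motif_b)
  if (pos_a + ma > la) stop("motif_a does not fit at pos_a", call. = FALSE)
  if (mb > lb) stop("motif_b longer than anchor_b", call. = FALSE)
  a_chars <- strsplit(anchor_a, "")[[1]]
  b_chars <- strsplit(anchor_b, "")[[1]]
  a_with <- paste(plant_motif(a_chars, motif_a, pos_a), collapse = "")
  a_cols <- (pos_a + 1):(pos_a + ma)   # motif A columns in the pair

  resp <- function(sa, sb) {
    enc <- cbind(one_hot_encode(sa), one_hot_encode(sb))
    if (response == "probability")
      return(predict(model, list(enc)))
    A <- if (method == "gradient_x_input") gradient_x_input(model, enc)
         else integrated_gradients(model, enc, steps = 20L)
    sum(A$values[, a_cols])
  }

  n_place <- lb %/% mb
  pos_b <- (seq_len(n_place) - 1L) * mb
  b_seqs <- vapply(pos_b, function(p)
    paste(plant_motif(b_chars, motif_b, p), collapse = ""), "")

  AB <- vapply(b_seqs, function(sb) resp(a_with, sb), 0)
  B_solo <- vapply(b_seqs, function(sb) resp(anchor_a, sb), 0)
  A_solo <- resp(a_with, anchor_b)
  bg <- resp(anchor_a, anchor_b)

  denom <- A_solo + B_solo - bg
  sc <- ifelse(abs(denom) < 1e-12, NA_real_, AB / denom)
  pm_i <- which.max(AB)
  structure(list(
    positions = data.frame(pos = pos_b, AB = AB, B_solo = B_solo,
                           score = sc),
    P_m = pos_b[pm_i], A_solo = A_solo, background = bg,
    score = sc[pm_i], score_defined = is.finite(sc[pm_i]),
    response = response),
    class = "cooperation_result")
}

#' @export
print.cooperation_result <- function(x, ...) {
  cat("Cooperation scan:", nrow(x$positions), "placements;",
      "peak at", x$P_m, "\n  score AB/(A+B-b) =",
      if (x$score_defined) signif(x$score, 4) else "undefined", "\n")
  invisible(x)
}

#' In-silico saturation mutagenesis of a regulatory region
#'
#' Replaces the called motif plus `flank` bases on each side with uniform
#' random sequence, re-predicts the interaction of the mutated distal
#' region with every partner, and reports the change in interaction degree
#' (number of partners above the probability threshold) per draw.
#'
#' @param model fitted classifier or scoring function.
#' @param distal background distal sequence (character).
#' @param partners list of partner (promoter/gene) sequences; each pair is
#'   encoded as distal columns first.
#' @param motif_start,motif_end 1-based motif span within `distal`.
#' @param flank bases extended on each side (published settings: 50, 100,
#'   200); clipped at the sequence bounds with a warning.
#' @param n_draws number of random replacements.
#' @param seed RNG seed (same seed, same draw sequence).
#' @param threshold probability cutoff (default: the model's).
#' @return list with `baseline_degree`, `draws` (data frame: `draw`,
#'   `degree`, `delta`), `mean_delta`, `window` (0-based half-open span
#'   that was mutated).
#' @export
saturation_mutation <- function(model, distal, partners, motif_start,
                                motif_end, flank = 50L, n_draws = 20L,
                                seed = 1L, threshold = NULL) {
  L <- nchar(distal)
  stopifnot(motif_start >= 1, motif_end <= L, motif_start <= motif_end)
  w0 <- motif_start - flank
  w1 <- motif_end + flank
  if (w0 < 1 || w1 > L) {
    warning("flank window clipped to the sequence bounds")
    w0 <- max(1, w0); w1 <- min(L, w1)
  }
  thr <- model_threshold(model, threshold)
  score <- score_function(model)
  enc_all <- function(d) {
    de <- one_hot_encode(d)
    lapply(partners, function(p) cbind(de, one_hot_encode(p)))
  }
  base_p <- score(enc_all(distal))
  base_deg <- sum(base_p > thr)
  set.seed(seed)
  dchars <- strsplit(distal, "")[[1]]
  degs <- integer(n_draws)
  for (d in seq_len(n_draws)) {
    mut <- dchars
    mut[w0:w1] <- sample(c("A", "C", "G", "T"), w1 - w0 + 1, replace = TRUE)
    p <- score(enc_all(paste(mut, collapse = "")))
    degs[d] <- sum(p > thr)
  }
  list(baseline_degree = base_deg,
       draws = data.frame(draw = seq_len(n_draws), degree = degs,
                          delta = degs - base_deg),
       mean_delta = mean(degs - base_deg),
       window = c(w0 - 1L, w1))
}

# ---- interval enrichment ----------------------------------------------

df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

# Sample one random interval of each requested width uniformly from the
# allowed ranges (positions where the whole interval fits).  `adf` is a
# plain data frame of allowed ranges (precomputed once per scheme).
sample_intervals <- function(adf, widths) {
  n <- length(widths)
  chrom <- character(n); start <- integer(n)
  lens <- adf$end - adf$start
  for (i in seq_len(n)) {
    cap <- pmax(0L, lens - widths[i] + 1L)
    if (sum(cap) == 0)
      stop("control space cannot fit an interval of width ", widths[i],
           call. = FALSE)
    ri <- sample.int(nrow(adf), 1, prob = cap)
    chrom[i] <- adf$chrom[ri]
    start[i] <- adf$start[ri] + sample.int(cap[ri], 1) - 1L
  }
  data.frame(chrom = chrom, start = start, end = start + widths)
}

# Fast overlap counting against a fixed, reduced (disjoint, sorted)
# feature set, split by chromosome; avoids per-replicate GRanges
# construction in the permutation loop.
feature_index <- function(fdf) {
  split(fdf[order(fdf$chrom, fdf$start), c("start", "end")],
        fdf$chrom[order(fdf$chrom, fdf$start)])
}

count_overlaps_fast <- function(df, fidx) {
  hits <- 0L
  for (ch in unique(df$chrom)) {
    fi <- fidx[[ch]]
    if (is.null(fi) || nrow(fi) == 0) next
    sel <- df$chrom == ch
    s <- df$start[sel]; e <- df$end[sel]
    # interval [s, e) overlaps a feature iff the last feature starting
    # before e has not ended by s
    idx <- findInterval(e - 1L, fi$start)
    ok <- idx >= 1L & idx <= nrow(fi)
    ov <- ok & fi$end[pmax(idx, 1L)] > s
    hits <- hits + sum(ov)
  }
  hits
}

#' Empirical motif enrichment in feature intervals
#'
#' Counts motif locations overlapping the feature intervals and compares
#' against `n_reps` random placements under two control schemes:
#' `"interaction"` draws equal-length positions from the interaction
#' sequences minus the motif positions, `"genome"` draws from the genome
#' minus the interaction sequences.  The empirical p-value uses the
#' add-one convention `p = (1 + #\{control >= observed\}) / (n_reps + 1)`,
#' which cannot return 0 at finite replicates.
#'
#' @param motifs data frame (`chrom`, `start`, `end`) of motif locations.
#' @param features data frame of feature intervals (e.g. open-chromatin
#'   regions or eQTL intervals).
#' @param interaction_regions data frame of the interaction sequences the
#'   motifs were mined from.
#' @param genome a [genome_ref()] or named vector of chromosome lengths.
#' @param scheme `"interaction"`, `"genome"`, or `"both"`.
#' @param n_reps control replicates (published analyses use 100).
#' @param seed RNG seed; controls the random draws only, never the
#'   observed count.
#' @return data frame with one row per scheme: `scheme`, `observed`,
#'   `control_mean`, `p_value`, `n_reps`.
#' @export
motif_enrichment <- function(motifs, features, interaction_regions,
                             genome, scheme = c("both", "interaction",
                                                "genome"),
                             n_reps = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  schemes <- if (scheme == "both") c("interaction", "genome") else scheme
  mg <- df_to_gr(motifs)
  fg <- GenomicRanges::reduce(df_to_gr(features))
  ig <- GenomicRanges::reduce(df_to_gr(interaction_regions))
  observed <- sum(IRanges::overlapsAny(mg, fg))
  lens <- if (inherits(genome, "genome_ref")) genome$lengths
          else unlist(genome)
  gg <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1, lens))
  widths <- motifs$end - motifs$start
  fidx <- feature_index(gr_to_df(fg))

  set.seed(seed)
  out <- NULL
  for (sc in schemes) {
    allowed <- if (sc == "interaction")
      GenomicRanges::setdiff(ig, GenomicRanges::reduce(mg))
    else GenomicRanges::setdiff(gg, ig)
    adf <- gr_to_df(allowed)
    ctrl <- vapply(seq_len(n_reps), function(r) {
      count_overlaps_fast(sample_intervals(adf, widths), fidx)
    }, 0L)
    out <- rbind(out, data.frame(
      scheme = sc, observed = observed, control_mean = mean(ctrl),
      p_value = (1 + sum(ctrl >= observed)) / (n_reps + 1),
      n_reps = n_reps))
  }
  out
}

# ---- motif clustering --------------------------------------------------

# Best ungapped-alignment match fraction over all offsets and both
# strands; 1 = one motif is a perfect substring match of the other at some
# offset.
motif_similarity <- function(a, b) {
  best <- 0
  bs <- c(b, revcomp(b))
  ca <- strsplit(a, "")[[1]]
  for (bb in bs) {
    cb <- strsplit(bb, "")[[1]]
    na <- length(ca); nb <- length(cb)
    for (off in (-nb + 1):(na - 1)) {
      ia <- max(1, 1 + off):min(na, nb + off)
      ib <- ia - off
      m <- sum(ca[ia] == cb[ib])
      best <- max(best, m / max(na, nb))
    }
  }
  best
}

#' Cluster called motifs into core motif groups
#'
#' Pairwise similarity is the best ungapped-alignment match fraction over
#' all offsets and both strands; motifs are grouped by average-linkage
#' hierarchical clustering on `1 - similarity`, cut at `n_clusters`.  Each
#' cluster is summarised by a position-frequency matrix (members aligned to
#' the cluster's longest motif at their best offset) and its consensus.
#'
#' @param motifs character vector of motif strings, or a `motif_calls`
#'   data frame.
#' @param n_clusters number of clusters (<= number of motifs).
#' @return list with `assignments` (integer vector), `consensus`
#'   (character per cluster), `pwm` (list of 4 x width matrices, columns
#'   summing to 1), `similarity` (the pairwise matrix).
#' @export
cluster_motifs <- function(motifs, n_clusters) {
  if (is.data.frame(motifs)) motifs <- motifs$motif
  n <- length(motifs)
  if (n_clusters > n)
    stop("n_clusters (", n_clusters, ") exceeds number of motifs (", n,
         ")", call. = FALSE)
  S <- diag(1, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    S[i, j] <- S[j, i] <- motif_similarity(motifs[i], motifs[j])
  }
  if (n_clusters == n) {
    cl <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
    cl <- stats::cutree(hc, k = n_clusters)
  }
  pwm <- vector("list", n_clusters)
  consensus <- character(n_clusters)
  for (k in seq_len(n_clusters)) {
    members <- motifs[cl == k]
    ref <- members[which.max(nchar(members))]
    w <- nchar(ref)
    counts <- matrix(0, 4, w, dimnames = list(CTCI_BASES, NULL))
    for (m in members) {
      # best offset/strand against the reference
      best <- c(score = -1, off = 0, rc = 0)
      for (rc in 0:1) {
        mm <- if (rc) revcomp(m) else m
        cm <- strsplit(mm, "")[[1]]
        cr <- strsplit(ref, "")[[1]]
        for (off in (-length(cm) + 1):(w - 1)) {
          ir <- max(1, 1 + off):min(w, length(cm) + off)
          im <- ir - off
          sc <- sum(cr[ir] == cm[im])
          if (sc > best["score"]) best <- c(score = sc, off = off, rc = rc)
        }
      }
      mm <- if (best["rc"]) revcomp(m) else m
      cm <- strsplit(mm, "")[[1]]
      ir <- max(1, 1 + best["off"]):min(w, length(cm) + best["off"])
      im <- ir - best["off"]
      for (t in seq_along(ir))
        counts[cm[im[t]], ir[t]] <- counts[cm[im[t]], ir[t]] + 1
    }
    cs <- colSums(counts)
    cs[cs == 0] <- 1
    pwm[[k]] <- sweep(counts, 2, cs, "/")
    consensus[k] <- paste(CTCI_BASES[apply(pwm[[k]], 2, which.max)],
                          collapse = "")
  }
  list(assignments = cl, consensus = consensus, pwm = pwm, similarity = S)
}

#' Write position-weight matrices in MEME minimal motif format
#'
#' @param pwms list of 4 x width matrices (rows A,T,G,C, columns summing
#'   to 1).
#' @param path output file.
#' @param names motif names (default `MOTIF_k`).
#' @export
write_meme <- function(pwms, path, names = NULL) {
  if (is.null(names)) names <- sprintf("MOTIF_%d", seq_along(pwms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (k in seq_along(pwms)) {
    m <- pwms[[k]]
    writeLines(sprintf("MOTIF %s", names[k]), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0",
      ncol(m)), con)
    # MEME column order is A C G T; internal row order is A,T,G,C
    for (j in seq_len(ncol(m)))
      writeLines(sprintf("%.6f %.6f %.6f %.6f",
                         m["A", j], m["C", j], m["G", j], m["T", j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write motif calls as BED
#'
#' @param calls a `motif_calls` data frame (pair-local coordinates).
#' @param path output file.
#' @param chrom chromosome name for all records.
#' @param offset 0-based genomic coordinate of the pair's first column.
#' @export
motif_calls_to_bed <- function(calls, path, chrom = "pair", offset = 0L) {
  rows <- sprintf("%s\t%d\t%d\t%s\t%.6g", chrom,
                  offset + calls$start - 1L, offset + calls$end,
                  calls$motif, calls$score)
  writeLines(rows, path)
  invisible(path)
}
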