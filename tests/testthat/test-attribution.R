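# The published worked example: a 4 x 5 gradient matrix whose printed rows
# (A, C, G, T order) are rearranged here into the package's A,T,G,C row
# order.  Column maxima are C .23, G .28, T .50, T .66, C .48.
worked_matrix <- function() {
  m <- rbind(A = c(0.02, 0,    0.034, 0,    0.2),
             T = c(0.16, 0,    0.5,   0.66, 0),
             G = c(0,    0.28, 0.1,   0.59, 0.07),
             C = c(0.23, 0,    0,     0,    0.48))
  m
}

test_that("the worked gradient matrix yields exactly the call CGTTC", {
  calls <- call_motifs(worked_matrix(), r = 0.2, N = 5)
  expect_equal(nrow(calls), 1)
  expect_identical(calls$motif, "CGTTC")
  expect_equal(calls$start, 1)
  expect_equal(calls$end, 5)
})

test_that("motif calling uses maximal runs, not sliding windows", {
  expect_equal(nrow(call_motifs(matrix(0, 4, 50), r = 0.2, N = 5)), 0)
  # a 12-long run above r yields ONE call of length 12
  m <- matrix(0, 4, 30)
  m[2, 10:21] <- 0.9
  calls <- call_motifs(m, r = 0.5, N = 5)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$length, 12)
  expect_identical(calls$motif, strrep("T", 12))
  # verify against exhaustive run enumeration
  score <- apply(m, 2, max)
  runs <- which(score > 0.5)
  expect_equal(calls$start, min(runs))
  expect_equal(calls$end, max(runs))
  # runs shorter than N are dropped
  m2 <- matrix(0, 4, 30)
  m2[1, 3:6] <- 1
  expect_equal(nrow(call_motifs(m2, r = 0.5, N = 5)), 0)
  expect_equal(nrow(call_motifs(m2, r = 0.5, N = 4)), 1)
})

test_that("raising r or N never increases the called territory", {
  # Under maximal-run semantics a higher threshold can SPLIT one long run
  # into two calls, so the call COUNT is monotone only in N; the total
  # number of called positions is monotone in both parameters.
  covered <- function(m, r, N) sum(call_motifs(m, r, N)$length)
  set.seed(17)
  for (rep in 1:10) {
    m <- matrix(runif(4 * 80), 4, 80)
    rs <- sort(runif(4))
    cov_r <- vapply(rs, function(r) covered(m, r, 3), 0)
    expect_true(all(diff(cov_r) <= 0))
    Ns <- 2:6
    cov_N <- vapply(Ns, function(N) covered(m, 0.5, N), 0)
    expect_true(all(diff(cov_N) <= 0))
    counts_N <- vapply(Ns, function(N)
      nrow(call_motifs(m, r = 0.5, N = N)), 0L)
    expect_true(all(diff(counts_N) <= 0))
  }
})

test_that("integrated gradients satisfy the completeness identity", {
  fit <- cached_fit()
  d <- cached_fit_data()
  x <- t(d$x[1, , ])
  ig <- integrated_gradients(fit, x, steps = 200)
  f_x <- predict(fit, list(x))
  f_0 <- predict(fit, list(x * 0))
  expect_lt(abs(sum(ig$values) - (f_x - f_0)), 0.01)
  # input == baseline -> identically zero
  ig0 <- integrated_gradients(fit, x, baseline = x, steps = 5)
  expect_equal(max(abs(ig0$values)), 0)
  expect_error(integrated_gradients(fit, x, steps = 0), "steps")
})

test_that("gradient-x-input agrees with one-step IG and zeroes N columns", {
  fit <- cached_fit()
  d <- cached_fit_data()
  x <- t(d$x[2, , ])
  x[, 5:10] <- 0                      # N columns
  gx <- gradient_x_input(fit, x)
  expect_true(all(gx$values[, 5:10] == 0))
  expect_true(all(is.finite(gx$values)))
  ig1 <- integrated_gradients(fit, x, steps = 1, rule = "right")
  expect_equal(gx$values, ig1$values, tolerance = 1e-10)
})

test_that("attribution mass concentrates on the planted motifs", {
  fit <- cached_fit()
  d <- cached_fit_data()
  man <- d$manifest
  pos <- which(man$label_true == 1 & man$motif_a != "")[1:10]
  ratio <- vapply(pos, function(i) {
    ig <- integrated_gradients(fit, t(d$x[i, , ]), steps = 30)
    sc <- apply(abs(ig$values), 2, max)
    mcols <- c((man$pos_a[i] + 1):(man$pos_a[i] + nchar(man$motif_a[i])),
               120 + (man$pos_b[i] + 1):(man$pos_b[i] +
                                           nchar(man$motif_b[i])))
    mean(sc[mcols]) / mean(sc[-mcols])
  }, 0)
  expect_gt(median(ratio), 2)   # motif columns carry clearly more mass
})

test_that("mined motifs recover the planted pair", {
  fit <- cached_fit()
  d <- cached_fit_data()
  man <- d$manifest
  pos <- which(man$label_true == 1)[1:25]
  calls <- mine_motifs(fit, d$x[pos, , , drop = FALSE], r = 0.2, N = 5,
                       top_n = 10)
  expect_gt(nrow(calls), 0)
  planted <- c("TGACGTCATC", "CACGTGGCTA")
  expect_lte(motif_edit_distance(planted[1], calls), 1)
  expect_lte(motif_edit_distance(planted[2], calls), 1)
  # the helper itself: substring call -> 0, unrelated call -> large
  expect_equal(motif_edit_distance("TGACGTCATC", "GACGTCA"), 0)
  expect_equal(motif_edit_distance("ACGT", c("ACGTACGTAA")), 0)
  expect_gt(motif_edit_distance("TGACGTCATC", "CCCCCCC"), 3)
})

test_that("cooperation scan covers the anchor and flags degenerate scores", {
  fit <- cached_fit()
  set.seed(23)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  res <- cooperation_scan(fit, bg(120), bg(120), "TGACGTCATC",
                          "CACGTGGCTA", pos_a = 40)
  expect_equal(nrow(res$positions), 120 %/% 10)
  expect_true(res$P_m %in% res$positions$pos)
  expect_true(is.finite(res$A_solo) && is.finite(res$background))
  # planted AND grammar: the response with both motifs beats the
  # background-median placement response
  expect_gt(max(res$positions$AB), stats::median(res$positions$B_solo))
  expect_error(cooperation_scan(fit, bg(120), bg(120), "TGACGTCATC",
                                strrep("A", 200)), "longer")
})

test_that("saturation mutagenesis is exact under a stub and seeded", {
  set.seed(29)
  distal <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  partners <- replicate(6, paste(sample(c("A", "C", "G", "T"), 120, TRUE),
                                 collapse = ""), simplify = FALSE)
  # constant stub ignores sequence -> delta identically zero
  res <- saturation_mutation(stub_model(0.9), distal, partners,
                             motif_start = 50, motif_end = 59,
                             flank = 20, n_draws = 10, seed = 5)
  expect_equal(res$baseline_degree, 6)
  expect_true(all(res$draws$delta == 0))
  expect_equal(res$mean_delta, 0)
  # same seed -> identical draw sequence (checked via a recording stub)
  seen <- new.env(); seen$x <- list()
  rec <- function(x) { seen$x <- c(seen$x, list(x)); rep(0.1, length(x)) }
  saturation_mutation(rec, distal, partners, 50, 59, flank = 10,
                      n_draws = 3, seed = 11)
  first <- seen$x; seen$x <- list()
  saturation_mutation(rec, distal, partners, 50, 59, flank = 10,
                      n_draws = 3, seed = 11)
  expect_identical(seen$x, first)
  expect_warning(
    saturation_mutation(stub_model(0.9), distal, partners, 2, 10,
                        flank = 50, n_draws = 1, seed = 1), "clipped")
})

test_that("enrichment p-values behave at the planted and saturated extremes", {
  lens <- c(chr1 = 20000L)
  features <- data.frame(chrom = "chr1", start = c(1000, 5000),
                         end = c(1600, 5600))
  regions <- data.frame(chrom = "chr1", start = seq(500, 9500, by = 1000),
                        end = seq(800, 9800, by = 1000))
  regions <- rbind(regions,
                   data.frame(chrom = "chr1", start = c(1000, 5000),
                              end = c(1600, 5600)))
  # motifs planted inside the features
  motifs <- data.frame(chrom = "chr1",
                       start = c(1100, 1300, 5100, 5300, 5500),
                       end = c(1110, 1310, 5110, 5310, 5510))
  res <- motif_enrichment(motifs, features, regions, lens,
                          n_reps = 100, seed = 3)
  expect_equal(nrow(res), 2)
  expect_equal(res$observed, c(5, 5))
  expect_lte(res$p_value[res$scheme == "interaction"], 0.02)
  # features covering the whole genome -> controls saturate, p ~ 1
  all_feat <- data.frame(chrom = "chr1", start = 0, end = 20000)
  res2 <- motif_enrichment(motifs, all_feat, regions, lens,
                           n_reps = 50, seed = 3)
  expect_true(all(res2$p_value > 0.9))
  # seed changes the controls, never the observed count
  res3 <- motif_enrichment(motifs, features, regions, lens,
                           n_reps = 20, seed = 99)
  expect_equal(res3$observed, res$observed)
})

test_that("motif clustering separates planted seed families", {
  # adjusted Rand index, computed from the contingency table
  ari <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sij <- sum(comb2(tab))
    si <- sum(comb2(rowSums(tab)))
    sj <- sum(comb2(colSums(tab)))
    n <- comb2(sum(tab))
    (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
  }
  set.seed(37)
  noisy <- function(seedmot, n) vapply(seq_len(n), function(i) {
    ch <- strsplit(seedmot, "")[[1]]
    j <- sample(length(ch), 1)
    ch[j] <- sample(c("A", "C", "G", "T"), 1)
    paste(ch, collapse = "")
  }, "")
  m1 <- noisy("TGACGTCATG", 10)
  m2 <- noisy("CCCGGAATTC", 10)
  truth <- rep(1:2, each = 10)
  cl <- cluster_motifs(c(m1, m2), n_clusters = 2)
  expect_equal(ari(cl$assignments, truth), 1)
  expect_true(all(vapply(cl$pwm, function(p)
    max(abs(colSums(p) - 1)), 0) < 1e-12))
  # n_clusters == n -> singletons, consensus equals each motif
  cl2 <- cluster_motifs(c("ACGTACGT", "TTTTAAAA"), n_clusters = 2)
  expect_equal(sort(cl2$consensus), sort(c("ACGTACGT", "TTTTAAAA")))
  expect_error(cluster_motifs(c("ACGT"), 2), "exceeds")
})

test_that("MEME export writes well-formed letter-probability blocks", {
  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.6, 0.2, 0.1), 4, 2,
                dimnames = list(c("A", "T", "G", "C"), NULL))
  f <- tempfile(fileext = ".meme")
  write_meme(list(pwm), f, names = "test_motif")
  txt <- readLines(f)
  expect_true(any(grepl("^MOTIF test_motif$", txt)))
  expect_true(any(grepl("alength= 4 w= 2", txt)))
  # first data row in A C G T order: A=.7 C=.1 G=.1 T=.1
  row1 <- txt[grep("letter-probability", txt) + 1]
  expect_equal(scan(text = row1, quiet = TRUE), c(0.7, 0.1, 0.1, 0.1))
})
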