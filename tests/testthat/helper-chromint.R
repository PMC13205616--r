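# Shared fixtures, built in code.

# Deterministic toy chromosome: repeating ACGT pattern is avoided; use a
# seeded random sequence so substrings are unique enough for identity
# checks.
toy_chrom <- function(len, seed = 7) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

toy_genome <- function(len = 20000, seed = 7) {
  genome_ref(c(chr1 = toy_chrom(len, seed)))
}

# A constant-probability stub model usable wherever scan/attribution
# functions accept a scoring function.
stub_model <- function(p) function(x) rep(p, length(x))

rc <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# One small trained model shared across attribution tests (trained once
# per test run).  An easy single-anchor-pair grammar at short anchors
# keeps this quick while giving genuinely informative gradients.
.chromint_test_cache <- new.env(parent = emptyenv())

cached_fit <- function() {
  if (!is.null(.chromint_test_cache$fit)) return(.chromint_test_cache$fit)
  sc <- synth_config(n_pairs = 600L, anchor_len = 120L,
                     motif_pairs = list(c("TGACGTCATC", "CACGTGGCTA")),
                     positional_mean = 60, positional_sd = 15,
                     label_noise = 0, seed = 42L)
  d <- generate_pairs(sc)
  cfg <- ctci_config(input_len = 240L, augment_shift = 30L,
                     epochs = 50L, seed = 7L)
  fit <- ctci_fit(d$x, d$labels, cfg, validation = 0.1, patience = 999L)
  .chromint_test_cache$fit <- fit
  .chromint_test_cache$data <- d
  fit
}

cached_fit_data <- function() {
  cached_fit()
  .chromint_test_cache$data
}
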