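# Shared fixtures, built in code and memoized so expensive objects are
# constructed once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small synthetic dataset at the generator's default signal settings.
tiny_ds <- function(n = 400L, seed = 1L, ...) {
  memo(paste0("ds_", n, "_", seed, "_", paste(c(...), collapse = "_")),
       synthesize_patches(gen_params(n = n, seed = seed, ...)))
}

# A deterministic pseudo-image (values in [0, 1], not all equal).
test_image <- function(side = 96L, channels = 3L, seed = 99L) {
  set.seed(seed)
  array(stats::runif(side * side * channels), dim = c(side, side, channels))
}

# Brute-force AUC oracle: exhaustive enumeration of all positive-negative
# pairs, ties counted one half.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
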