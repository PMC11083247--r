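# Shared fixtures, built in code at test time.

# Noise-free generator: collapsed TIS reproduce the marker table exactly.
noiseless_params <- function()
  generator_params(noise_sd = 0, lot_sd = 0)

# One default synthetic study + its TIS matrix, built once per test run.
.fixture_env <- new.env(parent = emptyenv())
cached_study_tm <- function() {
  if (is.null(.fixture_env$tm)) {
    .fixture_env$study <- make_study(seed = 2024L)
    .fixture_env$tm <- study_tis_matrix(.fixture_env$study)
  }
  .fixture_env$tm
}

# A small normalized TIS with a given value vector.
toy_tis <- function(values, mz = seq(50, length.out = length(values)),
                    sample_id = "toy", normalized = FALSE)
  tis(mz, values, normalized = normalized, sample_id = sample_id)

# Brute-force agglomerative clustering on raw points: recompute every
# inter-cluster distance from scratch at each step (no Lance-Williams
# update), for cross-checking hclust-based results.
naive_agglomeration <- function(points, linkage = c("average", "complete",
                                                    "single")) {
  linkage <- match.arg(linkage)
  clusters <- as.list(seq_len(nrow(points)))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    d <- as.matrix(stats::dist(points))[a, b, drop = FALSE]
    switch(linkage, average = mean(d), complete = max(d), single = min(d))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- cluster_dist(clusters[[i]], clusters[[j]])
      if (d < bd) { bd <- d; best <- c(j, i) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
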