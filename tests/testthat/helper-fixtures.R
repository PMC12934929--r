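# Shared fixtures: all built in code, nothing read from disk except the
# bundled genome specs.

toy_genome <- function(system = "XY") {
  ids <- if (system == "XY") c("A1", "A2", "X", "Y") else c("A1", "A2", "Z", "W")
  genome_spec(id = ids,
              length = c(100L, 200L, 150L, 50L),
              role = c("autosome", "autosome", "homogametic", "heterogametic"),
              system = system)
}

# idxstats object from a named vector of mapped counts, lengths from a spec
toy_idxstats <- function(counts, spec, sample_id = "s1", extra = NULL) {
  ch <- spec$chromosomes
  tab <- data.frame(id = c(ch$id, "*"),
                    length = c(ch$length, 0),
                    mapped = c(unname(counts[ch$id]), 0),
                    unmapped = 0,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) tab <- rbind(tab, extra)
  hostsex:::new_idxstats(sample_id, tab)
}

# small trained model on the human-like genome, memoized across test files
hs_cache <- new.env(parent = emptyenv())

small_model <- function() {
  if (is.null(hs_cache$model)) {
    hs_cache$model <- hostsex_train_default(example_genome("human"),
                                            seed = 101L, replicates = 60L)
  }
  hs_cache$model
}

# brute-force product-Gaussian kernel sum, deliberately loop-based
brute_kde_density <- function(points, h, qx, qy) {
  out <- numeric(length(qx))
  for (i in seq_along(qx)) {
    s <- 0
    for (j in seq_len(nrow(points))) {
      s <- s + exp(-0.5 * ((qx[i] - points[j, 1]) / h[1])^2
                   - 0.5 * ((qy[i] - points[j, 2]) / h[2])^2)
    }
    out[i] <- s / (nrow(points) * 2 * pi * h[1] * h[2])
  }
  out
}
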