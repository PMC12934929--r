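test_that("coverage is reads per base pair", {
  expect_equal(coverage(10, 100), 0.1)
  expect_equal(coverage(0, 100), 0)
  expect_equal(coverage(3, 7), 3 / 7)
})

test_that("Rx and Ry reproduce their canonical worked examples", {
  spec <- genome_spec(c("A1", "A2", "X", "Y"), c(100, 200, 150, 50),
                      c("autosome", "autosome", "homogametic", "heterogametic"))
  female_like <- toy_idxstats(c(A1 = 10, A2 = 20, X = 15, Y = 0), spec)
  m <- compute_metrics(female_like, spec)
  expect_equal(m$rx, 1.0)     # equal per-copy coverage, XX-like
  expect_equal(m$ry, 0.0)
  expect_equal(m$total_host_reads, 45)

  male_like <- toy_idxstats(c(A1 = 10, A2 = 20, X = 7, Y = 0), spec)
  expect_equal(compute_rx(male_like, spec), (7 / 150) / 0.1,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(round(compute_rx(male_like, spec), 4), 0.4667,
               ignore_attr = TRUE)

  expect_equal(compute_ry(toy_idxstats(c(A1 = 0, A2 = 0, X = 90, Y = 10), spec),
                          spec), 0.1)
  expect_equal(compute_ry(toy_idxstats(c(A1 = 0, A2 = 0, X = 50, Y = 0), spec),
                          spec), 0.0)
  expect_true(is.na(compute_ry(toy_idxstats(c(A1 = 9, A2 = 9, X = 0, Y = 0),
                                            spec), spec)))
})

test_that("Rx matches an explicit loop-based re-computation", {
  set.seed(23)
  spec <- example_genome("human")
  ch <- spec$chromosomes
  for (rep in 1:5) {
    counts <- stats::setNames(rpois(24, lambda = 300), ch$id)
    x <- toy_idxstats(counts, spec)
    # naive oracle: explicit loop over autosomes
    covx <- counts[["chrX"]] / ch$effective_length[ch$id == "chrX"]
    acc <- 0; n <- 0
    for (i in which(ch$role == "autosome")) {
      cov_a <- counts[[ch$id[i]]] / ch$effective_length[i]
      if (cov_a > 0) { acc <- acc + covx / cov_a; n <- n + 1 }
    }
    expect_equal(as.numeric(compute_rx(x, spec)), acc / n, tolerance = 1e-12)
  }
})

test_that("undefined-metric policy: autosome dropout, zero X, minimums", {
  spec <- example_genome("human")
  ch <- spec$chromosomes
  counts <- stats::setNames(rep(100, 24), ch$id)
  counts["chr1"] <- 0   # dropped from the mean, n reduced
  x <- toy_idxstats(counts, spec)
  rx <- compute_rx(x, spec)
  expect_equal(attr(rx, "n_autosomes_used"), 21L)
  expect_false(is.na(rx))

  counts[paste0("chr", 1:18)] <- 0   # only 4 usable autosomes < 5
  rx <- compute_rx(toy_idxstats(counts, spec), spec)
  expect_true(is.na(rx))
  expect_equal(attr(rx, "n_autosomes_used"), 4L)

  # zero homogametic coverage is a defined Rx of 0, not NA
  counts <- stats::setNames(rep(100, 24), ch$id)
  counts["chrX"] <- 0
  expect_equal(as.numeric(compute_rx(toy_idxstats(counts, spec), spec)), 0)

  # toy genomes: the minimum is capped at the spec's autosome count
  toy <- toy_genome()
  expect_false(is.na(compute_rx(toy_idxstats(c(A1 = 10, A2 = 20, X = 15, Y = 0),
                                             toy), toy)))
})

test_that("Ry and Rx are scale-invariant and Ry increases in Y reads", {
  spec <- toy_genome()
  base <- c(A1 = 30, A2 = 60, X = 20, Y = 5)
  m1 <- compute_metrics(toy_idxstats(base, spec), spec)
  m7 <- compute_metrics(toy_idxstats(base * 7, spec), spec)
  expect_equal(m1$rx, m7$rx, tolerance = 1e-12)
  expect_equal(m1$ry, m7$ry, tolerance = 1e-12)

  ry <- vapply(0:20, function(y)
    compute_ry(toy_idxstats(c(A1 = 1, A2 = 1, X = 40, Y = y), spec), spec), 0)
  expect_true(all(diff(ry) > 0))
})

test_that("relabeling XY as ZW leaves (rx, ry) identical with swapped sexes", {
  xy <- toy_genome("XY"); zw <- toy_genome("ZW")
  counts <- c(30, 60, 20, 5)
  mx <- compute_metrics(toy_idxstats(stats::setNames(counts, xy$chromosomes$id), xy), xy)
  mz <- compute_metrics(toy_idxstats(stats::setNames(counts, zw$chromosomes$id), zw), zw)
  expect_equal(mx$rx, mz$rx)
  expect_equal(mx$ry, mz$ry)
  # downstream labels swap: same role, opposite sex name
  expect_equal(unname(sex_labels("XY")["heterogametic"]), "male")
  expect_equal(unname(sex_labels("ZW")["heterogametic"]), "female")
})

test_that("vectorized grid metrics equal per-sample computation", {
  spec <- example_genome("human")
  sim <- simulate_grid(sim_params(spec, depths = c(200L, 5000L),
                                  replicates = 10L, seed = 5))
  vec <- sim_metrics(sim)
  for (i in seq_len(nrow(vec))) {
    one <- compute_metrics(as_idxstats(sim, i), spec)
    expect_equal(vec$rx[i], one$rx, tolerance = 1e-12)
    expect_equal(vec$ry[i], one$ry, tolerance = 1e-12)
    expect_equal(vec$total_host_reads[i], one$total_host_reads)
    expect_equal(vec$n_autosomes_used[i], one$n_autosomes_used)
  }
})

test_that("noiseless high-depth samples recover canonical metric values", {
  spec <- example_genome("human")
  p <- sim_params(spec, depths = 1000000L, replicates = 300L, seed = 31,
                  mismap_rate = 0, bias_sd = 0)
  m <- sim_metrics(simulate_grid(p))
  fem <- m[m$sex == "female", ]; mal <- m[m$sex == "male", ]
  se <- function(v) sd(v) / sqrt(length(v))
  expect_lt(abs(mean(fem$rx) - 1.0), 3 * se(fem$rx))
  expect_true(all(fem$ry == 0))
  expect_lt(abs(mean(mal$rx) - 0.5), 3 * se(mal$rx))
  ch <- spec$chromosomes
  ry_expect <- ch$effective_length[ch$role == "heterogametic"] /
    sum(ch$effective_length[ch$role != "autosome"])
  expect_lt(abs(mean(mal$ry) - ry_expect), 3 * se(mal$ry))

  # at moderate depth the ratio estimator keeps a small positive Jensen
  # bias (~(1-w)/(depth*w) per autosome), so only a coarse band holds
  p2 <- sim_params(spec, depths = 10000L, replicates = 300L, seed = 32,
                   mismap_rate = 0, bias_sd = 0)
  m2 <- sim_metrics(simulate_grid(p2))
  expect_lt(abs(mean(m2$rx[m2$sex == "female"]) - 1.0), 0.01)
})
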