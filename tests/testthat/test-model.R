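# training data generator for small classifier tests: two well-separated
# (rx, ry) clouds mimicking XX and XY samples
toy_training <- function(n = 200, seed = 9) {
  set.seed(seed)
  data.frame(
    rx = c(rnorm(n, 1.0, 0.08), rnorm(n, 0.5, 0.08)),
    ry = c(abs(rnorm(n, 0, 0.004)), rnorm(n, 0.25, 0.05)),
    sex = rep(c("female", "male"), each = n))
}

test_that("training separates the classes at canonical points", {
  m <- hostsex_fit(toy_training(), system = "XY")
  f_homo <- kde_density(m$kde_homogametic, 1.0, 0.0)
  f_het <- kde_density(m$kde_heterogametic, 1.0, 0.0)
  expect_gt(f_homo, f_het)
  expect_gt(kde_density(m$kde_heterogametic, 0.5, 0.25),
            kde_density(m$kde_homogametic, 0.5, 0.25))
})

test_that("training requires both classes and finite metrics", {
  d <- toy_training()
  expect_error(hostsex_fit(d[d$sex == "female", ]),
               class = "hostsex_training_error")
  d2 <- d
  d2$rx[d2$sex == "male"] <- NA
  expect_error(suppressMessages(hostsex_fit(d2)),
               class = "hostsex_training_error")
  d3 <- d
  d3$rx[1:5] <- NA
  expect_message(m <- hostsex_fit(d3), "dropping 5")
  expect_equal(m$n_dropped, 5L)
  expect_equal(m$kde_homogametic$n, 195L)
  expect_error(hostsex_fit(d, prior_homogametic = 1),
               class = "hostsex_training_error")
})

test_that("posteriors follow Bayes' rule with the class priors", {
  m <- hostsex_fit(toy_training(), system = "XY")
  set.seed(13)
  q <- data.frame(rx = runif(30, 0.3, 1.2), ry = runif(30, 0, 0.35))
  pred <- predict(m, q, threshold = 0.8)
  f_f <- kde_density(m$kde_homogametic, q$rx, q$ry)
  f_m <- kde_density(m$kde_heterogametic, q$rx, q$ry)
  manual <- 0.5 * f_f / (0.5 * f_f + 0.5 * f_m)
  ok <- f_f + f_m > 0
  expect_equal(pred$posterior_female[ok], manual[ok], tolerance = 1e-9)
  expect_equal(pred$posterior_female + pred$posterior_male,
               rep(1, 30), tolerance = 1e-12)
  # calls respect the threshold on the max posterior
  called <- pred$call %in% c("female", "male")
  expect_true(all(pred$posterior[called] >= 0.8))
  expect_true(all(pred$posterior[pred$call == "uncertain"] < 0.8 |
                    pred$posterior[pred$call == "uncertain"] == 0.5))
})

test_that("equal densities give 0.5 posteriors and an uncertain call", {
  set.seed(12)
  cloud <- data.frame(rx = rnorm(100, 0.8, 0.1), ry = abs(rnorm(100, 0.1, 0.03)))
  dd <- rbind(transform(cloud, sex = "female"), transform(cloud, sex = "male"))
  m <- hostsex_fit(dd)  # identical training sets for both classes
  pred <- predict(m, data.frame(rx = c(0.9, 0.6), ry = c(0.05, 0.1)))
  expect_equal(pred$posterior_female, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(as.character(pred$call), c("uncertain", "uncertain"))
})

test_that("undefined metrics and out-of-support points abstain at 0.5/0.5", {
  m <- hostsex_fit(toy_training())
  pred <- predict(m, data.frame(rx = c(NA, 50), ry = c(0.1, 9))) # 50,9 is far out
  expect_equal(as.character(pred$call), c("uncertain", "uncertain"))
  expect_equal(pred$posterior_female, c(0.5, 0.5))
  expect_equal(pred$posterior_male, c(0.5, 0.5))
})

test_that("samples below the read cutoff are insufficient_reads", {
  m <- hostsex_fit(toy_training())
  q <- data.frame(rx = c(1, 1), ry = c(0, 0), total_host_reads = c(150, 50))
  pred <- predict(m, q, min_reads = 100)
  expect_equal(as.character(pred$call), c("female", "insufficient_reads"))
  expect_true(is.na(pred$posterior[2]))
})

test_that("threshold is validated and monotone in abstentions", {
  m <- hostsex_fit(toy_training())
  expect_error(predict(m, data.frame(rx = 1, ry = 0), threshold = 0.5),
               class = "hostsex_config_error")
  expect_error(predict(m, data.frame(rx = 1, ry = 0), threshold = 1.2),
               class = "hostsex_config_error")
  set.seed(17)
  q <- data.frame(rx = runif(300, 0.3, 1.2), ry = runif(300, 0, 0.35))
  prev_uncertain <- NULL
  for (th in c(0.51, 0.7, 0.8, 0.95, 0.99)) {
    pred <- predict(m, q, threshold = th)
    unc <- which(pred$call == "uncertain")
    if (!is.null(prev_uncertain)) {
      # raising the threshold never converts uncertain into a sex call
      expect_true(all(prev_uncertain %in% unc))
    }
    prev_uncertain <- unc
  }
})

test_that("posteriors are monotone in the prior, which dominates in the limit", {
  d <- toy_training()
  m_eq <- hostsex_fit(d)
  m_f <- hostsex_fit(d, prior_homogametic = 1 - 1e-12)
  m_m <- hostsex_fit(d, prior_homogametic = 1e-12)
  set.seed(19)
  q <- data.frame(rx = runif(50, 0.4, 1.1), ry = runif(50, 0, 0.3))
  p_eq <- predict(m_eq, q, threshold = 0.8)
  pf <- predict(m_f, q, threshold = 0.8)
  pm <- predict(m_m, q, threshold = 0.8)
  supported <- !is.na(p_eq$posterior) & p_eq$posterior != 0.5
  # a larger homogametic prior never lowers the homogametic posterior
  expect_true(all(pf$posterior_female[supported] >=
                    p_eq$posterior_female[supported]))
  expect_true(all(pm$posterior_female[supported] <=
                    p_eq$posterior_female[supported]))
  # wherever the log likelihood ratio is smaller than the prior log odds
  # (log(1e12) ~ 27.6 nats) by more than the threshold logit, the extreme prior
  # decides the call; scan a dense transect across the decision boundary
  qb <- data.frame(rx = seq(0.4, 1.1, by = 0.001), ry = 0.02)
  lr <- kde_logdensity(m_eq$kde_homogametic, qb$rx, qb$ry) -
    kde_logdensity(m_eq$kde_heterogametic, qb$rx, qb$ry)
  near <- abs(lr) < 25
  expect_gt(sum(near), 0)
  pfb <- predict(m_f, qb, threshold = 0.8)
  pmb <- predict(m_m, qb, threshold = 0.8)
  expect_true(all(pfb$call[near] == "female"))
  expect_true(all(pmb$call[near] == "male"))
})

test_that("swapping training labels swaps the posteriors exactly", {
  d <- toy_training()
  swapped <- transform(d, sex = ifelse(sex == "female", "male", "female"))
  m1 <- hostsex_fit(d)
  m2 <- hostsex_fit(swapped)
  q <- data.frame(rx = runif(40, 0.3, 1.2), ry = runif(40, 0, 0.3))
  p1 <- predict(m1, q)
  p2 <- predict(m2, q)
  expect_equal(p1$posterior_female, p2$posterior_male, tolerance = 1e-12)
  expect_equal(p1$posterior_male, p2$posterior_female, tolerance = 1e-12)
})

test_that("ZW systems map the homogametic class to male", {
  d <- toy_training()
  lab <- ifelse(d$sex == "female", "male", "female")  # ZZ male looks XX-like
  mzw <- hostsex_fit(transform(d, sex = lab), system = "ZW")
  pred <- predict(mzw, data.frame(rx = c(1.0, 0.5), ry = c(0.0, 0.25)))
  expect_equal(as.character(pred$call), c("male", "female"))
})

test_that("models serialize and reload with identical posteriors", {
  m <- hostsex_fit(toy_training(), seed = 77)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hostsex_model(m, path)
  m2 <- read_hostsex_model(path)
  expect_identical(m2$kde_homogametic$points, m$kde_homogametic$points)
  expect_identical(m2$kde_homogametic$bandwidth, m$kde_homogametic$bandwidth)
  expect_identical(m2$seed, 77L)
  set.seed(29)
  q <- data.frame(rx = runif(100, 0, 1.5), ry = runif(100, 0, 0.4))
  expect_identical(predict(m, q), predict(m2, q))
  # a second write is byte-identical (deterministic serialization)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_hostsex_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))

  bad <- readLines(path)
  bad[1] <- "hostsex_model\t99"
  writeLines(bad, path2)
  expect_error(read_hostsex_model(path2),
               class = "hostsex_model_version_error")
})

test_that("threshold sweep rows equal independent per-threshold scoring", {
  set.seed(57)
  spec <- example_genome("human")
  m <- small_model()
  sim <- simulate_grid(sim_params(spec, depths = c(150L, 1000L),
                                  replicates = 50L, seed = 404))
  metrics <- sim_metrics(sim)
  ths <- c(0.51, 0.8, 0.99)
  tab <- sweep_threshold(m, metrics, metrics$sex, thresholds = ths)
  for (k in seq_along(ths)) {
    pred <- predict(m, metrics, threshold = ths[k])
    ev <- score_calls(pred$call, metrics$sex, mode = "paper")
    expect_equal(tab$accuracy[k], ev$overall$accuracy)
    expect_equal(tab$n_uncertain[k], ev$overall$n_uncertain)
    expect_equal(tab$f1_male[k], ev$per_class["male", "f1"])
    expect_equal(tab$recall_female[k], ev$per_class["female", "recall"])
  }
  expect_true(all(diff(tab$n_uncertain) >= 0))
})

test_that("print, summary and plot methods run", {
  m <- hostsex_fit(toy_training())
  expect_output(print(m), "hostsex_model")
  s <- summary(m)
  expect_s3_class(s, "summary.hostsex_model")
  expect_output(print(s), "KDE sex classifier")
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path, width = 400, height = 400)
  expect_silent(plot(m, grid_n = 25))
  grDevices::dev.off()
  expect_true(file.size(path) > 0)
})
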