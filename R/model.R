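# Per-sex KDE likelihood models and Bayesian posterior sex calls.

.hs_call_levels <- c("female", "male", "uncertain", "insufficient_reads")

#' Fit the two-class KDE sex classifier
#'
#' Trains one 2-D Gaussian kernel density estimator over (Rx, Ry) per sex.
#' At prediction time a sample's (Rx, Ry) is evaluated under both densities,
#' the likelihoods are combined with the class priors (equal by default), and
#' the posterior for the more likely sex is compared with the call threshold;
#' below it the sample is reported `uncertain`.
#'
#' Training samples with undefined (non-finite) Rx or Ry are excluded, with
#' the dropped count recorded in the model. Training pools all read depths
#' into the two sex-specific models.
#'
#' @param data data frame with numeric columns `rx`, `ry` and a `sex` column
#'   (`"female"`/`"male"`).
#' @param system `"XY"` or `"ZW"`; determines which sex is the
#'   homogametic-pair class (XX female / ZZ male).
#' @param bandwidth `"silverman"` (per-dimension rule of thumb, the default)
#'   or a positive length-2 numeric vector used for both classes.
#' @param bw_floor minimum bandwidth per dimension; keeps the near-degenerate
#'   Ry dimension of the homogametic-pair class from collapsing.
#' @param prior_homogametic prior probability of the homogametic-pair sex,
#'   in (0, 1). Default 0.5 (uniform prior).
#' @param density_floor if both class densities at a query fall below this
#'   value the sample is out of the model's support and the call is
#'   `uncertain` with posteriors reported as 0.5/0.5.
#' @param seed optional integer recorded for provenance (e.g. the simulator
#'   seed that produced the training data); not used in fitting.
#' @return Object of class `hostsex_model`.
#' @seealso [predict.hostsex_model()], [hostsex_train_default()],
#'   [write_hostsex_model()]
#' @export
hostsex_fit <- function(data, system = c("XY", "ZW"),
                        bandwidth = "silverman", bw_floor = 1e-4,
                        prior_homogametic = 0.5, density_floor = 1e-300,
                        seed = NULL) {
  system <- match.arg(system)
  stopifnot(is.data.frame(data), all(c("rx", "ry", "sex") %in% names(data)))
  if (!(prior_homogametic > 0 && prior_homogametic < 1))
    hs_error("prior_homogametic must lie strictly in (0, 1)",
             "hostsex_training_error")
  lab <- sex_labels(system)
  bad <- !is.finite(data$rx) | !is.finite(data$ry)
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    message(sprintf("dropping %d training sample(s) with undefined rx or ry",
                    n_dropped))
    data <- data[!bad, , drop = FALSE]
  }
  pts <- function(role) {
    sel <- data$sex == lab[[role]]
    if (sum(sel) < 2L)
      hs_error(sprintf("fewer than 2 usable training samples for the %s (%s) class",
                       role, lab[[role]]),
               "hostsex_training_error")
    cbind(data$rx[sel], data$ry[sel])
  }
  structure(list(
    system = system,
    kde_homogametic = fit_kde(pts("homogametic"), bandwidth, bw_floor),
    kde_heterogametic = fit_kde(pts("heterogametic"), bandwidth, bw_floor),
    prior_homogametic = prior_homogametic,
    density_floor = density_floor,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n_dropped = n_dropped,
    format_version = 1L
  ), class = "hostsex_model")
}

#' @export
print.hostsex_model <- function(x, ...) {
  lab <- sex_labels(x$system)
  cat(sprintf("<hostsex_model> %s system\n", x$system))
  cat(sprintf("  homogametic (%s): %d points, bandwidth (%.4g, %.4g)\n",
              lab["homogametic"], x$kde_homogametic$n,
              x$kde_homogametic$bandwidth[1], x$kde_homogametic$bandwidth[2]))
  cat(sprintf("  heterogametic (%s): %d points, bandwidth (%.4g, %.4g)\n",
              lab["heterogametic"], x$kde_heterogametic$n,
              x$kde_heterogametic$bandwidth[1], x$kde_heterogametic$bandwidth[2]))
  cat(sprintf("  prior (homogametic): %.3g\n", x$prior_homogametic))
  invisible(x)
}

#' @export
summary.hostsex_model <- function(object, ...) {
  lab <- sex_labels(object$system)
  mk <- function(kde, role) {
    data.frame(class = unname(lab[role]), role = role, n = kde$n,
               bw_rx = kde$bandwidth[1], bw_ry = kde$bandwidth[2],
               mean_rx = mean(kde$points[, 1]), mean_ry = mean(kde$points[, 2]))
  }
  out <- rbind(mk(object$kde_homogametic, "homogametic"),
               mk(object$kde_heterogametic, "heterogametic"))
  attr(out, "system") <- object$system
  attr(out, "n_dropped") <- object$n_dropped
  class(out) <- c("summary.hostsex_model", "data.frame")
  out
}

#' @export
print.summary.hostsex_model <- function(x, ...) {
  cat(sprintf("KDE sex classifier (%s system)\n", attr(x, "system")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (attr(x, "n_dropped") > 0)
    cat(sprintf("(%d training sample(s) dropped for undefined metrics)\n",
                attr(x, "n_dropped")))
  invisible(x)
}

#' Posterior sex calls for new samples
#'
#' Evaluates each sample's (Rx, Ry) under both per-sex kernel densities,
#' forms posteriors `p_s = prior_s * f_s / (prior_f * f_f + prior_m * f_m)`,
#' and calls the more probable sex when its posterior reaches `threshold`,
#' otherwise `uncertain`. Samples with undefined Rx or Ry, or whose point
#' lies outside the support of both densities (both below the model's
#' density floor), are `uncertain` with posteriors reported as 0.5/0.5.
#' If `newdata` carries a `total_host_reads` column, samples below
#' `min_reads` are reported `insufficient_reads` instead of being classified.
#'
#' @param object a [hostsex_fit()] model.
#' @param newdata data frame with columns `rx` and `ry` (e.g. from
#'   [compute_metrics()]); optional `sample_id` and `total_host_reads`.
#' @param threshold posterior call threshold in (0.5, 1]; default 0.80.
#' @param min_reads minimum host reads required to attempt a call;
#'   default 100.
#' @param ... unused.
#' @return Data frame with columns `sample_id` (if supplied),
#'   `total_host_reads` (if supplied), `rx`, `ry`, `posterior_female`,
#'   `posterior_male`, `posterior` (the larger of the two), `call`.
#' @export
predict.hostsex_model <- function(object, newdata, threshold = 0.80,
                                  min_reads = 100L, ...) {
  stopifnot(is.data.frame(newdata), all(c("rx", "ry") %in% names(newdata)))
  check_threshold(threshold)
  lab <- sex_labels(object$system)
  rx <- as.numeric(newdata$rx); ry <- as.numeric(newdata$ry)
  defined <- is.finite(rx) & is.finite(ry)
  lf_homo <- lf_het <- rep(-Inf, length(rx))
  lf_homo[defined] <- kde_logdensity(object$kde_homogametic,
                                     rx[defined], ry[defined])
  lf_het[defined] <- kde_logdensity(object$kde_heterogametic,
                                    rx[defined], ry[defined])
  floor_log <- log(object$density_floor)
  supported <- defined & (lf_homo >= floor_log | lf_het >= floor_log)
  lp_homo <- log(object$prior_homogametic)
  lp_het <- log1p(-object$prior_homogametic)
  post_homo <- rep(0.5, length(rx))
  post_homo[supported] <- stats::plogis((lf_homo + lp_homo - lf_het - lp_het)[supported])
  post <- data.frame(female = NA_real_, male = NA_real_)[rep(1, length(rx)), ,
                                                         drop = FALSE]
  post[[lab[["homogametic"]]]] <- post_homo
  post[[lab[["heterogametic"]]]] <- 1 - post_homo
  out <- data.frame(rx = rx, ry = ry,
                    posterior_female = post$female,
                    posterior_male = post$male,
                    stringsAsFactors = FALSE)
  out$posterior <- pmax(out$posterior_female, out$posterior_male)
  out$supported <- supported
  out <- apply_call_threshold(out, threshold)
  out$supported <- NULL
  if (!is.null(newdata$total_host_reads)) {
    out <- cbind(total_host_reads = newdata$total_host_reads, out)
    low <- newdata$total_host_reads < min_reads
    out$call[low] <- "insufficient_reads"
    out$posterior[low] <- NA_real_
    out$posterior_female[low] <- NA_real_
    out$posterior_male[low] <- NA_real_
  }
  if (!is.null(newdata$sample_id))
    out <- cbind(sample_id = newdata$sample_id, out,
                 stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

check_threshold <- function(threshold) {
  if (!(is.numeric(threshold) && length(threshold) == 1L &&
        threshold > 0.5 && threshold <= 1))
    hs_error("threshold must lie in (0.5, 1]", "hostsex_config_error")
  invisible(threshold)
}

# Re-derive calls from posteriors at a given threshold. Rows whose larger
# posterior is NA or exactly 0.5 (undefined metrics / density floor) are
# uncertain at every admissible threshold.
apply_call_threshold <- function(pred, threshold) {
  check_threshold(threshold)
  call <- rep("uncertain", nrow(pred))
  ok <- !is.na(pred$posterior) & pred$supported & pred$posterior >= threshold
  fem <- ok & pred$posterior_female >= pred$posterior_male
  call[fem] <- "female"
  call[ok & !fem] <- "male"
  pred$call <- factor(call, levels = .hs_call_levels)
  pred
}

#' Classify idxstats samples end to end
#'
#' Convenience pipeline: reads each idxstats file (or takes parsed tables),
#' computes (Rx, Ry), and produces posterior calls with the given model.
#'
#' @param samples character vector of idxstats paths, or a list of
#'   `hostsex_idxstats` objects.
#' @param spec a [genome_spec()] object.
#' @param model a [hostsex_fit()] model.
#' @param threshold posterior call threshold, default 0.80.
#' @param min_reads minimum host reads, default 100.
#' @param min_autosomes passed to [compute_rx()].
#' @return Result data frame, one row per sample (see
#'   [predict.hostsex_model()]).
#' @export
classify_samples <- function(samples, spec, model, threshold = 0.80,
                             min_reads = 100L, min_autosomes = 5L) {
  if (is.character(samples)) samples <- lapply(samples, read_idxstats)
  metrics <- do.call(rbind, lapply(samples, compute_metrics, spec = spec,
                                   min_autosomes = min_autosomes))
  stats::predict(model, metrics, threshold = threshold, min_reads = min_reads)
}

#' Precision/recall sweep over posterior thresholds
#'
#' Re-thresholds one set of posterior predictions across a grid of cutoffs
#' and scores each against ground truth, mirroring the analysis used to pick
#' the default threshold of 0.80. The abstention count is non-decreasing in
#' the threshold.
#'
#' @param model a [hostsex_fit()] model.
#' @param newdata metrics data frame (`rx`, `ry`, ...).
#' @param truth character vector of true sexes (`"female"`/`"male"`),
#'   one per row of `newdata`.
#' @param thresholds numeric vector of cutoffs in (0.5, 1].
#' @param mode recall convention passed to [score_calls()].
#' @param min_reads passed to [predict.hostsex_model()].
#' @return Data frame with one row per threshold: accuracy, per-sex
#'   precision/recall/F1, uncertainty rate and abstention count.
#' @export
sweep_threshold <- function(model, newdata, truth,
                            thresholds = seq(0.51, 0.99, by = 0.02),
                            mode = c("paper", "standard"), min_reads = 100L) {
  mode <- match.arg(mode)
  base <- stats::predict(model, newdata, threshold = 0.51,
                         min_reads = min_reads)
  # rows with NA or exactly-0.5 posteriors (undefined metrics, density
  # floor, exact ties) are uncertain at every admissible threshold
  base$supported <- !is.na(base$posterior) & base$posterior > 0.5
  rows <- lapply(thresholds, function(th) {
    pred <- apply_call_threshold(base, th)
    pred$call[base$call == "insufficient_reads"] <- "insufficient_reads"
    ev <- score_calls(pred$call, truth, mode = mode)
    data.frame(threshold = th,
               accuracy = ev$overall$accuracy,
               uncertainty_rate = ev$overall$uncertainty_rate,
               n_uncertain = ev$overall$n_uncertain,
               precision_female = ev$per_class["female", "precision"],
               recall_female = ev$per_class["female", "recall"],
               f1_female = ev$per_class["female", "f1"],
               precision_male = ev$per_class["male", "precision"],
               recall_male = ev$per_class["male", "recall"],
               f1_male = ev$per_class["male", "f1"])
  })
  do.call(rbind, rows)
}

#' Plot the fitted class densities
#'
#' Draws the training points of both classes and density contours of the two
#' KDEs over the (Rx, Ry) plane.
#'
#' @param x a [hostsex_fit()] model.
#' @param grid_n contour grid resolution per axis.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hostsex_model <- function(x, grid_n = 80, ...) {
  lab <- sex_labels(x$system)
  p1 <- x$kde_homogametic$points
  p2 <- x$kde_heterogametic$points
  all_pts <- rbind(p1, p2)
  xr <- range(all_pts[, 1]); yr <- range(all_pts[, 2])
  xr <- xr + c(-1, 1) * 0.05 * diff(xr)
  yr <- yr + c(-1, 1) * 0.05 * max(diff(yr), 0.01)
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "Rx", ylab = "Ry", ...)
  cols <- c(homogametic = "#D55E00", heterogametic = "#0072B2")
  graphics::points(p1, pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor(cols[1], 0.3))
  graphics::points(p2, pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor(cols[2], 0.3))
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  gq <- expand.grid(gx, gy)
  for (i in 1:2) {
    kde <- if (i == 1) x$kde_homogametic else x$kde_heterogametic
    z <- matrix(kde_density(kde, gq[[1]], gq[[2]]), length(gx))
    graphics::contour(gx, gy, z, add = TRUE, col = cols[i], nlevels = 6,
                      drawlabels = FALSE)
  }
  graphics::legend("topright", bty = "n", pch = 16, col = cols,
                   legend = sprintf("%s (%s)", lab, names(cols)))
  invisible(x)
}

#' Bundled pre-trained human XY model
#'
#' A compact classifier trained by the bundled simulator on the human-like
#' genome over the twelve-depth training grid with 40 replicates per
#' (depth, sex) cell, seed 20260920. Convenient for quick calls and
#' examples; for production use regenerate a full-size model with
#' `hostsex_train_default()` (1,000 replicates per cell) or the
#' `hostsex train` command.
#'
#' @return A `hostsex_model`.
#' @export
pretrained_model <- function() {
  read_hostsex_model(system.file("extdata", "model_human_xy.tsv",
                                 package = "hostsex", mustWork = TRUE))
}

#' Serialize / load a fitted model
#'
#' Versioned plain-text flat file storing the system, priors, density floor,
#' per-class bandwidths and training points, and the training seed. Doubles
#' are written with 17 significant digits so that a write/read round trip is
#' bit-equivalent. Loading a file with an unknown format version fails
#' loudly.
#'
#' @param model a [hostsex_fit()] model.
#' @param path file path.
#' @return [read_hostsex_model()] returns the model;
#'   [write_hostsex_model()] returns `path` invisibly.
#' @export
write_hostsex_model <- function(model, path) {
  stopifnot(inherits(model, "hostsex_model"))
  g <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("hostsex_model\t%d", model$format_version),
    sprintf("system\t%s", model$system),
    sprintf("prior_homogametic\t%s", g(model$prior_homogametic)),
    sprintf("density_floor\t%s", g(model$density_floor)),
    sprintf("seed\t%s", ifelse(is.na(model$seed), "NA", model$seed)),
    sprintf("n_dropped\t%d", model$n_dropped),
    sprintf("bandwidth_homogametic\t%s\t%s",
            g(model$kde_homogametic$bandwidth[1]),
            g(model$kde_homogametic$bandwidth[2])),
    sprintf("bandwidth_heterogametic\t%s\t%s",
            g(model$kde_heterogametic$bandwidth[1]),
            g(model$kde_heterogametic$bandwidth[2])),
    "class\trx\try"
  ), con)
  wpts <- function(kde, tag)
    writeLines(sprintf("%s\t%s\t%s", tag,
                       g(kde$points[, 1]), g(kde$points[, 2])), con)
  wpts(model$kde_homogametic, "homogametic")
  wpts(model$kde_heterogametic, "heterogametic")
  invisible(path)
}

#' @rdname write_hostsex_model
#' @export
read_hostsex_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  if (length(lines) < 9L || kv[[1]][1] != "hostsex_model")
    hs_error(sprintf("%s is not a hostsex model file", path),
             "hostsex_model_format_error")
  if (kv[[1]][2] != "1")
    hs_error(sprintf("unsupported model format version '%s'", kv[[1]][2]),
             "hostsex_model_version_error")
  hdr <- list()
  for (i in 2:8) hdr[[kv[[i]][1]]] <- kv[[i]][-1]
  pts <- kv[-(1:9)]
  tag <- vapply(pts, `[`, "", 1L)
  coords <- function(t) {
    sel <- pts[tag == t]
    cbind(as.numeric(vapply(sel, `[`, "", 2L)),
          as.numeric(vapply(sel, `[`, "", 3L)))
  }
  model <- structure(list(
    system = hdr$system,
    kde_homogametic = fit_kde(coords("homogametic"),
                              as.numeric(hdr$bandwidth_homogametic),
                              bw_floor = 0),
    kde_heterogametic = fit_kde(coords("heterogametic"),
                                as.numeric(hdr$bandwidth_heterogametic),
                                bw_floor = 0),
    prior_homogametic = as.numeric(hdr$prior_homogametic),
    density_floor = as.numeric(hdr$density_floor),
    seed = if (identical(hdr$seed, "NA")) NA_integer_
           else as.integer(hdr$seed),
    n_dropped = as.integer(hdr$n_dropped),
    format_version = 1L
  ), class = "hostsex_model")
  model
}
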