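# Scoring sex calls against ground truth, with a reject (abstention) option,
# plus simple fixed-threshold Rx / Ry baseline classifiers.

#' Score sex calls against ground truth
#'
#' Builds per-class confusion counts and computes accuracy, per-sex
#' precision, recall and F1, and the uncertainty rate. Abstentions
#' (`uncertain`, and `insufficient_reads`, which is counted as uncertain)
#' enter the recall denominator as false negatives. Two recall conventions
#' are provided:
#'
#' * `mode = "paper"`: recall_c = TP_c / (TP_c + FN_abstain_c), where false
#'   negatives are *only* the abstained true-c samples (miscalled samples
#'   appear as the other class's false positives but not in this
#'   denominator);
#' * `mode = "standard"`: recall_c = TP_c / (all true-c samples), the usual
#'   definition counting both abstained and miscalled samples.
#'
#' Paper-mode recall is never smaller than standard-mode recall. Precision
#' is TP_c / (TP_c + FP_c) in both modes. Ratios with a zero denominator are
#' reported as 0, and F1 is 0 when precision + recall = 0.
#'
#' @param calls factor/character vector of calls (`female`, `male`,
#'   `uncertain`, `insufficient_reads`).
#' @param truth character vector of true sexes (`female`/`male`).
#' @param mode `"paper"` or `"standard"` recall convention.
#' @return Object of class `hostsex_eval`: list with `mode`, `overall`
#'   (one-row data frame: `n_total`, `n_uncertain`, `accuracy`,
#'   `misclassification_rate`, `uncertainty_rate`) and `per_class`
#'   (data frame with rows `female`, `male`).
#' @export
score_calls <- function(calls, truth, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  calls <- as.character(calls)
  truth <- as.character(truth)
  if (length(calls) != length(truth) || anyNA(truth) ||
      !all(truth %in% c("female", "male")))
    hs_error("every call needs a ground-truth label of 'female' or 'male'",
             "hostsex_eval_error")
  abstained <- calls %in% c("uncertain", "insufficient_reads")
  per <- lapply(c(female = "female", male = "male"), function(cls) {
    other <- setdiff(c("female", "male"), cls)
    tp <- sum(truth == cls & calls == cls)
    fn_mis <- sum(truth == cls & calls == other)
    fn_abs <- sum(truth == cls & abstained)
    fp <- sum(truth == other & calls == cls)
    prec <- safe_ratio(tp, tp + fp)
    rec <- if (mode == "paper") safe_ratio(tp, tp + fn_abs)
           else safe_ratio(tp, tp + fn_abs + fn_mis)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(n_true = tp + fn_mis + fn_abs, tp = tp, fp = fp,
               fn_abstain = fn_abs, fn_miscalled = fn_mis,
               precision = prec, recall = rec, f1 = f1)
  })
  per_class <- do.call(rbind, per)
  n <- length(calls)
  overall <- data.frame(
    n_total = n,
    n_uncertain = sum(abstained),
    accuracy = safe_ratio(sum(per_class$tp), n),
    misclassification_rate = safe_ratio(sum(per_class$fn_miscalled), n),
    uncertainty_rate = safe_ratio(sum(abstained), n))
  structure(list(mode = mode, overall = overall, per_class = per_class),
            class = "hostsex_eval")
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' @export
print.hostsex_eval <- function(x, ...) {
  cat(sprintf("<hostsex_eval> mode=%s  n=%d  accuracy=%.3f  uncertain=%.3f\n",
              x$mode, x$overall$n_total, x$overall$accuracy,
              x$overall$uncertainty_rate))
  print(round(x$per_class[, c("n_true", "tp", "fp", "fn_abstain",
                              "fn_miscalled", "precision", "recall", "f1")],
              4))
  invisible(x)
}

#' Fixed-threshold baseline classifiers on Rx or Ry alone
#'
#' Context comparators for the KDE classifier: `baseline_rx()` calls the
#' homogametic-pair sex when Rx is at or above `upper` and the heterogametic
#' sex at or below `lower`; `baseline_ry()` calls the heterogametic sex at
#' or above its `upper` and the homogametic-pair sex at or below its
#' `lower`. Values in between, or undefined metrics, give `uncertain`.
#' Default cutoffs (Rx 0.8/0.6; Ry 0.075/0.016) follow conventional usage of
#' these statistics and are configurable.
#'
#' @param rx,ry numeric vectors of metric values (`NA` allowed).
#' @param system `"XY"` or `"ZW"` (maps the winning role to a sex label).
#' @param upper,lower decision cutoffs, `lower < upper`.
#' @return Factor of calls with levels `female`, `male`, `uncertain`,
#'   `insufficient_reads`.
#' @export
baseline_rx <- function(rx, system = "XY", upper = 0.8, lower = 0.6) {
  stopifnot(lower < upper)
  lab <- sex_labels(system)
  call <- rep("uncertain", length(rx))
  call[!is.na(rx) & rx >= upper] <- lab[["homogametic"]]
  call[!is.na(rx) & rx <= lower] <- lab[["heterogametic"]]
  factor(call, levels = .hs_call_levels)
}

#' @rdname baseline_rx
#' @export
baseline_ry <- function(ry, system = "XY", upper = 0.075, lower = 0.016) {
  stopifnot(lower < upper)
  lab <- sex_labels(system)
  call <- rep("uncertain", length(ry))
  call[!is.na(ry) & ry >= upper] <- lab[["heterogametic"]]
  call[!is.na(ry) & ry <= lower] <- lab[["homogametic"]]
  factor(call, levels = .hs_call_levels)
}

#' Depth-sweep benchmark of the KDE classifier and the baselines
#'
#' Simulates an evaluation grid, classifies every sample with the fitted
#' model (and the Rx / Ry threshold baselines), and tabulates the fraction
#' of correct, misclassified and uncertain samples per depth plus pooled
#' per-sex metrics. The evaluation grid must be simulated with a seed
#' disjoint from the training seed; by convention use
#' `training seed + eval_seed_offset`.
#'
#' @param model a [hostsex_fit()] model.
#' @param params a [sim_params()] object describing the evaluation grid.
#' @param threshold posterior call threshold, default 0.80.
#' @param min_reads minimum host reads, default 100.
#' @param min_autosomes passed to the Rx calculation.
#' @return List of class `hostsex_benchmark`: `per_depth` (data frame:
#'   depth, method, fractions correct / misclassified / uncertain),
#'   `pooled` (named list of [score_calls()] reports per method, paper
#'   mode), `pooled_standard` (same, standard mode), `calls` (the full
#'   per-sample call table with labels).
#' @export
benchmark_depth_sweep <- function(model, params, threshold = 0.80,
                                  min_reads = 100L, min_autosomes = 5L) {
  stopifnot(inherits(model, "hostsex_model"),
            inherits(params, "hostsex_sim_params"))
  sim <- simulate_grid(params)
  metrics <- sim_metrics(sim, min_autosomes = min_autosomes)
  pred <- stats::predict(model, metrics, threshold = threshold,
                         min_reads = min_reads)
  calls <- data.frame(metrics[, c("sample_id", "sex", "depth")],
                      kde = pred$call,
                      rx_baseline = baseline_rx(metrics$rx, model$system),
                      ry_baseline = baseline_ry(metrics$ry, model$system),
                      stringsAsFactors = FALSE)
  methods <- c("kde", "rx_baseline", "ry_baseline")
  per_depth <- do.call(rbind, lapply(params$depths, function(d) {
    sel <- calls$depth == d
    do.call(rbind, lapply(methods, function(m) {
      cc <- as.character(calls[[m]][sel])
      tr <- calls$sex[sel]
      data.frame(depth = d, method = m,
                 n = sum(sel),
                 correct = mean(cc == tr),
                 misclassified = mean(cc %in% c("female", "male") & cc != tr),
                 uncertain = mean(!cc %in% c("female", "male")))
    }))
  }))
  pooled <- lapply(stats::setNames(methods, methods), function(m)
    score_calls(calls[[m]], calls$sex, mode = "paper"))
  pooled_standard <- lapply(stats::setNames(methods, methods), function(m)
    score_calls(calls[[m]], calls$sex, mode = "standard"))
  structure(list(per_depth = per_depth, pooled = pooled,
                 pooled_standard = pooled_standard, calls = calls),
            class = "hostsex_benchmark")
}

#' Default offset between training and evaluation simulator seeds
#' @return Integer offset added to the training seed to obtain the
#'   evaluation seed, guaranteeing disjoint RNG substreams.
#' @export
eval_seed_offset <- function() 777L

#' @export
print.hostsex_benchmark <- function(x, ...) {
  cat("<hostsex_benchmark>\n")
  kde <- x$per_depth[x$per_depth$method == "kde", ]
  print(transform(kde, correct = round(correct, 3),
                  misclassified = round(misclassified, 3),
                  uncertain = round(uncertain, 3)),
        row.names = FALSE)
  invisible(x)
}
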