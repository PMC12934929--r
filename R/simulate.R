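# Count-level simulator for per-chromosome mapped-read tables.
#
# The classifier consumes only per-chromosome read counts, so the count
# distribution is the sufficient statistic of a read-level simulation:
# counts are drawn from a multinomial over chromosomes with probabilities
# proportional to copy number x effective length, perturbed by (a) a small
# per-chromosome log-normal bias and (b) a small mismapping rate that moves
# a fraction of the homogametic sex-chromosome weight onto the absent
# heterogametic chromosome for homogametic-pair individuals (residual
# homologous mismapping). Depths are exact: counts sum to the target depth.

#' Benchmark and training depth grids
#'
#' The benchmark grid spans 150 to 1,000,000 host reads over nine targets;
#' the training grid adds three intermediate depths (500; 2,500; 50,000)
#' for twelve targets in total.
#'
#' @return Integer vector of target depths.
#' @export
benchmark_depths <- function() {
  c(150L, 250L, 350L, 450L, 1000L, 5000L, 10000L, 100000L, 1000000L)
}

#' @rdname benchmark_depths
#' @export
training_depths <- function() {
  sort(c(benchmark_depths(), c(500L, 2500L, 50000L)))
}

#' Simulation parameters
#'
#' @param spec a [genome_spec()] object.
#' @param depths integer vector of target read depths.
#' @param replicates replicates per (depth, sex) cell; default 1000.
#' @param seed base RNG seed; every (depth, sex) cell derives its own
#'   deterministic substream from it, so any cell can be regenerated alone.
#' @param mismap_rate fraction of a homogametic-pair individual's
#'   sex-chromosome weight reassigned to the absent heterogametic
#'   chromosome; default 0.002.
#' @param bias_sd standard deviation (log scale) of the per-chromosome
#'   multiplicative weight bias; default 0.05.
#' @return Object of class `hostsex_sim_params`.
#' @export
sim_params <- function(spec, depths = benchmark_depths(), replicates = 1000L,
                       seed = 1L, mismap_rate = 0.002, bias_sd = 0.05) {
  stopifnot(inherits(spec, "hostsex_genome"),
            all(depths >= 1), replicates >= 1,
            mismap_rate >= 0, bias_sd >= 0)
  structure(list(spec = spec, depths = as.integer(depths),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 mismap_rate = mismap_rate, bias_sd = bias_sd),
            class = "hostsex_sim_params")
}

#' Expected per-chromosome read proportions for one sex
#'
#' Weight of chromosome c is proportional to
#' `copy_number(c, sex) * effective_length(c)`, normalized to sum to one.
#' The heterogametic chromosome has weight 0 for the homogametic-pair sex
#' (before any mismapping noise is applied); ignored sequences always have
#' weight 0.
#'
#' @param spec a [genome_spec()] object.
#' @param sex `"female"` or `"male"`.
#' @return Named probability vector over the spec's chromosomes.
#' @export
chromosome_weights <- function(spec, sex = c("female", "male")) {
  sex <- match.arg(sex)
  w <- copy_number(spec, sex) * spec$chromosomes$effective_length
  w / sum(w)
}

# deterministic per-cell seed below 2^31, a function of (seed, depth, sex)
# only, so a cell regenerates identically inside or outside a full grid
cell_seed <- function(seed, depth, sex) {
  sex_code <- match(sex, c("female", "male"))
  as.integer(((seed %% 2147483647) * 333667 + as.numeric(depth) * 7919 +
                sex_code * 104729) %% 2147483629)
}

# one multinomial draw of per-chromosome counts; uses the current RNG state
draw_counts <- function(spec, sex, depth, mismap_rate = 0.002,
                        bias_sd = 0.05) {
  w <- chromosome_weights(spec, sex)
  if (bias_sd > 0)
    w <- w * exp(stats::rnorm(length(w), 0, bias_sd))
  role <- spec$chromosomes$role
  het <- which(role == "heterogametic")
  homo <- which(role == "homogametic")
  if (mismap_rate > 0 && w[het] == 0) {
    w[het] <- w[homo] * mismap_rate
    w[homo] <- w[homo] * (1 - mismap_rate)
  }
  drop(stats::rmultinom(1L, size = depth, prob = w / sum(w)))
}

#' Simulate one idxstats table
#'
#' Draws per-chromosome counts for one sample of known sex at an exact
#' target depth. Uses (and advances) the current RNG state; call
#' `set.seed()` first for reproducibility.
#'
#' @param spec a [genome_spec()] object.
#' @param sex `"female"` or `"male"`.
#' @param depth total host reads (counts sum exactly to this).
#' @param mismap_rate,bias_sd noise knobs, see [sim_params()].
#' @param sample_id identifier for the simulated sample.
#' @return A `hostsex_idxstats` object (includes the `*` sentinel row).
#' @export
simulate_sample <- function(spec, sex, depth, mismap_rate = 0.002,
                            bias_sd = 0.05, sample_id = "sim") {
  counts <- draw_counts(spec, sex, depth, mismap_rate, bias_sd)
  ch <- spec$chromosomes
  new_idxstats(sample_id,
               data.frame(id = c(ch$id, "*"),
                          length = c(ch$length, 0),
                          mapped = c(counts, 0),
                          unmapped = c(rep(0, nrow(ch)), 0),
                          stringsAsFactors = FALSE))
}

#' Simulate a labeled (depth x sex x replicate) grid
#'
#' Generates `length(depths) * 2 * replicates` samples with ground-truth
#' labels. Each (depth, sex) cell uses an RNG substream derived
#' deterministically from `(seed, depth, sex)`, so regenerating one cell in
#' isolation reproduces exactly the tables it had within the full grid.
#'
#' @param params a [sim_params()] object.
#' @return Object of class `hostsex_sim`: list with `counts` (samples x
#'   chromosomes matrix), `labels` (data frame: `sample_id`, `sex`,
#'   `depth`, `replicate`) and `params`.
#' @export
simulate_grid <- function(params) {
  stopifnot(inherits(params, "hostsex_sim_params"))
  spec <- params$spec
  nchrom <- nrow(spec$chromosomes)
  cells <- expand.grid(sex = c("female", "male"), depth = params$depths,
                       stringsAsFactors = FALSE)
  n_total <- nrow(cells) * params$replicates
  counts <- matrix(0, nrow = n_total, ncol = nchrom,
                   dimnames = list(NULL, spec$chromosomes$id))
  labels <- data.frame(sample_id = character(n_total), sex = character(n_total),
                       depth = integer(n_total), replicate = integer(n_total),
                       stringsAsFactors = FALSE)
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    sex <- cells$sex[ci]; depth <- cells$depth[ci]
    set.seed(cell_seed(params$seed, depth, sex))
    for (r in seq_len(params$replicates)) {
      row <- row + 1L
      counts[row, ] <- draw_counts(spec, sex, depth,
                                   params$mismap_rate, params$bias_sd)
      labels$sample_id[row] <- sprintf("sim_%s_d%d_r%04d", sex, depth, r)
      labels$sex[row] <- sex
      labels$depth[row] <- depth
      labels$replicate[row] <- r
    }
  }
  structure(list(counts = counts, labels = labels, params = params),
            class = "hostsex_sim")
}

#' @export
print.hostsex_sim <- function(x, ...) {
  cat(sprintf("<hostsex_sim> %d samples: %d depths x 2 sexes x %d replicates\n",
              nrow(x$counts), length(x$params$depths), x$params$replicates))
  invisible(x)
}

#' Extract one simulated sample as an idxstats table
#'
#' @param sim a [simulate_grid()] object.
#' @param i row index into the grid.
#' @return A `hostsex_idxstats` object.
#' @export
as_idxstats <- function(sim, i) {
  stopifnot(inherits(sim, "hostsex_sim"))
  ch <- sim$params$spec$chromosomes
  new_idxstats(sim$labels$sample_id[i],
               data.frame(id = c(ch$id, "*"),
                          length = c(ch$length, 0),
                          mapped = c(sim$counts[i, ], 0),
                          unmapped = c(rep(0, nrow(ch)), 0),
                          stringsAsFactors = FALSE))
}

#' Compute (Rx, Ry) metrics for every simulated sample
#'
#' Vectorized equivalent of running [compute_metrics()] on each sample of a
#' simulated grid.
#'
#' @param sim a [simulate_grid()] object.
#' @param min_autosomes passed to the Rx calculation, see [compute_rx()].
#' @return Data frame: labels columns plus `total_host_reads`, `rx`, `ry`,
#'   `n_autosomes_used`.
#' @export
sim_metrics <- function(sim, min_autosomes = 5L) {
  stopifnot(inherits(sim, "hostsex_sim"))
  m <- metrics_from_counts(sim$counts, sim$params$spec, min_autosomes)
  cbind(sim$labels, m)
}

#' Simulate idxstats tables from a genome specification
#'
#' `simulate()` method for `hostsex_genome`: draws `nsim` samples of the
#' given sex and depth.
#'
#' @param object a [genome_spec()] object.
#' @param nsim number of samples.
#' @param seed optional seed.
#' @param sex,depth,mismap_rate,bias_sd see [simulate_sample()].
#' @param ... unused.
#' @return List of `hostsex_idxstats` objects.
#' @export
simulate.hostsex_genome <- function(object, nsim = 1, seed = NULL,
                                    sex = "female", depth = 10000L,
                                    mismap_rate = 0.002, bias_sd = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_sample(object, sex, depth, mismap_rate, bias_sd,
                    sample_id = sprintf("sim_%s_%04d", sex, i)))
}

#' Train the default classifier from simulated data
#'
#' Simulates the twelve-depth training grid for the given genome and fits
#' the per-sex KDE models, pooling all depths.
#'
#' @param spec a [genome_spec()] object; default the bundled human-like
#'   genome.
#' @param seed simulator seed (recorded in the model).
#' @param replicates replicates per (depth, sex) cell; default 1000.
#' @param depths training depth grid; default [training_depths()].
#' @param mismap_rate,bias_sd simulator noise knobs, see [sim_params()].
#' @param ... passed to [hostsex_fit()].
#' @return A `hostsex_model`.
#' @export
hostsex_train_default <- function(spec = example_genome("human"),
                                  seed = 20260920L, replicates = 1000L,
                                  depths = training_depths(),
                                  mismap_rate = 0.002, bias_sd = 0.05, ...) {
  params <- sim_params(spec, depths = depths, replicates = replicates,
                       seed = seed, mismap_rate = mismap_rate,
                       bias_sd = bias_sd)
  metrics <- sim_metrics(simulate_grid(params))
  suppressMessages(
    hostsex_fit(metrics, system = spec$system, seed = seed, ...)
  )
}
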