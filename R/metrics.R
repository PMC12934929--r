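# Normalized sex-chromosome coverage statistics Rx and Ry.
#
# Rx = (1/n) * sum_i cov(homogametic) / cov(autosome_i)   (~1 for XX/ZZ, ~0.5
#      for XY/ZW individuals); Ry = het_reads / (homo_reads + het_reads)
#      (~0 for the homogametic-pair sex, positive for the heterogametic sex).
# Coverage is mapped reads per bp of *effective* length (length minus
# excluded regions such as PARs).

#' Per-chromosome coverage
#'
#' @param mapped mapped read count.
#' @param effective_length effective chromosome length in bp (>= 1).
#' @return Reads per base pair.
#' @export
coverage <- function(mapped, effective_length) {
  stopifnot(all(effective_length >= 1))
  mapped / effective_length
}

# shared count extraction: named vector of mapped counts in spec order,
# errors if a non-ignored spec chromosome is missing from the table
spec_counts <- function(x, spec) {
  ch <- spec$chromosomes
  used <- ch[ch$role != "ignored", , drop = FALSE]
  idx <- match(used$id, x$table$id)
  if (anyNA(idx))
    hs_error(sprintf("sample '%s': idxstats is missing chromosomes: %s",
                     x$sample_id, paste(used$id[is.na(idx)], collapse = ", ")),
             "hostsex_missing_scaffold_error")
  stats::setNames(x$table$mapped[idx], used$id)
}

#' Rx: mean homogametic-chromosome/autosome coverage ratio
#'
#' The mean over autosomes i of
#' `coverage(homogametic chromosome) / coverage(autosome i)`.
#' Autosomes with zero mapped reads are skipped (their ratio is undefined)
#' and the mean is taken over the remaining autosomes; if fewer than
#' `min_autosomes` remain, Rx is undefined (`NA`). Zero homogametic-chromosome
#' coverage gives Rx = 0, which is a defined value: a heterogametic
#' individual with no X (or Z) reads at very low depth is real data.
#'
#' @param x a `hostsex_idxstats` object.
#' @param spec a [genome_spec()] object.
#' @param min_autosomes minimum autosomes with nonzero coverage required for
#'   a defined Rx; capped at the number of autosomes in the spec so small
#'   toy genomes remain usable. Default 5.
#' @return Rx, or `NA` if undefined. Attribute `n_autosomes_used` records
#'   how many autosomes entered the mean.
#' @export
compute_rx <- function(x, spec, min_autosomes = 5L) {
  counts <- spec_counts(x, spec)
  ch <- spec$chromosomes[spec$chromosomes$role != "ignored", , drop = FALSE]
  auto <- ch$role == "autosome"
  homo <- ch$role == "homogametic"
  cov_homo <- counts[homo] / ch$effective_length[homo]
  cov_auto <- counts[auto] / ch$effective_length[auto]
  usable <- cov_auto > 0
  n_used <- sum(usable)
  need <- min(as.integer(min_autosomes), sum(auto))
  rx <- if (n_used >= need) mean(cov_homo / cov_auto[usable]) else NA_real_
  structure(rx, n_autosomes_used = n_used)
}

#' Ry: heterogametic fraction of sex-chromosome reads
#'
#' `het_reads / (homo_reads + het_reads)` — the fraction of sex-chromosome
#' reads mapping to the heterogametic chromosome (Y in XY, W in ZW).
#' Undefined (`NA`) when no reads map to either sex chromosome.
#'
#' @inheritParams compute_rx
#' @return Ry in `[0, 1]`, or `NA`.
#' @export
compute_ry <- function(x, spec) {
  counts <- spec_counts(x, spec)
  ch <- spec$chromosomes[spec$chromosomes$role != "ignored", , drop = FALSE]
  yr <- counts[ch$role == "heterogametic"]
  xr <- counts[ch$role == "homogametic"]
  if (xr + yr == 0) NA_real_ else unname(yr / (xr + yr))
}

#' Compute the full (Rx, Ry) metric set for one sample
#'
#' Metric names are role-based, not letter-based: in a ZW system "rx" is the
#' Z-versus-autosome coverage ratio and "ry" is W/(Z+W), so a ZZ male looks
#' like an XX female on these axes and sex labels are assigned downstream
#' according to the system.
#'
#' @inheritParams compute_rx
#' @return One-row data frame with columns `sample_id`, `total_host_reads`,
#'   `rx`, `ry`, `n_autosomes_used`.
#' @export
compute_metrics <- function(x, spec, min_autosomes = 5L) {
  rx <- compute_rx(x, spec, min_autosomes)
  data.frame(sample_id = x$sample_id,
             total_host_reads = total_host_reads(x, spec),
             rx = as.numeric(rx),
             ry = compute_ry(x, spec),
             n_autosomes_used = attr(rx, "n_autosomes_used"),
             stringsAsFactors = FALSE)
}

# Vectorized metrics over a count matrix (rows = samples, columns named by
# chromosome id covering every non-ignored spec chromosome). Used by the
# simulator grid and the batch classifier; identical arithmetic to
# compute_rx/compute_ry.
metrics_from_counts <- function(counts, spec, min_autosomes = 5L) {
  ch <- spec$chromosomes[spec$chromosomes$role != "ignored", , drop = FALSE]
  counts <- counts[, ch$id, drop = FALSE]
  auto <- which(ch$role == "autosome")
  homo <- which(ch$role == "homogametic")
  het <- which(ch$role == "heterogametic")
  cov_homo <- counts[, homo] / ch$effective_length[homo]
  cov_auto <- sweep(counts[, auto, drop = FALSE], 2,
                    ch$effective_length[auto], "/")
  cov_auto[cov_auto == 0] <- NA_real_
  ratios <- cov_homo / cov_auto
  n_used <- rowSums(!is.na(cov_auto))
  rx <- rowMeans(ratios, na.rm = TRUE)
  need <- min(as.integer(min_autosomes), length(auto))
  rx[n_used < need] <- NA_real_
  sex_total <- counts[, homo] + counts[, het]
  ry <- ifelse(sex_total > 0, counts[, het] / sex_total, NA_real_)
  data.frame(total_host_reads = rowSums(counts),
             rx = rx, ry = ry, n_autosomes_used = n_used)
}
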