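---
title: "Coverage-based host sex inference: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based host sex inference: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostsex)
```

## The statistical model

A sample's host reads are summarised by two statistics computed from the
per-chromosome mapped-read counts of a `samtools idxstats` table, given a
genome specification that designates autosomes and the two sex chromosomes:

$$R_x = \frac{1}{n}\sum_{i=1}^{n}
  \frac{\mathrm{cov}(\mathrm{homogametic})}{\mathrm{cov}(\mathrm{autosome}_i)},
\qquad
R_y = \frac{\mathrm{het}}{\mathrm{homo} + \mathrm{het}},$$

where coverage is mapped reads per bp of *effective* length (chromosome
length minus excluded regions such as PARs) and `het`/`homo` are raw read
counts on the two sex chromosomes. Under ideal proportional sampling,
$E[R_x] \approx 1$ and $R_y \approx 0$ for the homogametic-pair sex (XX
female, ZZ male) and $E[R_x] \approx 0.5$ with clearly positive $R_y$ for
the heterogametic sex. At low depth both statistics scatter widely, so
fixed thresholds break down; instead each sex's joint (Rx, Ry)
distribution is estimated with a 2-D product-Gaussian kernel density
$\hat f_s$, trained on simulated samples pooled across read depths, and a
new sample is assigned the posterior

$$P(s \mid r_x, r_y) =
  \frac{\pi_s \hat f_s(r_x, r_y)}{\sum_t \pi_t \hat f_t(r_x, r_y)},
\qquad \pi_{\mathrm{female}} = \pi_{\mathrm{male}} = 0.5 .$$

The call is the more probable sex when its posterior reaches the threshold
(default 0.80), otherwise `uncertain`. Training on (Rx, Ry) jointly and
untransformed is a deliberate choice: a logit transform of Ry was
considered and rejected because Ry is exactly 0 for most homogametic-pair
samples, which a logit cannot represent.

Assumptions worth stating explicitly: reads land on chromosomes roughly in
proportion to copy number × length (i.e. upstream filtering has removed
duplicates and ambiguous mappings); the host has a well-assembled
heterogametic chromosome; and the individual carries a standard XX/XY or
ZZ/ZW complement. Sex-chromosome aneuploidies are outside the model.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | 0.80 | posterior prob. | balanced precision/recall across depths; raise toward 0.99 for precision, lower toward 0.5 for sensitivity |
| `min_reads` | 100 | host reads | below this the (Rx, Ry) point is mostly noise; reported `insufficient_reads` rather than dropped so output rows match input samples |
| `prior_homogametic` | 0.5 | probability | uniform prior; adjustable for cohorts of known composition |
| `bandwidth` | Silverman per dimension | Rx / Ry units | rule-of-thumb `0.9 min(sd, IQR/1.34) n^{-1/5}` per class and dimension |
| `bw_floor` | 1e-4 | Rx / Ry units | the homogametic class's Ry is a near-point-mass at 0; without a floor its bandwidth collapses and the density degenerates |
| `density_floor` | 1e-300 | density | queries where both class densities lie below this are outside the model's support and abstain at 0.5/0.5 |
| `min_autosomes` | 5 (capped at the spec's autosome count) | count | Rx skips zero-coverage autosomes; with fewer than this many usable ratios the mean is too unstable to report |
| `mismap_rate` | 0.002 | weight fraction | simulator: residual homologous mismapping onto the absent heterogametic chromosome |
| `bias_sd` | 0.05 | log scale | simulator: per-chromosome multiplicative weight bias (mappability, GC, assembly differences) |

## The simulator: what it emulates and what it does not

The classifier consumes only per-chromosome counts, so the count
distribution is the sufficient statistic of a read-level simulation. The
simulator therefore draws counts directly from a multinomial over
chromosomes with probabilities proportional to copy number × effective
length, at exact target depths over the grid {150, 250, 350, 450, 1,000,
5,000, 10,000, 100,000, 1,000,000} (benchmark) plus {500, 2,500, 50,000}
(training, twelve depths in total). Multinomial sampling with replacement
stands in for downsampling a much deeper alignment without replacement;
at ≤1M draws from a 10M-read pool the difference is negligible. Two noise
knobs perturb the weights per sample: a log-normal per-chromosome bias
(sd 0.05) and a mismapping rate (0.002) that moves a small fraction of the
homogametic sex-chromosome weight onto the heterogametic chromosome for
XX/ZZ individuals, so that female human samples show an occasional Y read.

What the simulator does **not** model: sequencing error, read length and
pairing, PCR duplicates, mappability structure along chromosomes, and —
most consequentially — the PAR- and repeat-driven ambiguity of real
X/Y (Z/W) alignments. Real female alignments against a full reference
acquire Y-mapped reads at a much higher and more variable rate than the
0.002 default, which fattens the female class's Ry distribution and makes
low-depth males (whose Y reads are often zero) genuinely ambiguous. With
the clean count-level defaults the female Ry training mass is a razor-thin
ridge at 0, so a low-depth male with zero Y reads tends to be *confidently
miscalled* female rather than abstained, while every male with at least
one Y read is confidently correct. Two visible consequences in this
package's own benchmark (run `scripts/acceptance.R` or the acceptance test
to compute them): overall accuracy at a given depth is *higher* than a
read-level pipeline would achieve, and the pooled male F1 under the
abstentions-as-false-negatives convention comes out near its ceiling
rather than being depressed by male abstentions. Passing benchmark tests
here therefore demonstrates the correctness of the statistics, the KDE
machinery and the decision rule under the stated count model — not
performance on real alignments, which depends on upstream filtering
quality.

## Numerical choices

* All densities are evaluated in log space with a per-query log-sum-exp
  over kernels, chunked so that large query sets never materialise the
  full query × training matrix. Out-of-support queries underflow to very
  negative log densities instead of exact zeros, and the density floor is
  compared in log space.
* Posteriors are computed as a logistic of the log-likelihood-ratio plus
  log prior odds (`plogis`), which is exact and avoids 0/0 at extreme
  ratios. Exactly equal densities give 0.5/0.5, which is `uncertain` at
  every admissible threshold — the tie-break never manufactures a call.
* Rx skips autosomes with zero mapped reads and records how many entered
  the mean; zero homogametic-chromosome coverage yields a *defined* Rx of
  0. The ratio-of-coverages estimator carries a finite-depth Jensen bias of
  roughly $(1-w_i)/(d\,w_i)$ per autosome (about +0.6% at 10,000 reads for
  a human-like genome, vanishing at high depth); tests assert the
  canonical values at depth 10^6 and only a coarse band at moderate depth
  for this reason.
* Exclusion regions are merged as half-open BED intervals and effective
  lengths are recomputed from the full chromosome length each time, making
  the operation idempotent.
* Model files store doubles with 17 significant digits, so
  serialise → load → serialise is byte-identical and loaded models give
  bit-identical posteriors.
* Each simulator (depth, sex) cell derives its RNG substream
  deterministically from the base seed, the depth and the sex, so any cell
  can be regenerated in isolation, bit-identically to its appearance in a
  full grid.

## Design decisions on open points

* **Scaffold lists.** A one-column list is interpreted with the last two
  lines as the homogametic and heterogametic chromosome; a two-column
  `id<TAB>role` dialect makes roles explicit. Scaffolds present in the
  idxstats file but absent from the list are ignored — the list is the
  inclusion filter — and unplaced/alt contigs should be left off the list
  rather than counted as autosomes.
* **PARs.** Exclusion is supported via BED input (bundled for the
  human-like spec) but off by default for non-human genomes, where PAR
  annotations are often unavailable.
* **Depth pooling.** One KDE per sex pooled over all training depths; a
  per-depth-stratified model family was considered and rejected as it
  requires a depth-matching step at prediction time that the pooled model
  avoids.
* **Problem sizes.** The test suite trains at 200 replicates per cell and
  the acceptance script at 1,000; both use 1,000 male + 1,000 female
  evaluation samples per benchmark depth in the script (200 in the fast
  suite). These sizes give standard errors on per-depth accuracy of under
  one percentage point at the script scale.
* **Bundled model.** The shipped `model_human_xy.tsv` is a compact
  convenience (40 replicates per cell, seed 20260920, regenerable with
  `hostsex train`); analyses should train a full-size model with
  `hostsex_train_default()`.

## Known limitations

Accuracy degrades, by design into abstention, when host reads are very
sparse or the heterogametic chromosome is poorly assembled (as for many
avian W chromosomes). Individuals with sex-chromosome aneuploidies (XXY,
X0, XYY) or otherwise atypical complements are not modelled and may be
miscalled or left uncertain. The tool infers *chromosomal* sex only — it
says nothing about gender — and applying it to human-derived data is
appropriate only within the consent and approvals governing the original
collection.
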