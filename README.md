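# hostsex

Host sex inference from metagenomic read counts.

## The problem

Shotgun metagenomic samples — stool, oral or nasal swabs, cecal contents,
wildlife fecal samples — always carry some host-derived reads alongside the
microbial ones. When sex metadata are missing, swapped or unrecorded, those
host reads are often the only way to recover the host's sex, but in
microbe-rich samples they can number in the hundreds, far too few for
variant-based methods. `hostsex` is for microbiome researchers who need
reliable host sex calls (or a metadata QC check) from nothing more than a
per-chromosome read-count table.

## The method

In a heterogametic sex-determination system, sex-chromosome dosage differs
between the sexes (XX/XY in mammals, ZZ/ZW in birds), so the distribution of
host reads over chromosomes encodes sex. From a `samtools idxstats` table
the package computes two normalized coverage statistics:

* **Rx** — the mean over autosomes *i* of
  `cov(X) / cov(autosome_i)`, where coverage is mapped reads per bp of
  effective (non-excluded) length. Expectation ≈ 1 for XX, ≈ 0.5 for XY.
* **Ry** — `Y_reads / (X_reads + Y_reads)`, the heterogametic fraction of
  sex-chromosome reads. ≈ 0 for XX, clearly positive for XY.

(For ZW hosts the same statistics are computed with Z in the homogametic
role and W in the heterogametic role; labels map to male/female
accordingly.)

The classifier models each sex's (Rx, Ry) distribution with a 2-D
product-Gaussian kernel density estimate trained on count-level simulations
spanning read depths from 150 to 1,000,000. For a new sample it evaluates
both densities, combines them with equal priors, and reports the posterior
probability of each sex. If the larger posterior is below a threshold
(default 0.80) the call is `uncertain`; samples with fewer than 100 host
reads are reported `insufficient_reads`.

The bundled simulator draws per-chromosome counts from a multinomial with
probabilities proportional to copy number × effective chromosome length,
with two small noise knobs (per-chromosome log-normal bias, and a
mismapping rate that gives XX samples a trickle of Y-mapped reads).

## Worked example

```r
library(hostsex)

spec  <- example_genome("human")        # 22 autosomes + X + Y
model <- pretrained_model()             # compact bundled classifier

# simulate three samples of known sex: a clear female, a clear male,
# and a sample with too few host reads to call
set.seed(42)
samples <- list(simulate_sample(spec, "female", 20000, sample_id = "donor_A"),
                simulate_sample(spec, "male",   20000, sample_id = "donor_B"),
                simulate_sample(spec, "female",    60, sample_id = "donor_C"))
classify_samples(samples, spec, model, threshold = 0.80, min_reads = 100)
```

```
  sample_id total_host_reads        rx          ry posterior_female
1   donor_A            20000 0.9513284 0.001031992        0.9985682
2   donor_B            20000 0.4690579 0.294117647        0.0000000
3   donor_C               60 1.1040473 0.000000000               NA
  posterior_male posterior               call
1    0.001431795 0.9985682             female
2    1.000000000 1.0000000               male
3             NA        NA insufficient_reads
```

`donor_A` sits near the XX signature (Rx ≈ 1, Ry ≈ 0) and `donor_B` near
the XY signature (Rx ≈ 0.5, Ry ≈ 0.29), both with posteriors above the
0.80 threshold; `donor_C` has only 60 host reads, below the 100-read
cutoff, so no call is attempted.

To train a full-size model instead of using the bundled one:

```r
model <- hostsex_train_default(spec, seed = 20260920, replicates = 1000)
```

From the shell, the same workflow is:

```sh
hostsex classify --idxstats sample.idxstats --genome human \
    --model model.tsv --threshold 0.8 --min-reads 100 --output calls.tsv
```

(`exec/hostsex` also provides `train`, `simulate`, `benchmark` and `sweep`
subcommands; see `hostsex --help`.)

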