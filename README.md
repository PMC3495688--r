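# shadowreg

Reference-free estimation of sequencing error rates in short-read data.

## The problem

Every sequencing experiment needs an answer to a basic quality question: what
fraction of my reads contain an error? The usual proxy — map the reads to a
reference genome and count mismatches — conflates sequencing errors with
genuine sample–reference differences (polymorphisms, strain mutations), and
is unavailable when no trustworthy reference exists (novel species, threat
detection, metagenomes).

`shadowreg` estimates error rates from the reads alone. When a frequent read
*t* is miscalled, the miscalled copies appear as *shadows*: observed
sequences within one or two edits of *t*. Error shadows accumulate linearly
with the copy number of *t*, while genuinely distinct neighboring sequences
do not, so in the regression

```
s_t = α + β·n_t + ε
```

(over the 1000 most frequent reads, with s_t the total count of t's observed
shadows and n_t the count of t) the robustly fitted slope β̂ = Δe/Δn
transforms into the per-read error rate

```
rate = Δe / (Δn + Δe) = β̂ / (1 + β̂).
```

Stratifying shadows by the differing position gives per-base (per-cycle)
rates; substitution, insertion and deletion errors are handled through
different neighborhood definitions. The package also ships the
mismatch-counting comparator `(U1+U2)/(U0+U1+U2)`, a repetitive-genome
diagnostic, a coverage-adequacy check, and a ground-truth simulator with
independent and burst (dependent) error models.

Intended users: sequencing-facility QC, method developers needing a
reference-free error estimate, and anyone comparing pipeline runs at the
level of individual samples.

## Worked example

```r
library(shadowreg)

# simulate a sample with known truth: 20 kb genome, 50k reads of 35 bp,
# 10% of reads carrying at least one substitution error
sim <- simulate_reads(genome_length = 2e4, n_reads = 5e4,
                      target_rate = 0.1, seed = 1)
sim
#> Simulated sequencing dataset (independent error model)
#>   genome 20,000 bp, 50,000 reads of 35 bp
#>   polymorphic sites: 0
#>   target per-read rate 0.1, realized 0.09784

fit <- shadow_regression(sim$observed_reads)
summary(fit)
#> Shadow regression error-rate estimate
#>   error type: substitution   top-k: 1000   max edit distance: 2
#>   per-read error rate: 0.08885 (SE 0.000187)
#>   slope 0.09751, intercept 0.004103 over 1000 points
#>   per-position rates: median 0.00188, range [3.16e-07, 0.00306]
```

The estimate (8.9%) sits within a percentage point of the bookkept truth
(9.8%); the gap is the documented mild underestimation of the top-k
protocol. `plot(fit)` draws the read-count/shadow-count scatter with the
fitted line; `plot(fit, which = "positions")` the per-cycle profile.

Mismatch counting against the (here, identical) reference agrees — but
becomes biased as soon as the sample genome differs from the reference:

```r
mismatch_error_rate(classify_reads(sim$observed_reads, sim$reference))
#> [1] 0.09755
```

The classical unmatched-tag arithmetic for tag libraries:

```r
error_fraction_from_match_counts(60633, c(56291, 88, 91))
#> $unmatched
#> [1] 4163
#> $fraction
#> [1] 6.8
```

A command-line front end (`exec/shadowerr`) wraps the same functions:

```sh
shadowerr estimate --input reads.fastq.gz --out report.json --positions pos.tsv
shadowerr reptest  --reference genome.fasta --read-length 36 --n-reads 200000 --seed 1
shadowerr simulate --out-dir sims --target-rate 0.2 --model dependent --replicates 5 --seed 1
```

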