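---
title: "Estimating sequencing error rates from read shadows"
author: "shadowreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sequencing error rates from read shadows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadowreg)
```

## The model

A sequencing run outputs many copies of many distinct short reads. When a
copy of read *t* is miscalled at one or two bases, the miscalled copy is
observed as a different sequence lying close to *t* in edit distance — a
*shadow* of *t*. Writing $n_t$ for the number of correctly sequenced copies
of *t* and $s_t$ for the total count of observed reads within the edit
neighborhood of *t*, error shadows accumulate in proportion to $n_t$, while
*legitimate* shadows — genuinely distinct sequences that happen to be
neighbors — do not depend on $n_t$. This motivates the linear model

$$ s_t = \alpha + \beta\, n_t + \varepsilon, $$

fitted over the most frequent reads in the sample. The slope
$\hat\beta = \Delta e / \Delta n$ is the number of additional error copies
per additional correct copy, so the per-read error rate — the fraction of
reads carrying at least one error — is

$$ \widehat{\text{rate}} = \frac{\Delta e}{\Delta n + \Delta e}
   = \frac{\hat\beta}{1 + \hat\beta}. $$

Stratifying the shadows by the position at which they differ from *t*
($s^i_t$, shadows differing at least at position $i$) and repeating the
regression per position yields per-base error rates
$\hat\beta^i/(1+\hat\beta^i)$.

Nothing in this construction uses a reference genome; that is the point.
The comparator implemented alongside it, *mismatch counting*, maps reads to
a reference and estimates the rate as $(U_1+U_2)/(U_0+U_1+U_2)$, where $U_k$
counts reads uniquely aligned with $k$ mismatches. Any genuine difference
between the sample and the reference (polymorphisms, strain mutations) is
miscounted as error, so the mismatch estimate is biased upward — the package
exposes both so the bias is visible.

## Assumptions and their failure modes

* **High-frequency reads are error free.** The regression uses the `top_k`
  (default 1000) most frequent reads as points and *excludes the whole top-k
  set from every shadow count*. A miscalled copy of a frequent read is itself
  a rare sequence; the converse — an error shadow frequent enough to enter the
  top k — happens only for the extreme head of very skewed count spectra, and
  removes that shadow's count from the regression response. At the package's
  default simulation conditions this costs a fraction of a percentage point
  (visible as mild underestimation); in the degenerate case where all error
  mass concentrates on one or two positions, each read has only a handful of
  possible shadows and the effect can silence the signal entirely — the test
  suite demonstrates this and works at a flatter abundance profile and
  smaller `top_k` in that scenario.
* **Neighborhoods capped at two edits.** Reads carrying three or more errors
  are invisible to the estimator. At per-read rates beyond roughly 0.3 the
  multi-error fraction becomes material and the estimate falls below the
  truth; the bias grows under error bursts (the dependent model below)
  because the first error begets more. The direction of this bias is fixed
  (underestimation) and tested.
* **Non-repetitive source sequence.** Repeats generate legitimate shadows
  whose counts *do* co-vary with $n_t$ (both scale with the repeat family's
  copy number), defeating the robust fit. `repetitiveness_test()` estimates
  the error rate on error-free reads sampled uniformly from a candidate
  reference; anything materially above zero (default threshold 0.005) flags
  the genome as too repetitive for direct application.
* **Uniform read length.** The shadow definition is length preserving;
  mixed-length input is rejected rather than silently truncated (an explicit
  `trim_to` option performs 3' truncation when wanted).

## Robust fitting

Legitimate shadows make some regression points outliers in $s$, so $\beta$
is estimated by Huber M-estimation (tuning constant 1.345, MAD residual
scale, at most 50 IRLS iterations, coefficient tolerance 1e-8) via
`MASS::rlm()`. Two numerical choices matter:

* When the bulk of the points lies exactly on a line, the MAD scale is zero
  and IRLS weights are undefined. `fit_robust_line()` detects this and
  refits ordinary least squares on the zero-residual subset, recovering the
  exact line whatever the remaining points do. This is what makes error-free
  input return exactly 0.
* A negative fitted slope (possible on error-free data by chance) is
  truncated to zero with a warning before the transform, since rates are
  nonnegative.

The reported standard error is the delta-method propagation
$\mathrm{SE}(\hat\beta)/(1+\hat\beta)^2$ of the weighted-least-squares slope
standard error, and is labeled as such; a bootstrap alternative
(`se_method = "bootstrap"`, 200 resamples of the regression points) is
available. Ties in read counts at the top-k boundary are broken
lexicographically by sequence, making every estimate invariant to input
order.

## Shadow definitions

Substitution shadows are the Hamming ball of radius `max_dist` (1 or 2)
minus the read itself: $3L$ sequences at distance 1, $3L + 9\binom{L}{2}$ up
to distance 2. For a 36-mer that is 5778 candidate sequences per target,
enumerated in C++ and looked up in a hash of the observed reads — cheap when
only the top 1000 reads are profiled.

Indel shadows must preserve read length, because an instrument that inserts
a base shifts the rest of the template out of the read, and a deletion pulls
one unknown template base in. An insertion shadow inserts a base before
position $p$ and drops the displaced 3' base; a deletion shadow removes
position $p$ and appends each of the four bases. Applying the rule twice
gives distance-2 shadows; duplicates are removed and a string reachable at
distance 1 keeps its distance-1 (minimal-edit) position attribution, taking
the smallest $p$ on ties. Insertions at the very start and deletions at the
very end of a read can turn one genuine read into another genuine read
shifted by one base, so per-position indel estimates are masked (`NA`) at
the first and last `indel_mask` (default 2) positions; per-read indel rates
are unaffected. An aggregate rate over all three error types
(`error_type = "all"`) is reported as the sum of the three separately
estimated rates — summing is transparent and keeps each component
inspectable, though pooling the three shadow sets before one regression
would be an equally defensible definition.

## Coverage requirements

The regression needs leverage: the top-k counts should spread over a range
of roughly 500, which requires the maximum count to reach roughly 500.
`coverage_adequacy()` reports both numbers; failure warns rather than
aborts, because thin coverage degrades precision rather than invalidating
the model.

## What the simulator emulates

`simulate_reads()` provides ground truth for validation:

* a uniform-random reference (default 100 kb) stands in for an arbitrary
  non-repetitive source sequence;
* read start positions receive Zipf weights (exponent 1) assigned to a
  random permutation of positions, reproducing the heavy-headed count
  spectrum of real count data (a few reads very frequent, most rare) that
  the top-k protocol relies on; at the default 2e5 reads of 35 bp this
  satisfies the adequacy check with a wide margin;
* per-position substitution rates follow a linearly increasing per-cycle
  shape (4x from first to last cycle, the qualitative pattern of
  cycle-dependent base-calling noise), scaled by bisection so the implied
  per-read rate $1-\prod_i(1-p_i)$ hits the requested target exactly; the
  shape is a configurable input;
* errors are injected per read copy either independently per position, or
  under the *dependent* model in which all rates downstream of a read's
  first error double (error bursts). The probability of at least one error
  is identical under both models, so one scaling serves both;
* an optional polymorphism step mutates the reference at a configurable
  per-base rate (e.g. 1/1000) before reads are sampled, to expose the
  reference bias of mismatch counting while leaving shadow regression
  untouched;
* the realized per-read error rate is bookkept exactly (the fraction of read
  copies that received at least one error), never re-derived.

What the simulator does **not** model: quality strings, paired-end layout,
sequence-motif-specific errors, indel errors (the indel estimators are
exercised on clean data and by enumeration oracles instead), and real
per-cycle error profiles. Passing the simulation checks therefore
demonstrates correctness of the estimator under its own model assumptions,
not performance on any particular instrument's quirks.

## Validation conditions and observed accuracy

The package's acceptance checks run the full loop at a fixed problem size
chosen to exercise the estimator at realistic depth while keeping a complete
200-replicate grid comfortably runnable on one CPU: 100 kb genome, 35 bp
reads, 2e5 reads per sample, target per-read rates 0.05–0.25 in steps of
0.05, 20 replicate seeds per rate, both error models, with one pool of
error-free reads per seed shared across all rates and models. The estimate's
median absolute deviation from truth is around 1 percentage point under both
models in these runs (the tests assert the documented bounds of 2 and 5
percentage points for the independent and dependent models respectively),
with the underestimation direction appearing at high rates as expected.

The mismatch-counting comparator is validated against a brute-force
all-offsets Hamming scan (the definition), including reverse-strand and
circular-reference modes; its production path uses a three-piece pigeonhole
seed index which finds every alignment with at most two mismatches exactly.

## Known limitations

* Rates at or above ~0.4 are systematically underestimated (two-edit cap).
* Indel shadow construction is one reasonable fixed-length convention; an
  instrument whose indel behavior differs (e.g. homopolymer-length errors)
  would need a different neighborhood definition, which the architecture
  allows but the package does not ship.
* Aggregate-rate reporting assumes error types are rare enough that their
  rates add approximately; at high rates the sum can exceed the true
  probability of any error.
* The repetitiveness threshold (0.005) operationalizes "very close to zero";
  it is configurable and genomes near the boundary deserve a look at the
  fitted scatter rather than trust in the flag.
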