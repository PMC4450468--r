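---
title: "Maximum-likelihood read trimming: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood read trimming: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mltrim)
```

## The trimming problem

Base-calling quality in short-read sequencing is typically worst at the two
extremities of a read: it drops abruptly over the first few cycles and
degrades slowly toward the end. Quality trimming removes those unreliable
stretches while keeping a contiguous central segment. Most trimmers do this
with sliding windows or running sums, which need window sizes and ad hoc
rules. `mltrim` instead treats trimming as a change-point estimation
problem: each read is modelled as an informative central segment framed by
two unreliable segments, and the two cut-points are estimated by maximum
likelihood. The only user parameter is `t`, the minimal phred score
considered informative.

## The probability–phred model

A phred score `q` encodes an error probability, so the probability that a
call is correct is `p_a(q) = 1 - 10^(-q/10)` (0.99 at q = 20). For
trimming, though, "informative" means *above the user's threshold*, not
"probably correct". The model therefore uses the shifted function

```
p_b(q, t) = 1 - 2^(-q/t)
```

which equals 0.5 exactly at `q = t`: a nucleotide is informative precisely
when its probability exceeds one half. At `t = 10·log10(2) ≈ 3.0103` the
shifted function coincides with `p_a`, so the classical phred
interpretation is a special case.

The shifted function alone under-rewards genuinely high scores (for
example `p_b(40, 20) = 0.75`), which would let unreliable positions
dominate the likelihood. The full curve `p(q, t)` therefore keeps
`p_b` up to `q = max(20, t)` and continues with a cubic Bezier spline that
reaches exactly 1 at `q = 45` and arrives flat:

```{r curve, fig.width = 5, fig.height = 4}
plot(build_curve(20))
```

Spline construction, and the choices that were genuinely open:

* The Bezier parameter is scaled as `u = (q - max(20, t)) / (45 - max(20, t))`,
  so the spline starts exactly at the value of `p_b` at the switch point
  (`u = 0`) and ends at 1 (`u = 1`); the curve is continuous for every
  `t`. An alternative scaling of `[t, 45]` onto `[0, 1]` is retained
  behind `scaling = "literal"` for comparison; for `t < 20` it introduces
  a jump at the switch point, which is why it is not the default.
* The second control point lies on the tangent to `p_b` at the switch
  point, evaluated one third of the way to 45 — the standard cubic-Bezier
  placement that makes the junction C¹.
* That control point is capped at 1. For very small `t` the shifted
  function is already nearly 1 at the switch point and its tangent exceeds
  1 before q = 45; capping keeps the control polygon monotone
  (`p1 ≤ p2 ≤ p3 = p4 = 1`), hence the spline itself a monotone
  probability. The cap is inactive for any `t` above ≈ 6.
* Scores above 45 (possible on modern instruments) clamp to probability 1.
* Non-integer `t` is allowed (the classical-phred limit itself is
  non-integer). `build_curve()` materializes the curve at integer q in
  `[0, 93]` for O(1) lookups; tests compare the table against direct
  evaluation.

## Segmentation by maximum likelihood

For a read of length `m` with nucleotides `n_i` and scores `q_i`, the tail
cut `k1` maximizes, over `k ∈ [1, m]`,

```
sum_{i ≤ k} [ log f0(n_i) − log k ]  +  sum_{i > k} [ log f1(n_i) − log(m − k) ]
```

where `f0(n_i) = p(q_i, t) · Pr(n_i)` is the informative-segment model —
`Pr(N)` being the empirical frequency of nucleotide `N` on `[1, k]`, over
the IUPAC alphabet with each ambiguity code counting as its own symbol —
and `f1(n_i) = (1 − p(q_i, t)) / 4` is the unreliable-segment model, under
which any base is equally likely. The `1/k` and `1/(m−k)` factors
normalize per occupied position; an empty tail contributes nothing. The
nucleotide frequencies have a closed-form maximum for each candidate `k`
(this is the complete-data view of EM: profile likelihood), so cut and
frequencies are jointly optimized by a single scan over `k`.

Because the quality signal is weak at the tail (slow degradation) and
strong at the head (abrupt), `k1` is estimated first on the whole read —
the most support — and then the head cut `k2` by the mirrored search on
`[1, k1]`. This double binary segmentation yields the best two cut-points
for the read. The head search is implemented by reversing the subsequence
and reusing the tail scan (`k2 = k1 − k1' + 1`); a test battery checks
that this is exactly equivalent to the direct head formulation.

Numerical choices:

* Every probability factor is floored at `1e-30` inside log-likelihoods,
  keeping the arithmetic finite; the floor can only affect ties between
  exact-zero candidates.
* Argmax ties are resolved toward the largest `k1` and the smallest `k2` —
  i.e. toward retaining the most nucleotides, consistent with the goal of
  removing no more than necessary. Candidates within `1e-9 · (1 + |max|)`
  of the maximum count as tied, so analytically equal likelihoods summed
  in different orders (the mirrored scan) resolve identically.
* The search ranges are `k1 ∈ [1, m]` and `k2 ∈ [1, k1]`, so the smallest
  possible retained segment is a single nucleotide; whole-read rejection
  is the job of the minimum-length filter (`min_read_size`, default 1).
* A read is never edited or reordered: the result is always a contiguous
  substring.

```{r example}
q <- c(rep(2L, 5), rep(40L, 40), rep(2L, 5))
s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
fit <- segment_read(s, q, t = 20)
summary(fit)
```

## Homopolymer (poly-N) trimming

Poly-A tails and other terminal homopolymers are only partly a quality
phenomenon: the run letter is called with moderate confidence, yet carries
no information. The poly-N mode keeps the same segmentation machinery and
replaces the unreliable-segment model with a letter-aware one:
`f1 = p(q, t)` when the observed base is the run letter, and
`(1 − p(q, t)) / 4` otherwise (a miscall that could have been the
letter). Terminal runs are then trimmed even at moderate phred scores.
When both passes are requested the poly-N pass runs first by default
(`polyN_first = TRUE`); the order is exposed because neither order is
canonical.

One property of the quality-only model worth knowing: through the
composition term `Pr(N)`, a long terminal homopolymer can shift the
quality-mode cut-points too, even at decent quality. The letter-aware mode
is the reliable tool for that job; the tests pin down both behaviours.

## The synthetic-read generator

There is no public fixture small enough for unit testing, so the package
generates its own reads with *planted* cut-points: uniform A/C/G/T
sequence, a step quality profile (unreliable head, informative centre,
unreliable tail) plus rounded Gaussian jitter, and optionally an appended
homopolymer block. The defaults — 100 nt reads, planted cuts (11, 90),
segment means 2/40/2 phred, jitter sd 3, homopolymer block at phred 30 —
emulate the canonical shape of real quality profiles with a step height
large enough that recovery is expected: phred 2 vs 40 straddles any
threshold in the practical range, and sd 3 is a realistic per-position
wobble that leaves the step unambiguous.

What the generator deliberately does *not* model: substitution or indel
sequencing errors, instrument-specific quality distributions, quality
binning, or gradual (non-step) decay. Passing recovery tests therefore
demonstrates correct change-point estimation under the model's own
assumptions, not trimming accuracy on any particular instrument's data.

Recovery behaves as expected: on 500 simulated reads with the default
profile, ≥ 95% of cut-point pairs are recovered within ±2 positions at
t = 20 (the acceptance suite reruns this; typical runs recover ≈ 99%),
the mean retained length is non-increasing in `t`, and recovery error
grows as the step height shrinks.

## File handling

FASTQ input is the 4-line dialect, plain or gzip (detected from the
content's magic bytes, never the file name); multi-line FASTQ is rejected
with a clear error. The phred offset defaults to 33 and can be set to 64;
a quality character below the offset raises an error that names the other
offset. Files are streamed in chunks (10,000 records by default), so
memory use is bounded regardless of file size. On writing, the third line
is always a bare `+`. Paired files are processed positionally in
lock-step — mate ids are not parsed — and a pair is dropped whenever
either mate falls below the minimum length, so outputs never desynchronize.
Trimming reads are independent, so the output is byte-identical for any
`threads` value; parallel workers only partition each chunk.

## Problem sizes used in the test suite

The suite validates the likelihood scan against an exhaustive naive search
on 1,000 random reads of length ≤ 30 (both quality and poly-N modes),
measures cut-point recovery on 500 simulated 100 nt reads, and checks the
file-layer contracts on batteries of a few hundred records. These sizes
make every property statistically meaningful while keeping the whole suite
in the tens of seconds.

## Known limitations

* At most two cut-points per read: a read with an unreliable interior
  stretch keeps it if the flanks are informative.
* No adapter-sequence matching, k-mer error correction, or quality-score
  recalibration; quality- and homopolymer-driven trimming only.
* `t = 45` is a degenerate corner: the shifted branch then extends to
  q = 45 and the curve never reaches 1 exactly; thresholds up to 40 are
  the sensible range.
* Paired output never contains singletons: if one mate dies, both die.
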