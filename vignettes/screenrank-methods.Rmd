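---
title: "Rank-sum statistics for sorted-gate reporter screens: models and methods"
author: "screenrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-sum statistics for sorted-gate reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenrank)
```

## The experiment this package analyzes

In a pooled FACS-reporter degradation screen, cells carrying a fluorescent
stability reporter (eGFP fused to a degron, with mCherry as an internal
control) are infected with a pooled sgRNA library, treated with a degrader
compound, and sorted into the top ("stable") and bottom ("unstable") tails
of the eGFP/mCherry ratio distribution. Guides that knock out a gene
required for drug-induced degradation shift their cells toward the stable
gate; sequencing the sorted populations and comparing guide abundance
between gates identifies those genes. A resistance screen has the same
shape with treatment arms instead of gates: guide enrichment in the
drug-treated arm relative to the DMSO arm marks genes whose loss confers
resistance. The alanine-scanning variant replaces sgRNAs with a library of
point mutants of the degron (or of the ligase substrate receptor), one
variant per residue, to map the positions required for degradation.

`screenrank` implements the complete analysis for all three designs, plus
the downstream assay quantifications that accompany such screens:
four-parameter log-logistic (4PL) dose–response fits yielding DC50 and
Dmax, LOESS display curves, the TR-FRET 520/490 ratio with hook-peak
localization, and intact-MS covalent labeling efficiency. A seeded
generator produces synthetic screens with known ground truth so every
statistical property can be verified end to end.

## The screen statistic

Let $c_{gs}$ be the read count of feature $g$ (an sgRNA or a variant) in
sample $s$. The five analysis steps are:

1. **Normalization.** Reads are scaled to each sample's total:
   $\tilde c_{gs} = c_{gs} \cdot S / \sum_h c_{hs}$, with $S = 10^6$
   (reads per million). This makes all downstream results invariant to
   per-sample sequencing depth, which the test suite asserts bit-exactly.
2. **Enrichment ratios.** For each sorting replicate $r$ with numerator
   sample $n_r$ (stable gate, or drug arm) and denominator sample $d_r$
   (unstable gate, or DMSO arm),
   $\rho_{gr} = (\tilde c_{g n_r} + \epsilon)/(\tilde c_{g d_r} + \epsilon)$.
   The pseudocount $\epsilon$ (default 0.5, applied after normalization to
   both sides) keeps ratios finite and direction-unbiased when a guide
   drops out of one gate; $\epsilon = 0$ reproduces the raw ratio and
   errors loudly on zero denominators.
3. **Fold change.** Each feature's median ratio across replicates is
   computed, and a target's fold change is the median of its features'
   median ratios ("median of medians"). With the usual 4 guides per gene,
   medians of even-sized sets are midpoints of the central pair.
4. **Rank statistic.** Within each replicate, features are ranked by
   $\rho_{gr}$ (rank 1 = most enriched by default; ties take average
   ranks, so each replicate's ranks always sum to $N(N+1)/2$). Each
   feature's ranks are summed across replicates, and the target rank
   statistic is the median of its features' rank sums.
5. **Empirical p-values.** A null distribution is simulated by assigning
   random ranks: in each of $B$ iterations (default 100), every
   replicate's ranks $1..N$ are independently permuted over features,
   rank sums are recomputed, features are partitioned into disjoint
   pseudo-targets of $k$ features, and each pseudo-target's median rank
   sum is a null draw. The two-sided p-value doubles the smaller of the
   two empirical tail probabilities, with a $+1$ correction in numerator
   and denominator so $p \in [2/(M+1), 1]$ and can never be zero.

Design choices within step 5 deserve spelling out, because the procedure
is underdetermined by a verbal description:

* **Independent permutation across replicates.** Ranks could be permuted
  jointly (preserving cross-replicate correlation) or independently per
  replicate; the statistic is defined over per-replicate ranks, so the
  null permutes each replicate independently. This is the natural null of
  "no reproducible gate preference".
* **Pooling pseudo-targets.** Each iteration yields
  $\lfloor N/k \rfloor$ pseudo-target draws, all of which enter the null.
  At 2,852 guides and $k = 4$ this turns 100 iterations into
  $M = 71{,}300$ draws, giving a p-value floor of $2/(M+1) \approx
  2.8 \times 10^{-5}$ at no extra cost. The iteration count remains a
  user parameter with default 100.
* **Finite-sample correction.** The $+1$ in both tails is the standard
  correction that makes empirical p-values valid (never zero) at any $M$.
* **Separate nulls per target size.** Libraries with heterogeneous
  feature counts per target get one null per distinct $k$, since the
  distribution of a median of $k$ rank sums depends on $k$.

Monte-Carlo p-values from this machinery are checked against exhaustive
enumeration of all $N!^R$ joint rank assignments on small libraries
(up to $N = 8$ with one replicate and $N = 4$ with two, across target
sizes 1, 2 and 4); agreement is within $\pm 0.02$ everywhere, and in
practice within $\pm 0.001$.

## The alanine-scanning variant

Scanning libraries mutate each residue of the degron individually to
alanine (alanines to arginine), one codon per variant, often synthesized
as several sub-libraries sequenced from the same sorted populations. The
pipeline differences are mechanical:

* sub-library count tables are concatenated (row-stacked over disjoint
  variants) before ratios and ranks are computed — by default per-sample
  totals are recomputed on the merged matrix, which treats the
  concatenated data as one sequencing pool. Because sub-libraries can
  also be normalized separately before merging (the verbal protocol is
  ambiguous on this point), `analyze_alascan(normalize =
  "per_sublibrary")` provides the alternative; with equal per-sub-library
  depths the two conventions agree to within the pseudocount's influence.
* every target has exactly one feature, so the "median of medians"
  collapses: a variant's fold change is its own median enrichment ratio
  across replicates, its rank statistic its own summed rank, and the null
  uses pseudo-targets of size 1.

Variant identifiers follow the wild-type-letter / position /
substituted-letter convention (`H437A`, `A401R`) and are parsed into
residue positions for profile plots.

## The synthetic-data generator

The generator stands in for raw screen sequencing data, which is not
reproducible at desk scale. It emulates the sorted-gate design: feature
$g$ of a target with log-scale effect $\beta$ has stable-gate sampling
weight $a_g e^{+\beta}$ and unstable-gate weight $a_g e^{-\beta}$
(renormalized), where $a_g$ is the library abundance. The symmetric
parameterization makes the expected log count ratio exactly $2\beta$,
which the tests verify at depth $10^6$ within 5%. A resistance screen
shifts only the drug arm ($a_g e^{\beta}$ vs. $a_g$). Counts are
multinomial draws of a fixed depth per sample; setting `dispersion`
$> 0$ draws sample proportions from a Dirichlet with total concentration
$1/\text{dispersion}$ first (Dirichlet-multinomial), a standard
one-parameter overdispersion family. The default conditions mirror the
screen design the statistics were built for: 713 targets with 4 guides
each (2,852 features), 3 sorting replicates, depth $10^6$ reads per
sample, pure multinomial noise, and lognormal abundance with log-sd 0.5 —
a moderate skew typical of pooled libraries after amplification.

Seeding is hierarchical: one global seed drives a deterministic
per-sample substream (the sample index is hashed into a 31-bit seed), so
identical calls are bit-identical and adding replicates never changes the
draws of earlier samples.

What the generator does **not** model: cell-growth dynamics between
infection and sorting, sgRNA cutting efficiency and knockout penetrance,
sorter impurity, and PCR jackpotting beyond the Dirichlet family. Null
calibration and planted-hit recovery on this generator therefore
demonstrate the statistics' correctness under the design's sampling
model, not robustness to every artifact of real screens. One consequence
observed in testing is worth noting for real data too: with heterogeneous
library abundance, low-abundance guides have noisier ratios and are
overrepresented in extreme ranks, a feature the random-rank null ignores;
at the default conditions the resulting p-values are still uniform to a
KS statistic of about 0.02–0.04 at 713 targets.

```{r calibration-example, eval = FALSE}
lib <- simulate_library()                     # 713 genes x 4 guides
truth <- sim_truth(library = lib, seed = 5)   # all effects zero
sim <- simulate_reporter_screen(truth, lib)
res <- screen_analysis(sim$counts, lib, sim$design)
mean(res$results$p_two_sided < 0.05)          # ~0.05 when calibrated
```

## Dose-response quantification

Reporter degradation is quantified from per-well flow summaries: each
well's eGFP geometric mean is normalized to its mCherry geometric mean,
and treated wells are expressed as a fraction of the mean vehicle (DMSO)
ratio. The dose dependence is displayed with a LOESS curve (local-linear,
tricube weights, default span 0.75, fitted on $\log_{10}$ concentration)
and quantified with the 4PL model

$$f(x) = d + \frac{a - d}{1 + (x/c)^b},$$

where $a$ and $d$ are the upper and lower asymptotes, $b$ the slope and
$c$ the inflection. Two derived quantities are reported: $\mathrm{DC}_{50}
= c$, since $f(c) = (a+d)/2$ exactly, and the maximal depth of degradation
$D_{max} = (1 - d/a) \cdot 100\%$, read from the fitted plateau. Because
reported Dmax values in practice are often eyeballed from the deepest
observed point, an empirical alternative
$(1 - \min \text{response}) \cdot 100\%$ is carried as a secondary column.

4PL least-squares surfaces are multimodal on sparse half-log grids, so
`fit_4pl()` runs bounded Levenberg-Marquardt from 8 heuristic starts
(four log-dose quantiles for $c$, two slope magnitudes, asymptotes from
the dose extremes) with $c$ parameterized on the log scale, and keeps the
best converged fit. Vehicle wells (concentration 0) are excluded from the
fit but anchor the normalization. Flat data — response range below
`flat_tol` — return `converged = FALSE` with an undefined DC50 rather
than an arbitrary number or an exception. On a noiseless 8-point half-log
grid the fit recovers the inflection within 1% and the plateau within
0.5 percentage points; at 10% multiplicative noise the median DC50 error
across 50 seeds is well inside two-fold.

## Closed-form assay metrics

* **TR-FRET:** each titration point is the 520 nm / 490 nm emission
  ratio (acceptor over terbium donor), invariant to common gain.
  Ternary-complex titrations of molecular-glue degraders typically rise
  and then fall at high compound concentration as binary complexes
  saturate (the hook effect); `hook_peak()` locates the maximum of the
  LOESS-smoothed curve on a dense log-dose grid and flags curves whose
  maximum sits at the highest dose as "no hook".
* **Labeling efficiency:** the fraction of protein carrying the covalent
  adduct, computed from deconvoluted zero-charge mass-spectrum peak
  heights as $h_{lab} / (h_{lab} + h_{unlab}) \times 100\%$. When peaks
  are not pre-labelled, the labeled peak is identified by requiring its
  mass to sit within a tolerance (default 2 Da on deconvoluted masses)
  of the unlabeled mass plus the expected adduct mass; zero or multiple
  candidates are errors, not guesses.
* **Competition growth assays:** marker-positive fractions are normalized
  per arm to day 0, yielding enrichment trajectories.

## Numerical and interface conventions

* Tables are tab-separated UTF-8 with mandatory headers; `"."` marks a
  missing sub-library; sample gate/arm roles live in an explicit YAML
  design file rather than column-name conventions.
* Library features absent from a count table are zero-filled with a
  logged warning (guide dropout is expected); features absent from the
  library, duplicated ids, negative or fractional counts, and all-zero
  samples are typed errors.
* Control guides are ranked with everything else by default
  (`exclude_controls = TRUE` removes them before normalization), since
  two-sided p-values make hit calling direction-agnostic either way.
* Fold changes are reported on the raw ratio scale; log2 is applied only
  in plots.
* All analysis problem sizes used in the shipped tests — 713 × 4 × 3
  screens at depth $10^6$, 500-iteration nulls, 20,000-iteration oracle
  comparisons, 50-seed dose-response recovery — were chosen as the
  smallest sizes at which the corresponding properties are sharp.

## Known limitations

* The empirical null assumes exchangeable features; systematic
  abundance-variance coupling is not modeled (see above), and no
  multiple-testing correction is applied — reported p-values are raw.
* Rank-based aggregation discards magnitude information; a gene whose
  four guides are all mildly enriched can outrank one with two strong
  and two dead guides. This is a property of the method, not a bug.
* The 4PL machinery does not model biphasic (hook-shaped) degradation
  curves; the hook region is located descriptively, not fitted.
* `simulate_alascan()` draws a synthetic wild-type sequence; variant ids
  are internally consistent but do not correspond to any real protein.
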