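---
title: "Methods: integrated miRNA/LFQ-proteomics differential expression"
author: "mirProt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA/LFQ-proteomics differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirProt)
```

# Scope and model

`mirProt` models a two-group cell-line study that combines a label-free
(LFQ) proteomics screen (five replicates per group) with a miRNA
microarray screen (three replicates per group), validates selected hits
by reference-normalized qPCR, and integrates the two screens by pairing
differentially expressed miRNAs with inversely regulated protein targets
drawn from a user-supplied miRNA–gene target map. A small motif-scanning
utility covers the companion question of whether a transcription factor's
binding motifs occur in a miRNA's promoter-proximal upstream window.

The package deliberately starts downstream of raw-data processing: MS
spectra search, match-between-runs, and probe-level array normalization
are out of scope; the inputs are a MaxQuant-style protein-groups table
and a complete probes-by-samples miRNA matrix.

# The proteomics stage

## Cleaning and valid-value filtering

`cleanProteinGroups()` removes decoy ("Reverse"), contaminant, and
only-identified-by-site rows and converts zero intensities to missing
(LFQ exports use 0 for "not quantified"). `filterValidValues()` then
retains a protein iff it has at least `minValid = 3` observed values —
by default *in at least one group*. The phrase "at most two missing out
of five" is ambiguous between a per-group and an either-group reading;
the either-group (`rule = "any"`) interpretation is the Perseus
convention and deliberately preserves group-absent proteins, which are
exactly the ones MNAR imputation is designed to rescue (a protein
convincingly present in one condition and undetected in the other is
often the most interesting kind of hit). The strict both-group rule is
available as `rule = "both"`.

## MNAR imputation

Low-abundance intensities drop below the detection limit, so
missingness is *not at random*: the lower the true intensity, the higher
the probability of a missing value. The standard remedy imputes from a
"downshifted Gaussian": per sample column with observed mean $m$ and
standard deviation $s$, each missing entry is drawn independently from

$$\mathcal N\!\left(m - \text{downshift}\cdot s,\;
(\text{width}\cdot s)^2\right),$$

with defaults width $= 0.3$ and downshift $= 1.8$ (the
transformation-comparison mode uses $1.75$). Imputation is per sample
column — each sample has its own detection limit — and observed cells
are never altered (asserted bit-exactly in the tests). A column needs at
least two observed values, otherwise $s$ is undefined and the function
errors rather than guessing. With `downshift = 0` and vanishing width
the imputed values collapse to the column mean, a useful sanity limit.

## The combined significance filter

Rather than a multiplicity correction — which at $n = 5$ costs much
sensitivity — the pipeline uses a *combined* filter: a protein is
`significant` iff Welch's t-test gives $p < 0.05$ **and** the
standardized log2 fold change satisfies $|z| > 1$. The $z$-score is the
standardization of the per-protein mean log2 ratio across all quantified
proteins (sample sd, $n-1$ denominator) — the quantity a volcano plot
puts on its x axis. This is a documented interpretive choice: the
combination of a variance-based and an effect-size-based criterion is
what controls the false-discovery proportion while keeping sensitivity,
and the null-calibration and parameter-recovery tests quantify both on
synthetic data (the combined filter always flags a subset of the
$p<0.05$ set; sensitivity for fourfold effects at 20% CV exceeds 0.9).

Two further tiers nest inside `significant`: `differential` adds a
raw-scale ratio $\ge 2$ or $\le 0.5$, and `top` a ratio $\ge 4$ or
$\le 0.25$. The chain `top` $\subseteq$ `differential` $\subseteq$
`significant` holds by construction and is asserted on every run.

The reported ratio uses the geometric convention $2^{\overline{\Delta
\log_2}}$ by default. Because legacy analyses often computed the
*arithmetic* mean ratio in a spreadsheet, `ratioMethod = "arithmetic"`
reproduces that convention; both are logged in the result metadata.
Tests are two-sided throughout, and a degenerate comparison with zero
variance in both groups and equal means returns $p = 1$ by convention.

# Power design

`minDetectableEffect(n, alpha, power)` solves for the smallest Cohen's
$d$ at which a two-sided unpaired two-sample t-test reaches the target
power, using the noncentral t distribution ($\mathrm{df} = 2n-2$,
noncentrality $d\sqrt{n/2}$) and `uniroot` to $|\Delta d| < 10^{-6}$.
For the modelled design ($n=5$, $\alpha=0.05$, power $0.9$) this gives
$d = 2.348$. The solver is cross-checked three ways: against
`power.t.test`, against the large-df normal approximation
$d \approx (z_{1-\alpha/2}+z_{\beta})\sqrt{2/n}$, and against a
$10^5$-replicate Monte-Carlo simulation.

Converting $d$ to a raw-scale fold change requires the within-group
spread on the log scale. The exact log-normal relation is used:
$\mathrm{FC} = \exp(d\,\sigma_{\ln})$ with
$\sigma_{\ln} = \sqrt{\ln(1+\mathrm{cv}^2)}$ (for small cv,
$\sigma_{\ln} \approx \mathrm{cv}$). The source workflow never states
its conversion arithmetic, so the expected band around the reported
1.7–1.8 fold equivalent is kept deliberately loose; with the four
observed group CVs (25.4, 21.4, 21.9, 19.6%) the exact relation yields
1.58–1.80.

# The miRNA stage

Arrays are complete (no censoring), so the stage reduces to probe
de-duplication (duplicate identifiers collapse to the per-sample
median), per-feature two-sample t-tests on log2 intensities, and
tiering. At $n = 3$ the equal-variance t-test is the default (a Welch
correction at two degrees of freedom sacrifices too much power for no
robustness gain on arrays); Welch is available by flag.

Selection uses the **raw** p-value ($p < 0.05$) combined with the fold
cutoff, while the BH-FDR is always computed and reported alongside —
the two selection conventions coexist in practice and the printed
top-hit tables themselves contain rows that are non-significant after
adjustment, which only the raw-p reading reproduces. `useFdr = TRUE`
switches selection to the adjusted values.

Fold changes are reported in the array's *signed* convention:
$r \ge 1 \mapsto +r$, $r < 1 \mapsto -1/r$, a strictly monotone
bijection from $(0,\infty)$ onto $(-\infty,-1]\cup[1,\infty)$ (so a
ratio of $1/111.69$ prints as $-111.69$). Locus annotation attaches a
cytoband and nearest common fragile site from a lookup table; lookups
are total (unknown identifiers annotate to `NA`). Locus fractions use
*prefix* matching — `"14q32"` aggregates 14q32.2 and 14q32.31 — because
locus-level summaries are reported at that resolution.

# qPCR quantification

`ddctFoldChange()` implements the comparative-CT method with
amplification efficiency fixed at exactly 2 (the method's assumption;
standard-curve efficiency estimation is out of scope). Per sample
$\Delta CT = CT_\text{target} - CT_\text{reference}$; groups are
aggregated by the arithmetic mean of $\Delta CT$ and
$\text{fold} = 2^{-\Delta\Delta CT}$. Reference normalization cancels
any per-sample CT offset, an invariance asserted to $10^{-12}$
(floating-point associativity precludes a bitwise assertion).
`percentChange()` renders folds in the reduction/increase reporting
convention (fold 0.001 is a 99.9% reduction).

# Integration

`pairInverse()` is a pure filter over the target map: an edge survives
iff the miRNA and the protein both pass their fold cutoffs (defaults 4
and 4, the "top hits" setting) *and* move in opposite directions. It
never invents edges (output $\subseteq$ map, asserted), is monotone in
the cutoffs, and with fully powered upstream stages recovers every
planted inverse edge — these are the three properties the test suite
enforces, the last by simulation with ground truth. Significance
filtering is intentionally left to the upstream DE stages so the
pairing rule stays a deterministic set operation. Gene symbols match
case-insensitively and exactly; alias resolution is a documented
non-goal.

The packaged target-map fixture is a **synthetic reconstruction** (and
is named accordingly): of the displayed network only the per-miRNA
target counts (7/3/7), the common target PAX8, and the ALDH1A2 edge of
miR-138-5p are known facts; the remaining gene symbols are plausible
stand-ins drawn from the printed protein-target table. Tests assert
only the known facts.

# Motif scanning

`scanMotifs()` slides each motif over every offset of the window and
counts exact base matches (ungapped; `N` never matches), reporting the
top hits per motif ranked by matches then position. Ungapped counting
is a deliberate simplification of gapped promoter alignment: the
quantities of interest are match fractions of 9–11 bp motifs, which
ungapped scanning captures while staying exhaustively verifiable (the
suite compares the scan against a brute-force enumeration on short
sequences). The default is forward-strand only — upstream windows are
supplied in promoter orientation — with `bothStrands = TRUE` available;
reverse-strand hits are equivalent to forward hits of the
reverse-complemented motif, also asserted. Coordinates are 0-based
relative to the window start; ties break by ascending position.
`upstreamWindow()` returns the final `window` (default 5000) bases of
an upstream-region FASTA record, whole with a warning when shorter.

# The synthetic-data module

The generators define the study conditions the tests and examples run
under; they are first-class, tested code, not throwaway fixtures.

* **Intensities** are log-normal. Within-group log2 spread derives from
  the coefficient of variation by the exact relation
  $\sigma_{\log_2} = \sqrt{\ln(1+\mathrm{cv}^2)}/\ln 2$, so the
  realized raw-scale CV of complete features equals the configured cv
  up to Monte-Carlo error. Defaults: log2 centre 25, between-feature sd
  2 (the typical scale of LFQ exports), cv 0.22 for proteomics (within
  the 19.6–25.4% band observed across the four groups of the modelled
  study) and 0.20 for arrays.
* **Effects**: a configured fraction of features (default 10%) receives
  a log2 shift in the treatment group, magnitudes uniform over the
  2–100-fold range observed for real top hits, signs random.
* **Missingness** (proteomics only) is logistic in the true log2
  intensity: censoring probability
  $\mathrm{plogis}(-(x-a)\cdot\text{steepness})$ with the anchor $a$ at
  the `mnarCensorQuantile` quantile of the simulated intensities
  (defaults 0.1 and steepness 2 give ~11–12% missing, the typical LFQ
  range). The mechanism behind downshifted-Gaussian imputation is
  exactly this left-censoring story, so the generator makes it
  explicit. Setting the censor quantile to 0 disables missingness
  entirely — a plain logistic anchored at the sample minimum would
  still censor half the entries there, so the zero case is
  special-cased, and the miRNA generator uses it.
* **Reproducibility**: one master seed per configuration with fixed
  per-stage substream seeds (background/effects, noise, censoring), so
  the uncensored matrix can be re-materialized independently of the
  censoring draw — the MNAR-direction test exploits exactly this.
* **qPCR tables** place the reference gene at a configurable CT and the
  target $\text{baseDeltaCt} - \log_2(\text{fold})$ cycles above the
  per-sample reference, with Gaussian cycle noise.
* **Promoters** are uniform ACGT backgrounds with a motif copy planted
  at a known offset after exactly `nMismatches` distinct substitutions.

What the generators do **not** emulate: correlated proteins or miRNAs,
peptide-level variance structure, array probe effects or background,
batch effects, and heavy-tailed intensity noise. Passing the recovery
tests therefore demonstrates that the statistical machinery is
implemented correctly under the model's own assumptions — not that the
pipeline is robust to every pathology of real data.

# Numerical choices and problem sizes

* The power solver brackets on $[10^{-8}, 10^3]$ with `uniroot`
  tolerance $10^{-8}$; all power/fold conversions are pure and
  deterministic.
* Degenerate inputs error early and specifically: imputation on a
  column with fewer than two observed values, z-scores of a constant
  vector, valid-value thresholds above the group size, promoter windows
  shorter than the motif.
* Writers serialize numerics as `%.17g`, so every writer/reader pair
  round-trips bit-exactly.
* The test suite runs its simulations at 500–2000 features, which puts
  three binomial standard errors around a 5% null rate at about ±1.5
  percentage points and keeps the whole suite under ten seconds on one
  CPU; the Monte-Carlo power confirmation uses $10^5$ replicates
  (±0.3 percentage points at three standard errors).
* `runPipeline()` stamps every tabular output with the MD5 of the
  effective configuration and the seed, and identical configurations
  reproduce byte-identical tables.

# Known limitations

* No between-run normalization: LFQ intensities are taken as already
  comparable across samples.
* The inverse-pairing stage is only as good as the supplied target map;
  no sequence-based target prediction is attempted.
* Signed folds and ratio tiers assume two groups; multi-group designs
  are out of scope.
* The equal-variance default for arrays and the raw-p selection default
  are field conventions, not universally optimal choices; both have
  flags.
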