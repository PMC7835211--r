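---
title: "Dual-contrast rank enrichment: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-contrast rank enrichment: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankenrich)
```

# Scope and design

`rankenrich` asks whether gene sets move *jointly* across two
differential-expression contrasts — prototypically, pathways induced by a
stimulus (high glucose) and reversed by a drug (the HDAC inhibitor valproic
acid) in a 2 × 2, four-group design (LG, LGV, HG, HGV). The package covers
the chain from a count matrix to per-set statistics; it deliberately starts
*after* alignment and read counting, and it deliberately stops *before*
figure styling: grids and tables are exported, plotting is left to the
caller.

# The differential-expression stand-in

The DE stage is a minimal moderated two-group t-test on log2
counts-per-million, not a re-implementation of the edgeR/limma family. That
is a considered choice: the enrichment statistics downstream consume only a
(log2FC, p) pair per gene, the moderated t on log-CPM is closed-form and
calibration-testable, and users with a preferred DE tool can inject its
output via `read_de_table()` and bypass this stage entirely.

Per gene, with `n_a`, `n_b` samples per group on log-CPM values:

* log2FC = mean(b) − mean(a); pooled residual variance `s²_g` on
  `d_g = n_a + n_b − 2` df;
* prior `(d₀, s₀²)` fitted by moment matching on log variances:
  `Var(log s²)` in excess of `trigamma(d_g/2)` identifies `trigamma(d₀/2)`
  (d₀ = ∞ when there is no excess — the prior is then a point mass), and the
  mean of the matched log-variance residual identifies `s₀²`;
* `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`;
  `t = log2FC / (s̃_g √(1/n_a + 1/n_b))` on `d₀ + d_g` df, two-sided.

Numerical choices: the pseudo-count is `c = 0.5`
(`log2((count + c)/(libsize + 2c) · 10⁶)`), the common convention that keeps
zeros finite; p-values are floored at the smallest positive double so the
downstream log-score is always defined; a zero-variance gene with `d₀ = 0`
(only possible with a user-supplied degenerate prior) is flagged and assigned
that floor rather than dividing by zero.

Normalization is total-count CPM only. TMM-style composition factors are
deliberately omitted: the simulator's libraries are composition-balanced by
construction, so the factors would be ≈ 1 where we can test them and
untested elsewhere. This is a documented limitation: when a large fraction
of the transcriptome shifts in one direction (or planted effects sit in a
small gene universe), CPM fold-change estimates absorb a composition bias of
roughly `log2(Σ shifted reads / Σ reads)`; at the default scale (50-gene
blocks in a 5000–10000-gene universe) it is below 0.05 log2 units.

# The ranking score

Genes are ranked by `s_g = sign(log2FC) · (−log10 p)`. The verbal recipe
"sign of the fold change divided by the log10 p-value" that circulates for
this score is non-monotone if applied literally — `sign/log10(p)` sends the
*most* significant up-regulated genes toward 0 from below — and contradicts
its own stated purpose of ranking from most up- to most down-regulated. The
implemented score induces exactly the ordering of `sign(log2FC)/p` (which the
test suite verifies by brute force) while staying bounded and
floating-point-safe; the literal variant is kept behind
`score_genes(..., literal = TRUE)` for audit. Raw p, not FDR, enters the
score: BH adjustment is monotone within a table, so the ordering would be
unchanged, but raw p keeps the score independent of the number of genes
tested. The p floor defaults to 1e−300, guarding `log10` against underflowed
p-values.

# Classic-mode pre-ranked GSEA

The 1D stage is the unweighted KS-style statistic: walking the ranked list,
the running sum gains `1/Nh` at members and loses `1/(N−Nh)` at non-members;
ES is the deviation of largest magnitude. Implementation detail that matters
for reproducibility: all extremum comparisons are done on the walk scaled by
`Nh(N−Nh)`, which makes every value an exact integer in double arithmetic —
mathematically tied maxima then compare equal instead of differing in the
last bit, and the documented tie rule (first deviation encountered wins,
logged) is actually reachable.

The null is gene-tag permutation — `nperm` random same-size member sets —
because the input is a pre-ranked list: phenotype permutation needs
per-sample data this stage never sees. Since that null distribution depends
only on set size, permutations are shared across sets of equal
post-intersection size, reducing cost from `O(sets · nperm · N)` to
`O(sizes · nperm · k)` with identical semantics. The nominal p is
plus-one-corrected within the sign class (`p > 0` always); NES divides ES by
the mean |null ES| of matching sign; the q-value compares, per sign, the
pooled-null and observed NES tail fractions, capped at 1. Defaults
`min_size = 10`, `max_size = 5000`, `nperm = 1000` follow pre-ranked GSEA
convention; none is prescribed by theory, and `nperm` bounds the smallest
attainable p at about `1/nperm`. Genes in a set but absent from the profile
are dropped (intersection semantics); a set with no overlap is skipped with
a logged reason, and a set covering the whole list is an error, since the
statistic is undefined.

# The two-dimensional rank MANOVA

The joint stage recomputes scores and scaled ranks *within the common gene
universe* of the two contrasts (ranks are not portable across universes),
mapping each gene to `r = (rank − (N+1)/2)/N ∈ (−0.5, 0.5)`, mean-centered
exactly even under ties. A set's displacement per dimension is
`s_d = 2·mean(r_d over members)`; the factor 2 makes an extreme top-flank
set approach `(N−k)/N ≈ 1` independent of N.

Significance is a one-way two-group MANOVA — members against all other
genes — on the bivariate ranks. The procedure "MANOVA of ranks" is
under-specified in common usage; this package fixes the simplest reading
consistent with testing displacement away from a uniform rank distribution:
members-vs-rest grouping, Pillai's trace, which for two groups is an exact
monotone transform of Hotelling's `T²`, with
`F = T²(N−3)/(2(N−2)) ~ F(2, N−3)`. This closed form is verified against
base R's `manova()` to 6 significant figures in the acceptance suite.
Alternative formulations (membership as a covariate-adjusted factor, other
trace statistics) are *not* guessed at; with two groups the four classical
MANOVA statistics coincide anyway. FDR over sets is Benjamini–Hochberg,
consistent with the package's global FDR language; `min_size = 10` for this
test because the F approximation on ranks is fragile for very small k.
Duplicate gene IDs are resolved at join time (smallest p wins, logged) — the
table readers refuse duplicates rather than resolving them silently.

The rank–rank density grid uses equal-width bins on [−0.5, 0.5], half-open
`[lo, hi)` with the last bin closed; rows index r1 ascending, columns r2
ascending, and the grid always sums to N. The stated conservation property
holds down to a single bin, so `bins = 1` is allowed even though any real
plot uses many.

# The synthetic world

`simulate_experiment()` emulates the four-group hepatocyte design: negative
binomial counts with mean `λ_g` and variance `λ + φλ²`, dispersion trend
`φ_g = φ₀ + a/λ_g`, per-sample library factors entering through the NB mean
(which keeps the family closed, unlike post-hoc thinning), and planted
coordinated shifts: members of a planted set have HG and HGV means scaled by
`2^δ_glucose` and HGV further by `2^δ_vpa`, so contrast HG-vs-LG carries
`δ_glucose` and HGV-vs-HG carries `δ_vpa`. Whether normoglycemic cells
respond to the drug the same way is left as an independent switch
(`vpa_affects_lg`, default off) rather than assumed.

Defaults, fixed once as a realistic stated world:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 10000 | order of the expressed-gene universe after filtering in a liver cell line |
| `n_reps` | 3 | the triplicate design |
| baseline log2 mean | N(5, 2) | long-tailed abundances, median ≈ 32 counts |
| `φ₀`, `a` | 0.05, 2 | BCV ≈ 0.22 for abundant genes, rising at low counts, the shape RNA-seq dispersion trends show |
| `libsize_cv` | 0.2 | typical depth variation across libraries |
| planted blocks | 5 sets × 50 genes, δ = +1.5/−1.5 | the induced-then-attenuated geometry under test |
| null sets | 30 sets, sizes 20–100 | pathway-sized negative controls |
| `frac_dropout_members` | 0 | planted sets fully coherent unless stressed |

What the generator does **not** emulate: GC and length bias, batch effects,
correlated genes within pathways beyond the planted mean shift, alignment
artifacts, and composition-unbalanced libraries. A green test therefore
establishes that the statistics are correct and calibrated *under the NB
model with independent genes* — it does not certify behaviour under
confounding that the model excludes.

Determinism contract: identical seed and configuration give bit-identical
output (verified at byte level on the serialized tables), and the simulator
restores the caller's RNG state.

# qPCR arithmetic

The comparative-Ct module implements `ΔCt = Ct_target − Ct_reference`,
`ΔΔCt = ΔCt − mean(ΔCt | calibrator group)`, `RQ = 2^−ΔΔCt`, under the
standard assumption of amplification efficiency exactly 2 per cycle;
efficiency-corrected variants are out of scope. The calibrator group is
geometric-mean-centered at RQ = 1 by construction. ChIP enrichment uses
percent-of-input with explicit dilution adjustment,
`Ct' = Ct_input − log2(1/f)`, `%input = 100 · 2^(Ct' − Ct_IP)`; the input
fraction `f` is a required argument precisely because no universal default
exists. The one-way ANOVA behind qPCR bar-plot asterisks is provided only as
a convenience wrapper (`rq_anova`).

# Calibration evidence

Everything quantitative claimed above is computed by the test suite, not
asserted: BH and the ES walk match brute-force oracles exactly; the rank
MANOVA matches `stats::manova()`; under the all-null simulation the DE
p-values and the 2D set p-values pass per-seed KS uniformity checks with
type-I error near nominal; planted log2FC is recovered without material bias
at the default scale; and planted +1.5/−1.5 sets are recovered at FDR ≤ 0.05
with the expected upper-left/lower-right geometry. See
`tests/testthat/test-acceptance.R` for the exact criteria and tolerances.

# Known limitations

* CPM-only normalization (composition bias under severe asymmetric
  regulation, see above).
* The DE stand-in is not numerically equivalent to edgeR or limma-voom; it
  is calibrated under the simulator's model, and external DE tables are the
  escape hatch.
* Two contrasts only; higher-dimensional joint enrichment is out of scope.
* Gene-tag permutation is the only GSEA null; sample permutation would
  require count-level input at the enrichment stage.
* Pathway-sized sets (k ≥ 10) are assumed for the 2D F approximation; the
  1D GSEA handles smaller sets but its p resolution is `1/nperm`.
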