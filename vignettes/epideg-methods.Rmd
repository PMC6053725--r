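---
title: "epideg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epideg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epideg` predicts which genes are differentially expressed between two
conditions from histone-mark ChIP-seq features, using the genes already
called by RNA-seq as training labels. This vignette documents the model and
its assumptions, every tunable parameter, what the synthetic-data generator
does (and does not) emulate, and the places where the methodology was
under-determined and a design decision had to be made.

## The model

The unit of analysis is the gene. For each gene the package assembles a
real-valued feature vector from ChIP-seq tracks indexed by genotype (wild
type `C` vs insensitive mutant `e`), histone mark (`K9`, `K14`, `K23` by
default) and condition (`A` air / `C` treated), and from peak calls on
those tracks. Training labels are binary — `up` or `down` — taken from the
RPKM fold-change rule below; the classifier therefore answers *"given that
a gene responds, in which direction?"* and its class probability is used to
rank unlabeled candidates. This is a deliberate restriction: genes that do
not respond at all are handled by the candidate-pool filter and the
precision cutoff, not by a three-class model.

### Coordinates

All interval arithmetic is 0-based half-open (BED convention). GFF3/GTF
input (1-based closed) is converted at the parser boundary, and GRanges
machinery is used internally with the `+1` shift applied at construction.
A read overlaps a segment when they share at least one base; abutting
half-open intervals do not overlap.

### Gene segments

Up to 16 named segments are derived per gene, strand-aware: `TSS1500`,
`TSS200` (upstream promoter windows), `TSSplus200` (first 200 bp
downstream of the TSS), `TTS200` (200 bp past the termination site),
`UTR5`/`UTR3` (from the annotated CDS), `first_exon`, `first_intron`,
`exon_body`, `intron_body`, `last_intron`, `last_exon`, `single_exon`,
`single_intron`, `full_transcript` (union of exons) and `full_gene` (exon
span including introns). Conventions worth stating:

- *first*/*last* are in transcription order and are populated whenever at
  least one element exists (for a one-intron gene `first_intron`,
  `last_intron` and `single_intron` all name the same interval);
  `single_*` is additionally populated only for exactly one element;
  `*_body` (excluding first and last) requires at least three.
  Single-exon genes get `single_exon` but not `first_exon`/`last_exon`:
  the segment list treats them as parallel categories.
- `UTR5`/`UTR3` require a CDS in the annotation and are missing otherwise
  — missing, not zero-length, and missingness propagates into the feature
  matrix as `NA`.
- Windows are clipped to `[0, chromosome length)`.
- With several isoforms per gene the longest transcript (summed exon
  length) is used; the choice is arbitrary but deterministic.

### Signal features

Per track, the read count over each segment is normalized RPKM-style,
`count / ((segment_length/1000) × (total_reads/10⁶))`. The methodology
we follow states only "normalized over segment length and total reads";
the RPKM form was chosen so chromatin densities share units with the
expression table. Two differential quantities are derived per
genotype × mark: `diff = (x_trt − x_ctl)/((x_trt + x_ctl)/2)`, bounded in
[−2, 2] with the bounds attained when one side is zero and defined as 0 at
(0, 0); and `log2FC = log₂((x_trt + ε)/(x_ctl + ε))` with pseudocount
ε = 10⁻³ on the normalized densities. Both are oriented treated-minus- (or
over-) control, so their signs agree whenever both inputs are positive.

Feature names concatenate the vocabulary: `CK9A_UTR5` is genotype C, mark
K9, condition A, segment UTR5; `CK9diff_UTR5` and `CK9log2FC_UTR5` are the
differentials. With the default vocabularies this yields 2 × 3 × 4 × 16 =
384 segment features plus 72 peak features (below), 456 in total. The
schema is configuration-driven rather than hard-coded: the vocabulary
determines the roster.

Missing values (absent segments, genes without peaks) are imputed to 0
immediately before model fitting — absence of signal is informative here —
and a per-column missingness report is attached to the imputed matrix.

### Peak features

Peaks are assigned to the nearest gene whose span lies within 5 kb (gap
distance, 0 when overlapping, strand ignored; equidistant ties go to the
lexicographically smallest gene id, which makes runs reproducible). Per
track each gene gets `numberpeaks`, `avg_peaksize`, `avg_FE` (mean fold
enrichment vs control) and `avg_distance`, as arithmetic means over its
assigned peaks.

Differential peaks between conditions are derived from peaks present in
both conditions (overlapping intervals, paired): the treated counts are
rescaled by a single factor 2^(−median M) so that the median
`M = log₂(trt/ctl)` over common peaks is exactly zero, then peaks with
`|M| ≥ 0.4` and `p ≤ 0.05` are kept, where p comes from the conditional
binomial test that the two counts share a Poisson mean (success
probability f/(1+f) given the normalization factor f). This replaces a
full M-A regression normalization with its median-shift special case: the
upstream method we emulate is used as a black box in the source material
and only its M statistic and thresholds are specified, so the package
implements the reproducible core. The differential peak's fold enrichment
is the M-derived ratio 2^M (the alternative — re-using the peak caller's
enrichment — is not reconstructible from peak files alone).

### DEG labels

A gene is labeled `up` when `rpkm_trt / rpkm_ctl > 1.5`, `down` for the
reverse, and in either case only when `max(rpkm_ctl, rpkm_trt) > 1`; RPKM
values are means over replicates. Two readings were possible for the
expression floor ("RPKM larger than 1"): requiring the *larger* condition
mean (chosen, and configurable) keeps genes that are silent in one
condition and expressed in the other — exactly the strongest responders —
whereas requiring both means would drop them. Labels are antisymmetric
under swapping the condition columns. `replicate_correlation()` (Pearson
on log2 RPKM) is provided as the replicate-QC statistic.

### Feature selection

- **Information gain**: `H(label) − H(label | feature)` in bits, with
  continuous features discretized by recursive binary entropy splits
  accepted under the minimum-description-length criterion. A feature with
  no acceptable split scores 0; an equal-frequency 10-bin fallback is
  available for degenerate cases but is off by default so that noise
  features stay at zero gain. Features with ≤ 10 distinct values are used
  as categories directly.
- **ReliefF**: all instances serve as sampling points; for each, the 10
  nearest hits and the prior-weighted nearest misses per class move
  feature weights by range-normalized value differences (Manhattan
  distance). Constant features get weight 0 by construction.
- **CFS**: forward best-first search (patience 5) over subsets scored by
  `merit = k·mean(r_cf)/√(k + k(k−1)·mean(r_ff))`, both correlation terms
  measured as symmetrical uncertainty on MDL-discretized features.

Ranked selectors keep the top `round_half_up(fraction × total)` features.
Round-half-up is forced by the documented feature counts this rule must
reproduce (5% of 468 → 23, 40% of 114 → 46, 30% of 84 → 25): floor fails
the second and ceiling fails the other two. The default fraction is 0.05.
In cross-validation the ranking is recomputed inside each training fold,
so no information from held-out genes leaks into selection.

### Classifiers

All five registered learners emit `P(up)`:

- `logistic` — ridge-penalized logistic regression by IRLS; the penalty
  (10⁻⁸, on standardized features, intercept unpenalized) exists purely
  for conditioning under separation. This is the headline model.
- `classification_via_regression` — least squares on the 0/1 indicator,
  predictions clipped to [0, 1]. The original formulation uses model
  trees; the linear special case is used here and documented as such.
- `lmt` — a small logistic model tree: depth-≤2 CART, ridge-logistic
  models in leaves with ≥ 30 rows and both classes, leaf rates otherwise.
- `random_forest` — 100 bagged CART trees (Gini, `mtry = ⌊√p⌋`),
  probabilities averaged.
- `random_subspace` — 10 CART trees each trained on a random half of the
  features, probabilities averaged.

The tree learner is implemented in-package (no tree package is assumed to
be installed); it is a plain CART with vectorized split search, minimum
node size 5 and depth cap 12. Ensemble randomness is seeded; training is
deterministic given (data, seed).

### Evaluation protocol

The labeled genes are split 80/20 by `stratified_split()`: the total
training size is `round_half_up(0.8 N)` and per-class counts follow the
largest-remainder method, which reproduces an exact 2139/535 split of 2674
genes. Stratification is an assumption (the protocol we follow does not
say); largest-remainder is what makes the printed totals attainable
exactly. 10-fold CV is stratified the same way (shuffle within class, deal
round-robin), reports per-fold and pooled confusion metrics (accuracy,
precision, recall, positive-class F, support-weighted F, MCC) and the AUC
of pooled out-of-fold probabilities in the Mann-Whitney form (ties ½).
Both the positive-class and the class-weighted F are reported because
published F values of this kind are ambiguous between the two. Zero
denominators yield 0 with a flag rather than NaN.

### Candidate selection

Candidates are the top 60% of genes by the larger condition-mean RPKM.
Pool genes are ranked by max-class probability (`max(p, 1−p)`; a
confidently-down gene is as valuable as a confidently-up one — this is the
reading of "class probability estimation" adopted here, and ties break by
gene id), grouped into 200-gene bins, and per-bin precision is computed
among *known* (RNA-seq-labeled) genes as the fraction whose predicted
direction matches. "Total precision > 0.95" is applied to the cumulative
(prefix) ratio; the selection is the longest prefix of bins whose
cumulative precision stays ≥ 0.95, hence always a whole number of bins.
Both the matched and known counts are emitted per bin so that alternative
precision readings can be recomputed from the output. Selected genes are
evaluated for direction agreement against an independent label set (by
default genes with |FC| > 4 in the second genotype): matches are TP,
contradictions FP, unevaluated genes neither. Enrichment of known DEGs in
the selection is tested with the hypergeometric upper tail.

## The synthetic world

`generate_dataset()` plants a known mark→expression association so every
stage is testable offline. Its defaults are the stated world of the
package's tests and are not tuned:

| parameter | default | rationale |
|---|---|---|
| `n_genes`, `n_chromosomes` | 1000, 2 | enough genes for stable CV at test scale |
| `frac_up`, `frac_down` | 0.10, 0.15 | down-regulation more common than up, as in the treatment response emulated |
| `effect_size` | 2 | 4-fold planted shift, log2 scale |
| `informative_marks` | K14, K23 | the treatment-responsive marks; K9 stays condition-independent |
| `responsive_genotype` | C | the mutant `e` carries no planted effect |
| `read_depth` | 200,000/track | keeps per-gene counts in the tens-to-hundreds |
| `noise_dispersion` | 0.1 | NB variance μ + 0.1 μ² — clearly overdispersed tag counts |
| replicate noise | lognormal, σ = 0.1 | high replicate correlation (~0.99), typical of good libraries |

Mechanics: non-overlapping genes with 1–6 exons and ≥ 3 kb intergenic gaps
(nearest-gene assignment is unambiguous by construction, ties are tested
separately on crafted fixtures); per-gene acetylation propensity coupled
to the expression baseline; per-track read counts negative-binomial with
the planted log2 shift applied to treated-condition means of planted genes
in the responsive genotype × informative marks only; reads emitted as
fixed 50 bp intervals uniform over the gene body ± promoter, plus 5%
uniform background; one peak locus per enriched gene shared across
conditions (so differential analysis sees common peaks) with fold
enrichment increasing in coverage; expression tables with two replicates
per condition whose planted fold changes satisfy the DEG thresholds up to
sampling noise. One master seed drives independent derived streams per
component, so the same configuration is byte-identical on rerun.

What the generator does **not** emulate: sequence content, mappability or
GC bias, fragment-length effects, peak-shape heterogeneity, isoform
switching, or correlated biological replicate structure. A green
end-to-end test therefore establishes that the pipeline's statistics and
bookkeeping are correct under a favorable, known signal — not that the
model will reach any particular performance on real chromatin data, where
effect sizes are smaller and features are strongly collinear.

For classifier-level checks, `simulate_labeled_features()` skips genomics
entirely: balanced up/down labels, `n_informative` Gaussian features with
a class mean gap of `effect_size`, the rest pure noise. The package's
recovery check (median 10-fold CV AUC ≥ 0.85 at effect 2 with 10
informative of 100 features, and AUC ≈ 0.5 at effect 0) uses a top-10%
selection cut, matching the planted 10/100 ratio.

## Numerical choices and edge cases

- `round_half_up()` everywhere a fraction becomes a count.
- `diff` at (0,0) is 0 by definition; `log2FC` at (0,0) is 0 because the
  pseudocount cancels.
- Zero-length segments produce missing densities (not ∞ or 0).
- The median-M normalization computes `M = M_raw − median(M_raw)` rather
  than re-logging rescaled counts, keeping the recentering exact in
  floating point.
- Discretization uses `match()` on sorted unique doubles, not `factor()`,
  because distinct doubles can collide as character levels.
- CV folds whose training data collapse to one class are skipped with a
  warning; if the surviving out-of-fold labels are single-class the AUC is
  NA rather than an error.
- The empty-selection case (first bin below the precision bar) warns and
  returns an empty table, preserving the bin-multiple invariant.
- MCC on the worked confusion table (TP 40, FP 10, FN 20, TN 30) is
  1000/√(6×10⁶) ≈ 0.408 — the value of the standard closed form, which
  the tests assert.

## Known limitations

- The exact 468-feature roster of the study the package generalizes
  cannot be reconstructed from public materials (384 segment features are
  derivable; the remaining 84 do not decompose from any stated peak
  vocabulary — the default schema yields 72). The schema is therefore
  configurable, and counts are asserted structurally (2×3×4×16) rather
  than against 468.
- Peak *calling* and expression *quantification* are consumed, not
  implemented: inputs are narrowPeak and RPKM tables.
- `classification_via_regression` and `lmt` are the linear/small-tree
  special cases of their namesakes, adequate as probability emitters but
  not bit-compatible with the original tree-ensemble implementations.
- Binary direction labels cannot express "responds weakly"; quantitative
  expression prediction is out of scope.
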