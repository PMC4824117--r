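---
title: "Methods: classifying deleterious missense variants from sequence profiles and structural ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying deleterious missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delvar)
```

## The problem and the model

A missense variant replaces one amino acid in a protein. Whether that
substitution disrupts the protein's molecular function depends both on
evolutionary constraint at the position (visible in a sequence profile)
and on the physical consequences for the folded structure (visible in the
energetics of refined structural models). `delvar` treats deleteriousness
prediction as binary classification with sparse logistic regression over a
fixed 106-feature representation:

$$P(\text{deleterious}\mid x) = \sigma\!\left(\beta_0 + \sum_{j \in S}
\beta_j z_j\right), \qquad z_j = \frac{x_j - \mu_j}{s_j},$$

where $S$ is a selected feature subset (at most 20 in combined mode) and
$\mu_j, s_j$ are center/scale learned on the training data only. Logistic
regression is used deliberately: the score is a probability, the decision
boundary is linear in interpretable physical quantities, and the
per-feature terms $\beta_j z_j$ decompose the logit exactly, which is what
makes the automated physical interpretation possible.

The key modelling assumptions are (i) feature effects are additive on the
logit scale; (ii) structural disruption is detectable as a *shift of the
variant ensemble relative to the native ensemble* in individual score
terms; and (iii) one substitution at a time (multi-site variants are out
of scope).

## Feature construction

**Sequence (5).** From a PSIBLAST ASCII PSSM: the log-odds of the native
and variant residues at the position, their difference
`pssm_diff = pssm_nat − pssm_mut`, the position's information content
(bits), and `aminochange`, a 3-level ordinal (0 = same broad chemical
class, 1 = class change, 2 = charge reversal) over the classes nonpolar
{A,V,L,I,M,F,W,P,G}, polar-uncharged {S,T,C,Y,N,Q}, positive {K,R,H},
negative {D,E}. `pssm_diff` is included as the canonical profile
substitution statistic; `aminochange` is deliberately coarse — it encodes
"broad chemical difference", not a substitution matrix.

**Structure (101).** All structural features are *native-ensemble
normalized*: a raw Rosetta score term is meaningless across proteins, but
the shift of the variant's distribution relative to the native ensemble's
spread is comparable. The workhorse is

$$z_t = \frac{\overline{v_t} - \overline{n_t}}{\mathrm{sd}(n_t)}$$

(`ensemble_normalize()`), with the sample standard deviation. For the fast
`ddg_monomer` protocol we keep the `best_k = 3` lowest-`total_score`
decoys per side (mirroring standard ddg averaging practice) and emit one
normalized shift per term in a fixed 17-term manifest. For `FastRelax`,
whose value is broader conformational sampling, four statistics per term
capture location (mean shift), tail (minimum shift), rank (native
quantile of the variant mean) and dispersion overlap (fraction of variant
decoys inside the native range), over a 20-term manifest, plus three
whole-ensemble statistics on `total_score` (sd ratio, range ratio, median
shift) — 83 features. The exact term manifests are fixed in
`feature_manifest()` so that feature vectors are comparable across runs;
they cover the standard talaris-style score decomposition. The single
surface feature is the PROBE-reported accessible area at the variant
position, used verbatim.

**Degenerate inputs.** A native ensemble with zero spread cannot
normalize; the shift is then reported as a signed cap at ±10 (0 when the
means also agree). The cap keeps degenerate fixtures finite without
letting them dominate standardized fits. Missing structure is *masked*
(`NA`), never imputed: a variant without a mappable model is routed to the
sequence-only classifier, because imputing 101 zeros would silently claim
physical evidence that does not exist.

## Structure handling

Models are standardized before use: one chain retained (requested, else
alphabetically first — deterministic and appropriate for single-domain
curation), all HETATM records and non-standard residues dropped (MSE is
dropped, not translated to MET; translation would be a reasonable
extension but changes the residue bookkeeping). Reference-to-model
numbering is reconciled by ungapped sliding-window alignment of the model
residue sequence against the reference sequence, keeping the placement
with the most identities (ties to the smallest offset). An ungapped window
is sufficient because standardized single-domain models are contiguous;
indel-containing homology models would need a gapped aligner and are a
known limitation. A residue-type mismatch at a covered position is an
*error*, distinct from unmapped coverage: it indicates the wrong model or
isoform, which the user must resolve rather than silently accept.

## Training protocol

**Stability selection.** 100 protein-level subsamples at 80% of proteins,
a 25-point logarithmic lambda grid taken from a full-data `glmnet` path,
selection frequency per feature defined as the maximum over the grid of
the fraction of subsamples in which the feature has a strictly nonzero
(|β| > 1e−8) coefficient, threshold 0.6, truncation to the 20 most
frequent. Subsampling by protein, not by variant, matters: variants of one
protein share sequence and fold, and variant-level resampling would leak
that structure into the selection frequencies. The defaults follow
standard stability-selection practice and are exposed as arguments;
single-class subsample draws are skipped (they carry no information about
feature relevance).

**Final fit.** The selected features are standardized and fitted by
minimizing the mean logistic deviance plus a light ridge penalty
(λ = 1e−3 by default), implemented directly with BFGS and an analytic
gradient (`reltol` 1e−14, start at zero — the objective is strictly
convex, so the optimum is unique and the fit deterministic). The small
ridge stabilizes the collinear Rosetta terms that survive selection
without materially shrinking the solution. Class imbalance is *not*
reweighted; the training prevalence is part of what the intercept should
learn, and the default synthetic prevalence (0.606 deleterious) mirrors
the curated training corpus this emulates (5,740 of 9,477).

**Decision rule.** `deleterious` iff score > 0.5, strictly: a variant at
exactly 0.5 is labelled neutral.

## Evaluation choices

Splits are always by protein (100 × 80/20 by default) for the same
leakage reason as above. AUROC is trapezoidal with tied scores grouped,
which makes it exactly the Mann–Whitney concordance probability (a
property the tests verify against a brute-force pair count). AUPR
integrates the *step-wise precision envelope* rather than a linear
interpolation: linear interpolation in PR space is optimistic, and the
envelope makes AUPR comparisons self-consistent. Averaged curves are
vertical averages on a fixed 101-point sweep grid; the averaged areas are
defined as the mean of member areas (not the area of the averaged curve).

Score-bin enrichment (`enrichment_by_bins()`) uses equal-width bins on
[0, 1]; bins with zero denominator are flagged and excluded from the
correlations (an undefined ratio carries no rank information — zero
filling would manufacture one). Spearman p-values use the exact null
distribution for ≤12 bins (falling back to the asymptotic approximation
when ties are present), Pearson p-values the usual t reference.

## Synthetic data: what it emulates and what it does not

The generators exist so the full pipeline — parsers included — can be
exercised with no external data. `generate_labeled_dataset()` emulates the
*shape* of a curated variant training corpus: variants grouped in
proteins (default 200 proteins × 5 variants, a desk-scale analogue of the
9,477-variant corpus), a 0.606 deleterious fraction, i.i.d. Gaussian
noise on all 106 features, and a planted mean shift on a chosen subset in
deleterious records. `generate_score_ensembles()` draws per-term Gaussian
decoys with the variant side shifted in native-sd units, so planted
effects are expressed on exactly the scale `ensemble_normalize()`
recovers. Gaussian noise is the right model for the *normalized* feature
space, not for raw Rosetta energies.

What passing tests on this data show: the selection machinery recovers
planted signal among 106 features at realistic sample sizes; the
classifier generalizes across protein-level splits; structure-only signal
is invisible to the sequence-only model (combined AUPR strictly higher).
What they do not show: performance on real variants, where features are
correlated, effects are heterogeneous, label noise exists and structures
are imperfect. The synthetic results are software verification, not a
biological benchmark.

## Numerical and design notes

* All generators and the selection resamples are pure functions of their
  seed; identical seeds give byte-identical datasets, splits and outputs.
* Score and PSSM writers render numbers at full precision (`%.17g`) so
  write → parse round-trips are bit-exact; prediction TSVs print scores at
  3 decimals, which is the precision at which they should be consumed.
* The PSSM parser requires exactly 42 numeric fields per position row (20
  log-odds, 20 percentages, information content, relative weight); the
  score-file parser accepts both the `SCORE:`-prefixed and bare
  whitespace dialects.
* Isoform aggregation keeps the highest-scoring isoform prediction (any
  deleterious isoform call is treated as evidence for the gene), ties to
  the lexicographically first identifier.
* Interpretation reports a category when its summed positive-logit
  contribution exceeds 10% of the total absolute structure contribution;
  the 10% default is a readability threshold, configurable per call.
  Sequence-only predictions yield a conservation-only statement — with no
  structural features there is no physical evidence to cite.

## Known limitations

Single substitutions only; single-chain models without ligands, nucleic
acids or metals (their interactions are invisible to the features);
ungapped numbering reconciliation; the ddg/relax term manifests are fixed
package-wide and must match the score files' vocabulary; and the shipped
defaults for stability selection, the ridge penalty and the reporting
threshold are sensible but not tuned to any particular corpus.
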