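---
title: "Sequence-based local frustration: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based local frustration: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqfrust)
```

## The model and its assumptions

`seqfrust` estimates local energetic frustration from sequence
information alone. The folded-state energy of a sequence $\sigma$ is
modelled as a sum of pairwise contact terms, with each pair weighted by
an evolutionary coupling score:

$$\gamma(\sigma) = \sum_{i<j} C_{ij}\, e(\sigma_i, \sigma_j),$$

where $C$ is a symmetric coupling-score matrix with zero diagonal
(typically plmc / EVcouplings output) and $e(\cdot,\cdot)$ a 20×20
knowledge-based contact potential. The coupling score stands in for the
probability that positions $i$ and $j$ are in contact: pairs that
covary strongly across the family are treated as spatially interacting.
For a substitution $m$ at position $k$ only terms involving $k$ change,
giving the incremental energy difference

$$\Delta\gamma_m = \gamma(\sigma^{wt}) - \gamma(\sigma^{mut})
  = \sum_{j \ne k} C_{kj}\left[e(\sigma_k, \sigma_j) - e(m, \sigma_j)\right],$$

and the frustration scalar is the unweighted mean over the 19
alternatives, $\Gamma_k = \tfrac{1}{19}\sum_m \Delta\gamma_m$. The sign
convention is fixed package-wide and recorded in every profile object:
**positive $\Gamma$ = frustrated** (mutations on average lower the
predicted energy), so higher $\Gamma$ is expected to track higher
thermal mobility and is used as the predictor of high B-factor.

Assumptions worth keeping in mind: the energy is purely pairwise and
additive; the potential is distance- and environment-independent; the
coupling matrix is used in full, with no top-$L$ sparsification or sign
clamping (negative APC-corrected scores are retained, since the model
places no sign restriction on $C$); and all 19 substitutions are
weighted equally, with no background-frequency weighting. This score is
deliberately *not* a Z-score against a decoy distribution — it measures
whether mutations tend to raise or lower the energy, not how wide the
mutant-energy distribution is.

## Parameters that matter

* **Potential table** (`table`): default is the embedded
  Miyazawa–Jernigan 1996 contact energies $e_{ij}$ (RT-scale,
  dimensionless), the most widely used variant of that family. The
  provenance label travels with the object, and any symmetric 20×20
  table can be loaded from a whitespace file via
  `read_potential_table()` (symmetry validated to 1e-9), so the variant
  is a configuration choice, not a hard-coded assumption. Profile
  contours depend only weakly on the variant because $\Gamma$ is a
  within-position contrast.
* **Score column** (`score_column`): EVcouplings files carry both raw
  (`fn`) and APC-corrected (`cn`) scores. The default is the
  APC-corrected column — the standard EVcouplings ranking score — with
  `raw` available.
* **Coverage masking**: positions appearing in no scored pair (e.g.
  alignment columns dropped upstream by the 30%-gap filter) are masked
  as undefined, never reported as zero, because a zero would be
  indistinguishable from "perfectly neutral" and corrupt rank
  correlations. All downstream statistics drop masked positions
  pairwise.
* **Strictness** (`strict`): unknown residue symbols are an error by
  default. In lenient mode they are masked and their coupling rows are
  zeroed before the profile is computed, so no neighbour's $\Gamma$
  ever consumes an undefined contact energy — silent substitution would
  corrupt the profile invisibly.
* **Smoothing window** (`window`, odd, default 5 for plotting): a
  centered moving average over defined neighbours, shrinking at the
  edges. Statistics default to the *raw* signal (`window = 1`);
  smoothing is opt-in, since smoothed profiles are a presentation
  device and smoothing before correlation would be an analysis choice
  the user should make explicitly.
* **B-factor alignment offset** (`offset`): author residue numbering
  rarely starts at 1; `offset = "auto"` maximizes sequence identity
  over integer offsets in [−500, 500]. A residue-identity mismatch rate
  above 50% is treated as a wrong chain or offset and rejected.

## Benchmarking conventions

Correlations are Spearman by default (Pearson available), computed by
pairwise-complete deletion; the p-value uses the large-sample
t-approximation with $n-2$ degrees of freedom, with an exact
permutation option for $n \le 10$. Quartile ground truth labels
residues strictly above the 75th / below the 25th linear-interpolation
percentile of the B-factor distribution as high / low; the convention
is pinned by the test suite because any percentile convention is
defensible but mixing them is not. ROC/PR evaluation is restricted to
the high ∪ low set (mid excluded), which makes the precision chance
baseline equal to the positive prevalence in that set — 0.5 for clean
quartiles — and therefore makes "precision above 0.5" a meaningful
better-than-chance statement. For the low-B task the score is negated.
AUC is computed by the rank formula (identical to the trapezoid over
the full threshold sweep, ties by average ranks) and average precision
as precision-weighted recall increments. The one-sided Wilcoxon
signed-rank test against the baseline enumerates all sign patterns
exactly for ≤ 15 nonzero differences (ties in absolute differences
handled by average ranks within the enumeration) and switches to the
normal approximation with continuity correction above.

## The synthetic generator

The generator (`synthetic_spec()` / `generate_synthetic_protein()`)
produces everything the pipeline consumes with a planted ground truth.
Construction: long-range contact topology ($|i-j| \ge 2$) drawn at the
requested density — chain-adjacent pairs carry no couplings, mirroring
the coevolution-analysis practice of discounting trivial backbone
neighbours, which would otherwise swamp the planted signal; coupling
magnitudes from an exponential distribution (heavy-ish tail, all
positive, matching the shape of real ranking scores); residues assigned
by a deterministic two-pass greedy sweep that minimizes the local
coupling-weighted energy at background positions and maximizes it at
planted ones — cheap, deterministic, and sufficient because the
recovery property being tested is statistical, not exact; B-factors as
an affine function $b_k = 20 + 10\,\mathbb{1}[\text{planted}_k] +
2\,\Gamma_k + \mathcal{N}(0, \text{sd})$, chosen to sit on a realistic
Å² scale; and one Frustratometer-style record per coupled pair with
$\theta$ the native pair energy and $\phi$ the mean over the 38
single-end substitutions. Random streams are split per concern
(topology, magnitudes, residues, noise) so changing one parameter does
not reshuffle unrelated draws.

The reference study conditions — 100 residues, 5% contact density, 20%
planted frustrated positions, noise-free B-factors, 20 instances — are
the package's fixed validation cohort. What the generator emulates is
the *logical* structure of real data: consistent couplings, sequence,
contact table and B-factors with a common latent frustration signal.
What it does not emulate: real coupling matrices contain phylogenetic
noise and APC artefacts; real sequences are not local-energy optima of
an MJ model; real B-factors mix thermal motion with static disorder,
crystal packing and refinement conventions; and real Frustratometer
energies come from a transferable force field, not from the same
potential table used by the sequence score. Passing the recovery tests
therefore demonstrates internal correctness and end-to-end consistency
of the implementation — not field performance on crystallographic data.

```{r recovery}
sp <- synthetic_spec(n = 100, seed = 1)
prot <- generate_synthetic_protein(sp)
prof <- frustration_profile(prot$couplings, prot$sequence)
ok <- prof$defined_mask
labs <- ifelse(prot$planted_mask, "high", "low")
roc_pr(prof$per_residue[ok], labs[ok], "high")$auc_roc
```

## Numerical choices and degenerate inputs

The profile is computed as one 20×n×n matrix product rather than a
mutant-by-mutant loop; a dense 500-residue instance completes in well
under ten seconds, and the test suite holds the incremental path to the
brute-force all-mutant recomputation at 1e-9. Exact identities
(identity mutation ⇒ $\Delta\gamma = 0$; linearity of $\gamma$ and
$\Gamma$ in $C$) hold to 1e-12 relative. Degenerate inputs are
representable, not fatal: an all-zero coupling matrix yields a fully
masked profile; a contact table with no records yields an all-masked
compressed profile. Genuinely unanswerable requests error instead:
correlations need ≥ 3 jointly defined pairs, quartile labels ≥ 8
defined values and nonzero spread, normalization nonzero spread,
the signed-rank test ≥ 5 nonzero differences. Altloc handling keeps
the highest-occupancy conformer per atom name (first on ties);
hydrogens are included in residue means when present (with a reported
count); insertion-code residues are distinct during extraction but are
skipped with a warning during numbering-based alignment, since placing
them correctly would require a full sequence alignment.

## Design decisions that were genuinely open

* Which Miyazawa–Jernigan variant the upstream literature intends is
  ambiguous; the 1996 $e_{ij}$ table is embedded as the default and the
  choice is documented and swappable rather than asserted.
* Whether coupling matrices should be sparsified (top-$L$ pairs) before
  the Hadamard product: the full matrix is used; sparsification is left
  to the caller by pre-filtering the input file.
* Uncovered-position handling in correlations (drop vs zero-fill):
  dropped pairwise, for the masking rationale above.
* Duplicate contact records in Frustratometer files (direct and
  water-mediated variants of one pair) are kept and averaged into
  $\epsilon$; cross-chain contacts are excluded when a chain is
  selected, with a reported count.
* The quartile restriction for ROC/PR (evaluating only top ∪ bottom
  quartile residues) was chosen to make the 0.5 precision baseline
  coherent; evaluating against the full chain would silently change the
  baseline to 0.25.

## Known limitations

$\Gamma$ inherits every bias of its inputs: poor alignments produce
sparse, noisy couplings and heavily masked profiles; the contact
potential is sequence-separation-blind; and the score summarizes only
the *mean* mutational energy change, not the distribution width, which
likely carries additional information about how strongly a position
anchors the fold. The B-factor comparator is itself an imperfect proxy
for frustration, confounded by crystal contacts and refinement
protocol. The package computes per-protein statistics; cohort-level
hypothesis testing beyond the provided Wilcoxon and paired-difference
summaries (e.g. distribution comparisons across protein sets) is left
to the user on the exported JSON reports.
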