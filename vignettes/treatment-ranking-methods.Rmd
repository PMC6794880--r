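---
title: "Methods: G1 order-relation weighting and TOPSIS treatment ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G1 order-relation weighting and TOPSIS treatment ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painrank)
```

## The decision problem

Choosing an interventional therapy for chronic cancer pain is a
multi-criteria problem: the candidate procedures differ in evidence level,
complication risk, persistence of relief, cost, and in how well they fit a
patient group's general condition and disease stage. painrank implements a
two-stage analysis: criterion weights are elicited from an expert panel by
the G1 order-relation method, and alternatives are then ranked by TOPSIS
closeness to the ideal profile. The built-in case study applies this to four
procedures for upper abdominal malignancy pain (lumbar epidural catheter,
spinal port, celiac plexus block, splanchnic nerve radiofrequency
thermocoagulation), eleven sub-criteria under five main headings
(convenience, pain, risk, duration, cost), and a panel of three pain
physicians, one oncologic surgeon and one oncologist. (The abstract of the
original study report counts "four criteria and eight sub-criteria" and
"four experts"; its methods and tables consistently use five main criteria,
eleven sub-criteria and five experts, and the package follows the tables.)

## Stage 1: G1 order-relation weighting

Each expert provides a strict importance ordering of the $n$ leaf criteria,
$C_{(1)} \succ \cdots \succ C_{(n)}$, and for each adjacent pair an
importance ratio $r_j = w_{(j-1)}/w_{(j)} \ge 1$ drawn from a nine-point
verbal scale: 1.0 (equal), 1.2 (slightly more), 1.4 (more), 1.6 (strongly
more), 1.8 (extremely more important), with odd tenths as intermediate
grades. Setting the unnormalized weight of the last-ranked criterion to 1
and back-multiplying by the ratios gives, after normalization,

$$
w_{(n)} = \Big[\, 1 + \sum_{i=2}^{n} \prod_{k=i}^{n} r_k \Big]^{-1},
\qquad
w_{(j)} = w_{(n)} \prod_{k=j+1}^{n} r_k .
$$

`g1_weight_vector()` evaluates this closed form; the test suite checks it
against a literal step-by-step recursion on hundreds of random judgements.
The method assumes the ordering is strict (equal importance is expressed as
$r_j = 1.0$, not as a tie) and deliberately avoids the full
pairwise-comparison matrix and consistency-ratio machinery of classical AHP
— with only adjacent ratios elicited, inconsistency cannot arise.

The bounded grid is treated as an elicitation vocabulary, not a mathematical
constraint: `g1_weight_vector()` accepts any real ratio $\ge 1$ and warns
when a value is off the grid; `strict_grid = TRUE` upgrades this to an
error. Ratios below 1 are always an error because they contradict the
stated ordering.

**Panel aggregation** is the component-wise arithmetic mean of the
per-expert weight vectors (`aggregate_weight_vectors()`). The mean of
normalized vectors is normalized, it is the natural symmetric rule when no
expert is privileged, and it reproduces the case study's reference weight
table; geometric or weighted panel rules would be straightforward additions
but none is needed here.

## Stage 2: TOPSIS

Given an $m \times n$ decision matrix $f_{ij}$ of non-negative scores,
`run_topsis()` composes five steps, each available separately for audit:

1. **Normalization** — the default `vector_column` divides each column by
   its Euclidean norm over the alternatives,
   $r_{ij} = f_{ij} / \sqrt{\sum_i f_{ij}^2}$. This is the established
   vector normalization: it makes columns commensurable while preserving
   ratios within a criterion. A `vector_row` variant (rows divided by their
   norm over criteria) is kept purely for reproduction experiments with
   nonstandard conventions; mixing score scales across criteria within a
   row has no decision-theoretic justification and it is never a default.
2. **Weighting** — $v_{ij} = w_j r_{ij}$.
3. **Ideal pair** — per column, the positive ideal takes the maximum over
   alternatives for benefit criteria and the minimum for cost criteria; the
   negative ideal mirrors it.
4. **Separation** — Euclidean distances $D_i^\pm$ of each alternative's row
   to the two ideals.
5. **Closeness and rank** — $\bar C_i = D_i^- / (D_i^+ + D_i^-) \in [0,1]$,
   rank 1 to the largest.

Closeness is invariant to scaling the weight vector by any positive
constant, so "unweighted" analyses simply use uniform weights $1/n$.

### Criterion directions

In the case-study scoring scheme every sub-criterion scale is pre-oriented
so that level 3 is the favourable pole (e.g. complication risk: high = 1,
low = 3), so all eleven columns default to benefit direction. Directions are
nevertheless configurable per column, both because other datasets will not
be pre-oriented and to support investigating how the reference ranking might
have been produced (`reproduce_ranking(..., directions = ...)`).

### Numerical conventions

* Exact rank ties (closeness differing by at most 1e-12 absolute) share the
  better rank, competition style ("1224"), stably in input order.
* If an alternative is identical to both ideals ($D^+ + D^- = 0$, which
  happens iff all alternatives coincide on every criterion), its closeness
  is defined as 0.5 — the symmetric, bounded convention.
* All-zero columns (or rows, for the row variant) cannot be normalized and
  are an error naming the offending column.
* Weight vectors must be strictly positive and are checked to sum to 1
  within 1e-9 where normalization is promised.

## The case study and its reference values

`pain_case_study()` embeds the elicited panel (five orderings with ten
ratios each), the 4 × 11 score matrix of averaged expert scores on the
levels {1, 1.5, 2, 2.5, 3} (half levels arise from averaging integer
scores), and the reference outputs of the original study report.
`reproduce_weights()` recomputes the weights: ten of eleven agree with the
reference table at 3 decimals, while procedure duration (C41) computes to
0.0220 against a printed 0.021. The comparison table flags the 0.001
difference instead of forcing agreement.

The reference *closeness* values are a different matter: no standard
convention we tested — column or row vector normalization, all-benefit or
single-cost-column directions, uniform or panel-mean weights — re-derives
them (e.g. the default convention yields weighted closeness 0.495, 0.658,
0.372, 0.388 versus printed 0.205, 0.800, 0.498, 0.746). The package
therefore stores them as comparison metadata only: `reproduce_ranking()`
prints computed and reference values side by side, tags the output with the
exact convention used, and never treats the printed numbers as expected
output. The qualitative headline does agree under the default convention:
the spinal port ranks first in the weighted analysis. Which convention (or
computational slip) produced the printed values is unknown; the
direction-and-normalization options exist so a user can continue that
investigation without the package asserting any candidate as intended.

### Robustness analyses

`leave_one_expert_out()` recomputes panel weights and ranking with each
expert removed; in the case study the spinal port stays rank 1 in all five
reduced panels. `perturb_ratios()` moves every elicited ratio up or down by
at most `delta` grid steps (0.1 each, clamped to [1.0, 1.8]) uniformly at
random, `reps` times, and reports the frequency of each (alternative, rank)
pair; results are a pure function of the seed. Defaults (`delta = 1`,
`reps = 100`) probe one elicitation grade of imprecision, the natural unit
of the scale.

## Synthetic data

The generators emulate the *format* and constraints of the elicitation, not
clinical reality:

* `gen_latent_weights()` draws a ground-truth weight vector whose sorted
  adjacent ratios all stay within the elicitation bound (default 1.8). The
  sorted vector is built directly from uniform admissible ratios and then
  shuffled across criteria — a constructive sampler, chosen because naive
  rejection from a flat simplex prior essentially never satisfies all ten
  ratio bounds at $n = 11$.
* `judgement_from_weights()` inverts the G1 construction (ordering by
  descending weight, exact adjacent ratios), optionally snapping ratios to
  the nearest grid point. Unquantized round trips recover the latent vector
  to 1e-9, which is the core parameter-recovery property test; quantized
  round trips are verified empirically to stay within 0.05 per component at
  $n = 11$ (compounded rounding of ±0.05 per ratio).
* `gen_panel()` models panel consensus with a shared base ordering perturbed
  by at most two adjacent swaps per expert (experts typically agree at the
  top and diverge lower down), with an independent-permutation alternative
  controlled by a concordance probability; ratios are uniform on the grid
  (or exact reals in `"exact"` mode).
* `gen_score_matrix()` draws i.i.d. uniform scores over the discrete levels.

None of these model correlations between criteria (e.g. cancer stage and
pain extent) or systematic expert bias, so passing property tests shows the
algebra and conventions are right — not that the method is robust on
clinically realistic inputs. Problem sizes used in the shipped tests (panels
up to 11 criteria, matrices up to 5 × 6, a few hundred replicates) keep the
full suite in the tens of seconds while exercising every property at
multiple shapes.

## Known limitations

* Ties in expert orderings are unsupported by design; equal importance is
  expressed through $r_j = 1.0$.
* The arithmetic-mean aggregation gives every expert equal influence; there
  is no reliability weighting or outlier handling beyond
  `leave_one_expert_out()`.
* Scores entering the decision matrix are already expert-averaged; the
  package does not model the raw per-expert scores behind half-point
  levels.
* Fuzzy or hesitant-fuzzy extensions of either stage are out of scope.
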