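---
title: "papfam: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{papfam: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papfam)
```

`papfam` implements a gene-family discovery and annotation pipeline for
purple acid phosphatases (PAPs): profile-based proteome scanning,
conserved-motif verification, sequence and promoter annotation,
neighbor-joining subgroup classification, and qPCR/association
statistics, together with a synthetic-data module that generates every
input with ground truth. This vignette documents the models, the
numerical conventions and the places where a genuine design choice had
to be made.

## The profile model and its scoring convention

`build_profile()` constructs a simplified Plan7 profile from a seed
alignment. Columns whose gap fraction is at most `match_gap_threshold`
(default 0.5) become match states; an all-gap column can never be one.
Match emissions are Laplace-smoothed relative frequencies,
$e_j(a) = (c_{ja} + \lambda)/(n_j + 20\lambda)$ with pseudocount
$\lambda = 1$ by default, and transition probabilities among
match/insert/delete states are estimated from the observed state paths
of the seed sequences with the same pseudocount (Plan7 forbids
I$\leftrightarrow$D transitions; the rare insert-next-to-delete cases
are folded into the match-side counts). The background is the fixed
uniform distribution over the 20 residues — a deliberate simplification
that keeps toy scores hand-checkable and makes the bit scale easy to
reason about.

`score_sequence()` computes a local (Smith–Waterman-style) Viterbi score
in bits. Two conventions define the scale:

* **Transitions are charged relative to each column's M→M
  probability.** The straight-through, all-match path is therefore free,
  and an ungapped full-length match scores exactly the sum of per-column
  emission log-odds (plus the entry/exit charge below). Gap moves cost
  $\log_2 a_j(\cdot)/a_j(\mathrm{MM})$, which behaves like affine gap
  penalties derived from the profile itself.
* **Local entry and exit are uniform over match columns and are
  charged:** every path pays $2\log_2(1/L)$ bits once, $L$ the number of
  match columns. Without this charge the maximum score of a *random*
  sequence grows like $\log_2(Ln)/\lambda^\ast$ with the search space —
  around 15–20 bits for a 200-column profile — and no fixed threshold
  can separate family from background. With it, shuffled decoys score
  about 0–5 bits while genuine members score in the hundreds, so the
  default 10-bit threshold is a conservative, permissive gate ahead of
  the motif screen. Because the charge is constant per path it changes
  no alignment decisions, only the scale.

A forward score (log-sum over all local paths, same conventions) is
reported alongside and is mathematically never below the Viterbi score.
The Viterbi recursion is verified in the test suite against brute-force
enumeration of every state path on small profiles. Reported coverages
split the match columns at $\lceil L/2 \rceil$: `n_half_coverage` and
`c_half_coverage` are the fractions of the N- and C-terminal halves
aligned as match states, and they drive the domain-architecture call.

## Motif blocks and chaining

The default block definitions encode the family consensus
D-x-G / G-D-x-x-Y / G-N-H-[D/E] / V-x-x-H / G-H-x-H with exactly seven
ligand-flagged positions (the N carries the flag in block 3, following
the consensus emphasis). `x` matches any canonical residue, never a gap
or stop. The one tolerated substitution shipped by default is the
block-2 terminal Y→F, the variant documented in plant PAP families;
the substitution table is user-extensible per block position.

`scan_blocks()` finds all raw occurrences (including
single-substitution matches when allowed) and chains them by dynamic
programming: the maximum-cardinality set of non-overlapping hits whose
block indices increase left-to-right. Ties are broken toward the
lexicographically smallest block-index tuple, then the smallest start
tuple — so a lone block-5 word upstream of a lone block-1 word yields
the block-1 hit. No maximum spacer length is imposed between blocks;
the family's inter-block spacings vary widely and the chaining needs no
cap to stay unambiguous. The chaining is verified against brute-force
enumeration of ordered hit subsets.

Verdicts: `pap_complete` requires all five blocks; `pap_variant`
requires 3–4 blocks *and* a profile score at or above the scan
threshold (degraded-motif members are retained on profile homology, the
practice for real family deviants); everything else is `reject`.

## Annotation conventions

* **Molecular weight** uses average (not monoisotopic) residue masses
  plus one water, the Compute-pI/ExPASy convention.
* **pI** solves net charge = 0 by bisection to $|q| < 10^{-4}$ under the
  Bjellqvist pKa set (side chains C 9.0, D 4.05, E 4.45, H 5.98, K 10.0,
  R 12.0, Y 10.0; C-terminus 3.55; residue-specific N-terminal pKa).
  The charge function is strictly decreasing in pH, so the root is
  unique.
* **Glycosylation** is a plain N-X(≠P)-[S/T] sequon scan — an
  explicitly simplified stand-in for trained predictors; externally
  produced predictor calls can be joined on as annotation columns
  through `annotate_proteins(external = ...)`.
* **Promoters** are whatever upstream window the user supplies
  (conventionally 3 kb), coordinates 1-based from the supplied 5′ end;
  internal arithmetic is 0-based half-open, and BED export follows BED
  conventions. Both-strand scanning is on by default since these boxes
  are orientation-ambiguous. One subtlety: P1BS (`GNATATNC`) is its own
  IUPAC reverse complement, so a naive two-strand scan reports every
  site twice; self-reverse-complementary patterns are therefore
  reported once, on the plus strand. Ambiguous bases in the promoter
  never match.
* **Gene structure** is inferred by chaining the CDS into the genomic
  sequence as exact segments, using greedy longest-exact-extension with
  earliest placement. This is exact precisely when exon segments are
  unique within the genomic sequence and reasonably long (≳10 bp) —
  the regime in which a cDNA–genomic comparison can recover the
  structure at all, and the regime the synthetic generator guarantees.
  Where a boundary base is ambiguous (the intron begins with the same
  base that starts the next exon) the placement of that single base is
  inherently underdetermined; the generator disambiguates its
  boundaries so round trips are exact. A strict mode additionally
  requires canonical GT..AG introns.

## Phylogenetics

Distances are protein p-distances on pairwise-deleted columns, with the
Poisson correction $d = -\ln(1-p)$ as the default; a saturated pair
($p=1$) is an error rather than an arbitrary large value. Trees come
from Saitou–Nei neighbor joining (via `ape::nj`), which is exact on
additive matrices — the test suite verifies topology and branch-length
recovery on random additive matrices. Negative branch-length estimates
are clamped to zero with a warning, the common convention. Bootstrap
support is column resampling with NJ on each replicate and bipartition
counting against the full-data tree; an alignment with no variable
columns yields all-zero supports with a `"no variation"` warning.

Subgroup assignment views the unrooted tree midpoint-rooted (rooting is
used only for clade enumeration; output trees stay unrooted) and walks
from each query toward the root until the first clade containing a
reference leaf. If that clade's references agree on one subgroup the
query inherits it; if they mix subgroups the call is `"unclassified"`,
and when the mixed subgroups still share one major group (e.g. IIa and
IIb) the `group` column carries that group with `group_only = TRUE` —
a deliberate refusal to guess below the resolution the tree supports.

## Expression and association statistics

ΔΔCt pairs target and reference wells by replicate, averages
replicate-level ΔCt per condition, and reports
$\mathrm{fold} = 2^{-\Delta\Delta Ct}$ with a two-sided Welch t-test on
the replicate ΔCt values (Welch rather than pooled: replicate variances
need not match). The 2^−ΔCt variant serves genotype panels without a
control condition. Correlations are plain Pearson with guards against
constant vectors.

Association is an ordinary least-squares GLM per SNP with additive
0/1/2 coding and structure covariates (ancestry coefficients or PCs):
the SNP term's F-test gives p, the partial R²
$100\,(\mathrm{RSS}_{\text{reduced}} - \mathrm{RSS}_{\text{full}})/\mathrm{TSS}$
gives PVE, and Benjamini–Hochberg gives q. Kinship-based mixed models
are deliberately out of scope — this is the fixed-effects
simplification of structured association, and its acceptance is
parameter recovery on synthetic panels, not replication of any
published mixed-model p-values. Missing genotypes are mean-imputed per
SNP by default (`missing = "drop"` removes samples per test instead).
MAF filtering excludes missing calls from the denominator and retains a
SNP exactly at the threshold. One documentation note: association
literature sometimes prints significance thresholds as "P ≥ 10⁻⁶" when
P ≤ 10⁻⁶ is clearly meant; `papfam` uses ≤ throughout.

## The synthetic-data module

Every generator is a pure function of its parameters and a seed; the
master seed fans out through `child_seed()` (a fixed affine map modulo
2³¹−1 with one stream index per generator), so adding a generator never
perturbs another's output.

* **Proteomes** (`make_family_proteome`): one random family template
  (~290 residues) carries the five concrete block words at random
  spacings (15–35 residue spacers); members copy it with 10% per-site
  substitution outside the blocks, so the member set doubles as an
  ungapped seed alignment. These choices emulate a well-conserved
  single-domain family of realistic size (default 25 members, 50
  shuffled decoys). Deviants have listed blocks overwritten with random
  residues (re-drawn if a motif survives by chance), optionally carry
  Y→F, and optionally have one half's family signal randomized to
  emulate single-domain architectures. Scaffolds are scrubbed of
  *accidental* block matches so the truth table's `blocks_present` is
  exact for every seed. What this generator does **not** emulate:
  insertions/deletions within the family, multi-domain architectures,
  compositional bias, or homologs at the twilight zone — so passing
  tests show correct recovery of planted signal, not performance on
  remote real-proteome homology.
* **Promoters** (`make_promoters`): uniform background with concrete
  element words planted at non-overlapping positions and strands;
  by default the background is scrubbed of chance element matches
  (a 3 kb window has ~1.5 expected chance P1BS hits otherwise), making
  planted positions exactly recoverable; `scrub = FALSE` preserves the
  raw background for false-positive-rate checks. The default plants
  P1BS in 18 of 25 promoters, the composition of a phosphate-responsive
  family.
* **Alignments** (`evolve_msa`): root uniform, per-branch per-site
  substitution to a uniformly chosen different residue — a
  Jukes–Cantor-like process without indels.
* **Panels** (`make_geno_pheno`): three subpopulations (weights
  0.4/0.35/0.25, trait shifts ±0.6, allele-frequency spread ±0.15)
  emulate a structured association panel of default size 92. The causal
  effect β is solved in closed form so that the SNP's
  **within-structure** variance share equals the requested PVE: the
  between-subpopulation component of a structured SNP's variance is
  absorbed by the covariates, so the partial R² a structure-adjusted
  model estimates is the within-structure share — defining planted PVE
  any other way would make the generator's truth unrecoverable by the
  very model it is meant to test. At n = 2000 the mean estimated PVE is
  within 2 points of truth; at n = 92 the estimator's spread is large
  (a single-panel estimate can be off by ±10 points), which is reported
  rather than asserted.
* **Ct tables and gene models** follow the formulas of the estimators
  they feed, with Gaussian replicate noise (default SD 0.2 cycles,
  3 replicates) and exon/intron lengths of 20–60/30–120 bp with GT..AG
  boundaries.

## Problem sizes and determinism

The shipped test suite and the acceptance script use: a 25-member +
50-decoy proteome against a ~194-column profile; 200 enumeration cases
each for Viterbi and block chaining and 100 for subgroup assignment;
200 random additive matrices (5–10 taxa); a 500-column alignment with
1000 bootstrap replicates; 1000 null SNPs at n = 92 for type-I
calibration; and 200 panels at n = 2000 for PVE recovery. These sizes
give stable statistics while keeping a full run in the low minutes on
one core. All randomness flows from a single seed; reruns are
byte-identical.

## Known limitations

* The profile scorer is not HMMER and does not aim for bit-exact HMMER
  scores or calibrated E-values; scores are comparable only within one
  profile.
* The architecture call is a coverage heuristic standing in for a
  domain-boundary tool; a full-length sequence with a degraded half can
  still read `complete` if the aligner bridges it cheaply.
* Association is fixed-effects only; with kinship confounding beyond
  discrete structure, p-values will be anticonservative.
* Subgroup assignment presumes the reference labelling is itself
  consistent with the tree; conflicting references produce
  `unclassified`/group-only calls rather than majority votes.
* The trained external predictors whose outputs the annotation table
  can ingest (signal peptides, subcellular localization, glycosylation,
  peroxisomal targeting) are not reimplemented; only the sequon scan is
  built in.
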