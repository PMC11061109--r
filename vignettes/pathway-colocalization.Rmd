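---
title: "Methods: pathway profiling, genomic co-localization and expression status"
author: "facoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway profiling, genomic co-localization and expression status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facoloc)
```

# Scope

`facoloc` implements a comparative-genomics survey of a DNA-repair gene
pathway — shipped with a 40-component Fanconi Anemia (FA) registry spanning
the activation, core, monoubiquitination, ID, endonuclease, HR/repair and
deubiquitination subcomplexes — across arbitrary genomes. Four stages are
covered: (i) phyletic presence/copy-number profiling from precomputed
homology-hit tables, with Pfam domain confirmation and gene-fusion
detection; (ii) a per-genome co-localization test of pathway genes against
a random-placement null; (iii) TPM normalization and differential-expression
status classification; and (iv) seeded synthetic-data generators with
planted ground truth. Running BLAST, alignment, tree inference and the
differential-expression model fit itself are out of scope: the package
consumes their outputs.

# Homolog profiling

Hit tables are screened at an inclusive e-value cutoff (default `1e-5`, the
standard BLASTp screening threshold for this kind of survey). Each target
protein is then assigned to the pathway component of its maximum-bitscore
hit; ties break by lower e-value, then lexicographic component symbol, so
assignment is a deterministic function of the hit set and invariant to row
order.

Interactive sequence-space clustering (CLANS-style) is often used to
separate specific from non-specific hits, but it has no crisp decision rule
that can be reimplemented and tested. `facoloc` instead recovers that
function with a **domain gate** (`confirm_architecture()`): an assignment is
kept only if the protein carries at least one diagnostic Pfam accession of
its assigned component. The gate is optional (default on in the CLI) because
registries may be incomplete; components without any diagnostic accession
(FANCB, FANCG, REV3 in the bundled registry) are exempt. This is a
deliberate design substitution, stated here prominently.

Copy numbers count **distinct protein identifiers**; collapsing splice
isoforms to genes is the caller's responsibility (a protein-to-gene map can
be applied upstream).

**Fusion detection.** A protein is called a fusion when it carries
diagnostic domains of two or more distinct components whose intervals do
not overlap and whose midpoints are at least `min_separation` apart
(default 100 aa — the threshold is not biologically canonical; known real
fusions of this kind are atypically long multi-kilobase-scale proteins, so
100 aa is conservative). Components in a call are reported N-terminal
first. Accessions shared by several components (PF08423 across the RAD51
paralogs, PF02182 across UHRF1/2) cannot self-trigger because a domain
interval always overlaps itself.

# Genome geometry and the co-localization test

## Distance convention

Coordinates are 1-based inclusive (GFF3). The distance between two genes on
one contig is the number of bases strictly between them,
`max(0, downstream_start - upstream_end - 1)`; overlapping genes are at
distance 0 and strand is ignored (no strand rule is standard for this kind
of clustering analysis). "Intergenic gap" in `genome_stats()` uses the same
convention on consecutive sorted gene pairs; contigs holding one gene
contribute no gap terms, and an all-singleton genome gets gap 0 with a
warning. Mean spacing is mean gene length plus mean gap. These are
assumptions the package states rather than inherited definitions: the
alternative (start-to-start spacing) changes `m` by one gene length and is
absorbed by the permutation null either way.

## Statistic

Pairs of labeled genes on a shared contig are classified at a window `W`
(default 250 kb, the distance range of enhancer-promoter-scale
interactions; the threshold is **inclusive** at exactly `W`); farther
same-contig pairs are `long_range`. The per-genome test statistic is

> X = the number of pathway genes having at least one pathway neighbor
> within `W` on the same contig,

which matches the "fraction of pathway genes colocalized" framing used to
summarise such surveys. The colocalized distinct-component pair count is
reported as a secondary descriptive statistic. Pairs between two copies of
the same component are excluded from pair listings by default
(`include_paralog_pairs` restores them); the test statistic itself ignores
component identity, since the null permutes anonymous labels.

## Analytic approximation

With `N` genes at mean spacing `s`, a window of radius `W` holds
`m = floor(W / s)` gene slots per side, clamped to `[0, N - 1]`. A focal
labeled gene therefore has `d = min(2m, N - 1)` neighbor slots among the
other `N - 1` positions, and under uniform placement of the remaining
`K - 1` labels the chance that at least one lands in the neighborhood is
the hypergeometric zero-class complement

    p_focal = 1 - C(N - K, d) / C(N - 1, d),

computed via `lchoose()` so large `N` cannot overflow. The analytic p-value
treats the `K` labeled genes as independent, `X ~ Binomial(K, p_focal)`,
and reports `P(X >= x_obs)`.

Two known biases are documented rather than patched:

* **Contig ends.** The average-based construction ignores edge genes with
  truncated neighborhoods. At `N = 8`, `m = 1` the exact pair probability
  is 7/28 = 0.25 while the closed form gives 2/7 ≈ 0.286. The bias shrinks
  as `m/N` does.
* **Pairing.** A colocalization event flags two genes at once, so `X` is
  over-dispersed relative to a binomial: small upper tails at `x = 1` are
  roughly doubled and at `x = 2` undershot, with absolute error on the
  order of `C(K, 2) * 2m/N`. In the two-gene case the exact p-value is
  `p_focal` while the binomial gives `p_focal^2`. The approximation is
  therefore trustworthy in the sparse regime (expected colocalized pairs
  well below 1) and in the saturated regime (both tails near 1), and the
  test suite checks agreement with the permutation null on a
  constant-spacing genome (where `m` is exact) in that sparse regime, at
  `N = 10000` and `(K, m)` in {(2,25), (3,10), (4,10), (5,5)}.

## Permutation null (authoritative)

Because the analytic construction is an approximation on several axes, the
decision rule uses a label permutation null: the `K` labels are reassigned
uniformly without replacement over the real gene coordinates, preserving
contig structure and spacing heterogeneity, and
`p = (1 + #{X_b >= x_obs}) / (B + 1)` (so `p >= 1/(B+1)` and the test is
valid at any `B`). The permutation loop is compiled (Rcpp) and draws
through R's RNG, so a single integer seed makes every run bit-identical;
genes are processed in sorted coordinate order so the draw order is
well-defined. Significance defaults to `alpha = 0.01` on the permutation
p-value, per genome, with no cross-genome multiplicity correction (an
optional Benjamini-Hochberg column is available in `coloc_test_table()`).

## Validation design and problem sizes

The test suite validates the machinery at sizes chosen to be statistically
informative on one CPU:

* **Exactness:** an 8-gene contig where all `choose(8,2)` label placements
  are enumerated; the permutation p must sit within 3 Monte Carlo SE of the
  exact p, and the closed-form `p_focal` must equal brute-force enumeration
  of its own slot model exactly.
* **Type-I error:** 500 null genomes (N = 2000 over 5 contigs, K = 20,
  W = 250 kb, B = 2000); the rejection count at `alpha = 0.01` must fall in
  the exact binomial 99% acceptance region. The statistic is discrete, so
  the attained level is conservative; the acceptance region includes that
  outcome by construction.
* **Power:** 200 genomes with a planted 5-gene cluster spanning at most
  100 kb. The surrounding conditions (N = 10000 genes over 5 contigs,
  K = 6 labels) were fixed a priori by a power calculation: with default
  fungal geometry `m ≈ 90`, the null probability that 5 of 6 labels each
  find a neighbor is ~1e-4, so detection at p < 0.01 is structural rather
  than tuned, and ≥ 95% detection is required.
* Background labels in clustered mode are placed farther than `max_span`
  from every cluster gene (the exclusion radius; the generator defines the
  planted signal to be exactly the cluster).

# Expression classification

TPM is the usual length-normalized measure:
`rate = counts / lengths`, `TPM = rate / sum(rate) * 1e6`; each sample sums
to 10^6 and the measure is invariant to count rescaling. Classification
follows the standard screening rule at `padj <= alpha` (default 0.05):
positive log2 fold change is `up`, negative is `down`; `padj > alpha` is
`not_significant`; a missing `padj` (or absent gene) is `not_detected`.
A fold change of exactly 0 at significant `padj` is classified
`not_significant`, since the "down < 0 > up" criterion excludes zero from
both classes. In the profile grid, multiple gene copies of one component in
one condition collapse by the precedence up > down > not_significant >
not_detected — a display decision (one cell per component) — with the copy
count kept in a `multiplicity` matrix so no information is lost.

# Synthetic data: what it does and does not emulate

`simulate_genome()` lays genes sequentially: leading gap, then alternating
length/gap draws. Defaults — log-normal lengths with median 1.5 kb and
`sdlog = 0.6`, exponential gaps with mean 1 kb, 5 contigs × 400 genes —
approximate compact fungal genome geometry, putting `m` at `W = 250 kb` in
the order-100 regime of real fungal assemblies. All parameters are
overridable; a global seed fans out to fixed per-generator sub-seeds so
adding a generator does not perturb existing draws.

The generators give every stage exact planted truth: hit tables whose true
homologs (e-values `10^-U(10,100)`, dominant bitscores) and decoys
(e-values `10^-U(0,4.5)`, all above the 1e-5 cutoff) make the expected
post-filter assignment computable; DE tables whose margins guarantee exact
status recovery; label plants defining the co-localization null and
alternative.

What the simulations do **not** capture: sequence content (no FASTA),
transposon landscapes and repeat-driven clustering, gene-density gradients
along chromosomes, orthology ambiguity from real gene families, and
correlated expression noise. Passing tests therefore demonstrate
correctness of the statistical machinery and bookkeeping, not that real
genomes satisfy the null's assumptions — which is precisely why the
permutation test, not the analytic formula, carries the decisions on real
data.

# Degenerate inputs and numerical choices

* `K = 1` (or `m = 0`): `p_focal = 0`, analytic and permutation p-values 1.
* `x_obs = 0`: p-value 1 by definition.
* `d >= N - K`: the neighborhood exhausts the unlabeled positions,
  `p_focal = 1`.
* Empty gene sets error (`"no genes"`); malformed GFF3 records are skipped
  with a warning, never silently.
* `choose()` ratios are computed in log space; permutation p-values use the
  add-one estimator; all tie-breaks (assignment, sorting) are total orders.

# Known limitations

* The analytic p-value is a diagnostic, not a decision rule (see above).
* The domain gate depends on registry completeness; with sparse Pfam
  annotations it can drop genuine homologs (gate off by default in the R
  API, on in the CLI profile command where decoys are the bigger risk).
* Fusion detection sees only annotated domains: a fusion whose second
  moiety lacks a diagnostic accession is invisible.
* The co-localization test conditions on gene positions and permutes
  labels; it does not model assembly fragmentation beyond what the contig
  structure already encodes.

# A worked example

```{r example, eval = FALSE}
g <- simulate_genome(5, 2000, seed = 7)
pl <- plant_labels(g, K = 6, mode = "clustered", cluster_size = 5,
                   max_span = 1e5, seed = 7)
run_coloc_test(pl$genes, window = 250000, B = 2000, seed = 7)
```
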