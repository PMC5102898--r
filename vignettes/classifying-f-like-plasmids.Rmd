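---
title: "Classifying F-like plasmids from their conjugation regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying F-like plasmids from their conjugation regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conjugative plasmids of the IncF/MOB_F12 family are major vehicles of
antibiotic-resistance and virulence genes in enterobacteria. They share an
F-type mating apparatus (MPF_F), but natural isolates differ substantially
in how the transfer (*tra*) region is organised and regulated: the
classical plasmids carry the *traM/traJ/finOP* fertility-inhibition
circuit in one long polycistronic operon, while other lineages replace
these regulators with unrelated DNA-binding proteins (TraJ_V, EntFR,
SphTR) and, in one lineage, rearrange the region into two convergent
operons. `fplasmid` turns that comparative-genomics analysis into a
reusable, fully testable pipeline: relaxase-based family typing, gene
presence/absence profiling, co-occurrence statistics, operon-architecture
inference, regulatory-group assignment, and a relaxase phylogeny.

This vignette documents the model and procedure, the tunable parameters,
the numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Relaxase typing

The family marker is the relaxase, the oriT-nicking protein that initiates
transfer. Membership is a conjunction of two signals, both evaluated on the
N-terminal relaxase domain (`domain_len = 300` residues, the catalytic
domain; shorter proteins are used whole and flagged truncated):

* **Motifs** — both degenerate motifs `(D/E)NYY` and `D(L/F)TF` must occur
  somewhere in the domain (`scan_motifs()`; overlapping hits are all
  reported).
* **Identity** — the best full-domain global-alignment identity against a
  relaxase reference panel must reach `id_threshold = 0.40`. The threshold
  sits below the most distant well-attested family pair (about 49%
  identity) but above the unrelated-relaxase background, which reaches
  down to the mid-20% range.

Candidate proteins are first retrieved with a permissive local-alignment
prefilter (`prefilter_evalue = 1e-25`), mirroring the bait-retrieval step
of a database sweep; proteins under 50 aa are never considered, because
motif and identity statistics are meaningless at that length. A plasmid
may carry several relaxases; all calls are reported and the best (highest
identity, ties broken by protein id) drives classification.

## The alignment engine

All comparisons use the package's own affine-gap dynamic programming
(compiled): Needleman–Wunsch for full-length identity, Smith–Waterman for
database-style presence calls. Choices that matter:

* **Scoring** — BLOSUM62 with gap open −11 and gap extend −1; a gap of
  length *k* scores `gap_open + k·gap_extend`. Residues outside the matrix
  alphabet are scored through its `X` column. A matrix in NCBI text format
  can be substituted (`read_score_matrix()`).
* **Identity** — identical columns divided by *all* alignment columns, so
  gap columns count against identity. This is the stricter, deterministic
  reading of "percent identity between two domains" and makes
  identity-targeted simulation exactly measurable.
* **Determinism** — the traceback resolves ties in a fixed order
  (diagonal, then up, then left; gap runs close as early as possible), so
  results are identical across platforms.
* **E-values** — Karlin–Altschul, `E = K·m·n·exp(−λS)` with the published
  gapped-BLOSUM62 constants λ = 0.267, K = 0.041 and the pair of sequence
  lengths as the search space. The constants are a fixed design choice;
  the test suite validates the calibration with a shuffle-null experiment
  (the observed fraction of pairs with `E < e₀` must sit within a factor
  of 3 of the model's `1 − exp(−e₀)`) rather than by matching any external
  search tool bit-for-bit.

## Presence/absence profiling and co-occurrence

The profile panel holds 36 conjugation proteins of the two classical
prototypes (TraJ, TraA, TraL, … TraX, TraM, TraY, FinO), with the
relaxase represented by its N-terminal 300 residues, plus the three
group-marker regulators. A gene is present in a plasmid when the best
Smith–Waterman hit over the plasmid's proteome reaches
`e_threshold = 1e-3`; the identity and best-hit protein are stored as
provenance only, never used as a gate. Cells are independent: one protein
may satisfy two panel entries, and no reciprocal-best filtering is
applied, matching a one-way query-against-proteome search.

From the binary matrix the package derives per-gene conservation
(column means, reported as descending percentages) and the co-occurrence
statistic

\[ C(i,j) = N - \mathrm{Hamming}(\mathrm{col}_i, \mathrm{col}_j), \]

the number of plasmids in which genes *i* and *j* agree (both present or
both absent). `C(i,i) = N`, complementary profiles give 0, and
`C + Hamming = N` is an invariant of the implementation. Because the
integer statistic depends on the dataset size, the normalized form `C/N`
is also written for cross-dataset comparison; the two are labelled
distinctly. No significance model is attached: a null distribution for
gene co-occurrence is deliberately out of scope.

## Architecture inference

Detected genes are located on the genome through the profiler's best-hit
provenance and clustered along the sequence: a gap over `max_gap = 5000`
bp starts a new cluster. With fewer than `min_genes = 4` located genes the
call is `fragmentary`. One co-oriented cluster is a `single_operon`; two
clusters on opposite strands transcribed away from each other, with the
relaxosome genes (*traD*, *traI*) separated from the pilus core, are
`bipartite_divergent`; two clusters transcribed toward each other are
`split_convergent`; anything else is `unknown`. The two numeric constants
are package defaults (no operon-clustering criterion is standard in this
setting) and are configurable per run; 5 kb comfortably exceeds the
intergenic spacing seen inside real *tra* operons while staying well below
the distance between independent loci. Features are treated linearly;
a cluster wrapping around the circular origin would be split in two
(a known limitation, harmless for the conjugation region, which is
essentially never annotated across the origin).

## Group assignment

The regulator profile (traM, traJ, traY, finO, the MPF marker traC, and
the three markers) is read directly off the matrix row. Rules are applied
in the fixed order A → B → C → D → E; the first match wins and the full
rule trace is retained as evidence. *traY* is never consulted: the gene is
small (~75 codons) and so often mis-annotated that its presence call is
unreliable, though it stays in the panel for profiling. Markers missing
from the panel yield `NA` ("unknown"), not `FALSE`, so a reduced panel
cannot silently produce negative marker evidence.

Flags are orthogonal to the group label: `derepressed_finO_minus` (group A
without *finO* — the F plasmid itself is the canonical case),
`deletion_derivative` (only *traI/traX/finO* remain of the core panel and
*traC* is gone — the reduction seen in *Shigella*-type plasmids),
`incomplete_mpf` (any essential gene missing) and `truncated_relaxase`.
The essential set defaults to the 13 pilus genes established by
transposon-insertion genetics (traA, traL, traE, traK, traB, traV, traC,
traW, traU, trbC, traN, traF, traH) plus traG, traD and traI for transfer
completeness; because the canonical list is scattered across the classical
genetics literature, the set is configurable. Host taxon is carried into
every report but never used as a classification feature: host association
is an observation, not a rule.

## Relaxase phylogeny

Pairwise distances between typed relaxase domains are `d = 1 − identity`
(global alignment). No multiple-hit correction is applied by default — the
deliverable is monophyly of groups, not branch-length estimation — but a
Poisson correction (`d = −log(identity)`, capped at 1) is available. Trees
are built by standard neighbor joining; negative branch-length estimates,
which NJ can produce on non-additive input, are clamped to zero with a
logged note. Rooting places the root at the midpoint of the outgroup's
pendant edge (the synthetic datasets ship a MOB_F11-like outgroup
relaxase). A group is called monophyletic when some clade's leaf set
equals it exactly; with no support values on a distance tree this is a
stricter criterion than reading a condensed bootstrap tree. Maximum
likelihood, model selection and bootstrap resampling are out of scope.

## The synthetic-data generator

The generator exists so every stage can be tested against known truth
without downloads. What it emulates:

* **Per-group gene complements and layouts** (`group_archetypes()`):
  group A as a single plus-strand operon with all 36 genes; group B as a
  minus-strand relaxosome cluster (*finO, traX, traI, traD*) diverging
  from a plus-strand pilus cluster; groups C and D as single operons with
  TraJ_V / EntFR at the *traJ* locus and no *finO*; group E as a pilus
  operon converging on a relaxosome operon in which SphTR sits
  immediately upstream of *traD*. Intergenic spacers are 50–500 bp;
  clusters are separated by 6–9 kb, beyond `max_gap`.
* **Controlled divergence** (`evolve()`): substitution-only evolution to a
  target identity, realized identity measured with the package's own
  aligner and required to land within ±0.03 (resampling up to 20 times);
  motif positions are protected intervals that are never mutated. Indels
  are deliberately off by default because they interact with the
  gap-counting identity denominator.
* **Two-tier relaxase divergence** (`make_dataset()`): each group gets a
  relaxase ancestor evolved from the reference at
  `between_identity = 0.5`, and each plasmid's relaxase diverges from its
  group ancestor at a per-plasmid identity drawn from
  `identity_range = c(0.6, 0.9)`. This reproduces the family's observed
  structure — within-group identities high, between-group identities near
  the 40–50% floor — and makes each group a true clade by construction.
  The typing panel therefore contains the group ancestors (a plasmid is
  scored against its *closest* reference, as in a database search), while
  all other genes diverge directly from their panel entry at the drawn
  identity, which is then exactly the identity the profiler observes.
* **Ablations**: *finO* loss on a group-A plasmid (the derepressed, F-like
  exception), reduction to the *traI/traX/finO* deletion signature,
  relaxase truncation, and motif knockouts (`ablate_motifs()` replaces the
  first residue of every motif occurrence with glycine, which cannot take
  part in either motif, so no new hit can arise).
* **Determinism**: every emitted byte is a pure function of the master
  seed; sub-seeds are derived arithmetically, and the GenBank writer uses
  a fixed date field, so identical calls are byte-identical.

What it does **not** emulate, and hence what green tests do not show about
real data: annotation errors (mis-called starts, frameshifts, missing
translations beyond the synthetic ablations), composition bias of real
proteomes (synthetic sequences are i.i.d. draws from background amino-acid
frequencies, which makes the E-value null better behaved than in nature),
genuinely tree-structured evolution within groups (the two-tier scheme is
star-like inside each group), cargo genes outside the conjugation region,
and the borderline 35–45% identity zone where family membership is
threshold-sensitive — borderline calls on real data should be inspected,
not trusted.

## Numerical and design choices

* Internal coordinates are 0-based half-open; GenBank's 1-based inclusive
  convention is converted at the file boundary only
  (`genbank_start = start + 1`, `genbank_end = end`).
* Gene labels are matched case-insensitively after stripping
  non-alphanumerics and trailing copy numbers ("TraD", "traD", "traD_1"
  all map to the same key), since annotation practice is inconsistent.
* CDS features without a translation are skipped with a warning, not
  fatal, so fragmentary records still flow through the pipeline.
* Presence calls use the E-value only; at E ≤ 10⁻³ a rare chance hit on a
  truly absent gene is expected at roughly the per-mille level per
  protein pair. The group rules are tolerant of most such hits, but a
  spurious marker or regulator hit can in principle perturb a call on an
  individual plasmid; the per-cell provenance makes such cells auditable.
* Report percentages round to the nearest integer, ties away from zero
  (200 of 256 prints as 78%).
* Simulation sizes used by the test suite: the cross-module fixture is
  1 plasmid per group plus a decoy; the dataset-scale test uses 5 × 10
  plasmids (seed 7), at which the full pipeline runs in about a minute on
  one core and recovers 100% of groups, flags and group monophyly.

## Limitations

* Single-pass local alignment stands in for iterated profile search; very
  remote homologs that only a profile method would detect are scored
  absent.
* The E-value model is the ungapped-theory formula with gapped constants;
  it is validated to factor-3 calibration, not to database-search
  accuracy.
* Unassigned plasmids are a label, not a model: idiosyncratic regulators
  outside the five schemes are reported but not further interpreted.
* Whether a bipartite group-B plasmid is self-transmissible cannot be
  decided from gene content; the package reports completeness and leaves
  the biology open.
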