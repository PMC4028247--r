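---
title: "vesitra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vesitra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Vesicle transport — the COP-II, COP-I and clathrin-coated vesicle systems,
retromer/ESCRT complexes, Rab GTPases, tethering factors and SNAREs — is
one of the most conserved pieces of eukaryotic cell biology. Surveying how
completely this machinery is conserved across plant proteomes requires four
coupled analyses: (i) inferring orthologous groups from all-vs-all protein
similarity, (ii) checking that the inferred (co-)orthologues still look
like the curated reference ("bait") proteins at the level of domain
architecture, (iii) assigning a subcellular localization consensus to each
protein, and (iv) asking whether (co-)orthologues are expressed
tissue-specifically. `vesitra` implements this pipeline end-to-end and
ships a seeded simulator so that every stage can be validated against
planted ground truth.

## Orthology inference

Two complementary algorithms are run over the same similarity graph and
their results are combined.

**The similarity graph.** Hits (BLAST-style 12-column tabular, or produced
by the built-in toy Smith–Waterman aligner) are filtered at an e-value
cutoff (default `1e-5`), self-hits are dropped, and the two directions of a
pair are averaged into one undirected weight $w = -\log_{10}\max(E,
10^{-180})$. Averaging (rather than taking the max) keeps the graph
symmetric, which Markov clustering requires. Edge weights are then
normalized by the mean weight of their (species pair, inter/intra) stratum,
removing systematic scale differences between proteome pairs; a stratum
with one edge normalizes to 1.

**Markov clustering (MCL).** The column-stochastic flow matrix (self-loops
weighted by each node's maximum incident weight) is alternately squared
(expansion) and raised elementwise to the inflation power (default 1.5,
the common OrthoMCL choice), pruned below `1e-5` and re-normalized, until
the largest entry change falls below `1e-6` or 100 iterations elapse
(non-convergence returns the current clustering with a warning flag).
Clusters are connected components of the non-zero support of the attractor
matrix. The procedure is fully deterministic for a fixed node ordering; the
test-suite checks it against an independent, loop-based reimplementation on
random graphs of up to eight nodes.

**Seed-and-expand.** For every species pair, reciprocal best hits (mutual
highest-weight partners; ties broken by lexicographic protein id) seed a
pairwise group. Same-species proteins whose intra-species weight to a seed
is *at least* the seed weight are added as in-paralogs (boundary inclusive,
the InParanoid convention). Pairwise groups sharing members are merged
transitively (union-find).

**Combination.** For each bait protein of the curated core set, the
combined group is the *union* of everything either algorithm co-grouped
with it — union, not intersection, because the combination exists to
reduce false negatives. Baits that claim one another merge into a single
group. A non-bait protein claimed by two groups goes to the group whose
bait it matches with the higher direct similarity weight; an exact tie
keeps it in both with an ambiguity flag. Proteins no algorithm placed with
a bait remain unassigned.

## Domain-architecture classes

Within each combined group a major bait is selected by priority — yeast
factors, then experimentally proven Arabidopsis factors, then predicted
Arabidopsis factors, ties by lexicographic accession — and the remaining
core factors become minor baits. Every other member's ordered list of
domain accessions (from the domain-hit table; overlapping hits >50% of the
shorter span are resolved by keeping the lower e-value) is compared with
the major bait's:

* **Class I** — ordered accession lists identical, including repeat counts
  (strictest reading of "same domains, same order"; two empty
  architectures are vacuously identical);
* **Class III** — accession sets disjoint, including exactly one empty
  side;
* **Class II** — everything in between: at least one shared accession but
  non-identical lists, covering both gained and lost domains.

Repeats are kept by default; a `collapse_repeats` switch collapses
consecutive duplicates before comparison for users who prefer the laxer
reading. The class-I fraction is reported to one decimal and as a rounded
percentage.

## Localization consensus

Votes are compartments from an 11-compartment vocabulary. "Majority" is
implemented as *plurality* (mode): with 11 compartments and up to 20
voters, a strict >50% majority is often unattainable, and published
per-protein scores of the "11 of 19" form imply a plurality rule. Ties are
reported as multi-compartment calls (slash-joined, e.g.
`mitochondrion/plastid`) rather than broken arbitrarily.

* **High-certainty tier:** if any experimental (GFP, MS) or literature
  record exists, the consensus is the plurality over those records only —
  predictor output can never override experimental evidence. Otherwise
  the plurality over the 20-predictor tier decides. All experimental-kind
  records pool into one vote set; no precedence among GFP, MS and
  literature is imposed.
* **Low-certainty tier:** six automatable tools (two 11-compartment, two
  three-class targeting, two single-compartment specialists). Before
  voting, 11-compartment calls in {vacuole, ER, Golgi, plasma membrane}
  are relabeled `endomembranes` (only in this tier, only for those tools);
  specialist tools vote only when positive.

Cross-species summaries count, per factor, the plant species with at least
one group member whose consensus contains a compartment; factors with
support in 7 or more of the 14-species panel are flagged.

## Expression clustering

Tissues with more than `max_n = 4` samples are reduced to the `max_n`
samples nearest (Euclidean) to the per-tissue median profile. The
average-linkage dendrogram on correlation distance (1 − Pearson) is
computed and attached for audit because the original procedure names
hierarchical clustering, but how a tree yields exactly four samples is
unspecified; nearest-to-median is the documented, deterministic
operationalization of "representative samples showing a median profile".

Gene × tissue means over the selected samples feed Euclidean k-means.
Each fit takes the best of `restarts = 10` initializations drawn with
**k-means++ seeding** from the run seed; plain uniform-random seeding was
observed to strand centers inside single planted clusters at k = 10 and is
the scikit-learn-default remedy, so we adopt it. Fits are bit-reproducible
given (seed, restarts). The elbow scan records best-of-restarts inertia
("distance to the optimal solution", which is 0 when every gene has its
own cluster) for k = 1..50; each k is additionally warm-started from the
previous best centroids plus the worst-fit gene, which makes the curve
non-increasing *by construction* rather than by luck. The working cluster
count defaults to k = 10. Per-cluster tissue medians use the standard
median (even counts average the two middle values). Localization
distributions per cluster count multi-compartment calls fractionally
(1/number of tied compartments) so row sums conserve cluster sizes.

## The synthetic world

The generator's defaults are a fixed statement, not a tuning knob:

* **Proteomes:** 4 plant-like species plus one outgroup; 30 ancestral
  families of 120-aa random proteins evolving down a star tree;
  per-branch lineage-specific duplication with probability 0.2; per-site
  substitution probability 0.05 (about 10% divergence between two
  tips — far above the toy aligner's detection floor, far below random);
  ordered 1–3-domain architectures over a 10-accession alphabet with
  gain/loss probability 0.1 per branch; two short and two stop-codon
  decoys to exercise the QC filter (length < 10, stop fraction > 20%,
  strict boundary). A star phylogeny suffices because the pipeline never
  reconciles trees; substitutions are uniform and indel-free because the
  aligner, not the evolutionary model, is under test.
* **Localization:** uniform truth over 11 compartments; each of 20
  predictors reports the truth with its configured accuracy, else a
  uniform wrong compartment; optional experimental records.
* **Expression:** 10 planted clusters × 50 genes over 9 tissues × 6
  samples; cluster profiles i.i.d. N(0, 3²) per tissue, gene noise
  N(0, 0.5²) — expected between-profile separation far exceeds five noise
  standard deviations.

What a green test establishes — and what it does not: the synthetic world
has no alignment ambiguity (no indels, no repeats, no promiscuous
domains), no compositional bias, no correlated predictor errors and no
batch structure in expression. Perfect recovery here validates the
*implementation* of the algorithms, not their adequacy on real proteomes,
where parameter choices (inflation, cutoffs) matter far more.

## Numerical choices and degenerate inputs

* Similarity weights are capped at 180 (e-value floor `1e-180`); the toy
  aligner's pseudo-e-value is computed on the log2 scale to avoid
  underflow.
* All tie-breaks (RBH partners, bait selection, group ordering) are
  lexicographic on protein id/accession with radix ordering, making every
  stage locale-independent and deterministic.
* MCL on a node with no edges gets a unit self-loop and becomes a
  singleton; a fully pruned column is reset to its self-loop.
* `kmeans` restarts that propose duplicated centers are skipped; if every
  restart fails (fewer distinct profiles than clusters) the fit falls back
  to the distinct rows, which already attains zero inertia.
* Empty inputs return empty, correctly typed outputs (QC, readers,
  summaries); empty clusters yield NA median rows.

## Known limitations

* The toy aligner is a stand-in with an ad-hoc e-value model; real runs
  should consume external search output in the tabular format.
* The combination step assumes bait identifiers exist in the protein
  universe and fails loudly otherwise; it does not attempt fuzzy accession
  matching.
* Cross-species counting treats a factor's groups as interchangeable; it
  does not distinguish which group contributed a species.
* The expression module consumes already-normalized matrices;
  normalization, probe-to-gene mapping and differential expression are out
  of scope.
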