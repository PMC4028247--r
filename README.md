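# vesitra

Comparative orthology and annotation of vesicle-transport factors.

Eukaryotic vesicle transport is run by seven factor families — COP-II,
COP-I, clathrin-coated vesicles (CCV), retromer/ESCRT, Rab GTPases,
tethering factors and SNAREs. `vesitra` is for comparative genomicists who
want to survey how completely this machinery is conserved across a set of
proteomes, starting from a curated "core set" of bait factors and
all-vs-all protein similarity. It implements, as a tested and reusable R
package, the full analysis chain:

1. **Sequence QC** — drop sequences shorter than 10 residues or with a
   stop-codon (`*`) fraction strictly above 20%.
2. **Orthologous-group inference, twice** —
   *Markov clustering*: similarity graph with weights
   $w = -\log_{10}\max(E, 10^{-180})$, normalized per (species-pair,
   inter/intra) stratum, clustered by alternating expansion
   ($M \leftarrow M^2$) and inflation ($m_{ij} \leftarrow m_{ij}^{r}$,
   column-renormalized, default $r = 1.5$);
   *seed-and-expand*: reciprocal best hits between each species pair seed
   pairwise groups, same-species in-paralogs with
   $w(a', a) \ge w(a, b)$ are added, and overlapping pairwise groups merge
   transitively.
3. **Combination** — per bait factor, the union of both algorithms'
   co-grouped members (union to cut false negatives; weight-based conflict
   resolution, ties flagged).
4. **Domain-architecture classes** — each member vs its group's major bait
   (priority: yeast > Arabidopsis-experimental > Arabidopsis-predicted):
   class I = identical ordered domain lists, class III = disjoint domain
   sets, class II = partial overlap.
5. **Localization consensus** — plurality voting at a high-certainty tier
   (experimental evidence overrides 20 predictors) and a low-certainty
   six-tool tier with the vacuole/ER/Golgi/PM calls merged as
   "endomembranes"; cross-species "n of 14" summaries with a ≥7 flag.
6. **Tissue-expression clustering** — ≤4 representative samples per tissue
   (nearest to the median profile), gene × tissue means, Euclidean k-means
   (k-means++ restarts, default k = 10) with a 1..50 elbow scan,
   per-cluster tissue medians and per-cluster localization distributions.

A seeded synthetic-data module plants orthogroups, domain gain/loss,
localization truth with noisy predictors and expression clusters, so the
whole pipeline runs end-to-end against known ground truth with no external
tools.

## Worked example

```r
library(vesitra)

sim  <- simulate_proteomes(sim_config(1))        # 5 species, 30 families
qc   <- qc_filter(sim$records)
hits <- simulate_similarity(qc$kept)
g    <- normalize_weights(build_graph(hits, qc$kept[, c("id", "species")]))
grp  <- combine_orthogroups(mcl(g), paranoid_groups(g), sim$core, g)

truth <- sim$truth[!sim$truth$is_decoy, ]
m     <- merge(truth, grp, by = "protein_id")
adjusted_rand_index(m$family, m$group_id)
```

Output (seed 1):

```
proteins: 183   kept: 179   dropped: 4      # 2 short + 2 stop-laden decoys
combined groups: 30                          # one per planted family
ARI vs planted truth: 1                      # perfect recovery
```

Classifying every member against its group's major bait and summarizing:

```r
archs <- split(sim$domains$accession, sim$domains$protein_id)
cls   <- classify_groups(grp, archs, sim$core)
summarize_classes(cls$assignments, sim$core)$totals
#>   I  II III
#> 112  37   0
```

112 of 149 classified members keep the bait's exact ordered architecture
(class I, 75.2%); the 37 class-II members carry the simulated domain
gains/losses; no member lost all shared domains (class III). On the
bundled survey counts, the same machinery reproduces the published
headline numbers: a 240-factor core set (= 8+16+18+20+68+45+65 and
= 212+45−17), a 78.9% ≈ 79% class-I fraction (416/527), a 776
(co-)orthologue three-species total (129+340+307), and exactly 8
yeast-only tethering factors from the tethering count table.

There is also a CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","vesitra.R",package="vesitra"))')" \
  run-all --seed 1 --out out_dir
```

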