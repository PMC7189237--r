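# photognn

Genome-neighborhood conservation features for photosynthetic protein
classification in prokaryotes.

## What problem this solves

Sequence similarity alone identifies photosynthetic proteins poorly: most
close homologs of photosynthetic proteins occur in non-photosynthetic
organisms.  In prokaryotes, however, functionally coupled genes stay
physical neighbors (operons, conserved gene clusters), and *how widely* an
adjacency is conserved across a phylogeny is informative about function.
`photognn` implements that idea end to end for people working on microbial
genome annotation:

1. **Neighborhoods** — genes on the same strand within ≤ 250 bp (or
   overlapping) chain into clusters; divergently transcribed adjacent
   clusters whose first genes lie 200–1000 bp apart are merged.
2. **Families** — a sequence-similarity network per E-value cutoff (1e-10,
   1e-50, 1e-100) is partitioned by Markov clustering (MCL).
3. **Phylo score** — for genomes *i, j*, shared gene content
   *s = |RBH| / mean proteome size* gives a distance *d = −ln(s)*; each
   (query family, neighbor family) adjacency observed in ≥ 3 genomes is
   scored by the total branch length of the neighbor-joining tree over
   exactly those genomes.  Wider conservation across more distant genomes
   ⇒ larger score.
4. **Profile** — queries × (threshold, neighbor family) scores, discretized
   to levels 0–3 at the positive-class quartiles (shipped defaults
   0.41079 / 2.61799), deduplicated, exported to ARFF/CSV.
5. **Classifier** — `photomod()` (random forest by default; SVM and naive
   Bayes variants) with gain-ratio feature selection, PCA, SMOTE/reweighting
   and nested 10×2 cross-validation; novel sequences are predicted by
   majority vote over their similarity matches (E-value ≤ 1), with
   `NOT_ASSIGNABLE` for queries that do not map into the collection.

A synthetic-collection generator (`generate_collection()`) plants conserved
neighborhoods with known ground truth so the entire pipeline is testable
without downloads, and `regenerate_fig1_toy()` builds a four-genome
demonstration of how stringency changes the profile.

## Worked example

```r
library(photognn)

gen <- generate_collection(synth_config(seed = 1))   # 10 genomes, 200 families
res <- run_pipeline(gen, "run1", cv = FALSE)
res$profile
#> Genome neighborhood profile: 500 queries x 186 features ( 200 T / 300 F )

cv <- nested_cv(res$profile, classifier = "rf", seed = 3)
cv
#> Nested 10x2 CV (rf):
#>   accuracy  1.000 +/- 0.000
#>   precision 1.000 +/- 0.000
#>   recall    1.000 +/- 0.000
#>   f1_minor  1.000 +/- 0.000
#>   mcc       1.000 +/- 0.000
```

The synthetic condition plants strongly conserved neighborhoods (90% of
genomes carry each positive cluster intact), so the forest recovers the
signal perfectly; permuting the labels drops the mean MCC to ≈ 0
(−0.10 in the same session), confirming the signal comes from the planted
conservation and not from the pipeline.  On the published 154-genome real
collection this feature space yields a cross-validated MCC of about 0.72 —
real data is much harder than the planted ceiling.

Classifying a confusion matrix by hand:

```r
compute_metrics(confusion_matrix(tp = 6, tn = 89, fp = 22, fn = 6))
#>  accuracy precision    recall  f1_minor       mcc
#> 0.7723577 0.2142857 0.5000000 0.3000000 0.2135665
```

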