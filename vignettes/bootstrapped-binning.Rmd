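---
title: "Bootstrapped supervised binning: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrapped supervised binning: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bootbin)
```

## The problem

Metagenomic sequencing yields a mixture of fragments (assembled contigs, or
raw long reads) from many organisms at once. *Binning* groups these
fragments into sets that each represent one organism or a population of
closely related organisms. `bootbin` implements a reference-independent
approach: no database of previously characterized genomes is consulted.
Instead, the only signal is the *genomic signature* — the vector of
oligonucleotide frequencies of each fragment, which is characteristic of
its source genome.

## The procedure

The method is a hybrid of unsupervised and supervised learning that
"bootstraps" its own training data from the input:

1. **Size selection.** Sequences are partitioned by length into *cluster
   points* (length ≥ `t_c`), *border points* (`t_b` ≤ length < `t_c`),
   *remaining points* (`min_len` ≤ length < `t_b`) and discarded sequences
   (< `min_len`, default 500 bp). Longer sequences have more stable
   signatures, so only they are trusted to define structure de novo.
2. **Signatures.** Each retained sequence is represented by its canonical
   pentamer frequency vector (512 features for k = 5): every sliding window
   consisting solely of A/C/G/T is counted under reverse-complement
   canonicalization, and counts are normalized by the number of counted
   windows. Canonicalization makes the signature strand-agnostic, which is
   required because contig orientation is arbitrary. A centered log-ratio
   (CLR) transform is then applied by default (see *Numerical choices*).
3. **Compression (optional).** To cut the cost of the embedding and
   clustering steps, points can be compressed by a factor `c`: unassigned
   points are drawn uniformly at random as *representatives*, each
   absorbing its `c` nearest unassigned neighbours in feature space as
   *associates*. `c = 1` roughly halves the point count.
4. **2D embedding.** The (possibly compressed) border + cluster points are
   embedded in 2D with Barnes–Hut t-SNE after a PCA pre-reduction to ≤ 50
   dimensions.
5. **Clustering.** DBSCAN is run on the 2D coordinates of the *cluster
   points only*. Border points shape the embedding — they pad the space
   between genome clouds and push clusters apart — but never receive de
   novo labels. Points not density-reachable from any core point are
   *noise*.
6. **Decompression and training.** Associates inherit their
   representative's cluster label, enlarging the training set beyond the
   sampled representatives. All non-noise cluster points plus their
   associates, with signature features and cluster labels, train a
   random-forest classifier.
7. **Final bins.** The classifier predicts a label for *every* sequence of
   length ≥ `min_len` — including border points, remaining points, and
   noise points. A *cluster* is thus an intermediate sequence set; a *bin*
   is the final one, and a bin tries to maximize recovery of its
   population's genome.

### Chunking

When one genome is spread over many more contigs than another (uneven
assembly fragmentation or abundance), cluster-point density in the
embedding reflects contig counts rather than genome sizes, which distorts
density-based clustering. `chunk_length = 3000` splits every sequence into
consecutive 3 kbp windows (a final tail shorter than `min_len` is merged
into the preceding window, so long contigs never shed discarded
fragments). The pipeline then operates entirely on chunks, and each parent
sequence receives the bin holding the largest total chunk length (ties go
to the smaller bin label). Majority vote by bp is our aggregation choice;
the per-parent agreement fraction is reported so unstable parents can be
inspected.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 5 | oligonucleotide length; 512 canonical features |
| `t_b`, `t_c` | 1000, 1000 bp | role thresholds; set both to 500 bp for short-read-free, narrow length distributions such as raw long reads |
| `min_len` | 500 bp | shortest sequence that receives a bin |
| `chunk_length` | 0 (off) | 3000 bp is the standard setting when enabled |
| `compression` | 0 (off) | 1 ("1NN") halves the embedded/clustered point set |
| `perplexity` | 30 | t-SNE neighbourhood scale, clamped to (n−1)/3 |
| `min_pts` | 20 | DBSCAN core-point threshold; decrease to find small clusters — necessary after heavy compression, otherwise clusters are missed |
| `eps` | `"auto"` | DBSCAN radius; estimated as the 95th percentile of (min_pts−1)-NN distances |
| `n_trees` | 500 | random-forest size |

A single master seed derives the stage seeds (compression, embedding,
forest) by fixed offsets, so every stage is independently reproducible and
two runs with the same configuration are byte-identical in all outputs.

## Numerical choices

* **CLR transform.** K-mer frequencies are compositional; Euclidean
  distance on raw frequencies is dominated by the most abundant k-mers.
  The CLR (log frequency minus the row mean of log frequencies) moves the
  data to log-ratio geometry. A pseudo-frequency of 1/(2W) per component
  (W = valid window count, floored at 1e-6) avoids log(0); it shrinks with
  sequence length, so long sequences are essentially unperturbed.
  `transform = "none"` is kept as an escape hatch for comparability
  experiments.
* **Ambiguity codes.** Windows containing N or any IUPAC ambiguity code
  are skipped deterministically, never randomized. A sequence with zero
  valid windows keeps a zero signature and is flagged.
* **eps estimation.** DBSCAN's radius is the classic k-distance heuristic:
  the 95th percentile of each point's distance to its (min_pts−1)-th
  nearest neighbour. Degenerate all-identical coordinates fall back to a
  machine-epsilon-scaled radius with a warning.
* **Tie-breaks.** Compression resolves equidistant neighbours by lower row
  index; cluster numbering follows discovery order from the lowest
  unassigned core point; chunk-vote ties go to the smaller bin label. All
  choices are deterministic.
* **Noise handling.** Noise points are excluded from classifier training
  (their labels are unreliable by construction) but still receive a bin at
  prediction time, so bins always partition the retained sequences.
* **Classifier features.** The forest is trained on transformed
  signatures, not on 2D coordinates: remaining points are never embedded,
  and signature space is the only representation shared by all sequences.
  Re-predicting the training sequences is deliberate — a cluster point may
  legitimately end up in a different bin than its de novo cluster.

## The synthetic-community generator

Real ground-truth benchmarks for binning require large external datasets
and third-party tools, so the package ships a simulator that preserves the
*mechanism* the method exploits: distinct per-genome composition.

* Genomes are sampled from order-2 Markov chains whose per-context
  transition rows are drawn from a symmetric Dirichlet (concentration 1 by
  default). Order 2 creates realistic pentamer structure at negligible
  cost; lower concentrations give more extreme, hence more mutually
  distinct, signatures.
* Fragments get uniformly random start positions and truncated log-normal
  lengths. The `"contigs"` preset (meanlog = log 8000, sdlog = 0.8,
  truncated to [500, 50000] bp, error-free) loosely emulates a short-read
  assembly; the `"nanopore"` preset (meanlog = log 6000, sdlog = 1.0,
  per-base error 0.1) emulates raw long reads, with errors split 1/2
  substitutions, 1/4 insertions, 1/4 deletions.
* The standard study condition used throughout the tests is 5 genomes of
  100 kbp and 150 fragments per genome (~750 sequences), which keeps every
  pipeline test and the acceptance script well under a minute per run.

What the simulator does **not** emulate: shared or horizontally
transferred regions between genomes, within-genome compositional
heterogeneity beyond the Markov model, strain mixtures, coverage/abundance
signal (unused by this method), and realistic error profiles
(homopolymer-biased indels). Passing the synthetic tests therefore
demonstrates the machinery is correct and the method recovers
compositionally distinct populations; it does not predict performance on
real communities with closely related strains, where signatures overlap
and manual inspection of the 2D report becomes important.

## Evaluation semantics

Given ground truth, each genome's *best bin* holds its largest bp-weighted
share. Sensitivity is that share over the genome's binned total; precision
is the best bin's majority-genome purity; F1 is their harmonic mean; means
and medians aggregate over genomes. Sequences the binner never claimed are
excluded from the denominators unless `strict = TRUE`. bp-weighting is the
default because recovering 90% of a genome in one bin matters regardless
of how many fragments carried it; `weight = "count"` suits chunk-level
scoring.

## Known limitations

* Compositional signatures cannot separate genomes with near-identical
  oligonucleotide usage (e.g. very closely related species); such groups
  merge into one bin, which the convex-hull report makes visible.
* DBSCAN on a t-SNE plane inherits t-SNE's tendency to split very dense
  duplicate-rich point sets into islands; with heavy chunking of
  high-coverage data, keep `min_pts` at or above its default (chunking
  multiplies the points per genome, so small-cluster sensitivity is not
  needed).
* The distance matrix in DBSCAN is materialized (O(n²) memory); with
  compression available this is a non-issue at the scales the tool
  targets (tens of thousands of embedded points).
* Quality estimation (completeness/contamination), taxonomic annotation
  and gene-level annotation are outside the package's scope; the
  annotation-overlay hook accepts any per-sequence TSV produced by
  external tools.
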