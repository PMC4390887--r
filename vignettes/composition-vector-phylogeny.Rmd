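---
title: "Composition-vector phylogeny: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-vector phylogeny: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvtreer)
```

## The method

cvtreer builds whole-genome phylogenies without sequence alignment.  The
input for one genome is its proteome — every protein product it encodes —
and the genome's signature is the spectrum of overlapping K-peptides
(length-K windows of consecutive residues, counted within each protein
independently).  Alignment-free comparison is the only practical option at
this scale: prokaryotic genomes differ so much in size and gene content that
no common set of orthologous segments exists, and whole-proteome input also
absorbs lateral gene transfer and lineage-dependent gene loss as ordinary
genome evolution rather than treating them as noise.

Raw K-peptide frequencies are dominated by short-range compositional
structure that mutates approximately neutrally.  To suppress that
background, each observed frequency $f_K(s)$ for $s = \alpha_1\ldots\alpha_K$
is compared with the prediction of a $(K-2)$-th order Markov model built
from the shorter spectra of the same proteome:

$$f^0(s) = \frac{f_{K-1}(\alpha_1\ldots\alpha_{K-1})\,
                 f_{K-1}(\alpha_2\ldots\alpha_K)}
                {f_{K-2}(\alpha_2\ldots\alpha_{K-1})},
\qquad
a(s) = \frac{f_K(s) - f^0(s)}{f^0(s)} \quad (a(s) = 0 \text{ if } f^0(s)=0).$$

The sparse vector of the $a(s)$ is the genome's composition vector.  Two
genomes are compared by the cosine of their composition vectors,

$$C(A,B) = \frac{\sum_s a_A(s)\, a_B(s)}{\lVert a_A\rVert\,\lVert a_B\rVert},
\qquad D(A,B) = \frac{1 - C(A,B)}{2} \in [0,1],$$

and the dissimilarity matrix is turned into an unrooted tree by
neighbor-joining.  Branching order is the scientifically meaningful output;
branch lengths are reported but not calibrated to time, because a constant
substitution rate cannot be assumed across a tree spanning many phyla.

### Assumptions worth stating

* Counting pools all proteins of a genome into one bag; the vector is
  invariant to protein order and to duplicating the whole proteome
  (frequencies are ratios).  Both invariances are property-tested.
* Windows containing any character outside the 20 standard amino acids are
  discarded from counts *and* totals at every length independently, so every
  $f$ stays a proper frequency.
* For an observed peptide the background $f^0(s)$ is always positive (its
  prefix, suffix and core were observed too), so $a(s)$ is well defined; the
  implementation asserts this rather than assuming it.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 6 | peptide length; supported 3–9.  K = 5, 6 give the most taxonomically consistent trees: shorter peptides carry too little signal and longer ones are too sparse to share between genomes.  K behaves as a resolution setting, not a fitted parameter — the pipeline is otherwise parameter-free (FASTA in, tree out). |
| `extended` | `FALSE` | store unobserved-but-predicted peptides as $a(s) = -1$ components.  The cosine is dominated by shared observed peptides, so the default stores observed peptides only; the flag exists for sensitivity analysis.  Both storages give identical dot products over the stored-key intersection, which the tests verify against a dense union-key oracle. |
| `bootstrap` (B) | 0 | replicates for proteome-level bootstrap: with no alignment there are no columns to resample, so the sampling pool is the genome's protein list, resampled with replacement to its original size, independently per genome and replicate, each sub-seeded from `(seed, replicate, genome)` so runs are reproducible and parallelizable. |

## Numerical choices

* **Neighbor-joining** uses the Saitou–Nei criterion with the
  Studier–Keppler $O(N^3)$ update.  Ties in the Q-matrix are broken by the
  smallest (row, column) index pair of the current matrix, making the tree a
  deterministic function of the input.  On additive matrices the algorithm
  is exact; the tests verify topology (Robinson–Foulds 0) and path lengths
  (within $10^{-9}$) on 500 random tree metrics of 4–12 leaves.
* **Negative branch estimates**, which arise on non-additive data, are
  clamped to zero in the output tree; the raw estimates stay in
  `attr(tree, "raw.edge.length")` and the clamped total is logged.  Display
  convention only — downstream topology queries never use lengths.
* **Dissimilarities** are accumulated in double precision with no applied
  tolerance; the final value is clipped to $[-1, 1]$ / $[0, 1]$ only to
  absorb last-bit floating error in the cosine of identical vectors.
* **Degenerate inputs** (a proteome with no valid K-window, a zero-norm
  vector) raise classed errors naming the genome, and bootstrap replicates
  that hit them are redrawn and counted.

## Monophyly, collapsing and the taxonomy layer

Monophyly is evaluated on the *unrooted* tree: a taxon is monophyletic when
some edge bipartitions the leaves into exactly the taxon's members versus
the rest.  This needs no outgroup information; when a rooted reading is
wanted, `is_monophyletic(..., rooted = TRUE)` requires the members to form a
clade of the stored rooting, and `root_by_outgroup()` makes that rooting
explicit.  Only genomes with *complete* lineages (no `Unclassified` rank
from domain to species) define taxon membership; incomplete genomes can
never break a taxon's monophyly but are surfaced through the `{m+n}`
bookkeeping, which is exactly what makes incomplete public-database lineages
easy to spot in a collapsed tree.

Collapsing replaces every maximal branch whose classified leaves share one
taxon at the chosen rank by a labelled leaf: `<C>Name{m}` for a clean
branch, `<C>Name{m+n}` when n incomplete genomes ride inside it, and
`<C>Name{k/m}` for each piece of a taxon split over several branches.  A
branch containing only incomplete genomes is labelled at the deepest rank
all its members share (e.g. `<P>Phylum{0+3}`).  Leaf accounting
($\sum$ parts $+ \sum n = N$) is checked on every fixture, including
degraded and deliberately paraphyletic ones.  When several split parts of
one taxon would render identically (e.g. two `<C>X{1/2}` leaves), tree tip
labels are disambiguated with a `#` suffix so Newick output stays valid.

The convergence report renders one line per taxon and rank D–G with one
slot per K — `K5` when monophyletic in the K = 5 tree, `-` when not — over
a configurable K range defaulting to 3–7.  The ASCII hyphen is used for the
empty slot.  Lineage-modification rules (`"old_fragment new_fragment"`)
rewrite exactly the ranks they name for every genome matching the old
fragment, must match at least one genome, and are invertible; the
involution is tested.

## The synthetic proteome evolver

`simulate_proteomes()` evolves a root proteome of i.i.d. uniform sequences
along a known tree: per site, substitution probability
$1 - e^{-\text{rate} \cdot \ell}$ on a branch of length $\ell$, to a
uniformly chosen different residue; optional whole-protein loss and
duplication per branch (defaults 0, available because robustness to gene
content variation is part of the method's claims).  The model is
intentionally simple — uniform substitution, no rate matrix, no indels, no
domain shuffling, no simulated LGT — so that its statistics are analyzable
and the expected behaviour of every pipeline stage is predictable.  Passing
the end-to-end tests therefore demonstrates correctness of the machinery
and internal consistency of the method under a known generating process; it
does not by itself certify performance on real proteomes, whose composition
is far from i.i.d.

### The frozen validation regime

End-to-end validation uses `validation_tree()` / `validation_params()`:
12-leaf random topologies whose branch lengths are drawn U(0.5, 1.5) and
rescaled so the maximum tip-to-tip path is 0.2 expected substitutions per
site, with 150 proteins per genome of mean length 250 (sd 40).  The depth
cap is the load-bearing choice: cosine dissimilarity saturates near 0.5
once two genomes share essentially no K-peptide, destroying additivity for
deep pairs, and 0.2 keeps every pair on the informative part of the curve
at K = 5 and 6 while leaving internal edges (a few times $10^{-2}$) long
enough to resolve at this proteome size.  These sizes were calibrated once
with a small pilot sweep and then frozen; under them the pipeline recovers
the true 12-leaf topology in ≥95% of 100 seeded replicates at both K = 5
and K = 6, and on a well-separated 8-taxon fixture (equal relative branch
lengths, same depth) every true bipartition reaches bootstrap support
≥ 0.9 at B = 100.  `scripts/acceptance.R` recomputes all of these numbers
from scratch.

Problem sizes throughout the test-suite (proteomes of tens to a couple of
hundred proteins, trees of 4–15 leaves, 100-replicate studies) are the
package's chosen desk-scale validation sizes; the method itself has no
intrinsic size limit beyond memory for the sparse vectors.

## Known limitations

* Real proteome-scale runs (thousands of genomes, K up to 9) want the
  parallelized implementations this package's pure-R pipeline does not try
  to replace; the focus here is a fully tested, deterministic reference.
* The dissimilarity is not an evolutionary distance; no correction maps it
  to substitutions per site, which is why branch lengths are de-emphasized.
* Taxon identity is plain `(rank, name)` string equality — no nomenclature
  validation or synonym handling.
* The jackknife variant of resampling (subsampling proteins without
  replacement) can be emulated but ships without separate statistics.
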