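---
title: "Learning interpretable protein-DNA energy models from complex structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning interpretable protein-DNA energy models from complex structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ideaEnergy)
```

## The model

Sequence-specific DNA recognition by transcription factors and other
DNA-binding proteins is, to a useful approximation, additive over contacts
between individual amino acids and nucleotides at the binding interface.
`ideaEnergy` learns a 20 x 4 interaction matrix $\gamma(a, n)$ — one energy
per (amino-acid type, nucleotide type) pair — from a protein-DNA complex
structure and its sequences, and uses it to score arbitrary sequence pairs
*threaded* onto that fixed structure:

$$E = \sum_{i \in \text{protein}, \; j \in \text{DNA}} \gamma(a_i, n_j)\,
\Theta(r_{ij}),$$

where the soft contact weight is a product of hyperbolic tangents,

$$\Theta(r) = \tfrac12\tanh\!\big(\kappa (r - r_\min)\big)
\tanh\!\big(\kappa (r_\max - r)\big) + \tfrac12,$$

with defaults $\kappa = 0.7\,\text{\AA}^{-1}$, $r_\min = -8$ Å,
$r_\max = 8$ Å, so that $\Theta(8\,\text{Å}) = 1/2$ exactly: two residues
whose representative atoms are closer than 8 Å count as "in contact".
Lower $E$ means stronger predicted binding. Because training leaves an
undetermined positive scale, all energies are in *reduced units*: rankings,
gaps, and ratios are meaningful; absolute magnitudes are not.

### Coarse-graining and the interface

Each amino acid is reduced to its C-alpha position. Each nucleotide is
represented by either the base C5 atom or the backbone P atom; the package
picks the kind whose atoms accumulate the larger number of (DNA atom,
C-alpha) pairs within 8, 9, and 10 Å summed — the closer atom kind carries
more information about the interface. Ties prefer C5, since base-proximal
atoms carry base identity. Interface membership itself uses the hard 8 Å
cutoff on representative atoms; the soft weight $\Theta$ is then applied to
*all* interface cross pairs. Pair counting (rather than per-atom counting)
is used in the representative-atom rule; this is a documented
interpretation, as the selection rule's counting unit is genuinely
ambiguous.

### Training by energy-gap maximization

The native interface sequences are treated as evolved strong binders.
Decoy (presumed weak) binders are generated by randomizing the interface
positions of either the DNA (1000 sequences by default) or the protein
(10000 by default) with i.i.d. uniform letters; a composition-preserving
shuffle is available as an option. DNA and protein decoys are never
randomized jointly. With $\phi$ the 20 x 4 matrix of summed contact weights
for one threaded sequence pair, training maximizes the gap-to-variance
ratio $\delta E / \Delta E$ with

$$A = \langle\phi_\text{decoy}\rangle - \langle\phi_\text{strong}\rangle,
\qquad
B = \langle\phi_\text{decoy}\phi_\text{decoy}^T\rangle -
\langle\phi_\text{decoy}\rangle\langle\phi_\text{decoy}^T\rangle,$$

whose maximizer is $\gamma \propto B^{-1} A$ (the Lagrange multiplier in
the underlying variational problem is eliminated analytically and never
represented). $B$ is a population covariance over decoys. When both decoy
sets exist they are pooled into one $A$/$B$; with several training
complexes, all native $\phi$ and all decoy $\phi$ are pooled likewise.

**Eigenvalue filtering.** $B$ is eigendecomposed, eigenvalues are sorted in
descending order, and all eigenvalues beyond the leading `n_modes` are
replaced by the `n_modes`-th before inversion. The default `n_modes = 70`
matches the published protocol; `n_modes = NULL` retains every eigenmode
carrying at least 0.1% of the leading eigenvalue. That relative threshold
was chosen from the observed spectra of synthetic ensembles, which are
bimodal: genuinely sampled contact-type modes sit above roughly 5e-3 of
the leading eigenvalue, while contact types that essentially never vary
produce a degenerate tail below roughly 2e-4 whose inversion only
amplifies the sampling noise of $A$. The solved $\gamma$ is normalized to
unit Frobenius norm (the scale is undetermined anyway) and its sign is
fixed so decoys score higher (weaker) than strong binders.

**Feature dimension.** The canonical flattened feature dimension here is
$20 \times 4 = 80$. Descriptions of this family of models sometimes quote
a 300-dimensional feature space; nothing in an (amino acid x nucleotide)
contact model requires more than 80 dimensions, so 80 is used throughout
and is held in a single internal constant.

### Threading and complementary strands

A target DNA is compared against the forward and the reverse strand native
sequences (full-strand identity; the reverse strand string of a
single-stranded structure is the reverse complement of its only strand) and
substituted into the more similar strand; ties go to the forward strand
with a warning. When the orientation of a target is unknown, both
replacements are scored and the lower-energy (stronger) one is reported,
since strong binders dominate experimental signals.

### Affinity calibration (ridge)

Measured affinities (e.g. SELEX-derived tables) can replace decoy
statistics entirely: given threaded features $\Phi$ (one row per measured
sequence) and free-energy differences $\Delta\Delta G = RT\ln(K_d$ ratio$)$
with $R = 1.98720425 \times 10^{-3}$ kcal/(mol K) and $T = 298.15$ K, the
calibrated model is the ridge solution
$\hat\gamma = \arg\min \lVert\Phi\gamma - \Delta\Delta G\rVert^2 +
\alpha\lVert\gamma\rVert^2$ with $\alpha = 0.01$ by default, computed via
the SVD. The pseudo-inverse formulation of this calibration is exactly this
regularized least-squares solve.

### Genome scanning

`scan_genome()` threads every window of the structure's protein-proximal
strand length $w$ along a sequence (an $L$-bp sequence yields exactly
$L - w + 1$ scores), normalizes energies into Z-scores against 1000
randomized decoy windows scored once globally,

$$Z = \frac{E - \langle E_\text{decoy}\rangle}{\mathrm{SD}(E_\text{decoy})},$$

averages Z over a centered window (500 bp by default, truncated at the
edges, `NA` windows excluded), and calls sites as maximal runs with
windowed $Z < -0.75$. Windows containing `N` are flagged missing rather
than zero-filled, to avoid fake strong calls. Coordinates are 0-based
half-open internally and in BED output. The averaging window should match
the resolution of the annotation being compared against: 500 bp mirrors
typical ChIP-seq peak resolution, whereas the synthetic benchmark below
plants motifs whose positions are known exactly and therefore uses
`window_bp = 1`. In peak evaluation, a scan position is labeled positive
when its $w$-bp window lies entirely inside a peak ("inside a peak" is
read as containment of the scanned window), and the AUC scores negated Z.
Only the given strand is scanned by default; scanning both strands and
taking the per-position minimum is available. Multi-template proteins are
scanned per template; no fusion rule is invented.

### Simulation export

For use as a short-range sequence-specific term in coarse-grained
protein-DNA simulations, the learned matrix is normalized by its total
absolute value, $W = \gamma / \sum_{a,n}|\gamma(a,n)|$ (signs preserved,
$\sum|W| = 1$), and tabulated as

$$V_\text{PD}(r) = \frac{W}{2}\big(1 + \tanh[\eta(r_0 - r)]\big),$$

with $r_0 = 8$ Å, $\eta = 0.7$ Å$^{-1}$, alongside a Debye-Hückel
electrostatic term (dielectric 78.0, vacuum permittivity 1 in
simulation-internal units) and a $4\epsilon(\sigma/r)^{12}$ excluded-volume
wall with $\sigma = 4$ Å. $W$ is a matrix and $\eta$ a scalar steepness;
the contact term attaches to the DNA phosphate site by convention
(configurable). Forces are analytic derivatives, never finite differences.
The overall energy scale of $W$ in kcal/mol is a required user input —
training cannot determine it. Tables are generic whitespace-separated
(r, E, F) files with self-describing headers; engine-specific formats are
out of scope.

## The synthetic-scenario generator

All tests run without downloads on synthetic scenarios
(`make_training_scenario()`):

* **Geometry.** DNA beads lie on a line at 6.5 Å spacing (about the base
  spacing of B-DNA); protein beads are placed either far away or at one of
  two calibrated offsets that create exactly 1 or exactly 3 contacts under
  the 8 Å cutoff, so a requested contact count is met exactly (and
  re-verified by brute force at construction). Both C5 and P pseudo-atoms
  are emitted so the representative-atom rule is exercised. The default
  training scenario uses 30 protein beads, 16 nt, 40 contacts.
* **Planted energetics.** A ground-truth matrix $\gamma^*$ (unit-norm
  Gaussian) defines the scenario's energetics. The native sequences are a
  Gibbs draw at selection temperature $t_{sel} = 0.6$ (reduced units), and
  the strong-binder ensemble is drawn per position from the conditional
  Boltzmann distribution at the same temperature — emulating evolutionary
  selection of good binders rather than a single global optimum. This
  matters statistically: with a single optimal native, only "which letter
  each position avoids" is identifiable and most of $\gamma^*$ cannot be
  recovered; with a Boltzmann ensemble, linear response gives
  $A \approx \beta B \gamma^*$, so gap training ($B^{-1}A$) recovers the
  planted matrix direction. $t_{sel}$ sits on the plateau between
  selection-strength bias (too cold) and vanishing signal (too hot);
  strong ensembles are sized like the decoy ensembles so the DNA-varied
  and protein-varied subsets carry identical weights in the pooled
  statistics.
* **Affinities.** Tables are threaded energies under $\gamma^*$ plus
  Gaussian noise, with the Kd column obtained by inverting the
  free-energy relation exactly.
* **Genomes.** Uniform (optionally GC-skewed) background with
  non-overlapping copies of the strongest $w$-mer under $\gamma^*$ planted
  at recorded positions. Because the threaded energy is additive over
  positions, the per-position argmin is the exact global argmin; for
  $w \le 8$ this is verified against exhaustive enumeration of all $4^w$
  candidates.

What the generator does *not* emulate: real protein-DNA geometry beyond
contact counts, DNA shape and flexibility, position-position couplings
(the planted energetics are exactly additive, as is the model), genomic
sequence composition, and chromatin context. A passing synthetic benchmark
therefore demonstrates correctness of the machinery and recoverability of
planted signal — not predictive accuracy on real complexes.

## Numerical choices and degenerate inputs

* Eigenvalues below $10^{-12}$ of the leading one count as zero; asking
  for more modes than that rank raises "insufficient decoy diversity".
* Fewer than two decoys, empty interfaces (nothing to randomize), all-zero
  feature matrices, zero decoy energy spread, and single-class label sets
  are all hard errors, not silent results.
* ROC AUC uses midranks, so ties are handled exactly; the
  "balanced" precision-recall variant subsamples the majority class to the
  minority size and averages over 20 seeded subsamples (a documented
  interpretation of balanced PR analysis).
* Strong/weak labeling from enrichment scores uses hi = 0.9 and lo = 0.3,
  escalating lo through 0.4 and 0.5 until at least three weak sequences
  exist.
* Altloc records: first location; insertion codes are preserved in residue
  keys; modified residues map through a user-extensible table (warning),
  unknown polymer residues are errors, hetero/water records are ignored.
* All randomness flows through explicit integer seeds that are recorded in
  the objects they produced (decoy sets, scan tracks, scenarios).

## Problem sizes in the test suite

Unit tests run scenarios with hundreds to a few thousand decoys; the
acceptance-style checks use the full study conditions (1000 DNA + 10000
protein decoys; a 100 kb genome with 20 planted sites; exhaustive $4^8$
motif verification). The complete suite featurizes a few hundred thousand
sequences and finishes in well under a minute on one core.

## Known limitations

* Threading assumes the training and testing sequences share one fixed
  structure; there is no re-threading onto flexible or predicted
  structures.
* The energy is strictly additive over contacts; cooperative multi-residue
  effects are outside the model class.
* Per-type (not per-position) energies: two identical amino acids
  contacting the same nucleotide type contribute identically wherever they
  sit.
* The exported simulation potential's absolute energy scale must be
  supplied by the user; only relative energetics are learned.
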