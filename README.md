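# ideaEnergy

Interpretable protein-DNA interaction energy models learned from complex
structures, in R.

Transcription factors and other DNA-binding proteins recognize their sites
through physicochemical contacts between amino acids and nucleotides.
`ideaEnergy` learns a 20 x 4 interaction matrix γ(a, n) — one energy per
(amino-acid type, nucleotide type) pair — from a protein-DNA complex
structure and its sequences, then uses it to rank binding affinities of
threaded sequence pairs, calibrate against measured affinity tables, scan
genomic sequence for binding sites, and export a sequence-specific pair
potential for coarse-grained simulation engines.

The core is statistical-potential optimization by **energy-gap
maximization**: native interface sequences are treated as evolved strong
binders; decoys are generated by randomizing interface positions; and γ
maximizes the gap-to-variance ratio

    δE / ΔE = (Aᵀγ) / sqrt(γᵀBγ),    γ ∝ B⁻¹A,

where A is the decoy-minus-native mean contact-count difference and B the
decoy contact covariance (eigenvalue-filtered before inversion). Threaded
binding energies are E = Σ γ(aᵢ, nⱼ) Θ(rᵢⱼ) with a tanh switching function
Θ that equals 1/2 at 8 Å. Energies are in reduced units: rankings and gaps
are meaningful, absolute magnitudes are not.

The package implements, per module:

* **structio** — PDB/mmCIF parsing to one bead per residue (Cα; base C5 or
  backbone P chosen by a triple-cutoff occurrence rule), interface
  extraction at 8 Å.
* **featurize** — switching function, contact-count features φ, seeded
  decoy generation, strand-selection threading of target DNA.
* **optimize** — gap statistics, filtered-inverse solve for γ, energy
  prediction, Kd↔ΔΔG conversion, ridge calibration against affinity tables.
* **evaluate** — strong/weak labeling from enrichment scores, ROC/PR AUCs
  (midrank ties), correlations, per-class density separation.
* **genomescan** — base-by-base scanning (L − w + 1 scores), decoy Z-score
  normalization, windowed averaging, site calling at Z < −0.75, evaluation
  against peak intervals; FASTA/BED/narrowPeak/bedGraph IO.
* **simpotential** — normalized interaction matrix W (Σ|W| = 1), tanh
  contact potential with Debye-Hückel and excluded-volume companions,
  tabulated (r, E, F) export with analytic forces.
* **synthfix** — synthetic complexes with exact contact counts, planted
  ground-truth matrices, affinity tables, genomes with recorded motif
  insertions; all seeded and reproducible.

## Worked example

Train on a synthetic complex with known ground-truth energetics, score a
mutational-scan affinity table, and recover planted genomic sites:

```r
library(ideaEnergy)
set.seed(1)

scenario <- make_training_scenario(n_protein = 30, n_dna = 16,
                                   n_contacts = 40, seed = 7)
model <- train_scenario(scenario)
model
#> Energy model (gap-optimized), 20 x 4, n_modes = 79
#>   strongest pair: T/DA (-0.274)
sum(model$gamma * scenario$gamma_star$gamma)  # cosine to the planted matrix
#> 0.941

## affinity table of 3-point mutants of the native site, scored by threading
native <- strsplit(scenario$decoys$native_dna, "")[[1]][1:16]
mutants <- vapply(1:100, function(i) {
  s <- native; pos <- sample(seq_along(s), 3)
  s[pos] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
  paste(s, collapse = "")
}, character(1))
tab <- sample_affinities(scenario$complex, scenario$interface,
                         scenario$gamma_star, sequences = mutants,
                         noise_sd = 0.2, seed = 2)
phi <- do.call(rbind, lapply(tab$sequence, function(s)
  as.numeric(thread_dna(scenario$complex, scenario$interface, s)$phi)))
correlations(predict_energy(model, phi), tab$ddg)
#> Pearson 0.79 / Spearman 0.79 over 100 variants

## genome scan: plant the strongest 8-mer and find it again
sc8 <- make_training_scenario(n_protein = 30, n_dna = 8, n_contacts = 24, seed = 5)
m8 <- train_scenario(sc8)
motif <- strongest_kmer(sc8$gamma_star, sc8$complex, sc8$interface)$motif
#> "ATAGACCG"
gen <- make_synthetic_genome(50000, motif, 10, seed = 3)
track <- scan_genome(m8, sc8$complex, sc8$interface, gen$genome,
                     window_bp = 1, seed = 4)
evaluate_vs_peaks(track$windowed_z, gen$truth, w = track$w)
#> 1
```

The trained matrix points within a few degrees of the planted ground truth
(cosine 0.94); predicted energies of noisy mutant affinities correlate at
0.79; and every one of the 10 planted sites is the scan's strongest signal
(AUC 1.0 against the truth intervals). The heatmap of any model is
available via `plot(model)`, and `write_gamma_tsv()` serializes it with a
JSON metadata sidecar.

A thin command-line front end for shell pipelines is installed at
`inst/cli/idea.R` with subcommands `train`, `scan` (bedGraph + BED + JSON
outputs), and `export-potential`.

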