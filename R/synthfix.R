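## synthfix: synthetic inputs for building and testing without downloads —
## toy coarse-grained complexes with exact contact counts, planted energy
## matrices, affinity tables with controlled noise, and synthetic genomes
## with ground-truth site annotations.

#' Planted (random) energy model
#'
#' Draws a 20x4 matrix of i.i.d. standard normal entries, scaled to unit
#' Frobenius norm: the ground-truth interaction matrix of a synthetic
#' scenario.
#'
#' @param seed Integer seed.
#' @return An [energy_model()] with `meta$planted = TRUE`.
#' @export
planted_energy_model <- function(seed = 1L) {
  g <- with_seed(seed, matrix(stats::rnorm(80), nrow = 20L))
  g <- g / sqrt(sum(g^2))
  energy_model(g, provenance = "gap-optimized",
               meta = list(planted = TRUE, seed = seed))
}

#' Toy coarse-grained protein-DNA complex with an exact contact count
#'
#' Places DNA beads along a line (6.5 Angstrom spacing, roughly the base C5
#' spacing of B-DNA) and protein beads either far away or attached near a
#' DNA bead at one of two calibrated offsets producing exactly 1 or exactly
#' 3 cross-molecule contacts under the 8 Angstrom cutoff, so the requested
#' total is met exactly (verified internally by a brute-force recount).
#' Both C5 and P pseudo-atoms are emitted (P on the far side of the DNA
#' line) so the representative-atom selection rule is exercised; C5 wins.
#' Native sequences are drawn uniformly at random.
#'
#' @param n_protein,n_dna Bead counts (per strand for DNA).
#' @param n_contacts Requested number of cross pairs within 8 Angstrom;
#'   at most `3 * n_protein`.
#' @param seed Integer seed.
#' @param two_strands If `TRUE`, add a reverse strand (reverse complement of
#'   the forward strand) placed away from the protein, contributing no
#'   contacts.
#' @return List with `complex` (resolved [cg_complex()]) and `interface`
#'   ([extract_interface()] at 8 Angstrom).
#' @export
make_toy_complex <- function(n_protein = 30, n_dna = 16, n_contacts = 40,
                             seed = 1L, two_strands = FALSE) {
  stopifnot(n_protein >= 1, n_dna >= 3, n_contacts >= 0,
            n_contacts <= 3 * n_protein)
  ## split the contact budget into beads making 3 contacts and 1 contact
  k3 <- max(0L, as.integer(ceiling((n_contacts - n_protein) / 2)))
  k1 <- n_contacts - 3L * k3
  while (k1 < 0L) { k3 <- k3 - 1L; k1 <- n_contacts - 3L * k3 }
  stopifnot(k3 + k1 <= n_protein)

  geom <- with_seed(seed, {
    fwd_letters <- sample(nt_letters(), n_dna, replace = TRUE)
    prot_letters <- sample(aa_alphabet(), n_protein, replace = TRUE)
    interior <- 2:(n_dna - 1)
    att3 <- interior[sample.int(length(interior), k3, replace = TRUE)]
    att1 <- sample.int(n_dna, k1, replace = TRUE)
    jit <- function(n) stats::runif(n, -0.25, 0.25)
    list(fwd = fwd_letters, prot = prot_letters, att3 = att3, att1 = att1,
         jx = jit(n_protein), jz = jit(n_protein))
  })

  dna_x <- 6.5 * seq_len(n_dna)
  px <- numeric(n_protein); py <- numeric(n_protein); pz <- numeric(n_protein)
  ## attached beads: offsets calibrated against the 6.5 A spacing so that
  ## y = 4 gives contacts to j-1, j, j+1 and y = 7.5 to j only, with >=0.1 A
  ## margin to the 8 A cutoff under the +-0.25 A jitter
  k <- 0L
  for (j in geom$att3) { k <- k + 1L; px[k] <- dna_x[j]; py[k] <- 4.0 }
  for (j in geom$att1) { k <- k + 1L; px[k] <- dna_x[j]; py[k] <- 7.5 }
  if (k < n_protein) {
    far <- (k + 1L):n_protein
    px[far] <- 6.5 * seq_along(far); py[far] <- 60 + 10 * seq_along(far)
  }
  px <- round(px + geom$jx, 3); pz <- round(pz + geom$jz, 3); py <- round(py, 3)

  protein <- data.frame(chain = "A", resid = as.character(seq_len(n_protein)),
                        type = geom$prot, x = px, y = py, z = pz,
                        stringsAsFactors = FALSE)
  fwd <- data.frame(
    chain = "B", strand = "fwd", idx = seq_len(n_dna),
    type = nt_alphabet()[match(geom$fwd, nt_letters())],
    x_c5 = round(dna_x, 3), y_c5 = 0, z_c5 = 0,
    x_p = round(dna_x, 3), y_p = -6.5, z_p = 0,
    x = NA_real_, y = NA_real_, z = NA_real_, stringsAsFactors = FALSE
  )
  dna <- fwd
  if (two_strands) {
    rev_letters <- rev(unname(complement_map[geom$fwd]))
    rev_x <- rev(dna_x)
    dna <- rbind(fwd, data.frame(
      chain = "C", strand = "rev", idx = seq_len(n_dna),
      type = nt_alphabet()[match(rev_letters, nt_letters())],
      x_c5 = round(rev_x, 3), y_c5 = -30, z_c5 = 0,
      x_p = round(rev_x, 3), y_p = -36.5, z_p = 0,
      x = NA_real_, y = NA_real_, z = NA_real_, stringsAsFactors = FALSE
    ))
  }
  cg <- cg_complex(protein, dna, source = sprintf("toy-%d", seed))
  cg <- suppressMessages(select_dna_representative(cg))
  interface <- extract_interface(cg, cutoff = 8)

  ## brute-force recount must equal the request
  d <- cross_dist(protein_xyz(cg), dna_xyz(cg))
  got <- sum(d <= 8)
  if (got != n_contacts) {
    stop("internal error: constructed ", got, " contacts, requested ", n_contacts)
  }
  list(complex = cg, interface = interface)
}

#' Plant a low-energy native sequence pair under a model
#'
#' Sweeps over interface bead letters (DNA and protein alternately),
#' resampling each position from its conditional Boltzmann distribution
#' `P(letter) ~ exp(-contribution / t_sel)` under `model` (Gibbs sampling);
#' at `t_sel = 0` this reduces to greedy coordinate descent onto the global
#' energy minimum, which the additive energy reaches in a few sweeps. A
#' finite temperature mimics an evolved rather than globally optimal native
#' sequence and keeps all letter types in play at the interface.
#'
#' @param cg A resolved [cg_complex()].
#' @param interface An [extract_interface()] selection.
#' @param model The planted [energy_model()].
#' @param t_sel Selection temperature in reduced units; 0 = greedy argmin.
#' @param seed Seed for the Gibbs sweeps (ignored at `t_sel = 0`).
#' @param params [switch_params()].
#' @param sweeps Number of sweeps (default 10; greedy descent stops early
#'   when converged).
#' @return The complex with planted native bead types.
#' @export
plant_native <- function(cg, interface, model, t_sel = 0, seed = 1L,
                         params = switch_params(), sweeps = 10) {
  pairs <- interface_pairs(cg, interface, params)
  if (length(pairs$w) == 0L) return(cg)
  g <- model$gamma
  choose <- function(contrib) {
    if (t_sel == 0) {
      which.min(contrib)
    } else {
      p <- exp(-(contrib - min(contrib)) / t_sel)
      sample.int(length(p), 1L, prob = p / sum(p))
    }
  }
  run_sweeps <- function() {
    for (sweep in seq_len(sweeps)) {
      changed <- FALSE
      a_idx <- aa_index(cg$protein$type)
      n_idx <- nt_index(dna_letters(cg))
      for (j in unique(pairs$dj)) {
        sel <- pairs$dj == j
        contrib <- colSums(pairs$w[sel] * g[a_idx[pairs$pi[sel]], , drop = FALSE])
        best <- choose(contrib)
        if (best != n_idx[j]) {
          n_idx[j] <- best
          cg$dna$type[j] <<- nt_alphabet()[best]
          changed <- TRUE
        }
      }
      for (i in unique(pairs$pi)) {
        sel <- pairs$pi == i
        contrib <- colSums(pairs$w[sel] * t(g)[n_idx[pairs$dj[sel]], , drop = FALSE])
        best <- choose(contrib)
        if (best != a_idx[i]) {
          a_idx[i] <- best
          cg$protein$type[i] <<- aa_alphabet()[best]
          changed <- TRUE
        }
      }
      if (t_sel == 0 && !changed) break
    }
  }
  if (t_sel == 0) run_sweeps() else with_seed(seed, run_sweeps())
  cg
}

## Per-position energy contributions under a model, given the native letters
## on the other molecule: contrib[j, n] for interface DNA beads and
## contrib[i, a] for interface protein beads.
position_contributions <- function(cg, interface, model, params = switch_params()) {
  pairs <- interface_pairs(cg, interface, params)
  g <- model$gamma
  a_nat <- aa_index(cg$protein$type)
  n_nat <- nt_index(dna_letters(cg))
  dna_contrib <- matrix(0, nrow = nrow(cg$dna), ncol = 4L)
  prot_contrib <- matrix(0, nrow = nrow(cg$protein), ncol = 20L)
  for (j in unique(pairs$dj)) {
    sel <- pairs$dj == j
    dna_contrib[j, ] <- colSums(pairs$w[sel] * g[a_nat[pairs$pi[sel]], , drop = FALSE])
  }
  for (i in unique(pairs$pi)) {
    sel <- pairs$pi == i
    prot_contrib[i, ] <- colSums(pairs$w[sel] * t(g)[n_nat[pairs$dj[sel]], , drop = FALSE])
  }
  list(dna = dna_contrib, protein = prot_contrib)
}

#' Sample strong-binder sequences by Boltzmann selection
#'
#' Emulates evolutionary selection for binding: interface letters are drawn
#' independently per position with probability proportional to
#' `exp(-contribution / t_sel)` under the planted matrix (the other
#' molecule's letters held native), so strong binders are an ensemble of
#' low-energy sequences rather than the single optimal one. In the
#' linear-response regime this makes the decoy-vs-strong contact-frequency
#' difference proportional to the decoy covariance times the planted matrix,
#' which is what gap-ratio training inverts.
#'
#' @param cg A resolved [cg_complex()].
#' @param interface An [extract_interface()] selection.
#' @param model The planted [energy_model()].
#' @param n_dna,n_protein Ensemble sizes.
#' @param t_sel Selection temperature in reduced energy units (default 0.6).
#' @param seed Integer seed.
#' @param params [switch_params()].
#' @return List with character vectors `dna` and `protein` (full per-bead
#'   sequences, non-interface positions native).
#' @export
sample_strong_binders <- function(cg, interface, model, n_dna = 1000,
                                  n_protein = 10000, t_sel = 0.6, seed = 1L,
                                  params = switch_params()) {
  stopifnot(t_sel > 0)
  contrib <- position_contributions(cg, interface, model, params)
  nat_dna <- dna_letters(cg)
  nat_prot <- cg$protein$type
  draw <- function(native, pos, weights, alphabet, n) {
    probs <- lapply(pos, function(p) {
      w <- exp(-weights[p, ] / t_sel)
      w / sum(w)
    })
    vapply(seq_len(n), function(i) {
      s <- native
      for (k in seq_along(pos)) {
        s[pos[k]] <- alphabet[sample.int(length(alphabet), 1L, prob = probs[[k]])]
      }
      paste(s, collapse = "")
    }, character(1))
  }
  with_seed(seed, {
    dna <- draw(nat_dna, interface$dna_idx, contrib$dna, nt_letters(), n_dna)
    protein <- draw(nat_prot, interface$protein_idx, contrib$protein,
                    aa_alphabet(), n_protein)
  })
  list(dna = dna, protein = protein, t_sel = t_sel, seed = seed)
}

#' Full synthetic training scenario
#'
#' Bundles the pieces of a planted-parameter study: a toy complex whose
#' native sequences are optimal under a planted interaction matrix, the
#' interface, the planted matrix, a Boltzmann-selected strong-binder
#' ensemble ([sample_strong_binders()]; sized like the decoy sets so strong
#' and decoy ensembles weight the DNA- and protein-varied subsets
#' identically), and uniform decoy sets.
#'
#' @inheritParams make_toy_complex
#' @param n_dna_decoys,n_protein_decoys Decoy counts (defaults 1000 / 10000).
#' @param t_sel Selection temperature for the native draw and the strong
#'   ensemble, in reduced energy units (default 0.6).
#' @param params [switch_params()].
#' @return List with `complex`, `interface`, `gamma_star`, `strong`,
#'   `decoys`, `seed`.
#' @export
make_training_scenario <- function(n_protein = 30, n_dna = 16, n_contacts = 40,
                                   seed = 1L, two_strands = FALSE,
                                   n_dna_decoys = 1000, n_protein_decoys = 10000,
                                   t_sel = 0.6, params = switch_params()) {
  toy <- make_toy_complex(n_protein, n_dna, n_contacts, seed = seed,
                          two_strands = two_strands)
  gamma_star <- planted_energy_model(seed = seed + 1000L)
  cg <- plant_native(toy$complex, toy$interface, gamma_star, t_sel = t_sel,
                     seed = seed + 4000L, params = params)
  if (two_strands) {
    ## keep the duplex consistent: reverse strand = reverse complement
    fwd_rows <- which(cg$dna$strand == "fwd")
    rev_rows <- which(cg$dna$strand == "rev")
    fwd_letters <- nt_letters()[match(cg$dna$type[fwd_rows], nt_alphabet())]
    rc <- rev(unname(complement_map[fwd_letters]))
    cg$dna$type[rev_rows][order(cg$dna$idx[rev_rows])] <-
      nt_alphabet()[match(rc, nt_letters())]
  }
  strong <- sample_strong_binders(cg, toy$interface, gamma_star,
                                  n_dna = n_dna_decoys,
                                  n_protein = n_protein_decoys,
                                  t_sel = t_sel, seed = seed + 3000L,
                                  params = params)
  decoys <- generate_decoys(cg, toy$interface, n_dna = n_dna_decoys,
                            n_protein = n_protein_decoys, seed = seed + 2000L)
  list(complex = cg, interface = toy$interface, gamma_star = gamma_star,
       strong = strong, decoys = decoys, seed = seed)
}

#' Train an energy model on a synthetic scenario
#'
#' Featurizes the scenario's strong-binder and decoy ensembles, forms the
#' gap statistics, and solves for the energy matrix (all numerically
#' nonzero eigenmodes retained).
#'
#' @param scenario A [make_training_scenario()] result.
#' @param n_modes Passed to [solve_gamma()] (`NULL` = all nonzero modes).
#' @param params [switch_params()].
#' @return An [energy_model()].
#' @export
train_scenario <- function(scenario, n_modes = NULL, params = switch_params()) {
  cg <- scenario$complex
  interface <- scenario$interface
  pairs <- interface_pairs(cg, interface, params)
  strong <- rbind(
    phi_matrix(cg, interface, dna_strings = scenario$strong$dna,
               params = params, pairs = pairs),
    phi_matrix(cg, interface, protein_strings = scenario$strong$protein,
               params = params, pairs = pairs)
  )
  decoys <- rbind(
    phi_matrix(cg, interface, dna_strings = scenario$decoys$dna,
               params = params, pairs = pairs),
    phi_matrix(cg, interface, protein_strings = scenario$decoys$protein,
               params = params, pairs = pairs)
  )
  stats <- compute_gap_statistics(strong, decoys)
  solve_gamma(stats, n_modes = n_modes,
              meta = list(scenario_seed = scenario$seed,
                          n_strong = nrow(strong), n_decoy = nrow(decoys)))
}

#' Synthetic affinity table
#'
#' Threads random (or supplied) DNA sequences onto the forward strand,
#' scores them under the given model, adds Gaussian noise, and derives the
#' dissociation-constant ratio by inverting the free-energy relation, so
#' `RT * log(kd_ratio)` reproduces the `ddg` column exactly at zero noise.
#'
#' @param cg A resolved [cg_complex()].
#' @param interface An [extract_interface()] selection.
#' @param model The (planted) [energy_model()].
#' @param n Number of random sequences (ignored when `sequences` given).
#' @param sequences Optional character vector of strand-length sequences.
#' @param noise_sd Gaussian noise standard deviation on the energies.
#' @param seed Integer seed.
#' @param temperature Kelvin (default 298.15).
#' @param params [switch_params()].
#' @return `data.frame` with columns `sequence`, `ddg`, `kd_ratio`.
#' @export
sample_affinities <- function(cg, interface, model, n = 100, sequences = NULL,
                              noise_sd = 0, seed = 1L, temperature = 298.15,
                              params = switch_params()) {
  w <- sum(cg$dna$strand == "fwd")
  if (is.null(sequences)) {
    sequences <- with_seed(seed, {
      vapply(seq_len(n), function(i)
        paste(sample(nt_letters(), w, replace = TRUE), collapse = ""),
        character(1))
    })
  }
  pairs <- interface_pairs(cg, interface, params)
  fwd_rows <- which(cg$dna$strand == "fwd")
  fwd_rows <- fwd_rows[order(cg$dna$idx[fwd_rows])]
  nat <- dna_letters(cg)
  full <- vapply(sequences, function(s) {
    letters <- nat
    letters[fwd_rows] <- seq_chars(s)
    paste(letters, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  Phi <- phi_matrix(cg, interface, dna_strings = full, params = params, pairs = pairs)
  e <- predict_energy(model, Phi)
  noise <- with_seed(seed + 1L, stats::rnorm(length(e), sd = noise_sd))
  ddg <- e + noise
  data.frame(sequence = sequences, ddg = ddg,
             kd_ratio = kd_from_ddg(ddg, temperature))
}

#' Strongest w-mer under a model
#'
#' The w-mer with the lowest threaded energy on the structure's
#' protein-proximal strand. Because the threaded energy is additive over
#' positions, the per-position argmin of the position-energy profile is the
#' exact global argmin; for `w <= 8` the result is verified by exhaustive
#' enumeration of all `4^w` w-mers.
#'
#' @param model An [energy_model()].
#' @param cg A resolved [cg_complex()].
#' @param interface An [extract_interface()] selection.
#' @param params [switch_params()].
#' @return List with `motif` (string) and its `energy`.
#' @export
strongest_kmer <- function(model, cg, interface, params = switch_params()) {
  prof <- scan_profile(model, cg, interface, params)
  pick <- apply(prof$M, 1L, which.min)
  motif <- paste(nt_letters()[pick], collapse = "")
  energy <- prof$E0 + sum(prof$M[cbind(seq_len(prof$w), pick)])
  if (prof$w <= 8L) {
    codes <- as.matrix(expand.grid(rep(list(1:4), prof$w)))
    e_all <- rep(prof$E0, nrow(codes))
    for (j in seq_len(prof$w)) e_all <- e_all + prof$M[j, codes[, j]]
    stopifnot(abs(min(e_all) - energy) < 1e-9)
  }
  list(motif = motif, energy = energy)
}

#' Synthetic genome with planted motif insertions
#'
#' Uniform (or GC-skewed) random background with `n_insertions`
#' non-overlapping copies of `motif` at recorded positions.
#'
#' @param length Genome length in bp.
#' @param motif Motif string (typically from [strongest_kmer()]).
#' @param n_insertions Number of planted copies.
#' @param seed Integer seed.
#' @param gc Background GC content (default 0.5 = uniform).
#' @return List with `genome` (string) and `truth` (`data.frame` of 0-based
#'   half-open `start`/`end`, sorted).
#' @export
make_synthetic_genome <- function(length, motif, n_insertions, seed = 1L,
                                  gc = 0.5) {
  w <- nchar(motif)
  stopifnot(length >= w, n_insertions >= 0, gc > 0, gc < 1)
  probs <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)  # A T C G
  with_seed(seed, {
    letters <- sample(nt_letters(), length, replace = TRUE, prob = probs)
    starts <- integer(0)
    if (n_insertions > 0) {
      avail <- seq_len(length - w + 1L)
      for (i in seq_len(n_insertions)) {
        if (length(avail) == 0L) stop("cannot place ", n_insertions,
                                      " non-overlapping insertions")
        p <- avail[sample.int(length(avail), 1L)]
        starts <- c(starts, p)
        avail <- avail[abs(avail - p) >= w]
      }
    }
  })
  starts <- sort(starts)
  for (p in starts) letters[p:(p + w - 1L)] <- seq_chars(motif)
  list(genome = paste(letters, collapse = ""),
       truth = data.frame(start = starts - 1L, end = starts - 1L + w))
}

#' Write a toy complex as a minimal PDB file
#'
#' Emits legal fixed-width ATOM records: C-alpha atoms for protein residues
#' and both C5 and P atoms for nucleotides, so the file round-trips through
#' [parse_complex()] and is readable by third-party parsers.
#'
#' @param cg A [cg_complex()].
#' @param file Output path.
#' @export
write_toy_pdb <- function(cg, file) {
  three <- names(aa_three_to_one)[match(cg$protein$type, aa_three_to_one)]
  lines <- character(0)
  serial <- 0L
  fmt <- function(serial, name, resn, chain, resno, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, "", resn, chain, resno, "", x, y, z, 1, 0, elem)
  }
  for (i in seq_len(nrow(cg$protein))) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, " CA ", three[i], cg$protein$chain[i], i,
                          cg$protein$x[i], cg$protein$y[i], cg$protein$z[i], "C"))
  }
  for (i in seq_len(nrow(cg$dna))) {
    d <- cg$dna[i, ]
    if (!is.na(d$x_c5)) {
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, " C5 ", d$type, d$chain, d$idx,
                            d$x_c5, d$y_c5, d$z_c5, "C"))
    }
    if (!is.na(d$x_p)) {
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, " P  ", d$type, d$chain, d$idx,
                            d$x_p, d$y_p, d$z_p, "P"))
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Write / read an affinity table as TSV
#'
#' @param table A [sample_affinities()] `data.frame`.
#' @param file TSV path.
#' @export
write_affinity_tsv <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_affinity_tsv
#' @export
read_affinity_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a genome as FASTA / truth intervals as BED
#'
#' @param genome Sequence string.
#' @param file Output path.
#' @param name Contig name.
#' @export
write_genome_fasta <- function(genome, file, name = "synthetic") {
  set <- Biostrings::DNAStringSet(stats::setNames(genome, name))
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' @rdname write_genome_fasta
#' @param truth `data.frame` with 0-based half-open `start`/`end`.
#' @export
write_truth_bed <- function(truth, file, name = "synthetic") {
  if (nrow(truth) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end)
  )
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
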