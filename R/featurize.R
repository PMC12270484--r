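## featurize: the soft-contact switching function Theta, feature vectors phi
## for threaded sequence pairs, decoy sequence generation, and the
## strand-selection threading rule for target DNA sequences.

#' Switching-function parameters
#'
#' Parameters of the hyperbolic-tangent switching function used to weight
#' amino-acid/nucleotide contacts: steepness `kappa` (1/Angstrom) and the
#' range limits `r_min`, `r_max` (Angstrom). The defaults (`kappa = 0.7`,
#' `r_min = -8`, `r_max = 8`) make two residues "in contact" (weight > 0.5)
#' when their representative atoms are closer than 8 Angstrom.
#'
#' @param kappa Steepness, must be positive.
#' @param r_min,r_max Range limits, `r_min < r_max`.
#' @return An object of class `switch_params`.
#' @export
switch_params <- function(kappa = 0.7, r_min = -8, r_max = 8) {
  stopifnot(kappa > 0, r_min < r_max)
  structure(list(kappa = kappa, r_min = r_min, r_max = r_max),
            class = "switch_params")
}

#' Soft-contact switching weight
#'
#' `theta(r) = 0.5 * tanh(kappa * (r - r_min)) * tanh(kappa * (r_max - r)) + 0.5`.
#' With the default parameters this equals 0.5 at exactly 8 Angstrom, is
#' close to 1 at contact distances and decays smoothly to 0 beyond the
#' contact range.
#'
#' @param r Distance(s) in Angstrom, non-negative.
#' @param params A [switch_params()] object.
#' @return Weight(s) in `[0, 1]`.
#' @export
theta <- function(r, params = switch_params()) {
  stopifnot(all(r >= 0))
  0.5 * tanh(params$kappa * (r - params$r_min)) *
    tanh(params$kappa * (params$r_max - r)) + 0.5
}

## Feature-space indexing: phi and gamma are 20x4 matrices (rows = amino
## acids in aa_alphabet() order, columns = nucleotides in nt_alphabet()
## order), flattened column-major to length-80 vectors where needed.
feature_dim <- function() 20L * 4L

empty_phi <- function() {
  matrix(0, nrow = 20L, ncol = 4L,
         dimnames = list(aa_alphabet(), nt_alphabet()))
}

flat_index <- function(aa_idx, nt_idx) aa_idx + 20L * (nt_idx - 1L)

## Precompute the interface pair list for a resolved complex: all (interface
## protein bead) x (interface DNA bead) pairs with their switching weights.
## The hard 8-A cutoff decides membership; the soft weight applies to every
## cross pair among interface beads.
interface_pairs <- function(cg, interface, params = switch_params()) {
  pi <- interface$protein_idx
  dj <- interface$dna_idx
  if (length(pi) == 0L || length(dj) == 0L) {
    return(list(pi = integer(0), dj = integer(0), w = numeric(0)))
  }
  d <- cross_dist(protein_xyz(cg)[pi, , drop = FALSE],
                  dna_xyz(cg)[dj, , drop = FALSE])
  grid <- expand.grid(i = seq_along(pi), j = seq_along(dj))
  list(pi = pi[grid$i], dj = dj[grid$j], w = theta(as.vector(d[cbind(grid$i, grid$j)]), params))
}

## normalize sequence arguments to per-bead letter vectors
protein_letters <- function(cg, protein_seq = NULL) {
  if (is.null(protein_seq)) return(cg$protein$type)
  letters <- seq_chars(protein_seq)
  if (length(letters) != nrow(cg$protein)) {
    stop("protein sequence length (", length(letters),
         ") does not match the protein bead count (", nrow(cg$protein), ")")
  }
  toupper(letters)
}

dna_letters <- function(cg, dna_seq = NULL) {
  if (is.null(dna_seq)) return(nt_letters()[match(cg$dna$type, nt_alphabet())])
  letters <- seq_chars(dna_seq)
  if (length(letters) != nrow(cg$dna)) {
    stop("DNA sequence length (", length(letters),
         ") does not match the DNA bead count (", nrow(cg$dna), ")")
  }
  toupper(letters)
}

#' Feature vector of a threaded sequence pair
#'
#' Computes `phi`, the 20x4 matrix of summed switching weights between each
#' amino-acid type and nucleotide type over all interface bead pairs, for an
#' arbitrary (protein, DNA) sequence pair threaded onto the fixed native
#' structure. Distances always come from the structure; only the residue
#' types at each bead change (threading assumption).
#'
#' @param cg A resolved [cg_complex()].
#' @param interface An [extract_interface()] selection.
#' @param protein_seq Protein sequence (string over all protein beads, in
#'   bead order) or `NULL` for the native sequence.
#' @param dna_seq DNA sequence (string over all DNA beads, forward strand
#'   5'->3' then reverse strand 5'->3') or `NULL` for the native sequence.
#' @param params [switch_params()].
#' @param pairs Optional precomputed pair list (internal fast path).
#' @return A 20x4 numeric matrix of class `feature_vector`.
#' @export
compute_phi <- function(cg, interface, protein_seq = NULL, dna_seq = NULL,
                        params = switch_params(), pairs = NULL) {
  if (is.null(pairs)) pairs <- interface_pairs(cg, interface, params)
  m <- empty_phi()
  if (length(pairs$w) == 0L) {
    class(m) <- c("feature_vector", class(m))
    return(m)
  }
  a <- aa_index(protein_letters(cg, protein_seq)[pairs$pi])
  n <- nt_index(dna_letters(cg, dna_seq)[pairs$dj])
  acc <- rowsum(pairs$w, group = flat_index(a, n))
  m[as.integer(rownames(acc))] <- acc[, 1]
  class(m) <- c("feature_vector", class(m))
  m
}

## Batch phi computation for decoy sets: returns an n x 80 matrix (rows =
## decoys, columns = flattened feature space). `which` selects whether the
## DNA letters or the protein letters vary across rows.
phi_matrix <- function(cg, interface, dna_strings = NULL, protein_strings = NULL,
                       params = switch_params(), pairs = NULL) {
  if (is.null(pairs)) pairs <- interface_pairs(cg, interface, params)
  vary_dna <- !is.null(dna_strings)
  vary_prot <- !is.null(protein_strings)
  stopifnot(xor(vary_dna, vary_prot))
  strings <- if (vary_dna) dna_strings else protein_strings
  n_dec <- length(strings)
  out <- matrix(0, nrow = n_dec, ncol = feature_dim())
  if (length(pairs$w) == 0L || n_dec == 0L) return(out)
  rows_idx <- seq_len(n_dec)
  if (vary_dna) {
    a_fix <- aa_index(cg$protein$type)[pairs$pi]
    L <- matrix(nt_index(unlist(strsplit(strings, ""), use.names = FALSE)),
                nrow = n_dec, byrow = TRUE)
    for (k in seq_along(pairs$w)) {
      col <- flat_index(a_fix[k], L[, pairs$dj[k]])
      idx <- cbind(rows_idx, col)
      out[idx] <- out[idx] + pairs$w[k]
    }
  } else {
    n_fix <- nt_index(nt_letters()[match(cg$dna$type, nt_alphabet())])[pairs$dj]
    L <- matrix(aa_index(unlist(strsplit(strings, ""), use.names = FALSE)),
                nrow = n_dec, byrow = TRUE)
    for (k in seq_along(pairs$w)) {
      col <- flat_index(L[, pairs$pi[k]], n_fix[k])
      idx <- cbind(rows_idx, col)
      out[idx] <- out[idx] + pairs$w[k]
    }
  }
  out
}

#' Generate randomized decoy sequences
#'
#' Decoy (presumed weak-binder) sequences are built from the native protein
#' and DNA sequences by replacing interface positions with i.i.d. uniform
#' draws from the corresponding alphabet (or with a composition-preserving
#' shuffle of the native interface letters). Non-interface positions are
#' untouched. DNA and protein decoys form separate sets.
#'
#' @param cg A resolved [cg_complex()].
#' @param interface An [extract_interface()] selection.
#' @param n_dna Number of DNA decoys (default 1000).
#' @param n_protein Number of protein decoys (default 10000).
#' @param seed Integer seed; recorded in the result.
#' @param method `"uniform"` (default) or `"shuffle"`.
#' @return An object of class `decoy_set`: list with character vectors
#'   `dna` (length `n_dna`, strings over all DNA beads) and `protein`
#'   (length `n_protein`), the `seed`, the randomized position sets, and the
#'   native sequences.
#' @export
generate_decoys <- function(cg, interface, n_dna = 1000, n_protein = 10000,
                            seed = 1L, method = c("uniform", "shuffle")) {
  method <- match.arg(method)
  stopifnot(n_dna >= 1, n_protein >= 1)
  if (length(interface$protein_idx) == 0L && length(interface$dna_idx) == 0L) {
    stop("nothing to randomize: empty interface")
  }
  nat_dna <- dna_letters(cg)
  nat_prot <- protein_letters(cg)
  randomize <- function(native, pos, alphabet, n) {
    vapply(seq_len(n), function(i) {
      s <- native
      if (length(pos) > 0L) {
        s[pos] <- if (method == "uniform") {
          sample(alphabet, length(pos), replace = TRUE)
        } else {
          sample(s[pos])
        }
      }
      paste(s, collapse = "")
    }, character(1))
  }
  with_seed(seed, {
    dna <- randomize(nat_dna, interface$dna_idx, nt_letters(), n_dna)
    protein <- randomize(nat_prot, interface$protein_idx, aa_alphabet(), n_protein)
  })
  structure(
    list(dna = dna, protein = protein, seed = seed,
         dna_positions = interface$dna_idx,
         protein_positions = interface$protein_idx,
         native_dna = paste(nat_dna, collapse = ""),
         native_protein = paste(nat_prot, collapse = "")),
    class = "decoy_set"
  )
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("Decoy set:", length(x$dna), "DNA +", length(x$protein),
      "protein decoys (seed", x$seed, ")\n")
  invisible(x)
}

#' Write a decoy set to FASTA
#'
#' Headers record the decoy index, molecule, and generation seed.
#'
#' @param decoys A [generate_decoys()] result.
#' @param file Output FASTA path.
#' @param which `"dna"` or `"protein"`.
#' @export
write_decoys_fasta <- function(decoys, file, which = c("dna", "protein")) {
  which <- match.arg(which)
  seqs <- decoys[[which]]
  names(seqs) <- sprintf("decoy_%s_%06d seed=%d", which, seq_along(seqs), decoys$seed)
  set <- if (which == "dna") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, file)
  invisible(file)
}

#' Thread a target DNA sequence onto the structure
#'
#' Decides by sequence identity whether the 5'->3' target corresponds to the
#' structure's forward or reverse strand, and substitutes it into the more
#' similar strand (ties go to the forward strand, with a warning). When the
#' orientation is unknown, both replacements are scored with `model` and the
#' one with the stronger (lower) predicted binding energy is reported, on
#' the grounds that strong binders dominate experimental signals.
#'
#' @param cg A resolved [cg_complex()].
#' @param interface An [extract_interface()] selection.
#' @param target_dna Target DNA string, length equal to one strand.
#' @param orientation_known If `TRUE` (default), pick the strand by identity
#'   alone; if `FALSE`, score both threadings with `model`.
#' @param model An `energy_model` (required when `orientation_known = FALSE`).
#' @param params [switch_params()].
#' @return A list with `dna_letters` (full per-bead letter vector), the
#'   chosen `strand`, the identity fractions, the threaded `phi`, and (when
#'   a model is supplied) the predicted `energy`.
#' @export
thread_dna <- function(cg, interface, target_dna, orientation_known = TRUE,
                       model = NULL, params = switch_params()) {
  target <- toupper(target_dna)
  s_fwd <- strand_sequence(cg, "fwd")
  has_rev <- any(cg$dna$strand == "rev")
  s_rev <- if (has_rev) strand_sequence(cg, "rev") else revcomp(s_fwd)
  if (nchar(target) != nchar(s_fwd)) {
    stop("target length (", nchar(target), ") does not match the strand length (",
         nchar(s_fwd), ")")
  }
  identity_to <- function(a, b) mean(seq_chars(a) == seq_chars(b))
  id_fwd <- identity_to(target, s_fwd)
  id_rev <- identity_to(target, s_rev)

  replace_strand <- function(strand, letters_new) {
    letters <- dna_letters(cg)
    rows <- which(cg$dna$strand == strand)
    rows <- rows[order(cg$dna$idx[rows])]
    letters[rows] <- seq_chars(letters_new)
    letters
  }
  thread_one <- function(strand) {
    if (strand == "fwd") {
      replace_strand("fwd", target)
    } else if (has_rev) {
      replace_strand("rev", target)
    } else {
      ## single-stranded structure: reverse orientation = thread the
      ## reverse complement onto the only strand
      replace_strand("fwd", revcomp(target))
    }
  }

  if (orientation_known) {
    if (id_fwd == id_rev) {
      warning("target equally similar to both strands; threading the forward strand",
              call. = FALSE)
      strand <- "fwd"
    } else {
      strand <- if (id_fwd > id_rev) "fwd" else "rev"
    }
    letters <- thread_one(strand)
    phi <- compute_phi(cg, interface, dna_seq = paste(letters, collapse = ""),
                       params = params)
    energy <- if (!is.null(model)) predict_energy(model, phi) else NULL
  } else {
    if (is.null(model)) stop("orientation_known = FALSE requires an energy model")
    cand <- lapply(c("fwd", "rev"), function(s) {
      letters <- thread_one(s)
      phi <- compute_phi(cg, interface, dna_seq = paste(letters, collapse = ""),
                         params = params)
      list(strand = s, letters = letters, phi = phi,
           energy = predict_energy(model, phi))
    })
    best <- which.min(vapply(cand, `[[`, numeric(1), "energy"))
    strand <- cand[[best]]$strand
    letters <- cand[[best]]$letters
    phi <- cand[[best]]$phi
    energy <- cand[[best]]$energy
  }
  list(dna_letters = letters, strand = strand,
       identity = c(fwd = id_fwd, rev = id_rev), phi = phi, energy = energy)
}
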