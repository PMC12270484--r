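## genomescan: slide the structure's DNA window along a genomic sequence,
## predict per-position threaded binding energies, normalize them to Z-scores
## against randomized decoy windows, average over windows, call sites below a
## Z threshold, and evaluate against peak intervals.

## The scan threads every w-mer onto the strand of the structure closest to
## the protein (most interface beads; ties -> forward). Because the energy is
## additive over contacts, threading reduces to a w x 4 position-energy
## matrix M plus a constant E0 from the other strand's native letters.
scan_profile <- function(model, cg, interface, params = switch_params()) {
  stopifnot(inherits(model, "energy_model"))
  pairs <- interface_pairs(cg, interface, params)
  n_if <- table(factor(cg$dna$strand[interface$dna_idx], levels = c("fwd", "rev")))
  strand <- if (n_if[["rev"]] > n_if[["fwd"]]) "rev" else "fwd"
  on_strand <- cg$dna$strand == strand
  w <- sum(on_strand)
  M <- matrix(0, nrow = w, ncol = 4L)
  E0 <- 0
  if (length(pairs$w) > 0L) {
    a <- aa_index(cg$protein$type)[pairs$pi]
    in_strand <- on_strand[pairs$dj]
    for (k in which(in_strand)) {
      j <- cg$dna$idx[pairs$dj[k]]
      M[j, ] <- M[j, ] + pairs$w[k] * model$gamma[a[k], ]
    }
    nat <- nt_index(dna_letters(cg))
    for (k in which(!in_strand)) {
      E0 <- E0 + pairs$w[k] * model$gamma[a[k], nat[pairs$dj[k]]]
    }
  }
  list(M = M, E0 = E0, w = w, strand = strand)
}

genome_codes <- function(genome_seq) {
  letters <- toupper(seq_chars(genome_seq))
  codes <- match(letters, nt_letters())  # N and anything else -> NA
  codes
}

#' Per-position threaded binding energies along a sequence
#'
#' Threads each window `genome_seq[i : i + w - 1]` onto the structure's
#' protein-proximal DNA strand and evaluates the model energy, producing
#' exactly `L - w + 1` scores for a length-`L` sequence. Windows containing
#' `N` (or any non-ACGT letter) score `NA`.
#'
#' @param model An [energy_model()].
#' @param cg A resolved [cg_complex()]; the scanned motif length `w` is the
#'   length of its protein-proximal strand.
#' @param interface An [extract_interface()] selection.
#' @param genome_seq Sequence as a string (alphabet `A`, `C`, `G`, `T`, `N`).
#' @param params [switch_params()].
#' @return Numeric vector of length `L - w + 1` with attribute `w`.
#' @export
scan_energies <- function(model, cg, interface, genome_seq,
                          params = switch_params()) {
  prof <- scan_profile(model, cg, interface, params)
  codes <- genome_codes(genome_seq)
  L <- length(codes)
  w <- prof$w
  if (L < w) stop("sequence shorter than the structural motif (", w, " bp)")
  n_pos <- L - w + 1L
  acc <- rep(prof$E0, n_pos)
  for (j in seq_len(w)) {
    acc <- acc + prof$M[j, codes[j:(j + n_pos - 1L)]]
  }
  attr(acc, "w") <- w
  acc
}

## energies of n random uniform w-mers under the same scan profile
decoy_window_energies <- function(prof, n = 1000, seed = 1L) {
  with_seed(seed, {
    codes <- matrix(sample.int(4L, n * prof$w, replace = TRUE), nrow = n)
  })
  e <- rep(prof$E0, n)
  for (j in seq_len(prof$w)) e <- e + prof$M[j, codes[, j]]
  e
}

#' Normalize energies to Z-scores against decoy energies
#'
#' `Z = (E - mean(E_decoy)) / SD(E_decoy)`, elementwise. Negative Z marks
#' stronger-than-random predicted binding.
#'
#' @param energies Numeric energies (may contain `NA`).
#' @param decoy_energies At least two decoy energies with nonzero spread.
#' @return Z-scores, same length as `energies`.
#' @export
znormalize <- function(energies, decoy_energies) {
  if (length(decoy_energies) < 2L) stop("need at least two decoy energies")
  s <- stats::sd(decoy_energies)
  if (s == 0) stop("zero decoy energy spread")
  (energies - mean(decoy_energies)) / s
}

#' Centered moving average of a Z-score track
#'
#' Averages over a centered window of `window_bp` positions; windows are
#' truncated at the track edges and missing (`NA`) scores are excluded from
#' each mean. A window with no non-missing scores yields `NA`.
#'
#' @param z Numeric per-position scores.
#' @param window_bp Window length in positions (default 500).
#' @return Smoothed track, same length as `z`.
#' @export
window_average <- function(z, window_bp = 500) {
  stopifnot(window_bp >= 1)
  n <- length(z)
  if (window_bp == 1) return(z)
  half_lo <- (window_bp - 1L) %/% 2L
  half_hi <- window_bp - 1L - half_lo
  vals <- ifelse(is.na(z), 0, z)
  cs <- c(0, cumsum(vals))
  cc <- c(0, cumsum(!is.na(z)))
  j <- seq_len(n)
  lo <- pmax(1L, j - half_lo)
  hi <- pmin(n, j + half_hi)
  count <- cc[hi + 1L] - cc[lo]
  out <- (cs[hi + 1L] - cs[lo]) / count
  out[count == 0] <- NA_real_
  out
}

#' Call binding sites from a windowed Z track
#'
#' Maximal runs of positions with windowed Z strictly below `threshold`
#' become intervals (0-based, half-open, in track coordinates shifted by
#' `offset`). Missing positions break runs.
#'
#' @param windowed_z Numeric track.
#' @param threshold Z threshold (default -0.75).
#' @param offset 0-based genomic offset of the first track position.
#' @return `data.frame` with columns `start`, `end`.
#' @export
call_sites <- function(windowed_z, threshold = -0.75, offset = 0L) {
  below <- !is.na(windowed_z) & windowed_z < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L + offset, end = ends[keep] + offset)
}

as_peak_df <- function(peaks) {
  if (inherits(peaks, "GRanges")) {
    data.frame(start = GenomicRanges::start(peaks) - 1L,
               end = GenomicRanges::end(peaks))
  } else {
    stopifnot(all(c("start", "end") %in% names(peaks)))
    as.data.frame(peaks[, c("start", "end")])
  }
}

#' ROC AUC of a Z track against known peak intervals
#'
#' Each scan position is labeled positive when its `w`-bp window lies inside
#' a peak interval; the AUC is computed with lower (more negative) Z scoring
#' as a stronger positive prediction. Missing positions are dropped.
#'
#' @param z Per-position (windowed) Z-scores.
#' @param peaks Peak intervals: a `data.frame` with 0-based half-open
#'   `start`/`end` columns, or a `GRanges`.
#' @param w Window width in bp represented by each position (default 1).
#' @param offset 0-based genomic offset of the first track position.
#' @return ROC AUC in `[0, 1]`.
#' @export
evaluate_vs_peaks <- function(z, peaks, w = 1L, offset = 0L) {
  peaks <- as_peak_df(peaks)
  keep <- !is.na(z)
  pos <- which(keep) - 1L + offset  # 0-based window starts
  windows <- IRanges::IRanges(start = pos + 1L, width = w)
  pk <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  hits <- IRanges::overlapsAny(windows, pk, type = "within")
  labels <- as.integer(hits)
  roc_auc(z[keep], labels)
}

#' Scan a genomic sequence for predicted binding sites
#'
#' End-to-end driver: per-position threaded energies, decoy-normalized
#' Z-scores (decoy energies come from `n_decoys` randomized windows scored
#' once, globally), centered window averaging, and site calling.
#'
#' @inheritParams scan_energies
#' @param contig Contig name recorded in the track.
#' @param offset 0-based genomic offset of the first sequence position.
#' @param window_bp Averaging window in positions (default 500; use 1 to
#'   skip smoothing).
#' @param z_threshold Site-calling threshold on windowed Z (default -0.75).
#' @param n_decoys Number of randomized decoy windows (default 1000).
#' @param seed Seed for decoy-window generation.
#' @return An object of class `genome_scan_track`: list with `contig`,
#'   `offset`, `w`, `strand`, `energies`, `z`, `windowed_z`, `window_bp`,
#'   `threshold`, `sites` (0-based half-open `data.frame`), decoy summary
#'   statistics, and the `seed`.
#' @export
scan_genome <- function(model, cg, interface, genome_seq, contig = "seq",
                        offset = 0L, window_bp = 500, z_threshold = -0.75,
                        n_decoys = 1000, seed = 1L, params = switch_params()) {
  prof <- scan_profile(model, cg, interface, params)
  energies <- scan_energies(model, cg, interface, genome_seq, params)
  dec <- decoy_window_energies(prof, n = n_decoys, seed = seed)
  z <- znormalize(energies, dec)
  wz <- window_average(z, window_bp)
  sites <- call_sites(wz, threshold = z_threshold, offset = offset)
  structure(
    list(contig = contig, offset = offset, w = prof$w, strand = prof$strand,
         energies = as.numeric(energies), z = z, windowed_z = wz,
         window_bp = window_bp, threshold = z_threshold, sites = sites,
         decoy_mean = mean(dec), decoy_sd = stats::sd(dec),
         n_decoys = n_decoys, seed = seed),
    class = "genome_scan_track"
  )
}

#' @export
print.genome_scan_track <- function(x, ...) {
  cat("Genome scan track [", x$contig, "], ", length(x$z), " positions, w = ",
      x$w, " bp\n", sep = "")
  cat("  window ", x$window_bp, " bp, threshold ", x$threshold, ", ",
      nrow(x$sites), " called site(s)\n", sep = "")
  invisible(x)
}

#' Read a genome (FASTA) or peak intervals (BED/narrowPeak)
#'
#' `read_genome_fasta` returns a named character vector of sequences.
#' `read_peaks` accepts 3+-column BED and 10-column narrowPeak dialects and
#' returns a `data.frame` with `contig` and 0-based half-open `start`/`end`.
#'
#' @param file Input path.
#' @export
read_genome_fasta <- function(file) {
  set <- Biostrings::readDNAStringSet(file)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_genome_fasta
#' @export
read_peaks <- function(file) {
  first <- utils::read.table(file, sep = "\t", nrows = 1, stringsAsFactors = FALSE)
  gr <- if (ncol(first) >= 10L) {
    rtracklayer::import(file, format = "BED",
                        extraCols = c(signalValue = "numeric", pValue = "numeric",
                                      qValue = "numeric", peak = "integer"))
  } else {
    rtracklayer::import(file, format = "BED")
  }
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Export a scan track as bedGraph and its called sites as BED
#'
#' @param track A [scan_genome()] result.
#' @param file Output path.
#' @param which `"windowed_z"` (default), `"z"`, or `"energies"`.
#' @export
write_bedgraph <- function(track, file, which = c("windowed_z", "z", "energies")) {
  which <- match.arg(which)
  vals <- track[[which]]
  keep <- !is.na(vals)
  gr <- GenomicRanges::GRanges(
    seqnames = track$contig,
    ranges = IRanges::IRanges(start = which(keep) + track$offset, width = 1L),
    score = vals[keep]
  )
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname write_bedgraph
#' @export
write_sites_bed <- function(track, file) {
  if (nrow(track$sites) == 0L) {
    writeLines(character(0), file)
    return(invisible(file))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = track$contig,
    ranges = IRanges::IRanges(start = track$sites$start + 1L, end = track$sites$end)
  )
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
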