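scan_fixture <- function() {
  cached("scan_fixture", {
    sc <- make_training_scenario(n_protein = 20, n_dna = 8, n_contacts = 20,
                                 seed = 5, n_dna_decoys = 200,
                                 n_protein_decoys = 2000)
    list(sc = sc, model = train_scenario(sc))
  })
}

test_that("scan bookkeeping yields exactly L - w + 1 scores", {
  fx <- scan_fixture()
  set.seed(21)
  g20 <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  e <- scan_energies(fx$model, fx$sc$complex, fx$sc$interface, g20)
  expect_length(e, 20 - attr(e, "w") + 1)

  for (i in 1:10) {
    L <- sample(50:400, 1)
    genome <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    e <- scan_energies(fx$model, fx$sc$complex, fx$sc$interface, genome)
    expect_length(e, L - 8 + 1)
  }
})

test_that("every scan position equals an independent threading computation", {
  fx <- scan_fixture()
  cg <- fx$sc$complex; sel <- fx$sc$interface
  set.seed(22)
  genome <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  e <- scan_energies(fx$model, cg, sel, genome)
  w <- attr(e, "w")
  nat <- ideaEnergy:::dna_letters(cg)
  fwd_rows <- which(cg$dna$strand == "fwd")
  for (i in c(1, 7, 23, 53)) {
    letters <- nat
    letters[fwd_rows] <- strsplit(substr(genome, i, i + w - 1), "")[[1]]
    ref <- predict_energy(fx$model,
                          compute_phi(cg, sel, dna_seq = paste(letters, collapse = "")))
    expect_equal(e[i], ref, tolerance = 1e-9)
  }

  ## windows containing N are flagged missing
  genome_n <- paste0(substr(genome, 1, 10), "N", substr(genome, 12, 60))
  en <- scan_energies(fx$model, cg, sel, genome_n)
  expect_true(all(is.na(en[(11 - w + 1):11])))
  expect_false(anyNA(en[12:(60 - w + 1)]))
})

test_that("Z normalization is anchored to the decoy moments and affine-invariant", {
  dec <- c(1, 2, 3, 4, 5)
  expect_equal(znormalize(mean(dec), dec), 0)
  expect_equal(znormalize(mean(dec) - sd(dec), dec), -1)
  set.seed(23)
  e <- rnorm(50); d <- rnorm(200)
  expect_equal(znormalize(3.7 * e + 2, 3.7 * d + 2), znormalize(e, d),
               tolerance = 1e-10)
  expect_error(znormalize(e, c(1)), "two decoy")
  expect_error(znormalize(e, rep(2, 10)), "zero decoy")
})

test_that("window averaging matches a brute-force per-window mean", {
  expect_equal(window_average(rep(-1, 50), 10), rep(-1, 50))
  ## single spike spreads as spike / window size in the interior
  z <- rep(0, 101); z[51] <- -5
  wz <- window_average(z, 11)
  expect_equal(wz[51], -5 / 11)
  expect_equal(wz[45], 0)

  set.seed(24)
  z <- rnorm(80); z[c(5, 40)] <- NA
  for (W in c(1, 4, 7, 500)) {
    wz <- window_average(z, W)
    half_lo <- (W - 1) %/% 2; half_hi <- W - 1 - half_lo
    ref <- vapply(seq_along(z), function(j) {
      win <- z[max(1, j - half_lo):min(length(z), j + half_hi)]
      mean(win, na.rm = TRUE)
    }, numeric(1))
    expect_equal(wz, ref, tolerance = 1e-12)
  }
})

test_that("site calling emits maximal sub-threshold runs as half-open intervals", {
  expect_equal(nrow(call_sites(rep(0, 10))), 0)
  z <- rep(0, 30); z[11:20] <- -1
  s <- call_sites(z, threshold = -0.75)
  expect_equal(s$start, 10)
  expect_equal(s$end, 20)

  ## alternating pattern equals an independent run-length scan
  set.seed(25)
  z <- rnorm(200, sd = 1)
  s <- call_sites(z, threshold = -0.75)
  below <- z < -0.75
  ref <- list(); run_start <- NA
  for (i in seq_along(below)) {
    if (below[i] && is.na(run_start)) run_start <- i
    if (!below[i] && !is.na(run_start)) {
      ref[[length(ref) + 1]] <- c(run_start - 1, i - 1); run_start <- NA
    }
  }
  if (!is.na(run_start)) ref[[length(ref) + 1]] <- c(run_start - 1, length(below))
  ref <- do.call(rbind, ref)
  expect_equal(as.matrix(s), ref, ignore_attr = TRUE)

  ## a stricter threshold calls a subset of positions
  s_strict <- call_sites(z, threshold = -1.5)
  pos <- function(df) unlist(mapply(seq, df$start, df$end - 1, SIMPLIFY = FALSE))
  expect_true(all(pos(s_strict) %in% pos(s)))
})

test_that("peak evaluation scores containment-labeled positions by negative Z", {
  ## all peak windows strictly lower than background: perfect AUC
  z <- rep(1, 100); z[c(10, 50)] <- -2
  peaks <- data.frame(start = c(9, 49), end = c(9 + 5, 49 + 5))
  expect_equal(evaluate_vs_peaks(z, peaks, w = 5, offset = 0), 1)

  ## shuffled labels are chance level
  set.seed(26)
  z <- rnorm(4000)
  peaks <- data.frame(start = seq(0, 3900, by = 100), end = seq(5, 3905, by = 100))
  expect_lt(abs(evaluate_vs_peaks(z, peaks, w = 5) - 0.5), 0.05)

  expect_error(evaluate_vs_peaks(rep(0, 10), data.frame(start = 0, end = 20), w = 5),
               "nonempty")
})

test_that("a planted strongest motif is the global energy minimum of the scan", {
  fx <- scan_fixture()
  ## scanning with the planted model itself: its strongest k-mer must be the
  ## global minimum wherever it was inserted
  mot <- strongest_kmer(fx$sc$gamma_star, fx$sc$complex, fx$sc$interface)
  gen <- make_synthetic_genome(5000, mot$motif, 5, seed = 27)
  tr <- scan_genome(fx$sc$gamma_star, fx$sc$complex, fx$sc$interface, gen$genome,
                    window_bp = 1, n_decoys = 500, seed = 28)
  expect_equal(sort(unique(tr$z[gen$truth$start + 1])),
               min(tr$z, na.rm = TRUE))
  ## called intervals all sit below threshold
  for (k in seq_len(nrow(tr$sites))) {
    expect_true(all(tr$windowed_z[(tr$sites$start[k] + 1):tr$sites$end[k]] < tr$threshold))
  }
})

test_that("Z tracks are invariant under positive rescaling of the model", {
  fx <- scan_fixture()
  set.seed(29)
  genome <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  t1 <- scan_genome(fx$model, fx$sc$complex, fx$sc$interface, genome,
                    window_bp = 25, n_decoys = 300, seed = 30)
  m2 <- energy_model(5 * fx$model$gamma, provenance = fx$model$provenance)
  t2 <- scan_genome(m2, fx$sc$complex, fx$sc$interface, genome,
                    window_bp = 25, n_decoys = 300, seed = 30)
  expect_equal(t1$z, t2$z, tolerance = 1e-9)
  expect_equal(t1$sites, t2$sites)
})

test_that("tracks and intervals survive BED/bedGraph round trips", {
  fx <- scan_fixture()
  set.seed(31)
  genome <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  tr <- scan_genome(fx$model, fx$sc$complex, fx$sc$interface, genome,
                    contig = "chrT", window_bp = 5, n_decoys = 200, seed = 32)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, bg)
  back <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(back$score, tr$windowed_z[!is.na(tr$windowed_z)], tolerance = 1e-4)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(tr, bed)
  if (nrow(tr$sites) > 0) {
    pk <- read_peaks(bed)
    expect_equal(pk$start, tr$sites$start)
    expect_equal(pk$end, tr$sites$end)
  }

  ## narrowPeak dialect (10 columns) reads through the same entry point
  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chrT\t10\t60\tpeak1\t0\t.\t5.5\t-1\t-1\t25",
               "chrT\t100\t140\tpeak2\t0\t.\t3.2\t-1\t-1\t20"), np)
  pk <- read_peaks(np)
  expect_equal(pk$start, c(10, 100))
  expect_equal(pk$end, c(60, 140))

  ## FASTA round trip for synthetic genomes
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(genome, fa, name = "chrT")
  expect_equal(unname(read_genome_fasta(fa)), genome)
})
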