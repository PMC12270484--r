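test_that("a minimal PDB record parses to one bead per residue", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ARG A   3       7.000   0.000   0.000  1.00  0.00           C",
    "ATOM      5  P    DA B   1       2.000   5.000   0.000  1.00  0.00           P",
    "ATOM      6  C5   DA B   1       2.000   3.000   0.000  1.00  0.00           C",
    "ATOM      7  P    DC B   2       5.000   5.000   0.000  1.00  0.00           P",
    "ATOM      8  C5   DC B   2       5.000   3.000   0.000  1.00  0.00           C",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  cg <- parse_complex(f)
  expect_equal(nrow(cg$protein), 3L)
  expect_equal(cg$protein$type, c("A", "G", "R"))
  expect_equal(nrow(cg$dna), 2L)
  expect_equal(cg$dna$type, c("DA", "DC"))
  expect_true(is.na(cg$rep_kind))

  ## residue lacking a C-alpha is skipped with a warning (ALA keeps its N)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-2], f2)
  expect_warning(cg2 <- parse_complex(f2), "C-alpha")
  expect_equal(nrow(cg2$protein), 2L)
  expect_equal(cg2$protein$type, c("G", "R"))

  ## missing molecules are hard errors
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines[1:4], "END"), f3)
  expect_error(parse_complex(f3), "no DNA")
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines[5:8], "END"), f4)
  expect_error(parse_complex(f4), "no protein")
})

test_that("a duplex fixture parses with counts matching an independent text scan", {
  ## protein chain + two DNA strands, written through the package, then
  ## re-counted by an independent line-level scan of the file
  toy <- make_toy_complex(n_protein = 12, n_dna = 6, n_contacts = 10,
                          seed = 3, two_strands = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(toy$complex, f)
  txt <- readLines(f)
  atom <- txt[startsWith(txt, "ATOM")]
  resname <- trimws(substr(atom, 18, 20))
  chain_res <- paste(substr(atom, 22, 22), trimws(substr(atom, 23, 26)))
  is_ca <- trimws(substr(atom, 13, 16)) == "CA"
  expected_protein <- length(unique(chain_res[is_ca]))
  expected_dna <- length(unique(chain_res[resname %in% c("DA", "DT", "DC", "DG")]))
  cg <- parse_complex(f)
  expect_equal(nrow(cg$protein), expected_protein)
  expect_equal(nrow(cg$dna), expected_dna)
  expect_setequal(unique(cg$dna$strand), c("fwd", "rev"))
})

test_that("representative-atom selection follows the triple-cutoff count", {
  ## forced geometry: C5 near, P far
  near_c5 <- random_complex(5, 4, seed = 1)
  near_c5$dna[, c("x_c5", "y_c5", "z_c5")] <- near_c5$protein[1:4, c("x", "y", "z")] + 2
  near_c5$dna[, c("x_p", "y_p", "z_p")] <- 1000
  expect_equal(select_dna_representative(near_c5)$rep_kind, "C5")

  ## mirrored: P near, C5 far
  near_p <- random_complex(5, 4, seed = 2)
  near_p$dna[, c("x_p", "y_p", "z_p")] <- near_p$protein[1:4, c("x", "y", "z")] + 2
  near_p$dna[, c("x_c5", "y_c5", "z_c5")] <- 1000
  expect_equal(select_dna_representative(near_p)$rep_kind, "P")

  ## random geometry agrees with a brute-force triple-cutoff pair count
  for (seed in 1:5) {
    cg <- random_complex(15, 10, seed = seed, box = 18)
    count <- function(cols) {
      total <- 0
      for (i in seq_len(nrow(cg$dna))) for (j in seq_len(nrow(cg$protein))) {
        d <- dist3(as.numeric(cg$dna[i, cols]),
                   as.numeric(cg$protein[j, c("x", "y", "z")]))
        total <- total + (d <= 8) + (d <= 9) + (d <= 10)
      }
      total
    }
    n_c5 <- count(c("x_c5", "y_c5", "z_c5"))
    n_p <- count(c("x_p", "y_p", "z_p"))
    expected <- if (n_c5 >= n_p) "C5" else "P"
    got <- suppressMessages(select_dna_representative(cg))
    expect_equal(got$rep_kind, expected)
  }
})

test_that("representative selection is invariant under rigid-body motion", {
  cg <- random_complex(15, 10, seed = 9, box = 18)
  k1 <- suppressMessages(select_dna_representative(cg))$rep_kind
  k2 <- suppressMessages(select_dna_representative(rigid_transform(cg)))$rep_kind
  expect_equal(k1, k2)
})

test_that("interface extraction matches an all-pairs scan and nests by cutoff", {
  ## boundary behaviour at the hard cutoff
  close_pair <- two_bead_complex(d = 7.9)
  sel <- extract_interface(close_pair, cutoff = 8)
  expect_equal(sel$protein_idx, 1L)
  expect_equal(sel$dna_idx, 1L)
  far_pair <- two_bead_complex(d = 8.1)
  expect_warning(sel2 <- extract_interface(far_pair, cutoff = 8), "empty")
  expect_length(sel2$protein_idx, 0L)
  expect_length(sel2$dna_idx, 0L)

  ## random 50-bead fixture vs an independent O(n^2) membership scan
  cg <- suppressMessages(select_dna_representative(
    random_complex(30, 20, seed = 4, box = 22)))
  sel <- extract_interface(cg, cutoff = 8)
  prot_in <- logical(30); dna_in <- logical(20)
  for (i in 1:30) for (j in 1:20) {
    d <- dist3(as.numeric(cg$protein[i, c("x", "y", "z")]),
               as.numeric(cg$dna[j, c("x", "y", "z")]))
    if (d <= 8) { prot_in[i] <- TRUE; dna_in[j] <- TRUE }
  }
  expect_equal(sel$protein_idx, which(prot_in))
  expect_equal(sel$dna_idx, which(dna_in))

  ## nesting: smaller cutoff selects a subset
  sel6 <- extract_interface(cg, cutoff = 6)
  expect_true(all(sel6$protein_idx %in% sel$protein_idx))
  expect_true(all(sel6$dna_idx %in% sel$dna_idx))
})

test_that("coarse-grained TSV round trip preserves beads", {
  toy <- make_toy_complex(n_protein = 10, n_dna = 6, n_contacts = 8, seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cg_tsv(toy$complex, f)
  back <- read_cg_tsv(f)
  expect_equal(back$protein$type, toy$complex$protein$type)
  expect_equal(back$protein$x, toy$complex$protein$x)
  expect_equal(back$dna$type, toy$complex$dna$type)
  expect_equal(back$dna$x_c5, toy$complex$dna$x_c5)
  expect_equal(back$dna$y_p, toy$complex$dna$y_p)
  ## resolving the rep kind again reproduces identical representative coords
  back <- suppressMessages(select_dna_representative(back))
  expect_equal(back$rep_kind, toy$complex$rep_kind)
  expect_equal(back$dna$x, toy$complex$dna$x)
})

test_that("modified residues map through the residue table", {
  lines <- c(
    "ATOM      1  CA  MSE A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       4.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C5  5CM B   1       2.000   3.000   0.000  1.00  0.00           C",
    "ATOM      4  P   5CM B   1       2.000   5.000   0.000  1.00  0.00           P",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  w <- capture_warnings(cg <- parse_complex(f))
  expect_true(all(grepl("modified residue", w)))
  expect_length(w, 2)
  expect_equal(cg$protein$type, c("M", "A"))
  expect_equal(cg$dna$type, "DC")

  ## unknown residue without a mapping is an error
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(sub("ALA", "XYZ", lines), f2)
  expect_error(suppressWarnings(parse_complex(f2)), "unknown residue")
})
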