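## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## small planted scenario for unit tests (reduced decoy counts)
small_scenario <- function() {
  cached("small_scenario", {
    make_training_scenario(n_protein = 30, n_dna = 16, n_contacts = 40,
                           seed = 7, n_dna_decoys = 200, n_protein_decoys = 2000)
  })
}

## hand-built two-bead complex: one protein bead, one DNA bead, at distance d
two_bead_complex <- function(d = 8, aa = "R", nt = "DC") {
  protein <- data.frame(chain = "A", resid = "1", type = aa,
                        x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  dna <- data.frame(chain = "B", strand = "fwd", idx = 1L, type = nt,
                    x_c5 = d, y_c5 = 0, z_c5 = 0,
                    x_p = d, y_p = -5, z_p = 0,
                    x = d, y = 0, z = 0, stringsAsFactors = FALSE)
  cg <- cg_complex(protein, dna, rep_kind = "C5", source = "two-bead")
  cg
}

## random geometry complex for oracle tests: beads scattered in a box
random_complex <- function(n_protein, n_dna, seed, box = 25) {
  set.seed(seed)
  protein <- data.frame(
    chain = "A", resid = as.character(seq_len(n_protein)),
    type = sample(aa_alphabet(), n_protein, replace = TRUE),
    x = runif(n_protein, 0, box), y = runif(n_protein, 0, box),
    z = runif(n_protein, 0, box), stringsAsFactors = FALSE
  )
  dna <- data.frame(
    chain = "B", strand = "fwd", idx = seq_len(n_dna),
    type = sample(nt_alphabet(), n_dna, replace = TRUE),
    x_c5 = runif(n_dna, 0, box), y_c5 = runif(n_dna, 0, box),
    z_c5 = runif(n_dna, 0, box),
    x_p = runif(n_dna, 0, box), y_p = runif(n_dna, 0, box),
    z_p = runif(n_dna, 0, box),
    x = NA_real_, y = NA_real_, z = NA_real_, stringsAsFactors = FALSE
  )
  cg_complex(protein, dna, source = paste0("random-", seed))
}

## independent brute-force pairwise distance
dist3 <- function(p, q) sqrt(sum((p - q)^2))

rigid_transform <- function(cg, angle = 0.7, shift = c(5, -3, 11)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), nrow = 3, byrow = TRUE)
  tx <- function(m) sweep(as.matrix(m) %*% t(R), 2, -shift)
  p <- tx(cg$protein[, c("x", "y", "z")])
  cg$protein$x <- p[, 1]; cg$protein$y <- p[, 2]; cg$protein$z <- p[, 3]
  for (cols in list(c("x_c5", "y_c5", "z_c5"), c("x_p", "y_p", "z_p"),
                    c("x", "y", "z"))) {
    if (all(!is.na(cg$dna[[cols[1]]]))) {
      d <- tx(cg$dna[, cols])
      cg$dna[[cols[1]]] <- d[, 1]; cg$dna[[cols[2]]] <- d[, 2]
      cg$dna[[cols[3]]] <- d[, 3]
    }
  }
  cg
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
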