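## structio: parse protein-DNA complexes into a one-bead-per-residue
## representation, resolve the DNA representative atom (C5 vs P), and extract
## the binding interface.

#' Coarse-grained protein-DNA complex
#'
#' Constructor for the one-bead-per-residue representation used throughout
#' the package: one bead per amino acid at the C-alpha position, one bead per
#' nucleotide at either the base C5 atom or the backbone P atom. Both DNA
#' candidate atoms are retained until [select_dna_representative()] resolves
#' the representative kind.
#'
#' @param protein `data.frame` with columns `chain`, `resid`, `type`
#'   (one-letter amino acid), `x`, `y`, `z`.
#' @param dna `data.frame` with columns `chain`, `strand` (`"fwd"`/`"rev"`),
#'   `idx` (1-based 5' to 3' per strand), `type` (`DA`/`DT`/`DC`/`DG`),
#'   candidate coordinates `x_c5`..`z_c5`, `x_p`..`z_p`, and resolved
#'   representative coordinates `x`, `y`, `z` (may be `NA` until resolved).
#' @param rep_kind `"C5"`, `"P"`, or `NA` while unresolved.
#' @param source Free-text identifier (e.g. a PDB accession).
#' @return An object of class `cg_complex`.
#' @export
cg_complex <- function(protein, dna, rep_kind = NA_character_, source = "") {
  stopifnot(is.data.frame(protein), is.data.frame(dna))
  if (!all(protein$type %in% aa_alphabet())) {
    stop("protein bead types outside the 20-letter alphabet")
  }
  if (!all(dna$type %in% nt_alphabet())) {
    stop("DNA bead types outside {DA, DT, DC, DG}")
  }
  if (!all(dna$strand %in% c("fwd", "rev"))) stop("strand labels must be fwd/rev")
  obj <- structure(
    list(protein = protein, dna = dna, rep_kind = rep_kind, source = source),
    class = "cg_complex"
  )
  obj
}

#' @export
print.cg_complex <- function(x, ...) {
  cat("Coarse-grained protein-DNA complex", if (nzchar(x$source)) paste0("[", x$source, "]"), "\n")
  cat("  protein beads:", nrow(x$protein), "(chains:",
      paste(unique(x$protein$chain), collapse = ","), ")\n")
  cat("  DNA beads:    ", nrow(x$dna), "(strands:",
      paste(unique(x$dna$strand), collapse = ","), ")\n")
  cat("  representative DNA atom:", ifelse(is.na(x$rep_kind), "<unresolved>", x$rep_kind), "\n")
  invisible(x)
}

## Euclidean cross-distance matrix between two coordinate data frames/matrices
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

protein_xyz <- function(cg) as.matrix(cg$protein[, c("x", "y", "z")])

dna_xyz <- function(cg) {
  if (is.na(cg$rep_kind)) stop("DNA representative atom not resolved; call select_dna_representative() first")
  as.matrix(cg$dna[, c("x", "y", "z")])
}

#' Parse a protein-DNA complex structure into coarse-grained beads
#'
#' Reads a PDB or mmCIF file (via \pkg{bio3d}) and reduces it to residue-level
#' beads: one bead per amino acid at the C-alpha atom, and one bead per
#' nucleotide carrying both candidate representative atoms (base C5 and
#' backbone P). Hetero/water records are ignored; modified residues are
#' resolved through `residue_map` (with a warning); the first alternate
#' location is used. Residues lacking the required atom are skipped with a
#' warning.
#'
#' @param file Path to a `.pdb` or `.cif` file, or a `bio3d` structure object.
#' @param residue_map Named character vector extending the built-in map of
#'   modified residue names to canonical ones (e.g. `c("5CM" = "DC")`).
#' @param source Identifier stored on the result; defaults to the file name.
#' @return A [cg_complex()] with unresolved representative kind.
#' @export
parse_complex <- function(file, residue_map = character(), source = NULL) {
  if (inherits(file, "pdb")) {
    pdb <- file
    if (is.null(source)) source <- "structure"
  } else {
    stopifnot(is.character(file), length(file) == 1L, file.exists(file))
    pdb <- if (grepl("\\.cif$", file, ignore.case = TRUE)) {
      bio3d::read.cif(file, verbose = FALSE)
    } else {
      bio3d::read.pdb(file, verbose = FALSE)
    }
    if (is.null(source)) source <- basename(file)
  }
  at <- pdb$atom
  rmap <- c(residue_map, default_residue_map)
  rmap <- rmap[!duplicated(names(rmap))]

  ## first alternate location only
  if (!is.null(at$alt)) {
    keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
    at <- at[keep_alt, , drop = FALSE]
  }

  ## resolve modified residue names; warn once per name
  mapped <- at$resid %in% names(rmap)
  if (any(mapped)) {
    for (nm in unique(at$resid[mapped])) {
      warning("mapping modified residue ", nm, " -> ", rmap[[nm]], call. = FALSE)
    }
    at$resid[mapped] <- unname(rmap[at$resid[mapped]])
  }

  is_aa <- at$resid %in% names(aa_three_to_one)
  is_nt <- at$resid %in% nt_alphabet()
  is_het <- at$type == "HETATM"
  unknown <- !is_aa & !is_nt & !is_het
  if (any(unknown)) {
    stop("unknown residue name(s): ",
         paste(unique(at$resid[unknown]), collapse = ", "),
         "; supply residue_map to resolve them")
  }
  at <- at[is_aa | is_nt, , drop = FALSE]  # drops unmapped hetero/water records

  ## residue key preserves insertion codes
  ins <- if (is.null(at$insert)) "" else ifelse(is.na(at$insert), "", at$insert)
  at$reskey <- paste(at$chain, at$resno, ins, sep = "|")

  aa_at <- at[at$resid %in% names(aa_three_to_one), , drop = FALSE]
  nt_at <- at[at$resid %in% nt_alphabet(), , drop = FALSE]
  if (nrow(aa_at) == 0L) stop("no protein")
  if (nrow(nt_at) == 0L) stop("no DNA")

  ## --- protein beads: one per residue with a CA atom ---
  keys <- unique(aa_at$reskey)
  ca <- aa_at[aa_at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$reskey), , drop = FALSE]
  missing_ca <- setdiff(keys, ca$reskey)
  if (length(missing_ca) > 0L) {
    warning("skipping ", length(missing_ca),
            " protein residue(s) lacking a C-alpha atom", call. = FALSE)
  }
  ca <- ca[match(intersect(keys, ca$reskey), ca$reskey), , drop = FALSE]
  protein <- data.frame(
    chain = ca$chain,
    resid = sub("^[^|]*\\|", "", ca$reskey),
    type = unname(aa_three_to_one[ca$resid]),
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )

  ## --- DNA beads: both candidate atoms kept ---
  dna_chains <- unique(nt_at$chain)
  if (length(dna_chains) > 2L) {
    stop("more than two DNA chains; only single- or double-stranded DNA is supported")
  }
  nt_keys <- unique(nt_at$reskey)
  c5 <- nt_at[nt_at$elety == "C5", , drop = FALSE]
  c5 <- c5[!duplicated(c5$reskey), , drop = FALSE]
  pp <- nt_at[nt_at$elety == "P", , drop = FALSE]
  pp <- pp[!duplicated(pp$reskey), , drop = FALSE]
  have_any <- nt_keys %in% c5$reskey | nt_keys %in% pp$reskey
  if (any(!have_any)) {
    warning("skipping ", sum(!have_any),
            " nucleotide(s) lacking both C5 and P atoms", call. = FALSE)
  }
  nt_keys <- nt_keys[have_any]
  first_of <- nt_at[!duplicated(nt_at$reskey), , drop = FALSE]
  first_of <- first_of[match(nt_keys, first_of$reskey), , drop = FALSE]
  pick <- function(tab, keys, col) tab[[col]][match(keys, tab$reskey)]
  dna <- data.frame(
    chain = first_of$chain,
    strand = ifelse(first_of$chain == dna_chains[1], "fwd", "rev"),
    idx = NA_integer_,
    type = first_of$resid,
    x_c5 = pick(c5, nt_keys, "x"), y_c5 = pick(c5, nt_keys, "y"), z_c5 = pick(c5, nt_keys, "z"),
    x_p = pick(pp, nt_keys, "x"), y_p = pick(pp, nt_keys, "y"), z_p = pick(pp, nt_keys, "z"),
    x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE
  )
  for (s in unique(dna$strand)) {
    dna$idx[dna$strand == s] <- seq_len(sum(dna$strand == s))
  }
  cg_complex(protein, dna, rep_kind = NA_character_, source = source)
}

#' Choose the DNA representative atom kind (C5 vs P)
#'
#' For each candidate atom kind, counts DNA-atom/C-alpha pairs at distance
#' no greater than 8, 9, and 10 Angstrom and sums the three counts; the kind
#' with the larger sum becomes the representative, on the hypothesis that DNA
#' atoms closer to the protein carry more information about the interaction.
#' Ties prefer C5 (base-proximal atoms carry base identity) and are logged.
#'
#' @param cg A [cg_complex()] with both candidate atom sets populated.
#' @return The input complex with `rep_kind` set and the resolved
#'   representative coordinates written into `x`, `y`, `z`; nucleotides
#'   lacking the chosen atom are dropped with a warning. The chosen kind is
#'   available as `$rep_kind`.
#' @export
select_dna_representative <- function(cg) {
  stopifnot(inherits(cg, "cg_complex"))
  ca <- protein_xyz(cg)
  count_kind <- function(cols) {
    xyz <- as.matrix(cg$dna[, cols])
    xyz <- xyz[stats::complete.cases(xyz), , drop = FALSE]
    if (nrow(xyz) == 0L) return(NA_real_)
    d <- cross_dist(xyz, ca)
    sum(d <= 8) + sum(d <= 9) + sum(d <= 10)
  }
  n_c5 <- count_kind(c("x_c5", "y_c5", "z_c5"))
  n_p <- count_kind(c("x_p", "y_p", "z_p"))
  if (is.na(n_c5) && is.na(n_p)) stop("no candidate DNA representative atoms present")
  kind <- if (is.na(n_p)) "C5"
  else if (is.na(n_c5)) "P"
  else if (n_c5 > n_p) "C5"
  else if (n_p > n_c5) "P"
  else {
    message("C5/P occurrence sums tied (", n_c5, "); preferring C5")
    "C5"
  }
  cols <- if (kind == "C5") c("x_c5", "y_c5", "z_c5") else c("x_p", "y_p", "z_p")
  have <- stats::complete.cases(cg$dna[, cols])
  if (any(!have)) {
    warning("dropping ", sum(!have), " nucleotide(s) lacking the ", kind,
            " representative atom", call. = FALSE)
  }
  dna <- cg$dna[have, , drop = FALSE]
  dna$x <- dna[[cols[1]]]; dna$y <- dna[[cols[2]]]; dna$z <- dna[[cols[3]]]
  for (s in unique(dna$strand)) dna$idx[dna$strand == s] <- seq_len(sum(dna$strand == s))
  cg$dna <- dna
  cg$rep_kind <- kind
  cg
}

#' Extract the protein-DNA binding interface
#'
#' A bead belongs to the interface when its representative atom lies within
#' `cutoff` of at least one representative atom of the other molecule. This
#' hard cutoff defines interface membership; the soft switching weight
#' ([theta()]) is applied on top of all interface pairs when featurizing.
#'
#' @param cg A resolved [cg_complex()].
#' @param cutoff Distance cutoff in Angstrom (default 8).
#' @return An object of class `interface_selection`: a list with integer
#'   vectors `protein_idx`, `dna_idx` (row indices into the complex's bead
#'   tables) and the `cutoff` used.
#' @export
extract_interface <- function(cg, cutoff = 8) {
  stopifnot(inherits(cg, "cg_complex"), cutoff > 0)
  d <- cross_dist(protein_xyz(cg), dna_xyz(cg))
  protein_idx <- which(apply(d <= cutoff, 1, any))
  dna_idx <- which(apply(d <= cutoff, 2, any))
  if (length(protein_idx) == 0L) {
    warning("empty protein-DNA interface at cutoff ", cutoff, " Angstrom", call. = FALSE)
  }
  structure(
    list(protein_idx = as.integer(protein_idx), dna_idx = as.integer(dna_idx),
         cutoff = cutoff),
    class = "interface_selection"
  )
}

#' @export
print.interface_selection <- function(x, ...) {
  cat("Interface selection (cutoff ", x$cutoff, " A): ",
      length(x$protein_idx), " protein beads, ",
      length(x$dna_idx), " DNA beads\n", sep = "")
  invisible(x)
}

#' Write / read a coarse-grained complex as TSV
#'
#' One row per bead per available atom kind (`CA` for protein; `C5` and `P`
#' rows for DNA), columns `molecule`, `chain`, `strand`, `index`, `type`,
#' `atom_kind`, `x`, `y`, `z`. The round trip is lossless for bead
#' identities and coordinates.
#'
#' @param cg A [cg_complex()].
#' @param file Path of the TSV to write or read.
#' @return `write_cg_tsv` returns `file` invisibly; `read_cg_tsv` returns a
#'   [cg_complex()] (unresolved representative kind).
#' @export
write_cg_tsv <- function(cg, file) {
  stopifnot(inherits(cg, "cg_complex"))
  prot <- data.frame(
    molecule = "protein", chain = cg$protein$chain, strand = NA_character_,
    index = seq_len(nrow(cg$protein)), type = cg$protein$type, atom_kind = "CA",
    x = cg$protein$x, y = cg$protein$y, z = cg$protein$z
  )
  rows <- list(prot)
  for (kind in c("C5", "P")) {
    cols <- if (kind == "C5") c("x_c5", "y_c5", "z_c5") else c("x_p", "y_p", "z_p")
    have <- stats::complete.cases(cg$dna[, cols])
    if (any(have)) {
      d <- cg$dna[have, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        molecule = "dna", chain = d$chain, strand = d$strand, index = d$idx,
        type = d$type, atom_kind = kind,
        x = d[[cols[1]]], y = d[[cols[2]]], z = d[[cols[3]]]
      )
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cg_tsv
#' @param source Identifier stored on the complex read back.
#' @export
read_cg_tsv <- function(file, source = basename(file)) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  prot <- tab[tab$molecule == "protein", , drop = FALSE]
  protein <- data.frame(
    chain = prot$chain, resid = as.character(prot$index), type = prot$type,
    x = prot$x, y = prot$y, z = prot$z, stringsAsFactors = FALSE
  )
  dn <- tab[tab$molecule == "dna", , drop = FALSE]
  key <- paste(dn$chain, dn$strand, dn$index)
  ukey <- unique(key)
  take <- function(kind, col) {
    rows <- dn[dn$atom_kind == kind, , drop = FALSE]
    rows[[col]][match(ukey, paste(rows$chain, rows$strand, rows$index))]
  }
  first <- dn[match(ukey, key), , drop = FALSE]
  dna <- data.frame(
    chain = first$chain, strand = first$strand, idx = first$index, type = first$type,
    x_c5 = take("C5", "x"), y_c5 = take("C5", "y"), z_c5 = take("C5", "z"),
    x_p = take("P", "x"), y_p = take("P", "y"), z_p = take("P", "z"),
    x = NA_real_, y = NA_real_, z = NA_real_, stringsAsFactors = FALSE
  )
  ord <- order(match(dna$strand, c("fwd", "rev")), dna$idx)
  cg_complex(protein, dna[ord, , drop = FALSE], source = source)
}

## native sequence of one DNA strand, 5'->3', as a single-letter string
strand_sequence <- function(cg, strand) {
  d <- cg$dna[cg$dna$strand == strand, , drop = FALSE]
  d <- d[order(d$idx), , drop = FALSE]
  paste(nt_letters()[match(d$type, nt_alphabet())], collapse = "")
}

## native protein sequence over beads, in bead order
protein_sequence <- function(cg) paste(cg$protein$type, collapse = "")
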