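#' @keywords internal
"_PACKAGE"

## Closed alphabets. Amino acids use the 20 canonical one-letter codes in
## alphabetical order; nucleotides use PDB deoxyribonucleotide residue names.
## Row/column order here fixes the flattening of the 20x4 feature space
## everywhere in the package (gamma, phi, TSV serialization).

#' Amino-acid and nucleotide alphabets
#'
#' Closed alphabets used throughout: 20 one-letter amino-acid codes and the
#' four deoxyribonucleotide residue names (`DA`, `DT`, `DC`, `DG`).
#' Their order fixes the row/column layout of every feature vector and
#' energy matrix in the package.
#'
#' @return A character vector.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
nt_alphabet <- function() c("DA", "DT", "DC", "DG")

## single-letter view of the nucleotide alphabet, same order
nt_letters <- function() c("A", "T", "C", "G")

## 3-letter -> 1-letter protein residue map (canonical 20)
aa_three_to_one <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

## default map for modified residues; user-extensible via the `residue_map`
## argument of parse_complex(). 5-methyl-cytosine and friends fold onto their
## parent base; MSE (selenomethionine) is by far the most common protein case.
default_residue_map <- c(
  `5CM` = "DC", `5MC` = "DC", `6MA` = "DA", DU = "DT", BRU = "DT",
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR"
)

complement_map <- c(A = "T", T = "A", C = "G", G = "C")

#' Reverse complement of a DNA string
#'
#' @param x A character string over `A`, `C`, `G`, `T` (and `N`).
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## split a sequence string into a character vector of letters
seq_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}

## map single nucleotide letters to indices in nt_alphabet() order
nt_index <- function(letters) {
  idx <- match(toupper(letters), nt_letters())
  if (anyNA(idx)) {
    bad <- unique(letters[is.na(idx)])
    stop("unknown nucleotide letter(s): ", paste(bad, collapse = ", "))
  }
  idx
}

aa_index <- function(letters) {
  idx <- match(toupper(letters), aa_alphabet())
  if (anyNA(idx)) {
    bad <- unique(letters[is.na(idx)])
    stop("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  idx
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards. All stochastic operations in the package go
## through this so a recorded seed reproduces outputs bit-identically.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
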