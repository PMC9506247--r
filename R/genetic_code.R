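#' Genetic code tables
#'
#' Returns a genetic code as used throughout the package: a named list with
#' the 64-entry codon to amino-acid map (DNA codons, stops as `"*"`) and the
#' NCBI translation-table id. The default is table 5, the invertebrate
#' mitochondrial code, under which AGA/AGG encode Ser, ATA encodes Met and
#' TGA encodes Trp.
#'
#' @param table_id NCBI translation table id (integer or string); default 5.
#' @return An object of class `genetic_code`: list with elements `table_id`
#'   and `codons` (named character vector of length 64, names are DNA
#'   codons, values one-letter amino acids with `"*"` for stop).
#' @examples
#' gc5 <- genetic_code()
#' gc5$codons[c("AGA", "ATA", "TGA")]  # S, M, W
#' @export
genetic_code <- function(table_id = 5) {
  codons <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(codons) == 64L)
  structure(list(table_id = as.integer(table_id), codons = codons),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code, NCBI translation table", x$table_id, "\n")
  stops <- names(x$codons)[x$codons == "*"]
  cat("  stop codons:", paste(stops, collapse = ", "), "\n")
  invisible(x)
}

# Translate one DNA codon (character scalar); NA for codons containing
# non-ACGT characters.
translate_codon <- function(codon, code) {
  aa <- unname(code$codons[codon])
  if (is.na(aa)) NA_character_ else aa
}

# Synonymous-family sizes keyed by amino acid (stops excluded).
family_sizes <- function(code) {
  aa <- code$codons[code$codons != "*"]
  table(aa)
}

#' Fold-degeneracy classification of codon positions
#'
#' For every codon and codon position, counts how many of the 3 possible
#' single-nucleotide substitutions preserve the encoded amino acid
#' (substitutions creating stop codons count as non-preserving) and assigns
#' the position to a degeneracy class: 0-fold if none preserve, 4-fold if
#' all three do, 2-fold otherwise (classical 2- and 3-fold sites pooled).
#' Stop codons themselves get `NA` classes.
#'
#' @param code a [genetic_code()].
#' @return A 64 x 3 integer matrix (rownames = DNA codons, values in
#'   `c(0, 2, 4)`, `NA` for stop codons).
#' @examples
#' deg <- fold_degeneracy(genetic_code())
#' deg["CTA", ]  # Leu: positions 1 and 3 are not 0-fold
#' @export
fold_degeneracy <- function(code = genetic_code()) {
  bases <- c("A", "C", "G", "T")
  cods <- names(code$codons)
  out <- matrix(NA_integer_, nrow = 64L, ncol = 3L,
                dimnames = list(cods, paste0("pos", 1:3)))
  for (cd in cods) {
    aa <- code$codons[[cd]]
    if (aa == "*") next
    spl <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      s <- 0L
      for (b in setdiff(bases, spl[pos])) {
        mut <- spl
        mut[pos] <- b
        if (code$codons[[paste(mut, collapse = "")]] == aa) s <- s + 1L
      }
      out[cd, pos] <- if (s == 0L) 0L else if (s == 3L) 4L else 2L
    }
  }
  out
}

# --- shared low-level sequence helpers ---------------------------------

# Reverse complement of a plain character DNA string (ACGTN + IUPAC).
revcomp <- function(seq) {
  comp <- chartr("ACGTUNRYKMSWBDHV", "TGCAANYRMKSWVHDB", toupper(seq))
  vapply(comp, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# RNA -> DNA codon notation and back (tables in the field print U).
dna_codon <- function(x) chartr("Uu", "Tt", x)
rna_codon <- function(x) chartr("Tt", "Uu", x)

# Split a string into a character vector of single bases.
seq_chars <- function(seq) strsplit(toupper(seq), "")[[1]]
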