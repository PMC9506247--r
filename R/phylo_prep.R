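# Conventional concatenation order of the 13 PCGs for PCG123 matrices.
pcg123_order <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                  "nad5", "nad4", "nad4l", "nad6", "cytb", "nad1")

#' Concatenate per-gene alignments into a supermatrix
#'
#' Builds the PCG123-style concatenated matrix: genes are joined in the
#' conventional order (nad2, cox1, cox2, atp8, atp6, cox3, nad3, nad5,
#' nad4, nad4l, nad6, cytb, nad1; genes outside this roster follow in
#' input order), taxa sorted lexicographically, with per-gene and
#' per-codon-position partitions recorded in 1-based inclusive coordinates
#' for interchange formats. Every gene must cover every taxon unless
#' `gap_fill` is set, in which case missing rows are filled with gaps.
#'
#' @param alignments named list of codon-aligned [gene_alignment()]s
#'   (names = gene symbols).
#' @param gap_fill fill missing taxon/gene combinations with `-`?
#' @return List of class `supermatrix`: `taxa`, `rows` (named character
#'   vector), `length`, `partitions` (data.frame `label`, `gene`, `start`,
#'   `end`, `kind` in `c("gene", "codon_position")`, `codon_pos`).
#' @export
concatenate <- function(alignments, gap_fill = FALSE) {
  if (!length(alignments)) stop("no alignments given")
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named list (gene symbols)")
  genes <- c(intersect(pcg123_order, names(alignments)),
             setdiff(names(alignments), pcg123_order))
  taxa <- sort(unique(unlist(lapply(alignments, `[[`, "taxa"))))
  gaps <- list()
  for (g in genes) {
    if (!alignments[[g]]$codon_aligned)
      stop("alignment for ", g, " is not codon-aligned")
    absent <- setdiff(taxa, alignments[[g]]$taxa)
    if (length(absent)) gaps[[g]] <- absent
  }
  if (length(gaps) && !gap_fill)
    stop("missing gene/taxon combinations (set gap_fill = TRUE): ",
         paste(vapply(names(gaps), function(g)
           paste0(g, ": ", paste(gaps[[g]], collapse = ",")), character(1)),
           collapse = "; "))
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  at <- 0L
  for (g in genes) {
    aln <- alignments[[g]]
    w <- aln$length
    for (tx in taxa) {
      piece <- if (tx %in% aln$taxa) aln$rows[[tx]] else strrep("-", w)
      rows[[tx]] <- paste0(rows[[tx]], piece)
    }
    parts[[length(parts) + 1L]] <-
      data.frame(label = g, gene = g, start = at + 1L, end = at + w,
                 kind = "gene", codon_pos = NA_integer_,
                 stringsAsFactors = FALSE)
    for (p in 1:3)
      parts[[length(parts) + 1L]] <-
        data.frame(label = sprintf("%s_pos%d", g, p), gene = g,
                   start = at + p, end = at + w, kind = "codon_position",
                   codon_pos = p, stringsAsFactors = FALSE)
    at <- at + w
  }
  structure(list(taxa = taxa, rows = rows, length = at,
                 partitions = do.call(rbind, parts)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d bp, %d gene partitions\n",
              length(x$taxa), x$length,
              sum(x$partitions$kind == "gene")))
  invisible(x)
}

#' Write a supermatrix
#'
#' @param sm a [concatenate()] supermatrix.
#' @param path output path.
#' @param format `"fasta"` or `"phylip-relaxed"` (relaxed names: taxon id,
#'   two spaces, sequence).
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path, format = c("fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  if (format == "fasta") {
    out <- character(0)
    for (tx in sm$taxa)
      out <- c(out, paste0(">", tx),
               gsub("(.{70})", "\\1\n", sm$rows[[tx]], perl = TRUE))
  } else {
    out <- c(sprintf("%d %d", length(sm$taxa), sm$length),
             vapply(sm$taxa, function(tx)
               sprintf("%s  %s", gsub("\\s", "_", tx), sm$rows[[tx]]),
               character(1)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA supermatrix back
#'
#' Reconstructs the row set of a supermatrix written with
#' [write_supermatrix()] (partitions are carried by the partition file, not
#' the sequence file).
#'
#' @param path FASTA path.
#' @return named character vector of rows.
#' @export
read_supermatrix_rows <- function(path) {
  aln <- read_alignment(path)
  aln$rows
}

#' Write a RAxML-style partition file
#'
#' One `DNA, label = start-end` line per gene partition and one
#' `DNA, label = start-end\\3` line per codon-position partition: 13 + 39
#' lines for a full 13-PCG matrix.
#'
#' @param sm a [concatenate()] supermatrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(sm, path) {
  p <- sm$partitions
  lines <- ifelse(p$kind == "gene",
                  sprintf("DNA, %s = %d-%d", p$label, p$start, p$end),
                  sprintf("DNA, %s = %d-%d\\3", p$label, p$start, p$end))
  writeLines(lines, path)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (exact on additive matrices) over a square
#' symmetric distance matrix with zero diagonal. Negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to 0 with a
#' warning. Trees are unrooted; an optional outgroup roots the returned
#' tree for presentation only.
#'
#' @param d square symmetric numeric matrix with taxon dimnames, or a
#'   `dist` object; n >= 3, finite entries.
#' @param outgroup optional taxon id to root the tree at.
#' @return An [ape::ape-package] `phylo` tree.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be square")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("missing or non-finite distances")
  if (any(abs(d - t(d)) > 1e-8)) stop("d must be symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  tr <- ape::nj(stats::as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Write / read Newick
#'
#' Thin wrappers over the ape Newick reader/writer so trees produced here
#' round-trip byte-stably.
#'
#' @param tree a `phylo` object.
#' @param path file path.
#' @return `path` invisibly (write); a `phylo` (read).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
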