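#' Base composition and strand skews of a sequence
#'
#' Counts A/T/G/C (ambiguous bases tracked separately and excluded from all
#' denominators) and computes percentages, A+T content, and the strand
#' skews
#' \deqn{AT~skew = (A - T)/(A + T), \qquad GC~skew = (G - C)/(G + C).}
#' A positive AT skew means more A than T on the analysed strand. Skews are
#' undefined (NA) when the denominator is zero.
#'
#' @param seq DNA string.
#' @param label region label carried into the output row.
#' @return One-row data.frame of class `base_composition` with columns
#'   `region`, `length`, `n_A`, `n_T`, `n_G`, `n_C`, `n_ambiguous`,
#'   `pct_A`, `pct_T`, `pct_G`, `pct_C`, `pct_AT`, `pct_GC`, `at_skew`,
#'   `gc_skew`. Percentages are fractions of counted (non-ambiguous) bases
#'   times 100; full precision is kept (round only for display).
#' @examples
#' compose("ATAT")$at_skew  # 0
#' @export
compose <- function(seq, label = "region") {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("empty sequence")
  ch <- seq_chars(seq)
  nA <- sum(ch == "A"); nT <- sum(ch == "T")
  nG <- sum(ch == "G"); nC <- sum(ch == "C")
  tot <- nA + nT + nG + nC
  amb <- length(ch) - tot
  pct <- function(n) if (tot > 0) 100 * n / tot else NA_real_
  skew <- function(x, y) if (x + y > 0) (x - y) / (x + y) else NA_real_
  out <- data.frame(region = label, length = length(ch),
                    n_A = nA, n_T = nT, n_G = nG, n_C = nC, n_ambiguous = amb,
                    pct_A = pct(nA), pct_T = pct(nT), pct_G = pct(nG),
                    pct_C = pct(nC), pct_AT = pct(nA + nT), pct_GC = pct(nG + nC),
                    at_skew = skew(nA, nT), gc_skew = skew(nG, nC),
                    stringsAsFactors = FALSE)
  class(out) <- c("base_composition", class(out))
  out
}

#' Composition by gene class and strand
#'
#' One [compose()] row per gene class present in the genome: the whole
#' genome (J-strand), all PCGs, all tRNAs, all rRNAs, the control region,
#' and the PCGs split into J-strand and N-strand sets. Stranded classes are
#' counted on coding-sense sequences (so an N-strand gene contributes its
#' reverse complement); classes absent from the annotation are omitted.
#'
#' @param genome a [mitogenome()].
#' @return data.frame, one row per available class.
#' @export
compose_by_class <- function(genome) {
  if (!nrow(genome$features)) stop("genome has no features")
  f <- genome$features
  pull <- function(rows) paste(vapply(seq_len(nrow(rows)), function(i)
    extract_gene(genome, rows[i, ]), character(1)), collapse = "")
  out <- list(compose(genome$sequence, "whole genome"))
  classes <- list(PCGs = f[f$ftype == "PCG", ],
                  tRNAs = f[f$ftype == "tRNA", ],
                  rRNAs = f[f$ftype == "rRNA", ],
                  CR = f[f$ftype == "control_region", ],
                  `J-strand PCGs` = f[f$ftype == "PCG" & f$strand == "+", ],
                  `N-strand PCGs` = f[f$ftype == "PCG" & f$strand == "-", ])
  for (lab in names(classes)) {
    rows <- classes[[lab]]
    if (!nrow(rows)) next
    out[[length(out) + 1L]] <- compose(pull(rows), lab)
  }
  do.call(rbind, out)
}

#' Per-gene composition table
#'
#' [compose()] applied to the coding-sense sequence of every feature.
#'
#' @param genome a [mitogenome()].
#' @return data.frame with one row per feature (region label
#'   `name.copy_index` when a gene is duplicated).
#' @export
compose_per_gene <- function(genome) {
  f <- genome$features
  if (!nrow(f)) stop("genome has no features")
  labs <- ifelse(stats::ave(seq_len(nrow(f)), f$name, FUN = length) > 1,
                 paste0(f$name, ".", f$copy_index), f$name)
  do.call(rbind, lapply(seq_len(nrow(f)), function(i)
    compose(extract_gene(genome, f[i, ]), labs[i])))
}

#' Whole-genome skew table across taxa
#'
#' One row per genome with J-strand whole-length A+T%, G+C% and both skews;
#' the shape used for AT%-vs-AT-skew / GC%-vs-GC-skew comparative scatter
#' plots across related taxa.
#'
#' @param genomes list of [mitogenome()] objects with unique ids.
#' @return data.frame with columns `taxon`, `pct_AT`, `at_skew`, `pct_GC`,
#'   `gc_skew`, ordered by taxon id.
#' @export
skew_scatter_table <- function(genomes) {
  if (!length(genomes)) stop("need at least one genome")
  ids <- vapply(genomes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicated genome ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(genomes, function(g) {
    cmp <- compose(g$sequence, g$id)
    data.frame(taxon = g$id, pct_AT = cmp$pct_AT, at_skew = cmp$at_skew,
               pct_GC = cmp$pct_GC, gc_skew = cmp$gc_skew,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$taxon), , drop = FALSE]
}
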