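#' Linearized circular gene order
#'
#' Rotates the circular feature order so it begins at an anchor gene
#' (conventionally trnI for insect mitogenomes) and reports each gene as a
#' signed symbol (sign = strand) with its copy index. The control region is
#' excluded by default, as in linearized gene-order depictions.
#'
#' @param genome a [mitogenome()].
#' @param anchor gene symbol used as linearization origin; if absent, the
#'   first feature is used with a warning.
#' @param include_cr keep control_region features?
#' @return List of class `gene_order`: `taxon`, `anchor`, `order`
#'   (data.frame `name`, `strand`, `copy_index`).
#' @export
gene_order <- function(genome, anchor = "trnI", include_cr = FALSE) {
  f <- genome$features
  if (!include_cr) f <- f[f$ftype != "control_region", , drop = FALSE]
  if (!nrow(f)) stop("no features to order")
  f <- f[order(f$start, f$end), , drop = FALSE]
  hit <- which(f$name == anchor)
  if (!length(hit)) {
    warning("anchor '", anchor, "' absent; rotating to first feature '",
            f$name[1], "'")
    hit <- 1L
    anchor <- f$name[1]
  }
  idx <- c(hit[1]:nrow(f), seq_len(hit[1] - 1L))
  structure(list(taxon = genome$id, anchor = anchor,
                 order = data.frame(name = f$name[idx], strand = f$strand[idx],
                                    copy_index = f$copy_index[idx],
                                    stringsAsFactors = FALSE)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  sym <- paste0(ifelse(x$order$strand == "-", "-", ""), x$order$name)
  cat("gene order of", x$taxon, "(anchor", paste0(x$anchor, "):\n  "),
      paste(sym, collapse = " "), "\n")
  invisible(x)
}

#' Reference (putative ancestral) insect gene order
#'
#' The putative ancestral arthropod arrangement of the 37 mitochondrial
#' genes, shipped as a data file; the usual reference for breakpoint
#' comparisons.
#'
#' @param include_cr keep the control-region row?
#' @return A `gene_order` (taxon `"ancestral"`).
#' @export
ancestral_gene_order <- function(include_cr = FALSE) {
  tab <- utils::read.delim(system.file("extdata", "ancestral_gene_order.tsv",
                                       package = "mitocomp"),
                           stringsAsFactors = FALSE)
  if (!include_cr) tab <- tab[tab$ftype != "control_region", , drop = FALSE]
  structure(list(taxon = "ancestral", anchor = tab$name[1],
                 order = data.frame(name = tab$name, strand = tab$strand,
                                    copy_index = 1L, stringsAsFactors = FALSE)),
            class = "gene_order")
}

# Strand-aware circular adjacency multiset of a gene order. Each adjacency
# between consecutive signed genes (a, b) is normalized so that reading the
# circle from the other strand, (-b, -a), yields the same key.
adjacency_keys <- function(ord) {
  sgn <- ifelse(ord$strand == "-", "-", "+")
  nm <- ord$name
  n <- length(nm)
  a <- paste0(sgn, nm)
  b <- paste0(sgn[c(2:n, 1)], nm[c(2:n, 1)])
  flip <- function(x) ifelse(substr(x, 1, 1) == "-",
                             paste0("+", substr(x, 2, nchar(x))),
                             paste0("-", substr(x, 2, nchar(x))))
  fwd <- paste(a, b, sep = "|")
  rev <- paste(flip(b), flip(a), sep = "|")
  pmin(fwd, rev)  # canonical orientation of each adjacency
}

#' Compare two gene orders
#'
#' Counts breakpoints — circular, strand-aware gene adjacencies present in
#' the query but absent from the reference (multiset difference, so
#' duplicated genes are matched copy-for-copy by their adjacent context) —
#' and reports the genes involved in disrupted adjacencies, duplications,
#' and genes missing from or extra to the reference roster.
#'
#' @param query,reference `gene_order` objects (see [gene_order()]).
#' @return List of class `rearrangement_report`: `breakpoints` (count),
#'   `moved_genes` (character), `duplicated` (data.frame gene/copies),
#'   `missing`, `extra` (vs the reference roster).
#' @export
compare_orders <- function(query, reference) {
  if (!nrow(query$order) || !nrow(reference$order)) stop("empty gene order")
  qk <- adjacency_keys(query$order)
  rk <- adjacency_keys(reference$order)
  # multiset difference
  broken <- qk
  for (k in rk) {
    i <- match(k, broken)
    if (!is.na(i)) broken <- broken[-i]
  }
  moved <- unique(sub("^[+-]", "", unlist(strsplit(broken, "|", fixed = TRUE))))
  qtab <- table(query$order$name)
  dup <- qtab[qtab > 1]
  structure(list(
    breakpoints = length(broken),
    moved_genes = sort(moved),
    duplicated = data.frame(gene = names(dup), copies = as.integer(dup),
                            stringsAsFactors = FALSE, row.names = NULL),
    missing = sort(setdiff(reference$order$name, query$order$name)),
    extra = sort(setdiff(query$order$name, reference$order$name))),
    class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat("breakpoints:", x$breakpoints, "\n")
  if (length(x$moved_genes))
    cat("genes in disrupted adjacencies:", paste(x$moved_genes, collapse = ", "), "\n")
  if (nrow(x$duplicated))
    cat("duplicated:", paste0(x$duplicated$gene, " x", x$duplicated$copies,
                              collapse = ", "), "\n")
  invisible(x)
}

#' Intergenic spacers and gene overlaps
#'
#' For consecutive features around the linearized circle (including the
#' wrap boundary), the gap `next start - previous end` is a spacer when
#' >= 1, an overlap when negative, abutting at 0. Features nested inside
#' another feature are excluded from the boundary walk and listed
#' separately, which keeps the circular tiling identity
#' `sum(lengths) + sum(spacers) - sum(overlaps) = genome length` testable.
#' The control region is excluded by default and reported via its length.
#'
#' @param genome a [mitogenome()].
#' @param include_cr include control_region features in the boundary walk?
#' @return List of class `spacer_overlap_report`: `boundaries` (data.frame
#'   `left`, `right`, `gap`), `n_spacers`, `spacer_bp`, `n_overlaps`,
#'   `overlap_bp`, `nested` (data.frame of contained features), `cr_length`
#'   (NA when absent or included).
#' @export
spacers_overlaps <- function(genome, include_cr = FALSE) {
  f <- genome$features
  if (nrow(f) < 2L) stop("need at least 2 features")
  cr_len <- NA_integer_
  if (!include_cr) {
    cr <- f[f$ftype == "control_region", , drop = FALSE]
    if (nrow(cr)) cr_len <- sum(cr$end - cr$start)
    f <- f[f$ftype != "control_region", , drop = FALSE]
  }
  f <- f[order(f$start, f$end), , drop = FALSE]
  # nested: a feature wholly inside another
  nested <- logical(nrow(f))
  for (i in seq_len(nrow(f))) for (j in seq_len(nrow(f))) {
    if (i != j && !nested[j] &&
        f$start[i] >= f$start[j] && f$end[i] <= f$end[j] &&
        (f$end[i] - f$start[i]) < (f$end[j] - f$start[j]))
      nested[i] <- TRUE
  }
  nest_tab <- f[nested, , drop = FALSE]
  f <- f[!nested, , drop = FALSE]
  n <- nrow(f)
  lab <- ifelse(stats::ave(seq_len(n), f$name, FUN = length) > 1,
                paste0(f$name, ".", f$copy_index), f$name)
  nxt <- c(2:n, 1)
  gap <- f$start[nxt] - f$end
  gap[n] <- (f$start[1] + genome$length) - f$end[n]  # wrap boundary
  boundaries <- data.frame(left = lab, right = lab[nxt], gap = as.integer(gap),
                           stringsAsFactors = FALSE)
  structure(list(boundaries = boundaries,
                 n_spacers = sum(gap >= 1L), spacer_bp = sum(gap[gap >= 1L]),
                 n_overlaps = sum(gap < 0L), overlap_bp = -sum(gap[gap < 0L]),
                 nested = nest_tab, cr_length = cr_len),
            class = "spacer_overlap_report")
}

#' @export
print.spacer_overlap_report <- function(x, ...) {
  cat(sprintf("%d spacers (%d bp), %d overlaps (%d bp)\n", x$n_spacers,
              x$spacer_bp, x$n_overlaps, x$overlap_bp))
  if (!is.na(x$cr_length)) cat("control region:", x$cr_length, "bp\n")
  invisible(x)
}

#' Find tandem repeat arrays
#'
#' Exhaustive scan over unit lengths and phases for maximal non-overlapping
#' tandem arrays, as used on mitochondrial control regions. Copies of a
#' unit may vary at up to `max_variable_positions` positions (default 1,
#' capturing units whose first base alternates, e.g. G/A); such positions
#' are reported as IUPAC degeneracy codes in the consensus unit. Ties are
#' broken by more copies, then longer span, then leftmost start. The
#' deliberate brute force (O(length x max unit length)) keeps the search
#' deterministic at control-region scale.
#'
#' @param region DNA string.
#' @param unit_len_range integer c(min, max) unit lengths to scan.
#' @param min_copies minimum copy number of a reported array.
#' @param max_variable_positions columns of the array allowed to vary
#'   across copies.
#' @return data.frame of class `repeat_report`, one row per array:
#'   `unit` (IUPAC consensus), `unit_len`, `copies`, `start`, `end`
#'   (0-based half-open span). Empty when nothing qualifies.
#' @examples
#' find_tandem_repeats("ACGACGACG", c(3, 3), 3)
#' @export
find_tandem_repeats <- function(region, unit_len_range = c(5L, 50L),
                                min_copies = 3L, max_variable_positions = 1L) {
  region <- toupper(as.character(region))
  ch <- seq_chars(region)
  L <- length(ch)
  kmin <- max(1L, as.integer(unit_len_range[1]))
  kmax <- min(as.integer(unit_len_range[2]), L %/% min_copies)
  cand <- list()
  for (k in seq.int(kmin, length.out = max(0L, kmax - kmin + 1L))) {
    s <- 0L
    while (s + min_copies * k <= L) {
      # grow the array copy by copy while <= max_variable_positions columns vary
      m <- 1L
      varying <- rep(FALSE, k)
      repeat {
        nxt <- s + m * k
        if (nxt + k > L) break
        diffc <- varying | (ch[(s + 1):(s + k)] != ch[(nxt + 1):(nxt + k)])
        # compare against all previous copies via running column variability
        newvar <- varying
        ref <- ch[(s + 1):(s + k)]
        add <- ch[(nxt + 1):(nxt + k)]
        newvar <- newvar | (ref != add)
        # a column also varies if earlier copies disagreed among themselves
        if (sum(newvar) > max_variable_positions) break
        varying <- newvar
        m <- m + 1L
      }
      if (m >= min_copies)
        cand[[length(cand) + 1L]] <- list(start = s, k = k, copies = m,
                                          varying = varying)
      s <- s + 1L
    }
  }
  if (!length(cand))
    return(structure(data.frame(unit = character(), unit_len = integer(),
                                copies = integer(), start = integer(),
                                end = integer()),
                     class = c("repeat_report", "data.frame")))
  # rank: more copies, longer span, leftmost; then greedily keep non-overlapping
  spans <- vapply(cand, function(x) x$copies * x$k, integer(1))
  copies <- vapply(cand, function(x) x$copies, integer(1))
  starts <- vapply(cand, function(x) x$start, integer(1))
  ordn <- order(-copies, -spans, starts)
  kept <- list()
  occupied <- rep(FALSE, L)
  for (i in ordn) {
    x <- cand[[i]]
    span <- (x$start + 1):(x$start + x$copies * x$k)
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    kept[[length(kept) + 1L]] <- x
  }
  rows <- lapply(kept, function(x) {
    cols <- matrix(ch[(x$start + 1):(x$start + x$copies * x$k)],
                   nrow = x$k)
    unit <- apply(cols, 1, function(col) iupac_code(unique(col)))
    data.frame(unit = paste(unit, collapse = ""), unit_len = x$k,
               copies = x$copies, start = x$start,
               end = x$start + x$copies * x$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_report", class(out))
  out
}

iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  map <- c(A = "A", C = "C", G = "G", T = "T",
           AG = "R", CT = "Y", GT = "K", AC = "M", CG = "S", AT = "W",
           CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  out <- map[key]
  if (is.na(out)) "N" else unname(out)
}

#' Longest poly-T run
#'
#' Position and length of the longest uninterrupted run of T (leftmost on
#' ties); the conserved poly-T stretch of control regions.
#'
#' @param region DNA string.
#' @return List `length` (0 when no T present) and `start` (0-based, NA
#'   when no T).
#' @examples
#' longest_polyT("AAATTTTG")  # length 4, start 3
#' @export
longest_polyT <- function(region) {
  region <- toupper(as.character(region))
  if (!nzchar(region)) stop("empty region")
  r <- rle(seq_chars(region))
  idx <- which(r$values == "T")
  if (!length(idx)) return(list(length = 0L, start = NA_integer_))
  best <- idx[which.max(r$lengths[idx])]
  starts <- cumsum(c(0L, r$lengths))
  list(length = as.integer(r$lengths[best]),
       start = as.integer(starts[best]))
}
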