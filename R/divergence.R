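#' Pairwise p-distance
#'
#' Proportion of differing sites between two aligned sequences, with
#' pairwise deletion: columns where either sequence has a gap or ambiguous
#' base are excluded from both numerator and denominator.
#'
#' @param a,b aligned DNA strings of equal length.
#' @return fraction in 0..1, or NA when no comparable sites remain.
#' @export
pairwise_p_distance <- function(a, b) {
  x <- seq_chars(a); y <- seq_chars(b)
  if (length(x) != length(y)) stop("sequences differ in length")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  sum(x[ok] != y[ok]) / sum(ok)
}

#' Jukes-Cantor distance
#'
#' Corrects an observed proportion of differences for multiple hits under
#' the one-parameter substitution model:
#' \deqn{d = -\frac{3}{4} \ln\left(1 - \frac{4p}{3}\right).}
#' Defined for `0 <= p < 0.75`; saturated inputs (`p >= 0.75`) return NA
#' with a warning.
#'
#' @param p observed proportion of differing sites (scalar or vector).
#' @return distance in substitutions per site.
#' @examples
#' jc_distance(0.3)  # 0.3831192...
#' @export
jc_distance <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p >= 0 & p < 0.75
  if (any(!ok & !is.na(p) & p >= 0.75))
    warning("p >= 0.75: Jukes-Cantor distance saturated, returning NA")
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Sliding-window nucleotide diversity
#'
#' Nucleotide diversity Pi — the average pairwise proportion of differing
#' sites over all unordered sequence pairs — computed in windows sliding
#' along the alignment, plus the per-gene value over the full length.
#' Pairwise deletion is applied within each window; a window where some
#' pair has no comparable sites reports NA but is kept in the profile.
#' Windows start at every `step` until fewer than `window` columns remain
#' (the final, possibly shorter tail window is included).
#'
#' @param alignment a [gene_alignment()] with >= 2 rows.
#' @param window window width, bp (default 200).
#' @param step step between window starts, bp (default 20).
#' @return List of class `diversity_profile`: `windows` (data.frame
#'   `start`, `end`, `midpoint`, `pi`; 0-based half-open), `gene_pi`,
#'   `mean_p_distance`, `mean_jc_distance`, `gene`, `n_taxa`.
#' @export
sliding_pi <- function(alignment, window = 200L, step = 20L) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  L <- ncol(m)
  if (window > L) stop("window exceeds alignment length")
  if (step < 1L) stop("step must be >= 1")
  pairs <- utils::combn(n, 2)
  pi_of <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    ps <- apply(pairs, 2, function(ij) {
      x <- sub[ij[1], ]; y <- sub[ij[2], ]
      ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
      if (!any(ok)) NA_real_ else sum(x[ok] != y[ok]) / sum(ok)
    })
    mean(ps)  # NA propagates when any pair lacks comparable sites
  }
  starts <- seq(0L, max(0L, L - window), by = step)
  if (starts[length(starts)] + window < L) starts <- c(starts, L - window)
  wins <- data.frame(start = starts, end = pmin(starts + window, L))
  wins$midpoint <- (wins$start + wins$end) / 2
  wins$pi <- vapply(seq_len(nrow(wins)), function(i)
    pi_of((wins$start[i] + 1L):wins$end[i]), numeric(1))
  p_all <- apply(pairs, 2, function(ij)
    pairwise_p_distance(alignment$rows[[ij[1]]], alignment$rows[[ij[2]]]))
  structure(list(windows = wins, gene_pi = pi_of(seq_len(L)),
                 mean_p_distance = mean(p_all),
                 mean_jc_distance = mean(suppressWarnings(jc_distance(p_all))),
                 gene = alignment$gene, n_taxa = n),
            class = "diversity_profile")
}

# --- Nei-Gojobori ------------------------------------------------------

# Synonymous-site fraction of each codon position: fraction of the 3
# possible single-base changes that preserve the amino acid (changes to
# stop codons are non-synonymous). Precomputed per code.
ng_site_table <- function(code) {
  bases <- c("A", "C", "G", "T")
  cods <- names(code$codons)
  s <- matrix(NA_real_, 64L, 3L, dimnames = list(cods, NULL))
  for (cd in cods) {
    if (code$codons[[cd]] == "*") next
    spl <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      syn <- 0L
      for (b in setdiff(bases, spl[pos])) {
        mut <- spl; mut[pos] <- b
        if (code$codons[[paste(mut, collapse = "")]] == code$codons[[cd]])
          syn <- syn + 1L
      }
      s[cd, pos] <- syn / 3
    }
  }
  s
}

# All orderings of the differing positions between two codons; returns the
# per-pathway (syn, nonsyn) step counts, dropping pathways through stops.
ng_pathways <- function(c1, c2, code) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(list(syn = 0, nonsyn = 0, n_path = 1L))
  perms <- if (length(d) == 1) list(d) else
    if (length(d) == 2) list(d, rev(d)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(p) d[p])
  syn <- nonsyn <- 0
  n_ok <- 0L
  for (p in perms) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    s_cnt <- n_cnt <- 0L
    ok <- TRUE
    for (pos in p) {
      aa_from <- code$codons[[paste(cur, collapse = "")]]
      cur[pos] <- tgt[pos]
      aa_to <- code$codons[[paste(cur, collapse = "")]]
      if (aa_to == "*" || aa_from == "*") { ok <- FALSE; break }
      if (aa_to == aa_from) s_cnt <- s_cnt + 1L else n_cnt <- n_cnt + 1L
    }
    if (ok) { syn <- syn + s_cnt; nonsyn <- nonsyn + n_cnt; n_ok <- n_ok + 1L }
  }
  list(syn = if (n_ok) syn / n_ok else NA_real_,
       nonsyn = if (n_ok) nonsyn / n_ok else NA_real_,
       n_path = n_ok)
}

#' Nei-Gojobori synonymous/non-synonymous proportions
#'
#' Counting method for a pair of in-frame coding sequences. Synonymous
#' sites per codon are the per-position fractions of single-base changes
#' that preserve the amino acid (changes creating stops count as
#' non-synonymous), averaged between the two sequences; `N = 3 x codons -
#' S` always. Observed differences are resolved by equal weighting over
#' all substitution pathways between the two codons, excluding pathways
#' that pass through a stop codon (renormalized); codon pairs whose every
#' pathway is blocked, or that contain gaps or ambiguous bases, are
#' skipped and tallied. Proportions are `pN = Nd/N`, `pS = Sd/S`.
#'
#' @param a,b in-frame coding DNA strings of equal length divisible by 3.
#' @param code a [genetic_code()].
#' @return List of class `ng_counts`: `pN`, `pS` (NA when the respective
#'   site total is 0), `Nd`, `Sd`, `N_sites`, `S_sites`, `n_codons`
#'   (compared), `n_skipped`.
#' @examples
#' ng <- nei_gojobori("TTT", "TTA", genetic_code())
#' c(ng$pN, ng$pS)  # 0.4, 0
#' @export
nei_gojobori <- function(a, b, code = genetic_code()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("length not divisible by 3")
  st <- ng_site_table(code)
  nc <- nchar(a) %/% 3L
  ca <- substring(a, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  cb <- substring(b, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  S <- N <- Sd <- Nd <- 0
  used <- 0L; skipped <- 0L
  for (i in seq_len(nc)) {
    c1 <- ca[i]; c2 <- cb[i]
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2) ||
        code$codons[[c1]] == "*" || code$codons[[c2]] == "*") {
      skipped <- skipped + 1L
      next
    }
    pw <- ng_pathways(c1, c2, code)
    if (pw$n_path == 0L) { skipped <- skipped + 1L; next }
    s_i <- (sum(st[c1, ]) + sum(st[c2, ])) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    Sd <- Sd + pw$syn
    Nd <- Nd + pw$nonsyn
    used <- used + 1L
  }
  structure(list(pN = if (N > 0) Nd / N else NA_real_,
                 pS = if (S > 0) Sd / S else NA_real_,
                 Nd = Nd, Sd = Sd, N_sites = N, S_sites = S,
                 n_codons = used, n_skipped = skipped),
            class = "ng_counts")
}

#' Per-gene substitution rates over a taxon set
#'
#' For each gene, Nei-Gojobori proportions are computed for every unordered
#' taxon pair and averaged: `Ka` and `Ks` are the mean raw proportions,
#' `JKa` and `JKs` their Jukes-Cantor-adjusted counterparts (by default the
#' correction is applied to each pair before averaging; set
#' `adjust_after_mean = TRUE` to correct the averaged proportions instead).
#' Ratios are formed after averaging and are NA when the denominator is 0.
#' Genes are returned ranked by `JKa_JKs` descending (fastest-evolving
#' first).
#'
#' @param alignments named list of codon-aligned [gene_alignment()]s.
#' @param code a [genetic_code()].
#' @param adjust_after_mean apply the Jukes-Cantor correction to the
#'   averaged proportions rather than per pair?
#' @return data.frame of class `substitution_rates`, one row per gene:
#'   `gene`, `n_taxa`, `Ka`, `Ks`, `Ka_Ks`, `JKa`, `JKs`, `JKa_JKs`.
#' @export
gene_rates <- function(alignments, code = genetic_code(),
                       adjust_after_mean = FALSE) {
  rows <- list()
  for (gene in names(alignments)) {
    aln <- alignments[[gene]]
    if (!aln$codon_aligned) stop("alignment for ", gene, " is not codon-aligned")
    n <- length(aln$taxa)
    if (n < 2L) {
      warning("gene ", gene, " has < 2 taxa; skipped")
      next
    }
    pairs <- utils::combn(n, 2)
    pN <- pS <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      ng <- nei_gojobori(aln$rows[[pairs[1, j]]], aln$rows[[pairs[2, j]]], code)
      pN[j] <- ng$pN; pS[j] <- ng$pS
    }
    Ka <- mean(pN, na.rm = TRUE); Ks <- mean(pS, na.rm = TRUE)
    if (adjust_after_mean) {
      JKa <- suppressWarnings(jc_distance(Ka))
      JKs <- suppressWarnings(jc_distance(Ks))
    } else {
      JKa <- mean(suppressWarnings(jc_distance(pN)), na.rm = TRUE)
      JKs <- mean(suppressWarnings(jc_distance(pS)), na.rm = TRUE)
    }
    ratio <- function(x, y) if (!is.na(y) && y > 0) x / y else NA_real_
    rows[[gene]] <- data.frame(gene = gene, n_taxa = n, Ka = Ka, Ks = Ks,
                               Ka_Ks = ratio(Ka, Ks), JKa = JKa, JKs = JKs,
                               JKa_JKs = ratio(JKa, JKs),
                               stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no gene with >= 2 taxa")
  out <- do.call(rbind, rows)
  out <- out[order(-out$JKa_JKs), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("substitution_rates", class(out))
  out
}
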