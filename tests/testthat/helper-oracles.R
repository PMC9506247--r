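# Independent oracles and fixture builders used across the suite.
# Translation here deliberately goes through seqinr (numcode = 5), a
# different code path from the package's Biostrings-backed genetic code.

oracle_translate <- function(codon) {
  seqinr::translate(seqinr::s2c(codon), numcode = 5)
}

BASES <- c("A", "C", "G", "T")

# Brute-force degeneracy class of one codon position: enumerate the 3
# substitutions, count amino-acid-preserving ones (stops non-preserving).
oracle_fold_class <- function(codon, pos) {
  aa <- oracle_translate(codon)
  if (aa == "*") return(NA_integer_)
  spl <- strsplit(codon, "")[[1]]
  s <- 0L
  for (b in setdiff(BASES, spl[pos])) {
    mut <- spl; mut[pos] <- b
    mut_aa <- oracle_translate(paste(mut, collapse = ""))
    if (mut_aa != "*" && mut_aa == aa) s <- s + 1L
  }
  if (s == 0L) 0L else if (s == 3L) 4L else 2L
}

# Exhaustive Nei-Gojobori pathway oracle for one codon pair: enumerate
# every ordering of the differing positions, drop orderings passing
# through stop codons, average the per-step synonymous/non-synonymous
# tallies over the surviving orderings.
oracle_ng_pathways <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(list(syn = 0, nonsyn = 0, n_path = 1L))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  syn <- nonsyn <- 0; n_ok <- 0L
  for (p in perm_list(d)) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    s_cnt <- n_cnt <- 0L; ok <- TRUE
    for (pos in p) {
      from <- oracle_translate(paste(cur, collapse = ""))
      cur[pos] <- tgt[pos]
      to <- oracle_translate(paste(cur, collapse = ""))
      if (from == "*" || to == "*") { ok <- FALSE; break }
      if (from == to) s_cnt <- s_cnt + 1L else n_cnt <- n_cnt + 1L
    }
    if (ok) { syn <- syn + s_cnt; nonsyn <- nonsyn + n_cnt; n_ok <- n_ok + 1L }
  }
  list(syn = if (n_ok) syn / n_ok else NA_real_,
       nonsyn = if (n_ok) nonsyn / n_ok else NA_real_, n_path = n_ok)
}

# Per-codon synonymous site count via the 9-neighbor enumeration.
oracle_ng_sites <- function(codon) {
  spl <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) for (b in setdiff(BASES, spl[pos])) {
    mut <- spl; mut[pos] <- b
    mut_aa <- oracle_translate(paste(mut, collapse = ""))
    if (mut_aa != "*" && mut_aa == aa) s <- s + 1 / 3
  }
  s
}

all_sense_codons <- function() {
  cods <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  cods[vapply(cods, function(cd) oracle_translate(cd) != "*", logical(1))]
}

# A tiny hand-annotated genome: 60 bp, a '+' PCG, a '-' tRNA and a CR.
toy_genome <- function() {
  seq <- paste0("ATGAAATTATTACCTTAA",        # PCG [0,18): ATG + 4 codons + TAA
                "GGGG",                      # spacer
                "ACCTAGGTTCAAGTCCTA",        # tRNA [22,40) '-'
                "TT",                        # spacer
                "ATATATATATATATTTTT")        # CR [42,60)
  mitogenome("toy", seq, features = data.frame(
    name = c("cox1", "trnC", "CR"),
    ftype = c("PCG", "tRNA", "control_region"),
    start = c(0L, 22L, 42L), end = c(18L, 40L, 60L),
    strand = c("+", "-", "+")))
}

# Distance matrix of a random tree with strictly positive branch lengths
# (additive by construction).
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.5))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
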