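# Default roster of the 37-gene insect mitogenome canon. PCG lengths are
# realistic field values expressed as coding codons (incl. start) plus a
# stop policy; an incomplete stop (T/TT) makes the CDS length = 1 or 2
# (mod 3), completed to UAA by polyadenylation in vivo.
default_pcg_spec <- function() {
  data.frame(
    name  = c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
              "nad5", "nad4", "nad4l", "nad6", "cytb", "nad1"),
    ncod  = c(319L, 511L, 227L, 31L, 225L, 261L, 117L,
              571L, 446L, 96L, 166L, 378L, 308L),
    start = c("ATA", "ATG", "ATT", "ATT", "ATA", "ATG", "ATA",
              "ATG", "ATT", "ATG", "ATT", "ATG", "ATG"),
    stop  = c("TAA", "TAA", "TAA", "T", "TAA", "TAA", "T",
              "TT", "TAA", "TAA", "T", "T", "T"),
    stringsAsFactors = FALSE)
}

default_gene_lengths <- function(cr_length) {
  pcg <- default_pcg_spec()
  pcg_len <- stats::setNames(pcg$ncod * 3L + nchar(pcg$stop), pcg$name)
  trna <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2", "M",
            "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y")
  # fixed realistic tRNA lengths in 57..71 bp, deterministic per gene
  trna_len <- stats::setNames(57L + (seq_along(trna) * 7L) %% 15L,
                              paste0("trn", trna))
  c(pcg_len, trna_len, rrnS = 750L, rrnL = 1020L, CR = as.integer(cr_length))
}

# Boundary gaps keyed by the left-hand gene; the long non-coding stretch
# follows nad2, and the five overlaps sit after tRNAs only, so overwriting
# the shared bases never corrupts a reading frame.
default_gaps <- c(nad2 = 345L, trnW = -1L, trnY = -6L, trnK = -1L,
                  trnA = -1L, trnG = -1L)

#' Blueprint for a synthetic mitogenome
#'
#' Describes the study conditions a generated genome emulates: the 37-gene
#' insect canon, a gene order (the putative ancestral arrangement, or an
#' "nlugens"-like one with the trnC-trnW swap, the nad6-trnP-trnT block
#' rearrangement and an extra trnC copy), a target base composition, and a
#' control region carrying a tandem-repeat array whose unit's first base
#' alternates G/A plus a poly-T run.
#'
#' @param id genome id.
#' @param order `"ancestral"`, `"nlugens"`, or a custom data.frame with
#'   columns `name`, `ftype`, `strand` (lengths from the default roster).
#' @param base_fractions named fractions for A/T/G/C summing to 1; the
#'   default matches the A+T-rich composition of delphacid mitogenomes
#'   (77.5% A+T).
#' @param cr_length control-region length, bp.
#' @param repeat_unit repeat unit; IUPAC `R` marks the alternating G/A
#'   first position (default 20 bp).
#' @param repeat_copies copy number of the tandem array (default 15).
#' @param polyT_length planted poly-T run length, bp (default 24).
#' @param exact_composition redraw free (non-coding, non-planted) bases so
#'   the whole-genome base tallies hit the target exactly?
#' @param target_length total genome length; NULL (default) derives it
#'   from the roster and spacer layout. When given, the spacer preceding
#'   the control region absorbs the difference.
#' @param seed RNG seed; the same blueprint and seed give byte-identical
#'   genomes.
#' @return list of class `genome_blueprint`.
#' @export
genome_blueprint <- function(id = "synthetic",
                             order = c("nlugens", "ancestral"),
                             base_fractions = c(A = 0.426, T = 0.349,
                                                G = 0.088, C = 0.137),
                             cr_length = 1304L,
                             repeat_unit = "RATATATATATATAAATATA",
                             repeat_copies = 15L,
                             polyT_length = 24L,
                             exact_composition = TRUE,
                             target_length = NULL,
                             seed = 1L) {
  if (is.character(order)) order <- match.arg(order)
  bf <- base_fractions[c("A", "T", "G", "C")]
  if (anyNA(bf) || abs(sum(bf) - 1) > 1e-6)
    stop("base_fractions must name A/T/G/C and sum to 1")
  structure(list(id = id, order = order, base_fractions = bf,
                 cr_length = as.integer(cr_length),
                 repeat_unit = toupper(repeat_unit),
                 repeat_copies = as.integer(repeat_copies),
                 polyT_length = as.integer(polyT_length),
                 exact_composition = isTRUE(exact_composition),
                 target_length = target_length,
                 seed = as.integer(seed)),
            class = "genome_blueprint")
}

blueprint_order_table <- function(bp) {
  anc <- utils::read.delim(system.file("extdata", "ancestral_gene_order.tsv",
                                       package = "mitocomp"),
                           stringsAsFactors = FALSE)
  if (is.data.frame(bp$order)) return(bp$order)
  if (identical(bp$order, "ancestral")) return(anc)
  # nlugens-like: swap trnW-trnC to trnC-trnW, reverse the trnT-trnP-nad6
  # block to nad6-trnP-trnT (strands kept), insert an extra trnC after nad2
  nm <- anc$name
  iw <- match("trnW", nm); ic <- match("trnC", nm)
  anc[c(iw, ic), ] <- anc[c(ic, iw), ]
  nm <- anc$name
  it <- match("trnT", nm); i6 <- match("nad6", nm)
  anc[it:i6, ] <- anc[i6:it, ]
  extra <- data.frame(name = "trnC", ftype = "tRNA", strand = "-",
                      stringsAsFactors = FALSE)
  i2 <- match("nad2", anc$name)
  rbind(anc[1:i2, ], extra, anc[(i2 + 1):nrow(anc), ])
}

# Sample n bases iid from the blueprint composition.
draw_bases <- function(n, bf) {
  if (n <= 0L) return(character(0))
  sample(names(bf), n, replace = TRUE, prob = bf)
}

#' Random in-frame coding sequence
#'
#' Start codon plus body codons drawn from a composition-biased codon
#' distribution with stop codons excluded (so the CDS is internally
#' stop-free by construction), plus the requested terminal stop.
#'
#' @param n_codons number of coding codons including the start.
#' @param code a [genetic_code()].
#' @param start start codon (default ATG).
#' @param stop `"TAA"`, `"TAG"`, `"T"`, `"TT"` or `""`.
#' @param base_probs named A/T/G/C sampling weights.
#' @return DNA string of length `3 * n_codons + nchar(stop)`.
#' @export
random_cds <- function(n_codons, code = genetic_code(), start = "ATG",
                       stop = "TAA",
                       base_probs = c(A = 0.426, T = 0.349, G = 0.088,
                                      C = 0.137)) {
  stopifnot(n_codons >= 2L)
  cods <- names(code$codons)[code$codons != "*"]
  w <- vapply(strsplit(cods, ""), function(b) prod(base_probs[b]), numeric(1))
  body <- sample(cods, n_codons - 1L, replace = TRUE, prob = w)
  paste0(start, paste(body, collapse = ""), stop)
}

# Break runs of T longer than maxrun inside chars[lo..hi] by swapping with
# a non-T base in the same window (multiset-preserving).
cap_t_runs <- function(chars, lo, hi, maxrun = 12L) {
  if (hi < lo) return(chars)
  repeat {
    r <- rle(chars[lo:hi] == "T")
    ends <- cumsum(r$lengths)
    long <- which(r$values & r$lengths > maxrun)
    if (!length(long)) break
    i <- long[1]
    pos <- lo - 1L + ends[i] - r$lengths[i] + maxrun + 1L  # first excess T
    cand <- setdiff(which(chars[lo:hi] != "T") + lo - 1L, pos)
    if (!length(cand)) break
    j <- cand[1]
    tmp <- chars[pos]; chars[pos] <- chars[j]; chars[j] <- tmp
  }
  chars
}

#' Generate a synthetic annotated mitogenome
#'
#' Lays the blueprint's gene roster around the circle with small intergenic
#' spacers, one long non-coding stretch after nad2, and five overlaps
#' placed after tRNAs; fills each PCG with a stop-free random CDS
#' honouring its start/stop policy; plants the control-region repeat array
#' (first unit base alternating G/A) and poly-T run; and, when
#' `exact_composition` is set, redraws the free bases (spacers and
#' control-region filler) as an exact multiset so the whole-genome tallies
#' hit the composition target. Everything planted is returned in a truth
#' record so analyses can be checked against it.
#'
#' @param bp a [genome_blueprint()].
#' @return list: `genome` (a [mitogenome()]) and `truth` (planted layout,
#'   base tallies, repeat/poly-T positions, gene order and roster).
#' @export
generate_genome <- function(bp = genome_blueprint()) {
  set.seed(bp$seed)
  code <- genetic_code()
  ord <- blueprint_order_table(bp)
  lens <- default_gene_lengths(bp$cr_length)
  pcg <- default_pcg_spec()
  bf <- bp$base_fractions

  # --- layout -----------------------------------------------------------
  n <- nrow(ord)
  gap_before <- integer(n)  # gap between element i-1 and i
  for (i in 2:n) {
    left <- ord$name[i - 1L]
    gap_before[i] <- if (left %in% names(default_gaps))
      default_gaps[[left]] else 2L
  }
  glen <- unname(lens[ord$name])
  starts <- integer(n); pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gap_before[i]
    starts[i] <- pos
    pos <- pos + glen[i]
  }
  L <- pos  # control region (last element) abuts the origin / first gene
  if (!is.null(bp$target_length)) {
    delta <- as.integer(bp$target_length) - L
    icr <- which(ord$ftype == "control_region")
    if (!length(icr)) stop("target_length requires a control region in the order")
    if (starts[icr[1]] + delta < 0) stop("target_length too short for the roster")
    gap_before[icr[1]] <- gap_before[icr[1]] + delta
    idx <- icr[1]:n
    starts[idx] <- starts[idx] + delta
    L <- L + delta
  }

  # --- per-gene sequences ----------------------------------------------
  chars <- rep(NA_character_, L)
  cr_parts <- NULL
  # minus-strand genes are drawn in coding sense from the complemented
  # fractions so their J-strand contribution matches the target bias
  bf_minus <- stats::setNames(bf[c("T", "A", "C", "G")], c("A", "T", "G", "C"))
  for (i in seq_len(n)) {
    nm <- ord$name[i]
    bf_i <- if (ord$strand[i] == "-") bf_minus else bf
    if (ord$ftype[i] == "PCG") {
      sp <- pcg[pcg$name == nm, ]
      coding <- random_cds(sp$ncod, code, start = sp$start, stop = sp$stop,
                           base_probs = bf_i)
      placed <- if (ord$strand[i] == "-") revcomp(coding) else coding
    } else if (ord$ftype[i] == "control_region") {
      cr_parts <- build_cr(bp, glen[i])
      placed <- cr_parts$seq
    } else {
      # stored directly as J-strand text, so drawn from the J-strand bias
      placed <- paste(draw_bases(glen[i], bf), collapse = "")
    }
    chars[(starts[i] + 1L):(starts[i] + glen[i])] <- seq_chars(placed)
  }
  free <- which(is.na(chars))  # spacers
  chars[free] <- draw_bases(length(free), bf)

  icr <- which(ord$ftype == "control_region")
  cr_start <- if (length(icr)) starts[icr[1]] else NA_integer_
  free_cr <- if (length(icr)) cr_start + cr_parts$filler_idx else integer(0)
  free_all <- c(free, free_cr)

  # --- exact composition fixup -----------------------------------------
  if (bp$exact_composition) {
    target <- round(L * bf)
    target["A"] <- target["A"] + (L - sum(target))  # force exact total
    fixed <- table(factor(chars[-free_all], levels = c("A", "T", "G", "C")))
    need <- target - as.numeric(fixed[names(target)])
    if (any(need < 0) || sum(need) != length(free_all))
      stop("infeasible composition: fixed gene content already exceeds ",
           "the target tallies for ",
           paste(names(target)[need < 0], collapse = ", "))
    chars[free_all] <- sample(rep(names(target), times = need))
  }
  # keep free stretches free of spurious long poly-T and keep the planted
  # poly-T flanks non-T
  free_all <- sort(free_all)
  for (seg in split(free_all, cumsum(c(1L, diff(free_all) != 1L)))) {
    chars <- cap_t_runs(chars, seg[1], seg[length(seg)])
  }
  if (length(icr)) {
    # flank constraints, enforced by count-preserving swaps inside the CR
    # filler: the poly-T run must not be extended by a flanking T, and the
    # base preceding the repeat array must differ from the unit's final
    # base so no shifted phase of the array gains an extra copy
    unit <- seq_chars(bp$repeat_unit)
    fixes <- rbind(
      data.frame(pos = cr_start + cr_parts$polyT_flanks, bad = "T"),
      data.frame(pos = cr_start + cr_parts$repeat_start,
                 bad = unit[length(unit)]))
    prot <- fixes$pos
    for (r in seq_len(nrow(fixes))) {
      p <- fixes$pos[r]; bad <- fixes$bad[r]
      if (!bad %in% c("A", "C", "G", "T")) next
      if (p < 1L || p > L || chars[p] != bad) next
      seg <- setdiff(free_cr, prot)
      j <- seg[chars[seg] != bad][1]
      if (!is.na(j)) { tmp <- chars[p]; chars[p] <- chars[j]; chars[j] <- tmp }
    }
  }

  sequence <- paste(chars, collapse = "")
  feats <- data.frame(name = ord$name, ftype = ord$ftype, start = starts,
                      end = starts + glen, strand = ord$strand,
                      copy_index = NA_integer_, stringsAsFactors = FALSE)
  genome <- mitogenome(bp$id, sequence, feats, circular = TRUE)

  counts <- table(factor(chars, levels = c("A", "T", "G", "C")))
  truth <- list(
    layout = cbind(feats[-6], gap_before = gap_before, length = glen),
    counts = stats::setNames(as.integer(counts), names(counts)),
    pct_AT = 100 * sum(counts[c("A", "T")]) / L,
    length = L,
    order = ord$name,
    cr = if (length(icr)) list(
      start = cr_start,
      repeat_start = cr_start + cr_parts$repeat_start,
      repeat_end = cr_start + cr_parts$repeat_end,
      unit = bp$repeat_unit, unit_len = nchar(bp$repeat_unit),
      copies = bp$repeat_copies,
      polyT_start = cr_start + cr_parts$polyT_start,
      polyT_length = bp$polyT_length) else NULL,
    seed = bp$seed)
  list(genome = genome, truth = truth)
}

# Control region: filler1 | repeat array | filler2 | poly-T | filler3.
# Returns the sequence, 0-based part coordinates within the CR, and the
# indices of filler (free) positions.
build_cr <- function(bp, cr_len) {
  unit <- seq_chars(bp$repeat_unit)
  k <- length(unit)
  arr <- character(0)
  for (i in seq_len(bp$repeat_copies)) {
    u <- unit
    u[u == "R"] <- if (i %% 2L == 1L) "G" else "A"
    arr <- c(arr, u)
  }
  f1 <- 100L
  f2 <- 50L
  rep_len <- length(arr)
  f3 <- cr_len - f1 - rep_len - f2 - bp$polyT_length
  if (f3 < 10L) stop("control region too short for its planted structures")
  seqv <- c(draw_bases(f1, bp$base_fractions), arr,
            draw_bases(f2, bp$base_fractions), rep("T", bp$polyT_length),
            draw_bases(f3, bp$base_fractions))
  filler_idx <- c(seq_len(f1), f1 + rep_len + seq_len(f2),
                  f1 + rep_len + f2 + bp$polyT_length + seq_len(f3))
  list(seq = paste(seqv, collapse = ""),
       repeat_start = f1, repeat_end = f1 + rep_len,
       polyT_start = f1 + rep_len + f2,
       polyT_flanks = c(f1 + rep_len + f2, f1 + rep_len + f2 + bp$polyT_length + 1L),
       filler_idx = filler_idx)
}

#' Divergence specification for the taxon simulator
#'
#' @param tree an ape `phylo` or a Newick string with branch lengths in
#'   candidate substitutions per site; default a balanced 4-taxon tree.
#' @param omega per-gene dN/dS acceptance probability for non-synonymous
#'   candidate changes (scalar recycled, or named by gene).
#' @param seed RNG seed.
#' @return list of class `divergence_spec`.
#' @export
divergence_spec <- function(tree = "((t1:0.15,t2:0.15):0.05,(t3:0.15,t4:0.15):0.05);",
                            omega = 0.2, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  if (any(omega <= 0)) stop("omega must be > 0")
  structure(list(tree = tree, omega = omega, seed = as.integer(seed)),
            class = "divergence_spec")
}

#' Simulate codon-level divergence along a tree
#'
#' Evolves each root CDS down the guide tree. On a branch of length t,
#' `Poisson(t * L)` candidate single-base changes are drawn uniformly over
#' sites and alternative bases; candidates creating stop codons are
#' rejected, synonymous candidates are always accepted, and non-synonymous
#' candidates are accepted with probability omega — so the realized
#' Ka/Ks tracks omega. No indels are simulated: the tip sequences form
#' gap-free codon alignments. The truth record keeps the realized
#' accepted-change counts per gene.
#'
#' @param root_genes named list/vector of in-frame, stop-free coding DNA
#'   strings (the ancestral state per gene).
#' @param spec a [divergence_spec()].
#' @param code a [genetic_code()].
#' @return list: `alignments` (named list of codon-aligned
#'   [gene_alignment()]s over the tree's tips) and `truth` (per gene:
#'   omega used, accepted synonymous / non-synonymous counts).
#' @export
evolve_taxa <- function(root_genes, spec = divergence_spec(),
                        code = genetic_code()) {
  set.seed(spec$seed)
  tree <- ape::reorder.phylo(spec$tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  omega <- spec$omega
  alignments <- list()
  truth <- list()
  for (g in names(root_genes)) {
    om <- if (!is.null(names(omega)) && g %in% names(omega))
      omega[[g]] else unname(omega[1])
    cds <- seq_chars(root_genes[[g]])
    if (length(cds) %% 3L != 0L) stop("root CDS for ", g, " not in frame")
    states <- vector("list", max(tree$edge))
    states[[root]] <- cds
    acc_s <- acc_n <- 0L
    # preorder walk: reverse postorder edge list
    for (e in rev(seq_len(nrow(tree$edge)))) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t_len <- tree$edge.length[e]
      s <- states[[par]]
      ncand <- stats::rpois(1L, t_len * length(s))
      for (j in seq_len(ncand)) {
        site <- sample.int(length(s), 1L)
        b <- sample(setdiff(c("A", "C", "G", "T"), s[site]), 1L)
        cpos <- (site - 1L) %/% 3L
        idx <- cpos * 3L + 1:3
        old_cod <- paste(s[idx], collapse = "")
        new <- s[idx]; new[site - cpos * 3L] <- b
        new_cod <- paste(new, collapse = "")
        if (code$codons[[new_cod]] == "*") next
        if (code$codons[[new_cod]] == code$codons[[old_cod]]) {
          s[site] <- b; acc_s <- acc_s + 1L
        } else if (stats::runif(1L) < om) {
          s[site] <- b; acc_n <- acc_n + 1L
        }
      }
      states[[child]] <- s
    }
    rows <- stats::setNames(vapply(seq_len(ntip), function(i)
      paste(states[[i]], collapse = ""), character(1)), tree$tip.label)
    alignments[[g]] <- gene_alignment(rows, gene = g, codon_aligned = TRUE)
    truth[[g]] <- list(omega = om, accepted_syn = acc_s, accepted_nonsyn = acc_n)
  }
  list(alignments = alignments, truth = truth)
}
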