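#' Count codons of a coding sequence
#'
#' Walks the CDS in frame 0. A trailing 1-2 bp remainder is recorded as an
#' incomplete stop codon (`T` or `TT`, completed to UAA by polyadenylation
#' in mitochondrial mRNAs) and excluded from the counts; a complete terminal
#' stop codon is recorded and likewise excluded. Codons containing non-ACGT
#' characters are skipped and tallied. Internal stop codons raise a warning
#' with their codon position but are still counted.
#'
#' @param cds coding-sense DNA string, length >= 6.
#' @param code a [genetic_code()].
#' @return List of class `codon_counts`: `counts` (named numeric, 64 DNA
#'   codons), `start_codon`, `stop_codon` (triplet, `"T"`/`"TT"`, or `NA`),
#'   `stop_complete` (logical), `n_skipped` (ambiguous codons),
#'   `internal_stops` (codon indices).
#' @examples
#' cc <- count_codons("ATGAAAT", genetic_code())
#' cc$stop_codon  # incomplete "T"
#' @export
count_codons <- function(cds, code = genetic_code()) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) < 6L) stop("CDS shorter than 6 bp")
  n_full <- nchar(cds) %/% 3L
  rem <- substr(cds, n_full * 3L + 1L, nchar(cds))
  cods <- substring(cds, seq(1L, by = 3L, length.out = n_full),
                    seq(3L, by = 3L, length.out = n_full))
  counts <- stats::setNames(numeric(64L), names(code$codons))
  stop_codon <- NA_character_
  stop_complete <- NA
  if (nzchar(rem)) {
    if (grepl("^T+$", rem)) {
      stop_codon <- rem
      stop_complete <- FALSE
    } else {
      warning("trailing remainder '", rem, "' is not a T/TT incomplete stop")
    }
  } else {
    last <- cods[n_full]
    if (!is.na(code$codons[last]) && code$codons[last] == "*") {
      stop_codon <- last
      stop_complete <- TRUE
      cods <- cods[-n_full]
    }
  }
  ok <- !grepl("[^ACGT]", cods)
  tab <- table(cods[ok])
  counts[names(tab)] <- as.numeric(tab)
  internal <- which(code$codons[cods] == "*" & ok)
  if (length(internal))
    warning("internal stop codon(s) at codon position(s) ",
            paste(internal, collapse = ", "))
  structure(list(counts = counts, start_codon = cods[1],
                 stop_codon = stop_codon, stop_complete = stop_complete,
                 n_skipped = sum(!ok), internal_stops = as.integer(internal)),
            class = "codon_counts")
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count of its synonymous
#' family: `RSCU(c) = count(c) * familySize / family total`. A value of 1
#' means no bias; values > 1 mark over-used codons. Stop codons are
#' excluded; a family with zero total gets `NA` RSCU. RSCU is invariant
#' under uniform scaling of the counts, so raw totals and per-gene means
#' give identical values.
#'
#' @param counts named numeric vector of per-codon counts (DNA or RNA codon
#'   names), or a `codon_counts` object.
#' @param code a [genetic_code()].
#' @return data.frame of class `codon_usage_table` with columns `codon`
#'   (RNA notation), `aa`, `count`, `rscu`, plus attribute
#'   `total_nonstop`.
#' @examples
#' rscu(c(UUU = 25.5, UUC = 4.5))[1, "rscu"]  # 1.70
#' @export
rscu <- function(counts, code = genetic_code()) {
  if (inherits(counts, "codon_counts")) counts <- counts$counts
  nm <- dna_codon(toupper(names(counts)))
  if (anyDuplicated(nm)) stop("duplicated codon names")
  full <- stats::setNames(numeric(64L), names(code$codons))
  unknown <- setdiff(nm, names(full))
  if (length(unknown)) stop("unknown codon(s): ", paste(unknown, collapse = ", "))
  full[nm] <- as.numeric(counts)
  if (any(full < 0)) stop("negative codon count")
  aa <- code$codons[names(full)]
  keep <- aa != "*"
  fam_tot <- tapply(full[keep], aa[keep], sum)
  fam_size <- table(aa[keep])
  val <- ifelse(keep & fam_tot[aa] > 0,
                full * as.numeric(fam_size[aa]) / as.numeric(fam_tot[aa]),
                ifelse(keep, NA_real_, 0))
  out <- data.frame(codon = rna_codon(names(full)), aa = unname(aa),
                    count = unname(full), rscu = unname(val),
                    stringsAsFactors = FALSE)
  attr(out, "total_nonstop") <- sum(full[keep])
  class(out) <- c("codon_usage_table", class(out))
  out
}

#' Amino-acid usage percentages
#'
#' Percentage of non-stop codons encoding each amino acid:
#' `100 * sum(counts of aa's codons) / total non-stop count`. Sums to 100
#' exactly at full precision.
#'
#' @inheritParams rscu
#' @return named numeric vector (one-letter amino acids), descending.
#' @export
aa_usage <- function(counts, code = genetic_code()) {
  if (inherits(counts, "codon_counts")) counts <- counts$counts
  tab <- rscu(counts, code)
  keep <- tab$aa != "*"
  tot <- sum(tab$count[keep])
  if (tot <= 0) stop("no non-stop codons counted")
  sort(100 * tapply(tab$count[keep], tab$aa[keep], sum) / tot,
       decreasing = TRUE)
}

#' Codon usage of a whole mitogenome
#'
#' Extracts every PCG in coding sense, counts codons per gene with
#' [count_codons()], and aggregates. Start codons are included in the
#' counts; terminal (complete or incomplete) stops are excluded. Counts are
#' reported both as raw totals and per-gene means (the form comparative
#' tables usually print); RSCU is identical for the two by scale
#' invariance.
#'
#' @param genome a [mitogenome()].
#' @param code a [genetic_code()].
#' @return List: `table` (a [rscu()] table with extra column `mean_count`),
#'   `aa_usage`, `start_stop` (data.frame gene/start/stop/complete),
#'   `total_nonstop`, `n_genes`.
#' @export
codon_usage_genome <- function(genome, code = genetic_code()) {
  pcgs <- genome$features[genome$features$ftype == "PCG", , drop = FALSE]
  if (!nrow(pcgs)) stop("genome has no PCG features")
  total <- stats::setNames(numeric(64L), names(code$codons))
  ss <- list()
  for (i in seq_len(nrow(pcgs))) {
    cc <- count_codons(extract_gene(genome, pcgs[i, ]), code)
    total <- total + cc$counts
    ss[[i]] <- data.frame(gene = pcgs$name[i], start_codon = cc$start_codon,
                          stop_codon = cc$stop_codon,
                          complete = cc$stop_complete,
                          stringsAsFactors = FALSE)
  }
  tab <- rscu(total, code)
  tab$mean_count <- tab$count / nrow(pcgs)
  list(table = tab, aa_usage = aa_usage(total, code),
       start_stop = do.call(rbind, ss),
       total_nonstop = attr(tab, "total_nonstop"), n_genes = nrow(pcgs))
}

#' Published codon counts for the N. lugens biotype-4 mitogenome
#'
#' The per-gene mean codon counts (counts averaged over the 13 PCGs)
#' published for the brown planthopper N. lugens biotype-4 mitogenome,
#' shipped as reference data for worked examples and checks.
#'
#' @return data.frame with columns `codon` (RNA notation), `aa`, `count`.
#' @export
nlugens_codon_counts <- function() {
  utils::read.delim(system.file("extdata", "nlugens_codon_counts.tsv",
                                package = "mitocomp"),
                    stringsAsFactors = FALSE)
}

#' Fold-degeneracy A+T profile across taxa
#'
#' Assigns every codon position of every gene to its degeneracy class
#' (0-fold: no synonymous change possible; 4-fold: all three changes
#' synonymous; 2-fold otherwise; see [fold_degeneracy()]) and reports the
#' A+T percentage of the bases at the sites of each class, per gene and
#' taxon, with the mean and SD across taxa. Terminal stop codons
#' (complete or incomplete) are excluded before profiling; codons
#' containing N are skipped.
#'
#' @param cds_sets named list (genes) of named character vectors (taxa) of
#'   in-frame coding sequences.
#' @param code a [genetic_code()].
#' @return List: `per_taxon` (data.frame gene/taxon/class/n_sites/pct_AT)
#'   and `summary` (gene/class/mean_pct_AT/sd_pct_AT/n_taxa).
#' @export
fold_class_profile <- function(cds_sets, code = genetic_code()) {
  deg <- fold_degeneracy(code)
  rows <- list()
  for (gene in names(cds_sets)) {
    for (taxon in names(cds_sets[[gene]])) {
      cds <- toupper(cds_sets[[gene]][[taxon]])
      cc <- count_codons(cds, code)  # strips terminal stop bookkeeping
      n_full <- nchar(cds) %/% 3L
      cods <- substring(cds, seq(1L, by = 3L, length.out = n_full),
                        seq(3L, by = 3L, length.out = n_full))
      if (isTRUE(cc$stop_complete)) cods <- cods[-length(cods)]
      at <- c(`0` = 0L, `2` = 0L, `4` = 0L)
      n <- c(`0` = 0L, `2` = 0L, `4` = 0L)
      for (cd in cods) {
        if (grepl("[^ACGT]", cd)) next
        cls <- deg[cd, ]
        if (anyNA(cls)) next  # stop codon (internal): no degeneracy class
        b <- strsplit(cd, "")[[1]]
        for (p in 1:3) {
          k <- as.character(cls[p])
          n[k] <- n[k] + 1L
          if (b[p] %in% c("A", "T")) at[k] <- at[k] + 1L
        }
      }
      for (k in c("0", "2", "4"))
        rows[[length(rows) + 1L]] <-
          data.frame(gene = gene, taxon = taxon,
                     class = paste0("P", k, "FD"), n_sites = n[[k]],
                     pct_AT = if (n[[k]] > 0) 100 * at[[k]] / n[[k]] else NA_real_,
                     stringsAsFactors = FALSE)
    }
  }
  per_taxon <- do.call(rbind, rows)
  agg <- do.call(data.frame, stats::aggregate(
    pct_AT ~ gene + class, data = per_taxon,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)),
    na.action = stats::na.omit))
  names(agg) <- c("gene", "class", "mean_pct_AT", "sd_pct_AT", "n_taxa")
  list(per_taxon = per_taxon, summary = agg)
}
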