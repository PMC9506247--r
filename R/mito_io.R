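#' Construct an annotated mitogenome
#'
#' The central data model: a (usually circular) mitochondrial genome given in
#' J-strand (majority-strand) orientation plus an ordered table of typed,
#' stranded gene features. Coordinates are 0-based half-open on the
#' linearized J-strand; a feature may span the origin of a circular genome,
#' encoded with `end > length` and interpreted modulo the genome length.
#'
#' @param id accession or label.
#' @param sequence DNA string over A/C/G/T/N, J-strand orientation.
#' @param features data.frame with columns `name`, `ftype` (one of `"PCG"`,
#'   `"tRNA"`, `"rRNA"`, `"control_region"`, `"other"`), `start`, `end`
#'   (0-based half-open), `strand` (`"+"` = J-strand, `"-"` = N-strand) and
#'   optionally `copy_index` (assigned per duplicate name if absent).
#' @param circular is the molecule circular? Origin-spanning features are
#'   only legal when `TRUE`.
#' @return An object of class `mitogenome`: list with `id`, `sequence`,
#'   `length`, `circular` and the validated, start-sorted `features` table.
#' @examples
#' g <- mitogenome("toy", strrep("ACGT", 25),
#'                 features = data.frame(name = "cox1", ftype = "PCG",
#'                                       start = 0, end = 30, strand = "+"))
#' g$length
#' @export
mitogenome <- function(id, sequence, features = NULL, circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  len <- nchar(sequence)
  if (is.null(features))
    features <- data.frame(name = character(), ftype = character(),
                           start = integer(), end = integer(),
                           strand = character(), copy_index = integer())
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("name", "ftype", "start", "end", "strand")
  miss <- setdiff(needed, names(features))
  if (length(miss)) stop("features lacks column(s): ", paste(miss, collapse = ", "))
  if (!"copy_index" %in% names(features)) features$copy_index <- NA_integer_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    bad <- which(!features$ftype %in%
                   c("PCG", "tRNA", "rRNA", "control_region", "other"))
    if (length(bad)) stop("unknown ftype: ", paste(unique(features$ftype[bad]), collapse = ", "))
    if (any(features$end <= features$start)) stop("feature with end <= start")
    if (any(features$end - features$start > len)) stop("feature longer than the genome")
    if (any(features$start < 0L | features$start >= len)) stop("feature start outside [0, length)")
    if (!circular && any(features$end > len))
      stop("feature exceeds the bounds of a linear genome")
    if (any(!features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    # number duplicate gene copies in start order unless provided
    features <- features[order(features$start, features$end), , drop = FALSE]
    na_ci <- is.na(features$copy_index)
    if (any(na_ci))
      features$copy_index[na_ci] <-
        stats::ave(seq_len(sum(na_ci)), features$name[na_ci], FUN = seq_along)
    features$copy_index <- as.integer(features$copy_index)
  }
  rownames(features) <- NULL
  structure(list(id = as.character(id), sequence = sequence, length = len,
                 circular = isTRUE(circular),
                 features = features[, c(needed, "copy_index")]),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("mitogenome '%s': %d bp, %s, %d features\n", x$id, x$length,
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

# --- gene-name normalisation -------------------------------------------

synonym_map <- function() {
  path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Map gene names to canonical mitochondrial symbols
#'
#' Case-insensitive lookup through the synonym table shipped with the
#' package (e.g. `COB`/`CYTB` to `cytb`, `ND4L` to `nad4l`, `12S` to
#' `rrnS`). Names already canonical pass through; unknown names are kept
#' as given.
#'
#' @param names character vector of gene names.
#' @return character vector of canonical symbols.
#' @export
canonical_gene_name <- function(names) {
  syn <- synonym_map()
  canon <- unique(c(syn$canonical,
                    paste0("cox", 1:3), paste0("nad", 1:6), "nad4l",
                    "atp6", "atp8", "cytb", "rrnS", "rrnL", "CR",
                    paste0("trn", c(LETTERS))))
  out <- character(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    hit <- match(toupper(nm), toupper(syn$synonym))
    if (!is.na(hit)) { out[i] <- syn$canonical[hit]; next }
    hit <- match(tolower(nm), tolower(canon))
    out[i] <- if (!is.na(hit)) canon[hit] else nm
  }
  # tRNAs keep their one-letter identity with original case of the rest
  ifelse(grepl("^trn", out, ignore.case = TRUE),
         paste0("trn", sub("^trn", "", out, ignore.case = TRUE)), out)
}

known_symbols <- function() {
  c(paste0("cox", 1:3), paste0("nad", 1:6), "nad4l", "atp6", "atp8", "cytb",
    "rrnS", "rrnL", "CR",
    paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                    "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y")))
}

ftype_to_gb <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                 control_region = "D-loop", other = "misc_feature")
gb_to_ftype <- c(CDS = "PCG", gene = "other", tRNA = "tRNA", rRNA = "rRNA",
                 "D-loop" = "control_region", misc_feature = "other")

# --- GenBank-style flat file -------------------------------------------

#' Read an annotated mitogenome
#'
#' Two dialects are supported. `"genbank"` reads a GenBank flat file
#' (LOCUS/FEATURES/ORIGIN) covering the feature keys CDS, tRNA, rRNA,
#' D-loop and misc_feature, with `complement(...)` strands and two-segment
#' `join(...)` locations for origin-spanning features. `"fasta+table"`
#' reads a FASTA sequence plus a tab-delimited feature table with columns
#' `name`, `ftype`, `start`, `end`, `strand`, `copy_index` (0-based
#' half-open coordinates). Gene names are passed through
#' [canonical_gene_name()]; names that remain unknown keep `ftype`
#' `"other"` with a warning.
#'
#' @param path file path (the FASTA file for `"fasta+table"`).
#' @param format `"genbank"` or `"fasta+table"`.
#' @param feature_table path of the feature table for `"fasta+table"`;
#'   defaults to `path` with its extension replaced by `.features.tsv`.
#' @return A validated [mitogenome()].
#' @export
read_mitogenome <- function(path, format = c("genbank", "fasta+table"),
                            feature_table = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "genbank") return(read_genbank(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record")
  if (is.null(feature_table))
    feature_table <- paste0(sub("\\.[^.]*$", "", path), ".features.tsv")
  if (!file.exists(feature_table)) stop("no such feature table: ", feature_table)
  ft <- utils::read.delim(feature_table, stringsAsFactors = FALSE)
  finish_read(id = sub("\\s.*$", "", names(seqs)[1]),
              sequence = as.character(seqs[[1]]), features = ft,
              circular = TRUE)
}

finish_read <- function(id, sequence, features, circular) {
  if (nrow(features)) {
    features$name <- canonical_gene_name(features$name)
    unknown <- !features$name %in% known_symbols()
    if (any(unknown)) {
      warning("unknown gene name(s) kept with ftype 'other': ",
              paste(unique(features$name[unknown]), collapse = ", "))
      features$ftype[unknown] <- "other"
    }
  }
  mitogenome(id, sequence, features, circular = circular)
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("no ORIGIN block in ", path)
  seq_lines <- lines[(ostart[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1):(ostart[1] - 1)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^\\s{1,10}\\S", ln) && !grepl("^\\s+/", ln)) {
        # feature key line: "  key  location"
        toks <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(toks) >= 2 && toks[1] %in% names(gb_to_ftype)) {
          if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
          cur <- list(key = toks[1], loc = toks[2], quals = character())
        } else if (!is.null(cur) && length(toks) == 1) {
          cur$loc <- paste0(cur$loc, toks[1])  # continued location
        } else {
          if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
          cur <- NULL  # e.g. source feature: ignore
        }
      } else if (!is.null(cur) && grepl("^\\s+/", ln)) {
        cur$quals <- c(cur$quals, trimws(ln))
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }
  L <- nchar(sequence)
  rows <- lapply(feats, function(f) {
    loc <- f$loc
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("^join\\(", loc)) {
      segs <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
      rng <- lapply(segs, parse_gb_range)
      if (length(rng) != 2L || rng[[2]][1] != 1L)
        stop("unsupported join location: ", f$loc)
      start <- rng[[1]][1] - 1L
      end <- L + rng[[2]][2]
    } else {
      rng <- parse_gb_range(loc)
      start <- rng[1] - 1L
      end <- rng[2]
    }
    gene <- sub('^/gene="?([^"]*)"?$', "\\1",
                grep("^/gene=", f$quals, value = TRUE)[1])
    ci <- grep("^/copy_index=", f$quals, value = TRUE)
    copy_index <- if (length(ci)) as.integer(sub("^/copy_index=", "", ci[1])) else NA_integer_
    data.frame(name = if (is.na(gene)) "unknown" else gene,
               ftype = unname(gb_to_ftype[f$key]), start = start, end = end,
               strand = strand, copy_index = copy_index,
               stringsAsFactors = FALSE)
  })
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), ftype = character(), start = integer(),
               end = integer(), strand = character(), copy_index = integer())
  finish_read(id, sequence, features, circular)
}

parse_gb_range <- function(x) {
  m <- regmatches(x, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", x))[[1]]
  if (length(m) != 3) stop("cannot parse location: ", x)
  c(as.integer(m[2]), as.integer(m[3]))
}

#' Write an annotated mitogenome
#'
#' Inverse of [read_mitogenome()]; `"genbank"` writes the flat-file dialect
#' that [read_mitogenome()] parses (1-based inclusive coordinates,
#' `complement()` for N-strand features, `join()` across the origin),
#' `"fasta+table"` writes a FASTA file plus a `.features.tsv` table in the
#' internal 0-based half-open convention. Round-trips are exact.
#'
#' @param genome a [mitogenome()].
#' @param path output path (FASTA path for `"fasta+table"`).
#' @param format `"genbank"` or `"fasta+table"`.
#' @return `path`, invisibly.
#' @export
write_mitogenome <- function(genome, path, format = c("genbank", "fasta+table")) {
  format <- match.arg(format)
  if (format == "fasta+table") {
    writeLines(c(paste0(">", genome$id),
                 gsub("(.{70})", "\\1\n", genome$sequence, perl = TRUE)), path)
    tab <- paste0(sub("\\.[^.]*$", "", path), ".features.tsv")
    utils::write.table(genome$features, tab, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  L <- genome$length
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s", genome$id, L,
                   if (genome$circular) "circular" else "linear"),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    loc <- if (f$end <= L) sprintf("%d..%d", f$start + 1L, f$end) else
      sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end - L)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-15s %s", ftype_to_gb[[f$ftype]], loc),
             sprintf('                     /gene="%s"', f$name),
             sprintf("                     /copy_index=%d", f$copy_index))
  }
  out <- c(out, "ORIGIN")
  sq <- tolower(genome$sequence)
  starts <- seq(1L, L, by = 60L)
  for (s in starts) {
    chunk <- substr(sq, s, min(s + 59L, L))
    blocks <- gsub("(.{10})", "\\1 ", chunk, perl = TRUE)
    out <- c(out, sprintf("%9d %s", s, trimws(blocks)))
  }
  writeLines(c(out, "//"), path)
  invisible(path)
}

# --- gene extraction ---------------------------------------------------

#' Extract a gene sequence in coding sense
#'
#' Returns the coding-sense sequence of a feature: the J-strand slice for
#' `+` features, its reverse complement for `-` features. Origin-spanning
#' features (`end > length`) are unwrapped modulo the genome length; the
#' returned string always has length `end - start`.
#'
#' @param genome a [mitogenome()].
#' @param feature a one-row slice of `genome$features`, a feature row index,
#'   or a gene name (first copy taken).
#' @return DNA string.
#' @export
extract_gene <- function(genome, feature) {
  if (is.character(feature)) {
    idx <- which(genome$features$name == feature)
    if (!length(idx)) stop("no feature named '", feature, "'")
    feature <- genome$features[idx[1], ]
  } else if (is.numeric(feature)) {
    feature <- genome$features[feature, ]
  }
  if (!nrow(merge(feature, genome$features)))
    stop("feature does not belong to this genome")
  L <- genome$length
  s <- feature$start; e <- feature$end
  raw <- if (e <= L) substr(genome$sequence, s + 1L, e) else
    paste0(substr(genome$sequence, s + 1L, L), substr(genome$sequence, 1L, e - L))
  if (feature$strand == "-") revcomp(raw) else raw
}

# --- alignments --------------------------------------------------------

#' Construct a gene alignment
#'
#' @param rows named character vector of equal-length aligned DNA strings
#'   (gap symbol `-`), names = taxon ids.
#' @param gene gene symbol the alignment belongs to.
#' @param codon_aligned declared by the caller (a flag, not inferred from
#'   content); if `TRUE`, row length must be divisible by 3.
#' @return An object of class `gene_alignment`: list with `gene`, `taxa`,
#'   `rows`, `codon_aligned`, `length`.
#' @export
gene_alignment <- function(rows, gene = NA_character_, codon_aligned = FALSE) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by taxon")
  if (anyDuplicated(names(rows)))
    stop("duplicate taxon id: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("ragged alignment rows")
  if (codon_aligned && widths[1] %% 3L != 0L)
    stop("codon-aligned rows must have length divisible by 3")
  structure(list(gene = gene, taxa = names(rows), rows = rows,
                 codon_aligned = isTRUE(codon_aligned),
                 length = unname(widths[1])),
            class = "gene_alignment")
}

#' Read a FASTA alignment
#'
#' @param path FASTA file with equal-length rows.
#' @inheritParams gene_alignment
#' @return A [gene_alignment()]; taxon order is file order, sequence
#'   uppercased.
#' @export
read_alignment <- function(path, gene = NA_character_, codon_aligned = FALSE) {
  seqs <- Biostrings::readBStringSet(path)
  rows <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  gene_alignment(rows, gene = gene, codon_aligned = codon_aligned)
}

#' Write a gene alignment as FASTA
#' @param aln a [gene_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  out <- character(0)
  for (tx in aln$taxa)
    out <- c(out, paste0(">", tx), gsub("(.{70})", "\\1\n", aln$rows[[tx]], perl = TRUE))
  writeLines(out, path)
  invisible(path)
}

# Character matrix view (taxa x columns) used by divergence stages.
alignment_matrix <- function(aln) {
  do.call(rbind, lapply(aln$rows, seq_chars))
}
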