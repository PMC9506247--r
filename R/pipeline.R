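#' Configuration for a full analysis run
#'
#' Validated up front; a serialized copy is written into the output
#' directory by [run_all()] so every bundle records how it was produced.
#'
#' @param genomes list of [mitogenome()] objects, or paths readable by
#'   [read_mitogenome()].
#' @param alignments optional named list of codon-aligned
#'   [gene_alignment()]s for the divergence and supermatrix stages; when
#'   NULL those stages run only if PCGs shared by >= 2 genomes can be
#'   extracted directly (equal-length, which synthetic genomes guarantee).
#' @param out_dir output directory (created if needed).
#' @param code_id NCBI genetic code table id (default 5).
#' @param window,step sliding-window parameters for Pi, bp.
#' @param repeat_unit_range unit lengths scanned by the repeat finder.
#' @param reference_order `"ancestral"` or a `gene_order` object.
#' @param seed seed forwarded to every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(genomes, alignments = NULL, out_dir = tempfile("mitocomp_"),
                       code_id = 5, window = 200L, step = 20L,
                       repeat_unit_range = c(5L, 50L),
                       reference_order = "ancestral", seed = 1L) {
  if (!length(genomes)) stop("need at least one genome")
  genomes <- lapply(genomes, function(g)
    if (inherits(g, "mitogenome")) g else read_mitogenome(g))
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  ref <- if (identical(reference_order, "ancestral")) ancestral_gene_order()
         else reference_order
  if (!inherits(ref, "gene_order")) stop("invalid reference_order")
  structure(list(genomes = genomes, alignments = alignments,
                 out_dir = out_dir, code_id = code_id,
                 window = as.integer(window), step = as.integer(step),
                 repeat_unit_range = as.integer(repeat_unit_range),
                 reference_order = ref, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(format(x, digits = 6, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

#' Run every applicable analysis stage
#'
#' Orchestrates the whole pipeline over the configured genomes:
#' composition tables, codon usage and RSCU, start/stop classification,
#' gene order and rearrangement report, spacer/overlap table,
#' control-region repeats and poly-T, and — when >= 2 taxa share
#' codon-aligned PCGs — fold-class profiling, sliding-window Pi, Ka/Ks
#' rates, the PCG123 supermatrix with partitions, and a neighbor-joining
#' tree. A stage whose prerequisites are absent is skipped with a logged
#' reason; a stage that errors is recorded and independent stages still
#' run. All randomness flows through the configured seed, so a rerun with
#' the same config is identical apart from timestamps (confined to the
#' log).
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: `outputs` (named file paths),
#'   `skipped` (named reasons), `errors` (named messages), `summary_path`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  code <- genetic_code(config$code_id)
  outputs <- list(); skipped <- list(); errors <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  out <- function(name) file.path(config$out_dir, name)
  stage <- function(name, expr) {
    res <- tryCatch({expr; note("stage ", name, ": ok"); TRUE},
                    error = function(e) {
                      errors[[name]] <<- conditionMessage(e)
                      note("stage ", name, ": ERROR ", conditionMessage(e))
                      FALSE
                    })
    invisible(res)
  }
  genomes <- config$genomes

  stage("composition", {
    tabs <- do.call(rbind, lapply(genomes, function(g) {
      tb <- compose_by_class(g); tb$taxon <- g$id; tb
    }))
    outputs$composition <- write_tsv(tabs, out("composition_by_class.tsv"))
    outputs$skew_table <- write_tsv(skew_scatter_table(genomes),
                                     out("skew_table.tsv"))
  })

  stage("codon_usage", {
    rows <- list(); ss <- list()
    for (g in genomes) {
      cu <- codon_usage_genome(g, code)
      tb <- cu$table; tb$taxon <- g$id
      rows[[g$id]] <- tb
      s <- cu$start_stop; s$taxon <- g$id
      ss[[g$id]] <- s
    }
    outputs$codon_usage <- write_tsv(do.call(rbind, rows), out("codon_usage.tsv"))
    outputs$start_stop <- write_tsv(do.call(rbind, ss), out("start_stop.tsv"))
  })

  stage("architecture", {
    reports <- lapply(genomes, function(g) {
      go <- gene_order(g)
      cmp <- compare_orders(go, config$reference_order)
      so <- spacers_overlaps(g)
      list(taxon = g$id,
           order = paste0(ifelse(go$order$strand == "-", "-", ""),
                          go$order$name, collapse = " "),
           breakpoints = cmp$breakpoints, moved = cmp$moved_genes,
           duplicated = cmp$duplicated,
           n_spacers = so$n_spacers, spacer_bp = so$spacer_bp,
           n_overlaps = so$n_overlaps, overlap_bp = so$overlap_bp,
           cr_length = so$cr_length)
    })
    outputs$architecture <- out("architecture.json")
    jsonlite::write_json(reports, outputs$architecture, auto_unbox = TRUE,
                         pretty = TRUE)
  })

  stage("control_region", {
    rows <- list()
    for (g in genomes) {
      crf <- g$features[g$features$ftype == "control_region", , drop = FALSE]
      if (!nrow(crf)) next
      cr <- extract_gene(g, crf[1, ])
      reps <- find_tandem_repeats(cr, config$repeat_unit_range)
      pt <- longest_polyT(cr)
      rows[[g$id]] <- list(taxon = g$id, repeats = reps,
                           polyT_length = pt$length, polyT_start = pt$start)
    }
    if (!length(rows)) {
      skipped$control_region <- "no genome has a control region"
      note("stage control_region: skipped (no CR)")
    } else {
      outputs$control_region <- out("control_region.json")
      jsonlite::write_json(rows, outputs$control_region, auto_unbox = TRUE,
                           pretty = TRUE)
    }
  })

  # shared codon alignments for the divergence stages
  alns <- config$alignments
  if (is.null(alns) && length(genomes) >= 2L) {
    alns <- tryCatch(shared_pcg_alignments(genomes), error = function(e) NULL)
  }
  if (is.null(alns) || length(alns) == 0L ||
      length(genomes) < 2L && is.null(config$alignments)) {
    msg <- if (length(genomes) < 2L) "divergence stages need >= 2 taxa"
           else "no shared equal-length PCGs and no alignments supplied"
    for (nm in c("fold_classes", "diversity", "rates", "phylo"))
      skipped[[nm]] <- msg
    note("divergence stages skipped: ", msg)
  } else {
    stage("fold_classes", {
      sets <- lapply(alns, function(a) a$rows)
      prof <- fold_class_profile(sets, code)
      outputs$fold_classes <- write_tsv(prof$summary, out("fold_classes.tsv"))
    })
    stage("diversity", {
      rows <- lapply(names(alns), function(g) {
        dp <- sliding_pi(alns[[g]], min(config$window, alns[[g]]$length),
                         config$step)
        w <- dp$windows; w$gene <- g; w
      })
      outputs$diversity <- write_tsv(do.call(rbind, rows), out("diversity.tsv"))
      per_gene <- do.call(rbind, lapply(names(alns), function(g) {
        dp <- sliding_pi(alns[[g]], alns[[g]]$length, alns[[g]]$length)
        data.frame(gene = g, pi = dp$gene_pi,
                   mean_p_distance = dp$mean_p_distance,
                   mean_jc_distance = dp$mean_jc_distance)
      }))
      outputs$diversity_per_gene <- write_tsv(per_gene,
                                               out("diversity_per_gene.tsv"))
    })
    stage("rates", {
      outputs$rates <- write_tsv(gene_rates(alns, code), out("gene_rates.tsv"))
    })
    stage("phylo", {
      sm <- concatenate(alns, gap_fill = TRUE)
      outputs$supermatrix <- out("supermatrix.fasta")
      write_supermatrix(sm, outputs$supermatrix)
      outputs$partitions <- out("partitions.txt")
      write_partitions(sm, outputs$partitions)
      m <- do.call(rbind, lapply(sm$rows, seq_chars))
      n <- length(sm$taxa)
      d <- matrix(0, n, n, dimnames = list(sm$taxa, sm$taxa))
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        p <- pairwise_p_distance(sm$rows[[i]], sm$rows[[j]])
        d[i, j] <- d[j, i] <- suppressWarnings(jc_distance(p))
      }
      if (any(!is.finite(d))) stop("saturated or missing pairwise distances")
      outputs$tree <- out("nj_tree.nwk")
      write_newick(nj_tree(d), outputs$tree)
    })
  }

  summary <- list(package = "mitocomp",
                  version = as.character(utils::packageVersion("mitocomp")),
                  n_genomes = length(genomes),
                  taxa = vapply(genomes, `[[`, character(1), "id"),
                  seed = config$seed, code_id = config$code_id,
                  window = config$window, step = config$step,
                  outputs = lapply(outputs, basename),
                  skipped = skipped, errors = errors)
  summary_path <- out("summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, out("run.log"))
  structure(list(outputs = outputs, skipped = skipped, errors = errors,
                 summary_path = summary_path, ok = length(errors) == 0L),
            class = "run_report")
}

# Codon alignments of PCGs shared by all genomes, built by direct
# extraction (terminal stops trimmed); genes whose extracted CDS lengths
# differ across taxa are dropped (no aligner is run here).
shared_pcg_alignments <- function(genomes) {
  ids <- vapply(genomes, `[[`, character(1), "id")
  genes <- Reduce(intersect, lapply(genomes, function(g)
    g$features$name[g$features$ftype == "PCG"]))
  out <- list()
  for (gn in genes) {
    rows <- stats::setNames(vapply(genomes, function(g) {
      cds <- extract_gene(g, gn)
      cc <- suppressWarnings(count_codons(cds, genetic_code()))
      drop <- if (isTRUE(cc$stop_complete)) 3L else
        if (isFALSE(cc$stop_complete)) nchar(cc$stop_codon) else 0L
      substr(cds, 1L, nchar(cds) - drop)
    }, character(1)), ids)
    if (length(unique(nchar(rows))) == 1L && nchar(rows[1]) %% 3L == 0L)
      out[[gn]] <- gene_alignment(rows, gene = gn, codon_aligned = TRUE)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", length(x$outputs), "outputs,", length(x$skipped),
      "skipped,", length(x$errors), "errors\n")
  invisible(x)
}
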