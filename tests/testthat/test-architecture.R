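test_that("gene_order rotates to the anchor and keeps duplicates", {
  gg <- generate_genome(genome_blueprint(seed = 4))
  go <- gene_order(gg$genome)
  expect_equal(go$order$name[1:4], c("trnI", "trnQ", "trnM", "nad2"))
  expect_equal(sum(go$order$name == "trnC"), 2)
  expect_equal(sort(go$order$copy_index[go$order$name == "trnC"]), c(1L, 2L))
  expect_false("CR" %in% go$order$name)
  # absent anchor falls back with a warning
  expect_warning(go2 <- gene_order(gg$genome, anchor = "nope"), "absent")
  expect_equal(go2$anchor, go2$order$name[1])
})

test_that("identical orders give zero breakpoints", {
  anc <- ancestral_gene_order()
  cmp <- compare_orders(anc, anc)
  expect_equal(cmp$breakpoints, 0)
  expect_length(cmp$moved_genes, 0)
  # rotation does not create breakpoints on a circle
  rot <- anc
  rot$order <- rbind(anc$order[10:nrow(anc$order), ], anc$order[1:9, ])
  expect_equal(compare_orders(rot, anc)$breakpoints, 0)
})

test_that("an adjacent transposition disrupts 3 adjacencies (oracle check)", {
  mk <- function(names) structure(
    list(taxon = "q", anchor = names[1],
         order = data.frame(name = names, strand = "+", copy_index = 1L)),
    class = "gene_order")
  ref_names <- paste0("g", 1:10)
  qry_names <- ref_names; qry_names[4:5] <- qry_names[5:4]
  cmp <- compare_orders(mk(qry_names), mk(ref_names))
  # brute-force adjacency-set oracle
  adj <- function(v) paste(v, c(v[-1], v[1]), sep = ">")
  oracle <- sum(!adj(qry_names) %in% adj(ref_names))
  expect_equal(oracle, 3)
  expect_equal(cmp$breakpoints, oracle)
  expect_setequal(cmp$moved_genes, c("g3", "g4", "g5", "g6"))
  # symmetry for permutation-only differences
  expect_equal(compare_orders(mk(ref_names), mk(qry_names))$breakpoints, 3)
})

test_that("strand changes count as rearrangement", {
  base <- data.frame(name = paste0("g", 1:6), strand = "+", copy_index = 1L)
  flip <- base; flip$strand[3] <- "-"
  mk <- function(ord) structure(list(taxon = "x", anchor = ord$name[1],
                                     order = ord), class = "gene_order")
  cmp <- compare_orders(mk(flip), mk(base))
  expect_equal(cmp$breakpoints, 2)
  expect_true("g3" %in% cmp$moved_genes)
})

test_that("the nlugens-like order is flagged against the ancestral reference", {
  gg <- generate_genome(genome_blueprint(seed = 6))
  cmp <- compare_orders(gene_order(gg$genome), ancestral_gene_order())
  expect_true(all(c("trnC", "trnW", "nad6", "trnP", "trnT") %in% cmp$moved_genes))
  expect_equal(cmp$duplicated$gene, "trnC")
  expect_equal(cmp$duplicated$copies, 2L)
  expect_length(cmp$missing, 0)
  expect_gt(cmp$breakpoints, 0)
})

test_that("spacer and overlap arithmetic is exact", {
  mk <- function(starts, ends) mitogenome("x", strrep("A", 300),
    features = data.frame(name = paste0("g", seq_along(starts)), ftype = "tRNA",
                          start = starts, end = ends, strand = "+"))
  # abutting
  so <- spacers_overlaps(mk(c(0, 100), c(100, 200)))
  expect_equal(so$boundaries$gap[1], 0)
  expect_equal(so$n_spacers, 1)          # only the wrap boundary 200 -> 0+300
  expect_equal(so$spacer_bp, 100)
  # spacer 4
  so <- spacers_overlaps(mk(c(0, 104), c(100, 200)))
  expect_equal(so$boundaries$gap[1], 4)
  # overlap 5
  so <- spacers_overlaps(mk(c(0, 95), c(100, 200)))
  expect_equal(so$boundaries$gap[1], -5)
  expect_equal(so$n_overlaps, 1)
  expect_equal(so$overlap_bp, 5)
})

test_that("nested features are excluded from boundary math and listed", {
  g <- mitogenome("x", strrep("A", 200), features = data.frame(
    name = c("big", "inner", "next"), ftype = c("rRNA", "tRNA", "tRNA"),
    start = c(0, 20, 120), end = c(100, 50, 180), strand = "+"))
  so <- suppressWarnings(spacers_overlaps(g))
  expect_equal(so$nested$name, "inner")
  expect_false("inner" %in% so$boundaries$left)
  expect_equal(nrow(so$boundaries), 2)
})

test_that("circular tiling identity holds on generated genomes", {
  for (sd in c(1, 9)) {
    g <- generate_genome(genome_blueprint(seed = sd))$genome
    so <- spacers_overlaps(g, include_cr = TRUE)
    expect_equal(sum(g$features$end - g$features$start) +
                   so$spacer_bp - so$overlap_bp,
                 g$length)
    expect_equal(nrow(so$nested), 0)
  }
})

test_that("tandem repeat finder handles exact toys and edge cases", {
  reps <- find_tandem_repeats("ACGACGACG", c(3, 3), 3)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$unit, "ACG")
  expect_equal(reps$copies, 3)
  expect_equal(c(reps$start, reps$end), c(0, 9))
  expect_equal(nrow(find_tandem_repeats("ACGTACGTTGCA", c(5, 6), 3)), 0)
  # reported arrays verify copy-by-copy and never overlap
  region <- paste0("TTT", strrep("ACGGT", 4), "CC", strrep("TTAGGC", 3), "A")
  reps <- find_tandem_repeats(region, c(4, 8), 3, max_variable_positions = 0)
  expect_gte(nrow(reps), 2)
  for (i in seq_len(nrow(reps))) {
    arr <- substr(region, reps$start[i] + 1, reps$end[i])
    expect_equal(arr, strrep(reps$unit[i], reps$copies[i]))
  }
  spans <- unlist(lapply(seq_len(nrow(reps)), function(i)
    (reps$start[i] + 1):reps$end[i]))
  expect_false(anyDuplicated(spans) > 0)
})

test_that("the planted control-region repeat array is recovered", {
  gg <- generate_genome(genome_blueprint(seed = 13))
  g <- gg$genome; tr <- gg$truth
  cr <- extract_gene(g, g$features[g$features$ftype == "control_region", ][1, ])
  reps <- find_tandem_repeats(cr)
  top <- reps[which.max(reps$copies), ]
  expect_equal(top$unit_len, tr$cr$unit_len)
  expect_equal(top$copies, tr$cr$copies)
  expect_equal(top$start, tr$cr$repeat_start - tr$cr$start)
  expect_equal(top$unit, tr$cr$unit)  # R consensus at the alternating base
})

test_that("longest poly-T run is found leftmost", {
  expect_equal(longest_polyT("AAATTTTG"), list(length = 4L, start = 3L))
  expect_equal(longest_polyT("TTAATT"), list(length = 2L, start = 0L))
  expect_equal(longest_polyT("AAAA"), list(length = 0L, start = NA_integer_))
  gg <- generate_genome(genome_blueprint(seed = 17))
  g <- gg$genome; tr <- gg$truth
  cr <- extract_gene(g, g$features[g$features$ftype == "control_region", ][1, ])
  pt <- longest_polyT(cr)
  expect_equal(pt$length, tr$cr$polyT_length)
  expect_equal(pt$start, tr$cr$polyT_start - tr$cr$start)
})
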