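test_that("mitogenome validates and sorts its feature table", {
  g <- toy_genome()
  expect_s3_class(g, "mitogenome")
  expect_equal(g$length, nchar(g$sequence))
  expect_equal(g$features$name, c("cox1", "trnC", "CR"))
  expect_true(!is.unsorted(g$features$start))

  expect_error(mitogenome("x", ""), "empty")
  expect_error(mitogenome("x", "ACGTX"), "outside")
  expect_error(
    mitogenome("x", strrep("A", 10),
               features = data.frame(name = "g", ftype = "PCG",
                                     start = 5, end = 5, strand = "+")),
    "end <= start")
  expect_error(
    mitogenome("x", strrep("A", 10), circular = FALSE,
               features = data.frame(name = "g", ftype = "PCG",
                                     start = 8, end = 12, strand = "+")),
    "linear")
})

test_that("duplicate gene copies are numbered in positional order", {
  g <- mitogenome("x", strrep("ACGT", 30), features = data.frame(
    name = c("trnC", "nad2", "trnC"), ftype = c("tRNA", "PCG", "tRNA"),
    start = c(50, 0, 90), end = c(60, 40, 100), strand = "+"))
  tc <- g$features[g$features$name == "trnC", ]
  expect_equal(tc$copy_index, c(1L, 2L))
  expect_equal(tc$start, c(50L, 90L))
})

test_that("extract_gene honours strand and the coordinate convention", {
  g <- mitogenome("x", "ATGAAACCCGGG", features = data.frame(
    name = c("cox1", "cox2"), ftype = "PCG", start = c(0, 0),
    end = c(6, 6), strand = c("+", "-")))
  expect_equal(extract_gene(g, g$features[1, ]), "ATGAAA")
  expect_equal(extract_gene(g, g$features[2, ]), "TTTCAT")
  # length contract: end - start, for every feature of the toy genome
  tg <- toy_genome()
  for (i in seq_len(nrow(tg$features)))
    expect_equal(nchar(extract_gene(tg, i)),
                 tg$features$end[i] - tg$features$start[i])
})

test_that("origin-spanning features unwrap modulo the genome length", {
  set.seed(11)
  seq <- paste(sample(BASES, 1000, replace = TRUE), collapse = "")
  g <- mitogenome("x", seq, features = data.frame(
    name = "CR", ftype = "control_region", start = 900, end = 1100,
    strand = "+"))
  got <- extract_gene(g, g$features[1, ])
  expect_equal(nchar(got), 200)
  expect_equal(got, paste0(substr(seq, 901, 1000), substr(seq, 1, 100)))
  # reverse-complement composition on a 12 bp toy: '-' wrap equals
  # revcomp of the '+' unwrapped slice, built by hand
  g2 <- mitogenome("y", "AACCGGTTACGT", features = data.frame(
    name = c("nad1", "nad2"), ftype = "PCG", start = c(8, 8), end = c(16, 16),
    strand = c("-", "+")))
  plus <- extract_gene(g2, g2$features[g2$features$strand == "+", ])
  expect_equal(plus, "ACGTAACC")
  expect_equal(extract_gene(g2, g2$features[g2$features$strand == "-", ]),
               "GGTTACGT")
})

test_that("minus-strand extraction equals revcomp of the plus slice (property)", {
  set.seed(42)
  for (rep in 1:20) {
    L <- sample(60:200, 1)
    seq <- paste(sample(BASES, L, replace = TRUE), collapse = "")
    s <- sample(0:(L - 1), 1)
    w <- sample(3:min(50, L), 1)
    f <- data.frame(name = c("a", "b"), ftype = "PCG", start = s, end = s + w,
                    strand = c("+", "-"))
    g <- mitogenome("p", seq, f)
    plus <- extract_gene(g, g$features[g$features$strand == "+", ])
    minus <- extract_gene(g, g$features[g$features$strand == "-", ])
    expect_equal(minus, mitocomp:::revcomp(plus))
  }
})

test_that("gene-name synonyms map to canonical symbols", {
  expect_equal(canonical_gene_name(c("CYTB", "COB", "ND4L", "12S", "cox1")),
               c("cytb", "cytb", "nad4l", "rrnS", "cox1"))
  expect_equal(canonical_gene_name("made_up_gene"), "made_up_gene")
})

test_that("GenBank round trip reproduces the genome exactly", {
  gg <- generate_genome(genome_blueprint(seed = 3))
  g <- gg$genome
  path <- withr::local_tempfile(fileext = ".gb")
  write_mitogenome(g, path, format = "genbank")
  back <- read_mitogenome(path, format = "genbank")
  expect_identical(back$id, g$id)
  expect_identical(back$sequence, g$sequence)
  expect_identical(back$length, g$length)
  expect_identical(back$features, g$features)
})

test_that("fasta+table round trip and a minimal GenBank record parse", {
  g <- toy_genome()
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_mitogenome(g, fa, format = "fasta+table")
  back <- read_mitogenome(fa, format = "fasta+table")
  expect_identical(back$sequence, g$sequence)
  expect_identical(back$features, g$features)

  # minimal two-gene record written by hand
  gb <- withr::local_tempfile(fileext = ".gb")
  set.seed(1)
  seqtxt <- paste(sample(BASES, 1000, replace = TRUE), collapse = "")
  g0 <- mitogenome("mini", seqtxt, features = data.frame(
    name = c("cox1", "nad1"), ftype = "PCG", start = c(0, 400),
    end = c(300, 700), strand = c("+", "-")))
  write_mitogenome(g0, gb)
  back <- read_mitogenome(gb)
  expect_equal(nrow(back$features), 2)
  expect_equal(back$features$name, c("cox1", "nad1"))
  expect_equal(back$features$strand, c("+", "-"))
})

test_that("unknown feature names are kept as ftype 'other' with a warning", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_mitogenome(g, path, format = "fasta+table")
  tab <- paste0(sub("\\.[^.]*$", "", path), ".features.tsv")
  ft <- read.delim(tab)
  ft$name[1] <- "mystery"
  write.table(ft, tab, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(back <- read_mitogenome(path, format = "fasta+table"),
                 "mystery")
  expect_equal(back$features$ftype[back$features$name == "mystery"], "other")
})

test_that("alignment reader enforces shape and uppercases", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "acgtacgta", ">t2", "ACGTACGTT"), path)
  aln <- read_alignment(path, gene = "cox1")
  expect_equal(aln$taxa, c("t1", "t2"))
  expect_equal(aln$rows[["t1"]], "ACGTACGTA")
  expect_equal(aln$length, 9)

  writeLines(c(">t1", "ACGT", ">t1", "ACGT"), path)
  expect_error(read_alignment(path), "duplicate taxon")
  writeLines(c(">t1", "ACGT", ">t2", "ACG"), path)
  expect_error(read_alignment(path), "ragged")
  # round trip preserves content
  writeLines(c(">t1", "acg-acgta", ">t2", "ACGTACGTT"), path)
  aln <- read_alignment(path)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  expect_identical(read_alignment(out)$rows, aln$rows)
})
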