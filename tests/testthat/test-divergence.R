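test_that("p-distance uses pairwise deletion", {
  expect_equal(pairwise_p_distance("ACGT", "ACGT"), 0)
  expect_equal(pairwise_p_distance(strrep("A", 100),
                                   paste0(strrep("A", 99), "C")), 0.01)
  expect_equal(pairwise_p_distance("A-CG", "AGCG"), 0)   # gap column dropped
  expect_equal(pairwise_p_distance("ANCG", "AGCT"), 1 / 3)
  expect_true(is.na(pairwise_p_distance("----", "AAAA")))
  expect_error(pairwise_p_distance("AC", "ACG"), "length")
})

test_that("Jukes-Cantor correction matches the closed form and its properties", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.3), -0.75 * log(1 - 4 * 0.3 / 3))
  expect_equal(jc_distance(0.3), 0.383119, tolerance = 1e-6)
  expect_warning(d <- jc_distance(0.75), "saturated")
  expect_true(is.na(d))
  # monotone increasing and >= p on a grid
  p <- seq(0, 0.74, by = 0.01)
  d <- jc_distance(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("sliding Pi reduces to p-distance for two sequences", {
  rows <- c(t1 = strrep("A", 100), t2 = paste0(strrep("A", 50), "C", strrep("A", 49)))
  aln <- gene_alignment(rows, gene = "g")
  dp <- sliding_pi(aln, window = 100, step = 10)
  expect_equal(dp$windows$pi, 0.01)
  expect_equal(dp$gene_pi, 0.01)
  # all-identical alignment: Pi = 0 everywhere
  same <- gene_alignment(c(a = strrep("ACGT", 30), b = strrep("ACGT", 30),
                           c = strrep("ACGT", 30)))
  expect_true(all(sliding_pi(same, 40, 20)$windows$pi == 0))
})

test_that("Pi equals the brute-force mean over pairs on a 4-row toy", {
  rows <- c(t1 = "AAAAAAAA", t2 = "AAAAAACA", t3 = "CAAAAAAA", t4 = "CAAAAACA")
  aln <- gene_alignment(rows)
  pairs <- combn(4, 2)
  oracle <- mean(apply(pairs, 2, function(ij)
    pairwise_p_distance(rows[ij[1]], rows[ij[2]])))
  dp <- sliding_pi(aln, window = 8, step = 8)
  expect_equal(dp$gene_pi, oracle)
  expect_equal(dp$windows$pi[1], oracle)
  # window = alignment length equals per-gene Pi (invariant)
  expect_equal(sliding_pi(aln, 8, 3)$gene_pi, oracle)
})

test_that("windows tile the alignment and empty-pair windows stay as NA", {
  rows <- c(a = paste0(strrep("A", 50), strrep("-", 50)),
            b = paste0(strrep("A", 50), strrep("-", 50)))
  aln <- gene_alignment(rows)
  dp <- sliding_pi(aln, window = 20, step = 20)
  expect_equal(dp$windows$start, c(0, 20, 40, 60, 80))
  expect_true(is.na(dp$windows$pi[4]))   # all-gap window kept, value missing
  expect_equal(dp$windows$pi[1], 0)
})

test_that("Nei-Gojobori reproduces the worked single-codon case exactly", {
  ng <- nei_gojobori("TTT", "TTA")
  expect_equal(ng$S_sites, 0.5)
  expect_equal(ng$N_sites, 2.5)
  expect_equal(ng$pN, 0.4)
  expect_equal(ng$pS, 0)
  ng0 <- nei_gojobori("ATGCTA", "ATGCTA")
  expect_equal(ng0$pN, 0)
  expect_equal(ng0$pS, 0)
})

test_that("site counts always satisfy N + S = 3 x compared codons", {
  set.seed(31)
  sense <- all_sense_codons()
  for (i in 1:20) {
    a <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    b <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    ng <- nei_gojobori(a, b)
    expect_equal(ng$N_sites + ng$S_sites, 3 * ng$n_codons)
  }
})

test_that("pathway counting equals the exhaustive oracle on all <=2-difference pairs", {
  sense <- all_sense_codons()
  pairs <- 0L
  for (c1 in sense) for (c2 in sense) {
    nd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (nd == 0 || nd > 2) next
    got <- mitocomp:::ng_pathways(c1, c2, genetic_code())
    want <- oracle_ng_pathways(c1, c2)
    expect_equal(got$syn, want$syn, label = paste(c1, c2))
    expect_equal(got$nonsyn, want$nonsyn, label = paste(c1, c2))
    expect_equal(got$n_path, want$n_path, label = paste(c1, c2))
    pairs <- pairs + 1L
  }
  expect_gt(pairs, 1000)
})

test_that("pathway counting equals the oracle on random pairs incl. 3 differences", {
  set.seed(77)
  sense <- all_sense_codons()
  code <- genetic_code()
  for (i in 1:500) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    got <- mitocomp:::ng_pathways(c1, c2, code)
    want <- oracle_ng_pathways(c1, c2)
    expect_equal(got$syn, want$syn, label = paste(c1, c2))
    expect_equal(got$nonsyn, want$nonsyn, label = paste(c1, c2))
  }
  # per-codon site fractions against the 9-neighbor oracle
  st <- mitocomp:::ng_site_table(code)
  for (cd in sense)
    expect_equal(sum(st[cd, ]), oracle_ng_sites(cd), label = cd)
})

test_that("gene_rates averages pairs and ranks genes by JKa/JKs", {
  rows <- c(a = "ATGCTACCTAAA", b = "ATGCTACCTAAA", c = "ATGCTACCTAAA")
  aln <- gene_alignment(rows, gene = "g", codon_aligned = TRUE)
  r <- gene_rates(list(g = aln))
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$Ka_Ks))
  expect_true(is.na(r$JKa_JKs))
  # two genes simulated at contrasting omega rank correctly
  set.seed(3)
  roots <- list(slow = random_cds(201, stop = ""),
                fast = random_cds(201, stop = ""))
  ev <- evolve_taxa(roots, divergence_spec(omega = c(slow = 0.1, fast = 0.6),
                                           seed = 11))
  r <- gene_rates(ev$alignments)
  expect_equal(r$gene, c("fast", "slow"))
  expect_gt(r$JKa_JKs[1], r$JKa_JKs[2])
  # per-pair vs after-mean JC adjustment are both available and close here
  r2 <- gene_rates(ev$alignments, adjust_after_mean = TRUE)
  expect_equal(r2$Ka, r$Ka)
  expect_equal(r2$JKa, r$JKa, tolerance = 0.05)
})

test_that("simulations under strong purifying selection stay below the 0.5 threshold", {
  set.seed(9)
  root <- list(g = random_cds(201, stop = ""))
  vals <- vapply(1:8, function(s) {
    ev <- evolve_taxa(root, divergence_spec(omega = 0.2, seed = 2000 + s))
    gene_rates(ev$alignments)$JKa_JKs
  }, numeric(1))
  expect_true(all(vals < 0.5))
})
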