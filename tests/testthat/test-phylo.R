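test_that("parse_newick validates trees and reports structured errors", {
  tr <- ref_tree4()
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4)
  expect_equal(total_tree_length(tr), 300)

  one <- parse_newick("(A:7);")
  expect_equal(total_tree_length(one), 7)

  expect_error(parse_newick("((A:1,A:1):1,B:2);"), "duplicate leaf")
  expect_error(parse_newick("((A:1,B):1,C:2);"), "missing branch length.*B")
  zero <- parse_newick("((A:0,B:0):0,C:0);")
  expect_equal(total_tree_length(zero), 0)
})

test_that("read_time_tree converts Byr trees to Myr", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);", path)
  tr <- read_time_tree(path, units = "Byr")
  expect_equal(total_tree_length(tr), 300)
})

test_that("prune_to_taxa spans exactly the requested leaves with no stem", {
  tr <- ref_tree4()
  expect_equal(total_tree_length(prune_to_taxa(tr, c("A", "B"))), 100)
  expect_equal(total_tree_length(prune_to_taxa(tr, c("A", "B", "C"))), 250)
  expect_equal(total_tree_length(prune_to_taxa(tr, tr$tip.label)), 300)
  expect_equal(total_tree_length(prune_to_taxa(tr, "A")), 0)
  expect_error(prune_to_taxa(tr, c("A", "zebra")), "zebra")
  expect_error(prune_to_taxa(tr, character(0)), "empty")
})

test_that("prune_to_taxa is monotone in the taxon set", {
  set.seed(5)
  tr <- simulate_timetree(8, 400, seed = 5)
  for (rep in 1:10) {
    taxa <- sample(tr$tip.label, sample(2:7, 1))
    extra <- sample(setdiff(tr$tip.label, taxa), 1)
    t1 <- total_tree_length(prune_to_taxa(tr, taxa))
    t2 <- total_tree_length(prune_to_taxa(tr, c(taxa, extra)))
    expect_gte(t2, t1)
  }
})

test_that("count_substitutions handles both counting modes", {
  tr <- ref_tree4()
  inv <- c(A = "A", B = "A", C = "A", D = "A")
  expect_equal(count_substitutions(inv, tr, "distinct"), 1)
  expect_equal(count_substitutions(inv, tr, "fitch"), 0)

  two <- c(A = "A", B = "K")
  expect_equal(count_substitutions(two, tr, "distinct"), 2)
  expect_equal(count_substitutions(two, tr, "fitch"), 1)

  # homoplasy: A,K,A,K on ((A,B),(C,D)) needs 2 changes (brute-force checked)
  hom <- c(A = "A", B = "K", C = "A", D = "K")
  expect_equal(count_substitutions(hom, tr, "fitch"), 2)
  expect_equal(brute_parsimony(tr, hom), 2)

  expect_error(count_substitutions(character(0), tr), "empty")
  expect_error(count_substitutions(c(Z = "A", A = "K"), tr, "fitch"),
               "not in tree")
})

test_that("fitch counts equal exhaustive minimization on random trees", {
  set.seed(11)
  for (rep in 1:12) {
    tr <- simulate_timetree(sample(4:6, 1), 100, seed = rep)
    for (cc in 1:15) {
      col <- random_column(tr)
      fitch <- count_substitutions(col, tr, "fitch")
      expect_equal(fitch, brute_parsimony(tr, col))
      n_distinct <- length(unique(col))
      expect_gte(fitch, n_distinct - 1)
      expect_lte(fitch, length(col) - 1)
    }
  }
})

test_that("fitch handles multifurcating trees exactly", {
  tr <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  col <- c(A = "A", B = "A", C = "K", D = "K", E = "L")
  expect_equal(count_substitutions(col, tr, "fitch"), brute_parsimony(tr, col))
})

test_that("site_rates implements r = 1000 s / t with pruning and gaps", {
  tr <- ref_tree4()
  aln <- protein_alignment(c(A = "AAKA", B = "AKA-", C = "A-KX", D = "A-K-"),
                           reference = "A")
  sr <- site_rates(aln, tr, mode = "distinct")
  expect_equal(nrow(sr), 4)
  # column 0: invariant, all 4 taxa -> s=1, t=300
  expect_equal(sr$s[1], 1); expect_equal(sr$t[1], 300)
  expect_equal(sr$r[1], 1000 / 300)
  # column 1: gapped in C,D -> A,K on the 100-Myr span
  expect_equal(sr$s[2], 2); expect_equal(sr$t[2], 100); expect_equal(sr$r[2], 20)
  # column 3: only A ungapped (X counts as gap) -> missing
  expect_true(sr$missing[4])
  expect_equal(sr$n_taxa_ungapped[4], 1)

  gappy <- protein_alignment(c(A = "--", B = "AK", C = "AK", D = "AK"), "A")
  expect_error(site_rates(gappy, tr), "no unambiguous residues")

  stranger <- protein_alignment(c(A = "AK", E = "AK"), "A")
  expect_error(site_rates(stranger, tr), "not in tree.*E")
})

test_that("site rates are invariant to row order and newick rotation", {
  tr <- ref_tree4()
  rot <- parse_newick("((D:50,C:50):50,(B:50,A:50):50);")
  seqs <- c(A = "AKLMA", B = "AKLIA", C = "AK-IA", D = "GK-IA")
  sr1 <- site_rates(protein_alignment(seqs, "A"), tr)
  sr2 <- site_rates(protein_alignment(rev(seqs), "A"), tr)
  sr3 <- site_rates(protein_alignment(seqs, "A"), rot)
  expect_equal(sr1, sr2)
  expect_equal(sr1, sr3)
})

test_that("fitch mode applies the zero-change rate floor", {
  tr <- ref_tree4()
  aln <- protein_alignment(c(A = "A", B = "A", C = "A", D = "A"), "A")
  sr <- site_rates(aln, tr, mode = "fitch")
  expect_equal(sr$s[1], 0)
  expect_equal(sr$r[1], 0.5 * 1000 / 300)
})

test_that("gene_rate averages non-missing sites into R and WE = 1/R", {
  mk <- function(r) data.frame(column = seq_along(r) - 1L, s = 1, t = 1,
                               r = r, n_taxa_ungapped = 4,
                               missing = is.na(r))
  g <- gene_rate(mk(c(2, 4, 6)), "g1")
  expect_equal(g$R, 4); expect_equal(g$WE, 0.25)
  expect_equal(g$L, 3); expect_equal(g$L_effective, 3)

  g2 <- gene_rate(mk(10), "g2")
  expect_equal(g2$R, 10); expect_equal(g2$WE, 0.1)

  g3 <- gene_rate(mk(c(1000 / 300, NA, 20)), "g3")
  expect_equal(g3$R, mean(c(1000 / 300, 20)))
  expect_equal(g3$L_effective, 2)

  expect_error(gene_rate(mk(c(NA, NA)), "g4"), "all sites missing")
})

test_that("gene_rates processes alignment sets and keeps R > 0 in distinct mode", {
  tr <- simulate_timetree(6, 300, seed = 3)
  alns <- list(
    gene_a = simulate_alignment(tr, rep(2, 40), gap_prob = 0.1, seed = 4),
    gene_b = simulate_alignment(tr, rep(20, 40), gap_prob = 0.1, seed = 5))
  gr <- gene_rates(alns, tr)
  expect_equal(gr$gene_id, c("gene_a", "gene_b"))
  expect_true(all(gr$R > 0))
  expect_true(all(is.finite(gr$WE)))
  expect_lt(gr$R[1], gr$R[2])  # slower gene has lower estimated rate
})
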