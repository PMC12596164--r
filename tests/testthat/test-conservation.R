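test_that("translate_cds follows the bacterial code conventions", {
  expect_equal(as.character(translate_cds("ATGAAA")), "MK")
  expect_equal(as.character(translate_cds("ATGAAATAA")), "MK")
  # table-11 alternative start: GTG initiates as M; without the rule, V
  expect_equal(as.character(translate_cds("GTGGCC")), "MA")
  expect_equal(as.character(translate_cds("GTGGCC", init_codon = FALSE)), "VA")
  expect_equal(as.character(translate_cds("ATGNNTAAA")), "MXK")
  expect_warning(out <- translate_cds("ATGTAAAAA", id = "rec7"),
                 "internal stop")
  expect_equal(as.character(out), "M*K")
  expect_equal(attr(out, "internal_stops"), 1L)
  expect_error(translate_cds("ATGA", id = "rec9"), "rec9")
  expect_error(translate_cds("ATGXAA"), "outside")
})

test_that("translate_cds_set matches per-record translation and keeps rows equal", {
  seqs <- c(a = "ATGAAACGT", b = "ATGAAACGA", c = "GTGAAACGT")
  expect_equal(unname(translate_cds_set(seqs)),
               vapply(seqs, function(s) as.character(translate_cds(s)), ""),
               ignore_attr = TRUE)
  # terminal stop trimmed only when shared by the whole set
  all_stop <- c(a = "ATGAAATAA", b = "ATGAAGTGA")
  expect_equal(unname(nchar(translate_cds_set(all_stop))), c(2L, 2L))
  mixed <- c(a = "ATGAAATAA", b = "ATGAAGAAA")
  expect_equal(unname(nchar(translate_cds_set(mixed))), c(3L, 3L))
})

test_that("column_entropy reproduces hand-computed values", {
  expect_equal(column_entropy(rep("A", 5)), 0)
  expect_equal(column_entropy(c("A", "A", "V", "V")), 1)
  expect_equal(column_entropy(c("A", "V", "L", "I")), 2)
  # 111 vs 1: hand-evaluated formula is the oracle
  h <- -(111 / 112 * log2(111 / 112) + 1 / 112 * log2(1 / 112))
  expect_equal(column_entropy(c(rep("A", 111), "V")), h, tolerance = 1e-14)
  # base e
  expect_equal(column_entropy(c("A", "V"), base = exp(1)), log(2))
  # gaps and X are excluded from the denominator
  expect_equal(column_entropy(c("A", "A", "-", "X")), 0)
  expect_equal(column_entropy(c("A", "V", "-", "-")), 1)
  expect_equal(column_entropy(c("-", "-", "X")), 0)
  expect_error(column_entropy(character(0)), "empty")
})

test_that("entropy columns respect their theoretical bounds", {
  set.seed(4)
  for (r in 1:20) {
    n <- sample(2:8, 1)
    col <- sample(c("A", "C", "D", "E", "*"), n, replace = TRUE)
    h <- column_entropy(col)
    expect_gte(h, 0)
    expect_lte(h, log2(min(21, n)) + 1e-12)
  }
})

test_that("gene_entropy_score matches its definition and invariances", {
  rows <- stats::setNames(rep(strrep("M", 300), 112), paste0("i", 1:112))
  expect_equal(gene_entropy_score(rows)$score, 0)
  # nine conserved columns plus one 50/50 column -> 1 bit / 10
  half <- c(rep("AAAAAAAAAA", 56), rep("AAAAAAAAAV", 56))
  names(half) <- paste0("i", seq_along(half))
  prof <- gene_entropy_score(half)
  expect_equal(prof$score, 0.1)
  expect_equal(prof$L, 10L)
  expect_equal(prof$score, sum(prof$per_column) / prof$L)
  # row order and whole-set duplication leave the score unchanged
  aln <- random_protein_alignment(5, 12)
  s0 <- gene_entropy_score(aln)$score
  expect_equal(gene_entropy_score(rev(aln))$score, s0)
  dup <- c(aln, stats::setNames(aln, paste0(names(aln), "_dup")))
  expect_equal(gene_entropy_score(dup)$score, s0, tolerance = 1e-12)
  expect_error(gene_entropy_score(c(a = "MK", b = "MKL")), "unequal")
  expect_error(gene_entropy_score(c(a = "MK")), ">= 2 sequences")
})

test_that("a divergent residue strictly increases a conserved column's entropy", {
  for (n in c(3, 7, 20)) {
    conserved <- rep("A", n)
    expect_gt(column_entropy(c(conserved, "W")), column_entropy(conserved))
  }
})

test_that("score equals the naive reimplementation on random small alignments", {
  set.seed(42)
  for (r in 1:25) {
    n <- sample(2:5, 1); L <- sample(1:6, 1)
    aln <- random_protein_alignment(n, L)
    expect_equal(gene_entropy_score(aln)$score, naive_entropy_score(aln),
                 tolerance = 1e-12)
  }
})

test_that("compare_groups: welch agrees with stats::t.test", {
  x <- c(0.011, 0.0021, 0.0065, 0.009); y <- c(0.001, 0.0002, 0.0004)
  got <- compare_groups(x, y, method = "welch")
  ref <- stats::t.test(x, y)
  expect_equal(got$t_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  ref1 <- stats::t.test(x, y, alternative = "greater")
  expect_equal(got$p_one_sided_greater, ref1$p.value, tolerance = 1e-12)
  student <- compare_groups(x, y, method = "student")
  refs <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(student$t_statistic, unname(refs$statistic), tolerance = 1e-12)
})

test_that("permutation p-values respect their combinatorial floor", {
  x <- c(5, 6, 7); y <- c(1, 2)
  got <- compare_groups(x, y, method = "permutation_exact")
  expect_gte(got$p_perm_greater, 1 / choose(5, 3))
  expect_gte(got$p_perm_two_sided, 1 / choose(5, 3))
  expect_true(got$n_permutations_or_exact$exact)
  # identical groups: mean difference 0, permutation p = 1
  same <- compare_groups(c(.1, .1, .1), c(.1, .1, .1),
                         method = "permutation_exact")
  expect_equal(same$p_perm_greater, 1)
  expect_equal(same$p_perm_two_sided, 1)
  expect_true(same$degenerate)
  expect_equal(same$p_two_sided, 1)
  # Monte-Carlo path is seeded and includes the observed labeling
  mc1 <- compare_groups(x, y, method = "permutation_mc",
                        n_permutations = 200, seed = 3)
  mc2 <- compare_groups(x, y, method = "permutation_mc",
                        n_permutations = 200, seed = 3)
  expect_identical(mc1$p_permutation, mc2$p_permutation)
  expect_gte(mc1$p_perm_greater, 1 / 201)
})

test_that("conservation_report tags groups, orders rows and is deterministic", {
  cfg <- tiny_config(seed = 2)
  sim <- simulate_population(cfg)
  gs <- isolate_gene_sets(sim$isolates)
  groups <- c(conA = "reference", conB = "target", free = "target")
  rep1 <- conservation_report(gs, groups, type = "cds")
  expect_equal(rep1$table$gene, c("conB", "free", "conA"))
  expect_equal(rep1$table$group, c("target", "target", "reference"))
  expect_equal(nrow(rep1$table), 3L)
  tsv1 <- withr::local_tempfile(fileext = ".tsv")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_conservation_report(rep1, tsv = tsv1)
  write_conservation_report(conservation_report(gs, groups, type = "cds"),
                            tsv = tsv2)
  expect_identical(readLines(tsv1), readLines(tsv2))
  # a one-sequence gene is excluded with a warning, not silently
  gs$lonely <- gs$free[1]
  groups["lonely"] <- "other"
  expect_warning(rep2 <- conservation_report(gs, groups, type = "cds"),
                 "lonely")
  expect_false("lonely" %in% rep2$table$gene)
  expect_error(conservation_report(gs, groups[-1], type = "cds"),
               "missing from group map")
})
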