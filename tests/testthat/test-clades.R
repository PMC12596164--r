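test_that("pairwise_identity is exact", {
  expect_equal(pairwise_identity(c(a = "ACGT", b = "ACGT"))[1, 2], 1)
  s <- strrep("A", 98)
  expect_equal(pairwise_identity(c(a = paste0(s, "AA"),
                                   b = paste0(s, "CC")))[1, 2], 0.98)
  expect_error(pairwise_identity(c(a = "ACGT", b = "ACG")), "unequal")
  expect_error(pairwise_identity(c(a = "AC-T", b = "ACGT")), "gap")
  expect_error(pairwise_identity(c(a = "ACGT")), "length")
})

test_that("min off-diagonal identity equals 1 - maxHamming/L exactly", {
  set.seed(9)
  L <- 120
  seqs <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("s", 1:6)
  mat <- pairwise_identity(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  hmax <- max(vapply(utils::combn(6, 2, simplify = FALSE), function(p)
    sum(chars[p[1], ] != chars[p[2], ]), 0L))
  off <- mat[row(mat) != col(mat)]
  expect_equal(min(off), 1 - hmax / L, tolerance = 1e-15)
})

test_that("read_ani_matrix validates, rescales and symmetrizes", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1, .99, .98, .99, 1, .97, .98, .97, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- file.path(dir, "ani.tsv")
  utils::write.table(m, p, sep = "\t", quote = FALSE)
  got <- read_ani_matrix(p)
  expect_equal(rownames(got), c("a", "b", "c"))
  expect_equal(got["a", "c"], 0.98)
  # percent dialect auto-detected
  utils::write.table(m * 100, p, sep = "\t", quote = FALSE)
  expect_equal(read_ani_matrix(p)["b", "c"], 0.97)
  # slight asymmetry averaged with a warning; gross asymmetry fatal
  m2 <- m; m2[1, 2] <- m2[1, 2] + 1e-8
  utils::write.table(m2, p, sep = "\t", quote = FALSE)
  expect_warning(got2 <- read_ani_matrix(p), "symmetrized")
  expect_equal(got2[1, 2], got2[2, 1])
  m3 <- m; m3[1, 2] <- 0.5
  utils::write.table(m3, p, sep = "\t", quote = FALSE)
  expect_error(read_ani_matrix(p), "asymmetric")
  utils::write.table(m[, 1:2], p, sep = "\t", quote = FALSE)
  expect_error(read_ani_matrix(p), "square")
})

test_that("cluster_clades recovers block structure at the stated cuts", {
  blockA <- strrep("A", 100)
  blockB <- paste0(strrep("A", 99), "C")  # 0.99 to blockA
  seqs <- c(a1 = blockA, a2 = blockA, b1 = blockB, b2 = blockB)
  mat <- pairwise_identity(seqs)
  asg <- cluster_clades(mat, cut_identity = 0.995)
  expect_equal(asg$n_clades, 2L)
  expect_equal(unname(asg$clade_of), c(1L, 1L, 2L, 2L))
  # all identical -> one clade at any cut < 1
  same <- pairwise_identity(c(x = blockA, y = blockA, z = blockA))
  expect_equal(cluster_clades(same, cut_identity = 0.9)$n_clades, 1L)
  # cut above the maximum pairwise identity -> singletons, allowed
  distinct <- c(x = paste0(strrep("A", 98), "AA"),
                y = paste0(strrep("A", 98), "CC"),
                z = paste0(strrep("A", 98), "GG"))
  expect_equal(cluster_clades(pairwise_identity(distinct),
                              cut_identity = 0.995)$n_clades, 3L)
  expect_error(cluster_clades(mat, cut_identity = 0), "cut_identity")
})

test_that("clustering is invariant to input order up to renumbering", {
  cfg <- tiny_config(seed = 4)
  sim <- simulate_population(cfg)
  concat <- stats::setNames(
    vapply(sim$isolates, function(x) paste(x$sequences, collapse = ""), ""),
    vapply(sim$isolates, `[[`, "", "isolate_id"))
  mat <- pairwise_identity(concat)
  asg <- cluster_clades(mat, cut_identity = 0.995)
  set.seed(1)
  perm <- sample(length(concat))
  asg_p <- cluster_clades(pairwise_identity(concat[perm]),
                          cut_identity = 0.995)
  expect_equal(adjusted_rand_index(asg$clade_of[names(asg_p$clade_of)],
                                   asg_p$clade_of), 1)
})

test_that("synthetic clades are recovered for any cut between the supports", {
  cfg <- tiny_config(seed = 6)
  sim <- simulate_population(cfg)
  meta <- isolate_metadata(sim$isolates)
  concat <- stats::setNames(
    vapply(sim$isolates, function(x) paste(x$sequences, collapse = ""), ""),
    meta$isolate_id)
  mat <- pairwise_identity(concat)
  truth <- stats::setNames(meta$clade, meta$isolate_id)
  same <- outer(truth, truth, "==")
  off <- row(mat) != col(mat)
  lo <- max(mat[off & !same]); hi <- min(mat[off & same])
  expect_lt(lo, hi)
  for (cut in c(lo + 0.25 * (hi - lo), (lo + hi) / 2, hi - 0.25 * (hi - lo))) {
    asg <- cluster_clades(mat, cut_identity = cut)
    expect_equal(adjusted_rand_index(asg$clade_of, truth[asg$ids]), 1)
  }
})

test_that("species_check applies the 95% convention", {
  ids <- c("a", "b")
  m <- matrix(c(1, 0.986, 0.986, 1), 2, dimnames = list(ids, ids))
  got <- species_check(m)
  expect_equal(got$min_identity, 0.986)
  expect_true(got$single_species)
  m2 <- matrix(c(1, 0.90, 0.90, 1), 2, dimnames = list(ids, ids))
  expect_false(species_check(m2)$single_species)
  m3 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(ids, ids))
  expect_equal(species_check(m3)$min_identity, 1)
  expect_true(species_check(m3)$single_species)
})

test_that("clade_relative_abundance computes fractions and persistence", {
  meta <- data.frame(isolate_id = paste0("i", 1:6),
                     time_point = c("t1", "t1", "t1", "t1", "t2", "t2"),
                     stringsAsFactors = FALSE)
  clades <- stats::setNames(c(1L, 1L, 2L, 2L, 1L, 1L), meta$isolate_id)
  tl <- clade_relative_abundance(clades, meta)
  expect_equal(unname(tl$fractions["t1", ]), c(0.5, 0.5))
  expect_equal(unname(tl$fractions["t2", ]), c(1, 0))
  expect_equal(rowSums(tl$fractions), c(t1 = 1, t2 = 1), tolerance = 1e-12)
  p2 <- tl$persistence[tl$persistence$clade == 2L, ]
  expect_equal(p2$first, "t1")
  expect_equal(p2$last, "t1")
  expect_equal(p2$n_time_points, 1L)
  expect_error(
    clade_relative_abundance(clades[-1], meta),
    "without clade assignment")
})

test_that("clade_newick emits a tree ape can read back", {
  seqs <- c(a = "AAAA", b = "AAAC", c = "CCCC", d = "CCCA")
  asg <- cluster_clades(pairwise_identity(seqs), cut_identity = 0.6)
  nwk <- clade_newick(asg)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, names(seqs))
})
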