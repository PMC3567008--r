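test_that("NJ recovers the worked 4-taxon additive matrix", {
  v <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  v["A", "B"] <- v["B", "A"] <- 5
  v["A", "C"] <- v["C", "A"] <- 7
  v["A", "D"] <- v["D", "A"] <- 8
  v["B", "C"] <- v["C", "B"] <- 8
  v["B", "D"] <- v["D", "B"] <- 9
  v["C", "D"] <- v["D", "C"] <- 9
  tr <- nj_tree(dist_from_matrix(v))
  expect_setequal(bip_keys(tr), "C|D")  # split AB|CD
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(v), colnames(v)], v, tolerance = 1e-9)
  # internal branch length 1, tip branches 2,3,4,5
  tip_edges <- tr$edge[, 2L] <= 4L
  tip_len <- tr$edge.length[tip_edges][order(tr$edge[tip_edges, 2L])]
  expect_equal(tip_len[order(tr$tip.label)], c(2, 3, 4, 5))
  expect_equal(sort(tr$edge.length[!tip_edges]), 1)
})

test_that("NJ is exact on random additive matrices", {
  set.seed(101)
  for (r in 1:30) {
    n <- sample(4:12, 1)
    ra <- random_additive(n)
    tr <- nj_tree(ra$dm)
    expect_setequal(bip_keys(tr), bip_keys(ra$tree))
    cp <- ape::cophenetic.phylo(tr)
    expect_equal(cp[ra$dm$ids, ra$dm$ids], ra$dm$values, tolerance = 1e-9)
  }
})

test_that("NJ handles n = 3 and degenerate matrices", {
  v <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dist_from_matrix(v))
  expect_equal(ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")],
               v, tolerance = 1e-9)
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star <- nj_tree(dist_from_matrix(z))
  expect_equal(star$Nnode, 1L)
  expect_true(all(star$edge.length == 0))
  vna <- v; vna["a", "b"] <- vna["b", "a"] <- NA
  expect_error(nj_tree(dist_from_matrix(vna)), "a-b")
})

test_that("bootstrap supports are deterministic and bounded", {
  set.seed(202)
  base <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  shift <- base
  mut <- sample(120, 18)
  shift[mut] <- vapply(shift[mut], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  flip <- function(z, i) { z[i] <- setdiff(c("A", "C", "G", "T"), z[i])[1]
                           paste(z, collapse = "") }
  a <- alignment(c(a1 = paste(base, collapse = ""), a2 = flip(base, 1),
                   b1 = paste(shift, collapse = ""), b2 = flip(shift, 2)),
                 locus = "x")
  t1 <- bootstrap_nj(a, n_reps = 100, seed = 9)
  t2 <- bootstrap_nj(a, n_reps = 100, seed = 9)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # two well-separated cherries: the single internal split at 100
  expect_true(all(sup == 100))
})

test_that("a single bootstrap replicate yields all-or-nothing support", {
  set.seed(17)
  a <- aln_from_rows(mutated_rows(5, 80))
  tr <- bootstrap_nj(a, n_reps = 1, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
})

test_that("bootstrap support is invariant to input row order", {
  set.seed(55)
  rows <- mutated_rows(6, 120)
  ids <- sprintf("i%d", 1:6)
  a1 <- alignment(stats::setNames(rows, ids), locus = "x")
  perm <- c(4, 2, 6, 1, 3, 5)
  a2 <- alignment(stats::setNames(rows[perm], ids[perm]), locus = "x")
  t1 <- bootstrap_nj(a1, n_reps = 50, seed = 12)
  t2 <- bootstrap_nj(a2, n_reps = 50, seed = 12)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("outgroup rooting places and preserves supports", {
  v <- matrix(c(0, 2, 8, 9,
                2, 0, 8, 9,
                8, 8, 0, 5,
                9, 9, 5, 0), 4,
              dimnames = list(c("x1", "x2", "y1", "og"),
                              c("x1", "x2", "y1", "og")))
  tr <- nj_tree(dist_from_matrix(v))
  rt <- root_with_outgroup(tr, "og")
  expect_true(ape::is.rooted(rt))
  kids <- ape::extract.clade(rt, ape::getMRCA(rt, c("x1", "x2")))$tip.label
  expect_setequal(kids, c("x1", "x2"))
  # idempotent up to topology
  rt2 <- root_with_outgroup(rt, "og")
  expect_setequal(bip_keys(rt2), bip_keys(rt))
  expect_error(root_with_outgroup(tr, c("x1", "x2", "y1", "og")),
               "not separable")
  expect_error(root_with_outgroup(tr, "nope"), "unknown outgroup")
})

test_that("monophyly testing reads clade support off the tree", {
  tr <- ape::read.tree(text = "((x1:1,x2:1)90:1,(y1:1,y2:1)85:1)r;")
  m <- is_monophyletic(tr, c("x1", "x2"))
  expect_true(m$monophyletic)
  expect_equal(m$support, 90)
  mixed <- is_monophyletic(tr, c("x1", "y1"))
  expect_false(mixed$monophyletic)
  expect_true(is.na(mixed$support))
  single <- is_monophyletic(tr, "x1")
  expect_true(single$monophyletic)
  expect_true(is.na(single$support))
  expect_error(is_monophyletic(tr, "zz"), "unknown tip")
})

test_that("Fitch scoring matches hand passes and brute force", {
  t1 <- ape::read.tree(text = "((w,x),(y,z));")
  t2 <- ape::read.tree(text = "((w,y),(x,z));")
  aln1 <- alignment(c(w = "A", x = "A", y = "G", z = "G"))
  expect_equal(fitch_score(t1, aln1), 1L)
  expect_equal(fitch_score(t2, aln1), 2L)
  const <- alignment(c(w = "ACG", x = "ACG", y = "ACG", z = "ACG"))
  expect_equal(fitch_score(t1, const), 0L)

  set.seed(66)
  codes <- c("A", "C", "G", "T")
  for (r in 1:10) {
    tips <- c("w", "x", "y", "z", "v")
    tr <- ape::rtree(5, tip.label = sample(tips))
    col <- sample(codes, 5, replace = TRUE)
    a <- alignment(stats::setNames(col, tips))
    expected <- brute_fitch(tr, stats::setNames(match(col, codes), tips), 4)
    expect_equal(fitch_score(tr, a), expected)
  }
})

test_that("appended indel characters add their own Fitch cost", {
  tr <- ape::read.tree(text = "((w,x),(y,z));")
  a <- alignment(c(w = "AC--G", x = "AC--G", y = "ACTAG", z = "ACTAG"))
  ic <- simple_indel_coding(a)
  base <- fitch_score(tr, a)
  with_indels <- fitch_score(tr, a, indels = ic)
  st <- ifelse(ic$states[, 1L] == "1", 1L, 2L)
  expected_extra <- brute_fitch(tr, st, 2)
  expect_equal(with_indels, base + expected_extra)
})

test_that("Fitch score on a star tree equals the minority-state total", {
  # on a star the optimal internal state is the column's majority state,
  # so each column costs (tips - majority count); variable-site count is
  # the corresponding lower bound
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  set.seed(13)
  rows <- replicate(5, paste(sample(c("A", "G"), 20, replace = TRUE),
                             collapse = ""))
  a <- alignment(stats::setNames(rows, letters[1:5]))
  m <- do.call(rbind, strsplit(unname(a$seqs), ""))
  expected <- sum(apply(m, 2, function(col) length(col) - max(table(col))))
  expect_equal(fitch_score(star, a), expected)
  expect_gte(fitch_score(star, a), variable_sites(a))
})
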