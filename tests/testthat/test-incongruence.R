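# rooted toy trees with full support everywhere unless stated
toy_map <- function() {
  species_map(
    c("A1", "A2", "B1", "B2", "C1", "C2", "og"),
    c("spA", "spA", "spB", "spB", "spC", "spC", "out"),
    c("c1", "c1", "c1", "c1", "c2", "c2", "outgroup"),
    is_outgroup = c(rep(FALSE, 6), TRUE))
}
toy_tree <- function(txt) ape::read.tree(text = txt)

test_that("fully concordant libraries are classified concordant", {
  t <- toy_tree(
    "(og:1,(((A1:1,A2:1)100:1,(B1:1,B2:1)100:1)100:1,(C1:1,C2:1)100:1)100:1)r;")
  rep <- classify_incongruence(t, t, toy_map())
  expect_true(all(rep$verdict == "concordant"))
})

test_that("clade-level cp/nuclear conflict flags a putative hybrid", {
  # A2's chloroplast sits with spA (clade c1), its nuclear copy with spC
  cp <- toy_tree(
    "(og:1,(((A1:1,A2:1)100:1,(B1:1,B2:1)100:1)100:1,(C1:1,C2:1)100:1)100:1)r;")
  # nuclear topology: A2 inside the spC clade
  nuc <- toy_tree(
    "(og:1,((A1:1,(B1:1,B2:1)100:1)100:1,((C1:1,C2:1)100:1,A2:1)100:1)100:1)r;")
  rep <- classify_incongruence(cp, nuc, toy_map())
  row <- rep[rep$individual == "A2", ]
  expect_equal(row$verdict, "putative_hybrid")
  expect_equal(row$maternal, "spA")
  # nuclear side resolves to clade c2 (spC cluster or its clade)
  expect_true(row$paternal %in% c("spC", "c2"))
  expect_true(all(rep$verdict[rep$individual %in%
                              c("A1", "B1", "B2", "C1", "C2")] ==
                  "concordant"))
})

test_that("consistent foreign placement in both genomes flags a mislabel", {
  # B2 sits inside the spC cluster in BOTH trees: its label, not its
  # genome, is wrong
  t <- toy_tree(
    "(og:1,(((A1:1,A2:1)100:1,B1:1)100:1,((C1:1,C2:1)100:1,B2:1)100:1)100:1)r;")
  rep <- classify_incongruence(t, t, toy_map())
  expect_equal(rep$verdict[rep$individual == "B2"],
               "suspected_misidentification")
})

test_that("unsupported placements stay unresolved, not flagged", {
  cp <- toy_tree(
    "(og:1,(((A1:1,A2:1)100:1,(B1:1,B2:1)100:1)100:1,(C1:1,C2:1)100:1)100:1)r;")
  nuc <- toy_tree(
    "(og:1,((A1:1,(B1:1,B2:1)100:1)100:1,((C1:1,C2:1)40:1,A2:1)40:1)100:1)r;")
  rep <- classify_incongruence(cp, nuc, toy_map(), support_threshold = 75)
  expect_false(rep$verdict[rep$individual == "A2"] == "putative_hybrid")
})

test_that("verdicts ignore tip order and clade renaming", {
  sim <- simulate_library(test_cfg(seed = 41, n_hybrids = 1L))
  cp <- root_with_outgroup(
    bootstrap_nj(cladegap:::library_concat(sim$library, "cpDNA"),
                 n_reps = 60, seed = 5), "outgroup_i1")
  nuc <- root_with_outgroup(
    bootstrap_nj(cladegap:::library_concat(sim$library, "nuclear"),
                 n_reps = 60, seed = 6), "outgroup_i1")
  rep1 <- classify_incongruence(cp, nuc, sim$library$map)
  map2 <- sim$library$map
  map2$clade <- paste0("renamed_", map2$clade)
  rep2 <- classify_incongruence(cp, nuc, map2)
  expect_equal(rep1$verdict, rep2$verdict)
  # shuffled map rows change nothing
  map3 <- sim$library$map[sample(nrow(sim$library$map)), ]
  class(map3) <- c("cg_species_map", "data.frame")
  rep3 <- classify_incongruence(cp, nuc, map3)
  expect_equal(rep1$verdict[order(rep1$individual)],
               rep3$verdict[order(rep3$individual)])
})

test_that("tree/tip mismatches and unrooted input are rejected", {
  t <- toy_tree(
    "(og:1,(((A1:1,A2:1)100:1,(B1:1,B2:1)100:1)100:1,(C1:1,C2:1)100:1)100:1)r;")
  t2 <- ape::drop.tip(t, "C2")
  expect_error(classify_incongruence(t, t2, toy_map()), "different tip")
  unr <- ape::unroot(t)
  expect_error(classify_incongruence(unr, unr, toy_map()), "rooted")
})

test_that("clade assignment finds the simulated home clade with margin", {
  sim <- simulate_library(test_cfg(seed = 43))
  sizes <- table(sim$truth$nominal_species)
  src <- names(sizes)[sizes >= 3][1]
  q_id <- sim$truth$individual[sim$truth$nominal_species == src][1]
  ho <- hold_out(sim$library, q_id)
  ac <- assign_clade(ho$query, ho$library, "query")
  expect_equal(ac$clade, sim$truth$nominal_clade[match(
    q_id, sim$truth$individual)])
  expect_gt(ac$margin, 0)
  expect_false(ac$placement_conflict)
})

test_that("equidistant queries raise a placement conflict", {
  # two clades, query exactly between them: margin 0
  A20 <- function(g) paste(c(rep("A", 20 - g), rep("G", g)), collapse = "")
  a <- alignment(c(x1 = A20(0), x2 = A20(0), y1 = A20(6), y2 = A20(6),
                   og = paste(c(rep("C", 4), rep("A", 16)), collapse = "")),
                 locus = "l1")
  map <- species_map(c("x1", "x2", "y1", "y2", "og"),
                     c("spX", "spX", "spY", "spY", "out"),
                     c("c1", "c1", "c2", "c2", "outgroup"),
                     is_outgroup = c(rep(FALSE, 4), TRUE))
  lib <- reference_library(list(l1 = a), map, c(l1 = "cpDNA"))
  ac <- assign_clade(list(l1 = A20(3)), lib)
  expect_equal(ac$margin, 0)
  expect_true(ac$placement_conflict)
})

test_that("single-clade libraries cannot run clade assignment", {
  a <- alignment(c(x1 = "ACGT", x2 = "ACGT"), locus = "l1")
  map <- species_map(c("x1", "x2"), c("spX", "spX"), c("c1", "c1"))
  lib <- reference_library(list(l1 = a), map, c(l1 = "cpDNA"))
  expect_error(assign_clade(list(l1 = "ACGT"), lib), ">= 2 ingroup clades")
})

test_that("in-library queries are identified at their species", {
  sim <- simulate_library(test_cfg(seed = 47))
  sizes <- table(sim$truth$nominal_species)
  src <- names(sizes)[sizes >= 3][2]
  q_id <- sim$truth$individual[sim$truth$nominal_species == src][1]
  ho <- hold_out(sim$library, q_id)
  res <- identify_species(ho$query, ho$library, "query",
                          boot_reps = 100, seed = 9)
  expect_equal(res$decision, "identified")
  expect_equal(res$species, src)
  expect_gte(res$support, 75)
  expect_true(res$gap_exists)
})

test_that("queries identical to a reference individual are identified", {
  sim <- simulate_library(test_cfg(seed = 49))
  sizes <- table(sim$truth$nominal_species)
  src <- names(sizes)[sizes >= 2][1]
  q_id <- sim$truth$individual[sim$truth$nominal_species == src][1]
  query <- lapply(sim$library$alignments, function(x) unname(x$seqs[[q_id]]))
  res <- identify_species(query, sim$library, "query",
                          boot_reps = 100, seed = 10)
  expect_equal(res$decision, "identified")
  expect_equal(res$species, src)
})

test_that("absent-species queries are never forced onto a species", {
  sim <- simulate_library(test_cfg(seed = 51))
  sizes <- table(sim$truth$nominal_species)
  gone <- names(sizes)[1]
  ho <- hold_out_species(sim$library, gone)
  res <- identify_species(ho$query, ho$library, "query",
                          boot_reps = 100, seed = 11)
  expect_true(res$decision %in% c("clade_only", "unresolved"))
})

test_that("sparsely sampled clades stop at clade rank with an advisory", {
  sim <- simulate_library(sim_config(
    n_clades = 3L, species_per_clade = 1L,
    individuals_per_species = c(2L, 3L),
    locus_lengths = c(ndhF = 300L, trnSG = 150L, waxy = 250L), seed = 53))
  sizes <- table(sim$truth$nominal_species)
  src <- names(sizes)[sizes >= 3][1]
  q_id <- sim$truth$individual[sim$truth$nominal_species == src][1]
  ho <- hold_out(sim$library, q_id)
  res <- identify_species(ho$query, ho$library, "query",
                          boot_reps = 50, seed = 12)
  expect_equal(res$decision, "clade_only")
  expect_match(res$advisory, "densify")
})

test_that("truth evaluation tabulates verdicts against roles", {
  truth <- data.frame(individual = c("i1", "i2", "i3"),
                      role = c("normal", "hybrid", "mislabeled"),
                      stringsAsFactors = FALSE)
  perfect <- data.frame(
    individual = c("i1", "i2", "i3"),
    verdict = c("concordant", "putative_hybrid",
                "suspected_misidentification"),
    stringsAsFactors = FALSE)
  ev <- truth_eval(perfect, truth)
  expect_equal(unname(ev$sensitivity), c(1, 1))
  expect_equal(ev$specificity, 1)
  expect_equal(ev$false_flag_rate, 0)
  lazy <- perfect; lazy$verdict <- "unresolved"
  ev2 <- truth_eval(lazy, truth)
  expect_equal(unname(ev2$sensitivity), c(0, 0))
  expect_error(truth_eval(data.frame(individual = "zz", verdict = "x"),
                          truth), "absent from truth")
})
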