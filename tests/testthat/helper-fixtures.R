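# Validation-scale simulator configuration: clade/species/individual
# structure reduced from the defaults, evolutionary depths and kappa at
# the simulator defaults (see the methods vignette).
test_cfg <- function(seed = 1L, ...) {
  args <- list(n_clades = 5L, species_per_clade = 3L,
               individuals_per_species = c(1L, 5L),
               locus_lengths = c(ndhF = 600L, trnSG = 250L, waxy = 500L),
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# low-divergence random alignment: ancestor plus per-row point mutations
mutated_rows <- function(n, L, rate = 0.08) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  replicate(n, {
    z <- base
    mut <- stats::runif(L) < rate
    z[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    paste(z, collapse = "")
  })
}

# tiny deterministic alignment builders
aln_from_rows <- function(rows, ids = sprintf("s%d", seq_along(rows)),
                          locus = "test") {
  alignment(stats::setNames(rows, ids), locus = locus)
}

# cg_dist from an explicit symmetric matrix
dist_from_matrix <- function(values, ids = rownames(values)) {
  dimnames(values) <- list(ids, ids)
  cladegap:::as_cg_dist(values)
}

# remove one individual from a simulated library, returning the reduced
# library plus the held-out individual's per-locus sequences
hold_out <- function(lib, id) {
  query <- lapply(lib$alignments, function(a) unname(a$seqs[[id]]))
  alns <- lapply(lib$alignments, function(a)
    alignment(a$seqs[names(a$seqs) != id], locus = a$locus))
  map <- lib$map[lib$map$individual != id, , drop = FALSE]
  class(map) <- c("cg_species_map", "data.frame")
  list(library = reference_library(alns, map, lib$partitions),
       query = query)
}

# remove every individual of a species (query = its first individual)
hold_out_species <- function(lib, species) {
  ids <- lib$map$individual[lib$map$species == species]
  query <- lapply(lib$alignments, function(a) unname(a$seqs[[ids[1L]]]))
  alns <- lapply(lib$alignments, function(a)
    alignment(a$seqs[!names(a$seqs) %in% ids], locus = a$locus))
  map <- lib$map[!lib$map$individual %in% ids, , drop = FALSE]
  class(map) <- c("cg_species_map", "data.frame")
  list(library = reference_library(alns, map, lib$partitions),
       query = query, true_species = species)
}

# brute-force small-parsimony score: minimize changes over all internal
# state assignments (states 1..k; 0 = missing, free)
brute_fitch <- function(tree, tip_states, k) {
  tr <- ape::unroot(tree)
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  internal <- ntip + seq_len(nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  best <- Inf
  tips <- tip_states[tr$tip.label]
  for (g in seq_len(nrow(grid))) {
    st <- c(tips, grid[g, ])
    cost <- 0L
    for (e in seq_len(nrow(tr$edge))) {
      a <- st[tr$edge[e, 1L]]; b <- st[tr$edge[e, 2L]]
      if (a != 0L && b != 0L && a != b) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best
}

# random binary tree with strictly positive branch lengths and its exact
# path-length (additive) distance matrix
random_additive <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  dm <- cladegap:::as_cg_dist(ape::cophenetic.phylo(tr))
  list(tree = tr, dm = dm)
}

bip_keys <- function(tree, all_tips = sort(tree$tip.label)) {
  cladegap:::bipartition_keys(tree, all_tips)
}
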