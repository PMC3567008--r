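#' Classify chloroplast-versus-nuclear tree incongruence
#'
#' Because cpDNA is maternally inherited and nuclear loci biparentally,
#' an individual whose chloroplast tree placement and nuclear tree
#' placement disagree at the clade level is a candidate hybrid (maternal
#' parent on the cpDNA side, paternal on the nuclear side), while an
#' individual whose two placements agree with each other but contradict
#' its nominal species label is a candidate misidentification.
#'
#' Each individual is assigned, in each tree, to the species (or, failing
#' a species-level majority, the clade) of the other individuals in its
#' smallest well-supported enclosing clade; assignment walks rootward
#' until a supported clade with a strict majority species or clade among
#' the other members is found.
#'
#' @param cp_tree,nuc_tree rooted `phylo` trees with bootstrap supports as
#'   node labels, sharing one tip set.
#' @param map a [species_map()] covering all tips.
#' @param support_threshold minimum bootstrap percent for a clade to count
#'   as supported (default 75).
#' @return data.frame of class `cg_incongruence`: one row per ingroup
#'   individual with the cp and nuclear assignments (species, clade,
#'   support) and `verdict` in `concordant`, `putative_hybrid`,
#'   `suspected_misidentification`, `unresolved`; hybrid rows carry
#'   `maternal`/`paternal` species-or-clade labels.
#' @export
classify_incongruence <- function(cp_tree, nuc_tree, map,
                                  support_threshold = 75) {
  stopifnot(inherits(map, "cg_species_map"))
  if (!setequal(cp_tree$tip.label, nuc_tree$tip.label))
    stop("cp and nuclear trees have different tip sets")
  if (!ape::is.rooted(cp_tree) || !ape::is.rooted(nuc_tree))
    stop("both trees must be rooted (use root_with_outgroup)")
  unmapped <- setdiff(cp_tree$tip.label, map$individual)
  if (length(unmapped) > 0L)
    stop("tips missing from species map: ", paste(unmapped, collapse = ", "))
  ids <- intersect(cp_tree$tip.label, ingroup_ids(map))
  cp_a <- lapply(ids, assign_in_tree, tree = cp_tree, map = map,
                 threshold = support_threshold)
  nu_a <- lapply(ids, assign_in_tree, tree = nuc_tree, map = map,
                 threshold = support_threshold)
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    S <- map_species(map, id)
    C <- map_clade(map, id)
    cp <- cp_a[[i]]; nu <- nu_a[[i]]
    agree_cp <- assignment_agrees(cp, S, C)
    agree_nu <- assignment_agrees(nu, S, C)
    verdict <- "unresolved"; maternal <- NA_character_; paternal <- NA_character_
    if (!is.null(cp) && !is.null(nu)) {
      if (agree_cp && agree_nu) {
        verdict <- "concordant"
      } else if (!is.na(cp$clade) && !is.na(nu$clade) &&
                 cp$clade != nu$clade) {
        verdict <- "putative_hybrid"
        maternal <- if (!is.na(cp$species)) cp$species else cp$clade
        paternal <- if (!is.na(nu$species)) nu$species else nu$clade
      } else if (assignments_match(cp, nu) && !agree_cp && !agree_nu) {
        verdict <- "suspected_misidentification"
      }
    } else if ((is.null(cp) && !is.null(nu) && agree_nu) ||
               (is.null(nu) && !is.null(cp) && agree_cp)) {
      verdict <- "concordant"  # one genome uninformative, other consistent
    }
    data.frame(individual = id, nominal_species = S, nominal_clade = C,
               cp_species = if (is.null(cp)) NA_character_ else cp$species,
               cp_clade = if (is.null(cp)) NA_character_ else cp$clade,
               cp_support = if (is.null(cp)) NA_real_ else cp$support,
               nuc_species = if (is.null(nu)) NA_character_ else nu$species,
               nuc_clade = if (is.null(nu)) NA_character_ else nu$clade,
               nuc_support = if (is.null(nu)) NA_real_ else nu$support,
               verdict = verdict, maternal = maternal, paternal = paternal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cg_incongruence", "data.frame")
  out
}

# Does an assignment corroborate nominal species S (clade C)? A species
# match is agreement; so is a clade match, even when the nearest
# supported cluster belongs to a same-clade sister species (a tip
# attaching next to its sister species is a sampling artifact, not a
# clade-scale conflict; verdicts are resolved at clade scale).
assignment_agrees <- function(a, S, C) {
  if (is.null(a)) return(FALSE)
  if (!is.na(a$species) && a$species == S) return(TRUE)
  !is.na(a$clade) && a$clade == C
}

# do two assignments name the same placement?
assignments_match <- function(a, b) {
  if (!is.na(a$species) && !is.na(b$species)) return(a$species == b$species)
  if (!is.na(a$clade) && !is.na(b$clade)) return(a$clade == b$clade)
  FALSE
}

# Assign a tip to the species/clade of the *other* members of its smallest
# well-supported enclosing clade; walk rootward until the other members
# show a strict-majority species (preferred) or clade. NULL when no
# supported enclosing clade resolves the placement.
assign_in_tree <- function(id, tree, map, threshold) {
  ntip <- length(tree$tip.label)
  tip <- match(id, tree$tip.label)
  labels <- tree$node.label
  node <- tree$edge[tree$edge[, 2L] == tip, 1L]
  root <- ntip + 1L
  while (TRUE) {
    sup <- node_support(tree, node, root, ntip, labels)
    if (!is.na(sup) && sup >= threshold) {
      others <- setdiff(ape::extract.clade(tree, node)$tip.label, id)
      others <- setdiff(others, outgroup_ids(map))
      if (length(others) > 0L) {
        sp_tab <- sort(table(map_species(map, others)), decreasing = TRUE)
        if (sp_tab[1L] > length(others) / 2)
          return(list(species = names(sp_tab)[1L],
                      clade = map$clade[match(names(sp_tab)[1L],
                                              map$species)],
                      support = sup))
        cl_tab <- sort(table(map_clade(map, others)), decreasing = TRUE)
        if (cl_tab[1L] > length(others) / 2)
          return(list(species = NA_character_, clade = names(cl_tab)[1L],
                      support = sup))
      }
    }
    if (node == root) return(NULL)
    node <- tree$edge[tree$edge[, 2L] == node, 1L]
  }
}

node_support <- function(tree, node, root, ntip, labels) {
  if (node == root) return(NA_real_)
  if (is.null(labels)) return(NA_real_)
  lab <- labels[node - ntip]
  if (is.na(lab) || !nzchar(lab)) return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

#' Step 1: assign a query to a major clade
#'
#' Clade barcoding: the query is assigned to the clade with the smallest
#' mean combined-locus distance from the query to that clade's reference
#' individuals; the margin is the runner-up mean minus the best mean. The
#' distance verdict is cross-checked by neighbor joining: the query must
#' attach inside the best clade's subtree of the rooted NJ tree, else a
#' `placement_conflict` flag is raised (as it is for a zero margin).
#'
#' @param query named list locus -> aligned sequence string (library
#'   coordinates); loci absent from the query are padded as missing.
#' @param library a [reference_library()] with >= 2 ingroup clades.
#' @param query_id tip label used for the query.
#' @param model,deletion passed to [distance_matrix()].
#' @return list with `clade`, `margin`, `mean_distances` (per clade) and
#'   `placement_conflict` (logical).
#' @export
assign_clade <- function(query, library, query_id = "query",
                         model = "K2P", deletion = "pairwise") {
  stopifnot(inherits(library, "cg_library"))
  clades <- unique(library$map$clade[!library$map$is_outgroup])
  if (length(clades) < 2L) stop("library must contain >= 2 ingroup clades")
  comb <- query_concat(query, library, query_id)
  dm <- distance_matrix(comb, model = model, deletion = deletion)
  qd <- dm$values[query_id, ]
  if (all(is.na(qd[names(qd) != query_id])))
    stop("query shares no sites with the library")
  means <- vapply(clades, function(cl) {
    members <- library$map$individual[library$map$clade == cl &
                                      !library$map$is_outgroup]
    mean(qd[intersect(members, names(qd))], na.rm = TRUE)
  }, numeric(1L))
  ord <- order(means)
  best <- clades[ord[1L]]
  margin <- means[ord[2L]] - means[ord[1L]]
  tree <- nj_tree(dm)
  og <- outgroup_ids(library$map)
  conflict <- margin <= 0
  if (length(og) > 0L && all(og %in% tree$tip.label)) {
    rt <- try(root_with_outgroup(tree, og), silent = TRUE)
    if (!inherits(rt, "try-error")) {
      members <- library$map$individual[library$map$clade == best &
                                        !library$map$is_outgroup]
      members <- intersect(members, rt$tip.label)
      mrca <- ape::getMRCA(rt, members)
      inside <- query_id %in% ape::extract.clade(rt, mrca)$tip.label
      conflict <- conflict || !inside
    }
  }
  list(clade = best, margin = unname(margin),
       mean_distances = sort(means), placement_conflict = conflict)
}

# combined alignment of library loci with the query row appended
query_concat <- function(query, library, query_id) {
  alns <- lapply(names(library$alignments), function(loc) {
    a <- library$alignments[[loc]]
    q <- if (loc %in% names(query)) toupper(query[[loc]])
         else strrep("?", a$length)
    if (nchar(q) != a$length)
      stop("query sequence for locus '", loc, "' has length ", nchar(q),
           ", expected ", a$length)
    alignment(c(a$seqs, stats::setNames(q, query_id)), locus = loc)
  })
  concatenate(alns)
}

#' Two-step identification of a query against an incomplete library
#'
#' Step 1 ([assign_clade()]) places the query in a major clade. Step 2
#' restricts the library to that clade (plus the outgroup), builds a
#' bootstrapped NJ tree from the combined loci with the query included,
#' and tests, for the nearest species S in the clade, (i) whether
#' S plus the query forms a supported monophyletic group in which the
#' query is exclusively nested (S's own individuals must not retain a
#' supported clade excluding the query), and (ii) whether the
#' target-specific barcode gap for S still holds with the query
#' counted among S's individuals. The query is `identified` as S only
#' when both criteria hold; otherwise the result is `clade_only` (step 2
#' ran but failed, or the clade is too sparsely sampled) or `unresolved`
#' (step 1 was ambiguous).
#'
#' A candidate species represented by a single reference individual
#' cannot be confirmed (its intraspecific variation is unknowable, so the
#' gap test would be driven by the query itself); such cases stop at
#' `clade_only` with a sampling advisory.
#'
#' @inheritParams assign_clade
#' @param support_threshold minimum bootstrap percent for the monophyly
#'   criterion (default 75).
#' @param separation_threshold bootstrap percent at which a
#'   reference-only clade excluding the query counts as decisive evidence
#'   against nesting (default 90; borderline support for a pair of
#'   conspecific references is expected under a within-species star
#'   radiation and is not disqualifying).
#' @param boot_reps bootstrap replicates for the step-2 tree (default 500).
#' @param seed integer seed for the bootstrap.
#' @return list of class `cg_identification` with `query_id`,
#'   `step1` (clade, margin, placement_conflict), `species` (candidate or
#'   `NA`), `monophyletic`, `support`, `gap_exists`, `decision` and
#'   optionally `advisory`.
#' @export
identify_species <- function(query, library, query_id = "query",
                             support_threshold = 75,
                             separation_threshold = 90,
                             boot_reps = 500L,
                             seed = 1L, model = "K2P",
                             deletion = "pairwise") {
  step1 <- assign_clade(query, library, query_id, model, deletion)
  res <- list(query_id = query_id, step1 = step1, species = NA_character_,
              monophyletic = NA, support = NA_real_, gap_exists = NA,
              decision = "unresolved")
  class(res) <- "cg_identification"
  if (step1$placement_conflict) {
    res$advisory <- "ambiguous clade placement; densify clade sampling"
    return(res)
  }
  map <- library$map
  clade_members <- map$individual[map$clade == step1$clade &
                                  !map$is_outgroup]
  clade_species <- unique(map_species(map, clade_members))
  if (length(clade_species) < 2L) {
    res$decision <- "clade_only"
    res$advisory <- paste0("clade '", step1$clade, "' has fewer than 2 ",
                           "sampled species; densify sampling before the ",
                           "species-level step")
    return(res)
  }
  og <- outgroup_ids(map)
  keep <- c(clade_members, og)
  sub_alns <- lapply(library$alignments, function(a)
    alignment(a$seqs[intersect(names(a$seqs), keep)], locus = a$locus))
  sub_lib <- reference_library(sub_alns,
                               subset_map(map, keep), library$partitions)
  comb <- query_concat(query, sub_lib, query_id)
  dm <- distance_matrix(comb, model = model, deletion = deletion)
  qd <- dm$values[query_id, ]
  sp_means <- vapply(clade_species, function(s) {
    m <- map$individual[map$species == s]
    mean(qd[intersect(m, names(qd))], na.rm = TRUE)
  }, numeric(1L))
  S <- clade_species[which.min(sp_means)]
  res$species <- S
  tree <- bootstrap_nj(comb, n_reps = boot_reps, seed = seed,
                       model = model, deletion = deletion)
  rooted <- if (length(og) > 0L)
    try(root_with_outgroup(tree, intersect(og, tree$tip.label)),
        silent = TRUE) else tree
  if (inherits(rooted, "try-error")) {
    res$advisory <- "outgroup not separable in the step-2 tree"
    res$decision <- "clade_only"
    return(res)
  }
  s_ref <- intersect(map$individual[map$species == S], rooted$tip.label)
  mono <- is_monophyletic(rooted, c(s_ref, query_id))
  res$monophyletic <- mono$monophyletic
  res$support <- mono$support
  # exclusive nesting: the reference individuals of S must not form a
  # well-supported clade of their own that excludes the query (a query
  # merely sister to the species cluster is not nested within it)
  nested <- TRUE
  if (length(s_ref) >= 2L) {
    sep <- is_monophyletic(rooted, s_ref)
    if (isTRUE(sep$monophyletic) && !is.na(sep$support) &&
        sep$support >= separation_threshold)
      nested <- FALSE
  }
  res$nested <- nested
  # gap test with the query counted among S's individuals
  map_q <- rbind(as.data.frame(subset_map(map, keep)),
                 data.frame(individual = query_id, species = S,
                            clade = step1$clade, is_outgroup = FALSE))
  class(map_q) <- c("cg_species_map", "data.frame")
  tg <- target_gap(dm, map_q, target = S)
  res$gap_exists <- isTRUE(tg$gap_exists)
  res$target_gap <- tg
  ok_mono <- isTRUE(mono$monophyletic) && !is.na(mono$support) &&
             mono$support >= support_threshold && nested
  if (length(s_ref) < 2L) {
    res$decision <- "clade_only"
    res$advisory <- paste0("species '", S, "' has a single reference ",
                           "individual; its intraspecific variation is ",
                           "unknown - densify sampling")
    return(res)
  }
  res$decision <- if (ok_mono && isTRUE(tg$gap_exists)) "identified"
                  else "clade_only"
  if (res$decision == "clade_only" && !isTRUE(tg$gap_exists))
    res$advisory <- paste0("no target-specific barcode gap for '", S,
                           "'; inspect the PCA of the distance matrix ",
                           "(pca_scatter) and densify sampling")
  res
}

subset_map <- function(map, ids) {
  out <- map[map$individual %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cg_species_map", "data.frame")
  out
}

#' @export
print.cg_identification <- function(x, ...) {
  cat("Query '", x$query_id, "': step 1 -> clade '", x$step1$clade,
      "' (margin ", format(x$step1$margin, digits = 4), ")\n", sep = "")
  if (!is.na(x$species))
    cat("  step 2 -> nearest species '", x$species, "': monophyly ",
        ifelse(isTRUE(x$monophyletic), "yes", "no"),
        " (support ", ifelse(is.na(x$support), "NA", x$support),
        "), gap ", ifelse(isTRUE(x$gap_exists), "present", "absent"),
        "\n", sep = "")
  cat("  decision: ", x$decision, "\n", sep = "")
  if (!is.null(x$advisory)) cat("  advisory: ", x$advisory, "\n", sep = "")
  invisible(x)
}
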