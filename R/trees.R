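#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (Studier-Keppler criterion, via
#' \code{\link[ape]{nj}}). Tips are ordered lexicographically by id before
#' agglomeration so tie-breaking is deterministic and independent of input
#' order. Negative estimated branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch, preserving tip-to-tip path
#' lengths through the parent. An all-zero matrix returns a star tree.
#'
#' @param dm a `cg_dist` with no `NA` entries and at least 3 individuals.
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "cg_dist"))
  v <- dm$values
  if (anyNA(v)) {
    idx <- which(is.na(v) & upper.tri(v), arr.ind = TRUE)
    pairs <- apply(idx, 1L, function(r)
      paste(dm$ids[r[1L]], dm$ids[r[2L]], sep = "-"))
    stop("distance matrix has undefined entries (",
         paste(utils::head(pairs, 3L), collapse = ", "),
         "); switch deletion policy or prune individuals")
  }
  n <- length(dm$ids)
  if (n < 3L) stop("neighbor joining needs >= 3 individuals")
  ord <- order(dm$ids)
  v <- v[ord, ord]
  if (all(v == 0)) {  # degenerate: star tree, zero lengths
    txt <- paste0("(", paste0(dm$ids[ord], ":0", collapse = ","), ");")
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(v))
  clamp_negative_branches(tr)
}

# set negative branch lengths to 0, moving the deficit onto the sibling
# branch so paths through the parent keep their length
clamp_negative_branches <- function(tr) {
  if (is.null(tr$edge.length) || all(tr$edge.length >= 0)) return(tr)
  for (e in which(tr$edge.length < 0)) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent & seq_along(tr$edge.length) != e)
    if (length(sibs) > 0L) {
      s <- sibs[1L]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
    }
  }
  tr
}

#' Read / write Newick trees
#'
#' Bootstrap supports travel as integer internal-node labels.
#'
#' @param path file path.
#' @return `read_tree`: a `phylo`.
#' @export
read_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick(txt)
  ape::read.tree(text = txt)
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10L)
  invisible(path)
}

# cheap structural validation with a character offset in the error
check_newick <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error at character ", i,
                           ": unmatched ')'")
    }
  }
  if (depth != 0L)
    stop("Newick parse error at character ", length(chars),
         ": ", depth, " unclosed '('")
  if (!grepl(";", txt, fixed = TRUE))
    stop("Newick parse error at character ", length(chars),
         ": missing ';'")
  invisible(TRUE)
}

# canonical keys for the non-trivial bipartitions of a tree, relative to a
# fixed tip universe: each key lists the sorted block not containing the
# alphabetically first tip
bipartition_keys <- function(tree, all_tips = sort(tree$tip.label)) {
  ref <- sort(all_tips)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) {
    block <- labs[ix]
    if (ref %in% block) block <- setdiff(all_tips, block)
    paste(sort(block), collapse = "|")
  }, character(1L))
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, integer(1L))
  unique(keys[sizes >= 2L & sizes <= length(all_tips) - 2L])
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' aligned columns with replacement `n_reps` times, recomputing the
#' distance matrix and NJ tree each time. The support of each internal
#' bipartition of the reference tree is the percentage of (non-skipped)
#' replicate trees containing that bipartition, rounded to the nearest
#' integer and stored as node labels. Replicates whose resampled matrix
#' has undefined (saturated / no-overlap) distances are skipped and
#' counted; a warning is raised if more than 10\% are skipped.
#'
#' @param aln a [alignment()] object.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer; fixes all resampling.
#' @param model,deletion passed to [distance_matrix()].
#' @param indels optional `cg_indel_matrix` whose binary characters are
#'   appended to the resampling universe (coded characters are then
#'   resampled on the same footing as nucleotide columns; they do not
#'   enter the distance computation).
#' @return the reference `phylo` with integer `node.label` supports
#'   (root label empty) and attributes `n_reps`, `n_skipped`.
#' @export
bootstrap_nj <- function(aln, n_reps = 500L, seed = 1L,
                         model = "K2P", deletion = "pairwise",
                         indels = NULL) {
  stopifnot(inherits(aln, "cg_alignment"), n_reps >= 1L)
  codes <- aln_codes(aln)
  if (deletion == "complete") {
    keep <- colSums(codes >= 1L & codes <= 4L) == nrow(codes)
    if (!any(keep)) stop("complete deletion removed every column")
    codes <- codes[, keep, drop = FALSE]
  }
  enc <- encode_codes(codes)
  ref_dm <- as_cg_dist(dist_from_patterns(enc, enc$weights, model),
                       model, deletion)
  ref <- nj_tree(ref_dm)
  all_tips <- sort(ref$tip.label)
  ref_keys <- bipartition_keys(ref, all_tips)
  counts <- stats::setNames(numeric(length(ref_keys)), ref_keys)
  L <- length(enc$col_pattern)
  n_pat <- length(enc$weights)
  skipped <- 0L
  set.seed(as.integer(seed))
  for (r in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    w <- as.numeric(tabulate(enc$col_pattern[idx], n_pat))
    vb <- dist_from_patterns(enc, w, model)
    if (anyNA(vb)) { skipped <- skipped + 1L; next }
    tb <- nj_tree(as_cg_dist(vb, model, deletion))
    hit <- ref_keys %in% bipartition_keys(tb, all_tips)
    counts[hit] <- counts[hit] + 1
  }
  used <- n_reps - skipped
  if (skipped > 0.1 * n_reps)
    warning(skipped, " of ", n_reps, " bootstrap replicates skipped ",
            "(undefined distances)")
  if (used == 0L) stop("all bootstrap replicates were skipped")
  support <- round(100 * counts / used)
  ref <- set_support_labels(ref, support, all_tips)
  attr(ref, "n_reps") <- n_reps
  attr(ref, "n_skipped") <- skipped
  ref
}

# write per-bipartition supports onto the node labels of a tree
set_support_labels <- function(tree, support, all_tips) {
  ref_tip <- sort(all_tips)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  node_labels <- vapply(seq_along(pp), function(k) {
    block <- labs[pp[[k]]]
    if (ref_tip %in% block) block <- setdiff(all_tips, block)
    m <- length(block)
    if (m < 2L || m > length(all_tips) - 2L) return("")
    key <- paste(sort(block), collapse = "|")
    if (key %in% names(support)) as.character(support[[key]]) else ""
  }, character(1L))
  tree$node.label <- node_labels
  tree
}

#' Root a tree on an outgroup
#'
#' @param tree an unrooted `phylo` (supports as node labels allowed).
#' @param outgroup_tips character vector of outgroup tip labels (a single
#'   tip or a set forming a clan of the unrooted tree).
#' @return a rooted `phylo`; supports are carried with their bipartitions.
#' @export
root_with_outgroup <- function(tree, outgroup_tips) {
  missing_tips <- setdiff(outgroup_tips, tree$tip.label)
  if (length(missing_tips) > 0L)
    stop("unknown outgroup tip(s): ", paste(missing_tips, collapse = ", "))
  if (length(outgroup_tips) >= length(tree$tip.label))
    stop("outgroup not separable: outgroup covers all tips")
  ok <- length(outgroup_tips) == 1L ||
    ape::is.monophyletic(tree, outgroup_tips)
  if (!ok) stop("outgroup not separable: not a clan of the tree")
  ape::root(tree, outgroup = outgroup_tips, resolve.root = TRUE,
            edgelabel = TRUE)
}

#' Test monophyly of a tip set in a rooted tree
#'
#' @param tree a rooted `phylo`, optionally with support node labels.
#' @param tips tip labels.
#' @return list with `monophyletic` (logical) and `support` (integer
#'   percent of the subtending branch, `NA` when unavailable, e.g. a
#'   singleton set, the full tip set, or an unlabeled node).
#' @export
is_monophyletic <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0L)
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (length(tips) <= 1L)
    return(list(monophyletic = TRUE, support = NA_real_))
  if (length(tips) == length(tree$tip.label))
    return(list(monophyletic = TRUE, support = NA_real_))
  node <- ape::getMRCA(tree, tips)
  desc <- ape::extract.clade(tree, node)$tip.label
  mono <- setequal(desc, tips)
  sup <- NA_real_
  if (mono && !is.null(tree$node.label)) {
    lab <- tree$node.label[node - length(tree$tip.label)]
    if (!is.na(lab) && nzchar(lab))
      sup <- suppressWarnings(as.numeric(lab))
  }
  list(monophyletic = mono, support = sup)
}

#' Fitch parsimony score of an alignment on a given topology
#'
#' Sums the small-parsimony (Fitch) cost over alignment columns, treating
#' gaps and missing data as unknown states that contribute no cost.
#' Binary indel characters, if supplied, are scored as additional
#' two-state characters.
#'
#' @param tree a `phylo` whose tips match the alignment's individuals.
#' @param aln a [alignment()] object.
#' @param indels optional `cg_indel_matrix` from [simple_indel_coding()].
#' @return integer parsimony length.
#' @export
fitch_score <- function(tree, aln, indels = NULL) {
  stopifnot(inherits(aln, "cg_alignment"))
  if (!setequal(tree$tip.label, names(aln$seqs)))
    stop("tree tips do not match alignment individuals")
  m <- aln_matrix(aln)
  m[!(m %in% CG_LEVELS)] <- "?"
  m[m == "-"] <- "?"
  pd <- phangorn::phyDat(tolower(m), type = "DNA")
  score <- phangorn::parsimony(ape::unroot(tree), pd, method = "fitch")
  if (!is.null(indels) && ncol(indels$states) > 0L) {
    st <- indels$states[tree$tip.label, , drop = FALSE]
    pb <- phangorn::phyDat(st, type = "USER", levels = c("0", "1"),
                           ambiguity = "?")
    score <- score + phangorn::parsimony(ape::unroot(tree), pb,
                                         method = "fitch")
  }
  as.integer(score)
}
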