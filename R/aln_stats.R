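#' Number of variable sites
#'
#' A column is variable when it contains at least two distinct nucleotide
#' states among `{A,C,G,T}`; gaps and missing characters do not count as
#' states.
#'
#' @param aln a [alignment()] object.
#' @return integer count of variable columns.
#' @export
variable_sites <- function(aln) {
  codes <- aln_codes(aln)
  counts <- base_counts(codes)
  sum(colSums(counts > 0L) >= 2L)
}

#' Number of parsimony-informative sites
#'
#' A column is parsimony-informative when at least two nucleotide states
#' each occur in at least two sequences.
#'
#' @inheritParams variable_sites
#' @return integer count of informative columns.
#' @export
parsimony_informative_sites <- function(aln) {
  codes <- aln_codes(aln)
  counts <- base_counts(codes)
  sum(colSums(counts >= 2L) >= 2L)
}

# 4 x L matrix of per-column base counts
base_counts <- function(codes) {
  L <- ncol(codes)
  matrix(vapply(1:4, function(b) colSums(codes == b), numeric(L)),
         nrow = 4L, ncol = L, byrow = TRUE)
}

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Alignment summary statistics
#'
#' Per-locus descriptive statistics in the style of a barcode-marker
#' comparison table: ungapped length range, aligned length, counts and
#' percentages of variable and parsimony-informative characters
#' (percentages of the aligned length, rounded half-up to 2 decimals),
#' and the mean pairwise sequence divergence Pi taken from a distance
#' matrix computed on the same alignment.
#'
#' @param aln a [alignment()] object.
#' @param dm a `cg_dist` computed from `aln` (defaults to K2P, pairwise
#'   deletion). Pi is the mean of its off-diagonal entries.
#' @return list of class `cg_aln_stats`.
#' @export
alignment_stats <- function(aln, dm = NULL) {
  stopifnot(inherits(aln, "cg_alignment"))
  codes <- aln_codes(aln)
  ungapped <- rowSums(codes >= 1L & codes <= 4L)
  nv <- variable_sites(aln)
  np <- parsimony_informative_sites(aln)
  if (length(aln$seqs) < 2L) {
    pi <- NA_real_
  } else {
    if (is.null(dm)) dm <- distance_matrix(aln)
    off <- dm$values[upper.tri(dm$values)]
    pi <- mean(off, na.rm = TRUE)
  }
  structure(list(
    locus = aln$locus,
    length_range = c(min(ungapped), max(ungapped)),
    aligned_length = aln$length,
    n_variable = nv,
    pct_variable = round_half_up(100 * nv / aln$length),
    n_parsimony_informative = np,
    pct_parsimony_informative = round_half_up(100 * np / aln$length),
    pi = pi), class = "cg_aln_stats")
}

#' @export
print.cg_aln_stats <- function(x, ...) {
  cat(sprintf(
    "Locus %s\n  Length range (bp)      %d-%d\n  Aligned length (bp)    %d\n  Variable characters    %d (%.2f%%)\n  Parsimony informative  %d (%.2f%%)\n  Sequence divergence Pi %s\n",
    x$locus, x$length_range[1L], x$length_range[2L], x$aligned_length,
    x$n_variable, x$pct_variable, x$n_parsimony_informative,
    x$pct_parsimony_informative,
    if (is.na(x$pi)) "NA" else sprintf("%.4f", x$pi)))
  invisible(x)
}

#' Simple indel coding of gap characters
#'
#' Every distinct maximal gap run (a start/end column pair observed in at
#' least one sequence) becomes one binary presence/absence character. A
#' sequence scores 1 when it carries exactly that run, `?` when one of its
#' runs strictly contains the character's range with different endpoints
#' (the run subsumes the character, so presence is unknowable), and 0
#' otherwise. Terminal gap runs are coded like internal ones unless
#' `ignore_terminal_gaps` is set.
#'
#' @param aln a [alignment()] object.
#' @param ignore_terminal_gaps drop gap runs touching the first or last
#'   column before coding (default `FALSE`).
#' @return list of class `cg_indel_matrix` with `characters`
#'   (data.frame: locus, start, end) and `states` (individuals x
#'   characters character matrix over `{"0","1","?"}`).
#' @export
simple_indel_coding <- function(aln, ignore_terminal_gaps = FALSE) {
  stopifnot(inherits(aln, "cg_alignment"))
  m <- aln_matrix(aln)
  ids <- rownames(m)
  runs_per_seq <- lapply(seq_len(nrow(m)), function(i) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
  })
  all_runs <- unique(do.call(rbind, runs_per_seq))
  empty <- function() structure(list(
    characters = data.frame(locus = character(), start = integer(),
                            end = integer()),
    states = matrix(character(), nrow = length(ids), ncol = 0L,
                    dimnames = list(ids, NULL))),
    class = "cg_indel_matrix")
  if (is.null(all_runs) || nrow(all_runs) == 0L) return(empty())
  if (ignore_terminal_gaps)
    all_runs <- all_runs[all_runs[, "start"] > 1L &
                         all_runs[, "end"] < aln$length, , drop = FALSE]
  if (nrow(all_runs) == 0L) return(empty())
  all_runs <- all_runs[order(all_runs[, "start"], all_runs[, "end"]), ,
                       drop = FALSE]
  nch <- nrow(all_runs)
  states <- matrix("0", nrow = length(ids), ncol = nch,
                   dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    runs <- runs_per_seq[[i]]
    if (nrow(runs) == 0L) next
    for (k in seq_len(nch)) {
      s <- all_runs[k, "start"]; e <- all_runs[k, "end"]
      exact <- runs[, "start"] == s & runs[, "end"] == e
      if (any(exact)) { states[i, k] <- "1"; next }
      subsumes <- runs[, "start"] <= s & runs[, "end"] >= e &
                  !(runs[, "start"] == s & runs[, "end"] == e)
      if (any(subsumes)) states[i, k] <- "?"
    }
  }
  structure(list(
    characters = data.frame(locus = aln$locus,
                            start = unname(all_runs[, "start"]),
                            end = unname(all_runs[, "end"])),
    states = states), class = "cg_indel_matrix")
}

#' @export
print.cg_indel_matrix <- function(x, ...) {
  cat("Indel character matrix: ", nrow(x$characters), " character(s) x ",
      nrow(x$states), " individuals\n", sep = "")
  invisible(x)
}
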