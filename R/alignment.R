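#' Construct an aligned sequence set
#'
#' An alignment holds equal-length sequences over the alphabet
#' `{A,C,G,T,-,N,?}` for one locus. `-` is an indel (gap) state and takes
#' part in indel coding; `N` and `?` are missing data and are ignored
#' everywhere. Any other character (e.g. IUPAC ambiguity codes) is mapped
#' to `?` with a warning, since downstream methods treat ambiguity as
#' absence of information.
#'
#' @param seqs named character vector, one string per individual.
#' @param locus locus name.
#' @return object of class `cg_alignment` with elements `locus`, `seqs`
#'   (upper-case, validated) and `length` (number of aligned columns).
#' @export
alignment <- function(seqs, locus = "locus") {
  if (length(seqs) == 0L) stop("alignment needs at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named by individual id")
  if (anyDuplicated(ids))
    stop("duplicate individual id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(seqs))
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("not aligned: record '", bad, "' has length ", nchar(seqs[bad]),
         ", expected ", lens[1L])
  }
  if (lens[1L] < 1L) stop("aligned length must be >= 1")
  n_bad <- 0L
  fixed <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    out <- !ch %in% c("A", "C", "G", "T", "-", "N", "?")
    if (any(out)) {
      n_bad <<- n_bad + sum(out)
      ch[out] <- "?"
      s <- paste(ch, collapse = "")
    }
    s
  }, character(1L))
  if (n_bad > 0L)
    warning(n_bad, " character(s) outside {A,C,G,T,-,N,?} mapped to '?'")
  structure(list(locus = locus, seqs = fixed, length = unname(lens[1L])),
            class = "cg_alignment")
}

#' Read an aligned multi-FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @param locus_name locus label stored on the alignment; defaults to the
#'   file name without extension.
#' @return a [alignment()] object.
#' @export
read_alignment <- function(path, locus_name = NULL) {
  if (is.null(locus_name))
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  seqs <- vapply(recs, as.character, character(1L))
  names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1L))
  alignment(seqs, locus = locus_name)
}

#' Write an alignment to FASTA
#' @param aln a [alignment()] object.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "cg_alignment"))
  seqinr::write.fasta(as.list(aln$seqs), names = names(aln$seqs),
                      file.out = path, nbchar = 80L)
  invisible(path)
}

#' @export
print.cg_alignment <- function(x, ...) {
  cat("Alignment '", x$locus, "': ", length(x$seqs), " sequences x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

# alignment as individuals x columns character matrix
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- names(aln$seqs)
  m
}

# integer codes: A=1 C=2 G=3 T=4, gap=5, missing(N/?)=0
CG_LEVELS <- c("A", "C", "G", "T", "-")

aln_codes <- function(aln) {
  m <- aln_matrix(aln)
  z <- match(m, CG_LEVELS, nomatch = 0L)  # N/? fall through to 0
  dim(z) <- dim(m)
  dimnames(z) <- dimnames(m)
  z
}

#' Concatenate per-locus alignments into a combined matrix
#'
#' Rows are the union of individuals over all loci, in first-seen order;
#' an individual missing from a locus is padded with `?` over that locus's
#' full aligned length. Used to build the multi-locus barcode matrix
#' (e.g. cpDNA + nuclear regions combined for higher discriminatory power).
#'
#' @param alignments list of [alignment()] objects, in the declared locus
#'   order.
#' @param locus name for the combined alignment.
#' @return a single [alignment()] object whose aligned length is the sum of
#'   the per-locus aligned lengths.
#' @export
concatenate <- function(alignments, locus = "combined") {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  stopifnot(all(vapply(alignments, inherits, logical(1L), "cg_alignment")))
  if (length(alignments) == 1L) return(alignments[[1L]])
  ids <- unique(unlist(lapply(alignments, function(a) names(a$seqs))))
  rows <- vapply(ids, function(id) {
    paste(vapply(alignments, function(a) {
      if (id %in% names(a$seqs)) unname(a$seqs[id])
      else strrep("?", a$length)
    }, character(1L)), collapse = "")
  }, character(1L))
  names(rows) <- ids
  alignment(rows, locus = locus)
}
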