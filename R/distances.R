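#' Kimura 2-parameter distance between two aligned sequences
#'
#' Over the sites where both sequences carry an unambiguous nucleotide,
#' let P be the proportion of transition differences (A<->G, C<->T) and Q
#' the proportion of transversion differences. The distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. When either log argument
#' is non-positive the pair is saturated and `NA` is returned with
#' attribute `flag = "saturated"`; with no comparable sites `NA` carries
#' `flag = "no overlap"`.
#'
#' @param seq_a,seq_b character strings (or character vectors of single
#'   characters) of equal aligned length.
#' @return the distance (numeric scalar), possibly `NA` with a `flag`
#'   attribute.
#' @export
k2p <- function(seq_a, seq_b) {
  a <- to_chars(seq_a); b <- to_chars(seq_b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ca <- code_chars(a); cb <- code_chars(b)
  ok <- ca >= 1L & ca <= 4L & cb >= 1L & cb <= 4L
  n <- sum(ok)
  if (n == 0L) return(structure(NA_real_, flag = "no overlap"))
  da <- ca[ok]; db <- cb[ok]
  diff <- da != db
  # purines coded 1 (A), 3 (G); pyrimidines 2 (C), 4 (T)
  ts <- diff & ((da %% 2L) == (db %% 2L))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  k2p_formula(P, Q)
}

k2p_formula <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(structure(NA_real_, flag = "saturated"))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Uncorrected p-distance between two aligned sequences
#' @inheritParams k2p
#' @return proportion of differing sites among comparable sites.
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- to_chars(seq_a); b <- to_chars(seq_b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  ca <- code_chars(a); cb <- code_chars(b)
  ok <- ca >= 1L & ca <= 4L & cb >= 1L & cb <= 4L
  if (!any(ok)) return(structure(NA_real_, flag = "no overlap"))
  sum(ca[ok] != cb[ok]) / sum(ok)
}

to_chars <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) strsplit(toupper(s), "", TRUE)[[1L]]
  else toupper(as.character(s))
}
code_chars <- function(ch) {
  z <- match(ch, CG_LEVELS, nomatch = 0L)
  z
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln a [alignment()] object.
#' @param model `"K2P"` (Kimura 2-parameter) or `"p"` (uncorrected).
#' @param deletion `"pairwise"` (default; each pair uses the sites where
#'   both members are unambiguous) or `"complete"` (columns containing any
#'   gap or missing character in any sequence are removed first).
#' @return object of class `cg_dist`: list with `ids`, `values` (symmetric
#'   numeric matrix, `NA` where a pair is saturated or has no shared
#'   sites), `model`, `deletion`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "cg_alignment"))
  if (length(aln$seqs) < 2L) stop("need >= 2 sequences")
  codes <- aln_codes(aln)
  if (deletion == "complete") {
    keep <- colSums(codes >= 1L & codes <= 4L) == nrow(codes)
    if (!any(keep))
      stop("complete deletion removed every column")
    codes <- codes[, keep, drop = FALSE]
  }
  enc <- encode_codes(codes)
  values <- dist_from_patterns(enc, enc$weights, model)
  structure(list(ids = rownames(codes), values = values,
                 model = model, deletion = deletion),
            class = "cg_dist")
}

#' @export
print.cg_dist <- function(x, ...) {
  cat("Distance matrix (", x$model, ", ", x$deletion, " deletion): ",
      length(x$ids), " individuals, ", sum(is.na(x$values[upper.tri(x$values)])),
      " undefined pair(s)\n", sep = "")
  invisible(x)
}

# Collapse alignment columns to site patterns with multiplicities.
# Returns indicator matrices (patterns x individuals) for the four bases
# plus column -> pattern index, so bootstrap replicates reduce to
# reweighting patterns.
encode_codes <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = "\r")
  pat <- match(key, unique(key))
  first <- !duplicated(pat)
  pc <- t(codes[, first, drop = FALSE])       # patterns x individuals
  list(I = lapply(1:4, function(b) (pc == b) * 1),
       col_pattern = pat,
       weights = as.numeric(tabulate(pat, max(pat))),
       n = nrow(codes), ids = rownames(codes))
}

# Weighted pairwise counts via crossproducts over site patterns.
dist_from_patterns <- function(enc, w, model) {
  I <- enc$I
  Rm <- I[[1L]] + I[[3L]]                     # purines A,G
  Ym <- I[[2L]] + I[[4L]]                     # pyrimidines C,T
  Vw <- (Rm + Ym) * w
  shared <- crossprod(Rm + Ym, Vw)
  matches <- crossprod(I[[1L]], I[[1L]] * w) + crossprod(I[[2L]], I[[2L]] * w) +
             crossprod(I[[3L]], I[[3L]] * w) + crossprod(I[[4L]], I[[4L]] * w)
  tvh <- crossprod(Rm, Ym * w)
  TV <- tvh + t(tvh)
  TS <- shared - matches - TV
  n <- enc$n
  if (model == "p") {
    D <- (TS + TV) / shared
  } else {
    P <- TS / shared
    Q <- TV / shared
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    D <- -0.5 * log(pmax(w1, 0)) - 0.25 * log(pmax(w2, 0))
    D[w1 <= 0 | w2 <= 0] <- NA_real_
  }
  D[shared == 0] <- NA_real_
  diag(D) <- 0
  D <- (D + t(D)) / 2  # enforce exact symmetry against fp noise
  dimnames(D) <- list(enc$ids, enc$ids)
  D
}

#' Write a distance matrix
#'
#' @param dm a `cg_dist` object.
#' @param path output path.
#' @param format `"phylip"` (square), `"phylip-lower"` (lower triangle) or
#'   `"tsv"` (square, with header row/column).
#' @export
write_distance_matrix <- function(dm, path,
                                  format = c("phylip", "phylip-lower", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dm, "cg_dist"))
  n <- length(dm$ids)
  if (n == 0L) stop("empty distance matrix")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("id", dm$ids), collapse = "\t"), con)
    for (i in seq_len(n))
      writeLines(paste(c(dm$ids[i], fmt(dm$values[i, ])), collapse = "\t"), con)
  } else {
    writeLines(sprintf("%5d", n), con)
    for (i in seq_len(n)) {
      vals <- if (format == "phylip") dm$values[i, ]
              else dm$values[i, seq_len(i - 1L)]
      writeLines(paste(c(sprintf("%-10s", dm$ids[i]), fmt(vals)),
                       collapse = "  "), con)
    }
  }
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path input path.
#' @param model,deletion metadata to stamp on the result (not stored in the
#'   file formats).
#' @return a `cg_dist` object.
#' @export
read_distance_matrix <- function(path, model = "K2P", deletion = "pairwise") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty distance matrix file")
  first <- strsplit(trimws(lines[1L]), "\t|\\s+")[[1L]]
  if (first[1L] == "id") {                      # tsv dialect
    ids <- first[-1L]
    n <- length(ids)
    vals <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
      vals[i, ] <- suppressWarnings(as.numeric(f[-1L]))
    }
  } else {                                      # phylip dialects
    n <- as.integer(first[1L])
    ids <- character(n)
    vals <- matrix(0, n, n)
    for (i in seq_len(n)) {
      f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
      ids[i] <- f[1L]
      x <- suppressWarnings(as.numeric(f[-1L]))
      if (length(x) == n) vals[i, ] <- x
      else if (length(x) == i - 1L) {           # lower triangle
        if (i > 1L) { vals[i, seq_len(i - 1L)] <- x
                      vals[seq_len(i - 1L), i] <- x }
      } else stop("malformed distance row for '", ids[i], "'")
    }
    dimnames(vals) <- list(ids, ids)
  }
  structure(list(ids = ids, values = vals, model = model, deletion = deletion),
            class = "cg_dist")
}

# cg_dist from a plain symmetric matrix (used by simulator oracles/tests)
as_cg_dist <- function(values, model = "K2P", deletion = "pairwise") {
  structure(list(ids = rownames(values), values = values,
                 model = model, deletion = deletion), class = "cg_dist")
}
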