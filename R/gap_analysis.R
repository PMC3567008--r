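#' All-species barcode-gap report
#'
#' Classifies every unordered pair of ingroup individuals as intraspecific
#' or interspecific and measures the overlap of the two distance
#' distributions: the fraction of interspecific distances at or below the
#' largest intraspecific distance. A barcode gap across the whole library
#' corresponds to an overlap fraction of zero.
#'
#' @param dm a `cg_dist`.
#' @param map a [species_map()]; outgroup individuals are excluded.
#' @return list of class `cg_gap_report` with data.frames `intra`
#'   (species, distance) and `inter` (species_a, species_b, distance) and
#'   `overlap_fraction` (`NA` when there are no intraspecific pairs).
#' @export
gap_report <- function(dm, map) {
  stopifnot(inherits(dm, "cg_dist"), inherits(map, "cg_species_map"))
  ids <- intersect(dm$ids, ingroup_ids(map))
  sp <- map_species(map, ids)
  n <- length(ids)
  if (n < 2L) stop("need >= 2 ingroup individuals")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  v <- dm$values[ids, ids][upper.tri(dm$values[ids, ids])]
  same <- sp[idx[, 1L]] == sp[idx[, 2L]]
  intra <- data.frame(species = sp[idx[same, 1L]], distance = v[same],
                      stringsAsFactors = FALSE)
  inter <- data.frame(species_a = pmin(sp[idx[!same, 1L]], sp[idx[!same, 2L]]),
                      species_b = pmax(sp[idx[!same, 1L]], sp[idx[!same, 2L]]),
                      distance = v[!same], stringsAsFactors = FALSE)
  overlap <- if (nrow(intra) == 0L) NA_real_
             else mean(inter$distance <= max(intra$distance, na.rm = TRUE),
                       na.rm = TRUE)
  structure(list(intra = intra, inter = inter,
                 overlap_fraction = overlap), class = "cg_gap_report")
}

#' @export
print.cg_gap_report <- function(x, ...) {
  cat("Barcode-gap report: ", nrow(x$intra), " intraspecific / ",
      nrow(x$inter), " interspecific pairs; overlap fraction ",
      format(x$overlap_fraction, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Target-specific ("modified") barcode-gap test
#'
#' Tests whether one focal species is separable from its closest
#' relatives under incomplete sampling: the gap exists when the smallest
#' distance from any focal individual to any relative individual exceeds
#' the largest distance among focal individuals. Only focal-to-relative
#' distances count; relative-to-relative variation is irrelevant to the
#' focal species' identifiability.
#'
#' @param dm a `cg_dist`.
#' @param map a [species_map()].
#' @param target focal species name.
#' @param relatives character vector of relative species, or `"auto"` to
#'   take the `k` species with the smallest mean interspecific distance to
#'   the target.
#' @param k number of relatives resolved by `"auto"` (default 2).
#' @param bin_width histogram bin width in distance units (default 0.002).
#' @return list of class `cg_target_gap` with `target`, `relatives`,
#'   `max_intra`, `min_inter`, `gap_exists` and a `histogram` data.frame
#'   (`bin_left`, `count_intra`, `count_inter`). For a singleton target
#'   `max_intra` and `gap_exists` are `NA` with an advisory attribute.
#' @export
target_gap <- function(dm, map, target, relatives = "auto", k = 2L,
                       bin_width = 0.002) {
  stopifnot(inherits(dm, "cg_dist"), inherits(map, "cg_species_map"))
  ids <- intersect(dm$ids, map$individual)
  sp <- map_species(map, ids)
  if (!target %in% sp) stop("target species '", target, "' not found")
  tgt_ids <- ids[sp == target]
  v <- dm$values[ids, ids]
  if (identical(relatives, "auto")) {
    others <- setdiff(unique(sp[!ids %in% outgroup_ids(map)]), target)
    if (length(others) == 0L) stop("no candidate relatives")
    mean_d <- vapply(others, function(s)
      mean(v[tgt_ids, ids[sp == s], drop = FALSE], na.rm = TRUE),
      numeric(1L))
    relatives <- names(sort(mean_d))[seq_len(min(k, length(others)))]
  }
  if (length(relatives) == 0L) stop("relatives set is empty")
  rel_ids <- ids[sp %in% relatives]
  if (length(rel_ids) == 0L) stop("no individuals for relatives")
  inter_d <- as.vector(v[tgt_ids, rel_ids, drop = FALSE])
  min_inter <- min(inter_d, na.rm = TRUE)
  if (length(tgt_ids) < 2L) {
    max_intra <- NA_real_
    gap <- NA
    advisory <- "target has a single individual; add conspecific samples"
  } else {
    intra_m <- v[tgt_ids, tgt_ids]
    intra_d <- intra_m[upper.tri(intra_m)]
    max_intra <- max(intra_d, na.rm = TRUE)
    gap <- min_inter > max_intra
    advisory <- NULL
  }
  intra_d <- if (length(tgt_ids) >= 2L) {
    im <- v[tgt_ids, tgt_ids]; im[upper.tri(im)]
  } else numeric(0)
  lo <- 0
  hi <- max(c(intra_d, inter_d), na.rm = TRUE)
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  hist_df <- data.frame(
    bin_left = breaks[-length(breaks)],
    count_intra = graphics::hist(intra_d, breaks = breaks,
                                 plot = FALSE)$counts,
    count_inter = graphics::hist(inter_d, breaks = breaks,
                                 plot = FALSE)$counts)
  out <- structure(list(target = target, relatives = relatives,
                        max_intra = max_intra, min_inter = min_inter,
                        gap_exists = gap, histogram = hist_df),
                   class = "cg_target_gap")
  if (!is.null(advisory)) attr(out, "advisory") <- advisory
  out
}

#' @export
print.cg_target_gap <- function(x, ...) {
  cat("Target barcode gap for '", x$target, "' vs {",
      paste(x$relatives, collapse = ", "), "}:\n  max intraspecific ",
      format(x$max_intra, digits = 4), ", min to relatives ",
      format(x$min_inter, digits = 4), " -> gap ",
      ifelse(is.na(x$gap_exists), "NA",
             ifelse(x$gap_exists, "present", "absent")), "\n", sep = "")
  if (!is.null(attr(x, "advisory")))
    cat("  advisory: ", attr(x, "advisory"), "\n", sep = "")
  invisible(x)
}

#' Principal components view of a distance matrix
#'
#' Treats the rows of the symmetric distance matrix as observations and
#' its columns as variables, centers the columns, and eigendecomposes the
#' covariance matrix (this is PCA of the distance matrix as a data table,
#' not principal coordinates analysis of the distances; see the methods
#' vignette). Useful when the all-species barcode gap fails: clusters of
#' individuals with similar distance profiles separate in the first two
#' components.
#'
#' @param dm a `cg_dist` with at least 3 individuals and no `NA`.
#' @return list of class `cg_pca` with `coordinates` (individuals x
#'   components), `eigenvalues` (non-increasing) and `variance_explained`.
#' @export
pca_scatter <- function(dm) {
  stopifnot(inherits(dm, "cg_dist"))
  if (length(dm$ids) < 3L) stop("PCA needs >= 3 individuals")
  if (anyNA(dm$values)) stop("distance matrix has undefined entries")
  x <- dm$values
  if (all(x == x[1L])) {
    k <- length(dm$ids)
    return(structure(list(
      coordinates = matrix(0, k, k - 1L,
                           dimnames = list(dm$ids,
                                           paste0("PC", seq_len(k - 1L)))),
      eigenvalues = rep(0, k - 1L),
      variance_explained = rep(NA_real_, k - 1L)), class = "cg_pca"))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(coordinates = pc$x,
                 eigenvalues = ev,
                 variance_explained = ev / sum(ev)), class = "cg_pca")
}

#' @export
print.cg_pca <- function(x, ...) {
  cat("PCA of distance matrix: ", nrow(x$coordinates), " individuals; ",
      "PC1 ", sprintf("%.1f%%", 100 * x$variance_explained[1L]),
      ", PC2 ", sprintf("%.1f%%", 100 * x$variance_explained[2L]),
      " of variance\n", sep = "")
  invisible(x)
}
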