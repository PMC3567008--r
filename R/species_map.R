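#' Construct an individual -> species -> clade map
#'
#' The map plays the role of the study's voucher table: every sequenced
#' individual carries a nominal species label, every species belongs to
#' exactly one major clade, and outgroup individuals (used only to root
#' trees) are flagged.
#'
#' @param individual,species,clade character vectors of equal length.
#' @param is_outgroup logical vector (default all `FALSE`).
#' @return a `data.frame` of class `cg_species_map` with columns
#'   `individual`, `species`, `clade`, `is_outgroup`.
#' @export
species_map <- function(individual, species, clade,
                        is_outgroup = rep(FALSE, length(individual))) {
  df <- data.frame(individual = as.character(individual),
                   species = as.character(species),
                   clade = as.character(clade),
                   is_outgroup = as.logical(is_outgroup),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$individual))
    stop("duplicate individual: ",
         df$individual[duplicated(df$individual)][1L])
  sp_clade <- unique(df[, c("species", "clade")])
  if (anyDuplicated(sp_clade$species)) {
    bad <- sp_clade$species[duplicated(sp_clade$species)][1L]
    stop("species '", bad, "' is mapped to more than one clade")
  }
  og_sp <- unique(df$species[df$is_outgroup])
  if (any(og_sp %in% df$species[!df$is_outgroup]))
    stop("outgroup species also appears among ingroup individuals")
  class(df) <- c("cg_species_map", "data.frame")
  df
}

#' Read a species map from TSV
#'
#' Expects a header with columns `individual`, `species`, `clade` and an
#' optional `is_outgroup` (0/1) column.
#'
#' @param path path to a tab-separated file.
#' @return a [species_map()] object.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("individual", "species", "clade")
  if (!all(need %in% names(df)))
    stop("species map must have columns: ", paste(need, collapse = ", "))
  og <- if ("is_outgroup" %in% names(df)) df$is_outgroup %in% c("1", "TRUE", "true")
        else rep(FALSE, nrow(df))
  species_map(df$individual, df$species, df$clade, og)
}

#' Write a species map to TSV
#' @param map a [species_map()] object.
#' @param path output path.
#' @export
write_species_map <- function(map, path) {
  out <- as.data.frame(map)
  out$is_outgroup <- as.integer(out$is_outgroup)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

map_species <- function(map, ids) {
  map$species[match(ids, map$individual)]
}
map_clade <- function(map, ids) {
  map$clade[match(ids, map$individual)]
}
ingroup_ids <- function(map) map$individual[!map$is_outgroup]
outgroup_ids <- function(map) map$individual[map$is_outgroup]

#' Bundle aligned loci, a species map and genome partitions
#'
#' A reference library is the unit the identification and incongruence
#' procedures operate on: one alignment per locus (all sharing one
#' individual universe; an individual may be absent from a locus), a
#' species map covering every individual, and a genome label
#' (`"cpDNA"` or `"nuclear"`) per locus.
#'
#' @param alignments named list of [alignment()] objects (names = loci).
#' @param map a [species_map()].
#' @param partitions named character vector, locus -> `"cpDNA"`/`"nuclear"`.
#' @return object of class `cg_library`.
#' @export
reference_library <- function(alignments, map, partitions) {
  stopifnot(inherits(map, "cg_species_map"))
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    stop("alignments must be a named list (names = locus names)")
  if (!all(names(alignments) %in% names(partitions)))
    stop("partition labels must cover all loci")
  if (!all(partitions %in% c("cpDNA", "nuclear")))
    stop("partition labels must be 'cpDNA' or 'nuclear'")
  all_ids <- unique(unlist(lapply(alignments, function(a) names(a$seqs))))
  unmapped <- setdiff(all_ids, map$individual)
  if (length(unmapped) > 0L)
    stop("individual(s) not in species map: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  structure(list(alignments = alignments, map = map,
                 partitions = partitions[names(alignments)]),
            class = "cg_library")
}

#' @export
print.cg_library <- function(x, ...) {
  cat("Reference library: ", length(x$alignments), " loci (",
      paste(names(x$alignments), unname(x$partitions), sep = "/",
            collapse = ", "), "), ",
      nrow(x$map), " individuals, ",
      length(unique(x$map$species[!x$map$is_outgroup])), " ingroup species, ",
      length(unique(x$map$clade[!x$map$is_outgroup])), " clades\n", sep = "")
  invisible(x)
}

# combined alignment of one genome partition (or all loci)
library_concat <- function(lib, genome = NULL) {
  keep <- if (is.null(genome)) names(lib$alignments)
          else names(lib$alignments)[lib$partitions == genome]
  if (length(keep) == 0L) stop("no loci with partition '", genome, "'")
  concatenate(lib$alignments[keep],
              locus = if (is.null(genome)) "combined" else genome)
}
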