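#' Configuration for the clade-structured barcode-library simulator
#'
#' The simulator emulates a multi-locus barcode reference library for a
#' genus sampled by major clades: an ultrametric genealogy in which the
#' major clades radiate at depth `d_clade`, species within a clade at
#' depth `d_species`, and individuals within a species coalesce in a star
#' at depth `d_intra` (expected substitutions per site); a single
#' outgroup individual attaches at `d_outgroup`. Sequences evolve under a
#' two-parameter (transition/transversion) substitution process with
#' ratio `kappa`, matching the K2P distance estimator. Indels are
#' simulated as deletion events (geometric lengths) so all sequences stay
#' in shared alignment coordinates. Hybrids get their cpDNA loci from a
#' maternal lineage and their nuclear locus from a paternal lineage in a
#' different clade; mislabels are individuals relabeled to a species in a
#' different clade.
#'
#' @param n_clades number of ingroup clades (default 9).
#' @param species_per_clade species per clade (default 3).
#' @param individuals_per_species inclusive range, e.g. `c(1, 7)`.
#' @param locus_lengths named numeric vector of aligned lengths (bp);
#'   defaults `c(ndhF = 1745, trnSG = 681, waxy = 1527)`.
#' @param partitions named genome labels per locus (`"cpDNA"`/`"nuclear"`).
#' @param d_clade,d_species,d_intra,d_outgroup depths in expected
#'   substitutions/site; must satisfy
#'   `d_intra < d_species < d_clade < d_outgroup` (defaults 0.005, 0.03,
#'   0.08, 0.12).
#' @param kappa transition:transversion rate ratio (default 2).
#' @param indel_rate deletion events per site per unit depth (default
#'   0.02).
#' @param mean_indel_length mean deletion length in bp (geometric;
#'   default 3).
#' @param n_hybrids,n_mislabels planted anomalies (default 0).
#' @param seed integer; fixes all randomness.
#' @return list of class `cg_sim_config`.
#' @export
sim_config <- function(n_clades = 9L, species_per_clade = 3L,
                       individuals_per_species = c(1L, 7L),
                       locus_lengths = c(ndhF = 1745L, trnSG = 681L,
                                         waxy = 1527L),
                       partitions = c(ndhF = "cpDNA", trnSG = "cpDNA",
                                      waxy = "nuclear"),
                       d_clade = 0.08, d_species = 0.03, d_intra = 0.005,
                       d_outgroup = 0.12, kappa = 2, indel_rate = 0.02,
                       mean_indel_length = 3, n_hybrids = 0L,
                       n_mislabels = 0L, seed = 1L) {
  if (!(d_intra < d_species && d_species < d_clade && d_clade < d_outgroup))
    stop("depths must satisfy d_intra < d_species < d_clade < d_outgroup")
  if (any(c(d_intra, indel_rate, kappa) < 0)) stop("rates must be >= 0")
  if (!setequal(names(locus_lengths), names(partitions)))
    stop("locus_lengths and partitions must name the same loci")
  structure(list(n_clades = as.integer(n_clades),
                 species_per_clade = as.integer(species_per_clade),
                 individuals_per_species = as.integer(individuals_per_species),
                 locus_lengths = locus_lengths, partitions = partitions,
                 d_clade = d_clade, d_species = d_species,
                 d_intra = d_intra, d_outgroup = d_outgroup,
                 kappa = kappa, indel_rate = indel_rate,
                 mean_indel_length = mean_indel_length,
                 n_hybrids = as.integer(n_hybrids),
                 n_mislabels = as.integer(n_mislabels),
                 seed = as.integer(seed)), class = "cg_sim_config")
}

# K80 substitution: evolve integer-coded sequence over branch length d
# (expected substitutions/site). Gap state (5) is inert; missing (0) stays.
evolve_seq <- function(seq, d, kappa) {
  if (d <= 0) return(seq)
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2     # to the transition partner
  p_tv <- 0.25 - 0.25 * e1                # to each transversion partner
  live <- which(seq >= 1L & seq <= 4L)
  if (length(live) == 0L) return(seq)
  u <- stats::runif(length(live))
  # partner tables: codes A=1 C=2 G=3 T=4; transition partner, then the
  # two transversion partners of each base
  ts_p <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  cur <- seq[live]
  new <- cur
  m1 <- u < p_ts
  m2 <- !m1 & u < p_ts + p_tv
  m3 <- !m1 & !m2 & u < p_ts + 2 * p_tv
  new[m1] <- ts_p[cur[m1]]
  new[m2] <- tv1[cur[m2]]
  new[m3] <- tv2[cur[m3]]
  seq[live] <- new
  seq
}

# apply Poisson(indel_rate * d * L) deletion events of geometric length
apply_deletions <- function(seq, d, rate, mean_len) {
  if (rate <= 0 || d <= 0) return(seq)
  L <- length(seq)
  n_ev <- stats::rpois(1L, rate * d * L)
  if (n_ev == 0L) return(seq)
  for (k in seq_len(n_ev)) {
    len <- 1L + stats::rgeom(1L, 1 / mean_len)
    start <- sample.int(L, 1L)
    seq[start:min(L, start + len - 1L)] <- 5L
  }
  seq
}

evolve_branch <- function(seq, d, cfg) {
  seq <- evolve_seq(seq, d, cfg$kappa)
  apply_deletions(seq, d, cfg$indel_rate, cfg$mean_indel_length)
}

#' Simulate a two-genome barcode reference library with known truth
#'
#' @param cfg a [sim_config()].
#' @return list of class `cg_sim` with elements `library` (a
#'   [reference_library()]), `truth` (data.frame: individual, role,
#'   nominal/true species and clade, maternal/paternal for hybrids) and
#'   internal ancestral states enabling [plant_hybrid()].
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "cg_sim_config"))
  set.seed(cfg$seed)
  loci <- names(cfg$locus_lengths)
  # layout: clades/species/individual counts
  clades <- sprintf("c%d", seq_len(cfg$n_clades))
  species <- unlist(lapply(clades, function(cl)
    sprintf("%s_sp%d", cl, seq_len(cfg$species_per_clade))))
  sp_clade <- rep(clades, each = cfg$species_per_clade)
  n_ind <- sample(cfg$individuals_per_species[1L]:
                  cfg$individuals_per_species[2L],
                  length(species), replace = TRUE)
  names(n_ind) <- species
  inds <- unlist(lapply(seq_along(species), function(s)
    sprintf("%s_i%d", species[s], seq_len(n_ind[s]))))
  ind_sp <- rep(species, n_ind)
  # ancestral sequences per locus: root -> ingroup -> clade -> species node
  sp_nodes <- vector("list", length(loci)); names(sp_nodes) <- loci
  tip_seqs <- vector("list", length(loci)); names(tip_seqs) <- loci
  for (loc in loci) {
    L <- cfg$locus_lengths[[loc]]
    root <- sample.int(4L, L, replace = TRUE)
    og_tip <- evolve_branch(root, cfg$d_outgroup, cfg)
    ingroup <- evolve_branch(root, cfg$d_outgroup - cfg$d_clade, cfg)
    # one clade stem per clade (shared by its species), then one branch
    # from the clade's species radiation down to each species node
    clade_nodes <- lapply(clades, function(cl)
      evolve_branch(ingroup, cfg$d_clade - cfg$d_species, cfg))
    names(clade_nodes) <- clades
    nodes <- lapply(species, function(s)
      evolve_branch(clade_nodes[[sp_clade[match(s, species)]]],
                    cfg$d_species - cfg$d_intra, cfg))
    names(nodes) <- species
    sp_nodes[[loc]] <- nodes
    tips <- lapply(seq_along(inds), function(i)
      evolve_branch(nodes[[ind_sp[i]]], cfg$d_intra, cfg))
    names(tips) <- inds
    tips[["outgroup_i1"]] <- og_tip
    tip_seqs[[loc]] <- tips
  }
  truth <- data.frame(individual = inds, nominal_species = ind_sp,
                      nominal_clade = sp_clade[match(ind_sp, species)],
                      role = "normal", true_species = ind_sp,
                      maternal = NA_character_, paternal = NA_character_,
                      stringsAsFactors = FALSE)
  sim <- structure(list(cfg = cfg, loci = loci, species = species,
                        sp_clade = stats::setNames(sp_clade, species),
                        n_ind = n_ind, sp_nodes = sp_nodes,
                        tip_seqs = tip_seqs, truth = truth),
                   class = "cg_sim")
  # planted anomalies
  if (cfg$n_hybrids > 0L)
    for (k in seq_len(cfg$n_hybrids)) {
      el <- eligible_parents(sim)
      pick <- el[sample.int(nrow(el), 1L), ]
      sim <- plant_hybrid(sim, pick$maternal, pick$paternal, reseed = FALSE)
    }
  if (cfg$n_mislabels > 0L) sim <- plant_mislabels(sim, cfg$n_mislabels)
  finalize_sim(sim)
}

# maternal/paternal candidate pairs: different clades, both >= 2 inds
eligible_parents <- function(sim) {
  ok <- names(sim$n_ind)[sim$n_ind >= 2L]
  if (length(ok) < 2L) stop("no eligible parent species (need >= 2 inds)")
  pairs <- expand.grid(maternal = ok, paternal = ok,
                       stringsAsFactors = FALSE)
  pairs[sim$sp_clade[pairs$maternal] != sim$sp_clade[pairs$paternal], ]
}

#' Plant a hybrid individual into a simulated library
#'
#' Appends one individual whose cpDNA loci descend from the maternal
#' species' lineage and whose nuclear locus descends from the paternal
#' species' lineage. The new individual carries the maternal species'
#' nominal label (as a field-collected hybrid would).
#'
#' @param sim a `cg_sim` from [simulate_library()].
#' @param maternal,paternal species names in different clades.
#' @param seed optional integer to reseed before drawing the hybrid's
#'   terminal-branch mutations (default: continue the current stream).
#' @param reseed internal; set `FALSE` to keep the active RNG stream.
#' @return the modified `cg_sim` (call [finalize_sim()] output accessors
#'   via `sim$library` after [simulate_library()]; `plant_hybrid` returns
#'   a sim whose `library`/`truth` are refreshed).
#' @export
plant_hybrid <- function(sim, maternal, paternal, seed = NULL,
                         reseed = !is.null(seed)) {
  stopifnot(inherits(sim, "cg_sim"))
  for (s in c(maternal, paternal))
    if (!s %in% sim$species) stop("unknown species '", s, "'")
  if (maternal == paternal) stop("self-cross: maternal == paternal")
  if (reseed) set.seed(as.integer(seed))
  k <- sum(sim$truth$role == "hybrid") + 1L
  id <- sprintf("%s_hyb%d", maternal, k)
  cfg <- sim$cfg
  for (loc in sim$loci) {
    parent <- if (cfg$partitions[[loc]] == "cpDNA") maternal else paternal
    sim$tip_seqs[[loc]][[id]] <-
      evolve_branch(sim$sp_nodes[[loc]][[parent]], cfg$d_intra, cfg)
  }
  sim$truth <- rbind(sim$truth, data.frame(
    individual = id, nominal_species = maternal,
    nominal_clade = unname(sim$sp_clade[maternal]), role = "hybrid",
    true_species = NA_character_, maternal = maternal, paternal = paternal,
    stringsAsFactors = FALSE))
  finalize_sim(sim)
}

# relabel individuals to species in a different clade; sources are drawn
# from species with >= 3 individuals so the remaining true-labeled
# individuals still dominate their cluster
plant_mislabels <- function(sim, n) {
  for (k in seq_len(n)) {
    sizes <- table(sim$truth$nominal_species[sim$truth$role == "normal"])
    src_sp <- names(sizes)[sizes >= 3L]
    src_sp <- src_sp[src_sp %in% sim$species]
    if (length(src_sp) == 0L) {
      warning("no species with >= 3 individuals; mislabel not planted")
      break
    }
    s <- src_sp[sample.int(length(src_sp), 1L)]
    cand <- sim$truth$individual[sim$truth$role == "normal" &
                                 sim$truth$nominal_species == s]
    victim <- cand[sample.int(length(cand), 1L)]
    fake_pool <- sim$species[sim$sp_clade != sim$sp_clade[s]]
    fake <- fake_pool[sample.int(length(fake_pool), 1L)]
    new_id <- sprintf("%s_x%d", fake, k)
    i <- match(victim, sim$truth$individual)
    sim$truth$individual[i] <- new_id
    sim$truth$nominal_species[i] <- fake
    sim$truth$nominal_clade[i] <- unname(sim$sp_clade[fake])
    sim$truth$role[i] <- "mislabeled"
    for (loc in sim$loci) {
      names(sim$tip_seqs[[loc]])[names(sim$tip_seqs[[loc]]) == victim] <-
        new_id
    }
  }
  sim
}

# build the user-facing library/truth views from the internal state
finalize_sim <- function(sim) {
  cfg <- sim$cfg
  chars <- c("A", "C", "G", "T", "-")
  alns <- lapply(sim$loci, function(loc) {
    seqs <- vapply(sim$tip_seqs[[loc]], function(z)
      paste(chars[z], collapse = ""), character(1L))
    alignment(seqs, locus = loc)
  })
  names(alns) <- sim$loci
  map <- species_map(
    individual = c(sim$truth$individual, "outgroup_i1"),
    species = c(sim$truth$nominal_species, "outgroup_sp"),
    clade = c(sim$truth$nominal_clade, "outgroup"),
    is_outgroup = c(rep(FALSE, nrow(sim$truth)), TRUE))
  sim$library <- reference_library(alns, map, cfg$partitions)
  sim
}

#' @export
print.cg_sim <- function(x, ...) {
  cat("Simulated library (seed ", x$cfg$seed, "): ", sep = "")
  print(x$library)
  tab <- table(x$truth$role)
  cat("  roles: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a simulated library to disk
#'
#' Emits one aligned FASTA per locus, `species_map.tsv` and `truth.tsv`.
#'
#' @param sim a `cg_sim`.
#' @param dir output directory (created if needed).
#' @export
write_library <- function(sim, dir) {
  stopifnot(inherits(sim, "cg_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (loc in sim$loci)
    write_alignment(sim$library$alignments[[loc]],
                    file.path(dir, paste0(loc, ".fa")))
  write_species_map(sim$library$map, file.path(dir, "species_map.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score an incongruence report against simulator truth
#'
#' @param report a `cg_incongruence` data.frame.
#' @param truth the `truth` element of a `cg_sim`.
#' @return list with the verdict-by-role `confusion` table and per-role
#'   `sensitivity` (correct verdict rate for hybrids and mislabels),
#'   `specificity` (concordant rate among normals) and
#'   `false_flag_rate` (normals flagged hybrid or misidentified).
#' @export
truth_eval <- function(report, truth) {
  if (!all(report$individual %in% truth$individual))
    stop("report contains individuals absent from truth")
  tr <- truth[match(report$individual, truth$individual), ]
  conf <- table(role = tr$role, verdict = report$verdict)
  rate <- function(role, verdict) {
    n <- sum(tr$role == role)
    if (n == 0L) return(NA_real_)
    sum(tr$role == role & report$verdict == verdict) / n
  }
  list(confusion = conf,
       sensitivity = c(hybrid = rate("hybrid", "putative_hybrid"),
                       mislabeled = rate("mislabeled",
                                         "suspected_misidentification")),
       specificity = rate("normal", "concordant"),
       false_flag_rate = if (sum(tr$role == "normal") == 0L) NA_real_ else
         sum(tr$role == "normal" &
             report$verdict %in% c("putative_hybrid",
                                   "suspected_misidentification")) /
         sum(tr$role == "normal"))
}
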