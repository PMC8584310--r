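#' Single-linkage aggregate detection
#'
#' Two ligand molecules (or a molecule and the nanotube) belong to the same
#' aggregate iff any pair of their atoms lies closer than `cutoff`; distances
#' use the minimum-image convention when the configuration is periodic.
#' Connected components of this contact graph are the aggregates
#' (single-linkage clustering). Labels are deterministic: clusters are
#' numbered by their lowest molecule index.
#'
#' @param config A [configuration()].
#' @param cutoff Contact distance cutoff in nm (default 0.35, a standard
#'   heavy-atom contact criterion). Must be below half the smallest box edge
#'   for minimum-image validity.
#' @param include_cnt Link molecules to the nanotube as well, so that the
#'   carrier-bound cluster can be identified.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (integer per molecule), `cnt_cluster` (label of the nanotube-containing
#'   cluster, or `NA` if none/absent), `n_clusters`, `sizes` (molecule count
#'   per cluster label).
#' @export
cluster_molecules <- function(config, cutoff = 0.35, include_cnt = TRUE) {
  stopifnot(inherits(config, "configuration"), cutoff > 0)
  if (config$periodic && cutoff > min(config$box) / 2) {
    stop("cutoff exceeds half the smallest box edge: minimum image invalid",
         call. = FALSE)
  }
  nmol <- n_molecules(config)
  if (nmol == 0L) {
    return(structure(list(labels = integer(0), cnt_cluster = NA_integer_,
                          n_clusters = 0L, sizes = integer(0)),
                     class = "cluster_assignment"))
  }
  atoms <- do.call(rbind, config$molecules)
  mol_of <- rep.int(seq_len(nmol), vapply(config$molecules, nrow, integer(1)))

  # molecule-molecule contact edges from the full atom-atom distance matrix
  d <- pair_dists(atoms, atoms, config$box, config$periodic)
  hit <- which(d < cutoff, arr.ind = TRUE)
  mi <- mol_of[hit[, 1]]
  mj <- mol_of[hit[, 2]]
  keep <- mi < mj
  edges <- unique(cbind(mi[keep], mj[keep]))

  # molecule-nanotube contacts (chunked per molecule: the tube can be large)
  cnt_contact <- rep(FALSE, nmol)
  has_cnt <- include_cnt && nrow(config$cnt) > 0L
  if (has_cnt) {
    for (j in seq_len(nmol)) {
      dj <- pair_dists(config$molecules[[j]], config$cnt, config$box,
                       config$periodic)
      cnt_contact[j] <- any(dj < cutoff)
    }
  }

  # components of the contact graph; the nanotube is vertex nmol + 1
  nv <- nmol + as.integer(has_cnt)
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  if (has_cnt && any(cnt_contact)) {
    g <- igraph::add_edges(g, rbind(which(cnt_contact), nmol + 1L))
  }
  comp <- igraph::components(g)$membership
  mol_comp <- comp[seq_len(nmol)]

  # relabel deterministically by lowest member molecule index
  first_seen <- unique(mol_comp)
  labels <- match(mol_comp, first_seen)
  cnt_cluster <- NA_integer_
  if (has_cnt) {
    cnt_comp <- comp[nmol + 1L]
    if (cnt_comp %in% first_seen) cnt_cluster <- match(cnt_comp, first_seen)
  }
  sizes <- tabulate(labels, nbins = length(first_seen))
  structure(
    list(labels = labels, cnt_cluster = cnt_cluster,
         n_clusters = length(first_seen), sizes = sizes),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d molecules in %d clusters%s\n",
              length(x$labels), x$n_clusters,
              if (is.na(x$cnt_cluster)) ""
              else sprintf(" (nanotube in cluster %d, %d molecules)",
                           x$cnt_cluster, x$sizes[x$cnt_cluster])))
  invisible(x)
}

#' Aggregate count and mean size
#'
#' @param assignment A [cluster_molecules()] result.
#' @param count_cnt_cluster Include the nanotube-containing cluster in the
#'   count and in the mean size? Its size counts ligand molecules only.
#' @return Named list `n_aggregates`, `mean_size` (`NaN` when there are no
#'   aggregates to average over).
#' @export
aggregate_stats <- function(assignment, count_cnt_cluster = TRUE) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  sizes <- assignment$sizes
  if (!count_cnt_cluster && !is.na(assignment$cnt_cluster)) {
    sizes <- sizes[-assignment$cnt_cluster]
  }
  list(n_aggregates = length(sizes), mean_size = mean(sizes))
}

#' @rdname percent_adsorbed
#' @param assignment A [cluster_molecules()] result computed on `x` (computed
#'   on the fly when omitted).
#' @param cutoff Contact cutoff (nm) used when `assignment` is omitted.
#' @param direct_only Count only molecules in direct atomic contact with the
#'   nanotube, rather than the whole nanotube-containing cluster.
#' @export
percent_adsorbed.configuration <- function(x, assignment = NULL,
                                           cutoff = 0.35,
                                           direct_only = FALSE, ...) {
  nmol <- n_molecules(x)
  if (nmol == 0L) return(0)
  if (direct_only) {
    if (nrow(x$cnt) == 0L) return(0)
    n_contact <- sum(vapply(x$molecules, function(m)
      any(pair_dists(m, x$cnt, x$box, x$periodic) < cutoff), logical(1)))
    return(100 * n_contact / nmol)
  }
  if (is.null(assignment)) assignment <- cluster_molecules(x, cutoff = cutoff)
  if (is.na(assignment$cnt_cluster)) return(0)
  100 * assignment$sizes[assignment$cnt_cluster] / nmol
}

#' Percent of ligands inside the nanotube (ring / virtual-sphere method)
#'
#' Reproduces the per-ring counting algorithm: the nanotube is partitioned
#' into single carbon rings along its axis; for each ring the centre of mass
#' is computed and a virtual sphere of radius `sphere_radius` is drawn around
#' it; every ligand molecule whose centre of mass falls inside at least one
#' sphere is counted (duplicates across rings removed). With rings densely
#' spaced along the axis the union of spheres is effectively a narrow
#' cylinder (with spherical caps) coaxial with the tube. Because the ring
#' centres follow the actual atom positions, a bent or flexing tube shifts
#' the spheres with it — the source of the small fluctuations this counter
#' shows on flexible tubes.
#'
#' @param config A [configuration()].
#' @param tube A [nanotube_model()] whose `ring_partition` indexes rows of
#'   `config$cnt`.
#' @param sphere_radius Sphere radius in nm. Default: half the (innermost)
#'   tube diameter, so that "inside" means within the tube lumen. (Setting it
#'   to the full diameter would also count molecules adsorbed on the outer
#'   wall.)
#' @return Percentage of ligand molecules inside, with attribute `"inside"`
#'   giving their molecule indices.
#' @export
percent_inside_ring_method <- function(config, tube,
                                       sphere_radius = min(tube$diameter) / 2) {
  stopifnot(inherits(config, "configuration"), inherits(tube, "nanotube_model"),
            sphere_radius > 0)
  if (length(tube$ring_partition) == 0L) {
    stop("tube has an empty ring partition", call. = FALSE)
  }
  nmol <- n_molecules(config)
  if (nmol == 0L) {
    return(structure(0, inside = integer(0)))
  }
  nonempty <- lengths(tube$ring_partition) > 0L
  if (!all(nonempty)) {
    warning("skipping degenerate ring(s) with 0 atoms")
  }
  centres <- t(vapply(tube$ring_partition[nonempty], function(idx)
    centre_of_mass(config$cnt[idx, , drop = FALSE]), numeric(3)))
  coms <- molecule_coms(config)
  d <- pair_dists(coms, centres, config$box, config$periodic)
  inside <- which(apply(d < sphere_radius, 1, any))
  structure(100 * length(inside) / nmol, inside = inside)
}

#' Adsorption summary of a configuration
#'
#' Composes the four headline statistics of a snapshot: number of aggregates,
#' mean aggregate size, percentage of ligand molecules adsorbed by the
#' nanotube (cluster membership) and percentage adsorbed inside it (ring
#' method). Both percentages are relative to the total number of ligand
#' molecules.
#'
#' @param config A [configuration()].
#' @param cutoff Contact cutoff (nm) for clustering.
#' @param tube A [nanotube_model()] (required for `pct_inside`; when `NULL`
#'   and the configuration has no carrier atoms, `pct_inside` is 0).
#' @param sphere_radius Ring-method sphere radius; default half the innermost
#'   tube diameter.
#' @param count_cnt_cluster Passed to [aggregate_stats()].
#' @return An object of class `adsorption_summary`: list with
#'   `n_aggregates`, `mean_aggregate_size`, `pct_adsorbed`, `pct_inside`.
#' @export
summarize_adsorption <- function(config, cutoff = 0.35, tube = NULL,
                                 sphere_radius = NULL,
                                 count_cnt_cluster = TRUE) {
  stopifnot(inherits(config, "configuration"))
  if (n_molecules(config) == 0L) {
    return(structure(list(n_aggregates = 0L, mean_aggregate_size = 0,
                          pct_adsorbed = 0, pct_inside = 0),
                     class = "adsorption_summary"))
  }
  assignment <- cluster_molecules(config, cutoff = cutoff)
  stats <- aggregate_stats(assignment, count_cnt_cluster = count_cnt_cluster)
  pct_ads <- percent_adsorbed(config, assignment)
  pct_in <- 0
  if (!is.null(tube)) {
    if (is.null(sphere_radius)) sphere_radius <- min(tube$diameter) / 2
    pct_in <- as.numeric(percent_inside_ring_method(config, tube,
                                                    sphere_radius))
  }
  structure(
    list(n_aggregates = stats$n_aggregates,
         mean_aggregate_size = stats$mean_size,
         pct_adsorbed = as.numeric(pct_ads), pct_inside = pct_in),
    class = "adsorption_summary"
  )
}

#' @export
print.adsorption_summary <- function(x, ...) {
  cat(sprintf(paste0("Adsorption summary: %d aggregates (mean size %.3g), ",
                     "%.4g%% adsorbed, %.4g%% inside\n"),
              x$n_aggregates, x$mean_aggregate_size, x$pct_adsorbed,
              x$pct_inside))
  invisible(x)
}
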