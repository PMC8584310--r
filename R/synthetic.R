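#' Nanotube model
#'
#' Geometric description of a (multi-walled) nanotube used by the ring-method
#' counter: axis anchor and direction, per-wall diameters, length, and the
#' partition of carrier atoms into axial carbon rings.
#'
#' @param axis_point Point on the tube axis (nm) where the tube starts.
#' @param axis_dir Unit vector along the axis.
#' @param diameter Numeric vector of achieved wall diameters (nm), innermost
#'   first.
#' @param length Tube length (nm).
#' @param walls Number of walls.
#' @param ring_partition List of integer vectors indexing carrier atoms, one
#'   per axial ring, ordered along the axis.
#' @return An object of class `nanotube_model`.
#' @export
nanotube_model <- function(axis_point, axis_dir, diameter, length, walls,
                           ring_partition) {
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  stopifnot(all(diameter > 0), length > 0, walls >= 1,
            is.list(ring_partition))
  structure(
    list(axis_point = axis_point, axis_dir = axis_dir, diameter = diameter,
         length = length, walls = walls, ring_partition = ring_partition),
    class = "nanotube_model"
  )
}

#' @export
print.nanotube_model <- function(x, ...) {
  cat(sprintf("Nanotube: %d wall(s), diameter(s) %s nm, length %g nm, %d rings\n",
              x$walls, paste(sprintf("%.3f", x$diameter), collapse = "/"),
              x$length, length(x$ring_partition)))
  invisible(x)
}

# C-C bond length (nm) and derived zigzag lattice constants
CC_BOND <- 0.142
ZIGZAG_A <- CC_BOND * sqrt(3)      # 0.246 nm graphene lattice constant
RING_SPACING <- 1.5 * CC_BOND     # 0.213 nm axial ring-pair spacing

#' Generate a zigzag carbon nanotube
#'
#' Builds an ideal zigzag-lattice cylinder (or concentric cylinders for a
#' multi-walled tube) with C-C bond length 0.142 nm. The achieved diameter of
#' each wall is the nearest realizable zigzag diameter d = 0.246 m / pi for
#' integer circumferential index m, always within half an index step
#' (~0.04 nm) of the request. An optional sinusoidal bend displaces the tube
#' perpendicular to its axis, emulating the longitudinal flexibility of real
#' nanotubes.
#'
#' @param diameter Requested wall diameter(s) in nm. Default: 6.42 nm for a
#'   single wall; 6.42/7.12/7.83 nm for a three-wall tube.
#' @param length Tube length (nm).
#' @param walls Number of walls (must match `length(diameter)` if both given).
#' @param origin Axis anchor: centre of the first ring.
#' @param axis Axis direction (any non-zero vector; normalised internally).
#' @param bend_amplitude Amplitude (nm) of a sinusoidal transverse bend
#'   (0 = ideal straight tube).
#' @param bend_period Axial period (nm) of the bend.
#' @param ring_bin Axial bin width (nm) used to group atoms into rings for
#'   the ring partition; default one zigzag ring-pair spacing (0.213 nm).
#' @return List with `model` (a [nanotube_model()]) and `atoms` (coordinate
#'   matrix, nm).
#' @export
generate_nanotube <- function(diameter = NULL, length = 20, walls = 1,
                              origin = c(0, 0, 0), axis = c(0, 0, 1),
                              bend_amplitude = 0, bend_period = length,
                              ring_bin = RING_SPACING) {
  if (is.null(diameter)) {
    defaults <- c(6.42, 7.12, 7.83)
    if (walls > 3) stop("supply explicit diameters for more than 3 walls",
                        call. = FALSE)
    diameter <- defaults[seq_len(walls)]
  }
  if (base::length(diameter) == 1L && walls > 1L) {
    diameter <- diameter + (seq_len(walls) - 1L) * 0.70
  }
  stopifnot(base::length(diameter) == walls, all(diameter > 0), length > 0)

  axis <- axis / sqrt(sum(axis^2))
  u <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])

  # zigzag unit cell: 4 rings per 0.426 nm period, alternating angular offset
  z_off <- c(0, 0.5, 1.5, 2) * CC_BOND
  a_off <- c(0, 0.5, 0.5, 0)                 # in units of 2*pi/m
  all_xyz <- list()
  achieved <- numeric(walls)
  for (w in seq_len(walls)) {
    m <- round(pi * diameter[w] / ZIGZAG_A)
    if (m < 8) stop("diameter too small for a zigzag lattice", call. = FALSE)
    achieved[w] <- ZIGZAG_A * m / pi
    r <- achieved[w] / 2
    n_cells <- floor(length / (3 * CC_BOND))
    zs <- as.vector(outer(z_off, (seq_len(n_cells) - 1L) * 3 * CC_BOND, "+"))
    offs <- rep(a_off, n_cells)
    zs_keep <- zs <= length
    zs <- zs[zs_keep]; offs <- offs[zs_keep]
    ang0 <- 2 * pi * (seq_len(m) - 1L) / m
    zz <- rep(zs, each = m)
    th <- rep(offs * 2 * pi / m, each = m) + rep(ang0, times = base::length(zs))
    bend <- bend_amplitude * sin(2 * pi * zz / bend_period)
    local <- cbind((r * cos(th) + bend), r * sin(th), zz)
    all_xyz[[w]] <- local
  }
  local <- do.call(rbind, all_xyz)
  atoms <- sweep(local[, 1, drop = FALSE] %*% rbind(u) +
                 local[, 2, drop = FALSE] %*% rbind(v) +
                 local[, 3, drop = FALSE] %*% rbind(axis), 2, origin, "+")

  ax_coord <- local[, 3]
  bins <- floor(ax_coord / ring_bin + 1e-9)
  ring_ids <- sort(unique(bins))
  ring_partition <- lapply(ring_ids, function(b) which(bins == b))
  model <- nanotube_model(origin, axis, achieved, length, walls,
                          ring_partition)
  list(model = model, atoms = atoms)
}

#' Generate a noisy release curve with known truth
#'
#' Evaluates a kinetic model at the sampling grid and adds seeded Gaussian
#' noise (clipped at zero). The default grid is the six-point protocol
#' 1, 3, 5, 10, 20, 30 minutes. With `value_kind = "auto"`, fraction-scale
#' models whose noiseless values stay within [0, 1.05] yield a
#' fraction-scale curve; otherwise the curve is amount-scale with C_inf = 1
#' recorded so that fraction-based models can still be fitted.
#'
#' @param model Kinetic model name.
#' @param params Named true parameter values.
#' @param times Sampling times (minutes).
#' @param noise_sd Gaussian noise standard deviation on the value scale.
#' @param heteroscedastic If `TRUE`, the noise sd is `noise_sd` times the
#'   noiseless value (proportional noise) instead of constant.
#' @param seed Optional integer seed for reproducibility.
#' @param value_kind `"auto"`, `"fraction"` or `"amount"`.
#' @return List with `curve` (a [release_curve()]), `model`, `params`.
#' @export
generate_release_curve <- function(model, params,
                                   times = c(1, 3, 5, 10, 20, 30),
                                   noise_sd = 0, heteroscedastic = FALSE,
                                   seed = NULL,
                                   value_kind = c("auto", "fraction", "amount")) {
  value_kind <- match.arg(value_kind)
  stopifnot(noise_sd >= 0)
  clean <- predict_release(model, params, times)
  if (!is.null(seed)) set.seed(seed)
  sd_vec <- if (heteroscedastic) noise_sd * clean else rep(noise_sd, length(times))
  values <- pmax(clean + stats::rnorm(length(times), 0, sd_vec), 0)
  spec <- kinetic_model_spec(model)
  if (value_kind == "auto") {
    value_kind <- if (max(values) <= 1.05) "fraction" else "amount"
  }
  c_inf <- if (value_kind == "amount" && spec$needs_fraction) 1 else NULL
  list(curve = release_curve(times, values, value_kind = value_kind,
                             c_inf = c_inf),
       model = model, params = params)
}

# distance from points (rows of p) to the tube axis segment, minimum-image
capsule_distance <- function(p, axis_point, axis_dir, length, box, periodic) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  centre <- axis_point + axis_dir * (length / 2)
  d <- sweep(p, 2, centre, "-")
  if (periodic) d <- min_image(d, box)
  q <- sweep(d, 2, centre, "+")          # min-image representative of p
  rel <- sweep(q, 2, axis_point, "-")
  s <- pmin(pmax(as.vector(rel %*% axis_dir), 0), length)
  foot <- matrix(axis_point, nrow(q), 3, byrow = TRUE) + outer(s, axis_dir)
  sqrt(rowSums((q - foot)^2))
}

#' Generate a boxed configuration with exact ground truth
#'
#' Places a nanotube and four controlled ligand populations in an
#' orthorhombic periodic box: molecules encapsulated inside the tube (in
#' contact with the inner wall), molecules adsorbed on the outer wall,
#' free-standing multi-molecule aggregates, and isolated free molecules.
#' Placement margins guarantee that the intended partition is the unique
#' single-linkage clustering at the generation cutoff: adsorbed molecules sit
#' at 0.9 x cutoff from a wall atom, while everything else is separated from
#' every other entity by more than 2 x cutoff, and non-encapsulated molecules
#' keep their centres of mass well clear of the ring-method capsule.
#'
#' Ligand molecules are rigid bead chains (default 3 beads, 0.2 nm spacing,
#' unit masses): the statistics operate on coordinates only, so no chemical
#' detail is needed and the ground truth is exact.
#'
#' @param box Box edge lengths (nm); default the 20 x 80 x 20 nm study box.
#' @param tube_diameter,tube_length,tube_walls Tube geometry passed to
#'   [generate_nanotube()]; defaults: three walls at 6.42/7.12/7.83 nm,
#'   20 nm long, axis along y, centred in the box.
#' @param include_tube Set `FALSE` for a tube-free box (then `n_surface` and
#'   `n_inside` must be 0).
#' @param n_free Number of isolated molecules.
#' @param aggregate_sizes Integer vector: one entry per free-standing
#'   aggregate, giving its molecule count (each >= 2).
#' @param n_surface Number of molecules adsorbed on the outer wall.
#' @param n_inside Number of molecules encapsulated in the tube lumen.
#' @param beads_per_molecule,bead_spacing Ligand bead-chain geometry.
#' @param cutoff Generation contact cutoff (nm); analysis at the same cutoff
#'   reproduces the truth exactly.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling attempts per molecule before a packing
#'   error.
#' @return List with `config` (a [configuration()]), `tube` (a
#'   [nanotube_model()] or `NULL`) and `truth`: per-molecule labels
#'   (`"inside"`, `"surface"`, `"aggregate_<k>"`, `"free"`), the intended
#'   partition, and intended `n_aggregates`, `mean_size`, `pct_adsorbed`,
#'   `pct_inside`.
#' @export
generate_configuration <- function(box = c(20, 80, 20), tube_diameter = NULL,
                                   tube_length = 20, tube_walls = 3,
                                   include_tube = TRUE, n_free = 0,
                                   aggregate_sizes = integer(),
                                   n_surface = 0, n_inside = 0,
                                   beads_per_molecule = 3, bead_spacing = 0.2,
                                   cutoff = 0.35, seed = NULL,
                                   max_tries = 500) {
  stopifnot(n_free >= 0, n_surface >= 0, n_inside >= 0,
            all(aggregate_sizes >= 2), beads_per_molecule >= 1, cutoff > 0)
  if (!include_tube && (n_surface > 0 || n_inside > 0)) {
    stop("surface/inside molecules require a tube", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  tube <- NULL; cnt <- matrix(numeric(), 0, 3)
  axis_point <- NULL; axis_dir <- c(0, 1, 0)
  if (include_tube) {
    axis_point <- c(box[1] / 2, (box[2] - tube_length) / 2, box[3] / 2)
    tb <- generate_nanotube(diameter = tube_diameter, length = tube_length,
                            walls = tube_walls, origin = axis_point,
                            axis = axis_dir)
    tube <- tb$model; cnt <- tb$atoms
  }
  sphere_radius <- if (include_tube) min(tube$diameter) / 2 else Inf
  sep <- 2.2 * cutoff          # margin above the 2 x cutoff requirement
  contact_gap <- 0.9 * cutoff

  chain <- function(start, dir, n = beads_per_molecule) {
    sweep(outer((seq_len(n) - 1) * bead_spacing, dir), 2, start, "+")
  }
  rand_dir <- function() {
    v <- stats::rnorm(3); v / sqrt(sum(v^2))
  }
  wall_atoms_in <- function(wall_r, ymin, ymax) {
    # atoms of the wall at radius wall_r with axial coordinate in range
    rad <- sqrt((cnt[, 1] - axis_point[1])^2 + (cnt[, 3] - axis_point[3])^2)
    ax <- cnt[, 2] - axis_point[2]
    which(abs(rad - wall_r) < 0.05 & ax > ymin & ax < ymax)
  }

  molecules <- list(); labels <- character(0)
  placed <- matrix(numeric(), 0, 3)
  too_close <- function(atoms, ref, lim) {
    nrow(ref) > 0L && min(pair_dists(atoms, ref, box, TRUE)) < lim
  }
  place <- function(make, check, what) {
    for (i in seq_len(max_tries)) {
      cand <- make()
      if (check(cand)) return(cand)
    }
    stop(sprintf("packing failed: could not place %s molecule after %d tries",
                 what, max_tries), call. = FALSE)
  }

  # encapsulated molecules: anchored to a random inner-wall atom, chain axial
  if (n_inside > 0) {
    r_in <- min(tube$diameter) / 2
    extent <- (beads_per_molecule - 1) * bead_spacing
    cands <- wall_atoms_in(r_in, 1, tube_length - 1 - extent)
    for (i in seq_len(n_inside)) {
      mol <- place(function() {
        at <- cnt[sample(cands, 1), ]
        radial <- c(at[1] - axis_point[1], 0, at[3] - axis_point[3])
        inward <- -radial / sqrt(sum(radial^2))
        chain(at + contact_gap * inward, axis_dir)
      }, function(m) !too_close(m, placed, sep), "inside")
      molecules <- c(molecules, list(mol)); labels <- c(labels, "inside")
      placed <- rbind(placed, mol)
    }
  }

  # surface-adsorbed molecules: anchored to a random outer-wall atom
  if (n_surface > 0) {
    r_out <- max(tube$diameter) / 2
    extent <- (beads_per_molecule - 1) * bead_spacing
    cands <- wall_atoms_in(r_out, 0.5, tube_length - 0.5 - extent)
    for (i in seq_len(n_surface)) {
      mol <- place(function() {
        at <- cnt[sample(cands, 1), ]
        radial <- c(at[1] - axis_point[1], 0, at[3] - axis_point[3])
        outward <- radial / sqrt(sum(radial^2))
        chain(at + contact_gap * outward, axis_dir)
      }, function(m) !too_close(m, placed, sep), "surface")
      molecules <- c(molecules, list(mol)); labels <- c(labels, "surface")
      placed <- rbind(placed, mol)
    }
  }

  # a candidate free-standing entity must stay out of the capsule region,
  # away from the tube wall, and away from everything already placed
  free_ok <- function(atoms) {
    if (too_close(atoms, placed, sep)) return(FALSE)
    if (include_tube) {
      if (too_close(atoms, cnt, 2 * cutoff)) return(FALSE)
      k <- beads_per_molecule
      coms <- t(vapply(seq_len(nrow(atoms) / k), function(j)
        colMeans(atoms[((j - 1) * k + 1):(j * k), , drop = FALSE]),
        numeric(3)))
      if (any(capsule_distance(coms, axis_point, axis_dir, tube_length, box,
                               TRUE) < sphere_radius + 0.5)) return(FALSE)
    }
    TRUE
  }
  rand_start <- function() stats::runif(3) * box

  # free-standing aggregates: chains of mutually linked molecules
  for (k in seq_along(aggregate_sizes)) {
    sz <- aggregate_sizes[k]
    mol_span <- (beads_per_molecule - 1) * bead_spacing + 0.8 * cutoff
    blob <- place(function() {
      dir <- rand_dir(); start <- rand_start()
      do.call(rbind, lapply(seq_len(sz) - 1L, function(j)
        chain(start + j * mol_span * dir, dir)))
    }, free_ok, sprintf("aggregate %d", k))
    for (j in seq_len(sz)) {
      rows <- ((j - 1) * beads_per_molecule + 1):(j * beads_per_molecule)
      molecules <- c(molecules, list(blob[rows, , drop = FALSE]))
      labels <- c(labels, sprintf("aggregate_%d", k))
    }
    placed <- rbind(placed, blob)
  }

  # isolated free molecules
  for (i in seq_len(n_free)) {
    mol <- place(function() chain(rand_start(), rand_dir()), free_ok, "free")
    molecules <- c(molecules, list(mol)); labels <- c(labels, "free")
    placed <- rbind(placed, mol)
  }

  # wrap into the primary box image
  molecules <- lapply(molecules, function(m) {
    for (kk in 1:3) m[, kk] <- m[, kk] %% box[kk]
    m
  })

  nmol <- length(molecules)
  n_ads <- n_surface + n_inside
  partition <- list()
  if (n_ads > 0) partition <- list(which(labels %in% c("inside", "surface")))
  for (k in seq_along(aggregate_sizes)) {
    partition <- c(partition, list(which(labels == sprintf("aggregate_%d", k))))
  }
  partition <- c(partition, as.list(which(labels == "free")))
  n_clusters <- length(partition)
  truth <- list(
    labels = labels, partition = partition,
    n_aggregates = n_clusters,
    mean_size = if (n_clusters > 0) nmol / n_clusters else 0,
    pct_adsorbed = if (nmol > 0) 100 * n_ads / nmol else 0,
    pct_inside = if (nmol > 0) 100 * n_inside / nmol else 0
  )
  list(config = configuration(box, cnt, molecules, periodic = TRUE),
       tube = tube, truth = truth)
}
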