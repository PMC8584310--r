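one_bead <- function(...) matrix(c(...), 1, 3)

test_that("contact clustering links by distance with single-linkage transitivity", {
  box <- c(10, 10, 10)
  # two 1-atom molecules 5 nm apart: separate clusters at cutoff 0.35
  cfg <- configuration(box, molecules = list(one_bead(1, 1, 1),
                                             one_bead(6, 1, 1)))
  a <- cluster_molecules(cfg, cutoff = 0.35)
  expect_equal(a$n_clusters, 2L)
  # chain A-B-C with 0.3 nm gaps: one cluster of 3 by transitivity
  cfg2 <- configuration(box, molecules = list(one_bead(1, 1, 1),
                                              one_bead(1.3, 1, 1),
                                              one_bead(1.6, 1, 1)))
  a2 <- cluster_molecules(cfg2, cutoff = 0.35)
  expect_equal(a2$n_clusters, 1L)
  expect_equal(a2$sizes, 3L)
})

test_that("clustering respects the minimum-image convention across the box edge", {
  box <- c(5, 5, 5)
  cfg <- configuration(box, molecules = list(one_bead(0.1, 1, 1),
                                             one_bead(4.9, 1, 1)))
  expect_equal(cluster_molecules(cfg, cutoff = 0.35)$n_clusters, 1L)
  cfg_np <- configuration(box, molecules = cfg$molecules, periodic = FALSE)
  expect_equal(cluster_molecules(cfg_np, cutoff = 0.35)$n_clusters, 2L)
})

test_that("clustering equals the brute-force union-find oracle on random configs", {
  for (s in 1:25) {
    cfg <- random_loose_config(seed = s)
    got <- cluster_molecules(cfg, cutoff = 0.6, include_cnt = FALSE)
    want <- uf_cluster_oracle(cfg, 0.6)
    expect_identical(as.integer(got$labels), as.integer(want),
                     label = sprintf("partition, seed %d", s))
  }
})

test_that("aggregate statistics count clusters and conserve molecules", {
  box <- c(20, 20, 20)
  mols <- c(lapply(1:10, function(i) one_bead(2 * i, 1, 1)))
  cfg <- configuration(box, molecules = mols)
  a <- cluster_molecules(cfg)
  st <- aggregate_stats(a)
  expect_equal(st$n_aggregates, 10L)
  expect_equal(st$mean_size, 1)
  # one cluster of 4 + 2 singletons -> (3, 2.0)
  mols2 <- list(one_bead(1, 1, 1), one_bead(1.3, 1, 1), one_bead(1.6, 1, 1),
                one_bead(1.9, 1, 1), one_bead(8, 8, 8), one_bead(14, 14, 14))
  a2 <- cluster_molecules(configuration(box, molecules = mols2))
  expect_equal(aggregate_stats(a2)$n_aggregates, 3L)
  expect_equal(aggregate_stats(a2)$mean_size, 2)
  expect_equal(sum(a2$sizes), 6L)
})

test_that("cluster sizes sum to the molecule count on random configurations", {
  for (s in 26:35) {
    cfg <- random_loose_config(seed = s)
    a <- cluster_molecules(cfg, cutoff = 0.5, include_cnt = FALSE)
    expect_equal(sum(a$sizes), length(cfg$molecules))
  }
})

test_that("percent adsorbed covers the all/none/partial cases", {
  gen_all <- generate_configuration(n_surface = 8, tube_walls = 1,
                                    tube_length = 8, seed = 6)
  expect_equal(percent_adsorbed(gen_all$config), 100)
  gen_none <- generate_configuration(n_free = 8, tube_walls = 1,
                                     tube_length = 8, seed = 7)
  expect_equal(percent_adsorbed(gen_none$config), 0)
  gen_mix <- generate_configuration(n_free = 70, n_surface = 30,
                                    tube_walls = 1, tube_length = 8, seed = 8)
  expect_equal(percent_adsorbed(gen_mix$config), 30)
})

test_that("direct-contact mode counts only molecules touching the tube", {
  # a two-molecule chain hanging off the wall: cluster mode counts both,
  # direct mode only the touching one
  gen <- generate_configuration(n_surface = 1, tube_walls = 1,
                                tube_length = 8, seed = 9)
  cfg <- gen$config
  surf <- cfg$molecules[[1]]
  com <- colMeans(surf)
  axis_centre <- c(cfg$box[1] / 2, 0, cfg$box[3] / 2)
  outward <- c(com[1] - axis_centre[1], 0, com[3] - axis_centre[3])
  outward <- outward / sqrt(sum(outward^2))
  tail_mol <- sweep(surf, 2, 0.3 * outward, "+")  # touches surf, not the wall
  cfg2 <- configuration(cfg$box, cfg$cnt,
                        c(cfg$molecules, list(tail_mol),
                          list(one_bead(cfg$box[1] / 2 + 8, com[2],
                                        cfg$box[3] / 2))))
  expect_equal(percent_adsorbed(cfg2), 100 * 2 / 3)
  expect_equal(percent_adsorbed(cfg2, direct_only = TRUE), 100 * 1 / 3,
               tolerance = 1e-12)
})

test_that("ring-method counts a molecule on the axis, not one outside", {
  tb <- generate_nanotube(walls = 1, length = 10, origin = c(10, 5, 10),
                          axis = c(0, 1, 0))
  r <- tb$model$diameter / 2
  box <- c(20, 20, 20)
  cfg <- configuration(box, tb$atoms,
                       list(one_bead(10, 10, 10),        # on axis, mid-length
                            one_bead(10 + 2 * r, 10, 10)))  # 2x radius out
  p <- percent_inside_ring_method(cfg, tb$model, sphere_radius = r)
  expect_equal(as.numeric(p), 50)
  expect_equal(attr(p, "inside"), 1L)
})

test_that("ring method equals the capsule oracle for ideal straight tubes", {
  for (s in 1:5) {
    set.seed(100 + s)
    box <- c(20, 40, 20)
    tb <- generate_nanotube(walls = 1, length = 15, origin = c(10, 12, 10),
                            axis = c(0, 1, 0))
    mols <- lapply(1:120, function(i) one_bead(runif(1) * box[1],
                                               runif(1) * box[2],
                                               runif(1) * box[3]))
    cfg <- configuration(box, tb$atoms, mols)
    r <- min(tb$model$diameter) / 2
    got <- sort(attr(percent_inside_ring_method(cfg, tb$model, r), "inside"))
    want <- sort(capsule_inside_oracle(cfg, tb$model, r))
    expect_identical(as.integer(got), as.integer(want),
                     label = sprintf("inside set, seed %d", 100 + s))
  }
})

test_that("a bent tube makes the ring method deviate from the straight cylinder", {
  box <- c(20, 40, 20)
  tbb <- generate_nanotube(walls = 1, length = 20, origin = c(10, 10, 10),
                           axis = c(0, 1, 0), bend_amplitude = 1.5,
                           bend_period = 20)
  r <- min(tbb$model$diameter) / 2
  # centre of mass 2.5 nm from the straight axis, opposite the bend direction
  cfg <- configuration(box, tbb$atoms, list(one_bead(10 - 2.5, 15, 10)))
  ring_set <- attr(percent_inside_ring_method(cfg, tbb$model, r), "inside")
  straight_set <- capsule_inside_oracle(cfg, tbb$model, r)
  expect_false(identical(as.integer(sort(ring_set)),
                         as.integer(sort(straight_set))))
  expect_equal(straight_set, 1L)     # straight cylinder says inside
  expect_length(ring_set, 0L)        # displaced rings say outside
})

test_that("statistics are invariant under molecule permutation and box translation", {
  gen <- generate_configuration(n_free = 12, aggregate_sizes = c(3, 2),
                                n_surface = 6, n_inside = 2, tube_walls = 1,
                                tube_length = 8, seed = 10)
  cfg <- gen$config
  base <- summarize_adsorption(cfg, tube = gen$tube)
  # permute molecules
  perm <- sample(length(cfg$molecules))
  cfg_p <- configuration(cfg$box, cfg$cnt, cfg$molecules[perm],
                         cfg$masses[perm])
  expect_equal(summarize_adsorption(cfg_p, tube = gen$tube), base)
  # translate everything by a lattice vector of the box
  shift <- cfg$box * c(1, -2, 3)
  cfg_t <- configuration(cfg$box, sweep(cfg$cnt, 2, shift, "+"),
                         lapply(cfg$molecules, sweep, 2, shift, "+"))
  expect_equal(summarize_adsorption(cfg_t, tube = gen$tube), base)
  # and by a generic (non-lattice) vector, wrapped implicitly by min-image
  shift2 <- c(1.7, -3.1, 0.4)
  cfg_s <- configuration(cfg$box, sweep(cfg$cnt, 2, shift2, "+"),
                         lapply(cfg$molecules, sweep, 2, shift2, "+"))
  expect_equal(summarize_adsorption(cfg_s, tube = gen$tube), base)
})

test_that("percent adsorbed is non-decreasing in the cutoff", {
  gen <- generate_configuration(n_free = 20, n_surface = 10, tube_walls = 1,
                                tube_length = 8, seed = 12)
  cuts <- c(0.2, 0.3, 0.35, 0.5, 0.8, 1.2)
  pct <- vapply(cuts, function(cc) percent_adsorbed(gen$config, cutoff = cc),
                numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("empty and degenerate inputs give well-defined results", {
  cfg <- configuration(c(5, 5, 5))
  a <- cluster_molecules(cfg)
  expect_equal(a$n_clusters, 0L)
  s <- summarize_adsorption(cfg)
  expect_equal(s$pct_adsorbed, 0)
  expect_equal(s$n_aggregates, 0L)
  expect_error(cluster_molecules(configuration(c(0.5, 0.5, 0.5),
                                               molecules = list(one_bead(0, 0, 0))),
                                 cutoff = 0.3), "half")
})
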