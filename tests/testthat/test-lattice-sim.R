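test_that("site allocation uses largest-remainder rounding and conserves totals", {
  expect_equal(allocate_counts(pure_composition("saturates"), 4),
               setNames(c(0L, 0L, 0L, 0L, 0L, 4L, 0L), lipid_classes()))
  counts <- allocate_counts(scenarios$membrane$Control, 40000)
  expect_identical(counts[["cholesterol"]], 10824L)  # 27.06% of 40,000
  expect_identical(sum(counts), 40000L)
  # conservation holds for arbitrary valid compositions and sizes
  set.seed(99)
  for (i in 1:25) {
    comp <- random_composition()
    n <- sample(7:5000, 1)
    expect_identical(sum(allocate_counts(comp, n)), as.integer(n))
  }
})

test_that("allocation rejects invalid compositions with the offending sum", {
  bad <- setNames(c(50, 10, 5, 5, 5, 10, 5), lipid_classes())
  expect_error(membrane_composition(bad), "90")
})

test_that("lattice initialization is seeded and conserves the allocation", {
  comp <- scenarios$membrane$Control
  l1 <- initialize_lattice(comp, c(50, 50), seed = 4)
  l2 <- initialize_lattice(comp, c(50, 50), seed = 4)
  l3 <- initialize_lattice(comp, c(50, 50), seed = 5)
  expect_identical(unclass(l1), unclass(l2))
  expect_false(identical(unclass(l1), unclass(l3)))
  expect_identical(lattice_counts(l1), lattice_counts(l3))
  expect_identical(lattice_counts(l1), allocate_counts(comp, 2500))
  expect_error(initialize_lattice(comp, c(0, 10)), "dims")
})

test_that("neighbor binding sums four periodic neighbors", {
  lat <- structure(matrix(0L, 6, 6), class = c("membrane_lattice", "matrix"))
  e_cc <- ff_default["cholesterol", "cholesterol"]
  expect_equal(neighbor_binding(lat, c(1, 1), ff_default), 4 * e_cc)
  expect_equal(neighbor_binding(lat, c(6, 6), ff_default), 4 * e_cc)
  # corner of a 3x3 periodic grid still has exactly 4 neighbor terms
  lat3 <- structure(matrix(sample(0:6, 9, replace = TRUE), 3, 3),
                    class = c("membrane_lattice", "matrix"))
  e <- unclass(ff_default)
  manual <- e[lat3[1, 1] + 1, lat3[3, 1] + 1] + e[lat3[1, 1] + 1, lat3[2, 1] + 1] +
    e[lat3[1, 1] + 1, lat3[1, 3] + 1] + e[lat3[1, 1] + 1, lat3[1, 2] + 1]
  expect_equal(neighbor_binding(lat3, c(1, 1), ff_default), manual)
})

test_that("compiled binding field matches a naive double loop", {
  set.seed(12)
  lat <- initialize_lattice(scenarios$membrane$`ADV/VI`, c(17, 23), seed = 12)
  bf <- binding_field(lat, ff_default)
  for (r in seq_len(17)) {
    for (c in seq_len(23)) {
      expect_equal(bf[r, c], neighbor_binding(lat, c(r, c), ff_default))
    }
  }
})

test_that("zero force field gives free diffusion: every site moves every sweep", {
  res <- run_simulation(scenarios$membrane$Control, ff_zero,
                        desk_cfg(seed = 3, iterations = 50, dims = c(40, 40)))
  expect_true(all(res$mobility == 1))
})

test_that("class counts are conserved and trajectories are seed-deterministic", {
  cfg <- desk_cfg(seed = 21, iterations = 60, dims = c(40, 40))
  r1 <- run_simulation(scenarios$membrane$`ADI/II`, ff_default, cfg)
  r2 <- run_simulation(scenarios$membrane$`ADI/II`, ff_default, cfg)
  expect_identical(unclass(r1$lattice), unclass(r2$lattice))
  expect_identical(r1$mobility, r2$mobility)
  expect_identical(lattice_counts(r1$lattice), lattice_counts(r1$initial))
  cfg2 <- desk_cfg(seed = 22, iterations = 60, dims = c(40, 40))
  r3 <- run_simulation(scenarios$membrane$`ADI/II`, ff_default, cfg2)
  expect_false(identical(unclass(r1$lattice), unclass(r3$lattice)))
  expect_true(all(r1$mobility >= 0 & r1$mobility <= 1))
})

test_that("metropolis rule at vanishing theta never decreases total binding", {
  cfg <- sim_config(dims = c(20, 20), iterations = 40, rule = "metropolis",
                    swap_scale_theta = 1e-30, seed = 8, record_rmsd = FALSE)
  res <- run_simulation(scenarios$membrane$Control, ff_default, cfg)
  b0 <- sum(binding_field(res$initial, ff_default))
  b1 <- sum(binding_field(res$lattice, ff_default))
  expect_gte(b1, b0)
})

test_that("the RMSD noise series starts at zero and has one entry per sweep", {
  cfg <- sim_config(dims = c(30, 30), iterations = 25, seed = 5)
  res <- run_simulation(scenarios$membrane$Control, ff_default, cfg)
  expect_length(res$rmsd_series, 25)
  expect_identical(res$rmsd_series[1], 0)
  expect_true(all(res$rmsd_series >= 0))
  expect_gt(res$rmsd_series[25], 0)
})

test_that("a single-class membrane develops no raft-sized low-mobility domains", {
  res <- run_simulation(pure_composition("cholesterol"), ff_default,
                        desk_cfg(seed = 31, iterations = 200))
  mask <- raft_mask(res$mobility)
  sizes <- label_domains(mask)$sizes
  expect_lt(if (length(sizes)) max(sizes) else 0, 10)
})

test_that("invalid configuration is rejected", {
  expect_error(sim_config(iterations = 0))
  expect_error(sim_config(swap_scale_theta = -1), "swap_scale_theta")
})
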