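test_that("cylinder interaction energy matches the direct formula", {
  chol <- cylinder_params(radius_R = 5.94, length_L = 19.99)
  s <- interaction_settings(hamaker_A = 1e-19, distance_D = 1.5)
  v <- lvw_energy(chol, chol, s)
  expect_equal(v, lvw_oracle(1e-19, 19.99, 1.5, 5.94, 5.94), tolerance = 1e-12)
  expect_equal(v, 1.1049888260e-19, tolerance = 1e-9)
  expect_gt(v, 0)
})

test_that("energy is symmetric in the pair and follows the scaling laws", {
  tab <- default_cylinder_table()
  s <- interaction_settings()
  pars <- lapply(seq_len(nrow(tab)), function(i) {
    cylinder_params(tab$width_radius_angstrom[i], tab$length_angstrom[i])
  })
  for (i in 1:6) {
    for (j in (i + 1):7) {
      expect_identical(lvw_energy(pars[[i]], pars[[j]], s),
                       lvw_energy(pars[[j]], pars[[i]], s))
    }
  }
  a <- pars[[1]]; b <- pars[[5]]
  # doubling the distance divides the energy by 2^(3/2)
  e1 <- lvw_energy(a, b, interaction_settings(distance_D = 1.5))
  e2 <- lvw_energy(a, b, interaction_settings(distance_D = 3.0))
  expect_equal(e1 / e2, 2^1.5, tolerance = 1e-12)
  # linear in the Hamaker constant
  e3 <- lvw_energy(a, b, interaction_settings(hamaker_A = 3.7e-20))
  expect_equal(e3 / e1, 3.7e-20 / 1e-19, tolerance = 1e-12)
  # linear in the (mean) length
  stretched <- cylinder_params(a$radius_R, a$length_L * 2)
  e4 <- lvw_energy(stretched, stretched, s)
  e5 <- lvw_energy(a, a, s)
  expect_equal(e4 / e5, 2, tolerance = 1e-12)
})

test_that("invalid geometry is rejected with a named parameter", {
  expect_error(cylinder_params(-1, 20), "radius_R")
  expect_error(cylinder_params(5, 0), "length_L")
  expect_error(interaction_settings(distance_D = -2), "distance_D")
  expect_error(interaction_settings(hamaker_A = 0), "hamaker_A")
})

test_that("force field agrees entrywise with the independent oracle", {
  tab <- default_cylinder_table()
  ff <- build_force_field(tab, interaction_settings())
  expect_true(isSymmetric(unclass(ff)))
  expect_true(all(ff > 0))
  for (i in 1:7) {
    for (j in 1:7) {
      L <- (tab$length_angstrom[i] + tab$length_angstrom[j]) / 2
      expect_equal(
        ff[tab$class[i], tab$class[j]],
        lvw_oracle(1e-19, L, 1.5, tab$width_radius_angstrom[i],
                   tab$width_radius_angstrom[j]),
        tolerance = 1e-12)
    }
  }
})

test_that("force field maximum sits on the pair maximizing L*sqrt(RiRj/(Ri+Rj))", {
  ff <- build_force_field()
  idx <- which(unclass(ff) == max(ff), arr.ind = TRUE)
  expect_true(all(rownames(ff)[idx[, 1]] == "sphingolipids"))
})

test_that("force field is order-independent and linear in the Hamaker constant", {
  tab <- default_cylinder_table()
  shuffled <- tab[c(4, 2, 7, 1, 6, 3, 5), ]
  expect_equal(unclass(build_force_field(shuffled)),
               unclass(build_force_field(tab)))
  k <- 2.5
  ff1 <- build_force_field(tab, interaction_settings(hamaker_A = 1e-19))
  ffk <- build_force_field(tab, interaction_settings(hamaker_A = k * 1e-19))
  expect_equal(unclass(ffk), k * unclass(ff1), tolerance = 1e-12)
})

test_that("a missing class is reported by name", {
  tab <- default_cylinder_table()
  expect_error(build_force_field(tab[tab$class != "dha", ]), "dha")
})
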