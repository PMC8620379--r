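# Shared fixtures for the test suite: everything is built in code.

scenarios <- scenario_set()
ff_default <- build_force_field(scenarios$cylinders)

# a zero force field with valid shape, for free-diffusion limits
ff_zero <- structure(matrix(0, 7, 7, dimnames = list(lipid_classes(), lipid_classes())),
                     class = c("force_field", "matrix"),
                     settings = interaction_settings())

# reduced-scale config used across stochastic tests
desk_cfg <- function(seed = NULL, iterations = 300, dims = c(100, 100)) {
  sim_config(dims = dims, iterations = iterations, seed = seed,
             record_rmsd = FALSE)
}

# a filled disc mask of radius r centered on an H x W lattice
disc_mask <- function(r, H = 64, W = 64, n_discs = 1, centers = NULL) {
  m <- matrix(FALSE, H, W)
  if (is.null(centers)) centers <- matrix(c(H / 2, W / 2), 1, 2)
  for (i in seq_len(nrow(centers))) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    for (y in 1:H) {
      dx2 <- r^2 - (y - cy)^2
      if (dx2 < 0) next
      dx <- sqrt(dx2)
      cols <- max(1, ceiling(cx - dx)):min(W, floor(cx + dx))
      m[y, cols] <- TRUE
    }
  }
  m
}

# independent direct evaluation of the cylinder interaction formula,
# kept deliberately separate from the package implementation
lvw_oracle <- function(A, L, D, Ri, Rj) {
  A * L / (12 * sqrt(2) * D^(3 / 2)) * sqrt(Ri * Rj / (Ri + Rj))
}

# uniform single-class composition
pure_composition <- function(class) {
  x <- setNames(rep(0, 7), lipid_classes())
  x[class] <- 100
  membrane_composition(x)
}
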