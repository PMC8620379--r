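#' Simulation configuration
#'
#' Bundles the knobs of the stochastic swap dynamics.
#'
#' @param dims Lattice dimensions `c(H, W)`, default `c(200, 200)`.
#' @param iterations Number of sweeps (default 1000; enough to reach a
#'   steady distribution of low-mobility regions at the default scale).
#' @param replicates Number of independent replicate simulations used by
#'   scenario-level summaries (default 10).
#' @param swap_scale_theta Energy scale of the swap rule in J, or `NULL`
#'   to auto-calibrate from the force field ([calibrate_theta()]).
#' @param rule Acceptance rule. `"binding"` (default): the probability
#'   to exchange falls exponentially with the current binding of the two
#'   participating elements, `p = exp(-(B - B_floor)/theta)` with
#'   `B_floor` the weakest realizable two-site binding — the higher the
#'   force between neighbors, the lower the probability to switch.
#'   `"metropolis"`: `p = min(1, exp((B_swap - B_cur)/theta))`,
#'   a binding-seeking equilibrium rule kept for sensitivity checks.
#' @param count_same_class Whether an accepted exchange between two
#'   elements of the same class counts as a change of position for the
#'   mobility map (default `TRUE`: any exchange is a move).
#' @param record_rmsd Record the per-iteration RMSD noise series
#'   (default `TRUE`).
#' @param seed Integer seed for the whole trajectory.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dims = c(200, 200), iterations = 1000, replicates = 10,
                       swap_scale_theta = NULL,
                       rule = c("binding", "metropolis"),
                       count_same_class = TRUE, record_rmsd = TRUE,
                       seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(dims) == 2, all(dims >= 1), iterations >= 1, replicates >= 1)
  if (!is.null(swap_scale_theta) && swap_scale_theta <= 0) {
    stop("swap_scale_theta must be positive", call. = FALSE)
  }
  structure(list(dims = as.integer(dims), iterations = as.integer(iterations),
                 replicates = as.integer(replicates),
                 swap_scale_theta = swap_scale_theta, rule = rule,
                 count_same_class = isTRUE(count_same_class),
                 record_rmsd = isTRUE(record_rmsd), seed = seed),
            class = "sim_config")
}

#' Preset configurations
#'
#' `"paper"` is the full study scale: 200x200 lattice, 1000 iterations,
#' 10 replicates, validation ensemble of 100. `"desk"` is a reduced
#' preset for interactive work and continuous testing: 100x100 lattice,
#' 300 iterations, 3 replicates, ensemble of 20.
#'
#' @param name `"paper"` or `"desk"`.
#' @param seed Optional seed stored in the config.
#' @return A list with elements `config` (a [sim_config()]) and
#'   `ensemble_size`.
#' @export
sim_preset <- function(name = c("paper", "desk"), seed = NULL) {
  name <- match.arg(name)
  if (name == "paper") {
    list(config = sim_config(dims = c(200, 200), iterations = 1000,
                             replicates = 10, seed = seed),
         ensemble_size = 100)
  } else {
    list(config = sim_config(dims = c(100, 100), iterations = 300,
                             replicates = 3, seed = seed),
         ensemble_size = 20)
  }
}

#' Run the membrane swap-dynamics simulation
#'
#' Initializes a lattice from the composition and applies the stochastic
#' exchange dynamics for `config$iterations` sweeps. One sweep visits
#' every site once in a fresh random permutation; each visited site
#' proposes an exchange with one uniformly chosen von Neumann neighbor
#' and the proposal is accepted with the probability given by
#' `config$rule`. The per-site mobility is the fraction of sweeps in
#' which the element at that site changed position.
#'
#' @param composition A [membrane_composition()].
#' @param force_field A [build_force_field()] matrix.
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: list with elements `lattice`
#'   (final grid), `initial` (starting grid), `mobility` (H x W matrix
#'   in \[0,1\]), `rmsd_series` (RMSD in J of the binding-energy field
#'   relative to the start, evaluated before each sweep, so entry 1 is
#'   0), `theta` (the scale actually used), `config`, and `seed`.
#' @export
#' @examples
#' ff <- build_force_field()
#' sc <- scenario_set()
#' res <- run_simulation(sc$membrane$Control, ff,
#'                       sim_config(dims = c(40, 40), iterations = 50, seed = 1))
#' range(res$mobility)
run_simulation <- function(composition, force_field, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  comp <- as_composition(composition)
  e <- unclass(force_field)
  theta <- config$swap_scale_theta
  if (is.null(theta)) theta <- calibrate_theta(force_field, config$rule)
  if (theta <= 0) stop("swap_scale_theta must be positive", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  lattice <- initialize_lattice(comp, config$dims)
  counts0 <- lattice_counts(lattice)
  grid <- matrix(as.integer(lattice), config$dims[1], config$dims[2])
  bfloor <- 8 * min(e)
  out <- run_sim_cpp(grid, e, config$iterations, theta, bfloor,
                     if (config$rule == "binding") 0L else 1L,
                     config$count_same_class, config$record_rmsd)
  final <- structure(out$grid, classes = lipid_classes(),
                     class = c("membrane_lattice", "matrix"))
  # lipid elements are only ever exchanged, so the class census is an
  # invariant of the dynamics; verify on every run
  if (!identical(lattice_counts(final), counts0)) {
    stop("internal error: lattice class counts were not conserved", call. = FALSE)
  }
  mobility <- out$accepted / config$iterations
  structure(list(lattice = final, initial = lattice, mobility = mobility,
                 rmsd_series = if (config$record_rmsd) as.numeric(out$rmsd) else NULL,
                 theta = theta, config = config, seed = config$seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Membrane simulation result\n")
  cat(sprintf("  lattice: %d x %d, %d iterations, rule = %s\n",
              nrow(x$lattice), ncol(x$lattice), x$config$iterations,
              x$config$rule))
  cat(sprintf("  theta = %.3e J, mean mobility = %.3f\n",
              x$theta, mean(x$mobility)))
  invisible(x)
}
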