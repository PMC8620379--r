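#' Random reference ensemble for the validation statistic
#'
#' Simulates `n` membranes with random (symmetric-Dirichlet) lipid
#' compositions through the standard pipeline, extracts each one's raft
#' composition, and records two quadratic differences per draw:
#' * `membrane_vs_raft` — between the random input membrane and its own
#'   simulated raft composition;
#' * `raft_vs_reference` — between the simulated raft composition and a
#'   fixed experimental raft reference (when supplied).
#'
#' Empirical 2.5/97.5 percentile bounds of each statistic form the 95%
#' confidence interval against which a data-driven solution is judged.
#' A draw whose raft region comes out empty is flagged and resampled.
#'
#' @param n Ensemble size (default 100).
#' @param force_field A [build_force_field()] matrix.
#' @param config A [sim_config()]; its `seed` (or the current RNG state)
#'   drives the whole ensemble.
#' @param reference_raft Optional experimental raft
#'   [membrane_composition()] for the second statistic.
#' @param alpha Dirichlet concentration for [random_composition()].
#' @param tau Raft mobility threshold passed to [raft_mask()]
#'   (default the fixed [raft_mobility_threshold()]).
#' @return List of class `raft_ensemble`: `draws` (data frame with both
#'   statistics per draw), `ci` (2.5/97.5 bounds per statistic),
#'   `resampled` (number of empty-raft redraws), `n`, plus the
#'   compositions of each draw.
#' @export
random_reference_ensemble <- function(n = 100, force_field,
                                      config = sim_config(),
                                      reference_raft = NULL, alpha = 1,
                                      tau = NULL) {
  stopifnot(n >= 2)
  if (!is.null(config$seed)) set.seed(config$seed)
  # per-draw sub-seeds so each simulation is independently reproducible
  seeds <- sample.int(.Machine$integer.max, 10 * n)
  d_mr <- numeric(n); d_rr <- rep(NA_real_, n)
  comps <- vector("list", n); raft_comps <- vector("list", n)
  resampled <- 0L; si <- 0L
  cfg <- config
  for (i in seq_len(n)) {
    repeat {
      si <- si + 1L
      if (si > length(seeds)) stop("too many empty-raft draws", call. = FALSE)
      set.seed(seeds[si])
      comp <- random_composition()
      cfg$seed <- seeds[si] %% 1000003L + 1L
      res <- run_simulation(comp, force_field, cfg)
      mask <- raft_mask(res$mobility, tau)
      if (any(mask)) break
      resampled <- resampled + 1L
    }
    raft <- lattice_composition(res$lattice, mask)
    comps[[i]] <- comp
    raft_comps[[i]] <- raft
    d_mr[i] <- quadratic_difference(comp, raft)
    if (!is.null(reference_raft)) {
      d_rr[i] <- quadratic_difference(raft, reference_raft)
    }
  }
  ci <- list(membrane_vs_raft = unname(quantile(d_mr, c(0.025, 0.975))))
  if (!is.null(reference_raft)) {
    ci$raft_vs_reference <- unname(quantile(d_rr, c(0.025, 0.975)))
  }
  structure(list(draws = data.frame(membrane_vs_raft = d_mr,
                                    raft_vs_reference = d_rr),
                 ci = ci, n = n, resampled = resampled,
                 compositions = comps, raft_compositions = raft_comps),
            class = "raft_ensemble")
}

#' Judge a data-driven solution against the random ensemble
#'
#' Runs the standard pipeline on an experimental membrane composition
#' and compares its two quadratic-difference statistics with the random
#' ensemble's 95% intervals. The acceptance logic: the membrane-vs-
#' simulated-raft difference should fall outside the random interval
#' (the experimental membrane is not a typical random composition), and
#' the simulated-vs-experimental-raft difference should fall below the
#' random interval's upper bound (the prediction is closer to the
#' measured raft composition than random solutions are).
#'
#' @param membrane_comp Experimental whole-membrane
#'   [membrane_composition()] (model input).
#' @param experimental_raft_comp Measured raft composition (reference).
#' @param ensemble A [random_reference_ensemble()] built with
#'   `reference_raft = experimental_raft_comp` and a matching config.
#' @param force_field,config,tau As in [random_reference_ensemble()].
#' @return List of class `validation_result`: observed statistics,
#'   interval bounds, verdicts, the simulated raft composition and the
#'   ensemble size.
#' @export
validate_solution <- function(membrane_comp, experimental_raft_comp, ensemble,
                              force_field, config = sim_config(), tau = NULL) {
  stopifnot(inherits(ensemble, "raft_ensemble"))
  res <- run_simulation(membrane_comp, force_field, config)
  mask <- raft_mask(res$mobility, tau)
  if (!any(mask)) stop("data-driven simulation produced an empty raft region",
                       call. = FALSE)
  raft <- lattice_composition(res$lattice, mask)
  d_mr <- quadratic_difference(membrane_comp, raft)
  d_rr <- quadratic_difference(raft, experimental_raft_comp)
  ci_mr <- ensemble$ci$membrane_vs_raft
  ci_rr <- ensemble$ci$raft_vs_reference
  structure(list(
    observed = c(membrane_vs_raft = d_mr, raft_vs_reference = d_rr),
    ci = ensemble$ci,
    outside_random_interval = d_mr < ci_mr[1] || d_mr > ci_mr[2],
    below_random_upper = if (is.null(ci_rr)) NA else d_rr < ci_rr[2],
    simulated_raft = raft,
    ensemble_size = ensemble$n
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Validation against random-composition ensemble (n =",
      x$ensemble_size, ")\n")
  cat(sprintf("  membrane vs simulated raft: D2 = %.1f, random 95%% CI [%.1f, %.1f] -> %s\n",
              x$observed["membrane_vs_raft"], x$ci$membrane_vs_raft[1],
              x$ci$membrane_vs_raft[2],
              if (x$outside_random_interval) "outside" else "inside"))
  if (!is.null(x$ci$raft_vs_reference)) {
    cat(sprintf("  simulated vs experimental raft: D2 = %.1f, random 95%% CI [%.1f, %.1f] -> %s upper bound\n",
                x$observed["raft_vs_reference"], x$ci$raft_vs_reference[1],
                x$ci$raft_vs_reference[2],
                if (isTRUE(x$below_random_upper)) "below" else "not below"))
  }
  invisible(x)
}
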