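#' Cylinder geometry of a lipid class
#'
#' Each lipid class is coarse-grained as the cylinder that best fits the
#' molecular volume, parameterized by its radius and length in Angstrom.
#'
#' @param radius_R Cylinder radius (Angstrom), > 0.
#' @param length_L Cylinder length (Angstrom), > 0.
#' @return A list of class `cylinder_params`.
#' @export
cylinder_params <- function(radius_R, length_L) {
  if (!is.numeric(radius_R) || length(radius_R) != 1 || is.na(radius_R) ||
      radius_R <= 0) {
    stop("radius_R must be a positive number", call. = FALSE)
  }
  if (!is.numeric(length_L) || length(length_L) != 1 || is.na(length_L) ||
      length_L <= 0) {
    stop("length_L must be a positive number", call. = FALSE)
  }
  structure(list(radius_R = radius_R, length_L = length_L),
            class = "cylinder_params")
}

#' Interaction settings for the London-Van der Waals energy
#'
#' @param hamaker_A Hamaker constant in J (vacuum magnitudes are in the
#'   1e-20 to 1e-19 J range; default 1e-19 J).
#' @param distance_D Intermolecular distance between cylinder surfaces in
#'   Angstrom (default 1.50, the model's fitted value).
#' @return A list of class `interaction_settings`.
#' @export
interaction_settings <- function(hamaker_A = 1e-19, distance_D = 1.5) {
  if (!is.numeric(hamaker_A) || hamaker_A <= 0) {
    stop("hamaker_A must be positive", call. = FALSE)
  }
  if (!is.numeric(distance_D) || distance_D <= 0) {
    stop("distance_D must be positive", call. = FALSE)
  }
  structure(list(hamaker_A = hamaker_A, distance_D = distance_D),
            class = "interaction_settings")
}

#' Non-retarded London-Van der Waals energy between two parallel cylinders
#'
#' Computes the additive, non-retarded London-Van der Waals attraction
#' between two lipid cylinders:
#'
#' \deqn{LVW_{ij} = \frac{A\,L}{12\sqrt{2}\,D^{3/2}}
#'   \sqrt{\frac{R_i R_j}{R_i + R_j}}}
#'
#' with Hamaker constant \eqn{A} (J), cylinder length \eqn{L} and radii
#' \eqn{R_i, R_j} (Angstrom), and intermolecular distance \eqn{D}
#' (Angstrom). For a heterogeneous pair the single length \eqn{L} is
#' taken as the arithmetic mean of the two class lengths, which makes the
#' energy symmetric by construction and reduces to the plain formula for
#' a within-class pair.
#'
#' @param params_i,params_j [cylinder_params()] for the two classes.
#' @param settings [interaction_settings()].
#' @return Interaction energy magnitude in J (> 0).
#' @export
#' @examples
#' chol <- cylinder_params(radius_R = 5.94, length_L = 19.99)
#' lvw_energy(chol, chol, interaction_settings(hamaker_A = 1e-19))
lvw_energy <- function(params_i, params_j, settings = interaction_settings()) {
  stopifnot(inherits(settings, "interaction_settings"))
  if (!inherits(params_i, "cylinder_params")) params_i <- do.call(cylinder_params, params_i)
  if (!inherits(params_j, "cylinder_params")) params_j <- do.call(cylinder_params, params_j)
  L <- (params_i$length_L + params_j$length_L) / 2
  Ri <- params_i$radius_R
  Rj <- params_j$radius_R
  settings$hamaker_A * L / (12 * sqrt(2) * settings$distance_D^1.5) *
    sqrt(Ri * Rj / (Ri + Rj))
}

#' Build the 7x7 London-Van der Waals force field
#'
#' Evaluates [lvw_energy()] on every pair of lipid classes, yielding the
#' symmetric matrix of pairwise interaction magnitudes that drives the
#' swap dynamics.
#'
#' @param params_table Data frame with columns `class`,
#'   `width_radius_angstrom`, `length_angstrom` covering all seven
#'   classes (default: the bundled mouse frontal-cortex cylinder table,
#'   [default_cylinder_table()]).
#' @param settings [interaction_settings()].
#' @return A 7x7 symmetric numeric matrix of class `force_field` with
#'   dimnames the canonical class names and the settings attached as
#'   attribute `settings`.
#' @export
#' @examples
#' ff <- build_force_field()
#' ff["saturates", "sphingolipids"]
build_force_field <- function(params_table = default_cylinder_table(),
                              settings = interaction_settings()) {
  cls <- lipid_classes()
  missing <- setdiff(cls, params_table$class)
  if (length(missing)) {
    stop("cylinder parameter table is missing classes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- params_table[match(cls, params_table$class), ]
  pars <- lapply(seq_len(7), function(i) {
    cylinder_params(rows$width_radius_angstrom[i], rows$length_angstrom[i])
  })
  e <- matrix(0, 7, 7, dimnames = list(cls, cls))
  for (i in 1:7) {
    for (j in i:7) {
      e[i, j] <- e[j, i] <- lvw_energy(pars[[i]], pars[[j]], settings)
    }
  }
  structure(e, class = c("force_field", "matrix"), settings = settings)
}

#' Default swap-rule energy scale calibrated from a force field
#'
#' The swap dynamics compare binding energies to a scale `theta`. The
#' default keeps acceptance probabilities in a useful dynamic range for
#' either rule:
#' * `"binding"` (kinetic-arrest rule): theta equals the spread
#'   `max - min` of the pairwise interaction energies. A two-site
#'   neighborhood holds eight bonds, so the acceptance probability
#'   spans `exp(-8)`..1 between the weakest- and strongest-bound
#'   realizable configurations — mixed neighborhoods stay mobile while
#'   strongly bound (saturate/sphingolipid-rich) clusters freeze, which
#'   is the quench depth at which the simulated membranes segregate
#'   into persistent low-mobility domains within 1000 iterations.
#' * `"metropolis"`: theta equals the median off-diagonal interaction
#'   energy.
#'
#' Either way theta scales linearly with the Hamaker constant, so the
#' dynamics depend only on energy ratios.
#'
#' @param force_field A [build_force_field()] matrix.
#' @param rule `"binding"` or `"metropolis"`.
#' @return Positive scalar (J).
#' @export
calibrate_theta <- function(force_field, rule = c("binding", "metropolis")) {
  rule <- match.arg(rule)
  e <- unclass(force_field)
  if (rule == "binding") {
    span <- max(e) - min(e)
    if (span <= 0) return(1)  # uniform field: scale is irrelevant
    span
  } else {
    off <- e[row(e) != col(e)]
    stats::median(off)
  }
}
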