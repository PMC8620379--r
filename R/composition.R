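#' The seven lipid classes of the membrane model
#'
#' Lipid species are aggregated by structural similarity into seven
#' classes; each class maps to a stable integer code 0-6 used to encode
#' lattice states.
#'
#' @return Character vector of the seven canonical class names, in code
#'   order (code = position - 1).
#' @export
#' @examples
#' lipid_classes()
lipid_classes <- function() {
  c("cholesterol", "sterol_esters", "dha", "n6_lcpufa",
    "monoenes", "saturates", "sphingolipids")
}

#' Construct and validate a membrane composition
#'
#' A membrane composition gives the mole percentage of each of the seven
#' lipid classes, summing to 100 (tolerance 0.5 to absorb rounding in
#' published tables).
#'
#' @param percent Named numeric vector; names must be the seven canonical
#'   class names (any order). All values must be non-negative.
#' @return A named numeric vector of class `membrane_composition`, in
#'   canonical class order.
#' @export
#' @examples
#' membrane_composition(c(
#'   cholesterol = 27.06, sterol_esters = 1.58, dha = 13.73,
#'   n6_lcpufa = 12.19, monoenes = 15.71, saturates = 27.47,
#'   sphingolipids = 2.26
#' ))
membrane_composition <- function(percent) {
  cls <- lipid_classes()
  if (is.null(names(percent)) || !setequal(names(percent), cls)) {
    bad <- setdiff(names(percent), cls)
    stop("composition must be named by the 7 canonical lipid classes (",
         paste(cls, collapse = ", "), ")",
         if (length(bad)) paste0("; unknown: ", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  x <- as.numeric(percent[cls])
  names(x) <- cls
  if (any(is.na(x)) || any(x < 0)) {
    stop("composition percentages must be non-negative and non-missing",
         call. = FALSE)
  }
  s <- sum(x)
  if (abs(s - 100) > 0.5) {
    stop(sprintf("composition percentages must sum to 100 (+/- 0.5), got %.4f", s),
         call. = FALSE)
  }
  structure(x, class = "membrane_composition")
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("Membrane composition (% of total lipids):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

# Internal: coerce a plausible input (named vector or composition) and
# validate.
as_composition <- function(x) {
  if (inherits(x, "membrane_composition")) x else membrane_composition(x)
}

#' Quadratic difference between two lipid compositions
#'
#' The validation statistic: the sum over the seven lipid classes of the
#' squared difference of percentages. Units are squared percentage
#' points. It is a true squared distance: non-negative, symmetric, zero
#' iff the compositions are equal.
#'
#' @param comp_a,comp_b Membrane compositions (see
#'   [membrane_composition()]).
#' @return Non-negative scalar.
#' @export
#' @examples
#' a <- membrane_composition(c(cholesterol = 50, sterol_esters = 0, dha = 0,
#'   n6_lcpufa = 0, monoenes = 0, saturates = 50, sphingolipids = 0))
#' quadratic_difference(a, a) # 0
quadratic_difference <- function(comp_a, comp_b) {
  a <- as_composition(comp_a)
  b <- as_composition(comp_b)
  sum((unclass(a) - unclass(b))^2)
}

#' Draw random membrane compositions on the simplex
#'
#' Samples compositions from a symmetric Dirichlet distribution over the
#' seven lipid classes, scaled to percentages. Used to build the random
#' reference ensemble of the validation procedure.
#'
#' @param n Number of compositions to draw.
#' @param alpha Dirichlet concentration (default 1: uniform over the
#'   simplex).
#' @return A single `membrane_composition` if `n = 1`, else a list of
#'   them. Uses R's RNG; seed with [set.seed()] for reproducibility.
#' @export
random_composition <- function(n = 1, alpha = 1) {
  draws <- lapply(seq_len(n), function(i) {
    g <- stats::rgamma(7, shape = alpha, rate = 1)
    membrane_composition(setNames(100 * g / sum(g), lipid_classes()))
  })
  if (n == 1) draws[[1]] else draws
}
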