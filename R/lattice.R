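#' Allocate lattice sites to lipid classes
#'
#' Converts percentages to integer site counts with largest-remainder
#' rounding, so the counts sum exactly to `n_sites` while each class
#' count is within one site of `percent * n_sites / 100`.
#'
#' @param composition A [membrane_composition()].
#' @param n_sites Total number of lattice sites (>= 1).
#' @return Named integer vector over the seven classes summing to
#'   `n_sites`.
#' @export
#' @examples
#' sc <- scenario_set()
#' allocate_counts(sc$membrane$Control, 40000)
allocate_counts <- function(composition, n_sites) {
  comp <- as_composition(composition)
  stopifnot(n_sites >= 1)
  # scale to exactly 100 first so a table row summing to 100 +/- 0.5
  # (printed rounding) still fills the lattice exactly
  pct <- unclass(comp) * 100 / sum(comp)
  exact <- pct * n_sites / 100
  base <- floor(exact)
  short <- n_sites - sum(base)
  if (short > 0) {
    # ties broken by class order, deterministically
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(comp)
  stopifnot(sum(counts) == n_sites)
  counts
}

#' Initialize a random membrane lattice
#'
#' Places the allocated multiset of lipid elements uniformly at random
#' on an `H x W` periodic lattice.
#'
#' @param composition A [membrane_composition()].
#' @param dims Integer vector `c(H, W)`, default `c(200, 200)`.
#' @param seed Optional integer seed; if given, the arrangement is fully
#'   reproducible.
#' @return Integer matrix of class codes 0-6 with attribute
#'   `"classes"`; class `"membrane_lattice"`.
#' @export
initialize_lattice <- function(composition, dims = c(200, 200), seed = NULL) {
  if (length(dims) != 2 || any(dims < 1)) {
    stop("dims must be two positive integers", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- allocate_counts(composition, prod(dims))
  codes <- rep.int(0:6, counts)
  grid <- matrix(sample(codes), nrow = dims[1], ncol = dims[2])
  structure(grid, classes = lipid_classes(), class = c("membrane_lattice", "matrix"))
}

#' Class counts of a lattice
#'
#' @param lattice A lattice of class codes 0-6.
#' @return Named integer vector of per-class site counts.
#' @export
lattice_counts <- function(lattice) {
  counts <- tabulate(as.integer(lattice) + 1L, nbins = 7)
  setNames(as.integer(counts), lipid_classes())
}

#' Composition (percent) of a lattice or lattice region
#'
#' @param lattice A lattice of class codes.
#' @param mask Optional logical matrix selecting a region.
#' @return A [membrane_composition()].
#' @export
lattice_composition <- function(lattice, mask = NULL) {
  codes <- if (is.null(mask)) as.integer(lattice) else as.integer(lattice[mask])
  if (length(codes) == 0) {
    stop("composition of an empty region is undefined", call. = FALSE)
  }
  counts <- tabulate(codes + 1L, nbins = 7)
  membrane_composition(setNames(100 * counts / sum(counts), lipid_classes()))
}

#' Binding energy of one site with its four neighbors
#'
#' Sums the force-field entries between a site's lipid class and its
#' four von Neumann neighbors under periodic wrap.
#'
#' @param lattice A lattice of class codes 0-6.
#' @param site Integer vector `c(row, col)` (1-based).
#' @param force_field A [build_force_field()] matrix.
#' @return Energy in J.
#' @export
neighbor_binding <- function(lattice, site, force_field) {
  H <- nrow(lattice); W <- ncol(lattice)
  r <- site[1]; c <- site[2]
  stopifnot(r >= 1, r <= H, c >= 1, c <= W)
  k <- lattice[r, c] + 1L
  up <- if (r == 1) H else r - 1
  dn <- if (r == H) 1 else r + 1
  lf <- if (c == 1) W else c - 1
  rt <- if (c == W) 1 else c + 1
  e <- unclass(force_field)
  e[k, lattice[up, c] + 1L] + e[k, lattice[dn, c] + 1L] +
    e[k, lattice[r, lf] + 1L] + e[k, lattice[r, rt] + 1L]
}

#' Per-site binding-energy field
#'
#' [neighbor_binding()] evaluated at every lattice site (compiled).
#'
#' @inheritParams neighbor_binding
#' @return Numeric matrix, same dimensions as the lattice (J).
#' @export
binding_field <- function(lattice, force_field) {
  binding_field_cpp(matrix(as.integer(lattice), nrow(lattice), ncol(lattice)),
                    unclass(force_field))
}
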