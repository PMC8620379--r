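#' Peroxidability index of a lipid composition
#'
#' A linear score of the susceptibility of a membrane region to lipid
#' peroxidation, restricted to the unsaturated classes of the model:
#'
#' \deqn{PI = 0.025\,\%monoenes + 5\,\%n6\_LCPUFA + 6\,\%DHA}
#'
#' Cholesterol, sterol esters, saturates and sphingolipids contribute
#' nothing. The score is linear in the composition, so the PI of a
#' mixture equals the composition-weighted PI; bounds are 0 (no
#' unsaturated classes) to 600 (pure DHA).
#'
#' @param composition A [membrane_composition()], or any named vector of
#'   non-negative percentages over the seven classes.
#' @return Dimensionless scalar in \[0, 600\].
#' @export
#' @examples
#' sc <- scenario_set()
#' peroxidability_index(sc$membrane$Control)
peroxidability_index <- function(composition) {
  comp <- as_composition(composition)
  unname(0.025 * comp["monoenes"] + 5 * comp["n6_lcpufa"] + 6 * comp["dha"])
}

# PI coefficients in lattice-code order (cholesterol, sterol_esters,
# dha, n6_lcpufa, monoenes, saturates, sphingolipids)
pi_coefficients <- function() {
  setNames(c(0, 0, 6, 5, 0.025, 0, 0), lipid_classes())
}

#' Peroxidability map over non-overlapping lattice patches
#'
#' Tiles the lattice into `patch_size x patch_size` blocks, converts
#' each block's class census to percentages and applies
#' [peroxidability_index()], giving an `(H/patch) x (W/patch)` map.
#'
#' @param lattice A membrane lattice of class codes.
#' @param patch_size Patch edge in cells (default 5); lattice dimensions
#'   must be divisible by it.
#' @return Numeric matrix of class `pi_map` with attribute
#'   `patch_size`.
#' @export
pi_patch_map <- function(lattice, patch_size = 5) {
  H <- nrow(lattice); W <- ncol(lattice)
  if (H %% patch_size != 0 || W %% patch_size != 0) {
    stop(sprintf(paste0("lattice dims (%d x %d) are not divisible by the ",
                        "patch size %d; crop the lattice first"),
                 H, W, patch_size), call. = FALSE)
  }
  coef <- pi_coefficients()
  # per-cell PI contribution; patch PI is the patch mean times 100/ n,
  # i.e. simply the mean contribution * 100 / 1 per percent scaling
  cell <- matrix(coef[as.integer(lattice) + 1L], H, W)
  ph <- H %/% patch_size; pw <- W %/% patch_size
  out <- matrix(0, ph, pw)
  for (i in seq_len(ph)) {
    rows <- ((i - 1) * patch_size + 1):(i * patch_size)
    for (j in seq_len(pw)) {
      cols <- ((j - 1) * patch_size + 1):(j * patch_size)
      # percent of each cell within the patch is 100/(patch^2)
      out[i, j] <- sum(cell[rows, cols]) * 100 / patch_size^2
    }
  }
  structure(out, patch_size = patch_size, class = c("pi_map", "matrix"))
}

#' Peroxidability inside and outside lipid rafts
#'
#' Applies [peroxidability_index()] to the compositions of the raft
#' region, the non-raft region, and the whole lattice. By linearity the
#' whole-membrane PI equals the area-weighted combination of the two
#' region values.
#'
#' @param lattice A membrane lattice.
#' @param mask A [raft_mask()] of matching dimensions.
#' @return List with `pi_inside`, `pi_outside`, `pi_whole` (an all-true
#'   mask yields `pi_outside = NA`).
#' @export
domain_pi <- function(lattice, mask) {
  dc <- domain_composition(lattice, mask)
  list(pi_inside = peroxidability_index(dc$inside),
       pi_outside = if (is.null(dc$outside)) NA_real_ else
         peroxidability_index(dc$outside),
       pi_whole = peroxidability_index(lattice_composition(lattice)))
}
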