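#' Bundled cylinder parameter table
#'
#' Cylinder radius and length per lipid class, estimated from mouse
#' frontal-cortex membranes, together with the fitted intermolecular
#' distance of 1.50 Angstrom exposed through [interaction_settings()].
#'
#' @return Data frame with columns `class`, `width_radius_angstrom`,
#'   `length_angstrom`.
#' @export
default_cylinder_table <- function() {
  path <- system.file("extdata", "cylinder_parameters.csv", package = "raftsim",
                      mustWork = TRUE)
  read.csv(path, check.names = FALSE)
}

#' Read a lipid-class composition table
#'
#' Accepts either a long table with columns `class,percent` (a single
#' composition) or a wide table with a `class` column followed by one
#' column per condition. Every composition is validated: the seven
#' canonical class names must be present and each column must sum to 100
#' within 0.5.
#'
#' @param path Path to a CSV file.
#' @return A single [membrane_composition()] for a long table, or a
#'   named list of them (one per condition column) for a wide table.
#' @export
#' @examples
#' p <- system.file("extdata", "frontal_cortex_cell_membrane.csv",
#'                  package = "raftsim")
#' comps <- read_composition_table(p)
#' comps$Control["cholesterol"]
read_composition_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  if (!"class" %in% names(tab)) {
    stop("composition table must have a 'class' column", call. = FALSE)
  }
  value_cols <- setdiff(names(tab), "class")
  if (length(value_cols) == 0) {
    stop("composition table has no value columns", call. = FALSE)
  }
  build <- function(col) {
    x <- setNames(tab[[col]], tab$class)
    tryCatch(membrane_composition(x),
             error = function(e) {
               stop(sprintf("condition '%s': %s", col, conditionMessage(e)),
                    call. = FALSE)
             })
  }
  if (identical(value_cols, "percent")) {
    build("percent")
  } else {
    setNames(lapply(value_cols, build), value_cols)
  }
}

#' Write a composition (or list of compositions) as CSV
#'
#' Inverse of [read_composition_table()]: a single composition is
#' written long (`class,percent`), a named list wide.
#'
#' @param x A `membrane_composition` or named list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(x, path) {
  if (inherits(x, "membrane_composition")) {
    df <- data.frame(class = names(x), percent = as.numeric(x))
  } else {
    df <- data.frame(class = lipid_classes())
    for (nm in names(x)) df[[nm]] <- as.numeric(as_composition(x[[nm]]))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The four study scenarios: human frontal-cortex compositions
#'
#' Loads the bundled experimental lipid-class tables for the Control and
#' the three Braak-stage conditions (ADI/II, ADIII/IV, ADV/VI): the
#' whole cell-membrane compositions used as simulation input, the lipid
#' raft compositions used as validation reference, and the cylinder
#' geometry table. The membrane table is the study's "cell membrane"
#' panel; figure panels elsewhere label the same data "non-rafts", so
#' the list also carries it under the alias `nonrafts`.
#'
#' @return A list of class `scenario_set` with elements `conditions`
#'   (character), `membrane` (list of compositions, the model input),
#'   `nonrafts` (alias of `membrane`), `rafts_experimental` (list of
#'   compositions, the validation reference) and `cylinders` (data
#'   frame).
#' @export
#' @examples
#' sc <- scenario_set()
#' sc$conditions
scenario_set <- function() {
  mem <- read_composition_table(system.file(
    "extdata", "frontal_cortex_cell_membrane.csv", package = "raftsim",
    mustWork = TRUE))
  raft <- read_composition_table(system.file(
    "extdata", "frontal_cortex_lipid_rafts.csv", package = "raftsim",
    mustWork = TRUE))
  conditions <- c("Control", "ADI/II", "ADIII/IV", "ADV/VI")
  stopifnot(setequal(names(mem), conditions), setequal(names(raft), conditions))
  structure(list(conditions = conditions,
                 membrane = mem[conditions],
                 nonrafts = mem[conditions],
                 rafts_experimental = raft[conditions],
                 cylinders = default_cylinder_table()),
            class = "scenario_set")
}

#' Export mobility / peroxidability maps as PNG heatmaps
#'
#' Writes one PNG per map with a fixed color range across maps so
#' conditions remain comparable, plus a small JSON sidecar recording the
#' color limits and map dimensions.
#'
#' @param maps Named list of numeric matrices.
#' @param outdir Output directory (created if needed).
#' @param zlim Common color limits; default the range over all maps.
#' @param palette Color palette function, default [grDevices::gray.colors].
#' @return Character vector of files written, invisibly.
#' @export
export_heatmaps <- function(maps, outdir, zlim = NULL,
                            palette = grDevices::gray.colors) {
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(zlim)) zlim <- range(unlist(lapply(maps, range)))
  files <- character(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    f <- file.path(outdir, paste0(safe, ".png"))
    grDevices::png(f, width = ncol(m), height = nrow(m))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), zlim = zlim,
                    col = palette(256), axes = FALSE, useRaster = TRUE)
    grDevices::dev.off()
    meta <- file.path(outdir, paste0(safe, ".json"))
    jsonlite::write_json(list(map = nm, dims = dim(m), zlim = zlim),
                         meta, auto_unbox = TRUE, digits = NA)
    files <- c(files, f, meta)
  }
  invisible(files)
}
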