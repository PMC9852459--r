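#' Three-shell optical model of an adipocyte
#'
#' Builds the concentric three-shell refractive-index model of a fat cell:
#' a large lipid-droplet core, a thin cytoplasm shell and a cell membrane.
#' All lengths are in micrometres. The default parameters describe a cell of
#' outer diameter 20.02 um: an 18 um lipid core (n = 1.46), a 1 um cytoplasm
#' shell (n = 1.35) and a 10 nm membrane (n = 1.42).
#'
#' @param core_diameter Diameter of the lipid-droplet core (um).
#' @param cytoplasm_thickness Thickness of the cytoplasm shell (um).
#' @param membrane_thickness Thickness of the membrane (um). The membrane is
#'   thinner than any affordable simulation grid; rasterization handles it
#'   separately (see [rasterize()]).
#' @param n_core Refractive index of the lipid droplet.
#' @param n_cytoplasm Refractive index of the cytoplasm.
#' @param n_membrane Refractive index of the membrane.
#' @param boundary_softness Width (um) of the sigmoidal blend replacing each
#'   sharp shell boundary; 0 gives hard boundaries.
#' @return An object of class `cell_model` with the validated parameters and
#'   the derived `outer_diameter`.
#' @examples
#' cell <- make_cell()
#' cell$outer_diameter  # 20.02
#' @export
make_cell <- function(core_diameter = 18,
                      cytoplasm_thickness = 1,
                      membrane_thickness = 0.01,
                      n_core = 1.46,
                      n_cytoplasm = 1.35,
                      n_membrane = 1.42,
                      boundary_softness = 0) {
  dims <- c(core_diameter = core_diameter,
            cytoplasm_thickness = cytoplasm_thickness,
            membrane_thickness = membrane_thickness)
  if (core_diameter <= 0)
    stop("'core_diameter' must be > 0", call. = FALSE)
  for (nm in c("cytoplasm_thickness", "membrane_thickness"))
    if (dims[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm), call. = FALSE)
  if (boundary_softness < 0)
    stop("'boundary_softness' must be >= 0", call. = FALSE)
  for (nm in c("n_core", "n_cytoplasm", "n_membrane")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1)
      stop(sprintf("'%s' must be a refractive index >= 1", nm), call. = FALSE)
  }
  structure(list(
    core_diameter = core_diameter,
    cytoplasm_thickness = cytoplasm_thickness,
    membrane_thickness = membrane_thickness,
    n_core = n_core,
    n_cytoplasm = n_cytoplasm,
    n_membrane = n_membrane,
    boundary_softness = boundary_softness,
    outer_diameter = core_diameter + 2 * cytoplasm_thickness +
      2 * membrane_thickness
  ), class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("Three-shell cell model\n")
  cat(sprintf("  core      : %.3f um diameter, n = %.3f\n",
              x$core_diameter, x$n_core))
  cat(sprintf("  cytoplasm : %.3f um shell,    n = %.3f\n",
              x$cytoplasm_thickness, x$n_cytoplasm))
  cat(sprintf("  membrane  : %.4f um shell,   n = %.3f\n",
              x$membrane_thickness, x$n_membrane))
  cat(sprintf("  outer diameter %.3f um, boundary softness %.2f um\n",
              x$outer_diameter, x$boundary_softness))
  invisible(x)
}

#' Radial refractive-index profile of a cell
#'
#' Evaluates n(r) for a [make_cell()] model. With hard boundaries the profile
#' is piecewise constant over the shells; with `boundary_softness > 0` each
#' shell transition is replaced by a logistic blend of that width, so the
#' value exactly at a boundary is the midpoint of the two shell indices.
#'
#' @param cell A `cell_model`.
#' @param r Radial distance(s) from the cell centre (um, >= 0).
#' @param n_embed Refractive index of the embedding medium returned far
#'   outside the cell (interstitial fluid).
#' @return Numeric vector of refractive indices, same length as `r`.
#' @examples
#' radial_profile(make_cell(), 0)    # 1.46 (lipid core)
#' radial_profile(make_cell(), 9.5)  # 1.35 (cytoplasm)
#' @export
radial_profile <- function(cell, r, n_embed = 1.36) {
  stopifnot(inherits(cell, "cell_model"))
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  r_core <- cell$core_diameter / 2
  r_cyt <- r_core + cell$cytoplasm_thickness
  r_mem <- r_cyt + cell$membrane_thickness
  s <- cell$boundary_softness
  if (s == 0) {
    out <- rep(n_embed, length(r))
    out[r < r_mem] <- cell$n_membrane
    out[r < r_cyt] <- cell$n_cytoplasm
    out[r < r_core] <- cell$n_core
    return(out)
  }
  # logistic step of width s: value 1 inside, 0 outside, 1/2 at the boundary
  blend <- function(r, rb) 1 / (1 + exp((r - rb) / (s / 4)))
  n_embed +
    blend(r, r_mem) * (cell$n_membrane - n_embed) +
    blend(r, r_cyt) * (cell$n_cytoplasm - cell$n_membrane) +
    blend(r, r_core) * (cell$n_core - cell$n_cytoplasm)
}
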