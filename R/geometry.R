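#' Eustachian-tube simulation geometry
#'
#' Builds the axial two-tube-plus-cavity domain: two cylindrical Eustachian
#' tubes of length `tube_length` and radius `tube_radius` joined by a cubic
#' nasopharynx cavity of side `cavity_side`, with the tube mouths centred on
#' opposing cavity faces. The x axis runs from the ipsilateral source plane
#' (x = 0, reflecting) to the contralateral absorbing plane
#' (x = 2 * tube_length + cavity_side). In `straight_channel` mode the cavity
#' is replaced by a cylinder of the same radius, so the whole domain is one
#' cylinder of the same total length; this variant exists so the stochastic
#' engine can be checked against the 1-D first-passage oracle.
#'
#' All lengths are in millimetres, the unit the anatomy is usually quoted in;
#' the engine converts to SI metres internally.
#'
#' @param mode `"two_tube_cavity"` (default) or `"straight_channel"`.
#' @param tube_length Tube length in mm (default 1.5).
#' @param tube_radius Tube radius in mm (default 0.05).
#' @param cavity_side Cavity side in mm (default 1.0).
#' @return An object of class `etGeometry` with the derived axial landmarks
#'   `x_source = 0`, `x_in`, `x_out` and `x_absorb` (mm).
#' @examples
#' g <- etGeometry()
#' g$x_absorb # 4 mm end-to-end at the defaults
#' @export
etGeometry <- function(mode = c("two_tube_cavity", "straight_channel"),
                       tube_length = 1.5, tube_radius = 0.05,
                       cavity_side = 1.0) {
  mode <- match.arg(mode)
  for (nm in c("tube_length", "tube_radius", "cavity_side")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("geometry field '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (2 * tube_radius > cavity_side)
    stop("geometry field 'tube_radius': tube mouth (diameter ",
         2 * tube_radius, " mm) exceeds the cavity face (side ",
         cavity_side, " mm)", call. = FALSE)
  g <- structure(list(
    mode = mode,
    tube_length = tube_length,
    tube_radius = tube_radius,
    cavity_side = cavity_side,
    x_source = 0,
    x_in = tube_length,
    x_out = tube_length + cavity_side,
    x_absorb = 2 * tube_length + cavity_side
  ), class = "etGeometry")
  g
}

#' @export
print.etGeometry <- function(x, ...) {
  cat("Eustachian-tube geometry (", x$mode, ")\n", sep = "")
  cat(sprintf("  tubes: length %.4g mm, radius %.4g mm\n",
              x$tube_length, x$tube_radius))
  if (x$mode == "two_tube_cavity")
    cat(sprintf("  cavity: cube of side %.4g mm\n", x$cavity_side))
  cat(sprintf("  landmarks (mm): x_in = %.4g, x_out = %.4g, x_absorb = %.4g\n",
              x$x_in, x$x_out, x$x_absorb))
  invisible(x)
}

# numeric vector handed to the compiled kernel, in metres
.geomVec <- function(geometry) {
  mm <- 1e-3
  c(if (geometry$mode == "straight_channel") 0 else 1,
    geometry$tube_radius * mm,
    geometry$x_in * mm,
    geometry$x_out * mm,
    geometry$x_absorb * mm,
    geometry$cavity_side / 2 * mm)
}

.asPointMatrix <- function(point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3)
    point
  } else {
    stopifnot(length(point) == 3)
    matrix(point, ncol = 3)
  }
}

#' Test whether points lie inside the simulation domain
#'
#' The domain is closed: points on the walls and on the absorbing plane
#' count as contained.
#'
#' @param geometry An [etGeometry()] object.
#' @param point A length-3 numeric vector, or an n x 3 matrix of points,
#'   in mm.
#' @return Logical vector, one value per point.
#' @export
geomContains <- function(geometry, point) {
  pts <- .asPointMatrix(point)
  stopifnot(all(is.finite(pts)))
  cpp_region_of(pts * 1e-3, .geomVec(geometry)) != 3L
}

#' Label the region a point falls in
#'
#' Regions are `ipsi_tube`, `cavity`, `contra_tube` or `outside`. Interface
#' planes use a half-open convention: a point exactly on x = x_in or
#' x = x_out belongs to the downstream (+x) region. The absorbing plane
#' itself belongs to `contra_tube`. In `straight_channel` mode the same
#' axial landmarks partition the single cylinder.
#'
#' @inheritParams geomContains
#' @return Character vector of region labels.
#' @export
regionOf <- function(geometry, point) {
  pts <- .asPointMatrix(point)
  stopifnot(all(is.finite(pts)))
  codes <- cpp_region_of(pts * 1e-3, .geomVec(geometry))
  c("ipsi_tube", "cavity", "contra_tube", "outside")[codes + 1L]
}

#' Wall-correct a proposed displacement by specular reflection
#'
#' Given a segment from `from` (inside the domain) to a proposed endpoint
#' `to`, applies specular reflection at each wall crossing (mirroring the
#' remaining displacement across the tangent plane at the hit point), up to
#' `max_reflections` sub-reflections. Reflections off the cylindrical tube
#' walls have purely radial normals and therefore never change the axial
#' coordinate — the property that makes the axial marginal of the confined
#' dynamics an exact 1-D diffusion. If the endpoint still cannot be placed
#' inside the domain the move is rejected and `from` is returned with
#' `rejected = TRUE` (the caller resamples the step). The absorbing plane is
#' not a reflecting surface: a trajectory reaching it is flagged `absorbed`
#' with the crossing point returned.
#'
#' @param geometry An [etGeometry()] object.
#' @param from,to Length-3 numeric vectors in mm; `from` must be inside.
#' @param max_reflections Bound on sub-reflections before rejection
#'   (default 8).
#' @return List with `endpoint` (mm), `n_reflections`, `absorbed`,
#'   `rejected`.
#' @examples
#' g <- etGeometry()
#' reflectSegment(g, c(1.0, 0, 0.02), c(1.1, 0, 0.08))$endpoint
#' @export
reflectSegment <- function(geometry, from, to, max_reflections = 8L) {
  stopifnot(length(from) == 3, length(to) == 3,
            all(is.finite(from)), all(is.finite(to)))
  if (!geomContains(geometry, from))
    stop("reflectSegment: 'from' lies outside the domain", call. = FALSE)
  res <- cpp_advance_segment(from * 1e-3, to * 1e-3, .geomVec(geometry),
                             as.integer(max_reflections))
  list(endpoint = as.numeric(res$endpoint) * 1e3,
       n_reflections = res$n_reflections,
       absorbed = res$status == 1L,
       rejected = res$status == 2L)
}
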