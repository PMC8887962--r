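#' @include probe.R
NULL

#' Translate a probe
#'
#' Shifts all contact positions and contour vertices by a fixed vector.
#' Shapes, plane axes, identifiers and wiring are unchanged; as a rigid
#' motion, all pairwise contact distances are preserved.
#'
#' @param x a [Probe].
#' @param translation numeric vector with `ndim` components, in
#'   `siUnits(x)`.
#' @return the translated [Probe].
#' @examples
#' p <- generateTetrode(radius = 10)
#' q <- moveProbe(p, c(600, 0))
#' @export
setMethod("moveProbe", "Probe", function(x, translation) {
  translation <- as.numeric(translation)
  if (length(translation) != x@ndim || any(!is.finite(translation))) {
    .stopValidation("translation must have %d finite components", x@ndim)
  }
  x@positions <- sweep(x@positions, 2L, translation, "+")
  if (nrow(x@contour)) {
    x@contour <- sweep(x@contour, 2L, translation, "+")
  }
  x
})

.rotationMatrix2d <- function(angleDeg) {
  th <- angleDeg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Rodrigues rotation about a unit axis
.rotationMatrix3d <- function(angleDeg, axis) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotate a probe
#'
#' Rigidly rotates contact positions, the contour, and the contact plane axes.
#' The angle is in **degrees**. 2-d probes rotate in the plane; 3-d probes
#' rotate about `axis`. The default rotation center is the centroid of the
#' contacts.
#'
#' @param x a [Probe].
#' @param angle rotation angle in degrees (counter-clockwise in 2-d).
#' @param center optional rotation center (`ndim` components); default is the
#'   contact centroid.
#' @param axis 3-vector rotation axis, required for 3-d probes and rejected
#'   for 2-d probes.
#' @return the rotated [Probe].
#' @examples
#' p <- generateMultiColumnsProbe(numColumns = 2, contactsPerColumn = 8)
#' q <- rotateProbe(p, 45)
#' @export
setMethod("rotateProbe", "Probe", function(x, angle, center = NULL, axis = NULL) {
  ndim <- x@ndim
  if (ndim == 2L) {
    if (!is.null(axis)) {
      .stopValidation("a rotation axis only applies to 3-d probes")
    }
    R <- .rotationMatrix2d(angle)
  } else {
    if (is.null(axis)) {
      .stopValidation("3-d probes require a rotation axis")
    }
    axis <- as.numeric(axis)
    if (length(axis) != 3L || sum(axis^2) == 0) {
      .stopValidation("axis must be a non-zero 3-vector")
    }
    R <- .rotationMatrix3d(angle, axis)
  }
  if (is.null(center)) {
    center <- if (nrow(x@positions)) colMeans(x@positions) else rep(0, ndim)
  }
  center <- as.numeric(center)
  if (length(center) != ndim) {
    .stopValidation("center must have %d components", ndim)
  }
  rot <- function(m) {
    sweep(sweep(m, 2L, center, "-") %*% t(R), 2L, center, "+")
  }
  x@positions <- rot(x@positions)
  if (nrow(x@contour)) x@contour <- rot(x@contour)
  n <- numContacts(x)
  if (n > 0) {
    for (j in 1:2) {
      v <- matrix(x@planeAxes[, j, ], ncol = ndim)
      x@planeAxes[, j, ] <- v %*% t(R)
    }
  }
  x
})

.PLANES <- list(xy = c(1L, 2L), yz = c(2L, 3L), xz = c(1L, 3L))

.planeCols <- function(plane) {
  cols <- .PLANES[[plane]]
  if (is.null(cols)) {
    .stopValidation("plane must be one of %s", paste(names(.PLANES), collapse = ", "))
  }
  cols
}

#' Lift a planar probe into 3-d
#'
#' Embeds a 2-d probe into 3-d space: the two stored coordinates are written
#' into the axes named by `plane` (e.g. `"xy"`) and the remaining coordinate
#' is 0 for every position, contour vertex and plane-axis vector. All
#' metadata (ids, shanks, wiring, annotations) is preserved.
#'
#' @param probe a 2-d [Probe].
#' @param plane which two axes receive the planar coordinates: `"xy"`,
#'   `"yz"` or `"xz"`.
#' @return a 3-d [Probe].
#' @export
setMethod("to3d", "Probe", function(probe, plane = "xy") {
  if (probe@ndim != 2L) {
    .stopValidation("to3d() requires a 2-d probe")
  }
  cols <- .planeCols(plane)
  n <- numContacts(probe)
  lift <- function(m) {
    out <- matrix(0, nrow(m), 3)
    out[, cols] <- m
    out
  }
  probe@ndim <- 3L
  probe@positions <- lift(probe@positions)
  probe@contour <- lift(probe@contour)
  ax <- array(0, c(n, 2L, 3L))
  if (n > 0) ax[, , cols] <- probe@planeAxes
  probe@planeAxes <- ax
  validObject(probe)
  probe
})

#' Project a 3-d probe onto a plane
#'
#' Inverse of [to3d()] for probes lying in a coordinate plane: keeps the two
#' coordinates named by `plane` and drops the third. Plane axes are projected
#' likewise, so the probe is only geometrically meaningful if its contacts lie
#' (up to a constant offset) in that plane.
#'
#' @param probe a 3-d [Probe].
#' @param plane which two axes to keep: `"xy"`, `"yz"` or `"xz"`.
#' @return a 2-d [Probe].
#' @export
setMethod("to2d", "Probe", function(probe, plane = "xy") {
  if (probe@ndim != 3L) {
    .stopValidation("to2d() requires a 3-d probe")
  }
  cols <- .planeCols(plane)
  n <- numContacts(probe)
  probe@ndim <- 2L
  probe@positions <- probe@positions[, cols, drop = FALSE]
  probe@contour <- probe@contour[, cols, drop = FALSE]
  ax <- array(0, c(n, 2L, 2L))
  if (n > 0) ax[, , ] <- probe@planeAxes[, , cols, drop = FALSE]
  probe@planeAxes <- ax
  validObject(probe)
  probe
})
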