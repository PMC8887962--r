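#' @include utils.R
NULL

#' Create an empty probe
#'
#' Returns a [Probe] with no contacts; add geometry with [setContacts()] or
#' use one of the layout generators ([generateMultiColumnsProbe()],
#' [generateMultiShankProbe()], [generateTetrode()]).
#'
#' @param ndim number of spatial dimensions, 2 or 3. Planar silicon probes are
#'   2-dimensional; 3 is for devices with out-of-plane geometry.
#' @param siUnits length unit used by every coordinate and shape parameter of
#'   the probe. One of `"um"`, `"mm"`, `"cm"`, `"m"`, `"inch"`.
#' @return an empty [Probe].
#' @examples
#' p <- createProbe()
#' numContacts(p)
#' @export
createProbe <- function(ndim = 2, siUnits = "um") {
  if (length(ndim) != 1L || is.na(suppressWarnings(as.integer(ndim))) ||
      as.numeric(ndim) != as.integer(ndim) || !as.integer(ndim) %in% c(2L, 3L)) {
    .stopValidation("ndim must be 2 or 3, got %s", paste(ndim, collapse = ","))
  }
  if (length(siUnits) != 1L || !siUnits %in% .LENGTH_UNITS) {
    .stopValidation(
      "unknown length unit '%s' (recognized: %s)",
      as.character(siUnits)[1], paste(.LENGTH_UNITS, collapse = ", ")
    )
  }
  ndim <- as.integer(ndim)
  new("Probe",
    ndim = ndim,
    siUnits = siUnits,
    positions = matrix(numeric(0), 0, ndim),
    planeAxes = array(numeric(0), c(0, 2, ndim)),
    contour = matrix(numeric(0), 0, ndim)
  )
}

.broadcastShapes <- function(shapes, n) {
  if (length(shapes) == 1L && n != 1L) shapes <- rep(shapes, n)
  if (length(shapes) != n) {
    .stopValidation(
      "contact shapes must be a single kind or one per contact (n = %d), got %d",
      n, length(shapes)
    )
  }
  bad <- setdiff(unique(shapes), .SHAPE_KINDS)
  if (length(bad)) {
    .stopValidation(
      "unknown contact shape '%s' (must be one of %s)",
      bad[1], paste(.SHAPE_KINDS, collapse = ", ")
    )
  }
  as.character(shapes)
}

.broadcastShapeParams <- function(shapeParams, n) {
  # a bare named list is one parameter record; a list of lists is per-contact
  if (is.list(shapeParams) && length(shapeParams) &&
      all(vapply(shapeParams, is.list, logical(1)))) {
    records <- shapeParams
  } else {
    records <- list(shapeParams)
  }
  if (length(records) == 1L && n != 1L) records <- rep(records, n)
  if (length(records) != n) {
    .stopValidation(
      "shape parameters must be one record or one per contact (n = %d), got %d",
      n, length(records)
    )
  }
  lapply(records, function(r) lapply(r, as.numeric))
}

#' Set the contact layout of a probe
#'
#' Stores positions, shapes, shape parameters and (optionally) per-contact
#' plane axes on a probe, replacing any previous contacts. `shapes` and
#' `shapeParams` may be given once and are then broadcast to every contact;
#' internally the probe always stores one entry per contact, so a broadcast
#' scalar and the explicitly repeated list produce identical probes.
#'
#' Defaults assigned when not supplied: plane axes `([1,0],[0,1])` (contacts
#' lying un-rotated in the probe plane; the `x`/`y` unit vectors padded with a
#' zero `z` component for 3-d probes), contact ids `"0" .. "n-1"` in storage
#' order, and a single shank `"0"`.
#'
#' @param probe a [Probe].
#' @param positions numeric `n x ndim` matrix of contact centers, in
#'   `siUnits(probe)`.
#' @param shapes shape kind (`"circle"`, `"square"`, `"rect"`) or a vector of
#'   length `n`.
#' @param shapeParams a named list (e.g. `list(radius = 5)`) or a list of `n`
#'   such records; `circle` takes `radius`, `square` takes `width`, `rect`
#'   takes `width` and `height`, all in `siUnits(probe)`.
#' @param planeAxes optional `n x 2 x ndim` array of orthonormal in-plane axis
#'   pairs, orienting square/rect contacts.
#' @return the updated [Probe].
#' @examples
#' p <- createProbe()
#' p <- setContacts(p, cbind(0, seq(0, 310, by = 10)),
#'                  shapes = "circle", shapeParams = list(radius = 5))
#' numContacts(p)
#' @export
setMethod("setContacts", "Probe",
  function(probe, positions, shapes = "circle",
           shapeParams = list(radius = 5), planeAxes = NULL) {
    ndim <- probe@ndim
    positions <- .asMatrix(positions, ndim, "positions")
    n <- nrow(positions)
    shapes <- .broadcastShapes(shapes, n)
    shapeParams <- .broadcastShapeParams(shapeParams, n)
    if (is.null(planeAxes)) {
      planeAxes <- .defaultPlaneAxes(n, ndim)
    } else {
      planeAxes <- array(as.numeric(planeAxes), dim(planeAxes))
      if (length(dim(planeAxes)) != 3L || !all(dim(planeAxes) == c(n, 2L, ndim))) {
        .stopValidation("planeAxes must be an array of dim (%d, 2, %d)", n, ndim)
      }
    }
    probe@positions <- positions
    probe@shapes <- shapes
    probe@shapeParams <- shapeParams
    probe@planeAxes <- planeAxes
    probe@contactIds <- as.character(seq_len(n) - 1L)
    probe@shankIds <- rep("0", n)
    probe@deviceChannelIndices <- integer(0)
    validObject(probe)
    probe
  }
)

#' @describeIn Probe number of contacts on the probe.
#' @param x a `Probe`.
#' @export
setMethod("numContacts", "Probe", function(x) nrow(x@positions))

#' @describeIn Probe number of spatial dimensions (2 or 3).
#' @export
setMethod("probeNdim", "Probe", function(x) x@ndim)

#' @describeIn Probe length unit of all coordinates.
#' @export
setMethod("siUnits", "Probe", function(x) x@siUnits)

#' @describeIn Probe `n x ndim` matrix of contact centers.
#' @export
setMethod("contactPositions", "Probe", function(x) x@positions)

#' @describeIn Probe per-contact shape kinds.
#' @export
setMethod("contactShapes", "Probe", function(x) x@shapes)

#' @describeIn Probe per-contact shape parameter records.
#' @export
setMethod("contactShapeParams", "Probe", function(x) x@shapeParams)

#' @describeIn Probe `n x 2 x ndim` array of in-plane axis pairs.
#' @export
setMethod("contactPlaneAxes", "Probe", function(x) x@planeAxes)

#' @describeIn Probe probe-intrinsic contact identifiers.
#' @export
setMethod("contactIds", "Probe", function(x) x@contactIds)

#' @describeIn Probe set the contact identifiers.
#' @param value replacement value.
#' @export
setMethod("contactIds<-", "Probe", function(x, value) {
  if (length(value) != numContacts(x)) {
    .stopValidation("need one contact id per contact")
  }
  x@contactIds <- as.character(value)
  validObject(x)
  x
})

#' @describeIn Probe per-contact shank identifiers.
#' @export
setMethod("shankIds", "Probe", function(x) x@shankIds)

#' @describeIn Probe assign contacts to shanks.
#' @export
setMethod("shankIds<-", "Probe", function(x, value) {
  if (length(value) != numContacts(x)) {
    .stopValidation("need one shank id per contact")
  }
  x@shankIds <- as.character(value)
  validObject(x)
  x
})

#' @describeIn Probe device channel index per contact (`-1` = unconnected);
#'   `integer(0)` while the probe is not wired.
#' @export
setMethod("deviceChannelIndices", "Probe", function(x) x@deviceChannelIndices)

#' @describeIn Probe outline polygon vertices (0-row matrix if absent).
#' @export
setMethod("probeContour", "Probe", function(x) x@contour)

#' @describeIn Probe set the outline polygon.
#' @export
setMethod("probeContour<-", "Probe", function(x, value) {
  x@contour <- .asMatrix(value, x@ndim, "contour")
  validObject(x)
  x
})

#' @describeIn Probe free-form probe annotations (name, manufacturer, ...).
#' @export
setMethod("annotations", "Probe", function(x) x@annotations)

#' @describeIn Probe replace the annotations list.
#' @export
setMethod("annotations<-", "Probe", function(x, value) {
  stopifnot(is.list(value))
  x@annotations <- value
  x
})

#' @describeIn Probe per-contact annotation vectors (material, impedance, ...).
#' @export
setMethod("contactAnnotations", "Probe", function(x) x@contactAnnotations)

#' @describeIn Probe replace the per-contact annotations.
#' @export
setMethod("contactAnnotations<-", "Probe", function(x, value) {
  stopifnot(is.list(value))
  x@contactAnnotations <- value
  validObject(x)
  x
})

#' Annotate a probe
#'
#' Convenience wrapper merging `key = value` pairs into [annotations()].
#'
#' @param probe a [Probe].
#' @param ... named values to merge into the annotations.
#' @return the annotated [Probe].
#' @export
annotateProbe <- function(probe, ...) {
  ann <- list(...)
  stopifnot(length(ann) == 0 || !is.null(names(ann)))
  probe@annotations[names(ann)] <- ann
  probe
}

setMethod("show", "Probe", function(object) {
  n <- numContacts(object)
  nm <- object@annotations[["name"]]
  cat(sprintf(
    "Probe%s - %d contacts, %d shank(s), %dd, unit %s\n",
    if (is.null(nm)) "" else sprintf(" '%s'", nm),
    n, length(unique(object@shankIds)), object@ndim, object@siUnits
  ))
  if (length(object@deviceChannelIndices)) {
    nc <- sum(object@deviceChannelIndices >= 0L)
    cat(sprintf("  wired: %d/%d contacts connected to device channels\n", nc, n))
  }
  if (n > 0) {
    kinds <- table(object@shapes)
    cat(sprintf("  shapes: %s\n",
                paste(sprintf("%s x%d", names(kinds), kinds), collapse = ", ")))
  }
  invisible(object)
})
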