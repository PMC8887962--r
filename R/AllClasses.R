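#' @include AllGenerics.R
NULL

.SHAPE_KINDS <- c("circle", "square", "rect")

.SHAPE_REQUIRED_PARAMS <- list(
  circle = "radius",
  square = "width",
  rect   = c("width", "height")
)

.LENGTH_UNITS <- c("um", "mm", "cm", "m", "inch")

.AXIS_TOL <- 1e-9

#' Probe: one physical extracellular probe
#'
#' A `Probe` holds the per-contact geometry of a single physical device: the
#' contact positions (in `siUnits`), the contact shapes and their size
#' parameters, per-contact in-plane orientation axes, probe-intrinsic contact
#' identifiers, shank membership, the optional planar outline of the silicon,
#' and -- once the probe has been wired to an acquisition device -- the device
#' channel index of every contact (`-1` marking unconnected contacts).
#'
#' All per-contact slots have one entry per contact; the validity method
#' enforces equal lengths, `ndim` consistency of every coordinate, exact shape
#' parameter sets (`circle` needs `radius`, `square` needs `width`, `rect`
#' needs `width` and `height`, all positive), orthonormal plane-axis pairs
#' (within 1e-9), and pairwise-distinct non-negative device channel indices.
#'
#' @slot ndim integer, 2 or 3 spatial dimensions.
#' @slot siUnits length unit for all coordinates (e.g. `"um"`).
#' @slot positions numeric matrix, one row per contact, `ndim` columns.
#' @slot shapes character vector of shape kinds (`circle`, `square`, `rect`).
#' @slot shapeParams list of per-contact named parameter lists.
#' @slot planeAxes numeric array `n x 2 x ndim`; rows `[i, 1, ]` and
#'   `[i, 2, ]` span the plane of contact `i`.
#' @slot contactIds character, probe-intrinsic channel names.
#' @slot shankIds character, partitioning contacts into shanks.
#' @slot deviceChannelIndices integer of length `n` once wired (`-1` =
#'   unconnected), or length 0 while the probe is not wired.
#' @slot contour numeric matrix of outline vertices (0 rows = no contour).
#' @slot annotations free-form named list (name, manufacturer, ...).
#' @slot contactAnnotations named list of per-contact vectors (material,
#'   impedance, ...), each of length `n`.
#'
#' @seealso [createProbe()], [setContacts()], [generateMultiShankProbe()]
#' @export
setClass("Probe",
  slots = c(
    ndim = "integer",
    siUnits = "character",
    positions = "matrix",
    shapes = "character",
    shapeParams = "list",
    planeAxes = "array",
    contactIds = "character",
    shankIds = "character",
    deviceChannelIndices = "integer",
    contour = "matrix",
    annotations = "list",
    contactAnnotations = "list"
  ),
  prototype = list(
    ndim = 2L,
    siUnits = "um",
    positions = matrix(numeric(0), 0, 2),
    shapes = character(0),
    shapeParams = list(),
    planeAxes = array(numeric(0), c(0, 2, 2)),
    contactIds = character(0),
    shankIds = character(0),
    deviceChannelIndices = integer(0),
    contour = matrix(numeric(0), 0, 2),
    annotations = list(),
    contactAnnotations = list()
  )
)

.validShapeParams <- function(kind, params) {
  required <- .SHAPE_REQUIRED_PARAMS[[kind]]
  if (is.null(required)) {
    return(sprintf("unknown contact shape '%s'", kind))
  }
  if (!is.list(params)) {
    return("shape parameters must be a named list")
  }
  keys <- names(params)
  if (!setequal(keys, required) || length(keys) != length(required)) {
    return(sprintf(
      "shape '%s' requires exactly parameter(s) {%s}, got {%s}",
      kind, paste(required, collapse = ", "), paste(keys, collapse = ", ")
    ))
  }
  vals <- unlist(params, use.names = FALSE)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    return(sprintf("shape '%s' parameters must be positive numbers", kind))
  }
  NULL
}

.validProbe <- function(object) {
  errs <- character(0)
  ndim <- object@ndim
  if (length(ndim) != 1L || !ndim %in% c(2L, 3L)) {
    return("ndim must be 2 or 3")
  }
  if (length(object@siUnits) != 1L || !object@siUnits %in% .LENGTH_UNITS) {
    errs <- c(errs, sprintf(
      "siUnits must be one of %s", paste(.LENGTH_UNITS, collapse = ", ")
    ))
  }
  n <- nrow(object@positions)
  if (ncol(object@positions) != ndim) {
    errs <- c(errs, sprintf("positions must have %d columns", ndim))
  }
  if (any(!is.finite(object@positions))) {
    errs <- c(errs, "positions must be finite")
  }
  for (what in c("shapes", "shapeParams", "contactIds", "shankIds")) {
    if (length(slot(object, what)) != n) {
      errs <- c(errs, sprintf("%s must have one entry per contact (n = %d)", what, n))
    }
  }
  pa <- object@planeAxes
  if (length(dim(pa)) != 3L || !all(dim(pa) == c(n, 2L, ndim))) {
    errs <- c(errs, sprintf("planeAxes must be an array of dim (%d, 2, %d)", n, ndim))
  } else if (n > 0) {
    for (i in seq_len(n)) {
      a <- pa[i, 1, ]
      b <- pa[i, 2, ]
      if (abs(sqrt(sum(a^2)) - 1) > .AXIS_TOL || abs(sqrt(sum(b^2)) - 1) > .AXIS_TOL) {
        errs <- c(errs, sprintf("plane axes of contact %d are not unit vectors", i))
        break
      }
      if (abs(sum(a * b)) > .AXIS_TOL) {
        errs <- c(errs, sprintf("plane axes of contact %d are not orthogonal", i))
        break
      }
    }
  }
  if (length(object@shapes) == n && length(object@shapeParams) == n) {
    for (i in seq_len(n)) {
      msg <- .validShapeParams(object@shapes[i], object@shapeParams[[i]])
      if (!is.null(msg)) {
        errs <- c(errs, sprintf("contact %d: %s", i, msg))
        break
      }
    }
  }
  dci <- object@deviceChannelIndices
  if (!length(dci) %in% c(0L, n)) {
    errs <- c(errs, "deviceChannelIndices must be empty or have one entry per contact")
  } else if (length(dci)) {
    if (any(is.na(dci)) || any(dci < -1L)) {
      errs <- c(errs, "device channel indices must be >= -1")
    } else {
      conn <- dci[dci >= 0L]
      if (anyDuplicated(conn)) {
        errs <- c(errs, "non-negative device channel indices must be distinct")
      }
    }
  }
  if (nrow(object@contour) > 0 && ncol(object@contour) != ndim) {
    errs <- c(errs, sprintf("contour vertices must have %d coordinates", ndim))
  }
  ca <- object@contactAnnotations
  if (length(ca)) {
    if (is.null(names(ca)) || any(names(ca) == "")) {
      errs <- c(errs, "contactAnnotations must be a named list")
    } else if (any(lengths(ca) != n)) {
      errs <- c(errs, "each contactAnnotations entry must have one value per contact")
    }
  }
  if (length(errs)) errs else TRUE
}

setValidity("Probe", .validProbe)

#' Shank: the contacts of one probe prong
#'
#' A `Shank` is a lightweight view of a parent [Probe] restricted to the
#' contacts carrying one `shank_id`. `contactIndices` are 1-based row indices
#' into the parent's per-contact arrays; across all shanks of a probe they
#' partition `1..n`.
#'
#' @slot shankId the shank identifier shared by all member contacts.
#' @slot probe the parent [Probe].
#' @slot contactIndices integer row indices into the parent's arrays.
#' @seealso [getShanks()]
#' @export
setClass("Shank",
  slots = c(
    shankId = "character",
    probe = "Probe",
    contactIndices = "integer"
  )
)

setValidity("Shank", function(object) {
  n <- nrow(object@probe@positions)
  idx <- object@contactIndices
  if (any(idx < 1L) || any(idx > n)) {
    return("contactIndices out of range for the parent probe")
  }
  if (!all(object@probe@shankIds[idx] == object@shankId)) {
    return("contactIndices reference contacts of a different shank")
  }
  TRUE
})

#' ProbeGroup: probes sharing one acquisition device
#'
#' Ordered collection of [Probe] objects recorded with the same acquisition
#' device. All members must share `ndim` and `siUnits`, and the non-negative
#' device channel indices must be distinct across the whole group (two
#' contacts cannot feed the same recorded trace).
#'
#' @slot probes list of [Probe] objects.
#' @seealso [probeGroup()], [addProbe()], [setGlobalDeviceChannelIndices()]
#' @export
setClass("ProbeGroup", slots = c(probes = "list"))

setValidity("ProbeGroup", function(object) {
  ps <- object@probes
  if (!all(vapply(ps, is, logical(1), class2 = "Probe"))) {
    return("probes must be a list of Probe objects")
  }
  if (length(ps) > 1) {
    nd <- vapply(ps, function(p) p@ndim, integer(1))
    un <- vapply(ps, function(p) p@siUnits, character(1))
    if (length(unique(nd)) != 1L) return("all probes in a group must share ndim")
    if (length(unique(un)) != 1L) return("all probes in a group must share siUnits")
  }
  dev <- unlist(lapply(ps, function(p) p@deviceChannelIndices))
  dev <- dev[!is.na(dev) & dev >= 0L]
  if (anyDuplicated(dev)) {
    return("device channel indices must be distinct across the probe group")
  }
  TRUE
})

#' StageTable: one stage of a wiring pathway
#'
#' A `StageTable` describes how one piece of hardware between the probe and
#' the acquisition system (a connector, adapter or headstage such as the Intan
#' RHD2164) reorders channels. `mapping` is a 0-based table of length `m`:
#' entry `i + 1` gives the output channel that receives input channel `i`,
#' with `-1` meaning the input is not connected. Non-negative entries must be
#' pairwise distinct and `< m`.
#'
#' @slot name stage name (e.g. `"RHD2164"`).
#' @slot mapping integer vector, 0-based output channel per input channel.
#' @seealso [stageTable()], [composeStages()]
#' @export
setClass("StageTable", slots = c(name = "character", mapping = "integer"))

setValidity("StageTable", function(object) {
  m <- length(object@mapping)
  v <- object@mapping
  if (any(is.na(v))) return("mapping must not contain NA")
  if (any(v < -1L)) return("mapping entries must be >= -1")
  if (any(v >= m)) return(sprintf("mapping entries must be < %d", m))
  if (anyDuplicated(v[v >= 0L])) {
    return("non-negative mapping entries must be pairwise distinct")
  }
  TRUE
})

#' Pathway: a named chain of wiring stages
#'
#' A `Pathway` names the full signal route from the probe connector to the
#' acquisition device (e.g. `"ASSY-156>RHD2164"`) as an ordered list of
#' [StageTable] stages. The composition of the stages is itself a valid stage
#' table and is what [wireProbe()] applies to a probe.
#'
#' @slot name pathway name, conventionally `"<connector>><headstage>"`.
#' @slot stages list of [StageTable] objects of equal size.
#' @seealso [wireProbe()], [listPathways()]
#' @export
setClass("Pathway", slots = c(name = "character", stages = "list"))

setValidity("Pathway", function(object) {
  st <- object@stages
  if (length(st) < 1L) return("a pathway needs at least one stage")
  if (!all(vapply(st, is, logical(1), class2 = "StageTable"))) {
    return("stages must be a list of StageTable objects")
  }
  sizes <- vapply(st, function(s) length(s@mapping), integer(1))
  if (length(unique(sizes)) != 1L) {
    return("consecutive stages must have compatible (equal) sizes")
  }
  TRUE
})
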