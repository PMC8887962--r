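#' @include probegroup.R
NULL

.SPEC_VERSION <- "0.2"

.REQUIRED_PROBE_FIELDS <- c("ndim", "si_units", "annotations",
                            "contact_positions", "contact_shapes",
                            "contact_shape_params")

.rowsToList <- function(m) {
  lapply(seq_len(nrow(m)), function(i) m[i, ])
}

.probeToRecord <- function(p) {
  n <- numContacts(p)
  rec <- list(ndim = p@ndim, si_units = p@siUnits)
  rec$annotations <- if (length(p@annotations)) {
    p@annotations
  } else {
    structure(list(), names = character(0))
  }
  if (length(p@contactAnnotations)) {
    rec$contact_annotations <- p@contactAnnotations
  }
  rec$contact_positions <- .rowsToList(p@positions)
  rec$contact_plane_axes <- lapply(seq_len(n), function(i) {
    list(p@planeAxes[i, 1, ], p@planeAxes[i, 2, ])
  })
  rec$contact_shapes <- p@shapes
  rec$contact_shape_params <- p@shapeParams
  rec$contact_ids <- p@contactIds
  if (nrow(p@contour)) {
    rec$probe_planar_contour <- .rowsToList(p@contour)
  }
  if (length(p@deviceChannelIndices)) {
    rec$device_channel_indices <- p@deviceChannelIndices
  }
  rec$shank_ids <- p@shankIds
  rec
}

.groupToDocument <- function(group) {
  list(
    specifications_version = .SPEC_VERSION,
    probes = lapply(group@probes, .probeToRecord)
  )
}

.writeProbeInterfaceDoc <- function(doc, path) {
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 4,
                           always_decimal = TRUE, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con = con, useBytes = TRUE)
  invisible(path)
}

#' Write probes to a probe-description JSON file
#'
#' Serializes a probe or probe group to the community JSON probe format: a
#' document with a `specifications_version` string and a `probes` list, each
#' probe record carrying the required fields (`ndim`, `si_units`,
#' `annotations`, `contact_positions`, `contact_shapes`,
#' `contact_shape_params`) plus the optional ones present on the object
#' (`contact_plane_axes`, `contact_ids`, `probe_planar_contour`,
#' `device_channel_indices`, `shank_ids`, `contact_annotations`). Key order
#' is fixed and reals are written at full precision, so writing is
#' deterministic: write -> read -> write reproduces the file byte for byte.
#'
#' @param x a [Probe] or [ProbeGroup].
#' @param path destination file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @seealso [readProbeInterface()]
#' @examples
#' g <- probeGroup(generateTetrode())
#' f <- tempfile(fileext = ".json")
#' writeProbeInterface(g, f)
#' @export
setMethod("writeProbeInterface", "ProbeGroup", function(x, path) {
  validObject(x)
  .writeProbeInterfaceDoc(.groupToDocument(x), path)
})

#' @rdname writeProbeInterface-ProbeGroup-method
#' @export
setMethod("writeProbeInterface", "Probe", function(x, path) {
  writeProbeInterface(probeGroup(list(x)), path)
})

.fieldError <- function(field, i, fmt, ...) {
  .stopValidation("probe %d, field '%s': %s", i, field, sprintf(fmt, ...))
}

.parsePositions <- function(x, ndim, field, i) {
  if (length(x) == 0) {
    return(matrix(numeric(0), 0, ndim))
  }
  rows <- lapply(x, function(r) unlist(r, use.names = FALSE))
  if (any(lengths(rows) != ndim)) {
    .fieldError(field, i, "every point needs %d coordinates", ndim)
  }
  m <- do.call(rbind, rows)
  storage.mode(m) <- "double"
  m
}

.parseScalarOrList <- function(x, n) {
  if (is.list(x)) unlist(x, use.names = FALSE) else x
}

.recordToProbe <- function(rec, i) {
  for (f in .REQUIRED_PROBE_FIELDS) {
    if (is.null(rec[[f]])) {
      .stopValidation("probe %d: missing required field '%s'", i, f)
    }
  }
  probe <- tryCatch(createProbe(rec$ndim, rec$si_units),
                    error = function(e) {
                      .stopValidation("probe %d: %s", i, conditionMessage(e))
                    })
  ndim <- probe@ndim
  pos <- .parsePositions(rec$contact_positions, ndim, "contact_positions", i)
  n <- nrow(pos)

  shapes <- .parseScalarOrList(rec$contact_shapes, n)
  if (!length(shapes) %in% c(1L, n) && !(n == 0 && length(shapes) == 0)) {
    .fieldError("contact_shapes", i, "expected 1 or %d entries, got %d",
                n, length(shapes))
  }

  sp <- rec$contact_shape_params
  singleRecord <- is.list(sp) && !is.null(names(sp)) && all(nzchar(names(sp)))
  if (!singleRecord && !length(sp) %in% c(if (n == 0) 0L else c(1L, n))) {
    .fieldError("contact_shape_params", i, "expected 1 or %d records, got %d",
                n, length(sp))
  }

  probe <- tryCatch(
    setContacts(probe, pos, shapes, sp),
    error = function(e) .stopValidation("probe %d: %s", i, conditionMessage(e))
  )

  if (!is.null(rec$contact_plane_axes)) {
    pa <- rec$contact_plane_axes
    if (length(pa) != n) {
      .fieldError("contact_plane_axes", i, "expected %d axis pairs, got %d",
                  n, length(pa))
    }
    ax <- array(0, c(n, 2L, ndim))
    for (k in seq_len(n)) {
      pair <- pa[[k]]
      if (length(pair) != 2L) {
        .fieldError("contact_plane_axes", i, "entry %d is not an axis pair", k)
      }
      ax[k, 1, ] <- unlist(pair[[1]], use.names = FALSE)
      ax[k, 2, ] <- unlist(pair[[2]], use.names = FALSE)
    }
    probe@planeAxes <- ax
  }
  if (!is.null(rec$contact_ids)) {
    ids <- as.character(.parseScalarOrList(rec$contact_ids, n))
    if (length(ids) == 1L && n != 1L) ids <- rep(ids, n)
    contactIds(probe) <- ids
  }
  if (!is.null(rec$shank_ids)) {
    sid <- as.character(.parseScalarOrList(rec$shank_ids, n))
    if (length(sid) == 1L && n != 1L) sid <- rep(sid, n)
    shankIds(probe) <- sid
  }
  if (!is.null(rec$probe_planar_contour)) {
    probeContour(probe) <- .parsePositions(rec$probe_planar_contour, ndim,
                                           "probe_planar_contour", i)
  }
  if (!is.null(rec$device_channel_indices)) {
    dci <- .parseScalarOrList(rec$device_channel_indices, n)
    if (length(dci) != n) {
      .fieldError("device_channel_indices", i, "expected %d entries, got %d",
                  n, length(dci))
    }
    probe <- setDeviceChannelIndices(probe, dci)
  }
  if (!is.null(rec$annotations) && length(rec$annotations)) {
    probe@annotations <- rec$annotations
  }
  if (!is.null(rec$contact_annotations) && length(rec$contact_annotations)) {
    probe@contactAnnotations <- lapply(rec$contact_annotations, function(v) {
      unlist(v, use.names = FALSE)
    })
  }
  probe <- tryCatch({
    validObject(probe)
    probe
  }, error = function(e) .stopValidation("probe %d: %s", i, conditionMessage(e)))
  probe
}

#' Read a probe-description JSON file
#'
#' Parses the community JSON probe format into a [ProbeGroup]. Scalar
#' `contact_shapes` / `contact_shape_params` are broadcast to every contact;
#' absent optional fields fall back to the model defaults (un-rotated plane
#' axes, contact ids `"0".."n-1"`, a single shank, no contour, unwired).
#' Unknown optional keys are tolerated for forward compatibility. Missing
#' required fields, unknown shape kinds and shape/parameter mismatches are
#' rejected with errors naming the offending field.
#'
#' @param path path to a probe-description JSON file.
#' @return a [ProbeGroup].
#' @seealso [writeProbeInterface()]
#' @export
readProbeInterface <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc$probes)) {
    .stopValidation("'%s' is not a probe description (missing 'probes' list)",
                    path)
  }
  ps <- lapply(seq_along(doc$probes), function(i) {
    .recordToProbe(doc$probes[[i]], i)
  })
  probeGroup(ps)
}
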