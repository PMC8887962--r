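#' @include viz.R
NULL

.polygonsToFrame <- function(geo, probeIdx) {
  frames <- lapply(seq_along(geo$contacts), function(i) {
    v <- geo$contacts[[i]]
    data.frame(x = v[, 1], y = v[, 2],
               grp = sprintf("p%d_c%d", probeIdx, i))
  })
  do.call(rbind, c(frames, list(data.frame(x = numeric(0), y = numeric(0),
                                           grp = character(0)))))
}

.contourToFrame <- function(geo, probeIdx) {
  if (is.null(geo$contour)) {
    return(data.frame(x = numeric(0), y = numeric(0), grp = character(0)))
  }
  data.frame(x = geo$contour[, 1], y = geo$contour[, 2],
             grp = sprintf("p%d_contour", probeIdx))
}

.plotGeometries <- function(geos, siUnit, showLabels, contactColor) {
  contacts <- do.call(rbind, lapply(seq_along(geos), function(k) {
    .polygonsToFrame(geos[[k]], k)
  }))
  contours <- do.call(rbind, lapply(seq_along(geos), function(k) {
    .contourToFrame(geos[[k]], k)
  }))
  labels <- do.call(rbind, lapply(geos, function(g) g$labels))
  gp <- ggplot2::ggplot()
  if (nrow(contours)) {
    gp <- gp + ggplot2::geom_polygon(
      data = contours, ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp),
      fill = "grey95", colour = "grey40", linewidth = 0.4
    )
  }
  if (nrow(contacts)) {
    gp <- gp + ggplot2::geom_polygon(
      data = contacts, ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp),
      fill = contactColor, colour = "grey20", linewidth = 0.2
    )
  }
  if (showLabels && nrow(labels)) {
    labels$text <- ifelse(is.na(labels$deviceText),
                          paste0("id", labels$contactId),
                          paste0("id", labels$contactId, "\n", labels$deviceText))
    gp <- gp + ggplot2::geom_text(
      data = labels, ggplot2::aes(x = .data$x, y = .data$y, label = .data$text),
      size = 2
    )
  }
  gp +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("x (%s)", siUnit), y = sprintf("y (%s)", siUnit)) +
    ggplot2::theme_minimal()
}

#' Plot a probe
#'
#' Draws the contacts as shaped patches and the contour, with equal aspect
#' ratio and axes labeled in the probe's length unit. With
#' `showLabels = TRUE` each contact is annotated with its contact id and,
#' when wired, its device channel index (`dev<k>`). 3-d probes are projected
#' onto `plane`. The figure is a ggplot object and is deterministic given the
#' probe.
#'
#' @param x a [Probe].
#' @param showLabels annotate contacts with ids / device indices?
#' @param plane projection plane for 3-d probes.
#' @param contactColor fill colour of the contact patches.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
setMethod("plotProbe", "Probe",
  function(x, showLabels = FALSE, plane = "xy", contactColor = "orange", ...) {
    .plotGeometries(list(probeToPolygons(x, plane = plane)), siUnits(x),
                    showLabels, contactColor)
  }
)

#' @describeIn plotProbe-Probe-method plot every probe of a group into one
#'   figure.
#' @export
setMethod("plotProbe", "ProbeGroup",
  function(x, showLabels = FALSE, plane = "xy", contactColor = "orange", ...) {
    validObject(x)
    geos <- lapply(x@probes, probeToPolygons, plane = plane)
    unit <- if (numProbes(x)) siUnits(x@probes[[1]]) else "um"
    .plotGeometries(geos, unit, showLabels, contactColor)
  }
)

#' Plot a probe group
#'
#' Alias of the [plotProbe()] method for [ProbeGroup] objects.
#'
#' @inheritParams plotProbe-Probe-method
#' @param group a [ProbeGroup].
#' @return a ggplot object.
#' @export
plotProbeGroup <- function(group, showLabels = FALSE, plane = "xy",
                           contactColor = "orange", ...) {
  plotProbe(group, showLabels = showLabels, plane = plane,
            contactColor = contactColor, ...)
}
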