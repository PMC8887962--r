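#' @include probe.R
NULL

# pentagon-with-tip vertices for one shank, counter-clockwise from top-left
.shankOutline <- function(xmin, xmax, ymin, ymax, margin) {
  rbind(
    c(xmin - margin, ymax + margin),
    c(xmin - margin, ymin - margin),
    c((xmin + xmax) / 2, ymin - 2 * margin),
    c(xmax + margin, ymin - margin),
    c(xmax + margin, ymax + margin)
  )
}

.gridPositions <- function(numColumns, contactsPerColumn, xPitch, yPitch,
                           yShiftPerColumn) {
  if (length(contactsPerColumn) == 1L) {
    contactsPerColumn <- rep(contactsPerColumn, numColumns)
  }
  if (length(contactsPerColumn) != numColumns) {
    .stopValidation("contactsPerColumn must be a scalar or one count per column")
  }
  if (is.null(yShiftPerColumn)) {
    yShiftPerColumn <- rep(0, numColumns)
  }
  if (length(yShiftPerColumn) != numColumns) {
    .stopValidation("yShiftPerColumn must give one offset per column")
  }
  if (any(contactsPerColumn < 1)) .stopValidation("column counts must be >= 1")
  if (xPitch <= 0 || yPitch <= 0) .stopValidation("pitches must be > 0")
  pos <- do.call(rbind, lapply(seq_len(numColumns), function(c1) {
    c0 <- c1 - 1L
    rows <- seq_len(contactsPerColumn[c1]) - 1L
    cbind(c0 * xPitch, rows * yPitch + yShiftPerColumn[c1])
  }))
  pos
}

#' Generate a multi-column probe layout
#'
#' Builds a single-shank probe whose contacts form `numColumns` vertical
#' columns. Contacts are stored column-major: column 0 bottom-to-top, then
#' column 1, and so on. Column `c` (0-based) sits at `x = c * xPitch`; row
#' `r` of that column at `y = r * yPitch + yShiftPerColumn[c + 1]`. Staggered
#' ("Poly"-style) layouts are obtained with per-column counts and y shifts.
#' A pentagonal outline (rectangle with margin plus a triangular tip below
#' the lowest contact) is attached unless `addContour = FALSE`.
#'
#' @param numColumns number of contact columns.
#' @param contactsPerColumn contacts per column; a scalar or one count per
#'   column.
#' @param xPitch horizontal distance between adjacent columns (`siUnits`).
#' @param yPitch vertical distance between adjacent contacts in a column.
#' @param yShiftPerColumn optional per-column vertical offsets (default all 0).
#' @param contactShape,contactShapeParams contact shape specification as in
#'   [setContacts()].
#' @param contourMargin margin of the auto-generated outline around the
#'   contacts (`siUnits`); the tip extends one further margin below.
#' @param addContour attach the auto-generated outline?
#' @param siUnits length unit of the probe.
#' @return a single-shank [Probe].
#' @examples
#' p <- generateMultiColumnsProbe(numColumns = 3,
#'                                contactsPerColumn = c(10, 12, 10),
#'                                yShiftPerColumn = c(25, 0, 25))
#' numContacts(p)
#' @export
generateMultiColumnsProbe <- function(numColumns = 2, contactsPerColumn = 8,
                                      xPitch = 20, yPitch = 20,
                                      yShiftPerColumn = NULL,
                                      contactShape = "circle",
                                      contactShapeParams = list(radius = 5),
                                      contourMargin = 20, addContour = TRUE,
                                      siUnits = "um") {
  pos <- .gridPositions(numColumns, contactsPerColumn, xPitch, yPitch,
                        yShiftPerColumn)
  probe <- createProbe(2, siUnits)
  probe <- setContacts(probe, pos, contactShape, contactShapeParams)
  if (addContour) {
    probeContour(probe) <- .shankOutline(min(pos[, 1]), max(pos[, 1]),
                                         min(pos[, 2]), max(pos[, 2]),
                                         contourMargin)
  }
  probe
}

#' Generate a multi-shank probe layout
#'
#' Repeats a multi-column grid across `numShanks` shanks spaced `shankPitch`
#' apart in x. Shank `k` (0-based) is the grid translated by `k * shankPitch`
#' with all its contacts assigned `shank_id` `"k"`; contact storage order is
#' column-major within each shank, shanks in increasing x. The attached
#' outline spans all shanks with one triangular tip per shank.
#'
#' @param numShanks number of shanks (>= 1).
#' @param shankPitch distance between consecutive shanks in x (`siUnits`).
#' @inheritParams generateMultiColumnsProbe
#' @return a [Probe] with `numShanks` shanks.
#' @examples
#' p <- generateMultiShankProbe(numShanks = 2, numColumns = 2,
#'                              contactsPerColumn = 8)
#' numContacts(p)          # 32
#' length(getShanks(p))    # 2
#' @export
generateMultiShankProbe <- function(numShanks = 2, shankPitch = 150,
                                    numColumns = 2, contactsPerColumn = 8,
                                    xPitch = 20, yPitch = 20,
                                    yShiftPerColumn = NULL,
                                    contactShape = "circle",
                                    contactShapeParams = list(radius = 5),
                                    contourMargin = 20, addContour = TRUE,
                                    siUnits = "um") {
  if (numShanks < 1) .stopValidation("numShanks must be >= 1")
  if (shankPitch <= 0) .stopValidation("shankPitch must be > 0")
  grid <- .gridPositions(numColumns, contactsPerColumn, xPitch, yPitch,
                         yShiftPerColumn)
  perShank <- nrow(grid)
  pos <- do.call(rbind, lapply(seq_len(numShanks) - 1L, function(k) {
    cbind(grid[, 1] + k * shankPitch, grid[, 2])
  }))
  probe <- createProbe(2, siUnits)
  probe <- setContacts(probe, pos, contactShape, contactShapeParams)
  shankIds(probe) <- as.character(rep(seq_len(numShanks) - 1L, each = perShank))
  if (addContour) {
    margin <- contourMargin
    ymin <- min(grid[, 2])
    ymax <- max(grid[, 2])
    top <- ymax + margin
    verts <- list(c(min(grid[, 1]) - margin, top))
    for (k in seq_len(numShanks) - 1L) {
      x0 <- min(grid[, 1]) + k * shankPitch
      x1 <- max(grid[, 1]) + k * shankPitch
      verts <- c(verts, list(
        c(x0 - margin, ymin - margin),
        c((x0 + x1) / 2, ymin - 2 * margin),
        c(x1 + margin, ymin - margin)
      ))
    }
    verts <- c(verts, list(c(max(grid[, 1]) + (numShanks - 1L) * shankPitch + margin, top)))
    probeContour(probe) <- do.call(rbind, verts)
  }
  probe
}

#' Generate a tetrode layout
#'
#' Four circular contacts at 45, 135, 225 and 315 degrees on a circle of the
#' given radius (a microwire-bundle tetrode idealized as a planar square),
#' forming a single shank.
#'
#' @param radius distance of each contact from the tetrode center (`siUnits`).
#' @param contactRadius radius of each circular contact.
#' @param siUnits length unit of the probe.
#' @return a 4-contact [Probe].
#' @examples
#' generateTetrode(radius = 10)
#' @export
generateTetrode <- function(radius = 10, contactRadius = 5, siUnits = "um") {
  if (!is.numeric(radius) || radius <= 0) {
    .stopValidation("radius must be > 0")
  }
  ang <- (c(45, 135, 225, 315)) * pi / 180
  pos <- cbind(radius * cos(ang), radius * sin(ang))
  probe <- createProbe(2, siUnits)
  setContacts(probe, pos, "circle", list(radius = contactRadius))
}
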