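#' @include library.R
NULL

.CIRCLE_VERTICES <- 32L

# vertices of one contact polygon, in the (2- or 3-d) probe space
.contactPolygon <- function(center, shape, params, ax1, ax2, circleVertices) {
  switch(shape,
    circle = {
      th <- seq(0, 2 * pi, length.out = circleVertices + 1L)[-(circleVertices + 1L)]
      r <- params$radius
      t(vapply(th, function(a) center + r * cos(a) * ax1 + r * sin(a) * ax2,
               numeric(length(center))))
    },
    square = ,
    rect = {
      w <- params$width
      h <- if (shape == "square") params$width else params$height
      corners <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
      t(apply(corners, 1, function(s) {
        center + s[1] * w / 2 * ax1 + s[2] * h / 2 * ax2
      }))
    },
    .stopValidation("unknown contact shape '%s'", shape)
  )
}

#' Contact and contour polygons of a probe
#'
#' The drawing-free geometry layer behind the plotting functions: computes
#' one closed polygon per contact (circles discretized with 32 vertices;
#' squares and rectangles as 4 corners oriented by the contact plane axes),
#' the contour polygon if present, and one label anchor per contact carrying
#' the contact id and -- when the probe is wired -- the device index text
#' `"dev<k>"`. 3-d probes are projected onto `plane`.
#'
#' @param probe a [Probe].
#' @param circleVertices number of vertices used to discretize circles.
#' @param plane projection plane for 3-d probes (`"xy"`, `"yz"`, `"xz"`).
#' @return a list with elements `contacts` (list of vertex matrices, one per
#'   contact), `contour` (vertex matrix or `NULL`), and `labels` (data frame
#'   with `x`, `y`, `contactId`, `deviceText`).
#' @examples
#' geo <- probeToPolygons(generateTetrode())
#' length(geo$contacts)
#' @export
setMethod("probeToPolygons", "Probe",
  function(probe, circleVertices = .CIRCLE_VERTICES, plane = "xy") {
    n <- numContacts(probe)
    cols <- if (probe@ndim == 3L) .planeCols(plane) else c(1L, 2L)
    polys <- lapply(seq_len(n), function(i) {
      poly <- .contactPolygon(
        probe@positions[i, ], probe@shapes[i], probe@shapeParams[[i]],
        probe@planeAxes[i, 1, ], probe@planeAxes[i, 2, ], circleVertices
      )
      poly[, cols, drop = FALSE]
    })
    contour <- if (nrow(probe@contour)) {
      probe@contour[, cols, drop = FALSE]
    } else {
      NULL
    }
    dci <- probe@deviceChannelIndices
    labels <- data.frame(
      x = probe@positions[, cols[1]],
      y = probe@positions[, cols[2]],
      contactId = probe@contactIds,
      deviceText = if (length(dci)) {
        ifelse(dci >= 0L, paste0("dev", dci), NA_character_)
      } else {
        rep(NA_character_, n)
      },
      stringsAsFactors = FALSE
    )
    list(contacts = polys, contour = contour, labels = labels)
  }
)
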