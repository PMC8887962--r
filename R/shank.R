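#' @include probe.R
NULL

#' Split a probe into its shanks
#'
#' Returns one [Shank] per distinct shank id, in order of first appearance of
#' the id along the contact storage order (shank ids are not sorted). The
#' shanks' contact indices are disjoint and together cover every contact of
#' the probe exactly once.
#'
#' @param probe a [Probe].
#' @return list of [Shank] objects (empty list for an empty probe).
#' @examples
#' p <- generateMultiShankProbe(numShanks = 2, numColumns = 2,
#'                              contactsPerColumn = 8)
#' length(getShanks(p))
#' @export
setMethod("getShanks", "Probe", function(probe) {
  ids <- unique(probe@shankIds)
  lapply(ids, function(id) {
    new("Shank",
      shankId = id,
      probe = probe,
      contactIndices = which(probe@shankIds == id)
    )
  })
})

#' @describeIn Shank number of contacts on the shank.
#' @param x a `Shank`.
#' @export
setMethod("numContacts", "Shank", function(x) length(x@contactIndices))

#' @describeIn Shank positions of the shank's contacts (rows of the parent).
#' @export
setMethod("contactPositions", "Shank", function(x) {
  x@probe@positions[x@contactIndices, , drop = FALSE]
})

#' @describeIn Shank contact identifiers of the shank's contacts.
#' @export
setMethod("contactIds", "Shank", function(x) x@probe@contactIds[x@contactIndices])

#' Shank id of a Shank
#' @param shank a [Shank].
#' @return the shank identifier.
#' @export
shankId <- function(shank) shank@shankId

#' Row indices of a shank's contacts in its parent probe
#' @param shank a [Shank].
#' @return 1-based integer indices into the parent probe's contact arrays.
#' @export
shankContactIndices <- function(shank) shank@contactIndices

setMethod("show", "Shank", function(object) {
  cat(sprintf("Shank '%s' - %d contacts\n", object@shankId,
              length(object@contactIndices)))
  invisible(object)
})
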