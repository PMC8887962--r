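#' @include probe.R
NULL

#' Create a probe group
#'
#' Aggregates probes recorded with the same acquisition device into a
#' [ProbeGroup]. Members must share `ndim` and `siUnits`, and any already
#' assigned device channel indices must be distinct across the whole group.
#'
#' @param ... [Probe] objects, or a single list of probes.
#' @return a [ProbeGroup].
#' @examples
#' p0 <- generateMultiShankProbe(numShanks = 2, numColumns = 2,
#'                               contactsPerColumn = 8)
#' p1 <- moveProbe(p0, c(600, 0))
#' g <- probeGroup(p0, p1)
#' numContacts(g)
#' @export
probeGroup <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && is.list(ps[[1]]) && !is(ps[[1]], "Probe")) {
    ps <- ps[[1]]
  }
  g <- new("ProbeGroup", probes = ps)
  validObject(g)
  g
}

#' Append a probe to a group
#'
#' @param group a [ProbeGroup].
#' @param probe the [Probe] to append; its `ndim`/`siUnits` must match the
#'   existing members and its device channel indices must not collide with
#'   indices already claimed in the group.
#' @return the extended [ProbeGroup].
#' @export
setMethod("addProbe", c("ProbeGroup", "Probe"), function(group, probe) {
  group@probes <- c(group@probes, list(probe))
  validObject(group)
  group
})

#' @describeIn ProbeGroup list of member probes.
#' @param x a `ProbeGroup`.
#' @export
setMethod("probes", "ProbeGroup", function(x) x@probes)

#' @describeIn ProbeGroup total contact count over all member probes.
#' @export
setMethod("numContacts", "ProbeGroup", function(x) {
  sum(vapply(x@probes, numContacts, integer(1)), 0L)
})

#' Number of probes in a group
#' @param x a [ProbeGroup].
#' @return integer count of member probes.
#' @export
numProbes <- function(x) length(x@probes)

#' @describeIn ProbeGroup concatenated device channel indices, in group order;
#'   probes that are not wired contribute `NA` for each contact.
#' @export
setMethod("deviceChannelIndices", "ProbeGroup", function(x) {
  unlist(lapply(x@probes, function(p) {
    d <- p@deviceChannelIndices
    if (length(d)) d else rep(NA_integer_, numContacts(p))
  }))
})

setMethod("show", "ProbeGroup", function(object) {
  cat(sprintf("ProbeGroup - %d probe(s), %d contacts total\n",
              length(object@probes), numContacts(object)))
  for (p in object@probes) {
    cat("  "); show(p)
  }
  invisible(object)
})
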