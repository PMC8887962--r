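#' @include probegroup.R
NULL

#' Create a wiring stage table
#'
#' @param name stage name (e.g. `"RHD2164"`).
#' @param mapping integer vector of 0-based output channels, entry `i + 1`
#'   being the output channel that receives input channel `i`; `-1` marks an
#'   unconnected input.
#' @return a [StageTable].
#' @examples
#' stageTable("identity8", 0:7)
#' @export
stageTable <- function(name, mapping) {
  s <- new("StageTable", name = as.character(name),
           mapping = as.integer(mapping))
  validObject(s)
  s
}

#' @describeIn StageTable the 0-based mapping vector.
#' @param x a `StageTable`.
#' @export
setMethod("stageMapping", "StageTable", function(x) x@mapping)

#' @describeIn StageTable number of channels the stage carries.
#' @export
setMethod("stageSize", "StageTable", function(x) length(x@mapping))

setMethod("show", "StageTable", function(object) {
  cat(sprintf("StageTable '%s' - %d channels (%d connected)\n",
              object@name, length(object@mapping),
              sum(object@mapping >= 0L)))
  invisible(object)
})

#' Create a wiring pathway
#'
#' @param name pathway name, conventionally `"<connector>><headstage>"`.
#' @param stages list of [StageTable] objects of equal size, ordered from the
#'   probe connector toward the acquisition device.
#' @return a [Pathway].
#' @export
pathway <- function(name, stages) {
  if (is(stages, "StageTable")) stages <- list(stages)
  p <- new("Pathway", name = as.character(name), stages = stages)
  validObject(p)
  p
}

#' Compose wiring stages into a single table
#'
#' Chains the per-stage channel permutations: input channel `i` of the first
#' stage comes out at `stages[[k]](...stages[[1]](i)...)`. A `-1`
#' (unconnected) at any stage propagates, so the channel ends up unconnected
#' in the composite. The composite of valid stage tables is itself a valid
#' stage table.
#'
#' @param stages a list of [StageTable] objects or a [Pathway].
#' @return the composed [StageTable].
#' @examples
#' a <- stageTable("rev", 7:0)
#' b <- stageTable("rot", c(1:7, 0))
#' stageMapping(composeStages(list(a, b)))
#' @export
composeStages <- function(stages) {
  if (is(stages, "Pathway")) stages <- stages@stages
  if (is(stages, "StageTable")) stages <- list(stages)
  if (!length(stages)) .stopValidation("need at least one stage to compose")
  for (s in stages) validObject(s)
  sizes <- vapply(stages, stageSize, integer(1))
  if (length(unique(sizes)) != 1L) {
    .stopValidation(
      "stage sizes are incompatible: %s", paste(sizes, collapse = " vs ")
    )
  }
  out <- stages[[1]]@mapping
  for (s in stages[-1]) {
    nxt <- s@mapping
    connected <- out >= 0L
    out[connected] <- nxt[out[connected] + 1L]
  }
  stageTable(paste(vapply(stages, function(s) s@name, character(1)),
                   collapse = ">"), out)
}

#' Invert a stage table
#'
#' Returns the table sending each output channel back to the input that feeds
#' it; outputs that no input reaches are `-1`. For a fully connected table
#' this is the inverse permutation: composing a table with its inverse gives
#' the identity.
#'
#' @param stage a [StageTable].
#' @return the inverted [StageTable].
#' @export
invertStage <- function(stage) {
  validObject(stage)
  m <- length(stage@mapping)
  inv <- rep(-1L, m)
  src <- which(stage@mapping >= 0L)
  inv[stage@mapping[src] + 1L] <- src - 1L
  stageTable(paste0(stage@name, ":inv"), inv)
}

#' Manually wire a probe
#'
#' Assigns the device channel index of every contact directly, for setups
#' where the full contact-to-trace mapping is already known. Contact `i`
#' (storage order) receives `indices[i]`; `-1` marks a contact that is not
#' connected to any recorded trace. Non-negative indices must be pairwise
#' distinct.
#'
#' @param probe a [Probe] with contacts.
#' @param indices integer vector, one device channel index per contact.
#' @return the wired [Probe].
#' @examples
#' p <- generateTetrode()
#' p <- setDeviceChannelIndices(p, c(3, 1, 2, 0))
#' deviceChannelIndices(p)
#' @export
setMethod("setDeviceChannelIndices", "Probe", function(probe, indices) {
  n <- numContacts(probe)
  if (n == 0L) .stopValidation("cannot wire a probe without contacts")
  if (length(indices) != n) {
    .stopValidation("need one device index per contact (n = %d), got %d",
                    n, length(indices))
  }
  probe@deviceChannelIndices <- as.integer(indices)
  validObject(probe)
  probe
})

#' Wire a whole probe group
#'
#' Assigns device channel indices to every contact of the group at once: the
#' vector is split across the probes in group order (the first probe takes
#' the first `n1` entries, and so on) and assigned per probe. Non-negative
#' indices must be distinct across the whole group.
#'
#' @param group a [ProbeGroup].
#' @param indices integer vector with one entry per contact in the group.
#' @return the wired [ProbeGroup].
#' @export
setMethod("setGlobalDeviceChannelIndices", "ProbeGroup", function(group, indices) {
  total <- numContacts(group)
  if (length(indices) != total) {
    .stopValidation("need one device index per contact across the group (%d), got %d",
                    total, length(indices))
  }
  offset <- 0L
  for (k in seq_along(group@probes)) {
    n <- numContacts(group@probes[[k]])
    group@probes[[k]] <- setDeviceChannelIndices(
      group@probes[[k]], indices[offset + seq_len(n)]
    )
    offset <- offset + n
  }
  validObject(group)
  group
})

## ---- pathway registry -----------------------------------------------------

.pathwayDirs <- function() {
  extra <- getOption("neuroprobe.pathwayDirs", character(0))
  c(extra, system.file("extdata", "pathways", package = "neuroprobe"))
}

.pathwayFromList <- function(doc) {
  stages <- lapply(doc$stages, function(s) {
    stageTable(s$name, unlist(s$mapping, use.names = FALSE))
  })
  pathway(doc$name, stages)
}

#' Read a pathway description file
#'
#' Pathway files are JSON documents
#' `{"name": ..., "stages": [{"name": ..., "mapping": [ints]}, ...]}` with
#' 0-based mappings, so new hardware pathways can be contributed as data
#' without code changes.
#'
#' @param path path to a pathway JSON file.
#' @return a [Pathway].
#' @export
readPathwayFile <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$name) || is.null(doc$stages)) {
    .stopValidation("'%s' is not a pathway file (needs name and stages)", path)
  }
  .pathwayFromList(doc)
}

#' List the registered wiring pathways
#'
#' Scans the bundled pathway directory plus any directories named by
#' `options(neuroprobe.pathwayDirs = ...)`.
#'
#' @return character vector of registered pathway names.
#' @export
listPathways <- function() {
  files <- unlist(lapply(.pathwayDirs(), function(d) {
    if (nzchar(d) && dir.exists(d)) {
      list.files(d, pattern = "\\.json$", full.names = TRUE)
    } else {
      character(0)
    }
  }))
  nms <- vapply(files, function(f) {
    tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE)$name %||% "",
             error = function(e) "")
  }, character(1), USE.NAMES = FALSE)
  sort(unique(nms[nzchar(nms)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Look up a registered pathway by name
#'
#' Pathway names use `">"` as the connector/headstage separator; `"__"` is
#' accepted as a filename/shell-friendly alias.
#'
#' @param name pathway name, e.g. `"synthetic-ASSY-156>RHD2164"`.
#' @return a [Pathway].
#' @export
getPathway <- function(name) {
  name <- gsub("__", ">", name, fixed = TRUE)
  for (d in .pathwayDirs()) {
    if (!nzchar(d) || !dir.exists(d)) next
    for (f in list.files(d, pattern = "\\.json$", full.names = TRUE)) {
      doc <- tryCatch(jsonlite::fromJSON(f, simplifyVector = FALSE),
                      error = function(e) NULL)
      if (!is.null(doc$name) && identical(doc$name, name)) {
        return(.pathwayFromList(doc))
      }
    }
  }
  .stopValidation("unknown pathway '%s' (registered: %s)", name,
                  paste(listPathways(), collapse = ", "))
}

#' Wire a probe through a named pathway
#'
#' Composes the pathway's per-stage channel tables and assigns the resulting
#' device channel index to each contact: contact `i` (storage order, 0-based
#' over the composed table's inputs) receives the composed mapping of input
#' `i`. The probe's contact count must equal the pathway's channel count.
#'
#' @param probe a [Probe].
#' @param pathway a [Pathway], a [StageTable], or the name of a registered
#'   pathway (see [listPathways()]).
#' @return the wired [Probe].
#' @examples
#' p <- generateMultiShankProbe(numShanks = 4, numColumns = 2,
#'                              contactsPerColumn = 8)
#' p <- wireProbe(p, "synthetic-ASSY-156>RHD2164")
#' head(deviceChannelIndices(p))
#' @export
setMethod("wireProbe", "Probe", function(probe, pathway) {
  if (is.character(pathway)) pathway <- getPathway(pathway)
  composed <- composeStages(pathway)
  n <- numContacts(probe)
  if (stageSize(composed) != n) {
    .stopValidation("pathway carries %d channels but the probe has %d contacts",
                    stageSize(composed), n)
  }
  setDeviceChannelIndices(probe, composed@mapping)
})
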