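#' @import methods
NULL

#' @export
setGeneric("numContacts", function(x) standardGeneric("numContacts"))

#' @export
setGeneric("probeNdim", function(x) standardGeneric("probeNdim"))

#' @export
setGeneric("siUnits", function(x) standardGeneric("siUnits"))

#' @export
setGeneric("contactPositions", function(x) standardGeneric("contactPositions"))

#' @export
setGeneric("contactShapes", function(x) standardGeneric("contactShapes"))

#' @export
setGeneric("contactShapeParams", function(x) standardGeneric("contactShapeParams"))

#' @export
setGeneric("contactPlaneAxes", function(x) standardGeneric("contactPlaneAxes"))

#' @export
setGeneric("contactIds", function(x) standardGeneric("contactIds"))

#' @export
setGeneric("contactIds<-", function(x, value) standardGeneric("contactIds<-"))

#' @export
setGeneric("shankIds", function(x) standardGeneric("shankIds"))

#' @export
setGeneric("shankIds<-", function(x, value) standardGeneric("shankIds<-"))

#' @export
setGeneric("deviceChannelIndices", function(x) standardGeneric("deviceChannelIndices"))

#' @export
setGeneric("probeContour", function(x) standardGeneric("probeContour"))

#' @export
setGeneric("probeContour<-", function(x, value) standardGeneric("probeContour<-"))

#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @export
setGeneric("annotations<-", function(x, value) standardGeneric("annotations<-"))

#' @export
setGeneric("contactAnnotations", function(x) standardGeneric("contactAnnotations"))

#' @export
setGeneric("contactAnnotations<-", function(x, value) standardGeneric("contactAnnotations<-"))

#' @export
setGeneric("setContacts", function(probe, positions, shapes = "circle",
                                   shapeParams = list(radius = 5),
                                   planeAxes = NULL)
  standardGeneric("setContacts"))

#' @export
setGeneric("getShanks", function(probe) standardGeneric("getShanks"))

#' @export
setGeneric("moveProbe", function(x, translation) standardGeneric("moveProbe"))

#' @export
setGeneric("rotateProbe", function(x, angle, center = NULL, axis = NULL)
  standardGeneric("rotateProbe"))

#' @export
setGeneric("to3d", function(probe, plane = "xy") standardGeneric("to3d"))

#' @export
setGeneric("to2d", function(probe, plane = "xy") standardGeneric("to2d"))

#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @export
setGeneric("addProbe", function(group, probe) standardGeneric("addProbe"))

#' @export
setGeneric("setDeviceChannelIndices", function(probe, indices)
  standardGeneric("setDeviceChannelIndices"))

#' @export
setGeneric("setGlobalDeviceChannelIndices", function(group, indices)
  standardGeneric("setGlobalDeviceChannelIndices"))

#' @export
setGeneric("stageMapping", function(x) standardGeneric("stageMapping"))

#' @export
setGeneric("stageSize", function(x) standardGeneric("stageSize"))

#' @export
setGeneric("wireProbe", function(probe, pathway) standardGeneric("wireProbe"))

#' @export
setGeneric("probeToPolygons", function(probe, ...) standardGeneric("probeToPolygons"))

#' @export
setGeneric("plotProbe", function(x, ...) standardGeneric("plotProbe"))

#' @export
setGeneric("writeProbeInterface", function(x, path) standardGeneric("writeProbeInterface"))

#' @export
setGeneric("writePrb", function(x, path) standardGeneric("writePrb"))
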