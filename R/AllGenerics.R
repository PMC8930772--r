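#' Accessors for scenes, prediction maps and segmentation results
#'
#' Standard slot accessors; user code should use these rather than `@`.
#'
#' @param object a [Scene-class], [PredictionMaps-class],
#'   [SegmentationResult-class] or [Calibration-class] object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("brightfield", function(object) standardGeneric("brightfield"))
#' @rdname accessors
#' @export
setGeneric("fluorescence", function(object) standardGeneric("fluorescence"))
#' @rdname accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))
#' @rdname accessors
#' @export
setGeneric("droplets", function(object) standardGeneric("droplets"))
#' @rdname accessors
#' @export
setGeneric("sceneCalibration", function(object) standardGeneric("sceneCalibration"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("strainTag", function(object) standardGeneric("strainTag"))
#' @rdname accessors
#' @export
setGeneric("seedMap", function(object) standardGeneric("seedMap"))
#' @rdname accessors
#' @export
setGeneric("bandwidthMap", function(object) standardGeneric("bandwidthMap"))
#' @rdname accessors
#' @export
setGeneric("embeddings", function(object) standardGeneric("embeddings"))
#' @rdname accessors
#' @export
setGeneric("instances", function(object) standardGeneric("instances"))
#' @rdname accessors
#' @export
setGeneric("removedInstances", function(object) standardGeneric("removedInstances"))

#' @rdname accessors
#' @export
setMethod("brightfield", "Scene", function(object) object@brightfield)
#' @rdname accessors
#' @export
setMethod("fluorescence", "Scene", function(object) object@fluorescence)
#' @rdname accessors
#' @export
setMethod("labelImage", "Scene", function(object) object@labelImage)
#' @rdname accessors
#' @export
setMethod("labelImage", "SegmentationResult", function(object) object@labelImage)
#' @rdname accessors
#' @export
setMethod("droplets", "Scene", function(object) object@droplets)
#' @rdname accessors
#' @export
setMethod("sceneCalibration", "Scene", function(object) object@calibration)
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "Calibration", function(object) object@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSizeUm", "Scene", function(object) object@calibration@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("strainTag", "Scene", function(object) object@strainTag)
#' @rdname accessors
#' @export
setMethod("seedMap", "PredictionMaps", function(object) object@seed)
#' @rdname accessors
#' @export
setMethod("bandwidthMap", "PredictionMaps", function(object) object@bandwidth)

#' @rdname accessors
#' @export
setMethod("embeddings", "PredictionMaps", function(object) {
  H <- nrow(object@seed); W <- ncol(object@seed)
  S <- max(H, W)
  list(row = (matrix(seq_len(H), H, W) - 0.5) / S + object@offsetRow,
       col = (matrix(seq_len(W), H, W, byrow = TRUE) - 0.5) / S + object@offsetCol)
})

#' @rdname accessors
#' @export
setMethod("instances", "SegmentationResult", function(object) object@instances)
#' @rdname accessors
#' @export
setMethod("removedInstances", "SegmentationResult", function(object) object@removed)
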