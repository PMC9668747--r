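#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' RoiTraceSet: fluorescence traces per ROI
#'
#' A \code{SummarizedExperiment} with ROIs as rows and imaging frames as
#' columns.  The \code{"F"} assay holds raw fluorescence (arbitrary units,
#' strictly positive); the \code{"dff"} assay, once added by
#' \code{\link{computeDff}}, holds (F - F0)/F0.  Row data carry the ROI
#' pixel size; metadata carry the frame rate (Hz) and modality
#' ("ca1_soma" or "ec3_axon").
#'
#' @exportClass RoiTraceSet
setClass("RoiTraceSet", contains = "SummarizedExperiment")

setValidity("RoiTraceSet", function(object) {
  msg <- character()
  if (!"F" %in% assayNames(object))
    msg <- c(msg, "an assay named 'F' is required")
  else {
    f <- assay(object, "F")
    if (any(!is.finite(f)) || any(f <= 0))
      msg <- c(msg, "F must be finite and strictly positive")
  }
  if ("dff" %in% assayNames(object) &&
      !identical(dim(assay(object, "dff")), dim(assay(object, "F"))))
    msg <- c(msg, "dff and F must share identical shape")
  if (!"roiSize" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must carry roiSize")
  md <- metadata(object)
  if (is.null(md$frameRate) || md$frameRate <= 0)
    msg <- c(msg, "metadata$frameRate must be a positive number")
  if (is.null(md$modality) || !md$modality %in% c("ca1_soma", "ec3_axon"))
    msg <- c(msg, "metadata$modality must be 'ca1_soma' or 'ec3_axon'")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTraceSet
#'
#' @param F numeric matrix [ROI, frame] of raw fluorescence, > 0.
#' @param roiSize integer pixel count per ROI.
#' @param frameRate imaging frame rate, Hz.
#' @param modality "ca1_soma" or "ec3_axon".
#' @return a \code{\link{RoiTraceSet}}
#' @export
RoiTraceSet <- function(F, roiSize, frameRate, modality) {
  obj <- new("RoiTraceSet", SummarizedExperiment(
    assays = list(F = F),
    rowData = DataFrame(roiSize = as.integer(roiSize)),
    metadata = list(frameRate = frameRate, modality = modality)))
  validObject(obj)
  obj
}

#' Raw fluorescence matrix
#' @param x a RoiTraceSet
#' @return numeric matrix [ROI, frame]
#' @export
rawF <- function(x) assay(x, "F")

#' dF/F matrix (NULL if not yet computed)
#' @param x a RoiTraceSet
#' @return numeric matrix [ROI, frame] or NULL
#' @export
dffValues <- function(x) {
  if ("dff" %in% assayNames(x)) assay(x, "dff") else NULL
}

#' ROI pixel sizes
#' @param x a RoiTraceSet
#' @return integer vector
#' @export
roiSize <- function(x) rowData(x)$roiSize

#' Imaging frame rate (Hz)
#' @param x a RoiTraceSet
#' @return numeric
#' @export
frameRate <- function(x) metadata(x)$frameRate

#' Recording modality
#' @param x a RoiTraceSet
#' @return "ca1_soma" or "ec3_axon"
#' @export
modality <- function(x) metadata(x)$modality
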