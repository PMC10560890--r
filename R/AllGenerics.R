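#' @rdname StabilityDataset-class
#' @param x a \linkS4class{StabilityDataset}.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname StabilityDataset-class
#' @export
setGeneric("lowerLimit", function(x) standardGeneric("lowerLimit"))

#' @rdname StabilityDataset-class
#' @export
setGeneric("sipName", function(x) standardGeneric("sipName"))

#' @rdname StabilityDataset-class
#' @export
setGeneric("sipUnit", function(x) standardGeneric("sipUnit"))

#' Per-timepoint descriptive summary
#'
#' @param x a \linkS4class{StabilityDataset}.
#' @param ... unused.
#' @return data.frame, see method documentation.
#' @export
setGeneric("contentSummary", function(x, ...) standardGeneric("contentSummary"))

#' Write a stability dataset to CSV
#'
#' @param x a \linkS4class{StabilityDataset}.
#' @param path output file path.
#' @param ... unused.
#' @export
setGeneric("writeDataset", function(x, path, ...) standardGeneric("writeDataset"))
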