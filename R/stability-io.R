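#' Construct a StabilityDataset
#'
#' @param records data.frame with the columns listed in
#'   \linkS4class{StabilityDataset}. Factors are coerced to character;
#'   row order is preserved.
#' @param sipName name of the stability-indicating parameter.
#' @param unit assay unit of the content column.
#' @param lowerLimit minimum acceptable potency (LL), original scale.
#' @return a validated \linkS4class{StabilityDataset}.
#' @examples
#' rec <- data.frame(lot_id = "A", condition = "RT", conditioning_months = 0,
#'                   time_value = c(0, 3), time_unit = "month",
#'                   replicate = 1, content = c(1000, 990))
#' StabilityDataset(rec, lowerLimit = 800)
#' @export
StabilityDataset <- function(records, sipName = "antigen content",
                             unit = "LEU", lowerLimit = 800) {
  records <- as.data.frame(records)
  for (col in c("lot_id", "condition", "time_unit"))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  if (nrow(records)) rownames(records) <- NULL
  new("StabilityDataset", records = records[, .RECORD_COLUMNS, drop = FALSE],
      sipName = sipName, unit = unit, lowerLimit = lowerLimit)
}

#' @rdname StabilityDataset-class
#' @aliases records,StabilityDataset-method
#' @export
setMethod("records", "StabilityDataset", function(x) x@records)

#' @rdname StabilityDataset-class
#' @export
setMethod("lowerLimit", "StabilityDataset", function(x) x@lowerLimit)

#' @rdname StabilityDataset-class
#' @export
setMethod("sipName", "StabilityDataset", function(x) x@sipName)

#' @rdname StabilityDataset-class
#' @export
setMethod("sipUnit", "StabilityDataset", function(x) x@unit)

setMethod("show", "StabilityDataset", function(object) {
  rec <- object@records
  cat("StabilityDataset:", nrow(rec), "assay results of",
      object@sipName, sprintf("(%s)\n", object@unit))
  if (nrow(rec)) {
    cat("  lots:", length(unique(rec$lot_id)),
        "| RT results:", sum(rec$condition == "RT"),
        "| ECTC results:", sum(rec$condition == "ECTC"), "\n")
  }
  cat("  lower limit:", object@lowerLimit, object@unit, "\n")
})

#' Read a stability dataset from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and "." as the
#' decimal separator. The canonical column order is
#' \code{lot_id, condition, conditioning_months, time_value, time_unit,
#' replicate, content}; other orders are accepted, and \code{columnMap}
#' can rename non-standard headers.
#'
#' @param path CSV file path.
#' @param lowerLimit minimum acceptable potency (LL) for this study.
#' @param columnMap optional named character vector mapping canonical
#'   names to the file's column names, e.g.
#'   \code{c(content = "assay_result")}.
#' @param sipName,unit passed to [StabilityDataset()].
#' @return a validated \linkS4class{StabilityDataset}; row order preserved.
#' @seealso [writeDataset()] for the inverse operation.
#' @export
readDataset <- function(path, lowerLimit = 800, columnMap = NULL,
                        sipName = "antigen content", unit = "LEU") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      from <- columnMap[[canon]]
      if (!from %in% names(raw))
        stop("columnMap names missing column ", dQuote(from), " in ", path)
      names(raw)[names(raw) == from] <- canon
    }
  }
  missing <- setdiff(.RECORD_COLUMNS, names(raw))
  if (length(missing))
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  if (nrow(raw) == 0L) {
    for (col in c("conditioning_months", "time_value", "replicate",
                  "content"))
      raw[[col]] <- numeric()
    for (col in c("lot_id", "condition", "time_unit"))
      raw[[col]] <- character()
  }
  if (!is.numeric(raw$content))
    stop("schema error: content column is not numeric in ", path)
  StabilityDataset(raw, sipName = sipName, unit = unit,
                   lowerLimit = lowerLimit)
}

#' @describeIn writeDataset Writes the canonical column order
#'   (\code{lot_id, condition, conditioning_months, time_value, time_unit,
#'   replicate, content}) as comma-separated UTF-8 with a header row.
#'   \code{readDataset(writeDataset(x, p), lowerLimit(x))} returns a
#'   dataset value-identical to \code{x}.
#' @return the output path, invisibly.
#' @export
setMethod("writeDataset", "StabilityDataset", function(x, path, ...) {
  utils::write.csv(x@records[, .RECORD_COLUMNS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
})

#' The built-in mock-study design
#'
#' The sampling plan of the package's reference mock stability study:
#' 24 lots followed for 24 months in the cold chain with lot counts
#' 24, 12, 24, 12, 24, 12 and 15 at months 0, 3, 6, 9, 12, 18 and 24
#' (123 RT results), plus ECTC series at days 0, 3, 7, 10, 12 and 14 for
#' 12 lots exposed after 0, 6 and 12 months of conditioning and 3 lots
#' exposed after 24 months (234 ECTC results). One result per scheduled
#' lot-timepoint.
#'
#' @return a \linkS4class{DesignScheme}.
#' @examples
#' d <- mockStudyDesign()
#' sum(d@rtCells$n_lots)  # 123 RT results
#' @export
mockStudyDesign <- function() {
  rt <- data.frame(month = c(0L, 3L, 6L, 9L, 12L, 18L, 24L),
                   n_lots = c(24L, 12L, 24L, 12L, 24L, 12L, 15L))
  days <- c(0L, 3L, 7L, 10L, 12L, 14L)
  ec <- do.call(rbind, lapply(c(0L, 6L, 12L, 24L), function(m)
    data.frame(conditioning_month = m, day = days,
               n_lots = if (m == 24L) 3L else 12L)))
  new("DesignScheme", rtCells = rt, ectcCells = ec,
      replicatesPerSample = 1L)
}

#' Total scheduled results of a design
#'
#' @param design a \linkS4class{DesignScheme}.
#' @return named numeric: \code{rt} and \code{ectc} result counts
#'   (lots x replicates summed over cells).
#' @export
designCounts <- function(design) {
  stopifnot(is(design, "DesignScheme"))
  r <- design@replicatesPerSample
  c(rt = sum(design@rtCells$n_lots) * r,
    ectc = sum(design@ectcCells$n_lots) * r)
}

setMethod("show", "DesignScheme", function(object) {
  n <- designCounts(object)
  cat("DesignScheme:", nrow(object@rtCells), "RT cells (", n[["rt"]],
      "results ),", nrow(object@ectcCells), "ECTC cells (", n[["ectc"]],
      "results ),", object@replicatesPerSample, "replicate(s)/sample\n")
})

#' @describeIn contentSummary One row per (condition, conditioning month,
#'   time) cell with the number of results, the mean and the SD of the
#'   observed content on the original (untransformed) scale. SD is NA for
#'   single-result cells. An empty dataset gives an empty table.
#' @export
setMethod("contentSummary", "StabilityDataset", function(x, ...) {
  rec <- x@records
  empty <- data.frame(condition = character(), conditioning_months = numeric(),
                      time_value = numeric(), time_unit = character(),
                      n = integer(), mean = numeric(), sd = numeric())
  if (!nrow(rec)) return(empty)
  key <- interaction(rec$condition, rec$conditioning_months, rec$time_value,
                     drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(rec, key), function(cell)
    data.frame(condition = cell$condition[1],
               conditioning_months = cell$conditioning_months[1],
               time_value = cell$time_value[1],
               time_unit = cell$time_unit[1],
               n = nrow(cell),
               mean = mean(cell$content),
               sd = if (nrow(cell) > 1L) stats::sd(cell$content) else NA_real_)))
  out <- out[order(out$condition, out$conditioning_months, out$time_value), ]
  rownames(out) <- NULL
  out
})
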