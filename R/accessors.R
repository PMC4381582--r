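#' Accessors for screen containers
#'
#' @param x a [ScreenDataset-class], [PairedScreenZ-class], [FourPLFit-class]
#'   or [ScreenTruth-class] object.
#' @return `wells()` the well table; `cellLines()` the cell-line identifiers;
#'   `libraryIndex()` the gene -> siRNA mapping; `hitGenes()` genes flagged as
#'   hits; `ic50()` the fitted IC50 in molar; `coefficients4PL()` the named
#'   parameter vector; `truthLabels()` the planted-gene logical vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))
#' @rdname accessors
#' @export
setMethod("wells", "ScreenDataset", function(x) x@wells)

#' @rdname accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @rdname accessors
#' @export
setMethod("cellLines", "ScreenDataset", function(x)
  sort(unique(x@wells$cell_line)))

#' @rdname accessors
#' @export
setGeneric("libraryIndex", function(x) standardGeneric("libraryIndex"))
#' @rdname accessors
#' @export
setMethod("libraryIndex", "ScreenDataset", function(x) x@libraryIndex)

#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
#' @rdname accessors
#' @export
setMethod("ic50", "FourPLFit", function(x) x@ic50)

#' @rdname accessors
#' @export
setGeneric("coefficients4PL", function(x) standardGeneric("coefficients4PL"))
#' @rdname accessors
#' @export
setMethod("coefficients4PL", "FourPLFit", function(x)
  c(bottom = x@bottom, top = x@top, hill = x@hill,
    log_ic50 = x@logIC50, ic50 = x@ic50))

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setMethod("truthLabels", "ScreenTruth", function(x) x@labels)

setMethod("show", "ScreenDataset", function(object) {
  w <- object@wells
  cat("ScreenDataset:", nrow(w), "wells,",
      length(unique(w$plate_id)), "plates,",
      length(unique(w$cell_line)), "cell line(s),",
      length(object@libraryIndex), "library genes\n")
  tab <- table(w$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "PairedScreenZ", function(object) {
  cat("PairedScreenZ:", length(object@genes), "genes x",
      ncol(object@zOver), "siRNA slots;",
      object@lineOver, "(overexpressing) vs", object@lineCtrl, "(control)\n")
  if (nrow(object@missing))
    cat("  ", nrow(object@missing), "missing (gene, siRNA, line) combinations\n")
})

setMethod("show", "FourPLFit", function(object) {
  cat(sprintf(
    "FourPLFit: IC50 = %.4g M (bottom %.3g, top %.3g, hill %.3g), rss %.4g, n = %d\n",
    object@ic50, object@bottom, object@top, object@hill, object@rss,
    object@nPoints))
  if (!is.na(object@ciLow))
    cat(sprintf("  bootstrap CI: [%.4g, %.4g] M\n", object@ciLow, object@ciHigh))
})

setMethod("show", "ScreenSimConfig", function(object) {
  cat(sprintf(
    "ScreenSimConfig: %d genes x %d siRNAs; lines %s (over) / %s (ctrl); %d planted SL genes (sf %.2g vs %.2g)\n",
    object@nGenes, object@sirnasPerGene, object@lineOver, object@lineCtrl,
    object@nPlanted, object@plantedSfOver, object@plantedSfCtrl))
  cat(sprintf(
    "  noise: well sd %.3g, plate sd %.3g, off-target rate %.3g\n",
    object@wellNoiseSd, object@plateEffectSd, object@offtargetRate))
})

setMethod("show", "ScreenTruth", function(object) {
  cat("ScreenTruth:", length(object@labels), "genes,",
      sum(object@labels), "planted synthetic-lethal\n")
})
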