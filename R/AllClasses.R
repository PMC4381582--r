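#' @import methods
NULL

.WELL_ROLES <- c("sample", "neg_control", "pos_control", "death_control", "empty")

.WELL_COLUMNS <- c("plate_id", "row", "col", "cell_line", "sirna_id",
                   "gene", "role", "reading")

#' ScreenDataset: validated container for plate-based screen wells
#'
#' Holds one long-format table of well measurements for an arrayed siRNA
#' viability screen, together with the siRNA library index (which siRNA
#' duplexes target which gene). Wells are stored in canonical order
#' (cell line, plate, row, column) so that two datasets built from the same
#' wells in any input order are identical.
#'
#' @slot wells data.frame with columns `plate_id`, `row` (letter A-H),
#'   `col` (integer 1-12), `cell_line`, `sirna_id`, `gene`,
#'   `role` (one of sample, neg_control, pos_control, death_control, empty)
#'   and `reading` (non-negative absorbance, arbitrary units).
#' @slot libraryIndex named list mapping gene to its ordered character vector
#'   of siRNA ids.
#'
#' @seealso [readScreenTable()], [survivingFractions()], [simulateScreen()]
#' @export
setClass("ScreenDataset",
  representation(wells = "data.frame", libraryIndex = "list"))

setValidity("ScreenDataset", function(object) {
  w <- object@wells
  msgs <- character()
  missing_cols <- setdiff(.WELL_COLUMNS, names(w))
  if (length(missing_cols))
    return(sprintf("wells is missing column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (!all(w$role %in% .WELL_ROLES))
    msgs <- c(msgs, sprintf("unknown well role(s): %s",
                            paste(setdiff(unique(w$role), .WELL_ROLES),
                                  collapse = ", ")))
  if (any(!is.finite(w$reading)) || any(w$reading < 0))
    msgs <- c(msgs, "readings must be finite and >= 0")
  key <- paste(w$plate_id, w$row, w$col, sep = "\r")
  if (anyDuplicated(key))
    msgs <- c(msgs, sprintf("duplicate (plate_id, row, col): %s",
                            paste(gsub("\r", "/", key[duplicated(key)][1]))))
  samp <- w$role == "sample"
  if (any(samp & (is.na(w$gene) | w$gene == "" |
                  is.na(w$sirna_id) | w$sirna_id == "")))
    msgs <- c(msgs, "sample wells must carry non-empty gene and sirna_id")
  if (any(samp)) {
    lib_pairs <- unlist(lapply(names(object@libraryIndex), function(g)
      paste(g, object@libraryIndex[[g]], sep = "\r")), use.names = FALSE)
    seen <- unique(paste(w$gene[samp], w$sirna_id[samp], sep = "\r"))
    orphan <- setdiff(seen, lib_pairs)
    if (length(orphan))
      msgs <- c(msgs, sprintf(
        "%d sample (gene, sirna_id) pair(s) absent from the library index",
        length(orphan)))
  }
  if (length(msgs)) msgs else TRUE
})

#' PairedScreenZ: per-gene z-score vectors paired across two cell lines
#'
#' Result of [aggregateGenes()]: for every gene, the ordered siRNA-level
#' z-scores in the overexpressing line and in the control line, aligned by
#' siRNA id. Missing (gene, siRNA, line) combinations are `NA` in the matrices
#' and listed in the `missing` report; such genes are never called hits.
#'
#' @slot genes character vector of gene identifiers (row order of matrices).
#' @slot sirnas list (per gene) of the ordered siRNA ids backing the columns.
#' @slot zOver,zCtrl numeric matrices, genes x siRNA slots, of z-scores in the
#'   overexpressing and control line respectively.
#' @slot missing data.frame (gene, sirna_id, missing_in) of unmeasured combinations.
#' @slot lineOver,lineCtrl the two cell-line identifiers.
#' @export
setClass("PairedScreenZ",
  representation(genes = "character", sirnas = "list",
                 zOver = "matrix", zCtrl = "matrix",
                 missing = "data.frame",
                 lineOver = "character", lineCtrl = "character"))

setValidity("PairedScreenZ", function(object) {
  if (nrow(object@zOver) != length(object@genes) ||
      nrow(object@zCtrl) != length(object@genes))
    return("z matrices must have one row per gene")
  if (!identical(dim(object@zOver), dim(object@zCtrl)))
    return("zOver and zCtrl must have identical dimensions")
  TRUE
})

#' FourPLFit: fitted four-parameter logistic dose-response model
#'
#' Variable-slope sigmoid `response = bottom + (top - bottom) /
#' (1 + 10^((logIC50 - log10(conc)) * hill))`, the classic Prism-style model
#' for inhibitor potency. Decreasing curves carry `hill > 0` under this
#' parameterization.
#'
#' @slot bottom,top lower/upper plateaus, percent.
#' @slot hill slope factor (dimensionless, > 0 for decreasing response).
#' @slot logIC50 log10 of the IC50 in molar.
#' @slot ic50 IC50 in molar, `10^logIC50`.
#' @slot rss residual sum of squares of the fit.
#' @slot ciLow,ciHigh percentile-bootstrap confidence bounds on the IC50
#'   (molar); `NA` when no bootstrap was requested.
#' @slot nPoints number of dose-response points fitted.
#' @seealso [fit4PL()]
#' @export
setClass("FourPLFit",
  representation(bottom = "numeric", top = "numeric", hill = "numeric",
                 logIC50 = "numeric", ic50 = "numeric", rss = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", nPoints = "integer"))

setValidity("FourPLFit", function(object) {
  if (!isTRUE(all.equal(object@ic50, 10^object@logIC50)))
    return("ic50 must equal 10^logIC50")
  if (object@rss < 0) return("rss must be >= 0")
  TRUE
})

#' ScreenSimConfig: generative conditions for a synthetic paired-line screen
#'
#' Describes an arrayed library of `nGenes` genes x `sirnasPerGene` siRNAs
#' screened in two paired cell lines, the per-plate control layout, the
#' planted synthetic-lethal gene set and its per-line mean surviving
#' fractions, the well-level off-target rate, and the noise model
#' (multiplicative Gaussian well noise plus a log-normal per-plate effect).
#'
#' @slot nGenes,sirnasPerGene library dimensions.
#' @slot lineOver,lineCtrl identifiers of the overexpressing and control clones.
#' @slot plateSampleCapacity sample wells per 96-well plate.
#' @slot nNegControl,nPosControl,nDeathControl control wells per plate.
#' @slot plantedGenes explicit planted gene ids, or empty to sample
#'   `nPlanted` genes at simulation time.
#' @slot nPlanted size of the planted synthetic-lethal set.
#' @slot plantedSfOver,plantedSfCtrl mean surviving fraction of planted genes
#'   in each line.
#' @slot offtargetRate fraction of sample wells receiving an extra
#'   independent off-target lethality draw.
#' @slot wellNoiseSd sd of the multiplicative Gaussian well noise.
#' @slot plateEffectSd sd (log scale) of the multiplicative plate effect.
#' @slot posControlSf,deathControlSf true surviving fractions of the
#'   positive- and death-control wells.
#' @seealso [screenSimConfig()], [simulateScreen()]
#' @export
setClass("ScreenSimConfig",
  representation(nGenes = "integer", sirnasPerGene = "integer",
                 lineOver = "character", lineCtrl = "character",
                 plateSampleCapacity = "integer",
                 nNegControl = "integer", nPosControl = "integer",
                 nDeathControl = "integer",
                 plantedGenes = "character", nPlanted = "integer",
                 plantedSfOver = "numeric", plantedSfCtrl = "numeric",
                 offtargetRate = "numeric", wellNoiseSd = "numeric",
                 plateEffectSd = "numeric",
                 posControlSf = "numeric", deathControlSf = "numeric"))

setValidity("ScreenSimConfig", function(object) {
  msgs <- character()
  if (object@nGenes < 1 || object@sirnasPerGene < 1)
    msgs <- c(msgs, "nGenes and sirnasPerGene must be >= 1")
  if (object@nPlanted > object@nGenes)
    msgs <- c(msgs, "planted set cannot exceed the library size")
  fr <- c(object@plantedSfOver, object@plantedSfCtrl, object@offtargetRate,
          object@posControlSf, object@deathControlSf)
  if (any(fr < 0 | fr > 1))
    msgs <- c(msgs, "surviving fractions and rates must lie in [0, 1]")
  if (object@wellNoiseSd < 0 || object@plateEffectSd < 0)
    msgs <- c(msgs, "noise sds must be >= 0")
  if (object@nNegControl < 1)
    msgs <- c(msgs, "each plate needs at least one negative-control well")
  total <- object@plateSampleCapacity + object@nNegControl +
    object@nPosControl + object@nDeathControl
  if (total > 96L)
    msgs <- c(msgs, sprintf("plate layout needs %d wells but a plate has 96", total))
  if (length(msgs)) msgs else TRUE
})

#' ScreenTruth: ground-truth labels of a simulated screen
#'
#' @slot labels named logical vector over all library genes; `TRUE` marks a
#'   planted synthetic-lethal gene.
#' @slot wellTruth data.frame of per-well latent true surviving fractions
#'   (`plate_id`, `row`, `col`, `cell_line`, `gene`, `sirna_id`, `true_sf`).
#' @export
setClass("ScreenTruth",
  representation(labels = "logical", wellTruth = "data.frame"))

setValidity("ScreenTruth", function(object) {
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    return("labels must be uniquely named by gene")
  TRUE
})
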