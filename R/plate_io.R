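#' Read a long-format screen well table
#'
#' Parses a CSV (or an already-loaded data.frame) with one row per well into
#' a validated [ScreenDataset-class]. Required columns are
#' `plate_id,row,col,cell_line,sirna_id,gene,role,reading`; extra columns are
#' ignored. Row order in the file never matters: wells are stored in
#' canonical (cell line, plate, row, column) order. The siRNA library index
#' is reconstructed from the sample wells, siRNAs listed in order of first
#' appearance per gene.
#'
#' @param source path to a CSV file, a connection, or a data.frame.
#' @return a [ScreenDataset-class].
#' @examples
#' sim <- simulateScreen(screenSimConfig(nGenes = 10, nPlanted = 2), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeScreenTable(sim$dataset, f)
#' ds <- readScreenTable(f)
#' ds
#' @export
readScreenTable <- function(source) {
  df <- if (is.data.frame(source)) source
        else utils::read.csv(source, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.WELL_COLUMNS, names(df))
  if (length(missing_cols))
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[.WELL_COLUMNS]
  df$plate_id <- as.character(df$plate_id)
  df$row <- as.character(df$row)
  df$col <- as.integer(df$col)
  df$cell_line <- as.character(df$cell_line)
  df$sirna_id <- ifelse(is.na(df$sirna_id), "", as.character(df$sirna_id))
  df$gene <- ifelse(is.na(df$gene), "", as.character(df$gene))
  df$role <- as.character(df$role)
  df$reading <- as.numeric(df$reading)
  key <- paste(df$plate_id, df$row, df$col, sep = "/")
  if (anyDuplicated(key))
    stop("integrity error: duplicate well address ", key[duplicated(key)][1],
         call. = FALSE)
  if (any(!is.finite(df$reading) | df$reading < 0))
    stop("integrity error: readings must be finite and >= 0", call. = FALSE)
  newScreenDataset(df)
}

#' @rdname readScreenTable
#' @param wells a well data.frame with the canonical columns.
#' @param libraryIndex optional gene -> siRNA-id mapping; reconstructed from
#'   the sample wells when omitted.
#' @export
newScreenDataset <- function(wells, libraryIndex = NULL) {
  ord <- order(wells$cell_line, wells$plate_id, wells$row, wells$col)
  wells <- wells[ord, .WELL_COLUMNS, drop = FALSE]
  rownames(wells) <- NULL
  if (is.null(libraryIndex)) {
    samp <- wells[wells$role == "sample", , drop = FALSE]
    pairs <- unique(samp[c("gene", "sirna_id")])
    libraryIndex <- split(pairs$sirna_id, pairs$gene)
    libraryIndex <- libraryIndex[order(names(libraryIndex))]
  }
  new("ScreenDataset", wells = wells, libraryIndex = libraryIndex)
}

#' Per-plate control QC report
#'
#' Lists, for every plate in the dataset, the number of wells of each role,
#' and flags as fatal any plate without at least one negative-control well —
#' such a plate cannot be normalized to a surviving fraction.
#'
#' @param ds a [ScreenDataset-class].
#' @return data.frame with one row per plate: `plate_id`, `cell_line`,
#'   `n_sample`, `n_neg_control`, `n_pos_control`, `n_death_control`,
#'   `n_empty`, `fatal`.
#' @export
validateControls <- function(ds) {
  stopifnot(is(ds, "ScreenDataset"))
  w <- wells(ds)
  plates <- unique(w[c("plate_id", "cell_line")])
  counts <- lapply(.WELL_ROLES, function(r)
    as.vector(table(factor(w$plate_id[w$role == r],
                           levels = plates$plate_id))))
  names(counts) <- paste0("n_", .WELL_ROLES)
  out <- cbind(plates,
               n_sample = counts$n_sample,
               n_neg_control = counts$n_neg_control,
               n_pos_control = counts$n_pos_control,
               n_death_control = counts$n_death_control,
               n_empty = counts$n_empty)
  out$fatal <- out$n_neg_control == 0L
  out <- out[order(out$cell_line, out$plate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pipeline record tables to CSV at full float precision
#'
#' All pipeline outputs (well tables, surviving fractions, z-scores, hit
#' calls, QC reports, fit tables) are plain data.frames; `writeTable()`
#' serializes them so that `readRecordTable(writeTable(x)) == x` bit-exactly:
#' doubles are printed with 17 significant digits, which round-trips IEEE
#' doubles losslessly.
#'
#' @param records a data.frame (possibly 0-row; the header is still written).
#' @param path output file path or connection.
#' @param columns optional character vector selecting/ordering the columns to
#'   write (e.g. to emit a canonical file schema without bookkeeping columns).
#' @return `path`, invisibly.
#' @export
writeTable <- function(records, path, columns = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(records))
    if (length(missing_cols))
      stop("cannot write: records lack column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    records <- records[columns]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      # keep integer-valued doubles typed as doubles on re-read
      plain <- !is.na(out[[j]]) & is.finite(out[[j]]) & !grepl("[.eE]", v)
      v[plain] <- paste0(v[plain], ".0")
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' @rdname writeTable
#' @param colClasses optional named vector of column classes passed to the
#'   reader (types are otherwise inferred).
#' @export
readRecordTable <- function(path, colClasses = NA) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = colClasses)
}

#' @rdname readScreenTable
#' @param ds a [ScreenDataset-class] to serialize.
#' @param path output CSV path.
#' @export
writeScreenTable <- function(ds, path) {
  stopifnot(is(ds, "ScreenDataset"))
  writeTable(wells(ds), path, columns = .WELL_COLUMNS)
}
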