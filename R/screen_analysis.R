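#' Per-plate surviving fractions
#'
#' Normalizes every well reading by the median reading of the
#' negative-control (non-targeting siRNA) wells on the same plate. The
#' surviving fraction of a well equal to that median is exactly 1, and any
#' multiplicative plate effect (incubation time, reagent batch, reader gain)
#' cancels because it scales samples and controls alike. Control wells are
#' scored too, carrying their own surviving fraction.
#'
#' @param ds a [ScreenDataset-class].
#' @return data.frame with columns `cell_line`, `plate_id`, `gene`,
#'   `sirna_id`, `role`, `sf`.
#' @examples
#' sim <- simulateScreen(screenSimConfig(nGenes = 20, nPlanted = 2), seed = 7)
#' sf <- survivingFractions(sim$dataset)
#' head(sf)
#' @export
survivingFractions <- function(ds) {
  stopifnot(is(ds, "ScreenDataset"))
  w <- wells(ds)
  w <- w[w$role != "empty", , drop = FALSE]
  neg <- w$role == "neg_control"
  plate_levels <- unique(w$plate_id)
  has_neg <- plate_levels %in% w$plate_id[neg]
  if (!all(has_neg))
    stop("normalization error: plate(s) without negative-control wells: ",
         paste(plate_levels[!has_neg], collapse = ", "), call. = FALSE)
  neg_med <- c(tapply(w$reading[neg], w$plate_id[neg], stats::median))
  if (any(neg_med == 0))
    stop("degenerate plate: negative-control median is zero on plate(s): ",
         paste(names(neg_med)[neg_med == 0], collapse = ", "), call. = FALSE)
  data.frame(cell_line = w$cell_line, plate_id = w$plate_id,
             gene = w$gene, sirna_id = w$sirna_id, role = w$role,
             sf = as.vector(w$reading / unname(neg_med[w$plate_id])),
             stringsAsFactors = FALSE)
}

#' Median-centered robust z-scores of surviving fractions
#'
#' Standardizes surviving fractions within strata as
#' `z = (sf - median(sf_sample)) / scale`, where the center and scale are
#' estimated from the stratum's sample wells only (controls are scored but
#' never shape the reference distribution). The default scale is the
#' normal-consistent MAD, `1.4826 * median(|sf - median|)`, robust against
#' the lethal tail the screen is designed to find; the sample standard
#' deviation is available for comparison. Strata are plates by default,
#' guarding against residual plate effects; per-cell-line pooling suits
#' single-plate data.
#'
#' If the MAD is zero the stratum falls back to the sd with a warning; if
#' that is also zero every z in the stratum is set to 0 with a warning.
#'
#' @param sf surviving-fraction records from [survivingFractions()].
#' @param stratify `"per_plate"` (default) or `"per_cell_line"`.
#' @param scale `"mad"` (default) or `"sd"`.
#' @return data.frame `cell_line`, `gene`, `sirna_id`, `surviving_fraction`,
#'   `zscore`, `plate_id`, `role`. Within every stratum the median z of
#'   sample wells is 0 by construction.
#' @export
medianCenteredZscores <- function(sf,
                                  stratify = c("per_plate", "per_cell_line"),
                                  scale = c("mad", "sd")) {
  stratify <- match.arg(stratify)
  scale <- match.arg(scale)
  stopifnot(is.data.frame(sf),
            all(c("cell_line", "plate_id", "gene", "sirna_id", "role", "sf")
                %in% names(sf)))
  stratum <- if (stratify == "per_plate")
    paste(sf$cell_line, sf$plate_id, sep = "\r") else sf$cell_line
  z <- numeric(nrow(sf))
  for (s in unique(stratum)) {
    idx <- stratum == s
    samp <- idx & sf$role == "sample"
    if (sum(samp) < 4L)
      stop("z-scoring needs >= 4 sample wells per stratum; stratum '",
           gsub("\r", "/", s), "' has ", sum(samp), call. = FALSE)
    x <- sf$sf[samp]
    ctr <- stats::median(x)
    sc <- if (scale == "mad") 1.4826 * stats::median(abs(x - ctr)) else stats::sd(x)
    if (scale == "mad" && sc == 0) {
      warning("MAD is zero in stratum '", gsub("\r", "/", s),
              "'; falling back to sd", call. = FALSE)
      sc <- stats::sd(x)
    }
    if (sc == 0) {
      warning("degenerate stratum '", gsub("\r", "/", s),
              "': zero scale, all z set to 0", call. = FALSE)
      z[idx] <- 0
    } else {
      z[idx] <- (sf$sf[idx] - ctr) / sc
    }
  }
  data.frame(cell_line = sf$cell_line, gene = sf$gene, sirna_id = sf$sirna_id,
             surviving_fraction = sf$sf, zscore = z, plate_id = sf$plate_id,
             role = sf$role, stringsAsFactors = FALSE)
}

#' Pair gene-level z-score vectors across the two screened lines
#'
#' Collects, for every library gene, the siRNA-level z-scores of its duplexes
#' in the overexpressing and control lines, aligned by siRNA id (sorted
#' within gene). Combinations measured in one line but not the other are NA
#' in the matrices and enumerated in the missing-data report rather than
#' silently dropped.
#'
#' @param z z-score records from [medianCenteredZscores()].
#' @param lineOver,lineCtrl cell-line identifiers of the overexpressing and
#'   control clones.
#' @return a [PairedScreenZ-class].
#' @export
aggregateGenes <- function(z, lineOver, lineCtrl) {
  stopifnot(is.data.frame(z),
            all(c("cell_line", "gene", "sirna_id", "zscore", "role")
                %in% names(z)))
  present <- unique(z$cell_line)
  for (ln in c(lineOver, lineCtrl))
    if (!ln %in% present)
      stop("unknown cell line: '", ln, "' (dataset has: ",
           paste(present, collapse = ", "), ")", call. = FALSE)
  zs <- z[z$role == "sample" & z$cell_line %in% c(lineOver, lineCtrl), ,
          drop = FALSE]
  genes <- sort(unique(zs$gene))
  sirnas <- lapply(split(zs$sirna_id, zs$gene)[genes],
                   function(s) sort(unique(s)))
  k <- if (length(sirnas)) max(lengths(sirnas)) else 0L
  fill <- function(line) {
    m <- matrix(NA_real_, nrow = length(genes), ncol = k,
                dimnames = list(genes, if (k) paste0("si", seq_len(k))))
    sub <- zs[zs$cell_line == line, , drop = FALSE]
    if (nrow(sub)) {
      slot_idx <- mapply(function(g, s) match(s, sirnas[[g]]),
                         sub$gene, sub$sirna_id)
      m[cbind(match(sub$gene, genes), slot_idx)] <- sub$zscore
    }
    m
  }
  zo <- fill(lineOver)
  zc <- fill(lineCtrl)
  miss <- data.frame(gene = character(), sirna_id = character(),
                     missing_in = character(), stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    sl <- seq_along(sirnas[[i]])
    for (line_m in list(list(zo, lineOver), list(zc, lineCtrl))) {
      na_slots <- sl[is.na(line_m[[1]][i, sl])]
      if (length(na_slots))
        miss <- rbind(miss, data.frame(
          gene = genes[i], sirna_id = sirnas[[i]][na_slots],
          missing_in = line_m[[2]], stringsAsFactors = FALSE))
    }
  }
  new("PairedScreenZ", genes = genes, sirnas = sirnas, zOver = zo, zCtrl = zc,
      missing = miss, lineOver = lineOver, lineCtrl = lineCtrl)
}

#' Concordance-based synthetic-lethality hit calling
#'
#' A gene is called a hit when at least `minConcordant` of its siRNAs score
#' below `threshold` (strict inequality) in the overexpressing line — the
#' multiple-duplex concordance rule that guards against single-siRNA
#' off-target artifacts — and its selectivity, the mean siRNA z in the
#' overexpressing line minus the mean in the control line, is at most
#' `selectivityMargin`, so that genes lethal in both clones are excluded.
#' Genes with any unmeasured siRNA are never hits (concordance cannot be
#' evaluated) and appear in the missing-data report of the input.
#'
#' @param pz a [PairedScreenZ-class] from [aggregateGenes()].
#' @param threshold z-score cutoff (must be negative); default -2.
#' @param minConcordant minimum number of siRNAs below the cutoff; default 2.
#' @param selectivityMargin maximum allowed mean-z difference
#'   (overexpressing - control); default -1.
#' @return data.frame sorted by ascending mean z in the overexpressing line:
#'   `gene`, `n_sirnas_below`, `hit`, `min_z_line_a` (overexpressing),
#'   `min_z_line_b` (control), `selectivity`, `mean_z_overexpr`,
#'   `mean_z_control`, `complete`.
#' @examples
#' sim <- simulateScreen(screenSimConfig(), seed = 1)
#' z <- medianCenteredZscores(survivingFractions(sim$dataset))
#' pz <- aggregateGenes(z, "M2.1", "V11")
#' hits <- callHits(pz)
#' head(subset(hits, hit))
#' @export
callHits <- function(pz, threshold = -2, minConcordant = 2L,
                     selectivityMargin = -1) {
  stopifnot(is(pz, "PairedScreenZ"))
  if (!(threshold < 0)) stop("threshold must be negative", call. = FALSE)
  k <- ncol(pz@zOver)
  if (minConcordant < 1L || minConcordant > k)
    stop("minConcordant must lie in [1, ", k, "]", call. = FALSE)
  n_below <- rowSums(pz@zOver < threshold, na.rm = TRUE)
  mean_over <- rowMeans(pz@zOver, na.rm = TRUE)
  mean_ctrl <- rowMeans(pz@zCtrl, na.rm = TRUE)
  # matrices may carry trailing NA slots for genes with fewer siRNAs; a gene
  # is complete when every slot backed by a library siRNA is measured
  n_lib <- lengths(pz@sirnas)
  measured_over <- rowSums(!is.na(pz@zOver))
  measured_ctrl <- rowSums(!is.na(pz@zCtrl))
  complete <- measured_over == n_lib & measured_ctrl == n_lib
  selectivity <- mean_over - mean_ctrl
  hit <- complete & n_below >= minConcordant & selectivity <= selectivityMargin
  out <- data.frame(
    gene = pz@genes,
    n_sirnas_below = as.integer(n_below),
    hit = hit,
    min_z_line_a = suppressWarnings(apply(pz@zOver, 1, min, na.rm = TRUE)),
    min_z_line_b = suppressWarnings(apply(pz@zCtrl, 1, min, na.rm = TRUE)),
    selectivity = selectivity,
    mean_z_overexpr = mean_over,
    mean_z_control = mean_ctrl,
    complete = complete,
    stringsAsFactors = FALSE)
  out <- out[order(out$mean_z_overexpr, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Z-score matrix of the called hits
#'
#' Restricts the paired z-score matrices to the hit genes, in the
#' deterministic hit-table order (ascending mean z in the overexpressing
#' line), with one column per (cell line, siRNA slot) — the matrix behind a
#' candidate heat map.
#'
#' @param hits hit table from [callHits()].
#' @param pz the [PairedScreenZ-class] the hits were called from.
#' @return numeric matrix, hit genes x 2k columns named
#'   `<line>.si1..sik`; 0-row when there are no hits.
#' @export
hitMatrix <- function(hits, pz) {
  stopifnot(is(pz, "PairedScreenZ"), is.data.frame(hits))
  genes <- hits$gene[hits$hit]
  k <- ncol(pz@zOver)
  m <- cbind(pz@zOver[match(genes, pz@genes), , drop = FALSE],
             pz@zCtrl[match(genes, pz@genes), , drop = FALSE])
  dimnames(m) <- list(genes,
                      c(paste(pz@lineOver, colnames(pz@zOver), sep = "."),
                        paste(pz@lineCtrl, colnames(pz@zCtrl), sep = ".")))
  m
}

#' Run the whole screen chain with one call
#'
#' Convenience wrapper: surviving fractions, z-scores, gene aggregation and
#' hit calling with a single set of parameters.
#'
#' @inheritParams survivingFractions
#' @inheritParams medianCenteredZscores
#' @inheritParams aggregateGenes
#' @inheritParams callHits
#' @return list with `sf`, `z`, `paired` ([PairedScreenZ-class]), `hits`, and
#'   `hitMatrix`.
#' @export
screenPipeline <- function(ds, lineOver, lineCtrl,
                           stratify = "per_plate", scale = "mad",
                           threshold = -2, minConcordant = 2L,
                           selectivityMargin = -1) {
  sf <- survivingFractions(ds)
  z <- medianCenteredZscores(sf, stratify = stratify, scale = scale)
  pz <- aggregateGenes(z, lineOver, lineCtrl)
  hits <- callHits(pz, threshold = threshold, minConcordant = minConcordant,
                   selectivityMargin = selectivityMargin)
  list(sf = sf, z = z, paired = pz, hits = hits,
       hitMatrix = hitMatrix(hits, pz))
}
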