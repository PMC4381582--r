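#' Relative-quantification fold changes from threshold cycles
#'
#' Classic delta-delta-Ct: technical replicates are averaged per
#' (sample, gene); each target gene's mean Ct is normalized by the arithmetic
#' mean of the housekeeping-gene Cts of the same sample (equivalent to the
#' geometric mean of housekeeping expression), giving delta-Ct; subtracting
#' the reference sample's delta-Ct gives delta-delta-Ct; the fold change is
#' `efficiency^(-ddCt)`, with the textbook perfect-doubling efficiency of 2
#' by default. The reference sample's own fold change is exactly 1. A uniform
#' Ct shift of a whole sample (pipetting/input amount) cancels in the
#' housekeeping normalization.
#'
#' @param records data.frame with columns `sample`, `gene`, `ct` and
#'   optionally `replicate`.
#' @param housekeeping character vector of housekeeping gene names (e.g.
#'   `c("18S", "ACTB")`); every sample must have all of them measured.
#' @param referenceSample sample identifier the fold changes are relative to.
#' @param efficiency amplification efficiency per cycle; default 2.
#' @return data.frame `sample`, `gene`, `delta_ct`, `ddct`, `fold` for every
#'   non-housekeeping gene.
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("ref", "kd"), each = 3),
#'   gene   = rep(c("PCTK1", "18S", "ACTB"), 2),
#'   ct     = c(26, 10, 20, 24, 10, 20))
#' foldChanges(ct, c("18S", "ACTB"), "ref")  # kd fold = 0.25^-1 ... = 4
#' @export
foldChanges <- function(records, housekeeping, referenceSample,
                        efficiency = 2) {
  stopifnot(is.data.frame(records),
            all(c("sample", "gene", "ct") %in% names(records)),
            length(housekeeping) >= 1, efficiency > 1)
  if (any(!is.finite(records$ct)))
    stop("data error: non-finite Ct value", call. = FALSE)
  if (!referenceSample %in% records$sample)
    stop("unknown reference sample: '", referenceSample, "'", call. = FALSE)
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = records, FUN = mean)
  for (s in unique(mean_ct$sample)) {
    have <- mean_ct$gene[mean_ct$sample == s]
    lack <- setdiff(housekeeping, have)
    if (length(lack))
      stop("data error: sample '", s, "' lacks housekeeping gene(s): ",
           paste(lack, collapse = ", "), call. = FALSE)
  }
  hk <- mean_ct[mean_ct$gene %in% housekeeping, , drop = FALSE]
  hk_mean <- c(tapply(hk$ct, hk$sample, mean))
  tg <- mean_ct[!mean_ct$gene %in% housekeeping, , drop = FALSE]
  tg$delta_ct <- as.vector(tg$ct - unname(hk_mean[tg$sample]))
  ref <- tg[tg$sample == referenceSample, , drop = FALSE]
  idx <- match(tg$gene, ref$gene)
  if (any(is.na(idx)))
    stop("data error: gene(s) missing in reference sample: ",
         paste(unique(tg$gene[is.na(idx)]), collapse = ", "), call. = FALSE)
  tg$ddct <- tg$delta_ct - ref$delta_ct[idx]
  tg$fold <- efficiency^(-tg$ddct)
  # the reference is its own baseline by definition; avoid 2^-0 round-off
  tg$fold[tg$sample == referenceSample] <- 1
  out <- tg[order(tg$gene, tg$sample),
            c("sample", "gene", "delta_ct", "ddct", "fold")]
  rownames(out) <- NULL
  out
}

#' Log2 expression relative to a reference sample
#'
#' Maps fold changes to log2 scale with the reference sample pinned at 0,
#' the usual presentation for expression panels against a normal-tissue
#' baseline.
#'
#' @param folds output of [foldChanges()] (needs `sample`, `gene`, `fold`).
#' @param referenceSample the sample mapped to 0.
#' @return the input with a `log2_fold` column added.
#' @export
log2NormalizeToReference <- function(folds, referenceSample) {
  stopifnot(is.data.frame(folds),
            all(c("sample", "gene", "fold") %in% names(folds)))
  if (any(folds$fold <= 0))
    stop("domain error: fold changes must be > 0", call. = FALSE)
  if (!referenceSample %in% folds$sample)
    stop("unknown reference sample: '", referenceSample, "'", call. = FALSE)
  out <- folds
  out$log2_fold <- log2(out$fold)
  out$log2_fold[out$sample == referenceSample] <- 0
  out
}
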