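#' Build a screen-simulation configuration
#'
#' Default values emulate the screened system: a kinome-scale arrayed library
#' of 719 genes with 3 siRNA duplexes each, transfected in parallel into a
#' c-Myc-overexpressing clone ("M2.1") and its empty-vector control ("V11"),
#' on 96-well plates carrying 80 sample wells plus 8 non-targeting negative
#' controls, 4 lethal positive controls and 4 cell-death controls. A planted
#' set of 5 synthetic-lethal genes has mean surviving fraction 0.4 in the
#' overexpressing line and 1.0 in the control line; 2% of sample wells
#' receive an extra independent off-target lethality draw; well noise is
#' multiplicative Gaussian with sd 0.05 and plates carry a log-normal
#' multiplicative effect with log-sd 0.05.
#'
#' @param nGenes,sirnasPerGene library dimensions.
#' @param lineOver,lineCtrl cell-line identifiers.
#' @param plateSampleCapacity sample wells per plate.
#' @param nNegControl,nPosControl,nDeathControl control wells per plate.
#' @param plantedGenes explicit planted gene ids (must be library genes), or
#'   `NULL` to sample `nPlanted` genes at simulation time.
#' @param nPlanted planted-set size when `plantedGenes` is `NULL`.
#' @param plantedSfOver,plantedSfCtrl planted mean surviving fractions.
#' @param offtargetRate fraction of sample wells with an off-target draw.
#' @param wellNoiseSd,plateEffectSd noise model parameters.
#' @param posControlSf,deathControlSf control-well true surviving fractions.
#' @return a [ScreenSimConfig-class].
#' @export
screenSimConfig <- function(nGenes = 719L, sirnasPerGene = 3L,
                            lineOver = "M2.1", lineCtrl = "V11",
                            plateSampleCapacity = 80L,
                            nNegControl = 8L, nPosControl = 4L,
                            nDeathControl = 4L,
                            plantedGenes = NULL, nPlanted = 5L,
                            plantedSfOver = 0.4, plantedSfCtrl = 1.0,
                            offtargetRate = 0.02, wellNoiseSd = 0.05,
                            plateEffectSd = 0.05,
                            posControlSf = 0.3, deathControlSf = 0.05) {
  new("ScreenSimConfig",
      nGenes = as.integer(nGenes), sirnasPerGene = as.integer(sirnasPerGene),
      lineOver = lineOver, lineCtrl = lineCtrl,
      plateSampleCapacity = as.integer(plateSampleCapacity),
      nNegControl = as.integer(nNegControl),
      nPosControl = as.integer(nPosControl),
      nDeathControl = as.integer(nDeathControl),
      plantedGenes = if (is.null(plantedGenes)) character() else plantedGenes,
      nPlanted = as.integer(if (is.null(plantedGenes)) nPlanted
                            else length(plantedGenes)),
      plantedSfOver = plantedSfOver, plantedSfCtrl = plantedSfCtrl,
      offtargetRate = offtargetRate, wellNoiseSd = wellNoiseSd,
      plateEffectSd = plateEffectSd,
      posControlSf = posControlSf, deathControlSf = deathControlSf)
}

# 96-well positions in row-major order: A1..A12, B1..B12, ...
.platePositions <- function() {
  data.frame(row = rep(LETTERS[1:8], each = 12L),
             col = rep(1:12, times = 8L), stringsAsFactors = FALSE)
}

#' Simulate a paired-line arrayed siRNA viability screen
#'
#' Lays the library out plate by plate (the same physical layout replicated
#' in each cell line, with per-line plate identifiers), assigns every well a
#' latent true surviving fraction — 1 for untargeted-effect wells and
#' negative controls, the planted per-line fractions for synthetic-lethal
#' genes, the configured fractions for positive/death controls — applies the
#' off-target draw (an extra multiplicative viability factor drawn uniformly
#' from \[0.5, 1\] on a random 2% of sample wells, modelling partial rogue
#' knockdown of unintended transcripts), and emits readings
#' `plate_effect * true_sf * (1 + N(0, wellNoiseSd))`, floored at 0.
#' The generator is a pure function of `(cfg, seed)`.
#'
#' @param cfg a [ScreenSimConfig-class].
#' @param seed integer RNG seed.
#' @return list with `dataset` (a [ScreenDataset-class]) and `truth`
#'   (a [ScreenTruth-class]).
#' @examples
#' sim <- simulateScreen(screenSimConfig(nGenes = 30, nPlanted = 3), seed = 42)
#' sim$dataset
#' sum(truthLabels(sim$truth))
#' @export
simulateScreen <- function(cfg, seed) {
  stopifnot(is(cfg, "ScreenSimConfig"))
  validObject(cfg)
  withr::with_seed(seed, {
    genes <- sprintf("KIN%04d", seq_len(cfg@nGenes))
    sirnas <- lapply(genes, function(g)
      paste0(g, "_si", seq_len(cfg@sirnasPerGene)))
    names(sirnas) <- genes
    planted <- if (length(cfg@plantedGenes)) {
      bad <- setdiff(cfg@plantedGenes, genes)
      if (length(bad))
        stop("config error: planted gene(s) not in library: ",
             paste(bad, collapse = ", "), call. = FALSE)
      cfg@plantedGenes
    } else sample(genes, cfg@nPlanted)

    lib <- data.frame(gene = rep(genes, each = cfg@sirnasPerGene),
                      sirna_id = unlist(sirnas), stringsAsFactors = FALSE)
    n_samp <- nrow(lib)
    n_plates <- ceiling(n_samp / cfg@plateSampleCapacity)
    plate_of <- rep(seq_len(n_plates), each = cfg@plateSampleCapacity)[seq_len(n_samp)]
    within_plate <- (seq_len(n_samp) - 1L) %% cfg@plateSampleCapacity + 1L
    pos <- .platePositions()

    ctrl_roles <- rep(c("neg_control", "pos_control", "death_control"),
                      times = c(cfg@nNegControl, cfg@nPosControl,
                                cfg@nDeathControl))
    ctrl_sf <- rep(c(1, cfg@posControlSf, cfg@deathControlSf),
                   times = c(cfg@nNegControl, cfg@nPosControl,
                             cfg@nDeathControl))

    one_line <- function(line, sf_planted) {
      true_sf <- ifelse(lib$gene %in% planted, sf_planted, 1)
      ot <- stats::runif(n_samp) < cfg@offtargetRate
      true_sf[ot] <- true_sf[ot] * stats::runif(sum(ot), 0.5, 1)
      samp <- data.frame(
        plate_id = sprintf("%s_P%02d", line, plate_of),
        row = pos$row[within_plate], col = pos$col[within_plate],
        cell_line = line, sirna_id = lib$sirna_id, gene = lib$gene,
        role = "sample", true_sf = true_sf, stringsAsFactors = FALSE)
      ctrl <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
        slots <- cfg@plateSampleCapacity + seq_along(ctrl_roles)
        data.frame(plate_id = sprintf("%s_P%02d", line, p),
                   row = pos$row[slots], col = pos$col[slots],
                   cell_line = line, sirna_id = "", gene = "",
                   role = ctrl_roles, true_sf = ctrl_sf,
                   stringsAsFactors = FALSE)
      }))
      w <- rbind(samp, ctrl)
      plate_eff <- exp(stats::rnorm(n_plates, 0, cfg@plateEffectSd))
      names(plate_eff) <- sprintf("%s_P%02d", line, seq_len(n_plates))
      w$reading <- pmax(0, unname(plate_eff[w$plate_id]) * w$true_sf *
                          (1 + stats::rnorm(nrow(w), 0, cfg@wellNoiseSd)))
      w
    }
    over <- one_line(cfg@lineOver, cfg@plantedSfOver)
    ctrl <- one_line(cfg@lineCtrl, cfg@plantedSfCtrl)
    all_wells <- rbind(over, ctrl)
    truth_wells <- all_wells[c("plate_id", "row", "col", "cell_line",
                               "gene", "sirna_id", "true_sf")]
    ds <- newScreenDataset(all_wells[.WELL_COLUMNS], libraryIndex = sirnas)
    labels <- stats::setNames(genes %in% planted, genes)
    list(dataset = ds,
         truth = new("ScreenTruth", labels = labels, wellTruth = truth_wells))
  })
}

#' Simulate dose-response series from a known 4PL curve
#'
#' Draws `nSeries` independent titration series: at every dose the response
#' is the 4PL mean plus Gaussian noise (percent points). Pure function of
#' its arguments and the seed.
#'
#' @param bottom,top,hill,ic50 generative 4PL parameters (ic50 in molar).
#' @param doses concentration grid, molar (> 0, non-empty).
#' @param noiseSd response noise sd, percent points.
#' @param nSeries number of independent series.
#' @param seed integer RNG seed.
#' @return data.frame `series`, `concentration`, `response`.
#' @export
simulateDoseResponse <- function(bottom = 0, top = 100, hill = 1,
                                 ic50 = 53e-9, doses, noiseSd = 3,
                                 nSeries = 1L, seed) {
  if (length(doses) == 0)
    stop("config error: empty dose list", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  mu <- .fourPL(doses, bottom, top, hill, log10(ic50))
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nSeries), function(s)
      data.frame(series = s, concentration = doses,
                 response = mu + stats::rnorm(length(doses), 0, noiseSd))))
  })
}

#' Simulate qPCR threshold cycles from a fold-change design
#'
#' Every (sample, gene) pair of the design yields technical replicates with
#' `Ct = base_ct - log2(fold) + N(0, ctNoiseSd)`: a 2-fold expression
#' increase surfaces one cycle earlier. Housekeeping genes must be present in
#' the design with fold 1 (zero effect) in every sample, mirroring their
#' stable-expression assumption.
#'
#' @param design data.frame with columns `sample`, `gene`, `fold` and
#'   optionally `base_ct` (default 20 when absent; housekeeping rows often
#'   carry their own, e.g. 10 for an abundant rRNA).
#' @param housekeeping character vector of housekeeping gene names.
#' @param ctNoiseSd technical Ct noise sd; default 0.15 cycles.
#' @param nReplicates technical replicates per (sample, gene); default 3.
#' @param seed integer RNG seed.
#' @return data.frame `sample`, `gene`, `ct`, `replicate`.
#' @export
simulateQpcr <- function(design, housekeeping, ctNoiseSd = 0.15,
                         nReplicates = 3L, seed) {
  stopifnot(is.data.frame(design),
            all(c("sample", "gene", "fold") %in% names(design)))
  if (!"base_ct" %in% names(design)) design$base_ct <- 20
  hk <- design[design$gene %in% housekeeping, , drop = FALSE]
  for (s in unique(design$sample)) {
    have <- hk[hk$sample == s, , drop = FALSE]
    if (!all(housekeeping %in% have$gene))
      stop("config error: sample '", s,
           "' lacks a housekeeping gene in the design", call. = FALSE)
  }
  if (any(hk$fold != 1))
    stop("config error: housekeeping genes must have fold 1 (zero effect)",
         call. = FALSE)
  withr::with_seed(seed, {
    n <- nrow(design)
    out <- design[rep(seq_len(n), each = nReplicates),
                  c("sample", "gene", "fold", "base_ct")]
    out$replicate <- rep(seq_len(nReplicates), times = n)
    out$ct <- out$base_ct - log2(out$fold) +
      stats::rnorm(nrow(out), 0, ctNoiseSd)
    rownames(out) <- NULL
    out[c("sample", "gene", "ct", "replicate")]
  })
}

#' Simulate a CAM xenograft pre/post diameter table
#'
#' Per embryo, a latent pre-treatment tumor size is drawn log-normally
#' around `meanDiameter` (mm); the two perpendicular pre-diameters scatter
#' multiplicatively around it, and post-diameters are the pre-diameters
#' times the group's growth factor times multiplicative noise. A treated
#' factor below 1 therefore yields predominantly shrinking volumes. With
#' zero noise and factor 1 the volume change is exactly 0.
#'
#' @param nPerGroup named integer vector, embryos per group, e.g.
#'   `c(vehicle = 8, treated = 8)`.
#' @param growthFactors named numeric vector of per-group multiplicative
#'   diameter factors over the treatment window, e.g.
#'   `c(vehicle = 1.3, treated = 0.8)`.
#' @param noiseSd sd of the multiplicative diameter noise; default 0.05.
#' @param meanDiameter median pre-treatment diameter, mm; default 3.
#' @param sizeSpreadSd log-sd of the between-embryo size distribution;
#'   default 0.15.
#' @param cellLine cell-line label for the records.
#' @param seed integer RNG seed.
#' @return data.frame `embryo_id`, `group`, `cell_line`, `d1_pre`, `d2_pre`,
#'   `d1_post`, `d2_post` (mm), ready for [growthAnalysis()].
#' @export
simulateCam <- function(nPerGroup = c(vehicle = 8L, treated = 8L),
                        growthFactors = c(vehicle = 1.3, treated = 0.8),
                        noiseSd = 0.05, meanDiameter = 3,
                        sizeSpreadSd = 0.15, cellLine = "M2.1", seed) {
  stopifnot(!is.null(names(nPerGroup)),
            all(names(nPerGroup) %in% names(growthFactors)))
  if (noiseSd < 0 || meanDiameter <= 0)
    stop("config error: noiseSd must be >= 0 and meanDiameter > 0",
         call. = FALSE)
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(names(nPerGroup), function(g) {
      n <- nPerGroup[[g]]
      if (n == 0) return(NULL)
      base <- stats::rlnorm(n, log(meanDiameter), sizeSpreadSd)
      d1_pre <- base * (1 + stats::rnorm(n, 0, noiseSd))
      d2_pre <- base * (1 + stats::rnorm(n, 0, noiseSd))
      f <- growthFactors[[g]]
      data.frame(embryo_id = sprintf("%s_%02d", g, seq_len(n)),
                 group = g, cell_line = cellLine,
                 d1_pre = d1_pre, d2_pre = d2_pre,
                 d1_post = d1_pre * f * (1 + stats::rnorm(n, 0, noiseSd)),
                 d2_post = d2_pre * f * (1 + stats::rnorm(n, 0, noiseSd)),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}
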