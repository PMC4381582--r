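#' Tumor volume from two perpendicular diameters
#'
#' Spherical volume `V = (4/3) * pi * r^3` with the radius taken, under the
#' default `"geomean"` rule, as half the geometric mean of the two
#' perpendicular caliper diameters, `r = sqrt(d1 * d2) / 2` — the standard
#' two-diameter estimate for roughly spheroidal xenografts, symmetric in
#' `(d1, d2)`. The alternative `"single-diameter"` rule uses half the
#' arithmetic mean diameter, `r = (d1 + d2) / 4`, for the reading of the
#' formula in which a single representative diameter is halved.
#'
#' @param d1,d2 perpendicular tumor diameters, mm (> 0); vectorized.
#' @param radiusRule `"geomean"` (default) or `"single-diameter"`.
#' @return tumor volume in mm^3.
#' @examples
#' tumorVolume(2, 2)   # sphere of radius 1: 4*pi/3
#' tumorVolume(4, 1)   # same volume under the geometric-mean rule
#' @export
tumorVolume <- function(d1, d2, radiusRule = c("geomean", "single-diameter")) {
  radiusRule <- match.arg(radiusRule)
  if (any(!is.finite(d1)) || any(!is.finite(d2)) || any(d1 <= 0) || any(d2 <= 0))
    stop("domain error: diameters must be finite and > 0", call. = FALSE)
  r <- switch(radiusRule,
              geomean = sqrt(d1 * d2) / 2,
              `single-diameter` = (d1 + d2) / 4)
  (4 / 3) * pi * r^3
}

#' Pre/post-treatment tumor growth analysis
#'
#' Computes per-embryo volumes before and after treatment from the four
#' caliper diameters, the volume change `delta_v = v_post - v_pre`, and
#' classifies a tumor as regressing iff `delta_v < 0` (strict: an unchanged
#' tumor is not regressing). Group summaries are computed over embryos.
#'
#' @param records data.frame with columns `embryo_id`, `group`, `cell_line`,
#'   `d1_pre`, `d2_pre`, `d1_post`, `d2_post` (mm). `group` may be a factor;
#'   unused levels are reported with `n = 0`.
#' @param radiusRule passed to [tumorVolume()].
#' @return list with `perEmbryo` (input plus `v_pre`, `v_post`, `delta_v`,
#'   `regressing`) and `perGroup` (`group`, `n`, `mean_delta_v`,
#'   `n_regressing`).
#' @export
growthAnalysis <- function(records, radiusRule = "geomean") {
  need <- c("embryo_id", "group", "cell_line",
            "d1_pre", "d2_pre", "d1_post", "d2_post")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  dd <- records[c("d1_pre", "d2_pre", "d1_post", "d2_post")]
  if (any(!stats::complete.cases(dd)))
    stop("data error: every record needs all four diameters", call. = FALSE)
  per <- records
  per$v_pre <- tumorVolume(per$d1_pre, per$d2_pre, radiusRule)
  per$v_post <- tumorVolume(per$d1_post, per$d2_post, radiusRule)
  per$delta_v <- per$v_post - per$v_pre
  per$regressing <- per$delta_v < 0
  grp <- if (is.factor(per$group)) levels(per$group) else unique(per$group)
  summ <- do.call(rbind, lapply(grp, function(g) {
    sub <- per[as.character(per$group) == g, , drop = FALSE]
    data.frame(group = g, n = nrow(sub),
               mean_delta_v = if (nrow(sub)) mean(sub$delta_v) else NA_real_,
               n_regressing = sum(sub$regressing),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(perEmbryo = per, perGroup = summ)
}
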