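#' Residual kinase activity from radiometric counts
#'
#' Converts scintillation counts (cpm) of a compound well into percent
#' residual activity between the assay's low control (no enzyme / full
#' inhibition) and high control (no inhibitor):
#' `100 * (cpm - low) / (high - low)`. A well matching the high control is
#' 100%, one matching the low control 0%. With noisy counts the result can
#' leave `[0, 100]`; it is not clipped unless asked, so that fitting sees the
#' raw scatter.
#'
#' @param cpm numeric vector of compound-well counts.
#' @param lowControl,highControl scalar control counts; `highControl` must
#'   exceed `lowControl`.
#' @param clip clamp the result into `[0, 100]`? Default `FALSE`.
#' @return percent residual activity, same length as `cpm`.
#' @examples
#' residualActivity(550, 100, 1000)   # 50
#' residualActivity(1000, 100, 1000)  # 100
#' @export
residualActivity <- function(cpm, lowControl, highControl, clip = FALSE) {
  if (!(highControl > lowControl))
    stop("degenerate assay: high control must exceed low control",
         call. = FALSE)
  if (any(cpm < 0) || lowControl < 0)
    stop("counts must be >= 0", call. = FALSE)
  out <- 100 * (cpm - lowControl) / (highControl - lowControl)
  if (clip) out <- pmin(pmax(out, 0), 100)
  out
}

# 4PL mean response at concentration conc (molar)
.fourPL <- function(conc, bottom, top, hill, logIC50) {
  bottom + (top - bottom) / (1 + 10^((logIC50 - log10(conc)) * hill))
}

# One Levenberg-Marquardt run with box constraints; parameters whose lower
# and upper bounds coincide are held fixed rather than optimized.
.fitOnce <- function(conc, response, start, lower, upper) {
  nm <- c("bottom", "top", "hill", "logIC50")
  start <- start[nm]; lower <- lower[nm]; upper <- upper[nm]
  free <- (upper - lower) > 1e-12
  full <- (lower + upper) / 2
  resid_fn <- function(p) {
    full[free] <- p
    response - .fourPL(conc, full[["bottom"]], full[["top"]],
                       full[["hill"]], full[["logIC50"]])
  }
  if (!any(free))
    return(list(par = full, rss = sum(resid_fn(numeric(0))^2)))
  p0 <- pmin(pmax(start[free], lower[free]), upper[free])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn,
                       lower = lower[free], upper = upper[free],
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  full[free] <- fit$par
  list(par = full, rss = sum(fit$fvec^2))
}

#' Fit a four-parameter logistic (variable slope) dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((logIC50 - log10(c)) * hill))`
#' by Levenberg-Marquardt with box constraints, restarted from a fixed
#' deterministic grid: `logIC50` starts at every observed log-dose and the
#' hill slope at 0.5, 1 and 2; the start with the smallest residual sum of
#' squares wins, ties broken toward the hill slope closest to 1. Default
#' constraints (`bottom` in \[-10, 50\], `top` in \[50, 120\], `hill` in
#' (0, 5\]) encode a decreasing percent-scale inhibition curve and are fully
#' overridable. An optional seeded case-resampling percentile bootstrap gives
#' a confidence interval on the IC50.
#'
#' @param conc dose concentrations, molar (> 0).
#' @param response measured responses, percent.
#' @param constraints list with elements `bottom`, `top`, `hill`, each
#'   `c(lower, upper)`; equal bounds hold a parameter fixed.
#' @param nBoot number of bootstrap resamples for the IC50 CI (0 = none).
#' @param seed integer RNG seed for the bootstrap; required when `nBoot > 0`.
#' @param level CI coverage level (default 0.95).
#' @return a [FourPLFit-class].
#' @examples
#' d <- 10^seq(-9, -5, by = 0.5)
#' y <- 100 / (1 + 10^((log10(53e-9) - log10(d)) * 1))
#' fit <- fit4PL(d, y)
#' ic50(fit)  # 5.3e-08
#' @export
fit4PL <- function(conc, response,
                   constraints = list(bottom = c(-10, 50),
                                      top = c(50, 120),
                                      hill = c(1e-3, 5)),
                   nBoot = 0L, seed = NULL, level = 0.95) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(conc) < 4L)
    stop("insufficient data: at least 4 dose-response points are required",
         call. = FALSE)
  if (nBoot > 0 && is.null(seed))
    stop("bootstrap needs a caller-supplied seed", call. = FALSE)
  ld <- log10(conc)
  lower <- c(bottom = constraints$bottom[1], top = constraints$top[1],
             hill = constraints$hill[1], logIC50 = min(ld) - 4)
  upper <- c(bottom = constraints$bottom[2], top = constraints$top[2],
             hill = constraints$hill[2], logIC50 = max(ld) + 4)
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  b0 <- clamp(min(response), lower["bottom"], upper["bottom"])
  t0 <- clamp(max(response), lower["top"], upper["top"])
  best <- NULL
  for (l0 in sort(unique(ld))) for (h0 in c(0.5, 1, 2)) {
    h0c <- clamp(h0, lower["hill"], upper["hill"])
    res <- .fitOnce(conc, response,
                    start = c(bottom = unname(b0), top = unname(t0),
                              hill = unname(h0c), logIC50 = l0),
                    lower = lower, upper = upper)
    if (is.null(res)) next
    if (is.null(best) ||
        res$rss < best$rss * (1 - 1e-9) ||
        (abs(res$rss - best$rss) <= 1e-9 * max(best$rss, 1) &&
         abs(res$par["hill"] - 1) < abs(best$par["hill"] - 1)))
      best <- res
  }
  if (is.null(best))
    stop("fit failure: no start converged; check dose range and constraints",
         call. = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    boots <- withr::with_seed(seed, {
      vapply(seq_len(nBoot), function(i) {
        idx <- sample.int(length(conc), replace = TRUE)
        if (length(unique(conc[idx])) < 4L) return(NA_real_)
        r <- .fitOnce(conc[idx], response[idx],
                      start = best$par, lower = lower, upper = upper)
        if (is.null(r)) NA_real_ else unname(10^r$par["logIC50"])
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    if (length(boots) >= 10)
      ci <- unname(stats::quantile(boots,
                                   c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  p <- best$par
  new("FourPLFit", bottom = unname(p["bottom"]), top = unname(p["top"]),
      hill = unname(p["hill"]), logIC50 = unname(p["logIC50"]),
      ic50 = unname(10^p["logIC50"]), rss = best$rss,
      ciLow = ci[1], ciHigh = ci[2], nPoints = length(conc))
}

#' Compare two titration curves on a shared dose grid
#'
#' Reports the per-dose response difference (curve B minus curve A), the
#' ratio of fitted IC50s, and a rescue index: the mean response difference
#' over doses at or below a cutoff (default 5 uM), quantifying how much a
#' second condition (e.g. target knock-down) restores viability across the
#' tested range. Replicate responses at a dose are averaged first. The two
#' curves must share their dose grid; interpolation is refused.
#'
#' @param curveA,curveB data.frames with columns `concentration` (molar) and
#'   `response` (percent).
#' @param rescueCutoff dose cutoff (molar) for the rescue index; default 5e-6.
#' @param ... passed to [fit4PL()] for both curves.
#' @return list with `perDose` (data.frame `concentration`, `response_a`,
#'   `response_b`, `delta`), `ic50Ratio` (`ic50_a / ic50_b`), `rescueIndex`,
#'   and the two [FourPLFit-class] objects `fitA`, `fitB`.
#' @export
compareTitrations <- function(curveA, curveB, rescueCutoff = 5e-6, ...) {
  stopifnot(all(c("concentration", "response") %in% names(curveA)),
            all(c("concentration", "response") %in% names(curveB)))
  avg <- function(cv) {
    agg <- stats::aggregate(response ~ concentration, data = cv, FUN = mean)
    agg[order(agg$concentration), , drop = FALSE]
  }
  a <- avg(curveA); b <- avg(curveB)
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(a$concentration, b$concentration, tolerance = 1e-8)))
    stop("grid mismatch: the two curves must share their concentration grid",
         call. = FALSE)
  fitA <- fit4PL(curveA$concentration, curveA$response, ...)
  fitB <- fit4PL(curveB$concentration, curveB$response, ...)
  delta <- b$response - a$response
  in_range <- a$concentration <= rescueCutoff
  list(perDose = data.frame(concentration = a$concentration,
                            response_a = a$response,
                            response_b = b$response,
                            delta = delta),
       ic50Ratio = ic50(fitA) / ic50(fitB),
       rescueIndex = if (any(in_range)) mean(delta[in_range]) else NA_real_,
       fitA = fitA, fitB = fitB)
}
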