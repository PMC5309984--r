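# Michaelis-Menten read-yield modelling and quantification-free post-PCR
# pooling normalisation. Final read count R saturates with initial DNA
# concentration C as R = C/(C + K_m) * R_max; fitting (K_m, R_max) lets the
# lab predict relative yield from C alone and adjust per-sample pool volumes
# without quantifying PCR products.

# Profiled sum of squares: for fixed K_m, R_max solves a linear least-squares
# problem in closed form. Robust on noiseless data, where nls() fails.
#' @noRd
mm_profile <- function(log_km, conc, reads) {
  km <- exp(log_km)
  w <- conc / (conc + km)
  rmax <- sum(w * reads) / sum(w * w)
  list(km = km, rmax = rmax, sse = sum((reads - rmax * w)^2))
}

#' Fit a Michaelis-Menten read-yield model
#'
#' Nonlinear least squares for `R = C/(C + K_m) * R_max` on raw reads.
#' `R_max` is profiled out in closed form and `K_m` is found by 1-D
#' minimisation on the log scale (relative tolerance 1e-8), bracketing the
#' data-driven initial guess (R_max0 = 95th percentile of R; K_m0 = the
#' concentration at half R_max0 by interpolation). After the first fit the
#' top/bottom 0.5% of residuals are trimmed and the model refitted once.
#'
#' @param conc Initial DNA concentrations (ng/ul).
#' @param reads Final read counts per sample.
#' @param trim Fraction of extreme residuals trimmed at each tail before the
#'   single refit (0 disables).
#' @return Object of class `mm_model`: list with `km`, `rmax`, `sigma`
#'   (residual SD), `n`.
#' @export
fit_mm <- function(conc, reads, trim = 0.005) {
  stopifnot(length(conc) == length(reads))
  if (length(conc) < 10) stop("need at least 10 observations")
  if (max(conc) < 4 * min(conc)) {
    stop("observations must span at least a 4-fold concentration range")
  }
  if (stats::sd(conc) == 0) stop("unidentifiable model: all concentrations equal")
  fit_once <- function(conc, reads) {
    rmax0 <- stats::quantile(reads, 0.95, names = FALSE)
    o <- order(conc)
    km0 <- tryCatch(
      stats::approx(reads[o], conc[o], xout = rmax0 / 2, ties = mean,
                    rule = 2)$y,
      error = function(e) stats::median(conc))
    if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(conc)
    lo <- log(km0) - 12; hi <- log(km0) + 12
    opt <- stats::optimize(function(lk) mm_profile(lk, conc, reads)$sse,
                           interval = c(lo, hi), tol = 1e-10)
    mm_profile(opt$minimum, conc, reads)
  }
  f <- fit_once(conc, reads)
  if (trim > 0 && length(conc) >= 1 / trim) {
    res <- reads - f$rmax * conc / (conc + f$km)
    qs <- stats::quantile(res, c(trim, 1 - trim), names = FALSE)
    keep <- res >= qs[1] & res <= qs[2]
    if (sum(keep) >= 10 && max(conc[keep]) >= 4 * min(conc[keep])) {
      f <- fit_once(conc[keep], reads[keep])
      conc <- conc[keep]; reads <- reads[keep]
    }
  }
  res <- reads - f$rmax * conc / (conc + f$km)
  structure(list(km = f$km, rmax = f$rmax,
                 sigma = stats::sd(res), n = length(conc)),
            class = "mm_model")
}

#' Predicted read yield at a DNA concentration
#'
#' @param model An `mm_model` (or any list with `km`, `rmax`).
#' @param conc Concentrations in ng/ul (>= 0).
#' @return Expected read counts `conc/(conc + km) * rmax`.
#' @export
predict_reads <- function(model, conc) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  conc / (conc + model$km) * model$rmax
}

#' Quantification-free pooling-volume plan
#'
#' Per-sample pool-volume multipliers `clamp(R_ref / predict(C_i), 1,
#' max_factor)` where `R_ref` is the predicted yield at a reference
#' concentration (default: where the curve reaches 90% of `R_max`, i.e.
#' `9 K_m`). Samples below `min_conc` ng/ul yield too little PCR product for
#' complete compensation and are flagged.
#'
#' @param conc Per-sample DNA concentrations (ng/ul).
#' @param model A fitted `mm_model`.
#' @param max_factor Physical cap on the volume multiplier.
#' @param ref_conc Reference concentration; default `9 * km`.
#' @param min_conc Below this the sample is flagged not fully compensable.
#' @return Data frame of class `pooling_plan`: `conc`, `predicted`,
#'   `factor`, `compensable`.
#' @export
pooling_volumes <- function(conc, model, max_factor = 4, ref_conc = NULL,
                            min_conc = 5) {
  ref_conc <- ref_conc %||% (9 * model$km)
  r_ref <- predict_reads(model, ref_conc)
  pred <- predict_reads(model, conc)
  factor <- clamp(ifelse(pred > 0, r_ref / pred, max_factor), 1, max_factor)
  structure(data.frame(conc = conc, predicted = pred, factor = factor,
                       compensable = conc >= min_conc),
            class = c("pooling_plan", "data.frame"))
}

#' @export
print.mm_model <- function(x, ...) {
  cat(sprintf("Michaelis-Menten read-yield model (n = %d)\n", x$n))
  cat(sprintf("  K_m   = %.4g ng/ul\n  R_max = %.6g reads\n  residual SD = %.4g\n",
              x$km, x$rmax, x$sigma))
  invisible(x)
}
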