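# Enzyme-assay rate conversion and Michaelis-Menten fitting.

#' Specific activity from an absorbance slope
#'
#' Converts a plate-reader absorbance slope (e.g. NADPH depletion followed
#' at 340 nm) into a specific activity in nkat/mg:
#' `|slope| / (epsilon * path)` gives the concentration rate in mM/min;
#' multiplied by the reaction volume it becomes mmol/min, converted to
#' nmol/s (x 1e6 / 60) and divided by the protein mass.
#'
#' @param slope Absorbance change per minute (AU/min; sign is ignored).
#' @param epsilon Molar absorptivity in mM^-1 cm^-1 (default 6.22, NADPH at
#'   340 nm).
#' @param path Optical path length in cm (well path depends on fill volume,
#'   so it is an explicit input).
#' @param volume Reaction volume in liters.
#' @param protein Protein mass in mg.
#' @return Specific activity in nkat/mg.
#' @export
rate_from_absorbance <- function(slope, epsilon = 6.22, path, volume,
                                 protein) {
  stopifnot(epsilon > 0, path > 0, volume > 0)
  if (any(protein <= 0)) stop("protein mass must be positive")
  abs(slope) / (epsilon * path) * volume * 1e6 / 60 / protein
}

#' Fit Michaelis-Menten kinetics
#'
#' Direct nonlinear least squares of `v = Vmax * S / (Km + S)`
#' (Levenberg-Marquardt), not a Lineweaver-Burk linearization, which would
#' bias the estimates under additive noise. The initializer is
#' deterministic: `Vmax0 = max(v)` and `Km0` the substrate concentration of
#' the observation closest to `Vmax0 / 2`.
#'
#' @param rates data.frame with columns `S` (mM) and `v` (nkat/mg); at
#'   least 3 distinct concentrations.
#' @return List of class `"mm_fit"` with `Km`, `Vmax`, `se` (named standard
#'   errors), `rss`, `n_points`, and the fitted `model`.
#' @export
fit_michaelis_menten <- function(rates) {
  stopifnot(is.data.frame(rates), all(c("S", "v") %in% names(rates)))
  rates <- rates[order(rates$S), , drop = FALSE]
  if (length(unique(rates$S)) < 3) {
    stop("need at least 3 distinct substrate concentrations")
  }
  vmax0 <- max(rates$v)
  km0 <- rates$S[which.min(abs(rates$v - vmax0 / 2))]
  if (km0 <= 0) km0 <- min(rates$S[rates$S > 0], 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = rates,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Michaelis-Menten fit failed (start Vmax=", signif(vmax0, 4),
           ", Km=", signif(km0, 4), "; n=", nrow(rates), " points, S in [",
           min(rates$S), ", ", max(rates$S), "]): ", conditionMessage(e))
    })
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(Km = unname(est["Km"]), Vmax = unname(est["Vmax"]),
                 se = c(Km = unname(se["Km"]), Vmax = unname(se["Vmax"])),
                 rss = sum(stats::resid(fit)^2),
                 n_points = nrow(rates), model = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n_points))
  cat(sprintf("  Km   = %.4g mM (se %.3g)\n", x$Km, x$se["Km"]))
  cat(sprintf("  Vmax = %.4g nkat/mg (se %.3g)\n", x$Vmax, x$se["Vmax"]))
  invisible(x)
}

#' Predicted rate from a Michaelis-Menten fit
#'
#' @param object An `"mm_fit"`.
#' @param S Substrate concentrations (mM).
#' @param ... Unused.
#' @return Predicted rates (nkat/mg).
#' @export
predict.mm_fit <- function(object, S, ...) {
  object$Vmax * S / (object$Km + S)
}
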