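#' Root-mean-square deviation
#'
#' `sqrt(mean((predicted - reference)^2))`, the error statistic used
#' throughout the benchmark validation.
#'
#' @param predicted,reference equal-length numeric vectors (log units).
#' @return RMSD in log units.
#' @export
rmsd <- function(predicted, reference) {
  if (length(predicted) != length(reference) || !length(predicted))
    pk_input_error("predicted and reference must have equal nonzero length")
  sqrt(mean((predicted - reference)^2))
}

#' Fit the linear empirical correction
#'
#' Fits `pKa(corrected) = a * pKa(computed) + b` by unweighted ordinary
#' least squares of the experimental values on the computed ones. The LEC
#' absorbs the systematic error of a given model chemistry (most visibly
#' the over-spread of computed pKa for highly charged species under
#' continuum solvation, which compresses the slope well below 1). Since the
#' identity map is in the fit family, the corrected RMSD can never exceed
#' the uncorrected one.
#'
#' @param observations data.frame with numeric columns `experimental` and
#'   `computed` (one row per benchmark pKa), e.g. from
#'   [load_reference_dataset()].
#' @return object of class `lec`: list with `a` (slope), `b` (intercept),
#'   `n_obs`, `rmsd_uncorrected`, `rmsd_corrected`, `observations` (with a
#'   `corrected` column appended), and the underlying [stats::lm] fit.
#' @seealso [predict.lec()] to apply the correction,
#'   [validate_against_reference()] for the packaged benchmark run.
#' @examples
#' obs <- data.frame(computed = c(1, 2, 3, 4), experimental = c(3.1, 4.9, 7.1, 8.9))
#' fit <- fit_lec(obs)
#' coef(fit)
#' predict(fit, 10)
#' @export
fit_lec <- function(observations) {
  obs <- as.data.frame(observations)
  if (!all(c("experimental", "computed") %in% names(obs)))
    pk_input_error("observations need columns 'experimental' and 'computed'")
  if (nrow(obs) < 2L) pk_input_error("need at least 2 observations")
  if (!all(is.finite(obs$experimental)) || !all(is.finite(obs$computed)))
    pk_input_error("observations must be finite")
  if (stats::var(obs$computed) == 0)
    pk_stop("polypka_fit_error", "degenerate design: computed values are all identical")
  fit <- stats::lm(experimental ~ computed, data = obs)
  a <- unname(stats::coef(fit)[["computed"]])
  b <- unname(stats::coef(fit)[["(Intercept)"]])
  obs$corrected <- a * obs$computed + b
  out <- list(a = a, b = b, n_obs = nrow(obs),
              rmsd_uncorrected = rmsd(obs$computed, obs$experimental),
              rmsd_corrected = rmsd(obs$corrected, obs$experimental),
              observations = obs, lm = fit)
  class(out) <- "lec"
  out
}

#' @export
print.lec <- function(x, ...) {
  cat("Linear empirical correction: pKa_corr = a * pKa_comp + b\n")
  cat(sprintf("  a = %.4f, b = %.4f   (n = %d)\n", x$a, x$b, x$n_obs))
  cat(sprintf("  RMSD uncorrected = %.3f, corrected = %.3f log units\n",
              x$rmsd_uncorrected, x$rmsd_corrected))
  invisible(x)
}

#' @export
summary.lec <- function(object, ...) {
  print(object)
  cat("\nOLS details:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
coef.lec <- function(object, ...) c(a = object$a, b = object$b)

#' Apply a linear empirical correction
#'
#' @param object a fitted [fit_lec()] model, or use [lec_model()] to build
#'   one from explicit coefficients.
#' @param newdata numeric vector of computed pKa values (log units); when
#'   omitted, the training computed values are corrected.
#' @param ... unused.
#' @return corrected pKa values, log units.
#' @export
predict.lec <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$observations$computed
  if (!is.numeric(newdata) || !all(is.finite(newdata)))
    pk_input_error("newdata must be finite numeric")
  object$a * newdata + object$b
}

#' @export
residuals.lec <- function(object, ...) {
  object$observations$experimental - object$observations$corrected
}

#' Build an LEC from explicit coefficients
#'
#' For applying a published correction (e.g. a = 0.5, b = 4.22) without
#' refitting. The returned object supports [predict.lec()]; fit statistics
#' are `NA`.
#'
#' @param a slope (dimensionless).
#' @param b intercept (log units).
#' @return an object of class `lec`.
#' @export
lec_model <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) pk_input_error("a and b must be finite")
  out <- list(a = a, b = b, n_obs = 0L,
              rmsd_uncorrected = NA_real_, rmsd_corrected = NA_real_,
              observations = data.frame(experimental = numeric(0),
                                        computed = numeric(0),
                                        corrected = numeric(0)),
              lm = NULL)
  class(out) <- "lec"
  out
}

#' Validate against the packaged macrocycle benchmark
#'
#' Runs the full benchmark validation on the packaged reference dataset of
#' 32 measured vs computed pKa over ten tetra-aza macrocycles: fits the LEC
#' (unless a fitted model is supplied), and reports the uncorrected and
#' corrected RMSD, the fitted coefficients, per-observation residuals, and
#' the first-minus-fourth computed and experimental pKa spread of molecule
#' 2 — the diagnostic for over-spreading of highly charged species by the
#' continuum solvent model.
#'
#' @param fit optional pre-fitted [fit_lec()] model; default refits on the
#'   packaged observations.
#' @return list of class `lec_validation`: `a`, `b`, `n_obs`,
#'   `rmsd_uncorrected`, `rmsd_corrected`, `residuals` (data.frame), and
#'   `molecule2_spread` (computed and experimental first-minus-fourth).
#' @export
validate_against_reference <- function(fit = NULL) {
  obs <- load_reference_dataset("table1")
  if (is.null(fit)) fit <- fit_lec(obs)
  if (!inherits(fit, "lec")) pk_input_error("fit must be an 'lec' object")
  corrected <- predict(fit, obs$computed)
  res <- data.frame(molecule = obs$molecule, step = obs$step,
                    experimental = obs$experimental, computed = obs$computed,
                    corrected = corrected,
                    residual = obs$experimental - corrected)
  m2 <- obs[obs$molecule == "2", ]
  spread <- list(
    computed = m2$computed[m2$step == 1] - m2$computed[m2$step == max(m2$step)],
    experimental = m2$experimental[m2$step == 1] - m2$experimental[m2$step == max(m2$step)])
  out <- list(a = fit$a, b = fit$b, n_obs = nrow(obs),
              rmsd_uncorrected = rmsd(obs$computed, obs$experimental),
              rmsd_corrected = rmsd(corrected, obs$experimental),
              residuals = res, molecule2_spread = spread)
  class(out) <- "lec_validation"
  out
}

#' @export
print.lec_validation <- function(x, ...) {
  cat(sprintf("Benchmark validation (n = %d):\n", x$n_obs))
  cat(sprintf("  LEC: a = %.4f, b = %.4f\n", x$a, x$b))
  cat(sprintf("  RMSD uncorrected = %.2f, corrected = %.2f log units\n",
              x$rmsd_uncorrected, x$rmsd_corrected))
  cat(sprintf("  molecule 2 pKa1 - pKa4 spread: computed %.1f, experimental %.1f log units\n",
              x$molecule2_spread$computed, x$molecule2_spread$experimental))
  invisible(x)
}

#' Leave-one-molecule-out cross-validation of the LEC
#'
#' Diagnostic extension (not part of the benchmark protocol): refits the
#' LEC with all observations of one molecule held out, predicts the
#' held-out pKa, and reports the pooled out-of-sample RMSD alongside the
#' in-sample one.
#'
#' @param observations as in [fit_lec()]; must carry a `molecule` column.
#' @return list with `rmsd_loo`, `rmsd_insample`, and `per_molecule`
#'   (data.frame of held-out RMSD per molecule).
#' @export
lec_loo_cv <- function(observations = load_reference_dataset("table1")) {
  obs <- as.data.frame(observations)
  if (is.null(obs$molecule)) pk_input_error("observations need a 'molecule' column")
  mols <- unique(obs$molecule)
  press <- 0; per <- list()
  for (m in mols) {
    train <- obs[obs$molecule != m, ]
    test <- obs[obs$molecule == m, ]
    f <- fit_lec(train)
    e <- test$experimental - predict(f, test$computed)
    press <- press + sum(e^2)
    per[[m]] <- data.frame(molecule = m, n = nrow(test),
                           rmsd = sqrt(mean(e^2)))
  }
  full <- fit_lec(obs)
  list(rmsd_loo = sqrt(press / nrow(obs)),
       rmsd_insample = full$rmsd_corrected,
       per_molecule = do.call(rbind, per))
}
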