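#' Fluorescence anisotropy from polarized intensities
#'
#' Standard anisotropy definition
#' `r = (I_parallel - g * I_perpendicular) / (I_parallel + 2 g * I_perpendicular)`
#' from blank-corrected parallel and perpendicular emission intensities,
#' with an instrument g-factor (default 1).
#'
#' @param I_parallel,I_perpendicular Blank-corrected intensities (vectors).
#' @param g Instrument g-factor (default 1).
#' @return Anisotropy value(s).
#' @examples
#' anisotropy(2, 1)  # 0.25
#' @export
anisotropy <- function(I_parallel, I_perpendicular, g = 1) {
  denom <- I_parallel + 2 * g * I_perpendicular
  if (any(denom <= 0)) {
    stop("total intensity I_parallel + 2 g I_perpendicular must be positive",
         call. = FALSE)
  }
  (I_parallel - g * I_perpendicular) / denom
}

#' Titration series for an affinity assay
#'
#' Holds (target concentration, response) pairs for one binding assay.
#' Responses are deltas relative to the zero-concentration point: the
#' anisotropy change `r - r0` for fluorescence anisotropy (FA), or the
#' free-aptamer peak depletion for affinity probe capillary electrophoresis
#' (APCE). Target concentration is carried in U/mL throughout — the
#' immunoassay-derived unit in which CA125-class targets are quantified —
#' and never converted to molar.
#'
#' @param concentration Target concentrations, U/mL (>= 0).
#' @param response Responses, same length (replicate points allowed).
#' @param assay `"FA"` or `"APCE"`.
#' @return An object of class `titration_series`: a data frame with columns
#'   `concentration`, `response`, and an `assay` attribute.
#' @export
titration_series <- function(concentration, response, assay = c("FA", "APCE")) {
  assay <- match.arg(assay)
  stopifnot(length(concentration) == length(response))
  if (any(concentration < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  structure(
    data.frame(concentration = as.numeric(concentration),
               response = as.numeric(response)),
    assay = assay,
    class = c("titration_series", "data.frame"))
}

#' Fit a saturation binding isotherm
#'
#' Fits the single-site saturation isotherm
#' `response = constant * T / (Kd + T)` to a titration by unweighted
#' nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]), where `T` is the target concentration and the
#' apparent `Kd` is the concentration at half-saturation. Initial guesses
#' are `Kd = median(T > 0)` and `constant = max(response)`. Standard errors
#' come from the fit covariance. Non-convergence and degenerate fits (e.g.
#' all-zero responses) are reported via `converged = FALSE` with a
#' diagnostic message rather than an exception.
#'
#' @param series A [titration_series], or a data frame with columns
#'   `concentration` and `response`.
#' @param average_replicates Average replicate responses at each
#'   concentration before fitting (default FALSE: unweighted fit to all
#'   points).
#' @return An object of class `isotherm_fit`: list with `Kd`, `amplitude`,
#'   `se_Kd`, `se_amplitude`, `converged`, `n_points`, `residual_sd`,
#'   `message`, and the underlying `fit` object (NULL on failure).
#' @export
fit_isotherm <- function(series, average_replicates = FALSE) {
  df <- as.data.frame(series)[, c("concentration", "response")]
  if (average_replicates) {
    df <- stats::aggregate(response ~ concentration, df, mean)
  }
  if (length(unique(df$concentration)) < 4) {
    stop("need at least 4 distinct concentrations to fit an isotherm",
         call. = FALSE)
  }
  start <- list(constant = max(df$response),
                Kd = median(df$concentration[df$concentration > 0]))
  if (!is.finite(start$constant) || start$constant == 0) start$constant <- 1e-6

  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ constant * concentration / (Kd + concentration),
      data = df, start = start,
      lower = c(constant = -Inf, Kd = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(
      list(Kd = NA_real_, amplitude = NA_real_, se_Kd = NA_real_,
           se_amplitude = NA_real_, converged = FALSE,
           n_points = nrow(df), residual_sd = NA_real_,
           message = conditionMessage(fit), fit = NULL),
      class = "isotherm_fit"))
  }
  co <- suppressWarnings(summary(fit)$coefficients)
  est <- coef(fit)
  converged <- isTRUE(fit$convInfo$isConv) && all(is.finite(co[, "Std. Error"]))
  degenerate <- abs(est["constant"]) <= 10 * co["constant", "Std. Error"] &&
    abs(est["constant"]) < 1e-8
  structure(
    list(Kd = unname(est["Kd"]), amplitude = unname(est["constant"]),
         se_Kd = unname(co["Kd", "Std. Error"]),
         se_amplitude = unname(co["constant", "Std. Error"]),
         converged = converged && !degenerate,
         n_points = nrow(df),
         residual_sd = summary(fit)$sigma,
         message = if (degenerate) "degenerate fit: amplitude ~ 0" else "ok",
         fit = fit),
    class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("Saturation isotherm fit: response = constant * T / (Kd + T)\n")
  if (is.na(x$Kd)) {
    cat("  fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  apparent Kd = %.4g +/- %.2g U/mL\n", x$Kd, x$se_Kd))
  cat(sprintf("  amplitude   = %.4g +/- %.2g\n", x$amplitude, x$se_amplitude))
  cat(sprintf("  converged: %s (%d points, residual SD %.3g)\n",
              x$converged, x$n_points, x$residual_sd))
  invisible(x)
}

#' Predict the fitted isotherm at given concentrations
#'
#' @param object An `isotherm_fit`.
#' @param concentration Concentrations, U/mL.
#' @param ... Unused.
#' @return Fitted responses `constant * T / (Kd + T)`.
#' @export
predict.isotherm_fit <- function(object, concentration, ...) {
  object$amplitude * concentration / (object$Kd + concentration)
}

#' APCE response from peak heights
#'
#' In affinity probe capillary electrophoresis, complex formation depletes
#' the free-aptamer peak; the aptamer peak height ratioed to an internal
#' standard reports the free fraction. The fitted response is the depletion
#' `ratio(0) - ratio(T)` (default, increasing toward saturation), or the
#' raw ratio itself under `convention = "fit_raw_ratio"`.
#'
#' @param points Data frame with columns `concentration`, `aptamer_peak`,
#'   `standard_peak` (standard peaks must be positive).
#' @param zero_conc_ratio Optional reference ratio at zero concentration;
#'   defaults to the mean ratio over the `concentration == 0` rows (an
#'   error if absent).
#' @param convention `"fit_depletion"` (default) or `"fit_raw_ratio"`.
#' @return A [titration_series] with `assay = "APCE"`.
#' @export
apce_response <- function(points, zero_conc_ratio = NULL,
                          convention = c("fit_depletion", "fit_raw_ratio")) {
  convention <- match.arg(convention)
  stopifnot(all(c("concentration", "aptamer_peak", "standard_peak") %in%
                  names(points)))
  if (any(points$standard_peak <= 0)) {
    stop("standard_peak must be positive", call. = FALSE)
  }
  ratio <- points$aptamer_peak / points$standard_peak
  if (is.null(zero_conc_ratio)) {
    at0 <- points$concentration == 0
    if (!any(at0)) {
      stop("no zero-concentration sample: supply zero_conc_ratio or a T = 0 row",
           call. = FALSE)
    }
    zero_conc_ratio <- mean(ratio[at0])
  }
  response <- switch(convention,
                     fit_depletion = zero_conc_ratio - ratio,
                     fit_raw_ratio = ratio)
  titration_series(points$concentration, response, assay = "APCE")
}

#' Simulate a titration from a known isotherm
#'
#' Generates `response = constant * T / (Kd + T)` plus i.i.d. Gaussian noise
#' per replicate at each grid concentration — a synthetic stand-in for a
#' plate-reader or CE titration with known ground-truth parameters, used
#' for parameter-recovery testing.
#'
#' @param Kd True apparent Kd, U/mL (> 0).
#' @param constant True saturation amplitude.
#' @param T_grid Concentration grid, U/mL.
#' @param noise_sd Gaussian noise SD on the response (>= 0).
#' @param n_replicates Replicates per concentration (default 1).
#' @param seed RNG seed.
#' @param assay Assay label for the series.
#' @return A [titration_series].
#' @export
simulate_titration <- function(Kd, constant, T_grid, noise_sd = 0,
                               n_replicates = 1, seed = 1, assay = "FA") {
  if (Kd <= 0) stop("Kd must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  Tc <- rep(T_grid, each = n_replicates)
  mu <- constant * Tc / (Kd + Tc)
  resp <- with_seed(seed, mu + rnorm(length(Tc), 0, noise_sd))
  titration_series(Tc, resp, assay = assay)
}

#' Read a titration CSV into a response series
#'
#' Accepts either fluorescence-anisotropy columns
#' (`assay, concentration_U_per_mL, replicate, I_parallel, I_perpendicular`)
#' — in which case anisotropy is computed per row and the response is
#' `r - r0` with `r0` the mean anisotropy of the zero-concentration rows —
#' or APCE columns (`assay, concentration_U_per_mL, replicate,
#' aptamer_peak, standard_peak`), handed to [apce_response()].
#'
#' @param path CSV path.
#' @param g FA g-factor (default 1).
#' @param convention APCE response convention (see [apce_response()]).
#' @return A [titration_series].
#' @export
read_titration_csv <- function(path, g = 1,
                               convention = c("fit_depletion", "fit_raw_ratio")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"concentration_U_per_mL" %in% names(df)) {
    stop("titration CSV needs a 'concentration_U_per_mL' column", call. = FALSE)
  }
  conc <- df$concentration_U_per_mL
  if (all(c("I_parallel", "I_perpendicular") %in% names(df))) {
    r <- anisotropy(df$I_parallel, df$I_perpendicular, g = g)
    at0 <- conc == 0
    if (!any(at0)) stop("FA titration needs zero-concentration rows", call. = FALSE)
    titration_series(conc, r - mean(r[at0]), assay = "FA")
  } else if (all(c("aptamer_peak", "standard_peak") %in% names(df))) {
    apce_response(data.frame(concentration = conc,
                             aptamer_peak = df$aptamer_peak,
                             standard_peak = df$standard_peak),
                  convention = convention)
  } else {
    stop("unrecognized titration columns: expected I_parallel/I_perpendicular ",
         "or aptamer_peak/standard_peak", call. = FALSE)
  }
}
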