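# Enzyme kinetics: assay unit conversion, Michaelis-Menten and first-order
# inactivation fits, total turnover number, and heme-protein purity (Rz).
#
# Fitting is nonlinear least squares (minpack.lm::nlsLM) in the native
# measurement space — not a Lineweaver-Burk linearization. Standard errors
# come from the fit covariance.

#' Define a spectrophotometric assay
#'
#' @param name assay label.
#' @param wavelength_nm monitoring wavelength.
#' @param epsilon molar extinction coefficient, 1/(M cm).
#' @param path_length_cm optical path (default 1).
#' @param sign whether absorbance tracks product appearance or substrate
#'   disappearance.
#' @return an `assay_def`.
#' @export
assay_def <- function(name, wavelength_nm, epsilon, path_length_cm = 1,
                      sign = c("product_appearance",
                               "substrate_disappearance")) {
  sign <- match.arg(sign)
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  if (path_length_cm <= 0) stop("path length must be positive")
  structure(list(name = name, wavelength_nm = wavelength_nm,
                 epsilon = epsilon, path_length_cm = path_length_cm,
                 sign = sign),
            class = "assay_def")
}

#' Standard UPO activity assays
#'
#' ABTS radical cation at 418 nm (36,000 1/(M cm)); 4-nitrocatechol from NBD
#' at 425 nm (9,700); 1-naphthol from naphthalene at 303 nm (2,010); H2O2
#' consumption (catalase activity) at 240 nm (43.6).
#'
#' @return named list of `assay_def` objects.
#' @export
upo_assays <- function() {
  list(
    abts = assay_def("ABTS", 418, 36000),
    nbd = assay_def("NBD", 425, 9700),
    naphthalene = assay_def("naphthalene", 303, 2010),
    catalase = assay_def("catalase", 240, 43.6,
                         sign = "substrate_disappearance"))
}

#' Convert an absorbance slope to enzyme units
#'
#' One enzyme unit (U) generates 1 umol of product per minute. The slope is
#' converted as `U = |dA/min| / (epsilon * path) * volume_L * 1e6 *
#' dilution`.
#'
#' @param dA_per_min absorbance change per minute.
#' @param assay an `assay_def`.
#' @param reaction_volume_mL reaction volume (default 1).
#' @param dilution enzyme dilution factor applied before the assay
#'   (default 1).
#' @return activity in umol/min (U).
#' @export
rate_from_slope <- function(dA_per_min, assay, reaction_volume_mL = 1,
                            dilution = 1) {
  stopifnot(inherits(assay, "assay_def"))
  if (reaction_volume_mL <= 0) stop("reaction volume must be positive")
  if (dilution <= 0) stop("dilution must be positive")
  abs(dA_per_min) / (assay$epsilon * assay$path_length_cm) *
    (reaction_volume_mL / 1000) * 1e6 * dilution
}

#' Assemble an initial-rate dataset
#'
#' @param substrate_uM substrate concentrations, uM.
#' @param rate initial rates, uM/s.
#' @param enzyme_nM enzyme concentration, nM.
#' @return a `rate_dataset` data frame.
#' @export
rate_dataset <- function(substrate_uM, rate, enzyme_nM) {
  if (length(substrate_uM) != length(rate))
    stop("substrate and rate vectors differ in length")
  if (any(substrate_uM < 0)) stop("substrate concentrations must be >= 0")
  if (!is.finite(enzyme_nM) || enzyme_nM <= 0)
    stop("enzyme_nM must be positive")
  structure(data.frame(substrate_uM = substrate_uM, rate = rate),
            enzyme_nM = enzyme_nM,
            class = c("rate_dataset", "data.frame"))
}

#' Fit the Michaelis-Menten model to an initial-rate dataset
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)`, initialized at
#' `Vmax0 = max(v)` and `Km0 = S` at half-maximal rate. `kcat = Vmax / [E]`.
#'
#' @param dataset a `rate_dataset` (rates in uM/s), or a data frame with
#'   columns `substrate_uM` and `rate` if `enzyme_nM` is given.
#' @param enzyme_nM enzyme concentration, nM (overrides the dataset
#'   attribute).
#' @return an `mm_fit` with components `kcat`, `kcat_se` (1/s), `Km`,
#'   `Km_se` (uM), `kcat_over_Km` (1/(M s)), `Vmax` (uM/s), `enzyme_nM`,
#'   `fit` (the nls object) and `data`.
#' @export
fit_mm <- function(dataset, enzyme_nM = NULL) {
  if (is.null(enzyme_nM)) enzyme_nM <- attr(dataset, "enzyme_nM")
  if (is.null(enzyme_nM)) stop("enzyme_nM is required")
  s <- dataset$substrate_uM; v <- dataset$rate
  if (length(unique(s)) < 4)
    stop("need at least 4 distinct substrate concentrations, got ",
         length(unique(s)))
  vmax0 <- max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s[s > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * s / (Km + s),
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (est["Km"] < min(s[s > 0]) / 100 || est["Km"] > max(s) * 100)
    warning("Km estimate (", signif(est["Km"], 3),
            " uM) is outside the sampled concentration range; ",
            "the dataset does not constrain it")
  e_uM <- enzyme_nM * 1e-3
  kcat <- unname(est["Vmax"] / e_uM)
  km <- unname(est["Km"])
  structure(list(
    kcat = kcat, kcat_se = unname(se["Vmax"] / e_uM),
    Km = km, Km_se = unname(se["Km"]),
    kcat_over_Km = if (km > 0 && kcat > 0)
      catalytic_efficiency(kcat, km) else NA_real_,
    Vmax = unname(est["Vmax"]), enzyme_nM = enzyme_nM,
    fit = fit, data = data.frame(substrate_uM = s, rate = v)),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit ([E] = %g nM, n = %d):\n", x$enzyme_nM,
    nrow(x$data)))
  cat(sprintf("  kcat     = %.4g +/- %.2g 1/s\n", x$kcat, x$kcat_se))
  cat(sprintf("  Km       = %.4g +/- %.2g uM\n", x$Km, x$Km_se))
  cat(sprintf("  kcat/Km  = %.3g 1/(M s)\n", x$kcat_over_Km))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(kcat = object$kcat, Km = object$Km,
    kcat_over_Km = object$kcat_over_Km)
}

#' @export
summary.mm_fit <- function(object, ...) {
  out <- data.frame(
    parameter = c("kcat (1/s)", "Km (uM)", "kcat/Km (1/(M s))"),
    estimate = c(object$kcat, object$Km, object$kcat_over_Km),
    se = c(object$kcat_se, object$Km_se, NA))
  out
}

#' @export
predict.mm_fit <- function(object, substrate_uM = NULL, ...) {
  if (is.null(substrate_uM)) substrate_uM <- object$data$substrate_uM
  object$Vmax * substrate_uM / (object$Km + substrate_uM)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$data$substrate_uM, x$data$rate, xlab = "[S] (uM)",
                 ylab = "v (uM/s)", ...)
  s <- seq(0, max(x$data$substrate_uM), length.out = 200)
  graphics::lines(s, predict(x, s))
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' @param kcat_s turnover number, 1/s.
#' @param Km_uM Michaelis constant, uM.
#' @return kcat/Km in 1/(M s).
#' @export
catalytic_efficiency <- function(kcat_s, Km_uM) {
  if (any(!is.finite(kcat_s)) || any(!is.finite(Km_uM)))
    stop("inputs must be finite")
  if (any(Km_uM <= 0)) stop("Km must be positive")
  if (any(kcat_s <= 0)) stop("kcat must be positive")
  kcat_s / (Km_uM * 1e-6)
}

#' Fit a first-order inactivation model
#'
#' Nonlinear least squares of `A(t) = A0 * exp(-k * t)` with `A0` free
#' (robust to normalization error), initialized from the log-linear
#' regression slope. `t_half = ln(2) / k`.
#'
#' @param time_min incubation times, minutes.
#' @param activity residual activities (fraction of t = 0).
#' @return an `inact_fit` with `k_inact`, `k_inact_se` (1/min), `t_half`
#'   (min), `A0`, `fit` and `data`.
#' @export
fit_inactivation <- function(time_min, activity) {
  if (is.data.frame(time_min)) {
    activity <- time_min[[2]]; time_min <- time_min[[1]]
  }
  if (length(time_min) < 4) stop("need at least 4 time points")
  if (length(time_min) != length(activity)) stop("length mismatch")
  if (any(activity <= 0))
    stop("activities must be positive (fractions of initial activity)")
  loglin <- stats::lm(log(activity) ~ time_min)
  slope <- unname(stats::coef(loglin)[2])
  if (slope >= 0)
    stop("activity does not decay over time; ",
         "first-order inactivation model violated")
  fit <- tryCatch(
    minpack.lm::nlsLM(activity ~ A0 * exp(-k * time_min),
                      start = list(A0 = exp(stats::coef(loglin)[1]),
                                   k = -slope),
                      lower = c(A0 = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("inactivation fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(
    k_inact = unname(est["k"]), k_inact_se = unname(se["k"]),
    t_half = log(2) / unname(est["k"]), A0 = unname(est["A0"]),
    fit = fit, data = data.frame(time_min = time_min, activity = activity)),
    class = "inact_fit")
}

#' @export
print.inact_fit <- function(x, ...) {
  cat(sprintf("first-order inactivation fit (n = %d):\n", nrow(x$data)))
  cat(sprintf("  k_inact = %.4g +/- %.2g 1/min\n", x$k_inact, x$k_inact_se))
  cat(sprintf("  t_1/2   = %.3g min\n", x$t_half))
  invisible(x)
}

#' @export
coef.inact_fit <- function(object, ...) {
  c(k_inact = object$k_inact, t_half = object$t_half, A0 = object$A0)
}

#' @export
predict.inact_fit <- function(object, time_min = NULL, ...) {
  if (is.null(time_min)) time_min <- object$data$time_min
  object$A0 * exp(-object$k_inact * time_min)
}

#' Half-life of a first-order decay
#' @param k_inact rate constant, 1/min.
#' @return ln(2)/k in minutes.
#' @export
half_life <- function(k_inact) {
  if (any(k_inact <= 0)) stop("k_inact must be positive")
  log(2) / k_inact
}

#' Total turnover number
#'
#' Moles of substrate converted per mole of enzyme; with both amounts in the
#' same volume the concentration ratio suffices.
#'
#' @param substrate_converted_uM converted substrate, uM.
#' @param enzyme_nM enzyme, nM.
#' @return dimensionless TTN.
#' @export
ttn <- function(substrate_converted_uM, enzyme_nM) {
  if (any(enzyme_nM <= 0)) stop("enzyme concentration must be positive")
  if (any(substrate_converted_uM < 0)) stop("converted substrate must be >= 0")
  substrate_converted_uM / (enzyme_nM * 1e-3)
}

#' Reinheitszahl (heme purity) ratio
#'
#' @param A420 absorbance at the Soret band (420 nm).
#' @param A280 absorbance at 280 nm.
#' @return A420/A280; ~2.0 indicates a homogeneous UPO preparation.
#' @export
rz_ratio <- function(A420, A280) {
  if (any(A280 <= 0)) stop("A280 must be positive")
  if (any(A420 < 0)) stop("A420 must be >= 0")
  A420 / A280
}
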