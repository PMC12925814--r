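# Assay-derived scalar metrics: control-normalised hemolysis
# percentage, four-parameter logistic (4PL) dose-response fitting, 1:1
# binding-isotherm KD fitting, and the therapeutic index.

#' Control-normalised hemolysis percentage
#'
#' `100 * (A - A_neg) / (A_pos - A_neg)`, clipped to `[0, 100]`;
#' whether clipping occurred is recorded in the `"clipped"` attribute.
#'
#' @param absorbance sample absorbance(s)
#' @param negative untreated (negative-control) absorbance
#' @param positive full-lysis (positive-control) absorbance; must exceed
#'   the negative control
#' @return hemolysis percentage(s)
#' @export
hemolysis_percent <- function(absorbance, negative, positive) {
  if (!(positive > negative))
    stop("degenerate controls: positive must exceed negative")
  raw <- 100 * (absorbance - negative) / (positive - negative)
  out <- pmin(100, pmax(0, raw))
  attr(out, "clipped") <- any(raw < 0 | raw > 100)
  out
}

#' Construct a dose-response table
#'
#' @param concentration concentrations in uM (non-negative; at least 4
#'   distinct values are required for fitting)
#' @param response responses in assay units
#' @param replicate optional replicate labels
#' @return data.frame of class `dose_response`
#' @export
dose_response <- function(concentration, response, replicate = 1L) {
  if (length(concentration) != length(response))
    stop("concentration and response lengths differ")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  out <- data.frame(concentration = as.numeric(concentration),
                    response = as.numeric(response),
                    replicate = replicate)
  out <- out[order(out$concentration), ]
  rownames(out) <- NULL
  class(out) <- c("dose_response", "data.frame")
  out
}

check_fit_data <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration", "response") %in% names(data)))
  if (length(unique(data$concentration)) < 4L)
    stop("fitting needs at least 4 distinct concentrations")
  data[data$concentration > 0, ]    # log-scale grid needs positive x
}

fourpl <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)` using
#' Levenberg-Marquardt with a deterministic multi-start over a
#' log-spaced IC50 grid and both slope signs; the start with the lowest
#' residual norm wins. After fitting, the orientation is normalised so
#' that `hill > 0` and `ic50` is the half-effect concentration; the
#' reported `bottom`/`top` are the ordered asymptotes. A fit is flagged
#' non-converged when the optimizer fails on every start, and
#' unidentified when the fitted span is within the residual noise or
#' the IC50 falls far outside the measured concentration range.
#'
#' @param data a [dose_response()] (or data.frame with `concentration`,
#'   `response`)
#' @param n_starts IC50 grid size
#' @return object of class `dose_response_fit`: list with `bottom`,
#'   `top`, `ic50` (uM), `hill`, `direction` (`"decreasing"` or
#'   `"increasing"` with concentration), `residual_norm`, `converged`,
#'   `identified`, `fitted` (function of concentration)
#' @export
fit_4pl <- function(data, n_starts = 12L) {
  data <- check_fit_data(data)
  x <- data$concentration; y <- data$response
  grid <- exp(seq(log(min(x)), log(max(x)), length.out = n_starts))
  span <- max(y) - min(y)
  best <- NULL
  for (e in grid) for (h in c(1, 2, -1, -2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fourpl(x, bottom, top, ic50, hill),
        start = list(bottom = min(y), top = max(y), ic50 = e, hill = h),
        lower = c(-Inf, -Inf, min(x) * 1e-6, -20),
        upper = c(Inf, Inf, max(x) * 1e6, 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(err) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best))
    stop("4PL fit failed to converge from any start; best residual: NA")
  cf <- stats::coef(best$fit)
  bottom <- cf[["bottom"]]; top <- cf[["top"]]
  ic50 <- cf[["ic50"]]; hill <- cf[["hill"]]
  if (hill < 0) {  # same curve re-parameterised with positive slope
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  # with hill > 0 the response runs from `top` at x -> 0 to `bottom`
  direction <- if (top >= bottom) "decreasing" else "increasing"
  lo <- min(bottom, top); hi <- max(bottom, top)
  sigma <- best$rn / sqrt(max(1, length(y) - 4))
  identified <- abs(top - bottom) > max(2 * sigma, 1e-3 * max(span, 1)) &&
    ic50 >= min(x) / 100 && ic50 <= max(x) * 100
  b_ <- if (direction == "decreasing") lo else hi   # value at x -> Inf
  t_ <- if (direction == "decreasing") hi else lo   # value at x -> 0
  ic50_ <- ic50; hill_ <- hill
  structure(list(bottom = lo, top = hi, ic50 = ic50, hill = hill,
                 direction = direction, residual_norm = best$rn,
                 converged = TRUE, identified = identified,
                 fitted = function(conc) fourpl(conc, b_, t_, ic50_, hill_)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("4PL fit: ic50=%.4g uM, hill=%.3f, span [%.3g, ",
                     "%.3g], %s, residual %.3g%s\n"),
              x$ic50, x$hill, x$bottom, x$top, x$direction,
              x$residual_norm,
              if (!x$identified) " [UNIDENTIFIED]" else ""))
  invisible(x)
}

#' Fit a 1:1 binding isotherm
#'
#' Least-squares fit of `y = baseline + amplitude * x / (kd + x)` with a
#' deterministic multi-start over a log-spaced KD grid. The KD is
#' flagged unidentified when it falls outside the measured
#' concentration range by more than a factor of 10 (e.g.
#' saturation-only data) or when its standard error exceeds half its
#' value.
#'
#' @param data a [dose_response()]
#' @param n_starts KD grid size
#' @return object of class `binding_fit`: list with `kd` (uM),
#'   `amplitude`, `baseline`, `kd_se`, `residual_norm`, `converged`,
#'   `identified`
#' @export
fit_kd_isotherm <- function(data, n_starts = 12L) {
  data <- check_fit_data(data)
  x <- data$concentration; y <- data$response
  grid <- exp(seq(log(min(x)), log(max(x)), length.out = n_starts))
  best <- NULL
  for (k0 in grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + amplitude * x / (kd + x),
        start = list(baseline = min(y), amplitude = max(y) - min(y),
                     kd = k0),
        lower = c(-Inf, -Inf, min(x) * 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(err) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rn <- sqrt(sum(stats::resid(fit)^2))
    if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
  }
  if (is.null(best))
    stop("isotherm fit failed to converge from any start")
  cf <- stats::coef(best$fit)
  kd <- cf[["kd"]]
  kd_se <- tryCatch(summary(best$fit)$coefficients["kd", "Std. Error"],
                    error = function(e) NA_real_)
  identified <- kd >= min(x) / 10 && kd <= max(x) * 10 &&
    (is.na(kd_se) || kd_se < 0.5 * kd)
  structure(list(kd = kd, amplitude = cf[["amplitude"]],
                 baseline = cf[["baseline"]], kd_se = kd_se,
                 residual_norm = best$rn, converged = TRUE,
                 identified = identified),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 isotherm fit: KD=%.4g uM (se %.3g), residual %.3g%s\n",
              x$kd, x$kd_se, x$residual_norm,
              if (!x$identified) " [UNIDENTIFIED]" else ""))
  invisible(x)
}

#' Therapeutic index
#'
#' The ratio of the concentration inducing 50% hemolysis to the
#' concentration giving 50% inhibition of TNF-alpha production:
#' `TI = IC50_hemolysis / IC50_TNF`. Exact ratio, no rounding.
#'
#' @param ic50_hemolysis 50%-hemolysis concentration in uM (> 0)
#' @param ic50_tnf 50%-TNF-inhibition concentration in uM (> 0)
#' @return list of class `therapeutic_index` with `ic50_hemolysis`,
#'   `ic50_tnf`, `ti`
#' @export
therapeutic_index <- function(ic50_hemolysis, ic50_tnf) {
  if (!(ic50_hemolysis > 0) || !(ic50_tnf > 0))
    stop("both IC50 values must be > 0")
  structure(list(ic50_hemolysis = ic50_hemolysis, ic50_tnf = ic50_tnf,
                 ti = ic50_hemolysis / ic50_tnf),
            class = "therapeutic_index")
}

#' @export
print.therapeutic_index <- function(x, ...) {
  cat(sprintf("TI = %.4g / %.4g = %.4g\n",
              x$ic50_hemolysis, x$ic50_tnf, x$ti))
  invisible(x)
}
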