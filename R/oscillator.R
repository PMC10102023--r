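#' Construct a gene oscillator
#'
#' A log-scale cosinor description of the 24-h expression rhythm of a single
#' clock gene. Expression is modelled multiplicatively:
#' \deqn{E(t) = \exp\{\mu + A \cos(2\pi (t - \phi)/24) + \sigma Z\}, \quad Z \sim N(0,1),}
#' so that expression is strictly positive and case-to-case scatter is
#' log-normal, which produces the heavy-tailed dispersion characteristic of
#' relative qPCR expression ratios.
#'
#' @param mesor Baseline of the log-expression curve (dimensionless,
#'   natural-log scale).
#' @param amplitude Log-scale amplitude \eqn{A \ge 0}. The noiseless
#'   peak-to-trough expression ratio is \eqn{\exp(2A)}.
#' @param acrophase Clock time of peak expression, hours in \eqn{[0, 24)}.
#' @param noise_sd Log-scale Gaussian standard deviation \eqn{\sigma \ge 0}.
#'
#' @return An object of class `gene_oscillator`.
#' @examples
#' nr1d1 <- gene_oscillator(mesor = 0, amplitude = 2, acrophase = 6)
#' cosinor_expression(6, nr1d1)   # exp(2), the noiseless peak
#' @export
gene_oscillator <- function(mesor = 0, amplitude = 1.2, acrophase = 6,
                            noise_sd = 0.5) {
  stopifnot(is.numeric(mesor), length(mesor) == 1L, is.finite(mesor))
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("`amplitude` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(acrophase) || length(acrophase) != 1L ||
      acrophase < 0 || acrophase >= 24)
    stop("`acrophase` must be a clock time in [0, 24)", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number", call. = FALSE)
  structure(
    list(mesor = mesor, amplitude = amplitude, acrophase = acrophase,
         noise_sd = noise_sd),
    class = "gene_oscillator"
  )
}

#' @export
print.gene_oscillator <- function(x, ...) {
  cat(sprintf(
    "<gene_oscillator> mesor %.3g, amplitude %.3g, acrophase %.2f h, noise sd %.3g\n",
    x$mesor, x$amplitude, x$acrophase, x$noise_sd))
  invisible(x)
}

#' Evaluate the cosinor expression model
#'
#' Returns relative expression at clock time `t` for the oscillator `osc`,
#' optionally perturbed by supplied standard-normal deviates (scaled by the
#' oscillator's `noise_sd`). With `noise_draw = 0` the deterministic curve is
#' returned.
#'
#' @param t Clock time(s) of death, hours in `[0, 24)`. Vectorized.
#' @param osc A [gene_oscillator()].
#' @param noise_draw Standard-normal deviate(s), recycled against `t`.
#' @return Strictly positive relative expression value(s).
#' @export
cosinor_expression <- function(t, osc, noise_draw = 0) {
  stopifnot(inherits(osc, "gene_oscillator"))
  if (any(!is.finite(t)) || any(t < 0) || any(t >= 24))
    stop("`t` must be clock time(s) in [0, 24)", call. = FALSE)
  exp(osc$mesor +
        osc$amplitude * cos(2 * pi * (t - osc$acrophase) / 24) +
        osc$noise_sd * noise_draw)
}

#' Convert relative expression to a cycle-threshold (Ct) value
#'
#' Inverts the exponential-amplification relationship
#' \eqn{E = (1 + \mathrm{eff})^{-Ct}} so the pipeline can be exercised from
#' the Ct entry point. `expr = 1` maps to `Ct = 0`; lower expression maps to
#' higher Ct.
#'
#' @param expr Relative expression, strictly positive. Vectorized.
#' @param efficiency Amplification efficiency in `(0, 1]` (1 = perfect
#'   doubling per cycle).
#' @return Ct values in cycles.
#' @seealso [ct_to_expression()], [ratios_from_ct()]
#' @export
ct_from_expression <- function(expr, efficiency = 1) {
  check_efficiency(efficiency)
  if (any(!is.finite(expr)) || any(expr <= 0))
    stop("`expr` must be strictly positive", call. = FALSE)
  -log(expr) / log1p(efficiency)
}

#' Convert a Ct value back to relative expression
#'
#' Inverse of [ct_from_expression()].
#'
#' @param ct Ct values in cycles. Vectorized.
#' @inheritParams ct_from_expression
#' @return Strictly positive relative expression.
#' @export
ct_to_expression <- function(ct, efficiency = 1) {
  check_efficiency(efficiency)
  if (any(!is.finite(ct))) stop("`ct` must be finite", call. = FALSE)
  exp(-ct * log1p(efficiency))
}

check_efficiency <- function(efficiency) {
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency <= 0 || efficiency > 1)
    stop("`efficiency` must be a single value in (0, 1]", call. = FALSE)
  invisible(efficiency)
}
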