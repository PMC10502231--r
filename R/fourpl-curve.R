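#' Four-parameter logistic dose-response curve
#'
#' Evaluates the 4PL model in the pharmacological (GraphPad-style)
#' parameterization on the log10-dose scale:
#' \deqn{f(d) = bottom + \frac{top - bottom}{1 + 10^{(\log_{10} IC_{50} - \log_{10} d)\, h}}}
#' With a negative Hill slope `hill` the curve decreases with dose, as for a
#' cytotoxic viability readout; at `d = ic50` the value is the midpoint
#' between the asymptotes.
#'
#' @param dose Numeric vector of strictly positive concentrations.
#' @param top,bottom Upper and lower asymptotes (survival fractions).
#' @param ic50 Midpoint concentration, same units as `dose`.
#' @param hill Hill slope; negative for inhibition.
#' @return Numeric vector of expected survival fractions.
#' @examples
#' fourpl(c(2.5, 9.6, 320), top = 1, bottom = 0.05, ic50 = 9.6, hill = -1.2)
#' @export
fourpl <- function(dose, top, bottom, ic50, hill) {
  stopifnot(all(dose > 0), ic50 > 0)
  bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(dose)) * hill))
}

# Invert the 4PL: the dose at which the curve passes through fraction `s`.
# Used to derive clone potencies from printed survival fractions and for
# ICmax-style calculations. s must lie strictly between the asymptotes.
fourpl_inverse <- function(s, top, bottom, ic50, hill) {
  stopifnot(s > min(top, bottom), s < max(top, bottom))
  # (top - bottom)/(s - bottom) - 1 = 10^((log ic50 - log d) * hill)
  r <- (top - bottom) / (s - bottom) - 1
  10^(log10(ic50) - log10(r) / hill)
}

# Given an observed survival fraction s at dose d and fixed shape
# (top, bottom, hill), solve for the ic50 that places the curve through
# (d, s). Closed form from the model equation.
fourpl_solve_ic50 <- function(s, dose, top, bottom, hill) {
  stopifnot(s > bottom, s < top, dose > 0)
  r <- (top - bottom) / (s - bottom) - 1
  10^(log10(dose) + log10(r) / hill)
}
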