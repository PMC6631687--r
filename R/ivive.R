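#' Well-stirred liver model
#'
#' Predicts hepatic (plasma) clearance from unbound intrinsic clearance,
#' plasma free fraction and hepatic blood flow, treating the liver as a
#' single well-mixed compartment:
#' `CL_p = Q * f_p * CL_int / (Q + f_p * CL_int)`.
#' The prediction is bounded above by both the hepatic blood flow `Q`
#' (flow-limited regime) and `f_p * CL_int` (restrictive, binding-limited
#' regime).
#'
#' @param cl_int Intrinsic clearance, mL/min/kg.
#' @param f_p Fraction unbound in plasma, in (0, 1].
#' @param q Hepatic blood flow, mL/min/kg (default 55, rat).
#' @return Predicted plasma clearance, mL/min/kg.
#' @examples
#' well_stirred_clearance(106.1, 0.027)  # ~2.7 mL/min/kg
#' @export
well_stirred_clearance <- function(cl_int, f_p, q = 55) {
  if (!is.numeric(cl_int) || any(!is.finite(cl_int)) || any(cl_int <= 0))
    stop_invalid_input("`cl_int` must be positive")
  if (!is.numeric(f_p) || any(!is.finite(f_p)) || any(f_p <= 0) || any(f_p > 1))
    stop_invalid_input("`f_p` must be in (0, 1]")
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    stop_invalid_input("`q` must be positive")
  q * f_p * cl_int / (q + f_p * cl_int)
}

#' Back-solve the plasma free fraction from the well-stirred model
#'
#' Algebraic inverse of [well_stirred_clearance()] in `f_p`:
#' `f_p = CL_p * Q / (CL_int * (Q - CL_p))`. Useful for reconstructing an
#' implied free fraction from a reported (CL_int, CL_p) pair; round-trips
#' through the forward model to machine precision.
#'
#' @param cl_p Plasma clearance, mL/min/kg; must be strictly below `q`.
#' @param cl_int Intrinsic clearance, mL/min/kg.
#' @param q Hepatic blood flow, mL/min/kg.
#' @return The implied fraction unbound in plasma.
#' @export
invert_well_stirred_fp <- function(cl_p, cl_int, q = 55) {
  assert_scalar_positive(cl_int, "cl_int")
  assert_scalar_positive(q, "q")
  if (!is.numeric(cl_p) || length(cl_p) != 1L || !is.finite(cl_p) || cl_p <= 0)
    stop_invalid_input("`cl_p` must be a single positive number")
  if (cl_p >= q)
    stop_no_solution(sprintf(
      "cl_p (%.3g) must be below hepatic blood flow q (%.3g): the well-stirred model cannot exceed Q",
      cl_p, q))
  cl_p * q / (cl_int * (q - cl_p))
}

#' Fold error of a clearance prediction
#'
#' Ratio predicted/observed; values below 1 indicate underprediction.
#'
#' @param predicted,observed Positive clearance values (same units).
#' @return `predicted / observed` (vectorized).
#' @export
fold_error <- function(predicted, observed) {
  if (!is.numeric(predicted) || !is.numeric(observed) ||
      any(!is.finite(predicted)) || any(!is.finite(observed)) ||
      any(predicted <= 0) || any(observed <= 0))
    stop_invalid_input("`predicted` and `observed` must be positive")
  predicted / observed
}

#' Average fold error (geometric-mean bias)
#'
#' `AFE = 10^(mean(log10(predicted/observed)))`, the geometric mean of the
#' per-compound fold errors. AFE < 1 indicates systematic underprediction;
#' its inverse is the fold underprediction.
#'
#' @param predicted,observed Positive numeric vectors of equal length.
#' @return The average fold error (unitless).
#' @examples
#' afe(c(2.72, 7.76, 4.70), c(3.22, 9.10, 7.10))  # ~0.78
#' @export
afe <- function(predicted, observed) {
  if (length(predicted) == 0L)
    stop_invalid_input("`predicted` must be non-empty")
  if (length(predicted) != length(observed))
    stop_invalid_input("`predicted` and `observed` must have equal length")
  10^mean(log10(fold_error(predicted, observed)))
}

#' Root mean square error of predictions
#'
#' `RMSE = sqrt(mean((predicted - observed)^2))`, in the units of the inputs.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return The root mean square error.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0L)
    stop_invalid_input("`predicted` must be non-empty")
  if (length(predicted) != length(observed))
    stop_invalid_input("`predicted` and `observed` must have equal length")
  if (!is.numeric(predicted) || !is.numeric(observed) ||
      any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop_invalid_input("inputs must be finite numeric")
  sqrt(mean((predicted - observed)^2))
}

#' Prediction-accuracy report
#'
#' Combines per-compound predicted and observed plasma clearances into fold
#' errors plus the overall bias/precision summary (AFE, fold underprediction
#' = 1/AFE, RMSE). All arithmetic is done at full precision; rounding is
#' applied only by the print/format methods (fold errors and AFE to 2
#' decimals, RMSE to 1).
#'
#' @param compound_id Character vector of compound labels.
#' @param predicted,observed Positive plasma clearances, mL/min/kg.
#' @return An object of class `accuracy_report`: a list with `per_compound`
#'   (data frame with `fold_error` column), `afe`, `fold_underprediction`
#'   and `rmse`.
#' @export
accuracy_report <- function(compound_id, predicted, observed) {
  if (length(compound_id) != length(predicted) ||
      length(predicted) != length(observed))
    stop_invalid_input("all inputs must have equal length")
  a <- afe(predicted, observed)
  structure(list(
    per_compound = data.frame(compound_id = as.character(compound_id),
                              predicted = predicted, observed = observed,
                              fold_error = fold_error(predicted, observed)),
    afe = a, fold_underprediction = 1 / a,
    rmse = rmse(predicted, observed)),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  tab <- x$per_compound
  tab$predicted <- round(tab$predicted, 2)
  tab$observed <- round(tab$observed, 2)
  tab$fold_error <- round(tab$fold_error, 2)
  cat("Clearance prediction accuracy\n")
  print(tab, row.names = FALSE)
  cat(sprintf("AFE = %.2f  (fold underprediction %.1f)   RMSE = %.1f mL/min/kg\n",
              x$afe, x$fold_underprediction, x$rmse))
  invisible(x)
}
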