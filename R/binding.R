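#' Plasma free fraction from an ultrafiltration count pair
#'
#' The free (unbound) fraction is the ratio of radioactivity in equal
#' volumes of ultrafiltrate and spiked plasma:
#' `f_p = counts_filtrate / counts_plasma`. Protein-bound radiotracer is
#' retained by the filter, so the filtrate carries only the free compound.
#' No correction is applied for nonspecific binding to the filtration
#' device.
#'
#' @param counts_plasma Counts in the spiked-plasma aliquot (> 0),
#'   vectorized.
#' @param counts_filtrate Counts in the equal-volume filtrate aliquot
#'   (>= 0). A filtrate count exceeding its plasma count is physically
#'   impossible and raises a data-quality error rather than being clamped.
#' @return Free fraction(s) in \[0, 1\].
#' @examples
#' free_fraction(33000, 891)  # ~0.027
#' @export
free_fraction <- function(counts_plasma, counts_filtrate) {
  if (!is.numeric(counts_plasma) || !is.numeric(counts_filtrate) ||
      length(counts_plasma) != length(counts_filtrate))
    stop_invalid_input("count vectors must be numeric and of equal length")
  if (any(!is.finite(counts_plasma)) || any(!is.finite(counts_filtrate)) ||
      any(counts_plasma <= 0) || any(counts_filtrate < 0))
    stop_invalid_input("counts_plasma must be > 0 and counts_filtrate >= 0")
  if (any(counts_filtrate > counts_plasma))
    stop_data_quality("filtrate counts exceed plasma counts: physically impossible, check the measurement")
  counts_filtrate / counts_plasma
}

#' Summarize free fractions across animals
#'
#' @param fp Numeric vector of per-animal free fractions (e.g. from
#'   [free_fraction()]).
#' @return A list with `mean`, `sd` (NA for a single animal) and `n`.
#' @export
summarize_free_fraction <- function(fp) {
  if (length(fp) == 0L)
    stop_invalid_input("no free-fraction values supplied")
  if (any(!is.finite(fp)) || any(fp < 0) || any(fp > 1))
    stop_invalid_input("free fractions must lie in [0, 1]")
  list(mean = mean(fp),
       sd = if (length(fp) > 1) stats::sd(fp) else NA_real_,
       n = length(fp))
}
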