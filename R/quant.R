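#' Reconstruct per-barcode densities from plating and qPCR
#'
#' The total barcoded density is measured by selective plating and the
#' barcode composition by qPCR; per-barcode densities are the renormalized
#' relative frequencies multiplied by the total. Frequencies below `floor`
#' are treated as qPCR noise and zeroed before renormalization.
#'
#' @param total_cfu_per_g total barcoded density (CFU/g), >= 0.
#' @param frequencies per-barcode relative frequencies, >= 0; need not sum
#'   to one.
#' @param floor calling floor applied to frequencies before renormalization
#'   (default 1e-4).
#' @return numeric vector of per-barcode CFU/g, summing exactly to
#'   `total_cfu_per_g`.
#' @examples
#' barcode_cfu(1e6, c(0.5, 0.5))
#' @export
barcode_cfu <- function(total_cfu_per_g, frequencies, floor = 1e-4) {
  if (total_cfu_per_g < 0) stop("'total_cfu_per_g' must be >= 0")
  frequencies <- as.numeric(frequencies)
  if (any(frequencies < 0) || anyNA(frequencies)) {
    stop("'frequencies' must be nonnegative")
  }
  if (total_cfu_per_g == 0) return(numeric(length(frequencies)))
  frequencies[frequencies < floor] <- 0
  s <- sum(frequencies)
  if (s == 0) {
    stop("all frequencies are zero but the total density is positive: ",
         "inconsistent readout")
  }
  total_cfu_per_g * frequencies / s
}

#' Pielou evenness of barcode counts
#'
#' Shannon entropy of the barcode proportions divided by its maximum
#' \eqn{\ln S}, where `S` is the number of barcodes in the experimental
#' design (not the observed richness), so a partially extinct set of
#' barcodes scores below 1 even if the survivors are balanced. Zero counts
#' contribute nothing to the entropy.
#'
#' @param counts per-barcode counts or densities, >= 0.
#' @param S number of barcodes in the design (default `length(counts)`).
#' @return evenness in \[0, 1\]; `NA` with attribute `extinct = TRUE` when
#'   every count is zero (no evenness can be estimated).
#' @examples
#' pielou_evenness(c(2, 1, 1, 0, 0, 0))
#' @export
pielou_evenness <- function(counts, S = length(counts)) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) stop("'counts' must be nonnegative")
  if (S < 2) stop("'S' must be >= 2")
  if (sum(counts) == 0) {
    return(structure(NA_real_, extinct = TRUE))
  }
  p <- counts / sum(counts)
  p <- p[p > 0]
  H <- -sum(p * log(p))
  H / log(S)
}

#' Competitive index
#'
#' Ratio of two strains' endpoint abundances normalized by their inoculum
#' ratio. When one side of the comparison pools several barcoded strains
#' against a single untagged strain, set the corresponding `*_pool` argument
#' so the pooled density is divided by the number of pooled barcodes (for
#' example, one untagged strain versus six pooled barcodes uses
#' `denominator_pool = 6`).
#'
#' @param numerator_end,denominator_end endpoint densities (> 0).
#' @param numerator_0,denominator_0 inoculum densities (> 0; both default 1,
#'   i.e. a 1:1 inoculum).
#' @param numerator_pool,denominator_pool number of barcoded strains pooled
#'   into each side (default 1).
#' @return the competitive index (dimensionless).
#' @examples
#' competitive_index(100, 1)                      # 100
#' competitive_index(6e8, 6e8, denominator_pool = 6) / 6  # one-sixth rule
#' @export
competitive_index <- function(numerator_end, denominator_end,
                              numerator_0 = 1, denominator_0 = 1,
                              numerator_pool = 1, denominator_pool = 1) {
  vals <- c(numerator_end, denominator_end, numerator_0, denominator_0)
  if (any(!is.finite(vals))) stop("inputs must be finite")
  if (any(vals <= 0)) {
    stop("zero or negative density: the competitive index is undefined; ",
         "report a bound from the detection limit instead")
  }
  num <- numerator_end / numerator_pool
  den <- denominator_end / denominator_pool
  (num / den) / (numerator_0 / denominator_0)
}

#' Per-barcode fold change relative to the inoculum
#'
#' @param endpoint_cfu endpoint per-barcode CFU (or CFU/g), >= 0.
#' @param inoculum_cfu inoculum per-barcode CFU, > 0 element-wise.
#' @return element-wise ratio; an extinct barcode maps to 0.
#' @export
fold_change <- function(endpoint_cfu, inoculum_cfu) {
  endpoint_cfu <- as.numeric(endpoint_cfu)
  inoculum_cfu <- as.numeric(inoculum_cfu)
  if (length(endpoint_cfu) != length(inoculum_cfu)) {
    stop("vectors must have equal length")
  }
  if (any(inoculum_cfu <= 0)) {
    stop("zero inoculum entry: fold change undefined")
  }
  if (any(endpoint_cfu < 0)) stop("'endpoint_cfu' must be >= 0")
  endpoint_cfu / inoculum_cfu
}
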