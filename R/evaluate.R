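#' Segmentation accuracy assessment
#'
#' Overlap of a binary segmentation against a ground-truth mask, summarized
#' by the Dice similarity coefficient `DSC = 2 TP / (2 TP + FP + FN)`.
#'
#' @name evaluate-dsc
NULL

#' Overlap counts against a ground-truth mask
#'
#' @param seg,truth binary vectors/arrays of equal size (nonzero =
#'   foreground)
#' @return list with integer `tp`, `fp`, `fn`, `tn`
#' @export
overlap_counts <- function(seg, truth) {
  if (length(seg) != length(truth)) {
    stop("segmentation and truth have different sizes (", length(seg),
         " vs ", length(truth), ")")
  }
  s <- as.logical(seg != 0)
  t <- as.logical(truth != 0)
  list(tp = sum(s & t), fp = sum(s & !t), fn = sum(!s & t), tn = sum(!s & !t))
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`; defined as 1 when both masks are empty.
#'
#' @inheritParams overlap_counts
#' @return scalar in `[0, 1]`
#' @export
dice <- function(seg, truth) {
  cnt <- overlap_counts(seg, truth)
  denom <- 2 * cnt$tp + cnt$fp + cnt$fn
  if (denom == 0) return(1)
  2 * cnt$tp / denom
}

#' Run the synthetic comparison experiment
#'
#' For every combination of method, SNR and noise seed: generate the
#' phantom, produce the (possibly noisy) re-estimated tensor field, segment
#' with the requested method, and score against the ground truth.
#' `snr = Inf` rows use the clean field directly. Deterministic given the
#' seeds.
#'
#' @param spec a [phantom_spec()]
#' @param snr_list SNR levels (may include `Inf`)
#' @param methods subset of `c("learned", "euclidean", "jdivergence",
#'   "geodesic")`
#' @param seeds integer noise seeds (one run per seed; collapsed to a single
#'   run for `snr = Inf`, which has no randomness)
#' @param ... forwarded to [segment_field()] (e.g. `alpha0`, `eps`)
#' @return data frame with columns `method`, `snr`, `seed`, `dsc`, `iters`,
#'   `final_cost`
#' @export
run_comparison <- function(spec = phantom_spec(), snr_list = c(Inf, 20, 15, 10),
                           methods = c("learned", "euclidean", "jdivergence",
                                       "geodesic"),
                           seeds = 1:10, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  ph <- make_phantom(spec)
  rows <- list()
  for (snr in snr_list) {
    snr_seeds <- if (is.infinite(snr)) seeds[1] else seeds
    for (seed in snr_seeds) {
      field <- noisy_field(ph$field, snr = snr, seed = seed)
      for (method in methods) {
        res <- segment_field(field, ph$labels, method = method, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, snr = snr, seed = seed,
          dsc = dice(res$seg, ph$truth),
          iters = res$iterations, final_cost = res$cost)
      }
    }
  }
  do.call(rbind, rows)
}
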