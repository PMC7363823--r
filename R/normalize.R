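#' Fit min-max normalization parameters on training batches
#'
#' Records per-variable minima and maxima (7 auxiliary inputs and 3
#' outputs) across all supplied batches, for scaling to [0, 1]. Values
#' outside the training range map outside [0, 1] by design (no clipping),
#' so extrapolation is visible rather than silently distorted. Fit this on
#' training batches only: test batches must never contribute to the ranges.
#'
#' @param batches List of \code{"fermentation_batch"} objects.
#' @return A list of class \code{"ferm_normalizer"} with \code{aux_min},
#'   \code{aux_max}, \code{out_min}, \code{out_max}.
#' @export
fit_normalizer <- function(batches) {
  stopifnot(length(batches) >= 1)
  aux <- do.call(rbind, lapply(batches, function(b) b$aux))
  out <- do.call(rbind, lapply(batches, function(b) b$outputs))
  rng <- function(m, what) {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
    flat <- which(hi - lo <= 0)
    if (length(flat)) {
      stop("fit_normalizer: constant ", what, " variable(s): ",
           paste(colnames(m)[flat], collapse = ", "))
    }
    list(min = lo, max = hi)
  }
  a <- rng(aux, "auxiliary")
  o <- rng(out, "output")
  structure(list(aux_min = a$min, aux_max = a$max,
                 out_min = o$min, out_max = o$max),
            class = "ferm_normalizer")
}

scale_01 <- function(m, lo, hi) {
  sweep(sweep(m, 2, lo, "-"), 2, hi - lo, "/")
}

unscale_01 <- function(m, lo, hi) {
  sweep(sweep(m, 2, hi - lo, "*"), 2, lo, "+")
}

#' Apply / invert the min-max scaling
#'
#' @param np A \code{"ferm_normalizer"}.
#' @param aux A q x 7 auxiliary-input matrix (original units).
#' @param outputs A q x 3 output matrix.
#' @return The scaled (or unscaled) matrix. \code{normalize_aux} and
#'   \code{normalize_outputs} map to the [0, 1] training range;
#'   \code{denormalize_outputs} inverts the output scaling back to g/L.
#'   Apply followed by invert is the identity to ~1e-12.
#' @export
normalize_aux <- function(np, aux) {
  stopifnot(inherits(np, "ferm_normalizer"))
  scale_01(aux, np$aux_min, np$aux_max)
}

#' @rdname normalize_aux
#' @export
normalize_outputs <- function(np, outputs) {
  stopifnot(inherits(np, "ferm_normalizer"))
  scale_01(outputs, np$out_min, np$out_max)
}

#' @rdname normalize_aux
#' @export
denormalize_outputs <- function(np, outputs) {
  stopifnot(inherits(np, "ferm_normalizer"))
  unscale_01(outputs, np$out_min, np$out_max)
}
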