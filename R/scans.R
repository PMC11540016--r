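#' Average repeated CBCT scans voxelwise
#'
#' Gel readout acquires several CBCT scans per condition (six pre- and six
#' post-irradiation in the reference protocol) and averages each set to
#' suppress stochastic noise by 1/sqrt(n) before background subtraction.
#'
#' @param scans list of [scalar_volume()]s on compatible geometries with a
#'   common quantity.
#' @return A [scalar_volume()] holding the voxelwise arithmetic mean.
#' @export
average_volumes <- function(scans) {
  if (!is.list(scans) || length(scans) == 0L)
    stop("scans must be a non-empty list of scalar_volume objects")
  if (!all(vapply(scans, inherits, TRUE, "scalar_volume")))
    stop("scans must all be scalar_volume objects")
  ref <- scans[[1]]
  for (s in scans[-1]) {
    stop_if_incompatible(ref$geometry, s$geometry, "scans")
    if (s$quantity != ref$quantity)
      stop("scans must share the same quantity")
  }
  acc <- Reduce(`+`, lapply(scans, `[[`, "values"))
  scalar_volume(acc / length(scans), ref$geometry, quantity = ref$quantity)
}

#' Background-subtract averaged CBCT scans
#'
#' Computes the voxelwise CBCT-number change (post minus pre), the gel's
#' measurable dose response.
#'
#' @param post_mean,pre_mean averaged post-/pre-irradiation [scalar_volume()]s
#'   with quantity `"cbct_number"` on compatible geometries.
#' @return A [scalar_volume()] with quantity `"delta_cbct"`.
#' @export
subtract_background <- function(post_mean, pre_mean) {
  stopifnot(inherits(post_mean, "scalar_volume"),
            inherits(pre_mean, "scalar_volume"))
  stop_if_incompatible(post_mean$geometry, pre_mean$geometry,
                       "post and pre volumes")
  if (post_mean$quantity != "cbct_number" || pre_mean$quantity != "cbct_number")
    stop("subtract_background expects cbct_number volumes")
  scalar_volume(post_mean$values - pre_mean$values, post_mean$geometry,
                quantity = "delta_cbct")
}
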