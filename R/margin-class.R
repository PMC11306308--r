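#' Bin a signed distance from the tumor border into a margin class
#'
#' The tumor border (distance 0) and everything inside it counts as tumor.
#' Tumor-free margins are `very_close` below 1 mm, `close` from 1 to 5 mm
#' (both endpoints included), and `clear` beyond 5 mm.
#'
#' @param distance_mm numeric vector of signed distances (mm); negative or
#'   zero means inside the tumor or on the border.
#' @return character vector of margin classes (see [margin_classes()]).
#' @export
#' @examples
#' assign_margin_class(c(-2, 0, 0.5, 1, 3, 5, 7))
assign_margin_class <- function(distance_mm) {
  if (!is.numeric(distance_mm) || any(!is.finite(distance_mm)))
    stop("distance_mm must be finite numeric")
  out <- character(length(distance_mm))
  out[distance_mm <= 0] <- "tumor"
  out[distance_mm > 0 & distance_mm < 1] <- "very_close"
  out[distance_mm >= 1 & distance_mm <= 5] <- "close"
  out[distance_mm > 5] <- "clear"
  out
}
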