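#' Normalise immunoblot band densities to the loading control
#'
#' Divides the chosen band density (full-length sensor, summed cleavage
#' fragments, or the calpain-1 target band) by the beta-actin loading-control
#' density, lane by lane. The quotient is invariant to uniform lane-wise
#' rescaling, so exposure differences between lanes cancel.
#'
#' @param lanes Tibble with one row per lane; columns `full_length`,
#'   `cleaved`, `actin`, and optionally `target` (densities, a.u.).
#' @param which Which band to normalise: `"full_length"`, `"cleaved"` or
#'   `"target"`.
#' @return The input with a `normalized` column (a.u./a.u.).
#' @export
#' @examples
#' lanes <- tibble::tibble(lane = 1, full_length = 4, cleaved = 2, actin = 2)
#' normalize_to_loading(lanes, "cleaved")$normalized # 1
normalize_to_loading <- function(lanes,
                                 which = c("full_length", "cleaved", "target")) {
  which <- match.arg(which)
  stopifnot(is.data.frame(lanes), all(c(which, "actin") %in% names(lanes)))
  dens <- lanes[[which]]
  actin <- lanes$actin
  stopifnot(is.numeric(dens), all(dens >= 0), is.numeric(actin))
  if (any(actin <= 0)) {
    stop("zero or negative loading-control density in lane(s): ",
         paste(which(actin <= 0), collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(lanes, normalized = dens / actin)
}

#' Sensor cleavage ratio
#'
#' Cleaved over full-length sensor density per lane, the within-lane readout
#' of calpain-mediated sensor cleavage. Like the loading-control
#' normalisation, the ratio cancels uniform exposure scaling.
#'
#' @param lanes Tibble with `full_length` and `cleaved` density columns.
#' @return The input with a `cleavage_ratio` column (dimensionless).
#' @export
#' @examples
#' cleavage_ratio(tibble::tibble(full_length = 4, cleaved = 1))$cleavage_ratio
cleavage_ratio <- function(lanes) {
  stopifnot(is.data.frame(lanes),
            all(c("full_length", "cleaved") %in% names(lanes)),
            all(lanes$cleaved >= 0))
  if (any(lanes$full_length <= 0)) {
    stop("zero or negative full-length density in lane(s): ",
         paste(which(lanes$full_length <= 0), collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(lanes, cleavage_ratio = .data$cleaved / .data$full_length)
}
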