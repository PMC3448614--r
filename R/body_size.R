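# Ratio-based estimation chain: incomplete skeletal element -> complete
# element length -> femur-equivalent length -> total body length.
#
# The proportion ratios come from reference specimens with a measured
# element, a femur(-equivalent) length and a scaled body-length estimate;
# one reference row per (species, element) calibrates the element:femur
# ratio, and one per species the body:femur ratio.

#' Calibrate skeletal proportions from a measurement table
#'
#' Derives, per species, the body length : femur length ratio and, per
#' (species, element), the femur : element ratio, from a measurement table
#' such as the packaged rhabdodontid one (see
#' \code{\link{load_element_table}}).  The reference row for each
#' calibration is the row with a directly measured (not estimated) length
#' when available, otherwise the row with the largest length.
#'
#' @param elements data frame with columns \code{species}, \code{specimen},
#'   \code{element}, \code{element_length_mm}, \code{element_estimated},
#'   \code{femur_length_mm}, \code{femur_estimated}, \code{body_length_m}.
#' @return an object of class \code{proportion_calibration}.
#' @export
calibrate_proportions <- function(elements) {
  stopifnot(is.data.frame(elements))
  out <- list()
  for (sp in unique(elements$species)) {
    rows <- elements[elements$species == sp, , drop = FALSE]
    # body:femur from the row with a measured femur, else the largest femur
    pick <- if (any(!rows$femur_estimated)) {
      r <- rows[!rows$femur_estimated, , drop = FALSE]
      r[which.max(r$femur_length_mm), ]
    } else rows[which.max(rows$femur_length_mm), ]
    body_per_femur <- 1000 * pick$body_length_m / pick$femur_length_mm
    el <- list()
    for (e in unique(rows$element)) {
      er <- rows[rows$element == e, , drop = FALSE]
      ref <- if (any(!er$element_estimated)) {
        r <- er[!er$element_estimated, , drop = FALSE]
        r[which.max(r$element_length_mm), ]
      } else er[which.max(er$element_length_mm), ]
      el[[e]] <- list(femur_per_element = ref$femur_length_mm / ref$element_length_mm,
                      reference = ref$specimen)
    }
    out[[sp]] <- list(body_per_femur = body_per_femur,
                      body_reference = pick$specimen, elements = el)
  }
  structure(out, class = "proportion_calibration")
}

#' @export
print.proportion_calibration <- function(x, ...) {
  cat("Proportion calibration for", length(x), "species\n")
  for (sp in names(x)) {
    cat(sprintf("  %s: body = %.3f x femur (ref %s); elements: %s\n", sp,
                x[[sp]]$body_per_femur / 1000, x[[sp]]$body_reference,
                paste(sprintf("%s x%.3f", names(x[[sp]]$elements),
                              vapply(x[[sp]]$elements,
                                     function(e) e$femur_per_element, 0)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Femur-equivalent length of a skeletal element
#'
#' Scales a (possibly incomplete, reconstructed) element length to the
#' femur length of the same individual using the species' calibrated
#' element : femur proportion.  A femur maps to itself.
#'
#' @param species species name present in the calibration.
#' @param element element type (\code{"femur"}, \code{"humerus"},
#'   \code{"tibia"}, ...).
#' @param length_mm element length in mm.
#' @param calibration a \code{proportion_calibration}.
#' @return femur-equivalent length in mm.
#' @export
femur_from_element <- function(species, element, length_mm, calibration) {
  if (length_mm <= 0) stop("element length must be positive")
  if (element == "femur") return(length_mm)
  cal <- calibration[[species]]
  if (is.null(cal) || is.null(cal$elements[[element]]))
    stop("no calibration for (", species, ", ", element, "); available: ",
         paste(unlist(lapply(names(calibration), function(sp)
           paste(sp, names(calibration[[sp]]$elements), sep = ":"))),
           collapse = ", "))
  length_mm * cal$elements[[element]]$femur_per_element
}

#' Total body length from femur length
#'
#' @param species species name present in the calibration (ignored when
#'   \code{ratio} is given directly).
#' @param femur_mm femur(-equivalent) length in mm.
#' @param calibration a \code{proportion_calibration}; or supply
#'   \code{ratio}.
#' @param ratio optional explicit body:femur ratio (body mm per femur mm).
#' @param round_to rounding grain in metres (default 0.1 m, half-up);
#'   \code{NULL} for no rounding.
#' @return estimated body length in metres.
#' @export
body_from_femur <- function(species = NULL, femur_mm, calibration = NULL,
                            ratio = NULL, round_to = 0.1) {
  if (any(femur_mm <= 0)) stop("femur length must be positive")
  if (is.null(ratio)) {
    if (is.null(calibration) || is.null(calibration[[species]]))
      stop("no body-length calibration for species '", species, "'")
    ratio <- calibration[[species]]$body_per_femur
  }
  m <- femur_mm * ratio / 1000
  if (is.null(round_to)) m else floor(m / round_to + 0.5) * round_to
}

#' Audit the implied body:femur ratios of a measurement table
#'
#' Recomputes, for every row, the ratio of estimated body length (mm) to
#' femur-equivalent length, flags rows outside a plausibility band, and
#' checks which printed body lengths are reproduced by the per-species
#' calibration after rounding.
#'
#' @param elements measurement table (see
#'   \code{\link{calibrate_proportions}}).
#' @param band numeric length-2: acceptable body:femur ratio range.
#' @return data frame of class \code{ratio_audit}: per-row implied ratio,
#'   in-band flag, calibrated body-length prediction and whether it
#'   reproduces the printed value at 0.1 m.
#' @export
ratio_audit <- function(elements, band = c(7.0, 7.7)) {
  if (!nrow(elements)) {
    out <- data.frame(species = character(0), specimen = character(0),
                      implied_ratio = numeric(0), in_band = logical(0),
                      predicted_m = numeric(0), reproduced = logical(0))
    class(out) <- c("ratio_audit", class(out))
    return(out)
  }
  cal <- calibrate_proportions(elements)
  implied <- 1000 * elements$body_length_m / elements$femur_length_mm
  predicted <- vapply(seq_len(nrow(elements)), function(i)
    body_from_femur(elements$species[i], elements$femur_length_mm[i], cal), 0)
  out <- data.frame(species = elements$species, specimen = elements$specimen,
                    femur_mm = elements$femur_length_mm,
                    body_m = elements$body_length_m,
                    implied_ratio = implied,
                    in_band = implied >= band[1] & implied <= band[2],
                    predicted_m = predicted,
                    reproduced = abs(predicted - elements$body_length_m) < 0.05 + 1e-9)
  attr(out, "band") <- band
  class(out) <- c("ratio_audit", class(out))
  out
}

#' @export
print.ratio_audit <- function(x, ...) {
  band <- attr(x, "band")
  cat(sprintf("Body:femur ratio audit (%d rows; band %.1f-%.1f)\n",
              nrow(x), band[1], band[2]))
  if (nrow(x)) {
    cat(sprintf("  implied ratios %.2f-%.2f; %d outside band; %d/%d printed body lengths reproduced at 0.1 m\n",
                min(x$implied_ratio), max(x$implied_ratio), sum(!x$in_band),
                sum(x$reproduced), nrow(x)))
    off <- x[!x$reproduced | !x$in_band, , drop = FALSE]
    if (nrow(off)) print.data.frame(off, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
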