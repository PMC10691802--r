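# Idealized spherical 10-10 electrode geometry for the 64-channel montage.
# Positions are constructed from row (anterior-posterior) and column
# (lateral) arc angles on a unit sphere, mirror-symmetric by construction.
# They are idealized layout coordinates, not measured digitizer positions;
# sufficient for spherical-spline CSD and contra/ipsi hemisphere logic.

.MONTAGE_ROWS <- c(
  Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
  CP = -18, P = -36, PO = -54, O = -72, I = -90
)

.MONTAGE_LABELS <- c(
  "Fp1", "Fpz", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2",
  "Iz"
)

# map a 10-10 label to (row, lateral index); T/TP/FT aliases sit on the
# C/CP/FC rows at index 7/8
.parse_label <- function(label) {
  alias <- c(T7 = "C7", T8 = "C8", TP7 = "CP7", TP8 = "CP8",
             FT7 = "FC7", FT8 = "FC8")
  lab <- if (label %in% names(alias)) alias[[label]] else label
  m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
  row <- m[2]
  col <- m[3]
  idx <- if (col == "z") 0L else as.integer(col)
  list(row = row, idx = idx)
}

#' Standard 64-channel montage with idealized spherical positions
#'
#' Returns the 64 channel labels of the extended 10-10 layout used by
#' 64-channel recording systems, with unit-sphere coordinates (x = right,
#' y = anterior, z = up) constructed from the standard row/column arc angles.
#' Left/right pairs are exact mirror images.
#'
#' @return A tibble with columns `channel`, `x`, `y`, `z`, `hemisphere`
#'   (`"left"`, `"right"`, `"midline"`).
#' @examples
#' head(standard_montage())
#' @export
standard_montage <- function() {
  lat_angle <- function(idx) {
    if (idx == 0L) return(0)
    c(`1` = 18, `2` = 18, `3` = 36, `4` = 36, `5` = 54, `6` = 54,
      `7` = 72, `8` = 72, `9` = 90, `10` = 90)[[as.character(idx)]]
  }
  rows <- purrr::map_dfr(.MONTAGE_LABELS, function(lab) {
    p <- .parse_label(lab)
    alpha <- .MONTAGE_ROWS[[p$row]] * pi / 180
    beta <- lat_angle(p$idx) * pi / 180
    side <- if (p$idx == 0L) 0 else if (p$idx %% 2L == 1L) -1 else 1
    tibble::tibble(
      channel = lab,
      x = side * cos(alpha) * sin(beta),
      y = sin(alpha),
      z = cos(alpha) * cos(beta),
      hemisphere = c("left", "midline", "right")[side + 2]
    )
  })
  rows
}

#' Region-of-interest channel sets
#'
#' Mirror-symmetric left/right channel sets for the three analysis ROIs:
#' occipital cue-processing channels (O1/PO3/PO7 vs O2/PO4/PO8),
#' occipito-temporal stimulus channels (P7/P9 vs P8/P10), and the midline
#' centro-parietal set used for the CPP (CPz/CP1/CP2, where CP1 is left and
#' CP2 right but the CPP is analyzed as their unsigned average).
#'
#' @param name One of `"occipital"`, `"stimulus"`, `"cpp"`.
#' @return A list with elements `name`, `left`, `right` (class `roi_spec`).
#' @export
roi_spec <- function(name = c("occipital", "stimulus", "cpp")) {
  name <- match.arg(name)
  spec <- switch(name,
    occipital = list(left = c("O1", "PO3", "PO7"),
                     right = c("O2", "PO4", "PO8")),
    stimulus = list(left = c("P7", "P9"), right = c("P8", "P10")),
    cpp = list(left = c("CP1"), right = c("CP2"), midline = "CPz")
  )
  structure(c(list(name = name), spec), class = "roi_spec")
}

#' All channels of an ROI
#' @param roi A `roi_spec`.
#' @return Character vector of channel names.
#' @export
roi_channels <- function(roi) {
  stopifnot(inherits(roi, "roi_spec"))
  unlist(roi[setdiff(names(roi), "name")], use.names = FALSE)
}
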