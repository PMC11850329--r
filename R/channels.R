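#' Standard 60-channel EEG montage
#'
#' Labels of the 60 EEG electrodes (10-10 system) used throughout the package,
#' plus the four periocular EOG electrodes (left/right outer canthus, above and
#' below the left eye).
#'
#' @return Character vector of 60 EEG labels (`fastcue_montage()`) or 4 EOG
#'   labels (`fastcue_eog_labels()`).
#' @export
fastcue_montage <- function() {
  c(
    "Fp1", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
}

#' @rdname fastcue_montage
#' @export
fastcue_eog_labels <- function() {
  c("EOGL", "EOGR", "EOGU", "EOGD")
}

#' Approximate 2-D electrode positions
#'
#' Schematic head-flattened coordinates for 10-10 labels, used for spatial
#' weighting in the simulator and for topographic plots. `x` runs left (-) to
#' right (+), `y` posterior (-) to anterior (+); unit scale is arbitrary.
#'
#' @param labels Character vector of 10-10 electrode labels.
#' @return Tibble with columns `label`, `x`, `y`.
#' @export
electrode_positions <- function(labels = fastcue_montage()) {
  rows <- c(
    Fp = 4, AF = 3, F = 2, FT = 1, FC = 1, T = 0, C = 0,
    TP = -1, CP = -1, P = -2, PO = -3, O = -4
  )
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1L]]
    if (length(m) != 3L) stop("unrecognized electrode label: ", lab)
    row <- m[2L]
    if (!row %in% names(rows)) stop("unrecognized electrode row: ", lab)
    idx <- m[3L]
    if (idx == "z") {
      steps <- 0
    } else {
      k <- as.integer(idx)
      steps <- if (k %% 2L == 1L) -(k + 1L) / 2 else k / 2
    }
    # temporal rows (FT/T/TP) sit one step further out than their FC/C/CP index
    c(x = steps * 0.25, y = rows[[row]] * 0.25)
  }
  xy <- t(vapply(labels, parse_one, c(x = 0, y = 0)))
  tibble::tibble(label = labels, x = unname(xy[, "x"]), y = unname(xy[, "y"]))
}

# Gaussian spatial pattern centred on an electrode, evaluated on `labels`.
spatial_pattern <- function(labels, center = "C1", sigma = 0.45) {
  pos <- electrode_positions(unique(c(labels, center)))
  c0 <- pos[pos$label == center, ]
  p <- pos[match(labels, pos$label), ]
  exp(-((p$x - c0$x)^2 + (p$y - c0$y)^2) / (2 * sigma^2))
}
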