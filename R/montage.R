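#' Electrode montages
#'
#' Built-in 2-D electrode coordinate table for the 30-channel 10-20 layout
#' used throughout the package, together with the standard 19- and 8-channel
#' subsets. Coordinates are a flat projection of the scalp: `x` increases to
#' the right, `y` to the front (anterior), both on an approximately unit
#' head radius.
#'
#' @param montage Montage name: `"ch30"`, `"ch19"` or `"ch8"`, or a
#'   character vector of channel labels drawn from the 30-channel table.
#' @return `montage_coordinates()` returns a data.frame with columns
#'   `label`, `x`, `y`; `montage_channels()` returns the channel labels.
#' @examples
#' head(montage_coordinates("ch30"))
#' montage_channels("ch8")
#' @export
montage_coordinates <- function(montage = "ch30") {
  labels <- montage_channels(montage)
  idx <- match(labels, .montage_table$label)
  .montage_table[idx, , drop = FALSE]
}

#' @rdname montage_coordinates
#' @export
montage_channels <- function(montage = "ch30") {
  if (length(montage) == 1L && montage %in% names(.montage_sets)) {
    return(.montage_sets[[montage]])
  }
  unknown <- setdiff(montage, .montage_table$label)
  if (length(unknown) > 0L) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  montage
}

# 2-D projected 10-20 positions (x: left -> right, y: posterior -> anterior)
.montage_table <- data.frame(
  label = c("Fp1", "Fp2", "AF3", "AF4",
            "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6",
            "T7", "C3", "Cz", "C4", "T8",
            "CP5", "CP1", "CP2", "CP6",
            "P7", "P3", "Pz", "P4", "P8",
            "O1", "Oz", "O2"),
  x = c(-0.31, 0.31, -0.34, 0.34,
        -0.81, -0.40, 0.00, 0.40, 0.81,
        -0.67, -0.22, 0.22, 0.67,
        -1.00, -0.50, 0.00, 0.50, 1.00,
        -0.67, -0.22, 0.22, 0.67,
        -0.81, -0.40, 0.00, 0.40, 0.81,
        -0.31, 0.00, 0.31),
  y = c(0.95, 0.95, 0.82, 0.82,
        0.59, 0.52, 0.50, 0.52, 0.59,
        0.29, 0.26, 0.26, 0.29,
        0.00, 0.00, 0.00, 0.00, 0.00,
        -0.29, -0.26, -0.26, -0.29,
        -0.59, -0.52, -0.50, -0.52, -0.59,
        -0.95, -1.00, -0.95),
  stringsAsFactors = FALSE
)

.montage_sets <- list(
  ch30 = .montage_table$label,
  ch19 = c("AF3", "AF4", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "C4",
           "T8", "Cz", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
  ch8  = c("F3", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")
)

# Pairwise Euclidean distances between electrodes of a montage
.montage_distances <- function(labels) {
  coords <- montage_coordinates(labels)
  as.matrix(stats::dist(coords[, c("x", "y")]))
}
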