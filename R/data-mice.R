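#' The three-mouse PyMT time-course dataset
#'
#' Per-mouse abundances of the 15 model variables in three PyMT mice at
#' four tumor-progression stages, sampled at weeks 6, 8, 10 and 12 and
#' re-indexed so that week 6 is day 0 (days 0, 14, 28, 42).  Cell
#' populations come from immune deconvolution of bulk tumor RNA-seq
#' scaled by tumor size; cancer and necrotic counts derive from the
#' 0.955:0.04:0.005 cancer:immune:necrotic composition; cytokines are
#' on a gene-expression scale.  Values are embedded verbatim at the
#' published precision.
#'
#' @return A tibble with 12 rows and 17 columns: `mouse` (1-3), `day`,
#'   and the 15 variables in canonical order, with attribute
#'   `frame = "dimensional"`.
#' @examples
#' pymt_mice()
#' @export
pymt_mice <- function() {
  d <- tibble::tribble(
    ~mouse, ~day, ~T_N, ~T_h, ~T_c, ~T_r, ~D_N, ~D, ~M_N, ~M,
    1L,  0L, 18.91552, 0.180307, 0.001385, 0.120725, 13.04028, 0.498882, 6.767523, 7.386616,
    1L, 14L, 6.771898, 0.673464, 4.279462, 0.001385, 8.607666, 0.001385, 6.115784, 15.72747,
    1L, 28L, 16.02047, 0.001385, 0.164525, 0.269144, 6.955235, 0.001385, 6.053538, 19.64027,
    1L, 42L, 8.807364, 0.073352, 2.217549, 0.001385, 11.31217, 0.313571, 1.842909, 17.24431,
    2L,  0L, 14.18682, 0.001459, 0.001459, 0.001459, 8.67344, 0.001459, 14.50968, 9.00316,
    2L, 14L, 2.54051, 0.787626, 0.001459, 0.001459, 13.30604, 0.001459, 26.56551, 0.632713,
    2L, 28L, 7.022259, 0.444987, 2.773333, 0.001459, 14.39057, 0.001459, 21.57876, 4.581648,
    2L, 42L, 11.05377, 0.001459, 3.951772, 0.001459, 8.180317, 0.001459, 7.14771, 8.669383,
    3L,  0L, 10.84328, 0.014559, 2.398143, 0.14663, 11.10196, 0.466044, 9.302918, 8.559201,
    3L, 14L, 11.18575, 0.748596, 0.235111, 0.001456, 11.90139, 0.001456, 6.080938, 16.72823,
    3L, 28L, 17.73009, 0.001456, 0.608837, 0.001456, 12.19168, 0.001456, 6.812254, 6.448463,
    3L, 42L, 10.89853, 1.288033, 0.552229, 0.001456, 12.57453, 0.001456, 13.96522, 7.217389
  )
  d2 <- tibble::tribble(
    ~C, ~N, ~A, ~H, ~IL12, ~IL10, ~IL6,
    6.56815,  0.034388, 93.82247, 1000, 28, 417, 2490,
    32.33359, 0.169286, 84.35702,  940, 24, 351, 1766,
    57.61312, 0.301639, 98.2119,  1103,  0, 404, 1599,
    83.48514, 0.437095, 83.62523, 1050,  2, 455, 1880,
    6.590515, 0.034505, 92.75787, 1182,  0, 450, 1602,
    32.26456, 0.168924, 87.67355,  932, 16, 723, 1068,
    57.54278, 0.301271, 101.5889,  945,  0, 429, 1646,
    83.60215, 0.437708, 78.01466,  807,  0, 319, 1490,
    6.73803,  0.035278, 85.66546, 1521, 19, 511, 3327,
    32.13758, 0.16826,  93.76585, 1549,  3, 566, 3481,
    57.83445, 0.302798, 87.59139,  957,  0, 349, 1716,
    83.28994, 0.436073, 92.99769,  779,  4, 278, 1490
  )
  out <- dplyr::bind_cols(d, d2)
  attr(out, "frame") <- "dimensional"
  out
}

.data_frame_of <- function(data) {
  attr(data, "frame", exact = TRUE)
}

.check_dataset <- function(data, frame = NULL) {
  need <- c("mouse", "day", tme_state_vars)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(data[, tme_state_vars])
  if (anyNA(vals) || any(vals < 0)) {
    stop("dataset values must be nonnegative and complete", call. = FALSE)
  }
  if (!is.null(frame)) {
    have <- .data_frame_of(data)
    if (!is.null(have) && !identical(have, frame)) {
      stop("dataset is in the ", have, " frame; expected ", frame,
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Read or write a mouse time-course dataset as CSV
#'
#' The canonical exchange format: one row per (mouse, day), integer
#' days counted from week 6, and the 15 named variable columns in
#' canonical order.
#'
#' @param data dataset tibble as returned by [pymt_mice()].
#' @param path file path.
#' @param frame which frame the file stores; recorded on read as the
#'   `frame` attribute.
#' @return `read_mice_csv()` returns the dataset tibble; the writer
#'   returns `path` invisibly.
#' @export
write_mice_csv <- function(data, path) {
  .check_dataset(data)
  utils::write.csv(data[, c("mouse", "day", tme_state_vars)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mice_csv
#' @export
read_mice_csv <- function(path, frame = "dimensional") {
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  out$mouse <- as.integer(out$mouse)
  out$day <- as.integer(out$day)
  for (v in tme_state_vars) out[[v]] <- as.double(out[[v]])
  .check_dataset(out)
  attr(out, "frame") <- frame
  out
}

#' Per-variable normalization scales
#'
#' The scale of each variable is its maximum over all mice and time
#' points, so that dividing the dataset by its scales maps every
#' variable into (0, 1] with a per-variable maximum of exactly 1.
#'
#' @param data dimensional dataset tibble.
#' @return A tibble with columns `variable` and `scale` (in input
#'   units), one row per model variable in canonical order.
#' @examples
#' tme_scales(pymt_mice())
#' @export
tme_scales <- function(data) {
  .check_dataset(data, frame = "dimensional")
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  sc <- vapply(tme_state_vars, function(v) max(data[[v]]), 0)
  if (any(sc <= 0)) {
    stop("variable(s) identically zero: ",
         paste(tme_state_vars[sc <= 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(variable = tme_state_vars, scale = unname(sc))
}

.scales_vec <- function(scales) {
  if (is.data.frame(scales)) {
    stats::setNames(scales$scale, scales$variable)[tme_state_vars]
  } else {
    scales[tme_state_vars]
  }
}

#' Switch a dataset between dimensional and non-dimensional frames
#'
#' Divides (or multiplies) each variable column by its scale.  The
#' round trip is the identity to floating precision.
#'
#' @param data dataset tibble.
#' @param scales scales tibble from [tme_scales()] (or a named vector).
#' @return The rescaled dataset with its `frame` attribute flipped.
#' @export
tme_nondimensionalize <- function(data, scales) {
  .check_dataset(data, frame = "dimensional")
  sc <- .scales_vec(scales)
  out <- data
  for (v in tme_state_vars) out[[v]] <- data[[v]] / sc[[v]]
  attr(out, "frame") <- "nondimensional"
  out
}

#' @rdname tme_nondimensionalize
#' @export
tme_redimensionalize <- function(data, scales) {
  .check_dataset(data, frame = "nondimensional")
  sc <- .scales_vec(scales)
  out <- data
  for (v in tme_state_vars) out[[v]] <- data[[v]] * sc[[v]]
  attr(out, "frame") <- "dimensional"
  out
}

#' Day-0 initial conditions per mouse
#'
#' @param data_nd non-dimensional dataset tibble.
#' @return A named list (one entry per mouse) of named state vectors.
#' @export
tme_inits <- function(data_nd) {
  .check_dataset(data_nd)
  d0 <- dplyr::filter(data_nd, .data$day == min(.data$day))
  out <- lapply(seq_len(nrow(d0)), function(i) {
    stats::setNames(as.double(d0[i, tme_state_vars]), tme_state_vars)
  })
  names(out) <- paste0("mouse", d0$mouse)
  out
}
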