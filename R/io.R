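# File formats: 16-bit PNG / TIFF slices (HU-like values stored with a
# +32768 offset), binary PNG or (row, col) CSV masks, long or wide
# annotation CSVs, and CSV/JSON export of feature matrices.

HU_OFFSET <- 32768

#' Read and write CT-like slices
#'
#' Slices are stored as 16-bit grayscale images with intensities offset by
#' +32768, so the full signed HU-like range round-trips exactly.  Writing
#' uses 16-bit TIFF; reading accepts 16-bit TIFF or PNG.
#'
#' @param path File path (`.tif`/`.tiff` or `.png` when reading).
#' @return `read_slice` returns an integer matrix; `write_slice` returns
#'   `path` invisibly.
#' @export
read_slice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(v)) == 3L) v <- v[, , 1]
  m <- round(v * 65535) - HU_OFFSET
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_slice
#' @param pixels Integer matrix of HU-like values in `[-32768, 32767]`.
#' @export
write_slice <- function(pixels, path) {
  v <- (pixels + HU_OFFSET) / 65535
  if (any(v < 0 | v > 1)) abort("pixel values outside the 16-bit range.")
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a binary mask
#'
#' Accepts an 8-bit PNG (any nonzero pixel is foreground) or a CSV pixel
#' list with columns `row`, `col` (1-based), in which case `dim` gives the
#' grid size.
#'
#' @param path File path.
#' @param dim Grid size `c(rows, cols)`, required for CSV masks.
#' @return Logical matrix.
#' @export
read_mask <- function(path, dim = NULL) {
  if (tolower(tools::file_ext(path)) == "csv") {
    if (is.null(dim)) abort("`dim` is required for CSV pixel-list masks.")
    d <- utils::read.csv(path)
    m <- matrix(FALSE, dim[1], dim[2])
    m[cbind(d$row, d$col)] <- TRUE
    m
  } else {
    v <- png::readPNG(path)
    if (length(base::dim(v)) == 3L) v <- v[, , 1]
    v > 0
  }
}

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read an annotation table
#'
#' Long CSVs have columns `sample_id`, `term` (one row per present term);
#' wide CSVs have `sample_id` plus one 0/1 or logical column per term.
#' Both are returned in wide form.
#'
#' @param path CSV file path.
#' @return Wide tibble: `sample_id` plus one logical column per term.
#' @export
read_annotations <- function(path) {
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (identical(sort(names(d)), c("sample_id", "term"))) {
    d |>
      mutate(present = TRUE) |>
      tidyr::pivot_wider(names_from = "term", values_from = "present",
                         values_fill = FALSE)
  } else {
    d |>
      mutate(across(-"sample_id",
                    function(x) if (is.numeric(x)) x > 0 else as.logical(x)))
  }
}

#' Write a feature matrix with its normalisation sidecar
#'
#' The matrix is written as CSV with fully expanded column names; if the
#' tibble carries `norm_stats` (see [zscore_normalize()]) they are written
#' to a JSON sidecar `<path>.norm.json`.
#'
#' @param features Feature tibble.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  stats <- attr(features, "norm_stats")
  if (!is.null(stats)) {
    jsonlite::write_json(stats, paste0(path, ".norm.json"),
                         digits = NA, dataframe = "columns")
  }
  invisible(path)
}
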