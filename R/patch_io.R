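#' Image patches and patch triplets
#'
#' An `image_patch` is a small rectangular crop of a clinical photograph:
#' an H x W x 3 array of sRGB values in `[0, 1]` together with the source
#' photograph id and the ROI it was cut from. A `patch_triplet` bundles the
#' target patch `S` with two perilesional patches `S1` and `S2` from the
#' same photograph; all similarity metrics operate on triplets.
#'
#' Coordinates are 0-based with a top-left origin: `x` indexes columns, `y`
#' rows, and an ROI `(x, y, w, h)` covers the half-open ranges
#' `[x, x + w) x [y, y + h)`. Patches must be at least 8 x 8 pixels: below
#' that the mean color is unstable and convolutional features degenerate.
#'
#' @param pixels numeric H x W x 3 array with values in `[0, 1]`.
#' @param source_id photograph identifier (scalar).
#' @param roi integer vector `c(x, y, w, h)` locating the patch in its
#'   source image, or `NULL` when the patch was built in memory.
#' @return `image_patch()` returns an object of class `"image_patch"`;
#'   `patch_triplet()` an object of class `"patch_triplet"` with elements
#'   `target`, `peri1`, `peri2`.
#' @export
image_patch <- function(pixels, source_id = NA_character_, roi = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort_percsim("`pixels` must be an H x W x 3 array.", "percsim_format_error")
  }
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L) {
    abort_percsim(
      sprintf("patch is %dx%d; patches must be at least 8x8 pixels.", d[1], d[2]),
      "percsim_roi_error"
    )
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    abort_percsim("pixel values must lie in [0, 1] with no missing values.",
                  "percsim_format_error")
  }
  structure(
    list(pixels = pixels, source_id = source_id, roi = roi),
    class = "image_patch"
  )
}

#' @rdname image_patch
#' @param target,peri1,peri2 `image_patch` objects sharing one `source_id`:
#'   the target (lesional) patch `S` and the two perilesional patches
#'   `S1`, `S2`.
#' @export
patch_triplet <- function(target, peri1, peri2) {
  for (p in list(target, peri1, peri2)) {
    if (!inherits(p, "image_patch")) {
      abort_percsim("all three patches must be `image_patch` objects.",
                    "percsim_usage_error")
    }
  }
  ids <- c(target$source_id, peri1$source_id, peri2$source_id)
  if (length(unique(ids[!is.na(ids)])) > 1L) {
    abort_percsim("target and perilesional patches must share one source_id.",
                  "percsim_usage_error")
  }
  structure(
    list(target = target, peri1 = peri1, peri2 = peri2,
         source_id = target$source_id),
    class = "patch_triplet"
  )
}

#' @export
print.image_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_patch> %dx%d px, source '%s'\n", d[1], d[2], x$source_id))
  invisible(x)
}

#' @export
print.patch_triplet <- function(x, ...) {
  cat(sprintf("<patch_triplet> source '%s' (S, S1, S2)\n", x$source_id))
  invisible(x)
}

#' Load a photograph as an sRGB array
#'
#' Reads an 8-bit PNG or JPEG photograph into an H x W x 3 array with
#' channel values in `[0, 1]` (8-bit values divided by 255). Pixels are
#' consumed as stored sRGB; no ICC-profile transformation is applied.
#' Grayscale and palette images are rejected: the color metrics need three
#' channels as captured.
#'
#' @param path path to a PNG or JPEG file.
#' @return numeric H x W x 3 array in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    abort_percsim(sprintf("image file not found: '%s'", path), "percsim_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    ebi <- EBImage::readImage(path)
    # EBImage stores (x = column, y = row[, channel]); transpose to rows first
    if (length(dim(ebi)) == 3L) aperm(as.array(ebi), c(2L, 1L, 3L)) else as.array(t(ebi))
  } else {
    abort_percsim(sprintf("unsupported image format '%s' for '%s'", ext, path),
                  "percsim_io_error")
  }
  if (length(dim(img)) == 2L || dim(img)[3] == 1L) {
    abort_percsim(
      sprintf("'%s' is grayscale/palette; 3-channel RGB input is required.", path),
      "percsim_format_error"
    )
  }
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  if (dim(img)[3] != 3L) {
    abort_percsim(sprintf("'%s' has %d channels; expected 3.", path, dim(img)[3]),
                  "percsim_format_error")
  }
  img
}

#' Extract a rectangular patch from an image
#'
#' Crops the region `[x, x + w) x [y, y + h)` (0-based, top-left origin,
#' x along columns) out of an H x W x 3 array.
#'
#' @param image numeric H x W x 3 array in `[0, 1]`.
#' @param roi integer vector or list `c(x, y, w, h)`.
#' @param source_id photograph identifier attached to the patch.
#' @return an [image_patch()].
#' @export
extract_patch <- function(image, roi, source_id = NA_character_) {
  roi <- as.integer(unlist(roi)[1:4])
  names(roi) <- c("x", "y", "w", "h")
  d <- dim(image)
  if (roi["w"] < 8L || roi["h"] < 8L) {
    abort_percsim("ROI width and height must be at least 8 pixels.",
                  "percsim_roi_error")
  }
  if (roi["x"] < 0L || roi["y"] < 0L ||
      roi["x"] + roi["w"] > d[2] || roi["y"] + roi["h"] > d[1]) {
    abort_percsim(
      sprintf("ROI (x=%d, y=%d, w=%d, h=%d) exceeds the %dx%d image bounds.",
              roi["x"], roi["y"], roi["w"], roi["h"], d[1], d[2]),
      "percsim_roi_error"
    )
  }
  rows <- (roi["y"] + 1L):(roi["y"] + roi["h"])
  cols <- (roi["x"] + 1L):(roi["x"] + roi["w"])
  image_patch(image[rows, cols, , drop = FALSE], source_id = source_id, roi = roi)
}

#' Read an ROI specification table
#'
#' Reads a CSV mapping each photograph to its three patch ROIs. The file
#' must have columns `photo_id, role, x, y, w, h` with `role` one of
#' `S` (target), `S1`, `S2` (perilesional); every `photo_id` must carry
#' exactly those three roles. Coordinates are 0-based, half-open, `x`
#' along columns.
#'
#' @param path path to the ROI CSV.
#' @return a tibble with one row per (photo, role), validated.
#' @export
read_roi_spec <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("photo_id", "role", "x", "y", "w", "h")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_percsim(paste0("ROI spec is missing columns: ",
                         paste(missing_cols, collapse = ", ")),
                  "percsim_spec_error")
  }
  bad_role <- setdiff(unique(df$role), c("S", "S1", "S2"))
  if (length(bad_role)) {
    abort_percsim(paste0("unknown ROI roles: ", paste(bad_role, collapse = ", ")),
                  "percsim_spec_error")
  }
  offenders <- df |>
    dplyr::count(.data$photo_id, .data$role) |>
    dplyr::group_by(.data$photo_id) |>
    dplyr::summarise(
      ok = dplyr::n() == 3L && all(.data$n == 1L),
      .groups = "drop"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(offenders)) {
    abort_percsim(
      paste0("each photo needs exactly one S, S1 and S2 ROI; offenders: ",
             paste(offenders$photo_id, collapse = ", ")),
      "percsim_spec_error"
    )
  }
  tibble::as_tibble(df)
}

#' Load the patch triplet of one photograph
#'
#' @param image H x W x 3 array (see [load_image()]).
#' @param roi_spec tibble from [read_roi_spec()], filtered or not.
#' @param photo_id which photograph's ROIs to use.
#' @return a [patch_triplet()].
#' @export
triplet_from_spec <- function(image, roi_spec, photo_id) {
  rows <- roi_spec[roi_spec$photo_id == photo_id, ]
  if (nrow(rows) != 3L) {
    abort_percsim(sprintf("photo '%s' does not have exactly 3 ROIs.", photo_id),
                  "percsim_spec_error")
  }
  get <- function(role) {
    r <- rows[rows$role == role, ]
    extract_patch(image, c(r$x, r$y, r$w, r$h), source_id = photo_id)
  }
  patch_triplet(get("S"), get("S1"), get("S2"))
}

#' Ordinal rating tables
#'
#' Validates an items x raters table of ordinal visibility scores (1-4).
#' Accepts either a wide matrix/data.frame (one column per rater) or a long
#' data frame with columns `item_id`, `rater_id`, `score`. Missing ratings
#' are not supported; panels must be complete.
#'
#' @param x wide matrix or long data frame of scores.
#' @param attribute which attribute was rated, `"color"` or `"texture"`.
#' @param levels number of scale levels (default 4).
#' @return an integer matrix of class `"rating_table"` (items x raters)
#'   with `item_ids` in rownames, `rater_ids` in colnames, and the
#'   attribute in an attribute.
#' @export
rating_table <- function(x, attribute = c("color", "texture"), levels = 4L) {
  attribute <- match.arg(attribute)
  if (is.data.frame(x) && all(c("item_id", "rater_id", "score") %in% names(x))) {
    wide <- tidyr::pivot_wider(
      dplyr::select(x, "item_id", "rater_id", "score"),
      names_from = "rater_id", values_from = "score"
    )
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- as.character(wide$item_id)
  } else {
    m <- as.matrix(x)
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("R", seq_len(ncol(m)))
  }
  if (anyNA(m)) {
    abort_percsim("rating table has missing entries; complete panels required.",
                  "percsim_format_error")
  }
  storage.mode(m) <- "integer"
  if (!all(m %in% seq_len(levels))) {
    abort_percsim(sprintf("all ratings must be integers in 1..%d.", levels),
                  "percsim_format_error")
  }
  if (ncol(m) < 2L) {
    abort_percsim("a rating table needs at least 2 raters.", "percsim_format_error")
  }
  structure(m, class = c("rating_table", "matrix"),
            attribute = attribute, levels = levels)
}

#' Gold-standard scores from a rater panel
#'
#' Averages each item's ratings over raters and rounds to the nearest scale
#' level. The rounded mean is the "gold standard" used to train and
#' validate the automated scores. Rounding defaults to half-away-from-zero
#' (2.5 -> 3) so that boundary items are assigned deterministically and
#' independently of banker's rounding.
#'
#' @param table a [rating_table()] or anything it accepts.
#' @param rounding `"half_away"` (default) or `"half_even"` (base [round()]).
#' @return a tibble with columns `item_id`, `mean_score`, `rounded_score`.
#' @export
gold_scores <- function(table, rounding = c("half_away", "half_even")) {
  rounding <- match.arg(rounding)
  if (!inherits(table, "rating_table")) table <- rating_table(table)
  mean_score <- rowMeans(table)
  rounded <- if (rounding == "half_away") round_half_away(mean_score) else round(mean_score)
  tibble::tibble(
    item_id = rownames(table),
    mean_score = as.numeric(mean_score),
    rounded_score = as.integer(rounded)
  )
}

#' Write gold scores to CSV
#'
#' @param gold tibble from [gold_scores()].
#' @param attribute attribute label written alongside.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gold_scores <- function(gold, attribute, path) {
  out <- data.frame(item_id = gold$item_id, attribute = attribute,
                    mean = gold$mean_score, rounded = gold$rounded_score)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
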