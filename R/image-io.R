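#' Read an image-folder dataset
#'
#' Expects the standard one-directory-per-class layout. Class order is the
#' lexicographic order of the subdirectory names. PNG (and JPEG, when the
#' jpeg package is installed) images are decoded, converted to grayscale by
#' channel averaging, rescaled to \[0, 1\] and resized to `image_size` by
#' nearest-neighbour resampling.
#'
#' @param path Directory containing one subdirectory per class.
#' @param image_size Target `c(H, W)`; default: size of the first image read.
#' @return A [labeled_dataset()]; `source_ids` hold the file paths.
#' @export
read_image_folder <- function(path, image_size = NULL) {
  assert_that(dir.exists(path), sprintf("directory not found: %s", path))
  dirs <- sort(list.dirs(path, recursive = FALSE, full.names = TRUE))
  assert_that(length(dirs) > 0,
              sprintf("no class subdirectories under %s", path))
  images <- list(); labels <- integer(0); ids <- character(0)
  class_names <- character(0)
  cls <- 0L
  for (d in dirs) {
    files <- sort(list.files(d, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) {
      warn(sprintf("empty class directory skipped: %s", d))
      next
    }
    cls <- cls + 1L
    class_names <- c(class_names, basename(d))
    for (f in files) {
      img <- decode_image(f)
      if (is.null(image_size)) image_size <- dim(img)
      images[[length(images) + 1]] <- resize_nn(img, image_size)
      labels <- c(labels, cls)
      ids <- c(ids, f)
    }
  }
  assert_that(length(images) > 0, "no decodable images found")
  labeled_dataset(images, labels, class_names, ids)
}

decode_image <- function(f) {
  img <- tryCatch({
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        abort(sprintf("jpeg package required to read %s", f))
      }
      jpeg::readJPEG(f)
    }
  }, error = function(e) abort(sprintf("unreadable image file: %s (%s)",
                                       f, conditionMessage(e))))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  pmin(pmax(img, 0), 1)
}

resize_nn <- function(img, size) {
  if (identical(dim(img), as.integer(size))) return(img)
  ri <- pmin(pmax(round(seq_len(size[1]) * nrow(img) / size[1]), 1), nrow(img))
  rj <- pmin(pmax(round(seq_len(size[2]) * ncol(img) / size[2]), 1), ncol(img))
  img[ri, rj, drop = FALSE]
}

#' Write a dataset as an image folder
#'
#' Writes one PNG per sample under `path/<class_name>/`, plus a
#' `manifest.csv` (columns `path`, `label`, `class`). A write-then-read
#' round trip preserves labels and counts.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_image_folder <- function(dataset, path) {
  assert_that(inherits(dataset, "labeled_dataset"), "dataset must be a labeled_dataset")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(dataset$labels))
  for (k in seq_along(dataset$labels)) {
    cls_name <- dataset$class_names[dataset$labels[k]]
    d <- file.path(path, cls_name)
    dir.create(d, showWarnings = FALSE)
    f <- file.path(d, sprintf("sample_%05d.png", k))
    png::writePNG(dataset$images[[k]], f)
    rows[[k]] <- tibble(path = f, label = dataset$labels[k], class = cls_name)
  }
  readr::write_csv(dplyr::bind_rows(rows), file.path(path, "manifest.csv"))
  invisible(path)
}
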