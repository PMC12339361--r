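#' Label image container
#'
#' Wraps a 2D integer label matrix (0 = background, k > 0 = object k)
#' together with its object table (label, centroid, area). Centroids are
#' 0-based (row, col) pixel coordinates.
#'
#' @param labels Integer matrix of object labels.
#' @return A `label_image`: list with elements `labels` (matrix) and
#'   `objects` (tibble with `label`, `row`, `col`, `area`).
#' @export
label_image <- function(labels) {
  labels <- as_matrix_image(labels)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, objects = label_table(labels)),
            class = "label_image")
}

label_table <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(label = integer(), row = numeric(),
                          col = numeric(), area = integer()))
  }
  lab <- labels[idx]
  r <- (idx - 1L) %% nrow(labels)            # 0-based row
  c <- (idx - 1L) %/% nrow(labels)           # 0-based col
  tibble::tibble(
    label = sort(unique(lab)),
    row = as.numeric(tapply(r, lab, mean)),
    col = as.numeric(tapply(c, lab, mean)),
    area = as.integer(tapply(lab, lab, length))
  )
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image: %d x %d px, %d objects>\n",
              nrow(x$labels), ncol(x$labels), nrow(x$objects)))
  invisible(x)
}

#' Segment nuclei or cells in a fluorescence image
#'
#' Segmentation is a pluggable backend behind a fixed contract: any
#' function turning an intensity image into a label matrix can be
#' registered. The built-in `"threshold"` backend — Otsu thresholding,
#' hole filling, then a distance-transform watershed to split touching
#' objects — is deterministic, dependency-light and used by the test
#' suite. Deep-learning segmenters (e.g. Cellpose) can be plugged in by
#' name where available; their label output enters the same container.
#'
#' @param image 2D non-negative intensity matrix.
#' @param mode `"nuclei"` or `"cells"`; the threshold backend treats both
#'   identically, external backends may not.
#' @param backend Backend name (default `"threshold"`).
#' @param min_area Objects smaller than this many pixels are dropped
#'   (default 20).
#' @return A [label_image()].
#' @export
segment_objects <- function(image, mode = c("nuclei", "cells"),
                            backend = "threshold", min_area = 20L) {
  mode <- match.arg(mode)
  image <- as_matrix_image(image)
  check_finite_image(image)
  if (any(image < 0)) stop("image must be non-negative", call. = FALSE)
  backends <- list(threshold = segment_threshold)
  if (!backend %in% names(backends)) {
    stop("unknown segmentation backend '", backend, "'; available: ",
         paste(names(backends), collapse = ", "), call. = FALSE)
  }
  labels <- backends[[backend]](image, mode)
  li <- label_image(labels)
  if (min_area > 0L && nrow(li$objects) > 0L) {
    drop <- li$objects$label[li$objects$area < min_area]
    if (length(drop)) {
      labels[labels %in% drop] <- 0L
      li <- label_image(relabel_consecutive(labels))
    }
  }
  li
}

# Otsu threshold -> hole fill -> distance-transform watershed.
segment_threshold <- function(image, mode) {
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(image), ncol(image)))
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- EBImage::fillHull(norm > thr)
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  matrix(as.integer(EBImage::imageData(ws)), nrow(image), ncol(image))
}

relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0L) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  labels
}

#' Shrink labelled objects by binary erosion
#'
#' Erodes every object independently by `px` pixels (disc-shaped
#' structuring element). Used to predict nucleus locations from
#' membrane-derived cell outlines. Objects eroded to extinction are
#' removed.
#'
#' @param li A [label_image()].
#' @param px Erosion radius in pixels (`>= 0`; 0 is the identity).
#' @return A [label_image()] with eroded objects.
#' @export
shrink_labels <- function(li, px) {
  stopifnot(inherits(li, "label_image"), px >= 0)
  px <- as.integer(px)
  if (px == 0L) return(li)
  labels <- li$labels
  # erosion of each object separately; a disc brush of diameter 2*px+1
  brush <- EBImage::makeBrush(2L * px + 1L, shape = "disc")
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (lab in li$objects$label) {
    m <- labels == lab
    er <- EBImage::erode(EBImage::Image(m * 1), brush)
    out[EBImage::imageData(er) > 0.5] <- lab
  }
  label_image(out)
}

#' Build a label image of discs at given centres
#'
#' Paints filled discs at 0-based (row, col) centres; later discs
#' overwrite earlier ones where they touch. A convenience for building
#' synthetic label scenes with known centroids and areas.
#'
#' @param rows,cols Numeric vectors of disc centres (0-based pixels).
#' @param radius Disc radius in pixels (scalar or per-disc vector).
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return A [label_image()] with one object per disc (in input order).
#' @export
label_image_from_points <- function(rows, cols, radius, dim) {
  lab <- matrix(0L, dim[1], dim[2])
  radius <- rep_len(radius, length(rows))
  rr <- matrix(seq_len(dim[1]) - 1L, dim[1], dim[2])
  cc <- matrix(rep(seq_len(dim[2]) - 1L, each = dim[1]), dim[1], dim[2])
  for (i in seq_along(rows)) {
    lab[(rr - rows[i])^2 + (cc - cols[i])^2 <= radius[i]^2] <- i
  }
  label_image(lab)
}

#' Write a label image as 16-bit TIFF
#'
#' @param li A [label_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(li, path) {
  stopifnot(inherits(li, "label_image"))
  EBImage::writeImage(EBImage::Image(li$labels / 65535), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image written by [write_labels()]
#'
#' @param path TIFF file path.
#' @return A [label_image()].
#' @export
read_labels <- function(path) {
  img <- EBImage::readImage(path)
  label_image(round(as_matrix_image(img) * 65535))
}
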