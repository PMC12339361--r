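#' Collapse a z-stack by averaging
#'
#' @param zstack List of 2D matrices (one per plane), all the same shape,
#'   or a single matrix (returned unchanged).
#' @return Pixelwise mean across planes.
#' @export
collapse_z <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  stopifnot(is.list(zstack), length(zstack) >= 1L)
  dims <- dim(zstack[[1]])
  for (p in zstack) {
    if (!identical(dim(p), dims)) {
      stop("z-stack planes differ in shape", call. = FALSE)
    }
  }
  Reduce(`+`, zstack) / length(zstack)
}

#' Local background subtraction
#'
#' Removes slowly varying background (uneven illumination, out-of-focus
#' haze) before intensity ratios are formed. The image is downsampled
#' `bg_downsample`-fold by block averaging; from each full-resolution
#' pixel the minimum over the `bg_window` x `bg_window` downsampled
#' pixels closest to it is subtracted, and negative results are set to
#' zero.
#'
#' @param image Non-negative 2D matrix.
#' @param params [pipeline_params()] (`bg_downsample`, `bg_window`).
#' @return Background-subtracted matrix, same shape, non-negative.
#' @export
local_background_subtract <- function(image, params = pipeline_params()) {
  image <- as_matrix_image(image)
  if (any(image < 0)) stop("image must be non-negative", call. = FALSE)
  ds <- block_downsample(image, params$bg_downsample)
  bg <- min_filter(ds, params$bg_window)
  # expand each downsampled block's background back to full resolution
  ri <- (seq_len(nrow(image)) - 1L) %/% params$bg_downsample + 1L
  ci <- (seq_len(ncol(image)) - 1L) %/% params$bg_downsample + 1L
  pmax(image - bg[ri, ci, drop = FALSE], 0)
}

#' Nuclear translocation score per cell
#'
#' Quantifies nuclear enrichment of a reporter (e.g. a transcription
#' factor fusion) as the Pearson correlation, over each cell's pixels,
#' between the nuclear stain and the reporter channel. Cytosolic
#' localisation anti-correlates with the nuclear stain; translocation
#' drives the correlation positive. Raw channels are used: Pearson is
#' already invariant to affine intensity changes.
#'
#' @param cells A [label_image()] of cell outlines.
#' @param nuclear,reporter 2D matrices in the same frame as `cells`.
#' @param min_pixels Cells with fewer pixels give `NA` (default 10).
#' @return Tibble: `label`, `area`, `translocation_r`, `mean_reporter`.
#'   `translocation_r` is `NA` when either channel has zero variance
#'   within the cell.
#' @export
translocation_score <- function(cells, nuclear, reporter, min_pixels = 10L) {
  stopifnot(inherits(cells, "label_image"))
  nuclear <- as_matrix_image(nuclear); reporter <- as_matrix_image(reporter)
  lmat <- cells$labels
  stopifnot(identical(dim(lmat), dim(nuclear)),
            identical(dim(lmat), dim(reporter)))
  idx <- which(lmat > 0L)
  lab <- lmat[idx]
  nv <- split(nuclear[idx], lab)
  rv <- split(reporter[idx], lab)
  tibble::tibble(
    label = as.integer(names(nv)),
    area = lengths(nv),
    translocation_r = unname(mapply(function(a, b) {
      if (length(a) < min_pixels || stats::sd(a) == 0 || stats::sd(b) == 0) {
        return(NA_real_)
      }
      stats::cor(a, b)
    }, nv, rv)),
    mean_reporter = unname(vapply(rv, mean, numeric(1)))
  )
}

#' Speck score per cell
#'
#' Detects punctate reporter aggregates (e.g. inflammasome specks) as
#' the ratio of high-frequency reporter signal to total reporter signal
#' per cell. The reporter is background-subtracted
#' ([local_background_subtract()]), high-pass filtered with a tight
#' Gaussian (`speck_sigma`), and negative pixels are removed; the score
#' is the mean filtered intensity over the cell's pixels divided by the
#' mean unfiltered (background-subtracted) intensity. A diffuse reporter
#' scores near zero; a bright micron-scale punctum dominates the
#' high-pass band and drives the ratio up.
#'
#' Cells whose mean reporter intensity falls below the
#' `expression_percentile` of the run, or whose denominator is zero, are
#' flagged `excluded_low_expression`.
#'
#' @param cells A [label_image()].
#' @param reporter Non-negative 2D matrix in the same frame.
#' @param params [pipeline_params()].
#' @return Tibble: `label`, `area`, `mean_reporter`, `speck_ratio`,
#'   `excluded_low_expression`.
#' @export
speck_score <- function(cells, reporter, params = pipeline_params()) {
  stopifnot(inherits(cells, "label_image"))
  reporter <- as_matrix_image(reporter)
  lmat <- cells$labels
  stopifnot(identical(dim(lmat), dim(reporter)))
  bg <- local_background_subtract(reporter, params)
  hp <- frequency_filter(bg, params$speck_sigma, "highpass")
  idx <- which(lmat > 0L)
  lab <- lmat[idx]
  denom <- vapply(split(bg[idx], lab), mean, numeric(1))
  numer <- vapply(split(hp[idx], lab), mean, numeric(1))
  out <- tibble::tibble(
    label = as.integer(names(denom)),
    area = unname(as.integer(table(lab))),
    mean_reporter = unname(denom),
    speck_ratio = unname(ifelse(denom > 0, numer / denom, NA_real_))
  )
  gate <- stats::quantile(out$mean_reporter,
                          params$expression_percentile / 100,
                          names = FALSE, type = 7)
  out$excluded_low_expression <- out$mean_reporter < gate |
    !(out$mean_reporter > 0)
  out
}
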