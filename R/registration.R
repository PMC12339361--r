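#' Multi-cycle sequencing image stack
#'
#' Container for the images of one field of view across sequencing
#' cycles: per cycle one nuclear-stain image plus three sequencing-channel
#' images, all the same shape.
#'
#' @param cycles List with one element per cycle; each element is a list
#'   with `nuclear` (matrix) and `channels` (list of three matrices).
#' @param pixel_size_um Pixel size in micrometres.
#' @return A `cycle_stack`.
#' @export
cycle_stack <- function(cycles, pixel_size_um = 0.325) {
  stopifnot(length(cycles) >= 1L)
  dims <- dim(cycles[[1]]$nuclear)
  for (cy in cycles) {
    stopifnot(length(cy$channels) == 3L)
    for (img in c(list(cy$nuclear), cy$channels)) {
      if (!identical(dim(img), dims)) {
        stop("all images in a cycle_stack must share one shape", call. = FALSE)
      }
    }
  }
  structure(list(cycles = cycles,
                 shifts = tibble::tibble(cycle = seq_along(cycles),
                                         dy = 0L, dx = 0L, peak_corr = NA_real_),
                 pixel_size_um = pixel_size_um,
                 aligned = FALSE),
            class = "cycle_stack")
}

#' @export
print.cycle_stack <- function(x, ...) {
  d <- dim(x$cycles[[1]]$nuclear)
  cat(sprintf("<cycle_stack: %d cycles, %d x %d px, %s>\n",
              length(x$cycles), d[1], d[2],
              if (x$aligned) "aligned" else "unaligned"))
  invisible(x)
}

n_cycles <- function(stack) length(stack$cycles)

#' Estimate the integer translation between two images
#'
#' Finds the shift `(dy, dx)` maximising the cross-correlation of the two
#' mean-subtracted images, computed in the frequency domain. The
#' convention is that `mov` equals `ref` displaced by `(dy, dx)` (content
#' moved down by `dy` rows and right by `dx` columns); aligning therefore
#' translates `mov` back by `(-dy, -dx)`.
#'
#' The peak is located on the full circular correlation surface and then
#' validated against `max_shift`: a drift beyond the bound is an error,
#' not a silently clipped estimate.
#'
#' @param ref,mov 2D image matrices of identical shape; neither constant.
#' @param max_shift Maximum allowed |dy|, |dx| in pixels.
#' @return A one-row tibble with `dy`, `dx` (integers) and `peak_corr`,
#'   the normalised correlation at the peak.
#' @examples
#' ref <- matrix(rnorm(64 * 64), 64)
#' s <- register_translation(ref, nisseq:::roll_image(ref, 5, -3), 20)
#' c(s$dy, s$dx)
#' @export
register_translation <- function(ref, mov, max_shift = 50L) {
  ref <- as_matrix_image(ref); mov <- as_matrix_image(mov)
  stopifnot(identical(dim(ref), dim(mov)))
  r0 <- ref - mean(ref); m0 <- mov - mean(mov)
  if (all(r0 == 0) || all(m0 == 0)) {
    stop("no structure to register: constant image", call. = FALSE)
  }
  cc <- Re(stats::fft(Conj(stats::fft(r0)) * stats::fft(m0), inverse = TRUE))
  cc <- cc / (length(cc) * sqrt(sum(r0^2) * sum(m0^2)))
  peak <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) { s <- i - 1L; if (s > n %/% 2L) s - n else s }
  dy <- wrap(peak[1], nrow(cc)); dx <- wrap(peak[2], ncol(cc))
  if (abs(dy) > max_shift || abs(dx) > max_shift) {
    stop(sprintf("registered shift (%d, %d) exceeds max_shift = %d",
                 dy, dx, as.integer(max_shift)), call. = FALSE)
  }
  tibble::tibble(dy = as.integer(dy), dx = as.integer(dx),
                 peak_corr = cc[peak])
}

#' Align all cycles of a stack to the first cycle
#'
#' Registers every cycle's nuclear-stain image against cycle 1 and applies
#' the recovered translation to that cycle's nuclear and sequencing
#' channels. Pixels shifted in from outside the frame are zero-filled.
#'
#' @param stack A [cycle_stack()].
#' @param max_shift Maximum allowed per-cycle shift in pixels.
#' @return The aligned `cycle_stack`; `$shifts` records the recovered
#'   `(dy, dx)` per cycle (cycle 1 is the zero reference).
#' @export
align_cycles <- function(stack, max_shift = 50L) {
  stopifnot(inherits(stack, "cycle_stack"))
  ref <- stack$cycles[[1]]$nuclear
  shifts <- list(tibble::tibble(dy = 0L, dx = 0L, peak_corr = 1))
  if (n_cycles(stack) > 1L) {
    for (ci in 2:n_cycles(stack)) {
      s <- tryCatch(
        register_translation(ref, stack$cycles[[ci]]$nuclear, max_shift),
        error = function(e) {
          stop("cycle ", ci, ": ", conditionMessage(e), call. = FALSE)
        }
      )
      shifts[[ci]] <- s
      if (s$dy != 0L || s$dx != 0L) {
        stack$cycles[[ci]]$nuclear <-
          shift_image(stack$cycles[[ci]]$nuclear, -s$dy, -s$dx)
        stack$cycles[[ci]]$channels <-
          lapply(stack$cycles[[ci]]$channels, shift_image, -s$dy, -s$dx)
      }
    }
  }
  sh <- dplyr::bind_rows(shifts)
  stack$shifts <- dplyr::mutate(sh, cycle = dplyr::row_number(),
                                .before = 1)
  stack$aligned <- TRUE
  stack
}
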