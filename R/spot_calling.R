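#' Gaussian frequency filtering
#'
#' High-pass filtering (unsharp mask: image minus its Gaussian blur, with
#' negative values set to zero) isolates the sharp rolling-circle spots
#' from diffuse nuclear background. Low-pass filtering (the blur itself)
#' is used to make base calling tolerant of small residual misalignments,
#' e.g. in deformable tissue.
#'
#' @param image 2D intensity matrix.
#' @param sigma Gaussian sigma in pixels (> 0).
#' @param mode `"highpass"` or `"lowpass"`.
#' @return Filtered matrix of the same shape.
#' @export
frequency_filter <- function(image, sigma, mode = c("highpass", "lowpass")) {
  mode <- match.arg(mode)
  image <- as_matrix_image(image)
  stopifnot(sigma > 0)
  blur <- as_matrix_image(EBImage::gblur(EBImage::Image(image), sigma = sigma))
  if (mode == "lowpass") return(blur)
  pmax(image - blur, 0)
}

#' Detect candidate rolling-circle amplification spots
#'
#' Sums the three sequencing channels over the first
#' `params$n_detection_cycles` cycles, high-pass filters the sum, and
#' keeps strict 8-connected local maxima whose filtered intensity exceeds
#' `max(detect_floor, median + detect_k * MAD)` of the filtered image.
#'
#' @param stack An aligned [cycle_stack()].
#' @param params [pipeline_params()].
#' @return Tibble of candidate spots (`spot_id`, `row`, `col`,
#'   `detect_intensity`), 0-based pixel coordinates, sorted by intensity
#'   descending. May have zero rows.
#' @export
detect_spots <- function(stack, params = pipeline_params()) {
  stopifnot(inherits(stack, "cycle_stack"))
  nc <- min(params$n_detection_cycles, n_cycles(stack))
  if (n_cycles(stack) < params$n_detection_cycles) {
    warning("stack has fewer cycles than n_detection_cycles; using all",
            call. = FALSE)
  }
  acc <- 0
  for (ci in seq_len(nc)) {
    acc <- acc + Reduce(`+`, stack$cycles[[ci]]$channels)
  }
  # signed high-pass: thresholding needs the symmetric noise floor, so
  # negatives are kept here (profile extraction zeroes them)
  filt <- acc - frequency_filter(acc, params$highpass_sigma, "lowpass")
  thr <- max(params$detect_floor,
             stats::median(filt) + params$detect_k * stats::mad(filt))
  if (thr <= 0) thr <- .Machine$double.eps
  hits <- which(local_maxima(filt) & filt >= thr)
  if (length(hits) == 0L) {
    return(tibble::tibble(spot_id = integer(), row = integer(),
                          col = integer(), detect_intensity = numeric()))
  }
  out <- tibble::tibble(
    row = as.integer((hits - 1L) %% nrow(filt)),
    col = as.integer((hits - 1L) %/% nrow(filt)),
    detect_intensity = filt[hits]
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$detect_intensity))
  dplyr::mutate(out, spot_id = dplyr::row_number(), .before = 1)
}

#' Extract per-cycle channel intensity profiles for spots
#'
#' For every cycle and sequencing channel the image is high-pass
#' filtered, negative values are removed, and intensities are summed over
#' the `spot_window` x `spot_window` pixel window centred on each spot.
#' Windows clipped by the image border are summed over their intersection
#' with the frame and flagged.
#'
#' @param stack An aligned [cycle_stack()].
#' @param spots Tibble from [detect_spots()] (needs `spot_id`, `row`,
#'   `col`).
#' @param params [pipeline_params()].
#' @return `spots` with list-column `raw` (one C x 3 matrix per spot,
#'   cycles in rows) and logical `edge_flag`.
#' @export
extract_profiles <- function(stack, spots, params = pipeline_params()) {
  stopifnot(inherits(stack, "cycle_stack"))
  C <- n_cycles(stack)
  nr <- nrow(stack$cycles[[1]]$nuclear)
  ncimg <- ncol(stack$cycles[[1]]$nuclear)
  if (nrow(spots) == 0L) {
    spots$raw <- list(); spots$edge_flag <- logical()
    return(spots)
  }
  stopifnot(all(spots$row >= 0), all(spots$row < nr),
            all(spots$col >= 0), all(spots$col < ncimg))
  half <- (params$spot_window - 1L) %/% 2L
  # filter every channel image once, then window-sum per spot
  filt <- vector("list", C)
  for (ci in seq_len(C)) {
    filt[[ci]] <- lapply(stack$cycles[[ci]]$channels, frequency_filter,
                         sigma = params$highpass_sigma, mode = "highpass")
  }
  raw <- vector("list", nrow(spots))
  edge <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    r1 <- spots$row[i] + 1L - half; r2 <- spots$row[i] + 1L + half
    c1 <- spots$col[i] + 1L - half; c2 <- spots$col[i] + 1L + half
    edge[i] <- r1 < 1L || c1 < 1L || r2 > nr || c2 > ncimg
    rr <- max(r1, 1L):min(r2, nr)
    cc <- max(c1, 1L):min(c2, ncimg)
    m <- matrix(0, C, 3)
    for (ci in seq_len(C)) {
      for (ch in 1:3) m[ci, ch] <- sum(filt[[ci]][[ch]][rr, cc])
    }
    raw[[i]] <- m
  }
  spots$raw <- raw
  spots$edge_flag <- edge
  spots
}

#' Estimate the channel crosstalk matrix from spot profiles
#'
#' Fluorophore emission bleeds across detection channels, so the measured
#' channel vector of a base is a fixed mixture of the pure base signals.
#' The mixing matrix is estimated from the data themselves: each
#' (spot, cycle) observation bright enough not to be a dark-base cycle is
#' provisionally called by its brightest raw channel; the channel vectors
#' assigned to each base are averaged; each base column is normalised to
#' peak 1. One refinement pass repeats the call on unmixed intensities
#' and re-averages, which removes the bias the bleed itself introduces
#' into the provisional calls.
#'
#' @param profiles Tibble with list-column `raw` from
#'   [extract_profiles()].
#' @param params [pipeline_params()].
#' @param refine Run the one-step refinement (default `TRUE`).
#' @param min_obs Minimum bright observations required per base class
#'   before the estimate is considered stable (default 30; fewer is an
#'   error).
#' @return A `crosstalk_matrix`: 3 x 3 numeric matrix, rows = channels,
#'   columns = the three fluorescent bases in `params$channel_bases`
#'   order, each column's maximum equal to 1.
#' @export
estimate_crosstalk <- function(profiles, params = pipeline_params(),
                               refine = TRUE, min_obs = 30L) {
  obs <- do.call(rbind, profiles$raw)          # (spots*cycles) x 3
  if (is.null(obs) || nrow(obs) == 0L) {
    stop("no observations to estimate crosstalk from", call. = FALSE)
  }
  # drop provisional dark cycles: all channels below the dark fraction of
  # the spot's maximum
  spot_max <- rep(vapply(profiles$raw, max, numeric(1)),
                  each = nrow(profiles$raw[[1]]))
  bright <- apply(obs, 1, max) >= params$g_dark_fraction * spot_max
  obs_b <- obs[bright, , drop = FALSE]
  if (nrow(obs_b) == 0L) stop("insufficient base diversity: no bright observations",
                              call. = FALSE)
  average_by_call <- function(calls) {
    M <- matrix(NA_real_, 3, 3,
                dimnames = list(paste0("ch", 1:3), params$channel_bases))
    for (b in 1:3) {
      sel <- calls == b
      if (sum(sel) < min_obs) {
        stop("insufficient base diversity: base ", params$channel_bases[b],
             " has ", sum(sel), " bright observations (need >= ", min_obs,
             ")", call. = FALSE)
      }
      M[, b] <- colMeans(obs_b[sel, , drop = FALSE])
    }
    sweep(M, 2, apply(M, 2, max), "/")
  }
  M <- average_by_call(max.col(obs_b, ties.method = "first"))
  if (refine) {
    un <- t(solve(M, t(obs_b)))
    M <- average_by_call(max.col(un, ties.method = "first"))
  }
  if (kappa(M) > 1e6) stop("estimated crosstalk matrix is ill-conditioned",
                           call. = FALSE)
  structure(M, class = c("crosstalk_matrix", "matrix", "array"))
}

#' Apply inverse-crosstalk unmixing to spot profiles
#'
#' Multiplies every cycle's measured channel vector by the inverse of the
#' crosstalk matrix, converting channel space to base space. Negative
#' unmixed values are kept; thresholding is deferred to base calling.
#'
#' @param profiles Tibble with list-column `raw`.
#' @param M A `crosstalk_matrix` (or any invertible 3 x 3 matrix).
#' @return `profiles` with list-column `unmixed` (C x 3 matrices, columns
#'   = bases) and `max_unmixed`, the largest unmixed entry per spot.
#' @export
unmix <- function(profiles, M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3L, 3L)))
  if (!all(is.finite(M)) || abs(det(M)) < 1e-12 || kappa(M) > 1e8) {
    stop("crosstalk matrix is singular or ill-conditioned", call. = FALSE)
  }
  Minv <- solve(M)
  bases <- colnames(M)
  profiles$unmixed <- lapply(profiles$raw, function(r) {
    u <- t(Minv %*% t(r))
    colnames(u) <- bases
    u
  })
  profiles$max_unmixed <- vapply(
    profiles$unmixed, function(u) if (length(u)) max(u) else -Inf, numeric(1))
  profiles
}

#' Call base sequences from unmixed spot profiles
#'
#' Three-colour sequencing chemistry leaves one base dark: a cycle in
#' which all three unmixed intensities fall below `g_dark_fraction` of
#' the spot's maximum unmixed intensity (across all its cycles) is called
#' as the dark base. Any other cycle is called as the base of its
#' brightest unmixed channel; an exact tie between the top two channels
#' yields `N`. Spots with no positive signal at all are called all-`N`.
#'
#' @param profiles Tibble with list-columns `unmixed` and `max_unmixed`
#'   from [unmix()].
#' @param params [pipeline_params()].
#' @return `profiles` with character column `sequence` (length = number
#'   of cycles, alphabet A/C/G/T/N).
#' @export
call_bases <- function(profiles, params = pipeline_params()) {
  dark <- dark_base(params)
  bases <- params$channel_bases
  profiles$sequence <- vapply(seq_len(nrow(profiles)), function(i) {
    u <- profiles$unmixed[[i]]
    mx <- profiles$max_unmixed[i]
    if (!is.finite(mx) || mx <= 0) {
      return(paste(rep("N", nrow(u)), collapse = ""))
    }
    thr <- params$g_dark_fraction * mx
    calls <- character(nrow(u))
    for (cy in seq_len(nrow(u))) {
      v <- u[cy, ]
      if (all(v < thr)) {
        calls[cy] <- dark
      } else {
        o <- order(v, decreasing = TRUE)
        calls[cy] <- if (v[o[1]] == v[o[2]]) "N" else bases[o[1]]
      }
    }
    paste(calls, collapse = "")
  }, character(1))
  profiles
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  cat("<crosstalk matrix: rows = channels, cols = bases, column max = 1>\n")
  print(unclass(x), digits = 3)
  invisible(x)
}
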