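#' Pair phenotype and sequencing fields of view
#'
#' Live phenotype images and in situ sequencing images of the same well
#' are acquired in separate sessions, possibly at different
#' magnifications. Candidate partners for each phenotype field of view
#' (FOV) are the sequencing FOVs whose stage position lies within one
#' field width; the phenotype image is rescaled onto the sequencing pixel
#' grid, candidates are ranked by cross-correlation at coarse (8 x 8
#' downsampled) resolution, and the best candidate is refined at fine
#' (2 x 2 downsampled) resolution. The total shift is the coarse and fine
#' estimates composed at full resolution.
#'
#' @param pheno,nis Tibbles with one row per FOV: `fov` (id), `image`
#'   (list-column of nuclear-stain matrices), `stage_x`, `stage_y`
#'   (stage position in micrometres).
#' @param params [pipeline_params()]; `pixel_size_um["pheno"]` and
#'   `pixel_size_um["nis"]` set the magnification ratio.
#' @return Tibble of FOV pairs: `pheno_fov`, `nis_fov`, `scale`
#'   (phenotype pixels per sequencing pixel), `coarse_dy/dx`,
#'   `fine_dy/dx`, `dy`, `dx` (total, sequencing-frame pixels), `corr`.
#'   Phenotype FOVs with no candidate in range or no candidate reaching
#'   `params$min_corr` are reported with `nis_fov = NA`.
#' @export
pair_fovs <- function(pheno, nis, params = pipeline_params()) {
  px_ph <- params$pixel_size_um[["pheno"]]
  px_nis <- params$pixel_size_um[["nis"]]
  scale <- px_ph / px_nis                    # pheno px are this many nis px
  out <- vector("list", nrow(pheno))
  for (i in seq_len(nrow(pheno))) {
    ph_img <- as_matrix_image(pheno$image[[i]])
    field_um <- max(dim(ph_img)) * px_ph
    d <- sqrt((nis$stage_x - pheno$stage_x[i])^2 +
                (nis$stage_y - pheno$stage_y[i])^2)
    cand <- which(d <= field_um)
    row0 <- tibble::tibble(pheno_fov = pheno$fov[i], nis_fov = NA,
                           scale = scale, coarse_dy = NA_integer_,
                           coarse_dx = NA_integer_, fine_dy = NA_integer_,
                           fine_dx = NA_integer_, dy = NA_integer_,
                           dx = NA_integer_, corr = NA_real_)
    if (length(cand) == 0L) { out[[i]] <- row0; next }
    ph_nis <- rescale_image(ph_img, scale)
    best <- NULL
    for (j in cand) {
      fit <- tryCatch(
        correlate_pair(ph_nis, as_matrix_image(nis$image[[j]]), params),
        error = function(e) list(coarse = c(0L, 0L), fine = c(0L, 0L),
                                 corr = -Inf))
      if (is.null(best) || fit$corr > best$fit$corr) best <- list(j = j, fit = fit)
    }
    if (best$fit$corr < params$min_corr) { out[[i]] <- row0; next }
    f <- best$fit
    row0$nis_fov <- nis$fov[best$j]
    row0[c("coarse_dy", "coarse_dx", "fine_dy", "fine_dx")] <-
      as.list(c(f$coarse, f$fine))
    row0$dy <- f$coarse[1] + f$fine[1]
    row0$dx <- f$coarse[2] + f$fine[2]
    row0$corr <- f$corr
    out[[i]] <- row0
  }
  dplyr::bind_rows(out)
}

# Coarse-then-fine correlation of a phenotype image (already on the nis
# pixel grid) against a sequencing nuclear image. Images are compared on
# a common zero-padded canvas so shapes may differ.
correlate_pair <- function(ph, nis, params) {
  dimc <- pmax(dim(ph), dim(nis))
  pad <- function(m) {
    out <- matrix(0, dimc[1], dimc[2])
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  ph <- pad(ph); nis <- pad(nis)
  cds <- params$coarse_downsample
  fds <- params$fine_downsample
  s8 <- register_translation(block_downsample(nis, cds),
                             block_downsample(ph, cds),
                             max_shift = max(dimc %/% (2L * cds)))
  coarse <- c(-s8$dy, -s8$dx) * cds          # shift to apply to ph
  ph_c <- shift_image(ph, coarse[1], coarse[2])
  s2 <- register_translation(block_downsample(nis, fds),
                             block_downsample(ph_c, fds),
                             max_shift = max(2L * cds %/% fds, 4L))
  fine <- c(-s2$dy, -s2$dx) * fds
  list(coarse = as.integer(coarse), fine = as.integer(fine),
       corr = s2$peak_corr)
}

# Bilinear rescale by a scale factor (output size = input size * scale).
rescale_image <- function(img, scale) {
  if (abs(scale - 1) < 1e-9) return(img)
  EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                     w = max(1L, round(nrow(img) * scale)),
                                     h = max(1L, round(ncol(img) * scale))))
}

#' Match phenotype nuclei to sequencing nuclei within a paired FOV
#'
#' Transforms phenotype nucleus centroids into the sequencing frame
#' (magnification scaling plus the FOV pair's shift) and matches each to
#' the nearest sequencing nucleus centroid. A match is kept only if the
#' centroids lie within `max_nucleus_move_um` of each other and the
#' nuclear areas agree within `area_ratio_bound` after correcting areas
#' by the squared magnification ratio. Ambiguity is fatal on both sides:
#' if two phenotype nuclei claim one sequencing nucleus, or a phenotype
#' nucleus has a second sequencing centroid inside the distance gate
#' closer than `ambiguity_ratio` times its nearest, all nuclei involved
#' are excluded.
#'
#' @param pheno,nis [label_image()] objects (phenotype nuclei and
#'   sequencing nuclei).
#' @param pair One row of the [pair_fovs()] output (needs `scale`, `dy`,
#'   `dx`).
#' @param params [pipeline_params()].
#' @return Tibble of matched cells: `pheno_label`, `nis_label`,
#'   `distance_um`, `area_ratio`, plus the transformed phenotype centroid
#'   (`row`, `col`, sequencing-frame pixels).
#' @export
match_nuclei <- function(pheno, nis, pair, params = pipeline_params()) {
  stopifnot(inherits(pheno, "label_image"), inherits(nis, "label_image"))
  px_nis <- params$pixel_size_um[["nis"]]
  po <- pheno$objects
  no <- nis$objects
  empty <- tibble::tibble(pheno_label = integer(), nis_label = integer(),
                          distance_um = numeric(), area_ratio = numeric(),
                          row = numeric(), col = numeric())
  if (nrow(po) == 0L || nrow(no) == 0L) return(empty)
  # phenotype centroids -> nis frame; areas scale with the square of the
  # magnification ratio
  tr_row <- po$row * pair$scale + pair$dy
  tr_col <- po$col * pair$scale + pair$dx
  tr_area <- po$area * pair$scale^2
  d_um <- sqrt(outer(tr_row, no$row, "-")^2 +
                 outer(tr_col, no$col, "-")^2) * px_nis
  nearest <- apply(d_um, 1, which.min)
  d1 <- d_um[cbind(seq_len(nrow(po)), nearest)]
  ok <- d1 <= params$max_nucleus_move_um
  ratio <- tr_area / no$area[nearest]
  ok <- ok & ratio <= params$area_ratio_bound &
    ratio >= 1 / params$area_ratio_bound
  # second-nearest ambiguity: another nis centroid inside the gate and
  # nearly as close as the nearest
  if (ncol(d_um) > 1L) {
    d2 <- apply(d_um, 1, function(v) sort(v, partial = 2)[2])
    close_second <- d2 <= params$max_nucleus_move_um &
      d2 < params$ambiguity_ratio * pmax(d1, .Machine$double.eps)
    ok <- ok & !close_second
  }
  keep <- which(ok)
  if (length(keep) == 0L) return(empty)
  # duplicate claims: two phenotype nuclei on one nis nucleus drop all
  claimed <- nearest[keep]
  dup <- claimed %in% claimed[duplicated(claimed)]
  keep <- keep[!dup]
  if (length(keep) == 0L) return(empty)
  tibble::tibble(pheno_label = po$label[keep],
                 nis_label = no$label[nearest[keep]],
                 distance_um = d1[keep],
                 area_ratio = ratio[keep],
                 row = tr_row[keep], col = tr_col[keep])
}
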