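#' Pipeline parameters
#'
#' Collects every tunable threshold of the analysis pipeline in one
#' validated list. Defaults are the values used throughout genome-scale
#' screens of this kind; each can be overridden per call.
#'
#' @param n_detection_cycles Number of leading sequencing cycles summed for
#'   spot detection (default 3).
#' @param spot_window Side length in pixels of the square window over which
#'   spot intensities are aggregated (default 5).
#' @param g_dark_fraction A cycle is called as the dark base G when all three
#'   unmixed channel intensities fall below this fraction of the spot's
#'   maximum unmixed intensity across all cycles (default 0.20).
#' @param dominance_fraction Minimum share of a nucleus's total matched-spot
#'   intensity that its top-ranked guide must contribute for assignment
#'   (default 2/3).
#' @param nucleus_intensity_threshold Minimum single-channel, single-cycle
#'   unmixed spot intensity (camera counts) per nucleus (default `7e5`; a
#'   `2e5` preset suits low-signal cell types such as iPSC-derived
#'   macrophages).
#' @param max_nucleus_move_um Maximum centroid displacement, in micrometres,
#'   tolerated when pairing a phenotype nucleus with a sequencing nucleus
#'   (default 11.1).
#' @param area_ratio_bound Nuclear areas must match within this fold margin
#'   when pairing nuclei (default 2, i.e. ratio within \[1/2, 2\]).
#' @param ambiguity_ratio A phenotype nucleus is discarded as ambiguous when
#'   its second-nearest sequencing nucleus inside the distance gate is closer
#'   than `ambiguity_ratio` times the nearest distance (default 1.2).
#' @param min_cells_per_gene Minimum number of phenotyped cells required
#'   before a gene is tested (default 10).
#' @param coarse_downsample Downsampling factor for coarse field-of-view
#'   mapping (default 8).
#' @param fine_downsample Downsampling factor for fine field-of-view mapping
#'   (default 2).
#' @param bg_downsample Block size of the downsampling step in local
#'   background subtraction (default 8).
#' @param bg_window Side length, in downsampled pixels, of the neighbourhood
#'   whose minimum is subtracted during local background subtraction
#'   (default 9).
#' @param label_shrink_px Erosion radius in pixels used to predict nucleus
#'   location from membrane-derived cell outlines (default 5).
#' @param highpass_sigma Gaussian sigma in pixels of the unsharp-mask
#'   high-pass filter applied to sequencing channels (default 4).
#' @param speck_sigma Gaussian sigma in pixels of the high-pass filter used
#'   by the speck metric; specks are small, so the kernel is tight
#'   (default 2).
#' @param detect_k Spot detection keeps local maxima brighter than
#'   `median + detect_k * MAD` of the filtered detection image (default 5).
#' @param detect_floor Absolute lower bound on the detection threshold, in
#'   filtered-intensity counts (default 0: the MAD rule decides).
#' @param max_shift Maximum per-cycle registration shift in pixels
#'   (default 50).
#' @param min_corr Minimum normalised correlation for accepting a
#'   field-of-view pair (default 0.2).
#' @param expression_percentile Cells whose mean reporter intensity falls
#'   below this percentile (0-100) of the run are excluded from phenotype
#'   analysis (default 5).
#' @param pixel_size_um Named numeric vector of pixel sizes in micrometres
#'   per modality, with entries `nis` and `pheno`.
#' @param channel_bases Character vector of length 3 mapping sequencing
#'   channels 1-3 (477, 546 and 638 nm) to bases; the fourth base is dark
#'   (default `c("A", "C", "T")`, G dark).
#'
#' @return A named list of class `nisseq_params`.
#' @examples
#' p <- pipeline_params(nucleus_intensity_threshold = 2e5)
#' p$dominance_fraction
#' @export
pipeline_params <- function(n_detection_cycles = 3L,
                            spot_window = 5L,
                            g_dark_fraction = 0.20,
                            dominance_fraction = 2 / 3,
                            nucleus_intensity_threshold = 7e5,
                            max_nucleus_move_um = 11.1,
                            area_ratio_bound = 2,
                            ambiguity_ratio = 1.2,
                            min_cells_per_gene = 10L,
                            coarse_downsample = 8L,
                            fine_downsample = 2L,
                            bg_downsample = 8L,
                            bg_window = 9L,
                            label_shrink_px = 5L,
                            highpass_sigma = 4,
                            speck_sigma = 2,
                            detect_k = 5,
                            detect_floor = 0,
                            max_shift = 50L,
                            min_corr = 0.2,
                            expression_percentile = 5,
                            pixel_size_um = c(nis = 0.325, pheno = 0.325),
                            channel_bases = c("A", "C", "T")) {
  p <- list(
    n_detection_cycles = as.integer(n_detection_cycles),
    spot_window = as.integer(spot_window),
    g_dark_fraction = g_dark_fraction,
    dominance_fraction = dominance_fraction,
    nucleus_intensity_threshold = nucleus_intensity_threshold,
    max_nucleus_move_um = max_nucleus_move_um,
    area_ratio_bound = area_ratio_bound,
    ambiguity_ratio = ambiguity_ratio,
    min_cells_per_gene = as.integer(min_cells_per_gene),
    coarse_downsample = as.integer(coarse_downsample),
    fine_downsample = as.integer(fine_downsample),
    bg_downsample = as.integer(bg_downsample),
    bg_window = as.integer(bg_window),
    label_shrink_px = as.integer(label_shrink_px),
    highpass_sigma = highpass_sigma,
    speck_sigma = speck_sigma,
    detect_k = detect_k,
    detect_floor = detect_floor,
    max_shift = as.integer(max_shift),
    min_corr = min_corr,
    expression_percentile = expression_percentile,
    pixel_size_um = pixel_size_um,
    channel_bases = toupper(channel_bases)
  )
  validate_params(p)
  structure(p, class = "nisseq_params")
}

validate_params <- function(p) {
  pos <- c(
    "spot_window", "g_dark_fraction", "dominance_fraction",
    "nucleus_intensity_threshold", "max_nucleus_move_um",
    "area_ratio_bound", "min_cells_per_gene", "coarse_downsample",
    "fine_downsample", "bg_downsample", "bg_window", "highpass_sigma",
    "speck_sigma", "max_shift"
  )
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("parameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  if (p$dominance_fraction <= 0.5 || p$dominance_fraction > 1) {
    stop("dominance_fraction must lie in (0.5, 1]", call. = FALSE)
  }
  if (p$g_dark_fraction <= 0 || p$g_dark_fraction >= 1) {
    stop("g_dark_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (p$label_shrink_px < 0) stop("label_shrink_px must be >= 0", call. = FALSE)
  if (length(p$channel_bases) != 3L ||
      anyDuplicated(p$channel_bases) ||
      !all(p$channel_bases %in% c("A", "C", "G", "T"))) {
    stop("channel_bases must be three distinct bases", call. = FALSE)
  }
  if (!all(c("nis", "pheno") %in% names(p$pixel_size_um))) {
    stop("pixel_size_um needs 'nis' and 'pheno' entries", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.nisseq_params <- function(x, ...) {
  cat("<nisseq pipeline parameters>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Dark base implied by the channel -> base mapping.
dark_base <- function(params) {
  setdiff(c("A", "C", "G", "T"), params$channel_bases)
}
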