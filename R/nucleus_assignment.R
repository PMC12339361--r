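#' Assign matched spots to segmented nuclei
#'
#' Every library-matched spot (status `exact` or `corrected`) contributes
#' its total intensity — the sum of its positive unmixed entries over all
#' cycles and channels — to the guide it matched, inside the nucleus
#' whose label contains the spot's centre pixel. Spots over background
#' (label 0) are discarded; `ambiguous` spots count toward a nucleus's
#' total intensity but toward no guide, so they erode dominance rather
#' than create it.
#'
#' A nucleus is `assigned` its top-ranked guide only if that guide holds
#' more than `dominance_fraction` (default two-thirds) of the nucleus's
#' total matched-spot intensity, and the brightest single-channel,
#' single-cycle unmixed intensity among its spots reaches
#' `nucleus_intensity_threshold`. Otherwise its status records the first
#' failed gate: `no_spot`, `below_intensity`, `not_dominant`, or
#' `ambiguous` (no guide-attributable intensity, or a tie at the top).
#'
#' @param spots Tibble from [match_spots()] with `row`, `col`, `unmixed`,
#'   `max_unmixed`, `status`, `guide_id`, `gene`.
#' @param labels A [label_image()] of nuclei sharing the spot coordinate
#'   frame.
#' @param params [pipeline_params()].
#' @return Tibble of nucleus calls: `label`, `row`, `col`, `area`,
#'   `status`, `guide_id`, `gene`, `dominance`, `max_intensity`,
#'   `n_spots`.
#' @export
assign_spots_to_nuclei <- function(spots, labels,
                                   params = pipeline_params()) {
  stopifnot(inherits(labels, "label_image"))
  lmat <- labels$labels
  if (nrow(spots) > 0L &&
      (max(spots$row) >= nrow(lmat) || max(spots$col) >= ncol(lmat))) {
    stop("spot positions fall outside the label image frame", call. = FALSE)
  }
  calls <- dplyr::mutate(labels$objects,
                         status = "no_spot",
                         guide_id = NA_character_, gene = NA_character_,
                         dominance = NA_real_, max_intensity = NA_real_,
                         n_spots = 0L)
  spots <- dplyr::filter(spots, .data$status %in%
                           c("exact", "corrected", "ambiguous"))
  if (nrow(spots) == 0L) return(calls)
  spots$nucleus <- lmat[cbind(spots$row + 1L, spots$col + 1L)]
  spots <- dplyr::filter(spots, .data$nucleus > 0L)
  if (nrow(spots) == 0L) return(calls)
  spots$total_intensity <- vapply(spots$unmixed,
                                  function(u) sum(pmax(u, 0)), numeric(1))
  per_nuc <- split(spots, spots$nucleus)
  for (nuc in per_nuc) {
    lab <- nuc$nucleus[1]
    i <- match(lab, calls$label)
    total <- sum(nuc$total_intensity)
    max_int <- max(nuc$max_unmixed)
    guided <- dplyr::filter(nuc, .data$status %in% c("exact", "corrected"))
    calls$n_spots[i] <- nrow(nuc)
    calls$max_intensity[i] <- max_int
    if (nrow(guided) == 0L || total <= 0) {
      calls$status[i] <- "ambiguous"
      next
    }
    by_guide <- tapply(guided$total_intensity, guided$guide_id, sum)
    top <- which.max(by_guide)
    dominance <- by_guide[[top]] / total
    calls$dominance[i] <- dominance
    if (sum(by_guide == by_guide[[top]]) > 1L) {
      calls$status[i] <- "ambiguous"
    } else if (max_int < params$nucleus_intensity_threshold) {
      calls$status[i] <- "below_intensity"
    } else if (dominance <= params$dominance_fraction) {
      calls$status[i] <- "not_dominant"
    } else {
      calls$status[i] <- "assigned"
      calls$guide_id[i] <- names(by_guide)[top]
      calls$gene[i] <- guided$gene[match(names(by_guide)[top],
                                         guided$guide_id)]
    }
  }
  calls
}

#' Summarise nucleus-level barcode mapping
#'
#' @param calls Tibble from [assign_spots_to_nuclei()].
#' @param lib Optional [barcode_library()]; when given, per-guide nucleus
#'   counts include guides with zero nuclei.
#' @return List with `by_status` (status fractions), `mapped_fraction`
#'   (assigned nuclei / all nuclei) and `per_guide` (nucleus counts).
#' @export
mapping_summary <- function(calls, lib = NULL) {
  n <- nrow(calls)
  by_status <- dplyr::count(calls, .data$status, name = "n_nuclei")
  by_status$fraction <- if (n > 0L) by_status$n_nuclei / n else numeric(0)
  assigned <- dplyr::filter(calls, .data$status == "assigned")
  per_guide <- dplyr::count(assigned, .data$guide_id, .data$gene,
                            name = "n_nuclei")
  if (!is.null(lib)) {
    per_guide <- dplyr::left_join(
      dplyr::select(tibble::as_tibble(lib), "guide_id", "gene"),
      dplyr::select(per_guide, "guide_id", "n_nuclei"),
      by = "guide_id")
    per_guide$n_nuclei[is.na(per_guide$n_nuclei)] <- 0L
  }
  list(by_status = by_status,
       mapped_fraction = if (n > 0L) nrow(assigned) / n else NA_real_,
       per_guide = per_guide)
}
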