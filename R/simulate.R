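#' Simulation configuration
#'
#' Collects every knob of the synthetic scene generator. Defaults emulate
#' a single spinning-disc field of view at x20 (0.325 um/px, 2048 px
#' sensor cropped to 1024 for speed) with ~200 nuclei, one dominant
#' rolling-circle spot per transduced nucleus, and intensities scaled so
#' that clean spots clear the 7e5 per-nucleus intensity gate used on real
#' data.
#'
#' @param dim Image height and width in pixels.
#' @param pixel_size_um Pixel size of the sequencing modality.
#' @param n_nuclei Number of nuclei placed (rejection-sampled so nuclei
#'   never overlap).
#' @param nucleus_radius_um Mean and sd of nucleus radius in micrometres.
#' @param nuclear_amplitude Peak intensity of the nuclear stain blobs.
#' @param spot_amplitude Mean and sd of the peak per-pixel spot amplitude
#'   (camera counts).
#' @param psf_sigma_px Gaussian point-spread sigma of spots, pixels.
#' @param background Constant background level added to every channel.
#' @param noise_sd Per-pixel Gaussian read-noise sd. The scene's
#'   signal-to-noise ratio is `spot_amplitude[1] / noise_sd`.
#' @param crosstalk 3 x 3 channel crosstalk matrix (rows = channels,
#'   columns = fluorescent bases); identity = no bleed.
#' @param phasing Fraction of each spot's signal lagging one cycle
#'   behind, in `[0, 1)`.
#' @param drift_px Per-cycle stage drift `(dy, dx)` in pixels; cycle c is
#'   displaced by `(c-1) * drift_px`.
#' @param frac_unbarcoded Fraction of nuclei carrying no barcode spot.
#' @param frac_double Fraction of barcoded nuclei carrying two
#'   independent integrations (two spots, usually different guides).
#' @param n_cycles Number of sequencing cycles rendered.
#' @param min_sep_factor Minimum centre separation between two nuclei, as
#'   a multiple of the sum of their radii.
#' @param seed Integer seed; every render is bit-reproducible from
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(dim = c(1024L, 1024L),
                       pixel_size_um = 0.325,
                       n_nuclei = 200L,
                       nucleus_radius_um = c(4.5, 0.5),
                       nuclear_amplitude = 5000,
                       spot_amplitude = c(1.5e5, 2e4),
                       psf_sigma_px = 1.5,
                       background = 500,
                       noise_sd = 50,
                       crosstalk = diag(3),
                       phasing = 0,
                       drift_px = c(0, 0),
                       frac_unbarcoded = 0,
                       frac_double = 0,
                       n_cycles = 6L,
                       min_sep_factor = 1.25,
                       seed = 1L) {
  stopifnot(length(dim) == 2L, all(dim >= 64L),
            frac_unbarcoded >= 0, frac_unbarcoded <= 1,
            frac_double >= 0, frac_double <= 1,
            phasing >= 0, phasing < 1,
            all(dim(crosstalk) == c(3L, 3L)))
  structure(list(dim = as.integer(dim), pixel_size_um = pixel_size_um,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_um = nucleus_radius_um,
                 nuclear_amplitude = nuclear_amplitude,
                 spot_amplitude = spot_amplitude,
                 psf_sigma_px = psf_sigma_px, background = background,
                 noise_sd = noise_sd, crosstalk = crosstalk,
                 phasing = phasing, drift_px = drift_px,
                 frac_unbarcoded = frac_unbarcoded,
                 frac_double = frac_double, n_cycles = as.integer(n_cycles),
                 min_sep_factor = min_sep_factor, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a barcode library
#'
#' Draws distinct random spacers for `n_genes` genes with
#' `guides_per_gene` guides each plus `n_nt` non-targeting controls
#' (gene label `"NT"`).
#'
#' @param n_genes,guides_per_gene,n_nt Library composition.
#' @param L Spacer length (default 20).
#' @param seed Integer seed.
#' @return A [barcode_library()].
#' @export
simulate_library <- function(n_genes, guides_per_gene = 2L, n_nt = 2L,
                             L = 20L, seed = 1L) {
  stopifnot(n_genes >= 1L, guides_per_gene >= 1L, n_nt >= 0L, L >= 1L)
  n <- n_genes * guides_per_gene + n_nt
  if (n > 0.5 * 4^L) {
    stop("cannot draw ", n, " distinct spacers of length ", L, call. = FALSE)
  }
  spacers <- with_seed_compat(seed, {
    out <- character(0)
    while (length(out) < n) {
      cand <- vapply(seq_len(n - length(out)), function(i) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = "")
      }, character(1))
      out <- unique(c(out, cand))
    }
    out[seq_len(n)]
  })
  gene <- c(rep(sprintf("G%04d", seq_len(n_genes)), each = guides_per_gene),
            rep("NT", n_nt))
  barcode_library(tibble::tibble(
    guide_id = sprintf("%s_g%d", gene,
                       c(rep(seq_len(guides_per_gene), n_genes),
                         seq_len(n_nt))),
    gene = gene, spacer = spacers))
}

# Add a Gaussian splat of peak `amp` at 0-based centre (r0, c0), rendered
# inside a +-4 sigma window.
add_gaussian <- function(img, r0, c0, sigma, amp) {
  w <- ceiling(4 * sigma)
  rr <- max(1L, floor(r0 + 1 - w)):min(nrow(img), ceiling(r0 + 1 + w))
  cc <- max(1L, floor(c0 + 1 - w)):min(ncol(img), ceiling(c0 + 1 + w))
  if (length(rr) == 0L || length(cc) == 0L) return(img)
  g <- exp(-(outer((rr - 1) - r0, rep(1, length(cc)))^2 +
               outer(rep(1, length(rr)), (cc - 1) - c0)^2) /
             (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + amp * g
  img
}

# Rejection-sample non-overlapping nucleus centres and radii (pixels).
sample_nuclei <- function(cfg) {
  r_px <- pmax(4, stats::rnorm(cfg$n_nuclei, cfg$nucleus_radius_um[1],
                               cfg$nucleus_radius_um[2]) / cfg$pixel_size_um)
  rows <- numeric(0); cols <- numeric(0); rad <- numeric(0)
  tries <- 0L
  i <- 1L
  while (i <= cfg$n_nuclei) {
    if (tries > 500L * cfg$n_nuclei) {
      stop("could not place ", cfg$n_nuclei, " non-overlapping nuclei; ",
           "reduce n_nuclei or nucleus size", call. = FALSE)
    }
    tries <- tries + 1L
    margin <- r_px[i] + 8
    r0 <- stats::runif(1, margin, cfg$dim[1] - 1 - margin)
    c0 <- stats::runif(1, margin, cfg$dim[2] - 1 - margin)
    if (length(rows)) {
      d <- sqrt((rows - r0)^2 + (cols - c0)^2)
      if (any(d < (rad + r_px[i]) * cfg$min_sep_factor)) next
    }
    rows <- c(rows, r0); cols <- c(cols, c0); rad <- c(rad, r_px[i])
    i <- i + 1L
  }
  tibble::tibble(nucleus = seq_len(cfg$n_nuclei), row = rows, col = cols,
                 radius_px = rad)
}

base_indicator <- function(base, channel_bases) {
  v <- numeric(3)
  hit <- match(base, channel_bases)
  if (!is.na(hit)) v[hit] <- 1       # dark base stays all-zero
  v
}

# n x 3 indicator matrix for a vector of single bases.
indicator_matrix <- function(bases, channel_bases) {
  m <- matrix(0, length(bases), 3)
  hit <- match(bases, channel_bases)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

# Render the three sequencing channels for all cycles at once. Each
# spot's Gaussian patch is computed a single time and re-added with the
# per-cycle, per-channel amplitude implied by its sequence, the phasing
# lag and the crosstalk matrix.
render_seq_cycles <- function(spots, cfg, params, nuclear_base) {
  n <- nrow(spots)
  splat <- vector("list", n)
  for (s in seq_len(n)) {
    sig <- cfg$psf_sigma_px
    w <- ceiling(4 * sig)
    rr <- max(1L, floor(spots$row[s] + 1 - w)):
      min(cfg$dim[1], ceiling(spots$row[s] + 1 + w))
    cc <- max(1L, floor(spots$col[s] + 1 - w)):
      min(cfg$dim[2], ceiling(spots$col[s] + 1 + w))
    g <- exp(-(outer(((rr - 1) - spots$row[s])^2,
                     ((cc - 1) - spots$col[s])^2, "+")) / (2 * sig^2))
    splat[[s]] <- list(rr = rr, cc = cc, g = g)
  }
  seq_chars <- if (n) do.call(rbind, strsplit(spots$detect_seq, "",
                                              fixed = TRUE)) else NULL
  cycles <- vector("list", cfg$n_cycles)
  for (cy in seq_len(cfg$n_cycles)) {
    chans <- list(matrix(0, cfg$dim[1], cfg$dim[2]),
                  matrix(0, cfg$dim[1], cfg$dim[2]),
                  matrix(0, cfg$dim[1], cfg$dim[2]))
    if (n) {
      V <- (1 - cfg$phasing) *
        indicator_matrix(seq_chars[, cy], params$channel_bases)
      if (cy > 1L && cfg$phasing > 0) {
        V <- V + cfg$phasing *
          indicator_matrix(seq_chars[, cy - 1L], params$channel_bases)
      }
      amps <- (V %*% t(cfg$crosstalk)) * spots$amplitude   # n x channels
      for (s in seq_len(n)) {
        sp <- splat[[s]]
        for (ch in 1:3) {
          if (amps[s, ch] > 0) {
            chans[[ch]][sp$rr, sp$cc] <-
              chans[[ch]][sp$rr, sp$cc] + amps[s, ch] * sp$g
          }
        }
      }
    }
    dy <- (cy - 1L) * cfg$drift_px[1]
    dx <- (cy - 1L) * cfg$drift_px[2]
    noisy <- function(img) {
      if (dy != 0 || dx != 0) img <- shift_image(img, dy, dx)
      pmax(img + cfg$background +
             matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                    nrow(img)), 0)
    }
    cycles[[cy]] <- list(nuclear = noisy(nuclear_base),
                         channels = lapply(chans, noisy))
  }
  cycles
}

#' Render a synthetic multi-cycle sequencing scene
#'
#' Builds a fully ground-truthed field of view: nuclei as Gaussian blobs
#' in the nuclear channel; per barcoded nucleus one (or, for
#' double-integration nuclei, two) rolling-circle spot whose cycle-c
#' channel vector encodes base c of its guide's detection sequence
#' through the configured crosstalk matrix; optional one-cycle phasing
#' lag; per-cycle stage drift; constant background and Gaussian read
#' noise.
#'
#' @param lib A [barcode_library()].
#' @param cfg A [sim_config()]; needs `n_cycles <=` detection-sequence
#'   length.
#' @param params [pipeline_params()] (only `channel_bases` is used, to
#'   decide which base is dark).
#' @return List: `stack` (a [cycle_stack()]), `nuclei` (truth tibble:
#'   centre, radius, guide/gene or `NA`), `spots` (truth tibble: position
#'   in the cycle-1 frame, planted detection sequence prefix, amplitude).
#' @export
render_nis_scene <- function(lib, cfg = sim_config(),
                             params = pipeline_params()) {
  stopifnot(inherits(lib, "barcode_library"))
  L <- nchar(lib$detect_seq[1])
  if (cfg$n_cycles > L) stop("n_cycles exceeds detection sequence length",
                             call. = FALSE)
  with_seed_compat(cfg$seed, {
    nuc <- sample_nuclei(cfg)
    # assign barcodes
    barcoded <- stats::runif(cfg$n_nuclei) >= cfg$frac_unbarcoded
    nuc$guide_id <- NA_character_
    nuc$gene <- NA_character_
    spots <- list()
    for (i in which(barcoded)) {
      n_int <- if (stats::runif(1) < cfg$frac_double) 2L else 1L
      gi <- sample.int(nrow(lib), n_int, replace = FALSE)
      nuc$guide_id[i] <- paste(lib$guide_id[gi], collapse = ";")
      nuc$gene[i] <- paste(lib$gene[gi], collapse = ";")
      for (g in gi) {
        ang <- stats::runif(1, 0, 2 * pi)
        rr <- stats::runif(1, 0, 0.4 * nuc$radius_px[i])
        spots[[length(spots) + 1L]] <- tibble::tibble(
          nucleus = i,
          row = nuc$row[i] + rr * sin(ang),
          col = nuc$col[i] + rr * cos(ang),
          guide_id = lib$guide_id[g],
          gene = lib$gene[g],
          detect_seq = substr(lib$detect_seq[g], 1L, cfg$n_cycles),
          amplitude = max(1, stats::rnorm(1, cfg$spot_amplitude[1],
                                          cfg$spot_amplitude[2])))
      }
    }
    spots <- if (length(spots)) dplyr::bind_rows(spots) else
      tibble::tibble(nucleus = integer(), row = numeric(), col = numeric(),
                     guide_id = character(), gene = character(),
                     detect_seq = character(), amplitude = numeric())
    if (nrow(spots)) spots$spot <- seq_len(nrow(spots))

    nuclear_base <- matrix(0, cfg$dim[1], cfg$dim[2])
    for (i in seq_len(nrow(nuc))) {
      nuclear_base <- add_gaussian(nuclear_base, nuc$row[i], nuc$col[i],
                                   nuc$radius_px[i] / 2,
                                   cfg$nuclear_amplitude)
    }

    cycles <- render_seq_cycles(spots, cfg, params, nuclear_base)
    list(stack = cycle_stack(cycles, cfg$pixel_size_um),
         nuclei = nuc, spots = spots)
  })
}

#' Render a dense field of barcode spots on a jittered grid
#'
#' A nucleus-free variant of [render_nis_scene()] for stress-testing the
#' base caller: spots are laid out on a grid with sub-pixel jitter so a
#' thousand ground-truthed spots fit one field of view.
#'
#' @param lib A [barcode_library()]; guides are sampled with replacement.
#' @param n_spots Number of spots to render.
#' @param cfg A [sim_config()]; `dim` must give at least `n_spots` grid
#'   cells at 24 px spacing.
#' @param params [pipeline_params()].
#' @return List: `stack` ([cycle_stack()], nuclear channel blank),
#'   `spots` (truth tibble with position, guide and detection sequence).
#' @export
render_spot_field <- function(lib, n_spots, cfg = sim_config(),
                              params = pipeline_params()) {
  stopifnot(inherits(lib, "barcode_library"))
  spacing <- 24
  per_row <- floor((cfg$dim[1] - spacing) / spacing)
  per_col <- floor((cfg$dim[2] - spacing) / spacing)
  if (per_row * per_col < n_spots) {
    stop("field too small for ", n_spots, " spots", call. = FALSE)
  }
  with_seed_compat(cfg$seed, {
    gi <- sample.int(nrow(lib), n_spots, replace = TRUE)
    cell <- sample.int(per_row * per_col, n_spots, replace = FALSE)
    spots <- tibble::tibble(
      spot = seq_len(n_spots),
      row = spacing * ((cell - 1L) %% per_row) + spacing / 2 +
        stats::runif(n_spots, -2, 2),
      col = spacing * ((cell - 1L) %/% per_row) + spacing / 2 +
        stats::runif(n_spots, -2, 2),
      guide_id = lib$guide_id[gi],
      gene = lib$gene[gi],
      detect_seq = substr(lib$detect_seq[gi], 1L, cfg$n_cycles),
      amplitude = pmax(1, stats::rnorm(n_spots, cfg$spot_amplitude[1],
                                       cfg$spot_amplitude[2])))
    cycles <- render_seq_cycles(spots, cfg, params,
                                matrix(0, cfg$dim[1], cfg$dim[2]))
    list(stack = cycle_stack(cycles, cfg$pixel_size_um), spots = spots)
  })
}

#' Render a live-phenotype scene matched to a sequencing scene
#'
#' Produces the phenotype-modality images for the nuclei of a rendered
#' sequencing scene: a nuclear-stain channel, a reporter channel whose
#' appearance depends on each cell's targeted gene, and a cell-body
#' channel usable for cell segmentation. Nuclei are jittered relative to
#' the sequencing scene (cells move between imaging sessions) and
#' rendered on the phenotype pixel grid.
#'
#' In `"translocation"` mode the reporter splits between nucleus and
#' cell body with nuclear fraction `baseline + effect(gene)`. In
#' `"speck"` mode each cell carries a bright punctum with probability
#' `baseline + effect(gene)` on top of a diffuse cell-body signal.
#'
#' @param scene Output of [render_nis_scene()].
#' @param mode `"translocation"` or `"speck"`.
#' @param effects Named numeric vector, gene -> additive effect on the
#'   nuclear fraction / speck probability. Unnamed genes (and unbarcoded
#'   nuclei) get 0.
#' @param params [pipeline_params()]; `pixel_size_um["pheno"]` sets the
#'   phenotype pixel grid.
#' @param baseline Baseline nuclear fraction or speck probability
#'   (default 0.25).
#' @param jitter_um Maximum nucleus displacement between modalities
#'   (uniform in a disc; default 2).
#' @param reporter_amplitude Total reporter intensity scale (default
#'   2000).
#' @param noise_sd,background Imaging noise of the phenotype modality.
#' @param seed Integer seed.
#' @return List: `nuclear`, `reporter`, `cell` (matrices on the phenotype
#'   grid) and `truth` (per-nucleus tibble with phenotype-frame centre,
#'   gene, and the planted nuclear fraction or speck indicator).
#' @export
render_phenotype_scene <- function(scene, mode = c("translocation", "speck"),
                                   effects = numeric(0),
                                   params = pipeline_params(),
                                   baseline = 0.25, jitter_um = 2,
                                   reporter_amplitude = 2000,
                                   noise_sd = 5, background = 100,
                                   seed = 1L) {
  mode <- match.arg(mode)
  px_nis <- params$pixel_size_um[["nis"]]
  px_ph <- params$pixel_size_um[["pheno"]]
  scale <- px_nis / px_ph                   # nis px -> pheno px
  dim_ph <- as.integer(round(dim(scene$stack$cycles[[1]]$nuclear) * scale))
  nuc <- scene$nuclei
  with_seed_compat(seed, {
    ang <- stats::runif(nrow(nuc), 0, 2 * pi)
    rj <- jitter_um * sqrt(stats::runif(nrow(nuc))) / px_ph
    truth <- tibble::tibble(
      nucleus = nuc$nucleus,
      row = nuc$row * scale + rj * sin(ang),
      col = nuc$col * scale + rj * cos(ang),
      radius_px = nuc$radius_px * scale,
      guide_id = nuc$guide_id,
      gene = nuc$gene)
    first_gene <- sub(";.*", "", truth$gene)
    eff <- ifelse(is.na(first_gene), 0,
                  ifelse(first_gene %in% names(effects),
                         effects[first_gene], 0))
    nuclear <- matrix(0, dim_ph[1], dim_ph[2])
    reporter <- matrix(0, dim_ph[1], dim_ph[2])
    cellch <- matrix(0, dim_ph[1], dim_ph[2])
    if (mode == "translocation") {
      truth$nuclear_fraction <- pmin(pmax(baseline + eff, 0), 1)
    } else {
      p <- pmin(pmax(baseline + eff, 0), 1)
      truth$speck <- stats::runif(nrow(truth)) < p
      truth$speck_prob <- p
    }
    for (i in seq_len(nrow(truth))) {
      sig_n <- truth$radius_px[i] / 2
      sig_c <- truth$radius_px[i]
      nuclear <- add_gaussian(nuclear, truth$row[i], truth$col[i], sig_n,
                              3000)
      cellch <- add_gaussian(cellch, truth$row[i], truth$col[i], sig_c,
                             1500)
      if (mode == "translocation") {
        # cytosolic reporter is an annulus (wide Gaussian minus the
        # nuclear profile, non-negative): a cytosolic cell shows a dark
        # nucleus, a translocated cell a bright one
        f <- truth$nuclear_fraction[i]
        reporter <- add_gaussian(reporter, truth$row[i], truth$col[i],
                                 sig_n,
                                 (2 * f - 1) * reporter_amplitude)
        reporter <- add_gaussian(reporter, truth$row[i], truth$col[i],
                                 sig_c, (1 - f) * reporter_amplitude)
      } else {
        reporter <- add_gaussian(reporter, truth$row[i], truth$col[i],
                                 sig_c, reporter_amplitude / 4)
        if (truth$speck[i]) {
          sang <- stats::runif(1, 0, 2 * pi)
          sr <- stats::runif(1, 0, 0.4 * truth$radius_px[i])
          reporter <- add_gaussian(reporter,
                                   truth$row[i] + sr * sin(sang),
                                   truth$col[i] + sr * cos(sang),
                                   1.2, 4 * reporter_amplitude)
        }
      }
    }
    noisy <- function(img) {
      pmax(img + background +
             matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img)), 0)
    }
    list(nuclear = noisy(nuclear), reporter = noisy(reporter),
         cell = noisy(cellch), truth = truth)
  })
}

#' Simulate a single-cell screen table
#'
#' Draws per-cell phenotype metrics directly (no images): the
#' non-targeting null distribution is log-normal and each planted hit
#' gene's metric is scaled by a fold change. Used to validate the screen
#' statistics at scale.
#'
#' @param n_genes Number of targeted genes.
#' @param cells_per_gene Cells per targeted gene.
#' @param n_nt_cells Cells in the non-targeting pool.
#' @param hit_fc Named numeric vector, gene name -> multiplicative fold
#'   change (e.g. `c(G0001 = 0.5)`); unnamed genes are null.
#' @param meanlog,sdlog Log-normal null parameters (defaults 0 and 0.5).
#' @param seed Integer seed.
#' @return Tibble with `gene` and `metric` columns (NT cells labelled
#'   `"NT"`).
#' @export
simulate_screen_table <- function(n_genes, cells_per_gene, n_nt_cells,
                                  hit_fc = numeric(0), meanlog = 0,
                                  sdlog = 0.5, seed = 1L) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  fc <- ifelse(genes %in% names(hit_fc), hit_fc[genes], 1)
  with_seed_compat(seed, {
    tibble::tibble(
      gene = c(rep(genes, each = cells_per_gene), rep("NT", n_nt_cells)),
      metric = c(stats::rlnorm(n_genes * cells_per_gene, meanlog, sdlog) *
                   rep(fc, each = cells_per_gene),
                 stats::rlnorm(n_nt_cells, meanlog, sdlog)))
  })
}
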