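#' Construct an image stack
#'
#' @param channels Named list of numeric matrices sharing one shape; must
#'   include a channel named `"hoechst"`.
#' @param truth Optional ground-truth placement tibble (simulated stacks).
#' @param meta Optional list of provenance (seeds, parameters, fixation).
#' @return A list of class `cc_image_stack`.
#' @export
image_stack <- function(channels, truth = NULL, meta = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  if (!"hoechst" %in% names(channels)) {
    stop("image stack must contain a channel named \"hoechst\"")
  }
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop("all channels must share one shape")
  structure(list(channels = channels, truth = truth, meta = meta),
            class = "cc_image_stack")
}

#' @export
print.cc_image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<cc_image_stack> %d x %d px, channels: %s\n", d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$truth)) cat(sprintf("  ground truth: %d cells\n", nrow(x$truth)))
  invisible(x)
}

# Integer pixel values of one rasterized nucleus: every pixel gets
# floor(total/area) counts and the remainder is spread one count per pixel,
# so the pixel sum equals `total` exactly (integer arithmetic).
disk_values <- function(total, n_px) {
  q <- total %/% n_px
  r <- total %% n_px
  v <- rep.int(q, n_px)
  if (r > 0) v[seq_len(r)] <- v[seq_len(r)] + 1
  v
}

#' Render a population as a multi-channel image
#'
#' Draws each cell as a disk of integer camera counts whose pixel sum equals
#' the cell's (noise-factored) total signal exactly; M-phase cells occupy
#' `m_phase_shrink_factor` times their interphase area with proportionally
#' concentrated intensity.  Under direct fixation the soluble MCM pool is
#' added to the MCM channels of every cell, reducing their relative
#' cell-to-cell variation; pre-extraction renders chromatin-bound signal only.
#' Pixel values are `background + signal + round(Gaussian read noise)`,
#' clamped to `[0, 65535]` (16-bit camera range).
#'
#' Cells are placed on a seeded, jittered grid whose pitch guarantees
#' `min_separation_px` between nucleus borders; if the requested image cannot
#' hold the population the error reports the achievable cell count.
#'
#' @param population A `cc_population`.
#' @param render A [render_params()].
#' @param fixation `"pre_extraction"` (chromatin-bound signal only) or
#'   `"direct"` (soluble MCM pool included).
#' @param channels Channels to render (default: Hoechst, EdU, Mcm3, Cdt1).
#' @return A `cc_image_stack` whose `truth` table holds, per cell: position,
#'   radius, phase, DNA content, the rendered integer total per channel
#'   (`total_*`), the noise-free totals (`sig_*`), `edu_label` and the
#'   M-phase flag.
#' @export
render_image <- function(population,
                         render = render_params(),
                         fixation = c("pre_extraction", "direct"),
                         channels = c("hoechst", "edu", "mcm3", "cdt1")) {
  params <- attr(population, "params")
  stopifnot(inherits(population, "cc_population"), !is.null(params),
            inherits(render, "cc_render_params"))
  fixation <- match.arg(fixation)
  stopifnot("hoechst" %in% channels)
  marker_chans <- setdiff(channels, "hoechst")
  missing_ch <- setdiff(paste0("sig_", marker_chans, recycle0 = TRUE),
                        names(population))
  if (length(missing_ch) > 0) {
    stop("unknown channels: ", paste(sub("^sig_", "", missing_ch), collapse = ", "))
  }

  n <- nrow(population)
  set.seed(render$seed)

  r_mean <- render$nucleus_radius_px[["mean"]]
  r_sd <- render$nucleus_radius_px[["sd"]]
  r_bound <- (r_mean + 4 * r_sd) * 2^(1 / 3)
  pitch <- ceiling(2 * r_bound + render$min_separation_px + 2)
  jitter_max <- max((pitch - 2 * r_bound - render$min_separation_px) / 2, 0)

  if (is.null(render$image_shape)) {
    g <- max(ceiling(sqrt(max(n, 1))), 1)
    shape <- c(g, g) * pitch
    grid_dim <- c(g, g)
  } else {
    shape <- render$image_shape
    grid_dim <- pmax(shape %/% pitch, 0)
    if (prod(grid_dim) < n) {
      stop(sprintf(
        "cannot place %d cells in a %d x %d image at this density; at most %d fit",
        n, shape[1], shape[2], prod(grid_dim)))
    }
  }

  mats <- lapply(channels, function(ch) {
    bg <- if (length(render$background_level) > 1)
      render$background_level[[ch]] else render$background_level
    matrix(bg, nrow = shape[1], ncol = shape[2])
  })
  names(mats) <- channels

  truth <- NULL
  if (n > 0) {
    slots <- sample.int(prod(grid_dim), n)
    slot_row <- (slots - 1) %% grid_dim[1]
    slot_col <- (slots - 1) %/% grid_dim[1]
    cy <- (slot_row + 0.5) * pitch + stats::runif(n, -jitter_max, jitter_max)
    cx <- (slot_col + 0.5) * pitch + stats::runif(n, -jitter_max, jitter_max)

    radius <- pmin(pmax(stats::rnorm(n, r_mean, r_sd), 2), r_mean + 4 * r_sd) *
      population$dna_content^(1 / 3)
    is_m <- population$phase == "M"
    radius[is_m] <- radius[is_m] * sqrt(render$m_phase_shrink_factor)

    # rendered integer totals per channel (staining noise folded in)
    totals <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
    for (ch in channels) {
      tot <- if (ch == "hoechst") {
        population$sig_hoechst * population$nf_hoechst
      } else {
        base <- population[[paste0("sig_", ch)]]
        if (fixation == "direct" && ch %in% c("mcm2", "mcm3")) {
          base <- base + params$soluble_mcm_pool
        }
        base * population[[paste0("nf_", ch)]]
      }
      totals[, ch] <- round(tot)
    }

    area_px <- integer(n)
    for (i in seq_len(n)) {
      r <- radius[i]
      ri <- ceiling(r)
      rows <- max(1, round(cy[i]) - ri):min(shape[1], round(cy[i]) + ri)
      cols <- max(1, round(cx[i]) - ri):min(shape[2], round(cx[i]) + ri)
      dy <- rows - cy[i]
      dx <- cols - cx[i]
      inside <- outer(dy^2, dx^2, `+`) <= r^2
      n_px <- sum(inside)
      if (n_px == 0) next
      area_px[i] <- n_px
      for (ch in channels) {
        sub <- mats[[ch]][rows, cols]
        sub[inside] <- sub[inside] + disk_values(totals[i, ch], n_px)
        mats[[ch]][rows, cols] <- sub
      }
    }

    truth <- tibble::tibble(
      cell_id = population$cell_id,
      lineage_id = population$lineage_id,
      x = cx, y = cy, radius_px = radius, area_px = area_px,
      phase = population$phase,
      dna_content = population$dna_content,
      edu_label = population$edu_label,
      generation = population$generation,
      arrested = population$arrested,
      m_phase = is_m
    )
    for (ch in channels) truth[[paste0("total_", ch)]] <- totals[, ch]
    for (ch in setdiff(channels, "hoechst")) {
      truth[[paste0("sig_", ch)]] <- population[[paste0("sig_", ch)]]
    }
    truth$sig_hoechst <- population$sig_hoechst
  }

  if (render$read_noise_sigma > 0) {
    for (ch in channels) {
      mats[[ch]] <- mats[[ch]] +
        round(stats::rnorm(length(mats[[ch]]), 0, render$read_noise_sigma))
    }
  }
  for (ch in channels) {
    mats[[ch]][mats[[ch]] < 0] <- 0
    mats[[ch]][mats[[ch]] > 65535] <- 65535
  }

  image_stack(mats, truth = truth,
              meta = list(fixation = fixation, seed = render$seed,
                          pitch = pitch, render = unclass(render),
                          population_seed = params$seed,
                          scenario = params$scenario))
}

#' Write / read an image stack as multi-page TIFF with sidecars
#'
#' Pixels are written as one 16-bit TIFF page per channel; channel names and
#' provenance go to a JSON sidecar and the ground truth (if any) to a CSV.
#' Values are integer camera counts, so a write/read round trip is exact.
#'
#' @param stack A `cc_image_stack`.
#' @param basename Path prefix; writes `<basename>.tif`, `<basename>.json`
#'   and, when ground truth is present, `<basename>_truth.csv`.
#' @return `write_image_stack` returns `basename` invisibly;
#'   `read_image_stack` returns a `cc_image_stack`.
#' @export
write_image_stack <- function(stack, basename) {
  stopifnot(inherits(stack, "cc_image_stack"))
  pages <- lapply(stack$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, paste0(basename, ".tif"), bits.per.sample = 16L,
                  compression = "none")
  sidecar <- list(channels = names(stack$channels),
                  shape = dim(stack$channels[[1]]),
                  meta = stack$meta)
  jsonlite::write_json(sidecar, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(stack$truth)) {
    utils::write.csv(stack$truth, paste0(basename, "_truth.csv"),
                     row.names = FALSE)
  }
  invisible(basename)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(basename) {
  pages <- tiff::readTIFF(paste0(basename, ".tif"), all = TRUE)
  sidecar <- jsonlite::read_json(paste0(basename, ".json"),
                                 simplifyVector = TRUE)
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- sidecar$channels
  truth_path <- paste0(basename, "_truth.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- tibble::as_tibble(utils::read.csv(truth_path))
    truth$phase <- factor(truth$phase, levels = phase_levels)
  }
  image_stack(channels, truth = truth, meta = sidecar$meta)
}
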