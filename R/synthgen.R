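# Synthetic paired bright-field / fluorescence frame generator.
#
# Emulates post-enrichment blood-sample frames: a mid-gray bright-field
# background with additive noise, a radial vignette and a low-frequency
# "cloudy" field; round cells rendered as a dark rim with a brighter,
# textured interior (defocused bright-field appearance); occasional touching
# pairs, rare very-bright cells that defeat naive global thresholding, and
# small bright debris specks. Fluorescence ground truth: green blobs at WBC
# centers, red blobs at CTC centers, never both.

#' Synthetic generator configuration
#'
#' Defaults emulate 20x magnification frames: 480x640 pixels at 0.46 um/px,
#' so a mean 11.5 um cell spans ~25 px (~500 px area). Both classes share the
#' 11.5 um mean diameter; CTCs have the wider spread. Bright-field appearance
#' differs between classes in rim depth/width and interior texture -- the
#' label-free signal the classifier learns. Intensities are 8-bit [0, 255].
#'
#' @param shape frame shape, c(rows, cols).
#' @param pixel_scale_um micrometres per pixel.
#' @param background,noise_sd bright-field background level and Gaussian
#'   noise standard deviation (8-bit units).
#' @param vignette_strength fractional darkening at the frame corners.
#' @param cloud_amp amplitude of the smooth low-frequency background field.
#' @param wbc_diam_mean,wbc_diam_sd,ctc_diam_mean,ctc_diam_sd diameter
#'   distributions in micrometres (normal, truncated at `trunc_sigmas` sd).
#' @param trunc_sigmas truncation width for the diameter draws.
#' @param very_bright_frac fraction of cells rendered near saturation.
#' @param touching_frac fraction of cells placed as touching pairs.
#' @param min_spacing_px minimum center-to-center spacing for non-touching
#'   cells; `margin_px` keeps centers away from the frame border.
#' @param margin_px placement margin from the frame border, pixels.
#' @param n_debris,debris_intensity count and peak brightness of small debris
#'   specks (radius 1-3 px, area well below a quarter of a typical cell).
#' @param profiles per-class radial intensity profile parameters
#'   (`rim_depth`, `rim_width`, `interior_amp`, `halo_amp`, `texture_sd`);
#'   free appearance parameters, not a contract.
#' @param very_bright_level peak intensity of very-bright cells.
#' @param fluor_background,fluor_noise_sd,fluor_amp,fluor_sigma_frac
#'   fluorescence channel background, noise, blob amplitude and blob sigma as
#'   a fraction of the cell radius.
#' @return a named list of generator parameters.
#' @export
synth_config <- function(shape = c(480L, 640L),
                         pixel_scale_um = 0.46,
                         background = 140, noise_sd = 4,
                         vignette_strength = 0.15, cloud_amp = 6,
                         wbc_diam_mean = 11.5, wbc_diam_sd = 0.8,
                         ctc_diam_mean = 11.5, ctc_diam_sd = 1.8,
                         trunc_sigmas = 3,
                         very_bright_frac = 0.05, touching_frac = 0.10,
                         min_spacing_px = 26, margin_px = 32,
                         n_debris = 25, debris_intensity = 70,
                         profiles = list(
                           WBC = list(rim_depth = 45, rim_width = 2.0,
                                      interior_amp = 10, halo_amp = 8,
                                      texture_sd = 3),
                           CTC = list(rim_depth = 60, rim_width = 3.0,
                                      interior_amp = 22, halo_amp = 10,
                                      texture_sd = 10)),
                         very_bright_level = 250,
                         fluor_background = 8, fluor_noise_sd = 2,
                         fluor_amp = 140, fluor_sigma_frac = 0.5) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$shape) == 2, all(cfg$shape >= 64),
            cfg$pixel_scale_um > 0, cfg$touching_frac >= 0,
            cfg$very_bright_frac >= 0, cfg$very_bright_frac <= 1)
  cfg$shape <- as.integer(cfg$shape)
  cfg
}

rtrunc_norm <- function(n, mean, sd, trunc_sigmas) {
  out <- rnorm(n, mean, sd)
  bad <- abs(out - mean) > trunc_sigmas * sd
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(out - mean) > trunc_sigmas * sd
  }
  out
}

new_synth_cell <- function(class_label, center_rc, diameter_um, pixel_scale_um,
                           profile, is_very_bright) {
  structure(list(class_label = class_label,
                 center_rc = as.numeric(center_rc),
                 diameter_um = diameter_um,
                 diameter_px = diameter_um / pixel_scale_um,
                 intensity_profile = profile,
                 is_very_bright = is_very_bright),
            class = "synth_cell")
}

#' Sample a synthetic cell population
#'
#' Draws diameters per class (WBC: narrow; CTC: wide; equal 11.5 um means by
#' default), flags a configured fraction of cells as very bright, and places
#' cell centers in the frame by rejection sampling: non-touching cells
#' respect `min_spacing_px`, while a configured fraction are deliberately
#' placed as touching pairs to exercise the watershed stage.
#'
#' @param n_wbc,n_ctc number of cells per class.
#' @param params a [synth_config()] list.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return list of `synth_cell` records (WBCs first, then CTCs).
#' @export
sample_population <- function(n_wbc, n_ctc, params = synth_config(), seed = 1L) {
  stopifnot(n_wbc >= 0, n_ctc >= 0)
  n <- n_wbc + n_ctc
  if (n == 0) return(list())
  with_seed(seed, {
    classes <- c(rep("WBC", n_wbc), rep("CTC", n_ctc))
    diam <- numeric(n)
    if (n_wbc > 0)
      diam[classes == "WBC"] <- rtrunc_norm(n_wbc, params$wbc_diam_mean,
                                            params$wbc_diam_sd, params$trunc_sigmas)
    if (n_ctc > 0)
      diam[classes == "CTC"] <- rtrunc_norm(n_ctc, params$ctc_diam_mean,
                                            params$ctc_diam_sd, params$trunc_sigmas)
    very_bright <- runif(n) < params$very_bright_frac
    radii <- diam / params$pixel_scale_um / 2

    # per-cell profile: class template with +-10% jitter and a texture seed
    profiles <- lapply(seq_len(n), function(i) {
      tmpl <- params$profiles[[classes[i]]]
      jit <- function(x) x * runif(1, 0.9, 1.1)
      list(rim_depth = jit(tmpl$rim_depth), rim_width = jit(tmpl$rim_width),
           interior_amp = jit(tmpl$interior_amp), halo_amp = jit(tmpl$halo_amp),
           texture_sd = tmpl$texture_sd,
           texture_seed = sample.int(.Machine$integer.max %/% 2L, 1))
    })

    # touching pairs: partner cells are attached to an anchor at ~0.85 of the
    # sum of radii; everything else keeps the configured minimum spacing
    n_pairs <- floor(params$touching_frac * n / 2)
    partner_of <- rep(NA_integer_, n)
    if (n_pairs > 0) {
      pick <- sample.int(n, 2 * n_pairs)
      partner_of[pick[seq_len(n_pairs) * 2]] <- pick[seq_len(n_pairs) * 2 - 1]
    }

    nr <- params$shape[1]; nc <- params$shape[2]; m <- params$margin_px
    if (nr - 2 * m < 1 || nc - 2 * m < 1)
      stop_ctc("ctcscope_placement_error",
               "frame %dx%d cannot hold any cell with margin %d px", nr, nc, m)
    place_order <- c(which(is.na(partner_of)), which(!is.na(partner_of)))
    centers <- NULL
    for (restart in seq_len(5L)) {   # rare dead-ends restart the whole frame
      centers <- matrix(NA_real_, n, 2)
      failed <- FALSE
      for (i in place_order) {
        anchor <- partner_of[i]
        placed <- FALSE
        for (attempt in seq_len(4000L)) {
          if (!is.na(anchor)) {
            ang <- runif(1, 0, 2 * pi)
            d <- 0.85 * (radii[i] + radii[anchor])
            cand <- centers[anchor, ] + d * c(sin(ang), cos(ang))
            if (cand[1] < m || cand[1] > nr - 1 - m ||
                cand[2] < m || cand[2] > nc - 1 - m) next
          } else {
            cand <- c(runif(1, m, nr - 1 - m), runif(1, m, nc - 1 - m))
          }
          others <- which(!is.na(centers[, 1]))
          others <- setdiff(others, anchor)
          ok <- TRUE
          if (length(others)) {
            dd <- sqrt((centers[others, 1] - cand[1])^2 +
                       (centers[others, 2] - cand[2])^2)
            lim <- if (is.na(anchor)) params$min_spacing_px
                   else 0.8 * params$min_spacing_px
            ok <- all(dd >= lim)
          }
          if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
        }
        if (!placed) { failed <- TRUE; break }
      }
      if (!failed) break
      if (restart == 5L)
        stop_ctc("ctcscope_placement_error",
                 paste0("could not place %d cells in a %dx%d frame with ",
                        "min spacing %g px and margin %d px"),
                 n, nr, nc, params$min_spacing_px, m)
    }

    lapply(seq_len(n), function(i)
      new_synth_cell(classes[i], centers[i, ], diam[i], params$pixel_scale_um,
                     profiles[[i]], very_bright[i]))
  })
}

# radial bright-field profile of one cell, added onto the canvas window
render_cell_patch <- function(cell, params, d) {
  p <- cell$intensity_profile
  R <- cell$diameter_px / 2
  rim <- -p$rim_depth * exp(-((d - R) / p$rim_width)^2)
  if (isTRUE(cell$is_very_bright)) {
    interior <- (params$very_bright_level - params$background) *
      exp(-(d / (0.8 * R))^4)
    return(rim + interior)
  }
  interior <- p$interior_amp / (1 + exp((d - 0.7 * R) / 1.5))
  halo <- p$halo_amp * exp(-((d - R - 2.5) / 2)^2)
  patch <- rim + interior + halo
  if (p$texture_sd > 0) {
    tex <- with_seed(p$texture_seed,
                     gaussian_smooth(matrix(rnorm(length(d), 0, p$texture_sd),
                                            nrow(d)), 0.8))
    patch <- patch + tex * (d < 0.8 * R)
  }
  patch
}

add_blob <- function(img, center, amp, sigma, power = 2) {
  nr <- nrow(img); nc <- ncol(img)
  rad <- ceiling(3.5 * sigma)
  r0 <- max(1, round(center[1]) + 1 - rad); r1 <- min(nr, round(center[1]) + 1 + rad)
  c0 <- max(1, round(center[2]) + 1 - rad); c1 <- min(nc, round(center[2]) + 1 + rad)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - 1 - center[1])^2, (cc - 1 - center[2])^2, "+"))
  img[rr, cc] <- img[rr, cc] + amp * exp(-(d / sigma)^power)
  img
}

#' Render a paired bright-field / fluorescence frame
#'
#' Bright field: background + low-frequency cloud + radial vignette +
#' per-cell radial profiles (dark rim, brighter textured interior;
#' very-bright cells near saturation) + debris specks + Gaussian noise,
#' clipped and rounded to 8-bit. Fluorescence: a Gaussian blob at each cell
#' center in the channel matching its class only (green = WBC, red = CTC).
#'
#' @param cells list of `synth_cell` (e.g. from [sample_population()]).
#' @param params a [synth_config()] list.
#' @param seed integer seed; rendering is deterministic given cells and seed.
#' @return a `field_pair`: list with integer-valued matrices `bright`,
#'   `fluor_green`, `fluor_red`, plus `cells`, `pixel_scale_um`, `seed`.
#' @export
render_pair <- function(cells, params = synth_config(), seed = 1L) {
  nr <- params$shape[1]; nc <- params$shape[2]
  for (cell in cells) {
    ctr <- cell$center_rc
    if (ctr[1] < 0 || ctr[1] > nr - 1 || ctr[2] < 0 || ctr[2] > nc - 1)
      stop_ctc("ctcscope_placement_error", "cell center (%g, %g) outside frame",
               ctr[1], ctr[2])
  }
  with_seed(seed, {
    # low-frequency cloudy background: coarse noise grid upsampled bilinearly
    coarse <- matrix(rnorm(8 * 10), 8, 10)
    rr <- (seq_len(nr) - 1) / (nr - 1) * 7
    cc <- (seq_len(nc) - 1) / (nc - 1) * 9
    cloud <- params$cloud_amp *
      matrix(bilinear_sample(coarse, rep(rr, times = nc), rep(cc, each = nr)), nr, nc)

    # radial vignette, darkening toward borders/corners
    dr2 <- ((seq_len(nr) - 1) - (nr - 1) / 2)^2
    dc2 <- ((seq_len(nc) - 1) - (nc - 1) / 2)^2
    rad2 <- outer(dr2, dc2, "+") / ((nr - 1)^2 / 4 + (nc - 1)^2 / 4)
    vign <- 1 - params$vignette_strength * rad2

    bright <- (params$background + cloud) * vign

    for (cell in cells) {
      R <- cell$diameter_px / 2
      win <- ceiling(R + 8)
      ctr <- cell$center_rc
      r0 <- max(1, round(ctr[1]) + 1 - win); r1 <- min(nr, round(ctr[1]) + 1 + win)
      c0 <- max(1, round(ctr[2]) + 1 - win); c1 <- min(nc, round(ctr[2]) + 1 + win)
      ri <- r0:r1; ci <- c0:c1
      d <- sqrt(outer((ri - 1 - ctr[1])^2, (ci - 1 - ctr[2])^2, "+"))
      bright[ri, ci] <- bright[ri, ci] + render_cell_patch(cell, params, d)
    }

    if (params$n_debris > 0) {
      for (k in seq_len(params$n_debris)) {
        pos <- c(runif(1, 2, nr - 3), runif(1, 2, nc - 3))
        bright <- add_blob(bright, pos, params$debris_intensity, runif(1, 1, 3))
      }
    }

    bright <- bright + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
    bright <- matrix(pmin(pmax(round(bright), 0), 255), nr, nc)

    make_fluor <- function(target_class) {
      ch <- matrix(params$fluor_background, nr, nc) +
        matrix(rnorm(nr * nc, 0, params$fluor_noise_sd), nr, nc)
      for (cell in cells) {
        if (cell$class_label != target_class) next
        ch <- add_blob(ch, cell$center_rc, params$fluor_amp,
                       params$fluor_sigma_frac * cell$diameter_px / 2)
      }
      matrix(pmin(pmax(round(ch), 0), 255), nr, nc)
    }
    fg <- make_fluor("WBC")
    fr <- make_fluor("CTC")

    structure(list(bright = bright, fluor_green = fg, fluor_red = fr,
                   cells = cells, pixel_scale_um = params$pixel_scale_um,
                   seed = as.integer(seed)),
              class = "field_pair")
  })
}

write_gray_png <- function(img, path) {
  png::writePNG(img / 255, path)
}

read_gray_png <- function(path) {
  if (!file.exists(path))
    stop_ctc("ctcscope_io_error", "missing image file: %s", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(round(x * 255), nrow(x), ncol(x))
}

#' Write / read a field pair on disk
#'
#' The pair is stored as three 8-bit grayscale PNGs (`bright.png`,
#' `fluor_green.png`, `fluor_red.png`), a ground-truth CSV `cells.csv` with
#' header `class,row,col,diameter_um`, and a JSON `manifest.json` carrying
#' the pixel scale, seed, shape and the remaining per-cell fields so that
#' `read_pair(write_pair(p))` restores images bit-exactly and cell records
#' field-exactly.
#'
#' @param pair a `field_pair`.
#' @param dir output directory (created if needed).
#' @return `write_pair` returns the manifest path; `read_pair` the pair.
#' @export
write_pair <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gray_png(pair$bright, file.path(dir, "bright.png"))
  write_gray_png(pair$fluor_green, file.path(dir, "fluor_green.png"))
  write_gray_png(pair$fluor_red, file.path(dir, "fluor_red.png"))
  cells_df <- data.frame(
    class = vapply(pair$cells, `[[`, "", "class_label"),
    row = vapply(pair$cells, function(s) s$center_rc[1], 0),
    col = vapply(pair$cells, function(s) s$center_rc[2], 0),
    diameter_um = vapply(pair$cells, `[[`, 0, "diameter_um"))
  write.csv(cells_df, file.path(dir, "cells.csv"), row.names = FALSE)
  manifest <- list(
    pixel_scale_um = pair$pixel_scale_um, seed = pair$seed,
    shape = dim(pair$bright),
    files = list(bright = "bright.png", fluor_green = "fluor_green.png",
                 fluor_red = "fluor_red.png", cells = "cells.csv"),
    cell_extra = lapply(pair$cells, function(s)
      list(is_very_bright = s$is_very_bright,
           intensity_profile = s$intensity_profile)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pair
#' @export
read_pair <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop_ctc("ctcscope_io_error", "missing manifest.json in %s", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  imgs <- lapply(c("bright", "fluor_green", "fluor_red"), function(nm) {
    read_gray_png(file.path(dir, man$files[[nm]]))
  })
  names(imgs) <- c("bright", "fluor_green", "fluor_red")
  shp <- vapply(imgs, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop_ctc("ctcscope_format_error", "channel shapes differ: %s",
             paste(apply(shp, 2, paste, collapse = "x"), collapse = ", "))
  cpath <- file.path(dir, man$files$cells)
  if (!file.exists(cpath))
    stop_ctc("ctcscope_io_error", "missing ground-truth file: %s", cpath)
  df <- read.csv(cpath, stringsAsFactors = FALSE)
  need <- c("class", "row", "col", "diameter_um")
  if (!all(need %in% names(df)))
    stop_ctc("ctcscope_format_error", "cells.csv must have header %s",
             paste(need, collapse = ","))
  scale <- man$pixel_scale_um
  cells <- lapply(seq_len(nrow(df)), function(i) {
    extra <- man$cell_extra[[i]]
    prof <- lapply(extra$intensity_profile, function(v) v)
    new_synth_cell(df$class[i], c(df$row[i], df$col[i]), df$diameter_um[i],
                   scale, prof, isTRUE(extra$is_very_bright))
  })
  structure(list(bright = imgs$bright, fluor_green = imgs$fluor_green,
                 fluor_red = imgs$fluor_red, cells = cells,
                 pixel_scale_um = scale, seed = as.integer(man$seed)),
            class = "field_pair")
}
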