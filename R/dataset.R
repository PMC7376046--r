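# Single-cell dataset construction: cropping, fluorescence label transfer,
# quality filtering (an automated surrogate for manual single-cell
# selection), per-crop normalization, and geometric augmentation.

new_cell_crop <- function(crop_id, pixels, source_frame, centroid_rc,
                          label = "UNLABELED", origin_id = crop_id,
                          transform_desc = "identity", frame_shape = NULL,
                          normalized = FALSE) {
  structure(list(crop_id = crop_id, pixels = pixels,
                 source_frame = source_frame,
                 centroid_rc = as.numeric(centroid_rc),
                 label = label, origin_id = origin_id,
                 transform_desc = transform_desc,
                 frame_shape = frame_shape, normalized = normalized),
            class = "cell_crop")
}

crop_label <- function(crop) crop$label
crop_labels <- function(crops) vapply(crops, `[[`, "", "label")
origin_ids <- function(crops) vapply(crops, `[[`, "", "origin_id")

#' Crop single-cell patches around region centroids
#'
#' Each region yields a `side` x `side` patch centered at the rounded
#' centroid (`round(centroid) - floor(side / 2)` is the first row/col).
#' Patches reaching past the frame are padded by edge replication. The
#' source centroid coordinates are recorded verbatim on each crop so a
#' per-frame count report can place predictions back in the frame.
#'
#' @param bright intensity matrix.
#' @param regions list of `cell_region` from [extract_regions()].
#' @param side patch side in pixels (default 30).
#' @param frame_id identifier recorded as the crop's source frame.
#' @return list of `cell_crop`, one per region, order preserved.
#' @export
crop_cells <- function(bright, regions, side = 30L, frame_id = "frame") {
  stopifnot(side >= 1)
  side <- as.integer(side)
  nr <- nrow(bright); nc <- ncol(bright)
  lapply(seq_along(regions), function(i) {
    ctr <- regions[[i]]$centroid_rc
    r0 <- round(ctr[1]) - side %/% 2L   # 0-based first row
    c0 <- round(ctr[2]) - side %/% 2L
    rows <- pmin(pmax(r0 + seq_len(side) - 1L, 0L), nr - 1L) + 1L
    cols <- pmin(pmax(c0 + seq_len(side) - 1L, 0L), nc - 1L) + 1L
    new_cell_crop(crop_id = sprintf("%s_r%03d", frame_id, i),
                  pixels = bright[rows, cols, drop = FALSE],
                  source_frame = frame_id, centroid_rc = ctr,
                  frame_shape = c(nr, nc))
  })
}

#' Transfer class labels from paired fluorescence channels
#'
#' For each crop, the mean signal in a disk of radius `side / 4` around the
#' centroid is compared to the frame background (channel median), scaled by
#' the channel's robust noise (MAD). A crop is labelled WBC when the green
#' SNR reaches `min_snr` and green exceeds red, CTC in the symmetric case,
#' and UNLABELED otherwise (including exact ties).
#'
#' @param crops list of `cell_crop`.
#' @param fluor_green,fluor_red fluorescence matrices, same shape as the
#'   source frame.
#' @param min_snr minimum signal-to-noise ratio to accept a label.
#' @return the crops with `label` filled in.
#' @export
transfer_labels <- function(crops, fluor_green, fluor_red, min_snr = 3) {
  if (!length(crops)) return(crops)
  shp <- crops[[1]]$frame_shape
  if (!is.null(shp) &&
      (!all(dim(fluor_green) == shp) || !all(dim(fluor_red) == shp)))
    stop_ctc("ctcscope_format_error",
             "fluorescence shape does not match source frame %dx%d",
             shp[1], shp[2])
  if (!all(dim(fluor_green) == dim(fluor_red)))
    stop_ctc("ctcscope_format_error", "fluorescence channel shapes differ")
  chan_stats <- function(ch) {
    v <- as.numeric(ch)
    noise <- stats::mad(v)
    if (noise == 0) noise <- max(sd(v), 1e-8)
    list(bg = median(v), noise = noise)
  }
  gs <- chan_stats(fluor_green); rs <- chan_stats(fluor_red)
  side <- nrow(crops[[1]]$pixels)
  rad <- side / 4
  nr <- nrow(fluor_green); nc <- ncol(fluor_green)
  disk_mean <- function(ch, ctr) {
    rr <- max(1, floor(ctr[1] + 1 - rad)):min(nr, ceiling(ctr[1] + 1 + rad))
    cc <- max(1, floor(ctr[2] + 1 - rad)):min(nc, ceiling(ctr[2] + 1 + rad))
    d <- sqrt(outer((rr - 1 - ctr[1])^2, (cc - 1 - ctr[2])^2, "+"))
    mean(ch[rr, cc][d <= rad])
  }
  lapply(crops, function(cr) {
    g_snr <- (disk_mean(fluor_green, cr$centroid_rc) - gs$bg) / gs$noise
    r_snr <- (disk_mean(fluor_red, cr$centroid_rc) - rs$bg) / rs$noise
    cr$label <- if (g_snr >= min_snr && g_snr > r_snr) "WBC"
      else if (r_snr >= min_snr && r_snr > g_snr) "CTC"
      else "UNLABELED"
    cr
  })
}

#' Quality rules for automated single-cell selection
#'
#' Replaces the manual selection of clean single-cell images with explicit,
#' reproducible rules on region shape and context.
#'
#' @param min_area_px,max_area_px region area bounds.
#' @param min_solidity minimum solidity (round single cells are near 1).
#' @param max_eccentricity maximum eccentricity (rejects merged/elongated
#'   blobs).
#' @param border_margin_px minimum centroid distance from the frame border.
#' @param max_overlap maximum fraction of a region's bounding box covered by
#'   any other region's bounding box.
#' @return named rule list.
#' @export
quality_rules <- function(min_area_px = 120, max_area_px = 2000,
                          min_solidity = 0.85, max_eccentricity = 0.8,
                          border_margin_px = 16, max_overlap = 0.3) {
  rules <- as.list(environment())
  stopifnot(all(vapply(rules, is.finite, TRUE)))
  rules
}

#' Filter crops on region quality
#'
#' Applies the rules in order (area, solidity, eccentricity, margin,
#' overlap); a rejected crop carries the first failed rule's name.
#'
#' @param crops,regions aligned 1:1 ([crop_cells()] output and its regions).
#' @param rules a [quality_rules()] list.
#' @return list with `kept` (crops), `kept_regions`, and `rejected`
#'   (list of `list(crop, reason)`).
#' @export
quality_filter <- function(crops, regions, rules = quality_rules()) {
  stopifnot(length(crops) == length(regions))
  n <- length(crops)
  bboxes <- lapply(regions, `[[`, "bbox")
  reason <- character(n)
  for (i in seq_len(n)) {
    rg <- regions[[i]]; cr <- crops[[i]]
    shp <- cr$frame_shape
    m <- rules$border_margin_px
    reason[i] <-
      if (rg$area_px < rules$min_area_px || rg$area_px > rules$max_area_px) "area"
      else if (rg$solidity < rules$min_solidity) "solidity"
      else if (rg$eccentricity > rules$max_eccentricity) "eccentricity"
      else if (!is.null(shp) &&
               (rg$centroid_rc[1] < m || rg$centroid_rc[1] > shp[1] - 1 - m ||
                rg$centroid_rc[2] < m || rg$centroid_rc[2] > shp[2] - 1 - m)) "margin"
      else {
        own <- (bboxes[[i]][3] - bboxes[[i]][1]) * (bboxes[[i]][4] - bboxes[[i]][2])
        ov <- 0
        for (j in seq_len(n)) if (j != i)
          ov <- max(ov, bbox_intersection(bboxes[[i]], bboxes[[j]]) / own)
        if (ov > rules$max_overlap) "overlap" else ""
      }
  }
  keep <- reason == ""
  list(kept = crops[keep], kept_regions = regions[keep],
       rejected = Map(function(cr, rs) list(crop = cr, reason = rs),
                      crops[!keep], reason[!keep]))
}

# least-squares plane over the outer `ring` border pixels, evaluated on the
# whole patch; the fit includes a constant term, making the residual operator
# a projection (normalize_crop is exactly idempotent as a consequence)
fit_border_plane <- function(p, ring = 3L) {
  s <- nrow(p)
  rr <- matrix(rep(seq_len(s) - 1, ncol(p)), s)
  cc <- matrix(rep(seq_len(s) - 1, each = nrow(p)), s)
  border <- rr < ring | rr >= s - ring | cc < ring | cc >= ncol(p) - ring
  X <- cbind(1, rr[border], cc[border])
  beta <- qr.coef(qr(X), p[border])
  beta[is.na(beta)] <- 0
  beta[1] + beta[2] * rr + beta[3] * cc
}

#' Normalize a single-cell crop
#'
#' Removes the local background tilt by fitting a least-squares plane to the
#' crop's outer 3-pixel border ring and subtracting it everywhere (a cell
#' near the well edge sits on a sloped, cloudy background), then
#' standardizes the patch to mean 0, standard deviation 1. The operator is
#' idempotent.
#'
#' @param crop a `cell_crop`.
#' @return the crop with real-valued normalized pixels.
#' @export
normalize_crop <- function(crop) {
  p <- crop$pixels
  if (sd(p) == 0)
    stop_ctc("ctcscope_degenerate_error",
             "constant patch cannot be normalized (crop %s)", crop$crop_id)
  resid <- p - fit_border_plane(p)
  s <- sd(resid)
  if (s < 1e-12)
    stop_ctc("ctcscope_degenerate_error",
             "patch is an exact background plane; zero variance after removal (crop %s)",
             crop$crop_id)
  crop$pixels <- (resid - mean(resid)) / s
  crop$normalized <- TRUE
  crop
}

#' Augmentation specification
#'
#' @param target_per_class number of crops per class after augmentation
#'   (default 1000, i.e. 1000 CTCs + 1000 WBCs).
#' @param rotation_range_deg rotations drawn uniformly in +- this range.
#' @param shear_range shear factors drawn uniformly in +- this range.
#' @param allow_hflip,allow_vflip enable horizontal/vertical reflection.
#' @param seed integer seed.
#' @return named list.
#' @export
augment_spec <- function(target_per_class = 1000L, rotation_range_deg = 180,
                         shear_range = 0.2, allow_hflip = TRUE,
                         allow_vflip = TRUE, seed = 1L) {
  stopifnot(target_per_class >= 1)
  list(target_per_class = as.integer(target_per_class),
       rotation_range_deg = rotation_range_deg, shear_range = shear_range,
       allow_hflip = allow_hflip, allow_vflip = allow_vflip,
       seed = as.integer(seed))
}

# affine resample of a square patch about its center; bilinear, edge clamp
affine_patch <- function(p, rot_deg, shear, hflip, vflip) {
  s <- nrow(p)
  ctr <- (s - 1) / 2
  th <- rot_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  S <- matrix(c(1, 0, shear, 1), 2)
  F <- diag(c(if (vflip) -1 else 1, if (hflip) -1 else 1))
  M <- R %*% S %*% F
  Minv <- solve(M)
  u <- rep(seq_len(s) - 1 - ctr, times = s)     # output row offsets
  v <- rep(seq_len(s) - 1 - ctr, each = s)      # output col offsets
  src <- Minv %*% rbind(u, v)
  matrix(bilinear_sample(p, src[1, ] + ctr, src[2, ] + ctr), s, s)
}

#' Geometric augmentation to a fixed per-class count
#'
#' Expands a labeled crop set to exactly `target_per_class` crops per class
#' using rotation, shear and horizontal/vertical reflection. Original crops
#' are included first; the remainder are synthesized by sampling a source
#' crop uniformly with replacement and applying a random transform within
#' the ranges in `spec` (bilinear interpolation, edge padding). Every synthesized
#' crop's `origin_id` points to its source original, which is what the
#' cross-validation harness partitions on to rule out leakage.
#'
#' @param crops labeled `cell_crop`s (no UNLABELED).
#' @param spec an [augment_spec()].
#' @return list of crops: `target_per_class` per class, originals first
#'   within each class (WBC block, then CTC block).
#' @export
augment_crops <- function(crops, spec = augment_spec()) {
  labs <- crop_labels(crops)
  if (any(labs == "UNLABELED"))
    stop_ctc("ctcscope_class_coverage_error",
             "augmentation input contains UNLABELED crops")
  out <- list()
  with_seed(spec$seed, {
    for (cls in CLASS_LEVELS) {
      src <- crops[labs == cls]
      if (!length(src))
        stop_ctc("ctcscope_class_coverage_error",
                 "class %s has no source crops to augment", cls)
      n_orig <- min(length(src), spec$target_per_class)
      block <- src[seq_len(n_orig)]
      n_new <- spec$target_per_class - n_orig
      if (n_new > 0) {
        pick <- sample.int(length(src), n_new, replace = TRUE)
        rot <- runif(n_new, -spec$rotation_range_deg, spec$rotation_range_deg)
        shr <- runif(n_new, -spec$shear_range, spec$shear_range)
        hf <- if (spec$allow_hflip) runif(n_new) < 0.5 else rep(FALSE, n_new)
        vf <- if (spec$allow_vflip) runif(n_new) < 0.5 else rep(FALSE, n_new)
        for (j in seq_len(n_new)) {
          s0 <- src[[pick[j]]]
          desc <- sprintf("rot=%.3f;shear=%.4f;hflip=%d;vflip=%d",
                          rot[j], shr[j], hf[j], vf[j])
          block[[n_orig + j]] <- new_cell_crop(
            crop_id = sprintf("aug_%s_%04d", cls, j),
            pixels = affine_patch(s0$pixels, rot[j], shr[j], hf[j], vf[j]),
            source_frame = s0$source_frame, centroid_rc = s0$centroid_rc,
            label = cls, origin_id = s0$origin_id, transform_desc = desc,
            frame_shape = s0$frame_shape, normalized = s0$normalized)
        }
      }
      out <- c(out, block)
    }
  })
  out
}

#' Write / read a crop store
#'
#' One grayscale PNG per crop (normalized crops are min-max scaled for
#' storage; raw values live in the index only through provenance) plus a CSV
#' index `crops.csv` with columns
#' `crop_id,frame,row,col,label,origin_id,transform`.
#'
#' @param crops list of `cell_crop`.
#' @param dir output directory.
#' @return invisibly, the index path.
#' @export
write_crops <- function(crops, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(
    crop_id = vapply(crops, `[[`, "", "crop_id"),
    frame = vapply(crops, `[[`, "", "source_frame"),
    row = vapply(crops, function(x) x$centroid_rc[1], 0),
    col = vapply(crops, function(x) x$centroid_rc[2], 0),
    label = crop_labels(crops),
    origin_id = origin_ids(crops),
    transform = vapply(crops, `[[`, "", "transform_desc"))
  for (cr in crops) {
    p <- cr$pixels
    rng <- range(p)
    p01 <- if (diff(rng) > 0) (p - rng[1]) / diff(rng) else p * 0
    png::writePNG(p01, file.path(dir, paste0(cr$crop_id, ".png")))
  }
  path <- file.path(dir, "crops.csv")
  write.csv(idx, path, row.names = FALSE)
  invisible(path)
}
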