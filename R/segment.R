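# Bright-field segmentation: brightness cap -> Otsu edge detection ->
# hole filling -> morphological opening + area filter -> marker-based
# watershed -> region measurement.

#' Segmentation parameters
#'
#' @param brightness_cap_percentile percentile (50, 100] used by
#'   [cap_brightness()]; intensities above it are clipped so that rare
#'   very-bright cells cannot pull the Otsu threshold away from the
#'   cell/background boundary.
#' @param open_radius_px disk radius of the morphological opening; also the
#'   merge radius for watershed markers.
#' @param min_area_px,max_area_px retained region area bounds
#'   (defaults bracket a ~500 px cell by roughly 0.25x-4x).
#' @param watershed_smoothing_sigma Gaussian sigma (pixels) used both for the
#'   pre-gradient smoothing and for smoothing the distance transform.
#' @param connectivity pixel connectivity, 4 or 8.
#' @param edge_mode `"gradient"` (Otsu on the smoothed gradient magnitude;
#'   default) or `"intensity"` (Otsu directly on intensities, keeping the
#'   below-threshold dark pixels) as a fallback.
#' @return named parameter list.
#' @export
segment_params <- function(brightness_cap_percentile = 99.5,
                           open_radius_px = 2L,
                           min_area_px = 120L, max_area_px = 2000L,
                           watershed_smoothing_sigma = 1.5,
                           connectivity = 8L,
                           edge_mode = c("gradient", "intensity")) {
  edge_mode <- match.arg(edge_mode)
  stopifnot(min_area_px < max_area_px, open_radius_px >= 1,
            connectivity %in% c(4L, 8L))
  list(brightness_cap_percentile = brightness_cap_percentile,
       open_radius_px = as.integer(open_radius_px),
       min_area_px = as.integer(min_area_px),
       max_area_px = as.integer(max_area_px),
       watershed_smoothing_sigma = watershed_smoothing_sigma,
       connectivity = as.integer(connectivity),
       edge_mode = edge_mode)
}

#' Clip intensities above a percentile
#'
#' Replaces the manual brightness adjustment used to stop very bright cells
#' from dominating Otsu thresholding: every intensity above the given
#' percentile of the frame (inverse-ECDF definition) is clipped to that
#' percentile value; all other pixels are untouched.
#'
#' @param bright intensity matrix.
#' @param percentile percentile in (50, 100].
#' @return matrix of the same shape.
#' @export
cap_brightness <- function(bright, percentile = 99.5) {
  if (length(bright) == 0) stop_ctc("ctcscope_parameter_error", "empty image")
  if (percentile <= 50 || percentile > 100)
    stop_ctc("ctcscope_parameter_error",
             "percentile must be in (50, 100], got %g", percentile)
  cap <- unname(quantile(as.numeric(bright), percentile / 100, type = 1))
  pmin(bright, cap)
}

#' Otsu threshold over a 256-bin histogram
#'
#' Finds the threshold t maximizing the between-class variance of the 256-bin
#' intensity histogram (values binned to 0..255 after clamping). Pixels with
#' value > t are "above". Ties break toward the lower threshold.
#'
#' @param values numeric vector of intensities.
#' @return threshold intensity (a bin value in 0..254).
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop_ctc("ctcscope_parameter_error", "empty sample")
  bins <- pmin(pmax(floor(values), 0), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  if (sum(h > 0) < 2)
    stop_ctc("ctcscope_degenerate_error",
             "degenerate histogram: all values in one bin; no Otsu threshold")
  p <- h / sum(h)
  levs <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * levs)
  mt <- m0[256]
  t_cand <- 1:255                       # threshold t = levs[t_cand]
  w <- w0[t_cand]; m <- m0[t_cand]
  valid <- w > 0 & w < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mt * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
  levs[which.max(sigma_b)]              # which.max takes the first (lower) tie
}

gradient_magnitude <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (x[3:nr, ] - x[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (x[, 3:nc] - x[, 1:(nc - 2)]) / 2
  sqrt(gr^2 + gc^2)
}

#' Edge mask via Otsu on the smoothed gradient magnitude
#'
#' Smooths the (capped) frame, computes the central-difference gradient
#' magnitude, rescales it to 0..255 and keeps pixels above the Otsu
#' threshold. Cell rims produce closed rings that the subsequent hole
#' filling turns into solid blobs.
#'
#' @param bright intensity matrix (after [cap_brightness()]).
#' @param params [segment_params()].
#' @return logical mask of the same shape.
#' @export
edge_mask <- function(bright, params = segment_params()) {
  if (length(bright) == 0) stop_ctc("ctcscope_parameter_error", "empty image")
  sm <- gaussian_smooth(bright, params$watershed_smoothing_sigma)
  if (params$edge_mode == "intensity") {
    t <- otsu_threshold(sm)
    return(sm <= t)
  }
  g <- gradient_magnitude(sm)
  gmax <- max(g)
  if (gmax <= 0)
    stop_ctc("ctcscope_degenerate_error",
             "degenerate histogram: flat image has no gradient edges")
  gs <- g / gmax * 255
  t <- otsu_threshold(gs)
  gs > t
}

cc_label <- function(mask, connectivity = 8L) {
  .cc_label_cpp(mask, as.integer(connectivity))
}

#' Fill enclosed holes in a binary mask
#'
#' Background components not connected (under the given connectivity) to the
#' image border become foreground; border-connected background is untouched
#' and foreground is never removed.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
fill_holes <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "logical"
  bg <- cc_label(!mask, connectivity)
  nr <- nrow(mask); nc <- ncol(mask)
  border_labels <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

disk_offsets <- function(radius) {
  r <- as.integer(radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off[off$dr^2 + off$dc^2 <= radius^2, , drop = FALSE]
}

shift_mask <- function(mask, dr, dc, fill = FALSE) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- mask[rs - dr, cs - dc]
  out
}

binary_erode <- function(mask, offsets) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift_mask(mask, offsets$dr[i], offsets$dc[i], fill = FALSE)
  out
}

binary_dilate <- function(mask, offsets) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift_mask(mask, offsets$dr[i], offsets$dc[i], fill = FALSE)
  out
}

#' Morphological opening and area filtering
#'
#' Opens the mask with a disk of radius `open_radius_px` (erosion then
#' dilation with the explicit offset set \eqn{dr^2 + dc^2 \le r^2}; pixels
#' outside the frame count as background), then removes connected components
#' whose area falls outside `[min_area_px, max_area_px]`.
#'
#' @param mask logical matrix.
#' @param params [segment_params()].
#' @return logical matrix.
#' @export
open_and_filter <- function(mask, params = segment_params()) {
  storage.mode(mask) <- "logical"
  off <- disk_offsets(params$open_radius_px)
  opened <- binary_dilate(binary_erode(mask, off), off)
  lab <- cc_label(opened, params$connectivity)
  n <- attr(lab, "n")
  if (n == 0) return(opened)
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= params$min_area_px & areas <= params$max_area_px)
  opened & (lab %in% keep)
}

new_label_map <- function(labels, n_regions, connectivity) {
  structure(list(labels = labels, n_regions = as.integer(n_regions),
                 connectivity = as.integer(connectivity)),
            class = "label_map")
}

#' Split a mask into cells with a marker-based watershed
#'
#' Markers are the regional maxima of the Gaussian-smoothed Euclidean
#' distance transform of the mask; maxima closer than `open_radius_px` are
#' merged (the deeper one wins). The negated distance surface is then flooded
#' from the markers, restricted to the mask, so touching cells split along
#' the distance valley between them. Boundary ties go to the lower label id.
#'
#' @param mask logical matrix.
#' @param params [segment_params()].
#' @return a `label_map`: integer matrix `labels` (0 = background) plus
#'   `n_regions`.
#' @export
watershed_split <- function(mask, params = segment_params()) {
  storage.mode(mask) <- "logical"
  if (!any(mask))
    return(new_label_map(matrix(0L, nrow(mask), ncol(mask)), 0L,
                         params$connectivity))
  d <- unclass(EBImage::distmap(matrix(as.numeric(mask), nrow(mask))))
  ds <- gaussian_smooth(d, params$watershed_smoothing_sigma)
  ds[!mask] <- 0

  # regional maxima of the smoothed distance (8-neighbourhood, plateaus kept)
  is_max <- matrix(TRUE, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ds >= shift_mask_num(ds, dr, dc, fill = -Inf))
  }
  is_max <- is_max & mask
  plat <- cc_label(is_max, 8L)
  n_cand <- attr(plat, "n")
  if (n_cand == 0) {  # can happen only for pathological masks; one marker
    idx <- which(mask)[which.max(ds[mask])]
    markers <- matrix(0L, nrow(mask), ncol(mask)); markers[idx] <- 1L
  } else {
    cand <- data.frame(id = integer(n_cand), r = numeric(n_cand),
                       c = numeric(n_cand), depth = numeric(n_cand))
    for (i in seq_len(n_cand)) {
      px <- which(plat == i, arr.ind = TRUE)
      j <- which.max(ds[px])
      cand$r[i] <- px[j, 1]; cand$c[i] <- px[j, 2]
      cand$depth[i] <- ds[px[j, 1], px[j, 2]]
    }
    # merge maxima closer than the opening radius; deeper marker survives
    ord <- order(-cand$depth, cand$r, cand$c)
    kept <- integer(0)
    for (i in ord) {
      if (length(kept)) {
        dd <- sqrt((cand$r[kept] - cand$r[i])^2 + (cand$c[kept] - cand$c[i])^2)
        if (any(dd < params$open_radius_px)) next
      }
      kept <- c(kept, i)
    }
    kept <- kept[order(cand$r[kept], cand$c[kept])]
    markers <- matrix(0L, nrow(mask), ncol(mask))
    markers[cbind(cand$r[kept], cand$c[kept])] <- seq_along(kept)
  }
  labs <- .marker_flood_cpp(-ds, markers, mask, params$connectivity)
  new_label_map(labs, max(markers), params$connectivity)
}

shift_mask_num <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

# lattice points inside-or-on the convex hull of a pixel set (Pick's theorem)
convex_pixel_area <- function(rc) {
  n <- nrow(rc)
  if (n < 3) return(n)
  h <- chull(rc[, 2], rc[, 1])
  hull <- rc[h, , drop = FALSE]
  if (nrow(hull) < 3) return(n)
  r <- hull[, 1]; c <- hull[, 2]
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  A <- abs(sum(c * r2 - c2 * r)) / 2
  B <- sum(mapply(function(dr, dc) {
    if (dr == 0 && dc == 0) 0 else gcd_int(abs(dr), abs(dc))
  }, r2 - r, c2 - c))
  if (A == 0) return(n)
  A + B / 2 + 1
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Measure labelled regions
#'
#' @param labels a `label_map` from [watershed_split()].
#' @return list of `cell_region` records ordered by region id: centroid
#'   (0-based row/col), half-open bounding box `c(r0, c0, r1, c1)`, area in
#'   pixels, solidity (area over convex-hull pixel count) and eccentricity
#'   (from second central moments).
#' @export
extract_regions <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  n <- labels$n_regions
  if (n == 0) return(list())
  out <- vector("list", n)
  px_all <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[px_all]
  for (i in seq_len(n)) {
    px <- px_all[ids == i, , drop = FALSE]
    r0 <- px[, 1] - 1; c0 <- px[, 2] - 1    # 0-based coordinates
    area <- nrow(px)
    ctr <- c(mean(r0), mean(c0))
    mu20 <- mean((r0 - ctr[1])^2); mu02 <- mean((c0 - ctr[2])^2)
    mu11 <- mean((r0 - ctr[1]) * (c0 - ctr[2]))
    tr <- mu20 + mu02
    det <- mu20 * mu02 - mu11^2
    disc <- sqrt(max(0, tr^2 / 4 - det))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    ecc <- if (l1 <= 1e-12) 0 else sqrt(max(0, 1 - l2 / l1))
    out[[i]] <- structure(list(
      region_id = i,
      centroid_rc = ctr,
      bbox = c(min(r0), min(c0), max(r0) + 1, max(c0) + 1),
      area_px = area,
      solidity = min(1, area / convex_pixel_area(px)),
      eccentricity = ecc), class = "cell_region")
  }
  out
}

#' Segment a bright-field frame
#'
#' Full composition: [cap_brightness()] -> [edge_mask()] -> [fill_holes()]
#' -> [open_and_filter()] -> [watershed_split()] -> [extract_regions()].
#'
#' @param bright intensity matrix.
#' @param params [segment_params()].
#' @return list with `label_map` and `regions`.
#' @export
segment_frame <- function(bright, params = segment_params()) {
  capped <- cap_brightness(bright, params$brightness_cap_percentile)
  m <- edge_mask(capped, params)
  # complementary connectivity for the background, the standard duality:
  # 8-connected foreground rings enclose 4-connected holes (and vice versa),
  # otherwise background leaks diagonally through closed rims
  m <- fill_holes(m, if (params$connectivity == 8L) 4L else 8L)
  m <- open_and_filter(m, params)
  lm <- watershed_split(m, params)
  list(label_map = lm, regions = extract_regions(lm))
}
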