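# End-to-end orchestration: synthesize or ingest paired frames, segment,
# build the labeled single-cell dataset, train (or load) the classifier,
# and emit a per-frame label-free count report.

apply_overrides <- function(defaults_fn, overrides) {
  if (is.null(overrides)) defaults_fn() else do.call(defaults_fn, overrides)
}

#' Run the full label-free counting pipeline
#'
#' Driven by a single configuration (YAML path or list) with blocks:
#' `synth` (frames, n_wbc, n_ctc, seed, optional generator `params`
#' overrides) or `input_dirs` (directories readable by [read_pair()]);
#' optional `segment$params` and `dataset` (`min_snr`, `rules`, `augment`)
#' overrides; and either `train` ([train_config()] fields) or `model` (a
#' checkpoint path). Each frame is segmented, cropped, quality-filtered,
#' fluorescence-labeled and normalized; labeled crops train the classifier
#' (augmented, 80/20 origin-level split); every kept crop is then classified
#' and counted at its recorded coordinates.
#'
#' @param config list or path to a YAML file.
#' @param out_dir optional run directory for artifacts (manifest echoing the
#'   config and seeds, per-frame reports JSON, predictions CSV, model
#'   checkpoint).
#' @return list with `reports` (one `count_report` per frame), `model`,
#'   `frames` (the `field_pair`s) and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$synth) && is.null(config$input_dirs))
    stop_ctc("ctcscope_config_error",
             "config needs a 'synth' block or 'input_dirs'")
  if (is.null(config$train) && is.null(config$model))
    stop_ctc("ctcscope_config_error",
             "config needs a 'train' block or a 'model' checkpoint path")

  frames <- if (!is.null(config$synth)) {
    sy <- config$synth
    gp <- apply_overrides(synth_config, sy$params)
    n_frames <- if (is.null(sy$frames)) 1L else as.integer(sy$frames)
    base_seed <- if (is.null(sy$seed)) 1L else as.integer(sy$seed)
    lapply(seq_len(n_frames), function(i) {
      cells <- sample_population(sy$n_wbc, sy$n_ctc, gp, seed = base_seed + i)
      render_pair(cells, gp, seed = base_seed + 10000L + i)
    })
  } else lapply(config$input_dirs, read_pair)
  names(frames) <- sprintf("frame%02d", seq_along(frames))

  sp <- apply_overrides(segment_params, config$segment$params)
  rules <- apply_overrides(quality_rules, config$dataset$rules)
  min_snr <- if (is.null(config$dataset$min_snr)) 3 else config$dataset$min_snr

  per_frame <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    seg <- segment_frame(fr$bright, sp)
    crops <- crop_cells(fr$bright, seg$regions, frame_id = names(frames)[i])
    qf <- quality_filter(crops, seg$regions, rules)
    kept <- transfer_labels(qf$kept, fr$fluor_green, fr$fluor_red, min_snr)
    kept <- lapply(kept, normalize_crop)
    list(seg = seg, kept = kept, n_rejected = length(qf$rejected))
  })

  labeled <- unlist(lapply(per_frame, function(pf)
    pf$kept[crop_labels(pf$kept) != "UNLABELED"]), recursive = FALSE)

  model <- if (!is.null(config$model)) {
    load_model(config$model)
  } else {
    tc <- do.call(train_config, config$train)
    aug_cfg <- config$dataset$augment
    spec <- apply_overrides(augment_spec, aug_cfg)
    aug <- augment_crops(labeled, spec)
    split <- split_by_origin(aug, 0.2, seed = spec$seed + 1L)
    train_model(build_model(tc), split$train, split$val, tc)
  }

  reports <- lapply(seq_along(frames), function(i) {
    pf <- per_frame[[i]]
    kept <- pf$kept
    cells <- if (length(kept)) {
      pred <- predict(model, kept)
      data.frame(row = vapply(kept, function(x) x$centroid_rc[1], 0),
                 col = vapply(kept, function(x) x$centroid_rc[2], 0),
                 p_wbc = pred$p_wbc, p_ctc = pred$p_ctc, label = pred$label,
                 stringsAsFactors = FALSE)
    } else data.frame(row = numeric(0), col = numeric(0), p_wbc = numeric(0),
                      p_ctc = numeric(0), label = character(0))
    structure(list(frame = names(frames)[i],
                   total_detected = length(kept) + pf$n_rejected,
                   n_classified = length(kept),
                   wbc_count = sum(cells$label == "WBC"),
                   ctc_count = sum(cells$label == "CTC"),
                   unclassified = pf$n_rejected,
                   cells = cells),
              class = "count_report")
  })
  names(reports) <- names(frames)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(config = config), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    preds <- do.call(rbind, lapply(reports, function(rp)
      if (nrow(rp$cells)) cbind(frame = rp$frame, rp$cells)))
    if (!is.null(preds))
      write.csv(preds, file.path(out_dir, "predictions.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(reports, function(rp)
      rp[c("frame", "total_detected", "n_classified", "wbc_count",
           "ctc_count", "unclassified")]),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    save_model(model, file.path(out_dir, "model.rds"))
  }

  list(reports = reports, model = model, frames = frames, config = config)
}

#' @export
print.count_report <- function(x, ...) {
  cat(sprintf("%s: %d cells detected | %d classified (%d WBC, %d CTC) | %d unclassified\n",
              x$frame, x$total_detected, x$n_classified, x$wbc_count,
              x$ctc_count, x$unclassified))
  invisible(x)
}

#' Annotate a frame with predicted cell classes
#'
#' Draws a ring marker at each classified cell's recorded coordinates
#' (green = WBC, red = CTC) over the grayscale frame.
#'
#' @param bright intensity matrix (8-bit range).
#' @param report a `count_report` whose coordinates lie in the frame.
#' @param path optional PNG output path.
#' @param radius marker ring radius, pixels.
#' @return H x W x 3 RGB array in `[0, 1]`, invisibly if written.
#' @export
annotate_frame <- function(bright, report, path = NULL, radius = 16) {
  nr <- nrow(bright); nc <- ncol(bright)
  g <- bright / 255
  img <- array(rep(g, 3), dim = c(nr, nc, 3))
  cells <- report$cells
  for (i in seq_len(nrow(cells))) {
    r <- cells$row[i]; c <- cells$col[i]
    if (r < 0 || r > nr - 1 || c < 0 || c > nc - 1)
      stop_ctc("ctcscope_consistency_error",
               "report coordinate (%g, %g) outside %dx%d frame", r, c, nr, nc)
    col3 <- if (cells$label[i] == "CTC") c(1, 0.1, 0.1) else c(0.1, 0.9, 0.1)
    rr <- max(1, floor(r + 1 - radius - 2)):min(nr, ceiling(r + 1 + radius + 2))
    cc <- max(1, floor(c + 1 - radius - 2)):min(nc, ceiling(c + 1 + radius + 2))
    d <- sqrt(outer((rr - 1 - r)^2, (cc - 1 - c)^2, "+"))
    ring <- abs(d - radius) <= 1
    for (ch in 1:3) {
      plane <- img[rr, cc, ch]
      plane[ring] <- col3[ch]
      img[rr, cc, ch] <- plane
    }
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
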