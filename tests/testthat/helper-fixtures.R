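# Shared fixtures, built in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a rendered frame with well-separated cells plus its segmentation
seg_fixture <- function() {
  cached("seg_fixture", {
    params <- synth_config(touching_frac = 0)
    cells <- sample_population(30, 10, params, seed = 42)
    pair <- render_pair(cells, params, seed = 42)
    seg <- segment_frame(pair$bright, segment_params())
    list(params = params, cells = cells, pair = pair, seg = seg)
  })
}

# labeled, normalized crops from two balanced frames (for CV-level tests)
crops_fixture <- function() {
  cached("crops_fixture", {
    params <- synth_config(touching_frac = 0)
    out <- list()
    for (s in 1:2) {
      cells <- sample_population(18, 18, params, seed = 300 + s)
      pair <- render_pair(cells, params, seed = 300 + s)
      seg <- segment_frame(pair$bright, segment_params())
      crops <- crop_cells(pair$bright, seg$regions,
                          frame_id = sprintf("fx%d", s))
      qf <- quality_filter(crops, seg$regions)
      lab <- transfer_labels(qf$kept, pair$fluor_green, pair$fluor_red)
      lab <- lab[vapply(lab, function(x) x$label, "") != "UNLABELED"]
      out <- c(out, lapply(lab, normalize_crop))
    }
    out
  })
}

# toy linearly separable crops: constant-offset patches with a fixed small
# texture, flagged as already normalized
make_toy_crops <- function(n_per_class, prefix = "toy") {
  mk <- function(n, cls, val) {
    lapply(seq_len(n), function(i) ctcscope:::new_cell_crop(
      crop_id = sprintf("%s_%s_%02d", prefix, cls, i),
      pixels = matrix(val + 0.01 * sin(i + seq_len(900)), 30, 30),
      source_frame = prefix, centroid_rc = c(15, 15), label = cls,
      normalized = TRUE))
  }
  c(mk(n_per_class, "WBC", -1), mk(n_per_class, "CTC", 1))
}

toy_train_config <- function(...) {
  args <- utils::modifyList(list(learning_rate = 0.01, max_epochs = 20,
                                 patience = 20, seed = 1), list(...))
  do.call(train_config, args)
}

disk_mask <- function(nr, nc, ctr_r, ctr_c, radius) {
  d <- sqrt(outer((seq_len(nr) - ctr_r)^2, (seq_len(nc) - ctr_c)^2, "+"))
  d <= radius
}

random_mask <- function(nr, nc, p = 0.5) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# greedy one-to-one matching of region centroids to true cell centers by
# increasing distance: returns per-cell centroid error (Inf for unrecovered
# cells) and the count of regions matched to no cell within `false_radius`
match_centroids <- function(region_ctrs, true_ctrs, false_radius = 5) {
  n_cells <- nrow(true_ctrs)
  errs <- rep(Inf, n_cells)
  if (is.null(region_ctrs) || nrow(region_ctrs) == 0)
    return(list(errs = errs, n_false = 0L))
  n_reg <- nrow(region_ctrs)
  dmat <- matrix(Inf, n_cells, n_reg)
  for (i in seq_len(n_cells))
    dmat[i, ] <- sqrt((region_ctrs[, 1] - true_ctrs[i, 1])^2 +
                      (region_ctrs[, 2] - true_ctrs[i, 2])^2)
  used <- rep(FALSE, n_reg)
  for (step in seq_len(min(n_cells, n_reg))) {
    j <- which.min(dmat)
    if (!is.finite(dmat[j])) break
    ci <- (j - 1) %% n_cells + 1; rj <- (j - 1) %/% n_cells + 1
    if (dmat[j] > false_radius) break
    errs[ci] <- dmat[j]
    used[rj] <- TRUE
    dmat[ci, ] <- Inf; dmat[, rj] <- Inf
  }
  list(errs = errs, n_false = sum(!used))
}
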