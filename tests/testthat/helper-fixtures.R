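# Shared fixtures and independent brute-force oracles.

# tile table shaped like count_per_tile() output, from explicit counts
make_tiles <- function(total, positive, side = 500) {
  n <- length(total)
  tiles <- tibble::tibble(
    row = (seq_len(n) - 1L) %/% 4L,
    col = (seq_len(n) - 1L) %% 4L,
    x0_px = col * side, y0_px = row * side,
    x1_px = x0_px + side, y1_px = y0_px + side,
    total_cells = as.integer(total),
    positive_cells = as.integer(positive),
    percent_positive = ifelse(total > 0, 100 * positive / total, NA_real_)
  )
  attr(tiles, "grid_origin") <- c(x = 0, y = 0)
  attr(tiles, "tile_side_px") <- side
  tiles
}

# direct-summation Pearson r (oracle, independent of cor())
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# direct-summation concordance correlation (population moments)
brute_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# brute-force confusion tally honoring the low=positive / high=negative
# conventions and the intermediate-exclusion rule
brute_confusion <- function(predicted, actual) {
  keep <- predicted != "intermediate" & actual != "intermediate"
  p <- predicted[keep]; a <- actual[keep]
  c(TP = sum(a == "low" & p == "low"),
    TN = sum(a == "high" & p == "high"),
    FP = sum(a == "high" & p == "low"),
    FN = sum(a == "low" & p == "high"),
    n_excluded = sum(!keep))
}

# small slide used by several tests: 1.5 x 1.5 mm (3 x 3 tiles),
# one hot spot confined to the top-left tile neighborhood
small_slide_spec <- function(seed = 1,
                             hotspots = list(hotspot_spec(c(400, 400), 250)),
                             ...) {
  slide_spec(width_um = 1500, height_um = 1500, hotspots = hotspots,
             seed = seed, ...)
}

# render isolated circular nuclei at given centers into a slide image
render_disks <- function(centers, radius = 5, size = 120, mpp = 1,
                         od_hema = 0.7, od_dab = 0, basis = stain_basis()) {
  hema <- matrix(0, size, size)
  dab <- matrix(0, size, size)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(size)) {
      for (cc in seq_len(size)) {
        if ((cc - 1 - centers[i, 1])^2 + (r - 1 - centers[i, 2])^2 <= radius^2) {
          hema[r, cc] <- hema[r, cc] + od_hema
          dab[r, cc] <- dab[r, cc] + od_dab
        }
      }
    }
  }
  od_to_rgb(synthesize_od(hema, dab, basis), mpp)
}
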