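#' Specify a hot spot for slide simulation
#'
#' @param center_um Length-2 vector, hot-spot center (x, y) in microns.
#' @param radius_um Radius in microns.
#' @param density_mult Multiplier on the base nucleus density inside
#'   the hot spot.
#' @param p_hot Ki67-positive probability inside the hot spot.
#' @return A list of class `hotspot_spec`.
#' @export
hotspot_spec <- function(center_um, radius_um, density_mult = 1.5,
                         p_hot = 0.85) {
  stopifnot(length(center_um) == 2L, radius_um > 0, density_mult >= 1,
            p_hot >= 0, p_hot <= 1)
  structure(list(center_um = center_um, radius_um = radius_um,
                 density_mult = density_mult, p_hot = p_hot),
            class = "hotspot_spec")
}

#' Specify a synthetic IHC slide
#'
#' Describes a brightfield Ki67 image to be simulated: canvas size and
#' scale, a spatially inhomogeneous nucleus point process (base density
#' plus circular hot spots), per-class Bernoulli positivity, nucleus
#' geometry, the stain optical-density levels of the two classes, and
#' background noise. The defaults give a 2 x 2 mm region with about
#' 9300 nuclei after thinning (`base_density` is the candidate Poisson
#' intensity; the hard core rejects part of it), roughly 580 cells per
#' 500-micron tile so every tile clears the 500-cell hot-spot
#' qualification, plus one proliferation hot spot on a 15%-positive
#' background.
#'
#' @param width_um,height_um Canvas size in microns.
#' @param mpp Microns per pixel.
#' @param base_density Candidate nuclei per mm^2 outside hot spots
#'   (0 gives a blank slide).
#' @param hotspots List of [hotspot_spec()]s; must lie inside the
#'   canvas.
#' @param p0 Base Ki67-positive probability.
#' @param nucleus_radius_px Length-2 range of nucleus semi-axes, px.
#' @param od_positive,od_negative Named vectors `c(hema=, dab=)` of
#'   stain optical-density levels for the two classes. Positive nuclei
#'   are DAB-dominant (brown), negative nuclei hematoxylin-only (blue).
#' @param noise_sd Gaussian noise sd added on each optical-density
#'   channel.
#' @param min_sep_factor Hard-core minimum center separation as a
#'   multiple of the maximum nucleus radius.
#' @param seed Integer seed; the whole simulation is deterministic in
#'   it.
#' @return A list of class `slide_spec`.
#' @export
slide_spec <- function(width_um = 2000, height_um = 2000, mpp = 1,
                       base_density = 3600,
                       hotspots = list(hotspot_spec(
                         center_um = c(width_um * 0.3, height_um * 0.3),
                         radius_um = min(width_um, height_um) * 0.18)),
                       p0 = 0.15,
                       nucleus_radius_px = c(3, 5),
                       od_positive = c(hema = 0.35, dab = 0.65),
                       od_negative = c(hema = 0.70, dab = 0.02),
                       noise_sd = 0.03,
                       min_sep_factor = 2,
                       seed = 1) {
  stopifnot(width_um > 0, height_um > 0, mpp > 0, base_density >= 0,
            p0 >= 0, p0 <= 1, length(nucleus_radius_px) == 2L,
            noise_sd >= 0)
  for (h in hotspots) {
    stopifnot(inherits(h, "hotspot_spec"))
    if (h$center_um[1] - h$radius_um < 0 ||
        h$center_um[1] + h$radius_um > width_um ||
        h$center_um[2] - h$radius_um < 0 ||
        h$center_um[2] + h$radius_um > height_um) {
      stop("hot spot extends outside the canvas", call. = FALSE)
    }
  }
  structure(list(width_um = width_um, height_um = height_um, mpp = mpp,
                 base_density = base_density, hotspots = hotspots,
                 p0 = p0, nucleus_radius_px = sort(nucleus_radius_px),
                 od_positive = od_positive, od_negative = od_negative,
                 noise_sd = noise_sd, min_sep_factor = min_sep_factor,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# greedy hard-core thinning with grid hashing; keeps candidate order
hardcore_thin <- function(x, y, min_sep) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  cell <- max(min_sep, 1e-9)
  cx <- floor(x / cell); cy <- floor(y / cell)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  keep <- logical(n)
  sep2 <- min_sep^2
  for (i in seq_len(n)) {
    ok <- TRUE
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(cx[i] + dx, cy[i] + dy)
        js <- buckets[[key]]
        if (!is.null(js)) {
          if (any((x[js] - x[i])^2 + (y[js] - y[i])^2 < sep2)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) break
    }
    if (ok) {
      keep[i] <- TRUE
      key <- paste(cx[i], cy[i])
      buckets[[key]] <- c(buckets[[key]], i)
    }
  }
  which(keep)
}

#' Simulate a Ki67 IHC slide with ground truth
#'
#' Draws nucleus centers from an inhomogeneous Poisson process (base
#' density, boosted inside hot spots) with hard-core thinning at the
#' configured minimum separation, labels each nucleus Bernoulli
#' positive (`p_hot` inside a hot spot, else `p0`), and renders each as
#' a randomly oriented ellipse through Beer--Lambert forward synthesis
#' in the given stain basis, plus Gaussian optical-density noise. The
#' true centers and labels are returned alongside the image, so the
#' generator doubles as the oracle for the imaging and tiling chain.
#'
#' @param spec A [slide_spec()].
#' @param basis Stain basis used for rendering; by default the same
#'   H-DAB basis the analyzer inverts (a deliberately closed loop —
#'   pass a perturbed basis to probe robustness separately).
#' @return A list of class `simulated_slide`: `image`
#'   ([slide_image()]), `truth` (tibble: `nucleus_id`, `x_px`, `y_px`,
#'   `label`, `in_hotspot`), `region` (full-canvas
#'   [region_annotation()]), and `spec`.
#' @export
simulate_slide <- function(spec = slide_spec(), basis = stain_basis()) {
  stopifnot(inherits(spec, "slide_spec"))
  set.seed(spec$seed)
  w_px <- round(spec$width_um / spec$mpp)
  h_px <- round(spec$height_um / spec$mpp)
  min_sep <- spec$min_sep_factor * max(spec$nucleus_radius_px)
  # feasibility: hexagonal packing bound for hard-core distance min_sep
  max_mult <- max(c(1, vapply(spec$hotspots, `[[`, numeric(1),
                              "density_mult")))
  peak_per_px2 <- spec$base_density * max_mult / 1e6 * spec$mpp^2
  if (peak_per_px2 > 0.55 * (2 / (sqrt(3) * min_sep^2))) {
    stop(sprintf(
      paste0("requested density (%.0f/mm^2 peak) is infeasible under the ",
             "minimum separation of %.1f px; lower the density or the ",
             "separation factor"),
      spec$base_density * max_mult, min_sep), call. = FALSE)
  }
  # candidate points: base process + hot-spot surplus
  lam_px2 <- spec$base_density / 1e6 * spec$mpp^2
  n_base <- stats::rpois(1, lam_px2 * w_px * h_px)
  x <- stats::runif(n_base, 0, w_px)
  y <- stats::runif(n_base, 0, h_px)
  for (h in spec$hotspots) {
    r_px <- h$radius_um / spec$mpp
    cx <- h$center_um[1] / spec$mpp
    cy <- h$center_um[2] / spec$mpp
    n_extra <- stats::rpois(1, lam_px2 * (h$density_mult - 1) * pi * r_px^2)
    if (n_extra > 0) {
      rr <- r_px * sqrt(stats::runif(n_extra))
      th <- stats::runif(n_extra, 0, 2 * pi)
      x <- c(x, cx + rr * cos(th))
      y <- c(y, cy + rr * sin(th))
    }
  }
  if (length(x) > 0) {
    ord <- sample.int(length(x))  # random thinning order
    x <- x[ord]; y <- y[ord]
    keep <- hardcore_thin(x, y, min_sep)
    x <- x[keep]; y <- y[keep]
  }
  # labels
  in_hot <- rep(FALSE, length(x))
  p <- rep(spec$p0, length(x))
  for (h in spec$hotspots) {
    r_px <- h$radius_um / spec$mpp
    d2 <- (x - h$center_um[1] / spec$mpp)^2 + (y - h$center_um[2] / spec$mpp)^2
    hit <- d2 <= r_px^2
    in_hot <- in_hot | hit
    p[hit] <- h$p_hot
  }
  positive <- stats::runif(length(x)) < p
  truth <- tibble::tibble(
    nucleus_id = seq_along(x),
    x_px = x, y_px = y,
    label = ifelse(positive, "positive", "negative"),
    in_hotspot = in_hot
  )
  # render
  hema <- matrix(0, h_px, w_px)
  dab <- matrix(0, h_px, w_px)
  rmin <- spec$nucleus_radius_px[1]; rmax <- spec$nucleus_radius_px[2]
  for (i in seq_along(x)) {
    rx <- stats::runif(1, rmin, rmax)
    ry <- stats::runif(1, rmin, rmax)
    th <- stats::runif(1, 0, pi)
    lv <- if (positive[i]) spec$od_positive else spec$od_negative
    x0 <- max(0, floor(x[i] - rmax)); x1 <- min(w_px - 1, ceiling(x[i] + rmax))
    y0 <- max(0, floor(y[i] - rmax)); y1 <- min(h_px - 1, ceiling(y[i] + rmax))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(ys - y[i], xs - x[i], function(a, b) b)   # x offsets
    dy <- outer(ys - y[i], xs - x[i], function(a, b) a)   # y offsets
    u <- (dx * cos(th) + dy * sin(th)) / rx
    v <- (-dx * sin(th) + dy * cos(th)) / ry
    mask <- (u^2 + v^2) <= 1
    ri <- ys + 1L; ci <- xs + 1L
    hema[ri, ci][mask] <- hema[ri, ci][mask] + lv[["hema"]]
    dab[ri, ci][mask] <- dab[ri, ci][mask] + lv[["dab"]]
  }
  od <- synthesize_od(hema, dab, basis)
  if (spec$noise_sd > 0) {
    od <- od + stats::rnorm(length(od), 0, spec$noise_sd)
    od[od < 0] <- 0
  }
  image <- od_to_rgb(od, spec$mpp)
  region <- rect_region(0, 0, w_px - 1, h_px - 1)
  structure(list(image = image, truth = truth, region = region, spec = spec),
            class = "simulated_slide")
}

#' @export
print.simulated_slide <- function(x, ...) {
  cat(sprintf(
    "<simulated_slide> %d nuclei (%.1f%% positive), %d hot spot(s), seed %d\n",
    nrow(x$truth), 100 * mean(x$truth$label == "positive"),
    length(x$spec$hotspots), x$spec$seed))
  invisible(x)
}

#' Ki67 indices computed from ground-truth labels
#'
#' Applies exactly the tiling and scoring definitions — the same grid,
#' counting and index rules used on detections — to the TRUE nucleus
#' centers and labels of a simulated slide, bypassing the imaging
#' chain. Serves as the oracle for end-to-end recovery tests.
#'
#' @param slide A `simulated_slide` from [simulate_slide()].
#' @param tile_size_um,min_cells,k Scoring parameters, as in
#'   [score_slide()].
#' @return A `slide_score` computed from truth labels.
#' @export
truth_indices <- function(slide, tile_size_um = 500, min_cells = 500, k = 5) {
  stopifnot(inherits(slide, "simulated_slide"))
  tiles <- build_grid(slide$region, slide$spec$mpp, tile_size_um)
  tiles <- count_per_tile(slide$truth, tiles, slide$region)
  score_tiles(tiles, detections = slide$truth,
              min_cells = min_cells, k = k,
              params = list(mpp = slide$spec$mpp,
                            tile_size_um = tile_size_um,
                            min_cells = min_cells, k = k,
                            source = "ground_truth"))
}

#' Specify a synthetic cohort
#'
#' Describes a cohort of early-stage, hormone-receptor-positive breast
#' cancer records with the qualitative dependence structure seen in
#' clinico-pathological practice: the Ki67 index rises with tumor grade
#' and mitotic score and falls with ER/PgR Allred scores, and the
#' Recurrence Score is driven chiefly by Ki67. Marginals of the ordinal
#' variables roughly follow the frequencies of a typical Oncotype
#' DX-tested cohort; the default coefficients give about 60/30/10
#' percent low/intermediate/high risk.
#'
#' @param n Number of patients.
#' @param noise_sd Gaussian noise sd on the Recurrence Score.
#' @param coefficients Named list of linear weights building `rs`:
#'   `intercept`, `ki67`, `mitotic`, `grade`, `pgr_allred` (the last
#'   three applied to centered scores).
#' @param single_signal If `TRUE`, predictors are drawn independently,
#'   the Ki67 index is uniform on `[0, 50]`, and `rs` depends on Ki67
#'   alone — the cleanest setting for parameter-recovery checks.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 328, noise_sd = 3,
                        coefficients = list(intercept = 1.5, ki67 = 0.95,
                                            mitotic = 1.2, grade = 0.8,
                                            pgr_allred = -0.8),
                        single_signal = FALSE, seed = 1) {
  stopifnot(n >= 1, noise_sd >= 0)
  need <- c("intercept", "ki67", "mitotic", "grade", "pgr_allred")
  if (!all(need %in% names(coefficients))) {
    stop("`coefficients` must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n = as.integer(n), noise_sd = noise_sd,
                 coefficients = coefficients,
                 single_signal = isTRUE(single_signal),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Predictor column sets for the forest harness
#'
#' The 13 chart variables (with the Ki67 index in the chosen variant),
#' optionally extended with the three RT-PCR expression scores from
#' Oncotype DX reports (`odx_*`), giving the 16-variable set.
#'
#' @param variant `"hotspot"` or `"wholeslide"` Ki67 index column.
#' @param include_odx Append `odx_er`, `odx_pgr`, `odx_her2`?
#' @return Character vector of column names.
#' @export
predictor_set <- function(variant = c("hotspot", "wholeslide"),
                          include_odx = FALSE) {
  variant <- match.arg(variant)
  base <- c("age", "tumor_size_mm", "tumor_grade", "nuclear_grade",
            "differentiation", "mitotic_score", "er_intensity", "er_allred",
            "pgr_intensity", "pgr_allred",
            paste0("ki67_", variant),
            "lymphovascular_invasion", "tumor_stage")
  if (include_odx) c(base, "odx_er", "odx_pgr", "odx_her2") else base
}

#' Simulate a cohort with Recurrence Scores
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per patient: `patient_id`, the 13 chart
#'   predictors (both Ki67 variants), `odx_er`, `odx_pgr`, `odx_her2`,
#'   and `rs` (truncated to `[0, 100]`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.21, 0.63, 0.16))
  nuclear_grade <- sample(1:3, n, replace = TRUE, prob = c(0.10, 0.56, 0.34))
  differentiation <- sample(1:3, n, replace = TRUE, prob = c(0.10, 0.28, 0.62))
  mit_prob <- rbind(c(0.80, 0.15, 0.05),
                    c(0.50, 0.35, 0.15),
                    c(0.10, 0.40, 0.50))
  mitotic <- vapply(grade, function(g) {
    sample(1:3, 1, prob = mit_prob[g, ])
  }, integer(1))
  er_intensity <- sample(1:3, n, replace = TRUE, prob = c(0.03, 0.05, 0.92))
  er_allred <- as.integer(clamp(round(5 + 0.8 * er_intensity +
                                        stats::rnorm(n, 0, 0.8)), 2, 8))
  pgr_intensity <- sample(1:3, n, replace = TRUE, prob = c(0.06, 0.29, 0.65))
  pgr_allred <- as.integer(clamp(round(3.2 + 1.1 * pgr_intensity +
                                         stats::rnorm(n, 0, 1.1)), 0, 8))
  age <- as.integer(clamp(round(stats::rnorm(n, 55, 10)), 29, 85))
  tumor_size <- clamp(round(stats::rlnorm(n, log(16), 0.45), 1), 2.5, 57)
  lvi <- stats::rbinom(n, 1, 0.15)
  stage <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  if (spec$single_signal) {
    ki67_hot <- stats::runif(n, 0, 50)
  } else {
    ki67_hot <- clamp(exp(log(15) + 0.30 * (grade - 2) +
                            0.35 * (mitotic - 2) -
                            0.10 * (er_allred - 7) -
                            0.06 * (pgr_allred - 6) +
                            stats::rnorm(n, 0, 0.55)),
                      0.3, 95)
  }
  ki67_ws <- clamp(ki67_hot * 0.45 * exp(stats::rnorm(n, 0, 0.20)), 0.1, 95)
  odx_er <- round(8 + 0.35 * er_allred + stats::rnorm(n, 0, 0.7), 1)
  odx_pgr <- round(4.5 + 0.50 * pgr_allred + stats::rnorm(n, 0, 0.8), 1)
  odx_her2 <- round(stats::rnorm(n, 9, 0.5), 1)
  co <- spec$coefficients
  if (spec$single_signal) {
    rs_raw <- 1.5 * ki67_hot
  } else {
    rs_raw <- co$intercept + co$ki67 * ki67_hot +
      co$mitotic * (mitotic - 1) + co$grade * (grade - 1) +
      co$pgr_allred * (pgr_allred - 6)
  }
  rs <- clamp(rs_raw + stats::rnorm(n, 0, spec$noise_sd), 0, 100)
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age, tumor_size_mm = tumor_size,
    tumor_grade = grade, nuclear_grade = nuclear_grade,
    differentiation = differentiation, mitotic_score = mitotic,
    er_intensity = er_intensity, er_allred = er_allred,
    pgr_intensity = pgr_intensity, pgr_allred = pgr_allred,
    ki67_hotspot = ki67_hot, ki67_wholeslide = ki67_ws,
    lymphovascular_invasion = lvi, tumor_stage = stage,
    odx_er = odx_er, odx_pgr = odx_pgr, odx_her2 = odx_her2,
    rs = rs
  )
}
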