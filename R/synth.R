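#' Simulate a cooked-rice image with known yellow-area ground truth
#'
#' Generates a grain-textured RGB image in which every pixel's class (yellow
#' vs white) is fixed by construction, so the generator's own pixel counts —
#' not a re-run of the classifier — are the ground truth. Yellow patches are
#' ellipse-shaped "grains" accumulated until exactly
#' `round(yellow_fraction * width * height)` pixels carry the yellow label;
#' yellow pixels get hues inside `yellow_hue_range` (below the 0.167
#' classification threshold) and moderate saturation, while white pixels get
#' a faint cool tint (hue well above the threshold) rather than being
#' perfectly achromatic, because achromatic pixels have hue 0 and would
#' classify as yellow under the literal hue rule. Brightness noise is applied
#' on the HSV value channel only, so it cannot move a pixel across the hue
#' threshold and the constructed labels stay exact.
#'
#' @param width,height Image size in pixels.
#' @param yellow_fraction Target fraction of yellow pixels in `[0, 1]`.
#' @param n_grains Approximate number of white grain outlines drawn for
#'   texture (brightness modulation only).
#' @param yellow_hue_range Hue interval for yellow pixels, inside
#'   `[0, 0.167)`.
#' @param white_hue Hue of the faint tint on white pixels (default 0.62,
#'   a cool near-neutral).
#' @param white_sat_range,yellow_sat_range Saturation intervals for the two
#'   classes.
#' @param value_range Brightness interval.
#' @param noise_sd Brightness noise, in 0--255 channel units, applied to the
#'   value channel.
#' @param seed Integer seed (required; generation is deterministic given it).
#' @return List: `image` (a `rice_image`), `labels` (logical H x W matrix,
#'   TRUE = yellow), `truth` (tibble: `n_total`, `n_yellow`,
#'   `yellow_fraction_target`, `yellow_percent`).
#' @export
simulate_rice_image <- function(width = 320, height = 240,
                                yellow_fraction = 0.3, n_grains = 150,
                                yellow_hue_range = c(0.09, 0.15),
                                white_hue = 0.62,
                                white_sat_range = c(0.02, 0.05),
                                yellow_sat_range = c(0.25, 0.45),
                                value_range = c(0.82, 0.98),
                                noise_sd = 2, seed) {
  if (missing(seed)) stop_config("seed is required")
  if (!is.numeric(yellow_fraction) || yellow_fraction < 0 || yellow_fraction > 1) {
    stop_config("yellow_fraction must lie in [0, 1]")
  }
  if (yellow_hue_range[1] < 0 || yellow_hue_range[2] >= 0.167) {
    stop_config("yellow_hue_range must sit inside [0, 0.167)")
  }
  withr::with_seed(seed, {
    n_total <- width * height
    target <- round(yellow_fraction * n_total)
    labels <- matrix(FALSE, height, width)

    # accumulate ellipse-shaped yellow patches up to the exact pixel budget
    iter <- 0L
    while (sum(labels) < target && iter < 50000L) {
      iter <- iter + 1L
      px <- ellipse_pixels(height, width,
                           cy = runif(1, 1, height), cx = runif(1, 1, width),
                           a = runif(1, 6, 12), b = runif(1, 2.5, 5),
                           theta = runif(1, 0, pi))
      new <- px[!labels[px]]
      need <- target - sum(labels)
      if (length(new) > need) new <- sample(new, need)
      labels[new] <- TRUE
    }
    if (sum(labels) < target) {   # near-full images: top up pixelwise
      pool <- which(!labels)
      labels[sample(pool, target - sum(labels))] <- TRUE
    }

    yellow <- as.vector(labels)
    n <- n_total
    h <- ifelse(yellow,
                runif(n, yellow_hue_range[1], yellow_hue_range[2]),
                white_hue + runif(n, -0.03, 0.03))
    s <- ifelse(yellow,
                runif(n, yellow_sat_range[1], yellow_sat_range[2]),
                runif(n, white_sat_range[1], white_sat_range[2]))
    v <- runif(n, value_range[1], value_range[2]) +
      grain_texture(height, width, n_grains) +
      rnorm(n, 0, noise_sd / 255)
    v <- pmin(pmax(v, 0.5), 1)

    rgb <- grDevices::col2rgb(grDevices::hsv(h, s, v))
    pixels <- array(0, dim = c(height, width, 3))
    pixels[, , 1] <- matrix(rgb[1, ], height, width)
    pixels[, , 2] <- matrix(rgb[2, ], height, width)
    pixels[, , 3] <- matrix(rgb[3, ], height, width)

    list(
      image = new_rice_image(pixels, metadata = list(
        synthetic = TRUE, seed = seed, width = width, height = height
      )),
      labels = labels,
      truth = tibble(
        n_total = n_total, n_yellow = sum(labels),
        yellow_fraction_target = yellow_fraction,
        yellow_percent = 100 * sum(labels) / n_total
      )
    )
  })
}

# linear indices of an ellipse footprint, clipped to the raster
ellipse_pixels <- function(h, w, cy, cx, a, b, theta) {
  r0 <- max(1L, floor(cy - a))
  r1 <- min(h, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a))
  c1 <- min(w, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1
  cols <- c0:c1
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  vv <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (vv / b)^2 <= 1
  idx <- which(inside)
  rr <- rows[(idx - 1L) %% length(rows) + 1L]
  cc <- cols[(idx - 1L) %/% length(rows) + 1L]
  (cc - 1L) * h + rr
}

# subtle darkening along random grain boundaries, value-channel only
grain_texture <- function(h, w, n_grains) {
  tex <- matrix(0, h, w)
  if (n_grains < 1) return(as.vector(tex))
  for (i in seq_len(n_grains)) {
    px <- ellipse_pixels(h, w, runif(1, 1, h), runif(1, 1, w),
                         runif(1, 6, 12), runif(1, 2.5, 5), runif(1, 0, pi))
    tex[px] <- tex[px] - runif(1, 0, 0.04)
  }
  as.vector(tex)
}

#' Simulate a double-compression force curve with known TPA ground truth
#'
#' Builds a piecewise-linear two-cycle profile: a triangular first
#' compression (peak `hardness`, base `t1`), a triangular withdrawal dip of
#' area `adhesiveness`, and a triangular second compression whose area is
#' `cohesiveness * A1` over base `t2`. The exact breakpoint times are
#' inserted into the uniform sampling grid, so the sampled polyline equals
#' the analytic curve and all closed-form features (emitted in `truth`) are
#' recoverable exactly by [compute_tpa()] when `noise_sd = 0`.
#'
#' @param hardness Peak force of cycle 1 (gf).
#' @param adhesiveness Magnitude of the negative withdrawal area (gf s).
#' @param t1,t2 Durations of the two positive-force phases (s).
#' @param cohesiveness Target `A2 / A1` ratio.
#' @param adhesion_time Duration of the withdrawal dip (s).
#' @param lead_in,gap,tail Zero-force padding before, between and after the
#'   active phases (s).
#' @param sample_rate Sampling rate (Hz).
#' @param noise_sd Additive Gaussian force noise (gf).
#' @param seed Integer seed (required).
#' @return List: `curve` (a `force_curve`) and `truth` (one-row tibble with
#'   the closed-form feature values, same columns as [compute_tpa()];
#'   `brittleness` is NA — the profile has no pre-peak maxima).
#' @export
simulate_force_curve <- function(hardness = 500, adhesiveness = 100,
                                 t1 = 2, t2 = 1.5, cohesiveness = 0.6,
                                 adhesion_time = 1, lead_in = 0.5, gap = 0.3,
                                 tail = 0.3, sample_rate = 500,
                                 noise_sd = 0, seed) {
  if (missing(seed)) stop_config("seed is required")
  for (nm in c("hardness", "adhesiveness", "t1", "t2", "cohesiveness",
               "adhesion_time", "sample_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop_config(nm, " must be a single positive number")
    }
  }
  A1 <- hardness * t1 / 2
  A2 <- cohesiveness * A1
  peak2 <- 2 * A2 / t2
  depth <- 2 * adhesiveness / adhesion_time

  bp_t <- cumsum(c(0, lead_in, t1 / 2, t1 / 2, adhesion_time / 2,
                   adhesion_time / 2, gap, t2 / 2, t2 / 2, tail))
  bp_f <- c(0, 0, hardness, 0, -depth, 0, 0, peak2, 0, 0)

  tt <- sort(c(seq(0, max(bp_t), by = 1 / sample_rate), bp_t))
  tt <- tt[c(TRUE, diff(tt) > 1e-9)]   # drop near-duplicate grid/breakpoint times
  ff <- approx(bp_t, bp_f, xout = tt)$y
  curve <- withr::with_seed(seed, {
    if (noise_sd > 0) ff <- ff + rnorm(length(ff), 0, noise_sd)
    as_force_curve(tibble(time = tt, force = ff), source = "synthetic")
  })

  springiness <- t2 / t1
  gumminess <- cohesiveness * hardness
  truth <- tibble(
    hardness = hardness, brittleness = NA_real_,
    adhesiveness = adhesiveness,
    springiness = springiness, cohesiveness = cohesiveness,
    gumminess = gumminess, chewiness = gumminess * springiness,
    resilience = 1,
    A1 = A1, A2 = A2, A3 = adhesiveness, A4 = A1 / 2, A5 = A1 / 2,
    T1 = t1, T2 = t2
  )
  list(curve = curve, truth = truth)
}

#' Simulate a sensory-panel score table with known variance components
#'
#' Generates a balanced variety x year x replicate panel. Each component
#' trait gets independent variety effects `~ N(0, var_g)`, a fixed year
#' offset `~ N(0, year_effect_sd^2)` shared across varieties, and residual
#' noise `~ N(0, var_e)` per observation. The IVOE is a latent linear
#' combination of viscosity, appearance and taste (default: the published
#' Model-1 coefficients 0.20/0.35/0.59 with intercept 0.13) plus Gaussian
#' noise whose standard deviation is calibrated, unless given, so the
#' generating signal-to-total variance matches `target_r2` (default 0.87,
#' the published fit). Scores are clipped to the panel's `[-3, 3]` scale and
#' the clipping rate is reported — at the default variances it is ~0.
#'
#' Defaults mirror the study's shape: 322 varieties scored in 2 years, with
#' trait means set to the published sample averages.
#'
#' @param n_varieties,n_years,n_reps Panel dimensions.
#' @param var_g,var_e Genetic and residual variance components
#'   (score units squared).
#' @param year_effect_sd SD of the fixed per-year offsets.
#' @param traits Component traits to generate.
#' @param trait_means Named means; defaults to the published sample averages.
#' @param trait_betas Named IVOE coefficients on (viscosity, appearance,
#'   taste).
#' @param intercept IVOE intercept.
#' @param noise_sd IVOE residual SD; `NULL` (default) calibrates it from
#'   `target_r2`.
#' @param target_r2 Generating signal fraction for the IVOE when `noise_sd`
#'   is `NULL`.
#' @param include_ivoe Set `FALSE` to generate component traits only.
#' @param seed Integer seed (required).
#' @return List: `data` (long `sensory_table`), `truth` (generating
#'   parameters incl. the realised `noise_sd` and per-trait year effects),
#'   `clipping_rate`.
#' @export
simulate_panel <- function(n_varieties = 322, n_years = 2, n_reps = 3,
                           var_g = 0.15, var_e = 0.05, year_effect_sd = 0.1,
                           traits = c("viscosity", "appearance", "taste",
                                      "hardness", "fragrance"),
                           trait_means = c(viscosity = -0.56,
                                           appearance = -0.49, taste = -0.66,
                                           hardness = 0.06,
                                           fragrance = -0.20),
                           trait_betas = c(viscosity = 0.20,
                                           appearance = 0.35, taste = 0.59),
                           intercept = 0.13, noise_sd = NULL,
                           target_r2 = 0.87, include_ivoe = TRUE, seed) {
  if (missing(seed)) stop_config("seed is required")
  if (var_g < 0 || var_e < 0) stop_config("variance components must be >= 0")
  if (include_ivoe && !all(names(trait_betas) %in% traits)) {
    stop_config("trait_betas name trait(s) not being generated: ",
                paste(setdiff(names(trait_betas), traits), collapse = ", "))
  }
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      variety = sprintf("V%03d", seq_len(n_varieties)),
      year = 2020 + seq_len(n_years) - 1L,
      replicate = seq_len(n_reps)
    )
    n_obs <- nrow(grid)
    year_effects <- list()
    scores <- purrr::map(traits, function(tr) {
      g <- rnorm(n_varieties, 0, sqrt(var_g))
      yr <- rnorm(n_years, 0, year_effect_sd)
      year_effects[[tr]] <<- yr
      mu <- if (tr %in% names(trait_means)) trait_means[[tr]] else 0
      mu + g[match(grid$variety, unique(grid$variety))] +
        yr[match(grid$year, unique(grid$year))] +
        rnorm(n_obs, 0, sqrt(var_e))
    })
    names(scores) <- traits

    realised_noise_sd <- noise_sd
    if (include_ivoe) {
      signal <- intercept
      for (tr in names(trait_betas)) {
        signal <- signal + trait_betas[[tr]] * scores[[tr]]
      }
      if (is.null(realised_noise_sd)) {
        realised_noise_sd <- sd(signal) * sqrt((1 - target_r2) / target_r2)
      }
      scores$IVOE <- signal + rnorm(n_obs, 0, realised_noise_sd)
    }

    long <- purrr::imap(scores, function(sc, tr) {
      dplyr::mutate(grid, trait = tr, score = sc)
    }) |> dplyr::bind_rows()
    clipped <- long$score < -3 | long$score > 3
    long$score <- pmin(pmax(long$score, -3), 3)

    list(
      data = as_sensory_table(long),
      truth = list(var_g = var_g, var_e = var_e,
                   year_effect_sd = year_effect_sd,
                   year_effects = year_effects,
                   trait_means = trait_means, trait_betas = trait_betas,
                   intercept = intercept, noise_sd = realised_noise_sd,
                   h2_expected = if (var_g + var_e > 0) var_g / (var_g + var_e)
                                 else NA_real_),
      clipping_rate = mean(clipped)
    )
  })
}
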