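# Independent brute-force oracles, deliberately written without reusing any
# riceval internals.

# textbook hexcone RGB->HSV, one pixel at a time
oracle_rgb_to_hsv_pixel <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else d / mx
  h <- if (d == 0) {
    0
  } else if (mx == r) {
    ((g - b) / d) %% 6 / 6
  } else if (mx == g) {
    ((b - r) / d + 2) / 6
  } else {
    ((r - g) / d + 4) / 6
  }
  c(h = h, s = s, v = v)
}

# per-pixel loop applying the hue-threshold rule
oracle_yellow_mask <- function(pixels, hue_threshold, saturation_gate = NULL) {
  d <- dim(pixels)
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      hsv <- oracle_rgb_to_hsv_pixel(pixels[i, j, 1], pixels[i, j, 2],
                                     pixels[i, j, 3])
      ok <- hsv["h"] < hue_threshold
      if (!is.null(saturation_gate)) ok <- ok && hsv["s"] >= saturation_gate
      mask[i, j] <- ok
    }
  }
  mask
}

# direct sums-of-squares loop for a balanced two-way layout without
# interaction (one value per cell)
oracle_two_way_ss <- function(df) {
  # df: variety, year, score (one row per cell)
  grand <- mean(df$score)
  vm <- tapply(df$score, df$variety, mean)
  ym <- tapply(df$score, df$year, mean)
  n_v <- length(vm); n_y <- length(ym)
  ss_variety <- n_y * sum((vm - grand)^2)
  ss_year <- n_v * sum((ym - grand)^2)
  ss_total <- sum((df$score - grand)^2)
  c(year = ss_year, variety = ss_variety,
    error = ss_total - ss_year - ss_variety, total = ss_total)
}

# exhaustive best-subset search via the normal equations (QR), independent
# of lm/lm.fit usage patterns in the package
oracle_best_subset_r2 <- function(X, y, k) {
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  best_r2 <- -Inf; best_set <- NULL
  for (set in combn(ncol(X), k, simplify = FALSE)) {
    A <- cbind(1, X[, set, drop = FALSE])
    beta <- qr.solve(crossprod(A), crossprod(A, y))
    rss <- sum((y - A %*% beta)^2)
    r2 <- 1 - rss / tss
    if (r2 > best_r2) { best_r2 <- r2; best_set <- set }
  }
  list(r2 = best_r2, set = best_set)
}

# analytic trapezoid areas of a sampled polyline restricted to a sign class,
# integrating across zero crossings exactly
oracle_signed_area <- function(t, f, positive = TRUE) {
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    f0 <- f[i]; f1 <- f[i + 1L]; dt <- t[i + 1L] - t[i]
    seg <- if (sign(f0) == sign(f1) || f0 == 0 || f1 == 0) {
      mean(c(f0, f1)) * dt
    } else {
      tc <- dt * abs(f0) / (abs(f0) + abs(f1))
      # contribution split at the crossing; keep the requested sign part below
      NA
    }
    if (is.na(seg)) {
      tc <- dt * abs(f0) / (abs(f0) + abs(f1))
      part0 <- 0.5 * f0 * tc
      part1 <- 0.5 * f1 * (dt - tc)
      if (positive) total <- total + max(part0, 0) + max(part1, 0)
      else total <- total + min(part0, 0) + min(part1, 0)
    } else {
      if (positive && f0 >= 0 && f1 >= 0) total <- total + seg
      if (!positive && f0 <= 0 && f1 <= 0) total <- total + seg
    }
  }
  total
}

# a small sensory table with known cell means, built directly
make_balanced_table <- function(n_varieties = 6, n_years = 2, n_reps = 2,
                                seed = 1) {
  set.seed(seed)
  grid <- expand.grid(variety = paste0("v", seq_len(n_varieties)),
                      year = 2020 + seq_len(n_years) - 1,
                      replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE)
  grid$trait <- "IVOE"
  grid$score <- round(runif(nrow(grid), -2, 1), 2)
  grid
}
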