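#' Parse a force curve from delimited text
#'
#' Reads a texture-analyzer export (comma- or tab-delimited) into a
#' `force_curve` tibble with columns `time` (s), `force` (gf) and, when
#' present, `displacement` (mm). Column names are matched case-insensitively
#' against common aliases, or given explicitly.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab from
#'   the first line.
#' @param time_col,force_col,displacement_col Column names in the file;
#'   `NULL` matches aliases (`time`/`t`/`sec`/`seconds`, `force`/`f`/`load`/
#'   `gf`, `displacement`/`distance`/`mm`).
#' @return A `force_curve` tibble.
#' @export
parse_force_curve <- function(path, sep = NULL, time_col = NULL,
                              force_col = NULL, displacement_col = NULL) {
  if (!file.exists(path)) stop_input("force-curve file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- tryCatch(
    read.csv(path, sep = sep, check.names = FALSE),
    error = function(e) stop_input("cannot parse '", path, "': ",
                                   conditionMessage(e))
  )
  find_col <- function(given, aliases, what, required = TRUE) {
    if (!is.null(given)) {
      if (!given %in% names(df)) {
        stop_input("column '", given, "' not found in ", path)
      }
      return(given)
    }
    hit <- which(tolower(names(df)) %in% aliases)
    if (length(hit) == 0L) {
      if (required) stop_input("no ", what, " column found in ", path,
                               " (looked for: ", paste(aliases, collapse = ", "), ")")
      return(NA_character_)
    }
    names(df)[hit[1]]
  }
  tc <- find_col(time_col, c("time", "t", "time_s", "sec", "seconds"), "time")
  fc <- find_col(force_col, c("force", "f", "load", "force_gf", "gf"), "force")
  dc <- find_col(displacement_col, c("displacement", "distance", "disp", "mm"),
                 "displacement", required = FALSE)
  out <- tibble(time = as.numeric(df[[tc]]), force = as.numeric(df[[fc]]))
  if (!is.na(dc)) out$displacement <- as.numeric(df[[dc]])
  as_force_curve(out, source = path)
}

#' Construct and validate a force curve
#'
#' @param x Data frame with numeric `time` (seconds, strictly increasing) and
#'   `force` (gram-force; negative during probe withdrawal), optionally
#'   `displacement` (mm). At least 10 samples, no missing values.
#' @param source Optional provenance string.
#' @return A `force_curve` tibble.
#' @export
as_force_curve <- function(x, source = NULL) {
  stopifnot(is.data.frame(x))
  if (!all(c("time", "force") %in% names(x))) {
    stop_input("force curve needs 'time' and 'force' columns")
  }
  if (nrow(x) < 10L) {
    stop_input("force curve too short: ", nrow(x), " samples (need >= 10)")
  }
  bad <- which(!is.finite(x$time) | !is.finite(x$force))
  if (length(bad)) stop_input("missing/non-numeric value at row ", bad[1])
  nonmono <- which(diff(x$time) <= 0)
  if (length(nonmono)) {
    stop_input("time not strictly increasing at row ", nonmono[1] + 1L)
  }
  out <- as_tibble(x[intersect(c("time", "force", "displacement"), names(x))])
  class(out) <- c("force_curve", class(out))
  attr(out, "source") <- source
  out
}

#' Segment a double-compression force curve into TPA windows
#'
#' Locates the two compression cycles by threshold crossings with hysteresis:
#' a cycle is recognised when force reaches the instrument trigger (default
#' 25 gf), and its window is the surrounding positive-force phase (entered
#' when force rises above 0, exited when it returns to 0 or below), which
#' prevents chatter near the trigger level. The adhesion window is the
#' contiguous negative-force run between the first and second cycles — the
#' probe-withdrawal phase whose area is adhesiveness. The first cycle is split
#' at its force peak into the downstroke (`down1`) and upstroke (`up1`)
#' sub-windows used for resilience.
#'
#' @param curve A `force_curve`.
#' @param trigger Trigger force in gf (default 25).
#' @return A `cycle_segmentation`: index windows `cycle1`, `adhesion`,
#'   `cycle2`, `down1`, `up1`, peak index `peak1`, and interpolated
#'   zero-crossing boundary times for each window.
#' @export
segment_cycles <- function(curve, trigger = 25) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is.numeric(trigger) || length(trigger) != 1L || trigger <= 0) {
    stop_config("trigger must be a single positive force (gf)")
  }
  t <- curve$time
  f <- curve$force
  n <- length(f)

  # Positive-force phases as index runs of f > 0
  pos <- f > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  phases <- Map(function(s, e) s:e, starts[r$values], ends[r$values])
  # Keep phases that reach the trigger (hysteresis: enter at >= trigger,
  # window extent is the whole positive run).
  supra <- purrr::keep(phases, function(idx) max(f[idx]) >= trigger)
  if (length(supra) < 2L) {
    stop_input("segmentation failed: found ", length(supra),
               " compression cycle(s) above the ", trigger,
               " gf trigger (need 2)")
  }
  cycle1 <- supra[[1]]
  cycle2 <- supra[[2]]

  # Contiguous negative run between the cycles (probe withdrawal)
  between <- (max(cycle1) + 1L):(min(cycle2) - 1L)
  between <- between[between >= 1L & between <= n]
  adhesion <- integer(0)
  if (length(between)) {
    neg <- f[between] < 0
    if (any(neg)) {
      rn <- rle(neg)
      en <- cumsum(rn$lengths)
      sn <- en - rn$lengths + 1L
      runs <- Map(function(s, e) between[s:e], sn[rn$values], en[rn$values])
      adhesion <- runs[[which.max(lengths(runs))]]
    }
  }

  peak1 <- cycle1[which.max(f[cycle1])]
  structure(
    list(
      cycle1 = cycle1, cycle2 = cycle2, adhesion = adhesion,
      down1 = cycle1[cycle1 <= peak1], up1 = cycle1[cycle1 >= peak1],
      peak1 = peak1,
      bounds = list(
        cycle1 = crossing_bounds(t, f, cycle1),
        cycle2 = crossing_bounds(t, f, cycle2),
        adhesion = if (length(adhesion)) crossing_bounds(t, f, adhesion)
      ),
      trigger = trigger
    ),
    class = "cycle_segmentation"
  )
}

# Zero-crossing times bracketing an index window, by linear interpolation
# against the neighbouring samples. Exact for piecewise-linear curves.
crossing_bounds <- function(t, f, idx) {
  i0 <- idx[1]
  i1 <- idx[length(idx)]
  t_lo <- t[i0]
  if (i0 > 1L && sign(f[i0 - 1L]) != sign(f[i0]) && f[i0] != f[i0 - 1L]) {
    t_lo <- t[i0 - 1L] + (0 - f[i0 - 1L]) * (t[i0] - t[i0 - 1L]) / (f[i0] - f[i0 - 1L])
  }
  t_hi <- t[i1]
  if (i1 < length(t) && sign(f[i1 + 1L]) != sign(f[i1]) && f[i1 + 1L] != f[i1]) {
    t_hi <- t[i1] + (0 - f[i1]) * (t[i1 + 1L] - t[i1]) / (f[i1 + 1L] - f[i1])
  }
  c(t_lo, t_hi)
}

# Trapezoidal force-time area over a window, extended to the interpolated
# zero crossings at both edges.
window_area <- function(t, f, idx, bounds) {
  a <- if (length(idx) > 1L) pracma::trapz(t[idx], f[idx]) else 0
  i0 <- idx[1]
  i1 <- idx[length(idx)]
  if (bounds[1] < t[i0]) a <- a + 0.5 * f[i0] * (t[i0] - bounds[1])
  if (bounds[2] > t[i1]) a <- a + 0.5 * f[i1] * (bounds[2] - t[i1])
  a
}

#' Compute TPA features from a segmented force curve
#'
#' Extracts the standard double-compression texture-profile descriptors.
#' With force in gf integrated over time in s:
#'
#' * `A1`, `A2` — positive areas of compression cycles 1 and 2 (gf s)
#' * `A3` — negative withdrawal area after cycle 1; `adhesiveness = |A3|`,
#'   the objective proxy for sensory viscosity
#' * `A4`, `A5` — areas of the cycle-1 downstroke and upstroke
#'   (`A4 + A5 = A1`); `resilience = A5 / A4`
#' * `T1`, `T2` — durations of the two positive-force phases (s);
#'   `springiness = T2 / T1`
#' * `hardness` — peak force of cycle 1 (gf); `brittleness` — the largest
#'   local maximum strictly before the hardness peak (NA when none)
#' * `cohesiveness = A2 / A1`; `gumminess = cohesiveness * hardness`;
#'   `chewiness = gumminess * springiness`
#'
#' Areas are trapezoidal with linear interpolation to the zero crossings at
#' window edges, so piecewise-linear curves integrate exactly. Undefined
#' ratios (zero denominators) come back as `NA`, never as an error.
#'
#' @param curve A `force_curve`.
#' @param seg A `cycle_segmentation`; computed from `curve` if omitted.
#' @param trigger Trigger force (gf) used when `seg` is omitted.
#' @param brittleness_prominence Minimum prominence of a pre-peak local
#'   maximum, as a fraction of hardness (default 0.05), so noise ripples do
#'   not register as brittleness.
#' @return One-row tibble of features (class `tpa_features`).
#' @export
#' @examples
#' sim <- simulate_force_curve(hardness = 500, adhesiveness = 100, seed = 1)
#' compute_tpa(sim$curve)
compute_tpa <- function(curve, seg = NULL, trigger = 25,
                        brittleness_prominence = 0.05) {
  stopifnot(inherits(curve, "force_curve"))
  seg <- seg %||% segment_cycles(curve, trigger)
  t <- curve$time
  f <- curve$force

  b1 <- seg$bounds$cycle1
  b2 <- seg$bounds$cycle2
  A1 <- window_area(t, f, seg$cycle1, b1)
  A2 <- window_area(t, f, seg$cycle2, b2)
  T1 <- b1[2] - b1[1]
  T2 <- b2[2] - b2[1]
  hardness <- max(f[seg$cycle1])
  tpk <- t[seg$peak1]
  A4 <- window_area(t, f, seg$down1, c(b1[1], tpk))
  A5 <- window_area(t, f, seg$up1, c(tpk, b1[2]))
  A3 <- if (length(seg$adhesion)) {
    window_area(t, f, seg$adhesion, seg$bounds$adhesion)
  } else 0
  adhesiveness <- abs(A3)

  brittleness <- pre_peak_maximum(f, seg$cycle1, seg$peak1,
                                  brittleness_prominence * hardness)

  ratio <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  springiness <- ratio(T2, T1)
  cohesiveness <- ratio(A2, A1)
  resilience <- ratio(A5, A4)
  gumminess <- cohesiveness * hardness
  chewiness <- gumminess * springiness

  out <- tibble(
    hardness = hardness, brittleness = brittleness,
    adhesiveness = adhesiveness,
    springiness = springiness, cohesiveness = cohesiveness,
    gumminess = gumminess, chewiness = chewiness, resilience = resilience,
    A1 = A1, A2 = A2, A3 = abs(A3), A4 = A4, A5 = A5, T1 = T1, T2 = T2
  )
  class(out) <- c("tpa_features", class(out))
  out
}

# Largest local maximum strictly before the hardness peak with at least the
# given prominence and a value below hardness; NA_real_ when none qualifies.
pre_peak_maximum <- function(f, cycle, peak, min_prom) {
  idx <- cycle[cycle < peak]
  if (length(idx) < 3L) return(NA_real_)
  fi <- f[idx]
  cand <- which(diff(sign(diff(fi))) < 0) + 1L   # interior local maxima
  if (!length(cand)) return(NA_real_)
  hardness <- f[peak]
  best <- NA_real_
  for (k in cand) {
    val <- fi[k]
    if (val >= hardness) next
    # prominence within the cycle: drop to the lowest point between the
    # candidate and higher ground on each side
    left <- fi[seq_len(k - 1L)]
    higher_l <- which(left > val)
    left_min <- if (length(higher_l)) min(fi[(max(higher_l)):(k)]) else min(fi[1:k])
    right <- fi[(k + 1L):length(fi)]
    higher_r <- which(right > val)
    right_min <- if (length(higher_r)) min(fi[k:(k + min(higher_r))]) else min(right)
    prom <- val - max(left_min, right_min)
    if (prom >= min_prom && (is.na(best) || val > best)) best <- val
  }
  best
}

#' TPA features for a batch of force curves
#'
#' Parses each file (or takes in-memory `force_curve`s), computes per-curve
#' features, averages replicates per sample, and — when a control sample is
#' named — records each sample's feature differences from the control, the
#' batch-correction convention used when samples are measured against a
#' shared reference.
#'
#' @param x Character vector of file paths or list of `force_curve` objects.
#' @param sample Sample identifiers, recycled against `x`; default one sample
#'   per curve.
#' @param control Optional sample id to use as the control; per-sample mean
#'   differences (`sample - control`) are reported for every numeric feature.
#' @param trigger Trigger force (gf).
#' @param ... Passed to [parse_force_curve()] for file input.
#' @return A list of tibbles (class `tpa_batch`): `features` (per curve),
#'   `sample_means`, and `vs_control` (NULL when no control given). Files
#'   that fail to parse or segment are reported with a warning and skipped;
#'   if all fail, an error is raised.
#' @export
batch_tpa <- function(x, sample = NULL, control = NULL, trigger = 25, ...) {
  if (inherits(x, "force_curve")) x <- list(x)
  n <- length(x)
  if (n == 0L) stop_input("no force curves supplied")
  sample <- rep_len(as.character(sample %||% seq_len(n)), n)

  rows <- purrr::map(seq_len(n), function(i) {
    res <- tryCatch({
      cv <- if (is.character(x)) parse_force_curve(x[[i]], ...) else x[[i]]
      compute_tpa(cv, trigger = trigger)
    }, error = function(e) {
      warning("curve ", i, " (", sample[i], ") skipped: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) return(NULL)
    dplyr::mutate(res, sample = sample[i], replicate = NA_integer_, .before = 1)
  })
  rows <- purrr::compact(rows)
  if (!length(rows)) stop_input("all ", n, " force curves failed")
  feats <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(replicate = dplyr::row_number()) |>
    dplyr::ungroup()

  means <- feats |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                   !dplyr::any_of("replicate"),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_replicates = dplyr::n(), .groups = "drop")

  vs_control <- NULL
  if (!is.null(control)) {
    if (!control %in% means$sample) {
      stop_input("control sample '", control, "' not found in batch")
    }
    ctrl <- dplyr::filter(means, .data$sample == control)
    num <- setdiff(names(means)[purrr::map_lgl(means, is.numeric)],
                   "n_replicates")
    vs_control <- means
    for (col in num) vs_control[[col]] <- means[[col]] - ctrl[[col]]
    vs_control$control <- control
  }

  structure(list(features = feats, sample_means = means,
                 vs_control = vs_control),
            class = "tpa_batch")
}
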