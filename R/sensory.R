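#' Validate a long-format sensory-panel score table
#'
#' Panels score cooked rice for the integrated value of organoleptic
#' evaluation (IVOE) and its component traits against a reference variety on
#' a -3..+3 scale. The canonical long format has one row per
#' (variety, year, replicate, trait).
#'
#' @param x Data frame with columns `variety`, `year`, `replicate`, `trait`,
#'   `score`; scores must lie in `[-3, 3]` and keys must be unique.
#' @return The validated tibble (class `sensory_table`).
#' @export
as_sensory_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("variety", "year", "replicate", "trait", "score")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop_input("sensory table missing column(s): ",
               paste(missing, collapse = ", "))
  }
  if (any(!is.finite(x$score))) stop_input("sensory scores contain missing values")
  if (any(x$score < -3 | x$score > 3)) {
    stop_input("sensory scores outside the [-3, 3] scale")
  }
  keys <- paste(x$variety, x$year, x$replicate, x$trait)
  if (anyDuplicated(keys)) {
    stop_input("duplicate (variety, year, replicate, trait) rows")
  }
  out <- as_tibble(x)
  class(out) <- unique(c("sensory_table", class(out)))
  out
}

#' Two-way ANOVA of panel scores (Year + Variety)
#'
#' Additive decomposition of one trait's scores into Year, Variety and Error,
#' the layout used for multi-environment variety panels. By default sensory
#' replicates are averaged to one value per variety-year cell first, so with
#' v varieties and y years the degrees of freedom are `y - 1`, `v - 1` and
#' `(y - 1)(v - 1)` — e.g. 1 / 321 / 321 for a 322-variety, two-year panel.
#' Both F statistics test against the error mean square.
#'
#' @param data A sensory table (see [as_sensory_table()]).
#' @param trait Trait to analyse (e.g. `"IVOE"`).
#' @param average_replicates Average replicate scores within each
#'   variety-year cell before fitting (default `TRUE`, matching the
#'   no-replicate-term layout). With `FALSE`, raw replicates are kept and
#'   pooled into the error term.
#' @return Tibble (class `rice_anova`) with one row per source
#'   (`Year`, `Variety`, `Error`, `Total`): `df`, `ss`, `ms`, `f`, `p`.
#'   The replicate mode and trait are carried as attributes.
#' @export
anova_two_way <- function(data, trait, average_replicates = TRUE) {
  data <- as_sensory_table(data)
  d <- dplyr::filter(data, .data$trait == !!trait)
  if (nrow(d) == 0L) stop_input("no rows for trait '", trait, "'")

  cells <- tidyr::expand_grid(variety = unique(d$variety),
                              year = unique(d$year))
  have <- dplyr::distinct(d, .data$variety, .data$year)
  miss <- dplyr::anti_join(cells, have, by = c("variety", "year"))
  if (nrow(miss)) {
    stop_input("unbalanced design: missing variety x year cell(s), e.g. ",
               paste(head(paste(miss$variety, miss$year, sep = "/"), 3),
                     collapse = ", "))
  }

  if (average_replicates) {
    d <- d |>
      dplyr::group_by(.data$variety, .data$year) |>
      dplyr::summarise(score = mean(.data$score), .groups = "drop")
  }

  fit <- aov(score ~ factor(year) + factor(variety), data = d)
  sm <- summary(fit)[[1]]
  ss <- sm[["Sum Sq"]]
  df <- sm[["Df"]]
  ms <- ss / df
  f <- c(ms[1] / ms[3], ms[2] / ms[3])
  p <- pf(f, df[1:2], df[3], lower.tail = FALSE)
  if (ms[3] <= .Machine$double.eps * (mean(d$score)^2 + 1)) {
    f <- c(NA_real_, NA_real_)
    p <- c(NA_real_, NA_real_)
  }
  out <- tibble(
    source = c("Year", "Variety", "Error", "Total"),
    df = c(df, sum(df)),
    ss = c(ss, sum(ss)),
    ms = c(ms, NA_real_),
    f = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_)
  )
  class(out) <- c("rice_anova", class(out))
  attr(out, "trait") <- trait
  attr(out, "replicates_averaged") <- average_replicates
  out
}

#' Recompute F statistics of an ANOVA table from its sums of squares
#'
#' Applies `F = (SS/df) / (SS_error/df_error)` to each non-error source —
#' useful for checking the internal consistency of published ANOVA tables,
#' where printed mean squares are often rounded too aggressively to recover
#' F from.
#'
#' @param tbl Tibble with columns `source`, `df`, `ss` (one ANOVA; `Error`
#'   row required).
#' @return The table with an `f_recomputed` column (NA for Error/Total).
#' @export
anova_f_from_ss <- function(tbl) {
  stopifnot(is.data.frame(tbl), all(c("source", "df", "ss") %in% names(tbl)))
  err <- tbl[tbl$source == "Error", ]
  if (nrow(err) != 1L) stop_input("need exactly one Error row")
  ms_e <- err$ss / err$df
  dplyr::mutate(
    as_tibble(tbl),
    f_recomputed = dplyr::if_else(
      .data$source %in% c("Error", "Total"), NA_real_,
      (.data$ss / .data$df) / ms_e
    )
  )
}

#' Broad-sense heritability from ANOVA mean squares
#'
#' Expected-mean-square estimator treating variety as a random effect:
#' `var_G = max(0, (MS_variety - MS_error) / r)` with `r` the number of
#' replications per variety entering the variety mean square, `var_E =
#' MS_error`, and `h2 = var_G / (var_G + var_E)`. Negative variance
#' components are truncated to zero, so `h2` always lies in `[0, 1]`.
#'
#' @param anova A `rice_anova` (or any tibble with `source`, `df`, `ss`)
#'   containing `Variety` and `Error` rows.
#' @param r_reps Replications per variety behind the variety mean square.
#'   Defaults to 2: in the two-year panel layout the years act as the
#'   replication effect.
#' @return One-row tibble: `var_g`, `var_e`, `r_reps`, `h2`.
#' @export
broad_sense_h2 <- function(anova, r_reps = 2) {
  stopifnot(is.data.frame(anova))
  if (!all(c("Variety", "Error") %in% anova$source)) {
    stop_input("ANOVA table must contain Variety and Error rows")
  }
  if (!is.numeric(r_reps) || r_reps < 1) {
    stop_config("r_reps must be >= 1")
  }
  ms <- function(src) {
    row <- anova[anova$source == src, ]
    row$ss / row$df
  }
  ms_v <- ms("Variety")
  ms_e <- ms("Error")
  var_g <- max(0, (ms_v - ms_e) / r_reps)
  var_e <- ms_e
  h2 <- if (var_g + var_e == 0) NA_real_ else var_g / (var_g + var_e)
  tibble(var_g = var_g, var_e = var_e, r_reps = r_reps, h2 = h2)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Equal-length numeric vectors (>= 3 complete pairs). Pairs with
#'   missing values are dropped.
#' @param pair Optional label for the pair (e.g. `"IVOE~viscosity"`).
#' @return One-row tibble: `pair`, `r`, `n`, `p`. Zero variance in either
#'   vector gives `r = NA` with a warning, not an error.
#' @export
pearson <- function(x, y, pair = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_input("need >= 3 complete pairs, got ", n)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(tibble(pair = pair, r = NA_real_, n = n, p = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(pair = pair, r = unname(ct$estimate), n = n, p = ct$p.value)
}

#' Paired t test between two measurement methods
#'
#' Two-sided t test on paired differences with a 95% confidence interval for
#' the mean difference — the comparison used to check instrument-derived
#' scores against sensory-panel values. Zero-variance differences are
#' flagged (`degenerate = TRUE`) rather than raised as an error: the CI then
#' collapses to a point and `t` is 0 (all differences zero) or infinite.
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 2`.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `conf_low`,
#'   `conf_high`, `degenerate`.
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop_input("x and y must be the same length")
  d <- x - y
  n <- length(d)
  if (n < 2L) stop_input("need >= 2 pairs")
  m <- mean(d)
  if (sd(d) <= 1e-10 * (abs(m) + 1e-100)) {
    return(tibble(
      t = if (m == 0) 0 else Inf * sign(m), df = n - 1,
      p = if (m == 0) 1 else 0,
      mean_diff = m, conf_low = m, conf_high = m, degenerate = TRUE
    ))
  }
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_diff = unname(tt$estimate),
    conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
    degenerate = FALSE
  )
}

#' Pairwise trait correlations of per-variety means
#'
#' Averages each trait over years and replicates to one value per variety,
#' then computes the pairwise-complete Pearson correlation between every
#' trait pair.
#'
#' @param data A sensory table (see [as_sensory_table()]).
#' @return Long tibble (class `trait_cor`): `trait1`, `trait2`, `r`, `n`,
#'   `p`; symmetric with unit diagonal. Constant traits are flagged with
#'   `r = NA` and a warning. Use [as.matrix()] for the square form.
#' @export
trait_correlation_matrix <- function(data) {
  data <- as_sensory_table(data)
  wide <- data |>
    dplyr::group_by(.data$variety, .data$trait) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "score")
  traits <- setdiff(names(wide), "variety")
  grid <- tidyr::expand_grid(trait1 = traits, trait2 = traits)
  out <- purrr::pmap(grid, function(trait1, trait2) {
    x <- wide[[trait1]]
    y <- wide[[trait2]]
    if (trait1 == trait2) {
      return(tibble(trait1 = trait1, trait2 = trait2,
                    r = 1, n = sum(is.finite(x)), p = NA_real_))
    }
    res <- suppressWarnings(pearson(x, y))
    tibble(trait1 = trait1, trait2 = trait2, r = res$r, n = res$n, p = res$p)
  }) |> dplyr::bind_rows()
  if (any(is.na(out$r[out$trait1 != out$trait2]))) {
    warning("one or more constant traits: correlations flagged NA",
            call. = FALSE)
  }
  class(out) <- c("trait_cor", class(out))
  out
}

#' @export
as.matrix.trait_cor <- function(x, ...) {
  wide <- tidyr::pivot_wider(as_tibble(x)[c("trait1", "trait2", "r")],
                             names_from = "trait2", values_from = "r")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$trait1
  m
}

#' Published ANOVA decomposition of the 322-variety Geng rice panel
#'
#' The year/variety/error sums of squares reported for the IVOE and its five
#' component traits in the two-year, 322-variety Geng rice eating-quality
#' study (one value per variety-year cell; df 1/321/321). Shipped as
#' reference constants so the internal consistency of the table — in
#' particular the variety F statistics, which equal `SS_variety / SS_error`
#' at equal df — can be checked with [anova_f_from_ss()].
#'
#' Note the printed mean squares in the original table are rounded too
#' coarsely to reproduce F (e.g. the IVOE variety MS prints as 0.3 although
#' 50.03/321 = 0.156); the sums of squares, not the printed MS, are the
#' consistent quantities.
#'
#' @return Tibble: `trait`, `source`, `df`, `ss`, `f_printed` (NA for
#'   Error/Total rows).
#' @export
published_sensory_anova <- function() {
  rows <- list(
    list("IVOE",       8.71, 50.03, 16.87, 75.62, 86.20, 2.96),
    list("appearance", 2.06, 29.33, 18.28, 49.66, 18.84, 1.60),
    list("viscosity",  5.24, 29.43, 11.32, 45.99, 77.34, 2.60),
    list("taste",      3.49, 33.12, 15.73, 52.33, 37.03, 2.11),
    list("hardness",   7.03, 19.75, 18.36, 45.14, 63.94, 1.08),
    list("fragrance",  3.29, 15.59,  9.82, 28.70, 55.93, 1.59)
  )
  purrr::map(rows, function(r) {
    tibble(
      trait = r[[1]],
      source = c("Year", "Variety", "Error", "Total"),
      df = c(1, 321, 321, 643),
      ss = c(r[[2]], r[[3]], r[[4]], r[[5]]),
      f_printed = c(r[[6]], r[[7]], NA_real_, NA_real_)
    )
  }) |> dplyr::bind_rows()
}
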