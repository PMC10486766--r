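# texture-profile-analysis feature extraction

# triangle cycle1 (peak 500 gf, base 2 s), rectangle-ish dip handled by the
# generator; here an explicit hand-built curve for closed-form checks
make_triangle_curve <- function(dt = 0.001) {
  # 0.5 s lead-in, triangle to 500 over 2 s, dip to -100 x 1 s (rectangle
  # with sharp edges approximated by near-vertical ramps), triangle to 400
  # over 1.5 s
  bp_t <- c(0, 0.5, 1.5, 2.5, 2.5001, 3.4999, 3.5, 3.8, 4.55, 5.3, 5.6)
  bp_f <- c(0, 0, 500, 0, -100, -100, 0, 0, 400, 0, 0)
  tt <- sort(c(seq(0, 5.6, by = dt), bp_t))
  tt <- tt[c(TRUE, diff(tt) > 1e-9)]
  as_force_curve(data.frame(time = tt, force = approx(bp_t, bp_f, tt)$y))
}

test_that("parse_force_curve reads comma and tab dialects identically", {
  d <- withr::local_tempdir()
  df <- data.frame(time = seq(0, 0.99, by = 0.01), force = sin(1:100))
  fc <- file.path(d, "c.csv")
  write.csv(df, fc, row.names = FALSE)
  ft <- file.path(d, "t.tsv")
  write.table(data.frame(Seconds = df$time, Load = df$force), ft,
              sep = "\t", row.names = FALSE)
  c1 <- parse_force_curve(fc)
  c2 <- parse_force_curve(ft)
  expect_equal(nrow(c1), 100)
  expect_equal(c1$time, c2$time)
  expect_equal(c1$force, c2$force)
})

test_that("non-monotone time and missing values are errors citing the row", {
  d <- withr::local_tempdir()
  df <- data.frame(time = seq(0, 1.1, by = 0.1), force = 1:12)
  df$time[7] <- df$time[5]   # time goes backwards at row 7
  f <- file.path(d, "bad.csv")
  write.csv(df, f, row.names = FALSE)
  expect_error(parse_force_curve(f), "row 7", class = "riceval_input_error")

  df2 <- data.frame(time = seq(0, 1.1, by = 0.1), force = 1:12)
  df2$force[4] <- NA
  write.csv(df2, f, row.names = FALSE)
  expect_error(parse_force_curve(f), "row 4", class = "riceval_input_error")

  write.csv(data.frame(a = 1:20, b = 1:20), f, row.names = FALSE)
  expect_error(parse_force_curve(f), "time", class = "riceval_input_error")
})

test_that("segment_cycles finds the two compressions and the adhesion dip", {
  cv <- make_triangle_curve(dt = 0.01)
  seg <- segment_cycles(cv)
  f <- cv$force
  expect_true(all(f[seg$cycle1] > 0))
  expect_true(all(f[seg$cycle2] > 0))
  expect_true(all(f[seg$adhesion] < 0))
  expect_lt(max(seg$cycle1), min(seg$adhesion))
  expect_lt(max(seg$adhesion), min(seg$cycle2))
  expect_equal(cv$time[seg$peak1], 1.5)
})

test_that("curves without two supra-trigger cycles fail segmentation", {
  one_pulse <- as_force_curve(data.frame(
    time = seq(0, 2, by = 0.01),
    force = pmax(0, 500 * (1 - abs(seq(0, 2, by = 0.01) - 1)))
  ))
  seg_err <- tryCatch(segment_cycles(one_pulse), error = identity)
  expect_s3_class(seg_err, "riceval_input_error")

  flat <- as_force_curve(data.frame(time = seq(0, 2, by = 0.01), force = 0))
  expect_error(segment_cycles(flat), class = "riceval_input_error")

  # sub-trigger bumps are ignored by the hysteresis rule
  low <- as_force_curve(data.frame(
    time = seq(0, 2, by = 0.01),
    force = 10 * sin(seq(0, 2, by = 0.01) * 10)^2
  ))
  expect_error(segment_cycles(low), class = "riceval_input_error")
})

test_that("closed-form triangle/rectangle curve yields the textbook features", {
  f <- compute_tpa(make_triangle_curve())
  expect_equal(f$hardness, 500)
  expect_equal(f$A1, 500, tolerance = 1e-3)
  expect_equal(f$adhesiveness, 100, tolerance = 1e-3)
  expect_equal(f$T1, 2, tolerance = 1e-4)
  expect_equal(f$T2, 1.5, tolerance = 1e-4)
  expect_equal(f$springiness, 0.75, tolerance = 1e-4)
  expect_equal(f$A2, 300, tolerance = 1e-3)
  expect_equal(f$cohesiveness, 0.6, tolerance = 1e-4)
  expect_equal(f$gumminess, 300, tolerance = 1e-3)
  expect_equal(f$chewiness, 225, tolerance = 1e-3)
  expect_equal(f$A4, 250, tolerance = 1e-3)
  expect_equal(f$A5, 250, tolerance = 1e-3)
  expect_equal(f$resilience, 1, tolerance = 1e-4)
  expect_true(is.na(f$brittleness))   # monotone ramp, no pre-peak maximum
})

test_that("force scaling is homogeneous of degree one in force features", {
  cv <- make_triangle_curve(dt = 0.005)
  cv2 <- as_force_curve(data.frame(time = cv$time, force = 2 * cv$force))
  f1 <- compute_tpa(cv)
  f2 <- compute_tpa(cv2)
  for (col in c("hardness", "A1", "A2", "A3", "A4", "A5", "adhesiveness",
                "gumminess", "chewiness")) {
    expect_equal(f2[[col]], 2 * f1[[col]], tolerance = 1e-10)
  }
  for (col in c("springiness", "cohesiveness", "resilience", "T1", "T2")) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-10)
  }
})

test_that("features are invariant to time translation", {
  cv <- make_triangle_curve(dt = 0.005)
  shifted <- as_force_curve(data.frame(time = cv$time + 7.3, force = cv$force))
  expect_equal(as.data.frame(compute_tpa(cv)),
               as.data.frame(compute_tpa(shifted)), tolerance = 1e-12)
})

test_that("areas agree with the signed-area oracle and converge in sampling", {
  cv_fine <- make_triangle_curve(dt = 0.001)    # ~1 kHz
  cv_coarse <- make_triangle_curve(dt = 0.01)   # ~100 Hz
  ff <- compute_tpa(cv_fine)
  fc <- compute_tpa(cv_coarse)
  # oracle: total positive / negative signed areas over the whole record
  expect_equal(ff$A1 + ff$A2,
               oracle_signed_area(cv_fine$time, cv_fine$force, TRUE),
               tolerance = 1e-6)
  expect_equal(-ff$A3,
               oracle_signed_area(cv_fine$time, cv_fine$force, FALSE),
               tolerance = 1e-6)
  for (col in c("hardness", "A1", "A2", "A3", "A4", "A5", "T1", "T2",
                "adhesiveness", "springiness", "cohesiveness", "resilience")) {
    expect_equal(fc[[col]], ff[[col]], tolerance = 0.01)
  }
})

test_that("generator ground truth is recovered across a seeded parameter sweep", {
  set.seed(202)
  for (i in 1:50) {
    sim <- simulate_force_curve(
      hardness = runif(1, 100, 2000),
      adhesiveness = runif(1, 20, 1500),
      t1 = runif(1, 0.5, 3), t2 = runif(1, 0.4, 2.5),
      cohesiveness = runif(1, 0.2, 0.9),
      adhesion_time = runif(1, 0.3, 2),
      sample_rate = sample(c(100, 250, 500), 1),
      seed = i
    )
    got <- compute_tpa(sim$curve)
    for (col in c("hardness", "A1", "A2", "A3", "A4", "A5", "T1", "T2",
                  "adhesiveness")) {
      expect_equal(got[[col]], sim$truth[[col]],
                   tolerance = 1e-3, label = paste(col, "at sweep", i))
    }
    # definitional identities, exactly as computed
    expect_identical(got$gumminess, got$cohesiveness * got$hardness)
    expect_identical(got$chewiness, got$gumminess * got$springiness)
  }
})

test_that("brittleness reports a qualifying pre-peak maximum and only then", {
  # shoulder peak at 200 gf before the 500 gf main peak
  bp_t <- c(0, 0.3, 0.8, 1.0, 1.6, 2.3, 2.35, 2.9, 2.95, 3.4, 3.9, 4.2)
  bp_f <- c(0, 0, 200, 120, 500, 0, -50, -50, 0, 300, 0, 0)
  tt <- sort(unique(c(seq(0, 4.2, by = 0.002), bp_t)))
  cv <- as_force_curve(data.frame(time = tt, force = approx(bp_t, bp_f, tt)$y))
  f <- compute_tpa(cv)
  expect_equal(f$brittleness, 200, tolerance = 1e-6)
  expect_equal(f$hardness, 500)

  # a 1%-of-hardness ripple is below the prominence floor -> undefined
  bp_f2 <- c(0, 0, 5, 2, 500, 0, -50, -50, 0, 300, 0, 0)
  cv2 <- as_force_curve(data.frame(time = tt, force = approx(bp_t, bp_f2, tt)$y))
  expect_true(is.na(compute_tpa(cv2)$brittleness))
})

test_that("batch_tpa averages replicates and compares against a control", {
  sims <- lapply(1:4, function(i) simulate_force_curve(seed = 7)$curve)
  b <- batch_tpa(sims, sample = rep("A", 4))
  expect_equal(nrow(b$features), 4)
  expect_equal(b$sample_means$adhesiveness, b$features$adhesiveness[1])

  # two samples with adhesiveness 100 and 300 -> means straddle; control
  # differences vanish on the control itself
  s1 <- simulate_force_curve(adhesiveness = 100, seed = 1)$curve
  s2 <- simulate_force_curve(adhesiveness = 300, seed = 2)$curve
  b2 <- batch_tpa(list(s1, s2, s1, s2), sample = c("A", "B", "A", "B"),
                  control = "A")
  expect_equal(sort(b2$sample_means$adhesiveness), c(100, 300),
               tolerance = 1e-6)
  ctrl_row <- b2$vs_control[b2$vs_control$sample == "A", ]
  num <- vapply(ctrl_row, is.numeric, logical(1))
  expect_true(all(abs(unlist(ctrl_row[num & names(ctrl_row) != "n_replicates"])) < 1e-9,
                  na.rm = TRUE))
  expect_equal(b2$vs_control$adhesiveness[b2$vs_control$sample == "B"], 200,
               tolerance = 1e-6)

  # mean of adhesiveness 100 and 300 within one sample is 200
  b3 <- batch_tpa(list(s1, s2), sample = c("S", "S"))
  expect_equal(b3$sample_means$adhesiveness, 200, tolerance = 1e-6)
})

test_that("unparsable curves are skipped with a warning, all-failed errors", {
  d <- withr::local_tempdir()
  good <- file.path(d, "good.csv")
  write.csv(simulate_force_curve(seed = 3)$curve, good, row.names = FALSE)
  bad <- file.path(d, "bad.csv")
  writeLines("nonsense", bad)
  expect_warning(b <- batch_tpa(c(good, bad)), "skipped")
  expect_equal(nrow(b$features), 1)
  expect_error(suppressWarnings(batch_tpa(c(bad, bad))),
               class = "riceval_input_error")
})
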