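test_that("fusion fraction is span sum per 10M reads, TICs excluded", {
  v <- fake_validated(c(10, 20, 30), c("INTER", "INTRA", "INTER"))
  expect_equal(fusion_fraction(v, 2e7, min_recommended_reads = 0)$fusion_fraction, 30)

  # TICs contribute nothing; unvalidated rows contribute nothing
  v2 <- fake_validated(c(10, 20, 30, 100), c("INTER", "INTRA", "INTER", "TIC"))
  expect_equal(fusion_fraction(v2, 2e7, min_recommended_reads = 0)$fusion_fraction, 30)
  v3 <- fake_validated(c(10, 20), c("INTER", "INTER"), validated = c(TRUE, FALSE))
  expect_equal(fusion_fraction(v3, 1e7, min_recommended_reads = 0)$fusion_fraction, 10)

  expect_equal(fusion_fraction(v[0, ], 2e7, min_recommended_reads = 0)$fusion_fraction, 0)
  expect_error(fusion_fraction(v, 0), "positive")
  expect_warning(fusion_fraction(v, 3e7), "40 M")

  # fusion-count mode
  expect_equal(fusion_fraction(v, 2e7, mode = "fusion_count",
                               min_recommended_reads = 0)$fusion_fraction,
               3 / 2)
})

test_that("fusion fraction is scale invariant in spans and read totals", {
  set.seed(81)
  for (i in 1:10) {
    n <- sample(1:8, 1)
    v <- fake_validated(sample(1:60, n, TRUE),
                        sample(c("INTER", "INTRA"), n, TRUE))
    reads <- sample(2e7:1.2e8, 1)
    ff <- fusion_fraction(v, reads, min_recommended_reads = 0)$fusion_fraction
    for (fac in c(2, 5, 10)) {
      v2 <- v
      v2$span_count <- v2$span_count * fac
      expect_equal(fusion_fraction(v2, reads * fac,
                                   min_recommended_reads = 0)$fusion_fraction, ff)
    }
  }
})

test_that("high-FF flag uses a strict 2x control rule", {
  expect_true(high_ff(5.5, 2.0))
  expect_false(high_ff(4.0, 2.0))   # exactly 2x is not high
  expect_false(high_ff(3.9, 2.0))
  set.seed(82)
  ff <- runif(50, 0, 10)
  ctl <- runif(1, 0.1, 3)
  expect_equal(high_ff(ff, ctl), ff > 2 * ctl)
  expect_equal(high_ff(ff, ctl, multiplier = 3), ff > 3 * ctl)
})

test_that("KM curves are valid step functions and the split rule is literal", {
  set.seed(83)
  recs <- tibble::tibble(sample_id = sprintf("S%02d", 1:12),
                         time = c(5, 8, 12, 20, 30, 33, 40, 45, 50, 60, 70, 80),
                         event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                   FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
                         ff = c(9, 8, 5, 3, 2.71, 2.7, 2.2, 2, 1.5, 1, 0.5, 0.1))
  fit <- km_stratify(recs)
  # ff > 2.7 goes high; exactly 2.7 goes low
  expect_equal(fit$groups[["HIGH_FF"]], 5L)
  expect_equal(fit$groups[["LOW_FF"]], 7L)
  curves <- tidy(fit)
  for (g in c("HIGH_FF", "LOW_FF")) {
    s <- curves$survival[curves$group == g]
    expect_equal(s[1], 1)                  # S(0) = 1
    expect_true(all(diff(s) <= 1e-12))     # non-increasing
    expect_true(all(s >= 0 & s <= 1))
  }
  g <- glance(fit)
  expect_equal(g$statistic, fit$chisq)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")

  # {1,2,3,4} at threshold 2.7: the two samples above 2.7 are high
  quick <- km_stratify(tibble::tibble(sample_id = letters[1:4],
                                      time = c(1, 2, 3, 4), event = TRUE,
                                      ff = c(1, 2, 3, 4)))
  expect_equal(quick$groups[["HIGH_FF"]], 2L)

  expect_error(km_stratify(tibble::tibble(sample_id = "a", time = 1,
                                          event = TRUE, ff = 10)), "per group")
})

test_that("log-rank statistic is zero for identical groups and label-symmetric", {
  times <- c(3, 6, 9, 14, 20, 28)
  events <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  recs <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    time = rep(times, 2), event = rep(events, 2),
    group = rep(c("HIGH_FF", "LOW_FF"), each = 6))
  fit <- km_stratify(recs)
  expect_equal(fit$chisq, 0)

  set.seed(84)
  recs2 <- tibble::tibble(sample_id = sprintf("S%02d", 1:20),
                          time = sample(1:50, 20), event = runif(20) < 0.7,
                          group = sample(c("HIGH_FF", "LOW_FF"), 20, TRUE,
                                         prob = c(0.4, 0.6)))
  fit_a <- km_stratify(recs2)
  recs2$group <- ifelse(recs2$group == "HIGH_FF", "LOW_FF", "HIGH_FF")
  fit_b <- km_stratify(recs2)
  expect_equal(fit_a$chisq, fit_b$chisq)
})

test_that("log-rank and KM agree with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(85)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    recs <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                           time = sample(1:60, n, TRUE),
                           event = runif(n) < 0.7,
                           ff = runif(n, 0, 6))
    if (length(unique(recs$ff > 2.7)) < 2) next
    fit <- km_stratify(recs)
    grp <- factor(ifelse(recs$ff > 2.7, "HIGH_FF", "LOW_FF"),
                  levels = c("HIGH_FF", "LOW_FF"))
    sd <- survival::survdiff(survival::Surv(recs$time, recs$event) ~ grp)
    expect_equal(fit$chisq, sd$chisq, tolerance = 1e-10)
    expect_equal(unname(fit$observed), unname(sd$obs))
    expect_equal(unname(fit$expected), unname(sd$exp), tolerance = 1e-10)

    sf <- survival::survfit(survival::Surv(recs$time, recs$event) ~ grp)
    sfs <- summary(sf)
    curves <- tidy(fit)
    ours <- curves[curves$n_event > 0, ]
    grp_lbl <- sub("^grp=", "", as.character(sfs$strata))
    for (g in unique(ours$group)) {
      expect_equal(ours$survival[ours$group == g],
                   sfs$surv[grp_lbl == g], tolerance = 1e-12)
    }
  }
})

test_that("TIC read ratio is the intron/exon mean depth ratio", {
  r <- tic_read_ratio(rep(100, 10), rep(25, 10))
  expect_equal(r$ratio, 0.25)
  expect_equal(tic_read_ratio(rep(80, 10), rep(0, 10))$ratio, 0)
  expect_error(tic_read_ratio(rep(0, 10), rep(5, 10)), "undefined")
  expect_error(tic_read_ratio(rep(10, 9), rep(5, 10)), "exactly 10")

  # planted chimera proportion recovered within binomial sampling error
  fx <- make_coverage_fixture(seed = 86, p = 0.3, depth = 500)
  exon <- coverage_window(fx$track, "chr4", fx$exon_window[1], fx$exon_window[2])
  intron <- coverage_window(fx$track, "chr4", fx$intron_window[1],
                            fx$intron_window[2])
  got <- tic_read_ratio(exon, intron)$ratio
  se <- sqrt(0.3 * 0.7 / (500 * 10))
  expect_lt(abs(got - 0.3), 3 * se)
})
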