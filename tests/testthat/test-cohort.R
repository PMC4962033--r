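test_that("a noiseless quadratic is recovered exactly with no healthy point below the band", {
  tv <- seq(0.02, 0.1, length.out = 60)
  pef <- 2 + 30 * tv - 40 * tv^2
  d <- data.frame(pef_norm = pef, tv_norm = tv)
  # an exactly quadratic cloud: lm warns that the fit is perfect
  model <- suppressWarnings(fit_reference(d))
  expect_equal(model$coefficients, c(2, 30, -40), tolerance = 1e-6)
  expect_equal(model$level, 0.99)          # default band level
  pr <- predict(model, tv)
  expect_true(all(pef >= pr$lower))
  expect_error(fit_reference(data.frame(pef_norm = 1:9, tv_norm = rep(0.5, 9))),
               "degenerate")
})

test_that("the lower 99% prediction bound leaves ~0.5% of fresh healthy draws below it", {
  set.seed(31)
  n <- 2000
  tv <- runif(n, 0.02, 0.1)
  pef <- 5 + 20 * tv + rnorm(n, sd = 0.8)
  model <- fit_reference(data.frame(pef_norm = pef, tv_norm = tv))
  m <- 20000
  tv2 <- runif(m, 0.02, 0.1)
  pef2 <- 5 + 20 * tv2 + rnorm(m, sd = 0.8)
  frac <- mean(pef2 < predict(model, tv2)$lower)
  # two-sided 99% interval: 0.5% in the lower tail, within Monte-Carlo error
  expect_gt(frac, 0.003)
  expect_lt(frac, 0.0075)
})

test_that("cohort model serialization round-trips through structured text", {
  set.seed(8)
  d <- data.frame(tv_norm = runif(50, 0.02, 0.1))
  d$pef_norm <- 4 + 10 * d$tv_norm + rnorm(50, sd = 0.3)
  model <- fit_reference(d)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_model(model, f)
  model2 <- read_cohort_model(f)
  x <- c(0.03, 0.07)
  expect_equal(predict(model2, x), predict(model, x), tolerance = 1e-6)
})

test_that("LDI is zero above the band, matches a constructed below-band volume share, and scales out V_ee", {
  co <- fx_cohort()
  model <- co$model
  m <- co$healthy[[1]]
  good <- m[!m$nonventilated & is.finite(m$pef_norm), ]
  # force every endpoint far above the bound
  up <- good; up$pef_norm <- up$pef_norm + 100
  expect_equal(lung_disease_index(up, model), 0)
  # construct endpoints supplying exactly 30% of volume far below the bound
  n <- nrow(good)
  k <- 40
  good$v_ee <- c(rep(0.3 / k, k), rep(0.7 / (n - k), n - k))
  good$pef_norm[seq_len(k)] <- -100
  good$pef_norm[(k + 1):n] <- good$pef_norm[(k + 1):n] + 100
  expect_equal(lung_disease_index(good, model), 30)
  # invariance to uniform rescaling of all supplied volumes
  scaled <- good; scaled$v_ee <- scaled$v_ee * 123.4
  expect_equal(lung_disease_index(scaled, model),
               lung_disease_index(good, model))
  # zero total volume is an error
  bad <- good; bad$v_ee[] <- 0
  expect_error(lung_disease_index(bad, model), "volume")
})

test_that("healthy cohorts score near-zero LDI and planted disease is recovered monotonically", {
  co <- fx_cohort()
  healthy_ldi <- vapply(co$healthy, lung_disease_index, numeric(1), co$model)
  expect_true(all(healthy_ldi <= 2))
  mean_ldi <- numeric(0)
  for (f in c(0.1, 0.2, 0.4)) {
    ldis <- vapply(1:3, function(i) {
      m <- simulate_subject_mechanics(
        230, co$protocol,
        disease_config(diseased_volume_fraction = f, blockage_fraction = f,
                       seed = 100 + i),
        seed = 200 + i * 7)$metrics
      lung_disease_index(m, co$model)
    }, numeric(1))
    mean_ldi <- c(mean_ldi, mean(ldis))
  }
  expect_lt(abs(mean_ldi[3] - 40), 5)       # planted 40% recovered
  expect_true(all(diff(mean_ldi) > 0))      # monotone in the planted fraction
})

test_that("distribution statistics match direct computation and manual binning", {
  expect_error(distribution_stats(0.1), "at least 2")
  expect_equal(distribution_stats(rep(0.12, 5))$sd, 0)
  set.seed(4)
  x <- rnorm(300, 0.12, 0.022)
  st <- distribution_stats(x, bin_width = 0.02, t_exp = 0.3)
  expect_equal(st$median, median(x))
  expect_equal(st$sd, sd(x))
  expect_equal(st$mean, mean(x))
  manual <- vapply(seq_len(length(st$breaks) - 1), function(i)
    sum(x > st$breaks[i] & x <= st$breaks[i + 1]), integer(1))
  expect_equal(st$counts, manual)
  expect_equal(sum(st$counts), length(x))
})

test_that("healthy phantom tau distributions reproduce the configured moments", {
  co <- fx_cohort()
  # drawn tau values across one subject's endpoints (n = 230)
  mech <- simulate_subject_mechanics(230, co$protocol, disease_config(seed = 3),
                                     seed = 55)$mechanics
  tau <- mech$compartments$tau
  expect_lt(abs(mean(tau) - 0.12), 3 * 0.022 / sqrt(230))
  expect_lt(abs(sd(tau) - 0.022), 3 * 0.022 / sqrt(2 * 229))
})

test_that("diseased phantoms built from the two reported modes are bimodal", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  p <- ventilation_protocol()
  taus <- unlist(lapply(1:4, function(i)
    simulate_subject_mechanics(
      230, p,
      disease_config(diseased_volume_fraction = 0.5,
                     healthy_tau_mean = 0.13, healthy_tau_sd = 0.038,
                     diseased_tau_mean = 0.22, diseased_tau_sd = 0.037,
                     seed = i),
      seed = 300 + i)$mechanics$compartments$tau))
  fit <- mclust::Mclust(taus, G = 2, modelNames = "V", verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  expect_lt(abs(mu[1] - 0.13), 0.02)
  expect_lt(abs(mu[2] - 0.22), 0.02)
})

test_that("phenotype clustering recovers planted groups and the angle convention", {
  set.seed(9)
  centers <- rbind(c(0.11, 0.02), c(0.13, 0.06), c(0.20, 0.03), c(0.22, 0.07))
  planted <- rep(1:4, each = 6)
  xy <- centers[planted, ] + matrix(rnorm(48, sd = 0.004), 24, 2)
  s <- data.frame(median_tau = xy[, 1], sd_tau = xy[, 2])
  cl <- cluster_phenotypes(s, k = 4, seed = 21)
  # labels equal the planted partition up to permutation
  tab <- table(planted, cl$labels)
  expect_equal(sum(apply(tab, 1, max)), 24)
  expect_true(all(apply(tab, 2, function(col) sum(col > 0)) == 1))
  # centroids match a Lloyd iteration started from the planted centres
  km_oracle <- kmeans(xy, centers = centers, algorithm = "Lloyd",
                      iter.max = 100)
  o <- order(cl$centers[, 1]); o2 <- order(km_oracle$centers[, 1])
  expect_equal(unname(cl$centers[o, ]), unname(km_oracle$centers[o2, ]),
               tolerance = 1e-8)
  # determinism given the seed
  cl2 <- cluster_phenotypes(s, k = 4, seed = 21)
  expect_identical(cl$labels, cl2$labels)
  # a subject at (P_median + delta, P_sd), delta > 0, has angle exactly 0:
  # with all sd values equal, P_sd equals every subject's sd
  s2 <- data.frame(median_tau = c(0.10, 0.12, 0.14, 0.16, 0.13, 0.13 + 0.05),
                   sd_tau = rep(0.04, 6))
  cl3 <- cluster_phenotypes(s2, k = 2, seed = 1)
  expect_equal(unname(cl3$angles[6]), 0)
  expect_error(cluster_phenotypes(s2, k = 9), "at least k")
})

test_that("group comparison reproduces the closed-form pooled t-test", {
  r <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  # closed form: means 2 and 3, pooled sd 1, se = sqrt(2/3)
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-1 / sqrt(2 / 3), 4), tolerance = 1e-9)
  # identical groups
  r0 <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # Welch option changes the degrees of freedom
  rw <- compare_groups(c(1, 2, 3, 4), c(10, 30, 50), var_equal = FALSE)
  expect_lt(rw$df, 5)
})

test_that("cohort analysis assembles summaries, clusters and significant group tests", {
  co <- fx_cohort()
  diseased <- lapply(1:4, function(i)
    simulate_subject_mechanics(
      230, co$protocol,
      disease_config(diseased_volume_fraction = 0.4, blockage_fraction = 0.4,
                     seed = 400 + i),
      seed = 500 + i)$metrics)
  res <- cohort_analysis(c(co$healthy, diseased),
                         c(rep("healthy", 7), rep("diseased", 4)),
                         seed = 2)
  expect_equal(nrow(res$subjects), 11)
  expect_true(all(res$subjects$ldi[res$subjects$group == "diseased"] >
                    max(res$subjects$ldi[res$subjects$group == "healthy"])))
  expect_lt(res$tests$ldi$p, 0.05)          # conventional significance level
  expect_equal(res$model$level, 0.99)
  expect_true(all(res$subjects$cluster %in% 1:4))
  expect_length(res$clusters$angles, 11)
  expect_true(all(res$subjects$angle_from_p > -pi &
                    res$subjects$angle_from_p <= pi))
})
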