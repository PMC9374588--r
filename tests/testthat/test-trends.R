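test_that("spline trend nests linear fits and rejects degenerate input", {
  x <- rep(2014:2019, each = 4)
  y <- 3 + 0.5 * x
  fit <- suppressWarnings(fit_spline_trend(x, y, k = 5)) # exact-fit warning
  expect_equal(fit$fitted, unname(y), tolerance = 1e-8)
  expect_gt(fit$adjusted_r2, 0.999)
  expect_error(fit_spline_trend(rep(1, 10), rnorm(10)), "distinct")
  expect_error(fit_spline_trend(1:5, 1:5, k = 5), "too few")
})

test_that("spline trend on pure noise has adjusted R^2 near zero", {
  set.seed(13)
  adj <- replicate(200, {
    x <- rep(1:7, each = 10)
    fit_spline_trend(x, rnorm(length(x)), k = 5)$adjusted_r2
  })
  expect_lt(abs(mean(adj)), 0.05)
})

test_that("spline trend recovers a hump-shaped seasonal peak", {
  set.seed(14)
  months <- rep(4:10, each = 4)
  truth <- function(m) 150 * exp(-(m - 7)^2 / 2)
  y <- truth(months) + rnorm(length(months), sd = 4)
  fit <- fit_spline_trend(months, y, k = 5)
  expect_equal(months[which.max(fit$fitted)], 7)
  expect_gt(fit$adjusted_r2, 0.9)
})

test_that("saturated case: spline reproduces group means for 5 levels", {
  set.seed(15)
  x <- rep(1:5, each = 6)
  y <- rnorm(length(x), mean = c(3, 9, 1, 7, 5)[x])
  fit <- fit_spline_trend(x, y, k = 5)
  means <- tapply(y, x, mean)
  expect_equal(unname(tapply(fit$fitted, x, mean)), unname(means),
               tolerance = 1e-8)
  expect_equal(unname(fit$fitted[x == 3][1]), unname(means[3]),
               tolerance = 1e-8)
})

test_that("basis reduction flags fits with few distinct x", {
  set.seed(16)
  x <- rep(1:3, each = 5)
  fit <- fit_spline_trend(x, rnorm(15), k = 5)
  expect_true(fit$reduced)
  expect_equal(fit$k_used, 3)
})

test_that("species_trend: closed-form slope for a perfectly linear series", {
  years <- 2014:2019
  res <- species_trend(c(10, 20, 30, 40, 50, 60), years)
  expect_equal(res$change_5yr, 5 / sd(years), tolerance = 1e-10)
  expect_equal(round(res$change_5yr, 4), 2.6726)
  expect_equal(res$slope_sd_per_year * 5, res$change_5yr)
  # standardization removes scale: tripling the counts changes nothing
  res3 <- species_trend(3 * c(10, 20, 30, 40, 50, 60), years)
  expect_equal(res3$change_5yr, res$change_5yr)
  expect_equal(res3$p_value, res$p_value)
})

test_that("species_trend: constant series and reversal symmetry", {
  years <- 2014:2019
  flat <- species_trend(rep(12, 6), years)
  expect_equal(flat$change_5yr, 0)
  expect_true(flat$zero_variance)
  expect_equal(flat$class, "stable")

  set.seed(17)
  y <- rpois(6, 40)
  fwd <- species_trend(y, years)
  rev <- species_trend(rev(y), years)
  expect_equal(rev$change_5yr, -fwd$change_5yr, tolerance = 1e-10)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-10)
  expect_error(species_trend(c(1, 2), 2014:2015), "3 years")
})

test_that("trend classes follow the p-value / sign rules", {
  years <- 2014:2019
  fake <- do.call(rbind, Map(function(p, s) {
    data.frame(species = "x", slope_sd_per_year = s, change_5yr = 5 * s,
               p_value = p, class = beemon:::classify_trend_(s, p),
               strong = is.finite(p) && p <= .01, zero_variance = FALSE,
               total_abundance = 100, yearly_cv = 50)
  }, c(.2, .07, .03, .005), c(-1, -1, -1, 1)))
  expect_equal(fake$class,
               c("stable", "weak decline", "decline", "increase"))
  cl <- classify_trends(fake)
  expect_equal(sum(cl$n), 4)
  expect_equal(attr(cl, "evidence")[["decline"]], 0.5)

  all_stable <- fake; all_stable$class <- "stable"
  expect_equal(classify_trends(all_stable)$proportion[1], 1)
})

test_that("species_trend_table pools sites, fills zero years, filters focal", {
  dat <- sim_fixture()
  tt <- species_trend_table(dat$specimens, min_total = 30)
  totals <- table(dat$specimens$species)
  expect_setequal(tt$species, names(totals)[totals >= 30])
  sp <- tt$species[1]
  yearly <- table(factor(dat$specimens$year[dat$specimens$species == sp],
                         levels = 2014:2019))
  direct <- species_trend(as.numeric(yearly), 2014:2019, species = sp)
  expect_equal(tt[tt$species == sp, ], direct, ignore_attr = TRUE)
})

test_that("null-trend classifier flags about alpha of species", {
  flagged <- unlist(lapply(1:5, function(s) {
    cfg <- sim_config(n_species = 40, n_genera = 8, n_families = 2,
                      abundance = list(meanlog = 2.1, sdlog = 1),
                      total_individuals = 60000, site_sd = 0, seed = 300 + s)
    sim <- simulate_specimens(cfg)
    tt <- species_trend_table(sim$specimens, min_total = 300)
    tt$class %in% c("decline", "increase")
  }))
  expect_gt(length(flagged), 120)
  rate <- mean(flagged)
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("abundance-change diagnostics match the correlation formula", {
  tr <- data.frame(change_5yr = c(1, 2, 3), total_abundance = c(5, 5, 5),
                   yearly_cv = c(10, 20, 15))
  res <- abundance_change_correlation(tr)
  expect_true(is.na(res$r[res$predictor == "total_abundance"]))

  tr2 <- data.frame(change_5yr = c(1, 4, 2, 5), total_abundance = c(1, 4, 2, 5),
                    yearly_cv = c(3, 1, 4, 1))
  res2 <- abundance_change_correlation(tr2)
  expect_equal(res2$r[1], 1)

  set.seed(18)
  tr3 <- data.frame(change_5yr = rnorm(10), total_abundance = rpois(10, 50),
                    yearly_cv = runif(10, 20, 90))
  res3 <- abundance_change_correlation(tr3)
  oracle <- cor(tr3$total_abundance, tr3$change_5yr)
  expect_equal(res3$r[1], oracle)
  expect_equal(res3$p_value[1],
               cor.test(tr3$total_abundance, tr3$change_5yr)$p.value)
})

test_that("metric_trend_table fits one model per metric", {
  dat <- sim_fixture()
  ms <- month_summary(build_month_matrix(dat$specimens, dat$grouping))
  mm <- metric_trend_table(ms, "month")
  expect_setequal(mm$metric, c("abundance", "richness", "diversity",
                               "evenness"))
  expect_true(all(mm$adjusted_r2 <= 1))
  expect_true(all(mm$p_value >= 0 & mm$p_value <= 1))
})
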