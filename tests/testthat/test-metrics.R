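test_that("inverse Simpson's matches the direct formula", {
  expect_equal(inverse_simpson(c(5, 5, 5, 5)), 4)
  expect_equal(inverse_simpson(7), 1)
  # direct formula oracle: 1/(0.01 + 0.01 + 0.64)
  expect_equal(inverse_simpson(c(10, 10, 80)), 1 / 0.66)
  expect_true(is.na(inverse_simpson(c(0, 0))))
  expect_error(inverse_simpson(c(-1, 2)), "non-negative")
})

test_that("diversity is invariant to rescaling and zero-padding", {
  counts <- c(12, 7, 3, 1)
  expect_equal(inverse_simpson(counts * 10), inverse_simpson(counts))
  expect_equal(inverse_simpson(c(counts, 0, 0)), inverse_simpson(counts))
  S <- sum(counts > 0)
  D <- inverse_simpson(counts)
  expect_true(D >= 1 && D <= S)
})

test_that("evenness is D/S, with Pielou as an option", {
  expect_equal(evenness(c(5, 5, 5, 5)), 1)
  expect_equal(evenness(7), 1)
  expect_equal(evenness(c(10, 10, 80)), (1 / 0.66) / 3)
  p <- c(0.1, 0.1, 0.8)
  expect_equal(evenness(c(10, 10, 80), method = "pielou"),
               -sum(p * log(p)) / log(3))
  expect_equal(evenness(c(3, 3, 3), method = "pielou"), 1)
})

test_that("analytic rarefaction: exact endpoints and monotonicity", {
  counts <- c(50, 30, 20)
  expect_equal(rarefied_richness(counts, sum(counts)), 3)
  expect_equal(rarefied_richness(counts, 1), 1)
  vals <- vapply(seq(1, 100, by = 7), rarefied_richness, numeric(1),
                 counts = counts)
  expect_true(all(diff(vals) >= -1e-12))
  expect_error(rarefied_richness(counts, 101), "n")
  # species rarer than the complement: impossible-draw branch
  expect_equal(rarefied_richness(c(99, 1), 100), 2)
})

test_that("accumulation curve is flat for a monoculture and ends at S", {
  expect_equal(accumulation_curve(rep("a", 20), n_perm = 5)$species,
               rep(1, 20))
  labels <- rep(c("a", "b", "c", "d"), c(40, 10, 5, 1))
  curve <- accumulation_curve(labels, n_perm = 50, seed = 1)
  expect_equal(curve$species[length(labels)], 4)
  expect_true(all(diff(curve$species) >= -1e-12))
})

test_that("accumulation curve equals analytic rarefaction in expectation", {
  counts <- c(40, 10, 5, 1)
  labels <- rep(letters[1:4], counts)
  curve <- accumulation_curve(labels, n_perm = 2000, seed = 7,
                              at = c(5, 15, 30))
  analytic <- vapply(c(5, 15, 30), rarefied_richness, numeric(1),
                     counts = counts)
  expect_equal(curve$species, analytic, tolerance = 0.02)
})

test_that("month_rarefaction pools sites and years within month", {
  dat <- sim_fixture()
  mr <- month_rarefaction(dat$specimens, n = 100)
  pooled_june <- table(dat$specimens$species[dat$specimens$month == 6])
  expect_equal(mr$rarefied_richness[mr$month == 6],
               rarefied_richness(as.numeric(pooled_june), 100))
  tiny <- month_rarefaction(dat$specimens, n = 10 * nrow(dat$specimens))
  expect_true(all(is.na(tiny$rarefied_richness)))
})

test_that("percent_change applies the difference-over-overall-mean formula", {
  expect_equal(round(percent_change(21, 168, 76)), 193)
  expect_equal(percent_change(5, 5, 123), 0)
  expect_equal(percent_change(10, 30, 20), 100)
  expect_error(percent_change(1, 2, 0), "nonzero")
})

test_that("yearly_cv uses the sample standard deviation", {
  expect_equal(yearly_cv(rep(4, 6)), 0)
  expect_equal(yearly_cv(c(10, 20)), 100 * sd(c(10, 20)) / 15)
  expect_equal(round(yearly_cv(c(10, 20)), 2), 47.14)
  expect_true(is.na(yearly_cv(c(-5, 5))))
  expect_true(is.na(yearly_cv(7)))
})

test_that("month_summary reproduces the two-step averaging by brute force", {
  dat <- sim_fixture()
  mcm <- build_month_matrix(dat$specimens, dat$grouping)
  ms <- month_summary(mcm)
  expect_equal(nrow(ms), 4 * 7) # 4 site-group replicates per month

  # brute-force oracle: metric per (site, month, year) -> mean over years
  # -> mean over sites in group, written as explicit loops
  pick <- function(g, m, metric_fun) {
    sites <- names(dat$grouping)[dat$grouping == g]
    site_means <- vapply(sites, function(s) {
      sel <- mcm$units$site_id == s & mcm$units$month == m
      vals <- apply(mcm$counts[sel, , drop = FALSE], 1, metric_fun)
      mean(vals, na.rm = TRUE)
    }, numeric(1))
    mean(site_means, na.rm = TRUE)
  }
  for (g in unique(ms$group)[1:2]) {
    for (m in c(4, 7, 10)) {
      row <- ms[ms$group == g & ms$month == m, ]
      expect_equal(row$abundance, pick(g, m, sum))
      expect_equal(row$richness, pick(g, m, function(x) sum(x > 0)))
      expect_equal(row$diversity, pick(g, m, inverse_simpson))
    }
  }
})

test_that("month_summary trivial cases: identical years and simple means", {
  df <- rbind(
    make_specimen_df(rep("Apis mellifera", 10), site = "S1",
                     date = "2014-06-10"),
    make_specimen_df(rep("Apis mellifera", 30), site = "S1",
                     date = "2015-06-10")
  )
  spec <- as_specimen_table(df)
  cm <- build_month_matrix(spec, site_grouping(c(S1 = "G1")))
  ms <- month_summary(cm)
  expect_equal(ms$abundance[ms$month == 6], 20) # mean of 10 and 30
  # identical communities every year: average equals the single-year metric
  df2 <- rbind(make_specimen_df(rep(c("A a", "B b"), c(4, 2)),
                                date = "2014-05-03"),
               make_specimen_df(rep(c("A a", "B b"), c(4, 2)),
                                date = "2015-05-03"))
  cm2 <- build_month_matrix(as_specimen_table(df2),
                            site_grouping(c(S1 = "G1")))
  ms2 <- month_summary(cm2)
  expect_equal(ms2$diversity[ms2$month == 5], inverse_simpson(c(4, 2)))
})

test_that("zero months contribute zero abundance but not diversity", {
  # one capture month out of seven: diversity defined only where bees exist
  df <- make_specimen_df(rep("Apis mellifera", 5), date = "2015-07-01")
  cm <- build_month_matrix(as_specimen_table(df),
                           site_grouping(c(S1 = "G1")))
  ms <- month_summary(cm)
  expect_equal(ms$abundance[ms$month == 4], 0)
  expect_true(is.na(ms$diversity[ms$month == 4]))
  expect_equal(ms$diversity[ms$month == 7], 1)
})

test_that("year_summary averages sites within groups", {
  dat <- sim_fixture()
  ycm <- build_year_matrix(dat$specimens, dat$grouping)
  ys <- year_summary(ycm)
  expect_equal(nrow(ys), 4 * length(unique(ycm$units$year)))
  g <- ys$group[1]; y <- ys$year[1]
  sites <- names(dat$grouping)[dat$grouping == g]
  sel <- ycm$units$site_id %in% sites & ycm$units$year == y
  expect_equal(ys$abundance[1], mean(rowSums(ycm$counts[sel, ])))
  expect_equal(ys$richness[1],
               mean(apply(ycm$counts[sel, ], 1, function(x) sum(x > 0))))
})
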