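# Cognitive composites, ROI adjustment, correlation table, compositional
# regression, Type II tests, quadratic comparison, FDR.

test_that("composites average within-test z-scores", {
  sc <- data.frame(t1 = c(1, 2, 3), t2 = c(3, 2, 1), t3 = c(5, 7, 9))
  one <- make_composite(sc, list(m = "t3"))
  expect_equal(one$m, as.numeric(scale(sc$t3)))
  dup <- make_composite(sc, list(m = c("t3", "t3")))
  expect_equal(dup$m, one$m)
  # opposite ranks cancel: z(t1) + z(t2) = 0 rowwise
  opp <- make_composite(sc, list(m = c("t1", "t2")))
  expect_equal(opp$m, c(0, 0, 0))
  # missing values: composite uses available tests, all-missing -> NA
  sc2 <- data.frame(t1 = c(1, 2, NA), t2 = c(4, 5, NA))
  cmp <- make_composite(sc2, list(m = c("t1", "t2")))
  expect_true(is.na(cmp$m[3]))
  expect_equal(cmp$m[1:2], c(-sqrt(0.5), sqrt(0.5)))
  expect_error(make_composite(data.frame(t = c(2, 2, 2)), list(m = "t")),
               "zero variance")
  expect_error(make_composite(sc, list(m = "nope")), "existing test")
})

test_that("ROI adjustment residualises on TIV/site/distortion and restores the mean", {
  set.seed(31)
  n <- 120
  tiv <- rnorm(n, 1550, 140)
  site <- factor(sample(c("A", "B"), n, TRUE))
  dist <- factor(sample(c("off", "on"), n, TRUE))
  vol <- 0.3 * tiv + 10 * (site == "B") + rnorm(n, 0, 20)
  adj <- adjust_roi(vol, tiv, site, dist)
  expect_equal(mean(adj), mean(vol), tolerance = 1e-9)
  expect_equal(cor(adj, tiv), 0, tolerance = 1e-9)
  expect_equal(unname(tapply(adj, site, mean)[1] - tapply(adj, site, mean)[2]),
               0, tolerance = 1e-6)
  # uncorrelated volume passes through unchanged up to the fitted noise
  vol2 <- rnorm(n, 100, 10)
  fit_only <- adjust_roi(vol2, tiv, site, dist)
  expect_equal(cor(fit_only, vol2), 1, tolerance = 0.05)
  expect_error(adjust_roi(vol, tiv, site, site), "Collinear")
  # constant adjusters are dropped rather than aliased
  expect_silent(adjust_roi(vol, tiv, rep("A", n), rep("off", n)))
})

test_that("Fisher-z intervals match hand arithmetic and the point-biserial is Pearson", {
  set.seed(32)
  d <- data.frame(x = rnorm(28), sex = factor(rep(c("male", "female"), 14),
                                              levels = c("male", "female")))
  d$y <- 0.5 * d$x + rnorm(28, 0, 0.8)
  tab <- correlation_table(d, variables = c("x", "y", "sex"), comp_cols = character(0))
  xy <- tab[tab$var1 == "x" & tab$var2 == "y", ]
  r <- cor(d$x, d$y)
  expect_equal(xy$r, r)
  expect_equal(xy$ci_low, tanh(atanh(r) - 1.96 / sqrt(25)), tolerance = 1e-3)
  expect_equal(xy$ci_high, tanh(atanh(r) + 1.96 / sqrt(25)), tolerance = 1e-3)
  # the worked interval: r = 0.5, n = 28 -> (0.156, 0.736)
  expect_equal(fisher_z_ci <- tanh(atanh(0.5) + c(-1, 1) * 1.96 / sqrt(25)),
               c(0.156, 0.736), tolerance = 5e-4)
  pb <- tab[tab$var2 == "sex" | tab$var1 == "sex", ][1, ]
  expect_equal(pb$method, "point_biserial")
  expect_equal(pb$r, cor(d$x, as.numeric(d$sex) - 1))
  # perfectly linear pair -> degenerate interval at 1
  d2 <- data.frame(a = 1:10, b = 2 * (1:10) + 3)
  t2 <- correlation_table(d2, variables = c("a", "b"), comp_cols = character(0))
  expect_equal(t2$r, 1)
  expect_equal(t2$ci_low, 1)
  expect_error(correlation_table(data.frame(a = rep(1, 10), b = 1:10),
                                 variables = c("a", "b"), comp_cols = character(0)),
               "constant")
})

test_that("compositional pairs get symmetric-balance correlations with bootstrap CIs", {
  set.seed(33)
  d <- as.data.frame(random_compositions(60))
  tab <- correlation_table(d, variables = timeuse_parts(), n_boot = 200, seed = 9)
  expect_true(all(tab$method == "symmetric_balance"))
  expect_equal(nrow(tab), 6)
  mv_sl <- tab[tab$var1 == "mvpa" & tab$var2 == "sleep", ]
  expect_equal(mv_sl$r, cor_coda(as.matrix(d), "mvpa", "sleep"))
  expect_true(mv_sl$ci_low <= mv_sl$r && mv_sl$r <= mv_sl$ci_high)
  # seeded bootstrap reproduces
  tab2 <- correlation_table(d, variables = timeuse_parts(), n_boot = 200, seed = 9)
  expect_identical(tab, tab2)
})

test_that("Type II tests equal brute-force nested-model F on a small fixture", {
  d <- make_fixture_cohort(n = 20, seed = 17)
  d$y <- with(d, 0.1 * age + 0.5 * (sex == "female") + rnorm(20, 0, 0.5))
  fit <- fit_timeuse_model(d, "y", covariates = c("age", "sex", "education"))
  tt <- type2_tests(fit)
  Z <- ilr_pivot(as.matrix(d[timeuse_parts()]))
  Xfull <- cbind(age = d$age, sexf = as.numeric(d$sex == "female"),
                 edu = d$education, Z)
  for (term in c("age", "sex", "education", "ilr")) {
    drop_cols <- switch(term, age = 1, sex = 2, education = 3, ilr = 4:6)
    bf <- brute_force_F(Xfull[, -drop_cols, drop = FALSE], Xfull, d$y)
    row <- tt[tt$term == term, ]
    expect_equal(row$F, bf$F, tolerance = 1e-8)
    expect_equal(row$df1, bf$df1)
    expect_equal(row$df2, bf$df2)
    expect_equal(row$p, bf$p, tolerance = 1e-8)
  }
})

test_that("Type II tests agree with car::Anova where conventions coincide", {
  skip_if_not_installed("car")
  set.seed(34)
  d <- make_fixture_cohort(n = 80, seed = 19)
  fit <- fit_timeuse_model(d, "y")
  tt <- type2_tests(fit)
  ca <- car::Anova(fit$fit, type = 2)
  for (term in c("age", "sex", "education", "ilr")) {
    expect_equal(tt$F[tt$term == term], ca[term, "F value"], tolerance = 1e-8)
    expect_equal(tt$p[tt$term == term], ca[term, "Pr(>F)"], tolerance = 1e-8)
  }
  # interaction model: the highest-order term matches car exactly too
  im <- fit_interaction_model(d, "y", "roi")
  ca2 <- car::Anova(im$fit$fit, type = 2)
  expect_equal(im$tests$F[im$tests$term == "ilr:roi_v"],
               ca2["ilr:roi_v", "F value"], tolerance = 1e-8)
})

test_that("marginality: main effects are tested without their interactions", {
  d <- make_fixture_cohort(n = 80, seed = 23)
  im <- fit_interaction_model(d, "y", "roi")
  tt <- im$tests
  # composition df2 comes from the model WITHOUT the interaction term
  n <- nrow(d)
  # model without the interaction: intercept + cov(3) + ilr(3) + roi = 8 params
  expect_equal(tt$df2[tt$term == "ilr"], n - 8)
  expect_equal(tt$df2[tt$term == "ilr:roi_v"], n - 11)  # full model
  expect_equal(tt$df1[tt$term == "ilr"], 3)
  expect_equal(tt$df1[tt$term == "ilr:roi_v"], 3)
  expect_setequal(tt$term, c("age", "sex", "education", "ilr", "roi_v", "ilr:roi_v"))
})

test_that("whole-composition F and p are invariant to the pivot ordering", {
  set.seed(35)
  d <- make_fixture_cohort(n = 100, seed = 29)
  d$y <- with(d, 0.3 * log(mvpa / sleep) + rnorm(100, 0, 0.4))
  orders <- list(timeuse_parts(), c("sleep", "sb", "lpa", "mvpa"),
                 c("sb", "mvpa", "sleep", "lpa"))
  Fs <- sapply(orders, function(o) {
    tt <- type2_tests(fit_timeuse_model(d, "y", pivot_order = o))
    c(tt$F[tt$term == "ilr"], tt$p[tt$term == "ilr"])
  })
  expect_lt(max(Fs[1, ]) - min(Fs[1, ]), 1e-8)
  expect_lt(max(Fs[2, ]) - min(Fs[2, ]), 1e-8)
  # fitted values are basis invariant as well
  f1 <- fitted(fit_timeuse_model(d, "y", pivot_order = orders[[1]])$fit)
  f2 <- fitted(fit_timeuse_model(d, "y", pivot_order = orders[[3]])$fit)
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("quadratic augmentation never increases RSS and detects curvature", {
  d <- make_fixture_cohort(n = 150, seed = 37)
  fit <- fit_timeuse_model(d, "y")
  q <- compare_quadratic(fit)
  expect_lte(q$rss_quadratic, q$rss_linear)
  expect_equal(q$df1, 3)
  # planted z1^2 effect is found
  Z <- ilr_pivot(as.matrix(d[timeuse_parts()]))
  d$y2 <- 0.8 * Z[, 1]^2 + rnorm(150, 0, 0.3)
  q2 <- compare_quadratic(fit_timeuse_model(d, "y2"))
  expect_lt(q2$p, 0.01)
})

test_that("rank-deficient or undersized designs are refused with names", {
  d <- make_fixture_cohort(n = 40, seed = 41)
  d$dup <- d$age
  expect_error(
    fit_timeuse_model(d, "y", covariates = c("age", "dup")),
    "aliased"
  )
  expect_error(fit_timeuse_model(d[1:6, ], "y"), "Too few")
  expect_error(fit_timeuse_model(d, "nope"), "not found")
})

test_that("listwise deletion drops rows missing the outcome", {
  d <- make_fixture_cohort(n = 50, seed = 43)
  d$y[1:5] <- NA
  fit <- fit_timeuse_model(d, "y")
  expect_equal(fit$n, 45)
})

test_that("log-outcome models keep the same term structure and dfs", {
  d <- make_fixture_cohort(n = 60, seed = 47)
  d$vent <- exp(rnorm(60, 3.2, 0.4))
  f1 <- fit_timeuse_model(d, "vent")
  f2 <- fit_timeuse_model(d, "vent", log_outcome = TRUE)
  t1 <- type2_tests(f1); t2 <- type2_tests(f2)
  expect_equal(t1$term, t2$term)
  expect_equal(t1$df1, t2$df1)
  expect_equal(t1$df2, t2$df2)
  expect_false(isTRUE(all.equal(coef(f1$fit), coef(f2$fit))))
  d$vent[1] <- -1
  expect_error(fit_timeuse_model(d, "vent", log_outcome = TRUE), "positive")
})

test_that("categorical ROI forms build the expected designs", {
  d <- make_fixture_cohort(n = 80, seed = 53)
  cont <- fit_interaction_model(d, "y", "roi", roi_form = "continuous")
  split <- fit_interaction_model(d, "y", "roi", roi_form = "mean_split")
  quart <- fit_interaction_model(d, "y", "roi", roi_form = "quartiles")
  expect_equal(cont$fit$n, split$fit$n)
  expect_s3_class(split$fit$data$roi_v, "factor")
  expect_equal(nlevels(split$fit$data$roi_v), 2)
  expect_equal(nlevels(quart$fit$data$roi_v), 4)
  expect_equal(split$fit$roi_split, mean(d$roi))
  expect_equal(quart$tests$df1[quart$tests$term == "ilr:roi_v"], 9)
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(57)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("planted regression coefficients are recovered within 3 SE at n = 378", {
  cfg <- cohort_config(n = 378, seed = 61)
  co <- generate_cohort(cfg)
  tr <- attr(co, "truth")
  sc <- tr$roi_scaling$long_term_memory
  co$roi_z <- (co$frontal - sc[["center"]]) / sc[["scale"]]
  im <- fit_interaction_model(co, "long_term_memory", "roi_z")
  cf <- coef(im$fit$fit); se <- sqrt(diag(vcov(im$fit$fit)))
  truth <- c(ilrz1 = tr$long_term_memory$ilr[1],
             ilrz2 = tr$long_term_memory$ilr[2],
             ilrz3 = tr$long_term_memory$ilr[3],
             `ilrz1:roi_v` = tr$long_term_memory$interaction[1],
             `ilrz2:roi_v` = tr$long_term_memory$interaction[2],
             `ilrz3:roi_v` = tr$long_term_memory$interaction[3])
  for (nm in names(truth)) {
    expect_lt(abs(cf[[nm]] - truth[[nm]]) / se[[nm]], 3)
  }
})

test_that("fit diagnostics report residual shape", {
  d <- make_fixture_cohort(n = 100, seed = 67)
  dg <- fit_diagnostics(fit_timeuse_model(d, "y"))
  expect_true(is.finite(dg$skewness))
  expect_true(dg$shapiro_p > 0 && dg$shapiro_p <= 1)
  expect_true(dg$max_leverage <= 1)
})
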