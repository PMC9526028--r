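test_that("fit_ols matches the normal-equation oracle and exact fits", {
  ## exact line
  X <- cbind(1, x = 1:10)
  fit <- fit_ols(X, 2 * (1:10))
  expect_equal(fit$coefficients$estimate, c(0, 2), tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  ## hand 5x3 matrix vs explicit solve
  X5 <- cbind(1, a = c(1, 2, 4, 3, 7), b = c(2, 1, 0, 5, 2))
  y5 <- c(3, 1, 4, 1, 5)
  orc <- oracle_ols(X5, y5)
  f5 <- fit_ols(X5, y5)
  expect_equal(f5$coefficients$estimate, orc$beta, tolerance = 1e-10)
  expect_equal(f5$coefficients$se, orc$se, tolerance = 1e-10)
  expect_equal(f5$df, orc$df)
  ## residuals orthogonal to the design
  expect_lt(max(abs(t(f5$X) %*% f5$residuals)), 1e-8 * max(abs(y5)))
  ## known-beta recovery
  set.seed(52)
  Xs <- cbind(1, x1 = rnorm(200), x2 = rnorm(200))
  beta <- c(1, -2, 0.5)
  ys <- Xs %*% beta + rnorm(200)
  fs <- fit_ols(Xs, ys)
  expect_true(all(abs(fs$coefficients$estimate - beta) <
                    3 * fs$coefficients$se))
  ## singular design errors, naming a column
  expect_error(fit_ols(cbind(1, x = 1:5, x2 = 2 * (1:5)), rnorm(5)),
               "singular|collinear")
})

test_that("build_design produces percent-scaled covariates and UGS dummies", {
  study <- small_study(6, n_sites = 40)
  df <- study$sites$sites
  df$ses <- rnorm(nrow(df))
  des <- build_design(df, scale = 250)
  expect_equal(colnames(des$X)[1:3], c("(Intercept)", "open_green", "impervious"))
  expect_equal(ncol(des$X), 3 + nlevels(des$factor) - 1)
  expect_equal(unname(des$X[, "impervious"]), df$impervious_250 * 100)
  expect_equal(qr(des$X)$rank, ncol(des$X))
  ## single observed level -> warning, no dummies
  df1 <- df; df1$ugs_type <- "home_garden"
  expect_warning(d1 <- build_design(df1, scale = 250), "single UGS level")
  expect_equal(ncol(d1$X), 3)
})

test_that("EMMs equal group means in a balanced one-way design", {
  set.seed(53)
  g <- rep(c("community_garden", "green_roof", "public_park"), each = 10)
  y <- rnorm(30) + rep(c(0, 1, 2), each = 10)
  X <- cbind("(Intercept)" = 1, stats::model.matrix(~factor(g))[, -1])
  colnames(X) <- c("(Intercept)", paste0("ugs_", c("green_roof", "public_park")))
  fit <- fit_ols(X, y)
  design <- list(factor_levels = c("community_garden", "green_roof", "public_park"),
                 covariates = character(0), covariate_means = numeric(0))
  emm <- emm_pairwise(fit, design, adjust = "none")
  expect_equal(emm$emmeans$emmean, as.numeric(tapply(y, g, mean)),
               tolerance = 1e-10)
  expect_equal(emm$contrasts$estimate[1],
               mean(y[g == "community_garden"]) - mean(y[g == "green_roof"]),
               tolerance = 1e-10)
})

test_that("two-level Tukey p equals the unadjusted t p (q = t*sqrt(2))", {
  set.seed(54)
  g <- rep(c("community_garden", "green_roof"), times = c(8, 14))
  y <- rnorm(22) + (g == "green_roof")
  X <- cbind("(Intercept)" = 1, ugs_green_roof = as.numeric(g == "green_roof"))
  fit <- fit_ols(X, y)
  design <- list(factor_levels = c("community_garden", "green_roof"),
                 covariates = character(0), covariate_means = numeric(0))
  p_tukey <- emm_pairwise(fit, design, adjust = "tukey")$contrasts$p
  p_none <- emm_pairwise(fit, design, adjust = "none")$contrasts$p
  expect_equal(p_tukey, p_none, tolerance = 1e-8)
})

test_that("covariate-adjusted EMM difference matches a prediction oracle", {
  set.seed(55)
  n <- 40
  g <- sample(c("community_garden", "green_roof"), n, TRUE, prob = c(0.7, 0.3))
  x <- rnorm(n, 50, 10)
  y <- 1 + 0.2 * x + 2 * (g == "green_roof") + rnorm(n)
  X <- cbind("(Intercept)" = 1, open_green = x,
             ugs_green_roof = as.numeric(g == "green_roof"))
  fit <- fit_ols(X, y)
  design <- list(factor_levels = c("community_garden", "green_roof"),
                 covariates = "open_green",
                 covariate_means = c(open_green = mean(x)))
  emm <- emm_pairwise(fit, design, adjust = "none")
  b <- fit$coefficients$estimate
  pred <- function(level) b[1] + b[2] * mean(x) + b[3] * (level == "green_roof")
  expect_equal(emm$emmeans$emmean,
               c(pred("community_garden"), pred("green_roof")),
               tolerance = 1e-10)
  expect_equal(emm$contrasts$estimate, pred("community_garden") - pred("green_roof"),
               tolerance = 1e-10)
  ## contrasts invariant to the dummy reference level
  X2 <- cbind("(Intercept)" = 1, open_green = x,
              ugs_community_garden = as.numeric(g == "community_garden"))
  fit2 <- fit_ols(X2, y)
  design2 <- list(factor_levels = c("green_roof", "community_garden"),
                  covariates = "open_green",
                  covariate_means = c(open_green = mean(x)))
  emm2 <- emm_pairwise(fit2, design2, adjust = "none")
  expect_equal(abs(emm2$contrasts$estimate), abs(emm$contrasts$estimate),
               tolerance = 1e-10)
  expect_equal(emm2$contrasts$p, emm$contrasts$p, tolerance = 1e-10)
})

test_that("morans_i matches the hand checkerboard and ape::Moran.I", {
  ## 2x2 rook lattice, values (+1,-1,-1,+1): S0 = 8, sum w z z = -8 -> I = -1
  w <- matrix(c(0, 1, 1, 0,
                1, 0, 0, 1,
                1, 0, 0, 1,
                0, 1, 1, 0), 4, byrow = TRUE)
  z <- c(1, -1, -1, 1)
  m <- morans_i(z, w)
  expect_equal(m$observed, -1)
  expect_equal(m$expected, -1 / 3)
  set.seed(56)
  for (rep in 1:5) {
    n <- 20
    coords <- matrix(runif(2 * n, 0, 100), n)
    ## ape::Moran.I row-standardizes internally, so hand it an already
    ## row-standardized matrix; its variance uses the randomization
    ## (kurtosis) formula rather than our normality one, so only the
    ## observed statistic and its expectation are comparable
    wk <- idw_weights(coords, row_standardize = TRUE)
    x <- rnorm(n)
    mine <- morans_i(x, wk)
    ref <- ape::Moran.I(x, wk)
    expect_equal(mine$observed, ref$observed, tolerance = 1e-10)
    expect_equal(mine$expected, ref$expected, tolerance = 1e-10)
  }
  ## the normality-assumption sd matches the spread of I over Gaussian draws
  coords <- matrix(runif(30, 0, 100), 15)
  wk <- knn_weights(coords, k = 4)
  draws <- replicate(4000, morans_i(rnorm(15), wk)$observed)
  m0 <- morans_i(rnorm(15), wk)
  expect_lt(abs(mean(draws) - m0$expected), 4 * sd(draws) / sqrt(4000))
  expect_lt(abs(sd(draws) - m0$sd), 4 * m0$sd / sqrt(2 * 4000) + 0.005)
  expect_error(morans_i(rep(1, 5), matrix(1, 5, 5)), "zero variance")
  expect_error(morans_i(rnorm(5), matrix(0, 5, 5)), "all-zero")
})

test_that("collinearity screen flags constructed and perfect collinearity", {
  set.seed(57)
  n <- 1000
  imp <- runif(n)
  df <- data.frame(impervious_250 = imp,
                   closed_green_250 = pmin(pmax(-0.92 * imp + 0.95 +
                                                  rnorm(n, 0, 0.03), 0), 1),
                   open_green_250 = runif(n, 0, 0.05))
  rep1 <- collinearity_screen(df, scale = 250)
  expect_true(any(rep1$flagged$var1 == "impervious" &
                    rep1$flagged$var2 == "closed_green"))
  expect_equal(rep1$dropped, "closed_green")
  ## identical columns -> r = 1
  df2 <- data.frame(impervious_250 = imp, closed_green_250 = imp,
                    open_green_250 = imp)
  expect_true(all(abs(collinearity_screen(df2)$correlations - 1) < 1e-12))
  ## independent columns -> nothing flagged
  df3 <- data.frame(impervious_250 = runif(n, 0, 0.5),
                    closed_green_250 = runif(n, 0, 0.3),
                    open_green_250 = runif(n, 0, 0.2))
  expect_equal(nrow(collinearity_screen(df3)$flagged), 0L)
})

test_that("criterion2 recovers a known impervious slope on synthetic data", {
  set.seed(58)
  study <- small_study(58, n_sites = 150)
  st <- study$sites
  ## construct ses with a known slope per percentage point of impervious
  truth <- -0.05
  ses <- data.frame(site_id = st$sites$site_id,
                    ses = 1 + truth * (st$sites$impervious_250 * 100) +
                      rnorm(150, 0, 0.8))
  res <- criterion2(st, ses, scale = 250)
  imp <- res$fit$coefficients[res$fit$coefficients$term == "impervious", ]
  expect_lt(abs(imp$estimate - truth), 3 * imp$se)
  expect_s3_class(res$moran, "moran_result")
  expect_true(abs(res$moran$observed) < 1)
})
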