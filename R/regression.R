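#' Build the Criterion-II design matrix
#'
#' Design for `ses.MFD ~ percent open green cover + percent impervious
#' surface + UGS type`: an intercept, the two land-cover covariates at the
#' chosen buffer scale (proportions multiplied by 100 so coefficients are
#' per percentage point), and treatment-coded dummies for the green-space
#' factor. Unobserved factor levels are dropped with a warning.
#'
#' @param st a [site_table()] whose `sites` also carry a `ses` column (merge
#'   the [ses_mfd()] output first), or any data.frame with the needed columns.
#' @param scale buffer radius whose covariate columns to use (250 or 500).
#' @param factor_reference reference UGS level (default `"community_garden"`).
#' @param percent multiply proportions by 100 (default `TRUE`).
#' @return list: `X` (design matrix), `y` (response, if a `ses` column is
#'   present), `covariates` (names), `factor_levels` (observed UGS levels in
#'   design order), `covariate_means`.
#' @export
build_design <- function(st, scale = 250, factor_reference = "community_garden",
                         percent = TRUE) {
  df <- if (inherits(st, "site_table")) st$sites else as.data.frame(st)
  cols <- paste0(c("open_green_", "impervious_"), scale)
  miss <- setdiff(c(cols, "ugs_type"), names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  mult <- if (percent) 100 else 1
  og <- df[[cols[1]]] * mult
  imp <- df[[cols[2]]] * mult
  f <- factor(df$ugs_type)
  empty <- setdiff(levels(f), unique(as.character(f)))
  if (length(empty)) {
    warning("dropping unobserved UGS levels: ", paste(empty, collapse = ", "))
    f <- droplevels(f)
  }
  if (factor_reference %in% levels(f))
    f <- stats::relevel(f, ref = factor_reference)
  X <- cbind("(Intercept)" = 1, open_green = og, impervious = imp)
  if (nlevels(f) >= 2) {
    dummies <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(dummies) <- paste0("ugs_", levels(f)[-1])
    X <- cbind(X, dummies)
  } else warning("single UGS level observed; no factor dummies")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  list(X = X, y = if ("ses" %in% names(df)) df$ses else NULL,
       covariates = c("open_green", "impervious"),
       factor = f, factor_levels = levels(f),
       covariate_means = c(open_green = mean(og), impervious = mean(imp)))
}

#' Ordinary least squares fit with coefficient table
#'
#' QR-based least squares (base R) wrapped behind a stable contract:
#' estimates, standard errors from `sigma^2 (X'X)^{-1}`, two-tailed t tests
#' on `n - p` degrees of freedom, residuals and the coefficient covariance.
#'
#' @param X design matrix (with intercept column if desired).
#' @param y numeric response.
#' @return list of class `ols_fit`: `coefficients` (data.frame with
#'   `term`, `estimate`, `se`, `t`, `p`), `df`, `sigma2`, `vcov`,
#'   `residuals`, `fitted`, `X`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X); y <- as.numeric(y)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular design; collinear columns: ", paste(drop, collapse = ", "))
  }
  fit <- lm.fit(X, y)
  res <- fit$residuals
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  tval <- fit$coefficients / se
  coefs <- data.frame(term = colnames(X), estimate = unname(fit$coefficients),
                      se = unname(se), t = unname(tval),
                      p = unname(2 * stats::pt(-abs(tval), df)),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, df = df, sigma2 = sigma2, vcov = vc,
                 residuals = res, fitted = fit$fitted.values, X = X, y = y),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("ols_fit: n = %d, residual df = %d, sigma^2 = %.4g\n",
              length(x$y), x$df, x$sigma2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Estimated marginal means and pairwise contrasts for the UGS factor
#'
#' EMM for level l is the model prediction with every covariate fixed at its
#' (unweighted) observed mean and the factor set to l. Contrast standard
#' errors come from the coefficient covariance; adjusted p-values use the
#' studentized-range (Tukey) distribution with `k` = number of levels on the
#' residual df, or Bonferroni, or none.
#'
#' @param fit an `ols_fit` on a design from [build_design()].
#' @param design the [build_design()] output used for the fit.
#' @param adjust `"tukey"` (default), `"bonferroni"` or `"none"`.
#' @return list of class `emm_table`: `emmeans` (level, emmean, se) and
#'   `contrasts` (contrast, estimate, se, t_ratio, df, p).
#' @export
emm_pairwise <- function(fit, design, adjust = c("tukey", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  levs <- design$factor_levels
  if (length(levs) < 2) stop("factor with >= 2 observed levels required")
  terms <- fit$coefficients$term
  grid <- matrix(0, length(levs), length(terms),
                 dimnames = list(levs, terms))
  grid[, "(Intercept)"] <- 1
  for (cv in design$covariates)
    if (cv %in% terms) grid[, cv] <- design$covariate_means[[cv]]
  for (l in levs[-1]) {
    col <- paste0("ugs_", l)
    if (!col %in% terms) stop("factor level column not in model: ", col)
    grid[l, col] <- 1
  }
  beta <- fit$coefficients$estimate
  emm <- as.numeric(grid %*% beta)
  emm_se <- sqrt(diag(grid %*% fit$vcov %*% t(grid)))
  k <- length(levs)
  pairs <- utils::combn(k, 2)
  ct <- apply(pairs, 2, function(ij) {
    v <- grid[ij[1], ] - grid[ij[2], ]
    est <- sum(v * beta)
    se <- sqrt(as.numeric(t(v) %*% fit$vcov %*% v))
    c(est = est, se = se)
  })
  est <- ct["est", ]; se <- ct["se", ]
  tr <- est / se
  p_raw <- 2 * stats::pt(-abs(tr), fit$df)
  p_adj <- switch(adjust,
    none = p_raw,
    bonferroni = pmin(1, p_raw * ncol(pairs)),
    tukey = stats::ptukey(abs(tr) * sqrt(2), nmeans = k, df = fit$df,
                          lower.tail = FALSE))
  structure(list(
    emmeans = data.frame(level = levs, emmean = emm, se = emm_se,
                         stringsAsFactors = FALSE),
    contrasts = data.frame(
      contrast = paste(levs[pairs[1, ]], "-", levs[pairs[2, ]]),
      estimate = est, se = se, t_ratio = tr, df = fit$df, p = p_adj,
      stringsAsFactors = FALSE),
    adjust = adjust), class = "emm_table")
}

#' @export
print.emm_table <- function(x, ...) {
  cat("estimated marginal means:\n"); print(x$emmeans, digits = 4)
  cat(sprintf("pairwise contrasts (%s-adjusted):\n", x$adjust))
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Moran's I spatial autocorrelation test
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with centered values
#' `z` and `S0 = sum w_ij`. Expectation under no autocorrelation is
#' `-1/(n-1)`; the variance uses the normality assumption and the two-tailed
#' p comes from the z statistic.
#'
#' @param values numeric vector (e.g. model residuals); must not be constant.
#' @param w square weight matrix, zero diagonal, not all zero.
#' @return list of class `moran_result`: `observed`, `expected`, `sd`, `z`,
#'   `p`, `n`.
#' @export
morans_i <- function(values, w) {
  x <- as.numeric(values); w <- as.matrix(w)
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (nrow(w) != n || ncol(w) != n) stop("weight matrix dimension mismatch")
  if (stats::sd(x) == 0) stop("zero variance in values")
  diag(w) <- 0
  S0 <- sum(w)
  if (S0 == 0) stop("all-zero weight matrix")
  z <- x - mean(x)
  I <- (n / S0) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  EI <- -1 / (n - 1)
  S1 <- sum((w + t(w))^2) / 2
  S2 <- sum((rowSums(w) + colSums(w))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  zstat <- (I - EI) / sqrt(varI)
  structure(list(observed = I, expected = EI, sd = sqrt(varI), z = zstat,
                 p = 2 * stats::pnorm(-abs(zstat)), n = n),
            class = "moran_result")
}

#' Spatial weight matrices for residual diagnostics
#'
#' `knn_weights` links each site to its `k` nearest neighbours (binary,
#' then optionally row-standardized); `idw_weights` uses inverse distance.
#'
#' @param coords two-column matrix of projected coordinates (meters).
#' @param k number of neighbours (default 8).
#' @param row_standardize divide each row by its sum (default `TRUE`).
#' @return square weight matrix with zero diagonal.
#' @export
knn_weights <- function(coords, k = 8, row_standardize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be < number of sites")
  d <- as.matrix(stats::dist(coords))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    w[i, nb] <- 1
  }
  if (row_standardize) w <- w / rowSums(w)
  w
}

#' @rdname knn_weights
#' @export
idw_weights <- function(coords, row_standardize = TRUE) {
  d <- as.matrix(stats::dist(as.matrix(coords)))
  w <- ifelse(d > 0, 1 / d, 0)
  diag(w) <- 0
  if (row_standardize) w <- w / rowSums(w)
  w
}

#' Collinearity screen for candidate land-cover covariates
#'
#' Pearson correlations among the three land-cover proportions at one scale;
#' pairs with `|r| >= threshold` are flagged and the configured victim
#' (default the closed-green cover, which tracks impervious surface closely
#' in urban mosaics) is dropped from the candidate set.
#'
#' @param st a [site_table()] or data.frame with the scale's columns.
#' @param scale buffer radius.
#' @param threshold absolute correlation triggering a flag (default 0.7).
#' @param drop which flagged variable to remove (default `"closed_green"`).
#' @return list of class `collinearity_report`: `correlations`, `flagged`
#'   (data.frame of flagged pairs), `dropped` (character).
#' @export
collinearity_screen <- function(st, scale = 250, threshold = 0.7,
                                drop = "closed_green") {
  df <- if (inherits(st, "site_table")) st$sites else as.data.frame(st)
  vars <- c("impervious", "open_green", "closed_green")
  cols <- paste0(vars, "_", scale)
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(df[, cols]); colnames(m) <- vars
  r <- stats::cor(m, use = "complete.obs")
  pairs <- utils::combn(vars, 2)
  flags <- data.frame(var1 = pairs[1, ], var2 = pairs[2, ],
                      r = r[cbind(pairs[1, ], pairs[2, ])],
                      stringsAsFactors = FALSE)
  flags$flagged <- abs(flags$r) >= threshold
  dropped <- if (any(flags$flagged & (flags$var1 == drop | flags$var2 == drop)))
    drop else character(0)
  structure(list(correlations = r, flagged = flags[flags$flagged, ],
                 dropped = dropped, threshold = threshold),
            class = "collinearity_report")
}

#' Fit the Criterion-II clustering regression
#'
#' Convenience wrapper: builds the design at one scale, fits the OLS model,
#' and returns fit, EMM contrasts and (when coordinates are available) the
#' Moran's I test on residuals.
#'
#' @inheritParams build_design
#' @param ses a `ses_result` (merged by `site_id` onto the site table).
#' @param adjust contrast adjustment, see [emm_pairwise()].
#' @param moran_weights `"knn"`, `"idw"` or `"none"`.
#' @param moran_k neighbours for knn weights.
#' @return list of class `criterion2_result`: `fit`, `emm`, `moran` (or
#'   `NULL`), `design`, `collinearity`, `scale`.
#' @export
criterion2 <- function(st, ses, scale = 250,
                       factor_reference = "community_garden",
                       adjust = "tukey", moran_weights = "knn", moran_k = 8) {
  stopifnot(inherits(st, "site_table"))
  df <- merge(st$sites, ses[, c("site_id", "ses")], by = "site_id")
  df <- df[!is.na(df$ses), , drop = FALSE]
  coll <- collinearity_screen(df, scale = scale)
  des <- build_design(df, scale = scale, factor_reference = factor_reference)
  fit <- fit_ols(des$X, df$ses)
  emm <- emm_pairwise(fit, des, adjust = adjust)
  moran <- NULL
  if (moran_weights != "none" && all(c("x", "y") %in% names(df))) {
    coords <- as.matrix(df[, c("x", "y")])
    w <- if (moran_weights == "knn") knn_weights(coords, k = moran_k)
         else idw_weights(coords)
    moran <- morans_i(fit$residuals, w)
  }
  structure(list(fit = fit, emm = emm, moran = moran, design = des,
                 collinearity = coll, scale = scale, data = df),
            class = "criterion2_result")
}
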