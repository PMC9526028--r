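## Independent brute-force oracles, kept free of the package's hot paths.

## Gower dissimilarity by explicit per-trait loop
oracle_gower_pair <- function(tt, i, j) {
  num <- 0; den <- 0
  for (k in names(tt$traits)) {
    x <- tt$traits[[k]]
    w <- tt$weights[[k]]
    if (tt$types[[k]] == "continuous") {
      rng <- max(x) - min(x)
      d <- if (rng == 0) 0 else abs(x[i] - x[j]) / rng
    } else d <- if (as.character(x[i]) == as.character(x[j])) 0 else 1
    num <- num + w * d; den <- den + w
  }
  num / den
}

## abundance-weighted MPD by double loop
oracle_mpd <- function(a, d) {
  idx <- which(a > 0)
  if (length(idx) < 2) return(NA_real_)
  num <- 0; den <- 0
  for (i in idx) for (j in idx) if (i < j) {
    num <- num + d[i, j] * a[i] * a[j]
    den <- den + a[i] * a[j]
  }
  num / den
}

## all within-column permutation assignments of a small matrix
oracle_all_shuffles <- function(ab) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  n <- nrow(ab)
  colperms <- lapply(seq_len(ncol(ab)), function(j)
    unique(perms(ab[, j])))
  grids <- expand.grid(lapply(colperms, seq_along))
  lapply(seq_len(nrow(grids)), function(g) {
    m <- ab
    for (j in seq_len(ncol(ab))) m[, j] <- colperms[[j]][[grids[g, j]]]
    m
  })
}

## exact ses/p per site by exhaustive enumeration of the frequency null
oracle_exact_ses <- function(cm, d) {
  shuffles <- oracle_all_shuffles(cm$abundance)
  obs <- sapply(seq_len(nrow(cm$abundance)), function(s)
    oracle_mpd(cm$abundance[s, ], d))
  nulls <- sapply(shuffles, function(m)
    sapply(seq_len(nrow(m)), function(s) oracle_mpd(m[s, ], d)))
  if (is.null(dim(nulls))) nulls <- matrix(nulls, nrow = 1)
  res <- lapply(seq_len(nrow(cm$abundance)), function(s) {
    nv <- nulls[s, ]; nv <- nv[!is.na(nv)]
    m <- mean(nv); sdv <- sd(nv)
    p <- min(1, 2 * min(mean(nv <= obs[s]), mean(nv >= obs[s])))
    list(ses = (obs[s] - m) / sdv, p = p, mean = m, sd = sdv)
  })
  res
}

## OLS by explicit normal equations
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(beta = as.numeric(beta), se = as.numeric(se), df = df)
}

## eigenvalues of an ordination triplet (duality diagram)
triplet_eigenvalues <- function(trip) {
  A <- sweep(trip$Z, 2, sqrt(trip$col_metric), "*")
  A <- sweep(A, 1, sqrt(trip$row_weights), "*")
  ev <- svd(A)$d^2
  ev[ev > 1e-10]
}
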