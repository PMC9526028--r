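#' Correspondence analysis of the abundance table
#'
#' Classical CA: with relative frequencies `p_ij = L_ij / sum(L)`, row
#' masses `r_i = sum_j p_ij` and column masses `c_j = sum_i p_ij`, the
#' doubly-standardized table is `L0_ij = p_ij / (r_i c_j) - 1`. Eigenvalues
#' and scores come from the SVD of `D_r^{1/2} L0 D_c^{1/2}`; the weighted
#' variance of the axis-k row (or column) scores equals eigenvalue k.
#'
#' @param cm a `community_matrix` (or plain non-negative matrix) with no
#'   all-zero row or column.
#' @return list of class `ca_result`: `row_weights`, `col_weights`, `L0`,
#'   `eig`, `row_scores`, `col_scores` (principal coordinates).
#' @export
correspondence_analysis <- function(cm) {
  L <- if (inherits(cm, "community_matrix")) cm$abundance else as.matrix(cm)
  if (any(L < 0)) stop("abundances must be non-negative")
  if (sum(L) == 0) stop("total abundance is zero")
  if (any(rowSums(L) == 0)) stop("all-zero row(s): filter uncolonized sites first")
  if (any(colSums(L) == 0)) stop("all-zero column(s): filter absent species first")
  P <- L / sum(L)
  r <- rowSums(P); cc <- colSums(P)
  L0 <- sweep(sweep(P, 1, r, "/"), 2, cc, "/") - 1
  S <- sweep(sweep(L0, 1, sqrt(r), "*"), 2, sqrt(cc), "*")
  sv <- svd(S)
  pos <- sv$d > 1e-12
  eig <- sv$d[pos]^2
  row_scores <- sweep(sv$u[, pos, drop = FALSE], 1, sqrt(r), "/") %*%
    diag(sv$d[pos], sum(pos))
  col_scores <- sweep(sv$v[, pos, drop = FALSE], 1, sqrt(cc), "/") %*%
    diag(sv$d[pos], sum(pos))
  rownames(row_scores) <- rownames(L); rownames(col_scores) <- colnames(L)
  structure(list(row_weights = r, col_weights = cc, L0 = L0, eig = eig,
                 row_scores = row_scores, col_scores = col_scores),
            class = "ca_result")
}

## weighted mean / population-style weighted sd (weights sum to 1)
wmean <- function(x, w) sum(w * x) / sum(w)
wsd <- function(x, w) {
  w <- w / sum(w)
  sqrt(sum(w * (x - sum(w * x))^2))
}

#' Weighted standardization of the environmental table
#'
#' Centers and scales each quantitative column by its CA-row-mass-weighted
#' mean and standard deviation (weights sum to 1); the column metric is the
#' identity. This is the "PCA on R" step of the three-table ordination.
#'
#' @param R data.frame or matrix of quantitative site covariates.
#' @param row_weights site masses from [correspondence_analysis()].
#' @return list of class `ord_triplet`: `Z` (transformed table),
#'   `row_weights`, `col_metric`.
#' @export
weighted_pca_env <- function(R, row_weights) {
  R <- as.data.frame(R)
  if (!all(vapply(R, is.numeric, logical(1))))
    stop("environmental table must be quantitative")
  w <- row_weights / sum(row_weights)
  Z <- sapply(names(R), function(j) {
    x <- R[[j]]
    s <- wsd(x, w)
    if (s == 0) stop("zero weighted variance in column: ", j)
    (x - wmean(x, w)) / s
  })
  rownames(Z) <- rownames(R)
  structure(list(Z = Z, row_weights = w,
                 col_metric = rep(1, ncol(Z)),
                 col_names = colnames(Z)), class = "ord_triplet")
}

#' Hill-Smith transformation of the mixed trait table
#'
#' Mixed-variable ordination coding: quantitative columns become weighted
#' z-scores with column metric 1; each level `m` of a nominal column becomes
#' the transformed indicator `1[x = m]/p_m - 1` with column metric `p_m`,
#' the weighted level frequency. With all-quantitative input this reduces to
#' [weighted_pca_env()]; with all-nominal input the downstream eigenvalues
#' are those of multiple correspondence analysis. Levels with zero weighted
#' frequency are dropped with a warning.
#'
#' @param tt a [trait_table()] (or data.frame; numeric columns treated as
#'   quantitative, others as nominal).
#' @param row_weights species masses from [correspondence_analysis()].
#' @return an `ord_triplet` (see [weighted_pca_env()]).
#' @export
hill_smith <- function(tt, row_weights) {
  if (inherits(tt, "trait_table")) {
    df <- tt$traits
    kinds <- tt$types
  } else {
    df <- as.data.frame(tt)
    kinds <- vapply(df, function(x) if (is.numeric(x)) "continuous" else "nominal",
                    character(1))
  }
  w <- row_weights / sum(row_weights)
  Z <- NULL; cm <- numeric(0); nm <- character(0)
  for (j in names(df)) {
    x <- df[[j]]
    if (kinds[[j]] == "continuous") {
      s <- wsd(x, w)
      if (s == 0) stop("zero weighted variance in trait: ", j)
      Z <- cbind(Z, (x - wmean(x, w)) / s)
      cm <- c(cm, 1); nm <- c(nm, j)
    } else {
      x <- factor(x)
      for (lev in levels(x)) {
        ind <- as.numeric(x == lev)
        p <- sum(w * ind)
        if (p == 0) {
          warning(sprintf("level '%s' of trait '%s' has zero weight; dropped", lev, j))
          next
        }
        Z <- cbind(Z, ind / p - 1)
        cm <- c(cm, p); nm <- c(nm, paste0(j, ".", lev))
      }
    }
  }
  colnames(Z) <- nm
  rownames(Z) <- rownames(df)
  structure(list(Z = Z, row_weights = w, col_metric = cm, col_names = nm),
            class = "ord_triplet")
}

#' RLQ coupled ordination of environment, abundance and traits
#'
#' Links the environment table R (sites), abundance table L and trait table
#' Q (species) by a generalized SVD of the cross matrix
#' `M = Z_R' D_r L0 D_c Z_Q` in the two column metrics. Eigenvalues are the
#' squared singular values of `D_mR^{1/2} M D_mQ^{1/2}`; their sum — the
#' total co-inertia — equals the metric-weighted squared norm of `M` and is
#' the statistic of the permutation tests.
#'
#' @param env an `ord_triplet` from [weighted_pca_env()] (rows = sites of L).
#' @param ca a `ca_result` for L.
#' @param trait an `ord_triplet` from [hill_smith()] (rows = species of L).
#' @return list of class `rlq_result`: `eig`, `total_coinertia`,
#'   `env_scores` and `trait_scores` (column loadings, unit-norm in their
#'   metrics), `site_scores` (`Z_R` projected), `species_scores` (`Z_Q`
#'   projected) and `species_scores_normed` (unit weighted norm per axis).
#' @export
rlq <- function(env, ca, trait) {
  stopifnot(inherits(env, "ord_triplet"), inherits(ca, "ca_result"),
            inherits(trait, "ord_triplet"))
  if (nrow(env$Z) != nrow(ca$L0)) stop("sites of R must match rows of L")
  if (nrow(trait$Z) != ncol(ca$L0)) stop("species of Q must match columns of L")
  r <- ca$row_weights; cc <- ca$col_weights
  M <- t(env$Z) %*% (r * ca$L0 %*% (cc * trait$Z))
  A <- sweep(sweep(M, 1, sqrt(env$col_metric), "*"), 2, sqrt(trait$col_metric), "*")
  sv <- svd(A)
  pos <- sv$d > 1e-12
  eig <- sv$d[pos]^2
  ## loadings back in original coordinates, unit-norm under the column metrics
  env_scores <- sweep(sv$u[, pos, drop = FALSE], 1, sqrt(env$col_metric), "/")
  trait_scores <- sweep(sv$v[, pos, drop = FALSE], 1, sqrt(trait$col_metric), "/")
  rownames(env_scores) <- env$col_names
  rownames(trait_scores) <- trait$col_names
  site_scores <- env$Z %*% (env$col_metric * env_scores)
  species_scores <- trait$Z %*% (trait$col_metric * trait_scores)
  normed <- sweep(species_scores, 2,
                  sqrt(colSums(cc * species_scores^2)), "/")
  structure(list(eig = eig, total_coinertia = sum(A^2),
                 env_scores = env_scores, trait_scores = trait_scores,
                 site_scores = site_scores, species_scores = species_scores,
                 species_scores_normed = normed, cross = M),
            class = "rlq_result")
}

#' @export
print.rlq_result <- function(x, ...) {
  cat(sprintf("rlq_result: %d axes, total co-inertia %.6g\n",
              length(x$eig), x$total_coinertia))
  cat("eigenvalues:", format(x$eig, digits = 4), "\n")
  invisible(x)
}

## total co-inertia for given L-derived quantities and tables (internal)
rlq_statistic <- function(L0, r, cc, Renv, Q) {
  env <- weighted_pca_env(Renv, r)
  tr <- hill_smith(Q, cc)
  M <- t(env$Z) %*% (r * L0 %*% (cc * tr$Z))
  A <- sweep(sweep(M, 1, sqrt(env$col_metric), "*"), 2, sqrt(tr$col_metric), "*")
  sum(A^2)
}

#' Model-2 / Model-4 permutation tests for the RLQ association
#'
#' Tests the two links of the three-table association with total co-inertia
#' as the statistic, recomputed for every permutation. Model 2 permutes
#' species identities (the pairing of L's columns with Q's rows); Model 4
#' permutes site identities (the pairing of L's rows with R). The CA masses
#' stay attached to L, so each permuted statistic re-standardizes R or Q
#' under the re-paired weights. One-tailed upper p with add-one correction.
#'
#' @param cm filtered `community_matrix` (single-species sites retained).
#' @param st a [site_table()] or data.frame of quantitative site covariates;
#'   when a `site_table`, the three land-cover proportions at `scale` are
#'   used.
#' @param tt a [trait_table()].
#' @param model `"model2"` or `"model4"`.
#' @param n_perm number of permutations (study value 49999).
#' @param scale buffer radius used to pick covariate columns.
#' @param seed optional integer seed.
#' @return list of class `perm_test_result`: `model`, `observed`, `perm`
#'   (permuted statistics), `n_perm`, `p`.
#' @export
rlq_permutation_test <- function(cm, st, tt, model = c("model2", "model4"),
                                 n_perm = 49999, scale = 250, seed = NULL) {
  model <- match.arg(model)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  Renv <- env_table_for_rlq(st, cm, scale)
  ca <- correspondence_analysis(cm)
  r <- ca$row_weights; cc <- ca$col_weights; L0 <- ca$L0
  Q <- if (inherits(tt, "trait_table")) tt else trait_table(as.data.frame(tt))
  Qdf <- Q$traits
  obs <- rlq_statistic(L0, r, cc, Renv, Q)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    if (model == "model2") {
      idx <- sample.int(nrow(Qdf))
      Qp <- Q; Qp$traits <- Qdf[idx, , drop = FALSE]
      perm[b] <- rlq_statistic(L0, r, cc, Renv, Qp)
    } else {
      idx <- sample.int(nrow(Renv))
      perm[b] <- rlq_statistic(L0, r, cc, Renv[idx, , drop = FALSE], Q)
    }
  }
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  structure(list(model = model, observed = obs, perm = perm,
                 n_perm = n_perm, p = p), class = "perm_test_result")
}

env_table_for_rlq <- function(st, cm, scale) {
  if (inherits(st, "site_table")) {
    df <- st$sites[match(cm$site_ids, st$sites$site_id), , drop = FALSE]
    if (anyNA(df$site_id)) stop("site table does not cover all community sites")
    cols <- paste0(c("open_green_", "closed_green_", "impervious_"), scale)
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    out <- df[, cols]
    names(out) <- c("open_green", "closed_green", "impervious")
    rownames(out) <- cm$site_ids
    out
  } else {
    out <- as.data.frame(st)
    if (nrow(out) != length(cm$site_ids)) stop("environment rows must match sites")
    out
  }
}

#' Sequential combination of the Model-2 and Model-4 tests
#'
#' The association is declared only if both links reject, so the combined
#' p-value is the maximum of the two.
#'
#' @param p_model2,p_model4 p-values in (0, 1\].
#' @return combined p-value.
#' @export
sequential_combine <- function(p_model2, p_model4) {
  stopifnot(p_model2 > 0, p_model2 <= 1, p_model4 > 0, p_model4 <= 1)
  max(p_model2, p_model4)
}

#' Run the full Criterion-III analysis
#'
#' Correspondence analysis of L, weighted PCA of R, Hill-Smith of Q, the
#' RLQ ordination, and both sequential permutation tests.
#'
#' @inheritParams rlq_permutation_test
#' @return list of class `criterion3_result`: `rlq`, `test2`, `test4`,
#'   `p_combined`, `scale`.
#' @export
criterion3 <- function(cm, st, tt, n_perm = 49999, scale = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Renv <- env_table_for_rlq(st, cm, scale)
  ca <- correspondence_analysis(cm)
  env <- weighted_pca_env(Renv, ca$row_weights)
  trip <- hill_smith(tt, ca$col_weights)
  ord <- rlq(env, ca, trip)
  t2 <- rlq_permutation_test(cm, st, tt, "model2", n_perm = n_perm, scale = scale)
  t4 <- rlq_permutation_test(cm, st, tt, "model4", n_perm = n_perm, scale = scale)
  structure(list(rlq = ord, test2 = t2, test4 = t4,
                 p_combined = sequential_combine(t2$p, t4$p), scale = scale),
            class = "criterion3_result")
}

#' Fourth-corner statistic for one trait and one environmental variable
#'
#' The weighted covariance `sum_ij r_i c_j L0_ij x_i y_j` between a single
#' quantitative environmental variable (weight-standardized over sites) and
#' a single quantitative trait (weight-standardized over species), mediated
#' by the abundance table. With one variable on each side, the leading RLQ
#' eigenvalue equals this statistic squared. Exposed as a testing oracle;
#' the pairwise fourth-corner post-hoc analysis is out of scope.
#'
#' @param cm a `community_matrix`.
#' @param env_var numeric per-site variable.
#' @param trait_var numeric per-species variable.
#' @return scalar statistic.
#' @export
fourth_corner_stat <- function(cm, env_var, trait_var) {
  ca <- correspondence_analysis(cm)
  r <- ca$row_weights; cc <- ca$col_weights
  x <- (env_var - wmean(env_var, r)) / wsd(env_var, r)
  y <- (trait_var - wmean(trait_var, cc)) / wsd(trait_var, cc)
  as.numeric(t(x * r) %*% ca$L0 %*% (cc * y))
}
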