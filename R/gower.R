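#' Gower dissimilarity matrix over mixed traits
#'
#' Classic Gower distance between species: for each trait k the per-pair
#' contribution is `|x_ik - x_jk| / range_k` for continuous traits (range
#' taken over the species pool in the table) and `1[x_ik != x_jk]` for
#' nominal traits; the distance is the weighted mean of contributions,
#' `d_ij = sum_k w_k d_ijk / sum_k w_k`. All distances lie in \[0, 1\].
#'
#' A continuous trait with zero range carries no information and contributes
#' 0 with a warning. Missing trait values are rejected: species with
#' incomplete traits are expected to be removed by the study filters, not
#' pairwise-deleted here.
#'
#' @param tt a [trait_table()].
#' @return A `dist_matrix`: list with `species_ids` and a symmetric `d`
#'   matrix with zero diagonal.
#' @export
gower_matrix <- function(tt) {
  stopifnot(inherits(tt, "trait_table"))
  n <- length(tt$species_ids)
  if (n < 2) stop("need >= 2 species")
  if (anyNA(tt$traits)) {
    bad <- names(tt$traits)[vapply(tt$traits, anyNA, logical(1))]
    stop("missing trait values (filter species first): ",
         paste(bad, collapse = ", "))
  }
  num <- matrix(0, n, n)
  wsum <- 0
  for (k in names(tt$traits)) {
    w <- tt$weights[[k]]
    x <- tt$traits[[k]]
    if (tt$types[[k]] == "continuous") {
      rng <- diff(range(x))
      if (rng == 0) {
        warning(sprintf("continuous trait '%s' has zero range; contributes 0", k))
        contrib <- matrix(0, n, n)
      } else contrib <- abs(outer(x, x, "-")) / rng
    } else {
      x <- as.character(x)
      contrib <- 1 * outer(x, x, "!=")
    }
    num <- num + w * contrib
    wsum <- wsum + w
  }
  d <- num / wsum
  if (all(d == 0)) warning("all species identical on all traits: zero distance matrix")
  dimnames(d) <- list(tt$species_ids, tt$species_ids)
  structure(list(species_ids = tt$species_ids, d = d), class = "dist_matrix")
}

#' Gower dissimilarity between two species
#'
#' Scalar entry point, identical to the corresponding [gower_matrix()] cell
#' (the continuous-trait ranges are still taken over the full table pool).
#'
#' @param a,b species ids present in `tt`.
#' @param tt a [trait_table()].
#' @return dissimilarity in \[0, 1\].
#' @export
gower_pair <- function(a, b, tt) {
  stopifnot(inherits(tt, "trait_table"))
  idx <- match(c(a, b), tt$species_ids)
  if (anyNA(idx)) stop("unknown species id: ", paste(c(a, b)[is.na(idx)], collapse = ", "))
  num <- 0; wsum <- 0
  for (k in names(tt$traits)) {
    w <- tt$weights[[k]]
    x <- tt$traits[[k]]
    if (tt$types[[k]] == "continuous") {
      rng <- diff(range(x))
      contrib <- if (rng == 0) 0 else abs(x[idx[1]] - x[idx[2]]) / rng
    } else contrib <- as.numeric(as.character(x[idx[1]]) != as.character(x[idx[2]]))
    num <- num + w * contrib
    wsum <- wsum + w
  }
  num / wsum
}

#' @rdname gower_matrix
#' @param dm a `dist_matrix`.
#' @param path CSV path (square matrix, species ids as header and first column).
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(species_id = dm$species_ids, dm$d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
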