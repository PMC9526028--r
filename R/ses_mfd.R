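#' Abundance-weighted mean pairwise functional distance (MFD)
#'
#' For one community with abundances `a` and functional distances `d`,
#' `MFD = sum_{i<j} d_ij a_i a_j / sum_{i<j} a_i a_j` over the species with
#' positive abundance (unordered pairs, i != j). With fewer than two species
#' present the quantity is undefined and `NA` is returned; batch callers
#' flag such sites rather than erroring.
#'
#' @param abundance numeric vector of species abundances (named or in the
#'   order of the distance matrix).
#' @param dm a `dist_matrix` from [gower_matrix()], or a plain symmetric
#'   matrix with zero diagonal.
#' @return MFD, or `NA_real_` when fewer than two species are present.
#' @export
mpd_weighted <- function(abundance, dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (!is.null(names(abundance)) && !is.null(colnames(d)))
    abundance <- abundance[colnames(d)]
  a <- as.numeric(abundance)
  if (length(a) != ncol(d)) stop("abundance length does not match distance matrix")
  if (sum(a > 0) < 2) return(NA_real_)
  num <- as.numeric(t(a) %*% d %*% a) / 2         # diag(d) = 0
  den <- (sum(a)^2 - sum(a^2)) / 2
  num / den
}

## vectorized MFD for all rows of an abundance matrix (internal hot path)
mfd_all_sites <- function(ab, d) {
  num <- rowSums((ab %*% d) * ab) / 2
  den <- (rowSums(ab)^2 - rowSums(ab^2)) / 2
  out <- num / den
  out[rowSums(ab > 0) < 2] <- NA_real_
  out
}

#' Frequency-preserving null randomization of a community matrix
#'
#' Independently permutes each species' abundances across sites. Per species,
#' the multiset of abundance values — and hence the occupancy (occurrence
#' frequency) — is conserved exactly; per-site richness is not.
#'
#' @param cm a pooled `community_matrix`.
#' @return A `community_matrix` with shuffled columns.
#' @export
null_frequency_shuffle <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  ab <- shuffle_columns(cm$abundance)
  out <- cm
  out$abundance <- ab
  out
}

shuffle_columns <- function(ab) {
  n <- nrow(ab)
  if (n == 1) return(ab)
  out <- ab
  for (j in seq_len(ncol(ab))) out[, j] <- ab[sample.int(n), j]
  out
}

## add-one two-tailed permutation p from observed vs null draws (ties both tails)
perm_p_two_tailed <- function(obs, nulls) {
  nulls <- nulls[!is.na(nulls)]
  n <- length(nulls)
  lo <- (1 + sum(nulls <= obs)) / (n + 1)
  hi <- (1 + sum(nulls >= obs)) / (n + 1)
  min(1, 2 * min(lo, hi))
}

#' Standardized effect size of MFD against the frequency null model
#'
#' For each site, compares the observed abundance-weighted MFD with its
#' distribution over `n_null` frequency-preserving randomizations
#' ([null_frequency_shuffle()]):
#' `ses = (MFD_obs - mean(MFD_null)) / sd(MFD_null)`.
#' Negative ses indicates trait clustering, positive ses overdispersion.
#' The two-tailed permutation p uses the add-one rank in both tails (ties
#' counted in both, capped at 1); a normal-approximation p
#' (`2 * pnorm(-|ses|)`) is reported alongside. A null draw can leave a site
#' with fewer than two species; such draws are dropped for that site and
#' `n_null_used` records how many informed the null moments. Sites whose
#' null SD is zero (e.g. constant distance matrices) are classified
#' `undefined`.
#'
#' @param cm pooled, filtered `community_matrix`.
#' @param dm `dist_matrix` covering the community's species.
#' @param n_null number of randomizations (study value 4999).
#' @param alpha two-tailed significance level (default 0.05).
#' @param seed optional integer seed for the randomizations.
#' @return A data.frame of class `ses_result` with one row per site:
#'   `site_id`, `mfd_obs`, `null_mean`, `null_sd`, `ses`, `p`,
#'   `p_normal`, `n_null`, `n_null_used`, `classification` (one of
#'   `clustered_significant`, `clustered_ns`, `overdispersed_ns`,
#'   `overdispersed_significant`, `random`, `undefined`).
#' @export
ses_mfd <- function(cm, dm, n_null = 4999, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cm, "community_matrix"), n_null >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  sp <- colnames(d)
  if (!is.null(sp) && !identical(sp, cm$species_ids)) {
    if (!all(cm$species_ids %in% sp))
      stop("distance matrix does not cover all species")
    d <- d[cm$species_ids, cm$species_ids]
  }
  ab <- cm$abundance
  obs <- mfd_all_sites(ab, d)
  nulls <- matrix(NA_real_, n_null, nrow(ab))
  for (b in seq_len(n_null))
    nulls[b, ] <- mfd_all_sites(shuffle_columns(ab), d)
  null_mean <- colMeans(nulls, na.rm = TRUE)
  null_sd <- apply(nulls, 2, stats::sd, na.rm = TRUE)
  used <- colSums(!is.na(nulls))
  ses <- (obs - null_mean) / null_sd
  ses[!is.finite(ses)] <- NA_real_
  p <- vapply(seq_len(nrow(ab)), function(s) {
    if (is.na(obs[s]) || is.na(ses[s])) return(NA_real_)
    perm_p_two_tailed(obs[s], nulls[, s])
  }, numeric(1))
  p_normal <- ifelse(is.na(ses), NA_real_, 2 * stats::pnorm(-abs(ses)))
  cls <- classify_ses(ses, p, alpha)
  out <- data.frame(site_id = cm$site_ids, mfd_obs = obs,
                    null_mean = null_mean, null_sd = null_sd, ses = ses,
                    p = p, p_normal = p_normal, n_null = n_null,
                    n_null_used = used, classification = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ses_result", "data.frame")
  out
}

classify_ses <- function(ses, p, alpha) {
  ifelse(is.na(ses) | is.na(p), "undefined",
  ifelse(ses < 0 & p < alpha, "clustered_significant",
  ifelse(ses > 0 & p < alpha, "overdispersed_significant",
  ifelse(ses < 0, "clustered_ns",
  ifelse(ses > 0, "overdispersed_ns", "random")))))
}

#' Summarize ses.MFD classifications across sites
#'
#' @param res a `ses_result` from [ses_mfd()].
#' @param ugs_type optional factor/character of green-space types aligned
#'   with `res$site_id` for a per-type breakdown of significant clustering.
#' @return list of counts: `n_total`, `n_defined`, `n_negative_ses`,
#'   `n_significant_clustered`, `n_significant_overdispersed`, `n_random`
#'   (non-significant sites, i.e. consistent with random assembly), and
#'   optionally `per_ugs` (significant-clustered counts by type).
#' @export
summarize_clustering <- function(res, ugs_type = NULL) {
  cls <- res$classification
  out <- list(
    n_total = nrow(res),
    n_defined = sum(cls != "undefined"),
    n_negative_ses = sum(res$ses < 0, na.rm = TRUE),
    n_significant_clustered = sum(cls == "clustered_significant"),
    n_significant_overdispersed = sum(cls == "overdispersed_significant"),
    n_random = sum(cls %in% c("clustered_ns", "overdispersed_ns", "random")))
  if (!is.null(ugs_type)) {
    sig <- cls == "clustered_significant"
    out$per_ugs <- as.list(table(factor(ugs_type)[sig]))
  }
  out
}

#' @rdname ses_mfd
#' @param res a `ses_result`.
#' @param path CSV path.
#' @export
write_ses_result <- function(res, path) {
  utils::write.csv(res, path, row.names = FALSE)
  invisible(path)
}
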