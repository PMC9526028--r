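#' Community matrix (sites x species brood-cell counts)
#'
#' Container for trap-nest abundance data: counts of completed brood cells
#' (including parasitized/diseased individuals) per species per site, with
#' per-site survey-year provenance. This is the L-table of the RLQ framework.
#'
#' @param abundance numeric matrix of non-negative integers, sites in rows,
#'   species in columns. Row and column names are used as identifiers when
#'   `site_ids` / `species_ids` are not given.
#' @param site_ids,species_ids character vectors of unique identifiers.
#' @param years_sampled named list (by site id) of integer survey years, or
#'   `NULL` when provenance is unknown (each site then counts as fully sampled).
#' @return An object of class `community_matrix`: a list with elements
#'   `abundance`, `site_ids`, `species_ids`, `years_sampled`.
#' @export
community_matrix <- function(abundance, site_ids = rownames(abundance),
                             species_ids = colnames(abundance),
                             years_sampled = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(site_ids)) site_ids <- paste0("site_", seq_len(nrow(abundance)))
  if (is.null(species_ids)) species_ids <- paste0("sp_", seq_len(ncol(abundance)))
  site_ids <- as.character(site_ids)
  species_ids <- as.character(species_ids)
  if (length(site_ids) != nrow(abundance) || length(species_ids) != ncol(abundance))
    stop("id lists must match matrix dimensions")
  if (anyDuplicated(site_ids)) stop("duplicate site ids")
  if (anyDuplicated(species_ids)) stop("duplicate species ids")
  bad <- which(!is.finite(abundance) | abundance < 0 | abundance != round(abundance),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("abundance must be a non-negative integer: offending cell site '%s', species '%s'",
                 site_ids[bad[1, 1]], species_ids[bad[1, 2]]))
  dimnames(abundance) <- list(site_ids, species_ids)
  storage.mode(abundance) <- "double"
  if (!is.null(years_sampled)) {
    years_sampled <- years_sampled[site_ids]
    names(years_sampled) <- site_ids
  }
  structure(list(abundance = abundance, site_ids = site_ids,
                 species_ids = species_ids, years_sampled = years_sampled),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species, total abundance %d\n",
              length(x$site_ids), length(x$species_ids), sum(x$abundance)))
  invisible(x)
}

#' Species trait table with variable-type specification
#'
#' The Q-table: one row per species, mixed-type trait columns. Every column
#' must be declared `continuous` or `nominal` in `types`; rank and count
#' traits are usually declared continuous so that their order information
#' enters the Gower distance (switch them to nominal to ignore order).
#'
#' @param traits data.frame of trait values, one row per species.
#' @param species_ids character vector (defaults to `rownames(traits)`).
#' @param types named character vector mapping every trait column to
#'   `"continuous"` or `"nominal"`. Columns not named are guessed from their
#'   storage type (numeric -> continuous, otherwise nominal).
#' @param weights named numeric vector of Gower weights (default all 1).
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(traits, species_ids = rownames(traits),
                        types = NULL, weights = NULL) {
  traits <- as.data.frame(traits)
  if (is.null(species_ids)) species_ids <- paste0("sp_", seq_len(nrow(traits)))
  species_ids <- as.character(species_ids)
  if (anyDuplicated(species_ids)) stop("duplicate species ids")
  if (length(species_ids) != nrow(traits)) stop("species_ids length mismatch")
  guessed <- vapply(traits, function(x) if (is.numeric(x)) "continuous" else "nominal",
                    character(1))
  if (is.null(types)) types <- guessed
  full <- guessed
  full[names(types)] <- types
  if (!all(full %in% c("continuous", "nominal")))
    stop("trait types must be 'continuous' or 'nominal'")
  if (!all(names(full) %in% names(traits)) || length(full) != ncol(traits))
    stop("types must cover exactly the trait columns")
  w <- rep(1, ncol(traits)); names(w) <- names(traits)
  if (!is.null(weights)) w[names(weights)] <- weights
  bad <- names(traits)[full == "continuous" &
                         !vapply(traits, is.numeric, logical(1))]
  if (length(bad)) stop("continuous traits must be numeric: ", paste(bad, collapse = ", "))
  rownames(traits) <- species_ids
  structure(list(traits = traits, species_ids = species_ids,
                 types = full, weights = w),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d species, %d traits (%d continuous, %d nominal)\n",
              length(x$species_ids), length(x$types),
              sum(x$types == "continuous"), sum(x$types == "nominal")))
  invisible(x)
}

#' Site covariate table
#'
#' The R-table: per-site urban-green-space (UGS) type, land-cover proportions
#' at one or more buffer scales, and optional projected coordinates (meters).
#'
#' @param sites data.frame with columns `site_id`, `ugs_type`, and for each
#'   scale `s` the columns `impervious_<s>`, `open_green_<s>`,
#'   `closed_green_<s>` (proportions in \[0,1\] of the non-water buffer area);
#'   optionally `x`, `y` coordinates.
#' @param scales integer vector of buffer radii (m) present in `sites`.
#' @return An object of class `site_table`.
#' @export
site_table <- function(sites, scales = c(250, 500)) {
  sites <- as.data.frame(sites)
  if (!"site_id" %in% names(sites)) stop("sites must have a site_id column")
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids")
  if ("ugs_type" %in% names(sites)) sites$ugs_type <- factor(sites$ugs_type)
  for (s in scales) {
    cols <- paste0(c("impervious_", "open_green_", "closed_green_"), s)
    miss <- setdiff(cols, names(sites))
    if (length(miss)) stop("missing land-cover columns: ", paste(miss, collapse = ", "))
    pr <- as.matrix(sites[, cols])
    if (any(pr < -1e-9 | pr > 1 + 1e-9, na.rm = TRUE))
      stop("land-cover proportions must lie in [0,1]")
    tot <- rowSums(pr)
    if (any(tot > 1 + 1e-6, na.rm = TRUE))
      stop(sprintf("non-water proportions exceed 1 at scale %d", s))
  }
  structure(list(sites = sites, scales = scales, site_ids = sites$site_id),
            class = "site_table")
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table: %d sites, scales {%s} m\n",
              length(x$site_ids), paste(x$scales, collapse = ", ")))
  invisible(x)
}

#' Read a community table from delimited text
#'
#' Expects a comma-separated UTF-8 table with a header row: first column the
#' site id, an optional `year` column, remaining columns species counts.
#' Rows sharing a site id (yearly records) are kept separate until
#' [pool_years()] is applied.
#'
#' @param path path to a CSV file.
#' @return A `community_matrix`; when a `year` column is present the matrix
#'   has one row per site-year (row ids `site@year`) and `years_sampled`
#'   records the years observed per site.
#' @export
read_community <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("community table needs a site column and >=1 species")
  site <- as.character(df[[1]])
  has_year <- "year" %in% names(df)[-1]
  year <- if (has_year) as.integer(df$year) else rep(NA_integer_, nrow(df))
  sp_cols <- setdiff(names(df)[-1], "year")
  ab <- as.matrix(df[, sp_cols, drop = FALSE])
  bad <- which(!is.finite(ab) | ab < 0 | ab != round(ab), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid abundance at row %d (site '%s'), species '%s': %s",
                 bad[1, 1], site[bad[1, 1]], sp_cols[bad[1, 2]],
                 format(ab[bad[1, , drop = FALSE]])))
  key <- if (has_year) paste(site, year, sep = "@") else site
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate site-year row: ", d)
  }
  years <- NULL
  if (has_year) {
    years <- split(year, site)[unique(site)]
  } else {
    years <- stats::setNames(vector("list", length(unique(site))), unique(site))
  }
  cm <- community_matrix(ab, site_ids = key, species_ids = sp_cols)
  cm$years_sampled <- years
  cm$pooled <- !has_year
  cm
}

#' Pool yearly community records into a single matrix
#'
#' Sums abundances across years within each site, preserving the per-site set
#' of sampled years for downstream filtering. Total abundance per species per
#' site is conserved.
#'
#' @param cm a `community_matrix` whose row ids are `site@year` keys (as
#'   produced by [read_community()] on a table with a `year` column), or an
#'   already-pooled matrix (returned unchanged).
#' @return A pooled `community_matrix` with one row per site.
#' @export
pool_years <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  if (!any(grepl("@", cm$site_ids, fixed = TRUE))) return(cm)
  site <- sub("@.*$", "", cm$site_ids)
  usite <- unique(site)
  pooled <- rowsum(cm$abundance, group = factor(site, levels = usite))
  out <- community_matrix(pooled, site_ids = usite, species_ids = cm$species_ids)
  out$years_sampled <- cm$years_sampled[usite]
  out
}

#' Study filtering rules for the clustering and RLQ analyses
#'
#' Produces the analysis-ready community and trait tables by applying, in
#' order: (a) species filters — drop species with missing `body_size`,
#' species on the configured exclusion list, and species never observed in
#' the pooled matrix (all-zero columns); (b) site filters — drop sites
#' sampled in fewer than `required_years` years, uncolonized sites (zero
#' total abundance), and sites with fewer than `min_species` species present.
#' Species filters run first, so a site reduced to one species by a species
#' drop counts as a singleton. Each removed id gets exactly one reason, the
#' first matching rule.
#'
#' @param cm pooled `community_matrix`.
#' @param tt `trait_table` covering (at least) the community's species.
#' @param required_years minimum number of sampled years per site (default 3);
#'   sites with unknown provenance (`NULL` year sets) always pass.
#' @param min_species minimum number of species with positive abundance per
#'   site: 2 for the clustering analysis (pairwise distances need two
#'   species), 1 for the RLQ analysis.
#' @param species_exclusions character vector of species ids to drop.
#' @param body_size_col name of the trait column whose missingness removes a
#'   species (default `"body_size"`; set `NULL` to skip the rule).
#' @return list with elements `community`, `traits` (filtered copies) and
#'   `report` (a `filter_report`: counts and a removal table with columns
#'   `id`, `what`, `reason`).
#' @export
apply_study_filters <- function(cm, tt, required_years = 3, min_species = 2,
                                species_exclusions = character(),
                                body_size_col = "body_size") {
  stopifnot(inherits(cm, "community_matrix"), inherits(tt, "trait_table"))
  removals <- data.frame(id = character(), what = character(),
                         reason = character(), stringsAsFactors = FALSE)
  note <- function(id, what, reason)
    rbind(removals, data.frame(id = id, what = what, reason = reason))

  ## species filters first
  sp <- cm$species_ids
  keep_sp <- rep(TRUE, length(sp)); names(keep_sp) <- sp
  in_tt <- sp %in% tt$species_ids
  miss_bs <- rep(FALSE, length(sp))
  if (!is.null(body_size_col) && body_size_col %in% names(tt$traits)) {
    bs <- tt$traits[[body_size_col]][match(sp, tt$species_ids)]
    miss_bs <- !in_tt | is.na(bs)
  } else miss_bs <- !in_tt
  excl <- sp %in% species_exclusions
  never <- colSums(cm$abundance) == 0
  for (i in seq_along(sp)) {
    if (!keep_sp[i]) next
    if (miss_bs[i]) { removals <- note(sp[i], "species", "missing_body_size"); keep_sp[i] <- FALSE }
    else if (excl[i]) { removals <- note(sp[i], "species", "excluded_by_config"); keep_sp[i] <- FALSE }
    else if (never[i]) { removals <- note(sp[i], "species", "uncolonized"); keep_sp[i] <- FALSE }
  }
  ab <- cm$abundance[, keep_sp, drop = FALSE]

  ## site filters
  sites <- cm$site_ids
  keep_site <- rep(TRUE, length(sites)); names(keep_site) <- sites
  nyears <- vapply(sites, function(s) {
    ys <- cm$years_sampled[[s]]
    if (is.null(ys)) Inf else length(unique(ys))
  }, numeric(1))
  richness <- rowSums(ab > 0)
  total <- rowSums(ab)
  for (i in seq_along(sites)) {
    if (nyears[i] < required_years) { removals <- note(sites[i], "site", "insufficient_years"); keep_site[i] <- FALSE }
    else if (total[i] == 0) { removals <- note(sites[i], "site", "uncolonized"); keep_site[i] <- FALSE }
    else if (richness[i] < min_species) { removals <- note(sites[i], "site", "singleton"); keep_site[i] <- FALSE }
  }
  if (!any(keep_site) || !any(keep_sp))
    stop("filters removed all sites or all species")

  out_cm <- community_matrix(ab[keep_site, , drop = FALSE],
                             site_ids = sites[keep_site],
                             species_ids = sp[keep_sp])
  out_cm$years_sampled <- cm$years_sampled[sites[keep_site]]
  keep_tt <- tt$species_ids %in% sp[keep_sp]
  out_tt <- trait_table(tt$traits[keep_tt, , drop = FALSE],
                        species_ids = tt$species_ids[keep_tt],
                        types = tt$types, weights = tt$weights)
  report <- structure(list(
    n_sites_in = length(sites), n_sites_out = sum(keep_site),
    n_species_in = length(sp), n_species_out = sum(keep_sp),
    removals = removals), class = "filter_report")
  list(community = out_cm, traits = out_tt, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: sites %d -> %d, species %d -> %d\n",
              x$n_sites_in, x$n_sites_out, x$n_species_in, x$n_species_out))
  if (nrow(x$removals)) print(table(x$removals$what, x$removals$reason))
  invisible(x)
}

#' @rdname apply_study_filters
#' @param ... passed to [apply_study_filters()].
#' @export
apply_criterion1_filters <- function(cm, tt, ...)
  apply_study_filters(cm, tt, min_species = 2, ...)

#' @rdname apply_study_filters
#' @export
apply_criterion3_filters <- function(cm, tt, ...)
  apply_study_filters(cm, tt, min_species = 1, ...)

#' Write / read helpers for study tables
#'
#' Round-trip the three study tables through plain CSV.
#' @param cm,tt,st objects to write.
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_community <- function(cm, path) {
  df <- data.frame(site_id = cm$site_ids, cm$abundance, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
write_traits <- function(tt, path) {
  df <- data.frame(species_id = tt$species_ids, tt$traits, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_traits <- function(path, types = NULL, weights = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  trait_table(df[, -1, drop = FALSE], species_ids = df[[1]],
              types = types, weights = weights)
}

#' @rdname table_io
#' @param scales buffer scales expected in the file.
#' @export
read_sites <- function(path, scales = c(250, 500)) {
  site_table(utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
             scales = scales)
}

#' @rdname table_io
#' @export
write_sites <- function(st, path) {
  utils::write.csv(st$sites, path, row.names = FALSE)
  invisible(path)
}
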