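#' Run configuration for the three-criterion pipeline
#'
#' @param community,traits,sites paths to CSV inputs, or `NULL` to simulate.
#' @param sim a [simulation_spec()] used when paths are `NULL`.
#' @param scale buffer radius for criteria II and III (250 or 500).
#' @param n_null randomizations for ses.MFD (study value 4999).
#' @param n_perm permutations per sequential-test model (study value 49999).
#' @param alpha global significance level (default 0.05).
#' @param adjust EMM contrast adjustment (default `"tukey"`).
#' @param required_years minimum sampled years per site (default 3).
#' @param species_exclusions species ids dropped by configuration.
#' @param seed root seed for every random stage.
#' @param outdir optional directory for CSV/JSON artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(community = NULL, traits = NULL, sites = NULL,
                       sim = simulation_spec(), scale = 250,
                       n_null = 4999, n_perm = 49999, alpha = 0.05,
                       adjust = "tukey", required_years = 3,
                       species_exclusions = character(), seed = 1L,
                       outdir = NULL) {
  stopifnot(n_null >= 1, n_perm >= 1, alpha > 0, alpha < 1)
  structure(list(community = community, traits = traits, sites = sites,
                 sim = sim, scale = scale, n_null = n_null, n_perm = n_perm,
                 alpha = alpha, adjust = adjust,
                 required_years = required_years,
                 species_exclusions = species_exclusions,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the full three-criterion analysis
#'
#' Executes, in order: input loading (or simulation), year pooling, the
#' clustering filters, Gower distances, ses.MFD with its null model
#' (Criterion I), the clustering regression with EMM contrasts and Moran's I
#' (Criterion II), the RLQ ordination with the Model-2/Model-4 sequential
#' tests on the single-species-inclusive site set (Criterion III), and the
#' combined verdict: environmental filtering is supported only when all
#' three criteria are met at the configured alpha.
#'
#' Criterion I is judged by a one-sided binomial test of the significantly
#' clustered fraction against alpha; Criterion II by the two-tailed test on
#' the impervious-surface slope; Criterion III by the combined sequential
#' p-value.
#'
#' @param config a [run_config()].
#' @return list of class `criteria_report`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ## inputs
  dat <- stage("input", {
    if (!is.null(config$community)) {
      list(community = pool_years(read_community(config$community)),
           traits = read_traits(config$traits),
           sites = read_sites(config$sites))
    } else {
      sim <- config$sim
      sim$seed <- config$seed
      s <- simulate_study(sim)
      list(community = s$community, traits = s$traits, sites = s$sites)
    }
  })

  ## criterion I
  f1 <- stage("filter_criterion1",
              apply_criterion1_filters(dat$community, dat$traits,
                                       required_years = config$required_years,
                                       species_exclusions = config$species_exclusions))
  dm <- stage("gower", gower_matrix(f1$traits))
  ses <- stage("ses_mfd",
               ses_mfd(f1$community, dm, n_null = config$n_null,
                       alpha = config$alpha, seed = config$seed))
  ugs <- dat$sites$sites$ugs_type[match(ses$site_id, dat$sites$sites$site_id)]
  counts <- summarize_clustering(ses, ugs_type = ugs)
  crit1_p <- stats::binom.test(counts$n_significant_clustered,
                               counts$n_defined, p = config$alpha,
                               alternative = "greater")$p.value
  crit1_met <- crit1_p < config$alpha

  ## criterion II
  c2 <- stage("criterion2",
              criterion2(dat$sites, ses, scale = config$scale,
                         adjust = config$adjust))
  imp <- c2$fit$coefficients[c2$fit$coefficients$term == "impervious", ]
  crit2_met <- nrow(imp) == 1 && imp$p < config$alpha

  ## criterion III
  f3 <- stage("filter_criterion3",
              apply_criterion3_filters(dat$community, dat$traits,
                                       required_years = config$required_years,
                                       species_exclusions = config$species_exclusions))
  c3 <- stage("criterion3",
              criterion3(f3$community, dat$sites, f3$traits,
                         n_perm = config$n_perm, scale = config$scale,
                         seed = config$seed + 1L))
  crit3_met <- c3$p_combined < config$alpha

  report <- structure(list(
    criterion1 = list(counts = counts, binomial_p = crit1_p, met = crit1_met,
                      filter = f1$report, ses = ses),
    criterion2 = list(coefficients = c2$fit$coefficients,
                      contrasts = c2$emm$contrasts,
                      moran = c2$moran, collinearity = c2$collinearity,
                      met = crit2_met, result = c2),
    criterion3 = list(eig = c3$rlq$eig,
                      total_coinertia = c3$rlq$total_coinertia,
                      p_model2 = c3$test2$p, p_model4 = c3$test4$p,
                      p_combined = c3$p_combined, met = crit3_met,
                      filter = f3$report, result = c3),
    verdict = if (crit1_met && crit2_met && crit3_met)
      "filtering_supported" else "filtering_not_supported",
    alpha = config$alpha, scale = config$scale, seed = config$seed),
    class = "criteria_report")
  if (!is.null(config$outdir)) write_report_artifacts(report, config$outdir)
  report
}

write_report_artifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_ses_result(report$criterion1$ses, file.path(outdir, "ses_mfd.csv"))
  utils::write.csv(report$criterion2$coefficients,
                   file.path(outdir, "criterion2_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(report$criterion2$contrasts,
                   file.path(outdir, "criterion2_contrasts.csv"),
                   row.names = FALSE)
  json <- report_json(report)
  jsonlite::write_json(json, file.path(outdir, "criteria_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

report_json <- function(report) {
  list(
    verdict = report$verdict, alpha = report$alpha, scale = report$scale,
    seed = report$seed,
    criterion1 = c(report$criterion1$counts,
                   list(binomial_p = report$criterion1$binomial_p,
                        met = report$criterion1$met)),
    criterion2 = list(
      impervious_beta = report$criterion2$coefficients$estimate[
        report$criterion2$coefficients$term == "impervious"],
      impervious_p = report$criterion2$coefficients$p[
        report$criterion2$coefficients$term == "impervious"],
      moran_i = if (!is.null(report$criterion2$moran))
        report$criterion2$moran$observed else NULL,
      moran_p = if (!is.null(report$criterion2$moran))
        report$criterion2$moran$p else NULL,
      met = report$criterion2$met),
    criterion3 = list(
      total_coinertia = report$criterion3$total_coinertia,
      p_model2 = report$criterion3$p_model2,
      p_model4 = report$criterion3$p_model4,
      p_combined = report$criterion3$p_combined,
      met = report$criterion3$met))
}

#' Render a criteria report as readable text
#'
#' @param report a `criteria_report` from [run_all()], possibly with
#'   criteria set to `NULL` (rendered as "not run").
#' @return character vector of lines (also printed invisibly friendly).
#' @export
report_render <- function(report) {
  lines <- c("Three-criterion environmental filtering report",
             sprintf("alpha = %.2f, scale = %s m, seed = %d",
                     report$alpha, report$scale, report$seed), "")
  c1 <- report$criterion1
  if (is.null(c1)) lines <- c(lines, "Criterion I: not run")
  else lines <- c(lines, sprintf(
    "Criterion I (trait clustering): %d/%d sites ses<0, %d significantly clustered, %d overdispersed -> %s",
    c1$counts$n_negative_ses, c1$counts$n_defined,
    c1$counts$n_significant_clustered, c1$counts$n_significant_overdispersed,
    if (c1$met) "MET" else "not met"))
  c2 <- report$criterion2
  if (is.null(c2)) lines <- c(lines, "Criterion II: not run")
  else {
    imp <- c2$coefficients[c2$coefficients$term == "impervious", ]
    lines <- c(lines, sprintf(
      "Criterion II (clustering ~ gradient): beta_imp = %.4g (p = %.3g)%s -> %s",
      imp$estimate, imp$p,
      if (!is.null(c2$moran)) sprintf(", Moran's I = %.3g (p = %.3g)",
                                      c2$moran$observed, c2$moran$p) else "",
      if (c2$met) "MET" else "not met"))
  }
  c3 <- report$criterion3
  if (is.null(c3)) lines <- c(lines, "Criterion III: not run")
  else lines <- c(lines, sprintf(
    "Criterion III (trait-environment association): p_model2 = %.3g, p_model4 = %.3g, combined = %.3g -> %s",
    c3$p_model2, c3$p_model4, c3$p_combined,
    if (c3$met) "MET" else "not met"))
  lines <- c(lines, "", sprintf("Verdict: %s", report$verdict))
  lines
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(report_render(x), sep = "\n")
  invisible(x)
}
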