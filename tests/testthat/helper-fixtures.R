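## Small in-code fixtures shared across test files.

toy_traits <- function() {
  trait_table(
    data.frame(
      body_size = c(2, 4, 3, 5),
      native_status = c("native", "non_native", "native", "native"),
      diet_type = c("aphids", "aphids", "pollen", "spiders"),
      stringsAsFactors = FALSE),
    species_ids = c("A", "B", "C", "D"),
    types = c(body_size = "continuous", native_status = "nominal",
              diet_type = "nominal"))
}

toy_community <- function() {
  ab <- rbind(s1 = c(A = 2, B = 1, C = 1, D = 0),
              s2 = c(A = 0, B = 3, C = 2, D = 1),
              s3 = c(A = 1, B = 0, C = 0, D = 4))
  community_matrix(ab)
}

random_mixed_traits <- function(n_species, n_cont = 2, n_nom = 2) {
  df <- as.data.frame(c(
    stats::setNames(lapply(seq_len(n_cont), function(i) rnorm(n_species)),
                    paste0("c", seq_len(n_cont))),
    stats::setNames(lapply(seq_len(n_nom), function(i)
      sample(letters[1:3], n_species, TRUE)), paste0("f", seq_len(n_nom)))))
  trait_table(df, species_ids = sprintf("sp%02d", seq_len(n_species)))
}

random_community <- function(n_site, n_sp, lambda = 2) {
  repeat {
    ab <- matrix(rpois(n_site * n_sp, lambda), n_site, n_sp)
    if (all(rowSums(ab) > 0) && all(colSums(ab) > 0)) break
  }
  community_matrix(ab, site_ids = sprintf("s%02d", seq_len(n_site)),
                   species_ids = sprintf("sp%02d", seq_len(n_sp)))
}

## a community/site/trait trio suitable for criterion3 at small size
small_study <- function(seed, n_sites = 48, n_species = 16, beta_f = 0) {
  simulate_study(simulation_spec(n_sites = n_sites, n_species = n_species,
                                 beta_f = beta_f, seed = seed))
}
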