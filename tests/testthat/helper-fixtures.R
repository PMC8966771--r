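# Shared fixtures, all generated in code at test time.

# deterministic marker panel + GRM, cached per configuration
fixture_grm <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 40, m = 300, seed = 11) {
    key <- paste(n, m, seed, sep = "_")
    if (is.null(cache[[key]])) {
      geno <- simulate_markers(n, m, seed = seed)
      cache[[key]] <- list(geno = geno, grm = compute_grm(qc_markers(geno)))
    }
    cache[[key]]
  }
})

# genetic values drawn on the covariance implied by a GRM
grm_mvn <- function(grm, seed = 1) {
  set.seed(seed)
  L <- t(chol(grm + diag(1e-8, nrow(grm))))
  as.numeric(L %*% rnorm(nrow(grm)))
}

# cross-validation inputs built from simulated ground truth: genotypic values
# are the noise-free genotype-level curves and the true parameters, so CV
# machinery can be exercised without running the curve fitter
fixture_inputs <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 30, seed = 5, n_flights = 8) {
    key <- paste(n, seed, n_flights, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- sim_config(
      n_genotypes = n, n_markers = 240, years = 2019,
      flight_days = round(seq(14, 75, length.out = n_flights)), seed = seed
    )
    study <- simulate_study(cfg)
    grm <- compute_grm(qc_markers(study$geno))
    flights <- dplyr::distinct(study$pheno, environment_id, day, gdd)
    truth <- study$truth$params
    gf_gv <- purrr::pmap_dfr(flights, function(environment_id, day, gdd) {
      tp <- truth[truth$environment_id == environment_id, ]
      g <- vapply(seq_len(nrow(tp)), function(i) {
        predict_gf_curve(gdd, as.list(tp[i, c("lai_amp", "r_g", "r_s",
                                              "t_g", "t_s")]))
      }, numeric(1))
      tibble::tibble(
        variate = sprintf("gf|%s|%03d", environment_id, day),
        environment_id = environment_id, day = day,
        genotype_id = tp$genotype_id, g = g
      )
    })
    param_gv <- truth |>
      tidyr::pivot_longer(dplyr::all_of(c("lai_amp", "r_g", "r_s", "t_g",
                                          "t_s")),
                          names_to = "param", values_to = "g") |>
      dplyr::transmute(
        variate = paste0(param, "|", environment_id),
        environment_id = environment_id, param = param,
        genotype_id = genotype_id, g = g
      )
    out <- cv_inputs(gf_gv, param_gv, grm, flights)
    cache[[key]] <- out
    out
  }
})

# quick synthetic observation table for the curve fitter: a few genotypes,
# optionally noise-free, with a flight schedule long enough to see senescence
fixture_obs <- function(n_genotypes = 3, nu = 0, jitter = 0, seed = 21,
                        flight_days = round(seq(10, 150, length.out = 24))) {
  cfg <- sim_config(n_genotypes = n_genotypes, n_markers = 60, years = 2019,
                    nu = nu, plot_jitter_sd = jitter,
                    flight_days = flight_days, seed = seed)
  simulate_study(cfg)
}
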