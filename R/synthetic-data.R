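#' Configuration of the synthetic multi-environment trial
#'
#' Defines the statistical structure of a simulated soybean field study: a
#' diversity panel genotyped at biallelic markers, grown for several years
#' under well-watered (C) and drought (D) treatments in replicated blocks,
#' with canopy green fraction recorded by repeated UAV flights. Genetic
#' signal enters through the five dynamics-curve parameters, which carry
#' marker-determined additive values with covariance `K_true` across
#' parameters, environment-specific means (drought shrinks `lai_amp`, `r_g`
#' and `t_g`), per-environment non-genetic deviations sized to hit the target
#' heritabilities, plot-level lognormal jitter, and mean-proportional
#' observation noise on the green fraction.
#'
#' @param n_genotypes,n_markers Panel and marker panel sizes.
#' @param n_families Founder families behind the panel (see
#'   [simulate_markers()]); family relatedness is what gives the genomic
#'   relationship matrix usable structure, as in a real diversity panel.
#'   `NULL` gives an unstructured panel.
#' @param family_resample Fraction of markers redrawn per individual within
#'   a family.
#' @param years,treatments Year labels and treatment codes; environments are
#'   their crossing (default 3 years x C/D = 6).
#' @param n_blocks Replicate blocks per environment.
#' @param flight_days Days after sowing of the UAV flights (default 16
#'   flights evenly spaced over days 14-75, i.e. starting after thinning).
#' @param season_days Length of the daily temperature record from sowing.
#' @param base_means Named list of parameter means under treatment C.
#' @param drought_mult Multipliers applied to the means under treatment D.
#' @param year_mult Per-year multipliers on `lai_amp` (heat-stressed years
#'   grow less).
#' @param h2 Named per-parameter heritabilities of the genotypic parameter
#'   values within an environment.
#' @param cv Named per-parameter coefficients of variation of the genotypic
#'   values around the environment mean.
#' @param K_true 5 x 5 genetic correlation matrix among the parameters
#'   (unit diagonal, positive definite).
#' @param nu Observation-noise coefficient: the GF residual s.d. on a date is
#'   `nu` times the mean GF of that date in the environment.
#' @param plot_jitter_sd Log-scale s.d. of the multiplicative plot-level
#'   jitter on the curve parameters (distinguishes genotypic from residual
#'   variance in the plot-level mixed model).
#' @param marker_missing_rate Fraction of marker calls set missing (for QC
#'   exercises).
#' @param seed Integer seed controlling the whole simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 200,
                       n_markers = 2000,
                       n_families = 25,
                       family_resample = 0.3,
                       years = c(2017, 2018, 2019),
                       treatments = c("C", "D"),
                       n_blocks = 2,
                       flight_days = round(seq(14, 75, length.out = 16)),
                       season_days = 160,
                       base_means = list(lai_amp = 3.2, r_g = 0.02,
                                         r_s = 0.004, t_g = 700, t_s = 2000),
                       drought_mult = c(lai_amp = 0.65, r_g = 0.8, r_s = 1,
                                        t_g = 0.85, t_s = 1),
                       year_mult = NULL,
                       h2 = c(lai_amp = 0.8, r_g = 0.6, r_s = 0.4,
                              t_g = 0.7, t_s = 0.4),
                       cv = c(lai_amp = 0.15, r_g = 0.15, r_s = 0.15,
                              t_g = 0.10, t_s = 0.08),
                       K_true = default_K_true(),
                       nu = 0.05,
                       plot_jitter_sd = 0.05,
                       marker_missing_rate = 0,
                       seed = 1) {
  if (is.null(year_mult)) {
    year_mult <- stats::setNames(
      c(1.05, 0.9, 1)[seq_along(years)], as.character(years)
    )
  }
  stopifnot(
    all(h2 >= 0 & h2 <= 1), nu >= 0,
    all(dim(K_true) == c(5, 5)), all(abs(diag(K_true) - 1) < 1e-10),
    min(eigen(K_true, symmetric = TRUE, only.values = TRUE)$values) > 0
  )
  structure(
    list(n_genotypes = n_genotypes, n_markers = n_markers,
         n_families = n_families, family_resample = family_resample,
         years = years,
         treatments = treatments, n_blocks = n_blocks,
         flight_days = flight_days, season_days = season_days,
         base_means = base_means, drought_mult = drought_mult,
         year_mult = year_mult, h2 = h2, cv = cv, K_true = K_true, nu = nu,
         plot_jitter_sd = plot_jitter_sd,
         marker_missing_rate = marker_missing_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default genetic correlation among the curve parameters
#'
#' Moderate positive correlations among the growth-phase parameters
#' (`lai_amp`, `r_g`, `t_g`) and weak links to the senescence pair, a
#' structure under which multi-trait models have signal to exploit.
#' @return 5 x 5 correlation matrix in parameter order
#'   `lai_amp, r_g, r_s, t_g, t_s`.
#' @export
default_K_true <- function() {
  K <- diag(5)
  rownames(K) <- colnames(K) <- dyn_param_names
  K["lai_amp", "r_g"] <- K["r_g", "lai_amp"] <- 0.5
  K["lai_amp", "t_g"] <- K["t_g", "lai_amp"] <- 0.4
  K["r_g", "t_g"] <- K["t_g", "r_g"] <- 0.3
  K["r_s", "t_s"] <- K["t_s", "r_s"] <- 0.3
  K["lai_amp", "t_s"] <- K["t_s", "lai_amp"] <- 0.2
  K
}

#' Simulate a biallelic marker panel
#'
#' Alternative-allele frequencies are drawn from a U-shaped Beta(0.5, 0.5)
#' (typical of diversity panels) and genotype codes sampled under
#' Hardy-Weinberg proportions as -1/0/1. With `n_families` set, the panel
#' gets family structure: founder genotypes are drawn first and each
#' individual inherits its family founder with a fraction
#' `family_resample` of markers redrawn from the population frequencies —
#' giving the blocky relatedness of a real diversity panel, without which a
#' genomic relationship matrix is close to the identity and genetic
#' covariances are poorly identified.
#'
#' @param n_genotypes,n_markers Panel dimensions.
#' @param missing_rate Fraction of calls set to `NA`.
#' @param n_families Number of founder families (`NULL` = unstructured,
#'   every genotype independent).
#' @param family_resample Fraction of markers redrawn per individual when
#'   `n_families` is set.
#' @param seed Optional seed (`NULL` continues the current RNG stream).
#' @return Coded marker matrix with genotype/marker dimnames; the drawn
#'   allele frequencies are attached as attribute `freq`.
#' @export
simulate_markers <- function(n_genotypes, n_markers, missing_rate = 0,
                             n_families = NULL, family_resample = 0.3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::rbeta(n_markers, 0.5, 0.5)
  draw_rows <- function(n) {
    u <- matrix(stats::runif(n * n_markers), n, n_markers)
    cum1 <- matrix((1 - p)^2, n, n_markers, byrow = TRUE)
    cum2 <- matrix((1 - p)^2 + 2 * p * (1 - p), n, n_markers, byrow = TRUE)
    codes <- matrix(0, n, n_markers)
    codes[u < cum1] <- -1
    codes[u >= cum2] <- 1
    codes
  }
  if (is.null(n_families)) {
    codes <- draw_rows(n_genotypes)
  } else {
    founders <- draw_rows(n_families)
    fam <- rep(seq_len(n_families), length.out = n_genotypes)
    codes <- founders[fam, , drop = FALSE]
    fresh <- draw_rows(n_genotypes)
    swap <- matrix(stats::runif(n_genotypes * n_markers) < family_resample,
                   n_genotypes, n_markers)
    codes[swap] <- fresh[swap]
  }
  if (missing_rate > 0) {
    codes[matrix(stats::runif(length(codes)) < missing_rate,
                 nrow(codes))] <- NA
  }
  dimnames(codes) <- list(sprintf("g%03d", seq_len(n_genotypes)),
                          sprintf("m%05d", seq_len(n_markers)))
  attr(codes, "freq") <- p
  codes
}

env_id <- function(year, treatment) paste(year, treatment, sep = "-")

env_param_means <- function(config) {
  purrr::map_dfr(config$years, function(yr) {
    purrr::map_dfr(config$treatments, function(tr) {
      mult <- if (tr == "D") config$drought_mult else
        stats::setNames(rep(1, 5), dyn_param_names)
      m <- unlist(config$base_means)[dyn_param_names] * mult[dyn_param_names]
      m["lai_amp"] <- m["lai_amp"] * config$year_mult[[as.character(yr)]]
      tibble::tibble(environment_id = env_id(yr, tr), year = yr,
                     treatment = tr, param = dyn_param_names,
                     mean = unname(m))
    })
  })
}

#' Simulate true genotypic curve parameters
#'
#' Additive genetic values are built from scaled marker codes with marker
#' effects drawn so the five parameters have genetic correlation `K_true`;
#' each genetic column is standardised so heritabilities are hit exactly in
#' the variance decomposition. Within each environment the genotypic value of
#' parameter p is `mean_ep * (1 + cv_p * (sqrt(h2_p) z_genetic +
#' sqrt(1 - h2_p) z_env))`, where the genetic standard normal `z` is shared
#' across environments (curve shape is a genotype property) and the
#' non-genetic deviation is drawn per genotype x environment.
#'
#' @param markers Coded marker matrix (from [simulate_markers()]).
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List: `params` (tibble genotype x environment x the five true
#'   parameters), `z_genetic` (genotype x parameter matrix of standardised
#'   genetic values), `env_means`.
#' @export
simulate_genetic_values <- function(markers, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- markers
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  sds <- apply(X, 2, stats::sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  m <- ncol(X)
  B <- matrix(stats::rnorm(m * 5), m, 5) %*% chol(config$K_true)
  z <- X %*% B / sqrt(m)
  z <- scale(z)                      # exact unit variance per column
  colnames(z) <- dyn_param_names

  means <- env_param_means(config)
  n <- nrow(z)
  params <- purrr::map_dfr(unique(means$environment_id), function(e) {
    me <- means[means$environment_id == e, ]
    vals <- purrr::map(dyn_param_names, function(p) {
      mp <- me$mean[me$param == p]
      h2p <- config$h2[[p]]; cvp <- config$cv[[p]]
      dev <- sqrt(h2p) * z[, p] +
        sqrt(1 - h2p) * stats::rnorm(n)
      unname(mp * (1 + cvp * dev))
    })
    names(vals) <- dyn_param_names
    tibble::tibble(
      genotype_id = rownames(markers), environment_id = e,
      year = me$year[1], treatment = me$treatment[1], !!!vals
    )
  })
  # keep parameter geometry valid even for extreme draws
  params <- params |>
    dplyr::mutate(
      lai_amp = pmax(.data$lai_amp, 0.05),
      r_g = pmax(.data$r_g, 1e-4), r_s = pmax(.data$r_s, 1e-5),
      t_g = pmax(.data$t_g, 50),
      t_s = pmax(.data$t_s, .data$t_g + 200)
    )
  list(params = params, z_genetic = z, env_means = means)
}

#' Simulate daily temperature records
#'
#' One seasonal temperature curve per year (shared by both treatments of the
#' year): a mid-summer sowing with daily means around 22-29 degrees C plus
#' day-to-day noise, accumulating roughly 17-19 degree-days per day so the
#' full record spans the plausible `t_g`/`t_s` ranges.
#'
#' @param config A [sim_config()].
#' @param sowing_dates Named vector of sowing dates per year (default July 1).
#' @param seed Optional seed.
#' @return Tibble `environment_id`, `date`, `tmean_c`.
#' @export
simulate_temperatures <- function(config, sowing_dates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sowing_dates)) {
    sowing_dates <- stats::setNames(
      as.Date(paste0(config$years, "-07-01")), as.character(config$years)
    )
  }
  purrr::map_dfr(config$years, function(yr) {
    day <- seq_len(config$season_days) - 1
    tmean <- 23 + 6 * sin(pi * (day + 25) / 210) +
      stats::rnorm(length(day), 0, 1.2)
    purrr::map_dfr(config$treatments, function(tr) {
      tibble::tibble(
        environment_id = env_id(yr, tr),
        date = sowing_dates[[as.character(yr)]] + day,
        tmean_c = round(tmean, 2)
      )
    })
  })
}

#' Simulate the plot-level green fraction trial
#'
#' Lays out `n_blocks` plots per genotype x environment, jitters the true
#' genotypic parameters per plot (multiplicative lognormal), evaluates the GF
#' curve at each flight's growing degree days and adds mean-proportional
#' Gaussian observation noise (s.d. `nu` x mean GF of the date), clipped to
#' `[0, 0.999]`.
#'
#' @param truth Output of [simulate_genetic_values()].
#' @param temps Output of [simulate_temperatures()].
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return Tibble with one row per observation: `plot_id`, `genotype_id`,
#'   `environment_id`, `year`, `treatment`, `block`, `date`, `day`, `gdd`,
#'   `gf` and the noise-free `gf_true`.
#' @export
simulate_trial <- function(truth, temps, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- thermal_time(temps)
  flights <- tt |>
    dplyr::filter(.data$day %in% config$flight_days) |>
    dplyr::select("environment_id", "date", "day", "gdd")

  plots <- truth$params |>
    tidyr::expand_grid(block = seq_len(config$n_blocks)) |>
    dplyr::mutate(plot_id = sprintf("%s_b%d_%s", .data$environment_id,
                                    .data$block, .data$genotype_id))
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, config$plot_jitter_sd))
  plots <- plots |>
    dplyr::mutate(dplyr::across(dplyr::all_of(dyn_param_names), jit))

  obs <- plots |>
    dplyr::inner_join(flights, by = "environment_id",
                      relationship = "many-to-many")
  obs$gf_true <- lai_to_gf(pmax(
    obs$lai_amp * (stable_logistic(obs$r_g * (obs$gdd - obs$t_g)) -
                     exp(pmin(obs$r_s * (obs$gdd - obs$t_s), 700))), 0
  ))
  obs <- obs |>
    dplyr::group_by(.data$environment_id, .data$day) |>
    dplyr::mutate(gf = pmin(pmax(
      .data$gf_true +
        stats::rnorm(dplyr::n(), 0, config$nu * mean(.data$gf_true)),
      0), 0.999)) |>
    dplyr::ungroup()
  obs |>
    dplyr::select("plot_id", "genotype_id", "environment_id", "year",
                  "treatment", "block", "date", "day", "gdd", "gf",
                  "gf_true") |>
    dplyr::arrange(.data$environment_id, .data$plot_id, .data$day)
}

#' Simulate a complete study
#'
#' Runs the marker, genetic-value, temperature and trial generators under one
#' seed, producing every input the analysis pipeline consumes plus the ground
#' truth for accuracy oracles. Regenerating with the same config reproduces
#' the data exactly.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: `geno` (marker matrix), `pheno`
#'   (observation tibble), `temps` (daily temperatures), `truth` (true
#'   genotypic parameters, genetic scores, environment means), `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  geno <- simulate_markers(config$n_genotypes, config$n_markers,
                           missing_rate = config$marker_missing_rate,
                           n_families = config$n_families,
                           family_resample = config$family_resample)
  truth <- simulate_genetic_values(geno, config)
  temps <- simulate_temperatures(config)
  pheno <- simulate_trial(truth, temps, config)
  structure(list(geno = geno, pheno = pheno, temps = temps, truth = truth,
                 config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic green-fraction study\n")
  cat(sprintf("  %d genotypes, %d markers, %d environments, %d flights/env\n",
              x$config$n_genotypes, x$config$n_markers,
              length(unique(x$pheno$environment_id)),
              length(x$config$flight_days)))
  cat(sprintf("  %d plot-level observations\n", nrow(x$pheno)))
  invisible(x)
}
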