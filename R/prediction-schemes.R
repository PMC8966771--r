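#' Genomic prediction of one green fraction variate (GP)
#'
#' The baseline model: a single-trait G-BLUP of the per-date green fraction
#' genotypic values, predicting the left-out genotypes from their genomic
#' relationship to the training set.
#'
#' @param g Tibble `genotype_id`, `g` for one variate (one date x
#'   environment).
#' @param grm Genomic relationship matrix.
#' @param train_ids,test_ids Training and left-out genotypes.
#' @param eig Optional precomputed training-set eigendecomposition (see
#'   [gblup()]).
#' @return Tibble `genotype_id`, `pred` (`mu + u`) for the test genotypes,
#'   with the fitted `gblup_fit` attached as attribute `fit`.
#' @export
predict_gp <- function(g, grm, train_ids, test_ids, eig = NULL) {
  fit <- gblup(g, grm, train_ids, test_ids, eig = eig)
  pr <- fit$predictions[fit$predictions$set == "test", ]
  out <- tibble::tibble(genotype_id = pr$genotype_id, pred = fit$mu + pr$u)
  attr(out, "fit") <- fit
  out
}

# gblup each dynamics parameter for one environment; returns list with the
# predicted parameter matrix (test genotypes x 5) and per-parameter fits
gblup_params <- function(param_gv, grm, train_ids, test_ids, eig = NULL) {
  fits <- purrr::map(dyn_param_names, function(p) {
    g <- param_gv[param_gv$param == p, c("genotype_id", "g")]
    gblup(g, grm, train_ids, test_ids, eig = eig)
  })
  names(fits) <- dyn_param_names
  pred <- vapply(fits, function(f) {
    pr <- f$predictions[f$predictions$set == "test", ]
    f$mu + pr$u[match(test_ids, pr$genotype_id)]
  }, numeric(length(test_ids)))
  pred <- matrix(pred, nrow = length(test_ids),
                 dimnames = list(test_ids, dyn_param_names))
  pred_var <- vapply(fits, function(f) {
    pr <- f$predictions[f$predictions$set == "test", ]
    pr$pred_var[match(test_ids, pr$genotype_id)]
  }, numeric(length(test_ids)))
  pred_var <- matrix(pred_var, nrow = length(test_ids),
                     dimnames = list(test_ids, dyn_param_names))
  list(pred = pred, pred_var = pred_var, fits = fits)
}

# evaluate GF trajectories for a matrix of parameter sets (rows) at gdd
trajectories_from_params <- function(par_mat, gdd, k = 0.5) {
  n <- nrow(par_mat); nd <- length(gdd)
  Tg <- matrix(gdd, n, nd, byrow = TRUE)
  growth <- stable_logistic(par_mat[, "r_g"] * (Tg - par_mat[, "t_g"]))
  sen <- exp(pmin(par_mat[, "r_s"] * (Tg - par_mat[, "t_s"]), 700))
  lai <- par_mat[, "lai_amp"] * (growth - sen)
  1 - exp(-k * pmax(lai, 0))
}

traj_tibble <- function(gf_mat, test_ids, days, model) {
  tibble::tibble(
    genotype_id = rep(test_ids, each = length(days)),
    day = rep(days, times = length(test_ids)),
    gf_pred = as.vector(t(gf_mat)),
    model = model
  )
}

#' Two-step genomic prediction of the growth trajectory (TGP)
#'
#' Predicts the five dynamics-curve parameters of the left-out genotypes by
#' single-trait G-BLUP, then reconstructs their green fraction trajectory by
#' running the predicted parameters through the dynamics curve at the target
#' environment's flight degree-days.
#'
#' @param param_gv Parameter genotypic values for the target environment:
#'   tibble with columns `param`, `genotype_id`, `g` covering all five
#'   parameters.
#' @inheritParams predict_gp
#' @param gdd Degree-days of the target flights.
#' @param days Day labels matching `gdd` (defaults to `gdd`).
#' @param k Extinction coefficient.
#' @return Trajectory tibble `genotype_id`, `day`, `gf_pred`, `model`, with
#'   attributes `params` (predicted parameter matrix), `param_var`
#'   (conditional prediction variances, the draw source for TGPG) and
#'   `invalid` (genotypes whose predicted `t_s <= t_g`, still evaluated with
#'   clamping).
#' @export
predict_tgp <- function(param_gv, grm, train_ids, test_ids, gdd,
                        days = gdd, k = 0.5, eig = NULL) {
  gp <- gblup_params(param_gv, grm, train_ids, test_ids, eig = eig)
  invalid <- rownames(gp$pred)[gp$pred[, "t_s"] <= gp$pred[, "t_g"]]
  if (length(invalid)) {
    warning("predicted t_s <= t_g for ", length(invalid),
            " genotype(s); trajectories clamped")
  }
  gf <- trajectories_from_params(gp$pred, gdd, k)
  out <- traj_tibble(gf, test_ids, days, "TGP")
  attr(out, "params") <- gp$pred
  attr(out, "param_var") <- gp$pred_var
  attr(out, "fits") <- gp$fits
  attr(out, "invalid") <- invalid
  out
}

#' Multi-trait genomic prediction of one variate (MGP)
#'
#' Builds an eleven-variate panel (the target plus ten supporting variates
#' chosen by the `s(h2) + s(|r|)` criterion), blanks the target for the test
#' genotypes, and fits the multi-trait Gibbs sampler; the posterior mean of
#' the blanked entries is the prediction.
#'
#' @param panel Genotype x variate matrix containing the target column and
#'   the chosen supporting columns; entries the test genotypes may not
#'   contribute (at minimum their target values) must already be `NA`.
#' @param target Target variate (column name of `panel`).
#' @inheritParams predict_gp
#' @param chain A [chain_config()].
#' @return Tibble `genotype_id`, `pred` for the test genotypes; the
#'   `multitrait_fit` is attached as attribute `fit`.
#' @export
predict_mgp <- function(panel, target, grm, test_ids, chain = chain_config()) {
  stopifnot(target %in% colnames(panel))
  if (!all(is.na(panel[test_ids, target]))) {
    stop("test genotypes must have NA target values in the panel",
         call. = FALSE)
  }
  fit <- fit_multitrait(panel, grm, chain)
  out <- predict_from_fit(fit, target, ids = test_ids)
  attr(out, "fit") <- fit
  out
}

#' Two-step multi-trait genomic prediction (TMGP)
#'
#' Jointly predicts the five dynamics parameters of the target environment
#' with the multi-trait sampler (optionally augmented with supporting
#' variates), then reconstructs trajectories from the posterior-mean
#' parameters.
#'
#' @param panel Genotype x variate matrix whose first five columns (by name)
#'   are the target environment's parameters, `NA` for test genotypes;
#'   further columns are optional supporting variates.
#' @inheritParams predict_tgp
#' @param chain A [chain_config()].
#' @return Trajectory tibble as in [predict_tgp()], with attributes `params`
#'   (posterior-mean parameters), `fit`, and `draws` (retained MCMC parameter
#'   draws, draws x genotype x parameter — the draw source for TMGPG).
#' @export
predict_tmgp <- function(panel, grm, test_ids, gdd, days = gdd, k = 0.5,
                         chain = chain_config()) {
  stopifnot(all(dyn_param_names %in% colnames(panel)))
  if (!all(is.na(panel[test_ids, dyn_param_names]))) {
    stop("test genotypes must have NA parameter values in the panel",
         call. = FALSE)
  }
  fit <- fit_multitrait(panel, grm, chain)
  preds <- purrr::map(dyn_param_names, function(p) {
    predict_from_fit(fit, p, ids = test_ids, draws = TRUE)
  })
  names(preds) <- dyn_param_names
  par_mat <- vapply(preds, function(x) x$pred, numeric(length(test_ids)))
  par_mat <- matrix(par_mat, nrow = length(test_ids),
                    dimnames = list(test_ids, dyn_param_names))
  invalid <- rownames(par_mat)[par_mat[, "t_s"] <= par_mat[, "t_g"]]
  if (length(invalid)) {
    warning("predicted t_s <= t_g for ", length(invalid),
            " genotype(s); trajectories clamped")
  }
  gf <- trajectories_from_params(par_mat, gdd, k)
  out <- traj_tibble(gf, test_ids, days, "TMGP")
  n_draws <- nrow(attr(preds[[1]], "draws"))
  draws <- array(NA_real_, c(n_draws, length(test_ids), 5),
                 dimnames = list(NULL, test_ids, dyn_param_names))
  for (p in dyn_param_names) draws[, , p] <- attr(preds[[p]], "draws")
  attr(out, "params") <- par_mat
  attr(out, "fit") <- fit
  attr(out, "draws") <- draws
  attr(out, "invalid") <- invalid
  out
}

#' Sample dynamics-parameter draws from single-trait G-BLUP fits
#'
#' For the ABC stage of TGPG, where the upstream model is REML/point-based:
#' draws come from the asymptotic predictive distribution, an independent
#' normal per genotype and parameter with the conditional prediction mean
#' and variance plugged in.
#'
#' @param params Predicted parameter matrix (test genotypes x 5).
#' @param param_var Matching conditional prediction variances.
#' @param n_samples Draws per genotype.
#' @param seed Optional seed.
#' @return Array draws x genotype x parameter.
#' @export
sample_param_draws <- function(params, param_var, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(params)
  draws <- array(NA_real_, c(n_samples, n, 5),
                 dimnames = list(NULL, rownames(params), dyn_param_names))
  for (p in dyn_param_names) {
    draws[, , p] <- matrix(stats::rnorm(n_samples * n), n_samples, n) *
      rep(sqrt(pmax(param_var[, p], 0)), each = n_samples) +
      rep(params[, p], each = n_samples)
  }
  draws
}

#' Refine trajectory draws against early-season observations (ABC)
#'
#' The rejection step of TGPG/TMGPG: each parameter draw implies a green
#' fraction trajectory; for every genotype the draws whose trajectory lies
#' closest (Euclidean distance on the GF scale) to that genotype's observed
#' early-season green fractions are kept, and the prediction for all dates is
#' the mean of the kept trajectories. Draws with invalid parameters
#' (non-positive rates or amplitude) receive infinite distance, preserving
#' the draw count. With no early observations for a genotype no selection is
#' applied (the prediction degrades to the plain posterior mean over all
#' draws).
#'
#' @param draws Array draws x genotype x parameter (from
#'   [sample_param_draws()] or a TMGP fit).
#' @param early_obs Tibble `genotype_id`, `day`, `gf` of early-season
#'   observations; `day` must match entries of `days`.
#' @param gdd,days Degree-days and day labels of all target flights
#'   (prediction is emitted for every date; the distance uses only the early
#'   dates).
#' @param n_keep Number of draws retained per genotype.
#' @param k Extinction coefficient.
#' @param model Label stored in the output.
#' @return Trajectory tibble `genotype_id`, `day`, `gf_pred`, `model`, with
#'   attribute `kept` (list of kept draw indices per genotype).
#' @export
abc_refine <- function(draws, early_obs, gdd, days = gdd, n_keep = 60,
                       k = 0.5, model = "TGPG") {
  stopifnot(length(gdd) == length(days), n_keep <= dim(draws)[1])
  ids <- dimnames(draws)[[2]]
  kept <- vector("list", length(ids))
  names(kept) <- ids
  out <- purrr::map_dfr(ids, function(id) {
    pm <- draws[, id, , drop = TRUE]
    if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1,
                                       dimnames = list(NULL, dyn_param_names))
    valid <- pm[, "lai_amp"] > 0 & pm[, "r_g"] > 0 & pm[, "r_s"] > 0
    gf <- trajectories_from_params(pm, gdd, k)   # draws x dates
    eo <- early_obs[early_obs$genotype_id == id, ]
    if (nrow(eo) == 0) {
      keep_idx <- seq_len(nrow(pm))
    } else {
      di <- match(eo$day, days)
      if (anyNA(di)) stop("early observation days not among target days",
                          call. = FALSE)
      dist <- sqrt(rowSums(
        (gf[, di, drop = FALSE] -
           matrix(eo$gf, nrow(gf), length(di), byrow = TRUE))^2
      ))
      dist[!valid] <- Inf
      if (all(!is.finite(dist))) {
        warning("all draw distances non-finite for ", id,
                ": falling back to the posterior mean")
        keep_idx <- seq_len(nrow(pm))
      } else {
        keep_idx <- order(dist)[seq_len(n_keep)]
      }
    }
    kept[[id]] <<- keep_idx
    tibble::tibble(
      genotype_id = id, day = days,
      gf_pred = colMeans(gf[keep_idx, , drop = FALSE]),
      model = model
    )
  })
  attr(out, "kept") <- kept
  out
}

#' TGP with early-season ABC refinement (TGPG)
#'
#' Runs [predict_tgp()], samples parameter draws from the asymptotic
#' predictive distribution of the G-BLUP fits, and refines them with
#' [abc_refine()] against the test genotypes' early-season observations.
#'
#' @inheritParams predict_tgp
#' @inheritParams abc_refine
#' @param n_samples Parameter draws per genotype.
#' @param seed Seed for the draw sampling.
#' @return Trajectory tibble labelled `"TGPG"`.
#' @export
predict_tgpg <- function(param_gv, grm, train_ids, test_ids, gdd, days = gdd,
                         early_obs, n_samples = 60000, n_keep = 60, k = 0.5,
                         seed = 1, eig = NULL) {
  tgp <- predict_tgp(param_gv, grm, train_ids, test_ids, gdd, days, k, eig)
  draws <- sample_param_draws(attr(tgp, "params"), attr(tgp, "param_var"),
                              n_samples, seed = seed)
  abc_refine(draws, early_obs, gdd, days, n_keep, k, model = "TGPG")
}

#' TMGP with early-season ABC refinement (TMGPG)
#'
#' Runs [predict_tmgp()] and refines its retained MCMC parameter draws with
#' [abc_refine()]; the draw ensemble is the posterior of the multi-trait
#' sampler itself.
#'
#' @inheritParams predict_tmgp
#' @inheritParams abc_refine
#' @return Trajectory tibble labelled `"TMGPG"`.
#' @export
predict_tmgpg <- function(panel, grm, test_ids, gdd, days = gdd, early_obs,
                          n_keep = 60, k = 0.5, chain = chain_config()) {
  tmgp <- predict_tmgp(panel, grm, test_ids, gdd, days, k, chain)
  abc_refine(attr(tmgp, "draws"), early_obs, gdd, days, n_keep, k,
             model = "TMGPG")
}
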