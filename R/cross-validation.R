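#' Bundle the inputs of a cross-validation experiment
#'
#' @param gf_gv Per-date green fraction genotypic values
#'   ([gf_genotypic_values()]): columns `variate`, `environment_id`, `day`,
#'   `genotype_id`, `g`.
#' @param param_gv Curve-parameter genotypic values
#'   ([param_genotypic_values()]): columns `variate`, `environment_id`,
#'   `param`, `genotype_id`, `g`.
#' @param grm Genomic relationship matrix covering all genotypes.
#' @param flights Tibble `environment_id`, `day`, `gdd` of the flight
#'   schedule per environment.
#' @param k Extinction coefficient used for trajectory reconstruction.
#' @return List of class `cv_inputs`, with the combined long genotypic-value
#'   table, the genotype x variate panel matrix and variate metadata
#'   precomputed.
#' @export
cv_inputs <- function(gf_gv, param_gv, grm, flights, k = 0.5) {
  stopifnot(all(c("variate", "environment_id", "day", "genotype_id", "g")
                %in% names(gf_gv)),
            all(c("variate", "environment_id", "param", "genotype_id", "g")
                %in% names(param_gv)),
            all(c("environment_id", "day", "gdd") %in% names(flights)))
  long <- dplyr::bind_rows(
    dplyr::transmute(gf_gv, variate = .data$variate,
                     genotype_id = as.character(.data$genotype_id),
                     g = .data$g),
    dplyr::transmute(param_gv, variate = .data$variate,
                     genotype_id = as.character(.data$genotype_id),
                     g = .data$g)
  )
  meta <- dplyr::bind_rows(
    dplyr::distinct(gf_gv, .data$variate, .data$environment_id, .data$day) |>
      dplyr::mutate(type = "gf", param = NA_character_),
    dplyr::distinct(param_gv, .data$variate, .data$environment_id,
                    .data$param) |>
      dplyr::mutate(type = "param", day = NA_integer_)
  )
  ids <- sort(unique(long$genotype_id))
  if (!all(ids %in% rownames(grm))) {
    stop("genotypes missing from the GRM", call. = FALSE)
  }
  structure(
    list(long = long, panel = panel_matrix(long)[ids, , drop = FALSE],
         meta = meta, grm = grm, flights = flights, k = k,
         genotype_ids = ids),
    class = "cv_inputs"
  )
}

#' Cross-validation plan
#'
#' @param n_folds Genotype folds (10 in the standard design).
#' @param repeats Number of repeated runs; repeat r uses seed `seed + r - 1`
#'   for the fold split.
#' @param seed Base seed.
#' @param chain [chain_config()] for the multi-trait models; the chain seed
#'   is offset deterministically per repeat/fold/date.
#' @param n_supports Supporting variates for MGP (10 gives the standard
#'   eleven-variate model; under the late-growth scheme 7 are criterion-
#'   selected and 3 are the latest early flights of the test environment).
#' @param tmgp_supports Supporting variates added to the five-parameter panel
#'   of TMGP (6 keeps the eleven-variate budget).
#' @param n_samples Parameter draws per genotype for the ABC stage of TGPG.
#' @param n_keep Draws kept by the ABC rejection step.
#' @param environments Optional subset of environments to evaluate (default
#'   all).
#' @param folds Optional subset of fold indices to evaluate (default all);
#'   the fold split itself always partitions every genotype.
#' @return List of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10, repeats = 3, seed = 1,
                    chain = chain_config(), n_supports = 10,
                    tmgp_supports = 6, n_samples = 60000, n_keep = 60,
                    environments = NULL, folds = NULL) {
  stopifnot(n_folds >= 2, repeats >= 1, n_keep <= n_samples)
  structure(list(n_folds = n_folds, repeats = repeats, seed = as.integer(seed),
                 chain = chain, n_supports = n_supports,
                 tmgp_supports = tmgp_supports, n_samples = n_samples,
                 n_keep = n_keep, environments = environments, folds = folds),
            class = "cv_plan")
}

#' Balanced random genotype folds
#'
#' @param genotype_ids Genotype labels.
#' @param n_folds Number of folds; sizes differ by at most one.
#' @param seed Seed controlling the split.
#' @return Tibble `genotype_id`, `fold`.
#' @export
make_folds <- function(genotype_ids, n_folds, seed = 1) {
  if (n_folds < 2) stop("`n_folds` must be at least 2", call. = FALSE)
  if (n_folds > length(genotype_ids)) {
    stop("more folds than genotypes", call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(genotype_ids)
  fold <- rep(seq_len(n_folds), length.out = length(genotype_ids))
  tibble::tibble(genotype_id = shuffled, fold = fold) |>
    dplyr::arrange(.data$genotype_id)
}

# per-fold variate statistics over the training genotypes: genomic h2 of
# every variate (shared eigendecomposition) and the correlation matrix
fold_variate_stats <- function(inputs, train_ids, eig) {
  P <- inputs$panel[train_ids, , drop = FALSE]
  h2 <- vapply(colnames(P), function(v) {
    # a variate that is constant in training (e.g. a curve parameter the
    # flight window never identifies) has no defined heritability
    if (stats::sd(P[, v]) == 0) return(NA_real_)
    g <- tibble::tibble(genotype_id = train_ids, g = P[, v])
    gblup(g, inputs$grm, train_ids, eig = eig)$h2
  }, numeric(1))
  list(h2 = h2, cormat = suppressWarnings(stats::cor(P)))
}

# candidate table for the supporting-variate criterion
support_candidates <- function(inputs, stats, target, exclude_envs = NULL) {
  meta <- inputs$meta
  cand <- meta$variate[meta$variate != target]
  if (!is.null(exclude_envs)) {
    cand <- setdiff(cand, meta$variate[meta$environment_id %in% exclude_envs])
  }
  tibble::tibble(variate = cand, h2 = stats$h2[cand],
                 r = stats$cormat[cand, target])
}

# supports for TMGP: criterion against the five target-environment
# parameters jointly (r = strongest correlation with any of them)
tmgp_support_candidates <- function(inputs, stats, targets,
                                    exclude_envs = NULL) {
  meta <- inputs$meta
  cand <- setdiff(meta$variate, targets)
  if (!is.null(exclude_envs)) {
    cand <- setdiff(cand, meta$variate[meta$environment_id %in% exclude_envs])
  }
  r <- suppressWarnings(
    apply(abs(stats$cormat[cand, targets, drop = FALSE]), 1, max,
          na.rm = TRUE)
  )
  r[!is.finite(r)] <- NA_real_
  tibble::tibble(variate = cand, h2 = stats$h2[cand], r = r)
}

cell_accuracy <- function(pred, truth) {
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0 || anyNA(pred)) {
    return(NA_real_)
  }
  stats::cor(truth, pred)
}

# one deterministic small-integer chain seed per evaluation cell
cell_seed <- function(base, rep, fold, env_i, day_i = 0L) {
  (base + 7919L * rep + 611L * fold + 101L * env_i + day_i) %% 2147483647L
}

# ---- shared scheme engine ---------------------------------------------------

# CV1, CV2 and CV3 share one cell loop; `scheme` switches the panel blanking
# policy, the supporting-variate pool and (CV3) the early/late handling.
run_cv_scheme <- function(inputs, models, plan, scheme) {
  stopifnot(inherits(inputs, "cv_inputs"), inherits(plan, "cv_plan"))
  known <- c("oracle", "GP", "TGP", "MGP", "TMGP", "TGPG", "TMGPG")
  stopifnot(all(models %in% known))
  if (scheme != "CV3" && any(models %in% c("TGPG", "TMGPG"))) {
    stop("TGPG/TMGPG require early-season observations (CV3)", call. = FALSE)
  }
  ids <- inputs$genotype_ids
  envs <- sort(unique(inputs$flights$environment_id))
  if (scheme %in% c("CV2", "CV3") && length(envs) < 2) {
    stop("leave-one-environment-out needs at least two environments",
         call. = FALSE)
  }
  eval_envs <- if (is.null(plan$environments)) envs else
    intersect(envs, plan$environments)
  eval_folds <- if (is.null(plan$folds)) seq_len(plan$n_folds) else
    intersect(seq_len(plan$n_folds), plan$folds)
  meta <- inputs$meta
  need_stats <- any(models %in% c("MGP", "TMGP", "TMGPG"))
  audit <- list()

  res <- purrr::map_dfr(seq_len(plan$repeats), function(rep_i) {
    folds <- make_folds(ids, plan$n_folds, seed = plan$seed + rep_i - 1)
    purrr::map_dfr(eval_folds, function(fold_i) {
      test_ids <- folds$genotype_id[folds$fold == fold_i]
      train_ids <- setdiff(ids, test_ids)
      eig <- eigen(inputs$grm[train_ids, train_ids], symmetric = TRUE)
      stats <- if (need_stats) fold_variate_stats(inputs, train_ids, eig)

      purrr::imap_dfr(eval_envs, function(env, env_i) {
        fl <- inputs$flights[inputs$flights$environment_id == env, ]
        fl <- fl[order(fl$day), ]
        split <- split_early_late(fl$day)
        eval_days <- if (scheme == "CV3") split$late else fl$day
        eval_gdd <- fl$gdd[match(eval_days, fl$day)]
        exclude_envs <- if (scheme %in% c("CV2", "CV3")) env
        early_obs <- if (scheme == "CV3") {
          early_var <- gf_variate(env, split$early)
          inputs$long |>
            dplyr::filter(.data$variate %in% early_var,
                          .data$genotype_id %in% test_ids) |>
            dplyr::left_join(meta[c("variate", "day")], by = "variate") |>
            dplyr::transmute(genotype_id = .data$genotype_id,
                             day = .data$day, gf = .data$g)
        }

        rows <- list()
        add_traj_rows <- function(traj, model) {
          purrr::map_dfr(eval_days, function(d) {
            tv <- gf_variate(env, d)
            truth <- inputs$panel[test_ids, tv]
            pred <- traj$gf_pred[traj$day == d][
              match(test_ids, traj$genotype_id[traj$day == d])]
            tibble::tibble(scheme = scheme, model = model,
                           environment_id = env, day = d, fold = fold_i,
                           rep = rep_i, accuracy = cell_accuracy(pred, truth),
                           n_test = length(test_ids))
          })
        }

        if ("oracle" %in% models) {
          rows$oracle <- purrr::map_dfr(eval_days, function(d) {
            truth <- inputs$panel[test_ids, gf_variate(env, d)]
            tibble::tibble(scheme = scheme, model = "oracle",
                           environment_id = env, day = d, fold = fold_i,
                           rep = rep_i, accuracy = cell_accuracy(truth, truth),
                           n_test = length(test_ids))
          })
        }

        if ("GP" %in% models) {
          rows$GP <- purrr::map_dfr(eval_days, function(d) {
            tv <- gf_variate(env, d)
            g <- tibble::tibble(genotype_id = train_ids,
                                g = inputs$panel[train_ids, tv])
            pred <- predict_gp(g, inputs$grm, train_ids, test_ids, eig = eig)
            truth <- inputs$panel[test_ids, tv]
            tibble::tibble(scheme = scheme, model = "GP",
                           environment_id = env, day = d, fold = fold_i,
                           rep = rep_i,
                           accuracy = cell_accuracy(
                             pred$pred[match(test_ids, pred$genotype_id)],
                             truth),
                           n_test = length(test_ids))
          })
        }

        pg <- NULL
        if (any(c("TGP", "TGPG") %in% models)) {
          pg <- param_gv_env(inputs, env, train_ids)
        }
        if ("TGP" %in% models) {
          traj <- suppressWarnings(predict_tgp(
            pg, inputs$grm, train_ids, test_ids, eval_gdd, eval_days,
            inputs$k, eig = eig))
          rows$TGP <- add_traj_rows(traj, "TGP")
        }
        if ("TGPG" %in% models) {
          traj <- suppressWarnings(predict_tgpg(
            pg, inputs$grm, train_ids, test_ids,
            gdd = fl$gdd, days = fl$day, early_obs = early_obs,
            n_samples = plan$n_samples, n_keep = plan$n_keep, k = inputs$k,
            seed = cell_seed(plan$seed, rep_i, fold_i, env_i), eig = eig))
          rows$TGPG <- add_traj_rows(traj, "TGPG")
        }

        if ("MGP" %in% models) {
          rows$MGP <- purrr::imap_dfr(eval_days, function(d, day_i) {
            tv <- gf_variate(env, d)
            if (scheme == "CV3") {
              cand <- support_candidates(inputs, stats, tv, exclude_envs)
              sel <- select_supporting_variates(cand, plan$n_supports - 3)
              extra <- gf_variate(env, utils::tail(split$early, 3))
              supports <- c(sel$variate, extra)
            } else {
              cand <- support_candidates(inputs, stats, tv, exclude_envs)
              sel <- select_supporting_variates(cand, plan$n_supports)
              supports <- sel$variate
            }
            panel <- build_panel(inputs, c(tv, supports), test_ids,
                                 scheme, env)
            ch <- plan$chain
            ch$seed <- cell_seed(ch$seed, rep_i, fold_i, env_i, day_i)
            pred <- predict_mgp(panel, tv, inputs$grm, test_ids, chain = ch)
            audit[[length(audit) + 1L]] <<- tibble::tibble(
              scheme = scheme, model = "MGP", environment_id = env, day = d,
              fold = fold_i, rep = rep_i, supports = list(supports)
            )
            truth <- inputs$panel[test_ids, tv]
            tibble::tibble(scheme = scheme, model = "MGP",
                           environment_id = env, day = d, fold = fold_i,
                           rep = rep_i,
                           accuracy = cell_accuracy(
                             pred$pred[match(test_ids, pred$genotype_id)],
                             truth),
                           n_test = length(test_ids))
          })
        }

        if (any(c("TMGP", "TMGPG") %in% models)) {
          targets <- param_variate(dyn_param_names, env)
          supports <- character()
          if (plan$tmgp_supports > 0) {
            cand <- tmgp_support_candidates(inputs, stats, targets,
                                            exclude_envs)
            supports <- select_supporting_variates(
              cand, plan$tmgp_supports)$variate
          }
          panel <- build_panel(inputs, c(targets, supports), test_ids,
                               scheme, env)
          colnames(panel)[seq_len(5)] <- dyn_param_names
          ch <- plan$chain
          ch$seed <- cell_seed(ch$seed, rep_i, fold_i, env_i, 99L)
          tmgp <- suppressWarnings(predict_tmgp(
            panel, inputs$grm, test_ids, eval_gdd, eval_days, inputs$k,
            chain = ch))
          audit[[length(audit) + 1L]] <<- tibble::tibble(
            scheme = scheme, model = "TMGP", environment_id = env,
            day = NA_integer_, fold = fold_i, rep = rep_i,
            supports = list(supports)
          )
          if ("TMGP" %in% models) rows$TMGP <- add_traj_rows(tmgp, "TMGP")
          if ("TMGPG" %in% models) {
            # re-evaluate the retained draws over the full flight schedule
            refined <- abc_refine(attr(tmgp, "draws"), early_obs,
                                  gdd = fl$gdd, days = fl$day,
                                  n_keep = min(plan$n_keep,
                                               dim(attr(tmgp, "draws"))[1]),
                                  k = inputs$k, model = "TMGPG")
            rows$TMGPG <- add_traj_rows(refined, "TMGPG")
          }
        }

        dplyr::bind_rows(rows)
      })
    })
  })
  attr(res, "audit") <- dplyr::bind_rows(audit)
  class(res) <- c("cv_result", class(res))
  res
}

# parameter genotypic values of one environment from the long table
param_gv_env <- function(inputs, env, train_ids) {
  v <- param_variate(dyn_param_names, env)
  inputs$long |>
    dplyr::filter(.data$variate %in% v) |>
    dplyr::mutate(param = sub("\\|.*$", "", .data$variate)) |>
    dplyr::select("param", "genotype_id", "g")
}

# blanking policy: which panel entries may the test genotypes contribute?
#  CV1  - none (their data are excluded from every environment)
#  CV2  - everything outside the held-out environment
#  CV3  - as CV2, plus their early-period green fractions in the held-out
#         environment (handled by the variate list passed in)
build_panel <- function(inputs, variates, test_ids, scheme, held_out_env) {
  P <- inputs$panel[, variates, drop = FALSE]
  meta <- inputs$meta
  if (scheme == "CV1") {
    P[test_ids, ] <- NA_real_
  } else {
    env_of <- meta$environment_id[match(variates, meta$variate)]
    day_of <- meta$day[match(variates, meta$variate)]
    blank <- env_of == held_out_env
    if (scheme == "CV3") {
      fl <- inputs$flights[inputs$flights$environment_id == held_out_env, ]
      early <- split_early_late(sort(fl$day))$early
      blank <- blank & !(ifelse(is.na(day_of), FALSE, day_of %in% early))
    }
    P[test_ids, blank] <- NA_real_
  }
  P
}

#' Split a flight schedule into early and late halves
#'
#' Equal observation counts in the two periods; with an odd number of
#' flights the early period receives the extra date.
#'
#' @param days Sorted observation days of one environment.
#' @return List with integer vectors `early` and `late`.
#' @export
split_early_late <- function(days) {
  days <- sort(days)
  n_early <- ceiling(length(days) / 2)
  list(early = days[seq_len(n_early)],
       late = days[setdiff(seq_along(days), seq_len(n_early))])
}

#' Cross-validation over genotypes (CV1)
#'
#' Ten-fold cross-validation in which the test genotypes' records are
#' excluded from the training data of every environment; each model then
#' predicts each environment x flight date, and accuracy is the correlation
#' with the held-out genotypic values across the test genotypes.
#'
#' @param inputs A [cv_inputs()] bundle.
#' @param models Character subset of `"oracle"`, `"GP"`, `"TGP"`, `"MGP"`,
#'   `"TMGP"`.
#' @param plan A [cv_plan()].
#' @return Tibble of class `cv_result`: `scheme`, `model`, `environment_id`,
#'   `day`, `fold`, `rep`, `accuracy`, `n_test`; the supporting-variate
#'   audit trail is attached as attribute `audit`.
#' @export
run_cv1 <- function(inputs, models = c("GP", "TGP"), plan = cv_plan()) {
  run_cv_scheme(inputs, models, plan, "CV1")
}

#' Cross-validation over genotype x environment combinations (CV2)
#'
#' Genotype folds and leave-one-environment-out applied simultaneously: the
#' test genotypes' records in the held-out environment are excluded, but
#' their records in the other environments remain available to the
#' multi-trait models (whose supporting variates are restricted to those
#' other environments). GP and TGP use only same-environment training data,
#' so their predictions coincide with CV1.
#'
#' @inheritParams run_cv1
#' @export
run_cv2 <- function(inputs, models = c("GP", "TGP"), plan = cv_plan()) {
  run_cv_scheme(inputs, models, plan, "CV2")
}

#' Cross-validation of the late growth period (CV3)
#'
#' As CV2, but the test genotypes' early-period green fractions in the
#' held-out environment are added to the conditioning data, and accuracy is
#' evaluated on the late-period dates only. MGP uses 7 criterion-selected
#' supports plus the latest three early flights of the held-out environment;
#' TGPG and TMGPG refine their parameter draws against the early
#' observations by ABC rejection.
#'
#' @inheritParams run_cv1
#' @param models Character subset of `"oracle"`, `"GP"`, `"TGP"`, `"MGP"`,
#'   `"TMGP"`, `"TGPG"`, `"TMGPG"`.
#' @export
run_cv3 <- function(inputs, models = c("TGP", "TGPG"), plan = cv_plan()) {
  fl_counts <- table(inputs$flights$environment_id)
  if (any(fl_counts < 4)) {
    stop("CV3 needs at least 4 flights per environment", call. = FALSE)
  }
  run_cv_scheme(inputs, models, plan, "CV3")
}

#' Summarise cross-validation accuracies
#'
#' Mean accuracy by scheme, model and environment (and overall per model),
#' averaging per-date correlations as plotted in per-date accuracy curves.
#'
#' @param results A `cv_result` tibble.
#' @return Tibble `scheme`, `model`, `environment_id` (`"all"` for the
#'   pooled row), `mean_accuracy`, `n_cells`.
#' @export
summarize_cv <- function(results) {
  stopifnot(nrow(results) > 0)
  by_env <- results |>
    dplyr::group_by(.data$scheme, .data$model, .data$environment_id) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
                     n_cells = dplyr::n(), .groups = "drop")
  overall <- results |>
    dplyr::group_by(.data$scheme, .data$model) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
                     n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(environment_id = "all")
  dplyr::bind_rows(by_env, overall)
}

#' Relative improvement of one model over another
#'
#' Reported as a ratio of mean correlation coefficients:
#' `(mean_A / mean_B - 1) * 100` percent.
#'
#' @param results A `cv_result` tibble.
#' @param model_a,model_b Model labels to compare.
#' @param by Optional grouping columns (e.g. `"environment_id"`).
#' @return Tibble with the group columns and `improvement_pct`; `NA` with a
#'   warning where the baseline mean is not positive.
#' @export
model_improvement <- function(results, model_a, model_b, by = character()) {
  means <- results |>
    dplyr::filter(.data$model %in% c(model_a, model_b)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "model")))) |>
    dplyr::summarise(m = mean(.data$accuracy, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "model", values_from = "m")
  bad <- means[[model_b]] <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("baseline mean accuracy not positive; improvement undefined")
  }
  means$improvement_pct <- ifelse(
    bad, NA_real_, (means[[model_a]] / means[[model_b]] - 1) * 100
  )
  means
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::as_tibble(object),
    ggplot2::aes(x = .data$day, y = .data$accuracy, colour = .data$model)
  ) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 1) +
    ggplot2::facet_wrap(~environment_id) +
    ggplot2::labs(x = "Days after sowing", y = "Accuracy (Pearson r)",
                  colour = "Model")
}
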