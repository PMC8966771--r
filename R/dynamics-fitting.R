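#' Configuration for the two-step dynamics fit
#'
#' Stage 1 searches `(t_g, t_s)` on an `n_grid` x `n_grid` lattice spanning
#' `tg_range` x `ts_range` (inclusive endpoints, so a 7-point grid on
#' (300, 1200) has 150 degree-day spacing), minimising the weighted
#' least-squares cost over the remaining parameters with Nelder-Mead at each
#' lattice point. Stage 2 repeats the search per plot inside a window of
#' half-width `refine_tg_halfwidth` / `refine_ts_halfwidth` centred on the
#' stage-1 optimum, truncated at the global ranges.
#'
#' @param tg_range,ts_range Degree-day search ranges for the growth inflection
#'   `t_g` and the senescence zero-crossing `t_s`.
#' @param n_grid Grid points per axis (inclusive endpoints).
#' @param refine_tg_halfwidth,refine_ts_halfwidth Half-widths of the stage-2
#'   refinement windows, in degree-days.
#' @param reltol Relative convergence tolerance of the Nelder-Mead simplex
#'   (used to polish the winning lattice point).
#' @param maxit Maximum simplex iterations for the polishing run.
#' @param scan_reltol,scan_maxit Looser simplex settings used while scanning
#'   the lattice; the best cell is then re-optimised at full tolerance, so
#'   the scan only has to rank cells, not resolve them.
#' @param init Initial values for `lai_amp`, `r_g` and `r_s`; positivity is
#'   enforced by optimising on the log scale.
#' @param ybar_min Dates whose environment-mean green fraction falls below
#'   this value are excluded from the cost (the weight 1/mean would blow up).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(tg_range = c(300, 1200),
                       ts_range = c(1400, 3000),
                       n_grid = 7,
                       refine_tg_halfwidth = 200,
                       refine_ts_halfwidth = 400,
                       reltol = 1e-8,
                       maxit = 2000,
                       scan_reltol = 1e-4,
                       scan_maxit = 200,
                       init = list(lai_amp = 2, r_g = 0.01, r_s = 0.004),
                       ybar_min = 1e-4) {
  stopifnot(
    tg_range[1] < tg_range[2], ts_range[1] < ts_range[2],
    n_grid >= 2, refine_tg_halfwidth > 0, refine_ts_halfwidth > 0
  )
  structure(
    list(
      tg_range = tg_range, ts_range = ts_range, n_grid = n_grid,
      refine_tg_halfwidth = refine_tg_halfwidth,
      refine_ts_halfwidth = refine_ts_halfwidth,
      reltol = reltol, maxit = maxit,
      scan_reltol = scan_reltol, scan_maxit = scan_maxit,
      init = init, ybar_min = ybar_min
    ),
    class = "fit_config"
  )
}

#' Weighted fitting cost for green fraction series
#'
#' Sum over observations of squared residuals divided by the mean observed
#' green fraction of the date: `sum((y - yhat)^2 / ybar)`. The normalisation
#' reflects measurement noise roughly proportional to the mean canopy cover on
#' a date. Dates whose mean is below `ybar_min` are excluded.
#'
#' @param observed,predicted Aligned observed and predicted green fractions.
#' @param ybar Mean observed green fraction of the corresponding date over all
#'   plots of the environment (one value per observation).
#' @param ybar_min Exclusion threshold for near-zero date means.
#' @return Non-negative scalar cost.
#' @export
fit_cost <- function(observed, predicted, ybar, ybar_min = 1e-4) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(ybar))
  if (any(ybar < 0)) stop("`ybar` must be non-negative", call. = FALSE)
  keep <- ybar >= ybar_min
  sum((observed[keep] - predicted[keep])^2 / ybar[keep])
}

# internal: weighted cost with precomputed weights (0 for excluded dates);
# compiled kernel, called once per simplex evaluation
gf_curve_cost <- function(gf, gdd, w, plot_index, la, r_g, r_s, t_g, t_s, k) {
  # simplex excursions can overflow exp(), and weakly identified directions
  # (senescence never observed) would otherwise let parameters drift without
  # bound on a flat cost plateau; a generous box with an effectively
  # infinite wall keeps every reported parameter physically plausible
  if (!all(is.finite(c(la, r_g, r_s, t_g, t_s))) ||
      any(la > 12) || r_g > 1 || r_s > 1 ||
      t_g < 0 || t_g > 3000 || t_s < 200 || t_s > 6000) {
    return(1e30)
  }
  val <- .gf_cost_cpp(gf, gdd, w, as.integer(plot_index), la, r_g, r_s,
                      t_g, t_s, k)
  if (!is.finite(val)) 1e30 else val
}

grid_points <- function(range, n) seq(range[1], range[2], length.out = n)

# Nelder-Mead over log(lai_amp per plot), log(r_g), log(r_s) at fixed (t_g, t_s)
optim_cell <- function(theta0, gf, gdd, w, plot_index, n_plots, t_g, t_s, k,
                       reltol, maxit) {
  fn <- function(theta) {
    gf_curve_cost(gf, gdd, w, plot_index,
                  la = exp(theta[seq_len(n_plots)]),
                  r_g = exp(theta[n_plots + 1]), r_s = exp(theta[n_plots + 2]),
                  t_g = t_g, t_s = t_s, k = k)
  }
  res <- stats::optim(theta0, fn, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  list(theta = res$par, cost = res$value, converged = res$convergence == 0L)
}

# grid search over (t_g, t_s) cells with loose simplex settings, then a
# full-tolerance polish of the best few cells (a cheap multi-start: the
# loose scan can mis-rank neighbouring basins). Cells are ordered t_g
# ascending then t_s ascending and compared strictly, so ties break to the
# lowest pair.
search_grid <- function(tg_vals, ts_vals, theta0, gf, gdd, w, plot_index,
                        n_plots, k, config, extra_cells = NULL,
                        n_polish = 2) {
  cells <- expand.grid(t_s = ts_vals, t_g = tg_vals)[, c("t_g", "t_s")]
  cells <- cells[order(cells$t_g, cells$t_s), ]
  if (!is.null(extra_cells)) cells <- rbind(extra_cells, cells)
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    t_g <- cells$t_g[i]; t_s <- cells$t_s[i]
    if (t_s <= t_g) next
    fit <- optim_cell(theta0, gf, gdd, w, plot_index, n_plots, t_g, t_s, k,
                      config$scan_reltol, config$scan_maxit)
    fits[[i]] <- c(fit, list(t_g = t_g, t_s = t_s))
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  costs <- vapply(fits, `[[`, numeric(1), "cost")
  top <- fits[order(costs)[seq_len(min(n_polish, length(fits)))]]

  # full polish: all parameters move, including (t_g, t_s), so the lattice
  # only has to provide the basin, not the optimum; parscale evens out the
  # O(1) log-rate axes against the O(1000) degree-day axes, and the simplex
  # restarts from its own optimum to guard against premature collapse
  fn_full <- function(par) {
    gf_curve_cost(gf, gdd, w, plot_index,
                  la = exp(par[seq_len(n_plots)]),
                  r_g = exp(par[n_plots + 1]), r_s = exp(par[n_plots + 2]),
                  t_g = par[n_plots + 3], t_s = par[n_plots + 4], k = k)
  }
  ctl <- list(reltol = config$reltol, maxit = config$maxit,
              parscale = c(rep(1, n_plots + 2), 100, 100))
  best <- top[[1]]
  for (cand in top) {
    res <- stats::optim(c(cand$theta, cand$t_g, cand$t_s), fn_full,
                        method = "Nelder-Mead", control = ctl)
    for (restart in 1:2) {
      if (res$value == 0) break
      res2 <- stats::optim(res$par, fn_full, method = "Nelder-Mead",
                           control = ctl)
      if (res2$value >= res$value * (1 - 1e-6)) { res <- res2; break }
      res <- res2
    }
    if (res$value < best$cost && res$par[n_plots + 4] > res$par[n_plots + 3]) {
      best <- list(theta = res$par[seq_len(n_plots + 2)],
                   cost = res$value, converged = res$convergence == 0L,
                   t_g = res$par[n_plots + 3], t_s = res$par[n_plots + 4])
    }
  }
  best
}

obs_required <- c("plot_id", "genotype_id", "environment_id", "day", "gdd", "gf")

# per-environment, per-day mean GF and the derived cost weights
cost_weights <- function(obs, ybar_min) {
  obs |>
    dplyr::group_by(.data$environment_id, .data$day) |>
    dplyr::mutate(ybar = mean(.data$gf)) |>
    dplyr::ungroup() |>
    dplyr::mutate(w = ifelse(.data$ybar >= ybar_min, 1 / .data$ybar, 0))
}

#' Stage-1 joint fit of one genotype's plots
#'
#' Fits the dynamics curve jointly to all plots of a genotype under the
#' assumption that `r_g`, `r_s`, `t_g` and `t_s` are genotype properties
#' shared across plots (and hence across watering treatments) while `lai_amp`
#' is plot-specific. `(t_g, t_s)` are found by grid search; at each lattice
#' point Nelder-Mead minimises the [fit_cost()] over the log-parameterised
#' remaining parameters.
#'
#' @param obs Observation-level data frame for one genotype: columns
#'   `plot_id`, `genotype_id`, `environment_id`, `day`, `gdd`, `gf`, plus the
#'   precomputed cost weight `w` (see [fit_dynamics()]; weights are
#'   `1/ybar_day` or 0 for excluded dates).
#' @param config A [fit_config()].
#' @param k Extinction coefficient for the GF conversion.
#' @return A list with elements `shared` (tibble row: `r_g`, `r_s`, `t_g`,
#'   `t_s`, `cost`, `converged`) and `plots` (tibble: `plot_id`, `lai_amp`).
#' @export
fit_genotype_joint <- function(obs, config = fit_config(), k = 0.5) {
  stopifnot(all(c(obs_required, "w") %in% names(obs)))
  plots <- unique(obs$plot_id)
  n_plots <- length(plots)
  plot_index <- match(obs$plot_id, plots)

  degenerate <- sum(obs$w) == 0 || all(obs$gf <= 0)
  if (degenerate) {
    return(list(
      shared = tibble::tibble(
        r_g = config$init$r_g, r_s = config$init$r_s,
        t_g = mean(config$tg_range), t_s = mean(config$ts_range),
        cost = NA_real_, converged = FALSE
      ),
      plots = tibble::tibble(plot_id = plots, lai_amp = config$init$lai_amp)
    ))
  }

  # data-driven lai_amp start: invert the largest observed GF per plot
  la0 <- vapply(plots, function(p) {
    top <- max(obs$gf[obs$plot_id == p])
    max(gf_to_lai(min(top, 0.95), k = k), 0.05)
  }, numeric(1))
  theta0 <- c(log(la0), log(config$init$r_g), log(config$init$r_s))

  best <- search_grid(
    grid_points(config$tg_range, config$n_grid),
    grid_points(config$ts_range, config$n_grid),
    theta0, obs$gf, obs$gdd, obs$w, plot_index, n_plots, k, config
  )
  list(
    shared = tibble::tibble(
      r_g = exp(best$theta[n_plots + 1]), r_s = exp(best$theta[n_plots + 2]),
      t_g = best$t_g, t_s = best$t_s, cost = best$cost,
      converged = best$converged
    ),
    plots = tibble::tibble(plot_id = plots,
                           lai_amp = exp(best$theta[seq_len(n_plots)]))
  )
}

#' Stage-2 per-plot refinement
#'
#' Re-fits a single plot starting from its genotype's stage-1 solution:
#' `(t_g, t_s)` are searched on a lattice inside a narrowed window centred on
#' the stage-1 values (truncated at the global ranges; the exact stage-1 cell
#' is always evaluated, so the refined cost never exceeds the stage-1 cost on
#' the plot beyond simplex tolerance), and the remaining parameters are
#' re-optimised from the stage-1 values.
#'
#' @param obs Observation rows of one plot (same columns as
#'   [fit_genotype_joint()]).
#' @param stage1 A one-row data frame / list with the plot's stage-1
#'   `lai_amp`, `r_g`, `r_s`, `t_g`, `t_s`.
#' @inheritParams fit_genotype_joint
#' @return One-row tibble: `lai_amp`, `r_g`, `r_s`, `t_g`, `t_s`, `cost`,
#'   `stage` (`"plot_refined"` or `"genotype_joint"` when the plot has too few
#'   observations to refine), `converged`.
#' @export
fit_plot_refine <- function(obs, stage1, config = fit_config(), k = 0.5) {
  stopifnot(all(c(obs_required, "w") %in% names(obs)),
            length(unique(obs$plot_id)) == 1L)
  s1 <- as.list(stage1)
  usable <- sum(obs$w > 0)
  if (usable < 5L) {
    return(tibble::tibble(
      lai_amp = s1$lai_amp, r_g = s1$r_g, r_s = s1$r_s,
      t_g = s1$t_g, t_s = s1$t_s,
      cost = gf_curve_cost(obs$gf, obs$gdd, obs$w, rep(1L, nrow(obs)),
                           s1$lai_amp, s1$r_g, s1$r_s, s1$t_g, s1$t_s, k),
      stage = "genotype_joint", converged = FALSE
    ))
  }
  tg_win <- c(max(s1$t_g - config$refine_tg_halfwidth, config$tg_range[1]),
              min(s1$t_g + config$refine_tg_halfwidth, config$tg_range[2]))
  ts_win <- c(max(s1$t_s - config$refine_ts_halfwidth, config$ts_range[1]),
              min(s1$t_s + config$refine_ts_halfwidth, config$ts_range[2]))
  theta0 <- log(c(s1$lai_amp, s1$r_g, s1$r_s))
  best <- search_grid(
    grid_points(tg_win, config$n_grid), grid_points(ts_win, config$n_grid),
    theta0, obs$gf, obs$gdd, obs$w, rep(1L, nrow(obs)), 1L, k, config,
    extra_cells = data.frame(t_g = s1$t_g, t_s = s1$t_s)
  )
  tibble::tibble(
    lai_amp = exp(best$theta[1]), r_g = exp(best$theta[2]),
    r_s = exp(best$theta[3]), t_g = best$t_g, t_s = best$t_s,
    cost = best$cost, stage = "plot_refined", converged = best$converged
  )
}

#' Fit the canopy dynamics model to every plot of a trial
#'
#' Runs the two-step estimation over a plot-level green fraction table:
#' stage 1 fits each genotype's plots jointly within a year (curve shape
#' shared across watering treatments, `lai_amp` per plot), stage 2 refines
#' every plot independently around its stage-1 solution.
#'
#' @param obs Observation-level data frame with columns `plot_id`,
#'   `genotype_id`, `environment_id`, `day` (days after sowing), `gdd`
#'   (degree-days at the observation) and `gf`. An optional `year` column
#'   defines the stage-1 pooling unit; without it all of a genotype's plots
#'   are pooled. Build this table with [read_phenotypes()] + [attach_gdd()],
#'   or from [simulate_study()] output.
#' @param config A [fit_config()].
#' @param k Extinction coefficient.
#' @return A tibble of class `dynamics_fit`, one row per plot: identifiers,
#'   the five fitted parameters, `cost`, `stage` and `converged`.
#' @export
fit_dynamics <- function(obs, config = fit_config(), k = 0.5) {
  stopifnot(all(obs_required %in% names(obs)))
  if (!"year" %in% names(obs)) obs$year <- "all"
  obs <- cost_weights(obs, config$ybar_min)

  groups <- obs |>
    dplyr::group_by(.data$genotype_id, .data$year) |>
    dplyr::group_split()

  fits <- purrr::map_dfr(groups, function(g_obs) {
    s1 <- fit_genotype_joint(g_obs, config, k)
    plot_meta <- g_obs |>
      dplyr::distinct(.data$plot_id, .data$genotype_id,
                      .data$environment_id, .data$year)
    purrr::map_dfr(s1$plots$plot_id, function(p) {
      p_obs <- g_obs[g_obs$plot_id == p, ]
      stage1 <- c(
        list(lai_amp = s1$plots$lai_amp[s1$plots$plot_id == p]),
        as.list(s1$shared[c("r_g", "r_s", "t_g", "t_s")])
      )
      refined <- if (isTRUE(s1$shared$converged)) {
        fit_plot_refine(p_obs, stage1, config, k)
      } else {
        tibble::tibble(
          lai_amp = stage1$lai_amp, r_g = stage1$r_g, r_s = stage1$r_s,
          t_g = stage1$t_g, t_s = stage1$t_s, cost = s1$shared$cost,
          stage = "genotype_joint", converged = FALSE
        )
      }
      dplyr::bind_cols(plot_meta[plot_meta$plot_id == p, ], refined)
    })
  })
  class(fits) <- c("dynamics_fit", class(fits))
  attr(fits, "k") <- k
  fits
}

#' @export
autoplot.dynamics_fit <- function(object, obs = NULL, plots = NULL, ...) {
  fits <- dplyr::as_tibble(object)
  if (!is.null(plots)) fits <- fits[fits$plot_id %in% plots, ]
  gdd_max <- if (is.null(obs)) max(fits$t_s) else max(obs$gdd)
  grid <- seq(0, gdd_max, length.out = 200)
  curves <- purrr::pmap_dfr(
    fits[c("plot_id", "lai_amp", "r_g", "r_s", "t_g", "t_s")],
    function(plot_id, ...) {
      tibble::tibble(plot_id = plot_id, gdd = grid,
                     gf = predict_gf_curve(grid, list(...),
                                           k = attr(object, "k") %||% 0.5))
    }
  )
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$gdd, y = .data$gf)) +
    ggplot2::geom_line(colour = "forestgreen") +
    ggplot2::facet_wrap(~plot_id) +
    ggplot2::labs(x = "Growing degree days", y = "Green fraction")
  if (!is.null(obs)) {
    pts <- obs[obs$plot_id %in% fits$plot_id, ]
    p <- p + ggplot2::geom_point(data = pts, size = 0.8, alpha = 0.6)
  }
  p
}
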