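#' Rank candidate supporting variates
#'
#' Supporting variates for a multi-trait model are chosen by the sum of two
#' z-scores computed over the candidate set: `s(h2) + s(|r|)`, where `h2` is
#' the genomic heritability of the candidate, `r` its correlation with the
#' target variate, and `s(.)` scales a vector to mean zero and unit variance.
#' Ties (and the degenerate case of a zero-variance column, whose z-scores
#' are set to 0) break towards higher `h2`, then lexicographic label.
#'
#' @param candidates Data frame with columns `variate`, `h2` and `r`. The
#'   target itself (and, under the relevant cross-validation scheme, any
#'   variate from a held-out environment) must already be excluded.
#' @param n_select Number of variates to return (10 in the standard
#'   eleven-variate model).
#' @return Tibble of the selected variates in rank order, with a `score`
#'   column; carries attribute `short = TRUE` when fewer candidates than
#'   `n_select` were available.
#' @export
select_supporting_variates <- function(candidates, n_select = 10) {
  stopifnot(all(c("variate", "h2", "r") %in% names(candidates)))
  # candidates whose heritability or target correlation is undefined (e.g.
  # constant in training) cannot be scored and are never useful supports
  candidates <- candidates[is.finite(candidates$h2) &
                             is.finite(candidates$r), , drop = FALSE]
  if (nrow(candidates) == 0) stop("no scorable candidates", call. = FALSE)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  ranked <- candidates |>
    dplyr::mutate(score = zscore(.data$h2) + zscore(abs(.data$r))) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$h2),
                   .data$variate)
  short <- nrow(ranked) < n_select
  if (short) {
    warning("fewer candidates (", nrow(ranked), ") than requested (",
            n_select, "): returning all")
  }
  out <- utils::head(ranked, n_select)
  attr(out, "short") <- short
  out
}

#' MCMC chain configuration
#'
#' @param iterations Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before retention.
#' @param thin Retain every `thin`-th post-burn-in sweep, so
#'   `(iterations - burn_in) / thin` draws are kept.
#' @param seed Integer seed; mandatory, every chain is reproducible.
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(iterations = 15000, burn_in = 5000, thin = 5,
                         seed = 1) {
  stopifnot(iterations > burn_in, thin >= 1,
            (iterations - burn_in) %% thin == 0)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)),
            class = "chain_config")
}

#' Long table to genotype x variate panel matrix
#'
#' @param long Tibble with columns `genotype_id`, `variate`, `g`.
#' @return Matrix, genotypes x variates, `NA` where unobserved.
#' @export
panel_matrix <- function(long) {
  wide <- tidyr::pivot_wider(long[c("genotype_id", "variate", "g")],
                             names_from = "variate", values_from = "g")
  Y <- as.matrix(wide[-1])
  rownames(Y) <- wide$genotype_id
  Y
}

riwish <- function(df, S) {
  # inverse-Wishart draw via the Wishart of the inverted scale
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}

safe_chol <- function(S, jitter = 1e-8) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) out <- chol(S + diag(jitter * max(diag(S), 1), nrow(S)))
  out
}

#' Multi-trait genomic prediction by Gibbs sampling
#'
#' Fits the multi-trait mixed model `g_j = m_j + u_j + e_j` over J variates,
#' with genetic effects `u_all ~ N(0, K (x) G)` (Kronecker of a J x J genetic
#' covariance among variates with the genomic relationship matrix) and
#' residuals `e_all ~ N(0, R (x) I)`. A Gibbs sampler alternates: genetic
#' effects on the eigenbasis of G (where the Kronecker conditional decouples
#' into n independent J-dimensional normals), inverse-Wishart updates of K
#' and R (weakly informative priors: J+2 degrees of freedom, 0.5 I scale),
#' a joint normal update of the means under a flat prior, and conditional-
#' normal imputation of unobserved panel entries (test genotypes), which is
#' how predictions arise.
#'
#' @param Y Genotype x variate matrix (see [panel_matrix()]); `NA` marks
#'   unobserved entries to be predicted. Rownames are genotype ids, all of
#'   which must appear in `grm`.
#' @param grm Genomic relationship matrix.
#' @param chain A [chain_config()].
#' @return Object of class `multitrait_fit`: posterior means `K_hat`,
#'   `R_hat`, `m_hat`, `u_hat` (n x J), retained draws `u_draws`
#'   (draws x n x J array) and `m_draws`, the chain config, and bookkeeping
#'   (`variates`, `genotype_ids`, `missing` mask).
#' @details Genotypes with no observed variate at all (the typical test set)
#'   are not data-augmented: their effects are drawn each sweep from the
#'   conditional prior given the observed genotypes' effects (through the
#'   relationship matrix), which avoids the slow-mixing feedback loop of
#'   imputing phenotypes that carry no information. Partially observed
#'   genotypes keep the usual conditional-normal imputation of their missing
#'   variates.
#' @export
fit_multitrait <- function(Y, grm, chain = chain_config()) {
  stopifnot(is.matrix(Y), ncol(Y) >= 1, !is.null(rownames(Y)))
  ids <- rownames(Y)
  if (!all(ids %in% rownames(grm))) {
    stop("panel genotypes missing from the GRM", call. = FALSE)
  }
  n <- nrow(Y); J <- ncol(Y)
  if (!all(colSums(!is.na(Y)) >= 1)) {
    stop("every variate needs at least one observed value", call. = FALSE)
  }
  set.seed(chain$seed)

  # fit on standardised columns: variates can live on wildly different
  # scales (degree-days vs rates), and both the sampler's conditioning and
  # the weakly informative inverse-Wishart prior assume O(1) variances;
  # results are transformed back to the original scale on exit
  sds <- apply(Y, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  Y <- sweep(Y, 2, sds, "/")

  G <- grm[ids, ids]
  miss <- is.na(Y)
  fm <- rowSums(!miss) == 0               # fully unobserved genotypes
  O <- which(!fm); F_ <- which(fm)
  nO <- length(O); nF <- length(F_)
  if (nO < 2) stop("need at least two genotypes with observations",
                   call. = FALSE)

  egO <- eigen(G[O, O], symmetric = TRUE)
  dO <- pmax(egO$values, 1e-8)
  UO <- egO$vectors
  if (nF > 0) {
    # conditional prior of the unobserved block given the observed one
    GOOinv <- UO %*% (t(UO) / dO)
    A <- G[F_, O, drop = FALSE] %*% GOOinv
    S_FF <- G[F_, F_, drop = FALSE] - A %*% G[O, F_, drop = FALSE]
    LS <- t(safe_chol((S_FF + t(S_FF)) / 2))
  }

  col_mu <- colMeans(Y, na.rm = TRUE)
  YcO <- Y[O, , drop = FALSE]
  missO <- miss[O, , drop = FALSE]
  for (j in seq_len(J)) YcO[missO[, j], j] <- col_mu[j]

  col_var <- apply(Y, 2, stats::var, na.rm = TRUE)
  col_var[!is.finite(col_var) | col_var == 0] <- 1
  K <- diag(col_var / 2, J)
  R <- diag(col_var / 2, J)
  m <- col_mu
  u <- matrix(0, n, J)

  nu0 <- J + 2
  S0 <- diag(0.5, J)

  # group partially observed genotypes by missingness pattern (blockwise
  # imputation of their unobserved variates)
  pat <- apply(missO, 1, paste, collapse = "")
  pat_groups <- split(seq_len(nO), pat)

  n_keep <- (chain$iterations - chain$burn_in) %/% chain$thin
  u_draws <- array(NA_real_, c(n_keep, n, J),
                   dimnames = list(NULL, ids, colnames(Y)))
  m_draws <- matrix(NA_real_, n_keep, J, dimnames = list(NULL, colnames(Y)))
  K_sum <- matrix(0, J, J); R_sum <- matrix(0, J, J)
  ucm_sum <- matrix(0, n, J)   # Rao-Blackwellised accumulator for u_hat
  kept <- 0L

  for (it in seq_len(chain$iterations)) {
    Kinv <- chol2inv(safe_chol(K))
    Kinv <- (Kinv + t(Kinv)) / 2
    Rinv <- chol2inv(safe_chol(R))
    Rinv <- (Rinv + t(Rinv)) / 2

    # --- effects of observed genotypes on the eigenbasis of G[O, O]
    Yt <- crossprod(UO, sweep(YcO, 2, m))
    smp <- .sample_u_rot_cpp(Yt, dO, Kinv, Rinv)
    Ut <- smp$Ut
    uO <- UO %*% Ut
    uO_mean <- UO %*% smp$Mt
    u[O, ] <- uO

    # --- effects of unobserved genotypes from the conditional prior
    if (nF > 0) {
      W <- matrix(stats::rnorm(nF * J), nF, J) %*% safe_chol(K)
      dev <- LS %*% W
      u[F_, ] <- A %*% uO + dev
    }

    # --- genetic covariance K | u: the quadratic form u' G^-1 u splits into
    #     the rotated observed block and the conditional deviation block
    SK <- S0 + crossprod(Ut / sqrt(dO))
    if (nF > 0) {
      Wdev <- forwardsolve(LS, dev)
      SK <- SK + crossprod(Wdev)
    }
    K <- riwish(nu0 + n, SK)

    # --- residual covariance R | residuals of observed genotypes
    E <- YcO - matrix(m, nO, J, byrow = TRUE) - uO
    R <- riwish(nu0 + nO, S0 + crossprod(E))

    # --- means (flat prior): m | rest ~ N(colMeans over observed rows, R/nO)
    ch_R <- safe_chol(R)
    m <- colMeans(YcO - uO) + drop(crossprod(ch_R, stats::rnorm(J))) / sqrt(nO)

    # --- impute missing variates of partially observed genotypes
    for (g_idx in pat_groups) {
      mpat <- missO[g_idx[1], ]
      if (!any(mpat)) next
      M <- which(mpat); Ov <- which(!mpat)
      mean_M <- matrix(m[M], length(g_idx), length(M), byrow = TRUE) +
        uO[g_idx, M, drop = FALSE]
      if (length(Ov)) {
        RooI <- chol2inv(safe_chol(R[Ov, Ov, drop = FALSE]))
        resO <- YcO[g_idx, Ov, drop = FALSE] -
          matrix(m[Ov], length(g_idx), length(Ov), byrow = TRUE) -
          uO[g_idx, Ov, drop = FALSE]
        A_imp <- R[M, Ov, drop = FALSE] %*% RooI
        mean_M <- mean_M + resO %*% t(A_imp)
        cond <- R[M, M, drop = FALSE] - A_imp %*% R[Ov, M, drop = FALSE]
      } else {
        cond <- R[M, M, drop = FALSE]
      }
      ch <- safe_chol((cond + t(cond)) / 2)
      z <- matrix(stats::rnorm(length(g_idx) * length(M)),
                  length(g_idx), length(M))
      YcO[g_idx, M] <- mean_M + z %*% ch
    }

    if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0) {
      kept <- kept + 1L
      u_draws[kept, , ] <- u
      m_draws[kept, ] <- m
      K_sum <- K_sum + K
      R_sum <- R_sum + R
      # point predictions average the conditional MEAN of the unobserved
      # genotypes' effects (Rao-Blackwellisation): the conditional-prior
      # noise belongs in the draws (ABC consumes it) but would only add
      # Monte-Carlo error to a posterior-mean prediction
      ucm <- u
      ucm[O, ] <- uO_mean
      if (nF > 0) ucm[F_, ] <- A %*% uO_mean
      ucm_sum <- ucm_sum + ucm
    }
  }

  # back to the original scale
  scale_out <- tcrossprod(sds)
  vn <- colnames(Y)
  dimnames(K_sum) <- dimnames(R_sum) <- list(vn, vn)
  for (j in seq_len(J)) u_draws[, , j] <- u_draws[, , j] * sds[j]
  m_draws <- sweep(m_draws, 2, sds, "*")
  structure(
    list(
      K_hat = K_sum / kept * scale_out, R_hat = R_sum / kept * scale_out,
      m_hat = colMeans(m_draws),
      u_hat = sweep(ucm_sum / kept, 2, sds, "*"),
      u_draws = u_draws, m_draws = m_draws,
      chain = chain, variates = colnames(Y), genotype_ids = ids,
      missing = miss
    ),
    class = "multitrait_fit"
  )
}

#' @export
print.multitrait_fit <- function(x, ...) {
  cat("Multi-trait G-BLUP (Gibbs) fit\n")
  cat(sprintf("  %d genotypes x %d variates, %d retained draws\n",
              length(x$genotype_ids), length(x$variates),
              dim(x$u_draws)[1]))
  invisible(x)
}

#' @export
tidy.multitrait_fit <- function(x, ...) {
  tibble::tibble(
    genotype_id = rep(x$genotype_ids, times = length(x$variates)),
    variate = rep(x$variates, each = length(x$genotype_ids)),
    g_hat = as.vector(
      x$u_hat + matrix(x$m_hat, nrow(x$u_hat), ncol(x$u_hat), byrow = TRUE)
    ),
    observed = as.vector(!x$missing)
  )
}

#' @export
glance.multitrait_fit <- function(x, ...) {
  tibble::tibble(
    n_genotypes = length(x$genotype_ids), n_variates = length(x$variates),
    n_draws = dim(x$u_draws)[1],
    iterations = x$chain$iterations, burn_in = x$chain$burn_in,
    thin = x$chain$thin, seed = x$chain$seed
  )
}

#' Point predictions and posterior draws for one variate
#'
#' @param fit A [fit_multitrait()] result.
#' @param target Variate label to extract.
#' @param ids Genotypes to report (default: all in the fit).
#' @param draws If `TRUE`, also return the retained posterior draws of
#'   `m_target + u` per genotype (draws x genotype matrix) for downstream
#'   trajectory sampling.
#' @return Tibble `genotype_id`, `pred` (posterior mean); with `draws =
#'   TRUE`, the draw matrix is attached as attribute `draws`.
#' @export
predict_from_fit <- function(fit, target, ids = fit$genotype_ids,
                             draws = FALSE) {
  stopifnot(inherits(fit, "multitrait_fit"))
  if (!target %in% fit$variates) stop("unknown variate: ", target, call. = FALSE)
  unknown <- setdiff(ids, fit$genotype_ids)
  if (length(unknown)) {
    stop("genotypes not in fit: ", paste(utils::head(unknown, 5),
                                         collapse = ", "), call. = FALSE)
  }
  j <- match(target, fit$variates)
  i <- match(ids, fit$genotype_ids)
  dm <- matrix(fit$u_draws[, i, j], nrow = dim(fit$u_draws)[1]) +
    fit$m_draws[, j]
  out <- tibble::tibble(genotype_id = ids,
                        pred = fit$u_hat[i, j] + fit$m_hat[j])
  if (draws) {
    colnames(dm) <- ids
    attr(out, "draws") <- dm
  }
  out
}
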