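#' Marker quality control and imputation
#'
#' Filters a coded biallelic marker matrix on missing rate and minor allele
#' frequency, prunes near-duplicate markers by pairwise linkage
#' disequilibrium in a greedy sliding window, and mean-imputes the remaining
#' missing calls.
#'
#' @param geno Numeric matrix, genotypes x markers, coded -1 (reference
#'   homozygote), 0 (heterozygote), 1 (alternative homozygote), `NA` missing.
#'   Row and column names identify genotypes and markers.
#' @param maf Minimum minor allele frequency (markers with MAF below this are
#'   dropped). Default 0.025.
#' @param max_missing Markers with a missing rate at or above this are
#'   dropped. Default 0.05.
#' @param ld_r2 Pairwise squared correlation at or above which the later
#'   marker of a pair is pruned. Default 0.95.
#' @param ld_window,ld_step Sliding-window size and step (in markers) for the
#'   LD pruning pass.
#' @return The filtered, imputed marker matrix (no missing values).
#' @export
qc_markers <- function(geno, maf = 0.025, max_missing = 0.05,
                       ld_r2 = 0.95, ld_window = 50, ld_step = 5) {
  stopifnot(is.matrix(geno))
  bad <- !(geno %in% c(-1, 0, 1, NA))
  if (any(bad)) stop("marker codes must be -1, 0, 1 or NA", call. = FALSE)

  miss <- colMeans(is.na(geno))
  geno <- geno[, miss < max_missing, drop = FALSE]

  p_alt <- (colMeans(geno == 1, na.rm = TRUE) +
              0.5 * colMeans(geno == 0, na.rm = TRUE))
  maf_obs <- pmin(p_alt, 1 - p_alt)
  geno <- geno[, !is.na(maf_obs) & maf_obs >= maf, drop = FALSE]

  if (ncol(geno) == 0L) stop("no markers survive quality control", call. = FALSE)

  # greedy sliding-window LD pruning: within each window the later marker of
  # any pair with r^2 >= ld_r2 is dropped
  m <- ncol(geno)
  keep <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(m - ld_window + 1L, 1L), by = ld_step)))
  for (s in starts) {
    idx <- seq(s, min(s + ld_window - 1L, m))
    idx <- idx[keep[idx]]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(
      stats::cor(geno[, idx, drop = FALSE], use = "pairwise.complete.obs")^2
    )
    for (j in seq_along(idx)[-1]) {
      earlier <- r2[seq_len(j - 1L), j]
      if (any(earlier >= ld_r2, na.rm = TRUE)) keep[idx[j]] <- FALSE
    }
  }
  geno <- geno[, keep, drop = FALSE]

  # column-mean imputation of remaining missing calls
  if (anyNA(geno)) {
    mu <- colMeans(geno, na.rm = TRUE)
    na_idx <- which(is.na(geno), arr.ind = TRUE)
    geno[na_idx] <- mu[na_idx[, 2]]
  }
  geno
}

#' Genomic relationship matrix
#'
#' Computes `G = X X' / c` from column-centred and scaled marker codes, with
#' the normalisation constant `c = trace(X X') / n` so that the mean diagonal
#' element equals 1 and genomic heritability sits on the usual scale.
#'
#' @param markers Imputed marker matrix (genotypes x markers), e.g. from
#'   [qc_markers()]. Zero-variance columns are dropped with a warning.
#' @return An n x n symmetric positive semi-definite matrix with genotype ids
#'   as dimnames.
#' @export
compute_grm <- function(markers) {
  stopifnot(is.matrix(markers), nrow(markers) >= 2, ncol(markers) >= 1)
  sds <- apply(markers, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance marker(s) excluded from the GRM")
    markers <- markers[, sds > 0, drop = FALSE]
  }
  if (ncol(markers) == 0L) stop("no polymorphic markers left", call. = FALSE)
  X <- scale(markers)
  XXt <- tcrossprod(X)
  G <- XXt * nrow(X) / sum(diag(XXt))
  dimnames(G) <- list(rownames(markers), rownames(markers))
  (G + t(G)) / 2
}

#' Genotypic values from replicated plot data
#'
#' Fits the plot-level mixed model `y = mu + block + genotype + e` with fixed
#' block effects (sum-to-zero contrasts, so `mu` is the overall mean) and
#' i.i.d. random genotype effects, via `lme4::lmer`. The genotypic value of a
#' genotype is `mu + BLUP`. Applied separately per trait (e.g. per flight
#' date and environment for green fraction, per environment for each curve
#' parameter).
#'
#' @param df Data frame with columns `genotype_id`, `block` and `value` (one
#'   row per plot).
#' @return A tibble `genotype_id`, `g`, with attributes `sigma2_s` (genotypic
#'   variance), `sigma2_e` (residual variance) and `mu`. When no genotype is
#'   replicated the variances are unidentifiable: plot means are returned
#'   with a warning and `NA` variance components.
#' @export
genotypic_values <- function(df) {
  stopifnot(all(c("genotype_id", "block", "value") %in% names(df)))
  reps <- table(df$genotype_id)
  if (max(reps) < 2L) {
    warning("no replication: returning plot means, variance components NA")
    out <- df |>
      dplyr::group_by(.data$genotype_id) |>
      dplyr::summarise(g = mean(.data$value), .groups = "drop")
    attr(out, "sigma2_s") <- NA_real_
    attr(out, "sigma2_e") <- NA_real_
    attr(out, "mu") <- mean(df$value)
    return(out)
  }
  df$block <- factor(df$block)
  df$genotype_id <- as.character(df$genotype_id)
  # near-constant traits (e.g. pre-emergence flight dates) produce benign
  # singular fits; the estimates are still the right degenerate limits
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    value ~ block + (1 | genotype_id), data = df,
    contrasts = if (nlevels(df$block) > 1) list(block = "contr.sum") else NULL,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )))
  mu <- unname(lme4::fixef(fit)[["(Intercept)"]])
  blup <- lme4::ranef(fit)$genotype_id
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- tibble::tibble(
    genotype_id = rownames(blup),
    g = mu + blup[["(Intercept)"]]
  )
  attr(out, "sigma2_s") <- vc$vcov[vc$grp == "genotype_id"]
  attr(out, "sigma2_e") <- vc$vcov[vc$grp == "Residual"]
  attr(out, "mu") <- mu
  out
}

#' Per-date green fraction genotypic values
#'
#' Runs [genotypic_values()] separately for every environment x observation
#' day of a plot-level green fraction table.
#'
#' @param obs Observation table with columns `genotype_id`, `environment_id`,
#'   `block`, `day`, `gf`.
#' @return Tibble `variate`, `environment_id`, `day`, `genotype_id`, `g`;
#'   variate labels have the form `"gf|<environment>|<day>"`.
#' @export
gf_genotypic_values <- function(obs) {
  stopifnot(all(c("genotype_id", "environment_id", "block", "day", "gf")
                %in% names(obs)))
  obs |>
    dplyr::group_by(.data$environment_id, .data$day) |>
    dplyr::group_modify(function(d, key) {
      gv <- genotypic_values(
        dplyr::transmute(d, genotype_id = .data$genotype_id,
                         block = .data$block, value = .data$gf)
      )
      gv
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(variate = gf_variate(.data$environment_id, .data$day),
                  .before = 1)
}

gf_variate <- function(environment_id, day) {
  sprintf("gf|%s|%03d", environment_id, as.integer(day))
}

param_variate <- function(param, environment_id) {
  paste0(param, "|", environment_id)
}

dyn_param_names <- c("lai_amp", "r_g", "r_s", "t_g", "t_s")

#' Genotypic values of the fitted curve parameters
#'
#' Runs [genotypic_values()] for each dynamics parameter within each
#' environment, treating a genotype's plots (blocks) as replicates.
#'
#' @param fits A [fit_dynamics()] result (plot-level parameter table) with an
#'   additional `block` column, or plots are treated as unlabelled replicates
#'   if `block` is absent.
#' @return Tibble `variate`, `environment_id`, `param`, `genotype_id`, `g`.
#' @export
param_genotypic_values <- function(fits) {
  fits <- dplyr::as_tibble(fits)
  if (!"block" %in% names(fits)) {
    fits <- fits |>
      dplyr::group_by(.data$genotype_id, .data$environment_id) |>
      dplyr::mutate(block = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  long <- tidyr::pivot_longer(
    fits[c("genotype_id", "environment_id", "block", dyn_param_names)],
    dplyr::all_of(dyn_param_names), names_to = "param", values_to = "value"
  )
  long |>
    dplyr::group_by(.data$environment_id, .data$param) |>
    dplyr::group_modify(~ genotypic_values(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(variate = param_variate(.data$param, .data$environment_id),
                  .before = 1)
}

# ---- single-trait G-BLUP (REML by spectral decomposition) -------------------

# restricted log-likelihood of the variance ratio lambda = sigma2_u / sigma2_e
# in y ~ N(1 m, sigma2_u G + sigma2_e I), on the eigenbasis of G
reml_profile <- function(log_lambda, d, ystar, xstar) {
  lambda <- exp(log_lambda)
  v <- lambda * d + 1
  w <- 1 / v
  xwx <- sum(w * xstar^2)
  beta <- sum(w * xstar * ystar) / xwx
  r <- ystar - xstar * beta
  n <- length(ystar)
  s2 <- sum(w * r^2) / (n - 1)
  ll <- -0.5 * ((n - 1) * log(s2) + sum(log(v)) + log(xwx))
  if (!is.finite(ll)) -1e300 else ll
}

#' Single-trait genomic BLUP
#'
#' Fits `g = m + u + e`, `u ~ N(0, sigma2_u G)`, `e ~ N(0, sigma2_e I)` on the
#' training genotypes by REML, profiling the variance ratio on the spectral
#' decomposition of the training-set relationship matrix (exact
#' one-dimensional search, no iterative solver). Test genotypes are predicted
#' from the conditional mean given the training records.
#'
#' @param g Tibble with columns `genotype_id` and `g` (one genotypic value per
#'   genotype), or a named numeric vector.
#' @param grm Genomic relationship matrix covering all ids ([compute_grm()]).
#' @param train_ids Genotypes used to fit the model.
#' @param test_ids Genotypes to predict (disjoint from `train_ids`); may be
#'   empty when only variance components are of interest.
#' @param eig Optional precomputed `eigen(grm[train_ids, train_ids],
#'   symmetric = TRUE)`, a worthwhile saving when many variates share one
#'   training set.
#' @return Object of class `gblup_fit`: list with `mu`, `sigma2_u`,
#'   `sigma2_e`, `h2`, `lambda`, and `predictions` (tibble `genotype_id`,
#'   `u`, `set`, `pred_var`; `u` is the genetic deviation from `mu`,
#'   `pred_var` the conditional prediction variance for test genotypes).
#' @export
gblup <- function(g, grm, train_ids, test_ids = character(), eig = NULL) {
  if (!is.data.frame(g)) {
    g <- tibble::tibble(genotype_id = names(g), g = unname(g))
  }
  stopifnot(length(train_ids) > 0, !anyDuplicated(c(train_ids, test_ids)))
  missing_ids <- setdiff(c(train_ids, test_ids), rownames(grm))
  if (length(missing_ids)) {
    stop("genotypes absent from the GRM: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  y <- g$g[match(train_ids, g$genotype_id)]
  if (anyNA(y)) stop("missing genotypic values for training ids", call. = FALSE)

  Gtr <- grm[train_ids, train_ids]
  eg <- if (is.null(eig)) eigen(Gtr, symmetric = TRUE) else eig
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ystar <- drop(crossprod(U, y))
  xstar <- drop(crossprod(U, rep(1, length(y))))

  # bounded profile search on the log-variance-ratio scale: coarse grid to
  # bracket the mode, then golden-section refinement
  grid <- seq(log(1e-5), log(1e5), length.out = 61)
  ll <- vapply(grid, reml_profile, numeric(1), d = d, ystar = ystar,
               xstar = xstar)
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(reml_profile, c(lo, hi), d = d, ystar = ystar,
                         xstar = xstar, maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)

  v <- lambda * d + 1
  w <- 1 / v
  mu <- sum(w * xstar * ystar) / sum(w * xstar^2)
  r <- ystar - xstar * mu
  sigma2_e <- sum(w * r^2) / (length(y) - 1)
  sigma2_u <- lambda * sigma2_e
  h2 <- sigma2_u / (sigma2_u + sigma2_e)

  # BLUPs: u_train = lambda G (lambda G + I)^-1 r; for test genotypes the
  # conditional mean G_xt (G_tr + I/lambda)^-1 r and its variance
  Vinv_r <- U %*% (w * r)               # (lambda G + I)^-1 (y - mu)
  u_train <- drop(Gtr %*% Vinv_r) * lambda
  preds <- tibble::tibble(genotype_id = train_ids, u = u_train,
                          set = "train", pred_var = NA_real_)
  if (length(test_ids)) {
    Gxt <- grm[test_ids, train_ids, drop = FALSE]
    u_test <- drop(Gxt %*% Vinv_r) * lambda
    # Var(u_test | y) = s2u (G_xx - G_xt (G_tr + I/lambda)^-1 G_tx)
    B <- U %*% (sqrt(lambda * w) * t(U))          # symmetric root of reduction
    red <- rowSums((Gxt %*% B)^2)
    pv <- pmax(sigma2_u * (diag(grm)[test_ids] ) - sigma2_u * red, 0)
    preds <- dplyr::bind_rows(
      preds,
      tibble::tibble(genotype_id = test_ids, u = u_test, set = "test",
                     pred_var = pv)
    )
  }
  structure(
    list(mu = mu, sigma2_u = sigma2_u, sigma2_e = sigma2_e, h2 = h2,
         lambda = lambda, predictions = preds),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("Single-trait G-BLUP fit\n")
  cat(sprintf("  mean %.4g, sigma2_u %.4g, sigma2_e %.4g, h2 %.3f\n",
              x$mu, x$sigma2_u, x$sigma2_e, x$h2))
  cat(sprintf("  %d training, %d test genotypes\n",
              sum(x$predictions$set == "train"),
              sum(x$predictions$set == "test")))
  invisible(x)
}

#' @export
tidy.gblup_fit <- function(x, ...) x$predictions

#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma2_u = x$sigma2_u, sigma2_e = x$sigma2_e,
                 h2 = x$h2, lambda = x$lambda)
}

#' Prediction accuracy
#'
#' Pearson correlation between genotypic values and their predictions, the
#' accuracy measure used throughout the cross-validation schemes.
#'
#' @param g_true,u_pred Paired numeric vectors (at least 3 pairs, both with
#'   non-zero variance).
#' @return Correlation in `[-1, 1]`.
#' @export
accuracy <- function(g_true, u_pred) {
  stopifnot(length(g_true) == length(u_pred))
  if (length(g_true) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(g_true) == 0 || stats::sd(u_pred) == 0) {
    stop("accuracy undefined: zero variance", call. = FALSE)
  }
  stats::cor(g_true, u_pred)
}
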