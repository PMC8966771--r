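toy_geno <- function() {
  m <- matrix(c(-1, 1, -1, 1,    # polymorphic
                -1, -1, -1, -1,  # monomorphic
                1, 1, -1, -1),   # polymorphic, uncorrelated with m1
              nrow = 4)
  dimnames(m) <- list(paste0("g", 1:4), paste0("m", 1:3))
  m
}

test_that("marker QC removes monomorphic, missing-heavy and duplicate sites", {
  g <- toy_geno()
  out <- qc_markers(g)
  expect_false("m2" %in% colnames(out))          # MAF 0 < 0.025

  g_miss <- g
  g_miss[1:2, 1] <- NA                           # missing rate 0.5 >= 0.05
  out <- qc_markers(g_miss)
  expect_false("m1" %in% colnames(out))

  g_dup <- cbind(g[, c(1, 3)], m4 = g[, 1])      # m4 duplicates m1 (r2 = 1)
  out <- qc_markers(g_dup)
  expect_equal(colnames(out), c("m1", "m3"))

  expect_error(qc_markers(g[, 2, drop = FALSE]), "survive")
  expect_error(qc_markers(matrix(2, 2, 2)), "codes")
})

test_that("mean imputation fills surviving missing calls", {
  set.seed(2)
  g <- simulate_markers(50, 20, missing_rate = 0.02, seed = 2)
  out <- qc_markers(g)
  expect_false(anyNA(out))
  # imputed value equals the column mean of observed codes
  na_pos <- which(is.na(g), arr.ind = TRUE)
  na_pos <- na_pos[colnames(g)[na_pos[, 2]] %in% colnames(out), , drop = FALSE]
  if (nrow(na_pos) > 0) {
    j <- na_pos[1, 2]
    expect_equal(out[na_pos[1, 1], colnames(g)[j]],
                 mean(g[, j], na.rm = TRUE))
  }
})

test_that("GRM construction matches direct matrix arithmetic", {
  g2 <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "m1"))
  expect_equal(compute_grm(g2),
               matrix(c(1, -1, -1, 1), 2, dimnames = list(c("a", "b"),
                                                          c("a", "b"))))

  # identical genotype rows: off-diagonal equals both diagonals
  g3 <- rbind(a = c(-1, 1, 0, 1), b = c(-1, 1, 0, 1), c = c(1, -1, 1, -1))
  colnames(g3) <- paste0("m", 1:4)
  G3 <- compute_grm(g3)
  expect_equal(G3["a", "b"], G3["a", "a"])
  expect_equal(G3["a", "b"], G3["b", "b"])

  # brute-force oracle on a random panel
  set.seed(10)
  g <- simulate_markers(10, 50, seed = 10)
  g <- g[, apply(g, 2, stats::sd) > 0]
  G <- compute_grm(g)
  X <- scale(g)
  c_const <- sum(diag(X %*% t(X))) / nrow(g)
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    oracle[i, j] <- sum(X[i, ] * X[j, ]) / c_const
  }
  expect_equal(unname(G), oracle, tolerance = 1e-12)
})

test_that("the GRM is symmetric PSD with unit mean diagonal", {
  fx <- fixture_grm()
  G <- fx$grm
  expect_equal(G, t(G), tolerance = 1e-10)
  expect_equal(mean(diag(G)), 1, tolerance = 1e-12)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  expect_warning(compute_grm(cbind(fx$geno[, 1:5], const = 0)),
                 "zero-variance")
})

test_that("genotypic values reduce to genotype means without residual noise", {
  df <- tibble::tibble(
    genotype_id = rep(paste0("g", 1:6), each = 2),
    block = rep(1:2, 6),
    value = rep(c(1, 3, 5, 2, 4, 6), each = 2)
  )
  gv <- genotypic_values(df)
  expect_equal(gv$g[match(paste0("g", 1:6), gv$genotype_id)],
               c(1, 3, 5, 2, 4, 6), tolerance = 1e-6)
  expect_lt(attr(gv, "sigma2_e"), 1e-8)
})

test_that("genotypic values collapse to the mean when genotypes are equal", {
  df <- tibble::tibble(
    genotype_id = rep(paste0("g", 1:6), each = 2),
    block = rep(1:2, 6),
    value = rep(c(2, 2.4), 6)
  )
  gv <- genotypic_values(df)
  expect_lt(attr(gv, "sigma2_s"), 1e-6)
  expect_equal(gv$g, rep(2.2, 6), tolerance = 1e-4)
})

test_that("unreplicated data fall back to plot means with a warning", {
  df <- tibble::tibble(genotype_id = paste0("g", 1:5), block = 1,
                       value = 1:5)
  expect_warning(gv <- genotypic_values(df), "replication")
  expect_equal(gv$g, as.numeric(1:5))
  expect_true(is.na(attr(gv, "sigma2_s")))
})

test_that("BLUPs shrink genotype means toward the grand mean", {
  set.seed(14)
  n_g <- 50
  s <- rnorm(n_g, 0, 1)
  df <- tibble::tibble(
    genotype_id = rep(sprintf("g%02d", 1:n_g), each = 2),
    block = rep(1:2, n_g),
    value = 5 + rep(s, each = 2) + rnorm(2 * n_g, 0, 1)
  )
  gv <- genotypic_values(df)
  raw <- tapply(df$value, df$genotype_id, mean)[gv$genotype_id]
  mu <- attr(gv, "mu")
  expect_true(all(abs(gv$g - mu) <= abs(raw - mu) + 1e-8))
  expect_lt(var(gv$g), var(raw))
  # variance components in the right region
  expect_gt(attr(gv, "sigma2_s"), 0.3)
  expect_lt(attr(gv, "sigma2_s"), 2.5)
})

test_that("G-BLUP with an identity relationship predicts no deviation", {
  ids <- paste0("g", 1:20)
  G <- diag(20); dimnames(G) <- list(ids, ids)
  set.seed(3)
  g <- tibble::tibble(genotype_id = ids, g = rnorm(20))
  fit <- gblup(g, G, train_ids = ids[1:15], test_ids = ids[16:20])
  pr <- fit$predictions
  expect_equal(pr$u[pr$set == "test"], rep(0, 5), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("G-BLUP variance components satisfy the heritability identity", {
  fx <- fixture_grm()
  u <- grm_mvn(fx$grm, seed = 8)
  set.seed(9)
  g <- tibble::tibble(genotype_id = rownames(fx$grm),
                      g = u + rnorm(40, 0, 0.6))
  fit <- gblup(g, fx$grm, rownames(fx$grm)[1:30], rownames(fx$grm)[31:40])
  expect_equal(fit$h2, fit$sigma2_u / (fit$sigma2_u + fit$sigma2_e),
               tolerance = 1e-10)
  expect_true(all(tidy(fit)$pred_var[tidy(fit)$set == "test"] >= 0))
  expect_equal(nrow(glance(fit)), 1)
  expect_error(gblup(g, fx$grm, c("nope")), "absent")
})

test_that("accuracy is the Pearson correlation with its closed form", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 2, 3), c(-1, -2, -3)), -1)
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-7)
  expect_error(accuracy(c(1, 2), c(1, 2)), "at least 3")
  expect_error(accuracy(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
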