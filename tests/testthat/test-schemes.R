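scheme_fixture <- function() {
  inp <- fixture_inputs(n = 30, seed = 5)
  ids <- inp$genotype_ids
  list(inp = inp, train = ids[1:24], test = ids[25:30])
}

test_that("GP predictions are the G-BLUP conditional means", {
  fx <- scheme_fixture()
  tv <- grep("^gf\\|2019-C", colnames(fx$inp$panel), value = TRUE)[4]
  g <- tibble::tibble(genotype_id = fx$train,
                      g = fx$inp$panel[fx$train, tv])
  pred <- predict_gp(g, fx$inp$grm, fx$train, fx$test)
  fit <- gblup(g, fx$inp$grm, fx$train, fx$test)
  pr <- fit$predictions
  expect_equal(pred$pred,
               fit$mu + pr$u[pr$set == "test"][match(fx$test,
                 pr$genotype_id[pr$set == "test"])])
})

test_that("TGP equals the manual composition of G-BLUP and the curve", {
  fx <- scheme_fixture()
  pg <- canopygp:::param_gv_env(fx$inp, "2019-C", fx$train)
  fl <- fx$inp$flights[fx$inp$flights$environment_id == "2019-C", ]
  traj <- predict_tgp(pg, fx$inp$grm, fx$train, fx$test,
                      gdd = fl$gdd, days = fl$day)
  par_mat <- attr(traj, "params")
  for (id in fx$test[1:2]) {
    manual <- predict_gf_curve(fl$gdd, as.list(par_mat[id, ]))
    expect_equal(traj$gf_pred[traj$genotype_id == id], manual)
  }
  # each parameter column reproduces an individual gblup run
  one <- gblup(pg[pg$param == "t_g", c("genotype_id", "g")],
               fx$inp$grm, fx$train, fx$test)
  pr <- one$predictions
  expect_equal(unname(par_mat[, "t_g"]),
               unname(one$mu + pr$u[pr$set == "test"][match(fx$test,
                 pr$genotype_id[pr$set == "test"])]))
  expect_true(all(traj$gf_pred >= 0 & traj$gf_pred < 1))
})

test_that("a test genotype at the training average regresses to the mean", {
  fx <- scheme_fixture()
  grm2 <- fx$inp$grm
  # replace one test genotype's relationships with the training average
  avg <- colMeans(grm2[fx$train, ])
  id <- fx$test[1]
  grm2[id, ] <- avg; grm2[, id] <- avg
  grm2[id, id] <- 1
  pg <- canopygp:::param_gv_env(fx$inp, "2019-C", fx$train)
  gp <- canopygp:::gblup_params(pg, grm2, fx$train, fx$test)
  # its predicted deviation is the average of the training BLUPs, i.e. small
  g_tg <- pg[pg$param == "t_g", ]
  expect_lt(abs(gp$pred[id, "t_g"] - mean(g_tg$g[match(fx$train, g_tg$genotype_id)])),
            2 * sd(g_tg$g))
})

test_that("ABC keeps the draws a brute-force distance sort would keep", {
  set.seed(50)
  n_draws <- 100
  gdd <- seq(100, 1500, length.out = 10)
  days <- seq_along(gdd)
  true_p <- c(lai_amp = 3, r_g = 0.02, r_s = 0.004, t_g = 600, t_s = 2000)
  draws <- array(NA_real_, c(n_draws, 1, 5),
                 dimnames = list(NULL, "gX", names(true_p)))
  for (p in names(true_p)) {
    draws[, 1, p] <- true_p[p] * exp(rnorm(n_draws, 0, 0.15))
  }
  draws[7, 1, ] <- true_p   # an exact draw
  early_days <- days[1:5]
  early_obs <- tibble::tibble(
    genotype_id = "gX", day = early_days,
    gf = predict_gf_curve(gdd[1:5], as.list(true_p))
  )
  ref <- abc_refine(draws, early_obs, gdd, days, n_keep = 10)
  kept <- attr(ref, "kept")$gX
  # oracle: explicit distances, explicit sort
  d_or <- sapply(seq_len(n_draws), function(i) {
    gf <- predict_gf_curve(gdd[1:5], as.list(draws[i, 1, ]))
    sqrt(sum((gf - early_obs$gf)^2))
  })
  expect_setequal(kept, order(d_or)[1:10])
  expect_true(7 %in% kept)                     # zero-distance draw always kept
  # prediction is the mean trajectory of the kept draws, over all dates
  manual <- rowMeans(sapply(kept, function(i) {
    predict_gf_curve(gdd, as.list(draws[i, 1, ]))
  }))
  expect_equal(ref$gf_pred, manual)
})

test_that("keeping every draw reduces ABC to the plain posterior mean", {
  set.seed(51)
  draws <- array(runif(60 * 1 * 5, 0.5, 1), c(60, 1, 5),
                 dimnames = list(NULL, "gX",
                                 c("lai_amp", "r_g", "r_s", "t_g", "t_s")))
  draws[, 1, "t_g"] <- runif(60, 400, 700)
  draws[, 1, "t_s"] <- runif(60, 1500, 2500)
  draws[, 1, "r_g"] <- runif(60, 0.01, 0.03)
  draws[, 1, "r_s"] <- runif(60, 0.002, 0.008)
  gdd <- seq(100, 1400, length.out = 8)
  obs <- tibble::tibble(genotype_id = "gX", day = 1:3,
                        gf = c(0.1, 0.3, 0.5))
  ref <- abc_refine(draws, obs, gdd, days = 1:8, n_keep = 60)
  mean_traj <- rowMeans(sapply(1:60, function(i) {
    predict_gf_curve(gdd, as.list(draws[i, 1, ]))
  }))
  expect_equal(ref$gf_pred, mean_traj)
})

test_that("invalid parameter draws get infinite distance but stay counted", {
  draws <- array(1, c(3, 1, 5),
                 dimnames = list(NULL, "gX",
                                 c("lai_amp", "r_g", "r_s", "t_g", "t_s")))
  draws[, 1, "t_g"] <- 500; draws[, 1, "t_s"] <- 2000
  draws[, 1, "r_g"] <- c(0.02, -0.01, 0.02)    # draw 2 invalid
  draws[, 1, "r_s"] <- 0.004
  draws[1, 1, "lai_amp"] <- 3; draws[3, 1, "lai_amp"] <- 3.2
  obs <- tibble::tibble(genotype_id = "gX", day = 1,
                        gf = predict_gf_curve(800, list(lai_amp = 3, r_g = 0.02,
                                                        r_s = 0.004, t_g = 500,
                                                        t_s = 2000)))
  ref <- abc_refine(draws, obs, gdd = c(800, 1200), days = 1:2, n_keep = 2)
  expect_false(2 %in% attr(ref, "kept")$gX)
})

test_that("without early observations ABC degrades to the posterior mean", {
  set.seed(52)
  draws <- array(NA_real_, c(20, 1, 5),
                 dimnames = list(NULL, "gX",
                                 c("lai_amp", "r_g", "r_s", "t_g", "t_s")))
  draws[, 1, "lai_amp"] <- runif(20, 2, 4)
  draws[, 1, "r_g"] <- 0.02; draws[, 1, "r_s"] <- 0.004
  draws[, 1, "t_g"] <- 600; draws[, 1, "t_s"] <- 2000
  empty <- tibble::tibble(genotype_id = character(), day = integer(),
                          gf = numeric())
  gdd <- c(400, 800)
  ref <- abc_refine(draws, empty, gdd, days = 1:2, n_keep = 3)
  mean_traj <- rowMeans(sapply(1:20, function(i) {
    predict_gf_curve(gdd, as.list(draws[i, 1, ]))
  }))
  expect_equal(ref$gf_pred, mean_traj)
})

test_that("predictive parameter draws are reproducible with matching moments", {
  params <- matrix(c(3, 0.02, 0.004, 600, 2000), 1,
                   dimnames = list("gX", c("lai_amp", "r_g", "r_s",
                                           "t_g", "t_s")))
  pv <- matrix(c(0.04, 1e-6, 1e-7, 100, 400), 1,
               dimnames = dimnames(params))
  d1 <- sample_param_draws(params, pv, 5000, seed = 77)
  d2 <- sample_param_draws(params, pv, 5000, seed = 77)
  expect_identical(d1, d2)
  expect_equal(mean(d1[, 1, "t_g"]), 600, tolerance = 1)
  expect_equal(sd(d1[, 1, "t_g"]), 10, tolerance = 0.5)
})

test_that("TMGP panels refuse observed test-genotype parameters", {
  fx <- scheme_fixture()
  targets <- paste0(c("lai_amp", "r_g", "r_s", "t_g", "t_s"), "|2019-C")
  panel <- fx$inp$panel[, targets]
  colnames(panel) <- c("lai_amp", "r_g", "r_s", "t_g", "t_s")
  expect_error(
    predict_tmgp(panel, fx$inp$grm, fx$test, gdd = c(500, 900)),
    "NA"
  )
})
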