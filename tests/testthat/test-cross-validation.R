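test_that("fold assignment is balanced, exhaustive and seed-stable", {
  ids <- sprintf("g%03d", 1:198)
  f <- make_folds(ids, 10, seed = 4)
  sizes <- table(f$fold)
  expect_equal(sort(unique(as.integer(sizes))), c(19, 20))
  expect_equal(sum(sizes == 20), 8)
  expect_equal(sum(sizes == 19), 2)
  expect_setequal(f$genotype_id, ids)

  f2 <- make_folds(ids, 10, seed = 4)
  expect_identical(f, f2)
  f3 <- make_folds(ids, 10, seed = 5)
  expect_false(identical(f$fold, f3$fold))

  singles <- make_folds(sprintf("g%02d", 1:10), 10, seed = 1)
  expect_equal(as.integer(table(singles$fold)), rep(1L, 10))
  expect_error(make_folds(ids, 1), "at least 2")
  expect_error(make_folds(ids[1:5], 10), "more folds")
})

test_that("the growth cycle splits into equal early and late halves", {
  s <- split_early_late(1:16)
  expect_equal(length(s$early), 8)
  expect_equal(length(s$late), 8)
  expect_true(max(s$early) < min(s$late))
  s_odd <- split_early_late(1:15)
  expect_equal(length(s_odd$early), 8)   # odd count favours the early period
  expect_equal(length(s_odd$late), 7)
})

test_that("an oracle model scores perfect accuracy under every scheme", {
  inp <- fixture_inputs(n = 30, seed = 5)
  plan <- cv_plan(n_folds = 3, repeats = 1, seed = 2)
  for (runner in list(run_cv1, run_cv2, run_cv3)) {
    res <- runner(inp, models = "oracle", plan = plan)
    expect_equal(res$accuracy, rep(1, nrow(res)), tolerance = 1e-12)
    expect_true(all(res$n_test == 10))
  }
})

test_that("every genotype is tested exactly once per repeat", {
  inp <- fixture_inputs(n = 30, seed = 5)
  plan <- cv_plan(n_folds = 3, repeats = 2, seed = 2)
  res <- run_cv1(inp, models = "oracle", plan = plan)
  # each (repeat, day, environment) cell covers all genotypes across folds
  per_rep <- res |>
    dplyr::group_by(rep, environment_id, day) |>
    dplyr::summarise(n = sum(n_test), .groups = "drop")
  expect_true(all(per_rep$n == 30))
})

test_that("GP predictions under CV2 coincide with CV1", {
  inp <- fixture_inputs(n = 30, seed = 5)
  plan <- cv_plan(n_folds = 3, repeats = 1, seed = 7)
  r1 <- run_cv1(inp, models = "GP", plan = plan)
  r2 <- run_cv2(inp, models = "GP", plan = plan)
  expect_equal(r1$accuracy,
               r2$accuracy[match(paste(r1$environment_id, r1$day, r1$fold),
                                 paste(r2$environment_id, r2$day, r2$fold))])
})

test_that("panel blanking removes exactly the leaking entries", {
  inp <- fixture_inputs(n = 30, seed = 5)
  ids <- inp$genotype_ids
  test_ids <- ids[1:5]
  some_gf <- grep("^gf\\|2019-C", colnames(inp$panel), value = TRUE)[1:3]
  other_env <- grep("^gf\\|2019-D", colnames(inp$panel), value = TRUE)[1:2]
  vars <- c(some_gf, other_env, "lai_amp|2019-C")

  p1 <- canopygp:::build_panel(inp, vars, test_ids, "CV1", "2019-C")
  expect_true(all(is.na(p1[test_ids, ])))
  expect_false(anyNA(p1[setdiff(ids, test_ids), ]))

  p2 <- canopygp:::build_panel(inp, vars, test_ids, "CV2", "2019-C")
  expect_true(all(is.na(p2[test_ids, c(some_gf, "lai_amp|2019-C")])))
  expect_false(anyNA(p2[test_ids, other_env]))

  fl <- inp$flights[inp$flights$environment_id == "2019-C", ]
  split <- split_early_late(sort(fl$day))
  early_var <- sprintf("gf|2019-C|%03d", split$early[1])
  late_var <- sprintf("gf|2019-C|%03d", split$late[1])
  p3 <- canopygp:::build_panel(inp, c(early_var, late_var, "lai_amp|2019-C"),
                               test_ids, "CV3", "2019-C")
  expect_false(anyNA(p3[test_ids, early_var]))
  expect_true(all(is.na(p3[test_ids, late_var])))
  expect_true(all(is.na(p3[test_ids, "lai_amp|2019-C"])))
})

test_that("supporting variates never come from the held-out environment", {
  inp <- fixture_inputs(n = 30, seed = 5)
  plan <- cv_plan(n_folds = 3, repeats = 1, seed = 3,
                  chain = chain_config(200, 100, 1, seed = 1),
                  n_supports = 4, environments = "2019-C", folds = 1)
  res <- run_cv2(inp, models = "MGP", plan = plan)
  audit <- attr(res, "audit")
  expect_gt(nrow(audit), 0)
  for (i in seq_len(nrow(audit))) {
    sup <- audit$supports[[i]]
    expect_false(any(grepl("2019-C", sup)),
                 info = paste("leaked supports:", paste(sup, collapse = ",")))
  }
})

test_that("CV3 supports combine the criterion picks with late early flights", {
  inp <- fixture_inputs(n = 30, seed = 5)
  plan <- cv_plan(n_folds = 3, repeats = 1, seed = 3,
                  chain = chain_config(200, 100, 1, seed = 1),
                  n_supports = 5, environments = "2019-C", folds = 1)
  res <- run_cv3(inp, models = "MGP", plan = plan)
  audit <- attr(res, "audit")
  fl <- inp$flights[inp$flights$environment_id == "2019-C", ]
  split <- split_early_late(sort(fl$day))
  expected_extra <- sprintf("gf|2019-C|%03d", utils::tail(split$early, 3))
  for (i in seq_len(nrow(audit))) {
    sup <- audit$supports[[i]]
    expect_length(sup, 5)
    # the three trailing supports are the latest early-period flights
    expect_equal(sup[3:5], expected_extra)
    # criterion-chosen supports avoid the held-out environment
    expect_false(any(grepl("2019-C", sup[1:2])))
  }
})

test_that("accuracy summaries and improvement ratios match hand arithmetic", {
  res <- tibble::tibble(
    scheme = "CV1", model = rep(c("A", "B"), each = 2),
    environment_id = "E", day = c(10, 20, 10, 20), fold = 1, rep = 1,
    accuracy = c(0.7, 0.5, 0.5, 0.3), n_test = 5
  )
  s <- summarize_cv(res)
  expect_equal(s$mean_accuracy[s$model == "A" & s$environment_id == "E"], 0.6)
  expect_equal(s$mean_accuracy[s$model == "B" & s$environment_id == "all"],
               0.4)
  imp <- model_improvement(res, "A", "B")
  expect_equal(imp$improvement_pct, 50)
  imp0 <- model_improvement(res, "A", "A")
  expect_equal(imp0$improvement_pct, 0)
  res_bad <- dplyr::mutate(res,
                           accuracy = ifelse(model == "B", -0.1, accuracy))
  expect_warning(model_improvement(res_bad, "A", "B"), "not positive")
})

test_that("impossible designs are rejected up front", {
  inp <- fixture_inputs(n = 30, seed = 5)
  one_env <- cv_inputs(
    dplyr::filter(inp$long, grepl("^gf\\|2019-C", variate)) |>
      dplyr::mutate(environment_id = "2019-C",
                    day = as.integer(sub(".*\\|", "", variate))),
    dplyr::filter(inp$long, !grepl("^gf", variate) &
                    grepl("2019-C", variate)) |>
      dplyr::mutate(environment_id = "2019-C",
                    param = sub("\\|.*", "", variate), day = NULL),
    inp$grm,
    dplyr::filter(inp$flights, environment_id == "2019-C")
  )
  plan <- cv_plan(n_folds = 3, repeats = 1, seed = 1)
  expect_error(run_cv2(one_env, models = "GP", plan = plan),
               "at least two environments")
  few <- inp
  few$flights <- dplyr::group_by(few$flights, environment_id) |>
    dplyr::slice_head(n = 3) |> dplyr::ungroup()
  expect_error(run_cv3(few, models = "GP", plan = plan), "4 flights")
  expect_error(run_cv1(inp, models = "TGPG", plan = plan), "CV3")
})
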