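test_that("confusion-matrix metrics reproduce hand computations", {
  cm <- matrix(c(40, 5, 10, 45), 2)  # truth in rows: [[40,10],[5,45]]
  ev <- evaluate_confusion(cm)
  expect_equal(ev$accuracy, 0.85)
  # kappa by hand: p_o = 0.85, p_e = (50*45 + 50*55)/100^2 = 0.5
  expect_equal(ev$kappa, (0.85 - 0.5) / (1 - 0.5))
  # Clopper-Pearson via the beta-quantile closed form
  expect_equal(ev$ci, c(qbeta(0.025, 85, 16), qbeta(0.975, 86, 15)),
               tolerance = 1e-10)
  expect_true(ev$ci[1] <= ev$accuracy && ev$accuracy <= ev$ci[2])
  # perfect diagonal
  evp <- evaluate_confusion(diag(c(10, 20, 30)))
  expect_equal(evp$accuracy, 1)
  expect_equal(evp$kappa, 1)
  # uniform matrix over k classes -> chance agreement, kappa 0
  evu <- evaluate_confusion(matrix(5, 3, 3))
  expect_equal(evu$kappa, 0)
  # degenerate one-class matrix: kappa undefined
  expect_warning(ev1 <- evaluate_confusion(matrix(7, 1, 1)), "undefined")
  expect_true(is.na(ev1$kappa))
  expect_error(evaluate_confusion(matrix(1, 2, 3)), "square")
})

test_that("Hand-Till AUC matches the rank formulation and its bounds", {
  # two classes: equals the Wilcoxon AUC of the class-1 score
  set.seed(1)
  s1 <- runif(40, 0.4, 1)
  s2 <- runif(60, 0, 0.6)
  prob <- cbind(a = c(s1, s2), b = 1 - c(s1, s2))
  truth <- rep(c("a", "b"), c(40, 60))
  wilcox <- mean(outer(s1, s2, function(u, v)
    (u > v) + 0.5 * (u == v)))
  expect_equal(hand_till_auc(prob, truth), wilcox)
  # perfect separation
  prob2 <- cbind(a = rep(c(1, 0), c(10, 10)), b = rep(c(0, 1), c(10, 10)))
  expect_equal(hand_till_auc(prob2, rep(c("a", "b"), each = 10)), 1)
  expect_true(is.na(hand_till_auc(prob2, rep("a", 20))))
})

test_that("two separable classes are fit perfectly", {
  set.seed(2)
  n <- 200
  x <- data.frame(u = c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)),
                  v = runif(n))
  y <- rep(c("lo", "hi"), each = n / 2)
  feats <- list(x = x, y = factor(y))
  fit <- fit_biotope_model(feats, model_config(ntree_grid = 100, seed = 3))
  expect_equal(fit$accuracy, 1)
  expect_equal(fit$kappa, 1)
  expect_equal(names(fit$importance)[1], "u")
})

test_that("permuted labels give kappa near zero at n = 1000", {
  set.seed(4)
  n <- 1000
  x <- data.frame(a = runif(n), b = runif(n), c = runif(n))
  y <- factor(sample(c("p", "q", "r"), n, TRUE))  # labels independent of x
  fit <- fit_biotope_model(list(x = x, y = y),
                           model_config(ntree_grid = 100,
                                        mtry_grid = 2, seed = 5))
  expect_lt(abs(fit$kappa), 0.1)
})

test_that("the 70/30 split is disjoint, exhaustive and untouched by resampling", {
  set.seed(6)
  n <- 300
  x <- data.frame(a = runif(n), b = runif(n))
  y <- factor(sample(c("x", "y", "z"), n, TRUE, prob = c(0.7, 0.2, 0.1)))
  for (how in c("none", "downsample", "upsample", "balanced", "smote")) {
    fit <- fit_biotope_model(list(x = x, y = y),
                             model_config(ntree_grid = 50, imbalance = how,
                                          seed = 7))
    tr <- fit$split$train
    te <- fit$split$test
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), seq_len(n))
    expect_lte(abs(length(tr) - 0.7 * n), 1)
    expect_equal(sum(fit$confusion), length(te))
  }
})

test_that("fits are deterministic for a fixed seed", {
  set.seed(8)
  n <- 150
  x <- data.frame(a = runif(n), b = runif(n))
  y <- factor(ifelse(x$a + 0.2 * rnorm(n) > 0.5, "hi", "lo"))
  f1 <- fit_biotope_model(list(x = x, y = y),
                          model_config(ntree_grid = c(50, 100), seed = 9))
  f2 <- fit_biotope_model(list(x = x, y = y),
                          model_config(ntree_grid = c(50, 100), seed = 9))
  expect_identical(f1$confusion, f2$confusion)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$hyperparameters, f2$hyperparameters)
})

test_that("feature matrices respect realm rules and centre sampling", {
  cfg <- tiny_config(seed = 11)
  sim <- simulate_seascape(cfg)
  lab <- assign_hub_labels(sim$stations, sim$records)
  stn <- cbind(sim$stations, h = lab$harmonized_label)
  grabs <- stn[stn$method == "grab", ]
  fe <- build_feature_matrix(grabs, "h", sim$env, sim$sediment, "endo")
  expect_false(any(c("slope", "par") %in% names(fe$x)))
  expect_true("sediment" %in% names(fe$x))
  expect_equal(nrow(fe$x), nrow(grabs))
  # predictor values are the containing cell's values
  i <- 1
  expect_equal(fe$x$salinity[i],
               sim$env$layers$salinity[grabs$row[i], grabs$col[i]])
  # epi realm: slope/par/photic in, restricted to hard cells
  counts <- grid_boulder_counts(sim$boulders, cfg$geom)
  hard <- hard_substrate_mask(classify_boulder_density(counts),
                              sim$sediment, cfg$geom)
  vids <- stn[stn$method == "video", ]
  fep <- build_feature_matrix(vids, "h", sim$env, sim$sediment, "epi",
                              hard = hard)
  expect_true(all(c("slope", "par", "photic") %in% names(fep$x)))
  expect_true(all(hard[cbind(fep$cells$row, fep$cells$col)]))
  # empty station set -> empty matrix, no crash
  fe0 <- build_feature_matrix(grabs[0, ], character(0), sim$env,
                              sim$sediment, "endo")
  expect_equal(nrow(fe0$x), 0)
})

test_that("grid predictions pair every token with a probability", {
  cfg <- tiny_config(seed = 12, biomass_theta = 0)
  sim <- simulate_seascape(cfg)
  lab <- assign_hub_labels(sim$stations, sim$records)
  stn <- cbind(sim$stations, h = lab$harmonized_label)
  grabs <- stn[stn$method == "grab" & !lab$excluded, ]
  fe <- build_feature_matrix(grabs, "h", sim$env, sim$sediment, "endo")
  fit <- fit_biotope_model(fe, model_config(ntree_grid = 100, seed = 13))
  pred <- predict_grid(fit, sim$env, sim$sediment, "endo")
  expect_identical(is.na(pred$token), is.na(pred$probability))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1,
                  na.rm = TRUE))
  # a cell deep inside a pure training condition is predicted confidently
  expect_gt(stats::median(pred$probability, na.rm = TRUE), 0.67)
  # missing predictor propagates NA
  env2 <- sim$env
  env2$layers$salinity[1, 1] <- NA
  pred2 <- predict_grid(fit, env2, sim$sediment, "endo")
  expect_true(is.na(pred2$token[1, 1]))
})
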