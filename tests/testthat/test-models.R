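test_that("reference model scores match the closed-form discriminant", {
  m <- referenceNetNetModel()
  zero <- as.data.frame(as.list(setNames(rep(0, 24), mtFeatureNames())),
                        check.names = FALSE)
  expect_equal(scoreRecords(m, zero), -0.8263)

  # worked example: Sh_3_i = Sh_3_j = annSh_3 = 1, everything else zero
  rec <- zero
  rec$Sh_3_i <- 1; rec$Sh_3_j <- 1; rec$annSh_3 <- 1
  expect_equal(scoreRecords(m, rec), 15.69 + 13.79 - 0.014 - 0.8263,
               tolerance = 1e-12)

  # independent dot-product oracle, term by term, on random vectors
  set.seed(42)
  for (r in 1:100) {
    x <- setNames(rnorm(24), mtFeatureNames())
    oracle <- -42.38 * x["Sh_0_i"] + 15.69 * x["Sh_3_i"] -
      44.95 * x["Sh_0_j"] + 13.79 * x["Sh_3_j"] -
      0.014 * x["annSh_3"] - 0.8263
    expect_equal(scoreRecords(m, as.data.frame(as.list(x),
                                               check.names = FALSE)),
                 unname(oracle), tolerance = 1e-10)
  }
})

test_that("reference model has exactly the five published features", {
  cf <- modelCoefficients(referenceNetNetModel())
  nz <- cf[cf != 0 & names(cf) != "e0"]
  expect_length(nz, 5L)
  expect_equal(unname(cf["a_0"]), -42.38)
  expect_true(all(cf[paste0("c_", 0:5)] == 0))   # no difference terms
  expect_equal(fittedStats(referenceNetNetModel())$n, 235540L)
})

test_that("linear score is linear and the boundary sits at zero", {
  m <- referenceNetNetModel()
  set.seed(1)
  x <- syntheticMtTable(10, seed = 1)[, mtFeatureNames()]
  y <- syntheticMtTable(10, seed = 2)[, mtFeatureNames()]
  sX <- scoreRecords(m, x); sY <- scoreRecords(m, y)
  sXY <- scoreRecords(m, x + y)
  expect_equal(sXY - sY, sX - m@intercept, tolerance = 1e-9)
  expect_equal(classifyRecords(m, x), as.integer(sX >= 0))
})

test_that("fitLda separates Gaussian clouds and matches MASS::lda direction", {
  set.seed(10)
  n <- 400
  x <- matrix(rnorm(n * 24), n, 24, dimnames = list(NULL, mtFeatureNames()))
  y <- rep(0:1, each = n / 2)
  x[y == 1, 1:4] <- x[y == 1, 1:4] + 2.5
  tbl <- data.frame(x, P_ann_Aij = y, check.names = FALSE)
  model <- fitLda(tbl)
  acc <- mean(classifyRecords(model, tbl) == y)
  expect_gt(acc, 0.95)
  st <- fittedStats(model)
  expect_gt(st$chisq, 0)
  expect_lt(st$p, 1e-6)

  # independent oracle: MASS::lda scaling is proportional to our direction
  fit <- MASS::lda(x, grouping = y)
  w <- c(model@coefI, model@coefJ, model@coefD, model@coefAnn)
  cosine <- abs(sum(w * fit$scaling)) /
    sqrt(sum(w^2) * sum(fit$scaling^2))
  expect_gt(cosine, 0.9999)
})

test_that("fitLda on permuted labels is at chance; ridge path on collinearity", {
  set.seed(30)
  tbl <- syntheticMtTable(600, seed = 30)    # labels independent of features
  model <- fitLda(tbl)
  acc <- mean(classifyRecords(model, tbl) == tbl$P_ann_Aij)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 600) + 0.05)

  # duplicated feature column (exact collinearity) triggers the ridge refit
  dup <- tbl
  dup$Sh_1_j <- dup$Sh_1_i
  expect_warning(mdup <- fitLda(dup), "ridge")
  expect_s4_class(mdup, "LinearNetNetModel")
  expect_gt(fittedStats(mdup)$ridge, 0)
})

test_that("linear model JSON round trip preserves coefficients", {
  set.seed(77)
  tbl <- syntheticMtTable(200, w = rnorm(24), seed = 77)
  model <- fitLda(tbl)
  f <- withr::local_tempfile(fileext = ".json")
  writeLinearModel(model, f)
  back <- readLinearModel(f)
  expect_equal(modelCoefficients(back), modelCoefficients(model))
  expect_equal(scoreRecords(back, tbl[1:5, ]), scoreRecords(model, tbl[1:5, ]))
})

test_that("classifier menu: coverage, deep shape, smoke round trips", {
  menu <- classifierMenu(seed = 1)
  expect_gte(length(menu), 10L)
  expect_true(all(c("lda", "logistic", "naive_bayes", "decision_tree",
                    "random_forest", "bagging", "boosting", "mlp_1h",
                    "mlp_2h", "deep_fc") %in% names(menu)))

  deep <- menu$deep_fc(n = 200L, epochs = 1L)
  expect_equal(deep$name, "deep_fc")
  tiny <- syntheticMtTable(40, w = c(rep(1, 4), rep(0, 20)), seed = 2)
  fitted <- deep$fit(as.matrix(tiny[, mtFeatureNames()]), tiny$P_ann_Aij)
  expect_equal(fitted$sizes, c(24L, 200L, 400L, 200L, 1L))

  tbl <- syntheticMtTable(200, w = c(rep(2, 6), rep(0, 18)), seed = 3)
  x <- as.matrix(tbl[, mtFeatureNames()]); y <- tbl$P_ann_Aij
  cfgs <- list(lda = menu$lda(), logistic = menu$logistic(),
               naive_bayes = menu$naive_bayes(),
               decision_table = menu$decision_table(),
               decision_tree = menu$decision_tree(),
               random_forest = menu$random_forest(ntree = 50),
               bagging = menu$bagging(nbag = 5),
               boosting = menu$boosting(nrounds = 5),
               mlp_1h = menu$mlp_1h(size = 5, maxit = 50),
               mlp_2h = menu$mlp_2h(epochs = 40, batchSize = 32),
               deep_fc = menu$deep_fc(n = 16, epochs = 30, dropout = 0.1,
                                      batchSize = 32))
  for (nm in names(cfgs)) {
    clf <- cfgs[[nm]]
    s <- clf$predict(clf$fit(x, y), x)
    expect_length(s, nrow(x))
    expect_true(all(s >= 0 & s <= 1), label = paste(nm, "scores in [0,1]"))
    # a strongly separable signal should be learned well above chance
    expect_gt(auroc(y, s), 0.7, label = paste(nm, "training AUROC"))
  }
  expect_null(menu$no_such_classifier)
})

test_that("in-package MLP learns a separable rule and is seed-deterministic", {
  set.seed(4)
  x <- matrix(rnorm(600 * 5), 600, 5)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  m1 <- mlpTrain(x, y, hidden = c(8, 4), epochs = 40, seed = 11)
  m2 <- mlpTrain(x, y, hidden = c(8, 4), epochs = 40, seed = 11)
  expect_identical(mlpPredict(m1, x), mlpPredict(m2, x))
  expect_gt(auroc(y, mlpPredict(m1, x)), 0.9)
  # dropout training still yields usable deterministic scores
  m3 <- mlpTrain(x, y, hidden = c(8), epochs = 40, dropout = 0.3, seed = 11)
  expect_gt(auroc(y, mlpPredict(m3, x)), 0.8)
})
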