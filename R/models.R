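# Two-group linear discriminant on a plain feature matrix. Returns the
# discriminant direction w and intercept b such that the boundary is
# w.x + b = 0 (classify 1 iff >= 0), plus Wilks Lambda / Bartlett chi2.
# Singular pooled covariance (e.g. the exactly collinear dSh columns of an
# mt table) triggers an escalating ridge with a warning.
.ldaTrain <- function(x, y, priors = c(0.5, 0.5)) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  n <- nrow(x); p <- ncol(x); g <- 2L
  if (n < p + 2L) stop("need at least p + 2 rows to fit the discriminant")
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  c0 <- sweep(x[y == 0L, , drop = FALSE], 2L, m0)
  c1 <- sweep(x[y == 1L, , drop = FALSE], 2L, m1)
  W <- crossprod(c0) + crossprod(c1)          # within-class scatter
  Sw <- W / (n - g)
  ridge <- 0
  wvec <- tryCatch(solve(Sw, m1 - m0), error = function(e) NULL)
  if (is.null(wvec) || rcond(Sw) < 1e-12) {
    ridge <- 1e-8 * mean(diag(Sw))
    if (ridge <= 0) ridge <- 1e-8
    repeat {
      SwR <- Sw + diag(ridge, p)
      wvec <- tryCatch(solve(SwR, m1 - m0), error = function(e) NULL)
      if (!is.null(wvec)) break
      ridge <- ridge * 10
    }
    warning("singular within-class covariance; ridge-regularized fit (ridge = ",
            format(ridge), ")")
  }
  b <- -sum(wvec * (m1 + m0)) / 2 + log(priors[2L] / priors[1L])
  mAll <- colMeans(x)
  ng <- c(sum(y == 0L), sum(y == 1L))
  B <- ng[1L] * tcrossprod(m0 - mAll) + ng[2L] * tcrossprod(m1 - mAll)
  WR <- W + diag(ridge * (n - g), p)
  ldW <- determinant(WR, logarithm = TRUE)$modulus
  ldT <- determinant(WR + B, logarithm = TRUE)$modulus
  logLambda <- as.numeric(ldW - ldT)
  chisq <- -(n - 1 - (p + g) / 2) * logLambda   # Bartlett's approximation
  df <- p * (g - 1L)
  pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  list(w = as.numeric(wvec), b = b,
       stats = list(n = n, chisq = chisq, p = pval,
                    wilksLambda = exp(logLambda), df = df, ridge = ridge))
}

#' Fit the linear Net-Net discriminant on an mt table
#'
#' Two-class linear discriminant analysis over the 24 mt features (18
#' pair-entropy features + 6 topology descriptors), with equal priors by
#' default, the decision boundary at score 0, and Bartlett's chi-square
#' approximation from Wilks' Lambda as the fit statistic. Because the dSh
#' columns are exact differences of the Sh columns, the within-class
#' covariance of a full mt table is singular; the fit then proceeds through
#' an escalating ridge with a warning.
#'
#' @param train an mt table from [buildMt()] (needs the
#'   [mtFeatureNames()] columns and `P_ann_Aij`), or any data.frame with
#'   those columns.
#' @param priors class prior probabilities `c(p0, p1)`; "proportional" uses
#'   the empirical frequencies.
#' @return a [LinearNetNetModel-class].
#' @export
fitLda <- function(train, priors = c(0.5, 0.5)) {
  feats <- mtFeatureNames()
  missing <- setdiff(feats, names(train))
  if (length(missing))
    stop("mt table is missing feature columns: ",
         paste(missing, collapse = ", "))
  y <- train$P_ann_Aij
  if (is.null(y)) stop("mt table is missing the meta-label column P_ann_Aij")
  if (identical(priors, "proportional"))
    priors <- c(mean(y == 0L), mean(y == 1L))
  res <- .ldaTrain(as.matrix(train[, feats]), y, priors = priors)
  w <- res$w
  new("LinearNetNetModel",
      coefI = w[1:6], coefJ = w[7:12], coefD = w[13:18], coefAnn = w[19:24],
      intercept = res$b, fittedStats = res$stats)
}

#' Score meta-records with a linear Net-Net model
#'
#' \eqn{S = \sum_k a_k Sh_{ki} + \sum_k b_k Sh_{kj} + \sum_k c_k \Delta
#' Sh_{kij} + \sum_k d_k {}^{ANN}Sh_k + e_0}, evaluated row-wise.
#' Classification is 1 iff `S >= 0`.
#'
#' @param model a [LinearNetNetModel-class].
#' @param records a data.frame with the 24 [mtFeatureNames()] columns.
#' @return numeric vector of scores S.
#' @seealso [classifyRecords()]
#' @export
scoreRecords <- function(model, records) {
  stopifnot(is(model, "LinearNetNetModel"))
  feats <- mtFeatureNames()
  missing <- setdiff(feats, names(records))
  if (length(missing))
    stop("records are missing features: ", paste(missing, collapse = ", "))
  x <- as.matrix(records[, feats])
  w <- c(model@coefI, model@coefJ, model@coefD, model@coefAnn)
  as.numeric(x %*% w) + model@intercept
}

#' @rdname scoreRecords
#' @return `classifyRecords`: integer 0/1 predictions (1 iff S >= 0).
#' @export
classifyRecords <- function(model, records) {
  as.integer(scoreRecords(model, records) >= 0)
}

#' The frozen published linear Net-Net model
#'
#' The reference five-feature discriminant reported for the original
#' 69-food-web study, carried verbatim: nonzero coefficients
#' `a_0 = -42.38`, `a_3 = 15.69` (node i), `b_0 = -44.95`, `b_3 = 13.79`
#' (node j), `d_3 = -0.014` (topology), intercept `e_0 = -0.8263`; all 19
#' other coefficients zero. The published fit statistics (n = 235540,
#' chi-square = 56326.2, p < 0.001) are attached as metadata. This model is
#' a fixture for scoring published-convention descriptors — it is not
#' refitted by the package.
#'
#' @return a [LinearNetNetModel-class].
#' @examples
#' m <- referenceNetNetModel()
#' rec <- as.data.frame(as.list(setNames(rep(0, 24), mtFeatureNames())))
#' scoreRecords(m, rec)   # the free term, -0.8263
#' @export
referenceNetNetModel <- function() {
  new("LinearNetNetModel",
      coefI = c(-42.38, 0, 0, 15.69, 0, 0),
      coefJ = c(-44.95, 0, 0, 13.79, 0, 0),
      coefD = rep(0, 6),
      coefAnn = c(0, 0, 0, -0.014, 0, 0),
      intercept = -0.8263,
      fittedStats = list(n = 235540L, chisq = 56326.2, p = "<0.001"))
}

#' Serialize / restore a linear model as flat JSON
#'
#' Writes the 25 coefficients by name (a_0..a_5, b_0..b_5, c_0..c_5,
#' d_0..d_5, e0) plus the fit statistics.
#'
#' @param model a [LinearNetNetModel-class].
#' @param path JSON file path.
#' @return `writeLinearModel`: `path` invisibly; `readLinearModel`: the
#'   model.
#' @export
writeLinearModel <- function(model, path) {
  cf <- modelCoefficients(model)
  jsonlite::write_json(list(coefficients = as.list(cf),
                            stats = fittedStats(model)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLinearModel
#' @export
readLinearModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf <- unlist(doc$coefficients)
  k <- 0:5
  new("LinearNetNetModel",
      coefI = as.numeric(cf[paste0("a_", k)]),
      coefJ = as.numeric(cf[paste0("b_", k)]),
      coefD = as.numeric(cf[paste0("c_", k)]),
      coefAnn = as.numeric(cf[paste0("d_", k)]),
      intercept = as.numeric(cf[["e0"]]),
      fittedStats = as.list(doc$stats))
}

#' Menu of meta-classifier builders
#'
#' Named builders for the meta-classifier families compared against the
#' linear baseline: each builder returns a list with `name`, `fit(x, y)` and
#' `predict(fitted, x)` (scores in \[0, 1\]), so all entries are
#' interchangeable in evaluation loops. Hyperparameters follow the original
#' study's settings mapped to their nearest equivalent here (e.g. boosting
#' via gradient-boosted trees with 10 rounds, a 500-tree random forest, an
#' 18-9 two-hidden-layer perceptron, and a deep fully-connected n-(2n)-n net
#' with n = 200 and dropout 0.5); behavioural equivalence with the original
#' tools is not promised.
#'
#' @param seed RNG seed applied inside each `fit`.
#' @return named list of builder functions; each builder accepts
#'   hyperparameter overrides.
#' @examples
#' menu <- classifierMenu(seed = 1)
#' names(menu)
#' @export
classifierMenu <- function(seed = 1L) {
  sigm <- function(z) 1 / (1 + exp(-z))
  wrap <- function(name, fit, predict) list(name = name, fit = fit,
                                            predict = predict)
  asXY <- function(x) { x <- as.matrix(x); storage.mode(x) <- "double"; x }
  list(
    lda = function(...) wrap("lda",
      fit = function(x, y) .ldaTrain(asXY(x), y, ...),
      predict = function(f, x) sigm(as.numeric(asXY(x) %*% f$w) + f$b)),
    logistic = function(maxit = 100L) wrap("logistic",
      fit = function(x, y) {
        suppressWarnings(stats::glm.fit(cbind(1, asXY(x)), y,
          family = stats::binomial(),
          control = list(maxit = maxit))$coefficients)
      },
      predict = function(f, x) {
        f[!is.finite(f)] <- 0
        sigm(as.numeric(cbind(1, asXY(x)) %*% f))
      }),
    naive_bayes = function(...) wrap("naive_bayes",
      fit = function(x, y) e1071::naiveBayes(as.data.frame(asXY(x)),
                                             factor(y, levels = 0:1), ...),
      predict = function(f, x)
        stats::predict(f, as.data.frame(asXY(x)), type = "raw")[, "1"]),
    decision_table = function(maxdepth = 3L, ...) wrap("decision_table",
      fit = function(x, y) rpart::rpart(y ~ ., data.frame(y = factor(y), x),
        method = "class", control = rpart::rpart.control(maxdepth = maxdepth,
                                                         ...)),
      predict = function(f, x)
        stats::predict(f, data.frame(x), type = "prob")[, "1"]),
    decision_tree = function(...) wrap("decision_tree",
      fit = function(x, y) rpart::rpart(y ~ ., data.frame(y = factor(y), x),
                                        method = "class", ...),
      predict = function(f, x)
        stats::predict(f, data.frame(x), type = "prob")[, "1"]),
    random_forest = function(ntree = 500L, ...) wrap("random_forest",
      fit = function(x, y) {
        set.seed(seed)
        randomForest::randomForest(asXY(x), factor(y, levels = 0:1),
                                   ntree = ntree, ...)
      },
      predict = function(f, x)
        stats::predict(f, asXY(x), type = "prob")[, "1"]),
    bagging = function(nbag = 10L, ...) wrap("bagging",
      fit = function(x, y) {
        set.seed(seed)
        df <- data.frame(y = factor(y), x)
        lapply(seq_len(nbag), function(b)
          rpart::rpart(y ~ ., df[sample.int(nrow(df), replace = TRUE), ],
                       method = "class", ...))
      },
      predict = function(f, x) {
        probs <- vapply(f, function(tree)
          stats::predict(tree, data.frame(x), type = "prob")[, "1"],
          numeric(nrow(as.matrix(x))))
        rowMeans(as.matrix(probs))
      }),
    boosting = function(nrounds = 10L, maxDepth = 3L, eta = 0.3)
      wrap("boosting",
        fit = function(x, y) {
          set.seed(seed)
          xgboost::xgb.train(
            params = list(objective = "binary:logistic",
                          max_depth = maxDepth, eta = eta, nthread = 1L),
            data = xgboost::xgb.DMatrix(asXY(x), label = y),
            nrounds = nrounds, verbose = 0)
        },
        predict = function(f, x)
          stats::predict(f, xgboost::xgb.DMatrix(asXY(x)))),
    mlp_1h = function(size = 13L, maxit = 200L, decay = 1e-4) wrap("mlp_1h",
      fit = function(x, y) {
        set.seed(seed)
        nnet::nnet(asXY(x), y, size = size, decay = decay, maxit = maxit,
                   trace = FALSE)
      },
      predict = function(f, x) as.numeric(stats::predict(f, asXY(x)))),
    mlp_2h = function(hidden = c(18L, 9L), epochs = 50L, ...) wrap("mlp_2h",
      fit = function(x, y) mlpTrain(asXY(x), y, hidden = hidden,
                                    epochs = epochs, seed = seed, ...),
      predict = function(f, x) mlpPredict(f, asXY(x))),
    deep_fc = function(n = 200L, epochs = 50L, dropout = 0.5,
                       batchSize = 4096L, ...) wrap("deep_fc",
      fit = function(x, y) mlpTrain(asXY(x), y, hidden = c(n, 2L * n, n),
                                    epochs = epochs, dropout = dropout,
                                    batchSize = batchSize, seed = seed, ...),
      predict = function(f, x) mlpPredict(f, asXY(x)))
  )
}
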