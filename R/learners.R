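# Candidate learner wrappers: a uniform fit/predict-probability surface over
# glmnet (RLR), ranger (RF), e1071 (SVM) and xgboost (XGB). Inputs are
# standardized numeric matrices; outputs are event probabilities. Every fit
# is wrapped in a derived seed so the whole ensemble is reproducible from
# one master seed.

learner_ids <- function() c("rlr", "rf", "svm", "xgb")

# published-default search spaces, random-sampled to <= grid_size points
learner_grid <- function(learner, grid_size = 25, seed = 1L) {
  full <- switch(learner,
    rlr = tidyr::expand_grid(alpha = c(0, 0.25, 0.5, 0.75, 1),
                             lambda = 10^seq(-4, 0, length.out = 5)),
    rf = tidyr::expand_grid(mtry_frac = c(0.1, 0.25, 0.5, 0.75, 1),
                            min_node = c(1, 5, 10, 20, 40),
                            num_trees = 300),
    svm = tidyr::expand_grid(cost = 2^seq(-2, 6, by = 2),
                             gamma = 2^seq(-8, 0, by = 2)),
    xgb = tidyr::expand_grid(eta = c(0.05, 0.1, 0.3),
                             max_depth = c(2, 4, 6),
                             nrounds = c(50, 150),
                             subsample = c(0.7, 1),
                             colsample = 0.8),
    abort(sprintf("unknown learner '%s'", learner))
  )
  if (nrow(full) <= grid_size) return(full)
  withr::with_seed(derive_seed(seed, paste0("grid-", learner)), {
    full[sample(nrow(full), grid_size), ]
  })
}

fit_learner <- function(learner, x, y, params, seed = 1L) {
  stopifnot(is.matrix(x), is.logical(y))
  fit <- withr::with_seed(derive_seed(seed, paste0("fit-", learner)), {
    switch(learner,
      rlr = glmnet::glmnet(x, factor(y), family = "binomial",
                           alpha = params$alpha, lambda = params$lambda),
      rf = ranger::ranger(
        x = x, y = factor(y), probability = TRUE,
        num.trees = params$num_trees,
        mtry = max(1L, floor(params$mtry_frac * ncol(x))),
        min.node.size = params$min_node,
        seed = derive_seed(seed, "ranger"), num.threads = 1
      ),
      svm = fit_svm_calibrated(x, y, params),
      xgb = xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta, max_depth = params$max_depth,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = as.numeric(y)),
        nrounds = params$nrounds, verbose = 0
      ),
      abort(sprintf("unknown learner '%s'", learner))
    )
  })
  structure(list(learner = learner, fit = fit, params = params,
                 features = colnames(x)),
            class = "fgi_learner_fit")
}

# SVM probabilities via our own Platt-style calibration of decision values
# (a logistic fit on the training decision values), which is deterministic.
fit_svm_calibrated <- function(x, y, params) {
  m <- e1071::svm(x, factor(y), kernel = "radial", cost = params$cost,
                  gamma = params$gamma, scale = FALSE, probability = FALSE)
  dec <- as.numeric(attr(predict(m, x, decision.values = TRUE),
                         "decision.values"))
  calib <- suppressWarnings(
    glm(y ~ dec, family = binomial(), data = data.frame(y = y, dec = dec))
  )
  list(svm = m, calib_coef = coef(calib))
}

predict_learner <- function(object, x) {
  stopifnot(inherits(object, "fgi_learner_fit"), is.matrix(x))
  switch(object$learner,
    rlr = as.numeric(predict(object$fit, x, type = "response",
                             s = object$params$lambda)),
    rf = {
      p <- predict(object$fit, data = x, num.threads = 1)$predictions
      as.numeric(p[, "TRUE"])
    },
    svm = {
      dec <- as.numeric(attr(
        predict(object$fit$svm, x, decision.values = TRUE),
        "decision.values"))
      plogis(object$fit$calib_coef[1] + object$fit$calib_coef[2] * dec)
    },
    xgb = as.numeric(predict(object$fit, x))
  )
}
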