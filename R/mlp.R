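# Classification stage: SMOTE minority oversampling, a three-layer MLP
# (tanh hidden layer, logistic output) trained on a convex blend of
# cross-entropy and weight decay, hyper-parameter grid search with
# stratified cross-validation, and ROC-based operating-threshold selection.

#' SMOTE synthetic minority oversampling
#'
#' For every minority sample u, one synthetic point is placed on the segment
#' to each of its k nearest minority neighbors v (Euclidean distance):
#' w = u + c (v - u), c ~ U(0, 1). Yields exactly k * m synthetic rows.
#'
#' @param minority numeric matrix (m x p) of minority-class samples, m > k.
#' @param k number of neighbors; @param seed RNG seed.
#' @return (k * m) x p matrix with attribute `"draws"` recording (u, v, c)
#'   for every synthetic row.
#' @export
smoteOversample <- function(minority, k = 5, seed = 1) {
  minority <- as.matrix(minority)
  m <- nrow(minority)
  if (k < 1) stop("k must be >= 1")
  if (m <= k) stop("need more minority samples than neighbors (m > k)")
  DD <- as.matrix(dist(minority))
  diag(DD) <- Inf
  out <- matrix(NA_real_, k * m, ncol(minority))
  colnames(out) <- colnames(minority)
  draws <- data.frame(u = integer(k * m), v = integer(k * m),
                      c = numeric(k * m))
  withSeed(seed, {
    row <- 0
    for (i in seq_len(m)) {
      nb <- order(DD[i, ])[seq_len(k)]
      for (j in nb) {
        row <- row + 1
        cc <- runif(1)
        out[row, ] <- minority[i, ] + cc * (minority[j, ] - minority[i, ])
        draws$u[row] <- i; draws$v[row] <- j; draws$c[row] <- cc
      }
    }
  })
  attr(out, "draws") <- draws
  out
}

# --- MLP internals -----------------------------------------------------

mlpUnpack <- function(theta, p, h) {
  list(W1 = matrix(theta[seq_len(p * h)], p, h),
       b1 = theta[p * h + seq_len(h)],
       w2 = theta[p * h + h + seq_len(h)],
       b2 = theta[p * h + 2 * h + 1])
}

mlpForward <- function(w, X) {
  Z <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  o <- plogis(as.vector(Z %*% w$w2) + w$b2)
  list(Z = Z, o = pmin(pmax(o, 1e-12), 1 - 1e-12))
}

mlpObjective <- function(X, y, p, h, eta) {
  nw <- p * h + h  # weight count excluding biases
  n <- nrow(X)
  fn <- function(theta) {
    w <- mlpUnpack(theta, p, h)
    fw <- mlpForward(w, X)
    ce <- -mean(y * log(fw$o) + (1 - y) * log(1 - fw$o))
    reg <- (sum(w$W1^2) + sum(w$w2^2)) / nw
    (1 - eta) * ce + eta * reg
  }
  gr <- function(theta) {
    w <- mlpUnpack(theta, p, h)
    fw <- mlpForward(w, X)
    d <- (fw$o - y) / n                    # d(CE)/d(output logit)
    gw2 <- as.vector(crossprod(fw$Z, d))
    gb2 <- sum(d)
    dZ <- (d %o% w$w2) * (1 - fw$Z^2)
    gW1 <- crossprod(X, dZ)
    gb1 <- colSums(dZ)
    g <- c(as.vector(gW1), gb1, gw2, gb2) * (1 - eta)
    reg <- c(as.vector(w$W1), rep(0, h), w$w2, 0) * (2 * eta / nw)
    g + reg
  }
  list(fn = fn, gr = gr)
}

#' Train the three-layer MLP
#'
#' tanh hidden layer, logistic output neuron, loss
#' E = (1 - eta) * CE + eta * mean(w^2) (cross-entropy blended with weight
#' decay over the non-bias weights), minimized by BFGS from a seeded random
#' initialization. Deterministic given the seed; the recorded loss trace is
#' non-increasing.
#'
#' @param X numeric matrix of standardized features; @param y binary 0/1.
#' @param nHidden hidden-layer width; @param eta regularization weight in
#'   \[0, 1); @param seed RNG seed; @param maxit total BFGS iterations.
#' @return list of class `"retiqaMlp"` with weights, `eta` and `trace`.
#' @export
trainMlp <- function(X, y, nHidden, eta = 0, seed = 1, maxit = 400) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (eta < 0 || eta >= 1) stop("eta must lie in [0, 1)")
  p <- ncol(X); h <- as.integer(nHidden)
  np <- p * h + 2 * h + 1
  theta <- withSeed(seed, rnorm(np, sd = 0.5 / sqrt(p + 1)))
  obj <- mlpObjective(X, y, p, h, eta)
  segments <- 4
  trace <- obj$fn(theta)
  for (sgm in seq_len(segments)) {
    opt <- optim(theta, obj$fn, obj$gr, method = "BFGS",
                 control = list(maxit = ceiling(maxit / segments),
                                reltol = 1e-10))
    theta <- opt$par
    trace <- c(trace, opt$value)
  }
  w <- mlpUnpack(theta, p, h)
  structure(list(W1 = w$W1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
                 nHidden = h, eta = eta, trace = cummin(trace),
                 seed = as.integer(seed)),
            class = "retiqaMlp")
}

#' MLP output scores
#'
#' @param fit a `"retiqaMlp"` fit; @param X standardized feature matrix.
#' @return scores strictly inside (0, 1).
#' @export
predictMlp <- function(fit, X) {
  mlpForward(fit, as.matrix(X))$o
}

stratifiedFolds <- function(y, folds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds)
        stop("fewer samples than folds in a class")
      fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold
}

standardizeFit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

standardizeApply <- function(X, st) {
  sweep(sweep(as.matrix(X), 2, st$center, "-"), 2, st$scale, "/")
}

# Augment a standardized training set with SMOTE minority synthetics
# (k per minority sample) when the minority is large enough.
smoteAugment <- function(X, y, k, seed) {
  tab <- table(factor(y, levels = c(0, 1)))
  minLab <- as.integer(names(tab)[which.min(tab)])
  mi <- which(y == minLab)
  if (length(mi) > k) {
    syn <- smoteOversample(X[mi, , drop = FALSE], k = k, seed = seed)
    X <- rbind(X, syn)
    y <- c(y, rep(minLab, nrow(syn)))
  }
  list(X = X, y = y)
}

#' Hyper-parameter grid search with stratified cross-validation
#'
#' Estimates validation accuracy (threshold 0.5) for every combination of
#' hidden-layer width and regularization weight using stratified k-fold
#' cross-validation; SMOTE oversampling is applied inside each training
#' fold only, never to the validation fold.
#'
#' @param X feature matrix; @param y binary 0/1 labels.
#' @param hiddenGrid,etaGrid candidate values.
#' @param folds number of folds; @param seed RNG seed;
#' @param smoteK SMOTE neighbors; @param maxit BFGS iterations per fit.
#' @return list with `nHidden`, `eta` (the accuracy argmax; ties go to the
#'   smaller width, then smaller eta) and the per-combination `cvTable`.
#' @export
gridSearchCv <- function(X, y, hiddenGrid = c(5, 10, 21),
                         etaGrid = c(0, 0.1), folds = 10, seed = 1,
                         smoteK = 5, maxit = 300) {
  X <- as.matrix(X)
  fold <- stratifiedFolds(y, folds, seed)
  grid <- expand.grid(eta = etaGrid, nHidden = hiddenGrid)[, 2:1]
  acc <- matrix(NA_real_, nrow(grid), folds)
  seeds <- spawnSeeds(seed + 7, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    st <- standardizeFit(X[tr, , drop = FALSE])
    Xtr <- standardizeApply(X[tr, , drop = FALSE], st)
    Xva <- standardizeApply(X[!tr, , drop = FALSE], st)
    aug <- smoteAugment(Xtr, y[tr], smoteK, seeds[f])
    for (g in seq_len(nrow(grid))) {
      fit <- trainMlp(aug$X, aug$y, grid$nHidden[g], grid$eta[g],
                      seed = seeds[f] + g, maxit = maxit)
      pred <- as.integer(predictMlp(fit, Xva) > 0.5)
      acc[g, f] <- mean(pred == y[!tr])
    }
  }
  cvTable <- cbind(grid, accuracy = rowMeans(acc))
  best <- which.max(cvTable$accuracy)  # first max: smaller width, then eta
  list(nHidden = grid$nHidden[best], eta = grid$eta[best], cvTable = cvTable)
}

#' Operating threshold from the ROC curve
#'
#' Returns the threshold whose (FPR, TPR) point is closest (Euclidean) to
#' the ideal corner (0, 1); candidate thresholds are midpoints between
#' consecutive unique scores (plus one below the minimum and one above the
#' maximum), so a perfectly separating classifier gets the midpoint between
#' the class score extremes. Ties are broken toward higher TPR, then lower
#' threshold. Prediction is positive when score > threshold (strict).
#'
#' @param scores classifier outputs; @param labels binary 0/1 (1 positive).
#' @return the selected threshold.
#' @export
selectThresholdRoc <- function(scores, labels) {
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  us <- sort(unique(scores))
  gap <- if (length(us) > 1) diff(range(us)) / 2 else 0.5
  cand <- c(us[1] - gap,
            if (length(us) > 1) (us[-1] + us[-length(us)]) / 2,
            us[length(us)] + gap)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  best <- NULL
  for (th in cand) {
    pred <- scores > th
    tpr <- sum(pred & labels == 1) / npos
    fpr <- sum(pred & labels == 0) / nneg
    d <- sqrt(fpr^2 + (1 - tpr)^2)
    if (is.null(best) || d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 &&
         (tpr > best$tpr + 1e-12 ||
          (abs(tpr - best$tpr) <= 1e-12 && th < best$th)))) {
      best <- list(d = d, tpr = tpr, th = th)
    }
  }
  best$th
}

#' Train the full quality classifier
#'
#' Standardizes the selected features, balances the classes with SMOTE
#' (k synthetic points per minority sample), optionally grid-searches the
#' hyper-parameters, trains the MLP on the augmented set, and selects the
#' operating threshold as the training-ROC point closest to (0, 1).
#'
#' @param features data.frame/matrix with named feature columns.
#' @param labels binary 0/1 (1 = adequate quality, the positive class).
#' @param selection a [SelectionResult-class] or character vector of feature
#'   names to use.
#' @param nHidden,eta hyper-parameters (used when `grid` is NULL).
#' @param grid optional list(hidden = ..., eta = ...) to cross-validate.
#' @param folds CV folds for the grid search; @param smoteK SMOTE neighbors;
#' @param seed RNG seed; @param maxit BFGS iterations;
#' @param referenceModel optional [NSSModel-class] stored with the model.
#' @return a [TrainedQualityModel-class].
#' @export
trainQualityModel <- function(features, labels, selection, nHidden = 21,
                              eta = 0.1, grid = NULL, folds = 10,
                              smoteK = 5, seed = 1, maxit = 400,
                              referenceModel = NULL) {
  sel <- if (is(selection, "SelectionResult")) selectedFeatures(selection)
         else as.character(selection)
  if (length(sel) == 0) stop("no features selected")
  X <- as.matrix(as.data.frame(features)[, sel, drop = FALSE])
  y <- as.integer(labels)
  if (!is.null(grid)) {
    gs <- gridSearchCv(X, y, grid$hidden, grid$eta, folds = folds,
                       seed = seed, smoteK = smoteK,
                       maxit = min(maxit, 300))
    nHidden <- gs$nHidden; eta <- gs$eta
  }
  st <- standardizeFit(X)
  Xs <- standardizeApply(X, st)
  aug <- smoteAugment(Xs, y, smoteK, seed + 1)
  fit <- trainMlp(aug$X, aug$y, nHidden, eta, seed = seed + 2,
                  maxit = maxit)
  th <- selectThresholdRoc(predictMlp(fit, aug$X), aug$y)
  th <- min(max(th, 1e-6), 1 - 1e-6)
  if (is.null(referenceModel)) referenceModel <- emptyNSSModel()
  new("TrainedQualityModel", selectedFeatures = sel,
      center = setNames(st$center, sel), scale = setNames(st$scale, sel),
      W1 = fit$W1, b1 = fit$b1, w2 = fit$w2, b2 = fit$b2,
      nHidden = as.integer(nHidden), eta = eta, threshold = th,
      referenceModel = referenceModel, seed = as.integer(seed),
      lossTrace = fit$trace)
}

emptyNSSModel <- function() {
  new("NSSModel", nu = numeric(0), sigma = matrix(numeric(0), 0, 0),
      blockCount = 0L, P = 64, T = 0.1)
}

#' Predict quality from a trained model
#'
#' Features are aligned by name, standardized with the stored training
#' statistics and passed through the network.
#'
#' @param object a [TrainedQualityModel-class].
#' @param newdata data.frame/matrix containing the selected feature columns.
#' @param type `"score"` for MLP outputs in (0, 1), `"label"` for the
#'   thresholded decision (1 = adequate; positive iff score > threshold).
#' @return numeric scores or integer labels.
#' @export
setMethod("predict", "TrainedQualityModel",
  function(object, newdata, type = c("score", "label")) {
    type <- match.arg(type)
    df <- as.data.frame(newdata)
    miss <- setdiff(object@selectedFeatures, colnames(df))
    if (length(miss))
      stop("missing feature columns: ", paste(miss, collapse = ", "))
    X <- as.matrix(df[, object@selectedFeatures, drop = FALSE])
    Xs <- standardizeApply(X, list(center = object@center,
                                   scale = object@scale))
    w <- list(W1 = object@W1, b1 = object@b1, w2 = object@w2,
              b2 = object@b2)
    sc <- predictMlp(w, Xs)
    if (type == "score") sc else as.integer(sc > object@threshold)
  })

#' Serialize / restore a trained quality model as portable JSON
#'
#' @param model a [TrainedQualityModel-class]; @param path file path.
#' @export
writeQualityModel <- function(model, path) {
  ref <- if (length(model@referenceModel@nu))
    list(nu = model@referenceModel@nu, sigma = model@referenceModel@sigma,
         P = model@referenceModel@P, T = model@referenceModel@T,
         count_blocks = model@referenceModel@blockCount)
  jsonlite::write_json(
    list(selected_features = model@selectedFeatures,
         center = model@center, scale = model@scale,
         W1 = model@W1, b1 = model@b1, w2 = model@w2, b2 = model@b2,
         n_hidden = model@nHidden, eta = model@eta,
         threshold = model@threshold, seed = model@seed,
         reference_model = ref),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeQualityModel
#' @export
readQualityModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(m, nr, nc) {
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    matrix(as.numeric(m), nr, nc)
  }
  p <- length(j$selected_features)
  h <- as.integer(j$n_hidden)
  ref <- if (!is.null(j$reference_model)) {
    k <- length(j$reference_model$nu)
    s <- toMat(j$reference_model$sigma, k, k)
    new("NSSModel", nu = as.numeric(j$reference_model$nu),
        sigma = (s + t(s)) / 2,
        blockCount = as.integer(j$reference_model$count_blocks),
        P = as.numeric(j$reference_model$P),
        T = as.numeric(j$reference_model$T))
  } else emptyNSSModel()
  new("TrainedQualityModel",
      selectedFeatures = as.character(j$selected_features),
      center = setNames(as.numeric(j$center), j$selected_features),
      scale = setNames(as.numeric(j$scale), j$selected_features),
      W1 = toMat(j$W1, p, h), b1 = as.numeric(j$b1),
      w2 = as.numeric(j$w2), b2 = as.numeric(j$b2),
      nHidden = h, eta = as.numeric(j$eta),
      threshold = as.numeric(j$threshold),
      referenceModel = ref, seed = as.integer(j$seed),
      lossTrace = numeric(0))
}
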