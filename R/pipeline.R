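# Pipeline aggregation: the canonical 40-feature vector, batch extraction
# with a shared reference NSS model, and the end-to-end workflow
# (reference model -> features -> selection -> classifier -> evaluation).

#' Canonical feature names
#'
#' The fixed order of the 40-feature vector: 12 entropy features, the
#' naturalness index, 18 wavelet sharpness features, 9 luminosity features.
#'
#' @return character vector of length 40.
#' @export
featureNames <- function() {
  c(as.vector(outer(paste0("sseq_", c("spacen_mean", "spacen_skew",
                                      "specen_mean", "specen_skew")),
                    paste0("_s", 1:3), paste0)),
    "niqe_q",
    as.vector(outer(paste0("cwt_", c("ent", "mean", "sd")),
                    paste0("_s", c(2, 4, 8, 16, 32, 64)), paste0)),
    c("lum_p1", "lum_p5", "lum_p10", "lum_p15", "lum_p20",
      "lum_d5_1", "lum_d10_5", "lum_d15_10", "lum_d20_15"))
}

# Reorder sseq block (computed scale-major) into canonical order and check
# completeness.
canonicalize <- function(v) {
  nm <- featureNames()
  if (!all(nm %in% names(v))) stop("incomplete feature vector")
  v[nm]
}

# Everything except niqe_q for one preprocessed image, plus its block
# parameter rows (so a reference model can be pooled without recomputing).
extractStageFeatures <- function(prep, P = 64, T = 0.1, M = 32,
                                 lumSigma = 19) {
  g <- greenChannel(imagePixels(prep))
  list(sseq = sseqFeatures(g, M = M),
       cwt = cwtFeatures(prep),
       lum = luminosityFromImage(prep, sigma = lumSigma),
       nss = blockNssParams(g, P, T))
}

#' Extract the canonical 40-feature vector of one image
#'
#' Runs preprocessing (FOV location + extension) and the four feature
#' extractors; the naturalness index is computed against the supplied
#' reference NSS model.
#'
#' @param img H x W x 3 fundus array (0-255) or a
#'   [PreprocessedImage-class].
#' @param ref reference [NSSModel-class] for `niqe_q`.
#' @param P,T naturalness block parameters; @param M entropy block size;
#' @param lumSigma background Gaussian sd.
#' @return named numeric vector of 40 finite values in canonical order.
#' @export
extractAllFeatures <- function(img, ref, P = 64, T = 0.1, M = 32,
                               lumSigma = 19) {
  prep <- if (is(img, "PreprocessedImage")) img else preprocessFundus(img)
  st <- extractStageFeatures(prep, P = P, T = T, M = M, lumSigma = lumSigma)
  niqe <- c(niqe_q = niqeDistance(ref, fitMVG(st$nss, P, T)))
  canonicalize(c(st$sseq, niqe, st$cwt, st$lum))
}

#' Batch feature extraction with a pooled reference model
#'
#' Preprocesses and characterizes every image once; the reference NSS model
#' is pooled from the block parameters of the images named by
#' `referenceIdx` (typically the adequate-quality training images), or an
#' existing model can be supplied. `niqe_q` is then computed for all
#' images.
#'
#' @param images list of fundus arrays, or a manifest data.frame from
#'   [generateFundusDataset()] (rows are materialized on demand).
#' @param referenceIdx integer indices of the images that define the
#'   reference model (ignored when `ref` is given).
#' @param ref optional prebuilt [NSSModel-class].
#' @param P,T,M,lumSigma stage parameters; @param verbose print progress.
#' @return list with `features` (data.frame n x 40) and `ref`.
#' @export
extractFeaturesBatch <- function(images, referenceIdx = NULL, ref = NULL,
                                 P = 64, T = 0.1, M = 32, lumSigma = 19,
                                 verbose = FALSE) {
  fromManifest <- is.data.frame(images)
  n <- if (fromManifest) nrow(images) else length(images)
  getImage <- function(i) {
    if (fromManifest) generateFundus(manifestScene(images[i, ]))$image
    else images[[i]]
  }
  stage <- vector("list", n)
  for (i in seq_len(n)) {
    prep <- preprocessFundus(getImage(i))
    stage[[i]] <- extractStageFeatures(prep, P = P, T = T, M = M,
                                       lumSigma = lumSigma)
    if (verbose && i %% 20 == 0) message("  extracted ", i, "/", n)
  }
  if (is.null(ref)) {
    if (is.null(referenceIdx) || length(referenceIdx) < 1)
      stop("referenceIdx needed when no reference model is given")
    pooled <- do.call(rbind, lapply(stage[referenceIdx], `[[`, "nss"))
    if (nrow(pooled) < 2) stop("fewer than 2 retained blocks in total")
    ref <- fitMVG(pooled, P, T)
  }
  rows <- lapply(stage, function(st) {
    niqe <- c(niqe_q = niqeDistance(ref, fitMVG(st$nss, P, T)))
    canonicalize(c(st$sseq, niqe, st$cwt, st$lum))
  })
  feats <- as.data.frame(do.call(rbind, rows))
  list(features = feats, ref = ref)
}

#' Run the full quality-assessment workflow on synthetic data
#'
#' Generates a labeled synthetic dataset, splits it into stratified
#' training/test halves, builds the reference NSS model from the adequate
#' training images, extracts the 40 features, selects features with
#' bootstrap FCBF, trains the SMOTE-balanced MLP (optionally
#' cross-validating the hyper-parameter grid), picks the ROC operating
#' threshold on the training set and evaluates on the held-out test set.
#' All artifacts (features.csv, selection.json, model.json, report.json)
#' are written when `outDir` is given.
#'
#' @param n dataset size; @param seed master seed; @param adequateFraction
#'   class balance of the generator.
#' @param trainFraction fraction of images in the training split.
#' @param B,threshold bootstrap FCBF replicates and count cutoff
#'   (threshold defaults to B/2).
#' @param grid list(hidden=..., eta=...) to cross-validate, or NULL to use
#'   `nHidden`/`eta` directly.
#' @param nHidden,eta fixed hyper-parameters when `grid` is NULL.
#' @param smoteK SMOTE neighbors; @param folds CV folds;
#' @param outDir optional artifact directory; @param verbose print
#'   progress.
#' @return list with `features`, `selection`, `model`, `report` (test-set
#'   evaluation), `cv` (grid-search result or NULL), `split` and `ref`.
#' @export
runPipeline <- function(n = 200, seed = 1, adequateFraction = 0.86,
                        trainFraction = 0.5, B = 1000,
                        threshold = ceiling(B / 2),
                        grid = list(hidden = c(5, 10, 21), eta = c(0, 0.1)),
                        nHidden = 21, eta = 0.1, smoteK = 5, folds = 10,
                        outDir = NULL, verbose = FALSE) {
  ds <- generateFundusDataset(n, adequateFraction, seed)
  y <- ds$labels
  # stratified train/test split
  idxTrain <- withSeed(seed + 13, {
    unlist(lapply(unique(y), function(cl) {
      idx <- which(y == cl)
      sample(idx, round(length(idx) * trainFraction))
    }))
  })
  isTrain <- seq_len(n) %in% idxTrain

  if (verbose) message("extracting features for ", n, " images ...")
  ext <- extractFeaturesBatch(ds$manifest,
                              referenceIdx = which(isTrain & y == 1),
                              verbose = verbose)
  feats <- ext$features

  if (verbose) message("bootstrap FCBF selection ...")
  selection <- bootstrapFcbf(feats[isTrain, ], y[isTrain], B = B,
                             threshold = threshold, seed = seed + 29)
  selNames <- selectedFeatures(selection)
  if (length(selNames) == 0) {
    # degenerate replicate agreement: fall back to the single-run FCBF
    selNames <- fcbf(feats[isTrain, ], y[isTrain])
  }

  if (verbose) message("training classifier ...")
  model <- trainQualityModel(feats[isTrain, ], y[isTrain], selNames,
                             nHidden = nHidden, eta = eta, grid = grid,
                             folds = folds, smoteK = smoteK,
                             seed = seed + 41, referenceModel = ext$ref)

  scoresTest <- predict(model, feats[!isTrain, ], type = "score")
  report <- evaluateScores(scoresTest, y[!isTrain], model@threshold)

  out <- list(features = cbind(feats, label = y, train = isTrain),
              selection = selection, selectedNames = selNames,
              model = model, report = report,
              split = list(train = which(isTrain), test = which(!isTrain)),
              ref = ext$ref, seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cbind(id = seq_len(n), feats, label = y,
                    train = as.integer(isTrain)),
              file.path(outDir, "features.csv"), row.names = FALSE)
    writeSelection(selection, file.path(outDir, "selection.json"))
    writeQualityModel(model, file.path(outDir, "model.json"))
    jsonlite::write_json(
      list(seed = seed, n = n, threshold = model@threshold,
           counts = report[c("tp", "fp", "tn", "fn")],
           metrics = report[c("se", "sp", "acc", "ppv", "f1")],
           auc = report$auc),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
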