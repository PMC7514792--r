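# Fast correlation-based filter: symmetrical-uncertainty relevance ranking
# with predominance-based redundancy removal, stabilised over bootstrap
# replicates of the training set.

# Map an arbitrary discrete vector to integer codes 1..k.
toCodes <- function(x) {
  u <- unique(x)
  list(codes = match(x, u), k = length(u))
}

#' Symmetrical uncertainty between two discrete variables
#'
#' SU(X, Y) = 2 (H(X) - H(X|Y)) / (H(X) + H(Y)), base-2 entropies; returns 0
#' when both variables are constant.
#'
#' @param x,y discrete vectors of equal length >= 2.
#' @return SU in \[0, 1\].
#' @export
symmetricalUncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  n <- length(x)
  cx <- toCodes(x); cy <- toCodes(y)
  hx <- shannonEntropyBits(tabulate(cx$codes, cx$k) / n)
  hy <- shannonEntropyBits(tabulate(cy$codes, cy$k) / n)
  if (hx + hy == 0) return(0)
  joint <- cx$codes + cx$k * (cy$codes - 1L)
  hxy <- shannonEntropyBits(tabulate(joint, cx$k * cy$k) / n)
  hxGivenY <- hxy - hy
  2 * (hx - hxGivenY) / (hx + hy)
}

#' Equal-frequency discretization of a feature matrix
#'
#' Each column is rank-binned into (up to) `bins` equal-frequency levels;
#' constant columns map to a single level. Deterministic and invariant to
#' monotone rescaling.
#'
#' @param features numeric matrix or data.frame (n >= 10 rows).
#' @param bins number of levels.
#' @return integer matrix of bin labels.
#' @export
discretizeFeatures <- function(features, bins = 10) {
  X <- as.matrix(features)
  if (nrow(X) < 10) stop("need at least 10 rows")
  apply(X, 2, function(x) {
    if (max(x) == min(x)) return(rep(1L, length(x)))
    as.integer(ceiling(rank(x, ties.method = "average") * bins / length(x)))
  })
}

#' Fast correlation-based filter
#'
#' Stage 1 ranks features by SU with the class label (features with zero
#' relevance are dropped; ties broken by original column order). Stage 2
#' sweeps the ranking and removes every remaining feature Xm that is
#' predominated by an earlier-kept Xn, i.e. SU(Xm, Xn) >= SU(Xm, C).
#'
#' @param features numeric matrix/data.frame with named columns (>= 2).
#' @param labels binary class vector (both classes present).
#' @param bins discretization levels.
#' @return character vector of kept feature names in relevance order, with
#'   attribute `"relevance"`.
#' @export
fcbf <- function(features, labels, bins = 10) {
  X <- as.matrix(features)
  if (ncol(X) < 2) stop("need at least 2 features")
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  D <- discretizeFeatures(X, bins)
  rel <- vapply(seq_len(ncol(D)),
                function(j) symmetricalUncertainty(D[, j], labels),
                numeric(1))
  keepIdx <- which(rel > 0)
  if (length(keepIdx) == 0) {
    out <- character(0)
    attr(out, "relevance") <- numeric(0)
    return(out)
  }
  ord <- keepIdx[order(-rel[keepIdx], keepIdx)]
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    for (j in seq_along(ord)) {
      if (j <= i || !alive[j]) next
      suPair <- symmetricalUncertainty(D[, ord[j]], D[, ord[i]])
      if (suPair >= rel[ord[j]]) alive[j] <- FALSE
    }
  }
  kept <- ord[alive]
  out <- colnames(X)[kept]
  attr(out, "relevance") <- unname(rel[kept])
  out
}

#' Bootstrap-stabilised FCBF selection
#'
#' Runs FCBF on `B` bootstrap replicates (uniform resampling with
#' replacement to the original size) and selects the features kept on at
#' least `threshold` runs. Per-replicate seeds are spawned from the master
#' seed with a prefix-stable stream, so results are reproducible and counts
#' can only grow with B.
#'
#' @param features numeric matrix/data.frame with named columns.
#' @param labels binary class vector.
#' @param B replicates; @param threshold selection count cutoff;
#' @param seed master seed; @param bins discretization levels.
#' @return a [SelectionResult-class].
#' @export
bootstrapFcbf <- function(features, labels, B = 1000, threshold = 500,
                          seed = 1, bins = 10) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  n <- nrow(X)
  seeds <- spawnSeeds(seed, B)
  counts <- setNames(integer(ncol(X)), colnames(X))
  for (b in seq_len(B)) {
    idx <- withSeed(seeds[b], sample.int(n, n, replace = TRUE))
    sel <- tryCatch(fcbf(X[idx, , drop = FALSE], labels[idx], bins),
                    error = function(e) character(0))
    counts[sel] <- counts[sel] + 1L
  }
  new("SelectionResult", featureNames = colnames(X),
      counts = unname(counts),
      selected = colnames(X)[counts >= threshold],
      B = as.integer(B), threshold = as.integer(threshold),
      seed = as.integer(seed))
}

#' Serialize a selection result as JSON
#'
#' @param sel a [SelectionResult-class]; @param path output file.
#' @export
writeSelection <- function(sel, path) {
  jsonlite::write_json(
    list(feature_names = sel@featureNames, counts = sel@counts,
         selected = sel@selected, B = sel@B, threshold = sel@threshold,
         seed = sel@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
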