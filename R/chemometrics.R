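#' Random calibration/prediction split
#'
#' Splits observations row-wise at the given fraction (default two-thirds
#' calibration, one-third prediction): the calibration group takes
#' \code{ceiling(fraction * n)} rows, the prediction group the remainder, so
#' 165 region spectra split into 110 and 55. The partition is disjoint,
#' exhaustive and reproducible from the seed. \code{by = "sample"} keeps all
#' regions of a sausage in the same group (grouped split).
#'
#' @param x a [SpectraSet-class], or an integer row count.
#' @param fraction calibration fraction in (0, 1).
#' @param seed integer seed for the random partition.
#' @param by \code{"row"} (default) or \code{"sample"}.
#' @return list with integer index vectors \code{calibration} and
#'   \code{prediction}.
#' @export
splitCalibrationPrediction <- function(x, fraction = 2 / 3, seed = 1L,
                                       by = c("row", "sample")) {
  by <- match.arg(by)
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  n <- if (is(x, "SpectraSet")) ncol(x) else as.integer(x)
  if (n < 2L) stopf("need at least 2 observations to split")
  if (by == "sample") {
    if (!is(x, "SpectraSet")) stopf("by = 'sample' needs a SpectraSet")
    codes <- sampleCode(x)
    u <- unique(codes)
    nCal <- ceiling(fraction * length(u))
    calCodes <- withSeed(seed, sample(u, nCal))
    cal <- which(codes %in% calCodes)
  } else {
    nCal <- ceiling(fraction * n)
    cal <- sort(withSeed(seed, sample.int(n, nCal)))
  }
  list(calibration = cal, prediction = setdiff(seq_len(n), cal))
}

#' Fit a PLSR model by NIPALS
#'
#' Univariate-response partial least squares regression. X and y are
#' mean-centred; each latent variable is extracted by the NIPALS iteration
#' (weight vector from the X'y covariance, normalised; scores; X loadings)
#' followed by deflation of X. The latent-variable solution is collapsed to
#' an intercept and a coefficient vector over bands,
#' \eqn{b = W (P'W)^{-1} q}, so prediction is a single affine map.
#'
#' @param X observations x bands matrix.
#' @param y numeric response (length \code{nrow(X)}).
#' @param nLatent number of latent variables (>= 1, at most
#'   \code{min(nrow(X) - 1, ncol(X))} and at most the rank of centred X).
#' @param tol convergence tolerance on the weight-vector change.
#' @param maxIter maximum NIPALS iterations per component.
#' @param wavelengthsNm optional wavelengths of the X columns.
#' @param chain optional pretreatment label to record.
#' @return A [PLSRModel-class].
#' @export
fitPLSR <- function(X, y, nLatent, tol = 1e-10, maxIter = 500L,
                    wavelengthsNm = NA_real_, chain = "Raw") {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("rows(X) = %d but length(y) = %d", n, length(y))
  if (n < 2L) stopf("need at least 2 observations")
  if (stats::var(y) == 0) stopf("zero-variance response")
  nLatent <- as.integer(nLatent)
  if (nLatent < 1L || nLatent > min(n - 1L, p))
    stopf("nLatent must be in 1..min(n-1, p) = %d", min(n - 1L, p))
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2L, xMean)
  f <- y - yMean
  W <- matrix(0, p, nLatent)
  P <- matrix(0, p, nLatent)
  Tm <- matrix(0, n, nLatent)
  q <- numeric(nLatent)
  for (a in seq_len(nLatent)) {
    u <- f
    w <- crossprod(E, u)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14)
      stopf("nLatent = %d exceeds the rank of the centred predictors (component %d degenerate)",
            nLatent, a)
    w <- w / nw
    repeat_count <- 0L
    repeat {
      t <- as.numeric(E %*% w)
      tt <- sum(t^2)
      if (tt < 1e-28)
        stopf("degenerate score vector at component %d", a)
      qa <- sum(t * f) / tt
      uNew <- f * qa
      wNew <- crossprod(E, uNew)
      nw <- sqrt(sum(wNew^2))
      if (nw < 1e-14) break  # residual response orthogonal to E
      wNew <- wNew / nw
      delta <- sqrt(sum((wNew - w)^2))
      w <- wNew
      repeat_count <- repeat_count + 1L
      if (delta < tol || repeat_count >= maxIter) break
    }
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    pLoad <- as.numeric(crossprod(E, t)) / tt
    qa <- sum(t * f) / tt
    E <- E - tcrossprod(t, pLoad)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- pLoad; Tm[, a] <- t; q[a] <- qa
  }
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  b0 <- yMean - sum(xMean * b)
  new("PLSRModel", nLatent = nLatent, xMean = xMean, yMean = yMean,
      weights = W, xLoadings = P, yLoadings = q, scores = Tm, coef = b,
      b0 = b0,
      wavelengthsNm = if (all(is.na(wavelengthsNm))) rep(NA_real_, p)
                      else as.numeric(wavelengthsNm),
      chain = chain)
}

#' @describeIn fitPLSR collapsed band coefficient vector b.
#' @param object a [PLSRModel-class].
#' @export
setMethod("regressionCoefficients", "PLSRModel", function(object) object@coef)

#' @describeIn fitPLSR collapsed intercept b0.
#' @export
setMethod("intercept", "PLSRModel", function(object) object@b0)

#' Predict from a PLSR model
#'
#' @param object a [PLSRModel-class].
#' @param newdata observations x bands matrix with the model's band count.
#' @param ... unused.
#' @return numeric predictions, \code{b0 + newdata \%*\% b}.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@coef))
    stopf("newdata has %d bands, model expects %d", ncol(newdata),
          length(object@coef))
  as.numeric(object@b0 + newdata %*% object@coef)
})

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel: %d latent variable(s), %d bands, chain '%s'\n",
              object@nLatent, length(object@coef), object@chain))
})

#' Coefficient of determination and root mean square error
#'
#' \eqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2} with
#' \eqn{\bar y} the mean of the evaluated set, and
#' \eqn{\mathrm{RMSE} = \sqrt{\sum (y_i - \hat y_i)^2 / n}}.
#'
#' @param y observed values.
#' @param yHat predicted values, same length.
#' @return list with \code{R2} and \code{RMSE}.
#' @export
computeMetrics <- function(y, yHat) {
  stopifnot(length(y) == length(yHat), length(y) >= 2L)
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) stopf("R2 undefined: zero variance in the evaluated set")
  ssRes <- sum((y - yHat)^2)
  list(R2 = 1 - ssRes / ssTot, RMSE = sqrt(ssRes / length(y)))
}

#' Cross-validated PLSR performance
#'
#' Leave-one-out or seeded k-fold cross-validation. The whole modelling
#' recipe -- the pretreatment chain (with its calibration-learned MSC
#' reference) and the PLSR fit -- is re-run inside every fold, and the
#' cross-validated metrics are computed from the pooled out-of-fold
#' predictions.
#'
#' @param X observations x bands matrix of spectra in the chain's input
#'   domain (raw reflectance/absorbance if a chain is given).
#' @param y response.
#' @param nLatent latent variables per fold fit.
#' @param scheme \code{"loo"} or \code{"kfold"}.
#' @param k folds for \code{"kfold"}.
#' @param seed fold-assignment seed for \code{"kfold"}.
#' @param chain optional [PretreatmentChain-class] (or string) refitted
#'   inside each fold.
#' @param fitHook optional function called once per fold refit (e.g. a
#'   counter for instrumentation).
#' @return list with \code{R2cv}, \code{RMSECV} and the out-of-fold
#'   predictions \code{yHat}.
#' @export
crossValidate <- function(X, y, nLatent, scheme = c("loo", "kfold"), k = 10L,
                          seed = 1L, chain = NULL, fitHook = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- if (scheme == "loo") as.list(seq_len(n)) else {
    if (k > n) stopf("k = %d exceeds n = %d", k, n)
    perm <- withSeed(seed, sample.int(n))
    split(perm, rep(seq_len(k), length.out = n))
  }
  if (!is.null(chain) && is.character(chain))
    chain <- pretreatmentChain(chain)
  yHat <- rep(NA_real_, n)
  for (fold in folds) {
    train <- setdiff(seq_len(n), fold)
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[fold, , drop = FALSE]
    if (!is.null(chain) && length(chain@steps)) {
      both <- applyChain(rbind(Xtr, Xte), chain,
                         calibrationRows = seq_along(train))
      Xtr <- both[seq_along(train), , drop = FALSE]
      Xte <- both[length(train) + seq_along(fold), , drop = FALSE]
    }
    fit <- fitPLSR(Xtr, y[train], nLatent = min(nLatent,
                                                length(train) - 1L,
                                                ncol(Xtr)))
    if (!is.null(fitHook)) fitHook()
    yHat[fold] <- predict(fit, Xte)
  }
  m <- computeMetrics(y, yHat)
  list(R2cv = m$R2, RMSECV = m$RMSE, yHat = yHat)
}

#' Parsimonious latent-variable selection
#'
#' Computes RMSECV for 1..\code{maxLv} latent variables and returns the
#' smallest count whose RMSECV is within \code{tolFrac} (default 2\%) of the
#' global minimum.
#'
#' @inheritParams crossValidate
#' @param maxLv largest latent-variable count to consider.
#' @param tolFrac parsimony tolerance as a fraction of the minimum RMSECV.
#' @return list with \code{nLatent} and the per-count \code{RMSECV} vector.
#' @export
selectNLatent <- function(X, y, maxLv, scheme = c("loo", "kfold"), k = 10L,
                          seed = 1L, chain = NULL, tolFrac = 0.02) {
  scheme <- match.arg(scheme)
  maxLv <- as.integer(maxLv)
  if (maxLv < 1L) stopf("maxLv must be >= 1")
  maxLv <- min(maxLv, nrow(as.matrix(X)) - 2L, ncol(as.matrix(X)))
  rmse <- vapply(seq_len(maxLv), function(a)
    crossValidate(X, y, a, scheme = scheme, k = k, seed = seed,
                  chain = chain)$RMSECV, numeric(1))
  best <- min(rmse)
  list(nLatent = which(rmse <= best * (1 + tolFrac))[1], RMSECV = rmse)
}

#' Full metric record for one pretreatment chain
#'
#' Applies the chain (MSC reference learned on the calibration rows), fits
#' PLSR on the calibration group, and reports the standard six-number record:
#' calibration R2/RMSEC, prediction R2/RMSEP on the held-out group, and
#' cross-validated R2/RMSECV (cross-validation run within the calibration
#' group, chain refit per fold). A \code{good_model} flag marks records with
#' high R2, low RMSE and a small |RMSEC - RMSECV| gap.
#'
#' @param set a [SpectraSet-class] in the chain's input domain.
#' @param chain a [PretreatmentChain-class] or chain string.
#' @param split list with \code{calibration}/\code{prediction} indices, as
#'   from [splitCalibrationPrediction()].
#' @param nLatent latent variables.
#' @param cvScheme cross-validation scheme passed to [crossValidate()].
#' @param goodR2,goodGap thresholds for the quality flag.
#' @return one-row data.frame: domain, treatment, n_latent, Rc2, RMSEC, Rp2,
#'   RMSEP, Rcv2, RMSECV, good_model.
#' @export
chainMetrics <- function(set, chain, split, nLatent, cvScheme = "loo",
                         goodR2 = 0.65, goodGap = 0.1) {
  stopifnot(is(set, "SpectraSet"))
  if (is.character(chain))
    chain <- pretreatmentChain(chain, spectralDomain(set))
  pre <- applyChain(set, chain, calibrationRows = split$calibration)
  M <- spectraMatrix(pre)
  y <- pHRef(set)
  cal <- split$calibration; prd <- split$prediction
  nl <- min(nLatent, length(cal) - 1L, ncol(M))
  fit <- fitPLSR(M[cal, , drop = FALSE], y[cal], nl, chain = chainLabel(chain))
  mc <- computeMetrics(y[cal], predict(fit, M[cal, , drop = FALSE]))
  mp <- computeMetrics(y[prd], predict(fit, M[prd, , drop = FALSE]))
  Xraw <- spectraMatrix(set)
  cv <- crossValidate(Xraw[cal, , drop = FALSE], y[cal], nl, scheme = cvScheme,
                      chain = chain)
  data.frame(domain = spectralDomain(set), treatment = chainLabel(chain),
             n_latent = nl, Rc2 = mc$R2, RMSEC = mc$RMSE, Rp2 = mp$R2,
             RMSEP = mp$RMSE, Rcv2 = cv$R2cv, RMSECV = cv$RMSECV,
             good_model = mc$R2 >= goodR2 &
               abs(mc$RMSE - cv$RMSECV) <= goodGap,
             stringsAsFactors = FALSE)
}

#' Serialize / read a PLSR model as JSON
#'
#' @param model a [PLSRModel-class].
#' @param path JSON path.
#' @return \code{readModelJSON}: a [PLSRModel-class].
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "PLSRModel"))
  obj <- list(type = "PLSRModel", n_latent = model@nLatent, b0 = model@b0,
              coef = model@coef, x_mean = model@xMean, y_mean = model@yMean,
              weights = model@weights, x_loadings = model@xLoadings,
              y_loadings = model@yLoadings,
              wavelengths_nm = model@wavelengthsNm, chain = model@chain)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "PLSRModel")) stopf("not a PLSRModel JSON file")
  new("PLSRModel", nLatent = as.integer(obj$n_latent),
      xMean = as.numeric(obj$x_mean), yMean = as.numeric(obj$y_mean),
      weights = as.matrix(obj$weights), xLoadings = as.matrix(obj$x_loadings),
      yLoadings = as.numeric(obj$y_loadings),
      scores = matrix(numeric(0), 0, as.integer(obj$n_latent)),
      coef = as.numeric(obj$coef), b0 = as.numeric(obj$b0),
      wavelengthsNm = as.numeric(obj$wavelengths_nm),
      chain = as.character(obj$chain))
}
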