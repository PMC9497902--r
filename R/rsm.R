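#' Construct a design factor
#'
#' @param name factor name (e.g. "X1").
#' @param center uncoded value at coded level 0.
#' @param halfrange uncoded units per coded unit.
#' @param units free-text units.
#' @return A [FactorSpec-class].
#' @export
factorSpec <- function(name, center, halfrange, units = "") {
  new("FactorSpec", name = name, center = as.numeric(center),
      halfrange = as.numeric(halfrange), units = units)
}

setMethod("show", "FactorSpec", function(object) {
  cat(sprintf("FactorSpec %s: %g +/- %g %s\n", object@name, object@center,
              object@halfrange, object@units))
})

#' Coded/uncoded factor transform
#'
#' Coded level c maps to the uncoded value \code{center + c * halfrange};
#' \code{to_coded} is the inverse affine map. The two directions round-trip
#' exactly.
#'
#' @param factor a [FactorSpec-class].
#' @param value numeric value(s) to transform.
#' @param direction \code{"to_uncoded"} or \code{"to_coded"}.
#' @return transformed value(s).
#' @examples
#' f <- factorSpec("X5", 75, 15, "min")
#' codeTransform(f, 1, "to_uncoded")  # 90
#' @export
codeTransform <- function(factor, value,
                          direction = c("to_uncoded", "to_coded")) {
  stopifnot(is(factor, "FactorSpec"))
  direction <- match.arg(direction)
  if (direction == "to_uncoded") factor@center + value * factor@halfrange
  else (value - factor@center) / factor@halfrange
}

#' Generate the five-factor central composite design
#'
#' Builds the rotatable-style CCD used for the casing-modification study: a
#' half-fraction 2^(5-1) factorial core whose fifth column follows the
#' defining relation X5 = X1 X2 X3 X4, two axial runs per factor at coded
#' distance \code{alpha}, and \code{nCenter} centre replicates -- 32 runs by
#' default. Run order is shuffled by \code{seed} (experiments are run in
#' random order); \code{seed = NULL} keeps the standard order.
#'
#' @param factors list of five [FactorSpec-class] objects
#'   (default [presetFactors()]).
#' @param alpha coded axial distance.
#' @param nCenter number of centre replicates.
#' @param seed run-order shuffle seed, or NULL for standard order.
#' @param generalize allow a factor count other than five (full factorial
#'   core is then used instead of the half fraction).
#' @return A [CCDDesign-class].
#' @export
generateCCD <- function(factors = presetFactors(), alpha = 2, nCenter = 6L,
                        seed = NULL, generalize = FALSE) {
  kf <- length(factors)
  if (kf != 5L && !generalize)
    stopf("the design is defined for exactly 5 factors (got %d); set generalize = TRUE for a full-factorial core", kf)
  stopifnot(all(vapply(factors, is, logical(1), "FactorSpec")))
  nCenter <- as.integer(nCenter)
  if (kf == 5L) {
    core <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4L)))
    core <- cbind(core, core[, 1] * core[, 2] * core[, 3] * core[, 4])
  } else {
    core <- as.matrix(expand.grid(rep(list(c(-1, 1)), kf)))
  }
  axial <- matrix(0, 2L * kf, kf)
  for (j in seq_len(kf)) {
    axial[2L * j - 1L, j] <- -alpha
    axial[2L * j, j] <- alpha
  }
  center <- matrix(0, nCenter, kf)
  coded <- rbind(core, axial, center)
  colnames(coded) <- vapply(factors, function(f) f@name, character(1))
  pointType <- c(rep("factorial", nrow(core)), rep("axial", nrow(axial)),
                 rep("center", nCenter))
  if (!is.null(seed)) {
    ord <- withSeed(seed, sample.int(nrow(coded)))
    coded <- coded[ord, , drop = FALSE]
    pointType <- pointType[ord]
  }
  rownames(coded) <- NULL
  new("CCDDesign", factors = factors, alpha = as.numeric(alpha),
      nCenter = nCenter, coded = coded, pointType = pointType)
}

#' Design matrices of a CCD
#'
#' @param design a [CCDDesign-class].
#' @return \code{codedMatrix}: runs x factors matrix of coded levels;
#'   \code{uncodedMatrix}: the same runs in uncoded units.
#' @export
codedMatrix <- function(design) {
  stopifnot(is(design, "CCDDesign"))
  design@coded
}

#' @rdname codedMatrix
#' @export
uncodedMatrix <- function(design) {
  stopifnot(is(design, "CCDDesign"))
  out <- design@coded
  for (j in seq_along(design@factors))
    out[, j] <- codeTransform(design@factors[[j]], design@coded[, j],
                              "to_uncoded")
  out
}

setMethod("show", "CCDDesign", function(object) {
  cat(sprintf("CCDDesign: %d factors, alpha = %g, %d runs (%d factorial, %d axial, %d center)\n",
              length(object@factors), object@alpha, nrow(object@coded),
              sum(object@pointType == "factorial"),
              sum(object@pointType == "axial"), object@nCenter))
})

#' Construct a quadratic response surface
#'
#' @param beta0 intercept.
#' @param linear named length-5 vector (X1..X5).
#' @param quadratic named length-5 vector of squared-term coefficients.
#' @param interaction named length-10 vector ("X1:X2", ..., "X4:X5").
#' @return A [QuadraticSurface-class].
#' @export
quadraticSurface <- function(beta0, linear, quadratic, interaction) {
  fn <- paste0("X", 1:5)
  pairs <- .interactionNames()
  linear <- linear[fn]; quadratic <- quadratic[fn]
  interaction <- interaction[pairs]
  if (any(is.na(linear)) || any(is.na(quadratic)) || any(is.na(interaction)))
    stopf("linear/quadratic need names X1..X5 and interaction names X1:X2 .. X4:X5")
  names(linear) <- fn; names(quadratic) <- fn; names(interaction) <- pairs
  new("QuadraticSurface", beta0 = as.numeric(beta0), linear = linear,
      quadratic = quadratic, interaction = interaction)
}

.interactionNames <- function() {
  idx <- utils::combn(5L, 2L)
  paste0("X", idx[1, ], ":X", idx[2, ])
}

## 21-column second-order model basis for a runs x 5 uncoded matrix.
.quadBasis <- function(U) {
  idx <- utils::combn(5L, 2L)
  inter <- sapply(seq_len(ncol(idx)), function(j)
    U[, idx[1, j]] * U[, idx[2, j]])
  if (is.null(dim(inter))) inter <- matrix(inter, nrow = 1L)
  B <- cbind(1, U, U^2, inter)
  colnames(B) <- c("(Intercept)", paste0("X", 1:5), paste0("X", 1:5, "^2"),
                   .interactionNames())
  B
}

#' Fit the quadratic response surface by least squares
#'
#' Ordinary least squares on the full 21-term second-order basis (intercept,
#' linear, pure quadratic, two-way interactions) in uncoded units.
#'
#' @param design a [CCDDesign-class].
#' @param responses numeric response vector, one per run.
#' @return A [QuadraticSurface-class].
#' @export
fitQuadraticSurface <- function(design, responses) {
  stopifnot(is(design, "CCDDesign"))
  U <- uncodedMatrix(design)
  if (length(responses) != nrow(U))
    stopf("%d responses for %d runs", length(responses), nrow(U))
  B <- .quadBasis(U)
  qrB <- qr(B)
  if (qrB$rank < ncol(B))
    stopf("design basis is rank deficient (rank %d < 21): too few distinct design points",
          qrB$rank)
  beta <- qr.coef(qrB, responses)
  quadraticSurface(beta[1], stats::setNames(beta[2:6], paste0("X", 1:5)),
                   stats::setNames(beta[7:11], paste0("X", 1:5)),
                   stats::setNames(beta[12:21], .interactionNames()))
}

#' Evaluate a quadratic surface
#'
#' @param surface a [QuadraticSurface-class].
#' @param x length-5 vector of uncoded factor values, or an n x 5 matrix.
#' @return predicted response(s).
#' @examples
#' evaluateSurface(presetSurface(), c(0, 0, 0, 0, 0))  # 59.0
#' @export
evaluateSurface <- function(surface, x) {
  stopifnot(is(surface, "QuadraticSurface"))
  U <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(U) != 5L) stopf("x must have 5 factor values")
  beta <- c(surface@beta0, surface@linear, surface@quadratic,
            surface@interaction)
  out <- as.numeric(.quadBasis(U) %*% beta)
  if (is.matrix(x)) out else out[1]
}

setMethod("show", "QuadraticSurface", function(object) {
  cat("QuadraticSurface (uncoded units):\n")
  cat(sprintf("  beta0 = %g\n", object@beta0))
  cat("  linear:", paste(sprintf("%s=%g", names(object@linear),
                                 object@linear), collapse = " "), "\n")
  cat("  quadratic:", paste(sprintf("%s=%g", names(object@quadratic),
                                    object@quadratic), collapse = " "), "\n")
  cat("  interaction:", paste(sprintf("%s=%g", names(object@interaction),
                                      object@interaction), collapse = " "),
      "\n")
})

#' Type III ANOVA for the quadratic surface
#'
#' Decomposes the response variation of a CCD experiment around the 20-term
#' quadratic model (intercept excluded from the term count). Each term's
#' adjusted sum of squares is the increase in residual SS when that term
#' (or term group) is dropped from the full model and the reduced model is
#' refitted (Type III, "Adj SS"). Residual error is split into lack of fit
#' and pure error using the replicated design points; the lack-of-fit F
#' ratio is \eqn{(SS_{LoF}/df_{LoF}) / (SS_{PE}/df_{PE})}. Significance
#' stars mark p < 0.05.
#'
#' For the 32-run design the df column is: Model 20, Linear 5, Square 5,
#' 2-way interaction 10, Error 11, Lack-of-Fit 6, Pure Error 5, Total 31.
#'
#' @param design a [CCDDesign-class] with replicated centre points.
#' @param responses numeric response vector, one per run.
#' @return data.frame with columns source, df, adj_SS, F, p, signif.
#' @export
anovaQuadratic <- function(design, responses) {
  stopifnot(is(design, "CCDDesign"))
  U <- uncodedMatrix(design)
  y <- as.numeric(responses)
  n <- nrow(U)
  if (length(y) != n) stopf("%d responses for %d runs", length(y), n)
  B <- .quadBasis(U)
  sse <- function(cols) {
    fit <- stats::lm.fit(B[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  full <- seq_len(ncol(B))
  sseFull <- sse(full)
  dfErr <- n - qr(B)$rank
  mse <- sseFull / dfErr
  sst <- sum((y - mean(y))^2)
  groups <- list(Model = 2:21, Linear = 2:6, Square = 7:11,
                 `2-Way Interaction` = 12:21)
  rowFor <- function(source, cols) {
    adj <- sse(setdiff(full, cols)) - sseFull
    df <- length(cols)
    Fv <- (adj / df) / mse
    p <- stats::pf(Fv, df, dfErr, lower.tail = FALSE)
    data.frame(source = source, df = df, adj_SS = adj, F = Fv, p = p,
               stringsAsFactors = FALSE)
  }
  rows <- list(rowFor("Model", groups$Model), rowFor("Linear", groups$Linear))
  for (j in 1:5) rows <- c(rows, list(rowFor(paste0("X", j), j + 1L)))
  rows <- c(rows, list(rowFor("Square", groups$Square)))
  for (j in 1:5)
    rows <- c(rows, list(rowFor(paste0("X", j, "^2"), j + 6L)))
  rows <- c(rows, list(rowFor("2-Way Interaction",
                              groups$`2-Way Interaction`)))
  inames <- .interactionNames()
  for (j in seq_along(inames))
    rows <- c(rows, list(rowFor(inames[j], j + 11L)))
  out <- do.call(rbind, rows)
  ## error decomposition from replicated design points
  key <- apply(round(design@coded, 10), 1L, paste, collapse = "/")
  reps <- split(seq_len(n), key)
  ssPE <- sum(vapply(reps, function(i) sum((y[i] - mean(y[i]))^2),
                     numeric(1)))
  dfPE <- n - length(reps)
  err <- data.frame(source = "Error", df = dfErr, adj_SS = sseFull,
                    F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  if (dfPE > 0L) {
    dfLoF <- dfErr - dfPE
    ssLoF <- sseFull - ssPE
    fLoF <- (ssLoF / dfLoF) / (ssPE / dfPE)
    pLoF <- stats::pf(fLoF, dfLoF, dfPE, lower.tail = FALSE)
    err <- rbind(err,
                 data.frame(source = "Lack of Fit", df = dfLoF,
                            adj_SS = ssLoF, F = fLoF, p = pLoF,
                            stringsAsFactors = FALSE),
                 data.frame(source = "Pure Error", df = dfPE, adj_SS = ssPE,
                            F = NA_real_, p = NA_real_,
                            stringsAsFactors = FALSE))
  } else {
    warning("no replicated design points: lack-of-fit rows omitted")
  }
  out <- rbind(out, err,
               data.frame(source = "Total", df = n - 1L, adj_SS = sst,
                          F = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
  out$signif <- ifelse(!is.na(out$p) & out$p < 0.05, "*", "")
  rownames(out) <- NULL
  out
}

#' Evaluate the surface on a 2-D grid of two factors
#'
#' Varies two factors over ranges (default the factorial range, coded -1..1,
#' of the supplied factor specs) while holding the other three fixed, and
#' evaluates the surface at every grid node. Feed the result to
#' \code{graphics::contour} or [plotContour()].
#'
#' @param surface a [QuadraticSurface-class].
#' @param vary character(2), names of the varied factors (e.g.
#'   \code{c("X1", "X3")}).
#' @param hold named numeric of the other three factors' uncoded values.
#' @param factors factor specs used for default ranges
#'   (default [presetFactors()]).
#' @param gridN nodes per axis.
#' @param ranges optional list with elements named after \code{vary}, each a
#'   length-2 uncoded range.
#' @return list with \code{x}, \code{y} (axis values) and \code{z}
#'   (\code{gridN} x \code{gridN} matrix of surface values).
#' @export
contourGrid <- function(surface, vary, hold, factors = presetFactors(),
                        gridN = 50L, ranges = NULL) {
  stopifnot(is(surface, "QuadraticSurface"), length(vary) == 2L)
  fn <- vapply(factors, function(f) f@name, character(1))
  if (!all(vary %in% fn)) stopf("vary must name two of %s",
                                paste(fn, collapse = ", "))
  if (any(vary %in% names(hold))) stopf("vary and hold factors overlap")
  others <- setdiff(fn, vary)
  if (!all(others %in% names(hold)))
    stopf("hold must fix the other three factors (%s)",
          paste(others, collapse = ", "))
  rng <- function(nm) {
    if (!is.null(ranges) && !is.null(ranges[[nm]])) return(ranges[[nm]])
    f <- factors[[match(nm, fn)]]
    c(f@center - f@halfrange, f@center + f@halfrange)
  }
  xs <- seq(rng(vary[1])[1], rng(vary[1])[2], length.out = gridN)
  ys <- seq(rng(vary[2])[1], rng(vary[2])[2], length.out = gridN)
  pts <- as.matrix(expand.grid(xs, ys))
  X <- matrix(0, nrow(pts), 5L)
  colnames(X) <- fn
  X[, vary[1]] <- pts[, 1]
  X[, vary[2]] <- pts[, 2]
  for (nm in others) X[, nm] <- hold[[nm]]
  z <- matrix(evaluateSurface(surface, X), gridN, gridN)
  list(x = xs, y = ys, z = z)
}

#' Render a labelled contour plot of a fitted surface
#'
#' @inheritParams contourGrid
#' @param path PNG output path.
#' @param main plot title.
#' @param ... forwarded to [contourGrid()].
#' @return the path, invisibly.
#' @export
plotContour <- function(surface, vary, hold, path, main = "Response surface",
                        ...) {
  cg <- contourGrid(surface, vary, hold, ...)
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  graphics::contour(cg$x, cg$y, cg$z, xlab = vary[1], ylab = vary[2],
                    main = main, labcex = 0.9)
  invisible(path)
}

#' Serialize / read a quadratic surface as JSON
#'
#' @param surface a [QuadraticSurface-class].
#' @param path JSON path.
#' @return \code{readSurfaceJSON}: a [QuadraticSurface-class].
#' @export
writeSurfaceJSON <- function(surface, path) {
  stopifnot(is(surface, "QuadraticSurface"))
  obj <- list(type = "QuadraticSurface", beta0 = surface@beta0,
              linear = as.list(surface@linear),
              quadratic = as.list(surface@quadratic),
              interaction = as.list(surface@interaction))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSurfaceJSON
#' @export
readSurfaceJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "QuadraticSurface"))
    stopf("not a QuadraticSurface JSON file")
  quadraticSurface(obj$beta0, unlist(obj$linear), unlist(obj$quadratic),
                   unlist(obj$interaction))
}
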