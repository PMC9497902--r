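## Shared fixtures, built in code at test time.

defaultGrid <- function() wavelengthGrid(350, 1100, 5)

## Small phantom used by segmentation/mapping tests.
smallPhantom <- function(seed = 11L, pH = 5.4, noiseSd = 0.002, ...) {
  generatePhantomHypercube(phantomSpec(nrow = 40L, ncol = 60L, pH = pH,
                                       noiseSd = noiseSd, seed = seed, ...))
}

## Rank-one "single latent direction" regression problem: X = t p', y = t.
oneFactorProblem <- function(n = 20L, p = 8L, seed = 42L) {
  withr::with_seed(seed, {
    t <- rnorm(n)
    pl <- rnorm(p)
    list(X = tcrossprod(t, pl), y = t)
  })
}

## Independent OLS oracle via the normal equations (with intercept).
olsOracle <- function(X, y) {
  Xc <- cbind(1, X)
  beta <- solve(crossprod(Xc), crossprod(Xc, y))
  as.numeric(Xc %*% beta)
}

## Random full-coefficient quadratic surface.
randomSurface <- function(seed) {
  withr::with_seed(seed, {
    quadraticSurface(rnorm(1, 0, 5),
                     setNames(rnorm(5), paste0("X", 1:5)),
                     setNames(rnorm(5, 0, 0.5), paste0("X", 1:5)),
                     setNames(rnorm(10, 0, 0.3),
                              apply(combn(5, 2), 2, function(ij)
                                paste0("X", ij[1], ":X", ij[2]))))
  })
}
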