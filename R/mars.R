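# Multivariate adaptive regression splines (additive, degree 1): forward
# hinge-pair selection followed by GCV backward pruning, plus an ordinary
# Gaussian/identity GLM and seeded k-fold cross-validation.

marsKnotCandidates <- function(xv, maxKnots, endspan = 3L) {
  u <- sort(unique(xv))
  if (length(u) > maxKnots)
    u <- unique(quantile(xv, probs = seq(0, 1, length.out = maxKnots),
                         names = FALSE, type = 7))
  if (length(u) < 2L) return(numeric())
  u <- u[-length(u)]
  # endspan: knots need support on both sides, or fold-out predictions
  # extrapolate from hinges fitted on a handful of points
  xs <- sort(xv)
  n <- length(xv)
  nBelow <- findInterval(u, xs)          # points <= knot
  u[nBelow >= endspan & (n - nBelow) >= endspan]
}

marsBasis <- function(x, terms) {
  n <- nrow(x)
  if (!nrow(terms)) return(matrix(1, n, 1L))
  cols <- lapply(seq_len(nrow(terms)), function(i) {
    v <- x[, terms$var[i]]
    if (terms$dir[i] > 0) pmax(v - terms$knot[i], 0)
    else pmax(terms$knot[i] - v, 0)
  })
  cbind(1, do.call(cbind, cols))
}

#' Fit an additive MARS model
#'
#' Friedman-style forward pass: at each step the reflected hinge pair
#' `max(0, x - t)`, `max(0, t - x)` (over all predictors and candidate
#' knots) giving the largest residual-sum-of-squares reduction is added,
#' up to `maxTerms` basis columns. The backward pass prunes terms to
#' minimize the generalized cross-validation criterion
#' `GCV = (RSS/n) / (1 - enp/n)^2` with effective parameters
#' `enp = M + penalty * (M - 1) / 2`. Interactions are not considered
#' (additive, degree 1).
#'
#' @param x Numeric predictor matrix (complete cases only).
#' @param y Numeric response.
#' @param maxTerms Maximum number of basis columns including the intercept
#'   (default `min(21, 2 * ncol(x) + 1)`).
#' @param penalty GCV penalty per knot (default 2, the additive-model
#'   convention).
#' @param maxKnots Maximum candidate knots per predictor; larger inputs use
#'   a quantile grid (default 101 for n <= 500, else 31).
#' @return An object of class `marsModel`: terms (var, knot, dir), coef,
#'   gcv, r2, fitted values.
#' @export
fitMars <- function(x, y, maxTerms = NULL, penalty = 2, maxKnots = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (anyNA(x) || anyNA(y)) stop("fitMars requires complete cases")
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (is.null(maxTerms)) maxTerms <- min(21L, 2L * p + 1L)
  if (maxTerms >= n) stop("maxTerms must be smaller than the sample size")
  if (is.null(maxKnots)) maxKnots <- if (n <= 300L) 101L else 31L

  tss <- sum((y - mean(y))^2)
  terms <- data.frame(var = character(), knot = numeric(), dir = numeric())
  B <- matrix(1, n, 1L)
  tolImprove <- max(1e-10 * tss, 1e-12)

  endspan <- max(3L, min(7L, n %/% 20L))
  knotsOf <- lapply(seq_len(p), function(j)
    marsKnotCandidates(x[, j], maxKnots, endspan))

  while (ncol(B) + 1L <= maxTerms) {
    qrB <- qr(B)
    Q <- qr.Q(qrB)
    r <- y - Q %*% crossprod(Q, y)
    best <- list(drop = 0)
    roomForPair <- ncol(B) + 2L <= maxTerms
    for (j in seq_len(p)) {
      kn <- knotsOf[[j]]
      if (!length(kn)) next
      xv <- x[, j]
      H1 <- pmax(outer(xv, kn, "-"), 0)
      QtH1 <- crossprod(Q, H1)
      raw1 <- colSums(H1 * H1)
      g11 <- raw1 - colSums(QtH1 * QtH1)
      c1 <- colSums(H1 * as.vector(r))
      xt <- xv - Q %*% crossprod(Q, xv)      # x orthogonal to current basis
      xx <- sum(xt * xt)
      xr <- sum(xt * r)
      h1x <- colSums(H1 * as.vector(xt))
      g22 <- g11 - 2 * h1x + xx
      g12 <- g11 - h1x
      c2 <- c1 - xr
      # raw energy of the mirrored hinge, for a relative conditioning guard
      raw2 <- raw1 - 2 * (colSums(H1 * xv) - kn * colSums(H1)) +
        (sum(xv * xv) - 2 * kn * sum(xv) + n * kn^2)
      det <- g11 * g22 - g12 * g12
      ok2 <- roomForPair & g11 > 1e-6 * pmax(raw1, 1e-12) &
        g22 > 1e-6 * pmax(raw2, 1e-12) &
        det > 1e-8 * pmax(g11 * g22, 1e-12)
      colTol <- 1e-10 * max(xx, 1)
      drop2 <- rep(-Inf, length(kn))
      drop2[ok2] <- (c1[ok2]^2 * g22[ok2] - 2 * c1[ok2] * c2[ok2] * g12[ok2] +
                       c2[ok2]^2 * g11[ok2]) / det[ok2]
      drop1 <- ifelse(g11 > pmax(colTol, 1e-6 * raw1), c1^2 / g11, -Inf)
      cand <- pmax(drop2, drop1)
      i <- which.max(cand)
      if (length(i) && cand[i] > best$drop) {
        best <- list(drop = cand[i], var = j, knot = kn[i],
                     pair = drop2[i] >= drop1[i])
      }
    }
    if (best$drop <= tolImprove) break
    vn <- colnames(x)[best$var]
    add <- data.frame(var = vn, knot = best$knot, dir = 1)
    if (isTRUE(best$pair))
      add <- rbind(add, data.frame(var = vn, knot = best$knot, dir = -1))
    terms <- rbind(terms, add)
    B <- marsBasis(x, terms)
  }

  gcvOf <- function(rss, M) (rss / n) / (1 - (M + penalty * (M - 1) / 2) / n)^2
  fitSubset <- function(keep) {
    Bk <- B[, c(TRUE, keep), drop = FALSE]
    f <- lm.fit(Bk, y)
    sum(f$residuals^2)
  }
  keep <- rep(TRUE, nrow(terms))
  bestKeep <- keep
  bestGcv <- gcvOf(fitSubset(keep), sum(keep) + 1L)
  cur <- keep
  while (sum(cur) > 0L) {
    rssDel <- vapply(which(cur), function(i) {
      tryKeep <- cur
      tryKeep[i] <- FALSE
      fitSubset(tryKeep)
    }, numeric(1))
    i <- which(cur)[which.min(rssDel)]
    cur[i] <- FALSE
    g <- gcvOf(min(rssDel), sum(cur) + 1L)
    if (g < bestGcv) {
      bestGcv <- g
      bestKeep <- cur
    }
  }
  terms <- terms[bestKeep, , drop = FALSE]
  B <- marsBasis(x, terms)
  f <- lm.fit(B, y)
  coefs <- f$coefficients
  coefs[is.na(coefs)] <- 0
  fitted <- as.vector(B %*% coefs)
  rss <- sum((y - fitted)^2)
  structure(list(terms = terms, coef = coefs,
                 gcv = gcvOf(rss, ncol(B)),
                 r2 = if (tss > 0) 1 - rss / tss else 0,
                 fitted = fitted, predictorNames = colnames(x),
                 penalty = penalty),
            class = "marsModel")
}

#' @export
predict.marsModel <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  missing <- setdiff(unique(object$terms$var), colnames(newx))
  if (length(missing))
    stop("newx lacks predictors: ", paste(missing, collapse = ", "))
  B <- marsBasis(newx, object$terms)
  as.vector(B %*% object$coef)
}

#' @export
print.marsModel <- function(x, ...) {
  cat("MARS model:", nrow(x$terms), "hinge terms, R^2 =",
      round(x$r2, 4), ", GCV =", signif(x$gcv, 5), "\n")
  if (nrow(x$terms)) {
    lab <- ifelse(x$terms$dir > 0,
                  sprintf("h(%s - %.4g)", x$terms$var, x$terms$knot),
                  sprintf("h(%.4g - %s)", x$terms$knot, x$terms$var))
    cat(paste0("  ", lab, ": ", signif(x$coef[-1L], 4), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Gaussian identity-link linear model
#'
#' Ordinary least squares of the response on the predictor columns;
#' rank-deficient designs drop collinear columns with a warning.
#'
#' @param x Predictor matrix.
#' @param y Response.
#' @return Object of class `glmModel` with coefficients, fitted values and
#'   R-squared.
#' @export
fitGlmModel <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < ncol(x) + 2L) stop("need at least p + 2 complete cases")
  B <- cbind(`(Intercept)` = 1, x)
  f <- lm.fit(B, y)
  if (any(is.na(f$coefficients))) {
    warning("dropping ", sum(is.na(f$coefficients)),
            " collinear column(s): ",
            paste(names(f$coefficients)[is.na(f$coefficients)],
                  collapse = ", "))
  }
  coefs <- f$coefficients
  coefs[is.na(coefs)] <- 0
  fitted <- as.vector(B %*% coefs)
  tss <- sum((y - mean(y))^2)
  rss <- sum((y - fitted)^2)
  structure(list(coef = coefs, fitted = fitted,
                 r2 = if (tss > 0) 1 - rss / tss else 0),
            class = "glmModel")
}

#' @export
predict.glmModel <- function(object, newx, ...) {
  B <- cbind(1, as.matrix(newx)[, names(object$coef)[-1L], drop = FALSE])
  as.vector(B %*% object$coef)
}

#' Seeded k-fold cross-validation
#'
#' Folds are assigned by a seeded shuffle, stratified by response decile so
#' every fold spans the response range; the cross-validated R-squared is
#' computed on the pooled out-of-fold predictions as `1 - RSS/TSS`.
#'
#' @param x Predictor matrix.
#' @param y Response.
#' @param fitFun Function `(x, y) -> model`.
#' @param predictFun Function `(model, x) -> predictions` (default
#'   [predict()]).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratify Stratify fold assignment by response decile.
#' @return A list: `pred` (pooled out-of-fold predictions), `fold`
#'   assignments, and `r2cv`.
#' @export
crossValidate <- function(x, y, fitFun, predictFun = predict, folds = 10,
                          seed = 1L, stratify = TRUE) {
  x <- as.matrix(x)
  n <- length(y)
  if (folds < 2L) stop("folds must be at least 2")
  if (n < folds) stop("need at least as many observations as folds")
  fold <- withSeed(seed, {
    if (stratify) {
      f <- integer(n)
      decile <- cut(rank(y, ties.method = "first"),
                    breaks = max(1L, min(10L, n %/% folds)), labels = FALSE)
      for (d in unique(decile)) {
        idx <- which(decile == d)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    } else sample(rep_len(seq_len(folds), n))
  })
  pred <- numeric(n)
  for (k in seq_len(folds)) {
    inK <- fold == k
    fit <- fitFun(x[!inK, , drop = FALSE], y[!inK])
    pred[inK] <- predictFun(fit, x[inK, , drop = FALSE])
  }
  tss <- sum((y - mean(y))^2)
  r2cv <- if (tss > 0) 1 - sum((y - pred)^2) / tss else 0
  list(pred = pred, fold = fold, r2cv = r2cv)
}
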