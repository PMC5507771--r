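# Centering/scaling preparation shared by the PLS fitters.
prepScale <- function(X, scaling) {
    xm <- colMeans(X)
    xs <- switch(scaling,
        uv = apply(X, 2L, stats::sd),
        pareto = sqrt(apply(X, 2L, stats::sd)),
        none = rep(1, ncol(X)))
    xs[!is.finite(xs) | xs <= 0] <- 1
    list(xm = xm, xs = xs,
         Xs = sweep(sweep(X, 2L, xm), 2L, xs, "/"))
}

# Single NIPALS-style PLS1 component on centered/scaled data.
pls1Component <- function(Xs, yc) {
    w <- drop(crossprod(Xs, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
        stop("response is orthogonal to every feature (X'y = 0)")
    w <- w / nw
    t <- drop(Xs %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(Xs, t)) / tt
    q <- sum(yc * t) / tt
    list(w = w, t = t, p = p, q = q)
}

#' Fit a single-component PLS1 model
#'
#' The standard PLS1 substrate of O-PLS: \eqn{w \propto X^T y} (unit norm),
#' \eqn{t = Xw}, \eqn{p = X^T t / t^T t}, \eqn{q = y^T t / t^T t};
#' predictions are \eqn{t q + \bar y}. Equivalent to
#' \code{fitOpls(..., n_orth = 0)}.
#'
#' @param X feature matrix (samples x features).
#' @param y numeric response.
#' @param scaling feature scaling: \code{"uv"} (unit variance, default for
#'   spectral features), \code{"pareto"} or \code{"none"}; features are
#'   always mean-centered.
#' @return An \linkS4class{OplsModel} with \code{nOrtho = 0}.
#' @export
fitPls1 <- function(X, y, scaling = c("uv", "pareto", "none")) {
    fitOpls(X, y, n_orth = 0L, scaling = scaling)
}

#' Fit an O-PLS(-DA) model
#'
#' Orthogonal projections to latent structures with a single predictive
#' component: iteratively, the loading of the current predictive component
#' is stripped of its y-predictive part to give an orthogonal weight
#' \eqn{w_o = p - (w^T p)w}; the orthogonal score \eqn{t_o = X w_o} and
#' loading \eqn{p_o} are removed from X (\eqn{X \leftarrow X - t_o p_o^T})
#' and the predictive component is refit on the filtered matrix. For a
#' single response this is algebraically equivalent to PLS1 with one extra
#' component in terms of fitted values, but concentrates the predictive
#' variation in one interpretable score.
#'
#' @inheritParams fitPls1
#' @param n_orth number of orthogonal components (>= 0). If the remaining
#'   orthogonal variation vanishes earlier, fitting stops and the actual
#'   number is recorded.
#' @param yLevels optional 2-vector of class labels behind a 0/1-coded y
#'   (recorded for discriminant models).
#' @return An \linkS4class{OplsModel}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X[, 1] - X[, 2] + rnorm(20, sd = 0.1)
#' m <- fitOpls(X, y, n_orth = 1)
#' m
#' @export
fitOpls <- function(X, y, n_orth = 1L, scaling = c("uv", "pareto", "none"),
                    yLevels = NA_character_) {
    scaling <- match.arg(scaling)
    X <- as.matrix(X)
    y <- as.numeric(y)
    n_orth <- as.integer(n_orth)
    if (n_orth < 0L) stop("n_orth must be >= 0")
    if (nrow(X) < n_orth + 3L)
        stop("need at least n_orth + 3 samples")
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
    if (stats::sd(y) == 0) stop("zero-variance response")
    pr <- prepScale(X, scaling)
    Xs <- pr$Xs
    ym <- mean(y)
    yc <- y - ym
    ssx <- sum(Xs^2)
    p <- ncol(X)
    Wo <- matrix(0, p, 0); Po <- matrix(0, p, 0)
    To <- matrix(0, nrow(X), 0)
    Xd <- Xs
    done <- 0L
    for (a in seq_len(n_orth)) {
        cmp <- pls1Component(Xd, yc)
        wo <- cmp$p - sum(cmp$w * cmp$p) * cmp$w
        nwo <- sqrt(sum(wo^2))
        if (nwo < 1e-12) break  # no orthogonal variation left
        wo <- wo / nwo
        to <- drop(Xd %*% wo)
        po <- drop(crossprod(Xd, to)) / sum(to^2)
        Xd <- Xd - tcrossprod(to, po)
        Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
        done <- a
    }
    cmp <- pls1Component(Xd, yc)
    res <- Xd - tcrossprod(cmp$t, cmp$p)
    r2x <- 1 - sum(res^2) / ssx
    r2y <- 1 - sum((yc - cmp$t * cmp$q)^2) / sum(yc^2)
    new("OplsModel",
        xMean = pr$xm, xScale = pr$xs, yMean = ym,
        weights = cmp$w, loadings = cmp$p, yLoading = cmp$q,
        orthoWeights = Wo, orthoLoadings = Po,
        scores = cmp$t, orthoScores = To,
        r2x = r2x, r2y = max(0, min(1, r2y)), nOrtho = done,
        scaling = scaling, yLevels = yLevels)
}

#' @rdname accessors
#' @export
setMethod("q2", "CvResult", function(x) x@q2)

setMethod("show", "OplsModel", function(object) {
    cat(sprintf(
        "OplsModel: 1 predictive + %d orthogonal component(s), %s scaling\n",
        object@nOrtho, object@scaling))
    cat(sprintf("  R2X = %.3f, R2Y = %.3f\n", object@r2x, object@r2y))
    if (!anyNA(object@yLevels))
        cat(sprintf("  discriminant coding: %s = 0, %s = 1\n",
                    object@yLevels[1], object@yLevels[2]))
})

#' Predict from an O-PLS(-DA) model
#'
#' Applies the stored centering/scaling, sequentially removes the stored
#' orthogonal components from the new data, and predicts
#' \eqn{\hat y = (Xw)q + \bar y}.
#'
#' @param object An \linkS4class{OplsModel}.
#' @param newdata feature matrix with the training columns.
#' @return list with \code{yhat} (predictions) and \code{scores}
#'   (predictive scores) per sample.
#' @export
setMethod("predict", "OplsModel", function(object, newdata) {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object@xMean))
        stop(sprintf("newdata has %d columns, model expects %d",
                     ncol(X), length(object@xMean)))
    Xs <- sweep(sweep(X, 2L, object@xMean), 2L, object@xScale, "/")
    for (a in seq_len(ncol(object@orthoWeights))) {
        to <- drop(Xs %*% object@orthoWeights[, a])
        Xs <- Xs - tcrossprod(to, object@orthoLoadings[, a])
    }
    t <- drop(Xs %*% object@weights)
    list(yhat = t * object@yLoading + object@yMean, scores = t)
})

# Seeded fold assignment; stratified deals each class round-robin (kept
# even when a class is smaller than k — spreading a tiny class across
# distinct folds is exactly what keeps every training set two-class).
# For binary responses the draw is validated: a training set reduced to a
# single class would make the discriminant fit degenerate, so such
# assignments are redrawn.
makeFolds <- function(y, k, stratified) {
    n <- length(y)
    if (stratified) {
        cls <- split(seq_len(n), y)
        if (min(lengths(cls)) < 2L) {
            warning("a class has fewer than 2 samples; ",
                    "falling back to unstratified assignment")
            stratified <- FALSE
        }
    }
    binary <- length(unique(y)) == 2L
    for (try in 1:100) {
        folds <- integer(n)
        if (stratified) {
            for (idx in cls)
                folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
        } else {
            folds[sample.int(n)] <- rep_len(seq_len(k), n)
        }
        if (!binary) return(folds)
        ok <- all(vapply(seq_len(k), function(f) {
            tr <- y[folds != f]
            !any(folds == f) || length(unique(tr)) == 2L
        }, logical(1)))
        if (ok) return(folds)
    }
    stop("could not draw folds keeping both classes in every training set")
}

#' k-fold cross-validated O-PLS(-DA)
#'
#' Randomly assigns samples to k folds (stratified by class for
#' discriminant analysis), fits the model on each fold's complement and
#' predicts the held-out samples, pooling the predicted residual sum of
#' squares (PRESS) over folds. \eqn{Q^2_{\hat Y} = 1 - PRESS/TSS} with TSS
#' about the full-sample mean (chemometrics convention). Centering and
#' scaling are estimated on the training folds only.
#'
#' @inheritParams fitOpls
#' @param k number of folds (default 7); \code{k = n} gives leave-one-out.
#' @param seed fold-assignment seed; NULL draws from the current RNG
#'   stream (used inside permutation loops).
#' @param stratified stratify fold assignment by the (binary) response.
#' @return A \linkS4class{CvResult}.
#' @export
kfoldCv <- function(X, y, k = 7L, n_orth = 1L,
                    scaling = c("uv", "pareto", "none"),
                    seed = NULL, stratified = FALSE) {
    scaling <- match.arg(scaling)
    X <- as.matrix(X)
    y <- as.numeric(y)
    n <- nrow(X)
    k <- as.integer(k)
    if (k > n) stop("k cannot exceed the sample count")
    if (k < 2L) stop("k must be >= 2")
    folds <- withSeed(seed, makeFolds(y, k, stratified))
    yhat <- rep(NA_real_, n)
    scores <- rep(NA_real_, n)
    for (f in seq_len(k)) {
        test <- folds == f
        if (!any(test)) next
        fit <- fitOpls(X[!test, , drop = FALSE], y[!test],
                       n_orth = n_orth, scaling = scaling)
        pr <- predict(fit, X[test, , drop = FALSE])
        yhat[test] <- pr$yhat
        scores[test] <- pr$scores
    }
    press <- sum((y - yhat)^2)
    tss <- sum((y - mean(y))^2)
    new("CvResult", folds = folds, yhat = yhat, cvScores = scores,
        press = press, tss = tss, q2 = 1 - press / tss, k = k)
}

setMethod("show", "CvResult", function(object) {
    cat(sprintf("CvResult: %d-fold CV, Q2_Yhat = %.3f (PRESS %.3g / TSS %.3g)\n",
                object@k, object@q2, object@press, object@tss))
})

#' Encode a two-level factor as a 0/1 response
#'
#' Levels are mapped to 0 and 1 by sorted level name; the mapping is
#' returned so discriminant models can record it.
#'
#' @param labels factor or character vector with exactly 2 distinct values,
#'   each appearing at least twice.
#' @return list with \code{y} (0/1 numeric) and \code{levels} (the labels
#'   encoded as 0 and 1, in that order).
#' @examples
#' encodeClasses(c("HFD", "CHD", "CHD", "HFD"))$levels  # CHD = 0, HFD = 1
#' @export
encodeClasses <- function(labels) {
    labels <- as.character(labels)
    lev <- sort(unique(labels))
    if (length(lev) != 2L)
        stop("exactly 2 classes are required (got ", length(lev),
             "); use a one-vs-rest contrast for more levels")
    if (any(table(labels) < 2L))
        stop("each class needs at least 2 samples")
    list(y = as.numeric(labels == lev[2L]), levels = lev)
}
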