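#' Permutation empirical p-value for a model statistic
#'
#' Permutes the response uniformly at random, recomputes the full
#' cross-validated statistic for each permutation (any CV folds are
#' re-drawn inside \code{model_fn} from the seeded stream, the conservative
#' choice), and returns the one-sided empirical p-value with the add-one
#' correction \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (n_{iter} + 1)},
#' so p = 0 is impossible and the smallest attainable value is
#' \eqn{1/(n_{iter}+1)}.
#'
#' @param model_fn function \code{(X, y) -> statistic} (e.g. a Q2 from
#'   k-fold CV). A failure on a permuted response is retried once with a
#'   fresh permutation, then raised.
#' @param X feature matrix.
#' @param y response vector.
#' @param n_iter number of permutations (>= 1).
#' @param seed seed for the permutation stream.
#' @return A \linkS4class{PermutationTest}.
#' @export
permutationPvalue <- function(model_fn, X, y, n_iter = 1000L, seed = 1L) {
    n_iter <- as.integer(n_iter)
    if (n_iter < 1L) stop("n_iter must be >= 1")
    ## the observed statistic is computed inside the same seeded stream as
    ## the permutations, so any internal randomness (e.g. CV fold draws)
    ## is reproducible
    res <- withSeed(seed, {
        observed <- model_fn(X, y)
        if (!is.finite(observed))
            stop("statistic is not finite on the original data")
        permuted <- vapply(seq_len(n_iter), function(i) {
            stat <- tryCatch(model_fn(X, sample(y)), error = function(e) NA)
            if (is.na(stat))  # resample once, then give up
                stat <- model_fn(X, sample(y))
            stat
        }, numeric(1))
        list(observed = observed, permuted = permuted)
    })
    observed <- res$observed
    permuted <- res$permuted
    new("PermutationTest",
        observed = observed, permuted = permuted, nIter = n_iter,
        pValue = (1 + sum(permuted >= observed)) / (n_iter + 1),
        seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("pValue", "PermutationTest", function(x) x@pValue)

setMethod("show", "PermutationTest", function(object) {
    cat(sprintf(
        "PermutationTest: observed %.4f vs %d permutations, p = %.4g\n",
        object@observed, object@nIter, object@pValue))
})

#' ROC curve and AUC of classifier scores
#'
#' Sweeps thresholds over the unique scores (a sample is called positive
#' when its score is at or above the threshold) and computes the AUC by the
#' rank (Mann-Whitney) formulation with ties contributing one half; the
#' trapezoidal integral of the curve equals this value exactly.
#'
#' @param scores numeric classifier scores (larger = more positive).
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return A \linkS4class{RocResult}.
#' @examples
#' r <- rocCurve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' auc(r)  # 0.75
#' @export
rocCurve <- function(scores, labels) {
    labels <- as.numeric(labels)
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    if (length(scores) != length(labels))
        stop("scores and labels lengths differ")
    r <- rank(scores)  # midranks: ties count one half
    aucVal <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    tpr <- vapply(thr, function(th) sum(scores >= th & labels == 1) / n1,
                  numeric(1))
    fpr <- vapply(thr, function(th) sum(scores >= th & labels == 0) / n0,
                  numeric(1))
    new("RocResult", thresholds = thr, fpr = fpr, tpr = tpr, auc = aucVal)
}

#' @rdname accessors
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: AUC = %.4f over %d thresholds\n",
                object@auc, length(object@thresholds)))
})

#' Cross-validate, permutation-test and (for classification) ROC a model
#'
#' Bundles the validation machinery around one O-PLS(-DA) model: k-fold
#' cross-validated \eqn{Q^2_{\hat Y}}, its permutation empirical p-value
#' (folds re-randomized within every permutation), and for two-class
#' responses the ROC of the cross-validated predictive scores.
#'
#' @param X feature matrix (samples x features).
#' @param y response: numeric for regression, or a two-level
#'   factor/character vector for discriminant analysis.
#' @param k folds (default 7).
#' @param n_orth orthogonal components (default 1).
#' @param scaling feature scaling.
#' @param n_iter permutations for the Q2 test.
#' @param seed master seed; fold and permutation streams are derived from
#'   it.
#' @return list with \code{cv} (\linkS4class{CvResult}), \code{perm}
#'   (\linkS4class{PermutationTest}), \code{roc}
#'   (\linkS4class{RocResult} or NULL), \code{model} (the full-data
#'   \linkS4class{OplsModel}) and a \code{summary} row of the headline
#'   numbers.
#' @export
validateModel <- function(X, y, k = 7L, n_orth = 1L,
                          scaling = c("uv", "pareto", "none"),
                          n_iter = 1000L, seed = 1L) {
    scaling <- match.arg(scaling)
    X <- as.matrix(X)
    classification <- is.factor(y) || is.character(y)
    yLevels <- NA_character_
    if (classification) {
        enc <- encodeClasses(y)
        y <- enc$y
        yLevels <- enc$levels
    }
    cv <- kfoldCv(X, y, k = k, n_orth = n_orth, scaling = scaling,
                  seed = deriveSeed(seed, "folds"),
                  stratified = classification)
    statFn <- function(Xp, yp)
        q2(kfoldCv(Xp, yp, k = k, n_orth = n_orth, scaling = scaling,
                   seed = NULL, stratified = classification))
    perm <- permutationPvalue(statFn, X, y, n_iter = n_iter,
                              seed = deriveSeed(seed, "perm"))
    roc <- if (classification) rocCurve(cv@cvScores, y) else NULL
    model <- fitOpls(X, y, n_orth = n_orth, scaling = scaling,
                     yLevels = yLevels)
    list(cv = cv, perm = perm, roc = roc, model = model,
         summary = data.frame(
             q2 = cv@q2, r2y = model@r2y, p = perm@pValue,
             auc = if (is.null(roc)) NA_real_ else roc@auc,
             n = nrow(X), k = k, n_orth = model@nOrtho,
             n_iter = n_iter, seed = seed))
}
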