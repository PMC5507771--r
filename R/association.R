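#' Spearman rank correlation with explicit degenerate handling
#'
#' Pearson correlation of midranks (ties receive average ranks), computed
#' on pairwise-complete observations. Zero rank variance in either variable
#' makes the coefficient undefined; it is returned as NA with the
#' \code{degenerate} flag set rather than silently dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{rho}, \code{n} (pairwise-complete count) and
#'   \code{degenerate}.
#' @examples
#' spearmanRho(1:5, c(5, 6, 7, 8, 7))$rho  # 8 / sqrt(95)
#' @export
spearmanRho <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("need >= 3 paired finite values")
    rx <- rank(x); ry <- rank(y)
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    vx <- sum(dx^2); vy <- sum(dy^2)
    if (vx == 0 || vy == 0)
        return(list(rho = NA_real_, n = n, degenerate = TRUE))
    list(rho = sum(dx * dy) / sqrt(vx * vy), n = n, degenerate = FALSE)
}

#' Permutation p-value for a Spearman correlation
#'
#' Two-sided empirical p on |rho|: y is permuted uniformly at random and
#' the add-one correction applied,
#' \eqn{p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(n_{iter}+1)}.
#'
#' @inheritParams spearmanRho
#' @param n_iter number of permutations.
#' @param seed RNG seed.
#' @return list with \code{rho}, \code{p}, \code{n}, \code{degenerate}.
#' @export
spearmanPermP <- function(x, y, n_iter = 999L, seed = 1L) {
    ok <- is.finite(x) & is.finite(y)
    xs <- x[ok]; ys <- y[ok]
    obs <- spearmanRho(xs, ys)
    if (obs$degenerate)
        return(list(rho = NA_real_, p = NA_real_, n = obs$n,
                    degenerate = TRUE))
    n_iter <- as.integer(n_iter)
    rx <- rank(xs)
    dx <- rx - mean(rx)
    vx <- sum(dx^2)
    hits <- withSeed(seed, {
        h <- 0L
        for (i in seq_len(n_iter)) {
            ry <- rank(ys[sample.int(length(ys))])
            dy <- ry - mean(ry)
            vy <- sum(dy^2)
            rp <- if (vy == 0) 0 else sum(dx * dy) / sqrt(vx * vy)
            if (abs(rp) >= abs(obs$rho) - 1e-12) h <- h + 1L
        }
        h
    })
    list(rho = obs$rho, p = (1 + hits) / (n_iter + 1), n = obs$n,
         degenerate = FALSE)
}

# Resolve a features argument (SrvFeatureSet or matrix) into an
# animal-rowed matrix with unique, stable column identifiers.
featureMatrixByAnimal <- function(features) {
    if (is(features, "SrvFeatureSet")) {
        m <- featureMatrix(features)
        cd <- colData(features)
        if (!is.null(cd$animal)) rownames(m) <- cd$animal
        rd <- rowData(features)
        colnames(m) <- sprintf("%.4f:%.4f:%s", rd$ppm_lo, rd$ppm_hi,
                               rd$label)
        m
    } else {
        m <- as.matrix(features)
        if (is.null(colnames(m)))
            colnames(m) <- sprintf("F%03d", seq_len(ncol(m)))
        m
    }
}

#' Metabolite x phenotype Spearman association map
#'
#' Computes the Spearman correlation and its permutation empirical p-value
#' for every baseline-feature x late-phenotype pair over the shared
#' animals, and masks cells at \code{p < alpha} (no multiple-testing
#' correction by default, mirroring per-cell significance masking; a
#' Benjamini-Hochberg option is available). Per-cell permutation seeds are
#' derived by stable hashing of the master seed with the feature and
#' phenotype identifiers, so subsetting either axis leaves the remaining
#' cells' p-values unchanged.
#'
#' @param features baseline (day-0) features: \linkS4class{SrvFeatureSet}
#'   or matrix with animal row names.
#' @param phenotypes late (day-20) phenotype table: \code{DataFrame} or
#'   data.frame with animal row names.
#' @param alpha significance threshold for the mask.
#' @param n_iter permutations per cell.
#' @param seed master seed.
#' @param correction \code{"none"} (default) or \code{"BH"} (mask on
#'   FDR-adjusted p-values; the \code{p} slot keeps raw values).
#' @return An \linkS4class{AssociationMatrix}.
#' @export
buildAssociationMatrix <- function(features, phenotypes, alpha = 0.05,
                                   n_iter = 999L, seed = 1L,
                                   correction = c("none", "BH")) {
    correction <- match.arg(correction)
    fm <- featureMatrixByAnimal(features)
    ph <- as.data.frame(phenotypes)
    shared <- intersect(rownames(fm), rownames(ph))
    if (!length(shared))
        stop("no shared animal ids between features and phenotypes")
    fm <- fm[shared, , drop = FALSE]
    ph <- ph[shared, , drop = FALSE]
    num <- vapply(ph, is.numeric, logical(1))
    ph <- ph[, num, drop = FALSE]
    nf <- ncol(fm); np <- ncol(ph)
    rho <- p <- nobs <- matrix(NA_real_, nf, np,
                               dimnames = list(colnames(fm), colnames(ph)))
    for (i in seq_len(nf)) {
        for (j in seq_len(np)) {
            cellSeed <- deriveSeed(seed, paste0(colnames(fm)[i], "|",
                                                colnames(ph)[j]))
            res <- spearmanPermP(fm[, i], ph[, j], n_iter = n_iter,
                                 seed = cellSeed)
            rho[i, j] <- res$rho
            p[i, j] <- res$p
            nobs[i, j] <- res$n
        }
    }
    pm <- p
    if (correction == "BH")
        pm[] <- stats::p.adjust(p, method = "BH")
    mask <- !is.na(pm) & pm < alpha
    new("AssociationMatrix", rho = rho, p = p, nObs = nobs, mask = mask,
        alpha = alpha, nIter = as.integer(n_iter), seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("associationRho", "AssociationMatrix", function(x) x@rho)

#' @rdname accessors
#' @export
setMethod("associationP", "AssociationMatrix", function(x) x@p)

#' @rdname accessors
#' @export
setMethod("significanceMask", "AssociationMatrix", function(x) x@mask)

#' @rdname setAlpha
#' @export
setMethod("setAlpha", "AssociationMatrix", function(x, alpha) {
    stopifnot(alpha > 0, alpha <= 1)
    x@alpha <- alpha
    x@mask <- !is.na(x@p) & x@p < alpha
    validObject(x)
    x
})

setMethod("show", "AssociationMatrix", function(object) {
    cat(sprintf(
        "AssociationMatrix: %d features x %d phenotypes (n_iter %d)\n",
        nrow(object@rho), ncol(object@rho), object@nIter))
    cat(sprintf("  significant cells at alpha %.3g: %d of %d\n",
                object@alpha, sum(object@mask),
                length(object@mask)))
})

#' Long-format rendering of an association matrix
#'
#' @param x An \linkS4class{AssociationMatrix}.
#' @return data.frame with feature, phenotype, rho, p, n and significance.
#' @export
associationTable <- function(x) {
    stopifnot(is(x, "AssociationMatrix"))
    data.frame(
        feature = rep(rownames(x@rho), times = ncol(x@rho)),
        phenotype = rep(colnames(x@rho), each = nrow(x@rho)),
        rho = as.vector(x@rho),
        p = as.vector(x@p),
        n = as.vector(x@nObs),
        significant = as.vector(x@mask))
}

#' Screen every phenotype for metabotype predictability
#'
#' Fits one permutation-validated O-PLS regression per (timepoint,
#' phenotype) pair, mirroring a quantitative-phenotype prediction table:
#' each phenotype is predicted from the metabolic features of the given
#' timepoint and the cross-validated \eqn{Q^2_{\hat Y}} is permutation
#' tested. Phenotypes without variance are skipped with a message.
#'
#' @param featuresByTimepoint named list (timepoint -> features) of
#'   \linkS4class{SrvFeatureSet} or animal-rowed matrices.
#' @param phenotypes phenotype table with animal row names.
#' @param k,n_orth,scaling cross-validation settings.
#' @param n_iter permutations per model.
#' @param seed master seed.
#' @return data.frame with timepoint, phenotype, q2, p, significant.
#' @export
phenotypePredictionScreen <- function(featuresByTimepoint, phenotypes,
                                      k = 7L, n_orth = 1L,
                                      scaling = c("uv", "pareto", "none"),
                                      n_iter = 99L, seed = 1L) {
    scaling <- match.arg(scaling)
    ph <- as.data.frame(phenotypes)
    num <- vapply(ph, is.numeric, logical(1))
    ph <- ph[, num, drop = FALSE]
    rows <- list()
    for (tp in names(featuresByTimepoint)) {
        fm <- featureMatrixByAnimal(featuresByTimepoint[[tp]])
        shared <- intersect(rownames(fm), rownames(ph))
        if (!length(shared))
            stop("no shared animal ids at timepoint ", tp)
        X <- fm[shared, , drop = FALSE]
        for (trait in colnames(ph)) {
            y <- ph[shared, trait]
            if (!stats::sd(y) > 0) {
                message("skipping zero-variance phenotype: ", trait)
                next
            }
            v <- validateModel(X, y, k = k, n_orth = n_orth,
                               scaling = scaling, n_iter = n_iter,
                               seed = deriveSeed(seed,
                                                 paste0(tp, "|", trait)))
            rows[[length(rows) + 1L]] <- data.frame(
                timepoint = tp, phenotype = trait,
                q2 = v$summary$q2, p = v$summary$p,
                significant = v$summary$p < 0.05)
        }
    }
    do.call(rbind, rows)
}
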