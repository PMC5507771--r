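# Independent oracles and small fixture builders used across the suite.

# Textbook iterative NIPALS PLS1 with X- and y-deflation, coded
# independently of the package's direct-formula fitter. Returns fitted
# values after `ncomp` components.
nipalsPls1Oracle <- function(X, y, ncomp = 1, scale. = TRUE) {
    xm <- colMeans(X)
    xs <- if (scale.) apply(X, 2, sd) else rep(1, ncol(X))
    xs[xs == 0] <- 1
    Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
    yc <- y - mean(y)
    fitted <- rep(mean(y), nrow(X))
    for (a in seq_len(ncomp)) {
        u <- yc
        w_old <- rep(Inf, ncol(X))
        repeat {  # converges in one pass for a single response
            w <- drop(crossprod(Xc, u))
            w <- w / sqrt(sum(w^2))
            tt <- drop(Xc %*% w)
            if (sum((w - w_old)^2) < 1e-14) break
            w_old <- w
            u <- yc
        }
        p <- drop(crossprod(Xc, tt)) / sum(tt^2)
        q <- sum(yc * tt) / sum(tt^2)
        fitted <- fitted + tt * q
        Xc <- Xc - tcrossprod(tt, p)
        yc <- yc - tt * q
    }
    fitted
}

# All n! permutations of 1..n as rows (n <= 7).
allPerms <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k)
        cbind(k, sub + (sub >= k))))
}

# Trapezoidal integral, for cross-checking AUC and curve areas.
trapzOracle <- function(x, y) {
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# A tiny noiseless spectral fixture: singlet peaks at given column centers,
# per-sample amplitudes, compact support.
singletFixture <- function(n_samples, n_points, centers, amps,
                           width = 3, seed = 1) {
    set.seed(seed)
    m <- matrix(0, n_samples, n_points)
    for (k in seq_along(centers)) {
        a <- amps[[k]]
        for (j in seq(-width, width)) {
            col <- centers[k] + j
            shape <- 1 / (1 + (j / (width / 2))^2)
            m[, col] <- m[, col] + a * shape
        }
    }
    rownames(m) <- sprintf("S%02d", seq_len(n_samples))
    m
}
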