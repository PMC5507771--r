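#' Statistical recoupling of variables (SRV) clustering
#'
#' Computes the correlation landscape between consecutive spectral columns
#' (Pearson across samples; pairs involving a constant column score 0) and
#' merges maximal runs where the landscape stays at or above
#' \code{corr_threshold} into clusters. Cluster boundaries therefore sit at
#' local minima of the landscape. Runs narrower than \code{min_size}
#' columns are discarded, unless \code{singlet_window > 0} and the run's
#' central column is a local maximum of the mean spectrum within that
#' window (a rescued singlet).
#'
#' @param ds A \linkS4class{SpectralSet} with at least 3 samples.
#' @param corr_threshold landscape threshold in (0, 1).
#' @param min_size minimum cluster width in columns (>= 1).
#' @param singlet_window 0 (default) disables singlet rescue.
#' @return data.frame of clusters: \code{start}, \code{end} (1-based
#'   inclusive column indices), \code{ppm_lo}, \code{ppm_hi},
#'   \code{label} (\code{"unassigned"} until annotated).
#' @export
srvCluster <- function(ds, corr_threshold = 0.9, min_size = 3L,
                       singlet_window = 0L) {
    stopifnot(is(ds, "SpectralSet"))
    if (corr_threshold <= 0 || corr_threshold >= 1)
        stop("corr_threshold must lie in (0, 1)")
    if (min_size < 1L) stop("min_size must be >= 1")
    m <- intensityMatrix(ds)
    if (nrow(m) < 3L)
        stop("SRV needs >= 3 samples for stable consecutive correlations")
    p <- ncol(m)
    sds <- apply(m, 2L, stats::sd)
    land <- numeric(p - 1L)
    for (j in seq_len(p - 1L)) {
        land[j] <- if (sds[j] == 0 || sds[j + 1L] == 0) 0
        else stats::cor(m[, j], m[, j + 1L])
    }
    above <- land >= corr_threshold
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    out <- list()
    meanSpec <- colMeans(m)
    for (k in seq_along(runs$values)) {
        if (!runs$values[k]) next
        lo <- starts[k]; hi <- ends[k] + 1L  # run of L edges spans L+1 columns
        width <- hi - lo + 1L
        keep <- width >= min_size
        if (!keep && singlet_window > 0L) {
            ctr <- (lo + hi) %/% 2L
            wlo <- max(1L, ctr - as.integer(singlet_window))
            whi <- min(p, ctr + as.integer(singlet_window))
            keep <- meanSpec[ctr] >= max(meanSpec[wlo:whi])
        }
        if (keep)
            out[[length(out) + 1L]] <- c(start = lo, end = hi)
    }
    ax <- ppm(ds)
    if (!length(out))
        return(data.frame(start = integer(), end = integer(),
                          ppm_lo = numeric(), ppm_hi = numeric(),
                          label = character()))
    df <- as.data.frame(do.call(rbind, out))
    df$ppm_lo <- pmin(ax[df$start], ax[df$end])
    df$ppm_hi <- pmax(ax[df$start], ax[df$end])
    df$label <- "unassigned"
    df[order(df$start), , drop = FALSE]
}

#' Collapse clusters into a feature table
#'
#' Each SRV cluster becomes one feature per sample: the mean (default) or
#' sum of its member columns.
#'
#' @param ds A \linkS4class{SpectralSet}.
#' @param clusters data.frame from \code{\link{srvCluster}} (possibly
#'   annotated).
#' @param mode \code{"mean"} or \code{"sum"}.
#' @return An \linkS4class{SrvFeatureSet}.
#' @export
clusterIntensities <- function(ds, clusters, mode = c("mean", "sum")) {
    stopifnot(is(ds, "SpectralSet"))
    mode <- match.arg(mode)
    if (!nrow(clusters)) stop("empty cluster list")
    m <- intensityMatrix(ds)
    if (any(clusters$start < 1L) || any(clusters$end > ncol(m)))
        stop("clusters out of range for this dataset")
    f <- vapply(seq_len(nrow(clusters)), function(k) {
        cols <- m[, clusters$start[k]:clusters$end[k], drop = FALSE]
        if (mode == "mean") rowMeans(cols) else rowSums(cols)
    }, numeric(nrow(m)))
    f <- matrix(f, nrow = nrow(m))
    rownames(f) <- rownames(m)
    se <- SummarizedExperiment(
        assays = list(features = t(unname(f))),
        rowData = DataFrame(clusters),
        colData = colData(ds))
    colnames(se) <- rownames(m)
    metadata(se)$mode <- mode
    new("SrvFeatureSet", se)
}

#' @rdname accessors
#' @export
setMethod("featureMatrix", "SrvFeatureSet", function(x) {
    m <- t(assay(x, "features"))
    rownames(m) <- colnames(x)
    colnames(m) <- rowData(x)$label
    m
})

#' @rdname accessors
#' @export
setMethod("clusterInfo", "SrvFeatureSet",
          function(x) as.data.frame(rowData(x)))

#' @rdname accessors
#' @export
setMethod("sampleIds", "SrvFeatureSet", function(x) colnames(x))

setMethod("show", "SrvFeatureSet", function(object) {
    rd <- rowData(object)
    cat(sprintf("SrvFeatureSet: %d samples x %d clusters\n",
                ncol(object), nrow(object)))
    ann <- sum(rd$label != "unassigned")
    cat(sprintf("  annotated clusters: %d (%s)\n", ann,
                paste(head(unique(rd$label[rd$label != "unassigned"]), 6),
                      collapse = ", ")))
    if (!is.null(metadata(object)$log_offset))
        cat(sprintf("  log-transformed (offset %.4g)\n",
                    metadata(object)$log_offset))
})

#' Variance-stabilizing log transform of a feature table
#'
#' Applies \code{log(value + offset)} cell-wise. The default offset is 1
#' percent of the positive median of the matrix, recorded in
#' \code{metadata(x)$log_offset}; multiplicative noise becomes approximately
#' additive so feature variance decouples from the mean at high intensity.
#'
#' @param ft An \linkS4class{SrvFeatureSet} or numeric matrix.
#' @param offset positive shift; NULL selects the default.
#' @return The transformed object (same class as the input).
#' @export
logTransform <- function(ft, offset = NULL) {
    m <- if (is(ft, "SrvFeatureSet")) featureMatrix(ft) else as.matrix(ft)
    if (is.null(offset)) {
        pos <- m[m > 0]
        if (!length(pos)) stop("no positive values; supply an offset")
        offset <- 0.01 * stats::median(pos)
    }
    if (offset <= 0 && any(m <= 0))
        stop("offset must be > 0 when values are not all positive")
    bad <- which(m + offset <= 0, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("value + offset <= 0 at [%s, %s]",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    lm <- log(m + offset)
    if (is(ft, "SrvFeatureSet")) {
        SummarizedExperiment::assay(ft, "features", withDimnames = FALSE) <-
            t(unname(lm))
        metadata(ft)$log_offset <- offset
        ft
    } else lm
}

#' Annotate SRV clusters with library metabolite names
#'
#' A cluster is labelled with the metabolite having a peak center inside the
#' cluster's ppm span; when several metabolites qualify the one whose
#' nearest qualifying center lies closest to the cluster midpoint wins,
#' with remaining ties broken lexicographically. Clusters containing no
#' library center stay \code{"unassigned"}.
#'
#' @param clusters cluster data.frame from \code{\link{srvCluster}}.
#' @param library A \linkS4class{MetaboliteLibrary}.
#' @return The cluster data.frame with filled \code{label}s.
#' @export
annotateClusters <- function(clusters, library) {
    stopifnot(is(library, "MetaboliteLibrary"))
    pk <- as.data.frame(library@peaks)
    if (!nrow(pk)) stop("library has no peaks")
    for (k in seq_len(nrow(clusters))) {
        lo <- clusters$ppm_lo[k]; hi <- clusters$ppm_hi[k]
        mid <- (lo + hi) / 2
        inside <- pk[pk$center >= lo & pk$center <= hi, , drop = FALSE]
        if (!nrow(inside)) next
        d <- abs(inside$center - mid)
        best <- inside$name[order(d, inside$name)]
        clusters$label[k] <- best[1L]
    }
    clusters
}
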