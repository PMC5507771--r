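#' Select an alignment reference sample
#'
#' Returns the sample with the highest mean Pearson correlation to all other
#' samples. All-constant spectra are excluded from candidacy; ties are
#' broken by lexicographic sample id.
#'
#' @param ds A \linkS4class{SpectralSet} with at least 2 samples.
#' @return A sample id.
#' @export
selectReference <- function(ds) {
    stopifnot(is(ds, "SpectralSet"))
    m <- intensityMatrix(ds)
    if (nrow(m) < 2L) stop("reference selection needs >= 2 samples")
    ok <- apply(m, 1L, stats::sd) > 0
    if (!any(ok)) stop("all spectra are constant; no reference can be chosen")
    cand <- rownames(m)[ok]
    cc <- stats::cor(t(m[ok, , drop = FALSE]))
    diag(cc) <- NA
    meanCor <- rowMeans(cc, na.rm = TRUE)
    if (length(cand) == 1L) return(cand)
    best <- meanCor >= max(meanCor) - 1e-12
    sort(cand[best])[1L]
}

# Best integer shift of seg against ref within [-max_shift, max_shift] by
# exhaustive Pearson cross-correlation; returns c(shift, gain over s = 0).
bestSegmentShift <- function(seg, ref, max_shift) {
    segCor <- function(s) {
        v <- shiftVector(seg, s)
        if (stats::sd(v) == 0 || stats::sd(ref) == 0) return(-Inf)
        stats::cor(v, ref)
    }
    cors <- vapply(seq.int(-max_shift, max_shift), segCor, numeric(1))
    c0 <- cors[max_shift + 1L]
    best <- which.max(cors)
    shift <- best - max_shift - 1L
    gain <- if (is.finite(c0)) cors[best] - c0 else 0
    c(shift = shift, gain = gain)
}

#' Recursive segment-wise peak alignment (RSPA)
#'
#' Aligns every sample to a reference spectrum by recursive segment
#' shifting: for the current segment the integer shift in
#' \code{[-max_shift, max_shift]} maximizing the Pearson cross-correlation
#' with the reference segment is found exhaustively; if the correlation gain
#' over the unshifted segment exceeds \code{corr_gain_threshold} the shift
#' is applied (edge-padding with the segment edge values); the segment is
#' then split at its lowest-intensity interior point and the halves are
#' processed recursively while they remain at least \code{min_segment}
#' points long.
#'
#' @param ds A \linkS4class{SpectralSet}.
#' @param reference_id sample to align to (default
#'   \code{selectReference(ds)}).
#' @param max_shift maximum |shift| in grid points (must be smaller than
#'   \code{min_segment}).
#' @param min_segment smallest segment length (points, >= 8).
#' @param corr_gain_threshold minimum correlation gain required to accept a
#'   shift; 0 accepts any strict improvement.
#' @return An \linkS4class{AlignmentResult}.
#' @export
rspaAlign <- function(ds, reference_id = selectReference(ds),
                      max_shift = 20L, min_segment = 32L,
                      corr_gain_threshold = 0) {
    stopifnot(is(ds, "SpectralSet"))
    max_shift <- as.integer(max_shift)
    min_segment <- as.integer(min_segment)
    if (max_shift < 0) stop("max_shift must be >= 0")
    if (min_segment < 8L) stop("min_segment must be >= 8 points")
    if (max_shift >= min_segment)
        stop("max_shift must be smaller than the segment length (min_segment)")
    m <- intensityMatrix(ds)
    if (!reference_id %in% rownames(m))
        stop("unknown reference_id: ", reference_id)
    ref <- m[reference_id, ]
    out <- m
    allShifts <- vector("list", nrow(m))
    names(allShifts) <- rownames(m)
    for (i in seq_len(nrow(m))) {
        id <- rownames(m)[i]
        if (id == reference_id) {
            allShifts[[i]] <- data.frame(start = integer(), end = integer(),
                                         shift = integer())
            next
        }
        x <- m[i, ]
        rec <- new.env(parent = emptyenv())
        rec$rows <- list()
        alignSegment <- function(lo, hi) {
            seg <- x[lo:hi]
            bs <- bestSegmentShift(seg, ref[lo:hi], max_shift)
            applied <- 0L
            if (bs[["gain"]] > corr_gain_threshold && bs[["shift"]] != 0L) {
                applied <- as.integer(bs[["shift"]])
                x[lo:hi] <<- shiftVector(seg, applied)
            }
            rec$rows[[length(rec$rows) + 1L]] <-
                data.frame(start = lo, end = hi, shift = applied)
            len <- hi - lo + 1L
            if (len >= 2L * min_segment) {
                cand <- seq.int(lo + min_segment - 1L, hi - min_segment)
                split <- cand[which.min(x[cand])]
                alignSegment(lo, split)
                alignSegment(split + 1L, hi)
            }
        }
        alignSegment(1L, ncol(m))
        out[i, ] <- x
        allShifts[[i]] <- do.call(rbind, rec$rows)
    }
    new("AlignmentResult",
        aligned = setIntensities(ds, out),
        shifts = allShifts,
        referenceId = reference_id,
        maxShift = max_shift)
}

#' @rdname accessors
#' @export
setMethod("alignedSpectra", "AlignmentResult", function(x) x@aligned)

#' @rdname accessors
#' @export
setMethod("shifts", "AlignmentResult", function(x) x@shifts)

setMethod("show", "AlignmentResult", function(object) {
    applied <- vapply(object@shifts,
                      function(s) sum(s$shift != 0L), integer(1))
    cat(sprintf(
        "AlignmentResult: %d samples aligned to '%s' (max_shift %d)\n",
        ncol(object@aligned), object@referenceId, object@maxShift))
    cat(sprintf("  non-zero segment shifts per sample: median %d, max %d\n",
                as.integer(stats::median(applied)), max(applied)))
})

#' Remove chemical-shift regions from a spectral set
#'
#' Drops all axis points with \code{lo <= ppm < hi} for any listed region
#' (half-open convention, so a point exactly at \code{hi} is kept).
#' Standard use: removal of the water and urea windows.
#'
#' @param ds A \linkS4class{SpectralSet}.
#' @param regions list of \code{c(lo, hi)} pairs (or a 2-column matrix).
#' @return A \linkS4class{SpectralSet} with the matching columns removed.
#' @export
excludeRegions <- function(ds, regions) {
    stopifnot(is(ds, "SpectralSet"))
    if (is.matrix(regions))
        regions <- lapply(seq_len(nrow(regions)), function(i) regions[i, ])
    if (!length(regions)) return(ds)
    ax <- ppm(ds)
    drop <- rep(FALSE, length(ax))
    for (rg in regions) {
        if (length(rg) != 2L || rg[1] >= rg[2])
            stop("each region must be c(lo, hi) with lo < hi")
        drop <- drop | (ax >= rg[1] & ax < rg[2])
    }
    if (all(drop)) stop("regions would remove every axis point")
    new("SpectralSet", ds[!drop, ])
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: for each sample the quotients
#' \eqn{q_j = x_j / ref_j} are formed over columns where the reference
#' exceeds a small floor, the dilution estimate is \eqn{median(q)}, and the
#' sample is divided by it. The reference defaults to the column-wise
#' median spectrum of the data. Negative intensities are floored at 0
#' before normalization.
#'
#' Dilution factors are identifiable only up to a global scale (the
#' reference absorbs the cohort-median dilution), so estimates should be
#' compared to known factors after dividing both by their medians.
#'
#' @param x matrix (samples x columns), \linkS4class{SpectralSet} or
#'   \linkS4class{SrvFeatureSet}.
#' @param reference \code{"median"} or an explicit numeric reference vector.
#' @param floor reference entries at or below this value are excluded from
#'   the quotients (default: 1e-8 of the reference maximum).
#' @return list with \code{normalized} (same class as the input),
#'   \code{dilutions} (named per-sample estimates), \code{reference} and
#'   \code{floor}.
#' @examples
#' m <- rbind(a = c(1, 2, 4), b = c(2, 4, 4))
#' pqnNormalize(m, reference = c(1, 2, 4))$dilutions  # a: 1, b: 2
#' @export
setGeneric("pqnNormalize", function(x, reference = "median", floor = NULL)
    standardGeneric("pqnNormalize"))

pqnCore <- function(m, reference, floor) {
    m <- pmax(m, 0)
    ref <- if (identical(reference, "median"))
        apply(m, 2L, stats::median)
    else as.numeric(reference)
    if (length(ref) != ncol(m))
        stop("reference length must match the column count")
    if (is.null(floor)) floor <- 1e-8 * max(ref, 0)
    use <- ref > floor
    if (!any(use))
        stop("reference has no entries above the floor")
    dil <- numeric(nrow(m))
    for (i in seq_len(nrow(m))) {
        q <- m[i, use] / ref[use]
        if (all(q == 0))
            stop("sample '", rownames(m)[i],
                 "' has no overlap with the reference")
        dil[i] <- stats::median(q)
    }
    names(dil) <- rownames(m)
    list(normalized = m / dil, dilutions = dil, reference = ref,
         floor = floor)
}

#' @rdname pqnNormalize
#' @export
setMethod("pqnNormalize", "matrix", function(x, reference = "median",
                                             floor = NULL) {
    pqnCore(x, reference, floor)
})

#' @rdname pqnNormalize
#' @export
setMethod("pqnNormalize", "SpectralSet", function(x, reference = "median",
                                                  floor = NULL) {
    res <- pqnCore(intensityMatrix(x), reference, floor)
    res$normalized <- setIntensities(x, res$normalized)
    res
})

#' @rdname pqnNormalize
#' @export
setMethod("pqnNormalize", "SrvFeatureSet", function(x, reference = "median",
                                                    floor = NULL) {
    res <- pqnCore(featureMatrix(x), reference, floor)
    y <- x
    SummarizedExperiment::assay(y, "features", withDimnames = FALSE) <-
        t(unname(res$normalized))
    metadata(y)$pqn_dilutions <- res$dilutions
    res$normalized <- y
    res
})
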