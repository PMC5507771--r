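#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' SpectralSet: a set of 1H-NMR spectra on a shared ppm axis
#'
#' A \linkS4class{SummarizedExperiment} whose rows are points of a strictly
#' monotone chemical-shift (ppm) axis (stored in \code{rowData(x)$ppm}) and
#' whose columns are samples. The single assay \code{"intensity"} holds the
#' spectral intensities; \code{colData} carries sample metadata
#' (\code{animal}, \code{timepoint}, \code{diet}).
#'
#' @seealso [SpectralSet()] for construction from a samples-in-rows matrix.
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

setValidity("SpectralSet", function(object) {
    msg <- character()
    if (!"intensity" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    ax <- rowData(object)$ppm
    if (is.null(ax)) {
        msg <- c(msg, "rowData must contain a 'ppm' column")
    } else {
        if (anyNA(ax) || !is.numeric(ax))
            msg <- c(msg, "ppm axis must be numeric without NA")
        d <- diff(ax)
        if (length(ax) > 1L && !(all(d > 0) || all(d < 0)))
            msg <- c(msg, "ppm axis must be strictly monotone")
    }
    ids <- colnames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' SrvFeatureSet: SRV cluster intensities per sample
#'
#' A \linkS4class{SummarizedExperiment} whose rows are SRV clusters
#' (\code{rowData}: \code{start}, \code{end} column indices into the parent
#' spectral axis, \code{ppm_lo}, \code{ppm_hi}, \code{label}) and whose
#' columns are samples, with assay \code{"features"}. Transformation
#' provenance (log offset, PQN dilution estimates) lives in
#' \code{metadata(x)}.
#'
#' @export
setClass("SrvFeatureSet", contains = "SummarizedExperiment")

setValidity("SrvFeatureSet", function(object) {
    msg <- character()
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    rd <- rowData(object)
    need <- c("start", "end", "ppm_lo", "ppm_hi", "label")
    if (!all(need %in% colnames(rd))) {
        msg <- c(msg, sprintf("rowData must contain columns: %s",
                              paste(need, collapse = ", ")))
    } else if (nrow(rd)) {
        if (any(rd$start > rd$end))
            msg <- c(msg, "cluster start must be <= end")
        if (is.unsorted(rd$start, strictly = TRUE) && nrow(rd) > 1L)
            msg <- c(msg, "clusters must be sorted by start index")
        if (nrow(rd) > 1L && any(rd$start[-1L] <= rd$end[-nrow(rd)]))
            msg <- c(msg, "clusters must be pairwise disjoint")
    }
    if (any(!is.finite(assay(object, "features"))))
        msg <- c(msg, "feature values must be finite")
    if (length(msg)) msg else TRUE
})

#' MetaboliteLibrary: named metabolites with peak multiplets
#'
#' Holds per-metabolite excretion parameters and per-peak line-shape
#' parameters used by the spectral simulator and by cluster annotation.
#'
#' @slot metabolites \code{DataFrame} with columns \code{name},
#'   \code{baseline_mean}, \code{baseline_sd} (log-scale SD of baseline
#'   excretion), \code{marker_loading} (coupling in [-1, 1] of baseline
#'   excretion to the latent outcome driver) and \code{extremity_loading}
#'   (coupling to the response-magnitude axis shared by extreme responders).
#' @slot peaks \code{DataFrame} with columns \code{name}, \code{center}
#'   (ppm), \code{relative_intensity} (> 0) and \code{half_width}
#'   (ppm, half width at half maximum; > 0).
#' @export
setClass("MetaboliteLibrary",
    representation(metabolites = "DataFrame", peaks = "DataFrame"))

setValidity("MetaboliteLibrary", function(object) {
    msg <- character()
    m <- object@metabolites; p <- object@peaks
    needm <- c("name", "baseline_mean", "baseline_sd", "marker_loading",
               "extremity_loading")
    needp <- c("name", "center", "relative_intensity", "half_width")
    if (!all(needm %in% colnames(m)))
        msg <- c(msg, sprintf("metabolites needs columns: %s",
                              paste(needm, collapse = ", ")))
    if (!all(needp %in% colnames(p)))
        msg <- c(msg, sprintf("peaks needs columns: %s",
                              paste(needp, collapse = ", ")))
    if (!length(msg)) {
        if (anyDuplicated(m$name))
            msg <- c(msg, "duplicate metabolite names")
        if (!all(p$name %in% m$name))
            msg <- c(msg, "peaks reference unknown metabolites")
        if (!all(m$name %in% p$name))
            msg <- c(msg, "every metabolite needs at least one peak")
        if (any(p$half_width <= 0))
            msg <- c(msg, "half_width must be > 0")
        if (any(p$relative_intensity <= 0))
            msg <- c(msg, "relative_intensity must be > 0")
        if (any(abs(m$marker_loading) > 1))
            msg <- c(msg, "marker_loading must lie in [-1, 1]")
        if (any(m$baseline_mean <= 0) || any(m$baseline_sd < 0))
            msg <- c(msg, "baseline_mean must be > 0 and baseline_sd >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticCohort: simulated spectra, phenotypes and ground truth
#'
#' @slot spectra \code{SimpleList} of \linkS4class{SpectralSet}, one per
#'   timepoint, named by day label.
#' @slot phenotypes \code{DataFrame} of quantitative traits, one row per
#'   animal, rownames = animal ids.
#' @slot groundTruth list with the latent driver \code{z}, response-magnitude
#'   axis \code{r}, planted \code{group} labels, true \code{concentrations}
#'   (per-timepoint matrices), true \code{dilutions} and \code{jitters}
#'   (per-timepoint vectors).
#' @slot config the \code{cohortConfig()} list the cohort was generated from.
#' @export
setClass("SyntheticCohort",
    representation(spectra = "SimpleList", phenotypes = "DataFrame",
                   groundTruth = "list", config = "list"))

setValidity("SyntheticCohort", function(object) {
    msg <- character()
    ids <- rownames(object@phenotypes)
    for (tp in names(object@spectra)) {
        ss <- object@spectra[[tp]]
        if (!identical(colData(ss)$animal, ids))
            msg <- c(msg, sprintf(
                "timepoint %s: animal ids do not match phenotype rows", tp))
    }
    gt <- object@groundTruth
    if (!is.null(gt$z) && !identical(names(gt$z), ids))
        msg <- c(msg, "ground-truth z must be named by the animal ids")
    if (length(msg)) msg else TRUE
})

#' AlignmentResult: RSPA output
#'
#' @slot aligned aligned \linkS4class{SpectralSet}, same shape as the input.
#' @slot shifts list (one element per sample) of data.frames with columns
#'   \code{start}, \code{end}, \code{shift}: the integer shift applied to
#'   each segment.
#' @slot referenceId the sample used as alignment reference.
#' @slot maxShift the configured maximum shift (points).
#' @export
setClass("AlignmentResult",
    representation(aligned = "SpectralSet", shifts = "list",
                   referenceId = "character", maxShift = "integer"))

setValidity("AlignmentResult", function(object) {
    msg <- character()
    for (s in object@shifts)
        if (nrow(s) && any(abs(s$shift) > object@maxShift))
            msg <- c(msg, "recorded shift exceeds maxShift")
    if (!object@referenceId %in% colnames(object@aligned))
        msg <- c(msg, "referenceId must be one of the sample ids")
    if (length(msg)) msg else TRUE
})

#' OplsModel: an O-PLS(-DA) model with one predictive component
#'
#' Stores centering/scaling, the predictive component (weights \code{w},
#' loadings \code{p}, y-loading \code{q}), the orthogonal components
#' (columns of \code{orthoWeights}/\code{orthoLoadings}) and the training
#' scores. The class covers plain PLS1 as the zero-orthogonal-component
#' special case.
#'
#' @slot xMean,xScale feature centering and scaling vectors.
#' @slot yMean training response mean.
#' @slot weights,loadings predictive weight and loading vectors
#'   (\code{weights} has unit norm).
#' @slot yLoading scalar y-loading of the predictive component.
#' @slot orthoWeights,orthoLoadings p x nOrtho matrices (possibly 0 columns);
#'   each orthogonal weight vector has unit norm and is orthogonal to
#'   \code{weights}.
#' @slot scores,orthoScores training predictive and orthogonal scores.
#' @slot r2x,r2y fractions of X and y variance explained.
#' @slot nOrtho number of orthogonal components actually fitted.
#' @slot scaling one of "uv", "pareto", "none".
#' @slot yLevels for discriminant models, the two class labels in the order
#'   encoded as 0 and 1; \code{NA_character_} for regression.
#' @export
setClass("OplsModel",
    representation(xMean = "numeric", xScale = "numeric", yMean = "numeric",
                   weights = "numeric", loadings = "numeric",
                   yLoading = "numeric",
                   orthoWeights = "matrix", orthoLoadings = "matrix",
                   scores = "numeric", orthoScores = "matrix",
                   r2x = "numeric", r2y = "numeric", nOrtho = "integer",
                   scaling = "character", yLevels = "character"))

setValidity("OplsModel", function(object) {
    msg <- character()
    tol <- 1e-8
    if (abs(sqrt(sum(object@weights^2)) - 1) > tol)
        msg <- c(msg, "predictive weights must have unit norm")
    if (ncol(object@orthoWeights)) {
        nrm <- sqrt(colSums(object@orthoWeights^2))
        if (any(abs(nrm - 1) > tol))
            msg <- c(msg, "orthogonal weights must have unit norm")
        dots <- abs(crossprod(object@orthoWeights, object@weights))
        if (any(dots > tol))
            msg <- c(msg, "orthogonal weights must be orthogonal to w")
    }
    if (object@r2y < -tol || object@r2y > 1 + tol)
        msg <- c(msg, "r2y must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' CvResult: k-fold cross-validation of an O-PLS(-DA) model
#'
#' @slot folds integer fold assignment per sample (1..k).
#' @slot yhat cross-validated (held-out) predictions, one per sample.
#' @slot cvScores cross-validated predictive scores, one per sample.
#' @slot press predicted residual sum of squares, pooled over folds.
#' @slot tss total sum of squares about the full-sample mean of y.
#' @slot q2 1 - press/tss (Q2_Yhat).
#' @slot k number of folds.
#' @export
setClass("CvResult",
    representation(folds = "integer", yhat = "numeric", cvScores = "numeric",
                   press = "numeric", tss = "numeric", q2 = "numeric",
                   k = "integer"))

setValidity("CvResult", function(object) {
    msg <- character()
    if (object@press < 0) msg <- c(msg, "press must be >= 0")
    if (object@q2 > 1 + 1e-12) msg <- c(msg, "q2 cannot exceed 1")
    if (length(object@yhat) != length(object@folds))
        msg <- c(msg, "yhat and folds lengths differ")
    if (anyNA(object@yhat))
        msg <- c(msg, "every sample must be predicted exactly once")
    if (length(msg)) msg else TRUE
})

#' PermutationTest: empirical p-value for a model statistic
#'
#' @slot observed the statistic on the unpermuted data.
#' @slot permuted statistic values for each permuted response.
#' @slot nIter number of permutations.
#' @slot pValue (1 + #\{permuted >= observed\}) / (nIter + 1).
#' @slot seed the seed the permutation stream started from.
#' @export
setClass("PermutationTest",
    representation(observed = "numeric", permuted = "numeric",
                   nIter = "integer", pValue = "numeric", seed = "integer"))

setValidity("PermutationTest", function(object) {
    msg <- character()
    if (length(object@permuted) != object@nIter)
        msg <- c(msg, "permuted vector length must equal nIter")
    lo <- 1 / (object@nIter + 1)
    if (object@pValue < lo - 1e-12 || object@pValue > 1 + 1e-12)
        msg <- c(msg, "pValue must lie in [1/(nIter+1), 1]")
    if (length(msg)) msg else TRUE
})

#' RocResult: ROC curve and AUC of cross-validated scores
#'
#' @slot thresholds decision thresholds (unique scores, decreasing, with
#'   sentinels at both ends).
#' @slot fpr,tpr false/true positive rates along the thresholds.
#' @slot auc area under the curve by the rank (Mann-Whitney) formulation,
#'   ties counting one half.
#' @export
setClass("RocResult",
    representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                   auc = "numeric"))

setValidity("RocResult", function(object) {
    msg <- character()
    if (object@auc < 0 || object@auc > 1)
        msg <- c(msg, "auc must lie in [0, 1]")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
        msg <- c(msg, "fpr and tpr must be non-decreasing")
    n <- length(object@thresholds)
    if (length(object@fpr) != n || length(object@tpr) != n)
        msg <- c(msg, "thresholds, fpr, tpr must be aligned")
    if (length(msg)) msg else TRUE
})

#' AssociationMatrix: feature x phenotype Spearman map
#'
#' @slot rho Spearman rank correlations (NA where degenerate).
#' @slot p permutation empirical p-values (two-sided on |rho|).
#' @slot nObs pairwise-complete n per cell.
#' @slot mask logical, \code{p < alpha} (FALSE where p is NA).
#' @slot alpha significance threshold.
#' @slot nIter permutations per cell.
#' @slot seed master seed for the per-cell seed derivation.
#' @export
setClass("AssociationMatrix",
    representation(rho = "matrix", p = "matrix", nObs = "matrix",
                   mask = "matrix", alpha = "numeric", nIter = "integer",
                   seed = "integer"))

setValidity("AssociationMatrix", function(object) {
    msg <- character()
    if (!identical(dim(object@rho), dim(object@p)) ||
        !identical(dim(object@rho), dim(object@mask)))
        msg <- c(msg, "rho, p and mask must share dimensions")
    if (any(abs(object@rho) > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "|rho| cannot exceed 1")
    expect <- !is.na(object@p) & object@p < object@alpha
    if (!identical(as.vector(object@mask), as.vector(expect)))
        msg <- c(msg, "mask must equal p < alpha (NA-safe)")
    if (length(msg)) msg else TRUE
})

#' StratificationResult: 2-SD disease sub-group labels
#'
#' @slot labels character vector of group labels per animal (named by id);
#'   levels LNG, L-IGT, Ob-IGT, midgroup.
#' @slot thresholds list with mean, sd and mean + k*sd per stratifying trait
#'   plus the lower-rule cutoffs used for LNG.
#' @slot rule human-readable statement of the rule actually applied.
#' @slot kSd the SD multiplier used (default 2).
#' @export
setClass("StratificationResult",
    representation(labels = "character", thresholds = "list",
                   rule = "character", kSd = "numeric"))

setValidity("StratificationResult", function(object) {
    ok <- all(object@labels %in% c("LNG", "L-IGT", "Ob-IGT", "midgroup"))
    if (!ok) "labels must be LNG, L-IGT, Ob-IGT or midgroup" else TRUE
})
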