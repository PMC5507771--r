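#' Construct a SpectralSet
#'
#' @param intensity numeric matrix with one row per sample and one column per
#'   ppm point (the orientation of the delimited-text interchange format).
#' @param ppm strictly monotone numeric chemical-shift axis, one value per
#'   column of \code{intensity}.
#' @param sampleData optional \code{DataFrame}/data.frame of sample metadata
#'   (e.g. \code{animal}, \code{timepoint}, \code{diet}), one row per sample.
#' @param sampleIds sample identifiers; default taken from
#'   \code{rownames(intensity)}.
#'
#' @return A \linkS4class{SpectralSet}.
#' @examples
#' ax <- seq(0.5, 9.5, length.out = 64)
#' m <- matrix(runif(2 * 64), nrow = 2,
#'             dimnames = list(c("a", "b"), NULL))
#' ss <- SpectralSet(m, ax)
#' dim(intensityMatrix(ss))
#' @export
SpectralSet <- function(intensity, ppm, sampleData = NULL,
                        sampleIds = rownames(intensity)) {
    intensity <- as.matrix(intensity)
    if (is.null(sampleIds))
        sampleIds <- sprintf("S%02d", seq_len(nrow(intensity)))
    if (length(ppm) != ncol(intensity))
        stop("length(ppm) must equal ncol(intensity)")
    if (is.null(sampleData))
        sampleData <- DataFrame(row.names = sampleIds)
    else {
        sampleData <- DataFrame(sampleData)
        rownames(sampleData) <- sampleIds
    }
    se <- SummarizedExperiment(
        assays = list(intensity = t(unname(intensity))),
        rowData = DataFrame(ppm = as.numeric(ppm)),
        colData = sampleData)
    colnames(se) <- sampleIds
    new("SpectralSet", se)
}

#' @rdname accessors
#' @export
setMethod("ppm", "SpectralSet", function(x) rowData(x)$ppm)

#' @rdname accessors
#' @export
setMethod("intensityMatrix", "SpectralSet", function(x) {
    m <- t(assay(x, "intensity"))
    rownames(m) <- colnames(x)
    m
})

#' @rdname accessors
#' @export
setMethod("sampleIds", "SpectralSet", function(x) colnames(x))

setMethod("show", "SpectralSet", function(object) {
    ax <- ppm(object)
    cat(sprintf("SpectralSet: %d samples x %d points, %.2f-%.2f ppm\n",
                ncol(object), nrow(object), min(ax), max(ax)))
    cd <- colData(object)
    if (ncol(cd))
        cat("  sample metadata:", paste(colnames(cd), collapse = ", "), "\n")
})

# Replace the intensity matrix (samples x points), keeping everything else.
setIntensities <- function(x, m) {
    SummarizedExperiment::assay(x, "intensity", withDimnames = FALSE) <-
        t(unname(m))
    x
}

#' Read / write the spectral interchange format
#'
#' Plain delimited text: the first row holds the ppm axis (first field
#' \code{"ppm"}), subsequent rows hold a sample id followed by intensities.
#'
#' @param x A \linkS4class{SpectralSet}.
#' @param file path to read from / write to.
#' @param sep field separator (default tab).
#' @return \code{readSpectralSet} returns a \linkS4class{SpectralSet};
#'   \code{writeSpectralSet} returns \code{file} invisibly.
#' @export
writeSpectralSet <- function(x, file, sep = "\t") {
    m <- intensityMatrix(x)
    hdr <- paste(c("ppm", format(ppm(x), digits = 10, trim = TRUE)),
                 collapse = sep)
    rows <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i],
                format(m[i, ], digits = 10, trim = TRUE)), collapse = sep),
        character(1))
    writeLines(c(hdr, rows), file)
    invisible(file)
}

#' @rdname writeSpectralSet
#' @export
readSpectralSet <- function(file, sep = "\t") {
    ln <- readLines(file)
    if (length(ln) < 2L) stop("spectral file needs an axis row and >= 1 sample")
    parts <- strsplit(ln, sep, fixed = TRUE)
    ax <- as.numeric(parts[[1]][-1L])
    ids <- vapply(parts[-1L], `[`, character(1), 1L)
    m <- do.call(rbind, lapply(parts[-1L], function(p) as.numeric(p[-1L])))
    rownames(m) <- ids
    SpectralSet(m, ax)
}

#' Write / read a feature or phenotype table as delimited text
#'
#' Feature tables use a header of cluster labels \code{"ppm_lo:ppm_hi:name"};
#' the first column holds sample ids.
#'
#' @param x An \linkS4class{SrvFeatureSet} or a data.frame-like table with
#'   row names.
#' @param file path.
#' @param sep field separator.
#' @export
writeFeatureTable <- function(x, file, sep = "\t") {
    rd <- rowData(x)
    hdr <- sprintf("%.4f:%.4f:%s", rd$ppm_lo, rd$ppm_hi, rd$label)
    m <- featureMatrix(x)
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    colnames(df) <- c("sample", hdr)
    utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeFeatureTable
#' @export
writePhenotypeTable <- function(x, file, sep = "\t") {
    df <- as.data.frame(x)
    df <- cbind(animal = rownames(df), df)
    utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeFeatureTable
#' @export
readPhenotypeTable <- function(file, sep = "\t") {
    df <- utils::read.table(file, sep = sep, header = TRUE,
                            check.names = FALSE)
    rownames(df) <- df$animal
    DataFrame(df[, setdiff(colnames(df), "animal"), drop = FALSE])
}
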