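#' Construct a metabolite library
#'
#' @param metabolites data.frame/DataFrame with columns \code{name},
#'   \code{baseline_mean} (arbitrary concentration units),
#'   \code{baseline_sd} (SD of log baseline excretion across animals),
#'   \code{marker_loading} (coupling in [-1, 1] to the latent outcome
#'   driver), \code{extremity_loading} (coupling to the response-magnitude
#'   axis; optional, default 0) and \code{hfd_logfc} (log fold-change of
#'   excretion under the dietary challenge; optional, default 0).
#' @param peaks data.frame/DataFrame with columns \code{name}, \code{center}
#'   (ppm), \code{relative_intensity} and \code{half_width} (ppm, HWHM).
#' @return A \linkS4class{MetaboliteLibrary}.
#' @export
MetaboliteLibrary <- function(metabolites, peaks) {
    metabolites <- DataFrame(metabolites)
    peaks <- DataFrame(peaks)
    if (is.null(metabolites$extremity_loading))
        metabolites$extremity_loading <- 0
    if (is.null(metabolites$hfd_logfc))
        metabolites$hfd_logfc <- 0
    new("MetaboliteLibrary", metabolites = metabolites, peaks = peaks)
}

#' @rdname accessors
#' @export
setMethod("metaboliteNames", "MetaboliteLibrary",
          function(x) as.character(x@metabolites$name))

#' @rdname accessors
#' @export
setMethod("peakTable", "MetaboliteLibrary",
          function(x) as.data.frame(x@peaks))

setMethod("show", "MetaboliteLibrary", function(object) {
    cat(sprintf("MetaboliteLibrary: %d metabolites, %d peaks\n",
                nrow(object@metabolites), nrow(object@peaks)))
    cat(" ", paste(metaboliteNames(object), collapse = ", "), "\n")
})

#' Default urinary metabolite library
#'
#' A small library of mouse-urine metabolites with literature-plausible
#' chemical shifts: the microbial-host methylamine pathway (TMA, DMA, MMA,
#' TMAO and their dietary precursor choline), the gut-microbial
#' co-metabolites hippurate and phenylacetylglycine (PAG), the TCA-cycle
#' intermediates citrate and 2-oxoglutarate, and creatinine. Marker loadings
#' encode the planted prodromal structure: methylamine excretion at baseline
#' couples positively to the latent disease driver (TMA negatively),
#' hippurate and PAG additionally mark response extremity. Baseline means
#' are order-of-magnitude choices in arbitrary intensity units, not measured
#' values.
#'
#' @param half_width default Lorentzian half width at half maximum (ppm).
#' @return A \linkS4class{MetaboliteLibrary}.
#' @examples
#' lib <- defaultMetaboliteLibrary()
#' metaboliteNames(lib)
#' @export
defaultMetaboliteLibrary <- function(half_width = 0.012) {
    metabolites <- data.frame(
        name = c("TMAO", "TMA", "DMA", "MMA", "choline", "hippurate",
                 "PAG", "citrate", "2-oxoglutarate", "creatinine",
                 "lactate", "alanine", "succinate", "fumarate", "glycine",
                 "formate", "allantoin", "N-acetylglycoprotein",
                 "trigonelline", "taurine", "creatine", "acetate",
                 "3-hydroxybutyrate", "valine", "tyrosine", "histidine"),
        baseline_mean = c(5, 2, 2.5, 1.2, 2, 4, 2.5, 3, 2.5, 6,
                          4, 2, 2.5, 1, 5, 1.5, 3, 3, 1.5,
                          5, 2.5, 2, 1.5, 1.5, 1.2, 1.2),
        baseline_sd = rep(0.3, 26),
        marker_loading = c(1.0, -0.35, 0.55, 0.5, 0.5, 0.45,
                           0.4, 0.15, 0.1, 0,
                           0, 0, 0.1, 0.1, 0, 0, 0, 0, 0,
                           0, 0, 0, 0, 0, 0, 0),
        extremity_loading = c(0, 0, 0, 0, 0, -2.0, -1.5, 0, 0, 0,
                              0, 0, 0, 0, 0, 0, 0, 0, 0,
                              0, 0, 0, 0, 0, 0, 0),
        hfd_logfc = c(0.5, 0.35, 0.4, 0.3, -0.2, -0.3, 0.15, 0, 0, 0,
                      0, 0, 0, 0, -0.1, 0, 0, 0.1, 0,
                      0, 0, 0, 0, 0, 0, 0))
    peaks <- data.frame(
        name = c("TMAO", "TMA", "DMA", "MMA",
                 "choline", "choline", "choline",
                 "hippurate", "hippurate", "hippurate", "hippurate",
                 "PAG", "PAG", "PAG", "PAG",
                 "citrate", "citrate",
                 "2-oxoglutarate", "2-oxoglutarate",
                 "creatinine", "creatinine",
                 "lactate", "lactate", "alanine", "succinate", "fumarate",
                 "glycine", "formate", "allantoin",
                 "N-acetylglycoprotein",
                 "trigonelline", "trigonelline", "trigonelline",
                 "taurine", "creatine", "creatine", "acetate",
                 "3-hydroxybutyrate", "valine", "valine",
                 "tyrosine", "tyrosine", "histidine", "histidine"),
        center = c(3.27, 2.88, 2.72, 2.61,
                   3.21, 3.52, 4.07,
                   7.84, 7.64, 7.55, 3.97,
                   7.43, 7.37, 3.75, 3.68,
                   2.54, 2.66,
                   2.45, 3.01,
                   3.05, 4.06,
                   1.33, 4.12, 1.48, 2.41, 6.52,
                   3.57, 8.46, 5.39,
                   2.04,
                   9.12, 8.84, 8.08,
                   3.43, 3.93, 3.04, 1.92,
                   1.20, 1.04, 0.99,
                   6.90, 7.19, 7.07, 8.60),
        relative_intensity = c(1, 1, 1, 1,
                               1, 0.22, 0.22,
                               0.5, 0.25, 0.5, 0.5,
                               0.5, 0.3, 0.3, 0.5,
                               0.5, 0.5,
                               0.67, 0.33,
                               0.6, 0.4,
                               0.75, 0.25, 0.75, 1, 1,
                               1, 1, 0.8,
                               1,
                               0.4, 0.3, 0.3,
                               1, 0.6, 0.4, 1,
                               0.8, 0.5, 0.5,
                               0.5, 0.5, 0.5, 0.5),
        half_width = half_width)
    MetaboliteLibrary(metabolites, peaks)
}
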