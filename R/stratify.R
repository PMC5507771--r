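#' Stratify a cohort by the 2-SD rule on glycemia and body weight
#'
#' Applies the extreme-responder rule: with \eqn{T = mean + k \cdot SD}
#' (sample SD, n-1 denominator) computed per trait over the cohort,
#' \itemize{
#'   \item Ob-IGT: cumulative glycemia > T_g and body weight > T_b;
#'   \item L-IGT: cumulative glycemia > T_g and body weight <= T_b;
#'   \item LNG: neither threshold exceeded and the configured lower rule
#'     holds (default: at or below the 0.10 sample quantile on both traits,
#'     so non-responders form a small tail group comparable in size to the
#'     2-SD extremes — the numeric boundary is a configuration choice, not
#'     a measured fact);
#'   \item midgroup: everything else.
#' }
#' Zero SD in a trait means no animal can exceed its threshold; this is
#' returned with a warning, not an error.
#'
#' @param pheno phenotype table (\code{DataFrame}/data.frame) with animal
#'   row names.
#' @param glycemia_col,bw_col column names of cumulative glycemia and body
#'   weight.
#' @param k_sd SD multiplier (default 2).
#' @param lng_rule list describing the lower rule: \code{list(type =
#'   "quantile", prob = q)} (default q = 0.10), \code{list(type =
#'   "median")}, or \code{list(type = "absolute", glycemia = g0, bw = b0)}.
#' @return A \linkS4class{StratificationResult}.
#' @export
stratifyPhenotypes <- function(pheno, glycemia_col = "CG", bw_col = "BW",
                               k_sd = 2,
                               lng_rule = list(type = "quantile",
                                               prob = 0.10)) {
    ph <- as.data.frame(pheno)
    for (col in c(glycemia_col, bw_col)) {
        if (!col %in% colnames(ph)) stop("column not found: ", col)
        if (sum(is.finite(ph[[col]])) < 3L)
            stop("column ", col, " needs >= 3 finite values")
    }
    g <- ph[[glycemia_col]]; b <- ph[[bw_col]]
    mg <- mean(g); sg <- stats::sd(g)
    mb <- mean(b); sb <- stats::sd(b)
    if (sg == 0 || sb == 0)
        warning("zero SD in a stratifying trait; ",
                "no animal exceeds its threshold")
    tg <- mg + k_sd * sg
    tb <- mb + k_sd * sb
    lower <- switch(lng_rule$type,
        median = list(g = stats::median(g), b = stats::median(b),
                      text = "at or below the sample median on both traits"),
        quantile = list(g = stats::quantile(g, lng_rule$prob, names = FALSE),
                        b = stats::quantile(b, lng_rule$prob, names = FALSE),
                        text = sprintf("at or below the %.2f quantile",
                                       lng_rule$prob)),
        absolute = list(g = lng_rule$glycemia, b = lng_rule$bw,
                        text = "at or below absolute cutoffs"),
        stop("unknown lng_rule type: ", lng_rule$type))
    lab <- ifelse(g > tg & b > tb, "Ob-IGT",
           ifelse(g > tg, "L-IGT",
           ifelse(g <= lower$g & b <= lower$b, "LNG", "midgroup")))
    names(lab) <- rownames(ph)
    rule <- sprintf(
        paste0("Ob-IGT: %s > mean+%g*SD (%.4g) and %s > mean+%g*SD (%.4g); ",
               "L-IGT: %s above threshold only; LNG: %s; else midgroup"),
        glycemia_col, k_sd, tg, bw_col, k_sd, tb, glycemia_col, lower$text)
    new("StratificationResult",
        labels = lab,
        thresholds = list(
            glycemia = c(mean = mg, sd = sg, threshold = tg),
            bw = c(mean = mb, sd = sb, threshold = tb),
            lower = c(glycemia = lower$g, bw = lower$b)),
        rule = rule, kSd = k_sd)
}

#' @rdname accessors
#' @export
setMethod("groupLabels", "StratificationResult", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("thresholds", "StratificationResult", function(x) x@thresholds)

setMethod("show", "StratificationResult", function(object) {
    tab <- table(factor(object@labels,
                        levels = c("LNG", "L-IGT", "Ob-IGT", "midgroup")))
    cat(sprintf("StratificationResult (k = %g SD): %s\n", object@kSd,
                paste(names(tab), tab, sep = "=", collapse = ", ")))
    cat("  rule:", object@rule, "\n")
})

#' Turn stratification labels into a binary contrast for O-PLS-DA
#'
#' @param result A \linkS4class{StratificationResult}.
#' @param contrast one of \code{"extreme"} (LNG + L-IGT + Ob-IGT vs
#'   midgroup), \code{"lean_vs_ob"} (LNG + L-IGT vs Ob-IGT),
#'   \code{"ng_vs_igt"} (LNG vs L-IGT + Ob-IGT) or \code{"lng_vs_ligt"}.
#' @return data.frame with \code{animal}, \code{group} (original label) and
#'   \code{class} (the contrast side), restricted to the contrasted
#'   animals.
#' @export
groupsToTargets <- function(result,
                            contrast = c("extreme", "lean_vs_ob",
                                         "ng_vs_igt", "lng_vs_ligt")) {
    stopifnot(is(result, "StratificationResult"))
    contrast <- match.arg(contrast)
    lab <- result@labels
    sides <- switch(contrast,
        extreme = list(extreme = c("LNG", "L-IGT", "Ob-IGT"),
                       midgroup = "midgroup"),
        lean_vs_ob = list(lean = c("LNG", "L-IGT"), obese = "Ob-IGT"),
        ng_vs_igt = list(NG = "LNG", IGT = c("L-IGT", "Ob-IGT")),
        lng_vs_ligt = list(LNG = "LNG", `L-IGT` = "L-IGT"))
    cls <- rep(NA_character_, length(lab))
    for (side in names(sides))
        cls[lab %in% sides[[side]]] <- side
    keep <- !is.na(cls)
    for (side in names(sides))
        if (!any(cls == side, na.rm = TRUE))
            stop(sprintf("contrast '%s': class '%s' is empty",
                         contrast, side))
    data.frame(animal = names(lab)[keep], group = lab[keep],
               class = cls[keep], row.names = NULL)
}
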