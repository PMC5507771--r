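#' Configuration for the synthetic isogenic cohort
#'
#' Returns a validated list of simulator parameters. Defaults describe a
#' desk-scale analogue of a 50-animal isogenic mouse cohort with urine
#' collections at days 0, 1, 2 and 20 of a dietary challenge: each animal
#' carries a latent disease driver z ~ N(0, 1); a few animals are planted as
#' extreme responders (z boosted well beyond 2 SD) or as non-responders
#' (z pushed low); baseline metabolite excretion couples to z through the
#' library's marker loadings; late phenotypes are monotone functions of z
#' plus independent noise.
#'
#' @param n_animals cohort size (>= 14 so that 7-fold CV keeps >= 2 per
#'   fold).
#' @param timepoints day labels of the urine collections.
#' @param n_ppm_points,ppm_range spectral grid.
#' @param noise_sd additive spectral noise SD (intensity units).
#' @param baseline_amplitude scale of the smooth spectral baseline.
#' @param dilution_log_sd SD of log urinary dilution factors.
#' @param jitter_max maximum |integer shift| (grid points) applied per
#'   spectrum, emulating chemical-shift variation.
#' @param effect_size latent-driver to metabolite coupling. The default is
#'   calibrated so the planted Spearman correlation between baseline TMAO
#'   excretion and day-20 cumulative glycemia is about 0.6.
#' @param pheno_noise multiplier on all phenotype noise SDs (0 = noiseless
#'   phenotypes, used by exact-recovery tests).
#' @param within_sd SD of per-timepoint log-concentration deviations around
#'   each animal's baseline excretion (day 0 is the baseline itself).
#' @param group_fractions named fractions of planted LNG, L-IGT and Ob-IGT
#'   animals. L-IGT can only be planted with \code{n_drivers = 2}.
#' @param n_drivers 1 (single latent driver, default) or 2 (independent
#'   glycemia and adiposity drivers, for stratification studies).
#' @param ob_boost,lng_boost ranges of the planted |z| for extreme
#'   responders and non-responders.
#' @param gtt_times IP-GTT sampling times (minutes), must start at 0.
#' @param tail_cutoff Lorentzian support cutoff in half-widths (Inf = full
#'   tails).
#' @param seed master seed; every draw of the simulation flows from it.
#' @return A named list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(n_animals = 50L,
                         timepoints = c(0, 1, 2, 20),
                         n_ppm_points = 2000L,
                         ppm_range = c(0.5, 9.5),
                         noise_sd = 0.05,
                         baseline_amplitude = 0.02,
                         dilution_log_sd = 0.2,
                         jitter_max = 3L,
                         effect_size = 0.19,
                         pheno_noise = 1,
                         within_sd = 0.15,
                         group_fractions = c(LNG = 0.08, `L-IGT` = 0,
                                             `Ob-IGT` = 0.08),
                         n_drivers = 1L,
                         ob_boost = c(3.2, 3.8),
                         lng_boost = c(2.0, 2.4),
                         gtt_times = c(0, 15, 30, 75),
                         tail_cutoff = Inf,
                         seed = 1L) {
    cfg <- list(n_animals = as.integer(n_animals),
                timepoints = timepoints, n_ppm_points = as.integer(n_ppm_points),
                ppm_range = ppm_range, noise_sd = noise_sd,
                baseline_amplitude = baseline_amplitude,
                dilution_log_sd = dilution_log_sd,
                jitter_max = as.integer(jitter_max),
                effect_size = effect_size, pheno_noise = pheno_noise,
                within_sd = within_sd, group_fractions = group_fractions,
                n_drivers = as.integer(n_drivers),
                ob_boost = ob_boost, lng_boost = lng_boost,
                gtt_times = gtt_times, tail_cutoff = tail_cutoff,
                seed = as.integer(seed))
    if (cfg$n_animals < 14L)
        stop("n_animals must be >= 14 (7-fold CV needs >= 2 per fold)")
    if (cfg$ppm_range[1] >= cfg$ppm_range[2])
        stop("ppm_range must satisfy low < high")
    sds <- c(cfg$noise_sd, cfg$dilution_log_sd, cfg$within_sd,
             cfg$pheno_noise)
    if (any(sds < 0)) stop("all SDs must be >= 0")
    if (cfg$jitter_max < 0) stop("jitter_max must be >= 0")
    need <- c("LNG", "L-IGT", "Ob-IGT")
    if (!all(need %in% names(cfg$group_fractions)))
        stop("group_fractions must name LNG, L-IGT and Ob-IGT")
    counts <- round(cfg$group_fractions[need] * cfg$n_animals)
    if (sum(counts) < 1L)
        stop("infeasible group fractions: fewer than 1 planted extreme")
    if (counts[["L-IGT"]] > 0 && cfg$n_drivers < 2L)
        stop("planting L-IGT animals requires n_drivers = 2")
    if (0.05 * cfg$n_ppm_points < 1)
        stop("n_ppm_points too small")
    class(cfg) <- c("cohortConfig", "list")
    cfg
}

# Dietary response ramp: 0 at day 0, saturating towards 1.
hfdRamp <- function(day) 1 - exp(-day / 1.5)

# Shift a vector by s integer points (positive = towards higher indices),
# padding with the edge value. Not circular, so alignment recovery is exact.
shiftVector <- function(x, s) {
    n <- length(x)
    s <- as.integer(s)
    if (s == 0L || abs(s) >= n) return(x)
    if (s > 0L) c(rep(x[1L], s), x[seq_len(n - s)])
    else c(x[seq.int(1L - s, n)], rep(x[n], -s))
}

#' Derive quantitative phenotypes from tolerance-test curves and weights
#'
#' Computes the standard IP-GTT summaries: cumulative glycemia (CG) as the
#' trapezoidal area under the glycemia curve, its above-baseline version
#' (dG = CG - G(0) x duration), the analogous insulin summaries (CI, dI),
#' the glycemia-to-insulinemia ratio IcumG = CG / CI, the disappearance-rate
#' proxy K = (G15 - Glast) / (tlast - 15), and organ-to-body-weight ratios.
#'
#' @param glycemia n x T matrix of glycemia (mM), one row per animal,
#'   rownames = animal ids; columns follow \code{times}.
#' @param times sampling times in minutes; must start at 0.
#' @param insulin optional n x T insulinemia matrix on the same times.
#' @param organ_weights optional n x p matrix of organ weights (g).
#' @param bw optional body-weight vector (g), required with
#'   \code{organ_weights}.
#' @return \code{DataFrame} of derived traits, one row per animal.
#' @examples
#' g <- matrix(c(5, 10, 5), nrow = 1, dimnames = list("a", NULL))
#' derivePhenotypes(g, times = c(0, 15, 30))$CG  # 225 mM.min
#' @export
derivePhenotypes <- function(glycemia, times, insulin = NULL,
                             organ_weights = NULL, bw = NULL) {
    glycemia <- as.matrix(glycemia)
    if (length(times) != ncol(glycemia))
        stop("times must match the curve columns")
    if (times[1] != 0)
        stop("curves must include time 0 (baseline)")
    if (any(glycemia < 0))
        stop("negative glycemia is not a valid curve")
    dur <- max(times) - times[1]
    out <- data.frame(row.names = rownames(glycemia))
    for (j in seq_along(times))
        out[[sprintf("G%d", times[j])]] <- glycemia[, j]
    out$CG <- apply(glycemia, 1L, function(y) trapz(times, y))
    out$dG <- out$CG - glycemia[, 1L] * dur
    i15 <- match(15, times)
    if (!is.na(i15) && length(times) > i15) {
        tl <- length(times)
        out$Kglyc <- (glycemia[, i15] - glycemia[, tl]) / (times[tl] - 15)
    }
    if (!is.null(insulin)) {
        insulin <- as.matrix(insulin)
        if (ncol(insulin) != length(times))
            stop("all curves must share the same sampling times")
        for (j in seq_along(times))
            out[[sprintf("I%d", times[j])]] <- insulin[, j]
        out$CI <- apply(insulin, 1L, function(y) trapz(times, y))
        out$dI <- out$CI - insulin[, 1L] * dur
        out$IcumG <- out$CG / out$CI
    }
    if (!is.null(organ_weights)) {
        if (is.null(bw)) stop("organ ratios require body weight")
        organ_weights <- as.matrix(organ_weights)
        for (j in seq_len(ncol(organ_weights))) {
            nmj <- colnames(organ_weights)[j]
            out[[nmj]] <- organ_weights[, j]
            out[[paste0(nmj, "_ratio")]] <- organ_weights[, j] / bw
        }
    }
    DataFrame(out)
}

#' Simulate a synthetic isogenic cohort
#'
#' Generates urinary spectra at each configured timepoint plus a day-20
#' phenotype table, with fully recorded ground truth. Per animal, a latent
#' driver z (standard normal, with planted extremes boosted beyond the 2-SD
#' band) sets both the baseline metabolite excretion
#' (\code{baseline_mean * exp(marker_loading * effect_size * z + noise)},
#' plus a response-magnitude term through the extremity loadings) and the
#' late phenotypes (monotone in z plus independent noise). Each spectrum
#' receives a multiplicative log-normal dilution factor and an integer
#' edge-padded shift, the distortions the PQN and alignment stages are meant
#' to undo.
#'
#' @param config a \code{\link{cohortConfig}()} list.
#' @param library a \linkS4class{MetaboliteLibrary}
#'   (default \code{defaultMetaboliteLibrary()}).
#' @return A \linkS4class{SyntheticCohort}.
#' @examples
#' cfg <- cohortConfig(n_animals = 14, n_ppm_points = 256, seed = 7)
#' coh <- simulateCohort(cfg)
#' coh
#' @export
simulateCohort <- function(config = cohortConfig(),
                           library = defaultMetaboliteLibrary()) {
    if (!inherits(config, "cohortConfig"))
        config <- do.call(cohortConfig, config)
    stopifnot(is(library, "MetaboliteLibrary"))
    withSeed(config$seed, simulateCohortImpl(config, library))
}

simulateCohortImpl <- function(cfg, library) {
    n <- cfg$n_animals
    ids <- sprintf("M%02d", seq_len(n))
    mets <- as.data.frame(library@metabolites)
    s <- cfg$pheno_noise

    ## latent drivers; planted extremes overwrite the normal draw
    zg <- stats::rnorm(n)
    za <- if (cfg$n_drivers >= 2L) stats::rnorm(n) else zg
    counts <- round(cfg$group_fractions[c("LNG", "L-IGT", "Ob-IGT")] * n)
    planted <- sample(ids, sum(counts))
    group <- setNames(rep("midgroup", n), ids)
    take <- function(k) {
        if (k < 1L) return(character(0))
        sel <- planted[seq_len(k)]
        planted <<- planted[-seq_len(k)]
        sel
    }
    lng <- take(counts[["LNG"]])
    ligt <- take(counts[["L-IGT"]])
    ob <- take(counts[["Ob-IGT"]])
    group[lng] <- "LNG"; group[ligt] <- "L-IGT"; group[ob] <- "Ob-IGT"
    boost <- function(rng, k) stats::runif(k, rng[1], rng[2])
    i <- match(ob, ids)
    zg[i] <- boost(cfg$ob_boost, length(i)); za[i] <- zg[i]
    if (cfg$n_drivers >= 2L && length(ob))
        za[i] <- boost(cfg$ob_boost, length(i))
    i <- match(ligt, ids)
    if (length(i)) zg[i] <- boost(cfg$ob_boost, length(i))
    i <- match(lng, ids)
    zg[i] <- -boost(cfg$lng_boost, length(i))
    za[i] <- if (cfg$n_drivers >= 2L) -boost(cfg$lng_boost, length(i)) else zg[i]
    names(zg) <- names(za) <- ids

    ## metabolite driver and response-magnitude axis (zero mean under the
    ## standard normal, uncorrelated with z by symmetry)
    zmet <- if (cfg$n_drivers >= 2L) (zg + za) / sqrt(2) else zg
    r <- abs(zmet) - sqrt(2 / pi)

    ## baseline log-concentrations (day 0)
    m <- nrow(mets)
    logc0 <- matrix(rep(log(mets$baseline_mean), each = n), n, m)
    logc0 <- logc0 + outer(zmet, mets$marker_loading) * cfg$effect_size +
        outer(r, mets$extremity_loading) * cfg$effect_size +
        matrix(stats::rnorm(n * m, 0, rep(mets$baseline_sd, each = n)), n, m)
    dimnames(logc0) <- list(ids, mets$name)

    axis <- seq(cfg$ppm_range[1], cfg$ppm_range[2],
                length.out = cfg$n_ppm_points)
    spectra <- list(); concs <- list(); dils <- list(); jits <- list()
    for (tp in cfg$timepoints) {
        lc <- logc0 + rep(mets$hfd_logfc * hfdRamp(tp), each = n)
        if (tp != cfg$timepoints[1])
            lc <- lc + matrix(stats::rnorm(n * m, 0, cfg$within_sd), n, m)
        conc <- exp(lc)
        dil <- exp(stats::rnorm(n, 0, cfg$dilution_log_sd))
        jit <- if (cfg$jitter_max > 0)
            sample(seq.int(-cfg$jitter_max, cfg$jitter_max), n, replace = TRUE)
        else rep(0L, n)
        names(dil) <- names(jit) <- ids
        mat <- matrix(0, n, cfg$n_ppm_points, dimnames = list(ids, NULL))
        for (k in seq_len(n)) {
            bseed <- sample.int(2^31 - 2, 1L)
            sig <- synthesizeSpectrum(conc[k, ], library, axis,
                                      noise_sd = 0,
                                      baseline_amplitude = cfg$baseline_amplitude,
                                      seed = bseed,
                                      tail_cutoff = cfg$tail_cutoff)
            obs <- shiftVector(dil[k] * sig, jit[k])
            if (cfg$noise_sd > 0)
                obs <- obs + stats::rnorm(cfg$n_ppm_points, 0, cfg$noise_sd)
            mat[k, ] <- obs
        }
        key <- as.character(tp)
        spectra[[key]] <- SpectralSet(
            mat, axis,
            sampleData = DataFrame(animal = ids, timepoint = tp,
                                   diet = ifelse(tp == 0, "pre-HFD", "HFD")),
            sampleIds = sprintf("%s_d%s", ids, key))
        concs[[key]] <- conc; dils[[key]] <- dil; jits[[key]] <- jit
    }

    ## day-20 phenotypes
    tt <- cfg$gtt_times
    shapeG <- c(0, 1, 0.8, 0.25)[seq_along(tt)]
    shapeI <- c(0, 1, 0.7, 0.3)[seq_along(tt)]
    tr0 <- function(x, lo = 0) pmax(x, lo)
    gbase <- tr0(6.5 + 0.8 * zg + stats::rnorm(n, 0, 0.35 * s), 1)
    ampG <- tr0(8 + 2.5 * zg + stats::rnorm(n, 0, 1 * s), 0.5)
    ibase <- tr0(1 + 0.25 * zg + stats::rnorm(n, 0, 0.15 * s), 0.1)
    ampI <- tr0(2 + 0.6 * zg + stats::rnorm(n, 0, 0.3 * s), 0.1)
    gly <- outer(gbase, rep(1, length(tt))) + outer(ampG, shapeG)
    ins <- outer(ibase, rep(1, length(tt))) + outer(ampI, shapeI)
    rownames(gly) <- rownames(ins) <- ids

    bw0 <- 20 + 0.5 * za + stats::rnorm(n, 0, 0.4 * s)
    bw <- 25 + 2.0 * za + stats::rnorm(n, 0, 0.7 * s)
    len <- 9.5 + 0.12 * za + stats::rnorm(n, 0, 0.1 * s)
    organs <- cbind(
        EPD = tr0(0.80 + 0.35 * za + stats::rnorm(n, 0, 0.12 * s)),
        RFP = tr0(0.35 + 0.18 * za + stats::rnorm(n, 0, 0.08 * s)),
        BAT = tr0(0.25 + stats::rnorm(n, 0, 0.05 * s)),
        heart = tr0(0.15 + 0.015 * zg + stats::rnorm(n, 0, 0.012 * s)))
    derived <- derivePhenotypes(gly, tt, insulin = ins,
                                organ_weights = organs, bw = bw)
    ph <- as.data.frame(derived)
    ph$BW_baseline <- bw0
    ph$BW <- bw
    ph$BW_gain <- bw - bw0
    ph$BMI <- bw / len^2
    ph$FG <- gbase
    ph$FI <- ibase
    ph$liver <- tr0(1.1 + stats::rnorm(n, 0, 0.10 * s))
    ph$kidney <- tr0(0.40 + stats::rnorm(n, 0, 0.04 * s))
    ph$leptin <- tr0(4 + 1.2 * za + stats::rnorm(n, 0, 0.8 * s))
    ph$adiponectin <- tr0(9 - 0.8 * za + stats::rnorm(n, 0, 0.9 * s))
    ph$triglycerides <- tr0(1.1 + 0.15 * zg + stats::rnorm(n, 0, 0.2 * s))
    ph$cholesterol <- tr0(2.2 + stats::rnorm(n, 0, 0.3 * s))
    ph$food_intake <- tr0(3.5 + 0.25 * za + stats::rnorm(n, 0, 0.35 * s))
    ph$dig_energy <- tr0(14 + 1.1 * za + stats::rnorm(n, 0, 1.4 * s))
    ph$rearings_OF <- tr0(round(30 - 4 * zmet + stats::rnorm(n, 0, 6 * s)))
    ph$distance_OF <- tr0(22 - 1.5 * zmet + stats::rnorm(n, 0, 4 * s))
    ph$center_time_OF <- tr0(35 + stats::rnorm(n, 0, 10 * s))
    ph$entries_open_arm <- tr0(round(8 + stats::rnorm(n, 0, 3 * s)))
    ph$time_open_arm <- tr0(60 + stats::rnorm(n, 0, 20 * s))
    ph$grooming <- tr0(round(6 + stats::rnorm(n, 0, 2.5 * s)))
    rownames(ph) <- ids

    new("SyntheticCohort",
        spectra = SimpleList(spectra),
        phenotypes = DataFrame(ph),
        groundTruth = list(z = zmet, z_glycemia = zg, z_adiposity = za,
                           r = r, group = group, concentrations = concs,
                           dilutions = dils, jitters = jits),
        config = unclass(cfg))
}

#' @rdname accessors
#' @export
setMethod("spectra", "SyntheticCohort", function(x) x@spectra)

#' @rdname accessors
#' @export
setMethod("phenotypes", "SyntheticCohort", function(x) x@phenotypes)

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticCohort", function(x) x@groundTruth)

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf("SyntheticCohort: %d animals, timepoints: %s\n",
                nrow(object@phenotypes),
                paste(names(object@spectra), collapse = ", ")))
    cat(sprintf("  %d phenotypes; planted groups: %s\n",
                ncol(object@phenotypes),
                paste(names(table(object@groundTruth$group)),
                      table(object@groundTruth$group),
                      collapse = ", ", sep = "=")))
})
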