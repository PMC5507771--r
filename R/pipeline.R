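#' Full-run configuration
#'
#' Nested configuration for \code{\link{runPipeline}}: one section per
#' stage, a master seed, stage toggles and an optional output directory.
#' Per-stage seeds are derived by stable hashing of the stage name with the
#' master seed, so toggling one stage never perturbs another stage's
#' randomness.
#'
#' @param seed master seed.
#' @param out_dir directory for delimited-text intermediates (NULL = keep
#'   everything in memory).
#' @param stages character vector of enabled stages, a subset of
#'   \code{c("simulate", "preprocess", "features", "stratify", "fit",
#'   "associate", "screen")}.
#' @param simulate arguments for \code{\link{cohortConfig}} (seed is
#'   derived, do not set it here).
#' @param preprocess list: \code{max_shift}, \code{min_segment},
#'   \code{corr_gain_threshold}, \code{exclude} (list of ppm windows;
#'   default removes the water and urea regions).
#' @param features list: \code{corr_threshold}, \code{min_size},
#'   \code{mode}.
#' @param stratify list: \code{glycemia_col}, \code{bw_col}, \code{k_sd},
#'   \code{lng_rule}.
#' @param fit list: \code{k}, \code{n_orth}, \code{scaling},
#'   \code{contrasts}.
#' @param validate list: \code{n_iter}.
#' @param associate list: \code{alpha}, \code{n_iter}.
#' @param screen list: \code{n_iter} (the screen stage is off by default:
#'   it fits one permutation-tested model per timepoint x phenotype).
#' @return A named list of class \code{"runConfig"}.
#' @export
runConfig <- function(seed = 1L, out_dir = NULL,
                      stages = c("simulate", "preprocess", "features",
                                 "stratify", "fit", "associate"),
                      simulate = list(),
                      preprocess = list(max_shift = 8L, min_segment = 32L,
                                        corr_gain_threshold = 0,
                                        exclude = list(c(4.5, 5.0),
                                                       c(5.4, 6.2))),
                      features = list(corr_threshold = 0.97, min_size = 3L,
                                      mode = "mean"),
                      stratify = list(glycemia_col = "CG", bw_col = "BW",
                                      k_sd = 2,
                                      lng_rule = list(type = "quantile",
                                                      prob = 0.10)),
                      fit = list(k = 7L, n_orth = 1L, scaling = "uv",
                                 contrasts = "extreme"),
                      validate = list(n_iter = 999L),
                      associate = list(alpha = 0.05, n_iter = 199L),
                      screen = list(n_iter = 99L)) {
    cfg <- list(seed = as.integer(seed), out_dir = out_dir,
                stages = stages, simulate = simulate,
                preprocess = preprocess, features = features,
                stratify = stratify, fit = fit, validate = validate,
                associate = associate, screen = screen)
    known <- c("simulate", "preprocess", "features", "stratify", "fit",
               "associate", "screen")
    if (!all(stages %in% known))
        stop("unknown stage(s): ",
             paste(setdiff(stages, known), collapse = ", "))
    class(cfg) <- c("runConfig", "list")
    cfg
}

runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full prodromal-metabotyping pipeline
#'
#' Orchestrates simulate -> align/trim -> SRV features (clustered on the
#' baseline timepoint, applied to every timepoint, PQN-normalized, then
#' log-transformed) -> 2-SD stratification of the late phenotypes ->
#' permutation-validated O-PLS-DA per contrast on the baseline features ->
#' baseline-feature x late-phenotype Spearman association map, and
#' optionally the per-phenotype prediction screen. Identical config (and
#' seed) gives an identical report.
#'
#' @param config a \code{\link{runConfig}()} list.
#' @param library a \linkS4class{MetaboliteLibrary}.
#' @return list: the run report with \code{config_hash}, \code{seed},
#'   per-contrast summaries, association summary, the screen table (when
#'   enabled) and the intermediate objects under \code{$objects}.
#' @export
runPipeline <- function(config = runConfig(),
                        library = defaultMetaboliteLibrary()) {
    if (!inherits(config, "runConfig"))
        config <- do.call(runConfig, config)
    stages <- config$stages
    report <- list(schema = "metaboPredict-report/1",
                   config_hash = configHash(unclass(config)),
                   seed = config$seed)
    objects <- list()
    outDir <- config$out_dir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    cohort <- NULL
    if ("simulate" %in% stages) {
        cohort <- runStage("simulate", {
            simArgs <- config$simulate
            simArgs$seed <- deriveSeed(config$seed, "simulate")
            simulateCohort(do.call(cohortConfig, simArgs), library)
        })
        objects$cohort <- cohort
        if (!is.null(outDir)) {
            for (tp in names(spectra(cohort)))
                writeSpectralSet(spectra(cohort)[[tp]],
                                 file.path(outDir,
                                           sprintf("spectra_d%s.tsv", tp)))
            writePhenotypeTable(phenotypes(cohort),
                                file.path(outDir, "phenotypes.tsv"))
        }
    }

    processed <- NULL
    if ("preprocess" %in% stages) {
        processed <- runStage("preprocess", {
            if (is.null(cohort))
                stop("no spectra available; enable the simulate stage ",
                     "or supply data")
            pp <- config$preprocess
            lapply(spectra(cohort), function(ss) {
                al <- rspaAlign(ss, max_shift = pp$max_shift,
                                min_segment = pp$min_segment,
                                corr_gain_threshold = pp$corr_gain_threshold)
                excludeRegions(alignedSpectra(al), pp$exclude)
            })
        })
        objects$processed <- processed
    }

    featuresByTp <- NULL
    if ("features" %in% stages) {
        featuresByTp <- runStage("features", {
            if (is.null(processed)) stop("preprocess stage required")
            fc <- config$features
            base <- processed[[1L]]
            clusters <- srvCluster(base, corr_threshold = fc$corr_threshold,
                                   min_size = fc$min_size)
            clusters <- annotateClusters(clusters, library)
            lapply(processed, function(ss) {
                ft <- clusterIntensities(ss, clusters, mode = fc$mode)
                logTransform(pqnNormalize(ft)$normalized)
            })
        })
        objects$features <- featuresByTp
        if (!is.null(outDir))
            for (tp in names(featuresByTp))
                writeFeatureTable(featuresByTp[[tp]],
                                  file.path(outDir,
                                            sprintf("features_d%s.tsv", tp)))
    }

    strat <- NULL
    if ("stratify" %in% stages) {
        strat <- runStage("stratify", {
            if (is.null(cohort)) stop("no phenotypes available")
            sc <- config$stratify
            stratifyPhenotypes(phenotypes(cohort),
                               glycemia_col = sc$glycemia_col,
                               bw_col = sc$bw_col, k_sd = sc$k_sd,
                               lng_rule = sc$lng_rule)
        })
        objects$stratification <- strat
        report$groups <- as.list(table(groupLabels(strat)))
    }

    if ("fit" %in% stages) {
        contrasts <- runStage("fit", {
            if (is.null(featuresByTp) || is.null(strat))
                stop("features and stratify stages required")
            fm <- featureMatrixByAnimal(featuresByTp[[1L]])
            out <- list()
            for (ctr in config$fit$contrasts) {
                tg <- groupsToTargets(strat, ctr)
                X <- fm[tg$animal, , drop = FALSE]
                v <- validateModel(X, tg$class, k = config$fit$k,
                                   n_orth = config$fit$n_orth,
                                   scaling = config$fit$scaling,
                                   n_iter = config$validate$n_iter,
                                   seed = deriveSeed(config$seed,
                                                     paste0("fit|", ctr)))
                v$summary$contrast <- ctr
                v$summary$n_class0 <- sum(tg$class ==
                                              sort(unique(tg$class))[1])
                v$summary$n_class1 <- sum(tg$class ==
                                              sort(unique(tg$class))[2])
                out[[ctr]] <- v
            }
            out
        })
        objects$contrasts <- contrasts
        report$contrasts <- lapply(contrasts, function(v)
            as.list(v$summary))
    }

    if ("associate" %in% stages) {
        assoc <- runStage("associate", {
            if (is.null(featuresByTp)) stop("features stage required")
            buildAssociationMatrix(
                featuresByTp[[1L]], phenotypes(cohort),
                alpha = config$associate$alpha,
                n_iter = config$associate$n_iter,
                seed = deriveSeed(config$seed, "associate"))
        })
        objects$association <- assoc
        report$association <- list(
            n_cells = length(significanceMask(assoc)),
            n_significant = sum(significanceMask(assoc)),
            alpha = assoc@alpha, n_iter = assoc@nIter)
        if (!is.null(outDir)) {
            utils::write.table(associationRho(assoc),
                               file.path(outDir, "association_rho.tsv"),
                               sep = "\t", quote = FALSE)
            utils::write.table(associationP(assoc),
                               file.path(outDir, "association_p.tsv"),
                               sep = "\t", quote = FALSE)
            utils::write.table(associationTable(assoc),
                               file.path(outDir, "association_long.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }

    if ("screen" %in% stages) {
        scr <- runStage("screen", {
            if (is.null(featuresByTp)) stop("features stage required")
            phenotypePredictionScreen(
                featuresByTp, phenotypes(cohort),
                k = config$fit$k, n_orth = config$fit$n_orth,
                scaling = config$fit$scaling,
                n_iter = config$screen$n_iter,
                seed = deriveSeed(config$seed, "screen"))
        })
        objects$screen <- scr
        report$screen <- scr
    }

    report$objects <- objects
    if (!is.null(outDir)) {
        small <- report[setdiff(names(report), "objects")]
        jsonlite::write_json(small, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    report
}
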