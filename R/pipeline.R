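#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one dataset: singleton removal,
#' parasite classification, relative-abundance conversion, per-sample
#' summaries and the negative-control screen, season x year ANOVA with
#' Tukey letters on parasite relative abundance and richness, per-year
#' resampled Baselga partitioning, PERMANOVA with pairwise season
#' comparisons, NMDS and SIMPER on the parasite community, writing one
#' TSV per stage plus a JSON run manifest. All randomness derives from
#' \code{seed}; the same inputs and seed give byte-identical outputs.
#'
#' @param input either the result of
#'   \code{\link{simulateParasiteDataset}} or a named list of paths
#'   (\code{counts}, \code{taxonomy}, \code{metadata}, \code{hits},
#'   \code{registry})
#' @param out_dir output directory
#' @param seed master seed; per-stage sub-seeds are derived from it
#' @param max_rank,min_identity classifier thresholds
#' @param alpha significance level for Tukey letters
#' @param k_resample,beta_reps per-year subsample size and repetitions
#'   for the resampled beta partition
#' @param n_perm PERMANOVA permutations
#' @param group_rank taxonomy rank used for per-group summaries
#' @return invisibly, a list with every stage result and the manifest
#' @export
runPipeline <- function(input, out_dir, seed = 1L,
                        max_rank = 10L, min_identity = 90,
                        alpha = 0.05, k_resample = 30L, beta_reps = 100L,
                        n_perm = 999L, group_rank = "division") {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) {
        message("[", name, "] ...")
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    if (!is.null(input$experiment)) {
        x <- input$experiment; hits <- input$hits
        registry <- input$registry
    } else {
        x <- stage("read", readAsvExperiment(input$counts, input$taxonomy,
                                             input$metadata))
        hits <- stage("read", readHitStore(input$hits))
        registry <- stage("read", readLiteratureRegistry(input$registry))
    }
    n_raw <- nrow(x)
    x <- stage("filter", dropSingletons(x))
    calls <- stage("classify",
                   classifyParasites(x, registry = registry, hits = hits,
                                     max_rank = max_rank,
                                     min_identity = min_identity))
    tl <- tallyProvenance(calls)
    message(sprintf(
        "[classify] parasitic %d (literature %d / ncbi %d / both %d) of %d ASVs (%.1f%%)",
        tl$parasitic, tl$literature, tl$ncbi, tl$both, tl$n_asvs,
        tl$percent))
    x <- stage("relabund", relativeAbundance(x))
    summ <- stage("summaries",
                  sampleSummaries(x, calls, by_group = TRUE,
                                  group_rank = group_rank))
    ctrl <- stage("controls", controlScreen(x, calls, group_rank))

    all_summ <- summ[summ$group == "all", ]
    anova_fits <- stage("anova", {
        lapply(c(rel_abundance = "rel_abundance", richness = "richness"),
               function(m) twoWayAnova(all_summ[[m]], all_summ$season,
                                       all_summ$year))
    })
    tukeys <- stage("tukey", {
        lapply(anova_fits, function(f)
            tukeyHsd(f$data$y, f$data$season, alpha = alpha,
                     df_resid = f$df_resid, ms_resid = f$ms_resid))
    })

    ## parasite community matrix: non-control samples, parasite ASVs,
    ## relative abundances over the whole sample
    keep <- !isControl(x)
    para <- intersect(rownames(x), parasiteAsvs(calls))
    rel <- t(.relMatrix(x)[para, keep, drop = FALSE])
    nonzero <- rowSums(rel) > 0
    if (!all(nonzero))
        message("[community] dropping ", sum(!nonzero),
                " samples with no parasite reads")
    rel <- rel[nonzero, , drop = FALSE]
    fac <- droplevels(as.data.frame(
        SummarizedExperiment::colData(x)[keep, c("season", "year")])[nonzero, ])
    fac$year <- factor(fac$year)

    beta <- stage("beta", {
        sub <- x[, keep][, nonzero]
        resampledBeta(sub[para, ], k = k_resample, reps = beta_reps,
                      seed = deriveSeed(seed, "beta"))
    })
    d <- stage("distance", brayCurtisMatrix(rel))
    perma <- stage("permanova",
                   permanovaTest(d, fac,
                                 terms = c("season", "year",
                                           "season:year"),
                                 n_perm = n_perm,
                                 seed = deriveSeed(seed, "permanova")))
    pairwise <- stage("pairwise",
                      pairwisePermanova(d, fac$season, n_perm = n_perm,
                                        seed = deriveSeed(seed, "pairwise")))
    nmds <- stage("nmds",
                  nmdsOrdination(d, seed = deriveSeed(seed, "nmds")))
    simper <- stage("simper", simperAnalysis(rel, fac$season))

    stage("write", {
        writeAnnotations(calls, file.path(out_dir, "annotations.tsv"))
        writeTsv(data.frame(metric = names(unlist(tl)),
                            value = unlist(tl)),
                 file.path(out_dir, "provenance_tally.tsv"))
        writeTsv(summ, file.path(out_dir, "sample_summaries.tsv"))
        writeTsv(data.frame(
            metric = c("n_reads", "n_asvs",
                       paste0("group:", names(ctrl$by_group)),
                       "parasitic_violations"),
            value = c(ctrl$n_reads, ctrl$n_asvs, unname(ctrl$by_group),
                      length(ctrl$parasitic_asvs))),
            file.path(out_dir, "control_screen.tsv"))
        av <- do.call(rbind, lapply(names(anova_fits), function(m) {
            t <- anova_fits[[m]]$table
            t$signif <- signifCodes(t$p.value)
            cbind(metric = m, t)
        }))
        writeTsv(av, file.path(out_dir, "anova.tsv"))
        tk <- do.call(rbind, lapply(names(tukeys), function(m) {
            t <- tukeys[[m]]$comparisons
            t$letters1 <- tukeys[[m]]$letters[t$level1]
            t$letters2 <- tukeys[[m]]$letters[t$level2]
            cbind(metric = m, t)
        }))
        writeTsv(tk, file.path(out_dir, "tukey.tsv"))
        writeTsv(beta$draws, file.path(out_dir, "beta_resampled.tsv"))
        pt <- perma$table
        pt$signif <- signifCodes(pt$p.value)
        writeTsv(pt, file.path(out_dir, "permanova.tsv"))
        writeTsv(pairwise, file.path(out_dir, "permanova_pairwise.tsv"))
        writeTsv(data.frame(sample_id = rownames(nmds$points),
                            nmds$points, stress = nmds$stress,
                            check.names = FALSE),
                 file.path(out_dir, "nmds.tsv"))
        sp <- do.call(rbind, lapply(names(simper), function(p)
            cbind(pair = p, utils::head(simper[[p]], 25L))))
        writeTsv(sp, file.path(out_dir, "simper.tsv"))
    })

    manifest <- list(
        package = "paraplank",
        version = as.character(utils::packageVersion("paraplank")),
        seed = seed,
        parameters = list(max_rank = max_rank,
                          min_identity = min_identity, alpha = alpha,
                          k_resample = k_resample, beta_reps = beta_reps,
                          n_perm = n_perm, group_rank = group_rank),
        stages = list(asvs_raw = n_raw, asvs_filtered = nrow(x),
                      samples = sum(keep),
                      samples_community = sum(nonzero),
                      parasitic = tl$parasitic),
        provenance = tl[c("literature", "ncbi", "both", "parasitic",
                          "percent")])
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(experiment = x, calls = calls, summaries = summ,
                   control = ctrl, anova = anova_fits, tukey = tukeys,
                   beta = beta, distance = d, permanova = perma,
                   pairwise = pairwise, nmds = nmds, simper = simper,
                   manifest = manifest))
}
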