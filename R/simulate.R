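#' Configuration for the synthetic plankton metabarcoding generator
#'
#' The generator emulates a multi-year weekly 18S metabarcoding
#' time-series of a temperate lake with a planted parasite community:
#' negative-binomial read counts with group-specific seasonal uplifts,
#' a PR2-style taxonomy, an offline hit store with planted host
#' metadata, a literature registry, and negative-control samples. The
#' defaults mirror the study design at roughly one tenth scale (2 years
#' of weekly samples, 50 parasite + 250 non-parasite ASVs, summer-
#' peaking Dinoflagellata and Perkinsozoa); \code{paperScaleConfig}
#' gives the full-scale preset (5 years, 441 + 2622 ASVs, 232 samples).
#'
#' @param n_years number of sampled years
#' @param start_year first calendar year
#' @param n_parasite_asvs,n_nonparasite_asvs community sizes
#' @param n_controls number of negative-control samples
#' @param parasite_group_weights named weights over parasite taxon
#'   groups (divisions)
#' @param seasonal_multipliers data.frame(group, peak_season,
#'   multiplier, shoulder): mean count multiplier in the group's peak
#'   season and in the two adjacent seasons (the seasonal cycle is
#'   smooth, so the opposite season is the most distinct — mirroring
#'   the summer-vs-winter contrast of temperate lakes)
#' @param base_mean_log,base_mean_sdlog log-normal law of per-ASV base
#'   mean reads
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed)
#' @param completeness probability in [0, 1] that a metadata-route
#'   parasite actually gets host text planted in a hit
#' @param rank_law probabilities over hit ranks 1..length(rank_law) for
#'   where the host text lands
#' @param route_probs probabilities of evidence routes (literature /
#'   ncbi / both) for parasite ASVs
#' @param inside_fraction fraction of non-parasite ASVs placed inside
#'   preselected groups (they exercise the no-host path)
#' @param biweekly_start sample only every other week in Jan-Feb of the
#'   first year?
#' @param max_samples optional cap: thin the date grid evenly to this
#'   many samples
#' @param scenario \code{"default"} (all-year communities),
#'   \code{"turnover"} (disjoint per-season parasite blocks) or
#'   \code{"nestedness"} (season communities nested by tier)
#' @param seed integer seed
#' @return validated config list
#' @export
simulationConfig <- function(
        n_years = 2L, start_year = 2015L,
        n_parasite_asvs = 50L, n_nonparasite_asvs = 250L,
        n_controls = 3L,
        parasite_group_weights = c(Chytridiomycota = 0.30,
                                   Dinoflagellata = 0.20,
                                   Oomycota = 0.20, Perkinsozoa = 0.10,
                                   Basidiomycota = 0.10,
                                   Microsporidia = 0.10),
        seasonal_multipliers = data.frame(
            group = c("Dinoflagellata", "Perkinsozoa"),
            peak_season = c("summer", "summer"),
            multiplier = c(5, 5),
            shoulder = c(2, 2)),
        base_mean_log = log(20), base_mean_sdlog = 0.7,
        dispersion = 2,
        completeness = 1,
        rank_law = c(0.55, 0.20, 0.10, 0.05, 0.04, 0.02,
                     0.01, 0.01, 0.01, 0.01),
        route_probs = c(literature = 0.25, ncbi = 0.60, both = 0.15),
        inside_fraction = 0.4,
        biweekly_start = FALSE,
        max_samples = NULL,
        scenario = c("default", "turnover", "nestedness"),
        seed = 42L) {
    scenario <- match.arg(scenario)
    stopifnot(n_years >= 1L, n_parasite_asvs >= 1L,
              n_nonparasite_asvs >= 1L, n_controls >= 0L,
              completeness >= 0, completeness <= 1,
              all(seasonal_multipliers$multiplier > 0),
              dispersion > 0, all(rank_law >= 0), sum(rank_law) > 0)
    list(n_years = as.integer(n_years), start_year = as.integer(start_year),
         n_parasite_asvs = as.integer(n_parasite_asvs),
         n_nonparasite_asvs = as.integer(n_nonparasite_asvs),
         n_controls = as.integer(n_controls),
         parasite_group_weights = parasite_group_weights,
         seasonal_multipliers = seasonal_multipliers,
         base_mean_log = base_mean_log, base_mean_sdlog = base_mean_sdlog,
         dispersion = dispersion, completeness = completeness,
         rank_law = rank_law / sum(rank_law), route_probs = route_probs,
         inside_fraction = inside_fraction,
         biweekly_start = biweekly_start, max_samples = max_samples,
         scenario = scenario, seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @param ... overrides passed on to \code{simulationConfig}
#' @export
paperScaleConfig <- function(...) {
    simulationConfig(n_years = 5L, n_parasite_asvs = 441L,
                     n_nonparasite_asvs = 2622L, n_controls = 3L,
                     biweekly_start = TRUE, max_samples = 232L, ...)
}

## weekly Monday grid across the simulated years
.samplingDates <- function(config) {
    y0 <- config$start_year
    first <- as.Date(sprintf("%d-01-01", y0))
    last <- as.Date(sprintf("%d-12-31", y0 + config$n_years - 1L))
    days <- seq(first, last, by = "day")
    mondays <- days[as.POSIXlt(days)$wday == 1L]
    if (config$biweekly_start) {
        m <- as.integer(format(mondays, "%m"))
        yy <- as.integer(format(mondays, "%Y"))
        early <- yy == y0 & m <= 2L
        keep <- !early | (seq_along(mondays) %% 2L == 1L)
        mondays <- mondays[keep]
    }
    if (!is.null(config$max_samples) &&
        length(mondays) > config$max_samples) {
        idx <- round(seq(1L, length(mondays),
                         length.out = config$max_samples))
        mondays <- mondays[unique(idx)]
    }
    mondays
}

.HOST_POOLS <- list(
    Chytridiomycota = c("Aulacoseira granulata", "Synedra acus",
                        "Asterionella formosa", "Daphnia galeata",
                        "Rana temporaria", "Entomophaga maimaiga"),
    Dinoflagellata = c("Meganyctiphanes norvegica", "fish",
                       "Perca fluviatilis", "Thoropa taophora",
                       "Baikalospongia recta"),
    Oomycota = c("Daphnia galeata", "nematode", "Perca fluviatilis",
                 "Asterionella formosa"),
    Basidiomycota = c("plant", "Entomophaga maimaiga"),
    Microsporidia = c("Daphnia galeata"))

.SUPERGROUPS <- c(Chytridiomycota = "Opisthokonta",
                  Basidiomycota = "Opisthokonta",
                  Microsporidia = "Opisthokonta",
                  Dinoflagellata = "Alveolata",
                  Perkinsozoa = "Alveolata",
                  Oomycota = "Stramenopiles",
                  Bacillariophyta = "Stramenopiles",
                  Ochrophyta = "Stramenopiles",
                  Chlorophyta = "Archaeplastida",
                  Streptophyta = "Archaeplastida",
                  Cryptophyta = "Hacrobia",
                  Haptophyta = "Hacrobia",
                  Metazoa = "Opisthokonta")

.OUTSIDE_GROUPS <- c("Bacillariophyta", "Chlorophyta", "Cryptophyta",
                     "Ochrophyta", "Streptophyta", "Metazoa", "Haptophyta")

.DECOY_TITLES <- c(
    "Uncultured eukaryote clone 18S ribosomal RNA gene, partial sequence",
    "Phylogenetic placement of uncultured freshwater clone",
    "Molecular survey of lake picoeukaryote diversity",
    "Uncultured fungus clone small subunit ribosomal RNA")

#' Plant host metadata into a synthetic hit store
#'
#' Builds the extended BLAST-tabular rows for every query in
#' \code{truth}: ten (or more) decoy hits per query carrying
#' taxonomy/phylogeny-style titles and no host information, and, for
#' metadata-route parasites, host text planted in exactly one hit at a
#' rank drawn from \code{rank_law}, with probability
#' \code{completeness}. The field carrying the host is chosen among
#' \code{host}, \code{isolation_source} and \code{title}. A fraction of
#' non-parasite queries also gets a trap hit below the 90% identity
#' threshold that does carry a host, to exercise the admission filter.
#'
#' @param truth data.frame with columns \code{asv_id}, \code{route}
#'   (\code{literature}/\code{ncbi}/\code{both}/\code{none}) and
#'   \code{host}
#' @param completeness planting probability in [0, 1]
#' @param rank_law probabilities over planting ranks 1..length
#' @param seed integer seed
#' @return hit-store data.frame (see \code{\link{readHitStore}})
#' @export
plantMetadata <- function(truth, completeness = 1,
                          rank_law = simulationConfig()$rank_law,
                          seed = NULL) {
    rank_law <- rank_law / sum(rank_law)
    withSeed(seed, {
        rows <- list()
        acc <- 0L
        n_q <- nrow(truth)
        ## all planting decisions drawn up front: under a fixed seed the
        ## planted set at lower completeness is a subset of the set at
        ## higher completeness (recall is then monotone by construction)
        u_plant <- stats::runif(n_q)
        rank_all <- sample.int(length(rank_law), n_q, replace = TRUE,
                               prob = rank_law)
        field_all <- sample(c("host", "iso", "title"), n_q,
                            replace = TRUE, prob = c(0.7, 0.15, 0.15))
        for (i in seq_len(n_q)) {
            id <- truth$asv_id[i]
            route <- truth$route[i]
            plant <- route %in% c("ncbi", "both") &&
                u_plant[i] < completeness
            r <- rank_all[i]
            n_hits <- max(10L, r)
            bit <- 500 - 5 * (seq_len(n_hits) - 1L)
            for (j in seq_len(n_hits)) {
                acc <- acc + 1L
                host <- ""; iso <- "freshwater lake"; ttl <-
                    sample(.DECOY_TITLES, 1L)
                if (plant && j == r) {
                    h <- truth$host[i]
                    field <- field_all[i]
                    ## title patterns need a capitalized name; fall back
                    ## to the host qualifier for lowercase vernaculars
                    if (field == "title" && !grepl("^[A-Z]", h))
                        field <- "host"
                    if (field == "host") host <- h
                    else if (field == "iso")
                        iso <- paste0("gut content of ", h)
                    else ttl <- paste0("Parasite of ", h,
                                       " small subunit rRNA gene")
                }
                rows[[length(rows) + 1L]] <- data.frame(
                    qseqid = id, saccver = sprintf("SYN%06d", acc),
                    pident = round(stats::runif(1, 90.5, 99.5), 2),
                    evalue = signif(stats::runif(1, 1e-120, 1e-60), 3),
                    bitscore = bit[j], host = host,
                    isolation_source = iso, title = ttl, note = "",
                    organism = "uncultured eukaryote",
                    stringsAsFactors = FALSE)
            }
            ## sub-threshold trap: host present but identity below 90
            if (route == "none" && i %% 5L == 0L) {
                acc <- acc + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    qseqid = id, saccver = sprintf("SYN%06d", acc),
                    pident = 85.0, evalue = 1e-40, bitscore = 600,
                    host = "Daphnia galeata",
                    isolation_source = "", title = "", note = "",
                    organism = "uncultured eukaryote",
                    stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, rows)
    })
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Produces every input the pipeline consumes — count table with
#' seasonal structure, taxonomy, sampling dates, offline hit store,
#' literature registry — plus the ground-truth table that says which
#' ASVs are parasitic, through which evidence route they are
#' discoverable, and what seasonal uplift they carry. Deterministic
#' under \code{config$seed}.
#'
#' @param config from \code{\link{simulationConfig}}
#' @return list with \code{experiment} (an
#'   \code{\linkS4class{AsvExperiment}}), \code{hits}, \code{registry},
#'   \code{truth}, \code{config}
#' @export
simulateParasiteDataset <- function(config = simulationConfig()) {
    withSeed(config$seed, {
        dates <- .samplingDates(config)
        n_s <- length(dates)
        sample_ids <- sprintf("S%04d", seq_len(n_s))
        n_p <- config$n_parasite_asvs
        n_n <- config$n_nonparasite_asvs
        n_asv <- n_p + n_n
        asv_ids <- sprintf("ASV%04d", seq_len(n_asv))
        is_para <- c(rep(TRUE, n_p), rep(FALSE, n_n))

        ## per-group parasite richness is fixed in proportion to the
        ## weights (largest-remainder rounding), as in a real community
        ## profile; which ASV gets which group stays arbitrary
        w <- config$parasite_group_weights
        quota <- floor(n_p * w / sum(w))
        rem <- n_p - sum(quota)
        if (rem > 0L) {
            frac <- n_p * w / sum(w) - quota
            quota[order(-frac)[seq_len(rem)]] <- quota[order(-frac)[seq_len(rem)]] + 1L
        }
        grp_p <- sample(rep(names(w), quota))
        n_inside <- round(config$inside_fraction * n_n)
        grp_n <- c(sample(names(w), n_inside, replace = TRUE, prob = w),
                   sample(.OUTSIDE_GROUPS, n_n - n_inside, replace = TRUE))
        group <- c(grp_p, grp_n)

        route <- rep("none", n_asv)
        rp <- config$route_probs
        route[seq_len(n_p)] <- sample(names(rp), n_p, replace = TRUE,
                                      prob = rp)
        ## Perkinsozoa hosts are a literature 'Various' call
        route[seq_len(n_p)][grp_p == "Perkinsozoa"] <- "literature"

        species_level <- rep(FALSE, n_asv)
        sl <- route %in% c("literature", "both") |
            (route == "ncbi" & stats::runif(n_asv) < 0.5)
        species_level[seq_len(n_p)] <- sl[seq_len(n_p)]

        host <- rep("", n_asv)
        for (i in seq_len(n_p)) {
            g <- grp_p[i]
            host[i] <- if (g == "Perkinsozoa") "Various"
                       else sample(.HOST_POOLS[[g]], 1L)
        }

        genus <- sprintf("Genus%04d", seq_len(n_asv))
        species <- ifelse(species_level,
                          paste(genus, "synthetica"), NA_character_)
        supergroup <- unname(.SUPERGROUPS[group])
        supergroup[is.na(supergroup)] <- "Eukaryota_X"
        taxonomy <- data.frame(
            asv_id = asv_ids, kingdom = "Eukaryota",
            supergroup = supergroup, division = group,
            class = paste0(group, "_classis"),
            order = paste0(group, "_ordo"),
            family = paste0(group, "_familia"),
            genus = genus, species = species,
            stringsAsFactors = FALSE)

        ## seasonal means (peak + shoulder on the adjacent seasons)
        season <- as.character(assignSeason(dates))
        mult_tab <- config$seasonal_multipliers
        if (is.null(mult_tab$shoulder))
            mult_tab$shoulder <- sqrt(mult_tab$multiplier)
        peak <- stats::setNames(rep(NA_character_, n_asv), asv_ids)
        mult <- stats::setNames(rep(1, n_asv), asv_ids)
        shld <- stats::setNames(rep(1, n_asv), asv_ids)
        for (r in seq_len(nrow(mult_tab))) {
            hit <- group == mult_tab$group[r]
            peak[hit] <- mult_tab$peak_season[r]
            mult[hit] <- mult_tab$multiplier[r]
            shld[hit] <- mult_tab$shoulder[r]
        }
        cyc <- c("winter", "spring", "summer", "autumn")
        neighbours <- function(s) cyc[(match(s, cyc) + c(-2L, 0L)) %% 4L + 1L]
        base_mu <- stats::rlnorm(n_asv, config$base_mean_log,
                                 config$base_mean_sdlog)

        tier <- rep(NA_integer_, n_asv)
        block <- rep(NA_character_, n_asv)
        counts <- matrix(0L, n_s, n_asv,
                         dimnames = list(sample_ids, asv_ids))
        if (config$scenario == "turnover") {
            block[seq_len(n_p)] <- sample(SEASON_LEVELS, n_p,
                                          replace = TRUE)
        } else if (config$scenario == "nestedness") {
            tier[seq_len(n_p)] <- sample.int(4L, n_p, replace = TRUE)
        }
        nest_order <- c(winter = 1L, spring = 2L, summer = 3L,
                        autumn = 4L)
        for (i in seq_len(n_asv)) {
            sf <- rep(1, n_s)
            if (!is.na(peak[i])) {
                sf[season == peak[i]] <- mult[i]
                sf[season %in% neighbours(peak[i])] <- shld[i]
            }
            mu <- base_mu[i] * sf
            x <- stats::rnbinom(n_s, size = config$dispersion, mu = mu)
            if (is_para[i] && config$scenario == "turnover") {
                x <- ifelse(season == block[i], 1L + x, 0L)
            } else if (is_para[i] && config$scenario == "nestedness") {
                x <- ifelse(nest_order[season] >= tier[i], 1L + x, 0L)
            }
            counts[, i] <- as.integer(x)
        }

        ## negative controls: trace reads of a few non-parasite ASVs
        if (config$n_controls > 0L) {
            ctrl_ids <- sprintf("NC%02d", seq_len(config$n_controls))
            ctrl <- matrix(0L, config$n_controls, n_asv,
                           dimnames = list(ctrl_ids, asv_ids))
            pool <- which(!is_para & group %in% .OUTSIDE_GROUPS)
            for (ci in seq_len(config$n_controls)) {
                pick <- sample(pool, min(8L, length(pool)))
                ctrl[ci, pick] <- stats::rpois(length(pick), 3) + 1L
            }
            counts <- rbind(counts, ctrl)
            dates <- c(dates, rep(dates[length(dates)],
                                  config$n_controls))
            is_control <- c(rep(FALSE, n_s),
                            rep(TRUE, config$n_controls))
        } else is_control <- rep(FALSE, n_s)

        truth <- data.frame(
            asv_id = asv_ids, is_parasite = is_para, route = route,
            host = host, group = group, species_level = species_level,
            peak_season = unname(peak), multiplier = unname(mult),
            base_mean = base_mu, block_season = block, tier = tier,
            stringsAsFactors = FALSE)

        ## registry: literature/both species + non-parasite decoys
        reg_rows <- truth[truth$route %in% c("literature", "both"), ]
        grouping <- defaultHostGrouping()
        registry <- data.frame(
            species = species[match(reg_rows$asv_id, asv_ids)],
            hosts = ifelse(reg_rows$host == "Various", "", reg_rows$host),
            host_group = vapply(reg_rows$host, function(h)
                if (h == "Various") "Various"
                else .groupOneHostSet(h, grouping), character(1L)),
            is_parasite = TRUE,
            citation = "synthetic literature record",
            stringsAsFactors = FALSE)
        ## a few explicitly non-parasitic entries, as real registries have
        registry <- rbind(registry, data.frame(
            species = sprintf("Decoygenus%02d innocua", 1:5),
            hosts = "", host_group = "", is_parasite = FALSE,
            citation = "synthetic literature record",
            stringsAsFactors = FALSE))

        ## hit store for every preselected ASV
        presel <- preselect(taxonomy, defaultPreselection())
        need_hits <- truth[presel, , drop = FALSE]
        hits <- plantMetadata(need_hits,
                              completeness = config$completeness,
                              rank_law = config$rank_law,
                              seed = deriveSeed(config$seed, "hits"))

        experiment <- AsvExperiment(counts, taxonomy = taxonomy,
                                    dates = dates,
                                    is_control = is_control)
        list(experiment = experiment, hits = hits, registry = registry,
             truth = truth, config = config)
    })
}

#' Write all synthetic inputs as interchange TSVs
#'
#' @param sim result of \code{\link{simulateParasiteDataset}}
#' @param dir output directory (created if needed)
#' @return named vector of file paths
#' @export
writeSyntheticData <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    x <- sim$experiment
    paths <- c(
        counts = file.path(dir, "asv_counts.tsv"),
        taxonomy = file.path(dir, "taxonomy.tsv"),
        metadata = file.path(dir, "sample_metadata.tsv"),
        hits = file.path(dir, "hit_store.tsv"),
        registry = file.path(dir, "literature_registry.tsv"),
        truth = file.path(dir, "ground_truth.tsv"))
    writeAsvTable(asvCounts(x, samplesAsRows = TRUE), paths["counts"])
    tax <- taxonomyTable(x)
    tax[is.na(tax)] <- ""
    writeTsv(tax, paths["taxonomy"])
    cd <- SummarizedExperiment::colData(x)
    writeSampleMetadata(
        data.frame(sample_id = rownames(cd), date = cd$date,
                   is_control = cd$is_control), paths["metadata"])
    writeHitStore(sim$hits, paths["hits"])
    writeLiteratureRegistry(sim$registry, paths["registry"])
    writeTsv(sim$truth, paths["truth"])
    paths
}
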