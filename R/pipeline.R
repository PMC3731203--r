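#' @include AllClasses.R synthetic.R process.R metacodon.R occupancy.R
#' @include queuing.R expression.R
NULL

#' Default pipeline configuration
#'
#' Plain key-value configuration driving \code{runPipeline}.  Every
#' threshold has the analysis default (occupancy head exclusion 4 codons,
#' expression window pads 12/14 nt with 8-codon head exclusion, queuing
#' candidate filters fold >= 2 with >= 32 reads in each condition); the
#' simulation block defines a two-condition experiment: a null WT library
#' and a mutant whose \code{perturb_codons} get an A-site dwell multiplier
#' of \code{perturb_factor}.
#'
#' @return Named list of configuration values.
#' @export
defaultRunConfig <- function() {
    list(seed = 1L, n_orfs = 20L, orf_min_codons = 150L,
         orf_max_codons = 250L, n_reads = 200000L,
         perturb_site = "A", perturb_codons = "AAA,CAA,GAA",
         perturb_factor = 1.5, queue_probability = 0,
         spacing_nt = 28L, fold_min = 2, reads_min = 32L,
         reads_min_mode = "each", gene_set = "")
}

#' Read / write a pipeline configuration
#'
#' One \code{key = value} pair per line; '#' comments and blank lines are
#' ignored.  Values are parsed as numbers where possible, otherwise kept
#' as strings.  Unknown keys are an error; missing keys take defaults.
#'
#' @param path file path.
#' @param config named list.
#' @return \code{readRunConfig}: the merged configuration list.
#' @export
readRunConfig <- function(path) {
    defaults <- defaultRunConfig()
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    cfg <- defaults
    for (ln in lines) {
        eq <- regexpr("=", ln, fixed = TRUE)
        if (eq < 0L) stop("malformed config line: ", ln)
        key <- trimws(substr(ln, 1L, eq - 1L))
        val <- trimws(substr(ln, eq + 1L, nchar(ln)))
        if (!key %in% names(defaults))
            stop("unknown config key: ", key)
        num <- suppressWarnings(as.numeric(val))
        cfg[[key]] <- if (!is.na(num)) num else val
    }
    cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    writeLines(paste(names(config), unlist(config), sep = " = "), path)
    invisible(path)
}

.needArtifact <- function(path, producer) {
    if (!file.exists(path))
        stop("missing upstream artifact '", basename(path),
             "'; run the '", producer, "' stage first", call. = FALSE)
    path
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.pipeTracks <- function(out_dir, which) {
    orfs <- loadReference(
        .needArtifact(file.path(out_dir, "reference.fasta"), "simulate"),
        .needArtifact(file.path(out_dir, "annotation.tsv"), "simulate"))
    fp <- readFiveprimeTable(.needArtifact(
        file.path(out_dir, paste0(which, "_footprints.tsv")), "simulate"))
    calfile <- file.path(out_dir, "calibration.tsv")
    cal <- if (file.exists(calfile)) {
        tab <- utils::read.delim(calfile)
        off <- stats::setNames(tab$offset, tab$length)
        new("PsiteCalibration", offsets = off,
            frame_shifts = off[["28"]] - off,
            source = tab$source[1], report = tab)
    } else fixedCalibration()
    list(orfs = orfs, fp = fp, cal = cal,
         tracks = poolAndFrameshift(fp, cal, orfs))
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end-to-end with explicit seeding; every stage
#' writes headered TSVs into \code{out_dir}, a manifest listing each file
#' with its row count and the configuration hash, and a log recording
#' dropped-read totals and fallback decisions.  Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param subcommand one of simulate, calibrate, metacodon, occupancy,
#'   compare, queuing, expression, all.
#' @param config configuration list or path (see \code{readRunConfig});
#'   NULL for defaults.
#' @param out_dir output directory (created).
#' @param seed overrides the configuration seed when given.
#' @return Invisibly, the manifest data.frame.
#' @export
runPipeline <- function(subcommand = c("all", "simulate", "calibrate",
                                       "metacodon", "occupancy",
                                       "compare", "queuing",
                                       "expression"),
                        config = NULL, out_dir = ".", seed = NULL) {
    subcommand <- match.arg(subcommand)
    cfg <- if (is.null(config)) defaultRunConfig()
           else if (is.character(config)) readRunConfig(config)
           else utils::modifyList(defaultRunConfig(), config)
    if (!is.null(seed)) cfg$seed <- seed
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfgfile <- file.path(out_dir, "config.used.txt")
    writeRunConfig(cfg, cfgfile)
    log <- character()
    stages <- if (subcommand == "all")
        c("simulate", "calibrate", "metacodon", "occupancy", "compare",
          "queuing", "expression")
    else subcommand
    seed0 <- as.integer(cfg$seed)
    pcods <- setdiff(strsplit(as.character(cfg$perturb_codons),
                              ",")[[1]], "")

    for (st in stages) {
        if (st == "simulate") {
            orfs <- buildSyntheticReference(
                n_orfs = cfg$n_orfs,
                length_range_codons = c(cfg$orf_min_codons,
                                        cfg$orf_max_codons),
                seed = seed0)
            writeReference(orfs, file.path(out_dir, "reference.fasta"),
                           file.path(out_dir, "annotation.tsv"))
            wt_truth <- simulationTruth(orfs, seed = seed0 + 1L)
            mut_truth <- simulationTruth(
                orfs, queue_probability = cfg$queue_probability,
                seed = seed0 + 2L)
            for (cd in pcods)
                mut_truth <- setDwell(mut_truth, cfg$perturb_site, cd,
                                      cfg$perturb_factor)
            wt <- simulateFootprints(orfs, wt_truth, cfg$n_reads)
            mut <- simulateFootprints(orfs, mut_truth, cfg$n_reads)
            writeFiveprimeTable(wt, file.path(out_dir,
                                              "wt_footprints.tsv"))
            writeFiveprimeTable(mut, file.path(out_dir,
                                               "mut_footprints.tsv"))
            writeTruthTables(mut_truth, file.path(out_dir, "truth"))
            log <- c(log, sprintf("simulate: %d WT + %d mutant reads",
                                  sum(wt$count), sum(mut$count)))
        } else if (st == "calibrate") {
            env <- .pipeTracks(out_dir, "wt")
            cal <- calibratePsite(env$fp, env$orfs, fallback_fixed = TRUE)
            rep <- calibrationReport(cal)
            rep$offset <- psiteOffset(cal)[as.character(rep$length)]
            rep$frame_shift <- frameShift(cal)[as.character(rep$length)]
            rep$source <- cal@source
            .writeTsv(rep, file.path(out_dir, "calibration.tsv"))
            log <- c(log, paste0("calibrate: source=", cal@source))
        } else if (st == "metacodon") {
            for (cond in c("wt", "mut")) {
                env <- .pipeTracks(out_dir, cond)
                bt <- assembleBulkTable(env$tracks, env$orfs,
                                        sample_id = cond)
                .writeTsv(bt, file.path(out_dir,
                                        paste0("bulk_", cond, ".tsv")))
            }
            bw <- utils::read.delim(file.path(out_dir, "bulk_wt.tsv"))
            bm <- utils::read.delim(file.path(out_dir, "bulk_mut.tsv"))
            .writeTsv(occupancyChange(bm, bw),
                      file.path(out_dir, "bulk_change.tsv"))
        } else if (st == "occupancy") {
            for (cond in c("wt", "mut")) {
                env <- .pipeTracks(out_dir, cond)
                occ <- singleCodonOccupancy(env$tracks, env$orfs,
                                            sites = .SITE_NAMES)
                .writeTsv(occ, file.path(out_dir,
                                         paste0("occupancy_", cond,
                                                ".tsv")))
                log <- c(log, sprintf(
                    "occupancy[%s]: %d records, dropped %s", cond,
                    nrow(occ),
                    paste(names(droppedCounts(env$tracks)),
                          droppedCounts(env$tracks), sep = "=",
                          collapse = ",")))
            }
        } else if (st == "compare") {
            ow <- utils::read.delim(.needArtifact(
                file.path(out_dir, "occupancy_wt.tsv"), "occupancy"))
            om <- utils::read.delim(.needArtifact(
                file.path(out_dir, "occupancy_mut.tsv"), "occupancy"))
            grid <- ksHeatmap(om, ow)
            long <- data.frame(
                codon = rep(rownames(grid$p), ncol(grid$p)),
                site = rep(colnames(grid$p), each = nrow(grid$p)),
                D = as.vector(grid$D), p_value = as.vector(grid$p),
                log10_p = as.vector(grid$log10_p))
            .writeTsv(long, file.path(out_dir, "ks_grid.tsv"))
            fc <- foldChangeVsCoverage(
                om[om$site == "A", ], ow[ow$site == "A", ],
                codon_sets = list(perturbed = pcods),
                min_reads = cfg$reads_min,
                min_reads_mode = cfg$reads_min_mode)
            .writeTsv(fc$instances,
                      file.path(out_dir, "fold_changes.tsv"))
            .writeTsv(fc$binned,
                      file.path(out_dir, "fold_change_bins.tsv"))
        } else if (st == "queuing") {
            fc <- utils::read.delim(.needArtifact(
                file.path(out_dir, "fold_changes.tsv"), "compare"))
            qc <- queuingConfig(fold_min = cfg$fold_min,
                                reads_min = cfg$reads_min,
                                reads_min_mode = cfg$reads_min_mode)
            cand <- selectCandidates(fc, qc)
            .writeTsv(cand, file.path(out_dir,
                                      "queuing_candidates.tsv"))
            if (nrow(cand)) {
                env <- .pipeTracks(out_dir, "mut")
                mp <- queuingMetaplot(cand, env$tracks, env$orfs, qc)
                .writeTsv(mp, file.path(out_dir,
                                        "queuing_metaplot.tsv"))
            } else {
                log <- c(log, "queuing: no candidates; metaplot skipped")
            }
        } else if (st == "expression") {
            tabs <- list()
            for (cond in c("wt", "mut")) {
                env <- .pipeTracks(out_dir, cond)
                tabs[[cond]] <- rpkmTable(env$tracks, env$orfs,
                                          sample_id = cond)
                .writeTsv(tabs[[cond]],
                          file.path(out_dir, paste0("rpkm_", cond,
                                                    ".tsv")))
            }
            fc <- foldChangeTable(tabs$mut, tabs$wt)
            .writeTsv(fc, file.path(out_dir, "expression_fc.tsv"))
            if (nzchar(cfg$gene_set) && file.exists(cfg$gene_set)) {
                targets <- readGeneSet(cfg$gene_set)
                ks <- targetSetKs(fc, targets)
                .writeTsv(data.frame(key = names(ks),
                                     value = unlist(ks)),
                          file.path(out_dir, "target_enrichment.tsv"))
            }
        }
    }
    files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          c("manifest.tsv", "pipeline.log")))
    nrows <- vapply(files, function(f) {
        p <- file.path(out_dir, f)
        if (grepl("\\.tsv$", f))
            length(readLines(p, warn = FALSE)) - 1L
        else NA_integer_
    }, integer(1))
    manifest <- data.frame(file = files, n_rows = nrows,
                           config_md5 = unname(tools::md5sum(cfgfile)))
    .writeTsv(manifest, file.path(out_dir, "manifest.tsv"))
    writeLines(log, file.path(out_dir, "pipeline.log"))
    invisible(manifest)
}
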