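#' Cohort summary table in the published layout
#'
#' Per-species average CE/mg per year (arithmetic mean over homes), followed
#' by the cohort means of the per-home group log-sums and of the per-home
#' moldiness index. Averaging is per-home first, then across homes, which
#' makes the identity `mean(ERMI) = mean(sum logs group 1) - mean(sum logs
#' group 2)` hold exactly.
#'
#' @param x a floored [MoldExperiment-class] with samples from both years.
#' @param years the two years; default the years present.
#' @param floor detection floor the input must satisfy.
#' @return data.frame with columns `name`, `group`, `avg_<year1>`,
#'   `avg_<year2>`; species rows first, then `Sum logs group 1`,
#'   `Sum logs group 2`, `ERMI`.
#' @export
cohortSummary <- function(x, years = NULL, floor = 1) {
    meta <- colData(x)
    if (is.null(years)) years <- sort(unique(meta$year))
    stopifnot(length(years) == 2L)
    conc <- concentrations(x)
    .assert_floored(conc, floor)
    i1 <- which(meta$year == years[1])
    i2 <- which(meta$year == years[2])
    e <- ermiScores(x, floor)
    species <- data.frame(
        name = rownames(conc), group = rowData(x)$group,
        a1 = rowMeans(conc[, i1, drop = FALSE]),
        a2 = rowMeans(conc[, i2, drop = FALSE]))
    sums <- data.frame(
        name = c("Sum logs group 1", "Sum logs group 2", "ERMI"),
        group = NA_integer_,
        a1 = c(mean(e$sum_logs_g1[i1]), mean(e$sum_logs_g2[i1]),
               mean(e$ermi[i1])),
        a2 = c(mean(e$sum_logs_g1[i2]), mean(e$sum_logs_g2[i2]),
               mean(e$ermi[i2])))
    out <- rbind(species, sums)
    colnames(out)[3:4] <- paste0("avg_", years)
    rownames(out) <- NULL
    out
}

#' Boxplots of Shannon diversity by region and year
#'
#' @param scores output of [scoreCohort()] (needs a `region` column).
#' @return a ggplot object.
#' @export
plotDiversity <- function(scores) {
    df <- as.data.frame(scores)
    if (!"region" %in% colnames(df)) stop("scores lack a 'region' column")
    ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$region),
                                     y = .data$shannon_h,
                                     fill = factor(.data$year))) +
        ggplot2::geom_boxplot() +
        ggplot2::labs(x = "Region", y = "Shannon Diversity Index (nats)",
                      fill = "Year") +
        ggplot2::theme_bw()
}

.md5 <- function(paths) unname(tools::md5sum(paths))

.split_sample_id <- function(id) {
    year <- suppressWarnings(as.integer(sub("^.*_", "", id)))
    if (anyNA(year))
        stop("sample_id must follow '<home_id>_<year>'; offending: ",
             paste(id[is.na(year)], collapse = ", "))
    data.frame(home_id = sub("_[^_]*$", "", id), year = year)
}

#' Run the full assessment pipeline
#'
#' Orchestrates quantify (when Ct input is given) -> floor -> score ->
#' compare into one reproducible run. Writes `scores.csv`,
#' `comparison_report.csv`, `tukey_report.csv` (Tukey HSD letters for Shannon
#' diversity across region-by-year groups), `qc_report.csv` (Ct input only),
#' an `sdi_boxplot.pdf`, and a `manifest.json` echoing the configuration with
#' MD5 checksums of every CSV report, so identical configurations reproduce
#' byte-identical reports.
#'
#' @param config a named list (or path to a JSON file) with fields:
#'   exactly one of `ct_csv` + `spike_csv` or `concentration_csv`;
#'   `metadata_csv`; `out_dir`; optional `alpha` (0.05), `family`
#'   (`"combined"`), `paired` (FALSE), `floor` (1), `dust_mass_mg` (5),
#'   `spike_tolerance_cycles` (3), `seed`.
#' @return the manifest, invisibly (list: `config`, `outputs`, `checksums`,
#'   `log`).
#' @export
runFullAnalysis <- function(config) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    defaults <- list(alpha = 0.05, family = "combined", paired = FALSE,
                     floor = 1, dust_mass_mg = 5,
                     spike_tolerance_cycles = 3, seed = NA_integer_)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]

    has_ct <- !is.null(config$ct_csv)
    has_conc <- !is.null(config$concentration_csv)
    problems <- character()
    if (has_ct == has_conc)
        problems <- c(problems,
                      "provide exactly one of ct_csv or concentration_csv")
    if (has_ct && is.null(config$spike_csv))
        problems <- c(problems, "ct_csv input requires spike_csv")
    if (is.null(config$metadata_csv))
        problems <- c(problems, "metadata_csv is required")
    if (is.null(config$out_dir))
        problems <- c(problems, "out_dir is required")
    for (f in c("ct_csv", "spike_csv", "concentration_csv", "metadata_csv"))
        if (!is.null(config[[f]]) && !file.exists(config[[f]]))
            problems <- c(problems, sprintf("%s not found: %s", f,
                                            config[[f]]))
    if (length(problems))
        stop("invalid run configuration:\n  ",
             paste(problems, collapse = "\n  "))

    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    panel <- buildDefaultPanel()
    metadata <- readMetadataCSV(config$metadata_csv)
    log <- character()
    outputs <- list()

    if (has_ct) {
        ct <- readCtCSV(config$ct_csv)
        spike <- readSpikeCSV(config$spike_csv)
        qcfg <- quantConfig(config$dust_mass_mg,
                            config$spike_tolerance_cycles, config$floor)
        q <- quantifyCohort(ct, spike, panel, qcfg)
        keys <- .split_sample_id(colnames(q$concentration))
        idx <- match(paste(keys$home_id, keys$year),
                     paste(metadata$home_id, metadata$year))
        if (anyNA(idx))
            stop("metadata missing for sample(s): ",
                 paste(colnames(q$concentration)[is.na(idx)], collapse = ", "))
        x <- MoldExperiment(q$concentration, metadata[idx, , drop = FALSE],
                            panel, detected = q$detected)
        qc_path <- file.path(config$out_dir, "qc_report.csv")
        utils::write.csv(q$qc, qc_path, row.names = FALSE, quote = FALSE)
        outputs$qc_report <- qc_path
        log <- c(log, sprintf("quantified %d samples; %d QC failures",
                              nrow(q$qc), sum(q$qc$verdict == "FAIL")))
    } else {
        x <- readConcentrationCSV(config$concentration_csv, panel,
                                  metadata = metadata)
        log <- c(log, sprintf("read %d samples from concentration CSV",
                              ncol(x)))
    }

    x <- floorConcentrations(x, config$floor)
    scores <- scoreCohort(x, config$floor)
    scores_path <- file.path(config$out_dir, "scores.csv")
    writeScoresCSV(scores, scores_path)
    outputs$scores <- scores_path

    yrs <- sort(unique(colData(x)$year))
    if (length(yrs) == 2L && all(table(colData(x)$year) >= 2L)) {
        report <- compareYears(x, years = yrs, alpha = config$alpha,
                               family = config$family,
                               paired = isTRUE(config$paired),
                               floor = config$floor)
        cmp_path <- file.path(config$out_dir, "comparison_report.csv")
        writeComparisonCSV(report, cmp_path)
        outputs$comparison_report <- cmp_path
        nm <- sum(report$method == "NM", na.rm = TRUE)
        log <- c(log, sprintf(
            "comparison battery: Holm family size %d, %d species NM, %d significant at alpha=%g",
            metadata(report)$holm_family_size, nm,
            sum(report$significant), config$alpha))
    } else {
        log <- c(log, "comparison battery skipped: need 2 years with >= 2 homes each")
    }

    df <- as.data.frame(scores)
    if ("region" %in% colnames(df)) {
        grp <- interaction(df$region, df$year, sep = "_", drop = TRUE)
        if (nlevels(grp) >= 2L && all(table(grp) >= 2L)) {
            tk <- anovaTukey(df$shannon_h, grp, alpha = config$alpha)
            tk_path <- file.path(config$out_dir, "tukey_report.csv")
            writeTukeyCSV(tk, tk_path)
            outputs$tukey_report <- tk_path
            if (any(tk$summary$small_n))
                log <- c(log, paste("Tukey groups with n < 3:",
                                    paste(tk$summary$group[tk$summary$small_n],
                                          collapse = ", ")))
        } else {
            log <- c(log, "Tukey stage skipped: region-year groups need n >= 2")
        }
        fig_path <- file.path(config$out_dir, "sdi_boxplot.pdf")
        ggplot2::ggsave(fig_path, plotDiversity(scores),
                        width = 7, height = 5)
        outputs$figure <- fig_path
    }

    csvs <- unlist(outputs[names(outputs) != "figure"], use.names = TRUE)
    manifest <- list(config = config,
                     outputs = lapply(outputs, normalizePath),
                     checksums = as.list(stats::setNames(.md5(csvs),
                                                         names(csvs))),
                     log = log)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    invisible(manifest)
}
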