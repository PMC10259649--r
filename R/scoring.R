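.assert_floored <- function(conc, floor = 1) {
    if (any(conc < floor))
        stop("concentrations below the detection floor (", floor,
             " CE/mg): apply floorConcentrations() first")
}

#' Environmental Relative Moldiness Index per sample
#'
#' The moldiness index of a home is the sum of the common (base-10) logs of
#' the 26 group-1 (water-damage indicator) concentrations minus the sum of
#' the common logs of the 10 group-2 (outdoor-origin) concentrations,
#' computed on floored CE/mg values:
#' \deqn{ERMI = \sum_{i=1}^{26} \log_{10}(s_{1i}) - \sum_{j=1}^{10} \log_{10}(s_{2j})}
#' With the floor at 1 CE/mg both log-sums are non-negative and a fully
#' non-detected group contributes 0.
#'
#' @param x a floored [MoldExperiment-class] (every value >= `floor`).
#' @param floor the detection floor the input must satisfy (default 1).
#' @return a [S4Vectors::DataFrame] with one row per sample: `home_id`,
#'   `year`, `sum_logs_g1`, `sum_logs_g2`, `ermi`.
#' @examples
#' panel <- buildDefaultPanel()
#' m <- matrix(1, 36, 1, dimnames = list(panelSpecies(panel), NULL))
#' x <- MoldExperiment(m, data.frame(home_id = "H1", year = 2018), panel)
#' ermiScores(x)$ermi  # 0
#' @export
ermiScores <- function(x, floor = 1) {
    conc <- concentrations(x)
    .assert_floored(conc, floor)
    g <- rowData(x)$group
    lg <- log10(conc)
    s1 <- colSums(lg[g == 1L, , drop = FALSE])
    s2 <- colSums(lg[g == 2L, , drop = FALSE])
    meta <- colData(x)
    S4Vectors::DataFrame(home_id = meta$home_id, year = meta$year,
                         sum_logs_g1 = unname(s1), sum_logs_g2 = unname(s2),
                         ermi = unname(s1 - s2),
                         row.names = colnames(x))
}

#' Shannon diversity and equitability per sample
#'
#' Treats the floored CE/mg values of the full 36-species panel as
#' abundances: with proportions `p_i = value_i / sum(values)`, the Shannon
#' index is `H = -sum(p_i * log(p_i))` (natural log, so nats), equitability
#' is `H / log(36)` (in \[0,1\]), and richness counts species strictly above
#' the floor (floor-level values are treated as censored non-observations for
#' richness but still enter the proportions, so an all-floor sample is
#' well-defined with uniform `p`).
#'
#' @inheritParams ermiScores
#' @return a [S4Vectors::DataFrame]: `home_id`, `year`, `shannon_h`,
#'   `equitability`, `richness`.
#' @export
shannonDiversity <- function(x, floor = 1) {
    conc <- concentrations(x)
    .assert_floored(conc, floor)
    p <- sweep(conc, 2, colSums(conc), "/")
    h <- -colSums(ifelse(p > 0, p * log(p), 0))
    meta <- colData(x)
    S4Vectors::DataFrame(home_id = meta$home_id, year = meta$year,
                         shannon_h = unname(h),
                         equitability = unname(h / log(nrow(conc))),
                         richness = unname(colSums(conc > floor)),
                         row.names = colnames(x))
}

#' Score a cohort: moldiness index plus diversity, joined with metadata
#'
#' One scored record per (home, year), carrying region and the other home
#' metadata, with group means by (region, year) and by year attached as
#' metadata for reporting.
#'
#' @inheritParams ermiScores
#' @return a [S4Vectors::DataFrame] with columns `home_id`, `year`, `region`
#'   (when present), `sum_logs_g1`, `sum_logs_g2`, `ermi`, `shannon_h`,
#'   `equitability`, `richness`; `metadata(...)$by_region_year` and
#'   `metadata(...)$by_year` hold the group means.
#' @export
scoreCohort <- function(x, floor = 1) {
    meta <- colData(x)
    if (anyNA(meta$home_id) || anyNA(meta$year))
        stop("samples lacking home_id/year metadata: ",
             paste(colnames(x)[is.na(meta$home_id) | is.na(meta$year)],
                   collapse = ", "))
    e <- ermiScores(x, floor)
    d <- shannonDiversity(x, floor)
    out <- e
    out$shannon_h <- d$shannon_h
    out$equitability <- d$equitability
    out$richness <- d$richness
    if ("region" %in% colnames(meta)) {
        out$region <- meta$region
        out <- out[, c("home_id", "year", "region", "sum_logs_g1",
                       "sum_logs_g2", "ermi", "shannon_h", "equitability",
                       "richness")]
    }
    num <- c("sum_logs_g1", "sum_logs_g2", "ermi", "shannon_h",
             "equitability", "richness")
    df <- as.data.frame(out)
    by_year <- stats::aggregate(df[num], by = list(year = df$year), FUN = mean)
    metadata(out)$by_year <- by_year
    if ("region" %in% colnames(df))
        metadata(out)$by_region_year <- stats::aggregate(
            df[num], by = list(region = df$region, year = df$year),
            FUN = mean)
    out
}

#' Write a scored cohort to CSV
#'
#' Schema: `home_id,year,region,sum_logs_g1,sum_logs_g2,ermi,shannon_h,`
#' `equitability,richness` at full precision.
#'
#' @param scores output of [scoreCohort()].
#' @param path CSV file path.
#' @export
writeScoresCSV <- function(scores, path) {
    utils::write.csv(as.data.frame(scores), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}
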