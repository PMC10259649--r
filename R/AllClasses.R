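#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' MoldPanel: the 36-assay ERMI registry
#'
#' An ordered registry of the 36 indicator-mold qPCR assays used by the
#' Environmental Relative Moldiness Index (ERMI): 26 group-1 species
#' (associated with indoor water damage) and 10 group-2 species (primarily of
#' outdoor origin). Each assay carries its standard-curve parameters
#' (`slope`, Ct per log10 cell equivalent, negative; `intercept`, the Ct at
#' 1 cell equivalent) and the final qPCR cycle `max_cycle` beyond which a
#' reaction is a non-detect.
#'
#' @slot assays a [S4Vectors::DataFrame] with one row per assay and columns
#'   `species`, `group` (integer 1 or 2), `slope`, `intercept`, `max_cycle`,
#'   plus reference columns `ref_avg_2018`/`ref_avg_2019` carrying the
#'   published cohort average concentrations (CE/mg) used to calibrate the
#'   synthetic generator.
#'
#' @seealso [buildDefaultPanel()]
#' @export
setClass("MoldPanel", slots = c(assays = "DataFrame"))

setValidity("MoldPanel", function(object) {
    a <- object@assays
    msg <- character()
    need <- c("species", "group", "slope", "intercept", "max_cycle")
    if (!all(need %in% colnames(a)))
        return(paste("assays must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(a$species))
        msg <- c(msg, "species names must be unique")
    if (!all(a$group %in% c(1L, 2L)))
        msg <- c(msg, "group must be 1 or 2")
    if (any(a$slope >= 0))
        msg <- c(msg, "slopes must be negative (more template, earlier Ct)")
    if (any(a$max_cycle <= 0))
        msg <- c(msg, "max_cycle must be positive")
    if (length(msg)) msg else TRUE
})

#' MoldExperiment: homes-by-panel concentration container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding mold concentrations
#' in cell equivalents per mg dust (CE/mg). Rows are the 36 panel species
#' (rowData carries the assay registry), columns are dust samples keyed by
#' `(home_id, year)` with home metadata in colData. Two assays are stored:
#' `"concentration"` (non-negative CE/mg; non-detects are 0 before flooring)
#' and `"detected"` (logical).
#'
#' Construct with [MoldExperiment()]; read from disk with
#' [readConcentrationCSV()].
#'
#' @export
setClass("MoldExperiment", contains = "SummarizedExperiment")

setValidity("MoldExperiment", function(object) {
    msg <- character()
    if (!all(c("concentration", "detected") %in% assayNames(object)))
        msg <- c(msg, "assays 'concentration' and 'detected' are required")
    else {
        conc <- assay(object, "concentration")
        if (any(conc < 0, na.rm = TRUE) || anyNA(conc))
            msg <- c(msg, "concentrations must be non-negative and non-missing")
    }
    if (!all(c("group") %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must carry the panel 'group' column")
    if (!all(c("home_id", "year") %in% colnames(colData(object))))
        msg <- c(msg, "colData must carry 'home_id' and 'year'")
    if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the synthetic cohort generator
#'
#' Collects every knob of [simulateCohort()]: the region design, per-species
#' lognormal baselines, the multiplicative water-damage and phylloplane-bloom
#' effects, remediation recovery, the detection floor, and the seed.
#'
#' @slot region_sizes integer(5), homes per region (default 6,5,2,5,2).
#' @slot years integer(2), sampling years (default 2018, 2019).
#' @slot mu numeric(36) or NULL; per-species mean of log10(CE/mg). NULL means
#'   "calibrate from the panel's published reference averages".
#' @slot sigma numeric, per-species sd of log10(CE/mg) (default 0.5; recycled).
#' @slot damage_multiplier_g1 numeric >= 1, fold-change of group-1 species in
#'   water-damaged homes (default 10).
#' @slot bloom_multiplier_g2 numeric >= 1, fold-change of group-2 species in
#'   the second year (default 3), emulating a post-hurricane phylloplane bloom.
#' @slot remediation_recovery numeric in \[0,1\], fraction of the damage effect
#'   removed in the second year for remediated homes (default 1).
#' @slot detection_floor numeric, CE/mg below which a draw is a non-detect
#'   (default 1).
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticConfig()], [simulateCohort()]
#' @export
setClass("SyntheticConfig", slots = c(
    region_sizes = "integer",
    years = "integer",
    mu = "ANY",
    sigma = "numeric",
    damage_multiplier_g1 = "numeric",
    bloom_multiplier_g2 = "numeric",
    remediation_recovery = "numeric",
    detection_floor = "numeric",
    seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (length(object@region_sizes) < 1L || any(object@region_sizes < 1L))
        msg <- c(msg, "region_sizes must be positive")
    if (length(object@years) != 2L || object@years[1] >= object@years[2])
        msg <- c(msg, "years must be two increasing years")
    if (object@damage_multiplier_g1 < 1 || object@bloom_multiplier_g2 < 1)
        msg <- c(msg, "effect multipliers must be >= 1")
    if (object@remediation_recovery < 0 || object@remediation_recovery > 1)
        msg <- c(msg, "remediation_recovery must be in [0,1]")
    if (any(object@sigma <= 0))
        msg <- c(msg, "sigma must be positive")
    if (object@detection_floor < 0)
        msg <- c(msg, "detection_floor must be non-negative")
    if (length(msg)) msg else TRUE
})
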