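# The 36-species ERMI registry. Names are the closed vocabulary of the panel
# (including the two Cladosporium cladosporioides assay types, the Mucor
# group assay, and Penicillium chrysogenum type 2); matching elsewhere is
# case-sensitive after whitespace trimming. ref_avg_* are the published
# cohort averages (CE/mg dust) used to calibrate the synthetic generator.
.panel_registry <- function() {
    g1 <- rbind(
        c("Aspergillus flavus",            12,    29),
        c("Aspergillus fumigatus",          2,     3),
        c("Aspergillus niger",            156,   357),
        c("Aspergillus ochraceus",          2,    13),
        c("Aspergillus penicillioides", 42363, 22068),
        c("Aspergillus restrictus",        94,    31),
        c("Aspergillus sclerotiorum",      68,    35),
        c("Aspergillus sydowii",          322,   326),
        c("Aspergillus unguis",            13,    19),
        c("Aspergillus versicolor",       668,   164),
        c("Aureobasidium pullulans",      170,    87),
        c("Chaetomium globosum",           73,   111),
        c("Cladosporium sphaerospermum",10082,   468),
        c("Eurotium amstelodami",         178,   300),
        c("Paecilomyces variotii",         16,    14),
        c("Penicillium brevicompactum",     3,    12),
        c("Penicillium corylophilum",       1,     1),
        c("Penicillium crustosum",          7,   615),
        c("Penicillium purpurogenum",       2,     9),
        c("Penicillium spinulosum",         1,     1),
        c("Penicillium variabile",         30,    12),
        c("Scopulariopsis brevicaulis",     4,     8),
        c("Scopulariopsis chartarum",      91,    32),
        c("Stachybotrys chartarum",         2,     2),
        c("Trichoderma viride",            18,     9),
        c("Wallemia sebi",               2318,  2346))
    g2 <- rbind(
        c("Acremonium strictum",            1,     3),
        c("Alternaria alternata",           5,    17),
        c("Aspergillus ustus",              3,     5),
        c("Cladosporium cladosporioides 1", 508, 1530),
        c("Cladosporium cladosporioides 2",   3,    3),
        c("Cladosporium herbarum",          1,     2),
        c("Epicoccum nigrum",               1,     1),
        c("Mucor group",                   14,    50),
        c("Penicillium chrysogenum 2",      1,     1),
        c("Rhizopus stolonifer",            4,    41))
    data.frame(
        species = c(g1[, 1], g2[, 1]),
        group = rep(c(1L, 2L), c(nrow(g1), nrow(g2))),
        ref_avg_2018 = as.numeric(c(g1[, 2], g2[, 2])),
        ref_avg_2019 = as.numeric(c(g1[, 3], g2[, 3])),
        stringsAsFactors = FALSE)
}

#' Build the default 36-assay ERMI panel
#'
#' Returns the standard ERMI registry: 26 group-1 assays (water-damage
#' indicator molds) and 10 group-2 assays (molds that primarily enter the
#' home from outdoors), in panel order. Standard-curve defaults assume a
#' perfectly efficient assay (one template doubling per cycle, slope
#' `-1/log10(2) = -3.3219`) with a single cell equivalent amplifying at the
#' final cycle (`intercept = max_cycle = 40`); load real per-assay curves by
#' editing `panelAssays()` columns or via [importPanelJSON()].
#'
#' @param slope,intercept,max_cycle standard-curve defaults applied to every
#'   assay.
#' @return a [MoldPanel-class] object.
#' @examples
#' panel <- buildDefaultPanel()
#' table(panelGroups(panel))
#' @export
buildDefaultPanel <- function(slope = -1 / log10(2), intercept = 40,
                              max_cycle = 40) {
    reg <- .panel_registry()
    a <- S4Vectors::DataFrame(
        species = reg$species,
        group = reg$group,
        slope = rep(slope, nrow(reg)),
        intercept = rep(intercept, nrow(reg)),
        max_cycle = rep(max_cycle, nrow(reg)),
        ref_avg_2018 = reg$ref_avg_2018,
        ref_avg_2019 = reg$ref_avg_2019)
    rownames(a) <- a$species
    new("MoldPanel", assays = a)
}

#' Panel accessors
#'
#' `panelAssays()` returns the full registry DataFrame; `panelSpecies()` the
#' species names in panel order; `panelGroups()` the integer group vector
#' named by species; `groupSpecies()` the species of one group.
#'
#' @param panel a [MoldPanel-class].
#' @param group 1 or 2.
#' @export
panelAssays <- function(panel) panel@assays

#' @rdname panelAssays
#' @export
panelSpecies <- function(panel) panel@assays$species

#' @rdname panelAssays
#' @export
panelGroups <- function(panel) {
    g <- panel@assays$group
    names(g) <- panel@assays$species
    g
}

#' @rdname panelAssays
#' @export
groupSpecies <- function(panel, group) {
    panel@assays$species[panel@assays$group == group]
}

setMethod("show", "MoldPanel", function(object) {
    g <- table(object@assays$group)
    cat(sprintf("MoldPanel with %d assays (%s group 1, %s group 2)\n",
                nrow(object@assays), g[["1"]], g[["2"]]))
    cat("  first:", object@assays$species[1], "\n")
    cat("  last: ", object@assays$species[nrow(object@assays)], "\n")
})

#' Validate a wide concentration table against a panel
#'
#' Schema validation that reports rather than throws: checks that every panel
#' species is present as a column, that no unknown species columns appear,
#' and that all values are non-negative and non-missing (`NA` is reserved for
#' the non-detect encoding handled by [readConcentrationCSV()]).
#'
#' @param x a data.frame in the wide concentration layout
#'   (`home_id`, `year`, then one column per species).
#' @param panel a [MoldPanel-class].
#' @return a character vector of human-readable violations; empty when valid.
#' @export
validateConcentrations <- function(x, panel) {
    violations <- character()
    sp <- panelSpecies(panel)
    for (col in c("home_id", "year"))
        if (!col %in% colnames(x))
            violations <- c(violations,
                            sprintf("missing key column '%s'", col))
    missing_sp <- setdiff(sp, colnames(x))
    for (s in missing_sp)
        violations <- c(violations,
                        sprintf("missing panel species column '%s'", s))
    extra <- setdiff(colnames(x), c("home_id", "year", sp))
    for (s in extra)
        violations <- c(violations,
                        sprintf("unknown species column '%s'", s))
    for (s in intersect(sp, colnames(x))) {
        v <- x[[s]]
        bad <- which(!is.na(v) & v < 0)
        for (i in bad)
            violations <- c(violations, sprintf(
                "negative concentration: row %d (home %s), species '%s'",
                i, as.character(x$home_id[i]), s))
    }
    violations
}

#' Export / import a panel registry as JSON
#'
#' The JSON schema carries one record per assay with fields `species`,
#' `group`, `slope`, `intercept`, `max_cycle`, so laboratory-specific
#' standard curves can be stored and reloaded.
#'
#' @param panel a [MoldPanel-class].
#' @param path file path.
#' @return `importPanelJSON()` returns a [MoldPanel-class];
#'   `exportPanelJSON()` returns `path` invisibly.
#' @export
exportPanelJSON <- function(panel, path) {
    a <- as.data.frame(panelAssays(panel))
    rownames(a) <- NULL
    jsonlite::write_json(
        a[, c("species", "group", "slope", "intercept", "max_cycle")],
        path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname exportPanelJSON
#' @export
importPanelJSON <- function(path) {
    a <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- S4Vectors::DataFrame(
        species = as.character(a$species),
        group = as.integer(a$group),
        slope = as.numeric(a$slope),
        intercept = as.numeric(a$intercept),
        max_cycle = as.numeric(a$max_cycle))
    reg <- .panel_registry()
    idx <- match(df$species, reg$species)
    df$ref_avg_2018 <- reg$ref_avg_2018[idx]
    df$ref_avg_2019 <- reg$ref_avg_2019[idx]
    rownames(df) <- df$species
    new("MoldPanel", assays = df)
}
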