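#' Construct a MoldExperiment
#'
#' Assembles the central container from a concentration matrix, home
#' metadata, and the assay panel. Columns (samples) are keyed
#' `"<home_id>_<year>"`; the same home may appear in both years, or in only
#' one.
#'
#' @param concentration numeric matrix of CE/mg, species x samples. Rownames
#'   must be exactly the panel species (any order; reordered to panel order).
#' @param metadata data.frame with one row per sample: columns `home_id`,
#'   `year` and optionally `region`, `water_damage`, `material`,
#'   `ventilation`, `dog`, `remediated`. Matched to samples by
#'   `(home_id, year)`.
#' @param panel a [MoldPanel-class].
#' @param detected logical matrix of the same shape; defaults to
#'   `concentration > 0`.
#' @return a [MoldExperiment-class].
#' @examples
#' panel <- buildDefaultPanel()
#' m <- matrix(10, nrow = 36, ncol = 2,
#'             dimnames = list(panelSpecies(panel), NULL))
#' meta <- data.frame(home_id = c("H1", "H1"), year = c(2018, 2019))
#' MoldExperiment(m, meta, panel)
#' @export
MoldExperiment <- function(concentration, metadata, panel,
                           detected = concentration > 0) {
    sp <- panelSpecies(panel)
    if (is.null(rownames(concentration)))
        stop("concentration matrix must have species rownames")
    rn <- trimws(rownames(concentration))
    missing_sp <- setdiff(sp, rn)
    if (length(missing_sp))
        stop("concentration matrix is missing panel species: ",
             paste(missing_sp, collapse = ", "))
    extra <- setdiff(rn, sp)
    if (length(extra))
        stop("unknown species in concentration matrix: ",
             paste(extra, collapse = ", "))
    rownames(concentration) <- rn
    concentration <- concentration[sp, , drop = FALSE]
    detected <- detected[sp, , drop = FALSE]

    keys <- paste(metadata$home_id, metadata$year, sep = "_")
    if (ncol(concentration) != nrow(metadata))
        stop("metadata must have one row per sample column")
    cd <- S4Vectors::DataFrame(metadata)
    rownames(cd) <- keys
    colnames(concentration) <- keys
    colnames(detected) <- keys
    se <- SummarizedExperiment(
        assays = list(concentration = concentration,
                      detected = detected),
        rowData = panelAssays(panel),
        colData = cd)
    new("MoldExperiment", se)
}

setMethod("show", "MoldExperiment", function(object) {
    callNextMethod()
    yrs <- table(colData(object)$year)
    cat("samples per year:",
        paste(sprintf("%s=%d", names(yrs), as.integer(yrs)), collapse = ", "),
        "\n")
})

#' Concentration and detection accessors
#'
#' `concentrations()` returns the species x samples CE/mg matrix;
#' `isDetected()` the logical detection matrix; `homeMetadata()` the sample
#' metadata as a data.frame.
#'
#' @param x a [MoldExperiment-class].
#' @export
concentrations <- function(x) assay(x, "concentration")

#' @rdname concentrations
#' @export
isDetected <- function(x) assay(x, "detected")

#' @rdname concentrations
#' @export
homeMetadata <- function(x) as.data.frame(colData(x))

# non-detect encodings accepted in the wide CSV
.is_nd <- function(v) is.na(v) | trimws(v) %in% c("", "ND", "nd")

#' Read / write the wide concentration CSV
#'
#' The wide schema has header `home_id,year,<36 species names>`; non-detects
#' are encoded as an empty cell or `ND` (written as `ND`) and become
#' concentration 0 with a `FALSE` detection flag. Values survive a
#' write/read round trip bit-equal (written with full precision).
#'
#' @param path CSV file path.
#' @param panel a [MoldPanel-class].
#' @param metadata optional data.frame of home metadata keyed by
#'   `(home_id, year)` (e.g. from [readMetadataCSV()]) joined onto the
#'   samples; defaults to the keys found in the file.
#' @return `readConcentrationCSV()` a [MoldExperiment-class];
#'   `writeConcentrationCSV()` the path, invisibly.
#' @export
readConcentrationCSV <- function(path, panel, metadata = NULL) {
    raw <- utils::read.csv(path, check.names = FALSE,
                           colClasses = "character")
    colnames(raw) <- trimws(colnames(raw))
    sp <- panelSpecies(panel)
    num <- raw
    violations <- character()
    for (s in intersect(colnames(raw), sp)) {
        v <- suppressWarnings(as.numeric(raw[[s]]))
        nd <- .is_nd(raw[[s]])
        garbled <- which(is.na(v) & !nd)
        for (i in garbled)
            violations <- c(violations, sprintf(
                "non-numeric value '%s' in row %d, species '%s'",
                raw[[s]][i], i, s))
        v[nd] <- NA  # NA marks a non-detect from here on
        num[[s]] <- v
    }
    violations <- c(violations, validateConcentrations(num, panel))
    if (length(violations))
        stop("invalid concentration table:\n  ",
             paste(violations, collapse = "\n  "))
    nsamp <- nrow(raw)
    conc <- matrix(0, nrow = length(sp), ncol = nsamp,
                   dimnames = list(sp, NULL))
    detm <- matrix(FALSE, nrow = length(sp), ncol = nsamp,
                   dimnames = list(sp, NULL))
    for (s in sp) {
        v <- num[[s]]
        detm[s, ] <- !is.na(v)
        v[is.na(v)] <- 0
        conc[s, ] <- v
    }
    meta <- data.frame(home_id = raw$home_id,
                       year = as.integer(raw$year))
    if (!is.null(metadata)) {
        idx <- match(paste(meta$home_id, meta$year),
                     paste(metadata$home_id, metadata$year))
        if (anyNA(idx))
            stop("metadata missing for home(s): ",
                 paste(unique(meta$home_id[is.na(idx)]), collapse = ", "))
        meta <- metadata[idx, , drop = FALSE]
    }
    MoldExperiment(conc, meta, panel, detected = detm)
}

#' @rdname readConcentrationCSV
#' @param x a [MoldExperiment-class] to write.
#' @export
writeConcentrationCSV <- function(x, path) {
    conc <- concentrations(x)
    det <- isDetected(x)
    meta <- homeMetadata(x)
    wide <- data.frame(home_id = meta$home_id, year = meta$year,
                       check.names = FALSE)
    for (s in rownames(conc)) {
        v <- format(conc[s, ], digits = 17, scientific = FALSE, trim = TRUE)
        v[!det[s, ]] <- "ND"
        wide[[s]] <- v
    }
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write the home metadata CSV
#'
#' Schema: `home_id,region,year,water_damage,material,ventilation,dog`
#' (an optional `remediated` column is preserved). Vocabulary follows the
#' study design: `material` in Cement/Wood/vinyl, `ventilation` in
#' Natural/full AC, logical `water_damage` and `dog`.
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
readMetadataCSV <- function(path) {
    m <- utils::read.csv(path, check.names = FALSE)
    m$year <- as.integer(m$year)
    m$region <- as.integer(m$region)
    for (col in intersect(c("water_damage", "dog", "remediated"), colnames(m)))
        m[[col]] <- as.logical(m[[col]])
    m
}

#' @rdname readMetadataCSV
#' @param metadata data.frame to write.
#' @export
writeMetadataCSV <- function(metadata, path) {
    utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
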