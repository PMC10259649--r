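#' Quantification settings
#'
#' @param dust_mass_mg dust mass analyzed per sample, mg (the protocol
#'   extracts 5 mg of sieved dust).
#' @param spike_tolerance_cycles maximum allowed |observed - reference| Ct
#'   shift of the *Geotrichum candidum* extraction spike before the sample is
#'   flagged as a QC failure (3 cycles is roughly an 8-fold recovery loss).
#' @param floor_ce_per_mg detection floor applied by [floorConcentrations()]
#'   so that every log10 term of the moldiness score is defined and
#'   non-negative.
#' @return a named list used by [quantifySample()] and
#'   [floorConcentrations()].
#' @export
quantConfig <- function(dust_mass_mg = 5, spike_tolerance_cycles = 3,
                        floor_ce_per_mg = 1) {
    stopifnot(dust_mass_mg > 0, spike_tolerance_cycles > 0,
              floor_ce_per_mg > 0)
    list(dust_mass_mg = dust_mass_mg,
         spike_tolerance_cycles = spike_tolerance_cycles,
         floor_ce_per_mg = floor_ce_per_mg)
}

#' Convert a cycle threshold to cell equivalents
#'
#' Inverts the per-assay linear standard curve
#' `Ct = intercept + slope * log10(CE)`, i.e. `CE = 10^((ct - intercept) /
#' slope)`. With the default perfect-doubling slope `-1/log10(2)` each cycle
#' earlier doubles the estimated template.
#'
#' @param ct cycle threshold(s); must lie in `(0, max_cycle]`. `NA` (a
#'   non-detect) is rejected: non-detects never take the numeric conversion
#'   path, they are floored downstream.
#' @param slope,intercept,max_cycle standard-curve parameters, e.g. one row
#'   of [panelAssays()].
#' @return cell equivalents (linear scale), same length as `ct`.
#' @examples
#' ctToCellEquivalents(40, slope = -1 / log10(2), intercept = 40) # 1 CE
#' @export
ctToCellEquivalents <- function(ct, slope, intercept, max_cycle = 40) {
    if (anyNA(ct))
        stop("non-detect Ct: use the flooring path, not numeric conversion")
    if (any(ct <= 0 | ct > max_cycle))
        stop(sprintf("ct must be in (0, %g]", max_cycle))
    if (slope >= 0) stop("slope must be negative")
    10^((ct - intercept) / slope)
}

#' Quantify one dust sample from its Ct records
#'
#' Converts per-assay replicate Ct values to cell equivalents, averages
#' replicates on the linear (CE) scale, and divides by the analyzed dust
#' mass to give CE/mg. Species with no amplifying replicate are non-detects
#' (value 0, flag `FALSE`). The extraction spike gates quality: if the
#' observed spike Ct deviates from its reference by more than
#' `spike_tolerance_cycles` the verdict is `"FAIL"` and the values are
#' returned flagged unreliable (they are still reported, never dropped).
#'
#' @param records data.frame with columns `species_name`, `replicate`, `ct`
#'   (`NA` = non-detect) for one sample.
#' @param spike list or one-row data.frame with `ct_observed` and
#'   `ct_reference`.
#' @param panel a [MoldPanel-class].
#' @param config see [quantConfig()].
#' @return list with `concentration` (named numeric over all panel species,
#'   CE/mg), `detected` (named logical), `qc` (list: `verdict` "PASS"/"FAIL",
#'   `delta_cycles`, `reliable`).
#' @export
quantifySample <- function(records, spike, panel, config = quantConfig()) {
    sp <- panelSpecies(panel)
    records$species_name <- trimws(records$species_name)
    unknown <- setdiff(unique(records$species_name), sp)
    if (length(unknown))
        stop("unknown species in Ct records: ",
             paste(unknown, collapse = ", "))
    dup <- duplicated(records[, c("species_name", "replicate")])
    if (any(dup))
        stop("duplicate (species, replicate) Ct records: ",
             paste(unique(records$species_name[dup]), collapse = ", "))

    conc <- stats::setNames(numeric(length(sp)), sp)
    det <- stats::setNames(logical(length(sp)), sp)
    a <- panelAssays(panel)
    for (s in unique(records$species_name)) {
        cts <- records$ct[records$species_name == s]
        cts <- cts[!is.na(cts)]
        if (!length(cts)) next  # all replicates non-detect
        ce <- ctToCellEquivalents(cts, slope = a[s, "slope"],
                                  intercept = a[s, "intercept"],
                                  max_cycle = a[s, "max_cycle"])
        conc[s] <- mean(ce) / config$dust_mass_mg
        det[s] <- TRUE
    }
    delta <- abs(spike$ct_observed - spike$ct_reference)
    pass <- delta <= config$spike_tolerance_cycles
    list(concentration = conc, detected = det,
         qc = list(verdict = if (pass) "PASS" else "FAIL",
                   delta_cycles = unname(delta), reliable = pass))
}

#' Quantify a cohort of samples
#'
#' Applies [quantifySample()] to every sample in a long Ct table and returns
#' the assembled concentration matrix plus the per-sample QC report.
#'
#' @param ct data.frame, long layout: `sample_id,species_name,replicate,ct`
#'   (`ct` empty/`NA` = non-detect).
#' @param spike data.frame: `sample_id,ct_observed,ct_reference`, one row per
#'   sample.
#' @param panel a [MoldPanel-class].
#' @param config see [quantConfig()].
#' @return list with `concentration` (species x samples matrix), `detected`
#'   (logical matrix), and `qc` (data.frame `sample_id,verdict,delta_cycles`).
#' @export
quantifyCohort <- function(ct, spike, panel, config = quantConfig()) {
    ids <- unique(ct$sample_id)
    sp <- panelSpecies(panel)
    conc <- matrix(0, length(sp), length(ids), dimnames = list(sp, ids))
    det <- matrix(FALSE, length(sp), length(ids), dimnames = list(sp, ids))
    qc <- data.frame(sample_id = ids, verdict = NA_character_,
                     delta_cycles = NA_real_)
    for (i in seq_along(ids)) {
        srow <- spike[spike$sample_id == ids[i], , drop = FALSE]
        if (nrow(srow) != 1L)
            stop("expected exactly one spike record for sample ", ids[i])
        q <- quantifySample(ct[ct$sample_id == ids[i], , drop = FALSE],
                            srow, panel, config)
        conc[, i] <- q$concentration
        det[, i] <- q$detected
        qc$verdict[i] <- q$qc$verdict
        qc$delta_cycles[i] <- q$qc$delta_cycles
    }
    list(concentration = conc, detected = det, qc = qc)
}

#' Read the long Ct CSV and the spike CSV
#'
#' Ct schema: `sample_id,species_name,replicate,ct` with `ct` empty for a
#' non-detect. Spike schema: `sample_id,ct_observed,ct_reference`.
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
readCtCSV <- function(path) {
    x <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(ct = "character"))
    x$ct <- suppressWarnings(as.numeric(x$ct))
    x$replicate <- as.integer(x$replicate)
    x
}

#' @rdname readCtCSV
#' @export
readSpikeCSV <- function(path) utils::read.csv(path, check.names = FALSE)

#' Apply the detection floor
#'
#' Replaces every concentration below `floor` by `floor`, leaving detection
#' flags untouched. Flooring makes the log10 terms of the moldiness score
#' total and non-negative (a fully non-detected group contributes 0 to its
#' log-sum) and is idempotent. It is the last quantification step: flooring
#' must happen after per-mg normalization, never before.
#'
#' @param x a [MoldExperiment-class] (or plain numeric matrix).
#' @param floor detection floor in CE/mg (default 1).
#' @return same class as `x`, floored.
#' @export
setGeneric("floorConcentrations",
           function(x, floor = 1) standardGeneric("floorConcentrations"))

#' @rdname floorConcentrations
#' @export
setMethod("floorConcentrations", "MoldExperiment", function(x, floor = 1) {
    conc <- assay(x, "concentration")
    conc[conc < floor] <- floor
    assay(x, "concentration") <- conc
    metadata(x)$floor <- floor
    x
})

#' @rdname floorConcentrations
#' @export
setMethod("floorConcentrations", "matrix", function(x, floor = 1) {
    x[x < floor] <- floor
    x
})
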