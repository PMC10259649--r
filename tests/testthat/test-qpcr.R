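perfect <- -1 / log10(2)  # one template doubling per cycle

test_that("standard-curve inversion matches its closed form", {
    # ct = intercept -> 1 CE
    expect_equal(ctToCellEquivalents(40, perfect, 40), 1)
    # one cycle earlier doubles the template
    expect_equal(ctToCellEquivalents(39, perfect, 40), 2, tolerance = 1e-3)
    # direct evaluation of 10^((ct - intercept)/slope)
    expect_equal(ctToCellEquivalents(26.713, perfect, 40), 1e4,
                 tolerance = 5e-3)
    # monotone: lower Ct never gives lower CE
    cts <- sort(runif(50, 5, 40))
    ces <- ctToCellEquivalents(cts, perfect, 40)
    expect_true(all(diff(ces) <= 0))
    # non-detects and out-of-range cycles are rejected
    expect_error(ctToCellEquivalents(NA_real_, perfect, 40), "floor")
    expect_error(ctToCellEquivalents(41, perfect, 40))
})

test_that("quantifySample averages replicate CEs and normalizes per mg", {
    panel <- buildDefaultPanel()
    # CE 500 over 5 mg -> 100 CE/mg (two replicates at the same Ct)
    ct500 <- 40 + perfect * log10(500)
    rec <- data.frame(species_name = "Wallemia sebi", replicate = 1:2,
                      ct = ct500)
    spike <- list(ct_observed = 30, ct_reference = 30)
    q <- quantifySample(rec, spike, panel)
    expect_equal(unname(q$concentration["Wallemia sebi"]), 100,
                 tolerance = 1e-9)
    expect_true(q$detected[["Wallemia sebi"]])
    expect_identical(q$qc$verdict, "PASS")

    # all species non-detect -> row of zeros, flags FALSE, QC still PASS
    nd <- data.frame(species_name = "Wallemia sebi", replicate = 1L,
                     ct = NA_real_)
    q0 <- quantifySample(nd, spike, panel)
    expect_true(all(q0$concentration == 0))
    expect_false(any(q0$detected))
    expect_identical(q0$qc$verdict, "PASS")

    # replicates average on the linear CE scale, not on Ct
    two <- data.frame(species_name = "Mucor group", replicate = 1:2,
                      ct = c(40 + perfect * log10(100),
                             40 + perfect * log10(400)))
    qm <- quantifySample(two, spike, panel)
    expect_equal(unname(qm$concentration["Mucor group"]), 250 / 5,
                 tolerance = 1e-9)
})

test_that("spike-in deviation beyond tolerance fails QC but keeps values", {
    panel <- buildDefaultPanel()
    rec <- data.frame(species_name = "Wallemia sebi", replicate = 1L,
                      ct = 30)
    q <- quantifySample(rec, list(ct_observed = 35, ct_reference = 30),
                        panel)
    expect_identical(q$qc$verdict, "FAIL")
    expect_equal(q$qc$delta_cycles, 5)
    expect_false(q$qc$reliable)
    expect_gt(q$concentration[["Wallemia sebi"]], 0)
})

test_that("unknown species and duplicate replicates are named in errors", {
    panel <- buildDefaultPanel()
    spike <- list(ct_observed = 30, ct_reference = 30)
    expect_error(quantifySample(
        data.frame(species_name = "Not a mold", replicate = 1L, ct = 30),
        spike, panel), "Not a mold")
    expect_error(quantifySample(
        data.frame(species_name = "Wallemia sebi", replicate = c(1L, 1L),
                   ct = c(30, 31)), spike, panel), "duplicate")
})

test_that("scaling all replicate CEs scales the CE/mg row before flooring", {
    panel <- buildDefaultPanel()
    spike <- list(ct_observed = 30, ct_reference = 30)
    base_ct <- 40 + perfect * log10(c(50, 200))
    rec <- function(shift) data.frame(
        species_name = "Alternaria alternata", replicate = 1:2,
        ct = base_ct + perfect * log10(shift))
    q1 <- quantifySample(rec(1), spike, panel)$concentration
    q8 <- quantifySample(rec(8), spike, panel)$concentration
    expect_equal(unname(q8["Alternaria alternata"]),
                 8 * unname(q1["Alternaria alternata"]), tolerance = 1e-9)
})

test_that("flooring is idempotent, preserves flags, and is applied after division", {
    panel <- buildDefaultPanel()
    set.seed(3)
    conc <- uniform_matrix(0, 3)
    conc[] <- 10^runif(length(conc), -1, 3)
    conc[1:5, 1] <- 0
    det <- conc > 0
    x <- MoldExperiment(conc, data.frame(home_id = c("A", "B", "C"),
                                         year = 2018), panel,
                        detected = det)
    f1 <- floorConcentrations(x, 1)
    f2 <- floorConcentrations(f1, 1)
    expect_identical(concentrations(f1), concentrations(f2))
    expect_true(all(concentrations(f1) >= 1))
    expect_identical(isDetected(f1), isDetected(x))
    expect_identical(as.vector(isDetected(f1)), as.vector(det))
    # values already above the floor are untouched (e.g. 2318 stays 2318)
    conc2 <- uniform_matrix(2318, 1)
    xf <- floorConcentrations(
        MoldExperiment(conc2, data.frame(home_id = "A", year = 2018), panel))
    expect_true(all(concentrations(xf) == 2318))

    # flooring after per-mg division, not before: CE = 2 over 5 mg must give
    # the floored 1 CE/mg, not 2/5 and not floor-then-divide
    spike <- list(ct_observed = 30, ct_reference = 30)
    rec <- data.frame(species_name = "Wallemia sebi", replicate = 1L,
                      ct = 40 + perfect * log10(2))
    q <- quantifySample(rec, spike, panel)
    expect_equal(unname(q$concentration["Wallemia sebi"]), 0.4,
                 tolerance = 1e-9)  # un-floored at the quantify stage
    expect_equal(floorConcentrations(matrix(q$concentration, ncol = 1))[1],
                 1)                 # floored once, after division
})

test_that("quantifyCohort assembles the matrix and the QC report", {
    panel <- buildDefaultPanel()
    ct <- rbind(
        data.frame(sample_id = "H01_2018", species_name = "Wallemia sebi",
                   replicate = 1L, ct = 30),
        data.frame(sample_id = "H02_2018", species_name = "Mucor group",
                   replicate = 1L, ct = NA_real_))
    spike <- data.frame(sample_id = c("H01_2018", "H02_2018"),
                        ct_observed = c(30, 36), ct_reference = 30)
    q <- quantifyCohort(ct, spike, panel)
    expect_identical(dim(q$concentration), c(36L, 2L))
    expect_identical(q$qc$verdict, c("PASS", "FAIL"))
    expect_false(q$detected["Mucor group", "H02_2018"])
})
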