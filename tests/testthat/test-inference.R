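test_that("exact rank-sum p matches brute-force enumeration, with and without ties", {
    w <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), mode = "exact")
    expect_equal(w$p_raw, 0.1)  # most extreme of the 20 assignments, 2-sided
    expect_identical(w$method, "wilcoxon_exact")
    expect_equal(w$statistic, 6)

    # identical samples -> p = 1 by symmetry
    expect_equal(wilcoxonRankSum(c(2, 2, 5), c(2, 2, 5), "exact")$p_raw, 1)

    # closed-form spot set without ties: agree with wilcox.test exact
    set.seed(31)
    for (i in 1:20) {
        n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
        x <- sample(seq_len(50), n1); y <- sample(51:100, n2) - 50.5
        expect_equal(wilcoxonRankSum(x, y, "exact")$p_raw,
                     stats::wilcox.test(x, y, exact = TRUE)$p.value,
                     tolerance = 1e-12)
    }

    # tie-bearing random sweep against the enumeration oracle
    set.seed(17)
    for (i in 1:60) {
        n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
        x <- sample(1:4, n1, replace = TRUE)
        y <- sample(1:4, n2, replace = TRUE)
        expect_equal(wilcoxonRankSum(x, y, "exact")$p_raw,
                     oracle_wilcoxon_exact(x, y), tolerance = 1e-12,
                     label = sprintf("case %d", i))
    }
    expect_error(wilcoxonRankSum(numeric(0), 1), "non-empty")
})

test_that("normal mode approximates exact mode and auto switches at n1+n2 = 12", {
    set.seed(5)
    worst <- worst_tied <- 0
    for (i in 1:200) {
        x <- rnorm(5)
        y <- rnorm(5) + runif(1, 0, 1)
        pe <- wilcoxonRankSum(x, y, "exact")$p_raw
        pn <- wilcoxonRankSum(x, y, "normal")$p_raw
        worst <- max(worst, abs(pe - pn))
        # heavily tied small samples: the approximation is rougher but sane
        xt <- sample(1:6, 5, replace = TRUE)
        yt <- sample(1:6, 5, replace = TRUE) + sample(0:1, 1)
        worst_tied <- max(worst_tied,
                          abs(wilcoxonRankSum(xt, yt, "exact")$p_raw -
                              wilcoxonRankSum(xt, yt, "normal")$p_raw))
    }
    expect_lt(worst, 0.05)
    expect_lt(worst_tied, 0.25)
    expect_identical(wilcoxonRankSum(1:6, 2:7)$method, "wilcoxon_exact")
    expect_identical(wilcoxonRankSum(1:7, 2:7)$method, "wilcoxon_normal")
    # degenerate all-tied input under the normal path
    expect_equal(wilcoxonRankSum(rep(1, 7), rep(1, 7), "normal")$p_raw, 1)
})

test_that("Holm step-down adjustment follows the by-hand formula", {
    expect_equal(holmBonferroni(c(0.01, 0.04)), c(0.02, 0.04))
    expect_equal(holmBonferroni(0.3), 0.3)              # m = 1
    expect_equal(holmBonferroni(c(0.5, 0.5, 0.5)), rep(1, 3))
    # never below raw; monotone along the sorted order; NA passthrough
    set.seed(9)
    p <- runif(25)
    adj <- holmBonferroni(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    withna <- holmBonferroni(c(0.01, NA, 0.04))
    expect_true(is.na(withna[2]))
    expect_equal(withna[c(1, 3)], c(0.02, 0.04))  # NA not in the family
    expect_error(holmBonferroni(c(0.2, 1.2)), "\\[0,1\\]")
})

test_that("Student's t handles the standard and degenerate cases", {
    x <- c(1, 2, 3); y <- c(2, 3, 4)
    tt <- studentT(x, y, "pooled")
    expect_equal(tt$statistic, -1.2247, tolerance = 1e-4)
    expect_equal(tt$p_raw, 0.2878, tolerance = 1e-3)

    same <- studentT(c(1, 2, 4), c(1, 2, 4))
    expect_equal(same$statistic, 0)
    expect_equal(same$p_raw, 1)

    far <- studentT(c(1, 2, 3, 4), c(1, 2, 3, 4) + 100)
    expect_lt(far$p_raw, 1e-6)

    # zero variance in both samples
    expect_equal(studentT(c(5, 5), c(5, 5))$p_raw, 1)
    deg <- studentT(c(5, 5), c(7, 7))
    expect_equal(deg$p_raw, 0)
    expect_true(deg$degenerate)
    expect_error(studentT(1, c(1, 2)), "at least 2")
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
    set.seed(12)
    for (i in 1:5) {
        x <- rnorm(6 + i); y <- rnorm(5) + 0.8
        tk <- anovaTukey(c(x, y), rep(c("g1", "g2"), c(length(x), 5)))
        tt <- stats::t.test(x, y, var.equal = TRUE)
        expect_equal(tk$pairwise$p_adjusted, tt$p.value, tolerance = 1e-6)
        expect_equal(tk$pairwise$q, abs(tt$statistic[[1]]) * sqrt(2),
                     tolerance = 1e-9)
    }
})

test_that("Tukey pairwise p-values agree with stats::TukeyHSD", {
    set.seed(77)
    v <- rnorm(40, rep(c(0, 0.5, 1, 0.2), each = 10))
    g <- rep(c("a", "b", "c", "d"), each = 10)
    tk <- anovaTukey(v, g)
    ref <- stats::TukeyHSD(stats::aov(v ~ factor(g)))$`factor(g)`
    key <- paste(tk$pairwise$group_b, tk$pairwise$group_a, sep = "-")
    expect_equal(tk$pairwise$p_adjusted, unname(ref[key, "p adj"]),
                 tolerance = 1e-8)
})

test_that("identical groups share one letter; degenerate zero-MSE flagged", {
    v <- rep(c(3, 4, 5), times = 3)  # three identical groups
    g <- rep(c("x", "y", "z"), each = 3)
    tk0 <- anovaTukey(v, g)
    expect_true(all(tk0$pairwise$p_adjusted == 1))
    expect_identical(tk0$summary$letter, rep("a", 3))

    degen <- anovaTukey(rep(c(1, 2), each = 3), rep(c("x", "y"), each = 3))
    expect_true(degen$degenerate)
    expect_true(all(degen$pairwise$p_adjusted == 0))
    expect_error(anovaTukey(1:3, c("a", "a", "b")), "fewer than 2")
})

test_that("compact letters satisfy the sharing biconditional on random patterns", {
    set.seed(42)
    for (i in 1:40) {
        k <- sample(3:6, 1)
        p <- matrix(1, k, k, dimnames = list(letters[1:k], letters[1:k]))
        for (a in 1:(k - 1)) for (b in (a + 1):k) {
            p[a, b] <- p[b, a] <- sample(c(0.001, 0.2), 1)
        }
        lets <- compactLetters(p, alpha = 0.05)
        for (a in 1:(k - 1)) for (b in (a + 1):k) {
            share <- length(intersect(strsplit(lets[a], "")[[1]],
                                      strsplit(lets[b], "")[[1]])) > 0
            expect_identical(share, p[a, b] > 0.05,
                             label = sprintf("iter %d pair %d-%d", i, a, b))
        }
    }
})

test_that("letter recovery: a,b,a when outer years are truly equal, a,a,a under the null", {
    aba <- vapply(1:20, function(s) {
        od <- simulateOutdoorSeries(mean_log = c(4.68, 4.86, 4.68),
                                    sd_log = 0.05, n_per_year = 50, seed = s)
        paste(anovaTukey(od$log_count, od$year)$summary$letter,
              collapse = "")
    }, character(1))
    expect_gte(sum(aba == "aba"), 19)

    aaa <- vapply(1:20, function(s) {
        od <- simulateOutdoorSeries(mean_log = rep(4.7, 3), sd_log = 0.05,
                                    n_per_year = 50, seed = s)
        paste(anovaTukey(od$log_count, od$year)$summary$letter,
              collapse = "")
    }, character(1))
    expect_gte(sum(aaa == "aaa"), 18)
})

test_that("comparison battery flags the injected effect, reports NM, and is order-invariant", {
    panel <- buildDefaultPanel()
    set.seed(300)
    n <- 20
    conc <- uniform_matrix(1, 2 * n)
    conc[] <- 10^rnorm(length(conc), 2, 0.4)
    # one species shifted 8-fold in the second year; one constant at floor
    years <- rep(c(2018L, 2019L), each = n)
    conc["Alternaria alternata", years == 2019L] <-
        conc["Alternaria alternata", years == 2019L] * 8
    conc["Penicillium spinulosum", ] <- 1
    x <- floorConcentrations(make_experiment(conc, years = years))
    rep1 <- compareYears(x, alpha = 0.05)
    expect_identical(nrow(rep1), 36L)
    expect_identical(rep1["Penicillium spinulosum", "method"], "NM")
    expect_true(is.na(rep1["Penicillium spinulosum", "p_raw"]))
    expect_identical(S4Vectors::metadata(rep1)$holm_family_size, 35L)
    expect_true(rep1["Alternaria alternata", "significant"])
    gt <- S4Vectors::metadata(rep1)$group_tests
    expect_identical(gt$metric, c("sum_logs_g1", "sum_logs_g2", "ermi"))
    expect_true(all(is.na(rep1$p_adjusted) | rep1$p_adjusted >= rep1$p_raw))

    # permuting home order changes no statistic
    perm <- sample(ncol(x))
    rep2 <- compareYears(x[, perm], alpha = 0.05)
    expect_equal(rep1$p_raw, rep2[rownames(rep1), ]$p_raw, tolerance = 1e-12)

    # per-group Holm family option adjusts within groups only
    repg <- compareYears(x, family = "per_group")
    g2 <- repg$group == 2L & !is.na(repg$p_raw)
    expect_equal(repg$p_adjusted[g2],
                 holmBonferroni(repg$p_raw[g2]), tolerance = 1e-12)
    expect_error(compareYears(x[, c(1:5, n + 1)]), "2 homes")
})

test_that("paired battery uses signed-rank and paired t on matched homes", {
    sim <- simulateCohort(syntheticConfig(seed = 13))
    x <- floorConcentrations(sim$experiment)
    rp <- compareYears(x, paired = TRUE)
    expect_true(all(rp$method[!is.na(rp$p_raw)] == "wilcoxon_signed_rank"))
    expect_identical(S4Vectors::metadata(rp)$group_tests$method[1],
                     "t_paired")
})
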