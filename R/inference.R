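# Distribution of the doubled rank sum of a size-n1 subset drawn from the
# doubled midranks d (integers). Generating-function DP: cnt[k+1, s+1] =
# number of size-k subsets with doubled rank sum s. Doubling keeps midranks
# (halves under ties) integral.
.ranksum_counts <- function(d, n1) {
    total <- sum(d)
    cnt <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
    cnt[1L, 1L] <- 1
    seen <- 0L
    for (di in d) {
        seen <- seen + 1L
        for (k in seq.int(min(n1, seen), 1L)) {
            nz <- which(cnt[k, ] > 0)
            if (length(nz))
                cnt[k + 1L, nz + di] <- cnt[k + 1L, nz + di] + cnt[k, nz]
        }
    }
    cnt[n1 + 1L, ]
}

#' Two-sample Wilcoxon rank-sum test with tie-aware exact mode
#'
#' Two-sided rank-sum test between independent samples. The exact mode
#' enumerates the permutation null distribution of the rank sum over all
#' `choose(n1+n2, n1)` group assignments of the observed (possibly tied)
#' values, using mid-ranks, so it remains exact under ties; the p-value is
#' `min(1, 2*min(P(W <= w), P(W >= w)))`. The normal mode uses the
#' tie-corrected normal approximation with continuity correction. `auto`
#' picks exact when `n1 + n2 <= 12`.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return list: `statistic` (rank sum of `x`, mid-ranks), `p_raw`, `method`
#'   (`"wilcoxon_exact"` or `"wilcoxon_normal"`), `n1`, `n2`.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p_raw # 0.1
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal")) {
    mode <- match.arg(mode)
    if (!length(x) || !length(y)) stop("samples must be non-empty")
    n1 <- length(x); n2 <- length(y)
    if (mode == "auto") mode <- if (n1 + n2 <= 12L) "exact" else "normal"
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n1)])
    if (mode == "exact") {
        d <- as.integer(round(2 * r))
        counts <- .ranksum_counts(d, n1)
        tot <- sum(counts)
        wd <- as.integer(round(2 * w))
        p_le <- sum(counts[seq_len(wd + 1L)]) / tot
        p_ge <- sum(counts[seq.int(wd + 1L, length(counts))]) / tot
        p <- min(1, 2 * min(p_le, p_ge))
        method <- "wilcoxon_exact"
    } else {
        if (stats::var(c(x, y)) == 0) {
            p <- 1
        } else {
            p <- stats::wilcox.test(x, y, exact = FALSE,
                                    correct = TRUE)$p.value
        }
        method <- "wilcoxon_normal"
    }
    list(statistic = w, p_raw = p, method = method, n1 = n1, n2 = n2)
}

#' Holm step-down multiple-testing adjustment
#'
#' Family-wise error control by the Holm step-down rule: the k-th smallest
#' p-value is multiplied by `m - k + 1`, capped at 1, with monotonicity
#' enforced along the sorted order; results are returned in input order and
#' are never below the raw p-values. `NA` entries (untestable hypotheses) are
#' passed through and do not count toward the family size.
#'
#' @param p numeric vector of p-values in \[0,1\] (`NA` allowed).
#' @return adjusted p-values, same order and length.
#' @examples
#' holmBonferroni(c(0.01, 0.04)) # 0.02, 0.04
#' @export
holmBonferroni <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0,1]")
    stats::p.adjust(p, method = "holm")
}

#' Two-sample Student's t-test
#'
#' Two-sided t-test, pooled-variance (`df = n1 + n2 - 2`) by default or
#' Welch. Degenerate inputs are resolved by convention: zero variance in both
#' samples gives p = 1 for equal means and p = 0 (flagged `degenerate`) for
#' unequal means.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @param variant `"pooled"` or `"welch"`.
#' @return list: `statistic` (t), `p_raw`, `method` (`"t_pooled"` or
#'   `"t_welch"`), `n1`, `n2`, `degenerate`.
#' @export
studentT <- function(x, y, variant = c("pooled", "welch")) {
    variant <- match.arg(variant)
    if (length(x) < 2L || length(y) < 2L)
        stop("each sample needs at least 2 observations")
    method <- if (variant == "pooled") "t_pooled" else "t_welch"
    if (stats::var(x) == 0 && stats::var(y) == 0) {
        equal <- isTRUE(all.equal(mean(x), mean(y)))
        return(list(statistic = if (equal) 0 else sign(mean(x) - mean(y)) * Inf,
                    p_raw = if (equal) 1 else 0, method = method,
                    n1 = length(x), n2 = length(y), degenerate = !equal))
    }
    ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
    list(statistic = unname(ht$statistic), p_raw = ht$p.value,
         method = method, n1 = length(x), n2 = length(y), degenerate = FALSE)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: starting from one letter covering all
#' groups, every significant pair splits each letter column containing both
#' members, and redundant (subset) columns are absorbed. The result
#' satisfies the display contract exactly: two groups share a letter if and
#' only if their pairwise comparison is non-significant at `alpha`.
#'
#' @param p symmetric matrix of pairwise adjusted p-values with group
#'   dimnames (diagonal ignored).
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group.
#' @export
compactLetters <- function(p, alpha = 0.05) {
    g <- rownames(p)
    k <- length(g)
    cols <- list(rep(TRUE, k))
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
        if (is.na(p[i, j]) || p[i, j] > alpha) next
        nxt <- list()
        for (col in cols) {
            if (col[i] && col[j]) {
                a <- col; a[i] <- FALSE
                b <- col; b[j] <- FALSE
                nxt <- c(nxt, list(a, b))
            } else nxt <- c(nxt, list(col))
        }
        # absorb: drop any column whose members are a subset of another's
        keep <- rep(TRUE, length(nxt))
        for (u in seq_along(nxt)) for (v in seq_along(nxt)) {
            if (u == v || !keep[u]) next
            if (all(nxt[[u]] <= nxt[[v]]) && keep[v] &&
                (any(nxt[[u]] != nxt[[v]]) || u > v))
                keep[u] <- FALSE
        }
        cols <- nxt[keep]
    }
    ord <- order(vapply(cols, function(col) which(col)[1], 1L))
    cols <- cols[ord]
    lab <- c(letters, as.vector(outer(letters, letters, paste0)))
    out <- vapply(seq_len(k), function(i)
        paste(lab[which(vapply(cols, `[`, TRUE, i))], collapse = ""),
        character(1))
    names(out) <- g
    out
}

#' One-way ANOVA with Tukey HSD pairwise comparisons and letters
#'
#' Fits a one-way ANOVA, then compares every pair of group means with the
#' Tukey-Kramer studentized-range test on the ANOVA mean-square error:
#' `q = |mean_a - mean_b| / sqrt(MSE/2 * (1/n_a + 1/n_b))`, with the adjusted
#' p-value from the studentized-range distribution with `k` groups and
#' `N - k` error degrees of freedom. A compact letter display summarizes the
#' pattern (groups sharing a letter do not differ at `alpha`).
#'
#' @param values numeric response.
#' @param groups group labels, same length (each group needs n >= 2).
#' @param alpha significance level for the letter display.
#' @return list of class `"TukeyResult"`: `summary` (data.frame `group`,
#'   `n`, `mean`, `sd`, `letter`, `small_n` flag for n < 3), `pairwise`
#'   (data.frame `group_a`, `group_b`, `diff`, `q`, `p_adjusted`), `mse`,
#'   `df`, `alpha`, `degenerate`.
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
    groups <- factor(groups)
    n <- table(groups)
    if (nlevels(groups) < 2L) stop("need at least 2 groups")
    if (any(n < 2L))
        stop("group(s) with fewer than 2 observations: ",
             paste(names(n)[n < 2L], collapse = ", "))
    fit <- stats::aov(values ~ groups)
    df <- fit$df.residual
    mse <- sum(stats::residuals(fit)^2) / df
    k <- nlevels(groups)
    means <- tapply(values, groups, mean)
    sds <- tapply(values, groups, stats::sd)
    # a residual mean square that is zero up to rounding noise means the
    # groups are internally constant; studentized ranges are then undefined
    degenerate <- mse <= 1e-12 * stats::var(values)
    pairs <- utils::combn(levels(groups), 2)
    pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     diff = NA_real_, q = NA_real_, p_adjusted = NA_real_)
    for (r in seq_len(ncol(pairs))) {
        a <- pairs[1, r]; b <- pairs[2, r]
        diff <- means[[b]] - means[[a]]
        if (degenerate) {
            pw$diff[r] <- diff
            pw$q[r] <- if (diff == 0) 0 else Inf
            pw$p_adjusted[r] <- if (diff == 0) 1 else 0
        } else {
            se <- sqrt(mse / 2 * (1 / n[[a]] + 1 / n[[b]]))
            q <- abs(diff) / se
            pw$diff[r] <- diff
            pw$q[r] <- q
            pw$p_adjusted[r] <- stats::ptukey(q, nmeans = k, df = df,
                                              lower.tail = FALSE)
        }
    }
    pm <- matrix(NA_real_, k, k, dimnames = list(levels(groups),
                                                 levels(groups)))
    for (r in seq_len(nrow(pw))) {
        pm[pw$group_a[r], pw$group_b[r]] <- pw$p_adjusted[r]
        pm[pw$group_b[r], pw$group_a[r]] <- pw$p_adjusted[r]
    }
    lets <- compactLetters(pm, alpha)
    out <- list(summary = data.frame(group = levels(groups),
                                     n = as.integer(n),
                                     mean = as.numeric(means),
                                     sd = as.numeric(sds),
                                     letter = unname(lets),
                                     small_n = as.integer(n) < 3L),
                pairwise = pw, mse = mse, df = df, alpha = alpha,
                degenerate = degenerate)
    class(out) <- "TukeyResult"
    out
}

#' @export
print.TukeyResult <- function(x, ...) {
    cat(sprintf("One-way ANOVA + Tukey HSD (alpha = %g, MSE = %.4g, df = %d)\n",
                x$alpha, x$mse, x$df))
    print(x$summary, row.names = FALSE)
    if (any(x$summary$small_n))
        cat("note: group(s) with n < 3 -",
            paste(x$summary$group[x$summary$small_n], collapse = ", "), "\n")
    invisible(x)
}

#' Between-year comparison battery over the full panel
#'
#' The study's comparison battery: for each of the 36 panel species, a
#' two-sided Wilcoxon rank-sum test of the per-home CE/mg values between the
#' two years, Holm-adjusted across the family of testable species; species
#' constant at the same value in both years are untestable and reported as
#' `"NM"` (no meaning), excluded from the adjustment family. The per-home
#' group log-sums and the moldiness index are compared with Student's
#' t-tests (reported unadjusted).
#'
#' @param x a floored [MoldExperiment-class] containing samples from both
#'   years (at least 2 homes per year).
#' @param years length-2 vector of years to compare; defaults to the two
#'   years present.
#' @param alpha significance level for flags.
#' @param family `"combined"` (one Holm family over all testable species) or
#'   `"per_group"` (separate families for group 1 and group 2).
#' @param paired use paired tests on homes present in both years (signed-rank
#'   and paired t).
#' @param mode Wilcoxon mode, see [wilcoxonRankSum()].
#' @param floor detection floor the input must satisfy.
#' @return a [S4Vectors::DataFrame] with one row per species: `species`,
#'   `group`, `avg_<year1>`, `avg_<year2>`, `statistic`, `p_raw`,
#'   `p_adjusted`, `significant`, `method`. `metadata(...)` carries
#'   `group_tests` (t-tests on `sum_logs_g1`, `sum_logs_g2`, `ermi`),
#'   `alpha`, `family`, `years`, and `holm_family_size`.
#' @export
compareYears <- function(x, years = NULL, alpha = 0.05,
                         family = c("combined", "per_group"),
                         paired = FALSE, mode = "auto", floor = 1) {
    family <- match.arg(family)
    meta <- colData(x)
    if (is.null(years)) years <- sort(unique(meta$year))
    if (length(years) != 2L)
        stop("exactly two years are compared; got ",
             paste(years, collapse = ", "))
    i1 <- which(meta$year == years[1])
    i2 <- which(meta$year == years[2])
    if (length(i1) < 2L || length(i2) < 2L)
        stop("need at least 2 homes in each year")
    conc <- concentrations(x)
    .assert_floored(conc, floor)
    if (paired) {
        common <- intersect(meta$home_id[i1], meta$home_id[i2])
        if (length(common) < 2L) stop("fewer than 2 homes sampled both years")
        i1 <- i1[match(common, meta$home_id[i1])]
        i2 <- i2[match(common, meta$home_id[i2])]
    }
    sp <- rownames(conc)
    grp <- rowData(x)$group
    res <- S4Vectors::DataFrame(
        species = sp, group = grp,
        avg1 = rowMeans(conc[, i1, drop = FALSE]),
        avg2 = rowMeans(conc[, i2, drop = FALSE]),
        statistic = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
        significant = FALSE, method = NA_character_, row.names = sp)
    for (s in sp) {
        vx <- conc[s, i1]; vy <- conc[s, i2]
        if (length(unique(c(vx, vy))) == 1L) {
            res[s, "method"] <- "NM"
            next
        }
        if (paired) {
            ht <- stats::wilcox.test(vx, vy, paired = TRUE, exact = FALSE,
                                     correct = TRUE)
            res[s, "statistic"] <- unname(ht$statistic)
            res[s, "p_raw"] <- ht$p.value
            res[s, "method"] <- "wilcoxon_signed_rank"
        } else {
            w <- wilcoxonRankSum(vx, vy, mode = mode)
            res[s, "statistic"] <- w$statistic
            res[s, "p_raw"] <- w$p_raw
            res[s, "method"] <- w$method
        }
    }
    if (family == "combined") {
        res$p_adjusted <- holmBonferroni(res$p_raw)
    } else {
        for (g in c(1L, 2L)) {
            idx <- which(res$group == g)
            res$p_adjusted[idx] <- holmBonferroni(res$p_raw[idx])
        }
    }
    res$significant <- !is.na(res$p_adjusted) & res$p_adjusted <= alpha

    e1 <- ermiScores(x[, i1], floor)
    e2 <- ermiScores(x[, i2], floor)
    gt <- lapply(c("sum_logs_g1", "sum_logs_g2", "ermi"), function(metric) {
        a <- e1[[metric]]; b <- e2[[metric]]
        tt <- if (paired) {
            ht <- stats::t.test(a, b, paired = TRUE)
            list(statistic = unname(ht$statistic), p_raw = ht$p.value,
                 method = "t_paired")
        } else studentT(a, b, variant = "pooled")
        data.frame(metric = metric, mean1 = mean(a), mean2 = mean(b),
                   statistic = tt$statistic, p_raw = tt$p_raw,
                   significant = tt$p_raw <= alpha, method = tt$method)
    })
    gt <- do.call(rbind, gt)
    colnames(res)[colnames(res) == "avg1"] <- paste0("avg_", years[1])
    colnames(res)[colnames(res) == "avg2"] <- paste0("avg_", years[2])
    colnames(gt)[colnames(gt) == "mean1"] <- paste0("mean_", years[1])
    colnames(gt)[colnames(gt) == "mean2"] <- paste0("mean_", years[2])
    metadata(res) <- list(group_tests = gt, alpha = alpha, family = family,
                          years = years,
                          holm_family_size = sum(!is.na(res$p_raw)),
                          paired = paired)
    res
}

#' Write comparison and Tukey reports to CSV
#'
#' `writeComparisonCSV()` mirrors the published per-species layout
#' (`species,group,avg_<y1>,avg_<y2>,p_raw,p_adjusted,significant,method`,
#' followed by the group-level t-test rows); `writeTukeyCSV()` writes
#' `group,n,mean,sd,letter,small_n`.
#'
#' @param report output of [compareYears()].
#' @param tukey a `TukeyResult` from [anovaTukey()].
#' @param path CSV file path.
#' @export
writeComparisonCSV <- function(report, path) {
    df <- as.data.frame(report)
    gt <- metadata(report)$group_tests
    yrs <- metadata(report)$years
    extra <- data.frame(
        species = c("Sum logs group 1", "Sum logs group 2", "ERMI"),
        group = NA_integer_,
        a1 = gt[[paste0("mean_", yrs[1])]],
        a2 = gt[[paste0("mean_", yrs[2])]],
        statistic = gt$statistic, p_raw = gt$p_raw,
        p_adjusted = NA_real_, significant = gt$significant,
        method = gt$method)
    colnames(extra)[3:4] <- paste0("avg_", yrs)
    utils::write.csv(rbind(df, extra), path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' @rdname writeComparisonCSV
#' @export
writeTukeyCSV <- function(tukey, path) {
    utils::write.csv(tukey$summary, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
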