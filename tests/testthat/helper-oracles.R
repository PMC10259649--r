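# Independent oracles and fixture builders, kept deliberately naive so they
# share no code path with the package implementation.

# Exact two-sided rank-sum p by brute-force enumeration of every size-n1
# subset of the combined mid-ranks (feasible for n1+n2 <= ~12).
oracle_wilcoxon_exact <- function(x, y) {
    r <- rank(c(x, y))
    n1 <- length(x)
    w_obs <- sum(r[seq_len(n1)])
    sets <- utils::combn(length(r), n1)
    ws <- apply(sets, 2, function(idx) sum(r[idx]))
    p_le <- mean(ws <= w_obs + 1e-9)
    p_ge <- mean(ws >= w_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
}

# Spreadsheet-style recomputation of the per-sample scores from a raw
# species-by-sample matrix (already floored), given group membership.
oracle_scores <- function(conc, groups) {
    t(apply(conc, 2, function(v) {
        lg <- log10(v)
        s1 <- sum(lg[groups == 1])
        s2 <- sum(lg[groups == 2])
        p <- v / sum(v)
        h <- -sum(p * log(p))
        c(sum_logs_g1 = s1, sum_logs_g2 = s2, ermi = s1 - s2,
          shannon_h = h, equitability = h / log(length(v)),
          richness = sum(v > 1))
    }))
}

# Build a small MoldExperiment from a species-by-sample matrix.
make_experiment <- function(conc, years = NULL, panel = buildDefaultPanel(),
                            region = NULL) {
    n <- ncol(conc)
    if (is.null(years)) years <- rep(2018L, n)
    meta <- data.frame(home_id = sprintf("H%02d", seq_len(n)), year = years)
    if (!is.null(region)) meta$region <- region
    MoldExperiment(conc, meta, panel)
}

# Uniform matrix at a given value across the whole panel.
uniform_matrix <- function(value, n_samples = 1,
                           panel = buildDefaultPanel()) {
    matrix(value, nrow = length(panelSpecies(panel)), ncol = n_samples,
           dimnames = list(panelSpecies(panel), NULL))
}
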