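#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, capped at 1; ties keep their
#' input order. Thin, validating wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0,1]`.
#' @return vector of BH-adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0,1] with no NA.")
  }
  p.adjust(p, method = "BH")
}

# Welch (or pooled Student) two-sample t test on a numeric vector split by a
# 2-level grouping; degenerate zero-variance cases handled explicitly.
welch_row <- function(x, g1_idx, g2_idx, pooled = FALSE) {
  x1 <- x[g1_idx]; x2 <- x[g2_idx]
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) return(c(mean(x1), mean(x2), NA, NA, NA))
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- var(x1); v2 <- var(x2)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- if (se2 > 0) se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else 1
  }
  if (se2 <= 0) {
    # both groups constant: identical means are a perfect null, differing
    # means an unbounded statistic
    if (m1 == m2) return(c(m1, m2, 0, df, 1))
    return(c(m1, m2, sign(m1 - m2) * Inf, df, 0))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(t), df)
  c(m1, m2, t, df, p)
}

check_two_groups <- function(groups, n, min_per_group = 2L) {
  groups <- as.factor(groups)
  if (length(groups) != n) abort("`groups` length must match the number of samples.")
  lev <- levels(droplevels(groups))
  if (length(lev) != 2L) abort("`groups` must have exactly two levels.")
  if (any(table(groups) < min_per_group)) {
    abort(sprintf("each group needs >= %d samples.", min_per_group))
  }
  factor(groups, levels = lev)
}

#' Differential latent variables between two sample groups
#'
#' Per latent variable, a two-sided Welch two-sample t test on the sample
#' loadings (pooled Student variant via `pooled = TRUE`), with
#' Benjamini-Hochberg adjustment across all latent variables. Rows are
#' ordered by q, then by decreasing |t|.
#'
#' @param loadings a `meth_loadings` object or a k x samples matrix.
#' @param groups two-level factor/character vector, one entry per sample
#'   (column order of the loading matrix).
#' @param pooled use the pooled-variance Student t test; default Welch.
#' @return tibble: `lv`, `mean_group1`, `mean_group2`, `t`, `df`, `p_value`,
#'   `q_value`. Group level names are in the `"group_levels"` attribute
#'   (group1 = first level).
#' @export
differential_lv <- function(loadings, groups, pooled = FALSE) {
  B <- if (inherits(loadings, "meth_loadings")) loadings$B else
    assert_matrix_like(loadings, "loadings")
  groups <- check_two_groups(groups, ncol(B))
  g1 <- which(groups == levels(groups)[1]); g2 <- which(groups == levels(groups)[2])
  res <- t(apply(B, 1, welch_row, g1_idx = g1, g2_idx = g2, pooled = pooled))
  out <- tibble(lv = rownames(B) %||% paste0("LV", seq_len(nrow(B))),
                mean_group1 = res[, 1], mean_group2 = res[, 2],
                t = res[, 3], df = res[, 4], p_value = res[, 5])
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$q_value, -abs(out$t)), ]
  attr(out, "group_levels") <- levels(groups)
  out
}

#' Differentially methylated positions between two groups
#'
#' Per-probe two-sided Welch t test on beta values over a chosen probe
#' subset, BH adjustment across all tested probes, and a methylation
#' direction relative to a named reference group: a probe is `hypo` when the
#' comparison group's mean beta is below the reference group's, `hyper` when
#' above, `NA` at exactly equal means. Probes with fewer than two non-missing
#' values in either group are excluded and counted in the `"n_excluded"`
#' attribute.
#'
#' @param beta probes x samples beta matrix.
#' @param probe_subset character vector of probe ids to test (must exist in
#'   `beta`).
#' @param groups two-level grouping, one entry per sample.
#' @param reference_group the level direction calls are relative to.
#' @param gene_map optional tibble (`probe_id`, `gene`) annotating each
#'   probe's nearest gene.
#' @param pooled use the pooled Student t test; default Welch.
#' @return tibble sorted by q: `probe_id`, `mean_ref`, `mean_cmp`,
#'   `mean_diff` (comparison - reference), `t`, `p_value`, `q_value`,
#'   `direction`, `gene`.
#' @export
dmp_test <- function(beta, probe_subset, groups, reference_group,
                     gene_map = NULL, pooled = FALSE) {
  beta <- validate_beta_matrix(beta)
  if (length(probe_subset) == 0L) abort("`probe_subset` is empty.")
  missing <- setdiff(probe_subset, rownames(beta))
  if (length(missing)) {
    abort(paste0(length(missing), " probe(s) of `probe_subset` absent from `beta`."))
  }
  groups <- check_two_groups(groups, ncol(beta))
  if (!reference_group %in% levels(groups)) {
    abort("`reference_group` is not a level of `groups`.")
  }
  ref <- which(groups == reference_group)
  cmp <- which(groups != reference_group)
  sub <- beta[probe_subset, , drop = FALSE]
  res <- t(apply(sub, 1, welch_row, g1_idx = cmp, g2_idx = ref, pooled = pooled))
  ok <- !is.na(res[, 5])
  n_excluded <- sum(!ok)
  res <- res[ok, , drop = FALSE]
  out <- tibble(
    probe_id = probe_subset[ok],
    mean_ref = res[, 2], mean_cmp = res[, 1],
    mean_diff = res[, 1] - res[, 2],
    t = res[, 3], p_value = res[, 5]
  )
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- dplyr::case_when(out$mean_diff < 0 ~ "hypo",
                                    out$mean_diff > 0 ~ "hyper",
                                    TRUE ~ NA_character_)
  if (!is.null(gene_map)) {
    out <- dplyr::left_join(out, dplyr::distinct(gene_map[, c("probe_id", "gene")]),
                            by = "probe_id")
  } else {
    out$gene <- NA_character_
  }
  out <- out[order(out$q_value, -abs(out$t)), ]
  attr(out, "n_excluded") <- n_excluded
  attr(out, "reference_group") <- reference_group
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time, the observed number of events in group 1 is
#' compared with its hypergeometric expectation given the risk sets; the
#' statistic `(sum O - sum E)^2 / sum V` is referred to a chi-square with one
#' degree of freedom.
#'
#' @param times non-negative follow-up times.
#' @param events event indicator (1 = event, 0 = censored).
#' @param groups two-level grouping.
#' @return one-row tibble: `statistic`, `df`, `p_value`, `observed1`,
#'   `expected1`.
#' @export
logrank_test <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  events <- as.integer(events)
  if (!all(events %in% c(0L, 1L))) abort("`events` must be 0/1.")
  if (sum(events) < 1L) abort("log-rank test needs at least one event.")
  groups <- check_two_groups(groups, length(times), min_per_group = 1L)
  g1 <- groups == levels(groups)[1]

  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events == 1L]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(events == 1L & times == t)
    d1 <- sum(events == 1L & times == t & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  tibble(statistic = stat, df = 1L,
         p_value = if (V > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1,
         observed1 = O, expected1 = E)
}
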