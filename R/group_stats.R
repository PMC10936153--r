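# groups may arrive as a named list of numeric vectors or as a data frame
# with `value` and `group` columns (the shape written by the coloc CSV)
as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups)))
      stopf("data-frame input needs `value` and `group` columns")
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
    stopf("groups must be a named list of numeric vectors")
  lens <- lengths(groups)
  if (any(lens == 0L)) stopf("empty group: %s",
                             paste(names(groups)[lens == 0L], collapse = ", "))
  lapply(groups, as.numeric)
}

#' Per-group mean and standard error
#'
#' Sample mean and SEM (sd with the n-1 denominator, divided by sqrt(n))
#' per group — the summary displayed as mean +/- SEM bars for each strain.
#' Singleton groups get `sem = 0` with a qc flag, so downstream plotting
#' never sees an undefined error bar.
#'
#' @param groups named list of numeric vectors, or a data frame with
#'   `value` and `group` columns.
#' @return A data frame: `group`, `n`, `mean`, `sem`, `qc_small_n`.
#' @export
summarize_groups <- function(groups) {
  gl <- as_group_list(groups)
  out <- data.frame(
    group = names(gl),
    n = lengths(gl),
    mean = vapply(gl, mean, numeric(1)),
    sem = vapply(gl, function(v)
      if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v)), numeric(1)),
    qc_small_n = lengths(gl) < 2L,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) comparing
#' group means of per-image colocalization coefficients across strains.
#' A completely constant data set returns `F = 0, p = 1`; zero
#' within-group variance with distinct means returns `F = Inf, p = 0`.
#'
#' @inheritParams summarize_groups
#' @return A list: `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  gl <- as_group_list(groups)
  if (length(gl) < 2L) stopf("ANOVA needs >= 2 groups")
  if (any(lengths(gl) < 2L)) stopf("each group needs n >= 2")
  df_b <- length(gl) - 1L
  df_w <- sum(lengths(gl)) - length(gl)
  values <- unlist(gl, use.names = FALSE)
  if (stats::var(values) == 0)
    return(list(F = 0, df_between = df_b, df_within = df_w, p = 1))
  ssw <- sum(vapply(gl, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0)
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0))
  dat <- data.frame(value = values,
                    group = factor(rep(names(gl), lengths(gl))))
  fit <- stats::oneway.test(value ~ group, data = dat, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]),
       p = unname(fit$p.value))
}

significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = TRUE) |> as.character()
}

#' Dunnett many-to-one comparisons by Monte-Carlo
#'
#' Compares every treatment group against a control with Dunnett-adjusted
#' two-sided p-values. The observed statistics are pooled-variance t
#' statistics (pooled across all groups); the family-wise null reference
#' distribution of max |t| — whose contrasts are correlated because they
#' share the control — is simulated under H0 from the normal model: group
#' means as `N(0, 1/n_g)`, pooled variance as `chi^2_df / df`, with all
#' draws flowing from the given seed. The adjusted p-value of a comparison
#' is the exceedance probability of its |t| under that max-|t| null,
#' floored at the unadjusted p-value (multiplicity can only increase p).
#'
#' @inheritParams summarize_groups
#' @param control name of the control group (must be present).
#' @param n_draws Monte-Carlo draws for the null distribution (>= 1e4).
#' @param seed integer seed; results are reproducible given the seed.
#' @return A data frame with one row per treatment: `comparison`,
#'   `estimate` (mean difference vs control), `t`, `df`, `p_unadj`,
#'   `p_adj`, `stars`.
#' @export
dunnett_mc <- function(groups, control, n_draws = 1e5, seed = 1L) {
  gl <- as_group_list(groups)
  if (!control %in% names(gl))
    stopf("control group '%s' not among: %s", control,
          paste(names(gl), collapse = ", "))
  if (length(gl) < 2L) stopf("need at least one treatment group")
  if (any(lengths(gl) < 2L)) stopf("each group needs n >= 2")
  if (n_draws < 1e4) stopf("n_draws must be >= 1e4 for a stable tail")
  trt <- setdiff(names(gl), control)
  n <- lengths(gl)
  k <- length(gl)
  df <- sum(n) - k
  s2 <- sum(vapply(gl, function(v) sum((v - mean(v))^2), numeric(1))) / df
  m0 <- mean(gl[[control]])
  n0 <- n[[control]]
  est <- vapply(trt, function(g) mean(gl[[g]]) - m0, numeric(1))
  se <- sqrt(s2 * (1 / n[trt] + 1 / n0))
  tobs <- est / se
  p_unadj <- 2 * stats::pt(-abs(tobs), df)

  maxT <- withr::with_seed(seed, {
    z0 <- stats::rnorm(n_draws, 0, 1 / sqrt(n0))
    s2_null <- stats::rchisq(n_draws, df) / df
    mx <- rep(0, n_draws)
    for (g in trt) {
      zg <- stats::rnorm(n_draws, 0, 1 / sqrt(n[[g]]))
      tg <- abs(zg - z0) / sqrt(s2_null * (1 / n[[g]] + 1 / n0))
      mx <- pmax(mx, tg)
    }
    mx
  })
  p_adj <- vapply(tobs, function(t) mean(maxT >= abs(t)), numeric(1))
  p_adj <- pmax(p_adj, p_unadj)
  data.frame(
    comparison = paste(trt, "-", control),
    estimate = unname(est), t = unname(tobs), df = df,
    p_unadj = unname(p_unadj), p_adj = unname(p_adj),
    stars = significance_stars(unname(p_adj)),
    stringsAsFactors = FALSE
  )
}

#' Aggregate a colocalization CSV into strain-level statistics
#'
#' Reads per-image results (see [write_coloc_csv()]) joined with a group
#' label per image, drops qc-failed rows, and reports per-group mean/SEM
#' plus the one-way ANOVA and Dunnett comparisons against the control.
#'
#' @param df data frame with `value` and `group` columns (e.g. pcc values
#'   keyed by strain).
#' @param control control group name.
#' @param n_draws,seed passed to [dunnett_mc()].
#' @return A list: `summary` (per-group data frame with `p_adj` and
#'   `stars` merged in; control row has `NA`), `anova`, `dunnett`.
#' @export
aggregate_groups <- function(df, control, n_draws = 1e5, seed = 1L) {
  summ <- summarize_groups(df)
  aov_res <- one_way_anova(df)
  dun <- dunnett_mc(df, control, n_draws, seed)
  idx <- match(paste(summ$group, "-", control), dun$comparison)
  summ$p_adj <- dun$p_adj[idx]
  summ$stars <- dun$stars[idx]
  list(summary = summ, anova = aov_res, dunnett = dun)
}
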