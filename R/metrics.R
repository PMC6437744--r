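# Analysis of calibration-curve cohorts: per-pad variability (CV),
# correlation structure (session curves vs individual and overall means),
# candidate baselines and the L1 effort distances they imply, plus the
# paired t-test and Greenhouse-Geisser-corrected repeated-measures ANOVA
# used to compare them. Sample (n-1) standard deviations are used
# throughout.

#' Coefficient of variation
#'
#' Relative standard deviation in percent: 100 * sd / |mean|, with the
#' sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 50
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(values) / abs(m)
}

#' Per-subject, per-pad CV table
#'
#' For every subject with at least two sessions, the CV of the selected
#' amplitude across sessions is computed pad by pad; each subject's row
#' is summarized as mean +/- sample SD over pads. Subjects with a single
#' session are dropped with a warning.
#'
#' @param dataset a [calibration_dataset()].
#' @return An object of class `cv_table`: list with `cv` (subjects x pads
#'   matrix, percent), and `summary` (data.frame with `subject_id`,
#'   `mean`, `sd`).
#' @export
cv_table <- function(dataset) {
  m <- curve_matrix(dataset)
  subj <- attr(m, "subject_id")
  keep <- names(which(table(subj) >= 2))
  dropped <- setdiff(unique(subj), keep)
  if (length(dropped)) {
    warning(sprintf("subject(s) with a single session excluded from CV table: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  usubj <- unique(subj)[unique(subj) %in% keep]
  cv <- t(vapply(usubj, function(s) {
    apply(m[subj == s, , drop = FALSE], 2, coefficient_of_variation)
  }, numeric(ncol(m))))
  rownames(cv) <- usubj
  structure(list(
    cv = cv,
    summary = cv_row_summary(cv)
  ), class = "cv_table")
}

#' Row summaries of a CV matrix
#'
#' Mean +/- sample SD of each subject's per-pad CVs. Exposed separately
#' so a transcribed CV matrix can be summarized without the underlying
#' amplitudes.
#'
#' @param cv numeric matrix, subjects x pads, in percent.
#' @return data.frame with `subject_id`, `mean`, `sd`.
#' @export
cv_row_summary <- function(cv) {
  data.frame(subject_id = rownames(cv) %||% as.character(seq_len(nrow(cv))),
             mean = apply(cv, 1, mean),
             sd = apply(cv, 1, stats::sd),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overall mean curve
#'
#' Per-pad arithmetic mean over every curve in the dataset. The result is
#' an analysis curve (off-grid); snap it with [to_grid()] before using it
#' as a stimulation baseline.
#'
#' @param dataset a non-empty [calibration_dataset()].
#' @return An off-grid [amplitude_curve()].
#' @export
mean_curve <- function(dataset) {
  m <- curve_matrix(dataset)
  if (nrow(m) == 0) stop("empty dataset", call. = FALSE)
  amplitude_curve(colMeans(m), grid = FALSE)
}

#' Per-pad percentile curve
#'
#' Per-pad percentile across curves under the linear-interpolation
#' convention (rank (n-1)q/100 + 1 between order statistics; R's default
#' quantile type 7). The 25th percentile is the streamlined procedure's
#' default a-priori baseline: it sits within or below each subject's
#' observed range while staying strongly correlated with the mean curve.
#'
#' @param dataset a non-empty [calibration_dataset()].
#' @param q percentile in [0, 100].
#' @param type passed to [stats::quantile()] (default 7).
#' @return An off-grid [amplitude_curve()].
#' @export
percentile_curve <- function(dataset, q = 25, type = 7) {
  if (length(q) != 1 || q < 0 || q > 100) stop("q must be in [0, 100]", call. = FALSE)
  m <- curve_matrix(dataset)
  if (nrow(m) == 0) stop("empty dataset", call. = FALSE)
  amplitude_curve(apply(m, 2, stats::quantile, probs = q / 100,
                        type = type, names = FALSE),
                  grid = FALSE)
}

#' Total (L1) distance between two curves
#'
#' Sum over pads of absolute amplitude differences, in mA. With one click
#' moving a pad by 0.1 mA, distance / 0.1 is the number of user actions
#' needed to move one curve onto the other, so this is the effort proxy
#' used to compare candidate baselines.
#'
#' @param baseline,curve equal-length numeric vectors or
#'   [amplitude_curve()]s.
#' @return Non-negative distance in mA.
#' @export
total_distance <- function(baseline, curve) {
  a <- as.numeric(baseline); b <- as.numeric(curve)
  if (length(a) != length(b)) {
    stop(sprintf("curve length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
  sum(abs(a - b))
}

#' Optimal constant baseline
#'
#' Exhaustive search over the device grid [0.1, 5.0] for the single
#' amplitude minimizing the summed L1 distance to every curve in the
#' dataset. Because the L1 minimizer is a median, the result agrees with
#' a pooled median of all pad amplitudes to within one grid step. Ties
#' break toward the smallest constant (lower amplitudes delay
#' habituation and let fine-tuning approach targets from below).
#'
#' @param dataset a non-empty [calibration_dataset()].
#' @param grid_step search step in mA (default the 0.1 device step).
#' @return List with `constant_mA` and `total_distance_mA` (summed over
#'   all curves).
#' @export
optimal_constant <- function(dataset, grid_step = device_limits()$step_mA) {
  m <- curve_matrix(dataset)
  if (nrow(m) == 0) stop("empty dataset", call. = FALSE)
  lim <- device_limits()
  cand <- seq(as_tenths(lim$min_mA), as_tenths(lim$max_mA),
              by = as_tenths(grid_step))
  vals <- as.vector(m)
  # exact in integer tenths so ties resolve deterministically
  vt <- round(vals * 10)
  tot <- vapply(cand, function(ct) sum(abs(vt - ct)), numeric(1))
  best <- which.min(tot) # first minimum = smallest constant
  list(constant_mA = from_tenths(cand[best]),
       total_distance_mA = tot[best] / 10)
}

#' Baseline strategy descriptor
#'
#' Names one of the candidate starting curves compared in the baseline
#' analysis: a constant amplitude on every pad, the cohort mean curve,
#' the cohort percentile curve, or the L1-optimal constant.
#'
#' @param kind `"constant"`, `"mean_curve"`, `"percentile_curve"` or
#'   `"optimal_constant"`.
#' @param constant_mA the amplitude, for `kind = "constant"`.
#' @param q the percentile, for `kind = "percentile_curve"`.
#' @return An object of class `baseline_strategy`.
#' @export
baseline_strategy <- function(kind = c("constant", "mean_curve",
                                       "percentile_curve", "optimal_constant"),
                              constant_mA = NULL, q = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (is.null(constant_mA)) stop("constant strategy needs constant_mA", call. = FALSE)
    lim <- device_limits()
    if (constant_mA <= 0 || constant_mA > lim$max_mA) {
      stop("constant_mA outside device range", call. = FALSE)
    }
  }
  if (kind == "percentile_curve") {
    q <- q %||% 25
    if (q < 0 || q > 100) stop("q must be in [0, 100]", call. = FALSE)
  }
  structure(list(kind = kind, constant_mA = constant_mA, q = q),
            class = "baseline_strategy")
}

#' Resolve a baseline strategy to a curve
#'
#' @param strategy a [baseline_strategy()] (or a plain list with the same
#'   fields).
#' @param dataset the [calibration_dataset()] the data-driven strategies
#'   are computed from.
#' @return An [amplitude_curve()] (off-grid for data-driven strategies).
#' @export
baseline_curve <- function(strategy, dataset) {
  n <- attr(dataset, "n_pads")
  switch(strategy$kind,
    constant = amplitude_curve(rep(strategy$constant_mA, n), grid = FALSE),
    mean_curve = mean_curve(dataset),
    percentile_curve = percentile_curve(dataset, strategy$q %||% 25),
    optimal_constant = amplitude_curve(
      rep(optimal_constant(dataset)$constant_mA, n), grid = FALSE),
    stop(sprintf("unknown baseline strategy kind '%s'", strategy$kind),
         call. = FALSE))
}

#' Compare candidate baselines by effort distance
#'
#' For each strategy, computes the L1 distance from the strategy's
#' baseline curve to every calibration curve in the dataset and
#' summarizes the distances as mean +/- sample SD. The per-curve distance
#' matrix is returned too, shaped for [rm_anova_gg()].
#'
#' @param dataset a non-empty [calibration_dataset()].
#' @param strategies list of [baseline_strategy()]s. Defaults to the
#'   three reference candidates: the 1.0 mA constant, the optimal
#'   constant, and the overall mean curve.
#' @return An object of class `baseline_comparison`: list with `summary`
#'   (data.frame `strategy`, `mean`, `sd`) and `distances` (curves x
#'   strategies matrix, mA).
#' @export
compare_baselines <- function(dataset,
                              strategies = list(
                                baseline_strategy("constant", constant_mA = 1.0),
                                baseline_strategy("optimal_constant"),
                                baseline_strategy("mean_curve"))) {
  m <- curve_matrix(dataset)
  if (nrow(m) == 0) stop("empty dataset", call. = FALSE)
  labels <- vapply(strategies, function(s) {
    switch(s$kind,
      constant = sprintf("constant_%.1f_mA", s$constant_mA),
      percentile_curve = sprintf("percentile_%g", s$q %||% 25),
      s$kind)
  }, character(1))
  dist <- vapply(strategies, function(s) {
    b <- as.numeric(baseline_curve(s, dataset))
    apply(m, 1, function(row) sum(abs(row - b)))
  }, numeric(nrow(m)))
  dist <- matrix(dist, nrow = nrow(m),
                 dimnames = list(NULL, labels))
  structure(list(
    summary = data.frame(strategy = labels,
                         mean = colMeans(dist),
                         sd = apply(dist, 2, stats::sd),
                         row.names = NULL),
    distances = dist
  ), class = "baseline_comparison")
}

#' Check a baseline against each subject's observed range
#'
#' A good a-priori baseline should sit within or below each subject's
#' observed amplitudes, so fine-tuning approaches preferred values from
#' below. This counts, per subject, the pads where the baseline exceeds
#' that subject's observed maximum; a count of zero means the baseline is
#' within or below the subject's range everywhere.
#'
#' @param baseline an [amplitude_curve()] (or numeric vector).
#' @param dataset a [calibration_dataset()] grouped by its `subject_id`.
#' @return Named integer vector of counts, one per subject.
#' @export
check_baseline_constraint <- function(baseline, dataset) {
  b <- as.numeric(baseline)
  m <- curve_matrix(dataset)
  subj <- attr(m, "subject_id")
  vapply(unique(subj), function(s) {
    mx <- apply(m[subj == s, , drop = FALSE], 2, max)
    sum(b > mx + .grid_tol)
  }, integer(1))
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper around [stats::cor()]: inputs must be equal
#' length (>= 3) and non-constant.
#'
#' @param a,b numeric vectors.
#' @return Correlation in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant input", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Correlation structure of a calibration cohort
#'
#' Per subject, correlates each session curve with (A) the overall mean
#' curve across all subjects and sessions and (B) that subject's
#' individual mean curve, and averages within subject. High values in
#' column B relative to column A indicate stable individual amplitude
#' patterns that a single group-level curve does not capture. When a
#' streamlined session per subject is supplied, two further columns are
#' added: (C) the correlation of the streamlined final curve with the
#' individual mean, and (D) with the streamlined baseline curve.
#'
#' @param dataset a [calibration_dataset()] with >= 2 sessions per
#'   subject.
#' @param streamlined optional [calibration_dataset()] of streamlined
#'   sessions (the first session per subject is used).
#' @param baseline optional [amplitude_curve()]: the streamlined a-priori
#'   baseline, required for column D.
#' @return An object of class `correlation_analysis`: list with
#'   `by_subject` (data.frame with columns `subject_id`,
#'   `r_overall_mean`, `r_overall_sd`, `r_individual_mean`,
#'   `r_individual_sd`, and optionally `r_streamlined_individual`,
#'   `r_streamlined_baseline`) and `summary` (column means +/- sample SD
#'   of the per-subject values).
#' @export
correlation_analysis <- function(dataset, streamlined = NULL, baseline = NULL) {
  m <- curve_matrix(dataset)
  subj <- attr(m, "subject_id")
  usubj <- unique(subj)
  few <- usubj[vapply(usubj, function(s) sum(subj == s), integer(1)) < 2]
  if (length(few)) {
    stop(sprintf("need >= 2 sessions per subject; offending: %s",
                 paste(few, collapse = ", ")), call. = FALSE)
  }
  overall <- colMeans(m)

  sl_curves <- NULL
  if (!is.null(streamlined)) {
    sm <- curve_matrix(streamlined)
    ssub <- attr(sm, "subject_id")
    sl_curves <- lapply(usubj, function(s) {
      idx <- which(ssub == s)
      if (!length(idx)) stop(sprintf(
        "no streamlined session for subject '%s'", s), call. = FALSE)
      sm[idx[1], ]
    })
  }

  rows <- lapply(seq_along(usubj), function(i) {
    s <- usubj[i]
    sm_i <- m[subj == s, , drop = FALSE]
    indiv <- colMeans(sm_i)
    rA <- apply(sm_i, 1, pearson_r, b = overall)
    rB <- apply(sm_i, 1, pearson_r, b = indiv)
    out <- data.frame(subject_id = s,
                      r_overall_mean = mean(rA), r_overall_sd = stats::sd(rA),
                      r_individual_mean = mean(rB), r_individual_sd = stats::sd(rB))
    if (!is.null(sl_curves)) {
      out$r_streamlined_individual <- pearson_r(sl_curves[[i]], indiv)
      if (!is.null(baseline)) {
        out$r_streamlined_baseline <- pearson_r(sl_curves[[i]],
                                                as.numeric(baseline))
      }
    }
    out
  })
  by_subject <- do.call(rbind, rows)
  num_cols <- setdiff(names(by_subject), "subject_id")
  summary <- data.frame(column = num_cols,
                        mean = vapply(num_cols, function(cn) mean(by_subject[[cn]]), numeric(1)),
                        sd = vapply(num_cols, function(cn) stats::sd(by_subject[[cn]]), numeric(1)),
                        row.names = NULL)
  structure(list(by_subject = by_subject, summary = summary),
            class = "correlation_analysis")
}

#' Paired-samples t-test
#'
#' Two-tailed paired t-test: t = mean(d) / (sd(d)/sqrt(n)) on the
#' differences d = x - y, with n - 1 degrees of freedom (delegates to
#' [stats::t.test()]).
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @return An object of class `paired_test_result`: list with `t`, `df`,
#'   `p`, and `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(x - y) == 0) {
    stop("degenerate paired test: zero variance of differences", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(ht$estimate)),
            class = "paired_test_result")
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Takes a complete units x conditions matrix (each row one unit measured
#' under every condition), fits the standard within-subject one-way
#' ANOVA, and corrects the degrees of freedom for non-sphericity with the
#' Greenhouse-Geisser epsilon computed from the double-centered condition
#' covariance matrix. Post hoc pairwise comparisons are paired t-tests
#' with Bonferroni adjustment (p multiplied by the number of comparisons
#' and capped at 1).
#'
#' @param data numeric matrix, units in rows (>= 3) and conditions in
#'   columns (>= 2); no missing cells.
#' @return An object of class `rm_anova_result`: list with `F`,
#'   `epsilon`, `df1`, `df2` (corrected), `p`, `df1_uncorrected`,
#'   `df2_uncorrected`, and `pairwise` (data.frame with `a`, `b`, `t`,
#'   `df`, `p_raw`, `p_bonferroni`).
#' @export
rm_anova_gg <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("missing or non-finite cells", call. = FALSE)
  n <- nrow(data); k <- ncol(data)
  if (k < 2) stop("need >= 2 conditions", call. = FALSE)
  if (n < 3) stop("need >= 3 units", call. = FALSE)
  cond_names <- colnames(data) %||% paste0("c", seq_len(k))

  long <- data.frame(y = as.vector(data),
                     unit = factor(rep(seq_len(n), times = k)),
                     cond = factor(rep(cond_names, each = n),
                                   levels = cond_names))
  fit <- stats::aov(y ~ cond + Error(unit), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  F_stat <- tab["cond", "F value"]

  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(data)
  C <- diag(k) - matrix(1 / k, k, k)
  Sc <- C %*% S %*% C
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc * Sc))
  eps <- min(max(eps, 1 / (k - 1)), 1)

  df1u <- k - 1
  df2u <- (k - 1) * (n - 1)
  df1 <- eps * df1u
  df2 <- eps * df2u
  p <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(seq_len(k), 2)
  n_comp <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- paired_t_test(data[, a], data[, b])
    data.frame(a = cond_names[a], b = cond_names[b],
               t = tt$t, df = tt$df, p_raw = tt$p,
               p_bonferroni = min(tt$p * n_comp, 1))
  }))
  structure(list(F = unname(F_stat), epsilon = eps,
                 df1 = df1, df2 = df2, p = p,
                 df1_uncorrected = df1u, df2_uncorrected = df2u,
                 pairwise = pw),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA (Greenhouse-Geisser): F(%.3f, %.3f) = %.3f, p = %.4g (epsilon = %.3f)\n",
              x$df1, x$df2, x$F, x$p, x$epsilon))
  cat("Bonferroni pairwise:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
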