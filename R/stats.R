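#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way design, computed from sums of squares: the
#' condition effect is tested against the condition-by-subject interaction,
#' `F = MS_condition / MS_(condition x subject)` with degrees of freedom
#' `(k - 1)` and `(k - 1)(n - 1)`. With two conditions this F equals the
#' squared paired t statistic. Post hoc pairwise condition contrasts are
#' paired t tests with Bonferroni-adjusted p values.
#'
#' @param data Long-format data.frame.
#' @param subject,condition,value Column names (strings).
#' @param correction `"none"` (default) or `"gg"` for Greenhouse-Geisser
#'   adjustment of the degrees of freedom (the F statistic is unchanged).
#' @return An `anova_result`: list with `effects` (effect, F, df_num,
#'   df_den, p, epsilon) and `posthoc` (contrast, mean_diff, p_raw,
#'   p_adjusted) data.frames.
#' @export
rm_anova_oneway <- function(data, subject = "subject",
                            condition = "condition", value = "value",
                            correction = c("none", "gg")) {
  correction <- match.arg(correction)
  s <- factor(data[[subject]])
  c_ <- factor(data[[condition]])
  y <- as.double(data[[value]])
  k <- nlevels(c_); n <- nlevels(s)
  if (k < 2L || n < 2L) {
    stop("design error: need >= 2 subjects and >= 2 conditions",
         call. = FALSE)
  }
  counts <- table(s, c_)
  if (any(counts != 1L)) {
    miss <- which(counts != 1L, arr.ind = TRUE)
    stop("design error: incomplete design; offending cell(s): ",
         paste(paste(rownames(counts)[miss[, 1]],
                     colnames(counts)[miss[, 2]], sep = ":"),
               collapse = ", "), call. = FALSE)
  }
  ymat <- matrix(0, n, k, dimnames = list(levels(s), levels(c_)))
  ymat[cbind(as.integer(s), as.integer(c_))] <- y
  g <- mean(ymat)
  ss_cond <- n * sum((colMeans(ymat) - g)^2)
  ss_subj <- k * sum((rowMeans(ymat) - g)^2)
  ss_tot <- sum((ymat - g)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  eps <- 1
  if (correction == "gg") eps <- gg_epsilon(stats::cov(ymat))
  f <- safe_f(ss_cond / df1, ss_err / df2)
  p <- pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  pairs <- utils::combn(levels(c_), 2)
  m <- ncol(pairs)
  ph <- data.frame(
    contrast = apply(pairs, 2, paste, collapse = " - "),
    mean_diff = apply(pairs, 2, function(pr)
      mean(ymat[, pr[1]]) - mean(ymat[, pr[2]])),
    p_raw = apply(pairs, 2, function(pr) {
      d <- ymat[, pr[1]] - ymat[, pr[2]]
      if (var(d) == 0) return(if (mean(d) == 0) 1 else 0)
      tt <- mean(d) / sqrt(var(d) / n)
      2 * pt(-abs(tt), n - 1)
    }))
  ph$p_adjusted <- bonferroni(ph$p_raw, m)
  structure(list(
    effects = data.frame(effect = condition, F = f, df_num = df1 * eps,
                         df_den = df2 * eps, p = p, epsilon = eps),
    posthoc = ph,
    design = list(type = "oneway_rm", n_subjects = n, n_conditions = k,
                  correction = correction)),
    class = "anova_result")
}

# Degenerate-variance guard: a zero effect over a zero error term is no
# effect (F = 0), a positive effect over a zero error term is infinite.
safe_f <- function(ms_num, ms_den) {
  if (ms_den > 0) return(ms_num / ms_den)
  if (ms_num == 0) 0 else Inf
}

# Greenhouse-Geisser epsilon from the covariance matrix of the
# within-subject measures (double-centered form).
gg_epsilon <- function(S) {
  k <- nrow(S)
  J <- diag(k) - 1 / k
  Sd <- J %*% S %*% J
  sum(diag(Sd))^2 / ((k - 1) * sum(Sd^2))
}

#' Mixed two-way repeated-measures ANOVA
#'
#' One between-subject factor (group) and one within-subject factor (time),
#' balanced complete design. Standard mixed-model decomposition: the group
#' effect is tested against subjects-within-groups, the time and group x time
#' effects against the time-by-subjects-within-groups error. Post hoc
#' contrasts are all pairwise group differences at each timepoint, using the
#' pooled error term (subjects-within-groups + within error), with
#' Bonferroni adjustment over all contrasts performed.
#'
#' @param data Long-format data.frame.
#' @param subject,group,time,value Column names (strings).
#' @param correction `"none"` or `"gg"` (Greenhouse-Geisser, applied to the
#'   within-subject effects only).
#' @return An `anova_result` with three effect rows (group, time,
#'   group:time) and the post hoc table.
#' @export
rm_anova_mixed <- function(data, subject = "subject", group = "group",
                           time = "time", value = "value",
                           correction = c("none", "gg")) {
  correction <- match.arg(correction)
  s <- factor(data[[subject]])
  gr <- factor(data[[group]])
  tm <- factor(data[[time]])
  y <- as.double(data[[value]])
  subj_group <- table(s, gr)
  if (any(rowSums(subj_group > 0) > 1L)) {
    bad <- rownames(subj_group)[rowSums(subj_group > 0) > 1L][1]
    stop("design error: subject ", bad, " appears in more than one group",
         call. = FALSE)
  }
  counts <- table(s, tm)
  if (any(counts != 1L)) {
    stop("design error: incomplete design (need exactly one observation ",
         "per subject x timepoint)", call. = FALSE)
  }
  n_per_group <- table(droplevels(gr[!duplicated(s)]))
  if (length(unique(n_per_group)) != 1L) {
    stop("design error: unbalanced groups (",
         paste(n_per_group, collapse = ", "),
         " subjects); balanced design required", call. = FALSE)
  }
  a <- nlevels(gr); n <- unname(n_per_group[1]); t_ <- nlevels(tm)
  g <- mean(y)
  m_subj <- tapply(y, s, mean)
  m_group <- tapply(y, gr, mean)
  m_time <- tapply(y, tm, mean)
  m_cell <- tapply(y, list(gr, tm), mean)
  ss_between <- t_ * sum((m_subj - g)^2)
  ss_group <- n * t_ * sum((m_group - g)^2)
  ss_sw <- ss_between - ss_group
  ss_time <- a * n * sum((m_time - g)^2)
  ss_cells <- n * sum((m_cell - g)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_tot <- sum((y - g)^2)
  ss_err <- ss_tot - ss_between - ss_time - ss_int
  df_group <- a - 1; df_sw <- a * (n - 1)
  df_time <- t_ - 1; df_int <- (a - 1) * (t_ - 1)
  df_err <- (t_ - 1) * a * (n - 1)
  eps <- 1
  if (correction == "gg") {
    # pooled within-group covariance across timepoints
    S <- matrix(0, t_, t_)
    ymat <- matrix(0, nlevels(s), t_)
    ymat[cbind(as.integer(s), as.integer(tm))] <- y
    grp_of_subj <- gr[!duplicated(s)][order(unique(as.integer(s)))]
    for (lev in levels(gr)) {
      block <- ymat[grp_of_subj == lev, , drop = FALSE]
      S <- S + stats::cov(block) * (nrow(block) - 1)
    }
    S <- S / (a * (n - 1))
    eps <- gg_epsilon(S)
  }
  f_group <- safe_f(ss_group / df_group, ss_sw / df_sw)
  f_time <- safe_f(ss_time / df_time, ss_err / df_err)
  f_int <- safe_f(ss_int / df_int, ss_err / df_err)
  effects <- data.frame(
    effect = c(group, time, paste0(group, ":", time)),
    F = c(f_group, f_time, f_int),
    df_num = c(df_group, df_time * eps, df_int * eps),
    df_den = c(df_sw, df_err * eps, df_err * eps),
    p = c(pf(f_group, df_group, df_sw, lower.tail = FALSE),
          pf(f_time, df_time * eps, df_err * eps, lower.tail = FALSE),
          pf(f_int, df_int * eps, df_err * eps, lower.tail = FALSE)),
    epsilon = c(1, eps, eps))
  ms_pool <- (ss_sw + ss_err) / (df_sw + df_err)
  df_pool <- df_sw + df_err
  pairs <- utils::combn(levels(gr), 2)
  ph <- do.call(rbind, lapply(levels(tm), function(tp) {
    data.frame(
      contrast = paste0(apply(pairs, 2, paste, collapse = " - "),
                        " @ ", tp),
      mean_diff = apply(pairs, 2, function(pr)
        m_cell[pr[1], tp] - m_cell[pr[2], tp]),
      p_raw = apply(pairs, 2, function(pr) {
        tt <- (m_cell[pr[1], tp] - m_cell[pr[2], tp]) /
          sqrt(2 * ms_pool / n)
        2 * pt(-abs(tt), df_pool)
      }))
  }))
  ph$p_adjusted <- bonferroni(ph$p_raw, nrow(ph))
  rownames(ph) <- NULL
  structure(list(effects = effects, posthoc = ph,
                 design = list(type = "mixed_rm", n_groups = a,
                               n_per_group = n, n_timepoints = t_,
                               correction = correction)),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$design$type, ")\n", sep = "")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %s: F(%.4g, %.4g) = %.4f, p = %.4g\n", eff$effect[i],
                eff$df_num[i], eff$df_den[i], eff$F[i], eff$p[i]))
  }
  if (nrow(x$posthoc)) {
    cat("Post hoc (Bonferroni, m = ", nrow(x$posthoc), "):\n", sep = "")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Bonferroni correction
#'
#' `p_adjusted = min(1, m * p)` for each raw p value.
#'
#' @param p_values Numeric vector of raw p values in `[0, 1]`.
#' @param m Number of comparisons in the family (>= length of `p_values`
#'   in usual use; any integer >= 1 accepted).
#' @return Adjusted p values, clamped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (length(m) != 1L || !is.finite(m) || m < 1) {
    stop("argument error: `m` must be a single number >= 1", call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("argument error: p values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, m * p_values)
}

#' Tabulate significance of ANOVA effects and contrasts
#'
#' Flattens one or more `anova_result` objects into a table flagging which
#' effects and post hoc contrasts are significant at `alpha` (strict
#' inequality: `p < alpha`).
#'
#' @param results An `anova_result`, or a (possibly named) list of them.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with columns `analysis`, `term`, `type`, `p`,
#'   `significant`.
#' @export
significance_report <- function(results, alpha = 0.05) {
  if (inherits(results, "anova_result")) results <- list(results)
  empty <- data.frame(analysis = character(), term = character(),
                      type = character(), p = double(),
                      significant = logical())
  if (!length(results)) return(empty)
  nm <- names(results)
  if (is.null(nm)) nm <- as.character(seq_along(results))
  nm[nm == ""] <- as.character(seq_along(results))[nm == ""]
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    rbind(
      data.frame(analysis = nm[i], term = r$effects$effect,
                 type = "effect", p = r$effects$p),
      if (nrow(r$posthoc)) {
        data.frame(analysis = nm[i], term = r$posthoc$contrast,
                   type = "posthoc", p = r$posthoc$p_adjusted)
      })
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
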