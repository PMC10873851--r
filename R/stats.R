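#' Topographic ANOVA (TANOVA) between paired conditions
#'
#' Nonparametric permutation test for a topographic difference between two
#' paired sets of maps. Each subject's map is L2-normalized (and zero-meaned),
#' the statistic is the GFP of the difference between the two grand-average
#' maps, and the null distribution is built by randomly swapping the condition
#' assignment within subject. The p value uses the add-one estimator
#' `p = (#{perm >= obs} + 1) / (n_perm + 1)`; for `n <= max_exact` subjects an
#' exact mode enumerates all `2^n` swaps and `p = #{perm >= obs} / 2^n`
#' (the identity permutation included).
#'
#' @param maps_a,maps_b numeric matrices `subjects x channels`, paired by row.
#' @param n_perm Monte-Carlo permutations (ignored in exact mode).
#' @param seed integer seed.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   default: exact when `subjects <= max_exact`.
#' @param max_exact subject count up to which enumeration is used (default 12).
#' @return Object of class `"ms_test"`: list with `statistic` (GFP of the
#'   grand-average difference), `p`, `method`, `n_perm`, `n`.
#' @export
tanova <- function(maps_a, maps_b, n_perm = 4999, seed = NULL, exact = NULL,
                   max_exact = 12) {
  maps_a <- as.matrix(maps_a)
  maps_b <- as.matrix(maps_b)
  if (!all(dim(maps_a) == dim(maps_b))) {
    stop("conditions must be paired: equal subjects and channels")
  }
  n <- nrow(maps_a)
  a <- normalize_maps(maps_a)
  b <- normalize_maps(maps_b)
  d <- a - b                      # per-subject difference of normalized maps
  stat_of <- function(m) {        # m: signs x subjects
    g <- (m %*% d) / n            # permuted grand-average differences
    sqrt(rowMeans(g^2) - rowMeans(g)^2)
  }
  obs <- stat_of(matrix(1, 1, n))[1]
  if (is.null(exact)) exact <- n <= max_exact
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats_null <- stat_of(signs)
    p <- mean(stats_null >= obs - 1e-12)
    method <- "exact"
    n_perm <- nrow(signs)
  } else {
    stats_null <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      stat_of(signs)
    })
    p <- (sum(stats_null >= obs - 1e-12) + 1) / (n_perm + 1)
    method <- "permutation"
  }
  structure(list(statistic = obs, p = p, method = method, n_perm = n_perm,
                 n = n),
            class = "ms_test")
}

#' @export
print.ms_test <- function(x, ...) {
  cat(sprintf("TANOVA (%s, %d resamples): statistic = %.4g, p = %.4g (n = %d)\n",
              x$method, x$n_perm, x$statistic, x$p, x$n))
  invisible(x)
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject sums-of-squares decomposition for a complete
#' subjects x class x condition design. Reports F and p for the class and
#' condition main effects and their interaction, each against its own
#' subject-interaction error stratum, with conventional (uncorrected) degrees
#' of freedom.
#'
#' @param table data.frame with columns `subject`, `condition`, `class`, and
#'   the response named by `parameter` (e.g. a cohort parameter table from
#'   [cohort_params()]).
#' @param parameter response column name.
#' @return Object of class `"ms_anova"`: data.frame with one row per effect
#'   (`class`, `condition`, `class:condition`) and columns `SS`, `df`,
#'   `SS_error`, `df_error`, `F`, `p`.
#' @export
rm_anova <- function(table, parameter = "time_coverage") {
  need <- c("subject", "condition", "class", parameter)
  if (!all(need %in% names(table))) {
    stop("table must have columns subject, condition, class and '",
         parameter, "'")
  }
  y <- table[[parameter]]
  subj <- factor(table$subject)
  A <- factor(table$class)
  B <- factor(table$condition)
  n <- nlevels(subj); a <- nlevels(A); b <- nlevels(B)
  if (n < 3) stop("need at least 3 subjects")
  if (nrow(table) != n * a * b ||
      any(tapply(y, list(subj, A, B), length) != 1)) {
    stop("design must be a complete subject x class x condition crossing")
  }
  g <- mean(y)
  m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_s <- tapply(y, subj, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, subj), mean)
  m_bs <- tapply(y, list(B, subj), mean)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + g)^2)
  ss_as <- b * sum((m_as - outer(m_a, rep(1, n)) -
                      outer(rep(1, a), m_s) + g)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, rep(1, n)) -
                      outer(rep(1, b), m_s) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  eff <- data.frame(
    effect = c("class", "condition", "class:condition"),
    SS = c(ss_a, ss_b, ss_ab),
    df = c(a - 1, b - 1, (a - 1) * (b - 1)),
    SS_error = c(ss_as, ss_bs, ss_abs),
    df_error = c((a - 1) * (n - 1), (b - 1) * (n - 1),
                 (a - 1) * (b - 1) * (n - 1)))
  eff$F <- (eff$SS / eff$df) / (eff$SS_error / eff$df_error)
  eff$p <- stats::pf(eff$F, eff$df, eff$df_error, lower.tail = FALSE)
  class(eff) <- c("ms_anova", "data.frame")
  eff
}

#' Paired t test with effect size
#'
#' Two-tailed paired t test (`df = n - 1`) with Cohen's d computed from the
#' pooled condition standard deviations, `d = mean(x - y) /
#' sqrt((var(x) + var(y)) / 2)`; the paired-difference form `dz =
#' mean(x - y) / sd(x - y)` is also reported. Degenerate inputs (zero variance
#' of the differences with nonzero mean) are flagged rather than tested.
#'
#' @param x,y paired per-subject values, equal length >= 3.
#' @return Object of class `"ms_ttest"`: list with `t`, `df`, `p`, `d`, `dz`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  pooled <- sqrt((stats::var(x) + stats::var(y)) / 2)
  if (sdd < .Machine$double.eps * max(1, abs(md))) {
    if (abs(md) < .Machine$double.eps) {
      out <- list(t = 0, df = n - 1, p = 1, d = 0, dz = 0, mean_diff = 0,
                  degenerate = FALSE)
    } else {
      out <- list(t = NA_real_, df = n - 1, p = NA_real_,
                  d = if (pooled > 0) md / pooled else NA_real_,
                  dz = NA_real_, mean_diff = md, degenerate = TRUE)
    }
    return(structure(out, class = "ms_ttest"))
  }
  tval <- md / (sdd / sqrt(n))
  structure(list(t = tval, df = n - 1,
                 p = 2 * stats::pt(-abs(tval), n - 1),
                 d = md / pooled, dz = md / sdd, mean_diff = md,
                 degenerate = FALSE),
            class = "ms_ttest")
}

#' @export
print.ms_ttest <- function(x, ...) {
  if (x$degenerate) {
    cat("paired t: degenerate (constant nonzero differences), t undefined\n")
  } else {
    cat(sprintf("t(%d) = %.3f, p = %.4g, Cohen's d = %.3f (dz = %.3f)\n",
                x$df, x$t, x$p, x$d, x$dz))
  }
  invisible(x)
}

#' Family of paired contrasts with Bonferroni control
#'
#' Runs [paired_t()] for every class x parameter contrast between the two
#' conditions of a cohort parameter table and flags significance at the
#' Bonferroni-corrected level `alpha_family` (default `alpha / m` over the
#' declared family; a fixed family alpha can be supplied instead).
#'
#' @param table cohort parameter table (columns `subject`, `condition`,
#'   `class`, `mean_duration`, `time_coverage`).
#' @param parameters response columns to contrast.
#' @param alpha nominal family-wise error rate.
#' @param alpha_family optional fixed per-test threshold overriding
#'   `alpha / m`.
#' @param conditions length-2 character: contrast is `conditions[1] -
#'   conditions[2]`.
#' @return data.frame: class, parameter, t, df, p, d, significant, threshold.
#' @export
paired_contrasts <- function(table, parameters = c("mean_duration",
                                                   "time_coverage"),
                             alpha = 0.05, alpha_family = NULL,
                             conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(as.character(table$condition))
  stopifnot(length(conditions) == 2)
  classes <- sort(unique(table$class))
  m <- length(classes) * length(parameters)
  thr <- if (is.null(alpha_family)) alpha / m else alpha_family
  rows <- list()
  for (p in parameters) {
    for (cl in classes) {
      xa <- table[table$class == cl & table$condition == conditions[1], ]
      ya <- table[table$class == cl & table$condition == conditions[2], ]
      x <- xa[[p]][order(xa$subject)]
      y <- ya[[p]][order(ya$subject)]
      tt <- paired_t(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, parameter = p, t = tt$t, df = tt$df, p = tt$p, d = tt$d,
        significant = !is.na(tt$p) && tt$p <= thr, threshold = thr)
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlations with Benjamini-Hochberg FDR control
#'
#' Correlates a per-subject trait score with each column of a matrix of
#' per-subject parameters (the declared test family), reporting r, the
#' t-based two-sided p (`df = n - 2`), the BH step-up adjusted p, and the
#' raw and adjusted decisions at `alpha`.
#'
#' @param trait numeric per-subject scores.
#' @param params numeric matrix or data.frame, `subjects x tests`; column
#'   names label the tests.
#' @param alpha FDR level.
#' @return data.frame: test, r, df, p, p_adj, reject_raw, reject_fdr.
#' @export
pearson_with_fdr <- function(trait, params, alpha = 0.05) {
  params <- as.matrix(params)
  n <- length(trait)
  if (nrow(params) != n) stop("'params' rows must match 'trait' length")
  if (n < 4) stop("need at least 4 subjects per test")
  if (stats::sd(trait) == 0) stop("zero-variance trait: correlation undefined")
  tests <- colnames(params)
  if (is.null(tests)) tests <- paste0("test", seq_len(ncol(params)))
  r <- p <- numeric(ncol(params))
  for (j in seq_len(ncol(params))) {
    ok <- stats::complete.cases(trait, params[, j])
    if (stats::sd(params[ok, j]) == 0) {
      stop("zero-variance parameter column: correlation undefined")
    }
    ct <- stats::cor.test(trait[ok], params[ok, j])
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(test = tests, r = r, df = n - 2, p = p, p_adj = p_adj,
             reject_raw = p <= alpha, reject_fdr = p_adj <= alpha)
}

#' Score the neuroticism scale of a Big Five inventory
#'
#' Sums eight 5-point Likert items after mapping reverse-keyed items
#' `x -> 6 - x`; the resulting score ranges from 8 to 40.
#'
#' @param items numeric vector of 8 responses in \[1, 5\], or a
#'   `subjects x 8` matrix.
#' @param reverse_keys indices of reverse-keyed items (default none).
#' @return Integer score(s) in \[8, 40\].
#' @examples
#' bfi_neuroticism_score(rep(1, 8))  # 8
#' bfi_neuroticism_score(rep(5, 8))  # 40
#' @export
bfi_neuroticism_score <- function(items, reverse_keys = integer(0)) {
  m <- if (is.matrix(items)) items else matrix(items, nrow = 1)
  if (ncol(m) != 8) stop("exactly 8 items are required")
  if (any(m < 1 | m > 5 | m != round(m))) {
    stop("items must be integers in [1, 5]")
  }
  if (length(reverse_keys)) {
    if (any(reverse_keys < 1 | reverse_keys > 8)) {
      stop("'reverse_keys' must index items 1..8")
    }
    m[, reverse_keys] <- 6 - m[, reverse_keys]
  }
  s <- as.integer(rowSums(m))
  if (!is.matrix(items)) s[1] else s
}

#' Odd-even split-half reliability
#'
#' Pearson correlation across subjects between the sum of odd-numbered items
#' and the sum of even-numbered items.
#'
#' @param item_matrix numeric matrix, `subjects x items` (>= 2 items, >= 4
#'   subjects).
#' @return Scalar correlation.
#' @export
odd_even_reliability <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("need at least 2 items")
  if (nrow(m) < 4) stop("need at least 4 subjects")
  odd <- rowSums(m[, seq(1, ncol(m), by = 2), drop = FALSE])
  even <- rowSums(m[, seq(2, ncol(m), by = 2), drop = FALSE])
  stats::cor(odd, even)
}
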