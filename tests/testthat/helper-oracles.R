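# Independent oracles used to validate the package implementations.
# These deliberately avoid the code paths they check.

# GEV of a fixed partition with dominant-eigenvector centroids, computed from
# first principles on zero-meaned maps
partition_gev <- function(x, labels) {
  xc <- x - rowMeans(x)
  num <- 0
  for (j in unique(labels)) {
    xj <- xc[labels == j, , drop = FALSE]
    ev <- eigen(crossprod(xj), symmetric = TRUE)
    num <- num + ev$values[1]
  }
  num / sum(xc^2)
}

# exhaustive optimum GEV over all 2-partitions of <= 8 maps
kmeans2_oracle <- function(x) {
  n <- nrow(x)
  stopifnot(n <= 8, n >= 2)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(lab)) < 2) next
    g <- partition_gev(x, lab)
    if (g > best) best <- g
  }
  best
}

# direct-scan run-length oracle for temporal parameters: mean interior run
# length (ms) and coverage per class, censoring runs that touch a mask
# boundary or the epoch edge
runlength_oracle <- function(labels, mask, fs, k) {
  n <- length(labels)
  run_class <- integer(0); run_len <- integer(0); run_cens <- logical(0)
  i <- 1L
  while (i <= n) {
    if (mask[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && !mask[j + 1] && labels[j + 1] == labels[i]) j <- j + 1L
    left_edge <- (i == 1L) || mask[i - 1L]
    right_edge <- (j == n) || mask[j + 1L]
    run_class <- c(run_class, labels[i])
    run_len <- c(run_len, j - i + 1L)
    run_cens <- c(run_cens, left_edge || right_edge)
    i <- j + 1L
  }
  labeled <- sum(!mask)
  dur <- cov <- rep(NA_real_, k)
  for (cl in seq_len(k)) {
    lens <- run_len[run_class == cl & !run_cens]
    dur[cl] <- if (length(lens)) mean(lens) * 1000 / fs else NA_real_
    cov[cl] <- sum(run_len[run_class == cl]) / labeled
  }
  list(mean_duration = dur, time_coverage = cov)
}

# brute-force within-subject two-way ANOVA sums of squares, via explicit loops
rm_anova_oracle <- function(df, response) {
  y <- df[[response]]
  s <- as.character(df$subject); a <- as.character(df$class)
  b <- as.character(df$condition)
  us <- unique(s); ua <- unique(a); ub <- unique(b)
  n <- length(us); na <- length(ua); nb <- length(ub)
  g <- mean(y)
  cell <- function(...) {
    sel <- rep(TRUE, length(y))
    args <- list(...)
    for (nm in names(args)) sel <- sel & (get(substr(nm, 1, 1)) == args[[nm]])
    mean(y[sel])
  }
  ss_a <- ss_b <- ss_ab <- ss_s <- ss_as <- ss_bs <- 0
  for (ai in ua) ss_a <- ss_a + n * nb * (cell(a1 = ai) - g)^2
  for (bi in ub) ss_b <- ss_b + n * na * (cell(b1 = bi) - g)^2
  for (si in us) ss_s <- ss_s + na * nb * (cell(s1 = si) - g)^2
  for (ai in ua) for (bi in ub) {
    ss_ab <- ss_ab + n * (cell(a1 = ai, b1 = bi) - cell(a1 = ai) -
                            cell(b1 = bi) + g)^2
  }
  for (ai in ua) for (si in us) {
    ss_as <- ss_as + nb * (cell(a1 = ai, s1 = si) - cell(a1 = ai) -
                             cell(s1 = si) + g)^2
  }
  for (bi in ub) for (si in us) {
    ss_bs <- ss_bs + na * (cell(b1 = bi, s1 = si) - cell(b1 = bi) -
                             cell(s1 = si) + g)^2
  }
  ss_tot <- sum((y - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  FA <- (ss_a / (na - 1)) / (ss_as / ((na - 1) * (n - 1)))
  FB <- (ss_b / (nb - 1)) / (ss_bs / ((nb - 1) * (n - 1)))
  FAB <- (ss_ab / ((na - 1) * (nb - 1))) /
    (ss_abs / ((na - 1) * (nb - 1) * (n - 1)))
  c(class = FA, condition = FB, interaction = FAB)
}

# exhaustive assignment optimum for small square cost matrices
assignment_oracle <- function(cost) {
  n <- nrow(cost)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ,
                 drop = FALSE]
  vals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  min(vals)
}
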