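## Monte-Carlo verification of the closed forms.
##
## Each experiment simulates replicates, estimates the summaries of interest
## with standard errors (sample SD / sqrt(R)), and scores them against the
## closed-form expectations as z = (mean - theory)/SE.  With the default
## threshold |z| < 4 and at most a few dozen simultaneous checks per report
## the family-wise false-alarm probability under the null is below 0.2%, so
## a report counts exceedances rather than failing on a single borderline z.
## Deterministic identities (the growth recurrence, SFS conservation) are
## asserted per replicate with zero tolerance: a violation raises an error.

new_mc_report <- function(kind, params, stats, z_threshold, seed, extras = list()) {
  stats$pass <- ifelse(stats$se > 0,
                       abs(stats$z) < z_threshold,
                       stats$mean == stats$theory)
  structure(list(kind = kind, params = params, seed = seed,
                 z_threshold = z_threshold, stats = stats,
                 exceedances = sum(!stats$pass), extras = extras),
            class = "mc_report")
}

stat_rows <- function(name, n, i, x, theory) {
  ## x: matrix with one column per statistic (rows = replicates), or vector
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  R <- nrow(x)
  m <- colMeans(x)
  se <- apply(x, 2L, stats::sd) / sqrt(R)
  z <- ifelse(se > 0, (m - theory) / se, ifelse(m == theory, 0, Inf))
  data.frame(name = name, n = n, i = i, R = R, mean = m, se = se,
             theory = theory, z = z, row.names = NULL)
}

## Ratio-estimator rows for a proportion sum(a)/sum(b) with per-replicate
## pairs (a_r, b_r); SE by the delta method, robust to the within-replicate
## correlation of the star indicators.
ratio_rows <- function(name, n, i, a, b, theory) {
  R <- nrow(a)
  A <- colSums(a); B <- colSums(b)
  p <- A / B
  se <- numeric(length(p))
  for (j in seq_along(p)) {
    resid <- a[, j] - p[j] * b[, j]
    se[j] <- sqrt(R * stats::var(resid)) / B[j]
  }
  z <- ifelse(se > 0, (p - theory) / se, ifelse(p == theory, 0, Inf))
  data.frame(name = name, n = n, i = i, R = R, mean = p, se = se,
             theory = theory, z = z, row.names = NULL)
}

#' @export
print.mc_report <- function(x, digits = 4, ...) {
  cat(sprintf("<mc_report: %s>  seed = %d, z threshold = %g\n",
              x$kind, x$seed, x$z_threshold))
  cat("parameters:", paste(names(x$params), unlist(x$params),
                           sep = " = ", collapse = ", "), "\n")
  df <- x$stats
  df$mean <- signif(df$mean, digits)
  df$se <- signif(df$se, digits)
  df$theory <- signif(df$theory, digits)
  df$z <- round(df$z, 2)
  print(df, row.names = FALSE)
  cat(sprintf("%d of %d checks exceed |z| >= %g\n",
              x$exceedances, nrow(df), x$z_threshold))
  invisible(x)
}

#' Did a Monte-Carlo report pass?
#'
#' @param report an `mc_report`.
#' @param max_exceedances maximum tolerated number of |z| threshold
#'   exceedances (default 0).
#' @export
mc_passed <- function(report, max_exceedances = 0L) {
  report$exceedances <= max_exceedances
}

#' Direct simulation experiment
#'
#' Simulates `reps` independent genealogies of size `n` with mutations at
#' rate `theta` and scores the mean frequency spectrum against theta/i, the
#' mean number of segregating sites against theta times the harmonic number,
#' each mean coalescent interval against 1/(i(i-1)), and the mean TMRCA
#' against (n-1)/n.
#'
#' @param n sample size (>= 2).
#' @param theta scaled mutation rate 4Nu (>= 0).
#' @param reps number of replicates (>= 100; SEs are meaningless below that).
#' @param seed RNG seed, recorded in the report.
#' @param z_threshold pass/fail threshold on |z| (default 4).
#' @return an `mc_report`.
#' @export
run_direct_experiment <- function(n, theta, reps, seed, z_threshold = 4) {
  n <- check_count(n, "n", min = 2L)
  theta <- check_theta(theta)
  reps <- check_count(reps, "reps", min = 100L)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  sfs <- matrix(0L, reps, n - 1L)
  ivals <- matrix(0, reps, n - 1L)   # columns t_n .. t_2
  S <- numeric(reps)
  tmrca <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- simulate_tree(n)
    ms <- place_mutations(g, theta)
    s <- sfs_from_mutations(ms)
    if (sum(s) != nrow(ms$mutations)) stop_state("SFS does not conserve mutations")
    sfs[r, ] <- s
    S[r] <- sum(s)
    hs <- sort(g$height[is.na(g$label)])
    ivals[r, ] <- diff(c(0, hs))
    tmrca[r] <- hs[n - 1L]
  }
  stats <- rbind(
    stat_rows("s_i", n, seq_len(n - 1L), sfs, expected_sfs(n, theta)),
    stat_rows("S", n, NA_integer_, S, expected_segregating_sites(n, theta)),
    stat_rows("t_i", n, n:2, ivals,
              vapply(n:2, expected_interval, numeric(1))),
    stat_rows("t_MRCA", n, NA_integer_, tmrca, expected_tmrca(n)))
  new_mc_report("direct", list(n = n, theta = theta, reps = reps),
                stats, z_threshold, seed)
}

#' Growth-chain experiment
#'
#' For each replicate, simulates a mutated genealogy at `n_start` and grows
#' it one tip at a time to `n_end`, checking the exact bookkeeping
#' recurrence at every step (any violation raises an internal-consistency
#' error: the identity holds by construction, so a failure is a bug, not
#' sampling noise). The report scores the final-size mean spectrum against
#' theta/i and, at every intermediate size n, the mean star counts
#' `s_{i,*}` against theta/n, the fraction of size-i mutations on the star
#' path against i/n, and the mean number of extension mutations against
#' theta/n.
#'
#' @param n_start starting sample size (>= 2).
#' @param n_end final sample size (> n_start).
#' @inheritParams run_direct_experiment
#' @return an `mc_report`; `extras$recurrence_checked` counts the
#'   (replicate, step) identity checks performed, all of which passed.
#' @export
run_growth_experiment <- function(n_start, n_end, theta, reps, seed,
                                  z_threshold = 4) {
  n_start <- check_count(n_start, "n_start", min = 2L)
  n_end <- check_count(n_end, "n_end", min = n_start + 1L)
  theta <- check_theta(theta)
  reps <- check_count(reps, "reps", min = 100L)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  steps <- n_start:(n_end - 1L)
  star <- lapply(steps, function(n) matrix(0L, reps, n - 1L))
  tot <- lapply(steps, function(n) matrix(0L, reps, n - 1L))
  ext <- matrix(0L, reps, length(steps))
  final_sfs <- matrix(0L, reps, n_end - 1L)
  names(star) <- names(tot) <- steps
  checked <- 0L
  for (r in seq_len(reps)) {
    ms <- place_mutations(simulate_tree(n_start), theta)
    for (k in seq_along(steps)) {
      n <- steps[k]
      tot[[k]][r, ] <- sfs_from_mutations(ms)
      gr <- grow_tree(ms)
      if (!check_recurrence(ms, gr$ms, gr$record))
        stop_state(sprintf(
          "growth recurrence violated at replicate %d, step n=%d", r, n))
      checked <- checked + 1L
      star[[k]][r, ] <- gr$record$star_counts
      ext[r, k] <- gr$record$extension_mutation_count
      ms <- gr$ms
    }
    final_sfs[r, ] <- sfs_from_mutations(ms)
  }
  stats <- stat_rows("s_i", n_end, seq_len(n_end - 1L), final_sfs,
                     expected_sfs(n_end, theta))
  for (k in seq_along(steps)) {
    n <- steps[k]
    cls <- seq_len(n - 1L)
    stats <- rbind(stats,
      stat_rows("s_star", n, cls, star[[k]], expected_star_count(n, theta)),
      ratio_rows("star_fraction", n, cls, star[[k]], tot[[k]], cls / n),
      stat_rows("ext_mutations", n, NA_integer_, ext[, k],
                expected_star_count(n, theta)))
  }
  ## star_fraction rows can be degenerate at tiny reps (no size-i mutations
  ## seen); drop rows with an undefined denominator rather than score NaN
  stats <- stats[is.finite(stats$mean) | stats$name != "star_fraction", ]
  new_mc_report("growth",
                list(n_start = n_start, n_end = n_end, theta = theta,
                     reps = reps),
                stats, z_threshold, seed,
                extras = list(recurrence_checked = checked))
}

#' Construction-equivalence experiment
#'
#' The tip-extension construction is distributionally equivalent to direct
#' simulation at the larger size. This experiment compares `reps` direct
#' simulations at size `n` against `reps` simulations at size `n-1` grown by
#' one step: per-bin two-sample z-scores on the mean spectra and on the mean
#' TMRCA (difference scored against 0 with pooled standard error). Each
#' arm's means are also scored against theory. A two-sample chi-square on
#' the pooled mutation size-class counts is reported in `extras$chisq` as a
#' stricter distribution-level diagnostic.
#'
#' @param n sample size of the direct arm (>= 3); the grown arm starts at n-1.
#' @inheritParams run_direct_experiment
#' @export
run_equivalence_experiment <- function(n, theta, reps, seed, z_threshold = 4) {
  n <- check_count(n, "n", min = 3L)
  theta <- check_theta(theta)
  reps <- check_count(reps, "reps", min = 100L)
  seed <- check_count(seed, "seed", min = 0L)
  set.seed(seed)
  sfs_d <- matrix(0L, reps, n - 1L)
  sfs_g <- matrix(0L, reps, n - 1L)
  tm_d <- numeric(reps)
  tm_g <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- simulate_tree(n)
    sfs_d[r, ] <- sfs_from_mutations(place_mutations(g, theta))
    tm_d[r] <- max(g$height)
    gr <- grow_tree(place_mutations(simulate_tree(n - 1L), theta))
    sfs_g[r, ] <- sfs_from_mutations(gr$ms)
    tm_g[r] <- max(gr$ms$tree$height)
  }
  two_sample <- function(name, i, xa, xb) {
    if (is.null(dim(xa))) { xa <- matrix(xa, ncol = 1L); xb <- matrix(xb, ncol = 1L) }
    R <- nrow(xa)
    d <- colMeans(xa) - colMeans(xb)
    se <- sqrt(apply(xa, 2L, stats::var) / R + apply(xb, 2L, stats::var) / R)
    z <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf))
    data.frame(name = name, n = n, i = i, R = R, mean = d, se = se,
               theory = 0, z = z, row.names = NULL)
  }
  cls <- seq_len(n - 1L)
  stats <- rbind(
    stat_rows("s_i_direct", n, cls, sfs_d, expected_sfs(n, theta)),
    stat_rows("s_i_grown", n, cls, sfs_g, expected_sfs(n, theta)),
    two_sample("s_i_diff", cls, sfs_d, sfs_g),
    stat_rows("t_MRCA_direct", n, NA_integer_, tm_d, expected_tmrca(n)),
    stat_rows("t_MRCA_grown", n, NA_integer_, tm_g, expected_tmrca(n)),
    two_sample("t_MRCA_diff", NA_integer_, tm_d, tm_g))
  counts <- rbind(direct = colSums(sfs_d), grown = colSums(sfs_g))
  chisq <- if (all(colSums(counts) > 0)) {
    suppressWarnings(stats::chisq.test(counts[, colSums(counts) > 0, drop = FALSE]))
  } else NULL
  new_mc_report("equivalence", list(n = n, theta = theta, reps = reps),
                stats, z_threshold, seed, extras = list(chisq = chisq))
}
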