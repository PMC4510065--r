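## Closed-form expectations under the standard neutral model, in coalescent
## units of 4N generations (so N is eliminated; theta = 4Nu).

#' Expected site frequency spectrum
#'
#' Under the standard infinite-sites neutral model with constant population
#' size, the expected number of polymorphic sites with i copies of the
#' derived allele in a sample of n is theta/i, for i = 1..n-1.
#'
#' @param n sample size (>= 2).
#' @param theta scaled mutation rate 4Nu (>= 0).
#' @return numeric vector `theta / (1:(n-1))`.
#' @export
expected_sfs <- function(n, theta) {
  n <- check_count(n, "n", min = 2L)
  theta <- check_theta(theta)
  theta / seq_len(n - 1L)
}

#' Expected number of segregating sites
#'
#' `theta * sum_{i=1}^{n-1} 1/i` — theta times the harmonic number, equal to
#' the sum of the expected frequency spectrum. The harmonic sum is computed
#' by direct ascending summation.
#'
#' @inheritParams expected_sfs
#' @export
expected_segregating_sites <- function(n, theta) {
  n <- check_count(n, "n", min = 2L)
  theta <- check_theta(theta)
  theta * sum(1 / seq_len(n - 1L))
}

#' Expected coalescent interval and time to the MRCA
#'
#' The epoch during which the sample has exactly i ancestral lineages is
#' exponential with mean 1/(i(i-1)) coalescent units (4N/(i(i-1))
#' generations); the expected time to the most recent common ancestor is the
#' telescoping sum (n-1)/n.
#'
#' @param i number of extant lineages during the interval (>= 2).
#' @return `expected_interval`: 1/(i(i-1)); `expected_tmrca`: (n-1)/n, both
#'   in coalescent units.
#' @export
expected_interval <- function(i) {
  i <- check_count(i, "i", min = 2L)
  1 / (i * (i - 1))
}

#' @rdname expected_interval
#' @param n sample size (>= 2).
#' @export
expected_tmrca <- function(n) {
  n <- check_count(n, "n", min = 2L)
  (n - 1) / n
}

#' Expected star-mutation count and star probability
#'
#' In one growth step from sample size n, the expected number of size-i
#' mutations on the split tip's root path is theta/n — independent of i:
#' the i/n chance that a uniformly chosen tip descends from a given size-i
#' mutation cancels the 1/i in the expected count of size-i mutations. This
#' cancellation is what closes the induction: theta/i - theta/n + theta/n
#' = theta/i.
#'
#' @param n sample size (>= 2).
#' @param theta scaled mutation rate (>= 0).
#' @return `expected_star_count`: theta/n. `star_probability`: i/n, the
#'   probability that a specific size-i mutation lies on the star path.
#' @export
expected_star_count <- function(n, theta) {
  n <- check_count(n, "n", min = 2L)
  check_theta(theta) / n
}

#' @rdname expected_star_count
#' @param i frequency class, 1 <= i <= n-1.
#' @export
star_probability <- function(i, n) {
  n <- check_count(n, "n", min = 2L)
  i <- check_count(i, "i", min = 1L)
  if (i > n - 1L) stop_parameter("`i` must be at most n-1")
  i / n
}

#' Frequency spectrum by numerical induction
#'
#' Re-executes the inductive construction numerically: starting from the
#' base case (for n = 2 all polymorphisms are singletons, so
#' E(s_1) = E(S) = theta), each step computes the expected spectrum at n+1
#' from the spectrum at n via the star-mutation recurrence
#' `E(s_i(n+1)) = E(s_i(n)) - E(s_{i,*}) + E(s_{i-1,*})` with
#' `E(s_{i,*}) = E(s_i(n)) * i/n`, and recovers the singleton class by
#' subtracting the classes of size >= 2 from the expected total number of
#' segregating sites. The result reproduces theta/i to machine precision.
#'
#' @param n target sample size (>= 2).
#' @param theta scaled mutation rate (>= 0).
#' @return numeric vector of length n-1, the induced expected spectrum.
#' @export
sfs_by_induction <- function(n, theta) {
  n <- check_count(n, "n", min = 2L)
  theta <- check_theta(theta)
  v <- theta                      # E(s_1(2)) = E(S(2)) = theta
  m <- 2L
  while (m < n) {
    star <- c(v * seq_len(m - 1L) / m, 0)    # E(s_{i,*}), s_{m,*} = 0
    vext <- c(v, 0)                          # s_m(m) = 0
    nxt <- numeric(m)
    for (i in 2:m) nxt[i] <- vext[i] - star[i] + star[i - 1L]
    nxt[1L] <- expected_segregating_sites(m + 1L, theta) - sum(nxt[2:m])
    v <- nxt
    m <- m + 1L
  }
  v
}

#' Table of closed-form expectations
#'
#' @param n sample size (>= 2).
#' @param theta scaled mutation rate (>= 0).
#' @return a data frame with columns `quantity`, `i` (frequency class or
#'   lineage count, NA where not applicable) and `value`: the expected SFS
#'   (theta/i), segregating sites, coalescent intervals, TMRCA, and the
#'   per-step star-count expectation theta/n.
#' @export
theory_table <- function(n, theta) {
  n <- check_count(n, "n", min = 2L)
  theta <- check_theta(theta)
  rbind(
    data.frame(quantity = "expected_sfs", i = seq_len(n - 1L),
               value = expected_sfs(n, theta)),
    data.frame(quantity = "expected_S", i = NA_integer_,
               value = expected_segregating_sites(n, theta)),
    data.frame(quantity = "expected_interval", i = 2:n,
               value = vapply(2:n, expected_interval, numeric(1))),
    data.frame(quantity = "expected_tmrca", i = NA_integer_,
               value = expected_tmrca(n)),
    data.frame(quantity = "expected_star_count", i = NA_integer_,
               value = expected_star_count(n, theta))
  )
}

#' Convert coalescent-unit times to generations
#'
#' All internal time quantities are in coalescent units of 4N generations;
#' multiply by 4N to recover generations for a given diploid size N.
#'
#' @param x time(s) in coalescent units.
#' @param N diploid population size (> 0).
#' @export
to_generations <- function(x, N) {
  if (length(N) != 1L || !is.finite(N) || N <= 0)
    stop_parameter("`N` must be a single positive number")
  x * 4 * N
}
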