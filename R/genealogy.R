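## Genealogy representation
##
## A `genealogy` is a rooted binary ultrametric tree stored as parallel
## vectors indexed by node id 1..2n-1:
##   parent  - node id of the parent, NA at the root
##   height  - height above the present, in coalescent units of 4N generations
##   label   - tip label (integer 1..n) for tips, NA for internal nodes
## Tips sit at height 0; heights strictly increase from child to parent.

new_genealogy <- function(parent, height, label) {
  structure(list(parent = as.integer(parent),
                 height = as.numeric(height),
                 label = as.integer(label),
                 n = sum(!is.na(label))),
            class = "genealogy")
}

#' Simulate a standard-coalescent genealogy
#'
#' Builds a sample genealogy backward in time: starting from `n` lineages,
#' the interval during which `i` lineages are extant is drawn exponential
#' with mean 1/(i(i-1)) (coalescent units of 4N generations), after which a
#' uniformly chosen unordered pair of the `i` lineages merges. Draw order is
#' interval first, then pair, so runs are reproducible from `set.seed()`.
#'
#' @param n sample size (integer >= 2).
#' @return a `genealogy`: rooted binary ultrametric tree with `n` tips at
#'   height 0, tip labels `1..n`, node heights in coalescent units.
#' @examples
#' set.seed(1)
#' g <- simulate_tree(5)
#' tree_summaries(g)$tmrca
#' @export
simulate_tree <- function(n) {
  n <- check_count(n, "n", min = 2L)
  K <- 2L * n - 1L
  parent <- rep(NA_integer_, K)
  height <- numeric(K)
  label <- c(seq_len(n), rep(NA_integer_, n - 1L))
  active <- seq_len(n)
  h <- 0
  nxt <- n
  for (i in n:2) {
    h <- h + stats::rexp(1L, rate = i * (i - 1))
    pair <- sample.int(i, 2L)
    nxt <- nxt + 1L
    parent[active[pair]] <- nxt
    height[nxt] <- h
    active <- c(active[-pair], nxt)
  }
  new_genealogy(parent, height, label)
}

## Number of descendant tips below each node (a tip counts itself).
## Children are processed before parents because heights strictly increase.
n_desc_tips <- function(g) {
  cnt <- ifelse(is.na(g$label), 0L, 1L)
  for (v in order(g$height)) {
    p <- g$parent[v]
    if (!is.na(p)) cnt[p] <- cnt[p] + cnt[v]
  }
  cnt
}

root_of <- function(g) which(is.na(g$parent))

tip_ids <- function(g) which(!is.na(g$label))

## Branch length above each node (NA at the root).
branch_lengths <- function(g) {
  L <- g$height[g$parent] - g$height
  L[is.na(g$parent)] <- NA_real_
  L
}

#' Summaries of a genealogy
#'
#' @param tree a `genealogy`.
#' @return a list with `tmrca` (root height), `total_length` (sum of all
#'   branch lengths), and `intervals`, the inter-coalescent intervals
#'   `t_n .. t_2` (named), all in coalescent units. `tmrca` equals
#'   `sum(intervals)` exactly and `total_length` equals `sum(i * t_i)` for an
#'   ultrametric tree.
#' @export
tree_summaries <- function(tree) {
  validate_genealogy(tree)
  n <- tree$n
  hs <- sort(tree$height[is.na(tree$label)])
  intervals <- diff(c(0, hs))
  names(intervals) <- paste0("t", n:2)
  L <- branch_lengths(tree)
  list(tmrca = hs[n - 1L],
       total_length = sum(L, na.rm = TRUE),
       intervals = intervals)
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d tips, TMRCA = %.6f coalescent units\n",
              x$n, max(x$height)))
  invisible(x)
}

## Structural invariants; used at module boundaries, not in hot loops.
validate_genealogy <- function(g) {
  if (!inherits(g, "genealogy")) stop_parameter("not a genealogy object")
  K <- length(g$parent)
  n <- g$n
  if (K != 2L * n - 1L)
    stop_state(sprintf("genealogy must have 2n-1 nodes (n=%d, nodes=%d)", n, K))
  if (sum(is.na(g$parent)) != 1L)
    stop_state("genealogy must have exactly one root")
  ok <- !is.na(g$parent)
  if (any(g$height[g$parent[ok]] <= g$height[ok]))
    stop_state("heights must strictly increase from child to parent")
  if (!setequal(g$label[!is.na(g$label)], seq_len(n)))
    stop_state("tip labels must be exactly 1..n")
  invisible(g)
}

## TRUE iff all tips are at height 0 (within tol); growth requires this.
tips_at_zero <- function(g, tol = 1e-9) {
  all(abs(g$height[tip_ids(g)]) <= tol)
}
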