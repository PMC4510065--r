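## Infinite-sites mutations on a genealogy.
##
## A `mutation_set` couples a genealogy with a data frame of mutations:
##   id       - integer, unique within the set
##   node     - the node *below* the branch carrying the mutation
##   height   - height above the present at which the mutation occurred
##   position - site position, uniform on [0,1) (continuous infinite sites)
##   size     - number of descendant tips (the frequency class), 1..n-1
##   origin   - "sim" for the initial simulation, "grow<n>" for mutations
##              placed on the tip extensions of the growth step to size n

new_mutation_set <- function(tree, mutations, theta) {
  structure(list(tree = tree, mutations = mutations, theta = theta),
            class = "mutation_set")
}

empty_mutations <- function() {
  fast_df(id = integer(), node = integer(), height = numeric(),
          position = numeric(), size = integer(), origin = character())
}

#' Place infinite-sites mutations on a genealogy
#'
#' Each branch of length L (coalescent units) receives a Poisson(theta * L)
#' number of mutations; mutation heights are uniform along the branch and
#' site positions uniform on [0,1). Under the time unit of 4N generations the
#' per-branch rate per unit time is theta = 4Nu, so no separate N or u enters.
#'
#' @param tree a `genealogy`.
#' @param theta scaled mutation rate 4Nu (>= 0).
#' @return a `mutation_set`.
#' @examples
#' set.seed(1)
#' ms <- place_mutations(simulate_tree(5), theta = 2)
#' sfs_from_mutations(ms)
#' @export
place_mutations <- function(tree, theta) {
  validate_genealogy(tree)
  theta <- check_theta(theta)
  L <- branch_lengths(tree)
  below <- which(!is.na(tree$parent))
  len <- L[below]
  k <- stats::rpois(length(below), theta * len)
  K <- sum(k)
  if (K == 0L) return(new_mutation_set(tree, empty_mutations(), theta))
  node <- rep.int(below, k)
  lens <- rep.int(len, k)
  h <- tree$height[node] + stats::runif(K) * lens
  sizes <- n_desc_tips(tree)[node]
  mut <- fast_df(id = seq_len(K), node = node, height = h,
                 position = stats::runif(K), size = as.integer(sizes),
                 origin = rep.int("sim", K))
  new_mutation_set(tree, mut, theta)
}

#' Site frequency spectrum of a mutation set
#'
#' @param ms a `mutation_set` for a sample of size n.
#' @return integer vector of length n-1; entry i is the number of mutations
#'   of size i (i copies of the derived allele). Entries sum to the number of
#'   segregating sites.
#' @export
sfs_from_mutations <- function(ms) {
  if (!inherits(ms, "mutation_set")) stop_parameter("not a mutation_set")
  tabulate(ms$mutations$size, nbins = ms$tree$n - 1L)
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("<mutation_set> n = %d tips, theta = %g, %d mutations\n",
              x$tree$n, x$theta, nrow(x$mutations)))
  cat("SFS:", paste(sfs_from_mutations(x), collapse = " "), "\n")
  invisible(x)
}

## Recompute every mutation's size and branch interval from the tree and
## compare with the stored values; audit used by tests and check_recurrence.
validate_mutation_set <- function(ms) {
  g <- ms$tree
  validate_genealogy(g)
  m <- ms$mutations
  if (nrow(m) == 0L) return(invisible(ms))
  sizes <- n_desc_tips(g)[m$node]
  if (!all(sizes == m$size)) stop_state("stored mutation sizes disagree with the tree")
  lo <- g$height[m$node]
  hi <- g$height[g$parent[m$node]]
  if (any(is.na(hi))) stop_state("mutation placed above the root")
  if (any(m$height < lo | m$height > hi))
    stop_state("mutation height outside its branch interval")
  if (anyDuplicated(m$position)) stop_state("duplicate site positions")
  invisible(ms)
}
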