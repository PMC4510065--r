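## Recursive tip-extension growth.
##
## An (n+1)-sample mutated genealogy is generated from an n-sample one by
## splitting a uniformly chosen tip (the *-tip) into two zero-length
## children and extending all n+1 tips downward by a shared exponential
## increment e with mean 1/(n(n+1)) coalescent units (distributed like
## t_{n+1}).  Mutations on the *-tip's root path (*-mutations) gain exactly
## one descendant; all other pre-existing mutations are unchanged; new
## mutations on the n+1 extension segments all have size 1.  This is NOT the
## same operation as coalescing an (n+1)-th sampled lineage into the n-tree.

## Node ids on the path from a tip to the root, excluding the root itself:
## the branches above these nodes form the root path.
root_path <- function(g, node) {
  path <- integer()
  v <- node
  while (!is.na(g$parent[v])) {
    path <- c(path, v)
    v <- g$parent[v]
  }
  path
}

#' Star-mutation counts for a chosen tip
#'
#' Counts, for each frequency class i, the mutations of size i lying on the
#' path from `star_tip` back to the root (the *-mutations of the growth
#' construction). Summing indicator variables over the size-i mutations, the
#' expectation of entry i is theta/n, independent of i.
#'
#' @param ms a `mutation_set` for sample size n.
#' @param star_tip tip label (integer in 1..n).
#' @return integer vector of length n-1; entry i is `s_{i,*}`.
#' @export
star_counts <- function(ms, star_tip) {
  if (!inherits(ms, "mutation_set")) stop_parameter("not a mutation_set")
  g <- ms$tree
  star_tip <- check_count(star_tip, "star_tip", min = 1L)
  tid <- tip_ids(g)[match(star_tip, g$label[tip_ids(g)])]
  if (is.na(tid)) stop_parameter(sprintf("no tip labelled %d", star_tip))
  path <- root_path(g, tid)
  on_path <- ms$mutations$node %in% path
  tabulate(ms$mutations$size[on_path], nbins = g$n - 1L)
}

#' Grow an n-sample mutated genealogy to n+1 samples
#'
#' Performs one step of the tip-extension construction: a uniformly chosen
#' tip becomes an internal node with two zero-length children; every one of
#' the n+1 tips is then extended downward by the same increment `e`, drawn
#' exponential with mean 1/(n(n+1)) coalescent units; new mutations fall on
#' the n+1 extension segments at rate theta per unit length (Poisson mean
#' theta*e per segment, heights uniform within the segment), each of size 1.
#' Pre-existing mutations keep their branches; a mutation's size increases by
#' exactly 1 iff it lies on the star lineage. Node heights are shifted so
#' tips are again at height 0, keeping repeated growth composable.
#'
#' Tips are relabelled: the star label is retired, the surviving n-1 tips
#' take labels 1..n-1 in order of their old labels, and the two children of
#' the split take labels n and n+1. The old-to-new mapping is recorded in
#' the returned record.
#'
#' Random draw order: star tip (unless supplied), extension length, then the
#' per-tip extension mutation counts and coordinates in new-label order.
#'
#' @param ms a `mutation_set` whose tree has all tips at height 0.
#' @param star_tip optional tip label to split (default: uniform draw);
#'   supplying it makes the step deterministic apart from mutation placement.
#' @return a list with `ms`, the grown `mutation_set` (n+1 tips), and
#'   `record`, a `star_record` holding `star_tip`, `star_counts`
#'   (`s_{i,*}`, length n-1), `extension_length`, `extension_mutation_count`
#'   and `label_map`.
#' @examples
#' set.seed(1)
#' ms <- place_mutations(simulate_tree(4), theta = 3)
#' gr <- grow_tree(ms)
#' check_recurrence(ms, gr$ms, gr$record)
#' @export
grow_tree <- function(ms, star_tip = NULL) {
  if (!inherits(ms, "mutation_set")) stop_parameter("not a mutation_set")
  g <- ms$tree
  n <- g$n
  if (n < 2L) stop_parameter("growth needs a sample of size >= 2")
  if (!tips_at_zero(g))
    stop_state("tree has nonzero tip heights; grow only normalized trees")
  theta <- ms$theta
  tips <- tip_ids(g)
  labs <- g$label[tips]

  if (is.null(star_tip)) {
    star_lab <- sample.int(n, 1L)
  } else {
    star_lab <- check_count(star_tip, "star_tip", min = 1L)
    if (!star_lab %in% labs) stop_parameter(sprintf("no tip labelled %d", star_lab))
  }
  star_node <- tips[match(star_lab, labs)]

  path <- root_path(g, star_node)
  on_path <- ms$mutations$node %in% path
  sc <- tabulate(ms$mutations$size[on_path], nbins = n - 1L)

  e <- stats::rexp(1L, rate = n * (n + 1))

  K <- length(g$parent)
  parent <- c(g$parent, star_node, star_node)
  height <- c(g$height + e, 0, 0)
  height[tips] <- 0            # old tips extended down to the present
  height[star_node] <- e       # except the star tip, now an internal node
  label <- c(g$label, NA_integer_, NA_integer_)

  ## relabel: survivors 1..n-1 by old-label order, children n and n+1
  surv <- tips[order(labs)]
  surv <- surv[surv != star_node]
  label[] <- NA_integer_
  label[surv] <- seq_len(n - 1L)
  label[K + 1L] <- n
  label[K + 2L] <- n + 1L
  g2 <- new_genealogy(parent, height, label)
  label_map <- fast_df(old_label = c(sort(labs[labs != star_lab]), star_lab),
                       new_label = c(seq_len(n - 1L), NA_integer_))

  mut <- ms$mutations
  if (nrow(mut) > 0L) {
    mut$height <- mut$height + e
    mut$size <- mut$size + as.integer(on_path)
  }

  ## extension mutations, one segment of length e per tip, in new-label order
  new_tips <- order(label, na.last = NA)      # node ids sorted by new label
  k <- stats::rpois(n + 1L, theta * e)
  ext_total <- sum(k)
  if (ext_total > 0L) {
    node <- rep.int(new_tips, k)
    base <- if (nrow(mut)) max(mut$id) else 0L
    mut <- fast_df(id = c(mut$id, base + seq_len(ext_total)),
                   node = c(mut$node, node),
                   height = c(mut$height, stats::runif(ext_total) * e),
                   position = c(mut$position, stats::runif(ext_total)),
                   size = c(mut$size, rep.int(1L, ext_total)),
                   origin = c(mut$origin,
                              rep.int(sprintf("grow%d", n + 1L), ext_total)))
  }

  record <- structure(list(star_tip = star_lab, star_counts = sc,
                           extension_length = e,
                           extension_mutation_count = ext_total,
                           label_map = label_map),
                      class = "star_record")
  list(ms = new_mutation_set(g2, mut, theta), record = record)
}

#' @export
print.star_record <- function(x, ...) {
  cat(sprintf("<star_record> star tip %d, e = %.6f, %d extension mutations\n",
              x$star_tip, x$extension_length, x$extension_mutation_count))
  cat("s_{i,*}:", paste(x$star_counts, collapse = " "), "\n")
  invisible(x)
}

#' Check the exact growth recurrence on one step
#'
#' Verifies the bookkeeping identity relating the frequency spectra before
#' and after one growth step: for i = 2..n,
#' `s_i(n+1) = s_i(n) - s_{i,*}(n) + s_{i-1,*}(n)` (with `s_n(n)` and
#' `s_{n,*}(n)` defined as zero), and for the singleton class the realized
#' form `s_1(n+1) = s_1(n) - s_{1,*}(n) + extension_mutation_count`. These
#' hold deterministically on every replicate; a failure is a bug, not noise.
#'
#' @param before the `mutation_set` of size n the step started from.
#' @param after the `mutation_set` of size n+1 the step produced.
#' @param rec the `star_record` of the step.
#' @return TRUE iff every identity holds exactly.
#' @export
check_recurrence <- function(before, after, rec) {
  if (!inherits(before, "mutation_set") || !inherits(after, "mutation_set"))
    stop_parameter("before/after must be mutation_sets")
  n <- before$tree$n
  if (after$tree$n != n + 1L)
    stop_parameter("`after` must have sample size exactly one larger than `before`")
  s_n <- c(sfs_from_mutations(before), 0L)        # s_i(n), i = 1..n (s_n = 0)
  star <- c(rec$star_counts, 0L)                  # s_{i,*}, i = 1..n (s_{n,*} = 0)
  s_np1 <- sfs_from_mutations(after)              # s_i(n+1), i = 1..n
  i <- 2:n
  all(s_np1[i] == s_n[i] - star[i] + star[i - 1L]) &&
    s_np1[1L] == s_n[1L] - star[1L] + rec$extension_mutation_count
}
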