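## Newick serialization.  Writing is a small bespoke serializer so the
## format is fixed (branch lengths to 6 decimal places, labels t1..tn,
## terminating semicolon); parsing goes through ape.

#' Write a genealogy as a Newick string
#'
#' @param tree a `genealogy`.
#' @param labels optional named character vector mapping tip label (as
#'   character) to output name; default renders tip k as `tk`.
#' @return a single Newick string, branch lengths in coalescent units with 6
#'   decimal places, e.g. `"(t1:0.500000,t2:0.500000);"` for a two-tip tree
#'   with t_2 = 0.5.
#' @export
write_newick <- function(tree, labels = NULL) {
  validate_genealogy(tree)
  g <- tree
  kids <- vector("list", length(g$parent))
  for (v in seq_along(g$parent)) {
    p <- g$parent[v]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], v)
  }
  fmt <- function(v) {
    s <- if (is.na(g$label[v])) {
      paste0("(", paste(vapply(kids[[v]], fmt, character(1)), collapse = ","), ")")
    } else if (!is.null(labels)) {
      labels[[as.character(g$label[v])]]
    } else {
      paste0("t", g$label[v])
    }
    p <- g$parent[v]
    if (is.na(p)) s
    else paste0(s, ":", sprintf("%.6f", g$height[p] - g$height[v]))
  }
  paste0(fmt(root_of(g)), ";")
}

#' Read a genealogy from a Newick string
#'
#' Parses with \pkg{ape} and converts to a `genealogy`: the tree must be
#' rooted, strictly binary and ultrametric within `tol` (all tips equally
#' distant from the root); tip heights are normalized to exactly 0. Tip
#' labels of the form `t<k>` become integer labels k; any other labels are
#' assigned 1..n in ape's tip order.
#'
#' @param text a Newick string (or a file path via `file`).
#' @param file optional path to read instead of `text`.
#' @param tol per-branch ultrametricity tolerance (default 1e-6, matching
#'   the writer's 6-decimal precision). Because rounding errors accumulate
#'   along root paths, a tip may deviate from the deepest tip by up to
#'   `n * tol` before the tree is rejected.
#' @return a `genealogy`.
#' @export
read_newick <- function(text = NULL, file = NULL, tol = 1e-6) {
  if (is.null(text)) {
    if (is.null(file)) stop_parameter("supply `text` or `file`")
    lines <- readLines(file)
    text <- paste(lines[!startsWith(lines, "#")], collapse = "")
  }
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) NULL)
  if (is.null(phy) || is.null(phy$edge))
    stop_format("not parseable as Newick")
  n <- length(phy$tip.label)
  if (n < 2L) stop_format("tree must have at least 2 tips")
  deg <- tabulate(phy$edge[, 1L], nbins = n + phy$Nnode)
  bad <- which(deg > 0L & deg != 2L)
  if (length(bad))
    stop_format(sprintf("tree is not binary: node %d has %d children",
                        bad[1L], deg[bad[1L]]))
  if (is.null(phy$edge.length))
    stop_format("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(phy)
  H <- max(depth[seq_len(n)])
  off <- H - depth[seq_len(n)]
  if (any(off > n * tol)) {
    w <- which.max(off)
    stop_format(sprintf("tree is not ultrametric: tip '%s' is %.3g below the deepest tip",
                        phy$tip.label[w], off[w]))
  }
  height <- H - depth
  height[seq_len(n)] <- 0
  parent <- rep(NA_integer_, n + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  lab <- rep(NA_integer_, n + phy$Nnode)
  m <- regmatches(phy$tip.label, regexec("^t([0-9]+)$", phy$tip.label))
  nums <- vapply(m, function(x) if (length(x) == 2L) as.integer(x[2L]) else NA_integer_,
                 integer(1))
  lab[seq_len(n)] <- if (!anyNA(nums) && setequal(nums, seq_len(n))) nums else seq_len(n)
  g <- new_genealogy(parent, height, lab)
  validate_genealogy(g)
  g
}
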