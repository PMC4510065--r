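## Text output: ms-style haplotype blocks and TSV writers.  Every file
## written by the package starts with '#' header lines recording the
## package version, parameters and seed.

header_lines <- function(params = list(), seed = NULL) {
  v <- as.character(utils::packageVersion("coalgrow"))
  h <- sprintf("# coalgrow %s", v)
  if (length(params))
    h <- c(h, paste0("# ", paste(names(params), unlist(params),
                                 sep = "=", collapse = " ")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed=%d", seed))
  h
}

#' Write a mutation set as an ms-style text block
#'
#' Produces the classic coalescent-simulator text block: a `segsites: K`
#' line, a `positions:` line with the site positions sorted ascending to 6
#' decimals, and one 0/1 row per tip in tip-label order (1 = derived
#' allele). Column sums equal the mutation sizes by construction.
#'
#' @param ms a `mutation_set`.
#' @return character vector of lines (no haplotype rows when there are no
#'   segregating sites).
#' @export
write_ms_block <- function(ms) {
  if (!inherits(ms, "mutation_set")) stop_parameter("not a mutation_set")
  m <- ms$mutations
  if (nrow(m) == 0L) return("segsites: 0")
  g <- ms$tree
  m <- m[order(m$position), , drop = FALSE]
  n <- g$n
  hap <- matrix(0L, n, nrow(m))
  for (v in tip_ids(g)) {
    hap[g$label[v], ] <- as.integer(m$node %in% root_path(g, v))
  }
  c(sprintf("segsites: %d", nrow(m)),
    paste("positions:", paste(sprintf("%.6f", m$position), collapse = " ")),
    apply(hap, 1L, paste, collapse = ""))
}

#' Write site frequency spectra as TSV
#'
#' @param sfs an integer matrix, one row per replicate, column i = s_i, or a
#'   single SFS vector.
#' @param path output path.
#' @param params named list recorded in the header.
#' @param seed seed recorded in the header.
#' @export
write_sfs_tsv <- function(sfs, path, params = list(), seed = NULL) {
  if (is.null(dim(sfs))) sfs <- matrix(sfs, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(params, seed), con)
  writeLines("replicate\ti\ts_i", con)
  df <- data.frame(replicate = rep(seq_len(nrow(sfs)), each = ncol(sfs)),
                   i = rep(seq_len(ncol(sfs)), nrow(sfs)),
                   s_i = as.integer(t(sfs)))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a growth audit log as TSV
#'
#' One row per growth step: replicate, step (the sample size grown from),
#' star tip label, extension length, extension mutation count, and the star
#' counts `s_{i,*}` comma-joined.
#'
#' @param rows a data frame as assembled by the CLI grow loop (columns
#'   `replicate`, `step`, `star_tip`, `extension_length`,
#'   `extension_mutation_count`, `star_counts`).
#' @inheritParams write_sfs_tsv
#' @export
write_audit_log <- function(rows, path, params = list(), seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(params, seed), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

audit_row <- function(record, replicate, step) {
  data.frame(replicate = replicate, step = step,
             star_tip = record$star_tip,
             extension_length = record$extension_length,
             extension_mutation_count = record$extension_mutation_count,
             star_counts = paste(record$star_counts, collapse = ","),
             stringsAsFactors = FALSE)
}
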