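# Five-tip fixture mirroring the worked example of the growth construction:
# topology ((t1,t2),t3) joined to (t4,t5); mutation A sits above the
# {t1,t2,t3} ancestor (size 3), mutation B above the {t4,t5} ancestor
# (size 2).  Splitting t4 makes B a *-mutation (size 2 -> 3) while A is
# untouched (size 3 -> 3); any extension mutation C has size 1.
fixture_tree <- function() {
  coalgrow:::new_genealogy(
    parent = c(6L, 6L, 8L, 7L, 7L, 8L, 9L, 9L, NA),
    height = c(0, 0, 0, 0, 0, 0.1, 0.2, 0.3, 0.6),
    label = c(1:5, rep(NA_integer_, 4)))
}

fixture_ms <- function(theta = 1) {
  mut <- data.frame(id = 1:2, node = c(8L, 7L), height = c(0.45, 0.35),
                    position = c(0.25, 0.75), size = c(3L, 2L),
                    origin = "sim", stringsAsFactors = FALSE)
  coalgrow:::new_mutation_set(fixture_tree(), mut, theta)
}

# two-tip tree with a chosen coalescence time
two_tip_tree <- function(t2 = 0.5) {
  coalgrow:::new_genealogy(parent = c(3L, 3L, NA),
                           height = c(0, 0, t2),
                           label = c(1L, 2L, NA))
}

# pairwise two-sample z-scores between rows of an mc_report stats subset
max_pairwise_z <- function(m, se) {
  z <- 0
  for (j in seq_along(m)) for (k in seq_len(j - 1L)) {
    z <- max(z, abs(m[j] - m[k]) / sqrt(se[j]^2 + se[k]^2))
  }
  z
}
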