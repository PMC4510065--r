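test_that("a two-tip tree serializes to the canonical string", {
  expect_identical(write_newick(two_tip_tree(0.5)),
                   "(t1:0.500000,t2:0.500000);")
})

test_that("write/read round-trips preserve heights and stabilize", {
  set.seed(23)
  for (case in 1:100) {
    n <- sample(2:10, 1)
    g <- simulate_tree(n)
    w0 <- write_newick(g)
    g1 <- read_newick(w0)
    expect_equal(g1$n, n)
    ## heights agree up to accumulated 6-decimal rounding
    expect_lt(max(abs(sort(g1$height) - sort(g$height))), n * 1e-6)
    w1 <- write_newick(g1)
    expect_identical(write_newick(read_newick(w1)), w1)  # idempotent
  }
})

test_that("the fixture survives a Newick round trip with its spectrum", {
  ms <- fixture_ms()
  g2 <- read_newick(write_newick(ms$tree))
  ## re-attach the mutations by locating the size-3 and size-2 ancestors
  cnt <- coalgrow:::n_desc_tips(g2)
  cherry45 <- which(vapply(seq_along(g2$parent), function(v) {
    kids <- which(!is.na(g2$parent) & g2$parent == v)
    length(kids) == 2 && setequal(g2$label[kids], c(4L, 5L))
  }, logical(1)))
  nodes <- c(which(cnt == 3L & is.na(g2$label)), cherry45)
  mut <- data.frame(id = 1:2, node = nodes,
                    height = g2$height[nodes] + 0.01,
                    position = c(0.25, 0.75), size = c(3L, 2L),
                    origin = "sim")
  ms2 <- coalgrow:::new_mutation_set(g2, mut, ms$theta)
  expect_identical(sfs_from_mutations(ms2), c(0L, 1L, 1L, 0L))
})

test_that("malformed input is rejected with a format error", {
  expect_error(read_newick("(t1:1,t2:1,t3:1);"),
               class = "coalgrow_format_error")     # multifurcation
  expect_error(read_newick("((t1:1,t2:2):1,t3:3);"),
               class = "coalgrow_format_error")     # not ultrametric
  expect_error(read_newick("not a tree"),
               class = "coalgrow_format_error")
  expect_error(read_newick("(t1,t2);"),
               class = "coalgrow_format_error")     # no branch lengths
})

test_that("a hand-written ultrametric tree can be grown", {
  g <- read_newick("((t1:0.2,t2:0.2):0.3,t3:0.5);")
  expect_equal(g$n, 3L)
  set.seed(33)
  ms <- place_mutations(g, 4)
  gr <- grow_tree(ms)
  expect_true(check_recurrence(ms, gr$ms, gr$record))
  expect_equal(gr$ms$tree$n, 4L)
})

test_that("reading from a file skips '#' header lines", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("# coalgrow test", "(t1:0.250000,t2:0.250000);"), path)
  g <- read_newick(file = path)
  expect_equal(max(g$height), 0.25)
})
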