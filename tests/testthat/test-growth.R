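test_that("growing the fixture reproduces the worked example", {
  ms <- fixture_ms(theta = 0)
  set.seed(4)
  gr <- grow_tree(ms, star_tip = 4)
  rec <- gr$record
  expect_identical(rec$star_tip, 4L)
  expect_identical(rec$star_counts, c(0L, 1L, 0L, 0L))  # B is the *-mutation
  expect_identical(rec$extension_mutation_count, 0L)
  after <- gr$ms
  expect_equal(after$tree$n, 6L)
  ## A stays size 3, B becomes size 3: spectrum (0,0,2,0,0)
  expect_identical(sfs_from_mutations(after), c(0L, 0L, 2L, 0L, 0L))
  expect_true(check_recurrence(ms, after, rec))
  ## relabelling: star label retired, survivors 1..4, children 5 and 6
  expect_setequal(after$tree$label[!is.na(after$tree$label)], 1:6)
  map <- rec$label_map
  expect_identical(map$new_label[map$old_label == 4], NA_integer_)
  expect_identical(map$new_label[map$old_label == 5], 4L)
})

test_that("extension mutations all have size one", {
  ms <- fixture_ms(theta = 50)
  set.seed(8)
  gr <- grow_tree(ms, star_tip = 4)
  new <- gr$ms$mutations[gr$ms$mutations$origin == "grow6", ]
  expect_gt(nrow(new), 0)   # theta*e large enough at this seed
  expect_true(all(new$size == 1L))
  expect_identical(nrow(new), gr$record$extension_mutation_count)
  expect_true(check_recurrence(ms, gr$ms, gr$record))
  expect_silent(coalgrow:::validate_mutation_set(gr$ms))
})

test_that("star_counts counts exactly the root-path mutations", {
  ms <- fixture_ms()
  expect_identical(star_counts(ms, 4), c(0L, 1L, 0L, 0L))  # B only
  expect_identical(star_counts(ms, 1), c(0L, 0L, 1L, 0L))  # A only
  empty <- coalgrow:::new_mutation_set(fixture_tree(),
                                       coalgrow:::empty_mutations(), 1)
  expect_identical(star_counts(empty, 3), integer(4))
  expect_error(star_counts(ms, 9), class = "coalgrow_parameter_error")
})

test_that("repeated growth keeps every invariant and the exact recurrence", {
  set.seed(21)
  for (case in 1:10) {
    theta <- runif(1, 0, 6)
    ms <- place_mutations(simulate_tree(2), theta)
    for (n in 2:7) {
      gr <- grow_tree(ms)
      expect_true(check_recurrence(ms, gr$ms, gr$record))
      expect_true(all(gr$record$star_counts <= sfs_from_mutations(ms)))
      ms <- gr$ms
      expect_equal(ms$tree$n, n + 1L)
      expect_silent(coalgrow:::validate_genealogy(ms$tree))
      expect_silent(coalgrow:::validate_mutation_set(ms))
      expect_true(coalgrow:::tips_at_zero(ms$tree))
    }
  }
})

test_that("a tampered grown spectrum fails the recurrence check", {
  set.seed(13)
  ms <- place_mutations(simulate_tree(5), 4)
  gr <- grow_tree(ms)
  bad <- gr$ms
  stopifnot(nrow(bad$mutations) > 0)
  bad$mutations$size[1] <- bad$mutations$size[1] %% (bad$tree$n - 1L) + 1L
  expect_false(check_recurrence(ms, bad, gr$record))
})

test_that("growth rejects unnormalized trees and bad sizes", {
  raised <- coalgrow:::new_genealogy(parent = c(3L, 3L, NA),
                                     height = c(0.05, 0.05, 0.5),
                                     label = c(1L, 2L, NA))
  ms <- coalgrow:::new_mutation_set(raised, coalgrow:::empty_mutations(), 1)
  expect_error(grow_tree(ms), class = "coalgrow_state_error")
  expect_error(grow_tree(fixture_ms(), star_tip = 7),
               class = "coalgrow_parameter_error")
  expect_error(check_recurrence(fixture_ms(), fixture_ms(), NULL),
               class = "coalgrow_parameter_error")
})

test_that("the star tip is uniform over tips", {
  set.seed(17)
  ms0 <- place_mutations(simulate_tree(5), 1)
  stars <- integer(3000)
  for (r in seq_along(stars)) {
    stars[r] <- grow_tree(ms0)$record$star_tip
  }
  tab <- tabulate(stars, 5)
  expect_gt(chisq.test(tab)$p.value, 1e-3)
})
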