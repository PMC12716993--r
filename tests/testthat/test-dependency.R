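# Minimal psi_calls stand-in for one replicate.
fake_calls <- function(levels, covs, condition = "WT", replicate = 1,
                       labels = "55", gene = "tRNA-Val-AAC-1") {
  df <- data.frame(ref_id = gene, pos = seq_along(levels) * 10L,
                   sprinzl_label = labels, compartment = "cyto",
                   level = levels, cov_treated = covs,
                   stringsAsFactors = FALSE)
  structure(list(calls = df, condition = condition, replicate = replicate),
            class = "psi_calls")
}

test_that("replicate levels average site-wise and zero-coverage replicates drop out", {
  s <- summarize_levels(list(fake_calls(0.8, 100), fake_calls(0.9, 120)))
  expect_equal(s$mean_level, 0.85)
  expect_equal(s$n_rep, 2L)

  s1 <- summarize_levels(fake_calls(0.7, 100))
  expect_equal(s1$mean_level, 0.7)

  # coverage-zero replicate contributes no level but records its coverage
  s0 <- summarize_levels(list(fake_calls(0.8, 100), fake_calls(0.0, 0)))
  expect_equal(s0$mean_level, 0.8)
  expect_equal(s0$coverages[[1]], c(100, 0))

  expect_error(summarize_levels(list(fake_calls(0.8, 100),
                                     fake_calls(0.9, 100, condition = "KO:X"))),
               class = "psimap_usage_error")
})

test_that("dependency requires knockout coverage in every replicate and a >0.20 drop", {
  wt <- summarize_levels(list(fake_calls(0.95, 200), fake_calls(0.95, 200)))
  ko <- summarize_levels(list(fake_calls(0.45, 100, condition = "KO:TRUB1"),
                              fake_calls(0.45, 120, condition = "KO:TRUB1")))
  d <- classify_dependency(wt, ko, "TRUB1")
  expect_equal(d$delta, 0.5)
  expect_true(d$eligible)
  expect_true(d$dependent)

  # one knockout replicate at coverage 19 -> ineligible, hence not dependent
  ko19 <- summarize_levels(list(fake_calls(0.45, 100, condition = "KO:TRUB1"),
                                fake_calls(0.45, 19, condition = "KO:TRUB1")))
  d19 <- classify_dependency(wt, ko19, "TRUB1")
  expect_false(d19$eligible)
  expect_false(d19$dependent)

  # a 0.05 drop is below threshold
  wt5 <- summarize_levels(fake_calls(0.50, 200))
  ko5 <- summarize_levels(fake_calls(0.45, 200, condition = "KO:TRUB1"))
  d5 <- classify_dependency(wt5, ko5, "TRUB1")
  expect_equal(d5$delta, 0.05)
  expect_false(d5$dependent)

  # decisions are invariant to replicate order
  ko_rev <- summarize_levels(list(fake_calls(0.45, 120, condition = "KO:TRUB1"),
                                  fake_calls(0.45, 100, condition = "KO:TRUB1")))
  expect_equal(classify_dependency(wt, ko_rev, "TRUB1")$dependent, d$dependent)

  # relative mode rescales the drop by the wild-type level
  dr <- classify_dependency(wt5, ko5, "TRUB1", mode = "relative")
  expect_equal(dr$delta, 0.1)
  expect_true(all(abs(d$delta) <= 1))
})

test_that("position table reports type-7 quartiles and 1.5 IQR whiskers", {
  reps <- fake_calls(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(100, 5))
  s <- summarize_levels(reps)
  v <- aggregate_views(s)
  pt <- v$position_table
  expect_equal(pt$n, 5L)
  expect_equal(pt$median, 0.3)
  expect_equal(pt$q1, 0.2)
  expect_equal(pt$q3, 0.4)
  expect_equal(pt$whisker_lo, 0.1)
  expect_equal(pt$whisker_hi, 0.5)

  # a single site collapses the box
  s1 <- summarize_levels(fake_calls(0.42, 100))
  pt1 <- aggregate_views(s1)$position_table
  expect_equal(pt1$q1, pt1$median)
  expect_equal(pt1$q3, pt1$median)

  # unlabeled sites group under "unassigned"
  s2 <- summarize_levels(fake_calls(0.6, 100, labels = NA))
  expect_equal(aggregate_views(s2)$position_table$sprinzl_label, "unassigned")
})

test_that("the dependency matrix mirrors shared-site redundancy", {
  # two synthases sharing position 55: each single knockout drops theta by 0.3
  # from 0.9, leaving residual modification, so both deltas sit below a full
  # wild-type stoichiometry but above the dependency threshold.
  wt <- summarize_levels(fake_calls(c(0.9, 0.9), c(200, 200),
                                    gene = "tRNA-Val-AAC-1"))
  ko_a <- summarize_levels(fake_calls(c(0.6, 0.9), c(200, 200),
                                      gene = "tRNA-Val-AAC-1",
                                      condition = "KO:TRUB1"))
  ko_b <- summarize_levels(fake_calls(c(0.9, 0.6), c(200, 200),
                                      gene = "tRNA-Val-AAC-1",
                                      condition = "KO:PUS10"))
  deps <- rbind(classify_dependency(wt, ko_a, "TRUB1"),
                classify_dependency(wt, ko_b, "PUS10"))
  m <- aggregate_views(wt, deps)$dependency_matrix
  expect_equal(dim(m), c(1L, 2L))
  expect_equal(unname(m["tRNA-Val-AAC-1", "TRUB1"]), 0.15)  # mean over the 2 sites
  expect_equal(unname(m["tRNA-Val-AAC-1", "PUS10"]), 0.15)
  expect_true(all(m < 0.9))   # residual modification: no delta reaches theta_WT
})
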