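# One-site harness: a single gene with a T at position 3, everything passing
# by default, so that each criterion can be failed in isolation.
call_one <- function(t_nC = 160, t_nT = 40, t_nA = 0, t_nG = 0,
                     c_nC = 0, c_nT = 200, c_nA = 0, c_nG = 0,
                     gene_id = "tRNA-Gly-GCC-1", global_fpr = 0.001,
                     thresholds = psi_thresholds()) {
  g <- trna_gene(gene_id, "AATAA")
  refs <- psimap:::new_ref_set(list(g))
  tr <- make_lib(site_row(gene_id, 3, nC = t_nC, nT = t_nT, nA = t_nA, nG = t_nG),
                 role = "treated")
  ct <- make_lib(site_row(gene_id, 3, nC = c_nC, nT = c_nT, nA = c_nA, nG = c_nG),
                 role = "control")
  fm <- fpr_model(stats::setNames(numeric(0), character(0)), global_fpr)
  call_psi(tr, ct, refs, fpr_model = fm, thresholds = thresholds,
           expressed = gene_id)$calls
}

test_that("a clean high-stoichiometry site is called", {
  row <- call_one()
  expect_true(row$called)
  expect_equal(row$level, 0.8)
  expect_equal(row$fail_reasons, "")
})

test_that("toggling exactly one criterion flips the call", {
  expect_false(call_one(t_nC = 39, t_nT = 10)$called)               # treated cov 49
  expect_false(call_one(c_nT = 49)$called)                          # control cov 49
  expect_false(call_one(c_nC = 3, c_nT = 147)$called)               # both arms of (2) fail
  expect_false(call_one(c_nA = 15, c_nG = 15, c_nT = 170)$called)   # T->R ratio 0.15
  expect_false(call_one(t_nC = 16, t_nT = 184)$called)              # level 0.08
  expect_false(call_one(t_nC = 24, t_nT = 176, global_fpr = 0.08)$called)  # q too large
})

test_that("the control-background criterion is an OR of its two arms", {
  # rate 0.0075 <= 0.01 passes even with 3 counts
  r1 <- call_one(c_nC = 3, c_nT = 397)
  expect_true(r1$flag_ctrl_conv)
  expect_true(r1$called)
  # rate 0.02 > 0.01 passes via counts <= 2
  r2 <- call_one(c_nC = 2, c_nT = 98)
  expect_true(r2$flag_ctrl_conv)
  expect_true(r2$called)
})

test_that("the level threshold is compartment specific", {
  # level 0.07: called for a mitochondrial gene, not for a cytosolic one
  mt <- call_one(t_nC = 14, t_nT = 186, gene_id = "mt-tRNA-Ser-GCT-1")
  cy <- call_one(t_nC = 14, t_nT = 186)
  expect_true(mt$called)
  expect_false(cy$called)
})

test_that("cytosolic calls require an expressed isodecoder", {
  g <- trna_gene("tRNA-Gly-GCC-1", "AATAA")
  refs <- psimap:::new_ref_set(list(g))
  tr <- make_lib(site_row("tRNA-Gly-GCC-1", 3, nC = 160, nT = 40), role = "treated")
  ct <- make_lib(site_row("tRNA-Gly-GCC-1", 3, nT = 200), role = "control")
  fm <- fpr_model(stats::setNames(numeric(0), character(0)), 0.001)
  res <- call_psi(tr, ct, refs, fpr_model = fm, expressed = character(0))
  expect_false(res$calls$called)
  expect_match(res$calls$fail_reasons, "expressed")
})

test_that("expressed isodecoders follow the median-coverage rule", {
  seqs <- c(hi = strrep("A", 9), zero = strrep("A", 9), mixed = strrep("A", 9))
  refs <- psimap:::new_ref_set(list(trna_gene("hi", seqs[["hi"]]),
                                    trna_gene("zero", seqs[["zero"]]),
                                    trna_gene("mixed", seqs[["mixed"]])))
  rows <- rbind(
    do.call(rbind, lapply(1:9, function(p) site_row("hi", p, ref_base = "A", nA = 60))),
    do.call(rbind, lapply(1:4, function(p) site_row("mixed", p, ref_base = "A", nA = 100)))
  )
  ct <- make_lib(rows, role = "control")
  got <- expressed_isodecoders(ct, refs, min_median_cov = 50)
  expect_equal(got, "hi")   # 9 positions: 'mixed' has median 0 (5 of 9 uncovered)
})

test_that("calls are invariant under permutation of the candidate order", {
  sim <- simulate_experiment(sim_config(seed = 13, n_genes = 10, replicates = 1,
                                        ko_drop = c()))
  tr <- sim$libraries[["WT_rep1_treated"]]
  ct <- sim$libraries[["WT_rep1_control"]]
  set.seed(1)
  perm <- sample(nrow(tr$sites))
  tr2 <- library_counts(tr$library_id, tr$role, tr$condition, tr$replicate,
                        tr$sites[perm, ])
  res1 <- call_psi(tr, ct, sim$refs)
  res2 <- call_psi(tr2, ct, sim$refs)
  expect_identical(res1$calls, res2$calls)
})

test_that("role mismatches are usage errors", {
  g <- trna_gene("g1", "AATAA")
  refs <- psimap:::new_ref_set(list(g))
  tr <- make_lib(site_row("g1", 3, nC = 10, nT = 40), role = "treated")
  expect_error(call_psi(tr, tr, refs), class = "psimap_usage_error")
})

test_that("q-values dominate p-values and flags reconstruct the verdict", {
  sim <- simulate_experiment(sim_config(seed = 17, n_genes = 15, replicates = 1,
                                        ko_drop = c()))
  res <- call_psi(sim$libraries[["WT_rep1_treated"]],
                  sim$libraries[["WT_rep1_control"]], sim$refs)
  cc <- res$calls
  expect_true(all(cc$q >= cc$p))
  expect_equal(cc$called,
               cc$flag_cov & cc$flag_ctrl_conv & cc$flag_ctrl_t2r &
                 cc$flag_level & cc$flag_q & cc$expressed)
  expect_true(all(cc$level >= 0 & cc$level <= 1))
})
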