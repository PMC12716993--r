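# Precursor fixture: 10-nt leader, exon 11..50, 20-nt intron 51..70,
# exon 71..110, 10-nt trailer 111..120.
make_pre_fixture <- function() {
  set.seed(19)
  mature_body <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                       collapse = "")
  leader <- paste(rep("G", 10), collapse = "")
  intron <- paste(rep("C", 20), collapse = "")
  trailer <- paste(rep("G", 10), collapse = "")
  seqfull <- paste0(leader, substr(mature_body, 1, 40), intron,
                    substr(mature_body, 41, 80), trailer)
  mature <- trna_gene("tRNA-Arg-TCT-1", paste0(mature_body, "CCA"),
                      cca_appended = TRUE)
  pre <- pre_trna_gene("pre-tRNA-Arg-TCT-1", seqfull,
                       leader = c(1L, 10L), trailer = c(111L, 120L),
                       introns = list(c(51L, 70L)),
                       mature_gene_id = "tRNA-Arg-TCT-1",
                       mature_sequence = mature$sequence)
  list(pre = pre, mature = mature)
}

test_that("reads are kept iff they overlap leader, intron or trailer", {
  fx <- make_pre_fixture()
  reads <- data.frame(
    read_id = c("leader_only", "junction_1nt", "exon_only", "trailer_only"),
    ref_id = fx$pre$gene_id,
    start = c(2L, 31L, 21L, 112L),
    strand = "sense",
    bases = c(strrep("A", 8),   # 2..9 inside the leader
              strrep("A", 21),  # 31..51 overlaps the intron by exactly 1 nt
              strrep("A", 20),  # 21..40 fully exonic
              strrep("A", 5)),  # inside the trailer
    stringsAsFactors = FALSE
  )
  expect_equal(classify_pre_read(reads, fx$pre),
               c("keep", "keep", "discard", "keep"))

  out <- data.frame(read_id = "r", ref_id = fx$pre$gene_id, start = 118L,
                    strand = "sense", bases = "AAAAA", stringsAsFactors = FALSE)
  expect_error(classify_pre_read(out, fx$pre), class = "psimap_alignment_error")
})

test_that("precursor positions map to mature coordinates through leader and introns", {
  fx <- make_pre_fixture()
  expect_equal(map_pre_to_mature(fx$pre, 11L), 1L)       # first exon base
  expect_equal(map_pre_to_mature(fx$pre, 71L), 41L)      # past a 20-nt intron
  expect_true(is.na(map_pre_to_mature(fx$pre, 60L)))     # inside the intron
  expect_true(is.na(map_pre_to_mature(fx$pre, 5L)))      # leader
  expect_true(is.na(map_pre_to_mature(fx$pre, 115L)))    # trailer
  expect_error(map_pre_to_mature(fx$pre, 0L), class = "psimap_domain_error")

  # exonic mapping is a bijection onto mature positions minus CCA
  exonic <- which(!psimap:::pre_region_mask(fx$pre))
  m <- map_pre_to_mature(fx$pre, exonic)
  expect_equal(sort(m), 1:80)
  expect_equal(anyDuplicated(m), 0L)
})

test_that("pre-tRNA annotation loads from BED and enforces reconciliation", {
  fx <- make_pre_fixture()
  mature_set <- psimap:::new_ref_set(list(fx$mature))

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">pre-tRNA-Arg-TCT-1", fx$pre$sequence), fa)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("pre-tRNA-Arg-TCT-1\t0\t10\tleader\t0\t+",
               "pre-tRNA-Arg-TCT-1\t50\t70\tintron\t0\t+",
               "pre-tRNA-Arg-TCT-1\t110\t120\ttrailer\t0\t+"), bed)
  pres <- load_pre_annotation(bed, fa, mature_set)
  expect_length(pres, 1L)
  expect_equal(pres[[1]]$introns[[1]], c(51L, 70L))

  # intron-free precursor is accepted
  fa2 <- withr::local_tempfile(fileext = ".fa")
  body <- sub("CCA$", "", fx$mature$sequence)
  writeLines(c(">pre-tRNA-Arg-TCT-1",
               paste0(strrep("G", 10), body, strrep("G", 10))), fa2)
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("pre-tRNA-Arg-TCT-1\t0\t10\tleader\t0\t+",
               "pre-tRNA-Arg-TCT-1\t90\t100\ttrailer\t0\t+"), bed2)
  pres2 <- load_pre_annotation(bed2, fa2, mature_set)
  expect_length(pres2[[1]]$introns, 0L)

  # exon concatenation that does not reconcile with the mature sequence
  bed3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("pre-tRNA-Arg-TCT-1\t0\t12\tleader\t0\t+",
               "pre-tRNA-Arg-TCT-1\t50\t70\tintron\t0\t+",
               "pre-tRNA-Arg-TCT-1\t110\t120\ttrailer\t0\t+"), bed3)
  expect_error(load_pre_annotation(bed3, fa, mature_set),
               class = "psimap_consistency_error")

  # overlapping intervals
  bed4 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("pre-tRNA-Arg-TCT-1\t0\t55\tleader\t0\t+",
               "pre-tRNA-Arg-TCT-1\t50\t70\tintron\t0\t+",
               "pre-tRNA-Arg-TCT-1\t110\t120\ttrailer\t0\t+"), bed4)
  expect_error(load_pre_annotation(bed4, fa, mature_set),
               class = "psimap_format_error")

  # unknown mature link
  expect_error(load_pre_annotation(bed, fa, psimap:::new_ref_set(list())),
               class = "psimap_lookup_error")
})

test_that("filtering then piling equals piling then masking exon-only reads", {
  fx <- make_pre_fixture()
  refs <- psimap:::new_ref_set(list(trna_gene(fx$pre$gene_id, fx$pre$sequence)))
  set.seed(23)
  reads <- data.frame(
    read_id = sprintf("r%d", 1:300), ref_id = fx$pre$gene_id,
    start = sample.int(120 - 15 + 1, 300, replace = TRUE), strand = "sense",
    bases = NA_character_, stringsAsFactors = FALSE
  )
  chars <- strsplit(fx$pre$sequence, "", fixed = TRUE)[[1]]
  reads$bases <- vapply(reads$start, function(s) {
    paste(chars[s:(s + 14)], collapse = "")
  }, character(1))

  verdict <- classify_pre_read(reads, fx$pre)
  a <- pileup(reads[verdict == "keep", ], refs)$sites
  b <- pileup(reads[classify_pre_read(reads, fx$pre) != "discard", ], refs)$sites
  expect_identical(a, b)
  # every read falls in exactly one class
  expect_true(all(verdict %in% c("keep", "discard")))
  expect_length(verdict, nrow(reads))
})

test_that("stage-specific planted stoichiometries are recovered from kept reads", {
  fx <- make_pre_fixture()
  cfg <- sim_config(seed = 31, pre_read_length = 30, pre_depth = 3000,
                    mature_depth = 500)
  # anticodon-arm site modified at both stages, T-loop-adjacent site mature only
  pre_t1 <- 25L   # exonic, near the intron-proximal exon
  chars <- strsplit(fx$pre$sequence, "", fixed = TRUE)[[1]]
  chars[c(25, 80)] <- "T"
  fx$pre$sequence <- paste(chars, collapse = "")
  truth <- data.frame(pre_pos = c(25L, 80L), theta_pre = c(0.8, 0.0),
                      theta_mature = c(0.8, 0.8))
  pools <- simulate_pre_reads(cfg, fx$pre, truth, fx$mature)
  kept <- pools$pre_treated[classify_pre_read(pools$pre_treated, fx$pre) == "keep", ]
  refs <- psimap:::new_ref_set(list(trna_gene(fx$pre$gene_id, fx$pre$sequence)))
  st <- pileup(kept, refs)$sites
  r25 <- site_rates(st[st$pos == 25L, ])
  r80 <- site_rates(st[st$pos == 80L, ])
  expect_gt(r25$coverage, 50)
  # planted 0.8 * gamma at the pre-installed site, background at the other
  expect_lt(abs(r25$t2c_rate - 0.8 * cfg$gamma),
            3 * sqrt(0.8 * 0.2 / r25$coverage) + 0.01)
  expect_lt(r80$t2c_rate, 0.05)

  # degenerate configurations
  expect_error(simulate_pre_reads(sim_config(seed = 1, pre_read_length = 500),
                                  fx$pre, truth, fx$mature),
               class = "psimap_config_error")
  empty <- simulate_pre_reads(sim_config(seed = 1, pre_depth = 0,
                                         mature_depth = 0, pre_read_length = 30),
                              fx$pre, truth, fx$mature)
  expect_equal(nrow(empty$pre_treated), 0L)
})

test_that("pre-vs-mature comparison assigns the verbal classes by level ratio", {
  pre_calls <- data.frame(
    ref_id = "pre-tRNA-Arg-TCT-1", pos = c(25L, 80L), level = c(0.85, 0.0),
    cov_treated = c(150L, 150L), called = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  mature_calls <- data.frame(
    ref_id = "tRNA-Arg-TCT-1", pos = c(15L, 50L), sprinzl_label = c("35", "55"),
    level = c(0.9, 0.8), called = TRUE, stringsAsFactors = FALSE
  )
  fx <- make_pre_fixture()
  cmp <- compare_pre_mature(pre_calls, mature_calls, list(fx$pre), min_cov = 20)
  expect_equal(nrow(cmp), 2L)
  # mature 15 -> pre 25 (leader 10): 0.85 >= 0.8 * 0.9 and called
  expect_equal(cmp$class[cmp$mature_pos == 15], "pre_installed")
  # mature 50 -> pre 80 (leader + intron): covered at level 0 -> mature specific
  expect_equal(cmp$class[cmp$mature_pos == 50], "mature_specific")
  expect_equal(cmp$pre_pos, c(25L, 80L))
  expect_equal(cmp$delta, c(0.9 - 0.85, 0.8 - 0.0))

  # low precursor coverage reports separately as uncovered
  pre_calls$cov_treated <- c(10L, 10L)
  cmp2 <- compare_pre_mature(pre_calls, mature_calls, list(fx$pre), min_cov = 20)
  expect_true(all(cmp2$class == "uncovered"))
})
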