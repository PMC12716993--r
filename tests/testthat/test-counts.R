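test_that("pileup counts sense reads base by base", {
  refs <- psimap:::new_ref_set(list(trna_gene("g1", "AATTTTGGCC")))
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    ref_id = "g1",
    start = c(3L, 3L, 3L, 3L),
    strand = c("sense", "sense", "sense", "antisense"),
    bases = c("CC", "CC", "CT", "CC"),
    stringsAsFactors = FALSE
  )
  lib <- pileup(reads, refs, role = "treated")
  st <- lib$sites
  expect_equal(st$nC[st$pos == 3], 3L)        # antisense read contributes nothing
  expect_equal(st$nT[st$pos == 3], 0L)
  expect_equal(st$nC[st$pos == 4], 2L)
  expect_equal(st$nT[st$pos == 4], 1L)
})

test_that("N contributes to no counter and '-' only increments deletions", {
  refs <- psimap:::new_ref_set(list(trna_gene("g1", "ACGTACGT")))
  reads <- data.frame(read_id = c("r1", "r2"), ref_id = "g1", start = 1L,
                      strand = "sense", bases = c("AN-T", "ACGT"),
                      stringsAsFactors = FALSE)
  st <- pileup(reads, refs)$sites
  expect_equal(st$nC[st$pos == 2], 1L)
  expect_equal(st$nA[st$pos == 2] + st$nG[st$pos == 2] + st$nT[st$pos == 2], 0L)
  expect_equal(st$nDel[st$pos == 3], 1L)
  expect_equal(st$nG[st$pos == 3], 1L)
  expect_equal(st$nA[st$pos == 2] + st$nC[st$pos == 2], 1L)  # N dropped entirely
})

test_that("pileup equals the brute-force counting oracle on a random fixture", {
  set.seed(5)
  seqs <- c(g1 = random_string <- paste(sample(c("A", "C", "G", "T"), 60,
                                               replace = TRUE), collapse = ""),
            g2 = paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE),
                       collapse = ""))
  refs <- psimap:::new_ref_set(list(trna_gene("g1", seqs[["g1"]]),
                                    trna_gene("g2", seqs[["g2"]])))
  reads <- random_reads(200, seqs, read_len = 8, seed = 9)
  got <- pileup(reads, refs)$sites
  want <- naive_pileup(reads, seqs)
  expect_equal(got, want)
})

test_that("reads exceeding reference bounds are an alignment error", {
  refs <- psimap:::new_ref_set(list(trna_gene("g1", "ACGT")))
  reads <- data.frame(read_id = "r1", ref_id = "g1", start = 3L,
                      strand = "sense", bases = "ACG", stringsAsFactors = FALSE)
  expect_error(pileup(reads, refs), class = "psimap_alignment_error")
  reads$ref_id <- "nope"
  expect_error(pileup(reads, refs), class = "psimap_alignment_error")
})

test_that("counts TSV round-trips bit-exactly and rejects malformed input", {
  sim <- simulate_experiment(sim_config(seed = 3, n_genes = 4, replicates = 1,
                                        ko_drop = c(), n_spikeins = 1))
  lib <- sim$libraries[["WT_rep1_treated"]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(lib, path)
  back <- read_counts_tsv(path)
  expect_identical(back$sites, lib$sites)
  expect_identical(back$library_id, lib$library_id)
  expect_identical(back$role, lib$role)
  expect_identical(back$replicate, lib$replicate)

  # 1-based output convention: a zero position is rejected
  lines <- readLines(path)
  body_at <- grep("^#", lines, invert = TRUE)[2]
  lines[body_at] <- sub("\t[0-9]+\t", "\t0\t", lines[body_at])
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(read_counts_tsv(bad), class = "psimap_format_error")

  # missing role metadata header
  lines2 <- readLines(path)
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines2[!grepl("^#role=", lines2)], bad2)
  expect_error(read_counts_tsv(bad2), class = "psimap_format_error")
})

test_that("read-record TSV round-trips through the 0-based interchange", {
  reads <- data.frame(read_id = c("a", "b"), ref_id = "g1", start = c(1L, 7L),
                      strand = c("sense", "antisense"), bases = c("ACGT", "TTTT"),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_read_records_tsv(reads, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(tab$start_0based, c(0L, 6L))
  expect_identical(read_read_records_tsv(path), reads)
})

test_that("site_rates computes bounded conversion metrics at T positions only", {
  st <- rbind(site_row("g", 1, nT = 90, nC = 10),
              site_row("g", 2, nA = 5, nG = 5),
              site_row("g", 3, nT = 98, nC = 2))
  r <- site_rates(st)
  expect_equal(r$t2c_rate, c(0.10, 0, 2 / 100))
  expect_equal(r$t2r_ratio, c(0, 1.0, 0))
  expect_equal(r$coverage, c(100, 10, 100))
  expect_true(all(r$t2c_rate >= 0 & r$t2c_rate <= 1))

  # zero-coverage convention
  r0 <- site_rates(site_row("g", 4))
  expect_equal(unlist(r0), c(t2c_rate = 0, t2r_ratio = 0, coverage = 0))

  expect_error(site_rates(site_row("g", 5, ref_base = "C", nC = 10)),
               class = "psimap_domain_error")

  # monotone in nC at fixed nC + nT
  rates <- vapply(0:50, function(k) {
    site_rates(site_row("g", 1, nC = k, nT = 50 - k))$t2c_rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})
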