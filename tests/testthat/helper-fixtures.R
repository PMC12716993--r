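# Fixture builders and independent oracles shared across the test files.

# A deterministic cloverleaf gene built from the simulator's assembler
# (labels depend only on the structure, so the random sequence is harmless).
make_clover_gene <- function(dloop_len = 8, long_arm = FALSE, seed = 42,
                             anticodon = "AAC", id = "tRNA-Test-AAC-1") {
  set.seed(seed)
  g <- psimap:::build_sim_gene(long_arm, dloop_len, anticodon)
  trna_gene(id, g$sequence, structure = g$structure, cca_appended = TRUE,
            type = "trna")
}

# One-gene reference set with T sites at chosen positions and chosen flanks.
make_flat_gene <- function(id = "tRNA-Test-AAA-1", len = 40, t_pos = integer(0),
                           flank = list()) {
  chars <- rep("A", len)
  chars[t_pos] <- "T"
  for (p in names(flank)) {
    p <- as.integer(p)
    chars[c(p - 1L, p + 1L)] <- flank[[as.character(p)]]
  }
  trna_gene(id, paste(chars, collapse = ""), type = "trna")
}

site_row <- function(ref_id, pos, ref_base = "T", nA = 0, nC = 0, nG = 0,
                     nT = 0, nDel = 0) {
  data.frame(ref_id = ref_id, pos = pos, ref_base = ref_base, nA = nA,
             nC = nC, nG = nG, nT = nT, nDel = nDel, stringsAsFactors = FALSE)
}

make_lib <- function(sites, role = "treated", id = paste0(role, "-lib"),
                     condition = "WT", replicate = 1) {
  library_counts(id, role, condition, replicate, sites)
}

# Brute-force pileup oracle: walk every read base by base.
naive_pileup <- function(reads, seqs) {
  acc <- list()
  for (i in seq_len(nrow(reads))) {
    if (reads$strand[i] != "sense") next
    bases <- strsplit(reads$bases[i], "", fixed = TRUE)[[1]]
    for (j in seq_along(bases)) {
      pos <- reads$start[i] + j - 1L
      key <- paste(reads$ref_id[i], pos)
      if (is.null(acc[[key]])) {
        acc[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L, del = 0L)
      }
      b <- bases[j]
      if (b %in% c("A", "C", "G", "T")) acc[[key]][b] <- acc[[key]][b] + 1L
      if (b == "-") acc[[key]]["del"] <- acc[[key]]["del"] + 1L
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(key) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    pos <- as.integer(parts[2])
    data.frame(ref_id = parts[1], pos = pos,
               ref_base = substr(seqs[[parts[1]]], pos, pos),
               nA = acc[[key]][["A"]], nC = acc[[key]][["C"]],
               nG = acc[[key]][["G"]], nT = acc[[key]][["T"]],
               nDel = acc[[key]][["del"]], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$ref_id, out$pos), ]
  rownames(out) <- NULL
  out
}

# Exact binomial upper-tail oracle via the log-scale term sum.
binom_tail_oracle <- function(k, n, p) {
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Brute-force BH step-up: q_i = min over j with p_(j) >= p_i of m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- q
  out
}

random_reads <- function(n, seqs, read_len = 8, seed = 1) {
  set.seed(seed)
  ids <- sample(names(seqs), n, replace = TRUE)
  starts <- vapply(ids, function(id) {
    sample.int(nchar(seqs[[id]]) - read_len + 1L, 1L)
  }, integer(1))
  bases <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T", "N", "-"), read_len, replace = TRUE,
                 prob = c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05)), collapse = "")
  }, character(1))
  data.frame(read_id = sprintf("r%d", seq_len(n)), ref_id = ids,
             start = unname(starts),
             strand = sample(c("sense", "antisense"), n, replace = TRUE,
                             prob = c(0.9, 0.1)),
             bases = bases, stringsAsFactors = FALSE)
}
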