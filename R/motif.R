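# Sequence-motif machinery around called sites: fixed windows, position
# frequency matrices, IUPAC consensus strings, and Jensen-Shannon
# differential motifs (columnwise, base-2, as in differential-logo plots).

IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", T = "U",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' Extract fixed sequence windows around called sites
#'
#' Windows span offsets `[-u, +d]` with the site at offset 0 (which must be a
#' reference T). Windows crossing a gene end are skipped, not padded; sites
#' whose centre is not T are skipped with a warning.
#'
#' @param calls A `psi_calls` or a data frame with `ref_id`, `pos` (and
#'   optionally `called`).
#' @param refs A `ref_set`.
#' @param u,d Upstream/downstream extents (defaults -5/+8, wide enough for an
#'   11-position motif).
#' @param only_called Restrict to called sites when a `called` column exists.
#' @return Data frame of class `"motif_windows"` with `ref_id`, `pos`,
#'   `bases`; extents kept in attributes `u`, `d`.
#' @export
extract_windows <- function(calls, refs, u = 5L, d = 8L, only_called = TRUE) {
  if (inherits(calls, "psi_calls")) calls <- calls$calls
  if (only_called && "called" %in% names(calls)) {
    calls <- calls[calls$called, , drop = FALSE]
  }
  if (u < 0L || d < 0L) psimap_abort("u and d must be >= 0", "psimap_domain_error")
  seqs <- ref_sequences(refs)
  lo <- calls$pos - u
  hi <- calls$pos + d
  inside <- lo >= 1L & hi <= nchar(seqs[calls$ref_id])
  calls <- calls[inside, , drop = FALSE]
  bases <- substring(seqs[calls$ref_id], calls$pos - u, calls$pos + d)
  centred <- substring(bases, u + 1L, u + 1L) == "T"
  if (any(!centred)) {
    warning(sprintf("skipping %d site(s) whose centre base is not T", sum(!centred)))
  }
  out <- data.frame(ref_id = calls$ref_id, pos = calls$pos,
                    bases = bases, stringsAsFactors = FALSE)[centred, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, u = u, d = d, class = c("motif_windows", "data.frame"))
}

#' Build a position frequency matrix from motif windows
#'
#' @param windows A `motif_windows` (or data frame with a `bases` column of
#'   equal-length strings).
#' @param pseudocount Added per base per column before normalization.
#' @return An object of class `"pfm"`: probability matrix (rows A,C,G,T;
#'   columns named by offset), `offsets`, `n`, `pseudocount`.
#' @export
build_pfm <- function(windows, pseudocount = 0.01) {
  if (nrow(windows) == 0L) {
    psimap_abort("cannot build a PFM from zero windows", "psimap_usage_error")
  }
  w <- unique(nchar(windows$bases))
  if (length(w) != 1L) {
    psimap_abort("windows must have equal length", "psimap_usage_error")
  }
  u <- attr(windows, "u") %||% 0L
  offsets <- seq_len(w) - 1L - u
  mat <- matrix(unlist(strsplit(windows$bases, "", fixed = TRUE)),
                nrow = nrow(windows), byrow = TRUE)
  counts <- apply(mat, 2L, function(col) {
    table(factor(col, levels = DNA_BASES))
  })
  n <- nrow(windows)
  prob <- (counts + pseudocount) / (n + 4 * pseudocount)
  dimnames(prob) <- list(DNA_BASES, offsets)
  structure(list(prob = prob, offsets = offsets, n = n,
                 pseudocount = pseudocount), class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d sequence(s), offsets %d..%d\n", x$n,
              min(x$offsets), max(x$offsets)))
  print(round(x$prob, 3))
  invisible(x)
}

#' IUPAC consensus string of a position frequency matrix
#'
#' Per offset, the smallest IUPAC code covering all bases at frequency at
#' least `min_freq`; the centre offset is rendered as the Greek letter Psi
#' and the output uses the RNA alphabet (U for T).
#'
#' @param pfm A [build_pfm()] result.
#' @param min_freq Inclusion frequency for a base (default 0.15).
#' @return Single consensus string.
#' @export
iupac_consensus <- function(pfm, min_freq = 0.15) {
  codes <- vapply(seq_along(pfm$offsets), function(j) {
    p <- pfm$prob[, j]
    bases <- DNA_BASES[p >= min_freq]
    if (!length(bases)) bases <- DNA_BASES[which.max(p)]
    IUPAC_FROM_SET[[paste(sort(bases), collapse = "")]]
  }, character(1))
  codes[pfm$offsets == 0L] <- "Ψ"
  paste(codes, collapse = "")
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Columnwise Jensen-Shannon differential motif
#'
#' Per offset, the Jensen-Shannon divergence (base 2, bounded by 1 bit)
#' between the two base distributions, plus per-base contribution vectors:
#' the signed base differences scaled to stack to the column's JSD, as drawn
#' in differential sequence logos.
#'
#' @param pfm1,pfm2 Two [build_pfm()] results over identical offsets.
#' @return An object of class `"diff_motif"`: `offsets`, `jsd` (bits per
#'   offset) and a 4 x width `contrib` matrix.
#' @export
diff_motif <- function(pfm1, pfm2) {
  if (!identical(pfm1$offsets, pfm2$offsets)) {
    psimap_abort("PFMs must share identical offsets", "psimap_usage_error")
  }
  W <- length(pfm1$offsets)
  jsd <- numeric(W)
  contrib <- matrix(0, nrow = 4L, ncol = W, dimnames = list(DNA_BASES, pfm1$offsets))
  for (j in seq_len(W)) {
    P <- pfm1$prob[, j]
    Q <- pfm2$prob[, j]
    M <- (P + Q) / 2
    jsd[j] <- entropy2(M) - (entropy2(P) + entropy2(Q)) / 2
    jsd[j] <- min(1, max(0, jsd[j]))   # clip fp noise at the bounds
    d <- P - Q
    s <- sum(abs(d))
    if (s > 0) contrib[, j] <- d / s * jsd[j]
  }
  structure(list(offsets = pfm1$offsets, jsd = jsd, contrib = contrib),
            class = "diff_motif")
}

#' @export
print.diff_motif <- function(x, ...) {
  cat(sprintf("<diff_motif> offsets %d..%d, total JSD %.3f bits (max %.3f at offset %d)\n",
              min(x$offsets), max(x$offsets), sum(x$jsd), max(x$jsd),
              x$offsets[which.max(x$jsd)]))
  invisible(x)
}

#' Write a PFM as TSV (offset, pA, pC, pG, pT)
#' @param pfm A `pfm`.
#' @param path Output path.
#' @param extra_headers Optional `#key=value` headers.
#' @export
write_pfm_tsv <- function(pfm, path, extra_headers = NULL) {
  df <- data.frame(offset = pfm$offsets, pA = pfm$prob["A", ],
                   pC = pfm$prob["C", ], pG = pfm$prob["G", ],
                   pT = pfm$prob["T", ])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(extra_headers)) {
    writeLines(sprintf("#%s=%s", names(extra_headers), extra_headers), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
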