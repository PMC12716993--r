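# Precursor tRNA analysis: read filtering (keep only reads proving precursor
# origin by overlapping leader/intron/trailer), precursor -> mature
# coordinate mapping, and the pre-vs-mature modification-level comparison.

#' Classify reads as precursor-derived or not
#'
#' A read is kept iff its interval overlaps at least one nucleotide of the
#' 5'-leader, an intron, or the 3'-trailer; reads that lie entirely within
#' exons are indistinguishable from mature-tRNA reads and are discarded.
#'
#' @param reads Read-record data frame aligned to the precursor reference.
#' @param pre A [pre_trna_gene()].
#' @return Character vector, `"keep"` or `"discard"` per read.
#' @export
classify_pre_read <- function(reads, pre) {
  if (nrow(reads) == 0L) return(character(0))
  n <- nchar(pre$sequence)
  end <- reads$start + nchar(reads$bases) - 1L
  if (any(reads$start < 1L) || any(end > n)) {
    psimap_abort("read outside the precursor reference", "psimap_alignment_error")
  }
  keep <- logical(nrow(reads))
  for (iv in c(list(pre$leader, pre$trailer), pre$introns)) {
    keep <- keep | (reads$start <= iv[2] & end >= iv[1])
  }
  ifelse(keep, "keep", "discard")
}

#' Map precursor positions to mature coordinates
#'
#' Leader, intron and trailer positions map to `NA`; an exonic position maps
#' to its mature position (1-based) by subtracting the leader and any
#' upstream introns. Composing with the mature gene's Sprinzl map yields the
#' canonical label.
#'
#' @param pre A `pre_trna_gene`.
#' @param pre_pos Integer vector of precursor positions (1-based).
#' @return Integer vector of mature positions; `NA` for precursor-only
#'   positions.
#' @export
map_pre_to_mature <- function(pre, pre_pos) {
  n <- nchar(pre$sequence)
  if (any(pre_pos < 1L | pre_pos > n)) {
    psimap_abort("pre_pos out of bounds", "psimap_domain_error")
  }
  mask <- pre_region_mask(pre)
  leader_len <- pre$leader[2] - pre$leader[1] + 1L
  out <- integer(length(pre_pos))
  for (i in seq_along(pre_pos)) {
    p <- pre_pos[i]
    if (mask[p]) {
      out[i] <- NA_integer_
    } else {
      up <- sum(vapply(pre$introns, function(iv) {
        if (iv[2] < p) iv[2] - iv[1] + 1L else 0L
      }, integer(1)))
      out[i] <- p - leader_len - up
    }
  }
  out
}

#' Compare pre-tRNA and mature modification levels
#'
#' For every called mature site, looks up the corresponding precursor
#' position (via the inverse exon mapping) in the precursor call table and
#' classifies the site: `pre_installed` when the precursor level reaches
#' `pre_installed_frac` of the mature level and the precursor site is itself
#' called; `mature_specific` when the covered precursor level falls below
#' `mature_specific_frac` of the mature level; `partial` otherwise;
#' `uncovered` when the precursor position is missing or below `min_cov`.
#'
#' @param pre_calls `psi_calls` (or its data frame) computed on precursor
#'   references from kept reads only.
#' @param mature_calls `psi_calls` (or data frame) on the mature references.
#' @param pre_genes A `pre_ref_set` (or list of `pre_trna_gene`) linking
#'   precursor to mature genes.
#' @param min_cov Minimum precursor treated coverage (default 20).
#' @param pre_installed_frac,mature_specific_frac Class boundaries (defaults
#'   0.8 and 0.1 of the mature level).
#' @return Data frame of class `"pre_mature_delta"`.
#' @export
compare_pre_mature <- function(pre_calls, mature_calls, pre_genes,
                               min_cov = 20, pre_installed_frac = 0.8,
                               mature_specific_frac = 0.1) {
  if (inherits(pre_calls, "psi_calls")) pre_calls <- pre_calls$calls
  if (inherits(mature_calls, "psi_calls")) mature_calls <- mature_calls$calls
  mature_calls <- mature_calls[mature_calls$called, , drop = FALSE]

  rows <- list()
  for (pre in pre_genes) {
    mm <- mature_calls[mature_calls$ref_id == pre$mature_gene_id, , drop = FALSE]
    if (!nrow(mm)) next
    exonic <- which(!pre_region_mask(pre))
    m_of_p <- map_pre_to_mature(pre, exonic)
    p_of_m <- stats::setNames(exonic, m_of_p)
    pc <- pre_calls[pre_calls$ref_id == pre$gene_id, , drop = FALSE]
    for (i in seq_len(nrow(mm))) {
      mpos <- mm$pos[i]
      ppos <- unname(p_of_m[as.character(mpos)])
      pre_level <- NA_real_
      pre_cov <- 0L
      pre_called <- FALSE
      if (!is.na(ppos)) {
        j <- which(pc$pos == ppos)
        if (length(j) == 1L) {
          pre_level <- pc$level[j]
          pre_cov <- pc$cov_treated[j]
          pre_called <- pc$called[j]
        }
      }
      cls <- if (is.na(ppos) || pre_cov < min_cov) {
        "uncovered"
      } else if (pre_called && pre_level >= pre_installed_frac * mm$level[i]) {
        "pre_installed"
      } else if (pre_level < mature_specific_frac * mm$level[i]) {
        "mature_specific"
      } else {
        "partial"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = pre$mature_gene_id, mature_pos = mpos,
        sprinzl_label = mm$sprinzl_label[i], pre_gene_id = pre$gene_id,
        pre_pos = if (is.na(ppos)) NA_integer_ else ppos,
        pre_level = pre_level, pre_cov = pre_cov,
        mature_level = mm$level[i],
        delta = mm$level[i] - pre_level, class = cls,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  class(out) <- c("pre_mature_delta", "data.frame")
  out
}
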