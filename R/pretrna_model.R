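# Precursor tRNA gene models: full transcript (5'-leader + exons + optional
# intron + 3'-trailer, no CCA) with intervals locating the precursor-only
# segments, linked to the mature reference.

#' Construct a pre-tRNA gene model
#'
#' Intervals are 1-based inclusive `c(start, end)` on the full precursor
#' sequence. The leader starts at position 1 and the trailer ends at the last
#' position; leader, introns and trailer are pairwise disjoint. When
#' `mature_sequence` is supplied, the concatenated exonic segments must equal
#' the mature sequence minus its 3'-CCA.
#'
#' @param gene_id Precursor identifier (convention: `"pre-"` + mature id).
#' @param sequence Full precursor DNA sequence.
#' @param leader,trailer Intervals `c(start, end)`.
#' @param introns List of intervals (possibly empty; intron-free precursors
#'   are the majority).
#' @param mature_gene_id Identifier of the linked mature gene.
#' @param mature_sequence Optional mature sequence (with or without CCA) used
#'   to verify exon reconciliation.
#' @return An object of class `"pre_trna_gene"`.
#' @export
pre_trna_gene <- function(gene_id, sequence, leader, trailer, introns = list(),
                          mature_gene_id, mature_sequence = NULL) {
  n <- nchar(sequence)
  ivs <- c(list(leader = leader, trailer = trailer),
           stats::setNames(introns, rep("intron", length(introns))))
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    if (length(iv) != 2L || iv[1] < 1L || iv[2] > n || iv[1] > iv[2]) {
      psimap_abort(sprintf("pre-tRNA '%s': %s interval out of bounds", gene_id, nm),
                   "psimap_format_error")
    }
  }
  if (leader[1] != 1L) {
    psimap_abort(sprintf("pre-tRNA '%s': leader must start at position 1", gene_id),
                 "psimap_format_error")
  }
  if (trailer[2] != n) {
    psimap_abort(sprintf("pre-tRNA '%s': trailer must end at the sequence end", gene_id),
                 "psimap_format_error")
  }
  cover <- unlist(lapply(ivs, function(iv) seq(iv[1], iv[2])))
  if (anyDuplicated(cover)) {
    psimap_abort(sprintf("pre-tRNA '%s': overlapping intervals", gene_id),
                 "psimap_format_error")
  }
  obj <- structure(
    list(gene_id = gene_id, sequence = sequence,
         leader = as.integer(leader), trailer = as.integer(trailer),
         introns = lapply(introns, as.integer),
         mature_gene_id = mature_gene_id),
    class = "pre_trna_gene"
  )
  if (!is.null(mature_sequence)) {
    mat <- sub("CCA$", "", mature_sequence)
    exons <- paste(strsplit(sequence, "", fixed = TRUE)[[1]][!pre_region_mask(obj)],
                   collapse = "")
    if (exons != mat) {
      psimap_abort(sprintf("pre-tRNA '%s': exon concatenation does not reconcile with mature '%s'",
                           gene_id, mature_gene_id), "psimap_consistency_error")
    }
  }
  obj
}

#' @export
print.pre_trna_gene <- function(x, ...) {
  cat(sprintf("<pre_trna_gene> %s -> %s (%d nt, leader %d, %d intron(s), trailer %d)\n",
              x$gene_id, x$mature_gene_id, nchar(x$sequence),
              x$leader[2] - x$leader[1] + 1L, length(x$introns),
              x$trailer[2] - x$trailer[1] + 1L))
  invisible(x)
}

# Logical mask over the precursor: TRUE for leader/intron/trailer positions.
pre_region_mask <- function(pre) {
  n <- nchar(pre$sequence)
  mask <- logical(n)
  for (iv in c(list(pre$leader, pre$trailer), pre$introns)) {
    mask[seq(iv[1], iv[2])] <- TRUE
  }
  mask
}

#' Load pre-tRNA gene models from BED + FASTA
#'
#' Each FASTA record is a full precursor sequence; BED features on it (name
#' field `leader`, `intron` or `trailer`; BED's 0-based half-open intervals
#' are converted on read) locate the precursor-only segments. The mature link
#' follows the `"pre-"` prefix convention and exon concatenation is verified
#' against the linked mature sequence minus CCA.
#'
#' @param bed_path BED file of leader/intron/trailer features.
#' @param fasta_path FASTA of full precursor sequences.
#' @param mature_set A `ref_set` containing the linked mature genes.
#' @return Named list of `pre_trna_gene` objects (class `"pre_ref_set"`).
#' @export
load_pre_annotation <- function(bed_path, fasta_path, mature_set) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  seqchr <- stats::setNames(as.character(seqs), ids)

  gr <- rtracklayer::import(bed_path)
  feats <- data.frame(
    ref = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = gr$name,
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(feats$name), c("leader", "intron", "trailer"))
  if (length(bad)) {
    psimap_abort(sprintf("unknown BED feature type(s): %s", paste(bad, collapse = ", ")),
                 "psimap_format_error")
  }

  genes <- lapply(ids, function(id) {
    fi <- feats[feats$ref == id, , drop = FALSE]
    if (sum(fi$name == "leader") != 1L || sum(fi$name == "trailer") != 1L) {
      psimap_abort(sprintf("pre-tRNA '%s': exactly one leader and one trailer required", id),
                   "psimap_format_error")
    }
    lead <- unlist(fi[fi$name == "leader", c("start", "end")], use.names = FALSE)
    trail <- unlist(fi[fi$name == "trailer", c("start", "end")], use.names = FALSE)
    intr <- fi[fi$name == "intron", , drop = FALSE]
    introns <- lapply(seq_len(nrow(intr)), function(i) c(intr$start[i], intr$end[i]))
    mature_id <- sub("^pre-", "", id)
    if (!mature_id %in% names(mature_set)) {
      psimap_abort(sprintf("pre-tRNA '%s': unknown mature gene '%s'", id, mature_id),
                   "psimap_lookup_error")
    }
    pre_trna_gene(id, seqchr[[id]], lead, trail, introns,
                  mature_gene_id = mature_id,
                  mature_sequence = mature_set[[mature_id]]$sequence)
  })
  names(genes) <- ids
  structure(genes, class = "pre_ref_set")
}

#' @export
print.pre_ref_set <- function(x, ...) {
  cat(sprintf("<pre_ref_set> %d precursor gene(s)\n", length(x)))
  invisible(x)
}
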