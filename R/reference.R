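#' Construct a tRNA (or plain) reference gene
#'
#' A reference record in mature orientation (5'->3', DNA alphabet). tRNA genes
#' may carry a dot-bracket secondary structure used for canonical Sprinzl
#' numbering; plain references (spike-ins, rRNA) carry none.
#'
#' @param gene_id Unique identifier, e.g. `"tRNA-Val-AAC-4"`. A `"mt-"` /
#'   `"MT-"` prefix marks mitochondrially encoded genes.
#' @param sequence DNA string over `A,C,G,T`; ends with `"CCA"` when
#'   `cca_appended` is `TRUE`.
#' @param structure Optional dot-bracket string of equal length.
#' @param compartment `"cyto"` or `"mito"`; inferred from the `gene_id`
#'   prefix when `NULL`.
#' @param cca_appended Whether the 3'-CCA end has been appended.
#' @param type One of `"trna"`, `"spikein"`, `"rrna"`.
#' @return An object of class `"trna_gene"`.
#' @export
trna_gene <- function(gene_id, sequence, structure = NULL, compartment = NULL,
                      cca_appended = FALSE, type = c("trna", "spikein", "rrna")) {
  type <- match.arg(type)
  if (!nzchar(sequence)) {
    psimap_abort(sprintf("gene '%s': empty sequence", gene_id),
                 "psimap_format_error")
  }
  if (grepl("[^ACGT]", sequence)) {
    psimap_abort(sprintf("gene '%s': sequence alphabet must be A/C/G/T", gene_id),
                 "psimap_format_error")
  }
  if (cca_appended && substr(sequence, nchar(sequence) - 2L, nchar(sequence)) != "CCA") {
    psimap_abort(sprintf("gene '%s': cca_appended but sequence does not end in CCA",
                         gene_id), "psimap_format_error")
  }
  if (!is.null(structure) && nchar(structure) != nchar(sequence)) {
    psimap_abort(sprintf("gene '%s': structure length %d != sequence length %d",
                         gene_id, nchar(structure), nchar(sequence)),
                 "psimap_format_error")
  }
  if (is.null(compartment)) {
    compartment <- if (grepl("^(mt-|MT-)", gene_id)) "mito" else "cyto"
  }
  compartment <- match.arg(compartment, c("cyto", "mito"))
  structure(
    list(gene_id = gene_id, sequence = sequence, structure = structure,
         compartment = compartment, cca_appended = cca_appended, type = type),
    class = "trna_gene"
  )
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s (%s, %s, %d nt%s)\n", x$gene_id, x$type,
              x$compartment, nchar(x$sequence),
              if (x$cca_appended) ", +CCA" else ""))
  invisible(x)
}

new_ref_set <- function(genes) {
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(genes, class = "ref_set")
}

#' @export
print.ref_set <- function(x, ...) {
  tab <- table(vapply(unclass(x), `[[`, character(1), "type"))
  cat(sprintf("<ref_set> %d references (%s)\n", length(x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
`[.ref_set` <- function(x, i) new_ref_set(unclass(x)[i])

#' Named vector of reference sequences
#' @param refs A `ref_set`.
#' @return Named character vector of sequences.
#' @export
ref_sequences <- function(refs) {
  vapply(unclass(refs), `[[`, character(1), "sequence")
}

#' Load, deduplicate and CCA-append a reference set
#'
#' Reads reference sequences from FASTA, optionally attaches dot-bracket
#' structures from a sidecar TSV (`gene_id`, `structure`), appends the 3'-CCA
#' end, and keeps one gene per distinct sequence (mature tRNA references are
#' highly redundant across the genome).
#'
#' @param fasta_path FASTA of DNA-alphabet reference sequences.
#' @param structure_path Optional TSV with columns `gene_id`, `structure`.
#' @param append_cca Append `"CCA"` to every sequence (structures are padded
#'   with three unpaired positions).
#' @param dedupe Keep exactly one gene per distinct (post-CCA) sequence, the
#'   lexicographically first `gene_id`.
#' @param type Reference type passed to [trna_gene()].
#' @return A `ref_set`.
#' @export
load_reference_set <- function(fasta_path, structure_path = NULL,
                               append_cca = TRUE, dedupe = TRUE,
                               type = "trna") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) return(new_ref_set(list()))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    psimap_abort(sprintf("duplicate gene_id in FASTA: %s",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "psimap_format_error")
  }
  seqchr <- as.character(seqs)
  names(seqchr) <- ids

  structures <- NULL
  if (!is.null(structure_path)) {
    st <- utils::read.table(structure_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (!all(c("gene_id", "structure") %in% names(st))) {
      psimap_abort("structure sidecar must have columns gene_id, structure",
                   "psimap_format_error")
    }
    structures <- stats::setNames(st$structure, st$gene_id)
  }

  genes <- lapply(ids, function(id) {
    s <- seqchr[[id]]
    db <- if (!is.null(structures) && id %in% names(structures)) structures[[id]] else NULL
    if (!is.null(db) && nchar(db) != nchar(s)) {
      psimap_abort(sprintf("gene '%s': structure length mismatch", id),
                   "psimap_format_error")
    }
    if (append_cca) {
      s <- paste0(s, "CCA")
      if (!is.null(db)) db <- paste0(db, "...")
    }
    trna_gene(id, s, structure = db, cca_appended = append_cca, type = type)
  })
  names(genes) <- ids

  if (dedupe) {
    ord <- order(ids)
    genes <- genes[ord]
    keep <- !duplicated(vapply(genes, `[[`, character(1), "sequence"))
    genes <- genes[keep]
  }
  new_ref_set(genes)
}
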