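# Canonical Sprinzl numbering of tRNA positions from a dot-bracket cloverleaf.
#
# The mature cloverleaf is parsed 5'->3' as: acceptor stem (7 bp), positions
# 8-9, D-stem (4 bp, 10-13), D-loop (length-dependent labels with 17A/20A/20B
# insertions or 17/20 drops), D-stem 3' strand (22-25), 26, anticodon stem
# (27-31), anticodon loop (32-38), stem 3' (39-43), variable region (44-48 or
# 44,45 plus an e-stem-loop), T-stem (49-53), T-loop (54-60), stem 3' (61-65),
# acceptor 3' strand (66-72), discriminator 73, and CCA 74-76 when appended.

numbering_error <- function(gene_id, why) {
  psimap_abort(sprintf("gene '%s': structure not cloverleaf-parsable (%s)",
                       gene_id, why), "psimap_numbering_error")
}

pair_table <- function(db, gene_id = "?") {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  pt <- integer(length(chars))
  open <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      open <- c(open, i)
    } else if (ch == ")") {
      if (!length(open)) numbering_error(gene_id, "unbalanced brackets")
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch != ".") {
      numbering_error(gene_id, sprintf("illegal structure character '%s'", ch))
    }
  }
  if (length(open)) numbering_error(gene_id, "unbalanced brackets")
  pt
}

# Length of the helix whose 5' strand starts at i (consecutive stacked pairs).
helix_len_at <- function(pt, i) {
  if (i > length(pt) || pt[i] == 0L) return(0L)
  l <- 1L
  while (i + l <= length(pt) && pt[i + l] == pt[i] - l) l <- l + 1L
  l
}

unpaired_run <- function(pt, i) {
  l <- 0L
  while (i + l <= length(pt) && pt[i + l] == 0L) l <- l + 1L
  l
}

# D-loop label allocation keyed by loop length (residues between 13 and 22).
dloop_labels <- function(n) {
  switch(as.character(n),
    "6"  = c("14", "15", "16", "18", "19", "21"),
    "7"  = c("14", "15", "16", "18", "19", "20", "21"),
    "8"  = as.character(14:21),
    "9"  = c("14", "15", "16", "17", "18", "19", "20", "20A", "21"),
    "10" = c("14", "15", "16", "17", "17A", "18", "19", "20", "20A", "21"),
    "11" = c("14", "15", "16", "17", "17A", "18", "19", "20", "20A", "20B", "21"),
    NULL
  )
}

#' Assign canonical Sprinzl labels to every position of a tRNA gene
#'
#' Parses the gene's dot-bracket structure into the canonical cloverleaf and
#' returns a bijective linear-position -> Sprinzl-label map. D-loops of length
#' 6-11 are handled by a fixed allocation table (inserting 17A/20A/20B or
#' dropping 17/20); long variable arms are labelled 44,45 then e11..e1k along
#' the 5' e-stem strand, e1..em around the loop and e2k..e21 along the 3'
#' strand. Genes whose structure is not cloverleaf-parsable (many mt-tRNAs)
#' can instead be numbered through an explicit `override` table.
#'
#' @param gene A [trna_gene()] with a `structure`, unless `override` is given.
#' @param override Optional data frame (see [load_numbering_override()]) with
#'   columns `gene_id`, `linear_pos_1based`, `sprinzl_label` covering every
#'   position of the gene.
#' @return An object of class `"sprinzl_map"`: list with `gene_id` and
#'   `labels` (character vector, one label per linear position).
#' @export
assign_sprinzl <- function(gene, override = NULL) {
  n_full <- nchar(gene$sequence)

  if (!is.null(override)) {
    ov <- override[override$gene_id == gene$gene_id, , drop = FALSE]
    if (nrow(ov) != n_full ||
        !setequal(ov$linear_pos_1based, seq_len(n_full)) ||
        anyDuplicated(ov$sprinzl_label)) {
      numbering_error(gene$gene_id, "override table does not define a bijection")
    }
    labels <- character(n_full)
    labels[ov$linear_pos_1based] <- ov$sprinzl_label
    return(structure(list(gene_id = gene$gene_id, labels = labels),
                     class = "sprinzl_map"))
  }

  if (is.null(gene$structure)) {
    numbering_error(gene$gene_id, "no structure and no override")
  }

  db <- gene$structure
  if (isTRUE(gene$cca_appended)) {
    if (substr(db, n_full - 2L, n_full) != "...") {
      numbering_error(gene$gene_id, "CCA must be unpaired")
    }
    db <- substr(db, 1L, n_full - 3L)
  }
  n <- nchar(db)
  pt <- pair_table(db, gene$gene_id)
  lab <- character(n)

  # Acceptor stem, 5' strand.
  if (helix_len_at(pt, 1L) != 7L) numbering_error(gene$gene_id, "acceptor stem != 7 bp")
  if (pt[1L] != n - 1L) numbering_error(gene$gene_id, "acceptor stem must close at the discriminator")
  lab[1:7] <- as.character(1:7)

  if (unpaired_run(pt, 8L) != 2L) numbering_error(gene$gene_id, "positions 8-9 malformed")
  lab[8:9] <- c("8", "9")

  # D-arm.
  if (helix_len_at(pt, 10L) != 4L) numbering_error(gene$gene_id, "D-stem != 4 bp")
  lab[10:13] <- as.character(10:13)
  dl <- pt[13L] - 14L            # loop length: residues strictly between 13 and 22
  dlab <- dloop_labels(dl)
  if (is.null(dlab) || unpaired_run(pt, 14L) != dl) {
    numbering_error(gene$gene_id, sprintf("D-loop length %d unsupported", dl))
  }
  lab[seq(14L, length.out = dl)] <- dlab
  lab[pt[13:10]] <- as.character(22:25)

  p26 <- pt[10L] + 1L
  if (unpaired_run(pt, p26) != 1L) numbering_error(gene$gene_id, "position 26 malformed")
  lab[p26] <- "26"

  # Anticodon arm.
  ac <- p26 + 1L
  if (helix_len_at(pt, ac) != 5L) numbering_error(gene$gene_id, "anticodon stem != 5 bp")
  lab[seq(ac, length.out = 5L)] <- as.character(27:31)
  acl <- pt[ac + 4L] - (ac + 5L)   # anticodon loop length
  if (acl != 7L || unpaired_run(pt, ac + 5L) != 7L) {
    numbering_error(gene$gene_id, "anticodon loop != 7 nt")
  }
  lab[seq(ac + 5L, length.out = 7L)] <- as.character(32:38)
  lab[pt[seq(ac + 4L, ac)]] <- as.character(39:43)

  # Variable region, then T-arm.
  v_start <- pt[ac] + 1L
  q <- v_start
  while (q <= n && pt[q] == 0L) q <- q + 1L
  if (q > n) numbering_error(gene$gene_id, "missing T-stem")
  r <- pt[q]
  s <- r + 1L
  while (s <= n && pt[s] == 0L) s <- s + 1L
  has_earm <- s <= n && pt[s] > s   # another helix opens after [q, r]: e-arm at q

  if (has_earm) {
    if (q - v_start != 2L) numbering_error(gene$gene_id, "long variable arm must start 44,45")
    lab[v_start] <- "44"
    lab[v_start + 1L] <- "45"
    h <- helix_len_at(pt, q)
    if (h < 1L || h > 7L) numbering_error(gene$gene_id, "e-stem length unsupported")
    lab[seq(q, length.out = h)] <- paste0("e1", seq_len(h))
    eloop_start <- q + h
    m <- pt[q + h - 1L] - eloop_start
    if (m < 1L || m > 5L || unpaired_run(pt, eloop_start) != m) {
      numbering_error(gene$gene_id, "e-loop length unsupported")
    }
    lab[seq(eloop_start, length.out = m)] <- paste0("e", seq_len(m))
    lab[pt[seq(q + h - 1L, q)]] <- paste0("e2", seq(h, 1L))
    gap <- s - r - 1L
    if (gap > 1L) numbering_error(gene$gene_id, "trailing variable-region nucleotides")
    if (gap == 1L) lab[r + 1L] <- "48"
    t_start <- s
  } else {
    v_len <- q - v_start
    if (v_len > 5L) numbering_error(gene$gene_id, "variable loop > 5 nt without an e-stem")
    if (v_len > 0L) lab[seq(v_start, length.out = v_len)] <- as.character(seq(44L, length.out = v_len))
    t_start <- q
  }

  if (helix_len_at(pt, t_start) != 5L) numbering_error(gene$gene_id, "T-stem != 5 bp")
  lab[seq(t_start, length.out = 5L)] <- as.character(49:53)
  tl <- pt[t_start + 4L] - (t_start + 5L)
  if (tl != 7L || unpaired_run(pt, t_start + 5L) != 7L) {
    numbering_error(gene$gene_id, "T-loop != 7 nt")
  }
  lab[seq(t_start + 5L, length.out = 7L)] <- as.character(54:60)
  lab[pt[seq(t_start + 4L, t_start)]] <- as.character(61:65)

  if (pt[t_start] + 1L != pt[7L]) numbering_error(gene$gene_id, "acceptor 3' strand misplaced")
  lab[pt[7:1]] <- as.character(66:72)
  lab[n] <- "73"

  if (isTRUE(gene$cca_appended)) lab <- c(lab, c("74", "75", "76"))

  if (any(!nzchar(lab)) || anyDuplicated(lab)) {
    numbering_error(gene$gene_id, "labelling is not a bijection")
  }
  structure(list(gene_id = gene$gene_id, labels = lab), class = "sprinzl_map")
}

#' @export
print.sprinzl_map <- function(x, ...) {
  cat(sprintf("<sprinzl_map> %s: %d positions (%s ... %s)\n", x$gene_id,
              length(x$labels), x$labels[1], x$labels[length(x$labels)]))
  invisible(x)
}

#' Linear position of a Sprinzl label
#' @param map A `sprinzl_map`.
#' @param label Character vector of Sprinzl labels.
#' @return Integer linear positions (1-based); `NA` when absent.
#' @export
sprinzl_position <- function(map, label) {
  match(label, map$labels)
}

#' Rank of Sprinzl labels under the canonical total order
#'
#' Numeric positions order naturally; insertions sort just after their parent
#' (17 < 17A < 18, 20 < 20A < 20B < 21) and the variable-arm block sorts
#' between 45 and 48 as e11..e17, e1..e5, e27..e21.
#'
#' @param labels Character vector of labels.
#' @return Numeric ranks (strictly increasing along a canonical gene).
#' @export
sprinzl_rank <- function(labels) {
  vapply(labels, function(l) {
    if (grepl("^[0-9]+$", l)) return(as.numeric(l))
    if (l == "17A") return(17.5)
    if (l == "20A") return(20.4)
    if (l == "20B") return(20.6)
    if (grepl("^e1[1-7]$", l)) return(45 + 0.01 * as.numeric(substr(l, 3, 3)))
    if (grepl("^e[1-5]$", l)) return(45.2 + 0.01 * as.numeric(substr(l, 2, 2)))
    if (grepl("^e2[1-7]$", l)) return(45.4 + 0.01 * (8 - as.numeric(substr(l, 3, 3))))
    NA_real_
  }, numeric(1), USE.NAMES = FALSE)
}

#' Load a per-gene Sprinzl numbering override table
#'
#' @param path TSV with columns `gene_id`, `linear_pos_1based`,
#'   `sprinzl_label`.
#' @return A data frame usable as the `override` of [assign_sprinzl()].
#' @export
load_numbering_override <- function(path) {
  ov <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character"))
  need <- c("gene_id", "linear_pos_1based", "sprinzl_label")
  if (!all(need %in% names(ov))) {
    psimap_abort("override table must have columns gene_id, linear_pos_1based, sprinzl_label",
                 "psimap_format_error")
  }
  ov
}
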