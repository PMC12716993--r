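# Per-library base-call count tables and the read -> counts pileup.

#' Construct a per-library count table
#'
#' @param library_id Library identifier.
#' @param role `"treated"` (chemically converted) or `"control"`.
#' @param condition Condition string: `"WT"`, `"KO:<gene>"` or `"KD:<gene>"`.
#' @param replicate Replicate index (>= 1).
#' @param sites Data frame with columns `ref_id`, `pos` (1-based),
#'   `ref_base`, `nA`, `nC`, `nG`, `nT`, `nDel`.
#' @return An object of class `"library_counts"`.
#' @export
library_counts <- function(library_id, role = c("treated", "control"),
                           condition = "WT", replicate = 1L, sites) {
  role <- match.arg(role)
  need <- c("ref_id", "pos", "ref_base", "nA", "nC", "nG", "nT", "nDel")
  if (!all(need %in% names(sites))) {
    psimap_abort(sprintf("sites must have columns: %s", paste(need, collapse = ", ")),
                 "psimap_format_error")
  }
  if (!is_count(replicate) || replicate < 1L) {
    psimap_abort("replicate must be an integer >= 1", "psimap_format_error")
  }
  cnt <- as.matrix(sites[, c("nA", "nC", "nG", "nT", "nDel")])
  if (any(cnt < 0) || any(cnt != trunc(cnt))) {
    psimap_abort("counts must be non-negative integers", "psimap_format_error")
  }
  if (anyDuplicated(site_key(sites$ref_id, sites$pos))) {
    psimap_abort("duplicate (ref_id, pos) in sites", "psimap_format_error")
  }
  sites <- sites[order(sites$ref_id, sites$pos), need]
  rownames(sites) <- NULL
  structure(
    list(library_id = library_id, role = role, condition = condition,
         replicate = as.integer(replicate), sites = sites),
    class = "library_counts"
  )
}

#' @export
print.library_counts <- function(x, ...) {
  cat(sprintf("<library_counts> %s (%s, %s, rep %d): %d positions on %d reference(s)\n",
              x$library_id, x$role, x$condition, x$replicate,
              nrow(x$sites), length(unique(x$sites$ref_id))))
  invisible(x)
}

#' Pile aligned read records into per-position base-call counts
#'
#' Reads are simplified gapless records: a base string aligned from `start`
#' (1-based) on the reference. Only sense-strand reads contribute; `N` calls
#' contribute to no counter and `-` increments the deletion counter only.
#'
#' @param reads Data frame with columns `read_id`, `ref_id`, `start`,
#'   `strand` (`"sense"`/`"antisense"`), `bases`.
#' @param refs A `ref_set` resolving every `ref_id`.
#' @param library_id,role,condition,replicate Metadata for the resulting
#'   [library_counts()].
#' @return A `library_counts`.
#' @export
pileup <- function(reads, refs, library_id = "pileup", role = "treated",
                   condition = "WT", replicate = 1L) {
  seqs <- ref_sequences(refs)
  empty <- data.frame(ref_id = character(0), pos = integer(0),
                      ref_base = character(0), nA = integer(0), nC = integer(0),
                      nG = integer(0), nT = integer(0), nDel = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) {
    return(library_counts(library_id, role, condition, replicate, empty))
  }
  if (!all(reads$ref_id %in% names(seqs))) {
    psimap_abort("read maps to an unknown reference", "psimap_alignment_error")
  }
  len <- nchar(reads$bases)
  if (any(reads$start < 1L) || any(reads$start + len - 1L > nchar(seqs[reads$ref_id]))) {
    psimap_abort("read exceeds reference bounds", "psimap_alignment_error")
  }
  sense <- reads$strand == "sense"
  reads <- reads[sense, , drop = FALSE]
  len <- len[sense]
  if (nrow(reads) == 0L) {
    return(library_counts(library_id, role, condition, replicate, empty))
  }

  basev <- unlist(strsplit(reads$bases, "", fixed = TRUE), use.names = FALSE)
  posv <- unlist(lapply(seq_len(nrow(reads)), function(i) {
    seq(reads$start[i], length.out = len[i])
  }), use.names = FALSE)
  refv <- rep(reads$ref_id, len)

  keyv <- site_key(refv, posv)
  tab <- table(keyv, factor(basev, levels = c("A", "C", "G", "T", "-", "N")))
  idx <- match(rownames(tab), keyv)
  sites <- data.frame(
    ref_id = refv[idx], pos = posv[idx], ref_base = NA_character_,
    nA = as.integer(tab[, "A"]), nC = as.integer(tab[, "C"]),
    nG = as.integer(tab[, "G"]), nT = as.integer(tab[, "T"]),
    nDel = as.integer(tab[, "-"]), stringsAsFactors = FALSE
  )
  sites$ref_base <- substring(seqs[sites$ref_id], sites$pos, sites$pos)
  library_counts(library_id, role, condition, replicate, sites)
}

#' Per-site conversion-rate metrics at reference-T positions
#'
#' `t2c_rate` is the fraction of T/C base calls read as C (the modification
#' level in a treated library, the background conversion rate in a control);
#' `t2r_ratio` is the fraction of all base calls read as A or G.
#'
#' @param sites Data frame of site counts (rows must have `ref_base == "T"`).
#' @return Data frame with `t2c_rate`, `t2r_ratio`, `coverage`.
#' @export
site_rates <- function(sites) {
  if (any(sites$ref_base != "T")) {
    psimap_abort("site_rates is defined only at reference-T positions",
                 "psimap_domain_error")
  }
  ct <- sites$nC + sites$nT
  cov <- sites$nA + sites$nC + sites$nG + sites$nT
  data.frame(
    t2c_rate = ifelse(ct == 0L, 0, sites$nC / ct),
    t2r_ratio = ifelse(cov == 0L, 0, (sites$nA + sites$nG) / cov),
    coverage = cov
  )
}

#' Write a count table as TSV
#'
#' Output columns are `ref_id`, `pos_1based`, `ref_base`, `nA`, `nC`, `nG`,
#' `nT`, `nDel`, preceded by `#key=value` metadata headers identifying the
#' library.
#'
#' @param lib A `library_counts`.
#' @param path Output path.
#' @param extra_headers Optional named character vector of additional
#'   `#key=value` header lines.
#' @export
write_counts_tsv <- function(lib, path, extra_headers = NULL) {
  meta <- c(library_id = lib$library_id, role = lib$role,
            condition = lib$condition, replicate = as.character(lib$replicate),
            extra_headers)
  out <- lib$sites
  names(out)[names(out) == "pos"] <- "pos_1based"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(meta), meta), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_counts_tsv()]
#' @param path Input path.
#' @return A `library_counts`.
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta_lines <- sub("^#", "", lines[hdr])
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
                          vapply(kv, `[[`, character(1), 1L))
  need <- c("library_id", "role", "condition", "replicate")
  if (!all(need %in% names(meta))) {
    psimap_abort(sprintf("missing metadata header(s): %s",
                         paste(setdiff(need, names(meta)), collapse = ", ")),
                 "psimap_format_error")
  }
  body <- utils::read.table(text = lines[-hdr], header = TRUE, sep = "\t",
                            colClasses = c("character", "integer", "character",
                                           rep("integer", 5L)))
  if (nrow(body) && any(body$pos_1based < 1L)) {
    psimap_abort("pos_1based must be >= 1", "psimap_format_error")
  }
  names(body)[names(body) == "pos_1based"] <- "pos"
  library_counts(meta[["library_id"]], meta[["role"]], meta[["condition"]],
                 as.integer(meta[["replicate"]]), body)
}

#' Write aligned read records as TSV
#'
#' Columns: `read_id`, `ref_id`, `start_0based`, `strand`, `bases` (the
#' interchange convention is 0-based; in-memory records are 1-based).
#'
#' @param reads Read-record data frame (1-based `start`).
#' @param path Output path.
#' @export
write_read_records_tsv <- function(reads, path) {
  out <- data.frame(read_id = reads$read_id, ref_id = reads$ref_id,
                    start_0based = reads$start - 1L, strand = reads$strand,
                    bases = reads$bases, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned read records from TSV
#' @param path Input path.
#' @return Read-record data frame with 1-based `start`.
#' @export
read_read_records_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "character", "character"))
  data.frame(read_id = df$read_id, ref_id = df$ref_id,
             start = df$start_0based + 1L, strand = df$strand,
             bases = df$bases, stringsAsFactors = FALSE)
}
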