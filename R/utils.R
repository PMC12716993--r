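# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish format/domain/usage failures.
psimap_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "psimap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

DNA_BASES <- c("A", "C", "G", "T")

random_bases <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# k-mer centred on pos (1-based); NA when the window leaves the sequence.
seq_context <- function(sequence, pos, k = 3L) {
  stopifnot(k %% 2L == 1L)
  flank <- (k - 1L) %/% 2L
  lo <- pos - flank
  hi <- pos + flank
  out <- substring(sequence, lo, hi)
  out[lo < 1L | hi > nchar(sequence)] <- NA_character_
  out
}

# Deterministic key used to join per-position tables.
site_key <- function(ref_id, pos) paste(ref_id, pos, sep = "\r")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}
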