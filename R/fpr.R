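# Motif-specific false-positive-rate model and the per-site test statistics.
# False conversion in the treated chemistry is context dependent, so the null
# rate is estimated per k-mer context (centred on the T) from unmodified
# substrate: spike-ins by preference, control counts as a fallback.

#' Construct a false-positive-rate model
#'
#' @param fpr Named numeric vector of per-context rates (names are k-mer
#'   contexts centred on the T, e.g. `"GTC"`).
#' @param global_fpr Fallback rate for contexts without an estimate.
#' @param context_k Odd context width.
#' @param source Where the rates came from (`"spikein"`, `"control"`,
#'   `"manual"`).
#' @return An object of class `"fpr_model"`.
#' @export
fpr_model <- function(fpr, global_fpr, context_k = 3L,
                      source = c("manual", "spikein", "control")) {
  source <- match.arg(source)
  if (any(fpr < 0 | fpr > 1) || global_fpr < 0 || global_fpr > 1) {
    psimap_abort("false-positive rates must lie in [0, 1]", "psimap_domain_error")
  }
  if (context_k %% 2L != 1L) {
    psimap_abort("context_k must be odd", "psimap_domain_error")
  }
  structure(list(context_k = as.integer(context_k), fpr = fpr,
                 global_fpr = global_fpr, source = source),
            class = "fpr_model")
}

#' @export
print.fpr_model <- function(x, ...) {
  cat(sprintf("<fpr_model> %d context(s) (k = %d, source = %s), global %.4g\n",
              length(x$fpr), x$context_k, x$source, x$global_fpr))
  invisible(x)
}

# Vectorized context -> rate lookup with global fallback.
fpr_lookup <- function(model, contexts) {
  v <- unname(model$fpr[contexts])
  v[is.na(v)] <- model$global_fpr
  v
}

#' Estimate motif-specific false-positive rates from unmodified references
#'
#' Pools T->C conversions per k-mer context over every reference-T position of
#' the library: the per-context rate is `sum(nC) / sum(nC + nT)`. Contexts
#' whose pooled denominator falls below `min_context_n` fall back to the
#' globally pooled rate.
#'
#' @param lib A `library_counts` covering unmodified reference-T positions
#'   (spike-ins preferred).
#' @param refs A `ref_set` supplying the reference sequences.
#' @param context_k Odd context width (default 3).
#' @param min_context_n Minimum pooled denominator for a per-context estimate.
#' @param source Label recorded in the model.
#' @return An [fpr_model()].
#' @export
estimate_motif_fpr <- function(lib, refs, context_k = 3L, min_context_n = 200L,
                               source = "spikein") {
  seqs <- ref_sequences(refs)
  st <- lib$sites
  st <- st[st$ref_base == "T" & st$ref_id %in% names(seqs), , drop = FALSE]
  if (nrow(st) == 0L) {
    psimap_abort("no eligible reference-T positions for FPR estimation",
                 "psimap_estimation_error")
  }
  ctx <- seq_context(seqs[st$ref_id], st$pos, context_k)
  ok <- !is.na(ctx)
  st <- st[ok, , drop = FALSE]
  ctx <- ctx[ok]
  if (nrow(st) == 0L) {
    psimap_abort("no eligible reference-T positions for FPR estimation",
                 "psimap_estimation_error")
  }
  num <- tapply(st$nC, ctx, sum)
  den <- tapply(st$nC + st$nT, ctx, sum)
  global <- sum(st$nC) / max(1L, sum(st$nC + st$nT))
  keep <- den >= min_context_n
  rates <- stats::setNames(as.numeric(num[keep] / pmax(1, den[keep])),
                           names(num)[keep])
  fpr_model(rates, global_fpr = global, context_k = context_k, source = source)
}

#' One-sided upper-tail binomial p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, fpr)`: the probability of observing at
#' least the seen number of T->C conversions under the context's false-positive
#' rate alone. `p = 1` when `k = 0`.
#'
#' @param k Observed conversion count(s).
#' @param n Number of T/C base calls.
#' @param fpr Null conversion rate(s).
#' @return Numeric vector of p-values.
#' @export
binomial_tail_p <- function(k, n, fpr) {
  if (any(k < 0 | n < 0 | k > n)) {
    psimap_abort("require 0 <= k <= n", "psimap_domain_error")
  }
  if (any(fpr < 0 | fpr > 1)) {
    psimap_abort("require 0 <= fpr <= 1", "psimap_domain_error")
  }
  stats::pbinom(k - 1, n, fpr, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order (`q >= p` elementwise).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    psimap_abort("p-values must lie in [0, 1]", "psimap_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}
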