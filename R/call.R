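# High-confidence pseudouridine site calling from paired treated/control
# count tables. A reference-T position is called when all five criteria hold:
#   (1) coverage >= 50 in both treated and control libraries;
#   (2) control conversion rate <= 0.01 OR control T->C count <= 2;
#   (3) control T->R (R = A/G) ratio <= 0.10;
#   (4) modification level >= 0.10 (cytosolic) / >= 0.05 (mitochondrial);
#   (5) BH-adjusted upper-tail binomial p-value < 0.001 under the
#       motif-specific false-positive rate;
# and, for cytosolic tRNA, the gene is an expressed isodecoder.

#' Calling thresholds
#'
#' Defaults are the standard values of the five calling criteria plus the
#' knockout-eligibility coverage bound.
#'
#' @param min_cov Criterion 1 coverage bound (both libraries).
#' @param max_ctrl_rate,max_ctrl_c_count Criterion 2 (an OR of the two arms).
#' @param max_ctrl_t2r Criterion 3 bound on the control T->R ratio.
#' @param min_level_cy,min_level_mt Criterion 4 level bounds by compartment.
#' @param max_q Criterion 5 bound on the BH-adjusted p-value.
#' @param min_cov_dependency Coverage bound for knockout-dependency eligibility.
#' @return An object of class `"psi_thresholds"`.
#' @export
psi_thresholds <- function(min_cov = 50, max_ctrl_rate = 0.01,
                           max_ctrl_c_count = 2, max_ctrl_t2r = 0.10,
                           min_level_cy = 0.10, min_level_mt = 0.05,
                           max_q = 0.001, min_cov_dependency = 20) {
  th <- list(min_cov = min_cov, max_ctrl_rate = max_ctrl_rate,
             max_ctrl_c_count = max_ctrl_c_count, max_ctrl_t2r = max_ctrl_t2r,
             min_level_cy = min_level_cy, min_level_mt = min_level_mt,
             max_q = max_q, min_cov_dependency = min_cov_dependency)
  rates <- c("max_ctrl_rate", "max_ctrl_t2r", "min_level_cy", "min_level_mt", "max_q")
  if (any(unlist(th[rates]) < 0 | unlist(th[rates]) > 1) ||
      min_cov < 0 || max_ctrl_c_count < 0 || min_cov_dependency < 0) {
    psimap_abort("threshold out of range", "psimap_domain_error")
  }
  structure(th, class = "psi_thresholds")
}

#' @export
print.psi_thresholds <- function(x, ...) {
  cat("<psi_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Expressed isodecoders from a control library
#'
#' A gene counts as expressed when its median per-position coverage in the
#' control library (positions without counts count as zero) reaches
#' `min_median_cov`.
#'
#' @param control A control `library_counts`.
#' @param refs A `ref_set`.
#' @param min_median_cov Median-coverage bound (default 50, mirroring the
#'   calling coverage criterion).
#' @return Character vector of expressed `gene_id`s.
#' @export
expressed_isodecoders <- function(control, refs, min_median_cov = 50) {
  seqs <- ref_sequences(refs)
  st <- control$sites
  cov <- st$nA + st$nC + st$nG + st$nT
  keep <- vapply(names(seqs), function(id) {
    v <- numeric(nchar(seqs[[id]]))
    rows <- st$ref_id == id
    v[st$pos[rows]] <- cov[rows]
    stats::median(v) >= min_median_cov
  }, logical(1))
  names(seqs)[keep]
}

#' Call pseudouridine sites from a treated/control library pair
#'
#' Evaluates every reference-T position present in both libraries against the
#' five calling criteria. The modification level is the raw treated
#' conversion rate `nC / (nC + nT)` (background is handled by the control
#' criteria and the binomial test, not by subtraction, unless
#' `subtract_ctrl`). The binomial test uses the site's k-mer context rate
#' from `fpr_model`; BH adjustment is applied once across all candidates.
#'
#' @param treated,control `library_counts` with matching roles.
#' @param refs A `ref_set`; candidate positions are restricted to its genes.
#' @param fpr_model An [fpr_model()]; when `NULL`, rates are estimated from
#'   the control library ([estimate_motif_fpr()]).
#' @param thresholds A [psi_thresholds()].
#' @param expressed Character vector of expressed cytosolic isodecoders;
#'   computed from the control library when `NULL`. Only cytosolic tRNA genes
#'   are subject to this filter.
#' @param subtract_ctrl Subtract the control conversion rate from the level
#'   (off by default).
#' @return An object of class `"psi_calls"`; `as.data.frame()` yields the
#'   per-site table with per-criterion flags and `called`.
#' @export
call_psi <- function(treated, control, refs, fpr_model = NULL,
                     thresholds = psi_thresholds(), expressed = NULL,
                     subtract_ctrl = FALSE) {
  if (!inherits(treated, "library_counts") || !inherits(control, "library_counts")) {
    psimap_abort("treated and control must be library_counts", "psimap_usage_error")
  }
  if (treated$role != "treated" || control$role != "control") {
    psimap_abort("library roles must be treated / control", "psimap_usage_error")
  }
  th <- thresholds
  seqs <- ref_sequences(refs)
  meta_comp <- vapply(unclass(refs), `[[`, character(1), "compartment")
  meta_type <- vapply(unclass(refs), `[[`, character(1), "type")

  ts <- treated$sites
  cs <- control$sites
  ts <- ts[ts$ref_base == "T" & ts$ref_id %in% names(seqs), , drop = FALSE]
  cs <- cs[cs$ref_base == "T" & cs$ref_id %in% names(seqs), , drop = FALSE]
  idx <- match(site_key(ts$ref_id, ts$pos), site_key(cs$ref_id, cs$pos))
  keep <- !is.na(idx)
  ts <- ts[keep, , drop = FALSE]
  cs <- cs[idx[keep], , drop = FALSE]

  if (is.null(fpr_model)) {
    fpr_model <- estimate_motif_fpr(control, refs, source = "control")
  }
  if (is.null(expressed)) {
    expressed <- expressed_isodecoders(control, refs, min_median_cov = th$min_cov)
  }

  # Sprinzl labels where the gene's structure parses (NA otherwise).
  label_of <- new.env(parent = emptyenv())
  labels_for <- function(id) {
    if (!is.null(label_of[[id]])) return(label_of[[id]])
    lab <- tryCatch(assign_sprinzl(refs[[id]])$labels,
                    psimap_numbering_error = function(e) rep(NA_character_, nchar(seqs[[id]])))
    if (meta_type[[id]] != "trna") lab <- rep(NA_character_, nchar(seqs[[id]]))
    label_of[[id]] <- lab
    lab
  }

  tr <- site_rates(ts)
  cr <- site_rates(cs)
  level <- tr$t2c_rate
  if (subtract_ctrl) level <- pmax(0, level - cr$t2c_rate)

  ctx <- seq_context(seqs[ts$ref_id], ts$pos, fpr_model$context_k)
  fpr <- fpr_lookup(fpr_model, ctx)
  p <- binomial_tail_p(ts$nC, ts$nC + ts$nT, fpr)
  q <- bh_adjust(p)

  compartment <- unname(meta_comp[ts$ref_id])
  flag_cov <- tr$coverage >= th$min_cov & cr$coverage >= th$min_cov
  flag_ctrl_conv <- cr$t2c_rate <= th$max_ctrl_rate | cs$nC <= th$max_ctrl_c_count
  flag_ctrl_t2r <- cr$t2r_ratio <= th$max_ctrl_t2r
  min_level <- ifelse(compartment == "mito", th$min_level_mt, th$min_level_cy)
  flag_level <- level >= min_level
  flag_q <- q < th$max_q
  needs_expressed <- meta_type[ts$ref_id] == "trna" & compartment == "cyto"
  expressed_ok <- !needs_expressed | ts$ref_id %in% expressed

  called <- flag_cov & flag_ctrl_conv & flag_ctrl_t2r & flag_level & flag_q &
    expressed_ok

  flags <- cbind(coverage = flag_cov, ctrl_conversion = flag_ctrl_conv,
                 ctrl_t2r = flag_ctrl_t2r, level = flag_level, q_value = flag_q,
                 expressed = expressed_ok)
  fail_reasons <- apply(flags, 1L, function(fl) {
    paste(colnames(flags)[!fl], collapse = ",")
  })

  sp <- vapply(seq_len(nrow(ts)), function(i) {
    labels_for(ts$ref_id[i])[ts$pos[i]]
  }, character(1))

  calls <- data.frame(
    ref_id = ts$ref_id, pos = ts$pos, sprinzl_label = sp,
    compartment = compartment, level = level,
    cov_treated = tr$coverage, cov_ctrl = cr$coverage,
    ctrl_rate = cr$t2c_rate, ctrl_c_count = cs$nC, ctrl_t2r = cr$t2r_ratio,
    context = ctx, fpr = fpr, p = p, q = q,
    flag_cov = flag_cov, flag_ctrl_conv = flag_ctrl_conv,
    flag_ctrl_t2r = flag_ctrl_t2r, flag_level = flag_level, flag_q = flag_q,
    expressed = expressed_ok, called = called, fail_reasons = fail_reasons,
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$ref_id, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL

  structure(
    list(calls = calls, thresholds = th, fpr_model = fpr_model,
         treated_id = treated$library_id, control_id = control$library_id,
         condition = treated$condition, replicate = treated$replicate,
         n_candidates = nrow(calls)),
    class = "psi_calls"
  )
}

#' @method as.data.frame psi_calls
#' @export
as.data.frame.psi_calls <- function(x, ...) x$calls

#' @export
print.psi_calls <- function(x, ...) {
  cc <- x$calls
  cat(sprintf("<psi_calls> %s vs %s (%s, rep %d)\n", x$treated_id, x$control_id,
              x$condition, x$replicate))
  cat(sprintf("  %d candidate T position(s), %d called", nrow(cc), sum(cc$called)))
  if (sum(cc$called)) {
    tab <- table(cc$compartment[cc$called])
    cat(sprintf(" (%s)", paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @method summary psi_calls
#' @export
summary.psi_calls <- function(object, ...) {
  cc <- object$calls
  fl <- c("flag_cov", "flag_ctrl_conv", "flag_ctrl_t2r", "flag_level",
          "flag_q", "expressed")
  fails <- vapply(fl, function(f) sum(!cc[[f]]), integer(1))
  out <- list(condition = object$condition, n_candidates = nrow(cc),
              n_called = sum(cc$called), criterion_failures = fails,
              level_summary = if (sum(cc$called)) summary(cc$level[cc$called]) else NULL)
  class(out) <- "summary.psi_calls"
  out
}

#' @export
print.summary.psi_calls <- function(x, ...) {
  cat(sprintf("Psi site calls, condition %s: %d candidates, %d called\n",
              x$condition, x$n_candidates, x$n_called))
  cat("Failures per criterion:\n")
  for (nm in names(x$criterion_failures)) {
    cat(sprintf("  %-15s %d\n", nm, x$criterion_failures[[nm]]))
  }
  if (!is.null(x$level_summary)) {
    cat("Called-site modification levels:\n")
    print(x$level_summary)
  }
  invisible(x)
}

#' @method plot psi_calls
#' @export
plot.psi_calls <- function(x, ...) {
  cc <- x$calls[x$calls$called, , drop = FALSE]
  if (!nrow(cc)) {
    warning("no called sites to plot")
    return(invisible(NULL))
  }
  lab <- ifelse(is.na(cc$sprinzl_label), "unassigned", cc$sprinzl_label)
  ord <- order(sprinzl_rank(lab))
  f <- factor(lab, levels = unique(lab[ord]))
  graphics::boxplot(cc$level ~ f, xlab = "Sprinzl position",
                    ylab = "modification level", ...)
  invisible(x)
}

#' Write a site-call table as TSV
#' @param x A `psi_calls`.
#' @param path Output path.
#' @param extra_headers Optional named character vector of `#key=value`
#'   header lines.
#' @export
write_psi_calls <- function(x, path, extra_headers = NULL) {
  out <- x$calls
  names(out)[names(out) == "pos"] <- "pos_1based"
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(treated_id = x$treated_id, control_id = x$control_id,
            condition = x$condition, replicate = as.character(x$replicate),
            extra_headers)
  writeLines(sprintf("#%s=%s", names(meta), meta), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-call table written by [write_psi_calls()]
#' @param path Input path.
#' @return The per-site calls data frame (1-based `pos`), with the header
#'   metadata in `attr(, "meta")`.
#' @export
read_psi_calls_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  kv <- strsplit(sub("^#", "", lines[hdr]), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
                          vapply(kv, `[[`, character(1), 1L))
  df <- utils::read.table(text = lines[-hdr], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  names(df)[names(df) == "pos_1based"] <- "pos"
  attr(df, "meta") <- meta
  df
}
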