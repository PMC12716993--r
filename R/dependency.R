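# Wild-type vs knockout comparison: replicate-level summaries, the
# dependency rule (coverage-eligible sites dropping by more than the
# threshold in the knockout), and the box-plot / heat-map style aggregations.

#' Summarize per-replicate calls for one condition
#'
#' Sites absent from a replicate (or with zero treated coverage there)
#' contribute no level to the mean; treated coverages are recorded for every
#' replicate (zero when absent) for eligibility checks.
#'
#' @param calls List of `psi_calls` (one per replicate) from the same
#'   condition, or a single `psi_calls`.
#' @param condition Expected condition; taken from the first element when
#'   `NULL`. A mismatch across replicates is an error.
#' @return A data frame of class `"condition_summary"`: one row per site with
#'   `mean_level`, `n_rep`, and list columns `levels`, `coverages`.
#' @export
summarize_levels <- function(calls, condition = NULL) {
  if (inherits(calls, "psi_calls")) calls <- list(calls)
  conds <- vapply(calls, `[[`, character(1), "condition")
  condition <- condition %||% conds[1]
  if (!all(conds == condition)) {
    psimap_abort(sprintf("condition mismatch across replicates: %s",
                         paste(unique(conds), collapse = " / ")),
                 "psimap_usage_error")
  }
  long <- do.call(rbind, lapply(seq_along(calls), function(i) {
    df <- calls[[i]]$calls
    df$.rep <- i
    df[, c("ref_id", "pos", "sprinzl_label", "compartment", "level",
           "cov_treated", ".rep")]
  }))
  n_rep <- length(calls)
  pieces <- split(long, site_key(long$ref_id, long$pos))
  rows <- lapply(pieces, function(g) {
    covs <- numeric(n_rep)
    covs[g$.rep] <- g$cov_treated
    lv <- g$level[g$cov_treated > 0]
    data.frame(
      ref_id = g$ref_id[1], pos = g$pos[1], sprinzl_label = g$sprinzl_label[1],
      compartment = g$compartment[1], condition = condition,
      n_rep = length(lv), mean_level = if (length(lv)) mean(lv) else NA_real_,
      levels = I(list(lv)), coverages = I(list(covs)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Classify knockout dependency of pseudouridine sites
#'
#' A site is eligible when every knockout replicate covers it with at least
#' `min_cov` reads, and dependent when, in addition, its mean level drops by
#' more than `delta_thresh` in the knockout. The default reads the drop as an
#' absolute difference in stoichiometry units; `mode = "relative"` uses the
#' fractional reduction instead.
#'
#' @param wt,ko `condition_summary` data frames for the wild-type and
#'   knockout condition (same reference space).
#' @param pus Name of the depleted pseudouridine synthase.
#' @param min_cov Knockout replicate coverage bound (default 20).
#' @param delta_thresh Reduction threshold (default 0.20).
#' @param mode `"absolute"` (default) or `"relative"`.
#' @return A data frame of class `"dependency_calls"`.
#' @export
classify_dependency <- function(wt, ko, pus, min_cov = 20, delta_thresh = 0.20,
                                mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  idx <- match(site_key(wt$ref_id, wt$pos), site_key(ko$ref_id, ko$pos))
  ko_mean <- rep(NA_real_, nrow(wt))
  eligible <- logical(nrow(wt))
  for (i in seq_len(nrow(wt))) {
    j <- idx[i]
    if (is.na(j)) next
    covs <- ko$coverages[[j]]
    eligible[i] <- all(covs >= min_cov) && is.finite(ko$mean_level[j])
    ko_mean[i] <- ko$mean_level[j]
  }
  delta <- wt$mean_level - ko_mean
  if (mode == "relative") delta <- delta / wt$mean_level
  dependent <- eligible & !is.na(delta) & delta > delta_thresh
  out <- data.frame(
    ref_id = wt$ref_id, pos = wt$pos, sprinzl_label = wt$sprinzl_label,
    pus = pus, wt_mean = wt$mean_level, ko_mean = ko_mean, delta = delta,
    eligible = eligible, dependent = dependent, stringsAsFactors = FALSE
  )
  class(out) <- c("dependency_calls", "data.frame")
  out
}

#' Position- and isodecoder-level aggregations
#'
#' `position_table` groups site levels by (Sprinzl label, condition) and
#' reports the box-plot statistics: n, median, quartiles (linear
#' interpolation), whisker bounds at 1.5 x IQR, and the raw points.
#' `dependency_matrix` is an isodecoder x PUS matrix of level drops at one
#' chosen label (the classic position-55 redundancy heat map).
#'
#' @param summaries A `condition_summary` or list of them.
#' @param deps Optional `dependency_calls` (or rbind of several, one per PUS).
#' @param matrix_label Sprinzl label for the dependency matrix (default
#'   `"55"`).
#' @return List with `position_table` (data frame) and `dependency_matrix`
#'   (numeric matrix or `NULL`).
#' @export
aggregate_views <- function(summaries, deps = NULL, matrix_label = "55") {
  if (inherits(summaries, "condition_summary")) summaries <- list(summaries)
  long <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(sprinzl_label = ifelse(is.na(s$sprinzl_label), "unassigned",
                                      s$sprinzl_label),
               condition = s$condition, level = s$mean_level,
               stringsAsFactors = FALSE)
  }))
  long <- long[is.finite(long$level), , drop = FALSE]
  groups <- split(long, list(long$sprinzl_label, long$condition), drop = TRUE)
  position_table <- do.call(rbind, lapply(groups, function(g) {
    x <- g$level
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    lo <- min(x[x >= qs[1] - 1.5 * iqr])
    hi <- max(x[x <= qs[3] + 1.5 * iqr])
    data.frame(sprinzl_label = g$sprinzl_label[1], condition = g$condition[1],
               n = length(x), q1 = qs[1], median = qs[2], q3 = qs[3],
               whisker_lo = lo, whisker_hi = hi, points = I(list(x)),
               stringsAsFactors = FALSE)
  }))
  ord <- order(sprinzl_rank(position_table$sprinzl_label),
               position_table$condition)
  position_table <- position_table[ord, , drop = FALSE]
  rownames(position_table) <- NULL

  dependency_matrix <- NULL
  if (!is.null(deps) && nrow(deps)) {
    dd <- deps[!is.na(deps$sprinzl_label) & deps$sprinzl_label == matrix_label, ,
               drop = FALSE]
    if (nrow(dd)) {
      dependency_matrix <- tapply(dd$delta, list(dd$ref_id, dd$pus), mean)
    }
  }
  list(position_table = position_table, dependency_matrix = dependency_matrix)
}
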