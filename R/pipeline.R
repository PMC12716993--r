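# Deterministic orchestration of the analysis stages over a structured
# config: simulate -> call -> compare -> motif -> pretrna. Every output TSV
# carries the package version, a config hash and the seed; a rerun with
# identical inputs is byte-identical.

pipeline_error <- function(stage, why) {
  psimap_abort(sprintf("stage '%s': %s", stage, why), "psimap_orchestration_error")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

run_headers <- function(config, seed) {
  c(psimap_version = as.character(utils::packageVersion("psimap")),
    config_hash = config_hash(config), seed = as.character(seed))
}

write_tsv <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(meta), meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_refs_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  genes <- lapply(seq_len(nrow(df)), function(i) {
    trna_gene(df$gene_id[i], df$sequence[i],
              structure = if (nzchar(df$structure[i])) df$structure[i] else NULL,
              compartment = df$compartment[i],
              cca_appended = df$cca_appended[i] == "TRUE", type = df$type[i])
  })
  new_ref_set(genes)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order under one seed, writing
#' deterministic TSV outputs (and a run log) below `out_dir`. The config is a
#' YAML file or a list with optional blocks `sim` (overrides for
#' [sim_config()]), `thresholds` ([psi_thresholds()] overrides), `dependency`
#' (`min_cov`, `delta_thresh`, `mode`), `motif` (`u`, `d`, `pseudocount`,
#' `min_freq`), and `pretrna` (`leader_len`, `trailer_len`, `intron_len`).
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "call", "compare", "motif",
#'   "pretrna")`.
#' @param seed Overrides `config$seed` (default 1 when neither is given).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = c("simulate", "call", "compare", "motif",
                                    "pretrna"),
                         seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- seed %||% config$seed %||% 1L
  meta <- run_headers(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  sim_dir <- file.path(out_dir, "sim")
  call_dir <- file.path(out_dir, "call")

  th <- do.call(psi_thresholds, config$thresholds %||% list())
  dep_opts <- utils::modifyList(list(min_cov = 20, delta_thresh = 0.20,
                                     mode = "absolute"),
                                config$dependency %||% list())
  motif_opts <- utils::modifyList(list(u = 5L, d = 8L, pseudocount = 0.01,
                                       min_freq = 0.15),
                                  config$motif %||% list())
  pre_opts <- utils::modifyList(list(leader_len = 12L, trailer_len = 10L,
                                     intron_len = 20L),
                                config$pretrna %||% list())

  manifest_path <- file.path(sim_dir, "manifest.tsv")
  refs_meta_path <- file.path(sim_dir, "refs_meta.tsv")

  # ---- simulate ------------------------------------------------------------
  if ("simulate" %in% stages) {
    dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                 config$sim %||% list()))
    sim <- simulate_experiment(cfg)
    seqs <- ref_sequences(sim$refs)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                                file.path(sim_dir, "refs.fasta"))
    refs_meta <- data.frame(
      gene_id = names(seqs),
      type = vapply(unclass(sim$refs), `[[`, character(1), "type"),
      compartment = vapply(unclass(sim$refs), `[[`, character(1), "compartment"),
      cca_appended = vapply(unclass(sim$refs), `[[`, logical(1), "cca_appended"),
      structure = vapply(unclass(sim$refs), function(g) g$structure %||% "",
                         character(1)),
      sequence = unname(seqs), stringsAsFactors = FALSE
    )
    write_tsv(refs_meta, refs_meta_path, meta)
    write_tsv(sim$truth, file.path(sim_dir, "truth.tsv"), meta)
    man <- do.call(rbind, lapply(sim$libraries, function(lib) {
      path <- file.path(sim_dir, paste0("counts_", lib$library_id, ".tsv"))
      write_counts_tsv(lib, path, extra_headers = meta)
      data.frame(library_id = lib$library_id, role = lib$role,
                 condition = lib$condition, replicate = lib$replicate,
                 path = basename(path), stringsAsFactors = FALSE)
    }))
    write_tsv(man, manifest_path, meta)
    note("simulate: %d reference(s), %d planted site(s), %d library(ies)",
         length(sim$refs), nrow(sim$truth), length(sim$libraries))
  }

  load_manifest <- function(stage) {
    if (!file.exists(manifest_path)) {
      pipeline_error(stage, "missing upstream artifact from stage 'simulate'")
    }
    utils::read.table(manifest_path, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE)
  }

  # ---- call ----------------------------------------------------------------
  if ("call" %in% stages) {
    man <- load_manifest("call")
    refs <- read_refs_meta(refs_meta_path)
    types <- vapply(unclass(refs), `[[`, character(1), "type")
    trna_refs <- refs[types == "trna"]
    spike_refs <- refs[types == "spikein"]
    dir.create(call_dir, recursive = TRUE, showWarnings = FALSE)
    libs <- lapply(seq_len(nrow(man)), function(i) {
      read_counts_tsv(file.path(sim_dir, man$path[i]))
    })
    names(libs) <- man$library_id

    wt_treated_1 <- man$library_id[man$condition == "WT" &
                                   man$role == "treated" & man$replicate == 1][1]
    fpr <- if (length(spike_refs) && !is.na(wt_treated_1)) {
      estimate_motif_fpr(libs[[wt_treated_1]], spike_refs, source = "spikein")
    } else NULL

    n_called <- 0L
    for (cond in unique(man$condition)) {
      for (r in sort(unique(man$replicate[man$condition == cond]))) {
        tid <- man$library_id[man$condition == cond & man$replicate == r &
                              man$role == "treated"]
        cid <- man$library_id[man$condition == cond & man$replicate == r &
                              man$role == "control"]
        if (!length(tid) || !length(cid)) next
        res <- call_psi(libs[[tid]], libs[[cid]], trna_refs, fpr_model = fpr,
                        thresholds = th)
        n_called <- n_called + sum(res$calls$called)
        write_psi_calls(res, file.path(call_dir,
                                       sprintf("calls_%s_rep%d.tsv",
                                               gsub(":", "-", cond), r)),
                        extra_headers = meta)
        note("call: %s rep %d -> %d candidate(s), %d called", cond, r,
             nrow(res$calls), sum(res$calls$called))
      }
    }
  }

  load_calls <- function(stage) {
    files <- if (dir.exists(call_dir)) {
      list.files(call_dir, pattern = "^calls_.*\\.tsv$", full.names = TRUE)
    } else character(0)
    if (!length(files)) {
      pipeline_error(stage, "missing upstream artifact from stage 'call'")
    }
    out <- lapply(files, read_psi_calls_tsv)
    names(out) <- basename(files)
    out
  }

  fake_psi_calls <- function(df, meta_attr) {
    structure(list(calls = df, condition = meta_attr[["condition"]],
                   replicate = as.integer(meta_attr[["replicate"]])),
              class = "psi_calls")
  }

  # ---- compare -------------------------------------------------------------
  if ("compare" %in% stages) {
    tabs <- load_calls("compare")
    byc <- split(tabs, vapply(tabs, function(t) attr(t, "meta")[["condition"]],
                              character(1)))
    summaries <- lapply(names(byc), function(cond) {
      summarize_levels(lapply(byc[[cond]], function(df) {
        fake_psi_calls(df, attr(df, "meta"))
      }))
    })
    names(summaries) <- names(byc)
    if (!"WT" %in% names(summaries)) pipeline_error("compare", "no WT calls")
    wt <- summaries[["WT"]]
    called_keys <- unique(unlist(lapply(byc[["WT"]], function(df) {
      site_key(df$ref_id[df$called], df$pos[df$called])
    })))
    wt_called <- wt[site_key(wt$ref_id, wt$pos) %in% called_keys, , drop = FALSE]
    deps <- list()
    for (cond in setdiff(names(summaries), "WT")) {
      pus <- sub("^K[OD]:", "", cond)
      deps[[cond]] <- classify_dependency(wt_called, summaries[[cond]], pus,
                                          min_cov = dep_opts$min_cov,
                                          delta_thresh = dep_opts$delta_thresh,
                                          mode = dep_opts$mode)
    }
    dep_all <- if (length(deps)) do.call(rbind, deps) else NULL
    views <- aggregate_views(unname(summaries), dep_all)
    pt <- views$position_table
    pt$points <- NULL
    write_tsv(pt, file.path(out_dir, "position_table.tsv"), meta)
    if (!is.null(dep_all)) {
      rownames(dep_all) <- NULL
      write_tsv(dep_all, file.path(out_dir, "dependency.tsv"), meta)
    }
    if (!is.null(views$dependency_matrix)) {
      dm <- data.frame(isodecoder = rownames(views$dependency_matrix),
                       views$dependency_matrix, check.names = FALSE)
      write_tsv(dm, file.path(out_dir, "dependency_matrix.tsv"), meta)
    }
    note("compare: %d condition(s), %d dependency record(s)",
         length(summaries), if (is.null(dep_all)) 0L else nrow(dep_all))
  }

  # ---- motif ---------------------------------------------------------------
  if ("motif" %in% stages) {
    tabs <- load_calls("motif")
    refs <- read_refs_meta(refs_meta_path)
    wt_tabs <- Filter(function(t) attr(t, "meta")[["condition"]] == "WT", tabs)
    if (!length(wt_tabs)) pipeline_error("motif", "no WT calls")
    wt1 <- wt_tabs[[1]]
    win <- extract_windows(wt1, refs, u = motif_opts$u, d = motif_opts$d)
    if (!nrow(win)) pipeline_error("motif", "no motif windows from called sites")
    pfm <- build_pfm(win, pseudocount = motif_opts$pseudocount)
    write_pfm_tsv(pfm, file.path(out_dir, "pfm_WT.tsv"), meta)
    cons <- iupac_consensus(pfm, min_freq = motif_opts$min_freq)
    writeLines(c(sprintf("#consensus=%s", cons)), file.path(out_dir, "motif_WT.txt"))
    for (t2 in Filter(function(t) attr(t, "meta")[["condition"]] != "WT", tabs)) {
      cond <- attr(t2, "meta")[["condition"]]
      win2 <- extract_windows(t2, refs, u = motif_opts$u, d = motif_opts$d)
      if (!nrow(win2)) next
      dm <- diff_motif(pfm, build_pfm(win2, pseudocount = motif_opts$pseudocount))
      write_tsv(data.frame(offset = dm$offsets, jsd_bits = dm$jsd,
                           dA = dm$contrib["A", ], dC = dm$contrib["C", ],
                           dG = dm$contrib["G", ], dT = dm$contrib["T", ]),
                file.path(out_dir, sprintf("diff_motif_%s.tsv",
                                           gsub(":", "-", cond))), meta)
    }
    note("motif: consensus %s from %d window(s)", cons, nrow(win))
  }

  # ---- pretrna -------------------------------------------------------------
  if ("pretrna" %in% stages) {
    if (!file.exists(refs_meta_path)) {
      pipeline_error("pretrna", "missing upstream artifact from stage 'simulate'")
    }
    tabs <- load_calls("pretrna")
    wt_tabs <- Filter(function(t) attr(t, "meta")[["condition"]] == "WT", tabs)
    if (!length(wt_tabs)) pipeline_error("pretrna", "no WT calls")
    mature_tab <- wt_tabs[[1]]
    refs <- read_refs_meta(refs_meta_path)
    types <- vapply(unclass(refs), `[[`, character(1), "type")
    cands <- mature_tab[mature_tab$called &
                        mature_tab$ref_id %in% names(refs)[types == "trna"], ,
                        drop = FALSE]
    if (!nrow(cands)) pipeline_error("pretrna", "no called mature sites")
    gene <- refs[[cands$ref_id[1]]]
    cfg <- do.call(sim_config, utils::modifyList(list(seed = seed),
                                                 config$sim %||% list()))
    set.seed(seed + 77L)
    pre <- simulate_pre_gene(gene, leader_len = pre_opts$leader_len,
                             trailer_len = pre_opts$trailer_len,
                             intron_len = pre_opts$intron_len)
    gsites <- cands[cands$ref_id == gene$gene_id, , drop = FALSE]
    exonic <- which(!pre_region_mask(pre))
    m_of_p <- map_pre_to_mature(pre, exonic)
    pre_truth <- data.frame(
      pre_pos = exonic[match(gsites$pos, m_of_p)],
      theta_pre = ifelse(gsites$sprinzl_label %in% c("54", "55"),
                         gsites$level, 0),   # early T-loop installation
      theta_mature = gsites$level
    )
    pre_truth <- pre_truth[!is.na(pre_truth$pre_pos), , drop = FALSE]
    pools <- simulate_pre_reads(cfg, pre, pre_truth, gene)
    verdict <- classify_pre_read(pools$pre_treated, pre)
    kept <- pools$pre_treated[verdict == "keep", , drop = FALSE]
    kept_ctrl <- pools$pre_control[
      classify_pre_read(pools$pre_control, pre) == "keep", , drop = FALSE]
    pre_refs <- new_ref_set(list(trna_gene(pre$gene_id, pre$sequence,
                                           compartment = gene$compartment)))
    pre_tr <- pileup(kept, pre_refs, "pre_treated", "treated")
    pre_ct <- pileup(kept_ctrl, pre_refs, "pre_control", "control")
    pre_calls <- call_psi(pre_tr, pre_ct, pre_refs, fpr_model = NULL,
                          thresholds = psi_thresholds(
                            min_cov = th$min_cov_dependency,
                            max_q = th$max_q),
                          expressed = pre$gene_id)
    cmp <- compare_pre_mature(pre_calls, mature_tab, list(pre),
                              min_cov = th$min_cov_dependency)
    write_tsv(cmp, file.path(out_dir, "pre_mature.tsv"), meta)
    note("pretrna: %s -> %d kept / %d read(s), %d compared site(s)",
         pre$gene_id, nrow(kept), length(verdict), nrow(cmp))
  }

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
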