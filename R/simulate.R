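# Seeded generator of miniature conversion-sequencing experiments: cloverleaf tRNA
# references with planted pseudouridine stoichiometries, unmodified
# spike-ins, treated/control/knockout count libraries with context-dependent
# background conversion, and precursor-tRNA read pools.

#' Default per-context background conversion rates
#'
#' Chemical false conversion is weakly context dependent; flanking guanosines
#' raise the rate threefold each and flanking cytidines 1.5-fold, from a
#' baseline of 0.001 (range 0.001-0.009, capped at 0.01).
#'
#' @return Named numeric vector over the 16 `"xTy"` trinucleotide contexts.
#' @export
default_context_fpr <- function() {
  ctx <- as.vector(outer(DNA_BASES, DNA_BASES, function(a, b) paste0(a, "T", b)))
  eps <- vapply(ctx, function(cc) {
    fl <- c(substr(cc, 1, 1), substr(cc, 3, 3))
    min(0.01, 0.001 * 3^sum(fl == "G") * 1.5^sum(fl == "C"))
  }, numeric(1))
  eps
}

#' Default planted-site classes
#'
#' Each class plants, with probability `prob` per eligible gene, a site at
#' the Sprinzl label with stoichiometry drawn uniformly from
#' `[theta_min, theta_max]`, attributed to one synthase. The mix mirrors the
#' dominant tRNA pseudouridine positions: near-universal 55, frequent 54/13,
#' anticodon-arm 38/32/31, and variable-loop e12 on long-arm genes.
#'
#' @return List of class definitions.
#' @export
default_site_classes <- function() {
  list(
    list(label = "55", prob = 0.90, theta_min = 0.60, theta_max = 0.95, pus = "TRUB1"),
    list(label = "54", prob = 0.25, theta_min = 0.40, theta_max = 0.90, pus = "PUS10"),
    list(label = "13", prob = 0.30, theta_min = 0.30, theta_max = 0.90, pus = "PUS7"),
    list(label = "38", prob = 0.15, theta_min = 0.30, theta_max = 0.80, pus = "PUS3"),
    list(label = "32", prob = 0.20, theta_min = 0.20, theta_max = 0.70, pus = "RPUSD2"),
    list(label = "31", prob = 0.10, theta_min = 0.05, theta_max = 0.25, pus = "RPUSD2"),
    list(label = "e12", prob = 0.50, theta_min = 0.30, theta_max = 0.80, pus = "PUS7L")
  )
}

#' Simulation configuration
#'
#' @param seed Mandatory RNG seed.
#' @param n_genes Number of tRNA genes.
#' @param fraction_mito Fraction of mitochondrially encoded genes.
#' @param variable_arm_fraction Fraction of cytosolic genes with a long
#'   variable arm (e-positions).
#' @param coverage Either `list(type = "fixed", mean = )` or
#'   `list(type = "nb", mean = , dispersion = )` (negative binomial per
#'   position per library).
#' @param gamma Conversion efficiency of the chemistry at a true site.
#' @param context_fpr Named per-context background conversion rates.
#' @param t2r_rate Background T->R (A/G) miscall rate.
#' @param replicates Replicates per condition.
#' @param ko_drop Named numeric vector: PUS name -> absolute stoichiometry
#'   drop at its sites in the corresponding knockout condition.
#' @param site_classes See [default_site_classes()].
#' @param n_spikeins,spikein_length Unmodified spike-in references.
#' @param pre_read_length,pre_depth,mature_depth Precursor read simulation.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed, n_genes = 50L, fraction_mito = 0.10,
                       variable_arm_fraction = 0.15,
                       coverage = list(type = "fixed", mean = 200),
                       gamma = 0.98, context_fpr = default_context_fpr(),
                       t2r_rate = 0.002, replicates = 2L,
                       ko_drop = c(TRUB1 = 0.5),
                       site_classes = default_site_classes(),
                       n_spikeins = 4L, spikein_length = 150L,
                       pre_read_length = 45L, pre_depth = 400L,
                       mature_depth = 400L) {
  if (missing(seed) || !is_count(seed)) {
    psimap_abort("a non-negative integer seed is mandatory", "psimap_config_error")
  }
  probs <- c(fraction_mito, variable_arm_fraction, gamma, t2r_rate, context_fpr,
             vapply(site_classes, function(cl) {
               c(cl$prob, cl$theta_min, cl$theta_max)
             }, numeric(3)))
  if (any(probs < 0 | probs > 1)) {
    psimap_abort("probabilities must lie in [0, 1]", "psimap_config_error")
  }
  if (!coverage$type %in% c("fixed", "nb")) {
    psimap_abort("coverage$type must be 'fixed' or 'nb'", "psimap_config_error")
  }
  if (length(ko_drop) && (any(ko_drop < 0 | ko_drop > 1) || is.null(names(ko_drop)))) {
    psimap_abort("ko_drop must be a named vector of drops in [0, 1]",
                 "psimap_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         fraction_mito = fraction_mito,
         variable_arm_fraction = variable_arm_fraction, coverage = coverage,
         gamma = gamma, context_fpr = context_fpr, t2r_rate = t2r_rate,
         replicates = as.integer(replicates), ko_drop = ko_drop,
         site_classes = site_classes, n_spikeins = as.integer(n_spikeins),
         spikein_length = as.integer(spikein_length),
         pre_read_length = as.integer(pre_read_length),
         pre_depth = as.integer(pre_depth),
         mature_depth = as.integer(mature_depth)),
    class = "sim_config"
  )
}

AA_CODES <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")

# One cloverleaf gene: returns list(sequence, structure) including 3'-CCA.
build_sim_gene <- function(long_arm, dloop_len, anticodon) {
  piece <- function(s, db) list(s = s, db = db)
  acc5 <- random_bases(7L)
  dstem5 <- random_bases(4L)
  ac5 <- random_bases(5L)
  t5 <- paste0(random_bases(4L), "G")           # G53 precedes the T-loop
  tloop <- paste0("TTC", sample(c("A", "G"), 1L), "A", random_bases(2L))
  acloop <- paste0(random_bases(1L), "T", anticodon, random_bases(2L))
  var <- if (long_arm) {
    e5 <- random_bases(3L)
    piece(paste0(random_bases(2L), e5, random_bases(4L), revcomp(e5)),
          paste0("..", "(((", "....", ")))"))
  } else {
    piece(random_bases(5L), ".....")
  }
  parts <- list(
    piece(acc5, strrep("(", 7L)),
    piece(random_bases(2L), ".."),
    piece(dstem5, "(((("),
    piece(random_bases(dloop_len), strrep(".", dloop_len)),
    piece(revcomp(dstem5), "))))"),
    piece(random_bases(1L), "."),
    piece(ac5, "((((("),
    piece(acloop, "......."),
    piece(revcomp(ac5), ")))))"),
    var,
    piece(t5, "((((("),
    piece(tloop, "......."),
    piece(revcomp(t5), ")))))"),
    piece(revcomp(acc5), ")))))))"),
    piece(random_bases(1L), "."),
    piece("CCA", "...")
  )
  list(sequence = paste(vapply(parts, `[[`, character(1), "s"), collapse = ""),
       structure = paste(vapply(parts, `[[`, character(1), "db"), collapse = ""))
}

# Column name used for a condition's stoichiometry in the truth table.
theta_column <- function(condition) paste0("theta_", gsub(":", "_", condition))

#' Planted stoichiometry of truth sites under one condition
#' @param truth The truth data frame from [simulate_experiment()].
#' @param condition Condition string (e.g. `"WT"`, `"KO:TRUB1"`).
#' @return Numeric vector of planted stoichiometries.
#' @export
truth_theta <- function(truth, condition) {
  col <- theta_column(condition)
  if (!col %in% names(truth)) {
    psimap_abort(sprintf("condition '%s' absent from truth", condition),
                 "psimap_usage_error")
  }
  truth[[col]]
}

#' Simulate a complete miniature experiment
#'
#' Generates cloverleaf-consistent tRNA references (canonical numbering
#' succeeds on every gene), plants pseudouridine sites per the configured
#' classes (forcing a T at the planted position, and the Watson-Crick partner
#' when paired), adds unmodified spike-ins, and draws treated/control count
#' libraries for the wild type and one knockout condition per entry of
#' `ko_drop`. At a reference-T position with stoichiometry theta, treated
#' T->C counts are Binomial(n, theta * gamma + (1 - theta) * eps(context)),
#' control counts Binomial(n, eps(context)); T->R miscalls are
#' Binomial(n, t2r_rate) split evenly between A and G. Everything is
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `refs` (a `ref_set` of tRNAs + spike-ins), `maps`
#'   (Sprinzl maps), `truth` (planted-site data frame with per-condition
#'   stoichiometries), `libraries` (named list of `library_counts`),
#'   `conditions`, and `config`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  conditions <- c("WT", if (length(cfg$ko_drop)) paste0("KO:", names(cfg$ko_drop)))

  # --- references -----------------------------------------------------------
  genes <- vector("list", cfg$n_genes)
  maps <- vector("list", cfg$n_genes)
  truth_rows <- list()
  for (i in seq_len(cfg$n_genes)) {
    mito <- stats::runif(1) < cfg$fraction_mito
    long_arm <- !mito && stats::runif(1) < cfg$variable_arm_fraction
    dloop_len <- sample(c(8L, 9L, 10L, 11L), 1L, prob = c(0.55, 0.25, 0.12, 0.08))
    anticodon <- random_bases(3L)
    id <- sprintf("%stRNA-%s-%s-%d", if (mito) "mt-" else "",
                  sample(AA_CODES, 1L), anticodon, i)
    g <- build_sim_gene(long_arm, dloop_len, anticodon)
    gene <- trna_gene(id, g$sequence, structure = g$structure,
                      cca_appended = TRUE, type = "trna")
    map <- assign_sprinzl(gene)
    chars <- strsplit(gene$sequence, "", fixed = TRUE)[[1]]
    pt <- pair_table(substr(gene$structure, 1L, nchar(gene$structure) - 3L), id)

    for (cl in cfg$site_classes) {
      idx <- match(cl$label, map$labels)
      if (is.na(idx)) next
      if (stats::runif(1) >= cl$prob) next
      chars[idx] <- "T"
      if (idx <= length(pt) && pt[idx] > 0L) chars[pt[idx]] <- "A"
      theta <- stats::runif(1, cl$theta_min, cl$theta_max)
      row <- data.frame(gene_id = id, pos = idx, sprinzl_label = cl$label,
                        pus = cl$pus, stringsAsFactors = FALSE)
      for (cond in conditions) {
        drop <- if (cond == "WT") 0 else {
          ko <- sub("^KO:", "", cond)
          if (cl$pus == ko) cfg$ko_drop[[ko]] else 0
        }
        row[[theta_column(cond)]] <- max(0, theta - drop)
      }
      truth_rows[[length(truth_rows) + 1L]] <- row
    }
    genes[[i]] <- trna_gene(id, paste(chars, collapse = ""),
                            structure = gene$structure, cca_appended = TRUE,
                            type = "trna")
    maps[[i]] <- map
  }
  names(maps) <- vapply(genes, `[[`, character(1), "gene_id")

  spikes <- lapply(seq_len(cfg$n_spikeins), function(i) {
    trna_gene(sprintf("spikein-%d", i), random_bases(cfg$spikein_length),
              type = "spikein")
  })
  refs <- new_ref_set(c(genes, spikes))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(gene_id = character(0), pos = integer(0),
               sprinzl_label = character(0), pus = character(0))

  # --- per-position model table --------------------------------------------
  seqs <- ref_sequences(refs)
  master <- do.call(rbind, lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    data.frame(ref_id = id, pos = seq_len(nchar(s)),
               ref_base = strsplit(s, "", fixed = TRUE)[[1]],
               stringsAsFactors = FALSE)
  }))
  master$ctx <- seq_context(seqs[master$ref_id], master$pos, 3L)
  eps_global <- mean(cfg$context_fpr)
  master$eps <- ifelse(is.na(master$ctx), eps_global,
                       unname(cfg$context_fpr[master$ctx]))
  master$eps[is.na(master$eps)] <- eps_global
  theta <- matrix(0, nrow = nrow(master), ncol = length(conditions),
                  dimnames = list(NULL, conditions))
  if (nrow(truth)) {
    at <- match(site_key(truth$gene_id, truth$pos),
                site_key(master$ref_id, master$pos))
    for (cond in conditions) theta[at, cond] <- truth_theta(truth, cond)
  }
  is_t <- master$ref_base == "T"
  L <- nrow(master)

  # --- libraries ------------------------------------------------------------
  draw_cov <- function() {
    if (cfg$coverage$type == "fixed") rep(as.integer(cfg$coverage$mean), L)
    else stats::rnbinom(L, mu = cfg$coverage$mean, size = cfg$coverage$dispersion)
  }
  libraries <- list()
  for (cond in conditions) {
    for (r in seq_len(cfg$replicates)) {
      for (role in c("treated", "control")) {
        n <- draw_cov()
        nA <- nC <- nG <- nT <- integer(L)
        rate <- if (role == "treated") {
          theta[, cond] * cfg$gamma + (1 - theta[, cond]) * master$eps
        } else {
          master$eps
        }
        tt <- which(is_t)
        C <- stats::rbinom(length(tt), n[tt], rate[tt])
        R <- stats::rbinom(length(tt), n[tt], cfg$t2r_rate)
        R <- pmin(R, n[tt] - C)
        A <- stats::rbinom(length(tt), R, 0.5)
        nC[tt] <- C
        nA[tt] <- A
        nG[tt] <- R - A
        nT[tt] <- n[tt] - C - R
        for (b in c("A", "C", "G")) {
          bb <- which(master$ref_base == b)
          if (b == "A") nA[bb] <- n[bb]
          if (b == "C") nC[bb] <- n[bb]
          if (b == "G") nG[bb] <- n[bb]
        }
        sites <- data.frame(ref_id = master$ref_id, pos = master$pos,
                            ref_base = master$ref_base, nA = nA, nC = nC,
                            nG = nG, nT = nT, nDel = 0L,
                            stringsAsFactors = FALSE)
        sites <- sites[n > 0L, , drop = FALSE]
        id <- sprintf("%s_rep%d_%s", gsub(":", "-", cond), r, role)
        libraries[[id]] <- library_counts(id, role, cond, r, sites)
      }
    }
  }

  list(refs = refs, maps = maps, truth = truth, libraries = libraries,
       conditions = conditions, config = cfg)
}

#' Build a precursor gene for a simulated mature tRNA
#'
#' Adds a random 5'-leader and 3'-trailer (and optionally an intron inserted
#' 3' of a chosen Sprinzl position, canonically 37) around the mature body
#' minus CCA. Uses the current RNG stream.
#'
#' @param gene A CCA-appended `trna_gene`.
#' @param leader_len,trailer_len,intron_len Segment lengths (intron 0 for an
#'   intron-free precursor).
#' @param intron_after_label Sprinzl label 5' of the intron insertion point.
#' @return A [pre_trna_gene()].
#' @export
simulate_pre_gene <- function(gene, leader_len = 12L, trailer_len = 10L,
                              intron_len = 0L, intron_after_label = "37") {
  if (!isTRUE(gene$cca_appended)) {
    psimap_abort("simulate_pre_gene expects a CCA-appended mature gene",
                 "psimap_config_error")
  }
  body <- substr(gene$sequence, 1L, nchar(gene$sequence) - 3L)
  leader <- random_bases(leader_len)
  trailer <- random_bases(trailer_len)
  if (intron_len > 0L) {
    cut <- sprinzl_position(assign_sprinzl(gene), intron_after_label)
    if (is.na(cut)) {
      psimap_abort(sprintf("label '%s' absent from gene '%s'",
                           intron_after_label, gene$gene_id),
                   "psimap_config_error")
    }
    intron <- random_bases(intron_len)
    seqfull <- paste0(leader, substr(body, 1L, cut), intron,
                      substr(body, cut + 1L, nchar(body)), trailer)
    introns <- list(c(leader_len + cut + 1L, leader_len + cut + intron_len))
  } else {
    seqfull <- paste0(leader, body, trailer)
    introns <- list()
  }
  n <- nchar(seqfull)
  pre_trna_gene(paste0("pre-", gene$gene_id), seqfull,
                leader = c(1L, leader_len),
                trailer = c(n - trailer_len + 1L, n), introns = introns,
                mature_gene_id = gene$gene_id,
                mature_sequence = gene$sequence)
}

# Draw gapless reads over one reference with per-position conversion probs.
draw_sim_reads <- function(refseq, ref_id, n_reads, read_len, p_conv, prefix) {
  cols <- data.frame(read_id = character(0), ref_id = character(0),
                     start = integer(0), strand = character(0),
                     bases = character(0), stringsAsFactors = FALSE)
  if (n_reads == 0L) return(cols)
  L <- nchar(refseq)
  if (read_len > L) {
    psimap_abort("read length exceeds reference length", "psimap_config_error")
  }
  chars <- strsplit(refseq, "", fixed = TRUE)[[1]]
  starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
  bases <- vapply(seq_len(n_reads), function(i) {
    idx <- seq(starts[i], length.out = read_len)
    v <- chars[idx]
    flip <- v == "T" & stats::runif(read_len) < p_conv[idx]
    v[flip] <- "C"
    paste(v, collapse = "")
  }, character(1))
  data.frame(read_id = sprintf("%s-%d", prefix, seq_len(n_reads)),
             ref_id = ref_id, start = starts, strand = "sense", bases = bases,
             stringsAsFactors = FALSE)
}

#' Simulate precursor and mature read pools for one gene
#'
#' Draws treated and control read pools over the precursor reference (planted
#' precursor-stage stoichiometries at `truth$pre_pos`) and a disjoint mature
#' pool over the linked mature reference (mature-stage stoichiometries at the
#' mapped positions), under the same conversion/background model as
#' [simulate_experiment()]. Seeded from `cfg$seed + 101` so the main
#' experiment stream is untouched.
#'
#' @param cfg A [sim_config()].
#' @param pre A `pre_trna_gene`.
#' @param truth Data frame with `pre_pos`, `theta_pre`, `theta_mature`.
#' @param mature_gene The linked mature `trna_gene`.
#' @return List of read data frames: `pre_treated`, `pre_control`,
#'   `mature_treated`, `mature_control`.
#' @export
simulate_pre_reads <- function(cfg, pre, truth, mature_gene) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 101L)
  conv_profile <- function(refseq, theta_at) {
    L <- nchar(refseq)
    theta <- numeric(L)
    theta[theta_at$pos] <- theta_at$theta
    ctx <- seq_context(rep(refseq, L), seq_len(L), 3L)
    eps <- unname(cfg$context_fpr[ctx])
    eps[is.na(eps)] <- mean(cfg$context_fpr)
    list(treated = theta * cfg$gamma + (1 - theta) * eps, control = eps)
  }
  pp <- conv_profile(pre$sequence,
                     data.frame(pos = truth$pre_pos, theta = truth$theta_pre))
  mpos <- map_pre_to_mature(pre, truth$pre_pos)
  ok <- !is.na(mpos)
  mp <- conv_profile(mature_gene$sequence,
                     data.frame(pos = mpos[ok], theta = truth$theta_mature[ok]))
  list(
    pre_treated = draw_sim_reads(pre$sequence, pre$gene_id, cfg$pre_depth,
                                 cfg$pre_read_length, pp$treated, "preT"),
    pre_control = draw_sim_reads(pre$sequence, pre$gene_id, cfg$pre_depth,
                                 cfg$pre_read_length, pp$control, "preC"),
    mature_treated = draw_sim_reads(mature_gene$sequence, mature_gene$gene_id,
                                    cfg$mature_depth, cfg$pre_read_length,
                                    mp$treated, "matT"),
    mature_control = draw_sim_reads(mature_gene$sequence, mature_gene$gene_id,
                                    cfg$mature_depth, cfg$pre_read_length,
                                    mp$control, "matC")
  )
}
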