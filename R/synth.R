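# Multi-cohort simulator: expression cohorts with batch effects, intrinsic
# subtype structure, bimodal marker genes, a PDL1-upregulated subpopulation,
# subtype-specific survival hazards and pCR odds, and PDL1-locus copy-number
# gains. All randomness flows from the seed in the configuration.

SUBTYPES <- c("LumA", "LumB", "Basal", "ERBB2", "NormalLike")

MARKER_GENES <- c(er = "ESR1", pr = "PGR", erbb2 = "ERBB2",
                  ki67 = "MKI67", pdl1 = "CD274")

#' Simulation configuration
#'
#' Builds and validates the parameter set for [generate_cohorts()]. Defaults
#' encode the study conditions the package emulates: five intrinsic subtypes
#' at proportions 28/23/22/15/12%, per-subtype PDL1-upregulation prevalence
#' implying ~20% overall (38% in basal), basal-specific protective hazard
#' ratios (0.55 for metastasis-free survival, 0.52 for breast-cancer-specific
#' survival) in the upregulated group, pCR odds ratios of 4.3 (basal) and 6.5
#' (ERBB2-enriched), and basal-enriched copy-number gains at the PDL1 locus
#' (17% vs 2%).
#'
#' Baseline exponential hazards are parameterized so that the no-upregulation
#' basal group has a 44% 5-year metastasis-free rate and a 68% 5-year
#' disease-specific rate, and the pooled cohort about 61% / 82%.
#'
#' @param n_datasets number of independent cohorts.
#' @param samples_per_dataset tumor samples per cohort.
#' @param n_genes total genes on the simulated array (must accommodate the 5
#'   marker genes, the subtype panel and the signature genes).
#' @param n_normal_per_dataset normal-breast samples appended to each cohort.
#' @param subtype_proportions named fractions over the five subtypes, sum 1.
#' @param pdl1_up_prevalence named per-subtype probability of true PDL1
#'   upregulation.
#' @param batch_location_sd SD (log2 units) of the per-dataset per-gene
#'   additive shift.
#' @param batch_scale_range interval for the per-dataset multiplicative scale
#'   factor.
#' @param marker_mode_separation distance (log2 units) between the negative
#'   and positive modes of the bimodal marker genes; also the raw offset of
#'   PDL1-upregulated tumors over normal breast.
#' @param hr_mfs,hr_oss named per-subtype hazard ratios (upregulated vs not)
#'   for the two endpoints.
#' @param pcr_or named per-subtype odds ratios of pathological complete
#'   response for upregulated vs not.
#' @param baseline_pcr_rate pCR probability in the no-upregulation group.
#' @param pcr_fraction fraction of tumors with neoadjuvant response recorded.
#' @param censoring_rate probability a subject receives random uniform
#'   censoring on (0, 120) months; all follow-up is truncated at 180 months.
#' @param baseline_hazard_mfs,baseline_hazard_oss named per-subtype
#'   exponential hazards (events per month) in the no-upregulation group.
#' @param n_signature_genes number of genes truly differentially expressed
#'   between PDL1 groups (80% up, 20% down).
#' @param signature_effect log2 fold change of the true signature genes.
#' @param cna_gain_prob named per-subtype probability of a DNA copy gain at
#'   the PDL1 locus.
#' @param seed integer seed; identical configurations generate bit-identical
#'   data.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_datasets = 5L,
                       samples_per_dataset = 300L,
                       n_genes = 2000L,
                       n_normal_per_dataset = 10L,
                       subtype_proportions = c(LumA = 0.28, LumB = 0.23,
                                               Basal = 0.22, ERBB2 = 0.15,
                                               NormalLike = 0.12),
                       pdl1_up_prevalence = c(LumA = 0.088, LumB = 0.150,
                                              Basal = 0.380, ERBB2 = 0.270,
                                              NormalLike = 0.118),
                       batch_location_sd = 1.0,
                       batch_scale_range = c(0.8, 1.25),
                       marker_mode_separation = 3.0,
                       hr_mfs = c(LumA = 1, LumB = 1, Basal = 0.55,
                                  ERBB2 = 1, NormalLike = 1),
                       hr_oss = c(LumA = 1, LumB = 1, Basal = 0.52,
                                  ERBB2 = 1, NormalLike = 1),
                       pcr_or = c(LumA = 1, LumB = 1, Basal = 4.3,
                                  ERBB2 = 6.5, NormalLike = 1),
                       baseline_pcr_rate = 0.21,
                       pcr_fraction = 0.3,
                       censoring_rate = 0.3,
                       baseline_hazard_mfs = c(LumA = 0.006978,
                                               LumB = 0.006978,
                                               Basal = 0.013677,
                                               ERBB2 = 0.006978,
                                               NormalLike = 0.006978),
                       baseline_hazard_oss = c(LumA = 0.002523,
                                               LumB = 0.002523,
                                               Basal = 0.006428,
                                               ERBB2 = 0.002523,
                                               NormalLike = 0.002523),
                       n_signature_genes = 100L,
                       signature_effect = 1.5,
                       cna_gain_prob = c(LumA = 0.02, LumB = 0.02,
                                         Basal = 0.17, ERBB2 = 0.02,
                                         NormalLike = 0.02),
                       seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              samples_per_dataset = as.integer(samples_per_dataset),
              n_genes = as.integer(n_genes),
              n_normal_per_dataset = as.integer(n_normal_per_dataset),
              subtype_proportions = subtype_proportions,
              pdl1_up_prevalence = pdl1_up_prevalence,
              batch_location_sd = batch_location_sd,
              batch_scale_range = batch_scale_range,
              marker_mode_separation = marker_mode_separation,
              hr_mfs = hr_mfs, hr_oss = hr_oss, pcr_or = pcr_or,
              baseline_pcr_rate = baseline_pcr_rate,
              pcr_fraction = pcr_fraction,
              censoring_rate = censoring_rate,
              baseline_hazard_mfs = baseline_hazard_mfs,
              baseline_hazard_oss = baseline_hazard_oss,
              n_signature_genes = as.integer(n_signature_genes),
              signature_effect = signature_effect,
              cna_gain_prob = cna_gain_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_datasets", "samples_per_dataset", "n_genes",
              "n_normal_per_dataset")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0L)
      stop("configuration error: '", f, "' must be a non-negative count")
  }
  if (cfg$n_datasets < 1L || cfg$samples_per_dataset < 1L)
    stop("configuration error: need at least one dataset and one sample")
  for (f in c("subtype_proportions", "pdl1_up_prevalence", "hr_mfs",
              "hr_oss", "pcr_or", "cna_gain_prob",
              "baseline_hazard_mfs", "baseline_hazard_oss")) {
    v <- cfg[[f]]
    if (!all(SUBTYPES %in% names(v)))
      stop("configuration error: '", f, "' must name all subtypes: ",
           paste(SUBTYPES, collapse = ", "))
  }
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
    stop("configuration error: subtype_proportions must sum to 1")
  fracs <- c(cfg$subtype_proportions, cfg$pdl1_up_prevalence,
             cfg$baseline_pcr_rate, cfg$pcr_fraction, cfg$censoring_rate,
             cfg$cna_gain_prob)
  if (any(fracs < 0 | fracs > 1))
    stop("configuration error: all fractions must lie in [0, 1]")
  if (any(c(cfg$hr_mfs, cfg$hr_oss, cfg$pcr_or) <= 0))
    stop("configuration error: hazard and odds ratios must be positive")
  min_genes <- length(MARKER_GENES) + 10L + cfg$n_signature_genes
  if (cfg$n_genes < min_genes)
    stop("configuration error: n_genes must be at least ", min_genes,
         " to hold markers, subtype panel and signature genes")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  cat(sprintf("  %d dataset(s) x %d tumors (+%d normal breast), %d genes, seed %d\n",
              x$n_datasets, x$samples_per_dataset, x$n_normal_per_dataset,
              x$n_genes, x$seed))
  cat("  subtype proportions:",
      paste(sprintf("%s=%.2f", names(x$subtype_proportions),
                    x$subtype_proportions), collapse = " "), "\n")
  cat("  PDL1-up prevalence:",
      paste(sprintf("%s=%.2f", names(x$pdl1_up_prevalence),
                    x$pdl1_up_prevalence), collapse = " "), "\n")
  invisible(x)
}

sim_gene_ids <- function(cfg) {
  n_panel <- min(50L, cfg$n_genes - length(MARKER_GENES) -
                       cfg$n_signature_genes)
  panel <- sprintf("SP%03d", seq_len(n_panel))
  sig <- sprintf("SIG%04d", seq_len(cfg$n_signature_genes))
  n_fill <- cfg$n_genes - length(MARKER_GENES) - n_panel - length(sig)
  fill <- if (n_fill > 0L) sprintf("FG%05d", seq_len(n_fill)) else character()
  list(markers = unname(MARKER_GENES), panel = panel, signature = sig,
       filler = fill,
       all = c(unname(MARKER_GENES), panel, sig, fill))
}

# deterministic subtype -> marker-mode map, before label noise
marker_mode_for_subtype <- function(subtype) {
  cbind(er    = subtype %in% c("LumA", "LumB"),
        pr    = subtype %in% c("LumA", "LumB"),
        erbb2 = subtype == "ERBB2",
        ki67  = subtype %in% c("LumB", "Basal", "ERBB2"))
}

#' Generate synthetic multi-cohort expression and clinical data
#'
#' Draws `n_datasets` cohorts sharing a gene space but carrying
#' dataset-specific location/scale batch effects. Tumors receive an intrinsic
#' subtype, bimodal receptor/proliferation marker expression (5% label
#' noise), a true PDL1-upregulation state with subtype-specific prevalence,
#' exponential survival times with subtype- and group-specific hazards,
#' independent censoring, a per-subtype logistic pCR outcome, and a true
#' copy-number gain state at the PDL1 locus (gains add half the signature
#' effect to PDL1 expression). Roughly every tenth gene is represented by two
#' probes (the second a noisier, attenuated copy), and five unmapped junk
#' probes are appended, to exercise probe collapse.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `cohorts` (list of `expression_cohort`),
#'   `clinical` (data frame of per-sample covariates and endpoints),
#'   `truth` (list of `samples` and `genes` truth tables), and `centroids`
#'   (gene-by-subtype matrix over the subtype panel, for the classifier).
#' @export
generate_cohorts <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ids <- sim_gene_ids(config)
  genes <- ids$all
  n_genes <- length(genes)

  mu <- stats::rnorm(n_genes, mean = 7, sd = 1)
  names(mu) <- genes
  # subtype centroids over the panel genes
  centroids <- matrix(stats::rnorm(length(ids$panel) * 5L, 0, 1.5),
                      nrow = length(ids$panel), ncol = 5L,
                      dimnames = list(ids$panel, SUBTYPES))
  # signature membership: first 80% up, rest down in the PDL1-up group
  n_up <- ceiling(0.8 * length(ids$signature))
  sig_dir <- ifelse(seq_along(ids$signature) <= n_up, 1, -1)
  gene_truth <- data.frame(
    gene_id = genes,
    class = c(rep("marker", length(ids$markers)),
              rep("panel", length(ids$panel)),
              ifelse(sig_dir > 0, "signature_up", "signature_down"),
              rep("filler", length(ids$filler))),
    de_effect = c(rep(0, length(ids$markers) + length(ids$panel)),
                  sig_dir * config$signature_effect,
                  rep(0, length(ids$filler))),
    stringsAsFactors = FALSE)
  # PDL1 itself is truly higher in the up group
  gene_truth$de_effect[gene_truth$gene_id == "CD274"] <-
    config$marker_mode_separation

  cohorts <- vector("list", config$n_datasets)
  clin_all <- vector("list", config$n_datasets)
  truth_all <- vector("list", config$n_datasets)
  sep <- config$marker_mode_separation

  for (d in seq_len(config$n_datasets)) {
    did <- sprintf("DS%02d", d)
    n_t <- config$samples_per_dataset
    n_n <- config$n_normal_per_dataset
    tumor_ids <- sprintf("%s_T%04d", did, seq_len(n_t))
    normal_ids <- if (n_n > 0L) sprintf("%s_N%03d", did, seq_len(n_n))
                  else character()

    subtype <- sample(SUBTYPES, n_t, replace = TRUE,
                      prob = config$subtype_proportions[SUBTYPES])
    up <- stats::rbinom(n_t, 1L,
                        config$pdl1_up_prevalence[subtype]) == 1L
    cna_gain <- stats::rbinom(n_t, 1L,
                              config$cna_gain_prob[subtype]) == 1L
    modes <- marker_mode_for_subtype(subtype)
    # 5% marker label noise, independent per marker
    for (m in colnames(modes)) {
      flip <- stats::runif(n_t) < 0.05
      modes[flip, m] <- !modes[flip, m]
    }

    expr <- matrix(stats::rnorm(n_genes * n_t, 0, 0.75),
                   nrow = n_genes, ncol = n_t,
                   dimnames = list(genes, tumor_ids))
    expr <- expr + mu
    expr[ids$panel, ] <- expr[ids$panel, ] + centroids[, subtype]
    for (m in names(MARKER_GENES)[1:4]) {
      g <- MARKER_GENES[[m]]
      expr[g, ] <- mu[g] + ifelse(modes[, m], sep, 0) +
        stats::rnorm(n_t, 0, 0.75)
    }
    # PDL1: normal-breast baseline mu["CD274"]; upregulated tumors sit one
    # bimodal separation above it, others at baseline; copy gains add half
    # the signature effect
    expr["CD274", ] <- mu["CD274"] + ifelse(up, sep, 0) +
      ifelse(cna_gain, config$signature_effect / 2, 0) +
      stats::rnorm(n_t, 0, 0.3)
    expr[ids$signature, ] <- expr[ids$signature, ] +
      outer(sig_dir * config$signature_effect, as.numeric(up))

    if (n_n > 0L) {
      nb <- matrix(stats::rnorm(n_genes * n_n, 0, 0.75),
                   nrow = n_genes, ncol = n_n,
                   dimnames = list(genes, normal_ids))
      nb <- nb + mu
      nb[ids$panel, ] <- nb[ids$panel, ] + centroids[, "NormalLike"]
      for (g in MARKER_GENES[1:4])
        nb[g, ] <- mu[g] + stats::rnorm(n_n, 0, 0.75)
      nb["CD274", ] <- mu["CD274"] + stats::rnorm(n_n, 0, 0.3)
      expr <- cbind(expr, nb)
    }

    # probe layer: every 10th gene gets a noisier attenuated second probe,
    # plus unmapped junk probes
    dup <- genes[seq_len(n_genes) %% 10L == 0L]
    probe_expr <- expr
    rownames(probe_expr) <- paste0(genes, "_1")
    if (length(dup) > 0L) {
      second <- 0.5 * expr[dup, , drop = FALSE] +
        matrix(stats::rnorm(length(dup) * ncol(expr), 0, 0.5),
               nrow = length(dup))
      rownames(second) <- paste0(dup, "_2")
      probe_expr <- rbind(probe_expr, second)
    }
    junk <- matrix(stats::rnorm(5L * ncol(expr), 5, 1), nrow = 5L,
                   dimnames = list(sprintf("JUNK%d", 1:5),
                                   colnames(probe_expr)))
    probe_expr <- rbind(probe_expr, junk)
    probe_map <- data.frame(
      probe_id = c(paste0(genes, "_1"), paste0(dup, "_2")),
      gene_id = c(genes, dup), stringsAsFactors = FALSE)

    # batch effect: global scale then per-probe additive shift
    scale_d <- stats::runif(1, config$batch_scale_range[1],
                            config$batch_scale_range[2])
    shift_d <- stats::rnorm(nrow(probe_expr), 0, config$batch_location_sd)
    probe_expr <- probe_expr * scale_d + shift_d

    roles <- c(rep("tumor", n_t), rep("normal_breast", n_n))
    names(roles) <- c(tumor_ids, normal_ids)
    cohorts[[d]] <- expression_cohort(dataset_id = did,
                                      platform = paste0("synth_", d),
                                      matrix = probe_expr,
                                      probe_map = probe_map,
                                      sample_roles = roles)

    # clinical covariates and outcomes (tumors only)
    age <- pmin(90, pmax(25, round(stats::rnorm(n_t, 58, 12))))
    grade_prob <- rbind(LumA = c(0.30, 0.50, 0.20),
                        LumB = c(0.10, 0.50, 0.40),
                        Basal = c(0.02, 0.18, 0.80),
                        ERBB2 = c(0.02, 0.18, 0.80),
                        NormalLike = c(0.30, 0.50, 0.20))
    grade <- vapply(subtype, function(s)
      sample(1:3, 1L, prob = grade_prob[s, ]), integer(1))
    pt <- ifelse(stats::runif(n_t) < 0.40, "pT1", "pT2-4")
    pn <- ifelse(stats::runif(n_t) < 0.50, "positive", "negative")
    histotype <- sample(c("DUC", "LOB", "MED", "MIX", "OTH"), n_t,
                        replace = TRUE,
                        prob = c(0.81, 0.07, 0.02, 0.04, 0.06))

    surv_draw <- function(base, hr) {
      rate <- base[subtype] * ifelse(up, hr[subtype], 1)
      t_ev <- stats::rexp(n_t, rate)
      cens <- ifelse(stats::runif(n_t) < config$censoring_rate,
                     stats::runif(n_t, 0, 120), 180)
      time <- pmax(1, ceiling(pmin(t_ev, cens)))
      list(time = time, event = as.integer(t_ev <= cens))
    }
    mfs <- surv_draw(config$baseline_hazard_mfs, config$hr_mfs)
    oss <- surv_draw(config$baseline_hazard_oss, config$hr_oss)

    p_pcr <- stats::plogis(stats::qlogis(config$baseline_pcr_rate) +
                             log(config$pcr_or[subtype]) * up)
    pcr <- ifelse(stats::runif(n_t) < config$pcr_fraction,
                  stats::rbinom(n_t, 1L, p_pcr), NA_integer_)

    clin_all[[d]] <- data.frame(
      sample_id = c(tumor_ids, normal_ids),
      dataset_id = did,
      role = roles,
      age = c(age, rep(NA_real_, n_n)),
      pT = c(pt, rep(NA_character_, n_n)),
      pN = c(pn, rep(NA_character_, n_n)),
      grade = c(grade, rep(NA_integer_, n_n)),
      histotype = c(histotype, rep(NA_character_, n_n)),
      mfs_time = c(mfs$time, rep(NA_real_, n_n)),
      mfs_event = c(mfs$event, rep(NA_integer_, n_n)),
      oss_time = c(oss$time, rep(NA_real_, n_n)),
      oss_event = c(oss$event, rep(NA_integer_, n_n)),
      pcr = c(pcr, rep(NA_integer_, n_n)),
      row.names = NULL, stringsAsFactors = FALSE)

    truth_all[[d]] <- data.frame(
      sample_id = tumor_ids,
      dataset_id = did,
      subtype = subtype,
      pdl1_up = up,
      er = modes[, "er"], pr = modes[, "pr"],
      erbb2 = modes[, "erbb2"], ki67 = modes[, "ki67"],
      cna_gain = cna_gain,
      row.names = NULL, stringsAsFactors = FALSE)
  }

  list(cohorts = cohorts,
       clinical = do.call(rbind, clin_all),
       truth = list(samples = do.call(rbind, truth_all),
                    genes = gene_truth),
       centroids = centroids)
}

#' Generate PDL1-locus copy-number log2 ratios
#'
#' Emits one log2 DNA copy ratio per tumor at the PDL1 locus. Samples whose
#' truth record carries a gain receive a ratio of at least log2(1.5) (about
#' 35% of gains reach the 2-fold amplification threshold); the remainder sit
#' in the neutral band.
#'
#' @param config the [sim_config()] used to generate the cohorts.
#' @param truth the `truth` element returned by [generate_cohorts()].
#' @return data frame with `sample_id`, `locus` and `log2_ratio`.
#' @export
generate_cna <- function(config, truth) {
  validate_sim_config(config)
  if (is.null(truth$samples))
    stop("truth tables missing; run generate_cohorts() first")
  set.seed(config$seed + 1L)
  s <- truth$samples
  n <- nrow(s)
  ratio <- pmin(0.55, pmax(-0.55, stats::rnorm(n, 0, 0.15)))
  gained <- which(s$cna_gain)
  if (length(gained) > 0L)
    ratio[gained] <- stats::runif(length(gained), log2(1.5), 1.3)
  data.frame(sample_id = s$sample_id, locus = "CD274",
             log2_ratio = ratio, stringsAsFactors = FALSE)
}

#' Write a simulated study to disk in plain-text formats
#'
#' Expression is written one TSV per dataset (probes x samples, log2),
#' the clinical table as CSV, probe map / CNA / truth tables as TSV, the
#' subtype centroids as TSV and the configuration as YAML.
#'
#' @param sim result of [generate_cohorts()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @param cna optional result of [generate_cna()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, config, dir, cna = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (co in sim$cohorts) {
    write_expression_tsv(co$matrix,
                         file.path(dir, paste0("expression_", co$dataset_id,
                                               ".tsv")))
  }
  utils::write.table(sim$cohorts[[1]]$probe_map,
                     file.path(dir, "probe_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  write_centroids_tsv(sim$centroids, file.path(dir, "centroids.tsv"))
  utils::write.table(sim$truth$samples, file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cna))
    utils::write.table(cna, file.path(dir, "cna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$batch_scale_range <- as.numeric(cfg$batch_scale_range)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
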