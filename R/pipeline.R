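# End-to-end orchestration: load or simulate cohorts, integrate, call
# markers and subtypes, and emit the report tables (clinicopathological
# associations, univariate Cox, basal-subtype Cox, pCR analysis, signature
# and metagene validation) plus a JSON run summary.

#' Read the clinical table (CSV)
#'
#' Expected columns: `sample_id`, `dataset_id`, `role`, covariates (`age`,
#' `pT`, `pN`, `grade`, `histotype`), endpoints (`mfs_time`, `mfs_event`,
#' `oss_time`, `oss_event`, `pcr`). Missing values are empty fields.
#' @param path file path.
#' @return data frame.
#' @export
read_clinical_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a probe annotation map (TSV with columns probe_id, gene_id)
#' @param path file path.
#' @return data frame.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    stop("probe map must have columns probe_id and gene_id")
  df
}

load_pipeline_inputs <- function(config) {
  if (identical(config$mode, "synth")) {
    args <- config$synth
    if (!is.null(args)) {
      for (f in c("subtype_proportions", "pdl1_up_prevalence", "hr_mfs",
                  "hr_oss", "pcr_or", "cna_gain_prob",
                  "baseline_hazard_mfs", "baseline_hazard_oss"))
        if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
      if (!is.null(args$batch_scale_range))
        args$batch_scale_range <- as.numeric(unlist(args$batch_scale_range))
    }
    if (is.null(args$seed) && !is.null(config$seed)) args$seed <- config$seed
    scfg <- do.call(sim_config, args %||% list())
    sim <- generate_cohorts(scfg)
    cna <- generate_cna(scfg, sim$truth)
    list(cohorts = sim$cohorts, clinical = sim$clinical,
         centroids = sim$centroids, cna = cna, sim_config = scfg)
  } else if (identical(config$mode, "files")) {
    f <- config$files
    needed <- c(f$expression, f$probe_map, f$clinical, f$centroids, f$cna)
    missing <- needed[!file.exists(needed)]
    if (length(missing) > 0L)
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    clinical <- read_clinical_csv(f$clinical)
    pm <- read_probe_map(f$probe_map)
    cohorts <- lapply(seq_along(f$expression), function(i) {
      m <- read_expression_tsv(f$expression[[i]])
      ids <- intersect(colnames(m), clinical$sample_id)
      roles <- clinical$role[match(ids, clinical$sample_id)]
      names(roles) <- ids
      did <- unique(clinical$dataset_id[match(ids, clinical$sample_id)])[1]
      expression_cohort(dataset_id = did, platform = "user",
                        matrix = m[, ids, drop = FALSE], probe_map = pm,
                        sample_roles = roles)
    })
    cna <- if (!is.null(f$cna)) utils::read.delim(f$cna,
                                                  stringsAsFactors = FALSE)
           else NULL
    list(cohorts = cohorts, clinical = clinical,
         centroids = read_centroids_tsv(f$centroids), cna = cna,
         sim_config = NULL)
  } else {
    stop("config 'mode' must be 'synth' or 'files'")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cox_univariate_rows <- function(clinical, time_col, event_col, vars) {
  rows <- list()
  for (v in names(vars)) {
    res <- tryCatch(
      cox_fit(clinical[[time_col]], clinical[[event_col]],
              stats::setNames(clinical[vars[[v]]], v)),
      error = function(e) NULL)
    if (is.null(res)) {
      rows[[v]] <- data.frame(variable = v, term = NA, n = NA,
                              hr = NA, lower = NA, upper = NA, p = NA)
    } else {
      rows[[v]] <- data.frame(variable = v, term = res$term,
                              n = attr(res, "n"), hr = res$hr,
                              lower = res$lower, upper = res$upper,
                              p = res$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the cohorts, normalizes each dataset (quantile
#' normalization, highest-variance probe collapse), assigns intrinsic
#' subtypes per dataset, standardizes to the luminal-A reference, pools,
#' calls marker and PDL1 statuses, and writes the report tables:
#' `table1_associations.tsv`, `table2_univariate_cox.tsv`,
#' `table3_subtype_cox.tsv`, `table5_pcr.tsv`, `signature_genes.tsv`,
#' `metagene_validation.tsv` and `run_summary.json`. Stage failures are
#' recorded in the summary; independent stages still run.
#'
#' @param config path to a YAML configuration or an equivalent list. Keys:
#'   `mode` (`"synth"` or `"files"`), `seed`, `synth` (simulator parameter
#'   overrides) or `files` (paths: `expression` vector, `probe_map`,
#'   `clinical`, `centroids`, optional `cna`).
#' @param out_dir output directory (created; must not require partial
#'   results — the configuration is validated before anything is written).
#' @return invisibly, the run summary list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  inputs <- load_pipeline_inputs(config)   # validates before any output
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  stages <- list()
  summary <- list(seed = seed,
                  package_version = as.character(utils::packageVersion("pdl1meta")))

  # --- integration -----------------------------------------------------
  cohorts <- lapply(inputs$cohorts, function(co) {
    co$matrix <- quantile_normalize(co$matrix)
    collapse_probes(co)
  })
  subtype_labels <- c()
  cohorts <- lapply(cohorts, function(co) {
    tumor <- names(co$sample_roles)[co$sample_roles == "tumor"]
    labs <- assign_subtypes(co$matrix[, tumor, drop = FALSE],
                            inputs$centroids)
    subtype_labels <<- c(subtype_labels, labs)
    suppressWarnings(standardize_to_reference(co, labs, "LumA"))
  })
  pooled <- pool_cohorts(cohorts)
  clinical <- call_all_markers(pooled, inputs$clinical)
  clinical$subtype <- unname(subtype_labels[clinical$sample_id])
  tumors <- clinical[clinical$role == "tumor", , drop = FALSE]
  tumors$age_group <- ifelse(tumors$age > 50, ">50", "<=50")
  tumors$grade_group <- ifelse(tumors$grade >= 2, "2-3", "1")
  stages$integrate <- "ok"

  summary$n_samples <- nrow(clinical)
  summary$n_tumor <- nrow(tumors)
  summary$n_normal_breast <- sum(clinical$role == "normal_breast")
  summary$subtype_counts <- as.list(table(tumors$subtype))
  summary$pdl1_up_fraction <- mean(tumors$pdl1 == "up")

  run_stage <- function(name, expr) {
    stages[[name]] <<- tryCatch({ expr; "ok" },
      error = function(e) paste("failed:", conditionMessage(e)))
  }

  # --- table 1: clinicopathological associations -----------------------
  run_stage("table1", {
    t1 <- association_table(tumors, "pdl1",
                            c("age_group", "histotype", "pN", "pT",
                              "grade_group", "er", "pr", "erbb2", "ki67",
                              "subtype"))
    out <- as.data.frame(t1)
    p <- attr(t1, "p")
    out$p <- p[out$variable]
    utils::write.table(out, file.path(out_dir, "table1_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- table 2: univariate Cox, whole cohort, MFS ----------------------
  uni_vars <- c(age = "age_group", pT = "pT", pN = "pN",
                grade = "grade_group", er = "er", pr = "pr",
                erbb2 = "erbb2", pdl1 = "pdl1")
  run_stage("table2", {
    t2 <- cox_univariate_rows(tumors, "mfs_time", "mfs_event", uni_vars)
    utils::write.table(t2, file.path(out_dir, "table2_univariate_cox.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- table 3: basal-subtype Cox (MFS and OSS), with multivariate -----
  run_stage("table3", {
    basal <- tumors[!is.na(tumors$subtype) & tumors$subtype == "Basal", ,
                    drop = FALSE]
    t3 <- list()
    for (ep in c("mfs", "oss")) {
      uni <- cox_univariate_rows(basal, paste0(ep, "_time"),
                                 paste0(ep, "_event"), uni_vars)
      uni$endpoint <- ep
      uni$analysis <- "univariate"
      sel_p <- stats::setNames(uni$p, uni$variable)
      sel <- build_multivariate(sel_p)
      if (length(sel) > 1L) {
        mv <- cox_fit(basal[[paste0(ep, "_time")]],
                      basal[[paste0(ep, "_event")]],
                      stats::setNames(basal[uni_vars[sel]], sel))
        mvr <- data.frame(variable = sel, term = mv$term,
                          n = attr(mv, "n"), hr = mv$hr, lower = mv$lower,
                          upper = mv$upper, p = mv$p, endpoint = ep,
                          analysis = "multivariate")
        t3[[ep]] <- rbind(uni, mvr)
      } else t3[[ep]] <- uni
    }
    utils::write.table(do.call(rbind, t3),
                       file.path(out_dir, "table3_subtype_cox.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- interaction tests ----------------------------------------------
  run_stage("interaction", {
    basal_ind <- ifelse(tumors$subtype == "Basal", "basal", "non_basal")
    summary$interaction_mfs_p <- interaction_test(
      tumors$mfs_time, tumors$mfs_event, tumors$pdl1, basal_ind)$p
    summary$interaction_oss_p <- interaction_test(
      tumors$oss_time, tumors$oss_event, tumors$pdl1, basal_ind)$p
  })

  # --- table 5: pCR ----------------------------------------------------
  run_stage("table5", {
    pa <- pcr_analysis(tumors)
    summary$pcr_excluded <- pa$n_excluded
    all_res <- c(list(whole_cohort = pa$overall), pa$by_subtype)
    t5 <- do.call(rbind, lapply(names(all_res), function(nm) {
      r <- all_res[[nm]]
      data.frame(stratum = nm,
                 noup_rd = r$counts[1, 1], noup_pcr = r$counts[1, 2],
                 up_rd = r$counts[2, 1], up_pcr = r$counts[2, 2],
                 pcr_rate_noup = r$rates[1], pcr_rate_up = r$rates[2],
                 p = r$p, or = r$or, lower = r$lower, upper = r$upper,
                 flag = if (r$estimable) "" else "not estimable")
    }))
    utils::write.table(t5, file.path(out_dir, "table5_pcr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- copy number ------------------------------------------------------
  if (!is.null(inputs$cna)) run_stage("cna", {
    cna <- inputs$cna
    states <- call_cna(cna$log2_ratio)
    ids <- intersect(cna$sample_id, colnames(pooled$matrix))
    expr <- pooled$matrix["CD274", ids]
    st <- states[match(ids, cna$sample_id)]
    assoc <- cna_expression_association(st, expr)
    summary$cna_gain_fraction <- mean(st %in% c("gain", "amplification"))
    summary$cna_expression_p <- assoc$p
    summary$cna_expression_t <- assoc$t
  })

  # --- signature: learn on dataset 1, validate on the next two ---------
  run_stage("signature", {
    dsets <- unique(pooled$provenance$dataset_id)
    learn_ids <- tumors$sample_id[tumors$dataset_id == dsets[1]]
    de <- moderated_t(pooled$matrix[, learn_ids, drop = FALSE],
                      factor(tumors$pdl1[match(learn_ids, tumors$sample_id)],
                             levels = c("no_up", "up")))
    sig <- select_signature(de)
    sig_all <- rbind(sig$up, sig$down)
    utils::write.table(sig_all[, c("gene_id", "log2fc", "t", "p", "q",
                                   "direction")],
                       file.path(out_dir, "signature_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_signature_genes <- nrow(sig_all)
    summary$n_signature_up <- nrow(sig$up)
    summary$n_signature_down <- nrow(sig$down)
    if (nrow(sig$up) > 0L && length(dsets) > 1L) {
      model <- fit_metagene(pooled$matrix[, learn_ids, drop = FALSE],
                            sig$up$gene_id,
                            tumors$pdl1[match(learn_ids, tumors$sample_id)])
      val_sets <- utils::head(dsets[-1], 2)
      vrows <- lapply(val_sets, function(ds) {
        vid <- tumors$sample_id[tumors$dataset_id == ds]
        v <- validate_metagene(model, pooled$matrix[, vid, drop = FALSE],
                               tumors$pdl1[match(vid, tumors$sample_id)])
        data.frame(dataset = ds, n = length(vid), accuracy = v$accuracy,
                   fisher_p = v$p, coverage = v$coverage)
      })
      utils::write.table(do.call(rbind, vrows),
                         file.path(out_dir, "metagene_validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary$metagene_threshold <- model$threshold
      summary$metagene_auc <- model$auc
    }
  })

  summary$stages <- stages
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
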