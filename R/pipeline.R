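#' Pipeline run configuration
#'
#' One object describing an end-to-end run: input (PLINK paths or a
#' [simulation_config()]), QC thresholds, the scan groupings, window
#' settings, MDS and admixture settings, and a master seed.
#'
#' Groupings are named lists of breed subsets (e.g.
#' `list(all = NULL, dairy = c("breed1","breed2"))`; `NULL` means all
#' breeds), plus the built-in `one_vs_rest` switch that adds a
#' per-breed focal-vs-pooled-rest contrast.
#'
#' @param input either a [simulation_config()] or
#'   `list(ped = path, map = path)`.
#' @param thresholds a [qc_thresholds()].
#' @param groupings named list of breed subsets to scan (`NULL` entry =
#'   all breeds).
#' @param one_vs_rest also run the per-breed focal-versus-rest scans?
#' @param window_width,window_mode passed to [fst_scan()].
#' @param q_low,q_high scan quantile levels.
#' @param mds_components components for [classical_mds()].
#' @param admixture `NULL` to skip, or a list with `K_range`, `n_runs`,
#'   `n_burnin`, `n_sweeps`.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = simulation_config(),
                       thresholds = qc_thresholds(),
                       groupings = list(all = NULL),
                       one_vs_rest = TRUE,
                       window_width = 8L, window_mode = "groups",
                       q_low = 0.01, q_high = 0.99,
                       mds_components = 3L,
                       admixture = list(K_range = 2:5, n_runs = 5L,
                                        n_burnin = 200L, n_sweeps = 800L),
                       seed = 1L) {
  structure(
    list(input = input, thresholds = thresholds, groupings = groupings,
         one_vs_rest = one_vs_rest, window_width = as.integer(window_width),
         window_mode = window_mode, q_low = q_low, q_high = q_high,
         mds_components = as.integer(mds_components), admixture = admixture,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# tiny rolling hash of the deparsed config, for output provenance stamps
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or PLINK read), the
#' two-pass QC cascade, windowed fixation-index scans for every configured
#' grouping plus optional one-vs-rest contrasts, genomic kinship /
#' classical MDS / cluster geometry, and the multi-run admixture harness
#' with the Evanno delta-K table. All tables are written as TSV under
#' `out_dir` (regions also as BED), a human-readable `report.txt`
#' summarises per-stage dimensions, and every run is a pure function of
#' `(config, seed)` — identical configs give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results (`genotypes`,
#'   `qc`, `scans`, `one_vs_rest`, `kinship`, `embedding`, `geometry`,
#'   `admixture`, `delta_k`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  hash <- config_hash(config)
  say("run: config hash %s, seed %d", hash, config$seed)

  stage <- "input"
  result <- list()
  tryCatch({
    if (inherits(config$input, "simulation_config")) {
      sim <- simulate_panel(config$input)
      gm <- sim$genotypes
      result$truth <- sim$truth
      say("input: simulated panel %d samples x %d markers",
          nrow(gm$dosage), ncol(gm$dosage))
    } else {
      gm <- read_plink_text(config$input$ped, config$input$map)
      say("input: read %s (%d samples x %d markers)", config$input$ped,
          nrow(gm$dosage), ncol(gm$dosage))
    }
    for (grp in config$groupings) {
      if (!is.null(grp) && !all(grp %in% levels(gm$breed)))
        stop(sprintf("grouping names unknown breed(s): %s",
                     paste(setdiff(grp, levels(gm$breed)), collapse = ", ")))
    }

    stage <- "qc"
    qc <- run_qc_pipeline(gm, config$thresholds)
    gm <- qc$genotypes
    write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
    for (st in qc$report$steps) {
      say("qc/%s: -%d samples, -%d markers", st$step,
          st$samples_removed, st$markers_removed)
    }
    say("qc: final panel %d samples x %d markers", nrow(gm$dosage), ncol(gm$dosage))
    result$qc <- qc$report

    stage <- "fst_scan"
    scans <- list()
    for (gname in names(config$groupings)) {
      grp <- config$groupings[[gname]]
      sub <- if (is.null(grp)) gm else
        subset_genotypes(gm, samples = which(gm$breed %in% grp))
      scan <- fst_scan(sub, width = config$window_width,
                       mode = config$window_mode,
                       q_low = config$q_low, q_high = config$q_high)
      write_scan(scan, sub$map, file.path(out_dir, paste0("scan_", gname)))
      say("scan/%s: %d windows, thresholds [%.4f, %.4f], %d high-outlier windows",
          gname, nrow(scan$windows), scan$thresholds["t_low"],
          scan$thresholds["t_high"], sum(scan$windows$outlier_high))
      scans[[gname]] <- scan
    }
    result$scans <- scans

    if (config$one_vs_rest && nlevels(gm$breed) >= 2L) {
      ovr <- list()
      for (b in levels(gm$breed)) {
        grouping <- ifelse(gm$breed == b, b, "rest")
        scan <- fst_scan(gm, grouping, width = config$window_width,
                         mode = config$window_mode,
                         q_low = config$q_low, q_high = config$q_high)
        write_scan(scan, gm$map, file.path(out_dir, paste0("scan_ovr_", b)))
        ovr[[b]] <- scan
        say("scan/one-vs-rest %s: %d high-outlier windows", b,
            sum(scan$windows$outlier_high))
      }
      result$one_vs_rest <- ovr
    }

    stage <- "kinship_mds"
    km <- genomic_kinship(gm)
    dd <- kinship_to_distance(km)
    emb <- classical_mds(dd, config$mds_components)
    geom <- cluster_geometry(emb, gm$breed)
    write_kinship_mds(km, emb, gm$breed, file.path(out_dir, "kinship"))
    say("mds: %d components, %d negative eigenvalue(s) dropped",
        ncol(emb$coordinates), emb$n_negative_eigenvalues)
    result$kinship <- km
    result$embedding <- emb
    result$geometry <- geom

    stage <- "admixture"
    if (!is.null(config$admixture)) {
      adm <- config$admixture
      mr <- multi_run(gm, K_range = adm$K_range, n_runs = adm$n_runs,
                      n_burnin = adm$n_burnin, n_sweeps = adm$n_sweeps,
                      base_seed = config$seed)
      dk <- evanno_delta_k(mr)
      utils::write.table(mr$table, file.path(out_dir, "admixture_runs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(dk$summary, file.path(out_dir, "delta_k.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      best_fit <- gibbs_admixture(gm, dk$best_K, adm$n_burnin, adm$n_sweeps,
                                  seed = config$seed)
      write_q_matrix(best_fit, gm$breed, file.path(out_dir, "q_matrix.tsv"))
      say("admixture: best K = %d (max delta-K %.2f)", dk$best_K,
          max(dk$summary$delta_k, na.rm = TRUE))
      result$admixture <- mr
      result$delta_k <- dk
      result$best_fit <- best_fit
    }
  }, error = function(e) {
    say("ERROR in stage %s: %s", stage, conditionMessage(e))
    writeLines(log_lines, file.path(out_dir, "report.txt"))
    stop(sprintf("pipeline failed in stage %s: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  result$genotypes <- gm
  writeLines(c(sprintf("config_hash\t%s", hash),
               sprintf("seed\t%d", config$seed), log_lines),
             file.path(out_dir, "report.txt"))
  invisible(result)
}
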