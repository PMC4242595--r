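#' Run the tag-profiling pipeline end to end on synthetic data
#'
#' Simulates a genome sized for the configured gene count, builds the
#' virtual tag catalog, simulates paired tumor/normal counts and their
#' error-bearing tag libraries, maps every library back against the
#' catalog (<= 1 mismatch), normalizes to TPM, tests each pair with the
#' Audic-Claverie test + BH, aggregates recurrently deregulated genes, and
#' -- when at least two recurrent genes exist -- clusters the recurrent
#' log2-ratio profiles two-way (average linkage, uncentered Pearson).
#' Because the generator plants known effects, the run report also scores
#' recovery: the fraction of planted genes called recurrent and the
#' empirical false discovery fraction among recurrent calls.
#'
#' Identical `config` (including its seed) reproduces the report exactly.
#'
#' @param config a [sim_config()].
#' @param fold_threshold,fdr_threshold per-pair call thresholds
#'   (fold > 1, FDR < 0.1% by default).
#' @param min_cases,min_avg_fold recurrence thresholds (half the cohort
#'   and average fold > 1 by default).
#' @param out_dir optional directory; when given, the genome FASTA,
#'   annotation BED, count matrices, recurrent-gene table and a JSON run
#'   report are written there.
#' @return object of class `dge_run`: catalog, study, library mapping
#'   summary, TPM matrix, per-pair results, recurrence table, dendrograms
#'   (or NULL) and `report` (the machine-readable summary).
#' @export
run_profiling <- function(config = sim_config(), fold_threshold = 1,
                          fdr_threshold = 0.001, min_cases = NULL,
                          min_avg_fold = 1, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome(n_chrom = 1L,
                            chrom_length = max(200L, config$n_genes * 450L),
                            n_transcripts = config$n_genes,
                            seed = config$seed)
  catalog <- build_tag_catalog(genome)
  study <- simulate_paired_counts(config)
  tags <- simulate_tags(study, catalog, config$tag_error_rate,
                        seed = config$seed + 2L)
  libs <- lapply(names(tags), function(nm)
    map_tags(tags[[nm]], catalog, library_id = nm))
  names(libs) <- names(tags)
  mapping <- data.frame(
    library = names(libs),
    clean_tags = vapply(libs, `[[`, numeric(1), "clean_tag_total"),
    unique_mapped = vapply(libs, `[[`, numeric(1), "unique_mapped_total"),
    ambiguous = vapply(libs, `[[`, numeric(1), "ambiguous"),
    unmapped = vapply(libs, `[[`, numeric(1), "unmapped"),
    stringsAsFactors = FALSE
  )
  mapping$pct_unique <- 100 * mapping$unique_mapped / mapping$clean_tags
  rownames(mapping) <- NULL
  tpm <- tpm_matrix(libs)

  pairs <- lapply(study$patients, function(p)
    call_pair(libs[[paste0(p, "_tumor")]], libs[[paste0(p, "_normal")]],
              fold_threshold = fold_threshold,
              fdr_threshold = fdr_threshold))
  names(pairs) <- study$patients
  rec <- recurrent_genes(pairs, min_cases = min_cases,
                         min_avg_fold = min_avg_fold)

  truth <- study$truth
  planted <- truth$gene[truth$is_de]
  called <- rec$gene_id[rec$is_recurrent]
  recovery <- if (length(planted)) mean(planted %in% called) else NA_real_
  emp_fdr <- if (length(called)) mean(!called %in% planted) else 0

  row_d <- col_d <- NULL
  if (length(called) >= 2 && length(study$patients) >= 2) {
    l2r <- sapply(pairs, `[[`, "log2ratio")
    rownames(l2r) <- pairs[[1]]$gene_id
    prof <- l2r[called, , drop = FALSE]
    row_d <- hierarchical_cluster(prof, "rows")
    col_d <- hierarchical_cluster(prof, "cols")
  }

  report <- list(
    version = as.character(utils::packageVersion("tagdge")),
    parameters = c(unclass(config),
                   list(fold_threshold = fold_threshold,
                        fdr_threshold = fdr_threshold,
                        min_cases = attr(rec, "min_cases"),
                        min_avg_fold = min_avg_fold)),
    catalog = list(n_tags = nrow(catalog$tags),
                   n_canonical = sum(catalog$tags$is_canonical),
                   genome_digest = catalog$genome_digest),
    mapping = mapping,
    de_per_pair = vapply(pairs, function(p) sum(p$is_de), numeric(1)),
    recurrent = list(total = sum(rec$is_recurrent),
                     up = sum(rec$is_recurrent & rec$direction == "up"),
                     down = sum(rec$is_recurrent & rec$direction == "down")),
    recovery = list(planted = length(planted),
                    recovered_fraction = recovery,
                    empirical_fdr = emp_fdr)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome$sequences, file.path(out_dir, "genome.fa"))
    write_bed(genome$annotation, file.path(out_dir, "annotation.bed"))
    write_counts(study$normal, file.path(out_dir, "counts_normal.tsv"))
    write_counts(study$tumor, file.path(out_dir, "counts_tumor.tsv"))
    write.table(as.data.frame(rec), file.path(out_dir, "recurrent.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_report(report, file.path(out_dir, "report.json"))
  }

  structure(list(genome = genome, catalog = catalog, study = study,
                 libraries = libs, mapping = mapping, tpm = tpm,
                 pairs = pairs, recurrence = rec,
                 row_dendro = row_d, col_dendro = col_d,
                 report = report),
            class = "dge_run")
}

#' @export
print.dge_run <- function(x, ...) {
  r <- x$report
  cat("Tag-based DGE profiling run\n")
  cat(sprintf("  catalog: %d virtual tags (%d canonical)\n",
              r$catalog$n_tags, r$catalog$n_canonical))
  cat(sprintf("  libraries: %d; mean %.1f%% uniquely mapped\n",
              nrow(r$mapping), mean(r$mapping$pct_unique)))
  cat(sprintf("  deregulated per pair: %s\n",
              paste(r$de_per_pair, collapse = ", ")))
  cat(sprintf("  recurrent genes: %d (%d up, %d down)\n",
              r$recurrent$total, r$recurrent$up, r$recurrent$down))
  if (!is.na(r$recovery$recovered_fraction))
    cat(sprintf("  planted recovery: %.1f%% of %d planted; empirical FDR %.1f%%\n",
                100 * r$recovery$recovered_fraction, r$recovery$planted,
                100 * r$recovery$empirical_fdr))
  invisible(x)
}

#' Run the staining-score and survival analysis
#'
#' Scores and dichotomizes every marker, builds the clinicopathologic
#' association table, fits per-marker Kaplan-Meier curves with log-rank
#' comparisons, the univariate and multivariate Cox tables, and the
#' combined-marker stratification. With zero events the Kaplan-Meier
#' curves are still emitted but Cox and log-rank are refused with a
#' recorded message.
#'
#' @param cohort a clinical data frame (see [read_clinical()]) or a path
#'   to a clinical TSV.
#' @param markers marker names.
#' @param out_dir optional directory for a JSON report plus KM plot-data
#'   tables.
#' @return object of class `survival_report`: `associations`, `km` (per
#'   marker), `logrank` (per marker), `cox` ([cox_table()] result or
#'   NULL), `combined`, `messages`.
#' @export
run_survival <- function(cohort, markers = c("ALDH2", "CCNE1", "SMAD3"),
                         out_dir = NULL) {
  if (is.character(cohort) && length(cohort) == 1)
    cohort <- read_clinical(cohort, required_markers = markers)
  for (m in markers) {
    gc <- paste0(m, "_group")
    if (is.null(cohort[[gc]])) {
      pc <- paste0(m, "_pct"); ic <- paste0(m, "_intensity")
      if (is.null(cohort[[pc]]) || is.null(cohort[[ic]]))
        stopf("missing marker column `%s` (or `%s`/`%s`)", gc, pc, ic)
      sc <- staining_index(cohort[[pc]], cohort[[ic]])
      cohort[[paste0(m, "_index")]] <- sc$staining_index
      cohort[[gc]] <- sc$group
    }
  }
  msgs <- character(0)
  assoc <- association_tests(cohort, markers)
  km <- lapply(markers, function(m)
    kaplan_meier(cohort, paste0(m, "_group")))
  names(km) <- markers
  n_events <- sum(cohort$event)
  lr <- cox <- combined <- NULL
  if (n_events == 0) {
    msgs <- c(msgs, "zero events: log-rank and Cox regression refused")
  } else {
    lr <- lapply(markers, function(m)
      logrank_test(cohort, paste0(m, "_group")))
    names(lr) <- markers
    cox <- tryCatch(
      cox_table(cohort, covariates = c("sex", "age", "t_stage",
                                       paste0(markers, "_group"))),
      error = function(e) {
        msgs <<- c(msgs, paste("Cox refused:", conditionMessage(e)))
        NULL
      })
    combined <- tryCatch(marker_combination(cohort), error = function(e) {
      msgs <<- c(msgs, paste("combined marker:", conditionMessage(e)))
      NULL
    })
  }
  res <- structure(list(cohort = cohort, associations = assoc, km = km,
                        logrank = lr, cox = cox, combined = combined,
                        n_events = n_events, messages = msgs),
                   class = "survival_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in markers)
      write.table(km[[m]]$table,
                  file.path(out_dir, paste0("km_", m, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    rep <- list(
      n_patients = nrow(cohort), n_events = n_events,
      associations = assoc,
      logrank = if (!is.null(lr)) lapply(lr, function(z)
        list(statistic = z$statistic, p = z$p)),
      multivariate = if (!is.null(cox)) cox$multivariate$table,
      messages = msgs
    )
    write_report(rep, file.path(out_dir, "survival_report.json"))
  }
  res
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("Survival analysis: %d patients, %d events\n",
              nrow(x$cohort), x$n_events))
  cat("  associations (p-values):\n")
  a <- x$associations
  for (i in seq_len(nrow(a)))
    cat(sprintf("    %s vs %s (%s): p = %.3g\n", a$var1[i], a$var2[i],
                a$test[i], a$p[i]))
  if (!is.null(x$logrank))
    for (m in names(x$logrank))
      cat(sprintf("  log-rank %s high vs low: chi2 = %.2f, p = %.3g\n",
                  m, x$logrank[[m]]$statistic, x$logrank[[m]]$p))
  if (!is.null(x$cox)) {
    cat("  multivariate Cox:\n")
    print(x$cox$multivariate)
  }
  if (!is.null(x$combined))
    cat(sprintf("  combined high-risk stratum (A- C+ S+): log-rank chi2 = %.2f, p = %.3g\n",
                x$combined$logrank$statistic, x$combined$logrank$p))
  if (length(x$messages))
    cat("  notes:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Totals of a deposited recurrent-gene list
#'
#' Counts a deposited recurrently-deregulated gene table (columns
#' `gene_id` and `direction`) for comparison against a study's printed
#' totals.
#'
#' @param deposited data frame with `gene_id` and `direction`
#'   (`"up"`/`"down"`).
#' @return named numeric vector: total, up, down.
#' @export
check_published_totals <- function(deposited) {
  stopifnot(is.data.frame(deposited),
            all(c("gene_id", "direction") %in% names(deposited)))
  c(total = nrow(deposited),
    up = sum(deposited$direction == "up"),
    down = sum(deposited$direction == "down"))
}
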