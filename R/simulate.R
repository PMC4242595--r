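#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults describe
#' the package's reference desk-scale study: 10 tumor/normal pairs, 500
#' genes, 5e4 clean tags per library with a lognormal abundance spectrum,
#' 10% of genes planted as differentially expressed at |log2FC| = 3 in 70%
#' of patients, Poisson tag-sampling noise, a 0.2% per-base tag sequencing
#' error rate, and a 103-patient survival cohort with three correlated
#' dichotomized markers each multiplying the hazard by `exp(marker_log_hr)`
#' when in its high-risk state.
#'
#' @param seed integer seed; the same seed reproduces every generator output
#'   byte for byte.
#' @param n_genes number of genes (one transcript each).
#' @param n_patients number of tumor/normal pairs.
#' @param library_size expected clean-tag count per library.
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param planted_log2fc absolute planted log2 fold change (tumor vs normal).
#' @param recurrence fraction of patients in which a planted effect is
#'   applied (`ceiling(recurrence * n_patients)` patients per gene).
#' @param nb_dispersion negative-binomial dispersion of per-library counts;
#'   0 gives Poisson sampling (tag sampling within one library).
#' @param tag_error_rate per-base substitution probability of emitted tags.
#' @param meanlog,sdlog lognormal parameters of the gene abundance spectrum.
#' @param cohort_size number of patients in the survival cohort.
#' @param marker_log_hr per-marker log hazard ratio of the high-risk state.
#' @param censor_rate target fraction of administratively censored patients.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L, n_genes = 500L, n_patients = 10L,
                       library_size = 5e4, de_fraction = 0.1,
                       planted_log2fc = 3, recurrence = 0.7,
                       nb_dispersion = 0, tag_error_rate = 0.002,
                       meanlog = 0, sdlog = 1,
                       cohort_size = 103L, marker_log_hr = 1.0,
                       censor_rate = 0.3) {
  cfg <- list(
    seed = check_count(seed, "seed", min = 0),
    n_genes = check_count(n_genes, "n_genes"),
    n_patients = check_count(n_patients, "n_patients"),
    library_size = check_count(library_size, "library_size"),
    de_fraction = check_prob(de_fraction, "de_fraction"),
    planted_log2fc = as.numeric(planted_log2fc),
    recurrence = check_prob(recurrence, "recurrence"),
    nb_dispersion = as.numeric(nb_dispersion),
    tag_error_rate = check_prob(tag_error_rate, "tag_error_rate"),
    meanlog = as.numeric(meanlog),
    sdlog = as.numeric(sdlog),
    cohort_size = check_count(cohort_size, "cohort_size"),
    marker_log_hr = as.numeric(marker_log_hr),
    censor_rate = check_prob(censor_rate, "censor_rate")
  )
  if (cfg$nb_dispersion < 0) stopf("`nb_dispersion` must be >= 0")
  if (cfg$cohort_size < 10) stopf("`cohort_size` must be >= 10")
  if (cfg$de_fraction > 0 && cfg$de_fraction * cfg$n_genes < 1)
    stopf("de_fraction * n_genes must be >= 1 when de_fraction > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with annotated transcripts
#'
#' Generates uniform-random chromosome sequences and places non-overlapping
#' transcripts on them (random strand). Every transcript is guaranteed to
#' contain at least one usable NlaIII site on its sense strand -- a CATG
#' whose 21-bp tag (CATG + 17 bp downstream in transcription direction)
#' lies fully inside the transcript; when the random sequence lacks one, a
#' CATG is planted at a valid position.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (>= 200).
#' @param n_transcripts total number of transcripts (named `gNNNN.t1`, gene
#'   id `gNNNN`).
#' @param seed integer seed.
#' @param tx_length integer range (min, max) of transcript lengths.
#' @return list of class `dge_genome` with `sequences` (named character
#'   vector) and `annotation` (BED-like data frame: chrom, start, end, name,
#'   score, strand; 0-based half-open).
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_length = 1000L,
                            n_transcripts = 5L, seed = 1L,
                            tx_length = c(150L, 400L)) {
  n_chrom <- check_count(n_chrom, "n_chrom")
  chrom_length <- check_count(chrom_length, "chrom_length", min = 200)
  n_transcripts <- check_count(n_transcripts, "n_transcripts")
  set.seed(seed)

  per_chrom <- rep(n_transcripts %/% n_chrom, n_chrom)
  extra <- n_transcripts %% n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1
  slot <- chrom_length %/% max(per_chrom, 1L)
  min_len <- max(60L, min(tx_length))
  if (slot < min_len + 2L)
    stopf("cannot place %d transcripts of >= %d bp on a %d bp chromosome",
          max(per_chrom), min_len, chrom_length)

  seqs <- character(n_chrom)
  names(seqs) <- sprintf("chr%d", seq_len(n_chrom))
  ann <- vector("list", n_chrom)
  gi <- 0L
  for (ci in seq_len(n_chrom)) {
    chars <- sample(DNA_BASES, chrom_length, replace = TRUE)
    nt <- per_chrom[ci]
    if (nt > 0) {
      starts <- ends <- integer(nt)
      strands <- character(nt)
      for (k in seq_len(nt)) {
        lo <- (k - 1L) * slot
        len <- min(sample(seq(min_len, max(tx_length)), 1L), slot - 2L)
        start <- lo + sample.int(slot - len - 1L, 1L) - 1L
        end <- start + len
        strand <- sample(c("+", "-"), 1L)
        # guarantee a usable sense-strand CATG fully inside the transcript
        s <- paste(chars[(start + 1):end], collapse = "")
        ok <- if (strand == "+") {
          any_catg_with_room(s, downstream = TRUE)
        } else {
          any_catg_with_room(s, downstream = FALSE)
        }
        if (!ok) {
          pos_rel <- if (strand == "+") {
            sample.int(len - 20L, 1L)            # 1-based, leaves >= 17 after
          } else {
            sample(seq(18L, len - 3L), 1L)       # leaves >= 17 before CATG
          }
          chars[(start + pos_rel):(start + pos_rel + 3L)] <-
            c("C", "A", "T", "G")
        }
        starts[k] <- start; ends[k] <- end; strands[k] <- strand
      }
      gid <- sprintf("g%04d", gi + seq_len(nt))
      ann[[ci]] <- data.frame(
        chrom = names(seqs)[ci], start = starts, end = ends,
        name = paste0(gid, ".t1"), score = 0L, strand = strands,
        stringsAsFactors = FALSE
      )
      gi <- gi + nt
    }
    seqs[ci] <- paste(chars, collapse = "")
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  structure(list(sequences = seqs, annotation = annotation),
            class = "dge_genome")
}

# is there a CATG in s with >= 17 bases downstream (plus strand) or
# upstream (minus strand, where the tag runs leftwards in genome space)?
#' @noRd
any_catg_with_room <- function(s, downstream = TRUE) {
  hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(FALSE)
  n <- nchar(s)
  if (downstream) any(hits + 20L <= n) else any(hits >= 18L)
}

#' Simulate paired tumor/normal gene counts
#'
#' Draws a lognormal gene-abundance spectrum shared by all libraries,
#' plants signed log2 fold changes on a random subset of genes (applied in
#' `ceiling(recurrence * n_patients)` patients each, sign fixed per gene),
#' and samples per-library counts as Poisson (`nb_dispersion = 0`) or
#' negative binomial around the library-size-scaled means.
#'
#' @param config a [sim_config()].
#' @return object of class `count_study`: matrices `normal` and `tumor`
#'   (genes x patients), `genes`, `patients`, `library_size`, and `truth`
#'   (per-gene `is_de`, `sign`, `log2fc`, and the affected-patient matrix).
#' @export
simulate_paired_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes; np <- config$n_patients
  genes <- sprintf("g%04d", seq_len(ng))
  patients <- sprintf("P%02d", seq_len(np))

  w <- rlnorm(ng, meanlog = config$meanlog, sdlog = config$sdlog)
  w <- w / sum(w)
  mu <- config$library_size * w
  if (config$library_size < ng)
    warnf("library_size (%g) below n_genes (%d): most genes have expected count < 1",
          config$library_size, ng)

  n_de <- round(config$de_fraction * ng)
  de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
  sgn <- integer(ng)
  if (n_de > 0)
    sgn[de_idx] <- sample(rep(c(1L, -1L), length.out = n_de))
  k_aff <- ceiling(config$recurrence * np)
  affected <- matrix(FALSE, ng, np, dimnames = list(genes, patients))
  for (g in de_idx) affected[g, sample.int(np, k_aff)] <- TRUE

  mu_normal <- matrix(mu, ng, np)
  mu_tumor <- mu_normal *
    2^(sgn * config$planted_log2fc * affected)

  draw <- function(m) {
    x <- if (config$nb_dispersion == 0) {
      rpois(length(m), lambda = m)
    } else {
      rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
    }
    matrix(x, ng, np, dimnames = list(genes, patients))
  }
  normal <- draw(mu_normal)
  tumor <- draw(mu_tumor)

  truth <- data.frame(
    gene = genes, is_de = sgn != 0L, sign = sgn,
    log2fc = sgn * config$planted_log2fc,
    n_affected = rowSums(affected), stringsAsFactors = FALSE
  )
  structure(list(normal = normal, tumor = tumor, genes = genes,
                 patients = patients, library_size = config$library_size,
                 truth = truth, affected = affected, config = config),
            class = "count_study")
}

#' @export
print.count_study <- function(x, ...) {
  cat(sprintf("Paired DGE count study: %d genes x %d patients (tumor + normal)\n",
              length(x$genes), length(x$patients)))
  cat(sprintf("  target library size %g; %d genes planted DE (|log2FC| = %g in %d/%d patients)\n",
              x$library_size, sum(x$truth$is_de), abs(x$config$planted_log2fc),
              ceiling(x$config$recurrence * length(x$patients)),
              length(x$patients)))
  invisible(x)
}

#' Emit sequenced 21-bp tag libraries from a count study
#'
#' Each gene's canonical catalog tag is emitted once per count, with every
#' base independently substituted (to a different base) with probability
#' `tag_error_rate`.
#'
#' @param count_study a [simulate_paired_counts()] result.
#' @param catalog a [build_tag_catalog()] result holding a canonical tag
#'   for every gene of the study.
#' @param tag_error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return named list of class `tag_libraries`; one data frame
#'   (`tag`, `count`) per library, names `<patient>_normal` /
#'   `<patient>_tumor`.
#' @export
simulate_tags <- function(count_study, catalog, tag_error_rate = 0.002,
                          seed = 1L) {
  stopifnot(inherits(count_study, "count_study"),
            inherits(catalog, "tag_catalog"))
  tag_error_rate <- check_prob(tag_error_rate, "tag_error_rate")
  canon <- catalog$tags[catalog$tags$is_canonical, , drop = FALSE]
  canon_seq <- setNames(canon$sequence, canon$gene_id)
  missing <- setdiff(count_study$genes, names(canon_seq))
  if (length(missing))
    stopf("no canonical tag in catalog for gene(s): %s",
          paste(head(missing, 5), collapse = ", "))
  set.seed(seed)

  emit <- function(counts) {
    reads <- rep(canon_seq[count_study$genes], counts)
    if (tag_error_rate > 0 && length(reads)) {
      k <- rbinom(length(reads), 21L, tag_error_rate)
      hit <- which(k > 0)
      if (length(hit)) {
        mut <- vapply(hit, function(i) {
          s <- strsplit(reads[i], "", fixed = TRUE)[[1]]
          pos <- sample.int(21L, k[i])
          for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
          paste(s, collapse = "")
        }, character(1))
        reads[hit] <- mut
      }
    }
    tab <- table(reads)
    data.frame(tag = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }

  libs <- list()
  for (j in seq_along(count_study$patients)) {
    p <- count_study$patients[j]
    libs[[paste0(p, "_normal")]] <- emit(count_study$normal[, j])
    libs[[paste0(p, "_tumor")]] <- emit(count_study$tumor[, j])
  }
  structure(libs, class = "tag_libraries")
}

#' Simulate a marker-dichotomized survival cohort
#'
#' Patients share a latent risk variable that drives three
#' immunohistochemistry markers (ALDH2, CCNE1, SMAD3) and tumor depth, so
#' marker groups are correlated with each other and with T stage. Staining
#' is generated as a proportion percentage plus an intensity grade and
#' scored through [staining_index()]; the high-risk states are low ALDH2,
#' high CCNE1 and high SMAD3. Survival is exponential with the hazard
#' multiplied by `exp(marker_log_hr)` per high-risk marker; censoring is an
#' independent exponential clock calibrated to `censor_rate`.
#'
#' @param config a [sim_config()].
#' @return data frame of class `clinical_cohort`: patient_id, sex, age,
#'   t_stage, per-marker `<M>_pct`, `<M>_intensity`, `<M>_index`,
#'   `<M>_group`, survival `time` (months) and `event` flag. The number of
#'   high-risk marker states per patient is attached as attribute
#'   `n_risk`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$cohort_size
  z <- rnorm(n)

  latent <- list(
    ALDH2 = -1.2 * z + rnorm(n),   # protective marker: risk when LOW
    CCNE1 = 1.2 * z + rnorm(n),
    SMAD3 = 1.2 * z + rnorm(n)
  )
  sd_l <- sqrt(1.2^2 + 1)
  out <- data.frame(patient_id = sprintf("pt%03d", seq_len(n)),
                    sex = sample(c("male", "female"), n, replace = TRUE,
                                 prob = c(0.75, 0.25)),
                    age = round(runif(n, 32, 87)),
                    stringsAsFactors = FALSE)
  tl <- 0.8 * z + rnorm(n)
  qs <- qnorm(c(0.60, 0.75)) * sqrt(0.8^2 + 1)
  out$t_stage <- factor(c("T1", "T2", "T3")[findInterval(tl, qs) + 1L],
                        levels = c("T1", "T2", "T3"))

  risk <- matrix(FALSE, n, 3, dimnames = list(NULL, names(latent)))
  for (m in names(latent)) {
    u <- pnorm(latent[[m]] / sd_l)
    pct <- pmin(100, pmax(0, round(100 * u)))
    intensity <- findInterval(u, c(0.15, 0.45, 0.75))
    sc <- staining_index(pct, intensity)
    out[[paste0(m, "_pct")]] <- pct
    out[[paste0(m, "_intensity")]] <- intensity
    out[[paste0(m, "_index")]] <- sc$staining_index
    out[[paste0(m, "_group")]] <- sc$group
    risk[, m] <- if (m == "ALDH2") sc$group == "low" else sc$group == "high"
  }
  n_risk <- rowSums(risk)

  h0 <- log(2) / 60   # zero-risk median survival of 60 months
  rate <- h0 * exp(config$marker_log_hr * n_risk)
  t_event <- rexp(n, rate)
  rc <- mean(rate) * config$censor_rate / max(1 - config$censor_rate, 1e-8)
  t_cens <- if (rc > 0) rexp(n, rc) else rep(Inf, n)
  out$event <- as.integer(t_event <= t_cens)
  out$time <- pmax(1, round(pmin(t_event, t_cens)))

  attr(out, "n_risk") <- n_risk
  class(out) <- c("clinical_cohort", "data.frame")
  out
}
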