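#' Read / write the pipeline's plain-text formats
#'
#' Strict, documented readers and writers: FASTA genomes (lowercase bases
#' are uppercased on read), BED-like 6-column annotation (chrom, start,
#' end, name, score, strand; 0-based half-open; `end <= start` rejected
#' with its line number), gene x library count matrices (gene ids in the
#' first column), 2-column tag lists (tag, count) and clinical tables.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of uppercase sequences.
#' @name tagdge_io
NULL

#' @rdname tagdge_io
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' @rdname tagdge_io
#' @param sequences named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' @rdname tagdge_io
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stopf("BED file must have 6 columns")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stopf("BED interval with end <= start at line %d", bad[1])
  if (!all(df$strand %in% c("+", "-")))
    stopf("BED strand must be + or -")
  df[, 1:6]
}

#' @rdname tagdge_io
#' @param annotation BED-like data frame.
#' @export
write_bed <- function(annotation, path) {
  write.table(annotation[, c("chrom", "start", "end", "name", "score",
                             "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname tagdge_io
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("count matrix has non-numeric entries")
  rownames(m) <- df[[1]]
  m
}

#' @rdname tagdge_io
#' @param counts gene x library numeric matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tagdge_io
#' @export
read_tags <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tag", "count") %in% names(df)))
    stopf("tag file needs columns `tag` and `count`")
  bad <- which(!grepl("^[ACGTN]+$", df$tag))
  if (length(bad))
    stopf("malformed tag at line %d: %s", bad[1] + 1L, df$tag[bad[1]])
  df
}

#' @rdname tagdge_io
#' @param tags data frame (`tag`, `count`).
#' @export
write_tags <- function(tags, path) {
  write.table(tags[, c("tag", "count")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname tagdge_io
#' @param required_markers marker names whose staining columns must exist.
#' @export
read_clinical <- function(path,
                          required_markers = c("ALDH2", "CCNE1", "SMAD3")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "age", "t_stage", "time", "event",
            paste0(required_markers, "_pct"),
            paste0(required_markers, "_intensity"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("clinical table missing column(s): %s",
          paste(miss, collapse = ", "))
  if (any(df$time <= 0)) stopf("clinical `time` must be positive")
  if (!all(df$event %in% c(0, 1))) stopf("clinical `event` must be 0/1")
  df$t_stage <- factor(df$t_stage, levels = c("T1", "T2", "T3"))
  # (re)derive staining indices and groups from the raw components
  for (m in required_markers) {
    sc <- staining_index(df[[paste0(m, "_pct")]],
                         df[[paste0(m, "_intensity")]])
    df[[paste0(m, "_index")]] <- sc$staining_index
    df[[paste0(m, "_group")]] <- sc$group
  }
  class(df) <- c("clinical_cohort", "data.frame")
  df
}

#' @rdname tagdge_io
#' @param cohort clinical data frame.
#' @export
write_clinical <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname tagdge_io
#' @param report a list (run report).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname tagdge_io
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
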