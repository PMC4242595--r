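#' Build the virtual NlaIII tag catalog of a genome
#'
#' Scans every chromosome, on both strands, for CATG restriction sites with
#' at least 17 usable bases downstream in reading direction and records the
#' 21-bp virtual tag (CATG + 17 bp) at each. CATG is its own reverse
#' complement, so a single genomic site can yield one tag per strand: the
#' plus-strand tag reads rightwards from the site, the minus-strand tag is
#' the reverse complement of the 21-mer ending 4 bases past the site.
#' Tags containing N are dropped. A tag is assigned to a transcript when
#' the full 21-mer lies inside the transcript on its sense strand; the
#' 3'-most assigned site of each transcript is flagged canonical, and tag
#' sequences occurring more than once in the catalog are flagged
#' non-unique.
#'
#' @param genome a [simulate_genome()] result, a named character vector of
#'   uppercase chromosome sequences, or a path to a FASTA file.
#' @param annotation BED-like data frame (chrom, start, end, name, score,
#'   strand; 0-based half-open) or a path to such a TSV; defaults to the
#'   annotation carried by a `dge_genome`. Gene ids derive from the name
#'   column by stripping a trailing `.tN` suffix.
#' @return object of class `tag_catalog`: `tags` (data frame with columns
#'   sequence, chrom, site_position, strand, transcript, gene_id,
#'   is_canonical, is_unique), `transcripts`, `no_canonical` (transcripts
#'   without a usable sense site) and `genome_digest` (md5 of the FASTA
#'   text).
#' @export
build_tag_catalog <- function(genome, annotation = NULL) {
  if (inherits(genome, "dge_genome")) {
    if (is.null(annotation)) annotation <- genome$annotation
    seqs <- genome$sequences
  } else if (is.character(genome) && length(genome) == 1 &&
             file.exists(genome)) {
    seqs <- read_fasta(genome)
  } else if (is.character(genome) && !is.null(names(genome))) {
    seqs <- toupper(genome)
  } else {
    stopf("`genome` must be a dge_genome, a named character vector or a FASTA path")
  }
  if (any(grepl("[^ACGTN]", seqs)))
    stopf("malformed genome: sequences must contain only A/C/G/T/N")
  if (is.character(annotation) && length(annotation) == 1)
    annotation <- read_bed(annotation)
  if (is.null(annotation)) stopf("`annotation` is required")
  bad <- setdiff(unique(annotation$chrom), names(seqs))
  if (length(bad))
    stopf("annotation references unknown chromosome(s): %s",
          paste(bad, collapse = ", "))
  lens <- nchar(seqs)
  if (any(annotation$end > lens[annotation$chrom]) || any(annotation$start < 0))
    stopf("annotation coordinates outside chromosome bounds")

  rows <- vector("list", length(seqs))
  for (ci in seq_along(seqs)) {
    s <- seqs[ci]; len <- lens[ci]
    hits <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    pos0 <- hits - 1L                               # 0-based CATG starts
    plus <- pos0[pos0 + 21L <= len]
    minus <- pos0[pos0 >= 17L]
    plus_seq <- if (length(plus))
      substring(s, plus + 1L, plus + 21L) else character(0)
    minus_seq <- if (length(minus))
      revcomp(substring(s, minus - 16L, minus + 4L)) else character(0)
    df <- data.frame(
      sequence = c(plus_seq, minus_seq),
      chrom = rep(names(seqs)[ci], length(plus) + length(minus)),
      site_position = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      stringsAsFactors = FALSE
    )
    rows[[ci]] <- df[!grepl("N", df$sequence, fixed = TRUE), , drop = FALSE]
  }
  tags <- do.call(rbind, rows)
  if (is.null(tags) || nrow(tags) == 0)
    tags <- data.frame(sequence = character(0), chrom = character(0),
                       site_position = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)

  # full-21-mer interval of each tag in genome coordinates
  tstart <- ifelse(tags$strand == "+", tags$site_position,
                   tags$site_position - 17L)
  tend <- ifelse(tags$strand == "+", tags$site_position + 21L,
                 tags$site_position + 4L)
  tags$transcript <- rep(NA_character_, nrow(tags))
  for (k in seq_len(nrow(annotation))) {
    a <- annotation[k, ]
    m <- is.na(tags$transcript) & tags$chrom == a$chrom &
      tags$strand == a$strand & tstart >= a$start & tend <= a$end
    tags$transcript[m] <- a$name
  }
  tags$gene_id <- ifelse(is.na(tags$transcript), NA_character_,
                         gene_of_transcript(tags$transcript))

  tags$is_canonical <- rep(FALSE, nrow(tags))
  no_canonical <- character(0)
  for (k in seq_len(nrow(annotation))) {
    a <- annotation[k, ]
    idx <- which(!is.na(tags$transcript) & tags$transcript == a$name)
    if (!length(idx)) { no_canonical <- c(no_canonical, a$name); next }
    pick <- if (a$strand == "+") idx[which.max(tags$site_position[idx])]
            else idx[which.min(tags$site_position[idx])]
    tags$is_canonical[pick] <- TRUE
  }
  tags$is_unique <- !(duplicated(tags$sequence) |
                        duplicated(tags$sequence, fromLast = TRUE))
  rownames(tags) <- NULL

  structure(list(tags = tags, transcripts = annotation$name,
                 no_canonical = no_canonical,
                 genome_digest = genome_md5(seqs)),
            class = "tag_catalog")
}

#' @export
print.tag_catalog <- function(x, ...) {
  cat(sprintf("Virtual NlaIII tag catalog: %d tags (%d unique, %d canonical) over %d transcripts\n",
              nrow(x$tags), sum(x$tags$is_unique), sum(x$tags$is_canonical),
              length(x$transcripts)))
  if (length(x$no_canonical))
    cat(sprintf("  %d transcript(s) without a usable sense-strand site\n",
                length(x$no_canonical)))
  cat(sprintf("  genome md5 %s\n", x$genome_digest))
  invisible(x)
}

#' Canonical tag of a transcript
#'
#' The canonical tag is the sense-strand virtual tag whose CATG site is
#' 3'-most within the transcript (largest genomic coordinate on the plus
#' strand, smallest on the minus strand); it represents the transcript's
#' expression in tag counting.
#'
#' @param transcript transcript id (annotation name column).
#' @param catalog a [build_tag_catalog()] result.
#' @return one-row data frame (the tag), or `NULL` when the transcript has
#'   no usable sense-strand site (these are listed in
#'   `catalog$no_canonical`).
#' @export
canonical_tag <- function(transcript, catalog) {
  stopifnot(inherits(catalog, "tag_catalog"))
  if (!transcript %in% catalog$transcripts)
    stopf("unknown transcript id: %s", transcript)
  idx <- which(catalog$tags$is_canonical &
                 !is.na(catalog$tags$transcript) &
                 catalog$tags$transcript == transcript)
  if (!length(idx)) return(NULL)
  catalog$tags[idx, , drop = FALSE]
}

#' @noRd
genome_md5 <- function(seqs) {
  tf <- tempfile(fileext = ".fa")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", seqs), tf)
  unname(tools::md5sum(tf))
}
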