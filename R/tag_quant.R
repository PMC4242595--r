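#' Map observed tags to a catalog with at most one mismatch
#'
#' Best-hit semantics of a short-tag mapper at desk scale, exact by
#' construction: a tag with an exact catalog hit is resolved at mismatch 0;
#' otherwise its full 1-substitution neighborhood (21 x 3 variants) is
#' looked up in an exact-match index. At its best mismatch level a tag is
#' counted to a gene when all hits lie in that single gene; hits spanning
#' two or more distinct genes (or two distinct unannotated sites) make it
#' ambiguous and it is discarded; a tag whose only hits are unannotated
#' catalog sites, or with no hit at all, is unmapped. Two catalog tags of
#' the same gene count once to the gene.
#'
#' @param tag_list data frame with columns `tag` and `count`, or a
#'   character vector of tags (unit counts).
#' @param catalog a [build_tag_catalog()] result.
#' @param max_mismatch 0 or 1 allowed substitutions.
#' @param library_id optional label carried into the result.
#' @return object of class `library_counts`: `clean_tag_total` (all
#'   well-formed tags), `unique_mapped_total`, `gene_counts` (named vector
#'   over the catalog's gene universe), `unmapped`, `ambiguous`,
#'   `malformed`.
#' @export
map_tags <- function(tag_list, catalog, max_mismatch = 1L,
                     library_id = NULL) {
  stopifnot(inherits(catalog, "tag_catalog"))
  if (is.character(tag_list))
    tag_list <- data.frame(tag = tag_list, count = 1L,
                           stringsAsFactors = FALSE)
  stopifnot(is.data.frame(tag_list), all(c("tag", "count") %in% names(tag_list)))
  if (!max_mismatch %in% c(0L, 1L))
    stopf("`max_mismatch` must be 0 or 1")

  ok <- nchar(tag_list$tag) == 21L
  malformed <- sum(tag_list$count[!ok])
  tag_list <- tag_list[ok, , drop = FALSE]
  clean_total <- sum(tag_list$count)

  genes <- sort(unique(catalog$tags$gene_id[!is.na(catalog$tags$gene_id)]))
  gene_counts <- setNames(numeric(length(genes)), genes)
  assign_of <- assign_tags(tag_list$tag, catalog, max_mismatch)
  mapped <- !is.na(assign_of) & assign_of != ""
  ambiguous <- sum(tag_list$count[is.na(assign_of)])
  unmapped <- sum(tag_list$count[!is.na(assign_of) & assign_of == ""])
  if (any(mapped)) {
    agg <- tapply(tag_list$count[mapped], assign_of[mapped], sum)
    gene_counts[names(agg)] <- as.numeric(agg)
  }

  structure(list(library_id = library_id %||% "library",
                 clean_tag_total = clean_total,
                 unique_mapped_total = sum(gene_counts),
                 gene_counts = gene_counts,
                 unmapped = unmapped, ambiguous = ambiguous,
                 malformed = malformed),
            class = "library_counts")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# per-tag gene assignment: gene id, "" = unmapped, NA = ambiguous
#' @noRd
assign_tags <- function(tags, catalog, max_mismatch = 1L) {
  ct <- catalog$tags
  unit <- ifelse(is.na(ct$gene_id), paste0(".site", seq_len(nrow(ct))),
                 ct$gene_id)
  units_by_seq <- lapply(split(unit, ct$sequence), unique)
  useq <- names(units_by_seq)

  resolve <- function(units) {
    if (length(units) == 0) return("")
    if (length(units) > 1) return(NA_character_)
    if (startsWith(units, ".site")) "" else units
  }

  out <- character(length(tags))
  ex <- match(tags, useq)
  hit0 <- !is.na(ex)
  out[hit0] <- vapply(units_by_seq[ex[hit0]], resolve, character(1))
  if (max_mismatch >= 1L && any(!hit0)) {
    todo <- which(!hit0)
    out[todo] <- vapply(tags[todo], function(tg) {
      ch <- strsplit(tg, "", fixed = TRUE)[[1]]
      vars <- character(63L); k <- 0L
      for (p in 1:21) {
        for (b in DNA_BASES[DNA_BASES != ch[p]]) {
          k <- k + 1L
          v <- ch; v[p] <- b
          vars[k] <- paste(v, collapse = "")
        }
      }
      m <- match(vars, useq)
      resolve(unique(unlist(units_by_seq[m[!is.na(m)]])))
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

#' @export
print.library_counts <- function(x, ...) {
  cat(sprintf("Library %s: %g clean tags; %g uniquely mapped (%.1f%%), %g ambiguous, %g unmapped",
              x$library_id, x$clean_tag_total, x$unique_mapped_total,
              if (x$clean_tag_total > 0)
                100 * x$unique_mapped_total / x$clean_tag_total else 0,
              x$ambiguous, x$unmapped))
  if (x$malformed > 0) cat(sprintf("; %g malformed rejected", x$malformed))
  cat("\n")
  invisible(x)
}

#' Tags-per-million normalization
#'
#' `TPM_g = count_g * 1e6 / denominator`. The default denominator is the
#' uniquely mapped tag total (expression is computed from uniquely mapping
#' tags), under which the TPM column sums to exactly one million; the raw
#' clean-tag total is available as an alternative.
#'
#' @param library_counts a [map_tags()] result, or a named count vector
#'   (denominator then defaults to its sum).
#' @param denominator `"unique_mapped"` or `"clean_total"`.
#' @return named numeric vector of TPM values.
#' @export
tpm_normalize <- function(library_counts,
                          denominator = c("unique_mapped", "clean_total")) {
  denominator <- match.arg(denominator)
  if (inherits(library_counts, "library_counts")) {
    counts <- library_counts$gene_counts
    den <- switch(denominator,
                  unique_mapped = library_counts$unique_mapped_total,
                  clean_total = library_counts$clean_tag_total)
  } else {
    counts <- library_counts
    den <- sum(counts)
  }
  if (!is.finite(den) || den <= 0) stopf("zero TPM denominator")
  counts * 1e6 / den
}

#' TPM expression matrix over several libraries
#'
#' @param libraries list of [map_tags()] results (a shared gene universe).
#' @param denominator see [tpm_normalize()].
#' @return genes x libraries numeric matrix; each column sums to 1e6 under
#'   the default denominator.
#' @export
tpm_matrix <- function(libraries, denominator = "unique_mapped") {
  stopifnot(length(libraries) >= 1)
  cols <- lapply(libraries, tpm_normalize, denominator = denominator)
  m <- do.call(cbind, cols)
  colnames(m) <- names(libraries) %||%
    vapply(libraries, function(l) l$library_id, character(1))
  m
}

#' Gene-detection saturation curve
#'
#' Subsamples the library without replacement (one nested random
#' permutation, so the curve is monotone within a draw) and reports, at a
#' grid of depths from 0 to the full library, the fraction of the
#' catalog's annotated genes detected by at least one uniquely mapped tag.
#'
#' @param tag_list data frame (`tag`, `count`).
#' @param catalog a [build_tag_catalog()] result.
#' @param n_steps number of depth points (>= 2), including 0 and the full
#'   depth.
#' @param seed integer seed of the subsampling permutation.
#' @param max_mismatch passed to the per-tag assignment.
#' @return data frame with columns `depth` and `detected_fraction`.
#' @export
saturation_curve <- function(tag_list, catalog, n_steps = 10L, seed = 1L,
                             max_mismatch = 1L) {
  n_steps <- check_count(n_steps, "n_steps", min = 2)
  # assign each distinct observed tag once, then expand to reads
  utags <- unique(tag_list$tag[nchar(tag_list$tag) == 21L])
  per_tag <- assign_tags(utags, catalog, max_mismatch)
  per_tag[is.na(per_tag) | per_tag == ""] <- NA_character_
  idx <- match(tag_list$tag, utags)
  reads <- rep(per_tag[idx], ifelse(is.na(idx), 0L, tag_list$count))
  n <- length(reads)
  universe <- length(unique(catalog$tags$gene_id[!is.na(catalog$tags$gene_id)]))
  set.seed(seed)
  reads <- reads[sample.int(n)]
  new_gene <- !is.na(reads) & !duplicated(reads, incomparables = NA)
  cum_detected <- cumsum(new_gene)
  depth <- unique(round(seq(0, n, length.out = n_steps)))
  frac <- ifelse(depth == 0, 0, cum_detected[pmax(depth, 1)] / universe)
  data.frame(depth = depth, detected_fraction = frac)
}
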