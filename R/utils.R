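# internal helpers

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar positive-integer check
#' @noRd
check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

#' @noRd
check_prob <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stopf("`%s` must be a single probability in [0, 1]", name)
  as.numeric(x)
}

# gene id from a transcript name: strip a trailing ".tN" suffix if present
#' @noRd
gene_of_transcript <- function(tx) sub("\\.t[0-9]+$", "", tx)
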