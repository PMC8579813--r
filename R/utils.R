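# Shared sequence helpers. Sequences are plain uppercase character strings on
# the {A,C,G,T,N} alphabet; integer encodings (A=1..N=5, or 0-based for the
# compiled kernels) stay internal.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement on the `{A,C,G,T,N}` alphabet (`N` maps to
#' `N`).  Any other character is an error.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("GGGAC") # the complementary half-site "GTCCC"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  validate_dna(seq)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

validate_dna <- function(seq, what = "sequence") {
  bad <- unique(unlist(strsplit(gsub("[ACGTN]", "", seq), "")))
  if (length(bad) > 0) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                  what, paste(sQuote(bad), collapse = ", ")))
  }
  invisible(seq)
}

# integer encoding A=1, C=2, G=3, T=4, N=5
encode_dna <- function(seq) {
  x <- match(strsplit(seq, "")[[1]], c(DNA_BASES, "N"))
  if (anyNA(x)) abort("sequence contains characters outside {A,C,G,T,N}")
  x
}

decode_dna <- function(idx) paste(c(DNA_BASES, "N")[idx], collapse = "")

# background vector named A/C/G/T from a GC fraction
gc_background <- function(gc) {
  stats::setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
}

# 0-order background frequencies estimated from a set of sequences (N ignored)
estimate_background <- function(seqs) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, DNA_BASES, drop = FALSE])
  if (sum(counts) == 0) return(gc_background(0.5))
  counts / sum(counts)
}

# independent integer sub-seeds derived from one master seed
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run code with a local RNG state seeded from `seed`
with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  code
}
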