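# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy classes. A sequence 'N' is deliberately absent from every
# non-N class: an undetermined base never satisfies a specific pattern symbol.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

# Reverse complement of a plain character string (keeps N and '-').
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# Coerce a DNAStringSet / named character vector to named character vector.
as_seq_vector <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    setNames(as.character(seqs), names(seqs))
  } else if (is.character(seqs)) {
    seqs
  } else {
    abort("`seqs` must be a DNAStringSet or a named character vector.")
  }
}

single_sequence <- function(seq) {
  if (methods::is(seq, "XStringSet")) {
    if (length(seq) != 1L) abort("expected a single sequence")
    setNames(as.character(seq), names(seq))
  } else if (methods::is(seq, "XString")) {
    setNames(as.character(seq), "seq")
  } else if (is.character(seq) && length(seq) == 1L) {
    if (is.null(names(seq))) names(seq) <- "seq"
    seq
  } else {
    abort("expected a single sequence (DNAString(Set) or character scalar)")
  }
}

`%!in%` <- function(x, y) !x %in% y

empty_hits <- function() {
  tibble(
    motif = character(), sequence_id = character(),
    start = integer(), end = integer(), strand = character(),
    core_similarity = double(), matrix_similarity = double()
  )
}
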