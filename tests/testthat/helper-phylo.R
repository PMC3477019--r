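# Alignment with a strongly planted (A,B) clade for bootstrap checks.
bootstrap_alignment <- function() {
  # clade (A,B) supported by 40 exclusive columns; background random
  set.seed(99)
  n_col <- 200
  root <- sample(c("A", "C", "G", "T"), n_col, replace = TRUE)
  derive <- function(base, idx, shift) {
    out <- base
    out[idx] <- c(A = "C", C = "G", G = "T", T = "A")[out[idx]]
    if (shift > 0) {
      jdx <- sample(setdiff(seq_len(n_col), idx), shift)
      out[jdx] <- c(A = "G", C = "T", G = "A", T = "C")[out[jdx]]
    }
    out
  }
  shared_ab <- sample(n_col, 40)
  a <- derive(derive(root, shared_ab, 0), sample(n_col, 2), 0)
  b <- derive(derive(root, shared_ab, 0), sample(n_col, 2), 0)
  c_ <- derive(root, sample(n_col, 8), 0)
  d <- derive(root, sample(n_col, 8), 0)
  vapply(list(A = a, B = b, C = c_, D = d), paste, character(1),
         collapse = "")
}

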