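# Shared toy motif libraries and models built in code.

toy_iupac_library <- function() {
  list(
    M1 = iupac_motif("M1", "CATTGTT"),
    M2 = iupac_motif("M2", "TCCCC"),
    M3 = iupac_motif("M3", "GGGCA"),
    M4 = iupac_motif("M4", "TATAAGG")
  )
}

toy_model <- function(name = "toy", gaps = data.frame(dmin = c(18, 4, 22),
                                                      dmax = c(22, 8, 26)),
                      quorum_k = 4L) {
  lib <- toy_iupac_library()
  regulatory_model(name, lapply(lib, model_element), gaps,
                   quorum_k = quorum_k)
}

# A PWM built from sites, moderately informative
toy_pwm <- function(name = "V$TOY.01") {
  build_pwm(
    sites = c("TGACTCA", "TGACTCA", "TGAGTCA", "TGACTCT", "AGACTCA",
              "TGACTCA"),
    pseudocount = 0.5, name = name
  )
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fabricate a pwm object directly from frequencies + information values,
# bypassing build_pwm, for formula-level checks
fabricated_pwm <- function(freq, ci, core_start = 1L,
                           core_length = ncol(freq), name = "fab") {
  rownames(freq) <- c("A", "C", "G", "T")
  structure(
    list(name = name, family = name, length = ncol(freq), freq = freq,
         ci = ci, core_start = as.integer(core_start),
         core_length = as.integer(core_length)),
    class = "pwm"
  )
}
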