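#' Build a position weight matrix
#'
#' Constructs a PWM from aligned binding sites or a position-count table.
#' Per-position base frequencies are `(count + pseudocount) / (n + 4 *
#' pseudocount)`. Each position carries an information value
#' `Ci = (100 / ln 4) * (sum_b f(i,b) ln f(i,b) + ln 4)` on a 0-100 scale
#' (0 = uniform, 100 = single base). The core is the run of `core_length`
#' consecutive positions with the largest summed information (leftmost on
#' ties) and is scored separately at scan time.
#'
#' @param sites Character vector of equal-length binding-site sequences
#'   (alternative to `counts`).
#' @param counts A 4 x L numeric matrix of base counts with rownames
#'   `A,C,G,T` (alternative to `sites`).
#' @param pseudocount Added to every count (default 0).
#' @param core_length Length of the core window (default 4, capped at L).
#' @param name Matrix name, e.g. `"V$MZF1.01"`.
#' @param family Matrix family; defaults to the name with a trailing
#'   `".NN"` suffix removed (`"V$MZF1.01"` -> `"V$MZF1"`).
#' @return An object of class `pwm`.
#' @export
build_pwm <- function(sites = NULL, counts = NULL, pseudocount = 0,
                      core_length = 4L, name = "pwm", family = NULL) {
  stopifnot(pseudocount >= 0)
  if (is.null(counts)) {
    if (is.null(sites) || length(sites) < 1L) {
      abort("provide `sites` or `counts`")
    }
    sites <- toupper(sites)
    L <- unique(nchar(sites))
    if (length(L) != 1L) abort("binding sites must all have equal length")
    mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
    counts <- vapply(seq_len(L), function(i) {
      tabulate(factor(mat[, i], levels = DNA_BASES), nbins = 4L)
    }, numeric(4))
    rownames(counts) <- DNA_BASES
  } else {
    if (!is.matrix(counts) || nrow(counts) != 4L) {
      abort("`counts` must be a 4 x L matrix")
    }
    if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
    counts <- counts[DNA_BASES, , drop = FALSE]
  }
  L <- ncol(counts)
  nsum <- colSums(counts)
  if (any(nsum + 4 * pseudocount == 0)) {
    abort("all-zero count column; supply a pseudocount > 0")
  }
  f <- sweep(counts + pseudocount, 2, nsum + 4 * pseudocount, "/")
  ci <- apply(f, 2, function(p) {
    h <- sum(ifelse(p > 0, p * log(p), 0))
    (100 / log(4)) * (h + log(4))
  })
  core_length <- min(as.integer(core_length), L)
  if (core_length < 1L) abort("core_length must be >= 1")
  win_sums <- vapply(seq_len(L - core_length + 1L), function(s) {
    sum(ci[s:(s + core_length - 1L)])
  }, numeric(1))
  core_start <- which.max(win_sums)  # leftmost maximum
  structure(
    list(
      name = name,
      family = family %||% sub("\\.[0-9]+$", "", name),
      length = L,
      freq = f,
      ci = as.numeric(ci),
      core_start = as.integer(core_start),
      core_length = core_length
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, " (family ", x$family, "), ", x$length,
      " positions, core ", x$core_start, "-",
      x$core_start + x$core_length - 1L, "\n", sep = "")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The per-position argmax base (ties broken towards A < C < G < T).
#' @param pwm A `pwm` object.
#' @return A character scalar of length `pwm$length`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freq, 2, which.max)], collapse = "")
}

#' Score a sequence window against a PWM
#'
#' Information-weighted similarity of a window to the matrix, normalized so
#' the consensus scores exactly 1:
#' `sim = sum_i Ci * f(i, b_i) / sum_i Ci * max_b f(i, b)`,
#' summed over all positions (`part = "matrix"`) or core positions only
#' (`part = "core"`). An `N` in the window contributes 0 at its position.
#' Windows against a matrix whose assessed positions carry no information
#' (all `Ci = 0`) score 1 by convention.
#'
#' @param pwm A `pwm` object.
#' @param window Character scalar of length `pwm$length`.
#' @param part `"matrix"` (all positions) or `"core"`.
#' @return Similarity in `[0, 1]`.
#' @export
score_window <- function(pwm, window, part = c("matrix", "core")) {
  part <- match.arg(part)
  window <- toupper(window)
  if (nchar(window) != pwm$length) {
    abort(paste0("window length ", nchar(window), " != matrix length ",
                 pwm$length))
  }
  idx <- if (part == "core") {
    pwm$core_start:(pwm$core_start + pwm$core_length - 1L)
  } else {
    seq_len(pwm$length)
  }
  b <- match(seq_chars(window), DNA_BASES)  # NA for N etc.
  fmax <- apply(pwm$freq, 2, max)
  num <- sum(vapply(idx, function(i) {
    if (is.na(b[i])) 0 else pwm$ci[i] * pwm$freq[b[i], i]
  }, numeric(1)))
  den <- sum(pwm$ci[idx] * fmax[idx])
  if (den == 0) return(1)
  num / den
}

# Vectorized scores of every window of `s` (character scalar) against pwm.
# Returns a list(matrix=, core=) of numeric vectors, one value per 0-based
# offset 0..(nchar(s) - L).
score_all_windows <- function(pwm, s) {
  L <- pwm$length
  n <- nchar(s)
  n_win <- n - L + 1L
  if (n_win < 1L) return(list(matrix = numeric(0), core = numeric(0)))
  b <- match(seq_chars(s), DNA_BASES)
  fmax <- apply(pwm$freq, 2, max)
  core_idx <- pwm$core_start:(pwm$core_start + pwm$core_length - 1L)
  num_mat <- numeric(n_win)
  num_core <- numeric(n_win)
  for (i in seq_len(L)) {
    wf <- unname(pwm$ci[i] * pwm$freq[, i])
    contrib <- wf[b[i:(i + n_win - 1L)]]
    contrib[is.na(contrib)] <- 0
    num_mat <- num_mat + contrib
    if (i %in% core_idx) num_core <- num_core + contrib
  }
  den_mat <- sum(pwm$ci * fmax)
  den_core <- sum(pwm$ci[core_idx] * fmax[core_idx])
  list(
    matrix = if (den_mat == 0) rep(1, n_win) else num_mat / den_mat,
    core = if (den_core == 0) rep(1, n_win) else num_core / den_core
  )
}

#' Scan a sequence with a PWM
#'
#' Emits a hit at every offset (on either strand by default) where the core
#' similarity and the whole-matrix similarity both reach their thresholds.
#' Minus-strand windows are scored on the reverse complement and reported in
#' forward coordinates (0-based, half-open).
#'
#' @param seq A single sequence (DNAString(Set) or character scalar, named).
#' @param pwm A `pwm` object.
#' @param core_threshold,matrix_threshold Minimum core / matrix similarity
#'   (defaults 0.75 and 0.80).
#' @param strands `"both"` or `"forward"`.
#' @return A tibble of hits: `motif`, `sequence_id`, `start`, `end`,
#'   `strand`, `core_similarity`, `matrix_similarity`, sorted by `start`
#'   then strand.
#' @export
scan_pwm <- function(seq, pwm, core_threshold = 0.75, matrix_threshold = 0.80,
                     strands = c("both", "forward")) {
  strands <- match.arg(strands)
  v <- single_sequence(seq)
  s <- toupper(unname(v))
  id <- names(v)
  n <- nchar(s)
  if (n < pwm$length) abort("sequence shorter than the matrix")
  one_strand <- function(str, strand) {
    sc <- score_all_windows(pwm, str)
    pass <- which(sc$core >= core_threshold & sc$matrix >= matrix_threshold)
    if (length(pass) == 0L) return(empty_hits())
    off <- pass - 1L
    if (strand == "+") {
      start <- off
    } else {
      start <- n - (off + pwm$length)
    }
    tibble(
      motif = pwm$name, sequence_id = id,
      start = as.integer(start), end = as.integer(start + pwm$length),
      strand = strand,
      core_similarity = sc$core[pass], matrix_similarity = sc$matrix[pass]
    )
  }
  hits <- one_strand(s, "+")
  if (strands == "both") {
    hits <- bind_rows(hits, one_strand(revcomp_chr(s), "-"))
  }
  arrange(hits, .data$start, .data$strand)
}

#' Create an IUPAC motif
#'
#' @param name Motif name (e.g. `"GRBOX"`).
#' @param pattern Pattern over the IUPAC nucleotide code
#'   (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`).
#' @param max_mismatches Number of pattern positions allowed to go unmatched
#'   (default 0).
#' @return An object of class `iupac_motif`.
#' @export
iupac_motif <- function(name, pattern, max_mismatches = 0L) {
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) abort("empty IUPAC pattern")
  chars <- seq_chars(pattern)
  bad <- chars %!in% names(IUPAC_SETS)
  if (any(bad)) {
    abort(paste0("illegal IUPAC symbol(s): ",
                 paste(unique(chars[bad]), collapse = ", ")))
  }
  stopifnot(max_mismatches >= 0)
  structure(
    list(name = name, pattern = pattern,
         max_mismatches = as.integer(max_mismatches),
         length = nchar(pattern)),
    class = "iupac_motif"
  )
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat("<iupac_motif> ", x$name, ": ", x$pattern, " (<= ", x$max_mismatches,
      " mismatches)\n", sep = "")
  invisible(x)
}

# Mismatch count of every window of `s` against the pattern; an N in the
# sequence satisfies only a pattern N.
iupac_mismatch_counts <- function(motif, s) {
  L <- motif$length
  n <- nchar(s)
  n_win <- n - L + 1L
  if (n_win < 1L) return(integer(0))
  ch <- seq_chars(s)
  pat <- seq_chars(motif$pattern)
  mism <- integer(n_win)
  for (i in seq_len(L)) {
    ok <- ch[i:(i + n_win - 1L)] %in% IUPAC_SETS[[pat[i]]]
    mism <- mism + !ok
  }
  mism
}

#' Scan a sequence with a degenerate IUPAC motif
#'
#' A hit is emitted wherever at most `max_mismatches` pattern positions are
#' unsatisfied, on either strand by default. An `N` in the sequence never
#' satisfies a non-N pattern symbol. `matrix_similarity` (and
#' `core_similarity`) report the matched fraction of positions, so an exact
#' match scores 1.0.
#'
#' @inheritParams scan_pwm
#' @param motif An [iupac_motif()].
#' @return A tibble of hits with the same columns as [scan_pwm()].
#' @export
scan_iupac <- function(seq, motif, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  v <- single_sequence(seq)
  s <- toupper(unname(v))
  id <- names(v)
  n <- nchar(s)
  if (n < motif$length) abort("sequence shorter than the pattern")
  one_strand <- function(str, strand) {
    mism <- iupac_mismatch_counts(motif, str)
    pass <- which(mism <= motif$max_mismatches)
    if (length(pass) == 0L) return(empty_hits())
    off <- pass - 1L
    L <- motif$length
    start <- if (strand == "+") off else n - (off + L)
    frac <- (L - mism[pass]) / L
    tibble(
      motif = motif$name, sequence_id = id,
      start = as.integer(start), end = as.integer(start + L),
      strand = strand,
      core_similarity = frac, matrix_similarity = frac
    )
  }
  hits <- one_strand(s, "+")
  if (strands == "both") {
    hits <- bind_rows(hits, one_strand(revcomp_chr(s), "-"))
  }
  arrange(hits, .data$start, .data$strand)
}

#' Scan a sequence set with motif libraries
#'
#' Applies [scan_pwm()] / [scan_iupac()] over every sequence and motif and
#' binds the hits. Family-level scanning: filter the returned tibble on the
#' family prefix of the motif name, or pre-subset the library.
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param pwms List of `pwm` objects (optional).
#' @param motifs List of `iupac_motif` objects (optional).
#' @inheritParams scan_pwm
#' @return A tibble of hits sorted by `sequence_id`, `start`, `strand`.
#' @export
scan_sequences <- function(seqs, pwms = list(), motifs = list(),
                           core_threshold = 0.75, matrix_threshold = 0.80,
                           strands = c("both", "forward")) {
  strands <- match.arg(strands)
  v <- as_seq_vector(seqs)
  out <- list()
  for (id in names(v)) {
    s <- setNames(v[id], id)
    for (p in pwms) {
      if (nchar(s) >= p$length) {
        out[[length(out) + 1L]] <-
          scan_pwm(s, p, core_threshold, matrix_threshold, strands)
      }
    }
    for (m in motifs) {
      if (nchar(s) >= m$length) {
        out[[length(out) + 1L]] <- scan_iupac(s, m, strands)
      }
    }
  }
  if (length(out) == 0L) return(empty_hits())
  arrange(bind_rows(out), .data$sequence_id, .data$start, .data$strand)
}

#' Read / write a PWM library
#'
#' The library format is plain text: one block per matrix, a header line
#' `>name<TAB>family` followed by four tab-separated count rows labelled
#' `A`, `C`, `G`, `T`; blank line between blocks.
#'
#' @param path File path.
#' @param pseudocount,core_length Passed to [build_pwm()].
#' @return `read_pwm_library`: a named list of `pwm` objects.
#' @export
read_pwm_library <- function(path, pseudocount = 0, core_length = 4L) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0L) abort("no matrix blocks found")
  pwms <- list()
  for (h in heads) {
    hf <- strsplit(sub("^>", "", lines[h]), "\t", fixed = TRUE)[[1]]
    name <- hf[1]
    family <- if (length(hf) >= 2L) hf[2] else NULL
    rows <- lines[(h + 1L):(h + 4L)]
    mat <- t(vapply(rows, function(r) {
      f <- strsplit(r, "\t", fixed = TRUE)[[1]]
      as.numeric(f[-1])
    }, numeric(length(strsplit(rows[1], "\t")[[1]]) - 1L)))
    labels <- vapply(rows, function(r) strsplit(r, "\t")[[1]][1], character(1))
    rownames(mat) <- labels
    pwms[[name]] <- build_pwm(counts = mat[DNA_BASES, , drop = FALSE],
                              pseudocount = pseudocount,
                              core_length = core_length,
                              name = name, family = family)
  }
  pwms
}

#' @rdname read_pwm_library
#' @param pwms Named list of `pwm` objects (counts are written as scaled
#'   frequencies).
#' @export
write_pwm_library <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name, "\t", p$family), con)
    m <- round(p$freq * 100, 6)
    for (b in DNA_BASES) {
      writeLines(paste(c(b, m[b, ]), collapse = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read an IUPAC motif list
#'
#' Tab-separated columns `name`, `pattern`, `max_mismatches` (header
#' optional).
#'
#' @param path File path.
#' @return A named list of `iupac_motif` objects.
#' @export
read_iupac_motifs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "pattern", "max_mismatches"),
                          colClasses = c("character", "character", "integer"))
  if (nrow(df) > 0L && df$name[1] == "name") df <- df[-1, , drop = FALSE]
  out <- pmap(df, function(name, pattern, max_mismatches) {
    iupac_motif(name, pattern, as.integer(max_mismatches))
  })
  setNames(out, df$name)
}

#' Write motif hits as BED-like TSV
#'
#' Columns: `sequence_id`, `start`, `end`, `motif`, `matrix_similarity`,
#' `strand`.
#' @param hits A hits tibble from [scan_sequences()] and friends.
#' @param path File path.
#' @export
write_hits <- function(hits, path) {
  out <- hits[, c("sequence_id", "start", "end", "motif",
                  "matrix_similarity", "strand")]
  readr::write_tsv(out, path)
  invisible(path)
}

#' Tidy a PWM into a long tibble
#'
#' @param x A `pwm` object.
#' @param ... Unused.
#' @return A tibble with one row per (position, base): `position`, `base`,
#'   `frequency`, `information`, `in_core`.
#' @exportS3Method generics::tidy
tidy.pwm <- function(x, ...) {
  core <- x$core_start:(x$core_start + x$core_length - 1L)
  tidyr::expand_grid(position = seq_len(x$length), base = DNA_BASES) |>
    mutate(
      frequency = purrr::map2_dbl(.data$position, .data$base,
                                  ~ x$freq[.y, .x]),
      information = x$ci[.data$position],
      in_core = .data$position %in% core
    )
}

#' @exportS3Method generics::glance
glance.pwm <- function(x, ...) {
  tibble(
    name = x$name, family = x$family, length = x$length,
    core_start = x$core_start, core_length = x$core_length,
    mean_information = mean(x$ci), consensus = pwm_consensus(x)
  )
}

#' Plot the information profile of a PWM
#'
#' Bar chart of per-position information (0-100) with the core window
#' shaded.
#' @param pwm A `pwm` object.
#' @return A ggplot object.
#' @export
plot_pwm_information <- function(pwm) {
  df <- tibble(
    position = seq_len(pwm$length), information = pwm$ci,
    in_core = seq_len(pwm$length) %in%
      pwm$core_start:(pwm$core_start + pwm$core_length - 1L)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$information,
                                   fill = .data$in_core)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "black"),
                               name = "core") +
    ggplot2::labs(x = "matrix position", y = "information (0-100)",
                  title = pwm$name) +
    ggplot2::theme_minimal()
}
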