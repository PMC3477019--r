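#' Build a regulatory model element
#'
#' Wraps a PWM or IUPAC motif together with its per-element stringency for
#' use inside a [regulatory_model()].
#'
#' @param motif A `pwm` or `iupac_motif` object, or a character name to be
#'   resolved against a library at scan time.
#' @param core_threshold,matrix_threshold PWM stringencies (ignored for
#'   IUPAC elements).
#' @param max_mismatches Override of the IUPAC mismatch allowance (ignored
#'   for PWM elements).
#' @return An element list used by [regulatory_model()].
#' @export
model_element <- function(motif, core_threshold = 0.75,
                          matrix_threshold = 0.80, max_mismatches = NULL) {
  if (inherits(motif, "pwm")) {
    list(type = "pwm", motif = motif, ref = motif$name,
         core_threshold = core_threshold, matrix_threshold = matrix_threshold)
  } else if (inherits(motif, "iupac_motif")) {
    if (!is.null(max_mismatches)) motif$max_mismatches <- as.integer(max_mismatches)
    list(type = "iupac", motif = motif, ref = motif$name)
  } else if (is.character(motif) && length(motif) == 1L) {
    list(type = "ref", ref = motif, core_threshold = core_threshold,
         matrix_threshold = matrix_threshold,
         max_mismatches = max_mismatches)
  } else {
    abort("`motif` must be a pwm, an iupac_motif, or a name")
  }
}

#' Create a regulatory model
#'
#' An ordered combination of motif elements (PWMs and/or IUPAC strings) with
#' an inclusive allowed gap range `[dmin, dmax]` (nt, 3' end of one element
#' to 5' start of the next) between each adjacent pair. The whole model is
#' matched on one orientation at a time (model-forward or model-reverse);
#' mixed-strand elements are not supported. `quorum_k` relaxes the match to
#' "at least k of the elements, in order" (default: all).
#'
#' @param name Model name.
#' @param elements List of [model_element()]s (length >= 2; a single-element
#'   model degenerates to a plain motif scan and is allowed).
#' @param gaps A data frame with columns `dmin`, `dmax` and one row per
#'   adjacent element pair.
#' @param quorum_k Minimum number of elements that must match
#'   (default all).
#' @return An object of class `regulatory_model`.
#' @export
regulatory_model <- function(name, elements, gaps,
                             quorum_k = length(elements)) {
  n <- length(elements)
  if (n < 1L) abort("a model needs at least one element")
  gaps <- as_tibble(gaps)
  if (n == 1L) gaps <- tibble(dmin = numeric(0), dmax = numeric(0))
  if (n > 1L && nrow(gaps) != n - 1L) {
    abort("`gaps` must have one row per adjacent element pair")
  }
  if (n > 1L && any(gaps$dmin > gaps$dmax)) abort("gap dmin > dmax")
  if (quorum_k < 1L || quorum_k > n) abort("quorum_k out of range")
  structure(
    list(name = name, elements = elements,
         gaps = gaps[, c("dmin", "dmax"), drop = FALSE],
         quorum_k = as.integer(quorum_k)),
    class = "regulatory_model"
  )
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat("<regulatory_model> ", x$name, ": ", length(x$elements),
      " elements, quorum ", x$quorum_k, "\n", sep = "")
  for (i in seq_along(x$elements)) {
    el <- x$elements[[i]]
    cat("  [", i, "] ", el$type, " ", el$ref, sep = "")
    if (i < length(x$elements)) {
      cat("  -- gap [", x$gaps$dmin[i], ", ", x$gaps$dmax[i], "] -->", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

# Resolve 'ref' elements against libraries; returns the model with every
# element carrying a concrete motif object.
resolve_model <- function(model, pwms = list(), motifs = list()) {
  model$elements <- map(model$elements, function(el) {
    if (el$type != "ref") return(el)
    nm <- el$ref
    if (nm %in% names(pwms)) {
      out <- model_element(pwms[[nm]],
                           core_threshold = el$core_threshold %||% 0.75,
                           matrix_threshold = el$matrix_threshold %||% 0.80)
    } else if (nm %in% names(motifs)) {
      out <- model_element(motifs[[nm]], max_mismatches = el$max_mismatches)
    } else {
      abort(paste0("unresolvable motif reference '", nm, "' in model"))
    }
    out
  })
  model
}

element_length <- function(el) el$motif$length

element_hits_fwd <- function(el, s, id) {
  if (el$type == "pwm") {
    scan_pwm(setNames(s, id), el$motif,
             core_threshold = el$core_threshold,
             matrix_threshold = el$matrix_threshold,
             strands = "forward")
  } else {
    scan_iupac(setNames(s, id), el$motif, strands = "forward")
  }
}

# Composite inclusive gap range between chosen elements i < j of the model
# when elements i+1 .. j-1 are skipped: skipped elements contribute their
# fixed lengths, intervening gap ranges add up.
composite_gap <- function(model, i, j) {
  dmin <- sum(model$gaps$dmin[i:(j - 1L)])
  dmax <- sum(model$gaps$dmax[i:(j - 1L)])
  skipped <- if (j - i >= 2L) {
    sum(vapply(model$elements[(i + 1L):(j - 1L)], element_length, numeric(1)))
  } else 0
  c(dmin + skipped, dmax + skipped)
}

#' Scan a sequence for a regulatory model
#'
#' Left-to-right chaining: hits of the first (matched) element seed partial
#' chains, which extend to the next element whenever a hit exists whose gap
#' to the chain tail lies within the allowed range. Both model orientations
#' are screened; minus-orientation matches are found on the reverse
#' complement and reported in forward coordinates. With `quorum_k` below the
#' element count, any in-order subsequence of at least `quorum_k` elements
#' matches, the allowed gap across skipped elements being the sum of the
#' intervening ranges plus the skipped elements' lengths.
#'
#' @param seq A single sequence (DNAString(Set) or named character scalar).
#' @param model A [regulatory_model()].
#' @param pwms,motifs Named libraries to resolve by-name element references.
#' @return A tibble of model hits: `model`, `sequence_id`, `start`, `end`
#'   (span from first to last matched element, half-open, forward
#'   coordinates), `orientation`, `matched_count` and `element_hits`
#'   (list-column of per-element hit tibbles in model order), sorted by
#'   `start`.
#' @export
scan_model <- function(seq, model, pwms = list(), motifs = list()) {
  model <- resolve_model(model, pwms, motifs)
  v <- single_sequence(seq)
  s <- toupper(unname(v))
  id <- names(v)
  n <- nchar(s)
  n_el <- length(model$elements)

  chains_on <- function(str) {
    # per-element forward hits on `str`
    hit_lists <- map(model$elements, element_hits_fwd, s = str, id = id)
    subsets <- element_subsets(n_el, model$quorum_k)
    out <- list()
    for (sel in subsets) {
      partial <- map(seq_len(nrow(hit_lists[[sel[1]]])), function(r)
        list(rows = r, els = sel[1]))
      if (length(sel) > 1L) {
        for (k in 2L:length(sel)) {
          el_j <- sel[k]
          el_i <- sel[k - 1L]
          rng <- composite_gap(model, el_i, el_j)
          hj <- hit_lists[[el_j]]
          nxt <- list()
          for (ch in partial) {
            tail_end <- hit_lists[[el_i]]$end[ch$rows[length(ch$rows)]]
            ok <- which(hj$start - tail_end >= rng[1] &
                          hj$start - tail_end <= rng[2])
            for (r in ok) {
              nxt[[length(nxt) + 1L]] <-
                list(rows = c(ch$rows, r), els = c(ch$els, el_j))
            }
          }
          partial <- nxt
          if (length(partial) == 0L) break
        }
      }
      out <- c(out, partial)
    }
    # keep only maximal chains: drop a chain whose (element, hit) pairs are
    # a strict subset of another chain's
    if (length(out) > 1L) {
      keys <- map(out, function(ch) paste(ch$els, ch$rows, sep = ":"))
      sizes <- lengths(keys)
      keep <- vapply(seq_along(out), function(i) {
        !any(vapply(seq_along(out), function(j) {
          j != i && sizes[j] > sizes[i] && all(keys[[i]] %in% keys[[j]])
        }, logical(1)))
      }, logical(1))
      out <- out[keep]
    }
    list(chains = out, hit_lists = hit_lists)
  }

  collect <- function(res, orientation) {
    if (length(res$chains) == 0L) return(empty_model_hits())
    rows <- map(res$chains, function(ch) {
      eh <- bind_rows(map2(ch$els, ch$rows, function(e, r) {
        mutate(res$hit_lists[[e]][r, ], element = e)
      }))
      span_start <- min(eh$start)
      span_end <- max(eh$end)
      if (orientation == "-") {
        new_start <- n - eh$end
        new_end <- n - eh$start
        eh$start <- as.integer(new_start)
        eh$end <- as.integer(new_end)
        eh$strand <- "-"
        sp <- c(n - span_end, n - span_start)
      } else {
        sp <- c(span_start, span_end)
      }
      tibble(
        model = model$name, sequence_id = id,
        start = as.integer(sp[1]), end = as.integer(sp[2]),
        orientation = orientation,
        matched_count = length(ch$els),
        element_hits = list(eh)
      )
    })
    bind_rows(rows)
  }

  fwd <- collect(chains_on(s), "+")
  rev <- collect(chains_on(revcomp_chr(s)), "-")
  hits <- bind_rows(fwd, rev)
  if (nrow(hits) == 0L) return(hits)
  hits <- distinct(hits, .data$start, .data$end, .data$orientation,
                   .data$matched_count, .keep_all = TRUE)
  arrange(hits, .data$start, .data$orientation)
}

# In-order element subsequences of 1..n with size >= k. For k = n this is
# just the full chain. Maximality: a subset that is contained in another
# matching subset would double-report; subsets are enumerated largest-first
# and only maximal matched chains are kept by the distinct() in scan_model.
element_subsets <- function(n, k) {
  if (k >= n) return(list(seq_len(n)))
  sizes <- seq(n, k)
  out <- list()
  for (sz in sizes) {
    cmb <- utils::combn(n, sz, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

empty_model_hits <- function() {
  tibble(
    model = character(), sequence_id = character(),
    start = integer(), end = integer(), orientation = character(),
    matched_count = integer(), element_hits = list()
  )
}

#' Screen a promoter set with a model
#'
#' Applies [scan_model()] to every record of a promoter set.
#'
#' @param promoters A [Biostrings::DNAStringSet] or named character vector.
#' @param model A [regulatory_model()].
#' @param pwms,motifs Named libraries for by-name element references.
#' @return An object of class `promoter_screen`: list with `hits` (bound
#'   tibble of model hits), `n_sequences`, `n_with_hits` and
#'   `sequences_with_hits`.
#' @export
screen_promoter_set <- function(promoters, model, pwms = list(),
                                motifs = list()) {
  v <- as_seq_vector(promoters)
  model <- resolve_model(model, pwms, motifs)
  min_len <- max(vapply(model$elements, element_length, numeric(1)))
  hits <- map(names(v), function(id) {
    if (nchar(v[[id]]) < min_len) return(empty_model_hits())
    scan_model(setNames(v[id], id), model)
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) hits <- empty_model_hits()
  with_hits <- unique(hits$sequence_id)
  structure(
    list(hits = hits, n_sequences = length(v),
         n_with_hits = length(with_hits),
         sequences_with_hits = with_hits,
         model = model$name),
    class = "promoter_screen"
  )
}

#' @export
print.promoter_screen <- function(x, ...) {
  cat("<promoter_screen> model ", x$model, ": ", x$n_with_hits, "/",
      x$n_sequences, " sequences with >= 1 hit\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.promoter_screen <- function(x, ...) {
  tibble(model = x$model, n_sequences = x$n_sequences,
         n_with_hits = x$n_with_hits,
         frac_with_hits = ifelse(x$n_sequences == 0, NA_real_,
                                 x$n_with_hits / x$n_sequences))
}

#' Test a model's conservation across orthologous promoter sets
#'
#' Screens the model against one promoter set per species and reports, per
#' species, whether at least one model hit exists; the model passes when the
#' number of supporting species reaches `min_species`.
#'
#' @param model A [regulatory_model()].
#' @param ortholog_sets Named list (species -> DNAStringSet / named
#'   character vector) of ortholog promoter sets.
#' @param min_species Minimum number of species with a hit.
#' @param pwms,motifs Named libraries for by-name element references.
#' @return An object of class `conservation_report`: list with `species`
#'   (tibble `species`, `n_hits`, `present`), `n_present`, `min_species`,
#'   `pass`.
#' @export
conserved_across_species <- function(model, ortholog_sets, min_species,
                                     pwms = list(), motifs = list()) {
  if (length(ortholog_sets) < 1L) abort("need at least one species set")
  if (min_species > length(ortholog_sets)) {
    warn("min_species exceeds the number of species; conservation can never pass")
  }
  rows <- imap(ortholog_sets, function(set, sp) {
    v <- as_seq_vector(set)
    if (length(v) == 0L) {
      warn(paste0("species '", sp, "' has an empty promoter set"))
      return(tibble(species = sp, n_hits = 0L, present = FALSE))
    }
    scr <- screen_promoter_set(v, model, pwms, motifs)
    tibble(species = sp, n_hits = nrow(scr$hits),
           present = scr$n_with_hits > 0L)
  })
  species <- bind_rows(rows)
  structure(
    list(species = species, n_present = sum(species$present),
         min_species = min_species,
         pass = sum(species$present) >= min_species,
         model = model$name),
    class = "conservation_report"
  )
}

#' @export
print.conservation_report <- function(x, ...) {
  cat("<conservation_report> model ", x$model, ": ", x$n_present,
      " species with hits (need ", x$min_species, ") -> ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.conservation_report <- function(x, ...) x$species

#' @exportS3Method generics::glance
glance.conservation_report <- function(x, ...) {
  tibble(model = x$model, n_present = x$n_present,
         min_species = x$min_species, pass = x$pass)
}

#' Read / write model files
#'
#' One model per block. Block grammar (tab-separated):
#' \preformatted{
#' model <name> quorum <k>
#' element pwm|iupac <reference> [core_th] [matrix_th] [max_mismatches]
#' gap <dmin> <dmax>
#' ...
#' }
#' Elements and gaps alternate; `end` closes a block.
#'
#' @param path File path.
#' @return `read_model_file`: a named list of [regulatory_model()]s with
#'   by-name element references (resolve at scan time against libraries).
#' @export
read_model_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  models <- list()
  i <- 1L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (f[1] != "model") abort(paste0("expected 'model' line, got: ", lines[i]))
    name <- f[2]
    quorum <- if (length(f) >= 4L && f[3] == "quorum") as.integer(f[4]) else NA
    elements <- list()
    gaps <- list()
    i <- i + 1L
    while (i <= length(lines)) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (f[1] == "end") { i <- i + 1L; break }
      if (f[1] == "element") {
        type <- f[2]
        el <- list(type = "ref", ref = f[3],
                   core_threshold = if (length(f) >= 4L) as.numeric(f[4]) else 0.75,
                   matrix_threshold = if (length(f) >= 5L) as.numeric(f[5]) else 0.80,
                   max_mismatches = if (length(f) >= 6L) as.integer(f[6]) else NULL)
        el$declared_type <- type
        elements[[length(elements) + 1L]] <- el
      } else if (f[1] == "gap") {
        gaps[[length(gaps) + 1L]] <- tibble(dmin = as.numeric(f[2]),
                                            dmax = as.numeric(f[3]))
      } else {
        abort(paste0("unrecognized model-file line: ", lines[i]))
      }
      i <- i + 1L
    }
    models[[name]] <- regulatory_model(
      name = name, elements = elements, gaps = bind_rows(gaps),
      quorum_k = if (is.na(quorum)) length(elements) else quorum
    )
  }
  models
}

#' @rdname read_model_file
#' @param models Named list of [regulatory_model()]s.
#' @export
write_model_file <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    writeLines(paste("model", m$name, "quorum", m$quorum_k, sep = "\t"), con)
    for (i in seq_along(m$elements)) {
      el <- m$elements[[i]]
      type <- if (el$type == "ref") el$declared_type %||% "pwm" else el$type
      fields <- c("element", type, el$ref)
      if (type == "pwm") {
        fields <- c(fields, el$core_threshold %||% 0.75,
                    el$matrix_threshold %||% 0.80)
      } else if (!is.null(el$max_mismatches %||% el$motif$max_mismatches)) {
        fields <- c(fields, "", "",
                    el$max_mismatches %||% el$motif$max_mismatches)
      }
      writeLines(paste(fields, collapse = "\t"), con)
      if (i < length(m$elements)) {
        writeLines(paste("gap", m$gaps$dmin[i], m$gaps$dmax[i], sep = "\t"),
                   con)
      }
    }
    writeLines("end", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Plot model hits along sequences
#'
#' Segment plot of the matched element chain of each model hit, one row per
#' sequence.
#' @param hits Model-hit tibble from [scan_model()] /
#'   [screen_promoter_set()]`$hits`.
#' @return A ggplot object.
#' @export
plot_model_hits <- function(hits) {
  if (nrow(hits) == 0L) abort("no hits to plot")
  eh <- bind_rows(map(seq_len(nrow(hits)), function(i) {
    mutate(hits$element_hits[[i]],
           sequence_id = hits$sequence_id[i],
           orientation = hits$orientation[i],
           hit_index = i)
  }))
  ggplot2::ggplot(eh) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$sequence_id, yend = .data$sequence_id,
                   colour = .data$motif),
      linewidth = 4
    ) +
    ggplot2::facet_wrap(~orientation, ncol = 1) +
    ggplot2::labs(x = "position (nt, forward strand)", y = NULL,
                  colour = "element") +
    ggplot2::theme_minimal()
}
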