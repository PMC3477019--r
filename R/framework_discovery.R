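# Framework discovery: ordered motif combinations shared by a quorum of
# promoter sequences with consistent inter-element distances.
#
# Hits are canonicalized into reading-direction coordinates so that '+' and
# '-' chains share one arithmetic: rstart/rend increase 5'->3' along the
# strand the chain lives on, and the gap between consecutive elements is
# rstart(next) - rend(prev) (3' end of one element to 5' start of the next),
# required to be >= 0.

reading_coords <- function(hits) {
  mutate(hits,
         rstart = ifelse(.data$strand == "+", .data$start, -.data$end),
         rend = ifelse(.data$strand == "+", .data$end, -.data$start))
}

# Best window of width <= 2*tol over observed gaps, maximizing the number of
# distinct supporting sequences (ties: smallest window start). `obs` is a
# tibble with columns gap and sequence_id. Returns row indices of `obs`
# falling in the chosen window, or integer(0) if no window reaches `quorum`.
best_gap_window <- function(obs, tol, quorum) {
  gaps <- sort(unique(obs$gap))
  best_n <- -1L
  best_idx <- integer(0)
  for (g in gaps) {
    idx <- which(obs$gap >= g & obs$gap <= g + 2 * tol)
    n_seq <- length(unique(obs$sequence_id[idx]))
    if (n_seq > best_n) {
      best_n <- n_seq
      best_idx <- idx
    }
  }
  if (best_n >= quorum) best_idx else integer(0)
}

#' Discover conserved ordered motif combinations (frameworks)
#'
#' Apriori-style search over per-sequence motif hit lists: every ordered
#' motif pair co-occurring (in order, non-overlapping, same strand) in at
#' least `quorum` sequences with gap lengths confinable to a window of width
#' `2 * gap_tolerance` seeds a 2-element framework; frameworks are then
#' extended rightwards one element at a time while the quorum and the
#' gap-consistency rule keep holding, up to `max_elements`. Only maximal
#' frameworks are reported: a framework is dropped when its element chain is
#' a contiguous subsequence of a longer reported framework with equal
#' support.
#'
#' @param hits A tibble of motif hits (columns `sequence_id`, `motif`,
#'   `start`, `end`, `strand`) as produced by [scan_sequences()].
#' @param quorum Minimum number of distinct sequences that must contain an
#'   instance (>= 2).
#' @param max_elements Maximum chain length (default 6).
#' @param gap_tolerance Half-width (nt) of the allowed gap window
#'   (default 10): observed gaps of retained instances span at most
#'   `2 * gap_tolerance`.
#' @param same_strand All elements of a chain must lie on one strand
#'   (default TRUE). With `FALSE`, strand is ignored and all hits are
#'   treated as forward.
#' @return A tibble with one row per framework: `framework_id`, `elements`
#'   (list of motif names), `n_elements`, `support`, `gaps` (list-tibble
#'   with `dmin`, `dmax` per adjacent pair) and `instances` (list-tibble
#'   with `sequence_id`, `strand`, `starts`, `gaps`), ordered by
#'   `n_elements` descending then element names.
#' @export
discover_frameworks <- function(hits, quorum, max_elements = 6L,
                                gap_tolerance = 10, same_strand = TRUE) {
  stopifnot(quorum >= 2L)
  n_seqs <- length(unique(hits$sequence_id))
  if (quorum > n_seqs) {
    abort(paste0("quorum (", quorum, ") exceeds the number of sequences (",
                 n_seqs, ")"))
  }
  h <- hits
  if (!same_strand) h$strand <- "+"
  h <- reading_coords(h)
  h <- arrange(h, .data$sequence_id, .data$strand, .data$rstart)
  h$.hit <- seq_len(nrow(h))

  # chains are stored as integer vectors of row indices into `h`
  chain_tbl <- function(chain_list) {
    tibble(
      sequence_id = map_chr(chain_list, ~ h$sequence_id[.x[1]]),
      chain = chain_list
    )
  }

  seed_level <- function() {
    out <- list()
    motifs <- sort(unique(h$motif))
    for (m1 in motifs) {
      for (m2 in motifs) {
        a <- h[h$motif == m1, ]
        b <- h[h$motif == m2, ]
        pairs <- dplyr::inner_join(
          a[, c("sequence_id", "strand", "rend", ".hit")],
          b[, c("sequence_id", "strand", "rstart", ".hit")],
          by = c("sequence_id", "strand"),
          suffix = c("_1", "_2"), relationship = "many-to-many"
        )
        pairs <- filter(pairs, .data$rstart - .data$rend >= 0,
                        .data$.hit_1 != .data$.hit_2)
        if (nrow(pairs) == 0L) next
        obs <- tibble(gap = pairs$rstart - pairs$rend,
                      sequence_id = pairs$sequence_id)
        idx <- best_gap_window(obs, gap_tolerance, quorum)
        if (length(idx) == 0L) next
        kept <- pairs[idx, ]
        out[[length(out) + 1L]] <- list(
          elements = c(m1, m2),
          chains = map2(kept$.hit_1, kept$.hit_2, c)
        )
      }
    }
    out
  }

  extend_one <- function(fw) {
    out <- list()
    tails <- map_int(fw$chains, ~ .x[length(.x)])
    tail_info <- h[tails, c("sequence_id", "strand", "rend")]
    motifs <- sort(unique(h$motif))
    for (m in motifs) {
      cand <- h[h$motif == m, ]
      obs <- list()
      ext <- list()
      for (ci in seq_along(fw$chains)) {
        rows <- which(cand$sequence_id == tail_info$sequence_id[ci] &
                        cand$strand == tail_info$strand[ci] &
                        cand$rstart >= tail_info$rend[ci] &
                        cand$.hit %!in% fw$chains[[ci]])
        for (r in rows) {
          obs[[length(obs) + 1L]] <- tibble(
            gap = cand$rstart[r] - tail_info$rend[ci],
            sequence_id = tail_info$sequence_id[ci]
          )
          ext[[length(ext) + 1L]] <- c(fw$chains[[ci]], cand$.hit[r])
        }
      }
      if (length(obs) == 0L) next
      obs <- bind_rows(obs)
      idx <- best_gap_window(obs, gap_tolerance, quorum)
      if (length(idx) == 0L) next
      out[[length(out) + 1L]] <- list(
        elements = c(fw$elements, m),
        chains = ext[idx]
      )
    }
    out
  }

  levels <- list()
  current <- seed_level()
  k <- 2L
  while (length(current) > 0L) {
    levels[[as.character(k)]] <- current
    if (k >= max_elements) break
    nxt <- list()
    for (fw in current) nxt <- c(nxt, extend_one(fw))
    # dedup extensions that reach one element sequence via several parents
    if (length(nxt) > 1L) {
      keys <- map_chr(nxt, ~ paste(.x$elements, collapse = "\r"))
      nxt <- map(split(seq_along(nxt), keys), function(is) {
        chains <- unique(do.call(c, map(nxt[is], "chains")))
        list(elements = nxt[[is[1]]]$elements, chains = chains)
      })
      names(nxt) <- NULL
    }
    current <- nxt
    k <- k + 1L
  }

  all_fw <- do.call(c, unname(levels))
  if (is.null(all_fw) || length(all_fw) == 0L) return(empty_frameworks())

  summarize_fw <- function(fw) {
    chains <- fw$chains
    seqs <- map_chr(chains, ~ h$sequence_id[.x[1]])
    gaps_per_chain <- map(chains, function(ch) {
      h$rstart[ch[-1]] - h$rend[ch[-length(ch)]]
    })
    n_gaps <- length(fw$elements) - 1L
    gap_tbl <- tibble(
      pair = seq_len(n_gaps),
      dmin = vapply(seq_len(n_gaps), function(j)
        min(map_dbl(gaps_per_chain, ~ .x[j])), numeric(1)),
      dmax = vapply(seq_len(n_gaps), function(j)
        max(map_dbl(gaps_per_chain, ~ .x[j])), numeric(1))
    )
    inst <- tibble(
      sequence_id = seqs,
      strand = map_chr(chains, ~ h$strand[.x[1]]),
      starts = map(chains, ~ h$start[.x]),
      gaps = gaps_per_chain
    ) |>
      arrange(.data$sequence_id)
    tibble(
      elements = list(fw$elements),
      n_elements = length(fw$elements),
      support = length(unique(seqs)),
      gaps = list(gap_tbl),
      instances = list(inst)
    )
  }

  res <- bind_rows(map(all_fw, summarize_fw))

  # maximality: drop contiguous sub-chains of an equal-support framework
  is_subchain <- function(small, big) {
    ns <- length(small)
    nb <- length(big)
    if (ns >= nb) return(FALSE)
    any(vapply(seq_len(nb - ns + 1L), function(o)
      identical(big[o:(o + ns - 1L)], small), logical(1)))
  }
  keep <- vapply(seq_len(nrow(res)), function(i) {
    !any(vapply(seq_len(nrow(res)), function(j) {
      j != i && res$support[j] == res$support[i] &&
        is_subchain(res$elements[[i]], res$elements[[j]])
    }, logical(1)))
  }, logical(1))
  res <- res[keep, , drop = FALSE]

  res <- arrange(res, dplyr::desc(.data$n_elements),
                 map_chr(.data$elements, paste, collapse = ","))
  res$framework_id <- paste0("fw", seq_len(nrow(res)))
  select(res, "framework_id", "elements", "n_elements", "support",
         "gaps", "instances")
}

empty_frameworks <- function() {
  tibble(
    framework_id = character(), elements = list(), n_elements = integer(),
    support = integer(), gaps = list(), instances = list()
  )
}

#' Turn a discovered framework into a screenable regulatory model
#'
#' The model keeps the framework's element order; each inter-element gap is
#' allowed in `[0, distance_factor * g_ref]` where `g_ref` is the gap
#' observed in the instance on `reference_sequence_id` (the reference
#' promoter, e.g. the human ortholog). The default factor of 2 doubles the
#' reference distances.
#'
#' @param fw One framework (a single row of [discover_frameworks()] output).
#' @param reference_sequence_id Sequence whose instance supplies the
#'   reference gaps; an error if the framework has no instance there.
#' @param distance_factor Multiplier on the reference gaps (default 2).
#' @param pwms,motifs Named motif libraries used to resolve element
#'   references when scanning (stored in the model).
#' @param core_threshold,matrix_threshold Default PWM stringencies copied
#'   into every PWM element.
#' @param name Model name (default derived from the framework id).
#' @return A [regulatory_model()].
#' @export
framework_to_model <- function(fw, reference_sequence_id,
                               distance_factor = 2.0,
                               pwms = list(), motifs = list(),
                               core_threshold = 0.75,
                               matrix_threshold = 0.80,
                               name = NULL) {
  if (nrow(fw) != 1L) abort("`fw` must be a single framework row")
  inst <- fw$instances[[1]]
  ref <- inst[inst$sequence_id == reference_sequence_id, , drop = FALSE]
  if (nrow(ref) == 0L) {
    abort(paste0("framework has no instance on reference sequence '",
                 reference_sequence_id, "'"))
  }
  g_ref <- ref$gaps[[1]]
  elements <- map(fw$elements[[1]], function(nm) {
    if (nm %in% names(motifs)) {
      model_element(motifs[[nm]])
    } else if (nm %in% names(pwms)) {
      model_element(pwms[[nm]], core_threshold = core_threshold,
                    matrix_threshold = matrix_threshold)
    } else {
      # unresolved reference: keep by name, resolved at scan time
      list(type = "ref", ref = nm, core_threshold = core_threshold,
           matrix_threshold = matrix_threshold)
    }
  })
  gaps <- tibble(dmin = rep(0, length(g_ref)),
                 dmax = floor(distance_factor * g_ref))
  regulatory_model(
    name = name %||% paste0(fw$framework_id, "_model"),
    elements = elements, gaps = gaps
  )
}
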