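# Clone-to-chromosome mapping and candidate gene selection.
#
# A model hit found in a clone (contig) is placed on the chromosome by one
# of four orientation configurations, determined by the model's strand in
# the clone and the clone's strand on the chromosome. Writing x and y for
# the chromosomal start and end of the clone and a for the model offset in
# clone coordinates:
#
#   case A (model +, clone +, gene strand +): a' = x + a, z = a' + W
#   case B (model -, clone +, gene strand -): a' = x + a, z = a' - W
#   case C (model -, clone -, gene strand +): a' = y - a, z = a' + W
#   case D (model +, clone -, gene strand -): a' = y - a, z = a' - W
#
# with W the TSS search-window width (2000 nt by default). a' is the
# chromosomal coordinate of the model's 5' end in its reading direction and
# z the far bound of the window in which candidate gene TSSs are sought.
# The model-in-clone strand for the B/C configurations follows from
# requiring the two strand flips (model-in-clone, clone-on-chromosome) to
# compose to the stated chromosomal gene strand; the round-trip mapping
# test exercises this consistency.

#' Read a clone (contig) mapping table
#'
#' Tab-separated columns `clone_id`, `chromosome`, `x`, `y`, `clone_strand`
#' (chromosomal start/end of the clone and its orientation).
#'
#' @param path File path.
#' @return A tibble of clone mappings.
#' @export
read_clone_mappings <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("clone_id", "chromosome", "x", "y", "clone_strand")
  if (!all(needed %in% names(df))) {
    abort(paste0("clone mapping file must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (any(df$x >= df$y)) abort("clone mapping with x >= y")
  df
}

case_table <- tibble::tibble(
  case = c("A", "B", "C", "D"),
  model_strand = c("+", "-", "-", "+"),
  clone_strand = c("+", "+", "-", "-"),
  chrom_strand = c("+", "-", "+", "-")
)

#' Map model hits from clone to chromosomal coordinates
#'
#' Applies the orientation-dependent coordinate rules (cases A-D, see the
#' package vignette) to place each model hit on the chromosome and to open
#' the TSS search window of width `window` nt in the model's reading
#' direction.
#'
#' @param hits Tibble with one row per model hit in clone coordinates:
#'   columns `clone_id`, `a` (offset of the model in the clone, nt), `span`
#'   (model span, nt) and `model_strand` (orientation of the model within
#'   the clone). Additional columns are carried through.
#' @param clones Clone mapping tibble (columns `clone_id`, `chromosome`,
#'   `x`, `y`, `clone_strand`), see [read_clone_mappings()].
#' @param window Search-window width W in nt (default 2000).
#' @return The hits tibble augmented with `chromosome`, `case`, `a_prime`,
#'   `z` and `chrom_strand`.
#' @export
map_hit_to_chromosome <- function(hits, clones, window = 2000L) {
  m <- left_join(hits, clones, by = "clone_id")
  if (any(is.na(m$chromosome))) {
    abort(paste0("unknown clone id(s): ",
                 paste(unique(m$clone_id[is.na(m$chromosome)]), collapse = ", ")))
  }
  if (any(m$a < 0) || any(m$a + m$span > m$y - m$x)) {
    abort("model hit extends past the clone boundary")
  }
  m <- left_join(m, case_table, by = c("model_strand", "clone_strand"))
  m |>
    mutate(
      a_prime = ifelse(.data$clone_strand == "+",
                       .data$x + .data$a, .data$y - .data$a),
      z = ifelse(.data$chrom_strand == "+",
                 .data$a_prime + window, .data$a_prime - window)
    )
}

#' Invert the clone-to-chromosome mapping
#'
#' Recovers the clone-frame offset `a` from a mapped hit; the round trip
#' `map_hit_to_chromosome()` then `map_hit_to_clone()` is the identity.
#'
#' @param mapped Output of [map_hit_to_chromosome()].
#' @return `mapped` with column `a` recomputed from `a_prime`.
#' @export
map_hit_to_clone <- function(mapped) {
  mutate(mapped,
         a = ifelse(.data$clone_strand == "+",
                    .data$a_prime - .data$x, .data$y - .data$a_prime))
}

#' Select candidate co-regulated genes downstream of mapped model hits
#'
#' Within each hit's TSS search window `[a', z]`, genes are retained when
#' they (1) lie on the hit's chromosomal strand, read in the same direction,
#' directly downstream of the model; (2) have a TSS at most
#' `max_tss_distance` nt from the model's 3' end, or overlap the model by at
#' most `max_overlap` nt; and (3) are not entered beyond `max_overlap` nt.
#' Genes failing a filter are returned with the failed filter named so that
#' rejections are auditable; restrict to `retained` for the final candidate
#' list.
#'
#' @param mapped Mapped hits from [map_hit_to_chromosome()].
#' @param genes Gene annotation tibble from [parse_annotations()] (columns
#'   `gene_id`, `chromosome`, `strand`, `tss`).
#' @param max_tss_distance Maximum distance (nt, inclusive) from the model
#'   3' end to the TSS (default 500).
#' @param max_overlap Maximum model/gene overlap (nt, inclusive; default
#'   200).
#' @return A tibble with one row per (hit, gene-in-window) pair: `gene_id`,
#'   `chromosome`, `gene_strand`, `case`, `a_prime`, `z`, `tss_distance`
#'   (negative = overlap), `overlap_len`, `failed_filter` (`NA`, or one of
#'   `"orientation"`, `"tss_distance"`, `"overlap"`) and `retained`, sorted
#'   by chromosome, `a_prime`, `gene_id`.
#' @export
assign_genes <- function(mapped, genes, max_tss_distance = 500L,
                         max_overlap = 200L) {
  rows <- map(seq_len(nrow(mapped)), function(i) {
    hit <- mapped[i, ]
    lo <- min(hit$a_prime, hit$z)
    hi <- max(hit$a_prime, hit$z)
    cand <- filter(genes, .data$chromosome == hit$chromosome,
                   .data$tss >= lo, .data$tss <= hi)
    if (nrow(cand) == 0L) return(NULL)
    three_end <- if (hit$chrom_strand == "+") hit$a_prime + hit$span
                 else hit$a_prime - hit$span
    d <- if (hit$chrom_strand == "+") cand$tss - three_end
         else three_end - cand$tss
    overlap <- ifelse(d < 0, pmin(-d, hit$span), 0L)
    failed <- dplyr::case_when(
      cand$strand != hit$chrom_strand ~ "orientation",
      d >= 0 & d > max_tss_distance ~ "tss_distance",
      d < 0 & overlap > max_overlap ~ "overlap",
      TRUE ~ NA_character_
    )
    tibble(
      gene_id = cand$gene_id,
      chromosome = cand$chromosome,
      gene_strand = cand$strand,
      case = hit$case,
      clone_id = hit$clone_id,
      a_prime = hit$a_prime,
      z = hit$z,
      tss_distance = as.numeric(d),
      overlap_len = as.numeric(overlap),
      failed_filter = failed,
      retained = is.na(failed)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      gene_id = character(), chromosome = character(),
      gene_strand = character(), case = character(), clone_id = character(),
      a_prime = numeric(), z = numeric(), tss_distance = numeric(),
      overlap_len = numeric(), failed_filter = character(),
      retained = logical()
    ))
  }
  arrange(out, .data$chromosome, .data$a_prime, .data$gene_id)
}

#' Write candidate genes as TSV
#'
#' @param candidates Output of [assign_genes()].
#' @param path File path.
#' @export
write_candidates <- function(candidates, path) {
  readr::write_tsv(candidates, path)
  invisible(path)
}
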