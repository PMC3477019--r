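# Ground-truthed synthetic inputs for every pipeline stage. Each generator
# is driven by a single integer seed (recorded in the truth object) and is
# bit-reproducible: the same seed yields byte-identical files.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# A concrete sequence realizing a model element: PWM elements contribute
# their consensus, IUPAC elements one random base per degeneracy class.
realize_element <- function(el) {
  if (el$type == "pwm") return(pwm_consensus(el$motif))
  chars <- seq_chars(el$motif$pattern)
  paste(vapply(chars, function(c) {
    opts <- setdiff(IUPAC_SETS[[c]], "N")
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Generate a promoter set with a planted regulatory model
#'
#' Draws i.i.d. background sequence at the stated GC content and inserts,
#' into a `plant_fraction` subset of the records, one instance of the model
#' (element realizations in order) with each inter-element gap drawn
#' uniformly from `mid +/- gap_jitter` nt, where `mid` is the midpoint of
#' the model's allowed gap range. All placements are recorded in the truth
#' object.
#'
#' @param n_sequences Number of promoter records.
#' @param length Record length in nt (default 2000, i.e. a 1500 + 500
#'   promoter window).
#' @param planted_model A [regulatory_model()] with concrete (non-`ref`)
#'   elements.
#' @param gap_jitter Half-width (nt) of the planted gap jitter.
#' @param background_gc Background GC fraction (default 0.5).
#' @param plant_fraction Fraction of records receiving an instance
#'   (default 1).
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes `promoters.fasta`
#'   and `truth.json` there.
#' @return A list with `sequences` (DNAStringSet) and `truth` (list:
#'   `seed`, parameters, and `placements`, a tibble of `sequence_id`,
#'   `offset`, `element_starts`, `gaps`).
#' @export
make_promoter_set <- function(n_sequences, length = 2000L, planted_model,
                              gap_jitter = 2L, background_gc = 0.5,
                              plant_fraction = 1.0, seed = 1L,
                              out_dir = NULL) {
  el_seqs0 <- map(planted_model$elements, function(el) {
    if (el$type == "ref") abort("planted model must have concrete elements")
    el
  })
  withr::with_seed(seed, {
    ids <- sprintf("prom_%02d", seq_len(n_sequences))
    planted_ids <- ids[seq_len(round(plant_fraction * n_sequences))]
    placements <- list()
    seqs <- vapply(ids, function(id) {
      s <- random_dna(length, background_gc)
      if (id %in% planted_ids) {
        el_seqs <- vapply(el_seqs0, realize_element, character(1))
        mids <- round((planted_model$gaps$dmin + planted_model$gaps$dmax) / 2)
        gaps <- vapply(mids, function(m) {
          max(0L, m + sample.int(2L * gap_jitter + 1L, 1L) - gap_jitter - 1L)
        }, numeric(1))
        insert <- paste0(el_seqs[1],
                         paste(vapply(seq_along(gaps), function(j) {
                           paste0(random_dna(gaps[j], background_gc),
                                  el_seqs[j + 1L])
                         }, character(1)), collapse = ""))
        if (nchar(insert) > length) abort("planted model does not fit")
        off <- sample.int(length - nchar(insert) + 1L, 1L) - 1L
        s <- paste0(substr(s, 1, off), insert,
                    substr(s, off + nchar(insert) + 1L, length))
        starts <- off + cumsum(c(0, head(nchar(el_seqs), -1) + gaps))
        placements[[id]] <<- tibble(
          sequence_id = id, offset = off,
          element_starts = list(as.integer(starts)),
          gaps = list(as.integer(gaps))
        )
      }
      s
    }, character(1))
    sequences <- Biostrings::DNAStringSet(setNames(seqs, ids))
    truth <- list(
      seed = seed,
      params = list(n_sequences = n_sequences, length = length,
                    gap_jitter = gap_jitter, background_gc = background_gc,
                    plant_fraction = plant_fraction,
                    model = planted_model$name),
      placements = bind_rows(placements)
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(sequences, file.path(out_dir, "promoters.fasta"))
      write_truth(truth, file.path(out_dir, "truth.json"))
    }
    list(sequences = sequences, truth = truth)
  })
}

#' Generate a toy genome exercising the clone-orientation cases
#'
#' Builds one chromosome per requested orientation case (A-D): a clone with
#' known chromosomal placement `(x, y, clone_strand)`, a model instance at
#' clone offset `a`, a target gene whose TSS sits a known, retained distance
#' downstream of the model's 3' end in its reading direction, and decoy
#' genes each violating exactly one selection filter (wrong strand, TSS
#' distance just past the limit, overlap past the limit).
#'
#' @param cases Subset of `c("A","B","C","D")`.
#' @param decoy_genes Decoys per case (cycled through the three violation
#'   types).
#' @param seed Integer seed.
#' @param model_span Model span in nt (default 300; must exceed the overlap
#'   limit for the overlap decoy to be constructible).
#' @param window Search-window width W (default 2000).
#' @param max_tss_distance,max_overlap The filter limits the decoys are
#'   placed against (defaults 500 and 200).
#' @param target_distance TSS distance of the planted target gene
#'   (default 300).
#' @param out_dir Optional directory; writes `genome.fasta`, `clones.tsv`,
#'   `genes.gff3`, `hits.tsv` and `truth.json`.
#' @return A list with `genome` (DNAStringSet), `clones` (tibble), `genes`
#'   (tibble in the [parse_annotations()] convention), `hits` (clone-frame
#'   model hits for [map_hit_to_chromosome()]) and `truth`.
#' @export
make_genome_fixture <- function(cases = c("A", "B", "C", "D"),
                                decoy_genes = 3L, seed = 1L,
                                model_span = 300L, window = 2000L,
                                max_tss_distance = 500L, max_overlap = 200L,
                                target_distance = 300L, out_dir = NULL) {
  stopifnot(length(cases) >= 1L, all(cases %in% case_table$case))
  withr::with_seed(seed, {
    chr_len <- 16000L
    x <- 2000L
    y <- 12000L
    a <- 1500L
    gene_len <- 2000L
    decoy_types <- rep(c("strand", "distance", "overlap"),
                       length.out = decoy_genes)
    genome <- list()
    clones <- list()
    genes <- list()
    hits <- list()
    truth_rows <- list()
    mk_gene <- function(gene_id, chromosome, strand, tss) {
      if (strand == "+") {
        tibble(gene_id = gene_id, chromosome = chromosome, strand = strand,
               start = tss, end = min(tss + gene_len, chr_len), tss = tss)
      } else {
        tibble(gene_id = gene_id, chromosome = chromosome, strand = strand,
               start = max(0L, tss + 1L - gene_len), end = tss + 1L,
               tss = tss)
      }
    }
    for (case in cases) {
      cfg <- case_table[case_table$case == case, ]
      chrom <- paste0("chr", case)
      genome[[chrom]] <- random_dna(chr_len, 0.5)
      clones[[chrom]] <- tibble(
        clone_id = paste0("clone", case), chromosome = chrom,
        x = x, y = y, clone_strand = cfg$clone_strand
      )
      a_prime <- if (cfg$clone_strand == "+") x + a else y - a
      sgn <- if (cfg$chrom_strand == "+") 1L else -1L
      three_end <- a_prime + sgn * model_span
      hits[[chrom]] <- tibble(
        model = paste0("model", case), clone_id = paste0("clone", case),
        a = a, span = model_span, model_strand = cfg$model_strand
      )
      target_tss <- three_end + sgn * target_distance
      genes[[paste0(chrom, "_target")]] <-
        mk_gene(paste0("target_", case), chrom, cfg$chrom_strand, target_tss)
      truth_rows[[chrom]] <- tibble(
        case = case, chromosome = chrom, x = x, y = y,
        clone_strand = cfg$clone_strand, model_strand = cfg$model_strand,
        chrom_strand = cfg$chrom_strand, a = a, span = model_span,
        a_prime = a_prime, z = a_prime + sgn * window,
        target_gene = paste0("target_", case),
        target_tss = target_tss
      )
      type_seen <- c(strand = 0L, distance = 0L, overlap = 0L)
      for (k in seq_along(decoy_types)) {
        ty <- decoy_types[k]
        j <- type_seen[[ty]]  # 0 for the first decoy of each type
        type_seen[[ty]] <- j + 1L
        gid <- paste0("decoy_", case, "_", ty, "_", k)
        g <- switch(ty,
          strand = mk_gene(gid, chrom,
                           if (cfg$chrom_strand == "+") "-" else "+",
                           three_end + sgn * (target_distance + 10L * (j + 1L))),
          # first distance decoy sits exactly 1 nt past the limit
          distance = mk_gene(gid, chrom, cfg$chrom_strand,
                             three_end + sgn * (max_tss_distance + 1L + 5L * j)),
          overlap = mk_gene(gid, chrom, cfg$chrom_strand,
                            three_end - sgn * (max_overlap + 50L + 5L * j))
        )
        genes[[paste0(chrom, "_", gid)]] <- g
        truth_rows[[paste0(chrom, "_", gid)]] <- tibble(
          case = case, chromosome = chrom, x = x, y = y,
          clone_strand = cfg$clone_strand, model_strand = cfg$model_strand,
          chrom_strand = cfg$chrom_strand, a = a, span = model_span,
          a_prime = a_prime, z = a_prime + sgn * window,
          target_gene = NA_character_, target_tss = NA_integer_,
          decoy_gene = gid, decoy_type = ty
        )
      }
    }
    genome <- Biostrings::DNAStringSet(unlist(genome))
    clones <- bind_rows(clones)
    genes <- bind_rows(genes)
    hits <- bind_rows(hits)
    truth <- list(
      seed = seed,
      params = list(cases = cases, decoy_genes = decoy_genes,
                    model_span = model_span, window = window,
                    max_tss_distance = max_tss_distance,
                    max_overlap = max_overlap,
                    target_distance = target_distance),
      planted = bind_rows(truth_rows)
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_fasta(genome, file.path(out_dir, "genome.fasta"))
      readr::write_tsv(clones, file.path(out_dir, "clones.tsv"))
      write_gff3(genes, file.path(out_dir, "genes.gff3"))
      readr::write_tsv(hits, file.path(out_dir, "hits.tsv"))
      write_truth(truth, file.path(out_dir, "truth.json"))
    }
    list(genome = genome, clones = clones, genes = genes, hits = hits,
         truth = truth)
  })
}

# Write a gene tibble (internal 0-based half-open convention) as GFF3.
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Generate an expression matrix with planted over-expression
#'
#' Log-normal baseline intensities per probe, multiplied in the first
#' (target) tissue by the planted fold for selected probes, with Gaussian
#' noise on the log scale.
#'
#' @param n_probes Number of probes.
#' @param n_samples_per_tissue Samples per tissue.
#' @param tissues Tissue labels; the first is the target tissue carrying
#'   the planted effects.
#' @param planted_up Data frame with columns `probe` (ids among
#'   `probe_0001` style names or indices) and `fold` (> 0).
#' @param noise_sd Standard deviation of the log-scale noise (>= 0).
#' @param seed Integer seed.
#' @param out_dir Optional directory; writes `expression.tsv`, `groups.tsv`
#'   and `truth.json`.
#' @return A list with `em` (an [expression_matrix()]) and `truth`.
#' @export
make_expression_fixture <- function(n_probes, n_samples_per_tissue,
                                    tissues = c("target", "reference"),
                                    planted_up = NULL, noise_sd = 0.1,
                                    seed = 1L, out_dir = NULL) {
  stopifnot(noise_sd >= 0, length(tissues) >= 2L)
  if (!is.null(planted_up)) {
    planted_up <- as_tibble(planted_up)
    stopifnot(all(planted_up$fold > 0))
    if (is.numeric(planted_up$probe)) {
      planted_up$probe <- sprintf("probe_%04d", planted_up$probe)
    }
  } else {
    planted_up <- tibble(probe = character(), fold = numeric())
  }
  withr::with_seed(seed, {
    probes <- sprintf("probe_%04d", seq_len(n_probes))
    samples <- unlist(map(tissues, function(t)
      paste0(t, "_s", seq_len(n_samples_per_tissue))))
    groups <- setNames(rep(tissues, each = n_samples_per_tissue), samples)
    baseline <- exp(rnorm(n_probes, mean = log(100), sd = 1))
    fold <- setNames(rep(1, n_probes), probes)
    fold[planted_up$probe] <- planted_up$fold
    values <- matrix(0, nrow = n_probes, ncol = length(samples),
                     dimnames = list(probes, samples))
    for (j in seq_along(samples)) {
      eff <- if (groups[j] == tissues[1]) fold else rep(1, n_probes)
      values[, j] <- baseline * eff *
        exp(rnorm(n_probes, mean = 0, sd = noise_sd))
    }
    em <- expression_matrix(values, groups)
    truth <- list(
      seed = seed,
      params = list(n_probes = n_probes,
                    n_samples_per_tissue = n_samples_per_tissue,
                    tissues = tissues, noise_sd = noise_sd),
      planted = planted_up
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      df <- as_tibble(values, rownames = "probe")
      readr::write_tsv(df, file.path(out_dir, "expression.tsv"))
      readr::write_tsv(tibble(sample = samples, tissue = unname(groups)),
                       file.path(out_dir, "groups.tsv"))
      write_truth(truth, file.path(out_dir, "truth.json"))
    }
    list(em = em, truth = truth)
  })
}

write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
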