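#' Read a DNA FASTA file
#'
#' Reads a (possibly multi-record) FASTA file, uppercases soft-masked
#' residues, and validates the alphabet against `{A,C,G,T,N,-}`. Record ids
#' must be unique; the id is the first whitespace-delimited token of the
#' header, the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with the
#'   descriptions in `metadata(x)$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  res <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN-]", res)
  if (any(bad)) {
    abort(paste0("sequence(s) with characters outside {A,C,G,T,N,-}: ",
                 paste(ids[bad], collapse = ", ")))
  }
  if (any(nchar(res) == 0L)) abort("empty sequence record(s) in FASTA")
  out <- Biostrings::DNAStringSet(setNames(res, ids))
  S4Vectors::metadata(out)$description <- setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  v <- as_seq_vector(seqs)
  if (is.null(names(v)) || any(names(v) == "")) {
    abort("all sequences must be named to write FASTA")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(v)) {
    writeLines(paste0(">", names(v)[i]), con)
    s <- v[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse gene annotations from GFF3 or BED
#'
#' Converts annotation records to the package's internal coordinate
#' convention: 0-based, half-open intervals on the forward chromosome strand.
#' GFF3 input (1-based, inclusive) and BED input (already 0-based half-open)
#' are both supported. The transcription start site is derived strand-aware:
#' the interval's left edge for `+` genes and `end - 1` for `-` genes.
#'
#' @param path Path to a GFF3 or 6-column BED file.
#' @param dialect `"gff3"` or `"bed"`. Defaults to guessing from the file
#'   extension.
#' @return A tibble with columns `gene_id`, `chromosome`, `strand`, `start`,
#'   `end`, `tss`, in stable input order.
#' @export
parse_annotations <- function(path, dialect = c("auto", "gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  validate_annotation_lines(path, dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3")
  if (length(gr) == 0L) {
    return(tibble(gene_id = character(), chromosome = character(),
                  strand = character(), start = integer(), end = integer(),
                  tss = integer()))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  ids <- if (dialect == "bed") {
    S4Vectors::mcols(gr)$name
  } else {
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
    if ("Name" %in% names(mc)) id <- ifelse(is.na(id), as.character(mc$Name), id)
    if ("gene_id" %in% names(mc)) id <- ifelse(is.na(id), as.character(mc$gene_id), id)
    id
  }
  if (any(is.na(ids))) {
    ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  }
  start0 <- BiocGenerics::start(gr) - 1L  # GRanges is 1-based inclusive
  end0 <- BiocGenerics::end(gr)
  tibble(
    gene_id = as.character(ids),
    chromosome = as.character(GenomeInfoDb::seqnames(gr)),
    strand = strand,
    start = as.integer(start0),
    end = as.integer(end0),
    tss = as.integer(ifelse(strand == "+", start0, end0 - 1L))
  )
}

# Pre-scan raw lines so malformed records are reported with a line number
# (rtracklayer silently coerces e.g. an absent strand to "*").
validate_annotation_lines <- function(path, dialect) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "#")) next
    if (dialect == "bed" && (startsWith(line, "track") || startsWith(line, "browser"))) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (dialect == "bed") {
      if (length(f) < 6L) {
        abort(paste0("malformed BED line ", i, ": expected >= 6 fields, got ",
                     length(f)))
      }
      if (is.na(suppressWarnings(as.numeric(f[2]))) ||
          is.na(suppressWarnings(as.numeric(f[3])))) {
        abort(paste0("malformed BED line ", i, ": non-numeric coordinates"))
      }
      if (f[6] %!in% c("+", "-")) {
        abort(paste0("unknown strand symbol '", f[6], "' at line ", i))
      }
    } else {
      if (length(f) != 9L) {
        abort(paste0("malformed GFF3 line ", i, ": expected 9 fields, got ",
                     length(f)))
      }
      if (is.na(suppressWarnings(as.numeric(f[4]))) ||
          is.na(suppressWarnings(as.numeric(f[5])))) {
        abort(paste0("malformed GFF3 line ", i, ": non-numeric coordinates"))
      }
      if (f[7] %!in% c("+", "-")) {
        abort(paste0("unknown strand symbol '", f[7], "' at line ", i))
      }
    }
  }
  invisible(TRUE)
}

#' Extract promoter regions around transcription start sites
#'
#' For each gene, extracts the window spanning `upstream_len` nucleotides
#' upstream of the TSS plus `downstream_len` nucleotides of the gene itself
#' (TSS included), reported 5'->3' on the gene's coding strand (minus-strand
#' windows are reverse-complemented). Windows running off a chromosome end
#' are truncated and flagged, never an error.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @param genes Tibble of gene annotations as returned by
#'   [parse_annotations()] (columns `gene_id`, `chromosome`, `strand`, `tss`).
#' @param upstream_len,downstream_len Window extents in nt (defaults 1500 and
#'   500).
#' @return A tibble with columns `gene_id`, `residues`, `upstream_len`,
#'   `downstream_len` (the extents actually obtained), `tss_offset` (0-based
#'   index of the TSS within `residues`) and `truncated`.
#' @export
extract_promoter <- function(genome, genes, upstream_len = 1500L,
                             downstream_len = 500L) {
  gv <- as_seq_vector(genome)
  rows <- pmap(
    list(genes$gene_id, genes$chromosome, genes$strand, genes$tss),
    function(gene_id, chromosome, strand, tss) {
      if (chromosome %!in% names(gv)) {
        abort(paste0("chromosome '", chromosome, "' absent from genome (gene ",
                     gene_id, ")"))
      }
      chr <- gv[[chromosome]]
      len <- nchar(chr)
      if (strand == "+") {
        lo <- tss - upstream_len
        hi <- tss + downstream_len   # half-open
      } else {
        lo <- tss - downstream_len + 1L
        hi <- tss + upstream_len + 1L
      }
      clo <- max(0L, lo)
      chi <- min(len, hi)
      if (chi <= clo) abort(paste0("promoter window empty for gene ", gene_id))
      res <- substr(chr, clo + 1L, chi)
      if (strand == "-") res <- revcomp_chr(res)
      up_actual <- if (strand == "+") tss - clo else chi - 1L - tss
      down_actual <- nchar(res) - up_actual
      tibble(
        gene_id = gene_id, residues = res,
        upstream_len = as.integer(up_actual),
        downstream_len = as.integer(down_actual),
        tss_offset = as.integer(up_actual),
        truncated = (clo > lo) || (chi < hi)
      )
    }
  )
  bind_rows(rows)
}

#' Quality-filter sequences by gaps and unknown-base content
#'
#' Discards sequences containing alignment gaps (`-`) and sequences whose
#' fraction of `N` over the assessed region strictly exceeds
#' `max_unknown_frac` (a sequence at exactly the threshold is kept).
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param max_unknown_frac Maximum tolerated `N` fraction (default 0.10).
#' @param drop_gapped Discard any sequence containing `-` (default TRUE).
#' @param region Optional integer pair `c(from, to)` (1-based, inclusive)
#'   restricting the `N`-fraction computation to a sub-window, e.g. the
#'   promoter part of a longer import.
#' @return A list with `kept` (DNAStringSet), `discarded` (DNAStringSet) and
#'   `report`, a tibble of `(id, reason)` for every discard
#'   (reasons: `"gap"`, `"unknown-fraction"`).
#' @export
qc_filter_sequences <- function(seqs, max_unknown_frac = 0.10,
                                drop_gapped = TRUE, region = NULL) {
  stopifnot(max_unknown_frac >= 0, max_unknown_frac <= 1)
  v <- as_seq_vector(seqs)
  if (length(v) == 0L) {
    return(list(kept = Biostrings::DNAStringSet(),
                discarded = Biostrings::DNAStringSet(),
                report = tibble(id = character(), reason = character())))
  }
  reason <- rep(NA_character_, length(v))
  for (i in seq_along(v)) {
    s <- v[[i]]
    if (drop_gapped && grepl("-", s, fixed = TRUE)) {
      reason[i] <- "gap"
      next
    }
    part <- if (is.null(region)) s else {
      substr(s, max(1L, region[1]), min(nchar(s), region[2]))
    }
    n_frac <- (nchar(part) - nchar(gsub("N", "", part, fixed = TRUE))) / nchar(part)
    if (n_frac > max_unknown_frac) reason[i] <- "unknown-fraction"
  }
  keep <- is.na(reason)
  list(
    kept = Biostrings::DNAStringSet(v[keep]),
    discarded = Biostrings::DNAStringSet(v[!keep]),
    report = tibble(id = names(v)[!keep], reason = reason[!keep])
  )
}
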