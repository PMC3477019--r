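# The ANT2-style example model: CATTGTT (GRBOX) / TCCCC / GGGC / TATAA
ant2_like_model <- function(quorum_k = 4L, dmax = 40) {
  regulatory_model(
    "ant2_like",
    list(
      model_element(iupac_motif("GRBOX", "CATTGTT")),
      model_element(iupac_motif("MZF1", "TCCCC")),
      model_element(iupac_motif("EGR1", "GGGC")),
      model_element(iupac_motif("TATA", "TATAA"))
    ),
    gaps = data.frame(dmin = c(0, 0, 0), dmax = rep(dmax, 3)),
    quorum_k = quorum_k
  )
}

ant2_like_sequence <- function() {
  paste0("CATTGTT", strrep("A", 10), "TCCCC", strrep("A", 5), "GGGC",
         strrep("A", 20), "TATAA")
}

test_that("a planted ordered element chain yields exactly one model hit", {
  s <- setNames(ant2_like_sequence(), "p")
  h <- scan_model(s, ant2_like_model())
  expect_equal(nrow(h), 1L)
  expect_equal(h$orientation, "+")
  expect_equal(h$matched_count, 4L)
  eh <- h$element_hits[[1]]
  expect_equal(eh$motif, c("GRBOX", "MZF1", "EGR1", "TATA"))
  expect_true(all(diff(eh$start) > 0))
  expect_equal(h$start, 0L)
  expect_equal(h$end, unname(nchar(s)))
})

test_that("all elements are required in order (full quorum)", {
  # element removed -> no hit
  s2 <- setNames(sub("TCCCC", "AAAAA", ant2_like_sequence()), "p")
  expect_equal(nrow(scan_model(s2, ant2_like_model())), 0L)
  # permuted order -> no hit
  s3 <- setNames(paste0("TCCCC", strrep("A", 10), "CATTGTT", strrep("A", 5),
                        "GGGC", strrep("A", 20), "TATAA"), "p")
  h3 <- scan_model(s3, ant2_like_model())
  expect_equal(nrow(h3[h3$matched_count == 4L, ]), 0L)
})

test_that("relaxed quorum_k accepts chains missing elements", {
  s2 <- setNames(sub("TCCCC", "AAAAA", ant2_like_sequence()), "p")
  h <- scan_model(s2, ant2_like_model(quorum_k = 3L))
  expect_gte(nrow(h), 1L)
  expect_true(all(h$matched_count >= 3L))
  best <- h[which.max(h$matched_count), ]
  expect_equal(best$element_hits[[1]]$motif, c("GRBOX", "EGR1", "TATA"))
})

test_that("minus-orientation hits are reported in forward coordinates", {
  s <- ant2_like_sequence()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h <- scan_model(setNames(rc, "p"), ant2_like_model())
  expect_equal(nrow(h), 1L)
  expect_equal(h$orientation, "-")
  expect_equal(h$start, 0L)
  expect_equal(h$end, nchar(s))
  eh <- h$element_hits[[1]]
  expect_true(all(eh$strand == "-"))
  # element order in model order = descending forward coordinates
  expect_true(all(diff(eh$start) < 0))
})

test_that("gap ranges are inclusive at both ends", {
  m <- regulatory_model(
    "two",
    list(model_element(iupac_motif("a", "CATTG")),
         model_element(iupac_motif("b", "TCCCC"))),
    gaps = data.frame(dmin = 10, dmax = 10)
  )
  hit <- function(gap) {
    s <- setNames(paste0("CATTG", strrep("A", gap), "TCCCC"), "x")
    nrow(scan_model(s, m)[scan_model(s, m)$orientation == "+", ])
  }
  expect_equal(hit(10), 1L)
  expect_equal(hit(9), 0L)
  expect_equal(hit(11), 0L)
})

test_that("chaining equals brute-force enumeration on small inputs", {
  lib <- list(a = iupac_motif("a", "CAT"), b = iupac_motif("b", "GGA"),
              c = iupac_motif("c", "TTC"))
  model <- regulatory_model(
    "bf", lapply(lib, model_element),
    gaps = data.frame(dmin = c(0, 0), dmax = c(15, 15))
  )
  brute <- function(s) {
    n <- nchar(s)
    out <- list()
    for (orient in c("+", "-")) {
      str <- if (orient == "+") s else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      hits <- lapply(lib, function(m)
        scan_iupac(setNames(str, "x"), m, strands = "forward"))
      if (any(vapply(hits, nrow, integer(1)) == 0)) next
      combos <- expand.grid(i = seq_len(nrow(hits[[1]])),
                            j = seq_len(nrow(hits[[2]])),
                            k = seq_len(nrow(hits[[3]])))
      for (r in seq_len(nrow(combos))) {
        h1 <- hits[[1]][combos$i[r], ]
        h2 <- hits[[2]][combos$j[r], ]
        h3 <- hits[[3]][combos$k[r], ]
        g1 <- h2$start - h1$end
        g2 <- h3$start - h2$end
        if (g1 >= 0 && g1 <= 15 && g2 >= 0 && g2 <= 15) {
          span <- c(h1$start, h3$end)
          if (orient == "-") span <- c(n - span[2], n - span[1])
          out[[length(out) + 1]] <- paste(span[1], span[2], orient)
        }
      }
    }
    sort(unique(unlist(out)))
  }
  set.seed(13)
  n_nonempty <- 0
  for (i in 1:20) {
    # enriched background so chains actually occur
    s <- paste(sample(c("CAT", "GGA", "TTC", "AA", "C"), 60, replace = TRUE,
                      prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), collapse = "")
    s <- substr(s, 1, 150)
    got <- scan_model(setNames(s, "x"), model)
    got_keys <- sort(unique(paste(got$start, got$end, got$orientation)))
    expect_identical(got_keys, brute(s))
    if (nrow(got) > 0) n_nonempty <- n_nonempty + 1
  }
  expect_gte(n_nonempty, 3)  # the comparison must exercise real chains
})

test_that("widening gaps or lowering quorum never removes hits", {
  s <- setNames(ant2_like_sequence(), "p")
  narrow <- scan_model(s, ant2_like_model(dmax = 25))
  wide <- scan_model(s, ant2_like_model(dmax = 60))
  key <- function(h) paste(h$start, h$end, h$orientation)
  expect_true(all(key(narrow) %in% key(wide)))
  relaxed <- scan_model(s, ant2_like_model(quorum_k = 3L))
  expect_true(all(key(wide) %in% key(relaxed)))
})

test_that("a single-element model degenerates to the plain motif scan", {
  m <- regulatory_model("one", list(model_element(iupac_motif("g", "CATTGTT"))),
                        gaps = data.frame())
  s <- setNames(paste0("AAA", "CATTGTT", "CCC"), "x")
  h <- scan_model(s, m)
  direct <- scan_iupac(s, iupac_motif("g", "CATTGTT"))
  expect_equal(nrow(h), nrow(direct))
  expect_equal(sort(h$start), sort(direct$start))
})

test_that("screen_promoter_set summarizes planted promoters correctly", {
  model <- ant2_like_model()
  set.seed(8)
  planted_ids <- c("p02", "p05", "p09")
  seqs <- setNames(lapply(sprintf("p%02d", 1:10), function(id) {
    bg <- random_seq(400)
    if (id %in% planted_ids) {
      paste0(substr(bg, 1, 100), ant2_like_sequence(), substr(bg, 160, 400))
    } else bg
  }), sprintf("p%02d", 1:10))
  seqs <- vapply(seqs, identity, character(1))
  scr <- screen_promoter_set(seqs, model)
  expect_equal(scr$n_sequences, 10L)
  expect_setequal(scr$sequences_with_hits, planted_ids)
  g <- glance(scr)
  expect_equal(g$n_with_hits, 3L)
  # double placement in one promoter -> 2 hits for that id
  dbl <- setNames(paste0(ant2_like_sequence(), strrep("G", 50),
                         ant2_like_sequence()), "d")
  h <- scan_model(dbl, model)
  expect_equal(nrow(h), 2L)
  # empty set
  e <- screen_promoter_set(setNames(character(0), character(0)), model)
  expect_equal(glance(e)$n_sequences, 0L)
})

test_that("cross-species conservation passes at min_species", {
  model <- ant2_like_model()
  set.seed(15)
  sets <- lapply(1:6, function(i) {
    ids <- paste0("sp", i, "_prom")
    s <- if (i <= 5) paste0(random_seq(50), ant2_like_sequence(),
                            random_seq(50)) else random_seq(300)
    setNames(s, ids)
  })
  names(sets) <- paste0("species", 1:6)
  rep5 <- conserved_across_species(model, sets, min_species = 5)
  expect_true(rep5$pass)
  expect_setequal(rep5$species$species[rep5$species$present],
                  paste0("species", 1:5))
  rep6 <- conserved_across_species(model, sets, min_species = 6)
  expect_false(rep6$pass)
  expect_true(conserved_across_species(model, sets[1], min_species = 1)$pass)
  expect_warning(
    res <- conserved_across_species(model, sets, min_species = 10),
    "never pass"
  )
  expect_false(res$pass)
  # empty species set counts as absent with a warning
  sets$empty <- setNames(character(0), character(0))
  expect_warning(r <- conserved_across_species(model, sets, 5), "empty")
  expect_false(r$species$present[r$species$species == "empty"])
})

test_that("model files round-trip and resolve against libraries", {
  m <- ant2_like_model()
  path <- withr::local_tempfile(fileext = ".model")
  write_model_file(list(ant2_like = m), path)
  back <- read_model_file(path)[["ant2_like"]]
  expect_equal(length(back$elements), 4L)
  expect_equal(back$gaps$dmax, m$gaps$dmax)
  expect_equal(back$quorum_k, 4L)
  lib <- list(GRBOX = iupac_motif("GRBOX", "CATTGTT"),
              MZF1 = iupac_motif("MZF1", "TCCCC"),
              EGR1 = iupac_motif("EGR1", "GGGC"),
              TATA = iupac_motif("TATA", "TATAA"))
  h <- scan_model(setNames(ant2_like_sequence(), "p"), back, motifs = lib)
  expect_equal(nrow(h), 1L)
  expect_error(scan_model(setNames(ant2_like_sequence(), "p"), back),
               "unresolvable")
})

test_that("every reported hit verifies its own invariants", {
  model <- ant2_like_model()
  s <- setNames(paste0(ant2_like_sequence(), strrep("T", 30),
                       ant2_like_sequence()), "p")
  h <- scan_model(s, model)
  for (i in seq_len(nrow(h))) {
    eh <- h$element_hits[[i]]
    expect_equal(nrow(eh), h$matched_count[i])
    ord <- if (h$orientation[i] == "+") diff(eh$start) > 0 else
      diff(eh$start) < 0
    expect_true(all(ord))
    # recheck gaps in reading direction (element rows are in model order)
    rs <- if (h$orientation[i] == "+") eh$start else nchar(s) - eh$end
    re <- if (h$orientation[i] == "+") eh$end else nchar(s) - eh$start
    gaps <- rs[-1] - re[-length(re)]
    expect_true(all(gaps >= model$gaps$dmin & gaps <= model$gaps$dmax))
  }
})
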