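tm_ann <- function(id, start, end, n = NULL) {
  segment_annotation(id, data.frame(label = "TM1", kind = "TM",
                                    start = start, end = end),
                     seq_length = n)
}

test_that("the default map applies the canonical QTY pairing", {
  rec <- protein_record("p", "LIVF")
  res <- apply_substitution(rec, tm_ann("p", 1, 4))
  expect_equal(res$variant$sequence, "QTTY")
  expect_equal(nrow(res$events), 4)
  expect_equal(res$events$from, c("L", "I", "V", "F"))
  expect_equal(res$events$to, c("Q", "T", "T", "Y"))
  expect_equal(res$events$segment_label, rep("TM1", 4))

  # nothing in scope -> identity transform
  loops <- segment_annotation("p", data.frame(label = "ICL1", kind = "ICL",
                                              start = 1, end = 4))
  res0 <- apply_substitution(rec, loops)
  expect_equal(res0$variant$sequence, "LIVF")
  expect_equal(nrow(res0$events), 0)

  # no map sources present -> no events
  g <- protein_record("g", "GGGG")
  expect_equal(nrow(apply_substitution(g, tm_ann("g", 1, 4))$events), 0)

  expect_error(apply_substitution(rec, tm_ann("other", 1, 4)), "annotation")
})

test_that("scope control: segment kinds and per-design extra positions", {
  rec <- protein_record("p", "LLLLLLLL")
  ann <- segment_annotation("p", data.frame(
    label = c("TM1", "ICL1", "CTERM"),
    kind = c("TM", "ICL", "CTERM"),
    start = c(1, 4, 7), end = c(3, 6, 8)))
  res <- apply_substitution(rec, ann, scope = c("TM", "ICL"))
  expect_equal(res$variant$sequence, "QQQQQQLL")
  res2 <- apply_substitution(rec, ann, scope = "TM", extra_positions = 8)
  expect_equal(res2$variant$sequence, "QQQLLLLQ")
  expect_equal(res2$events$segment_label, c("TM1", "TM1", "TM1", "CTERM"))
  expect_error(apply_substitution(rec, ann, extra_positions = 99),
               "out of range")
})

test_that("substitution invariants hold for random records and maps", {
  set.seed(31)
  for (k in 1:25) {
    sx <- synth_7tm_sequence(1000 + k)
    res <- apply_substitution(sx$record, sx$annotation)
    n <- nchar(res$native$sequence)
    # length conservation
    expect_equal(nchar(res$variant$sequence), n)
    # events exactly where the sequences differ, and only at L/I/V/F -> Q/T/T/Y
    ca <- strsplit(res$native$sequence, "")[[1]]
    cb <- strsplit(res$variant$sequence, "")[[1]]
    expect_equal(which(ca != cb), res$events$position)
    pair <- paste0(res$events$from, res$events$to)
    expect_true(all(pair %in% c("LQ", "IT", "VT", "FY")))
    # every event inside the TM scope
    tm_pos <- unlist(Map(seq.int,
      sx$annotation$segments$start[sx$annotation$segments$kind == "TM"],
      sx$annotation$segments$end[sx$annotation$segments$kind == "TM"]))
    expect_true(all(res$events$position %in% tm_pos))
    # idempotence: Q, T, Y are not map sources
    res2 <- apply_substitution(res$variant,
                               segment_annotation(res$variant$id,
                                                  sx$annotation$segments))
    expect_equal(nrow(res2$events), 0)
    # exact identity complement (half-up at 2 decimals)
    expect_equal(positional_identity(res$native, res$variant),
                 floor(100 * (1 - nrow(res$events) / n) * 100 + 0.5) / 100,
                 tolerance = 1e-9)
  }
})

test_that("positional identity is exact and rejects unequal lengths", {
  expect_equal(positional_identity(protein_record("a", "QTTY"),
                                   protein_record("b", "LIVF")), 0)
  r <- protein_record("a", "MKTA")
  expect_equal(positional_identity(r, r), 100)
  expect_equal(positional_identity(protein_record("a", "LIVA"),
                                   protein_record("b", "QTTA")), 25)
  expect_error(positional_identity(r, protein_record("b", "MKT")), "length")
})

test_that("variation statistics count overall and membrane rates", {
  rec <- protein_record("p", paste0("LLLL", "LLLL", strrep("G", 8)))
  ann <- tm_ann("p", 1, 8, 16)
  res <- apply_substitution(rec, ann)
  # 8 TM leucines substituted out of 16 residues
  st <- variation_stats(res, ann)
  expect_equal(st$total_variation_pct, 50)
  expect_equal(st$membrane_variation_pct, 100)

  # spec-style worked case: 4 events on a 16-mer, one 8-residue TM with all
  # events -> total 25%, membrane 50%
  rec2 <- protein_record("q", paste0("LLLLGGGG", strrep("G", 8)))
  ann2 <- tm_ann("q", 1, 8, 16)
  res2 <- apply_substitution(rec2, ann2)
  st2 <- variation_stats(res2, ann2)
  expect_equal(res2$events$position, 1:4)
  expect_equal(st2$total_variation_pct, 25)
  expect_equal(st2$membrane_variation_pct, 50)
  expect_equal(st2$identity_pct, 100 - st2$total_variation_pct)
  expect_equal(st2$n_tm_residues, 8)

  # zero events
  res0 <- apply_substitution(protein_record("z", "GGGG"), tm_ann("z", 1, 4))
  st0 <- variation_stats(res0, tm_ann("z", 1, 4))
  expect_equal(st0$total_variation_pct, 0)
  expect_equal(st0$membrane_variation_pct, 0)
})

test_that("alignment rendering marks matches, blocks and the ruler", {
  a <- protein_record("a", "LIVF")
  b <- protein_record("b", "QTTY")
  txt <- render_alignment(a, b)
  expect_match(txt, "\\*\\*\\*\\*")
  expect_match(render_alignment(a, a), "\\|\\|\\|\\|")

  a70 <- protein_record("a", strrep("L", 70))
  b70 <- protein_record("b", paste0(strrep("Q", 60), strrep("L", 10)))
  txt70 <- render_alignment(a70, b70, block_width = 60)
  lines <- strsplit(txt70, "\n")[[1]]
  # two blocks: 60 and 10 columns of match line
  stars <- grep("^\\s+[|*]+$", lines, value = TRUE)
  expect_equal(nchar(trimws(stars)), c(60, 10))
  expect_match(txt70, "60 substituted positions")

  ann <- tm_ann("a", 1, 2, 4)
  with_ruler <- render_alignment(a, b, annotation = ann)
  expect_match(with_ruler, "HH")
  expect_error(render_alignment(a70, a), "length")
})

test_that("substitution maps serialize, validate and round-trip", {
  m <- qty_map()
  back <- read_substitution_map(write_substitution_map(m))
  expect_equal(back$rules, m$rules)
  expect_equal(back$name, "QTY")
  # the appendix-style alternative codes are plain data
  to_ala <- substitution_map("toA", c(Q = "A", T = "A", Y = "A"))
  rec <- protein_record("v", "QTTY")
  expect_equal(apply_substitution(rec, tm_ann("v", 1, 4),
                                  map = to_ala)$variant$sequence, "AAAA")
  expect_error(substitution_map("bad", c(L = "L")), "itself")
  expect_error(substitution_map("bad", c(L = "B")), "valid")
})
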