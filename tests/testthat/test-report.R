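test_that("run_pair composes sequence, physchem, structure and surface", {
  dir <- withr::local_tempdir()
  files <- synth_fixture("pair", dir, seed = 5)
  expect_true(all(file.exists(files)))

  cfg <- list(pair_id = "synthpair",
              native_fasta = files[["native_fasta"]],
              segments = files[["segments"]],
              ref_pdb = files[["native_pdb"]],
              mobile_pdb = files[["variant_pdb"]],
              n_points = 240)
  rep <- run_pair(cfg)
  expect_s3_class(rep, "pair_report")
  expect_equal(rep$stats$identity_pct, 100 - rep$stats$total_variation_pct)
  expect_gt(rep$stats$n_events, 0)
  # identical coordinates -> RMSD 0; hydrophobic fraction decreases
  expect_lt(rep$superposition$rmsd, 1e-6)
  expect_lt(rep$surface$delta$fraction_change, 0)
  # provenance is populated
  expect_equal(rep$provenance$map, "QTY")
  expect_match(rep$provenance$tool, "^qtykit")

  # sequence-only config: structure fields absent
  rep0 <- run_pair(list(pair_id = "seqonly",
                        native_fasta = files[["native_fasta"]],
                        segments = files[["segments"]]))
  expect_null(rep0$superposition)
  expect_null(rep0$surface)
})

test_that("written reports are deterministic (byte-identical re-runs)", {
  dir <- withr::local_tempdir()
  files <- synth_fixture("pair", dir, seed = 9)
  cfg <- list(pair_id = "det", native_fasta = files[["native_fasta"]],
              segments = files[["segments"]])
  d1 <- file.path(dir, "r1"); d2 <- file.path(dir, "r2")
  write_pair_report(run_pair(cfg), d1)
  write_pair_report(run_pair(cfg), d2)
  for (f in c("det.tsv", "det.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("synthetic fixtures are deterministic per seed and self-consistent", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- synth_fixture("sequence", d1, seed = 1)
  f2 <- synth_fixture("sequence", d2, seed = 1)
  expect_identical(readLines(f1[["fasta"]]), readLines(f2[["fasta"]]))
  expect_identical(readLines(f1[["segments"]]), readLines(f2[["segments"]]))
  f3 <- synth_fixture("sequence", d2, seed = 2)
  expect_false(identical(readLines(f1[["fasta"]]), readLines(f3[["fasta"]])))

  # the pair fixture passes the pipeline self-checks
  fp <- synth_fixture("pair", d1, seed = 3)
  nat <- parse_fasta(fp[["native_fasta"]])[[1]]
  var <- parse_fasta(fp[["variant_fasta"]])[[1]]
  ann <- load_segments(fp[["segments"]], nat)
  ev <- read.delim(fp[["events"]])
  expect_equal(positional_identity(nat, var),
               floor(100 * (1 - nrow(ev) / nchar(nat$sequence)) * 100 + 0.5) / 100)
  reapplied <- apply_substitution(var, segment_annotation(var$id,
                                                          ann$segments))
  expect_equal(nrow(reapplied$events), 0)

  # bundle fixture: 7 x 22 -> 154 CA atoms
  fb <- synth_fixture("bundle", d1, seed = 1, n_helices = 7,
                      spec = helix_spec(22))
  expect_equal(nrow(parse_pdb(fb[["pdb"]])$atoms), 154)
})

test_that("batches continue past failing pairs", {
  dir <- withr::local_tempdir()
  files <- synth_fixture("pair", dir, seed = 7)
  good <- list(pair_id = "ok", native_fasta = files[["native_fasta"]],
               segments = files[["segments"]])
  bad <- list(pair_id = "broken", native_fasta = "/nonexistent.fasta")
  res <- run_batch(list(good, bad, modifyList(good, list(pair_id = "ok2"))))
  expect_named(res$reports, c("ok", "ok2"))
  expect_named(res$failures, "broken")

  # JSON manifest route
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(good), manifest, auto_unbox = TRUE)
  res2 <- run_batch(manifest, out_dir = file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out", "ok.tsv")))
  expect_length(res2$failures, 0)
})

test_that("the receptor battery computes per-receptor rows from flat files", {
  # only the synthetic stand-in entry is bundled; real accessions are
  # reported as missing, never fetched
  bat <- receptor_battery(extdata_path("uniprot"))
  expect_equal(sort(bat$missing), sort(battery_receptors()$accession))

  # drive it end-to-end on synthetic flat entries standing in for two
  # receptors
  dir <- withr::local_tempdir()
  for (acc in c("P61073", "P51681")) {
    sx <- synth_7tm_sequence(match(acc, battery_receptors()$accession),
                             id = acc)
    writeLines(synth_uniprot_flat(sx$record, sx$annotation),
               file.path(dir, paste0(acc, ".txt")), sep = "")
  }
  bat2 <- receptor_battery(dir)
  expect_equal(nrow(bat2$table), 2)
  expect_setequal(bat2$table$receptor, c("CXCR4", "CCR5"))
  expect_true(all(bat2$table$identity_pct ==
                  100 - bat2$table$total_variation_pct))
  expect_true(all(bat2$table$membrane_variation_pct > 0))
})

test_that("the CLI drives convert, superpose, sasa and synth", {
  dir <- withr::local_tempdir()
  files <- synth_fixture("pair", dir, seed = 11)

  out <- capture.output(status <- qty_cli(c(
    "convert", "--fasta", files[["native_fasta"]],
    "--segments", files[["segments"]])))
  expect_identical(status, 0L)
  expect_match(out[1], "^>")
  var_cli <- parse_fasta(paste(out, collapse = "\n"))[[1]]
  expect_identical(var_cli$sequence,
                   parse_fasta(files[["variant_fasta"]])[[1]]$sequence)

  moved <- file.path(dir, "moved.pdb")
  out2 <- capture.output(qty_cli(c(
    "superpose", "--ref", files[["native_pdb"]],
    "--mobile", files[["variant_pdb"]], "--out", moved)))
  expect_match(out2[2], "^rmsd\t0\\.000$")
  expect_true(file.exists(moved))

  out3 <- capture.output(qty_cli(c("sasa", "--pdb", files[["native_pdb"]],
                                   "--points", "120")))
  expect_match(out3[1], "^chain\t")
  expect_gt(length(out3), 10)

  out4 <- capture.output(qty_cli(c("synth", "--kind", "sequence",
                                   "--seed", "4", "--dir",
                                   file.path(dir, "s"))))
  expect_true(file.exists(file.path(dir, "s", "synth7tm.fasta")))

  expect_error(qty_cli(c("convert")), "--fasta is required")
  expect_error(qty_cli("nope"), "unknown subcommand")
})
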