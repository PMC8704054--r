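# End-to-end drivers: per-pair reports combining sequence, physicochemical,
# structural and surface comparisons; deterministic synthetic-fixture
# generation; and the receptor battery used against UniProt entries.

#' Run a full native/variant comparison from a configuration
#'
#' A pair configuration names a native sequence source, a segment source, a
#' substitution map and scope, and optionally a pair of structure files.
#' The driver runs substitution -> identity/variation -> pI/MW, and, when
#' structures are present, C-alpha superposition (optionally trimmed to TM
#' segments) and the native-vs-variant surface comparison.
#'
#' Recognized config fields: `pair_id`; one of `native_record` /
#' `native_fasta` / `uniprot_txt`; one of `annotation` / `segments` (TSV
#' path or text; defaults to TRANSMEM features when `uniprot_txt` is the
#' sequence source, or hydropathy inference as a last resort); `map` (a
#' [substitution_map()] or TSV path, default QTY); `scope` (default "TM");
#' `extra_positions`; `ref_pdb` / `mobile_pdb` (+ `ref_chain`,
#' `mobile_chain`, `trim`); surface parameters `probe_radius`, `n_points`,
#' `exposure_threshold`, `adjacency_cutoff`.
#'
#' @param config a named list as described above
#' @return object of class `pair_report`: `pair_id`, `native`, `variant`,
#'   `events`, `stats` ([variation_stats()]), `physchem`
#'   ([pair_physchem()]), optional `superposition` and `surface`, and a
#'   `provenance` list sufficient to re-run the pair
#' @export
run_pair <- function(config) {
  stopifnot(is.list(config))
  pair_id <- config$pair_id %||% "pair"

  native <- if (!is.null(config$native_record)) {
    config$native_record
  } else if (!is.null(config$native_fasta)) {
    parse_fasta(config$native_fasta)[[1]]
  } else if (!is.null(config$uniprot_txt)) {
    record_from_uniprot_text(config$uniprot_txt)
  } else {
    stop("[seqio] config must name a native sequence source", call. = FALSE)
  }

  annotation <- if (!is.null(config$annotation)) {
    config$annotation
  } else if (!is.null(config$segments)) {
    load_segments(config$segments, native)
  } else if (!is.null(config$uniprot_txt)) {
    transmem_from_uniprot_text(config$uniprot_txt, native)
  } else {
    infer_tm_segments(native)
  }

  map <- config$map %||% qty_map()
  if (is.character(map)) map <- read_substitution_map(map)
  scope <- config$scope %||% "TM"
  extra <- config$extra_positions %||% integer()

  result <- apply_substitution(native, annotation, map, scope, extra)
  stats <- variation_stats(result, annotation)
  physchem <- pair_physchem(result$native, result$variant)

  report <- list(pair_id = pair_id, native = result$native,
                 variant = result$variant, events = result$events,
                 stats = stats, physchem = physchem,
                 superposition = NULL, surface = NULL,
                 provenance = list(
                   tool = paste0("qtykit ",
                                 as.character(utils::packageVersion("qtykit"))),
                   native_source = config$native_fasta %||%
                     config$uniprot_txt %||% "in-memory record",
                   segment_source = config$segments %||%
                     (if (!is.null(config$uniprot_txt)) "uniprot TRANSMEM"
                      else "inferred or in-memory"),
                   map = map$name, scope = scope,
                   extra_positions = extra))

  if (!is.null(config$ref_pdb) && !is.null(config$mobile_pdb)) {
    ref <- if (inherits(config$ref_pdb, "structure_model")) config$ref_pdb
           else parse_pdb(config$ref_pdb)
    mob <- if (inherits(config$mobile_pdb, "structure_model")) config$mobile_pdb
           else parse_pdb(config$mobile_pdb)
    if (isTRUE(config$trim)) {
      ref <- trim_to_segments(ref, annotation)
      mob <- trim_to_segments(mob, annotation)
    }
    sup <- superpose_models(ref, mob, config$ref_chain, config$mobile_chain)
    report$superposition <- list(rmsd = sup$superposition$rmsd,
                                 n_matched = sup$superposition$n_matched)
    report$surface <- compare_surfaces(
      ref, mob,
      probe_radius = config$probe_radius %||% 1.4,
      n_points = config$n_points %||% 960,
      exposure_threshold = config$exposure_threshold %||% 10,
      adjacency_cutoff = config$adjacency_cutoff %||% 8)
  }
  class(report) <- "pair_report"
  report
}

#' @export
print.pair_report <- function(x, ...) {
  cat(sprintf("<pair_report> %s: %s vs %s\n", x$pair_id, x$native$id,
              x$variant$id))
  print(x$stats)
  print(x$physchem)
  if (!is.null(x$superposition)) {
    cat(sprintf("  superposition: RMSD %.3f A over %d CA\n",
                x$superposition$rmsd, x$superposition$n_matched))
  }
  if (!is.null(x$surface)) {
    cat(sprintf("  surface: hydrophobic fraction %.3f -> %.3f (delta %+.3f)\n",
                x$surface$native$hydrophobic_fraction,
                x$surface$variant$hydrophobic_fraction,
                x$surface$delta$fraction_change))
  }
  invisible(x)
}

#' One-row TSV summary of a pair report
#'
#' @param report a [run_pair()] result
#' @param header include the header line (default TRUE)
#' @return TSV text (diff-able, spreadsheet-compatible)
#' @export
pair_report_tsv <- function(report, header = TRUE) {
  s <- report$stats
  p <- report$physchem
  cols <- c(pair_id = report$pair_id,
            native = report$native$id, variant = report$variant$id,
            length = nchar(report$native$sequence),
            n_events = s$n_events,
            identity_pct = sprintf("%.2f", s$identity_pct),
            total_variation_pct = sprintf("%.2f", s$total_variation_pct),
            membrane_variation_pct = sprintf("%.2f", s$membrane_variation_pct),
            pI_native = sprintf("%.2f", p$pI_native),
            pI_variant = sprintf("%.2f", p$pI_variant),
            delta_pI = sprintf("%.2f", p$delta_pI),
            mw_native = sprintf("%.2f", p$mw_native),
            mw_variant = sprintf("%.2f", p$mw_variant),
            delta_mw = sprintf("%.2f", p$delta_mw),
            delta_mw_pct = sprintf("%.2f", p$delta_mw_pct),
            rmsd = if (is.null(report$superposition)) "NA"
                   else sprintf("%.3f", report$superposition$rmsd),
            hydrophobic_fraction_change =
              if (is.null(report$surface)) "NA"
              else sprintf("%.4f", report$surface$delta$fraction_change))
  body <- paste(cols, collapse = "\t")
  if (header) {
    paste0(paste(names(cols), collapse = "\t"), "\n", body, "\n")
  } else {
    paste0(body, "\n")
  }
}

#' Write a pair report to disk
#'
#' Emits `<pair_id>.tsv` (one-row summary) and `<pair_id>.json` (structured
#' sidecar with events, patches and provenance; no timestamps, so identical
#' inputs give byte-identical output).
#'
#' @param report a [run_pair()] result
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_pair_report <- function(report, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, paste0(report$pair_id, ".tsv"))
  writeLines(pair_report_tsv(report), tsv, sep = "")
  sidecar <- list(
    pair_id = report$pair_id,
    events = report$events,
    stats = unclass(report$stats),
    physchem = unclass(report$physchem),
    superposition = report$superposition,
    surface = if (!is.null(report$surface)) list(
      native_fraction = report$surface$native$hydrophobic_fraction,
      variant_fraction = report$surface$variant$hydrophobic_fraction,
      native_patch_areas = report$surface$native$patch_areas,
      variant_patch_areas = report$surface$variant$patch_areas,
      delta = report$surface$delta),
    provenance = report$provenance)
  js <- file.path(dir, paste0(report$pair_id, ".json"))
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, json = js))
}

#' Run a batch of pair configurations
#'
#' @param manifest a list of configs, or a path to a JSON (always supported)
#'   or YAML (requires the `yaml` package) manifest whose top level is a
#'   list of pair configs
#' @param out_dir optional directory to write per-pair reports into
#' @return list with `reports` (named by pair_id) and `failures` (named
#'   character vector of error messages); failing pairs do not stop the
#'   batch
#' @export
run_batch <- function(manifest, out_dir = NULL) {
  configs <- if (is.character(manifest)) {
    ext <- tolower(tools::file_ext(manifest))
    if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML manifests need the 'yaml' package; use JSON instead",
             call. = FALSE)
      }
      yaml::read_yaml(manifest)
    } else {
      jsonlite::read_json(manifest, simplifyVector = FALSE)
    }
  } else {
    manifest
  }
  reports <- list()
  failures <- character()
  for (cfg in configs) {
    id <- cfg$pair_id %||% paste0("pair", length(reports) + length(failures) + 1)
    r <- tryCatch(run_pair(cfg), error = function(e) e)
    if (inherits(r, "error")) {
      failures[[id]] <- conditionMessage(r)
    } else {
      reports[[id]] <- r
      if (!is.null(out_dir)) write_pair_report(r, out_dir)
    }
  }
  list(reports = reports, failures = failures)
}

# Deterministic per-seed RNG scope: never touches the global stream outside.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic 7TM sequence with its annotation
#'
#' Emulates the sequence-level architecture of a seven-transmembrane
#' receptor: an N-terminal polar stretch, seven hydrophobic helical segments
#' of 20-25 residues drawn from L, I, V, F, A, G, alternating intracellular/
#' extracellular polar loops, and a C-terminal tail. The TM composition
#' weights put the expected L+I+V+F share at 52%, the middle of the
#' membrane-variation band observed for real GPCR designs, and the segment
#' length defaults give a ~350-residue chain, a typical chemokine-receptor
#' length. Deterministic for a given seed.
#'
#' @param seed integer seed
#' @param id record id (default "synth7tm")
#' @param tm_len_range inclusive range of TM segment lengths
#' @param loop_len_range inclusive range of loop lengths
#' @param nterm_len_range,cterm_len_range inclusive ranges of terminal
#'   segment lengths
#' @return list: `record` ([protein_record()]) and `annotation`
#'   ([segment_annotation()])
#' @export
synth_7tm_sequence <- function(seed, id = "synth7tm",
                               tm_len_range = c(20, 25),
                               loop_len_range = c(10, 25),
                               nterm_len_range = c(25, 40),
                               cterm_len_range = c(40, 60)) {
  tm_pool <- c("L", "I", "V", "F", "A", "G")
  tm_w <- c(0.18, 0.12, 0.14, 0.08, 0.28, 0.20)
  loop_pool <- c("D", "E", "K", "R", "S", "T", "N", "Q", "G", "P", "H")
  with_seed(seed, {
    draw <- function(n, pool, w = NULL) {
      paste(sample(pool, n, replace = TRUE, prob = w), collapse = "")
    }
    rlen <- function(rng) sample(seq(rng[1], rng[2]), 1)
    parts <- character()
    seg <- data.frame(label = character(), kind = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    pos <- 0L
    add <- function(label, kind, s) {
      parts[[length(parts) + 1L]] <<- s
      seg[nrow(seg) + 1L, ] <<- list(label, kind, pos + 1L, pos + nchar(s))
      pos <<- pos + nchar(s)
    }
    add("NTERM", "NTERM", draw(rlen(nterm_len_range), loop_pool))
    for (k in 1:7) {
      add(paste0("TM", k), "TM", draw(rlen(tm_len_range), tm_pool, tm_w))
      if (k < 7) {
        kind <- if (k %% 2 == 1) "ICL" else "ECL"
        add(paste0(kind, (k + 1) %/% 2), kind,
            draw(rlen(loop_len_range), loop_pool))
      }
    }
    add("CTERM", "CTERM", draw(rlen(cterm_len_range), loop_pool))
    record <- protein_record(id, paste(parts, collapse = ""),
                             name = "synthetic 7TM receptor")
    list(record = record,
         annotation = segment_annotation(id, seg,
                                         seq_length = nchar(record$sequence)))
  })
}

#' Write synthetic fixtures to files
#'
#' `kind = "sequence"` writes a FASTA and a segment TSV for a synthetic 7TM
#' protein; `"bundle"` writes a PDB of an idealized 7-helix bundle;
#' `"pair"` writes native + QTY FASTA, segments, events TSV, and two bundle
#' PDBs with identical coordinates and native/variant residue labels.
#' Byte-identical re-runs for the same seed and parameters.
#'
#' @param kind "sequence", "bundle" or "pair"
#' @param dir output directory
#' @param seed integer seed (required; there is no hidden RNG state)
#' @param ... passed to [synth_7tm_sequence()] / [build_bundle()]
#' @return named character vector of the files written
#' @export
synth_fixture <- function(kind = c("sequence", "bundle", "pair"), dir, seed,
                          ...) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character()
  if (kind == "sequence") {
    sx <- synth_7tm_sequence(seed, ...)
    out["fasta"] <- file.path(dir, "synth7tm.fasta")
    out["segments"] <- file.path(dir, "synth7tm_segments.tsv")
    write_fasta(sx$record, out["fasta"])
    write_segments(sx$annotation, out["segments"])
  } else if (kind == "bundle") {
    model <- build_bundle(...)
    out["pdb"] <- file.path(dir, "bundle.pdb")
    write_pdb(model, out["pdb"])
  } else {
    sx <- synth_7tm_sequence(seed, ...)
    res <- apply_substitution(sx$record, sx$annotation)
    out["native_fasta"] <- file.path(dir, "native.fasta")
    out["variant_fasta"] <- file.path(dir, "variant.fasta")
    out["segments"] <- file.path(dir, "segments.tsv")
    out["events"] <- file.path(dir, "events.tsv")
    write_fasta(res$native, out["native_fasta"])
    write_fasta(res$variant, out["variant_fasta"])
    write_segments(sx$annotation, out["segments"])
    ev <- res$events
    writeLines(c("position\tfrom\tto\tsegment_label",
                 sprintf("%d\t%s\t%s\t%s", ev$position, ev$from, ev$to,
                         ev$segment_label)),
               out["events"])
    nat_bundle <- build_bundle(sequence = res$native,
                               annotation = sx$annotation,
                               model_id = "native_bundle")
    var_bundle <- build_bundle(sequence = res$variant,
                               annotation = sx$annotation,
                               model_id = "variant_bundle")
    out["native_pdb"] <- file.path(dir, "native_bundle.pdb")
    out["variant_pdb"] <- file.path(dir, "variant_bundle.pdb")
    write_pdb(nat_bundle, out["native_pdb"])
    write_pdb(var_bundle, out["variant_pdb"])
  }
  out
}

#' Format a record and annotation as a synthetic UniProt-style flat entry
#'
#' Produces the minimal subset of a UniProt flat file that
#' [record_from_uniprot_text()] and [transmem_from_uniprot_text()] consume:
#' ID/AC lines, one `FT TRANSMEM` feature per TM segment, and the `SQ`
#' block. Intended for download-free testing; the output is labelled as
#' synthetic in a comment line.
#'
#' @param record a [protein_record()]
#' @param annotation a [segment_annotation()] of the record
#' @return flat-file text
#' @export
synth_uniprot_flat <- function(record, annotation) {
  seg <- annotation$segments
  tm <- seg[seg$kind == "TM", , drop = FALSE]
  n <- nchar(record$sequence)
  starts <- seq(1L, n, by = 60L)
  blocks <- substring(record$sequence, starts, pmin(starts + 59L, n))
  sq_lines <- vapply(blocks, function(b) {
    grp <- substring(b, seq(1, nchar(b), 10), pmin(seq(10, nchar(b) + 9, 10),
                                                   nchar(b)))
    paste0("     ", paste(grp, collapse = " "))
  }, "")
  paste0(paste(c(
    sprintf("ID   %s_SYNTH              Reviewed;         %d AA.",
            toupper(record$id), n),
    sprintf("AC   %s;", record$id),
    "CC   -!- SYNTHETIC ENTRY generated by qtykit::synth_uniprot_flat; not a real UniProt record.",
    sprintf("FT   TRANSMEM        %d..%d", tm$start, tm$end),
    sprintf("SQ   SEQUENCE   %d AA;  0 MW;  0000000000000000 CRC64;", n),
    sq_lines,
    "//"), collapse = "\n"), "\n")
}

#' Fetch a UniProt flat-file entry (network required)
#'
#' Convenience helper for populating a local fixture directory; nothing in
#' the test suite calls it. Downloads `https://rest.uniprot.org/uniprotkb/
#' <accession>.txt`.
#'
#' @param accession UniProt accession, e.g. "P61073"
#' @param dest destination file (default `<accession>.txt` in `dir`)
#' @param dir destination directory
#' @return the destination path, invisibly
#' @export
fetch_uniprot_txt <- function(accession, dest = NULL, dir = ".") {
  dest <- dest %||% file.path(dir, paste0(accession, ".txt"))
  url <- paste0("https://rest.uniprot.org/uniprotkb/", accession, ".txt")
  status <- utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  if (status != 0) stop("download failed for ", accession, call. = FALSE)
  invisible(dest)
}

#' The eight receptors of the native/QTY comparison battery
#'
#' @return data.frame with columns `receptor` and `accession`
#' @export
battery_receptors <- function() {
  data.frame(
    receptor = c("CCR5", "CCR9", "CXCR2", "CXCR4", "CCR10", "CXCR5",
                 "CXCR7", "OR1D2"),
    accession = c("P51681", "P51686", "P25025", "P61073", "P46092",
                  "P32302", "P25106", "P34982"),
    stringsAsFactors = FALSE
  )
}

#' Run the receptor comparison battery from UniProt flat files
#'
#' For each receptor whose `<accession>.txt` flat file exists in `dir`,
#' applies the QTY map over the TRANSMEM annotation and reports identity,
#' variation rates and pI/MW deltas. Missing entries are reported, not
#' fetched: populate `dir` with [fetch_uniprot_txt()] beforehand.
#'
#' @param dir directory of UniProt flat files
#' @param scope substitution scope (default TM-only)
#' @param overrides optional named list of extra 1-based positions per
#'   receptor (per-design intracellular/C-terminal modifications)
#' @return list: `table` (one data.frame row per computed receptor) and
#'   `missing` (accessions without a flat file)
#' @export
receptor_battery <- function(dir, scope = "TM", overrides = list()) {
  rec <- battery_receptors()
  rows <- list()
  missing <- character()
  for (i in seq_len(nrow(rec))) {
    path <- file.path(dir, paste0(rec$accession[i], ".txt"))
    if (!file.exists(path)) {
      missing <- c(missing, rec$accession[i])
      next
    }
    native <- record_from_uniprot_text(path)
    ann <- transmem_from_uniprot_text(path, native)
    extra <- overrides[[rec$receptor[i]]] %||% integer()
    res <- apply_substitution(native, ann, scope = scope,
                              extra_positions = extra,
                              variant_id = paste0(rec$receptor[i], "_QTY"))
    st <- variation_stats(res, ann)
    pc <- pair_physchem(res$native, res$variant)
    rows[[rec$receptor[i]]] <- data.frame(
      receptor = rec$receptor[i], accession = rec$accession[i],
      length = nchar(native$sequence), n_events = st$n_events,
      identity_pct = st$identity_pct,
      total_variation_pct = st$total_variation_pct,
      membrane_variation_pct = st$membrane_variation_pct,
      delta_pI = pc$delta_pI, delta_mw = pc$delta_mw,
      delta_mw_pct = pc$delta_mw_pct,
      stringsAsFactors = FALSE
    )
  }
  table <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
           else NULL
  list(table = table, missing = missing)
}
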