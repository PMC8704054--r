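# The substitution engine: configurable residue-substitution codes applied
# within annotated segments, plus identity/variation statistics and
# plain-text alignment rendering of native/variant pairs.

#' Construct a substitution map
#'
#' A named set of one-letter source -> target residue replacement rules.
#' Maps are plain data so that alternative codes (e.g. replacing Q/T/Y by
#' alanine, arginine or glycine to probe helix propensity) are expressible
#' without touching the engine.
#'
#' @param name map name
#' @param rules named character vector, `c(L = "Q", ...)`; no residue may map
#'   to itself
#' @return object of class `substitution_map`
#' @export
substitution_map <- function(name, rules) {
  src <- names(rules)
  tgt <- unname(rules)
  if (is.null(src) || any(!nzchar(src))) {
    stop("rules must be a named character vector", call. = FALSE)
  }
  if (!all(src %in% AA_CODES) || !all(tgt %in% AA_CODES)) {
    stop("substitution rules must use valid one-letter residue codes",
         call. = FALSE)
  }
  if (any(src == tgt)) {
    stop("a residue may not map to itself: ", src[src == tgt][1],
         call. = FALSE)
  }
  if (anyDuplicated(src)) {
    stop("duplicate source residue in map", call. = FALSE)
  }
  structure(list(name = name, rules = stats::setNames(tgt, src)),
            class = "substitution_map")
}

#' The canonical QTY map
#'
#' The QTY code replaces the four hydrophobic residues of transmembrane
#' helices by polar, uncharged residues whose side-chain electron densities
#' resemble the originals: leucine by glutamine, isoleucine and valine by
#' threonine, and phenylalanine by tyrosine.
#'
#' @return a [substitution_map()] named "QTY"
#' @export
qty_map <- function() {
  substitution_map("QTY", c(L = "Q", I = "T", V = "T", F = "Y"))
}

#' Read / write substitution maps as TSV
#'
#' Dialect: a `# name: <name>` comment line followed by `from<TAB>to` rows.
#'
#' @param x file path or literal text
#' @return a [substitution_map()]
#' @export
read_substitution_map <- function(x) {
  lines <- input_lines(x)
  nm_line <- grep("^#\\s*name:", lines, value = TRUE)
  nm <- if (length(nm_line)) trimws(sub("^#\\s*name:", "", nm_line[1])) else "custom"
  rows <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  if (!length(parts) || any(lengths(parts) != 2L)) {
    stop("substitution map rows must be 'from<TAB>to'", call. = FALSE)
  }
  substitution_map(nm, stats::setNames(vapply(parts, `[[`, "", 2L),
                                       vapply(parts, `[[`, "", 1L)))
}

#' @rdname read_substitution_map
#' @param map a [substitution_map()]
#' @param path optional output file
#' @export
write_substitution_map <- function(map, path = NULL) {
  txt <- paste0("# name: ", map$name, "\n",
                paste(sprintf("%s\t%s", names(map$rules), map$rules),
                      collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @export
print.substitution_map <- function(x, ...) {
  cat(sprintf("<substitution_map> %s: %s\n", x$name,
              paste(sprintf("%s->%s", names(x$rules), x$rules),
                    collapse = ", ")))
  invisible(x)
}

#' Apply a substitution map within annotated segments
#'
#' Every residue lying inside a segment whose kind is in `scope` (plus any
#' `extra_positions`) and whose code is a map source is replaced by its
#' target; all other positions are untouched, so native and variant always
#' have equal length. The default scope is the transmembrane segments only;
#' receptors whose designs additionally modify intracellular-loop or
#' C-terminal residues can name those positions in `extra_positions`.
#'
#' @param record native [protein_record()]
#' @param annotation [segment_annotation()] for the same record
#' @param map a [substitution_map()]; default [qty_map()]
#' @param scope segment kinds to substitute within (default `"TM"`)
#' @param extra_positions additional 1-based positions to include
#' @param variant_id id for the variant record (default `<id>_QTY`-style)
#' @return object of class `qty_result`: `native`, `variant`, and an
#'   `events` data.frame (position, from, to, segment_label)
#' @examples
#' rec <- protein_record("demo", "LIVFGGGG")
#' ann <- segment_annotation("demo", data.frame(
#'   label = "TM1", kind = "TM", start = 1, end = 4))
#' apply_substitution(rec, ann)
#' @export
apply_substitution <- function(record, annotation, map = qty_map(),
                               scope = "TM", extra_positions = integer(),
                               variant_id = NULL) {
  stopifnot(inherits(record, "protein_record"),
            inherits(annotation, "segment_annotation"),
            inherits(map, "substitution_map"))
  if (annotation$record_id != record$id) {
    stop(sprintf("annotation is for '%s', record is '%s'",
                 annotation$record_id, record$id), call. = FALSE)
  }
  n <- nchar(record$sequence)
  if (nrow(annotation$segments) && max(annotation$segments$end) > n) {
    stop("annotation extends past the end of the record", call. = FALSE)
  }
  extra_positions <- as.integer(extra_positions)
  if (length(extra_positions) &&
      (min(extra_positions) < 1L || max(extra_positions) > n)) {
    stop("extra_positions out of range", call. = FALSE)
  }
  in_scope <- sort(unique(c(segment_positions(annotation, kinds = scope),
                            extra_positions)))
  chars <- seq_chars(record$sequence)
  hit <- in_scope[chars[in_scope] %in% names(map$rules)]
  variant_chars <- chars
  variant_chars[hit] <- unname(map$rules[chars[hit]])

  seg <- annotation$segments
  label_at <- function(p) {
    k <- which(seg$start <= p & seg$end >= p)
    if (length(k)) seg$label[k[1]] else "extra"
  }
  events <- data.frame(
    position = hit,
    from = chars[hit],
    to = variant_chars[hit],
    segment_label = if (length(hit)) vapply(hit, label_at, "") else character(),
    stringsAsFactors = FALSE
  )
  vid <- variant_id %||% paste0(record$id, "_", map$name)
  variant <- protein_record(vid, paste(variant_chars, collapse = ""),
                            name = if (nzchar(record$name))
                              paste(record$name, map$name, "variant") else "")
  structure(list(native = record, variant = variant, events = events,
                 map_name = map$name, scope = scope),
            class = "qty_result")
}

#' @export
print.qty_result <- function(x, ...) {
  cat(sprintf("<qty_result> %s -> %s: %d substitution events (map %s, scope %s)\n",
              x$native$id, x$variant$id, nrow(x$events), x$map_name,
              paste(x$scope, collapse = "+")))
  invisible(x)
}

#' Positional sequence identity
#'
#' Percentage of positions at which two equal-length sequences agree,
#' reported to two decimal places (half-up). Substitution-only pairs share
#' their coordinate system, so no alignment is involved; unequal lengths are
#' an error by design.
#'
#' @param a,b [protein_record()]s of equal length
#' @return identity percentage (0..100)
#' @export
positional_identity <- function(a, b) {
  stopifnot(inherits(a, "protein_record"), inherits(b, "protein_record"))
  if (nchar(a$sequence) != nchar(b$sequence)) {
    stop(sprintf("sequences differ in length (%d vs %d); positional identity is undefined",
                 nchar(a$sequence), nchar(b$sequence)), call. = FALSE)
  }
  ca <- seq_chars(a$sequence)
  cb <- seq_chars(b$sequence)
  round_half_up(100 * mean(ca == cb), 2)
}

#' Variation statistics of a native/variant pair
#'
#' Total variation is the percentage of all positions substituted; membrane
#' variation restricts both numerator and denominator to transmembrane
#' segments. Identity and total variation are complementary
#' (identity = 100 - total).
#'
#' @param result a [qty_result()]
#' @param annotation the [segment_annotation()] used for the substitution
#' @return object of class `variation_stats` with fields `identity_pct`,
#'   `total_variation_pct`, `membrane_variation_pct`, `n_events`,
#'   `n_tm_residues`
#' @export
variation_stats <- function(result, annotation) {
  stopifnot(inherits(result, "qty_result"),
            inherits(annotation, "segment_annotation"))
  if (annotation$record_id != result$native$id) {
    stop("annotation and result refer to different records", call. = FALSE)
  }
  n <- nchar(result$native$sequence)
  tm_pos <- segment_positions(annotation, "TM")
  ev_pos <- result$events$position
  n_tm_events <- sum(ev_pos %in% tm_pos)
  if (!length(tm_pos) && n_tm_events > 0) {
    stop("events inside TM segments but annotation has no TM segments",
         call. = FALSE)
  }
  total <- round_half_up(100 * length(ev_pos) / n, 2)
  membrane <- if (length(tm_pos)) {
    round_half_up(100 * n_tm_events / length(tm_pos), 2)
  } else 0
  structure(list(
    identity_pct = round_half_up(100 - 100 * length(ev_pos) / n, 2),
    total_variation_pct = total,
    membrane_variation_pct = membrane,
    n_events = length(ev_pos),
    n_tm_residues = length(tm_pos)
  ), class = "variation_stats")
}

#' @export
print.variation_stats <- function(x, ...) {
  cat(sprintf(
    "<variation_stats> identity %.2f%% | total variation %.2f%% | membrane variation %.2f%% (%d events, %d TM residues)\n",
    x$identity_pct, x$total_variation_pct, x$membrane_variation_pct,
    x$n_events, x$n_tm_residues))
  invisible(x)
}

#' Render a native/variant alignment as text
#'
#' Blocks of `block_width` columns with, per block: an optional segment ruler
#' (TM columns marked `H`, loops `-`), sequence a, a match line (`|` equal,
#' `*` different), sequence b, and position numbers. A legend lists the
#' substituted positions.
#'
#' @param a,b equal-length [protein_record()]s
#' @param annotation optional [segment_annotation()] for the ruler line
#' @param block_width columns per block (default 60)
#' @return a single string of rendered text
#' @export
render_alignment <- function(a, b, annotation = NULL, block_width = 60) {
  stopifnot(inherits(a, "protein_record"), inherits(b, "protein_record"))
  n <- nchar(a$sequence)
  if (n != nchar(b$sequence)) {
    stop("cannot render sequences of unequal length", call. = FALSE)
  }
  ca <- seq_chars(a$sequence)
  cb <- seq_chars(b$sequence)
  match_line <- ifelse(ca == cb, "|", "*")
  ruler <- rep(" ", n)
  if (!is.null(annotation)) {
    ruler[segment_positions(annotation, c("ICL", "ECL", "NTERM", "CTERM"))] <- "-"
    ruler[segment_positions(annotation, "TM")] <- "H"
  }
  out <- c(sprintf("# %s vs %s (%d aa)", a$id, b$id, n))
  for (s in seq(1L, n, by = block_width)) {
    e <- min(s + block_width - 1L, n)
    idx <- s:e
    if (!is.null(annotation)) {
      out <- c(out, paste0("        ", paste(ruler[idx], collapse = "")))
    }
    out <- c(out,
             sprintf("%7d %s", s, paste(ca[idx], collapse = "")),
             paste0("        ", paste(match_line[idx], collapse = "")),
             sprintf("%7d %s", s, paste(cb[idx], collapse = "")),
             "")
  }
  subs <- which(ca != cb)
  out <- c(out, sprintf("# %d substituted positions%s", length(subs),
                        if (length(subs)) paste0(": ",
                          paste(sprintf("%s%d%s", ca[subs], subs, cb[subs]),
                                collapse = " ")) else ""))
  paste0(paste(out, collapse = "\n"), "\n")
}
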