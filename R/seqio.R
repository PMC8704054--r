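# Sequence and segment-annotation I/O, plus hydropathy-based transmembrane
# inference used as a fallback when no curated annotation is available.

#' Construct a protein record
#'
#' A `protein_record` is an identified amino-acid sequence: the unit of all
#' sequence-level operations in the package. Sequences are uppercased on
#' construction and must consist exclusively of the 20 standard one-letter
#' codes; ambiguity codes (B, Z, X) and non-standard letters (U, O) are
#' rejected because downstream substitution, mass and charge computations
#' need exact residue identities.
#'
#' @param id non-empty identifier (accession or label)
#' @param sequence amino-acid sequence string
#' @param name optional free-text description
#' @return object of class `protein_record` with fields `id`, `name`,
#'   `sequence`
#' @examples
#' protein_record("x", "MKTAYIAK")
#' @export
protein_record <- function(id, sequence, name = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("record id must be a non-empty string", call. = FALSE)
  }
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string (record '", id, "')",
         call. = FALSE)
  }
  sequence <- toupper(sequence)
  chars <- seq_chars(sequence)
  bad <- which(!(chars %in% AA_CODES))
  if (length(bad)) {
    stop(sprintf("record '%s': illegal residue character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  structure(list(id = id, name = name, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$name)) paste0(" ", x$name) else ""))
  s <- x$sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' @export
length.protein_record <- function(x) nchar(x$sequence)

# Resolve a text input that may be a file path or literal text.
input_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Parse FASTA text into protein records
#'
#' @param x a file path, a single string of FASTA text, or a character vector
#'   of lines
#' @return list of [protein_record()] in input order; ids are the first
#'   whitespace-delimited token of each header, the remainder becomes `name`
#' @examples
#' parse_fasta(">x demo\nMKT\n")
#' @export
parse_fasta <- function(x) {
  lines <- input_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in FASTA input", call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("FASTA input must start with a '>' header", call. = FALSE)
  idx <- cumsum(is_hdr)
  records <- lapply(split(seq_along(lines), idx), function(ii) {
    hdr <- sub("^>", "", lines[ii[1]])
    tok <- strsplit(trimws(hdr), "\\s+")[[1]]
    if (!length(tok) || !nzchar(tok[1])) {
      stop("FASTA header without an identifier", call. = FALSE)
    }
    body <- paste(gsub("[ \t]", "", lines[ii[-1]]), collapse = "")
    if (!nzchar(body)) {
      stop("record '", tok[1], "' has an empty sequence", call. = FALSE)
    }
    gap <- regexpr("[-.*]", body)
    if (gap > 0) {
      stop(sprintf("record '%s': gap/stop character '%s' at position %d",
                   tok[1], substr(body, gap, gap), gap), call. = FALSE)
    }
    protein_record(tok[1], body,
                   name = if (length(tok) > 1) paste(tok[-1], collapse = " ") else "")
  })
  names(records) <- NULL
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  records
}

#' Write protein records as FASTA
#'
#' Round-trips bit-identically through [parse_fasta()] for sequence content.
#'
#' @param records a `protein_record` or list of them
#' @param path optional output file; when `NULL` the text is returned
#' @param line_width wrap width for sequence lines (default 60)
#' @return FASTA text, invisibly when written to `path`
#' @export
write_fasta <- function(records, path = NULL, line_width = 60) {
  if (inherits(records, "protein_record")) records <- list(records)
  if (!length(records)) stop("no records to write", call. = FALSE)
  stopifnot(line_width >= 1)
  chunks <- vapply(records, function(r) {
    hdr <- paste0(">", r$id, if (nzchar(r$name)) paste0(" ", r$name) else "")
    n <- nchar(r$sequence)
    starts <- seq(1L, n, by = line_width)
    body <- substring(r$sequence, starts, pmin(starts + line_width - 1L, n))
    paste(c(hdr, body), collapse = "\n")
  }, "")
  txt <- paste0(paste(chunks, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

SEGMENT_KINDS <- c("TM", "ICL", "ECL", "NTERM", "CTERM")

#' Construct a segment annotation
#'
#' Labeled 1-based inclusive intervals over a protein record. Transmembrane
#' (`TM`) segments must be pairwise non-overlapping; a canonical 7TM
#' annotation carries segments TM1..TM7 in order.
#'
#' @param record_id id of the annotated record
#' @param segments data.frame with columns `label`, `kind`
#'   (TM/ICL/ECL/NTERM/CTERM), `start`, `end` (1-based inclusive)
#' @param seq_length optional sequence length for range validation
#' @return object of class `segment_annotation`
#' @export
segment_annotation <- function(record_id, segments, seq_length = NULL) {
  need <- c("label", "kind", "start", "end")
  if (!is.data.frame(segments) || !all(need %in% names(segments))) {
    stop("segments must be a data.frame with columns label, kind, start, end",
         call. = FALSE)
  }
  segments <- segments[need]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  bad_kind <- setdiff(unique(segments$kind), SEGMENT_KINDS)
  if (length(bad_kind)) {
    stop("unknown segment kind: ", bad_kind[1], call. = FALSE)
  }
  if (any(segments$start < 1L) || any(segments$end < segments$start)) {
    stop("segment intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(seq_length) && any(segments$end > seq_length)) {
    i <- which(segments$end > seq_length)[1]
    stop(sprintf("segment %s (%d..%d) exceeds sequence length %d",
                 segments$label[i], segments$start[i], segments$end[i],
                 seq_length), call. = FALSE)
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  tm <- segments[segments$kind == "TM", , drop = FALSE]
  if (nrow(tm) > 1) {
    ov <- which(tm$start[-1] <= tm$end[-nrow(tm)])
    if (length(ov)) {
      stop(sprintf("overlapping TM segments %s and %s",
                   tm$label[ov[1]], tm$label[ov[1] + 1]), call. = FALSE)
    }
  }
  structure(list(record_id = record_id, segments = segments),
            class = "segment_annotation")
}

#' @export
print.segment_annotation <- function(x, ...) {
  cat(sprintf("<segment_annotation> %s: %d segments (%d TM)\n", x$record_id,
              nrow(x$segments), sum(x$segments$kind == "TM")))
  print(x$segments)
  invisible(x)
}

# Residue positions covered by segments of the given kinds.
segment_positions <- function(annotation, kinds = "TM") {
  seg <- annotation$segments
  seg <- seg[seg$kind %in% kinds, , drop = FALSE]
  if (!nrow(seg)) return(integer())
  sort(unique(unlist(Map(seq.int, seg$start, seg$end))))
}

#' Load a tab-separated segment table
#'
#' Dialect: one segment per line, `label<TAB>kind<TAB>start<TAB>end`,
#' 1-based inclusive coordinates; `#` starts a comment line.
#'
#' @param x file path or literal text
#' @param record the [protein_record()] the table annotates
#' @return [segment_annotation()]
#' @export
load_segments <- function(x, record) {
  stopifnot(inherits(record, "protein_record"))
  lines <- input_lines(x)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rows <- which(keep)
  if (!length(rows)) stop("no segment rows in input", call. = FALSE)
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  n_ok <- lengths(parts) == 4L
  if (!all(n_ok)) {
    stop("line ", rows[which(!n_ok)[1]],
         ": expected 4 tab-separated fields (label, kind, start, end)",
         call. = FALSE)
  }
  df <- data.frame(
    label = vapply(parts, `[[`, "", 1L),
    kind = vapply(parts, `[[`, "", 2L),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L))),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    bad <- which(is.na(df$start) | is.na(df$end))[1]
    stop("line ", rows[bad], ": non-numeric interval bound", call. = FALSE)
  }
  out_of_range <- df$start < 1L | df$end > nchar(record$sequence) |
    df$end < df$start
  if (any(out_of_range)) {
    bad <- which(out_of_range)[1]
    stop(sprintf("line %d: interval %d..%d out of range for %d-residue record '%s'",
                 rows[bad], df$start[bad], df$end[bad],
                 nchar(record$sequence), record$id), call. = FALSE)
  }
  segment_annotation(record$id, df, seq_length = nchar(record$sequence))
}

#' Write a segment annotation as TSV
#'
#' @param annotation a [segment_annotation()]
#' @param path optional output file
#' @return TSV text, invisibly when written
#' @export
write_segments <- function(annotation, path = NULL) {
  seg <- annotation$segments
  txt <- paste0(paste(sprintf("%s\t%s\t%d\t%d", seg$label, seg$kind,
                              seg$start, seg$end), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Extract transmembrane segments from UniProt flat text
#'
#' Reads `FT TRANSMEM` features from a UniProt flat-file entry and returns
#' them as TM1..TMn segments. The entry's sequence length (`SQ` line) is
#' checked against the supplied record.
#'
#' @param x file path or literal flat-file text
#' @param record the matching [protein_record()]
#' @return [segment_annotation()] containing only TM segments
#' @export
transmem_from_uniprot_text <- function(x, record) {
  stopifnot(inherits(record, "protein_record"))
  lines <- input_lines(x)
  sq <- grep("^SQ\\s+SEQUENCE\\s+(\\d+)\\s+AA", lines, value = TRUE)
  if (length(sq)) {
    n <- as.integer(sub("^SQ\\s+SEQUENCE\\s+(\\d+)\\s+AA.*$", "\\1", sq[1]))
    if (n != nchar(record$sequence)) {
      stop(sprintf("sequence length mismatch: entry says %d aa, record '%s' has %d",
                   n, record$id, nchar(record$sequence)), call. = FALSE)
    }
  }
  tm_lines <- grep("^FT\\s+TRANSMEM\\s", lines, value = TRUE)
  if (!length(tm_lines)) {
    stop("no transmembrane annotation (FT TRANSMEM) in entry", call. = FALSE)
  }
  # Both legacy "FT TRANSMEM   30  55" and current "FT TRANSMEM 30..55"
  rng <- regmatches(tm_lines,
                    regexpr("(\\d+)(\\.\\.|\\s+)(\\d+)", tm_lines))
  if (length(rng) != length(tm_lines)) {
    stop("unparseable TRANSMEM feature line", call. = FALSE)
  }
  nums <- lapply(strsplit(rng, "[^0-9]+"), as.integer)
  df <- data.frame(
    label = paste0("TM", seq_along(nums)),
    kind = "TM",
    start = vapply(nums, `[[`, 0L, 1L),
    end = vapply(nums, `[[`, 0L, 2L),
    stringsAsFactors = FALSE
  )
  segment_annotation(record$id, df, seq_length = nchar(record$sequence))
}

#' Parse the sequence out of UniProt flat text
#'
#' Convenience companion to [transmem_from_uniprot_text()]: reads the `SQ`
#' block of a flat-file entry into a [protein_record()], using the first `AC`
#' accession (or `ID` name) as the id.
#'
#' @param x file path or literal flat-file text
#' @return [protein_record()]
#' @export
record_from_uniprot_text <- function(x) {
  lines <- input_lines(x)
  sq_at <- grep("^SQ\\s", lines)
  if (!length(sq_at)) stop("no SQ block in entry", call. = FALSE)
  body <- lines[(sq_at[1] + 1):length(lines)]
  end <- grep("^//", body)
  if (length(end)) body <- body[seq_len(end[1] - 1L)]
  seqtxt <- gsub("[^A-Za-z]", "", paste(body, collapse = ""))
  ac <- grep("^AC\\s", lines, value = TRUE)
  id <- if (length(ac)) {
    sub(";.*$", "", sub("^AC\\s+", "", ac[1]))
  } else {
    idl <- grep("^ID\\s", lines, value = TRUE)
    if (length(idl)) strsplit(sub("^ID\\s+", "", idl[1]), "\\s+")[[1]][1] else "unknown"
  }
  de <- grep("^DE\\s+RecName", lines, value = TRUE)
  nm <- if (length(de)) sub(";\\s*$", "", sub(".*Full=", "", de[1])) else ""
  nm <- sub("\\s*\\{.*\\}", "", nm)
  protein_record(id, seqtxt, name = nm)
}

#' Windowed Kyte-Doolittle hydropathy profile
#'
#' Mean hydropathy over a sliding window of odd width; positions whose window
#' would extend past either terminus carry no score, so the profile has
#' `length - window + 1` scored positions centred at
#' `(window-1)/2 + 1 .. length - (window-1)/2`.
#'
#' @param record a [protein_record()]
#' @param window odd positive window width (default 19, a TM-scan standard)
#' @param scale named hydropathy vector; defaults to Kyte-Doolittle
#' @return object of class `hydropathy_profile` with `record_id`, `window`,
#'   `positions` (window centres) and `scores`
#' @export
hydropathy_profile <- function(record, window = 19,
                               scale = kyte_doolittle_scale()) {
  stopifnot(inherits(record, "protein_record"))
  n <- nchar(record$sequence)
  if (window %% 2 != 1 || window < 1) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  if (window > n) {
    stop(sprintf("window (%d) exceeds sequence length (%d)", window, n),
         call. = FALSE)
  }
  h <- unname(scale[seq_chars(record$sequence)])
  if (anyNA(h)) stop("residue missing from hydropathy scale", call. = FALSE)
  cs <- cumsum(c(0, h))
  scores <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  half <- (window - 1L) %/% 2L
  structure(list(record_id = record$id, window = as.integer(window),
                 positions = seq.int(half + 1L, n - half), scores = scores),
            class = "hydropathy_profile")
}

#' The Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector over the 20 one-letter codes
#' @export
kyte_doolittle_scale <- function() {
  df <- read_table_tsv("kyte_doolittle.tsv")
  stats::setNames(df$hydropathy, df$code)
}

#' Infer transmembrane segments from hydropathy
#'
#' Fallback-quality annotation for sequences without curated TM boundaries:
#' maximal runs of windowed mean Kyte-Doolittle hydropathy above `threshold`,
#' kept when at least `min_len` residues long, become TM1..TMn. Curated
#' segment tables should always take precedence when available.
#'
#' @inheritParams hydropathy_profile
#' @param threshold hydropathy cutoff (default 1.6, the classic TM-scan value)
#' @param min_len minimum run length in residues (default 15)
#' @return [segment_annotation()] with zero or more TM segments
#' @export
infer_tm_segments <- function(record, window = 19, threshold = 1.6,
                              min_len = 15) {
  prof <- hydropathy_profile(record, window = window)
  above <- prof$scores > threshold
  segs <- list()
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    pos <- prof$positions[starts[k]:ends[k]]
    if (length(pos) >= min_len) segs[[length(segs) + 1L]] <- range(pos)
  }
  df <- if (length(segs)) {
    data.frame(label = paste0("TM", seq_along(segs)), kind = "TM",
               start = vapply(segs, `[[`, 0L, 1L),
               end = vapply(segs, `[[`, 0L, 2L), stringsAsFactors = FALSE)
  } else {
    data.frame(label = character(), kind = character(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  }
  segment_annotation(record$id, df, seq_length = nchar(record$sequence))
}
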