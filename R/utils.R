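# Internal helpers shared across modules.

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
ONE_TO_THREE <- stats::setNames(names(THREE_TO_ONE), unname(THREE_TO_ONE))

#' Round half away from zero
#'
#' Base R rounds half to even; reported percentages follow the conventional
#' half-up rule so that printed values match hand calculation.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Locate a shipped TSV data table, tolerating both installed and source trees.
qtykit_table_path <- function(name) {
  p <- system.file("extdata", "tables", name, package = "qtykit")
  if (!nzchar(p)) {
    stop("data table not found: ", name, call. = FALSE)
  }
  p
}

read_table_tsv <- function(name) {
  utils::read.delim(qtykit_table_path(name), comment.char = "#",
                    stringsAsFactors = FALSE)
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
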