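# Sequence-level physical chemistry: average molecular weight and
# isoelectric point in the Expasy Compute pI/MW convention, and the
# native-vs-variant deltas used in the pair characteristics tables.

#' Average residue mass table
#'
#' Average (not monoisotopic) residue masses in Da plus the mass of one water
#' molecule added per chain, following the Expasy Compute pI/MW convention so
#' that native/variant mass deltas are comparable with values computed there.
#'
#' @return object of class `mass_table` with `residue_masses` (named numeric)
#'   and `water_mass`
#' @export
average_mass_table <- function() {
  df <- read_table_tsv("aa_masses_average.tsv")
  structure(list(residue_masses = stats::setNames(df$mass, df$code),
                 water_mass = 18.0153),
            class = "mass_table")
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water, reported to 2 decimals.
#'
#' @param record a [protein_record()]
#' @param table a mass table from [average_mass_table()]
#' @return mass in Da
#' @examples
#' molecular_weight(protein_record("g", "G"))  # 75.07
#' @export
molecular_weight <- function(record, table = average_mass_table()) {
  stopifnot(inherits(record, "protein_record"))
  round_half_up(exact_mw(record, table), 2)
}

# unrounded chain mass; deltas are computed from this so that per-event
# mass conservation holds to well under 0.01 Da
exact_mw <- function(record, table) {
  m <- table$residue_masses[seq_chars(record$sequence)]
  if (anyNA(m)) {
    missing <- setdiff(unique(seq_chars(record$sequence)),
                       names(table$residue_masses))
    stop("residue absent from mass table: ", missing[1], call. = FALSE)
  }
  sum(m) + table$water_mass
}

#' pKa sets for charge and pI calculation
#'
#' `expasy_pkas()` returns the Bjellqvist set as deployed by the Expasy
#' Compute pI/MW tool, including residue-specific N-terminal alpha-amino
#' pKas; `lehninger_pkas()` returns the classic textbook set as an
#' alternative. Both ship as editable TSV files under
#' `inst/extdata/tables/`.
#'
#' @return object of class `pka_set`: `cterm`, `nterm` (named vector with a
#'   `default` entry plus optional per-residue entries) and `side` (named
#'   vector over D, E, H, C, Y, K, R)
#' @export
expasy_pkas <- function() pka_set_from_tsv("pkas_expasy.tsv", "expasy")

#' @rdname expasy_pkas
#' @export
lehninger_pkas <- function() pka_set_from_tsv("pkas_lehninger.tsv", "lehninger")

pka_set_from_tsv <- function(file, name) {
  df <- read_table_tsv(file)
  v <- stats::setNames(df$pka, df$group)
  if (any(v <= 0 | v >= 14)) stop("pKa values must lie in (0, 14)", call. = FALSE)
  nt <- v[startsWith(names(v), "nterm")]
  names(nt) <- sub("^nterm_", "", names(nt))
  side <- v[startsWith(names(v), "side_")]
  names(side) <- sub("^side_", "", names(side))
  need <- c("D", "E", "H", "C", "Y", "K", "R")
  if (!all(need %in% names(side)) || !"default" %in% names(nt) ||
      !"cterm" %in% names(v)) {
    stop("incomplete pKa table: ", file, call. = FALSE)
  }
  structure(list(name = name, cterm = unname(v["cterm"]), nterm = nt,
                 side = side),
            class = "pka_set")
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: the free N-terminus and
#' the side chains of K, R, H contribute `+1/(1 + 10^(pH - pKa))` each; the
#' free C-terminus and the side chains of D, E, C, Y contribute
#' `-1/(1 + 10^(pKa - pH))` each. Cysteines are treated as free (no
#' disulfide correction), matching Expasy.
#'
#' @param record a [protein_record()]
#' @param pH pH in \[0, 14\]
#' @param pkas a [expasy_pkas()]-style pKa set
#' @return signed net charge (elementary charges)
#' @export
net_charge <- function(record, pH, pkas = expasy_pkas()) {
  stopifnot(inherits(record, "protein_record"), pH >= 0, pH <= 14)
  chars <- seq_chars(record$sequence)
  cnt <- table(factor(chars, levels = AA_CODES))
  pos_term <- if (chars[1] %in% names(pkas$nterm)) {
    pkas$nterm[[chars[1]]]
  } else {
    pkas$nterm[["default"]]
  }
  positive <- 1 / (1 + 10^(pH - pos_term)) +
    cnt[["K"]] / (1 + 10^(pH - pkas$side[["K"]])) +
    cnt[["R"]] / (1 + 10^(pH - pkas$side[["R"]])) +
    cnt[["H"]] / (1 + 10^(pH - pkas$side[["H"]]))
  negative <- 1 / (1 + 10^(pkas$cterm - pH)) +
    cnt[["D"]] / (1 + 10^(pkas$side[["D"]] - pH)) +
    cnt[["E"]] / (1 + 10^(pkas$side[["E"]] - pH)) +
    cnt[["C"]] / (1 + 10^(pkas$side[["C"]] - pH)) +
    cnt[["Y"]] / (1 + 10^(pkas$side[["Y"]] - pH))
  positive - negative
}

#' Isoelectric point by bisection
#'
#' Net charge is strictly decreasing in pH, so its zero is unique; it is
#' located by bisection on \[0, 14\] to tolerance `tol` and reported to 2
#' decimals.
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units (default 0.001)
#' @return the isoelectric point (pH units)
#' @export
isoelectric_point <- function(record, pkas = expasy_pkas(), tol = 0.001) {
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(record, mid, pkas) > 0) lo <- mid else hi <- mid
  }
  round_half_up((lo + hi) / 2, 2)
}

#' Physicochemical comparison of a native/variant pair
#'
#' Computes pI and molecular weight for both sequences and their unsigned
#' deltas; the mass delta is also expressed as a percentage of the native
#' mass, the form used in the pair characteristics tables.
#'
#' @param native,variant equal-length [protein_record()]s
#' @param table mass table
#' @param pkas pKa set
#' @return object of class `pair_physchem` with fields `pI_native`,
#'   `pI_variant`, `delta_pI`, `mw_native`, `mw_variant`, `delta_mw`,
#'   `delta_mw_pct`
#' @export
pair_physchem <- function(native, variant, table = average_mass_table(),
                          pkas = expasy_pkas()) {
  if (nchar(native$sequence) != nchar(variant$sequence)) {
    stop("native and variant must have equal length", call. = FALSE)
  }
  pin <- isoelectric_point(native, pkas)
  piv <- isoelectric_point(variant, pkas)
  mwn <- exact_mw(native, table)
  mwv <- exact_mw(variant, table)
  structure(list(
    pI_native = pin, pI_variant = piv,
    delta_pI = round_half_up(abs(piv - pin), 2),
    mw_native = round_half_up(mwn, 2), mw_variant = round_half_up(mwv, 2),
    delta_mw = round_half_up(abs(mwv - mwn), 2),
    delta_mw_pct = round_half_up(100 * abs(mwv - mwn) / mwn, 2)
  ), class = "pair_physchem")
}

#' @export
print.pair_physchem <- function(x, ...) {
  cat(sprintf("<pair_physchem> pI %.2f -> %.2f (delta %.2f) | MW %.2f -> %.2f Da (delta %.2f Da, %.2f%%)\n",
              x$pI_native, x$pI_variant, x$delta_pI, x$mw_native,
              x$mw_variant, x$delta_mw, x$delta_mw_pct))
  invisible(x)
}
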