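# Structure handling: fixed-column PDB I/O, residue matching between
# substitution-only variant pairs, Kabsch superposition with RMSD, and
# idealized alpha-helix / helix-bundle generators used as download-free
# structural fixtures.

#' Construct a structure model
#'
#' A flat atom table: one row per atom with chain, residue number, residue
#' name (3-letter), atom name, element and Cartesian coordinates in
#' Angstrom. At most one atom may exist per (chain, residue, atom name).
#'
#' @param model_id label for the model
#' @param atoms data.frame with columns `chain`, `residue_seq`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z` (and optionally
#'   `occupancy`, `bfactor`)
#' @return object of class `structure_model`
#' @export
structure_model <- function(model_id, atoms) {
  need <- c("chain", "residue_seq", "residue_name", "atom_name", "element",
            "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    stop("atoms must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!nrow(atoms)) stop("structure model has no atoms", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in model", call. = FALSE)
  }
  key <- paste(atoms$chain, atoms$residue_seq, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate atom: ", key[duplicated(key)][1], call. = FALSE)
  }
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  if (!"bfactor" %in% names(atoms)) atoms$bfactor <- 0
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, chains %s\n",
              x$model_id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$residue_seq))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# Guess the element from a PDB atom name when columns 77-78 are blank.
element_from_atom_name <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE"),
         two, substr(nm, 1, 1))
}

#' Parse a PDB file
#'
#' Fixed-column parser for ATOM records. Alternate locations are resolved to
#' the highest-occupancy conformer (ties go to altLoc 'A'); HETATM records
#' are ignored unless `keep_hetatm = TRUE`; `model_index` selects among
#' MODEL/ENDMDL blocks (default: the first).
#'
#' @param x file path or literal PDB text
#' @param model_index which MODEL block to read (default 1)
#' @param keep_hetatm include HETATM records (default FALSE)
#' @param model_id optional id; defaults to the file name or "pdb"
#' @return a [structure_model()]
#' @export
parse_pdb <- function(x, model_index = 1, keep_hetatm = FALSE,
                      model_id = NULL) {
  is_path <- length(x) == 1L && !grepl("\n", x) && file.exists(x)
  if (is.null(model_id)) {
    model_id <- if (is_path) sub("\\.(pdb|ent)$", "", basename(x)) else "pdb"
  }
  lines <- input_lines(x)
  rectype <- substr(lines, 1, 6)
  # restrict to the requested MODEL block, if any
  model_starts <- which(rectype == "MODEL ")
  if (length(model_starts)) {
    if (model_index > length(model_starts)) {
      stop(sprintf("model_index %d but file has %d MODEL blocks",
                   model_index, length(model_starts)), call. = FALSE)
    }
    ends <- which(rectype == "ENDMDL")
    stop_at <- ends[ends > model_starts[model_index]][1]
    if (is.na(stop_at)) stop_at <- length(lines)
    keep <- seq.int(model_starts[model_index] + 1L, stop_at - 1L)
    lines <- lines[keep]
    rectype <- rectype[keep]
  }
  wanted <- rectype == "ATOM  " | (keep_hetatm & rectype == "HETATM")
  atom_lines <- lines[wanted]
  line_no <- which(wanted)
  if (!length(atom_lines)) stop("no ATOM records", call. = FALSE)

  f <- function(from, to) trimws(substr(atom_lines, from, to))
  xs <- suppressWarnings(as.numeric(f(31, 38)))
  ys <- suppressWarnings(as.numeric(f(39, 46)))
  zs <- suppressWarnings(as.numeric(f(47, 54)))
  badc <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(badc)) {
    stop("malformed coordinate field at line ", line_no[badc[1]],
         call. = FALSE)
  }
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(f(61, 66)))
  bf[is.na(bf)] <- 0
  elem <- f(77, 78)
  an <- f(13, 16)
  elem <- ifelse(nzchar(elem), toupper(elem), element_from_atom_name(an))
  atoms <- data.frame(
    chain = substr(atom_lines, 22, 22),
    residue_seq = suppressWarnings(as.integer(f(23, 26))),
    residue_name = f(18, 20),
    atom_name = an,
    altloc = substr(atom_lines, 17, 17),
    element = elem,
    x = xs, y = ys, z = zs, occupancy = occ, bfactor = bf,
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$residue_seq)) {
    stop("malformed residue number at line ",
         line_no[which(is.na(atoms$residue_seq))[1]], call. = FALSE)
  }
  # altloc resolution: keep highest occupancy; ties prefer 'A'/blank order
  key <- paste(atoms$chain, atoms$residue_seq, atoms$atom_name)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$residue_seq,
                                   atoms$atom_name)), , drop = FALSE]
  # restore file order
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  atoms$altloc <- NULL
  structure_model(model_id, atoms)
}

#' Write a structure model as PDB text
#'
#' @param model a [structure_model()]
#' @param path optional output file
#' @return PDB text, invisibly when written
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
    a$residue_name, a$chain, a$residue_seq, a$x, a$y, a$z, a$occupancy,
    a$bfactor, a$element)
  txt <- paste0(paste(c(lines, "TER", "END"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

# First chain containing protein residues (any chain here; models are
# protein-only after HETATM filtering).
default_chain <- function(model) model$atoms$chain[1]

#' Match residues between two models by residue number
#'
#' Pairs residues present in both chains with equal `residue_seq` and
#' possessing the named atom (default CA). Valid for substitution-only
#' variant pairs, which share their numbering; a sequence-identity guard in
#' [superpose_models()] protects against accidental mispairing.
#'
#' @param a,b [structure_model()]s
#' @param chain_a,chain_b chain identifiers (default: first chain of each)
#' @param atom atom name to require (default `"CA"`)
#' @return data.frame with columns `residue_seq`, `residue_a`, `residue_b`
#'   (3-letter names), ascending in `residue_seq`
#' @export
match_residues <- function(a, b, chain_a = NULL, chain_b = NULL,
                           atom = "CA") {
  chain_a <- chain_a %||% default_chain(a)
  chain_b <- chain_b %||% default_chain(b)
  sel <- function(m, ch) {
    at <- m$atoms
    at <- at[at$chain == ch & at$atom_name == atom, , drop = FALSE]
    at[order(at$residue_seq), , drop = FALSE]
  }
  aa <- sel(a, chain_a)
  bb <- sel(b, chain_b)
  common <- intersect(aa$residue_seq, bb$residue_seq)
  if (!length(common)) {
    stop(sprintf("no common residues with atom %s between chains %s and %s",
                 atom, chain_a, chain_b), call. = FALSE)
  }
  common <- sort(common)
  data.frame(
    residue_seq = common,
    residue_a = aa$residue_name[match(common, aa$residue_seq)],
    residue_b = bb$residue_name[match(common, bb$residue_seq)],
    stringsAsFactors = FALSE
  )
}

#' Kabsch superposition of two paired point sets
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`: centroids are subtracted, the rotation comes from the
#' SVD of the covariance matrix with the reflection corrected by the sign of
#' its determinant, and the RMSD is computed over the transformed mobile
#' points. The returned rotation always has determinant +1 — mirror-image
#' inputs are never "solved" by a reflection.
#'
#' @param reference,mobile n x 3 numeric matrices, n >= 3, not collinear
#' @return object of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd`, `n_matched`. The transform maps a
#'   mobile point p to `rotation %*% p + translation`.
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (ncol(reference) != 3 || ncol(mobile) != 3) {
    stop("point sets must be n x 3 matrices", call. = FALSE)
  }
  n <- nrow(reference)
  if (nrow(mobile) != n) stop("point counts differ", call. = FALSE)
  if (n < 3) stop("need at least 3 paired points", call. = FALSE)
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  # collinearity check: rank of the centred reference < 2
  sv_ref <- svd(Q)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    stop("degenerate (collinear) point configuration", call. = FALSE)
  }
  H <- crossprod(P, Q)  # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd, n_matched = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d matched points, RMSD %.3f A\n",
              x$n_matched, x$rmsd))
  invisible(x)
}

#' Apply a superposition to a model
#'
#' @param model a [structure_model()]
#' @param sup a [kabsch_superpose()] result
#' @return transformed [structure_model()]
#' @export
transform_model <- function(model, sup) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  moved <- xyz %*% t(sup$rotation) +
    matrix(sup$translation, nrow(xyz), 3, byrow = TRUE)
  out <- model
  out$atoms$x <- moved[, 1]
  out$atoms$y <- moved[, 2]
  out$atoms$z <- moved[, 3]
  out
}

#' Superpose two structure models on matched C-alpha atoms
#'
#' Convenience wrapper: matches residues by number ([match_residues()]),
#' optionally verifies that the matched sequences are at least
#' `min_identity` identical (guards against mispaired chains), runs
#' [kabsch_superpose()] on the named atom coordinates, and returns the
#' superposition together with the matched pairs and the transformed mobile
#' model.
#'
#' @inheritParams match_residues
#' @param reference,mobile [structure_model()]s
#' @param min_identity minimum fraction of matched residues with identical
#'   or QTY-related names (default 0.3)
#' @return list: `superposition`, `pairs`, `mobile_transformed`
#' @export
superpose_models <- function(reference, mobile, chain_a = NULL,
                             chain_b = NULL, atom = "CA",
                             min_identity = 0.3) {
  pairs <- match_residues(reference, mobile, chain_a, chain_b, atom)
  ident <- mean(pairs$residue_a == pairs$residue_b)
  if (ident < min_identity) {
    stop(sprintf("matched residues only %.0f%% identical; chains look mispaired",
                 100 * ident), call. = FALSE)
  }
  coords <- function(m, ch, rs) {
    at <- m$atoms
    ch <- ch %||% default_chain(m)
    at <- at[at$chain == ch & at$atom_name == atom, , drop = FALSE]
    at <- at[match(rs, at$residue_seq), , drop = FALSE]
    as.matrix(at[, c("x", "y", "z")])
  }
  sup <- kabsch_superpose(coords(reference, chain_a, pairs$residue_seq),
                          coords(mobile, chain_b, pairs$residue_seq))
  list(superposition = sup, pairs = pairs,
       mobile_transformed = transform_model(mobile, sup))
}

#' Restrict a model to annotated transmembrane segments
#'
#' Keeps atoms whose residue number falls inside a TM segment of the
#' annotation; loops and termini are removed, mirroring the practice of
#' superposing 7TM bundles only.
#'
#' @param model a [structure_model()]
#' @param annotation a [segment_annotation()] in the model's residue
#'   numbering
#' @return trimmed [structure_model()]
#' @export
trim_to_segments <- function(model, annotation) {
  pos <- segment_positions(annotation, "TM")
  keep <- model$atoms$residue_seq %in% pos
  if (!any(keep)) {
    stop("annotation covers no residue present in the model", call. = FALSE)
  }
  structure_model(paste0(model$model_id, "_tm"),
                  model$atoms[keep, , drop = FALSE])
}

#' Ideal alpha-helix parameters
#'
#' Canonical alpha-helix geometry: 1.5 A rise and 100 degrees of twist per
#' residue (3.6 residues and 5.4 A per full turn), C-alpha atoms on a
#' cylinder of radius 2.3 A.
#'
#' @param n_residues number of residues (>= 4)
#' @param rise_per_residue axial rise per residue in A
#' @param twist_per_residue twist per residue in degrees
#' @param radius C-alpha cylinder radius in A
#' @return object of class `helix_spec`
#' @export
helix_spec <- function(n_residues = 26, rise_per_residue = 1.5,
                       twist_per_residue = 100, radius = 2.3) {
  if (n_residues < 4) stop("a helix needs at least 4 residues", call. = FALSE)
  structure(list(n_residues = as.integer(n_residues),
                 rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue, radius = radius),
            class = "helix_spec")
}

#' Build an ideal C-alpha alpha-helix
#'
#' Residue i sits at angle `i * twist` on a cylinder of the given radius at
#' height `i * rise`; residue names are poly-alanine unless a sequence is
#' supplied.
#'
#' @param spec a [helix_spec()]
#' @param chain chain identifier
#' @param start_residue first residue number
#' @param sequence optional one-letter sequence of length `n_residues`
#' @param model_id model label
#' @return a C-alpha-only [structure_model()]
#' @export
build_ideal_helix <- function(spec = helix_spec(), chain = "A",
                              start_residue = 1, sequence = NULL,
                              model_id = "ideal_helix") {
  i <- seq_len(spec$n_residues) - 1L
  theta <- i * spec$twist_per_residue * pi / 180
  res_names <- if (is.null(sequence)) {
    rep("ALA", spec$n_residues)
  } else {
    ch <- seq_chars(toupper(sequence))
    if (length(ch) != spec$n_residues) {
      stop("sequence length does not match n_residues", call. = FALSE)
    }
    unname(ONE_TO_THREE[ch])
  }
  atoms <- data.frame(
    chain = chain,
    residue_seq = start_residue + i,
    residue_name = res_names,
    atom_name = "CA",
    element = "C",
    x = spec$radius * cos(theta),
    y = spec$radius * sin(theta),
    z = i * spec$rise_per_residue,
    stringsAsFactors = FALSE
  )
  structure_model(model_id, atoms)
}

#' Build an idealized transmembrane helix bundle
#'
#' Places ideal helices with vertical axes at equal angular spacing on a
#' circle of `bundle_radius`, alternating up/down orientation as in an
#' antiparallel transmembrane bundle. When a sequence and its segment
#' annotation are supplied, each TM segment provides one helix whose residue
#' numbers and names follow the annotation; otherwise all helices follow
#' `spec`.
#'
#' @param n_helices number of helices (default 7)
#' @param spec a [helix_spec()] used for every helix (geometry always comes
#'   from here)
#' @param bundle_radius distance of each helix axis from the bundle centre
#'   in A (default 9.5, a 7TM-like packing)
#' @param sequence optional [protein_record()]
#' @param annotation optional [segment_annotation()] of `sequence`; its TM
#'   segments override `n_helices` and per-helix lengths
#' @param chain chain identifier
#' @param model_id model label
#' @return a C-alpha-only [structure_model()]
#' @export
build_bundle <- function(n_helices = 7, spec = helix_spec(),
                         bundle_radius = 9.5, sequence = NULL,
                         annotation = NULL, chain = "A",
                         model_id = "bundle") {
  if (!is.null(annotation)) {
    seg <- annotation$segments
    seg <- seg[seg$kind == "TM", , drop = FALSE]
    if (!nrow(seg)) stop("annotation has no TM segments", call. = FALSE)
    n_helices <- nrow(seg)
  } else {
    seg <- NULL
  }
  if (n_helices < 1) stop("need at least one helix", call. = FALSE)
  phis <- 2 * pi * (seq_len(n_helices) - 1L) / n_helices
  parts <- vector("list", n_helices)
  for (k in seq_len(n_helices)) {
    if (is.null(seg)) {
      hs <- spec
      start_res <- 1L + (k - 1L) * spec$n_residues
      subseq <- NULL
    } else {
      hs <- helix_spec(seg$end[k] - seg$start[k] + 1L,
                       spec$rise_per_residue, spec$twist_per_residue,
                       spec$radius)
      start_res <- seg$start[k]
      subseq <- if (!is.null(sequence)) {
        substr(sequence$sequence, seg$start[k], seg$end[k])
      }
    }
    h <- build_ideal_helix(hs, chain = chain, start_residue = start_res,
                           sequence = subseq, model_id = "h")
    at <- h$atoms
    # centre the helix on its own axis midpoint, flip every other helix
    at$z <- at$z - mean(range(at$z))
    if (k %% 2 == 0) {
      at$z <- -at$z
      at$x <- -at$x
    }
    at$x <- at$x + bundle_radius * cos(phis[k])
    at$y <- at$y + bundle_radius * sin(phis[k])
    parts[[k]] <- at
  }
  atoms <- do.call(rbind, parts)
  atoms <- atoms[order(atoms$residue_seq), , drop = FALSE]
  structure_model(model_id, atoms)
}

#' Fitted helical geometry of a C-alpha trace
#'
#' Fits the helix axis (principal-component initialization refined by a
#' least-squares cylinder fit that minimizes the variance of radial
#' distances), then reports the mean per-residue axial rise, the mean
#' per-residue twist about the axis, residues per turn (360/twist) and pitch
#' (rise x residues per turn).
#'
#' @param model a [structure_model()] whose CA atoms trace one helix
#' @return list: `axis` (unit 3-vector), `rise_per_residue`,
#'   `twist_per_residue` (degrees), `residues_per_turn`, `pitch`, `radius`
#' @export
helix_geometry <- function(model) {
  at <- model$atoms
  at <- at[at$atom_name == "CA", , drop = FALSE]
  at <- at[order(at$residue_seq), , drop = FALSE]
  X <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(X)
  if (n < 6) stop("need at least 6 CA atoms to fit a helix", call. = FALSE)
  C <- sweep(X, 2, colMeans(X))
  ax0 <- svd(C)$v[, 1]
  to_sph <- function(v) c(acos(max(-1, min(1, v[3]))), atan2(v[2], v[1]))
  from_sph <- function(p) c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]),
                            cos(p[1]))
  radial_var <- function(p) {
    a <- from_sph(p)
    pr <- drop(C %*% a)
    perp <- C - outer(pr, a)
    stats::var(sqrt(rowSums(perp^2)))
  }
  fit <- stats::optim(to_sph(ax0 / sqrt(sum(ax0^2))), radial_var,
                      method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  a <- from_sph(fit$par)
  if (sum(a * (X[n, ] - X[1, ])) < 0) a <- -a
  pr <- drop(C %*% a)
  perp <- C - outer(pr, a)
  e1 <- perp[1, ] / sqrt(sum(perp[1, ]^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  ang <- atan2(drop(perp %*% e2), drop(perp %*% e1))
  dtw <- (diff(ang) + 2 * pi) %% (2 * pi)
  twist <- mean(dtw) * 180 / pi
  rise <- mean(diff(pr))
  list(axis = a, rise_per_residue = rise, twist_per_residue = twist,
       residues_per_turn = 360 / twist, pitch = rise * 360 / twist,
       radius = mean(sqrt(rowSums(perp^2))))
}
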