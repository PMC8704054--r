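# Solvent-accessible surface area (Shrake-Rupley with a deterministic
# spiral point set) and hydrophobic patch detection: the quantitative
# counterpart of surface-hydrophobicity renderings of native membrane
# receptors versus their water-solubilized variants.

#' Van der Waals radii for SASA
#'
#' United-atom radii in Angstrom (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20,
#' P 1.80), shipped as an editable TSV.
#'
#' @return named numeric vector keyed by element symbol
#' @export
vdw_radii <- function() {
  df <- read_table_tsv("vdw_radii.tsv")
  stats::setNames(df$radius, df$element)
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral /
# Fibonacci lattice). No RNG: SASA values are bit-reproducible.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, `n_points` quasi-uniform points are placed on a sphere of
#' radius `r_atom + probe`; the accessible fraction is the share of points
#' not inside any neighbouring atom's expanded sphere, scaled by the
#' sphere's area `4 * pi * (r_atom + probe)^2`.
#'
#' @param model a [structure_model()]
#' @param probe_radius solvent probe radius in A (default 1.4, water)
#' @param n_points test points per atom (default 960)
#' @param radii element radius table from [vdw_radii()]
#' @return object of class `sasa_result`: `probe_radius`, `n_points`,
#'   `per_atom` (numeric, A^2 per atom in model order), `per_residue`
#'   (data.frame chain, residue_seq, residue_name, area), `total_area`
#' @export
shrake_rupley_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                               radii = vdw_radii()) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  unknown <- setdiff(unique(at$element), names(radii))
  if (length(unknown)) {
    stop("no van der Waals radius for element: ", unknown[1], call. = FALSE)
  }
  n <- nrow(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- unname(radii[at$element]) + probe_radius
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  max_r <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + max_r & seq_len(n) != i)
    nb <- nb[di[nb] < rad[i] + rad[nb]]
    if (!length(nb)) {
      areas[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      d2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- d2 >= rad[j]^2
    }
    areas[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  res_key <- paste(at$chain, at$residue_seq)
  agg <- rowsum(areas, res_key)
  first <- !duplicated(res_key)
  per_res <- data.frame(
    chain = at$chain[first],
    residue_seq = at$residue_seq[first],
    residue_name = at$residue_name[first],
    area = agg[match(res_key[first], rownames(agg)), 1],
    stringsAsFactors = FALSE
  )
  per_res <- per_res[order(per_res$chain, per_res$residue_seq), , drop = FALSE]
  rownames(per_res) <- NULL
  structure(list(probe_radius = probe_radius, n_points = n_points,
                 per_atom = areas, per_residue = per_res,
                 total_area = sum(areas)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (%d residues), probe %.1f A, %d pts/atom\n",
              x$total_area, length(x$per_atom), nrow(x$per_residue),
              x$probe_radius, x$n_points))
  invisible(x)
}

DEFAULT_HYDROPHOBIC <- c("L", "I", "V", "F")
EXTENDED_HYDROPHOBIC <- c("L", "I", "V", "F", "A", "M", "W", "C")

#' Detect exposed hydrophobic patches
#'
#' Residues of the hydrophobic set whose solvent-accessible area exceeds
#' `exposure_threshold` become graph nodes; nodes whose C-alpha atoms lie
#' within `adjacency_cutoff` are connected; connected components are the
#' patches, reported largest first. The hydrophobic exposed fraction is the
#' summed area of all hydrophobic-set residues (exposed or not) over the
#' total area.
#'
#' @param model the [structure_model()] the SASA was computed from
#' @param sasa matching [shrake_rupley_sasa()] result
#' @param hydrophobic_set one-letter residue codes counted as hydrophobic
#'   (default L, I, V, F; `EXTENDED_HYDROPHOBIC` adds A, M, W, C)
#' @param exposure_threshold per-residue area (A^2) above which a residue
#'   counts as exposed (default 10)
#' @param adjacency_cutoff CA-CA distance (A) connecting exposed residues
#'   (default 8)
#' @return object of class `patch_report`: `hydrophobic_set`,
#'   `exposure_threshold`, `hydrophobic_fraction`, `patches` (list of
#'   data.frames with chain, residue_seq, residue_name, area; sorted by
#'   summed area, descending), `patch_areas`
#' @export
hydrophobic_patches <- function(model, sasa,
                                hydrophobic_set = DEFAULT_HYDROPHOBIC,
                                exposure_threshold = 10,
                                adjacency_cutoff = 8) {
  pr <- sasa$per_residue
  if (nrow(pr) != length(unique(paste(model$atoms$chain,
                                      model$atoms$residue_seq)))) {
    stop("sasa does not match model", call. = FALSE)
  }
  three <- unname(ONE_TO_THREE[hydrophobic_set])
  is_h <- pr$residue_name %in% three
  frac <- if (sasa$total_area > 0) sum(pr$area[is_h]) / sasa$total_area else 0

  exposed <- which(is_h & pr$area > exposure_threshold)
  patches <- list()
  if (length(exposed)) {
    ca <- model$atoms[model$atoms$atom_name == "CA", , drop = FALSE]
    key <- paste(ca$chain, ca$residue_seq)
    idx <- match(paste(pr$chain[exposed], pr$residue_seq[exposed]), key)
    has_ca <- !is.na(idx)
    exposed <- exposed[has_ca]
    idx <- idx[has_ca]
    if (length(exposed)) {
      xyz <- as.matrix(ca[idx, c("x", "y", "z")])
      m <- length(exposed)
      adj <- as.matrix(stats::dist(xyz)) <= adjacency_cutoff
      comp <- rep(NA_integer_, m)
      cid <- 0L
      for (s in seq_len(m)) {
        if (!is.na(comp[s])) next
        cid <- cid + 1L
        queue <- s
        comp[s] <- cid
        while (length(queue)) {
          v <- queue[1]
          queue <- queue[-1]
          nb <- which(adj[v, ] & is.na(comp))
          comp[nb] <- cid
          queue <- c(queue, nb)
        }
      }
      patches <- lapply(split(exposed, comp), function(ii) {
        pr[ii, c("chain", "residue_seq", "residue_name", "area")]
      })
      patches <- patches[order(vapply(patches, function(p) sum(p$area), 0),
                               decreasing = TRUE)]
      names(patches) <- NULL
    }
  }
  structure(list(
    hydrophobic_set = hydrophobic_set,
    exposure_threshold = exposure_threshold,
    adjacency_cutoff = adjacency_cutoff,
    hydrophobic_fraction = frac,
    patches = patches,
    patch_areas = vapply(patches, function(p) sum(p$area), 0)
  ), class = "patch_report")
}

#' @export
print.patch_report <- function(x, ...) {
  cat(sprintf("<patch_report> hydrophobic exposed fraction %.3f; %d patch(es)%s\n",
              x$hydrophobic_fraction, length(x$patches),
              if (length(x$patches))
                paste0(", largest ", sprintf("%.1f", x$patch_areas[1]), " A^2")
              else ""))
  invisible(x)
}

#' Compare native and variant surfaces
#'
#' Runs SASA + patch detection on both models and summarizes the change in
#' hydrophobic exposed fraction and largest-patch area (variant minus
#' native). On identical coordinates with QTY-relabelled residues, the
#' fraction can only decrease, since Q, T and Y are not members of the
#' hydrophobic set.
#'
#' @param native,variant residue-matched [structure_model()]s
#' @param ... passed on to [shrake_rupley_sasa()] and
#'   [hydrophobic_patches()]
#' @param probe_radius,n_points see [shrake_rupley_sasa()]
#' @param hydrophobic_set,exposure_threshold,adjacency_cutoff see
#'   [hydrophobic_patches()]
#' @return list: `native` and `variant` patch reports, and `delta` with
#'   `fraction_change` and `largest_patch_change`
#' @export
compare_surfaces <- function(native, variant, probe_radius = 1.4,
                             n_points = 960,
                             hydrophobic_set = DEFAULT_HYDROPHOBIC,
                             exposure_threshold = 10,
                             adjacency_cutoff = 8) {
  sn <- shrake_rupley_sasa(native, probe_radius, n_points)
  sv <- shrake_rupley_sasa(variant, probe_radius, n_points)
  pn <- hydrophobic_patches(native, sn, hydrophobic_set,
                            exposure_threshold, adjacency_cutoff)
  pv <- hydrophobic_patches(variant, sv, hydrophobic_set,
                            exposure_threshold, adjacency_cutoff)
  largest <- function(p) if (length(p$patch_areas)) p$patch_areas[1] else 0
  list(native = pn, variant = pv,
       delta = list(
         fraction_change = pv$hydrophobic_fraction - pn$hydrophobic_fraction,
         largest_patch_change = largest(pv) - largest(pn)))
}

#' Export per-residue SASA and patch membership as TSV
#'
#' @param model the model the report concerns
#' @param sasa its [shrake_rupley_sasa()] result
#' @param report its [hydrophobic_patches()] result
#' @param path optional output file
#' @return TSV text with columns chain, residue_seq, residue_name, area,
#'   hydrophobic, patch (0 = none)
#' @export
write_surface_tsv <- function(model, sasa, report, path = NULL) {
  pr <- sasa$per_residue
  three <- unname(ONE_TO_THREE[report$hydrophobic_set])
  patch_id <- integer(nrow(pr))
  for (k in seq_along(report$patches)) {
    p <- report$patches[[k]]
    patch_id[match(paste(p$chain, p$residue_seq),
                   paste(pr$chain, pr$residue_seq))] <- k
  }
  lines <- c("chain\tresidue_seq\tresidue_name\tarea\thydrophobic\tpatch",
             sprintf("%s\t%d\t%s\t%.3f\t%d\t%d", pr$chain, pr$residue_seq,
                     pr$residue_name, pr$area,
                     as.integer(pr$residue_name %in% three), patch_id))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
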