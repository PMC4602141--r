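## Shrake-Rupley solvent-accessible surface area.
##
## Each atom's van der Waals sphere is expanded by the probe radius and
## sampled with a deterministic golden-spiral point set; the accessible
## area is the exposed-point fraction times the expanded sphere area.
## No RNG is involved, so results are bit-stable across runs.

## n approximately equidistributed unit vectors (Fibonacci / golden spiral)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom SASA by rolling a probe sphere over the van der
#' Waals surface, approximated by counting sample points on each atom's
#' probe-expanded sphere that fall outside every neighbor's expanded
#' sphere.  Radii default to the Bondi set (C 1.70, N 1.55, O 1.52,
#' S 1.80 Angstrom).
#'
#' @param model a hydrogen-free [yrb_structure()].
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points number of sample points per atom (>= 12); accuracy
#'   improves roughly with 1/sqrt(n_points).
#' @param radii optional named numeric vector of per-element van der
#'   Waals radii overriding/extending the Bondi defaults.
#' @param subset optional logical or integer index of atoms to compute
#'   areas for; occlusion still considers all atoms in `model`.
#' @return an object of class `"yrb_sasa"`: list with `area` (numeric,
#'   per atom, Angstrom^2; atoms outside `subset` are `NA`), `total`,
#'   `probe_radius`, `n_sphere_points`, `radii_set_name`.
#' @export
#' @examples
#' m <- build_peptide("AG")
#' shrake_rupley_sasa(m, n_points = 240)$total
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               radii = NULL, subset = NULL) {
  stopifnot(inherits(model, "yrb_structure"))
  if (n_points < 12) stop("n_points must be >= 12")
  a <- model$atoms
  if (any(a$element %in% c("H", "D")))
    stop("model contains hydrogens; run strip_hydrogens() first")
  n <- nrow(a)
  r <- vdw_radius(a$element)
  if (!is.null(radii)) {
    idx <- match(a$element, normalize_element(names(radii)))
    r[!is.na(idx)] <- radii[idx[!is.na(idx)]]
  }
  if (anyNA(r))
    stop("no van der Waals radius for atom(s): ",
         paste(unique(paste0(a$name[is.na(r)], " (", a$element[is.na(r)], ")")),
               collapse = ", "),
         "; supply them via the 'radii' argument")
  which_atoms <- if (is.null(subset)) seq_len(n) else seq_len(n)[subset]
  area <- rep(NA_real_, n)
  if (n == 0) {
    return(structure(list(area = area, total = 0, probe_radius = probe,
                          n_sphere_points = n_points,
                          radii_set_name = "bondi"),
                     class = "yrb_sasa"))
  }
  xyz <- coords(model)
  sphere <- golden_spiral_points(n_points)
  rexp <- r + probe
  for (i in which_atoms) {
    ri <- rexp[i]
    ## neighbors whose expanded spheres can occlude atom i
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + rexp)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * ri^2
      next
    }
    pts <- sphere * ri
    pts <- sweep(pts, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      exposed <- exposed & (dj2 > rexp[j]^2)
    }
    area[i] <- 4 * pi * ri^2 * sum(exposed) / n_points
  }
  structure(list(area = area, total = sum(area, na.rm = TRUE),
                 probe_radius = probe, n_sphere_points = n_points,
                 radii_set_name = "bondi"),
            class = "yrb_sasa")
}

#' @export
print.yrb_sasa <- function(x, ...) {
  cat(sprintf(
    "yrb_sasa: total %.2f A^2 (%d atoms, probe %.2f A, %d points, radii '%s')\n",
    x$total, sum(!is.na(x$area)), x$probe_radius, x$n_sphere_points,
    x$radii_set_name))
  invisible(x)
}

#' Solvent-accessible surface area per YRB class
#'
#' Partitions a per-atom SASA over the atom classes; the per-class areas
#' sum exactly to the total.
#'
#' @param classified a [classify_structure()] result.
#' @param sasa a [shrake_rupley_sasa()] result on the same model (computed
#'   with defaults if omitted).
#' @return data.frame with `class`, `area`, `fraction`.
#' @export
class_sasa <- function(classified, sasa = NULL) {
  stopifnot(inherits(classified, "yrb_classified"))
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(classified$model)
  stopifnot(length(sasa$area) == natoms(classified$model))
  cls <- factor(classified$classes, levels = YRB_CLASSES_ALL)
  area <- vapply(split(sasa$area, cls), function(x) sum(x, na.rm = TRUE),
                 numeric(1))
  data.frame(class = YRB_CLASSES_ALL, area = unname(area),
             fraction = if (sasa$total > 0) unname(area) / sasa$total
                        else rep(NA_real_, length(area)))
}
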