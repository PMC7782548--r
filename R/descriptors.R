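#' Rational switching function
#'
#' Smooth counting kernel used for water coordination numbers:
#' `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with even `m > n`, continuous at
#' the removable singularity r = r0 where it equals `n/m`. Values are in
#' \[0, 1\] and decrease monotonically with distance.
#'
#' @param r0 shell radius (nm); default 0.35 nm, the first-hydration-shell
#'   scale conventional in enhanced sampling.
#' @param n_exp,m_exp even exponents, `m_exp > n_exp` (defaults 6 and 12).
#' @return object of class `switching_params`.
#' @export
switching_params <- function(r0 = 0.35, n_exp = 6L, m_exp = 12L) {
  stopifnot(r0 > 0, n_exp %% 2 == 0, m_exp %% 2 == 0, m_exp > n_exp)
  structure(list(r0 = r0, n = as.integer(n_exp), m = as.integer(m_exp)),
            class = "switching_params")
}

#' Evaluate the switching function
#'
#' @param r distance(s), nm (>= 0).
#' @param p a [switching_params()].
#' @return dimensionless value(s) in \[0, 1\].
#' @export
switching <- function(r, p = switching_params()) {
  stopifnot(inherits(p, "switching_params"), all(r >= 0))
  x <- r / p$r0
  num <- 1 - x^p$n
  den <- 1 - x^p$m
  out <- ifelse(abs(den) < 1e-12, p$n / p$m, num / den)
  # removable singularity: series value n/m at x = 1 (l'Hopital)
  out
}

#' Water coordination number of a point
#'
#' Sum of the switching function over all water-oxygen distances from
#' `center` - a smooth count of the waters in the first shell of the point.
#'
#' @param center length-3 point (nm).
#' @param oxygens k x 3 matrix of water-oxygen positions (nm); may be empty.
#' @param p a [switching_params()].
#' @return dimensionless coordination number (0 when no oxygens).
#' @export
coordination <- function(center, oxygens, p = switching_params()) {
  if (is.null(oxygens) || NROW(oxygens) == 0L) return(0)
  oxygens <- matrix(oxygens, ncol = 3)
  d <- sqrt(rowSums(sweep(oxygens, 2, center)^2))
  sum(switching(d, p))
}

frame_waters <- function(frame, water_labels = c("OW", "W")) {
  frame$xyz[frame$elements %in% water_labels, , drop = FALSE]
}

#' Ligand-centred water descriptors L
#'
#' One coordination number per ligand point, describing the water solvation
#' shell around the ligand. Points are the frame atoms whose element label is
#' in `ligand_labels` (default `LIG`), in frame order.
#'
#' @param frame a single frame (see [read_xyz_frames()]).
#' @param ligand_labels element labels that define the ligand points.
#' @param p a [switching_params()].
#' @param water_labels element labels counted as water oxygens.
#' @return named numeric vector `L_1..L_nL`.
#' @export
ligand_descriptors <- function(frame, ligand_labels = "LIG",
                               p = switching_params(),
                               water_labels = c("OW", "W")) {
  idx <- which(frame$elements %in% ligand_labels)
  if (length(idx) == 0L)
    stop("no ligand atoms labelled ", paste(ligand_labels, collapse = "/"),
         " in frame")
  wat <- frame_waters(frame, water_labels)
  L <- vapply(idx, function(i) coordination(frame$xyz[i, ], wat, p), numeric(1))
  setNames(L, paste0("L_", seq_along(idx)))
}

#' Binding-axis water descriptors V
#'
#' Coordination numbers at fixed points along the host axis, spanning the
#' inside and the mouth of the binding pocket: point k sits at
#' `origin + (k-1) * spacing * dir`, so `V_1` is the deepest point in the
#' cavity and later points move out towards the solvent.
#'
#' @param frame a single frame.
#' @param axis list with `origin` and `dir` (unit vector); defaults to the
#'   frame's own axis definition.
#' @param n_points number of axis points (>= 2; default 8).
#' @param spacing spacing between points (nm; default 0.2).
#' @param p a [switching_params()].
#' @param water_labels element labels counted as water oxygens.
#' @return named numeric vector `V_1..V_n`.
#' @export
axis_descriptors <- function(frame, axis = frame$axis, n_points = 8L,
                             spacing = 0.2, p = switching_params(),
                             water_labels = c("OW", "W")) {
  stopifnot(n_points >= 2L, spacing > 0)
  dir <- axis$dir / sqrt(sum(axis$dir^2))
  wat <- frame_waters(frame, water_labels)
  V <- vapply(seq_len(n_points) - 1L, function(k)
    coordination(axis$origin + k * spacing * dir, wat, p), numeric(1))
  setNames(V, paste0("V_", seq_len(n_points)))
}

#' Geometric CVs: axial projection and orientation cosine
#'
#' `s_z` is the signed projection of the ligand centre of mass on the binding
#' axis (relative to the axis origin); `cos_theta` is the cosine of the angle
#' between the ligand's own axis (first to last ligand atom) and the binding
#' axis.
#'
#' @param frame a single frame.
#' @param axis binding-axis definition (defaults to the frame's).
#' @param ligand_labels element labels of the ligand atoms (>= 2 needed for
#'   the orientation).
#' @return list with `s_z` (nm) and `cos_theta` (in \[-1, 1\]).
#' @export
geometry_cvs <- function(frame, axis = frame$axis, ligand_labels = "LIG") {
  idx <- which(frame$elements %in% ligand_labels)
  if (length(idx) < 2L) stop("ligand needs >= 2 atoms for orientation")
  dir <- axis$dir / sqrt(sum(axis$dir^2))
  com <- colMeans(frame$xyz[idx, , drop = FALSE])
  lig_axis <- frame$xyz[idx[length(idx)], ] - frame$xyz[idx[1], ]
  nl <- sqrt(sum(lig_axis^2))
  if (nl < 1e-12) stop("zero-length ligand axis")
  list(s_z = sum((com - axis$origin) * dir),
       cos_theta = sum(lig_axis * dir) / nl)
}

#' Descriptor table for a set of frames
#'
#' Computes the full water descriptor vector `d = (L, V)` plus the geometric
#' CVs for every frame, in COLVAR layout (one row per frame, a `time` column
#' first).
#'
#' @param frames an `xyz_frames` list.
#' @param p a [switching_params()].
#' @param n_axis_points,axis_spacing axis-grid definition (see
#'   [axis_descriptors()]).
#' @param ligand_labels,water_labels element-label selections.
#' @return data.frame `time, L_1.., V_1.., s_z, cos_theta`.
#' @export
descriptor_table <- function(frames, p = switching_params(),
                             n_axis_points = 8L, axis_spacing = 0.2,
                             ligand_labels = "LIG",
                             water_labels = c("OW", "W")) {
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    L <- ligand_descriptors(fr, ligand_labels, p, water_labels)
    V <- axis_descriptors(fr, fr$axis, n_axis_points, axis_spacing, p, water_labels)
    g <- geometry_cvs(fr, fr$axis, ligand_labels)
    c(time = i - 1, L, V, s_z = g$s_z, cos_theta = g$cos_theta)
  })
  as.data.frame(do.call(rbind, rows))
}
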