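#' Toy host + ligand + water-bead frames
#'
#' Geometric fixtures for the descriptor machinery. The host is a cylindrical
#' cavity of radius `r_cavity` along the +z axis, with its entrance at z = 0
#' and its bottom at `z = -depth`; the binding axis runs from the cavity
#' bottom towards the solvent (+z). The host body (the material around and
#' below the cavity) excludes water in both states. In "B" frames the
#' three-bead ligand sits inside the dry cavity; in "U" frames it floats
#' beyond the funnel mouth, fully solvated, and the cavity interior holds a
#' fluctuating number of waters (0 to `cavity_occupancy_max`, uniform per
#' frame) - emulating the wet/dry fluctuations of an unbound pocket, which
#' is what makes the cavity descriptors informative in the unbound ensemble.
#' Waters are labelled `OW`, ligand beads `LIG`.
#'
#' @param n_frames number of frames.
#' @param n_waters bulk water beads per frame (cavity waters come on top).
#' @param state_label "B" (bound) or "U" (unbound).
#' @param seed integer seed (generation is seed-deterministic).
#' @param box cubic box edge lengths (nm).
#' @param r_cavity,depth cavity radius and depth (nm).
#' @param ligand_jitter s.d. of the ligand bead placement noise (nm).
#' @param cavity_occupancy_max maximum number of cavity waters in a U frame
#'   (default 6, about the bulk-density capacity of the cavity volume).
#' @return `xyz_frames` list; each frame's `axis` has `origin` at the cavity
#'   bottom and `dir = (0,0,1)`.
#' @export
toy_host_guest_frames <- function(n_frames, n_waters, state_label = c("B", "U"),
                                  seed = 1, box = c(3, 3, 3),
                                  r_cavity = 0.5, depth = 0.8,
                                  ligand_jitter = 0.05,
                                  cavity_occupancy_max = 6L) {
  state_label <- match.arg(state_label)
  axis <- list(origin = c(0, 0, -depth), dir = c(0, 0, 1))
  # host body: cavity volume plus the wall/floor material around it
  in_host <- function(xyz) {
    r2 <- xyz[, 1]^2 + xyz[, 2]^2
    (xyz[, 3] > -depth - 0.3) & (xyz[, 3] < 0.1) & (r2 < (r_cavity + 0.35)^2)
  }
  with_seed(seed, {
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      # ligand: three beads stacked along its own axis
      if (state_label == "B") {
        base <- c(0, 0, -depth + 0.15)
        lig_dir <- c(0, 0, 1)
      } else {
        base <- c(0, 0, 1.2)
        th <- stats::runif(1, 0, pi); ph <- stats::runif(1, 0, 2 * pi)
        lig_dir <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      }
      lig <- rbind(base, base + 0.25 * lig_dir, base + 0.5 * lig_dir)
      lig <- lig + matrix(stats::rnorm(9, 0, ligand_jitter), 3, 3)
      # bulk waters: uniform in the box, outside the host body and off the
      # ligand beads
      wat <- matrix(numeric(0), 0, 3)
      if (n_waters > 0) {
        need <- n_waters
        while (need > 0) {
          cand <- cbind(stats::runif(2 * need + 8, -box[1] / 2, box[1] / 2),
                        stats::runif(2 * need + 8, -box[2] / 2, box[2] / 2),
                        stats::runif(2 * need + 8, -depth - 0.2, box[3] - depth - 0.2))
          keep <- !in_host(cand)
          for (j in seq_len(nrow(lig)))
            keep <- keep & (rowSums(sweep(cand, 2, lig[j, ])^2) > 0.28^2)
          cand <- cand[keep, , drop = FALSE]
          take <- min(nrow(cand), need)
          wat <- rbind(wat, cand[seq_len(take), , drop = FALSE])
          need <- need - take
        }
      }
      # U frames: a fluctuating number of waters inside the cavity
      if (state_label == "U" && cavity_occupancy_max > 0) {
        n_cav <- sample(0:cavity_occupancy_max, 1)
        if (n_cav > 0) {
          rr <- sqrt(stats::runif(n_cav)) * (r_cavity - 0.1)
          ang <- stats::runif(n_cav, 0, 2 * pi)
          cav <- cbind(rr * cos(ang), rr * sin(ang),
                       stats::runif(n_cav, -depth + 0.05, 0))
          wat <- rbind(wat, cav)
        }
      }
      frames[[f]] <- new_frame(
        elements = c(rep("LIG", 3), rep("OW", nrow(wat))),
        xyz = rbind(lig, wat), box = box, axis = axis,
        comment = sprintf("state=%s frame=%d", state_label, f)
      )
    }
    structure(frames, class = "xyz_frames")
  })
}
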