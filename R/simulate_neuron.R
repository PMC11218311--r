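#' Simulate a branched neuron morphology in SWC convention
#'
#' Grows a rooted tree from a soma at the origin: `n_primary` neurites
#' leave the soma at evenly spaced angles (with optional jitter) and each
#' branch bifurcates `branch_depth` times, every segment being a straight
#' edge of `segment_len_um`. The morphology is planar (z = 0) so that a
#' pixel render can be cross-checked against the vector representation.
#'
#' @param branch_depth number of bifurcation generations (>= 0). A depth
#'   of 0 gives unbranched primary neurites.
#' @param segment_len_um straight segment length, micrometres.
#' @param seed integer seed; fixes angle jitter.
#' @param n_primary number of primary neurites from the soma.
#' @param branch_angle_deg half-angle between daughter branches.
#' @param jitter_deg sd of Gaussian angular jitter per segment (0 for an
#'   exact star/binary-tree geometry).
#' @param type SWC type code assigned to neurites (3 = basal dendrite).
#' @return `NeuronMorphology`: data.frame with SWC columns
#'   `id, type, x, y, z, radius, parent`.
#' @export
simulate_neuron_swc <- function(branch_depth, segment_len_um = 10, seed = 1L,
                                n_primary = 3, branch_angle_deg = 30,
                                jitter_deg = 5, type = 3L) {
  stopifnot(branch_depth >= 0, segment_len_um > 0, n_primary >= 0)
  set.seed(as.integer(seed))
  nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                      radius = 4, parent = -1L)
  nid <- 1L
  grow <- function(parent_id, origin, heading_deg, depth) {
    ang <- heading_deg + if (jitter_deg > 0) rnorm(1, sd = jitter_deg) else 0
    tip <- origin + segment_len_um *
      c(cos(ang * pi / 180), sin(ang * pi / 180))
    nid <<- nid + 1L
    nodes <<- rbind(nodes, data.frame(id = nid, type = as.integer(type),
                                      x = tip[1], y = tip[2], z = 0,
                                      radius = 0.5, parent = parent_id))
    my_id <- nid
    if (depth > 0) {
      grow(my_id, tip, ang - branch_angle_deg, depth - 1)
      grow(my_id, tip, ang + branch_angle_deg, depth - 1)
    }
  }
  if (n_primary > 0)
    for (k in seq_len(n_primary))
      grow(1L, c(0, 0), (k - 1) * 360 / n_primary, branch_depth)
  structure(nodes, class = c("NeuronMorphology", "data.frame"))
}

#' Read a neuron morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments
#' allowed. Coordinates are taken as micrometres.
#'
#' @param path SWC file path.
#' @return `NeuronMorphology` data.frame.
#' @export
read_swc <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z",
                                  "radius", "parent"))
  validate_morphology(tab)
  structure(tab, class = c("NeuronMorphology", "data.frame"))
}

#' Write a neuron morphology to an SWC file
#'
#' @param morph `NeuronMorphology` data.frame.
#' @param path output path.
#' @export
write_swc <- function(morph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC: id type x y z radius parent", con)
  write.table(morph[, c("id", "type", "x", "y", "z", "radius", "parent")],
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Structural validation: unique ids, exactly one root, acyclic parents,
# finite coordinates.
validate_morphology <- function(morph) {
  stopifnot(all(c("id", "type", "x", "y", "z", "radius", "parent") %in%
                  names(morph)))
  if (anyDuplicated(morph$id)) stop("duplicate SWC node ids")
  if (any(!is.finite(as.matrix(morph[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  roots <- morph$id[morph$parent < 0]
  if (length(roots) != 1) stop("morphology must have exactly one root")
  # cycle check by walking each node to the root
  idx <- match(morph$parent, morph$id)
  for (start in seq_len(nrow(morph))) {
    seen <- integer(0); cur <- start; steps <- 0
    while (!is.na(idx[cur])) {
      cur <- idx[cur]; steps <- steps + 1
      if (steps > nrow(morph)) stop("cyclic parent links in morphology")
    }
  }
  invisible(TRUE)
}
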