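#' Standard 32-channel 10-20 montage
#'
#' Builds the 32-electrode extended international 10-20 montage used by the
#' pipeline (the layout of a 32-channel wearable EEG cap). Electrode
#' positions are constructed on an idealized unit sphere from the classic
#' 10-20 geometry (outer ring electrodes on the equator, Cz at the vertex,
#' intermediate 10-10 electrodes as normalized arc midpoints) and projected
#' to 2-D scalp coordinates in millimetres by an azimuthal-equidistant
#' projection with a 92 mm head radius.
#'
#' @return A data.frame with columns `channel`, `x`, `y` (mm, right/anterior
#'   positive) and `z3`, the unit-sphere height (used only for reference).
#' @export
standard_montage <- function() {
  # idealized unit-sphere positions of the principal 10-20 electrodes
  # (x right, y anterior, z superior); outer ring at z = 0
  p <- list(
    Fp1 = c(-0.309, 0.951, 0), Fp2 = c(0.309, 0.951, 0),
    F7  = c(-0.809, 0.588, 0), F8  = c(0.809, 0.588, 0),
    T7  = c(-1, 0, 0),         T8  = c(1, 0, 0),
    P7  = c(-0.809, -0.588, 0), P8 = c(0.809, -0.588, 0),
    O1  = c(-0.309, -0.951, 0), O2 = c(0.309, -0.951, 0),
    Oz  = c(0, -1, 0),
    Fz  = c(0, 0.7071, 0.7071), Cz = c(0, 0, 1), Pz = c(0, -0.7071, 0.7071),
    F3  = c(-0.545, 0.673, 0.5), F4 = c(0.545, 0.673, 0.5),
    C3  = c(-0.7071, 0, 0.7071), C4 = c(0.7071, 0, 0.7071),
    P3  = c(-0.545, -0.673, 0.5), P4 = c(0.545, -0.673, 0.5)
  )
  nrm <- function(v) v / sqrt(sum(v^2))
  mid <- function(a, b) nrm(nrm(a) + nrm(b))
  # intermediate 10-10 electrodes as arc midpoints
  p$AF3 <- mid(p$Fp1, p$F3); p$AF4 <- mid(p$Fp2, p$F4)
  p$FC1 <- mid(mid(p$Fz, p$Cz), mid(p$F3, p$C3))
  p$FC2 <- mid(mid(p$Fz, p$Cz), mid(p$F4, p$C4))
  p$FC5 <- mid(mid(p$F3, p$C3), mid(p$F7, p$T7))
  p$FC6 <- mid(mid(p$F4, p$C4), mid(p$F8, p$T8))
  p$CP1 <- mid(mid(p$Pz, p$Cz), mid(p$P3, p$C3))
  p$CP2 <- mid(mid(p$Pz, p$Cz), mid(p$P4, p$C4))
  p$CP5 <- mid(mid(p$P3, p$C3), mid(p$P7, p$T7))
  p$CP6 <- mid(mid(p$P4, p$C4), mid(p$P8, p$T8))
  p$PO3 <- mid(p$P3, p$O1); p$PO4 <- mid(p$P4, p$O2)
  p$PO7 <- mid(p$P7, p$O1); p$PO8 <- mid(p$P8, p$O2)

  channels <- c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
                "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
                "PO7", "PO3", "PO4", "PO8", "Oz")
  head_radius_mm <- 92
  xy <- t(vapply(channels, function(ch) {
    v <- nrm(p[[ch]])
    theta <- acos(min(1, max(-1, v[3])))     # polar angle from vertex
    r2 <- sqrt(v[1]^2 + v[2]^2)
    u <- if (r2 < 1e-12) c(0, 0) else c(v[1], v[2]) / r2
    c(theta * head_radius_mm * u[1], theta * head_radius_mm * u[2], v[3])
  }, numeric(3)))
  data.frame(channel = channels, x = xy[, 1], y = xy[, 2], z3 = xy[, 3],
             stringsAsFactors = FALSE)
}

#' Channel adjacency from electrode distances
#'
#' Two channels are neighbors when their projected scalp distance is below
#' `max_dist_mm`. On the shipped montage the default of 75 mm connects each
#' electrode to its immediate 10-20/10-10 neighbors (2-8 neighbors per
#' channel, no isolated electrodes, C3-Cz style principal-ring pairs
#' included) while keeping the graph sparse.
#'
#' @param montage data.frame as returned by [standard_montage()].
#' @param max_dist_mm neighbor distance threshold in millimetres.
#' @return Symmetric logical adjacency matrix with `FALSE` diagonal.
#' @export
channel_adjacency <- function(montage = standard_montage(), max_dist_mm = 75) {
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  adj <- d > 0 & d <= max_dist_mm
  dimnames(adj) <- list(montage$channel, montage$channel)
  adj
}

#' Lattice adjacency for regular 1-D or 2-D statistic maps
#'
#' @param dims integer vector of length 1 (time courses) or 2
#'   (frequency-by-time maps); 2-D lattices use 4-connectivity.
#' @return Adjacency list in the compressed form used by the TFCE kernel:
#'   a list with integer vectors `neighbors` (0-based, concatenated) and
#'   `offsets` (length `prod(dims) + 1`).
#' @keywords internal
lattice_adjacency <- function(dims) {
  if (length(dims) == 1L) {
    n <- dims
    nb <- lapply(seq_len(n), function(i) {
      c(if (i > 1L) i - 1L, if (i < n) i + 1L)
    })
  } else if (length(dims) == 2L) {
    nr <- dims[1]; nc <- dims[2]
    idx <- function(r, c) (c - 1L) * nr + r
    nb <- vector("list", nr * nc)
    for (c in seq_len(nc)) {
      for (r in seq_len(nr)) {
        v <- c(if (r > 1L) idx(r - 1L, c), if (r < nr) idx(r + 1L, c),
               if (c > 1L) idx(r, c - 1L), if (c < nc) idx(r, c + 1L))
        nb[[idx(r, c)]] <- v
      }
    }
  } else {
    stop("only 1-D or 2-D lattices are supported")
  }
  compress_adjacency(nb)
}

# convert a list-of-neighbor-indices (1-based) to the compressed 0-based form
compress_adjacency <- function(nb_list) {
  lens <- lengths(nb_list)
  list(neighbors = as.integer(unlist(nb_list, use.names = FALSE) - 1L),
       offsets = as.integer(c(0L, cumsum(lens))))
}

# adjacency matrix -> compressed form
matrix_adjacency <- function(adj) {
  nb <- lapply(seq_len(nrow(adj)), function(i) which(adj[i, ]))
  compress_adjacency(nb)
}
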