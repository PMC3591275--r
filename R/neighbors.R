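#' Simulation box geometry
#'
#' @param Lx,Ly box dimensions (um).
#' @param periodic_x,periodic_y logical; periodic wrapping per direction.
#' @return A `box_spec` list.
#' @export
box_spec <- function(Lx, Ly, periodic_x = TRUE, periodic_y = TRUE) {
  stopifnot(Lx > 0, Ly > 0)
  structure(list(Lx = Lx, Ly = Ly, periodic_x = isTRUE(periodic_x),
                 periodic_y = isTRUE(periodic_y)), class = "box_spec")
}

#' @rdname box_spec
#' @param x a `box_spec` or a [sim_config()] (band boundary = periodic in y
#'   only).
#' @export
as_box <- function(x) {
  if (inherits(x, "box_spec")) return(x)
  if (inherits(x, "sim_config")) {
    return(box_spec(x$Lx, x$Ly, periodic_x = x$boundary == "periodic",
                    periodic_y = TRUE))
  }
  stop("cannot interpret box geometry")
}

# minimum-image displacement per component
min_image <- function(d, L, periodic) {
  if (!periodic) return(d)
  d - L * round(d / L)
}

# displacement matrix pos[to,] - pos[from,] under the box geometry
edge_displacements <- function(pos, from, to, box) {
  dx <- min_image(pos[to, 1] - pos[from, 1], box$Lx, box$periodic_x)
  dy <- min_image(pos[to, 2] - pos[from, 2], box$Ly, box$periodic_y)
  cbind(dx, dy)
}

#' Sector-based neighbor detection
#'
#' Splits the neighborhood of every particle into 6 equal 60-degree sectors
#' (the +x axis is a sector boundary) and takes the closest particle within
#' `cutoff` in each sector as a neighbor. The relation is in general
#' asymmetric; `symmetrize = TRUE` takes the union of both directions (used
#' for momentum-conservation checks). Ties within a sector are broken by the
#' lower particle index.
#'
#' @param positions N x 2 matrix of positions (um).
#' @param cutoff neighbor cutoff distance (um), default 100.
#' @param box a [box_spec()] (or `sim_config`); `NULL` means non-periodic.
#' @param symmetrize logical; symmetrize the neighbor relation.
#' @return A `neighbor_graph`: list with `nbr` (N x 6 neighbor indices, NA =
#'   empty sector), `dist` (matching distances), `rbar` (mean sector distance
#'   with `cutoff` substituted in empty sectors), `degree`, `edges` (directed
#'   edge data.frame `from`, `to`), `cutoff`, `box`.
#' @examples
#' pos <- cbind(c(0, 20, -20), c(0, 0, 0))
#' g <- find_neighbors(pos, cutoff = 100, box = box_spec(200, 200))
#' g$degree
#' @export
find_neighbors <- function(positions, cutoff = 100, box = NULL,
                           symmetrize = FALSE) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || ncol(positions) != 2 || !all(is.finite(positions)))
    stop("positions must be a finite N x 2 numeric matrix")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(box)) {
    box <- box_spec(max(diff(range(positions[, 1])), 1),
                    max(diff(range(positions[, 2])), 1),
                    periodic_x = FALSE, periodic_y = FALSE)
  } else box <- as_box(box)

  res <- cpp_sector_neighbors(positions, cutoff, box$Lx, box$Ly,
                              box$periodic_x, box$periodic_y)
  nbr <- res$nbr
  nbr[nbr == 0L] <- NA_integer_
  dist <- res$dist
  n <- nrow(positions)

  valid <- !is.na(nbr)
  from <- rep.int(seq_len(n), 6)[valid]
  to <- nbr[valid]
  if (symmetrize) {
    key <- unique(c(paste(from, to), paste(to, from)))
    parts <- matrix(as.integer(unlist(strsplit(key, " ", fixed = TRUE))),
                    ncol = 2, byrow = TRUE)
    from <- parts[, 1]; to <- parts[, 2]
  }

  rbar_dist <- dist
  rbar_dist[is.na(rbar_dist)] <- cutoff
  g <- list(nbr = nbr, dist = dist,
            rbar = rowMeans(rbar_dist),
            degree = rowSums(valid),
            edges = data.frame(from = from, to = to),
            cutoff = cutoff, box = box, symmetrized = isTRUE(symmetrize))
  class(g) <- "neighbor_graph"
  g
}

#' Local cell density from the sector neighbor graph
#'
#' The local density at a cell is `d_i = 2 / (sqrt(3) * rbar_i^2)` with
#' `rbar_i` the mean distance to its 6 sector neighbors (empty sectors
#' contribute the cutoff distance), so that a hexagonal lattice of spacing
#' `a` reports its true number density `2 / (sqrt(3) a^2)`.
#'
#' @param graph a [find_neighbors()] result.
#' @param i optional particle indices (default: all).
#' @return Density values (1/um^2), strictly positive.
#' @export
local_density <- function(graph, i = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  r <- if (is.null(i)) graph$rbar else graph$rbar[i]
  2 / (sqrt(3) * r^2)
}

# 60-degree sector index in 1..6 of displacements (dx, dy); same comparison
# rule (including the boundary snap tolerance) as the compiled neighbor
# search, sector boundaries anchored on the +x axis
sector_index <- function(dx, dy) {
  sqrt3 <- 1.7320508075688772
  tol <- 1e-9 * (abs(dx) + abs(dy))
  dy <- ifelse(abs(dy) <= tol, 0, dy)
  lower <- !(dy > 0 | (dy == 0 & dx > 0))
  dx <- ifelse(lower, -dx, dx)
  dy <- ifelse(lower, -dy, dy)
  diff <- dy - sqrt3 * dx
  diff <- ifelse(abs(diff) <= tol, 0, diff)
  diff2 <- dy + sqrt3 * dx
  diff2 <- ifelse(abs(diff2) <= tol, 0, diff2)
  s <- ifelse(dx > 0 & diff < 0, 0L,
              ifelse(ifelse(dx >= 0, diff >= 0, diff2 > 0), 1L, 2L))
  s + ifelse(lower, 3L, 0L) + 1L
}

# one-off sector density at an arbitrary point against a position set;
# used by the division acceptance check (point itself excluded by distance 0)
sector_density_at <- function(point, positions, cutoff, box) {
  dx <- min_image(positions[, 1] - point[1], box$Lx, box$periodic_x)
  dy <- min_image(positions[, 2] - point[2], box$Ly, box$periodic_y)
  d <- sqrt(dx^2 + dy^2)
  keep <- d > 0 & d <= cutoff
  rbar <- rep(cutoff, 6)
  if (any(keep)) {
    sec <- sector_index(dx[keep], dy[keep])
    ds <- d[keep]
    for (s in unique(sec)) rbar[s] <- min(ds[sec == s])
  }
  2 / (sqrt(3) * mean(rbar)^2)
}

#' Pairwise interaction force
#'
#' Central force derived from a pair potential that is the sum of a repulsive
#' short-range gaussian core and a Heaviside-gated linear attractive branch:
#' the radial force magnitude (positive = repulsive) is
#' `A_rep * (r / r_rep^2) * exp(-r^2 / (2 r_rep^2))` minus
#' `A_att * (r - r_att) / (r_cut - r_att)` on `r_att < r <= r_cut`, and zero
#' beyond `r_cut`. Below 0.5 um the magnitude is pinned at its value at
#' 0.5 um so that nearly coincident particles (freshly divided daughters)
#' separate robustly.
#'
#' @param r_vec displacement(s) `x_j - x_i`: a length-2 vector or an N x 2
#'   matrix (um).
#' @param potential a list with `A_rep`, `r_rep`, `A_att`, `r_att`, `r_cut`
#'   (a [sim_config()] works).
#' @return Force on particle i (um/h^2), same shape as `r_vec`. The force is
#'   antisymmetric: `pair_force(-r) == -pair_force(r)`.
#' @export
pair_force <- function(r_vec, potential) {
  vec <- is.null(dim(r_vec))
  rv <- if (vec) matrix(r_vec, ncol = 2) else as.matrix(r_vec)
  r <- sqrt(rv[, 1]^2 + rv[, 2]^2)
  mag <- radial_force(r, potential)
  out <- -(mag / ifelse(r > 0, r, 1)) * rv
  if (any(r == 0)) {
    warning("pair_force: zero separation; capped magnitude along +x applied")
    out[r == 0, 1] <- mag[r == 0]
    out[r == 0, 2] <- 0
  }
  if (vec) out[1, ] else out
}

# radial force magnitude (positive = repulsive), capped below r = 0.5 um
radial_force <- function(r, pot) {
  f <- pot$A_rep * (r / pot$r_rep^2) * exp(-r^2 / (2 * pot$r_rep^2))
  att <- r > pot$r_att & r <= pot$r_cut
  f[att] <- f[att] - pot$A_att * (r[att] - pot$r_att) / (pot$r_cut - pot$r_att)
  f[r > pot$r_cut] <- 0
  low <- r < 0.5
  if (any(low)) f[low] <- radial_force(0.5, pot)
  f
}

#' Pair potential energy
#'
#' The continuous potential whose negative radial derivative is the
#' [pair_force()] magnitude: gaussian core plus quadratic attractive well on
#' `(r_att, r_cut]`, constant beyond `r_cut`, linear continuation below the
#' 0.5 um force cap.
#'
#' @param r distances (um).
#' @param potential as in [pair_force()].
#' @return Potential values (um^2/h^2).
#' @export
pair_potential <- function(r, potential) {
  pot <- potential
  U <- pot$A_rep * exp(-r^2 / (2 * pot$r_rep^2))
  att <- r > pot$r_att
  ra <- pmin(r[att], pot$r_cut)
  U[att] <- U[att] + pot$A_att * (ra - pot$r_att)^2 / (2 * (pot$r_cut - pot$r_att))
  low <- r < 0.5
  if (any(low)) {
    U0 <- pot$A_rep * exp(-0.25 / (2 * pot$r_rep^2))
    U[low] <- U0 + radial_force(0.5, pot) * (0.5 - r[low])
  }
  U
}

#' Angles between successive neighbors
#'
#' For every cell i and every pair (j, k) of its neighbors that are also
#' neighbors of each other (in either direction of the sector relation),
#' emits the absolute angle between the vectors `x_j - x_i` and `x_k - x_i`.
#' On a perfect hexagonal packing all angles are 60 degrees.
#'
#' @param graph a [find_neighbors()] result.
#' @param positions the positions the graph was computed from.
#' @param cells optional indices of the focal cells to evaluate (e.g. to
#'   exclude cells at an open boundary); default all.
#' @return Numeric vector of angles in degrees, in `[0, 180]`.
#' @export
successive_neighbor_angles <- function(graph, positions, cells = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(cells)) cells <- seq_len(n)
  box <- graph$box
  out <- vector("list", n)
  for (i in cells) {
    nb <- graph$nbr[i, ]
    nb <- nb[!is.na(nb)]
    if (length(nb) < 2) next
    prs <- utils::combn(nb, 2)
    ang <- numeric(0)
    for (c_ in seq_len(ncol(prs))) {
      j <- prs[1, c_]; k <- prs[2, c_]
      if (!(k %in% graph$nbr[j, ] || j %in% graph$nbr[k, ])) next
      vj <- edge_displacements(positions, i, j, box)
      vk <- edge_displacements(positions, i, k, box)
      cosv <- sum(vj * vk) / (sqrt(sum(vj^2)) * sqrt(sum(vk^2)))
      ang <- c(ang, acos(pmin(pmax(cosv, -1), 1)) * 180 / pi)
    }
    out[[i]] <- ang
  }
  unlist(out) %||% numeric(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
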