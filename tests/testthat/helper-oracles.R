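# Brute-force reference implementations used as oracles. They share the
# package's sector-boundary convention (comparison-based with the boundary
# snap) but are otherwise naive O(N^2)/O(N^3) loops, independent of the
# cell-list fast paths.

oracle_min_image <- function(d, L, periodic) {
  if (!periodic) return(d)
  d - L * round(d / L)
}

oracle_sector <- function(dx, dy) {
  sqrt3 <- 1.7320508075688772
  tol <- 1e-9 * (abs(dx) + abs(dy))
  if (abs(dy) <= tol) dy <- 0
  base <- 0L
  if (!(dy > 0 || (dy == 0 && dx > 0))) {
    base <- 3L; dx <- -dx; dy <- -dy
  }
  diff <- dy - sqrt3 * dx
  if (abs(diff) <= tol) diff <- 0
  diff2 <- dy + sqrt3 * dx
  if (abs(diff2) <= tol) diff2 <- 0
  if (dx > 0 && diff < 0) return(base + 1L)
  if (if (dx >= 0) diff >= 0 else diff2 > 0) return(base + 2L)
  base + 3L
}

# all-pairs sector neighbor scan
oracle_sector_neighbors <- function(pos, cutoff, box) {
  n <- nrow(pos)
  nbr <- matrix(NA_integer_, n, 6)
  dist <- matrix(NA_real_, n, 6)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- oracle_min_image(pos[j, 1] - pos[i, 1], box$Lx, box$periodic_x)
    dy <- oracle_min_image(pos[j, 2] - pos[i, 2], box$Ly, box$periodic_y)
    d <- sqrt(dx^2 + dy^2)
    if (d > cutoff || d == 0) next
    s <- oracle_sector(dx, dy)
    if (is.na(dist[i, s]) || d < dist[i, s] ||
        (d == dist[i, s] && j < nbr[i, s])) {
      dist[i, s] <- d; nbr[i, s] <- j
    }
  }
  list(nbr = nbr, dist = dist)
}

# all-pairs annulus counting for g(r); bins (k*dr, (k+1)*dr]
oracle_pair_counts <- function(pos, box, dr, rmax) {
  n <- nrow(pos)
  nb <- ceiling(rmax / dr)
  counts <- numeric(nb)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- oracle_min_image(pos[j, 1] - pos[i, 1], box$Lx, box$periodic_x)
    dy <- oracle_min_image(pos[j, 2] - pos[i, 2], box$Ly, box$periodic_y)
    d <- sqrt(dx^2 + dy^2)
    if (d == 0 || d > rmax) next
    k <- max(ceiling(d / dr), 1)
    if (k <= nb) counts[k] <- counts[k] + 1
  }
  counts
}

# double-loop spatial velocity correlation (mean-removed, normalized)
oracle_spatial_corr <- function(pos, u, box, dr, rmax) {
  u <- u - mean(u)
  n <- nrow(pos)
  nb <- ceiling(rmax / dr)
  s <- numeric(nb); cnt <- numeric(nb)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- oracle_min_image(pos[j, 1] - pos[i, 1], box$Lx, box$periodic_x)
    dy <- oracle_min_image(pos[j, 2] - pos[i, 2], box$Ly, box$periodic_y)
    d <- sqrt(dx^2 + dy^2)
    if (d == 0 || d > rmax) next
    k <- max(ceiling(d / dr), 1)
    if (k <= nb) { s[k] <- s[k] + u[i] * u[j]; cnt[k] <- cnt[k] + 1 }
  }
  val <- ifelse(cnt > 0, s / cnt, NA_real_)
  list(normalized = c(1, val / mean(u^2)), counts = c(n, cnt))
}

# triple-loop successive-neighbor angles
oracle_angles <- function(nbr, pos, box) {
  n <- nrow(pos)
  out <- numeric(0)
  for (i in seq_len(n)) {
    nb <- nbr[i, ]; nb <- nb[!is.na(nb)]
    if (length(nb) < 2) next
    for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
      j <- nb[a]; k <- nb[b]
      if (!(k %in% nbr[j, ] || j %in% nbr[k, ])) next
      vj <- c(oracle_min_image(pos[j, 1] - pos[i, 1], box$Lx, box$periodic_x),
              oracle_min_image(pos[j, 2] - pos[i, 2], box$Ly, box$periodic_y))
      vk <- c(oracle_min_image(pos[k, 1] - pos[i, 1], box$Lx, box$periodic_x),
              oracle_min_image(pos[k, 2] - pos[i, 2], box$Ly, box$periodic_y))
      cs <- sum(vj * vk) / sqrt(sum(vj^2) * sum(vk^2))
      out <- c(out, acos(min(max(cs, -1), 1)) * 180 / pi)
    }
  }
  out
}

# hexagonal lattice fixture in a commensurate periodic box; a nonzero
# rotation returns a generically oriented (non-periodic) patch, the
# situation of a relaxed sheet where lattice bonds do not sit on sector
# boundaries
hex_fixture <- function(nx = 12, ny = 12, a = 16, jitter = 0, rotate = 0) {
  Lx <- nx * a
  Ly <- ny * a * sqrt(3) / 2
  pos <- epimotion:::hex_packing(nx * ny, Lx, Ly, jitter)
  if (rotate != 0) {
    th <- rotate * pi / 180
    ctr <- c(Lx, Ly) / 2
    rel <- sweep(pos, 2, ctr)
    pos <- sweep(rel %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th))),
                 2, ctr, `+`)
    return(list(pos = pos, box = box_spec(4 * Lx, 4 * Ly, FALSE, FALSE),
                a = a, n = nx * ny))
  }
  list(pos = pos, box = box_spec(Lx, Ly), a = a, n = nx * ny)
}
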