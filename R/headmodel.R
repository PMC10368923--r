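#' Region labels of the synthetic source space
#'
#' Twelve labelled regions: six bilateral areas (frontal, sensorimotor,
#' temporal, temporo-parietal junction, occipital, cerebellum). The cerebellar
#' pair forms its own "group" in the adjacency graph; all others are cortical.
#'
#' @return character vector of 12 region labels.
#' @export
region_labels <- function() {
  as.vector(outer(c("frontal", "sensorimotor", "temporal", "TPJ",
                    "occipital", "cerebellum"),
                  c("L", "R"), paste, sep = "_"))
}

# unit direction of each region centroid; x = right, y = anterior, z = up
region_directions <- function() {
  base <- rbind(
    frontal      = c(0.45,  0.75,  0.48),
    sensorimotor = c(0.55,  0.10,  0.83),
    temporal     = c(0.92,  0.05, -0.10),
    TPJ          = c(0.75, -0.45,  0.40),
    occipital    = c(0.30, -0.90,  0.18),
    cerebellum   = c(0.33, -0.72, -0.60)
  )
  out <- matrix(0, 12, 3)
  labs <- region_labels()
  for (i in seq_len(6)) {
    d <- base[i, ] / sqrt(sum(base[i, ]^2))
    out[i, ]     <- d * c(-1, 1, 1)  # left hemisphere mirrors x
    out[i + 6, ] <- d
  }
  rownames(out) <- labs
  out
}

rotation_to <- function(target) {
  # rotation matrix mapping the z-axis onto unit vector `target`
  z <- c(0, 0, 1)
  v <- c(z[2] * target[3] - z[3] * target[2],
         z[3] * target[1] - z[1] * target[3],
         z[1] * target[2] - z[2] * target[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(z * target)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

golden_patch <- function(n, center, ang_radius) {
  # quasi-uniform points within a spherical cap around `center`
  ga <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  theta <- ang_radius * sqrt((i - 0.5) / n)
  phi <- i * ga
  pts <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  pts %*% t(rotation_to(center / sqrt(sum(center^2))))
}

#' Build a synthetic spherical head model
#'
#' Places `n_electrodes` electrodes quasi-uniformly on the upper unit sphere
#' plus an inferior-posterior patch over the cerebellum, scatters
#' `nodes_per_region` source nodes around each of the 12 region centroids
#' (cortical nodes at eccentricity 0.85, cerebellar nodes deeper at 0.70,
#' exercising the depth asymmetry of inverse solutions), computes the
#' average-referenced analytic leadfield for radially oriented unit dipoles,
#' and connects k-nearest-neighbour nodes within each source group (cortex vs
#' cerebellum).
#'
#' @param n_electrodes number of electrodes (>= 16).
#' @param nodes_per_region source nodes per region (>= 1).
#' @param seed integer seed for the node jitter.
#' @param k_adjacency neighbours per node in the source graph.
#' @param bridge_edges optional 2-column integer matrix of explicitly
#'   configured extra edges (e.g. cerebello-cortical); default none.
#' @param ecc_cortex,ecc_cerebellum radial eccentricity of cortical and
#'   cerebellar nodes (head radius = 1).
#' @return an object of class `head_model` with fields `electrode_positions`
#'   (n_electrodes x 3, unit norm), `source_positions` (n_sources x 3),
#'   `source_labels`, `leadfield` (n_electrodes x n_sources, microvolts per
#'   unit dipole moment, average-referenced), `adjacency` (symmetric logical,
#'   zero diagonal).
#' @export
build_head_model <- function(n_electrodes, nodes_per_region, seed = 1L,
                             k_adjacency = 4L, bridge_edges = NULL,
                             ecc_cortex = 0.85, ecc_cerebellum = 0.70) {
  if (n_electrodes < 16) stop_invalid("n_electrodes must be >= 16")
  if (nodes_per_region < 1) stop_invalid("nodes_per_region must be >= 1")
  set.seed(seed)

  n_patch <- max(8L, round(n_electrodes / 8))
  n_up <- n_electrodes - n_patch
  ga <- pi * (3 - sqrt(5))
  i <- seq_len(n_up)
  z <- 1 - 0.97 * (i - 0.5) / n_up           # upper sphere, down to z ~ 0.03
  r <- sqrt(pmax(0, 1 - z^2))
  upper <- cbind(r * cos(i * ga), r * sin(i * ga), z)
  patch <- golden_patch(n_patch, c(0, -0.72, -0.60), 0.5)
  elec <- rbind(upper, patch)
  elec <- elec / sqrt(rowSums(elec^2))

  dirs <- region_directions()
  labs <- region_labels()
  src_pos <- NULL
  src_lab <- character(0)
  for (j in seq_len(12)) {
    ecc <- if (grepl("^cerebellum", labs[j])) ecc_cerebellum else ecc_cortex
    for (m in seq_len(nodes_per_region)) {
      d <- dirs[j, ] + rnorm(3, sd = 0.12)
      d <- d / sqrt(sum(d^2))
      src_pos <- rbind(src_pos, d * ecc)
      src_lab <- c(src_lab, labs[j])
    }
  }

  n_src <- nrow(src_pos)
  lead <- matrix(0, n_electrodes, n_src)
  for (s in seq_len(n_src)) {
    moment <- src_pos[s, ] / sqrt(sum(src_pos[s, ]^2))  # radial orientation
    lead[, s] <- dipole_leadfield(src_pos[s, ], moment, elec)
  }
  lead <- lead * 3   # gain to a realistic microvolt scale per unit moment

  cereb <- grepl("^cerebellum", src_lab)
  adj <- matrix(FALSE, n_src, n_src)
  for (grp in list(which(!cereb), which(cereb))) {
    if (length(grp) < 2) next
    d2 <- as.matrix(dist(src_pos[grp, , drop = FALSE]))
    k <- min(k_adjacency, length(grp) - 1)
    for (a in seq_along(grp)) {
      nb <- grp[order(d2[a, ])[2:(k + 1)]]
      adj[grp[a], nb] <- TRUE
    }
  }
  adj <- adj | t(adj)
  if (!is.null(bridge_edges)) {
    for (e in seq_len(nrow(bridge_edges))) {
      adj[bridge_edges[e, 1], bridge_edges[e, 2]] <- TRUE
      adj[bridge_edges[e, 2], bridge_edges[e, 1]] <- TRUE
    }
  }
  diag(adj) <- FALSE

  structure(list(
    electrode_positions = elec,
    source_positions = src_pos,
    source_labels = src_lab,
    leadfield = lead,
    adjacency = adj
  ), class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d electrodes, %d sources (%d regions)\n",
              nrow(x$electrode_positions), ncol(x$leadfield),
              length(unique(x$source_labels))))
  invisible(x)
}

#' Surface potential of a current dipole in a homogeneous conducting sphere
#'
#' Exact solution for the electric potential generated on the surface of a
#' homogeneous sphere (radius 1, conductivity `sigma`) by a current dipole,
#' evaluated by the Legendre expansion of the insulated-boundary Green
#' function summed to machine tolerance, then average-referenced. For a
#' dipole at eccentricity f the series converges geometrically in f^n.
#'
#' @param position dipole location, `||position|| < 1`.
#' @param moment dipole moment vector.
#' @param electrode_positions matrix (n x 3) of unit vectors.
#' @param sigma conductivity (arbitrary units).
#' @param tol relative truncation tolerance of the series.
#' @return average-referenced potential at each electrode.
#' @export
dipole_leadfield <- function(position, moment, electrode_positions,
                             sigma = 1, tol = 1e-13) {
  r0 <- sqrt(sum(position^2))
  if (r0 >= 1) stop_invalid("dipole must lie strictly inside the unit sphere")
  re <- electrode_positions
  if (r0 < 1e-12) {
    v <- 3 * (re %*% moment) / (4 * pi * sigma)
    return(drop(v) - mean(v))
  }
  rhat <- position / r0
  u <- drop(re %*% rhat)            # cos(angle) electrode vs dipole axis
  p_r0 <- sum(moment * rhat)
  p_re <- drop(re %*% moment)

  nmax <- min(2000L, max(60L, ceiling(log(tol) / log(max(r0, 1e-3))) + 10L))
  Pnm1 <- rep(1, length(u))         # P_0
  Pn <- u                           # P_1
  dPnm1 <- rep(0, length(u))        # P_0'
  dPn <- rep(1, length(u))          # P_1'
  v <- numeric(length(u))
  pow <- 1                          # r0^{n-1}
  for (n in seq_len(nmax)) {
    cn <- (2 * n + 1) / n
    an <- n * Pn * p_r0 + dPn * (p_re - u * p_r0)
    term <- cn * pow * an
    v <- v + term
    if (n > 3 && max(abs(term)) < tol * max(abs(v), 1e-300)) break
    # advance recurrences to order n+1
    Pnp1 <- ((2 * n + 1) * u * Pn - n * Pnm1) / (n + 1)
    dPnp1 <- dPnm1 + (2 * n + 1) * Pn
    Pnm1 <- Pn; Pn <- Pnp1
    dPnm1 <- dPn; dPn <- dPnp1
    pow <- pow * r0
  }
  v <- v / (4 * pi * sigma)
  v - mean(v)
}

#' Graph distance between source nodes
#'
#' Shortest-path hop count on the source adjacency graph (igraph backend);
#' `Inf` for disconnected pairs.
#'
#' @param adjacency symmetric logical/0-1 matrix.
#' @param from,to node indices.
#' @return numeric hop distance(s).
#' @export
graph_hops <- function(adjacency, from, to) {
  g <- igraph::graph_from_adjacency_matrix(adjacency * 1, mode = "undirected")
  d <- igraph::distances(g, v = from, to = to)
  drop(d)
}

#' Sensor adjacency graph from electrode positions
#'
#' Symmetric k-nearest-neighbour graph over electrodes, used by the
#' sensor-level cluster statistics.
#'
#' @param head a `head_model`.
#' @param k neighbours per electrode.
#' @return symmetric logical adjacency matrix.
#' @export
electrode_adjacency <- function(head, k = 4L) {
  pos <- head$electrode_positions
  n <- nrow(pos)
  d2 <- as.matrix(dist(pos))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    adj[i, order(d2[i, ])[2:(k + 1)]] <- TRUE
  }
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  adj
}
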