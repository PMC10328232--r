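#' Parameters for grid/strip snapping
#'
#' @param lambda_deform weight of the neighbour-distance preservation term.
#' @param max_iter maximum optimization sweeps.
#' @param tol convergence threshold on the energy decrease.
#' @param smoothing_iters Taubin smoothing iterations applied to the target
#'   surface by the `snap` pipeline stage.
#' @export
snap_params <- function(lambda_deform = 1.0, max_iter = 200L, tol = 1e-6,
                        smoothing_iters = 20L) {
  if (lambda_deform < 0) stop("lambda_deform must be >= 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(lambda_deform = lambda_deform,
                 max_iter = as.integer(max_iter), tol = tol,
                 smoothing_iters = as.integer(smoothing_iters)),
            class = "snap_params")
}

#' Taubin-smoothed snapping target surface
#'
#' Shrink-compensated iterative neighbour averaging (lambda/mu Taubin
#' scheme), preserving vertex and face counts and watertightness; a sphere
#' keeps its radius to within a percent at the default settings and a
#' planar patch is a fixed point.
#'
#' @param pial watertight [surface_mesh()].
#' @param iters smoothing iterations (0 returns the input).
#' @param lambda,mu Taubin step sizes (`0 < lambda < -mu`).
#' @export
smooth_target_surface <- function(pial, iters = 20, lambda = 0.5,
                                  mu = -0.53) {
  if (!is_watertight(pial)) stop("smoothing target must be watertight")
  if (iters == 0) return(pial)
  n <- nrow(pial$vertices)
  e <- rbind(pial$faces[, 1:2], pial$faces[, 2:3], pial$faces[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  A@x[] <- 1  # duplicate edge entries collapse to unit weights
  deg <- Matrix::rowSums(A)
  v <- pial$vertices
  for (it in seq_len(iters)) {
    lap <- as.matrix(A %*% v) / deg - v
    v <- v + lambda * lap
    lap <- as.matrix(A %*% v) / deg - v
    v <- v + mu * lap
  }
  out <- pial
  out$vertices <- v
  out
}

#' Neighbour topology of a surface array
#'
#' 4-neighbourhood over the rows x cols layout for grids, the consecutive
#' chain for strips and depths.
#'
#' @param electrode an [electrode()].
#' @return m x 2 integer matrix of contact index pairs.
#' @export
grid_edges <- function(electrode) {
  n <- n_contacts(electrode)
  if (electrode$kind == "grid") {
    shape <- electrode$grid_shape
    if (is.null(shape) || prod(shape) != n)
      stop("grid_shape inconsistent with contact count")
    rows <- shape[1]; cols <- shape[2]
    at <- function(r, c) (r - 1L) * cols + c  # row-major, as make_grid
    e <- list()
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      if (c < cols) e[[length(e) + 1L]] <- c(at(r, c), at(r, c + 1L))
      if (r < rows) e[[length(e) + 1L]] <- c(at(r, c), at(r + 1L, c))
    }
    do.call(rbind, e)
  } else {
    if (n < 2) return(matrix(integer(0), 0, 2))
    cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  }
}

snap_energy <- function(x, x0, edges, d0, lambda) {
  e <- sum((x - x0)^2)
  if (nrow(edges)) {
    dl <- sqrt(rowSums((x[edges[, 1], , drop = FALSE] -
                        x[edges[, 2], , drop = FALSE])^2))
    e <- e + lambda * sum((dl - d0)^2)
  }
  e
}

#' Snap a grid or strip onto the cortical surface
#'
#' Corrects brain-shift displacement by minimizing
#' \deqn{E(x) = \sum_i \|x_i - x_i^0\|^2 +
#'   \lambda \sum_{(i,j)} (\|x_i - x_j\| - d_{ij}^0)^2}
#' subject to every contact lying on the target surface. The solver starts
#' from the naive per-contact nearest-point projection and alternates a
#' damped Gauss-Seidel sweep on the unconstrained energy (fixed sweep order
#' = contact order) with re-projection of each contact onto its nearest
#' surface point; a sweep that fails to decrease the energy is rolled back
#' at half damping, so the energy trace is non-increasing and the result
#' never scores worse than the naive projection. Fully deterministic.
#'
#' @param electrode a grid or strip [electrode()] (depths are rejected;
#'   snapping corrects surface arrays only).
#' @param surface watertight target [surface_mesh()], typically from
#'   [smooth_target_surface()].
#' @param params a [snap_params()].
#' @return `snap_result`: `coordinates` (n x 3 on the surface),
#'   `displacement` per contact (mm from the input positions),
#'   `edge_distortion` (relative length change per edge), `energy_trace`
#'   (energy after each sweep, element 1 = naive projection), `energy`,
#'   `naive_energy`, `iterations`, `converged`.
#' @export
snap_to_surface <- function(electrode, surface, params = snap_params()) {
  if (!electrode$kind %in% c("grid", "strip"))
    stop("snapping applies to grid/strip electrodes, not ", electrode$kind)
  if (!is_watertight(surface)) stop("snapping target must be watertight")
  x0 <- electrode$positions
  n <- nrow(x0)
  edges <- grid_edges(electrode)
  d0 <- if (nrow(edges)) sqrt(rowSums((x0[edges[, 1], , drop = FALSE] -
                                       x0[edges[, 2], , drop = FALSE])^2))
        else numeric(0)
  lambda <- params$lambda_deform
  # neighbour lists
  nbr <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    nbr[[a]] <- rbind(nbr[[a]], c(b, d0[k]))
    nbr[[b]] <- rbind(nbr[[b]], c(a, d0[k]))
  }
  x <- project_to_surface(x0, surface)$points
  E <- snap_energy(x, x0, edges, d0, lambda)
  naive_energy <- E
  trace <- numeric(0)
  eta <- 1.0
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    improved <- FALSE
    while (eta > 1e-6) {
      xn <- x
      for (i in seq_len(n)) {
        nb <- nbr[[i]]
        if (is.null(nb)) {
          tgt <- x0[i, ]
        } else {
          diffs <- -sweep(xn[nb[, 1], , drop = FALSE], 2, xn[i, ], "-")
          len <- sqrt(rowSums(diffs^2))
          u <- diffs / pmax(len, 1e-12)
          # local stationary point of the unconstrained energy at contact i
          tgt <- (x0[i, ] + lambda * colSums(xn[nb[, 1], , drop = FALSE] +
                                             u * nb[, 2])) /
                 (1 + lambda * nrow(nb))
        }
        xi <- (1 - eta) * xn[i, ] + eta * tgt
        xn[i, ] <- project_to_surface(matrix(xi, 1), surface)$points
      }
      En <- snap_energy(xn, x0, edges, d0, lambda)
      if (En <= E + 1e-12) {
        improved <- E - En > params$tol
        x <- xn
        E <- En
        break
      }
      eta <- eta / 2  # rollback: retry the sweep with smaller steps
    }
    trace <- c(trace, E)
    if (!improved) { converged <- TRUE; break }
  }
  dl <- if (nrow(edges)) sqrt(rowSums((x[edges[, 1], , drop = FALSE] -
                                       x[edges[, 2], , drop = FALSE])^2))
        else numeric(0)
  structure(list(
    coordinates = x,
    displacement = sqrt(rowSums((x - x0)^2)),
    edge_distortion = if (length(d0)) (dl - d0) / d0 else numeric(0),
    energy_trace = trace,
    energy = E,
    naive_energy = naive_energy,
    iterations = length(trace),
    converged = converged), class = "snap_result")
}

#' @export
print.snap_result <- function(x, ...) {
  cat(sprintf(paste0("<snap_result> %d iterations, energy %.4g ",
                     "(naive %.4g), max displacement %.2f mm\n"),
              x$iterations, x$energy, x$naive_energy,
              max(x$displacement)))
  invisible(x)
}
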