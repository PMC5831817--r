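#' Parameters for the force-directed map layout
#'
#' Attraction acts along each edge with magnitude
#' `attraction_scale * (weight / max_weight) * distance` (weights are
#' normalised by the map's maximum so layout behaviour is cutoff-independent
#' in scale); every node pair repels with magnitude
#' `repulsion_scale / distance^2`. Positions move by `step_size` times the
#' net force, and the step size is multiplied by `cooling` each iteration.
#' Relaxation stops when the mean per-iteration displacement falls below
#' `convergence_tol` or after `max_iter` iterations.
#'
#' @param attraction_scale,repulsion_scale positive force scales.
#' @param step_size positive initial step.
#' @param cooling multiplicative step decay in (0, 1).
#' @param max_iter iteration cap.
#' @param convergence_tol mean-displacement stopping tolerance.
#' @return A `layout_params` list.
#' @export
layout_params <- function(attraction_scale = 1, repulsion_scale = 0.05,
                          step_size = 0.05, cooling = 0.97,
                          max_iter = 500, convergence_tol = 1e-4) {
  stopifnot(attraction_scale > 0, repulsion_scale > 0, step_size > 0,
            cooling > 0, cooling < 1, max_iter >= 1, convergence_tol > 0)
  structure(list(attraction_scale = attraction_scale,
                 repulsion_scale = repulsion_scale, step_size = step_size,
                 cooling = cooling, max_iter = max_iter,
                 convergence_tol = convergence_tol),
            class = "layout_params")
}

#' Force-directed relaxation of a similarity graph
#'
#' Iterative spring-embedder over the graph's weighted edges, started from
#' uniform-random coordinates in the unit cube. Fully deterministic given
#' `seed`: reruns with the same graph, parameters, dimensionality and seed
#' give bitwise-identical coordinates. Coincident points are separated by a
#' small deterministic jitter drawn from the same RNG stream rather than
#' producing non-finite forces.
#'
#' @param graph `similarity_graph` with >= 1 node.
#' @param params `layout_params`.
#' @param dims 2 or 3.
#' @param seed RNG seed.
#' @return A `layout_state`: list with `dims`, `coords` (matrix with seq_id
#'   rownames), `rng_seed`, `iterations_run`, `converged`.
#' @export
layout_graph <- function(graph, params = layout_params(), dims = 2, seed = 1) {
  stopifnot(dims %in% c(2, 3), nrow(graph$nodes) >= 1)
  ids <- graph$nodes$seq_id
  n <- length(ids)
  with_local_seed(seed, {
    coords <- matrix(runif(n * dims), n, dims, dimnames = list(ids, NULL))
    edges <- graph$edges
    max_w <- if (nrow(edges) && max(edges$weight) > 0) max(edges$weight) else 1
    ei <- match(edges$id_a, ids)
    ej <- match(edges$id_b, ids)
    ew <- params$attraction_scale * edges$weight / max_w
    step <- params$step_size
    iter <- 0L
    converged <- n == 1
    while (iter < params$max_iter && !converged) {
      iter <- iter + 1L
      # pairwise displacements and distances
      d2 <- as.matrix(stats::dist(coords))^2
      close <- which(d2 < 1e-18 & upper.tri(d2), arr.ind = TRUE)
      if (nrow(close)) {
        jitter_nodes <- unique(close[, 1])
        coords[jitter_nodes, ] <- coords[jitter_nodes, , drop = FALSE] +
          matrix(runif(length(jitter_nodes) * dims, -1e-6, 1e-6),
                 ncol = dims)
        d2 <- as.matrix(stats::dist(coords))^2
      }
      force <- matrix(0, n, dims)
      # repulsion: magnitude r/d^2 along (xi - xj)/d  => r * (xi - xj) / d^3
      inv_d3 <- 1 / (d2 * sqrt(d2))
      diag(inv_d3) <- 0
      for (k in seq_len(dims)) {
        diff_k <- outer(coords[, k], coords[, k], "-")
        force[, k] <- force[, k] +
          params$repulsion_scale * rowSums(diff_k * inv_d3)
      }
      # attraction: magnitude a*(w/maxw)*d along (xj - xi)/d => a*(w/maxw)*(xj - xi)
      if (length(ei)) {
        for (k in seq_len(dims)) {
          pull <- ew * (coords[ej, k] - coords[ei, k])
          force[, k] <- force[, k] +
            tapply_sum(pull, ei, n) - tapply_sum(pull, ej, n)
        }
      }
      delta <- step * force
      coords <- coords + delta
      step <- step * params$cooling
      mean_disp <- mean(sqrt(rowSums(delta^2)))
      converged <- mean_disp < params$convergence_tol
    }
    structure(list(dims = dims, coords = coords, rng_seed = seed,
                   iterations_run = iter, converged = converged),
              class = "layout_state")
  })
}

tapply_sum <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Per-group mean distance from the map centre
#'
#' The centroid is the mean of all node coordinates; each group's statistic
#' is the mean Euclidean distance of its members to that centroid. Groups are
#' ranked descending (rank 1 = most distant = most divergent in sequence).
#' Requested groups with no members are omitted with a warning.
#'
#' @param layout `layout_state`.
#' @param groups named character vector mapping seq_id -> group name (nodes
#'   missing from `groups` or mapped to `NA`/`"OTHER"` are ignored).
#' @return data.frame with `group`, `mean_center_distance`, `rank`, ordered
#'   by decreasing distance.
#' @export
center_distance <- function(layout, groups) {
  coords <- layout$coords
  centroid <- colMeans(coords)
  ids <- rownames(coords)
  grp <- groups[ids]
  keep <- !is.na(grp) & grp != "OTHER"
  requested <- setdiff(unique(groups), c(NA, "OTHER"))
  lost <- setdiff(requested, unique(grp[keep]))
  if (length(lost)) {
    warning("group(s) with no members in the layout omitted: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  d <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  means <- tapply(d[keep], grp[keep], mean)
  out <- data.frame(group = names(means),
                    mean_center_distance = as.numeric(means))
  out <- out[order(-out$mean_center_distance, out$group), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write the center-distance report as TSV
#' @param cd data.frame from [center_distance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_center_distance_tsv <- function(cd, path) {
  cd$mean_center_distance <- sprintf("%.17g", cd$mean_center_distance)
  write.table(cd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
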