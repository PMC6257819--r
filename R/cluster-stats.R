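#' Cluster-based permutation test over frequency-by-time maps
#'
#' Group-level inference on per-subject decoding-accuracy maps against
#' chance. A one-sample t-value is computed per (frequency, time) cell;
#' cells with `t > t_threshold` (default 2.0) are grouped into clusters by
#' 4-neighborhood adjacency in the frequency-by-time grid (no diagonals),
#' and each cluster's mass is the sum of its t-values. The null
#' distribution of the maximum cluster mass is built by randomly
#' sign-flipping each subject's deviation map (map minus chance) -- the
#' one-sample permutation scheme that label shuffling reduces to for
#' accuracy-versus-chance tests -- and each observed cluster's p-value is
#' the proportion of permutation maxima at least as large, with the +1
#' correction, one-sided (greater).
#'
#' @param subject_maps list of per-subject freqs x times accuracy matrices
#'   (identical dimensions), or a 3-d array subjects x freqs x times.
#' @param chance chance accuracy subtracted from every map.
#' @param t_threshold cluster entry threshold on the t-value.
#' @param n_permutations Monte-Carlo permutations (default 1000; a warning
#'   is issued below 100).
#' @param seed integer seed.
#' @return a `cluster_result`: list with `t_map`, `clusters` (list of
#'   `mask`, `mass`, `p`), `max_mass_null`, `t_threshold`,
#'   `n_permutations`.
#' @export
cluster_permutation <- function(subject_maps, chance = 1 / 3,
                                t_threshold = 2.0, n_permutations = 1000,
                                seed = 1L) {
  if (is.list(subject_maps)) {
    dims <- unique(lapply(subject_maps, dim))
    if (length(dims) != 1L) stop("subject maps have heterogeneous axes", call. = FALSE)
    arr <- aperm(simplify2array(subject_maps), c(3, 1, 2))
  } else {
    arr <- subject_maps
  }
  n_sub <- dim(arr)[1]
  if (n_sub < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (n_permutations < 100) {
    warning("fewer than 100 permutations: p-values will be coarse", call. = FALSE)
  }
  nf <- dim(arr)[2]; nt <- dim(arr)[3]
  dev <- matrix(arr - chance, nrow = n_sub)  # subjects x cells
  ssq <- colSums(dev^2)

  t_of_means <- function(m) {
    v <- (ssq - n_sub * m^2) / (n_sub - 1)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n_sub)
  }
  t_obs <- t_of_means(colMeans(dev))
  t_map <- matrix(t_obs, nf, nt)

  comp <- connected_components(t_map > t_threshold)
  masses <- vapply(seq_len(comp$n), function(i) sum(t_map[comp$labels == i]),
                   numeric(1))

  local_rng(seed)
  max_null <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    tp <- matrix(t_of_means(colMeans(dev * flips)), nf, nt)
    cp <- connected_components(tp > t_threshold)
    max_null[p] <- if (cp$n == 0L) 0 else {
      max(vapply(seq_len(cp$n), function(i) sum(tp[cp$labels == i]), numeric(1)))
    }
  }

  clusters <- lapply(seq_len(comp$n), function(i) {
    list(mask = comp$labels == i, mass = masses[i],
         p = (sum(max_null >= masses[i]) + 1) / (n_permutations + 1))
  })
  ord <- order(vapply(clusters, `[[`, numeric(1), "mass"), decreasing = TRUE)
  structure(list(t_map = t_map, clusters = clusters[ord],
                 max_mass_null = max_null, t_threshold = t_threshold,
                 n_permutations = n_permutations, chance = chance),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d cluster(s), t > %.2f, %d permutations>\n",
              length(x$clusters), x$t_threshold, x$n_permutations))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d cells, mass %.2f, p = %.4f\n",
                i, sum(cl$mask), cl$mass, cl$p))
  }
  invisible(x)
}

#' Label connected components of a logical matrix (4-connectivity)
#'
#' Flood-fill labeling of TRUE cells, treating cells as adjacent when they
#' share an edge along the row (frequency) or column (time) dimension;
#' diagonal neighbors are not adjacent.
#'
#' @param mask logical matrix.
#' @return list with `labels` (integer matrix, 0 = background) and `n`
#'   (number of components).
#' @export
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  n <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    n <- n + 1L
    stack <- start
    labels[start] <- n
    while (length(stack)) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (cell - 1L) %% nr + 1L
      cl <- (cell - 1L) %/% nr + 1L
      nbr <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
               if (cl > 1L) cell - nr, if (cl < nc) cell + nr)
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      labels[nbr] <- n
      stack <- c(stack, nbr)
    }
  }
  list(labels = labels, n = n)
}

#' Jaccard overlap between a cluster mask and a reference mask
#'
#' @param mask,reference logical matrices of equal dimension.
#' @return intersection over union (0 when both are empty).
#' @export
mask_jaccard <- function(mask, reference) {
  u <- sum(mask | reference)
  if (u == 0) return(0)
  sum(mask & reference) / u
}
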