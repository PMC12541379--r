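# 2D atlas of proteome vectors for visualization only. The projection is a
# seeded force-directed layout of the symmetrized k-nearest-neighbour graph:
# `n_neighbors` sets the neighbourhood graph and `min_dist` the enforced
# minimum separation between distinct points after rescaling. Coordinates
# are never fed back into clustering or distance computation.

#' Project vectors to 2D atlas coordinates
#'
#' @param vectors Numeric matrix (n x d) with accession rownames;
#'   `n > n_neighbors` required.
#' @param n_neighbors Neighbourhood size of the kNN graph.
#' @param min_dist Minimum separation between distinct projected points
#'   (coordinates are rescaled so the smallest nonzero pairwise 2D distance
#'   equals it).
#' @param seed Seed making the layout deterministic.
#' @return A `phage_atlas` tibble with `accession`, `x`, `y`; parameters in
#'   the `parameters` attribute.
#' @export
atlas_project <- function(vectors, n_neighbors = 16L, min_dist = 0.6, seed = 1L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n <= n_neighbors) {
    abort(sprintf("need more points (%d) than n_neighbors (%d)", n, n_neighbors),
          class = "phagempr_input_error")
  }
  if (is.null(rownames(vectors))) rownames(vectors) <- sprintf("g%04d", seq_len(n))
  D <- as.matrix(dist(vectors))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(n_neighbors + 1L)]
    cbind(i, nb, D[i, nb])
  }))
  # symmetrize: keep each undirected edge once
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  key <- paste(a, b)
  first <- !duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(a[first], b[first]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  w <- 1 / (edges[first, 3] + 1e-12)
  coords <- withr_seed(seed, igraph::layout_with_fr(g, weights = w, niter = 500L))
  # enforce the minimum separation between distinct points
  d2 <- dist(coords)
  pos <- d2[d2 > 0]
  if (length(pos) > 0L) coords <- coords * (min_dist / min(pos))
  out <- tibble(accession = rownames(vectors),
                x = coords[, 1], y = coords[, 2])
  attr(out, "parameters") <- list(n_neighbors = as.integer(n_neighbors),
                                  min_dist = min_dist, seed = seed,
                                  method = "knn-force-layout",
                                  visualization_only = TRUE)
  class(out) <- c("phage_atlas", class(out))
  out
}

#' Plot methods for result objects
#'
#' `autoplot.phage_atlas` draws the 2D atlas (optionally coloured by an
#' annotation rank), `autoplot.ami_profile` the AMI-vs-eps curve, and
#' `autoplot.threshold_report` the within/between distance histograms with
#' the chosen threshold.
#'
#' @param object A result object.
#' @param annotations Optional annotation tibble for colouring the atlas.
#' @param rank Rank column used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot phage_atlas
#' @export
autoplot.phage_atlas <- function(object, annotations = NULL, rank = "genus", ...) {
  df <- as_tibble(object)
  if (!is.null(annotations)) {
    df <- left_join(df, annotations[, c("accession", rank)], by = "accession")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data[[rank]]))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::labs(x = "atlas-1", y = "atlas-2") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot ami_profile
#' @export
autoplot.ami_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$eps, .data$ami)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "eps (flat-cut distance threshold)",
                  y = sprintf("AMI vs %s", attr(object, "rank") %||% "labels")) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot threshold_report
#' @export
autoplot.threshold_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$distance, fill = .data$pair_type)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 60) +
    ggplot2::geom_vline(xintercept = object$best_threshold, linetype = 2) +
    ggplot2::labs(x = "pairwise MPR distance", fill = NULL) +
    ggplot2::theme_minimal()
}
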