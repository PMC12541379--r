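# Placement of new proteomes against a precomputed MPR store: embed ->
# average -> exact nearest-neighbour search -> unclassified gate ->
# re-cluster the neighbourhood together with the query and return the
# condensed subtree. Neighbours' annotations are reported, never asserted
# as the query's taxonomy.

#' Exact nearest neighbours of a query MPR in a vector store
#'
#' @param query_mpr Numeric d-vector.
#' @param store A `vector_store` (or a bare matrix with accession rownames).
#' @param k Number of neighbours; if `k` exceeds the store size the list is
#'   truncated with a warning.
#' @return Tibble with `accession` and `distance`, ascending by distance,
#'   ties broken lexicographically by accession.
#' @export
nearest_neighbours <- function(query_mpr, store, k = 50L) {
  mat <- store_matrix(store)
  if (nrow(mat) == 0L) abort("empty store", class = "phagempr_input_error")
  if (k < 1L) abort("k must be >= 1", class = "phagempr_input_error")
  query_mpr <- as.numeric(query_mpr)
  if (length(query_mpr) != ncol(mat)) {
    abort("store/query dimension mismatch", class = "phagempr_input_error")
  }
  if (k > nrow(mat)) {
    warn(sprintf("k = %d exceeds store size %d; truncating", k, nrow(mat)))
    k <- nrow(mat)
  }
  d <- sqrt(rowSums(sweep(mat, 2L, query_mpr)^2))
  ord <- order(d, rownames(mat))[seq_len(k)]
  tibble(accession = rownames(mat)[ord], distance = unname(d[ord]))
}

store_matrix <- function(store) {
  if (inherits(store, "vector_store")) return(store$matrix)
  mat <- as.matrix(store)
  if (is.null(rownames(mat))) abort("store matrix needs accession rownames")
  mat
}

#' Place a query proteome against a precomputed MPR store
#'
#' Builds the query MPR (from protein records via `backend`, or from a
#' supplied vector), retrieves the `k` exact nearest neighbours, and gates
#' on the nearest distance: above `threshold` the query is deemed
#' unclassified; otherwise the neighbourhood plus the query is re-clustered
#' ([build_hierarchy()]) and the condensed subtree returned with the query
#' as one of its leaves. `threshold` has no default on purpose — calibrate
#' it from [threshold_analysis()].
#'
#' @param records Tibble of protein records (`protein_id`, `sequence`), or
#'   `NULL` when `query_vector` is given.
#' @param store A `vector_store` (or matrix with accession rownames).
#' @param threshold Unclassified gate on the nearest-neighbour distance.
#' @param k Neighbourhood size.
#' @param backend Embedding backend for `records`.
#' @param annotations Optional annotation tibble joined onto the neighbour
#'   list.
#' @param query_accession Leaf name used for the query.
#' @param query_vector Optional precomputed query MPR (skips embedding).
#' @return A `phage_query` list: `query_accession`, `neighbours` (tibble,
#'   ascending distance, annotation columns joined when available),
#'   `status` (`"placed"` or `"unclassified"`), `subtree`
#'   (a `phage_hierarchy` over neighbourhood plus query when placed, else
#'   `NULL`), `parameters`.
#' @export
place_query <- function(records = NULL, store, threshold, k = 50L,
                        backend = NULL, annotations = NULL,
                        query_accession = "query", query_vector = NULL) {
  assert_scalar_number(threshold, "threshold")
  mat <- store_matrix(store)
  if (is.null(query_vector)) {
    if (is.null(records) || nrow(records) == 0L) {
      abort("empty proteome", class = "phagempr_input_error")
    }
    if (is.null(backend)) abort("backend required to embed records",
                                class = "phagempr_config_error")
    reps <- embed_proteome(records, backend)
    query_vector <- compute_mpr(reps)
  }
  query_vector <- as.numeric(query_vector)
  if (length(query_vector) != ncol(mat)) {
    abort("store/backend dimension mismatch", class = "phagempr_input_error")
  }
  nn <- nearest_neighbours(query_vector, mat, k = k)
  if (!is.null(annotations)) {
    nn <- left_join(nn, annotations, by = "accession")
  }
  placed <- nn$distance[1] <= threshold
  subtree <- NULL
  if (placed) {
    sub <- rbind(mat[nn$accession, , drop = FALSE],
                 matrix(query_vector, 1L, dimnames = list(query_accession)))
    subtree <- build_hierarchy(pairwise_distances(sub))
  }
  structure(list(
    query_accession = query_accession,
    neighbours = nn,
    status = if (placed) "placed" else "unclassified",
    subtree = subtree,
    parameters = list(k = as.integer(k), unclassified_threshold = threshold)
  ), class = "phage_query")
}

#' @export
print.phage_query <- function(x, ...) {
  cat(sprintf("<phage_query> '%s': %s (nearest %.4g, k = %d)\n",
              x$query_accession, x$status, x$neighbours$distance[1],
              x$parameters$k))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy phage_query
#' @export
tidy.phage_query <- function(x, ...) x$neighbours

#' @rdname tidiers
#' @method glance phage_query
#' @export
glance.phage_query <- function(x, ...) {
  tibble(query_accession = x$query_accession, status = x$status,
         nearest_distance = x$neighbours$distance[1],
         k = x$parameters$k,
         unclassified_threshold = x$parameters$unclassified_threshold)
}
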