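# Synthetic embedding-space datasets with the statistical structure the
# method assumes: protein families are angular (von Mises-Fisher) clusters
# around unit directions, proteomes are bags of family draws, and a nested
# genus < subfamily < family taxonomy is realized by hierarchical sharing of
# disjoint protein-family pools. The generator enters at the embedding layer;
# no amino-acid sequences are simulated.

#' Describe a nested synthetic taxonomy design
#'
#' Composition rules: each protein of a genome is drawn from the genus core
#' pool with probability `shared_genus - shared_subfamily`, the subfamily
#' core pool with probability `shared_subfamily - shared_family`, the family
#' core pool with probability `shared_family`, and otherwise from the global
#' remainder of the K-family pool. Pools at different taxa are disjoint, so
#' the expected composition fraction shared by two genomes is `shared_genus`
#' within a genus, `shared_subfamily` within a subfamily (across genera) and
#' `shared_family` within a family (across subfamilies).
#'
#' @param n_families Number of taxonomic families.
#' @param n_subfamilies_per_family,n_genera_per_subfamily,n_genomes_per_genus
#'   Nested taxon counts.
#' @param d Embedding dimension.
#' @param K Protein-family pool size.
#' @param kappa von Mises-Fisher concentration of every protein family.
#' @param m_range Proteome-size range (inclusive) sampled uniformly.
#' @param shared Numeric length-3 vector `(genus, subfamily, family)` of
#'   descending shared-composition fractions, each in `[0, 1]`.
#' @param pool_sizes Core pool sizes `(genus, subfamily, family)` drawn per
#'   taxon from K.
#' @param orthogonal Use exactly orthogonal family directions (requires
#'   `K <= d`); default draws uniform random directions.
#' @param seed Seed; the whole dataset is a deterministic function of the
#'   design.
#' @return A `taxonomy_design` list.
#' @export
taxonomy_design <- function(n_families = 3L, n_subfamilies_per_family = 2L,
                            n_genera_per_subfamily = 3L, n_genomes_per_genus = 8L,
                            d = 64L, K = 200L, kappa = 50,
                            m_range = c(60L, 100L),
                            shared = c(genus = 0.90, subfamily = 0.60, family = 0.30),
                            pool_sizes = c(genus = 2L, subfamily = 3L, family = 4L),
                            orthogonal = FALSE, seed = 11L) {
  shared <- unname(as.numeric(shared))
  if (length(shared) != 3L || any(shared < 0) || any(shared > 1)) {
    abort("shared must be three fractions in [0, 1]", class = "phagempr_input_error")
  }
  if (shared[1] < shared[2] || shared[2] < shared[3]) {
    abort("shared fractions must be descending: genus >= subfamily >= family",
          class = "phagempr_input_error")
  }
  counts <- c(n_families, n_subfamilies_per_family, n_genera_per_subfamily,
              n_genomes_per_genus)
  if (any(counts < 1L)) abort("all taxon counts must be >= 1",
                              class = "phagempr_input_error")
  n_genera <- n_families * n_subfamilies_per_family * n_genera_per_subfamily
  n_subfam <- n_families * n_subfamilies_per_family
  need <- n_genera * pool_sizes[[1]] + n_subfam * pool_sizes[[2]] +
    n_families * pool_sizes[[3]]
  if (need > K) {
    abort(sprintf("infeasible design: disjoint core pools need %d protein families but K = %d",
                  need, K), class = "phagempr_input_error")
  }
  structure(list(
    n_families = as.integer(n_families),
    n_subfamilies_per_family = as.integer(n_subfamilies_per_family),
    n_genera_per_subfamily = as.integer(n_genera_per_subfamily),
    n_genomes_per_genus = as.integer(n_genomes_per_genus),
    d = as.integer(d), K = as.integer(K), kappa = as.numeric(kappa),
    m_range = as.integer(m_range), shared = shared,
    pool_sizes = as.integer(pool_sizes), orthogonal = isTRUE(orthogonal),
    seed = as.integer(seed)
  ), class = "taxonomy_design")
}

#' Generate a synthetic embedding dataset from a taxonomy design
#'
#' Deterministic given the design (including its seed): family directions
#' are drawn once, each genome receives a fixed family assignment per the
#' composition rules, and its protein embeddings are von Mises-Fisher draws
#' around the assigned directions.
#'
#' @param design A [taxonomy_design()].
#' @param annotation_noise Fraction of genomes whose genus/subfamily/family
#'   annotation is scrambled to a different taxon (ground truth is kept in
#'   the `truth` element).
#' @return A `synthetic_dataset` list: `model` ([family_model()]),
#'   `assignments` (named list of per-genome family index vectors),
#'   `representations` (named list of per-genome unit embedding matrices),
#'   `mpr` (n x d MPR matrix), `annotations` and `truth` (tibbles with
#'   accession + rank columns), `design`.
#' @export
generate_dataset <- function(design, annotation_noise = 0) {
  stopifnot(inherits(design, "taxonomy_design"))
  withr_seed(design$seed, {
    mu <- random_directions(design$K, design$d, orthogonal = design$orthogonal)
    model <- family_model(mu, kappa = rep(design$kappa, design$K))

    # disjoint core pools per taxon, carved from 1..K in order; the remainder
    # is the global pool
    taxa <- expand.grid(
      genus_i = seq_len(design$n_genera_per_subfamily),
      subfam_i = seq_len(design$n_subfamilies_per_family),
      family_i = seq_len(design$n_families)
    )
    taxa$family <- sprintf("F%02d", taxa$family_i)
    taxa$subfamily <- sprintf("F%02d_S%02d", taxa$family_i, taxa$subfam_i)
    taxa$genus <- sprintf("F%02d_S%02d_G%02d", taxa$family_i, taxa$subfam_i, taxa$genus_i)
    ps <- design$pool_sizes
    nxt <- 1L
    take <- function(k) {
      ids <- seq.int(nxt, length.out = k)
      nxt <<- nxt + k
      ids
    }
    family_pool <- lapply(unique(taxa$family), function(f) take(ps[3]))
    names(family_pool) <- unique(taxa$family)
    subfam_pool <- lapply(unique(taxa$subfamily), function(s) take(ps[2]))
    names(subfam_pool) <- unique(taxa$subfamily)
    genus_pool <- lapply(taxa$genus, function(g) take(ps[1]))
    names(genus_pool) <- taxa$genus
    global_pool <- seq.int(nxt, design$K)

    p_genus <- design$shared[1] - design$shared[2]
    p_subfam <- design$shared[2] - design$shared[3]
    p_family <- design$shared[3]
    p_global <- 1 - design$shared[1]

    genomes <- taxa[rep(seq_len(nrow(taxa)), each = design$n_genomes_per_genus), ]
    genomes$accession <- sprintf("SYN%05d", seq_len(nrow(genomes)))

    assignments <- vector("list", nrow(genomes))
    representations <- vector("list", nrow(genomes))
    for (i in seq_len(nrow(genomes))) {
      m <- if (design$m_range[1] == design$m_range[2]) design$m_range[1] else
        sample(seq(design$m_range[1], design$m_range[2]), 1L)
      src <- sample.int(4L, m, replace = TRUE,
                        prob = c(p_genus, p_subfam, p_family, p_global))
      pools <- list(genus_pool[[genomes$genus[i]]],
                    subfam_pool[[genomes$subfamily[i]]],
                    family_pool[[genomes$family[i]]],
                    global_pool)
      fam <- integer(m)
      for (s in 1:4) {
        idx <- src == s
        if (any(idx)) fam[idx] <- resample(pools[[s]], sum(idx))
      }
      assignments[[i]] <- fam
      reps <- matrix(0, m, design$d)
      for (k in unique(fam)) {
        sel <- fam == k
        reps[sel, ] <- sample_vmf(model$mu[k, ], design$kappa, sum(sel))
      }
      rownames(reps) <- sprintf("%s_%05d", genomes$accession[i], seq_len(m))
      representations[[i]] <- reps
    }
    names(assignments) <- genomes$accession
    names(representations) <- genomes$accession

    truth <- tibble(
      accession = genomes$accession,
      realm = "SynReal01", kingdom = "SynKing01", class = "SynClass01",
      family = genomes$family, subfamily = genomes$subfamily,
      genus = genomes$genus
    )
    annotations <- truth
    if (annotation_noise > 0) {
      n_noise <- round(annotation_noise * nrow(annotations))
      if (n_noise > 0L) {
        pick <- sample.int(nrow(annotations), n_noise)
        for (j in pick) {
          other <- sample(setdiff(seq_len(nrow(taxa)), match(truth$genus[j], taxa$genus)), 1L)
          annotations$family[j] <- taxa$family[other]
          annotations$subfamily[j] <- taxa$subfamily[other]
          annotations$genus[j] <- taxa$genus[other]
        }
      }
    }

    mpr <- mpr_matrix(representations)
    structure(list(model = model, assignments = assignments,
                   representations = representations, mpr = mpr,
                   annotations = annotations, truth = truth, design = design),
              class = "synthetic_dataset")
  })
}

# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genomes, d = %d, K = %d protein families\n",
              nrow(x$mpr), x$design$d, x$design$K))
  invisible(x)
}
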