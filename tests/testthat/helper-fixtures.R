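# Fixture builders shared across tests; everything is generated in code.

write_fasta <- function(records, path = tempfile(fileext = ".faa")) {
  lines <- unlist(lapply(seq_along(records), function(i) {
    c(paste0(">", names(records)[i]), records[[i]])
  }))
  writeLines(lines, path)
  path
}

# A small nested design that runs in well under a second.
small_design <- function(seed = 11L, ...) {
  taxonomy_design(
    n_families = 2L, n_subfamilies_per_family = 2L, n_genera_per_subfamily = 2L,
    n_genomes_per_genus = 4L, d = 32L, K = 80L, kappa = 50,
    m_range = c(30L, 50L), seed = seed, ...
  )
}

# Maximally separated design: each genus draws all proteins from its own
# single signature family with near-deterministic embeddings.
separable_design <- function(seed = 11L, n_genomes_per_genus = 4L) {
  taxonomy_design(
    n_families = 2L, n_subfamilies_per_family = 1L, n_genera_per_subfamily = 3L,
    n_genomes_per_genus = n_genomes_per_genus, d = 32L, K = 32L, kappa = 1000,
    m_range = c(20L, 30L), shared = c(1, 0, 0),
    pool_sizes = c(1L, 1L, 1L), orthogonal = TRUE, seed = seed
  )
}

# Each family's genomes all draw from the family's own two signature
# protein families with near-deterministic embeddings: families are tight,
# well-separated clades (genera carry no extra signal here).
family_separable_design <- function(seed = 11L) {
  taxonomy_design(
    n_families = 2L, n_subfamilies_per_family = 1L, n_genera_per_subfamily = 3L,
    n_genomes_per_genus = 4L, d = 32L, K = 32L, kappa = 1000,
    m_range = c(20L, 30L), shared = c(1, 1, 1),
    pool_sizes = c(1L, 1L, 2L), orthogonal = TRUE, seed = seed
  )
}

# Two tight pairs far apart: within-pair distance 1, between 100.
two_pair_distances <- function() {
  D <- matrix(100, 4, 4,
              dimnames = list(c("a1", "a2", "b1", "b2"), c("a1", "a2", "b1", "b2")))
  D["a1", "a2"] <- D["a2", "a1"] <- 1
  D["b1", "b2"] <- D["b2", "b1"] <- 1
  diag(D) <- 0
  D
}

line_distances <- function(x, names = sprintf("p%d", seq_along(x))) {
  D <- as.matrix(dist(matrix(x, ncol = 1)))
  dimnames(D) <- list(names, names)
  D
}
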