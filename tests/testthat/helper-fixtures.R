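# Small in-code fixtures shared across test files.

toy_table <- function() {
  feature_table(matrix(
    c(5L, 0L, 2L, 7L,
      1L, 3L, 0L, 9L,
      4L, 1L, 1L, 6L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("s1", "s2", "s3"), c("asv1", "asv2", "asv3", "asv4"))))
}

toy_metadata <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    individual_id = c("i1", "i1", "i2", "i2"),
    habitat = c("saliva", "buccal_mucosa", "saliva", "buccal_mucosa"),
    sex = c("F", "F", "M", "M"),
    age = c(25, 25, 40, 40))
}

toy_taxonomy <- function(features, genus, species = features) {
  tibble::tibble(
    feature_id = features,
    kingdom = "Bacteria", phylum = "Firmicutes", class = "Bacilli",
    order = "Lactobacillales", family = "Streptococcaceae",
    genus = genus, species = species)
}

# a small paired study used by several files (cached per test run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prof <- default_profiles(n_tail = 120)
      cache <<- c(generate_paired_study(
        simulation_config(n_individuals = 15, seed = 99,
                          depth_range = c(8000L, 12000L)),
        prof$saliva, prof$mucosa), list(profiles = prof))
    }
    cache
  }
})

brute_shannon <- function(x, base = 2) {
  p <- x / sum(x)
  acc <- 0
  for (pi in p) if (pi > 0) acc <- acc - pi * log(pi, base = base)
  acc
}

brute_chao1 <- function(x) {
  f1 <- 0; f2 <- 0; s <- 0
  for (xi in x) {
    if (xi > 0) s <- s + 1
    if (xi == 1) f1 <- f1 + 1
    if (xi == 2) f2 <- f2 + 1
  }
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

brute_simpson <- function(x) {
  p <- x / sum(x)
  acc <- 1
  for (pi in p) acc <- acc - pi^2
  acc
}

# all length-k non-negative integer vectors summing to total
all_compositions <- function(k, total) {
  if (k == 1) return(matrix(total, 1, 1))
  out <- list()
  for (first in 0:total) {
    rest <- all_compositions(k - 1, total - first)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

brute_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  if (den == 0) 0 else num / den
}
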