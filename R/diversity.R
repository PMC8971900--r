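#' Alpha-diversity indices for a single count vector
#'
#' `shannon()` is \eqn{-\sum p_i \log_2 p_i} (bits, base configurable);
#' `chao1()` is the bias-corrected estimator
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} with \eqn{F_1, F_2} the
#' singleton and doubleton counts; `simpson()` is the Gini--Simpson index
#' \eqn{1 - \sum p_i^2}.
#'
#' @param counts Non-negative count vector over taxa with positive total.
#' @param base Logarithm base for Shannon (default 2: bits).
#' @return A single numeric value.
#' @export
#' @examples
#' shannon(c(10, 10, 10, 10))  # 2 bits
#' chao1(c(1, 1, 2, 5))        # 4.5
#' simpson(c(1, 1, 2))         # 0.625
shannon <- function(counts, base = 2) {
  p <- check_counts(counts)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @rdname shannon
#' @export
simpson <- function(counts) {
  p <- check_counts(counts)
  1 - sum(p^2)
}

check_counts <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("all-zero count vector", call. = FALSE)
  counts / total
}

#' Per-sample alpha diversity table
#'
#' @param table A feature-table matrix (ideally rarefied to a common depth).
#' @param base Shannon logarithm base.
#' @return A tibble with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `chao1`, `simpson`, and the `depth` each sample sums to.
#' @export
alpha_diversity <- function(table, base = 2) {
  tibble::tibble(
    sample_id = rownames(table),
    richness = as.integer(rowSums(table > 0)),
    shannon = apply(table, 1, shannon, base = base),
    chao1 = apply(table, 1, chao1),
    simpson = apply(table, 1, simpson),
    depth = unname(rowSums(table)))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{D(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; 0 means two
#' samples share the same composition, 1 that they share no taxa.
#'
#' @param rel A relative-abundance (or count) matrix, samples in rows.
#' @return A symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(rel) {
  if (nrow(rel) < 2) stop("need at least 2 samples", call. = FALSE)
  n <- nrow(rel)
  d <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(rel[i, ] - rel[j, ]))
      den <- sum(rel[i, ] + rel[j, ])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
    }
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal NMDS (monotone regression, stress-1) with a classical-scaling
#' start and random restarts, as implemented by \pkg{vegan}. Coordinates are
#' defined only up to rotation and reflection; downstream comparisons should
#' use rotation-invariant quantities (distances between embedded points).
#'
#' @param dm A symmetric dissimilarity matrix.
#' @param dims Embedding dimension.
#' @param seed Integer seed for the random restarts.
#' @param trymax Maximum random restarts.
#' @return A list with `points` (tibble: sample_id and nmds1..nmdsk),
#'   `stress` and `converged`.
#' @export
nmds_ordination <- function(dm, dims = 2, seed = 1L, trymax = 40) {
  dm <- as.matrix(dm)
  if (max(dm) == 0) {
    pts <- matrix(0, nrow(dm), dims)
    return(list(points = tibble::tibble(sample_id = rownames(dm),
                                        as_nmds_cols(pts)),
                stress = 0, converged = TRUE))
  }
  set.seed(seed)
  fit <- suppressWarnings(vegan::metaMDS(stats::as.dist(dm), k = dims,
                                         trymax = trymax, trace = 0))
  list(points = tibble::tibble(sample_id = rownames(dm),
                               as_nmds_cols(fit$points)),
       stress = fit$stress,
       converged = isTRUE(fit$converged))
}

as_nmds_cols <- function(pts) {
  colnames(pts) <- paste0("nmds", seq_len(ncol(pts)))
  tibble::as_tibble(pts)
}

#' Two-group comparison of a per-sample quantity
#'
#' Welch's unequal-variance two-sample t-test of a per-sample value (for
#' example the Shannon index) between the two levels of a metadata factor,
#' reporting each level's mean and standard error (SD / sqrt(n)).
#'
#' @param values Named numeric vector (names are sample ids) or a data frame
#'   with columns `sample_id` and `value`.
#' @param metadata Sample metadata.
#' @param factor Metadata column with exactly two levels (default
#'   `"habitat"`).
#' @return One-row tibble: levels, means, SEs, `statistic`, `p_value`,
#'   `test`.
#' @export
compare_groups <- function(values, metadata, factor = "habitat") {
  metadata <- validate_metadata(metadata)
  v <- as_value_vector(values)
  metadata <- metadata[match(names(v), metadata$sample_id), ]
  g <- metadata[[factor]]
  lev <- unique(g)
  if (length(lev) != 2) stop("factor must have exactly 2 levels", call. = FALSE)
  x <- v[g == lev[1]]
  y <- v[g == lev[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 samples per level", call. = FALSE)
  }
  tt <- stats::t.test(x, y)
  tibble::tibble(
    level1 = lev[1], mean1 = mean(x), se1 = stats::sd(x) / sqrt(length(x)),
    level2 = lev[2], mean2 = mean(y), se2 = stats::sd(y) / sqrt(length(y)),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    test = "Welch two-sample t-test")
}

as_value_vector <- function(values) {
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- values$sample_id
    v
  } else {
    if (is.null(names(values))) stop("values must be named by sample id", call. = FALSE)
    values
  }
}

#' Spearman correlation of a per-sample value with subject age
#'
#' Computed separately within each habitat group, matching how age effects
#' on diversity are usually screened in paired-habitat designs.
#'
#' @param values Named numeric vector or `sample_id`/`value` data frame.
#' @param metadata Sample metadata with an `age` column.
#' @return A tibble with one row per habitat: `habitat`, `rho`, `p_value`,
#'   `n`.
#' @export
spearman_age <- function(values, metadata) {
  metadata <- validate_metadata(metadata)
  if (!"age" %in% names(metadata)) stop("metadata has no age column", call. = FALSE)
  v <- as_value_vector(values)
  metadata <- metadata[match(names(v), metadata$sample_id), ]
  purrr::map_dfr(unique(metadata$habitat), function(h) {
    sel <- metadata$habitat == h
    x <- metadata$age[sel]
    y <- v[sel]
    if (sum(sel) < 3) stop("need >= 3 observations per habitat", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("constant input: Spearman correlation undefined", call. = FALSE)
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    tibble::tibble(habitat = h, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = sum(sel))
  })
}

#' Per-taxon group comparison of relative abundances
#'
#' For the `top_n` taxa by overall mean relative abundance (default 10,
#' the usual scope of a dominant-taxa table), reports each habitat's mean
#' and standard error, a Welch t-test p-value, significance stars
#' (`**` p < 0.01, `***` p < 0.001) and -- as a clearly labelled extension
#' beyond the raw-p convention -- a Benjamini--Hochberg adjusted p column.
#'
#' @param rel A relative-abundance matrix, usually collapsed to phylum or
#'   genus rank.
#' @param metadata Sample metadata.
#' @param top_n Number of top taxa to test (`Inf` for all).
#' @param factor Two-level metadata factor.
#' @return A tibble sorted by overall mean abundance, descending: `taxon`,
#'   per-level mean/SE, `statistic`, `p_value`, `stars`, `p_adj_bh`.
#' @export
differential_abundance <- function(rel, metadata, top_n = 10,
                                   factor = "habitat") {
  metadata <- validate_metadata(metadata)
  overall <- colMeans(rel)
  keep <- names(sort(overall, decreasing = TRUE))
  keep <- utils::head(keep, top_n)
  res <- purrr::map_dfr(keep, function(tax) {
    v <- rel[, tax]
    names(v) <- rownames(rel)
    row <- compare_groups(v, metadata, factor = factor)
    tibble::tibble(taxon = tax, overall_mean = overall[[tax]], row)
  })
  res$stars <- ifelse(res$p_value < 0.001, "***",
                      ifelse(res$p_value < 0.01, "**", "ns"))
  res$p_adj_bh <- stats::p.adjust(res$p_value, method = "BH")
  dplyr::arrange(res, dplyr::desc(.data$overall_mean))
}
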