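#' Individual-unique low-abundance species
#'
#' Ranks species by overall mean relative abundance (rank 1 = most
#' abundant) and, among species ranked strictly outside `rank_threshold`,
#' finds those whose presence is confined to a single individual's samples.
#' The discriminated fraction is the share of individuals carrying at least
#' one such species. High-abundance species are excluded by the rank rule
#' regardless of uniqueness: only the rare tail is individual-specific
#' enough to be forensically usable.
#'
#' @param table A species-level feature-table matrix (counts).
#' @param metadata Sample metadata.
#' @param rank_threshold Species ranked at or above this are excluded
#'   (default 100).
#' @param habitat Optional habitat to restrict to (`NULL` pools both, with
#'   ranking computed on the pooled table).
#' @return A list with `unique_species` (tibble: individual_id, feature_id,
#'   rank), `fraction` (discriminated individuals / individuals),
#'   `n_individuals`, `rank_threshold`.
#' @export
find_unique_taxa <- function(table, metadata, rank_threshold = 100,
                             habitat = NULL) {
  metadata <- validate_metadata(metadata)
  if (!is.null(habitat)) {
    habitat <- match.arg(habitat, habitat_levels())
    metadata <- metadata[metadata$habitat == habitat, ]
    table <- table[rownames(table) %in% metadata$sample_id, , drop = FALSE]
  }
  table <- table[, colSums(table) > 0, drop = FALSE]
  rel <- to_relative(table)
  ranks <- rank(-colMeans(rel), ties.method = "first")
  if (ncol(table) <= rank_threshold) {
    warning("only ", ncol(table), " species present; every species is a ",
            "candidate under rank threshold ", rank_threshold)
    candidates <- names(ranks)
  } else {
    candidates <- names(ranks)[ranks > rank_threshold]
  }

  ind_of <- metadata$individual_id[match(rownames(table), metadata$sample_id)]
  uniq <- purrr::map_dfr(candidates, function(sp) {
    carriers <- unique(ind_of[table[, sp] > 0])
    if (length(carriers) == 1) {
      tibble::tibble(individual_id = carriers, feature_id = sp,
                     rank = unname(ranks[sp]))
    } else {
      NULL
    }
  })
  if (nrow(uniq) == 0) {
    uniq <- tibble::tibble(individual_id = character(),
                           feature_id = character(), rank = integer())
  }
  n_ind <- length(unique(metadata$individual_id))
  list(unique_species = uniq,
       fraction = length(unique(uniq$individual_id)) / n_ind,
       n_individuals = n_ind,
       rank_threshold = rank_threshold)
}

#' Core taxa: present in every individual
#'
#' A taxon (usually a genus, on a genus-collapsed table) belongs to the
#' core microbiome when it has a nonzero count in at least one sample of
#' every individual. The `Unassigned` pooling bucket is not a taxon and is
#' excluded.
#'
#' @param table A (genus-level) feature-table matrix.
#' @param metadata Sample metadata.
#' @return Character vector of core taxa, sorted by overall mean relative
#'   abundance, descending.
#' @export
core_taxa <- function(table, metadata) {
  metadata <- validate_metadata(metadata)
  ind_of <- metadata$individual_id[match(rownames(table), metadata$sample_id)]
  inds <- unique(ind_of)
  present_everywhere <- vapply(colnames(table), function(tax) {
    carriers <- unique(ind_of[table[, tax] > 0])
    length(setdiff(inds, carriers)) == 0
  }, logical(1))
  core <- colnames(table)[present_everywhere]
  core <- setdiff(core, "Unassigned")
  rel_means <- colMeans(to_relative(table))[core]
  core[order(-rel_means)]
}

#' Microbial code: renormalized core-taxon profile per individual
#'
#' Each individual's profile (mean relative abundance over that
#' individual's samples, optionally restricted to one habitat) is cut down
#' to the core taxa and renormalized to sum to 1 -- a compact fingerprint
#' analogous to an STR profile.
#'
#' @param rel A (genus-level) relative-abundance matrix.
#' @param metadata Sample metadata.
#' @param core Character vector of core taxa.
#' @param habitat Optional habitat restriction.
#' @return A numeric matrix (individuals x core taxa) whose rows sum to 1.
#' @export
microbial_code <- function(rel, metadata, core, habitat = NULL) {
  if (length(core) == 0) stop("core set is empty", call. = FALSE)
  metadata <- validate_metadata(metadata)
  if (!is.null(habitat)) {
    habitat <- match.arg(habitat, habitat_levels())
    metadata <- metadata[metadata$habitat == habitat, ]
  }
  missing <- setdiff(core, colnames(rel))
  if (length(missing) > 0) {
    stop("core taxa absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  inds <- unique(metadata$individual_id)
  code <- t(vapply(inds, function(ind) {
    ids <- metadata$sample_id[metadata$individual_id == ind]
    ids <- intersect(ids, rownames(rel))
    prof <- colMeans(rel[ids, core, drop = FALSE])
    total <- sum(prof)
    if (total == 0) stop("individual '", ind, "' has zero core abundance",
                         call. = FALSE)
    prof / total
  }, numeric(length(core))))
  dimnames(code) <- list(inds, core)
  code
}

#' Match a query code against a reference code database
#'
#' Bray--Curtis distance from the query profile to every reference row,
#' returned best match first (ties broken by reference id).
#'
#' @param query Named numeric code vector (must share the reference's
#'   core-taxon ordering).
#' @param reference A code matrix as returned by [microbial_code()].
#' @return A tibble `reference_id`, `distance`, `rank`, ascending distance.
#' @export
match_code <- function(query, reference) {
  if (!identical(names(query), colnames(reference))) {
    stop("query and reference use different core-taxon orderings", call. = FALSE)
  }
  d <- apply(reference, 1, function(r) {
    den <- sum(query + r)
    if (den == 0) 0 else sum(abs(query - r)) / den
  })
  ord <- order(d, names(d))
  tibble::tibble(reference_id = names(d)[ord], distance = unname(d[ord]),
                 rank = seq_along(d))
}

#' Full personal-discrimination report
#'
#' Runs the three discrimination analyses together: rank-threshold unique
#' species at species level, core genera, and the renormalized microbial
#' code (per habitat).
#'
#' @param table A feature-table matrix (finest level available).
#' @param taxonomy Taxonomy tibble.
#' @param metadata Sample metadata.
#' @param rank_threshold Rank cut-off for the unique-species rule.
#' @param habitat Habitat used for the unique-species ranking and the code
#'   (default `"saliva"`); core genera always use all samples.
#' @return An object of class `discrimination_report`: list with
#'   `unique_species`, `fraction`, `core`, `code`, `rank_threshold`,
#'   `habitat`.
#' @export
discriminate_individuals <- function(table, taxonomy, metadata,
                                     rank_threshold = 100,
                                     habitat = "saliva") {
  species <- collapse_taxa(table, taxonomy, "species")
  genus <- collapse_taxa(table, taxonomy, "genus")
  uniq <- find_unique_taxa(species, metadata, rank_threshold = rank_threshold,
                           habitat = habitat)
  core <- core_taxa(genus, metadata)
  code <- if (length(core) > 0) {
    microbial_code(to_relative(genus), metadata, core, habitat = habitat)
  } else {
    NULL
  }
  structure(list(unique_species = uniq$unique_species,
                 fraction = uniq$fraction,
                 n_individuals = uniq$n_individuals,
                 core = core, code = code,
                 rank_threshold = rank_threshold, habitat = habitat),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Personal discrimination report (", x$habitat, ")\n", sep = "")
  cat(sprintf("  %d/%d individuals carry a unique species outside rank %d (fraction %.2f)\n",
              length(unique(x$unique_species$individual_id)),
              x$n_individuals, x$rank_threshold, x$fraction))
  cat(sprintf("  core microbiome: %d taxa\n", length(x$core)))
  invisible(x)
}
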