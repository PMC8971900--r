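#' Construct and validate a feature table
#'
#' The central data object of the pipeline: a samples x features matrix of
#' non-negative integer read counts, with unique sample identifiers as row
#' names and unique feature (ASV / taxon) identifiers as column names. It is
#' deliberately a plain base matrix so it can be handed straight to
#' \pkg{vegan}; every function in this package that takes `table` expects this
#' shape.
#'
#' @param counts A numeric matrix (samples in rows, features in columns) with
#'   complete dimnames, or a data frame coercible to one.
#' @return The validated integer matrix.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 2, 7), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' feature_table(m)
feature_table <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix (samples x features)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("feature table needs sample row names and feature column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicated feature id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-integer count at sample '%s', feature '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

habitat_levels <- function() c("saliva", "buccal_mucosa")

#' Validate sample metadata
#'
#' Metadata is a tibble with required columns `sample_id`, `individual_id`,
#' `habitat` and optional `sex`, `age`. Habitat labels come from the closed
#' set `saliva` / `buccal_mucosa`; an individual may contribute at most one
#' sample per habitat (the paired-swab design).
#'
#' @param metadata A data frame of per-sample records.
#' @return The metadata as a validated tibble.
#' @export
validate_metadata <- function(metadata) {
  metadata <- tibble::as_tibble(metadata)
  need <- c("sample_id", "individual_id", "habitat")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicated sample id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(metadata$habitat), habitat_levels())
  if (length(bad) > 0) {
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(habitat_levels(), collapse = ", "), ")", call. = FALSE)
  }
  dup <- dplyr::count(metadata, .data$individual_id, .data$habitat)
  dup <- dplyr::filter(dup, .data$n > 1)
  if (nrow(dup) > 0) {
    stop("individual '", dup$individual_id[1], "' has more than one '",
         dup$habitat[1], "' sample", call. = FALSE)
  }
  metadata
}

taxonomy_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Validate a taxonomy table
#'
#' @param taxonomy A data frame with a `feature_id` column and the seven rank
#'   columns kingdom...species (`NA` marks an unassigned rank).
#' @return The taxonomy as a validated tibble.
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- tibble::as_tibble(taxonomy)
  miss <- setdiff(c("feature_id", taxonomy_ranks()), names(taxonomy))
  if (length(miss) > 0) {
    stop("taxonomy is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(taxonomy$feature_id)) {
    stop("feature mapped more than once in taxonomy: ",
         paste(unique(taxonomy$feature_id[duplicated(taxonomy$feature_id)]), collapse = ", "),
         call. = FALSE)
  }
  taxonomy[, c("feature_id", taxonomy_ranks())]
}

# ---- file I/O ---------------------------------------------------------------

#' Read / write a feature table in the QIIME2 TSV dialect
#'
#' The on-disk layout is the common biom-TSV export: a leading `#OTU ID`
#' header cell, features as rows and samples as columns. Internally the table
#' is transposed to samples x features.
#'
#' @param path Path to a tab-separated feature table.
#' @return For `read_feature_table`, a validated feature-table matrix.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "#OTU ID" && names(df)[1] != "X.OTU.ID") {
    stop("expected a '#OTU ID' header in ", path, call. = FALSE)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  feature_table(t(m))
}

#' @rdname read_feature_table
#' @param table A feature-table matrix.
#' @export
write_feature_table <- function(table, path) {
  out <- t(table)
  df <- data.frame(`#OTU ID` = rownames(out), out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write taxonomy as two-column TSV
#'
#' Column 1 is the feature id, column 2 a semicolon-delimited lineage
#' (Greengenes/Silva-style `g__` prefixes are tolerated and stripped); an
#' optional third confidence column is ignored. Unassigned trailing ranks may
#' simply be absent from the lineage string.
#'
#' @param path Path to a tab-separated taxonomy file.
#' @return For `read_taxonomy`, a tibble with `feature_id` plus seven rank
#'   columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("taxonomy file needs >= 2 columns: ", path, call. = FALSE)
  lineages <- strsplit(as.character(df[[2]]), ";", fixed = TRUE)
  ranks <- purrr::map(lineages, function(parts) {
    parts <- trimws(parts)
    parts <- sub("^[a-z]__", "", parts)
    parts[parts == ""] <- NA_character_
    length(parts) <- 7L
    parts
  })
  tax <- do.call(rbind, ranks)
  colnames(tax) <- taxonomy_ranks()
  validate_taxonomy(tibble::tibble(feature_id = as.character(df[[1]]),
                                   tibble::as_tibble(tax)))
}

#' @rdname read_taxonomy
#' @param taxonomy A validated taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) {
  taxonomy <- validate_taxonomy(taxonomy)
  lineage <- apply(as.matrix(taxonomy[, taxonomy_ranks()]), 1, function(r) {
    r[is.na(r)] <- ""
    paste(r, collapse = ";")
  })
  utils::write.table(
    data.frame(`Feature ID` = taxonomy$feature_id, Taxon = lineage,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' @param path Path to a tab-separated metadata file with columns
#'   `sample_id`, `individual_id`, `habitat` and optionally `sex`, `age`.
#' @return For `read_metadata`, a validated metadata tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param metadata A validated metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(validate_metadata(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- table preparation ------------------------------------------------------

#' Remove singleton features
#'
#' Drops features whose total count across the whole merged table equals 1
#' (the QIIME2 convention for "singleton": one read in the entire study, not
#' one read in a sample). This is the first preparation step, applied before
#' rarefaction.
#'
#' @param table A feature-table matrix.
#' @return The table without singleton features.
#' @export
remove_singletons <- function(table) {
  totals <- colSums(table)
  keep <- totals != 1
  if (!any(keep)) stop("all features are singletons; empty table", call. = FALSE)
  table[, keep, drop = FALSE]
}

#' Rarefaction (leveling) depth
#'
#' The leveling depth is a fixed fraction of the minimum per-sample sequence
#' total, rounded down: `floor(fraction * min(sample totals))`. The default
#' fraction is 0.95.
#'
#' @param table A feature-table matrix.
#' @param fraction Fraction of the minimum sample total to keep.
#' @return Integer depth.
#' @export
#' @examples
#' m <- matrix(c(60L, 40L, 70L, 50L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("a", "b")))
#' rarefaction_depth(m)  # floor(0.95 * 110) = 104
rarefaction_depth <- function(table, fraction = 0.95) {
  if (nrow(table) == 0 || ncol(table) == 0) stop("empty table", call. = FALSE)
  totals <- rowSums(table)
  if (any(totals == 0)) {
    stop("sample with zero total: ", rownames(table)[which(totals == 0)[1]],
         call. = FALSE)
  }
  as.integer(floor(fraction * min(totals)))
}

#' Rarefy a feature table to a common depth
#'
#' Each sample is subsampled uniformly without replacement to exactly `depth`
#' reads (one seeded draw). Samples whose total is below `depth` are dropped
#' with a warning rather than padded.
#'
#' @param table A feature-table matrix.
#' @param depth Target reads per sample.
#' @param seed Integer seed for the subsampling draw.
#' @return A rarefied feature-table matrix in which every retained sample
#'   sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  totals <- rowSums(table)
  drop <- totals < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[drop], collapse = ", "))
    table <- table[!drop, , drop = FALSE]
  }
  if (nrow(table) == 0) stop("no samples at or above depth ", depth, call. = FALSE)
  set.seed(seed)
  # vegan heuristically warns when no feature has a small count; that is a
  # legitimate state for a filtered count table, so the hint is muffled
  out <- withCallingHandlers(
    vegan::rrarefy(table, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  feature_table(out)
}

#' Collapse a feature table to a taxonomic rank
#'
#' Counts are summed over features that share the lineage prefix up to
#' `rank`. Features unassigned at that rank -- or missing from the taxonomy
#' entirely (pooled by default, with a message) -- are gathered into an
#' `"Unassigned"` bucket so per-sample totals are conserved exactly.
#'
#' @param table A feature-table matrix.
#' @param taxonomy A taxonomy tibble.
#' @param rank One of kingdom, phylum, class, order, family, genus, species.
#' @param missing How to treat features absent from the taxonomy: `"pool"`
#'   into Unassigned (default) or `"error"`.
#' @return A feature-table matrix whose columns are lineage prefixes at
#'   `rank` (labelled by the rank-level name).
#' @export
collapse_taxa <- function(table, taxonomy, rank = "genus",
                          missing = c("pool", "error")) {
  rank <- match.arg(rank, taxonomy_ranks())
  missing <- match.arg(missing)
  taxonomy <- validate_taxonomy(taxonomy)
  upto <- seq_len(match(rank, taxonomy_ranks()))

  idx <- match(colnames(table), taxonomy$feature_id)
  if (anyNA(idx)) {
    absent <- colnames(table)[is.na(idx)]
    if (missing == "error") {
      stop("feature(s) missing from taxonomy: ",
           paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    }
    message(length(absent), " feature(s) missing from taxonomy pooled into Unassigned")
  }
  lin <- as.matrix(taxonomy[, taxonomy_ranks()])[idx, upto, drop = FALSE]
  label <- lin[, length(upto)]
  # unassigned at the requested rank (or absent from taxonomy) -> one bucket
  label[is.na(label) | is.na(idx)] <- "Unassigned"

  groups <- factor(label, levels = unique(label))
  out <- t(rowsum(t(table), groups))
  colnames(out) <- levels(groups)
  feature_table(out)
}

#' Convert counts to relative abundances
#'
#' @param table A feature-table matrix.
#' @return A numeric matrix of the same shape whose rows each sum to 1.
#' @export
to_relative <- function(table) {
  totals <- rowSums(table)
  if (any(totals == 0)) {
    stop("all-zero sample: ", rownames(table)[which(totals == 0)[1]], call. = FALSE)
  }
  sweep(table, 1, totals, "/")
}
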