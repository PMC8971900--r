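#' Sloan neutral-model expected occupancy
#'
#' Under the neutral community model, a taxon with metacommunity relative
#' abundance `p` is detected (local relative abundance above the detection
#' limit `d`) with probability
#' \eqn{\hat F(p) = 1 - B(d;\, Nm\,p,\; Nm\,(1 - p))}, where `B` is the
#' regularized incomplete beta CDF and `Nm` the product of local community
#' size and immigration rate -- the only identifiable migration parameter.
#'
#' @param p Metacommunity relative abundance(s) in `[0, 1]`.
#' @param Nm Migration parameter (> 0).
#' @param d Detection limit on relative abundance.
#' @return Predicted occupancy in `[0, 1]` (0 where `p = 0`).
#' @export
ncm_occupancy <- function(p, Nm, d) {
  out <- ifelse(p > 0 & p < 1,
                1 - stats::pbeta(d, Nm * p, Nm * (1 - p)),
                as.numeric(p >= 1))
  out[p == 0] <- 0
  out
}

#' @rdname ncm_occupancy
#' @details `ncm_occupancy_reads()` replaces the hard detection limit with
#' the exact probability of drawing at least one read at depth `D` when the
#' local relative abundance is beta-distributed:
#' \eqn{1 - E[(1-x)^D] = 1 - B(Nm\,p, Nm\,(1-p) + D) / B(Nm\,p, Nm\,(1-p))}.
#' The two agree when the per-read detection scale `1/D` is far below the
#' beta spread (`D >> Nm`); at high `Nm` relative to depth the read-level
#' form is the unbiased occupancy model for count data.
#' @param D Sequencing depth (reads per sample).
#' @export
ncm_occupancy_reads <- function(p, Nm, D) {
  a <- Nm * p
  b <- Nm * (1 - p)
  out <- ifelse(p > 0 & p < 1,
                1 - exp(lbeta(a, b + D) - lbeta(a, b)),
                as.numeric(p >= 1))
  out[p == 0] <- 0
  out
}

#' Fit the Sloan neutral community model
#'
#' Estimates `Nm` by nonlinear least squares of observed occupancy
#' frequencies on the neutral expectation ([ncm_occupancy()], or
#' [ncm_occupancy_reads()] with `detection = "reads"`), computes the
#' goodness of fit `R^2 = 1 - SSE/SST`, builds a 95% prediction band around
#' the fitted curve, and partitions taxa into those occurring more often
#' than predicted (`above`), within the band (`fit`), or less often
#' (`below`). The band combines the exact binomial quantiles of occupancy
#' (n = number of samples) with the uncertainty of the estimated
#' metacommunity abundance propagated through the curve slope, so that taxa
#' are not flagged as non-neutral merely because their mean abundance is
#' noisy. The `Nm` confidence interval is a parametric basic bootstrap:
#' neutral data are re-simulated from the fitted model at the observed
#' depths and re-estimated, which also corrects the attenuation bias that
#' noisy abundance estimates induce at low `Nm`.
#'
#' @param table A feature-table matrix, ideally rarefied to a common depth;
#'   at least 10 samples and 5 taxa with nonzero totals.
#' @param detection `"limit"` for the classic hard detection threshold at
#'   `d`, `"reads"` for exact read-level (beta-binomial) detection at the
#'   mean sample depth.
#' @param detection_limit Relative-abundance detection limit `d` for
#'   `detection = "limit"`; default `1 / mean(sample total)`, which is
#'   `1 / depth` after rarefaction.
#' @param conf Confidence level of the occupancy band and the `Nm` CI.
#' @param n_boot Bootstrap replicates for the `Nm` CI (0 skips the CI).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return An object of class `ncm_fit`: a list with `Nm`, `Nm_lower`,
#'   `Nm_upper`, `r_squared`, `detection_limit`, `n_samples`, and `taxa`, a
#'   tibble with per-taxon `p`, `freq_obs`, `freq_pred`, `lower`, `upper`,
#'   `partition`.
#' @export
#' @examples
#' prof <- default_profiles(n_tail = 60)
#' tab <- simulate_neutral_assembly(
#'   simulation_config(n_samples = 30, N = 1e4, m = 0.1, seed = 2,
#'                     depth_range = c(5000, 5000)),
#'   prof$saliva)
#' fit <- fit_ncm(tab)
#' glance(fit)
fit_ncm <- function(table, detection = c("limit", "reads"),
                    detection_limit = NULL, conf = 0.95, n_boot = 199,
                    boot_seed = 1L) {
  detection <- match.arg(detection)
  if (nrow(table) < 10) stop("need >= 10 samples to fit the model", call. = FALSE)
  keep <- colSums(table) > 0
  table <- table[, keep, drop = FALSE]
  if (ncol(table) < 5) stop("fewer than 5 taxa with nonzero totals", call. = FALSE)

  rel <- to_relative(table)
  p <- colMeans(rel)
  var_p <- apply(rel, 2, stats::var) / nrow(table)
  freq_obs <- colMeans(table > 0)
  depths <- rowSums(table)
  d <- if (detection == "limit") {
    detection_limit %||% (1 / mean(depths))
  } else {
    mean(depths)   # depth D for read-level detection
  }
  occ_fun <- if (detection == "limit") ncm_occupancy else ncm_occupancy_reads

  Nm <- estimate_nm(p, freq_obs, d, occ_fun)
  if (is.na(Nm)) {
    stop("neutral-model optimizer failure", call. = FALSE)
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(substream_seed(boot_seed, "ncm_boot"))
    boots <- replicate(n_boot, {
      sim <- simulate_ncm_counts(p, Nm, depths)
      estimate_nm(colMeans(sim / rowSums(sim)), colMeans(sim > 0), d, occ_fun)
    })
    # basic (pivot) interval: corrects the first-order estimation bias;
    # widened to contain the point estimate (pure pivot intervals can
    # exclude it when the bias correction exceeds the bootstrap spread)
    qs <- stats::quantile(boots, c(1 - (1 - conf) / 2, (1 - conf) / 2),
                          na.rm = TRUE)
    ci <- pmax(unname(2 * Nm - qs), 0)
    ci <- c(min(ci[1], Nm), max(ci[2], Nm))
  }

  pred <- occ_fun(p, Nm, d)
  sse_fit <- sum((freq_obs - pred)^2)
  sst <- sum((freq_obs - mean(freq_obs))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sse_fit / sst
  if (is.na(r2)) {
    message("occupancy is constant across taxa; R^2 undefined (poor fit)")
  }

  # 95% prediction band: exact binomial quantiles of occupancy (Wilson's
  # normal approximation misclassifies the F ~ 1 boundary, where F_obs = 1
  # is a typical draw from Binomial(n, 0.99)) widened by the abundance-
  # estimate uncertainty propagated through the curve slope
  n <- nrow(table)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  slope <- (occ_fun(pmin(p * 1.01, 1), Nm, d) - occ_fun(p * 0.99, Nm, d)) /
    (0.02 * p)
  sd_tot <- sqrt(pred * (1 - pred) / n + slope^2 * var_p)
  lower <- pmax(0, pmin(stats::qbinom((1 - conf) / 2, n, pred) / n,
                        pred - z * sd_tot))
  upper <- pmin(1, pmax(stats::qbinom(1 - (1 - conf) / 2, n, pred) / n,
                        pred + z * sd_tot))
  partition <- ifelse(freq_obs > upper, "above",
                      ifelse(freq_obs < lower, "below", "fit"))

  structure(list(
    Nm = Nm,
    Nm_lower = ci[1],
    Nm_upper = ci[2],
    r_squared = r2,
    detection = detection,
    detection_limit = if (detection == "limit") d else 1 / d,
    n_samples = n,
    conf = conf,
    taxa = tibble::tibble(
      taxon = colnames(table), p = unname(p),
      freq_obs = unname(freq_obs), freq_pred = unname(pred),
      lower = unname(lower), upper = unname(upper),
      partition = factor(unname(partition),
                         levels = c("above", "fit", "below")))),
    class = "ncm_fit")
}

# Re-simulate counts from the fitted neutral model (beta local abundance,
# multinomial reads) at the observed per-sample depths.
simulate_ncm_counts <- function(p, Nm, depths) {
  k <- length(p)
  t(vapply(depths, function(D) {
    x <- ifelse(p > 0, stats::rbeta(k, Nm * p, Nm * (1 - p)), 0)
    if (sum(x) == 0) x[which.max(p)] <- 1
    as.integer(stats::rmultinom(1, D, x / sum(x)))
  }, integer(k)))
}

# Grid-started nonlinear least squares for the migration parameter. When the
# NLS step cannot improve on the grid (e.g. constant occupancy, where the
# objective is flat in Nm), the coarse grid optimum is returned so degenerate
# data yield a poor fit rather than an error.
estimate_nm <- function(p, freq_obs, d, occ_fun) {
  grid <- 10^seq(-1, 7, by = 0.25)
  sse <- vapply(grid, function(nm) sum((freq_obs - occ_fun(p, nm, d))^2),
                numeric(1))
  if (all(!is.finite(sse))) return(NA_real_)
  start <- grid[which.min(sse)]
  tryCatch(
    unname(stats::coef(minpack.lm::nlsLM(
      freq_obs ~ occ_fun(p, Nm, d),
      start = list(Nm = start), lower = 1e-6, upper = 1e12,
      control = minpack.lm::nls.lm.control(maxiter = 500)))[["Nm"]]),
    error = function(e) start)
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.4g (95%% CI %.4g-%.4g), R^2 = %.3f\n",
              x$Nm, x$Nm_lower, x$Nm_upper, x$r_squared))
  cat(sprintf("  %d taxa, %d samples, detection limit %.3g\n",
              nrow(x$taxa), x$n_samples, x$detection_limit))
  print(partition_counts(x))
  invisible(x)
}

#' Count taxa per neutral-fit partition
#'
#' @param fit An `ncm_fit`.
#' @return A tibble with rows `above`, `fit`, `below` and their taxon
#'   counts (summing to the number of fitted taxa).
#' @export
partition_counts <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  tb <- table(fit$taxa$partition)
  tibble::tibble(partition = names(tb), n = as.integer(tb))
}

# Proportional-abundance refill of a binary null pattern: every present
# taxon gets one read, the remaining (total - richness) reads are multinomial
# with probabilities proportional to the group-wide (regional) abundance of
# the present taxa. Preserves the sample total and richness exactly.
refill_abundance <- function(pa_row, total, regional) {
  present <- which(pa_row > 0)
  counts <- integer(length(pa_row))
  counts[present] <- 1L
  extra <- total - length(present)
  if (extra > 0) {
    pr <- regional[present]
    if (sum(pr) == 0) pr <- rep(1, length(present))
    counts[present] <- counts[present] +
      as.integer(stats::rmultinom(1, extra, pr))
  }
  counts
}

#' Null-model beta-diversity and deterministic strength
#'
#' For each group of samples, compares observed beta diversity (mean
#' pairwise Bray--Curtis) with a null ensemble that scrambles which taxa
#' occur where while preserving each sample's richness and read total and
#' each taxon's occupancy count: presences are randomized by the curveball
#' fixed-fixed algorithm and abundances refilled proportionally to regional
#' abundance. Reports, per group, the richness pool gamma, mean per-sample
#' richness, observed and null beta, the standardized effect size
#' `ses = (obs - mean null) / sd null`, and the deterministic strength
#' percentage (see [deterministic_strength()]).
#'
#' @param table A feature-table matrix.
#' @param metadata Sample metadata (optional; omit to treat the whole table
#'   as one group).
#' @param group Metadata column defining groups (default `"habitat"`).
#' @param n_null Number of null randomizations.
#' @param seed Integer seed.
#' @return An object of class `null_model_result`: list with `summary`
#'   (tibble, one row per group) and `pairs` (tibble of per-pair observed
#'   and null-mean dissimilarities).
#' @export
null_model <- function(table, metadata = NULL, group = "habitat",
                       n_null = 999, seed = 1L) {
  groups <- if (is.null(metadata)) {
    list(all = rownames(table))
  } else {
    metadata <- validate_metadata(metadata)
    metadata <- metadata[match(rownames(table), metadata$sample_id), ]
    split(metadata$sample_id, metadata[[group]])
  }

  res <- purrr::imap(groups, function(ids, gname) {
    sub <- table[ids, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    if (nrow(sub) < 3) stop("group '", gname, "' has fewer than 3 samples",
                            call. = FALSE)
    null_model_one(sub, gname, n_null,
                   substream_seed(seed, paste0("null_", gname)))
  })

  structure(list(summary = dplyr::bind_rows(purrr::map(res, "summary")),
                 pairs = dplyr::bind_rows(purrr::map(res, "pairs"))),
            class = "null_model_result")
}

null_model_one <- function(sub, gname, n_null, seed) {
  totals <- rowSums(sub)
  regional <- colSums(sub)
  pa <- (sub > 0) * 1L

  d_obs <- as.matrix(vegan::vegdist(sub, method = "bray"))
  obs_beta <- mean(d_obs[lower.tri(d_obs)])

  nm <- vegan::nullmodel(pa, "curveball")
  sims <- stats::simulate(nm, nsim = n_null, seed = seed)
  set.seed(substream_seed(seed, "refill"))

  null_betas <- numeric(n_null)
  d_null_sum <- matrix(0, nrow(sub), nrow(sub))
  for (k in seq_len(n_null)) {
    null_counts <- t(vapply(seq_len(nrow(sub)), function(i) {
      refill_abundance(sims[i, , k], totals[i], regional)
    }, integer(ncol(sub))))
    dk <- as.matrix(vegan::vegdist(null_counts, method = "bray"))
    null_betas[k] <- mean(dk[lower.tri(dk)])
    d_null_sum <- d_null_sum + dk
  }
  d_null_mean <- d_null_sum / n_null
  sd_null <- stats::sd(null_betas)
  if (sd_null == 0) stop("zero null variance: ses undefined", call. = FALSE)

  lt <- which(lower.tri(d_obs), arr.ind = TRUE)
  pairs <- tibble::tibble(
    group = gname,
    sample_i = rownames(sub)[lt[, 1]], sample_j = rownames(sub)[lt[, 2]],
    d_obs = d_obs[lt], d_null_mean = d_null_mean[lt])

  list(summary = tibble::tibble(
    group = gname,
    gamma = ncol(sub),
    obs_mean_alpha = mean(rowSums(sub > 0)),
    obs_beta = obs_beta,
    mean_null_beta = mean(null_betas),
    sd_null_beta = sd_null,
    ses_beta = (obs_beta - mean(null_betas)) / sd_null,
    ds = deterministic_strength(pairs$d_obs, pairs$d_null_mean),
    n_null = n_null, seed = seed),
    pairs = pairs)
}

#' @export
print.null_model_result <- function(x, ...) {
  cat("Null-model beta-diversity result\n")
  print(x$summary)
  invisible(x)
}

#' Deterministic strength from observed and null dissimilarities
#'
#' Per sample pair, the selection strength is the relative departure of the
#' observed dissimilarity from its null expectation:
#' `(d_obs - d_null) / d_obs` when observed exceeds the null mean
#' (heterogeneous selection), `(d_null - d_obs) / d_null` otherwise
#' (homogenizing selection). The deterministic strength is 100 times the
#' mean over pairs, in `[0, 100]`; higher values indicate stronger
#' deterministic (selection-driven) assembly. Pairs where both quantities
#' are zero carry no signal and are skipped with a warning.
#'
#' @param d_obs Observed pairwise dissimilarities.
#' @param d_null Matching null-mean dissimilarities.
#' @return Deterministic strength as a percentage.
#' @export
deterministic_strength <- function(d_obs, d_null) {
  stopifnot(length(d_obs) == length(d_null))
  undef <- d_obs == 0 & d_null == 0
  if (any(undef)) {
    warning(sum(undef), " pair(s) with zero observed and null dissimilarity skipped")
    d_obs <- d_obs[!undef]
    d_null <- d_null[!undef]
  }
  ss <- ifelse(d_obs > d_null,
               (d_obs - d_null) / d_obs,
               (d_null - d_obs) / d_null)
  100 * mean(pmax(0, ss))
}
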