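#' Pearson correlation with a two-sided t test
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, neither constant.
#' @return a `correlation_result`: list with `r`, `r_squared`, `p_value`
#'   (two-sided, from the t transform with n - 2 degrees of freedom), `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(min(r, 1), -1)
  t_stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  structure(list(r = r, r_squared = r^2, p_value = min(p, 1), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f (R^2 = %.4f), P = %.4g, n = %d\n",
              x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Correlation between a principal component and geography
#'
#' The default analysis unit is the state: per-state mean PC scores are
#' correlated with the state coordinate, matching the handful-of-populations
#' regime in which such correlations are usually reported; `unit = "sample"`
#' correlates per-sample scores instead.
#'
#' @param pca a `pca_result` (or a named score vector).
#' @param metadata data frame with `sample_id`, `state`, and the coordinate
#'   column.
#' @param axis `"latitude"` or `"longitude"`.
#' @param pc component index (default 1).
#' @param unit `"state"` (default) or `"sample"`.
#' @return a `correlation_result`, with the aggregated table attached as
#'   attribute `"points"`.
#' @export
pc_vs_latitude <- function(pca, metadata, axis = c("latitude", "longitude"),
                           pc = 1, unit = c("state", "sample")) {
  axis <- match.arg(axis)
  unit <- match.arg(unit)
  if (!axis %in% names(metadata)) {
    stop("metadata has no '", axis, "' column")
  }
  scores <- if (inherits(pca, "pca_result")) pca$scores[, pc] else pca
  idx <- match(names(scores), metadata$sample_id)
  if (anyNA(idx)) stop("metadata missing for some samples")
  coord <- metadata[[axis]][idx]
  if (anyNA(coord)) stop("missing ", axis, " coordinate(s)")
  if (unit == "sample") {
    res <- pearson_correlation(coord, scores)
    attr(res, "points") <- data.frame(unit = names(scores), coord = coord,
                                      score = scores)
    return(res)
  }
  state <- metadata$state[idx]
  states <- unique(state)
  mean_score <- vapply(states, function(s) mean(scores[state == s]), numeric(1))
  mean_coord <- vapply(states, function(s) mean(coord[state == s]), numeric(1))
  res <- pearson_correlation(mean_coord, mean_score)
  attr(res, "points") <- data.frame(unit = states, coord = mean_coord,
                                    score = mean_score)
  res
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371.0 km (sub-0.5%
#' error at regional scale).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Correlate pairwise F_ST with geographic distance
#'
#' Simple Pearson correlation over the unordered group pairs (distance in km
#' from [haversine_km()]), with an optional Mantel permutation p-value
#' reported alongside: the parametric p treats pairs as independent, which
#' they are not, so the Mantel test is the conservative companion.
#'
#' @param fst_matrix symmetric matrix of pairwise F_ST (group names as
#'   dimnames).
#' @param coords data frame with `group`, `latitude`, `longitude`.
#' @param mantel_permutations permutations for the Mantel test (0 disables).
#' @param seed integer seed for the permutation stream.
#' @return list with `cor` (a `correlation_result`), `pairs` (data frame of
#'   group pairs, F_ST and km), and `mantel_p` (`NA` when disabled).
#' @export
fst_vs_distance <- function(fst_matrix, coords, mantel_permutations = 0,
                            seed = 1) {
  groups <- rownames(fst_matrix)
  if (is.null(groups)) stop("fst_matrix needs group names as dimnames")
  idx <- match(groups, coords$group)
  if (anyNA(idx)) stop("coordinates missing for group(s): ",
                       paste(groups[is.na(idx)], collapse = ", "))
  lat <- coords$latitude[idx]
  lon <- coords$longitude[idx]
  K <- length(groups)
  if (K < 3) stop("need at least 3 groups")
  pairs <- utils::combn(K, 2)
  fst <- fst_matrix[t(pairs)]
  km <- haversine_km(lat[pairs[1, ]], lon[pairs[1, ]],
                     lat[pairs[2, ]], lon[pairs[2, ]])
  pair_tab <- data.frame(group1 = groups[pairs[1, ]],
                         group2 = groups[pairs[2, ]],
                         fst = fst, km = km, stringsAsFactors = FALSE)
  if (stats::sd(fst) == 0) {
    return(list(cor = NULL, pairs = pair_tab, mantel_p = NA_real_,
                flagged = "constant F_ST across pairs"))
  }
  res <- pearson_correlation(km, fst)
  mantel_p <- NA_real_
  if (mantel_permutations > 0) {
    dm_f <- matrix(0, K, K); dm_f[t(pairs)] <- fst; dm_f <- dm_f + t(dm_f)
    dm_d <- matrix(0, K, K); dm_d[t(pairs)] <- km; dm_d <- dm_d + t(dm_d)
    set.seed(seed)
    mt <- vegan::mantel(stats::as.dist(dm_d), stats::as.dist(dm_f),
                        permutations = mantel_permutations)
    mantel_p <- mt$signif
  }
  list(cor = res, pairs = pair_tab, mantel_p = mantel_p)
}
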