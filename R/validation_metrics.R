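#' Align two effort grids on a common cell set
#'
#' Grids are compared cell by cell after aligning on coordinates. The
#' default inclusion rule keeps the union of nonzero supports (zeros kept
#' as zeros: coverage gaps in AIS-like data are informative); the
#' alternative keeps only cells nonzero in both.
#'
#' @param a,b Tibbles `lat`, `lon`, `value`.
#' @param include `"union"` (default) or `"intersection"`.
#' @return Tibble `lat`, `lon`, `a`, `b`.
#' @export
align_grids <- function(a, b, include = c("union", "intersection")) {
  include <- match.arg(include)
  m <- dplyr::full_join(
    dplyr::rename(a, a = "value"), dplyr::rename(b, b = "value"),
    by = c("lat", "lon")
  )
  m$a[is.na(m$a)] <- 0
  m$b[is.na(m$b)] <- 0
  if (include == "union") m[m$a > 0 | m$b > 0, ] else m[m$a > 0 & m$b > 0, ]
}

#' Cell-wise Spearman rank correlation of two grids
#'
#' Rank correlation over the included cells, ties mid-ranked; the usual
#' large-sample p value is reported.
#'
#' @param a,b Tibbles `lat`, `lon`, `value` on a common grid.
#' @param include Inclusion rule, see [align_grids()].
#' @return List `rho`, `p_value`, `n`.
#' @export
spearman_cells <- function(a, b, include = "union") {
  m <- align_grids(a, b, include)
  if (nrow(m) < 3) stop("fewer than 3 cells included in the comparison")
  ct <- suppressWarnings(cor.test(m$a, m$b, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(m))
}

entropy_of <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' V-measure comparison of two effort maps
#'
#' Each grid's included cells are classed into `n_classes` quantile bins of
#' `log(value + eps)` (scale-free, so the score is invariant to multiplying
#' one grid by a positive constant), and the co-located class labels form a
#' contingency table. Homogeneity is `1 - H(A|B)/H(A)`, completeness
#' `1 - H(B|A)/H(B)`, and the V-measure their harmonic mean. A single-class
#' partition has zero entropy and scores 1 on its own term, by convention.
#'
#' @param a,b Tibbles `lat`, `lon`, `value`.
#' @param n_classes Number of quantile classes (default 10).
#' @param include Inclusion rule, see [align_grids()].
#' @param eps Offset inside the log (default 1e-9 x the grid maximum).
#' @return List `vmeasure`, `homogeneity`, `completeness`, `n`.
#' @export
vmeasure_maps <- function(a, b, n_classes = 10, include = "union",
                          eps = NULL) {
  m <- align_grids(a, b, include)
  if (nrow(m) == 0) stop("empty overlap between the grids")
  bin <- function(x) {
    e <- eps %||% (1e-9 * max(x, 1e-300))
    lx <- log(x + e)
    br <- unique(quantile(lx, probs = seq(0, 1, length.out = n_classes + 1)))
    if (length(br) < 2) return(rep(1L, length(x)))
    cut(lx, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  vmeasure_from_labels(bin(m$a), bin(m$b), n = nrow(m))
}

#' V-measure from two label vectors
#'
#' The entropy arithmetic behind [vmeasure_maps()], exposed for direct use
#' on class labels.
#'
#' @param la,lb Integer or factor class labels of equal length.
#' @param n Optional cell count to report.
#' @return List `vmeasure`, `homogeneity`, `completeness`, `n`.
#' @export
vmeasure_from_labels <- function(la, lb, n = length(la)) {
  tab <- table(la, lb)
  joint <- tab / sum(tab)
  pa <- rowSums(joint); pb <- colSums(joint)
  ha <- entropy_of(pa); hb <- entropy_of(pb)
  # conditional entropies H(A|B), H(B|A)
  hab <- -sum(joint[joint > 0] *
                log(joint / rep(pb, each = nrow(joint)))[joint > 0])
  hba <- -sum(joint[joint > 0] *
                log(joint / rep(pa, times = ncol(joint)))[joint > 0])
  h <- if (ha == 0) 1 else 1 - hab / ha
  c_ <- if (hb == 0) 1 else 1 - hba / hb
  v <- if (h + c_ == 0) 0 else 2 * h * c_ / (h + c_)
  list(vmeasure = v, homogeneity = h, completeness = c_, n = n)
}

#' Cosine similarity of latitudinal and longitudinal marginals
#'
#' Each grid is summed over longitude to a latitude profile (and vice
#' versa); the cosine of the angle between the two grids' profiles measures
#' agreement at the coarser marginal scale, which is more forgiving of
#' small spatial offsets than cell-by-cell comparison.
#'
#' @param a,b Tibbles `lat`, `lon`, `value`.
#' @return List `cosine_lat`, `cosine_lon`.
#' @export
cosine_marginals <- function(a, b) {
  marg <- function(d, coord) {
    tapply(d$value, d[[coord]], sum)
  }
  cosine <- function(u, v) {
    keys <- union(names(u), names(v))
    x <- ifelse(is.na(u[keys]), 0, u[keys])
    y <- ifelse(is.na(v[keys]), 0, v[keys])
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) stop("zero marginal vector")
    sum(x * y) / (nx * ny)
  }
  list(cosine_lat = cosine(marg(a, "lat"), marg(b, "lat")),
       cosine_lon = cosine(marg(a, "lon"), marg(b, "lon")))
}

#' Mean relative error of reconstructed versus observed counts
#'
#' For each key (country, sector, and any further grouping columns), the
#' mean of `|fit - obs| / obs` over the observed years; observations equal
#' to zero are excluded from the mean and counted.
#'
#' @param fits Tibble with key columns, `year`, `fitted`.
#' @param observations Tibble with the same key columns, `year`,
#'   `n_vessels`.
#' @param by Key columns (default `c("saup", "sector")`).
#' @return Tibble of keys with `mre`, `n_obs`, `n_zero_excluded`.
#' @export
reconstruction_error_report <- function(fits, observations,
                                        by = c("saup", "sector")) {
  joined <- dplyr::inner_join(
    dplyr::select(fits, dplyr::all_of(by), "year", "fitted"),
    dplyr::select(observations, dplyr::all_of(by), "year", "n_vessels"),
    by = c(by, "year")
  )
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mre = mean(abs(.data$fitted[.data$n_vessels > 0] -
                       .data$n_vessels[.data$n_vessels > 0]) /
                   .data$n_vessels[.data$n_vessels > 0]),
      n_obs = sum(.data$n_vessels > 0),
      n_zero_excluded = sum(.data$n_vessels == 0),
      .groups = "drop"
    )
}

#' Full comparison report for two effort grids
#'
#' Bundles the cell-wise Spearman correlation, the V-measure with its
#' homogeneity and completeness components, and the marginal cosines into
#' one record, optionally per length category.
#'
#' @param a,b Tibbles `lat`, `lon`, `value`.
#' @param n_classes Quantile classes for the V-measure.
#' @param include Inclusion rule, see [align_grids()].
#' @return A one-row tibble: `spearman`, `p_value`, `vmeasure`,
#'   `homogeneity`, `completeness`, `cosine_lat`, `cosine_lon`, `n_cells`.
#' @export
compare_grids <- function(a, b, n_classes = 10, include = "union") {
  sp <- spearman_cells(a, b, include)
  vm <- vmeasure_maps(a, b, n_classes, include)
  cm <- cosine_marginals(a, b)
  tibble(
    spearman = sp$rho, p_value = sp$p_value,
    vmeasure = vm$vmeasure, homogeneity = vm$homogeneity,
    completeness = vm$completeness,
    cosine_lat = cm$cosine_lat, cosine_lon = cm$cosine_lon,
    n_cells = sp$n
  )
}
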