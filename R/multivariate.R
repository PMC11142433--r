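#' Correlation-scaled principal component analysis
#'
#' PCA of a complete-case log10 measurement matrix with every column
#' centred and scaled to unit variance, so measurements with larger
#' absolute values do not dominate the decomposition.
#'
#' @param m Numeric matrix (specimens x measurements), no missing cells,
#'   at least 3 rows and 2 columns, no zero-variance column.
#' @return An object of class `"pca_scaled"`: `scores` (specimen x PC),
#'   `loadings` (measurement x PC), `explained` (fractions of variance,
#'   summing to 1), and the fitted `prcomp` object.
#' @export
pca_scaled <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3 || ncol(m) < 2) {
    stop("need at least 3 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(m)) stop("matrix has missing cells", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation,
                 explained = expl, prcomp = p),
            class = "pca_scaled")
}

#' Two-group k-means clustering
#'
#' k-means with k = 2 fixed a priori (the dimorphism hypothesis), Lloyd's
#' algorithm with `n_start` seeded initializations; the run with the
#' smallest total within-cluster sum of squares wins. Deterministic given
#' `seed` and the data.
#'
#' @param points Numeric matrix of coordinates (e.g. PCA scores).
#' @param seed Integer seed.
#' @param n_start Number of random initializations (default 50).
#' @return An object of class `"cluster_two"`: `labels` (1/2 per row),
#'   `centers`, `tot_withinss`, `seed`.
#' @export
kmeans_two <- function(points, seed = 1L, n_start = 50L) {
  points <- as.matrix(points)
  if (nrow(unique(points)) < 2) {
    stop("need at least 2 distinct points", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(points, centers = 2, nstart = n_start,
                      algorithm = "Lloyd", iter.max = 100)
  structure(list(labels = km$cluster, centers = km$centers,
                 tot_withinss = km$tot.withinss, seed = seed),
            class = "cluster_two")
}

#' Agreement between a clustering and a morph labelling
#'
#' Cluster ids are arbitrary, so agreement is maximized over the two
#' possible id permutations. Ambiguous morph labels must be excluded by
#' the caller.
#'
#' @param cluster_labels Vector with two distinct values.
#' @param morph_labels Vector of the same length with two distinct values.
#' @return Agreement fraction in \[0.5, 1\].
#' @export
concordance <- function(cluster_labels, morph_labels) {
  if (length(cluster_labels) != length(morph_labels)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  cl <- as.integer(factor(cluster_labels))
  mo <- as.integer(factor(morph_labels))
  max(mean(cl == mo), mean(cl == 3L - mo))
}

# --- convex-hull overlap in the PC1/PC2 plane ------------------------------

on_segment <- function(p, q, r) {
  q[1] <= max(p[1], r[1]) + 1e-12 && q[1] >= min(p[1], r[1]) - 1e-12 &&
  q[2] <= max(p[2], r[2]) + 1e-12 && q[2] >= min(p[2], r[2]) - 1e-12
}

orient <- function(p, q, r) {
  v <- (q[2] - p[2]) * (r[1] - q[1]) - (q[1] - p[1]) * (r[2] - q[2])
  if (abs(v) < 1e-12) 0L else if (v > 0) 1L else 2L
}

segments_intersect <- function(p1, q1, p2, q2) {
  o1 <- orient(p1, q1, p2); o2 <- orient(p1, q1, q2)
  o3 <- orient(p2, q2, p1); o4 <- orient(p2, q2, q1)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_segment(p1, p2, q1)) ||
  (o2 == 0 && on_segment(p1, q2, q1)) ||
  (o3 == 0 && on_segment(p2, p1, q2)) ||
  (o4 == 0 && on_segment(p2, q1, q2))
}

point_in_hull <- function(pt, hull) {
  n <- nrow(hull)
  if (n == 1) return(all(abs(pt - hull[1, ]) < 1e-12))
  if (n == 2) return(orient(hull[1, ], hull[2, ], pt) == 0 &&
                     on_segment(hull[1, ], pt, hull[2, ]))
  sgn <- 0L
  for (i in seq_len(n)) {
    o <- orient(hull[i, ], hull[i %% n + 1, ], pt)
    if (o == 0L) next
    if (sgn == 0L) sgn <- o else if (o != sgn) return(FALSE)
  }
  TRUE
}

#' Do the 2-D convex hulls of two point sets intersect?
#'
#' Operationalizes the visual "do the clusters overlap" judgment: clusters
#' are called overlapping when their convex hulls in the first two
#' principal components intersect (shared boundary counts as overlap).
#' Handles degenerate hulls (1 or 2 points).
#'
#' @param a,b Two-column numeric matrices of points.
#' @return Logical.
#' @export
hulls_overlap <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ha <- a[grDevices::chull(a), , drop = FALSE]
  hb <- b[grDevices::chull(b), , drop = FALSE]
  edges <- function(h) {
    n <- nrow(h)
    if (n == 1) list(list(h[1, ], h[1, ]))
    else lapply(seq_len(n), function(i) list(h[i, ], h[i %% n + 1, ]))
  }
  for (ea in edges(ha)) for (eb in edges(hb)) {
    if (segments_intersect(ea[[1]], ea[[2]], eb[[1]], eb[[2]])) return(TRUE)
  }
  any(apply(ha, 1, point_in_hull, hull = hb)) ||
    any(apply(hb, 1, point_in_hull, hull = ha))
}

#' PCA + k-means pipeline on a measurement subset
#'
#' Extracts the complete cases of an element for a set of measurement
#' codes, log10-transforms, runs the correlation-scaled PCA, clusters all
#' PC scores into two groups, and flags whether the two clusters' convex
#' hulls overlap in the PC1/PC2 plane. Used both for the full per-element
#' analysis and for the reruns that drop individual measurements.
#'
#' @param table A measurement table.
#' @param element Element name.
#' @param codes Measurement codes to include (>= 2).
#' @param seed Seed for k-means.
#' @return A list: `pca` (`pca_scaled`), `clusters` (`cluster_two`),
#'   `overlap` (logical), `separation` (the gap between the two clusters
#'   along the line joining their centers in the PC1/PC2 plane, divided
#'   by the SD of all points projected on that line; near or below zero
#'   for a continuous cloud cut in half, clearly positive when there is
#'   visual daylight between the groups), `specimen_id`, `n`, `codes`.
#' @export
subset_rerun <- function(table, element, codes, seed = 1L) {
  if (length(codes) < 2) stop("need at least 2 measurement codes",
                              call. = FALSE)
  cc <- complete_cases(table, element, codes)
  m <- sapply(codes, function(code) log10_values(cc, element, code))
  m <- matrix(m, ncol = length(codes),
              dimnames = list(cc$specimen_id, codes))
  pca <- pca_scaled(m)
  cl <- kmeans_two(pca$scores, seed = seed)
  s12 <- pca$scores[, 1:2, drop = FALSE]
  g1 <- s12[cl$labels == 1, , drop = FALSE]
  g2 <- s12[cl$labels == 2, , drop = FALSE]
  ov <- hulls_overlap(g1, g2)
  # normalized daylight between the clusters along the line joining
  # their centers; a continuum cut in half scores near zero, two truly
  # separate groups score clearly positive
  u <- colMeans(g2) - colMeans(g1)
  u <- u / sqrt(sum(u^2))
  p1 <- drop(g1 %*% u); p2 <- drop(g2 %*% u)
  if (mean(p1) > mean(p2)) { tmp <- p1; p1 <- p2; p2 <- tmp }
  sep <- (min(p2) - max(p1)) / stats::sd(c(p1, p2))
  list(pca = pca, clusters = cl, overlap = ov, separation = sep,
       specimen_id = cc$specimen_id, n = nrow(m), codes = codes)
}
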