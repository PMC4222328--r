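#' ROI window mean of an ERP
#'
#' Mean amplitude over the ROI channels and the in-window samples
#' (half-open window, `t >= lo & t < hi`).
#'
#' @param erp an `mmn_erp`.
#' @param window `c(lo, hi)` in seconds.
#' @param roi character vector of channel names.
#' @return Scalar mean amplitude, microvolts.
#' @export
window_mean <- function(erp, window, roi) {
  stopifnot(inherits(erp, "mmn_erp"))
  i <- match(roi, erp$channel_names)
  if (anyNA(i))
    stop("config error: ROI channel(s) missing: ",
         paste(roi[is.na(i)], collapse = ", "), call. = FALSE)
  sel <- in_window(erp$times, window)
  if (!any(sel))
    stop("config error: window contains no samples", call. = FALSE)
  mean(erp$data[i, sel])
}

#' Analysis windows of the sensor-space statistics
#'
#' The four deflection windows examined at the fronto-central ROI: an early
#' negativity (40-80 ms), the main MMN window (135-175 ms), the following
#' positivity (230-270 ms), and a late negativity (340-500 ms), all
#' relative to the divergence-locked time zero.
#'
#' @return Named list of `c(lo, hi)` windows in seconds.
#' @export
default_windows <- function() {
  list(early = c(0.040, 0.080), mmn = c(0.135, 0.175),
       p2 = c(0.230, 0.270), late = c(0.340, 0.500))
}

#' Assemble a 2x2 within-subject condition table
#'
#' @param values subjects x 4 matrix of condition amplitudes (microvolts),
#'   no missing cells, >= 2 subjects.
#' @param root,suffix length-4 factor-level assignments of the columns.
#' @return An `mmn_condition_table`.
#' @export
condition_table <- function(values,
                            root = c("A1", "A1", "A2", "A2"),
                            suffix = c("B1", "B2", "B1", "B2")) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 4, nrow(values) >= 2, !anyNA(values),
            length(root) == 4, length(suffix) == 4)
  structure(list(values = values,
                 factors = data.frame(condition = colnames(values) %||%
                                        paste0("c", 1:4),
                                      root = root, suffix = suffix,
                                      stringsAsFactors = FALSE)),
            class = "mmn_condition_table")
}

## per-subject contrast scores for the three effects of a 2x2 table
effect_contrast <- function(tab, effect) {
  f <- tab$factors
  r <- f$root == f$root[1]
  s <- f$suffix == f$suffix[1]
  w <- switch(effect,
              root = ifelse(r, 1, -1),
              suffix = ifelse(s, 1, -1),
              interaction = ifelse(r, 1, -1) * ifelse(s, 1, -1),
              stop("unknown effect: ", effect, call. = FALSE))
  drop(tab$values %*% w)
}

## one-sample F (df 1, n-1) on contrast scores: equals the squared paired t
contrast_f <- function(d) {
  n <- length(d)
  v <- var(d)
  if (v == 0)
    stop("degenerate-data error: zero contrast variance", call. = FALSE)
  f <- n * mean(d)^2 / v
  list(F = f, df1 = 1L, df2 = n - 1L, p = pf(f, 1, n - 1, lower.tail = FALSE))
}

#' 2x2 repeated-measures ANOVA
#'
#' Computes each effect (main effect of ROOT, main effect of SUFFIX, and
#' their interaction) from per-subject contrast scores: with cell means
#' `c11, c12, c21, c22` per subject, main ROOT uses
#' `(c11 + c12) - (c21 + c22)`, main SUFFIX `(c11 - c12) + (c21 - c22)`,
#' and the interaction `(c11 - c12) - (c21 - c22)`. For a two-level
#' within-subject factor the contrast F with `df = (1, n - 1)` is exactly
#' the classical repeated-measures ANOVA F (and the squared paired t).
#'
#' @param tab an [condition_table()].
#' @return Data frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
rm_anova_2x2 <- function(tab) {
  stopifnot(inherits(tab, "mmn_condition_table"))
  rows <- lapply(c("root", "suffix", "interaction"), function(e) {
    res <- tryCatch(contrast_f(effect_contrast(tab, e)),
                    error = function(err)
                      stop("degenerate-data error for effect '", e, "': ",
                           conditionMessage(err), call. = FALSE))
    data.frame(effect = e, F = res$F, df1 = res$df1, df2 = res$df2,
               p = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Planned pairwise comparison
#'
#' Paired F test with `df = (1, n - 1)` (the squared paired t) on the
#' per-subject difference of two conditions; p-values are uncorrected.
#'
#' @param a,b paired per-subject condition values.
#' @return List `F`, `df1`, `df2`, `p`.
#' @export
planned_comparison <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  contrast_f(a - b)
}

#' Critical F threshold
#'
#' Upper-tail quantile of the F distribution; `f_critical(0.05, 1, 25)` is
#' 4.24 to two decimals, the voxel threshold used by the cluster test at
#' n = 26.
#'
#' @param alpha upper-tail probability (default 0.05).
#' @param df1,df2 degrees of freedom.
#' @return The threshold.
#' @export
f_critical <- function(alpha = 0.05, df1 = 1, df2) {
  if (!(alpha > 0 && alpha < 1) || df1 < 1 || df2 < 1)
    stop("config error: invalid alpha or degrees of freedom", call. = FALSE)
  qf(alpha, df1, df2, lower.tail = FALSE)
}

## ---- 3D volumes ----------------------------------------------------------

## Thin-plate-spline scatter interpolation matrix: rows map channel values
## to the listed plane points. Reproduces affine fields exactly and is
## exact at the nodes.
tps_matrix <- function(nodes, targets) {
  n <- nrow(nodes)
  U <- function(r2) ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  d2 <- outer(nodes[, 1], nodes[, 1], "-")^2 +
    outer(nodes[, 2], nodes[, 2], "-")^2
  K <- U(d2)
  P <- cbind(1, nodes)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  d2t <- outer(targets[, 1], nodes[, 1], "-")^2 +
    outer(targets[, 2], nodes[, 2], "-")^2
  E <- cbind(U(d2t), 1, targets)
  (E %*% solve(M))[, seq_len(n), drop = FALSE]
}

#' Convert per-subject condition ERPs to 3D volumes
#'
#' Per time frame, scatters channel values to their projected grid cells
#' and interpolates the remaining in-hull cells with a thin-plate spline
#' evaluated at cell centers (node-exact; affine fields are reproduced
#' exactly). Out-of-hull voxels are invalid and excluded from all
#' statistics. The two grid axes and the time axis form the 3D volume the
#' cluster statistics operate on.
#'
#' @param erps list of subjects, each a named list of condition `mmn_erp`
#'   objects on a common grid.
#' @param proj an `mmn_projection` of the montage the ERPs were recorded
#'   with.
#' @param time_window optional `c(lo, hi)` seconds restricting the frames
#'   (half-open); default the full epoch.
#' @param root,suffix factor-level assignment of the conditions (defaults
#'   assume the order c11, c12, c21, c22).
#' @return An `mmn_volume_stack`: `data` (subjects x conditions x voxels),
#'   `vox_index` (0-based grid index per voxel), `dims` (nx, ny, frames),
#'   `times`, `cells`, `factors`, `conditions`.
#' @export
erps_to_volumes <- function(erps, proj, time_window = NULL,
                            root = c("A1", "A1", "A2", "A2"),
                            suffix = c("B1", "B2", "B1", "B2")) {
  stopifnot(length(erps) >= 1, inherits(proj, "mmn_projection"))
  conditions <- names(erps[[1]])
  e1 <- erps[[1]][[1]]
  if (!all(proj$channel %in% e1$channel_names))
    stop("input error: projection channels missing from ERPs", call. = FALSE)
  sel <- if (is.null(time_window)) rep(TRUE, length(e1$times)) else
    in_window(e1$times, time_window)
  times <- e1$times[sel]
  nx <- proj$grid_size[1]; ny <- proj$grid_size[2]; nt <- length(times)
  cells <- which(proj$valid_mask, arr.ind = TRUE)
  W <- tps_matrix(proj$plane_cells, cells)
  ## electrode-bearing cells take the channel value exactly (scatter)
  cell_key <- paste(cells[, 1], cells[, 2])
  node_key <- paste(proj$cell[, 1], proj$cell[, 2])
  hit <- match(node_key, cell_key)
  W[hit, ] <- 0
  W[cbind(hit, seq_along(hit))] <- 1
  n_cells <- nrow(cells)
  vox_index <- as.integer(
    rep(cells[, 1] - 1L + nx * (cells[, 2] - 1L), times = nt) +
      nx * ny * rep(seq_len(nt) - 1L, each = n_cells))
  chan_rows <- match(proj$channel, e1$channel_names)
  data <- array(NA_real_,
                c(length(erps), length(conditions), n_cells * nt))
  for (s in seq_along(erps)) {
    for (k in seq_along(conditions)) {
      erp <- erps[[s]][[conditions[k]]]
      data[s, k, ] <- as.vector(W %*% erp$data[chan_rows, sel, drop = FALSE])
    }
  }
  structure(list(data = data, vox_index = vox_index,
                 dims = c(nx, ny, nt), times = times, cells = cells,
                 conditions = conditions,
                 factors = data.frame(condition = conditions, root = root,
                                      suffix = suffix,
                                      stringsAsFactors = FALSE)),
            class = "mmn_volume_stack")
}

#' Label suprathreshold voxels into face-connected clusters
#'
#' Connected-component labelling of the valid voxels of a 3D statistic map
#' under face (6-neighbour) adjacency.
#'
#' @param supra logical vector over valid voxels.
#' @param vox_index 0-based full-grid linear index per valid voxel.
#' @param dims grid dimensions `c(nx, ny, nt)`.
#' @return Integer cluster labels (0 = subthreshold).
#' @export
label_clusters <- function(supra, vox_index, dims) {
  label_clusters_cpp(as.logical(supra), as.integer(vox_index),
                     as.integer(dims))
}

#' Monte-Carlo p-value of a cluster mass
#'
#' The `"count"` convention (`#(null >= mass) / n_perm`) matches the
#' printed arithmetic `965 of 1000 below` to `p = 0.035`; ties count toward
#' the null. The `(k + 1) / (n + 1)` convention is available as
#' `"plus-one"`.
#'
#' @param mass observed cluster mass.
#' @param null_masses vector of null maximum cluster masses.
#' @param convention `"count"` (default) or `"plus-one"`.
#' @return The p-value.
#' @export
perm_p <- function(mass, null_masses, convention = c("count", "plus-one")) {
  convention <- match.arg(convention)
  k <- sum(null_masses >= mass)
  if (convention == "count") k / length(null_masses)
  else (k + 1) / (length(null_masses) + 1)
}

## voxel-wise one-sample F map from per-subject contrasts (n x V)
voxel_f_map <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  ss <- colSums(D^2)
  v <- (ss - n * m^2) / (n - 1)
  ifelse(v > 1e-300, n * m^2 / v, ifelse(abs(m) > 1e-150, 1e12, 0))
}

#' Cluster-mass permutation test on sensor x time volumes
#'
#' Forms per-subject effect-contrast volumes, computes the voxel-wise
#' repeated-measures F map (contrast formulation, df 1, n - 1), thresholds
#' it, labels suprathreshold voxels into face-connected 3D clusters, and
#' weighs each cluster by the sum of its member F ratios. The null
#' distribution of the maximum cluster mass is built by sign-flipping every
#' subject's contrast volume independently with probability one half
#' (exact under within-subject exchangeability of the factor labelling),
#' re-deriving the F map, threshold, and labelling each iteration. Each
#' observed cluster's p-value is the fraction of null maxima at least as
#' heavy.
#'
#' @param vols an `mmn_volume_stack`.
#' @param effect `"interaction"` (default), `"root"`, or `"suffix"`.
#' @param f_threshold voxel threshold; default `f_critical(alpha, 1,
#'   n - 1)`.
#' @param alpha threshold level used when `f_threshold` is NULL (default
#'   0.05).
#' @param n_perm Monte-Carlo iterations (default 1000).
#' @param seed integer seed for the sign flips.
#' @param p_convention passed to [perm_p()].
#' @return An `mmn_cluster_result`: `clusters` (data.frame with `id`,
#'   `n_voxels`, `mass`, `p`, time extent in ms), `labels`, `f_map`,
#'   `null_max_masses`, `f_threshold`, `effect`, `seed`, `connectivity`.
#' @export
cluster_permutation <- function(vols, effect = "interaction",
                                f_threshold = NULL, alpha = 0.05,
                                n_perm = 1000, seed = 1,
                                p_convention = "count") {
  stopifnot(inherits(vols, "mmn_volume_stack"))
  if (n_perm < 1) stop("config error: n_perm must be >= 1", call. = FALSE)
  n <- dim(vols$data)[1]
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  tabf <- structure(list(values = diag(4), factors = vols$factors),
                    class = "mmn_condition_table")
  w <- switch(effect,
              root = effect_contrast(tabf, "root"),
              suffix = effect_contrast(tabf, "suffix"),
              interaction = effect_contrast(tabf, "interaction"),
              stop("unknown effect: ", effect, call. = FALSE))
  ## n x V per-subject contrast volumes
  D <- matrix(0, n, dim(vols$data)[3])
  for (k in seq_along(w))
    if (w[k] != 0) D <- D + w[k] * vols$data[, k, ]
  if (is.null(f_threshold)) f_threshold <- f_critical(alpha, 1, n - 1)
  fmap <- voxel_f_map(D)
  supra <- fmap > f_threshold
  labels <- label_clusters(supra, vols$vox_index, vols$dims)
  rng <- local_rng(seed)
  signs <- matrix(rng(sample(c(-1L, 1L), n_perm * n, replace = TRUE)),
                  n_perm, n)
  null_max <- perm_null_max_mass(D, vols$vox_index, vols$dims, f_threshold,
                                 signs)
  if (max(labels) > 0) {
    frame_of <- rep(seq_len(vols$dims[3]), each = nrow(vols$cells))
    cl <- lapply(seq_len(max(labels)), function(id) {
      mem <- labels == id
      fr <- frame_of[mem]
      data.frame(id = id, n_voxels = sum(mem),
                 mass = sum(fmap[mem]),
                 t_min_ms = 1000 * min(vols$times[fr]),
                 t_max_ms = 1000 * max(vols$times[fr]))
    })
    clusters <- do.call(rbind, cl)
    clusters$p <- vapply(clusters$mass, perm_p, numeric(1),
                         null_masses = null_max, convention = p_convention)
    clusters <- clusters[order(-clusters$mass), , drop = FALSE]
  } else {
    clusters <- data.frame(id = integer(0), n_voxels = integer(0),
                           mass = numeric(0), t_min_ms = numeric(0),
                           t_max_ms = numeric(0), p = numeric(0))
  }
  structure(list(clusters = clusters, labels = labels, f_map = fmap,
                 null_max_masses = as.numeric(null_max),
                 f_threshold = f_threshold, effect = effect, seed = seed,
                 connectivity = 6L, n_perm = n_perm,
                 p_convention = p_convention),
            class = "mmn_cluster_result")
}

#' @export
print.mmn_cluster_result <- function(x, ...) {
  cat(sprintf("<mmn_cluster_result> effect=%s, F>%.3f, %d clusters, %d permutations\n",
              x$effect, x$f_threshold, nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

## half-open window selection with a sub-nanosecond guard against
## floating-point drift of the time grid
in_window <- function(times, window) {
  times >= window[1] - 1e-9 & times < window[2] - 1e-9
}
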