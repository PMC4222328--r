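#' @useDynLib mmnpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var cor median fft qf pf setNames
#' @importFrom stats nextn mvfft
#' @importFrom utils read.table write.table write.csv read.csv
#' @importFrom grDevices chull
NULL

CHANNEL_ROLES <- c("EEG", "EOG", "REFERENCE")

#' Construct an electrode montage
#'
#' A montage holds an ordered set of named channels with 3D head-centered
#' positions (right-anterior-superior: +x right, +y anterior, +z superior,
#' vertex at +z) and named regions of interest (ROIs).
#'
#' @param name character vector of channel labels (non-empty, unique).
#' @param position numeric matrix (n x 3) of channel coordinates.
#' @param role character vector, each one of `"EEG"`, `"EOG"`, `"REFERENCE"`.
#'   Defaults to `"EOG"` for names starting with `"EOG"`, `"EEG"` otherwise.
#' @param rois named list of character vectors; every member must name an
#'   existing channel.
#' @return An object of class `mmn_montage`: a list with elements
#'   `channels` (data.frame name/x/y/z/role) and `rois`.
#' @export
montage <- function(name, position, role = NULL, rois = list()) {
  name <- as.character(name)
  if (length(name) == 0L || anyNA(name) || any(!nzchar(name)))
    stop("channel names must be non-empty", call. = FALSE)
  if (anyDuplicated(name))
    stop("format error: duplicate channel names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  position <- matrix(as.numeric(position), ncol = 3)
  if (nrow(position) != length(name))
    stop("position must have one row per channel", call. = FALSE)
  if (any(!is.finite(position)))
    stop("channel positions must be finite", call. = FALSE)
  if (is.null(role))
    role <- ifelse(startsWith(name, "EOG"), "EOG", "EEG")
  role <- match.arg(role, CHANNEL_ROLES, several.ok = TRUE)
  role <- rep_len(role, length(name))
  if (!any(role == "EEG"))
    stop("montage must contain at least one EEG channel", call. = FALSE)
  channels <- data.frame(name = name, x = position[, 1], y = position[, 2],
                         z = position[, 3], role = role,
                         stringsAsFactors = FALSE)
  m <- structure(list(channels = channels, rois = list()),
                 class = "mmn_montage")
  for (rn in names(rois)) m <- add_roi(m, rn, rois[[rn]])
  m
}

#' @export
print.mmn_montage <- function(x, ...) {
  cat(sprintf("<mmn_montage> %d channels (%d EEG, %d EOG), %d ROI(s)\n",
              nrow(x$channels), sum(x$channels$role == "EEG"),
              sum(x$channels$role == "EOG"), length(x$rois)))
  invisible(x)
}

#' Attach a region of interest to a montage
#'
#' @param m an `mmn_montage`.
#' @param name ROI name.
#' @param members character vector of channel names already in the montage.
#' @return The montage with the ROI attached.
#' @export
add_roi <- function(m, name, members) {
  members <- as.character(members)
  missing <- setdiff(members, m$channels$name)
  if (length(missing))
    stop("config error: ROI '", name, "' references unknown channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m$rois[[name]] <- members
  m
}

eeg_channels <- function(m) m$channels$name[m$channels$role == "EEG"]

#' Read an electrode-position file
#'
#' Reads a whitespace-delimited `.sfp`-style file with one `name x y z` row
#' per channel. Channel roles default from the name (an `EOG` prefix marks
#' ocular channels). Positions are optionally rescaled to the unit sphere;
#' the pipeline only uses angular information so the length unit is
#' immaterial.
#'
#' @param path path to the position file.
#' @param roi_spec named list of channel-name vectors, or a path to a YAML
#'   file mapping ROI name to a channel list.
#' @param normalize logical; rescale each position to unit norm (default TRUE).
#' @return An `mmn_montage`.
#' @export
load_montage <- function(path, roi_spec = NULL, normalize = TRUE) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("name", "x", "y", "z"))
  pos <- as.matrix(tab[, c("x", "y", "z")])
  if (normalize) {
    nrm <- sqrt(rowSums(pos^2))
    if (any(nrm == 0)) stop("format error: zero-length position", call. = FALSE)
    pos <- pos / nrm
  }
  if (is.character(roi_spec) && length(roi_spec) == 1L)
    roi_spec <- yaml::read_yaml(roi_spec)
  if (is.null(roi_spec)) roi_spec <- list()
  montage(tab$name, pos, rois = roi_spec)
}

#' Write a montage to an electrode-position file
#'
#' @param m an `mmn_montage`.
#' @param path output path (`name x y z` per line, whitespace-delimited).
#' @export
write_montage <- function(m, path) {
  df <- m$channels[, c("name", "x", "y", "z")]
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Azimuthal-equidistant projection of a unit vector about +z:
## plane radius = polar angle (radians), direction = azimuth.
azimuthal_xy <- function(pos) {
  pos <- pos / sqrt(rowSums(pos^2))
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))
  rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  u <- ifelse(rho > 0, theta * pos[, 1] / rho, 0)
  v <- ifelse(rho > 0, theta * pos[, 2] / rho, 0)
  cbind(u = u, v = v)
}

## Nominal plane position of the FCz site (midline, ~23 deg anterior of
## vertex) used as the default fronto-central ROI center.
FCZ_PLANE <- c(0, 23 * pi / 180)

#' Project EEG electrode positions to a flat grid
#'
#' Applies an azimuthal-equidistant projection about the vertex (+z), which
#' preserves radial distances from the vertex and is the standard flat-map
#' convention for EEG, then linearly rescales the plane into an integer grid.
#' The electrode-plane grid supplies the two spatial axes of the 3D
#' (space x space x time) volumes used by the cluster statistics.
#'
#' @param m an `mmn_montage` with at least 3 non-collinear EEG positions.
#' @param grid_size integer pair, cells per axis (default `c(32, 32)`).
#' @return An object of class `mmn_projection`: `channel` (EEG names),
#'   `plane` (continuous u/v), `cell` (integer cell per channel),
#'   `grid_size`, `valid_mask` (logical matrix, TRUE inside the electrode
#'   convex hull), and `cell_center` coordinates.
#' @export
project_to_plane <- function(m, grid_size = c(32, 32)) {
  grid_size <- as.integer(rep_len(grid_size, 2L))
  if (any(grid_size < 2L)) stop("config error: grid too small", call. = FALSE)
  eeg <- m$channels[m$channels$role == "EEG", , drop = FALSE]
  if (nrow(eeg) < 3L) stop("need at least 3 EEG channels", call. = FALSE)
  uv <- azimuthal_xy(as.matrix(eeg[, c("x", "y", "z")]))
  if (qr(cbind(1, uv))$rank < 3L)
    stop("EEG positions are collinear after projection", call. = FALSE)
  rmax <- max(abs(uv), sqrt(.Machine$double.eps))
  ## symmetric center-based cell mapping: vertex -> center cell, mirror
  ## electrodes -> mirror cells
  ctr <- floor(grid_size / 2) + 1L
  scl <- (grid_size / 2 - 1) / rmax
  cell <- cbind(ctr[1] + as.integer(round(uv[, 1] * scl[1])),
                ctr[2] + as.integer(round(uv[, 2] * scl[2])))
  key <- paste(cell[, 1], cell[, 2])
  if (anyDuplicated(key))
    stop("config error: grid ", grid_size[1], "x", grid_size[2],
         " too small to give distinct cells to all EEG channels",
         call. = FALSE)
  if (any(cell < 1L) || any(cell[, 1] > grid_size[1]) ||
      any(cell[, 2] > grid_size[2]))
    stop("config error: projected cells out of grid bounds", call. = FALSE)
  ## continuous coordinates of each channel in cell units (for interpolation)
  plane_cells <- cbind(ctr[1] + uv[, 1] * scl[1], ctr[2] + uv[, 2] * scl[2])
  hull <- chull(plane_cells)
  hx <- plane_cells[hull, 1]; hy <- plane_cells[hull, 2]
  valid <- matrix(FALSE, grid_size[1], grid_size[2])
  gx <- rep(seq_len(grid_size[1]), times = grid_size[2])
  gy <- rep(seq_len(grid_size[2]), each = grid_size[1])
  inside <- point_in_poly(gx, gy, hx, hy)
  valid[cbind(gx[inside], gy[inside])] <- TRUE
  valid[cell] <- TRUE  # every mapped cell is valid by construction
  structure(list(channel = eeg$name, plane = uv, cell = cell,
                 plane_cells = plane_cells, grid_size = grid_size,
                 valid_mask = valid,
                 fcz_cell = c(ctr[1] + FCZ_PLANE[1] * scl[1],
                              ctr[2] + FCZ_PLANE[2] * scl[2])),
            class = "mmn_projection")
}

## Ray-casting point-in-polygon, boundary-inclusive within eps.
point_in_poly <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    ## boundary: distance to segment within eps
    dx <- vx[j] - vx[i]; dy <- vy[j] - vy[i]
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - vx[i]) * dx + (py - vy[i]) * dy) / L2)) else 0
    d2 <- (px - (vx[i] + t * dx))^2 + (py - (vy[i] + t * dy))^2
    inside <- inside | (d2 < eps)
    j <- i
  }
  inside
}

#' Default fronto-central ROI for a synthetic montage
#'
#' Selects the `n` EEG channels nearest (by projected-plane distance) to the
#' nominal FCz site. Real analyses should supply their own ROI channel list;
#' this default only serves simulated montages, where no canonical channel
#' names exist.
#'
#' @param m an `mmn_montage`.
#' @param n ROI size (default 46, capped at the number of EEG channels).
#' @param proj optional precomputed `mmn_projection`.
#' @return Character vector of channel names.
#' @export
frontocentral_roi <- function(m, n = 46, proj = NULL) {
  if (is.null(proj)) proj <- project_to_plane(m)
  n <- min(n, length(proj$channel))
  d <- sqrt((proj$plane[, 1] - FCZ_PLANE[1])^2 +
            (proj$plane[, 2] - FCZ_PLANE[2])^2)
  proj$channel[order(d)][seq_len(n)]
}

#' Generate a synthetic electrode cap
#'
#' Builds a ring layout on the upper head surface (one vertex electrode plus
#' concentric rings, back-projected from the azimuthal-equidistant plane),
#' with three periocular EOG channels (above/below the left eye and lateral
#' to the right eye), emulating a high-density active-electrode cap. The
#' default emulates a 128-channel recording arrangement.
#'
#' @param n_eeg number of EEG channels (default 128).
#' @param roi_size fronto-central ROI size attached as ROI
#'   `"frontocentral"` (default 46, capped at `n_eeg`); `0` skips the ROI.
#' @return An `mmn_montage` with `n_eeg` EEG channels and 3 EOG channels.
#' @export
synthetic_montage <- function(n_eeg = 128, roi_size = 46) {
  stopifnot(n_eeg >= 4)
  ## ring counts proportional to circumference, vertex electrode first
  theta_max <- 1.55  # just below the ear line (pi/2)
  n_rings <- max(2L, round(sqrt(n_eeg) * 0.62))
  radii <- theta_max * seq_len(n_rings) / n_rings
  w <- radii / sum(radii)
  ## cumulative-rounding allocation: counts sum exactly to n_eeg - 1
  counts <- diff(c(0L, round(cumsum(w) * (n_eeg - 1L))))
  u <- 0; v <- 0
  for (r in seq_len(n_rings)) {
    k <- counts[r]
    ang <- 2 * pi * (seq_len(k) - 1L) / k + (r %% 2) * pi / k + pi / 2
    u <- c(u, radii[r] * cos(ang))
    v <- c(v, radii[r] * sin(ang))
  }
  theta <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  pos <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  names_eeg <- c("Cz", sprintf("E%03d", seq_len(n_eeg - 1L)))
  eog_pos <- rbind(c(-0.31, 0.95, -0.05),   # above left eye
                   c(-0.31, 0.93, -0.28),   # below left eye
                   c(0.59, 0.76, -0.18))    # lateral to right eye
  m <- montage(c(names_eeg, "EOGup", "EOGlow", "EOGlat"),
               rbind(pos, eog_pos),
               role = c(rep("EEG", n_eeg), rep("EOG", 3)))
  if (roi_size > 0)
    m <- add_roi(m, "frontocentral", frontocentral_roi(m, roi_size))
  m
}
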