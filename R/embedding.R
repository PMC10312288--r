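#' Embed vectorized functional networks in two dimensions
#'
#' Unsupervised 2D embedding of FN adjacency vectors. The default backend is
#' the UMAP algorithm (cosine metric), run through the `umap-learn` Python
#' package via a subprocess, with the mode-specific parameters used for the
#' published figures: full-trial FNs use `n_neighbors = 50, min_dist = 1`;
#' temporal FNs (all trials and windows embedded jointly) use
#' `n_neighbors = 100, min_dist = 0.1`. A pure-R `"pca"` backend (principal
#' components of L2-normalized vectors, an approximation of cosine geometry)
#' is provided for environments without Python; it preserves the contract
#' but not UMAP's manifold layout.
#'
#' No label information enters the embedding.
#'
#' @param vectors matrix (samples x features), e.g. rows from
#'   [vectorize_fn()]
#' @param mode `"full_trial"` or `"temporal"` (sets the UMAP parameters)
#' @param seed integer seed (UMAP `random_state`)
#' @param backend `"umap"` (default) or `"pca"`
#' @param n_neighbors,min_dist override the mode's parameters
#' @param metadata optional data.frame (one row per sample) carried through
#' @return object of class `embedding_result`: `coords` (samples x 2),
#'   `metadata`, `params`
#' @export
embed_fns <- function(vectors, mode = c("full_trial", "temporal"), seed = 1L,
                      backend = c("umap", "pca"), n_neighbors = NULL,
                      min_dist = NULL, metadata = NULL) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  vectors <- as.matrix(vectors)
  if (is.null(n_neighbors))
    n_neighbors <- if (mode == "full_trial") 50L else 100L
  if (is.null(min_dist))
    min_dist <- if (mode == "full_trial") 1 else 0.1
  if (nrow(vectors) < n_neighbors)
    stop(sprintf(paste("fewer samples (%d) than n_neighbors (%d);",
                       "reduce n_neighbors"), nrow(vectors), n_neighbors))
  coords <- if (backend == "umap")
    umap_subprocess(vectors, n_neighbors, min_dist, seed)
  else
    pca_cosine_2d(vectors)
  params <- list(mode = mode, backend = backend, n_neighbors = n_neighbors,
                 min_dist = min_dist, metric = "cosine", seed = seed)
  structure(list(coords = coords, metadata = metadata, params = params),
            class = "embedding_result")
}

umap_subprocess <- function(vectors, n_neighbors, min_dist, seed) {
  python <- Sys.which("python")
  if (python == "")
    stop("python not found on PATH; use backend = \"pca\"")
  dir <- tempfile("umap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  in_path <- file.path(dir, "x.csv")
  out_path <- file.path(dir, "emb.csv")
  utils::write.table(vectors, in_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(
    paste0("import warnings, numpy as np\n",
           "warnings.filterwarnings('ignore')\n",
           "import umap\n",
           "x = np.loadtxt(%s, delimiter=',', ndmin=2)\n",
           "e = umap.UMAP(n_components=2, n_neighbors=%d, min_dist=%s,\n",
           "              metric='cosine', random_state=%d).fit_transform(x)\n",
           "np.savetxt(%s, e, delimiter=',')\n"),
    deparse(in_path), n_neighbors, format(min_dist), as.integer(seed),
    deparse(out_path))
  script_path <- file.path(dir, "run.py")
  writeLines(script, script_path)
  status <- system2(python, script_path, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out_path))
    stop("umap subprocess failed; use backend = \"pca\"")
  as.matrix(utils::read.table(out_path, sep = ","))
}

# first two principal components of row-normalized vectors
pca_cosine_2d <- function(vectors) {
  nrm <- sqrt(rowSums(vectors^2))
  nrm[nrm == 0] <- 1
  xn <- vectors / nrm
  xc <- scale(xn, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = 2, nv = 0)
  coords <- sv$u %*% diag(sv$d[1:2], 2, 2)
  dimnames(coords) <- NULL
  coords
}

#' Interpolate a smooth trajectory through embedded windows
#'
#' Spline path through the 2D embedding of one trial's temporal FNs, ordered
#' by window time (natural cubic splines of x and y against time; linear
#' when fewer than 4 knots). The path passes through every knot.
#'
#' @param coords matrix (knots x 2), ordered by time
#' @param times knot times (default: indices)
#' @param n_points samples along the dense path (default 200)
#' @return data.frame with `t`, `x`, `y`
#' @export
interpolate_trajectory <- function(coords, times = seq_len(nrow(coords)),
                                   n_points = 200L) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least 2 points")
  method <- if (nrow(coords) >= 4) "natural" else "linear"
  tt <- seq(min(times), max(times), length.out = n_points)
  interp <- function(v) {
    if (method == "linear") stats::approx(times, v, xout = tt)$y
    else stats::splinefun(times, v, method = "natural")(tt)
  }
  data.frame(t = tt, x = interp(coords[, 1]), y = interp(coords[, 2]))
}

#' Per-direction density contours of embedded networks
#'
#' Bivariate kernel density estimate (Scott-style normal-reference
#' bandwidth, via [MASS::kde2d()]) of the embedded (x, y) positions for each
#' reach direction, for visualizing the territory each direction occupies.
#'
#' @param coords matrix (samples x 2)
#' @param directions direction label per sample
#' @param grid_n KDE grid resolution per axis (default 50)
#' @param bandwidth optional common bandwidth (length 2)
#' @return named list per direction: `x`, `y`, `z` (density grid integrating
#'   to ~1), suitable for `contour()`
#' @export
density_contours <- function(coords, directions, grid_n = 50L,
                             bandwidth = NULL) {
  coords <- as.matrix(coords)
  lims <- c(range(coords[, 1]), range(coords[, 2]))
  out <- lapply(split(seq_along(directions), directions), function(idx) {
    if (length(idx) < 5) stop("need at least 5 points per direction")
    h <- if (is.null(bandwidth))
      c(MASS::bandwidth.nrd(coords[idx, 1]),
        MASS::bandwidth.nrd(coords[idx, 2])) else bandwidth
    h[h <= 0] <- diff(lims[1:2]) / grid_n
    MASS::kde2d(coords[idx, 1], coords[idx, 2], h = h, n = grid_n, lims = lims)
  })
  out
}
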