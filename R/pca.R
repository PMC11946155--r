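#' Half-sample a time series or ERP case matrix
#'
#' Every second sample is retained starting at the first; no additional
#' filtering is applied (the signal is already low-passed far below the new
#' Nyquist).
#'
#' @param x numeric vector, or matrix with time in columns.
#' @return decimated vector or matrix.
#' @export
half_sample <- function(x) {
  if (is.matrix(x)) x[, seq(1, ncol(x), by = 2), drop = FALSE]
  else x[seq(1, length(x), by = 2)]
}

#' Covariance-matrix PCA (all components retained)
#'
#' Eigendecomposition of the variables' covariance matrix. Loadings are
#' eigenvectors scaled by the square root of their eigenvalue -- in the
#' covariance metric they are already in the data's units (microvolts), which
#' is what the "scaled factor loading" curves plot. Scores are standardised
#' (unit variance) projections, so `scores %*% t(loadings)` reconstructs the
#' centred data when all components are kept.
#'
#' @param X cases x variables matrix (no missing values).
#' @return list of class `oscdyn_pca`: `loadings` (variables x components),
#'   `scores` (cases x components, unit variance), `eigenvalues`,
#'   `variance_pct`, `total_variance`, `centre`, `n_zero` (count of
#'   numerically zero eigenvalues, flagged not dropped).
#' @export
pca_covariance <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in case matrix", call. = FALSE)
  centre <- colMeans(X)
  Xc <- sweep(X, 2, centre)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  total <- sum(lam)
  loadings <- e$vectors %*% diag(sqrt(lam), length(lam))
  raw <- Xc %*% e$vectors
  sdv <- sqrt(lam)
  scores <- sweep(raw, 2, ifelse(sdv > 0, sdv, 1), "/")
  structure(list(
    loadings = loadings, scores = scores, eigenvalues = lam,
    variance_pct = if (total > 0) lam / total * 100 else rep(0, length(lam)),
    total_variance = total, centre = centre,
    n_zero = sum(e$values < 1e-12 * max(e$values, 0))
  ), class = "oscdyn_pca")
}

#' Varimax criterion (raw form)
#'
#' Sum over factors of the variance of the squared loadings; the quantity
#' Varimax rotation maximises.
#'
#' @param L loading matrix.
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(v) mean(v^2) - mean(v)^2))
}

#' Varimax rotation with optional Kaiser normalisation
#'
#' Rows (variables) are rescaled to unit communality during rotation when
#' `kaiser_normalize` (with a numerical floor so near-zero-communality
#' variables cannot blow up), rescaled back afterwards. The rotation itself is
#' [stats::varimax()] with the stated tolerance.
#'
#' @param loadings variables x components loading matrix.
#' @param kaiser_normalize apply Kaiser normalisation (default `TRUE`).
#' @param tol convergence tolerance on the criterion (default 1e-7).
#' @return list: `loadings` (rotated), `rotmat` (orthogonal, `R'R = I`).
#' @export
rotate_varimax <- function(loadings, kaiser_normalize = TRUE, tol = 1e-7) {
  L <- as.matrix(loadings)
  if (!all(is.finite(L))) stop("non-finite loadings", call. = FALSE)
  if (ncol(L) < 2) return(list(loadings = L, rotmat = diag(ncol(L))))
  sc <- sqrt(rowSums(L^2))
  if (kaiser_normalize) {
    floor_sc <- 1e-8 * max(sc, 1e-300)
    scl <- pmax(sc, floor_sc)
    r <- stats::varimax(L / scl, normalize = FALSE, eps = tol)
    list(loadings = (L / scl) %*% r$rotmat * scl, rotmat = unclass(r$rotmat))
  } else {
    r <- stats::varimax(L, normalize = FALSE, eps = tol)
    list(loadings = L %*% r$rotmat, rotmat = unclass(r$rotmat))
  }
}

#' Promax oblique rotation of a Varimax solution
#'
#' The target matrix is the element-wise signed power of the Varimax loadings
#' (`|L|^kappa * sign(L)`); an oblique Procrustes fit maps the Varimax
#' loadings onto it, and factors are rescaled to unit variance so
#' `diag(Phi) = 1`. Returns pattern, structure (`= pattern %*% Phi`), and the
#' factor correlation matrix. If the Procrustes system is singular the
#' Varimax solution is returned with `Phi = I` and `degenerate = TRUE`.
#'
#' @param varimax_loadings rotated loadings from [rotate_varimax()].
#' @param kappa power of the target (default 3, the ERP-PCA convention).
#' @return list: `pattern`, `structure`, `Phi`, `rotmat` (transformation
#'   applied to the Varimax loadings), `degenerate`.
#' @export
rotate_promax <- function(varimax_loadings, kappa = 3) {
  L <- as.matrix(varimax_loadings)
  Q <- abs(L)^kappa * sign(L)
  out <- tryCatch({
    U <- solve(crossprod(L), crossprod(L, Q))
    d <- diag(solve(crossprod(U)))
    U <- U %*% diag(sqrt(d), ncol(U))      # unit factor variances: diag(Phi) = 1
    Phi <- solve(crossprod(U))
    pattern <- L %*% U
    list(pattern = pattern, structure = pattern %*% Phi, Phi = Phi,
         rotmat = U, degenerate = FALSE)
  }, error = function(e) NULL)
  if (is.null(out)) {
    k <- ncol(L)
    out <- list(pattern = L, structure = L, Phi = diag(k), rotmat = diag(k),
                degenerate = TRUE)
  }
  out
}

#' Post-rotation explained variance (percent)
#'
#' Orthogonal solutions: column sums of squared rotated loadings over the
#' total variance. Oblique solutions: structure-loading sums of squares over
#' the total variance (a documented attribution choice; oblique variance
#' shares are not additive).
#'
#' @param L rotated loadings (orthogonal) or structure loadings (oblique).
#' @param total_variance trace of the input covariance matrix.
#' @return numeric vector of percentages.
#' @export
rotated_variance_pct <- function(L, total_variance) {
  colSums(L^2) / total_variance * 100
}

#' Select substantial components by a minimum-variance cutoff
#'
#' @param variance_pct post-rotation explained-variance percentages.
#' @param min_variance_pct cutoff (default 1.5).
#' @return integer indices of selected components, in descending-variance
#'   order (possibly empty).
#' @export
select_components <- function(variance_pct, min_variance_pct = 1.5) {
  idx <- which(variance_pct >= min_variance_pct)
  idx[order(variance_pct[idx], decreasing = TRUE)]
}

#' Flip component signs so each peak scaled loading is positive
#'
#' Scores flip with their loadings (and, for oblique solutions, Phi rows and
#' columns), so amplitude measures keep their data-driven sign.
#'
#' @param loadings scaled loadings (variables x components).
#' @param scores case scores.
#' @param Phi optional factor correlation matrix.
#' @return list with flipped `loadings`, `scores`, `Phi`, and `flip` signs.
#' @keywords internal
flip_components <- function(loadings, scores, Phi = NULL) {
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    pk <- which.max(abs(loadings[, j]))
    if (loadings[pk, j] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  if (!is.null(Phi)) Phi <- diag(flip) %*% Phi %*% diag(flip)
  list(loadings = loadings, scores = scores, Phi = Phi, flip = flip)
}

#' Per-participant global-mean component amplitudes
#'
#' A case's component amplitude is its factor score times the scaled loading
#' at the component's peak variable (the absolute-maximum loading), in
#' microvolts; the participant's global mean averages this over all channels
#' (and conditions where pooled). `mean_amplitude` and `peak_amplitude`
#' differ only in sign handling at the peak: `peak` uses the signed loading
#' value at its absolute maximum (after the positive-peak sign convention the
#' two coincide; both are kept for interface fidelity).
#'
#' @param scaled_loadings variables x components matrix (microvolts).
#' @param scores case scores (unit variance).
#' @param participant per-case participant ids.
#' @param components component indices to measure.
#' @param mode `"mean_amplitude"` or `"peak_amplitude"`.
#' @param centre optional per-variable mean (the PCA `centre`); when given,
#'   its value at the component's peak variable is added back, so component
#'   amplitudes keep the data's polarity (N-components come out negative).
#' @return matrix participants x components of global-mean amplitudes, with
#'   participant ids as row names.
#' @export
component_amplitude <- function(scaled_loadings, scores, participant,
                                components,
                                mode = c("mean_amplitude", "peak_amplitude"),
                                centre = NULL) {
  mode <- match.arg(mode)
  if (any(components < 1 | components > ncol(scaled_loadings))) {
    stop("unknown component index", call. = FALSE)
  }
  peaks <- vapply(components, function(j) which.max(abs(scaled_loadings[, j])),
                  integer(1))
  amp_case <- sapply(seq_along(components), function(i) {
    a <- scores[, components[i]] * scaled_loadings[peaks[i], components[i]]
    if (!is.null(centre)) a <- a + centre[peaks[i]]
    a
  })
  amp_case <- matrix(amp_case, nrow = nrow(scores))
  ids <- unique(participant)
  out <- t(vapply(ids, function(p) colMeans(amp_case[participant == p, , drop = FALSE]),
                  numeric(length(components))))
  out <- matrix(out, nrow = length(ids))
  rownames(out) <- as.character(ids)
  colnames(out) <- colnames(scaled_loadings)[components] %||%
    paste0("C", components)
  out
}

#' Frequency PCA of noise-free oscillation spectra
#'
#' Covariance-input PCA over cases = participant x channel, all components
#' extracted and Promax-rotated; components at or above the variance cutoff
#' are selected, sign-aligned, and summarised by peak frequency and
#' per-participant global mean amplitude.
#'
#' @param X cases x frequency-bins matrix of oscillation amplitudes (uV).
#' @param participant per-case participant ids.
#' @param freq_hz frequency of each column.
#' @param cutoff minimum post-rotation variance percent (default 1.5).
#' @param kappa Promax power (default 3).
#' @param kaiser_normalize Kaiser-normalise rows during the Varimax stage
#'   (default `FALSE`: row normalisation equalises near-empty frequency bins
#'   with the oscillation bands and fragments weak bands into sub-threshold
#'   pieces; see the methods vignette).
#' @return list of class `oscdyn_fpca`: the PCA, rotation, selection
#'   (`selected`, `peak_hz`, `variance_pct`), and `amplitudes`
#'   (participants x selected components).
#' @export
fpca <- function(X, participant, freq_hz = 0:(ncol(X) - 1), cutoff = 1.5,
                 kappa = 3, kaiser_normalize = FALSE) {
  pca <- pca_covariance(X)
  active <- which(pca$eigenvalues > 1e-12 * max(pca$eigenvalues))
  vm <- rotate_varimax(pca$loadings[, active, drop = FALSE],
                       kaiser_normalize = kaiser_normalize)
  # retain substantial components on the orthogonal (Varimax) solution, then
  # rotate the retained subspace obliquely: Promax over the full space
  # collapses near-degenerate noise directions onto the dominant band and
  # makes the oblique variance shares meaningless
  vpct_vm <- rotated_variance_pct(vm$loadings, pca$total_variance)
  keep <- select_components(vpct_vm, cutoff)
  if (!length(keep)) {
    return(structure(list(
      pca = pca, pattern = NULL, structure = NULL, Phi = NULL, scores = NULL,
      variance_pct = vpct_vm, selected = integer(0), peak_hz = numeric(0),
      freq_hz = freq_hz, amplitudes = NULL, degenerate = FALSE
    ), class = "oscdyn_fpca"))
  }
  pm <- rotate_promax(vm$loadings[, keep, drop = FALSE], kappa = kappa)
  scores_vm <- pca$scores[, active, drop = FALSE] %*% vm$rotmat
  scores <- scores_vm[, keep, drop = FALSE] %*% t(solve(pm$rotmat))
  fl <- flip_components(pm$structure, scores, pm$Phi)
  structure_l <- fl$loadings
  pattern <- sweep(pm$pattern, 2, fl$flip, "*")
  vpct <- rotated_variance_pct(structure_l, pca$total_variance)
  sel <- order(vpct, decreasing = TRUE)
  peak_hz <- freq_hz[apply(abs(structure_l), 2, which.max)]
  amplitudes <- {
    a <- component_amplitude(structure_l, fl$scores, participant, sel,
                             mode = "mean_amplitude", centre = pca$centre)
    colnames(a) <- paste0("F", sel)
    a
  }
  structure(list(
    pca = pca, pattern = pattern, structure = structure_l, Phi = fl$Phi,
    scores = fl$scores, variance_pct = vpct, variance_pct_varimax = vpct_vm,
    selected = sel, peak_hz = peak_hz, freq_hz = freq_hz,
    amplitudes = amplitudes, degenerate = pm$degenerate
  ), class = "oscdyn_fpca")
}

#' Temporal PCA of averaged ERPs (one condition)
#'
#' Covariance-input PCA with Kaiser normalisation and unrestricted Varimax
#' rotation of all (rank-supported) components; selection by variance cutoff;
#' per-participant global mean peak amplitudes.
#'
#' @param X cases x time-points matrix of mean ERPs (uV).
#' @param participant per-case participant ids.
#' @param time_ms time of each column.
#' @param cutoff minimum post-rotation variance percent (default 1.5).
#' @return list of class `oscdyn_tpca`: rotated `loadings`, `scores`,
#'   `variance_pct`, `selected`, `peak_ms`, `amplitudes`.
#' @export
tpca <- function(X, participant, time_ms, cutoff = 1.5) {
  pca <- pca_covariance(X)
  active <- which(pca$eigenvalues > 1e-12 * max(pca$eigenvalues))
  vm <- rotate_varimax(pca$loadings[, active, drop = FALSE], kaiser_normalize = TRUE)
  scores <- pca$scores[, active, drop = FALSE] %*% vm$rotmat
  fl <- flip_components(vm$loadings, scores)
  vpct <- rotated_variance_pct(fl$loadings, pca$total_variance)
  sel <- select_components(vpct, cutoff)
  peak_ms <- time_ms[apply(abs(fl$loadings), 2, which.max)]
  amplitudes <- if (length(sel)) {
    a <- component_amplitude(fl$loadings, fl$scores, participant, sel,
                             mode = "peak_amplitude", centre = pca$centre)
    colnames(a) <- paste0("T", sel)
    a
  } else NULL
  structure(list(
    pca = pca, loadings = fl$loadings, scores = fl$scores,
    variance_pct = vpct, selected = sel, peak_ms = peak_ms,
    time_ms = time_ms, amplitudes = amplitudes
  ), class = "oscdyn_tpca")
}
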