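# Cross-system comparison machinery: 4-point rigid transform between two
# capture coordinate systems, spline resampling to a common rate,
# consensus temporal alignment by cross-correlation, and per-joint error
# statistics.

#' Solve the transform mapping point set A onto point set B
#'
#' Two modes are provided. `"literal"` solves the homogeneous block
#' equation `RT = B A^-1` exactly from four non-coplanar correspondences
#' (the linear block is not constrained to be a rotation, so marker noise
#' propagates into shear/scale). `"rigid"` (default) returns the
#' least-squares orthogonal transform (Kabsch/Procrustes via SVD), which
#' is the practical choice for noisy markers.
#'
#' @param A,B n x 3 matrices of corresponding points (mm); literal mode
#'   requires exactly 4 non-coplanar points, rigid mode at least 3
#'   non-collinear points.
#' @param mode `"rigid"` or `"literal"`.
#' @return A list of class `rigid_transform` with `R` (3 x 3), `T`
#'   (3-vector) and `mode`.
#' @export
solve_correspondence_transform <- function(A, B,
                                           mode = c("rigid", "literal")) {
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    stop("A and B must have the same dimensions", call. = FALSE)
  if (mode == "literal") {
    if (nrow(A) != 4)
      stop("literal mode needs exactly 4 correspondences", call. = FALSE)
    Ah <- rbind(t(A), 1)  # 4 x 4 homogeneous
    Bh <- rbind(t(B), 1)
    if (abs(det(Ah)) < 1e-6 * max(abs(Ah))^3)
      stop(paste("literal mode: the four points of A are coplanar,",
                 "the homogeneous system is singular"), call. = FALSE)
    M <- Bh %*% solve(Ah)
    Rm <- M[1:3, 1:3, drop = FALSE]
    Tv <- M[1:3, 4]
  } else {
    if (nrow(A) < 3)
      stop("rigid mode needs at least 3 correspondences", call. = FALSE)
    ca <- colMeans(A); cb <- colMeans(B)
    Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
    H <- t(Ac) %*% Bc
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    Rm <- sv$v %*% D %*% t(sv$u)
    Tv <- cb - drop(Rm %*% ca)
  }
  structure(list(R = Rm, T = Tv, mode = mode), class = "rigid_transform")
}

#' Apply a transform to points
#' @param X A `rigid_transform`.
#' @param points 3-vector or n x 3 matrix (mm).
#' @return Transformed points, same shape: `y = R x + T`.
#' @export
apply_transform <- function(X, points) {
  if (is.null(dim(points)))
    return(drop(X$R %*% points) + X$T)
  sweep(points %*% t(X$R), 2, X$T, "+")
}

#' Invert a transform
#' @param X A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(X) {
  Ri <- solve(X$R)
  structure(list(R = Ri, T = -drop(Ri %*% X$T), mode = X$mode),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> mode = %s\n", x$mode))
  cat("R:\n"); print(round(x$R, 6))
  cat("T:", paste(round(x$T, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Resample a 3D trajectory to a target rate with cubic splines
#'
#' Third-order spline interpolation per axis, sampled uniformly at
#' `target_rate` over the original time span. Knots are reproduced
#' exactly at coincident timestamps.
#'
#' @param t Numeric vector of timestamps (s), strictly increasing.
#' @param X n x 3 position matrix (mm).
#' @param target_rate Target sampling rate, Hz.
#' @return List with `t` (new timestamps) and `X` (resampled positions).
#' @export
resample_trajectory <- function(t, X, target_rate) {
  X <- as.matrix(X)
  if (length(t) < 4)
    stop("resample_trajectory: need at least 4 samples", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("resample_trajectory: timestamps must be strictly increasing",
         call. = FALSE)
  tn <- seq(t[1], t[length(t)], by = 1 / target_rate)
  Xn <- sapply(1:3, function(j)
    stats::spline(t, X[, j], xout = tn, method = "fmm")$y)
  list(t = tn, X = Xn)
}

# Normalized (Pearson) cross-correlation between equal-rate trajectories
# at integer lags: per-axis correlations averaged. Positive lag means B
# is delayed with respect to A.
lagged_correlation <- function(XA, XB, lag) {
  n <- min(nrow(XA), nrow(XB))
  if (lag >= 0) {
    ia <- seq_len(n - lag); ib <- ia + lag
  } else {
    ib <- seq_len(n + lag); ia <- ib - lag
  }
  if (length(ia) < 3) return(-Inf)
  cors <- vapply(1:3, function(j) {
    a <- XA[ia, j]; b <- XB[ib, j]
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  if (all(is.na(cors))) return(-Inf)
  mean(cors, na.rm = TRUE)
}

best_lag <- function(XA, XB, max_lag) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) lagged_correlation(XA, XB, L), numeric(1))
  if (all(!is.finite(cc))) return(NULL)
  peak <- max(cc, na.rm = TRUE)
  cand <- lags[which(cc >= peak - 1e-12)]
  cand[which.min(abs(cand))]  # ties toward the smaller |lag|
}

#' Consensus temporal alignment of two trajectory sets
#'
#' Computes a candidate lag for the hand, elbow and shoulder trajectories
#' as the peak of the normalized cross-correlation (per-axis Pearson
#' correlations averaged), then chooses the candidate that maximizes the
#' mean correlation applied simultaneously to all three joints. Flat
#' (zero-variance) trajectories are excluded from the candidate set.
#'
#' @param trajsA,trajsB Named lists with elements `hand`, `elbow`,
#'   `shoulder`, each an n x 3 matrix sampled at the same rate.
#' @param max_lag Search window in samples (default 60, i.e. +-2 s at
#'   30 Hz).
#' @return A list of class `alignment_result`: per-joint candidate lags
#'   (`cc_h`, `cc_e`, `cc_s`), the chosen `lag` and the mean correlation
#'   at that lag.
#' @export
temporal_align <- function(trajsA, trajsB, max_lag = 60) {
  joints <- c(hand = "cc_h", elbow = "cc_e", shoulder = "cc_s")
  cands <- list()
  for (j in names(joints)) {
    L <- best_lag(as.matrix(trajsA[[j]]), as.matrix(trajsB[[j]]), max_lag)
    cands[[joints[[j]]]] <- L  # NULL drops flat joints
  }
  if (!length(cands))
    stop("temporal_align: all trajectories are flat", call. = FALSE)
  mean_corr_at <- function(L) {
    cc <- vapply(names(joints), function(j)
      lagged_correlation(as.matrix(trajsA[[j]]), as.matrix(trajsB[[j]]), L),
      numeric(1))
    cc[!is.finite(cc)] <- NA_real_  # flat joints carry no evidence
    mean(cc, na.rm = TRUE)
  }
  uniq <- unique(unlist(cands))
  scores <- vapply(uniq, mean_corr_at, numeric(1))
  peak <- max(scores)
  best <- uniq[scores >= peak - 1e-12]
  chosen <- best[which.min(abs(best))]
  structure(list(cc_h = cands$cc_h, cc_e = cands$cc_e, cc_s = cands$cc_s,
                 lag = chosen, mean_correlation = peak),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(paste0("<alignment_result> lag = %d samples ",
                     "(cc_h = %s, cc_e = %s, cc_s = %s), ",
                     "mean correlation %.4f\n"),
              x$lag, format(x$cc_h), format(x$cc_e), format(x$cc_s),
              x$mean_correlation))
  invisible(x)
}

#' Shift a trajectory set by a lag
#'
#' Applies the alignment: drops `lag` leading samples of B (or of A for
#' negative lags) and truncates both to common length.
#'
#' @param XA,XB n x 3 matrices.
#' @param lag Integer lag (samples), positive = B delayed.
#' @return List with aligned `A` and `B`.
#' @export
apply_lag <- function(XA, XB, lag) {
  XA <- as.matrix(XA); XB <- as.matrix(XB)
  if (lag >= 0) XB <- XB[-seq_len(lag), , drop = FALSE][, , drop = FALSE]
  else XA <- XA[-seq_len(-lag), , drop = FALSE]
  n <- min(nrow(XA), nrow(XB))
  list(A = XA[seq_len(n), , drop = FALSE], B = XB[seq_len(n), , drop = FALSE])
}

#' Per-frame trajectory error
#'
#' Instant position errors as the Euclidean distance between the two
#' systems' 3D positions, frame by frame, with mean and population
#' standard deviation.
#'
#' @param trajA,trajB Aligned n x 3 matrices of equal length (mm).
#' @return List with `distances` (mm per frame), `mean`, `sd`
#'   (population SD).
#' @export
trajectory_error <- function(trajA, trajB) {
  trajA <- as.matrix(trajA); trajB <- as.matrix(trajB)
  if (nrow(trajA) != nrow(trajB))
    stop("trajectory_error: trajectories must have equal length",
         call. = FALSE)
  d <- sqrt(rowSums((trajA - trajB)^2))
  m <- mean(d)
  list(distances = d, mean = m, sd = sqrt(mean((d - m)^2)))
}
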