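## MODULE localize -- release-site localization on frame-scan stacks:
## per-trial 2D Gaussian fits and the 95% confinement ellipse.

#' Stimulus-evoked difference image of a frame-scan stack
#'
#' Mean of the post-stimulus frames falling within one sensor decay
#' constant of the stimulation frame, minus the mean of the baseline
#' frames, per pixel.
#'
#' @param stack array (rows x cols x frames) or the list returned by
#'   \code{\link{synthesizeFrameScanStack}}.
#' @param stimFrame stimulation frame index.
#' @param baselineFrames indices of baseline frames (default: all
#'   frames before \code{stimFrame}).
#' @param kernelTau sensor decay constant (ms) sizing the post window.
#' @param frameRate frames per second.
#' @return Numeric matrix (the \eqn{\Delta F} image).
#' @export
differenceMap <- function(stack, stimFrame = NULL, baselineFrames = NULL,
                          kernelTau = 40, frameRate = 62.5) {
  if (is.list(stack)) {
    if (is.null(stimFrame)) stimFrame <- stack$stimFrame
    if (!is.null(stack$frameRate)) frameRate <- stack$frameRate
    stack <- stack$stack
  }
  if (length(dim(stack)) != 3 || is.null(stimFrame))
    stop("malformed input: need a 3D stack and a stimulation frame",
         call. = FALSE)
  nF <- dim(stack)[3]
  if (is.null(baselineFrames)) baselineFrames <- seq_len(stimFrame - 1L)
  if (length(baselineFrames) < 1 || stimFrame <= max(0, length(baselineFrames)))
    stop("malformed input: need stimFrame > number of baseline frames >= 1",
         call. = FALSE)
  nPost <- max(1L, round(kernelTau / (1000 / frameRate)))
  post <- stimFrame:min(nF, stimFrame + nPost - 1L)
  apply(stack[, , post, drop = FALSE], c(1, 2), mean) -
    apply(stack[, , baselineFrames, drop = FALSE], c(1, 2), mean)
}

#' Fit a 2D Gaussian to a difference image
#'
#' Nonlinear least squares of
#' \eqn{A \exp(-(x-x_0)^2/2\sigma_x^2 - (y-y_0)^2/2\sigma_y^2) + c}
#' with sub-pixel centroid precision, initialized at the image maximum.
#' A flat or degenerate image yields a failure-labelled result with an
#' undefined centroid.
#'
#' @param img \eqn{\Delta F} image (at least 7 x 7 pixels).
#' @param pixelSize micrometers per pixel (centroid is returned in um,
#'   origin at the field corner).
#' @return List: \code{centroid} (x, y in um), \code{amplitude},
#'   \code{sigma} (x, y widths in um), \code{offset}, \code{residual}
#'   (RMS), \code{ok}.
#' @export
fitGaussian2D <- function(img, pixelSize = 0.1) {
  if (nrow(img) < 7 || ncol(img) < 7)
    stop("image must be larger than 7 x 7 pixels", call. = FALSE)
  nx <- nrow(img); ny <- ncol(img)
  xs <- (seq_len(nx) - 0.5) * pixelSize
  ys <- (seq_len(ny) - 0.5) * pixelSize
  df <- data.frame(x = rep(xs, times = ny), y = rep(ys, each = nx),
                   z = as.vector(img))
  if (sd(df$z) == 0)
    return(list(centroid = c(NA_real_, NA_real_), amplitude = 0,
                sigma = c(NA_real_, NA_real_), offset = df$z[1],
                residual = 0, ok = FALSE))
  i0 <- arrayInd(which.max(img), dim(img))
  start <- list(A = max(df$z) - median(df$z), x0 = xs[i0[1]],
                y0 = ys[i0[2]], sx = 2 * pixelSize, sy = 2 * pixelSize,
                c0 = median(df$z))
  fit <- try(minpack.lm::nlsLM(
    z ~ A * exp(-(x - x0)^2 / (2 * sx^2) - (y - y0)^2 / (2 * sy^2)) + c0,
    data = df, start = start,
    lower = c(A = -Inf, x0 = 0, y0 = 0, sx = pixelSize / 10,
              sy = pixelSize / 10, c0 = -Inf),
    upper = c(A = Inf, x0 = max(xs) + pixelSize, y0 = max(ys) + pixelSize,
              sx = max(xs), sy = max(ys), c0 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(centroid = c(NA_real_, NA_real_), amplitude = NA_real_,
                sigma = c(NA_real_, NA_real_), offset = NA_real_,
                residual = NA_real_, ok = FALSE))
  cf <- coef(fit)
  list(centroid = c(cf[["x0"]], cf[["y0"]]), amplitude = cf[["A"]],
       sigma = c(cf[["sx"]], cf[["sy"]]), offset = cf[["c0"]],
       residual = sqrt(mean(resid(fit)^2)), ok = TRUE)
}

#' Confinement ellipse of success centroids
#'
#' Quantifies the spatial confinement of release-event centroids: the
#' covariance ellipse of the points is scaled to the empirical 95%
#' Mahalanobis radius, so it contains exactly \eqn{\lceil 0.95 n
#' \rceil} of the points by construction. A minimum-area enclosing
#' ellipse (Khachiyan's algorithm, then shrunk to the same coverage) is
#' available as an alternative construction.
#'
#' @param centroids n x 2 matrix (um).
#' @param coverage fraction of points to contain (default 0.95).
#' @param method \code{"covariance"} (default) or \code{"minarea"}.
#' @return List: \code{center}, \code{axes} (full lengths, short
#'   first), \code{orientation} (radians), \code{nInside}, \code{n},
#'   \code{coverage}, plus the shape matrix \code{shape} and radius
#'   \code{radius} such that points with
#'   \eqn{(p-c)^T S^{-1} (p-c) \le r^2} are inside.
#' @export
confinementEllipse <- function(centroids, coverage = 0.95,
                               method = c("covariance", "minarea")) {
  method <- match.arg(method)
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 20)
    stop("insufficient data: need >= 20 centroids", call. = FALSE)
  m <- ceiling(coverage * n)
  if (method == "covariance") {
    ctr <- colMeans(centroids)
    S <- cov(centroids)
    d2 <- mahalanobis(centroids, ctr, S)
    r2 <- sort(d2)[m]
  } else {
    ke <- .minAreaEllipse(centroids)
    ctr <- ke$center; S <- ke$shape
    d2 <- mahalanobis(centroids, ctr, S)
    r2 <- sort(d2)[m]
  }
  eg <- eigen(S, symmetric = TRUE)
  axes <- 2 * sqrt(eg$values * r2)          # full axis lengths
  inside <- sum(d2 <= r2 + 1e-12)
  list(center = ctr, axes = sort(axes),
       orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       nInside = inside, n = n, coverage = coverage, shape = S,
       radius = sqrt(r2))
}

# Khachiyan's minimum-volume enclosing ellipse (2D)
.minAreaEllipse <- function(P, tol = 1e-4) {
  n <- nrow(P)
  Q <- t(cbind(P, 1))
  u <- rep(1 / n, n)
  repeat {
    X <- Q %*% diag(u) %*% t(Q)
    M <- diag(t(Q) %*% solve(X) %*% Q)
    j <- which.max(M)
    step <- (M[j] - 3) / (3 * (M[j] - 1))
    u2 <- (1 - step) * u
    u2[j] <- u2[j] + step
    if (sum(abs(u2 - u)) < tol) { u <- u2; break }
    u <- u2
  }
  ctr <- as.numeric(t(P) %*% u)
  S <- t(P) %*% diag(u) %*% P - ctr %*% t(ctr)
  list(center = ctr, shape = S * 2)
}

#' Localize release events across a set of frame-scan stacks
#'
#' Applies \code{\link{differenceMap}} and \code{\link{fitGaussian2D}}
#' to each stack and assembles the centroid table. When amplitude
#' labels are not imported from the trace analysis, the 2-sigma rule is
#' applied to the Gaussian amplitudes (SD estimated from
#' baseline-frame difference images).
#'
#' @param stacks list of stacks (arrays or
#'   \code{\link{synthesizeFrameScanStack}} results).
#' @param pixelSize micrometers per pixel.
#' @param labels optional character vector of imported labels.
#' @return data.frame(trial, x, y, amplitude, sx, sy, label).
#' @export
localizeStacks <- function(stacks, pixelSize = 0.1, labels = NULL) {
  res <- lapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    ps <- if (is.list(st) && !is.null(st$pixelSize)) st$pixelSize
          else pixelSize
    g <- fitGaussian2D(differenceMap(st), ps)
    data.frame(trial = i, x = g$centroid[1], y = g$centroid[2],
               amplitude = g$amplitude, sx = g$sigma[1], sy = g$sigma[2])
  })
  out <- do.call(rbind, res)
  if (!is.null(labels)) {
    out$label <- labels
  } else {
    s <- sd(out$amplitude, na.rm = TRUE)
    mu <- median(out$amplitude, na.rm = TRUE)
    out$label <- ifelse(out$amplitude > mu + 2 * s, "success", "failure")
  }
  out
}
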