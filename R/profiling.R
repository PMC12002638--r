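#' Intensity line profile through an image
#'
#' Samples the image by linear interpolation at uniform steps along a
#' direction through a centre point. Works on 2D images (bilinear) and 3D
#' stacks (trilinear).
#'
#' @param image numeric matrix `(ny, nx)` or array `(nz, ny, nx)`.
#' @param grid its [voxel_grid()] (for a matrix, the y/x spacings are
#'   used).
#' @param center_nm physical centre, `c(x, y)` or `c(x, y, z)`.
#' @param direction unit direction, same length as `center_nm`; the
#'   default is the x axis.
#' @param length_nm profile length (default 1000 nm).
#' @param step_nm sampling step; defaults to the lateral pixel size.
#' @return Object of class `line_profile`: data frame with `position_nm`
#'   (centred on 0) and `intensity`. At least 7 samples are required.
#' @export
line_profile <- function(image, grid, center_nm, direction = NULL,
                         length_nm = 1000, step_nm = NULL) {
  nd <- if (is.matrix(image)) 2L else 3L
  if (is.null(direction)) direction <- if (nd == 2) c(1, 0) else c(1, 0, 0)
  stopifnot(length(center_nm) == nd, length(direction) == nd)
  direction <- direction / sqrt(sum(direction^2))
  step_nm <- step_nm %||% grid$spacing[["x"]]
  pos <- seq(-length_nm / 2, length_nm / 2, by = step_nm)
  if (length(pos) < 7) stop("profile must have at least 7 samples")
  pts <- outer(pos, direction) + rep(center_nm, each = length(pos))
  vals <- if (nd == 2) interp2(image, grid, pts) else interp3(image, grid, pts)
  if (anyNA(vals)) stop("line profile leaves the image bounds")
  structure(data.frame(position_nm = pos, intensity = vals),
            class = c("line_profile", "data.frame"))
}

# bilinear interpolation; pts columns (x, y)
interp2 <- function(img, grid, pts) {
  fy <- (pts[, 2] - grid$origin[["y"]]) / grid$spacing[["y"]]
  fx <- (pts[, 1] - grid$origin[["x"]]) / grid$spacing[["x"]]
  j0 <- floor(fy); i0 <- floor(fx)
  ty <- fy - j0; tx <- fx - i0
  ny <- nrow(img); nx <- ncol(img)
  ok <- j0 >= 0 & j0 <= ny - 2 & i0 >= 0 & i0 <= nx - 2
  out <- rep(NA_real_, nrow(pts))
  j <- j0[ok] + 1; i <- i0[ok] + 1
  g <- function(jj, ii) img[cbind(jj, ii)]
  out[ok] <- (1 - ty[ok]) * (1 - tx[ok]) * g(j, i) +
    (1 - ty[ok]) * tx[ok] * g(j, i + 1) +
    ty[ok] * (1 - tx[ok]) * g(j + 1, i) +
    ty[ok] * tx[ok] * g(j + 1, i + 1)
  out
}

# trilinear interpolation; pts columns (x, y, z)
interp3 <- function(img, grid, pts) {
  fz <- (pts[, 3] - grid$origin[["z"]]) / grid$spacing[["z"]]
  fy <- (pts[, 2] - grid$origin[["y"]]) / grid$spacing[["y"]]
  fx <- (pts[, 1] - grid$origin[["x"]]) / grid$spacing[["x"]]
  k0 <- floor(fz); j0 <- floor(fy); i0 <- floor(fx)
  tz <- fz - k0; ty <- fy - j0; tx <- fx - i0
  d <- dim(img)
  ok <- k0 >= 0 & k0 <= d[1] - 2 & j0 >= 0 & j0 <= d[2] - 2 &
    i0 >= 0 & i0 <= d[3] - 2
  out <- rep(NA_real_, nrow(pts))
  k <- k0[ok] + 1; j <- j0[ok] + 1; i <- i0[ok] + 1
  g <- function(kk, jj, ii) img[cbind(kk, jj, ii)]
  uz <- tz[ok]; uy <- ty[ok]; ux <- tx[ok]
  out[ok] <-
    (1 - uz) * ((1 - uy) * ((1 - ux) * g(k, j, i) + ux * g(k, j, i + 1)) +
                  uy * ((1 - ux) * g(k, j + 1, i) + ux * g(k, j + 1, i + 1))) +
    uz * ((1 - uy) * ((1 - ux) * g(k + 1, j, i) + ux * g(k + 1, j, i + 1)) +
            uy * ((1 - ux) * g(k + 1, j + 1, i) + ux * g(k + 1, j + 1, i + 1)))
  out
}

#' Axial profile of a stack through a point
#'
#' Sums the intensity over a small lateral disc per z-plane, giving a
#' high signal-to-noise axial profile of an isolated object (used for
#' axial nano-ruler calibration).
#'
#' @param stack numeric array.
#' @param grid its [voxel_grid()].
#' @param center_nm physical `c(x, y)` (or `c(x, y, z)`; z ignored).
#' @param radius_nm lateral integration radius.
#' @return A `line_profile` with one sample per z-plane.
#' @export
axial_profile <- function(stack, grid, center_nm, radius_nm = 100) {
  d <- dim(stack)
  jj <- seq_len(d[2]); ii <- seq_len(d[3])
  yv <- grid$origin[["y"]] + (jj - 1) * grid$spacing[["y"]] - center_nm[2]
  xv <- grid$origin[["x"]] + (ii - 1) * grid$spacing[["x"]] - center_nm[1]
  sel_j <- jj[abs(yv) <= radius_nm]
  sel_i <- ii[abs(xv) <= radius_nm]
  disc <- outer(yv[sel_j]^2, xv[sel_i]^2, `+`) <= radius_nm^2
  vals <- vapply(seq_len(d[1]), function(k) {
    pl <- stack[k, sel_j, sel_i, drop = TRUE]
    sum(pl[disc])
  }, 0)
  if (length(vals) < 7) stop("profile must have at least 7 samples")
  pos <- grid$origin[["z"]] + (seq_len(d[1]) - 1) * grid$spacing[["z"]]
  structure(data.frame(position_nm = pos - mean(pos), intensity = vals),
            class = c("line_profile", "data.frame"))
}

gauss1 <- function(x, b, a, mu, sigma) b + a * exp(-(x - mu)^2 / (2 * sigma^2))

#' Fit the FWHM of a single-peak profile
#'
#' Least-squares fit of a 1D Gaussian plus constant offset;
#' `FWHM = 2 sqrt(2 ln 2) sigma`. Fits that do not converge, or whose
#' peak sits at the profile boundary, are flagged and should be excluded
#' from summaries.
#'
#' @param profile a [line_profile()].
#' @return List with `fwhm_nm`, `mu_nm`, `sigma_nm`, `amplitude`,
#'   `offset`, `converged` and `at_boundary`.
#' @export
fit_fwhm <- function(profile) {
  x <- profile$position_nm
  y <- profile$intensity
  b0 <- unname(quantile(y, 0.1))
  a0 <- max(y) - b0
  mu0 <- x[which.max(y)]
  w <- pmax(y - b0, 0)
  s0 <- sqrt(sum(w * (x - mu0)^2) / max(sum(w), 1e-12))
  s0 <- max(s0, diff(range(x)) / 50)
  try_fit <- function(st) tryCatch(
    minpack.lm::nlsLM(y ~ gauss1(x, b, a, mu, sigma),
                      start = st,
                      lower = c(-Inf, 0, min(x), 1e-3),
                      upper = c(Inf, Inf, max(x), diff(range(x))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # noiseless, grid-symmetric profiles can give a rank-deficient Jacobian
  # at the first start; retry from perturbed starts
  starts <- list(
    list(b = b0, a = a0, mu = mu0, sigma = s0),
    list(b = b0, a = a0, mu = mu0 + 0.1 * diff(x[1:2]), sigma = 1.2 * s0),
    list(b = b0 + 0.05 * a0, a = 0.9 * a0,
         mu = mu0 + 0.5 * diff(x[1:2]), sigma = 0.8 * s0))
  fit <- NULL
  for (st in starts) {
    fit <- try_fit(st)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    return(list(fwhm_nm = NA_real_, mu_nm = NA_real_, sigma_nm = NA_real_,
                amplitude = NA_real_, offset = NA_real_, converged = FALSE,
                at_boundary = NA))
  p <- coef(fit)
  rng <- range(x)
  edge <- 0.1 * diff(rng)
  list(fwhm_nm = sigma_to_fwhm(p[["sigma"]]), mu_nm = p[["mu"]],
       sigma_nm = p[["sigma"]], amplitude = p[["a"]], offset = p[["b"]],
       converged = TRUE,
       at_boundary = p[["mu"]] < rng[1] + edge || p[["mu"]] > rng[2] - edge)
}

gauss2 <- function(x, b, a1, a2, mu1, mu2, sigma)
  b + a1 * exp(-(x - mu1)^2 / (2 * sigma^2)) +
  a2 * exp(-(x - mu2)^2 / (2 * sigma^2))

aicc <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}

#' Peak-to-peak separation and Rayleigh dip of a two-peak profile
#'
#' Fits both a single-Gaussian and a double-Gaussian (shared width) model
#' with constant offset. The pair is reported as resolved iff the
#' two-peak model is preferred by AICc and the dip between the fitted
#' peaks is positive. The dip percentage is
#' `(mean peak height - valley at the midpoint) / mean peak height * 100`
#' on the fitted, offset-subtracted curve (the Rayleigh-criterion
#' convention).
#'
#' @param profile a [line_profile()].
#' @param sigma_fixed optional known Gaussian sigma in nm (e.g. from the
#'   channel PSF during calibration); when given, sigma is not fitted.
#' @return List with `distance_nm`, `dip_percent`, `resolved`, the fitted
#'   peak positions and the two models' AICc.
#' @export
peak_separation <- function(profile, sigma_fixed = NULL) {
  x <- profile$position_nm
  y <- profile$intensity
  n <- length(x)
  f1 <- fit_fwhm(profile)
  rss1 <- if (f1$converged)
    sum((y - gauss1(x, f1$offset, f1$amplitude, f1$mu_nm, f1$sigma_nm))^2)
  else sum((y - mean(y))^2)
  aicc1 <- aicc(rss1, n, 4)

  b0 <- unname(quantile(y, 0.1))
  a0 <- max(y) - b0
  s0 <- sigma_fixed %||% (if (f1$converged) f1$sigma_nm / 1.5 else
    diff(range(x)) / 10)
  mu0 <- if (f1$converged) f1$mu_nm else x[which.max(y)]
  sep0 <- max(2 * s0, diff(range(x)) / 8)
  # data-driven peak starts: the two highest local maxima of the lightly
  # smoothed profile, when they exist
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[c(1, n)] <- y[c(1, n)]
  locmax <- which(diff(sign(diff(ys))) < 0) + 1
  mu_start2 <- NULL
  if (length(locmax) >= 2) {
    top <- locmax[order(ys[locmax], decreasing = TRUE)]
    for (second in top[-1]) {
      if (abs(x[second] - x[top[1]]) > 2 * diff(x[1:2])) {
        mu_start2 <- sort(c(x[top[1]], x[second]))
        break
      }
    }
  }
  unresolved <- function() list(distance_nm = NA_real_,
                                dip_percent = NA_real_, resolved = FALSE,
                                two_peak_preferred = FALSE,
                                mu1_nm = NA_real_, mu2_nm = NA_real_,
                                aicc_single = aicc1, aicc_double = NA_real_)
  fit_from <- function(mus) tryCatch({
    if (is.null(sigma_fixed)) {
      minpack.lm::nlsLM(
        y ~ gauss2(x, b, a1, a2, mu1, mu2, sigma),
        start = list(b = b0, a1 = a0, a2 = a0, mu1 = mus[1],
                     mu2 = mus[2], sigma = s0),
        lower = c(-Inf, 0, 0, min(x), min(x), 1e-3),
        upper = c(Inf, Inf, Inf, max(x), max(x), diff(range(x))),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    } else {
      sf <- sigma_fixed
      minpack.lm::nlsLM(
        y ~ gauss2(x, b, a1, a2, mu1, mu2, sf),
        start = list(b = b0, a1 = a0, a2 = a0, mu1 = mus[1],
                     mu2 = mus[2]),
        lower = c(-Inf, 0, 0, min(x), min(x)),
        upper = c(Inf, Inf, Inf, max(x), max(x)),
        control = minpack.lm::nls.lm.control(maxiter = 300))
    }
  }, error = function(e) NULL)
  # two starting points: a generic symmetric split and the observed peaks;
  # keep the better-fitting converged model
  cands <- list(fit_from(c(mu0 - sep0 / 2, mu0 + sep0 / 2)),
                if (!is.null(mu_start2)) fit_from(mu_start2))
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) return(unresolved())
  rss <- vapply(cands, function(f) sum(residuals(f)^2), 0)
  fit2 <- cands[[which.min(rss)]]
  if (is.null(fit2)) return(unresolved())
  p <- coef(fit2)
  sg <- if (is.null(sigma_fixed)) p[["sigma"]] else sigma_fixed
  mu1 <- min(p[["mu1"]], p[["mu2"]])
  mu2 <- max(p[["mu1"]], p[["mu2"]])
  curve <- function(t) gauss2(t, 0, p[["a1"]], p[["a2"]],
                              p[["mu1"]], p[["mu2"]], sg)
  # the dip is measured between the fitted curve's own maxima: near the
  # resolution limit the two apparent peaks sit inside the fitted centres
  mid <- (mu1 + mu2) / 2
  valley <- curve(mid)
  dip <- NA_real_
  if (mu2 - mu1 > 1e-6) {
    o1 <- stats::optimize(curve, c(mu1 - sg, mid), maximum = TRUE)
    o2 <- stats::optimize(curve, c(mid, mu2 + sg), maximum = TRUE)
    h <- mean(c(o1$objective, o2$objective))
    bimodal <- o1$maximum < mid - 1e-6 && o2$maximum > mid + 1e-6 &&
      h > valley
    dip <- if (bimodal && h > 0) (h - valley) / h * 100 else 0
  }
  rss2 <- sum((y - (p[["b"]] + curve(x)))^2)
  k2 <- if (is.null(sigma_fixed)) 7 else 6
  aicc2 <- aicc(rss2, n, k2)
  preferred <- is.finite(aicc2) && aicc2 < aicc1
  resolved <- preferred && is.finite(dip) && dip > 0
  list(distance_nm = mu2 - mu1, dip_percent = dip, resolved = resolved,
       two_peak_preferred = preferred,
       mu1_nm = mu1, mu2_nm = mu2, aicc_single = aicc1, aicc_double = aicc2)
}

#' Mean centroid offset between matched confocal and STED centres
#'
#' Nearest-neighbour matches each confocal centre to a STED centre within
#' `max_match_nm` and reports the per-axis mean signed difference
#' (STED minus confocal), the channel-registration quantity.
#'
#' @param centers_confocal,centers_sted matrices or data frames with
#'   columns `cx`, `cy` (and optionally `cz`, ignored).
#' @param max_match_nm maximum match distance (default 200 nm).
#' @return List with `dx_nm`, `dy_nm` and `n_matched`; a warning is
#'   issued below 5 matched pairs.
#' @export
channel_offset <- function(centers_confocal, centers_sted,
                           max_match_nm = 200) {
  a <- as_xy_matrix(centers_confocal)
  b <- as_xy_matrix(centers_sted)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("need centres in both channels")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  nn <- apply(d2, 1, which.min)
  dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(a)), nn)]))
  ok <- dmin <= max_match_nm
  if (sum(ok) < 5)
    warning("fewer than 5 matched cluster pairs; offset estimate unstable")
  list(dx_nm = mean(b[nn[ok], 1] - a[ok, 1]),
       dy_nm = mean(b[nn[ok], 2] - a[ok, 2]),
       n_matched = sum(ok))
}

as_xy_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("cx", "cy")])
  x <- rbind(x)
  x[, 1:2, drop = FALSE]
}
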