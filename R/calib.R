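#' Tail mask: sinogram bins outside the object's projected support
#'
#' In the tail region the trues vanish (no activity along the LOR crosses
#' the object), so measured counts there are scatter only — the signal the
#' kernel calibration matches. Support is delimited from the mu-map's
#' projection (robust to emission noise): a bin belongs to the tail iff its
#' mu line integral is below `eps_support` *and* it is at least
#' `margin_bins` radial bins away from any support bin.
#'
#' @param mu attenuation [pet_volume()] of the calibration object.
#' @param geometry a [scanner_geometry()].
#' @param margin_bins guard band (radial bins) excluded next to the
#'   support; never adds bins when increased.
#' @param eps_support support threshold on the mu line integral
#'   (dimensionless).
#' @return logical array `(n_views, n_radial, n_slices)` of class
#'   `tail_mask`.
#' @export
tail_mask <- function(mu, geometry, margin_bins = 2L, eps_support = 1e-3) {
  stopifnot(inherits(mu, "pet_volume"), inherits(geometry, "scanner_geometry"))
  margin_bins <- as.integer(margin_bins)
  stopifnot(margin_bins >= 0L)
  li <- unclass(mu_line_integrals(mu, geometry))
  support <- li >= eps_support
  dil <- support
  if (margin_bins > 0L) {
    nr <- dim(support)[2]
    for (k in seq_len(margin_bins)) {
      dil[, seq_len(nr - k), ] <- dil[, seq_len(nr - k), ] | support[, k + seq_len(nr - k), ]
      dil[, k + seq_len(nr - k), ] <- dil[, k + seq_len(nr - k), ] | support[, seq_len(nr - k), ]
    }
  }
  tail <- !dil
  if (!any(tail)) stop("empty tail mask: the object fills the field of view")
  structure(tail, support = support, class = c("tail_mask", "array"))
}

#' Fit scatter kernel parameters by tail matching
#'
#' Finds `(alpha, beta)` minimizing the squared mismatch, over tail bins
#' only, between the calculated scatter distribution and the measured
#' prompts. The calculated scatter at a candidate `(alpha, beta)` is the
#' self-consistent solution of
#' \deqn{\hat{s} = \mathrm{conv}(p \cdot 1_{\neg tail} +
#'   \hat{s} \cdot 1_{tail};\ \alpha, \beta)}
#' (a short fixed-point iteration per view), and the objective is
#' \deqn{\sum_{tail} \left(\hat{s} - p\right)^2 .}
#' In the tail the measurement is pure scatter, so a matching estimate
#' there pins down both the kernel amplitude and its width. Feeding the
#' measured non-tail counts plus the *estimated* (noise-free) tail
#' scatter into the convolution — rather than the raw prompts — matters
#' twice over: it reproduces the convolution model exactly at the true
#' parameters, and it removes the degenerate near-identity kernel
#' (`alpha` tiny, `conv(p) = p`) which would otherwise reproduce the
#' measured tail counts, Poisson noise included, with near-zero residual.
#' The `(alpha, beta)` landscape is a narrow curved valley (a broader
#' kernel can be traded against a larger amplitude), so the optimizer
#' profiles the amplitude out: `beta` is scanned on a log-spaced grid and
#' `alpha` is minimized by a bounded 1D search at each node; the best node
#' is then refined by the same nested search over a bracketing `beta`
#' interval. Fully deterministic.
#'
#' @param prompts measured [sinogram()], nonnegative.
#' @param mask a [tail_mask()].
#' @param bounds list with `alpha` and `beta` ranges (both positive).
#' @param grid_density integer length-2; `grid_density[2]` is the number
#'   of log-spaced `beta` scan nodes (`alpha` is profiled out
#'   continuously at each node).
#' @param mode convolution mode used in the estimate (see
#'   [scatter_convolve()]); match the mode used for correction.
#' @param objective `"lsq"` (least squares over tail bins) or `"poisson"`
#'   (Poisson negative log-likelihood of the tail counts given the
#'   calculated scatter). Least squares is the simplest matching
#'   criterion and is fine for high-count calibration data; with sparse
#'   tail counts the likelihood weighs the orders-of-magnitude range of
#'   tail expectations correctly and recovers parameters at nearly the
#'   information bound.
#' @param weighting for `"lsq"` only: `"none"` or `"poisson"`
#'   (weights `1/max(counts, 1)`).
#' @param refine run the local refinement (default) or return the best
#'   grid cell.
#' @return object of class `kernel_fit`: the fitted [kernel_params()] plus
#'   diagnostics (objective, tail bin count, bound flags).
#' @export
fit_kernel_params <- function(prompts, mask,
                              bounds = list(alpha = c(0.01, 10), beta = c(0.01, 50)),
                              grid_density = c(40L, 40L),
                              mode = c("zeropad", "circular"),
                              objective = c("lsq", "poisson"),
                              weighting = c("none", "poisson"),
                              refine = TRUE) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  weighting <- match.arg(weighting)
  stopifnot(inherits(prompts, "sinogram"), inherits(mask, "tail_mask"))
  if (!identical(dim(prompts), dim(mask))) stop("mask and sinogram shapes differ")
  if (!any(mask)) stop("empty tail mask")
  geom <- .sino_geometry(prompts)
  spacing <- .sino_spacing(geom)
  d <- dim(prompts)
  arr <- unclass(prompts)

  tail_totals <- sum(arr[mask])
  if (tail_totals <= 0) stop("tail counts are all zero; nothing to match")

  # precompute per-view (padded) FFTs and tail indices
  if (mode == "zeropad") {
    dp <- c(.good_fft_size(2L * d[2]), .good_fft_size(2L * d[3]))
  } else {
    dp <- d[2:3]
  }
  grid_f <- frequency_grid(dp, spacing)
  views <- seq_len(d[1])
  F_list <- vector("list", d[1])
  idx_list <- vector("list", d[1])
  val_list <- vector("list", d[1])
  w_list <- vector("list", d[1])
  support <- attr(mask, "support")
  if (is.null(support)) stop("mask lacks a support attribute; build it with tail_mask()")
  pad_idx_list <- vector("list", d[1]) # tail positions inside the padded plane
  for (v in views) {
    plane <- arr[v, , ]
    m <- mask[v, , ]
    idx_list[[v]] <- which(m)
    ij <- which(m, arr.ind = TRUE)
    pad_idx_list[[v]] <- ij[, 1] + (ij[, 2] - 1L) * dp[1]
    val_list[[v]] <- plane[m]
    w_list[[v]] <- if (weighting == "poisson") 1 / pmax(plane[m], 1) else rep(1, sum(m))
    padded <- matrix(0, dp[1], dp[2])
    padded[seq_len(d[2]), seq_len(d[3])] <- plane * !m
    F_list[[v]] <- stats::fft(padded)
  }
  npad <- prod(dp)

  warm <- vector("list", d[1]) # converged tail estimates, reused across
  # candidate evaluations (the fixed point is unique, so the warm start
  # only affects the iteration count, not the solution)
  objective_log <- function(la, lb) {
    S <- stats::plogis(-(la + exp(lb) * grid_f$f2))
    tot <- 0
    for (v in views) {
      ti <- idx_list[[v]]
      if (!length(ti)) next
      pidx <- pad_idx_list[[v]]
      base_t <- Re(stats::fft(F_list[[v]] * S, inverse = TRUE))[pidx] / npad
      # self-consistent tail scatter: s = base + conv(s * 1_tail) at the
      # tail bins; geometric convergence (the tail-to-tail return mass is
      # below the kernel's DC gain)
      s_t <- if (is.null(warm[[v]])) base_t else warm[[v]]
      feed <- matrix(0, dp[1], dp[2])
      iterate <- function(s) {
        feed[pidx] <- s
        base_t + Re(stats::fft(stats::fft(feed) * S, inverse = TRUE))[pidx] / npad
      }
      # the map is linear and contractive; Aitken extrapolation along the
      # dominant mode cuts the iteration count by an order of magnitude.
      # 1e-7 relative is far below the objective differences the search
      # discriminates, so the cap is cheap insurance, not an accuracy limit
      for (it in seq_len(15L)) {
        s1 <- iterate(s_t)
        s2 <- iterate(s1)
        d1 <- s1 - s_t
        d2 <- s2 - s1
        den <- sum(d1 * d1)
        lam <- if (den > 0) sum(d2 * d1) / den else 0
        s_t <- if (lam > 0 && lam < 0.99) s2 + d2 * (lam / (1 - lam)) else s2
        if (max(abs(d2)) <= 1e-7 * max(abs(s_t), 1e-12)) break
      }
      warm[[v]] <<- s_t
      if (objective == "poisson") {
        s_pos <- pmax(s_t, 1e-12)
        tot <- tot + sum(s_pos - val_list[[v]] * log(s_pos))
      } else {
        r <- s_t - val_list[[v]]
        tot <- tot + sum(w_list[[v]] * r * r)
      }
    }
    tot
  }

  la_lim <- log(bounds$alpha)
  lb_lim <- log(bounds$beta)
  la_grid <- seq(la_lim[1], la_lim[2], length.out = grid_density[1])
  profile_alpha <- function(lb, tol = 1e-3) {
    # scan then refine: the alpha slice can be multimodal on noisy data
    ovals <- vapply(la_grid, objective_log, numeric(1), lb = lb)
    ja <- which.min(ovals)
    o <- stats::optimize(function(la) objective_log(la, lb),
      lower = la_grid[max(ja - 1L, 1L)],
      upper = la_grid[min(ja + 1L, length(la_grid))],
      tol = tol
    )
    if (ovals[ja] < o$objective) {
      o <- list(minimum = la_grid[ja], objective = ovals[ja])
    }
    o
  }
  lb_grid <- seq(lb_lim[1], lb_lim[2], length.out = grid_density[2])
  prof <- lapply(lb_grid, profile_alpha)
  prof_obj <- vapply(prof, `[[`, numeric(1), "objective")
  jb <- which.min(prof_obj)
  best <- c(prof[[jb]]$minimum, lb_grid[jb])
  best_obj <- prof_obj[jb]

  if (refine) {
    # the beta profile can carry more than one dip (near-twin kernels);
    # refine every local minimum of the scanned profile and keep the best
    nb <- length(lb_grid)
    is_locmin <- vapply(seq_len(nb), function(j) {
      (j == 1L || prof_obj[j] <= prof_obj[j - 1L]) &&
        (j == nb || prof_obj[j] <= prof_obj[j + 1L])
    }, logical(1))
    # noise can dimple the profile; refine only the deepest few dips
    locs <- which(is_locmin)
    locs <- locs[order(prof_obj[locs])][seq_len(min(3L, length(locs)))]
    for (j in locs) {
      lo <- lb_grid[max(j - 1L, 1L)]
      hi <- lb_grid[min(j + 1L, nb)]
      if (hi <= lo) next
      ob <- stats::optimize(function(lb) profile_alpha(lb, tol = 1e-5)$objective,
        lower = lo, upper = hi, tol = 1e-7
      )
      fin <- profile_alpha(ob$minimum, tol = 1e-8)
      if (fin$objective < best_obj) {
        best <- c(fin$minimum, ob$minimum)
        best_obj <- fin$objective
      }
    }
  }

  at_bound <- c(
    alpha = min(abs(best[1] - la_lim)) < 1e-3,
    beta = min(abs(best[2] - lb_lim)) < 1e-3
  )
  structure(
    list(
      params = kernel_params(exp(best[1]), exp(best[2])),
      objective = best_obj,
      objective_type = objective,
      n_tail_bins = sum(mask),
      at_bound = at_bound,
      mode = mode,
      weighting = weighting
    ),
    class = "kernel_fit"
  )
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf(
    "<kernel_fit> alpha = %.5g, beta = %.5g cm^2 | objective %.4g over %d tail bins%s\n",
    x$params$alpha, x$params$beta, x$objective, x$n_tail_bins,
    if (any(x$at_bound)) " [optimum at a bound]" else ""
  ))
  invisible(x)
}

#' @export
coef.kernel_fit <- function(object, ...) {
  c(alpha = object$params$alpha, beta = object$params$beta)
}

#' Assemble a calibration table from per-phantom fits
#'
#' @param volumes_cm3 numeric vector of object volumes.
#' @param fits list of [kernel_params()] or `kernel_fit` objects, matching
#'   `volumes_cm3`.
#' @return a [calibration_table()] sorted by volume.
#' @export
build_calibration_table <- function(volumes_cm3, fits) {
  stopifnot(length(volumes_cm3) == length(fits), length(fits) >= 1L)
  pars <- lapply(fits, function(f) {
    if (inherits(f, "kernel_fit")) f$params else f
  })
  ok <- vapply(pars, inherits, logical(1), what = "kernel_params")
  if (!all(ok)) stop("fits must be kernel_params or kernel_fit objects")
  calibration_table(
    volumes_cm3,
    vapply(pars, function(p) p$alpha, numeric(1)),
    vapply(pars, function(p) p$beta, numeric(1))
  )
}
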