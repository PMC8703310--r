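#' Fitting configuration
#'
#' Control parameters of the linear-combination fit. The defaults mirror the
#' control values used for in vivo \eqn{^{31}}P analysis: per-signal
#' frequency adjustments with a 0.01 ppm Gaussian prior; zero-order phase
#' prior -96 +/- 10 degrees; first-order phase prior 7 +/- 4 degrees/ppm;
#' the reference peak (PCr) pinned at 0 ppm; a minimum baseline knot spacing
#' of 99 ppm (one spline segment across the whole window, i.e. an almost
#' rigid smooth baseline) with the regularizer weight chosen by generalized
#' cross-validation inside the configured bounds.
#'
#' @param shift_sd Prior SD of per-signal frequency adjustment, ppm.
#' @param phase0_mean,phase0_sd Zero-order phase prior, degrees.
#' @param phase1_mean,phase1_sd First-order phase prior, degrees/ppm.
#' @param reference_peak Label whose frequency adjustment is fixed at 0.
#' @param baseline_knot_spacing Minimum spline knot spacing, ppm.
#' @param baseline_alpha_min,baseline_alpha_max Bounds of the baseline
#'   smoothing weight explored by GCV.
#' @param baseline_enabled Logical; include a spline baseline.
#' @param broadening_max Upper bound on the shared extra Lorentzian
#'   broadening, Hz.
#' @param shift_max Hard bound on per-signal adjustment, ppm.
#' @param fit_window ppm interval fitted (clipped to the axis).
#' @param noise_window ppm interval assumed signal-free for noise estimation.
#' @param amplitude_nonneg Logical; constrain amplitudes to be nonnegative.
#' @param maxit Maximum outer iterations.
#' @return A `phos_fit_config` list.
#' @export
fit_config <- function(shift_sd = 0.01,
                       phase0_mean = -96, phase0_sd = 10,
                       phase1_mean = 7, phase1_sd = 4,
                       reference_peak = "PCr",
                       baseline_knot_spacing = 99,
                       baseline_alpha_min = 7.8e-10,
                       baseline_alpha_max = 3.9e-7,
                       baseline_enabled = TRUE,
                       broadening_max = 25,
                       shift_max = 0.3,
                       fit_window = c(-20, 10),
                       noise_window = c(12, 18),
                       amplitude_nonneg = TRUE,
                       maxit = 400L) {
  stopifnot(shift_sd > 0, phase0_sd > 0, phase1_sd > 0,
            baseline_knot_spacing > 0, broadening_max > 0,
            fit_window[1] < fit_window[2])
  structure(list(shift_sd = shift_sd, phase0_mean = phase0_mean,
                 phase0_sd = phase0_sd, phase1_mean = phase1_mean,
                 phase1_sd = phase1_sd, reference_peak = reference_peak,
                 baseline_knot_spacing = baseline_knot_spacing,
                 baseline_alpha_min = baseline_alpha_min,
                 baseline_alpha_max = baseline_alpha_max,
                 baseline_enabled = baseline_enabled,
                 broadening_max = broadening_max, shift_max = shift_max,
                 fit_window = fit_window, noise_window = noise_window,
                 amplitude_nonneg = amplitude_nonneg,
                 maxit = as.integer(maxit)),
            class = "phos_fit_config")
}

wrap_deg <- function(x) ((x + 180) %% 360) - 180

# column-wise DFT under the package transform contract
spec_fft_mat <- function(X, axis) {
  X[1, ] <- X[1, ] / 2
  f <- stats::mvfft(X)
  n <- axis$n_points
  nneg <- floor(n / 2)
  asc <- rbind(f[(n - nneg + 1):n, , drop = FALSE],
               f[1:(n - nneg), , drop = FALSE])
  asc[n:1, , drop = FALSE]
}

# Estimate the per-channel frequency-domain noise SD from a signal-free
# region; falls back to the outermost high-ppm decile if the configured
# window misses the axis.
estimate_noise_sd <- function(spectrum, config) {
  ppm <- spectrum$axis$ppm
  idx <- which(ppm >= config$noise_window[1] & ppm <= config$noise_window[2])
  if (length(idx) < 16) {
    hi <- stats::quantile(ppm, 0.9)
    idx <- which(ppm >= hi)
  }
  v <- c(Re(spectrum$freq[idx]), Im(spectrum$freq[idx]))
  stats::sd(v - mean(v))
}

# Baseline spline design on the fit window plus its second-difference
# penalty matrix (NULL when the baseline has too few coefficients to
# penalize or is disabled).
baseline_design <- function(ppm_w, config) {
  if (!config$baseline_enabled)
    return(list(B = NULL, D = NULL, nb = 0L))
  rng <- range(ppm_w)
  span <- diff(rng)
  nseg <- max(1L, floor(span / config$baseline_knot_spacing))
  knots <- if (nseg > 1) seq(rng[1], rng[2], length.out = nseg + 1L)[-c(1, nseg + 1L)] else NULL
  B <- splines::bs(ppm_w, knots = knots, degree = 3, intercept = TRUE,
                   Boundary.knots = rng)
  B <- unclass(B); attributes(B) <- attributes(B)["dim"]
  nb <- ncol(B)
  D <- if (nb >= 3) diff(diag(nb), differences = 2) else NULL
  list(B = B, D = D, nb = nb)
}

# Internal: everything both the optimizer and the CRLB need at a given
# parameter vector.
fit_engine <- function(spectrum, basis, config) {
  axis <- spectrum$axis
  if (!axes_equal(axis, basis$axis)) {
    ba <- basis$axis
    if (abs(ba$dwell_s - axis$dwell_s) < 1e-12 &&
        abs(ba$larmor_mhz - axis$larmor_mhz) < 1e-9 &&
        ba$n_points >= axis$n_points) {
      # same dwell: truncate member FIDs to the spectrum length
      basis$members <- lapply(basis$members, function(m)
        as_spectrum(m$fid[seq_len(axis$n_points)], axis, m$provenance))
      basis$axis <- axis
    } else {
      stop("fit_spectrum: spectrum and basis axes are incompatible")
    }
  }
  K <- length(basis$members)
  labels <- basis$labels
  Fm <- vapply(basis$members, function(m) m$fid, complex(axis$n_points))
  ppm <- axis$ppm
  win <- c(max(config$fit_window[1], min(ppm)),
           min(config$fit_window[2], max(ppm)))
  idx <- which(ppm >= win[1] & ppm <= win[2])
  if (length(idx) < K + 8) stop("fit window too small")
  ppm_w <- ppm[idx]
  bl <- baseline_design(ppm_w, config)
  t_s <- axis$time_s
  L <- axis$larmor_mhz  # Hz per ppm
  free <- which(labels != config$reference_peak)
  list(axis = axis, basis = basis, K = K, labels = labels, Fm = Fm,
       idx = idx, ppm_w = ppm_w, bl = bl, t_s = t_s, L = L, free = free,
       D = spectrum$freq[idx], config = config)
}

# Modified (shifted + broadened) member columns over the window.
member_columns <- function(eng, delta, gamma) {
  mods <- exp((2i * pi * eng$L * outer(eng$t_s, delta)) - pi * gamma * eng$t_s)
  G <- eng$Fm * mods
  list(C = spec_fft_mat(G, eng$axis)[eng$idx, , drop = FALSE], G = G)
}

stack_design <- function(C, bl, alpha) {
  W <- nrow(C); K <- ncol(C)
  A <- rbind(Re(C), Im(C))
  if (!is.null(bl$B)) {
    Z <- matrix(0, W, bl$nb)
    A <- cbind(A, rbind(bl$B, Z), rbind(Z, bl$B))
    if (!is.null(bl$D) && alpha > 0) {
      pen <- sqrt(alpha) * bl$D
      zK <- matrix(0, nrow(pen), K)
      z2 <- matrix(0, nrow(pen), bl$nb)
      A <- rbind(A, cbind(zK, pen, z2), cbind(zK, z2, pen))
    }
  }
  A
}

# GCV selection of the baseline penalty weight on the unconstrained
# penalized problem at the initial parameter values.
select_alpha <- function(eng, C, d) {
  bl <- eng$bl
  cfg <- eng$config
  if (is.null(bl$D)) return(0)
  A0 <- stack_design(C, bl, 0)
  y <- c(Re(d), Im(d))
  n <- length(y)
  K <- ncol(C)
  P0 <- matrix(0, ncol(A0), ncol(A0))
  ib1 <- K + seq_len(bl$nb)
  ib2 <- K + bl$nb + seq_len(bl$nb)
  DtD <- crossprod(bl$D)
  grid <- exp(seq(log(cfg$baseline_alpha_min), log(cfg$baseline_alpha_max),
                  length.out = 7))
  AtA <- crossprod(A0); Aty <- crossprod(A0, y)
  best <- grid[1]; best_score <- Inf
  for (a in grid) {
    P <- P0; P[ib1, ib1] <- a * DtD; P[ib2, ib2] <- a * DtD
    M <- AtA + P
    sol <- tryCatch(solve(M, cbind(Aty, t(A0))), error = function(e) NULL)
    if (is.null(sol)) next
    x <- sol[, 1]
    H_diag_sum <- sum(A0 * t(sol[, -1, drop = FALSE]))  # tr(A0 M^-1 A0')
    rss <- sum((y - A0 %*% x)^2)
    score <- (rss / n) / (1 - min(H_diag_sum / n, 0.99))^2
    if (score < best_score) { best_score <- score; best <- a }
  }
  best
}

#' Fit a spectrum by linear combination of basis spectra
#'
#' Minimizes the squared discrepancy between the measured complex spectrum
#' and a model built from amplitude-scaled, frequency-shifted, Lorentzian-
#' broadened basis members plus a penalized-spline baseline, over the
#' configured ppm window, with Gaussian priors on the phases and the
#' per-signal frequency adjustments. Zero- and first-order phase are applied
#' to the data; the inner linear subproblem (amplitudes under a
#' nonnegativity constraint, plus baseline coefficients) is solved exactly by
#' active-set least squares at every step of a quasi-Newton outer
#' optimization over (shifts, broadening, phase0, phase1) with analytic
#' envelope gradients. The fit is deterministic: initialization is fixed
#' (shifts 0, broadening from the tallest-peak width, phases at their prior
#' means refined by a coarse phase0 grid search).
#'
#' @param spectrum A `phos_spectrum`.
#' @param basis A `phos_basis` on a compatible axis (same dwell; a longer
#'   basis is truncated, anything else is an error).
#' @param config A [fit_config()].
#' @return An object of class `phos_fit` with elements `amplitudes`,
#'   `shifts_ppm`, `broadening_hz`, `phase0_deg`, `phase1_deg_ppm`,
#'   `baseline` (complex, on the window), `fitted` (complex model incl.
#'   baseline, data domain), `residual` (data - fitted), `noise_sd`,
#'   `relative_intensities`, `relative_crlb`, `diagnostics`.
#' @export
fit_spectrum <- function(spectrum, basis, config = fit_config()) {
  stopifnot(inherits(spectrum, "phos_spectrum"), inherits(basis, "phos_basis"))
  eng <- fit_engine(spectrum, basis, config)
  basis <- eng$basis   # possibly truncated to the spectrum axis
  K <- eng$K
  noise_sd <- estimate_noise_sd(spectrum, config)
  scale <- max(Mod(eng$D))
  if (scale <= 0) stop("empty spectrum")
  d0 <- eng$D / scale
  sig_n <- max(noise_sd / scale, 1e-12)
  nonneg <- if (config$amplitude_nonneg) seq_len(K) else integer()

  # initialization: broadening from the tallest peak's apparent FWHM
  mag <- Mod(eng$D)
  pk <- which.max(mag)
  half <- mag[pk] / 2
  lo <- pk; while (lo > 1 && mag[lo] > half) lo <- lo - 1
  hi <- pk; while (hi < length(mag) && mag[hi] > half) hi <- hi + 1
  fwhm_obs <- abs(eng$ppm_w[min(hi, length(mag))] - eng$ppm_w[lo]) * eng$L
  gamma0 <- min(max(fwhm_obs - min(basis$fwhm_hz), 0), config$broadening_max)

  alpha <- {
    cols0 <- member_columns(eng, numeric(K), gamma0)
    ph0 <- (config$phase0_mean + config$phase1_mean * eng$ppm_w) * pi / 180
    select_alpha(eng, cols0$C, d0 * exp(-1i * ph0))
  }

  prior <- function(delta, p0, p1) {
    sum((delta / config$shift_sd)^2) +
      (wrap_deg(p0 - config$phase0_mean) / config$phase0_sd)^2 +
      ((p1 - config$phase1_mean) / config$phase1_sd)^2
  }

  nfree <- length(eng$free)
  unpack <- function(par) {
    delta <- numeric(K)
    delta[eng$free] <- par[seq_len(nfree)]
    list(delta = delta, gamma = par[nfree + 1],
         p0 = par[nfree + 2], p1 = par[nfree + 3])
  }

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    th <- unpack(par)
    cols <- member_columns(eng, th$delta, th$gamma)
    phw <- (th$p0 + th$p1 * eng$ppm_w) * pi / 180
    dph <- d0 * exp(-1i * phw)
    A <- stack_design(cols$C, eng$bl, alpha)
    y <- c(Re(dph), Im(dph), numeric(nrow(A) - 2 * length(dph)))
    sol <- bounded_ls(A, y, nonneg)
    x <- sol$x
    a <- x[seq_len(K)]
    nb <- eng$bl$nb
    bline <- if (nb > 0)
      complex(real = eng$bl$B %*% x[K + seq_len(nb)],
              imaginary = eng$bl$B %*% x[K + nb + seq_len(nb)])
    else complex(real = numeric(length(dph)))
    rc <- drop(cols$C %*% a) + bline - dph
    penb <- if (!is.null(eng$bl$D) && alpha > 0)
      alpha * (sum((eng$bl$D %*% x[K + seq_len(nb)])^2) +
               sum((eng$bl$D %*% x[K + nb + seq_len(nb)])^2)) else 0
    obj <- sum(Mod(rc)^2) + penb + sig_n^2 * prior(th$delta, th$p0, th$p1)
    # envelope gradient (linear coefficients held at their optimum)
    gpar <- numeric(length(par))
    dG <- cols$G * (2i * pi * eng$L * eng$t_s)
    dC <- spec_fft_mat(dG, eng$axis)[eng$idx, , drop = FALSE]
    for (j in seq_len(nfree)) {
      m <- eng$free[j]
      gpar[j] <- 2 * sum(Re(Conj(rc) * (a[m] * dC[, m]))) +
        sig_n^2 * 2 * th$delta[m] / config$shift_sd^2
    }
    gfid <- (cols$G %*% a) * (-pi * eng$t_s)
    dCg <- spec_fft_mat(gfid, eng$axis)[eng$idx, , drop = FALSE]
    gpar[nfree + 1] <- 2 * sum(Re(Conj(rc) * dCg))
    # d(rc)/d(phase) = -d(dph)/d(phase) = +i * (pi/180) * scale_term * dph
    gpar[nfree + 2] <- 2 * sum(Re(Conj(rc) * (1i * pi / 180 * dph))) +
      sig_n^2 * 2 * wrap_deg(th$p0 - config$phase0_mean) / config$phase0_sd^2
    gpar[nfree + 3] <- 2 * sum(Re(Conj(rc) * (1i * pi / 180 * eng$ppm_w * dph))) +
      sig_n^2 * 2 * (th$p1 - config$phase1_mean) / config$phase1_sd^2
    val <- list(obj = obj, grad = gpar, a = a, x = x, rc = rc,
                baseline = bline, C = cols$C, G = cols$G, dph = dph,
                phw = phw, sol = sol)
    cache$key <- key; cache$val <- val
    val
  }

  # coarse zero-order phase initialization: the envelope gradient vanishes
  # when all amplitudes clamp to zero at a badly wrong phase, so scan first
  p0_grid <- wrap_deg(config$phase0_mean + seq(-180, 150, by = 30))
  par0 <- c(numeric(nfree), gamma0, config$phase0_mean, config$phase1_mean)
  obj_at <- function(p0) {
    par0[nfree + 2] <- p0
    evaluate(par0)$obj
  }
  p0_best <- p0_grid[which.min(vapply(p0_grid, obj_at, numeric(1)))]
  par0[nfree + 2] <- p0_best

  lower <- c(rep(-config$shift_max, nfree), 0, -1e4, -1e4)
  upper <- c(rep(config$shift_max, nfree), config$broadening_max, 1e4, 1e4)
  opt <- stats::optim(par0, fn = function(p) evaluate(p)$obj,
                      gr = function(p) evaluate(p)$grad,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = config$maxit, factr = 1e4,
                                     pgtol = 1e-12,
                                     parscale = c(rep(config$shift_sd, nfree),
                                                  1, config$phase0_sd,
                                                  config$phase1_sd)))
  fin <- evaluate(opt$par)
  th <- unpack(opt$par)
  amplitudes <- fin$a * scale
  names(amplitudes) <- eng$labels
  shifts <- th$delta; names(shifts) <- eng$labels
  fitted <- (drop(fin$C %*% fin$a) + fin$baseline) * exp(1i * fin$phw) * scale
  residual <- eng$D - fitted
  fit <- list(amplitudes = amplitudes, shifts_ppm = shifts,
              broadening_hz = th$gamma, phase0_deg = wrap_deg(th$p0),
              phase1_deg_ppm = th$p1,
              baseline = fin$baseline * scale, baseline_ppm = eng$ppm_w,
              fitted = fitted, residual = residual,
              window_idx = eng$idx, window_ppm = eng$ppm_w,
              noise_sd = noise_sd, scale = scale, alpha = alpha,
              linear_coef = fin$x * scale,
              labels = eng$labels, config = config,
              diagnostics = list(converged = opt$convergence == 0,
                                 optim_code = opt$convergence,
                                 message = opt$message,
                                 counts = opt$counts,
                                 objective = fin$obj,
                                 nnls_iters = fin$sol$iters,
                                 alpha = alpha))
  class(fit) <- "phos_fit"
  if (!fit$diagnostics$converged)
    warning("fit_spectrum: optimizer did not report convergence")
  fit$relative_intensities <- relative_intensities(fit)
  fit$relative_crlb <- tryCatch(estimate_crlb(fit, basis, config),
                                error = function(e) {
                                  fit$diagnostics$crlb_error <<- conditionMessage(e)
                                  rep(NA_real_, length(eng$labels))
                                })
  fit
}

#' @export
print.phos_fit <- function(x, ...) {
  cat(sprintf(
    "<phos_fit> %d signals, broadening %.2f Hz, phase0 %.1f deg, phase1 %.2f deg/ppm%s\n",
    length(x$amplitudes), x$broadening_hz, x$phase0_deg, x$phase1_deg_ppm,
    if (x$diagnostics$converged) "" else " [NOT CONVERGED]"))
  df <- data.frame(label = x$labels,
                   amplitude = signif(unname(x$amplitudes), 5),
                   shift_ppm = signif(unname(x$shifts_ppm), 3),
                   rel_crlb_pct = signif(unname(x$relative_crlb), 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cramer-Rao lower bounds of the fitted amplitudes
#'
#' Assembles the Fisher information from the analytic partial derivatives of
#' the complex model (amplitudes, free frequency adjustments, shared
#' broadening, both phases, baseline coefficients) over the real and
#' imaginary channels of the fit window, scaled by the noise variance, and
#' reports `100 * sqrt((F^-1)_mm) / amplitude_m` per signal. Amplitudes at
#' the nonnegativity boundary are reported as `NA` (their bound is
#' undefined); a singular information matrix falls back to a pseudo-inverse
#' with a diagnostics flag.
#'
#' @param fit A `phos_fit`.
#' @param basis The basis used for the fit.
#' @param config The fit configuration.
#' @param noise_sd Optional override of the noise SD (default: the fit's).
#' @return Named vector of relative CRLBs in percent. Attribute
#'   `"crlb_abs"` carries the absolute amplitude bounds; attribute
#'   `"singular"` flags pseudo-inversion.
#' @export
estimate_crlb <- function(fit, basis, config = fit$config, noise_sd = NULL) {
  stopifnot(inherits(fit, "phos_fit"))
  sigma <- if (is.null(noise_sd)) fit$noise_sd else noise_sd
  if (!is.finite(sigma) || sigma <= 0) stop("positive noise_sd required")
  eng <- list(axis = basis$axis,
              Fm = vapply(basis$members, function(m) m$fid,
                          complex(basis$axis$n_points)),
              t_s = basis$axis$time_s, L = basis$axis$larmor_mhz,
              idx = fit$window_idx)
  K <- length(fit$labels)
  cols <- {
    mods <- exp((2i * pi * eng$L * outer(eng$t_s, unname(fit$shifts_ppm))) -
                  pi * fit$broadening_hz * eng$t_s)
    G <- eng$Fm * mods
    list(C = spec_fft_mat(G, basis$axis)[eng$idx, , drop = FALSE], G = G)
  }
  a <- unname(fit$amplitudes)
  phw <- (fit$phase0_deg + fit$phase1_deg_ppm * fit$window_ppm) * pi / 180
  eip <- exp(1i * phw)
  active <- a > 0
  free_shift <- active & fit$labels != config$reference_peak
  Msig <- drop(cols$C %*% a) + fit$baseline
  Jc <- list()
  cn <- character()
  for (m in which(active)) {
    Jc[[length(Jc) + 1]] <- eip * cols$C[, m]
    cn <- c(cn, paste0("amp_", fit$labels[m]))
  }
  dC <- spec_fft_mat(cols$G * (2i * pi * eng$L * eng$t_s),
                     basis$axis)[eng$idx, , drop = FALSE]
  for (m in which(free_shift)) {
    Jc[[length(Jc) + 1]] <- eip * a[m] * dC[, m]
    cn <- c(cn, paste0("shift_", fit$labels[m]))
  }
  dCg <- spec_fft_mat((cols$G %*% a) * (-pi * eng$t_s),
                      basis$axis)[eng$idx, , drop = FALSE]
  Jc[[length(Jc) + 1]] <- eip * drop(dCg); cn <- c(cn, "broadening")
  Jc[[length(Jc) + 1]] <- 1i * pi / 180 * eip * Msig; cn <- c(cn, "phase0")
  Jc[[length(Jc) + 1]] <- 1i * pi / 180 * fit$window_ppm * eip * Msig
  cn <- c(cn, "phase1")
  bl <- baseline_design(fit$window_ppm, config)
  if (!is.null(bl$B)) {
    for (j in seq_len(bl$nb)) {
      Jc[[length(Jc) + 1]] <- eip * bl$B[, j]
      cn <- c(cn, paste0("bre_", j))
    }
    for (j in seq_len(bl$nb)) {
      Jc[[length(Jc) + 1]] <- 1i * eip * bl$B[, j]
      cn <- c(cn, paste0("bim_", j))
    }
  }
  Jcm <- do.call(cbind, Jc)
  J <- rbind(Re(Jcm), Im(Jcm))
  FI <- crossprod(J) / sigma^2
  # Jacobi equilibration: parameters have wildly different units (amplitude,
  # ppm, Hz, degrees), so condition the matrix before inverting
  dsc <- 1 / sqrt(pmax(diag(FI), .Machine$double.xmin))
  FIs <- FI * tcrossprod(dsc)
  singular <- FALSE
  Covs <- tryCatch(solve(FIs), error = function(e) NULL)
  if (is.null(Covs)) {
    singular <- TRUE
    s <- svd(FIs)
    pos <- s$d > max(s$d) * 1e-12
    Covs <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  Cov <- Covs * tcrossprod(dsc)
  crlb_abs <- rep(NA_real_, K)
  amp_cols <- match(paste0("amp_", fit$labels[active]), cn)
  crlb_abs[active] <- sqrt(pmax(diag(Cov)[amp_cols], 0))
  rel <- 100 * crlb_abs / a
  rel[!active] <- NA_real_
  names(rel) <- fit$labels
  attr(rel, "crlb_abs") <- stats::setNames(crlb_abs, fit$labels)
  attr(rel, "singular") <- singular
  if (singular) warning("Fisher information singular; pseudo-inverse used")
  rel
}

#' Relative signal intensities
#'
#' Expresses fitted amplitudes as percentages of the summed amplitude over a
#' reporting subset; the default subset is the six prominent signals used
#' for tissue comparisons (gamma-, alpha-, beta-ATP, GPC, PCr, Pi) when they
#' are all present, otherwise all fitted signals.
#'
#' @param fit A `phos_fit`, or a named numeric vector of amplitudes.
#' @param subset Character vector of labels to report over.
#' @return Named percentages summing to 100.
#' @export
relative_intensities <- function(fit, subset = NULL) {
  amps <- if (inherits(fit, "phos_fit")) fit$amplitudes else fit
  if (is.null(subset)) {
    std <- c("gATP", "aATP", "bATP", "GPC", "PCr", "Pi")
    subset <- if (all(std %in% names(amps))) std else names(amps)
  }
  if (!length(subset)) stop("empty reporting subset")
  missing <- setdiff(subset, names(amps))
  if (length(missing))
    stop("labels not in fit: ", paste(missing, collapse = ", "))
  a <- amps[subset]
  tot <- sum(a)
  if (tot <= 0) stop("all amplitudes in the reporting subset are zero")
  100 * a / tot
}

#' Grade agreement from a coefficient of variation
#'
#' Four-level grading of between-method agreement: CV below 10 percent is
#' "very good", 10-20 "good", 20-30 "acceptable", above 30 "not acceptable".
#'
#' @param cv Coefficient(s) of variation in percent.
#' @return Character vector of grades.
#' @export
grade_agreement <- function(cv) {
  ifelse(cv < 10, "very good",
         ifelse(cv <= 20, "good",
                ifelse(cv <= 30, "acceptable", "not acceptable")))
}

#' Compare two quantification methods by coefficient of variation
#'
#' For each spectrum and signal, computes the CV of the pair of relative
#' intensities `100 * sd(pair) / mean(pair)` (sample SD of two values, i.e.
#' `|a - b| / sqrt(2)`), then averages across spectra per signal and grades
#' the agreement via [grade_agreement()].
#'
#' @param results_a,results_b Equal-length lists of named numeric vectors of
#'   relative intensities (one vector per spectrum, matching labels).
#' @return A list with `per_spectrum` (matrix of CVs, spectra x signals),
#'   `mean_cv` (named vector) and `grade` (named character vector).
#' @export
compare_methods <- function(results_a, results_b) {
  stopifnot(length(results_a) == length(results_b), length(results_a) >= 1)
  labs <- names(results_a[[1]])
  cvm <- matrix(NA_real_, length(results_a), length(labs),
                dimnames = list(NULL, labs))
  for (i in seq_along(results_a)) {
    a <- results_a[[i]]; b <- results_b[[i]]
    if (!identical(sort(names(a)), sort(names(b))) ||
        !all(labs %in% names(a)))
      stop("compare_methods: label mismatch in spectrum ", i)
    b <- b[names(a)]
    sdp <- abs(a[labs] - b[labs]) / sqrt(2)
    mn <- (a[labs] + b[labs]) / 2
    cvm[i, ] <- 100 * sdp / mn
  }
  mean_cv <- colMeans(cvm)
  list(per_spectrum = cvm, mean_cv = mean_cv,
       grade = stats::setNames(grade_agreement(mean_cv), labs))
}
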