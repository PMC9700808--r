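#' Construct a protein decay (cycloheximide-chase) dataset
#'
#' @param time_h Time in hours since translation shut-off.
#' @param intensity Normalized band intensity (e.g. GFP/actin densitometry
#'   ratio); strictly positive.
#' @param label Free-text label.
#' @return A `decay_dataset` data frame with columns `time_h`, `intensity`.
#' @export
decay_dataset <- function(time_h, intensity, label = "") {
  time_h <- as.numeric(time_h); intensity <- as.numeric(intensity)
  if (length(time_h) != length(intensity)) stop("time/intensity length mismatch")
  if (length(time_h) < 3L) stop("need at least 3 observations")
  if (any(time_h < 0)) stop("negative time points")
  if (any(intensity <= 0)) stop("non-positive intensities")
  if (length(unique(time_h)) < 2L) stop("need at least 2 distinct time points")
  out <- data.frame(time_h = time_h, intensity = intensity)
  attr(out, "label") <- label
  class(out) <- c("decay_dataset", "data.frame")
  out
}

#' Read a decay time course from CSV
#'
#' Expected columns: `time_h`, `intensity`, optionally `replicate` (all
#' replicates are pooled for fitting). Units are fixed by the dialect: hours
#' and dimensionless normalized intensity.
#'
#' @param path CSV file path.
#' @param label Free-text label (defaults to the file name).
#' @return A `decay_dataset`.
#' @export
read_decay_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("time_h", "intensity"), names(df))
  if (length(miss)) stop("decay CSV lacks columns: ", paste(miss, collapse = ", "))
  decay_dataset(df$time_h, df$intensity, label = label)
}

#' Fit a protein half-life by least squares
#'
#' One-phase exponential decay without plateau, `y = I0 exp(-k t)`, fit
#' either by nonlinear least squares (initialized from the log-linear
#' estimate) or by ordinary least squares of `log y` on `t`. The half-life
#' is `t_half = ln 2 / k`. The two methods agree exactly on noiseless data;
#' on noisy data the nls fit weights large intensities more.
#'
#' @param d A `decay_dataset`.
#' @param method `"nls"` (default) or `"loglinear"`.
#' @param bootstrap Number of nonparametric bootstrap resamples for the
#'   half-life standard error (0 = none).
#' @param seed Seed for the bootstrap resampling.
#' @return A `half_life_fit`: list with `t_half` (hours), `k` (1/h), `i0`,
#'   `rss`, `n`, `method`, and `se_t_half` (NA without bootstrap).
#' @export
fit_half_life <- function(d, method = c("nls", "loglinear"),
                          bootstrap = 0L, seed = NULL) {
  stopifnot(inherits(d, "decay_dataset"))
  method <- match.arg(method)
  est <- half_life_point(d$time_h, d$intensity, method)
  se <- NA_real_
  if (bootstrap > 0L) {
    se <- local_seed(seed, {
      n <- nrow(d)
      reps <- vapply(seq_len(bootstrap), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        tryCatch(half_life_point(d$time_h[i], d$intensity[i], method)$t_half,
                 error = function(e) NA_real_)
      }, numeric(1))
      stats::sd(reps, na.rm = TRUE)
    })
  }
  out <- c(est, list(n = nrow(d), method = method, se_t_half = se,
                     label = attr(d, "label")))
  class(out) <- "half_life_fit"
  out
}

half_life_point <- function(t, y, method) {
  ll <- stats::lm(log(y) ~ t)
  k0 <- -unname(stats::coef(ll)[2L])
  i00 <- exp(unname(stats::coef(ll)[1L]))
  if (method == "loglinear") {
    if (!is.finite(k0) || k0 <= 0) stop("no measurable decay (k <= 0)")
    fitted <- i00 * exp(-k0 * t)
    return(list(t_half = log(2) / k0, k = k0, i0 = i00,
                rss = sum((y - fitted)^2)))
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- 1e-3
  fit <- minpack.lm::nlsLM(
    y ~ i0 * exp(-k * t),
    start = list(i0 = max(i00, 1e-12), k = k0),
    lower = c(i0 = 1e-12, k = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 1e-10) stop("no measurable decay (k <= 0)")
  list(t_half = log(2) / cf[["k"]], k = unname(cf[["k"]]),
       i0 = unname(cf[["i0"]]), rss = sum(stats::resid(fit)^2))
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("half_life_fit (%s): t1/2 = %.3g h (k = %.3g /h, I0 = %.3g)\n",
              x$method, x$t_half, x$k, x$i0))
  cat(sprintf("  n = %d, RSS = %.3g", x$n, x$rss))
  if (is.finite(x$se_t_half)) cat(sprintf(", bootstrap SE = %.3g h", x$se_t_half))
  cat("\n")
  invisible(x)
}

#' Construct a saturation binding dataset
#'
#' @param conc_uM Protein concentration in micromolar; non-negative.
#' @param fraction_bound Fraction of probe bound, in \[0, 1.05\] (slight
#'   overshoot above 1 tolerated for densitometry noise).
#' @param label Free-text label.
#' @return A `binding_dataset` data frame.
#' @export
binding_dataset <- function(conc_uM, fraction_bound, label = "") {
  conc_uM <- as.numeric(conc_uM); fraction_bound <- as.numeric(fraction_bound)
  if (length(conc_uM) != length(fraction_bound)) stop("length mismatch")
  if (length(conc_uM) < 4L) stop("need at least 4 observations")
  if (any(conc_uM < 0)) stop("negative concentrations")
  if (any(fraction_bound < 0 | fraction_bound > 1.05)) {
    stop("fraction_bound outside [0, 1.05]")
  }
  out <- data.frame(conc_uM = conc_uM, fraction_bound = fraction_bound)
  attr(out, "label") <- label
  class(out) <- c("binding_dataset", "data.frame")
  out
}

#' Read a binding curve from CSV
#'
#' Expected columns: `conc_uM`, `fraction_bound`.
#'
#' @param path CSV file path.
#' @param label Free-text label.
#' @return A `binding_dataset`.
#' @export
read_binding_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("conc_uM", "fraction_bound"), names(df))
  if (length(miss)) stop("binding CSV lacks columns: ", paste(miss, collapse = ", "))
  binding_dataset(df$conc_uM, df$fraction_bound, label = label)
}

#' Fit a one-site binding isotherm (Kd estimation)
#'
#' Least-squares fit of the hyperbola `f = Bmax c / (Kd + c)` (one-site
#' specific binding, Hill coefficient 1), as used for saturation EMSA data.
#' Initialization: `Kd` = concentration at half the maximal observed
#' fraction bound, `Bmax` = maximal observed fraction bound.
#'
#' @param d A `binding_dataset`.
#' @param fix_bmax Optional fixed `Bmax` (e.g. 1 for fully saturable probe);
#'   `NULL` (default) fits it.
#' @param bootstrap Number of bootstrap resamples for the Kd standard error.
#' @param seed Seed for the bootstrap.
#' @return A `kd_fit`: list with `kd` (micromolar), `bmax`, `rss`, `n`,
#'   `se_kd`.
#' @export
fit_kd <- function(d, fix_bmax = NULL, bootstrap = 0L, seed = NULL) {
  stopifnot(inherits(d, "binding_dataset"))
  bmax0 <- if (is.null(fix_bmax)) max(d$fraction_bound) else fix_bmax
  if (!any(d$fraction_bound > 0.5 * bmax0)) {
    warning("Kd poorly constrained: no observation above half-saturation")
  }
  est <- kd_point(d$conc_uM, d$fraction_bound, fix_bmax)
  se <- NA_real_
  if (bootstrap > 0L) {
    se <- local_seed(seed, {
      n <- nrow(d)
      reps <- vapply(seq_len(bootstrap), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        tryCatch(kd_point(d$conc_uM[i], d$fraction_bound[i], fix_bmax)$kd,
                 error = function(e) NA_real_)
      }, numeric(1))
      stats::sd(reps, na.rm = TRUE)
    })
  }
  out <- c(est, list(n = nrow(d), se_kd = se, label = attr(d, "label")))
  class(out) <- "kd_fit"
  out
}

kd_point <- function(conc, f, fix_bmax = NULL) {
  bmax0 <- if (is.null(fix_bmax)) max(f) else fix_bmax
  half <- bmax0 / 2
  above <- conc[f >= half]
  kd0 <- if (length(above)) min(above) else stats::median(conc[conc > 0])
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- 1
  if (is.null(fix_bmax)) {
    fit <- minpack.lm::nlsLM(
      f ~ bmax * conc / (kd + conc),
      start = list(bmax = max(bmax0, 1e-6), kd = kd0),
      lower = c(bmax = 1e-9, kd = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(fit)
    bmax <- unname(cf[["bmax"]])
  } else {
    bmax <- fix_bmax
    fit <- minpack.lm::nlsLM(
      f ~ bmax * conc / (kd + conc),
      start = list(kd = kd0), lower = c(kd = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(fit)
  }
  if (!fit$convInfo$isConv) {
    stop("Kd fit did not converge: ", fit$convInfo$stopMessage)
  }
  list(kd = unname(cf[["kd"]]), bmax = bmax, rss = sum(stats::resid(fit)^2))
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("kd_fit: Kd = %.3g uM (Bmax = %.3g)\n", x$kd, x$bmax))
  cat(sprintf("  n = %d, RSS = %.3g", x$n, x$rss))
  if (is.finite(x$se_kd)) cat(sprintf(", bootstrap SE = %.3g uM", x$se_kd))
  cat("\n")
  invisible(x)
}

#' Write a fit result as JSON
#'
#' @param fit A `half_life_fit` or `kd_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  expr
}
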