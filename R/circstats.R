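# Descriptive mobility-profile summaries and Watson-Williams tests for equal
# mean directions. Descriptive rows use ordinary arithmetic on degrees (the
# intervertebral angles are small, and the summary convention sum = n * mean
# then holds exactly); the Watson-Williams test uses the circular
# construction on radians.

#' Angle sample for one trial x profile group
#'
#' @param angles_deg numeric vector of intervertebral angles (degrees);
#'   `NA` entries (missing joints) are dropped.
#' @param group group label, e.g. `"PCVMLat"`.
#' @param joints optional joint ids aligned with `angles_deg`.
#' @return An `angle_sample`: list with `group`, `joints`, `degrees`,
#'   `radians`.
#' @export
angle_sample <- function(angles_deg, group = "sample", joints = NULL) {
  keep <- !is.na(angles_deg)
  a <- as.numeric(angles_deg[keep])
  if (!length(a)) stop("empty angle sample (sample error)")
  structure(list(group = group,
                 joints = if (!is.null(joints)) joints[keep],
                 degrees = a, radians = a * pi / 180),
            class = "angle_sample")
}

#' Descriptive summary of a mobility profile
#'
#' The summary-table row convention for one trial x profile group: count,
#' arithmetic mean, standard deviation, minimum, maximum, and the sum (the
#' total mobility of the neck, i.e. the summed per-joint maxima).
#'
#' @param sample an [angle_sample()] (or a numeric vector of degrees).
#' @return data.frame with columns `group`, `n`, `mean`, `s.d.`, `min`,
#'   `max`, `sum` (degrees).
#' @export
summarize_angles <- function(sample) {
  if (is.numeric(sample)) sample <- angle_sample(sample)
  a <- sample$degrees
  data.frame(group = sample$group, n = length(a), mean = mean(a),
             s.d. = if (length(a) > 1L) stats::sd(a) else 0,
             min = min(a), max = max(a), sum = sum(a),
             stringsAsFactors = FALSE)
}

# ---- circular primitives ----------------------------------------------------

circ_resultant <- function(rad) {
  c(C = sum(cos(rad)), S = sum(sin(rad)))
}

circ_mean_rad <- function(rad) {
  r <- circ_resultant(rad)
  atan2(r["S"], r["C"])
}

# Maximum-likelihood concentration from a mean resultant length, standard
# piecewise inversion of A(kappa) = I1/I0 (Fisher 1993, eq. 4.40-4.42).
kappa_from_rbar <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Watson-Williams test for equal mean directions
#'
#' F-type circular test of the null hypothesis that k groups of angles share
#' one mean direction:
#' `F = K * (N - k) * (sum R_i - R) / ((k - 1) * (N - sum R_i))`,
#' with `R_i` the group resultant lengths, `R` the pooled resultant length,
#' and `K = 1 + 3 / (8 kappa)` the concentration-based correction factor,
#' `kappa` estimated from the weighted group mean resultant length. The
#' p-value comes from the F distribution with `(k - 1, N - k)` degrees of
#' freedom. Assumption flags are raised when the estimated concentration is
#' low (`kappa < 1`, where the F approximation degrades) or the group
#' concentrations look heterogeneous.
#'
#' @param groups list of [angle_sample()] objects (k >= 2, each n_i >= 2), or
#'   a list of numeric vectors of degrees.
#' @return A `ww_test`: list with `F`, `df`, `p.value`, `K`, `kappa`,
#'   per-group `means_deg` and `R_i`, pooled `R`, and `flags`.
#' @export
watson_williams <- function(groups) {
  if (length(groups) < 2L) stop("need k >= 2 groups (test error)")
  groups <- lapply(groups, function(g)
    if (inherits(g, "angle_sample")) g else angle_sample(g))
  ns <- vapply(groups, function(g) length(g$radians), integer(1))
  if (any(ns < 2L)) stop("every group needs n >= 2 (test error)")
  k <- length(groups)
  N <- sum(ns)
  res <- lapply(groups, function(g) circ_resultant(g$radians))
  Ri <- vapply(res, function(r) sqrt(sum(r^2)), numeric(1))
  pooled <- Reduce(`+`, res)
  R <- sqrt(sum(pooled^2))
  rbar_w <- sum(Ri) / N
  kappa <- kappa_from_rbar(rbar_w)
  K <- 1 + 3 / (8 * kappa)
  within <- N - sum(Ri)   # within-group dispersion
  between <- sum(Ri) - R  # between-group dispersion
  if (within < 1e-9) {
    # perfectly concentrated groups: means either coincide or differ exactly
    Fstat <- if (between < 1e-9) 0 else Inf
  } else {
    Fstat <- max(0, K * ((N - k) * between) / ((k - 1) * within))
  }
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  kappa_i <- vapply(seq_len(k), function(i) kappa_from_rbar(Ri[i] / ns[i]),
                    numeric(1))
  flags <- character(0)
  if (kappa < 1) flags <- c(flags, "low concentration")
  ratio <- max(kappa_i) / max(min(kappa_i), 1e-12)
  if (is.finite(ratio) && ratio > 4)
    flags <- c(flags, "heterogeneous concentrations")
  structure(list(
    F = Fstat, df = c(k - 1, N - k), p.value = p, K = K, kappa = kappa,
    groups = vapply(groups, `[[`, character(1), "group"),
    n = ns,
    means_deg = vapply(groups, function(g)
      (circ_mean_rad(g$radians) * 180 / pi) %% 360, numeric(1)),
    R_i = Ri, R = R, rbar = rbar_w, flags = flags),
    class = "ww_test")
}

#' @export
print.ww_test <- function(x, ...) {
  cat("Watson-Williams test for equal mean directions\n")
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  F = %.5g on (%d, %d) df, p = %.5g (K = %.4f, kappa = %.3g)\n",
              x$F, x$df[1L], x$df[2L], x$p.value, x$K, x$kappa))
  if (length(x$flags)) cat("  assumption flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pairwise Watson-Williams comparison matrix
#'
#' Runs [watson_williams()] for every unordered pair of groups and lays the
#' p-values out as an upper-triangular matrix (rows = first k-1 groups,
#' columns = last k-1 groups), with significance marked at p <= 0.05.
#'
#' @param samples named list of [angle_sample()] objects (or numeric degree
#'   vectors), or a long-format angle table data.frame with columns
#'   `trial`, `profile`, `angle_deg` (groups = trial x profile).
#' @param alpha significance threshold for the `significant` marks.
#' @return A `ww_matrix`: list with `p` (matrix), `significant` (logical
#'   matrix), `tests` (list of `ww_test` keyed `"A|B"`), `alpha`.
#' @export
compare_all <- function(samples, alpha = 0.05) {
  if (is.data.frame(samples)) {
    need <- c("trial", "profile", "angle_deg")
    if (!all(need %in% names(samples)))
      stop("angle table needs columns ", paste(need, collapse = ","))
    abbr <- c(lateral = "Lat", dorsal = "Dors", ventral = "Vent")
    pf <- ifelse(samples$profile %in% names(abbr),
                 abbr[samples$profile], samples$profile)
    key <- paste0(samples$trial, pf)
    samples <- lapply(split(samples$angle_deg, key), function(a) a)
  }
  nms <- names(samples)
  if (is.null(nms)) nms <- paste0("G", seq_along(samples))
  samples <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (inherits(s, "angle_sample")) s else angle_sample(s, group = nms[i])
  })
  k <- length(samples)
  if (k < 2L) stop("need >= 2 groups (test error)")
  p <- matrix(NA_real_, k - 1L, k - 1L,
              dimnames = list(nms[seq_len(k - 1L)], nms[-1L]))
  tests <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tst <- tryCatch(watson_williams(samples[c(i, j)]), error = function(e) e)
      if (inherits(tst, "error")) next
      p[nms[i], nms[j]] <- tst$p.value
      tests[[paste(nms[i], nms[j], sep = "|")]] <- tst
    }
  }
  structure(list(p = p, significant = !is.na(p) & p <= alpha,
                 tests = tests, alpha = alpha),
            class = "ww_matrix")
}

#' @export
print.ww_matrix <- function(x, ...) {
  cat(sprintf("Pairwise Watson-Williams p-values (* marks p <= %g)\n", x$alpha))
  disp <- matrix("", nrow(x$p), ncol(x$p), dimnames = dimnames(x$p))
  for (i in seq_len(nrow(x$p))) for (j in seq_len(ncol(x$p))) {
    if (!is.na(x$p[i, j]))
      disp[i, j] <- paste0(signif(x$p[i, j], 4),
                           if (x$significant[i, j]) "*" else "")
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ww_matrix <- function(x, ...) {
  as.data.frame(x$p)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler; used by the test suite's calibration
#' simulations. Uses R's RNG stream, so `set.seed()` gives reproducibility.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (> 0).
#' @return numeric vector of angles in radians in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) stop("kappa must be > 0")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      u3 <- stats::runif(1)
      out[i] <- (sign(u3 - 0.5) * acos(f) + mu) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}
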