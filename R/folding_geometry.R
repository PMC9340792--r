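#' Change of basis between log-morphometrics and the folding variables K, S, I
#'
#' A cortical hemisphere (or curvature-corrected lobe) is summarized by three
#' primary morphometrics: average cortical thickness \eqn{T} (mm), total pial
#' area \eqn{A_T} (mm\eqn{^2}) and exposed (hull) area \eqn{A_E}
#' (mm\eqn{^2}).  Under the self-similar folding model these obey the
#' power law \eqn{T^{1/2} A_T = k\, A_E^{\alpha}} with theoretical exponent
#' \eqn{\alpha = 5/4}.  Working with the base-10 logs
#' \eqn{(x_{AT}, x_{AE}, x_{T^2}) = (\log_{10} A_T, \log_{10} A_E,
#' \log_{10} T^2)}, the model suggests a rotated basis:
#' \itemize{
#'   \item \eqn{K = x_{AT} - \frac{5}{4} x_{AE} + \frac{1}{4} x_{T^2}}
#'     (\eqn{= \log_{10} k}), a near-invariant tied to the viscoelastic
#'     properties of cortical matter;
#'   \item \eqn{I = x_{AT} + x_{AE} + x_{T^2}}, the isometric-volume axis
#'     (all areas scale together);
#'   \item \eqn{S}, a dimensionless shape axis.  Two variants are supported:
#'     \code{"orthogonal"} (the default), \eqn{S = \frac{3}{2} x_{AT} +
#'     \frac{3}{4} x_{AE} - \frac{9}{4} x_{T^2}}, the unique direction (up to
#'     scale) perpendicular to both K and I; and \code{"printed"},
#'     \eqn{S = \frac{3}{2} x_{AT} - \frac{3}{4} x_{AE} - \frac{9}{4}
#'     x_{T^2}}, which is not perpendicular to I (dot product \eqn{-3/2}) but
#'     is retained for literal reproduction of published coefficient sets.
#' }
#' The linear map is invertible for either variant, so no information is lost.
#'
#' @name folding_geometry
NULL

#' Coefficient matrix of the (K, S, I) basis
#'
#' Rows are the K, S and I coefficient vectors applied to
#' \eqn{(x_{AT}, x_{AE}, x_{T^2})}.
#'
#' @param s_variant `"orthogonal"` or `"printed"` (see [folding_geometry]).
#' @return A 3x3 numeric matrix with rownames `K`, `S`, `I`.
#' @export
ksi_matrix <- function(s_variant = c("orthogonal", "printed")) {
  s_variant <- match.arg(s_variant)
  s_row <- if (s_variant == "orthogonal") c(3 / 2, 3 / 4, -9 / 4)
           else c(3 / 2, -3 / 4, -9 / 4)
  m <- rbind(K = c(1, -5 / 4, 1 / 4), S = s_row, I = c(1, 1, 1))
  colnames(m) <- c("x_at", "x_ae", "x_t2")
  m
}

#' Log-coordinates of a morphometric record
#'
#' @param avg_thickness_mm,total_area_mm2,exposed_area_mm2 positive numerics
#'   (vectorized): T in mm, A_T and A_E in mm^2.
#' @return data.frame with columns `x_at`, `x_ae`, `x_t2` where
#'   `x_t2 = 2*log10(T)`.
#' @export
to_log_coords <- function(avg_thickness_mm, total_area_mm2, exposed_area_mm2) {
  if (any(!is.finite(avg_thickness_mm)) || any(!is.finite(total_area_mm2)) ||
      any(!is.finite(exposed_area_mm2)) ||
      any(avg_thickness_mm <= 0) || any(total_area_mm2 <= 0) ||
      any(exposed_area_mm2 <= 0))
    stop("T, A_T and A_E must all be finite and strictly positive")
  data.frame(x_at = log10(total_area_mm2),
             x_ae = log10(exposed_area_mm2),
             x_t2 = 2 * log10(avg_thickness_mm))
}

#' Map log-coordinates to the folding variables K, S, I
#'
#' @param coords data.frame with columns `x_at`, `x_ae`, `x_t2`
#'   (from [to_log_coords()]).
#' @inheritParams ksi_matrix
#' @return data.frame with columns `K`, `S`, `I` and attribute `s_variant`.
#' @export
compute_ksi <- function(coords, s_variant = c("orthogonal", "printed")) {
  s_variant <- match.arg(s_variant)
  stopifnot_cols(coords, c("x_at", "x_ae", "x_t2"), "coords")
  if (any(!is.finite(as.matrix(coords[c("x_at", "x_ae", "x_t2")]))))
    stop("log-coordinates must be finite")
  m <- ksi_matrix(s_variant)
  out <- as.data.frame(as.matrix(coords[c("x_at", "x_ae", "x_t2")]) %*% t(m))
  names(out) <- c("K", "S", "I")
  attr(out, "s_variant") <- s_variant
  out
}

#' Invert the K, S, I map back to log-coordinates
#'
#' @param ksi data.frame with columns `K`, `S`, `I`.
#' @inheritParams ksi_matrix
#' @return data.frame with columns `x_at`, `x_ae`, `x_t2`;
#'   `compute_ksi(invert_ksi(f), v)` reproduces `f` to < 1e-10.
#' @export
invert_ksi <- function(ksi, s_variant = c("orthogonal", "printed")) {
  s_variant <- match.arg(s_variant)
  stopifnot_cols(ksi, c("K", "S", "I"), "ksi")
  m_inv <- solve(ksi_matrix(s_variant))
  out <- as.data.frame(as.matrix(ksi[c("K", "S", "I")]) %*% t(m_inv))
  names(out) <- c("x_at", "x_ae", "x_t2")
  out
}

#' Gyrification index
#'
#' GI = A_T / A_E, the ratio of total pial area to exposed hull area.
#'
#' @param total_area_mm2,exposed_area_mm2 areas in mm^2; `exposed_area_mm2`
#'   must be positive.
#' @return numeric vector of gyrification indices.
#' @export
compute_gi <- function(total_area_mm2, exposed_area_mm2) {
  if (any(exposed_area_mm2 <= 0)) stop("exposed area must be positive")
  total_area_mm2 / exposed_area_mm2
}

#' Fit the self-similarity exponent alpha
#'
#' Ordinary least squares of \eqn{y = \log_{10}(A_T \sqrt{T})} on
#' \eqn{x = \log_{10}(A_E)}.  Under the folding scaling law the slope is
#' \eqn{\alpha} (theoretical value 1.25) and the intercept is
#' \eqn{\log_{10} k}.  Each row (one hemisphere or lobe observation) is one
#' point; no weighting.
#'
#' @param records morphometric data.frame with columns `avg_thickness_mm`,
#'   `total_area_mm2`, `exposed_area_mm2` (e.g. from [read_morph_table()]).
#' @param conf_level confidence level for the Student-t slope interval.
#' @return An object of class `scaling_fit`: list with `alpha`, `log10_k`,
#'   `ci95_alpha` (length-2), `se_alpha`, `n`, `r2`.
#' @export
fit_alpha <- function(records, conf_level = 0.95) {
  stopifnot_cols(records, c("avg_thickness_mm", "total_area_mm2",
                            "exposed_area_mm2"), "records")
  lc <- to_log_coords(records$avg_thickness_mm, records$total_area_mm2,
                      records$exposed_area_mm2)
  x <- lc$x_ae
  y <- lc$x_at + 0.25 * lc$x_t2    # log10(A_T sqrt(T)); x_t2 = 2 log10 T
  n <- length(x)
  if (n < 2 || diff(range(x)) == 0)
    stop("degenerate design: need >= 2 records with distinct exposed areas")
  fit <- lm(y ~ x)
  alpha <- unname(coef(fit)[2])
  k0 <- unname(coef(fit)[1])
  if (n >= 3) {
    se <- summary(fit)$coefficients[2, 2]
    tq <- qt(1 - (1 - conf_level) / 2, df = n - 2)
    ci <- alpha + c(-1, 1) * tq * se
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  r2 <- if (var(y) > 0) summary(fit)$r.squared else 1
  structure(list(alpha = alpha, log10_k = k0, ci95_alpha = ci, se_alpha = se,
                 n = n, r2 = r2, conf_level = conf_level),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Self-similarity fit: alpha = %.4f", x$alpha))
  if (!is.na(x$se_alpha))
    cat(sprintf(" [%.4f, %.4f] (95%% CI)", x$ci95_alpha[1], x$ci95_alpha[2]))
  cat(sprintf("\n  log10(k) = %.4f, n = %d, R^2 = %.3f\n",
              x$log10_k, x$n, x$r2))
  invisible(x)
}

#' Augment a morphometric table with K, S, I and GI columns
#'
#' @param records morphometric data.frame (see [read_morph_table()]).
#' @inheritParams ksi_matrix
#' @return `records` with extra columns `K`, `S`, `I`, `GI` and an
#'   `s_variant` attribute.
#' @export
add_folding_coords <- function(records, s_variant = c("orthogonal", "printed")) {
  s_variant <- match.arg(s_variant)
  lc <- to_log_coords(records$avg_thickness_mm, records$total_area_mm2,
                      records$exposed_area_mm2)
  ksi <- compute_ksi(lc, s_variant)
  records$K <- ksi$K
  records$S <- ksi$S
  records$I <- ksi$I
  records$GI <- compute_gi(records$total_area_mm2, records$exposed_area_mm2)
  attr(records, "s_variant") <- s_variant
  records
}
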