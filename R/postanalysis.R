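# Derived quantities: the critical micelle concentration from a
# two-regime linear fit of the free-monomer fraction, small-angle
# scattering intensities from g(r) with Ornstein-Zernike fitting, and
# the surfactant packing parameter with its micelle-shape prediction.

#' Critical micelle concentration by two-regime linear fit
#'
#' Below the CMC essentially all added surfactant stays monomeric;
#' above it, added material enters aggregates, so the free-monomer
#' fraction versus concentration shows two near-linear regimes.  For
#' every order-preserving split with at least two points per side, two
#' least-squares lines are fitted; the split minimizing the pooled
#' squared residual wins, and the CMC is the abscissa of the line
#' intersection.
#'
#' @param concentrations mM, at least 4 values spanning both regimes.
#' @param monomer_fractions matching free-monomer fractions in [0, 1].
#' @return an object of class `cmc_fit`: `cmc` (mM), per-regime
#'   `low`/`high` coefficient pairs (intercept, slope), the winning
#'   `split`, and per-regime residual sums of squares.
#' @examples
#' conc <- c(2, 5, 10, 15, 30, 50, 70)
#' mf <- ifelse(conc <= 15, 0.98 - 0.001 * conc, 1.18 - 0.011 * conc)
#' fit_cmc(conc, mf)$cmc  # 20 (the planted breakpoint)
#' @export
fit_cmc <- function(concentrations, monomer_fractions) {
  n <- length(concentrations)
  if (n < 4) stop("need at least 4 points for a two-regime fit")
  stopifnot(length(monomer_fractions) == n,
            all(monomer_fractions >= 0), all(monomer_fractions <= 1))
  ord <- order(concentrations)
  x <- concentrations[ord]; y <- monomer_fractions[ord]
  best <- NULL
  for (k in 2:(n - 2)) {
    f1 <- lm(y[1:k] ~ x[1:k])
    f2 <- lm(y[(k + 1):n] ~ x[(k + 1):n])
    rss <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(k = k, rss = rss,
                   c1 = unname(coef(f1)), c2 = unname(coef(f2)),
                   rss1 = sum(f1$residuals^2), rss2 = sum(f2$residuals^2))
  }
  dslope <- best$c1[2] - best$c2[2]
  if (abs(dslope) < 1e-12)
    stop("no intersection: the two fitted regimes are parallel")
  cmc <- (best$c2[1] - best$c1[1]) / dslope
  structure(list(cmc = cmc,
                 low = c(intercept = best$c1[1], slope = best$c1[2]),
                 high = c(intercept = best$c2[1], slope = best$c2[2]),
                 split = best$k, rss_low = best$rss1, rss_high = best$rss2,
                 concentrations = x, monomer_fractions = y),
            class = "cmc_fit")
}

#' @export
print.cmc_fit <- function(x, ...) {
  cat("Two-regime CMC fit:", length(x$concentrations), "points, split after",
      x$split, "\n  CMC =", signif(x$cmc, 4), "mM\n")
  invisible(x)
}

#' Scattering intensity from a radial distribution function
#'
#' \deqn{I(Q) \propto 1 + 4\pi\rho \int (g(r)-1)\, r^2
#'   \frac{\sin(Qr)}{Qr}\, dr}
#' evaluated by trapezoidal quadrature on the binned g(r).  If g has
#' not converged to 1 at the largest r (|g-1| > 0.05) a warning note is
#' recorded in the result rather than raised.
#'
#' @param rdf an `rdf_result` or a data frame with columns `r`, `g`.
#' @param number_density particle number density \eqn{\rho}, nm^-3.
#' @param Q scattering-vector grid, nm^-1 (default 0.1-5, 200 points).
#' @return list with `table` (data frame `Q`, `I`) and `warning`
#'   (character or NULL).
#' @export
saxs_from_rdf <- function(rdf, number_density,
                          Q = seq(0.1, 5, length.out = 200)) {
  tab <- if (inherits(rdf, "rdf_result")) rdf$table else rdf
  r <- tab$r; g <- tab$g
  warn <- NULL
  if (abs(g[length(g)] - 1) > 0.05)
    warn <- sprintf("g(r_max = %.2f nm) = %.3f has not converged to 1",
                    r[length(r)], g[length(g)])
  h <- g - 1
  I <- vapply(Q, function(q) {
    f <- h * r^2 * ifelse(q * r == 0, 1, sin(q * r) / (q * r))
    1 + 4 * pi * number_density *
      sum(diff(r) * (head(f, -1) + tail(f, -1)) / 2)
  }, 0)
  list(table = data.frame(Q = Q, I = I), warning = warn)
}

#' Ornstein-Zernike line-shape fit
#'
#' Nonlinear least squares of \eqn{I(Q) = I_0 / (1 + Q^2 \xi^2)}, the
#' scattering signature of exponentially decaying density correlations
#' with correlation length \eqn{\xi}.  Initial guesses are
#' \eqn{I_0 = \max I} and \eqn{\xi} from the half-maximum Q.
#'
#' @param Q scattering vectors, nm^-1 (at least 3).
#' @param I positive intensities.
#' @return an object of class `oz_fit` with `I0`, `xi` (nm) and the
#'   residual sum of squares.
#' @export
fit_oz <- function(Q, I) {
  stopifnot(length(Q) >= 3, length(I) == length(Q))
  if (any(I <= 0)) stop("intensities must be positive")
  I0_0 <- max(I)
  below <- which(I <= I0_0 / 2)
  xi_0 <- if (length(below)) 1 / Q[below[1]] else 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 / (1 + Q^2 * xi^2),
                      start = list(I0 = I0_0, xi = xi_0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    stop("Ornstein-Zernike fit did not converge (start I0 = ",
         signif(I0_0, 4), ", xi = ", signif(xi_0, 4), ")")
  p <- coef(fit)
  structure(list(I0 = unname(p["I0"]), xi = unname(p["xi"]),
                 rss = sum(residuals(fit)^2)),
            class = "oz_fit")
}

#' @export
print.oz_fit <- function(x, ...) {
  cat("Ornstein-Zernike fit: I0 =", signif(x$I0, 4), ", xi =",
      signif(x$xi, 4), "nm (rss", signif(x$rss, 3), ")\n")
  invisible(x)
}

#' Surfactant packing parameter
#'
#' \eqn{N_s = V_t / (A_c\, l_t)} with tail volume \eqn{V_t} (nm^3),
#' head-tail contact area \eqn{A_c} (nm^2) and tail length \eqn{l_t}
#' (nm).  Shape classes follow standard surfactant packing theory:
#' spheres below 1/3, cylinders up to 1/2, bilayers up to 1, inverted
#' aggregates above 1.
#'
#' @param V_t tail volume, nm^3.
#' @param A_c head-tail contact area, nm^2.
#' @param l_t tail length, nm.
#' @return an object of class `packing_result` with `N_s` and `shape`.
#' @examples
#' packing_parameter(0.603, 1.55, 1.0)  # N_s = 0.389, cylinder
#' @export
packing_parameter <- function(V_t, A_c, l_t) {
  if (any(c(V_t, A_c, l_t) <= 0)) stop("all inputs must be positive")
  N_s <- V_t / (A_c * l_t)
  shape <- if (N_s < 1 / 3) "sphere" else if (N_s < 1 / 2) "cylinder"
  else if (N_s <= 1) "bilayer" else "inverted"
  structure(list(V_t = V_t, A_c = A_c, l_t = l_t, N_s = N_s,
                 shape = shape),
            class = "packing_result")
}

#' @export
print.packing_result <- function(x, ...) {
  cat("Packing parameter N_s =", signif(x$N_s, 4), "->", x$shape, "\n")
  invisible(x)
}
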