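#' Estimate the critical micelle concentration by two-line intersection
#'
#' Fits ordinary least-squares lines to the unimeric (low-concentration) and
#' micellar (high-concentration) segments of a dye-solubilisation curve for
#' every contiguous split with at least `min_points` per side, picks the
#' split minimising the total sum of squared errors, and reports the CMC as
#' the abscissa of the two fitted lines' intersection (the extrapolated
#' crossing, not the split position).
#'
#' @param curve a [solubilisation_curve()] or data.frame with columns
#'   `concentration`, `delta_absorbance` (>= 6 points).
#' @param min_points minimum points per segment (default 3).
#' @param transform `"linear"` fits in concentration coordinates (the default,
#'   matching a plot of absorbance difference against wt%); `"log10"` fits in
#'   log10 concentration, back-transforming the intersection.
#' @return an object of class `cmc_fit` with elements `cmc`, `left_line` /
#'   `right_line` (intercept, slope), `split_index`, `sse_total`,
#'   `diagnostics` (per-candidate SSE table) and the data.
#' @export
estimate_cmc <- function(curve, min_points = 3, transform = c("linear", "log10")) {
  transform <- match.arg(transform)
  if (!all(c("concentration", "delta_absorbance") %in% names(curve)))
    stop_input("`curve` needs columns concentration and delta_absorbance")
  o <- order(curve$concentration)
  conc <- curve$concentration[o]
  y <- curve$delta_absorbance[o]
  n <- length(conc)
  if (n < 2 * min_points)
    stop_input("insufficient data: need at least ", 2 * min_points, " points")
  x <- if (transform == "log10") log10(conc) else conc
  fit_line <- function(idx) {
    f <- lm(y[idx] ~ x[idx])
    c(coef(f)[[1]], coef(f)[[2]], sum(resid(f)^2))
  }
  splits <- min_points:(n - min_points)
  diag <- data.frame(split_index = splits, sse = NA_real_, intersection = NA_real_)
  fits <- vector("list", length(splits))
  for (s in seq_along(splits)) {
    k <- splits[s]
    L <- fit_line(1:k); R <- fit_line((k + 1):n)
    diag$sse[s] <- L[3] + R[3]
    xi <- if (abs(L[2] - R[2]) > 0) (R[1] - L[1]) / (L[2] - R[2]) else NA_real_
    diag$intersection[s] <- if (transform == "log10" && !is.na(xi)) 10^xi else xi
    fits[[s]] <- list(L = L, R = R, xi = xi)
  }
  best <- which.min(diag$sse)
  L <- fits[[best]]$L; R <- fits[[best]]$R
  slope_gap <- abs(L[2] - R[2])
  if (slope_gap <= 1e-9 * max(abs(L[2]), abs(R[2]), 1))
    stop_input("no intersection: fitted segment lines are parallel ",
               "(data may lack a breakpoint)")
  xi <- fits[[best]]$xi
  cmc <- if (transform == "log10") 10^xi else xi
  if (!is.finite(cmc) || cmc < min(conc) || cmc > max(conc))
    stop_input("no intersection inside the data range ",
               "(estimated crossing at ", signif(cmc, 4), " wt%)")
  structure(list(cmc = cmc,
                 left_line = c(intercept = L[1], slope = L[2]),
                 right_line = c(intercept = R[1], slope = R[2]),
                 split_index = splits[best],
                 sse_total = diag$sse[best],
                 diagnostics = diag, transform = transform,
                 concentration = conc, delta_absorbance = y),
            class = "cmc_fit")
}

#' @export
print.cmc_fit <- function(x, ...) {
  cat(sprintf("Two-line CMC estimate: %.4g wt%%\n", x$cmc))
  cat(sprintf("  split after point %d of %d (total SSE %.4g, %s x)\n",
              x$split_index, length(x$concentration), x$sse_total, x$transform))
  cat(sprintf("  unimeric line: %.4g + %.4g c; micellar line: %.4g + %.4g c\n",
              x$left_line[1], x$left_line[2], x$right_line[1], x$right_line[2]))
  invisible(x)
}

#' @export
coef.cmc_fit <- function(object, ...) {
  c(cmc = object$cmc,
    unimeric_intercept = unname(object$left_line[1]),
    unimeric_slope = unname(object$left_line[2]),
    micellar_intercept = unname(object$right_line[1]),
    micellar_slope = unname(object$right_line[2]))
}

#' @export
predict.cmc_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$concentration
          else if (is.data.frame(newdata)) newdata$concentration else newdata
  x <- if (object$transform == "log10") log10(conc) else conc
  xb <- if (object$transform == "log10") log10(object$cmc) else object$cmc
  ifelse(x <= xb,
         object$left_line[1] + object$left_line[2] * x,
         object$right_line[1] + object$right_line[2] * x)
}

#' @export
plot.cmc_fit <- function(x, ...) {
  graphics::plot(x$concentration, x$delta_absorbance, log = "x",
                 xlab = "concentration (wt%)",
                 ylab = expression(Delta * "absorbance"), ...)
  ord <- order(x$concentration)
  graphics::lines(x$concentration[ord], predict(x)[ord], col = "steelblue")
  graphics::abline(v = x$cmc, lty = 2, col = "firebrick")
  graphics::mtext(sprintf("CMC = %.4g wt%%", x$cmc), side = 3, line = 0.2)
  invisible(x)
}

#' Fit a quadratic standard curve
#'
#' Least-squares quadratic `dA = a x^2 + b x + c` of absorbance difference on
#' concentration, with `R^2 = 1 - SSE/SST`. Constant responses (SST = 0) are
#' assigned `R^2 = 0` and flagged degenerate.
#'
#' @param curve a [solubilisation_curve()] or data.frame with columns
#'   `concentration`, `delta_absorbance` (>= 4 points, >= 3 distinct
#'   concentrations).
#' @return an object of class `standard_curve` with `coefficients`
#'   (a, b, c), `r_squared`, `calibration_range`, `degenerate` flag and the
#'   data.
#' @export
fit_standard_curve <- function(curve) {
  if (!all(c("concentration", "delta_absorbance") %in% names(curve)))
    stop_input("`curve` needs columns concentration and delta_absorbance")
  x <- curve$concentration; y <- curve$delta_absorbance
  if (length(x) < 4) stop_input("need at least 4 points for a quadratic fit")
  if (length(unique(x)) < 3)
    stop_input("rank-deficient design: need at least 3 distinct concentrations")
  f <- lm(y ~ x + I(x^2))
  a <- coef(f)[["I(x^2)"]]; b <- coef(f)[["x"]]; cc <- coef(f)[["(Intercept)"]]
  sst <- sum((y - mean(y))^2)
  sse <- sum(resid(f)^2)
  degenerate <- sst == 0
  structure(list(coefficients = c(a = a, b = b, c = cc),
                 r_squared = if (degenerate) 0 else 1 - sse / sst,
                 calibration_range = range(x), degenerate = degenerate,
                 concentration = x, delta_absorbance = y),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("Quadratic standard curve: dA = %.4g x^2 + %.4g x + %.4g\n",
              co["a"], co["b"], co["c"]))
  cat(sprintf("  R^2 = %.4f over [%.4g, %.4g] wt%%%s\n", x$r_squared,
              x$calibration_range[1], x$calibration_range[2],
              if (x$degenerate) "  (degenerate: constant response)" else ""))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) object$coefficients

#' @export
predict.standard_curve <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$concentration
       else if (is.data.frame(newdata)) newdata$concentration else newdata
  co <- object$coefficients
  co["a"] * x^2 + co["b"] * x + co["c"]
}

#' @export
plot.standard_curve <- function(x, ...) {
  graphics::plot(x$concentration, x$delta_absorbance,
                 xlab = "concentration (wt%)",
                 ylab = expression(Delta * "absorbance"), ...)
  xs <- seq(x$calibration_range[1], x$calibration_range[2], length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "steelblue")
  graphics::mtext(sprintf("R² = %.4f", x$r_squared), side = 3, line = 0.2)
  invisible(x)
}

#' Invert a quadratic standard curve
#'
#' Solves `a x^2 + b x + c = dA` for concentration, returning for each
#' absorbance difference the real root on the monotone branch of the parabola
#' that covers the calibration range. Admissible solutions must lie in
#' `[0, 1.1 * max(calibration range)]`; anything else is an out-of-range
#' error.
#'
#' @param sc a fitted [fit_standard_curve()] object.
#' @param delta_absorbance absorbance-difference value(s) to invert.
#' @return concentrations in wt%, same length as `delta_absorbance`.
#' @export
invert_standard_curve <- function(sc, delta_absorbance) {
  stopifnot(inherits(sc, "standard_curve"))
  co <- sc$coefficients
  a <- co[["a"]]; b <- co[["b"]]; cc <- co[["c"]]
  lo <- 0; hi <- 1.1 * sc$calibration_range[2]
  vertex <- if (abs(a) > 0) -b / (2 * a) else NA_real_
  vapply(delta_absorbance, function(dA) {
    if (abs(a) < 1e-12) {
      if (abs(b) < 1e-12) stop_input("degenerate curve: cannot invert")
      root <- (dA - cc) / b
      if (root < lo || root > hi)
        stop_input("out of range: inverted concentration ", signif(root, 4),
                   " wt% outside [0, ", signif(hi, 4), "]")
      return(root)
    }
    disc <- b^2 - 4 * a * (cc - dA)
    if (disc < 0)
      stop_input("out of range: no real root for dA = ", signif(dA, 4))
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    # monotone branch covering the calibration range: the side of the vertex
    # the calibration interval sits on (the fitted range is assumed monotone)
    mid <- mean(sc$calibration_range)
    branch <- roots[sign(roots - vertex) == sign(mid - vertex) | roots == vertex]
    ok <- branch[branch >= lo & branch <= hi]
    if (length(ok) == 0)
      stop_input("out of range: no admissible root for dA = ", signif(dA, 4))
    # prefer the root inside (or nearest to) the calibration interval
    ok[which.min(pmax(0, sc$calibration_range[1] - ok,
                      ok - sc$calibration_range[2]))]
  }, numeric(1))
}

#' LDH cytotoxicity release percentages
#'
#' Background-corrects each well (`signal = A490 - A690`: absorbance at
#' 490 nm for released LDH minus 690 nm background) and normalises samples
#' between the medium-blank and full-lysis control means:
#' `release = 100 * (s - mean(s_blank)) / (mean(s_lysis) - mean(s_blank))`.
#'
#' @param records data.frame with columns `a490`, `a690`, `role` (one of
#'   `"sample"`, `"medium_blank"`, `"lysis_control"`) and optionally `well`.
#' @return an `ldh_release` data.frame of the sample wells with `signal` and
#'   `release_pct`; blank and lysis means are attached as attributes.
#' @export
ldh_release <- function(records) {
  need <- c("a490", "a690", "role")
  if (!all(need %in% names(records)))
    stop_input("`records` needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(records$role), c("sample", "medium_blank", "lysis_control"))
  if (length(bad)) stop_input("unknown roles: ", paste(bad, collapse = ", "))
  s <- records$a490 - records$a690
  s_blank <- s[records$role == "medium_blank"]
  s_lysis <- s[records$role == "lysis_control"]
  if (length(s_blank) < 1 || length(s_lysis) < 1)
    stop_input("need at least one medium_blank and one lysis_control well")
  mb <- mean(s_blank); ml <- mean(s_lysis)
  if (ml <= mb)
    stop_input("invalid controls: lysis mean (", signif(ml, 4),
               ") must exceed blank mean (", signif(mb, 4), ")")
  keep <- records$role == "sample"
  out <- data.frame(
    well = if ("well" %in% names(records)) records$well[keep]
           else paste0("sample", seq_len(sum(keep))),
    signal = s[keep],
    release_pct = 100 * (s[keep] - mb) / (ml - mb))
  attr(out, "blank_mean") <- mb
  attr(out, "lysis_mean") <- ml
  class(out) <- c("ldh_release", "data.frame")
  out
}
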