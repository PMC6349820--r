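#' Logicle transform parameters
#'
#' The logicle is the standard biexponential analysis scale for cytometry
#' data (Parks, Roeder & Moore parameterization): approximately linear
#' around zero and logarithmic at high intensity. `t` is the top of scale
#' (raw units), `m` the total display width in decades, `w` the
#' linearization width in decades, and `a` additional negative-display
#' decades (default 0). On the transformed scale the raw value `t` maps to
#' `m` and, with `a = 0`, raw 0 maps to `w`.
#'
#' @param w linearization width, decades; `0 <= w <= m/2`.
#' @param t top of scale, raw units; `> 0`.
#' @param m total display decades; `> 0`.
#' @param a extra negative decades; default 0.
#' @return object of class `logicle_params` holding the parameters and the
#'   precomputed biexponential coefficients.
#' @examples
#' p <- logicle_params(w = 0.6, t = 10000, m = 4.5)
#' logicle(c(0, 100, 10000), p)
#' @export
logicle_params <- function(w = 0.6, t = 10000, m = 4.5, a = 0) {
  if (!(t > 0)) stopf("logicle: t must be > 0")
  if (!(m > 0)) stopf("logicle: m must be > 0")
  if (w < 0 || w > m / 2) stopf("logicle: need 0 <= w <= m/2")
  if (a < 0) stopf("logicle: a must be >= 0")

  # normalized coordinates: the transformed scale y in [0, 1] corresponds
  # to display value y * (m + a) - a
  wn <- w / (m + a)
  x2 <- a / (m + a)
  x1 <- x2 + wn
  x0 <- x2 + 2 * wn
  b <- (m + a) * log(10)
  d <- if (wn == 0) b else {
    # root of 2*log(d/b) + wn*(d + b) = 0 on (0, b)
    f <- function(d) 2 * (log(d) - log(b)) + wn * (d + b)
    stats::uniroot(f, lower = b * 1e-12, upper = b, tol = 1e-14)$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a / exp(d * x1)
  aa <- t / ((exp(b) - mf_a) - c_a / exp(d))
  structure(list(w = w, t = t, m = m, a = a,
                 b = b, d = d, coef_a = aa, coef_c = c_a * aa,
                 coef_f = -mf_a * aa, x1 = x1),
            class = "logicle_params")
}

#' @export
print.logicle_params <- function(x, ...) {
  cat(sprintf("logicle(w = %g, t = %g, m = %g, a = %g)\n", x$w, x$t, x$m, x$a))
  invisible(x)
}

# biexponential: normalized scale y -> raw data value
biexp <- function(y, p) p$coef_a * exp(p$b * y) - p$coef_c * exp(-p$d * y) + p$coef_f

#' Logicle transform
#'
#' Maps raw intensities to the logicle display scale (decades). Strictly
#' increasing; the inverse is [logicle_inverse()]. The forward map inverts
#' the closed-form biexponential numerically (vectorized
#' bisection + Newton polish, accurate to ~1e-12 relative).
#'
#' @param x numeric vector or matrix of raw values (finite; negatives
#'   allowed).
#' @param params a [logicle_params()] object.
#' @return transformed values, same shape as `x`; `x = t` maps to `m`.
#' @export
logicle <- function(x, params = logicle_params()) {
  stopifnot(inherits(params, "logicle_params"))
  if (any(!is.finite(x)))
    stopf("logicle: non-finite input at positions %s",
          paste(utils::head(which(!is.finite(x)), 10), collapse = ", "))
  dm <- dim(x)
  v <- as.numeric(x)
  # bracket on the normalized scale; biexp spans far beyond any real data
  lo <- rep(-10, length(v)); hi <- rep(10, length(v))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    up <- biexp(mid, params) < v
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  y <- (lo + hi) / 2
  for (it in 1:3) {  # Newton polish
    fy <- biexp(y, params) - v
    dy <- params$coef_a * params$b * exp(params$b * y) +
          params$coef_c * params$d * exp(-params$d * y)
    y <- y - fy / dy
  }
  out <- y * (params$m + params$a) - params$a
  dim(out) <- dm
  dimnames(out) <- dimnames(x)
  out
}

#' Inverse logicle transform
#' @param y values on the logicle display scale (decades)
#' @param params a [logicle_params()] object
#' @return raw-scale values, same shape as `y`
#' @export
logicle_inverse <- function(y, params = logicle_params()) {
  stopifnot(inherits(params, "logicle_params"))
  yn <- (y + params$a) / (params$m + params$a)
  out <- biexp(yn, params)
  dim(out) <- dim(y)
  dimnames(out) <- dimnames(y)
  out
}

#' Floor-clip a matrix at a small positive value
#'
#' The edge-activity rule divides by the target's expression on inhibitory
#' edges, and logicle output can be <= 0 near zero, so values are floored
#' at a small `eps` before embedding. The number of clipped entries is
#' reported via a message and the `"n_clipped"` attribute.
#'
#' @param x numeric matrix
#' @param eps positive floor, default 1e-6
#' @return clipped matrix with attribute `n_clipped`
#' @export
clip_floor <- function(x, eps = 1e-6) {
  if (!(eps > 0)) stopf("clip_floor: eps must be > 0")
  n_clipped <- sum(x < eps)
  out <- pmax(x, eps)
  if (n_clipped > 0)
    message(sprintf("clip_floor: %d of %d entries (%.3g%%) raised to %g",
                    n_clipped, length(x), 100 * n_clipped / length(x), eps))
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Center and scale columns (z-scaling)
#'
#' Without `params`, each column is centered to mean 0 and scaled to unit
#' standard deviation (n - 1 denominator) and the fitted parameters are
#' returned for later application to test data. With `params` (from a
#' training fit), those are applied unchanged — test data is never refit.
#'
#' @param x numeric matrix with column names
#' @param params optional list with `center` and `scale` named by column
#' @param drop_constant drop zero-variance columns with a warning instead
#'   of erroring
#' @return list with `values` (scaled matrix), `center`, `scale`
#' @export
zscale <- function(x, params = NULL, drop_constant = FALSE) {
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(params)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    zero <- scale == 0 | !is.finite(scale)
    if (any(zero)) {
      if (!drop_constant)
        stopf("zero-variance column(s): %s (use drop_constant = TRUE to drop)",
              paste(colnames(x)[zero], collapse = ", "))
      warnf("dropping %d zero-variance column(s): %s", sum(zero),
            paste(colnames(x)[zero], collapse = ", "))
      x <- x[, !zero, drop = FALSE]
      center <- center[!zero]; scale <- scale[!zero]
    }
  } else {
    if (!setequal(colnames(x), names(params$center)))
      stopf("zscale: column names do not match training parameters")
    x <- x[, names(params$center), drop = FALSE]
    center <- params$center; scale <- params$scale
  }
  values <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(values = values, center = center, scale = scale)
}

#' Simple cell-cycle gating from Ki67 and phospho-Histone H3
#'
#' Assigns `G0` when Ki67 is below its threshold (absence of Ki67 marks
#' quiescence), `M` when pH3 is at or above its threshold (pH3 positivity
#' marks mitosis), and `other` otherwise. `M` takes precedence when both
#' rules fire, pH3 being the more specific marker. G1/S/G2 are not
#' assigned. Thresholds are on the transformed scale; the default is half
#' the feature median, a deliberately crude heuristic — gate visually for
#' real data.
#'
#' @param x expression matrix (cells x features, transformed scale)
#' @param ki67 name of the Ki67 feature column
#' @param ph3 name of the pH3 feature column
#' @param thresholds optional named list/vector with elements `ki67`, `ph3`
#' @return factor of length `nrow(x)` with levels `G0`, `M`, `other`
#' @export
cell_cycle_gate <- function(x, ki67 = "Ki67", ph3 = "pH3", thresholds = NULL) {
  x <- as_expression_matrix(x)
  for (f in c(ki67, ph3))
    if (!f %in% colnames(x)) stopf("feature '%s' not found", f)
  if (is.null(thresholds))
    thresholds <- list(ki67 = 0.5 * stats::median(x[, ki67]),
                       ph3  = 0.5 * stats::median(x[, ph3]))
  lab <- rep("other", nrow(x))
  lab[x[, ki67] < thresholds$ki67] <- "G0"
  lab[x[, ph3] >= thresholds$ph3] <- "M"   # precedence over G0
  factor(lab, levels = c("G0", "M", "other"))
}

#' Read an expression matrix from delimited text
#'
#' First column is the cell id, remaining columns are features. An optional
#' metadata sidecar (TSV keyed by cell id) is joined by id.
#'
#' @param path expression CSV/TSV
#' @param sep field separator (default tab)
#' @param metadata optional path to a metadata TSV whose first column is
#'   the cell id
#' @return list with `values` (matrix, rownames = cell ids) and `metadata`
#'   (data.frame or NULL)
#' @export
read_expression <- function(path, sep = "\t", metadata = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  md <- NULL
  if (!is.null(metadata)) {
    md <- utils::read.table(metadata, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    md <- md[match(ids, as.character(md[[1]])), , drop = FALSE]
    rownames(md) <- ids
  }
  list(values = values, metadata = md)
}

#' Write an expression matrix as TSV
#' @param values matrix with cell ids as rownames
#' @param path output path
#' @param id_col name for the id column
#' @export
write_expression <- function(values, path, id_col = "cell_id") {
  df <- data.frame(rownames(values), values, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
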