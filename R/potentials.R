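#' Stepwise pair potentials
#'
#' A `potential_spec` describes an isotropic stepwise pair potential: an
#' impenetrable core of diameter `sigma` followed by zero or more constant
#' shells.  Shell `i` spans `sigma * lambda[i-1] <= r < sigma * lambda[i]`
#' (with `lambda[0] = 1`) and has potential value `depth[i]` in units of kT;
#' the potential is `+Inf` below `sigma` and `0` beyond the last boundary.
#' A hard sphere is the zero-shell case; a square well of range `lambda` and
#' attractive strength `epsilon` has one shell of value `-epsilon`.
#'
#' All quantities are in reduced units: `sigma = 1`, particle mass `m = 1`,
#' `kT = 1`, so the time unit is `sigma * sqrt(m/kT)`.
#'
#' @param kind one of `"hs"`, `"sw"`, `"double_sw"`.
#' @param params named list of parameters.  For `"sw"`: `lambda` (> 1) and
#'   `epsilon` (well depth, positive means attractive, stored as value
#'   `-epsilon`).  For `"double_sw"`: `boundaries` (strictly increasing, > 1)
#'   and `depths` (potential values, same length).  For `"hs"`: none.
#' @param sigma core diameter (default 1, reduced units).
#' @return an object of class `potential_spec` with fields `sigma`,
#'   `boundaries` (vector of lambda_i), `depths` (potential values u_i) and
#'   `kind`.
#' @examples
#' hs <- make_spec("hs")
#' sw <- make_spec("sw", list(lambda = 1.25, epsilon = 1))
#' evaluate_potential(sw, 1.1)   # -1 inside the well
#' @export
make_spec <- function(kind = c("hs", "sw", "double_sw"), params = list(),
                      sigma = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a positive scalar")
  if (kind == "hs") {
    boundaries <- numeric(0)
    depths <- numeric(0)
  } else if (kind == "sw") {
    lambda <- params$lambda
    eps <- params$epsilon
    if (is.null(lambda) || is.null(eps))
      stop("square well requires 'lambda' and 'epsilon'")
    boundaries <- as.numeric(lambda)
    depths <- -as.numeric(eps)
    if (length(boundaries) != 1L || length(depths) != 1L)
      stop("'lambda' and 'epsilon' must be scalars")
  } else {
    boundaries <- as.numeric(params$boundaries)
    depths <- as.numeric(params$depths)
    if (length(boundaries) == 0L || is.null(params$depths))
      stop("double square well requires 'boundaries' and 'depths'")
    if (length(boundaries) != length(depths))
      stop("'boundaries' and 'depths' must have equal length")
  }
  if (anyNA(boundaries) || anyNA(depths))
    stop("non-finite potential parameters")
  if (any(boundaries <= 1))
    stop("all shell boundaries must exceed 1 (in units of sigma)")
  if (length(boundaries) > 1L && any(diff(boundaries) <= 0))
    stop("shell boundaries must be strictly increasing")
  structure(
    list(kind = kind, sigma = sigma, boundaries = boundaries,
         depths = depths, kT = 1),
    class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("Stepwise pair potential ('%s'), sigma = %g, kT = 1\n",
              x$kind, x$sigma))
  if (length(x$boundaries) == 0L) {
    cat("  hard sphere: u = +Inf (r < sigma), 0 otherwise\n")
  } else {
    lo <- c(1, x$boundaries[-length(x$boundaries)])
    for (i in seq_along(x$boundaries))
      cat(sprintf("  shell %d: u = %g kT for %g <= r/sigma < %g\n",
                  i, x$depths[i], lo[i], x$boundaries[i]))
  }
  invisible(x)
}

#' Evaluate a stepwise pair potential
#'
#' Returns `+Inf` for `r < sigma`, the shell value for
#' `sigma <= r < lambda_last * sigma`, and 0 beyond.  Values exactly at a
#' boundary take the inner-shell value (left-closed intervals), the same
#' convention used by the event mechanics.
#'
#' @param spec a [make_spec()] object.
#' @param r separation(s), must be positive.
#' @return potential value(s) in kT units.
#' @export
evaluate_potential <- function(spec, r) {
  stopifnot(inherits(spec, "potential_spec"))
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("'r' must be positive and finite")
  edges <- spec$sigma * c(1, spec$boundaries)
  vals <- c(spec$depths, 0)
  out <- numeric(length(r))
  out[r < spec$sigma] <- Inf
  ok <- r >= spec$sigma
  if (any(ok)) {
    # r exactly at lambda_i*sigma takes the inner-shell value, and r = sigma
    # lies in the first shell
    idx <- findInterval(r[ok], edges, left.open = TRUE)
    idx[r[ok] == spec$sigma] <- 1L
    out[ok] <- vals[pmin(idx, length(vals))]
  }
  out
}

#' Serialize / deserialize a potential spec
#'
#' The text form is a small key-value block (`kind`, `sigma`, one
#' `shell: boundary depth` line per shell) suitable for config files.
#'
#' @param spec a [make_spec()] object.
#' @return `format_spec`: a character vector of lines. `parse_spec`: a
#'   `potential_spec`.
#' @export
format_spec <- function(spec) {
  stopifnot(inherits(spec, "potential_spec"))
  lines <- c(paste0("kind: ", spec$kind),
             paste0("sigma: ", format(spec$sigma, digits = 17)))
  for (i in seq_along(spec$boundaries))
    lines <- c(lines, sprintf("shell: %s %s",
                              format(spec$boundaries[i], digits = 17),
                              format(spec$depths[i], digits = 17)))
  lines
}

#' @rdname format_spec
#' @param lines character vector as produced by `format_spec`.
#' @export
parse_spec <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), "")
  kind <- vals[keys == "kind"]
  sigma <- as.numeric(vals[keys == "sigma"])
  if (length(kind) != 1L || length(sigma) != 1L)
    stop("malformed potential block: need exactly one 'kind' and 'sigma'")
  sh <- vals[keys == "shell"]
  if (length(sh) == 0L) {
    make_spec("hs", sigma = sigma)
  } else {
    parts <- do.call(rbind, lapply(strsplit(sh, "\\s+"), as.numeric))
    if (kind == "sw" && nrow(parts) == 1L) {
      make_spec("sw", list(lambda = parts[1, 1], epsilon = -parts[1, 2]),
                sigma = sigma)
    } else {
      make_spec("double_sw",
                list(boundaries = parts[, 1], depths = parts[, 2]),
                sigma = sigma)
    }
  }
}

# interaction range in absolute length units (sigma for HS)
potential_range <- function(spec) {
  if (length(spec$boundaries) == 0L) spec$sigma
  else spec$sigma * spec$boundaries[length(spec$boundaries)]
}
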