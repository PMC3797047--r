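#' Save / load a compact representation
#'
#' The compact model — singular values, basis vectors, polynomial surrogate
#' coefficients and the parameter domain — persists as one structured JSON
#' document at full double precision, so save/load/evaluate round-trips are
#' bit-identical.  The format version is checked on load.
#'
#' @param compact a [compact_representation()].
#' @param path file path.
#' @return `save_compact_model`: the path, invisibly.
#' @export
save_compact_model <- function(compact, path) {
  stopifnot(inherits(compact, "compact_representation"))
  surr <- compact$surrogate
  doc <- list(
    format = "rdfsvd-compact-1",
    grid = list(r_max = compact$grid$r_max, m = compact$grid$m),
    p = compact$p, delta = compact$delta,
    param_names = as.list(compact$param_names),
    domain = lapply(compact$domain, as.numeric),
    singular_values = as.numeric(compact$singular_values),
    basis = apply(compact$basis, 2, as.numeric, simplify = FALSE),
    surrogate = list(
      n_params = surr$n_params,
      fits = lapply(surr$fits, function(f) {
        out <- list(degree = f$degree, coef = as.numeric(f$coef),
                    rms = f$rms)
        if (!is.null(f$exponents))
          out$exponents <- list(i = f$exponents$i, j = f$exponents$j)
        out
      })))
  # I(17) = 17 significant digits: doubles survive the text round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_compact_model
#' @return `load_compact_model`: the `compact_representation`.
#' @export
load_compact_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("load error: cannot parse '", path, "': ",
                         conditionMessage(e)))
  if (!identical(doc$format, "rdfsvd-compact-1"))
    stop("load error: unsupported format version '",
         if (is.null(doc$format)) "<missing>" else doc$format, "'")
  need <- c("grid", "p", "singular_values", "basis", "surrogate", "domain",
            "param_names")
  if (!all(need %in% names(doc)))
    stop("load error: truncated or malformed model file")
  grid <- radial_grid(r_max = doc$grid$r_max, m = doc$grid$m)
  basis <- if (is.list(doc$basis)) do.call(cbind, doc$basis)
           else t(doc$basis)  # read_json stacks the column arrays as rows
  pn <- unlist(doc$param_names)
  domain <- stats::setNames(lapply(seq_along(pn), function(j)
    as.numeric(if (is.list(doc$domain)) doc$domain[[j]] else doc$domain[, j])),
    pn)
  fits <- doc$surrogate$fits
  if (is.data.frame(fits))
    fits <- lapply(seq_len(nrow(fits)), function(i) as.list(fits[i, ]))
  fits <- lapply(fits, function(f) {
    out <- list(degree = as.integer(f$degree),
                coef = as.numeric(unlist(f$coef)), rms = as.numeric(f$rms))
    if (!is.null(f$exponents))
      out$exponents <- data.frame(i = unlist(f$exponents$i),
                                  j = unlist(f$exponents$j))
    out
  })
  surr <- structure(list(fits = fits, domain = domain,
                         n_params = as.integer(doc$surrogate$n_params),
                         param_names = unlist(doc$param_names),
                         p = as.integer(doc$p)),
                    class = "poly_surrogate")
  structure(list(grid = grid, p = as.integer(doc$p), delta = doc$delta,
                 singular_values = as.numeric(doc$singular_values),
                 basis = basis, surrogate = surr, domain = domain,
                 param_names = unlist(doc$param_names),
                 version = doc$format),
            class = "compact_representation")
}

#' Write an RDF sample as tab-separated text
#'
#' @param sample an `rdf_sample`.
#' @param path file path.
#' @export
write_rdf_sample <- function(sample, path) {
  stopifnot(inherits(sample, "rdf_sample"))
  hdr <- c("# rdfsvd rdf_sample v1",
           sprintf("# r_max: %.17g", sample$grid$r_max),
           sprintf("# m: %d", sample$grid$m),
           sprintf("# theta: %s",
                   paste(names(sample$theta), sample$theta, sep = "=",
                         collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("r\tg", con)
  writeLines(sprintf("%.17g\t%.17g", sample$grid$centers, sample$values), con)
  invisible(path)
}
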