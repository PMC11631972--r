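#' Neutrosophic sample
#'
#' A `neutro_sample` is an ordered collection of interval-valued observations
#' \eqn{[x_L, x_N]} together with the indeterminacy interval that generated
#' (or is assumed for) them.  It is stored as a data.frame with columns
#' `lower` and `upper` plus attributes `indet` ([indet_interval()]), `label`,
#' and optional `flags`/`corrections` metadata.
#'
#' @param lower positive numeric vector of lower endpoints.
#' @param upper numeric vector of upper endpoints, `>= lower` elementwise.
#' @param indet the [indet_interval()] attached to the sample.
#' @param label free-text label.
#' @param flags character vector of data-quality flags (e.g. `"incomplete"`).
#' @return an object of class `neutro_sample`.
#' @export
neutro_sample <- function(lower, upper, indet = indet_interval(0, 0),
                          label = "", flags = character()) {
  check_x_positive(lower, "lower")
  if (!is.numeric(upper) || length(upper) != length(lower) ||
      any(!is.finite(upper)))
    stop("'upper' must be numeric and match 'lower' in length", call. = FALSE)
  if (any(upper < lower))
    stop("validation error: upper < lower for some observations",
         call. = FALSE)
  structure(data.frame(lower = as.numeric(lower), upper = as.numeric(upper)),
            indet = as_indet(indet), label = label, flags = flags,
            class = c("neutro_sample", "data.frame"))
}

#' @export
print.neutro_sample <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Neutrosophic sample%s: n = %d\n",
              if (nzchar(lab)) paste0(" '", lab, "'") else "", nrow(x)))
  print(attr(x, "indet"))
  flags <- attr(x, "flags")
  if (length(flags))
    cat("flags:", paste(flags, collapse = ", "), "\n")
  corr <- attr(x, "corrections")
  if (!is.null(corr)) cat("corrections:", corr, "\n")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Convert crisp observations to a neutrosophic sample
#'
#' Applies the neutrosophication rule \eqn{x \mapsto [x(1+I_L), x(1+I_N)]}.
#' With \eqn{I_L = 0} (the usual convention) the lower endpoint equals the
#' crisp value.
#'
#' @param crisp positive numeric vector of crisp observations.
#' @param indet an [indet_interval()] (or scalar / length-2 numeric).
#' @param label label for the resulting sample.
#' @return a [neutro_sample()].
#' @examples
#' neutrosophy(c(14.918, 10.656), indet_interval(0, 0.05))
#' @export
neutrosophy <- function(crisp, indet = indet_interval(0, 0.05), label = "") {
  check_x_positive(crisp, "crisp")
  I <- as_indet(indet)
  neutro_sample(crisp * (1 + I[["lower"]]), crisp * (1 + I[["upper"]]),
                indet = I, label = label)
}

#' Bundled datasets
#'
#' Loads one of the two interval-valued datasets shipped with the package,
#' both neutrosophied with \eqn{I = [0, 0.05]} and stored with the upper
#' endpoints exactly as published (5 decimal places):
#'
#' * `"covid_nl"`: 30 daily COVID-19 rough mortality rates for the
#'   Netherlands, 31 March - 30 April 2020.  One published lower value
#'   (observation 2) is corrected from the misprinted 10.056 to 10.656 — the
#'   published upper endpoint 11.18880 = 10.656 x 1.05 identifies the typo;
#'   the correction is recorded in the `corrections` attribute.
#' * `"relief"`: relief times of patients receiving an analgesic.  The source
#'   table describes 20 patients but prints only 14 values; the sample is
#'   returned as printed and carries the flag `"incomplete"` (it is *not*
#'   silently completed from the literature's 20-value dataset).
#'
#' @param name `"covid_nl"` or `"relief"`.
#' @return a [neutro_sample()].
#' @examples
#' covid <- load_dataset("covid_nl")
#' nrow(covid)   # 30
#' @export
load_dataset <- function(name = c("covid_nl", "relief")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "nesbr3",
                      mustWork = TRUE)
  ns <- read_sample(path, format = "interval")
  attr(ns, "indet") <- indet_interval(0, 0.05)
  attr(ns, "label") <- name
  if (name == "relief") {
    attr(ns, "flags") <- "incomplete"
    warning("the 'relief' dataset is incomplete: the source describes 20 ",
            "patients but prints only 14 values", call. = FALSE)
  }
  if (name == "covid_nl") {
    attr(ns, "corrections") <-
      "lower[2] = 10.656 (misprinted as 10.056; implied by upper 11.18880 = 10.656 * 1.05)"
  }
  ns
}

#' Read and write neutrosophic samples
#'
#' `read_sample()` reads either an interval CSV (header `lower,upper`, comma
#' separated, dot decimal) or a crisp text file (UTF-8, one positive decimal
#' per line, `#` comments allowed) that is then neutrosophied with `indet`.
#' `write_sample()` writes the interval CSV; a write-then-read round trip is
#' the identity to full precision.
#'
#' @param path file path.
#' @param format `"interval"` or `"crisp"`.
#' @param indet indeterminacy interval applied when `format = "crisp"`.
#' @param nsample a [neutro_sample()].
#' @return `read_sample()` a [neutro_sample()]; `write_sample()` `path`
#'   invisibly.
#' @export
read_sample <- function(path, format = c("interval", "crisp"),
                        indet = indet_interval(0, 0.05)) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("I/O error: cannot open '%s'", path), call. = FALSE)
  if (format == "crisp") {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    keep <- nzchar(lines)
    vals <- suppressWarnings(as.numeric(lines[keep]))
    if (any(is.na(vals))) {
      bad <- which(keep)[which(is.na(vals))[1L]]
      stop(sprintf("parse error at line %d of '%s'", bad, path),
           call. = FALSE)
    }
    check_x_positive(vals, "crisp values")
    return(neutrosophy(vals, indet, label = basename(path)))
  }
  tab <- tryCatch(read.csv(path, header = TRUE),
                  error = function(e)
                    stop(sprintf("parse error in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (!all(c("lower", "upper") %in% names(tab)))
    stop("parse error: interval CSV must have a 'lower,upper' header",
         call. = FALSE)
  if (any(!is.finite(tab$lower)) || any(!is.finite(tab$upper))) {
    bad <- which(!is.finite(tab$lower) | !is.finite(tab$upper))[1L]
    stop(sprintf("parse error at data row %d of '%s'", bad, path),
         call. = FALSE)
  }
  neutro_sample(tab$lower, tab$upper, indet = indet, label = basename(path))
}

#' @rdname read_sample
#' @export
write_sample <- function(nsample, path) {
  stopifnot(inherits(nsample, "neutro_sample"))
  ## full-precision round trip
  df <- data.frame(lower = format(nsample$lower, digits = 17, trim = TRUE),
                   upper = format(nsample$upper, digits = 17, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
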