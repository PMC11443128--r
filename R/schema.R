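#' Age-band schema
#'
#' An ordered set of contiguous age bands starting at age 0, with a single
#' open-ended final band. The schema is the coordinate system of every
#' stratified table in the package: event counts, populations, deaths, rates
#' and life-table columns are all indexed by its band labels.
#'
#' @param lower Integer vector of band lower bounds in years, starting at 0,
#'   strictly increasing. The final band is open-ended (width `Inf`).
#' @param labels Optional character vector of band labels. Defaults to
#'   `"<lower>-<upper>"` for closed bands and `"<lower>+"` for the open band.
#'
#' @return An object of class `age_band_schema`: a data frame with columns
#'   `label`, `lower` and `width` (years; `Inf` for the final band).
#'
#' @details The default schema, [default_age_bands()], is the conventional
#'   set of 19 five-year epochs 0-4, 5-9, ..., 85-89, 90+ used in national
#'   lifetime-risk analyses. Bands are closed-open intervals
#'   `[lower, lower + width)`; the final band is `[lower, Inf)`.
#'
#' @examples
#' default_age_bands()
#' age_band_schema(c(0, 65))  # two bands: 0-64 and 65+
#' @export
age_band_schema <- function(lower, labels = NULL) {
  if (!is.numeric(lower) || length(lower) < 1L) {
    stop("'lower' must be a non-empty numeric vector of band lower bounds")
  }
  lower <- as.numeric(lower)
  if (lower[1L] != 0) stop("age bands must start at age 0")
  if (length(lower) > 1L && any(diff(lower) <= 0)) {
    stop("band lower bounds must be strictly increasing")
  }
  width <- c(diff(lower), Inf)
  if (is.null(labels)) {
    upper <- lower + width - 1
    labels <- ifelse(is.finite(width),
                     paste0(lower, "-", upper),
                     paste0(lower, "+"))
  }
  if (anyDuplicated(labels)) stop("band labels must be unique")
  if (length(labels) != length(lower)) {
    stop("'labels' must have one entry per band")
  }
  out <- data.frame(label = as.character(labels), lower = lower,
                    width = width, stringsAsFactors = FALSE)
  class(out) <- c("age_band_schema", "data.frame")
  out
}

#' @rdname age_band_schema
#' @export
default_age_bands <- function() {
  age_band_schema(seq(0, 90, by = 5))
}

#' @export
print.age_band_schema <- function(x, ...) {
  cat("Age-band schema:", nrow(x), "bands,",
      x$label[1L], "...", x$label[nrow(x)], "(open)\n")
  invisible(x)
}

n_bands <- function(schema) nrow(schema)

band_labels <- function(schema) schema$label

# Resolve labels against a schema; error names the offending values.
match_bands <- function(labels, schema, context = "table") {
  idx <- match(labels, schema$label)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop(sprintf("unknown band label(s) in %s: %s", context,
                 paste(bad, collapse = ", ")))
  }
  idx
}

# Index of the band containing each age (closed-open intervals).
band_of_age <- function(age, schema) {
  findInterval(age, schema$lower)
}
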