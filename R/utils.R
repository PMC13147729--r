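#' @keywords internal
"_PACKAGE"

# Internal helpers shared across the pipeline.

stop2 <- function(...) stop(..., call. = FALSE)

#' Round half away from zero
#'
#' Report-time rounding for percentages. `base::round()` rounds half to even;
#' printed survey-style percentages conventionally round half up, so 13.205
#' becomes 13.21 and -13.205 becomes -13.21.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Derive a per-component substream seed from a master seed.  Kept below
# 2^31 - 1 so it is always a valid R integer.
sub_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  as.integer((as.double(seed) * 48271 + component * 16807) %% 2147483647)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop2(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop2(sprintf("`%s` must lie in [0, 1]", name))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uppercase + strip whitespace: the canonical form for gene-symbol matching.
norm_genes <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!is.na(x) & nzchar(x)]
}

# Split semicolon-separated gene annotations into a probe -> gene long table.
explode_genes <- function(probe_id, genes) {
  parts <- strsplit(as.character(genes), ";", fixed = TRUE)
  n <- lengths(parts)
  out <- data.frame(
    probe_id = rep(probe_id, n),
    gene = toupper(trimws(unlist(parts, use.names = FALSE))),
    stringsAsFactors = FALSE
  )
  out[!is.na(out$gene) & nzchar(out$gene), , drop = FALSE]
}
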