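# Shared fixture builders and independent oracles for the test suite.

# Minimal moderated-fit-style table built from explicit vectors.
make_fit_table <- function(probe_id, slope, significant,
                           subgroup = NULL, p_adj = NULL, p_raw = NULL,
                           mean_m = 0, mean_beta = 0.5) {
  n <- length(probe_id)
  data.frame(
    probe_id = probe_id,
    slope_m_per_year = slope,
    significant = significant,
    subgroup = subgroup %||% rep("HM", n),
    p_adj = p_adj %||% ifelse(significant, 0.01, 0.5),
    p_raw = p_raw %||% ifelse(significant, 0.001, 0.4),
    mean_m = rep_len(mean_m, n),
    mean_beta = rep_len(mean_beta, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle for the posterior-variance convex combination.
posterior_var_oracle <- function(s2, d, d0, s02) {
  out <- numeric(length(s2))
  for (i in seq_along(s2)) {
    out[i] <- if (is.infinite(d0)) s02 else (d0 * s02 + d[i] * s2[i]) / (d0 + d[i])
  }
  out
}

# Brute-force all-pairs interval overlap: probe position inside a BED
# half-open interval [start, end) iff start <= pos < end.
overlap_oracle <- function(probes, icrs) {
  hits <- list()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(icrs))) {
      if (probes$chr[i] == icrs$chr[j] &&
          probes$pos[i] >= icrs$start[j] && probes$pos[i] < icrs$end[j]) {
        hits[[length(hits) + 1]] <- data.frame(
          probe_id = probes$probe_id[i], icr_id = j,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(probe_id = character(), icr_id = integer()))
  }
  do.call(rbind, hits)
}

# Tiny covariate table with non-degenerate age/bmi/patient columns.
toy_covariates <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%02d", 1:n),
    age = seq(18, 35, length.out = n),
    bmi = runif(n, 19, 32),
    patient = rep_len(c(0, 1), n),
    sperm_quality = rep_len(c(0, 0, 1), n),
    stringsAsFactors = FALSE
  )
}
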