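# Methylation-subgroup classification, M-to-beta effect back-transformation,
# subgroup summary tables, genomic-context cross-tabs and top-list selection.

#' Assign methylation subgroups from mean beta-values
#'
#' A CpG site is unmethylated (UM) when its mean beta is below 0.20,
#' hemi-methylated (HM) when 0.20 <= mean beta <= 0.80 (both boundaries
#' inclusive), and fully methylated (FM) above 0.80.
#'
#' @param mean_betas per-probe mean beta-values in \[0, 1\].
#' @return character vector of labels `"UM"`, `"HM"`, `"FM"`.
#' @export
assign_subgroups <- function(mean_betas) {
  if (!is.numeric(mean_betas) || any(is.na(mean_betas)) ||
      any(mean_betas < 0) || any(mean_betas > 1)) {
    stop2("`mean_betas` must lie in [0, 1] with no missing values")
  }
  ifelse(mean_betas < 0.20, "UM", ifelse(mean_betas <= 0.80, "HM", "FM"))
}

#' Back-transform an M-scale effect to the beta scale (intercept method)
#'
#' Given a baseline M-value `m0` and an M-scale change `delta_m`, the
#' corresponding beta-scale change is
#' \deqn{\Delta\beta = \frac{2^{M_0+\Delta M}}{1+2^{M_0+\Delta M}} -
#'       \frac{2^{M_0}}{1+2^{M_0}}}
#' i.e. the difference of inverse-logistic transforms. The baseline used in
#' this package is the probe's observed mean M across subjects.
#'
#' @param m0 baseline M-value(s).
#' @param delta_m M-scale change(s), e.g. a per-year regression slope.
#' @return beta-scale change(s), same length as the inputs.
#' @export
delta_beta_from_m <- function(m0, delta_m) {
  if (!is.numeric(m0) || !is.numeric(delta_m) ||
      any(!is.finite(m0)) || any(!is.finite(delta_m))) {
    stop2("`m0` and `delta_m` must be finite numerics")
  }
  m_to_beta(m0 + delta_m) - m_to_beta(m0)
}

#' Summarize differentially methylated CpGs by subgroup
#'
#' Builds the per-subgroup frequency table of analyzed sites and
#' significant DMCs: site counts, DMC counts, the negative/positive
#' direction split, each subgroup's share of all DMCs, and the DMC rate
#' within the subgroup. Percentages are carried at full precision with
#' report-rounded (2 decimals, half-up) twins.
#'
#' @param fits per-probe table with columns `significant` (logical) and a
#'   slope column (`slope_m_per_year` or `slope_age`).
#' @param labels per-probe subgroup labels aligned with `fits` rows
#'   (defaults to `fits$subgroup`).
#' @param alpha significance level recorded in the summary (must match the
#'   `significant` flag's threshold; only validated for range).
#' @return `data.frame` with rows `All`, `UM`, `HM`, `FM` and columns
#'   `n_sites`, `pct_sites`, `n_dmcs`, `n_negative`, `n_positive`,
#'   `pct_of_dmcs`, `pct_negative`, `pct_positive`, `pct_of_sites` plus
#'   `*_rounded` report columns.
#' @export
summarize_dmcs <- function(fits, labels = fits$subgroup, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop2("`alpha` must lie in (0, 1)")
  }
  if (is.null(labels) || length(labels) != nrow(fits)) {
    stop2("`labels` must provide one subgroup label per row of `fits`")
  }
  slope <- fits$slope_m_per_year %||% fits$slope_age
  if (is.null(slope)) stop2("`fits` must carry a slope column")
  sig <- as.logical(fits$significant)

  groups <- list(All = rep(TRUE, nrow(fits)),
                 UM = labels == "UM", HM = labels == "HM", FM = labels == "FM")
  total_sites <- nrow(fits)
  total_dmcs <- sum(sig)

  out <- do.call(rbind, lapply(names(groups), function(g) {
    in_g <- groups[[g]]
    n_sites <- sum(in_g)
    n_dmcs <- sum(sig & in_g)
    n_neg <- sum(sig & in_g & slope < 0)
    n_pos <- sum(sig & in_g & slope > 0)
    data.frame(
      subgroup = g,
      n_sites = n_sites,
      pct_sites = if (total_sites > 0) 100 * n_sites / total_sites else 0,
      n_dmcs = n_dmcs,
      n_negative = n_neg,
      n_positive = n_pos,
      pct_of_dmcs = if (total_dmcs > 0) 100 * n_dmcs / total_dmcs else 0,
      pct_negative = if (n_dmcs > 0) 100 * n_neg / n_dmcs else 0,
      pct_positive = if (n_dmcs > 0) 100 * n_pos / n_dmcs else 0,
      pct_of_sites = if (n_sites > 0) 100 * n_dmcs / n_sites else 0,
      stringsAsFactors = FALSE
    )
  }))
  for (col in c("pct_sites", "pct_of_dmcs", "pct_negative", "pct_positive",
                "pct_of_sites")) {
    out[[paste0(col, "_rounded")]] <- round_half_up(out[[col]], 2)
  }
  attr(out, "alpha") <- alpha
  out
}

#' Cross-tabulate DMCs by genomic context
#'
#' Counts significant DMCs by CpG-island relation and by functional region,
#' split by direction of the age effect (and by methylation subgroup for
#' the island table). Probes annotated to several functional regions are
#' counted once, in the `multiple` category. The negative:positive ratio is
#' reported per context with a flag where the positive count is zero.
#'
#' @param fits `moderated_fit_table` (or any table with `probe_id`,
#'   `significant`, a slope column and `subgroup`).
#' @param annotation probe annotation with `probe_id`, `island_relation`,
#'   `functional_region`.
#' @return list of two `data.frame`s: `island` (island relation x subgroup
#'   counts with `n_negative`, `n_positive`, `ratio_neg_pos`,
#'   `ratio_defined`) and `functional` (the same by functional region).
#' @export
crosstab_genomic <- function(fits, annotation) {
  slope <- fits$slope_m_per_year %||% fits$slope_age
  dmc <- fits[as.logical(fits$significant), , drop = FALSE]
  dmc_slope <- slope[as.logical(fits$significant)]
  idx <- match(dmc$probe_id, annotation$probe_id)
  if (anyNA(idx)) {
    stop2("annotation missing for DMC probes: ",
          paste(utils::head(dmc$probe_id[is.na(idx)], 5), collapse = ", "))
  }
  island <- annotation$island_relation[idx]
  region <- annotation$functional_region[idx]
  # multi-region annotations collapse to one `multiple` category
  region[grepl(";", region, fixed = TRUE)] <- "multiple"

  tab_by <- function(context, levels_ctx, subgroup = NULL) {
    cells <- if (is.null(subgroup)) {
      data.frame(context = levels_ctx, stringsAsFactors = FALSE)
    } else {
      expand.grid(context = levels_ctx, subgroup = c("UM", "HM", "FM"),
                  stringsAsFactors = FALSE)
    }
    cells$n_negative <- cells$n_positive <- 0L
    for (i in seq_len(nrow(cells))) {
      in_cell <- context == cells$context[i]
      if (!is.null(subgroup)) in_cell <- in_cell & dmc$subgroup == cells$subgroup[i]
      cells$n_negative[i] <- sum(in_cell & dmc_slope < 0)
      cells$n_positive[i] <- sum(in_cell & dmc_slope > 0)
    }
    cells$n_dmcs <- cells$n_negative + cells$n_positive
    cells$ratio_defined <- cells$n_positive > 0
    cells$ratio_neg_pos <- ifelse(cells$ratio_defined,
                                  cells$n_negative / cells$n_positive, NA_real_)
    cells
  }

  island_levels <- c("Island", "Shore", "Shelf", "OpenSea")
  island_levels <- union(island_levels, unique(island))
  region_levels <- sort(unique(c(region, "multiple")))
  list(
    island = tab_by(island, island_levels, subgroup = TRUE),
    functional = tab_by(region, region_levels)
  )
}

#' Select the most significant DMCs per subgroup
#'
#' For each methylation subgroup, keeps the `k` significant probes with the
#' lowest BH-adjusted p-value (ties broken by raw p, then probe id; stable).
#' Rows with an absolute M-scale slope strictly greater than the magnitude
#' threshold are flagged `high_magnitude`. The union across subgroups forms
#' the "top 90" set at the default `k = 30`.
#'
#' @param fits a `moderated_fit_table` with `subgroup`, `significant`,
#'   `p_adj`, `p_raw` and a slope column.
#' @param k top-list size per subgroup (default 30).
#' @param magnitude_threshold absolute slope cutoff for the high-magnitude
#'   flag (default 0.1, strict inequality).
#' @return `data.frame` of selected rows with added `rank_in_subgroup` and
#'   `high_magnitude`; warns when a subgroup holds fewer than `k`
#'   significant probes.
#' @export
select_top <- function(fits, k = 30, magnitude_threshold = 0.1) {
  k <- assert_count(k, "k", min = 1)
  slope_col <- if ("slope_m_per_year" %in% names(fits)) "slope_m_per_year" else "slope_age"
  sig <- fits[as.logical(fits$significant), , drop = FALSE]
  out <- list()
  for (g in c("UM", "HM", "FM")) {
    rows <- sig[sig$subgroup == g, , drop = FALSE]
    if (nrow(rows) == 0) next
    ord <- order(rows$p_adj, rows$p_raw, rows$probe_id)
    rows <- rows[ord, , drop = FALSE]
    if (nrow(rows) < k) {
      warning("subgroup ", g, " has only ", nrow(rows),
              " significant probes (requested ", k, ")", call. = FALSE)
    }
    rows <- utils::head(rows, k)
    rows$rank_in_subgroup <- seq_len(nrow(rows))
    out[[g]] <- rows
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- fits[0, , drop = FALSE]
    res$rank_in_subgroup <- integer(0)
  }
  res$high_magnitude <- abs(res[[slope_col]]) > magnitude_threshold
  rownames(res) <- NULL
  res
}
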