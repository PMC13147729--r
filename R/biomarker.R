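# Cross-study overlap counting, the eight-indicator "score of interest",
# and the final biomarker selection rule.

ind_cols <- c("icr", "co", "multi_cpg", "top90", "ma", "op", "is_island", "pr")

#' Count gene overlaps across study lists
#'
#' Given named gene lists from independent studies, counts for every
#' k = 1..N how many genes appear in at least k of the lists, and (for up
#' to 5 lists) the full Venn-region breakdown.
#'
#' @param gene_lists named list of character vectors of gene symbols
#'   (uppercased internally); at least 2 lists.
#' @return list with `at_least` (`k`, `n_genes`, non-increasing in `k`) and
#'   `venn` (one row per non-empty list combination: `region`, `n_genes`;
#'   `NULL` for more than 5 lists).
#' @export
overlap_counts <- function(gene_lists) {
  if (!is.list(gene_lists) || length(gene_lists) < 2) {
    stop2("`gene_lists` must be a list of at least 2 gene lists")
  }
  lists <- lapply(gene_lists, function(x) unique(norm_genes(x)))
  n <- length(lists)
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- paste0("list", seq_len(n))
  }
  all_genes <- unique(unlist(lists))
  member <- vapply(lists, function(l) all_genes %in% l,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
  k_count <- rowSums(member)
  at_least <- data.frame(k = seq_len(n),
                         n_genes = vapply(seq_len(n), function(k)
                           sum(k_count >= k), integer(1)))

  venn <- NULL
  if (n <= 5 && length(all_genes) > 0) {
    pattern <- apply(member, 1, function(r) paste(names(lists)[r], collapse = "&"))
    tab <- table(pattern)
    venn <- data.frame(region = names(tab), n_genes = as.integer(tab),
                       stringsAsFactors = FALSE, row.names = NULL)
  }
  list(at_least = at_least, venn = venn)
}

#' Sum indicator columns into the score of interest
#'
#' The score of interest is the integer sum (0-8) of a gene's eight binary
#' indicators: ICR-linked, co-listed by at least three other studies,
#' multiple significant DMCs, top-90 membership, high effect magnitude
#' (|delta-M| > 0.1), opposite direction (methylation increasing at an
#' unmethylated site or decreasing at a fully methylated site), CpG-island
#' DMC, and promoter DMC.
#'
#' @param v a numeric/integer vector of eight 0/1 indicators, or a
#'   `data.frame` holding the indicator columns `icr`, `co`, `multi_cpg`,
#'   `top90`, `ma`, `op`, `is_island`, `pr` (one score per row).
#' @return integer score(s) in 0..8.
#' @export
score_of_interest <- function(v) {
  if (is.data.frame(v)) {
    miss <- setdiff(ind_cols, names(v))
    if (length(miss)) stop2("missing indicator columns: ", paste(miss, collapse = ", "))
    mat <- as.matrix(v[, ind_cols])
  } else {
    if (length(v) != 8) stop2("indicator vector must have exactly 8 elements")
    mat <- matrix(as.numeric(v), nrow = 1)
  }
  if (any(is.na(mat)) || !all(mat %in% c(0, 1))) {
    stop2("all indicators must be 0 or 1")
  }
  as.integer(rowSums(mat))
}

#' Compute the eight biomarker indicators for one gene
#'
#' Evaluates the indicator definitions on a gene's significant DMCs.
#'
#' @param gene gene symbol (matched case-insensitively).
#' @param dmcs significant rows of a `moderated_fit_table` (needs
#'   `probe_id`, a slope column, `subgroup`).
#' @param annotation probe annotation (`probe_id`, `genes`,
#'   `island_relation`, `functional_region`, `crossreactive`).
#' @param icr_hits `hits` element of [map_icrs()] run on the same DMCs
#'   (`NULL` treated as no ICR links).
#' @param top_probes character vector of probe ids in the top-90 set
#'   (union of per-subgroup top lists from [select_top()]).
#' @param external_lists named list of external study gene lists; `co` is 1
#'   when the gene appears in at least `co_threshold` of them.
#' @param magnitude_threshold strict cutoff on |slope| for `ma`.
#' @param co_threshold number of external lists required for `co`.
#' @return one-row `data.frame`: `gene`, the eight indicators, `score`,
#'   `n_dmcs` and `crossreactive_only` (all of the gene's DMCs sit on
#'   cross-reactive probes).
#' @export
compute_indicators <- function(gene, dmcs, annotation, icr_hits = NULL,
                               top_probes = character(),
                               external_lists = list(),
                               magnitude_threshold = 0.1,
                               co_threshold = 3) {
  gene <- norm_genes(gene)
  slope <- dmcs$slope_m_per_year %||% dmcs$slope_age
  long <- explode_genes(dmcs$probe_id,
                        annotation$genes[match(dmcs$probe_id, annotation$probe_id)])
  rows <- match(unique(long$probe_id[long$gene == gene]), dmcs$probe_id)
  if (length(rows) == 0) {
    stop2("gene ", gene, " has no significant DMC in `dmcs`")
  }
  probes <- dmcs$probe_id[rows]
  ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
  s <- slope[rows]
  sg <- dmcs$subgroup[rows]

  in_lists <- vapply(external_lists, function(l) gene %in% norm_genes(l),
                     logical(1))
  out <- data.frame(
    gene = gene,
    icr = as.integer(!is.null(icr_hits) && any(probes %in% icr_hits$probe_id)),
    co = as.integer(sum(in_lists) >= co_threshold),
    multi_cpg = as.integer(length(probes) >= 2),
    top90 = as.integer(any(probes %in% top_probes)),
    ma = as.integer(any(abs(s) > magnitude_threshold)),
    op = as.integer(any((s > 0 & sg == "UM") | (s < 0 & sg == "FM"))),
    is_island = as.integer(any(ann$island_relation == "Island")),
    pr = as.integer(any(ann$functional_region == "promoter")),
    stringsAsFactors = FALSE
  )
  out$score <- score_of_interest(out)
  out$n_dmcs <- length(probes)
  out$crossreactive_only <- all(as.logical(ann$crossreactive))
  out
}

#' Build score cards for a set of genes
#'
#' Applies [compute_indicators()] to each gene (by default, every gene with
#' at least one significant DMC) and returns one score card per gene,
#' sorted by score (descending) then symbol.
#'
#' @inheritParams compute_indicators
#' @param genes genes to score; default all genes with a significant DMC.
#' @return `data.frame` of score cards.
#' @export
build_scorecards <- function(dmcs, annotation, icr_hits = NULL,
                             top_probes = character(),
                             external_lists = list(), genes = NULL,
                             magnitude_threshold = 0.1, co_threshold = 3) {
  if (is.null(genes)) {
    long <- explode_genes(dmcs$probe_id,
                          annotation$genes[match(dmcs$probe_id,
                                                 annotation$probe_id)])
    genes <- sort(unique(long$gene))
  } else {
    genes <- norm_genes(genes)
  }
  cards <- do.call(rbind, lapply(genes, compute_indicators, dmcs = dmcs,
                                 annotation = annotation, icr_hits = icr_hits,
                                 top_probes = top_probes,
                                 external_lists = external_lists,
                                 magnitude_threshold = magnitude_threshold,
                                 co_threshold = co_threshold))
  if (is.null(cards)) return(NULL)
  cards <- cards[order(-cards$score, cards$gene), , drop = FALSE]
  rownames(cards) <- NULL
  cards
}

#' Select biomarker candidate genes
#'
#' Final selection rule: keep disease-related genes that are ICR-linked,
#' plus disease-related genes without an ICR link whose score of interest
#' reaches the threshold; then drop genes on the pseudogene list and genes
#' whose only supporting DMCs are cross-reactive probes. The result is
#' deterministic (score descending, then symbol).
#'
#' @param scorecards score-card table from [build_scorecards()] (or a
#'   transcribed equivalent with `gene`, the indicator columns and
#'   `score`).
#' @param asd_genes character vector of disease-associated genes.
#' @param icr_linked optional character vector overriding which genes count
#'   as ICR-linked; defaults to `scorecards$icr == 1`.
#' @param pseudogenes genes to exclude as pseudogenes.
#' @param crossreactive_only genes whose evidence is exclusively
#'   cross-reactive probes; defaults to the score-card column when present.
#' @param threshold minimum score for non-ICR-linked genes (default 3).
#' @return `data.frame` of selected score-card rows.
#' @export
select_biomarkers <- function(scorecards, asd_genes, icr_linked = NULL,
                              pseudogenes = character(),
                              crossreactive_only = NULL, threshold = 3) {
  asd <- norm_genes(asd_genes)
  if (length(asd) == 0) return(scorecards[0, , drop = FALSE])
  genes <- norm_genes_keep(scorecards$gene)
  is_icr <- if (is.null(icr_linked)) scorecards$icr == 1 else genes %in% norm_genes(icr_linked)
  if (is.null(crossreactive_only)) {
    crossreactive_only <- if ("crossreactive_only" %in% names(scorecards)) {
      genes[as.logical(scorecards$crossreactive_only)]
    } else character()
  }
  keep <- genes %in% asd &
    (is_icr | scorecards$score >= threshold) &
    !(genes %in% norm_genes(pseudogenes)) &
    !(genes %in% norm_genes(crossreactive_only))
  out <- scorecards[keep, , drop = FALSE]
  out <- out[order(-out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the packaged worked-example score card
#'
#' A 28-gene score card of ASD-associated (predicted) imprinted genes with
#' their eight indicator columns and published scores, shipped as a
#' plain-text fixture for regression-testing [score_of_interest()] and
#' [select_biomarkers()].
#'
#' @return `data.frame` with `gene`, `chr`, `probe_id`, the eight indicator
#'   columns, `score_printed` and `crossreactive_probe`.
#' @export
load_example_scorecard <- function() {
  path <- system.file("extdata", "asd_imprinted_scorecard.csv",
                      package = "spermage", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
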