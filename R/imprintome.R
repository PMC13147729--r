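# Mapping of differentially methylated CpGs to imprinted genes and imprint
# control regions (ICRs), with parent-of-origin summaries.  ICR intervals
# arrive in BED convention (0-based, half-open); a probe position p hits
# interval [s, e) iff s <= p < e, so a probe exactly at the `end`
# coordinate does not hit.

#' Map DMCs to imprinted genes
#'
#' Matches the gene annotations of each DMC probe (semicolon-exploded,
#' uppercased) against an imprinted-gene list. A probe annotated to several
#' genes can match each of them.
#'
#' @param dmcs `data.frame` of DMC rows with a `probe_id` column (e.g. the
#'   significant subset of a `moderated_fit_table`).
#' @param annotation probe annotation with `probe_id` and `genes`.
#' @param imprinted imprinted-gene table with `gene`, `status`,
#'   `expressed_allele` (`M` maternally expressed, `P` paternally
#'   expressed, `I` isoform dependent).
#' @return list with `hits` (one row per DMC-gene pairing: `probe_id`,
#'   `gene`, `status`, `expressed_allele`) and `summary` (single row:
#'   `n_dmcs`, `n_dmcs_matched`, `pct_dmcs_matched`, `n_genes_matched`,
#'   `n_imprinted_on_array`, `pct_imprinted_genes_hit`, plus gene counts
#'   `n_genes_M`, `n_genes_P`, `n_genes_I`).
#' @export
map_genes <- function(dmcs, annotation, imprinted) {
  if (is.null(imprinted) || nrow(imprinted) == 0) {
    imprinted <- data.frame(gene = character(), status = character(),
                            expressed_allele = character(),
                            stringsAsFactors = FALSE)
  }
  imprinted$gene <- norm_genes_keep(imprinted$gene)
  idx <- match(dmcs$probe_id, annotation$probe_id)
  if (anyNA(idx)) {
    stop2("annotation missing for DMC probes: ",
          paste(utils::head(dmcs$probe_id[is.na(idx)], 5), collapse = ", "))
  }
  long <- explode_genes(dmcs$probe_id, annotation$genes[idx])
  hits <- long[long$gene %in% imprinted$gene, , drop = FALSE]
  hits <- merge(hits, imprinted, by = "gene", sort = FALSE)
  hits <- hits[order(hits$probe_id, hits$gene), c("probe_id", "gene",
                                                  "status", "expressed_allele")]
  rownames(hits) <- NULL

  array_long <- explode_genes(annotation$probe_id, annotation$genes)
  on_array <- intersect(imprinted$gene, unique(array_long$gene))
  genes_hit <- unique(hits$gene)
  allele_of <- imprinted$expressed_allele[match(genes_hit, imprinted$gene)]

  summary <- data.frame(
    n_dmcs = nrow(dmcs),
    n_dmcs_matched = length(unique(hits$probe_id)),
    pct_dmcs_matched = if (nrow(dmcs) > 0)
      round_half_up(100 * length(unique(hits$probe_id)) / nrow(dmcs), 2) else 0,
    n_genes_matched = length(genes_hit),
    n_imprinted_on_array = length(on_array),
    pct_imprinted_genes_hit = if (length(on_array) > 0)
      round_half_up(100 * length(genes_hit) / length(on_array), 2) else 0,
    n_genes_M = sum(allele_of == "M"),
    n_genes_P = sum(allele_of == "P"),
    n_genes_I = sum(allele_of == "I")
  )
  list(hits = hits, summary = summary)
}

# toupper/trim but preserve length (for table columns that may hold "")
norm_genes_keep <- function(x) toupper(trimws(as.character(x)))

#' Map DMCs to imprint control regions
#'
#' A DMC hits an ICR when its position lies inside the half-open interval
#' (`start <= pos < end`), so a probe exactly at the BED `end` coordinate
#' does not hit. An optional symmetric flank widens every interval. A DMC inside two overlapping ICRs contributes one DMC count
#' but two DMC-ICR pairings.
#'
#' @param dmcs `data.frame` of DMC rows with `probe_id`.
#' @param annotation probe annotation with `probe_id`, `chr`, `pos`.
#' @param icrs ICR table from [read_icr_bed()] (`chr`, 0-based half-open
#'   `start`/`end`, `gene`, `origin`).
#' @param flank extra bases added on both sides of every ICR (default 0).
#' @return list with `hits` (`probe_id`, `icr_id`, `gene`, `origin`) and
#'   `summary`: one row per origin (`paternal`, `maternal`, `unknown`) plus
#'   `total`, with `n_dmcs`, `n_icrs`, `n_genes`.
#' @export
map_icrs <- function(dmcs, annotation, icrs, flank = 0) {
  idx <- match(dmcs$probe_id, annotation$probe_id)
  if (anyNA(idx)) {
    stop2("annotation missing for DMC probes: ",
          paste(utils::head(dmcs$probe_id[is.na(idx)], 5), collapse = ", "))
  }
  if (is.null(icrs) || nrow(icrs) == 0) {
    hits <- data.frame(probe_id = character(), icr_id = integer(),
                       gene = character(), origin = character(),
                       stringsAsFactors = FALSE)
  } else {
    probe_gr <- GenomicRanges::GRanges(
      seqnames = as.character(annotation$chr[idx]),
      ranges = IRanges::IRanges(start = annotation$pos[idx], width = 1))
    icr_gr <- GenomicRanges::GRanges(
      seqnames = as.character(icrs$chr),
      ranges = IRanges::IRanges(start = icrs$start - flank,
                                end = icrs$end - 1L + flank))
    ov <- GenomicRanges::findOverlaps(probe_gr, icr_gr, ignore.strand = TRUE)
    hits <- data.frame(
      probe_id = dmcs$probe_id[S4Vectors::queryHits(ov)],
      icr_id = S4Vectors::subjectHits(ov),
      gene = norm_genes_keep(icrs$gene)[S4Vectors::subjectHits(ov)],
      origin = icrs$origin[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE
    )
    hits <- hits[order(hits$probe_id, hits$icr_id), , drop = FALSE]
    rownames(hits) <- NULL
  }

  origins <- c("paternal", "maternal", "unknown")
  summary <- do.call(rbind, lapply(origins, function(o) {
    h <- hits[hits$origin == o, , drop = FALSE]
    data.frame(origin = o,
               n_dmcs = length(unique(h$probe_id)),
               n_icrs = length(unique(h$icr_id)),
               n_genes = length(unique(h$gene)),
               stringsAsFactors = FALSE)
  }))
  summary <- rbind(summary, data.frame(
    origin = "total",
    n_dmcs = sum(summary$n_dmcs),
    n_icrs = length(unique(hits$icr_id)),
    n_genes = length(unique(hits$gene)),
    stringsAsFactors = FALSE
  ))
  list(hits = hits, summary = summary)
}

#' Summarize imprinted-gene hits by expressed allele and ICR origin
#'
#' Gene-level reconciliation of the two mapping routes: counts of matched
#' imprinted genes by expressed allele (M / P / I), and counts of ICR-linked
#' genes by parental origin of methylation. A gene linked to ICRs of more
#' than one origin appears once per origin and carries a `multi_origin`
#' flag.
#'
#' @param gene_hits `hits` element of [map_genes()] (or `NULL`).
#' @param icr_hits `hits` element of [map_icrs()] (or `NULL`).
#' @return list with `by_expressed_allele` (`expressed_allele`, `n_genes`,
#'   `total` attribute row included) and `by_origin` (`origin`, `gene`
#'   rows collapsed to `n_genes` with `n_multi_origin`).
#' @export
parent_of_origin_summary <- function(gene_hits = NULL, icr_hits = NULL) {
  by_allele <- NULL
  if (!is.null(gene_hits) && nrow(gene_hits) > 0) {
    per_gene <- unique(gene_hits[, c("gene", "expressed_allele")])
    counts <- table(factor(per_gene$expressed_allele, levels = c("M", "P", "I")))
    by_allele <- data.frame(expressed_allele = c(names(counts), "total"),
                            n_genes = c(as.integer(counts), nrow(per_gene)),
                            stringsAsFactors = FALSE)
  }
  by_origin <- NULL
  if (!is.null(icr_hits) && nrow(icr_hits) > 0) {
    pairs <- unique(icr_hits[, c("gene", "origin")])
    multi <- names(which(table(pairs$gene) > 1))
    pairs$multi_origin <- pairs$gene %in% multi
    agg <- stats::aggregate(gene ~ origin, data = pairs, FUN = length)
    names(agg)[2] <- "n_genes"
    agg$n_multi_origin <- vapply(agg$origin, function(o) {
      sum(pairs$multi_origin[pairs$origin == o])
    }, integer(1))
    by_origin <- agg
    attr(by_origin, "gene_origin_pairs") <- pairs
  }
  list(by_expressed_allele = by_allele, by_origin = by_origin)
}
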