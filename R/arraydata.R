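# Array data handling: beta/M transforms, probe filters, and the tabular
# formats the pipeline exchanges (beta TSV, covariate/annotation CSV, ICR BED,
# gene-list text).

#' Convert beta-values to M-values
#'
#' Methylation proportions (beta-values) are heteroscedastic near 0 and 1;
#' regression is therefore run on the log2-odds (M-value) scale,
#' \eqn{M = \log_2(\beta / (1 - \beta))}. Values are first clipped to
#' `[epsilon, 1 - epsilon]` so the transform is finite everywhere.
#'
#' @param beta numeric matrix (probes x subjects) or vector of proportions.
#' @param epsilon clipping guard in (0, 0.5); default `1e-6`.
#' @return object of the same shape with M-values.
#' @seealso [m_to_beta()]
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      is.na(epsilon) || epsilon <= 0 || epsilon >= 0.5) {
    stop2("`epsilon` must be a single value in (0, 0.5)")
  }
  if (!is.numeric(beta)) stop2("`beta` must be numeric")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  attributes(m) <- attributes(beta)
  m
}

#' Convert M-values to beta-values
#'
#' Inverse logistic (base 2) transform, \eqn{\beta = 2^M / (1 + 2^M)}.
#' Round-trips with [beta_to_m()] to within 1e-12 for beta inside the
#' clipping guard.
#'
#' @param m numeric matrix or vector of M-values; must be finite.
#' @return object of the same shape with beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop2("`m` must be numeric")
  if (any(!is.finite(m))) stop2("`m` must be finite everywhere")
  # 1/(1 + 2^-M) is stable for large |M| in both directions
  b <- 1 / (1 + 2^(-m))
  attributes(b) <- attributes(m)
  b
}

#' Filter probes by detection quality and probe blacklists
#'
#' Removes, in order of precedence, (1) probes whose detection p-value
#' exceeds 0.01 in at least one subject, (2) probes flagged as overlapping
#' a SNP, and (3) probes flagged as cross-reactive. Each probe is counted
#' once, under the first rule that removes it, so the report is a partition.
#'
#' @param beta probes x subjects beta matrix with probe ids as rownames.
#' @param detp optional detection p-value matrix, same shape as `beta`.
#' @param annotation probe annotation `data.frame` with columns
#'   `probe_id`, `snp`, `crossreactive`.
#' @param detection,snp,crossreactive logical switches for the three rules.
#' @param detection_threshold detection p-value cutoff; a probe fails when
#'   `p > detection_threshold` (strict) in one or more subjects.
#' @return list with `beta` (retained rows, order preserved) and `report`,
#'   a one-row `data.frame` with columns `n_input`, `n_removed_detection`,
#'   `n_removed_snp`, `n_removed_crossreactive`, `n_retained`.
#' @export
filter_probes <- function(beta, detp = NULL, annotation = NULL,
                          detection = TRUE, snp = FALSE, crossreactive = FALSE,
                          detection_threshold = 0.01) {
  if (!is.matrix(beta)) stop2("`beta` must be a matrix with probe rownames")
  probes <- rownames(beta)
  if (is.null(probes)) stop2("`beta` must have probe ids as rownames")
  n_input <- nrow(beta)

  removed <- rep(NA_character_, n_input)
  if (detection && !is.null(detp)) {
    if (!all(dim(detp) == dim(beta))) {
      stop2("`detp` must have the same dimensions as `beta`")
    }
    bad <- rowSums(detp > detection_threshold) >= 1
    removed[bad] <- "detection"
  }
  if (snp || crossreactive) {
    if (is.null(annotation)) stop2("`annotation` required for flag-based filters")
    ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]
    if (anyNA(ann$probe_id)) {
      stop2("annotation is missing probes: ",
            paste(utils::head(probes[is.na(ann$probe_id)], 5), collapse = ", "))
    }
    if (snp) {
      bad <- is.na(removed) & as.logical(ann$snp)
      removed[bad] <- "snp"
    }
    if (crossreactive) {
      bad <- is.na(removed) & as.logical(ann$crossreactive)
      removed[bad] <- "crossreactive"
    }
  }

  keep <- is.na(removed)
  report <- data.frame(
    n_input = n_input,
    n_removed_detection = sum(removed == "detection", na.rm = TRUE),
    n_removed_snp = sum(removed == "snp", na.rm = TRUE),
    n_removed_crossreactive = sum(removed == "crossreactive", na.rm = TRUE),
    n_retained = sum(keep)
  )
  list(beta = beta[keep, , drop = FALSE], report = report)
}

# ---- readers / writers ------------------------------------------------------

#' Read a beta-value matrix from TSV
#'
#' Expects probes as rows, a `probe_id` first column, and one column per
#' subject.
#'
#' @param path TSV file path.
#' @return numeric matrix with probe rownames and subject colnames.
#' @export
read_beta_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") stop2("beta TSV must start with a `probe_id` column")
  if (anyDuplicated(df$probe_id)) {
    stop2("duplicate probe_id in ", path, ": ",
          df$probe_id[duplicated(df$probe_id)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- df$probe_id
  m
}

#' @rdname read_beta_tsv
#' @param beta probes x subjects matrix.
#' @export
write_beta_tsv <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject covariate table
#'
#' CSV with header `subject_id,age,bmi,patient` plus optional extras.
#' Age, BMI and patient status must be complete (no missing values).
#'
#' @param path CSV file path.
#' @return `data.frame` of covariates.
#' @export
read_covariates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "bmi", "patient")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("covariate file missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(df$age) || anyNA(df$bmi) || anyNA(df$patient)) {
    stop2("covariates must not contain missing age/bmi/patient values")
  }
  if (anyDuplicated(df$subject_id)) stop2("duplicate subject_id in ", path)
  df
}

#' Read a probe annotation table
#'
#' CSV with header
#' `probe_id,chr,pos,island_relation,functional_region,genes,snp,crossreactive`
#' (genes semicolon-separated, `pos` 1-based).
#'
#' @param path CSV file path.
#' @return `data.frame` of probe annotation.
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chr = "character"))
  need <- c("probe_id", "chr", "pos", "island_relation", "functional_region",
            "genes", "snp", "crossreactive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("annotation file missing columns: ", paste(miss, collapse = ", "))
  dup <- duplicated(df$probe_id)
  if (any(dup)) {
    stop2("duplicate probe_id in annotation at line ",
          which(dup)[1] + 1L, ": ", df$probe_id[dup][1])
  }
  df$genes[is.na(df$genes)] <- ""
  df
}

#' Read an ICR interval file (BED)
#'
#' Six-column BED, 0-based half-open, with the name field encoded as
#' `gene|origin` where origin is `paternal`, `maternal` or `unknown`.
#'
#' @param path BED file path.
#' @return `data.frame` with columns `chr`, `start`, `end` (0-based
#'   half-open, as in the file), `gene`, `origin`.
#' @export
read_icr_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop2("malformed BED file ", path, ": ",
                                           conditionMessage(e)))
  name <- as.character(gr$name)
  parts <- strsplit(name, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop2("malformed ICR name field at BED line ", bad[1],
          " (expected `gene|origin`): ", name[bad[1]])
  }
  gene <- toupper(vapply(parts, `[`, "", 1))
  origin <- vapply(parts, `[`, "", 2)
  ok <- origin %in% c("paternal", "maternal", "unknown")
  if (!all(ok)) {
    stop2("invalid ICR origin at BED line ", which(!ok)[1], ": ", origin[!ok][1])
  }
  data.frame(
    chr = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based half-open
    end = GenomicRanges::end(gr),
    gene = gene,
    origin = origin,
    stringsAsFactors = FALSE
  )
}

#' Read a gene list (one symbol per line)
#'
#' Lines starting with `#` are comments; symbols are uppercased and
#' whitespace-stripped.
#'
#' @param path text file path.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}

#' Load a full dataset from fixture files
#'
#' Reads the beta matrix, covariates and annotation (plus optional ICR BED,
#' imprinted-gene CSV, gene lists and ground-truth table) and checks
#' alignment: covariate subjects must exactly match beta columns, and the
#' annotation must cover every beta row.
#'
#' @param beta_path,covariate_path,annotation_path required file paths.
#' @param icr_path optional ICR BED path.
#' @param imprinted_path optional imprinted-gene CSV
#'   (`gene,status,expressed_allele`).
#' @param gene_list_paths optional named character vector/list of gene-list
#'   file paths.
#' @param truth_path optional ground-truth CSV from the generator.
#' @return a `methylation_dataset` list with elements `beta`, `covariates`,
#'   `annotation`, `icrs`, `imprinted`, `gene_lists`, `truth`.
#' @export
load_dataset <- function(beta_path, covariate_path, annotation_path,
                         icr_path = NULL, imprinted_path = NULL,
                         gene_list_paths = NULL, truth_path = NULL) {
  beta <- read_beta_tsv(beta_path)
  covariates <- read_covariates_csv(covariate_path)
  annotation <- read_annotation_csv(annotation_path)

  if (!identical(colnames(beta), as.character(covariates$subject_id))) {
    only_beta <- setdiff(colnames(beta), covariates$subject_id)
    only_cov <- setdiff(covariates$subject_id, colnames(beta))
    stop2("subject ids in covariates do not match beta columns; ",
          "only in beta: [", paste(only_beta, collapse = ", "), "]; ",
          "only in covariates: [", paste(only_cov, collapse = ", "), "]")
  }
  missing_ann <- setdiff(rownames(beta), annotation$probe_id)
  if (length(missing_ann)) {
    stop2("annotation is missing probes present in the beta matrix: ",
          paste(utils::head(missing_ann, 5), collapse = ", "))
  }

  icrs <- if (!is.null(icr_path)) read_icr_bed(icr_path) else NULL
  imprinted <- if (!is.null(imprinted_path)) {
    imp <- utils::read.csv(imprinted_path, stringsAsFactors = FALSE)
    imp$gene <- toupper(imp$gene)
    imp
  } else NULL
  gene_lists <- if (!is.null(gene_list_paths)) {
    lapply(gene_list_paths, read_gene_list)
  } else NULL
  truth <- if (!is.null(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  } else NULL

  structure(
    list(beta = beta, covariates = covariates, annotation = annotation,
         icrs = icrs, imprinted = imprinted, gene_lists = gene_lists,
         truth = truth),
    class = "methylation_dataset"
  )
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("methylation_dataset:", nrow(x$beta), "probes x", ncol(x$beta),
      "subjects\n")
  if (!is.null(x$icrs)) cat("  ICRs:", nrow(x$icrs), "\n")
  if (!is.null(x$imprinted)) cat("  imprinted genes:", nrow(x$imprinted), "\n")
  if (!is.null(x$truth)) {
    cat("  planted probes:", sum(x$truth$planted), "\n")
  }
  invisible(x)
}
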