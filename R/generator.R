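# Synthetic 450K-style array generator.  Emulates the study conditions of a
# sperm ageing cohort: 63 men aged 18-35, methylation beta-values with a
# three-state bimodal distribution (unmethylated / hemi-methylated / fully
# methylated), and linear age effects planted on the M scale with
# subgroup-specific direction probabilities.  Every stage of the analysis can
# be exercised against the recorded ground truth.

#' Generator configuration
#'
#' Bundles all tunable parameters of the synthetic-array generator. The
#' defaults are calibrated to the cohort conditions the pipeline targets:
#' subgroup weights 46.95/10.03/43.02 percent (UM/HM/FM), ages 18-35 with
#' mean about 25.5, a 31.8 percent overweight rate increasing with age, a
#' 23.8 percent patient rate decreasing with age, and CpG-island context
#' proportions of a 450K manifest (30.91 percent island, 36.28 percent open
#' sea).
#'
#' @param n_subjects number of subjects (>= 3).
#' @param n_probes number of probes (>= 1).
#' @param subgroup_weights named 3-vector of probe-subgroup proportions
#'   (UM, HM, FM); must sum to 1.
#' @param beta_archetypes per-subgroup `c(mean, conc)` of the beta
#'   distribution a probe's baseline methylation is drawn from. The default
#'   means (0.08 / 0.50 / 0.91) put essentially all baseline draws inside
#'   their subgroup's mean-beta window and give an array-wide mean
#'   methylation close to 0.48.
#' @param effect_fraction proportion of probes with a planted age effect.
#' @param effect_sizes distribution of the planted per-year M-scale slope
#'   magnitude: either `list(dist = "lognormal", meanlog, sdlog)` or
#'   `list(dist = "fixed", value)`.
#' @param direction_probs named per-subgroup probability that a planted
#'   effect is negative (defaults follow the observed direction split of
#'   age-associated CpGs: 91.84 / 74.73 / 53.27 percent negative).
#' @param residual_sd_m residual noise sd on the M scale.
#' @param age_range integer age bounds (years).
#' @param age_mean_target target mean age; draws are rejected until the
#'   sample mean is within `age_mean_tol` (best draw kept as fallback).
#' @param age_mean_tol tolerance on the realised mean age.
#' @param overweight_rate,patient_rate target marginal rates of BMI >= 25
#'   and fertility-patient status.
#' @param bmi_age_coef,patient_age_coef logistic slopes (per year of age)
#'   linking BMI category and patient status to age; positive for BMI
#'   (overweight more likely at older age), negative for patient status.
#' @param island_props named proportions for island / shore / shelf /
#'   open-sea context.
#' @param region_props named proportions for functional-region context.
#' @param snp_rate,crossreactive_rate per-probe flag rates.
#' @param gene_locus_bp width of one gene locus on the synthetic genome;
#'   probes falling into the same locus share a gene symbol.
#' @param second_gene_prob probability a gene-annotated probe carries a
#'   second (neighbouring) gene symbol.
#' @param imprinted_fraction fraction of the synthetic gene pool tagged as
#'   imprinted and given an ICR.
#' @param seed master seed; every generator component derives its own
#'   substream from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 63,
                             n_probes = 50000,
                             subgroup_weights = c(UM = 0.4695, HM = 0.1003, FM = 0.4302),
                             beta_archetypes = list(UM = c(mean = 0.08, conc = 100),
                                                    HM = c(mean = 0.50, conc = 12),
                                                    FM = c(mean = 0.91, conc = 100)),
                             effect_fraction = 0.03,
                             effect_sizes = list(dist = "lognormal",
                                                 meanlog = log(0.04), sdlog = 0.4),
                             direction_probs = c(UM = 0.9184, HM = 0.7473, FM = 0.5327),
                             residual_sd_m = 0.3,
                             age_range = c(18L, 35L),
                             age_mean_target = 25.48,
                             age_mean_tol = 0.6,
                             overweight_rate = 0.318,
                             patient_rate = 0.238,
                             bmi_age_coef = 0.15,
                             patient_age_coef = -0.25,
                             island_props = c(Island = 0.3091, Shore = 0.2300,
                                              Shelf = 0.0981, OpenSea = 0.3628),
                             region_props = c(promoter = 0.20, `5UTR` = 0.08,
                                              `1stExon` = 0.05, body = 0.30,
                                              `3UTR` = 0.04, intergenic = 0.25,
                                              multiple = 0.08),
                             snp_rate = 0.15,
                             crossreactive_rate = 0.06,
                             gene_locus_bp = 50000,
                             second_gene_prob = 0.05,
                             imprinted_fraction = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_subjects = assert_count(n_subjects, "n_subjects", min = 3),
    n_probes = assert_count(n_probes, "n_probes", min = 1),
    subgroup_weights = subgroup_weights,
    beta_archetypes = beta_archetypes,
    effect_fraction = assert_prob(effect_fraction, "effect_fraction"),
    effect_sizes = effect_sizes,
    direction_probs = assert_prob(direction_probs, "direction_probs"),
    residual_sd_m = residual_sd_m,
    age_range = as.integer(age_range),
    age_mean_target = age_mean_target,
    age_mean_tol = age_mean_tol,
    overweight_rate = assert_prob(overweight_rate, "overweight_rate"),
    patient_rate = assert_prob(patient_rate, "patient_rate"),
    bmi_age_coef = bmi_age_coef,
    patient_age_coef = patient_age_coef,
    island_props = island_props,
    region_props = region_props,
    snp_rate = assert_prob(snp_rate, "snp_rate"),
    crossreactive_rate = assert_prob(crossreactive_rate, "crossreactive_rate"),
    gene_locus_bp = as.integer(gene_locus_bp),
    second_gene_prob = assert_prob(second_gene_prob, "second_gene_prob"),
    imprinted_fraction = assert_prob(imprinted_fraction, "imprinted_fraction"),
    seed = as.integer(seed)
  )
  if (length(cfg$subgroup_weights) != 3 ||
      abs(sum(cfg$subgroup_weights) - 1) > 1e-9 ||
      any(cfg$subgroup_weights < 0)) {
    stop2("`subgroup_weights` must be 3 non-negative proportions summing to 1")
  }
  if (!setequal(names(cfg$subgroup_weights), c("UM", "HM", "FM"))) {
    stop2("`subgroup_weights` must be named UM, HM, FM")
  }
  if (length(cfg$direction_probs) != 3 ||
      !setequal(names(cfg$direction_probs), c("UM", "HM", "FM"))) {
    stop2("`direction_probs` must be named UM, HM, FM")
  }
  if (abs(sum(cfg$island_props) - 1) > 1e-6) {
    stop2("`island_props` must sum to 1")
  }
  if (cfg$residual_sd_m < 0) stop2("`residual_sd_m` must be >= 0")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2]) {
    stop2("`age_range` must be c(lower, upper) with lower <= upper")
  }
  if (!is.list(cfg$effect_sizes) ||
      !cfg$effect_sizes$dist %in% c("lognormal", "fixed")) {
    stop2("`effect_sizes$dist` must be \"lognormal\" or \"fixed\"")
  }
  structure(cfg, class = "generator_config")
}

draw_effect_magnitudes <- function(n, spec) {
  switch(spec$dist,
    lognormal = stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog),
    fixed = rep(spec$value, n)
  )
}

#' Simulate a subject covariate table
#'
#' Ages are drawn as whole years, uniform on the configured range, then
#' re-drawn (rejection, keeping the closest attempt) until the sample mean
#' lies within tolerance of the target. BMI category and patient status are
#' linked to age through logistic models whose intercepts are set to hit the
#' configured marginal rates at the target mean age: overweight probability
#' increases with age, patient probability decreases.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param config a [generator_config()].
#' @return `data.frame` with columns `subject_id`, `age`, `bmi`,
#'   `patient`, `sperm_quality`.
#' @export
make_covariates <- function(n_subjects = config$n_subjects,
                            config = generator_config()) {
  n_subjects <- assert_count(n_subjects, "n_subjects", min = 3)
  if (!inherits(config, "generator_config")) stop2("`config` must be a generator_config")
  set.seed(sub_seed(config$seed, 1L))

  lo <- config$age_range[1]; hi <- config$age_range[2]
  if (lo == hi) {
    age <- rep(lo, n_subjects)
  } else {
    target <- min(max(config$age_mean_target, lo), hi)
    best <- NULL; best_gap <- Inf
    for (i in seq_len(200)) {
      cand <- sample(lo:hi, n_subjects, replace = TRUE)
      gap <- abs(mean(cand) - target)
      if (gap < best_gap) { best <- cand; best_gap <- gap }
      if (gap <= config$age_mean_tol) break
    }
    age <- best
  }

  ref_age <- config$age_mean_target
  p_ow <- stats::plogis(stats::qlogis(config$overweight_rate) +
                          config$bmi_age_coef * (age - ref_age))
  overweight <- stats::rbinom(n_subjects, 1, p_ow)
  bmi <- ifelse(overweight == 1,
                stats::runif(n_subjects, 25, 33),
                stats::runif(n_subjects, 19, 24.9))
  p_pat <- stats::plogis(stats::qlogis(config$patient_rate) +
                           config$patient_age_coef * (age - ref_age))
  patient <- stats::rbinom(n_subjects, 1, p_pat)
  sperm_quality <- stats::rbinom(n_subjects, 1, 0.254)  # 1 = abnormal

  data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    age = age,
    bmi = round(bmi, 1),
    patient = patient,
    sperm_quality = sperm_quality,
    stringsAsFactors = FALSE
  )
}

#' Simulate a probe annotation table with imprinted genes and ICRs
#'
#' Probes are placed uniformly on a synthetic genome (chromosomes 1-22 and
#' X); island and functional-region context are sampled at the configured
#' array-wide proportions. Gene symbols are positional: probes falling into
#' the same gene locus share a symbol, so genes are contiguous intervals. A
#' configurable fraction of genes is tagged imprinted and assigned an ICR
#' interval guaranteed to contain at least one of the gene's probes.
#'
#' @param n_probes number of probes (>= 1).
#' @param config a [generator_config()].
#' @return an `array_annotation` list with elements `probes` (annotation
#'   `data.frame`), `imprinted` (`gene,status,expressed_allele`) and `icrs`
#'   (0-based half-open `chr,start,end,gene,origin`).
#' @export
make_annotation <- function(n_probes = config$n_probes,
                            config = generator_config()) {
  n_probes <- assert_count(n_probes, "n_probes", min = 1)
  if (!inherits(config, "generator_config")) stop2("`config` must be a generator_config")
  set.seed(sub_seed(config$seed, 2L))

  chroms <- c(as.character(1:22), "X")
  chr <- sample(chroms, n_probes, replace = TRUE)
  pos <- sample.int(100000000L, n_probes, replace = TRUE)
  island_relation <- sample(names(config$island_props), n_probes,
                            replace = TRUE, prob = config$island_props)
  functional_region <- sample(names(config$region_props), n_probes,
                              replace = TRUE, prob = config$region_props)
  snp <- stats::rbinom(n_probes, 1, config$snp_rate)
  crossreactive <- stats::rbinom(n_probes, 1, config$crossreactive_rate)

  # positional gene model: locus index within chromosome -> symbol
  locus <- pos %/% config$gene_locus_bp
  gene1 <- sprintf("G%s_%d", chr, locus)
  gene1[functional_region == "intergenic"] <- ""
  has_second <- stats::rbinom(n_probes, 1, config$second_gene_prob) == 1 &
    nzchar(gene1)
  gene2 <- sprintf("G%s_%d", chr, locus + 1L)
  genes <- ifelse(has_second, paste(gene1, gene2, sep = ";"), gene1)

  probes <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chr = chr,
    pos = pos,
    island_relation = island_relation,
    functional_region = functional_region,
    genes = toupper(genes),
    snp = snp,
    crossreactive = crossreactive,
    stringsAsFactors = FALSE
  )

  long <- explode_genes(probes$probe_id, probes$genes)
  pool <- unique(long$gene)
  n_imp <- round(length(pool) * config$imprinted_fraction)
  imprinted <- icrs <- NULL
  if (n_imp >= 1) {
    imp_genes <- sample(pool, n_imp)
    imprinted <- data.frame(
      gene = imp_genes,
      status = sample(c("confirmed", "predicted"), n_imp, replace = TRUE,
                      prob = c(0.55, 0.45)),
      expressed_allele = sample(c("M", "P", "I"), n_imp, replace = TRUE,
                                prob = c(0.52, 0.44, 0.04)),
      stringsAsFactors = FALSE
    )
    # one ICR per imprinted gene, anchored on one of its probes so the
    # interval provably contains >= 1 probe position
    anchor_rows <- vapply(imp_genes, function(g) {
      ids <- long$probe_id[long$gene == g]
      match(ids[sample.int(length(ids), 1)], probes$probe_id)
    }, integer(1))
    apos <- probes$pos[anchor_rows]
    start0 <- pmax(0L, apos - 1L - sample.int(200L, n_imp, replace = TRUE))
    end0 <- apos + sample(200:2000, n_imp, replace = TRUE)
    icrs <- data.frame(
      chr = probes$chr[anchor_rows],
      start = start0,
      end = end0,
      gene = imp_genes,
      origin = sample(c("paternal", "maternal", "unknown"), n_imp,
                      replace = TRUE, prob = c(0.25, 0.28, 0.47)),
      stringsAsFactors = FALSE
    )
  }

  structure(list(probes = probes, imprinted = imprinted, icrs = icrs),
            class = "array_annotation")
}

#' Simulate a beta-value matrix with planted age effects
#'
#' Each probe is assigned a methylation subgroup, a baseline beta drawn from
#' that subgroup's archetype beta distribution, and (for a configured
#' fraction) a planted linear age effect on the M scale. Subject-level
#' M-values are `baseline + delta_m * (age - mean(age)) + N(0, sd)`, then
#' mapped back to beta via the inverse logistic, so all beta-values are
#' strictly inside (0, 1).
#'
#' @param annotation an `array_annotation` from [make_annotation()] (or its
#'   `$probes` data.frame).
#' @param covariates covariate table from [make_covariates()].
#' @param config a [generator_config()].
#' @return list with `beta` (probes x subjects matrix) and `truth`
#'   (`probe_id,planted,true_delta_m_per_year,true_subgroup`).
#' @export
make_beta_matrix <- function(annotation, covariates,
                             config = generator_config()) {
  if (!inherits(config, "generator_config")) stop2("`config` must be a generator_config")
  probes <- if (inherits(annotation, "array_annotation")) annotation$probes else annotation
  if (is.null(probes) || nrow(probes) == 0) stop2("`annotation` must contain probes")
  if (is.null(covariates) || nrow(covariates) == 0) stop2("`covariates` must be non-empty")
  if (anyDuplicated(probes$probe_id)) {
    stop2("duplicate probe ids in annotation: ",
          probes$probe_id[duplicated(probes$probe_id)][1])
  }
  set.seed(sub_seed(config$seed, 3L))

  n_probes <- nrow(probes)
  n_subjects <- nrow(covariates)
  groups <- c("UM", "HM", "FM")
  subgroup <- sample(groups, n_probes, replace = TRUE,
                     prob = config$subgroup_weights[groups])

  baseline_beta <- numeric(n_probes)
  for (g in groups) {
    idx <- subgroup == g
    arch <- config$beta_archetypes[[g]]
    a <- arch[["mean"]] * arch[["conc"]]
    b <- (1 - arch[["mean"]]) * arch[["conc"]]
    baseline_beta[idx] <- stats::rbeta(sum(idx), a, b)
  }
  baseline_m <- beta_to_m(baseline_beta)

  planted <- stats::runif(n_probes) < config$effect_fraction
  delta_m <- numeric(n_probes)
  n_pl <- sum(planted)
  if (n_pl > 0) {
    mag <- draw_effect_magnitudes(n_pl, config$effect_sizes)
    neg <- stats::runif(n_pl) < config$direction_probs[subgroup[planted]]
    delta_m[planted] <- ifelse(neg, -mag, mag)
  }

  age_c <- covariates$age - mean(covariates$age)
  m <- matrix(baseline_m, n_probes, n_subjects) +
    outer(delta_m, age_c) +
    matrix(stats::rnorm(n_probes * n_subjects, sd = config$residual_sd_m),
           n_probes, n_subjects)
  beta <- m_to_beta(m)
  dimnames(beta) <- list(probes$probe_id, covariates$subject_id)

  truth <- data.frame(
    probe_id = probes$probe_id,
    planted = planted,
    true_delta_m_per_year = delta_m,
    true_subgroup = subgroup,
    stringsAsFactors = FALSE
  )
  list(beta = beta, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [make_covariates()], [make_annotation()] and
#' [make_beta_matrix()] from one configuration.
#'
#' @param config a [generator_config()].
#' @return a `methylation_dataset` (see [load_dataset()]) with the
#'   generator's ground truth attached.
#' @export
simulate_dataset <- function(config = generator_config()) {
  covariates <- make_covariates(config$n_subjects, config)
  ann <- make_annotation(config$n_probes, config)
  bm <- make_beta_matrix(ann, covariates, config)
  structure(
    list(beta = bm$beta, covariates = covariates, annotation = ann$probes,
         icrs = ann$icrs, imprinted = ann$imprinted, gene_lists = NULL,
         truth = bm$truth, config = config),
    class = "methylation_dataset"
  )
}

#' Write a dataset to a fixture directory
#'
#' Emits `beta.tsv`, `covariates.csv`, `annotation.csv`, `icrs.bed`,
#' `imprinted.csv`, `truth.csv`, one `<name>.txt` per gene list, and a
#' `manifest.json` recording the generator seed. The file set round-trips
#' losslessly through [load_dataset()].
#'
#' @param dataset a `methylation_dataset`.
#' @param outdir output directory (created if absent).
#' @return invisibly, a named vector of written paths.
#' @export
write_fixture <- function(dataset, outdir) {
  if (is.null(dataset$beta) || nrow(dataset$beta) == 0) {
    stop2("dataset has no probes; nothing written")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop2("cannot create output directory ", outdir)

  paths <- c(beta = file.path(outdir, "beta.tsv"),
             covariates = file.path(outdir, "covariates.csv"),
             annotation = file.path(outdir, "annotation.csv"))
  write_beta_tsv(dataset$beta, paths["beta"])
  utils::write.csv(dataset$covariates, paths["covariates"], row.names = FALSE)
  utils::write.csv(dataset$annotation, paths["annotation"], row.names = FALSE)

  if (!is.null(dataset$icrs) && nrow(dataset$icrs) > 0) {
    paths["icrs"] <- file.path(outdir, "icrs.bed")
    bed <- data.frame(dataset$icrs$chr, dataset$icrs$start, dataset$icrs$end,
                      paste(dataset$icrs$gene, dataset$icrs$origin, sep = "|"),
                      0L, ".")
    utils::write.table(bed, paths["icrs"], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(dataset$imprinted)) {
    paths["imprinted"] <- file.path(outdir, "imprinted.csv")
    utils::write.csv(dataset$imprinted, paths["imprinted"], row.names = FALSE)
  }
  if (!is.null(dataset$truth)) {
    paths["truth"] <- file.path(outdir, "truth.csv")
    utils::write.csv(dataset$truth, paths["truth"], row.names = FALSE)
  }
  for (nm in names(dataset$gene_lists %||% list())) {
    p <- file.path(outdir, paste0(nm, ".txt"))
    writeLines(dataset$gene_lists[[nm]], p)
    paths[nm] <- p
  }
  paths["manifest"] <- file.path(outdir, "manifest.json")
  seed <- if (!is.null(dataset$config)) dataset$config$seed else NA_integer_
  jsonlite::write_json(
    list(seed = seed, n_probes = nrow(dataset$beta),
         n_subjects = ncol(dataset$beta),
         package_version = as.character(utils::packageVersion("spermage"))),
    paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
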